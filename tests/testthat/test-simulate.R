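test_that("karyotype inheritance follows Mendelian ZW segregation", {
  set.seed(42)
  # selfing an amphigenic hermaphrodite: 1 WW : 2 ZW : 1 ZZ, so
  # hermaphrodite (any W) : male = 3 : 1
  off <- inherit_karyotype("ZW", "SELF", n = 40000)
  herm <- sum(off != "ZZ")
  expect_gt(herm / (40000 - herm), 2.85)
  expect_lt(herm / (40000 - herm), 3.15)
  # monogenics self true
  expect_setequal(unique(inherit_karyotype("WW", "SELF", n = 1000)), "WW")
  # ZZ x ZW: half ZZ, half ZW
  off2 <- inherit_karyotype("ZZ", "ZW", n = 40000)
  expect_setequal(unique(off2), c("ZZ", "ZW"))
  expect_lt(abs(mean(off2 == "ZZ") - 0.5), 0.02)
  # males cannot self
  expect_error(inherit_karyotype("ZZ", "SELF"), "model error")
})

test_that("phenotype is a deterministic function of karyotype", {
  expect_identical(
    karyotype_phenotype(c("ZZ", "ZW", "WW"), "dioecious"),
    c("male", "female", "female")
  )
  expect_identical(
    karyotype_phenotype(c("ZZ", "ZW", "WW"), "androdioecious"),
    c("male", "hermaphrodite", "hermaphrodite")
  )
})

test_that("marker copy number tracks chromosome dose and null alleles", {
  expect_identical(assign_marker_copies("ZW", "W_specific"), 1L)
  expect_identical(assign_marker_copies("WW", "Z_specific"), 0L)
  expect_identical(assign_marker_copies("ZZ", "autosomal"), 2L)
  expect_identical(assign_marker_copies("ZZ", "Z_specific"), 2L)
  expect_identical(assign_marker_copies("WW", "W_specific"), 2L)
  expect_identical(assign_marker_copies("ZW", "shared_sexlinked", n_null = 1L), 1L)
  expect_identical(assign_marker_copies("ZZ", "autosomal", n_null = 2L), 0L)
})

test_that("read depth is proportional to copy number with the stated mean", {
  set.seed(99)
  expect_identical(unique(draw_depth(rep(0L, 500), 300)), 0L)
  d2 <- draw_depth(rep(2L, 10000), 300)
  expect_lt(abs(mean(d2) - 300) / 300, 0.03)
  d1 <- draw_depth(rep(1L, 10000), 300)
  expect_lt(abs(mean(d1) - 150) / 150, 0.03)
  expect_error(draw_depth(2L, 300, dispersion = 0), "config error")
  expect_error(draw_depth(2L, -5), "config error")
})

test_that("simulation is deterministic given the seed", {
  cfg <- study_cfg(seed = 5, n_autosomal = 30L)
  s1 <- simulate_population(cfg)
  s2 <- simulate_population(cfg)
  expect_identical(s1$catalogue$calls, s2$catalogue$calls)
  expect_identical(s1$truth, s2$truth)
})

test_that("W-specific markers are fully present in females, fully absent in males", {
  sim <- simulate_population(study_cfg(seed = 3, n_W_specific = 18L))
  truth <- sim$truth
  w_ids <- truth$markers$marker_id[truth$markers$category == "W_specific"]
  esp <- truth$individuals[truth$individuals$population == "ESP", ]
  dm <- depth_matrix(sim$catalogue)
  cm <- called_matrix(sim$catalogue)
  females <- esp$id[esp$karyotype == "ZW"]
  males <- esp$id[esp$karyotype == "ZZ"]
  expect_true(all(cm[w_ids, females]))
  expect_true(all(dm[w_ids, females] >= 15L))
  expect_true(all(dm[w_ids, males] == 0L))
})

test_that("one round of selfing amphigenic founders yields one third monogenics
           among hermaphrodite offspring", {
  sim <- simulate_population(sim_config(
    pop_specs = list(pop_spec(
      "KOE", "androdioecious", n_hermaphrodite = 400L,
      selfing_generations = 1L, fraction_monogenic_founders = 0,
      n_founders = 30L, brood_size = 40L
    )),
    architecture = sim_architecture(
      n_autosomal = 5L, n_W_specific = 0L, n_Z_specific = 0L,
      n_shared_sexlinked = 0L, n_ld_flanking = 0L
    ),
    seed = 21
  ))
  k <- sim$truth$individuals$karyotype
  expect_setequal(unique(k), c("WW", "ZW"))
  expect_lt(abs(mean(k == "WW") - 1 / 3), 0.05)
})

test_that("simulated coverage matches the dose expectations after normalization", {
  sim <- simulate_population(study_cfg(seed = 13, n_autosomal = 120L))
  cov <- normalize_depths(sim$catalogue)
  vm <- coverage_matrix(cov)
  truth <- sim$truth
  auto <- truth$markers$marker_id[truth$markers$category == "autosomal"]
  z_ids <- truth$markers$marker_id[truth$markers$category == "Z_specific"]
  zw <- truth$individuals$id[truth$individuals$karyotype == "ZW"]
  expect_gt(mean(vm[auto, ]), 0.95)
  expect_lt(mean(vm[auto, ]), 1.05)
  expect_gt(mean(vm[z_ids, zw]), 0.45)
  expect_lt(mean(vm[z_ids, zw]), 0.55)
})

test_that("flanking markers at r = 0 are fully associated with the sex
           chromosomes in a dioecious population", {
  sim <- simulate_population(sim_config(
    pop_specs = list(pop_spec("ESP", "dioecious", n_female = 15L, n_male = 15L)),
    architecture = sim_architecture(
      n_autosomal = 10L, n_W_specific = 0L, n_Z_specific = 0L,
      n_shared_sexlinked = 0L, n_ld_flanking = 4L
    ),
    r = 0, seed = 31
  ))
  gm <- genotype_matrix(sim$catalogue)
  truth <- sim$truth
  ld_ids <- truth$markers$marker_id[truth$markers$category == "ld_flanking"]
  females <- truth$individuals$id[truth$individuals$karyotype == "ZW"]
  males <- truth$individuals$id[truth$individuals$karyotype == "ZZ"]
  expect_true(all(gm[ld_ids, females] == "p/q"))
  expect_true(all(gm[ld_ids, males] == "q/q"))
})

test_that("invalid population specifications are rejected", {
  expect_error(pop_spec("P", "dioecious", n_female = 0, n_male = 5),
               "config error")
  expect_error(pop_spec("P", "androdioecious", n_hermaphrodite = 0),
               "config error")
  expect_error(pop_spec("P", "androdioecious", n_hermaphrodite = 5,
                        n_male = 2, selfing_generations = 0),
               "config error")
  expect_error(sim_architecture(n_autosomal = -1), "config error")
})
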