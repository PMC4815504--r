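test_that("W-specific discovery recovers exactly the planted markers in a
           dioecious population", {
  sim <- simulate_population(study_cfg(seed = 2, n_W_specific = 18L))
  d <- run_discovery(sim)
  truth <- sim$truth
  esp_calls <- d$eval$calls[d$eval$calls$population == "ESP", ]
  found_w <- esp_calls$marker_id[esp_calls$category == "W_specific"]
  planted_w <- truth$markers$marker_id[truth$markers$category == "W_specific"]
  expect_setequal(found_w, planted_w)
  expect_length(found_w, 18L)
})

test_that("a marker present in everyone is never chromosome-specific", {
  sim <- simulate_population(study_cfg(seed = 4))
  cat2 <- sim$catalogue
  cov <- normalize_depths(cat2)
  esp <- cat2$individuals[cat2$individuals$population == "ESP", ]
  females <- esp$id[esp$phenotype == "female"]
  males <- esp$id[esp$phenotype == "male"]
  calls <- find_chromosome_specific(cat2, cov, females, males)
  auto <- sim$truth$markers$marker_id[sim$truth$markers$category == "autosomal"]
  expect_length(intersect(calls$marker_id, auto), 0L)
  expect_error(
    find_chromosome_specific(cat2, cov, females, c(males, females[1])),
    "overlap"
  )
})

test_that("Z-specific discovery uses monogenic hermaphrodites as the
           contrast group", {
  sim <- simulate_population(study_cfg(seed = 6, n_Z_specific = 11L))
  d <- run_discovery(sim)
  truth <- sim$truth
  koe_calls <- d$eval$calls[d$eval$calls$population == "KOE", ]
  found_z <- koe_calls$marker_id[koe_calls$category == "Z_specific"]
  planted_z <- truth$markers$marker_id[truth$markers$category == "Z_specific"]
  expect_setequal(found_z, planted_z)
  expect_length(found_z, 11L)
})

test_that("segregation discovery recovers shared sex-linked markers with
           the correct W/Z phase", {
  sim <- simulate_population(study_cfg(seed = 10, n_shared_sexlinked = 21L))
  d <- run_discovery(sim)
  truth <- sim$truth
  planted <- truth$markers$marker_id[truth$markers$category == "shared_sexlinked"]
  for (pop in c("ESP", "KOE")) {
    pc <- d$eval$calls[d$eval$calls$population == pop, ]
    found <- pc[pc$category == "sexlinked_alleles", ]
    expect_setequal(found$marker_id, planted)
    expect_true(all(found$w_allele == "W"))
    expect_true(all(found$z_allele == "Z"))
  }
})

test_that("monomorphic markers and non-qualifying patterns are not called
           sex-linked", {
  depths <- matrix(300L, 3, 4,
                   dimnames = list(c("mono", "badhet", "good"),
                                   c("f1", "f2", "m1", "m2")))
  genos <- rbind(
    mono = rep("a/a", 4),
    badhet = c("a/b", "a/a", "a/a", "a/a"),   # not het in all ZW
    good = c("w/z", "w/z", "z/z", "z/z")
  )
  cat1 <- toy_catalogue(depths, genos,
                        phenotypes = c("female", "female", "male", "male"))
  res <- find_sexlinked_alleles(
    cat1, groups = list(ZW = c("f1", "f2"), ZZ = c("m1", "m2"))
  )
  expect_identical(res$marker_id, "good")
  expect_identical(res$w_allele, "w")
  expect_identical(res$z_allele, "z")
  expect_error(
    find_sexlinked_alleles(cat1, groups = list(c("f1"), c("m1"))),
    "precondition error"
  )
})

test_that("hermaphrodite classification thresholds the mean W coverage", {
  cov <- tibble::tibble(
    marker_id = rep(c("w1", "w2"), each = 3),
    individual_id = rep(c("h1", "h2", "h3"), 2),
    value = c(1.0, 0.5, 0.75, 1.0, 0.5, 0.75)
  )
  cl <- classify_hermaphrodites(cov, c("w1", "w2"), c("h1", "h2", "h3"))
  expect_identical(cl$karyotype_call,
                   c("monogenic_WW", "amphigenic_ZW", "ambiguous"))
  expect_error(classify_hermaphrodites(cov, character(), "h1"),
               "precondition error")
})

test_that("simulated hermaphrodites classify 15/15 with no ambiguity", {
  cfg <- study_cfg(seed = 12, n_W_specific = 2L)
  cfg$lambda_range <- c(300, 300)
  sim <- simulate_population(cfg)
  d <- run_discovery(sim)
  cl <- d$eval$hermaphrodites$KOE
  truth_k <- sim$truth$individuals
  expect_identical(nrow(cl), 15L)
  expect_false(any(cl$karyotype_call == "ambiguous"))
  called_ww <- cl$individual_id[cl$karyotype_call == "monogenic_WW"]
  true_ww <- truth_k$id[truth_k$karyotype == "WW" &
                          truth_k$population == "KOE"]
  expect_setequal(called_ww, true_ww)
})

test_that("no marker is assigned to more than one category", {
  sim <- simulate_population(study_cfg(seed = 16))
  d <- run_discovery(sim)
  classified <- d$eval$calls[d$eval$calls$category != "unclassified", ]
  per_pop <- split(classified, classified$population)
  for (pc in per_pop) {
    expect_identical(anyDuplicated(pc$marker_id), 0L)
  }
})

test_that("the XY mirror model finds nothing in ZW data, and swapping
           phenotype labels restores the ZW result under XY", {
  sim <- simulate_population(sim_config(
    pop_specs = list(pop_spec("ESP", "dioecious", n_female = 12L, n_male = 14L)),
    architecture = sim_architecture(
      n_autosomal = 60L, n_W_specific = 5L, n_Z_specific = 0L,
      n_shared_sexlinked = 5L, n_ld_flanking = 0L
    ),
    seed = 18
  ))
  cat2 <- remove_repetitive(filter_high_coverage(sim$catalogue))
  cov <- normalize_depths(cat2)
  ev_zw <- evaluate_model(cat2, cov, segregation_model("female_ZW"))
  ev_xy <- evaluate_model(cat2, cov, segregation_model("male_XY"))
  expect_identical(sum(ev_xy$summary$n_total), 0L)
  expect_identical(sum(ev_zw$summary$n_total), 10L)

  # relabel phenotypes male <-> female: under male_XY the same
  # individuals play the same roles, so results must match exactly
  swapped <- cat2
  swapped$individuals$phenotype <-
    c(male = "female", female = "male")[swapped$individuals$phenotype]
  ev_sw <- evaluate_model(swapped, cov, segregation_model("male_XY"))
  expect_identical(ev_sw$summary$n_W_specific, ev_zw$summary$n_W_specific)
  expect_identical(ev_sw$summary$n_sexlinked_alleles,
                   ev_zw$summary$n_sexlinked_alleles)
  expect_setequal(ev_sw$calls$marker_id, ev_zw$calls$marker_id)
})

test_that("a shared marker with a Z-lineage null allele escapes the strict
           segregation criteria", {
  sim <- simulate_population(study_cfg(seed = 20, n_shared_sexlinked = 4L,
                                       n_shared_z_null = 1L))
  truth <- sim$truth$markers
  null_id <- truth$marker_id[truth$z_null]
  clean_ids <- truth$marker_id[truth$category == "shared_sexlinked" & !truth$z_null]
  # sanity: at least one ESP female actually carries the null Z
  esp_f <- sim$truth$individuals$id[
    sim$truth$individuals$population == "ESP" &
      sim$truth$individuals$karyotype == "ZW"
  ]
  gm <- genotype_matrix(sim$catalogue)
  expect_true(any(gm[null_id, esp_f] == "W/W", na.rm = TRUE))

  d <- run_discovery(sim)
  esp_calls <- d$eval$calls[d$eval$calls$population == "ESP", ]
  found <- esp_calls$marker_id[esp_calls$category == "sexlinked_alleles"]
  expect_false(null_id %in% found)
  expect_true(all(clean_ids %in% found))
})

test_that("tidy and glance expose calls and counts", {
  sim <- simulate_population(study_cfg(seed = 22, n_autosomal = 30L))
  d <- run_discovery(sim)
  td <- tidy(d$eval)
  gl <- glance(d$eval)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("marker_id", "category", "population") %in% names(td)))
  expect_identical(gl$population, c("ESP", "KOE"))
  expect_identical(gl$n_total,
                   gl$n_W_specific + gl$n_Z_specific + gl$n_sexlinked_alleles)
})
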