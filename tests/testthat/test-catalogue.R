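test_that("catalogue TSV round-trips, preserving the missingness pattern", {
  # 2-marker, 3-individual toy with exactly one missing cell
  lines <- c(
    "marker_id\ti1\ti2\ti3",
    "m1\ta/a:30\ta/b:25\t./.:4",
    "m2\tc/c:40\tc/c:18\tc/c:22"
  )
  catf <- withr::local_tempfile(fileext = ".tsv")
  metaf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(lines, catf)
  readr::write_tsv(tibble::tibble(
    id = c("i1", "i2", "i3"), population = "P1",
    phenotype = c("female", "female", "male")
  ), metaf)

  cat1 <- read_catalogue(catf, metaf)
  expect_identical(dim(depth_matrix(cat1)), c(2L, 3L))
  expect_identical(sum(!called_matrix(cat1)), 1L)
  expect_identical(depth_matrix(cat1)["m1", "i3"], 4L)

  out_cat <- withr::local_tempfile(fileext = ".tsv")
  out_meta <- withr::local_tempfile(fileext = ".tsv")
  write_catalogue(cat1, out_cat, out_meta)
  cat2 <- read_catalogue(out_cat, out_meta)
  expect_identical(cat2$calls, cat1$calls)
  expect_identical(cat2$individuals, cat1$individuals)
})

test_that("default-scale simulator output parses with zero validation errors", {
  sim <- simulate_population(sim_config(seed = 1))
  expect_identical(dim(depth_matrix(sim$catalogue)), c(3822L, 47L))
  paths <- write_simulation(sim, file.path(withr::local_tempdir(), "sim"))
  reread <- read_catalogue(paths[1], paths[2])
  expect_identical(reread$calls, sim$catalogue$calls)
})

test_that("malformed inputs fail with informative errors", {
  tmp <- withr::local_tempdir()
  metaf <- file.path(tmp, "meta.tsv")
  readr::write_tsv(tibble::tibble(
    id = "i1", population = "P1", phenotype = "male"
  ), metaf)

  badhdr <- file.path(tmp, "badhdr.tsv")
  writeLines(c("locus\ti1", "m1\ta/a:30"), badhdr)
  expect_error(read_catalogue(badhdr, metaf), "line 1")

  nometa <- file.path(tmp, "nometa.tsv")
  writeLines(c("marker_id\ti1\ti2", "m1\ta/a:30\ta/a:30"), nometa)
  expect_error(read_catalogue(nometa, metaf), "metadata error.*i2")

  negdep <- file.path(tmp, "negdep.tsv")
  writeLines(c("marker_id\ti1", "m1\ta/a:-3"), negdep)
  expect_error(read_catalogue(negdep, metaf), "validation error")

  badcell <- file.path(tmp, "badcell.tsv")
  writeLines(c("marker_id\ti1", "m1\taa:30"), badcell)
  expect_error(read_catalogue(badcell, metaf), "format error.*m1")
})

test_that("catalogue constructor enforces its invariants", {
  calls <- tibble::tibble(
    marker_id = "m1", individual_id = "i1",
    allele_a = "a", allele_b = "a", depth = 10L
  )
  inds <- tibble::tibble(id = "i1", population = "P", phenotype = "male")
  # genotype call below the call threshold in force
  expect_error(rad_catalogue(calls, inds), "call")
  expect_s3_class(rad_catalogue(calls, inds, call_threshold = 10L),
                  "rad_catalogue")
  # one-sided genotype
  calls2 <- dplyr::mutate(calls, allele_b = NA, depth = 30L)
  expect_error(rad_catalogue(calls2, inds), "both alleles")
  # females and hermaphrodites may not share a population
  inds3 <- tibble::tibble(
    id = c("i1", "i2"), population = "P",
    phenotype = c("female", "hermaphrodite")
  )
  calls3 <- tibble::tibble(
    marker_id = "m1", individual_id = c("i1", "i2"),
    allele_a = "a", allele_b = "a", depth = 30L
  )
  expect_error(rad_catalogue(calls3, inds3), "dioecious|androdioecious")
})

test_that("genepop export encodes genotypes and populations exactly", {
  depths <- matrix(30L, 1, 3, dimnames = list("m1", c("i1", "i2", "i3")))
  genos <- matrix(c("a1/a2", "a1/a1", "a2/a2"), 1, 3)
  cat1 <- toy_catalogue(depths, genos,
                        populations = c("A", "A", "B"),
                        phenotypes = c("female", "male", "male"))
  gp <- withr::local_tempfile()
  write_genepop(cat1, path = gp, title = "t")
  lines <- readLines(gp)
  expect_identical(sum(lines == "Pop"), 2L)
  expect_match(lines[lines != "Pop"][2], "^m1$")
  expect_match(grep("^i1", lines, value = TRUE), "i1 , 001002$")
  expect_match(grep("^i3", lines, value = TRUE), "i3 , 002002$")
})

test_that("genepop export excludes markers with missing genotypes", {
  depths <- matrix(c(30L, 30L, 30L, 4L), 2, 2,
                   dimnames = list(c("m1", "m2"), c("i1", "i2")))
  genos <- matrix(c("a/a", "b/b", "a/b", NA), 2, 2)
  cat1 <- toy_catalogue(depths, genos)
  gp <- withr::local_tempfile()
  # default marker choice drops m2 (missing in i2)
  write_genepop(cat1, path = gp)
  expect_false("m2" %in% readLines(gp))
  # asking for it explicitly is a precondition error
  expect_error(write_genepop(cat1, markers = c("m1", "m2"), path = gp),
               "precondition error")
})

test_that("genepop export of a simulated selfing population survives an
           independent re-parse with identical genotype counts", {
  sim <- simulate_population(sim_config(
    pop_specs = list(pop_spec("KOE", "androdioecious",
                              n_hermaphrodite = 10L, n_male = 3L,
                              selfing_generations = 2L)),
    architecture = sim_architecture(
      n_autosomal = 30L, n_W_specific = 0L, n_Z_specific = 0L,
      n_shared_sexlinked = 0L, n_ld_flanking = 0L
    ),
    prop_polymorphic = 1, seed = 11
  ))
  gp <- withr::local_tempfile()
  write_genepop(sim$catalogue, path = gp)
  parsed <- parse_genepop_minimal(gp)
  gm <- genotype_matrix(sim$catalogue)
  # reconstruct genotype strings from the parsed 3-digit codes and
  # compare per-marker genotype count tables
  for (m in unique(parsed$marker)) {
    codes <- parsed$code[parsed$marker == m]
    expect_false(any(codes == "000000"))
    orig <- table(gm[m, ])
    enc <- table(paste(substr(codes, 1, 3), substr(codes, 4, 6)))
    expect_identical(unname(sort(as.vector(orig))),
                     unname(sort(as.vector(enc))))
  }
})
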