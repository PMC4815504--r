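# Shared fixtures and small independent oracles used across tests.

`%||%` <- function(x, y) if (is.null(x)) y else x

# A compact two-population study: dioecious 12F/14M plus androdioecious
# with a fixed 4 WW / 11 ZW / 6 ZZ composition, small autosome count.
study_cfg <- function(seed, n_autosomal = 60L, n_W_specific = 5L,
                      n_Z_specific = 4L, n_shared_sexlinked = 5L,
                      n_ld_flanking = 0L, n_shared_z_null = 0L) {
  sim_config(
    pop_specs = list(
      pop_spec("ESP", "dioecious", n_female = 12L, n_male = 14L),
      pop_spec("KOE", "androdioecious",
               n_by_karyotype = c(WW = 4L, ZW = 11L, ZZ = 6L),
               selfing_generations = 3L,
               fraction_monogenic_founders = 0.25)
    ),
    architecture = sim_architecture(
      n_autosomal = n_autosomal, n_W_specific = n_W_specific,
      n_Z_specific = n_Z_specific, n_shared_sexlinked = n_shared_sexlinked,
      n_ld_flanking = n_ld_flanking, n_shared_z_null = n_shared_z_null
    ),
    seed = seed
  )
}

# filter -> normalize -> evaluate, returning everything recovery tests need
run_discovery <- function(sim, model = segregation_model("female_ZW")) {
  cat2 <- remove_repetitive(filter_high_coverage(sim$catalogue))
  cov <- normalize_depths(cat2)
  list(catalogue = cat2, cov = cov,
       eval = evaluate_model(cat2, cov, model))
}

# hand-rolled catalogue builder: depth matrix + optional genotype matrix
# (list of "a/b" strings or NA), default genotype called wherever depth
# >= threshold with a constant homozygous genotype
toy_catalogue <- function(depths, genotypes = NULL, populations = NULL,
                          phenotypes = NULL, call_threshold = 15L) {
  n_m <- nrow(depths)
  n_i <- ncol(depths)
  marker_id <- rownames(depths) %||% paste0("m", seq_len(n_m))
  ind_id <- colnames(depths) %||% paste0("i", seq_len(n_i))
  if (is.null(genotypes)) {
    genotypes <- ifelse(depths >= call_threshold, "x/x", NA)
  }
  parts <- strsplit(ifelse(is.na(genotypes), "NA/NA", genotypes), "/")
  a <- vapply(parts, `[`, "", 1L)
  b <- vapply(parts, `[`, "", 2L)
  a[a == "NA"] <- NA
  b[b == "NA"] <- NA
  calls <- tibble::tibble(
    marker_id = rep(marker_id, times = n_i),
    individual_id = rep(ind_id, each = n_m),
    allele_a = as.vector(a), allele_b = as.vector(b),
    depth = as.integer(as.vector(depths))
  )
  inds <- tibble::tibble(
    id = ind_id,
    population = populations %||% rep("P1", n_i),
    phenotype = phenotypes %||% rep("female", n_i)
  )
  rad_catalogue(calls, inds, call_threshold = call_threshold)
}

# Minimal, independent Genepop reader used as the round-trip oracle:
# returns a long tibble (population, individual_id, marker, code).
parse_genepop_minimal <- function(path) {
  lines <- readLines(path)
  pop_idx <- which(lines == "Pop")
  markers <- lines[2:(pop_idx[1] - 1)]
  out <- list()
  bounds <- c(pop_idx, length(lines) + 1L)
  for (p in seq_along(pop_idx)) {
    rows <- lines[(bounds[p] + 1L):(bounds[p + 1L] - 1L)]
    for (row in rows) {
      halves <- strsplit(row, " , ", fixed = TRUE)[[1]]
      codes <- strsplit(trimws(halves[2]), " +")[[1]]
      stopifnot(length(codes) == length(markers))
      out[[length(out) + 1L]] <- tibble::tibble(
        population = p, individual_id = halves[1],
        marker = markers, code = codes
      )
    }
  }
  dplyr::bind_rows(out)
}
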