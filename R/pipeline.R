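#' End-to-end discovery run
#'
#' Executes the fixed stage order on either a simulation configuration
#' or a catalogue already on disk: coverage filtering (high-coverage /
#' repeat filters), per-individual normalization, sex-linkage discovery
#' under the requested heterogametic model(s) (W-specific search,
#' hermaphrodite classification where applicable, Z-specific search,
#' SNP-segregation search), an optional genotypic LD screen per
#' population with the sex-linked-pair summary, population
#' differentiation and polymorphism summaries, and the restriction-site
#' region-size arithmetic. Every stage's tables are written to
#' `out_dir` as TSV/JSON and collected in the returned bundle; given the
#' same configuration and seed the outputs are byte-identical.
#'
#' @param sim A [sim_config()] to simulate from (exclusive with
#'   `catalogue_path`).
#' @param catalogue_path,metadata_path TSV inputs as read by
#'   [read_catalogue()] (exclusive with `sim`).
#' @param out_dir Output directory, created if needed.
#' @param model `"female_ZW"`, `"male_XY"` or `"both"`.
#' @param alpha,n_perm LD screen parameters.
#' @param ld Run the pairwise LD screen (quadratic in the number of
#'   polymorphic markers; disable for large catalogues).
#' @param gc_content,motif Inputs of the region-size arithmetic.
#' @param min_depth,min_individuals High-coverage filter parameters.
#' @param seed Seed recorded in the bundle and used for every stochastic
#'   stage (simulation and LD permutations).
#' @return Invisibly, a list with elements `catalogue`, `normalized`,
#'   `filter_report`, `models` (one `zw_model_eval` per hypothesis),
#'   `ld`, `popgen`, `regionsize`, and `paths` of all files written.
#' @export
run_pipeline <- function(sim = NULL, catalogue_path = NULL,
                         metadata_path = NULL, out_dir,
                         model = c("female_ZW", "male_XY", "both"),
                         alpha = 0.05, n_perm = 999L, ld = TRUE,
                         gc_content = 0.47, motif = "CCTGCAGG",
                         min_depth = 20L, min_individuals = 6L,
                         seed = 1L) {
  model <- match.arg(model)
  if (is.null(sim) == is.null(catalogue_path)) {
    abort("config error: supply exactly one of `sim` or `catalogue_path`.")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  emit_tsv <- function(x, name) {
    p <- file.path(out_dir, name)
    readr::write_tsv(tibble::as_tibble(x), p)
    paths[[name]] <<- p
  }
  emit_json <- function(x, name) {
    p <- file.path(out_dir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths[[name]] <<- p
  }

  set.seed(seed)
  if (!is.null(sim)) {
    sim$seed <- sim$seed %||% seed
    sim_out <- simulate_population(sim)
    cat0 <- sim_out$catalogue
    write_catalogue(cat0, file.path(out_dir, "catalogue.tsv"),
                    file.path(out_dir, "metadata.tsv"))
    paths[["catalogue.tsv"]] <- file.path(out_dir, "catalogue.tsv")
    paths[["metadata.tsv"]] <- file.path(out_dir, "metadata.tsv")
    emit_tsv(sim_out$truth$markers, "truth_markers.tsv")
    emit_tsv(sim_out$truth$individuals, "truth_individuals.tsv")
  } else {
    cat0 <- read_catalogue(catalogue_path, metadata_path)
  }

  cat1 <- filter_high_coverage(cat0, min_depth = min_depth,
                               min_individuals = min_individuals)
  cat2 <- remove_repetitive(cat1)
  cov <- normalize_depths(cat2)
  rep <- filter_report(cat2, cov)
  emit_json(list(steps = as.list(rep$steps),
                 reference_set_size = rep$reference_set_size,
                 per_individual_reference_median =
                   rep$per_individual_reference_median),
            "filter_report.json")
  emit_tsv(cov, "normalized_coverage.tsv")

  hypotheses <- if (model == "both") c("female_ZW", "male_XY") else model
  evals <- list()
  for (h in hypotheses) {
    ev <- evaluate_model(cat2, cov, segregation_model(h))
    evals[[h]] <- ev
    emit_tsv(ev$calls, paste0("sexlink_calls_", h, ".tsv"))
    emit_tsv(ev$summary, paste0("sexlink_summary_", h, ".tsv"))
  }
  zw <- evals[["female_ZW"]] %||% evals[[1]]
  sexlinked_ids <- unique(
    zw$calls$marker_id[zw$calls$category %in%
                         c("W_specific", "Z_specific", "sexlinked_alleles")]
  )

  ld_out <- NULL
  if (ld) {
    ld_out <- list()
    for (pop in unique(cat2$individuals$population)) {
      scr <- ld_screen(cat2, population = pop, alpha = alpha, n_perm = n_perm)
      ld_out[[pop]] <- list(
        results = scr,
        proportion_significant = attr(scr, "proportion_significant"),
        sexlinked = summarize_sexlinked_pairs(scr, sexlinked_ids)
      )
      emit_tsv(scr, paste0("ld_", pop, ".tsv"))
    }
    emit_json(purrr::map(ld_out, function(x) {
      list(n_pairs_tested = attr(x$results, "n_pairs_tested"),
           proportion_significant = x$proportion_significant,
           sexlinked = x$sexlinked)
    }), "ld_summary.json")
  }

  pops <- unique(cat2$individuals$population)
  popgen <- list(polymorphism = polymorphism_summary(cat2))
  if (length(pops) >= 2L) {
    popgen$fst <- fst_weir_cockerham(cat2, populations = pops[1:2])
  }
  emit_tsv(popgen$polymorphism, "polymorphism.tsv")
  emit_json(list(
    polymorphism = as.list(popgen$polymorphism),
    fst = if (!is.null(popgen$fst)) glance(popgen$fst)$fst,
    fst_n_loci = if (!is.null(popgen$fst)) popgen$fst$n_loci
  ), "popgen.json")

  spacing <- expected_spacing(site_probability(motif, gc_content))
  region <- purrr::map(
    split(zw$summary, zw$summary$population),
    function(s) region_extent(spacing, n_markers = s$n_total)
  )
  emit_json(list(
    motif = motif, gc_content = gc_content,
    p_site = spacing$p_site, spacing_kb = spacing$spacing_kb,
    spacing_rounded_kb = spacing$spacing_rounded_kb,
    extent_by_population = region
  ), "regionsize.json")

  emit_json(list(
    seed = seed, model = model, alpha = alpha, n_perm = n_perm,
    min_depth = min_depth, min_individuals = min_individuals,
    gc_content = gc_content, motif = motif,
    simulated = !is.null(sim)
  ), "run_config.json")

  invisible(list(
    catalogue = cat2, normalized = cov, filter_report = rep,
    models = evals, ld = ld_out, popgen = popgen,
    regionsize = list(spacing = spacing, extent_by_population = region),
    paths = paths
  ))
}
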