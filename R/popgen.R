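#' Weir-Cockerham F(ST) between two populations
#'
#' The variance-components estimator of Weir & Cockerham (1984) for
#' diploid genotype data: per locus and allele, the among-population
#' (a), among-individual-within-population (b) and within-individual (c)
#' components are computed from sample sizes, allele frequencies and
#' observed heterozygosity, and the multilocus estimate is the ratio of
#' sums `sum(a) / sum(a + b + c)` across loci (loci monomorphic over
#' both populations contribute zero to every component). Negative
#' estimates are reported as computed, not truncated.
#'
#' @param cat A [rad_catalogue] containing (at least) two populations.
#' @param populations Length-2 character vector of population labels;
#'   default the first two in the catalogue.
#' @param loci Marker ids to use; default (AUTO) all markers genotyped
#'   in every individual of at least one of the two populations.
#' @return A `rad_fst` object: list with `fst` (multilocus estimate),
#'   `n_loci`, and `per_locus` (tibble of `marker_id`, `a`, `b`, `c`,
#'   and the per-locus ratio `fst`).
#' @export
fst_weir_cockerham <- function(cat, populations = NULL, loci = NULL) {
  inds <- cat$individuals
  populations <- populations %||% unique(inds$population)[1:2]
  stopifnot(length(populations) == 2L,
            all(populations %in% inds$population))
  ids1 <- inds$id[inds$population == populations[1]]
  ids2 <- inds$id[inds$population == populations[2]]
  if (length(ids1) < 2L || length(ids2) < 2L) {
    abort("each population needs at least 2 individuals.")
  }
  cm <- called_matrix(cat)
  if (is.null(loci)) {
    all1 <- rowSums(cm[, ids1, drop = FALSE]) == length(ids1)
    all2 <- rowSums(cm[, ids2, drop = FALSE]) == length(ids2)
    loci <- rownames(cm)[all1 | all2]
  }
  stopifnot(all(loci %in% rownames(cm)))
  calls <- cat$calls |>
    dplyr::filter(.data$marker_id %in% loci,
                  .data$individual_id %in% c(ids1, ids2),
                  !is.na(.data$allele_a)) |>
    dplyr::mutate(pop = ifelse(.data$individual_id %in% ids1, 1L, 2L))
  if (nrow(calls) == 0L) abort("no genotype calls at the requested loci.")
  by_pop_ok <- calls |>
    dplyr::distinct(.data$marker_id, .data$pop) |>
    dplyr::count(.data$pop)
  if (nrow(by_pop_ok) < 2L) {
    abort("a population has no genotype calls at any locus.")
  }

  per_locus <- calls |>
    dplyr::group_by(.data$marker_id) |>
    dplyr::group_modify(~ .wc_locus(.x)) |>
    dplyr::ungroup()
  denom <- per_locus$a + per_locus$b + per_locus$c
  fst <- sum(per_locus$a) / sum(denom)
  structure(
    list(
      fst = fst,
      n_loci = nrow(per_locus),
      populations = populations,
      per_locus = dplyr::mutate(
        per_locus,
        fst = ifelse(denom > 0, .data$a / denom, NA_real_)
      )
    ),
    class = "rad_fst"
  )
}

# Weir & Cockerham (1984) variance components for one locus.
# df columns: individual_id, allele_a, allele_b, pop (1/2).
.wc_locus <- function(df) {
  r <- 2L
  n_i <- tapply(df$pop, df$pop, length)
  if (length(n_i) < 2L || any(n_i < 1L)) {
    return(tibble::tibble(a = 0, b = 0, c = 0))
  }
  alleles <- unique(c(df$allele_a, df$allele_b))
  if (length(alleles) < 2L) {
    return(tibble::tibble(a = 0, b = 0, c = 0))
  }
  nbar <- mean(n_i)
  n_c <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  a_tot <- b_tot <- c_tot <- 0
  for (al in alleles) {
    cnt <- (df$allele_a == al) + (df$allele_b == al)
    het <- (df$allele_a == al) != (df$allele_b == al)
    p_i <- tapply(cnt, df$pop, sum) / (2 * n_i)
    h_i <- tapply(het, df$pop, mean)
    pbar <- sum(n_i * p_i) / (r * nbar)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    a <- (nbar / n_c) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    c <- hbar / 2
    a_tot <- a_tot + a
    b_tot <- b_tot + b
    c_tot <- c_tot + c
  }
  tibble::tibble(a = a_tot, b = b_tot, c = c_tot)
}

#' @export
print.rad_fst <- function(x, ...) {
  cat("<rad_fst> ", paste(x$populations, collapse = " vs "),
      ": FST = ", format(x$fst, digits = 4),
      " over ", x$n_loci, " loci\n", sep = "")
  invisible(x)
}

#' @describeIn fst_weir_cockerham Per-locus variance components and
#'   ratios as a tibble.
#' @param x A `rad_fst` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.rad_fst <- function(x, ...) x$per_locus

#' @describeIn fst_weir_cockerham One-row multilocus summary.
#' @exportS3Method generics::glance
glance.rad_fst <- function(x, ...) {
  tibble::tibble(
    population_1 = x$populations[1], population_2 = x$populations[2],
    fst = x$fst, n_loci = x$n_loci
  )
}

#' Within-population marker polymorphism summary
#'
#' A marker counts as polymorphic when at least two alleles are observed
#' among the population's genotype calls; markers with no call in the
#' population are not scored.
#'
#' @param cat A [rad_catalogue].
#' @param population Population label (default: each population in the
#'   catalogue, one row per population).
#' @return Tibble: `population`, `n_markers` (scored), `n_polymorphic`,
#'   `proportion`.
#' @export
polymorphism_summary <- function(cat, population = NULL) {
  pops <- population %||% unique(cat$individuals$population)
  purrr::map_dfr(pops, function(pop) {
    ids <- cat$individuals$id[cat$individuals$population == pop]
    tab <- cat$calls |>
      dplyr::filter(.data$individual_id %in% ids, !is.na(.data$allele_a)) |>
      dplyr::group_by(.data$marker_id) |>
      dplyr::summarise(
        n_alleles = dplyr::n_distinct(c(.data$allele_a, .data$allele_b)),
        .groups = "drop"
      )
    tibble::tibble(
      population = pop,
      n_markers = nrow(tab),
      n_polymorphic = sum(tab$n_alleles >= 2L),
      proportion = if (nrow(tab) > 0L) sum(tab$n_alleles >= 2L) / nrow(tab) else NA_real_
    )
  })
}
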