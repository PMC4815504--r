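#' G statistic of a two-locus genotype contingency table
#'
#' The log-likelihood-ratio statistic of independence,
#' `2 * sum(O * log(O / E))` over non-empty cells, on the genotype x
#' genotype table of two loci.
#'
#' @param tab A contingency table (matrix of counts).
#' @return The G statistic (numeric scalar).
#' @export
g_statistic <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  keep <- tab > 0
  2 * sum(tab[keep] * log(tab[keep] / e[keep]))
}

#' Genotypic linkage-disequilibrium permutation test for one marker pair
#'
#' Tests the null hypothesis that genotypes at two loci are independent,
#' as population LD screens on unphased data do: the genotype x genotype
#' contingency table is summarized by the G (log-likelihood-ratio)
#' statistic and its null distribution obtained by permuting one locus's
#' genotypes across individuals. The returned p-value uses the add-one
#' correction `(1 + #{G_perm >= G_obs}) / (n_perm + 1)`. Individuals
#' missing a genotype at either locus are excluded; a locus monomorphic
#' among the remaining individuals is not testable.
#'
#' @param g1,g2 Genotype vectors (character strings such as `"a/b"`, or
#'   factors), one entry per individual, `NA` for missing.
#' @param n_perm Number of permutations.
#' @return One-row tibble: `statistic`, `p_value`, `n_individuals`,
#'   `testable`. For an untestable pair `statistic` and `p_value` are
#'   `NA`.
#' @export
#' @examples
#' set.seed(7)
#' g1 <- sample(c("a/a", "a/b", "b/b"), 30, replace = TRUE)
#' genotypic_ld_test(g1, g1, n_perm = 99)$p_value  # 1/100
genotypic_ld_test <- function(g1, g2, n_perm = 10000L) {
  keep <- !is.na(g1) & !is.na(g2)
  g1 <- as.character(g1[keep])
  g2 <- as.character(g2[keep])
  # canonical observation order: the test is exchangeable over
  # individuals, and sorting makes the permutation stream (hence the
  # realized p-value) invariant to how the input rows were ordered
  ord <- order(g1, g2)
  g1 <- factor(g1[ord])
  g2 <- factor(g2[ord])
  if (nlevels(g1) < 2L || nlevels(g2) < 2L || length(g1) == 0L) {
    return(tibble::tibble(
      statistic = NA_real_, p_value = NA_real_,
      n_individuals = length(g1), testable = FALSE
    ))
  }
  res <- ld_perm_core(as.integer(g1) - 1L, as.integer(g2) - 1L,
                      as.integer(n_perm))
  tibble::tibble(
    statistic = res$statistic, p_value = res$p_value,
    n_individuals = length(g1), testable = TRUE
  )
}

#' Screen all marker pairs of a population for genotypic LD
#'
#' Restricted - as population-level Genepop-style screens are - to
#' markers genotyped in every individual of the population; pairs where
#' either locus is monomorphic are excluded from the testable
#' denominator. All remaining unordered pairs are permutation-tested.
#'
#' @param cat A [rad_catalogue].
#' @param population Population label to screen.
#' @param alpha Significance level applied to raw p-values.
#' @param n_perm Permutations per pair.
#' @param markers Optional explicit marker subset (still subject to the
#'   genotyped-in-all restriction).
#' @param adjust If `"BH"`, adds a Benjamini-Hochberg adjusted
#'   `p_adjusted` column and bases `significant` on it.
#' @return A `rad_ld` tibble: `marker_a`, `marker_b` (pair order
#'   canonicalized `a < b`), `statistic`, `p_value`, `n_individuals`,
#'   `significant`; attributes `n_pairs_tested` and
#'   `proportion_significant`.
#' @export
ld_screen <- function(cat, population = NULL, alpha = 0.05, n_perm = 10000L,
                      markers = NULL, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  inds <- cat$individuals
  if (!is.null(population)) {
    inds <- inds[inds$population == population, , drop = FALSE]
  }
  gm <- genotype_matrix(cat)[, inds$id, drop = FALSE]
  if (!is.null(markers)) gm <- gm[intersect(rownames(gm), markers), , drop = FALSE]
  complete <- rowSums(is.na(gm)) == 0L
  n_distinct_geno <- apply(gm, 1L, function(x) length(unique(x[!is.na(x)])))
  use <- rownames(gm)[complete & n_distinct_geno >= 2L]
  empty <- tibble::tibble(
    marker_a = character(), marker_b = character(), statistic = double(),
    p_value = double(), n_individuals = integer(), significant = logical()
  )
  if (length(use) < 2L) {
    warn("fewer than 2 polymorphic fully-genotyped markers; nothing to test.")
    out <- empty
  } else {
    pairs <- combn(sort(use), 2L)
    out <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
      a <- pairs[1L, k]
      b <- pairs[2L, k]
      dplyr::mutate(
        genotypic_ld_test(gm[a, ], gm[b, ], n_perm = n_perm),
        marker_a = a, marker_b = b, .before = 1L
      )
    })
    out <- out[out$testable, setdiff(names(out), "testable")]
  }
  if (adjust == "BH" && nrow(out) > 0L) {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
    out$significant <- out$p_adjusted < alpha
  } else if (nrow(out) > 0L) {
    out$significant <- out$p_value < alpha
  }
  structure(
    out,
    class = c("rad_ld", class(tibble::tibble())),
    alpha = alpha,
    n_pairs_tested = nrow(out),
    proportion_significant = if (nrow(out) > 0L) mean(out$significant) else NA_real_
  )
}

#' Summarize significant LD pairs involving sex-linked markers
#'
#' Counts how many significantly associated marker pairs contain at
#' least one known completely sex-linked marker, and lists the distinct
#' partner markers - the candidates for residing on the sex chromosomes
#' without meeting the strict complete-linkage criteria.
#'
#' @param results A `rad_ld` tibble from [ld_screen()].
#' @param sexlinked_ids Character vector of completely sex-linked marker
#'   ids.
#' @return List: `n_pairs_sig`, `n_sexlinked_pairs_sig`, `proportion`
#'   (of significant pairs that involve a sex-linked marker), and
#'   `partner_markers` (non-sex-linked partners in those pairs).
#' @export
summarize_sexlinked_pairs <- function(results, sexlinked_ids) {
  sig <- results[results$significant %in% TRUE, , drop = FALSE]
  linked <- sig$marker_a %in% sexlinked_ids | sig$marker_b %in% sexlinked_ids
  partners <- setdiff(
    unique(c(sig$marker_a[linked], sig$marker_b[linked])), sexlinked_ids
  )
  list(
    n_pairs_sig = nrow(sig),
    n_sexlinked_pairs_sig = sum(linked),
    proportion = if (nrow(sig) > 0L) sum(linked) / nrow(sig) else NA_real_,
    partner_markers = sort(partners)
  )
}
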