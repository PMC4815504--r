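#' Probability of a restriction-site motif under an i.i.d. base model
#'
#' With genome GC content `gc`, each position is C or G with probability
#' `gc/2` each and A or T with probability `(1 - gc)/2` each, so an
#' unambiguous motif occurs at a given position with probability
#' `(gc/2)^n_GC * ((1-gc)/2)^n_AT`. The SbfI site CCTGCAGG is its own
#' reverse complement, so a single-strand scan already counts every
#' cut site once.
#'
#' @param motif Recognition sequence over `A`, `C`, `G`, `T` (ambiguity
#'   codes are not supported).
#' @param gc Genome GC content in (0, 1).
#' @return Per-position site probability.
#' @export
#' @examples
#' site_probability("CCTGCAGG", 0.47)
site_probability <- function(motif, gc) {
  stopifnot(is.character(motif), length(motif) == 1L, nchar(motif) > 0L)
  if (gc <= 0 || gc >= 1) abort("gc must lie strictly between 0 and 1.")
  bases <- strsplit(toupper(motif), "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "T"))) {
    abort("unsupported base code in motif; only A/C/G/T are allowed.")
  }
  n_gc <- sum(bases %in% c("C", "G"))
  n_at <- length(bases) - n_gc
  (gc / 2)^n_gc * ((1 - gc) / 2)^n_at
}

#' Expected spacing between restriction sites
#'
#' The expected distance between successive motif occurrences is the
#' reciprocal of the per-position site probability. Because each cut
#' site yields two RAD markers (one on each flank), this spacing is also
#' the expected span of genome per pair of RAD markers. The estimate is
#' additionally rounded to the nearest 100 kb (minimum 100 kb), the
#' resolution at which back-of-envelope region sizes are quoted.
#'
#' @param p_site Per-position site probability (e.g. from
#'   [site_probability()]).
#' @return A `spacing_estimate` list: `p_site`, `spacing_bp`,
#'   `spacing_kb`, `spacing_rounded_kb`.
#' @export
#' @examples
#' expected_spacing(site_probability("CCTGCAGG", 0.47))
expected_spacing <- function(p_site) {
  stopifnot(p_site > 0)
  spacing_bp <- 1 / p_site
  spacing_kb <- spacing_bp / 1000
  structure(
    list(
      p_site = p_site,
      spacing_bp = spacing_bp,
      spacing_kb = spacing_kb,
      spacing_rounded_kb = max(100, round(spacing_kb / 100) * 100)
    ),
    class = "spacing_estimate"
  )
}

#' @export
print.spacing_estimate <- function(x, ...) {
  cat("<spacing_estimate> p =", format(x$p_site, digits = 4),
      "-> 1 site per", format(x$spacing_kb, digits = 4), "kb",
      "(rounded:", x$spacing_rounded_kb, "kb)\n")
  invisible(x)
}

#' Genomic extent implied by a count of sex-linked markers or sites
#'
#' Converts a number of completely sex-linked RAD markers (two markers
#' flank each restriction site, so `n_sites = round(n_markers / 2)`,
#' ties to even) or a direct count of restriction sites into an expected
#' genomic extent, multiplying by the rounded expected spacing.
#'
#' @param spacing A `spacing_estimate` from [expected_spacing()].
#' @param n_markers Number of RAD markers (exclusive with `n_sites`).
#' @param n_sites Number of restriction sites.
#' @return List: `n_sites`, `extent_kb` (using the rounded spacing),
#'   `extent_mb`, and `extent_kb_exact` (using the unrounded spacing).
#' @export
#' @examples
#' sp <- expected_spacing(site_probability("CCTGCAGG", 0.47))
#' region_extent(sp, n_markers = 41)$extent_mb
region_extent <- function(spacing, n_markers = NULL, n_sites = NULL) {
  stopifnot(inherits(spacing, "spacing_estimate"))
  if (is.null(n_markers) == is.null(n_sites)) {
    abort("supply exactly one of n_markers or n_sites.")
  }
  if (!is.null(n_markers)) {
    if (n_markers < 0) abort("n_markers must be >= 0.")
    n_sites <- round(n_markers / 2)
  }
  if (n_sites < 0) abort("n_sites must be >= 0.")
  extent_kb <- n_sites * spacing$spacing_rounded_kb
  list(
    n_sites = n_sites,
    extent_kb = extent_kb,
    extent_mb = extent_kb / 1000,
    extent_kb_exact = n_sites * spacing$spacing_kb
  )
}

#' Simulate an i.i.d. genome and count motif occurrences
#'
#' Monte-Carlo companion to [site_probability()]: generates random
#' genomes at the given GC content and counts (possibly overlapping)
#' motif occurrences, returning the empirical mean spacing.
#'
#' @param motif Recognition sequence.
#' @param gc GC content.
#' @param genome_size Genome length in bp.
#' @param n_genomes Number of replicate genomes.
#' @return List: `n_sites` (total across replicates), `mean_spacing_bp`.
#' @export
simulate_site_spacing <- function(motif, gc, genome_size = 1e6, n_genomes = 10L) {
  bases <- c("A", "C", "G", "T")
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  total <- 0L
  for (i in seq_len(n_genomes)) {
    g <- paste(sample(bases, genome_size, replace = TRUE, prob = prob),
               collapse = "")
    # overlapping occurrences via lookahead
    total <- total + length(gregexpr(paste0("(?=", motif, ")"), g,
                                     perl = TRUE)[[1]] |> (\(x) x[x > 0])())
  }
  list(
    n_sites = total,
    mean_spacing_bp = n_genomes * genome_size / max(total, 1L)
  )
}
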