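#' Retain high-coverage markers scored in enough individuals
#'
#' Builds the "filtered catalogue": markers with depth strictly greater
#' than `min_depth` reads in at least `min_individuals` individuals are
#' kept, everything else is dropped. The defaults (>20 reads, >=6
#' individuals) correspond to requiring the marker in at least as many
#' individuals as the smallest sex sample.
#'
#' @param cat A [rad_catalogue].
#' @param min_depth Depth that must be exceeded (strictly) for a cell to
#'   count, in reads.
#' @param min_individuals Minimum number of qualifying individuals.
#' @return A filtered [rad_catalogue]; the `"filter_log"` attribute
#'   accumulates a tibble of step names and marker counts.
#' @export
filter_high_coverage <- function(cat, min_depth = 20L, min_individuals = 6L) {
  stopifnot(min_depth >= 0L, min_individuals >= 1L)
  dm <- depth_matrix(cat)
  if (nrow(dm) == 0L) {
    warn("empty catalogue: nothing to filter.")
    return(cat)
  }
  keep <- rownames(dm)[rowSums(dm > min_depth) >= min_individuals]
  out <- subset_catalogue(cat, markers = keep)
  attr(out, "filter_log") <- dplyr::bind_rows(
    attr(cat, "filter_log") %||%
      tibble::tibble(step = "input", n_markers = nrow(dm)),
    tibble::tibble(step = "high_coverage", n_markers = length(keep))
  )
  out
}

#' Remove putative repetitive markers by mean-depth outlier filtering
#'
#' Markers assembled from repetitive elements attract reads from many
#' genomic copies and show inflated coverage. Each marker's mean depth
#' over genotyped cells is computed, and markers whose mean exceeds the
#' grand mean by more than two standard deviations (of the marker means)
#' are removed in a single pass.
#'
#' @param cat A [rad_catalogue] with at least 2 markers.
#' @param n_sd Number of standard deviations above the mean tolerated.
#' @return A filtered [rad_catalogue] (with updated `"filter_log"`).
#' @export
remove_repetitive <- function(cat, n_sd = 2) {
  dm <- depth_matrix(cat)
  if (nrow(dm) < 2L) abort("need >=2 markers to assess coverage outliers.")
  cm <- called_matrix(cat)
  use <- ifelse(cm, dm, NA)
  means <- rowMeans(use, na.rm = TRUE)
  # markers with no genotyped cell fall back to cells with any reads
  none <- !is.finite(means)
  if (any(none)) {
    pos <- ifelse(dm > 0L, dm, NA)
    means[none] <- rowMeans(pos[none, , drop = FALSE], na.rm = TRUE)
    means[!is.finite(means)] <- 0
  }
  cutoff <- mean(means) + n_sd * sd(means)
  keep <- rownames(dm)[means <= cutoff]
  out <- subset_catalogue(cat, markers = keep)
  attr(out, "filter_log") <- dplyr::bind_rows(
    attr(cat, "filter_log") %||%
      tibble::tibble(step = "input", n_markers = nrow(dm)),
    tibble::tibble(step = "repeat_filter", n_markers = length(keep))
  )
  out
}

#' Normalize read depths by each individual's reference median
#'
#' Total coverage differs between sequencing libraries, so raw depths
#' are not comparable across individuals. Each individual's depths are
#' divided by that individual's median depth over a reference set of
#' candidate autosomal markers - by default (`reference = NULL`, AUTO)
#' the markers genotyped in every individual. On this scale diploid
#' markers sit near 1.0 and hemizygous (single-copy) markers near 0.5,
#' the contrast all coverage-based sex-linkage evidence rests on.
#'
#' @param cat A [rad_catalogue].
#' @param reference Character vector of reference marker ids, or `NULL`
#'   to select the markers called in all individuals.
#' @return A `rad_normcov` object: a tibble (`marker_id`,
#'   `individual_id`, `value`) with attributes
#'   `reference_marker_ids` and `reference_medians` (named per
#'   individual, in reads).
#' @export
normalize_depths <- function(cat, reference = NULL) {
  dm <- depth_matrix(cat)
  cm <- called_matrix(cat)
  if (is.null(reference)) {
    reference <- rownames(dm)[rowSums(cm) == ncol(cm)]
    if (length(reference) == 0L) {
      abort(paste0(
        "no marker is genotyped in all individuals; pass an explicit ",
        "`reference` marker set."
      ))
    }
  } else {
    if (length(reference) == 0L) abort("`reference` must be non-empty.")
    stopifnot(all(reference %in% rownames(dm)))
  }
  med <- apply(dm[reference, , drop = FALSE], 2L, median)
  if (any(med <= 0)) {
    abort(paste0(
      "reference median is zero for individual(s): ",
      paste(names(med)[med <= 0], collapse = ", ")
    ))
  }
  values <- sweep(dm, 2L, med, `/`)
  out <- tibble::tibble(
    marker_id = rep(rownames(dm), times = ncol(dm)),
    individual_id = rep(colnames(dm), each = nrow(dm)),
    value = as.vector(values)
  )
  structure(
    out,
    class = c("rad_normcov", class(out)),
    reference_marker_ids = reference,
    reference_medians = med
  )
}

#' @rdname normalize_depths
#' @param x,cov A `rad_normcov` object.
#' @export
reference_medians <- function(cov) attr(cov, "reference_medians")

#' @rdname normalize_depths
#' @export
coverage_matrix <- function(cov) {
  ids <- unique(cov$marker_id)
  inds <- unique(cov$individual_id)
  matrix(cov$value, nrow = length(ids), dimnames = list(ids, inds))
}

#' Summarize the coverage filtering applied to a catalogue
#'
#' @param cat A filtered [rad_catalogue].
#' @param cov Optionally, the matching `rad_normcov` (adds the reference
#'   set size and per-individual reference medians).
#' @return A list (`filter_report`) with the marker counts at each
#'   filtering step, and when `cov` is given, `reference_set_size` and
#'   `per_individual_reference_median`.
#' @export
filter_report <- function(cat, cov = NULL) {
  log <- attr(cat, "filter_log") %||%
    tibble::tibble(step = "input", n_markers = length(marker_ids(cat)))
  rep <- list(steps = log)
  if (!is.null(cov)) {
    rep$reference_set_size <- length(attr(cov, "reference_marker_ids"))
    rep$per_individual_reference_median <- as.list(reference_medians(cov))
  }
  structure(rep, class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n")
  print(x$steps)
  if (!is.null(x$reference_set_size)) {
    cat("reference set:", x$reference_set_size, "markers; medians ",
        paste(range(unlist(x$per_individual_reference_median)), collapse = "-"),
        "reads\n")
  }
  invisible(x)
}
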