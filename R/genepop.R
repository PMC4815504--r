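#' Export a catalogue subset in Genepop format
#'
#' Writes the classic Genepop dialect: a title line, one marker name per
#' line, then a `Pop` line before each population's individuals, each
#' individual as `"id ,"` followed by space-separated diploid genotypes
#' coded with 3 digits per allele (`"001002"`; `"000000"` would denote a
#' missing genotype, but by default only markers genotyped in every
#' included individual may be exported, mirroring the usual
#' "found in all individuals" restriction for population LD screens).
#'
#' @param cat A [rad_catalogue].
#' @param markers Marker ids to export; default all markers genotyped in
#'   every included individual.
#' @param path Output file path.
#' @param title Title line content.
#' @param allow_missing If `TRUE`, markers with missing genotypes are
#'   permitted and encoded `"000000"`; off by default (a missing
#'   genotype among included individuals is then an error).
#' @return `path`, invisibly. The allele coding used per marker is
#'   attached as the `"allele_codes"` attribute (a named list of named
#'   integer vectors).
#' @export
write_genepop <- function(cat, markers = NULL, path, title = "radzw export",
                          allow_missing = FALSE) {
  called <- called_matrix(cat)
  markers <- markers %||% rownames(called)[rowSums(called) == ncol(called)]
  stopifnot(all(markers %in% marker_ids(cat)))
  if (!allow_missing) {
    bad <- markers[rowSums(!called[markers, , drop = FALSE]) > 0L]
    if (length(bad) > 0L) {
      abort(paste0(
        "precondition error: marker(s) with missing genotypes among ",
        "included individuals: ", paste(head(bad, 5L), collapse = ", ")
      ))
    }
  }
  calls <- cat$calls |> dplyr::filter(.data$marker_id %in% markers)
  codes <- calls |>
    tidyr::pivot_longer(c("allele_a", "allele_b"), values_to = "allele") |>
    dplyr::filter(!is.na(.data$allele)) |>
    dplyr::distinct(.data$marker_id, .data$allele) |>
    dplyr::arrange(.data$marker_id, .data$allele) |>
    dplyr::group_by(.data$marker_id) |>
    dplyr::mutate(code = dplyr::row_number()) |>
    dplyr::ungroup()
  over <- codes |> dplyr::count(.data$marker_id) |> dplyr::filter(.data$n > 99L)
  if (nrow(over) > 0L) {
    abort(paste0(
      "encoding error: >99 alleles at marker(s) ",
      paste(over$marker_id, collapse = ", ")
    ))
  }
  code_of <- function(marker, allele) {
    i <- match(paste(marker, allele), paste(codes$marker_id, codes$allele))
    codes$code[i]
  }
  geno <- calls |>
    dplyr::mutate(
      gp = ifelse(
        is.na(.data$allele_a), "000000",
        sprintf("%03d%03d",
                pmin(code_of(.data$marker_id, .data$allele_a),
                     code_of(.data$marker_id, .data$allele_b)),
                pmax(code_of(.data$marker_id, .data$allele_a),
                     code_of(.data$marker_id, .data$allele_b)))
      )
    )
  gp_wide <- geno |>
    dplyr::select("marker_id", "individual_id", "gp") |>
    tidyr::pivot_wider(names_from = "marker_id", values_from = "gp")
  gp_wide <- gp_wide[match(cat$individuals$id, gp_wide$individual_id),
                     c("individual_id", markers)]

  lines <- c(title, markers)
  for (pop in unique(cat$individuals$population)) {
    lines <- c(lines, "Pop")
    ids <- cat$individuals$id[cat$individuals$population == pop]
    rows <- gp_wide[gp_wide$individual_id %in% ids, , drop = FALSE]
    lines <- c(lines, paste0(
      rows$individual_id, " , ",
      apply(rows[, -1, drop = FALSE], 1L, paste, collapse = " ")
    ))
  }
  writeLines(lines, path)
  code_list <- split(setNames(codes$code, codes$allele), codes$marker_id)
  attr(path, "allele_codes") <- code_list
  invisible(path)
}
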