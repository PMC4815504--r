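#' Construct a RAD marker catalogue
#'
#' A catalogue couples per-cell genotype calls and read depths for a set of
#' RAD markers scored across individuals, with individual-level metadata
#' (population, phenotypic sex, and optionally the sex-chromosome
#' karyotype). It is the central container of the package: filters,
#' normalization and every discovery stage consume and return catalogues
#' or tibbles derived from them.
#'
#' @param calls Tibble with one row per marker x individual cell and
#'   columns `marker_id`, `individual_id`, `allele_a`, `allele_b`
#'   (character; both `NA` when no genotype was called) and `depth`
#'   (non-negative integer read count). Cells absent from `calls` are
#'   filled in as depth 0 with no call, so a sparse table is accepted.
#' @param individuals Tibble with columns `id`, `population`, `phenotype`
#'   (one of `"male"`, `"female"`, `"hermaphrodite"`) and optionally
#'   `karyotype` (one of `"ZZ"`, `"ZW"`, `"WW"`, `"unknown"`; defaults to
#'   `"unknown"`).
#' @param call_threshold Minimum read depth (reads) at which a genotype
#'   call is considered valid; cells carrying a call below this depth are
#'   rejected. Default 15, the usual minimum number of identical reads
#'   required to call a RAD allele.
#'
#' @return An object of class `rad_catalogue`: a list with elements
#'   `calls` (complete marker x individual long tibble in canonical
#'   order) and `individuals`, plus the `call_threshold` attribute.
#' @export
#' @examples
#' calls <- tibble::tibble(
#'   marker_id = c("m1", "m1", "m2"),
#'   individual_id = c("i1", "i2", "i1"),
#'   allele_a = c("a", "a", NA), allele_b = c("a", "b", NA),
#'   depth = c(30L, 25L, 4L)
#' )
#' inds <- tibble::tibble(
#'   id = c("i1", "i2"), population = "P1",
#'   phenotype = c("female", "male")
#' )
#' rad_catalogue(calls, inds)
rad_catalogue <- function(calls, individuals, call_threshold = 15L) {
  individuals <- tibble::as_tibble(individuals)
  if (!all(c("id", "population", "phenotype") %in% names(individuals))) {
    abort("`individuals` needs columns id, population, phenotype.")
  }
  if (anyDuplicated(individuals$id)) {
    abort("individual ids must be unique within a dataset.")
  }
  if (!all(individuals$phenotype %in% c("male", "female", "hermaphrodite"))) {
    abort("phenotype must be one of male, female, hermaphrodite.")
  }
  if (!"karyotype" %in% names(individuals)) individuals$karyotype <- "unknown"
  individuals$karyotype[is.na(individuals$karyotype)] <- "unknown"
  if (!all(individuals$karyotype %in% c("ZZ", "ZW", "WW", "unknown"))) {
    abort("karyotype must be one of ZZ, ZW, WW, unknown.")
  }
  mixed <- individuals |>
    dplyr::distinct(.data$population, .data$phenotype) |>
    dplyr::filter(.data$phenotype != "male") |>
    dplyr::count(.data$population) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(mixed) > 0L) {
    abort(paste0(
      "population(s) ", paste(mixed$population, collapse = ", "),
      " mix females and hermaphrodites; a population is either dioecious ",
      "(females + males) or androdioecious (hermaphrodites + males)."
    ))
  }

  calls <- tibble::as_tibble(calls)
  needed <- c("marker_id", "individual_id", "allele_a", "allele_b", "depth")
  if (!all(needed %in% names(calls))) {
    abort(paste("`calls` needs columns", paste(needed, collapse = ", ")))
  }
  if (!all(calls$individual_id %in% individuals$id)) {
    missing_ids <- setdiff(unique(calls$individual_id), individuals$id)
    abort(paste0(
      "metadata error: individual(s) in calls absent from metadata: ",
      paste(head(missing_ids, 5L), collapse = ", ")
    ))
  }
  calls$depth <- vctrs::vec_cast(calls$depth, integer())
  if (anyNA(calls$depth) || any(calls$depth < 0L)) {
    abort("validation error: depths must be non-negative integers.")
  }
  one_sided <- xor(is.na(calls$allele_a), is.na(calls$allele_b))
  if (any(one_sided)) {
    abort("validation error: a genotype call must supply both alleles.")
  }
  called <- !is.na(calls$allele_a)
  if (any(called & calls$depth < call_threshold)) {
    abort(paste0(
      "validation error: genotype call with depth below the call ",
      "threshold (", call_threshold, " reads)."
    ))
  }

  marker_ids <- unique(calls$marker_id)
  grid <- tidyr::expand_grid(marker_id = marker_ids, individual_id = individuals$id)
  if (anyDuplicated(calls[c("marker_id", "individual_id")])) {
    abort("validation error: duplicated marker x individual cell.")
  }
  calls <- grid |>
    dplyr::left_join(calls, by = c("marker_id", "individual_id")) |>
    dplyr::mutate(depth = dplyr::coalesce(.data$depth, 0L))

  out <- structure(
    list(calls = calls, individuals = individuals),
    class = "rad_catalogue",
    call_threshold = as.integer(call_threshold)
  )
  out
}

#' @export
print.rad_catalogue <- function(x, ...) {
  cat(
    "<rad_catalogue> ", length(marker_ids(x)), " markers x ",
    nrow(x$individuals), " individuals (",
    paste(unique(x$individuals$population), collapse = ", "),
    "); call threshold ", attr(x, "call_threshold"), " reads\n",
    sep = ""
  )
  invisible(x)
}

#' Catalogue accessors
#'
#' `marker_ids()` returns marker identifiers in catalogue order;
#' `call_threshold()` the depth at which genotypes were called;
#' `depth_matrix()`, `called_matrix()` and `genotype_matrix()` return
#' marker x individual matrices of read depth, call status, and genotype
#' strings (`"a/b"` with alleles sorted, `NA` when uncalled).
#'
#' @param cat A [rad_catalogue].
#' @return A character vector, integer, or matrix as described above.
#' @export
marker_ids <- function(cat) unique(cat$calls$marker_id)

#' @rdname marker_ids
#' @export
call_threshold <- function(cat) attr(cat, "call_threshold")

#' @rdname marker_ids
#' @export
depth_matrix <- function(cat) {
  m <- matrix(
    cat$calls$depth,
    nrow = length(marker_ids(cat)), byrow = TRUE,
    dimnames = list(marker_ids(cat), cat$individuals$id)
  )
  m
}

#' @rdname marker_ids
#' @export
called_matrix <- function(cat) {
  m <- matrix(
    !is.na(cat$calls$allele_a),
    nrow = length(marker_ids(cat)), byrow = TRUE,
    dimnames = list(marker_ids(cat), cat$individuals$id)
  )
  m
}

#' @rdname marker_ids
#' @export
genotype_matrix <- function(cat) {
  g <- ifelse(
    is.na(cat$calls$allele_a), NA_character_,
    paste(
      pmin(cat$calls$allele_a, cat$calls$allele_b),
      pmax(cat$calls$allele_a, cat$calls$allele_b),
      sep = "/"
    )
  )
  matrix(
    g, nrow = length(marker_ids(cat)), byrow = TRUE,
    dimnames = list(marker_ids(cat), cat$individuals$id)
  )
}

#' Subset a catalogue by markers or individuals
#'
#' @param cat A [rad_catalogue].
#' @param markers Character vector of marker ids to keep (default all).
#' @param individuals Character vector of individual ids to keep.
#' @return A [rad_catalogue] restricted to the requested cells; any
#'   filter log accumulated by coverage filters is carried over.
#' @export
subset_catalogue <- function(cat, markers = NULL, individuals = NULL) {
  markers <- markers %||% marker_ids(cat)
  individuals <- individuals %||% cat$individuals$id
  stopifnot(all(markers %in% marker_ids(cat)),
            all(individuals %in% cat$individuals$id))
  inds <- cat$individuals[cat$individuals$id %in% individuals, , drop = FALSE]
  calls <- cat$calls |>
    dplyr::filter(.data$marker_id %in% markers,
                  .data$individual_id %in% individuals)
  out <- rad_catalogue(calls, inds, call_threshold = call_threshold(cat))
  attr(out, "filter_log") <- attr(cat, "filter_log")
  out
}

# ---- TSV input/output -------------------------------------------------------

#' Read a marker catalogue and its metadata from TSV files
#'
#' The catalogue dialect is one row per marker: a `marker_id` column
#' followed by one column per individual, each cell encoded
#' `"alleleA/alleleB:depth"`, with `"./.:depth"` for a cell without a
#' genotype call (a depth of 0 means the marker is absent from that
#' individual's reads). The metadata file has columns `id`, `population`,
#' `phenotype` and optionally `karyotype`.
#'
#' @param path Catalogue TSV path.
#' @param metadata_path Metadata TSV path.
#' @param call_threshold Depth threshold in force for genotype calls
#'   (reads); parsed calls below it are a validation error.
#' @return A [rad_catalogue].
#' @export
read_catalogue <- function(path, metadata_path, call_threshold = 15L) {
  meta <- readr::read_tsv(metadata_path, col_types = readr::cols(.default = "c"))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  if (names(raw)[1] != "marker_id") {
    abort("format error: line 1 of the catalogue must start with a 'marker_id' column.")
  }
  samples <- names(raw)[-1]
  if (!all(samples %in% meta$id)) {
    abort(paste0(
      "metadata error: catalogue sample(s) missing from metadata: ",
      paste(setdiff(samples, meta$id), collapse = ", ")
    ))
  }
  long <- raw |>
    tidyr::pivot_longer(-"marker_id",
                        names_to = "individual_id", values_to = "cell")
  bad <- !grepl("^[^/:]+/[^/:]+:-?[0-9]+$", long$cell)
  if (any(bad)) {
    first <- which(bad)[1]
    abort(paste0(
      "format error: malformed cell '", long$cell[first], "' (marker ",
      long$marker_id[first], ", individual ", long$individual_id[first], ")."
    ))
  }
  parts <- strsplit(long$cell, "[/:]")
  long$allele_a <- vapply(parts, `[`, "", 1L)
  long$allele_b <- vapply(parts, `[`, "", 2L)
  long$depth <- as.integer(vapply(parts, `[`, "", 3L))
  miss <- long$allele_a == "." & long$allele_b == "."
  long$allele_a[miss] <- NA_character_
  long$allele_b[miss] <- NA_character_
  if (any(long$depth < 0L)) {
    abort("validation error: negative depth in catalogue.")
  }
  meta <- meta[match(samples, meta$id), , drop = FALSE]
  rad_catalogue(
    long[c("marker_id", "individual_id", "allele_a", "allele_b", "depth")],
    meta,
    call_threshold = call_threshold
  )
}

#' Write a marker catalogue (and optionally its metadata) to TSV
#'
#' Inverse of [read_catalogue()]; `read_catalogue(write_catalogue(cat))`
#' is the identity on valid catalogues, including the missingness
#' pattern.
#'
#' @param cat A [rad_catalogue].
#' @param path Catalogue TSV output path.
#' @param metadata_path Optional metadata TSV output path.
#' @return `path`, invisibly.
#' @export
write_catalogue <- function(cat, path, metadata_path = NULL) {
  cells <- cat$calls |>
    dplyr::mutate(cell = ifelse(
      is.na(.data$allele_a),
      paste0("./.:", .data$depth),
      paste0(.data$allele_a, "/", .data$allele_b, ":", .data$depth)
    )) |>
    dplyr::select("marker_id", "individual_id", "cell") |>
    tidyr::pivot_wider(names_from = "individual_id", values_from = "cell")
  readr::write_tsv(cells, path)
  if (!is.null(metadata_path)) {
    readr::write_tsv(cat$individuals, metadata_path)
  }
  invisible(path)
}
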