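#' Expected segregation patterns under a heterogametic model
#'
#' Instantiates the predicted presence/coverage/zygosity patterns of
#' completely sex-linked markers under female heterogamety (ZW; males
#' ZZ, females/hermaphrodites carry at least one W) or its mirror, male
#' heterogamety (XY: swap the sexes and rename W to Y and Z to X).
#' Under the ZW model a W-specific marker is present and hemizygous
#' (normalized coverage about 0.5, single allele) in ZW carriers,
#' present at diploid coverage in WW monogenic hermaphrodites, and
#' absent in ZZ males; a Z-specific marker mirrors this; a marker shared
#' between Z and W segregates a W-diagnostic allele that makes every ZW
#' individual heterozygous and every ZZ and WW individual homozygous.
#'
#' @param heterogametic `"female_ZW"` or `"male_XY"`.
#' @return A `segregation_model`: list with the heterogametic sex, the
#'   phenotype carrying the female-limited (W/Y) chromosome, and a
#'   `class_expectations` tibble (marker class x karyotype expected
#'   presence, normalized coverage and zygosity).
#' @export
segregation_model <- function(heterogametic = c("female_ZW", "male_XY")) {
  heterogametic <- match.arg(heterogametic)
  exp_tbl <- tibble::tribble(
    ~marker_class, ~karyotype, ~presence, ~normalized_coverage, ~zygosity,
    "W_specific", "ZW", "present", 0.5, "hemizygous",
    "W_specific", "WW", "present", 1.0, "homozygous_or_het",
    "W_specific", "ZZ", "absent", NA_real_, NA_character_,
    "Z_specific", "ZW", "present", 0.5, "hemizygous",
    "Z_specific", "WW", "absent", NA_real_, NA_character_,
    "Z_specific", "ZZ", "present", 1.0, "homozygous_or_het",
    "sexlinked_alleles", "ZW", "present", 1.0, "het_with_specific_allele",
    "sexlinked_alleles", "WW", "present", 1.0, "homozygous",
    "sexlinked_alleles", "ZZ", "present", 1.0, "homozygous"
  )
  het_phenotypes <- if (heterogametic == "female_ZW") {
    c("female", "hermaphrodite")
  } else {
    "male"
  }
  structure(
    list(
      heterogametic_sex = heterogametic,
      het_phenotypes = het_phenotypes,
      chromosome_names = if (heterogametic == "female_ZW") {
        c(limited = "W", shared = "Z")
      } else {
        c(limited = "Y", shared = "X")
      },
      class_expectations = exp_tbl
    ),
    class = "segregation_model"
  )
}

#' @export
print.segregation_model <- function(x, ...) {
  cat("<segregation_model>", x$heterogametic_sex, "\n")
  print(x$class_expectations)
  invisible(x)
}

# expected copies of the focal chromosome given a karyotype label
.focal_copies <- function(karyotype, chromosome) {
  vapply(strsplit(karyotype, ""), function(ch) sum(ch == chromosome), 0L)
}

#' Find chromosome-specific markers by presence-absence and coverage
#'
#' A marker specific to one sex chromosome must be present (genotyped)
#' in every individual carrying that chromosome and absent (no call,
#' depth below `absent_max_depth`) in every individual lacking it.
#' Presence-pattern hits are then annotated with depth evidence, judged
#' at the marker level the way coverage plots are read: the mean
#' normalized coverage over carriers holding one copy of the focal
#' chromosome must fall in the hemizygosity window, the mean over
#' carriers holding two copies (e.g. WW hermaphrodites at a W-specific
#' marker) in the homozygous window, and the mean over
#' unknown-karyotype carriers anywhere between the two windows' outer
#' bounds. Zygosity evidence remains per individual: every single-copy
#' carrier must show a single allele. A cell whose depth falls between
#' `absent_max_depth` and the call threshold is neither cleanly present
#' nor cleanly absent and disqualifies the marker.
#'
#' @param cat A [rad_catalogue].
#' @param cov The matching `rad_normcov` from [normalize_depths()].
#' @param carriers,non_carriers Disjoint, non-empty character vectors of
#'   individual ids.
#' @param chromosome `"W"` or `"Z"`: the chromosome the marker would be
#'   specific to (used to label the call and to pick the expected
#'   coverage window per carrier karyotype).
#' @param karyotypes Optional named character vector giving (putative)
#'   karyotypes of the carriers; defaults to the catalogue metadata.
#'   Carriers with unknown karyotype are accepted in either window and
#'   exempt from the single-allele requirement.
#' @param hemi_window,hom_window Normalized-coverage intervals accepted
#'   as hemizygous and as diploid.
#' @param absent_max_depth Maximum raw depth (reads) still counted as
#'   absence.
#' @return Tibble of sex-linkage calls: `marker_id`, `category`
#'   (`"W_specific"`/`"Z_specific"` when all evidence holds, otherwise
#'   `"unclassified"`), and logical evidence flags
#'   `presence_pattern_ok`, `coverage_ok`, `zygosity_ok`.
#' @export
find_chromosome_specific <- function(cat, cov, carriers, non_carriers,
                                     chromosome = c("W", "Z"),
                                     karyotypes = NULL,
                                     hemi_window = c(0.25, 0.75),
                                     hom_window = c(0.75, 1.5),
                                     absent_max_depth = 5L) {
  chromosome <- match.arg(chromosome)
  if (length(carriers) == 0L || length(non_carriers) == 0L) {
    abort("precondition error: carriers and non_carriers must be non-empty.")
  }
  if (length(intersect(carriers, non_carriers)) > 0L) {
    abort("precondition error: carriers and non_carriers overlap.")
  }
  stopifnot(all(c(carriers, non_carriers) %in% cat$individuals$id))
  if (is.null(karyotypes)) {
    karyotypes <- setNames(cat$individuals$karyotype, cat$individuals$id)
  }
  dm <- depth_matrix(cat)
  cm <- called_matrix(cat)
  gm <- genotype_matrix(cat)
  vm <- coverage_matrix(cov)[rownames(dm), , drop = FALSE]

  present_all <- rowSums(cm[, carriers, drop = FALSE]) == length(carriers)
  absent_all <- rowSums(
    !cm[, non_carriers, drop = FALSE] &
      dm[, non_carriers, drop = FALSE] < absent_max_depth
  ) == length(non_carriers)
  hits <- rownames(dm)[present_all & absent_all]
  if (length(hits) == 0L) {
    return(tibble::tibble(
      marker_id = character(), category = character(),
      presence_pattern_ok = logical(), coverage_ok = logical(),
      zygosity_ok = logical()
    ))
  }

  kar <- karyotypes[carriers]
  copies <- ifelse(
    is.na(kar) | kar == "unknown", NA_integer_, .focal_copies(kar, chromosome)
  )
  cov_hit <- vm[hits, carriers, drop = FALSE]
  group_mean_ok <- function(cols, lo, hi, closed_lo = TRUE) {
    if (length(cols) == 0L) return(rep(TRUE, length(hits)))
    m <- rowMeans(cov_hit[, cols, drop = FALSE])
    if (closed_lo) m >= lo & m <= hi else m > lo & m <= hi
  }
  coverage_ok <-
    group_mean_ok(which(!is.na(copies) & copies == 1L),
                  hemi_window[1], hemi_window[2]) &
    group_mean_ok(which(!is.na(copies) & copies == 2L),
                  hom_window[1], hom_window[2], closed_lo = FALSE) &
    group_mean_ok(which(is.na(copies)), hemi_window[1], hom_window[2])

  g_hit <- gm[hits, carriers, drop = FALSE]
  single <- !is.na(g_hit) &
    vapply(strsplit(as.vector(g_hit), "/"),
           function(x) length(unique(x)) == 1L, TRUE)
  single <- matrix(single, nrow = length(hits))
  need_single <- matrix(rep(!is.na(copies) & copies == 1L, each = length(hits)),
                        nrow = length(hits))
  zygosity_ok <- rowSums(!need_single | single) == length(carriers)

  tibble::tibble(
    marker_id = hits,
    category = ifelse(coverage_ok & zygosity_ok,
                      paste0(chromosome, "_specific"), "unclassified"),
    presence_pattern_ok = TRUE,
    coverage_ok = coverage_ok,
    zygosity_ok = zygosity_ok
  )
}

#' Find markers with completely sex-linked alleles
#'
#' Detects markers present on both sex chromosomes whose SNP alleles are
#' chromosome-diagnostic. Under the ZW model every heterogametic (ZW)
#' individual must be heterozygous and carry exactly one allele never
#' seen in homogametic (ZZ) individuals - the W-linked allele, shared by
#' all ZW individuals - while every ZZ individual is homozygous for
#' Z-linked alleles; when monogenic (WW) individuals are supplied they
#' must be homozygous for the W-linked allele. Only markers genotyped in
#' all grouped individuals are considered.
#'
#' @param cat A [rad_catalogue].
#' @param groups Named list of individual id vectors keyed by karyotype:
#'   `ZW` (required) and `ZZ` (required), `WW` optional - or their XY
#'   mirror labels `XY`, `XX`, `YY`.
#' @param model A [segregation_model()]; used only to label output.
#' @return Tibble of calls: `marker_id`, `category`
#'   (`"sexlinked_alleles"`), evidence flags, and the phased `w_allele`
#'   and `z_allele` (the latter `NA` if several Z-linked alleles
#'   segregate).
#' @export
find_sexlinked_alleles <- function(cat, groups,
                                   model = segregation_model("female_ZW")) {
  lab <- names(groups)
  allowed <- c("ZW", "ZZ", "WW", "XY", "XX", "YY")
  if (is.null(lab) || !all(lab %in% allowed)) {
    abort("precondition error: groups must be named with karyotype labels (ZW/ZZ/WW or XY/XX/YY).")
  }
  het <- groups[[intersect(lab, c("ZW", "XY"))[1] %||% "ZW"]]
  hom <- groups[[intersect(lab, c("ZZ", "XX"))[1] %||% "ZZ"]]
  ww <- if (any(lab %in% c("WW", "YY"))) groups[[intersect(lab, c("WW", "YY"))[1]]] else NULL
  if (length(het) == 0L || length(hom) == 0L) {
    abort("precondition error: both heterogametic and homogametic groups must be non-empty.")
  }
  all_ids <- c(het, hom, ww)
  stopifnot(all(all_ids %in% cat$individuals$id))

  cm <- called_matrix(cat)
  typed_all <- rowSums(cm[, all_ids, drop = FALSE]) == length(all_ids)
  candidates <- rownames(cm)[typed_all]

  calls <- cat$calls |>
    dplyr::filter(.data$marker_id %in% candidates,
                  .data$individual_id %in% all_ids)
  split_calls <- split(calls, calls$marker_id)

  res <- purrr::map(split_calls, function(mc) {
    a <- setNames(mc$allele_a, mc$individual_id)
    b <- setNames(mc$allele_b, mc$individual_id)
    hom_alleles <- unique(c(a[hom], b[hom]))
    hom_is_hom <- all(a[hom] == b[hom])
    het_is_het <- all(a[het] != b[het])
    if (!hom_is_hom || !het_is_het) return(NULL)
    # the allele each heterogametic individual carries beyond the Z pool
    w_cand <- purrr::map(het, function(i) setdiff(c(a[i], b[i]), hom_alleles))
    if (any(lengths(w_cand) != 1L)) return(NULL)
    w_allele <- unique(unlist(w_cand))
    if (length(w_allele) != 1L) return(NULL)
    if (!is.null(ww)) {
      if (!all(a[ww] == w_allele & b[ww] == w_allele)) return(NULL)
    }
    tibble::tibble(
      marker_id = mc$marker_id[1], category = "sexlinked_alleles",
      presence_pattern_ok = TRUE, coverage_ok = NA, zygosity_ok = TRUE,
      w_allele = w_allele,
      z_allele = if (length(hom_alleles) == 1L) hom_alleles else NA_character_
    )
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(
      marker_id = character(), category = character(),
      presence_pattern_ok = logical(), coverage_ok = logical(),
      zygosity_ok = logical(), w_allele = character(), z_allele = character()
    )
  }
  out |> dplyr::arrange(.data$marker_id)
}

#' Classify hermaphrodites as monogenic (WW) or amphigenic (ZW)
#'
#' In an androdioecious population a W-specific marker is diploid in
#' monogenic (WW) hermaphrodites but hemizygous in amphigenic (ZW)
#' hermaphrodites, so its normalized coverage separates the two
#' karyotypes around 1.0 vs 0.5. Each hermaphrodite's mean normalized
#' coverage over the supplied W-specific markers is thresholded, with a
#' dead zone in between reported as `ambiguous`.
#'
#' @param cov A `rad_normcov`.
#' @param w_specific_markers Non-empty character vector of W-specific
#'   marker ids.
#' @param hermaphrodites Character vector of hermaphrodite individual
#'   ids.
#' @param threshold_lo Mean coverage at or below which the call is
#'   amphigenic (ZW).
#' @param threshold_hi Mean coverage at or above which the call is
#'   monogenic (WW).
#' @return A `zw_herm_class` tibble: `individual_id`,
#'   `mean_w_coverage`, `karyotype_call` (`"monogenic_WW"`,
#'   `"amphigenic_ZW"` or `"ambiguous"`).
#' @export
classify_hermaphrodites <- function(cov, w_specific_markers, hermaphrodites,
                                    threshold_lo = 0.70, threshold_hi = 0.80) {
  if (length(w_specific_markers) == 0L) {
    abort("precondition error: need at least one W-specific marker.")
  }
  stopifnot(threshold_lo <= threshold_hi)
  sub <- cov |>
    dplyr::filter(.data$marker_id %in% w_specific_markers,
                  .data$individual_id %in% hermaphrodites) |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::summarise(mean_w_coverage = mean(.data$value), .groups = "drop") |>
    dplyr::mutate(karyotype_call = dplyr::case_when(
      .data$mean_w_coverage >= threshold_hi ~ "monogenic_WW",
      .data$mean_w_coverage <= threshold_lo ~ "amphigenic_ZW",
      TRUE ~ "ambiguous"
    ))
  sub <- sub[match(hermaphrodites, sub$individual_id), , drop = FALSE]
  structure(sub, class = c("zw_herm_class", class(tibble::tibble())))
}

#' Run the full sex-linkage discovery under a heterogametic hypothesis
#'
#' Applies the complete inference, population by population, in the
#' canonical order: chromosome-specific discovery via presence-absence
#' and coverage, hermaphrodite karyotype classification (androdioecious
#' populations, using the W-specific markers just found), Z-specific
#' discovery (androdioecious only - it requires monogenic WW individuals
#' as the W-only contrast group; in a dioecious population both sexes
#' carry a Z so presence-absence is uninformative), and finally
#' SNP-segregation discovery of shared sex-linked markers. Running it
#' under both hypotheses (`female_ZW` and `male_XY`) provides the
#' classic model comparison: data simulated or generated under ZW yield
#' no candidates when evaluated under XY.
#'
#' @param cat A filtered [rad_catalogue].
#' @param cov The matching `rad_normcov`.
#' @param model A [segregation_model()].
#' @param ... Threshold arguments passed on to
#'   [find_chromosome_specific()] (`hemi_window`, `hom_window`,
#'   `absent_max_depth`).
#' @param threshold_lo,threshold_hi Passed to
#'   [classify_hermaphrodites()].
#' @return A `zw_model_eval` object: list with `model`, per-population
#'   call tibbles (`calls`), hermaphrodite classifications
#'   (`hermaphrodites`), and a `summary` tibble of counts
#'   (`n_W_specific`, `n_Z_specific`, `n_sexlinked_alleles`, `n_total`
#'   per population).
#' @export
evaluate_model <- function(cat, cov, model = segregation_model("female_ZW"),
                           threshold_lo = 0.70, threshold_hi = 0.80, ...) {
  stopifnot(inherits(model, "segregation_model"))
  inds <- cat$individuals
  pops <- unique(inds$population)
  all_calls <- list()
  herm_class <- list()
  summaries <- list()
  for (pop in pops) {
    pi <- inds[inds$population == pop, , drop = FALSE]
    herms <- pi$id[pi$phenotype == "hermaphrodite"]
    system <- if (length(herms) > 0L) "androdioecious" else "dioecious"
    het_ids <- pi$id[pi$phenotype %in% model$het_phenotypes]
    hom_ids <- setdiff(pi$id, het_ids)
    if (length(het_ids) == 0L || length(hom_ids) == 0L) {
      warn(paste0("population ", pop, " lacks one phenotype class under the ",
                  model$heterogametic_sex, " model; skipped."))
      next
    }
    # putative karyotypes implied by the hypothesis: the heterogametic
    # phenotype carries one limited chromosome (hermaphrodites may be
    # WW or ZW and stay unknown until classified on coverage)
    kar <- setNames(rep("unknown", nrow(pi)), pi$id)
    kar[hom_ids] <- "ZZ"
    kar[setdiff(het_ids, herms)] <- "ZW"

    w_calls <- find_chromosome_specific(
      cat, cov, carriers = het_ids, non_carriers = hom_ids,
      chromosome = "W", karyotypes = kar, ...
    )
    w_ids <- w_calls$marker_id[w_calls$category == "W_specific"]

    z_calls <- NULL
    groups <- list(ZW = setdiff(het_ids, herms), ZZ = hom_ids)
    if (system == "androdioecious" && length(herms) > 0L &&
        model$heterogametic_sex == "female_ZW") {
      if (length(w_ids) > 0L) {
        hc <- classify_hermaphrodites(
          cov, w_ids, herms,
          threshold_lo = threshold_lo, threshold_hi = threshold_hi
        )
        herm_class[[pop]] <- hc
        mono <- hc$individual_id[hc$karyotype_call == "monogenic_WW"]
        amph <- hc$individual_id[hc$karyotype_call == "amphigenic_ZW"]
        kar[mono] <- "WW"
        kar[amph] <- "ZW"
        if (length(mono) > 0L && length(amph) > 0L) {
          z_calls <- find_chromosome_specific(
            cat, cov, carriers = c(hom_ids, amph), non_carriers = mono,
            chromosome = "Z", karyotypes = kar, ...
          )
        }
        groups <- list(ZW = amph, ZZ = hom_ids,
                       WW = if (length(mono) > 0L) mono)
        groups <- purrr::compact(groups)
      } else {
        groups <- list(ZW = character(), ZZ = hom_ids)
      }
    }
    sl_calls <- if (length(groups$ZW) > 0L) {
      find_sexlinked_alleles(cat, groups, model)
    } else {
      NULL
    }
    calls <- dplyr::bind_rows(
      dplyr::mutate(w_calls, stage = "chromosome_specific"),
      if (!is.null(z_calls)) dplyr::mutate(z_calls, stage = "chromosome_specific"),
      if (!is.null(sl_calls)) dplyr::mutate(sl_calls, stage = "segregation")
    )
    if (is.null(calls) || nrow(calls) == 0L) {
      calls <- tibble::tibble(marker_id = character(), category = character())
    }
    all_calls[[pop]] <- dplyr::mutate(calls, population = pop)
    n_w <- sum(calls$category == "W_specific")
    n_z <- sum(calls$category == "Z_specific")
    n_s <- sum(calls$category == "sexlinked_alleles")
    summaries[[pop]] <- tibble::tibble(
      population = pop, sexual_system = system,
      n_W_specific = n_w, n_Z_specific = n_z,
      n_sexlinked_alleles = n_s, n_total = n_w + n_z + n_s
    )
  }
  structure(
    list(
      model = model,
      calls = dplyr::bind_rows(all_calls),
      hermaphrodites = herm_class,
      summary = dplyr::bind_rows(summaries)
    ),
    class = "zw_model_eval"
  )
}

#' @export
print.zw_model_eval <- function(x, ...) {
  cat("<zw_model_eval>", x$model$heterogametic_sex, "\n")
  print(x$summary)
  invisible(x)
}

#' @describeIn evaluate_model Per-marker calls with evidence flags, one
#'   row per classified or presence-pattern-matching marker.
#' @param x A `zw_model_eval`.
#' @exportS3Method generics::tidy
tidy.zw_model_eval <- function(x, ...) {
  tibble::as_tibble(x$calls)
}

#' @describeIn evaluate_model One row per population with category
#'   counts.
#' @exportS3Method generics::glance
glance.zw_model_eval <- function(x, ...) {
  x$summary
}
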