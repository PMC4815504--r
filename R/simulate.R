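#' Population specification for the ZW simulator
#'
#' Describes one simulated population. Two sexual systems are supported:
#' a dioecious obligate outcrosser (females ZW, males ZZ; genotypes drawn
#' as random unions of gametes at the founder allele frequencies) and an
#' androdioecious selfer (hermaphrodites WW or ZW, rare males ZZ;
#' individuals are sampled from broods produced by lineages that have
#' selfed for `selfing_generations` discrete generations, which builds up
#' homozygosity and genome-wide genotypic disequilibrium).
#'
#' @param name Population label.
#' @param sexual_system `"dioecious"` or `"androdioecious"`.
#' @param n_female,n_male,n_hermaphrodite Number of sampled individuals
#'   per phenotype. A dioecious population needs females and males; an
#'   androdioecious one needs hermaphrodites (males optional but require
#'   amphigenic ZW lineages to arise).
#' @param n_by_karyotype Optional named vector fixing the sampled
#'   karyotype composition, e.g. `c(WW = 4, ZW = 11, ZZ = 6)` (the
#'   phenotype counts are then derived from it). Only meaningful for
#'   androdioecious populations, where hermaphrodites are a mixture of
#'   monogenic (WW) and amphigenic (ZW) karyotypes.
#' @param selfing_generations Discrete selfing generations between the
#'   founders and the sampled brood (androdioecious only); 0 samples the
#'   founders themselves.
#' @param fraction_monogenic_founders Probability that a founder
#'   hermaphrodite is monogenic (WW) rather than amphigenic (ZW).
#' @param n_founders Number of founder (and maintained) selfing lineages.
#' @param brood_size Selfed offspring per lineage in the sampled brood.
#' @return A `pop_spec` list.
#' @export
pop_spec <- function(name,
                     sexual_system = c("dioecious", "androdioecious"),
                     n_female = 0L, n_male = 0L, n_hermaphrodite = 0L,
                     n_by_karyotype = NULL,
                     selfing_generations = 0L,
                     fraction_monogenic_founders = 0,
                     n_founders = 8L,
                     brood_size = 30L) {
  sexual_system <- match.arg(sexual_system)
  if (!is.null(n_by_karyotype)) {
    stopifnot(all(names(n_by_karyotype) %in% c("WW", "ZW", "ZZ")))
    n_male <- sum(n_by_karyotype[names(n_by_karyotype) == "ZZ"])
    n_w <- sum(n_by_karyotype[names(n_by_karyotype) != "ZZ"])
    if (sexual_system == "dioecious") n_female <- n_w else n_hermaphrodite <- n_w
  }
  if (sexual_system == "dioecious") {
    if (n_female < 1L || n_male < 1L) {
      abort("config error: a dioecious population needs >=1 female and >=1 male.")
    }
    if (n_hermaphrodite > 0L) {
      abort("config error: hermaphrodites cannot occur in a dioecious population.")
    }
  } else {
    if (n_hermaphrodite < 1L) {
      abort("config error: an androdioecious population needs >=1 hermaphrodite.")
    }
    if (n_female > 0L) {
      abort("config error: females are recorded as hermaphrodites in an androdioecious population.")
    }
    if (selfing_generations < 1L && (n_male > 0L || !is.null(n_by_karyotype))) {
      abort("config error: males/karyotype mixtures need >=1 selfed brood generation.")
    }
  }
  structure(
    list(
      name = name, sexual_system = sexual_system,
      n_female = as.integer(n_female), n_male = as.integer(n_male),
      n_hermaphrodite = as.integer(n_hermaphrodite),
      n_by_karyotype = n_by_karyotype,
      selfing_generations = as.integer(selfing_generations),
      fraction_monogenic_founders = fraction_monogenic_founders,
      n_founders = as.integer(n_founders),
      brood_size = as.integer(brood_size)
    ),
    class = "pop_spec"
  )
}

#' Marker architecture of a simulated genome
#'
#' @param n_autosomal Diploid markers present on autosomes.
#' @param n_W_specific Markers whose restriction site exists only on the
#'   W chromosome (hemizygous in ZW carriers, absent in ZZ).
#' @param n_Z_specific Markers present only on the Z.
#' @param n_shared_sexlinked Markers present on both Z and W but with
#'   chromosome-diagnostic alleles (the completely sex-linked SNP class).
#' @param n_ld_flanking Diploid markers co-inherited with the sex-linked
#'   block at recombination fraction `r`, with alleles fully associated
#'   with Z vs W in the founders.
#' @param n_shared_z_null Of the shared sex-linked markers, how many
#'   carry a null allele segregating on the Z lineage (the restriction
#'   site lost on some Z copies), the known blind spot of strict
#'   complete-linkage criteria.
#' @return A `sim_architecture` list.
#' @export
sim_architecture <- function(n_autosomal = 3769L, n_W_specific = 18L,
                             n_Z_specific = 11L, n_shared_sexlinked = 21L,
                             n_ld_flanking = 3L, n_shared_z_null = 0L) {
  counts <- c(n_autosomal, n_W_specific, n_Z_specific,
              n_shared_sexlinked, n_ld_flanking, n_shared_z_null)
  if (any(counts < 0L)) abort("config error: architecture counts must be >= 0.")
  if (n_shared_z_null > n_shared_sexlinked) {
    abort("config error: n_shared_z_null cannot exceed n_shared_sexlinked.")
  }
  structure(as.list(environment()), class = "sim_architecture")
}

#' Full simulator configuration
#'
#' The defaults emulate the study design the package was validated
#' against: a dioecious population of 12 females + 14 males and an
#' androdioecious population of 15 hermaphrodites + 6 males, a 3822-marker
#' catalogue, per-individual mean autosomal depth between 200 and 450
#' reads, and genotype calls requiring 15 reads.
#'
#' @param pop_specs List of [pop_spec()] objects.
#' @param architecture A [sim_architecture()].
#' @param r Recombination fraction in `[0, 0.5]` between the sex-linked
#'   block and each flanking marker; 0 means complete linkage.
#' @param lambda_range Per-individual mean autosomal read depth is drawn
#'   uniformly from this range (reads).
#' @param dispersion Negative-binomial size parameter of the depth
#'   model; the default 150 gives a coefficient of variation of about
#'   10% at 300 reads, the marker-level noise scale of a high-coverage,
#'   duplicate-removed RAD library.
#' @param call_threshold Reads required to call a genotype (default 15).
#' @param null_allele_rate Probability that an autosomal marker segregates
#'   a restriction-site null allele.
#' @param prop_polymorphic Probability that an autosomal marker is a SNP
#'   (two founder alleles) rather than monomorphic.
#' @param maf_range Founder minor-allele frequency range for polymorphic
#'   autosomal markers.
#' @param z_null_freq Frequency of the null allele among Z copies at
#'   shared markers flagged by `n_shared_z_null`.
#' @param seed Integer seed; the whole simulation is deterministic given
#'   it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(pop_specs = list(
                         pop_spec("ESP", "dioecious", n_female = 12L, n_male = 14L),
                         pop_spec("KOE", "androdioecious", n_hermaphrodite = 15L,
                                  n_male = 6L, selfing_generations = 3L,
                                  fraction_monogenic_founders = 0.25)
                       ),
                       architecture = sim_architecture(),
                       r = 0,
                       lambda_range = c(200, 450),
                       dispersion = 150,
                       call_threshold = 15L,
                       null_allele_rate = 0,
                       prop_polymorphic = 0.3,
                       maf_range = c(0.1, 0.5),
                       z_null_freq = 0.5,
                       seed = 1L) {
  stopifnot(r >= 0, r <= 0.5, dispersion > 0,
            all(lambda_range > 0), length(lambda_range) == 2L,
            null_allele_rate >= 0, null_allele_rate <= 1)
  if (inherits(pop_specs, "pop_spec")) pop_specs <- list(pop_specs)
  structure(as.list(environment()), class = "sim_config")
}

#' Karyotype inheritance under the ZW model
#'
#' Draws offspring karyotypes from two parents (or one selfing
#' hermaphrodite): each parent contributes one of its two sex chromosomes
#' uniformly at random. The W acts as a dominant feminizing/hermaphrodite
#' factor, so selfing an amphigenic (ZW) hermaphrodite yields WW:ZW:ZZ in
#' 1:2:1, i.e. three hermaphrodites for every male, while a monogenic
#' (WW) hermaphrodite selfs true.
#'
#' @param parent1 Karyotype, one of `"ZZ"`, `"ZW"`, `"WW"`.
#' @param parent2 Karyotype of the second parent, or `"SELF"` to self
#'   `parent1` (only hermaphroditic karyotypes, ZW or WW, may self).
#' @param n Number of independent offspring to draw.
#' @return Character vector of offspring karyotypes.
#' @export
#' @examples
#' set.seed(1)
#' table(inherit_karyotype("ZW", "SELF", n = 1000))
inherit_karyotype <- function(parent1, parent2 = "SELF", n = 1L) {
  valid <- c("ZZ", "ZW", "WW")
  if (!parent1 %in% valid) abort("parent1 must be one of ZZ, ZW, WW.")
  if (identical(parent2, "SELF")) {
    if (parent1 == "ZZ") {
      abort("model error: a ZZ male cannot self-fertilize.")
    }
    parent2 <- parent1
  }
  if (!parent2 %in% valid) abort("parent2 must be ZZ, ZW, WW or 'SELF'.")
  g1 <- sample(strsplit(parent1, "")[[1]], n, replace = TRUE)
  g2 <- sample(strsplit(parent2, "")[[1]], n, replace = TRUE)
  n_w <- (g1 == "W") + (g2 == "W")
  c("ZZ", "ZW", "WW")[n_w + 1L]
}

#' Phenotype implied by a karyotype
#'
#' Phenotype is a deterministic function of karyotype: any W copy makes
#' the individual female (dioecious system) or hermaphrodite
#' (androdioecious system); ZZ individuals are male.
#'
#' @param karyotype Character vector of `"ZZ"`, `"ZW"`, `"WW"`.
#' @param sexual_system `"dioecious"` or `"androdioecious"`.
#' @return Character vector of phenotypes.
#' @export
karyotype_phenotype <- function(karyotype,
                                sexual_system = c("dioecious", "androdioecious")) {
  sexual_system <- match.arg(sexual_system)
  ifelse(karyotype == "ZZ", "male",
         if (sexual_system == "dioecious") "female" else "hermaphrodite")
}

#' Copy number of a marker given karyotype and marker class
#'
#' W-specific markers exist in as many copies as there are W chromosomes,
#' Z-specific markers as many as Z chromosomes, and autosomal / shared
#' sex-linked / flanking markers in two copies; null alleles (lost
#' restriction sites) subtract copies.
#'
#' @param karyotype `"ZZ"`, `"ZW"` or `"WW"` (vectorized).
#' @param category One of `"autosomal"`, `"W_specific"`, `"Z_specific"`,
#'   `"shared_sexlinked"`, `"ld_flanking"`.
#' @param n_null Number of chromosome copies carrying a null allele at
#'   this marker (0, 1 or 2).
#' @return Integer copy number in `{0, 1, 2}`.
#' @export
assign_marker_copies <- function(karyotype, category, n_null = 0L) {
  stopifnot(all(karyotype %in% c("ZZ", "ZW", "WW")),
            all(category %in% c("autosomal", "W_specific", "Z_specific",
                                "shared_sexlinked", "ld_flanking")))
  n_w <- vapply(strsplit(karyotype, ""), function(x) sum(x == "W"), 0L)
  base <- ifelse(category == "W_specific", n_w,
                 ifelse(category == "Z_specific", 2L - n_w, 2L))
  pmax(0L, base - as.integer(n_null))
}

#' Draw a read depth for a marker cell
#'
#' Depth is negative-binomial with mean `copies / 2 * lambda` (a
#' hemizygous marker yields half the reads of a diploid one) and the
#' given dispersion; zero copies always yield zero reads.
#'
#' @param copies Copy number in `{0, 1, 2}` (vectorized).
#' @param lambda Individual mean depth at diploid markers (reads).
#' @param dispersion Negative-binomial size parameter (> 0).
#' @return Integer vector of read depths.
#' @export
draw_depth <- function(copies, lambda, dispersion = 150) {
  if (any(dispersion <= 0)) abort("config error: dispersion must be > 0.")
  if (any(lambda <= 0)) abort("config error: lambda must be > 0.")
  as.integer(rnbinom(length(copies), mu = copies / 2 * lambda, size = dispersion))
}

# ---- internal machinery -----------------------------------------------------

# A sex chromosome is a list: type ("W"/"Z"), flank (alleles at the
# ld_flanking markers), znull (logical per shared marker; only Z copies
# can carry a null). Autosomal alleles are stored separately as an
# n_autosomal x 2 character matrix ("a", "b", or "0" for a null allele).

.new_chromosome <- function(type, arch, r, z_null_flags, z_null_freq,
                            founder = FALSE) {
  diag_allele <- if (type == "W") "p" else "q"
  other <- if (type == "W") "q" else "p"
  n_ld <- arch$n_ld_flanking
  flank <- if (n_ld > 0L) {
    if (founder || r == 0) rep(diag_allele, n_ld) else
      ifelse(runif(n_ld) < r, other, diag_allele)
  } else character()
  znull <- if (type == "Z") {
    z_null_flags & (runif(arch$n_shared_sexlinked) < z_null_freq)
  } else {
    rep(FALSE, arch$n_shared_sexlinked)
  }
  list(type = type, flank = flank, znull = znull)
}

.founder_autosomes <- function(freq_tbl) {
  # one diploid genotype column pair drawn at the founder frequencies
  draw <- function() {
    u <- runif(nrow(freq_tbl))
    ifelse(u < freq_tbl$p_a, "a",
           ifelse(u < freq_tbl$p_a + freq_tbl$p_b, "b", "0"))
  }
  cbind(draw(), draw())
}

.make_individual <- function(karyotype, arch, r, freq_tbl, z_null_flags,
                             z_null_freq, founder = FALSE) {
  types <- strsplit(karyotype, "")[[1]]
  types <- sort(types, decreasing = TRUE)  # Z before W irrelevant; fixed order
  list(
    karyotype = karyotype,
    chroms = list(
      .new_chromosome(types[1], arch, r, z_null_flags, z_null_freq, founder),
      .new_chromosome(types[2], arch, r, z_null_flags, z_null_freq, founder)
    ),
    autosomes = .founder_autosomes(freq_tbl)
  )
}

.gamete <- function(ind, r, n_autosomal) {
  k <- sample(c(1L, 2L), 1L)
  chrom <- ind$chroms[[k]]
  other <- ind$chroms[[3L - k]]
  if (length(chrom$flank) > 0L && r > 0) {
    swap <- runif(length(chrom$flank)) < r
    chrom$flank[swap] <- other$flank[swap]
  }
  idx <- sample(c(1L, 2L), n_autosomal, replace = TRUE)
  list(chrom = chrom,
       autosomes = ind$autosomes[cbind(seq_len(n_autosomal), idx)])
}

.self_offspring <- function(ind, r, n_autosomal) {
  g1 <- .gamete(ind, r, n_autosomal)
  g2 <- .gamete(ind, r, n_autosomal)
  n_w <- (g1$chrom$type == "W") + (g2$chrom$type == "W")
  list(
    karyotype = c("ZZ", "ZW", "WW")[n_w + 1L],
    chroms = list(g1$chrom, g2$chrom),
    autosomes = cbind(g1$autosomes, g2$autosomes)
  )
}

.simulate_pop_individuals <- function(spec, arch, r, freq_tbl,
                                      z_null_flags, z_null_freq) {
  n_auto <- arch$n_autosomal
  if (spec$sexual_system == "dioecious") {
    karyos <- c(rep("ZW", spec$n_female), rep("ZZ", spec$n_male))
    inds <- lapply(karyos, .make_individual, arch = arch, r = r,
                   freq_tbl = freq_tbl, z_null_flags = z_null_flags,
                   z_null_freq = z_null_freq, founder = (r == 0))
    return(inds)
  }
  # androdioecious: founder lineages -> selfing generations -> brood sample
  founder_karyo <- ifelse(
    runif(spec$n_founders) < spec$fraction_monogenic_founders, "WW", "ZW"
  )
  lineages <- lapply(founder_karyo, .make_individual, arch = arch, r = r,
                     freq_tbl = freq_tbl, z_null_flags = z_null_flags,
                     z_null_freq = z_null_freq, founder = TRUE)
  g <- spec$selfing_generations
  if (g == 0L) {
    pool <- lineages
  } else {
    if (g > 1L) {
      for (gen in seq_len(g - 1L)) {
        lineages <- lapply(lineages, function(ind) {
          # the lineage persists through a selfed hermaphrodite offspring
          # of the founder karyotype (amphigenic lines stay amphigenic,
          # monogenic lines self true anyway)
          repeat {
            off <- .self_offspring(ind, r, n_auto)
            if (off$karyotype == ind$karyotype) return(off)
          }
        })
      }
    }
    pool <- unlist(lapply(lineages, function(ind) {
      lapply(seq_len(spec$brood_size), function(i) .self_offspring(ind, r, n_auto))
    }), recursive = FALSE)
  }
  pool_karyo <- vapply(pool, function(x) x$karyotype, "")
  pick <- integer()
  if (!is.null(spec$n_by_karyotype)) {
    for (k in names(spec$n_by_karyotype)) {
      avail <- which(pool_karyo == k)
      need <- spec$n_by_karyotype[[k]]
      if (length(avail) < need) {
        abort(paste0("config error: brood produced only ", length(avail),
                     " ", k, " individuals, ", need, " requested."))
      }
      pick <- c(pick, sample(avail, need))
    }
  } else {
    herm <- which(pool_karyo != "ZZ")
    male <- which(pool_karyo == "ZZ")
    if (length(herm) < spec$n_hermaphrodite || length(male) < spec$n_male) {
      abort("config error: brood too small for the requested phenotype counts.")
    }
    pick <- c(sample(herm, spec$n_hermaphrodite),
              if (spec$n_male > 0L) sample(male, spec$n_male))
  }
  pool[pick]
}

# allele pair (chromosome-borne alleles, NA = no copy) for one individual
# across all markers, given the truth table
.allele_pairs <- function(ind, truth_markers) {
  n <- nrow(truth_markers)
  a1 <- rep(NA_character_, n)
  a2 <- rep(NA_character_, n)
  cat_ <- truth_markers$category
  auto_rows <- which(cat_ == "autosomal")
  a1[auto_rows] <- ind$autosomes[, 1]
  a2[auto_rows] <- ind$autosomes[, 2]
  a1[auto_rows][ind$autosomes[, 1] == "0"] <- NA
  a2[auto_rows][ind$autosomes[, 2] == "0"] <- NA
  types <- c(ind$chroms[[1]]$type, ind$chroms[[2]]$type)
  w_rows <- which(cat_ == "W_specific")
  z_rows <- which(cat_ == "Z_specific")
  s_rows <- which(cat_ == "shared_sexlinked")
  l_rows <- which(cat_ == "ld_flanking")
  for (k in 1:2) {
    vec <- if (k == 1L) a1 else a2
    ch <- ind$chroms[[k]]
    vec[w_rows] <- if (ch$type == "W") "w" else NA_character_
    vec[z_rows] <- if (ch$type == "Z") "z" else NA_character_
    if (length(s_rows) > 0L) {
      vec[s_rows] <- if (ch$type == "W") "W" else ifelse(ch$znull, NA, "Z")
    }
    if (length(l_rows) > 0L) vec[l_rows] <- ch$flank
    if (k == 1L) a1 <- vec else a2 <- vec
  }
  cbind(a1, a2)
}

#' Simulate one or more populations with ZW inheritance
#'
#' Generates a complete marker catalogue (genotype calls + read depths)
#' plus the planted ground truth for every marker and individual, under
#' the configuration's marker architecture and depth model. Genotypes
#' are called wherever at least one marker copy exists and the drawn
#' depth reaches the call threshold; hemizygous or homozygous cells show
#' a single allele, so zygosity alone cannot distinguish them (exactly
#' the ambiguity the normalized-coverage evidence resolves).
#'
#' @param cfg A [sim_config()].
#' @return A `rad_sim` object: list with `catalogue` (a
#'   [rad_catalogue]), and `truth` holding `markers` (tibble:
#'   `marker_id`, `category`, `w_allele`, `z_allele`, `z_null`) and
#'   `individuals` (tibble: `id`, `population`, `phenotype`,
#'   `karyotype`, `lambda`).
#' @export
#' @examples
#' sim <- simulate_population(sim_config(
#'   pop_specs = list(pop_spec("P", "dioecious", n_female = 4, n_male = 4)),
#'   architecture = sim_architecture(n_autosomal = 50, n_W_specific = 3,
#'     n_Z_specific = 2, n_shared_sexlinked = 2, n_ld_flanking = 0),
#'   seed = 42
#' ))
#' sim$catalogue
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  arch <- cfg$architecture
  n_total <- arch$n_autosomal + arch$n_W_specific + arch$n_Z_specific +
    arch$n_shared_sexlinked + arch$n_ld_flanking
  if (n_total < 1L) abort("config error: architecture has zero markers.")

  categories <- sample(rep(
    c("autosomal", "W_specific", "Z_specific", "shared_sexlinked", "ld_flanking"),
    times = c(arch$n_autosomal, arch$n_W_specific, arch$n_Z_specific,
              arch$n_shared_sexlinked, arch$n_ld_flanking)
  ))
  width <- nchar(as.character(n_total))
  truth_markers <- tibble::tibble(
    marker_id = sprintf(paste0("m%0", width, "d"), seq_len(n_total)),
    category = categories,
    w_allele = ifelse(categories == "shared_sexlinked", "W", NA),
    z_allele = ifelse(categories == "shared_sexlinked", "Z", NA),
    z_null = FALSE
  )
  if (arch$n_shared_z_null > 0L) {
    shared_idx <- which(truth_markers$category == "shared_sexlinked")
    null_idx <- shared_idx[seq_len(arch$n_shared_z_null)]
    truth_markers$z_null[null_idx] <- TRUE
  }
  z_null_flags <- truth_markers$z_null[truth_markers$category == "shared_sexlinked"]

  # founder allele frequencies, shared between populations
  poly <- runif(arch$n_autosomal) < cfg$prop_polymorphic
  maf <- runif(arch$n_autosomal, cfg$maf_range[1], cfg$maf_range[2])
  has_null <- runif(arch$n_autosomal) < cfg$null_allele_rate
  f_null <- ifelse(has_null, runif(arch$n_autosomal, 0.05, 0.3), 0)
  p_a <- ifelse(poly, 1 - maf, 1) * (1 - f_null)
  p_b <- ifelse(poly, maf, 0) * (1 - f_null)
  freq_tbl <- tibble::tibble(p_a = p_a, p_b = p_b)

  all_calls <- list()
  all_inds <- list()
  for (spec in cfg$pop_specs) {
    inds <- .simulate_pop_individuals(spec, arch, cfg$r, freq_tbl,
                                      z_null_flags, cfg$z_null_freq)
    karyos <- vapply(inds, function(x) x$karyotype, "")
    phen <- karyotype_phenotype(karyos, spec$sexual_system)
    tag <- toupper(substr(phen, 1, 1))
    ids <- paste0(spec$name, "_", tag, stats::ave(seq_along(phen), phen, FUN = seq_along))
    lambda <- runif(length(inds), cfg$lambda_range[1], cfg$lambda_range[2])

    n_mark <- n_total
    depth <- matrix(0L, n_mark, length(inds))
    a1 <- matrix(NA_character_, n_mark, length(inds))
    a2 <- a1
    for (j in seq_along(inds)) {
      pairs <- .allele_pairs(inds[[j]], truth_markers)
      copies <- rowSums(!is.na(pairs))
      depth[, j] <- draw_depth(copies, lambda[j], cfg$dispersion)
      called <- depth[, j] >= cfg$call_threshold & copies >= 1L
      lo <- pmin(pairs[, 1], pairs[, 2], na.rm = TRUE)
      hi <- pmax(pairs[, 1], pairs[, 2], na.rm = TRUE)
      a1[called, j] <- lo[called]
      a2[called, j] <- hi[called]
    }
    calls <- tibble::tibble(
      marker_id = rep(truth_markers$marker_id, times = length(inds)),
      individual_id = rep(ids, each = n_mark),
      allele_a = as.vector(a1), allele_b = as.vector(a2),
      depth = as.integer(as.vector(depth))
    )
    all_calls[[spec$name]] <- calls
    all_inds[[spec$name]] <- tibble::tibble(
      id = ids, population = spec$name, phenotype = phen,
      karyotype = karyos, lambda = lambda
    )
  }
  truth_inds <- dplyr::bind_rows(all_inds)
  individuals <- truth_inds |>
    dplyr::mutate(karyotype = "unknown") |>
    dplyr::select("id", "population", "phenotype", "karyotype")
  catalogue <- rad_catalogue(
    dplyr::bind_rows(all_calls), individuals,
    call_threshold = cfg$call_threshold
  )
  structure(
    list(catalogue = catalogue,
         truth = list(markers = truth_markers, individuals = truth_inds),
         config = cfg),
    class = "rad_sim"
  )
}

#' @export
print.rad_sim <- function(x, ...) {
  cat("<rad_sim> seed", x$config$seed %||% NA, "\n")
  print(x$catalogue)
  print(dplyr::count(x$truth$markers, .data$category))
  invisible(x)
}

#' Write a simulation to disk
#'
#' Emits the catalogue TSV, the metadata TSV and a marker/individual
#' truth TSV pair under a common file prefix.
#'
#' @param sim A `rad_sim` from [simulate_population()].
#' @param prefix Path prefix; files `<prefix>_catalogue.tsv`,
#'   `<prefix>_metadata.tsv`, `<prefix>_truth_markers.tsv` and
#'   `<prefix>_truth_individuals.tsv` are written.
#' @return The four paths, invisibly.
#' @export
write_simulation <- function(sim, prefix) {
  paths <- paste0(prefix, c("_catalogue.tsv", "_metadata.tsv",
                            "_truth_markers.tsv", "_truth_individuals.tsv"))
  write_catalogue(sim$catalogue, paths[1], paths[2])
  readr::write_tsv(sim$truth$markers, paths[3])
  readr::write_tsv(sim$truth$individuals, paths[4])
  invisible(paths)
}
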