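## Synthetic-data generators.
##
## Every input the pipeline consumes can be generated here with the
## statistical structure the downstream analysis assumes: a multi-site
## patient/control cohort with age-related thinning and a planted
## sex-by-group atrophy interaction, spatially autocorrelated regional gene
## maps with a planted gene set tracking the interaction map, donor-level
## microarray bundles, gene-set collections, and a genes-by-tissues TPM
## table. All generators are pure functions of (config, seed).

#' Evaluate code under a temporary RNG seed, restoring global state
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Cohort configuration for the synthetic multi-site study
#'
#' Defines the simulated study: group-by-sex sample sizes, the parcellation
#' size, additive/multiplicative scanner (site) effects, age-related cortical
#' thinning, and a planted sex-by-group atrophy interaction concentrated in a
#' subset of regions. Defaults mirror a prodromal-synucleinopathy design:
#' a male-skewed patient group (294 M / 49 F), sex-imbalanced controls
#' (213 M / 131 F), ages in 55-80 years, and patients thinning more in males
#' than in females (the planted "selective protection" of females).
#'
#' @param n_patients_f,n_patients_m,n_controls_f,n_controls_m Group sizes.
#' @param n_regions Number of cortical parcels (left hemisphere; default 499).
#' @param n_sites Number of acquisition sites.
#' @param site_shift Additive site effect in mm; scalar (recycled, centered)
#'   or vector of length `n_sites`.
#' @param site_scale Multiplicative site effect on the noise SD; scalar or
#'   vector of length `n_sites`, all > 0.
#' @param age_range Two-element numeric, years.
#' @param age_slope Thickness change per year of age (mm/year; negative =
#'   thinning).
#' @param atrophy_regions Integer region ids carrying the planted patient
#'   atrophy (subset of `1:n_regions`). The default is the 60 highest ids,
#'   which form a compact polar cap on the Fibonacci geometry — a focal
#'   atrophy patch. (Low ids form a thin annulus at the hemisphere rim,
#'   which is a poor stand-in for focal atrophy and interacts badly with
#'   hemispheric spin nulls.)
#' @param atrophy_male,atrophy_female Mean thickness change (mm) in patients
#'   within `atrophy_regions`, by sex. `|atrophy_female| <= |atrophy_male|`
#'   plants the female-protection interaction.
#' @param noise_sd Residual thickness SD in mm.
#' @param seed Integer seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients_f = 49, n_patients_m = 294,
                          n_controls_f = 131, n_controls_m = 213,
                          n_regions = 499, n_sites = 3,
                          site_shift = c(-0.05, 0, 0.05),
                          site_scale = c(1, 1.15, 0.9),
                          age_range = c(55, 80), age_slope = -0.01,
                          atrophy_regions = seq(max(1, n_regions - 59),
                                                n_regions),
                          atrophy_male = -0.3, atrophy_female = -0.1,
                          noise_sd = 0.25, seed = 1L) {
  counts <- c(n_patients_f, n_patients_m, n_controls_f, n_controls_m,
              n_regions, n_sites)
  if (any(counts <= 0) || any(counts != round(counts)))
    stop("all counts must be positive integers")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (length(site_shift) == 1) site_shift <- rep(site_shift, n_sites)
  if (length(site_scale) == 1) site_scale <- rep(site_scale, n_sites)
  if (length(site_shift) != n_sites || length(site_scale) != n_sites)
    stop("site_shift and site_scale must have length 1 or n_sites")
  if (any(site_scale <= 0)) stop("site_scale must be > 0")
  if (length(age_range) != 2 || diff(age_range) <= 0)
    stop("age_range must be an increasing pair of years")
  atrophy_regions <- as.integer(atrophy_regions)
  if (!all(atrophy_regions %in% seq_len(n_regions)))
    stop("atrophy_regions must be a subset of 1..n_regions")
  if (abs(atrophy_female) > abs(atrophy_male))
    stop("|atrophy_female| must be <= |atrophy_male| (planted protection)")
  structure(list(
    n_patients_f = n_patients_f, n_patients_m = n_patients_m,
    n_controls_f = n_controls_f, n_controls_m = n_controls_m,
    n_regions = n_regions, n_sites = n_sites,
    site_shift = site_shift, site_scale = site_scale,
    age_range = age_range, age_slope = age_slope,
    atrophy_regions = atrophy_regions,
    atrophy_male = atrophy_male, atrophy_female = atrophy_female,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Expression-generator configuration
#'
#' @param n_genes Number of genes.
#' @param smoothing_length Angular scale (radians) of the exponential spatial
#'   autocorrelation kernel applied to background gene maps; 0 disables
#'   smoothing.
#' @param planted_set_size Number of planted genes tracking the interaction
#'   map (>= 5 so the planted set survives the enrichment size filter).
#' @param planted_coupling Correlation in [0, 1] between each planted gene's
#'   regional profile and the interaction map.
#' @param seed Integer seed.
#' @return A list of class `expression_config`.
#' @export
expression_config <- function(n_genes = 1000, smoothing_length = 0.3,
                              planted_set_size = 20, planted_coupling = 0.8,
                              seed = 1L) {
  if (n_genes < 10) stop("n_genes must be >= 10")
  if (planted_coupling < 0 || planted_coupling > 1)
    stop("planted_coupling must lie in [0, 1]")
  if (planted_set_size < 5)
    stop("planted_set_size must be >= 5")
  if (planted_set_size > n_genes) stop("planted_set_size exceeds n_genes")
  if (smoothing_length < 0) stop("smoothing_length must be >= 0")
  structure(list(n_genes = n_genes, smoothing_length = smoothing_length,
                 planted_set_size = planted_set_size,
                 planted_coupling = planted_coupling, seed = as.integer(seed)),
            class = "expression_config")
}

#' Generate region geometry on the left unit hemisphere
#'
#' Places `n_regions` quasi-uniform region centroids on the unit hemisphere
#' (x <= 0, the left hemisphere convention) using a Fibonacci lattice with a
#' small seeded angular jitter, standing in for the centroids of a cortical
#' parcellation. MNI coordinates are the spherical centroids scaled to a
#' 100 mm radius.
#'
#' @param n_regions Number of regions (>= 10).
#' @param seed Integer seed.
#' @return A data.frame with columns `region_id`, `hemisphere`, `sx`, `sy`,
#'   `sz` (unit sphere) and `mni_x`, `mni_y`, `mni_z` (mm).
#' @export
generate_geometry <- function(n_regions = 499, seed = 1L) {
  if (n_regions < 10) stop("n_regions must be >= 10")
  with_seed(seed, {
    i <- seq_len(n_regions)
    golden <- (1 + sqrt(5)) / 2
    x <- -((i - 0.5) / n_regions)             # uniform in (-1, 0): left only
    phi <- 2 * pi * i / golden + stats::runif(n_regions, -0.02, 0.02)
    x <- x + stats::runif(n_regions, -0.2, 0.2) / n_regions
    x <- pmin(pmax(x, -1 + 1e-9), -1e-9)
    r <- sqrt(1 - x^2)
    xyz <- cbind(sx = x, sy = r * cos(phi), sz = r * sin(phi))
    data.frame(region_id = i, hemisphere = "L", xyz,
               mni_x = 100 * xyz[, 1], mni_y = 100 * xyz[, 2],
               mni_z = 100 * xyz[, 3])
  })
}

#' Smooth per-region baseline thickness profile (deterministic in geometry)
#' @keywords internal
#' @noRd
baseline_thickness <- function(geom) {
  2.5 + 0.15 * geom$sz + 0.1 * sin(3 * geom$sy)
}

#' Generate a synthetic multi-site cohort with a planted sex interaction
#'
#' Thickness for participant i in region r is
#' `baseline(r) + age_slope * (age_i - midpoint) + site_shift[s_i] +
#'  site_scale[s_i] * noise + atrophy`, where the atrophy term applies to
#' patients only, within `atrophy_regions`, with amplitude `atrophy_male` or
#' `atrophy_female` by sex. Ages are uniform on `age_range`; sites are
#' assigned round-robin. Non-positive thickness values (possible only under
#' extreme configurations) are clipped to 0.01 mm with a warning.
#'
#' @param cfg A [cohort_config()].
#' @param geom Geometry from [generate_geometry()]; must have
#'   `cfg$n_regions` rows.
#' @return A list with `participants` (data.frame: id, group, sex, age, site)
#'   and `thickness` (participants x regions matrix, mm; columns named by
#'   region id).
#' @export
generate_cohort <- function(cfg, geom) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (nrow(geom) != cfg$n_regions)
    stop("geometry has ", nrow(geom), " regions; config expects ",
         cfg$n_regions)
  with_seed(cfg$seed, {
    grp <- c(rep("patient", cfg$n_patients_f + cfg$n_patients_m),
             rep("control", cfg$n_controls_f + cfg$n_controls_m))
    sex <- c(rep("F", cfg$n_patients_f), rep("M", cfg$n_patients_m),
             rep("F", cfg$n_controls_f), rep("M", cfg$n_controls_m))
    n <- length(grp)
    participants <- data.frame(
      id = sprintf("sub-%04d", seq_len(n)),
      group = grp, sex = sex,
      age = stats::runif(n, cfg$age_range[1], cfg$age_range[2]),
      site = paste0("site", rep_len(seq_len(cfg$n_sites), n)),
      stringsAsFactors = FALSE
    )
    site_idx <- rep_len(seq_len(cfg$n_sites), n)
    base <- baseline_thickness(geom)
    eps <- matrix(stats::rnorm(n * cfg$n_regions, 0, cfg$noise_sd),
                  n, cfg$n_regions)
    thick <- matrix(base, n, cfg$n_regions, byrow = TRUE) +
      cfg$age_slope * (participants$age - mean(cfg$age_range)) +
      cfg$site_shift[site_idx] +
      cfg$site_scale[site_idx] * eps
    amp <- ifelse(grp == "patient",
                  ifelse(sex == "M", cfg$atrophy_male, cfg$atrophy_female), 0)
    thick[, cfg$atrophy_regions] <- thick[, cfg$atrophy_regions] + amp
    if (any(thick <= 0)) {
      warning("clipped ", sum(thick <= 0), " non-positive thickness value(s)")
      thick[thick <= 0] <- 0.01
    }
    dimnames(thick) <- list(participants$id, geom$region_id)
    list(participants = participants, thickness = thick)
  })
}

#' Ground-truth sex-interaction map implied by a cohort configuration
#'
#' The planted per-region female-minus-male atrophy contrast:
#' `atrophy_female - atrophy_male` inside `atrophy_regions`, 0 elsewhere.
#' Positive values mean females are less atrophied than males (protection),
#' matching the sign convention of [sex_interaction_estimates()].
#'
#' @param cfg A [cohort_config()].
#' @return Numeric vector of length `n_regions`, named by region id.
#' @export
planted_interaction_map <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  m <- numeric(cfg$n_regions)
  m[cfg$atrophy_regions] <- cfg$atrophy_female - cfg$atrophy_male
  names(m) <- seq_len(cfg$n_regions)
  m
}

#' Generate a regions x genes expression matrix with planted signal genes
#'
#' Background genes are spatially smoothed Gaussian fields (exponential
#' kernel in angular distance, scale `smoothing_length`). Planted genes mix
#' the standardized interaction map with smoothed noise at correlation
#' `planted_coupling`. Every gene column is standardized to mean 0, SD 1
#' across regions.
#'
#' @param cfg An [expression_config()].
#' @param geom Geometry from [generate_geometry()].
#' @param interaction_map Numeric vector, one value per region of `geom`.
#' @return A list with `expression` (regions x genes matrix, rows named by
#'   region id, columns by gene id) and `planted_genes` (character).
#' @export
generate_expression <- function(cfg, geom, interaction_map) {
  stopifnot(inherits(cfg, "expression_config"))
  n_r <- nrow(geom)
  if (length(interaction_map) != n_r)
    stop("interaction_map length must equal the number of regions")
  if (cfg$planted_coupling > 0 && stats::sd(interaction_map) == 0)
    stop("interaction_map is constant; cannot plant a coupled signal")
  with_seed(cfg$seed, {
    genes <- sprintf("G%05d", seq_len(cfg$n_genes))
    K <- if (cfg$smoothing_length > 0) {
      A <- angular_distance(as.matrix(geom[, c("sx", "sy", "sz")]))
      exp(-A / cfg$smoothing_length)
    } else diag(n_r)
    raw <- matrix(stats::rnorm(n_r * cfg$n_genes), n_r, cfg$n_genes)
    X <- zscore_cols(K %*% raw)
    planted <- sort(sample(cfg$n_genes, cfg$planted_set_size))
    if (cfg$planted_coupling > 0) {
      m <- as.numeric(scale(interaction_map))
      cc <- cfg$planted_coupling
      X[, planted] <- cc * m + sqrt(1 - cc^2) * X[, planted]
      X <- zscore_cols(X)
    }
    dimnames(X) <- list(geom$region_id, genes)
    list(expression = X, planted_genes = genes[planted])
  })
}

#' Generate donor-level microarray bundles
#'
#' Emulates the structure of post-mortem donor microarrays: per donor, tissue
#' samples with MNI coordinates jittered around region centroids plus a few
#' far-off unassignable samples; 1-3 probes per gene with one high-fidelity
#' probe and optionally a noisy probe and/or a background-failing probe; and
#' per probe x sample boolean above-background calls. A shared ground-truth
#' regional profile per gene (smooth field on the geometry) underlies all
#' donors, so the assembly pipeline can be validated against the truth.
#'
#' @param n_donors Number of donors (>= 2).
#' @param genes Character vector of gene ids, or a count.
#' @param geom Geometry from [generate_geometry()].
#' @param seed Integer seed.
#' @param region_coverage Fraction of regions sampled per donor.
#' @param jitter_mm SD of the coordinate jitter around centroids (mm).
#' @param n_far_samples Unassignable samples per donor, placed far from every
#'   centroid to exercise the exclusion rule.
#' @param noise_sd Intensity noise SD of the high-fidelity probe.
#' @param p_extra_noisy,p_extra_failing Probabilities that a gene carries an
#'   additional noisy probe / a background-failing probe.
#' @return A list of class `donor_bundle`: `probes` (probe_id, gene),
#'   `donors` (per donor: `samples` data.frame, `intensity` probes x samples,
#'   `background` logical probes x samples), and `truth` (regions x genes
#'   ground-truth profiles).
#' @export
generate_donor_microarrays <- function(n_donors = 6, genes, geom, seed = 1L,
                                       region_coverage = 0.7, jitter_mm = 2,
                                       n_far_samples = 3, noise_sd = 0.1,
                                       p_extra_noisy = 0.3,
                                       p_extra_failing = 0.2) {
  if (n_donors < 2) stop("n_donors must be >= 2")
  if (is.numeric(genes)) genes <- sprintf("G%05d", seq_len(genes))
  n_g <- length(genes)
  n_r <- nrow(geom)
  with_seed(seed, {
    A <- angular_distance(as.matrix(geom[, c("sx", "sy", "sz")]))
    K <- exp(-A / 0.3)
    truth <- zscore_cols(K %*% matrix(stats::rnorm(n_r * n_g), n_r, n_g))
    dimnames(truth) <- list(geom$region_id, genes)

    n_extra_noisy <- stats::rbinom(n_g, 1, p_extra_noisy)
    n_extra_fail <- stats::rbinom(n_g, 1, p_extra_failing)
    probe_gene <- rep(genes, times = 1 + n_extra_noisy + n_extra_fail)
    kind <- unlist(mapply(function(a, b) {
      c("hifi", if (a) "noisy", if (b) "failing")
    }, n_extra_noisy, n_extra_fail, SIMPLIFY = FALSE))
    o <- order(probe_gene, match(kind, c("hifi", "noisy", "failing")))
    probe_gene <- probe_gene[o]; kind <- kind[o]
    probes <- data.frame(probe_id = sprintf("P%05d", seq_along(probe_gene)),
                         gene = probe_gene, kind = kind,
                         stringsAsFactors = FALSE)
    n_p <- nrow(probes)
    gene_idx <- match(probes$gene, genes)

    donors <- lapply(seq_len(n_donors), function(d) {
      regions <- sort(sample(n_r, max(2, round(region_coverage * n_r))))
      n_s <- length(regions) + n_far_samples
      coords <- rbind(
        as.matrix(geom[regions, c("mni_x", "mni_y", "mni_z")]) +
          matrix(stats::rnorm(3 * length(regions), 0, jitter_mm),
                 ncol = 3),
        matrix(stats::rnorm(3 * n_far_samples, 0, 5) + 400, ncol = 3)
      )
      samples <- data.frame(
        sample_id = sprintf("D%d_S%03d", d, seq_len(n_s)),
        mni_x = coords[, 1], mni_y = coords[, 2], mni_z = coords[, 3],
        true_region = c(geom$region_id[regions], rep(NA_integer_,
                                                     n_far_samples)),
        stringsAsFactors = FALSE
      )
      donor_scale <- stats::runif(1, 0.8, 1.25)
      donor_shift <- stats::rnorm(1, 0, 0.2)
      base <- truth[c(regions, sample(n_r, n_far_samples)), gene_idx,
                    drop = FALSE]
      noise_mult <- ifelse(probes$kind == "noisy", 8, 1)
      intensity <- donor_scale * (t(base) +
        matrix(stats::rnorm(n_p * n_s), n_p, n_s) * noise_sd * noise_mult) +
        donor_shift
      intensity[probes$kind == "failing", ] <-
        matrix(stats::rnorm(sum(probes$kind == "failing") * n_s, 0, 0.05),
               ncol = n_s)
      bg_rate <- ifelse(probes$kind == "failing", 0.3, 0.98)
      background <- matrix(stats::rbinom(n_p * n_s, 1,
                                         rep(bg_rate, n_s)) == 1, n_p, n_s)
      dimnames(intensity) <- list(probes$probe_id, samples$sample_id)
      dimnames(background) <- dimnames(intensity)
      list(samples = samples, intensity = intensity, background = background)
    })
    structure(list(probes = probes[, c("probe_id", "gene")],
                   donors = donors, truth = truth),
              class = "donor_bundle")
  })
}

#' Generate a gene-set collection containing the planted set
#'
#' @param genes Universe of gene ids.
#' @param planted_set Character vector of planted genes (stored under the
#'   name `"planted_interaction_set"`).
#' @param n_random_sets Number of additional random sets.
#' @param size_range Inclusive size range for random sets.
#' @param seed Integer seed.
#' @return Named list of character vectors (a gene-set collection).
#' @export
generate_genesets <- function(genes, planted_set, n_random_sets = 50,
                              size_range = c(5, 200), seed = 1L) {
  if (size_range[1] < 1 || size_range[2] > length(genes) ||
      size_range[1] > size_range[2])
    stop("size_range must lie within [1, number of genes]")
  if (!all(planted_set %in% genes)) stop("planted_set must be drawn from genes")
  with_seed(seed, {
    sizes <- sample(seq(size_range[1], size_range[2]), n_random_sets,
                    replace = TRUE)
    sets <- lapply(sizes, function(k) sample(genes, k))
    names(sets) <- sprintf("random_set_%03d", seq_len(n_random_sets))
    c(list(planted_interaction_set = planted_set), sets)
  })
}

#' Generate a genes x tissues TPM table with brain-enriched genes
#'
#' Emulates a bulk-RNA tissue compendium: 54 tissues of which 13 are brain
#' subregions. Brain-enriched genes get elevated TPM in brain tissues;
#' other genes are drawn from a flat log-normal. All TPM >= 0.
#'
#' @param genes Character vector of gene ids.
#' @param n_tissues Total number of tissues (default 54).
#' @param n_brain Number of brain tissues (default 13).
#' @param brain_enriched_genes Subset of `genes` to make brain-enriched.
#' @param brain_fold Fold elevation of brain TPM for enriched genes.
#' @param seed Integer seed.
#' @return A list with `tpm` (genes x tissues matrix) and `labels`
#'   (data.frame: tissue, is_brain).
#' @export
generate_tissue_table <- function(genes, n_tissues = 54, n_brain = 13,
                                  brain_enriched_genes = character(),
                                  brain_fold = 8, seed = 1L) {
  if (n_brain < 2 || n_tissues - n_brain < 2)
    stop("need >= 2 brain and >= 2 non-brain tissues")
  if (!all(brain_enriched_genes %in% genes))
    stop("brain_enriched_genes must be drawn from genes")
  with_seed(seed, {
    tissues <- c(sprintf("brain_%02d", seq_len(n_brain)),
                 sprintf("tissue_%02d", seq_len(n_tissues - n_brain)))
    is_brain <- c(rep(TRUE, n_brain), rep(FALSE, n_tissues - n_brain))
    tpm <- matrix(stats::rlnorm(length(genes) * n_tissues, meanlog = 2,
                                sdlog = 0.6),
                  length(genes), n_tissues,
                  dimnames = list(genes, tissues))
    enriched <- genes %in% brain_enriched_genes
    tpm[enriched, is_brain] <- tpm[enriched, is_brain] * brain_fold
    list(tpm = tpm,
         labels = data.frame(tissue = tissues, is_brain = is_brain,
                             stringsAsFactors = FALSE))
  })
}
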