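## Assembly of a regions x genes expression matrix from donor-level
## microarray bundles, following the standard imaging-transcriptomics
## workflow: background-call probe filtering, sample-to-parcel mapping,
## most-stable-probe selection, cross-donor consistency filtering, and
## within-then-across donor normalization and aggregation.
##
## The enforced order is: background filter -> sample assignment -> probe
## selection -> gene consistency filter -> normalize/aggregate.

#' Drop probes failing background in too many samples
#'
#' Keeps probes whose above-background fraction, pooled across all donors'
#' samples, is at least `min_fraction` (default 0.5: a probe must exceed
#' background noise in at least 50% of samples across donors).
#'
#' @param bundle A `donor_bundle`.
#' @param min_fraction Minimum pooled above-background fraction (inclusive).
#' @return The bundle with failing probes removed from every donor.
#' @export
filter_probes_background <- function(bundle, min_fraction = 0.5) {
  stopifnot(inherits(bundle, "donor_bundle"))
  above <- rowSums(do.call(cbind, lapply(bundle$donors, `[[`, "background")))
  total <- sum(vapply(bundle$donors, function(d) ncol(d$background),
                      integer(1)))
  keep <- (above / total) >= min_fraction
  bundle$probes <- bundle$probes[keep, , drop = FALSE]
  bundle$donors <- lapply(bundle$donors, function(d) {
    d$intensity <- d$intensity[keep, , drop = FALSE]
    d$background <- d$background[keep, , drop = FALSE]
    d
  })
  bundle$report$probes_dropped_background <- sum(!keep)
  bundle
}

#' Assign donor samples to parcels by nearest centroid
#'
#' Each sample is assigned to the nearest region centroid (Euclidean
#' distance in MNI mm) if within `max_distance_mm`, else excluded. Only
#' left-hemisphere centroids are used (the pipeline is left-hemisphere-only).
#' The default tolerance is twice the median nearest-centroid spacing of the
#' geometry.
#'
#' @param bundle A `donor_bundle`.
#' @param geom Geometry table from [generate_geometry()].
#' @param max_distance_mm Assignment tolerance; `NULL` for the default.
#' @return The bundle with a `region` column added to each donor's samples
#'   (NA = excluded).
#' @export
assign_samples_to_parcels <- function(bundle, geom, max_distance_mm = NULL) {
  stopifnot(inherits(bundle, "donor_bundle"))
  geom <- geom[geom$hemisphere == "L", , drop = FALSE]
  cent <- as.matrix(geom[, c("mni_x", "mni_y", "mni_z")])
  if (is.null(max_distance_mm)) {
    dc <- as.matrix(stats::dist(cent))
    diag(dc) <- Inf
    max_distance_mm <- 2 * stats::median(apply(dc, 1, min))
  }
  n_excluded <- 0L
  bundle$donors <- lapply(bundle$donors, function(d) {
    s <- as.matrix(d$samples[, c("mni_x", "mni_y", "mni_z")])
    # squared distances sample x centroid
    d2 <- outer(rowSums(s^2), rep(1, nrow(cent))) -
      2 * s %*% t(cent) + outer(rep(1, nrow(s)), rowSums(cent^2))
    nearest <- max.col(-d2, ties.method = "first")
    dist <- sqrt(pmax(d2[cbind(seq_len(nrow(s)), nearest)], 0))
    region <- ifelse(dist <= max_distance_mm, geom$region_id[nearest],
                     NA_integer_)
    n_excluded <<- n_excluded + sum(is.na(region))
    d$samples$region <- region
    d
  })
  bundle$report$samples_excluded <- n_excluded
  bundle$report$max_distance_mm <- max_distance_mm
  bundle
}

#' Per-donor regional mean profiles for each probe (or selected gene probe)
#' @keywords internal
#' @noRd
donor_region_profiles <- function(bundle, values = "intensity") {
  lapply(bundle$donors, function(d) {
    ok <- !is.na(d$samples$region)
    if (!any(ok)) return(NULL)
    x <- t(d[[values]][, ok, drop = FALSE])      # samples x probes
    g <- d$samples$region[ok]
    rs <- rowsum(x, group = g)
    cnt <- as.vector(table(g)[rownames(rs)])
    rs / cnt
  })
}

#' Differential stability of each probe/gene column across donor pairs
#'
#' Mean across donor pairs of the Pearson correlation between regional mean
#' profiles, computed over regions sampled by both donors.
#' @keywords internal
#' @noRd
differential_stability <- function(profiles) {
  n_d <- length(profiles)
  n_col <- ncol(profiles[[which(!vapply(profiles, is.null, logical(1)))[1]]])
  acc <- matrix(0, 0, n_col)
  sums <- numeric(n_col)
  counts <- numeric(n_col)
  for (i in seq_len(n_d - 1)) for (j in seq(i + 1, n_d)) {
    pi <- profiles[[i]]; pj <- profiles[[j]]
    if (is.null(pi) || is.null(pj)) next
    common <- intersect(rownames(pi), rownames(pj))
    if (length(common) < 3) next
    a <- pi[common, , drop = FALSE]
    b <- pj[common, , drop = FALSE]
    sa <- col_sds(a); sb <- col_sds(b)
    r <- (colMeans(a * b) - colMeans(a) * colMeans(b)) /
      (sa * sb) * length(common) / (length(common) - 1)
    ok <- is.finite(r)
    sums[ok] <- sums[ok] + r[ok]
    counts[ok] <- counts[ok] + 1
  }
  ds <- ifelse(counts > 0, sums / counts, NA_real_)
  names(ds) <- colnames(profiles[[which(!vapply(profiles, is.null,
                                                logical(1)))[1]]])
  ds
}

#' Select one probe per gene by differential stability
#'
#' For genes with multiple probes, keeps the probe with the highest
#' differential stability (mean across donor pairs of the Pearson
#' correlation between regional mean profiles); ties are broken by the
#' lowest probe id. Genes whose probes all lack a finite stability estimate
#' are dropped with a message. Requires samples to be assigned
#' ([assign_samples_to_parcels()]) first.
#'
#' @param bundle A `donor_bundle` with assigned samples.
#' @return The bundle reduced to one probe per gene, with a
#'   `probe_stability` column added to `$probes`.
#' @export
select_probe_per_gene <- function(bundle) {
  stopifnot(inherits(bundle, "donor_bundle"))
  if (is.null(bundle$donors[[1]]$samples$region))
    stop("samples must be assigned to parcels before probe selection")
  profiles <- donor_region_profiles(bundle)
  ds <- differential_stability(profiles)
  ord <- order(bundle$probes$gene, -ifelse(is.finite(ds), ds, -Inf),
               bundle$probes$probe_id)
  first <- !duplicated(bundle$probes$gene[ord])
  keep_ids <- bundle$probes$probe_id[ord][first]
  keep <- bundle$probes$probe_id %in% keep_ids & is.finite(ds)
  dropped_genes <- setdiff(bundle$probes$gene,
                           bundle$probes$gene[keep])
  if (length(dropped_genes))
    message("dropped ", length(dropped_genes),
            " gene(s) with no stable probe")
  bundle$probes <- bundle$probes[keep, , drop = FALSE]
  bundle$probes$probe_stability <- ds[bundle$probes$probe_id]
  bundle$donors <- lapply(bundle$donors, function(d) {
    d$intensity <- d$intensity[keep, , drop = FALSE]
    d$background <- d$background[keep, , drop = FALSE]
    d
  })
  bundle$report$genes_dropped_no_probe <- length(dropped_genes)
  bundle
}

#' Drop genes with inconsistent expression across donors
#'
#' Keeps genes whose differential stability (computed on the selected probe)
#' is at least `min_stability` (default 0.1). Requires >= 2 donors and a
#' one-probe-per-gene bundle.
#'
#' @param bundle A `donor_bundle` after [select_probe_per_gene()].
#' @param min_stability Minimum differential stability (inclusive).
#' @return The bundle with inconsistent genes removed.
#' @export
filter_inconsistent_genes <- function(bundle, min_stability = 0.1) {
  stopifnot(inherits(bundle, "donor_bundle"))
  if (length(bundle$donors) < 2) stop("need >= 2 donors")
  if (anyDuplicated(bundle$probes$gene))
    stop("run select_probe_per_gene() first (multiple probes per gene)")
  ds <- bundle$probes$probe_stability
  if (is.null(ds))
    ds <- differential_stability(donor_region_profiles(bundle))
  keep <- is.finite(ds) & ds >= min_stability
  bundle$report$genes_dropped_inconsistent <- sum(!keep)
  bundle$probes <- bundle$probes[keep, , drop = FALSE]
  bundle$donors <- lapply(bundle$donors, function(d) {
    d$intensity <- d$intensity[keep, , drop = FALSE]
    d$background <- d$background[keep, , drop = FALSE]
    d
  })
  bundle
}

#' Scaled robust sigmoid normalization of one vector
#' @keywords internal
#' @noRd
scaled_robust_sigmoid <- function(x) {
  med <- stats::median(x)
  iqr <- stats::IQR(x)
  sig <- if (iqr > 0) iqr / 1.35 else stats::sd(x)
  if (!is.finite(sig) || sig == 0) return(rep(0.5, length(x)))
  y <- 1 / (1 + exp(-(x - med) / sig))
  rng <- range(y)
  if (diff(rng) == 0) rep(0.5, length(y)) else (y - rng[1]) / diff(rng)
}

#' Normalize within donors and aggregate to a regions x genes matrix
#'
#' Per donor, each gene's intensities are normalized across that donor's
#' assigned samples (scaled robust sigmoid rescaled to `[0, 1]` by default),
#' averaged over samples within region within donor, then averaged across
#' donors per region; finally each gene is z-scored across regions. Regions
#' with no sample in any donor are dropped with a message.
#'
#' @param bundle A one-probe-per-gene `donor_bundle` with assigned samples.
#' @param normalize "srs" (scaled robust sigmoid, default) or "none".
#' @return A list with `expression` (regions x genes matrix, rows named by
#'   region id, columns by gene id) and `report` (assembly counts).
#' @export
normalize_and_aggregate <- function(bundle, normalize = c("srs", "none")) {
  stopifnot(inherits(bundle, "donor_bundle"))
  normalize <- match.arg(normalize)
  if (anyDuplicated(bundle$probes$gene))
    stop("run select_probe_per_gene() first (multiple probes per gene)")
  genes <- bundle$probes$gene
  per_donor <- lapply(bundle$donors, function(d) {
    ok <- !is.na(d$samples$region)
    if (!any(ok)) return(NULL)
    x <- t(d$intensity[, ok, drop = FALSE])     # samples x genes
    if (normalize == "srs") x <- apply(x, 2, scaled_robust_sigmoid)
    if (is.null(dim(x))) x <- matrix(x, nrow = sum(ok))
    g <- d$samples$region[ok]
    rs <- rowsum(x, group = g)
    rs / as.vector(table(g)[rownames(rs)])
  })
  per_donor <- per_donor[!vapply(per_donor, is.null, logical(1))]
  if (!length(per_donor)) stop("no assigned samples in any donor")
  all_regions <- sort(unique(as.integer(unlist(lapply(per_donor, rownames)))))
  acc <- matrix(0, length(all_regions), length(genes),
                dimnames = list(all_regions, genes))
  cnt <- matrix(0, length(all_regions), length(genes))
  for (p in per_donor) {
    idx <- match(as.integer(rownames(p)), all_regions)
    acc[idx, ] <- acc[idx, ] + p
    cnt[idx, ] <- cnt[idx, ] + 1
  }
  expr <- acc / cnt
  sd0 <- col_sds(expr) == 0
  if (any(sd0)) {
    message("dropped ", sum(sd0), " constant gene(s) before z-scoring")
    expr <- expr[, !sd0, drop = FALSE]
  }
  expr <- zscore_cols(expr)
  report <- bundle$report %||% list()
  report$n_regions <- nrow(expr)
  report$n_genes <- ncol(expr)
  list(expression = expr, report = report)
}

#' Full donor-bundle assembly pipeline
#'
#' Runs, in order: background probe filter, sample-to-parcel assignment,
#' most-stable-probe selection, cross-donor consistency filter, and
#' within-then-across donor normalization/aggregation.
#'
#' @param bundle A raw `donor_bundle`.
#' @param geom Geometry table.
#' @param min_fraction Background-call threshold (see
#'   [filter_probes_background()]).
#' @param max_distance_mm Assignment tolerance (see
#'   [assign_samples_to_parcels()]).
#' @param min_stability Consistency threshold (see
#'   [filter_inconsistent_genes()]).
#' @param normalize Normalization method (see [normalize_and_aggregate()]).
#' @return As [normalize_and_aggregate()], with a stage-by-stage report.
#' @export
assemble_expression <- function(bundle, geom, min_fraction = 0.5,
                                max_distance_mm = NULL, min_stability = 0.1,
                                normalize = "srs") {
  bundle <- filter_probes_background(bundle, min_fraction)
  bundle <- assign_samples_to_parcels(bundle, geom, max_distance_mm)
  bundle <- select_probe_per_gene(bundle)
  bundle <- filter_inconsistent_genes(bundle, min_stability)
  normalize_and_aggregate(bundle, normalize)
}
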