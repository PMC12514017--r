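## Partial least squares regression of the region-wise sex-interaction map
## on regional gene expression, with spin-based latent-variable significance
## (random spherical rotations of region centroids, preserving spatial
## autocorrelation) and bootstrap gene ratios.
##
## Univariate-response PLS by iterative deflation (NIPALS-equivalent):
## w_k ~ X'y on the deflated matrices, unit-norm weights, region scores
## t_k = X w_k, per-component fraction of y-variance explained from the
## regression of y on t_k. Signs are fixed so that corr(t_k, y) >= 0.

#' Z-score columns, mapping zero-variance columns to 0 (bootstrap guard)
#' @keywords internal
#' @noRd
zscore_cols_safe <- function(x) {
  mu <- colMeans(x)
  sd <- col_sds(x)
  out <- sweep(x, 2, mu, "-")
  sd[sd == 0] <- Inf
  sweep(out, 2, sd, "/")
}

#' Core deflation PLS on pre-standardized inputs
#' @param Xz regions x genes, columns z-scored; yc centered response
#' @return list(W, Tt, q, frac) with unit-norm weight columns
#' @keywords internal
#' @noRd
pls_core <- function(Xz, yc, K) {
  n <- nrow(Xz)
  p <- ncol(Xz)
  W <- matrix(0, p, K)
  Tt <- matrix(0, n, K)
  q <- numeric(K)
  frac <- numeric(K)
  ssy <- sum(yc^2)
  Xd <- Xz
  yd <- yc
  for (k in seq_len(K)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break  # response orthogonal to remaining X space
    w <- w / nw
    t <- Xd %*% w
    tt <- sum(t^2)
    if (tt < 1e-24) break
    qk <- sum(yd * t) / tt
    frac[k] <- qk^2 * tt / ssy
    W[, k] <- w
    Tt[, k] <- t
    q[k] <- qk
    p_load <- crossprod(Xd, t) / tt
    Xd <- Xd - tcrossprod(t, p_load)
    yd <- yd - qk * t
  }
  list(W = W, Tt = Tt, q = q, frac = frac)
}

#' Fit a univariate-response PLS model
#'
#' Finds latent components maximizing covariance between regional gene
#' expression and a regional outcome (here, sex-interaction estimates).
#' Gene expression columns are z-scored across regions and the outcome is
#' centered before fitting. Component signs are fixed so that each region
#' score correlates non-negatively with the outcome.
#'
#' @param X Regions x genes expression matrix.
#' @param y Numeric outcome, one value per region (e.g. interaction betas).
#' @param n_components Number of latent components to extract.
#' @return An object of class `pls_model`: `weights` (genes x K, unit norm),
#'   `scores` (regions x K), `y_loading`, `frac_y_variance` (per component),
#'   `cum_frac`, and `sign_flipped` (logical per component).
#' @export
pls_fit <- function(X, y, n_components = 1) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (stats::sd(y) == 0) stop("constant outcome y")
  if (n_components < 1) stop("n_components must be >= 1")
  rk <- qr(X)$rank
  if (n_components > rk)
    stop("n_components (", n_components, ") exceeds rank(X) = ", rk)
  Xz <- zscore_cols(X)
  yc <- y - mean(y)
  fit <- pls_core(Xz, yc, n_components)
  flipped <- logical(n_components)
  for (k in seq_len(n_components)) {
    if (all(fit$Tt[, k] == 0)) next
    if (stats::cor(fit$Tt[, k], yc) < 0) {
      fit$W[, k] <- -fit$W[, k]
      fit$Tt[, k] <- -fit$Tt[, k]
      fit$q[k] <- -fit$q[k]
      flipped[k] <- TRUE
    }
  }
  rownames(fit$W) <- colnames(X)
  rownames(fit$Tt) <- rownames(X)
  structure(list(weights = fit$W, scores = fit$Tt, y_loading = fit$q,
                 frac_y_variance = fit$frac,
                 cum_frac = cumsum(fit$frac),
                 sign_flipped = flipped, n_components = n_components),
            class = "pls_model")
}

#' Nearest-centroid reassignment induced by one rotation
#' @keywords internal
#' @noRd
spin_reassign <- function(cent, Q, unique_assign = FALSE) {
  rot <- cent %*% t(Q)
  d2 <- outer(rowSums(cent^2), rep(1, nrow(rot))) - 2 * cent %*% t(rot) +
    outer(rep(1, nrow(cent)), rowSums(rot^2))
  if (!unique_assign) return(max.col(-d2, ties.method = "first"))
  # greedy one-to-one: assign pairs in increasing distance order
  n <- nrow(cent)
  perm <- integer(n)
  ord <- order(d2)
  used_i <- logical(n)
  used_j <- logical(n)
  left <- n
  for (idx in ord) {
    i <- (idx - 1) %% n + 1
    j <- (idx - 1) %/% n + 1
    if (used_i[i] || used_j[j]) next
    perm[i] <- j
    used_i[i] <- TRUE
    used_j[j] <- TRUE
    left <- left - 1
    if (left == 0) break
  }
  perm
}

#' Uniform random rotation matrix (QR of a Gaussian matrix, det +1)
#' @keywords internal
#' @noRd
random_rotation <- function() {
  qrd <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qrd)
  Q <- Q %*% diag(sign(diag(qr.R(qrd))))
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  Q
}

#' Spatial-autocorrelation-preserving spin permutations
#'
#' For each permutation, draws a uniform random 3-D rotation, rotates all
#' spherical region centroids, and reassigns each original region to the
#' nearest rotated centroid. The resulting index rows permute regional maps
#' while preserving their spatial autocorrelation. Under nearest-neighbour
#' reassignment duplicates are allowed; `unique_assign = TRUE` switches to a
#' greedy one-to-one matching.
#'
#' @param geom Geometry table (single hemisphere).
#' @param n_perm Number of permutations (warning below 100).
#' @param seed Integer seed.
#' @param unique_assign Force a one-to-one reassignment.
#' @return An object of class `spin_nulls` with `perm` (n_perm x n_regions
#'   integer matrix), `seed`, and coverage diagnostics.
#' @export
spin_permutations <- function(geom, n_perm = 1000, seed = 1L,
                              unique_assign = FALSE) {
  if (length(unique(geom$hemisphere)) != 1)
    stop("spin permutations require a single-hemisphere geometry")
  if (n_perm < 100)
    warning("n_perm < 100 gives unstable permutation p-values")
  cent <- as.matrix(geom[, c("sx", "sy", "sz")])
  n <- nrow(cent)
  with_seed(seed, {
    perm <- matrix(0L, n_perm, n)
    for (b in seq_len(n_perm))
      perm[b, ] <- spin_reassign(cent, random_rotation(), unique_assign)
    structure(list(perm = perm, seed = seed, n_regions = n,
                   mean_unique = mean(apply(perm, 1,
                                            function(r) length(unique(r)))) / n),
              class = "spin_nulls")
  })
}

#' Spin-test significance of each latent component
#'
#' Refits the PLS model with the outcome permuted by each spin null and
#' compares the per-component fraction of outcome variance explained against
#' the empirical fit. A component is significant when few nulls explain more
#' variance than the original outcome vector.
#' `p_k = (1 + #(null frac_k >= empirical frac_k)) / (1 + n_perm)`.
#'
#' @param model A fitted `pls_model`.
#' @param X,y The data the model was fitted on.
#' @param nulls A `spin_nulls` object for the same regions.
#' @return Numeric vector of spin p-values, one per component.
#' @export
lv_significance <- function(model, X, y, nulls) {
  stopifnot(inherits(model, "pls_model"), inherits(nulls, "spin_nulls"))
  X <- as.matrix(X)
  if (nulls$n_regions != nrow(X)) stop("null set does not match regions")
  K <- model$n_components
  Xz <- zscore_cols(X)
  emp <- model$frac_y_variance
  n_perm <- nrow(nulls$perm)
  exceed <- numeric(K)
  for (b in seq_len(n_perm)) {
    yp <- y[nulls$perm[b, ]]
    fr <- pls_core(Xz, yp - mean(yp), K)$frac
    exceed <- exceed + (fr >= emp)
  }
  (1 + exceed) / (1 + n_perm)
}

#' Bootstrap standard errors and ratios for PLS gene weights
#'
#' Resamples regions with replacement (jointly for the expression rows and
#' the outcome), refits the PLS model on each replicate, aligns each
#' replicate component's sign to the empirical region scores, and reports
#' per-gene bootstrap SEs and ratios (empirical weight / SE), interpretable
#' as z-scores for ranking genes. Replicates with a degenerate (constant)
#' resampled outcome are redrawn and counted.
#'
#' @param X Regions x genes expression matrix.
#' @param y Regional outcome vector.
#' @param components Integer vector of components to report (e.g. `c(1, 3)`).
#' @param n_boot Number of bootstrap replicates (default 5000).
#' @param seed Integer seed.
#' @return An object of class `pls_bootstrap`: `weight`, `se`, `ratio`
#'   (genes x reported components), `n_boot`, `n_redrawn`.
#' @export
bootstrap_gene_weights <- function(X, y, components = 1, n_boot = 5000,
                                   seed = 1L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  K <- max(components)
  model <- pls_fit(X, y, n_components = K)
  n <- nrow(X)
  p <- ncol(X)
  with_seed(seed, {
    s <- matrix(0, p, K)
    s2 <- matrix(0, p, K)
    n_redrawn <- 0L
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (stats::sd(y[idx]) > 0) break
        n_redrawn <- n_redrawn + 1L
      }
      fit <- pls_core(zscore_cols_safe(X[idx, , drop = FALSE]),
                      y[idx] - mean(y[idx]), K)
      for (k in seq_len(K)) {
        ref <- model$scores[idx, k]
        if (stats::sd(fit$Tt[, k]) > 0 && stats::sd(ref) > 0 &&
            stats::cor(fit$Tt[, k], ref) < 0)
          fit$W[, k] <- -fit$W[, k]
      }
      s <- s + fit$W
      s2 <- s2 + fit$W^2
    }
    se <- sqrt(pmax(s2 / n_boot - (s / n_boot)^2, 0) * n_boot / (n_boot - 1))
    if (any(se[, components] == 0))
      stop("zero bootstrap SE for some gene(s); increase n_boot")
    ratio <- model$weights / se
    dimnames(ratio) <- list(colnames(X), paste0("LV", seq_len(K)))
    structure(list(weight = model$weights[, components, drop = FALSE],
                   se = se[, components, drop = FALSE],
                   ratio = ratio[, components, drop = FALSE],
                   components = components,
                   n_boot = n_boot, n_redrawn = n_redrawn),
              class = "pls_bootstrap")
  })
}

#' Ranked gene list from bootstrap ratios
#'
#' Genes sorted by descending bootstrap ratio for one component; ties are
#' broken by gene id so ranks are deterministic.
#'
#' @param boot A `pls_bootstrap`.
#' @param component Which reported component to rank by.
#' @return Named numeric vector of bootstrap ratios, sorted descending.
#' @export
bootstrap_ranked_list <- function(boot, component = 1) {
  stopifnot(inherits(boot, "pls_bootstrap"))
  col <- match(component, boot$components)
  if (is.na(col)) stop("component ", component, " was not reported")
  r <- boot$ratio[, col]
  r[order(-r, names(r))]
}

#' Correlation between region scores and the outcome map
#'
#' @param model A fitted `pls_model`.
#' @param y Regional outcome vector.
#' @param component Component index.
#' @return A list with Pearson `r` and the two-sided `p` from the
#'   t-transform.
#' @export
region_score_correlation <- function(model, y, component = 1) {
  stopifnot(inherits(model, "pls_model"))
  t_k <- model$scores[, component]
  if (length(y) < 3) stop("need >= 3 regions")
  ct <- stats::cor.test(t_k, y)
  list(r = unname(ct$estimate), p = ct$p.value)
}
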