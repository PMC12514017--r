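## Empirical-Bayes location/scale harmonization of region-wise thickness
## across acquisition sites (ComBat), preserving group, age, and sex effects.
##
## Parametric priors: normal on the additive site effect gamma, inverse-gamma
## on the multiplicative effect delta; hyperparameters by moments; joint
## fixed-point updates (gamma then delta) iterated to tolerance. The fit is
## split from the application so harmonization can be audited and re-applied.

#' Covariate design matrix (intercept dropped; site indicators span it)
#' @keywords internal
#' @noRd
combat_cov_design <- function(participants, covariates, xlevels = NULL) {
  if (length(covariates) == 0) return(matrix(0, nrow(participants), 0))
  missing <- setdiff(covariates, names(participants))
  if (length(missing))
    stop("covariate(s) not in participant table: ",
         paste(missing, collapse = ", "))
  df <- participants[, covariates, drop = FALSE]
  for (v in covariates) {
    if (is.character(df[[v]]) || is.factor(df[[v]])) {
      lev <- if (!is.null(xlevels[[v]])) xlevels[[v]] else
        sort(unique(as.character(df[[v]])))
      bad <- setdiff(unique(as.character(df[[v]])), lev)
      if (length(bad)) stop("unknown level(s) in ", v, ": ",
                            paste(bad, collapse = ", "))
      df[[v]] <- factor(df[[v]], levels = lev)
    }
  }
  mm <- stats::model.matrix(stats::reformulate(covariates), df)
  mm[, -1, drop = FALSE]
}

#' Fit the empirical-Bayes site-harmonization model
#'
#' Standardizes each region using a full-rank design of site indicators plus
#' protected covariates (default group, age, sex), then estimates per-site
#' additive (gamma) and multiplicative (delta) effects in standardized units
#' and shrinks them with parametric empirical Bayes: a normal prior on gamma
#' and an inverse-gamma prior on delta, hyperparameters estimated by moments
#' across regions, solved by fixed-point iteration (relative tolerance 1e-6,
#' at most 500 iterations).
#'
#' @param thickness Participants x regions numeric matrix (mm).
#' @param participants Data.frame with a `site` column plus the covariates.
#' @param covariates Character vector of covariate names to protect
#'   (default `c("group", "age", "sex")`).
#' @return An object of class `combat_model`.
#' @export
combat_fit <- function(thickness, participants,
                       covariates = c("group", "age", "sex")) {
  thickness <- as.matrix(thickness)
  n <- nrow(thickness)
  if (nrow(participants) != n)
    stop("participants and thickness row counts differ")
  if (!"site" %in% names(participants)) stop("participants needs a site column")
  site <- factor(participants$site)
  n_per_site <- table(site)
  small <- names(n_per_site)[n_per_site < 2]
  if (length(small))
    stop("site(s) with < 2 participants: ", paste(small, collapse = ", "))

  xlevels <- list()
  for (v in covariates)
    if (is.character(participants[[v]]) || is.factor(participants[[v]]))
      xlevels[[v]] <- sort(unique(as.character(participants[[v]])))
  cov_mm <- combat_cov_design(participants, covariates, xlevels)
  # explicit indicators (model.matrix rejects single-level factors)
  site_mm <- vapply(levels(site), function(l) as.numeric(site == l),
                    numeric(n))
  design <- cbind(site_mm, cov_mm)
  if (qr(design)$rank < ncol(design))
    stop("design matrix is rank deficient (collinear site/covariates)")

  beta <- solve(crossprod(design), crossprod(design, thickness))
  n_sites <- nlevels(site)
  site_coef <- beta[seq_len(n_sites), , drop = FALSE]
  cov_coef <- beta[-seq_len(n_sites), , drop = FALSE]

  # grand mean: site-size-weighted average of site intercepts
  alpha <- as.numeric(n_per_site / n) %*% site_coef
  resid_full <- thickness - design %*% beta
  var_pooled <- colMeans(resid_full^2)
  if (any(var_pooled <= 0))
    stop("zero residual variance in region(s): ",
         paste(utils::head(colnames(thickness)[var_pooled <= 0]),
               collapse = ", "))

  stand_mean <- matrix(alpha, n, ncol(thickness), byrow = TRUE) +
    (if (ncol(cov_mm)) cov_mm %*% cov_coef else 0)
  Z <- (thickness - stand_mean) / matrix(sqrt(var_pooled), n,
                                         ncol(thickness), byrow = TRUE)

  n_r <- ncol(thickness)
  gamma_hat <- matrix(NA_real_, n_sites, n_r)
  delta_hat <- matrix(NA_real_, n_sites, n_r)
  for (s in seq_len(n_sites)) {
    zi <- Z[site == levels(site)[s], , drop = FALSE]
    gamma_hat[s, ] <- colMeans(zi)
    # denominator n_s, consistent with var_pooled, so a single site gives
    # delta_hat == 1 exactly
    delta_hat[s, ] <- colMeans(sweep(zi, 2, gamma_hat[s, ], "-")^2)
  }

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  for (s in seq_len(n_sites)) {
    ns <- as.integer(n_per_site[s])
    g_bar <- mean(gamma_hat[s, ])
    tau2 <- stats::var(gamma_hat[s, ])
    m <- mean(delta_hat[s, ])
    s2 <- stats::var(delta_hat[s, ])
    if (!is.finite(tau2) || tau2 < 1e-12 || !is.finite(s2) || s2 < 1e-12) {
      # degenerate hyperpriors (e.g. a single site): keep raw estimates,
      # shrinking gamma fully to its prior mean when tau2 collapses
      if (is.finite(tau2) && tau2 < 1e-12) gamma_star[s, ] <- g_bar
      next
    }
    lambda <- (2 * s2 + m^2) / s2
    theta <- (m * s2 + m^3) / s2
    zi <- Z[site == levels(site)[s], , drop = FALSE]
    g_old <- gamma_hat[s, ]
    d_old <- delta_hat[s, ]
    for (it in seq_len(500)) {
      g_new <- (ns * tau2 * gamma_hat[s, ] + d_old * g_bar) /
        (ns * tau2 + d_old)
      ssq <- colSums(sweep(zi, 2, g_new, "-")^2)
      d_new <- (theta + 0.5 * ssq) / (ns / 2 + lambda - 1)
      change <- max(abs(g_new - g_old) / pmax(abs(g_old), 1e-8),
                    abs(d_new - d_old) / d_old)
      g_old <- g_new
      d_old <- d_new
      if (change < 1e-6) break
    }
    gamma_star[s, ] <- g_old
    delta_star[s, ] <- d_old
  }
  if (any(delta_star <= 0)) stop("non-positive shrunk variance ratio delta*")
  dimnames(gamma_star) <- list(levels(site), colnames(thickness))
  dimnames(delta_star) <- dimnames(gamma_star)

  structure(list(
    covariates = covariates, xlevels = xlevels,
    site_levels = levels(site), n_per_site = as.integer(n_per_site),
    alpha = as.numeric(alpha), cov_coef = cov_coef,
    var_pooled = var_pooled, gamma_star = gamma_star,
    delta_star = delta_star, regions = colnames(thickness)
  ), class = "combat_model")
}

#' Apply a fitted harmonization model
#'
#' Removes the shrunk site location/scale effects and restores the protected
#' covariate effects: `(standardized - gamma*) / sqrt(delta*)`
#' back-transformed to mm.
#'
#' @param model A `combat_model` from [combat_fit()].
#' @param thickness Participants x regions matrix with the model's regions.
#' @param participants Data.frame with `site` and the model's covariates;
#'   sites must be a subset of the model's sites.
#' @return Harmonized thickness matrix, same shape as the input.
#' @export
combat_apply <- function(model, thickness, participants) {
  stopifnot(inherits(model, "combat_model"))
  thickness <- as.matrix(thickness)
  n <- nrow(thickness)
  if (!is.null(model$regions) && !is.null(colnames(thickness)) &&
      !identical(colnames(thickness), model$regions))
    stop("thickness columns do not match the fitted regions")
  site <- as.character(participants$site)
  unknown <- setdiff(unique(site), model$site_levels)
  if (length(unknown))
    stop("unknown site label(s): ", paste(unknown, collapse = ", "))
  cov_mm <- combat_cov_design(participants, model$covariates, model$xlevels)
  stand_mean <- matrix(model$alpha, n, ncol(thickness), byrow = TRUE) +
    (if (ncol(cov_mm)) cov_mm %*% model$cov_coef else 0)
  sdm <- matrix(sqrt(model$var_pooled), n, ncol(thickness), byrow = TRUE)
  Z <- (thickness - stand_mean) / sdm
  idx <- match(site, model$site_levels)
  Zadj <- (Z - model$gamma_star[idx, , drop = FALSE]) /
    sqrt(model$delta_star[idx, , drop = FALSE])
  out <- Zadj * sdm + stand_mean
  dimnames(out) <- dimnames(thickness)
  out
}

#' Fit and apply harmonization in one step
#'
#' @inheritParams combat_fit
#' @return Harmonized thickness matrix.
#' @export
combat_harmonize <- function(thickness, participants,
                             covariates = c("group", "age", "sex")) {
  combat_apply(combat_fit(thickness, participants, covariates),
               thickness, participants)
}
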