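## Control-referenced normative modeling (W-scores), per-region
## sex-interaction estimation, and regional atrophy tests.
##
## W-scores standardize each patient's regional thickness against the value
## predicted from controls by a per-region regression on age and sex,
## divided by the control residual SD. Negative W = thinner than expected
## for that age and sex. Sex is coded male = 0 / female = 1 throughout, so a
## positive interaction beta means females are less atrophied than males.

#' Female-indicator coding used across the package (male = 0, female = 1)
#' @keywords internal
#' @noRd
female_indicator <- function(sex) {
  sex <- as.character(sex)
  bad <- setdiff(unique(sex), c("F", "M"))
  if (length(bad)) stop("sex must be coded F/M; found: ",
                        paste(bad, collapse = ", "))
  as.numeric(sex == "F")
}

#' Fit the normative control model (thickness ~ age + sex per region)
#'
#' Per-region ordinary least squares on controls only, with residual SD
#' using denominator n - 3 (intercept, age, sex).
#'
#' @param controls_thickness Controls x regions matrix (mm).
#' @param controls_covars Data.frame with `age` and `sex` (F/M) for the same
#'   rows.
#' @return An object of class `normative_model`: per-region coefficients
#'   (intercept, age, sexF), residual SD, and `n_controls`.
#' @export
fit_normative <- function(controls_thickness, controls_covars) {
  Y <- as.matrix(controls_thickness)
  n <- nrow(Y)
  if (n < 10) stop("need >= 10 controls to fit the normative model")
  if (nrow(controls_covars) != n) stop("covariate rows do not match controls")
  if (!all(c("age", "sex") %in% names(controls_covars)))
    stop("controls_covars needs age and sex columns")
  X <- cbind(1, age = controls_covars$age,
             sexF = female_indicator(controls_covars$sex))
  if (qr(X)$rank < 3)
    stop("degenerate control covariates (age or sex has no variation)")
  beta <- solve(crossprod(X), crossprod(X, Y))
  resid <- Y - X %*% beta
  rss <- colSums(resid^2)
  sigma <- sqrt(rss / (n - 3))
  if (any(sigma <= 1e-12)) {
    bad <- colnames(Y)[sigma <= 1e-12]
    stop("zero residual variance in region(s): ",
         paste(utils::head(bad), collapse = ", "))
  }
  structure(list(coef = beta, resid_sd = sigma, n_controls = n,
                 regions = colnames(Y)),
            class = "normative_model")
}

#' Compute W-scores against a fitted normative model
#'
#' `W(i, r) = (observed - predicted(age_i, sex_i)) / residual_sd(r)`.
#'
#' @param thickness Participants x regions matrix.
#' @param covars Data.frame with `age` and `sex` for the same rows; an `id`
#'   column, if present, is used in error messages.
#' @param model A `normative_model` from [fit_normative()].
#' @return Participants x regions W-score matrix (unitless).
#' @export
compute_wscores <- function(thickness, covars, model) {
  stopifnot(inherits(model, "normative_model"))
  Y <- as.matrix(thickness)
  if (nrow(covars) != nrow(Y)) stop("covariate rows do not match thickness")
  ids <- covars$id %||% rownames(Y) %||% seq_len(nrow(Y))
  miss <- !is.finite(covars$age) | is.na(covars$sex)
  if (any(miss))
    stop("missing covariate(s) for participant(s): ",
         paste(utils::head(ids[miss]), collapse = ", "))
  X <- cbind(1, covars$age, female_indicator(covars$sex))
  pred <- X %*% model$coef
  W <- (Y - pred) / matrix(model$resid_sd, nrow(Y), ncol(Y), byrow = TRUE)
  dimnames(W) <- dimnames(Y)
  W
}

#' Per-region sex-interaction estimates from patient W-scores
#'
#' Regresses each region's patient W-scores on the female indicator
#' (male = 0, female = 1). The slope equals the female-minus-male mean
#' W-score difference exactly; positive beta = females less atrophied than
#' males. P-values from the two-sided OLS t-test; q-values by
#' Benjamini-Hochberg across regions.
#'
#' @param wscores Patients x regions W-score matrix.
#' @param patient_sex Character vector (F/M), one per patient row.
#' @return Data.frame: region, beta, t, p, q, n_f, n_m.
#' @export
sex_interaction_estimates <- function(wscores, patient_sex) {
  W <- as.matrix(wscores)
  f <- female_indicator(patient_sex)
  n_f <- sum(f == 1)
  n_m <- sum(f == 0)
  if (n_f < 2 || n_m < 2)
    stop("need >= 2 patients of each sex (have ", n_f, " F, ", n_m, " M)")
  n <- nrow(W)
  beta <- colMeans(W[f == 1, , drop = FALSE]) -
    colMeans(W[f == 0, , drop = FALSE])
  # OLS on an indicator: residual variance pools the within-sex variances
  rss <- colSums((W[f == 1, , drop = FALSE] -
                    matrix(colMeans(W[f == 1, , drop = FALSE]),
                           n_f, ncol(W), byrow = TRUE))^2) +
    colSums((W[f == 0, , drop = FALSE] -
               matrix(colMeans(W[f == 0, , drop = FALSE]),
                      n_m, ncol(W), byrow = TRUE))^2)
  se <- sqrt(rss / (n - 2) * (1 / n_f + 1 / n_m))
  t <- beta / se
  p <- 2 * stats::pt(-abs(t), df = n - 2)
  data.frame(region = colnames(W) %||% seq_len(ncol(W)),
             beta = beta, t = t, p = p,
             q = stats::p.adjust(p, method = "BH"),
             n_f = n_f, n_m = n_m, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Regional atrophy tests (one-sample t of W-scores against 0)
#'
#' Tests, per region, whether patient W-scores deviate from 0 (the expected
#' value in matched controls), optionally within one sex, with
#' Benjamini-Hochberg FDR across the tested regions.
#'
#' @param wscores Patients x regions W-score matrix.
#' @param patient_sex Character vector (F/M) per patient; required when
#'   `subset` is "F" or "M".
#' @param subset "all", "F", or "M".
#' @return A list with `table` (region, mean_w, t, p, q) and the counts
#'   `n_sig_p` / `n_sig_q` (regions with p < 0.05 / q < 0.05, negative
#'   direction included in the two-sided test) plus the proportions.
#' @export
regional_atrophy_test <- function(wscores, patient_sex = NULL,
                                  subset = c("all", "F", "M")) {
  subset <- match.arg(subset)
  W <- as.matrix(wscores)
  if (subset != "all") {
    if (is.null(patient_sex)) stop("patient_sex required for a sex subset")
    W <- W[as.character(patient_sex) == subset, , drop = FALSE]
  }
  n <- nrow(W)
  if (n < 3) stop("subset has ", n, " patients; need >= 3")
  mu <- colMeans(W)
  sd <- col_sds(W)
  if (any(sd == 0)) {
    t <- ifelse(mu == 0, 0, sign(mu) * Inf)
    p <- ifelse(mu == 0, 1, 0)
    t[sd > 0] <- (mu / (sd / sqrt(n)))[sd > 0]
    p[sd > 0] <- (2 * stats::pt(-abs(t), df = n - 1))[sd > 0]
  } else {
    t <- mu / (sd / sqrt(n))
    p <- 2 * stats::pt(-abs(t), df = n - 1)
  }
  q <- stats::p.adjust(p, method = "BH")
  tab <- data.frame(region = colnames(W) %||% seq_len(ncol(W)),
                    mean_w = mu, t = t, p = p, q = q, row.names = NULL,
                    stringsAsFactors = FALSE)
  list(table = tab, n = n,
       n_sig_p = sum(p < 0.05), n_sig_q = sum(q < 0.05),
       prop_sig_p = mean(p < 0.05), prop_sig_q = mean(q < 0.05))
}
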