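## Internal helpers shared across modules.

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Column standard deviations of a matrix
#' @keywords internal
#' @noRd
col_sds <- function(x, denom = c("n-1", "n")) {
  denom <- match.arg(denom)
  n <- nrow(x)
  mu <- colMeans(x)
  ss <- colSums(x^2) - n * mu^2
  ss[ss < 0] <- 0  # numerical guard
  sqrt(ss / if (denom == "n-1") n - 1 else n)
}

#' Z-score the columns of a matrix
#' @keywords internal
#' @noRd
zscore_cols <- function(x) {
  mu <- colMeans(x)
  sd <- col_sds(x)
  if (any(sd == 0)) stop("cannot z-score constant column(s): ",
                         paste(utils::head(which(sd == 0)), collapse = ", "))
  sweep(sweep(x, 2, mu, "-"), 2, sd, "/")
}

#' Angular (great-circle) distance matrix between unit vectors
#' @keywords internal
#' @noRd
angular_distance <- function(xyz) {
  g <- tcrossprod(as.matrix(xyz))
  g[g > 1] <- 1
  g[g < -1] <- -1
  acos(g)
}

#' Moran's I spatial autocorrelation with k-nearest-neighbour weights
#'
#' Diagnostic used to check that generated gene maps are spatially smooth and
#' that spin permutations preserve smoothness. Binary k-nearest-neighbour
#' weights (row-standardized) over Euclidean distance between centroids.
#'
#' @param values Numeric vector, one value per region.
#' @param coords Matrix of region coordinates (rows aligned with `values`).
#' @param k Number of nearest neighbours (default 6).
#' @return Moran's I statistic (scalar).
#' @export
moran_i <- function(values, coords, k = 6L) {
  n <- length(values)
  stopifnot(nrow(coords) == n, k >= 1, k < n)
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[seq_len(k)]
    w[i, nb] <- 1 / k
  }
  z <- values - mean(values)
  denom <- sum(z^2)
  if (denom == 0) return(NA_real_)
  (n / sum(w)) * sum(w * tcrossprod(z)) / denom
}

#' Write a TSV with a provenance header comment
#' @keywords internal
#' @noRd
write_tsv_stamped <- function(df, path, stage = NULL, seed = NULL,
                              config_hash = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  meta <- c(
    if (!is.null(stage)) paste0("# stage: ", stage),
    if (!is.null(seed)) paste0("# seed: ", seed),
    if (!is.null(config_hash)) paste0("# config_hash: ", config_hash)
  )
  if (length(meta)) writeLines(meta, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by write_tsv_stamped (skips # header comments)
#' @keywords internal
#' @noRd
read_tsv_stamped <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
}
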