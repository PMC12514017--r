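## Preranked gene-set enrichment on bootstrap-ratio-ranked genes: weighted
## Kolmogorov-Smirnov running-sum enrichment scores, gene-label permutation
## NES and p-values, Benjamini-Hochberg FDR within each NES sign stratum,
## and greedy weighted set-cover redundancy reduction of significant terms.

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one term per line, `name TAB description TAB gene...`.
#' Duplicate genes within a term are deduplicated with a warning; a line
#' with fewer than three fields is an error naming the line.
#'
#' @param path Path to a GMT file.
#' @return Named list of character gene vectors, with term descriptions in
#'   `attr(, "description")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  descs <- character(length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("malformed GMT line ", i, ": fewer than 3 tab-separated fields")
    nms[i] <- f[1]
    descs[i] <- f[2]
    genes <- f[-(1:2)]
    if (anyDuplicated(genes)) {
      warning("duplicate gene(s) in term ", f[1], "; deduplicated")
      genes <- unique(genes)
    }
    sets[[i]] <- genes
  }
  names(sets) <- nms
  names(descs) <- nms
  attr(sets, "description") <- descs
  sets
}

#' Write a gene-set collection to a GMT file
#'
#' @param sets Named list of character gene vectors.
#' @param path Output path.
#' @param descriptions Optional named character descriptions (defaults to
#'   the `description` attribute or `"na"`).
#' @return The path, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- attr(sets, "description")
  if (is.null(descriptions))
    descriptions <- stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]] %||% "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Running-sum walk over hit positions (weighted KS, weight exponent 1)
#' @param abs_scores |score| in ranked order; pos sorted hit positions
#' @keywords internal
#' @noRd
es_walk <- function(abs_scores, pos, N) {
  k <- length(pos)
  hs <- abs_scores[pos]
  S <- sum(hs)
  h <- if (S > 0) hs / S else rep(1 / k, k)
  cumh <- cumsum(h)
  d <- if (N > k) 1 / (N - k) else 0
  gap <- (pos - seq_len(k)) * d
  post <- cumh - gap                 # walk value just after each hit
  pre <- c(0, cumh[-k]) - gap        # walk value just before each hit
  max_post <- max(post)
  min_walk <- min(pre, 0)            # the walk ends at exactly 0
  if (max_post >= -min_walk)
    list(es = max_post, j = which.max(post), positive = TRUE)
  else
    list(es = min_walk, j = which.min(pre), positive = FALSE)
}

#' Enrichment score of one gene set in a ranked list
#'
#' Weighted Kolmogorov-Smirnov running sum: hits increment by
#' `|score|/sum(|score| over hits)`, misses decrement by `1/(N - n_set)`;
#' the ES is the extremum of the walk by absolute value (an exact tie
#' between the positive and negative extremum resolves positive). The
#' leading edge is
#' the hit genes at or before the extremum (positive ES) or at or after it
#' (negative ES).
#'
#' @param ranked Named numeric vector of scores sorted in decreasing order.
#' @param members Character vector of member gene ids.
#' @return A list with `es` (in `[-1, 1]`) and `leading_edge` (character).
#' @export
enrichment_score <- function(ranked, members) {
  N <- length(ranked)
  pos <- sort(which(names(ranked) %in% members))
  if (!length(pos)) stop("gene set has no overlap with the ranked universe")
  w <- es_walk(abs(ranked), pos, N)
  le <- if (w$es > 0) names(ranked)[pos[seq_len(w$j)]]
        else if (w$es < 0) names(ranked)[pos[seq(w$j, length(pos))]]
        else character(0)
  list(es = w$es, leading_edge = le)
}

#' Sort a ranked list descending with deterministic gene-id tie-breaks
#' @keywords internal
#' @noRd
sort_ranked <- function(ranked) {
  if (is.null(names(ranked)) || anyDuplicated(names(ranked)))
    stop("ranked list must have unique gene names")
  ranked[order(-ranked, names(ranked))]
}

#' Preranked gene-set enrichment with permutation NES and FDR
#'
#' Applies the 5-2000 size filter (inclusive, on the intersection with the
#' ranked universe), computes each term's enrichment score, builds a null ES
#' distribution per term from gene-label permutations of the scores,
#' normalizes (`NES = ES / mean(|null ES| with matching sign)`), computes
#' add-one permutation p-values as the tail of `|ES|` over all nulls, and
#' Benjamini-Hochberg q-values separately for positive and negative NES.
#'
#' @param ranked Named numeric score vector (e.g. bootstrap ratios); sorted
#'   internally (descending, ties by gene id).
#' @param collection Named list of gene sets.
#' @param min_size,max_size Inclusive size filter on the intersected sets.
#' @param n_perm Number of gene-label permutations.
#' @param seed Integer seed.
#' @return A data.frame with one row per retained term: `term`, `size`,
#'   `n_leading_edge`, `es`, `nes`, `p`, `q`, and a list-column
#'   `leading_edge`.
#' @export
gsea_preranked <- function(ranked, collection, min_size = 5, max_size = 2000,
                           n_perm = 1000, seed = 1L) {
  ranked <- sort_ranked(ranked)
  N <- length(ranked)
  if (N < 50) stop("ranked list must contain >= 50 genes")
  universe <- names(ranked)
  inter <- lapply(collection, function(g) {
    gg <- intersect(unique(g), universe)
    if (!length(gg) && length(g))
      message("term skipped (no overlap with ranked universe)")
    gg
  })
  sizes <- lengths(inter)
  keep <- sizes >= min_size & sizes <= max_size
  if (!any(keep)) {
    warning("all terms filtered out by size/overlap")
    return(data.frame(term = character(0), size = integer(0),
                      n_leading_edge = integer(0), es = numeric(0),
                      nes = numeric(0), p = numeric(0), q = numeric(0)))
  }
  inter <- inter[keep]
  sizes <- sizes[keep]
  abs_s <- abs(ranked)
  with_seed(seed, {
    rows <- lapply(seq_along(inter), function(i) {
      obs <- enrichment_score(ranked, inter[[i]])
      k <- sizes[i]
      null_es <- vapply(seq_len(n_perm), function(b) {
        es_walk(abs_s, sort(sample.int(N, k)), N)$es
      }, numeric(1))
      same <- if (obs$es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
      denom <- mean(abs(same))
      if (!length(same) || !is.finite(denom) || denom == 0)
        denom <- mean(abs(null_es))
      nes <- obs$es / denom
      # add-one tail on |ES| over all nulls: calibrated regardless of the
      # observed sign (a sign-conditional tail would double the alpha)
      p <- (1 + sum(abs(null_es) >= abs(obs$es))) / (1 + n_perm)
      data.frame(term = names(inter)[i], size = k,
                 n_leading_edge = length(obs$leading_edge),
                 es = obs$es, nes = nes, p = p,
                 stringsAsFactors = FALSE,
                 leading_edge = I(list(obs$leading_edge)))
    })
    res <- do.call(rbind, rows)
    res$q <- NA_real_
    pos <- res$es >= 0
    if (any(pos)) res$q[pos] <- stats::p.adjust(res$p[pos], method = "BH")
    if (any(!pos)) res$q[!pos] <- stats::p.adjust(res$p[!pos], method = "BH")
    res[order(-res$nes), c("term", "size", "n_leading_edge", "es", "nes",
                           "p", "q", "leading_edge")]
  })
}

#' Greedy weighted set cover over leading-edge genes
#'
#' Selects up to `k` terms maximizing the covered-gene objective
#' `f(S) = sum over covered genes of the largest -log10(p) among selecting
#' terms`. Greedy steps pick the term with the largest marginal gain; ties
#' are broken by larger raw marginal coverage, then by lexical term id.
#'
#' @param results A data.frame as returned by [gsea_preranked()] (needs
#'   `term`, `p`, and the `leading_edge` list-column).
#' @param k Maximum number of terms to select.
#' @return The selected rows of `results`, in selection order.
#' @export
weighted_set_cover <- function(results, k = 10) {
  if (!nrow(results)) return(results)
  if (is.null(results$leading_edge))
    stop("results must carry a leading_edge column")
  w <- -log10(results$p)
  le <- lapply(results$leading_edge, as.character)
  covered <- new.env(parent = emptyenv())  # gene -> current best weight
  gain_of <- function(i) {
    g <- le[[i]]
    cur <- vapply(g, function(x) {
      v <- covered[[x]]
      if (is.null(v)) 0 else v
    }, numeric(1))
    list(gain = sum(pmax(0, w[i] - cur)), new = sum(cur == 0))
  }
  selected <- integer(0)
  remaining <- seq_len(nrow(results))
  for (step in seq_len(min(k, nrow(results)))) {
    info <- lapply(remaining, gain_of)
    gains <- vapply(info, `[[`, numeric(1), "gain")
    if (all(gains <= 0)) break
    news <- vapply(info, `[[`, numeric(1), "new")
    ord <- order(-gains, -news, results$term[remaining])
    best <- remaining[ord[1]]
    selected <- c(selected, best)
    for (g in le[[best]]) {
      v <- covered[[g]]
      if (is.null(v) || w[best] > v) covered[[g]] <- w[best]
    }
    remaining <- setdiff(remaining, best)
  }
  results[selected, , drop = FALSE]
}
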