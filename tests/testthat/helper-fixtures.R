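# Shared fixture builders. Everything is generated in code; no stored data.

# A minimal donor bundle built by hand, for boundary tests of the probe
# filters: `bg` is a list of per-donor logical probe x sample matrices,
# `intensity` per-donor numeric matrices of the same shape.
manual_bundle <- function(probes, donors) {
  structure(list(probes = probes, donors = donors), class = "donor_bundle")
}

# Donor entry with samples placed exactly at the given region centroids.
donor_at_centroids <- function(geom, regions, intensity, background = NULL,
                               donor_id = 1) {
  n_s <- length(regions)
  samples <- data.frame(
    sample_id = sprintf("D%d_S%03d", donor_id, seq_len(n_s)),
    mni_x = geom$mni_x[regions], mni_y = geom$mni_y[regions],
    mni_z = geom$mni_z[regions], true_region = geom$region_id[regions],
    stringsAsFactors = FALSE
  )
  if (is.null(background))
    background <- matrix(TRUE, nrow(intensity), n_s)
  dimnames(intensity) <- list(rownames(intensity), samples$sample_id)
  dimnames(background) <- dimnames(intensity)
  list(samples = samples, intensity = intensity, background = background)
}

# Independent brute-force enrichment-score oracle: walks the full ranked
# list one step at a time (no shared code with the package implementation).
brute_force_es <- function(ranked, members) {
  hit <- names(ranked) %in% members
  n_set <- sum(hit)
  s_hit <- sum(abs(ranked[hit]))
  val <- 0
  walk <- numeric(length(ranked))
  for (i in seq_along(ranked)) {
    val <- if (hit[i]) {
      val + (if (s_hit > 0) abs(ranked[i]) / s_hit else 1 / n_set)
    } else {
      val - 1 / (length(ranked) - n_set)
    }
    walk[i] <- val
  }
  m <- max(abs(walk))
  # on an exact |ES| tie the package convention prefers the positive side
  if (any(walk >= m - 1e-13)) m else -m
}

# Exhaustive weighted-set-cover oracle: best subset of size <= k under
# f(S) = sum over covered genes of the max weight among covering terms.
brute_force_cover <- function(le_sets, weights, k) {
  idx <- seq_along(le_sets)
  best <- list(score = -Inf, sel = integer(0))
  for (m in 0:min(k, length(idx))) {
    combos <- if (m == 0) list(integer(0)) else
      asplit(utils::combn(idx, m), 2)
    for (sel in combos) {
      genes <- unique(unlist(le_sets[sel]))
      score <- sum(vapply(genes, function(g) {
        max(weights[sel][vapply(le_sets[sel], function(s) g %in% s,
                                logical(1))])
      }, numeric(1)))
      if (score > best$score) best <- list(score = score, sel = sel)
    }
  }
  best
}
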