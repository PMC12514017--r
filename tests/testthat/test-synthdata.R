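# Synthetic-data generators: geometry, cohort, expression, donor bundles,
# gene sets, tissue tables.

test_that("geometry is a deterministic quasi-uniform left hemisphere", {
  g <- generate_geometry(499, seed = 1)
  expect_equal(nrow(g), 499)
  expect_true(all(g$hemisphere == "L"))
  expect_true(all(g$sx <= 0))
  norms <- sqrt(g$sx^2 + g$sy^2 + g$sz^2)
  expect_true(all(abs(norms - 1) < 1e-9))
  expect_false(any(duplicated(g[, c("sx", "sy", "sz")])))
  expect_equal(g$mni_x, 100 * g$sx)

  expect_identical(g, generate_geometry(499, seed = 1))
  expect_false(identical(g, generate_geometry(499, seed = 2)))

  # brute-force pairwise angular separation at small n
  g10 <- generate_geometry(10, seed = 2)
  xyz <- as.matrix(g10[, c("sx", "sy", "sz")])
  ang <- c()
  for (i in 1:9) for (j in (i + 1):10)
    ang <- c(ang, acos(min(1, sum(xyz[i, ] * xyz[j, ]))))
  expect_gt(min(ang), 0)

  expect_error(generate_geometry(9), "n_regions")
})

test_that("cohort config validates its invariants", {
  expect_error(cohort_config(n_patients_f = 0), "positive")
  expect_error(cohort_config(noise_sd = 0), "noise_sd")
  expect_error(cohort_config(atrophy_regions = c(1, 600)), "subset")
  expect_error(cohort_config(atrophy_male = -0.1, atrophy_female = -0.3),
               "atrophy_female")
  expect_error(cohort_config(site_shift = c(0, 1), n_sites = 3), "length")
})

test_that("cohort thickness follows the planted generative structure", {
  geom <- generate_geometry(40, seed = 1)
  cfg <- cohort_config(n_patients_f = 30, n_patients_m = 30,
                       n_controls_f = 30, n_controls_m = 30,
                       n_regions = 40, n_sites = 1, site_shift = 0,
                       site_scale = 1, atrophy_regions = 1:10,
                       atrophy_male = -0.3, atrophy_female = -0.1,
                       noise_sd = 0.1, seed = 7)
  coh <- generate_cohort(cfg, geom)
  expect_equal(dim(coh$thickness), c(120, 40))
  expect_true(all(coh$thickness > 0))
  pt <- coh$participants
  in_atr <- rowMeans(coh$thickness[, 1:10])
  m_pat <- mean(in_atr[pt$group == "patient" & pt$sex == "M"])
  f_pat <- mean(in_atr[pt$group == "patient" & pt$sex == "F"])
  ctl <- mean(in_atr[pt$group == "control"])
  expect_lt(m_pat, f_pat)
  expect_lt(f_pat, ctl)

  # determinism
  expect_identical(coh, generate_cohort(cfg, geom))
})

test_that("null cohorts show no group difference (simulation calibration)", {
  geom <- generate_geometry(10, seed = 1)
  sig <- 0
  for (s in 1:100) {
    cfg <- cohort_config(n_patients_f = 20, n_patients_m = 20,
                         n_controls_f = 20, n_controls_m = 20,
                         n_regions = 10, n_sites = 1, site_shift = 0,
                         site_scale = 1, atrophy_regions = 1:2,
                         atrophy_male = 0, atrophy_female = 0,
                         noise_sd = 0.1, seed = 5000 + s)
    coh <- generate_cohort(cfg, geom)
    pat <- coh$participants$group == "patient"
    p <- stats::t.test(coh$thickness[pat, 1],
                       coh$thickness[!pat, 1])$p.value
    sig <- sig + (p < 0.01)
  }
  expect_lte(sig, 5)  # non-significant at alpha=0.01 in >= 95% of seeds
})

test_that("planted expression genes track the interaction map as configured", {
  geom <- generate_geometry(120, seed = 2)
  map <- c(rep(1, 30), rep(0, 90))

  ex1 <- generate_expression(
    expression_config(n_genes = 50, planted_set_size = 5,
                      planted_coupling = 1, seed = 3), geom, map)
  r1 <- abs(cor(ex1$expression[, ex1$planted_genes], map))
  expect_true(all(r1 > 1 - 1e-12))

  ex0 <- generate_expression(
    expression_config(n_genes = 50, planted_set_size = 5,
                      planted_coupling = 0, seed = 3), geom, map)
  r0 <- abs(cor(ex0$expression[, ex0$planted_genes], map))
  expect_lt(mean(r0), 2 / sqrt(120) + 0.05)

  # every column standardized
  expect_true(all(abs(colMeans(ex1$expression)) < 1e-12))
  expect_true(all(abs(apply(ex1$expression, 2, sd) - 1) < 1e-12))

  expect_error(generate_expression(
    expression_config(seed = 1), geom, rep(0, 120)), "constant")
})

test_that("spatial autocorrelation of gene maps increases with smoothing", {
  geom <- generate_geometry(150, seed = 4)
  coords <- as.matrix(geom[, c("sx", "sy", "sz")])
  mean_i <- vapply(c(0, 0.15, 0.5), function(sl) {
    ex <- generate_expression(
      expression_config(n_genes = 30, smoothing_length = sl,
                        planted_coupling = 0, seed = 9),
      geom, rep(0, 150))
    mean(apply(ex$expression, 2, moran_i, coords = coords))
  }, numeric(1))
  expect_true(all(diff(mean_i) > 0))
  expect_lt(abs(mean_i[1]), 0.05)  # no smoothing ~ no autocorrelation
})

test_that("donor bundles carry probe structure and unassignable samples", {
  geom <- generate_geometry(30, seed = 5)
  bd <- generate_donor_microarrays(3, 40, geom, seed = 6, n_far_samples = 3)
  expect_s3_class(bd, "donor_bundle")
  expect_equal(length(bd$donors), 3)
  per_gene <- table(bd$probes$gene)
  expect_true(all(per_gene >= 1 & per_gene <= 3))
  expect_equal(sum(is.na(bd$donors[[1]]$samples$true_region)), 3)
  far <- bd$donors[[1]]$samples[is.na(bd$donors[[1]]$samples$true_region), ]
  cent <- as.matrix(geom[, c("mni_x", "mni_y", "mni_z")])
  dmin <- min(sqrt(outer(rowSums(as.matrix(far[, 2:4])^2), rep(1, 30)) -
                     2 * as.matrix(far[, 2:4]) %*% t(cent) +
                     outer(rep(1, 3), rowSums(cent^2))))
  expect_gt(dmin, 100)  # far-off samples really are far from all centroids
  expect_error(generate_donor_microarrays(1, 10, geom), "n_donors")
})

test_that("gene-set generation includes the planted set and validates sizes", {
  genes <- sprintf("G%03d", 1:100)
  sets <- generate_genesets(genes, genes[1:20], n_random_sets = 10,
                            size_range = c(5, 30), seed = 3)
  expect_named(sets[1], "planted_interaction_set")
  expect_setequal(sets$planted_interaction_set, genes[1:20])
  expect_true(all(lengths(sets[-1]) >= 5 & lengths(sets[-1]) <= 30))
  expect_false(any(vapply(sets, anyDuplicated, integer(1)) > 0))
  expect_error(generate_genesets(genes, genes[1:5], size_range = c(0, 10)),
               "size_range")
  expect_error(generate_genesets(genes, genes[1:5], size_range = c(5, 101)),
               "size_range")
})

test_that("GMT files round-trip a generated collection exactly", {
  genes <- sprintf("G%03d", 1:50)
  sets <- generate_genesets(genes, genes[1:10], n_random_sets = 5,
                            size_range = c(3, 20), seed = 4)
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_identical(names(back), names(sets))
  for (nm in names(sets)) expect_identical(back[[nm]], sets[[nm]])
})

test_that("tissue tables plant brain enrichment and obey TPM constraints", {
  genes <- sprintf("G%02d", 1:20)
  tt <- generate_tissue_table(genes, brain_enriched_genes = "G01", seed = 5)
  expect_equal(dim(tt$tpm), c(20, 54))
  expect_true(all(tt$tpm >= 0))
  expect_equal(sum(tt$labels$is_brain), 13)
  over <- overexpressing_tissues(tt, "G01")
  brain <- tt$labels$tissue[tt$labels$is_brain]
  # brain tissues over-represented among overexpressing tissues
  expect_gt(mean(over %in% brain), mean(tt$labels$is_brain))
  expect_error(generate_tissue_table(genes, n_brain = 1), "brain")
})
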