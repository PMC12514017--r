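# Donor-bundle assembly: background filter, sample-to-parcel mapping,
# probe selection by differential stability, consistency filter, and
# normalization/aggregation.

test_that("background filter applies the pooled >= 50% rule at the boundary", {
  probes <- data.frame(probe_id = c("P1", "P2", "P3", "P4"),
                       gene = c("G1", "G2", "G3", "G4"),
                       stringsAsFactors = FALSE)
  # 100 pooled samples across two donors; above-background counts 100/50/49/0
  bg1 <- rbind(rep(TRUE, 60),
               c(rep(TRUE, 30), rep(FALSE, 30)),
               c(rep(TRUE, 29), rep(FALSE, 31)),
               rep(FALSE, 60))
  bg2 <- rbind(rep(TRUE, 40),
               c(rep(TRUE, 20), rep(FALSE, 20)),
               c(rep(TRUE, 20), rep(FALSE, 20)),
               rep(FALSE, 40))
  donors <- list(
    list(samples = data.frame(sample_id = sprintf("a%d", 1:60)),
         intensity = matrix(0, 4, 60), background = bg1),
    list(samples = data.frame(sample_id = sprintf("b%d", 1:40)),
         intensity = matrix(0, 4, 40), background = bg2))
  bd <- filter_probes_background(manual_bundle(probes, donors))
  expect_identical(bd$probes$probe_id, c("P1", "P2"))  # 100% and exactly 50%
  expect_equal(bd$report$probes_dropped_background, 2L)

  all_above <- donors
  all_above[[1]]$background[] <- TRUE
  all_above[[2]]$background[] <- TRUE
  bd2 <- filter_probes_background(manual_bundle(probes, all_above))
  expect_equal(nrow(bd2$probes), 4L)  # nothing removed
})

test_that("samples map to nearest centroids within tolerance only", {
  geom <- generate_geometry(40, seed = 1)
  probes <- data.frame(probe_id = "P1", gene = "G1",
                       stringsAsFactors = FALSE)
  d <- donor_at_centroids(geom, c(3, 17), matrix(0, 1, 2))
  d$samples$mni_x[2] <- d$samples$mni_x[2] + 500  # push far from everything
  bd <- assign_samples_to_parcels(manual_bundle(probes, list(d, d)), geom)
  expect_equal(bd$donors[[1]]$samples$region, c(3L, NA_integer_))
  expect_equal(bd$report$samples_excluded, 2L)

  # jittered generator samples return to their source region
  bd2 <- generate_donor_microarrays(2, 10, geom, seed = 2, jitter_mm = 1,
                                    n_far_samples = 2)
  bd2 <- assign_samples_to_parcels(bd2, geom)
  for (dn in bd2$donors) {
    ok <- !is.na(dn$samples$true_region)
    expect_gte(mean(dn$samples$region[ok] == dn$samples$true_region[ok]),
               0.99)
    expect_true(all(is.na(dn$samples$region[!ok])))
  }
})

test_that("probe selection maximizes differential stability", {
  geom <- generate_geometry(30, seed = 3)
  regions <- 1:30
  profile <- sin(seq(0, 3 * pi, length.out = 30))

  # identical duplicate probes: lowest probe id wins
  probes <- data.frame(probe_id = c("P2", "P1"), gene = c("G1", "G1"),
                       stringsAsFactors = FALSE)
  inten <- rbind(profile, profile)
  rownames(inten) <- probes$probe_id
  donors <- list(donor_at_centroids(geom, regions, inten, donor_id = 1),
                 donor_at_centroids(geom, regions, inten, donor_id = 2))
  bd <- assign_samples_to_parcels(manual_bundle(probes, donors), geom)
  sel <- select_probe_per_gene(bd)
  expect_identical(sel$probes$probe_id, "P1")

  # shared-profile probe beats a pure-noise probe across seeds
  wins <- 0
  for (s in 1:100) {
    set.seed(s)
    good <- rbind(profile + rnorm(30, 0, 0.1), rnorm(30))
    rownames(good) <- c("P1", "P2")
    bad <- rbind(profile + rnorm(30, 0, 0.1), rnorm(30))
    rownames(bad) <- c("P1", "P2")
    pb <- data.frame(probe_id = c("P1", "P2"), gene = "G1",
                     stringsAsFactors = FALSE)
    dn <- list(donor_at_centroids(geom, regions, good, donor_id = 1),
               donor_at_centroids(geom, regions, bad, donor_id = 2))
    b <- select_probe_per_gene(
      assign_samples_to_parcels(manual_bundle(pb, dn), geom))
    wins <- wins + (b$probes$probe_id == "P1")
  }
  expect_gte(wins, 99)
})

test_that("inconsistent genes are filtered by differential stability", {
  geom <- generate_geometry(25, seed = 4)
  profile <- cos(seq(0, 2 * pi, length.out = 25))
  set.seed(9)
  # G1 identical across donors (DS = 1); G2 independent noise (E[DS] ~ 0)
  make_int <- function() rbind(G1p = profile, G2p = rnorm(25))
  probes <- data.frame(probe_id = c("G1p", "G2p"), gene = c("G1", "G2"),
                       stringsAsFactors = FALSE)
  donors <- list(donor_at_centroids(geom, 1:25, make_int(), donor_id = 1),
                 donor_at_centroids(geom, 1:25, make_int(), donor_id = 2),
                 donor_at_centroids(geom, 1:25, make_int(), donor_id = 3))
  bd <- select_probe_per_gene(
    assign_samples_to_parcels(manual_bundle(probes, donors), geom))
  kept <- filter_inconsistent_genes(bd, min_stability = 0.1)
  expect_identical(kept$probes$gene, "G1")
  expect_equal(kept$probes$probe_stability, 1, tolerance = 1e-12)

  none <- filter_inconsistent_genes(bd, min_stability = -Inf)
  expect_equal(nrow(none$probes), 2L)  # threshold below all: nothing dropped
  expect_error(filter_inconsistent_genes(
    manual_bundle(bd$probes, bd$donors[1])), ">= 2 donors")
})

test_that("aggregation identities hold without normalization", {
  geom <- generate_geometry(20, seed = 5)
  set.seed(10)
  inten <- matrix(rnorm(3 * 20), 3, 20,
                  dimnames = list(c("P1", "P2", "P3"), NULL))
  probes <- data.frame(probe_id = c("P1", "P2", "P3"),
                       gene = c("G1", "G2", "G3"),
                       stringsAsFactors = FALSE)
  one <- list(donor_at_centroids(geom, 1:20, inten))
  out1 <- normalize_and_aggregate(
    assign_samples_to_parcels(manual_bundle(probes, one), geom),
    normalize = "none")
  # one donor, one sample per region: output = z-scored input profile
  expect_equal(out1$expression, zscore <- scale(t(inten)),
               tolerance = 1e-12, ignore_attr = TRUE)

  # two donors with identical profiles equal the single-donor output
  two <- list(donor_at_centroids(geom, 1:20, inten, donor_id = 1),
              donor_at_centroids(geom, 1:20, inten, donor_id = 2))
  out2 <- normalize_and_aggregate(
    assign_samples_to_parcels(manual_bundle(probes, two), geom),
    normalize = "none")
  expect_equal(out1$expression, out2$expression, tolerance = 1e-12)
})

test_that("donor-level intensity scaling does not change the output", {
  geom <- generate_geometry(20, seed = 6)
  set.seed(11)
  inten <- matrix(rnorm(2 * 20), 2, 20,
                  dimnames = list(c("P1", "P2"), NULL))
  probes <- data.frame(probe_id = c("P1", "P2"), gene = c("G1", "G2"),
                       stringsAsFactors = FALSE)
  plain <- list(donor_at_centroids(geom, 1:20, inten, donor_id = 1),
                donor_at_centroids(geom, 1:20, inten, donor_id = 2))
  scaled <- list(donor_at_centroids(geom, 1:20, inten, donor_id = 1),
                 donor_at_centroids(geom, 1:20, inten * 10, donor_id = 2))
  o1 <- normalize_and_aggregate(
    assign_samples_to_parcels(manual_bundle(probes, plain), geom))
  o2 <- normalize_and_aggregate(
    assign_samples_to_parcels(manual_bundle(probes, scaled), geom))
  expect_lt(max(abs(o1$expression - o2$expression)), 1e-6)
})

test_that("full assembly reproduces ground truth on a noise-free bundle", {
  geom <- generate_geometry(40, seed = 7)
  bd <- generate_donor_microarrays(3, 25, geom, seed = 8,
                                   region_coverage = 1, jitter_mm = 0.5,
                                   noise_sd = 1e-6, p_extra_noisy = 0,
                                   p_extra_failing = 0)
  out <- assemble_expression(bd, geom, normalize = "none")
  expect_equal(nrow(out$expression), 40)
  expect_false(any(is.na(out$expression)))
  truth <- bd$truth[rownames(out$expression), colnames(out$expression)]
  r <- vapply(seq_len(ncol(truth)),
              function(j) cor(out$expression[, j], truth[, j]), numeric(1))
  expect_true(all(r > 0.999))
  # assembly report tracks every stage
  expect_true(all(c("probes_dropped_background", "samples_excluded",
                    "genes_dropped_inconsistent", "n_genes") %in%
                    names(out$report)))
})
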