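# Empirical-Bayes site harmonization: identity on a single site, removal of
# planted location/scale effects, preservation of protected covariates, and
# agreement with an independent reference implementation.

combat_cohort <- function(n_sites, site_shift, site_scale, n_regions = 60,
                          noise_sd = 0.1, seed = 11, n_per_cell = 50) {
  geom <- generate_geometry(n_regions, seed = 1)
  cfg <- cohort_config(n_patients_f = n_per_cell, n_patients_m = n_per_cell,
                       n_controls_f = n_per_cell, n_controls_m = n_per_cell,
                       n_regions = n_regions, n_sites = n_sites,
                       site_shift = site_shift, site_scale = site_scale,
                       atrophy_regions = 1:5, atrophy_male = 0,
                       atrophy_female = 0, noise_sd = noise_sd, seed = seed)
  generate_cohort(cfg, geom)
}

test_that("a single site yields an identity harmonization", {
  coh <- combat_cohort(1, 0, 1)
  model <- combat_fit(coh$thickness, coh$participants)
  expect_lt(max(abs(model$gamma_star)), 1e-6)
  expect_lt(max(abs(model$delta_star - 1)), 1e-6)
  adj <- combat_apply(model, coh$thickness, coh$participants)
  expect_lt(max(abs(adj - coh$thickness)), 1e-6)
})

test_that("planted additive and multiplicative site effects are removed", {
  coh <- combat_cohort(2, c(0, 0.4), c(1, 2), n_regions = 200,
                       n_per_cell = 150, seed = 6)
  adj <- combat_harmonize(coh$thickness, coh$participants)
  site <- coh$participants$site
  raw_gap <- mean(abs(colMeans(coh$thickness[site == "site1", ]) -
                        colMeans(coh$thickness[site == "site2", ])))
  adj_gap <- mean(abs(colMeans(adj[site == "site1", ]) -
                        colMeans(adj[site == "site2", ])))
  expect_gt(raw_gap, 0.35)       # the planted shift is really there
  expect_lt(adj_gap, 0.02)       # and harmonization removes it

  sd1 <- apply(adj[site == "site1", ], 2, sd)
  sd2 <- apply(adj[site == "site2", ], 2, sd)
  raw_sd2 <- apply(coh$thickness[site == "site2", ], 2, sd)
  raw_sd1 <- apply(coh$thickness[site == "site1", ], 2, sd)
  # within-site SD mixes the x2 noise scale with the common age trend
  expect_gt(median(raw_sd2 / raw_sd1), 1.6)
  expect_true(all(abs(sd2 / sd1 - 1) < 0.25))
  expect_lt(mean(abs(sd2 / sd1 - 1)), 0.1)
})

test_that("a protected sex effect survives harmonization unchanged", {
  # compare against the no-site-effect counterfactual generated from the
  # same seed (identical noise draws), so Cohen's d is directly comparable
  coh <- combat_cohort(2, c(0, 0.4), c(1, 1), n_regions = 100,
                       n_per_cell = 150, seed = 7)
  truth <- combat_cohort(1, 0, 1, n_regions = 100, n_per_cell = 150,
                         seed = 7)
  f <- coh$participants$sex == "F"
  th <- coh$thickness
  th[f, ] <- th[f, ] + 0.08
  th_truth <- truth$thickness
  th_truth[f, ] <- th_truth[f, ] + 0.08
  adj <- combat_harmonize(th, coh$participants)
  d_of <- function(M) vapply(seq_len(ncol(M)), function(r)
    cohens_d_from_summary(mean(M[f, r]), sd(M[f, r]), sum(f),
                          mean(M[!f, r]), sd(M[!f, r]), sum(!f)),
    numeric(1))
  expect_lt(max(abs(d_of(adj) - d_of(th_truth))), 0.05)
})

test_that("refitting on harmonized data finds no site effect left", {
  coh <- combat_cohort(3, c(-0.2, 0, 0.3), c(1, 1.5, 0.8), n_regions = 80,
                       n_per_cell = 80, seed = 8)
  adj <- combat_harmonize(coh$thickness, coh$participants)
  refit <- combat_fit(adj, coh$participants)
  expect_lt(max(abs(refit$gamma_star)), 0.05)  # standardized units
  expect_lt(max(abs(refit$delta_star - 1)), 0.15)
})

test_that("site ANOVA rejects at nominal rate after harmonization", {
  coh <- combat_cohort(3, c(-0.3, 0, 0.3), c(1, 1.6, 0.7), n_regions = 200,
                       n_per_cell = 60, seed = 9)
  adj <- combat_harmonize(coh$thickness, coh$participants)
  pt <- coh$participants
  covar <- model.matrix(~ group + age + sex, pt)
  rej <- vapply(seq_len(ncol(adj)), function(r) {
    res <- stats::lm.fit(covar, adj[, r])$residuals
    summary(stats::aov(res ~ factor(pt$site)))[[1]][["Pr(>F)"]][1] < 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.07)
})

test_that("a planted age slope is recovered after harmonization", {
  geom <- generate_geometry(60, seed = 1)
  cfg <- cohort_config(n_patients_f = 50, n_patients_m = 50,
                       n_controls_f = 100, n_controls_m = 100,
                       n_regions = 60, n_sites = 2, site_shift = c(0, 0.4),
                       site_scale = c(1, 1.5), atrophy_regions = 1:5,
                       atrophy_male = 0, atrophy_female = 0,
                       age_slope = -0.01, noise_sd = 0.1, seed = 10)
  coh <- generate_cohort(cfg, geom)
  adj <- combat_harmonize(coh$thickness, coh$participants)
  slopes <- vapply(seq_len(ncol(adj)), function(r)
    coef(stats::lm(adj[, r] ~ coh$participants$age))[2], numeric(1))
  expect_lt(abs(mean(slopes) - (-0.01)), 0.001)  # within 10%
})

test_that("fit errors name undersized sites and reject collinear designs", {
  coh <- combat_cohort(2, c(0, 0.2), c(1, 1), n_per_cell = 10)
  pt <- coh$participants
  pt$site[pt$site == "site2"] <- "site1"
  pt$site[1] <- "lonely_site"
  expect_error(combat_fit(coh$thickness, pt), "lonely_site")

  pt2 <- coh$participants
  pt2$copy <- pt2$age
  expect_error(combat_fit(coh$thickness, pt2,
                          covariates = c("age", "copy")), "rank deficient")
  pt3 <- coh$participants
  expect_error(combat_apply(combat_fit(coh$thickness, pt3),
                            coh$thickness,
                            transform(pt3, site = "siteX")), "unknown site")
})

test_that("harmonization agrees with the sva reference implementation", {
  skip_if_not_installed("sva")
  geom <- generate_geometry(60, seed = 2)
  cfg <- cohort_config(n_patients_f = 30, n_patients_m = 30,
                       n_controls_f = 30, n_controls_m = 30,
                       n_regions = 60, n_sites = 3,
                       site_shift = c(-0.2, 0, 0.3),
                       site_scale = c(1, 1.6, 0.8),
                       atrophy_regions = 1:10, noise_sd = 0.1, seed = 4)
  coh <- generate_cohort(cfg, geom)
  mine <- combat_harmonize(coh$thickness, coh$participants)
  mod <- model.matrix(~ group + age + sex, coh$participants)
  ref <- suppressMessages(t(sva::ComBat(dat = t(coh$thickness),
                                        batch = coh$participants$site,
                                        mod = mod)))
  # conventions differ slightly (variance denominators); agreement to ~0.01mm
  expect_lt(max(abs(mine - ref)), 0.02)
  expect_lt(mean(abs(mine - ref)), 0.005)
  expect_gt(cor(as.vector(mine), as.vector(ref)), 0.9999)
})
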