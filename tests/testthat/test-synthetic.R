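test_that("simulation is deterministic given the seed", {
  cfg <- small_sim_config(seed = 42)
  a <- simulate_community(cfg)
  b <- simulate_community(cfg)
  expect_identical(a$morphology, b$morphology)
  expect_identical(a$observations, b$observations)
  expect_identical(a$profiles, b$profiles)
  expect_identical(a$introductions, b$introductions)
  c2 <- simulate_community(small_sim_config(seed = 43))
  expect_false(identical(a$morphology, c2$morphology))
})

test_that("zero covariance collapses every individual onto the species mean", {
  cfg <- sim_config(morpho_cov = matrix(0, 6, 6), seed = 1,
                    n_individuals_per_species_site = 3)
  m <- simulate_morphology(cfg)
  for (sp in rownames(cfg$morpho_means)) {
    sub <- m[m$species == sp, ]
    expect_equal(unique(sub$wing_length), cfg$morpho_means[sp, "wing_length"],
                 tolerance = 1e-12)
    expect_equal(unique(sub$mass), cfg$morpho_means[sp, "mass"],
                 tolerance = 1e-12)
  }
})

test_that("simulated trait means converge to the configured means", {
  cfg <- sim_config(n_species = 1, n_sites = 1,
                    morpho_means = default_means <- matrix(
                      c(60, 20, 10, 4, 4, 15), 1,
                      dimnames = list("sp01", c(morpho_traits(), "mass"))),
                    n_individuals_per_species_site = 2000, seed = 99)
  m <- simulate_morphology(cfg)
  se <- sqrt(cfg$morpho_cov[1, 1] / 2000)
  expect_lt(abs(mean(m$wing_length) - 60), 3 * se)
  expect_true(all(m[, c(morpho_traits(), "mass")] > 0))
})

test_that("non-PSD covariance and bad behaviour config raise configuration errors", {
  bad <- diag(6); bad[1, 2] <- bad[2, 1] <- 5  # eigenvalue -4
  expect_error(sim_config(morpho_cov = bad), "positive semi-definite")
  expect_error(
    sim_config(behavior_coefs = list(perching = list(
      intercept = 0, slope = 1, ratio = "tarsus_to_wing"))),
    "not in the vocabulary"
  )
  expect_error(
    sim_config(behavior_coefs = list(gleaning = list(
      intercept = 0, slope = 1, ratio = "wingspan"))),
    "unknown ratio"
  )
  expect_error(sim_config(n_intro_species = 1, n_native_species = 0,
                          seed = 1) |> simulate_invasion_history(),
               "at least 2 species")
})

test_that("a zero logit gives one-half behaviour frequency and heights scale with canopy", {
  cfg <- small_sim_config(
    seed = 2,
    behavior_coefs = list(
      gleaning = list(intercept = 0, slope = 0, ratio = "tarsus_to_wing")
    ),
    n_obs_per_species_site = 250
  )
  m <- simulate_morphology(cfg)
  ev <- simulate_observations(cfg, compute_ratios(m))
  expect_lt(abs(mean(ev$gleaning) - 0.5), 0.02)  # logit^-1(0) = 0.5
  # raw height = relative height x canopy height by construction
  expect_true(all(ev$min_height <= ev$max_height))
  rh <- relative_heights(ev)
  expect_equal(rh$rel_max_height * ev$canopy_height_mean, ev$max_height,
               tolerance = 1e-12)
})

test_that("a strong positive slope orders species' behaviour frequencies", {
  # two species differing only in tarsus length -> tarsus:wing 0.25 vs 0.45
  means <- matrix(c(80, 20, 10, 4, 4, 20,
                    80, 36, 10, 4, 4, 20), 2, byrow = TRUE,
                  dimnames = list(c("lo", "hi"), c(morpho_traits(), "mass")))
  cfg <- sim_config(
    n_species = 2, n_sites = 1, morpho_means = means,
    behavior_coefs = list(
      gleaning = list(intercept = -3.5, slope = 10, ratio = "tarsus_to_wing")
    ),
    n_obs_per_species_site = 5000, seed = 31
  )
  m <- simulate_morphology(cfg)
  ev <- simulate_observations(cfg, compute_ratios(m))
  p_lo <- mean(ev$gleaning[ev$species == "lo"])
  p_hi <- mean(ev$gleaning[ev$species == "hi"])
  expect_gt(p_hi, p_lo)
})

test_that("identical niche profiles force PS features to one", {
  cfg <- small_sim_config(seed = 6, identical_profiles = TRUE)
  inv <- simulate_invasion_history(cfg)
  expect_true(all(inv$features$mean_ps_diet == 1))
  expect_true(all(inv$features$mean_ps_for == 1))
})

test_that("null establishment coefficients leave establishment unrelated to PS", {
  cfg <- sim_config(
    n_intro_species = 500, n_native_species = 10, n_families = 20,
    estab_coefs = c(intercept = 0, richness = 0, years = 0,
                    ps_diet = 0, ps_for = 0),
    family_sd = 0, seed = 17
  )
  inv <- simulate_invasion_history(cfg)
  f <- inv$features
  fit <- stats::glm(established ~ mean_ps_diet, data = f, family = binomial())
  ci <- suppressMessages(stats::confint(fit))["mean_ps_diet", ]
  expect_true(ci[1] < 0 && ci[2] > 0)
  expect_lt(abs(mean(f$established) - 0.5), 0.07)
})

test_that("a strong negative diet-PS effect shows up across PS quartile bins", {
  cfg <- sim_config(
    n_intro_species = 2000, n_native_species = 10, n_families = 20,
    estab_coefs = c(intercept = 4, richness = 0, years = 0,
                    ps_diet = -8, ps_for = 0),
    family_sd = 0, seed = 23
  )
  inv <- simulate_invasion_history(cfg)
  f <- inv$features
  bins <- cut(f$mean_ps_diet,
              stats::quantile(f$mean_ps_diet, probs = seq(0, 1, 0.25)),
              include.lowest = TRUE)
  rates <- tapply(f$established, bins, mean)
  expect_true(all(diff(rates) < 0))
})

test_that("establishment frequency per PS bin matches the configured inverse logit", {
  cfg <- sim_config(
    n_intro_species = 5000, n_native_species = 10, n_families = 20,
    estab_coefs = c(intercept = 4, richness = 0, years = 0,
                    ps_diet = -8, ps_for = 0),
    family_sd = 0, seed = 29
  )
  inv <- simulate_invasion_history(cfg)
  f <- inv$features
  bins <- cut(f$mean_ps_diet, breaks = stats::quantile(
    f$mean_ps_diet, probs = seq(0, 1, 0.2)), include.lowest = TRUE)
  for (b in levels(bins)) {
    sub <- f[bins == b, ]
    expected <- mean(plogis(4 - 8 * sub$mean_ps_diet))
    mc_se <- sqrt(expected * (1 - expected) / nrow(sub)) + 1e-6
    expect_lt(abs(mean(sub$established) - expected), 4 * mc_se)
  }
})

test_that("the written ground-truth sidecar and tables land on disk", {
  dir <- withr::local_tempdir()
  sim <- simulate_community(small_sim_config(seed = 12))
  paths <- write_community_tables(sim, dir)
  expect_true(all(file.exists(paths)))
  truth <- jsonlite::read_json(paths["ground_truth"])
  expect_equal(truth$estab_coefs$ps_diet, unname(sim$config$estab_coefs["ps_diet"]))
})
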