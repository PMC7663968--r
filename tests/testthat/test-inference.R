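test_that("the model registry mirrors the literature-derived design", {
  reg <- model_registry()
  expect_equal(nrow(reg), 10)
  # foraging behaviours use 4 species, movement/height/location responses 5
  foraging <- reg$response %in% c("gleaning", "flycatching", "frugivory")
  expect_true(all(reg$n_species[foraging] == 4L))
  expect_true(all(reg$n_species[!foraging] == 5L))
  # among the correlated bill ratios only one enters each model
  for (p in reg$predictors) {
    expect_lte(sum(p %in% c("horizontal_bill_aspect", "bill_slenderness")), 1)
  }
  expect_equal(reg$predictors[reg$response == "gleaning"][[1]],
               c("bill_slenderness", "tarsus_to_wing"))
  expect_true(all(reg$family[grepl("height", reg$response)] == "gaussian"))
})

test_that("behaviour GLMM recovers a strong configured slope (single replicate)", {
  cfg <- small_sim_config(
    seed = 101,
    n_obs_per_species_site = 120,
    behavior_coefs = list(
      gleaning = list(intercept = -5, slope = 16, ratio = "tarsus_to_wing")
    )
  )
  m <- simulate_morphology(cfg)
  ratios <- compute_ratios(m)
  ev <- simulate_observations(cfg, ratios)
  fit <- fit_behavior_model(response_vectors(ev), ratios, "gleaning",
                            "tarsus_to_wing")
  co <- coef_table(fit)
  est <- co$estimate[co$term == "tarsus_to_wing"]
  se <- co$se[co$term == "tarsus_to_wing"]
  expect_gt(est, 0)
  expect_lt(abs(est - 16), 1.96 * se * 1.5)
  expect_true(all(c("site", "species") %in% names(fit$n_groups)))
})

test_that("constant predictors and degenerate designs are clean errors", {
  ratios <- compute_ratios(toy_morphology())
  ratios$tarsus_to_wing <- 0.5
  ev <- toy_events(6)
  ev$species <- rep(c("spA", "spB"), 3)
  ev$site <- rep(c("s1", "s2"), each = 3)
  ev$gleaning[1:3] <- TRUE
  rv <- response_vectors(ev)
  expect_error(fit_behavior_model(rv, ratios, "gleaning", "tarsus_to_wing"),
               "constant")
  ratios2 <- compute_ratios(toy_morphology())
  ev$site <- "s1"
  expect_error(
    fit_behavior_model(response_vectors(ev), ratios2, "gleaning",
                       "tarsus_to_wing"),
    "at least 2 sites"
  )
  expect_error(
    fit_behavior_model(rv, ratios, "gleaning", "wingspan"),
    "unknown predictor"
  )
})

test_that("height models report Satterthwaite df and recover a mass effect", {
  # steeper-than-default mass effect on relative height via a dedicated
  # construction: heights correlated with species mass
  cfg <- small_sim_config(seed = 55, n_obs_per_species_site = 80)
  m <- simulate_morphology(cfg)
  ratios <- compute_ratios(m)
  ev <- simulate_observations(cfg, ratios)
  rh <- relative_heights(ev)
  mass_of <- stats::setNames(ratios$mass_mean / 1000,
                             paste(ratios$species, ratios$site))
  mkey <- mass_of[paste(rh$species, rh$site)]
  set.seed(1)
  rh$rel_max_height <- 0.3 + 12 * mkey + rnorm(nrow(rh), 0, 0.15)
  rh$rel_min_height <- pmax(rh$rel_max_height - 0.2, 0)
  fits <- fit_height_model(rh, ratios)
  expect_named(fits, c("max", "min"))
  co <- coef_table(fits$max)
  expect_equal(fits$max$family, "gaussian")
  mass_row <- co[co$term == "mass_kg", ]
  expect_gt(mass_row$estimate, 0)
  expect_false(is.na(mass_row$df))   # fractional Satterthwaite df
  expect_lt(mass_row$p_value, 0.05)
})

test_that("quasibinomial PS-vs-distance fit reports t statistics on n - 2 df", {
  set.seed(77)
  n <- 40
  sp <- sprintf("s%02d", 1:9)
  pairs <- t(utils::combn(sp, 2))
  d <- runif(nrow(pairs), 0, 8)
  ps <- plogis(1.2 - 0.4 * d + rnorm(nrow(pairs), 0, 0.3))
  ps_tbl <- tibble::tibble(species_a = pairs[, 1], species_b = pairs[, 2],
                           kind = "behavior", site = NA_character_, ps = ps)
  d_tbl <- tibble::tibble(species_a = pairs[, 1], species_b = pairs[, 2],
                          site = NA_character_, euclidean_distance = d)
  fit <- fit_ps_vs_distance(ps_tbl, d_tbl)
  co <- coef_table(fit)
  expect_equal(unique(co$df), nrow(pairs) - 2)
  slope <- co[co$term == "euclidean_distance", ]
  expect_lt(slope$estimate, 0)
  expect_lt(abs(slope$estimate - (-0.4)), 1.96 * slope$se * 1.5)
  expect_false(is.na(fit$dispersion))
  # constant response: slope ~ 0 and tiny dispersion
  ps_tbl$ps <- 0.5
  fit0 <- fit_ps_vs_distance(ps_tbl, d_tbl)
  co0 <- coef_table(fit0)
  expect_lt(abs(co0$estimate[co0$term == "euclidean_distance"]), 1e-8)
  expect_lt(fit0$dispersion, 1e-12)
  expect_error(fit_ps_vs_distance(ps_tbl[1:2, ], d_tbl[1:2, ]), "at least 3")
})

test_that("establishment model recovers the sign of a strong PS-diet effect", {
  cfg <- sim_config(
    n_intro_species = 300, n_native_species = 12, n_families = 30,
    estab_coefs = c(intercept = 2.6, richness = -0.028, years = 0.013,
                    ps_diet = -8, ps_for = 1.131),
    family_sd = 0.5, seed = 202
  )
  inv <- simulate_invasion_history(cfg)
  pp <- pairwise_ps(inv$profiles)
  f <- build_features(inv$introductions, pp[pp$kind == "diet", ],
                      pp[pp$kind == "foraging_stratum", ])
  fit <- fit_establishment_model(f, mode = "all")
  co <- coef_table(fit)
  slope <- co[co$term == "mean_ps_diet", ]
  expect_lt(slope$estimate, 0)
  expect_lt(abs(slope$estimate - (-8)), 2.5 * slope$se)
  expect_equal(fit$family, "binomial")
  # no_gamebirds mode drops exactly the flagged species
  n_drop <- sum(f$game_bird & !f$single_individual)
  fit_ng <- fit_establishment_model(f, mode = "no_gamebirds")
  expect_equal(fit$n_obs - fit_ng$n_obs, n_drop)
})

test_that("zero-variance limit of the binomial GLMM equals the plain GLM", {
  set.seed(12)
  n <- 300
  d <- data.frame(
    y = rbinom(n, 1, 0.35),
    x = rnorm(n),
    site = sample(paste0("s", 1:4), n, TRUE),
    species = sample(paste0("sp", 1:5), n, TRUE)
  )
  limit <- glmm_zero_variance_limit(y ~ x + (1 | site) + (1 | species), d)
  ref <- stats::coef(stats::glm(y ~ x, data = d, family = binomial()))
  expect_equal(unname(limit), unname(ref), tolerance = 1e-6)
})
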