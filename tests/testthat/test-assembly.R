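# Hand-traced expectations for the toy timeline (see helper-fixtures.R).
# With two diet categories PS(a, b) = (min(a1, b1) + min(a2, b2)) / 100,
# giving the pairwise values used below.

test_that("incumbent community follows the before-or-during rule", {
  rec <- toy_timeline()
  expect_setequal(incumbent_community(rec, 1890), c("nat1", "nat2"))
  expect_setequal(incumbent_community(rec, 1900), c("nat1", "nat2", "A"))
  # same-year introductions are included
  expect_true("D" %in% incumbent_community(rec, 1910, focal = "C"))
  # the focal species is excluded from its own incumbent set
  expect_false("C" %in% incumbent_community(rec, 1910, focal = "C"))
})

test_that("extirpation boundary conventions differ exactly at the boundary year", {
  rec <- toy_timeline()  # B last reported 1910
  expect_true("B" %in% incumbent_community(rec, 1910, boundary = "inclusive"))
  expect_false("B" %in% incumbent_community(rec, 1910, boundary = "strict"))
  expect_false("B" %in% incumbent_community(rec, 1911, boundary = "inclusive"))
  expect_true("B" %in% incumbent_community(rec, 1909, boundary = "strict"))
})

test_that("toy-timeline features match full manual computation (both boundaries)", {
  rec <- toy_timeline()
  m <- toy_profiles_matrix()
  profiles <- dplyr::bind_rows(
    tibble::tibble(species = rep(rownames(m), each = 2), profile_kind = "diet",
                   category = rep(c("c1", "c2"), 6), percent = as.vector(t(m)),
                   certainty = "A"),
    tibble::tibble(species = rep(rownames(m), each = 2),
                   profile_kind = "foraging_stratum",
                   category = rep(c("c1", "c2"), 6), percent = as.vector(t(m)),
                   certainty = "A")
  )
  pp <- pairwise_ps(profiles)
  psd <- pp[pp$kind == "diet", ]
  psf <- pp[pp$kind == "foraging_stratum", ]

  f <- build_features(rec, psd, psf, boundary = "inclusive")
  expect_equal(f$species, c("A", "B", "C", "D"))
  expect_equal(f$incumbent_richness, c(2L, 3L, 5L, 5L))
  expect_equal(f$n_introduction_years, c(1L, 2L, 1L, 1L))
  expect_equal(f$mean_ps_diet, c(0.8, (0.9 + 0.7 + 0.6) / 3, 0.6, 0.8),
               tolerance = 1e-12)
  expect_equal(f$mean_ps_for, f$mean_ps_diet)
  expect_equal(f$established, c(TRUE, FALSE, TRUE, FALSE))

  fs <- build_features(rec, psd, psf, boundary = "strict")
  expect_equal(fs$incumbent_richness, c(2L, 3L, 4L, 4L))
  expect_equal(fs$mean_ps_diet,
               c(0.8, (0.9 + 0.7 + 0.6) / 3, (0.5 + 0.7 + 0.8 + 0.6) / 4, 0.8),
               tolerance = 1e-12)
})

test_that("identical profiles give mean PS of exactly 1 for every introduction", {
  rec <- toy_timeline()
  m <- toy_profiles_matrix()
  m[] <- rep(c(50, 50), each = 6)
  profiles <- tibble::tibble(
    species = rep(rownames(m), each = 2), profile_kind = "diet",
    category = rep(c("c1", "c2"), 6), percent = as.vector(t(m)),
    certainty = "A"
  )
  pp <- pairwise_ps(profiles)
  f <- build_features(rec, pp, pp)
  expect_true(all(f$mean_ps_diet == 1))
})

test_that("incumbent sets grow monotonically except at extirpations", {
  set.seed(8)
  inv <- simulate_invasion_history(small_sim_config(seed = 8))
  rec <- inv$introductions
  years <- sort(unique(rec$first_introduction_year))
  prev <- incumbent_community(rec, years[1] - 1)
  for (y in years) {
    cur <- incumbent_community(rec, y)
    extirpated <- rec$species[!is.na(rec$extirpation_year) &
                                rec$extirpation_year < y]
    expect_true(all(setdiff(prev, extirpated) %in% cur))
    prev <- cur
  }
})

test_that("build_features reproduces the simulator's internal features exactly", {
  inv <- simulate_invasion_history(small_sim_config(seed = 3))
  pp <- pairwise_ps(inv$profiles)
  f <- build_features(
    inv$introductions,
    pp[pp$kind == "diet", ],
    pp[pp$kind == "foraging_stratum", ]
  )
  truth <- inv$features[order(inv$features$species), ]
  got <- f[order(f$species), ]
  expect_equal(got$species, truth$species)
  expect_equal(got$incumbent_richness, truth$incumbent_richness)
  expect_equal(got$mean_ps_diet, truth$mean_ps_diet, tolerance = 1e-12)
  expect_equal(got$mean_ps_for, truth$mean_ps_for, tolerance = 1e-12)
  expect_equal(got$n_introduction_years, truth$n_introduction_years)
  expect_equal(got$established, truth$established)
})

test_that("exclusion modes drop exactly the flagged rows", {
  inv <- simulate_invasion_history(small_sim_config(seed = 5))
  pp <- pairwise_ps(inv$profiles)
  f <- build_features(inv$introductions, pp[pp$kind == "diet", ],
                      pp[pp$kind == "foraging_stratum", ])
  n_game <- sum(f$game_bird)
  n_single <- sum(f$single_individual)
  expect_gt(n_game, 0)
  all_mode <- apply_exclusions(f, "all", drop_single_individual = FALSE)
  expect_equal(nrow(all_mode), nrow(f))
  ng <- apply_exclusions(f, "no_gamebirds", drop_single_individual = FALSE)
  expect_equal(nrow(ng), nrow(f) - n_game)
  both <- apply_exclusions(f, "no_gamebirds", drop_single_individual = TRUE)
  expect_equal(nrow(both), nrow(f) - sum(f$game_bird | f$single_individual))
  expect_error(
    apply_exclusions(f[f$game_bird, ], "no_gamebirds",
                     drop_single_individual = FALSE),
    "no introductions remain"
  )
})
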