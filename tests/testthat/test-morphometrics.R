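test_that("morphological ratios match hand computation", {
  r <- compute_ratios(toy_morphology())
  a <- r[r$species == "spA" & r$site == "s1", ]
  expect_equal(a$tarsus_to_wing, 1.0)          # tarsus 20 / wing 20
  expect_equal(a$horizontal_bill_aspect, 2.5)  # culmen 10 / width 4
  # ellipse cross-section: pi * 2 * 2 = 12.566 mm^2 -> 10 / 12.566 = 0.7958
  expect_equal(a$bill_slenderness, 10 / (pi * 2 * 2), tolerance = 1e-12)
  expect_equal(round(a$bill_slenderness, 4), 0.7958)
  expect_equal(a$mass_mean, 10)
  expect_equal(a$n_individuals, 2L)
  # rectangle alternative
  r2 <- compute_ratios(toy_morphology(), bill_area = "rectangle")
  expect_equal(r2$bill_slenderness[1], 10 / 16)
})

test_that("horizontal bill aspect is scale-consistent", {
  m <- toy_morphology()
  m2 <- dplyr::mutate(m, culmen_length = culmen_length * 3.7,
                      bill_width_nares = bill_width_nares * 3.7)
  expect_equal(compute_ratios(m)$horizontal_bill_aspect,
               compute_ratios(m2)$horizontal_bill_aspect, tolerance = 1e-12)
})

test_that("ratios average per individual, not as a ratio of means", {
  m <- toy_morphology()[1:2, ]
  m$tarsus_length <- c(10, 30)
  m$wing_length <- c(20, 40)
  r <- compute_ratios(m)
  expect_equal(r$tarsus_to_wing, mean(c(10 / 20, 30 / 40)))
  expect_false(isTRUE(all.equal(r$tarsus_to_wing, 40 / 60)))
})

test_that("juveniles are excluded and empty groups are dropped with warning", {
  m <- toy_morphology()
  m$age_class[m$species == "spB" & m$site == "s2"] <- "juvenile"
  m$tarsus_length[1] <- 40  # juvenile value should not matter below
  m$age_class[1] <- "juvenile"
  expect_warning(r <- compute_ratios(m), "spB@s2")
  expect_equal(nrow(r), 3)
  a <- r[r$species == "spA" & r$site == "s1", ]
  expect_equal(a$n_individuals, 1L)
  expect_equal(a$tarsus_to_wing, 1.0)
})

test_that("PCA morphospace has expected structure", {
  set.seed(5)
  m <- simulate_morphology(small_sim_config())
  ms <- pca_morphospace(m)
  expect_s3_class(ms, "morphospace")
  expect_equal(ncol(ms$loadings), 5)
  expect_equal(sum(ms$var_explained), 1)
  expect_equal(nrow(ms$scores), nrow(m))
  # duplicate rows get identical scores
  m2 <- dplyr::bind_rows(m, m[7, ])
  ms2 <- pca_morphospace(m2)
  last <- nrow(ms2$scores)
  expect_equal(as.numeric(ms2$scores[last, grep("^PC", names(ms2$scores))]),
               as.numeric(ms2$scores[7, grep("^PC", names(ms2$scores))]))
})

test_that("two perfectly correlated traits load on a single component", {
  n <- 50
  set.seed(2)
  base <- rnorm(n, 20, 3)
  m <- tibble::tibble(
    species = "x", site = "s", individual_id = as.character(1:n),
    wing_length = base, tarsus_length = 2 * base,
    culmen_length = 10, bill_width_nares = 4, bill_depth_nares = 4,
    mass = 10, age_class = "adult"
  )
  expect_warning(ms <- pca_morphospace(m), "constant")
  expect_equal(length(ms$traits), 2)
  expect_equal(ms$var_explained[1], 1, tolerance = 1e-12)
})

test_that("isotropic data spreads variance roughly equally", {
  set.seed(9)
  n <- 4000
  m <- tibble::tibble(
    species = "x", site = "s", individual_id = as.character(1:n),
    wing_length = rnorm(n), tarsus_length = rnorm(n),
    culmen_length = rnorm(n), bill_width_nares = rnorm(n),
    bill_depth_nares = rnorm(n), mass = 1, age_class = "adult"
  )
  ms <- pca_morphospace(m)
  expect_true(all(abs(ms$var_explained - 0.2) < 0.03))
})

test_that("centroid distances are Euclidean and match brute force", {
  scores <- tibble::tibble(
    individual_id = as.character(1:4),
    species = c("a", "a", "b", "b"), site = "s1",
    PC1 = c(0, 0, 3, 3), PC2 = c(0, 0, 4, 4)
  )
  d <- centroid_distances(scores)
  expect_equal(d$euclidean_distance, 5)  # 3-4-5 triangle
  scores$PC1[3:4] <- 0; scores$PC2[3:4] <- 0
  expect_equal(centroid_distances(scores)$euclidean_distance, 0)

  set.seed(13)
  sc <- tibble::tibble(
    individual_id = as.character(1:60),
    species = rep(sprintf("sp%d", 1:10), each = 6),
    site = "s1",
    PC1 = rnorm(60), PC2 = rnorm(60), PC3 = rnorm(60)
  )
  d <- centroid_distances(sc)
  expect_equal(nrow(d), choose(10, 2))
  cent <- aggregate(cbind(PC1, PC2, PC3) ~ species, data = sc, FUN = mean)
  rownames(cent) <- cent$species
  for (i in sample(nrow(d), 15)) {
    v <- as.numeric(cent[d$species_a[i], 2:4]) - as.numeric(cent[d$species_b[i], 2:4])
    expect_equal(d$euclidean_distance[i], sqrt(sum(v^2)), tolerance = 1e-12)
  }
})

test_that("sites with a single species yield no pairs, not an error", {
  scores <- tibble::tibble(
    individual_id = c("1", "2"), species = c("a", "a"), site = "s1",
    PC1 = c(0, 1)
  )
  expect_equal(nrow(centroid_distances(scores)), 0)
})

test_that("full-rank PCA scores preserve Euclidean distances of centred data", {
  set.seed(21)
  m <- simulate_morphology(small_sim_config())
  ms <- pca_morphospace(m)
  x <- as.matrix(m[, morpho_traits()])
  xc <- scale(x, center = TRUE, scale = FALSE)
  sc <- as.matrix(ms$scores[, grep("^PC", names(ms$scores))])
  idx <- sample(nrow(x), 20)
  for (k in seq(2, 20, by = 2)) {
    i <- idx[k - 1]; j <- idx[k]
    expect_equal(sqrt(sum((sc[i, ] - sc[j, ])^2)),
                 sqrt(sum((xc[i, ] - xc[j, ])^2)), tolerance = 1e-9)
  }
})
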