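# Shared fixtures, built in code.

small_sim_config <- function(seed = 1, ...) {
  defaults <- list(
    n_intro_species = 40, n_native_species = 6, n_families = 10,
    n_game_families = 2, n_game_species = 6,
    n_individuals_per_species_site = 10, n_obs_per_species_site = 20,
    seed = seed
  )
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# A hand-sized morphology table: 2 species x 2 sites x 2 individuals,
# round numbers so ratios are hand-checkable.
toy_morphology <- function() {
  tibble::tibble(
    species = rep(c("spA", "spB"), each = 4),
    site = rep(rep(c("s1", "s2"), each = 2), 2),
    individual_id = sprintf("ind%02d", 1:8),
    wing_length = c(20, 20, 20, 20, 80, 80, 80, 80),
    tarsus_length = c(20, 20, 20, 20, 20, 20, 20, 20),
    culmen_length = c(10, 10, 10, 10, 12, 12, 12, 12),
    bill_width_nares = c(4, 4, 4, 4, 6, 6, 6, 6),
    bill_depth_nares = c(4, 4, 4, 4, 6, 6, 6, 6),
    mass = c(10, 10, 10, 10, 40, 40, 40, 40),
    age_class = "adult"
  )
}

# Minimal observation events with full control over flags.
toy_events <- function(n = 4) {
  tibble::tibble(
    event_id = sprintf("ev%02d", seq_len(n)),
    species = "spA",
    site = "s1",
    point_id = "p1",
    min_height = 2,
    max_height = 8,
    canopy_height_mean = 10,
    location = "interior",
    gleaning = FALSE, flycatching = FALSE,
    nectarivory = FALSE, frugivory = FALSE,
    hop = FALSE, walk = FALSE, flight = FALSE, hanging = FALSE,
    interaction_score = 0L,
    flock_size = 1L
  )
}

# Random proper distributions over k categories.
random_distributions <- function(n, k) {
  m <- matrix(rgamma(n * k, shape = 0.7), nrow = n)
  m / rowSums(m)
}

# Six-species toy introduction timeline, hand-traceable.
# nat1, nat2 native; A 1900 (established); B 1905 (failed, last seen 1910);
# C 1910; D 1910 (two same-year introductions); C established, D failed
# (last seen 1912).
toy_timeline <- function() {
  tibble::tibble(
    species = c("nat1", "nat2", "A", "B", "C", "D"),
    family = c("famN", "famN", "fam1", "fam1", "fam2", "fam3"),
    native = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    game_bird = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    introduction_years = list(
      integer(0), integer(0), 1900L, c(1905L, 1908L), 1910L, 1910L
    ),
    first_introduction_year = c(NA, NA, 1900L, 1905L, 1910L, 1910L),
    extirpation_year = c(NA, NA, NA, 1910L, NA, 1912L),
    established = c(NA, NA, TRUE, FALSE, TRUE, FALSE),
    single_individual = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)
  )
}

# Hand-built diet profiles over 2 categories for the toy timeline species.
toy_profiles_matrix <- function() {
  m <- matrix(c(
    80, 20,
    60, 40,
    50, 50,
    90, 10,
    30, 70,
    70, 30
  ), ncol = 2, byrow = TRUE,
  dimnames = list(c("nat1", "nat2", "A", "B", "C", "D"), c("c1", "c2")))
  m
}
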