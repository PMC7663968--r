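# Synthetic community generator. Emits the four canonical input tables
# (morphology, observations, niche profiles, introduction history) with
# known ground-truth parameters so every downstream stage has a
# parameter-recovery or oracle test without external data.

default_morpho_means <- function(n_species) {
  # Five passerine archetypes spanning a small nectarivore/gleaner to a
  # bulbul-sized frugivore: wing, tarsus, culmen, bill width, bill depth
  # (mm) and mass (g).
  base <- matrix(c(
    57, 17, 9.0, 3.2, 3.4, 11,
    67, 26, 11.0, 4.0, 4.4, 21,
    95, 23, 16.0, 5.5, 6.0, 42,
    90, 22, 15.0, 5.2, 5.6, 38,
    92, 30, 14.0, 4.8, 4.6, 30
  ), nrow = 5, byrow = TRUE)
  idx <- ((seq_len(n_species) - 1) %% 5) + 1
  scale <- 1 + 0.02 * ((seq_len(n_species) - 1) %/% 5)
  m <- base[idx, , drop = FALSE] * scale
  dimnames(m) <- list(
    sprintf("sp%02d", seq_len(n_species)),
    c(morpho_traits(), "mass")
  )
  m
}

default_behavior_coefs <- function() {
  list(
    gleaning = list(intercept = -5, slope = 16, ratio = "tarsus_to_wing"),
    flycatching = list(intercept = 7, slope = -29.4, ratio = "tarsus_to_wing"),
    frugivory = list(intercept = 10, slope = -13.9, ratio = "bill_slenderness"),
    nectarivory = list(intercept = -2.2, slope = 0, ratio = "tarsus_to_wing"),
    hop = list(intercept = -4.5, slope = 16.4, ratio = "tarsus_to_wing"),
    hanging = list(intercept = 1, slope = -200, ratio = "mass_kg"),
    flight = list(intercept = 0.5, slope = 0, ratio = "tarsus_to_wing"),
    walk = list(intercept = -3, slope = 0, ratio = "tarsus_to_wing")
  )
}

#' Configuration for the synthetic community generator
#'
#' Bundles and validates every parameter of the synthetic-data module. The
#' defaults emulate the scale of the motivating field system: 5 focal
#' species observed at 4 sites, behaviour probabilities on the logit scale
#' driven by site-averaged morphological ratios with slopes of the
#' magnitude reported for real novel bird communities, and an island
#' introduction history of 126 introduced plus 12 native species over
#' 1850--2000 with establishment governed by niche distinctiveness.
#'
#' @param n_species,n_sites,n_individuals_per_species_site Focal community
#'   dimensions for the morphology and observation tables.
#' @param morpho_means Per-species matrix of 6 trait means (five linear
#'   traits in mm plus mass in g); default archetypes supplied.
#' @param morpho_cov Shared 6x6 trait covariance (must be symmetric
#'   positive semi-definite).
#' @param juvenile_fraction Fraction of individuals flagged juvenile.
#' @param behavior_coefs Named list mapping each behaviour/movement flag to
#'   `list(intercept, slope, ratio)` on the logit scale; `ratio` names one
#'   of [ratio_vocabulary()]. Flags without coefficients are drawn with
#'   probability `baseline_flag_prob`.
#' @param n_obs_per_species_site Observation events per species x site.
#' @param n_points_per_site Observation points per site (each with its own
#'   mean canopy height).
#' @param baseline_flag_prob Bernoulli probability for flags without
#'   configured coefficients.
#' @param n_intro_species,n_native_species Introduction-history community
#'   size.
#' @param n_families Number of taxonomic families, the establishment
#'   model's random-intercept grouping.
#' @param n_game_families,n_game_species Game-bird structure: this many
#'   introduced species are assigned to the first `n_game_families`
#'   families and flagged as game birds.
#' @param single_individual_prob Probability an introduction is recorded
#'   as a single released individual.
#' @param n_diet_categories,n_strata_categories Niche-profile category
#'   counts (diet and foraging-stratum distributions).
#' @param dirichlet_conc,dirichlet_conc_strata Dirichlet concentration
#'   parameters (scalar or per-category vector, all > 0) for the diet and
#'   stratum profiles.
#' @param identical_profiles If `TRUE`, every species receives the same
#'   (uniform) profile — a degenerate setting for oracle tests.
#' @param timeline_span Two calendar years bounding first introductions.
#' @param estab_coefs Named length-5 vector of logit-scale establishment
#'   coefficients: `intercept`, `richness`, `years`, `ps_diet`, `ps_for`.
#' @param family_sd SD of the per-family normal random intercept.
#' @param mean_extra_intro_years Poisson mean of additional introduction
#'   years beyond the first.
#' @param extirpation_lag_range Years after introduction at which a failed
#'   introduction is last reported (uniform over this integer range; the
#'   minimum of 1 keeps same-year incumbency well defined).
#' @param seed Integer seed; every simulate_* operation derives its stream
#'   from it, so a fixed seed fixes every emitted table exactly.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_species = 5,
                       n_sites = 4,
                       n_individuals_per_species_site = 20,
                       morpho_means = default_morpho_means(n_species),
                       morpho_cov = diag(c(2, 0.8, 0.5, 0.2, 0.2, 1.5)^2),
                       juvenile_fraction = 0,
                       behavior_coefs = default_behavior_coefs(),
                       n_obs_per_species_site = 35,
                       n_points_per_site = 11,
                       baseline_flag_prob = 0.2,
                       n_intro_species = 126,
                       n_native_species = 12,
                       n_families = 35,
                       n_game_families = 3,
                       n_game_species = 20,
                       single_individual_prob = 0.05,
                       n_diet_categories = 10,
                       n_strata_categories = 7,
                       dirichlet_conc = 0.5,
                       dirichlet_conc_strata = 0.8,
                       identical_profiles = FALSE,
                       timeline_span = c(1850, 2000),
                       estab_coefs = c(intercept = 2.6, richness = -0.028,
                                       years = 0.013, ps_diet = -6.649,
                                       ps_for = 1.131),
                       family_sd = 0.5,
                       mean_extra_intro_years = 0.7,
                       extirpation_lag_range = c(1, 30),
                       seed = 1L) {
  counts <- c(n_species = n_species, n_sites = n_sites,
              n_individuals_per_species_site = n_individuals_per_species_site,
              n_obs_per_species_site = n_obs_per_species_site,
              n_points_per_site = n_points_per_site,
              n_intro_species = n_intro_species,
              n_families = n_families,
              n_diet_categories = n_diet_categories,
              n_strata_categories = n_strata_categories)
  if (any(counts < 1)) {
    stop("configuration error: counts must be >= 1 (",
         paste(names(counts)[counts < 1], collapse = ", "), ")", call. = FALSE)
  }
  if (!is.matrix(morpho_means) || ncol(morpho_means) != 6 ||
      nrow(morpho_means) != n_species) {
    stop("configuration error: morpho_means must be an n_species x 6 matrix",
         call. = FALSE)
  }
  if (any(morpho_means <= 0)) {
    stop("configuration error: trait means must be positive", call. = FALSE)
  }
  if (!isSymmetric(unname(morpho_cov)) ||
      any(eigen(morpho_cov, symmetric = TRUE, only.values = TRUE)$values <
            -1e-8 * max(1, max(abs(morpho_cov))))) {
    stop("configuration error: morpho_cov must be symmetric positive semi-definite",
         call. = FALSE)
  }
  if (any(c(dirichlet_conc, dirichlet_conc_strata) <= 0)) {
    stop("configuration error: Dirichlet concentrations must be > 0",
         call. = FALSE)
  }
  vocab <- c(behavior_vocabulary(), movement_vocabulary())
  bad_flags <- setdiff(names(behavior_coefs), vocab)
  if (length(bad_flags) > 0) {
    stop("configuration error: behaviour(s) not in the vocabulary: ",
         paste(bad_flags, collapse = ", "), call. = FALSE)
  }
  bad_ratio <- vapply(behavior_coefs,
                      function(b) !b$ratio %in% ratio_vocabulary(), logical(1))
  if (any(bad_ratio)) {
    stop("configuration error: unknown ratio predictor for: ",
         paste(names(behavior_coefs)[bad_ratio], collapse = ", "),
         call. = FALSE)
  }
  if (length(timeline_span) != 2 || timeline_span[1] > timeline_span[2]) {
    stop("configuration error: timeline_span must be (start_year, end_year)",
         call. = FALSE)
  }
  needed <- c("intercept", "richness", "years", "ps_diet", "ps_for")
  if (!all(needed %in% names(estab_coefs))) {
    stop("configuration error: estab_coefs must be named ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  if (family_sd < 0) {
    stop("configuration error: family_sd must be non-negative", call. = FALSE)
  }
  if (extirpation_lag_range[1] < 1) {
    stop("configuration error: extirpation lag must be at least 1 year",
         call. = FALSE)
  }
  structure(
    list(
      n_species = n_species, n_sites = n_sites,
      n_individuals_per_species_site = n_individuals_per_species_site,
      morpho_means = morpho_means, morpho_cov = morpho_cov,
      juvenile_fraction = juvenile_fraction,
      behavior_coefs = behavior_coefs,
      n_obs_per_species_site = n_obs_per_species_site,
      n_points_per_site = n_points_per_site,
      baseline_flag_prob = baseline_flag_prob,
      n_intro_species = n_intro_species,
      n_native_species = n_native_species,
      n_families = n_families, n_game_families = n_game_families,
      n_game_species = n_game_species,
      single_individual_prob = single_individual_prob,
      n_diet_categories = n_diet_categories,
      n_strata_categories = n_strata_categories,
      dirichlet_conc = dirichlet_conc,
      dirichlet_conc_strata = dirichlet_conc_strata,
      identical_profiles = identical_profiles,
      timeline_span = timeline_span,
      estab_coefs = estab_coefs, family_sd = family_sd,
      mean_extra_intro_years = mean_extra_intro_years,
      extirpation_lag_range = extirpation_lag_range,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

site_codes <- function(cfg) sprintf("site%d", seq_len(cfg$n_sites))

#' Simulate individual morphology records
#'
#' Draws individuals from a per-species multivariate normal over the five
#' linear traits plus mass, with the shared covariance from the
#' configuration. Draws containing non-positive measurements are resampled
#' (rather than truncated) so the emitted distribution stays multivariate
#' normal conditioned on positivity.
#'
#' @param cfg A [sim_config()].
#' @param seed Seed for this operation; defaults to `cfg$seed`.
#' @return A morphology tibble, one row per individual.
#' @export
simulate_morphology <- function(cfg, seed = cfg$seed) {
  set.seed(seed)
  sites <- site_codes(cfg)
  n_per_sp <- cfg$n_sites * cfg$n_individuals_per_species_site
  draw_species <- function(mu) {
    x <- MASS::mvrnorm(n_per_sp, mu, cfg$morpho_cov)
    if (n_per_sp == 1) x <- matrix(x, nrow = 1)
    for (tries in seq_len(1000)) {
      bad <- which(apply(x, 1, function(r) any(r <= 0)))
      if (length(bad) == 0) break
      x[bad, ] <- MASS::mvrnorm(length(bad), mu, cfg$morpho_cov)
    }
    if (any(x <= 0)) {
      stop("could not draw positive measurements; check means vs covariance",
           call. = FALSE)
    }
    x
  }
  rows <- lapply(rownames(cfg$morpho_means), function(sp) {
    x <- draw_species(cfg$morpho_means[sp, ])
    tibble::tibble(
      species = sp,
      site = rep(sites, each = cfg$n_individuals_per_species_site),
      individual_id = sprintf("%s_%s_%03d", sp,
                              rep(sites, each = cfg$n_individuals_per_species_site),
                              unlist(lapply(sites, function(s)
                                seq_len(cfg$n_individuals_per_species_site)))),
      wing_length = x[, 1], tarsus_length = x[, 2], culmen_length = x[, 3],
      bill_width_nares = x[, 4], bill_depth_nares = x[, 5], mass = x[, 6]
    )
  })
  out <- dplyr::bind_rows(rows)
  out$age_class <- ifelse(runif(nrow(out)) < cfg$juvenile_fraction,
                          "juvenile", "adult")
  out
}

#' Simulate foraging/movement observation events
#'
#' Generates observation events per species x site. Each behaviour or
#' movement flag is drawn Bernoulli with
#' `logit p = intercept + slope * ratio`, where the ratio value is the
#' species' site-averaged morphological ratio supplied in
#' `morpho_site_means` — the same site-averaged table the analysis path
#' uses, so configured slopes are recoverable by the behaviour models.
#' Events can carry several true flags at once. Relative heights are drawn
#' from a beta-based distribution allowing supra-canopy values, then
#' multiplied by the per-point mean canopy height so raw and canopy heights
#' are both emitted.
#'
#' @param cfg A [sim_config()].
#' @param morpho_site_means Site-averaged ratio table from
#'   [compute_ratios()]; must cover every species x site simulated.
#' @param seed Seed for this operation; defaults to `cfg$seed + 1`.
#' @return An observation-event tibble.
#' @export
simulate_observations <- function(cfg, morpho_site_means, seed = cfg$seed + 1) {
  set.seed(seed)
  vocab <- c(behavior_vocabulary(), movement_vocabulary())
  ratios <- dplyr::mutate(morpho_site_means, mass_kg = .data$mass_mean / 1000)
  ratios <- dplyr::arrange(ratios, .data$species, .data$site)
  # fixed per-point canopy heights, per site
  canopy <- lapply(site_codes(cfg), function(s) {
    stats::setNames(rlnorm(cfg$n_points_per_site, log(10), 0.25),
                    sprintf("%s_pt%02d", s, seq_len(cfg$n_points_per_site)))
  })
  names(canopy) <- site_codes(cfg)
  n <- cfg$n_obs_per_species_site
  parts <- lapply(seq_len(nrow(ratios)), function(i) {
    r <- ratios[i, ]
    pts <- sample(names(canopy[[r$site]]), n, replace = TRUE)
    ch <- canopy[[r$site]][pts]
    rel_max <- rbeta(n, 2.2, 1.6) * 1.3
    rel_min <- rel_max * rbeta(n, 2, 1.2)
    ev <- tibble::tibble(
      species = r$species, site = r$site, point_id = pts,
      min_height = rel_min * ch, max_height = rel_max * ch,
      canopy_height_mean = unname(ch),
      location = sample(location_levels(), n, replace = TRUE,
                        prob = c(0.5, 0.4, 0.08, 0.02))
    )
    for (flag in vocab) {
      b <- cfg$behavior_coefs[[flag]]
      p <- if (is.null(b)) {
        cfg$baseline_flag_prob
      } else {
        plogis(b$intercept + b$slope * r[[b$ratio]])
      }
      ev[[flag]] <- rbinom(n, 1, p) == 1
    }
    ev$interaction_score <- sample(0:4, n, replace = TRUE,
                                   prob = c(0.3, 0.25, 0.2, 0.15, 0.1))
    single <- runif(n) < 0.69
    ev$flock_size <- ifelse(single, 1L,
                            sample(2:10, n, replace = TRUE, prob = 9:1))
    ev
  })
  out <- dplyr::bind_rows(parts)
  out$event_id <- sprintf("ev%05d", seq_len(nrow(out)))
  dplyr::relocate(out, "event_id")
}

# Dirichlet draw scaled to percentages summing to 100.
rdirichlet_pct <- function(n, conc, n_cat) {
  conc <- rep_len(conc, n_cat)
  g <- matrix(rgamma(n * n_cat, shape = conc), nrow = n, byrow = TRUE)
  100 * g / rowSums(g)
}

diet_category_labels <- function(n) {
  std <- c("Inv", "Vend", "Vect", "Vfish", "Vunk", "Scav", "Fruit", "Nect",
           "Seed", "PlantO")
  if (n == length(std)) std else sprintf("diet%02d", seq_len(n))
}

strata_category_labels <- function(n) {
  std <- c("WatBelowSurf", "WatAroundSurf", "Ground", "Understory",
           "MidHigh", "Canopy", "Aerial")
  if (n == length(std)) std else sprintf("stratum%02d", seq_len(n))
}

profile_matrix_to_long <- function(m, kind, certainty) {
  tibble::tibble(
    species = rep(rownames(m), each = ncol(m)),
    profile_kind = kind,
    category = rep(colnames(m), times = nrow(m)),
    percent = as.vector(t(m)),
    certainty = rep(certainty, each = ncol(m))
  )
}

#' Simulate an island introduction history with niche profiles
#'
#' Assigns every species (native and introduced) Dirichlet-distributed diet
#' and foraging-stratum percentage profiles, draws first introduction years
#' across the configured timeline, and walks the timeline in arrival order.
#' For each introduction it computes incumbent richness, the number of
#' introduction years, and the mean diet/stratum PS against the current
#' incumbent community — through the very same [incumbent_community()] and
#' PS code the analysis path uses — then draws establishment from the
#' configured logit-scale coefficients plus a per-family normal random
#' intercept. Failed introductions receive an extirpation (last-report)
#' year. Native species are seeded as incumbents from the start of the
#' timeline.
#'
#' @param cfg A [sim_config()].
#' @param seed Seed for this operation; defaults to `cfg$seed + 2`.
#' @return A list with `introductions` (introduction-record tibble),
#'   `profiles` (long niche-profile tibble covering both kinds),
#'   `features` (the ground-truth feature table used for the establishment
#'   draws), and `truth` (configured coefficients and realised family
#'   effects).
#' @export
simulate_invasion_history <- function(cfg, seed = cfg$seed + 2) {
  set.seed(seed)
  n_nat <- cfg$n_native_species
  n_int <- cfg$n_intro_species
  if (n_nat + n_int < 2) {
    stop("configuration error: need at least 2 species to compare against",
         call. = FALSE)
  }
  natives <- if (n_nat > 0) sprintf("nat%02d", seq_len(n_nat)) else character(0)
  intros <- sprintf("int%03d", seq_len(n_int))
  all_sp <- c(natives, intros)

  fams <- sprintf("fam%02d", seq_len(cfg$n_families))
  game_fams <- fams[seq_len(min(cfg$n_game_families, cfg$n_families))]
  other_fams <- setdiff(fams, game_fams)
  if (length(other_fams) == 0) other_fams <- fams
  n_game <- min(cfg$n_game_species, n_int)
  game_sp <- if (n_game > 0) sample(intros, n_game) else character(0)
  family_of <- stats::setNames(character(length(all_sp)), all_sp)
  family_of[natives] <- sample(other_fams, n_nat, replace = TRUE)
  family_of[setdiff(intros, game_sp)] <-
    sample(other_fams, n_int - n_game, replace = TRUE)
  family_of[game_sp] <- sample(game_fams, n_game, replace = TRUE)

  n_all <- length(all_sp)
  if (cfg$identical_profiles) {
    diet <- matrix(100 / cfg$n_diet_categories, n_all, cfg$n_diet_categories)
    strata <- matrix(100 / cfg$n_strata_categories, n_all,
                     cfg$n_strata_categories)
  } else {
    diet <- rdirichlet_pct(n_all, cfg$dirichlet_conc, cfg$n_diet_categories)
    strata <- rdirichlet_pct(n_all, cfg$dirichlet_conc_strata,
                             cfg$n_strata_categories)
  }
  dimnames(diet) <- list(all_sp, diet_category_labels(cfg$n_diet_categories))
  dimnames(strata) <- list(all_sp,
                           strata_category_labels(cfg$n_strata_categories))
  certainty <- sample(c("A", "B", "C", "D1"), n_all, replace = TRUE,
                      prob = c(0.86, 0.05, 0.02, 0.07))
  names(certainty) <- all_sp

  span <- cfg$timeline_span
  first_year <- sample(seq(span[1], span[2]), n_int, replace = TRUE)
  intro_years <- lapply(seq_len(n_int), function(i) {
    extra <- rpois(1, cfg$mean_extra_intro_years)
    later <- seq(first_year[i], span[2])
    yrs <- c(first_year[i],
             if (extra > 0 && length(later) > 1)
               sample(later[-1], min(extra, length(later) - 1)))
    sort(unique(yrs))
  })
  single_ind <- runif(n_int) < cfg$single_individual_prob
  fam_eff <- stats::setNames(rnorm(cfg$n_families, 0, cfg$family_sd), fams)

  records <- tibble::tibble(
    species = all_sp,
    family = unname(family_of[all_sp]),
    native = all_sp %in% natives,
    game_bird = all_sp %in% game_sp,
    introduction_years = c(replicate(n_nat, integer(0), simplify = FALSE),
                           intro_years),
    first_introduction_year = c(rep(NA_integer_, n_nat), first_year),
    extirpation_year = NA_integer_,
    established = NA,
    single_individual = c(rep(FALSE, n_nat), single_ind)
  )
  records$established[records$native] <- NA

  psd <- ps_matrix(diet)
  psf <- ps_matrix(strata)
  b <- cfg$estab_coefs
  ord <- order(records$first_introduction_year, records$species)
  ord <- ord[!records$native[ord]]
  feats <- vector("list", length(ord))
  for (k in seq_along(ord)) {
    i <- ord[k]
    sp <- records$species[i]
    fr <- feature_row(
      records, sp, records$first_introduction_year[i],
      records$introduction_years[[i]], psd, psf,
      boundary = "inclusive", count_unprofiled = TRUE,
      family = records$family[i], established = NA,
      game_bird = records$game_bird[i],
      single_individual = records$single_individual[i]
    )
    lp <- b["intercept"] +
      b["richness"] * fr$incumbent_richness +
      b["years"] * fr$n_introduction_years +
      b["ps_diet"] * ifelse(is.na(fr$mean_ps_diet), 0, fr$mean_ps_diet) +
      b["ps_for"] * ifelse(is.na(fr$mean_ps_for), 0, fr$mean_ps_for) +
      fam_eff[records$family[i]]
    est <- rbinom(1, 1, plogis(lp)) == 1
    records$established[i] <- est
    if (!est) {
      lag <- sample(seq(cfg$extirpation_lag_range[1],
                        cfg$extirpation_lag_range[2]), 1)
      records$extirpation_year[i] <-
        records$first_introduction_year[i] + lag
    }
    fr$established <- est
    feats[[k]] <- fr
  }

  profiles <- dplyr::bind_rows(
    profile_matrix_to_long(diet, "diet", certainty),
    profile_matrix_to_long(strata, "foraging_stratum", certainty)
  )
  list(
    introductions = records,
    profiles = profiles,
    features = dplyr::bind_rows(feats),
    truth = list(
      estab_coefs = b,
      family_sd = cfg$family_sd,
      family_effects = tibble::tibble(family = fams, effect = unname(fam_eff)),
      seed = seed
    )
  )
}

#' Simulate a complete synthetic community
#'
#' Runs the full generator: morphology, site-averaged ratios, observation
#' events driven by those ratios, the introduction history with niche
#' profiles, and additional diet/stratum profiles for the focal
#' (morphology) species so that community-wide similarity-versus-distance
#' analyses have matching inputs.
#'
#' @param cfg A [sim_config()].
#' @return A list with `config`, `morphology`, `ratios`, `observations`,
#'   `profiles` (invasion + focal species), `introductions`, `features`
#'   (ground-truth establishment features), and `truth` (all configured
#'   coefficients).
#' @export
simulate_community <- function(cfg = sim_config()) {
  morphology <- simulate_morphology(cfg)
  ratios <- compute_ratios(morphology)
  observations <- simulate_observations(cfg, ratios)
  invasion <- simulate_invasion_history(cfg)

  set.seed(cfg$seed + 3)
  focal_sp <- rownames(cfg$morpho_means)
  if (cfg$identical_profiles) {
    fd <- matrix(100 / cfg$n_diet_categories, length(focal_sp),
                 cfg$n_diet_categories)
    fs <- matrix(100 / cfg$n_strata_categories, length(focal_sp),
                 cfg$n_strata_categories)
  } else {
    fd <- rdirichlet_pct(length(focal_sp), cfg$dirichlet_conc,
                         cfg$n_diet_categories)
    fs <- rdirichlet_pct(length(focal_sp), cfg$dirichlet_conc_strata,
                         cfg$n_strata_categories)
  }
  dimnames(fd) <- list(focal_sp, diet_category_labels(cfg$n_diet_categories))
  dimnames(fs) <- list(focal_sp,
                       strata_category_labels(cfg$n_strata_categories))
  focal_cert <- rep("A", length(focal_sp))
  profiles <- dplyr::bind_rows(
    invasion$profiles,
    profile_matrix_to_long(fd, "diet", focal_cert),
    profile_matrix_to_long(fs, "foraging_stratum", focal_cert)
  )

  list(
    config = cfg,
    morphology = morphology,
    ratios = ratios,
    observations = observations,
    profiles = profiles,
    introductions = invasion$introductions,
    features = invasion$features,
    truth = c(invasion$truth,
              list(behavior_coefs = cfg$behavior_coefs, seed = cfg$seed))
  )
}

#' Write the four canonical tables plus a ground-truth sidecar
#'
#' Serialises a simulated community to the delimited-text schemas the
#' ingest module reads back, alongside a JSON sidecar holding every true
#' coefficient for parameter-recovery tests.
#'
#' @param sim Result of [simulate_community()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_community_tables <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    morphology = file.path(dir, "morphology.csv"),
    observations = file.path(dir, "observations.csv"),
    niche_profiles = file.path(dir, "niche_profiles.csv"),
    introductions = file.path(dir, "introductions.csv"),
    ground_truth = file.path(dir, "ground_truth.json")
  )
  write_morphology(sim$morphology, paths["morphology"])
  write_observations(sim$observations, paths["observations"])
  write_niche_profiles(sim$profiles, paths["niche_profiles"])
  write_introductions(sim$introductions, paths["introductions"])
  truth <- sim$truth
  truth$estab_coefs <- as.list(truth$estab_coefs)
  truth$features <- sim$features
  jsonlite::write_json(truth, paths["ground_truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
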