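# End-to-end orchestration: simulate or ingest, derive analysis variables,
# fit the model suite, and emit a deterministic, reproducible bundle.

#' Configuration for a pipeline run
#'
#' Exactly one data source is active per run: either the synthetic
#' generator (`sim`) or a set of file `paths` naming the four input tables
#' (`morphology`, `observations`, `niche_profiles`, `introductions`).
#' The remaining switches select the documented module conventions.
#'
#' @param sim A [sim_config()], or `NULL` when reading files.
#' @param paths Named list of the four table paths, or `NULL` when
#'   simulating.
#' @param behavior_denominator Behaviour-frequency normalisation
#'   (see [behavior_distribution()]).
#' @param extirpation_boundary Incumbency boundary convention
#'   (see [incumbent_community()]).
#' @param pca_standardize,pca_include_mass Morphospace options
#'   (see [pca_morphospace()]).
#' @param bill_area Bill cross-section approximation
#'   (see [compute_ratios()]).
#' @param drop_single_individual Establishment-model exclusion switch.
#' @param foraging_exclude_species Species excluded from the
#'   foraging-behaviour models and the within-site PS-versus-distance
#'   model (species too rarely observed foraging to characterise).
#' @param strict Strict ingest validation (files mode).
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       paths = NULL,
                       behavior_denominator = c("occurrences", "events"),
                       extirpation_boundary = c("inclusive", "strict"),
                       pca_standardize = FALSE,
                       pca_include_mass = FALSE,
                       bill_area = c("ellipse", "rectangle"),
                       drop_single_individual = TRUE,
                       foraging_exclude_species = character(0),
                       strict = TRUE) {
  if (is.null(sim) == is.null(paths)) {
    stop("exactly one of 'sim' or 'paths' must be given", call. = FALSE)
  }
  if (!is.null(paths)) {
    need <- c("morphology", "observations", "niche_profiles", "introductions")
    miss <- setdiff(need, names(paths))
    if (length(miss) > 0) {
      stop("paths must name the four tables; missing: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(
      sim = sim, paths = paths,
      behavior_denominator = match.arg(behavior_denominator),
      extirpation_boundary = match.arg(extirpation_boundary),
      pca_standardize = pca_standardize,
      pca_include_mass = pca_include_mass,
      bill_area = match.arg(bill_area),
      drop_single_individual = drop_single_individual,
      foraging_exclude_species = foraging_exclude_species,
      strict = strict
    ),
    class = "run_config"
  )
}

collect_fits <- function(fits) {
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    co <- f$coefficients
    co$model <- nm
    co$family <- f$family
    co$n_obs <- f$n_obs
    co$converged <- f$converged
    co
  })
  out <- dplyr::bind_rows(rows)
  dplyr::relocate(out, "model")
}

#' Run the full analysis pipeline
#'
#' Orchestrates an end-to-end run: obtain the four input tables (synthetic
#' or from files), compute site-averaged ratios, the PCA morphospace and
#' species-centroid distances, relative heights, behaviour distributions
#' and response vectors, all pairwise PS tables, the incumbent-community
#' feature table, and the whole model suite (registered
#' behaviour-versus-morphology models, the two height models, the
#' within-site and community-wide PS-versus-distance models, and the
#' establishment model under both exclusion modes). Any stage failure
#' aborts with the stage named in the error.
#'
#' Results are deterministic given the configuration (all randomness flows
#' from the simulator seed): running the same configuration twice produces
#' identical bundles, and identical output files when `out_dir` is set.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory; when given, every derived
#'   table, the coefficient table, and a provenance record (configuration
#'   plus package version) are written as delimited text/JSON.
#' @return A list bundle with the input tables, derived tables, `fits`
#'   (named `ecofit_result` objects), `coefficients` (tidy coefficient
#'   table across fits), and `provenance`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$sim)) {
    sim <- with_stage("simulate", simulate_community(config$sim))
    morphology <- sim$morphology
    observations <- sim$observations
    profiles <- sim$profiles
    introductions <- sim$introductions
  } else {
    morphology <- with_stage("ingest",
                             read_morphology(config$paths$morphology,
                                             strict = config$strict))
    observations <- with_stage("ingest",
                               read_observations(config$paths$observations,
                                                 strict = config$strict))
    profiles <- with_stage("ingest",
                           read_niche_profiles(config$paths$niche_profiles,
                                               strict = config$strict))
    introductions <- with_stage("ingest",
                                read_introductions(config$paths$introductions,
                                                   strict = config$strict))
  }

  ratios <- with_stage("morphometrics",
                       compute_ratios(morphology, bill_area = config$bill_area))
  morphospace <- with_stage("morphometrics",
                            pca_morphospace(morphology,
                                            include_mass = config$pca_include_mass,
                                            standardize = config$pca_standardize))
  dist_site <- with_stage("morphometrics",
                          centroid_distances(morphospace, "species_site"))
  dist_species <- with_stage("morphometrics",
                             centroid_distances(morphospace, "species"))

  heights <- with_stage("foraging", relative_heights(observations))
  responses <- with_stage("foraging", response_vectors(observations))
  excl <- config$foraging_exclude_species
  behav_dist <- with_stage("foraging", suppressWarnings(
    behavior_distribution(observations,
                          denominator = config$behavior_denominator)
  ))

  ps_behavior <- with_stage("similarity", pairwise_ps(behav_dist))
  ps_profiles <- with_stage("similarity", pairwise_ps(profiles))
  ps_diet <- ps_profiles[ps_profiles$kind == "diet", , drop = FALSE]
  ps_for <- ps_profiles[ps_profiles$kind == "foraging_stratum", , drop = FALSE]

  features <- with_stage("assembly", build_features(
    introductions, ps_diet, ps_for,
    boundary = config$extirpation_boundary
  ))

  fits <- list()
  registry <- model_registry()
  for (i in seq_len(nrow(registry))) {
    r <- registry[i, ]
    nm <- paste0("p", r$prediction, "_", r$response)
    if (r$family == "gaussian") {
      which_h <- if (r$response == "rel_max_height") "max" else "min"
      fits[[nm]] <- with_stage("inference", fit_height_model(
        heights, ratios, predictors = r$predictors[[1]], which = which_h
      ))
    } else {
      # foraging behaviours exclude the configured rarely-foraging species
      is_foraging <- r$response %in% behavior_vocabulary()
      fits[[nm]] <- with_stage("inference", fit_behavior_model(
        responses, ratios, r$response, r$predictors[[1]],
        exclude_species = if (is_foraging) excl else NULL
      ))
    }
  }
  fits[["ps_vs_distance_focal"]] <- with_stage("inference", fit_ps_vs_distance(
    ps_behavior, dist_site, exclude_species = excl
  ))
  morph_species <- unique(morphology$species)
  ps_diet_morph <- ps_diet[ps_diet$species_a %in% morph_species &
                             ps_diet$species_b %in% morph_species, ,
                           drop = FALSE]
  fits[["ps_vs_distance_community"]] <- with_stage(
    "inference", fit_ps_vs_distance(ps_diet_morph, dist_species)
  )
  fits[["establishment_all"]] <- with_stage("inference", fit_establishment_model(
    features, mode = "all",
    drop_single_individual = config$drop_single_individual
  ))
  fits[["establishment_no_gamebirds"]] <- with_stage(
    "inference", fit_establishment_model(
      features, mode = "no_gamebirds",
      drop_single_individual = config$drop_single_individual
    )
  )

  flat_fits <- list()
  for (nm in names(fits)) {
    f <- fits[[nm]]
    if (inherits(f, "ecofit_result")) {
      flat_fits[[nm]] <- f
    } else {
      for (sub in names(f)) flat_fits[[paste0(nm, "_", sub)]] <- f[[sub]]
    }
  }
  coefficients <- collect_fits(flat_fits)

  provenance <- list(
    package = "ecofitr",
    version = as.character(utils::packageVersion("ecofitr")),
    mode = if (is.null(config$sim)) "files" else "simulate",
    seed = if (is.null(config$sim)) NA_integer_ else config$sim$seed,
    options = config[c("behavior_denominator", "extirpation_boundary",
                       "pca_standardize", "pca_include_mass", "bill_area",
                       "drop_single_individual",
                       "foraging_exclude_species")]
  )

  bundle <- list(
    morphology = morphology, observations = observations,
    profiles = profiles, introductions = introductions,
    ratios = ratios, morphospace = morphospace,
    distances_site = dist_site, distances_species = dist_species,
    relative_heights = heights, responses = responses,
    behavior_distributions = behav_dist,
    ps_behavior = ps_behavior, ps_profiles = ps_profiles,
    features = features,
    fits = flat_fits, coefficients = coefficients,
    provenance = provenance
  )

  if (!is.null(out_dir)) {
    with_stage("report", write_bundle(bundle, out_dir))
  }
  bundle
}

#' Write a pipeline bundle to disk
#'
#' Emits every derived table as CSV, the PCA loadings for audit, the tidy
#' coefficient table, and a provenance JSON (configuration, seed, package
#' version). Output is deterministic: identical bundles produce
#' byte-identical files.
#'
#' @param bundle A bundle from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the output directory.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) readr::write_csv(df, file.path(out_dir, name))
  w(bundle$ratios, "ratios.csv")
  w(bundle$distances_site, "centroid_distances_site.csv")
  w(bundle$distances_species, "centroid_distances_species.csv")
  w(bundle$behavior_distributions, "behavior_distributions.csv")
  w(bundle$ps_behavior, "ps_behavior.csv")
  w(bundle$ps_profiles, "ps_profiles.csv")
  w(bundle$features, "introduction_features.csv")
  w(bundle$coefficients, "model_coefficients.csv")
  loadings <- tibble::as_tibble(bundle$morphospace$loadings, rownames = "trait")
  w(loadings, "pca_loadings.csv")
  ve <- tibble::tibble(
    component = paste0("PC", seq_along(bundle$morphospace$var_explained)),
    var_explained = bundle$morphospace$var_explained
  )
  w(ve, "pca_variance_explained.csv")
  jsonlite::write_json(bundle$provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
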