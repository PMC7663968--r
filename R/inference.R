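# Model suite: binomial GLMMs of behaviour against site-averaged
# morphology, gaussian mixed models of relative height, the quasibinomial
# similarity-versus-distance model, and the binomial establishment GLMM.
#
# Estimation follows standard defaults: Laplace-approximated ML for
# binomial GLMMs (Wald z statistics), REML with Satterthwaite degrees of
# freedom for the gaussian height models (t statistics), and IRLS with a
# moment-estimated dispersion for the quasibinomial GLM (t statistics on
# residual df). Mass enters every model in kilograms (`mass_kg`) so that
# coefficient magnitudes are on the conventional reporting scale.

new_fit_result <- function(coefficients, family, n_obs, n_groups = list(),
                           converged = TRUE, singular = FALSE,
                           dispersion = NA_real_, note = NULL, model = NULL) {
  structure(
    list(
      coefficients = coefficients,
      family = family,
      n_obs = n_obs,
      n_groups = n_groups,
      converged = converged,
      singular = singular,
      dispersion = dispersion,
      note = note,
      model = model
    ),
    class = "ecofit_result"
  )
}

#' @export
print.ecofit_result <- function(x, ...) {
  cat("Model fit (", x$family, "), n = ", x$n_obs, sep = "")
  if (length(x$n_groups) > 0) {
    cat("; groups: ",
        paste(names(x$n_groups), unlist(x$n_groups), sep = "=", collapse = ", "),
        sep = "")
  }
  cat("\n")
  if (!x$converged) cat("** fit did not converge cleanly **\n")
  if (x$singular) cat("** singular random-effect fit (variance at 0) **\n")
  print(as.data.frame(x$coefficients), digits = 4, row.names = FALSE)
  if (!is.na(x$dispersion)) cat("Dispersion:", format(x$dispersion, digits = 4), "\n")
  if (!is.null(x$note)) cat(x$note, "\n")
  invisible(x)
}

#' Coefficient table of a fit result
#'
#' @param x An `ecofit_result`.
#' @param ... Unused.
#' @return The coefficient tibble (`term`, `estimate`, `se`, `statistic`,
#'   `df`, `p_value`).
#' @export
coef_table <- function(x, ...) {
  stopifnot(inherits(x, "ecofit_result"))
  x$coefficients
}

# Fit a model while recording convergence/singularity diagnostics.
fit_quietly <- function(expr) {
  warnings <- character(0)
  fit <- withCallingHandlers(
    expr,
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) invokeRestart("muffleMessage")
  )
  # scale-diagnostic advisories ("Rescale variables?") are kept as notes;
  # only genuine optimizer failures clear the converged flag
  conv_bad <- any(grepl("failed to converge|convergence code|pwrssUpdate",
                        warnings, ignore.case = TRUE))
  list(fit = fit, converged = !conv_bad, warnings = warnings)
}

glmer_result <- function(formula, data, note = NULL) {
  res <- fit_quietly(
    lme4::glmer(formula, data = data, family = stats::binomial())
  )
  fit <- res$fit
  sm <- summary(fit)$coefficients
  coefs <- tibble::tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    se = sm[, "Std. Error"],
    statistic = sm[, "z value"],
    df = NA_real_,
    p_value = sm[, "Pr(>|z|)"]
  )
  ngrp <- as.list(lme4::ngrps(fit))
  new_fit_result(coefs, "binomial", n_obs = stats::nobs(fit),
                 n_groups = ngrp, converged = res$converged,
                 singular = lme4::isSingular(fit), note = note, model = fit)
}

check_model_data <- function(df, response, predictors) {
  if (nrow(df) == 0) {
    stop("no data rows available for response '", response, "'", call. = FALSE)
  }
  for (p in predictors) {
    v <- df[[p]]
    if (max(v) == min(v)) {
      stop("predictor '", p, "' is constant; model cannot be fitted",
           call. = FALSE)
    }
  }
  if (length(unique(df$site)) < 2 || length(unique(df$species)) < 2) {
    stop("need at least 2 sites and 2 species to fit the mixed model",
         call. = FALSE)
  }
  invisible(df)
}

join_predictors <- function(responses, ratios, predictors) {
  ratios <- dplyr::mutate(ratios, mass_kg = .data$mass_mean / 1000)
  bad <- setdiff(predictors, ratio_vocabulary())
  if (length(bad) > 0) {
    stop("unknown predictor(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  dplyr::inner_join(responses,
                    ratios[, c("species", "site", predictors), drop = FALSE],
                    by = c("species", "site"))
}

#' Fit a behaviour-versus-morphology binomial mixed model
#'
#' Fits the probability of observing a behaviour (per event) against
#' site-averaged morphological ratios, with random intercepts for site and
#' species and a binomial error distribution (Laplace-approximated ML).
#' Wald z statistics and normal-tail p-values are reported.
#'
#' @param responses Event-level 0/1 response tibble from
#'   [response_vectors()].
#' @param ratios Site-averaged ratio table from [compute_ratios()].
#' @param response Name of the response column (e.g. `"gleaning"`).
#' @param predictors Character vector of predictors among
#'   [ratio_vocabulary()].
#' @param exclude_species Species codes to drop before fitting (e.g. a
#'   species observed foraging too rarely to characterise).
#' @return An `ecofit_result`. Non-convergence or a singular
#'   random-effect fit is flagged on the result, never silent.
#' @export
fit_behavior_model <- function(responses, ratios, response, predictors,
                               exclude_species = NULL) {
  df <- join_predictors(responses, ratios, predictors)
  df <- df[!df$species %in% exclude_species, , drop = FALSE]
  df <- df[!is.na(df[[response]]), , drop = FALSE]
  check_model_data(df, response, predictors)
  form <- stats::as.formula(paste(
    response, "~", paste(predictors, collapse = " + "),
    "+ (1 | site) + (1 | species)"
  ))
  glmer_result(form, df)
}

#' Fit the relative-height linear mixed models
#'
#' Fits canopy-relative observation height against morphology with random
#' intercepts for site and species (REML). Satterthwaite-approximated
#' degrees of freedom and t statistics are reported; the fractional df are
#' approximation-dependent. Separate fits for the maximum and minimum
#' height of each observation. If the mixed model cannot be fitted (e.g.
#' degenerate grouping), the fit degrades to ordinary least squares with a
#' warning.
#'
#' @param heights Relative-height tibble from [relative_heights()].
#' @param ratios Site-averaged ratio table.
#' @param predictors Predictors among [ratio_vocabulary()]; default
#'   tarsus-to-wing ratio and mass (kg).
#' @param which `"both"` (default, returns a named list), `"max"`, or
#'   `"min"`.
#' @param exclude_species Species codes to drop before fitting.
#' @return An `ecofit_result`, or a list with elements `max` and `min`.
#' @export
fit_height_model <- function(heights, ratios,
                             predictors = c("tarsus_to_wing", "mass_kg"),
                             which = c("both", "max", "min"),
                             exclude_species = NULL) {
  which <- match.arg(which)
  df <- join_predictors(heights, ratios, predictors)
  df <- df[!df$species %in% exclude_species, , drop = FALSE]
  fit_one <- function(response) {
    sub <- df[!is.na(df[[response]]), , drop = FALSE]
    check_model_data(sub, response, predictors)
    form <- stats::as.formula(paste(
      response, "~", paste(predictors, collapse = " + "),
      "+ (1 | site) + (1 | species)"
    ))
    res <- tryCatch({
      r <- fit_quietly(lmerTest::lmer(form, data = sub, REML = TRUE))
      sm <- summary(r$fit)$coefficients
      coefs <- tibble::tibble(
        term = rownames(sm),
        estimate = sm[, "Estimate"],
        se = sm[, "Std. Error"],
        statistic = sm[, "t value"],
        df = sm[, "df"],
        p_value = sm[, "Pr(>|t|)"]
      )
      new_fit_result(coefs, "gaussian", n_obs = stats::nobs(r$fit),
                     n_groups = as.list(lme4::ngrps(r$fit)),
                     converged = r$converged,
                     singular = lme4::isSingular(r$fit), model = r$fit)
    }, error = function(e) {
      warning("mixed model failed (", conditionMessage(e),
              "); falling back to ordinary least squares", call. = FALSE)
      lmfit <- stats::lm(stats::as.formula(paste(
        response, "~", paste(predictors, collapse = " + "))), data = sub)
      sm <- summary(lmfit)$coefficients
      coefs <- tibble::tibble(
        term = rownames(sm),
        estimate = sm[, "Estimate"],
        se = sm[, "Std. Error"],
        statistic = sm[, "t value"],
        df = stats::df.residual(lmfit),
        p_value = sm[, "Pr(>|t|)"]
      )
      new_fit_result(coefs, "gaussian", n_obs = nrow(sub),
                     note = "ordinary least squares fallback", model = lmfit)
    })
    res
  }
  switch(which,
    both = list(max = fit_one("rel_max_height"), min = fit_one("rel_min_height")),
    max = fit_one("rel_max_height"),
    min = fit_one("rel_min_height")
  )
}

#' Fit niche similarity against morphospace distance
#'
#' Relates pairwise niche similarity (PS, a proportion) to the Euclidean
#' distance between species centroids in morphospace with a quasibinomial
#' generalized linear model (logit link, moment-estimated dispersion).
#' t statistics on the residual degrees of freedom (`n_pairs - 2`) are
#' reported. Pair tables carrying a `site` column are joined within site
#' (the within-site, behaviour-based variant); otherwise pairs are joined
#' at the species level (the community-wide, trait-database variant).
#'
#' @param ps_pairs Pairwise PS tibble from [pairwise_ps()], one `kind`.
#' @param distances Centroid-distance tibble from [centroid_distances()].
#' @param exclude_species Species codes to drop (both sides of each pair).
#' @return An `ecofit_result` with the estimated dispersion.
#' @export
fit_ps_vs_distance <- function(ps_pairs, distances, exclude_species = NULL) {
  by_site <- !all(is.na(ps_pairs$site)) && !all(is.na(distances$site))
  ps <- ps_pairs
  dd <- distances
  if (!is.null(exclude_species)) {
    ps <- ps[!(ps$species_a %in% exclude_species |
                 ps$species_b %in% exclude_species), , drop = FALSE]
    dd <- dd[!(dd$species_a %in% exclude_species |
                 dd$species_b %in% exclude_species), , drop = FALSE]
  }
  ps$key <- pair_key(ps$species_a, ps$species_b)
  dd$key <- pair_key(dd$species_a, dd$species_b)
  if (by_site) {
    df <- dplyr::inner_join(
      ps[, c("key", "site", "ps")], dd[, c("key", "site", "euclidean_distance")],
      by = c("key", "site")
    )
  } else {
    df <- dplyr::inner_join(
      ps[, c("key", "ps")], dd[, c("key", "euclidean_distance")],
      by = "key"
    )
  }
  if (nrow(df) < 3) {
    stop("need at least 3 (PS, distance) pairs; got ", nrow(df), call. = FALSE)
  }
  fit <- stats::glm(ps ~ euclidean_distance, data = df,
                    family = stats::quasibinomial())
  sm <- summary(fit)
  co <- sm$coefficients
  coefs <- tibble::tibble(
    term = rownames(co),
    estimate = co[, "Estimate"],
    se = co[, "Std. Error"],
    statistic = co[, "t value"],
    df = stats::df.residual(fit),
    p_value = co[, "Pr(>|t|)"]
  )
  new_fit_result(coefs, "quasibinomial", n_obs = nrow(df),
                 dispersion = sm$dispersion, model = fit)
}

#' Fit the establishment model
#'
#' Binomial generalized linear mixed model of establishment success against
#' incumbent-community richness, the number of introduction years
#' (propagule-pressure proxy), and mean diet and foraging-stratum PS to the
#' incumbent community, with a random intercept for taxonomic family.
#' Because the model has a single scalar random effect, it is estimated by
#' adaptive Gauss-Hermite quadrature (9 points) rather than the Laplace
#' special case, which measurably improves standard-error accuracy at
#' realistic sample sizes.
#' Families with a single member are retained (the random intercept handles
#' singletons). Wald z statistics are reported. Rows with undefined PS
#' features are dropped with a message.
#'
#' @param features Feature tibble from [build_features()].
#' @param mode Exclusion mode, `"all"` or `"no_gamebirds"` (see
#'   [apply_exclusions()]).
#' @param drop_single_individual Drop single-individual introductions
#'   (default `TRUE`).
#' @return An `ecofit_result`.
#' @export
fit_establishment_model <- function(features, mode = c("all", "no_gamebirds"),
                                    drop_single_individual = TRUE) {
  mode <- match.arg(mode)
  df <- apply_exclusions(features, mode = mode,
                         drop_single_individual = drop_single_individual)
  undef <- !df$ps_defined | is.na(df$established)
  if (any(undef)) {
    message("dropping ", sum(undef),
            " introduction(s) with undefined features or outcome")
    df <- df[!undef, , drop = FALSE]
  }
  if (nrow(df) < 10) {
    stop("too few introductions (", nrow(df), ") to fit the establishment model",
         call. = FALSE)
  }
  df$established <- as.integer(df$established)
  # single scalar random effect: adaptive Gauss-Hermite quadrature is
  # feasible and gives noticeably better SEs than the Laplace special case
  res <- fit_quietly(lme4::glmer(
    established ~ incumbent_richness + n_introduction_years +
      mean_ps_diet + mean_ps_for + (1 | family),
    data = df, family = stats::binomial(), nAGQ = 9
  ))
  fit <- res$fit
  sm <- summary(fit)$coefficients
  coefs <- tibble::tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    se = sm[, "Std. Error"],
    statistic = sm[, "z value"],
    df = NA_real_,
    p_value = sm[, "Pr(>|z|)"]
  )
  new_fit_result(coefs, "binomial", n_obs = stats::nobs(fit),
                 n_groups = as.list(lme4::ngrps(fit)),
                 converged = res$converged, singular = lme4::isSingular(fit),
                 note = paste0("mode: ", mode), model = fit)
}

#' Registry of the literature-derived ecomorphology model specifications
#'
#' One row per registered model: the behavioural response, the error
#' family, the morphological predictors selected from the literature, and
#' the number of focal species the design prescribes for that response
#' (4 for the foraging behaviours, which exclude the rarely foraging
#' insectivore; 5 for movement, location, and height responses). Among the
#' correlated bill ratios only one enters each model.
#'
#' @return A tibble with columns `prediction`, `response`, `family`,
#'   `predictors` (list-column), `n_species`.
#' @export
model_registry <- function() {
  tibble::tibble(
    prediction = c(1L, 1L, 2L, 3L, 4L, 5L, 6L, 7L, 7L, 8L),
    response = c("rel_max_height", "rel_min_height", "gleaning",
                 "flycatching", "frugivory", "hanging", "hop",
                 "in_periphery", "in_interior", "on_ground"),
    family = c("gaussian", "gaussian", "binomial", "binomial", "binomial",
               "binomial", "binomial", "binomial", "binomial", "binomial"),
    predictors = list(
      c("tarsus_to_wing", "mass_kg"),
      c("tarsus_to_wing", "mass_kg"),
      c("bill_slenderness", "tarsus_to_wing"),
      c("horizontal_bill_aspect", "tarsus_to_wing"),
      c("bill_slenderness", "mass_kg"),
      c("tarsus_to_wing", "mass_kg"),
      c("tarsus_to_wing", "mass_kg"),
      c("tarsus_to_wing", "mass_kg"),
      c("tarsus_to_wing", "mass_kg"),
      c("tarsus_to_wing", "mass_kg")
    ),
    n_species = c(5L, 5L, 4L, 4L, 4L, 5L, 5L, 5L, 5L, 5L)
  )
}

#' Fixed-effect estimates of a binomial mixed model in the zero-variance limit
#'
#' Builds the Laplace deviance function of the binomial mixed model via
#' lme4's modular interface, pins every random-effect standard deviation at
#' zero, and minimises the deviance over the fixed effects alone. In this
#' limit the random effects vanish from the linear predictor, so the
#' returned estimates coincide with those of the corresponding plain GLM —
#' a numerical identity the test suite verifies.
#'
#' @param formula A `glmer`-style formula with random-effect terms.
#' @param data Model data.
#' @return Named vector of fixed-effect estimates at zero random-effect
#'   variance.
#' @export
glmm_zero_variance_limit <- function(formula, data) {
  devfun <- lme4::glmer(formula, data = data, family = stats::binomial(),
                        devFunOnly = TRUE)
  rho <- environment(devfun)
  n_theta <- length(rho$dpars)
  n_beta <- length(rho$lower) - n_theta
  objective <- function(beta) devfun(c(rep(0, n_theta), beta))
  opt <- stats::nlminb(rep(0, n_beta), objective,
                       control = list(rel.tol = 1e-14, x.tol = 1e-12,
                                      eval.max = 2000, iter.max = 1000))
  opt <- stats::optim(opt$par, objective, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 500))
  beta <- opt$par
  names(beta) <- colnames(rho$pp$X)
  beta
}
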