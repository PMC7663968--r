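# Invasion-history reconstruction: incumbent communities at each
# introduction date and the establishment-model feature table.

#' Incumbent community at a given year
#'
#' Returns the set of species present on the island in `year`: every native
#' species plus every species introduced before or during `year`, minus
#' species already extirpated. Under the default `"inclusive"` boundary a
#' species whose extirpation (last-report) year equals `year` still counts
#' as present that year; the `"strict"` convention drops it.
#'
#' @param records Introduction-record tibble (see [read_introductions()]):
#'   columns `species`, `native`, `first_introduction_year`,
#'   `extirpation_year` (NA when never extirpated), among others.
#' @param year Calendar year of interest.
#' @param focal Optional focal species code to exclude from the set.
#' @param boundary Extirpation boundary convention, `"inclusive"` (default)
#'   or `"strict"`.
#' @return A character vector of species codes.
#' @export
incumbent_community <- function(records, year, focal = NULL,
                                boundary = c("inclusive", "strict")) {
  boundary <- match.arg(boundary)
  arrived <- records$native |
    (!is.na(records$first_introduction_year) &
       records$first_introduction_year <= year)
  ext <- records$extirpation_year
  gone <- if (boundary == "inclusive") {
    !is.na(ext) & ext < year
  } else {
    !is.na(ext) & ext <= year
  }
  setdiff(records$species[arrived & !gone], focal)
}

# One establishment-model feature row; shared verbatim between
# build_features() and the invasion-history simulator so the simulator's
# internal features are the same code path the analysis uses.
feature_row <- function(records, sp, year, intro_years, psd, psf,
                        boundary, count_unprofiled, family, established,
                        game_bird, single_individual) {
  incumbents <- incumbent_community(records, year, focal = sp, boundary = boundary)
  profiled_d <- intersect(incumbents, rownames(psd))
  profiled_f <- intersect(incumbents, rownames(psf))
  richness <- if (count_unprofiled) {
    length(incumbents)
  } else {
    length(union(profiled_d, profiled_f))
  }
  ps_d <- if (sp %in% rownames(psd) && length(profiled_d) > 0) {
    mean(psd[sp, profiled_d])
  } else {
    NA_real_
  }
  ps_f <- if (sp %in% rownames(psf) && length(profiled_f) > 0) {
    mean(psf[sp, profiled_f])
  } else {
    NA_real_
  }
  tibble::tibble(
    species = sp,
    family = family,
    intro_year = year,
    incumbent_richness = richness,
    n_introduction_years = length(unique(intro_years)),
    mean_ps_diet = ps_d,
    mean_ps_for = ps_f,
    established = established,
    game_bird = game_bird,
    single_individual = single_individual,
    ps_defined = !is.na(ps_d) && !is.na(ps_f)
  )
}

# Accept either a pairwise-PS tibble (from pairwise_ps()) or a symmetric
# PS matrix; return the matrix form.
as_ps_matrix <- function(x) {
  if (is.matrix(x)) {
    return(x)
  }
  sp <- sort(unique(c(x$species_a, x$species_b)))
  m <- matrix(NA_real_, length(sp), length(sp), dimnames = list(sp, sp))
  m[cbind(x$species_a, x$species_b)] <- x$ps
  m[cbind(x$species_b, x$species_a)] <- x$ps
  diag(m) <- 1
  m
}

#' Establishment-model feature table
#'
#' For every non-native introduction, reconstructs the incumbent community
#' at the species' first introduction year and computes the predictors of
#' the establishment model: incumbent species richness, the number of
#' distinct years in which the species was introduced (a propagule-pressure
#' proxy), and the mean diet and foraging-stratum proportional similarity
#' to the incumbent community.
#'
#' Species lacking niche profiles never contribute to the PS averages, but
#' by default still count towards incumbent richness (switch with
#' `count_unprofiled_richness`). An introduction facing an empty incumbent
#' set gets `NA` PS features and `ps_defined = FALSE` so that downstream
#' fits can exclude it explicitly.
#'
#' @param records Introduction-record tibble.
#' @param ps_diet,ps_for Pairwise PS for diet and foraging-stratum
#'   profiles: either tibbles from [pairwise_ps()] or symmetric PS
#'   matrices.
#' @param boundary Extirpation boundary convention, see
#'   [incumbent_community()].
#' @param count_unprofiled_richness Should species without niche profiles
#'   count towards incumbent richness? Default `TRUE`.
#' @return A tibble with one row per introduced species, ordered by
#'   introduction year then species code.
#' @export
build_features <- function(records, ps_diet, ps_for,
                           boundary = c("inclusive", "strict"),
                           count_unprofiled_richness = TRUE) {
  boundary <- match.arg(boundary)
  psd <- as_ps_matrix(ps_diet)
  psf <- as_ps_matrix(ps_for)
  intro <- records[!records$native, , drop = FALSE]
  if (nrow(intro) == 0) {
    stop("no non-native introduction records", call. = FALSE)
  }
  intro <- intro[order(intro$first_introduction_year, intro$species), ,
                 drop = FALSE]
  rows <- lapply(seq_len(nrow(intro)), function(i) {
    r <- intro[i, ]
    feature_row(
      records, r$species, r$first_introduction_year,
      r$introduction_years[[1]], psd, psf,
      boundary = boundary, count_unprofiled = count_unprofiled_richness,
      family = r$family, established = r$established,
      game_bird = r$game_bird, single_individual = r$single_individual
    )
  })
  dplyr::bind_rows(rows)
}

#' Apply the establishment-model exclusion rules
#'
#' Filters the feature table for the two reported model variants: the full
#' set of introduced terrestrial species, or the variant excluding game
#' birds (species introduced for hunting, whose persistence may reflect
#' stocking rather than ecology). Species for which only a single
#' individual was reported to have been introduced are dropped in both
#' variants by default.
#'
#' @param features Feature tibble from [build_features()].
#' @param mode `"all"` or `"no_gamebirds"`.
#' @param drop_single_individual Drop single-individual introductions
#'   (default `TRUE`).
#' @return The filtered feature tibble; an empty result is an error.
#' @export
apply_exclusions <- function(features, mode = c("all", "no_gamebirds"),
                             drop_single_individual = TRUE) {
  mode <- match.arg(mode)
  out <- features
  if (drop_single_individual) {
    out <- out[!out$single_individual, , drop = FALSE]
  }
  if (mode == "no_gamebirds") {
    out <- out[!out$game_bird, , drop = FALSE]
  }
  if (nrow(out) == 0) {
    stop("no introductions remain after exclusions (mode = '", mode, "')",
         call. = FALSE)
  }
  out
}
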