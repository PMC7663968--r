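# Reading, validating, and writing the four canonical input tables.
# CSV is the default; TSV is accepted (delimiter inferred from the first
# line). Files are UTF-8. Validation collects row-level invariant breaches
# with line numbers; `strict = TRUE` (default) turns them into errors,
# `strict = FALSE` warns and attaches the issue table as an attribute.

read_delim_guess <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  first <- readLines(path, n = 1L, warn = FALSE)
  delim <- if (grepl("\t", first)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    stop("schema error in ", what, " table: missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
}

report_issues <- function(df, issues, strict, what) {
  if (nrow(issues) == 0) {
    return(df)
  }
  shown <- utils::head(sprintf("  line %s: %s", issues$row + 1, issues$message), 15)
  msg <- paste0(what, " validation: ", nrow(issues), " issue(s)\n",
                paste(shown, collapse = "\n"))
  if (strict) {
    stop(msg, call. = FALSE)
  }
  warning(msg, call. = FALSE)
  attr(df, "validation_issues") <- issues
  df
}

issue <- function(row, message) tibble::tibble(row = row, message = message)

#' Read and validate a morphology table
#'
#' One row per measured individual: species, site, individual id, the five
#' linear measurements (mm), mass (g), and age class. Measurements may be
#' missing per field; present values must be positive. Juvenile rows are
#' retained and flagged — downstream operations exclude them.
#'
#' @param path Path to a CSV/TSV file.
#' @param strict Treat row-level invariant breaches as errors (default)
#'   or as warnings with the issue table attached.
#' @return A validated morphology tibble.
#' @export
read_morphology <- function(path, strict = TRUE) {
  df <- read_delim_guess(path)
  require_columns(df, c("species", "site", "individual_id", morpho_traits(),
                        "mass", "age_class"), "morphology")
  df$age_class <- ifelse(is.na(df$age_class), "unknown", df$age_class)
  issues <- list()
  for (v in c(morpho_traits(), "mass")) {
    bad <- which(!is.na(df[[v]]) & df[[v]] <= 0)
    if (length(bad) > 0) {
      issues[[v]] <- issue(bad, sprintf("%s must be positive (%s = %g)",
                                        v, df$species[bad], df[[v]][bad]))
    }
  }
  bad_age <- which(!df$age_class %in% c("adult", "juvenile", "unknown"))
  if (length(bad_age) > 0) {
    issues$age <- issue(bad_age, sprintf("unknown age_class '%s'",
                                         df$age_class[bad_age]))
  }
  report_issues(df, dplyr::bind_rows(issues), strict, "morphology")
}

#' Read and validate an observation-event table
#'
#' One row per timed observation: heights, per-point mean canopy height,
#' in-plant location, presence/absence flags for the four foraging
#' behaviours and four movement modes, interaction-intensity score (0-4),
#' and flock size. Heights are accepted as arbitrary reals (the field
#' protocol estimated them to the nearest 1.5 m; no re-rounding is done).
#'
#' @inheritParams read_morphology
#' @return A validated observation tibble with logical flag columns.
#' @export
read_observations <- function(path, strict = TRUE) {
  df <- read_delim_guess(path)
  flags <- c(behavior_vocabulary(), movement_vocabulary())
  require_columns(df, c("event_id", "species", "site", "point_id",
                        "min_height", "max_height", "canopy_height_mean",
                        "location", flags, "interaction_score", "flock_size"),
                  "observations")
  for (v in flags) df[[v]] <- as.logical(df[[v]])
  issues <- list()
  bad <- which(!is.na(df$min_height) & !is.na(df$max_height) &
                 df$min_height > df$max_height)
  if (length(bad) > 0) {
    issues$h <- issue(bad, sprintf("min_height %g > max_height %g",
                                   df$min_height[bad], df$max_height[bad]))
  }
  bad <- which(!is.na(df$canopy_height_mean) & df$canopy_height_mean <= 0)
  if (length(bad) > 0) {
    issues$c <- issue(bad, sprintf("canopy_height_mean must be > 0 (%g)",
                                   df$canopy_height_mean[bad]))
  }
  bad <- which(!df$interaction_score %in% 0:4)
  if (length(bad) > 0) {
    issues$i <- issue(bad, sprintf("interaction_score %s not in 0..4",
                                   df$interaction_score[bad]))
  }
  bad <- which(!is.na(df$flock_size) & df$flock_size < 1)
  if (length(bad) > 0) {
    issues$f <- issue(bad, "flock_size must be >= 1")
  }
  bad <- which(!df$location %in% location_levels())
  if (length(bad) > 0) {
    issues$l <- issue(bad, sprintf("unknown location '%s'", df$location[bad]))
  }
  report_issues(df, dplyr::bind_rows(issues), strict, "observations")
}

#' Read and validate niche profiles
#'
#' Long format: one row per species x category with the percentage of use,
#' the profile kind (`diet` or `foraging_stratum`), and the compiler's
#' certainty grade (A, B, C, D1, D2, or unknown). Each species' profile
#' must sum to 100 within a tolerance of 0.5 percentage points, and all
#' species of one kind must share the same category set (the PS statistic
#' is defined component-wise). Low-certainty (D1/D2) profiles are retained
#' by default; pass `keep_certainty` to filter.
#'
#' @inheritParams read_morphology
#' @param keep_certainty Optional character vector of certainty grades to
#'   retain (e.g. `c("A", "B")`); `NULL` keeps everything.
#' @return A validated long niche-profile tibble.
#' @export
read_niche_profiles <- function(path, strict = TRUE, keep_certainty = NULL) {
  df <- read_delim_guess(path)
  require_columns(df, c("species", "profile_kind", "category", "percent",
                        "certainty"), "niche profiles")
  if (!is.null(keep_certainty)) {
    df <- df[df$certainty %in% keep_certainty, , drop = FALSE]
  }
  issues <- list()
  bad <- which(!df$profile_kind %in% c("diet", "foraging_stratum"))
  if (length(bad) > 0) {
    issues$k <- issue(bad, sprintf("unknown profile_kind '%s'",
                                   df$profile_kind[bad]))
  }
  bad <- which(!is.na(df$percent) & df$percent < 0)
  if (length(bad) > 0) {
    issues$neg <- issue(bad, "percent must be non-negative")
  }
  bad <- which(!df$certainty %in% c("A", "B", "C", "D1", "D2", "unknown"))
  if (length(bad) > 0) {
    issues$cert <- issue(bad, sprintf("unknown certainty grade '%s'",
                                      df$certainty[bad]))
  }
  sums <- dplyr::summarise(
    dplyr::group_by(df, .data$species, .data$profile_kind),
    total = sum(.data$percent), row = dplyr::first(dplyr::cur_group_rows()),
    .groups = "drop"
  )
  bad_sum <- sums[abs(sums$total - 100) > 0.5, , drop = FALSE]
  if (nrow(bad_sum) > 0) {
    issues$sum <- issue(
      bad_sum$row,
      sprintf("%s %s profile sums to %g, not 100",
              bad_sum$species, bad_sum$profile_kind, bad_sum$total)
    )
  }
  # identical category ordering across species, per kind
  for (k in unique(df$profile_kind)) {
    sub <- df[df$profile_kind == k, ]
    cats <- split(sub$category, sub$species)
    ref <- cats[[1]]
    mism <- names(cats)[!vapply(cats, identical, logical(1), y = ref)]
    if (length(mism) > 0) {
      issues[[paste0("ord_", k)]] <- issue(
        0L, sprintf("category set/order for kind '%s' differs for species: %s",
                    k, paste(mism, collapse = ", "))
      )
    }
  }
  report_issues(df, dplyr::bind_rows(issues), strict, "niche profiles")
}

#' Read and validate introduction-history records
#'
#' One row per species: family, native and game-bird flags, the set of
#' introduction years (semicolon-separated in the file), the first
#' introduction year (defaulting to the earliest listed year), the
#' extirpation year (last year reported; empty when never extirpated),
#' the establishment outcome, and the single-individual flag. Native
#' species need no introduction year.
#'
#' @inheritParams read_morphology
#' @return A validated introduction-record tibble; `introduction_years` is
#'   a list-column of integer vectors.
#' @export
read_introductions <- function(path, strict = TRUE) {
  df <- read_delim_guess(path)
  require_columns(df, c("species", "family", "native", "game_bird",
                        "introduction_years", "first_introduction_year",
                        "extirpation_year", "established",
                        "single_individual"), "introductions")
  df$native <- as.logical(df$native)
  df$game_bird <- as.logical(df$game_bird)
  df$established <- as.logical(df$established)
  df$single_individual <- as.logical(df$single_individual)
  yrs <- strsplit(as.character(df$introduction_years), ";", fixed = TRUE)
  df$introduction_years <- lapply(yrs, function(v) {
    v <- v[!is.na(v) & nzchar(v)]
    sort(unique(as.integer(v)))
  })
  df$first_introduction_year <- as.integer(df$first_introduction_year)
  df$extirpation_year <- as.integer(df$extirpation_year)
  no_first <- is.na(df$first_introduction_year) &
    lengths(df$introduction_years) > 0
  df$first_introduction_year[no_first] <-
    vapply(df$introduction_years[no_first], min, integer(1))
  issues <- list()
  bad <- which(!df$native & is.na(df$first_introduction_year))
  if (length(bad) > 0) {
    issues$y <- issue(bad, sprintf("non-native species %s lacks an introduction year",
                                   df$species[bad]))
  }
  bad <- which(!is.na(df$extirpation_year) &
                 !is.na(df$first_introduction_year) &
                 df$extirpation_year < df$first_introduction_year)
  if (length(bad) > 0) {
    issues$e <- issue(bad, sprintf("%s extirpated (%d) before first introduction (%d)",
                                   df$species[bad], df$extirpation_year[bad],
                                   df$first_introduction_year[bad]))
  }
  report_issues(df, dplyr::bind_rows(issues), strict, "introductions")
}

#' Write pipeline tables to delimited text
#'
#' Counterparts of the `read_*` functions; `write(read(x))` is
#' field-identical for valid files. The introduction-year set is
#' serialised as a semicolon-separated list.
#'
#' @param df The tibble to write.
#' @param path Output file path (CSV).
#' @return Invisibly, `path`.
#' @name write_tables
NULL

#' @rdname write_tables
#' @export
write_morphology <- function(df, path) {
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_tables
#' @export
write_observations <- function(df, path) {
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_tables
#' @export
write_niche_profiles <- function(df, path) {
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_tables
#' @export
write_introductions <- function(df, path) {
  out <- df
  out$introduction_years <- vapply(
    df$introduction_years,
    function(v) paste(v, collapse = ";"),
    character(1)
  )
  readr::write_csv(out, path)
  invisible(path)
}
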