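# Foraging-observation analysis variables: relative heights, behaviour
# frequency distributions, and per-event binary response vectors.

#' Canopy-relative observation heights
#'
#' Converts the raw minimum and maximum heights of each observation to
#' canopy-relative heights by dividing by the mean canopy height of the
#' observation point. Values above 1 are legitimate (birds in emergent
#' trees above the average canopy). Events with a missing or non-positive
#' canopy height are excluded with a warning.
#'
#' @param events Observation-event tibble (see [read_observations()] or
#'   [simulate_observations()]).
#' @return A tibble with `event_id`, `species`, `site`, `rel_min_height`,
#'   `rel_max_height`.
#' @export
relative_heights <- function(events) {
  bad <- is.na(events$canopy_height_mean) | events$canopy_height_mean <= 0
  if (any(bad)) {
    warning("excluding ", sum(bad),
            " event(s) with missing or non-positive canopy height",
            call. = FALSE)
    events <- events[!bad, , drop = FALSE]
  }
  tibble::tibble(
    event_id = events$event_id,
    species = events$species,
    site = events$site,
    rel_min_height = events$min_height / events$canopy_height_mean,
    rel_max_height = events$max_height / events$canopy_height_mean
  )
}

#' Behaviour relative-frequency distributions
#'
#' Builds, per species (by default per species at each site), the relative
#' frequency distribution over the four foraging behaviours (gleaning,
#' flycatching, nectarivory, frugivory). Only events with at least one
#' behaviour flag set count as foraging events. Because a single event may
#' carry several behaviour flags, two normalisations are offered:
#'
#' * `"occurrences"` (default): frequency of behaviour *b* is the number of
#'   flag occurrences of *b* divided by the total number of flag
#'   occurrences, so multi-behaviour events contribute to several
#'   categories and the distribution still sums to 1.
#' * `"events"`: each foraging event carries unit weight split equally
#'   among its flagged behaviours, so no event counts more than once.
#'
#' @param events Observation-event tibble.
#' @param pooling `"species_site"` (default) or `"species"` (pooled over
#'   sites; the `site` column is then `NA`).
#' @param denominator Normalisation convention, see above.
#' @return A tibble with `species`, `site`, one column per behaviour
#'   (frequencies summing to 1), and `n_events` (number of foraging
#'   events). Groups observed but never foraging are excluded with a
#'   warning, since their distribution is undefined.
#' @export
behavior_distribution <- function(events,
                                  pooling = c("species_site", "species"),
                                  denominator = c("occurrences", "events")) {
  pooling <- match.arg(pooling)
  denominator <- match.arg(denominator)
  behs <- behavior_vocabulary()
  miss <- setdiff(behs, names(events))
  if (length(miss) > 0) {
    stop("events lack behaviour flag column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  flags <- as.matrix(events[, behs, drop = FALSE]) * 1
  n_flags <- rowSums(flags)
  foraging <- n_flags > 0

  group_of <- function(df) {
    if (pooling == "species_site") paste(df$species, df$site, sep = "\r")
    else df$species
  }
  all_groups <- unique(group_of(events))
  ev <- events[foraging, , drop = FALSE]
  fl <- flags[foraging, , drop = FALSE]
  wt <- if (denominator == "events") fl / rowSums(fl) else fl
  g <- group_of(ev)

  kept <- unique(g)
  lost <- setdiff(all_groups, kept)
  if (length(lost) > 0) {
    warning("excluding group(s) with zero foraging events: ",
            paste(gsub("\r", "@", lost), collapse = ", "), call. = FALSE)
  }
  if (length(kept) == 0) {
    stop("no foraging events at all; behaviour distributions undefined",
         call. = FALSE)
  }
  totals <- rowsum(wt, g)
  freqs <- totals / rowSums(totals)
  n_events <- as.vector(table(g)[rownames(totals)])
  key <- rownames(totals)
  out <- tibble::tibble(
    species = if (pooling == "species_site") sub("\r.*$", "", key) else key,
    site = if (pooling == "species_site") sub("^.*\r", "", key) else NA_character_
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(freqs))
  out$n_events <- n_events
  dplyr::arrange(out, .data$species, .data$site)
}

#' Per-event binary response vectors for the behaviour models
#'
#' Expands each observation event into the 0/1 responses modelled
#' downstream: the four foraging behaviours, the four movement modes, and
#' mutually exclusive in-plant location indicators (`in_interior`,
#' `in_periphery`, `on_ground`; `NA` when the location was not recorded).
#' Events flagged with several behaviours contribute a 1 to each of the
#' corresponding responses.
#'
#' @param events Observation-event tibble.
#' @return A tibble with `event_id`, `species`, `site`, and one integer
#'   column per response. An empty input yields an empty tibble with the
#'   full column set; model fits refuse empty data with a clear error.
#' @export
response_vectors <- function(events) {
  behs <- behavior_vocabulary()
  movs <- movement_vocabulary()
  out <- tibble::tibble(
    event_id = events$event_id,
    species = events$species,
    site = events$site
  )
  for (v in c(behs, movs)) {
    out[[v]] <- as.integer(events[[v]])
  }
  loc <- events$location
  unknown <- is.na(loc) | loc == "unknown"
  out$in_interior <- ifelse(unknown, NA_integer_, as.integer(loc == "interior"))
  out$in_periphery <- ifelse(unknown, NA_integer_, as.integer(loc == "periphery"))
  out$on_ground <- ifelse(unknown, NA_integer_, as.integer(loc == "ground"))
  out
}
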