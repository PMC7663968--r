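# Morphological ratios, PCA morphospace, and centroid distances.

bill_cross_section <- function(width, depth, formula = c("ellipse", "rectangle")) {
  formula <- match.arg(formula)
  switch(formula,
    ellipse = pi * (width / 2) * (depth / 2),
    rectangle = width * depth
  )
}

#' Site-averaged morphological ratios
#'
#' Computes, for each measured adult individual, the tarsus-to-wing ratio,
#' the horizontal bill aspect ratio (culmen length / bill width at the
#' nares), and bill slenderness (culmen length / bill cross-sectional area
#' at the nares), then averages the per-individual ratios for each species
#' at each site. Larger bill slenderness means a longer, thinner bill;
#' smaller means a more robust bill. Juvenile records are excluded from all
#' computations.
#'
#' The bill cross-section is approximated as an ellipse,
#' \eqn{\pi (w/2)(d/2)}, by default; a rectangular approximation
#' (\eqn{w \times d}) is available since only relative ordering across
#' species matters for the downstream model signs.
#'
#' @param records A morphology tibble (see [read_morphology()] or
#'   [simulate_morphology()]): one row per measured individual with columns
#'   `species`, `site`, the five linear traits in mm, `mass` in g, and
#'   `age_class`.
#' @param bill_area Cross-sectional area approximation, `"ellipse"`
#'   (default) or `"rectangle"`.
#' @return A tibble with one row per species x site: `tarsus_to_wing`,
#'   `horizontal_bill_aspect`, `bill_slenderness` (per mm), `mass_mean` (g),
#'   and `n_individuals`. Species x site groups with no adult records are
#'   omitted with a warning.
#' @export
compute_ratios <- function(records, bill_area = c("ellipse", "rectangle")) {
  bill_area <- match.arg(bill_area)
  need <- c("species", "site", morpho_traits(), "mass", "age_class")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    stop("morphology records lack columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  adults <- records[is.na(records$age_class) | records$age_class != "juvenile", ,
                    drop = FALSE]
  lost <- dplyr::anti_join(
    dplyr::distinct(records, .data$species, .data$site),
    dplyr::distinct(adults, .data$species, .data$site),
    by = c("species", "site")
  )
  if (nrow(lost) > 0) {
    warning("omitting species x site groups with no adult records: ",
            paste(paste(lost$species, lost$site, sep = "@"), collapse = ", "),
            call. = FALSE)
  }
  if (nrow(adults) == 0) {
    stop("no adult morphology records available", call. = FALSE)
  }
  per_ind <- dplyr::mutate(adults,
    tarsus_to_wing = .data$tarsus_length / .data$wing_length,
    horizontal_bill_aspect = .data$culmen_length / .data$bill_width_nares,
    bill_slenderness = .data$culmen_length /
      bill_cross_section(.data$bill_width_nares, .data$bill_depth_nares, bill_area)
  )
  out <- dplyr::summarise(
    dplyr::group_by(per_ind, .data$species, .data$site),
    tarsus_to_wing = mean(.data$tarsus_to_wing, na.rm = TRUE),
    horizontal_bill_aspect = mean(.data$horizontal_bill_aspect, na.rm = TRUE),
    bill_slenderness = mean(.data$bill_slenderness, na.rm = TRUE),
    mass_mean = mean(.data$mass, na.rm = TRUE),
    n_individuals = dplyr::n(),
    .groups = "drop"
  )
  dplyr::arrange(out, .data$species, .data$site)
}

#' Individual-level PCA morphospace
#'
#' Runs a principal component analysis on the raw (centred, by default
#' unstandardised) linear morphological measurements with the individual
#' bird as the experimental unit, after excluding juveniles and incomplete
#' cases. All components are retained so the morphospace is lossless:
#' Euclidean distances on the full score matrix equal distances on the
#' centred trait data.
#'
#' @param records Morphology tibble as for [compute_ratios()].
#' @param include_mass Include body mass as a sixth variable (default
#'   `FALSE`: the morphospace is built from the five linear traits, with
#'   mass treated as a separate predictor downstream).
#' @param standardize Scale traits to unit variance before the PCA
#'   (default `FALSE`, i.e. the PCA runs on raw, centred measurements;
#'   setting this changes all downstream centroid distances).
#' @return An object of class `morphospace`: a list with `scores` (tibble
#'   of individual ids, species, site, and PC coordinates), `loadings`,
#'   `sdev`, `var_explained`, `traits`, and the `standardize` flag.
#'   Constant trait columns are dropped with a warning.
#' @export
pca_morphospace <- function(records, include_mass = FALSE, standardize = FALSE) {
  traits <- morpho_traits()
  if (include_mass) traits <- c(traits, "mass")
  adults <- records[is.na(records$age_class) | records$age_class != "juvenile", ,
                    drop = FALSE]
  keep <- stats::complete.cases(adults[, traits, drop = FALSE])
  adults <- adults[keep, , drop = FALSE]
  if (nrow(adults) < 2) {
    stop("need at least 2 complete adult records for a PCA", call. = FALSE)
  }
  x <- as.matrix(adults[, traits, drop = FALSE])
  constant <- apply(x, 2, function(v) max(v) == min(v))
  if (any(constant)) {
    warning("dropping constant trait column(s): ",
            paste(colnames(x)[constant], collapse = ", "), call. = FALSE)
    x <- x[, !constant, drop = FALSE]
  }
  if (ncol(x) == 0) {
    stop("all trait columns are constant; no morphospace", call. = FALSE)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = standardize)
  scores <- dplyr::bind_cols(
    adults[, intersect(c("individual_id", "species", "site"), names(adults)),
           drop = FALSE],
    tibble::as_tibble(pc$x)
  )
  structure(
    list(
      scores = scores,
      loadings = pc$rotation,
      sdev = pc$sdev,
      var_explained = pc$sdev^2 / sum(pc$sdev^2),
      traits = colnames(x),
      standardize = standardize,
      center = pc$center
    ),
    class = "morphospace"
  )
}

#' @export
print.morphospace <- function(x, ...) {
  cat("Morphospace PCA on", length(x$traits), "traits,",
      nrow(x$scores), "individuals\n")
  cat("Variance explained:",
      paste(sprintf("%s %.1f%%", paste0("PC", seq_along(x$var_explained)),
                    100 * x$var_explained), collapse = ", "), "\n")
  invisible(x)
}

#' Euclidean distances between species centroids in morphospace
#'
#' Computes the species centroid (mean score vector over all retained
#' principal components) for each group and the Euclidean distance
#' \eqn{D_E} between every unordered pair of species centroids. With the
#' default grouping, centroids are computed per species at each site and
#' only within-site pairs are emitted; the pooled `"species"` grouping
#' computes one centroid per species across sites.
#'
#' @param ms A `morphospace` object from [pca_morphospace()], or its
#'   `scores` tibble.
#' @param grouping `"species_site"` (default) or `"species"`.
#' @return A tibble with columns `species_a`, `species_b`, `site` (`NA` for
#'   pooled grouping), and `euclidean_distance`. Sites holding a single
#'   species yield no rows.
#' @export
centroid_distances <- function(ms, grouping = c("species_site", "species")) {
  grouping <- match.arg(grouping)
  scores <- if (inherits(ms, "morphospace")) ms$scores else ms
  pc_cols <- grep("^PC[0-9]+$", names(scores), value = TRUE)
  if (length(pc_cols) == 0) {
    stop("no principal-component columns found in scores", call. = FALSE)
  }
  one_site <- function(sub, site_label) {
    cent <- dplyr::summarise(
      dplyr::group_by(sub, .data$species),
      dplyr::across(dplyr::all_of(pc_cols), mean),
      .groups = "drop"
    )
    cent <- dplyr::arrange(cent, .data$species)
    if (nrow(cent) < 2) {
      return(NULL)
    }
    m <- as.matrix(cent[, pc_cols, drop = FALSE])
    rownames(m) <- cent$species
    d <- as.matrix(stats::dist(m))
    idx <- which(upper.tri(d), arr.ind = TRUE)
    tibble::tibble(
      species_a = rownames(d)[idx[, 1]],
      species_b = rownames(d)[idx[, 2]],
      site = site_label,
      euclidean_distance = d[idx]
    )
  }
  if (grouping == "species") {
    return(one_site(scores, NA_character_))
  }
  parts <- lapply(sort(unique(scores$site)), function(s) {
    one_site(scores[scores$site == s, , drop = FALSE], s)
  })
  dplyr::bind_rows(parts)
}
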