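# Proportional similarity (PS) between resource-use distributions.
#
# PS = sum_i min(p_i, q_i) over a shared, identically ordered category set.
# PS = 1 for identical distributions and 0 for disjoint support; it equals
# 1 - L1(p, q) / 2, which the tests exploit as an independent oracle.

# Coerce a non-negative vector to proportions. Percent inputs (sum ~ 100)
# are divided by 100 first; proportion inputs (sum ~ 1) pass through.
normalize_distribution <- function(x, tol = 1e-6, what = "distribution") {
  if (anyNA(x) || any(x < 0)) {
    stop(what, " has missing or negative components", call. = FALSE)
  }
  s <- sum(x)
  if (abs(s / 100 - 1) <= tol) {
    x / 100
  } else if (abs(s - 1) <= tol) {
    x
  } else {
    stop(sprintf(
      "%s sums to %.8g; expected 1 (proportions) or 100 (percents) within tolerance %g",
      what, s, tol
    ), call. = FALSE)
  }
}

#' Proportional similarity between two distributions
#'
#' Computes the proportional similarity index
#' \eqn{PS = \sum_i \min(p_i, q_i)} between two resource-use (or behaviour)
#' distributions defined over the same ordered category set. PS ranges from
#' 0 (disjoint support) to 1 (identical distributions). Inputs may be given
#' as proportions (summing to 1) or percentages (summing to 100, the
#' EltonTraits convention); percentages are converted before comparison.
#'
#' @param p,q Non-negative numeric vectors over the same categories, in the
#'   same order. If both are named the names must match exactly, including
#'   order, since PS is defined component-wise.
#' @param tol Tolerance for the sums-to-one check, applied after any percent
#'   conversion.
#' @return A single number in \[0, 1\]. Identical inputs return exactly 1.
#' @examples
#' proportional_similarity(c(0.5, 0.5), c(0.9, 0.1)) # 0.6
#' @export
proportional_similarity <- function(p, q, tol = 1e-6) {
  if (length(p) != length(q)) {
    stop("distributions have different lengths (", length(p), " vs ",
         length(q), ")", call. = FALSE)
  }
  if (!is.null(names(p)) && !is.null(names(q)) && !identical(names(p), names(q))) {
    extra <- union(setdiff(names(p), names(q)), setdiff(names(q), names(p)))
    if (length(extra) > 0) {
      stop("category mismatch between distributions: ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
    stop("categories are ordered differently: [",
         paste(names(p), collapse = ", "), "] vs [",
         paste(names(q), collapse = ", "), "]", call. = FALSE)
  }
  p <- normalize_distribution(p, tol, "first distribution")
  q <- normalize_distribution(q, tol, "second distribution")
  if (all(p == q)) {
    return(1)
  }
  sum(pmin(p, q))
}

# Full symmetric PS matrix for a species-by-category matrix whose rows are
# distributions (proportions or percents). Row names are required. The
# diagonal is exactly 1.
ps_matrix <- function(m, tol = 1e-6) {
  if (is.null(rownames(m))) {
    stop("profile matrix must have species row names", call. = FALSE)
  }
  m <- t(apply(m, 1, normalize_distribution, tol = tol, what = "profile"))
  out <- matrix(0, nrow(m), nrow(m), dimnames = list(rownames(m), rownames(m)))
  for (k in seq_len(ncol(m))) {
    out <- out + outer(m[, k], m[, k], pmin)
  }
  # identical profiles have PS exactly 1, immune to summation round-off
  key <- apply(m, 1, paste, collapse = "\r")
  out[outer(key, key, "==")] <- 1
  out
}

# Long niche-profile tibble (one profile_kind) -> species x category matrix.
profiles_to_matrix <- function(profiles, kind) {
  sub <- profiles[profiles$profile_kind == kind, , drop = FALSE]
  if (nrow(sub) == 0) {
    stop("no profiles of kind '", kind, "'", call. = FALSE)
  }
  ref <- sub$category[sub$species == sub$species[1]]
  wide <- tidyr::pivot_wider(
    sub[, c("species", "category", "percent")],
    names_from = "category", values_from = "percent"
  )
  if (anyNA(wide)) {
    bad <- wide$species[!stats::complete.cases(wide)]
    stop("profiles of kind '", kind, "' have unequal category sets; offending species: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(wide[, ref, drop = FALSE])
  rownames(m) <- wide$species
  m
}

# Symmetric PS matrix -> tidy unordered-pair tibble.
ps_matrix_to_pairs <- function(m, kind, site = NA_character_) {
  sp <- rownames(m)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble::tibble(
    species_a = sp[idx[, 1]],
    species_b = sp[idx[, 2]],
    kind = kind,
    site = site,
    ps = m[idx]
  )
}

#' Pairwise proportional similarity for a set of profiles
#'
#' Computes PS for every unordered pair of species, either from long-format
#' niche profiles (diet or foraging-stratum percentage distributions, one row
#' per species x category) or from behaviour frequency distributions as
#' produced by [behavior_distribution()]. Behaviour distributions carrying a
#' `site` column are compared within site.
#'
#' @param x Either a long niche-profile tibble with columns `species`,
#'   `profile_kind`, `category`, `percent`, or a behaviour-distribution
#'   tibble with columns `species`, `site`, one column per behaviour, and
#'   `n_events`.
#' @param tol Normalisation tolerance passed to [proportional_similarity()].
#' @return A tibble with columns `species_a`, `species_b`, `kind`, `site`,
#'   `ps`; one row per unordered pair, self-pairs omitted.
#' @export
pairwise_ps <- function(x, tol = 1e-6) {
  if (all(c("species", "profile_kind", "category", "percent") %in% names(x))) {
    kinds <- unique(x$profile_kind)
    out <- lapply(kinds, function(k) {
      m <- profiles_to_matrix(x, k)
      m <- m[sort(rownames(m)), , drop = FALSE]
      if (nrow(m) < 2) stop("need at least 2 profiles of kind '", k, "'", call. = FALSE)
      ps_matrix_to_pairs(ps_matrix(m, tol), kind = k)
    })
    return(dplyr::bind_rows(out))
  }
  behs <- intersect(behavior_vocabulary(), names(x))
  if ("species" %in% names(x) && length(behs) == length(behavior_vocabulary())) {
    site_vals <- if ("site" %in% names(x)) x$site else rep(NA_character_, nrow(x))
    out <- lapply(split(seq_len(nrow(x)), site_vals, drop = TRUE), function(i) {
      sub <- x[i, , drop = FALSE]
      if (nrow(sub) < 2) {
        return(NULL)
      }
      m <- as.matrix(sub[, behs, drop = FALSE])
      rownames(m) <- sub$species
      m <- m[sort(rownames(m)), , drop = FALSE]
      ps_matrix_to_pairs(ps_matrix(m, tol), kind = "behavior",
                         site = site_vals[i[1]])
    })
    return(dplyr::bind_rows(out))
  }
  stop("input is neither a niche-profile table nor a behaviour-distribution table",
       call. = FALSE)
}

#' Mean proportional similarity of a focal species to a species set
#'
#' Averages the pairwise PS between one focal species and every member of a
#' reference set (typically the incumbent community at the focal species'
#' introduction date). The focal species never contributes to its own
#' average.
#'
#' @param focal Focal species code.
#' @param others Character vector of reference species codes.
#' @param pairs A pairwise PS tibble from [pairwise_ps()] (a single `kind`).
#' @return The arithmetic mean PS, a single number.
#' @export
mean_ps_to_set <- function(focal, others, pairs) {
  others <- setdiff(unique(others), focal)
  if (length(others) == 0) {
    stop("empty reference set for focal species '", focal, "'", call. = FALSE)
  }
  sel <- pairs[(pairs$species_a == focal & pairs$species_b %in% others) |
                 (pairs$species_b == focal & pairs$species_a %in% others), ,
               drop = FALSE]
  found <- ifelse(sel$species_a == focal, sel$species_b, sel$species_a)
  missing <- setdiff(others, found)
  if (length(missing) > 0) {
    stop("missing pairwise PS between '", focal, "' and: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  mean(sel$ps[match(others, found)])
}
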