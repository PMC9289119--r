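#' Collapse the two seasonal visits to per-point abundances
#'
#' Each census point is visited twice in a breeding season; because the
#' community turns over within the season (late-arriving migrants, changing
#' abundances of residents), the per-point abundance of a species is taken as
#' the maximum of its two visit counts, the best available estimate of the
#' maximum local population. Summing visits would double-count territorial
#' individuals.
#'
#' @param counts Long-format data.frame with columns `point`, `visit`,
#'   `species`, `count` (non-negative integers, visit in 1:2). Species/point
#'   combinations without a row count as 0.
#' @return Species x point abundance matrix (rownames species, colnames
#'   points).
#' @export
collapse_visits <- function(counts) {
  req <- c("point", "visit", "species", "count")
  if (!all(req %in% names(counts)))
    stop("counts must have columns: ", paste(req, collapse = ", "))
  if (any(counts$count < 0)) stop("counts must be non-negative")
  if (!all(counts$visit %in% c(1, 2)))
    stop("visit index must be 1 or 2")
  nv <- tapply(counts$visit, counts$point, function(v) length(unique(v)))
  if (any(nv < 2))
    warning(sum(nv < 2), " point(s) have records for a single visit; ",
            "missing visits are treated as zero counts")
  sp <- sort(unique(as.character(counts$species)))
  pt <- sort(unique(as.character(counts$point)))
  ab <- matrix(0, length(sp), length(pt), dimnames = list(sp, pt))
  # per (species, point, visit) sum, then max over visits
  for (v in 1:2) {
    cv <- counts[counts$visit == v, , drop = FALSE]
    if (nrow(cv) == 0) next
    m <- tapply(cv$count, list(as.character(cv$species),
                               as.character(cv$point)), sum)
    m[is.na(m)] <- 0
    ab[rownames(m), colnames(m)] <-
      pmax(ab[rownames(m), colnames(m)], m)
  }
  ab
}

#' Suitable-habitat area of census points for each species
#'
#' A point's suitable area for a species is the point area times the summed
#' proportions of the aggregated habitat classes in which the species has at
#' least one preferred source class.
#'
#' @param composition Point x aggregated-class proportion matrix (rows sum
#'   to 1), rownames = point ids.
#' @param prefs Species x source-class binary preference matrix (rownames =
#'   species).
#' @param map Source-to-aggregated class map; default
#'   [preference_to_aggregated].
#' @param area_ha Area of one census point in hectares (default
#'   [point_area_ha]).
#' @return Point x species matrix of suitable areas (ha).
#' @export
suitable_area <- function(composition, prefs, map = preference_to_aggregated,
                          area_ha = point_area_ha) {
  prefs <- .pref_matrix(prefs)
  agg <- colnames(composition)
  # species x aggregated-class suitability indicator
  agg_pref <- aggregate_habitats(prefs, map = map, classes = agg)
  agg_pref <- (agg_pref > 0) + 0
  area_ha * composition %*% t(agg_pref)
}

#' Geographical density: individuals per hectare of surveyed area
#'
#' Total abundance divided by the total physical area covered by the survey
#' (number of points times the point area), irrespective of habitat.
#'
#' @param abundance Species x point abundance matrix ([collapse_visits()]).
#' @param n_points Number of surveyed points (defaults to `ncol(abundance)`).
#' @inheritParams suitable_area
#' @return Named vector of densities (ind/ha).
#' @export
geographical_density <- function(abundance, n_points = ncol(abundance),
                                 area_ha = point_area_ha) {
  if (n_points < 1) stop("at least one census point is required")
  rowSums(abundance) / (n_points * area_ha)
}

#' Ecological density: individuals per hectare of suitable habitat
#'
#' Total abundance divided by the summed suitable-habitat area, by default
#' over the points where the species was recorded (`mode = "presence"`);
#' `mode = "all_points"` divides by the suitable area over every surveyed
#' point. A presence at a point with zero mapped suitable habitat is taken as
#' evidence of suitability: the point contributes its full area to the
#' denominator and the species is flagged `zero_suitable_presence`.
#'
#' @inheritParams geographical_density
#' @param suitable Point x species suitable-area matrix ([suitable_area()]).
#' @param mode `"presence"` (default) or `"all_points"`.
#' @return data.frame with `species`, `total_count`, `n_presence_points`,
#'   `suitable_area_total` (the denominator used, ha), `eco_density`
#'   (ind/ha) and `flags`. Species with zero total abundance are excluded
#'   with a warning (their ecological density is undefined).
#' @export
ecological_density <- function(abundance, suitable,
                               mode = c("presence", "all_points"),
                               area_ha = point_area_ha) {
  mode <- match.arg(mode)
  stopifnot(identical(colnames(abundance), rownames(suitable)))
  sp <- rownames(abundance)
  absent <- rowSums(abundance) == 0
  if (any(absent)) {
    warning("excluding ", sum(absent),
            " species with zero total abundance (ecological density undefined)")
    sp <- sp[!absent]
  }
  out <- lapply(sp, function(s) {
    ab <- abundance[s, ]
    pres <- ab > 0
    sa <- suitable[, s]
    flags <- character(0)
    zero_suit_pres <- pres & sa <= 0
    if (any(zero_suit_pres)) {
      sa[zero_suit_pres] <- area_ha
      flags <- c(flags, "zero_suitable_presence")
    }
    denom <- if (mode == "presence") sum(sa[pres]) else sum(sa)
    data.frame(species = s,
               total_count = sum(ab),
               n_presence_points = sum(pres),
               suitable_area_total = denom,
               eco_density = sum(ab) / denom,
               flags = paste(flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-species density table from census data
#'
#' End-to-end density computation: collapses visits, aggregates the habitat
#' composition onto the 7 analysis classes if given in source categories, and
#' returns both geographical and ecological densities per species.
#'
#' @param counts Long count table (see [collapse_visits()]).
#' @param habitat data.frame with a `point` column and one column per habitat
#'   class (either the 12 census categories or the 7 aggregated ones);
#'   proportions per row sum to 1.
#' @param prefs Species x source-class binary preference table.
#' @param map Preference-class aggregation map.
#' @param habitat_map Census-class aggregation map (used when `habitat` is in
#'   source categories).
#' @inheritParams ecological_density
#' @return data.frame with species, total_count, n_presence_points,
#'   suitable_area_total, geo_density, eco_density, flags.
#' @export
density_table <- function(counts, habitat, prefs,
                          map = preference_to_aggregated,
                          habitat_map = census_to_aggregated,
                          mode = c("presence", "all_points"),
                          area_ha = point_area_ha) {
  mode <- match.arg(mode)
  if (!"point" %in% names(habitat)) stop("habitat table needs a `point` column")
  comp <- as.matrix(habitat[setdiff(names(habitat), c("point", "transect"))])
  rownames(comp) <- as.character(habitat$point)
  if (!all(colnames(comp) %in% aggregated_classes7))
    comp <- aggregate_habitats(comp, map = habitat_map)
  bad <- abs(rowSums(comp) - 1) > 1e-9
  if (any(bad))
    stop(sum(bad), " habitat composition row(s) do not sum to 1")
  ab <- collapse_visits(counts)
  prefs <- .pref_matrix(prefs)
  missing_sp <- setdiff(rownames(ab), rownames(prefs))
  if (length(missing_sp) > 0)
    stop("species without preference data: ",
         paste(missing_sp, collapse = ", "))
  missing_pt <- setdiff(colnames(ab), rownames(comp))
  if (length(missing_pt) > 0)
    stop("points without habitat composition: ",
         paste(missing_pt, collapse = ", "))
  comp <- comp[colnames(ab), , drop = FALSE]
  sa <- suitable_area(comp, prefs[rownames(ab), , drop = FALSE],
                      map = map, area_ha = area_ha)
  eco <- ecological_density(ab, sa, mode = mode, area_ha = area_ha)
  geo <- geographical_density(ab, area_ha = area_ha)
  eco$geo_density <- unname(geo[eco$species])
  eco[c("species", "total_count", "n_presence_points", "suitable_area_total",
        "geo_density", "eco_density", "flags")]
}
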