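#' Habitat taxonomies and aggregation maps
#'
#' The census protocol records the biotope composition around every point in
#' 12 field categories; analyses use 7 aggregated classes (the four open
#' categories merge into `open`, the two water categories into `water`, urban
#' and suburban into `urban`). Species habitat preferences come from a
#' European-scale trait compilation with 15 habitat classes and 9 diet
#' classes; for suitability calculations the 15 preference classes are mapped
#' onto the same 7 aggregated census classes.
#'
#' @format Character vectors of class labels, and named character vectors
#'   mapping source classes to aggregated classes.
#' @name habitat_taxonomy
NULL

#' @rdname habitat_taxonomy
#' @export
census_classes12 <- c(
  "coniferous_forest", "deciduous_forest", "mixed_forest", "shrub",
  "meadows", "fields", "alpine", "rocks",
  "water_bodies", "marshes", "urban", "suburban"
)

#' @rdname habitat_taxonomy
#' @export
aggregated_classes7 <- c(
  "deciduous_forest", "coniferous_forest", "mixed_forest", "shrub",
  "open", "water", "urban"
)

#' @rdname habitat_taxonomy
#' @export
census_to_aggregated <- c(
  coniferous_forest = "coniferous_forest",
  deciduous_forest  = "deciduous_forest",
  mixed_forest      = "mixed_forest",
  shrub             = "shrub",
  meadows           = "open",
  fields            = "open",
  alpine            = "open",
  rocks             = "open",
  water_bodies      = "water",
  marshes           = "water",
  urban             = "urban",
  suburban          = "urban"
)

#' @rdname habitat_taxonomy
#' @export
preference_classes15 <- c(
  "coniferous_forest", "deciduous_forest", "woodland", "shrub",
  "savanna", "tundra", "grassland", "mountain_meadows", "desert", "rocks",
  "reed", "swamp", "freshwater", "marine",
  "human_settlement"
)

# woodland (generic wooded habitat) is carried to mixed forest and marine to
# water; both are absent from the open/water/urban merge lists of the source
# taxonomy and need a home among the 7 census classes.
#' @rdname habitat_taxonomy
#' @export
preference_to_aggregated <- c(
  coniferous_forest = "coniferous_forest",
  deciduous_forest  = "deciduous_forest",
  woodland          = "mixed_forest",
  shrub             = "shrub",
  savanna           = "open",
  tundra            = "open",
  grassland         = "open",
  mountain_meadows  = "open",
  desert            = "open",
  rocks             = "open",
  reed              = "water",
  swamp             = "water",
  freshwater        = "water",
  marine            = "water",
  human_settlement  = "urban"
)

#' @rdname habitat_taxonomy
#' @export
diet_classes9 <- c(
  "folivore", "frugivore", "granivore", "insectivore",
  "other_invertebrates", "piscivore", "other_vertebrates",
  "scavenger", "omnivore"
)

#' Census point area in hectares
#'
#' Census points have a 100 m radius, so each covers pi * (100 m)^2 =
#' 31415.9 m^2 = pi hectares (3.14159 ha).
#' @export
point_area_ha <- pi

#' Aggregate a habitat composition onto the analysis classes
#'
#' Sums the proportions of the source classes belonging to each aggregated
#' class. Area is conserved: the output sums to the same total as the input.
#'
#' @param composition Named numeric vector of proportions over source
#'   classes, or a data.frame/matrix with one column per source class (rows
#'   are points).
#' @param map Named character vector mapping each source class to its
#'   aggregated class. Defaults to the census 12-to-7 map.
#' @param classes Output class labels (and order). Defaults to the 7
#'   aggregated classes.
#' @return A named vector (or matrix, one row per input row) of proportions
#'   over `classes`.
#' @examples
#' aggregate_habitats(c(meadows = 0.3, fields = 0.2, urban = 0.5))
#' @export
aggregate_habitats <- function(composition, map = census_to_aggregated,
                               classes = aggregated_classes7) {
  if (is.data.frame(composition)) composition <- as.matrix(composition)
  vec_in <- is.null(dim(composition))
  if (vec_in) composition <- matrix(composition, nrow = 1,
                                    dimnames = list(NULL, names(composition)))
  src <- colnames(composition)
  if (is.null(src)) stop("composition must have class labels (names/colnames)")
  unknown <- setdiff(src, names(map))
  if (length(unknown) > 0)
    stop("unknown habitat class label(s): ", paste(unknown, collapse = ", "))
  out <- matrix(0, nrow(composition), length(classes),
                dimnames = list(rownames(composition), classes))
  for (cl in classes) {
    members <- src[map[src] == cl]
    if (length(members) > 0)
      out[, cl] <- rowSums(composition[, members, drop = FALSE])
  }
  if (vec_in) out[1, ] else out
}
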