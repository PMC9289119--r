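#' Species specialization index
#'
#' The species specialization index (SSI) for a species occupying `h` of `H`
#' possible classes is `sqrt(H/h - 1)`. It equals the population coefficient
#' of variation (SD/mean with divisor `H`) of the species' binary
#' presence/absence vector across the classes, so generalists (`h = H`) score
#' 0 and the index is maximal for a species confined to a single class.
#'
#' @param h Number of occupied classes (integer, `1 <= h <= H`). Vectorized.
#' @param H Total number of possible classes.
#' @return Dimensionless specialization value(s).
#' @examples
#' compute_ssi(1, 15)  # most specialized: 3.742
#' compute_ssi(6, 15)  # 1.225
#' compute_ssi(9, 9)   # full generalist: 0
#' @seealso [ssi_from_vector()], [ssi_table()]
#' @export
compute_ssi <- function(h, H) {
  if (any(h != round(h)) || any(H != round(H)))
    stop("h and H must be integers")
  if (any(h == 0))
    stop("undefined specialization: species occupies no class (h = 0)")
  if (any(h < 0) || any(H < 1))
    stop("h and H must be positive")
  if (any(h > H))
    stop("h cannot exceed H")
  sqrt(H / h - 1)
}

#' SSI from a binary occupancy vector
#'
#' @param presence Binary vector (0/1) over all `H` classes; at least one 1.
#' @param domain Optional label ("habitat" or "diet") carried to the result.
#' @return A list with `h`, `H`, `ssi` and `domain`.
#' @export
ssi_from_vector <- function(presence, domain = NA_character_) {
  if (!all(presence %in% c(0, 1)))
    stop("presence vector entries must be 0 or 1")
  h <- sum(presence)
  H <- length(presence)
  if (h == 0)
    stop("undefined specialization: all-zero presence vector")
  list(h = h, H = H, ssi = compute_ssi(h, H), domain = domain)
}

#' Per-species SSI table for habitat and diet
#'
#' Computes habitat and diet specialization from binary preference matrices.
#' `H` is the number of columns of each matrix, i.e. the full preference
#' taxonomy (15 habitat classes, 9 diet classes), not the classes observed in
#' any particular census: specialization is a species attribute independent
#' of local habitat availability.
#'
#' @param prefs_habitat Species x habitat-class binary matrix/data.frame with
#'   species as rownames (or a `species` column).
#' @param prefs_diet Optional species x diet-class binary matrix, same rules.
#' @return data.frame with columns `species`, `h_habitat`, `ssi_habitat` and,
#'   when diet preferences are given, `h_diet`, `ssi_diet`.
#' @export
ssi_table <- function(prefs_habitat, prefs_diet = NULL) {
  ph <- .pref_matrix(prefs_habitat)
  out <- data.frame(
    species = rownames(ph),
    h_habitat = rowSums(ph),
    ssi_habitat = compute_ssi(rowSums(ph), ncol(ph)),
    stringsAsFactors = FALSE
  )
  if (!is.null(prefs_diet)) {
    pd <- .pref_matrix(prefs_diet)
    if (!identical(rownames(ph), rownames(pd))) {
      pd <- pd[match(out$species, rownames(pd)), , drop = FALSE]
      if (anyNA(rownames(pd)))
        stop("species in habitat and diet preference tables do not match")
    }
    out$h_diet <- rowSums(pd)
    out$ssi_diet <- compute_ssi(rowSums(pd), ncol(pd))
  }
  rownames(out) <- NULL
  out
}

# coerce a preference table (data.frame with species column/rownames, or
# matrix) to a binary matrix with species rownames
.pref_matrix <- function(prefs) {
  if (is.data.frame(prefs)) {
    if ("species" %in% names(prefs)) {
      rn <- as.character(prefs$species)
      prefs <- prefs[setdiff(names(prefs), "species")]
      prefs <- as.matrix(prefs)
      rownames(prefs) <- rn
    } else {
      prefs <- as.matrix(prefs)
    }
  }
  if (is.null(rownames(prefs)))
    stop("preference table must identify species (rownames or species column)")
  if (!all(prefs %in% c(0, 1)))
    stop("preference entries must be binary (0/1)")
  if (any(rowSums(prefs) == 0))
    stop("species with all-zero preference row: ",
         paste(rownames(prefs)[rowSums(prefs) == 0], collapse = ", "))
  prefs
}
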