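#' First-axis PCA reduction of a trait block
#'
#' Reduces a block of continuous traits (morphology: body, wing, tail, bill
#' and tarsus lengths; or reproduction: clutch size, broods per year, egg
#' mass, life span) to its first principal component. Traits are
#' z-standardized first (correlation-matrix PCA): the blocks mix units (mm,
#' g, years), so an unscaled PCA would be dominated by whichever trait has
#' the largest numeric variance. PC1 is sign-oriented so that its loading on
#' the first column is positive; PCA axes are only defined up to sign, so
#' downstream inference must not depend on the orientation.
#'
#' @param block Species x trait numeric matrix or data.frame, species as
#'   rownames. Rows with missing values are dropped with a warning.
#' @param scale. Standardize traits before decomposition (default TRUE).
#' @return Object of class `pc_result`: list with `scores` (named PC1 score
#'   vector), `loadings` (trait x PC rotation matrix), `variance_explained`
#'   (percentage per PC, sums to 100) and `variance_explained_pc1`.
#' @export
pca_reduce <- function(block, scale. = TRUE) {
  block <- as.matrix(block)
  if (nrow(block) < 2 || ncol(block) < 2)
    stop("PCA needs at least 2 species and 2 traits")
  if (anyNA(block)) {
    keep <- stats::complete.cases(block)
    warning("dropping ", sum(!keep), " species with missing trait values")
    block <- block[keep, , drop = FALSE]
  }
  sds <- apply(block, 2, stats::sd)
  if (any(sds == 0))
    stop("constant trait column(s): ",
         paste(colnames(block)[sds == 0], collapse = ", "))
  pc <- stats::prcomp(block, center = TRUE, scale. = scale.)
  if (pc$rotation[1, 1] < 0) {
    pc$rotation[, 1] <- -pc$rotation[, 1]
    pc$x[, 1] <- -pc$x[, 1]
  }
  ve <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  structure(list(
    scores = stats::setNames(pc$x[, 1], rownames(block)),
    loadings = pc$rotation,
    variance_explained = ve,
    variance_explained_pc1 = ve[1]
  ), class = "pc_result")
}

#' @export
print.pc_result <- function(x, ...) {
  cat(sprintf("PC1 over %d traits, %d species; %.2f%% of variance\n",
              nrow(x$loadings), length(x$scores), x$variance_explained_pc1))
  cat("PC1 loadings:\n")
  print(round(x$loadings[, 1], 3))
  invisible(x)
}

#' Average sex-specific trait columns
#'
#' Columns named `<trait>_f` and `<trait>_m` are replaced by their mean
#' `<trait>`, computed before any transformation.
#'
#' @param traits data.frame of trait values.
#' @return data.frame with sex-specific pairs averaged.
#' @export
sex_average <- function(traits) {
  fcols <- grep("_f$", names(traits), value = TRUE)
  for (fc in fcols) {
    base <- sub("_f$", "", fc)
    mc <- paste0(base, "_m")
    if (mc %in% names(traits)) {
      traits[[base]] <- (traits[[fc]] + traits[[mc]]) / 2
      traits[[fc]] <- NULL
      traits[[mc]] <- NULL
    }
  }
  traits
}

#' Assemble the per-species predictor table for the density models
#'
#' Merges trait values, specialization indices and PC scores into one
#' regression-ready table: natural-log body mass, the structural-size and
#' slow-fast PC scores (ssPC, sfPC), habitat and diet SSI, breeding range,
#' and treatment-coded nest-type dummies with ground nests (`G`) as the
#' reference level. Body mass is kept separate from the PC blocks; because it
#' correlates with both PCs, the pairwise correlations (body mass vs ssPC,
#' body mass vs sfPC, ssPC vs sfPC) are recorded in the `correlations`
#' attribute so the modelling stage can report them.
#'
#' @param traits data.frame with `species`, `body_mass`, `nest_type` (levels
#'   G, GC, H, OA), `breeding_range` and optionally `forest_dependency`.
#' @param ssi data.frame from [ssi_table()].
#' @param pca_morph,pca_repro `pc_result` objects for the morphological and
#'   reproductive blocks.
#' @return data.frame keyed by `species` with columns `log_body_mass`,
#'   `ssPC`, `sfPC`, `ssi_habitat`, `ssi_diet`, `breeding_range`,
#'   `nest_type` (factor, reference G) and dummies `nestGC`, `nestH`,
#'   `nestOA`; attribute `correlations`.
#' @export
prepare_predictors <- function(traits, ssi, pca_morph, pca_repro) {
  sp <- as.character(traits$species)
  miss <- setdiff(sp, as.character(ssi$species))
  miss <- union(miss, setdiff(as.character(ssi$species), sp))
  miss <- union(miss, setdiff(sp, names(pca_morph$scores)))
  miss <- union(miss, setdiff(sp, names(pca_repro$scores)))
  if (length(miss) > 0)
    stop("species keys do not align across tables: ",
         paste(sort(miss), collapse = ", "))
  if (any(traits$body_mass <= 0)) stop("body mass must be positive")
  nest <- factor(as.character(traits$nest_type),
                 levels = c("G", "GC", "H", "OA"))
  if (anyNA(nest)) stop("nest_type must be one of G, GC, H, OA")
  out <- data.frame(
    species = sp,
    log_body_mass = log(traits$body_mass),
    ssPC = unname(pca_morph$scores[sp]),
    sfPC = unname(pca_repro$scores[sp]),
    ssi_habitat = ssi$ssi_habitat[match(sp, ssi$species)],
    ssi_diet = ssi$ssi_diet[match(sp, ssi$species)],
    breeding_range = traits$breeding_range,
    nest_type = nest,
    nestGC = as.integer(nest == "GC"),
    nestH = as.integer(nest == "H"),
    nestOA = as.integer(nest == "OA"),
    stringsAsFactors = FALSE
  )
  if (!is.null(traits$forest_dependency))
    out$forest_dependency <- traits$forest_dependency
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }
  attr(out, "correlations") <- c(
    body_mass_ssPC = safe_cor(out$log_body_mass, out$ssPC),
    body_mass_sfPC = safe_cor(out$log_body_mass, out$sfPC),
    ssPC_sfPC = safe_cor(out$ssPC, out$sfPC)
  )
  out
}
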