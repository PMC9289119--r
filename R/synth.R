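#' Configuration for the synthetic census generator
#'
#' Bundles and validates all parameters of the synthetic study system: a
#' mosaic landscape of census points, a bird community whose within-habitat
#' intensity is linked to habitat specialization, Brownian traits on a
#' simulated phylogeny, and a sample of perturbed trees.
#'
#' Defaults emulate the scale of a country-wide point-count scheme analysed
#' at the species level: 1000 points in transects of 20, 150 species,
#' habitat-niche breadths of 1-6 of the 15 preference classes (specialization
#' index between 1.22 and 3.74, median near 2), a baseline of 0.3
#' individuals per hectare of suitable habitat, and a log-linear
#' specialization-intensity link with slope `ssi_effect` (so `ssi_effect = 0`
#' is an exact null). Species intensities additionally carry a Brownian
#' species effect on the log scale (`phylo_sigma2`, rate per unit height of
#' the unit-height tree): real abundances are phylogenetically conserved,
#' and this is the component that makes the Brownian GLS residual model
#' appropriate for the generated data.
#'
#' @param n_points Number of census points (>= 1).
#' @param n_species Number of species (>= 3).
#' @param habitat_classes Aggregated landscape classes (default the 7
#'   analysis classes).
#' @param dirichlet_concentration Dirichlet concentration of point
#'   compositions; larger = more homogeneous points; `Inf` gives every point
#'   the uniform composition.
#' @param niche_breadth_prob Probabilities over habitat-niche breadth
#'   h = 1, 2, ... (at most 15 values).
#' @param diet_breadth_prob Probabilities over diet-niche breadth h = 1..9.
#' @param base_intensity Expected individuals per ha of suitable habitat for
#'   an average (SSI = 0, no species effect) species.
#' @param ssi_effect Slope gamma of log intensity on habitat SSI.
#' @param phylo_sigma2 Brownian rate of the log-intensity species effect
#'   (0 disables it).
#' @param tree_birth_rate Yule speciation rate of the base tree.
#' @param trait_sigma2 Brownian rate of the latent trait axes.
#' @param n_trees Number of perturbed trees in the tree sample.
#' @param jitter_sd Lognormal SD of the branch-length jitter applied to each
#'   perturbed tree (0 = exact copies).
#' @param n_nni Number of random NNI topology moves per perturbed tree.
#' @param nest_type_prob Named probabilities for nest types G, GC, H, OA.
#' @param niche_model `"general"`: niches are random subsets of all 15
#'   preference classes, so specialists also have less suitable area.
#'   `"single_biotope"`: all species prefer source classes within the open
#'   biotope group only, so habitat availability is identically distributed
#'   across specialization levels -- a balanced-habitat design that isolates
#'   the specialization-intensity link from the availability confound.
#' @param points_per_transect Points per transect (default 20).
#' @param seed Optional integer; every generator derives its own substream
#'   from it, making all outputs bit-reproducible.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_points = 1000,
                       n_species = 150,
                       habitat_classes = aggregated_classes7,
                       dirichlet_concentration = 1,
                       niche_breadth_prob = c(0.15, 0.30, 0.25, 0.15,
                                              0.10, 0.05),
                       diet_breadth_prob = c(0.20, 0.30, 0.20, 0.10, 0.07,
                                             0.05, 0.03, 0.02, 0.03),
                       base_intensity = 0.3,
                       ssi_effect = 0.2,
                       phylo_sigma2 = 0.25,
                       tree_birth_rate = 1,
                       trait_sigma2 = 1,
                       n_trees = 10,
                       jitter_sd = 0.1,
                       n_nni = 0,
                       nest_type_prob = c(G = 0.3, GC = 0.1, H = 0.3,
                                          OA = 0.3),
                       niche_model = c("general", "single_biotope"),
                       points_per_transect = 20,
                       seed = NULL) {
  niche_model <- match.arg(niche_model)
  if (n_points < 1) stop("n_points must be >= 1")
  if (n_species < 3) stop("n_species must be >= 3")
  if (!(dirichlet_concentration > 0))
    stop("dirichlet_concentration must be strictly positive")
  if (base_intensity <= 0) stop("base_intensity must be strictly positive")
  if (tree_birth_rate <= 0) stop("tree_birth_rate must be strictly positive")
  if (trait_sigma2 < 0 || phylo_sigma2 < 0 || jitter_sd < 0)
    stop("variance parameters must be non-negative")
  if (any(niche_breadth_prob < 0) || sum(niche_breadth_prob) <= 0 ||
      length(niche_breadth_prob) > length(preference_classes15))
    stop("invalid niche_breadth_prob")
  if (any(diet_breadth_prob < 0) || sum(diet_breadth_prob) <= 0 ||
      length(diet_breadth_prob) > length(diet_classes9))
    stop("invalid diet_breadth_prob")
  structure(as.list(environment()), class = "sim_config")
}

# per-stage RNG substream: independent, reproducible stages from one seed
.stage_seed <- function(cfg, stage) {
  if (is.null(cfg$seed)) return(invisible(NULL))
  offsets <- c(landscape = 11L, niches = 23L, trees = 37L, traits = 53L,
               community = 71L)
  set.seed((as.integer(cfg$seed) + offsets[[stage]] * 1009L) %%
             .Machine$integer.max)
}

#' Simulate a mosaic landscape of census points
#'
#' Each point gets a habitat composition drawn from a symmetric Dirichlet
#' over the aggregated classes (via normalized gamma draws);
#' `dirichlet_concentration = Inf` gives the exact uniform composition.
#' Points are grouped into transects; every point covers [point_area_ha]
#' hectares (100 m census radius).
#'
#' @param cfg A [sim_config()].
#' @return data.frame with `point`, `transect` and one proportion column per
#'   habitat class (rows sum to 1).
#' @export
simulate_landscape <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  .stage_seed(cfg, "landscape")
  H <- length(cfg$habitat_classes)
  n <- cfg$n_points
  if (is.infinite(cfg$dirichlet_concentration)) {
    comp <- matrix(1 / H, n, H)
  } else {
    g <- matrix(stats::rgamma(n * H, shape = cfg$dirichlet_concentration),
                n, H)
    comp <- g / rowSums(g)
  }
  colnames(comp) <- cfg$habitat_classes
  out <- data.frame(
    point = sprintf("pt%05d", seq_len(n)),
    transect = sprintf("tr%04d",
                       (seq_len(n) - 1) %/% cfg$points_per_transect + 1),
    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(comp))
}

#' Simulate binary niche (preference) vectors
#'
#' Draws habitat-niche breadths from `niche_breadth_prob` and assigns the
#' preferred source classes at random (under `niche_model =
#' "single_biotope"`, only from the open-biotope source classes), plus diet
#' preference vectors over the 9 diet classes.
#'
#' @param cfg A [sim_config()].
#' @return List with binary matrices `habitat` (species x 15) and `diet`
#'   (species x 9), species as rownames.
#' @export
simulate_niches <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  .stage_seed(cfg, "niches")
  sp <- sprintf("sp%03d", seq_len(cfg$n_species))
  open_src <- names(preference_to_aggregated)[
    preference_to_aggregated == "open"]
  pool <- if (cfg$niche_model == "single_biotope") open_src
          else preference_classes15
  pb <- cfg$niche_breadth_prob
  pb <- pb[seq_len(min(length(pb), length(pool)))]
  hab <- matrix(0L, cfg$n_species, length(preference_classes15),
                dimnames = list(sp, preference_classes15))
  h <- sample(seq_along(pb), cfg$n_species, replace = TRUE, prob = pb)
  for (i in seq_len(cfg$n_species))
    hab[i, sample(pool, h[i])] <- 1L
  diet <- matrix(0L, cfg$n_species, length(diet_classes9),
                 dimnames = list(sp, diet_classes9))
  hd <- sample(seq_along(cfg$diet_breadth_prob), cfg$n_species,
               replace = TRUE, prob = cfg$diet_breadth_prob)
  for (i in seq_len(cfg$n_species))
    diet[i, sample(diet_classes9, hd[i])] <- 1L
  list(habitat = hab, diet = diet)
}

#' Simulate a Yule tree and a sample of perturbed trees
#'
#' Grows a pure-birth tree over the species, rescales it to unit height
#' (the Brownian GLS profiles the overall scale out anyway), and derives
#' `n_trees` variants by lognormal branch-length jitter and optional random
#' NNI moves, emulating the topological/branch-length uncertainty of a
#' posterior tree sample.
#'
#' @param cfg A [sim_config()].
#' @return List with `base` (the generating tree) and `trees` (list of
#'   `n_trees` perturbed trees over the same tips).
#' @export
simulate_tree_set <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  .stage_seed(cfg, "trees")
  base <- ape::rphylo(cfg$n_species, birth = cfg$tree_birth_rate, death = 0)
  base$tip.label <- sprintf("sp%03d", seq_len(cfg$n_species))
  base$edge.length <- base$edge.length /
    max(ape::node.depth.edgelength(base))
  trees <- lapply(seq_len(cfg$n_trees), function(i) {
    tr <- base
    if (cfg$n_nni > 0) tr <- phangorn::rNNI(tr, moves = cfg$n_nni)
    if (cfg$jitter_sd > 0)
      tr$edge.length <- tr$edge.length *
        stats::rlnorm(length(tr$edge.length),
                      meanlog = -cfg$jitter_sd^2 / 2,
                      sdlog = cfg$jitter_sd)
    tr
  })
  list(base = base, trees = trees)
}

#' Simulate Brownian motion on a tree
#'
#' Propagates independent Gaussian increments (variance `sigma2` times
#' branch length) from a root value of 0 down every edge, visiting parents
#' before children.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param sigma2 Brownian rate (variance per unit branch length).
#' @param n_traits Number of independent replicate traits.
#' @return Tip x trait matrix (rownames = tip labels).
#' @export
simulate_bm <- function(tree, sigma2, n_traits = 1) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  ntip <- length(tree$tip.label)
  x <- matrix(0, ntip + tree$Nnode, n_traits)
  cw <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(cw$edge))) {
    par <- cw$edge[k, 1]; child <- cw$edge[k, 2]
    x[child, ] <- x[par, ] +
      stats::rnorm(n_traits, 0, sqrt(sigma2 * cw$edge.length[k]))
  }
  out <- x[seq_len(ntip), , drop = FALSE]
  rownames(out) <- tree$tip.label
  out
}

#' Simulate species trait values on a phylogeny
#'
#' Morphological traits share a Brownian latent size axis (plus small
#' independent Brownian deviations), reproductive traits share a latent
#' pace-of-life axis with slow-fast loadings (clutch size and broods
#' positive, egg mass and life span negative), and body mass follows the
#' size axis; all are exponentiated to positive measurement scales. Nest
#' type and forest dependency are categorical draws; breeding range is
#' lognormal and phylogenetically unstructured.
#'
#' @param tree Rooted `phylo` over the species.
#' @param cfg A [sim_config()].
#' @return data.frame with `species`, five morphological traits (mm), four
#'   reproductive traits, `body_mass` (g), `breeding_range` (km2),
#'   `nest_type` and `forest_dependency`.
#' @export
simulate_traits <- function(tree, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(tree$edge.length) || all(tree$edge.length == 0))
    stop("tree must have positive branch lengths")
  .stage_seed(cfg, "traits")
  sp <- tree$tip.label
  s2 <- cfg$trait_sigma2
  size <- simulate_bm(tree, s2)[, 1]
  pace <- simulate_bm(tree, s2)[, 1]
  # small independent Brownian deviations around the shared latent axes:
  # morphometric traits are near-collinear in real birds, life-history
  # traits only slightly less so
  idio <- function(rate) simulate_bm(tree, rate * s2)[, 1]
  out <- data.frame(
    species = sp,
    body_length = exp(5.0 + size + idio(0.05)),
    wing_length = exp(4.6 + size + idio(0.05)),
    tail_length = exp(4.2 + size + idio(0.05)),
    bill_length = exp(2.6 + size + idio(0.05)),
    tarsus_length = exp(3.1 + size + idio(0.05)),
    clutch_size = exp(1.5 + 0.8 * pace + idio(0.03)),
    broods_per_year = exp(0.3 + 0.8 * pace + idio(0.03)),
    egg_mass = exp(0.7 - 0.8 * pace + idio(0.03)),
    life_span = exp(2.0 - 0.8 * pace + idio(0.03)),
    body_mass = exp(3.0 + 1.2 * size + idio(0.05)),
    breeding_range = exp(stats::rnorm(length(sp), 14, 1)),
    nest_type = sample(names(cfg$nest_type_prob), length(sp),
                       replace = TRUE, prob = cfg$nest_type_prob),
    forest_dependency = sample(c("none", "low", "medium", "high"),
                               length(sp), replace = TRUE),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Simulate a point-count community census
#'
#' Species counts at each point and visit are Poisson with mean
#' `intensity_s * suitable_area_sp`, where the suitable area is computed
#' exactly as in [suitable_area()] and the within-suitable-habitat intensity
#' is `base_intensity * exp(ssi_effect * SSI_s + eps_s)` with an optional
#' Brownian species effect `eps` on the supplied tree. The two visits are
#' independent draws.
#'
#' @param cfg A [sim_config()].
#' @param landscape Output of [simulate_landscape()].
#' @param niches Output of [simulate_niches()].
#' @param tree Tree for the Brownian species effect (required when
#'   `phylo_sigma2 > 0`).
#' @return List with `counts` (long data.frame: point, transect, visit,
#'   species, count) and `truth` (niche matrix, true SSI, species effects,
#'   true intensities).
#' @export
simulate_community <- function(cfg, landscape, niches, tree = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  .stage_seed(cfg, "community")
  comp <- as.matrix(landscape[cfg$habitat_classes])
  rownames(comp) <- landscape$point
  ssi <- compute_ssi(rowSums(niches$habitat), ncol(niches$habitat))
  eps <- if (cfg$phylo_sigma2 > 0) {
    if (is.null(tree)) stop("tree required when phylo_sigma2 > 0")
    simulate_bm(tree, cfg$phylo_sigma2)[rownames(niches$habitat), 1]
  } else {
    stats::setNames(numeric(nrow(niches$habitat)), rownames(niches$habitat))
  }
  intensity <- cfg$base_intensity * exp(cfg$ssi_effect * ssi + eps)
  sa <- suitable_area(comp, niches$habitat)  # points x species, ha
  lambda <- sweep(sa, 2, intensity, "*")
  sp <- colnames(sa)
  counts <- do.call(rbind, lapply(1:2, function(v) {
    cnt <- matrix(stats::rpois(length(lambda), lambda), nrow(lambda))
    data.frame(point = rep(landscape$point, times = length(sp)),
               transect = rep(landscape$transect, times = length(sp)),
               visit = v,
               species = rep(sp, each = nrow(lambda)),
               count = as.vector(cnt),
               stringsAsFactors = FALSE)
  }))
  rownames(counts) <- NULL
  list(counts = counts,
       truth = list(niche = niches$habitat, ssi = ssi, epsilon = eps,
                    intensity = intensity))
}

#' Simulate a complete synthetic study
#'
#' Runs every generator in order (landscape, niches, tree sample, traits,
#' community) under the configuration's seed substreams.
#'
#' @param cfg A [sim_config()].
#' @return List with `landscape`, `niches`, `trees`, `traits`, `counts` and
#'   `truth`.
#' @export
simulate_dataset <- function(cfg) {
  landscape <- simulate_landscape(cfg)
  niches <- simulate_niches(cfg)
  trees <- simulate_tree_set(cfg)
  traits <- simulate_traits(trees$base, cfg)
  comm <- simulate_community(cfg, landscape, niches, trees$base)
  list(landscape = landscape, niches = niches, trees = trees,
       traits = traits, counts = comm$counts, truth = comm$truth,
       config = cfg)
}
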