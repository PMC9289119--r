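test_that("landscape compositions are probability vectors over the classes", {
  cfg <- sim_config(n_points = 20, n_species = 5, seed = 1)
  lsc <- simulate_landscape(cfg)
  comp <- as.matrix(lsc[aggregated_classes7])
  expect_equal(nrow(comp), 20)
  expect_equal(unname(rowSums(comp)), rep(1, 20), tolerance = 1e-12)
  expect_true(all(comp >= 0))
  expect_equal(length(unique(lsc$transect)), 1)  # 20 points = 1 transect
})

test_that("infinite Dirichlet concentration gives the uniform composition", {
  cfg <- sim_config(n_points = 6, n_species = 5,
                    dirichlet_concentration = Inf, seed = 1)
  comp <- as.matrix(simulate_landscape(cfg)[aggregated_classes7])
  expect_equal(unname(comp), matrix(1 / 7, 6, 7))
})

test_that("generators are bit-reproducible under a fixed seed", {
  cfg <- sim_config(n_points = 30, n_species = 8, n_trees = 3, seed = 99)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$landscape, d2$landscape)
  expect_identical(d1$counts, d2$counts)
  expect_identical(d1$traits, d2$traits)
  expect_identical(ape::write.tree(d1$trees$base),
                   ape::write.tree(d2$trees$base))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_species = 2), "n_species")
  expect_error(sim_config(n_points = 0), "n_points")
  expect_error(sim_config(dirichlet_concentration = 0), "concentration")
  expect_error(sim_config(base_intensity = -1), "base_intensity")
})

test_that("species never occur where their niche misses the habitat", {
  cfg <- sim_config(n_points = 40, n_species = 10, seed = 3)
  lsc <- simulate_landscape(cfg)
  # force a water-only landscape and a forest-only species
  lsc[aggregated_classes7] <- 0
  lsc$water <- 1
  niches <- simulate_niches(cfg)
  niches$habitat[1, ] <- 0L
  niches$habitat[1, "coniferous_forest"] <- 1L
  cfg2 <- sim_config(n_points = 40, n_species = 10, phylo_sigma2 = 0,
                     seed = 3)
  comm <- simulate_community(cfg2, lsc, niches)
  sp1 <- rownames(niches$habitat)[1]
  expect_equal(sum(comm$counts$count[comm$counts$species == sp1]), 0)
})

test_that("counts are Poisson with intensity x suitable-area mean", {
  # gamma = 0, every species suited everywhere -> mean count per point/visit
  # equals base_intensity * point area
  cfg <- sim_config(n_points = 400, n_species = 10, ssi_effect = 0,
                    phylo_sigma2 = 0, base_intensity = 0.5, seed = 4)
  lsc <- simulate_landscape(cfg)
  niches <- simulate_niches(cfg)
  niches$habitat[] <- 1L
  comm <- simulate_community(cfg, lsc, niches)
  mean_count <- mean(comm$counts$count)
  expected <- 0.5 * pi
  se <- sqrt(expected / (400 * 10 * 2))
  expect_lt(abs(mean_count - expected), 4 * se)
  expect_true(all(comm$counts$count >= 0))
  expect_true(all(comm$counts$count == round(comm$counts$count)))
  # intensities carried in the ground truth match the configured law
  expect_equal(unname(comm$truth$intensity),
               unname(0.5 * exp(0 * comm$truth$ssi + comm$truth$epsilon)))
})

test_that("tree sets share tips; zero jitter reproduces the base topology", {
  cfg <- sim_config(n_points = 10, n_species = 12, n_trees = 5,
                    jitter_sd = 0, seed = 6)
  ts <- simulate_tree_set(cfg)
  expect_length(ts$trees, 5)
  for (tr in ts$trees) {
    expect_equal(sort(tr$tip.label), sort(ts$base$tip.label))
    expect_length(unique(tr$tip.label), 12)
  }
  expect_identical(ape::write.tree(ts$trees[[1]]),
                   ape::write.tree(ts$base))
  cons <- consensus_tree(ts$trees)
  expect_equal(ape::cophenetic.phylo(cons)[ts$base$tip.label,
                                           ts$base$tip.label],
               ape::cophenetic.phylo(ts$base)[ts$base$tip.label,
                                              ts$base$tip.label],
               tolerance = 1e-12)
  # base tree rescaled to unit height
  expect_equal(max(ape::node.depth.edgelength(ts$base)), 1)
})

test_that("Brownian simulation matches the closed-form contrast variance", {
  tr <- ape::read.tree(text = "(A:0.7,B:0.7);")
  set.seed(8)
  contrasts <- replicate(1000, {
    x <- simulate_bm(tr, sigma2 = 2)
    x["A", 1] - x["B", 1]
  })
  # var of tip contrast = 2 * sigma2 * t
  v <- 2 * 2 * 0.7
  expect_lt(abs(var(contrasts) - v), 4 * v * sqrt(2 / 999))
})

test_that("zero trait variance collapses all traits to the root value", {
  cfg <- sim_config(n_points = 10, n_species = 8, trait_sigma2 = 0, seed = 9)
  ts <- simulate_tree_set(cfg)
  traits <- simulate_traits(ts$base, cfg)
  for (cl in c("body_length", "clutch_size", "body_mass"))
    expect_equal(length(unique(traits[[cl]])), 1)
  expect_error(simulate_traits(structure(list(tip.label = "A"),
                                         class = "phylo"), cfg),
               "branch lengths")
})

test_that("niche breadths follow the configured distribution support", {
  cfg <- sim_config(n_points = 10, n_species = 200,
                    niche_breadth_prob = c(0, 0, 1), seed = 10)
  niches <- simulate_niches(cfg)
  expect_true(all(rowSums(niches$habitat) == 3))
  expect_true(all(niches$habitat %in% 0:1))
  # balanced design: only open-biotope source classes are ever used
  cfgb <- sim_config(n_points = 10, n_species = 50,
                     niche_model = "single_biotope", seed = 11)
  nb <- simulate_niches(cfgb)
  open_src <- names(preference_to_aggregated)[
    preference_to_aggregated == "open"]
  expect_true(all(nb$habitat[, setdiff(preference_classes15, open_src)] == 0))
})

test_that("ecological density recovers the specialization-intensity link", {
  # gamma > 0: log ecological density regresses on true SSI with slope
  # near gamma (Monte-Carlo, one large landscape)
  cfg <- sim_config(n_points = 1500, n_species = 60, ssi_effect = 0.4,
                    phylo_sigma2 = 0, seed = 12)
  lsc <- simulate_landscape(cfg)
  niches <- simulate_niches(cfg)
  comm <- simulate_community(cfg, lsc, niches)
  dens <- suppressWarnings(
    density_table(comm$counts, lsc, niches$habitat))
  ssi <- comm$truth$ssi[dens$species]
  slope <- coef(lm(log(dens$eco_density) ~ ssi))[2]
  expect_gt(slope, 0)
  expect_lt(abs(slope - 0.4), 0.15)
})
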