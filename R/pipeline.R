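#' Configuration for an end-to-end analysis run
#'
#' Exactly one of `sim` (a [sim_config()] for a synthetic study) or `inputs`
#' (paths to census/trait files) must be supplied.
#'
#' @param sim A [sim_config()] for synthetic data.
#' @param inputs Named list of file paths: `counts`, `habitat`,
#'   `prefs_habitat`, `prefs_diet`, `traits` (CSV) and `trees` (Newick, one
#'   per line).
#' @param density_mode `"presence"` or `"all_points"` (see
#'   [ecological_density()]).
#' @param log_response Model log-transformed densities. The default (FALSE)
#'   fits raw densities; the log scale is appropriate when density variation
#'   is multiplicative.
#' @param consensus_threshold Majority-rule threshold for
#'   [consensus_tree()].
#' @param delta_cut AIC retention window for [select_and_average()].
#' @param method `"ML"` or `"REML"` for the single-predictor fits (dredging
#'   always compares ML AICs).
#' @param pc Which trait PC enters the full models: `"ssPC"`, `"sfPC"` or
#'   `"both"` (two separate model sets; the PCs never co-occur in one model
#'   because of their high correlation).
#' @param stability Also rerun dredging over every tree in the sample and
#'   report coefficient stability.
#' @param seed Integer seed recorded in the report; seeds the simulation
#'   substreams.
#' @param out_dir Optional output directory for CSV/JSON/Newick artifacts.
#' @return Object of class `run_config`.
#' @export
run_config <- function(sim = NULL, inputs = NULL,
                       density_mode = c("presence", "all_points"),
                       log_response = FALSE,
                       consensus_threshold = 0.5,
                       delta_cut = 2,
                       method = "ML",
                       pc = c("ssPC", "sfPC", "both"),
                       stability = FALSE,
                       seed = 1L,
                       out_dir = NULL) {
  if (is.null(sim) == is.null(inputs))
    stop("exactly one of `sim` or `inputs` must be given")
  if (!is.null(sim)) {
    stopifnot(inherits(sim, "sim_config"))
    sim$seed <- as.integer(seed)
  }
  structure(list(sim = sim, inputs = inputs,
                 density_mode = match.arg(density_mode),
                 log_response = log_response,
                 consensus_threshold = consensus_threshold,
                 delta_cut = delta_cut, method = method,
                 pc = match.arg(pc), stability = stability,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

.morph_traits <- c("body_length", "wing_length", "tail_length",
                   "bill_length", "tarsus_length")
.repro_traits <- c("clutch_size", "broods_per_year", "egg_mass", "life_span")

#' Run the full density-trait analysis
#'
#' Executes every stage in order: data (simulated or loaded), per-species
#' densities in geographical and ecological space, habitat and diet SSI,
#' trait PCAs and predictor assembly, consensus tree and Brownian
#' covariance, the single-predictor PGLS suite, all-subsets dredging with
#' delta-AIC selection and full model averaging for both density responses,
#' and (optionally) the robustness of the averaged coefficients over the
#' tree sample. Each stage failure is reported with the stage name.
#'
#' The dredged full models contain nest type, one trait PC, habitat SSI,
#' diet SSI and breeding range; body mass is excluded from the full models
#' because it correlates with both PCs (the correlations are recorded in the
#' report).
#'
#' @param cfg A [run_config()].
#' @return (Invisibly) a list with all intermediate tables, the fitted
#'   objects, and `report`: row counts, predictor correlations, retained
#'   model counts and the averaged habitat-SSI coefficients (the headline
#'   contrast between geographical and ecological space). With `out_dir`
#'   set, writes `densities.csv`, `ssi.csv`, `predictors.csv`, `table1.csv`,
#'   `dredge_<response>_<pc>.csv`, `table2_<response>_<pc>.csv`,
#'   `consensus.nwk`, `stability.csv` (optional) and `report.json`.
#' @export
run_ecodensity <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  warnings_log <- character(0)
  stage <- function(name, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e)
        stop("stage `", name, "` failed: ", conditionMessage(e),
             call. = FALSE)),
      warning = function(w) {
        warnings_log <<- c(warnings_log,
                           paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }

  dat <- stage("data", {
    if (!is.null(cfg$sim)) {
      sd <- simulate_dataset(cfg$sim)
      list(counts = sd$counts, habitat = sd$landscape,
           prefs_habitat = sd$niches$habitat, prefs_diet = sd$niches$diet,
           traits = sd$traits, trees = sd$trees$trees, truth = sd$truth)
    } else {
      ins <- cfg$inputs
      list(counts = utils::read.csv(ins$counts),
           habitat = utils::read.csv(ins$habitat),
           prefs_habitat = utils::read.csv(ins$prefs_habitat),
           prefs_diet = if (!is.null(ins$prefs_diet))
             utils::read.csv(ins$prefs_diet),
           traits = utils::read.csv(ins$traits),
           trees = read_trees(ins$trees),
           truth = NULL)
    }
  })

  dens <- stage("density",
    density_table(dat$counts, dat$habitat, dat$prefs_habitat,
                  mode = cfg$density_mode))
  ssi <- stage("ssi", ssi_table(dat$prefs_habitat, dat$prefs_diet))
  traits <- stage("traits_input", sex_average(dat$traits))
  pca_morph <- stage("pca_morph",
    pca_reduce(.block_matrix(traits, .morph_traits)))
  pca_repro <- stage("pca_repro",
    pca_reduce(.block_matrix(traits, .repro_traits)))
  preds <- stage("predictors",
    prepare_predictors(traits, ssi, pca_morph, pca_repro))

  model_data <- stage("merge", {
    md <- merge(preds, dens, by = "species")
    dropped <- setdiff(preds$species, md$species)
    if (length(dropped) > 0)
      warning(length(dropped), " species without density estimates ",
              "dropped from the models")
    if (cfg$log_response) {
      md$geo_density <- log(md$geo_density)
      md$eco_density <- log(md$eco_density)
    }
    md[order(md$species), ]
  })

  cons <- stage("consensus",
    consensus_tree(dat$trees, threshold = cfg$consensus_threshold))
  V <- stage("vcv", brownian_vcv(cons, species_order = model_data$species))

  table1 <- stage("single_predictor_suite",
    single_predictor_suite(model_data, V, method = cfg$method))

  pcs <- if (cfg$pc == "both") c("ssPC", "sfPC") else cfg$pc
  dredges <- list(); table2 <- list()
  for (resp in c("geo_density", "eco_density")) {
    for (pc in pcs) {
      key <- paste(resp, pc, sep = "_")
      f <- stats::reformulate(
        c("nest_type", pc, "ssi_habitat", "ssi_diet", "breeding_range"),
        response = resp)
      dredges[[key]] <- stage(paste0("dredge_", key),
        dredge_pgls(f, model_data, V))
      table2[[key]] <- stage(paste0("average_", key),
        select_and_average(dredges[[key]], delta_cut = cfg$delta_cut))
    }
  }

  stability <- NULL
  if (cfg$stability) {
    f <- stats::reformulate(
      c("nest_type", pcs[1], "ssi_habitat", "ssi_diet", "breeding_range"),
      response = "eco_density")
    stability <- stage("stability",
      dredge_over_trees(f, model_data, dat$trees, delta_cut = cfg$delta_cut,
                        consensus = cons))
  }

  ssi_coef <- function(key) {
    co <- table2[[key]]$coefficients
    co$estimate[co$term == "ssi_habitat"]
  }
  report <- list(
    seed = cfg$seed,
    n_points = length(unique(dat$counts$point)),
    n_species_counted = length(unique(dat$counts$species)),
    n_species_modelled = nrow(model_data),
    density_mode = cfg$density_mode,
    log_response = cfg$log_response,
    geo_density_range = range(dens$geo_density),
    eco_density_range = range(dens$eco_density),
    ssi_habitat_range = range(ssi$ssi_habitat),
    pca_variance_pc1 = c(ssPC = pca_morph$variance_explained_pc1,
                         sfPC = pca_repro$variance_explained_pc1),
    predictor_correlations = attr(preds, "correlations"),
    n_retained_models = vapply(table2, function(a) a$n_retained, 0),
    ssi_habitat_coefficient = vapply(names(table2), ssi_coef, 0),
    warnings = warnings_log)

  out <- list(config = cfg, data = dat, densities = dens, ssi = ssi,
              pca_morph = pca_morph, pca_repro = pca_repro,
              predictors = preds, model_data = model_data,
              consensus = cons, V = V, table1 = table1,
              dredges = dredges, table2 = table2, stability = stability,
              report = report)
  if (!is.null(cfg$out_dir)) stage("write", .write_outputs(out, cfg$out_dir))
  invisible(out)
}

.block_matrix <- function(traits, cols) {
  m <- as.matrix(traits[cols])
  rownames(m) <- traits$species
  m
}

.write_outputs <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, name)
    utils::write.csv(x, file.path(dir, name), row.names = FALSE)
  wcsv(out$densities, "densities.csv")
  wcsv(out$ssi, "ssi.csv")
  wcsv(out$predictors, "predictors.csv")
  wcsv(out$table1, "table1.csv")
  for (key in names(out$dredges)) {
    wcsv(out$dredges[[key]]$table, paste0("dredge_", key, ".csv"))
    wcsv(out$table2[[key]]$coefficients, paste0("table2_", key, ".csv"))
  }
  if (!is.null(out$stability)) wcsv(out$stability, "stability.csv")
  ape::write.tree(out$consensus, file.path(dir, "consensus.nwk"))
  jsonlite::write_json(out$report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}
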