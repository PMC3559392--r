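#' Build a run configuration
#'
#' Collects paths, thermodynamic constants, solver settings and output
#' conventions for an end-to-end run. Unspecified fields take the documented
#' defaults; a configuration round-trips through a JSON (or YAML) file via
#' [readRunConfig()] / [writeRunConfig()].
#'
#' @param model path to a model (SBML file or tabular directory), or `NULL`
#'   to generate a synthetic model.
#' @param format `"sbml"` or `"tabular"`.
#' @param formation,reaction_energies paths to energy-table TSVs (`NULL`
#'   with a synthetic model: its masked tables are used).
#' @param media optional media TSV (`reaction_id`, `lb`, `ub`).
#' @param out_dir output directory.
#' @param temperature,gas_constant,default_conc constants of the millimolar
#'   adjustment (K; energy mol^-1 K^-1; mol/L).
#' @param energy_unit unit label carried through all outputs.
#' @param bin_edges interior histogram edges (must contain 0).
#' @param zero_tol zero tolerance for fluxes and weights.
#' @param pfba apply the parsimonious secondary objective after FBA.
#' @param svd_tol relative singular-value cutoff of the least squares.
#' @param strict strict input validation (duplicate/unmatched ids error).
#' @param seed seed for the synthetic generator.
#' @param synthetic named list overriding [syntheticSpec()] arguments.
#' @return a `list` of class `"thermoweight_config"`.
#' @export
runConfig <- function(model = NULL, format = "tabular", formation = NULL,
                      reaction_energies = NULL, media = NULL,
                      out_dir = "thermoweight_run", temperature = 298,
                      gas_constant = 1.987e-3, default_conc = 0.001,
                      energy_unit = "kcal/mol",
                      bin_edges = c(-200, -100, -50, 0, 40, 100),
                      zero_tol = 1e-9, pfba = FALSE, svd_tol = 1e-10,
                      strict = FALSE, seed = 1, synthetic = list()) {
  cfg <- list(model = model, format = format, formation = formation,
              reaction_energies = reaction_energies, media = media,
              out_dir = out_dir, temperature = temperature,
              gas_constant = gas_constant, default_conc = default_conc,
              energy_unit = energy_unit, bin_edges = bin_edges,
              zero_tol = zero_tol, pfba = pfba, svd_tol = svd_tol,
              strict = strict, seed = seed, synthetic = synthetic)
  class(cfg) <- "thermoweight_config"
  cfg
}

#' @rdname runConfig
#' @param path a JSON (`.json`) or YAML (`.yml`/`.yaml`) config file.
#' @export
readRunConfig <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs needs the yaml package", call. = FALSE)
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(runConfig))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(runConfig, raw)
}

#' @rdname runConfig
#' @param config a `thermoweight_config`.
#' @export
writeRunConfig <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Run the full pipeline: complete, adjust, FBA, weights, balance
#'
#' Executes the stages in order — load (or generate) the model, assemble the
#' energy tables, infer unknown formation energies and complete the reaction
#' energies, adjust to the millimolar reference, solve FBA (with optional
#' media), compute weights, histogram, extreme-reaction report, weight-flux
#' scatter, graph export, and the free-energy balance — writing each result
#' as TSV plus a JSON run manifest (config echo, package version, solver
#' metadata, stage counts, file checksums) into `config$out_dir`. On a stage
#' error partial outputs are kept next to a `FAILED` marker naming the
#' stage.
#'
#' @param config a `thermoweight_config` from [runConfig()].
#' @return (invisibly) a list with the in-memory results: `model`,
#'   `completed` (tables), `inference`, `report`, `flux`, `weights`,
#'   `histogram`, `extremes`, `scatter`, `balance`, `manifest`.
#' @export
runPipeline <- function(config = runConfig()) {
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- "configuration"
  manifest <- list(config = unclass(config),
                   package_version = as.character(utils::packageVersion(
                     "thermoweight")),
                   stages = list())
  on_fail <- function(e) {
    writeLines(c(paste("FAILED at stage:", stage), conditionMessage(e)),
               file.path(out, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    for (p in c(config$model, config$formation, config$reaction_energies,
                config$media))
      if (!is.null(p) && !file.exists(p))
        stop("input path does not exist: ", p, call. = FALSE)

    stage <- "model"
    if (is.null(config$model)) {
      synth <- do.call(syntheticSpec, utils::modifyList(
        list(seed = config$seed), as.list(config$synthetic)))
      gen <- generateSyntheticModel(synth)
      model <- gen$model
      tables <- gen$masked
      writeModel(model, file.path(out, "model"))
    } else {
      model <- loadModel(config$model, config$format)
      stage <- "energy tables"
      fm <- if (is.null(config$formation)) NULL
            else loadEnergyTable(config$formation, "formation",
                                 strict = config$strict)
      rxt <- if (is.null(config$reaction_energies)) NULL
             else loadEnergyTable(config$reaction_energies, "reaction",
                                  strict = config$strict)
      tables <- energyTables(model, fm, rxt, unit = config$energy_unit,
                             strict = config$strict)
    }
    ms <- modelSummary(model)
    manifest$stages$model <- ms
    message(sprintf("model: %d reactions (%d internal, %d exchange, %d biomass), %d species, %d compounds",
                    ms$n_reactions_total, ms$n_internal, ms$n_exchange,
                    ms$n_biomass, ms$n_species, ms$n_compounds))

    stage <- "inference"
    acfg <- adjustmentConfig(R = config$gas_constant, T = config$temperature,
                             default_conc = config$default_conc,
                             unit = config$energy_unit)
    comp <- completeEnergies(model, tables, acfg, tol = config$svd_tol)
    inf <- comp$inference
    manifest$stages$inference <- list(
      n_unknown_compounds = length(inf@X_ids),
      n_usable_rows = length(inf@usable_rows),
      rank = inf@rank,
      residual_norm = sqrt(sum(inf@residuals^2)),
      n_weakly_determined = sum(inf@weakly_determined))
    message(sprintf("inference: %d unknowns, %d usable rows, rank %d",
                    length(inf@X_ids), length(inf@usable_rows), inf@rank))
    fm_out <- comp$tables@formation
    writeTsv(data.frame(compound = fm_out$compound, value = fm_out$value,
                        provenance = fm_out$provenance,
                        weakly_determined = fm_out$weakly_determined),
             file.path(out, "inferred_formation_energies.tsv"))
    rx_out <- comp$tables@reaction
    writeTsv(data.frame(reaction = rx_out$reaction, dGr0 = rx_out$dGr0,
                        dGm = rx_out$dGm, provenance = rx_out$provenance),
             file.path(out, "completed_reaction_energies.tsv"))
    writeTsv(comp$report, file.path(out, "consistency_report.tsv"))

    stage <- "fba"
    problem <- fluxProblem(model)
    if (!is.null(config$media)) {
      media <- stopIfMissing(readTsv(config$media),
                             c("reaction_id", "lb", "ub"), "media")
      problem <- applyMedia(problem, media)
    }
    flux <- solveFBA(problem, pfba = config$pfba)
    if (solverStatus(flux) != "optimal")
      stop("FBA did not reach an optimum (status ", solverStatus(flux), ")",
           call. = FALSE)
    manifest$stages$fba <- c(list(objective = objectiveValue(flux)),
                             flux@metadata)
    message(sprintf("fba: optimal, objective %.6g", objectiveValue(flux)))
    writeTsv(data.frame(reaction_id = names(fluxes(flux)),
                        flux = unname(fluxes(flux))),
             file.path(out, "fluxes.tsv"))

    stage <- "weights"
    dGm <- stats::setNames(rx_out$dGm, rx_out$reaction)
    internal <- names(reactionClass(model))[reactionClass(model) == "internal"]
    w <- computeWeights(dGm, flux, scope = internal,
                        zero_tol = config$zero_tol)
    hist <- binWeights(w, edges = config$bin_edges,
                       zero_tol = config$zero_tol)
    extremes <- extremeReactions(w)
    sc <- scatterCorrelation(w, fluxes(flux)[internal])
    manifest$stages$weights <- list(
      n_weighted = length(w), n_zero = sum(w == 0),
      histogram = stats::setNames(as.list(hist$count), hist$scope),
      pearson_r = sc$r)
    message(sprintf("weights: %d reactions, %d zero, pearson r(w,v) %.3f",
                    length(w), sum(w == 0), sc$r))
    writeTsv(data.frame(reaction_id = names(w), w = unname(w)),
             file.path(out, "weights.tsv"))
    writeTsv(hist, file.path(out, "weight_histogram.tsv"))
    writeTsv(sc$pairs, file.path(out, "weight_flux_scatter.tsv"))
    exportGraph(model, w, file.path(out, "weighted_network.graphml"))

    stage <- "balance"
    bal <- energyBalance(comp$tables, flux, model,
                         zero_tol = config$zero_tol)
    manifest$stages$balance <- list(
      G_env = bal@G_env, G_sys = bal@G_sys, G_phy = bal@G_phy,
      chemical_pct = bal@fractions[["chemical_pct"]],
      physical_pct = bal@fractions[["physical_pct"]],
      unit = paste0(bal@unit, " gDW^-1 h^-1"))
    message(sprintf("balance: G_env %.4f, G_sys %.4f, G_phy %.4f",
                    bal@G_env, bal@G_sys, bal@G_phy))
    writeBalance(bal, file.path(out, "balance.tsv"))

    stage <- "manifest"
    files <- setdiff(list.files(out, recursive = TRUE), "manifest.json")
    manifest$files <- lapply(stats::setNames(files, files), function(f)
      unname(tools::md5sum(file.path(out, f))))
    manifest$units <- list(energy = config$energy_unit,
                           flux = "mmol gDW^-1 h^-1",
                           weight = paste0(config$energy_unit,
                                           " gDW^-1 h^-1"))
    manifest$reaction_class_convention <- paste(
      "exchange = EX_/DM_ prefixed; biomass excluded from internal and",
      "exchange sums; weights cover internal reactions")
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null", force = TRUE)
    invisible(list(model = model, completed = comp$tables,
                   inference = inf, report = comp$report, flux = flux,
                   weights = w, histogram = hist, extremes = extremes,
                   scatter = sc, balance = bal, manifest = manifest))
  }, error = on_fail)
}
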