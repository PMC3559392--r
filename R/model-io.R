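#' Assemble a StoichiometricModel from its parts
#'
#' Low-level constructor used by [loadModel()] and the synthetic generator.
#' `stoich` gives the nonzero coefficients as triplets; coefficients are kept
#' both as numerics (in the sparse matrix) and as their original decimal
#' strings (for lossless tabular round-trips).
#'
#' @param species `data.frame` with `id`, `compound`, `compartment`.
#' @param reactions `data.frame` with `id`, `class`, `lb`, `ub`, `objective`.
#' @param stoich `data.frame` with `species_id`, `reaction_id`, `coefficient`
#'   (numeric or character).
#' @param metadata list of provenance notes.
#' @return a [StoichiometricModel-class].
#' @export
stoichiometricModel <- function(species, reactions, stoich,
                                metadata = list()) {
  stopIfMissing(species, c("id", "compound", "compartment"), "species")
  stopIfMissing(reactions, c("id", "class", "lb", "ub", "objective"),
                "reactions")
  stopIfMissing(stoich, c("species_id", "reaction_id", "coefficient"),
                "stoich")
  if (nrow(species) == 0L || nrow(reactions) == 0L)
    stop("empty model: zero species or zero reactions", call. = FALSE)
  bad_sp <- setdiff(stoich$species_id, species$id)
  if (length(bad_sp))
    stop("stoichiometry references undeclared species: ",
         paste(utils::head(bad_sp, 5L), collapse = ", "), call. = FALSE)
  bad_rx <- setdiff(stoich$reaction_id, reactions$id)
  if (length(bad_rx))
    stop("stoichiometry references undeclared reactions: ",
         paste(utils::head(bad_rx, 5L), collapse = ", "), call. = FALSE)
  coef_chr <- as.character(stoich$coefficient)
  coef_num <- as.numeric(coef_chr)
  if (any(is.na(coef_num)))
    stop("non-numeric stoichiometric coefficient in rows: ",
         paste(utils::head(which(is.na(coef_num)), 5L), collapse = ", "),
         call. = FALSE)
  S <- Matrix::sparseMatrix(
    i = match(stoich$species_id, species$id),
    j = match(stoich$reaction_id, reactions$id),
    x = coef_num, dims = c(nrow(species), nrow(reactions)),
    dimnames = list(species$id, reactions$id)
  )
  rec <- data.frame(species_id = stoich$species_id,
                    reaction_id = stoich$reaction_id,
                    coefficient = coef_chr, stringsAsFactors = FALSE)
  rownames(species) <- NULL
  rownames(reactions) <- NULL
  new("StoichiometricModel", S = S, species = species, reactions = reactions,
      stoichRecords = rec, metadata = metadata)
}

#' Load a constraint-based metabolic model
#'
#' Reads either an SBML Level 2 file in the constraint-based (COBRA) dialect
#' — species with compartments, reactions with reactant/product
#' stoichiometries and `LOWER_BOUND` / `UPPER_BOUND` /
#' `OBJECTIVE_COEFFICIENT` kinetic-law parameters — or the package's tabular
#' dialect: a directory with `reactions.tsv` (id, class, lb, ub, objective),
#' `species.tsv` (id, compound, compartment) and `stoich.tsv` (species_id,
#' reaction_id, coefficient), all tab-separated with header rows.
#'
#' SBML boundary species (`boundaryCondition="true"`) are dropped, matching
#' the convention of constraint-based reconstructions where they only mark
#' the system boundary. Leading `M_` / `R_` prefixes are stripped from SBML
#' identifiers. After reading, reactions are classified with
#' [classifyReactions()] and species mapped to base compounds with
#' [buildCompoundMap()] (for SBML; tabular files declare both explicitly).
#'
#' @param path SBML file, or directory holding the three tabular files.
#' @param format `"sbml"` or `"tabular"`.
#' @param ... passed to [classifyReactions()] (e.g. `biomass_id`).
#' @return a [StoichiometricModel-class].
#' @export
loadModel <- function(path, format = c("sbml", "tabular"), ...) {
  format <- match.arg(format)
  if (format == "sbml") {
    model <- readSBMLModel(path)
    model <- buildCompoundMap(model, syntax = "sbml")
    model <- classifyReactions(model, ...)
  } else {
    model <- readTabularModel(path)
    cls <- model@reactions$class
    if (any(is.na(cls) | cls == ""))
      model <- classifyReactions(model, ...)
    if (!any(model@reactions$class == "exchange"))
      warning("no exchange-prefixed reactions found", call. = FALSE)
  }
  validObject(model)
  model
}

readSBMLModel <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("SBML parse failure in ", path, ": ", conditionMessage(e),
         call. = FALSE))
  xml2::xml_ns_strip(doc)
  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (length(sp_nodes) == 0L || length(rx_nodes) == 0L)
    stop("empty model: SBML file declares zero species or zero reactions",
         call. = FALSE)
  sp_id <- xml2::xml_attr(sp_nodes, "id")
  boundary <- xml2::xml_attr(sp_nodes, "boundaryCondition")
  boundary <- !is.na(boundary) & boundary %in% c("true", "1")
  comp <- xml2::xml_attr(sp_nodes, "compartment")
  keep <- !boundary
  sp_id_keep <- sub("^M_", "", sp_id[keep])
  species <- data.frame(id = sp_id_keep, compound = sp_id_keep,
                        compartment = ifelse(is.na(comp[keep]), "",
                                             comp[keep]),
                        stringsAsFactors = FALSE)
  dropped <- sub("^M_", "", sp_id[!keep])

  n_rx <- length(rx_nodes)
  rx_id <- sub("^R_", "", xml2::xml_attr(rx_nodes, "id"))
  if (anyNA(rx_id))
    stop("SBML format error: reaction element without an id attribute",
         call. = FALSE)
  lb <- rep(-1000, n_rx); ub <- rep(1000, n_rx); obj <- rep(0, n_rx)
  rev_attr <- xml2::xml_attr(rx_nodes, "reversible")
  irrev <- !is.na(rev_attr) & rev_attr %in% c("false", "0")
  lb[irrev] <- 0
  sp_l <- vector("list", n_rx); rx_l <- vector("list", n_rx)
  co_l <- vector("list", n_rx)
  for (k in seq_len(n_rx)) {
    node <- rx_nodes[[k]]
    for (p in xml2::xml_find_all(node, "./kineticLaw//parameter")) {
      pid <- xml2::xml_attr(p, "id")
      val <- suppressWarnings(as.numeric(xml2::xml_attr(p, "value")))
      if (is.na(pid) || is.na(val)) next
      if (pid == "LOWER_BOUND") lb[k] <- val
      else if (pid == "UPPER_BOUND") ub[k] <- val
      else if (pid == "OBJECTIVE_COEFFICIENT") obj[k] <- val
    }
    reac <- xml2::xml_find_all(node, "./listOfReactants/speciesReference")
    prod <- xml2::xml_find_all(node, "./listOfProducts/speciesReference")
    ids <- c(xml2::xml_attr(reac, "species"), xml2::xml_attr(prod, "species"))
    st <- c(xml2::xml_attr(reac, "stoichiometry"),
            xml2::xml_attr(prod, "stoichiometry"))
    st[is.na(st)] <- "1"
    sgn <- rep(c("-", ""), c(length(reac), length(prod)))
    ids <- sub("^M_", "", ids)
    in_model <- !(ids %in% dropped)
    if (!all(ids[in_model] %in% species$id))
      stop("SBML format error: reaction ", rx_id[k],
           " references undeclared species ",
           paste(setdiff(ids[in_model], species$id), collapse = ", "),
           call. = FALSE)
    sp_l[[k]] <- ids[in_model]
    rx_l[[k]] <- rep(rx_id[k], sum(in_model))
    co_l[[k]] <- paste0(sgn, st)[in_model]
  }
  reactions <- data.frame(id = rx_id, class = "internal", lb = lb, ub = ub,
                          objective = obj, stringsAsFactors = FALSE)
  stoich <- data.frame(species_id = unlist(sp_l), reaction_id = unlist(rx_l),
                       coefficient = unlist(co_l), stringsAsFactors = FALSE)
  stoichiometricModel(species, reactions, stoich,
                      metadata = list(source = path, format = "sbml",
                                      boundary_species_dropped = length(dropped),
                                      stoichiometry_note = paste(
                                        "coefficients taken from the model",
                                        "file as authoritative")))
}

readTabularModel <- function(path) {
  files <- file.path(path, c("reactions.tsv", "species.tsv", "stoich.tsv"))
  miss <- files[!file.exists(files)]
  if (length(miss))
    stop("tabular model incomplete, missing: ",
         paste(basename(miss), collapse = ", "), call. = FALSE)
  reactions <- stopIfMissing(readTsv(files[1]),
                             c("id", "class", "lb", "ub", "objective"),
                             "reactions.tsv")
  species <- stopIfMissing(readTsv(files[2]),
                           c("id", "compound", "compartment"), "species.tsv")
  stoich <- stopIfMissing(readTsv(files[3]),
                          c("species_id", "reaction_id", "coefficient"),
                          "stoich.tsv")
  species$compartment[is.na(species$compartment)] <- ""
  reactions$class[is.na(reactions$class)] <- ""
  stoichiometricModel(species, reactions, stoich,
                      metadata = list(source = path, format = "tabular"))
}

#' Write a model in the tabular dialect
#'
#' Emits `reactions.tsv`, `species.tsv` and `stoich.tsv` into `dir`.
#' Stoichiometric coefficients are written from the preserved decimal
#' strings, so a load/write/load cycle reproduces the model exactly.
#'
#' @param model a [StoichiometricModel-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeModel <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rx <- model@reactions
  rx$lb <- numChr(rx$lb); rx$ub <- numChr(rx$ub)
  rx$objective <- numChr(rx$objective)
  writeTsv(rx, file.path(dir, "reactions.tsv"))
  writeTsv(model@species, file.path(dir, "species.tsv"))
  writeTsv(model@stoichRecords, file.path(dir, "stoich.tsv"))
  invisible(dir)
}

#' Classify reactions as internal, exchange or biomass
#'
#' Reactions whose identifier starts with one of the exchange prefixes
#' (default `EX_` and `DM_`, matched after an optional SBML `R_` prefix) are
#' tagged `exchange`. The biomass reaction is the one named by `biomass_id`
#' if given; otherwise the first id matching `biomass_pattern`
#' (case-insensitive), falling back to a reaction with a nonzero objective
#' coefficient. All remaining reactions are `internal`. Biomass is kept out
#' of both the internal and exchange sets used downstream (weights, balance)
#' while remaining available as the FBA objective.
#'
#' @param model a [StoichiometricModel-class].
#' @param biomass_id optional explicit biomass reaction id.
#' @param exchange_prefixes character vector of id prefixes.
#' @param biomass_pattern regular expression for biomass detection.
#' @return the model with `reaction_class` filled; the partition
#'   internal/exchange/biomass covers every reaction exactly once.
#' @export
classifyReactions <- function(model, biomass_id = NULL,
                              exchange_prefixes = c("EX_", "DM_"),
                              biomass_pattern = "biomass") {
  ids <- model@reactions$id
  pref <- paste0("^(R_)?(", paste(exchange_prefixes, collapse = "|"), ")")
  cls <- ifelse(grepl(pref, ids), "exchange", "internal")
  if (!is.null(biomass_id)) {
    if (!biomass_id %in% ids)
      stop("biomass reaction not in model: ", biomass_id, call. = FALSE)
    cls[ids == biomass_id] <- "biomass"
  } else {
    hit <- grepl(biomass_pattern, ids, ignore.case = TRUE)
    if (!any(hit)) hit <- model@reactions$objective != 0
    if (any(hit)) cls[which(hit)[1L]] <- "biomass"
  }
  if (!any(cls == "exchange"))
    warning("no exchange-prefixed reactions found", call. = FALSE)
  model@reactions$class <- cls
  model
}

#' Map compartmentalized species to base compounds
#'
#' A compound carries one Gibbs formation energy regardless of compartment,
#' so `"atp[c]"`, `"atp[p]"` and `"atp[e]"` all map to compound `"atp"`.
#' Recomputes the species-to-compound map from the identifier syntax (see
#' [parseSpeciesIds()]) and stores the distinct-compound count in the model
#' metadata.
#'
#' @param model a [StoichiometricModel-class].
#' @param syntax identifier dialect, see [parseSpeciesIds()].
#' @param strict error on species ids that match no dialect (default: such
#'   ids map to themselves).
#' @return the model with the species-to-compound map updated.
#' @export
buildCompoundMap <- function(model, syntax = "auto", strict = FALSE) {
  parsed <- parseSpeciesIds(model@species$id, syntax = syntax,
                            strict = strict)
  model@species$compound <- parsed$compound
  has_comp <- parsed$compartment != ""
  model@species$compartment[has_comp] <- parsed$compartment[has_comp]
  model@metadata$n_compounds <- length(unique(parsed$compound))
  model
}

#' Reaction-count summary of a model
#'
#' The counts a reconstruction is usually described by: reactions with and
#' without the biomass reaction, the exchange/internal split, species and
#' distinct compounds. Both reaction totals are reported explicitly because
#' published counts alternate between them.
#'
#' @param model a [StoichiometricModel-class].
#' @return named list of counts.
#' @export
modelSummary <- function(model) {
  cls <- model@reactions$class
  list(
    n_reactions_total = nrow(model@reactions),
    n_reactions_excl_biomass = sum(cls != "biomass"),
    n_internal = sum(cls == "internal"),
    n_exchange = sum(cls == "exchange"),
    n_biomass = sum(cls == "biomass"),
    n_species = nrow(model@species),
    n_compounds = length(unique(model@species$compound)),
    compartments = sort(unique(model@species$compartment))
  )
}
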