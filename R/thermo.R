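#' Configuration for the millimolar adjustment
#'
#' Builds an [AdjustmentConfig-class] with the conventions used to reference
#' standard reaction energies (1 M) to cellular metabolite concentrations
#' (1 mM): every participating compound contributes `n_i * ln(c_i)` at the
#' default 1 mM concentration, dissolved H2 and O2 carry their saturation
#' concentrations, and water and protons are left out of the concentration
#' sum entirely. Compounds are matched by base compound id, not by formula.
#'
#' @param R gas constant, default 1.987e-3 kcal mol^-1 K^-1.
#' @param T temperature (K), default 298.
#' @param default_conc reference concentration (mol/L), default 0.001.
#' @param special_conc named numeric, per-compound overrides; default
#'   `c(h2 = 3.4e-5, o2 = 5.5e-5)`.
#' @param excluded_compounds base compound ids excluded from the sum;
#'   default `c("h", "h2o")`.
#' @param unit energy unit label carried into outputs.
#' @return an [AdjustmentConfig-class].
#' @export
adjustmentConfig <- function(R = 1.987e-3, T = 298, default_conc = 0.001,
                             special_conc = c(h2 = 3.4e-5, o2 = 5.5e-5),
                             excluded_compounds = c("h", "h2o"),
                             unit = "kcal/mol") {
  new("AdjustmentConfig", R = R, T = T, default_conc = default_conc,
      special_conc = special_conc,
      excluded_compounds = excluded_compounds, unit = unit)
}

#' Concentration-correction term per reaction
#'
#' For each requested reaction, computes `R*T*sum(n_i * log(c_i))` over its
#' participating species occurrences (a compound present in two compartments
#' of one reaction contributes one term per species), with `n_i` the signed
#' stoichiometric coefficient and `c_i` the concentration of the species'
#' base compound. Excluded compounds contribute nothing.
#'
#' @param model a [StoichiometricModel-class].
#' @param cfg an [AdjustmentConfig-class].
#' @param reactions reaction ids (default: all).
#' @return named numeric vector of correction terms (energy/mol).
#' @export
concentrationCorrections <- function(model, cfg = adjustmentConfig(),
                                     reactions = reactionIds(model)) {
  validObject(cfg)
  missing_rx <- setdiff(reactions, model@reactions$id)
  if (length(missing_rx))
    stop("unknown reaction id(s): ", paste(missing_rx, collapse = ", "),
         call. = FALSE)
  conc <- rep(cfg@default_conc, nrow(model@species))
  ov <- match(model@species$compound, names(cfg@special_conc))
  conc[!is.na(ov)] <- cfg@special_conc[ov[!is.na(ov)]]
  lnc <- log(conc)
  lnc[model@species$compound %in% cfg@excluded_compounds] <- 0
  corr <- as.numeric(Matrix::crossprod(model@S, lnc)) * cfg@R * cfg@T
  names(corr) <- model@reactions$id
  corr[reactions]
}

#' Adjust a standard reaction energy to the 1 mM reference state
#'
#' Returns `dGr0 + R*T*sum(n_i * ln(c_i))` for the named reaction, the
#' free-energy change when all (non-excluded) metabolites sit at their
#' configured concentrations rather than 1 M. A reaction whose reactant and
#' product coefficient sums are equal (after exclusions, no overrides) is
#' returned unchanged since the log terms cancel.
#'
#' @param model a [StoichiometricModel-class].
#' @param reaction a reaction id.
#' @param dGr0_value the standard reaction energy (finite).
#' @param cfg an [AdjustmentConfig-class].
#' @return the adjusted energy `dGm`.
#' @export
#' @examples
#' m <- exampleToyModel()
#' adjustToMillimolar(m, "v1", -10)
adjustToMillimolar <- function(model, reaction, dGr0_value,
                               cfg = adjustmentConfig()) {
  if (!is.finite(dGr0_value))
    stop("dGr0_value must be finite for reaction ", reaction, call. = FALSE)
  dGr0_value + concentrationCorrections(model, cfg, reaction)[[1L]]
}

#' Read a delimited energy table
#'
#' Reads a TSV with header columns `id` and `value` (and optionally
#' `offset`, an additive per-reaction term such as a transport-energy
#' contribution). Blank or `NA` values mark the energy as unknown. Duplicate
#' ids keep the last occurrence with a warning (an error in strict mode).
#'
#' @param path TSV file.
#' @param kind `"formation"` (per compound) or `"reaction"` (per reaction).
#' @param strict error instead of warn on duplicates.
#' @return `data.frame` fragment with `id`, `value`, `known` (and `offset`
#'   for reaction tables).
#' @export
loadEnergyTable <- function(path, kind = c("formation", "reaction"),
                            strict = FALSE) {
  kind <- match.arg(kind)
  raw <- readTsv(path)
  if (nrow(raw) == 0L) {
    warning("empty energy table: ", path, call. = FALSE)
    out <- data.frame(id = character(), value = numeric(),
                      known = logical(), stringsAsFactors = FALSE)
    if (kind == "reaction") out$offset <- numeric()
    return(out)
  }
  stopIfMissing(raw, c("id", "value"), basename(path))
  if (anyDuplicated(raw$id)) {
    dups <- unique(raw$id[duplicated(raw$id)])
    if (strict)
      stop("duplicate ids in ", basename(path), ": ",
           paste(dups, collapse = ", "), call. = FALSE)
    warning("duplicate ids in ", basename(path), " (last occurrence kept): ",
            paste(dups, collapse = ", "), call. = FALSE)
    raw <- raw[!duplicated(raw$id, fromLast = TRUE), , drop = FALSE]
  }
  value <- suppressWarnings(as.numeric(raw$value))
  out <- data.frame(id = as.character(raw$id), value = value,
                    known = is.finite(value), stringsAsFactors = FALSE)
  out$value[!out$known] <- NA_real_
  if (kind == "reaction")
    out$offset <- if ("offset" %in% names(raw)) {
      o <- suppressWarnings(as.numeric(raw$offset)); o[is.na(o)] <- 0; o
    } else 0
  out
}

#' Build full energy tables aligned to a model
#'
#' Expands formation/reaction fragments (see [loadEnergyTable()]) to cover
#' every compound and reaction of the model; ids absent from a fragment are
#' flagged unknown. Fragment ids absent from the model are reported with a
#' warning (an error in strict mode).
#'
#' @param model a [StoichiometricModel-class].
#' @param formation,reaction fragments with `id`, `value` (`known` optional);
#'   `NULL` for an all-unknown table.
#' @param unit energy unit label.
#' @param strict error on unmatched ids.
#' @return an [EnergyTables-class].
#' @export
energyTables <- function(model, formation = NULL, reaction = NULL,
                         unit = "kcal/mol", strict = FALSE) {
  cpds <- compoundIds(model)
  rxns <- reactionIds(model)
  fm <- data.frame(compound = cpds, value = NA_real_, known = FALSE,
                   provenance = NA_character_, weakly_determined = FALSE,
                   stringsAsFactors = FALSE)
  rx <- data.frame(reaction = rxns, dGr0 = NA_real_, known = FALSE,
                   provenance = NA_character_, offset = 0, dGm = NA_real_,
                   stringsAsFactors = FALSE)
  fill <- function(tab, frag, key, valcol, what) {
    if (is.null(frag) || nrow(frag) == 0L) return(tab)
    unmatched <- setdiff(frag$id, tab[[key]])
    if (length(unmatched)) {
      msg <- paste0(length(unmatched), " ", what,
                    " id(s) not in the model: ",
                    paste(utils::head(unmatched, 5L), collapse = ", "))
      if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
      frag <- frag[frag$id %in% tab[[key]], , drop = FALSE]
    }
    idx <- match(frag$id, tab[[key]])
    known <- if ("known" %in% names(frag)) frag$known else is.finite(frag$value)
    tab[[valcol]][idx] <- ifelse(known, frag$value, NA_real_)
    tab$known[idx] <- known
    tab$provenance[idx] <- ifelse(known, "input", NA_character_)
    if ("offset" %in% names(frag) && "offset" %in% names(tab))
      tab$offset[idx] <- frag$offset
    tab
  }
  fm <- fill(fm, formation, "compound", "value", "formation-table")
  rx <- fill(rx, reaction, "reaction", "dGr0", "reaction-table")
  new("EnergyTables", formation = fm, reaction = rx, unit = unit)
}

#' Apply the millimolar adjustment to all known reaction energies
#'
#' Fills the `dGm` column of the reaction table:
#' `dGm = dGr0 + offset + concentration correction` for every reaction with
#' a known (or inferred) standard energy.
#'
#' @param model a [StoichiometricModel-class].
#' @param tables an [EnergyTables-class].
#' @param cfg an [AdjustmentConfig-class].
#' @return the tables with `dGm` filled.
#' @export
adjustReactionEnergies <- function(model, tables, cfg = adjustmentConfig()) {
  rx <- tables@reaction
  corr <- concentrationCorrections(model, cfg, rx$reaction)
  rx$dGm <- ifelse(rx$known, rx$dGr0 + rx$offset + corr, NA_real_)
  tables@reaction <- rx
  tables
}
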