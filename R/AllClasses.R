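#' @import methods
#' @importFrom Matrix sparseMatrix t rowSums colSums
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Constraint-based metabolic model
#'
#' Holds the sparse stoichiometric matrix of a genome-scale (or toy)
#' metabolic reconstruction together with species, compound and reaction
#' metadata, flux bounds and the linear objective. Rows of `S` are
#' compartmentalized species (e.g. `"atp[c]"`), columns are reactions.
#' Several species in different compartments may map to one base compound,
#' which is the unit that carries a Gibbs formation energy.
#'
#' @slot S sparse stoichiometric matrix (`Matrix::dgCMatrix`), species x
#'   reactions, entries are dimensionless stoichiometric coefficients.
#' @slot species `data.frame` with columns `id`, `compound`, `compartment`;
#'   one row per row of `S`.
#' @slot reactions `data.frame` with columns `id`, `class` (one of
#'   `"internal"`, `"exchange"`, `"biomass"`), `lb`, `ub`
#'   (mmol gDW^-1 h^-1) and `objective`; one row per column of `S`.
#' @slot stoichRecords `data.frame` (`species_id`, `reaction_id`,
#'   `coefficient` as character) preserving the exact decimal strings of the
#'   source file for lossless round-trips.
#' @slot metadata list of provenance notes (source path, format, counts).
#'
#' @seealso [loadModel()], [classifyReactions()], [buildCompoundMap()]
#' @export
setClass("StoichiometricModel",
  representation(
    S = "Matrix",
    species = "data.frame",
    reactions = "data.frame",
    stoichRecords = "data.frame",
    metadata = "list"
  )
)

setValidity("StoichiometricModel", function(object) {
  msg <- character()
  if (nrow(object@S) != nrow(object@species))
    msg <- c(msg, "nrow(S) must equal the number of species")
  if (ncol(object@S) != nrow(object@reactions))
    msg <- c(msg, "ncol(S) must equal the number of reactions")
  need_sp <- c("id", "compound", "compartment")
  if (!all(need_sp %in% names(object@species)))
    msg <- c(msg, "species needs columns id, compound, compartment")
  need_rx <- c("id", "class", "lb", "ub", "objective")
  if (!all(need_rx %in% names(object@reactions)))
    msg <- c(msg, "reactions needs columns id, class, lb, ub, objective")
  if (anyDuplicated(object@species$id))
    msg <- c(msg, "duplicated species ids")
  if (anyDuplicated(object@reactions$id))
    msg <- c(msg, "duplicated reaction ids")
  if (length(msg) == 0L) {
    # "" marks a not-yet-classified reaction (pre-classifyReactions state)
    if (!all(object@reactions$class %in% c("internal", "exchange", "biomass",
                                           "")))
      msg <- c(msg, "reaction class must be internal, exchange or biomass")
    if (any(object@reactions$lb > object@reactions$ub))
      msg <- c(msg, "lb > ub for some reaction")
  }
  if (length(msg)) msg else TRUE
})

#' Per-compound and per-reaction Gibbs energy tables
#'
#' Carries standard Gibbs formation energies per base compound and standard
#' Gibbs reaction energies per reaction, each with a known/unknown flag and a
#' provenance tag (`"input"` from a group-contribution table, `"inferred"`
#' after least-squares completion). `dGm` holds the reaction energy adjusted
#' to the 1 mM reference state once computed.
#'
#' @slot formation `data.frame` (`compound`, `value`, `known`, `provenance`,
#'   `weakly_determined`).
#' @slot reaction `data.frame` (`reaction`, `dGr0`, `known`, `provenance`,
#'   `offset`, `dGm`). `offset` is an optional additive per-reaction term
#'   (e.g. a transport-energy contribution supplied with the input table).
#' @slot unit energy unit string, default `"kcal/mol"`.
#' @export
setClass("EnergyTables",
  representation(
    formation = "data.frame",
    reaction = "data.frame",
    unit = "character"
  )
)

setValidity("EnergyTables", function(object) {
  msg <- character()
  f <- object@formation; r <- object@reaction
  if (!all(c("compound", "value", "known", "provenance") %in% names(f)))
    msg <- c(msg, "formation needs compound, value, known, provenance")
  if (!all(c("reaction", "dGr0", "known", "provenance") %in% names(r)))
    msg <- c(msg, "reaction needs reaction, dGr0, known, provenance")
  if (length(msg) == 0L) {
    if (any(f$known & !is.finite(f$value)))
      msg <- c(msg, "known formation energies must be finite")
    if (any(!f$known & !is.na(f$value)))
      msg <- c(msg, "unknown formation energies must have no numeric entry")
    if (any(r$known & !is.finite(r$dGr0)))
      msg <- c(msg, "known reaction energies must be finite")
    if (any(!r$known & !is.na(r$dGr0)))
      msg <- c(msg, "unknown reaction energies must have no numeric entry")
  }
  if (length(msg)) msg else TRUE
})

#' Millimolar-adjustment configuration
#'
#' Constants and conventions for referencing standard reaction energies to
#' cellular (1 mM) metabolite concentrations. Water and protons are excluded
#' from the concentration sum; dissolved gases carry fixed concentrations.
#'
#' @slot R gas constant (energy mol^-1 K^-1); default 1.987e-3 kcal/(mol K).
#' @slot T temperature in K, default 298.
#' @slot default_conc reference concentration in mol/L, default 0.001 (1 mM).
#' @slot special_conc named numeric of per-compound overrides
#'   (default `c(h2 = 3.4e-5, o2 = 5.5e-5)`).
#' @slot excluded_compounds base compound ids excluded from the sum
#'   (default `c("h", "h2o")`).
#' @slot unit energy unit string.
#' @export
setClass("AdjustmentConfig",
  representation(
    R = "numeric",
    T = "numeric",
    default_conc = "numeric",
    special_conc = "numeric",
    excluded_compounds = "character",
    unit = "character"
  )
)

setValidity("AdjustmentConfig", function(object) {
  msg <- character()
  if (object@T <= 0) msg <- c(msg, "T must be > 0")
  if (object@default_conc <= 0) msg <- c(msg, "default_conc must be > 0")
  if (length(object@special_conc) && any(object@special_conc <= 0))
    msg <- c(msg, "all concentrations must be strictly positive")
  if (length(msg)) msg else TRUE
})

#' Reduced least-squares system for formation-energy inference
#'
#' The inference step writes reaction energies as `t(S) %*% (P + T %*% X)`
#' where `P` holds the known per-species formation energies (0 at unknowns),
#' `T` is the binary species x unknown-compound transfer matrix and `X` the
#' unknown compound energies. Restricting to reactions with known energy
#' whose row of `t(S) %*% T` is nonzero gives the reduced system
#' `Q %*% X = b` solved in the least-squares sense.
#'
#' @slot X_ids ordered unknown-compound ids (columns of `Q`).
#' @slot P per-species formation-energy vector, zero at unknown entries.
#' @slot Fvec per-reaction energy vector (NA where unknown).
#' @slot F_known logical mask over reactions.
#' @slot T_mat sparse binary species x unknown-compound transfer matrix.
#' @slot Q,b reduced coefficient matrix and right-hand side.
#' @slot usable_rows reaction ids of the rows of `Q`.
#' @slot X0 minimum-norm least-squares solution.
#' @slot residuals per-row `b - Q %*% X0`.
#' @slot rank numerical rank of `Q`.
#' @slot singular_values singular values of `Q`.
#' @slot weakly_determined logical per unknown compound: TRUE when the
#'   compound has a non-negligible component in the null space of `Q`, i.e.
#'   its inferred value is not unique.
#' @slot tol relative singular-value cutoff used.
#' @export
setClass("InferenceResult",
  representation(
    X_ids = "character",
    P = "numeric",
    Fvec = "numeric",
    F_known = "logical",
    T_mat = "Matrix",
    Q = "matrix",
    b = "numeric",
    usable_rows = "character",
    X0 = "numeric",
    residuals = "numeric",
    rank = "integer",
    singular_values = "numeric",
    weakly_determined = "logical",
    tol = "numeric"
  )
)

#' Flux balance analysis problem
#'
#' A model reference plus (possibly overridden) objective and bounds; media
#' specifications are applied here before solving.
#'
#' @slot model the [StoichiometricModel-class].
#' @slot objective per-reaction objective coefficients.
#' @slot lb,ub per-reaction flux bounds (mmol gDW^-1 h^-1).
#' @export
setClass("FluxProblem",
  representation(
    model = "StoichiometricModel",
    objective = "numeric",
    lb = "numeric",
    ub = "numeric"
  )
)

setValidity("FluxProblem", function(object) {
  msg <- character()
  n <- nrow(object@model@reactions)
  if (length(object@objective) != n || length(object@lb) != n ||
      length(object@ub) != n)
    msg <- c(msg, "objective/lb/ub must have one entry per reaction")
  else {
    if (all(object@objective == 0))
      msg <- c(msg, "objective has no nonzero coefficient")
    if (any(object@lb > object@ub)) msg <- c(msg, "lb > ub after override")
  }
  if (length(msg)) msg else TRUE
})

#' Flux distribution from FBA
#'
#' @slot v named per-reaction flux vector (mmol gDW^-1 h^-1); empty unless
#'   the solve was optimal.
#' @slot objectiveValue optimal objective (NA unless optimal).
#' @slot status one of `"optimal"`, `"infeasible"`, `"unbounded"`.
#' @slot metadata solver configuration record (solver, tolerances, whether
#'   the parsimonious secondary objective was applied).
#' @export
setClass("FluxDistribution",
  representation(
    v = "numeric",
    objectiveValue = "numeric",
    status = "character",
    metadata = "list"
  )
)

#' Free-energy balance decomposition
#'
#' `G_env` is the free-energy input rate summed over exchange reactions,
#' `G_sys` the dissipation rate summed over internal chemistry, and
#' `G_phy = -(G_env + G_sys)` the physical-process remainder, an estimate by
#' difference. Fractions split `|G_env|` into chemical and physical parts.
#'
#' @slot G_env,G_sys,G_phy scalar rates (energy gDW^-1 h^-1).
#' @slot fractions named numeric: `chemical_pct`, `physical_pct`.
#' @slot unit energy unit of the rates.
#' @slot metadata flux-solution and convention metadata.
#' @export
setClass("EnergyBalance",
  representation(
    G_env = "numeric",
    G_sys = "numeric",
    G_phy = "numeric",
    fractions = "numeric",
    unit = "character",
    metadata = "list"
  )
)

#' Specification for the synthetic model generator
#'
#' @slot n_compounds,n_compartments,n_internal_reactions,n_exchange_reactions
#'   integer sizes. `n_internal_reactions` counts the random internal
#'   reactions added on top of the planted transport/chain/biomass scaffold.
#' @slot frac_unknown_compounds fraction in [0, 1) of compounds whose
#'   formation energy is masked in the released table.
#' @slot mask_reaction_frac fraction of reactions touching a masked compound
#'   whose reaction energy is itself masked (the rest stay known and serve as
#'   inference constraints).
#' @slot noise_sd Gaussian noise sd added to reaction energies (energy/mol).
#' @slot seed integer random seed; generation is a pure function of the spec.
#' @slot sparsity mean number of participants per random reaction.
#' @export
setClass("SyntheticSpec",
  representation(
    n_compounds = "integer",
    n_compartments = "integer",
    n_internal_reactions = "integer",
    n_exchange_reactions = "integer",
    frac_unknown_compounds = "numeric",
    mask_reaction_frac = "numeric",
    noise_sd = "numeric",
    seed = "integer",
    sparsity = "numeric"
  )
)

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (object@n_compounds < 1L) msg <- c(msg, "n_compounds must be >= 1")
  if (object@n_compartments < 1L) msg <- c(msg, "n_compartments must be >= 1")
  if (object@n_exchange_reactions < 1L)
    msg <- c(msg, "n_exchange_reactions must be >= 1 (a feasible uptake path is required)")
  if (object@frac_unknown_compounds < 0 || object@frac_unknown_compounds >= 1)
    msg <- c(msg, "frac_unknown_compounds must be in [0, 1)")
  if (object@noise_sd < 0) msg <- c(msg, "noise_sd must be >= 0")
  if (object@n_exchange_reactions > object@n_compounds)
    msg <- c(msg, "cannot have more exchange reactions than compounds")
  if (length(msg)) msg else TRUE
})
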