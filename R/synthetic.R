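#' Specification for a synthetic metabolic model
#'
#' The generator produces toy constraint-based models with known ground
#' truth so the completion, FBA, weighting and balance machinery can be
#' exercised end to end without external model files. Defaults describe a
#' small but non-trivial network: 30 compounds over 2 compartments plus an
#' extracellular compartment, 60 random internal reactions of about 4
#' participants each, 6 exchange reactions, 20% of compounds with masked
#' formation energy, and a quarter of the reactions touching a masked
#' compound with their reaction energy masked as well (the rest remain as
#' inference constraints, mirroring the known/unknown split of curated
#' reconstructions).
#'
#' @param n_compounds,n_compartments,n_internal_reactions,n_exchange_reactions
#'   integer sizes; `n_internal_reactions` counts the random reactions added
#'   on top of the planted uptake-transport-chain-biomass scaffold.
#' @param frac_unknown_compounds fraction of compounds masked, in [0, 1).
#' @param mask_reaction_frac fraction of masked-compound-touching reactions
#'   whose energy is masked too.
#' @param noise_sd sd of Gaussian noise added to the released reaction
#'   energies of constraint rows (energy/mol); emulates group-contribution
#'   estimation error on the equations the inference actually uses.
#' @param seed integer seed; generation is a pure function of the spec.
#' @param sparsity mean participants per random reaction.
#' @return a [SyntheticSpec-class].
#' @export
syntheticSpec <- function(n_compounds = 30, n_compartments = 2,
                          n_internal_reactions = 60,
                          n_exchange_reactions = 6,
                          frac_unknown_compounds = 0.2,
                          mask_reaction_frac = 0.25,
                          noise_sd = 0, seed = 1, sparsity = 4) {
  new("SyntheticSpec",
      n_compounds = as.integer(n_compounds),
      n_compartments = as.integer(n_compartments),
      n_internal_reactions = as.integer(n_internal_reactions),
      n_exchange_reactions = as.integer(n_exchange_reactions),
      frac_unknown_compounds = frac_unknown_compounds,
      mask_reaction_frac = mask_reaction_frac,
      noise_sd = noise_sd, seed = as.integer(seed), sparsity = sparsity)
}

#' Generate a synthetic model with ground-truth thermodynamics
#'
#' Compounds receive formation energies drawn uniformly on [-200, 50];
#' reaction energies follow from the stoichiometry
#' (`dGr = sum_i s_i * dGf(i)`), with Gaussian noise of sd `noise_sd` added
#' to the released energies of reactions touching a masked compound (the
#' inference constraint rows; reactions fully covered by known formation
#' energies stay self-consistent, as group-contribution reaction energies
#' derived from the same formation energies would be). A feasible
#' source-to-biomass path with open uptake (bound 10) is always planted, so
#' the FBA optimum is strictly positive. Each masked compound is guaranteed
#' to appear in at least one constraint row so that no unknown is left
#' structurally unconstrained; full column rank of the reduced system is
#' reported, not forced.
#'
#' @param spec a [SyntheticSpec-class].
#' @return list with `model` ([StoichiometricModel-class]), `truth` and
#'   `masked` ([EnergyTables-class]), `dGf_true` (named numeric),
#'   `masked_compounds`, `rank` and `n_unknowns` of the reduced system built
#'   from the masked tables, and `spec`.
#' @export
generateSyntheticModel <- function(spec = syntheticSpec()) {
  validObject(spec)
  if (spec@n_compounds - spec@n_exchange_reactions < 3L)
    stop("spec cannot host a feasible source-to-biomass path: need at ",
         "least 3 non-exchange compounds for the chain", call. = FALSE)
  withSeed(spec@seed, {
    n_cpd <- spec@n_compounds
    cpds <- sprintf("cpd%03d", seq_len(n_cpd))
    dGf_true <- stats::setNames(stats::runif(n_cpd, -200, 50), cpds)
    comps <- c("c", "p", "m")[seq_len(min(spec@n_compartments, 3L))]

    species <- data.frame(id = paste0(cpds, "[c]"), compound = cpds,
                          compartment = "c", stringsAsFactors = FALSE)
    for (cp in setdiff(comps, "c")) {
      extra <- cpds[stats::runif(n_cpd) < 0.3]
      if (length(extra))
        species <- rbind(species, data.frame(
          id = paste0(extra, "[", cp, "]"), compound = extra,
          compartment = cp, stringsAsFactors = FALSE))
    }
    ex_cpds <- sample(cpds, spec@n_exchange_reactions)
    source_cpd <- ex_cpds[1L]
    species <- rbind(species, data.frame(
      id = paste0(ex_cpds, "[e]"), compound = ex_cpds, compartment = "e",
      stringsAsFactors = FALSE))

    rx <- list(); st <- list()
    addRx <- function(id, class, lb, ub, obj, sp, coef) {
      rx[[length(rx) + 1L]] <<- data.frame(
        id = id, class = class, lb = lb, ub = ub, objective = obj,
        stringsAsFactors = FALSE)
      st[[length(st) + 1L]] <<- data.frame(
        species_id = sp, reaction_id = id, coefficient = coef,
        stringsAsFactors = FALSE)
    }
    for (cpd in ex_cpds) {
      up <- cpd == source_cpd
      addRx(paste0("EX_", cpd, "(e)"), "exchange",
            if (up) -10 else 0, if (up) 0 else 1000, 0,
            paste0(cpd, "[e]"), -1)
      addRx(paste0("TR_", cpd), "internal", 0, 1000, 0,
            paste0(cpd, c("[e]", "[c]")), c(-1, 1))
    }
    chain <- c(source_cpd, sample(setdiff(cpds, ex_cpds), 3L))
    for (k in 1:3)
      addRx(sprintf("CH%02d", k), "internal", 0, 1000, 0,
            paste0(chain[k:(k + 1L)], "[c]"), c(-1, 1))
    addRx("BIOMASS_synth", "biomass", 0, 1000, 1,
          paste0(chain[4L], "[c]"), -1)

    internal_sp <- species$id[species$compartment != "e"]
    for (k in seq_len(spec@n_internal_reactions)) {
      np <- max(2L, stats::rpois(1L, spec@sparsity))
      np <- min(np, length(internal_sp))
      parts <- sample(internal_sp, np)
      # mass balance (unit compound masses): reactant and product
      # coefficient sums must match, so no reaction loop can create matter
      # and the biomass drain stays uptake-limited; the member-count split
      # is kept within a factor 2 so magnitudes stay in {1, 2}
      a_lo <- max(1L, ceiling(np / 3)); a_hi <- min(np - 1L, floor(2 * np / 3))
      a <- if (a_lo >= a_hi) a_lo else sample(a_lo:a_hi, 1L)
      b <- np - a
      coef <- numeric(np)
      bigside <- max(a, b)
      mk <- function(n_side, target) {        # n_side coefs in {1,2} summing to target
        out <- rep(1, n_side)
        extra <- target - n_side
        if (extra > 0) out[seq_len(extra)] <- 2
        out
      }
      coef[seq_len(a)] <- -mk(a, bigside)
      coef[a + seq_len(b)] <- mk(b, bigside)
      rev <- stats::runif(1) < 0.5
      addRx(sprintf("RXN%03d", k), "internal", if (rev) -1000 else 0, 1000,
            0, parts, coef)
    }
    reactions <- do.call(rbind, rx)
    stoich <- do.call(rbind, st)
    model <- stoichiometricModel(species, reactions, stoich,
                                 metadata = list(source = "synthetic",
                                                 seed = spec@seed))

    dGf_sp <- dGf_true[model@species$compound]
    dGr_true <- as.numeric(Matrix::crossprod(model@S, dGf_sp))
    names(dGr_true) <- reactions$id
    noise_z <- stats::rnorm(nrow(reactions))  # drawn unconditionally so the
                                              # stream is noise_sd-invariant
    n_mask <- round(spec@frac_unknown_compounds * n_cpd)
    masked_cpds <- if (n_mask > 0) sample(cpds, n_mask) else character()
    # a reaction constrains a masked compound only through its NET
    # coefficient: a compound moved unchanged between compartments cancels
    # out of the reaction energy, exactly as shared molecular groups do
    netCoef <- function(cpd) as.numeric(Matrix::crossprod(
      model@S, as.numeric(model@species$compound == cpd)))
    net <- vapply(masked_cpds, netCoef, numeric(nrow(reactions)))
    touches <- if (length(masked_cpds)) rowSums(abs(net)) > 1e-12
               else rep(FALSE, nrow(reactions))
    mask_rx <- touches & stats::runif(nrow(reactions)) < spec@mask_reaction_frac
    # identifiability guarantee: keep at least one constraint row per
    # masked compound
    for (cpd in masked_cpds) {
      in_rx <- abs(net[, cpd]) > 1e-12
      if (any(in_rx) && !any(in_rx & !mask_rx))
        mask_rx[which(in_rx)[1L]] <- FALSE
    }
    dGr_obs <- dGr_true + spec@noise_sd * noise_z * as.numeric(touches)

    truth <- energyTables(model,
      formation = data.frame(id = cpds, value = unname(dGf_true)),
      reaction = data.frame(id = reactions$id, value = unname(dGr_true)))
    masked <- energyTables(model,
      formation = data.frame(id = cpds,
        value = ifelse(cpds %in% masked_cpds, NA_real_, unname(dGf_true))),
      reaction = data.frame(id = reactions$id,
        value = ifelse(mask_rx, NA_real_, unname(dGr_obs))))

    rank <- 0L; n_unknowns <- length(masked_cpds)
    if (n_unknowns > 0L) {
      sys <- buildInferenceSystem(model, masked)
      sv <- svd(sys$Q)$d
      rank <- sum(sv > 1e-10 * max(sv, 0))
    }
    list(model = model, truth = truth, masked = masked,
         dGf_true = dGf_true, masked_compounds = masked_cpds,
         rank = as.integer(rank), n_unknowns = n_unknowns, spec = spec)
  })
}

#' Minimal worked example model
#'
#' A four-reaction toy: uptake of compound A (`EX_A`, bounds [-10, 0]),
#' transport into the cytoplasm, conversion A -> B and a biomass drain on B
#' carrying the objective. Used in examples and tests.
#'
#' @return a [StoichiometricModel-class].
#' @export
exampleToyModel <- function() {
  species <- data.frame(
    id = c("A[e]", "A[c]", "B[c]"),
    compound = c("A", "A", "B"),
    compartment = c("e", "c", "c"), stringsAsFactors = FALSE)
  reactions <- data.frame(
    id = c("EX_A(e)", "TR_A", "v1", "BIOMASS"),
    class = c("exchange", "internal", "internal", "biomass"),
    lb = c(-10, 0, 0, 0), ub = c(0, 1000, 1000, 1000),
    objective = c(0, 0, 0, 1), stringsAsFactors = FALSE)
  stoich <- data.frame(
    species_id = c("A[e]", "A[e]", "A[c]", "A[c]", "B[c]", "B[c]"),
    reaction_id = c("EX_A(e)", "TR_A", "TR_A", "v1", "v1", "BIOMASS"),
    coefficient = c(-1, -1, 1, -1, 1, -1), stringsAsFactors = FALSE)
  stoichiometricModel(species, reactions, stoich,
                      metadata = list(source = "exampleToyModel"))
}
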