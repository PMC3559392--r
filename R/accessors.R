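#' @rdname StoichiometricModel-class
#' @param object,x a `StoichiometricModel`
#' @export
setGeneric("stoichMatrix", function(x) standardGeneric("stoichMatrix"))

#' @rdname StoichiometricModel-class
#' @export
setMethod("stoichMatrix", "StoichiometricModel", function(x) x@S)

#' @rdname StoichiometricModel-class
#' @export
setGeneric("speciesIds", function(x) standardGeneric("speciesIds"))

#' @rdname StoichiometricModel-class
#' @export
setMethod("speciesIds", "StoichiometricModel", function(x) x@species$id)

#' @rdname StoichiometricModel-class
#' @export
setGeneric("compoundIds", function(x) standardGeneric("compoundIds"))

#' @rdname StoichiometricModel-class
#' @export
setMethod("compoundIds", "StoichiometricModel",
          function(x) unique(x@species$compound))

#' @rdname StoichiometricModel-class
#' @export
setGeneric("reactionIds", function(x) standardGeneric("reactionIds"))

#' @rdname StoichiometricModel-class
#' @export
setMethod("reactionIds", "StoichiometricModel", function(x) x@reactions$id)

#' @rdname StoichiometricModel-class
#' @export
setGeneric("reactionClass", function(x) standardGeneric("reactionClass"))

#' @rdname StoichiometricModel-class
#' @export
setMethod("reactionClass", "StoichiometricModel", function(x) {
  stats::setNames(x@reactions$class, x@reactions$id)
})

#' @rdname StoichiometricModel-class
#' @export
setGeneric("speciesToCompound", function(x) standardGeneric("speciesToCompound"))

#' @rdname StoichiometricModel-class
#' @export
setMethod("speciesToCompound", "StoichiometricModel", function(x) {
  stats::setNames(x@species$compound, x@species$id)
})

#' @rdname StoichiometricModel-class
#' @export
setGeneric("bounds", function(x) standardGeneric("bounds"))

#' @rdname StoichiometricModel-class
#' @export
setMethod("bounds", "StoichiometricModel", function(x) {
  data.frame(id = x@reactions$id, lb = x@reactions$lb, ub = x@reactions$ub)
})

#' @rdname StoichiometricModel-class
#' @export
setGeneric("objectiveCoefficients",
           function(x) standardGeneric("objectiveCoefficients"))

#' @rdname StoichiometricModel-class
#' @export
setMethod("objectiveCoefficients", "StoichiometricModel", function(x) {
  stats::setNames(x@reactions$objective, x@reactions$id)
})

setMethod("show", "StoichiometricModel", function(object) {
  cls <- table(factor(object@reactions$class,
                      c("internal", "exchange", "biomass")))
  cat("StoichiometricModel\n")
  cat(sprintf("  %d species (%d compounds, %d compartments) x %d reactions\n",
              nrow(object@species), length(unique(object@species$compound)),
              length(unique(object@species$compartment)),
              nrow(object@reactions)))
  cat(sprintf("  reaction classes: %d internal, %d exchange, %d biomass\n",
              cls[["internal"]], cls[["exchange"]], cls[["biomass"]]))
  cat(sprintf("  nonzeros in S: %d\n", length(object@S@x)))
  invisible(NULL)
})

#' @rdname EnergyTables-class
#' @param x an `EnergyTables`
#' @export
setGeneric("formationEnergies", function(x) standardGeneric("formationEnergies"))

#' @rdname EnergyTables-class
#' @export
setMethod("formationEnergies", "EnergyTables", function(x) x@formation)

#' @rdname EnergyTables-class
#' @export
setGeneric("reactionEnergies", function(x) standardGeneric("reactionEnergies"))

#' @rdname EnergyTables-class
#' @export
setMethod("reactionEnergies", "EnergyTables", function(x) x@reaction)

#' @rdname EnergyTables-class
#' @export
setGeneric("energyUnit", function(x) standardGeneric("energyUnit"))

#' @rdname EnergyTables-class
#' @export
setMethod("energyUnit", "EnergyTables", function(x) x@unit)

setMethod("show", "EnergyTables", function(object) {
  f <- object@formation; r <- object@reaction
  cat("EnergyTables [", object@unit, "]\n", sep = "")
  cat(sprintf("  formation: %d compounds (%d known, %d unknown, %d inferred)\n",
              nrow(f), sum(f$known), sum(!f$known),
              sum(f$provenance == "inferred")))
  cat(sprintf("  reaction : %d reactions (%d known, %d unknown, %d inferred)\n",
              nrow(r), sum(r$known), sum(!r$known),
              sum(r$provenance == "inferred")))
  if (!all(is.na(r$dGm)))
    cat(sprintf("  dGm (1 mM reference) available for %d reactions\n",
                sum(!is.na(r$dGm))))
  invisible(NULL)
})

setMethod("show", "InferenceResult", function(object) {
  cat("InferenceResult\n")
  cat(sprintf("  reduced system Q: %d x %d, rank %d\n",
              nrow(object@Q), ncol(object@Q), object@rank))
  cat(sprintf("  residual norm: %.6g; weakly determined compounds: %d\n",
              sqrt(sum(object@residuals^2)), sum(object@weakly_determined)))
  invisible(NULL)
})

#' @rdname FluxDistribution-class
#' @param x a `FluxDistribution`
#' @export
setGeneric("fluxes", function(x) standardGeneric("fluxes"))

#' @rdname FluxDistribution-class
#' @export
setMethod("fluxes", "FluxDistribution", function(x) x@v)

#' @rdname FluxDistribution-class
#' @export
setGeneric("objectiveValue", function(x) standardGeneric("objectiveValue"))

#' @rdname FluxDistribution-class
#' @export
setMethod("objectiveValue", "FluxDistribution", function(x) x@objectiveValue)

#' @rdname FluxDistribution-class
#' @export
setGeneric("solverStatus", function(x) standardGeneric("solverStatus"))

#' @rdname FluxDistribution-class
#' @export
setMethod("solverStatus", "FluxDistribution", function(x) x@status)

setMethod("show", "FluxDistribution", function(object) {
  cat("FluxDistribution: status", object@status)
  if (object@status == "optimal")
    cat(sprintf(", objective %.6g, %d/%d nonzero fluxes",
                object@objectiveValue, sum(object@v != 0), length(object@v)))
  cat("\n")
  invisible(NULL)
})

setMethod("show", "EnergyBalance", function(object) {
  cat("EnergyBalance [", object@unit, " gDW^-1 h^-1]\n", sep = "")
  cat(sprintf("  G_env = %.4f (input from environment)\n", object@G_env))
  cat(sprintf("  G_sys = %.4f (chemical dissipation)\n", object@G_sys))
  cat(sprintf("  G_phy = %.4f (physical remainder, by difference)\n",
              object@G_phy))
  cat(sprintf("  share of G_env: %.2f%% chemical, %.2f%% physical\n",
              object@fractions[["chemical_pct"]],
              object@fractions[["physical_pct"]]))
  invisible(NULL)
})
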