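# Fixtures are built in code; oracles here are written independently of the
# implementation paths they check.

# two-compound, two-reaction tabular fixture written to a temp dir
writeTabularToy <- function(dir = tempfile("toymodel")) {
  dir.create(dir, showWarnings = FALSE)
  writeLines(c("id\tclass\tlb\tub\tobjective",
               "r1\tinternal\t0\t1000\t0",
               "r2\tinternal\t-1000\t1000\t1"),
             file.path(dir, "reactions.tsv"))
  writeLines(c("id\tcompound\tcompartment",
               "a[c]\ta\tc", "b[c]\tb\tc", "c[c]\tc\tc"),
             file.path(dir, "species.tsv"))
  writeLines(c("species_id\treaction_id\tcoefficient",
               "a[c]\tr1\t-1", "b[c]\tr1\t1",
               "b[c]\tr2\t-1", "c[c]\tr2\t0.5"),
             file.path(dir, "stoich.tsv"))
  dir
}

# minimal SBML Level 2 file in the constraint-based dialect; includes one
# boundary species that the reader must drop
writeToySBML <- function(path = tempfile(fileext = ".xml"),
                         undeclared_species = FALSE,
                         empty = FALSE) {
  ref <- if (undeclared_species) "M_zz_c" else "M_b_c"
  rxns <- if (empty) "" else paste0('
    <reaction id="R_EX_a" reversible="true">
      <listOfReactants><speciesReference species="M_a_e" stoichiometry="1"/></listOfReactants>
      <kineticLaw><listOfParameters>
        <parameter id="LOWER_BOUND" value="-10"/>
        <parameter id="UPPER_BOUND" value="0"/>
        <parameter id="OBJECTIVE_COEFFICIENT" value="0"/>
      </listOfParameters></kineticLaw>
    </reaction>
    <reaction id="R_Ta" reversible="false">
      <listOfReactants><speciesReference species="M_a_e"/></listOfReactants>
      <listOfProducts><speciesReference species="M_a_c"/></listOfProducts>
    </reaction>
    <reaction id="R_v1" reversible="false">
      <listOfReactants><speciesReference species="M_a_c"/></listOfReactants>
      <listOfProducts>
        <speciesReference species="', ref, '" stoichiometry="2"/>
        <speciesReference species="M_bnd_b" stoichiometry="1"/>
      </listOfProducts>
      <kineticLaw><listOfParameters>
        <parameter id="LOWER_BOUND" value="0"/>
        <parameter id="UPPER_BOUND" value="500"/>
      </listOfParameters></kineticLaw>
    </reaction>
    <reaction id="R_BIOMASS_toy" reversible="false">
      <listOfReactants><speciesReference species="M_b_c"/></listOfReactants>
      <kineticLaw><listOfParameters>
        <parameter id="LOWER_BOUND" value="0"/>
        <parameter id="UPPER_BOUND" value="1000"/>
        <parameter id="OBJECTIVE_COEFFICIENT" value="1"/>
      </listOfParameters></kineticLaw>
    </reaction>')
  species <- if (empty) "" else '
    <species id="M_a_e" compartment="e"/>
    <species id="M_a_c" compartment="c"/>
    <species id="M_b_c" compartment="c"/>
    <species id="M_bnd_b" compartment="b" boundaryCondition="true"/>'
  xml <- paste0('<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="1">
<model id="toy">
  <listOfCompartments>
    <compartment id="c"/><compartment id="e"/><compartment id="b"/>
  </listOfCompartments>
  <listOfSpecies>', species, '</listOfSpecies>
  <listOfReactions>', rxns, '</listOfReactions>
</model>
</sbml>')
  writeLines(xml, path)
  path
}

# model + fully known energies for hand-checked balance arithmetic:
# EX_A (A in), R1: A -> B, EX_B (B out); formation A = -10, B = -13
balanceToy <- function() {
  species <- data.frame(id = c("A[e]", "B[e]"), compound = c("A", "B"),
                        compartment = "e", stringsAsFactors = FALSE)
  reactions <- data.frame(
    id = c("EX_A(e)", "R1", "EX_B(e)"),
    class = c("exchange", "internal", "exchange"),
    lb = c(-5, 0, 0), ub = c(0, 1000, 1000),
    objective = c(0, 1, 0), stringsAsFactors = FALSE)
  stoich <- data.frame(
    species_id = c("A[e]", "A[e]", "B[e]", "B[e]"),
    reaction_id = c("EX_A(e)", "R1", "R1", "EX_B(e)"),
    coefficient = c(-1, -1, 1, -1), stringsAsFactors = FALSE)
  model <- stoichiometricModel(species, reactions, stoich)
  tables <- energyTables(model,
    formation = data.frame(id = c("A", "B"), value = c(-10, -13)),
    reaction = data.frame(id = reactions$id, value = c(10, -3, 13)))
  list(model = model, tables = adjustReactionEnergies(model, tables))
}

# LP oracle: enumerate basic solutions of  max c'v, S v = 0, lb <= v <= ub.
# For each choice of basic columns and each assignment of the remaining
# variables to a bound, solve for the basic part and keep feasible points.
lpVertexOracle <- function(S, cc, lb, ub) {
  S <- as.matrix(S)
  S <- S[rowSums(abs(S)) > 0, , drop = FALSE]
  n <- length(cc)
  m <- qr(S)$rank
  best <- -Inf
  sets <- if (m == 0) list(integer()) else
    asplit(utils::combn(n, min(m, n)), 2)
  for (Bset in sets) {
    Bset <- as.integer(Bset)
    Nset <- setdiff(seq_len(n), Bset)
    SB <- S[, Bset, drop = FALSE]
    if (length(Bset) && qr(SB)$rank < length(Bset)) next
    grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(Nset)))
    if (nrow(grid) == 0L) grid <- data.frame(row.names = 1)
    for (g in seq_len(nrow(grid))) {
      vN <- ifelse(unlist(grid[g, ]), ub[Nset], lb[Nset])
      rhs <- if (length(Nset)) -S[, Nset, drop = FALSE] %*% vN
             else matrix(0, nrow(S), 1)
      vB <- tryCatch(qr.solve(SB, rhs), error = function(e) NULL)
      if (is.null(vB)) next
      if (max(abs(SB %*% vB - rhs)) > 1e-8) next
      v <- numeric(n)
      v[Bset] <- vB; v[Nset] <- vN
      if (all(v >= lb - 1e-9) && all(v <= ub + 1e-9))
        best <- max(best, sum(cc * v))
    }
  }
  best
}

# least-squares oracle via the pseudo-inverse (MASS, independent route)
pinvOracle <- function(Q, b) as.numeric(MASS::ginv(Q) %*% b)

expect_model_invariants <- function(model) {
  expect_true(validObject(model))
  cls <- reactionClass(model)
  expect_equal(sum(cls == "internal") + sum(cls == "exchange") +
                 sum(cls == "biomass"), length(cls))
  expect_lte(length(compoundIds(model)), length(speciesIds(model)))
}
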