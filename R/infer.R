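#' Transfer matrix from unknown compounds to species rows
#'
#' Each unknown compound has a single formation energy that must appear in
#' every compartmental species row where the compound occurs. The binary
#' transfer matrix `T` (species x unknown compounds) places entry 1 at
#' (species i, unknown j) when species i is an instance of unknown compound
#' j; each row has at most one nonzero.
#'
#' @param model a [StoichiometricModel-class].
#' @param tables an [EnergyTables-class] with the formation table loaded.
#' @return list with `T_mat` (sparse) and `X_ids` (unknown compound ids, in
#'   formation-table order, i.e. order of first appearance in the model).
#' @export
buildTransferMatrix <- function(model, tables) {
  fm <- tables@formation
  X_ids <- fm$compound[!fm$known]
  n_sp <- nrow(model@species)
  if (length(X_ids) == 0L) {
    warning("no unknown compounds: inference is a no-op", call. = FALSE)
    T_mat <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                  dims = c(n_sp, 0L),
                                  dimnames = list(model@species$id, NULL))
    return(list(T_mat = T_mat, X_ids = character()))
  }
  j <- match(model@species$compound, X_ids)
  i <- which(!is.na(j))
  T_mat <- Matrix::sparseMatrix(i = i, j = j[i], x = 1,
                                dims = c(n_sp, length(X_ids)),
                                dimnames = list(model@species$id, X_ids))
  list(T_mat = T_mat, X_ids = X_ids)
}

#' Reduced least-squares system for the unknown formation energies
#'
#' Starting from `t(S) %*% (P + T %*% X) = F` — reaction energies are the
#' stoichiometry-weighted sums of per-species formation energies — keeps the
#' rows (reactions) whose energy `F` is known and whose coefficient row in
#' `t(S) %*% T` is nonzero, i.e. known-energy reactions actually touching an
#' unknown compound. Those rows constrain `X` via `Q %*% X = b` with
#' `b = F - t(S) %*% P` restricted to the kept rows.
#'
#' @param model a [StoichiometricModel-class].
#' @param tables an [EnergyTables-class].
#' @param T_mat transfer matrix from [buildTransferMatrix()] (rebuilt when
#'   `NULL`).
#' @return list with `Q` (dense matrix, rows named by reaction), `b`,
#'   `usable_rows`, plus the ingredients `P`, `Fvec`, `F_known`, `T_mat`,
#'   `X_ids`.
#' @export
buildInferenceSystem <- function(model, tables, T_mat = NULL) {
  tm <- if (is.null(T_mat)) buildTransferMatrix(model, tables)
        else list(T_mat = T_mat, X_ids = colnames(T_mat))
  fm <- tables@formation
  pv <- fm$value[match(model@species$compound, fm$compound)]
  P <- ifelse(is.na(pv), 0, pv)
  names(P) <- model@species$id
  rx <- tables@reaction[match(reactionIds(model), tables@reaction$reaction), ]
  Fvec <- stats::setNames(rx$dGr0, rx$reaction)
  F_known <- stats::setNames(rx$known, rx$reaction)
  A <- Matrix::crossprod(model@S, tm$T_mat)        # reactions x unknowns
  touches <- Matrix::rowSums(abs(A)) > 0
  usable <- which(F_known & touches)
  if (length(tm$X_ids) > 0L && length(usable) == 0L) {
    constrained <- Matrix::colSums(abs(A[F_known, , drop = FALSE])) > 0
    stop("underdetermined system: no known-energy reaction touches an ",
         "unknown compound; unconstrained compounds: ",
         paste(tm$X_ids[!constrained], collapse = ", "), call. = FALSE)
  }
  Q <- as.matrix(A[usable, , drop = FALSE])
  rownames(Q) <- names(F_known)[usable]
  colnames(Q) <- tm$X_ids
  StP <- as.numeric(Matrix::crossprod(model@S, P))
  b <- Fvec[usable] - StP[usable]
  list(Q = Q, b = unname(b), usable_rows = names(F_known)[usable],
       P = P, Fvec = Fvec, F_known = F_known,
       T_mat = tm$T_mat, X_ids = tm$X_ids, StP = StP)
}

#' Minimum-norm least-squares solve
#'
#' Solves `min ||Q %*% X - b||_2` by singular value decomposition with a
#' relative singular-value cutoff; on rank deficiency the returned solution
#' has minimum Euclidean norm among all minimizers, and unknowns with a
#' non-negligible null-space component are flagged weakly determined (their
#' value is not unique and should be interpreted with care).
#'
#' @param Q coefficient matrix (rows = constraints, columns = unknowns).
#' @param b right-hand side.
#' @param tol relative singular-value cutoff (default 1e-10 x largest).
#' @return list with `X0`, `residuals` (`b - Q %*% X0`), `rank`,
#'   `singular_values`, `weakly_determined`.
#' @export
solveLeastSquares <- function(Q, b, tol = 1e-10) {
  if (ncol(Q) == 0L)
    return(list(X0 = numeric(), residuals = unname(b), rank = 0L,
                singular_values = numeric(), weakly_determined = logical()))
  if (nrow(Q) == 0L) stop("Q has no rows", call. = FALSE)
  if (!all(is.finite(Q)) || !all(is.finite(b)))
    stop("non-finite entries in Q or b", call. = FALSE)
  sv <- svd(Q, nu = min(dim(Q)), nv = ncol(Q))   # full V for the null space
  d <- sv$d
  rank <- sum(d > tol * d[1L])
  dinv <- ifelse(seq_along(d) <= rank, 1 / d, 0)
  X0 <- as.numeric(sv$v[, seq_along(d), drop = FALSE] %*%
                     (dinv * crossprod(sv$u, b)))
  names(X0) <- colnames(Q)
  weakly <- rep(FALSE, ncol(Q))
  if (rank < ncol(Q)) {
    Nspace <- sv$v[, (rank + 1L):ncol(Q), drop = FALSE]
    weakly <- sqrt(rowSums(Nspace^2)) > 1e-8
  }
  names(weakly) <- colnames(Q)
  list(X0 = X0, residuals = unname(b - as.numeric(Q %*% X0)), rank = rank,
       singular_values = d, weakly_determined = weakly)
}

#' Infer unknown formation energies from known reaction energies
#'
#' Runs [buildTransferMatrix()], [buildInferenceSystem()] and
#' [solveLeastSquares()] and bundles the result.
#'
#' @param model a [StoichiometricModel-class].
#' @param tables an [EnergyTables-class].
#' @param tol relative singular-value cutoff.
#' @return an [InferenceResult-class].
#' @export
inferFormationEnergies <- function(model, tables, tol = 1e-10) {
  sys <- buildInferenceSystem(model, tables)
  sol <- solveLeastSquares(sys$Q, sys$b, tol = tol)
  new("InferenceResult", X_ids = sys$X_ids, P = sys$P,
      Fvec = unname(ifelse(sys$F_known, sys$Fvec, NA_real_)),
      F_known = unname(sys$F_known), T_mat = sys$T_mat, Q = sys$Q,
      b = sys$b, usable_rows = sys$usable_rows, X0 = unname(sol$X0),
      residuals = sol$residuals, rank = as.integer(sol$rank),
      singular_values = sol$singular_values,
      weakly_determined = unname(sol$weakly_determined), tol = tol)
}

#' Complete the energy tables from an inference solution
#'
#' Computes `F0 = t(S) %*% (P + T %*% X0)` — the reaction-energy vector
#' implied by the completed formation energies — then fills previously
#' unknown formation energies from `X0` and previously unknown reaction
#' energies from `F0`, both flagged provenance `"inferred"`. Energies that
#' were known on input are never overwritten; discrepancies against `F0` are
#' the subject of [consistencyReport()].
#'
#' @param model a [StoichiometricModel-class].
#' @param tables an [EnergyTables-class].
#' @param inference an [InferenceResult-class].
#' @return list with `tables` (completed) and `F0` (named numeric over all
#'   reactions).
#' @export
backSubstitute <- function(model, tables, inference) {
  if (!is(inference, "InferenceResult"))
    stop("inference must be an InferenceResult", call. = FALSE)
  Pc <- inference@P + as.numeric(inference@T_mat %*% inference@X0)
  X0 <- inference@X0; X_ids <- inference@X_ids
  weakly <- inference@weakly_determined
  F0 <- as.numeric(Matrix::crossprod(model@S, Pc))
  names(F0) <- reactionIds(model)
  fm <- tables@formation
  idx <- match(X_ids, fm$compound)
  fm$value[idx] <- X0
  fm$known[idx] <- TRUE
  fm$provenance[idx] <- "inferred"
  fm$weakly_determined[idx] <- weakly
  rx <- tables@reaction
  fill <- !rx$known
  rxi <- match(rx$reaction, names(F0))
  rx$dGr0[fill] <- F0[rxi[fill]]
  rx$known[fill] <- TRUE
  rx$provenance[fill] <- "inferred"
  tables@formation <- fm
  tables@reaction <- rx
  list(tables = tables, F0 = F0)
}

#' Consistency report over the four reaction categories
#'
#' Partitions the reactions into: (1) energy unknown on input (filled by
#' inference, nothing to compare against); (2) energy known on input and
#' involving at least one initially-unknown compound — the rows of the
#' reduced system; (3) energy known and involving no unknown compound;
#' (4) all reactions with known input energy, the union of 2 and 3. For the
#' comparable categories the report gives max and RMS discrepancy
#' `|F0 - F|` between the recomputed and the input energies, with verdict
#' `"consistent"` when the max discrepancy is at most
#' `atol + rtol * ||least-squares residual||_2`.
#'
#' @param tables the *completed* [EnergyTables-class] (provenance tags mark
#'   what was known on input).
#' @param F0 recomputed reaction-energy vector from [backSubstitute()].
#' @param inference an [InferenceResult-class].
#' @param atol,rtol absolute tolerance and residual-norm multiplier.
#' @return `data.frame` with one row per category: `category`, `n`,
#'   `max_discrepancy`, `rms_discrepancy`, `verdict`.
#' @export
consistencyReport <- function(tables, F0, inference, atol = 1e-6, rtol = 1) {
  rx <- tables@reaction
  input_known <- rx$known & rx$provenance == "input"
  usable <- rx$reaction %in% inference@usable_rows
  cat1 <- !input_known
  cat2 <- input_known & usable
  cat3 <- input_known & !usable
  cat4 <- input_known
  disc <- abs(F0[match(rx$reaction, names(F0))] - rx$dGr0)
  tolv <- atol + rtol * sqrt(sum(inference@residuals^2))
  summarise <- function(sel, label, comparable) {
    if (!comparable || sum(sel) == 0L)
      return(data.frame(category = label, n = sum(sel),
                        max_discrepancy = NA_real_, rms_discrepancy = NA_real_,
                        verdict = if (comparable) "empty" else "cannot compare",
                        stringsAsFactors = FALSE))
    d <- disc[sel]
    data.frame(category = label, n = sum(sel), max_discrepancy = max(d),
               rms_discrepancy = sqrt(mean(d^2)),
               verdict = if (max(d) <= tolv) "consistent" else "inconsistent",
               stringsAsFactors = FALSE)
  }
  rbind(
    summarise(cat1, "unknown energy (inferred)", FALSE),
    summarise(cat2, "known energy, involves unknown compounds", TRUE),
    summarise(cat3, "known energy, no unknown compounds", TRUE),
    summarise(cat4, "all known energies", TRUE)
  )
}

#' Thermodynamic completion pipeline
#'
#' Infers unknown compound formation energies from known reaction energies
#' (least squares on the standard scale), back-substitutes to fill unknown
#' reaction energies, applies the millimolar adjustment and produces the
#' consistency report. The inference runs on the standard scale and the
#' adjustment afterwards.
#'
#' @param model a [StoichiometricModel-class].
#' @param tables an [EnergyTables-class] (partial coverage allowed).
#' @param cfg an [AdjustmentConfig-class].
#' @param tol relative singular-value cutoff of the least-squares solve.
#' @return list with `tables` (completed, `dGm` filled), `inference`
#'   ([InferenceResult-class]), `F0` and `report`.
#' @export
completeEnergies <- function(model, tables, cfg = adjustmentConfig(),
                             tol = 1e-10) {
  inference <- inferFormationEnergies(model, tables, tol = tol)
  bs <- backSubstitute(model, tables, inference)
  completed <- adjustReactionEnergies(model, bs$tables, cfg)
  report <- consistencyReport(completed, bs$F0, inference)
  list(tables = completed, inference = inference, F0 = bs$F0,
       report = report)
}
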