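#' Set up a flux balance analysis problem
#'
#' Captures the model reference, the linear objective (by default the
#' model's objective column; when that is all-zero, the biomass reaction
#' gets coefficient 1) and a working copy of the bounds that media
#' specifications may override.
#'
#' @param model a [StoichiometricModel-class].
#' @param objective optional named numeric of objective coefficients.
#' @return a [FluxProblem-class].
#' @export
fluxProblem <- function(model, objective = NULL) {
  rx <- model@reactions
  obj <- rx$objective
  if (!is.null(objective)) {
    bad <- setdiff(names(objective), rx$id)
    if (length(bad))
      stop("objective names not in model: ", paste(bad, collapse = ", "),
           call. = FALSE)
    obj <- rep(0, nrow(rx))
    obj[match(names(objective), rx$id)] <- objective
  } else if (all(obj == 0)) {
    bio <- which(rx$class == "biomass")
    if (length(bio)) obj[bio[1L]] <- 1
  }
  names(obj) <- rx$id
  prob <- new("FluxProblem", model = model, objective = unname(obj),
              lb = rx$lb, ub = rx$ub)
  validObject(prob)
  prob
}

#' Apply a media specification to a flux problem
#'
#' Replaces the bounds of the listed exchange reactions. In strict-minimal
#' mode (the default) every exchange reaction *not* listed is closed to
#' uptake (`lb = 0`), so the listed nutrients are the only inputs; secretion
#' stays open. Keys that are not exchange reactions are rejected.
#'
#' @param problem a [FluxProblem-class] (or a model, converted implicitly).
#' @param media `data.frame` with columns `reaction_id`, `lb`, `ub`.
#' @param strict_minimal close unlisted exchange uptakes.
#' @return the updated [FluxProblem-class].
#' @export
applyMedia <- function(problem, media, strict_minimal = TRUE) {
  if (is(problem, "StoichiometricModel")) problem <- fluxProblem(problem)
  stopIfMissing(media, c("reaction_id", "lb", "ub"), "media")
  rx <- problem@model@reactions
  idx <- match(media$reaction_id, rx$id)
  if (anyNA(idx))
    stop("media lists unknown reaction id(s): ",
         paste(media$reaction_id[is.na(idx)], collapse = ", "),
         call. = FALSE)
  not_ex <- rx$class[idx] != "exchange"
  if (any(not_ex))
    stop("media keys must be exchange reactions; offending id(s): ",
         paste(media$reaction_id[not_ex], collapse = ", "), call. = FALSE)
  if (strict_minimal) {
    close_idx <- which(rx$class == "exchange" & !(rx$id %in% media$reaction_id))
    problem@lb[close_idx] <- pmax(problem@lb[close_idx], 0)
  }
  problem@lb[idx] <- media$lb
  problem@ub[idx] <- media$ub
  if (any(problem@lb > problem@ub))
    stop("media leaves lb > ub for some reaction", call. = FALSE)
  problem
}

# Solve max c'v  s.t.  S v = 0, lb <= v <= ub  with the package's
# bounded-variable simplex. Species participating in no reaction give null
# constraint rows and are dropped.
solveBoundedLP <- function(S, cc, lb, ub, maximise = TRUE) {
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("non-finite bounds; replace infinities with a large finite range",
         call. = FALSE)
  Sd <- as.matrix(S)
  Sd <- Sd[rowSums(abs(Sd)) > 0, , drop = FALSE]
  res <- boundedSimplex(Sd, rep(0, nrow(Sd)), cc, lb, ub,
                        maximise = maximise)
  if (res$status == "optimal")
    list(solved = 1L, v = res$x, value = res$value)
  else if (res$status == "infeasible")
    list(solved = -1L, v = NULL, value = NA_real_)
  else list(solved = 0L, v = NULL, value = NA_real_)
}

#' Solve the flux balance analysis linear program
#'
#' Maximizes the objective subject to the steady-state constraint
#' `S %*% v = 0` and the flux bounds. The solver is the package's
#' deterministic two-phase bounded-variable simplex, recorded in the result
#' metadata so
#' runs are reproducible; FBA optima are generally degenerate, and the
#' optional parsimonious step (`pfba = TRUE`) re-solves for the flux vector
#' of minimum total flux `sum(|v|)` among the optima, selecting a
#' reproducible representative.
#'
#' @param problem a [FluxProblem-class] or a [StoichiometricModel-class].
#' @param pfba apply the parsimonious secondary objective.
#' @param feas_tol steady-state feasibility tolerance used for the
#'   post-solve check.
#' @return a [FluxDistribution-class]; on infeasibility the status is
#'   returned and no flux vector is fabricated.
#' @export
#' @examples
#' m <- exampleToyModel()
#' solveFBA(m)
solveFBA <- function(problem, pfba = FALSE, feas_tol = 1e-9) {
  if (is(problem, "StoichiometricModel")) problem <- fluxProblem(problem)
  model <- problem@model
  S <- model@S
  cc <- problem@objective
  lb <- problem@lb; ub <- problem@ub
  meta <- list(solver = "boundedSimplex (two-phase primal simplex, Bland's rule, deterministic)",
               feas_tol = feas_tol, pfba = pfba)
  sol <- solveBoundedLP(S, cc, lb, ub, maximise = TRUE)
  if (sol$solved == -1L)
    return(new("FluxDistribution", v = numeric(), objectiveValue = NA_real_,
               status = "infeasible", metadata = meta))
  if (sol$solved != 1L)
    return(new("FluxDistribution", v = numeric(), objectiveValue = NA_real_,
               status = "unbounded", metadata = meta))
  v <- sol$v
  if (pfba) {
    # min sum(p + n) with v = p - n at the fixed optimum c'v = z*;
    # the split boxes reproduce exactly lb <= v <= ub
    n <- length(cc)
    Sd <- as.matrix(S)
    Sd <- Sd[rowSums(abs(Sd)) > 0, , drop = FALSE]
    Aeq <- rbind(cbind(Sd, -Sd), c(cc, -cc))
    beq <- c(rep(0, nrow(Sd)), sol$value)
    p_lo <- pmax(lb, 0); p_hi <- pmax(ub, 0)
    n_lo <- pmax(-ub, 0); n_hi <- pmax(-lb, 0)
    res <- boundedSimplex(Aeq, beq, rep(1, 2L * n),
                          c(p_lo, n_lo), c(p_hi, n_hi), maximise = FALSE)
    if (res$status == "optimal") {
      v <- res$x[seq_len(n)] - res$x[n + seq_len(n)]
      meta$pfba_total_flux <- sum(abs(v))
    } else {
      meta$pfba_note <- "parsimonious step did not converge; primary optimum kept"
    }
  }
  imbalance <- max(abs(as.numeric(S %*% v)))
  if (imbalance > feas_tol)
    warning(sprintf("steady-state residual %.3g exceeds feas_tol", imbalance),
            call. = FALSE)
  meta$steady_state_residual <- imbalance
  names(v) <- model@reactions$id
  new("FluxDistribution", v = v, objectiveValue = sol$value,
      status = "optimal", metadata = meta)
}
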