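#' Energetic reaction weights
#'
#' The weight of a reaction is its free-energy dissipation rate
#' `w = dGm * v` (energy gDW^-1 h^-1): the free-energy change per mole times
#' the moles passing per unit time. Fluxes with magnitude below `zero_tol`
#' are snapped to exactly 0 first, so LP solver noise cannot leak into the
#' zero-weight class.
#'
#' @param dGm named numeric of millimolar-adjusted reaction energies.
#' @param flux a [FluxDistribution-class] or named flux vector.
#' @param scope reaction ids to weight (default: every reaction named in
#'   `dGm`); typically the internal (reconstructed) reactions.
#' @param zero_tol magnitudes below this snap to zero (default 1e-9).
#' @return named numeric weight vector over `scope`.
#' @export
computeWeights <- function(dGm, flux, scope = names(dGm), zero_tol = 1e-9) {
  v <- if (is(flux, "FluxDistribution")) fluxes(flux) else flux
  miss_e <- scope[!(scope %in% names(dGm)) | is.na(dGm[scope])]
  if (length(miss_e))
    stop("missing millimolar energy for in-scope reaction(s): ",
         paste(utils::head(miss_e, 5L), collapse = ", "), call. = FALSE)
  miss_v <- setdiff(scope, names(v))
  if (length(miss_v))
    stop("missing flux for in-scope reaction(s): ",
         paste(utils::head(miss_v, 5L), collapse = ", "), call. = FALSE)
  vv <- v[scope]
  vv[abs(vv) < zero_tol] <- 0
  w <- dGm[scope] * vv
  w[abs(w) < zero_tol] <- 0
  w
}

# parse a scope label: "<-200", ">100" or "a~b"
parseScope <- function(label) {
  label <- gsub("−", "-", gsub("\\s", "", label))  # tolerate minus sign
  if (grepl("^<", label)) c(-Inf, as.numeric(sub("^<", "", label)))
  else if (grepl("^>", label)) c(as.numeric(sub("^>", "", label)), Inf)
  else {
    parts <- strsplit(label, "~", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) stop("cannot parse scope: ", label, call. = FALSE)
    as.numeric(parts)
  }
}

inScope <- function(w, lo, hi, zero_tol = 1e-9) {
  # negative-side bins are [lo, hi) with hi exclusive, positive-side (lo, hi]
  # with lo exclusive; the exact-zero class is |w| <= zero_tol.
  if (hi <= 0) w >= lo & w < hi & abs(w) > zero_tol
  else if (lo >= 0) w > lo & w <= hi & abs(w) > zero_tol
  else w >= lo & w <= hi
}

#' Weight-scope histogram
#'
#' Bins the weight vector into ordered scopes built from interior edges that
#' must bracket 0: open outer bins, half-open negative bins `[lo, hi)`, an
#' exact-zero bin (`|w| <= zero_tol`) and positive bins `(lo, hi]`. Every
#' weight lands in exactly one bin, so the counts partition the weighted
#' reaction set.
#'
#' @param w weight vector.
#' @param edges strictly increasing interior edges containing 0; the default
#'   reproduces the scopes `<-200`, `-200~-100`, `-100~-50`, `-50~0`, `0`,
#'   `0~40`, `40~100`, `>100`.
#' @param zero_tol width of the exact-zero class.
#' @return `data.frame` with `scope`, `count`, `pct` (percent of
#'   `length(w)`, 2 decimals).
#' @export
binWeights <- function(w, edges = c(-200, -100, -50, 0, 40, 100),
                       zero_tol = 1e-9) {
  if (is.unsorted(edges, strictly = TRUE))
    stop("bin edges must be strictly increasing (overlapping bins)",
         call. = FALSE)
  if (!0 %in% edges) stop("bin edges must contain 0", call. = FALSE)
  neg <- edges[edges < 0]; pos <- edges[edges > 0]
  lows <- c(-Inf, neg, 0, 0, pos)
  highs <- c(neg, 0, 0, pos, Inf)
  labels <- character(length(lows))
  counts <- integer(length(lows))
  wz <- w
  wz[abs(wz) <= zero_tol] <- 0
  for (k in seq_along(lows)) {
    lo <- lows[k]; hi <- highs[k]
    labels[k] <- if (lo == hi) "0"
      else if (is.infinite(lo)) paste0("<", numChr(hi))
      else if (is.infinite(hi)) paste0(">", numChr(lo))
      else paste0(numChr(lo), "~", numChr(hi))
    counts[k] <- if (lo == hi) sum(wz == 0)
      else sum(inScope(wz, lo, hi, zero_tol))
  }
  stopifnot(sum(counts) == length(w))
  data.frame(scope = labels, count = counts,
             pct = round(100 * counts / length(w), 2L),
             stringsAsFactors = FALSE)
}

#' Highly-dissipative (and other extreme-weight) reactions
#'
#' For each requested scope label (`"<-200"`, `"-100~-50"`, `">40"`, ...)
#' lists the reactions whose weight falls inside it, sorted by decreasing
#' `|w|`. Reactions at the tails of the weight distribution are the main
#' free-energy dissipation channels of the network.
#'
#' @param w named weight vector.
#' @param thresholds character vector of scope labels.
#' @param annotations optional `data.frame` with an `id` column, passed
#'   through to the report.
#' @return named list of `data.frame`s (`id`, `w`, annotation columns).
#' @export
extremeReactions <- function(w, thresholds = c("<-200", "-100~-50", ">40"),
                             annotations = NULL) {
  out <- lapply(thresholds, function(label) {
    iv <- parseScope(label)
    sel <- which(inScope(w, iv[1L], iv[2L]))
    sel <- sel[order(-abs(w[sel]))]
    df <- data.frame(id = names(w)[sel], w = unname(w[sel]),
                     stringsAsFactors = FALSE)
    if (!is.null(annotations) && nrow(df))
      df <- cbind(df, annotations[match(df$id, annotations$id),
                                  setdiff(names(annotations), "id"),
                                  drop = FALSE])
    rownames(df) <- NULL
    df
  })
  names(out) <- thresholds
  out
}

#' Weight-flux scatter data and Pearson correlation
#'
#' Emits the `(w, v)` pair table together with the Pearson correlation
#' coefficient and its two-sided test. A degenerate input (either vector
#' constant) yields `undefined = TRUE` with `r = NA` rather than an error.
#'
#' @param w,v equal-length weight and flux vectors.
#' @return list with `pairs` (`data.frame`), `r`, `statistic`, `p_value`,
#'   `undefined`.
#' @export
scatterCorrelation <- function(w, v) {
  if (length(w) != length(v))
    stop("w and v must have equal length", call. = FALSE)
  pairs <- data.frame(w = unname(w), v = unname(v))
  if (!is.null(names(w))) pairs <- cbind(id = names(w), pairs)
  if (length(w) < 3L || stats::sd(w) == 0 || stats::sd(v) == 0)
    return(list(pairs = pairs, r = NA_real_, statistic = NA_real_,
                p_value = NA_real_, undefined = TRUE))
  ct <- stats::cor.test(w, v, method = "pearson")
  list(pairs = pairs, r = unname(ct$estimate), statistic = unname(ct$statistic),
       p_value = ct$p.value, undefined = FALSE)
}

#' Build the weighted bipartite species-reaction graph
#'
#' Species become nodes of type `"metabolite"`, reactions nodes of type
#' `"reaction"` carrying their weight `w`; each nonzero stoichiometric
#' coefficient becomes an edge whose direction follows the coefficient sign
#' (species -> reaction for reactants, reaction -> species for products)
#' with the coefficient magnitude as edge attribute.
#'
#' @param model a [StoichiometricModel-class].
#' @param w named weight vector (reactions without an entry get `NA`).
#' @return an `igraph` graph.
#' @export
buildWeightedGraph <- function(model, w) {
  trip <- Matrix::summary(model@S)
  sp <- model@species$id[trip$i]
  rx <- model@reactions$id[trip$j]
  from <- ifelse(trip$x < 0, sp, rx)
  to <- ifelse(trip$x < 0, rx, sp)
  nodes <- data.frame(
    name = c(model@species$id, model@reactions$id),
    type = rep(c("metabolite", "reaction"),
               c(nrow(model@species), nrow(model@reactions))),
    w = c(rep(NA_real_, nrow(model@species)),
          unname(w[match(model@reactions$id, names(w))])),
    stringsAsFactors = FALSE)
  edges <- data.frame(from = from, to = to, coefficient = abs(trip$x),
                      stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nodes)
}

#' Export the weighted metabolic network
#'
#' Writes the bipartite species-reaction graph (see [buildWeightedGraph()])
#' as GraphML or as a plain edge-list TSV (`from`, `to`, `coefficient`,
#' `reaction_w`). With `projection = TRUE` a reaction-adjacency projection
#' is additionally written next to `path` (suffix `.projection.tsv`):
#' reactions sharing a metabolite, edge weight the mean of the two reaction
#' weights.
#'
#' @param model a [StoichiometricModel-class].
#' @param w named weight vector.
#' @param path output file.
#' @param format `"graphml"` or `"edgelist"`.
#' @param projection also write the reaction-projection edge list.
#' @return `path`, invisibly.
#' @export
exportGraph <- function(model, w, path, format = c("graphml", "edgelist"),
                        projection = FALSE) {
  format <- match.arg(format)
  g <- buildWeightedGraph(model, w)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  if (format == "graphml") {
    ok <- tryCatch({ igraph::write_graph(g, path, format = "graphml"); TRUE },
                   error = function(e) stop("cannot write graph to ", path,
                                            ": ", conditionMessage(e),
                                            call. = FALSE))
  } else {
    el <- igraph::as_data_frame(g, what = "edges")
    nodes <- igraph::as_data_frame(g, what = "vertices")
    el$reaction_w <- nodes$w[match(
      ifelse(nodes$type[match(el$from, nodes$name)] == "reaction",
             el$from, el$to), nodes$name)]
    writeTsv(el, path)
  }
  if (projection) {
    wn <- w[!is.na(w)]
    inc <- abs(model@S[, names(wn), drop = FALSE]) > 0
    pairs <- which(as.matrix(Matrix::crossprod(inc)) > 0, arr.ind = TRUE)
    pairs <- pairs[pairs[, 1L] < pairs[, 2L], , drop = FALSE]
    proj <- data.frame(from = names(wn)[pairs[, 1L]],
                       to = names(wn)[pairs[, 2L]],
                       weight = (wn[pairs[, 1L]] + wn[pairs[, 2L]]) / 2)
    writeTsv(proj, paste0(tools::file_path_sans_ext(path), ".projection.tsv"))
  }
  invisible(path)
}

#' Re-import a GraphML export
#'
#' @param path GraphML file written by [exportGraph()].
#' @return an `igraph` graph.
#' @export
importGraph <- function(path) igraph::read_graph(path, format = "graphml")
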