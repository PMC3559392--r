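# Internal helpers: identifier normalisation and TSV plumbing.

#' Split a compartmentalized species id into compound and compartment
#'
#' Two identifier dialects are supported behind one normalizer: the bracket
#' style used in published reconstructions (`"atp[c]"`) and the SBML style
#' (`"M_atp_c"`, optional `M_` prefix, trailing `_<compartment>`). In
#' `"auto"` mode the bracket form is tried first. An id matching neither
#' dialect maps to itself with compartment `""` in lenient mode, and raises
#' an error in strict mode.
#'
#' @param ids character vector of species identifiers.
#' @param syntax `"auto"`, `"bracket"`, `"sbml"` or `"none"`.
#' @param strict error on non-matching ids instead of identity fallback.
#' @return `data.frame` with columns `id`, `compound`, `compartment`.
#' @export
#' @examples
#' parseSpeciesIds(c("atp[c]", "M_atp_p", "h2o"))
parseSpeciesIds <- function(ids, syntax = c("auto", "bracket", "sbml", "none"),
                            strict = FALSE) {
  syntax <- match.arg(syntax)
  compound <- ids
  compartment <- rep("", length(ids))
  if (syntax != "none") {
    bracket <- grepl("^(.+)\\[([A-Za-z0-9]+)\\]$", ids)
    sbml <- grepl("^(M_)?(.+)_([a-z]{1,2})$", ids)
    use_bracket <- bracket & syntax %in% c("auto", "bracket")
    use_sbml <- !use_bracket & sbml & syntax %in% c("auto", "sbml")
    compound[use_bracket] <- sub("^(.+)\\[([A-Za-z0-9]+)\\]$", "\\1",
                                 ids[use_bracket])
    compartment[use_bracket] <- sub("^(.+)\\[([A-Za-z0-9]+)\\]$", "\\2",
                                    ids[use_bracket])
    compound[use_sbml] <- sub("^(M_)?(.+)_([a-z]{1,2})$", "\\2", ids[use_sbml])
    compartment[use_sbml] <- sub("^(M_)?(.+)_([a-z]{1,2})$", "\\3",
                                 ids[use_sbml])
    unmatched <- !(use_bracket | use_sbml)
    if (strict && any(unmatched))
      stop("species ids do not match the compartment syntax: ",
           paste(utils::head(ids[unmatched], 5L), collapse = ", "),
           call. = FALSE)
  }
  data.frame(id = ids, compound = compound, compartment = compartment,
             stringsAsFactors = FALSE)
}

readTsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, colClasses = NA,
                    na.strings = c("NA", ""))
}

writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

# format numerics without scientific notation surprises in TSV output
numChr <- function(x) format(x, digits = 15, trim = TRUE, scientific = FALSE)

stopIfMissing <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  invisible(df)
}

# Run code with a private RNG stream, restoring the caller's state.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
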