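#' @import methods
NULL

#' Domain-abundance census matrix
#'
#' Container for a genomic census of protein domain structures: a nonnegative
#' integer matrix of abundances `g` with domains as rows and proteomes as
#' columns. Row names are domain identifiers (SCOP-style concise
#' classification strings such as `"c.26.1.1"` are typical), column names are
#' proteome identifiers.
#'
#' @slot counts nonnegative numeric matrix, domains x proteomes, with unique
#'   row and column names.
#'
#' @seealso [AbundanceMatrix()], [encodeCharacters()], [simulateCensus()]
#' @export
setClass("AbundanceMatrix", slots = c(counts = "matrix"))

setValidity("AbundanceMatrix", function(object) {
  g <- object@counts
  if (!is.numeric(g)) return("counts must be numeric")
  if (anyNA(g)) return("counts must not contain NA")
  if (any(g < 0)) return("counts must be nonnegative")
  if (is.null(rownames(g)) || is.null(colnames(g)))
    return("counts must have row (domain) and column (proteome) names")
  if (anyDuplicated(rownames(g))) return("domain ids must be unique")
  if (anyDuplicated(colnames(g))) return("proteome ids must be unique")
  TRUE
})

#' Ordered multistate phylogenetic character matrix
#'
#' Taxa x characters matrix of integer states in `0 .. nStates - 1`, with
#' linearly ordered (Wagner) state transformation and an optional
#' hypothetical-ancestor state vector used for Lundberg rooting.
#'
#' @slot states integer matrix (taxa x characters) with entries in
#'   `0 .. nStates - 1`; row names are taxon labels.
#' @slot nStates single integer, the number of ordered states S.
#' @slot ancestor integer vector of length `ncol(states)` (the hypothetical
#'   ancestor), or `integer(0)` when absent.
#' @slot ordering character flag, always `"linear"`: states transform along
#'   linearly ordered, reversible pathways with cost |i - j|.
#'
#' @seealso [CharacterMatrix()], [wagnerLength()], [searchMP()]
#' @export
setClass("CharacterMatrix",
         slots = c(states = "matrix", nStates = "integer",
                   ancestor = "integer", ordering = "character"))

setValidity("CharacterMatrix", function(object) {
  x <- object@states
  S <- object@nStates
  if (length(S) != 1L || is.na(S) || S < 2L) return("nStates must be a single integer >= 2")
  if (!is.numeric(x)) return("states must be an integer matrix")
  if (anyNA(x)) return("states must not contain NA")
  if (any(x < 0L) || any(x >= S)) return("every state must lie in 0 .. nStates-1")
  if (is.null(rownames(x))) return("states must have taxon row names")
  if (anyDuplicated(rownames(x))) return("taxon labels must be unique")
  if (length(object@ancestor)) {
    a <- object@ancestor
    if (length(a) != ncol(x)) return("ancestor length must equal the character count")
    if (any(a < 0L) || any(a >= S)) return("ancestor states must lie in 0 .. nStates-1")
  }
  if (!identical(object@ordering, "linear")) return("ordering must be \"linear\"")
  TRUE
})

#' Configuration of the synthetic-data generators
#'
#' One object fixes every tunable of the synthetic census, sequence and tRNA
#' generators, including the seed that makes all downstream draws
#' reproducible.
#'
#' @slot nDomains number of domain taxa in the census (>= 3).
#' @slot nProteomes number of proteome columns (>= 2).
#' @slot nTrna number of tRNA taxa (>= 4).
#' @slot seqCount number of protein sequences to draw (>= 2).
#' @slot seqLengthRange integer pair, minimum and maximum residue count.
#' @slot nStates ordered-state count for simulated characters (default 24).
#' @slot plantedDipeptides character vector of 2-mers over the 20-letter
#'   alphabet whose chain transition weights are boosted in ancient families.
#' @slot enrichmentFactor multiplier (>= 1) applied to planted transitions.
#' @slot noiseSd nonnegative standard deviation of the log-normal abundance
#'   noise.
#' @slot seed single integer seed.
#'
#' @seealso [simulationConfig()], [simulateCensus()], [simulateSequences()],
#'   [simulateTrnaMatrix()]
#' @export
setClass("SimulationConfig",
         slots = c(nDomains = "integer", nProteomes = "integer",
                   nTrna = "integer", seqCount = "integer",
                   seqLengthRange = "integer", nStates = "integer",
                   plantedDipeptides = "character",
                   enrichmentFactor = "numeric", noiseSd = "numeric",
                   seed = "integer"))

setValidity("SimulationConfig", function(object) {
  if (object@nDomains < 3L) return("nDomains must be >= 3")
  if (object@nProteomes < 2L) return("nProteomes must be >= 2")
  if (object@nTrna < 4L) return("nTrna must be >= 4")
  if (object@seqCount < 2L) return("seqCount must be >= 2")
  if (length(object@seqLengthRange) != 2L ||
      any(object@seqLengthRange < 2L) ||
      object@seqLengthRange[1L] > object@seqLengthRange[2L])
    return("seqLengthRange must be an increasing pair of residue counts >= 2")
  if (object@nStates < 2L) return("nStates must be >= 2")
  if (length(object@plantedDipeptides)) {
    ok <- grepl(sprintf("^[%s]{2}$", paste(aminoAcids(), collapse = "")),
                object@plantedDipeptides)
    if (!all(ok)) return("plantedDipeptides must be 2-mers over the 20-letter alphabet")
  }
  if (object@enrichmentFactor < 1) return("enrichmentFactor must be >= 1")
  if (object@noiseSd < 0) return("noiseSd must be nonnegative")
  if (length(object@seed) != 1L || is.na(object@seed)) return("seed must be a single integer")
  TRUE
})
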