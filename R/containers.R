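#' Construct an AbundanceMatrix
#'
#' @param counts nonnegative numeric matrix, domains x proteomes.
#' @param domainIds,proteomeIds optional identifier vectors overriding the
#'   dimnames of `counts`.
#' @return an [AbundanceMatrix-class] object.
#' @examples
#' g <- matrix(c(0, 5, 10, 2, 3, 4), nrow = 3,
#'             dimnames = list(paste0("d", 1:3), c("p1", "p2")))
#' AbundanceMatrix(g)
#' @export
AbundanceMatrix <- function(counts, domainIds = NULL, proteomeIds = NULL) {
  counts <- as.matrix(counts)
  if (!is.null(domainIds)) rownames(counts) <- domainIds
  if (!is.null(proteomeIds)) colnames(counts) <- proteomeIds
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("domain%03d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("proteome%03d", seq_len(ncol(counts)))
  new("AbundanceMatrix", counts = counts)
}

#' Construct a CharacterMatrix
#'
#' @param states integer matrix (taxa x characters), entries in
#'   `0 .. nStates - 1`, with taxon row names.
#' @param nStates number of ordered states S (default the smallest S covering
#'   the observed states, at least 2).
#' @param ancestor optional hypothetical-ancestor state vector (length =
#'   character count).
#' @param taxa optional taxon labels overriding `rownames(states)`.
#' @return a [CharacterMatrix-class] object with linear (Wagner) ordering.
#' @examples
#' x <- matrix(c(0L, 1L, 3L, 2L, 0L, 1L), nrow = 3,
#'             dimnames = list(c("A", "B", "C"), NULL))
#' CharacterMatrix(x, nStates = 4)
#' @export
CharacterMatrix <- function(states, nStates = NULL, ancestor = NULL, taxa = NULL) {
  states <- as.matrix(states)
  storage.mode(states) <- "integer"
  if (!is.null(taxa)) rownames(states) <- taxa
  if (is.null(nStates)) nStates <- max(2L, max(states) + 1L)
  new("CharacterMatrix", states = states, nStates = as.integer(nStates),
      ancestor = if (is.null(ancestor)) integer(0) else as.integer(ancestor),
      ordering = "linear")
}

#' @rdname AbundanceMatrix
#' @param x an AbundanceMatrix or CharacterMatrix.
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' @rdname AbundanceMatrix
#' @export
setMethod("counts", "AbundanceMatrix", function(x) x@counts)

#' @rdname AbundanceMatrix
#' @export
setGeneric("domainIds", function(x) standardGeneric("domainIds"))

#' @rdname AbundanceMatrix
#' @export
setMethod("domainIds", "AbundanceMatrix", function(x) rownames(x@counts))

#' @rdname AbundanceMatrix
#' @export
setGeneric("proteomeIds", function(x) standardGeneric("proteomeIds"))

#' @rdname AbundanceMatrix
#' @export
setMethod("proteomeIds", "AbundanceMatrix", function(x) colnames(x@counts))

#' @rdname CharacterMatrix
#' @param x a CharacterMatrix.
#' @export
setGeneric("states", function(x) standardGeneric("states"))

#' @rdname CharacterMatrix
#' @export
setMethod("states", "CharacterMatrix", function(x) x@states)

#' @rdname CharacterMatrix
#' @export
setGeneric("nStates", function(x) standardGeneric("nStates"))

#' @rdname CharacterMatrix
#' @export
setMethod("nStates", "CharacterMatrix", function(x) x@nStates)

#' @rdname CharacterMatrix
#' @export
setGeneric("taxa", function(x) standardGeneric("taxa"))

#' @rdname CharacterMatrix
#' @export
setMethod("taxa", "CharacterMatrix", function(x) rownames(x@states))

#' @rdname CharacterMatrix
#' @export
setGeneric("ancestor", function(x) standardGeneric("ancestor"))

#' @rdname CharacterMatrix
#' @export
setMethod("ancestor", "CharacterMatrix", function(x) {
  if (length(x@ancestor)) x@ancestor else NULL
})

setMethod("show", "AbundanceMatrix", function(object) {
  g <- object@counts
  cat(sprintf("AbundanceMatrix: %d domains x %d proteomes\n", nrow(g), ncol(g)))
  cat(sprintf("  total abundance %s; occupancy %.1f%%\n",
              format(sum(g), big.mark = ","), 100 * mean(g > 0)))
  k <- min(5L, nrow(g)); j <- min(5L, ncol(g))
  print(g[seq_len(k), seq_len(j), drop = FALSE])
  if (nrow(g) > k || ncol(g) > j) cat("  ...\n")
  invisible(object)
})

setMethod("show", "CharacterMatrix", function(object) {
  x <- object@states
  cat(sprintf("CharacterMatrix: %d taxa x %d linearly ordered characters (S = %d)\n",
              nrow(x), ncol(x), object@nStates))
  if (length(object@ancestor))
    cat("  hypothetical ancestor present\n")
  k <- min(5L, nrow(x)); j <- min(8L, ncol(x))
  print(x[seq_len(k), seq_len(j), drop = FALSE])
  if (nrow(x) > k || ncol(x) > j) cat("  ...\n")
  invisible(object)
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat(sprintf("  census: %d domains x %d proteomes, noiseSd = %g\n",
              object@nDomains, object@nProteomes, object@noiseSd))
  cat(sprintf("  sequences: %d, length %d-%d, %d planted 2-mers, enrichment x%g\n",
              object@seqCount, object@seqLengthRange[1], object@seqLengthRange[2],
              length(object@plantedDipeptides), object@enrichmentFactor))
  cat(sprintf("  tRNA: %d taxa, S = %d; seed = %d\n",
              object@nTrna, object@nStates, object@seed))
  invisible(object)
})
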