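# Synthetic censuses, sequence sets and tRNA character matrices with the
# statistical structure the downstream analyses assume, plus ground truth for
# recovery tests. The generators emulate the shape of a genome census of
# domain structures and of a culled single-domain PDB sequence set; they make
# no attempt at realistic genome sizes or 3-D structure.

#' Default planted dipeptide set
#'
#' A synthetic 33-member set of 2-mers used as the enrichment ground truth.
#' Its size mirrors the number of dipeptides reported enriched in ancient
#' fold families, and its makeup follows the same qualitative rules: members
#' are built from ancient (Group 1/2) residues plus the prebiotically
#' abundant Gly/Glu, Ala/Gly/Val/Ile/Leu act as hubs, and Ser is absent. It
#' is a synthetic stand-in, not the published list.
#'
#' @return character vector of 33 dipeptides.
#' @export
defaultPlantedDipeptides <- function() {
  c("AL", "LA", "AV", "VA", "AI", "IA", "AT", "TA", "AK", "KA", "AG",
    "GA", "GV", "VG", "GI", "IG", "GL", "LG", "GT", "TG", "VL", "LV",
    "VI", "IV", "IL", "LI", "AF", "FA", "PA", "AP", "KV", "TV", "EG")
}

#' Construct a SimulationConfig
#'
#' The defaults define the standard synthetic study conditions: a census of
#' 50 domains across 20 proteomes with log-normal abundance noise of sd 0.3,
#' 400 sequences of 80-200 residues with a 33-dipeptide planted set boosted
#' 5-fold in ancient families, 12 tRNA taxa, and 24 ordered character states.
#'
#' @param nDomains,nProteomes,nTrna,seqCount,seqLengthRange,nStates,plantedDipeptides,enrichmentFactor,noiseSd,seed
#'   see [SimulationConfig-class].
#' @return a validated [SimulationConfig-class] object.
#' @export
simulationConfig <- function(nDomains = 50L, nProteomes = 20L, nTrna = 12L,
                             seqCount = 400L, seqLengthRange = c(80L, 200L),
                             nStates = 24L,
                             plantedDipeptides = defaultPlantedDipeptides(),
                             enrichmentFactor = 5, noiseSd = 0.3, seed = 1L) {
  if (nDomains < 3L) stop("invalid config: nDomains must be >= 3")
  new("SimulationConfig",
      nDomains = as.integer(nDomains), nProteomes = as.integer(nProteomes),
      nTrna = as.integer(nTrna), seqCount = as.integer(seqCount),
      seqLengthRange = as.integer(seqLengthRange),
      nStates = as.integer(nStates),
      plantedDipeptides = as.character(plantedDipeptides),
      enrichmentFactor = as.numeric(enrichmentFactor),
      noiseSd = as.numeric(noiseSd), seed = as.integer(seed))
}

#' Simulate a domain-abundance census
#'
#' Domains are born in a ranked order at evenly spaced times on a `[0, 1)`
#' timescale and accumulate genomic abundance in every proteome at a rate
#' proportional to the time elapsed since birth, the standing assumption that
#' the popularity of a domain structure grows with its age. Per-proteome
#' accumulation rates are phylogenetically autocorrelated: a Yule organismal
#' tree is drawn and rates follow geometric Brownian variation along it.
#' Observed counts are `round(rate * elapsed * exp(noise))` with log-normal
#' noise of standard deviation `noiseSd`; under noise, recently born domains
#' round to zero in part of the proteomes, so older domains are both more
#' abundant and more widespread.
#'
#' @param config a [SimulationConfig-class].
#' @return list with elements `census` (an [AbundanceMatrix-class]),
#'   `truth` (list: `birthOrder`, domain ids oldest first; `birthRank`, named
#'   rank vector; `birthTime`, named birth times) and `tree` (the organismal
#'   Yule tree).
#' @export
simulateCensus <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  n <- config@nDomains
  p <- config@nProteomes
  withr::with_seed(config@seed, {
    domainIds <- sprintf("ff%03d", seq_len(n))
    birthOrder <- sample(domainIds)           # oldest first
    birthRank <- stats::setNames(seq_len(n), birthOrder)[domainIds]
    tBirth <- (birthRank - 1) / n             # oldest at 0
    orgTree <- ape::rphylo(p, birth = 1, death = 0)
    orgTree$tip.label <- sprintf("proteome%02d", seq_len(p))
    orgTree$edge.length <- orgTree$edge.length / max(ape::node.depth.edgelength(orgTree))
    rates <- 10 * exp(ape::rTraitCont(orgTree, sigma = 0.3))
    lambda <- outer(1 - tBirth, rates[orgTree$tip.label])
    eps <- if (config@noiseSd > 0)
      matrix(exp(stats::rnorm(n * p, 0, config@noiseSd)), n, p) else 1
    g <- round(lambda * eps)
    dimnames(g) <- list(domainIds, orgTree$tip.label)
    list(census = AbundanceMatrix(g),
         truth = list(birthOrder = birthOrder,
                      birthRank = stats::setNames(birthRank, domainIds),
                      birthTime = stats::setNames(tBirth, domainIds)),
         tree = orgTree)
  })
}

# first-order chain transition matrix: uniform background with planted
# dipeptide transitions multiplied by `factor`, rows renormalized
.chainMatrix <- function(planted, factor) {
  aa <- aminoAcids()
  W <- matrix(1, 20, 20, dimnames = list(aa, aa))
  if (length(planted) && factor != 1) {
    for (d in planted) {
      r <- substr(d, 1L, 1L); c <- substr(d, 2L, 2L)
      W[r, c] <- W[r, c] * factor
    }
  }
  W / rowSums(W)
}

.sampleChain <- function(len, P, start) {
  aaIdx <- integer(len)
  cum <- t(apply(P, 1L, cumsum))
  u <- stats::runif(len)
  aaIdx[1L] <- sample.int(20L, 1L, prob = start)
  for (i in 2:len)
    aaIdx[i] <- findInterval(u[i], cum[aaIdx[i - 1L], ]) + 1L
  paste(aminoAcids()[aaIdx], collapse = "")
}

# secondary structure as a 3-class segment process over the DSSP alphabet
.sampleStructure <- function(len) {
  out <- character(0)
  while (length(out) < len) {
    cls <- sample(c("helix", "strand", "coil"), 1L, prob = c(0.40, 0.25, 0.35))
    runLen <- switch(cls,
                     helix = 4L + stats::rpois(1L, 6),
                     strand = 3L + stats::rpois(1L, 3),
                     coil = 2L + stats::rpois(1L, 3))
    seg <- switch(cls,
                  helix = rep(sample(c("H", "G", "I"), 1L,
                                     prob = c(0.8, 0.15, 0.05)), runLen),
                  strand = rep(sample(c("E", "B"), 1L, prob = c(0.85, 0.15)),
                               runLen),
                  coil = sample(c("T", "S", " "), runLen, replace = TRUE,
                                prob = c(0.3, 0.2, 0.5)))
    out <- c(out, seg)
  }
  paste(out[seq_len(len)], collapse = "")
}

#' Simulate a culled single-domain sequence set with structure annotation
#'
#' Each timeline family receives sequences drawn from a first-order
#' amino-acid chain. Families with `nd <= ancientCutoff` use a chain whose
#' transition weights for the planted dipeptides are multiplied by
#' `enrichmentFactor`; all other families use the uniform background chain.
#' Every record carries a same-length secondary-structure string over the
#' DSSP letter set `{H,G,I,E,B,T,S,' '}` generated by a helix/strand/coil
#' segment process.
#'
#' @param config a [SimulationConfig-class].
#' @param timeline data.frame with columns `ffId` and `nd` (one row per fold
#'   family), e.g. built from a census tree or supplied directly.
#' @param ancientCutoff families at or below this nd use the enriched chain
#'   (default 0.2).
#' @return data.frame with columns `id`, `residues`, `ffId`, `nd`,
#'   `structure` (one row per sequence).
#' @export
simulateSequences <- function(config, timeline, ancientCutoff = 0.2) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  if (missing(timeline) || is.null(timeline) || !nrow(timeline))
    stop("invalid input: timeline must be a nonempty data.frame")
  stopifnot(all(c("ffId", "nd") %in% names(timeline)))
  withr::with_seed(config@seed + 1L, {
    nSeq <- config@seqCount
    fam <- timeline[rep_len(seq_len(nrow(timeline)), nSeq), ]
    lens <- sample(config@seqLengthRange[1L]:config@seqLengthRange[2L],
                   nSeq, replace = TRUE)
    Pback <- .chainMatrix(character(0), 1)
    Panc <- .chainMatrix(config@plantedDipeptides, config@enrichmentFactor)
    start <- rep(1 / 20, 20)
    residues <- character(nSeq)
    structure <- character(nSeq)
    for (i in seq_len(nSeq)) {
      P <- if (fam$nd[i] <= ancientCutoff) Panc else Pback
      residues[i] <- .sampleChain(lens[i], P, start)
      structure[i] <- .sampleStructure(lens[i])
    }
    data.frame(id = sprintf("seq%04d", seq_len(nSeq)),
               residues = residues, ffId = fam$ffId, nd = fam$nd,
               structure = structure, stringsAsFactors = FALSE)
  })
}

#' Simulate an ordered multistate tRNA character matrix
#'
#' Characters evolve along a random rooted binary tree from an all-zero
#' ancestor with a drift toward higher states, emulating the model in which
#' conformational order increases through evolution. Per edge and character
#' the state changes by `rpois(2 * noiseSd) - rpois(0.5 * noiseSd)`, clamped
#' to `0 .. nStates-1`, so `noiseSd = 0` leaves every taxon identical to the
#' ancestor. Isoacceptor-like groups are planted as true clades of the
#' generating tree and ranked by the node depth of their most recent common
#' ancestor. Each planted group also receives a small block of clade-marker
#' characters carrying a large shared derived state on the group's stem,
#' emulating the diagnostic substructural features isoacceptor families
#' share; planted groups are therefore monophyletic in most parsimonious
#' trees and their constraint statistic S is 0.
#'
#' @param config a [SimulationConfig-class] (`nTrna >= 4`).
#' @param nChars number of characters (default 40), including the marker
#'   blocks (the markers are silent when `noiseSd = 0`).
#' @param markersPerGroup clade-marker characters per planted group
#'   (default 3).
#' @return list with `matrix` (a [CharacterMatrix-class] with all-zero
#'   ancestor), `groups` (named list of planted taxon groups), `tree` (the
#'   generating rooted tree) and `truth` (list with `groupAges`, group ->
#'   age rank).
#' @export
simulateTrnaMatrix <- function(config, nChars = 40L, markersPerGroup = 3L) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  n <- config@nTrna
  S <- config@nStates
  withr::with_seed(config@seed + 2L, {
    tree <- ape::rtree(n, tip.label = sprintf("trna%02d", seq_len(n)))
    edge <- tree$edge
    po <- rev(.postorderEdges(edge))      # preorder: parents first
    nNode <- max(edge)
    statesAll <- matrix(0L, nNode, nChars)
    up <- 2 * config@noiseSd
    down <- 0.5 * config@noiseSd
    for (r in po) {
      parentState <- statesAll[edge[r, 1L], ]
      delta <- stats::rpois(nChars, up) - stats::rpois(nChars, down)
      statesAll[edge[r, 2L], ] <- pmax(0L, pmin(S - 1L,
                                                parentState + delta))
    }
    X <- statesAll[seq_len(n), , drop = FALSE]
    rownames(X) <- tree$tip.label
    # planted groups: disjoint clades of 2 .. ceiling(n/3) tips
    nTip <- n
    below <- vector("list", nNode)
    depth <- numeric(nNode)
    for (r in po) depth[edge[r, 2L]] <- depth[edge[r, 1L]] + 1
    for (r in .postorderEdges(edge)) {
      ch <- edge[r, 2L]
      tipsBelow <- if (ch <= nTip) tree$tip.label[ch] else below[[ch]]
      below[[edge[r, 1L]]] <- c(below[[edge[r, 1L]]], tipsBelow)
      if (ch > nTip) below[[ch]] <- tipsBelow
    }
    cand <- (nTip + 1L):nNode
    sizes <- lengths(below[cand])
    keep <- cand[sizes >= 2L & sizes <= ceiling(n / 3)]
    keep <- keep[order(depth[keep])]
    groups <- list()
    used <- character(0)
    for (v in keep) {
      tips <- below[[v]]
      if (!length(intersect(tips, used))) {
        groups[[sprintf("grp%02d", length(groups) + 1L)]] <- tips
        used <- c(used, tips)
      }
    }
    ages <- vapply(groups, function(g) {
      min(depth[match(g, tree$tip.label)])
    }, 0)
    # clade-marker blocks: a large shared derived state on each group's stem
    if (length(groups) && markersPerGroup > 0L && config@noiseSd > 0) {
      jump <- max(2L, S %/% 2L)
      blockStart <- nChars - length(groups) * markersPerGroup + 1L
      if (blockStart >= 1L) {
        for (i in seq_along(groups)) {
          cols <- blockStart + (i - 1L) * markersPerGroup +
            seq_len(markersPerGroup) - 1L
          rows <- match(groups[[i]], tree$tip.label)
          X[rows, cols] <- pmin(S - 1L, X[rows, cols] + jump)
        }
      }
    }
    cm <- CharacterMatrix(X, nStates = S, ancestor = rep(0L, nChars))
    list(matrix = cm, groups = groups, tree = tree,
         truth = list(groupAges = rank(ages, ties.method = "first")))
  })
}

#' Write sequence records to FASTA plus a structure annotation table
#'
#' @param records data.frame from [simulateSequences()].
#' @param fastaPath FASTA output path (headers `id ffId nd`).
#' @param annotPath optional tab-separated annotation path with columns
#'   `id`, `ffId`, `nd`, `structure`.
#' @return invisibly, `fastaPath`.
#' @export
writeSequenceFasta <- function(records, fastaPath, annotPath = NULL) {
  seqs <- Biostrings::AAStringSet(records$residues)
  names(seqs) <- sprintf("%s %s %.4f", records$id, records$ffId, records$nd)
  Biostrings::writeXStringSet(seqs, fastaPath)
  if (!is.null(annotPath))
    utils::write.table(records[, c("id", "ffId", "nd", "structure")],
                       annotPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fastaPath)
}

#' Read sequence records written by [writeSequenceFasta()]
#'
#' @param fastaPath FASTA path.
#' @param annotPath optional annotation path restoring `structure`.
#' @return data.frame with columns `id`, `residues`, `ffId`, `nd` and, when
#'   the annotation is given, `structure`.
#' @export
readSequenceFasta <- function(fastaPath, annotPath = NULL) {
  seqs <- Biostrings::readAAStringSet(fastaPath)
  parts <- strsplit(names(seqs), " ")
  rec <- data.frame(id = vapply(parts, `[[`, "", 1L),
                    residues = as.character(seqs),
                    ffId = vapply(parts, `[[`, "", 2L),
                    nd = as.numeric(vapply(parts, `[[`, "", 3L)),
                    stringsAsFactors = FALSE)
  if (!is.null(annotPath)) {
    ann <- utils::read.table(annotPath, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    rec$structure <- ann$structure[match(rec$id, ann$id)]
  }
  rownames(rec) <- NULL
  rec
}
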