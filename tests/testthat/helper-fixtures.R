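# Shared fixture builders and independent oracles used across test files.

# random ordered character matrix
randomCharMatrix <- function(nTaxa, nChars, S = 6L, seed = 1L,
                             ancestor = NULL) {
  withr::with_seed(seed, {
    X <- matrix(sample(0:(S - 1L), nTaxa * nChars, replace = TRUE),
                nTaxa, nChars,
                dimnames = list(sprintf("t%02d", seq_len(nTaxa)), NULL))
    CharacterMatrix(X, nStates = S, ancestor = ancestor)
  })
}

# independent Wagner-length oracle: phangorn Sankoff with |i - j| step costs
phangornLength <- function(tree, cm) {
  S <- nStates(cm)
  cost <- outer(0:(S - 1L), 0:(S - 1L), function(i, j) abs(i - j))
  dimnames(cost) <- list(0:(S - 1L), 0:(S - 1L))
  X <- states(cm)
  chr <- apply(X, 2L, as.character)
  rownames(chr) <- rownames(X)
  pd <- phangorn::phyDat(chr, type = "USER", levels = as.character(0:(S - 1L)))
  phangorn::parsimony(tree, pd, method = "sankoff", cost = cost)
}

# independent monophyly check: root at an outside tip and inspect the clade
isMonophyleticOracle <- function(tree, group) {
  out <- setdiff(tree$tip.label, group)[1L]
  rt <- ape::root(tree, outgroup = out, resolve.root = TRUE)
  mr <- ape::getMRCA(rt, group)
  setequal(ape::extract.clade(rt, mr)$tip.label, group)
}

# exhaustive constraint-S oracle over all unrooted topologies (<= 7 taxa),
# scored with the phangorn oracle
constraintSOracle <- function(cm, group) {
  X <- states(cm)
  if (!is.null(ancestor(cm)))
    X <- rbind(X, ANCESTOR = ancestor(cm))
  cm2 <- CharacterMatrix(X, nStates = nStates(cm))
  trees <- phangorn::allTrees(nrow(X), rooted = FALSE, tip.label = rownames(X))
  lens <- vapply(trees, phangornLength, 0, cm = cm2)
  mono <- vapply(trees, isMonophyleticOracle, TRUE, group = group)
  min(lens[mono]) - min(lens)
}

# records with planted structure for the region-bias positive control:
# the enriched 2-mer lives in helices, never in loops
loopAvoidanceRecords <- function(n = 10L, seed = 42L) {
  withr::with_seed(seed, {
    rec <- lapply(seq_len(n), function(i) {
      k <- 8L + i %% 3L                         # helix block of AL repeats
      helix <- paste(rep("AL", k), collapse = "")
      loopRes <- paste(sample(c("Q", "N", "E", "D"), 2L * k, TRUE),
                       collapse = "")
      data.frame(id = sprintf("s%02d", i),
                 residues = paste0(helix, loopRes),
                 structure = paste0(strrep("H", 2L * k), strrep(" ", 2L * k)),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rec)
  })
}
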