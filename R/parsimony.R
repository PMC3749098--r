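# Wagner (linearly ordered, reversible) maximum parsimony: tree scoring by
# linear-cost dynamic programming, tree search (exhaustive, hill-climbing,
# parsimony ratchet), Lundberg rooting, constraint analysis, bootstrap and
# tree statistics.

.BIG <- 1e9

# Postorder edge ordering computed without assuming ape's internal order:
# reverse preorder from the root guarantees every child subtree is complete
# before its edge to the parent is consumed.
.postorderEdges <- function(edge) {
  nE <- nrow(edge)
  rootCand <- setdiff(edge[, 1L], edge[, 2L])
  root <- rootCand[1L]
  byParent <- split(seq_len(nE), edge[, 1L])
  out <- integer(nE)
  stk <- byParent[[as.character(root)]]
  nOut <- 0L
  while (length(stk)) {
    r <- stk[length(stk)]
    stk <- stk[-length(stk)]
    nOut <- nOut + 1L
    out[nOut] <- r
    ch <- edge[r, 2L]
    kids <- byParent[[as.character(ch)]]
    if (!is.null(kids)) stk <- c(stk, kids)
  }
  rev(out)
}

# leaf cost array: S x K x nTip, 0 at the observed state, .BIG elsewhere
.leafCostArray <- function(X, S) {
  n <- nrow(X); K <- ncol(X)
  a <- array(.BIG, dim = c(S, K, n))
  for (i in seq_len(n)) a[cbind(X[i, ] + 1L, seq_len(K), i)] <- 0
  a
}

# min_j c[j, ] + |i - j| via two cumulative passes (linear-cost transform)
.linTransform <- function(cc, S) {
  if (S > 1L) {
    for (i in 2:S) cc[i, ] <- pmin(cc[i, ], cc[i - 1L, ] + 1)
    for (i in (S - 1L):1L) cc[i, ] <- pmin(cc[i, ], cc[i + 1L, ] + 1)
  }
  cc
}

# Minimum total Wagner cost of one topology. edge: 2-column matrix, tips
# 1..nTip matching rows of the leaf cost array.
.scoreEdges <- function(edge, nTip, leafCost, S, weights = NULL) {
  po <- .postorderEdges(edge)
  nNode <- max(edge)
  cost <- vector("list", nNode)
  for (r in po) {
    p <- edge[r, 1L]; ch <- edge[r, 2L]
    cc <- if (ch <= nTip) matrix(leafCost[, , ch], nrow = S) else cost[[ch]]
    cc <- .linTransform(cc, S)
    cost[[p]] <- if (is.null(cost[[p]])) cc else cost[[p]] + cc
  }
  root <- edge[po[length(po)], 1L]
  rc <- cost[[root]]
  m <- rc[1L, ]
  if (S > 1L) for (i in 2:S) m <- pmin(m, rc[i, ])
  if (is.null(weights)) sum(m) else sum(m * weights)
}

# map a phylo's tips onto the rows of X and score it
.scorePhylo <- function(phy, X, S, weights = NULL) {
  ord <- match(phy$tip.label, rownames(X))
  if (anyNA(ord))
    stop("tree leaves and matrix taxa differ: ",
         paste(phy$tip.label[is.na(ord)], collapse = ", "))
  lc <- .leafCostArray(X[ord, , drop = FALSE], S)
  .scoreEdges(phy$edge, length(phy$tip.label), lc, S, weights)
}

.charMatrixOf <- function(m) {
  stopifnot(is(m, "CharacterMatrix"))
  states(m)
}

# matrix possibly augmented with the ancestor as taxon "ANCESTOR"
.augmentedStates <- function(m) {
  X <- states(m)
  if (is.null(ancestor(m))) return(X)
  rbind(X, ANCESTOR = ancestor(m))
}

#' Wagner parsimony length of a tree
#'
#' Minimum total cost over ancestral-state assignments, with cost `|i - j|`
#' per change between linearly ordered, reversible states, summed over all
#' characters. Computed by linear-cost (Sankoff-type) dynamic programming; the
#' result does not depend on the position of the root.
#'
#' @param tree a `phylo` tree (rooted or unrooted) whose leaf labels equal the
#'   taxa of `m`. A leaf labelled `ANCESTOR` is scored with the matrix's
#'   ancestor states when those are present.
#' @param m a [CharacterMatrix-class].
#' @param weights optional per-character weights (used by the ratchet).
#' @return tree length in steps.
#' @examples
#' x <- matrix(c(0L, 3L), ncol = 1, dimnames = list(c("A", "B"), NULL))
#' tr <- ape::read.tree(text = "(A,B);")
#' wagnerLength(tr, CharacterMatrix(x, nStates = 4))  # 3
#' @export
wagnerLength <- function(tree, m, weights = NULL) {
  X <- .charMatrixOf(m)
  tips <- tree$tip.label
  if ("ANCESTOR" %in% tips && !is.null(ancestor(m))) X <- .augmentedStates(m)
  if (!setequal(tips, rownames(X)))
    stop("leaf/taxon mismatch: tree has {",
         paste(setdiff(tips, rownames(X)), collapse = ","),
         "} not in matrix; matrix has {",
         paste(setdiff(rownames(X), tips), collapse = ","), "} not in tree")
  .scorePhylo(tree, X, nStates(m), weights)
}

# ---- tree surgery on rooted binary phylo ------------------------------------

# Trees built by the surgery below are structurally valid but do not follow
# ape's node-numbering conventions; rewrite through newick before handing a
# tree to ape or to the caller.
.toNewick <- function(phy) {
  nTip <- length(phy$tip.label)
  edge <- phy$edge
  byParent <- split(edge[, 2L], edge[, 1L])
  root <- setdiff(edge[, 1L], edge[, 2L])[1L]
  build <- function(v) {
    if (v <= nTip) return(phy$tip.label[v])
    kids <- byParent[[as.character(v)]]
    paste0("(", paste(vapply(kids, build, ""), collapse = ","), ")")
  }
  paste0(build(root), ";")
}

.normalizePhylo <- function(phy) ape::read.tree(text = .toNewick(phy))

# rooted tree on the first three labels: ((l1,l2),l3)
.startTree <- function(labels) {
  edge <- matrix(c(4L, 5L, 5L, 4L,
                   5L, 1L, 2L, 3L), ncol = 2L)
  structure(list(edge = edge, tip.label = labels[1:3], Nnode = 2L),
            class = "phylo")
}

# attach a new tip (label) onto edge row e of a rooted phylo
.attachTip <- function(phy, e, label) {
  nTip <- length(phy$tip.label)
  edge <- phy$edge
  # renumber: internal nodes shift by 1 because a tip is added
  edge[edge > nTip] <- edge[edge > nTip] + 1L
  newTip <- nTip + 1L
  newNode <- nTip + 1L + phy$Nnode + 1L
  p <- edge[e, 1L]; ch <- edge[e, 2L]
  edge[e, ] <- c(p, newNode)
  edge <- rbind(edge, c(newNode, ch), c(newNode, newTip))
  structure(list(edge = edge, tip.label = c(phy$tip.label, label),
                 Nnode = phy$Nnode + 1L), class = "phylo")
}

# the two NNI rearrangements around internal edge row e (child is internal)
.nniNeighbors <- function(phy, e) {
  edge <- phy$edge
  nTip <- length(phy$tip.label)
  v <- edge[e, 2L]; u <- edge[e, 1L]
  if (v <= nTip) return(list())
  vKids <- which(edge[, 1L] == v)
  uKids <- setdiff(which(edge[, 1L] == u), e)
  if (!length(uKids)) return(list())
  s <- uKids[1L]
  out <- vector("list", 2L)
  for (k in 1:2) {
    a <- vKids[k]
    e2 <- edge
    e2[a, 1L] <- u
    e2[s, 1L] <- v
    out[[k]] <- structure(list(edge = e2, tip.label = phy$tip.label,
                               Nnode = phy$Nnode), class = "phylo")
  }
  out
}

# canonical key of the unrooted topology: sorted splits (smaller side as
# sorted label string)
.splitSet <- function(phy) {
  nTip <- length(phy$tip.label)
  edge <- phy$edge
  po <- .postorderEdges(edge)
  nNode <- max(edge)
  below <- vector("list", nNode)
  keys <- character(0)
  allTips <- sort(phy$tip.label)
  for (r in po) {
    ch <- edge[r, 2L]
    tipsBelow <- if (ch <= nTip) phy$tip.label[ch] else below[[ch]]
    below[[edge[r, 1L]]] <- c(below[[edge[r, 1L]]], tipsBelow)
    if (ch > nTip) below[[ch]] <- tipsBelow
    k <- length(tipsBelow)
    if (k >= 2L && k <= nTip - 2L) {
      side <- sort(tipsBelow)
      other <- setdiff(allTips, side)
      small <- if (length(side) < length(other) ||
                   (length(side) == length(other) &&
                    side[1L] < other[1L])) side else other
      keys <- c(keys, paste(small, collapse = "|"))
    }
  }
  sort(unique(keys))
}

.topologyKey <- function(phy) paste(.splitSet(phy), collapse = ";")

.hasSplit <- function(phy, group) {
  group <- sort(group)
  if (length(group) < 2L || length(group) > length(phy$tip.label) - 2L)
    return(TRUE)  # trivially a split
  other <- sort(setdiff(phy$tip.label, group))
  small <- if (length(group) < length(other) ||
               (length(group) == length(other) && group[1L] < other[1L]))
    group else other
  paste(small, collapse = "|") %in% .splitSet(phy)
}

# ---- search -----------------------------------------------------------------

# deterministic stepwise addition over the taxa of X (rows), optionally
# keeping `group` monophyletic
.stepwiseAddition <- function(X, S, addOrder, group = NULL, weights = NULL) {
  labels <- addOrder
  phy <- .startTree(labels)
  lc <- .leafCostArray(X[labels, , drop = FALSE], S)
  if (length(labels) == 3L) return(phy)
  for (t in 4:length(labels)) {
    nE <- nrow(phy$edge)
    best <- NULL; bestLen <- Inf
    for (e in seq_len(nE)) {
      cand <- .attachTip(phy, e, labels[t])
      if (!is.null(group) && !.hasSplit(cand, intersect(group, cand$tip.label)))
        next
      len <- .scoreEdges(cand$edge, t, lc[, , seq_len(t), drop = FALSE], S, weights)
      if (len < bestLen) { bestLen <- len; best <- cand }
    }
    phy <- best
  }
  phy
}

# steepest-descent NNI hill climbing; returns list(tree, length, pool) where
# pool holds co-optimal topologies encountered at the final length
.nniOptimize <- function(phy, X, S, weights = NULL, group = NULL,
                         maxTrees = 20L) {
  nTip <- length(phy$tip.label)
  lc <- .leafCostArray(X[phy$tip.label, , drop = FALSE], S)
  len <- .scoreEdges(phy$edge, nTip, lc, S, weights)
  repeat {
    improved <- FALSE
    ties <- list()
    internal <- which(phy$edge[, 2L] > nTip)
    for (e in internal) {
      for (cand in .nniNeighbors(phy, e)) {
        if (!is.null(group) && !.hasSplit(cand, group)) next
        l2 <- .scoreEdges(cand$edge, nTip, lc, S, weights)
        if (l2 < len) {
          phy <- cand; len <- l2; improved <- TRUE
          ties <- list()
          break
        } else if (l2 == len) {
          ties <- c(ties, list(cand))
        }
      }
      if (improved) break
    }
    if (!improved) {
      pool <- c(list(phy), ties)
      keys <- vapply(pool, .topologyKey, "")
      pool <- pool[!duplicated(keys)]
      if (length(pool) > maxTrees) pool <- pool[seq_len(maxTrees)]
      return(list(tree = phy, length = len, pool = pool))
    }
  }
}

#' Maximum-parsimony tree search over ordered characters
#'
#' Searches tree space for minimum Wagner length. `"exhaustive"` scores every
#' unrooted topology (guaranteed optimal, allowed up to 9 taxa);
#' `"hillclimb"` runs `nStarts` addition-sequence replicates (the first in
#' matrix row order, the rest in seeded random orders), each followed by
#' nearest-neighbor-interchange descent, and keeps the best; `"ratchet"`
#' additionally alternates NNI optimization under reweighted characters (a
#' random 25% upweighted to 2) and the original weights until `nIdle`
#' iterations pass without improvement. All ties are broken deterministically
#' (lowest edge / first candidate).
#'
#' @param m a [CharacterMatrix-class] with >= 3 taxa.
#' @param strategy `"hillclimb"` (default), `"exhaustive"` or `"ratchet"`.
#' @param seed integer seed for the stochastic parts (addition orders,
#'   ratchet reweighting); the same seed reproduces the same search.
#' @param nStarts number of addition-sequence replicates for the heuristic
#'   strategies (default 5; use 1 for large matrices with strong signal).
#' @param nIdle ratchet stopping rule: idle iterations tolerated (default 5).
#' @param maxTrees cap on the number of co-optimal trees returned (default 20).
#' @param group optional taxon subset forced monophyletic during the search
#'   (used by [constraintS()]).
#' @param includeAncestor include the matrix's hypothetical ancestor as an
#'   additional terminal taxon labelled `ANCESTOR` (used by constraint
#'   analysis, where monophyly must be judged on the rooted topology); the
#'   default searches over the taxa only and leaves rooting to
#'   [lundbergRoot()].
#' @return list with elements `trees` (list of `phylo`, all equally best
#'   topologies found), `length` (their shared Wagner length) and `strategy`.
#' @export
searchMP <- function(m, strategy = c("hillclimb", "exhaustive", "ratchet"),
                     seed = 1L, nStarts = 5L, nIdle = 5L, maxTrees = 20L,
                     group = NULL, includeAncestor = FALSE) {
  strategy <- match.arg(strategy)
  X <- if (includeAncestor) .augmentedStates(m) else states(m)
  S <- nStates(m)
  n <- nrow(X)
  if (n < 3L) stop("at least 3 taxa are required")
  if (!is.null(group)) {
    group <- as.character(group)
    if (!all(group %in% rownames(X))) stop("group contains unknown taxa")
  }
  labels <- rownames(X)

  if (strategy == "exhaustive") {
    if (n > 9L)
      stop("exhaustive search is refused for more than 9 taxa (",
           n, " requested): the number of unrooted topologies grows as ",
           "(2n-5)!!; use strategy = \"hillclimb\" or \"ratchet\"")
    trees <- phangorn::allTrees(n, rooted = FALSE, tip.label = labels)
    lc <- .leafCostArray(X, S)
    lens <- vapply(trees, function(tr) {
      ord <- match(tr$tip.label, labels)
      ed <- tr$edge
      ed[ed <= n] <- ord[ed[ed <= n]]
      .scoreEdges(ed, n, lc, S)
    }, 0)
    if (!is.null(group)) {
      ok <- vapply(trees, .hasSplit, TRUE, group = group)
      lens[!ok] <- Inf
    }
    best <- min(lens)
    idx <- which(lens == best)
    if (length(idx) > maxTrees) idx <- idx[seq_len(maxTrees)]
    return(list(trees = lapply(trees[idx], function(tr) tr),
                length = best, strategy = strategy))
  }

  orders <- withr::with_seed(seed, {
    c(list(labels),
      lapply(seq_len(max(0L, nStarts - 1L)), function(i) sample(labels)))
  })
  res <- NULL
  for (ord in orders) {
    start <- .stepwiseAddition(X, S, ord, group = group)
    cand <- .nniOptimize(start, X, S, group = group, maxTrees = maxTrees)
    if (is.null(res) || cand$length < res$length) {
      res <- cand
    } else if (cand$length == res$length) {
      pool <- c(res$pool, cand$pool)
      keys <- vapply(pool, .topologyKey, "")
      res$pool <- pool[!duplicated(keys)]
      if (length(res$pool) > maxTrees) res$pool <- res$pool[seq_len(maxTrees)]
    }
  }

  if (strategy == "ratchet") {
    K <- ncol(X)
    withr::with_seed(seed, {
      idle <- 0L
      while (idle < nIdle) {
        w <- rep(1, K)
        w[sample.int(K, max(1L, round(0.25 * K)))] <- 2
        pert <- .nniOptimize(res$tree, X, S, weights = w, group = group,
                             maxTrees = 1L)
        re <- .nniOptimize(pert$tree, X, S, group = group, maxTrees = maxTrees)
        if (re$length < res$length) {
          res <- re; idle <- 0L
        } else {
          if (re$length == res$length) {
            pool <- c(res$pool, re$pool)
            keys <- vapply(pool, .topologyKey, "")
            res$pool <- pool[!duplicated(keys)][seq_len(min(maxTrees,
                                                 sum(!duplicated(keys))))]
          }
          idle <- idle + 1L
        }
      }
    })
  }

  list(trees = lapply(res$pool, .normalizePhylo), length = res$length,
       strategy = strategy)
}

#' Lundberg rooting with a hypothetical ancestor
#'
#' Attaches the hypothetical ancestor to the tree edge that minimizes total
#' Wagner length (no outgroup taxa required) and places the root at the
#' attachment point. When several edges tie, the lowest-indexed edge is
#' chosen.
#'
#' @param tree a `phylo` tree whose leaves are the taxa of `m` (a rooted tree
#'   is treated as its unrooted topology).
#' @param m a [CharacterMatrix-class].
#' @param ancestor ancestor state vector; defaults to the matrix's own
#'   ancestor slot.
#' @return a rooted `phylo` whose root is the ancestor attachment point.
#' @export
lundbergRoot <- function(tree, m, ancestor = NULL) {
  if (is.null(ancestor)) ancestor <- ancestor(m)
  if (is.null(ancestor)) stop("missing ancestor state vector")
  X <- states(m)
  if (length(ancestor) != ncol(X))
    stop("ancestor length must equal the character count")
  X <- rbind(X, ANCESTOR = as.integer(ancestor))
  S <- nStates(m)
  phy <- tree
  if (ape::is.rooted(phy)) phy <- ape::unroot(phy)
  nE <- nrow(phy$edge)
  nTip <- length(phy$tip.label)
  lens <- numeric(nE)
  for (e in seq_len(nE)) {
    cand <- .attachTip(phy, e, "ANCESTOR")
    lens[e] <- .scorePhylo(cand, X, S)
  }
  eBest <- which.min(lens)  # lowest index on ties
  attached <- .normalizePhylo(.attachTip(phy, eBest, "ANCESTOR"))
  rooted <- ape::root(attached, outgroup = "ANCESTOR", resolve.root = TRUE)
  ape::drop.tip(rooted, "ANCESTOR")
}

#' Constraint analysis: extra steps to force a group monophyletic
#'
#' `S = length(best tree with the group constrained monophyletic) -
#' length(unconstrained best tree)`, a measure of the ancestrality of tRNA
#' groups (smaller S = less recruitment = more ancient). Always `>= 0`; a
#' group that is the full taxon set (or a single taxon) is trivially
#' monophyletic and gets `S = 0`.
#'
#' @param m a [CharacterMatrix-class]. Its ancestor, when present, is included
#'   as an additional taxon so monophyly is assessed on the rooted topology.
#' @param group character vector of taxon labels.
#' @param strategy search strategy passed to [searchMP()]; the default uses
#'   exhaustive search for up to 9 taxa and hill climbing above that.
#' @param seed seed forwarded to the searches.
#' @return number of additional steps S (nonnegative).
#' @export
constraintS <- function(m, group, strategy = NULL, seed = 1L) {
  group <- as.character(group)
  allTaxa <- taxa(m)
  if (!length(group)) stop("group must be nonempty")
  if (!all(group %in% allTaxa))
    stop("group contains unknown taxa: ",
         paste(setdiff(group, allTaxa), collapse = ", "))
  hasAnc <- !is.null(ancestor(m))
  if (length(group) < 2L || length(group) == length(allTaxa) ||
      (!hasAnc && length(group) >= length(allTaxa) - 1L))
    return(0)
  nEff <- length(allTaxa) + as.integer(hasAnc)
  if (is.null(strategy))
    strategy <- if (nEff <= 9L) "exhaustive" else "hillclimb"
  free <- searchMP(m, strategy, seed = seed, maxTrees = 1L,
                   includeAncestor = hasAnc)
  if (length(free$trees) && .hasSplit(free$trees[[1L]], group)) {
    forced <- free
  } else {
    forced <- searchMP(m, strategy, seed = seed, maxTrees = 1L, group = group,
                       includeAncestor = hasAnc)
  }
  max(0, forced$length - free$length)
}

#' Nonparametric bootstrap support
#'
#' Characters are resampled with replacement to the original character count;
#' each replicate matrix is analysed with the given search strategy, and the
#' support of every internal clade of the reference tree is the percentage of
#' replicate best trees containing the corresponding bipartition.
#'
#' @param m a [CharacterMatrix-class].
#' @param replicates number of bootstrap replicates (>= 1).
#' @param seed integer seed; fixed seed gives identical supports on rerun.
#' @param strategy search strategy for replicates (default `"hillclimb"`).
#' @param tree optional reference `phylo`; defaults to the best tree from a
#'   search on the full matrix (Lundberg-rooted when an ancestor is present).
#' @return the reference tree with `node.label` holding percentage support of
#'   each internal node's clade (the root is labelled `""`).
#' @export
bootstrapSupport <- function(m, replicates = 100L, seed = 1L,
                             strategy = c("hillclimb", "exhaustive", "ratchet"),
                             tree = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(replicates >= 1L)
  if (is.null(tree)) {
    res <- searchMP(m, strategy, seed = seed, maxTrees = 1L)
    tree <- res$trees[[1L]]
    if (!is.null(ancestor(m))) tree <- lundbergRoot(tree, m)
  }
  X <- states(m)
  K <- ncol(X)
  anc <- ancestor(m)
  repKeys <- withr::with_seed(seed, {
    lapply(seq_len(replicates), function(b) {
      idx <- sample.int(K, K, replace = TRUE)
      mb <- CharacterMatrix(X[, idx, drop = FALSE], nStates = nStates(m),
                            ancestor = if (is.null(anc)) NULL else anc[idx])
      rb <- searchMP(mb, strategy, seed = seed + b, maxTrees = 1L)
      .splitSet(rb$trees[[1L]])
    })
  })
  nTip <- length(tree$tip.label)
  edge <- tree$edge
  po <- .postorderEdges(edge)
  nNode <- max(edge)
  below <- vector("list", nNode)
  for (r in po) {
    ch <- edge[r, 2L]
    tipsBelow <- if (ch <= nTip) tree$tip.label[ch] else below[[ch]]
    below[[edge[r, 1L]]] <- c(below[[edge[r, 1L]]], tipsBelow)
    if (ch > nTip) below[[ch]] <- tipsBelow
  }
  allTips <- sort(tree$tip.label)
  splitKeyOf <- function(tips) {
    side <- sort(tips)
    other <- setdiff(allTips, side)
    small <- if (length(side) < length(other) ||
                 (length(side) == length(other) && side[1L] < other[1L]))
      side else other
    paste(small, collapse = "|")
  }
  labs <- character(tree$Nnode)
  rootNode <- nTip + 1L
  for (v in (nTip + 1L):nNode) {
    tipsBelow <- below[[v]]
    k <- length(tipsBelow)
    if (v == rootNode || k < 2L || k > nTip - 2L) {
      labs[v - nTip] <- ""
    } else {
      key <- splitKeyOf(tipsBelow)
      hits <- vapply(repKeys, function(ks) key %in% ks, TRUE)
      labs[v - nTip] <- sprintf("%g", round(100 * mean(hits), 1))
    }
  }
  tree$node.label <- labs
  tree
}

#' Tree statistics: length, CI, RI and g1 skewness
#'
#' The ensemble consistency index is `CI = sum(per-character minima) /
#' length`, where the minimum for an ordered character is its leaf state range
#' (max - min). The retention index is `RI = (sum(maxima) - length) /
#' (sum(maxima) - sum(minima))` with the per-character maximum the star-tree
#' (bush) length, i.e. the minimum over a single median ancestral state of the
#' summed distances. `g1` is the sample skewness of the Wagner lengths of
#' `nRandom` topologies drawn uniformly at random; strongly negative `g1`
#' indicates phylogenetic signal.
#'
#' @param trees a `phylo`, or list of `phylo` (as returned in
#'   `searchMP()$trees`); the reported length is the minimum over them.
#' @param m a [CharacterMatrix-class].
#' @param nRandom number of random topologies for g1 (default 1000).
#' @param seed integer seed for the random topologies.
#' @return list with elements `length`, `ci`, `ri`, `g1` (CI and RI are `NA`
#'   when the matrix carries no variation).
#' @export
treeStats <- function(trees, m, nRandom = 1000L, seed = 1L) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) stop("at least one tree is required")
  X <- states(m)
  S <- nStates(m)
  len <- min(vapply(trees, wagnerLength, 0, m = m))
  minima <- apply(X, 2L, function(x) max(x) - min(x))
  maxima <- apply(X, 2L, function(x) {
    med <- sort(x)[ceiling(length(x) / 2)]
    sum(abs(x - med))
  })
  ci <- ri <- NA_real_
  if (len > 0 && sum(maxima) > sum(minima)) {
    ci <- sum(minima) / len
    ri <- (sum(maxima) - len) / (sum(maxima) - sum(minima))
  }
  labels <- rownames(X)
  lc <- .leafCostArray(X, S)
  lens <- withr::with_seed(seed, {
    vapply(seq_len(nRandom), function(i) {
      tr <- ape::rtopology(length(labels), rooted = FALSE, tip.label = labels)
      ord <- match(tr$tip.label, labels)
      ed <- tr$edge
      ed[ed <= length(labels)] <- ord[ed[ed <= length(labels)]]
      .scoreEdges(ed, length(labels), lc, S)
    }, 0)
  })
  n <- length(lens)
  zc <- lens - mean(lens)
  s <- sqrt(sum(zc^2) / (n - 1))
  g1 <- if (s > 0) (n / ((n - 1) * (n - 2))) * sum((zc / s)^3) else NA_real_
  list(length = len, ci = ci, ri = ri, g1 = g1)
}
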