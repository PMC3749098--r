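# Sequence culling, amino-acid / dipeptide signature vectors per fold family,
# hypergeometric enrichment in ancient families, group contrasts, hydropathy
# summaries and dipeptide networks.

.dipeptideUniverse <- function() {
  aa <- aminoAcids()
  as.vector(t(outer(aa, aa, paste0)))  # ordered pairs, row-major by first residue
}

#' Cull a sequence set by length, domain annotation and pairwise identity
#'
#' Mirrors the high-quality culling of a structural sequence set: sequences
#' outside the length range, with more than one fold-family assignment, or
#' with an unassigned stretch longer than `maxUnassigned` residues are
#' dropped; then a greedy identity cull processes sequences by descending
#' length and rejects any sequence whose identity to an already retained one
#' reaches `maxIdentity`. Identity is `matches / overlap length`, maximized
#' over all ungapped sliding offsets with overlap of at least half the
#' shorter sequence. This is a lightweight stand-in for a full culling
#' server; only the thresholds matter downstream.
#'
#' @param records data.frame with a `residues` column; optional columns
#'   `nDomains` (number of fold-family assignments, default 1) and
#'   `unassignedRun` (longest unassigned stretch, default 0).
#' @param maxIdentity identity threshold (default 0.25).
#' @param lengthRange allowed residue counts (default `c(40, 10000)`).
#' @param singleDomain drop records with `nDomains > 1` (default TRUE).
#' @param maxUnassigned longest tolerated unassigned stretch (default 30).
#' @return the retained subset of `records` (possibly empty).
#' @export
cullSequences <- function(records, maxIdentity = 0.25,
                          lengthRange = c(40L, 10000L), singleDomain = TRUE,
                          maxUnassigned = 30L) {
  len <- nchar(records$residues)
  keep <- len >= lengthRange[1L] & len <= lengthRange[2L]
  if (singleDomain && "nDomains" %in% names(records))
    keep <- keep & records$nDomains <= 1L
  if ("unassignedRun" %in% names(records))
    keep <- keep & records$unassignedRun <= maxUnassigned
  records <- records[keep, , drop = FALSE]
  if (!nrow(records)) return(records)
  ord <- order(nchar(records$residues), decreasing = TRUE)
  records <- records[ord, , drop = FALSE]
  ints <- lapply(records$residues, function(s) utf8ToInt(s))
  retained <- integer(0)
  for (i in seq_len(nrow(records))) {
    ok <- TRUE
    for (j in retained) {
      if (.slidingIdentity(ints[[i]], ints[[j]]) >= maxIdentity) {
        ok <- FALSE
        break
      }
    }
    if (ok) retained <- c(retained, i)
  }
  out <- records[retained, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# max over ungapped offsets of matches/overlap, overlap >= half the shorter
.slidingIdentity <- function(a, b) {
  la <- length(a); lb <- length(b)
  minOv <- max(1L, ceiling(min(la, lb) / 2))
  best <- 0
  for (off in (-(la - minOv)):(lb - minOv)) {
    i1 <- max(1L, 1L - off); i2 <- min(la, lb - off)
    if (i2 - i1 + 1L < minOv) next
    ov <- i2 - i1 + 1L
    id <- sum(a[i1:i2] == b[(i1 + off):(i2 + off)]) / ov
    if (id > best) best <- id
  }
  best
}

#' Overlapping dipeptide and residue counts of one sequence
#'
#' Counts the `L - 1` sequentially overlapping 2-mers of a length-L sequence.
#' Pairs containing an ambiguous residue (X or Z) are tallied separately and
#' excluded from the 400-vector of ordered standard pairs, so
#' `sum(dipep) + ambiguous == L - 1`.
#'
#' @param seq residue string over the 20-letter alphabet plus X/Z.
#' @return list with `dipep` (named 400-vector), `aa` (named 20-vector of
#'   standard residue counts), `ambiguous` (count of 2-mers touching X/Z)
#'   and `aaAmbiguous` (count of X/Z residues).
#' @examples
#' dipeptideCounts("ALA")$dipep[c("AL", "LA")]
#' @export
dipeptideCounts <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    stop("seq must be one nonempty residue string")
  ch <- strsplit(seq, "")[[1L]]
  bad <- setdiff(unique(ch), c(aminoAcids(), "X", "Z"))
  if (length(bad))
    stop("unknown residue code(s): ", paste(bad, collapse = ", "))
  aa <- table(factor(ch, levels = aminoAcids()))
  aaAmb <- sum(ch %in% c("X", "Z"))
  L <- length(ch)
  dip <- character(0)
  amb <- 0L
  if (L >= 2L) {
    first <- ch[-L]; second <- ch[-1L]
    isAmb <- first %in% c("X", "Z") | second %in% c("X", "Z")
    amb <- sum(isAmb)
    dip <- paste0(first[!isAmb], second[!isAmb])
  }
  dipep <- table(factor(dip, levels = .dipeptideUniverse()))
  list(dipep = c(unclass(dipep)), aa = c(unclass(aa)),
       ambiguous = amb, aaAmbiguous = aaAmb)
}

#' Amino-acid and dipeptide composition profiles per fold family
#'
#' Pools the sequences of each fold family into 20-dimensional amino-acid and
#' 400-dimensional dipeptide frequency signature vectors, and arranges them
#' as evolutionary heat-map matrices: rows (families) ordered by domain age
#' (`nd` ascending), columns (residues or dipeptides) ordered by global mean
#' frequency, descending.
#'
#' @param records data.frame with columns `residues`, `ffId` and `nd`.
#' @return list with `families` (data.frame: `ffId`, `nd`, `aaCount`,
#'   `dipepCount`), `aaFreq` (families x 20 matrix, rows sum to 1),
#'   `dipepFreq` (families x 400), and heat-map-ordered copies `aaHeatmap`
#'   and `dipepHeatmap`.
#' @export
buildProfiles <- function(records) {
  need <- c("residues", "ffId", "nd")
  if (!all(need %in% names(records)))
    stop("records must carry columns: ", paste(need, collapse = ", "))
  if (anyNA(records$nd))
    stop("record(s) without nd: ",
         paste(records$id[is.na(records$nd)], collapse = ", "))
  ffs <- unique(records$ffId)
  nd <- vapply(ffs, function(f) records$nd[match(f, records$ffId)], 0)
  aaM <- matrix(0, length(ffs), 20, dimnames = list(ffs, aminoAcids()))
  dpM <- matrix(0, length(ffs), 400,
                dimnames = list(ffs, .dipeptideUniverse()))
  for (i in seq_len(nrow(records))) {
    ct <- dipeptideCounts(records$residues[i])
    f <- records$ffId[i]
    aaM[f, ] <- aaM[f, ] + ct$aa
    dpM[f, ] <- dpM[f, ] + ct$dipep
  }
  fam <- data.frame(ffId = ffs, nd = nd,
                    aaCount = rowSums(aaM), dipepCount = rowSums(dpM),
                    stringsAsFactors = FALSE)
  aaF <- aaM / pmax(1, rowSums(aaM))
  dpF <- dpM / pmax(1, rowSums(dpM))
  rowOrd <- order(fam$nd)
  aaOrd <- order(colMeans(aaF), decreasing = TRUE)
  dpOrd <- order(colMeans(dpF), decreasing = TRUE)
  list(families = fam, aaFreq = aaF, dipepFreq = dpF,
       aaHeatmap = aaF[rowOrd, aaOrd, drop = FALSE],
       dipepHeatmap = dpF[rowOrd, dpOrd, drop = FALSE])
}

#' Select the ancient subset of a sequence set
#'
#' Ancient families are those predating the first anticodon-binding domain on
#' the nd timeline. The default follows the strict `nd < cutoff` convention;
#' `inclusive = TRUE` switches to `nd <= cutoff` (both conventions appear in
#' the literature and the choice only matters when families sit exactly at
#' the cutoff).
#'
#' @param records data.frame with an `nd` column.
#' @param cutoff age threshold (default 0.2).
#' @param inclusive use `<=` instead of `<` (default FALSE).
#' @return the ancient subset of `records`.
#' @export
ancientRecords <- function(records, cutoff = 0.2, inclusive = FALSE) {
  keep <- if (inclusive) records$nd <= cutoff else records$nd < cutoff
  records[keep, , drop = FALSE]
}

# upper-tail hypergeometric probability P(X >= k) by explicit summation of
# C(M,j) C(N-M, n-j) / C(N,n); log-scale for stability
.hypergeomTail <- function(k, M, N, n) {
  jmax <- min(M, n)
  if (k > jmax) return(0)
  j <- k:jmax
  lo <- lchoose(M, j) + lchoose(N - M, n - j) - lchoose(N, n)
  min(1, sum(exp(lo)))
}

#' Hypergeometric enrichment of residues or dipeptides in ancient families
#'
#' For every item (residue or ordered dipeptide) occurring in the ancient
#' set, let `k` and `n` be its occurrences and the total occurrences in the
#' ancient set, and `M` and `N` the same in the full set. Items whose
#' ancient proportion strictly exceeds the global proportion (`k/n > M/N`)
#' are tested with the upper tail of the hypergeometric distribution,
#' `p = sum_(j >= k) C(M,j) C(N-M, n-j) / C(N,n)` (the observed `k`
#' included), and flagged enriched at `p < alpha`. Items failing the strict
#' filter carry `p = NA` and are never flagged.
#'
#' @param ancient data.frame of ancient records (`residues` column); must be
#'   a subset of `all`.
#' @param all data.frame of all records.
#' @param alpha significance level (default 0.01).
#' @param item `"dipeptide"` (default) or `"aa"`.
#' @param adjust `"none"` (default, the fixed-alpha convention) or `"BH"`
#'   for Benjamini-Hochberg adjusted p-values.
#' @return data.frame with columns `item`, `M`, `k`, `N`, `n`, `p`,
#'   `enriched`, sorted by p.
#' @export
hypergeomEnrichment <- function(ancient, all, alpha = 0.01,
                                item = c("dipeptide", "aa"),
                                adjust = c("none", "BH")) {
  item <- match.arg(item)
  adjust <- match.arg(adjust)
  countsOf <- function(records) {
    tot <- NULL
    for (s in records$residues) {
      ct <- dipeptideCounts(s)
      v <- if (item == "dipeptide") ct$dipep else ct$aa
      tot <- if (is.null(tot)) v else tot + v
    }
    tot
  }
  kv <- countsOf(ancient)
  Mv <- countsOf(all)
  n <- sum(kv); N <- sum(Mv)
  if (any(kv > Mv) || n > N)
    stop("data-consistency error: ancient counts exceed totals; ",
         "is the ancient set a subset of the full set?")
  present <- kv > 0
  res <- data.frame(item = names(kv), M = as.numeric(Mv), k = as.numeric(kv),
                    N = N, n = n, p = NA_real_, enriched = FALSE,
                    stringsAsFactors = FALSE)
  testable <- present & (kv / n > Mv / N)
  res$p[testable] <- vapply(which(testable), function(i) {
    .hypergeomTail(kv[i], Mv[i], N, n)
  }, 0)
  pUse <- res$p
  if (adjust == "BH") pUse <- stats::p.adjust(res$p, method = "BH")
  res$enriched <- !is.na(pUse) & pUse < alpha
  res[order(res$p), ]
}

#' Chi-square contrast of dipeptide group sets against permutation expectation
#'
#' Maps every counted dipeptide to one of the 9 cells given by the age group
#' (1/2/3) of its first and second residue, and contrasts the observed cell
#' counts against the expectation under free permutation of the residue
#' order of the concatenated sequences (recounted per permutation and
#' averaged). Cells with zero expectation are dropped with a warning and the
#' degrees of freedom reduced accordingly.
#'
#' @param records data.frame with a `residues` column.
#' @param groups residue partition (default [ageGroups()]).
#' @param nPermutations number of free permutations (default 100).
#' @param seed integer seed.
#' @return list with `observed` and `expected` cell counts (named 9-vectors),
#'   `observedProp`, `expectedProp`, `chisq`, `df`, `p`.
#' @export
groupSetContrast <- function(records, groups = ageGroups(),
                             nPermutations = 100L, seed = 1L) {
  .checkPartition(groups, "group partition")
  gOf <- stats::setNames(rep(names(groups), lengths(groups)),
                         unlist(groups, use.names = FALSE))
  cellNames <- as.vector(t(outer(names(groups), names(groups),
                                 function(a, b) paste0(a, "-", b))))
  cellCounts <- function(ch) {
    L <- length(ch)
    first <- ch[-L]; second <- ch[-1L]
    ok <- first %in% names(gOf) & second %in% names(gOf)
    cells <- paste0(gOf[first[ok]], "-", gOf[second[ok]])
    table(factor(cells, levels = cellNames))
  }
  chAll <- unlist(strsplit(records$residues, ""), use.names = FALSE)
  obs <- cellCounts(chAll)
  exp0 <- withr::with_seed(seed, {
    acc <- 0
    for (b in seq_len(nPermutations))
      acc <- acc + cellCounts(sample(chAll))
    acc / nPermutations
  })
  keep <- exp0 > 0
  if (!all(keep))
    warning("cell(s) with zero expectation dropped: ",
            paste(cellNames[!keep], collapse = ", "))
  chisq <- sum((obs[keep] - exp0[keep])^2 / exp0[keep])
  df <- sum(keep) - 1L
  list(observed = c(unclass(obs)), expected = c(unclass(exp0)),
       observedProp = c(unclass(obs)) / sum(obs),
       expectedProp = c(unclass(exp0)) / sum(exp0),
       chisq = chisq, df = df,
       p = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Dipeptide makeup network
#'
#' Builds the undirected graph in which nodes are the residues participating
#' in the given dipeptides and each edge is weighted by the number of
#' dipeptide types joining the residue pair (so AL and LA together give the
#' A-L edge weight 2); self-pairs become self-loops. Node degree (counting
#' edge weights) is stored as the vertex attribute `size`.
#'
#' @param enriched nonempty character vector of 2-mers.
#' @return an `igraph` undirected weighted graph.
#' @export
dipeptideNetwork <- function(enriched) {
  if (!length(enriched)) stop("enriched dipeptide list must be nonempty")
  first <- substr(enriched, 1L, 1L)
  second <- substr(enriched, 2L, 2L)
  key <- ifelse(first <= second, paste0(first, second), paste0(second, first))
  w <- table(key)
  ends <- do.call(rbind, strsplit(names(w), ""))
  g <- igraph::graph_from_data_frame(
    data.frame(from = ends[, 1L], to = ends[, 2L],
               weight = as.numeric(w), stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = sort(unique(c(first, second))))
  igraph::V(g)$size <- igraph::strength(g, loops = TRUE)
  g
}
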