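# Secondary-structure parsing, region classification, region-bias tests for
# enriched dipeptides, T-loop boundary ratios and exchange-graph analyses.

.OMEGA <- "\u03a9"

#' Region classes of the DSSP alphabet
#'
#' Helical regions H pool the DSSP letters h/g/i (alpha, 3-10 and pi helix),
#' strand regions E pool e/b (beta strand and bridge), turn/bend regions T
#' pool t/s, and everything else (including blank coil) is the non-regular
#' loop class Omega.
#'
#' @return named character vector mapping DSSP letters (upper case, plus
#'   `" "`) to region classes.
#' @export
regionClasses <- function() {
  c(H = "H", G = "H", I = "H", E = "E", B = "E", T = "T", S = "T",
    " " = .OMEGA, "-" = .OMEGA, C = .OMEGA)
}

#' Classify a DSSP structure string into region classes
#'
#' Length-preserving, case-insensitive mapping of per-residue DSSP letters to
#' the four region classes H / E / T / Omega.
#'
#' @param structure DSSP-letter string (or character vector of them).
#' @return string(s) over `{H, E, T, Omega}` of the same length.
#' @examples
#' classifyRegions("HGIEBTS ")  # "HHHEETT" followed by the loop class Omega
#' @export
classifyRegions <- function(structure) {
  map <- regionClasses()
  out <- vapply(structure, function(s) {
    ch <- toupper(strsplit(s, "")[[1L]])
    cls <- map[ch]
    if (anyNA(cls)) {
      pos <- which(is.na(cls))[1L]
      stop("unknown DSSP letter '", ch[pos], "' at position ", pos)
    }
    paste(cls, collapse = "")
  }, "", USE.NAMES = FALSE)
  out
}

#' Parse secondary-structure assignments
#'
#' Reads either a classic DSSP output file (per-residue records following the
#' `#  RESIDUE` header; the summary letter is column 17, blanks preserved,
#' chain-break records skipped) or the simplified tab-separated annotation
#' written by [writeSequenceFasta()] (columns `id` and `structure`).
#'
#' @param path file path.
#' @return named character vector of per-chain (or per-record) DSSP-letter
#'   strings.
#' @export
parseDssp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (any(grepl("^\\s*#\\s+RESIDUE", lines))) {
    hdr <- grep("^\\s*#\\s+RESIDUE", lines)[1L]
    if (hdr == length(lines)) stop("malformed DSSP file: no residue records")
    body <- lines[(hdr + 1L):length(lines)]
    body <- body[nzchar(trimws(body))]
    aaCol <- substring(body, 14L, 14L)
    keep <- aaCol != "!"                       # chain breaks
    body <- body[keep]
    chain <- substring(body, 12L, 12L)
    ss <- substring(body, 17L, 17L)
    out <- vapply(split(ss, chain), paste, "", collapse = "")
    return(out)
  }
  first <- lines[nzchar(trimws(lines))][1L]
  if (is.null(first) || !grepl("\t", first))
    stop("malformed header: neither a DSSP file nor a tab-separated annotation")
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          colClasses = "character", check.names = FALSE,
                          strip.white = FALSE)
  if (!all(c("id", "structure") %in% names(df)))
    stop("malformed header: annotation needs 'id' and 'structure' columns")
  stats::setNames(df$structure, df$id)
}

# Mann-Whitney wrapper: exact for small untied samples, normal approximation
# with tie correction otherwise
.mannWhitney <- function(x, y, alternative = "two.sided") {
  if (length(x) < 1L || length(y) < 1L) return(NA_real_)
  hasTies <- anyDuplicated(c(x, y)) > 0L
  if (!hasTies && length(x) <= 8L && length(y) <= 8L) {
    stats::wilcox.test(x, y, alternative = alternative, exact = TRUE)$p.value
  } else {
    suppressWarnings(stats::wilcox.test(x, y, alternative = alternative,
                                        exact = FALSE, correct = TRUE)$p.value)
  }
}

# unordered region-class key of a dipeptide position: "H-H", "T-O", ...
.dipepClassKeys <- function() {
  cls <- c("H", "E", "T", .OMEGA)
  keys <- character(0)
  for (i in seq_along(cls))
    for (j in i:length(cls))
      keys <- c(keys, paste(cls[i], cls[j], sep = "-"))
  keys
}

.classOfPairs <- function(regionString) {
  ch <- strsplit(regionString, "")[[1L]]
  L <- length(ch)
  if (L < 2L) return(character(0))
  a <- ch[-L]; b <- ch[-1L]
  lo <- ifelse(a <= b, a, b)
  hi <- ifelse(a <= b, b, a)
  paste(lo, hi, sep = "-")
}

#' Region-bias test of enriched dipeptides
#'
#' For every sequence, compares the distribution of enriched-dipeptide
#' occurrences over dipeptide region classes with that of all dipeptides.
#' A dipeptide's class is the unordered pair of its residues' region classes
#' (so the turn/loop boundary T-Omega merges both orientations). Per class, a
#' two-sided Mann-Whitney test across sequences contrasts the per-sequence
#' frequency of enriched occurrences in the class against the per-sequence
#' frequency of all dipeptides in the class; the direction is `+` when the
#' enriched central tendency is higher and `-` when lower. Classes with no
#' occurrences anywhere are skipped with a note.
#'
#' @param enriched character vector of enriched 2-mers.
#' @param records data.frame with `residues` and `structure` columns.
#' @return data.frame with columns `class`, `p`, `direction`, `nEnriched`
#'   (sequences contributing enriched occurrences), `meanEnriched`,
#'   `meanAll`.
#' @export
regionBiasTest <- function(enriched, records) {
  if (!all(c("residues", "structure") %in% names(records)))
    stop("records must carry residues and structure columns")
  if (any(nchar(records$structure) != nchar(records$residues)))
    stop("structure strings must match sequence lengths")
  keys <- .dipepClassKeys()
  enrFreq <- matrix(NA_real_, nrow(records), length(keys),
                    dimnames = list(NULL, keys))
  allFreq <- matrix(NA_real_, nrow(records), length(keys),
                    dimnames = list(NULL, keys))
  enriched <- unique(enriched)
  for (i in seq_len(nrow(records))) {
    s <- records$residues[i]
    ch <- strsplit(s, "")[[1L]]
    L <- length(ch)
    if (L < 2L) next
    dip <- paste0(ch[-L], ch[-1L])
    cls <- .classOfPairs(classifyRegions(records$structure[i]))
    tabAll <- table(factor(cls, levels = keys))
    allFreq[i, ] <- tabAll / sum(tabAll)
    isEnr <- dip %in% enriched
    if (any(isEnr)) {
      tabEnr <- table(factor(cls[isEnr], levels = keys))
      enrFreq[i, ] <- tabEnr / sum(tabEnr)
    }
  }
  out <- data.frame(class = keys, p = NA_real_, direction = "",
                    nEnriched = 0L, meanEnriched = NA_real_,
                    meanAll = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_along(keys)) {
    x <- enrFreq[, j]; x <- x[!is.na(x)]
    y <- allFreq[, j]; y <- y[!is.na(y)]
    if (!length(x) || (all(x == 0) && all(y == 0))) {
      message("class ", keys[j], " has no occurrences; skipped")
      next
    }
    out$p[j] <- .mannWhitney(x, y)
    out$nEnriched[j] <- length(x)
    out$meanEnriched[j] <- mean(x)
    out$meanAll[j] <- mean(y)
    if (!is.na(out$p[j]) && mean(x) != mean(y))
      out$direction[j] <- if (mean(x) > mean(y)) "+" else "-"
  }
  out
}

#' Ratio of turn-boundary to other loop dipeptides
#'
#' Among the occurrences of enriched dipeptides in one record,
#' `r = (# spanning a T/Omega boundary) / (# involving an Omega residue but
#' not at a T boundary)`. Loops of rigid (ancient-like) proteins give large
#' r. When the denominator is zero the ratio is undefined and flagged.
#'
#' @param record one-row data.frame (or list) with `residues` and `structure`.
#' @param enriched character vector of enriched 2-mers.
#' @return list with `r` (possibly `Inf` or `NaN`), `nBoundary`, `nOtherLoop`
#'   and `defined` (FALSE when the denominator is zero).
#' @export
tOmegaRatio <- function(record, enriched) {
  if (is.null(record$structure) || is.na(record$structure[1L]))
    stop("record has no structure string")
  s <- record$residues[1L]
  ch <- strsplit(s, "")[[1L]]
  L <- length(ch)
  dip <- paste0(ch[-L], ch[-1L])
  reg <- strsplit(classifyRegions(record$structure[1L]), "")[[1L]]
  a <- reg[-L]; b <- reg[-1L]
  isEnr <- dip %in% enriched
  boundary <- isEnr & ((a == "T" & b == .OMEGA) | (a == .OMEGA & b == "T"))
  otherLoop <- isEnr & (a == .OMEGA | b == .OMEGA) & !boundary
  nB <- sum(boundary); nO <- sum(otherLoop)
  list(r = nB / nO, nBoundary = nB, nOtherLoop = nO, defined = nO > 0L)
}

# compact letter display from a pairwise "not significantly different"
# adjacency: maximal cliques share a letter
.compactLetters <- function(groupNames, notDiff) {
  g <- igraph::graph_from_adjacency_matrix(notDiff, mode = "undirected",
                                           diag = FALSE)
  cliques <- igraph::max_cliques(g)
  letters_ <- stats::setNames(rep("", length(groupNames)), groupNames)
  for (k in seq_along(cliques)) {
    members <- groupNames[as.integer(cliques[[k]])]
    for (m in members)
      letters_[m] <- paste0(letters_[m], letters[k])
  }
  # isolated vertices (different from everything) still need a letter
  lone <- names(letters_)[letters_ == ""]
  for (i in seq_along(lone))
    letters_[lone[i]] <- letters[length(cliques) + i]
  letters_
}

#' Exchange-group frequencies per secondary-structure class, with ANOVA
#'
#' For every DSSP letter class (alpha-helix H, 3-10 helix G, pi helix I,
#' strand E, bridge B, turn T, bend S) and every exchange group, computes the
#' per-sequence frequency of the group's residues among residues carrying
#' that letter, then tests group differences with a one-way ANOVA and a
#' Tukey HSD post hoc at alpha = 0.05 summarized as a compact letter display
#' (groups sharing a letter are not significantly different).
#'
#' @param records data.frame with `residues` and `structure` columns.
#' @param groups residue partition (default [exchangeGroups()]).
#' @param poolHelix pool G and I with H before computing frequencies
#'   (default FALSE).
#' @param restrict optional residue subset (e.g. one age group) to dissect
#'   the analysis; frequencies are then computed within that subset.
#' @return named list, one element per structure class present, each a list
#'   with `means` (named group means), `F`, `p`, `letters` and `n`
#'   (sequences contributing).
#' @export
exchangeGroupAnalysis <- function(records, groups = exchangeGroups(),
                                  poolHelix = FALSE, restrict = NULL) {
  .checkPartition(groups, "exchange groups")
  if (length(groups) < 2L) stop("degenerate input: need >= 2 groups")
  gOf <- stats::setNames(rep(names(groups), lengths(groups)),
                         unlist(groups, use.names = FALSE))
  ssLetters <- c("H", "G", "I", "E", "B", "T", "S")
  if (poolHelix) ssLetters <- c("H", "E", "B", "T", "S")
  freq <- list()
  for (i in seq_len(nrow(records))) {
    ch <- strsplit(records$residues[i], "")[[1L]]
    ss <- toupper(strsplit(records$structure[i], "")[[1L]])
    if (poolHelix) ss[ss %in% c("G", "I")] <- "H"
    if (!is.null(restrict)) {
      keep <- ch %in% restrict
      ch <- ch[keep]; ss <- ss[keep]
    }
    for (L in ssLetters) {
      at <- ss == L
      if (!any(at)) next
      gr <- gOf[ch[at]]
      tab <- table(factor(gr, levels = names(groups)))
      freq[[L]] <- rbind(freq[[L]], tab / sum(tab))
    }
  }
  present <- vapply(names(groups), function(g)
    any(unlist(strsplit(records$residues, "")) %in% groups[[g]]), TRUE)
  if (!all(present))
    stop("degenerate input: group(s) absent from data: ",
         paste(names(groups)[!present], collapse = ", "))
  out <- list()
  for (L in intersect(ssLetters, names(freq))) {
    m <- freq[[L]]
    if (nrow(m) < 2L) next
    df <- data.frame(freq = as.vector(m),
                     group = factor(rep(colnames(m), each = nrow(m)),
                                    levels = names(groups)))
    ssBetween <- sum(tapply(df$freq, df$group, function(v)
      length(v) * (mean(v) - mean(df$freq))^2))
    if (ssBetween == 0) {
      res <- list(means = colMeans(m), F = 0, p = 1,
                  letters = stats::setNames(rep("a", ncol(m)), colnames(m)),
                  n = nrow(m))
    } else {
      fit <- stats::aov(freq ~ group, data = df)
      an <- summary(fit)[[1L]]
      tk <- stats::TukeyHSD(fit, conf.level = 0.95)$group
      nd <- matrix(FALSE, ncol(m), ncol(m),
                   dimnames = list(colnames(m), colnames(m)))
      for (r in rownames(tk)) {
        pair <- strsplit(r, "-")[[1L]]
        nd[pair[1L], pair[2L]] <- nd[pair[2L], pair[1L]] <- tk[r, "p adj"] >= 0.05
      }
      res <- list(means = colMeans(m), F = an[["F value"]][1L],
                  p = an[["Pr(>F)"]][1L],
                  letters = .compactLetters(colnames(m), nd),
                  n = nrow(m))
    }
    out[[L]] <- res
  }
  out
}
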