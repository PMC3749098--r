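# Node-distance (nd) timelines, molecular-clock ages, age-group labels and
# aaRS-tRNA coevolution regressions.

#' Molecular clock specifications
#'
#' Linear clocks converting relative node distance to geological age:
#' fold level `t = -3.802 nd + 3.814` and fold-superfamily level
#' `t = -3.831 nd + 3.628`, in billions of years before present (Gy).
#'
#' @param level `"F"` (fold) or `"FSF"` (fold superfamily), or pass an
#'   explicit `slope`/`intercept` pair.
#' @param slope,intercept explicit clock coefficients (slope must be
#'   negative).
#' @return list with elements `slope`, `intercept`, `level`.
#' @export
clockSpec <- function(level = c("F", "FSF"), slope = NULL, intercept = NULL) {
  if (is.null(slope)) {
    level <- match.arg(level)
    if (level == "F") list(slope = -3.802, intercept = 3.814, level = "F")
    else list(slope = -3.831, intercept = 3.628, level = "FSF")
  } else {
    if (slope >= 0) stop("a molecular clock must have negative slope in nd")
    list(slope = slope, intercept = intercept, level = "custom")
  }
}

#' Relative node distance (nd) of every leaf
#'
#' For each leaf, counts the nodes on the path from the root to the leaf and
#' rescales the counts to `[0, 1]`: the earliest-diverging leaf (fewest nodes)
#' anchors at `nd = 0`, the deepest at `nd = 1`. Node distance is the relative
#' age of a domain, with time flowing from the origin (`nd = 0`) to the
#' present (`nd = 1`). When all leaves are equally deep (a perfectly balanced
#' tree) every nd is 0 and a warning is issued.
#'
#' @param tree a rooted `phylo`.
#' @return named numeric vector, leaf label -> nd.
#' @examples
#' tr <- ape::read.tree(text = "(((A,B),C),D);")
#' computeNd(tr)  # D = 0, C = 0.5, A = B = 1
#' @export
computeNd <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object")
  if (!ape::is.rooted(tree)) stop("computeNd requires a rooted tree")
  nTip <- length(tree$tip.label)
  edge <- tree$edge
  nNode <- max(edge)
  depth <- numeric(nNode)
  root <- setdiff(edge[, 1L], edge[, 2L])[1L]
  # preorder: parent depths known before children
  po <- rev(.postorderEdges(edge))
  for (r in po) depth[edge[r, 2L]] <- depth[edge[r, 1L]] + 1
  d <- depth[seq_len(nTip)]
  names(d) <- tree$tip.label
  rng <- max(d) - min(d)
  if (rng == 0) {
    warning("all leaves equally deep; every nd set to 0")
    return(d * 0)
  }
  (d - min(d)) / rng
}

#' Geological age from a molecular clock
#'
#' `age = slope * nd + intercept` (Gy before present). Ages that would fall
#' below zero are clamped to 0 with a warning, since negative geological ages
#' are meaningless.
#'
#' @param nd node distance(s) in `[0, 1]`.
#' @param clock a clock from [clockSpec()] (default the fold-level clock).
#' @return numeric vector of ages in Gy.
#' @examples
#' clockAge(0.020)  # ~3.7 Gy, the age of the first class II catalytic domain
#' clockAge(0.126)  # ~3.3 Gy, the first (CP1) editing domain
#' @export
clockAge <- function(nd, clock = clockSpec("F")) {
  if (any(is.na(nd)) || any(nd < 0) || any(nd > 1))
    stop("nd must lie in [0, 1]")
  age <- clock$slope * nd + clock$intercept
  if (any(age < 0)) {
    warning("age(s) beyond the clock intercept clamped to 0 Gy")
    age[age < 0] <- 0
  }
  age
}

#' Timeline of domains from a rooted tree
#'
#' Combines [computeNd()] and [clockAge()] into a timeline table and, when an
#' amino-acid mapping is supplied, attaches age-group labels via
#' [assignGroups()].
#'
#' @param tree rooted `phylo` of domains.
#' @param clock clock from [clockSpec()].
#' @param aa optional named character vector mapping domain ids to the amino
#'   acid they charge (for group labels).
#' @return data.frame with columns `domainId`, `nd`, `ageGy` and, when `aa`
#'   is given, `aa`, `group123`, `groupABC`.
#' @export
buildTimeline <- function(tree, clock = clockSpec("F"), aa = NULL) {
  nd <- computeNd(tree)
  out <- data.frame(domainId = names(nd), nd = unname(nd),
                    ageGy = unname(clockAge(nd, clock)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$nd), ]
  rownames(out) <- NULL
  if (!is.null(aa)) {
    out$aa <- unname(aa[out$domainId])
    out <- assignGroups(out)
  }
  out
}

#' Attach age-group and expansion-group labels
#'
#' Adds `group123` (ancient editing Groups 1/2 and anticodon-binding Group 3
#' amino-acid partition) and `groupABC` (code expansion stages A/B/C) columns
#' from the residue in column `aa`. Residue codes outside the 20-letter
#' alphabet are labelled `"unassigned"` without error. Both partition tables
#' are validated to cover the 20 amino acids exactly, with no residue in two
#' groups.
#'
#' @param entries data.frame with a character column `aa` of one-letter
#'   residue codes.
#' @param tables list with elements `group123` and `groupABC`, each a named
#'   list of residue vectors (defaults [ageGroups()] and [expansionGroups()]).
#' @return `entries` with `group123` and `groupABC` columns added.
#' @export
assignGroups <- function(entries,
                         tables = list(group123 = ageGroups(),
                                       groupABC = expansionGroups())) {
  if (!"aa" %in% names(entries)) stop("entries must carry an 'aa' column")
  .checkPartition(tables$group123, "group123 table")
  .checkPartition(tables$groupABC, "groupABC table")
  lookup <- function(groups, aa) {
    lab <- rep("unassigned", length(aa))
    for (g in names(groups)) lab[aa %in% groups[[g]]] <- g
    lab
  }
  entries$group123 <- lookup(tables$group123, entries$aa)
  entries$groupABC <- lookup(tables$groupABC, entries$aa)
  entries
}

#' Coevolution regression of tRNA age on domain age
#'
#' Least-squares fit of a constraint statistic `s` (e.g. S_aac or S_cod, the
#' age of tRNA isoacceptors or anticodon-specific tRNAs) on domain age `nd`.
#' In through-origin mode (the slope-only form `s = b nd`) the slope is
#' `sum(x y) / sum(x^2)`, the coefficient of determination is uncentered and
#' the F statistic has (1, n-1) degrees of freedom; with an intercept the
#' standard simple regression on (1, n-2) df is reported. Both modes are
#' available because published slope-only fits and ordinary fits differ in
#' their df conventions.
#'
#' @param points data.frame with numeric columns `nd` and `s` (>= 3 rows).
#' @param throughOrigin fit `s ~ nd + 0` (default) or `s ~ nd`.
#' @return list with `slope`, `slopeSe`, `intercept` (NA when through origin),
#'   `r2`, `f`, `p`, `df`, `n`.
#' @export
coevolutionRegression <- function(points, throughOrigin = TRUE) {
  stopifnot(all(c("nd", "s") %in% names(points)))
  x <- points$nd; y <- points$s
  n <- length(x)
  if (n < 3L) stop("at least 3 points are required")
  if (length(unique(x)) == 1L) stop("all nd values identical; no regression")
  fit <- if (throughOrigin) stats::lm(y ~ x + 0) else stats::lm(y ~ x)
  # summary.lm warns on exact fits ("essentially perfect fit"); harmless here
  sm <- suppressWarnings(summary(fit))
  co <- stats::coef(sm)
  slope <- co["x", "Estimate"]
  slopeSe <- co["x", "Std. Error"]
  fstat <- unname(sm$fstatistic)
  list(slope = unname(slope), slopeSe = unname(slopeSe),
       intercept = if (throughOrigin) NA_real_
                   else unname(co["(Intercept)", "Estimate"]),
       r2 = sm$r.squared,
       f = fstat[1L],
       p = stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE),
       df = c(fstat[2L], fstat[3L]), n = n)
}

#' Write a timeline table
#'
#' @param timeline data.frame from [buildTimeline()].
#' @param path file path for the tab-separated output.
#' @return invisibly, `path`.
#' @export
writeTimeline <- function(timeline, path) {
  utils::write.table(timeline, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
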