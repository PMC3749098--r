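# Encoding of abundance censuses as linearly ordered multistate characters,
# and tab-separated / NEXUS matrix IO.

.stateSymbols <- function(S) {
  if (S > 24L) stop("the 0-9A-N alphabet supports at most 24 states")
  c(as.character(0:9), LETTERS[1:14])[seq_len(S)]
}

#' Encode an abundance matrix as ordered multistate characters
#'
#' Each proteome column becomes one phylogenetic character. Abundances are
#' optionally log-transformed (`ln(g + 1)`), rescaled to `[0, 1]` by the
#' column maximum (or by the global maximum when `perColumn = FALSE`), and
#' discretized into `nStates` equal-width ordered bins with edges at `i/S`:
#' half-open low bins, closed top bin, so a rescaled value of 1 maps to state
#' `S - 1`. All-zero columns map to state 0 for every taxon. Character states
#' transform along linearly ordered, reversible pathways.
#'
#' @param m an [AbundanceMatrix-class].
#' @param nStates number of ordered states S (>= 2; default 24, the 0-9A-N
#'   alphabet).
#' @param transform `"log"` (default) or `"linear"`.
#' @param perColumn normalize each proteome column by its own maximum
#'   (default) rather than by the global maximum.
#' @param ancestor optional ancestor specification: `"max"` plants the
#'   hypothetical ancestor at the maximum state for every character (the
#'   polarization under which abundance grows with age), `"min"` at state 0,
#'   `NULL` for none, or an explicit integer vector.
#' @return a [CharacterMatrix-class] with taxa = domains.
#' @examples
#' g <- matrix(c(0, 5, 10), ncol = 1,
#'             dimnames = list(c("d1", "d2", "d3"), "p1"))
#' states(encodeCharacters(AbundanceMatrix(g), nStates = 2, transform = "linear"))
#' @export
encodeCharacters <- function(m, nStates = 24L, transform = c("log", "linear"),
                             perColumn = TRUE, ancestor = "max") {
  stopifnot(is(m, "AbundanceMatrix"))
  transform <- match.arg(transform)
  S <- as.integer(nStates)
  if (is.na(S) || S < 2L) stop("invalid parameter: nStates must be >= 2")
  g <- counts(m)
  if (!length(g)) stop("abundance matrix is empty")
  x <- if (transform == "log") log(g + 1) else g
  mx <- if (perColumn) apply(x, 2L, max) else rep(max(x), ncol(x))
  mx[mx == 0] <- 1  # all-zero columns stay 0 -> state 0
  v <- sweep(x, 2L, mx, "/")
  st <- pmin(floor(v * S), S - 1L)
  storage.mode(st) <- "integer"
  anc <- NULL
  if (is.character(ancestor)) {
    anc <- switch(match.arg(ancestor, c("max", "min")),
                  max = rep(S - 1L, ncol(st)),
                  min = rep(0L, ncol(st)))
  } else if (!is.null(ancestor)) {
    anc <- as.integer(ancestor)
  }
  CharacterMatrix(st, nStates = S, ancestor = anc)
}

#' Read and write character matrices (tab-separated and NEXUS)
#'
#' Both formats store states as single symbols from the `0-9A-N` alphabet
#' (state 0 -> `"0"`, ..., state 10 -> `"A"`, ..., state 23 -> `"N"`, so S up
#' to 24). A hypothetical-ancestor row, when present, is written as a row
#' labelled `ANCESTOR` and restored as the ancestor slot on reading; the
#' label is therefore reserved. Writing then reading reproduces taxa, states,
#' nStates and ancestor exactly.
#'
#' The tab-separated dialect is one comment line `# nStates=S` followed by
#' `taxon<TAB>symbols` rows. The NEXUS dialect is a standard `DATA` block
#' with a `SYMBOLS` list of the first S alphabet characters.
#'
#' @param x a [CharacterMatrix-class].
#' @param path file path.
#' @param format `"tsv"` or `"nexus"`.
#' @return `readCharacterMatrix` returns a [CharacterMatrix-class];
#'   `writeCharacterMatrix` invisibly returns `path`.
#' @export
writeCharacterMatrix <- function(x, path, format = c("tsv", "nexus")) {
  stopifnot(is(x, "CharacterMatrix"))
  format <- match.arg(format)
  S <- nStates(x)
  sym <- .stateSymbols(S)
  st <- states(x)
  if ("ANCESTOR" %in% rownames(st))
    stop("taxon label ANCESTOR is reserved for the ancestor row")
  rows <- apply(st, 1L, function(r) paste(sym[r + 1L], collapse = ""))
  if (!is.null(ancestor(x)))
    rows <- c(rows, ANCESTOR = paste(sym[ancestor(x) + 1L], collapse = ""))
  if (format == "tsv") {
    lines <- c(sprintf("# nStates=%d", S),
               sprintf("%s\t%s", names(rows), rows))
  } else {
    lines <- c("#NEXUS", "BEGIN DATA;",
               sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(rows), ncol(st)),
               sprintf("  FORMAT SYMBOLS=\"%s\";", paste(sym, collapse = "")),
               "  MATRIX",
               sprintf("    %s  %s", format(names(rows)), rows),
               "  ;", "END;")
  }
  writeLines(lines, path)
  invisible(path)
}

.decodeSymbolRows <- function(labels, rows, S, lineNo, nchar_expected = NULL) {
  sym <- .stateSymbols(S)
  nc <- nchar(rows)
  if (is.null(nchar_expected)) nchar_expected <- nc[1L]
  bad <- which(nc != nchar_expected)
  if (length(bad))
    stop(sprintf("malformed row %d (line %d): expected %d characters, found %d",
                 bad[1L], lineNo[bad[1L]], nchar_expected, nc[bad[1L]]))
  st <- matrix(0L, length(rows), nchar_expected,
               dimnames = list(labels, NULL))
  for (i in seq_along(rows)) {
    ch <- strsplit(rows[i], "")[[1L]]
    idx <- match(ch, sym)
    if (anyNA(idx)) {
      j <- which(is.na(idx))[1L]
      stop(sprintf("parse error at line %d: state symbol '%s' outside alphabet %s",
                   lineNo[i], ch[j], paste(sym, collapse = "")))
    }
    st[i, ] <- idx - 1L
  }
  anc <- NULL
  if ("ANCESTOR" %in% labels) {
    anc <- st["ANCESTOR", ]
    st <- st[setdiff(labels, "ANCESTOR"), , drop = FALSE]
  }
  CharacterMatrix(st, nStates = S, ancestor = anc)
}

#' @rdname writeCharacterMatrix
#' @export
readCharacterMatrix <- function(path, format = c("tsv", "nexus")) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "tsv") {
    hdr <- grep("^#\\s*nStates=", lines, value = TRUE)
    if (!length(hdr)) stop("parse error: missing '# nStates=' header")
    S <- as.integer(sub("^#\\s*nStates=", "", hdr[1L]))
    body <- grep("^#", lines, invert = TRUE)
    body <- body[nzchar(trimws(lines[body]))]
    parts <- strsplit(lines[body], "\t")
    if (any(lengths(parts) != 2L)) {
      i <- which(lengths(parts) != 2L)[1L]
      stop(sprintf("malformed row %d (line %d): expected taxon<TAB>states",
                   i, body[i]))
    }
    labels <- vapply(parts, `[[`, "", 1L)
    rows <- vapply(parts, `[[`, "", 2L)
    .decodeSymbolRows(labels, rows, S, body)
  } else {
    fmt <- grep("FORMAT\\s+SYMBOLS", lines, value = TRUE)
    if (!length(fmt)) stop("parse error: missing FORMAT SYMBOLS line")
    symstr <- sub(".*SYMBOLS=\"([^\"]+)\".*", "\\1", fmt[1L])
    S <- nchar(symstr)
    i0 <- grep("^\\s*MATRIX\\s*$", lines)
    i1 <- grep("^\\s*;\\s*$", lines)
    i1 <- i1[i1 > i0][1L]
    if (!length(i0) || is.na(i1)) stop("parse error: missing MATRIX block")
    body <- (i0 + 1L):(i1 - 1L)
    body <- body[nzchar(trimws(lines[body]))]
    parts <- strsplit(trimws(lines[body]), "\\s+")
    if (any(lengths(parts) != 2L)) {
      i <- which(lengths(parts) != 2L)[1L]
      stop(sprintf("malformed row %d (line %d) in MATRIX block", i, body[i]))
    }
    labels <- vapply(parts, `[[`, "", 1L)
    rows <- vapply(parts, `[[`, "", 2L)
    .decodeSymbolRows(labels, rows, S, body)
  }
}

#' Read and write abundance matrices as tab-separated tables
#'
#' Plain rectangular table: first column `domain`, remaining columns one per
#' proteome, integer abundances.
#'
#' @param m an [AbundanceMatrix-class].
#' @param path file path.
#' @return `readAbundanceMatrix` returns an [AbundanceMatrix-class];
#'   `writeAbundanceMatrix` invisibly returns `path`.
#' @export
writeAbundanceMatrix <- function(m, path) {
  stopifnot(is(m, "AbundanceMatrix"))
  df <- data.frame(domain = domainIds(m), counts(m), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeAbundanceMatrix
#' @export
readAbundanceMatrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  g <- as.matrix(df[, -1L, drop = FALSE])
  rownames(g) <- df[[1L]]
  AbundanceMatrix(g)
}
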