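# The vis-a-vis complementary-codon representation of the genetic code,
# groove-mode and expansion-stage annotation, and acceptor-stem composition
# summaries.

.RNA_BASES <- c("A", "C", "G", "U")

#' Reverse complement of an RNA codon
#'
#' The vis-a-vis representation places each codon head-to-head with its
#' reverse complement, so codon position 1 pairs with position 3. The pairing
#' is involutive and fixed-point free: no RNA triplet can equal its own
#' reverse complement (its middle base would have to pair with itself), so
#' the 64 codons fall into exactly 32 unordered pairs.
#'
#' @param codon RNA triplet(s) over A/C/G/U.
#' @return the reverse-complement codon(s).
#' @examples
#' complementCodon("GCA")  # "UGC"
#' @export
complementCodon <- function(codon) {
  codon <- toupper(codon)
  if (any(nchar(codon) != 3L) ||
      any(!strsplit(paste(codon, collapse = ""), "")[[1L]] %in% .RNA_BASES))
    stop("invalid base: codons must be RNA triplets over A/C/G/U")
  comp <- chartr("ACGU", "UGCA", codon)
  vapply(strsplit(comp, ""), function(x) paste(rev(x), collapse = ""), "")
}

#' The standard genetic code as an RNA codon table
#'
#' @return named character vector, RNA codon -> amino-acid one-letter code
#'   (`"*"` for stops).
#' @export
standardCode <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(unname(gc), chartr("T", "U", names(gc)))
}

#' Default groove-mode assignment by aaRS class
#'
#' Class II synthetases approach tRNA from the major groove, class I from the
#' minor groove. The default maps each amino acid to the groove of the class
#' of its synthetase (class II: G, A, P, S, T, H, D, N, K, F); known
#' behavioural exceptions (TyrRS, PheRS) are annotations on top of this
#' table, not pairing rules, and callers may override any entry.
#'
#' @return named character vector, amino acid -> `"major"` or `"minor"`.
#' @export
defaultGrooveModes <- function() {
  classII <- c("G", "A", "P", "S", "T", "H", "D", "N", "K", "F")
  aa <- aminoAcids()
  stats::setNames(ifelse(aa %in% classII, "major", "minor"), aa)
}

#' Default code-expansion stage by amino acid
#'
#' The operational code starts with TyrRS-homologous charging
#' (`operational-1`, Tyr) and splits into the Leu and Ser lineages
#' (`operational-2`); the remaining amino acids carry their standard-code
#' expansion stage A, B or C.
#'
#' @return named character vector, amino acid -> stage label.
#' @export
defaultStages <- function() {
  aa <- aminoAcids()
  stage <- rep("unassigned", length(aa))
  names(stage) <- aa
  for (g in names(expansionGroups())) stage[expansionGroups()[[g]]] <- g
  stage["Y"] <- "operational-1"
  stage[c("L", "S")] <- "operational-2"
  stage
}

#' Build the vis-a-vis complementary-codon table
#'
#' One row per codon with its amino acid, reverse-complement codon (and that
#' codon's amino acid), groove mode of tRNA recognition and expansion-stage
#' label. Codons whose amino acid lacks a stage entry are labelled
#' `unassigned` with a warning (stop codons are always unassigned).
#'
#' @param code codon table (default [standardCode()]).
#' @param grooves amino acid -> groove assignment (default
#'   [defaultGrooveModes()]).
#' @param stages amino acid -> stage assignment (default [defaultStages()]).
#' @return data.frame with columns `codon`, `aa`, `complementCodon`,
#'   `complementAa`, `groove`, `complementGroove`, `stage`; 64 rows.
#' @export
buildVisAVis <- function(code = standardCode(), grooves = defaultGrooveModes(),
                         stages = defaultStages()) {
  codons <- names(code)
  comp <- complementCodon(codons)
  aa <- unname(code)
  compAa <- unname(code[comp])
  grooveOf <- function(a) ifelse(a %in% names(grooves),
                                 unname(grooves[a]), NA_character_)
  stageOf <- function(a) ifelse(a %in% names(stages),
                                unname(stages[a]), "unassigned")
  stage <- stageOf(aa)
  stage[aa == "*"] <- "unassigned"
  missingStage <- aa != "*" & stage == "unassigned"
  if (any(missingStage))
    warning("codon(s) without stage assignment left unassigned: ",
            paste(codons[missingStage], collapse = ", "))
  out <- data.frame(codon = codons, aa = aa, complementCodon = comp,
                    complementAa = compAa,
                    groove = grooveOf(aa), complementGroove = grooveOf(compAa),
                    stage = stage, stringsAsFactors = FALSE)
  stopifnot(all(out$complementCodon %in% out$codon))
  out
}

#' Acceptor-stem N2/N73 composition and complementarity tally
#'
#' Summarizes base composition at the discriminator (N73) and at the first
#' base of the 2:71 acceptor-stem pair (N2) per group, and, when records
#' carry codons, tallies the coordinated complementarity of C2-G72 / G2-C72
#' base pairs across complementary codon pairs: a pair of codon sides is
#' coordinated when one side's consensus N2 is C and the other's is G.
#'
#' @param records data.frame with columns `id`, `aa`, `n73`, `bp2` (the 2:71
#'   pair written `"N2:N71"`) and optionally `codon`.
#' @param by grouping column for the composition summaries (default `"aa"`).
#' @return list with `n2Composition` and `n73Composition` (group x base count
#'   matrices), and, when codons are present, `pairs` (data.frame of
#'   complementary codon pairs with consensus N2 of each side and a
#'   `coordinated` flag) and `exceptions` (count of non-coordinated pairs).
#' @export
n2Composition <- function(records, by = "aa") {
  if (!nrow(records)) stop("records must be nonempty")
  okBp <- grepl("^[ACGU]:[ACGU]$", records$bp2)
  if (any(!okBp)) {
    warning(sum(!okBp), " record(s) with malformed base pair skipped")
    records <- records[okBp, , drop = FALSE]
  }
  n2 <- substr(records$bp2, 1L, 1L)
  grp <- records[[by]]
  comp <- function(x) {
    t(vapply(split(factor(x, levels = .RNA_BASES), grp),
             function(v) table(v), stats::setNames(integer(4), .RNA_BASES)))
  }
  out <- list(n2Composition = comp(n2), n73Composition = comp(records$n73))
  if ("codon" %in% names(records)) {
    codons <- unique(records$codon)
    compCodon <- complementCodon(codons)
    key <- ifelse(codons < compCodon, paste(codons, compCodon),
                  paste(compCodon, codons))
    pairs <- unique(key)
    consensusN2 <- function(codon) {
      v <- n2[records$codon == codon]
      if (!length(v)) return(NA_character_)
      names(sort(table(v), decreasing = TRUE))[1L]
    }
    tab <- do.call(rbind, lapply(strsplit(pairs, " "), function(p) {
      a <- consensusN2(p[1L]); b <- consensusN2(p[2L])
      data.frame(codonA = p[1L], codonB = p[2L], n2A = a, n2B = b,
                 coordinated = !is.na(a) && !is.na(b) &&
                   setequal(c(a, b), c("C", "G")),
                 stringsAsFactors = FALSE)
    }))
    withData <- !is.na(tab$n2A) & !is.na(tab$n2B)
    out$pairs <- tab
    out$exceptions <- sum(withData & !tab$coordinated)
  }
  out
}
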