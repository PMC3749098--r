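# Residue alphabets, hydropathy scale and the amino-acid partitions used
# throughout the timeline, dipeptide and structure analyses.

#' The 20 standard amino acids
#'
#' @return character vector of the 20 one-letter codes.
#' @export
aminoAcids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Kyte-Doolittle hydropathy scale
#'
#' Positive values are hydrophobic. The mean over the 20 residues is -0.49.
#'
#' @return named numeric vector, residue -> hydropathy index.
#' @export
kyteDoolittle <- function() {
  c(I = 4.5, V = 4.2, L = 3.8, F = 2.8, C = 2.5, M = 1.9, A = 1.8,
    G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6,
    H = -3.2, E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9, R = -4.5)
}

#' Age-group partition of the amino acids (aaRS domain groups 1/2/3)
#'
#' Group 1 holds the amino acids charged by the most ancient editing-capable
#' catalytic domains (TyrRS, SerRS, LeuRS), Group 2 those of intermediate-age
#' type I tRNA interactions, and Group 3 those tied to recent
#' anticodon-binding domains. The three sets partition the 20 residues
#' (3 + 8 + 9).
#'
#' @return named list of character vectors with elements `"1"`, `"2"`, `"3"`.
#' @export
ageGroups <- function() {
  list(`1` = c("Y", "S", "L"),
       `2` = c("K", "F", "P", "T", "A", "M", "I", "V"),
       `3` = c("E", "Q", "R", "C", "G", "W", "N", "D", "H"))
}

#' Anticodon-binding expansion groups A/B/C of the standard code
#'
#' Three stages of genetic-code expansion, from the founding Pro-Ala stage (A)
#' through intermediate (B) to late recruitments (C). The sets partition the
#' 20 residues (5 + 7 + 8).
#'
#' @return named list of character vectors with elements `"A"`, `"B"`, `"C"`.
#' @export
expansionGroups <- function() {
  list(A = c("P", "A", "T", "G", "H"),
       B = c("V", "M", "I", "C", "Q", "R", "L"),
       C = c("D", "N", "K", "S", "E", "Y", "F", "W"))
}

#' Sense-antisense codon exchange-graph groups H/T/E
#'
#' Partition of the 20 amino acids by the secondary-structure class their
#' exchange graph preserves: helix (H), turn (T) and strand (E)
#' (5 + 8 + 7 residues).
#'
#' @return named list of character vectors with elements `"H"`, `"T"`, `"E"`.
#' @export
exchangeGroups <- function() {
  list(H = c("L", "K", "F", "E", "Q"),
       T = c("S", "P", "T", "A", "R", "C", "G", "W"),
       E = c("Y", "M", "I", "V", "N", "D", "H"))
}

.checkPartition <- function(groups, what = "partition") {
  all20 <- sort(unlist(groups, use.names = FALSE))
  if (anyDuplicated(all20))
    stop(what, ": residue assigned to more than one group: ",
         paste(unique(all20[duplicated(all20)]), collapse = ", "))
  if (!identical(all20, aminoAcids()))
    stop(what, " must cover the 20 standard amino acids exactly")
  invisible(TRUE)
}

#' Mean Kyte-Doolittle hydropathy of residues or dipeptides
#'
#' For a set of residues the unweighted mean index is returned. For
#' dipeptides (2-mers) the mean is taken over all residue slots, so each
#' occurrence of a residue in the multiset contributes once
#' (occurrence-weighted).
#'
#' @param items character vector of residue one-letter codes, or of 2-mers.
#' @param scale named hydropathy vector (default [kyteDoolittle()]).
#' @return single numeric mean.
#' @examples
#' kdMean(aminoAcids())                        # -0.49
#' kdMean(c("S","L","P","K","M","I","V","A","T","F"))  # 1.2
#' @export
kdMean <- function(items, scale = kyteDoolittle()) {
  if (!length(items)) stop("items must be nonempty")
  nch <- unique(nchar(items))
  if (length(nch) != 1L || !nch %in% c(1L, 2L))
    stop("items must be all residues or all dipeptides")
  res <- unlist(strsplit(items, ""), use.names = FALSE)
  unknown <- setdiff(res, names(scale))
  if (length(unknown))
    stop("unknown residue code(s): ", paste(unknown, collapse = ", "))
  mean(scale[res])
}
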