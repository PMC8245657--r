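#' Mutant protein for a non-synonymous SNV
#'
#' Applies an nsSNV to its transcript's protein: the returned protein
#' equals the wildtype translation except at the substituted position.
#' Only nsSNVs are accepted (synonymous, nonsense, splicing and INDEL
#' variants do not define a single-substitution mutant protein).
#'
#' @param model a [TranscriptModel-class] object.
#' @param variant a classified one-row data.frame (or list) with
#'   `mutation_class`, `cds_position`, `ref`, `alt`.
#' @return list with `protein` (mutant protein string), `position`
#'   (1-based substituted residue), `refAA`, `altAA`.
#' @export
mutantProtein <- function(model, variant) {
  if (!identical(as.character(variant$mutation_class), "nsSNV"))
    stop("mutantProtein is defined for nsSNV variants only", call. = FALSE)
  wt <- as.character(proteinSequence(model))
  cds <- as.character(cdsSequence(model))
  pos <- as.integer(variant$cds_position)
  if (pos < 1L || pos > nchar(cds))
    stop("cds_position outside CDS", call. = FALSE)
  if (substring(cds, pos, pos) != variant$ref)
    stop("ref base mismatch with transcript model", call. = FALSE)
  ci <- (pos - 1L) %/% 3L
  off <- (pos - 1L) %% 3L
  start <- ci * 3L + 1L
  codon <- substring(cds, start, start + 2L)
  altCodon <- paste0(substring(codon, 1L, off), variant$alt,
                     substring(codon, off + 2L, 3L))
  refAA <- unname(Biostrings::GENETIC_CODE[codon])
  altAA <- unname(Biostrings::GENETIC_CODE[altCodon])
  if (is.na(altAA) || altAA == "*" || refAA == altAA)
    stop("variant does not encode a simple amino-acid substitution",
         call. = FALSE)
  mut <- wt
  substr(mut, ci + 1L, ci + 1L) <- altAA
  list(protein = mut, position = ci + 1L, refAA = refAA, altAA = altAA)
}

#' Enumerate all mutant peptide windows containing a substituted residue
#'
#' Emits, for each requested length `L`, every window of length `L` lying
#' fully inside the protein and containing the substituted position —
#' exactly once, ordered by length then start. Windows are never padded
#' past the protein termini; only real substrings are returned. The
#' wildtype counterpart is the same window with the substituted residue
#' reverted (requires `wildtypeAA`).
#'
#' @param protein mutant protein string.
#' @param position 1-based substituted residue position.
#' @param lengths integer vector of peptide lengths (default 8:11).
#' @param wildtypeAA the wildtype residue at `position` (optional; if
#'   missing, `wildtype_sequence` is `NA`).
#' @return data.frame with `length`, `start`, `sequence`,
#'   `mutated_offset` (0-based index of the substituted residue within the
#'   peptide) and `wildtype_sequence`.
#' @examples
#' p <- paste(rep("A", 100), collapse = "")
#' substr(p, 50, 50) <- "W"
#' nrow(enumerateMutantPeptides(p, 50))  # 8 + 9 + 10 + 11 = 38
#' @export
enumerateMutantPeptides <- function(protein, position, lengths = 8:11,
                                    wildtypeAA = NULL) {
  n <- nchar(protein)
  if (length(position) != 1L || position < 1L || position > n)
    stop("position outside the protein", call. = FALSE)
  pieces <- lapply(sort(unique(as.integer(lengths))), function(L) {
    lo <- max(1L, position - L + 1L)
    hi <- min(position, n - L + 1L)
    if (hi < lo) return(NULL)
    start <- lo:hi
    data.frame(length = L, start = start,
               sequence = substring(protein, start, start + L - 1L),
               mutated_offset = as.integer(position - start))
  })
  out <- do.call(rbind, pieces)
  if (is.null(out))
    out <- data.frame(length = integer(0), start = integer(0),
                      sequence = character(0), mutated_offset = integer(0))
  out$wildtype_sequence <- if (is.null(wildtypeAA)) {
    rep(NA_character_, nrow(out))
  } else {
    wt <- out$sequence
    substr(wt, out$mutated_offset + 1L, out$mutated_offset + 1L) <- wildtypeAA
    wt
  }
  rownames(out) <- NULL
  out
}
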