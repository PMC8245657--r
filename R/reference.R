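#' Generate a synthetic reference transcript panel
#'
#' Builds `nGenes` random coding sequences usable as a stand-in for a
#' transcript annotation: each CDS starts with ATG, is padded to a multiple
#' of 3 within the requested length range, carries no internal stop codon,
#' ends with a random stop codon, and receives a handful of exon junction
#' offsets (roughly one per 150 nt) at random interior positions. Output is
#' fully determined by `seed`.
#'
#' @param nGenes number of transcripts (>= 1).
#' @param cdsLengthRange integer pair, min/max CDS length in nt (>= 27).
#' @param seed integer seed.
#' @return a named list of [TranscriptModel-class] objects (names are gene
#'   symbols `G0001`, ...).
#' @examples
#' panel <- generateReference(3, c(90, 300), seed = 1)
#' panel[[1]]
#' @export
generateReference <- function(nGenes, cdsLengthRange = c(300L, 900L),
                              seed = 1L) {
  if (length(nGenes) != 1L || is.na(nGenes) || nGenes < 1)
    stop("nGenes must be a single integer >= 1", call. = FALSE)
  if (length(cdsLengthRange) != 2L || any(is.na(cdsLengthRange)) ||
      cdsLengthRange[1] > cdsLengthRange[2] || cdsLengthRange[1] < 27)
    stop("cdsLengthRange must be an increasing pair of lengths >= 27",
         call. = FALSE)
  set.seed(as.integer(seed))
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  stops <- names(gc)[gc == "*"]
  models <- vector("list", nGenes)
  for (i in seq_len(nGenes)) {
    len <- sample(seq(cdsLengthRange[1], cdsLengthRange[2]), 1L)
    len <- max(27L, (len %/% 3L) * 3L)
    nCodons <- len %/% 3L
    body <- sample(sense, nCodons - 2L, replace = TRUE)
    cds <- paste(c("ATG", body, sample(stops, 1L)), collapse = "")
    nJunctions <- max(1L, round(len / 150))
    bounds <- sort(sample(seq(4L, len - 4L), min(nJunctions, len - 7L)))
    bounds <- bounds[!duplicated(bounds)]
    models[[i]] <- TranscriptModel(
      geneSymbol = sprintf("G%04d", i), cds = cds,
      exonBoundaries = as.integer(bounds),
      strand = sample(c("+", "-"), 1L))
  }
  names(models) <- vapply(models, geneSymbol, "")
  models
}

#' Write / read a reference panel (FASTA + annotation TSV)
#'
#' The CDS sequences go to a FASTA file (via [Biostrings::writeXStringSet])
#' and the annotation (gene symbol, comma-separated exon boundary offsets,
#' strand) to a tab-separated file.
#'
#' @param reference a list of [TranscriptModel-class] objects.
#' @param fastaPath,annotationPath output/input file paths.
#' @return `writeReferencePanel` returns the paths invisibly;
#'   `readReferencePanel` returns the named list of models.
#' @export
writeReferencePanel <- function(reference, fastaPath, annotationPath) {
  seqs <- Biostrings::DNAStringSet(
    vapply(reference, function(m) as.character(cdsSequence(m)), ""))
  names(seqs) <- vapply(reference, geneSymbol, "")
  Biostrings::writeXStringSet(seqs, fastaPath)
  ann <- data.frame(
    gene_symbol = names(seqs),
    exon_boundaries = vapply(reference, function(m)
      paste(exonBoundaries(m), collapse = ","), ""),
    strand = vapply(reference, cdsStrand, ""))
  .writeTsv(ann, annotationPath)
  invisible(c(fastaPath, annotationPath))
}

#' @rdname writeReferencePanel
#' @export
readReferencePanel <- function(fastaPath, annotationPath) {
  seqs <- Biostrings::readDNAStringSet(fastaPath)
  ann <- read.delim(annotationPath, colClasses = "character")
  .assertCols(ann, c("gene_symbol", "exon_boundaries", "strand"),
              "reference annotation")
  if (!setequal(names(seqs), ann$gene_symbol))
    stop("FASTA and annotation name different transcripts", call. = FALSE)
  models <- lapply(seq_len(nrow(ann)), function(i) {
    b <- ann$exon_boundaries[i]
    bounds <- if (nzchar(b)) as.integer(strsplit(b, ",")[[1]]) else integer(0)
    TranscriptModel(ann$gene_symbol[i],
                    as.character(seqs[[ann$gene_symbol[i]]]),
                    bounds, ann$strand[i])
  })
  names(models) <- ann$gene_symbol
  models
}
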