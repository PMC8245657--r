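#' RNA read count at a mutated position
#'
#' Looks up the tabulated RNA-seq read count for each variant. Mode
#' `"covering"` (default) counts all reads covering the mutated position —
#' the conservative reading of expression support; `"mutant_supporting"`
#' counts only reads carrying the mutant allele. Variants absent from the
#' table count 0.
#'
#' @param counts data.frame with `variant_id`, `covering`, `mutant`.
#' @param variantIds character vector of variant ids (or a data.frame with
#'   a `variant_id` column).
#' @param mode `"covering"` or `"mutant_supporting"`.
#' @return non-negative integer vector, one per requested variant.
#' @export
mutationReadCount <- function(counts, variantIds,
                              mode = c("covering", "mutant_supporting")) {
  mode <- match.arg(mode)
  if (is.data.frame(variantIds)) variantIds <- variantIds$variant_id
  .assertCols(counts, c("variant_id", "covering", "mutant"),
              "RNA read-count table")
  if (nrow(counts) && any(counts$covering < 0 | counts$mutant < 0))
    stop("RNA read counts must be non-negative", call. = FALSE)
  col <- if (mode == "covering") counts$covering else counts$mutant
  hit <- match(variantIds, counts$variant_id)
  out <- ifelse(is.na(hit), 0L, col[hit])
  as.integer(out)
}

#' Per-patient neoantigen load
#'
#' The full per-patient neoantigen computation: take the classified
#' variants' nsSNVs, build each mutant protein, enumerate all 8-11mer
#' windows containing the substituted residue, predict binding to the
#' patient's (deduplicated) HLA class I alleles, keep predictions with
#' IC50 strictly below the threshold, and keep variants whose RNA read
#' count meets `minRnaReadCount`. The neoantigen load is the count of what
#' remains under the configured unit — distinct mutant peptide sequences
#' by default.
#'
#' @param variants classified variant data.frame (see [classifyVariants]).
#' @param reference named list of [TranscriptModel-class] objects.
#' @param hla character vector of the patient's HLA class I alleles.
#' @param rnaCounts RNA read-count table (`variant_id`, `covering`,
#'   `mutant`).
#' @param params a [NeoantigenParams-class] object.
#' @param predictor predictor function (default [toyPredictor]).
#' @param readCountMode passed to [mutationReadCount].
#' @return list with `load` (integer), `records` (data.frame of
#'   peptide-allele rows passing both criteria: `variant_id`,
#'   `gene_symbol`, `sequence`, `wildtype_sequence`, `length`, `start`,
#'   `mutated_offset`, `hla_allele`, `ic50_nm`, `read_count`), `binders`
#'   (rows passing the IC50 criterion alone), `nPredictedBinders`
#'   (IC50-only count under the same unit) and `nNsSnv`.
#' @export
neoantigenLoad <- function(variants, reference, hla, rnaCounts,
                           params = NeoantigenParams(),
                           predictor = toyPredictor(),
                           readCountMode = "covering") {
  .assertCols(variants, c("variant_id", "mutation_class"), "variant table")
  ns <- variants[variants$mutation_class == "nsSNV", , drop = FALSE]
  empty <- data.frame(variant_id = character(0), gene_symbol = character(0),
                      sequence = character(0),
                      wildtype_sequence = character(0), length = integer(0),
                      start = integer(0), mutated_offset = integer(0),
                      hla_allele = character(0), ic50_nm = numeric(0),
                      read_count = integer(0))
  countUnit <- function(df) switch(params@loadCountingUnit,
    distinct_peptides = length(unique(df$sequence)),
    peptide_allele_pairs = nrow(df),
    variants = length(unique(df$variant_id)))
  if (nrow(ns) == 0L)
    return(list(load = 0L, records = empty, binders = empty,
                nPredictedBinders = 0L, nNsSnv = 0L))
  .assertCols(ns, c("transcript_id", "gene_symbol", "ref_aa", "alt_aa",
                    "protein_position"), "classified nsSNV table")
  readCount <- mutationReadCount(rnaCounts, ns$variant_id,
                                 mode = readCountMode)
  # vectorised across variants: mutant proteins by single-residue
  # replacement, then all windows containing the substituted position
  wtByTid <- vapply(reference, function(m)
    as.character(proteinSequence(m)), "")
  mutProt <- wtByTid[ns$transcript_id]
  pos <- ns$protein_position
  substr(mutProt, pos, pos) <- ns$alt_aa
  protLen <- nchar(mutProt)
  pepList <- lapply(sort(unique(params@peptideLengths)), function(L) {
    lo <- pmax(1L, pos - L + 1L)
    hi <- pmin(pos, protLen - L + 1L)
    cnt <- pmax(0L, hi - lo + 1L)
    if (sum(cnt) == 0L) return(NULL)
    idx <- rep(seq_along(cnt), cnt)
    start <- sequence(cnt) - 1L + lo[idx]
    data.frame(length = L, start = start,
               sequence = substring(mutProt[idx], start, start + L - 1L),
               mutated_offset = as.integer(pos[idx] - start),
               variant_id = ns$variant_id[idx],
               gene_symbol = ns$gene_symbol[idx],
               read_count = readCount[idx])
  })
  peps <- do.call(rbind, pepList)
  if (!is.null(peps)) {
    wt <- peps$sequence
    substr(wt, peps$mutated_offset + 1L, peps$mutated_offset + 1L) <-
      ns$ref_aa[match(peps$variant_id, ns$variant_id)]
    peps$wildtype_sequence <- wt
  }
  if (is.null(peps) || nrow(peps) == 0L)
    return(list(load = 0L, records = empty, binders = empty,
                nPredictedBinders = 0L, nNsSnv = nrow(ns)))
  preds <- predictBinding(peps, hla, predictor = predictor)
  binders <- filterBinders(preds, params)
  binders <- binders[, names(empty)]
  records <- binders[binders$read_count >= params@minRnaReadCount, ,
                     drop = FALSE]
  rownames(binders) <- NULL
  rownames(records) <- NULL
  list(load = as.integer(countUnit(records)), records = records,
       binders = binders, nPredictedBinders = as.integer(countUnit(binders)),
       nNsSnv = nrow(ns))
}

#' Rank vaccine candidate peptides for one HLA allele
#'
#' Restricts neoantigen records to a single HLA allele and a (stricter)
#' RNA read-count threshold — the rule used to pick peptides for synthesis
#' — and ranks them by ascending IC50, breaking ties by peptide
#' lexicographic order. A peptide appearing via several variants is kept
#' once at its best IC50. Wildtype counterparts stay attached.
#'
#' @param records neoantigen record data.frame (see [neoantigenLoad]).
#' @param allele HLA allele to restrict to.
#' @param minReadCount minimum RNA read count (default 2).
#' @param topK maximum number of candidates returned (default 10).
#' @param patientAlleles optional patient genotype; if given, `allele`
#'   must be among them.
#' @return ranked data.frame of at most `topK` candidates with a `rank`
#'   column.
#' @export
selectVaccineCandidates <- function(records, allele, minReadCount = 2,
                                    topK = 10, patientAlleles = NULL) {
  .assertCols(records, c("sequence", "wildtype_sequence", "hla_allele",
                         "ic50_nm", "read_count"), "record table")
  known <- patientAlleles %||% unique(records$hla_allele)
  if (length(known) && !allele %in% known)
    stop("allele ", allele, " is not among the patient's alleles",
         call. = FALSE)
  sel <- records[records$hla_allele == allele &
                 records$read_count >= minReadCount, , drop = FALSE]
  if (nrow(sel) == 0L) {
    sel$rank <- integer(0)
    return(sel)
  }
  sel <- sel[order(sel$ic50_nm, sel$sequence), , drop = FALSE]
  sel <- sel[!duplicated(sel$sequence), , drop = FALSE]
  sel <- head(sel, topK)
  sel$rank <- seq_len(nrow(sel))
  rownames(sel) <- NULL
  sel
}
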