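#' Predict HLA binding for mutant peptides
#'
#' Produces one prediction per (peptide, allele) pair. Alleles are
#' deduplicated first: a homozygous allele listed twice contributes one
#' set of predictions (identical predictions add no information). With a
#' table-backed predictor, pairs absent from the table are returned with
#' `ic50_nm = NA` and listed in the `missing` attribute — reported, never
#' silently dropped; in strict mode they raise a coverage error.
#'
#' @param peptides data.frame from [enumerateMutantPeptides] (needs a
#'   `sequence` column; extra columns are carried through) or a character
#'   vector of peptide sequences.
#' @param alleles character vector of HLA allele names.
#' @param predictor a predictor function from [toyPredictor] or
#'   [tablePredictor] (default: the built-in deterministic matrix model).
#' @param strict error when a pair cannot be resolved (default FALSE).
#' @return data.frame with the peptide columns plus `hla_allele`,
#'   `ic50_nm`, `predictor_id`; unresolved pairs carried as `NA` and
#'   summarised in `attr(, "missing")`.
#' @export
predictBinding <- function(peptides, alleles, predictor = toyPredictor(),
                           strict = FALSE) {
  if (is.character(peptides)) peptides <- data.frame(sequence = peptides)
  .assertCols(peptides, "sequence", "peptide table")
  alleles <- unique(alleles)
  if (length(alleles) == 0L) stop("no HLA alleles supplied", call. = FALSE)
  id <- attr(predictor, "predictor_id") %||% "custom"
  perAllele <- lapply(alleles, function(al) {
    out <- peptides
    out$hla_allele <- al
    out$ic50_nm <- predictor(peptides$sequence, al)
    out
  })
  out <- do.call(rbind, perAllele)
  out$predictor_id <- id
  rownames(out) <- NULL
  missing <- out[is.na(out$ic50_nm), c("sequence", "hla_allele")]
  if (nrow(missing)) {
    if (strict)
      stop("affinity source does not cover ", nrow(missing),
           " (peptide, allele) pair(s)", call. = FALSE)
    .logMsg("warn", nrow(missing), " (peptide, allele) pair(s) unresolved ",
            "by the affinity source")
  }
  attr(out, "missing") <- missing
  out
}

#' Keep predictions below the IC50 binder threshold
#'
#' Strict inequality: a prediction passes iff `ic50_nm < ic50ThresholdNm`
#' (500 nM by default); a pair at exactly the threshold is dropped, as are
#' unresolved (`NA`) pairs.
#'
#' @param predictions data.frame from [predictBinding].
#' @param params a [NeoantigenParams-class] object.
#' @return the passing subset of `predictions`.
#' @export
filterBinders <- function(predictions, params = NeoantigenParams()) {
  .assertCols(predictions, "ic50_nm", "prediction table")
  keep <- !is.na(predictions$ic50_nm) &
    predictions$ic50_nm < params@ic50ThresholdNm
  out <- predictions[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
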