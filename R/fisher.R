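#' Two-sided Fisher's exact test p-value for tumor/normal allele counts
#'
#' Computes, for each site, the exact two-sided p-value of the 2x2 table
#' `[[tumor_ref, tumor_alt], [normal_ref, normal_alt]]`: the sum over all
#' tables with the same margins of the hypergeometric probabilities that do
#' not exceed the observed table's probability (the usual two-sided
#' convention, identical to [stats::fisher.test]). Small-sided evidence of
#' tumor-specific alternate alleles drives the p-value down; the statistic
#' is symmetric, so swapping rows with columns leaves it unchanged.
#'
#' @param tumorRef,tumorAlt,normalRef,normalAlt non-negative read counts
#'   (vectors are recycled to a common length).
#' @return numeric vector of p-values in (0, 1].
#' @examples
#' fisherSomaticP(90, 10, 100, 0)   # tumor-specific 10% VAF at 100x
#' fisherSomaticP(0, 2, 2, 0)       # 1/3
#' @export
fisherSomaticP <- function(tumorRef, tumorAlt, normalRef, normalAlt) {
  n <- max(length(tumorRef), length(tumorAlt),
           length(normalRef), length(normalAlt))
  tr <- rep_len(as.numeric(tumorRef), n)
  ta <- rep_len(as.numeric(tumorAlt), n)
  nr <- rep_len(as.numeric(normalRef), n)
  na_ <- rep_len(as.numeric(normalAlt), n)
  if (any(c(tr, ta, nr, na_) < 0, na.rm = TRUE))
    stop("allele counts must be non-negative", call. = FALSE)
  if (any(tr + ta + nr + na_ == 0))
    stop("undefined evidence: tumor and normal depth both zero",
         call. = FALSE)
  vapply(seq_len(n), function(i) {
    row1 <- tr[i] + ta[i]
    col1 <- tr[i] + nr[i]
    col2 <- ta[i] + na_[i]
    k <- max(0, row1 - col2):min(row1, col1)
    d <- dhyper(k, col1, col2, row1)
    dObs <- dhyper(tr[i], col1, col2, row1)
    min(1, sum(d[d <= dObs * (1 + 1e-7)]))
  }, numeric(1))
}
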