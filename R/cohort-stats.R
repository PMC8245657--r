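#' Fragments per kilobase of transcript per million mapped reads
#'
#' `FPKM = reads * 1e9 / (totalMappedReads * geneLengthBp)`; zero reads
#' give 0. Pure function of its arguments.
#'
#' @param geneReads read (fragment) count for the gene.
#' @param geneLengthBp transcript length in bp (>= 1).
#' @param totalMappedReads library size (>= 1).
#' @return FPKM value(s).
#' @examples
#' fpkm(10, 1000, 1e6)  # 10
#' @export
fpkm <- function(geneReads, geneLengthBp, totalMappedReads) {
  if (any(geneLengthBp < 1) || any(totalMappedReads < 1))
    stop("gene length and total mapped reads must be >= 1", call. = FALSE)
  if (any(geneReads < 0)) stop("read counts must be >= 0", call. = FALSE)
  geneReads * 1e9 / (totalMappedReads * geneLengthBp)
}

#' Pearson correlation with a two-sided p-value
#'
#' Thin wrapper around [stats::cor.test] (Pearson; two-sided p from the t
#' transform of r with n - 2 degrees of freedom), rejecting degenerate
#' input explicitly.
#'
#' @param x,y numeric vectors of equal length >= 3 with non-zero variance.
#' @return list with `r`, `p`, `n`.
#' @export
pearsonCor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need equal-length vectors with n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Two-group comparison by Student's t-test with medians and ranges
#'
#' Reports the equal-variance two-sample Student's t statistic and
#' two-sided p-value (or the paired test when `paired = TRUE` and lengths
#' match), together with each group's median and range in the
#' `median = m, range: lo-hi` style used for subtype comparisons. When
#' both groups are constant the comparison is degenerate: flagged, with
#' t = 0 / p = 1 if the constants agree.
#'
#' @param a,b numeric vectors (each n >= 2).
#' @param paired paired test (lengths must match; default FALSE).
#' @return list with `t`, `p`, `degenerate`, `paired`, and per-group
#'   `median` / `range`.
#' @export
groupCompare <- function(a, b, paired = FALSE) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs n >= 2", call. = FALSE)
  if (paired && length(a) != length(b))
    stop("paired comparison needs equal-length groups", call. = FALSE)
  degenerate <- FALSE
  if (paired) {
    d <- a - b
    if (stats::sd(d) == 0) {
      degenerate <- TRUE
      tt <- list(statistic = c(t = if (all(d == 0)) 0 else Inf),
                 p.value = if (all(d == 0)) 1 else 0)
    } else tt <- t.test(a, b, paired = TRUE)
  } else if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    degenerate <- TRUE
    same <- a[1] == b[1]
    tt <- list(statistic = c(t = if (same) 0 else Inf),
               p.value = if (same) 1 else 0)
  } else {
    tt <- t.test(a, b, var.equal = TRUE)
  }
  list(t = unname(tt$statistic), p = tt$p.value, degenerate = degenerate,
       paired = paired,
       medianA = median(a), rangeA = range(a),
       medianB = median(b), rangeB = range(b))
}

#' ELISpot response positivity
#'
#' A sample is positive when its spot count is strictly more than
#' `1 + margin` times the control (default margin 0.5: "> 50% higher");
#' a sample at exactly +50% is not positive. With zero control spots any
#' response is positive and the fold increase is unbounded.
#'
#' @param sampleSpots,controlSpots non-negative spot counts.
#' @param margin required excess over control (default 0.5).
#' @return list with `fold`, `positive`, `unboundedFold`.
#' @export
elispotResponse <- function(sampleSpots, controlSpots, margin = 0.5) {
  if (sampleSpots < 0 || controlSpots < 0)
    stop("spot counts must be non-negative", call. = FALSE)
  if (controlSpots == 0) {
    pos <- sampleSpots > 0
    return(list(fold = if (pos) Inf else NA_real_, positive = pos,
                unboundedFold = pos))
  }
  list(fold = sampleSpots / controlSpots,
       positive = sampleSpots > controlSpots * (1 + margin),
       unboundedFold = FALSE)
}

#' Calcein-release cytotoxicity percentage
#'
#' `(control - sample) / control * 100`. A sample brighter than the
#' control yields a negative percentage, reported unclipped (the formula
#' has no floor).
#'
#' @param controlFluorescence control reading (> 0).
#' @param sampleFluorescence sample reading (>= 0).
#' @return cytotoxicity percentage.
#' @examples
#' cytotoxicityPercent(200, 50)  # 75
#' @export
cytotoxicityPercent <- function(controlFluorescence, sampleFluorescence) {
  if (any(controlFluorescence <= 0))
    stop("control fluorescence must be > 0", call. = FALSE)
  (controlFluorescence - sampleFluorescence) / controlFluorescence * 100
}

DEFAULT_IMMUNE_GENES <- c("CD8A", "CD4", "TCRB", "GZMA", "GZMB", "PRF1")

#' Cohort-level statistics report
#'
#' Computes the cohort correlations (total exonic vs nsSNV count, nsSNV
#' count vs predicted binders, nsSNV count vs neoantigen load, and
#' neoantigen load vs each immune gene's FPKM) and the TNBC vs non-TNBC
#' load comparison, as one flat results table. The subtype comparison uses
#' the unpaired equal-variance t-test: the groups differ in size, so a
#' paired test is not defined for them (a note is logged).
#'
#' @param profiles data.frame with one row per patient: `patient_id`,
#'   `tnbc_flag` (logical), `n_exonic`, `n_nssnv`, `n_predicted_binders`,
#'   `neoantigen_load`.
#' @param immuneFpkm optional data.frame of per-patient FPKM values, one
#'   column per immune gene (rows aligned with `profiles`).
#' @param immuneGenes genes to correlate with load (default the six
#'   T-cell/cytolytic markers CD8A, CD4, TCRB, GZMA, GZMB, PRF1).
#' @return data.frame with columns `comparison`, `type`, `estimate`, `p`,
#'   `n`, plus `median_tnbc`/`median_non_tnbc` attributes on the subtype
#'   row via the `groups` attribute.
#' @export
cohortReport <- function(profiles, immuneFpkm = NULL,
                         immuneGenes = DEFAULT_IMMUNE_GENES) {
  .assertCols(profiles, c("patient_id", "tnbc_flag", "n_exonic", "n_nssnv",
                          "n_predicted_binders", "neoantigen_load"),
              "cohort profile table")
  if (nrow(profiles) < 3L)
    stop("need at least 3 patient profiles", call. = FALSE)
  rows <- list()
  addCor <- function(label, x, y) {
    # degenerate (zero-variance) pairs are reported as NA, not fatal
    pc <- tryCatch(pearsonCor(x, y), error = function(e)
      list(r = NA_real_, p = NA_real_, n = length(x)))
    rows[[length(rows) + 1L]] <<- data.frame(
      comparison = label, type = "pearson", estimate = pc$r, p = pc$p,
      n = pc$n)
  }
  addCor("n_exonic~n_nssnv", profiles$n_exonic, profiles$n_nssnv)
  addCor("n_nssnv~n_predicted_binders", profiles$n_nssnv,
         profiles$n_predicted_binders)
  addCor("n_nssnv~neoantigen_load", profiles$n_nssnv,
         profiles$neoantigen_load)
  if (!is.null(immuneFpkm)) {
    for (g in intersect(immuneGenes, names(immuneFpkm)))
      addCor(paste0("neoantigen_load~", g), profiles$neoantigen_load,
             immuneFpkm[[g]])
  }
  .logMsg("info", "subtype comparison uses the unpaired equal-variance ",
          "t-test (groups differ in size; a paired test is not defined)")
  a <- profiles$neoantigen_load[profiles$tnbc_flag]
  b <- profiles$neoantigen_load[!profiles$tnbc_flag]
  gc_ <- if (length(a) >= 2L && length(b) >= 2L) groupCompare(a, b) else
    list(t = NA_real_, p = NA_real_)  # a subtype group too small to test
  rows[[length(rows) + 1L]] <- data.frame(
    comparison = "load:TNBC~non-TNBC", type = "t_test", estimate = gc_$t,
    p = gc_$p, n = nrow(profiles))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "groups") <- gc_
  out
}

#' Scatter plot for one cohort correlation
#'
#' Convenience ggplot2 scatter of two profile columns with the Pearson r
#' annotated. Requires ggplot2 (Suggests).
#'
#' @param profiles cohort profile data.frame.
#' @param xCol,yCol column names to plot.
#' @return a ggplot object.
#' @export
plotCorrelation <- function(profiles, xCol = "n_nssnv",
                            yCol = "neoantigen_load") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  pc <- pearsonCor(profiles[[xCol]], profiles[[yCol]])
  df <- data.frame(x = profiles[[xCol]], y = profiles[[yCol]])
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = xCol, y = yCol,
                  subtitle = sprintf("r = %.3f (n = %d)", pc$r, pc$n))
}

utils::globalVariables(c("x", "y"))
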