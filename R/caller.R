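#' Call somatic variants from tumor/normal allele counts
#'
#' Applies the six-filter Fisher's-exact-test caller to a table of
#' per-site allele counts. A site is emitted iff all of the following hold
#' (boundary semantics follow the printed inequalities literally):
#' tumor depth and normal depth both `>= minDepth`; tumor alt reads
#' `>= minVariantDepth`; tumor VAF `>= minTumorVaf` (inclusive); normal VAF
#' `< maxNormalVaf` (exclusive); Fisher p `< maxFisherP` (exclusive).
#' Output rows keep the input order. Counts are assumed already filtered
#' for base quality (>= 15) and mapping artefacts upstream.
#'
#' @param sites data.frame with columns `transcript_id`, `cds_position`,
#'   `ref`, `alt`, `tumor_ref`, `tumor_alt`, `normal_ref`, `normal_alt`
#'   (extra columns are passed through).
#' @param params a [CallerParams-class] object.
#' @return data.frame of called sites with added columns `fisher_p`,
#'   `tumor_vaf`, `normal_vaf`, `variant_id`.
#' @examples
#' sites <- data.frame(transcript_id = "G1", cds_position = 10,
#'                     ref = "A", alt = "T", tumor_ref = 90, tumor_alt = 10,
#'                     normal_ref = 100, normal_alt = 0)
#' callSomaticVariants(sites, CallerParams())
#' @export
callSomaticVariants <- function(sites, params = CallerParams()) {
  cols <- c("transcript_id", "cds_position", "ref", "alt", "tumor_ref",
            "tumor_alt", "normal_ref", "normal_alt")
  .assertCols(sites, cols, "allele-count table")
  if (nrow(sites) == 0L) {
    out <- sites
    out$fisher_p <- numeric(0); out$tumor_vaf <- numeric(0)
    out$normal_vaf <- numeric(0); out$variant_id <- character(0)
    return(out)
  }
  td <- sites$tumor_ref + sites$tumor_alt
  nd <- sites$normal_ref + sites$normal_alt
  tvaf <- ifelse(td > 0, sites$tumor_alt / td, NA_real_)
  nvaf <- ifelse(nd > 0, sites$normal_alt / nd, NA_real_)
  keep <- td >= params@minDepth & nd >= params@minDepth &
    sites$tumor_alt >= params@minVariantDepth &
    !is.na(tvaf) & tvaf >= params@minTumorVaf &
    !is.na(nvaf) & nvaf < params@maxNormalVaf
  keep[is.na(keep)] <- FALSE
  p <- rep(NA_real_, nrow(sites))
  if (any(keep))  # Fisher test only where the cheap filters already pass
    p[keep] <- fisherSomaticP(sites$tumor_ref[keep], sites$tumor_alt[keep],
                              sites$normal_ref[keep], sites$normal_alt[keep])
  keep <- keep & !is.na(p) & p < params@maxFisherP
  out <- sites[keep, , drop = FALSE]
  out$fisher_p <- p[keep]
  out$tumor_vaf <- tvaf[keep]
  out$normal_vaf <- nvaf[keep]
  out$variant_id <- variantId(out$transcript_id, out$cds_position,
                              out$ref, out$alt)
  rownames(out) <- NULL
  out
}

# per-CDS-position logical mask of the splice-site window: the 2 exonic
# bases on each side of every exon junction (proxy for the canonical
# donor/acceptor dinucleotides in this intron-less coordinate system)
.spliceMask <- function(model) {
  n <- length(cdsSequence(model))
  mask <- logical(n)
  for (b in exonBoundaries(model)) {
    lo <- max(1L, b - 1L)
    hi <- min(n, b + 2L)
    mask[lo:hi] <- TRUE
  }
  mask
}

#' Classify somatic variants into the six mutation classes
#'
#' Assigns each variant exactly one of `nsSNV`, `sSNV`, `stopgain`,
#' `stoploss`, `splicing`, `INDEL`. Insertion/deletion alt tokens (`INS`,
#' `DEL`) are INDELs; SNVs falling in the splice-site window around an
#' exon junction are `splicing`; all other SNVs are classified by
#' translating the mutated codon (new stop: `stopgain`; lost terminal
#' stop: `stoploss`; same residue: `sSNV`; otherwise `nsSNV`). For coding
#' SNVs `ref_aa`, `alt_aa` and `protein_position` are populated.
#'
#' @param variants data.frame with `transcript_id`, `cds_position`, `ref`,
#'   `alt` (typically the output of [callSomaticVariants]).
#' @param reference named list of [TranscriptModel-class] objects.
#' @return the input with added columns `mutation_class`, `gene_symbol`,
#'   `ref_aa`, `alt_aa`, `protein_position`, `variant_id`.
#' @export
classifyVariants <- function(variants, reference) {
  .assertCols(variants, c("transcript_id", "cds_position", "ref", "alt"),
              "variant table")
  n <- nrow(variants)
  cls <- rep(NA_character_, n)
  gene <- rep(NA_character_, n)
  refAA <- rep(NA_character_, n)
  altAA <- rep(NA_character_, n)
  protPos <- rep(NA_integer_, n)
  unknown <- setdiff(unique(variants$transcript_id), names(reference))
  if (length(unknown))
    stop("unknown transcript(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  gcode <- Biostrings::GENETIC_CODE
  for (tid in unique(variants$transcript_id)) {
    idx <- which(variants$transcript_id == tid)
    model <- reference[[tid]]
    cds <- as.character(cdsSequence(model))
    len <- nchar(cds)
    pos <- variants$cds_position[idx]
    if (any(pos < 1L | pos > len))
      stop("cds_position outside CDS for transcript ", tid, call. = FALSE)
    gene[idx] <- geneSymbol(model)
    alt <- variants$alt[idx]
    isIndel <- alt %in% INDEL_TOKENS
    cls[idx[isIndel]] <- "INDEL"
    snv <- idx[!isIndel]
    if (length(snv)) {
      spos <- variants$cds_position[snv]
      salt <- variants$alt[snv]
      refObs <- variants$ref[snv]
      refModel <- substring(cds, spos, spos)
      bad <- refObs != refModel
      if (any(bad))
        stop("ref base mismatch with transcript ", tid, " at CDS position ",
             paste(spos[bad], collapse = ", "), call. = FALSE)
      mask <- .spliceMask(model)
      isSplice <- mask[spos]
      cls[snv[isSplice]] <- "splicing"
      cod <- snv[!isSplice]
      if (length(cod)) {
        cpos <- variants$cds_position[cod]
        calt <- variants$alt[cod]
        ci <- (cpos - 1L) %/% 3L
        off <- (cpos - 1L) %% 3L
        start <- ci * 3L + 1L
        refCodon <- substring(cds, start, start + 2L)
        altCodon <- paste0(substring(refCodon, 1L, off),
                           calt,
                           substring(refCodon, off + 2L, 3L))
        ra <- unname(gcode[refCodon])
        aa <- unname(gcode[altCodon])
        if (anyNA(aa))
          stop("alt base must be one of A/C/G/T (or INS/DEL)", call. = FALSE)
        k <- ifelse(ra == "*" & aa != "*", "stoploss",
             ifelse(aa == "*" & ra != "*", "stopgain",
             ifelse(ra == aa, "sSNV", "nsSNV")))
        cls[cod] <- k
        refAA[cod] <- ra
        altAA[cod] <- aa
        protPos[cod] <- ci + 1L
      }
    }
  }
  out <- variants
  out$mutation_class <- cls
  out$gene_symbol <- gene
  out$ref_aa <- refAA
  out$alt_aa <- altAA
  out$protein_position <- protPos
  out$variant_id <- variantId(out$transcript_id, out$cds_position,
                              out$ref, out$alt)
  out
}

#' Per-class mutation counts and nsSNV fraction
#'
#' @param variants data.frame of classified variants (`mutation_class`
#'   populated for every row).
#' @return list with `counts` (named integer over the six classes),
#'   `total`, and `nssnvFraction` (`NA` when there are no variants).
#' @export
summarizeMutations <- function(variants) {
  if (nrow(variants) == 0L) {
    counts <- setNames(integer(length(MUTATION_CLASSES)), MUTATION_CLASSES)
    return(list(counts = counts, total = 0L, nssnvFraction = NA_real_))
  }
  .assertCols(variants, "mutation_class", "variant table")
  if (anyNA(variants$mutation_class) ||
      !all(variants$mutation_class %in% MUTATION_CLASSES))
    stop("all variants must carry one of the six mutation classes",
         call. = FALSE)
  counts <- vapply(MUTATION_CLASSES,
                   function(k) sum(variants$mutation_class == k), 0L)
  list(counts = counts, total = nrow(variants),
       nssnvFraction = unname(counts["nsSNV"]) / nrow(variants))
}
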