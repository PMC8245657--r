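# Exhaustive catalog of single-base substitutions in a reference panel,
# each classified with the same classifier the pipeline uses, so simulated
# ground-truth classes and called classes can never disagree by
# construction. Cached per panel (the expensive part of simulation).
.substitutionCatalog <- function(reference) {
  key <- paste(names(reference),
               vapply(reference, function(m) length(cdsSequence(m)), 0L),
               vapply(reference, function(m)
                 as.character(Biostrings::subseq(cdsSequence(m), 1, 12)), ""),
               collapse = "|")
  hit <- .pkgCache$catalogKey
  if (!is.null(hit) && identical(hit, key)) return(.pkgCache$catalog)
  bases <- c("A", "C", "G", "T")
  pieces <- lapply(reference, function(m) {
    cds <- as.character(cdsSequence(m))
    n <- nchar(cds)
    ref <- strsplit(cds, "")[[1]]
    df <- data.frame(
      transcript_id = geneSymbol(m),
      cds_position = rep(seq_len(n), each = 3L),
      ref = rep(ref, each = 3L))
    df$alt <- unlist(lapply(ref, function(b) bases[bases != b]),
                     use.names = FALSE)
    df
  })
  cat <- do.call(rbind, pieces)
  rownames(cat) <- NULL
  cat <- classifyVariants(cat, reference)
  .pkgCache$catalogKey <- key
  .pkgCache$catalog <- cat
  cat
}

.truncBetaVaf <- function(n, shape1, shape2, vafMin) {
  lo <- pbeta(vafMin, shape1, shape2)
  qbeta(runif(n, lo, 1), shape1, shape2)
}

#' Simulate a tumor/normal cohort with known ground truth
#'
#' Draws, for each patient, an exonic mutation burden (Poisson with a TNBC
#' multiplier), a six-class mutation mix dominated by nsSNVs, concrete
#' substitutions sampled from an exhaustive classified catalog of the
#' reference panel (so ground-truth classes match the classifier by
#' construction), tumor/normal allele counts (tumor alt reads binomial at
#' the drawn VAF; normal alt reads only through sequencing error), decoy
#' sites (germline heterozygous at VAF ~ 0.5 in both samples, and pure
#' noise) for specificity testing, zero-inflated RNA read counts at each
#' mutated position, and an HLA class I genotype (two draws per locus,
#' homozygosity possible). The seed in `params` fully determines the
#' cohort.
#'
#' @param reference non-empty named list of [TranscriptModel-class]
#'   objects.
#' @param params a [SimulationParams-class] object.
#' @return list of [SyntheticPatient-class] objects.
#' @examples
#' ref <- generateReference(3, c(150, 300), seed = 1)
#' cohort <- simulateCohort(ref, SimulationParams(nPatients = 2L,
#'                                                meanBurden = 5, seed = 9L))
#' cohort[[1]]
#' @export
simulateCohort <- function(reference, params = SimulationParams()) {
  if (length(reference) == 0L)
    stop("reference panel must be non-empty", call. = FALSE)
  validObject(params)
  catalog <- .substitutionCatalog(reference)
  set.seed(params@seed)
  snvPool <- split(seq_len(nrow(catalog)), catalog$mutation_class)
  posKey <- paste(catalog$transcript_id, catalog$cds_position)
  classes <- MUTATION_CLASSES
  nTnbc <- round(params@nPatients * params@tnbcFraction)
  subtypes <- sample(c(rep("TNBC", nTnbc),
                       rep("non-TNBC", params@nPatients - nTnbc)))
  locus <- sub("^(HLA-[A-Z]+)\\*.*$", "\\1", params@hlaPool)
  poolByLocus <- split(params@hlaPool, locus)
  err <- params@sequencingErrorRate  # per-base error read probability
  patients <- vector("list", params@nPatients)
  for (i in seq_len(params@nPatients)) {
    mult <- if (subtypes[i] == "TNBC") params@tnbcBurdenMultiplier else 1
    burden <- rpois(1L, params@meanBurden * mult)
    demand <- if (burden > 0)
      drop(rmultinom(1L, burden, params@classMix[classes])) else
      setNames(integer(length(classes)), classes)
    rows <- integer(0)
    for (k in setdiff(classes, "INDEL")) {
      pool <- snvPool[[k]]
      d <- min(demand[[k]], length(pool))
      if (d > 0) rows <- c(rows, pool[sample.int(length(pool), d)])
    }
    tv <- catalog[rows, , drop = FALSE]
    if (demand[["INDEL"]] > 0) {
      pool <- snvPool[["nsSNV"]]  # reuse positions; alt becomes a token
      d <- min(demand[["INDEL"]], length(pool))
      idf <- catalog[pool[sample.int(length(pool), d)], , drop = FALSE]
      idf$alt <- sample(INDEL_TOKENS, d, replace = TRUE)
      idf$mutation_class <- "INDEL"
      idf$ref_aa <- NA_character_; idf$alt_aa <- NA_character_
      idf$protein_position <- NA_integer_
      tv <- rbind(tv, idf)
    }
    tv <- tv[!duplicated(paste(tv$transcript_id, tv$cds_position)), ,
             drop = FALSE]
    nV <- nrow(tv)
    tv$variant_id <- variantId(tv$transcript_id, tv$cds_position, tv$ref,
                               tv$alt)
    tv$vaf <- .truncBetaVaf(nV, params@vafShape1, params@vafShape2,
                            params@vafMin)
    td <- pmax(1L, rpois(nV, params@tumorDepth))
    nd <- pmax(1L, rpois(nV, params@normalDepth))
    ta <- rbinom(nV, td, tv$vaf)
    na_ <- rbinom(nV, nd, err)
    somatic <- data.frame(
      transcript_id = tv$transcript_id, cds_position = tv$cds_position,
      ref = tv$ref, alt = tv$alt,
      tumor_ref = td - ta, tumor_alt = ta,
      normal_ref = nd - na_, normal_alt = na_,
      site_type = rep("somatic", nV))
    usedPos <- paste(tv$transcript_id, tv$cds_position)
    decoy <- function(nSites, type, pTumor, pNormal) {
      if (nSites == 0L) return(NULL)
      free <- which(!(posKey %in% usedPos))
      nSites <- min(nSites, length(free))
      dd <- catalog[free[sample.int(length(free), nSites)], , drop = FALSE]
      dd <- dd[!duplicated(paste(dd$transcript_id, dd$cds_position)), ,
               drop = FALSE]
      m <- nrow(dd)
      if (m == 0L) return(NULL)
      dtd <- pmax(1L, rpois(m, params@tumorDepth))
      dnd <- pmax(1L, rpois(m, params@normalDepth))
      dta <- rbinom(m, dtd, pTumor)
      dna <- rbinom(m, dnd, pNormal)
      data.frame(transcript_id = dd$transcript_id,
                 cds_position = dd$cds_position, ref = dd$ref, alt = dd$alt,
                 tumor_ref = dtd - dta, tumor_alt = dta,
                 normal_ref = dnd - dna, normal_alt = dna,
                 site_type = rep(type, m))
    }
    germ <- decoy(rpois(1L, burden * params@germlineDecoyRate),
                  "germline_het", 0.5, 0.5)
    noise <- decoy(rpois(1L, burden * params@noiseDecoyRate),
                   "noise", err, err)
    ac <- rbind(somatic, germ, noise)
    ac <- ac[sample.int(nrow(ac)), , drop = FALSE]
    rownames(ac) <- NULL
    covering <- ifelse(runif(nV) < params@rnaZeroProb, 0L,
                       rnbinom(nV, size = params@rnaSize, mu = params@rnaMu))
    rna <- data.frame(variant_id = tv$variant_id,
                      covering = as.integer(covering),
                      mutant = rbinom(nV, covering, tv$vaf))
    hla <- unlist(lapply(poolByLocus, function(p)
      sample(p, 2L, replace = TRUE)), use.names = FALSE)
    tvOut <- tv[, c("variant_id", "transcript_id", "cds_position", "ref",
                    "alt", "mutation_class", "gene_symbol", "vaf")]
    rownames(tvOut) <- NULL
    patients[[i]] <- new("SyntheticPatient",
      patientId = sprintf("P%02d", i), subtype = subtypes[i],
      trueVariants = tvOut, alleleCounts = ac, rnaReadCounts = rna,
      hlaAlleles = hla)
  }
  patients
}
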