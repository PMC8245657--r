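#' @import methods
#' @importClassesFrom Biostrings DNAString AAString
#' @importFrom stats dhyper qbeta pbeta runif rpois rbinom rnbinom rmultinom
#'   cor.test t.test median setNames
#' @importFrom utils read.delim write.table packageVersion head
NULL

MUTATION_CLASSES <- c("nsSNV", "sSNV", "stopgain", "stoploss", "splicing",
                      "INDEL")
INDEL_TOKENS <- c("INS", "DEL")
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y")

#' TranscriptModel: a CDS-only transcript with exon junction annotation
#'
#' Holds one coding sequence (CDS) used as the coordinate system for
#' variant simulation, classification and peptide enumeration. The CDS
#' starts at ATG, ends in a stop codon, and contains no internal stops;
#' the protein slot is derived by translation and excludes the terminal
#' stop. Exon boundaries are CDS offsets after which an exon junction
#' falls; they stand in for genomic exon structure when deciding whether
#' an SNV hits a splice donor/acceptor region.
#'
#' @slot geneSymbol gene symbol the transcript belongs to.
#' @slot cds a [Biostrings::DNAString] coding sequence.
#' @slot exonBoundaries integer CDS offsets of exon junctions, strictly
#'   increasing and interior to the CDS.
#' @slot strand `"+"` or `"-"` (annotation only; coordinates are CDS-based).
#' @slot protein derived [Biostrings::AAString] (no terminal stop).
#' @export
setClass("TranscriptModel",
  slots = c(geneSymbol = "character", cds = "DNAString",
            exonBoundaries = "integer", strand = "character",
            protein = "AAString"))

setValidity("TranscriptModel", function(object) {
  msgs <- character(0)
  cds <- as.character(object@cds)
  n <- nchar(cds)
  if (n < 27L) msgs <- c(msgs, "CDS must be at least 27 nt")
  if (n %% 3L != 0L) msgs <- c(msgs, "CDS length must be divisible by 3")
  if (substr(cds, 1L, 3L) != "ATG") msgs <- c(msgs, "CDS must start with ATG")
  codons <- substring(cds, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  if (anyNA(aa)) msgs <- c(msgs, "CDS contains a non-ACGT codon")
  else {
    if (aa[length(aa)] != "*") msgs <- c(msgs, "CDS must end in a stop codon")
    if (any(aa[-length(aa)] == "*")) msgs <- c(msgs, "internal stop codon")
    if (!identical(paste(aa[-length(aa)], collapse = ""),
                   as.character(object@protein)))
      msgs <- c(msgs, "protein slot does not match CDS translation")
  }
  b <- object@exonBoundaries
  if (length(b) && (any(diff(b) <= 0L) || any(b < 1L) || any(b >= n)))
    msgs <- c(msgs, "exon boundaries must be strictly increasing and interior")
  if (!object@strand %in% c("+", "-")) msgs <- c(msgs, "strand must be + or -")
  if (length(msgs)) msgs else TRUE
})

#' Construct a TranscriptModel
#'
#' @param geneSymbol gene symbol.
#' @param cds coding sequence (character or [Biostrings::DNAString]):
#'   `ATG ... stop`, length divisible by 3, no internal stop.
#' @param exonBoundaries integer CDS offsets of exon junctions.
#' @param strand `"+"` or `"-"`.
#' @return a validated [TranscriptModel-class] object; the protein slot is
#'   derived by translation.
#' @examples
#' tm <- TranscriptModel("TP53", "ATGGATCCTAAAGGGTTTCCCGATTAA", c(9L, 18L))
#' proteinSequence(tm)
#' @export
TranscriptModel <- function(geneSymbol, cds, exonBoundaries = integer(0),
                            strand = "+") {
  cds <- Biostrings::DNAString(as.character(cds))
  prot <- sub("\\*$", "",
              suppressWarnings(as.character(Biostrings::translate(cds))))
  new("TranscriptModel", geneSymbol = as.character(geneSymbol), cds = cds,
      exonBoundaries = as.integer(exonBoundaries), strand = strand,
      protein = Biostrings::AAString(prot))
}

setMethod("show", "TranscriptModel", function(object) {
  cat("TranscriptModel", object@geneSymbol, "| CDS", length(object@cds),
      "nt | protein", length(object@protein), "aa |",
      length(object@exonBoundaries), "exon junction(s) | strand",
      object@strand, "\n")
})

#' Simulation parameters for the synthetic tumor/normal cohort generator
#'
#' Encodes the cohort structure the generator emulates: patient number and
#' TNBC fraction, per-patient exonic mutation burden (with a TNBC
#' multiplier), tumor/normal sequencing depths, the truncated-Beta variant
#' allele fraction model, per-base sequencing error, the six-class mutation
#' mix dominated by nsSNVs, a zero-inflated negative-binomial RNA read-count
#' model, decoy site rates, and the HLA allele pool. The seed fully
#' determines the generated cohort.
#'
#' @slot nPatients number of patients.
#' @slot tnbcFraction proportion of patients labelled TNBC.
#' @slot meanBurden expected exonic mutations per non-TNBC patient.
#' @slot tnbcBurdenMultiplier burden ratio TNBC / non-TNBC (> 1).
#' @slot tumorDepth,normalDepth mean read depths (Poisson).
#' @slot vafShape1,vafShape2,vafMin Beta(shape1, shape2) variant allele
#'   fraction, truncated to `[vafMin, 1]`.
#' @slot sequencingErrorRate per-base probability of an error read; a
#'   specific alternate base is reached with one third of this rate.
#' @slot classMix named probabilities over the six mutation classes.
#' @slot rnaZeroProb,rnaMu,rnaSize zero-inflated negative binomial model of
#'   RNA reads covering a mutated position.
#' @slot germlineDecoyRate,noiseDecoyRate decoy sites per true variant
#'   (germline heterozygous, VAF ~ 0.5 in both samples; pure noise).
#' @slot hlaPool HLA class I allele names patients draw from.
#' @slot seed integer seed; identical parameters give identical cohorts.
#' @export
setClass("SimulationParams",
  slots = c(nPatients = "integer", tnbcFraction = "numeric",
            meanBurden = "numeric", tnbcBurdenMultiplier = "numeric",
            tumorDepth = "numeric", normalDepth = "numeric",
            vafShape1 = "numeric", vafShape2 = "numeric", vafMin = "numeric",
            sequencingErrorRate = "numeric", classMix = "numeric",
            rnaZeroProb = "numeric", rnaMu = "numeric", rnaSize = "numeric",
            germlineDecoyRate = "numeric", noiseDecoyRate = "numeric",
            hlaPool = "character", seed = "integer"))

setValidity("SimulationParams", function(object) {
  msgs <- character(0)
  inunit <- function(x) all(x >= 0 & x <= 1)
  if (object@nPatients < 1L) msgs <- c(msgs, "nPatients must be >= 1")
  if (!inunit(object@tnbcFraction)) msgs <- c(msgs, "tnbcFraction in [0,1]")
  if (object@meanBurden < 0) msgs <- c(msgs, "meanBurden must be >= 0")
  if (object@tnbcBurdenMultiplier <= 0)
    msgs <- c(msgs, "tnbcBurdenMultiplier must be > 0")
  if (object@tumorDepth < 1 || object@normalDepth < 1)
    msgs <- c(msgs, "depths must be >= 1")
  if (!inunit(object@sequencingErrorRate))
    msgs <- c(msgs, "sequencingErrorRate in [0,1]")
  if (!inunit(object@vafMin)) msgs <- c(msgs, "vafMin in [0,1]")
  if (!setequal(names(object@classMix), MUTATION_CLASSES) ||
      !inunit(object@classMix) ||
      abs(sum(object@classMix) - 1) > 1e-8)
    msgs <- c(msgs, "classMix must be probabilities over the six classes summing to 1")
  if (!inunit(object@rnaZeroProb)) msgs <- c(msgs, "rnaZeroProb in [0,1]")
  if (object@rnaMu < 0 || object@rnaSize <= 0)
    msgs <- c(msgs, "rnaMu >= 0 and rnaSize > 0 required")
  if (object@germlineDecoyRate < 0 || object@noiseDecoyRate < 0)
    msgs <- c(msgs, "decoy rates must be >= 0")
  if (length(msgs)) msgs else TRUE
})

DEFAULT_HLA_POOL <- c(
  "HLA-A*02:01", "HLA-A*02:06", "HLA-A*24:02", "HLA-A*11:01", "HLA-A*31:01",
  "HLA-B*07:02", "HLA-B*15:01", "HLA-B*35:01", "HLA-B*40:02", "HLA-B*51:01",
  "HLA-C*01:02", "HLA-C*03:03", "HLA-C*07:02", "HLA-C*08:01", "HLA-C*14:02")

#' Construct SimulationParams
#'
#' Defaults describe a 31-patient breast-cancer-like cohort with 13 TNBC
#' cases carrying twice the mutation burden, ~62.4% nsSNVs among exonic
#' mutations, 100x tumor/normal depths, and a zero-inflated RNA read-count
#' model so the expression filter has real attrition.
#'
#' @param nPatients,tnbcFraction cohort composition.
#' @param meanBurden,tnbcBurdenMultiplier expected exonic mutations per
#'   non-TNBC patient and the TNBC ratio.
#' @param tumorDepth,normalDepth mean sequencing depths.
#' @param vafShape1,vafShape2,vafMin truncated Beta VAF model.
#' @param sequencingErrorRate per-base error probability.
#' @param classMix named six-class probability vector.
#' @param rnaZeroProb,rnaMu,rnaSize RNA covering-read model.
#' @param germlineDecoyRate,noiseDecoyRate decoy sites per true variant.
#' @param hlaPool HLA class I allele names (locus parsed from the name).
#' @param seed integer seed.
#' @return a [SimulationParams-class] object.
#' @export
SimulationParams <- function(nPatients = 31L, tnbcFraction = 13 / 31,
                             meanBurden = 72, tnbcBurdenMultiplier = 2,
                             tumorDepth = 100, normalDepth = 100,
                             vafShape1 = 2, vafShape2 = 5, vafMin = 0.05,
                             sequencingErrorRate = 0.001,
                             classMix = c(nsSNV = 0.624, sSNV = 0.24,
                                          INDEL = 0.06, splicing = 0.05,
                                          stopgain = 0.025, stoploss = 0.001),
                             rnaZeroProb = 0.4, rnaMu = 10, rnaSize = 1,
                             germlineDecoyRate = 1, noiseDecoyRate = 0.5,
                             hlaPool = DEFAULT_HLA_POOL, seed = 1L) {
  new("SimulationParams", nPatients = as.integer(nPatients),
      tnbcFraction = tnbcFraction, meanBurden = meanBurden,
      tnbcBurdenMultiplier = tnbcBurdenMultiplier, tumorDepth = tumorDepth,
      normalDepth = normalDepth, vafShape1 = vafShape1,
      vafShape2 = vafShape2, vafMin = vafMin,
      sequencingErrorRate = sequencingErrorRate,
      classMix = classMix[MUTATION_CLASSES], rnaZeroProb = rnaZeroProb,
      rnaMu = rnaMu, rnaSize = rnaSize, germlineDecoyRate = germlineDecoyRate,
      noiseDecoyRate = noiseDecoyRate, hlaPool = hlaPool,
      seed = as.integer(seed))
}

setMethod("show", "SimulationParams", function(object) {
  cat("SimulationParams:", object@nPatients, "patients (",
      round(object@tnbcFraction * object@nPatients), "TNBC ), burden",
      object@meanBurden, "x", object@tnbcBurdenMultiplier,
      "| depth", object@tumorDepth, "/", object@normalDepth,
      "| seed", object@seed, "\n")
})

#' Somatic caller thresholds
#'
#' The six-filter somatic caller configuration: minimum sequencing depth
#' (applied to tumor and normal), minimum variant-supporting reads in the
#' tumor, minimum tumor variant allele fraction (inclusive), maximum normal
#' VAF (exclusive), and the Fisher's exact test p-value cutoff (exclusive).
#' Base-quality filtering (quality >= 15) is assumed upstream of the allele
#' counts.
#'
#' @slot minDepth minimum tumor and normal depth (default 10).
#' @slot minVariantDepth minimum tumor alt reads (default 4).
#' @slot minTumorVaf minimum tumor VAF, inclusive (default 0.10).
#' @slot maxNormalVaf maximum normal VAF, exclusive (default 0.02).
#' @slot maxFisherP Fisher p-value cutoff, exclusive (default 0.05).
#' @export
setClass("CallerParams",
  slots = c(minDepth = "integer", minVariantDepth = "integer",
            minTumorVaf = "numeric", maxNormalVaf = "numeric",
            maxFisherP = "numeric"))

setValidity("CallerParams", function(object) {
  msgs <- character(0)
  if (object@minDepth < 0L || object@minVariantDepth < 0L)
    msgs <- c(msgs, "depth thresholds must be >= 0")
  props <- c(object@minTumorVaf, object@maxNormalVaf, object@maxFisherP)
  if (any(props < 0 | props > 1))
    msgs <- c(msgs, "proportions/probabilities must be in [0,1]")
  if (length(msgs)) msgs else TRUE
})

#' @rdname CallerParams-class
#' @param minDepth,minVariantDepth,minTumorVaf,maxNormalVaf,maxFisherP see
#'   the class slots.
#' @return a [CallerParams-class] object.
#' @export
CallerParams <- function(minDepth = 10L, minVariantDepth = 4L,
                         minTumorVaf = 0.10, maxNormalVaf = 0.02,
                         maxFisherP = 0.05) {
  new("CallerParams", minDepth = as.integer(minDepth),
      minVariantDepth = as.integer(minVariantDepth),
      minTumorVaf = minTumorVaf, maxNormalVaf = maxNormalVaf,
      maxFisherP = maxFisherP)
}

setMethod("show", "CallerParams", function(object) {
  cat("CallerParams: depth >=", object@minDepth, "| alt reads >=",
      object@minVariantDepth, "| tumor VAF >=", object@minTumorVaf,
      "| normal VAF <", object@maxNormalVaf, "| Fisher p <",
      object@maxFisherP, "\n")
})

#' Neoantigen filtering parameters
#'
#' Thresholds defining a neoantigen: predicted HLA class I binding affinity
#' strictly below `ic50ThresholdNm` (default 500 nM) and RNA reads covering
#' the mutated position at least `minRnaReadCount` (default 1). The load
#' counting unit decides what "neoantigen load" counts: distinct mutant
#' peptide sequences (default), peptide-allele pairs, or source variants.
#'
#' @slot ic50ThresholdNm IC50 cutoff in nM, strict inequality (default 500).
#' @slot minRnaReadCount minimum RNA read count, inclusive (default 1).
#' @slot peptideLengths peptide lengths enumerated (default 8:11).
#' @slot loadCountingUnit one of `"distinct_peptides"`,
#'   `"peptide_allele_pairs"`, `"variants"`.
#' @export
setClass("NeoantigenParams",
  slots = c(ic50ThresholdNm = "numeric", minRnaReadCount = "numeric",
            peptideLengths = "integer", loadCountingUnit = "character"))

setValidity("NeoantigenParams", function(object) {
  msgs <- character(0)
  if (object@ic50ThresholdNm <= 0) msgs <- c(msgs, "ic50ThresholdNm must be > 0")
  if (object@minRnaReadCount < 0) msgs <- c(msgs, "minRnaReadCount must be >= 0")
  if (any(object@peptideLengths < 1L))
    msgs <- c(msgs, "peptideLengths must be positive")
  if (!object@loadCountingUnit %in%
      c("distinct_peptides", "peptide_allele_pairs", "variants"))
    msgs <- c(msgs, "unknown loadCountingUnit")
  if (length(msgs)) msgs else TRUE
})

#' @rdname NeoantigenParams-class
#' @param ic50ThresholdNm,minRnaReadCount,peptideLengths,loadCountingUnit
#'   see the class slots.
#' @return a [NeoantigenParams-class] object.
#' @export
NeoantigenParams <- function(ic50ThresholdNm = 500, minRnaReadCount = 1,
                             peptideLengths = 8:11,
                             loadCountingUnit = "distinct_peptides") {
  new("NeoantigenParams", ic50ThresholdNm = ic50ThresholdNm,
      minRnaReadCount = minRnaReadCount,
      peptideLengths = as.integer(peptideLengths),
      loadCountingUnit = loadCountingUnit)
}

setMethod("show", "NeoantigenParams", function(object) {
  cat("NeoantigenParams: IC50 <", object@ic50ThresholdNm,
      "nM | RNA reads >=", object@minRnaReadCount, "| lengths",
      paste(range(object@peptideLengths), collapse = "-"), "| unit",
      object@loadCountingUnit, "\n")
})

#' A simulated patient with ground truth
#'
#' One synthetic tumor/normal pair: the subtype label, the ground-truth
#' somatic events (with class and drawn VAF), the observed per-site allele
#' counts (true sites plus germline-het and noise decoys), RNA read counts
#' at mutated positions (covering and mutant-supporting), and the HLA
#' class I genotype.
#'
#' @slot patientId patient identifier.
#' @slot subtype `"TNBC"` or `"non-TNBC"`.
#' @slot trueVariants data.frame of ground-truth events (`variant_id`,
#'   `transcript_id`, `cds_position`, `ref`, `alt`, `mutation_class`, `vaf`).
#' @slot alleleCounts data.frame of observed sites (canonical allele-count
#'   columns plus a `site_type` column for testing).
#' @slot rnaReadCounts data.frame (`variant_id`, `covering`, `mutant`).
#' @slot hlaAlleles up to 6 HLA class I allele names.
#' @export
setClass("SyntheticPatient",
  slots = c(patientId = "character", subtype = "character",
            trueVariants = "data.frame", alleleCounts = "data.frame",
            rnaReadCounts = "data.frame", hlaAlleles = "character"))

setValidity("SyntheticPatient", function(object) {
  msgs <- character(0)
  if (!object@subtype %in% c("TNBC", "non-TNBC"))
    msgs <- c(msgs, "subtype must be TNBC or non-TNBC")
  if (length(object@hlaAlleles) > 6L)
    msgs <- c(msgs, "at most 6 HLA class I alleles")
  tv <- object@trueVariants
  if (nrow(tv)) {
    ac <- object@alleleCounts
    acid <- paste(ac$transcript_id, ac$cds_position, ac$ref, ac$alt, sep = ":")
    hits <- vapply(tv$variant_id, function(v) sum(acid == v), 0L)
    if (any(hits != 1L))
      msgs <- c(msgs, "every true variant needs exactly one allele-count site")
    if (nrow(object@rnaReadCounts) &&
        !all(object@rnaReadCounts$variant_id %in% tv$variant_id))
      msgs <- c(msgs, "RNA read-count keys must be true variants")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SyntheticPatient", function(object) {
  cat("SyntheticPatient", object@patientId, "(", object@subtype, "):",
      nrow(object@trueVariants), "true variants,",
      nrow(object@alleleCounts), "sites,", length(object@hlaAlleles),
      "HLA alleles\n")
})
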