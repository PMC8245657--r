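# shared fixtures and independent oracles, built in code at test time

# hand-written transcript with known codon layout:
# codons: ATG GAT AAA TGG CCC GGG TTT GAT CAT TAA
#          M   D   K   W   P   G   F   D   H   *
# exon junction after offset 15 (between codons 5 and 6)
tinyTranscript <- function() {
  TranscriptModel("TST1", "ATGGATAAATGGCCCGGGTTTGATCATTAA",
                  exonBoundaries = 15L, strand = "+")
}

# minimal allele-count site row
makeSite <- function(tumorRef, tumorAlt, normalRef, normalAlt,
                     transcript = "TST1", pos = 5L, ref = "A", alt = "T") {
  data.frame(transcript_id = transcript, cds_position = pos, ref = ref,
             alt = alt, tumor_ref = tumorRef, tumor_alt = tumorAlt,
             normal_ref = normalRef, normal_alt = normalAlt)
}

# independent Fisher oracle: explicit choose()-based enumeration of every
# table sharing the observed margins, summing probabilities <= observed
fisherOracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; col1 <- a + c; n <- r1 + r2
  ks <- max(0, col1 - r2):min(r1, col1)
  probs <- choose(r1, ks) * choose(r2, col1 - ks) / choose(n, col1)
  pObs <- probs[ks == a]
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# independent window oracle: brute-force scan of every window of length L
# fully inside a protein of length n, keeping those containing position i
windowOracle <- function(n, i, L) {
  starts <- seq_len(max(0L, n - L + 1L))
  starts[starts <= i & i <= starts + L - 1L]
}

randomProtein <- function(n) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
               n, replace = TRUE), collapse = "")
}

# small reference panel shared across tests (regenerated per file; cheap)
smallReference <- function(nGenes = 5, range = c(150, 450), seed = 7) {
  generateReference(nGenes, range, seed = seed)
}

# run caller -> classifier -> load for one synthetic patient
patientLoad <- function(patient, reference,
                        callerParams = CallerParams(),
                        neoParams = NeoantigenParams()) {
  calls <- callSomaticVariants(alleleCounts(patient), callerParams)
  cl <- classifyVariants(calls, reference)
  neoantigenLoad(cl, reference, hlaAlleles(patient), rnaReadCounts(patient),
                 neoParams)
}
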