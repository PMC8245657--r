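ref1 <- list(TST1 = tinyTranscript())

classifyOne <- function(pos, refBase, altBase) {
  v <- data.frame(transcript_id = "TST1", cds_position = pos, ref = refBase,
                  alt = altBase)
  classifyVariants(v, ref1)
}

test_that("each genetic-code-forced class is assigned correctly", {
  # TGG -> TAG at codon 4: Trp -> stop
  out <- classifyOne(11L, "G", "A")
  expect_equal(out$mutation_class, "stopgain")
  expect_equal(out$ref_aa, "W")
  expect_equal(out$alt_aa, "*")
  # AAA -> AAG at codon 3: Lys -> Lys
  out <- classifyOne(9L, "A", "G")
  expect_equal(out$mutation_class, "sSNV")
  expect_equal(out$protein_position, 3L)
  # GAT -> GAA at codon 2: Asp -> Glu
  out <- classifyOne(6L, "T", "A")
  expect_equal(out$mutation_class, "nsSNV")
  expect_equal(c(out$ref_aa, out$alt_aa), c("D", "E"))
  expect_equal(out$protein_position, 2L)
  # terminal TAA -> TCA: lost stop
  out <- classifyOne(29L, "A", "C")
  expect_equal(out$mutation_class, "stoploss")
  # terminal TAA -> TGA: stop stays stop, protein unchanged
  out <- classifyOne(29L, "A", "G")
  expect_equal(out$mutation_class, "sSNV")
})

test_that("splice-window SNVs and INDEL tokens take precedence", {
  # exon junction after offset 15: positions 14-17 are the splice window
  for (pos in c(14L, 15L, 16L, 17L)) {
    refBase <- substring("ATGGATAAATGGCCCGGGTTTGATCATTAA", pos, pos)
    altBase <- setdiff(c("A", "C", "G", "T"), refBase)[1]
    expect_equal(classifyOne(pos, refBase, altBase)$mutation_class,
                 "splicing")
  }
  # one base outside the window classifies by codon again
  expect_false(classifyOne(13L, "C", "A")$mutation_class == "splicing")
  out <- classifyOne(5L, "A", "DEL")
  expect_equal(out$mutation_class, "INDEL")
})

test_that("coordinate and reference mismatches are rejected", {
  expect_error(classifyOne(31L, "A", "T"), "outside CDS")
  expect_error(classifyOne(1L, "C", "T"), "ref base mismatch")
  expect_error(classifyOne(5L, "A", "N"), "INS/DEL")
})

test_that("classification is total and sSNV means unchanged protein", {
  ref <- smallReference()
  cohort <- simulateCohort(ref, SimulationParams(nPatients = 3L,
                                                 meanBurden = 30,
                                                 seed = 5L))
  for (pt in cohort) {
    calls <- callSomaticVariants(alleleCounts(pt))
    cl <- classifyVariants(calls, ref)
    expect_true(all(cl$mutation_class %in%
      c("nsSNV", "sSNV", "stopgain", "stoploss", "splicing", "INDEL")))
    # synonymous iff translated mutant protein equals the wildtype protein
    snv <- cl[!cl$alt %in% c("INS", "DEL") &
              !cl$mutation_class %in% c("splicing"), ]
    for (i in seq_len(nrow(snv))) {
      m <- ref[[snv$transcript_id[i]]]
      cds <- as.character(cdsSequence(m))
      substr(cds, snv$cds_position[i], snv$cds_position[i]) <- snv$alt[i]
      mutProt <- suppressWarnings(as.character(Biostrings::translate(
        Biostrings::DNAString(cds))))
      wtProt <- paste0(as.character(proteinSequence(m)), "*")
      expect_equal(snv$mutation_class[i] == "sSNV",
                   identical(mutProt, wtProt))
    }
  }
})

test_that("summarizeMutations counts conserve and fraction is exact", {
  empty <- summarizeMutations(data.frame(mutation_class = character(0)))
  expect_equal(sum(empty$counts), 0L)
  expect_true(is.na(empty$nssnvFraction))
  v <- data.frame(mutation_class = c(rep("nsSNV", 5), rep("sSNV", 3)))
  s <- summarizeMutations(v)
  expect_equal(s$total, 8L)
  expect_equal(s$nssnvFraction, 0.625)
  expect_equal(sum(s$counts), nrow(v))
  expect_error(summarizeMutations(data.frame(mutation_class = NA)),
               "six mutation classes")
})
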