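test_that("mutantProtein applies exactly one substitution", {
  ref1 <- list(TST1 = tinyTranscript())
  v <- classifyVariants(data.frame(transcript_id = "TST1",
                                   cds_position = 6L, ref = "T", alt = "A"),
                        ref1)
  mp <- mutantProtein(ref1$TST1, v)
  wt <- as.character(proteinSequence(ref1$TST1))
  expect_equal(mp$position, 2L)
  expect_equal(c(mp$refAA, mp$altAA), c("D", "E"))
  diff <- which(strsplit(mp$protein, "")[[1]] != strsplit(wt, "")[[1]])
  expect_equal(diff, 2L)
  # GAT -> GAA in codon 8 (the second Asp): position 8, D -> E
  v8 <- classifyVariants(data.frame(transcript_id = "TST1",
                                    cds_position = 24L, ref = "T",
                                    alt = "A"), ref1)
  mp8 <- mutantProtein(ref1$TST1, v8)
  expect_equal(mp8$position, 8L)
  expect_equal(c(mp8$refAA, mp8$altAA), c("D", "E"))
  # a synonymous variant is rejected
  vs <- classifyVariants(data.frame(transcript_id = "TST1",
                                    cds_position = 9L, ref = "A",
                                    alt = "G"), ref1)
  expect_error(mutantProtein(ref1$TST1, vs), "nsSNV")
})

test_that("window counts match the closed-form cardinalities", {
  p <- randomProtein(100)
  expect_equal(nrow(enumerateMutantPeptides(p, 50)), 38L)  # 8+9+10+11
  expect_equal(nrow(enumerateMutantPeptides(p, 1)), 4L)
  expect_equal(nrow(enumerateMutantPeptides(p, 5)), 20L)
  expect_error(enumerateMutantPeptides(p, 0), "position")
  expect_error(enumerateMutantPeptides(p, 101), "position")
})

test_that("enumeration matches the brute-force window oracle", {
  set.seed(11)
  for (n in c(7, 8, 11, 12, 19, 25, 30)) {
    prot <- randomProtein(n)
    for (i in seq_len(n)) {
      got <- enumerateMutantPeptides(prot, i)
      for (L in 8:11) {
        starts <- windowOracle(n, i, L)
        sub <- got[got$length == L, ]
        expect_equal(sub$start, starts)
        # closed-form count
        expect_equal(nrow(sub),
                     max(0, min(i, n - L + 1) - max(1, i - L + 1) + 1))
      }
    }
  }
})

test_that("each peptide is a real substring carrying the substitution", {
  prot <- randomProtein(60)
  pos <- 33L
  mut <- prot
  substr(mut, pos, pos) <- "W"
  out <- enumerateMutantPeptides(mut, pos, wildtypeAA = substr(prot, pos,
                                                              pos))
  expect_gt(nrow(out), 0)
  for (i in seq_len(nrow(out))) {
    expect_equal(out$sequence[i],
                 substr(mut, out$start[i], out$start[i] + out$length[i] - 1))
    expect_equal(substr(out$sequence[i], out$mutated_offset[i] + 1,
                        out$mutated_offset[i] + 1), "W")
    # wildtype counterpart differs at exactly the mutated offset
    d <- which(strsplit(out$sequence[i], "")[[1]] !=
               strsplit(out$wildtype_sequence[i], "")[[1]])
    expect_equal(d, out$mutated_offset[i] + 1L)
  }
  # no duplicated (length, start) windows
  expect_false(anyDuplicated(out[, c("length", "start")]) > 0)
})
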