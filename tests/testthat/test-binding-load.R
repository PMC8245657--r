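refL <- smallReference(6, c(240, 480), seed = 9)

# one classified patient via the full caller path
cohortL <- simulateCohort(refL, SimulationParams(nPatients = 4L,
                                                 meanBurden = 25,
                                                 seed = 17L))
classifiedL <- lapply(cohortL, function(pt)
  classifyVariants(callSomaticVariants(alleleCounts(pt)), refL))

test_that("predictBinding emits one prediction per peptide-allele pair", {
  prot <- randomProtein(100)
  peps <- enumerateMutantPeptides(prot, 50)
  alleles <- c("HLA-A*02:01", "HLA-A*24:02", "HLA-B*07:02", "HLA-B*15:01",
               "HLA-C*01:02", "HLA-C*03:03")
  out <- predictBinding(peps, alleles)
  expect_equal(nrow(out), 38L * 6L)
  # homozygous allele deduplicated before pairing
  out2 <- predictBinding(peps, c(alleles, alleles[1]))
  expect_equal(nrow(out2), nrow(out))
})

test_that("table predictors report missing pairs instead of dropping them", {
  tab <- data.frame(allele = "HLA-A*02:01",
                    peptide = c("AAAAAAAA", "CCCCCCCC"),
                    ic50_nm = c(100, 600))
  path <- tempfile(fileext = ".tsv")
  writeAffinityTable(tab, path)
  at <- readAffinityTable(path)
  out <- predictBinding(c("AAAAAAAA", "DDDDDDDD"), "HLA-A*02:01",
                        predictor = tablePredictor(at))
  expect_equal(nrow(out), 2L)
  expect_equal(out$ic50_nm, c(100, NA))
  expect_equal(nrow(attr(out, "missing")), 1L)
  expect_error(
    predictBinding(c("AAAAAAAA", "DDDDDDDD"), "HLA-A*02:01",
                   predictor = tablePredictor(at), strict = TRUE),
    "does not cover")
})

test_that("the IC50 filter uses a strict inequality at 500 nM", {
  preds <- data.frame(ic50_nm = c(499.9, 500.0, 500.1, NA))
  out <- filterBinders(preds)
  expect_equal(out$ic50_nm, 499.9)
  expect_equal(nrow(filterBinders(preds[0, , drop = FALSE])), 0L)
})

test_that("mutationReadCount honours modes and absence", {
  counts <- data.frame(variant_id = c("v1", "v2"), covering = c(5L, 1L),
                       mutant = c(2L, 0L))
  expect_equal(mutationReadCount(counts, c("v1", "v2", "v3")), c(5L, 1L, 0L))
  expect_equal(mutationReadCount(counts, "v1", mode = "mutant_supporting"),
               2L)
  # read count 1 meets the >= 1 expression criterion but not the
  # stricter >= 2 candidate-selection rule
  expect_true(mutationReadCount(counts, "v2") >= 1)
  expect_false(mutationReadCount(counts, "v2") >= 2)
  expect_error(
    mutationReadCount(data.frame(variant_id = "v", covering = -1L,
                                 mutant = 0L), "v"),
    "non-negative")
})

test_that("load counts distinct passing peptides under the default unit", {
  ref1 <- list(TST1 = tinyTranscript())
  v <- classifyVariants(data.frame(transcript_id = "TST1",
                                   cds_position = 6L, ref = "T", alt = "A"),
                        ref1)
  # patient with zero nsSNVs
  v0 <- v[0, ]
  z <- neoantigenLoad(v0, ref1, "HLA-A*02:01",
                      data.frame(variant_id = character(0),
                                 covering = integer(0),
                                 mutant = integer(0)))
  expect_equal(z$load, 0L)
  # exactly 3 peptides resolvable, all strong binders, read count 1
  peps <- enumerateMutantPeptides(mutantProtein(ref1$TST1, v)$protein,
                                  2)$sequence
  tab <- data.frame(allele = "HLA-A*02:01", peptide = unique(peps)[1:3],
                    ic50_nm = c(50, 60, 70))
  path <- tempfile(fileext = ".tsv"); writeAffinityTable(tab, path)
  pred <- tablePredictor(readAffinityTable(path))
  rna <- data.frame(variant_id = v$variant_id, covering = 1L, mutant = 1L)
  res <- neoantigenLoad(v, ref1, "HLA-A*02:01", rna, predictor = pred)
  expect_equal(res$load, 3L)
  expect_equal(res$nNsSnv, 1L)
  # raising the read-count requirement to 2 empties the load
  res2 <- neoantigenLoad(v, ref1, "HLA-A*02:01", rna,
                         NeoantigenParams(minRnaReadCount = 2),
                         predictor = pred)
  expect_equal(res2$load, 0L)
  expect_equal(res2$nPredictedBinders, 3L)  # binding alone is unaffected
})

test_that("vectorised load equals the composition of the basic operations", {
  cl <- classifiedL[[1]]
  pt <- cohortL[[1]]
  res <- neoantigenLoad(cl, refL, hlaAlleles(pt), rnaReadCounts(pt))
  ns <- cl[cl$mutation_class == "nsSNV", ]
  manual <- list()
  for (i in seq_len(nrow(ns))) {
    mp <- mutantProtein(refL[[ns$transcript_id[i]]], ns[i, ])
    pep <- enumerateMutantPeptides(mp$protein, mp$position, 8:11, mp$refAA)
    pep$variant_id <- ns$variant_id[i]
    manual[[i]] <- pep
  }
  manual <- do.call(rbind, manual)
  got <- res$binders
  for (al in unique(hlaAlleles(pt))) {
    ic <- toyBindingModel(manual$sequence, al)
    pass <- manual[ic < 500, ]
    sub <- got[got$hla_allele == al, ]
    expect_setequal(paste(sub$variant_id, sub$sequence),
                    paste(pass$variant_id, pass$sequence))
  }
  # wildtype counterparts agree with the per-variant route
  m <- merge(got, manual, by = c("variant_id", "start", "length"))
  expect_gt(nrow(m), 0)
  expect_equal(m$wildtype_sequence.x, m$wildtype_sequence.y)
})

test_that("load is monotone in both thresholds and conserves structure", {
  for (i in seq_along(cohortL)) {
    pt <- cohortL[[i]]
    cl <- classifiedL[[i]]
    loads <- vapply(c(500, 250, 50), function(thr)
      neoantigenLoad(cl, refL, hlaAlleles(pt), rnaReadCounts(pt),
                     NeoantigenParams(ic50ThresholdNm = thr))$load, 0L)
    expect_true(all(diff(loads) <= 0))
    loadsR <- vapply(c(1, 2, 5), function(rc)
      neoantigenLoad(cl, refL, hlaAlleles(pt), rnaReadCounts(pt),
                     NeoantigenParams(minRnaReadCount = rc))$load, 0L)
    expect_true(all(diff(loadsR) <= 0))
    # pipeline conservation: records <= nsSNVs <= called variants
    res <- neoantigenLoad(cl, refL, hlaAlleles(pt), rnaReadCounts(pt))
    expect_lte(length(unique(res$records$variant_id)), res$nNsSnv)
    expect_lte(res$nNsSnv, nrow(cl))
  }
})

test_that("a duplicated homozygous allele leaves the load unchanged", {
  pt <- cohortL[[2]]
  cl <- classifiedL[[2]]
  rna <- rnaReadCounts(pt)
  rna$covering <- pmax(1L, rna$covering)  # fully expressed cohort
  hla <- unique(hlaAlleles(pt))
  a <- neoantigenLoad(cl, refL, hla, rna)$load
  b <- neoantigenLoad(cl, refL, c(hla, hla[1]), rna)$load
  expect_equal(a, b)
})

test_that("vaccine candidates are allele-restricted, ranked and capped", {
  records <- data.frame(
    variant_id = sprintf("v%02d", 1:12), gene_symbol = "G",
    sequence = sprintf("PEPTIDEN%02d", 1:12),
    wildtype_sequence = sprintf("PEPTIDEW%02d", 1:12),
    length = 10L, start = 1L, mutated_offset = 7L,
    hla_allele = c(rep("HLA-A*02:06", 11), "HLA-B*07:02"),
    ic50_nm = c(rep(100, 2), 300, 10, 20, 30, 40, 50, 60, 70, 80, 5),
    read_count = c(rep(2L, 11), 5L))
  out <- selectVaccineCandidates(records, "HLA-A*02:06", topK = 10)
  expect_equal(nrow(out), 10L)
  expect_true(all(out$hla_allele == "HLA-A*02:06"))
  expect_true(!is.unsorted(out$ic50_nm))
  # tie at IC50 100 broken lexicographically
  tied <- out$sequence[out$ic50_nm == 100]
  expect_equal(tied, sort(tied))
  # read-count 2 is required: nothing passes with counts of 1
  r1 <- records; r1$read_count <- 1L
  expect_equal(nrow(selectVaccineCandidates(r1, "HLA-A*02:06")), 0L)
  expect_error(selectVaccineCandidates(records, "HLA-A*99:99"),
               "not among")
})
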