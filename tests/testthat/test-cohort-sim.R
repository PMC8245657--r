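refSim <- smallReference(8, c(300, 600), seed = 2)

test_that("zero mean burden yields variant-free patients", {
  cohort <- simulateCohort(refSim, SimulationParams(nPatients = 3L,
                                                    meanBurden = 0,
                                                    seed = 4L))
  for (pt in cohort) expect_equal(nrow(trueVariants(pt)), 0L)
})

test_that("an empty reference is rejected", {
  expect_error(simulateCohort(list(), SimulationParams()), "non-empty")
})

test_that("identical parameters give byte-identical serialized cohorts", {
  p <- SimulationParams(nPatients = 3L, meanBurden = 20, seed = 12L)
  d1 <- tempfile(); d2 <- tempfile()
  writeCohortDir(simulateCohort(refSim, p), d1)
  writeCohortDir(simulateCohort(refSim, p), d2)
  files <- list.files(d1)
  expect_true(length(files) > 0)
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  # and a different seed changes the cohort
  p2 <- SimulationParams(nPatients = 3L, meanBurden = 20, seed = 13L)
  d3 <- tempfile()
  writeCohortDir(simulateCohort(refSim, p2), d3)
  expect_false(identical(readLines(file.path(d1, files[1])),
                         readLines(file.path(d3, files[1]))))
})

test_that("TNBC patients carry the configured burden excess", {
  p <- SimulationParams(nPatients = 31L, tnbcFraction = 13 / 31,
                        tnbcBurdenMultiplier = 2, meanBurden = 40,
                        seed = 11L)
  cohort <- simulateCohort(refSim, p)
  burden <- vapply(cohort, function(pt) nrow(trueVariants(pt)), 0L)
  tnbc <- vapply(cohort, subtype, "") == "TNBC"
  expect_equal(sum(tnbc), 13L)
  expect_gt(mean(burden[tnbc]), mean(burden[!tnbc]))
})

test_that("realized class mix matches the configured mix within 3 points", {
  p <- SimulationParams(nPatients = 40L, meanBurden = 300, seed = 21L)
  cohort <- simulateCohort(refSim, p)
  classes <- unlist(lapply(cohort, function(pt)
    trueVariants(pt)$mutation_class))
  expect_gt(length(classes), 10000)
  expect_lt(abs(mean(classes == "nsSNV") - 0.624), 0.03)
})

test_that("expected burden increases with meanBurden", {
  grid <- c(5, 15, 30)
  means <- vapply(seq_along(grid), function(i) {
    reps <- vapply(1:50, function(r) {
      p <- SimulationParams(nPatients = 1L, meanBurden = grid[i],
                            tnbcFraction = 0,
                            germlineDecoyRate = 0, noiseDecoyRate = 0,
                            seed = as.integer(1000 * i + r))
      nrow(trueVariants(simulateCohort(refSim, p)[[1]]))
    }, 0L)
    mean(reps)
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("normal samples stay clean of somatic signal", {
  p <- SimulationParams(nPatients = 10L, meanBurden = 100, seed = 31L)
  cohort <- simulateCohort(refSim, p)
  frac <- vapply(cohort, function(pt) {
    ac <- alleleCounts(pt)
    som <- ac[ac$site_type == "somatic", ]
    nd <- som$normal_ref + som$normal_alt
    rate <- 0.001  # generator's default per-base error rate
    thresh <- nd * rate + 5 * sqrt(nd * rate * (1 - rate))
    mean(som$normal_alt > thresh)
  }, 0)
  expect_lt(mean(frac), 0.01)
})

test_that("ground truth, allele counts and RNA keys are consistent", {
  p <- SimulationParams(nPatients = 2L, meanBurden = 25, seed = 41L)
  cohort <- simulateCohort(refSim, p)
  for (pt in cohort) {
    expect_true(validObject(pt))
    tv <- trueVariants(pt)
    ac <- alleleCounts(pt)
    ids <- variantId(ac$transcript_id, ac$cds_position, ac$ref, ac$alt)
    expect_true(all(tv$variant_id %in% ids))
    expect_setequal(rnaReadCounts(pt)$variant_id, tv$variant_id)
    expect_lte(length(hlaAlleles(pt)), 6L)
    # ground-truth classes agree with the classifier on the same sites
    cl <- classifyVariants(
      tv[, c("transcript_id", "cds_position", "ref", "alt")], refSim)
    expect_equal(cl$mutation_class, tv$mutation_class)
  }
})
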