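test_that("fpkm implements the normalisation exactly", {
  expect_equal(fpkm(10, 1000, 1e6), 10)
  expect_equal(fpkm(0, 500, 1e7), 0)
  # joint doubling of reads and library size cancels
  expect_equal(fpkm(20, 1000, 2e6), fpkm(10, 1000, 1e6))
  expect_error(fpkm(10, 0, 1e6), ">= 1")
  expect_error(fpkm(10, 1000, 0), ">= 1")
  # pure function: repeated calls agree
  expect_identical(fpkm(7, 1234, 5e6), fpkm(7, 1234, 5e6))
})

test_that("pearsonCor matches the covariance/SD formula and cor.test", {
  expect_equal(pearsonCor(1:4, 1:4)$r, 1)
  expect_equal(pearsonCor(1:4, -(1:4))$r, -1)
  x <- c(1, 2, 3); y <- c(1, 2, 4)
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  got <- pearsonCor(x, y)
  expect_equal(got$r, manual, tolerance = 1e-12)
  expect_equal(got$n, 3L)
  expect_error(pearsonCor(c(1, 1, 1), y), "zero variance")
  expect_error(pearsonCor(1:2, 1:2), "n >= 3")
})

test_that("pearsonCor is invariant under positive affine transforms", {
  set.seed(8)
  x <- rnorm(20); y <- rnorm(20)
  r0 <- pearsonCor(x, y)$r
  expect_equal(pearsonCor(3 * x + 7, y)$r, r0, tolerance = 1e-12)
  expect_equal(pearsonCor(x, 0.5 * y - 2)$r, r0, tolerance = 1e-12)
})

test_that("groupCompare reports Student's t with medians and ranges", {
  same <- c(3, 5, 9)
  out <- groupCompare(same, same)
  expect_equal(out$t, 0)
  expect_equal(out$p, 1)
  deg <- groupCompare(c(1, 1, 1, 1), c(1, 1, 1, 1))
  expect_true(deg$degenerate)
  expect_equal(deg$p, 1)
  a <- c(10, 20, 30); b <- c(40, 50, 60)
  out <- groupCompare(a, b)
  # textbook pooled-variance formula
  sp2 <- (sum((a - 20)^2) + sum((b - 50)^2)) / 4
  tManual <- (20 - 50) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(out$t, tManual, tolerance = 1e-12)
  expect_equal(out$medianA, 20)
  expect_equal(out$rangeB, c(40, 60))
  expect_error(groupCompare(1, c(1, 2)), "n >= 2")
  # paired mode on equal-length groups
  p <- groupCompare(c(1, 2, 3, 4), c(2, 3, 4, 6), paired = TRUE)
  expect_equal(p$p, t.test(c(1, 2, 3, 4), c(2, 3, 4, 6),
                           paired = TRUE)$p.value)
  expect_error(groupCompare(1:3, 1:4, paired = TRUE), "equal-length")
})

test_that("two-sample t p agrees with a permutation test", {
  set.seed(99)
  a <- rnorm(15, 0); b <- rnorm(15, 0.6)
  pT <- groupCompare(a, b)$p
  pooled <- c(a, b)
  obs <- abs(mean(a) - mean(b))
  perms <- replicate(5000, {
    idx <- sample(30, 15)
    abs(mean(pooled[idx]) - mean(pooled[-idx]))
  })
  pPerm <- mean(perms >= obs)
  expect_lt(abs(pT - pPerm), 0.05)
})

test_that("ELISpot positivity requires strictly more than +50%", {
  expect_true(elispotResponse(151, 100)$positive)
  expect_false(elispotResponse(150, 100)$positive)
  expect_false(elispotResponse(0, 0)$positive)
  z <- elispotResponse(5, 0)
  expect_true(z$positive)
  expect_true(z$unboundedFold)
  expect_error(elispotResponse(-1, 10), "non-negative")
})

test_that("cytotoxicity percentage follows the release formula unclipped", {
  expect_equal(cytotoxicityPercent(100, 100), 0)
  expect_equal(cytotoxicityPercent(200, 50), 75)
  expect_equal(cytotoxicityPercent(100, 120), -20)
  expect_error(cytotoxicityPercent(0, 10), "> 0")
})

test_that("cohortReport computes the correlation set and subtype test", {
  set.seed(5)
  n <- 12
  nss <- rpois(n, 60)
  profiles <- data.frame(
    patient_id = sprintf("P%02d", 1:n),
    tnbc_flag = rep(c(TRUE, FALSE), each = n / 2),
    n_exonic = nss + rpois(n, 35),
    n_nssnv = nss,
    n_predicted_binders = 3L * nss,
    neoantigen_load = 2L * nss)  # load deterministic-linear in nsSNVs
  fpkms <- data.frame(CD8A = rlnorm(n), CD4 = rlnorm(n), TCRB = rlnorm(n),
                      GZMA = rlnorm(n), GZMB = rlnorm(n), PRF1 = rlnorm(n))
  rep_ <- suppressMessages(cohortReport(profiles, fpkms))
  expect_equal(
    rep_$estimate[rep_$comparison == "n_nssnv~neoantigen_load"], 1)
  expect_equal(sum(rep_$type == "pearson"), 9L)
  expect_equal(sum(rep_$type == "t_test"), 1L)
  expect_error(cohortReport(profiles[1:2, ]), "at least 3")
})
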