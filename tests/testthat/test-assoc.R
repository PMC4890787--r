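test_that("clean data pass QC unchanged and QC is idempotent", {
  gm <- random_genotype_matrix(n = 60, m = 80, seed = 51)
  ped <- founder_pedigree(rownames(gm$calls))
  res <- qc_filter(gm, ped)
  expect_identical(res$genotypes$calls, gm$calls)
  ## idempotence with moderate random missingness
  gm2 <- random_genotype_matrix(n = 60, m = 80, miss = 0.04, seed = 52)
  once <- qc_filter(gm2, ped)$genotypes
  twice <- qc_filter(once, ped)$genotypes
  expect_identical(twice$calls, once$calls)
})

test_that("individuals and SNPs violating call-rate / MAF thresholds are removed", {
  gm <- random_genotype_matrix(n = 50, m = 100, seed = 53)
  calls <- gm$calls
  calls[1, sample(100, 15)] <- NA       # individual call rate 0.85
  calls[, 2] <- c(rep(NA, 8), calls[9:50, 2])  # SNP call rate 0.84
  calls[, 3] <- c(1L, rep(0L, 49))      # MAF = 0.01
  gm <- genotype_matrix(calls, gm$markers)
  res <- qc_filter(gm, founder_pedigree(rownames(calls)))
  expect_false("I0001" %in% rownames(res$genotypes$calls))
  expect_false(any(c("S0002", "S0003") %in% colnames(res$genotypes$calls)))
  expect_equal(res$report$ind_low_call_rate, 1L)
})

test_that("Mendelian inconsistency removes the offender above 5 percent", {
  m <- 100
  ## two homozygous parents whose offspring can reveal inconsistencies, plus
  ## 18 uninformative trios (het x het) that dilute the per-SNP error rate
  calls <- rbind(sire = rep(0L, m), dam = rep(0L, m),
                 kid_bad = rep(0L, m), kid_ok = rep(0L, m),
                 sire2 = rep(1L, m), dam2 = rep(1L, m),
                 matrix(1L, 18, m, dimnames = list(sprintf("pad%02d", 1:18),
                                                   NULL)))
  ## offspring 2 with both parents 0 at 6% of SNPs: impossible
  calls["kid_bad", 1:6] <- 2L
  ## single-call inconsistency (1% for the bird, 5% for the SNP): masked only
  calls["kid_ok", 10] <- 2L
  colnames(calls) <- sprintf("S%03d", seq_len(m))
  gm <- genotype_matrix(calls, data.frame(id = colnames(calls), chrom = "chr1",
                                          bp = seq_len(m)))
  ped <- founder_pedigree(rownames(calls))
  ped$sire[ped$id %in% c("kid_bad", "kid_ok")] <- "sire"
  ped$dam[ped$id %in% c("kid_bad", "kid_ok")] <- "dam"
  ped$sire[grepl("^pad", ped$id)] <- "sire2"
  ped$dam[grepl("^pad", ped$id)] <- "dam2"
  res <- qc_filter(gm, ped)
  expect_false("kid_bad" %in% rownames(res$genotypes$calls))
  expect_true("kid_ok" %in% rownames(res$genotypes$calls))
  expect_true(is.na(res$genotypes$calls["kid_ok", "S010"]))
})

test_that("W-linked markers are dropped and Z-het female calls masked", {
  calls <- matrix(1L, 10, 3, dimnames = list(sprintf("I%02d", 1:10),
                                             c("A1", "W1", "Z1")))
  calls[, 1] <- rep(c(0L, 1L, 2L), length.out = 10)
  gm <- genotype_matrix(calls, data.frame(id = colnames(calls),
                                          chrom = c("chr1", "W", "Z"),
                                          bp = 1:3))
  ped <- founder_pedigree(rownames(calls), sex = rep(c("M", "F"), 5))
  res <- qc_filter(gm, ped)
  expect_false("W1" %in% colnames(res$genotypes$calls))
  z <- res$genotypes$calls[, "Z1"]
  expect_true(all(is.na(z[ped$sex == "F"])))
  expect_true(all(z[ped$sex == "M"] == 1L))
})

test_that("kinship behaves for duplicates, inbred lines and independence", {
  gm <- random_genotype_matrix(n = 40, m = 500, seed = 55)
  calls <- gm$calls
  calls[2, ] <- calls[1, ]  # duplicate individuals
  gm <- genotype_matrix(calls, gm$markers)
  K <- compute_kinship(gm)
  expect_equal(K[1, 2], K[1, 1])
  expect_equal(K, t(K))
  ## independent genotypes: off-diagonals near zero
  off <- K[lower.tri(K)]
  off <- off[abs(off - K[1, 1]) > 1e-9]
  expect_lt(mean(abs(off)), 0.1)
  ## two inbred founder lines: between-line < within-line entries
  line <- rbind(matrix(2L, 5, 100), matrix(0L, 5, 100))
  line[, 1:50] <- 2L - line[, 1:50]  # alternate fixation so MAF is 0.5
  rownames(line) <- sprintf("L%02d", 1:10)
  colnames(line) <- sprintf("S%03d", 1:100)
  gml <- genotype_matrix(line, data.frame(id = colnames(line), chrom = "c",
                                          bp = 1:100))
  Kl <- compute_kinship(gml)
  expect_lt(Kl[1, 6], Kl[1, 2])
  ## monomorphic-only input is degenerate
  mono <- matrix(2L, 5, 10, dimnames = list(letters[1:5], LETTERS[1:10]))
  expect_error(compute_kinship(
    genotype_matrix(mono, data.frame(id = LETTERS[1:10], chrom = "c",
                                     bp = 1:10))), "degenerate")
})

test_that("null association p-values are uniform and type-I error nominal", {
  set.seed(56)
  gm <- random_genotype_matrix(n = 300, m = 1000, seed = 56)
  ph <- data.frame(id = rownames(gm$calls),
                   mb_week10 = stats::rbinom(300, 1, 0.5),
                   mb_at_birth = stats::rbinom(300, 1, 0.3))
  kin <- compute_kinship(gm)
  scan <- assoc_scan(gm, ph, kin)
  expect_gt(stats::ks.test(scan$p, "punif")$p.value, 0.01)
  for (alpha in c(0.05, 0.01)) {
    obs <- mean(scan$p < alpha)
    expect_lt(abs(obs - alpha), 3 * sqrt(alpha * (1 - alpha) / 1000))
  }
})

test_that("with identity kinship the scan reduces to the plain score test", {
  set.seed(57)
  n <- 120
  gm <- random_genotype_matrix(n = n, m = 30, seed = 57)
  ph <- data.frame(id = rownames(gm$calls),
                   mb_week10 = stats::rbinom(n, 1, 0.5),
                   mb_at_birth = stats::rbinom(n, 1, 0.3))
  K <- diag(n)
  dimnames(K) <- list(ph$id, ph$id)
  scan <- assoc_scan(gm, ph, K)
  ## independent oracle: covariate-adjusted residuals tested marker by marker
  r <- stats::resid(stats::lm(ph$mb_week10 ~ ph$mb_at_birth))
  for (j in c(1, 7, 19)) {
    p_oracle <- summary(stats::lm(r ~ gm$calls[, j]))$coefficients[2, 4]
    expect_equal(scan$p[j], p_oracle, tolerance = 1e-10)
  }
})

test_that("a fully penetrant dominant locus gives an extreme peak that a
           conditional scan removes", {
  cross <- simulate_cross(mb_cross_config(n_f2 = 564, seed = 58))
  qc <- qc_filter(cross$genotypes, cross$pedigree)
  kin <- compute_kinship(qc$genotypes, exclude_chrom = "chr27")
  scan <- assoc_scan(qc$genotypes, cross$phenotypes, kin)
  expect_equal(attr(scan, "peak_marker"), "M006")  # marker at the locus
  expect_lt(scan$p[scan$marker == "M006"], 1e-19)
  expect_equal(scan$r2_peak[scan$marker == "M006"], 1)
  ## conditioning on the peak: no marker remains genome-wide significant
  expect_message(
    cond <- conditional_scan(qc$genotypes, cross$phenotypes, kin, "M006"),
    "skipped")
  expect_true(is.na(cond$p[cond$marker == "M006"]))
  expect_gt(min(cond$p, na.rm = TRUE), bonferroni_threshold(nrow(cond)))
  ## conditioning on a null marker leaves the peak essentially unchanged
  cond_null <- conditional_scan(qc$genotypes, cross$phenotypes, kin, "BG1_001")
  lp0 <- scan$neg_log10_p[scan$marker == "M006"]
  lp1 <- cond_null$neg_log10_p[cond_null$marker == "M006"]
  expect_lt(abs(lp0 - lp1), 0.15 * lp0 + 1)
})

test_that("power at the causal marker grows with sample size and penetrance", {
  lp <- function(n, pen, seed) {
    cross <- simulate_cross(mb_cross_config(n_f2 = n, penetrance = pen,
                                            seed = seed,
                                            n_background_chrom = 2))
    kin <- compute_kinship(cross$genotypes, exclude_chrom = "chr27")
    scan <- assoc_scan(cross$genotypes, cross$phenotypes, kin)
    scan$neg_log10_p[scan$marker == "M006"]
  }
  small <- mean(vapply(1:2, function(s) lp(100, 1, s), numeric(1)))
  large <- mean(vapply(1:2, function(s) lp(400, 1, s + 10), numeric(1)))
  expect_gt(large, small)
  lowpen <- mean(vapply(1:2, function(s) lp(400, 0.5, s + 20), numeric(1)))
  expect_gt(large, lowpen)
})

test_that("Bonferroni threshold follows alpha over the test count", {
  expect_equal(bonferroni_threshold(1), 0.05)
  expect_equal(bonferroni_threshold(10, 0.10), 0.01)
  expect_equal(bonferroni_threshold(43493), 0.05 / 43493)
  expect_equal(signif(bonferroni_threshold(43493), 5), 1.1496e-06)
  expect_error(bonferroni_threshold(0), ">= 1")
})

test_that("LD r2 matches the haplotype-frequency computation", {
  ## haplotypes AB x4, ab x4, Ab x1, aB x1; all 100 ordered pairs form the
  ## diploid sample, so genotype correlation equals the haplotype r exactly:
  ## D = 0.4 - 0.25 = 0.15, r = D / 0.25 = 0.6, r2 = 0.36
  hapA <- rep(c(1, 1, 1, 1, 0, 0, 0, 0, 1, 0), times = 10)
  hapB <- rep(c(1, 1, 1, 1, 0, 0, 0, 0, 0, 1), times = 10)
  hapA2 <- rep(c(1, 1, 1, 1, 0, 0, 0, 0, 1, 0), each = 10)
  hapB2 <- rep(c(1, 1, 1, 1, 0, 0, 0, 0, 0, 1), each = 10)
  calls <- cbind(A = hapA + hapA2, B = hapB + hapB2)
  rownames(calls) <- sprintf("I%03d", 1:100)
  gm <- genotype_matrix(calls, data.frame(id = c("A", "B"), chrom = "c",
                                          bp = 1:2))
  expect_equal(ld_r2(gm, "A", "B"), 0.36)
  expect_equal(ld_r2(gm, "A", "B"), ld_r2(gm, "B", "A"))
  expect_equal(ld_r2(gm, "A", "A"), 1)
  ## monomorphic marker: undefined
  calls2 <- cbind(calls, M = rep(2L, 100))
  gm2 <- genotype_matrix(calls2, data.frame(id = c("A", "B", "M"),
                                            chrom = "c", bp = 1:3))
  expect_error(ld_r2(gm2, "A", "M"), "monomorphic")
})
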