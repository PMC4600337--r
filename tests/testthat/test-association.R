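test_that("genotype counts exclude missing values and obligate carriers", {
  fx <- make_geno(
    rbind(c(2L, 2L), c(2L, NA), c(0L, 0L), c(0L, 1L), c(1L, 2L)),
    c("case", "case", "control", "control", "obligate_carrier")
  )
  tab <- genotype_counts(fx$genotypes, fx$map, "T001")
  expect_equal(unname(tab["case", ]), c(0, 0, 2))
  expect_equal(unname(tab["control", ]), c(2, 0, 0))
  tab2 <- genotype_counts(fx$genotypes, fx$map, "T002")
  expect_equal(sum(tab2["case", ]), 1) # one missing case dropped
  expect_identical(rownames(tab2), c("case", "control")) # no carrier row
  expect_error(genotype_counts(fx$genotypes, fx$map, "nope"), "not found")
})

test_that("chi-square matches an independent textbook computation", {
  tab <- rbind(c(13, 0, 0), c(0, 35, 34))
  got <- chisq_2x3(tab)
  want <- oracle_chisq(tab)
  expect_equal(got$chi2_stat, want$stat, tolerance = 1e-6)
  expect_equal(got$df, want$df)
  expect_equal(got$p_value, want$p, tolerance = 1e-6)
  expect_lt(got$p_value, 1e-15)

  # random tables, cross-checked against stats::chisq.test without
  # continuity correction (dropping empty columns first)
  set.seed(12)
  for (i in 1:25) {
    t2 <- matrix(rpois(6, 5), 2, 3)
    if (sum(t2) == 0) next
    got <- chisq_2x3(t2)
    if (got$degenerate) next
    ref <- suppressWarnings(
      stats::chisq.test(t2[, colSums(t2) > 0, drop = FALSE], correct = FALSE)
    )
    expect_equal(got$chi2_stat, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p_value, unname(ref$p.value), tolerance = 1e-10)
  }
})

test_that("identical rows and degenerate tables behave as expected", {
  flat <- chisq_2x3(rbind(c(10, 10, 10), c(10, 10, 10)))
  expect_equal(flat$chi2_stat, 0)
  expect_equal(flat$df, 2)
  expect_equal(flat$p_value, 1)
  deg <- chisq_2x3(rbind(c(5, 0, 0), c(5, 0, 0)))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)
  expect_equal(deg$df, 0)
  expect_error(chisq_2x3(matrix(0, 2, 3)), "grand total")
})

test_that("chi-square is invariant to row swap and column permutation", {
  set.seed(77)
  for (i in 1:20) {
    tab <- matrix(rpois(6, 8), 2, 3)
    if (sum(tab) == 0) next
    base <- chisq_2x3(tab)
    expect_equal(chisq_2x3(tab[2:1, ])$chi2_stat, base$chi2_stat)
    perm <- sample(3)
    expect_equal(chisq_2x3(tab[, perm])$chi2_stat, base$chi2_stat)
  }
})

test_that("exact test agrees with fisher.test and collapses to 2x2 correctly", {
  expect_equal(fisher_2x3(rbind(c(10, 10, 10), c(10, 10, 10))), 1)
  set.seed(5)
  for (i in 1:20) {
    tab <- matrix(rpois(6, 3), 2, 3)
    if (any(rowSums(tab) == 0) || sum(colSums(tab) > 0) < 2) next
    expect_equal(
      fisher_2x3(tab),
      stats::fisher.test(tab[, colSums(tab) > 0, drop = FALSE])$p.value,
      tolerance = 1e-8
    )
  }
  # an empty column contributes nothing: identical p to the reduced 2x2
  tab <- rbind(c(4, 0, 3), c(1, 0, 6))
  expect_equal(fisher_2x3(tab), stats::fisher.test(tab[, c(1, 3)])$p.value,
    tolerance = 1e-10
  )
  expect_error(fisher_2x3(rbind(c(400, 0, 0), c(200, 0, 0))), "enumeration bound")
})

test_that("Bonferroni threshold is alpha over the number of tests", {
  expect_equal(signif(bonferroni_threshold(0.05, 29720), 3), 1.68e-6)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 54602), 0.05 / 54602)
  expect_error(bonferroni_threshold(0.05, 0), "n_tests")
})

test_that("recessive pattern requires all cases in one clean homozygote cell", {
  expect_true(recessive_pattern(rbind(c(0, 0, 13), c(20, 30, 0))))
  expect_true(recessive_pattern(rbind(c(13, 0, 0), c(0, 30, 20))))
  expect_false(recessive_pattern(rbind(c(0, 1, 12), c(20, 30, 0))))
  expect_false(recessive_pattern(rbind(c(0, 0, 13), c(20, 30, 1))))
  expect_false(recessive_pattern(rbind(c(0, 0, 0), c(20, 30, 0))))
})

test_that("scan localizes the simulated locus and flags its pattern", {
  for (s in 1:3) {
    sim <- simulate_population(sim_config(seed = s, genotyping_error_rate = 0.01))
    qc <- apply_qc(sim$genotypes, sim$map)
    scan <- assoc_scan(qc$genotypes, qc$map)
    top <- scan[which.min(scan$p_chi2), ]
    lo <- max(sim$truth$case_ibd$start_bp)
    hi <- min(sim$truth$case_ibd$end_bp)
    expect_gte(top$position_bp, lo)
    expect_lte(top$position_bp, hi)
    expect_lt(top$p_chi2, attr(scan, "threshold"))
  }
})

test_that("single-marker scan uses threshold alpha and fisher path runs", {
  fx <- make_geno(
    rbind(c(2L), c(2L), c(0L), c(1L)),
    c("case", "case", "control", "control")
  )
  scan <- assoc_scan(fx$genotypes, fx$map, alpha = 0.05, test = "both")
  expect_equal(attr(scan, "threshold"), 0.05)
  expect_equal(nrow(scan), 1)
  expect_true(!is.na(scan$p_fisher))
  expect_true(scan$recessive_consistent)
})

test_that("scan tidiers and Manhattan plot expose the expected surface", {
  sim <- simulate_population(sim_config(n_markers = 50, disease_locus_marker = 25))
  scan <- assoc_scan(sim$genotypes, sim$map)
  td <- tidy(scan)
  expect_true(all(c("marker_id", "p_chi2", "neg_log10_p") %in% names(td)))
  gl <- glance(scan)
  expect_equal(gl$n_markers, 50)
  p <- autoplot(scan)
  expect_s3_class(p, "ggplot")
})
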