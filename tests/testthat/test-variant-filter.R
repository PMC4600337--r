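site_row <- function(support = 3, first25 = 1, cov = 10, qual = 20, frac = 0.15) {
  tibble::tibble(
    sample_id = "s", chromosome = "1", position_bp = 100,
    ref_base = "C", alt_base = "T",
    unique_read_support = support, first25_support = first25,
    raw_coverage = cov, base_quality = qual, alt_fraction = frac
  )
}

test_that("all five caller rules are inclusive at their boundaries", {
  at_boundary <- filter_pileup_sites(site_row())
  expect_true(at_boundary$pass)
  just_under <- filter_pileup_sites(site_row(support = 2))
  expect_false(just_under$pass)
  expect_false(just_under$pass_unique_reads)
  expect_true(just_under$pass_first25 && just_under$pass_coverage &&
    just_under$pass_base_quality && just_under$pass_alt_fraction)
  frac_fail <- filter_pileup_sites(site_row(frac = 0.149))
  expect_false(frac_fail$pass)
  expect_false(frac_fail$pass_alt_fraction)
  expect_true(frac_fail$pass_unique_reads)
})

test_that("vectorized filter equals brute-force rule re-application", {
  set.seed(13)
  n <- 10000
  sites <- tibble::tibble(
    sample_id = "s", chromosome = "1", position_bp = seq_len(n),
    ref_base = "A", alt_base = "G",
    raw_coverage = rpois(n, 15),
    unique_read_support = pmin(rpois(n, 4), rpois(n, 15)),
    first25_support = 0L,
    base_quality = runif(n, 0, 45),
    alt_fraction = runif(n)
  )
  sites$unique_read_support <- pmin(sites$unique_read_support, sites$raw_coverage)
  sites$first25_support <- rbinom(n, sites$unique_read_support, 0.5)
  t <- caller_thresholds()
  got <- filter_pileup_sites(sites, t)$pass
  want <- vapply(seq_len(n), function(i) oracle_filter(sites[i, ], t), logical(1))
  expect_identical(got, want)
})

test_that("alt-fraction bands genotype with inclusive het bounds", {
  frs <- c(0, 0.10, 0.15, 0.50, 0.85, 0.86, 1)
  pile <- dplyr::bind_rows(lapply(frs, function(f) site_row(frac = f, cov = 50)))
  g <- genotype_from_pileup(pile)$genotype
  expect_equal(g, c("homref", "homref", "het", "het", "het", "homalt", "homalt"))
  expect_equal(genotype_from_pileup(site_row(cov = 5))$genotype, "nocall")
})

test_that("genotypes are recovered from clean and noisy pileups", {
  set.seed(23)
  truth_codes <- matrix(sample(0:2, 1000, TRUE), nrow = 1)
  fx <- make_geno(truth_codes, "case")
  clean <- simulate_pileups(fx$genotypes, fx$map,
    mean_depth = 30,
    base_error_rate = 0, seed = 1
  )
  clean <- clean[clean$raw_coverage >= 10, ]
  g <- genotype_from_pileup(clean)$genotype
  want <- c("homref", "het", "homalt")[truth_codes[1, match(clean$position_bp, fx$map$position_bp)] + 1L]
  expect_equal(mean(g == want), 1)

  noisy <- simulate_pileups(fx$genotypes, fx$map,
    mean_depth = 200,
    base_error_rate = 0.01, seed = 2
  )
  g2 <- genotype_from_pileup(noisy)$genotype
  want2 <- c("homref", "het", "homalt")[truth_codes[1, ] + 1L]
  expect_gte(mean(g2 == want2), 0.99)
})

test_that("recessive concordance applies the case/control model", {
  calls <- tibble::tibble(
    chromosome = "1", position_bp = 100, ref_base = "C", alt_base = "T",
    sample_id = c(paste0("case", 1:4), paste0("ctl", 1:6)),
    genotype = c(rep("homalt", 4), "het", rep("homref", 5))
  )
  cases <- paste0("case", 1:4)
  ctls <- paste0("ctl", 1:6)
  res <- recessive_concordance(calls, cases, ctls)
  expect_true(res$concordant)
  expect_equal(res$reason, "concordant")

  bad1 <- calls
  bad1$genotype[5] <- "homalt" # a control homozygote
  expect_equal(recessive_concordance(bad1, cases, ctls)$reason, "control_homalt")
  bad2 <- calls
  bad2$genotype[1] <- "het" # a heterozygous case
  expect_equal(recessive_concordance(bad2, cases, ctls)$reason, "case_not_homalt")
  bad3 <- calls
  bad3$genotype[2] <- "nocall" # uncallable case is conservative
  expect_equal(recessive_concordance(bad3, cases, ctls)$reason, "case_nocall")
  expect_false(recessive_concordance(bad3, cases, ctls)$concordant)
})

test_that("codon arithmetic is exact", {
  expect_equal(codon_index(1423), 475L)
  expect_equal(codon_index(1), 1L)
  expect_equal(codon_index(3), 1L)
  expect_equal(codon_index(4), 2L)
  expect_error(codon_index(0), "cds_position")
})

test_that("CDS annotation classifies the premature-stop substitution", {
  # glutamine codon CAG mutated C>T at its first base becomes TAG (stop)
  cds <- paste0("ATG", "CAG", "AAA", "TGA")
  ann <- annotate_cds(cds, 4, "C", "T")
  expect_equal(ann$ref_codon, "CAG")
  expect_equal(ann$alt_codon, "TAG")
  expect_equal(ann$ref_aa, "Q")
  expect_equal(ann$alt_aa, "*")
  expect_equal(ann$consequence, "stop_gain")
  expect_equal(ann$codon_index, 2L)
  expect_equal(ann$truncation_aa, 3 - 2 + 1) # protein 3 residues, stop at codon 2

  same <- annotate_cds(cds, 4, "C", "C")
  expect_equal(same$consequence, "synonymous")
  expect_identical(same$ref_codon, same$alt_codon)

  # truncation at codon 475 of a 500-residue protein removes 26 residues
  long_cds <- paste0(
    strrep("GCT", 474), "CAG", strrep("GCT", 25), "TGA"
  )
  ann475 <- annotate_cds(long_cds, 1423, "C", "T")
  expect_equal(ann475$codon_index, 475L)
  expect_equal(ann475$consequence, "stop_gain")
  expect_equal(ann475$truncation_aa, 26L)

  expect_error(annotate_cds(cds, 4, "G", "T"), "reference mismatch")
  expect_error(annotate_cds("ATGC", 1, "A", "G"), "multiple of 3")
})

test_that("translating the mutated CDS stops exactly at the reported codon", {
  set.seed(3)
  for (rep in 1:5) {
    n_codon <- sample(20:60, 1)
    body <- sample(c("GCT", "GAA", "CTG", "TCA", "CAA"), n_codon - 1, TRUE)
    cds <- paste0(paste(body, collapse = ""), "TGA")
    # pick a CAA/CAG-style codon and force a stop gain via C>T at base 1
    targets <- which(body %in% c("CAA", "CAG"))
    if (length(targets) == 0) next
    ci <- targets[1]
    pos <- (ci - 1) * 3 + 1
    ann <- annotate_cds(cds, pos, "C", "T")
    expect_equal(ann$consequence, "stop_gain")
    mutated <- cds
    substr(mutated, pos, pos) <- "T"
    aa <- strsplit(as.character(
      Biostrings::translate(Biostrings::DNAString(mutated))
    ), "")[[1]]
    expect_equal(which(aa == "*")[1], ann$codon_index)
  }
})

test_that("the concordance filter isolates the causal variant among decoys", {
  # one truth recessive site plus decoys with high population frequency
  set.seed(19)
  n_cases <- 4
  survivors <- function(n_controls, seed) {
    n_decoy <- 50
    truth <- c(rep(2L, n_cases), rep(c(1L, 0L), length.out = n_controls))
    decoys <- matrix(
      sample(0:2, (n_cases + n_controls) * n_decoy, TRUE, prob = c(.1, .2, .7)),
      ncol = n_decoy
    )
    fx <- make_geno(
      cbind(truth, decoys),
      c(rep("case", n_cases), rep("control", n_controls))
    )
    pile <- simulate_pileups(fx$genotypes, fx$map,
      mean_depth = 100,
      base_error_rate = 0.001, seed = seed
    )
    calls <- call_variants(pile)
    conc <- recessive_concordance(
      calls,
      fx$genotypes$sample_id[fx$genotypes$phenotype == "case"],
      fx$genotypes$sample_id[fx$genotypes$phenotype == "control"]
    )
    conc[conc$concordant, "position_bp", drop = TRUE]
  }
  truth_pos <- 1 # first marker position in make_geno spacing
  few <- lengths <- c()
  for (s in 1:5) {
    surv_small <- survivors(2, s)
    surv_large <- survivors(8, s + 100)
    expect_true(1 %in% surv_small)
    expect_true(1 %in% surv_large)
    few <- c(few, length(surv_small))
    lengths <- c(lengths, length(surv_large))
  }
  expect_gt(mean(few), mean(lengths)) # decoy survival falls with more controls
})
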