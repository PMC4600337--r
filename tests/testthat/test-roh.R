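test_that("homozygous runs follow the termination and trimming rules", {
  fx <- make_geno(
    rbind(
      c(2L, 2L, 2L, 1L, 2L),
      c(2L, NA, 2L, 1L, 0L),
      c(1L, 1L, 1L, 1L, 1L)
    ),
    c("case", "case", "control")
  )
  runs <- homozygous_runs(fx$genotypes, fx$map, min_markers = 2)
  r1 <- runs[runs$sample_id == "s01", ]
  expect_equal(nrow(r1), 1)
  expect_equal(r1$start_bp, fx$map$position_bp[1])
  expect_equal(r1$end_bp, fx$map$position_bp[3])
  expect_equal(r1$n_markers, 3)
  r2 <- runs[runs$sample_id == "s02", ]
  expect_equal(nrow(r2), 1) # missing tolerated inside, run over markers 1-3
  expect_equal(r2$end_bp, fx$map$position_bp[3])
  expect_equal(r2$n_markers, 2)
  expect_equal(nrow(runs[runs$sample_id == "s03", ]), 0) # all het
})

test_that("shared regions require the identical homozygous allele", {
  codes <- rbind(
    c(1L, 0L, 2L, 2L, 2L, 2L, 1L, 0L),
    c(0L, 1L, 2L, 2L, 2L, 2L, 2L, 2L),
    c(2L, 2L, 2L, 2L, 2L, 2L, 0L, 0L), # control sharing markers 3-6
    c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L) # control with the opposite allele
  )
  fx <- make_geno(codes, c("case", "case", "control", "control"))
  reg <- shared_homozygous_regions(fx$genotypes, fx$map, min_markers = 2)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$start_bp, fx$map$position_bp[3])
  expect_equal(reg$end_bp, fx$map$position_bp[6])
  expect_equal(reg$n_controls_sharing, 1)
  # opposite homozygotes at a marker break sharing entirely
  codes2 <- rbind(c(2L, 2L, 2L), c(2L, 0L, 2L))
  fx2 <- make_geno(codes2, c("case", "case"))
  expect_error(shared_homozygous_regions(fx2$genotypes, fx2$map), NA)
  reg2 <- shared_homozygous_regions(fx2$genotypes, fx2$map, min_markers = 2)
  expect_equal(nrow(reg2), 0)
})

test_that("shared regions equal the exhaustive window oracle", {
  set.seed(41)
  for (rep in 1:20) {
    n_case <- sample(2:10, 1)
    nm <- sample(10:30, 1)
    codes <- matrix(
      sample(c(0L, 1L, 2L, NA), n_case * nm, TRUE, prob = c(.45, .15, .3, .1)),
      nrow = n_case
    )
    fx <- make_geno(
      rbind(codes, matrix(0L, 2, nm)),
      c(rep("case", n_case), "control", "control")
    )
    got <- shared_homozygous_regions(fx$genotypes, fx$map, min_markers = 3)
    want <- oracle_shared_regions(codes, fx$map$position_bp, min_markers = 3)
    expect_equal(got$start_bp, want$start_bp)
    expect_equal(got$end_bp, want$end_bp)
  }
})

test_that("adding a case can only shrink or split shared regions", {
  set.seed(55)
  for (rep in 1:10) {
    nm <- 25
    codes <- matrix(
      sample(c(0L, 1L, 2L), 6 * nm, TRUE, prob = c(.5, .1, .4)),
      nrow = 6
    )
    covered <- function(k) {
      fx <- make_geno(
        rbind(codes[seq_len(k), , drop = FALSE], matrix(0L, 1, nm)),
        c(rep("case", k), "control")
      )
      reg <- shared_homozygous_regions(fx$genotypes, fx$map, min_markers = 1)
      unlist(lapply(seq_len(nrow(reg)), function(i) {
        which(fx$map$position_bp >= reg$start_bp[i] & fx$map$position_bp <= reg$end_bp[i])
      }))
    }
    expect_true(all(covered(6) %in% covered(3)))
  }
})

test_that("region ranking prefers fewest control-sharers with stated tie-breaks", {
  regions <- tibble::tibble(
    chromosome = "1",
    start_bp = c(500, 100, 300, 200),
    end_bp = c(800, 400, 400, 300),
    length_bp = c(301, 301, 101, 101),
    n_cases_sharing = c(13, 13, 13, 13),
    n_controls_sharing = c(4, 1, 4, 4)
  )
  ranked <- rank_regions(regions)
  expect_equal(ranked$n_controls_sharing, c(1, 4, 4, 4))
  # ties on (cases, controls): longer first, then earlier start
  expect_equal(ranked$start_bp, c(100, 500, 200, 300))
  expect_equal(nrow(rank_regions(regions[0, ])), 0)
})

test_that("region length reporting rounds to 2 decimals", {
  expect_equal(region_length_mb(74897451, 76370694), 1.47)
  expect_equal(region_length_mb(1, 1e6), 1.00)
  expect_equal(region_length_mb(5, 5), 0.00)
  expect_error(region_length_mb(10, 5), "start_bp")
})

test_that("top-ranked region converges on the truth interval as cases accrue", {
  lens <- sapply(c(4, 8, 13), function(k) {
    sim <- simulate_population(sim_config(n_cases = k, seed = 61))
    qc <- apply_qc(sim$genotypes, sim$map)
    reg <- rank_regions(shared_homozygous_regions(qc$genotypes, qc$map))
    top <- reg[1, ]
    expect_lte(top$start_bp, sim$truth$disease_position_bp)
    expect_gte(top$end_bp, sim$truth$disease_position_bp)
    top$length_bp
  })
  expect_true(lens[1] >= lens[3])
})

test_that("region genotype codes classify against the associated allele", {
  codes <- rbind(
    c(2L, 2L, 2L),
    c(2L, 2L, 2L),
    c(1L, NA, 0L)
  )
  fx <- make_geno(codes, c("case", "case", "control"))
  reg <- shared_homozygous_regions(fx$genotypes, fx$map, min_markers = 3)
  cd <- genotype_region_codes(fx$genotypes, fx$map, reg[1, ])
  ctl <- cd[cd$sample_id == "s03", ]
  expect_equal(ctl$state, c("het", "missing", "normal_hom"))
  expect_true(all(cd$state[cd$phenotype == "case"] == "associated_hom"))
  expect_s3_class(autoplot(cd), "ggplot")
})
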