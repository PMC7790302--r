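test_that("steady-state pool follows the closed forms at the boundaries", {
  no_inc <- genotype_spec("x", allele_params(1, 0), allele_params(2, 0))
  expect_equal(
    pool_summary(steady_state_pool(no_inc, nmd_params(0.5)))$inclusion_fraction, 0
  )
  all_inc <- genotype_spec("y", allele_params(1.5, 1), allele_params(0.5, 1))
  ps <- pool_summary(steady_state_pool(all_inc, nmd_params(1)))
  expect_equal(ps$inclusion_fraction, 1)
  expect_equal(ps$total, 2)
})

test_that("calibrated pools reproduce the published inclusion levels and ~50% loss", {
  nmd <- nmd_params(0.031)
  wt <- steady_state_pool(
    genotype_spec("+/+", allele_params(1, 0.24), allele_params(1, 0.24)), nmd
  )
  ki <- steady_state_pool(
    genotype_spec("+/KI", allele_params(1, 0.24), allele_params(1, 1)), nmd
  )
  expect_equal(pool_summary(wt)$inclusion_fraction, 0.0097, tolerance = 0.01)
  expect_equal(pool_summary(ki)$inclusion_fraction, 0.048, tolerance = 0.01)
  expect_equal(pool_summary(ki)$total / pool_summary(wt)$total, 0.52, tolerance = 0.01)
})

test_that("the stable pool is linear in transcription rate", {
  withr::with_seed(3, {
    for (rep in 1:10) {
      psi <- runif(2)
      s <- runif(1)
      t0 <- runif(2, 0.1, 5)
      c_scale <- runif(1, 0.5, 10)
      p1 <- steady_state_pool(
        genotype_spec("a", allele_params(t0[1], psi[1]), allele_params(t0[2], psi[2])),
        nmd_params(s)
      )
      p2 <- steady_state_pool(
        genotype_spec(
          "b", allele_params(c_scale * t0[1], psi[1]),
          allele_params(c_scale * t0[2], psi[2])
        ),
        nmd_params(s)
      )
      expect_equal(p2$included, c_scale * p1$included)
      expect_equal(p2$excluded, c_scale * p1$excluded)
      expect_equal(
        pool_summary(p2)$inclusion_fraction,
        pool_summary(p1)$inclusion_fraction
      )
    }
  })
})

test_that("zero reads give an empty track and read set", {
  gm <- scn1a_gene_model(with_sequence = FALSE)
  pool <- steady_state_pool(
    genotype_spec("x", allele_params(1, 0.5), allele_params(1, 0.5)), nmd_params(1)
  )
  sim <- simulate_reads(pool, gm, library_protocol("uniform", total_reads = 0))
  expect_equal(nrow(sim$reads), 0L)
  expect_equal(sum(sim$track$depth), 0)
  expect_equal(sim$mapped_reads, 0L)
})

test_that("read simulation conserves aligned bases exactly and is seed-deterministic", {
  gm <- scn1a_gene_model(with_sequence = FALSE)
  pool <- steady_state_pool(
    genotype_spec("x", allele_params(1, 0.3), allele_params(1, 0.3)), nmd_params(0.5)
  )
  for (mode in c("uniform", "three_prime")) {
    prot <- library_protocol(mode, total_reads = 3000)
    a <- simulate_reads(pool, gm, prot, seed = 99)
    b <- simulate_reads(pool, gm, prot, seed = 99)
    expect_identical(a$reads, b$reads)
    expect_identical(a$track$depth, b$track$depth)
    expect_equal(sum(a$track$depth), sum(a$reads$end - a$reads$start))
    expect_equal(sum(a$reads$end - a$reads$start), 3000 * prot$read_length)
  }
})

test_that("piled-up simulated depth matches the brute-force oracle on a small run", {
  gm <- scn1a_gene_model(with_sequence = FALSE)
  pool <- steady_state_pool(
    genotype_spec("x", allele_params(1, 0.5), allele_params(1, 0.5)), nmd_params(1)
  )
  sim <- simulate_reads(pool, gm, library_protocol("uniform", total_reads = 150), seed = 5)
  region <- list(chrom = gm$chrom, start = min(gm$exons$start), end = max(gm$exons$end))
  expect_equal(sim$track$depth, brute_force_depth(sim$reads, region))
})

test_that("uniform coverage is flat within sampling error on a single isoform", {
  # single-exon gene so every base belongs to the one expressed isoform;
  # interior bases (at least one read length from either transcript end)
  # should be flat up to Poisson noise, whose CV shrinks as reads grow
  m <- toy_model(1000L, poison_idx = 1)
  pool <- steady_state_pool(
    genotype_spec("x", allele_params(1, 1), allele_params(1, 1)), nmd_params(1)
  )
  cv_at <- function(n_reads, seed) {
    prot <- library_protocol("uniform", read_length = 50L, total_reads = n_reads)
    sim <- simulate_reads(pool, m, prot, seed = seed)
    interior <- sim$track$depth[51:950]
    sd(interior) / mean(interior)
  }
  cv_small <- cv_at(2e4, 2)
  cv_large <- cv_at(2e5, 2)
  expect_lt(cv_large, 0.05)
  expect_lt(cv_large, cv_small / 2) # ~1/sqrt(10) scaling
})

test_that("a 3'-biased library is blind to a poison exon far from the 3' end", {
  gm <- scn1a_gene_model(with_sequence = FALSE)
  pool <- steady_state_pool(
    genotype_spec("x", allele_params(1, 0.05), allele_params(1, 0.05)), nmd_params(1)
  )
  prot <- library_protocol("three_prime", total_reads = 400, decay_length = 300)
  sim <- simulate_reads(pool, gm, prot, seed = 13)
  counts <- exon_read_counts(sim$reads, gm)
  expect_lte(counts$count[counts$kind == "poison"], 1L)
  expect_gt(sum(counts$count), 300L)
})

test_that("reads longer than the shortest expressed isoform are rejected", {
  m <- toy_model(c(100L, 64L), poison_idx = 2)
  pool <- steady_state_pool(
    genotype_spec("x", allele_params(1, 0.5), allele_params(1, 0.5)), nmd_params(1)
  )
  expect_error(
    simulate_reads(pool, m, library_protocol("uniform", read_length = 120, total_reads = 10)),
    class = "pexquant_config_error"
  )
})

test_that("qPCR Ct obeys the efficiency model and the detection limit", {
  pool1 <- steady_state_pool(
    genotype_spec("a", allele_params(1, 0.5), allele_params(1, 0.5)), nmd_params(1)
  )
  pool_half <- steady_state_pool(
    genotype_spec("b", allele_params(0.5, 0.5), allele_params(0.5, 0.5)), nmd_params(1)
  )
  qp <- qpcr_params(noise_sd = 0)
  ct1 <- simulate_qpcr(pool1, qp, seed = 1)
  ct2 <- simulate_qpcr(pool_half, qp, seed = 1)
  # halving every quantity with E = 2 adds exactly one cycle
  expect_equal(
    ct2$ct[ct2$assay == "amplicon3"] - ct1$ct[ct1$assay == "amplicon3"], 1
  )
  # abundance below the detection limit reports UD, not a number
  tiny <- steady_state_pool(
    genotype_spec("c", allele_params(1e-9, 0.5), allele_params(1e-9, 0.5)),
    nmd_params(1)
  )
  ct3 <- simulate_qpcr(tiny, qp, seed = 1)
  expect_true(is.na(ct3$ct[ct3$assay == "amplicon3"]))
  # zero quantity is UD, not an error
  none <- steady_state_pool(
    genotype_spec("d", allele_params(1, 0), allele_params(1, 0)), nmd_params(1)
  )
  ct4 <- simulate_qpcr(none, qp, seed = 1)
  expect_true(is.na(ct4$ct[ct4$assay == "amplicon2"]))
})

test_that("calibrated pools give the published brain Ct spacing", {
  nmd <- nmd_params(0.031)
  wt <- steady_state_pool(
    genotype_spec("+/+", allele_params(1, 0.241), allele_params(1, 0.241)), nmd
  )
  # intercept chosen so the total assay sits at the published brain Ct
  qp <- qpcr_params(ct_intercept = 21.6 + log2(pool_summary(wt)$total), noise_sd = 0)
  ct <- simulate_qpcr(wt, qp, seed = 1)
  amp3 <- ct$ct[ct$assay == "amplicon3"]
  amp2 <- ct$ct[ct$assay == "amplicon2"]
  expect_equal(amp3, 21.6, tolerance = 1e-8)
  expect_equal(amp2 - amp3, -log2(pool_summary(wt)$inclusion_fraction))
  expect_equal(amp2, 28.3, tolerance = 0.01)
})

test_that("time-course trajectories are monotone and anchored at the plan endpoints", {
  plan <- timecourse_plan()
  traj <- timecourse_trajectory(plan)
  expect_equal(traj$psi_true[1], 0.70)
  expect_equal(traj$psi_true[nrow(traj)], 0.08)
  expect_true(all(diff(traj$psi_true) < 0))
  expect_true(all(diff(traj$expression) > 0))
  expect_lt(traj$psi_true[traj$timepoint == "P30"], 0.10)
  expect_equal(cor(traj$psi_true, traj$expression, method = "spearman"), -1)
  flat <- timecourse_trajectory(timecourse_plan(psi_start = 0.3, psi_end = 0.3))
  expect_equal(flat$psi_true, rep(0.3, nrow(flat)))
  expect_error(
    timecourse_plan(psi_start = 0.1, psi_end = 0.5),
    class = "pexquant_config_error"
  )
})

test_that("the usage estimator applied to the simulated time course tracks the truth", {
  gm <- scn1a_gene_model(with_sequence = FALSE)
  tc <- simulate_timecourse(
    timecourse_plan(), gm,
    library_protocol("uniform", total_reads = 1e5), seed = 21
  )
  usage <- vapply(
    tc$track, function(tr) poison_usage_percent(tr, gm)$usage_percent,
    numeric(1)
  )
  expect_equal(usage[1], 70, tolerance = 0.1) # 10% relative at 3e4 reads
  expect_lt(max(abs(usage - 100 * tc$psi_true)), 8)
  expect_lte(cor(usage, tc$expression, method = "spearman"), -0.9)
})

test_that("cohort simulation is seeded and reproduces the weaning deficit in expectation", {
  plan <- cohort_plan(seed = 17)
  a <- simulate_cohort(plan)
  b <- simulate_cohort(plan)
  expect_identical(a, b)
  expect_setequal(a$weaning$genotype, c("+/+", "+/KI"))
  expect_equal(sum(a$weaning$n), 73L)
  expect_true(all(a$survival$time_months <= plan$horizon))
  # expected +/KI count at deficit probability 0.27 and n = 73 is ~20
  kis <- vapply(1:200, function(i) {
    sim <- simulate_cohort(cohort_plan(seed = 1000L + i))
    sim$weaning$n[sim$weaning$genotype == "+/KI"]
  }, integer(1))
  expect_equal(mean(kis), 73 * 0.27, tolerance = 0.05)
})

test_that("log-rank power at hazard ratio 10 with 50 per arm exceeds 95%", {
  plan <- cohort_plan(
    n = c("+/+" = 50L, "+/KI" = 50L),
    hazards = c("+/+" = 0.005, "+/KI" = 0.05), horizon = 18
  )
  p <- vapply(1:500, function(i) {
    sim <- simulate_cohort(plan, seed = 5000L + i)
    logrank(sim$survival)$p
  }, numeric(1))
  expect_gt(mean(p < 0.05), 0.95)
})
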