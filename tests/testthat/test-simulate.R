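# Trajectory and haplotype simulator: closed forms, invariants, determinism.

test_that("the deterministic selection update matches hand evaluation", {
  # p = 0.1, s = 0.02, h = 0.5: w-bar = 1.002, p' = 0.1011/1.002
  expect_equal(wf_deterministic_update(0.1, 0.02, 0.5),
               (0.01 * 1.02 + 0.09 * 1.01) /
                 (0.01 * 1.02 + 0.18 * 1.01 + 0.81),
               tolerance = 1e-12)
  expect_equal(wf_deterministic_update(0.3, 0, 0.5), 0.3)
  expect_equal(wf_deterministic_update(c(0, 1), 0.1, 0.2), c(0, 1))
  # recessive allele at low frequency barely moves; additive moves more
  expect_lt(wf_deterministic_update(0.01, 0.05, 0) - 0.01,
            wf_deterministic_update(0.01, 0.05, 0.5) - 0.01)
})

test_that("neutral drift is a martingale and fixes with probability 1/(2N)", {
  set.seed(31)
  N <- 50
  final <- replicate(4000, wf_absorption_run(N, s = 0, k0 = 1))
  phat <- mean(final == 2 * N)
  se <- sqrt(phat * (1 - phat) / 4000)
  expect_lt(abs(phat - 1 / (2 * N)), 3 * max(se, sqrt(0.01 * 0.99 / 4000)))
  # martingale: E[p_final] = p_initial from an interior start
  final2 <- replicate(3000, wf_absorption_run(N, s = 0, k0 = 30,
                                              generations = 50))
  se2 <- sd(final2 / (2 * N)) / sqrt(3000)
  expect_lt(abs(mean(final2 / (2 * N)) - 0.3), 3 * se2)
})

test_that("prior draws stay in bounds and are uniform before conditioning", {
  set.seed(33)
  d <- sample_prior("SDN", 10000)
  expect_true(all(d$s_A >= 0 & d$s_A <= 0.015))
  expect_true(all(d$s_NA >= 0.005 & d$s_NA <= 0.05))
  expect_true(all(d$t_mut >= 40000 & d$t_mut <= 70000))
  ks <- suppressWarnings(ks.test(d$t_mut, "punif", 40000, 70000))
  expect_gt(ks$p.value, 0.01)
  set.seed(99); a <- sample_prior("SSV", 5)
  set.seed(99); b <- sample_prior("SSV", 5)
  expect_identical(a, b)
  expect_error(sample_prior("XXX"))
})

test_that("conditioned trajectories segregate in both demes with sane origins", {
  dem <- gravel_demography("EAS")
  set.seed(35)
  for (m in c("NTR", "SDN", "SSV")) {
    th <- sample_prior(m, 1)
    sc <- selection_scenario(m, th$s_A, th$s_NA, th$t_mut, th$f0)
    tr <- simulate_trajectory(sc, dem)
    expect_true(all(tr$freq1 >= 0 & tr$freq1 <= 1))
    f2 <- tr$freq2[!is.na(tr$freq2)]
    expect_true(all(f2 >= 0 & f2 <= 1))
    expect_gt(tr$freq1[1], 0); expect_lt(tr$freq1[1], 1)
    expect_gt(tr$freq2[1], 0); expect_lt(tr$freq2[1], 1)
    expect_gte(tr$origin, 1)
    expect_equal(length(tr$K1), tr$origin + 1)
  }
  # unconditioned single pass exists and respects bounds
  sc <- selection_scenario("SDN", 0.005, 0.02, 55000)
  tr0 <- simulate_trajectory(sc, dem, condition = "none")
  expect_true(all(tr0$freq1 >= 0 & tr0$freq1 <= 1))
})

test_that("selection raises the mean final non-African frequency", {
  dem <- gravel_demography("EAS")
  set.seed(37)
  run <- function(s_NA) {
    mean(replicate(60, {
      sc <- selection_scenario("SSV", 0, s_NA, 30000, 0.1, check = FALSE)
      simulate_trajectory(sc, dem)$freq2[1]
    }))
  }
  expect_gt(run(0.05), run(0))
})

test_that("haplotype samples honour mu = 0 and the focal frequency", {
  dem <- gravel_demography("EAS")
  set.seed(39)
  sc <- selection_scenario("SDN", 0.005, 0.03, 55000)
  tr <- simulate_trajectory(sc, dem)
  spc0 <- simulator_spec(mu = 0)
  smp0 <- simulate_haplotypes(tr, dem, spc0)
  expect_equal(ncol(smp0$matrix), 1)           # only the focal column
  expect_equal(smp0$positions, 8000)
  # focal sample frequency is binomial around the trajectory's final state
  spc <- simulator_spec()
  daf2 <- replicate(40, {
    smp <- simulate_haplotypes(tr, dem, spc)
    mean(smp$matrix[smp$pop_labels == "nonAFR", smp$focal_index])
  })
  se <- sqrt(tr$freq2[1] * (1 - tr$freq2[1]) / 100 / 40)
  expect_lt(abs(mean(daf2) - tr$freq2[1]), 4 * se + 0.01)
})

test_that("neutral constant-N simulations match Watterson's expectation", {
  set.seed(41)
  N <- 5000; n <- 20; L <- 4000; mu <- 2.36e-8
  dem <- constant_demography(N, lambda = 10)
  spc <- suppressWarnings(simulator_spec(region_length = L, focal_pos = 2000,
                                         n_sample = c(n, 0), mu = mu))
  S <- replicate(400, ncol(simulate_neutral_sample(dem, spc)$matrix))
  ES <- 4 * N * mu * L * sum(1 / seq_len(n - 1))
  expect_lt(abs(mean(S) - ES), 3 * sd(S) / sqrt(length(S)))
})

test_that("a strong recent sweep lengthens non-African haplotypes (XP-EHH)", {
  dem <- gravel_demography("EAS")
  spc <- simulator_spec(n_sample = c(40, 40))
  map <- constant_map(1.76, 12000)
  set.seed(43)
  xp <- function(model, s_NA, f0 = NA) {
    vals <- replicate(25, {
      sc <- selection_scenario(model, 0, s_NA, 30000, f0, check = FALSE)
      tr <- simulate_trajectory(sc, dem)
      smp <- simulate_haplotypes(tr, dem, spc)
      tryCatch(xpehh_raw(smp, smp$focal_index, map, daf_min = 0),
               sweepabc_undefined = function(e) NA_real_)
    })
    mean(vals, na.rm = TRUE)
  }
  expect_gt(xp("SSV", 0.05, 0.05), xp("SSV", 0, 0.05))
})

test_that("batches are deterministic given the seed and log acceptance", {
  dem <- gravel_demography("EAS")
  spc <- simulator_spec(n_sample = c(20, 20))
  set.seed(45); t1 <- simulate_batch("SDN", 25, dem, spc)
  set.seed(45); t2 <- simulate_batch("SDN", 25, dem, spc)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 25)
  expect_gt(attr(t1, "acceptance_rate"), 0)
  expect_lte(attr(t1, "acceptance_rate"), 1)
  expect_true(all(t1$model == "SDN"))
  b <- prior_bounds("SDN")
  expect_true(all(t1$s_A >= b$s_A[1] & t1$s_A <= b$s_A[2]))
  expect_true(all(t1$t_mut >= b$t_mut[1] & t1$t_mut <= b$t_mut[2]))
})

test_that("batch checkpoints make interrupted runs resumable", {
  dem <- gravel_demography("EAS")
  spc <- simulator_spec(n_sample = c(20, 20))
  ckp <- tempfile()
  set.seed(47)
  full <- simulate_batch("SSV", 12, dem, spc)
  # simulate an interrupted run: checkpoint after 6, then resume
  set.seed(47)
  part <- simulate_batch("SSV", 6, dem, spc, checkpoint_path = ckp,
                         checkpoint_every = 6)
  resumed <- simulate_batch("SSV", 12, dem, spc, checkpoint_path = ckp,
                            checkpoint_every = 100)
  expect_equal(resumed$s_NA, full$s_NA, tolerance = 1e-12)
  expect_equal(resumed$xpehh_site, full$xpehh_site, tolerance = 1e-12)
})

test_that("neutral null distributions centre Fay and Wu's H near zero", {
  set.seed(49)
  dem <- constant_demography(5000, lambda = 10)
  spc <- suppressWarnings(simulator_spec(region_length = 4000, focal_pos = 2000,
                                         n_sample = c(30, 0)))
  null <- neutral_null_sims(dem, spc, n = 300)
  expect_s3_class(null, "score_distribution")
  expect_lt(abs(mean(null$values)), 0.25)
  # an observed H below every simulated value gets the floor bound
  p <- empirical_pvalue(min(null$values) - 10, null)
  expect_true(isTRUE(attr(p, "floor_bound")))
})
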