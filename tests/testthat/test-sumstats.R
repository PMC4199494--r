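# Within- and between-population statistics against brute-force oracles and
# hand-derived values.

test_that("pairwise diversity matches brute force and hand values", {
  s <- make_sample(hap_mat(c("00", "01", "11", "11")))
  w <- window_spec("whole_region")
  expect_equal(pairwise_diversity(s, w, "P1"), 7 / 6)
  expect_equal(pairwise_diversity(s, w, "P1"), brute_pi(s, w))
  mono <- make_sample(matrix(1L, 4, 3))
  expect_equal(pairwise_diversity(mono, w, "P1"), 0)
  # duplicating every haplotype rescales pi by the n/(n-1) factor ratio only
  dup <- make_sample(hap_mat(c("00", "01", "11", "11",
                               "00", "01", "11", "11")))
  expect_equal(pairwise_diversity(dup, w, "P1"), brute_pi(dup, w))
  expect_error(pairwise_diversity(make_sample(matrix(0L, 1, 2)), w, "P1"),
               ">= 2")
})

test_that("Watterson's theta matches the harmonic-sum form", {
  w <- window_spec("whole_region")
  expect_equal(watterson_theta(make_sample(matrix(0L, 4, 3)), w, "P1"), 0)
  s2 <- make_sample(hap_mat(c("01", "10")))
  expect_equal(watterson_theta(s2, w, "P1"), 2)   # S = 2, a_1 = 1
  set.seed(1)
  s <- random_sample(4, 6)
  expect_equal(watterson_theta(s, w, "P1"), brute_thetaW(s, w))
  # S = 7, n = 4 gives 7 / (1 + 1/2 + 1/3)
  s7 <- make_sample(rbind(c(1,1,1,1,1,1,1), matrix(0L, 3, 7)))
  expect_equal(watterson_theta(s7, w, "P1"), 7 / (1 + 1/2 + 1/3))
})

test_that("Tajima's D matches the 1989 constants and is undefined at S = 0", {
  s <- make_sample(hap_mat(c("00", "01", "11", "11")))
  w <- window_spec("whole_region")
  expect_equal(tajimas_d(s, w, "P1"), brute_tajD(s, w), tolerance = 1e-12)
  expect_equal(round(tajimas_d(s, w, "P1"), 2), 0.59)
  expect_error(tajimas_d(make_sample(matrix(0L, 4, 2)), w, "P1"),
               class = "sweepabc_undefined")
})

test_that("Fay and Wu's H matches direct evaluation of both estimators", {
  w <- window_spec("whole_region")
  s1 <- make_sample(matrix(c(1L, 0L, 0L, 0L), 4, 1))   # derived count 1 of 4
  expect_equal(fay_wu_h(s1, w, "P1"), 0.5 - 1 / 6)
  s3 <- make_sample(matrix(c(1L, 1L, 1L, 0L), 4, 1))   # derived count 3 of 4
  expect_equal(fay_wu_h(s3, w, "P1"), 0.5 - 1.5)
  expect_equal(fay_wu_h(make_sample(matrix(0L, 4, 2)), w, "P1"), 0)
  un <- make_sample(hap_mat(c("01", "10")))
  un$polarized <- FALSE
  expect_error(fay_wu_h(un, w, "P1"), "polarized")
})

test_that("every SFS statistic equals its oracle on exhaustive small samples", {
  w <- window_spec("whole_region")
  set.seed(42)
  for (rep in 1:25) {
    s <- random_sample(n_hap = sample(4:8, 1), n_site = sample(2:6, 1))
    expect_equal(pairwise_diversity(s, w, "P1"), brute_pi(s, w))
    expect_equal(watterson_theta(s, w, "P1"), brute_thetaW(s, w))
    expect_equal(fay_wu_h(s, w, "P1"), brute_fwH(s, w))
    expect_equal(tajimas_d(s, w, "P1"), brute_tajD(s, w))
  }
})

test_that("Weir-Cockerham site F_ST components match the 1984 formulas", {
  # fixed difference: theta exactly 1 regardless of sample size
  cnt <- rbind(c(0, 0, 10), c(12, 0, 0))
  expect_equal(wc_fst_site(cnt)$theta, 1)
  # equal frequencies with HWE genotypes: s2 = 0 forces theta <= 0
  cnt2 <- rbind(c(4, 8, 4), c(4, 8, 4))
  expect_lte(wc_fst_site(cnt2)$theta, 0)
  # p1 = 0.29, p2 = 0.97 with 50 HWE diploids each
  hwe <- function(p, n) {
    het <- round(2 * p * (1 - p) * n)
    hd <- round(p * n - het / 2)
    c(n - het - hd, het, hd)
  }
  cnt3 <- rbind(hwe(0.29, 50), hwe(0.97, 50))
  o <- brute_wc(cnt3)
  r <- wc_fst_site(cnt3)
  expect_equal(r$theta, unname(o["theta"]))
  expect_equal(c(r$a, r$b, r$c), unname(o[c("a", "b", "c")]))
  expect_equal(r$theta, 0.66, tolerance = 0.02)
  # same-allele monomorphic site is undefined, not 0
  expect_error(wc_fst_site(rbind(c(5, 0, 0), c(5, 0, 0))),
               class = "sweepabc_undefined")
})

test_that("window F_ST is a ratio of sums consistent with per-site components", {
  set.seed(7)
  s <- random_sample(8, 4, two_pop = TRUE)
  w1 <- window_spec("whole_region")
  # single-site window reduces to the site estimator
  s1 <- make_sample(s$matrix[, 1, drop = FALSE], positions = 100,
                    labels = s$pop_labels)
  expect_equal(region_fst(s1, w1), wc_fst_site(genotype_counts(s1, 1))$theta)
  # multi-site: hand ratio of summed components
  comps <- lapply(seq_len(ncol(s$matrix)), function(j)
    brute_wc(rbind(
      c(sum(s$matrix[1:4, j][c(1, 3)] + s$matrix[1:4, j][c(2, 4)] == 0),
        sum(s$matrix[1:4, j][c(1, 3)] + s$matrix[1:4, j][c(2, 4)] == 1),
        sum(s$matrix[1:4, j][c(1, 3)] + s$matrix[1:4, j][c(2, 4)] == 2)),
      c(sum(s$matrix[5:8, j][c(1, 3)] + s$matrix[5:8, j][c(2, 4)] == 0),
        sum(s$matrix[5:8, j][c(1, 3)] + s$matrix[5:8, j][c(2, 4)] == 1),
        sum(s$matrix[5:8, j][c(1, 3)] + s$matrix[5:8, j][c(2, 4)] == 2))))
  )
  num <- sum(vapply(comps, function(x) x["a"], numeric(1)))
  den <- sum(vapply(comps, function(x) sum(x[c("a", "b", "c")]), numeric(1)))
  expect_equal(region_fst(s, w1), num / den)
  mono <- make_sample(matrix(0L, 8, 2), labels = s$pop_labels)
  expect_error(region_fst(mono, w1), class = "sweepabc_undefined")
})

test_that("Reynolds gene-copy F_ST behaves per the 1983 estimator", {
  expect_equal(reynolds_fst_site(c(20, 20), c(20, 0)), 1)
  expect_lte(reynolds_fst_site(c(20, 20), c(8, 8)), 0)
  expect_equal(reynolds_fst_site(c(20, 20), c(4, 16)),
               brute_reynolds(c(20, 20), c(4, 16)))
  set.seed(3)
  for (i in 1:10) {
    n <- sample(4:30, 2, replace = TRUE)
    k <- pmin(pmax(rbinom(2, n, runif(1)), c(1, 0)), n)
    if (sum(k) == 0 || sum(k) == sum(n)) next
    expect_equal(reynolds_fst_site(n, k), brute_reynolds(n, k))
  }
})

test_that("empirical p-values count tail exceedances without re-adding the score", {
  d <- score_distribution(1:999, "upper")
  expect_equal(empirical_pvalue(500, d), 500 / 999)    # ties counted
  p <- empirical_pvalue(1000, d)
  expect_equal(as.numeric(p), 1 / 999)                 # floor bound
  expect_true(isTRUE(attr(p, "floor_bound")))
  dl <- score_distribution(1:1000, "lower")
  expect_equal(empirical_pvalue(500.5, dl), 0.5)
  set.seed(5)
  vals <- c(rnorm(95), rep(2.5, 5))
  expect_equal(empirical_pvalue(2.5, score_distribution(vals, "upper")),
               5 / 100)
  expect_error(score_distribution(numeric(0)), ">= 2")
})

test_that("binned standardization yields per-bin mean 0 and sd 1", {
  set.seed(11)
  scores <- rnorm(600)
  freqs <- runif(600, 0.05, 0.95)
  z <- standardize_binned(scores, freqs, bin_width = 0.1)
  bin <- floor(freqs / 0.1)
  for (b in unique(bin)) {
    expect_lt(abs(mean(z[bin == b])), 1e-9)
    expect_lt(abs(sd(z[bin == b]) - 1), 1e-9)
  }
  # sparse bins are merged and flagged
  z2 <- standardize_binned(c(rnorm(50), 5), c(runif(50, 0, 0.05), 0.99),
                           bin_width = 0.01)
  expect_gt(length(attr(z2, "merged_bins")), 0)
})

test_that("summary vector entries equal their standalone operations", {
  set.seed(21)
  dem <- constant_demography(5000, lambda = 10)
  spc <- simulator_spec(region_length = 12000, focal_pos = 8000,
                        n_sample = c(20, 20))
  # two-pop neutral sample with a focal column bolted on
  dem2 <- gravel_demography("EAS", lambda = 10)
  sc <- selection_scenario("SDN", s_A = 0.005, s_NA = 0.02, t_mut = 55000)
  tr <- simulate_trajectory(sc, dem2)
  smp <- simulate_haplotypes(tr, dem2, spc)
  map <- constant_map(1.76, 12000)
  sv <- compute_summary_vector(smp, map = map)
  expect_setequal(names(sv), default_registry())
  w4 <- window_spec("symmetric"); w8 <- window_spec("asymmetric")
  expect_equal(unname(sv["pi_4kb_p1"]), pairwise_diversity(smp, w4, "AFR"))
  expect_equal(unname(sv["thetaW_8kb_p2"]), watterson_theta(smp, w8, "nonAFR"))
  expect_equal(unname(sv["fwH_8kb_p1"]), fay_wu_h(smp, w8, "AFR"))
  expect_equal(unname(sv["fst_region"]),
               region_fst(smp, window_spec("whole_region")))
  expect_equal(unname(sv["fst_site"]),
               reynolds_fst_site(c(20, 20),
                                 c(sum(smp$matrix[1:20, smp$focal_index]),
                                   sum(smp$matrix[21:40, smp$focal_index]))))
  expect_equal(unname(sv["xpehh_site"]),
               xpehh_raw(smp, smp$focal_index, map, daf_min = 0))
  expect_equal(unname(sv["daf_p1"]), mean(smp$matrix[1:20, smp$focal_index]))
  # focal frequencies constructed by hand: 29/100 and 97/100 derived
  m <- cbind(c(rep(1L, 29), rep(0L, 71), rep(1L, 97), rep(0L, 3)))
  s2 <- make_sample(cbind(m, 1L - m[, 1]), positions = c(100, 200),
                    labels = rep(c("A", "B"), each = 100), focal_index = 1)
  sv2 <- compute_summary_vector(s2, registry = c("daf_p1", "daf_p2"),
                                map = constant_map(1.76, 300))
  expect_equal(unname(sv2["daf_p1"]), 0.29)
  expect_equal(unname(sv2["daf_p2"]), 0.97)
})
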