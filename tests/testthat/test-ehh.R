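# Haplotype-homozygosity statistics against pair-enumeration oracles.

test_that("EHH equals the carrier-pair identity fraction", {
  m <- hap_mat(c("100", "100", "101", "111", "000", "010"))
  s <- make_sample(m, focal_index = 1)
  expect_equal(ehh(s, "P1", 1, 1, 1), 1)               # target = core
  # carriers of allele 1 at site 1 are rows 1:4; interval patterns over
  # sites 2:3 are {00, 00, 01, 11}: only one identical pair among six
  expect_equal(ehh(s, "P1", 1, 1, 3), 1 / 6)
  expect_equal(ehh(s, "P1", 1, 1, 3), brute_ehh(s, "P1", 1, 1, 3))
  ident <- make_sample(hap_mat(c("111", "111", "110", "011")), focal_index = 1)
  expect_equal(ehh(ident, "P1", 1, 1, 2), 1)   # carriers identical over 1..2
  solo <- make_sample(hap_mat(c("10", "00", "00")))
  expect_error(ehh(solo, "P1", 1, 1, 2), class = "sweepabc_undefined")
})

test_that("iHH integrates EHH decay with truncation and edge flagging", {
  map <- constant_map(2, 1000)   # 2 cM/Mb over 1 kb
  # all carriers identical across the region: iHH = genetic region length
  m <- matrix(1L, 4, 3)
  m[4, ] <- c(0L, 1L, 0L)
  s <- make_sample(m, positions = c(100, 500, 900), region_length = 1000)
  v <- ihh(s, "P1", 1, 1, map)
  expect_true(attr(v, "edge_truncated"))
  # carriers of 1 at site 1 (rows 1:3) are identical: EHH = 1 everywhere and
  # flat extension to both edges integrates the full map length
  expect_equal(as.numeric(v), map_cM(map, 1000) - map_cM(map, 0))
  # EHH drops below the threshold at the adjacent site on both sides: only
  # the first trapezoid on each side contributes
  m2 <- rbind(c(1, 0, 1, 0, 1), c(0, 0, 1, 1, 0), c(1, 1, 1, 0, 0),
              c(0, 1, 1, 1, 0))
  s2 <- make_sample(m2, positions = c(100, 200, 300, 400, 500),
                    region_length = 600)
  # adjacent-site EHH is 1/3 on both sides; truncation 0.4 stops there
  v2 <- ihh(s2, "P1", 3, 1, map, truncation = 0.4)
  d <- abs(map_cM(map, 200) - map_cM(map, 300))
  expect_equal(as.numeric(v2), 2 * d * (1 + 1 / 3) / 2)
  expect_equal(as.numeric(v2),
               as.numeric(brute_ihh(s2, "P1", 3, 1, map, truncation = 0.4)))
  # doubling all map rates doubles the integral
  expect_equal(as.numeric(ihh(s2, "P1", 3, 1, constant_map(4, 1000),
                              truncation = 0.4)),
               2 * as.numeric(v2))
})

test_that("iHH equals its oracle on random small samples, both cores", {
  set.seed(13)
  map <- constant_map(1.5, 700)
  for (rep in 1:10) {
    s <- random_sample(6, 6)
    s$region_length <- 700
    core <- sample(2:5, 1)
    for (al in 0:1) {
      rows <- which(s$pop_labels == "P1")
      if (sum(s$matrix[rows, core] == al) < 2) next
      expect_equal(as.numeric(ihh(s, "P1", core, al, map)),
                   as.numeric(brute_ihh(s, "P1", core, al, map)))
    }
    expect_equal(as.numeric(ihh(s, "P1", core, NULL, map)),
                 as.numeric(brute_ihh_pooled(s, "P1", core, map)))
  }
})

test_that("raw iHS is the log iHH ratio with the MAF filter", {
  map <- constant_map(1, 800)
  # perfectly symmetric ancestral/derived haplotype structure
  m <- rbind(c(1, 1, 0), c(1, 0, 1), c(0, 1, 0), c(0, 0, 1))
  s <- make_sample(m, positions = c(200, 400, 600), region_length = 800)
  expect_equal(ihs_raw(s, "P1", 2, map), 0)
  set.seed(17)
  repeat {
    s2 <- random_sample(6, 5)
    cnt <- sum(s2$matrix[, 3])
    if (cnt >= 2 && cnt <= 4) break
  }
  s2$region_length <- 700
  core <- 3
  ia <- brute_ihh(s2, "P1", core, 0, constant_map(1.5, 700))
  id <- brute_ihh(s2, "P1", core, 1, constant_map(1.5, 700))
  expect_equal(ihs_raw(s2, "P1", core, constant_map(1.5, 700)),
               log(ia / id))
  rare <- make_sample(cbind(c(1L, rep(0L, 19)), rbinom(20, 1, 0.5)))
  expect_error(ihs_raw(rare, "P1", 1, constant_map(1, 300)),
               class = "sweepabc_undefined")
})

test_that("raw XP-EHH is antisymmetric and matches the pooled-iHH oracle", {
  map <- constant_map(1.76, 900)
  # identical haplotype sets in both populations give exactly 0
  block <- hap_mat(c("101", "011", "110", "101"))
  s <- make_sample(rbind(block, block), positions = c(200, 500, 700),
                   labels = rep(c("A", "B"), each = 4), focal_index = 2,
                   region_length = 900)
  expect_equal(xpehh_raw(s, 2, map, pop_a = "A", pop_b = "B", daf_min = 0), 0)
  # population A homogeneous, B diverse: positive, equal to the oracle ratio
  mA <- matrix(rep(c(1L, 0L, 1L), each = 4), 4)
  mB <- hap_mat(c("110", "011", "101", "010"))
  s2 <- make_sample(rbind(mA, mB), positions = c(200, 500, 700),
                    labels = rep(c("A", "B"), each = 4), focal_index = 2,
                    region_length = 900)
  v <- xpehh_raw(s2, 2, map, pop_a = "A", pop_b = "B", daf_min = 0)
  expect_gt(v, 0)
  expect_equal(v, log(brute_ihh_pooled(s2, "A", 2, map) /
                      brute_ihh_pooled(s2, "B", 2, map)))
  expect_equal(xpehh_raw(s2, 2, map, pop_a = "B", pop_b = "A", daf_min = 0),
               -v)
  expect_error(xpehh_raw(s2, 2, map, daf_min = 0.99),
               class = "sweepabc_undefined")
})

test_that("EHH is non-increasing for nested intervals and stats respect bounds", {
  set.seed(19)
  for (rep in 1:8) {
    s <- random_sample(8, 6)
    core <- 3
    rows <- which(s$pop_labels == "P1")
    if (sum(s$matrix[rows, core] == 1) < 2) next
    es <- vapply(3:6, function(t) ehh(s, "P1", core, 1, t), numeric(1))
    expect_true(all(diff(es) <= 1e-12))
    expect_true(all(es >= 0 & es <= 1))
    expect_gte(as.numeric(ihh(s, "P1", core, 1, constant_map(1, 700))), 0)
  }
})
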