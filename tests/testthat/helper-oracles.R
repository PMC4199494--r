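# Independent brute-force oracles: every statistic re-derived by exhaustive
# enumeration (pair/site loops) or from first-principles formulas written
# separately from the package implementations.

make_sample <- function(mat, positions = NULL, labels = NULL,
                        focal_index = NULL, region_length = NULL) {
  mat <- as.matrix(mat)
  if (is.null(positions)) positions <- seq_len(ncol(mat)) * 100
  if (is.null(labels)) labels <- rep("P1", nrow(mat))
  if (is.null(region_length)) region_length <- max(positions) + 100
  haplotype_sample(mat, positions, labels, focal_index, region_length)
}

# haplotypes from strings like c("00", "01", "11")
hap_mat <- function(strings) {
  do.call(rbind, lapply(strsplit(strings, ""), as.integer))
}

sub_mat <- function(sample, window, pop) {
  rows <- which(sample$pop_labels == pop)
  fp <- if (window$kind == "whole_region") NULL else
    sample$positions[sample$focal_index]
  sites <- if (window$kind == "whole_region") seq_along(sample$positions) else
    which(sample$positions >= max(0, fp - window$up_bp) &
          sample$positions <= min(sample$region_length, fp + window$down_bp))
  sample$matrix[rows, sites, drop = FALSE]
}

# pi: mean pairwise Hamming distance over all haplotype pairs
brute_pi <- function(sample, window = window_spec("whole_region"), pop = "P1") {
  m <- sub_mat(sample, window, pop)
  n <- nrow(m)
  tot <- 0
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      tot <- tot + sum(m[i, ] != m[j, ])
  tot / choose(n, 2)
}

brute_thetaW <- function(sample, window = window_spec("whole_region"),
                         pop = "P1") {
  m <- sub_mat(sample, window, pop)
  cnt <- colSums(m)
  S <- sum(cnt > 0 & cnt < nrow(m))
  S / sum(1 / seq_len(nrow(m) - 1))
}

# Tajima's D from the 1989 paper's constants, written out independently
brute_tajD <- function(sample, window = window_spec("whole_region"),
                       pop = "P1") {
  m <- sub_mat(sample, window, pop)
  n <- nrow(m)
  cnt <- colSums(m)
  S <- sum(cnt > 0 & cnt < n)
  if (S == 0) return(NA_real_)
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n * n + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / (a1 * a1)
  e1 <- c1 / a1
  e2 <- c2 / (a1 * a1 + a2)
  (brute_pi(sample, window, pop) - S / a1) /
    sqrt(e1 * S + e2 * S * (S - 1))
}

brute_fwH <- function(sample, window = window_spec("whole_region"),
                      pop = "P1") {
  m <- sub_mat(sample, window, pop)
  n <- nrow(m)
  cnt <- colSums(m)
  cnt <- cnt[cnt > 0 & cnt < n]
  tp <- sum(2 * cnt * (n - cnt)) / (n * (n - 1))
  th <- sum(2 * cnt * cnt) / (n * (n - 1))
  tp - th
}

# Weir & Cockerham (1984) components from genotype counts, two populations
brute_wc <- function(counts) {
  n <- rowSums(counts)
  p <- (counts[, 2] + 2 * counts[, 3]) / (2 * n)
  het <- counts[, 2] / n
  r <- 2
  nbar <- sum(n) / r
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  pbar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * het) / sum(n)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) * s2 / r - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) * s2 / r - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc, theta = a / (a + b + cc))
}

# Reynolds (1983) gene-copy ANOVA estimator from haploid counts
brute_reynolds <- function(n, k) {
  p <- k / n
  r <- 2
  nbar <- sum(n) / r
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  pbar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) * s2 / r) / (nbar - 1))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) * s2 / r)
  a / (a + b)
}

# EHH by explicit pair enumeration over the inclusive core..target block
brute_ehh <- function(sample, pop, core, allele, target) {
  rows <- which(sample$pop_labels == pop)
  car <- rows[sample$matrix[rows, core] == allele]
  rng <- sort(c(core, target))
  k <- length(car)
  same <- 0
  for (i in seq_len(k - 1))
    for (j in (i + 1):k)
      if (all(sample$matrix[car[i], rng[1]:rng[2]] ==
              sample$matrix[car[j], rng[1]:rng[2]])) same <- same + 1
  same / choose(k, 2)
}

# iHH by explicit EHH evaluation at every site plus hand trapezoid, matching
# the package truncation conventions (first sub-threshold site included;
# flat extension to the region edge otherwise)
brute_ihh <- function(sample, pop, core, allele, map, truncation = 0.05) {
  gpos <- map_cM(map, sample$positions)
  S <- ncol(sample$matrix)
  one <- function(idxs, edge_bp) {
    es <- vapply(idxs, function(t) brute_ehh(sample, pop, core, allele, t),
                 numeric(1))
    below <- which(es < truncation)
    if (length(below) > 0) {
      use <- seq_len(below[1])
      x <- abs(gpos[idxs[use]] - gpos[core]); y <- es[use]
    } else {
      x <- c(abs(gpos[idxs] - gpos[core]),
             abs(map_cM(map, edge_bp) - gpos[core]))
      y <- c(es, es[length(es)])
    }
    if (length(x) < 2) return(0)
    sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
  }
  one(core:1, 0) + one(core:S, sample$region_length)
}

# pooled-definition iHH (identity includes the core allele): all haplotypes
# of the population are carriers and pair identity is checked over the block
brute_ihh_pooled <- function(sample, pop, core, map, truncation = 0.05) {
  rows <- which(sample$pop_labels == pop)
  gpos <- map_cM(map, sample$positions)
  S <- ncol(sample$matrix)
  pool_ehh <- function(target) {
    rng <- sort(c(core, target))
    k <- length(rows)
    same <- 0
    for (i in seq_len(k - 1))
      for (j in (i + 1):k)
        if (all(sample$matrix[rows[i], rng[1]:rng[2]] ==
                sample$matrix[rows[j], rng[1]:rng[2]])) same <- same + 1
    same / choose(k, 2)
  }
  one <- function(idxs, edge_bp) {
    es <- vapply(idxs, pool_ehh, numeric(1))
    below <- which(es < truncation)
    if (length(below) > 0) {
      use <- seq_len(below[1])
      x <- abs(gpos[idxs[use]] - gpos[core]); y <- es[use]
    } else {
      x <- c(abs(gpos[idxs] - gpos[core]),
             abs(map_cM(map, edge_bp) - gpos[core]))
      y <- c(es, es[length(es)])
    }
    if (length(x) < 2) return(0)
    sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
  }
  one(core:1, 0) + one(core:S, sample$region_length)
}

# random binary sample generator for exhaustive-oracle property tests
random_sample <- function(n_hap = 6, n_site = 5, two_pop = FALSE) {
  repeat {
    m <- matrix(rbinom(n_hap * n_site, 1, runif(1, 0.2, 0.8)), n_hap)
    cnt <- colSums(m)
    if (all(cnt > 0 & cnt < n_hap)) break   # keep focal-eligible columns
  }
  labels <- if (two_pop) rep(c("P1", "P2"), each = n_hap / 2)
            else rep("P1", n_hap)
  make_sample(m, labels = labels)
}

# NIPALS PLS2 oracle (independent of mixOmics): X, Y centred
nipals_pls <- function(X, Y, ncomp) {
  X <- scale(X, scale = FALSE); Y <- scale(Y, scale = FALSE)
  TT <- matrix(0, nrow(X), ncomp)
  W <- matrix(0, ncol(X), ncomp)
  P <- matrix(0, ncol(X), ncomp)
  for (a in seq_len(ncomp)) {
    u <- Y[, which.max(apply(Y, 2, var)), drop = FALSE]
    for (it in 1:500) {
      w <- crossprod(X, u); w <- w / sqrt(sum(w^2))
      tt <- X %*% w
      q <- crossprod(Y, tt); q <- q / sqrt(sum(q^2))
      u_new <- Y %*% q
      if (sum((u_new - u)^2) < 1e-12 * sum(u^2)) { u <- u_new; break }
      u <- u_new
    }
    p <- crossprod(X, tt) / sum(tt^2)
    X <- X - tt %*% t(p)
    Y <- Y - tt %*% t(crossprod(Y, tt) / sum(tt^2))
    TT[, a] <- tt; W[, a] <- w; P[, a] <- p
  }
  list(scores = TT, weights = W, loadings = P)
}

# minimal phased VCF writer for round-trip tests (AA in INFO; 1-based POS)
write_toy_vcf <- function(sample, path, contig = "chr19", start = 1) {
  ids <- unique(sub("_[ab]$", "", paste0(
    sample$pop_labels, "_", rep(seq_len(nrow(sample$matrix) / 2), each = 2))))
  n_ind <- nrow(sample$matrix) / 2
  ids <- paste0("S", seq_len(n_ind))
  lines <- c("##fileformat=VCFv4.2",
             "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", ids), collapse = "\t"))
  for (s in seq_along(sample$positions)) {
    gts <- vapply(seq_len(n_ind), function(i)
      paste0(sample$matrix[2 * i - 1, s], "|", sample$matrix[2 * i, s]),
      character(1))
    lines <- c(lines, paste(c(contig, start + round(sample$positions[s]),
                              ".", "A", "G", ".", "PASS", "AA=A", "GT", gts),
                            collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(ids)
}
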