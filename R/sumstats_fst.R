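# F_ST estimators. Two flavours are used in different parts of the pipeline:
# the Weir & Cockerham (1984) genotype-based estimator (variance components
# a, b, c with observed heterozygosity) for the genome-scan surface, and the
# Reynolds/Weir/Cockerham (1983) coancestry estimator in its gene-copy ANOVA
# form for the ABC summary vector, which consumes phased haplotypes.

#' Weir-Cockerham F_ST variance components at one site
#'
#' The 1984 estimator for two populations of diploid genotypes: among-
#' population (a), among-individual (b) and within-individual (c) variance
#' components, with theta-hat = a / (a + b + c). Observed heterozygosity
#' enters through the genotype counts, so no Hardy-Weinberg assumption is
#' made. A site monomorphic for the same allele in both populations is
#' undefined (0/0) and signals a classed error rather than returning 0.
#'
#' @param counts 2 x 3 matrix of genotype counts per population, columns
#'   (hom-ancestral, het, hom-derived); see [genotype_counts()].
#' @return List with `a`, `b`, `c` and `theta`.
#' @export
wc_fst_site <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 2) stop("exactly two populations are required")
  n <- rowSums(counts)                       # diploid individuals
  if (any(n < 1)) stop("each population needs >= 1 genotype")
  if (mean(n) <= 1)
    undefined_stat("F_ST undefined: the 1984 components need n-bar > 1 diploid")
  p <- (counts[, 2] + 2 * counts[, 3]) / (2 * n)   # derived frequency
  hobs <- counts[, 2] / n                          # observed het frequency
  r <- 2
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * hobs) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  den <- a + b + cc
  if (abs(den) < 1e-300)
    undefined_stat("F_ST undefined: site monomorphic in both populations")
  list(a = a, b = b, c = cc, theta = a / den)
}

# Vectorized Weir-Cockerham components for many sites at once: genotypes are
# reconstructed by pairing consecutive haplotypes within each population.
wc_components_sites <- function(sample, sites) {
  pops <- unique(sample$pop_labels)
  p <- h <- matrix(0, nrow = 2, ncol = length(sites))
  nind <- numeric(2)
  for (k in 1:2) {
    rows <- pop_rows(sample, pops[k])
    if (length(rows) %% 2 != 0)
      stop("population ", pops[k],
           " has an odd haplotype count; cannot pair genotypes")
    a1 <- sample$matrix[rows[seq(1, length(rows), 2)], sites, drop = FALSE]
    a2 <- sample$matrix[rows[seq(2, length(rows), 2)], sites, drop = FALSE]
    G <- a1 + a2
    nind[k] <- nrow(G)
    p[k, ] <- colMeans(G) / 2
    h[k, ] <- colMeans(G == 1L)
  }
  r <- 2
  nbar <- mean(nind)
  if (nbar <= 1)
    undefined_stat("F_ST undefined: the 1984 components need n-bar > 1 diploid")
  nc <- (r * nbar - sum(nind^2) / (r * nbar)) / (r - 1)
  pbar <- colSums(nind * p) / (r * nbar)
  s2 <- colSums(nind * sweep(p, 2, pbar)^2) / ((r - 1) * nbar)
  hbar <- colSums(nind * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc)
}

#' Multi-site Weir-Cockerham F_ST over a window
#'
#' Ratio of sums: sum of a over usable sites divided by the sum of
#' (a + b + c), not a mean of per-site ratios. Sites that are undefined
#' (monomorphic for the same allele in both populations) are skipped; if no
#' site is usable the window estimate is undefined.
#'
#' @param sample a [haplotype_sample] with two populations.
#' @param window a [window_spec].
#' @return theta-hat for the window.
#' @export
region_fst <- function(sample, window = window_spec("whole_region")) {
  sites <- window_sites(sample, window)
  if (length(sites) == 0)
    undefined_stat("window F_ST undefined: no usable polymorphic site")
  comp <- wc_components_sites(sample, sites)
  den_site <- comp$a + comp$b + comp$c
  use <- abs(den_site) > 1e-300
  if (!any(use))
    undefined_stat("window F_ST undefined: no usable polymorphic site")
  sum(comp$a[use]) / sum(den_site[use])
}

#' Reynolds (1983) coancestry F_ST at one site, from haplotype counts
#'
#' The Reynolds/Weir/Cockerham (1983) estimator in its gene-copy ANOVA form:
#' the 1984 variance components computed on haploid gene copies (the
#' within-individual heterozygosity terms vanish), which is the 1983
#' coancestry estimator under random mating. Used for the focal-site F_ST of
#' the ABC summary vector.
#'
#' @param n haploid sample sizes per population (length 2).
#' @param k derived-allele counts per population (length 2).
#' @return theta-hat (may be negative; exactly 1 for a fixed difference).
#' @export
reynolds_fst_site <- function(n, k) {
  if (length(n) != 2 || length(k) != 2) stop("two populations are required")
  if (any(n < 2)) stop("each population needs >= 2 gene copies")
  p <- k / n
  r <- 2
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2) / (nbar - 1))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2)
  if (abs(a + b) < 1e-300)
    undefined_stat("Reynolds F_ST undefined: site monomorphic in both populations")
  a / (a + b)
}

# focal-site Reynolds F_ST of a two-population sample
focal_reynolds_fst <- function(sample) {
  if (is.null(sample$focal_index)) stop("sample has no focal site")
  pops <- unique(sample$pop_labels)
  n <- vapply(pops, function(p) length(pop_rows(sample, p)), integer(1))
  k <- vapply(pops, function(p)
    sum(sample$matrix[pop_rows(sample, p), sample$focal_index]), numeric(1))
  reynolds_fst_site(n, k)
}
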