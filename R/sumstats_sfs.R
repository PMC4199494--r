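# Site-frequency-spectrum statistics on windows around the focal site.
# The arithmetic lives in kernels operating on per-site derived counts, so
# the standalone operations and the batched summary-vector path share one
# implementation.

derived_counts <- function(sample, window, pop) {
  rows <- pop_rows(sample, pop_label(sample, pop))
  sites <- window_sites(sample, window)
  list(i = colSums(sample$matrix[rows, sites, drop = FALSE]),
       n = length(rows))
}

harmonic <- function(k) if (k < 1) 0 else sum(1 / seq_len(k))

pi_kernel <- function(i, n) sum(2 * i * (n - i)) / (n * (n - 1))

thetaW_kernel <- function(i, n) sum(i > 0 & i < n) / harmonic(n - 1)

# Tajima (1989) normalizing constants
tajima_constants <- function(n) {
  a1 <- harmonic(n - 1)
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

tajD_kernel <- function(i, n, ct = tajima_constants(n)) {
  S <- sum(i > 0 & i < n)
  if (S == 0) undefined_stat("Tajima's D undefined: no segregating site")
  (pi_kernel(i, n) - S / ct$a1) / sqrt(ct$e1 * S + ct$e2 * S * (S - 1))
}

fwH_kernel <- function(i, n) {
  i <- i[i > 0 & i < n]   # sites segregating within this population
  (sum(2 * i * (n - i)) - sum(2 * i^2)) / (n * (n - 1))
}

#' Mean pairwise differences (pi)
#'
#' Average number of differences between two haplotypes of the population in
#' the window: sum over sites of 2 i (n - i) / (n (n - 1)) with i the derived
#' count among the n haplotypes.
#'
#' @param sample a [haplotype_sample].
#' @param window a [window_spec].
#' @param pop population label (or 1/2).
#' @return pi in count units.
#' @export
pairwise_diversity <- function(sample, window = window_spec("whole_region"),
                               pop = 1) {
  dc <- derived_counts(sample, window, pop)
  if (dc$n < 2) stop("pairwise diversity needs >= 2 haplotypes")
  pi_kernel(dc$i, dc$n)
}

#' Watterson's theta
#'
#' S / a_n with S the number of sites segregating in the population's window
#' subsample and a_n the (n-1)-th harmonic number.
#'
#' @inheritParams pairwise_diversity
#' @return Watterson's estimator of theta for the window.
#' @export
watterson_theta <- function(sample, window = window_spec("whole_region"),
                            pop = 1) {
  dc <- derived_counts(sample, window, pop)
  if (dc$n < 2) stop("Watterson's theta needs >= 2 haplotypes")
  thetaW_kernel(dc$i, dc$n)
}

#' Tajima's D
#'
#' (pi - theta_W) / sqrt(e1 S + e2 S (S - 1)) with the 1989 constants.
#' Undefined (a classed error, not 0) when the window has no segregating
#' site in the population.
#'
#' @inheritParams pairwise_diversity
#' @return Tajima's D for the window.
#' @export
tajimas_d <- function(sample, window = window_spec("whole_region"), pop = 1) {
  dc <- derived_counts(sample, window, pop)
  if (dc$n < 2) stop("Tajima's D needs >= 2 haplotypes")
  tajD_kernel(dc$i, dc$n)
}

#' Fay and Wu's H
#'
#' The unnormalized 2000 form theta_pi - theta_H, with
#' theta_H = sum over sites of 2 i^2 / (n (n - 1)). Strongly negative H
#' indicates an excess of high-frequency derived alleles, as expected after
#' a recent sweep. Requires derived/ancestral polarization.
#'
#' @inheritParams pairwise_diversity
#' @return H for the window (0 when no site segregates).
#' @export
fay_wu_h <- function(sample, window = window_spec("whole_region"), pop = 1) {
  if (!isTRUE(sample$polarized))
    stop("Fay and Wu's H requires a polarized sample")
  dc <- derived_counts(sample, window, pop)
  if (dc$n < 2) stop("Fay and Wu's H needs >= 2 haplotypes")
  fwH_kernel(dc$i, dc$n)
}
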