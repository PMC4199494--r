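#' Two-deme piecewise demographic model
#'
#' Internal representation used by both the trajectory simulator and the
#' coalescent: per-generation haploid deme sizes (already divided by the
#' rescaling factor lambda), the per-generation migration probability, the
#' split generation, and piecewise-constant epoch sizes for the ancestral
#' single-deme era. Generations are counted backward from the present in
#' rescaled units (one rescaled generation = lambda real generations).
#'
#' @param twoN1,twoN2 integer vectors of haploid (2N) sizes per rescaled
#'   generation before present for deme 1 (African/ancestral) and deme 2
#'   (non-African; 0 where the deme does not exist). Values beyond the vector
#'   end are clamped to the last entry.
#' @param mig per-rescaled-generation migration probability between demes.
#' @param G_split split time in rescaled generations.
#' @param ep_g,ep_2N ancestral-era epoch boundaries (rescaled generations,
#'   ascending) and haploid sizes for the continuous-time coalescent phase.
#' @param G_pergen how many rescaled generations the coalescent must step
#'   through one generation at a time before the single-deme continuous-time
#'   phase may take over (at least the split time; 0 for a constant history).
#' @param lambda rescaling factor applied to sizes, rates and times.
#' @param generation_years years per generation.
#' @param label free-text label.
#' @return An object of class `demographic_model`.
#' @export
demographic_model <- function(twoN1, twoN2, mig, G_split, ep_g, ep_2N,
                              lambda = 10, generation_years = 25,
                              label = "custom", G_pergen = G_split) {
  if (any(twoN1 <= 0)) stop("deme 1 sizes must be positive")
  if (any(twoN2 < 0)) stop("deme 2 sizes must be non-negative")
  if (any(mig < 0)) stop("migration rate must be >= 0")
  if (G_split <= 0) stop("split time must be positive")
  if (is.unsorted(ep_g, strictly = TRUE)) stop("epoch boundaries must be strictly ordered")
  structure(list(twoN1 = as.integer(round(twoN1)),
                 twoN2 = as.integer(round(twoN2)),
                 mig = as.numeric(mig), G_split = as.integer(G_split),
                 ep_g = as.integer(ep_g), ep_2N = as.integer(round(ep_2N)),
                 G_pergen = as.integer(G_pergen),
                 lambda = lambda, generation_years = generation_years,
                 label = label),
            class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  cat(sprintf("demographic_model '%s' (lambda = %g, %g yr/generation)\n",
              x$label, x$lambda, x$generation_years))
  cat(sprintf("  split at %d rescaled generations (%.0f years ago)\n",
              x$G_split, x$G_split * x$lambda * x$generation_years))
  cat(sprintf("  present 2N (rescaled): deme1 %d, deme2 %d\n",
              x$twoN1[1], x$twoN2[1]))
  invisible(x)
}

#' Out-of-Africa two-deme demography (Gravel et al. 2011 parameter values)
#'
#' African deme: ancestral size 7,310 until the African expansion 148 kya,
#' then 14,474. Non-African deme: splits off 51 kya at bottleneck size 1,861,
#' then from 23 kya grows exponentially from 1,032 at 0.38%/generation
#' (European configuration) or from 554 at 0.48%/generation (East Asian
#' configuration). Symmetric migration: 15e-5/generation between Africa and
#' the out-of-Africa bottleneck population, then 2.5e-5 (Africa-Europe) or
#' 0.78e-5 (Africa-East Asia). Generation time 25 years.
#'
#' @param nonafrican `"EAS"` or `"EUR"`: which continental configuration the
#'   non-African deme follows.
#' @param lambda rescaling factor (sizes / lambda, rates and times x lambda).
#' @param generation_years years per generation.
#' @param horizon_gens how many (real) generations of per-generation size
#'   arrays to tabulate; beyond this everything is in the constant ancestral
#'   era and sizes are clamped.
#' @return A [demographic_model].
#' @export
gravel_demography <- function(nonafrican = c("EAS", "EUR"), lambda = 10,
                              generation_years = 25, horizon_gens = 7000) {
  nonafrican <- match.arg(nonafrican)
  N_anc <- 7310; N_afr <- 14474; N_boot <- 1861
  T_exp <- 5920; T_split <- 2040; T_growth <- 920
  if (nonafrican == "EAS") { N0 <- 554; gr <- 0.0048; m_recent <- 0.78e-5 }
  else { N0 <- 1032; gr <- 0.0038; m_recent <- 2.5e-5 }
  m_boot <- 15e-5

  G <- ceiling(horizon_gens / lambda)
  g <- seq_len(G) - 1L           # rescaled generations before present
  tau <- g * lambda              # real generations before present
  n1 <- ifelse(tau < T_exp, N_afr, N_anc)
  n2 <- ifelse(tau < T_growth, N0 * exp(gr * (T_growth - tau)),
               ifelse(tau < T_split, N_boot, 0))
  mig <- lambda * ifelse(tau < T_growth, m_recent,
                         ifelse(tau < T_split, m_boot, 0))
  G_split <- as.integer(round(T_split / lambda))
  demographic_model(twoN1 = round(2 * n1 / lambda),
                    twoN2 = round(2 * n2 / lambda),
                    mig = mig, G_split = G_split,
                    ep_g = c(G_split, as.integer(round(T_exp / lambda))),
                    ep_2N = round(2 * c(N_afr, N_anc) / lambda),
                    lambda = lambda, generation_years = generation_years,
                    label = paste0("gravel_", nonafrican))
}

#' Constant-size single-deme demography
#'
#' Used for neutral calibration runs and as a building block for null tests.
#'
#' @param N diploid effective size.
#' @param lambda rescaling factor.
#' @param generation_years years per generation.
#' @return A [demographic_model] whose deme 2 is absent.
#' @export
constant_demography <- function(N, lambda = 10, generation_years = 25) {
  twoN <- as.integer(round(2 * N / lambda))
  demographic_model(twoN1 = rep(twoN, 2), twoN2 = c(0L, 0L),
                    mig = c(0, 0), G_split = 1L,
                    ep_g = c(0L), ep_2N = twoN,
                    lambda = lambda, generation_years = generation_years,
                    label = sprintf("constant_N%g", N), G_pergen = 0L)
}

#' Single-population demography for demographic-null testing
#'
#' The marginal history of one continental group under the out-of-Africa
#' model: used to build the neutral null distribution of site-frequency
#' statistics (e.g. Fay and Wu's H).
#'
#' @param pop `"AFR"`, `"EUR"` or `"EAS"`.
#' @inheritParams gravel_demography
#' @return A [demographic_model] with deme 2 absent.
#' @export
single_pop_demography <- function(pop = c("AFR", "EUR", "EAS"), lambda = 10,
                                  generation_years = 25) {
  pop <- match.arg(pop)
  two <- gravel_demography(if (pop == "EUR") "EUR" else "EAS",
                           lambda = lambda, generation_years = generation_years)
  G_split <- two$G_split
  if (pop == "AFR") {
    twoN1 <- two$twoN1
  } else {
    twoN1 <- two$twoN2
    twoN1[twoN1 == 0L] <- two$twoN1[twoN1 == 0L]   # ancestral sizes pre-split
  }
  demographic_model(twoN1 = twoN1, twoN2 = rep(0L, length(twoN1)),
                    mig = rep(0, length(twoN1)), G_split = 1L,
                    ep_g = two$ep_g, ep_2N = two$ep_2N,
                    lambda = lambda, generation_years = generation_years,
                    label = paste0("single_", pop), G_pergen = two$G_split)
}

#' Simulator specification
#'
#' Region geometry, mutation and recombination rates, sample sizes and the
#' rescaling factor for forward simulation. Defaults: a 12 kb region with the
#' focal site at 8 kb (leaving >= 6 kb upstream and >= 2 kb downstream for the
#' 8 kb window), mutation rate 2.36e-8 per bp per generation, constant
#' recombination 1.76 cM/Mb, 100 sampled haplotypes per deme, lambda = 10.
#'
#' @param region_length region length in bp.
#' @param focal_pos position of the focal site in bp (0-based).
#' @param mu per-bp per-generation mutation rate.
#' @param rec_cM_Mb recombination rate in cM/Mb.
#' @param n_sample haplotypes sampled per deme (length-2 integer).
#' @param lambda rescaling factor (must match the demography's).
#' @return An object of class `simulator_spec`.
#' @export
simulator_spec <- function(region_length = 12000, focal_pos = 8000,
                           mu = 2.36e-8, rec_cM_Mb = 1.76,
                           n_sample = c(100, 100), lambda = 10) {
  if (mu < 0 || lambda <= 0) stop("mu must be >= 0 and lambda > 0")
  if (focal_pos <= 0 || focal_pos >= region_length)
    stop("focal position must lie inside the region")
  if (focal_pos < 6000 || region_length - focal_pos < 2000)
    warning("region does not accommodate the default 8 kb asymmetric window")
  structure(list(region_length = region_length, focal_pos = focal_pos,
                 mu = mu, rec_cM_Mb = rec_cM_Mb,
                 rec = rec_cM_Mb * 1e-8,
                 n_sample = as.integer(n_sample), lambda = lambda),
            class = "simulator_spec")
}
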