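#' Deterministic Wright-Fisher selection update
#'
#' One generation of deterministic change of the derived-allele frequency
#' under genotype fitnesses 1 : 1+hs : 1+s:
#' p' = (p^2 (1+s) + p(1-p)(1+hs)) / w-bar.
#'
#' @param p current derived-allele frequency.
#' @param s selection coefficient of the derived homozygote.
#' @param h dominance coefficient.
#' @return The post-selection frequency (before migration and drift).
#' @export
wf_deterministic_update <- function(p, s, h = 0.5) {
  vapply(p, cpp_wf_update, numeric(1), s = s, h = h)
}

#' Unconditioned single-deme Wright-Fisher run to absorption
#'
#' Runs binomial drift with selection from `k0` copies in a constant
#' population of `2N` gene copies for at most `generations` generations and
#' returns the final copy count. Used for closed-form checks (neutral
#' fixation probability 1/(2N), the martingale property of neutral drift).
#'
#' @param N diploid population size (no rescaling applied).
#' @param s,h selection and dominance coefficients.
#' @param k0 initial derived copy count.
#' @param generations maximum number of generations.
#' @return Final derived copy count (0 and 2N are absorbing).
#' @export
wf_absorption_run <- function(N, s = 0, h = 0.5, k0 = 1, generations = 100000L) {
  cpp_wf_absorb(as.integer(2 * N), s, h, as.integer(k0),
                as.integer(generations))
}

#' Simulate a derived-allele frequency trajectory
#'
#' Per-generation Wright-Fisher update (deterministic selection with genotype
#' fitnesses 1 : 1+hs : 1+s, then symmetric migration at rate m, then binomial
#' drift with the epoch's 2N), in rescaled units (selection coefficients are
#' rescaled exactly, (1+s)^lambda - 1, preserving the per-step growth
#' factor). SDN starts from one new copy at t_mut: in the ancestral deme if
#' t_mut predates the split, otherwise one copy in each deme (the per-deme
#' onset-state convention of trajectory-conditioned simulators; the
#' post-split case is flagged in the returned object). NTR is identical with
#' s = 0. SSV imposes the standing frequency f0 in each deme at t_mut and
#' applies s_NA in the non-African deme only; pastward of the onset the
#' standing variant has no modelled origin (its carriers' ancestry is
#' unconstrained, so sweeps from standing variation are genuinely soft).
#' With `condition = "segregating"` trajectories are rejection-resampled
#' until the final state segregates in both demes.
#'
#' @param scenario a [selection_scenario].
#' @param demography a [demographic_model].
#' @param condition `"segregating"` (default) or `"none"` (single
#'   unconditioned forward pass; no rejection).
#' @param max_attempts rejection cap; exceeding it is an error reporting the
#'   acceptance rate.
#' @return An object of class `trajectory`: per-generation derived copy
#'   counts and frequencies in each deme (index 1 = present), the origin
#'   generation, and the number of attempts used.
#' @export
simulate_trajectory <- function(scenario, demography,
                                condition = c("segregating", "none"),
                                max_attempts = 1e6) {
  condition <- match.arg(condition)
  stopifnot(inherits(scenario, "selection_scenario"),
            inherits(demography, "demographic_model"))
  lam <- demography$lambda
  g_mut <- max(1L, as.integer(round(
    scenario$t_mut / demography$generation_years / lam)))
  model_code <- match(scenario$model, c("NTR", "SDN", "SSV")) - 1L
  if (condition == "none")
    return(trajectory_unconditioned(scenario, demography, g_mut))
  res <- cpp_wf_trajectory(model_code, g_mut,
                           ifelse(is.na(scenario$f0), 0, scenario$f0),
                           rescale_selection(scenario$s_A, lam),
                           rescale_selection(scenario$s_NA, lam),
                           scenario$h,
                           demography$twoN1, demography$twoN2,
                           demography$mig, demography$G_split,
                           as.integer(max_attempts), 0L)
  if (!isTRUE(res$accepted))
    stop(sprintf(
      "conditioning failed after %d attempts (acceptance rate < %.2g)",
      res$attempts, 1 / res$attempts))
  out <- new_trajectory(res$K1, res$K2, res$origin, res$attempts, demography)
  if (scenario$model != "SSV" && g_mut < demography$G_split)
    attr(out, "postsplit_onset") <- TRUE
  out
}

# one rescaled generation stands for lambda real generations: preserve the
# lambda-generation growth factor of the selected genotype
rescale_selection <- function(s, lambda) (1 + s)^lambda - 1

new_trajectory <- function(K1, K2, origin, attempts, demography) {
  len <- length(K1)
  gi <- pmin(seq_len(len), length(demography$twoN1))
  n1 <- demography$twoN1[gi]
  n2 <- demography$twoN2[gi]
  f1 <- K1 / n1
  f2 <- ifelse(n2 > 0, K2 / pmax(n2, 1L), NA_real_)
  structure(list(K1 = K1, K2 = K2, freq1 = f1, freq2 = f2,
                 origin = origin, attempts = attempts,
                 G_split = demography$G_split, lambda = demography$lambda),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "trajectory: origin %d rescaled generations ago; final frequencies %.3f / %s; %d attempt(s)\n",
    x$origin, x$freq1[1],
    ifelse(is.na(x$freq2[1]), "-", sprintf("%.3f", x$freq2[1])), x$attempts))
  invisible(x)
}

# single unconditioned forward pass in plain R (same update order as the
# C++ path: selection, migration, drift); also serves as a readable
# specification of the forward model
trajectory_unconditioned <- function(scenario, demography, g_mut) {
  d <- demography
  len <- length(d$twoN1)
  at <- function(v, g) v[min(g + 1L, len)]
  K1 <- integer(g_mut + 1); K2 <- integer(g_mut + 1)
  lam <- d$lambda
  sA <- rescale_selection(scenario$s_A, lam)
  sNA <- rescale_selection(scenario$s_NA, lam)
  h <- scenario$h
  if (scenario$model == "SSV") {
    K1[g_mut + 1] <- max(1L, round(at(d$twoN1, g_mut) * scenario$f0))
    if (g_mut < d$G_split)
      K2[g_mut + 1] <- max(1L, round(at(d$twoN2, g_mut) * scenario$f0))
    sA <- 0
  } else {
    K1[g_mut + 1] <- 1L
    if (g_mut < d$G_split) K2[g_mut + 1] <- 1L
  }
  for (g in g_mut:1) {
    if (g - 1 >= d$G_split) {
      p <- K1[g + 1] / at(d$twoN1, g)
      pp <- cpp_wf_update(p, if (scenario$model == "SDN") sA else 0, h)
      K1[g] <- rbinom(1, at(d$twoN1, g - 1), pp)
    } else if (g >= d$G_split) {
      p <- K1[g + 1] / at(d$twoN1, g)
      pp <- cpp_wf_update(p, if (scenario$model == "SDN") sA else 0, h)
      K1[g] <- rbinom(1, at(d$twoN1, g - 1), pp)
      K2[g] <- rbinom(1, at(d$twoN2, g - 1), pp)
    } else {
      p1 <- K1[g + 1] / at(d$twoN1, g)
      p2 <- K2[g + 1] / at(d$twoN2, g)
      p1s <- cpp_wf_update(p1, if (scenario$model == "SSV") 0 else sA, h)
      p2s <- cpp_wf_update(p2, sNA, h)
      m <- at(d$mig, g)
      K1[g] <- rbinom(1, at(d$twoN1, g - 1), (1 - m) * p1s + m * p2s)
      K2[g] <- rbinom(1, at(d$twoN2, g - 1), (1 - m) * p2s + m * p1s)
    }
  }
  new_trajectory(K1, K2, g_mut, 1L, demography)
}
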