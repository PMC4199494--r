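#' Simulate a two-population haplotype sample conditional on a trajectory
#'
#' Linked neutral variation over the region is generated by a structured
#' coalescent conditioned on the focal-allele frequency trajectory: sampled
#' lineages are labelled by deme and by allelic class at the focal site,
#' coalesce within class at rate set by the per-generation class copy
#' numbers, recombine between focal site and flanking material (re-assigning
#' the flanking class by the current class frequencies), and migrate between
#' demes; neutral mutations accumulate under the infinite-sites model at rate
#' mu per bp. The focal column itself is set from the sampled allelic
#' classes, drawn binomially from the trajectory's final deme frequencies
#' (redrawn if the pooled sample would be monomorphic); it receives no
#' mutation of its own.
#'
#' @param trajectory a [trajectory] from [simulate_trajectory()].
#' @param demography the [demographic_model] the trajectory was simulated
#'   under.
#' @param spec a [simulator_spec].
#' @return A [haplotype_sample] with populations `"AFR"` and `"nonAFR"` and
#'   `focal_index` set.
#' @export
simulate_haplotypes <- function(trajectory, demography, spec) {
  stopifnot(inherits(trajectory, "trajectory"),
            inherits(demography, "demographic_model"),
            inherits(spec, "simulator_spec"))
  n1 <- spec$n_sample[1]; n2 <- spec$n_sample[2]
  p1 <- trajectory$freq1[1]; p2 <- trajectory$freq2[1]
  for (i in 1:10000) {
    cls <- c(rbinom(n1, 1, p1), rbinom(n2, 1, p2))
    if (sum(cls) > 0 && sum(cls) < n1 + n2) break
    if (i == 10000) stop("could not draw a biallelic focal sample")
  }
  lam <- demography$lambda
  res <- cpp_coalescent(n1, n2, spec$region_length, spec$focal_pos,
                        as.integer(cls), spec$mu * lam, spec$rec * lam,
                        trajectory$K1, trajectory$K2,
                        demography$twoN1, demography$twoN2, demography$mig,
                        demography$G_split, demography$G_pergen,
                        demography$ep_g, demography$ep_2N)
  assemble_sample(res, cls, n1, n2, spec)
}

assemble_sample <- function(res, cls, n1, n2, spec) {
  pos <- res$positions
  mat <- res$matrix
  keep <- !duplicated(pos)            # infinite-sites: ties have measure zero
  pos <- pos[keep]; mat <- mat[, keep, drop = FALSE]
  at <- findInterval(spec$focal_pos, pos)
  pos <- append(pos, spec$focal_pos, after = at)
  mat <- cbind(mat[, seq_len(at), drop = FALSE], cls,
               if (at < ncol(mat)) mat[, (at + 1):ncol(mat), drop = FALSE])
  colnames(mat) <- NULL
  labels <- c(rep("AFR", n1), rep("nonAFR", n2))
  haplotype_sample(mat, pos, labels, focal_index = at + 1L,
                   region_length = spec$region_length)
}

#' Simulate a batch of conditioned simulations with summary statistics
#'
#' Draws scenario parameters from the model's uniform prior, simulates the
#' allele-frequency trajectory, and keeps the draw only if the derived allele
#' segregates in both demes at present (redrawing the parameters otherwise,
#' so that the effective, post-conditioning prior is the one the rejection
#' step sees). Each accepted trajectory is expanded into a haplotype sample
#' and summarised. The overall acceptance rate of parameter draws and the
#' count of flagged (sentinel-containing) rows are attached as attributes.
#'
#' @param model `"NTR"`, `"SDN"` or `"SSV"`.
#' @param n_sims number of accepted simulations to produce.
#' @param demography a [demographic_model].
#' @param spec a [simulator_spec].
#' @param registry statistic registry, see [default_registry()].
#' @param h dominance coefficient for all draws.
#' @param map [genetic_map]; defaults to the spec's constant-rate map.
#' @param max_attempts cap on total parameter draws per accepted simulation.
#' @param checkpoint_path if non-NULL, a path prefix: every
#'   `checkpoint_every` accepted rows the partial table is written to
#'   `<prefix>.tsv` with a JSON sidecar recording progress and RNG state, and
#'   an interrupted run restarted with the same arguments resumes from it.
#' @param checkpoint_every rows between checkpoints.
#' @return A data.frame with the scenario parameters and one column per
#'   registry statistic; attributes `acceptance_rate`, `attempts` and
#'   `n_flagged`.
#' @export
simulate_batch <- function(model, n_sims, demography, spec,
                           registry = default_registry(), h = 0.5,
                           map = NULL, max_attempts = 1e6,
                           checkpoint_path = NULL, checkpoint_every = 1000) {
  stopifnot(n_sims >= 1)
  if (is.null(map)) map <- constant_map(spec$rec_cM_Mb, spec$region_length)
  lam <- demography$lambda
  model_code <- match(model, c("NTR", "SDN", "SSV")) - 1L
  rows <- vector("list", n_sims)
  pars <- vector("list", n_sims)
  start <- 1L; attempts_total <- 0
  if (!is.null(checkpoint_path) && file.exists(paste0(checkpoint_path, ".json"))) {
    ck <- jsonlite::read_json(paste0(checkpoint_path, ".json"),
                              simplifyVector = TRUE)
    done <- ck$rows_done
    tab <- read_result_tsv(paste0(checkpoint_path, ".tsv"))
    if (nrow(tab) >= done && done > 0) {
      for (i in seq_len(done)) {
        pars[[i]] <- tab[i, c("model", "s_A", "s_NA", "t_mut", "f0", "h")]
        rows[[i]] <- unlist(tab[i, setdiff(colnames(tab),
                                           c("model", "s_A", "s_NA", "t_mut", "f0", "h"))])
      }
      start <- done + 1L
      attempts_total <- ck$attempts
      assign(".Random.seed", as.integer(ck$rng_state), envir = globalenv())
      message("resuming batch from checkpoint at row ", done)
    }
  }
  b <- prior_bounds(model)
  rng <- function(nm) if (is.null(b[[nm]])) c(0, 0) else b[[nm]]
  for (i in seq(start, length.out = n_sims - start + 1L)) {
    res <- cpp_draw_conditioned(model_code, h, rng("t_mut"), rng("s_A"),
                                rng("s_NA"), rng("f0"),
                                demography$generation_years, lam,
                                demography$twoN1, demography$twoN2,
                                demography$mig, demography$G_split,
                                as.integer(max_attempts), 0L)
    if (!isTRUE(res$accepted))
      stop(sprintf("conditioning failed for %s after %d draws (acceptance rate < %.2g)",
                   model, max_attempts, 1 / max_attempts))
    attempts_total <- attempts_total + res$attempts
    traj <- new_trajectory(res$K1, res$K2, res$origin, res$attempts, demography)
    smp <- simulate_haplotypes(traj, demography, spec)
    sv <- compute_summary_vector(smp, registry, map)
    pars[[i]] <- data.frame(model = model, s_A = res$s_A, s_NA = res$s_NA,
                            t_mut = res$t_mut, f0 = res$f0, h = h,
                            stringsAsFactors = FALSE)
    rows[[i]] <- as.numeric(sv)
    if (!is.null(checkpoint_path) && i %% checkpoint_every == 0) {
      part <- batch_table(pars[seq_len(i)], rows[seq_len(i)], registry)
      write_result_tsv(part, paste0(checkpoint_path, ".tsv"))
      jsonlite::write_json(list(rows_done = i, attempts = attempts_total,
                                rng_state = get(".Random.seed",
                                                envir = globalenv())),
                           paste0(checkpoint_path, ".json"),
                           auto_unbox = TRUE)
    }
  }
  out <- batch_table(pars, rows, registry)
  attr(out, "acceptance_rate") <- n_sims / attempts_total
  attr(out, "attempts") <- attempts_total
  attr(out, "n_flagged") <- sum(!complete.cases(
    out[, setdiff(colnames(out), c("model", "f0")), drop = FALSE]))
  out
}

batch_table <- function(pars, rows, registry) {
  par_df <- do.call(rbind, pars)
  stat_mat <- do.call(rbind, rows)
  colnames(stat_mat) <- registry
  cbind(par_df, as.data.frame(stat_mat), stringsAsFactors = FALSE)
}

#' Neutral null distribution of a site-frequency statistic
#'
#' Simulates `n` neutral replicates of the focal region under a
#' single-population demographic model and returns the distribution of the
#' chosen statistic over the whole region, for use as a demographic null in
#' [empirical_pvalue()] (lower tail for Fay and Wu's H).
#'
#' @param demography a single-population [demographic_model], e.g. from
#'   [single_pop_demography()].
#' @param spec a [simulator_spec]; `n_sample[1]` haplotypes are drawn.
#' @param n number of replicates.
#' @param statistic function(sample, window, pop) -> value; default
#'   [fay_wu_h()].
#' @param tail which tail of the distribution is extreme under the
#'   alternative.
#' @return A [score_distribution].
#' @export
neutral_null_sims <- function(demography, spec, n = 10000,
                              statistic = fay_wu_h, tail = "lower") {
  vals <- numeric(n)
  wr <- window_spec("whole_region")
  for (i in seq_len(n)) {
    smp <- simulate_neutral_sample(demography, spec)
    vals[i] <- tryCatch(statistic(smp, wr, "P1"),
                        sweepabc_undefined = function(e) NA_real_)
  }
  score_distribution(vals[!is.na(vals)], tail = tail)
}

#' Simulate one neutral (unconditioned) haplotype sample
#'
#' Plain neutral coalescent under the given demography; no focal site.
#' With a two-deme demography both demes are sampled.
#'
#' @inheritParams neutral_null_sims
#' @return A [haplotype_sample] without a focal site.
#' @export
simulate_neutral_sample <- function(demography, spec) {
  lam <- demography$lambda
  single <- all(demography$twoN2 == 0L)
  n1 <- spec$n_sample[1]
  n2 <- if (single) 0L else spec$n_sample[2]
  res <- cpp_coalescent(n1, n2, spec$region_length, -1,
                        integer(n1 + n2), spec$mu * lam, spec$rec * lam,
                        integer(0), integer(0),
                        demography$twoN1, demography$twoN2, demography$mig,
                        demography$G_split, demography$G_pergen,
                        demography$ep_g, demography$ep_2N)
  pos <- res$positions
  keep <- !duplicated(pos)
  labels <- if (single) rep("P1", n1) else c(rep("AFR", n1), rep("nonAFR", n2))
  haplotype_sample(res$matrix[, keep, drop = FALSE], pos[keep], labels,
                   focal_index = NULL, region_length = spec$region_length)
}
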