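#' Fit the two-stage ABC sweep inference to an observed summary vector
#'
#' Stage one (model choice): the observed vector is compared against all
#' simulations by rejection in a PLS-DA-reduced statistic space, giving
#' posterior probabilities and Bayes factors for NTR, SDN and SSV. Stage two
#' (parameter estimation): within the winning model (or `param_model`), a
#' regression-mode PLS is fitted with the model's parameters as response and
#' the rejection is repeated among that model's simulations only; the
#' retained parameter rows give the posterior mode and 95% credible
#' interval per parameter.
#'
#' @param observed named numeric observed summary vector (ids matching the
#'   simulation table's statistic columns; `NA` sentinels drop the affected
#'   statistic with a warning).
#' @param sim_table combined simulation table from [simulate_batch()].
#' @param retain_fraction rejection retention fraction.
#' @param n_components PLS components (both stages).
#' @param adjustment parameter-posterior adjustment, see
#'   [estimate_parameters()].
#' @param param_model model whose parameters to estimate (default: the
#'   posterior-mode model).
#' @return An object of class `sweep_abc` with model posteriors, Bayes
#'   factors, and the parameter posterior of the chosen model.
#' @export
abc_sweep <- function(observed, sim_table, retain_fraction = 0.01,
                      n_components = 7, adjustment = "none",
                      param_model = NULL) {
  cols <- stat_columns(sim_table)
  obs <- observed[cols]
  bad <- cols[is.na(obs)]
  if (length(bad) > 0)
    warning("observed vector has undefined statistic(s) removed from this run: ",
            paste(bad, collapse = ", "))
  use <- setdiff(cols, bad)
  pipe <- fit_choice_pipeline(sim_table, use, n_components)
  choice <- choice_observed(pipe, obs[use], retain_fraction)
  winner <- if (is.null(param_model)) names(which.max(choice$posterior))
            else param_model

  par_cols <- switch(winner,
                     NTR = "t_mut",
                     SDN = c("s_A", "s_NA", "t_mut"),
                     SSV = c("s_NA", "f0", "t_mut"))
  mrows <- sim_table[sim_table$model == winner, , drop = FALSE]
  mstats <- as.matrix(mrows[, use, drop = FALSE])
  ok <- complete.cases(mstats)
  mrows <- mrows[ok, , drop = FALSE]
  mstats <- mstats[ok, , drop = FALSE]
  z <- zscore_table(mstats, obs[use])
  ncomp <- min(n_components, ncol(z$z), nrow(z$z) - 1)
  pls <- fit_pls(z$z, as.matrix(mrows[, par_cols, drop = FALSE]),
                 "regression", ncomp)
  scores <- project_pls(pls, z$z)
  obs_scores <- project_pls(pls, z$obs_z)
  rej <- abc_reject(obs_scores, scores, retain_fraction)
  params <- estimate_parameters(mrows[rej$index, par_cols, drop = FALSE],
                                rej$distance, adjustment,
                                sim_scores = scores[rej$index, , drop = FALSE],
                                observed_scores = obs_scores,
                                support = prior_bounds(winner))
  structure(list(posterior = choice$posterior,
                 bayes_factors = choice$bayes_factors,
                 model = winner, parameters = params,
                 n_retained_choice = length(choice$rejection$index),
                 n_retained_params = length(rej$index),
                 retain_fraction = retain_fraction,
                 n_components = ncomp, dropped_stats = bad),
            class = "sweep_abc")
}

#' @export
print.sweep_abc <- function(x, ...) {
  cat("ABC selection-model inference\n")
  cat("model posterior probabilities:\n")
  for (m in names(x$posterior))
    cat(sprintf("  %s: %.1f%%\n", m, 100 * x$posterior[m]))
  cat(sprintf("chosen model: %s\n", x$model))
  cat("parameter posterior (mode, 95% CI):\n")
  print(x$parameters)
  invisible(x)
}

#' @export
summary.sweep_abc <- function(object, ...) {
  x <- object
  fmt <- function(nm, scale, unit) {
    p <- x$parameters[[nm]]
    if (is.null(p)) return(NULL)
    sprintf("%s: %.2f (%.2f-%.2f) %s", nm, p$mode / scale,
            p$ci[1] / scale, p$ci[2] / scale, unit)
  }
  p_next <- max(x$posterior[setdiff(names(x$posterior), x$model)])
  bf <- if (p_next > 0)
    sprintf("%.2g", x$posterior[x$model] / p_next)
  else   # next model absent from the retained set: report the floor bound
    sprintf("> %.2g", x$posterior[x$model] * x$n_retained_choice)
  cat(sprintf("P(%s) = %.1f%%; Bayes factor vs next model: %s\n",
              x$model, 100 * x$posterior[x$model], bf))
  lines <- c(fmt("t_mut", 1000, "kya"), fmt("s_A", 0.01, "%"),
             fmt("s_NA", 0.01, "%"), fmt("f0", 0.01, "%"))
  for (l in lines) cat(" ", l, "\n")
  invisible(x)
}
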