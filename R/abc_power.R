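# Cross-validation of ABC model choice on held-out pseudo-observed
# simulations, and the dominance-model comparison.

PARAM_COLS <- c("model", "s_A", "s_NA", "t_mut", "f0", "h")

#' Statistic columns of a simulation table
#'
#' The columns of a [simulate_batch()] table that belong to the summary
#' registry (everything except the scenario parameters).
#'
#' @param sim_table a simulation table.
#' @return Character vector of statistic column names.
#' @export
stat_columns <- function(sim_table) setdiff(colnames(sim_table), PARAM_COLS)

# downsample every label to the smallest label count so posterior shares are
# not driven by unequal simulation budgets
balance_indices <- function(labels) {
  tab <- table(labels)
  m <- min(tab)
  unlist(lapply(names(tab), function(l) {
    idx <- which(labels == l)
    if (length(idx) > m) sample(idx, m) else idx
  }), use.names = FALSE)
}

# fit the model-choice pipeline (z-score + PLS-DA + projection) on a
# training table restricted to the given statistic columns
fit_choice_pipeline <- function(train, cols, n_components) {
  stats_mat <- as.matrix(train[, cols, drop = FALSE])
  complete <- complete.cases(stats_mat)
  stats_mat <- stats_mat[complete, , drop = FALSE]
  labels <- train$model[complete]
  bal <- balance_indices(labels)
  stats_mat <- stats_mat[bal, , drop = FALSE]
  labels <- labels[bal]
  z <- zscore_table(stats_mat)
  ncomp <- min(n_components, ncol(z$z), nrow(z$z) - 1)
  pls <- fit_pls(z$z, labels, "discriminant", ncomp)
  list(z = z, pls = pls, labels = labels,
       scores = project_pls(pls, z$z),
       n_dropped = sum(!complete))
}

choice_observed <- function(pipe, obs, retain_fraction) {
  obs_z <- (as.numeric(obs[colnames(pipe$z$z)]) - pipe$z$center) / pipe$z$scale
  names(obs_z) <- colnames(pipe$z$z)
  rej <- abc_reject(project_pls(pipe$pls, obs_z), pipe$scores, retain_fraction)
  mp <- model_posterior(pipe$labels[rej$index],
                        models = sort(unique(pipe$labels)))
  list(posterior = mp$posterior, bayes_factors = mp$bayes_factors,
       rejection = rej)
}

#' Cross-validate the power of ABC model choice
#'
#' Holds out `n_pseudo` simulations per model as pseudo-observed datasets,
#' fits the model-choice pipeline (z-scoring, PLS-DA reduction, rejection)
#' on the remaining simulations with balanced per-model training counts, and
#' assigns each pseudo-observed dataset to the model with the highest
#' posterior probability. Pseudo-observed rows containing undefined
#' (sentinel) statistics are handled by refitting the pipeline without the
#' affected statistics for that sentinel pattern; training rows with
#' sentinels on the used columns are dropped and counted.
#'
#' @param sim_table simulation table from [simulate_batch()] (rows of all
#'   models combined).
#' @param n_pseudo pseudo-observed datasets held out per model.
#' @param retain_fraction rejection retention fraction.
#' @param n_components PLS components.
#' @return An object of class `sweep_power`: confusion matrix, per-model
#'   correct-assignment rates with binomial standard errors, counts.
#' @export
cross_validate_power <- function(sim_table, n_pseudo, retain_fraction = 0.01,
                                 n_components = 7) {
  models <- sort(unique(sim_table$model))
  cols <- stat_columns(sim_table)
  avail <- table(sim_table$model)
  if (any(avail[models] <= n_pseudo))
    stop("n_pseudo exceeds the available rows for some model")
  pseudo_idx <- unlist(lapply(models, function(m)
    sample(which(sim_table$model == m), n_pseudo)), use.names = FALSE)
  train <- sim_table[-pseudo_idx, , drop = FALSE]
  pseudo <- sim_table[pseudo_idx, , drop = FALSE]

  pstats <- as.matrix(pseudo[, cols, drop = FALSE])
  pattern <- apply(is.na(pstats), 1, function(r) paste(cols[r], collapse = ","))
  assigned <- character(nrow(pseudo))
  dropped_training <- 0L
  for (pat in unique(pattern)) {
    bad <- if (nzchar(pat)) strsplit(pat, ",")[[1]] else character(0)
    use <- setdiff(cols, bad)
    if (length(use) == 0) { assigned[pattern == pat] <- NA_character_; next }
    pipe <- fit_choice_pipeline(train, use, n_components)
    dropped_training <- max(dropped_training, pipe$n_dropped)
    for (i in which(pattern == pat)) {
      res <- choice_observed(pipe, pstats[i, use], retain_fraction)
      top <- which(res$posterior == max(res$posterior))
      if (length(top) > 1) top <- sample(top, 1)   # break posterior ties fairly
      assigned[i] <- names(res$posterior)[top]
    }
  }
  confusion <- table(true = pseudo$model,
                     assigned = factor(assigned, levels = models))
  rates <- diag(prop.table(confusion, 1))
  se <- sqrt(rates * (1 - rates) / rowSums(confusion))
  structure(list(confusion = confusion, rates = rates, se = se,
                 n_pseudo = n_pseudo, retain_fraction = retain_fraction,
                 n_components = n_components,
                 n_dropped_training = dropped_training),
            class = "sweep_power")
}

#' @export
print.sweep_power <- function(x, ...) {
  cat("ABC model-choice cross-validation (", x$n_pseudo,
      " pseudo-observed per model)\n", sep = "")
  print(x$confusion)
  cat("correct-assignment rates (binomial SE):\n")
  for (m in names(x$rates))
    cat(sprintf("  %s: %.1f%% (%.1f%%)\n", m, 100 * x$rates[m], 100 * x$se[m]))
  invisible(x)
}

#' Dominance-model comparison by joint ABC model choice
#'
#' Runs one rejection-ABC model choice over all seven categories (NTR plus
#' SDN and SSV under each dominance coefficient h in \{0, 0.38, 0.5\}) and
#' reports the joint posterior, the dominance marginal (summing SDN and SSV
#' within each h, NTR kept separate), and the selection-model marginal
#' within each dominance model.
#'
#' @param tables named list of simulation tables (each from
#'   [simulate_batch()] run at one dominance setting); jointly they must
#'   cover NTR and both selection models under h = 0, 0.38 and 0.5.
#' @param observed named numeric observed summary vector.
#' @param retain_fraction,n_components rejection and PLS settings.
#' @return List with `joint`, `dominance_marginal`, `selection_within`.
#' @export
dominance_model_choice <- function(tables, observed, retain_fraction = 0.01,
                                   n_components = 7) {
  all_tab <- do.call(rbind, c(tables, list(make.row.names = FALSE)))
  cat_label <- ifelse(all_tab$model == "NTR", "NTR",
                      sprintf("%s_h%g", all_tab$model, all_tab$h))
  need <- c("NTR", as.vector(outer(c("SDN", "SSV"), c(0, 0.38, 0.5),
                                   function(m, h) sprintf("%s_h%g", m, h))))
  missing_cat <- setdiff(need, unique(cat_label))
  if (length(missing_cat) > 0)
    stop("missing dominance/selection categories: ",
         paste(missing_cat, collapse = ", "))
  tab <- all_tab
  tab$model <- cat_label
  cols <- stat_columns(tab)
  obs <- observed[cols]
  bad <- cols[is.na(obs)]
  use <- setdiff(cols, bad)
  pipe <- fit_choice_pipeline(tab, use, n_components)
  res <- choice_observed(pipe, obs[use], retain_fraction)
  joint <- res$posterior
  hs <- c(0, 0.38, 0.5)
  dom <- vapply(hs, function(h)
    sum(joint[sprintf(c("SDN_h%g", "SSV_h%g"), h)]), numeric(1))
  names(dom) <- sprintf("h%g", hs)
  dom <- c(dom, NTR = unname(joint["NTR"]))
  sel <- vapply(hs, function(h) {
    p <- joint[sprintf(c("SDN_h%g", "SSV_h%g"), h)]
    if (sum(p) == 0) return(c(NA_real_, NA_real_))   # no mass in this stratum
    p / sum(p)
  }, numeric(2))
  dimnames(sel) <- list(c("SDN", "SSV"), sprintf("h%g", hs))
  list(joint = joint, dominance_marginal = dom, selection_within = sel,
       bayes_factors = res$bayes_factors)
}
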