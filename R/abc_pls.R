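# Summary-statistic standardization and PLS reduction. The distances of the
# rejection step are computed in a low-dimensional PLS score space:
# discriminant mode (dummy-coded model labels as response) for model choice,
# regression mode (parameter columns as response) for parameter estimation.

#' Z-score a simulation table and transform the observed vector with it
#'
#' Columns are standardized to mean 0, sd 1 across simulations; the observed
#' vector is transformed with the same constants. Constant columns are
#' dropped with a warning (they carry no distance information). The
#' transform is invertible via the returned constants.
#'
#' @param sim_stats numeric matrix/data.frame of simulated statistics (one
#'   row per simulation).
#' @param observed named numeric vector of observed statistics (must cover
#'   the simulation columns).
#' @return List with `z` (standardized matrix), `obs_z`, `center`, `scale`
#'   and `dropped` (names of constant columns).
#' @export
zscore_table <- function(sim_stats, observed = NULL) {
  x <- as.matrix(sim_stats)
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  keep <- scl > 0
  if (!all(keep))
    warning("dropping constant column(s): ",
            paste(colnames(x)[!keep], collapse = ", "))
  x <- x[, keep, drop = FALSE]
  z <- sweep(sweep(x, 2, ctr[keep]), 2, scl[keep], "/")
  obs_z <- NULL
  if (!is.null(observed)) {
    miss <- setdiff(colnames(x), names(observed))
    if (length(miss) > 0)
      stop("observed vector lacks column(s): ", paste(miss, collapse = ", "))
    obs_z <- (as.numeric(observed[colnames(x)]) - ctr[keep]) / scl[keep]
    names(obs_z) <- colnames(x)
  }
  list(z = z, obs_z = obs_z, center = ctr[keep], scale = scl[keep],
       dropped = names(ctr)[!keep])
}

#' Fit a PLS reduction of the summary statistics
#'
#' Partial least squares with `n_components` latent components maximizing
#' covariance with the response: model labels (dummy-coded; PLS-DA) in
#' discriminant mode, parameter columns in regression mode. Score vectors
#' are mutually orthogonal on the training data.
#'
#' @param table numeric matrix of (standardized) statistics, one simulation
#'   per row.
#' @param response factor/character of model labels (discriminant mode) or a
#'   numeric matrix of parameters (regression mode).
#' @param mode `"discriminant"` or `"regression"`.
#' @param n_components number of latent components (default 7).
#' @return An object of class `pls_model`.
#' @export
fit_pls <- function(table, response, mode = c("discriminant", "regression"),
                    n_components = 7) {
  mode <- match.arg(mode)
  x <- as.matrix(table)
  if (is.null(colnames(x))) colnames(x) <- paste0("s", seq_len(ncol(x)))
  if (n_components > min(ncol(x), nrow(x) - 1))
    stop("n_components exceeds the rank of the statistic table")
  if (mode == "discriminant") {
    f <- factor(response)
    if (nlevels(f) < 2) stop("discriminant mode needs >= 2 classes")
    y <- stats::model.matrix(~ f - 1)
    colnames(y) <- levels(f)
  } else {
    y <- as.matrix(response)
    if (is.null(colnames(y))) colnames(y) <- paste0("y", seq_len(ncol(y)))
  }
  fit <- mixOmics::pls(x, y, ncomp = n_components, scale = FALSE,
                       mode = "regression")
  structure(list(fit = fit, mode = mode, n_components = n_components,
                 columns = colnames(x)),
            class = "pls_model")
}

#' Project rows into the PLS component space
#'
#' @param model a `pls_model` from [fit_pls()].
#' @param rows numeric matrix (or single named vector) on the same statistic
#'   columns, standardized with the same constants as the training table.
#' @return Matrix of component scores, one row per input row.
#' @export
project_pls <- function(model, rows) {
  if (is.null(dim(rows))) rows <- matrix(rows, nrow = 1,
                                         dimnames = list(NULL, names(rows)))
  rows <- as.matrix(rows)[, model$columns, drop = FALSE]
  unname(predict(model$fit, rows)$variates)
}
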