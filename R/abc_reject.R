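# Rejection ABC: retain the simulations closest to the observed summary in
# the reduced statistic space; model posteriors are retained-set shares and
# parameter posteriors come from the retained parameter rows.

#' Rejection step: retain the closest simulations
#'
#' Euclidean distances between the observed score vector and every simulated
#' score row; the `ceiling(retain_fraction * n)` smallest distances are
#' retained, with ties at the cutoff all kept.
#'
#' @param observed_scores numeric vector of observed component scores.
#' @param sim_scores numeric matrix of simulated component scores.
#' @param retain_fraction fraction of simulations to retain, in (0, 1].
#' @return List with `index` (retained row indices) and `distance`.
#' @export
abc_reject <- function(observed_scores, sim_scores, retain_fraction = 0.01) {
  sim_scores <- as.matrix(sim_scores)
  if (nrow(sim_scores) == 0) stop("empty simulation table")
  if (retain_fraction <= 0 || retain_fraction > 1)
    stop("retain_fraction must be in (0, 1]")
  d <- sqrt(colSums((t(sim_scores) - as.numeric(observed_scores))^2))
  m <- ceiling(retain_fraction * length(d))
  cutoff <- sort(d, partial = m)[m]
  idx <- which(d <= cutoff)
  list(index = idx, distance = d[idx])
}

#' Model posterior probabilities and Bayes factors from a retained set
#'
#' P(model) is the (training-count adjusted) share of the model among the
#' retained simulations; with balanced training sets this is the plain
#' retained share. Bayes factors are posterior-probability ratios under
#' equal model priors. Models absent from the retained set get posterior 0
#' with the resolution floor `1/n_retained` attached as a bound
#' (`attr(., "floor")`); Bayes factors against them are reported at the
#' floor bound.
#'
#' @param retained_labels model labels of the retained simulations.
#' @param training_counts named vector of per-model training-set sizes (for
#'   the unequal-budget adjustment); `NULL` assumes balanced sets.
#' @param models the full model set (training labels by default); a model
#'   absent from training is excluded with a warning.
#' @return List with `posterior` (named, sums to 1), `bayes_factors`
#'   (matrix), `n_retained`.
#' @export
model_posterior <- function(retained_labels, training_counts = NULL,
                            models = NULL) {
  if (length(retained_labels) == 0) stop("empty retained set")
  if (is.null(models)) models <- sort(unique(retained_labels))
  if (!is.null(training_counts)) {
    absent <- models[!(models %in% names(training_counts)) |
                       training_counts[models] %in% c(0, NA)]
    if (length(absent) > 0) {
      warning("model(s) absent from training excluded: ",
              paste(absent, collapse = ", "))
      models <- setdiff(models, absent)
    }
  }
  k <- table(factor(retained_labels, levels = models))
  w <- if (is.null(training_counts)) rep(1, length(models))
       else 1 / training_counts[models]
  post <- as.numeric(k) * w / sum(as.numeric(k) * w)
  names(post) <- models
  bf <- outer(post, post, function(a, b) a / b)
  dimnames(bf) <- list(models, models)
  structure(list(posterior = post, bayes_factors = bf,
                 n_retained = length(retained_labels)),
            floor = 1 / length(retained_labels))
}

#' Posterior mode and 95% credible interval per parameter
#'
#' The posterior sample is the retained parameter rows (optionally
#' local-linear regression adjusted toward the observed scores, Beaumont
#' style, with Epanechnikov distance weights). The mode is the maximum of a
#' Gaussian kernel density (Silverman's rule bandwidth) and the credible
#' interval the 2.5%/97.5% quantiles; adjusted values are clamped to the
#' prior support.
#'
#' @param params data.frame/matrix of retained parameter rows (one column
#'   per parameter).
#' @param distances rejection distances of the retained rows.
#' @param adjustment `"none"` (pure rejection) or `"loclinear"`.
#' @param sim_scores,observed_scores component scores of the retained rows
#'   and of the observation (required for `"loclinear"`).
#' @param support named list of `c(lower, upper)` prior bounds used for
#'   clamping.
#' @return An object of class `abc_param_posterior`: per-parameter list with
#'   `mode`, `ci`, `sample`; attribute `unstable` when fewer than 50 rows
#'   were retained.
#' @export
estimate_parameters <- function(params, distances, adjustment = c("none", "loclinear"),
                                sim_scores = NULL, observed_scores = NULL,
                                support = NULL) {
  adjustment <- match.arg(adjustment)
  params <- as.data.frame(params)
  unstable <- nrow(params) < 50
  if (unstable)
    warning("fewer than 50 retained rows; credible intervals are unstable")
  wts <- rep(1, nrow(params))
  if (adjustment == "loclinear") {
    if (is.null(sim_scores) || is.null(observed_scores))
      stop("loclinear adjustment needs sim_scores and observed_scores")
    dmax <- max(distances) * (1 + 1e-12)
    wts <- 1 - (distances / dmax)^2               # Epanechnikov kernel
    X <- sweep(as.matrix(sim_scores), 2, as.numeric(observed_scores))
    for (j in seq_len(ncol(params))) {
      fitj <- stats::lm.wfit(cbind(1, X), params[[j]], wts)
      params[[j]] <- fitj$coefficients[1] + fitj$residuals
    }
  }
  out <- lapply(names(params), function(nm) {
    v <- params[[nm]]
    if (!is.null(support) && nm %in% names(support))
      v <- pmin(pmax(v, support[[nm]][1]), support[[nm]][2])
    if (length(unique(v)) == 1) {
      mode <- v[1]; ci <- c(v[1], v[1])
    } else {
      dens <- density(v, bw = stats::bw.nrd0(v), weights = wts / sum(wts))
      mode <- dens$x[which.max(dens$y)]
      if (!is.null(support) && nm %in% names(support))
        mode <- min(max(mode, support[[nm]][1]), support[[nm]][2])
      ci <- unname(quantile_weighted(v, c(0.025, 0.975), wts))
    }
    list(mode = mode, ci = ci, sample = v)
  })
  names(out) <- names(params)
  structure(out, unstable = unstable, class = "abc_param_posterior")
}

quantile_weighted <- function(x, probs, w = rep(1, length(x))) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

#' @export
print.abc_param_posterior <- function(x, digits = 3, ...) {
  for (nm in names(x))
    cat(sprintf("  %-8s mode %s (%s-%s)\n", nm,
                format(x[[nm]]$mode, digits = digits),
                format(x[[nm]]$ci[1], digits = digits),
                format(x[[nm]]$ci[2], digits = digits)))
  invisible(x)
}
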