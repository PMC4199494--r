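#' Prior bounds for the selection scenarios
#'
#' Uniform prior ranges used for scenario draws: SDN (selection on a de novo
#' mutation): s_A ~ U(0, 1.5%), s_NA ~ U(0.5%, 5%), t_mut ~ U(40, 70) kya;
#' SSV (selection on standing variation): s_NA ~ U(0, 5%], f0 ~ U(0, 20%),
#' t_mut ~ U(21, 51) kya; NTR (neutral): appearance time t ~ U(40, 70) kya.
#'
#' @param model `"NTR"`, `"SDN"` or `"SSV"`.
#' @return Named list of `c(lower, upper)` bounds for the model's parameters
#'   (selection coefficients as fractions, times in years before present).
#' @export
prior_bounds <- function(model = c("NTR", "SDN", "SSV")) {
  model <- match.arg(model)
  switch(model,
    NTR = list(t_mut = c(40000, 70000)),
    SDN = list(s_A = c(0, 0.015), s_NA = c(0.005, 0.05),
               t_mut = c(40000, 70000)),
    SSV = list(s_NA = c(0, 0.05), f0 = c(0, 0.20), t_mut = c(21000, 51000)))
}

#' One draw of the selection-scenario parameter vector
#'
#' @param model `"NTR"`, `"SDN"` or `"SSV"`.
#' @param s_A selection coefficient of the derived allele in the African deme.
#' @param s_NA selection coefficient in the non-African deme.
#' @param t_mut time in years before present at which the mutation appears
#'   (NTR/SDN) or becomes beneficial (SSV).
#' @param f0 standing frequency at selection onset (SSV only).
#' @param h dominance coefficient (0 recessive, 0.38 supra-additive,
#'   0.5 additive).
#' @param check validate parameters against the prior bounds.
#' @return An object of class `selection_scenario`.
#' @export
selection_scenario <- function(model, s_A = 0, s_NA = 0, t_mut, f0 = NA_real_,
                               h = 0.5, check = TRUE) {
  model <- match.arg(model, c("NTR", "SDN", "SSV"))
  if (check) {
    b <- prior_bounds(model)
    chk <- function(name, val) {
      if (val < b[[name]][1] - 1e-12 || val > b[[name]][2] + 1e-12)
        stop(sprintf("%s = %g outside the %s prior [%g, %g]",
                     name, val, model, b[[name]][1], b[[name]][2]))
    }
    chk("t_mut", t_mut)
    if (model == "SDN") { chk("s_A", s_A); chk("s_NA", s_NA) }
    if (model == "SSV") { chk("s_NA", s_NA); chk("f0", f0) }
  }
  if (model == "SSV" && is.na(f0)) stop("SSV requires a standing frequency f0")
  if (model == "NTR") { s_A <- 0; s_NA <- 0 }
  if (model == "SSV") s_A <- 0
  structure(list(model = model, s_A = s_A, s_NA = s_NA, t_mut = t_mut,
                 f0 = f0, h = h),
            class = "selection_scenario")
}

#' @export
print.selection_scenario <- function(x, ...) {
  cat(sprintf("selection_scenario %s: s_A = %.4f, s_NA = %.4f, t_mut = %.0f yr, f0 = %s, h = %.2f\n",
              x$model, x$s_A, x$s_NA, x$t_mut,
              ifelse(is.na(x$f0), "-", sprintf("%.3f", x$f0)), x$h))
  invisible(x)
}

#' Draw scenarios from the uniform priors
#'
#' Raw (pre-conditioning) draws. The realized prior after conditioning on
#' present-day segregation in both demes is non-uniform and is recorded
#' empirically by [simulate_batch()].
#'
#' @param model `"NTR"`, `"SDN"` or `"SSV"`.
#' @param n number of draws.
#' @param h dominance coefficient attached to every draw.
#' @return A data.frame with columns model, s_A, s_NA, t_mut, f0, h.
#' @export
sample_prior <- function(model = c("NTR", "SDN", "SSV"), n = 1, h = 0.5) {
  model <- match.arg(model)
  b <- prior_bounds(model)
  draw <- function(name) runif(n, b[[name]][1], b[[name]][2])
  out <- data.frame(model = rep(model, n),
                    s_A = if (model == "SDN") draw("s_A") else rep(0, n),
                    s_NA = if (model == "NTR") rep(0, n) else draw("s_NA"),
                    t_mut = draw("t_mut"),
                    f0 = if (model == "SSV") draw("f0") else rep(NA_real_, n),
                    h = rep(h, n), stringsAsFactors = FALSE)
  out
}
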