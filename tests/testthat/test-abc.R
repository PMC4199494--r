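# PLS reduction, rejection ABC, posteriors, cross-validation, dominance.

test_that("z-scoring standardizes columns and transforms the observed vector", {
  set.seed(51)
  x <- matrix(rnorm(500, mean = 3, sd = 2), 100, 5,
              dimnames = list(NULL, paste0("s", 1:5)))
  obs <- colMeans(x)
  z <- zscore_table(x, obs)
  expect_true(all(abs(colMeans(z$z)) < 1e-9))
  expect_true(all(abs(apply(z$z, 2, sd) - 1) < 1e-9))
  expect_true(all(abs(z$obs_z) < 1e-9))          # observed at column means
  # invertible: de-standardizing recovers the inputs
  back <- sweep(sweep(z$z, 2, z$scale, "*"), 2, z$center, "+")
  expect_equal(back, x, ignore_attr = TRUE)
  # constant columns are dropped with a warning
  x2 <- cbind(x, konst = 1)
  expect_warning(z2 <- zscore_table(x2, c(obs, konst = 1)), "konst")
  expect_false("konst" %in% colnames(z2$z))
  expect_error(zscore_table(x, obs[-1]), "lacks")
})

test_that("PLS-DA separates separable classes and matches a NIPALS oracle", {
  set.seed(53)
  n <- 120
  cls <- rep(c("A", "B"), each = n / 2)
  x <- cbind(rnorm(n, ifelse(cls == "A", -4, 4)), rnorm(n))
  colnames(x) <- c("s1", "s2")
  fit <- fit_pls(x, cls, "discriminant", n_components = 2)
  sc <- project_pls(fit, x)
  mA <- mean(sc[cls == "A", 1]); mB <- mean(sc[cls == "B", 1])
  pooled <- sqrt((var(sc[cls == "A", 1]) + var(sc[cls == "B", 1])) / 2)
  expect_gt(abs(mA - mB) / pooled, 5)
  # training-score orthogonality
  g <- crossprod(sc)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  # component scores match an independent NIPALS implementation up to sign
  y <- stats::model.matrix(~ factor(cls) - 1)
  orc <- nipals_pls(x, y, 2)
  for (a in 1:2)
    expect_gt(abs(cor(sc[, a], orc$scores[, a])), 1 - 1e-6)
  # pure-noise response explains nothing out of sample
  set.seed(54)
  xr <- matrix(rnorm(600), 100, 6); colnames(xr) <- paste0("s", 1:6)
  yr <- rnorm(100)
  fr <- fit_pls(xr[1:70, ], yr[1:70], "regression", 3)
  pred_basis <- project_pls(fr, xr[71:100, ])
  r2 <- summary(lm(yr[71:100] ~ pred_basis))$r.squared
  expect_lt(r2, 0.35)
  expect_error(fit_pls(xr, yr, "regression", n_components = 200), "rank")
})

test_that("rejection keeps the closest simulations with ties", {
  set.seed(55)
  sim <- matrix(rnorm(300), 100, 3)
  obs <- rnorm(3)
  r <- abc_reject(obs, sim, retain_fraction = 0.1)
  d_all <- sqrt(colSums((t(sim) - obs)^2))
  expect_equal(sort(r$distance), sort(d_all)[seq_along(r$index)])
  expect_equal(r$distance, d_all[r$index])
  # retain everything
  expect_equal(length(abc_reject(obs, sim, 1)$index), 100)
  # observed identical to one row: retained at distance zero
  r1 <- abc_reject(sim[17, ], sim, retain_fraction = 1 / 100)
  expect_true(17 %in% r1$index)
  expect_equal(min(r1$distance), 0)
  # ties at the cutoff are all retained
  simt <- matrix(c(1, 1, 1, 2), 4, 1)
  rt <- abc_reject(0, simt, retain_fraction = 0.25)
  expect_equal(length(rt$index), 3)
  expect_error(abc_reject(obs, sim[0, , drop = FALSE]), "empty")
})

test_that("model posteriors are retained shares with consistent Bayes factors", {
  labs <- c(rep("SDN", 50), rep("SSV", 30), rep("NTR", 20))
  mp <- model_posterior(labs)
  expect_equal(unname(mp$posterior[c("SDN", "SSV", "NTR")]),
               c(0.5, 0.3, 0.2))
  expect_equal(sum(mp$posterior), 1, tolerance = 1e-9)
  expect_equal(unname(mp$bayes_factors["SDN", "SSV"]), 5 / 3)
  # Bayes factors multiply
  bf <- mp$bayes_factors
  expect_equal(bf["SDN", "NTR"], bf["SDN", "SSV"] * bf["SSV", "NTR"])
  # training-count adjustment rebalances unequal budgets
  mp2 <- model_posterior(labs, training_counts = c(SDN = 5000, SSV = 3000,
                                                   NTR = 2000))
  expect_equal(unname(mp2$posterior), rep(1 / 3, 3), tolerance = 1e-9)
  # all-one-model retention reports a floor for the absent models
  mp3 <- model_posterior(rep("SDN", 100), models = c("NTR", "SDN", "SSV"))
  expect_equal(unname(mp3$posterior["SDN"]), 1)
  expect_equal(attr(mp3, "floor"), 1 / 100)
  expect_warning(model_posterior(labs, training_counts = c(SDN = 10, SSV = 10),
                                 models = c("SDN", "SSV", "NTR")), "NTR")
})

test_that("parameter posteriors give sane modes and credible intervals", {
  expect_warning(ep0 <- estimate_parameters(data.frame(x = rep(2, 10)),
                                            rep(0.1, 10)), "unstable")
  expect_equal(ep0$x$mode, 2)
  expect_equal(ep0$x$ci, c(2, 2))
  set.seed(57)
  u <- data.frame(theta = runif(10000))
  ep <- estimate_parameters(u, runif(10000))
  expect_lt(abs(ep$theta$ci[1] - 0.025), 0.01)
  expect_lt(abs(ep$theta$ci[2] - 0.975), 0.01)
  expect_gt(ep$theta$mode, 0); expect_lt(ep$theta$mode, 1)
  # clamping to the prior support
  ep2 <- estimate_parameters(data.frame(s_NA = runif(200, 0.04, 0.06)),
                             runif(200), support = list(s_NA = c(0, 0.05)))
  expect_lte(ep2$s_NA$ci[2], 0.05)
  # local-linear adjustment runs and stays in support
  sc <- matrix(rnorm(400), 200, 2)
  ep3 <- estimate_parameters(data.frame(s_NA = runif(200, 0, 0.05)),
                             sqrt(rowSums(sc^2)), adjustment = "loclinear",
                             sim_scores = sc, observed_scores = c(0, 0),
                             support = list(s_NA = c(0, 0.05)))
  expect_gte(ep3$s_NA$ci[1], 0)
  expect_lte(ep3$s_NA$ci[2], 0.05)
})

make_synth_table <- function(n_per, sep, models = c("NTR", "SDN", "SSV")) {
  do.call(rbind, lapply(seq_along(models), function(k) {
    stats <- matrix(rnorm(n_per * 5, mean = sep * k), n_per, 5)
    colnames(stats) <- paste0("s", 1:5)
    cbind(data.frame(model = models[k], s_A = runif(n_per, 0, 0.015),
                     s_NA = runif(n_per, 0.005, 0.05),
                     t_mut = runif(n_per, 40000, 70000),
                     f0 = NA_real_, h = 0.5),
          as.data.frame(stats))
  }))
}

test_that("cross-validation recovers exchangeability and separability limits", {
  set.seed(59)
  # identical generative processes: assignment is a coin flip per model
  tab0 <- make_synth_table(400, sep = 0, models = c("SDN", "SSV"))
  pw0 <- cross_validate_power(tab0, n_pseudo = 100, retain_fraction = 0.1,
                              n_components = 3)
  se <- sqrt(0.5 * 0.5 / 100)
  for (r in pw0$rates) expect_lt(abs(r - 0.5), 4 * se)
  # fully separated statistic supports: perfect assignment
  tab1 <- make_synth_table(300, sep = 30)
  pw1 <- cross_validate_power(tab1, n_pseudo = 80, n_components = 3)
  expect_equal(unname(pw1$rates), c(1, 1, 1))
  expect_error(cross_validate_power(tab1, n_pseudo = 400), "exceeds")
})

test_that("posterior calibration: the true model gets above-chance posterior", {
  set.seed(61)
  tab <- make_synth_table(400, sep = 1.2)
  cols <- paste0("s", 1:5)
  post_true <- numeric(0)
  pseudo_idx <- unlist(lapply(c("NTR", "SDN", "SSV"), function(m)
    sample(which(tab$model == m), 70)))
  train <- tab[-pseudo_idx, ]
  z <- zscore_table(as.matrix(train[, cols]))
  pls <- fit_pls(z$z, train$model, "discriminant", 3)
  sc <- project_pls(pls, z$z)
  for (i in pseudo_idx) {
    oz <- (as.numeric(tab[i, cols]) - z$center) / z$scale
    names(oz) <- names(z$center)
    r <- abc_reject(project_pls(pls, oz), sc, 0.05)
    mp <- model_posterior(train$model[r$index],
                          models = c("NTR", "SDN", "SSV"))
    post_true <- c(post_true, mp$posterior[tab$model[i]])
  }
  expect_gt(mean(post_true), 1 / 3)
})

test_that("dominance model choice returns coherent marginals", {
  set.seed(63)
  mk <- function(model, h, mu) {
    stats <- matrix(rnorm(150 * 4, mean = mu), 150, 4)
    colnames(stats) <- paste0("s", 1:4)
    cbind(data.frame(model = model, s_A = 0, s_NA = 0.02, t_mut = 5e4,
                     f0 = NA_real_, h = h), as.data.frame(stats))
  }
  tabs <- list(mk("NTR", 0.5, 0),
               mk("SDN", 0, 2), mk("SDN", 0.38, 4), mk("SDN", 0.5, 6),
               mk("SSV", 0, 2.5), mk("SSV", 0.38, 4.5), mk("SSV", 0.5, 6.5))
  obs <- c(s1 = 2.2, s2 = 2.2, s3 = 2.2, s4 = 2.2)
  dm <- dominance_model_choice(tabs, obs, retain_fraction = 0.05,
                               n_components = 3)
  expect_equal(sum(dm$joint), 1, tolerance = 1e-9)
  expect_equal(sum(dm$dominance_marginal), 1, tolerance = 1e-9)
  defined <- colSums(is.na(dm$selection_within)) == 0
  expect_true(any(defined))
  expect_true(all(abs(colSums(dm$selection_within[, defined, drop = FALSE]) - 1)
                  < 1e-9))
  # observed sits in the h = 0 stratum: recessive marginal dominates
  expect_equal(names(which.max(dm$dominance_marginal[1:3])), "h0")
  expect_error(dominance_model_choice(tabs[-2], obs), "missing")
})

test_that("the two-stage fit assigns a self-simulated observation correctly", {
  set.seed(65)
  tab <- make_synth_table(500, sep = 2.5)
  cols <- paste0("s", 1:5)
  obs <- as.numeric(tab[750, cols]); names(obs) <- cols   # an SDN row
  fit <- abc_sweep(obs, tab, retain_fraction = 0.05, n_components = 3)
  expect_s3_class(fit, "sweep_abc")
  expect_equal(sum(fit$posterior), 1, tolerance = 1e-9)
  expect_equal(names(which.max(fit$posterior)), "SDN")
  expect_setequal(names(fit$parameters), c("s_A", "s_NA", "t_mut"))
  for (p in fit$parameters) {
    expect_lte(p$ci[1], p$mode + 1e-9)
    expect_gte(p$ci[2], p$mode - 1e-9)
  }
  out <- capture.output(print(fit))
  expect_true(any(grepl("SDN", out)))
})
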