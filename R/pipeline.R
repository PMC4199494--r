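# Config-driven orchestration: each cmd_* function wraps one pipeline stage,
# seeds its own RNG from the top-level seed via the documented splitting
# scheme, and records outputs in a run manifest.

demography_from_config <- function(cfg) {
  d <- cfg$demography
  if (d$kind == "constant")
    constant_demography(d$N, lambda = d$lambda,
                        generation_years = d$generation_years)
  else
    gravel_demography(d$nonafrican, lambda = d$lambda,
                      generation_years = d$generation_years)
}

spec_from_config <- function(cfg) {
  s <- cfg$simulator
  simulator_spec(region_length = s$region_length, focal_pos = s$focal_pos,
                 mu = s$mu, rec_cM_Mb = s$rec_cM_Mb,
                 n_sample = s$n_sample, lambda = cfg$demography$lambda)
}

manifest_add <- function(manifest, stage, paths, extra = list()) {
  manifest$stages[[stage]] <- c(list(
    outputs = as.list(paths),
    md5 = as.list(unname(tools::md5sum(unlist(paths)))),
    time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")), extra)
  manifest
}

write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the simulation stage: one conditioned batch per model
#'
#' @param cfg a `run_config` from [load_config()] (or a compatible list).
#' @param out_dir output directory (defaults to the config's).
#' @return Invisibly, the named list of written table paths; acceptance
#'   rates are logged and recorded in the manifest.
#' @export
cmd_simulate <- function(cfg, out_dir = cfg$out_dir) {
  cfg <- validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dem <- demography_from_config(cfg)
  spc <- spec_from_config(cfg)
  hash <- config_hash(cfg)
  manifest <- list(config_hash = hash, seed = cfg$seed,
                   package = as.character(utils::packageVersion("sweepabc")),
                   stages = list())
  paths <- character(0)
  for (i in seq_along(cfg$models)) {
    m <- cfg$models[i]
    set.seed(child_seed(cfg$seed, i))
    tab <- simulate_batch(m, cfg$abc$n_sims, dem, spc,
                          registry = cfg$registry, h = cfg$dominance)
    p <- file.path(out_dir, sprintf("sims_%s_h%g.tsv", m, cfg$dominance))
    write_result_tsv(tab, p, meta = c(config_hash = hash,
                                      seed = as.character(cfg$seed),
                                      model = m,
                                      acceptance_rate = sprintf(
                                        "%.6g", attr(tab, "acceptance_rate"))))
    message(sprintf("%s: %d simulations, acceptance rate %.3g, %d flagged",
                    m, nrow(tab), attr(tab, "acceptance_rate"),
                    attr(tab, "n_flagged")))
    paths[m] <- p
    manifest <- manifest_add(manifest, paste0("simulate_", m), p,
                             list(acceptance_rate = attr(tab, "acceptance_rate")))
  }
  write_manifest(manifest, out_dir)
  invisible(paths)
}

#' Compute the observed summary vector from a phased VCF
#'
#' @param cfg a `run_config`.
#' @param vcf path to a phased VCF with ancestral-allele annotation.
#' @param map path to a genetic-map file, or `NULL` for the config's
#'   constant-rate fallback (an error suggests the fallback when the map is
#'   missing).
#' @param focal 1-based position of the focal variant within the VCF contig.
#' @param region list(contig, start, end), 1-based inclusive.
#' @param sample_ids named list of sample ids per population.
#' @param out_dir output directory.
#' @return The observed `summary_vector` (also written as TSV).
#' @export
cmd_observed_stats <- function(cfg, vcf, map = NULL, focal, region,
                               sample_ids, out_dir = cfg$out_dir) {
  cfg <- validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gm <- if (is.null(map)) {
    message("no genetic map given; using the constant-rate fallback (",
            cfg$simulator$rec_cM_Mb, " cM/Mb)")
    constant_map(cfg$simulator$rec_cM_Mb, region$end - region$start + 1)
  } else if (!file.exists(map)) {
    stop("genetic map not found: ", map,
         "; pass map = NULL to fall back to a constant rate")
  } else read_genetic_map(map)
  smp <- read_vcf_haplotypes(vcf, region, sample_ids)
  fi <- which(abs(smp$positions - (focal - region$start)) < 0.5)
  if (length(fi) != 1)
    stop("focal variant absent (or not uniquely biallelic) at position ", focal)
  smp$focal_index <- fi
  sv <- compute_summary_vector(smp, cfg$registry, gm)
  if (isTRUE(attr(sv, "flagged")))
    message("frequency-filter / undefined exclusions: ",
            paste(attr(sv, "undefined"), collapse = ", "))
  p <- file.path(out_dir, "observed_stats.tsv")
  write_result_tsv(data.frame(statistic = names(sv), value = as.numeric(sv)),
                   p, meta = c(config_hash = config_hash(cfg),
                               seed = as.character(cfg$seed)))
  invisible(sv)
}

#' Run the ABC stage on simulation tables and an observed vector
#'
#' @param cfg a `run_config`.
#' @param sim_tables list of simulation tables (or TSV paths).
#' @param observed named observed summary vector (or an
#'   `observed_stats.tsv` path).
#' @param out_dir output directory.
#' @return The [abc_sweep()] fit (also written as TSV + JSON report).
#' @export
cmd_abc <- function(cfg, sim_tables, observed, out_dir = cfg$out_dir) {
  cfg <- validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(sim_tables)) sim_tables <- lapply(sim_tables, read_result_tsv)
  sim <- do.call(rbind, c(sim_tables, list(make.row.names = FALSE)))
  if (is.character(observed)) {
    tab <- read_result_tsv(observed)
    observed <- stats::setNames(tab$value, tab$statistic)
  }
  set.seed(child_seed(cfg$seed, 101L))
  fit <- abc_sweep(observed, sim, retain_fraction = cfg$abc$retain_fraction,
                   n_components = cfg$abc$n_components)
  report <- data.frame(model = names(fit$posterior),
                       posterior = as.numeric(fit$posterior))
  write_result_tsv(report, file.path(out_dir, "abc_model_posterior.tsv"),
                   meta = c(config_hash = config_hash(cfg),
                            seed = as.character(cfg$seed)))
  jsonlite::write_json(list(
    posterior = as.list(fit$posterior),
    bayes_factors = fit$bayes_factors,
    model = fit$model,
    parameters = lapply(fit$parameters, function(p)
      list(mode = p$mode, ci = p$ci))),
    file.path(out_dir, "abc_report.json"), auto_unbox = TRUE, digits = NA)
  invisible(fit)
}

#' Run the model-choice power assessment
#'
#' @param cfg a `run_config`.
#' @param sim_tables list of simulation tables (or TSV paths).
#' @param out_dir output directory.
#' @return The [cross_validate_power()] result (also written as TSV).
#' @export
cmd_power <- function(cfg, sim_tables, out_dir = cfg$out_dir) {
  cfg <- validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(sim_tables)) sim_tables <- lapply(sim_tables, read_result_tsv)
  sim <- do.call(rbind, c(sim_tables, list(make.row.names = FALSE)))
  set.seed(child_seed(cfg$seed, 201L))
  pw <- cross_validate_power(sim, cfg$abc$n_pseudo,
                             retain_fraction = cfg$abc$retain_fraction,
                             n_components = cfg$abc$n_components)
  out <- data.frame(model = names(pw$rates), rate = as.numeric(pw$rates),
                    se = as.numeric(pw$se))
  write_result_tsv(out, file.path(out_dir, "power_rates.tsv"),
                   meta = c(config_hash = config_hash(cfg),
                            seed = as.character(cfg$seed)))
  invisible(pw)
}

#' Fay and Wu's H demographic-null test for an observed sample
#'
#' Computes H over the observed region and an empirical lower-tail p-value
#' against `n_sims` neutral simulations under the single-population
#' demographic model.
#'
#' @param cfg a `run_config`.
#' @param sample a [haplotype_sample] (one population is tested).
#' @param pop which population of the sample to test.
#' @param null_pop single-population demography label (`"AFR"`, `"EUR"`,
#'   `"EAS"`).
#' @param n_sims number of neutral null simulations.
#' @return List with `H`, `p_value` and the null [score_distribution].
#' @export
cmd_fwtest <- function(cfg, sample, pop = 1, null_pop = "EAS",
                       n_sims = 10000) {
  cfg <- validate_config(cfg)
  h_obs <- fay_wu_h(sample, window_spec("whole_region"), pop)
  set.seed(child_seed(cfg$seed, 301L))
  dem <- single_pop_demography(null_pop, lambda = cfg$demography$lambda)
  spc <- spec_from_config(cfg)
  nn <- sum(sample$pop_labels == pop_label(sample, pop))
  spc$n_sample <- c(nn, 0L)
  null <- neutral_null_sims(dem, spc, n = n_sims)
  list(H = h_obs, p_value = empirical_pvalue(h_obs, null), null = null)
}
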