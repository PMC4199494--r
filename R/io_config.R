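# Structured run configuration (YAML), result-table I/O with provenance
# header comments, and the seed-splitting scheme used by the pipeline.

config_defaults <- function() {
  list(
    seed = NULL,
    models = c("NTR", "SDN", "SSV"),
    dominance = 0.5,
    demography = list(kind = "gravel", nonafrican = "EAS", lambda = 10,
                      generation_years = 25),
    simulator = list(region_length = 12000, focal_pos = 8000,
                     mu = 2.36e-8, rec_cM_Mb = 1.76,
                     n_sample = c(100, 100)),
    abc = list(n_sims = 10000, retain_fraction = 0.01, n_components = 7,
               n_pseudo = 200),
    registry = default_registry(),
    out_dir = "."
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, fills documented defaults, validates every
#' numeric field against its range and rejects unknown keys. A seed is
#' mandatory (every pipeline command is stochastic). Re-serializing the
#' loaded configuration reproduces the effective configuration.
#'
#' @param path YAML file path.
#' @return An object of class `run_config` (a validated named list).
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  defs <- config_defaults()
  unknown <- setdiff(names(raw), names(defs))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (sect in c("demography", "simulator", "abc")) {
    bad <- setdiff(names(raw[[sect]]), names(defs[[sect]]))
    if (length(bad) > 0)
      stop("unknown config key(s): ", paste0(sect, "$", bad, collapse = ", "))
  }
  cfg <- modifyList(defs, raw)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (is.null(cfg$seed)) stop("config error at 'seed': a seed is mandatory")
  chk <- function(ok, key, msg) if (!ok) stop("config error at '", key, "': ", msg)
  chk(cfg$seed == as.integer(cfg$seed) && cfg$seed >= 0, "seed",
      "must be a non-negative integer")
  chk(all(cfg$models %in% c("NTR", "SDN", "SSV")), "models",
      "must be a subset of NTR, SDN, SSV")
  chk(cfg$dominance %in% c(0, 0.38, 0.5) || (cfg$dominance >= 0 && cfg$dominance <= 1),
      "dominance", "must lie in [0, 1]")
  chk(cfg$demography$kind %in% c("gravel", "constant"), "demography$kind",
      "must be 'gravel' or 'constant'")
  chk(cfg$demography$lambda > 0, "demography$lambda", "must be > 0")
  chk(cfg$simulator$mu >= 0, "simulator$mu", "must be >= 0")
  chk(cfg$simulator$rec_cM_Mb >= 0, "simulator$rec_cM_Mb", "must be >= 0")
  chk(cfg$simulator$region_length > 0, "simulator$region_length", "must be > 0")
  chk(cfg$simulator$focal_pos > 0 &&
        cfg$simulator$focal_pos < cfg$simulator$region_length,
      "simulator$focal_pos", "must lie inside the region")
  chk(cfg$abc$retain_fraction > 0 && cfg$abc$retain_fraction <= 1,
      "abc$retain_fraction", "must be in (0, 1]")
  chk(cfg$abc$n_components >= 1, "abc$n_components", "must be >= 1")
  chk(cfg$abc$n_sims >= 1, "abc$n_sims", "must be >= 1")
  structure(cfg, class = "run_config")
}

#' Deterministic configuration hash
#'
#' MD5 of the canonical YAML serialization; recorded in result-table
#' headers so outputs can be traced to the configuration that produced them.
#'
#' @param cfg a `run_config`.
#' @return Character MD5 hash.
#' @export
config_hash <- function(cfg) {
  x <- unclass(cfg)
  x$out_dir <- NULL            # where results go is not part of what they are
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(yaml::as.yaml(x), tf)
  unname(tools::md5sum(tf))
}

# derive a per-stage child seed from the top-level seed (documented scheme:
# splitmix-style multiply-and-add, folded into the 31-bit integer range)
child_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 48271 + 104729 * stage) %% (2^31 - 1))
}

#' Write / read a result table as TSV with provenance header comments
#'
#' Header comment lines (`# key: value`) record at least the package
#' version; pipeline commands add the config hash and seed.
#'
#' @param x data.frame.
#' @param path output path.
#' @param meta named character vector of extra header fields.
#' @return Invisibly, `path`.
#' @export
write_result_tsv <- function(x, path, meta = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(meta, package = as.character(utils::packageVersion("sweepabc")))
  writeLines(sprintf("# %s: %s", names(meta), meta), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_result_tsv
#' @export
read_result_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE)
}
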