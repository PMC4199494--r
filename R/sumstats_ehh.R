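# Haplotype-homozygosity statistics: EHH decay, its integral over genetic
# distance (iHH), and the raw log-ratio scores iHS and XP-EHH. The site scan
# runs in C++; integration, truncation and map lookup happen here.

carriers_of <- function(sample, pop, core_site, core_allele) {
  rows <- pop_rows(sample, pop_label(sample, pop))
  rows[sample$matrix[rows, core_site] == core_allele]
}

#' Extended haplotype homozygosity between a core site and a target site
#'
#' Fraction of pairs of core-allele carriers that are identical at every site
#' between core and target inclusive.
#'
#' @param sample a [haplotype_sample].
#' @param pop population label (or 1/2).
#' @param core_site,target_site site (column) indices.
#' @param core_allele 0 (ancestral) or 1 (derived).
#' @return EHH in `[0, 1]`.
#' @export
ehh <- function(sample, pop, core_site, core_allele = 1,
                target_site = core_site) {
  car <- carriers_of(sample, pop, core_site, core_allele)
  if (length(car) < 2)
    undefined_stat("EHH undefined: fewer than 2 carriers of the core allele")
  rng <- sort(c(core_site, target_site))
  block <- sample$matrix[car, rng[1]:rng[2], drop = FALSE]
  key <- apply(block, 1, paste, collapse = "")
  cnt <- table(key)
  sum(choose(cnt, 2)) / choose(length(car), 2)
}

# trapezoid integral of an EHH decay (both directions) against genetic
# distance, truncated at the first site where EHH < truncation (included as
# the last node); extended flat to the region edge when never truncated
integrate_decay <- function(dec, gpos, core_site, truncation, map,
                            region_length) {
  edge_flag <- FALSE
  one_side <- function(evals, step, edge_bp) {
    idx <- core_site + step * (seq_along(evals) - 1)
    below <- which(evals < truncation)
    if (length(below) > 0) {
      stopi <- below[1]
      x <- abs(gpos[idx[1:stopi]] - gpos[core_site])
      y <- evals[1:stopi]
    } else {
      edge_flag <<- TRUE
      x <- c(abs(gpos[idx] - gpos[core_site]),
             abs(map_cM(map, edge_bp) - gpos[core_site]))
      y <- c(evals, evals[length(evals)])
    }
    if (length(x) < 2) return(0)
    sum(diff(x) * (head(y, -1) + y[-1]) / 2)
  }
  val <- one_side(dec$left, -1L, 0) +
         one_side(dec$right, +1L, region_length)
  structure(val, edge_truncated = edge_flag)
}

#' Integrated EHH (iHH) around a core allele
#'
#' EHH is computed outward from the core in both directions and integrated by
#' the trapezoid rule against genetic distance (cM). Each direction is
#' truncated at the first site where EHH falls below `truncation` (that site
#' is included as the last trapezoid node); if EHH never falls below the
#' threshold before the region edge, the integral is extended to the edge at
#' the last EHH value and the result is flagged (`attr(., "edge_truncated")`).
#' With `core_allele = NULL` the pooled (site-wise) definition is used: all
#' haplotypes of the population enter and identity includes the core allele,
#' so EHH starts at the core-site homozygosity (the XP-EHH convention).
#'
#' @inheritParams ehh
#' @param map a [genetic_map] covering the region.
#' @param truncation EHH truncation threshold.
#' @return iHH in cM, with attribute `edge_truncated`.
#' @export
ihh <- function(sample, pop, core_site, core_allele = 1, map,
                truncation = 0.05) {
  rows <- pop_rows(sample, pop_label(sample, pop))
  if (is.null(core_allele)) {
    if (length(rows) < 2)
      undefined_stat("iHH undefined: fewer than 2 haplotypes")
    car_idx <- seq_along(rows)
    pooled <- TRUE
  } else {
    car <- carriers_of(sample, pop, core_site, core_allele)
    if (length(car) < 2)
      undefined_stat("iHH undefined: fewer than 2 carriers of the core allele")
    car_idx <- match(car, rows)
    pooled <- FALSE
  }
  sub <- sample$matrix[rows, , drop = FALSE]
  dec <- cpp_ehh_decay(sub, car_idx - 1L, core_site - 1L, pooled)
  gpos <- map_cM(map, sample$positions)
  integrate_decay(dec, gpos, core_site, truncation, map,
                  sample$region_length)
}

#' Raw (unstandardized) iHS at a core site
#'
#' ln(iHH_ancestral / iHH_derived) within one population. Requires minor
#' allele frequency >= `maf_min` at the core (the EHH signal breaks down for
#' rare alleles); zero iHH in either allelic class is undefined.
#'
#' @inheritParams ihh
#' @param maf_min minor-allele-frequency filter at the core site.
#' @return Unstandardized iHS (positive: longer ancestral haplotypes).
#' @export
ihs_raw <- function(sample, pop, core_site, map, truncation = 0.05,
                    maf_min = 0.05) {
  rows <- pop_rows(sample, pop_label(sample, pop))
  p <- mean(sample$matrix[rows, core_site])
  if (min(p, 1 - p) < maf_min)
    undefined_stat(sprintf(
      "iHS filtered out: core minor allele frequency %.3f < %.2f",
      min(p, 1 - p), maf_min))
  ia <- ihh(sample, pop, core_site, 0L, map, truncation)
  id <- ihh(sample, pop, core_site, 1L, map, truncation)
  if (ia <= 0 || id <= 0)
    undefined_stat("iHS undefined: zero iHH in one allelic class")
  log(as.numeric(ia) / as.numeric(id))
}

#' Raw (unstandardized) XP-EHH at a core site
#'
#' ln(iHH_A / iHH_B) with the pooled per-population iHH at the core site
#' (all chromosomes; identity includes the core allele), population A being
#' the candidate-selected population: positive values mean longer haplotypes
#' around the core in A. Swapping A and B negates the score.
#'
#' @param sample a two-population [haplotype_sample].
#' @param core_site site (column) index of the core.
#' @param map a [genetic_map].
#' @param pop_a,pop_b labels (or 1/2) of the candidate-selected and
#'   reference populations.
#' @param truncation EHH truncation threshold.
#' @param daf_min derived-allele-frequency filter in the pooled sample (the
#'   genome-scan convention; set to 0 to disable, as the ABC feature space
#'   does).
#' @return Unstandardized XP-EHH.
#' @export
xpehh_raw <- function(sample, core_site, map, pop_a = 2, pop_b = 1,
                      truncation = 0.05, daf_min = 0.05) {
  daf <- mean(sample$matrix[, core_site])
  if (daf < daf_min)
    undefined_stat(sprintf(
      "XP-EHH filtered out: derived allele frequency %.3f < %.2f",
      daf, daf_min))
  ia <- ihh(sample, pop_a, core_site, NULL, map, truncation)
  ib <- ihh(sample, pop_b, core_site, NULL, map, truncation)
  if (ia <= 0 || ib <= 0)
    undefined_stat("XP-EHH undefined: zero iHH in one population")
  log(as.numeric(ia) / as.numeric(ib))
}

#' Standardize scores within derived-allele-frequency bins
#'
#' Bins scores by frequency (default 1% bins), merges bins holding fewer
#' than two scores into the nearest adequate bin (flagged), and z-scores
#' within each final bin so that every bin has mean 0 and standard deviation
#' 1. With a single bin this is plain standardization (the XP-EHH
#' convention).
#'
#' @param scores numeric scores (e.g. raw iHS).
#' @param freqs derived-allele frequencies, same length.
#' @param bin_width frequency bin width; `1` gives a single bin.
#' @return Standardized scores; attribute `merged_bins` lists bins that were
#'   merged.
#' @export
standardize_binned <- function(scores, freqs, bin_width = 0.01) {
  stopifnot(length(scores) == length(freqs))
  bin <- pmin(floor(freqs / bin_width), ceiling(1 / bin_width) - 1)
  tab <- table(bin)
  good <- as.numeric(names(tab))[tab >= 2]
  if (length(good) == 0) stop("no bin holds >= 2 scores")
  merged <- character(0)
  for (b in as.numeric(names(tab))[tab < 2]) {
    tgt <- good[which.min(abs(good - b))]
    merged <- c(merged, sprintf("%d->%d", b, tgt))
    bin[bin == b] <- tgt
  }
  out <- scores
  for (b in unique(bin)) {
    sel <- bin == b
    out[sel] <- (scores[sel] - mean(scores[sel])) / sd(scores[sel])
  }
  structure(out, merged_bins = merged)
}
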