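#' Empirical score distribution
#'
#' A sorted collection of scores (genome-wide or simulation-wide) against
#' which an observed score is ranked.
#'
#' @param values numeric scores.
#' @param tail `"upper"` or `"lower"`: which tail is extreme.
#' @return An object of class `score_distribution`.
#' @export
score_distribution <- function(values, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  values <- sort(as.numeric(values))
  if (length(values) < 2) stop("a score distribution needs >= 2 values")
  structure(list(values = values, tail = tail), class = "score_distribution")
}

#' Empirical p-value of a score against a distribution
#'
#' Upper tail: p = #\{x >= score\} / N (the focal score is not re-added to
#' the distribution); lower tail analogous. With zero exceedances the floor
#' 1/N is reported as an upper bound and flagged
#' (`attr(., "floor_bound") = TRUE`).
#'
#' @param score observed score.
#' @param dist a [score_distribution] (or numeric vector, upper tail).
#' @return The empirical p-value.
#' @export
empirical_pvalue <- function(score, dist) {
  if (!inherits(dist, "score_distribution"))
    dist <- score_distribution(dist, "upper")
  N <- length(dist$values)
  k <- if (dist$tail == "upper") sum(dist$values >= score)
       else sum(dist$values <= score)
  if (k == 0) structure(1 / N, floor_bound = TRUE) else k / N
}

#' Default summary-statistic registry
#'
#' The statistic set of the ABC feature space: pi, Watterson's theta,
#' Tajima's D and Fay and Wu's H in the 4 kb symmetric and 8 kb asymmetric
#' windows for both populations (16 entries), the Reynolds F_ST at the focal
#' site, Weir-Cockerham F_ST over the 4 kb window and over the whole region,
#' the raw XP-EHH at the focal site, and the derived focal-allele frequency
#' in each population (22 entries in total; configurable).
#'
#' @return Character vector of statistic ids.
#' @export
default_registry <- function() {
  sfs <- as.vector(outer(
    as.vector(outer(c("pi", "thetaW", "tajD", "fwH"), c("4kb", "8kb"),
                    paste, sep = "_")),
    c("p1", "p2"), paste, sep = "_"))
  c(sfs, "fst_site", "fst_4kb", "fst_region", "xpehh_site", "daf_p1", "daf_p2")
}

#' Compute the summary vector of a two-population sample
#'
#' Evaluates every statistic in the registry on the sample. Statistics that
#' are undefined on the input (e.g. Tajima's D with no segregating site, or
#' XP-EHH with fewer than two derived carriers in a population) are recorded
#' as `NA` sentinels and the vector is flagged; the ABC layer decides how to
#' handle flagged rows.
#'
#' @param sample a two-population [haplotype_sample] with `focal_index` set.
#' @param registry statistic ids, see [default_registry()].
#' @param map a [genetic_map] for the haplotype statistics.
#' @return Named numeric vector of class `summary_vector` with attributes
#'   `flagged` and `undefined` (ids of sentinel entries).
#' @export
compute_summary_vector <- function(sample, registry = default_registry(),
                                   map) {
  if (is.null(sample$focal_index)) stop("summary vector requires a focal site")
  pops <- unique(sample$pop_labels)
  w4 <- window_spec("symmetric")
  w8 <- window_spec("asymmetric")
  wR <- window_spec("whole_region")
  wins <- list(`4kb` = window_sites(sample, w4),
               `8kb` = window_sites(sample, w8))
  # per-population derived counts over all sites, computed once
  cnt <- lapply(pops, function(p)
    colSums(sample$matrix[pop_rows(sample, p), , drop = FALSE]))
  nhap <- vapply(pops, function(p) length(pop_rows(sample, p)), integer(1))
  ct <- lapply(nhap, tajima_constants)
  sfs_kernels <- list(pi = pi_kernel, thetaW = thetaW_kernel,
                      tajD = function(i, n) tajD_kernel(i, n),
                      fwH = fwH_kernel)
  eval_one <- function(id) {
    parts <- strsplit(id, "_")[[1]]
    if (parts[1] %in% names(sfs_kernels)) {
      k <- as.integer(sub("p", "", parts[3]))
      i <- cnt[[k]][wins[[parts[2]]]]
      if (parts[1] == "tajD") return(tajD_kernel(i, nhap[k], ct[[k]]))
      return(sfs_kernels[[parts[1]]](i, nhap[k]))
    }
    switch(id,
      fst_site = focal_reynolds_fst(sample),
      fst_4kb = region_fst(sample, w4),
      fst_region = region_fst(sample, wR),
      # inside the ABC feature space the scan-stage 5% frequency filter does
      # not apply: the statistic is used whenever it is computable
      xpehh_site = xpehh_raw(sample, sample$focal_index, map,
                             pop_a = 2, pop_b = 1, daf_min = 0),
      daf_p1 = cnt[[1]][sample$focal_index] / nhap[1],
      daf_p2 = cnt[[2]][sample$focal_index] / nhap[2],
      stop("unknown statistic id: ", id))
  }
  out <- vapply(registry, function(id)
    tryCatch(as.numeric(eval_one(id)),
             sweepabc_undefined = function(e) NA_real_),
    numeric(1))
  names(out) <- registry
  structure(out, flagged = anyNA(out),
            undefined = registry[is.na(out)], class = "summary_vector")
}

#' @export
print.summary_vector <- function(x, ...) {
  cat("summary_vector (", length(x), " statistics",
      if (isTRUE(attr(x, "flagged")))
        paste0("; flagged, undefined: ",
               paste(attr(x, "undefined"), collapse = ", ")),
      ")\n", sep = "")
  print(round(unclass(x), 4), ...)
  invisible(x)
}
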