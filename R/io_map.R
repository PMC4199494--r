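#' Genetic map with piecewise-linear physical-to-genetic interpolation
#'
#' @param positions physical positions in bp, strictly increasing.
#' @param rates local recombination rates in cM/Mb, one per position.
#' @param cum_map cumulative genetic positions in cM; if omitted, computed by
#'   trapezoid integration of the rates. The first entry is shifted to 0.
#' @return An object of class `genetic_map`.
#' @export
genetic_map <- function(positions, rates, cum_map = NULL) {
  if (length(positions) != length(rates)) stop("positions/rates length mismatch")
  if (length(positions) > 1 && any(diff(positions) <= 0))
    stop("map positions must be strictly increasing")
  if (any(rates < 0)) stop("recombination rates must be >= 0")
  if (is.null(cum_map)) {
    cum_map <- if (length(positions) == 1) 0 else
      c(0, cumsum(diff(positions) *
                    (head(rates, -1) + rates[-1]) / 2 * 1e-6))
  }
  cum_map <- cum_map - cum_map[1]
  if (any(diff(cum_map) < 0)) stop("cumulative map must be non-decreasing")
  structure(list(positions = as.numeric(positions), rates = as.numeric(rates),
                 cum_map = as.numeric(cum_map)),
            class = "genetic_map")
}

#' Constant-rate genetic map over a region
#'
#' @param rate_cM_Mb recombination rate in cM/Mb.
#' @param region_length region length in bp.
#' @return A two-point [genetic_map].
#' @export
constant_map <- function(rate_cM_Mb, region_length) {
  genetic_map(c(0, region_length), rep(rate_cM_Mb, 2))
}

#' Read a HapMap-style genetic-map text file
#'
#' Whitespace/tab-delimited columns: position (bp), rate (cM/Mb), cumulative
#' genetic position (cM); a header line is tolerated. A single-row map gives
#' constant-rate extrapolation at its rate.
#'
#' @param path file path.
#' @return A [genetic_map].
#' @export
read_genetic_map <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- is.na(suppressWarnings(
    as.numeric(strsplit(trimws(first), "\\s+")[[1]][1])))
  tab <- read.table(path, header = has_header)
  if (ncol(tab) < 3) stop("genetic map needs columns position, rate, cumulative cM")
  genetic_map(tab[[1]], tab[[2]], tab[[3]])
}

#' Genetic position (cM) of physical positions
#'
#' Piecewise-linear interpolation on the cumulative map; beyond the mapped
#' interval, linear extrapolation with the edge rate (for a single-row map,
#' constant-rate extrapolation at its rate).
#'
#' @param map a [genetic_map].
#' @param pos physical positions in bp.
#' @return Genetic positions in cM (monotone non-decreasing in `pos`).
#' @export
map_cM <- function(map, pos) {
  p <- map$positions; cm <- map$cum_map; r <- map$rates
  if (length(p) == 1)
    return((pos - p[1]) * r[1] * 1e-6)
  out <- approx(p, cm, xout = pos, rule = 2)$y
  below <- pos < p[1]
  above <- pos > p[length(p)]
  out[below] <- cm[1] - (p[1] - pos[below]) * r[1] * 1e-6
  out[above] <- cm[length(cm)] + (pos[above] - p[length(p)]) * r[length(r)] * 1e-6
  out
}
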