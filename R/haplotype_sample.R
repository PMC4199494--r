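#' Phased haplotype sample over a genomic region
#'
#' The universal currency of the package: a binary haplotype-by-site matrix
#' (0 = ancestral, 1 = derived allele) with physical positions, one population
#' label per haplotype (at most two populations), an optional focal-site index
#' and the region length in bp. Positions use the internal 0-based convention;
#' the VCF reader is the only 1-based surface.
#'
#' @param matrix integer/numeric matrix, haplotypes in rows, sites in columns,
#'   entries 0/1.
#' @param positions numeric vector of strictly increasing positions in bp
#'   (0-based, within `[0, region_length)`).
#' @param pop_labels character vector, one label per haplotype row.
#' @param focal_index column index of the focal variant, or `NULL`.
#' @param region_length region length in bp.
#' @param polarized logical; whether allele 1 is a confirmed derived allele.
#' @return An object of class `haplotype_sample`.
#' @export
haplotype_sample <- function(matrix, positions, pop_labels, focal_index = NULL,
                             region_length, polarized = TRUE) {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "integer"
  if (length(positions) != ncol(matrix))
    stop("positions length must equal the number of sites")
  if (length(pop_labels) != nrow(matrix))
    stop("pop_labels length must equal the number of haplotypes")
  if (ncol(matrix) > 0 && any(matrix != 0L & matrix != 1L))
    stop("haplotype entries must be 0 (ancestral) or 1 (derived)")
  if (ncol(matrix) > 1 && any(diff(positions) <= 0))
    stop("positions must be strictly increasing")
  pops <- unique(pop_labels)
  if (length(pops) > 2) stop("at most two populations are supported")
  if (any(table(pop_labels) < 1)) stop("each population must be non-empty")
  if (!is.null(focal_index)) {
    focal_index <- as.integer(focal_index)
    cnt <- sum(matrix[, focal_index])
    if (cnt == 0L || cnt == nrow(matrix))
      stop("focal site must be biallelic in the pooled sample")
  }
  structure(list(matrix = matrix, positions = as.numeric(positions),
                 pop_labels = as.character(pop_labels),
                 focal_index = focal_index,
                 region_length = as.numeric(region_length),
                 polarized = isTRUE(polarized)),
            class = "haplotype_sample")
}

#' @export
print.haplotype_sample <- function(x, ...) {
  tab <- table(x$pop_labels)
  cat(sprintf("haplotype_sample: %d haplotypes x %d sites over %g bp\n",
              nrow(x$matrix), ncol(x$matrix), x$region_length))
  cat("  populations:", paste(sprintf("%s (n=%d)", names(tab), tab),
                              collapse = ", "), "\n")
  if (!is.null(x$focal_index))
    cat(sprintf("  focal site: column %d at %.1f bp, derived count %d/%d\n",
                x$focal_index, x$positions[x$focal_index],
                sum(x$matrix[, x$focal_index]), nrow(x$matrix)))
  invisible(x)
}

# row indices of a population's haplotypes
pop_rows <- function(sample, pop) {
  idx <- which(sample$pop_labels == pop)
  if (length(idx) == 0) stop("unknown population label: ", pop)
  idx
}

# resolve a pop argument given either a label or a 1/2 position
pop_label <- function(sample, pop) {
  pops <- unique(sample$pop_labels)
  if (is.numeric(pop)) pops[pop] else pop
}

#' Window specification relative to the focal site
#'
#' @param kind `"symmetric"` (default 2 kb each side, a 4 kb window),
#'   `"asymmetric"` (default 6 kb upstream, 2 kb downstream, an 8 kb window)
#'   or `"whole_region"`.
#' @param up_bp,down_bp window extent upstream/downstream of the focal
#'   position in bp (ignored for `whole_region`).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(kind = c("symmetric", "asymmetric", "whole_region"),
                        up_bp = NULL, down_bp = NULL) {
  kind <- match.arg(kind)
  if (is.null(up_bp))
    up_bp <- switch(kind, symmetric = 2000, asymmetric = 6000, whole_region = Inf)
  if (is.null(down_bp))
    down_bp <- switch(kind, symmetric = 2000, asymmetric = 2000, whole_region = Inf)
  if (up_bp < 0 || down_bp < 0) stop("window extents must be >= 0")
  structure(list(kind = kind, up_bp = up_bp, down_bp = down_bp),
            class = "window_spec")
}

# site (column) indices falling inside a window, clipped to the region
window_sites <- function(sample, window) {
  if (window$kind == "whole_region") return(seq_along(sample$positions))
  if (is.null(sample$focal_index))
    stop("window relative to the focal site requires focal_index")
  fp <- sample$positions[sample$focal_index]
  lo <- max(0, fp - window$up_bp)
  hi <- min(sample$region_length, fp + window$down_bp)
  which(sample$positions >= lo & sample$positions <= hi)
}

# reconstruct diploid genotype counts (hom-anc, het, hom-der) at one site by
# pairing consecutive haplotypes within each population (GT field order)
genotype_counts <- function(sample, site) {
  pops <- unique(sample$pop_labels)
  out <- matrix(0L, nrow = length(pops), ncol = 3,
                dimnames = list(pops, c("hom_anc", "het", "hom_der")))
  for (p in pops) {
    rows <- pop_rows(sample, p)
    if (length(rows) %% 2 != 0)
      stop("population ", p, " has an odd haplotype count; cannot pair genotypes")
    a <- sample$matrix[rows[seq(1, length(rows), 2)], site]
    b <- sample$matrix[rows[seq(2, length(rows), 2)], site]
    g <- a + b
    out[p, ] <- c(sum(g == 0), sum(g == 1), sum(g == 2))
  }
  out
}
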