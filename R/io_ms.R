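#' Read an ms-format haplotype block
#'
#' Parses the standard coalescent-simulator text block ("//", "segsites: k",
#' "positions: ...", 0/1 haplotype rows) into a [haplotype_sample].
#' Positions in `[0, 1)` are rescaled by the region length.
#'
#' @param lines character vector of lines (a single block), or a file path.
#' @param region_length bp length used to unscale positions.
#' @param n_per_pop haplotype counts per population (defaults to one
#'   population containing all rows).
#' @param pop_names population labels.
#' @return A [haplotype_sample].
#' @export
read_ms_block <- function(lines, region_length = 1, n_per_pop = NULL,
                          pop_names = NULL) {
  if (length(lines) == 1 && file.exists(lines)) lines <- readLines(lines)
  i <- grep("^//", lines)
  if (length(i) > 0) lines <- lines[(i[1] + 1):length(lines)]
  segline <- grep("^segsites:", lines, value = TRUE)
  if (length(segline) == 0) stop("no 'segsites:' line found")
  S <- as.integer(sub("^segsites:\\s*", "", segline[1]))
  if (S == 0) {
    mat <- matrix(integer(0), nrow = 0, ncol = 0)
    pos <- numeric(0)
    hl <- character(0)
  } else {
    posline <- grep("^positions:", lines, value = TRUE)
    if (length(posline) == 0) stop("no 'positions:' line found")
    pos <- as.numeric(strsplit(trimws(sub("^positions:", "", posline[1])),
                               "\\s+")[[1]])
    if (length(pos) != S)
      stop(sprintf("positions line has %d entries but segsites is %d",
                   length(pos), S))
    hl <- grep("^[01]+$", lines, value = TRUE)
    if (any(nchar(hl) != S))
      stop("haplotype row length inconsistent with segsites")
    mat <- do.call(rbind, lapply(strsplit(hl, ""), as.integer))
  }
  n <- if (S == 0) { if (is.null(n_per_pop)) 0L else sum(n_per_pop) } else nrow(mat)
  if (is.null(n_per_pop)) n_per_pop <- n
  if (is.null(pop_names)) pop_names <- paste0("P", seq_along(n_per_pop))
  labels <- rep(pop_names, n_per_pop)
  if (S == 0) mat <- matrix(integer(0), nrow = length(labels), ncol = 0)
  haplotype_sample(mat, pos * region_length, labels,
                   region_length = region_length)
}

#' Write a haplotype sample as an ms-format block
#'
#' Positions are rescaled to `[0, 1)` by the region length and printed with
#' six decimals; `read_ms_block(write_ms_block(x))` reproduces the matrix and
#' positions within that precision.
#'
#' @param sample a [haplotype_sample].
#' @param path file path, or `NULL` to return the lines.
#' @return Invisibly, the character lines written.
#' @export
write_ms_block <- function(sample, path = NULL) {
  S <- ncol(sample$matrix)
  lines <- c("//", paste0("segsites: ", S))
  if (S > 0) {
    lines <- c(lines,
               paste("positions:",
                     paste(sprintf("%.6f", sample$positions /
                                     sample$region_length),
                           collapse = " ")),
               apply(sample$matrix, 1, paste, collapse = ""))
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
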