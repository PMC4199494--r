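#' Read phased haplotypes from a VCF region
#'
#' Extracts a phased diploid genotype matrix for the requested samples over a
#' 1-based inclusive interval and polarizes it against the ancestral-allele
#' annotation (0 = ancestral, 1 = derived). Only biallelic SNPs with a
#' high-confidence ancestral call equal to REF or ALT are kept; indels,
#' multiallelic records and sites with missing/low-confidence ancestral
#' annotation are dropped and counted (`attr(., "dropped")`). Positions are
#' converted to the internal 0-based convention relative to the region
#' start. This is the package's only 1-based coordinate surface.
#'
#' @param path VCF file (plain text or gzipped).
#' @param region list with `contig`, `start`, `end` (1-based inclusive).
#' @param sample_ids named list of sample-id character vectors, one entry per
#'   population (at most two); order defines population order.
#' @param ancestral_key INFO key carrying the ancestral allele.
#' @param accept_lowercase whether lower-case (low-confidence) ancestral
#'   calls are accepted.
#' @return A [haplotype_sample]; two haplotype rows per sample in input
#'   order.
#' @export
read_vcf_haplotypes <- function(path, region, sample_ids,
                                ancestral_key = "AA",
                                accept_lowercase = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  pos <- as.numeric(fix$POS)
  keep <- fix$CHROM == region$contig & pos >= region$start & pos <= region$end
  if (!any(keep)) stop("no records in the requested region")
  v <- v[keep, ]
  fix <- fix[keep, , drop = FALSE]
  pos <- pos[keep]

  dropped <- c(multiallelic = 0L, indel = 0L, no_ancestral = 0L)
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    warning(sum(multi), " multiallelic site(s) dropped")
    dropped["multiallelic"] <- sum(multi)
  }
  indel <- !multi & (nchar(fix$REF) != 1 | nchar(fix$ALT) != 1)
  dropped["indel"] <- sum(indel)
  aa <- vcfR::extract.info(v, element = ancestral_key)
  aa[is.na(aa)] <- "."
  aa_clean <- sub("\\|.*", "", aa)          # tolerate AA=a|b|c style annotations
  valid_case <- if (accept_lowercase) toupper(aa_clean) %in% c("A", "C", "G", "T")
                else aa_clean %in% c("A", "C", "G", "T")
  matches <- toupper(aa_clean) == toupper(fix$REF) |
             toupper(aa_clean) == toupper(fix$ALT)
  no_aa <- !multi & !indel & (!valid_case | !matches)
  dropped["no_ancestral"] <- sum(no_aa)
  ok <- !multi & !indel & !no_aa
  if (!any(ok)) stop("no usable biallelic SNPs with ancestral annotation")

  ids <- unlist(sample_ids, use.names = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  missing_ids <- setdiff(ids, colnames(gt))
  if (length(missing_ids) > 0)
    stop("samples absent from VCF: ", paste(missing_ids, collapse = ", "))
  gt <- gt[ok, ids, drop = FALSE]
  fix <- fix[ok, , drop = FALSE]
  pos <- pos[ok]
  aa_up <- toupper(aa_clean[ok])

  unphased <- which(grepl("/", gt) | is.na(gt), arr.ind = TRUE)
  if (nrow(unphased) > 0)
    stop(sprintf("unphased or missing genotype for sample %s at position %s",
                 colnames(gt)[unphased[1, 2]], fix$POS[unphased[1, 1]]))
  split_alleles <- function(col) {
    parts <- strsplit(col, "|", fixed = TRUE)
    bad <- lengths(parts) != 2
    if (any(bad))
      stop("non-diploid genotype at position ", fix$POS[which(bad)[1]])
    matrix(as.integer(unlist(parts)), nrow = 2)
  }
  hap <- matrix(0L, nrow = 2 * length(ids), ncol = nrow(gt))
  for (j in seq_along(ids)) {
    al <- split_alleles(gt[, j])
    hap[2 * j - 1, ] <- al[1, ]
    hap[2 * j, ] <- al[2, ]
  }
  # polarize: derived = allele differing from the ancestral call
  anc_is_alt <- aa_up == toupper(fix$ALT)
  hap[, anc_is_alt] <- 1L - hap[, anc_is_alt, drop = FALSE]

  labels <- rep(rep(names(sample_ids), vapply(sample_ids, length, integer(1))),
                each = 2)
  smp <- haplotype_sample(hap, pos - region$start, labels,
                          focal_index = NULL,
                          region_length = region$end - region$start + 1)
  attr(smp, "dropped") <- dropped
  smp
}
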