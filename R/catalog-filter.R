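#' @include catalog-io.R
NULL

#' Filter whole-genome mutation calls by depth and allele support
#'
#' Keeps calls covered by at least `minDepth` reads whose alt-allele fraction
#' lies inside the closed support window `[supportLo, supportHi]`. The
#' defaults implement the heterozygosity-style filter used for clonal
#' mutation-accumulation isolates: more than nine reads covering the site and
#' 45--55 percent of reads supporting the mutation, which removes both
#' low-coverage artifacts and subclonal calls.
#'
#' @param records mutation record data.frame with `depth` and `alt_fraction`.
#' @param minDepth minimum read depth (kept iff `depth >= minDepth`).
#' @param supportLo,supportHi inclusive alt-fraction window.
#' @return The kept records. Attribute `"rejections"` carries per-reason
#'   counts (`depth`, `support`); a record failing both is counted under
#'   both reasons.
#' @export
filterGenomeCalls <- function(records, minDepth = 10, supportLo = 0.45,
                              supportHi = 0.55) {
  if (!all(c("depth", "alt_fraction") %in% names(records)))
    stop("records must carry depth and alt_fraction")
  bad <- which(is.na(records$depth) | is.na(records$alt_fraction))
  if (length(bad))
    stop("missing depth/alt_fraction for record(s) ",
         paste(head(bad, 10L), collapse = ", "))
  failDepth <- records$depth < minDepth
  failSupport <- records$alt_fraction < supportLo |
    records$alt_fraction > supportHi
  kept <- records[!failDepth & !failSupport, , drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "rejections") <- c(depth = sum(failDepth),
                                support = sum(failSupport))
  kept
}

#' Filter reporter-gene (CAN1-style) calls by read support
#'
#' Amplicon-sequencing calls are kept when supported by at least `minReads`
#' independent reads making up strictly more than `minFraction` of all reads
#' for the sample.
#'
#' @param records data.frame with `supporting_reads` and `support_fraction`.
#' @param minReads minimum supporting reads (inclusive).
#' @param minFraction support-fraction threshold (strict `>`).
#' @return Kept records, with a `"rejections"` attribute as in
#'   [filterGenomeCalls()].
#' @export
filterCan1Calls <- function(records, minReads = 2, minFraction = 0.30) {
  if (!all(c("supporting_reads", "support_fraction") %in% names(records)))
    stop("records must carry supporting_reads and support_fraction")
  bad <- which(is.na(records$supporting_reads) |
                 is.na(records$support_fraction))
  if (length(bad))
    stop("missing read support for record(s) ",
         paste(head(bad, 10L), collapse = ", "))
  failReads <- records$supporting_reads < minReads
  failFraction <- records$support_fraction <= minFraction
  kept <- records[!failReads & !failFraction, , drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "rejections") <- c(reads = sum(failReads),
                                fraction = sum(failFraction))
  kept
}

#' Remove calls recurring across samples
#'
#' A call with the same (chrom, pos, ref, alt) key in two or more samples is
#' removed from every sample, as a likely inherited polymorphism or alignment
#' artifact rather than an independent mutation. Different alt alleles at the
#' same position are distinct keys and are retained. The operation is
#' idempotent.
#'
#' @param records combined multi-sample record data.frame (>= 2 samples).
#' @return Kept records; attribute `"removed"` holds the removed rows.
#' @export
removeRecurrent <- function(records) {
  if (length(unique(records$sample)) < 2L)
    stop("removeRecurrent needs records from at least 2 samples")
  key <- paste(records$chrom, records$pos, records$ref, records$alt,
               sep = "\r")
  nSamples <- rowsum(as.integer(!duplicated(paste(key, records$sample))),
                     key)
  recurrent <- rownames(nSamples)[nSamples[, 1L] >= 2L]
  drop <- key %in% recurrent
  kept <- records[!drop, , drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "removed") <- records[drop, , drop = FALSE]
  kept
}
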