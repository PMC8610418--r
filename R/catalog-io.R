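#' @include mutasym-package.R
NULL

# Row-level validation shared by both readers. `line` maps data rows to file
# lines so malformed rows are reported where they sit in the file.
validateRecords <- function(df, line = seq_len(nrow(df)) + 1L,
                            context = "records") {
  need <- REQUIRED_RECORD_COLS
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(context, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  bad <- function(cond, what) {
    if (any(cond))
      stop(context, ": ", what, " at line(s) ",
           paste(head(line[cond], 10L), collapse = ", "))
  }
  df$pos <- as.numeric(df$pos)
  df$depth <- as.numeric(df$depth)
  df$alt_fraction <- as.numeric(df$alt_fraction)
  bad(is.na(df$pos) | df$pos < 1 | df$pos != floor(df$pos),
      "pos must be a positive integer")
  okAllele <- function(a) grepl("^[ACGT-]+$", a)
  bad(!okAllele(df$ref), "ref allele has characters outside {A,C,G,T,-}")
  bad(!okAllele(df$alt), "alt allele has characters outside {A,C,G,T,-}")
  bad(df$ref == df$alt, "ref equals alt")
  bad(is.na(df$depth) | df$depth < 0, "depth missing or negative")
  bad(is.na(df$alt_fraction) | df$alt_fraction < 0 | df$alt_fraction > 1,
      "alt_fraction missing or outside [0, 1]")
  df
}

#' Read a per-sample mutation catalog
#'
#' Reads mutation records from the package's TSV dialect (columns `sample`,
#' `chrom`, `pos`, `ref`, `alt`, `depth`, `alt_fraction`) or from a minimal
#' single-sample VCF carrying read depth and alt-allele fraction in the
#' `DP` and `AF` INFO fields. Every row becomes exactly one record; malformed
#' rows abort with their line numbers.
#'
#' @param path file to read.
#' @param format `"tsv"` or `"vcf"`.
#' @param sample sample identifier for VCF input (defaults to the file name
#'   without extension; the TSV dialect carries its own `sample` column).
#' @return data.frame of mutation records.
#' @seealso [writeCatalogTsv()], [writeCatalogVcf()], [filterGenomeCalls()]
#' @export
readCatalog <- function(path, format = c("tsv", "vcf"), sample = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "tsv") {
    df <- read.delim(path, colClasses = "character")
    df <- validateRecords(df, context = path)
  } else {
    vcf <- VariantAnnotation::readVcf(path)
    rr <- SummarizedExperiment::rowRanges(vcf)
    info <- VariantAnnotation::info(vcf)
    if (!all(c("DP", "AF") %in% names(info)))
      stop(path, ": VCF must define DP and AF INFO fields")
    alt <- as.character(unlist(VariantAnnotation::alt(vcf)))
    if (length(alt) != length(rr))
      stop(path, ": multi-allelic rows are not supported")
    if (is.null(sample))
      sample <- sub("\\.[^.]*$", "", basename(path))
    df <- data.frame(sample = sample,
                     chrom = as.character(seqnames(rr)),
                     pos = start(rr),
                     ref = as.character(VariantAnnotation::ref(vcf)),
                     alt = alt,
                     depth = as.numeric(unlist(info$DP)),
                     alt_fraction = as.numeric(unlist(info$AF)))
    df <- validateRecords(df, context = path)
  }
  rownames(df) <- NULL
  df
}

#' Write mutation records to the TSV dialect
#'
#' @param records mutation record data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeCatalogTsv <- function(records, path) {
  validateRecords(records, context = "records")
  write.table(records[, REQUIRED_RECORD_COLS], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write one sample's records as a minimal VCF
#'
#' Emits a minimal VCFv4.2 file (one sample per file) with depth and
#' alt-allele fraction in the `DP`/`AF` INFO fields, readable by
#' [readCatalog()] and by standard VCF tooling.
#'
#' @param records records of a single sample.
#' @param path output file.
#' @param contigLengths optional named vector of chromosome lengths for
#'   `##contig` header lines.
#' @return `path`, invisibly.
#' @export
writeCatalogVcf <- function(records, path, contigLengths = NULL) {
  validateRecords(records, context = "records")
  if (length(unique(records$sample)) > 1L)
    stop("writeCatalogVcf writes one sample per file; got ",
         length(unique(records$sample)), " samples")
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##source=mutasym"),
           sprintf("##sample=%s", unique(records$sample)))
  if (!is.null(contigLengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contigLengths), as.integer(contigLengths)))
  hdr <- c(hdr,
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alt allele fraction\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  ord <- order(records$chrom, records$pos)
  records <- records[ord, ]
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\tDP=%d;AF=%s",
                  records$chrom, as.integer(records$pos), records$ref,
                  records$alt, as.integer(round(records$depth)),
                  format(records$alt_fraction, digits = 6, trim = TRUE))
  writeLines(c(hdr, body), path)
  invisible(path)
}
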