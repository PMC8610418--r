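#' @include catalog-filter.R
NULL

# Classify a single-record event from its allele lengths. "-" denotes the
# empty allele in breakpoint-style indel notation.
classifySingleton <- function(ref, alt) {
  refLen <- ifelse(ref == "-", 0L, nchar(ref))
  altLen <- ifelse(alt == "-", 0L, nchar(alt))
  ifelse(refLen == altLen, "substitution",
         ifelse(altLen > refLen, "insertion", "deletion"))
}

#' Cluster nearby mutation records into events
#'
#' Single-linkage chaining within each (sample, chromosome): consecutive
#' records whose start positions differ by at most `maxGap` bp join the same
#' event. Events of two or more records are complex mutations; isolated
#' records are classified as substitution, insertion, or deletion by allele
#' lengths (equal-length multi-nucleotide alleles count as block
#' substitutions occupying their span).
#'
#' @param records mutation record data.frame; a `sample` column is optional
#'   (absent means a single sample).
#' @param maxGap maximum start-position difference (bp) joining neighbours.
#' @param sort sort unsorted input internally (default); with `sort = FALSE`
#'   unsorted input is an error.
#' @return data.frame of events (`sample`, `chrom`, `start`, `end`,
#'   `event_class`, `n_records`, `ref`, `alt`; alleles are NA for complex
#'   events), sorted by sample, chromosome and start. Attribute
#'   `"membership"` gives each input record's event row index, in input
#'   order, so that events partition the records.
#' @export
clusterEvents <- function(records, maxGap = 10, sort = TRUE) {
  if (!nrow(records)) {
    ev <- data.frame(sample = character(), chrom = character(),
                     start = numeric(), end = numeric(),
                     event_class = character(), n_records = integer(),
                     ref = character(), alt = character())
    attr(ev, "membership") <- integer()
    return(ev)
  }
  sample <- if ("sample" %in% names(records)) records$sample else ""
  ord <- order(sample, records$chrom, records$pos)
  if (!identical(ord, seq_len(nrow(records)))) {
    if (!sort) stop("records are not sorted by (sample, chrom, pos)")
    message("clusterEvents: sorting records by (sample, chrom, pos)")
  }
  r <- records[ord, , drop = FALSE]
  s <- sample[ord]
  grp <- paste(s, r$chrom, sep = "\r")
  n <- nrow(r)
  sameGrp <- c(FALSE, grp[-1L] == grp[-n])
  gap <- c(NA_real_, diff(r$pos))
  newEvent <- !(sameGrp & gap <= maxGap)
  eid <- cumsum(newEvent)
  nRec <- tabulate(eid)
  first <- which(newEvent)
  refWidth <- ifelse(r$ref == "-", 1L, nchar(r$ref))
  endPos <- r$pos + refWidth - 1L
  ev <- data.frame(
    sample = s[first],
    chrom = r$chrom[first],
    start = r$pos[first],
    end = as.numeric(tapply(endPos, eid, max)),
    n_records = nRec)
  ev$event_class <- ifelse(ev$n_records >= 2L, "complex",
                           classifySingleton(r$ref[first], r$alt[first]))
  ev$ref <- ifelse(ev$n_records >= 2L, NA_character_, r$ref[first])
  ev$alt <- ifelse(ev$n_records >= 2L, NA_character_, r$alt[first])
  ev <- ev[, c("sample", "chrom", "start", "end", "event_class",
               "n_records", "ref", "alt")]
  rownames(ev) <- NULL
  membership <- integer(n)
  membership[ord] <- eid
  attr(ev, "membership") <- membership
  ev
}

#' Construct a SampleCatalog
#'
#' Bundles one sample's mutation records with the events produced by
#' [clusterEvents()].
#'
#' @param records records of a single sample.
#' @param sampleId,genotype,treatment labels; `sampleId` defaults to the
#'   records' `sample` column.
#' @param maxGap passed to [clusterEvents()].
#' @return A [SampleCatalog-class] object.
#' @export
SampleCatalog <- function(records, sampleId = NULL, genotype = "",
                          treatment = "", maxGap = 10) {
  present <- if ("sample" %in% names(records)) unique(records$sample)
             else character()
  if (is.null(sampleId)) {
    if (length(present) != 1L)
      stop("records contain ", length(present),
           " samples; supply sampleId or subset first")
    sampleId <- present
  } else if (length(present) > 1L) {
    if (!sampleId %in% present)
      stop("sampleId '", sampleId, "' not found among the records' samples")
    records <- records[records$sample == sampleId, , drop = FALSE]
  }
  records$sample <- sampleId  # relabel single-sample records
  ord <- order(records$chrom, records$pos)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  ev <- clusterEvents(records, maxGap = maxGap)
  attr(ev, "membership") <- NULL
  new("SampleCatalog", sampleId = as.character(sampleId),
      genotype = as.character(genotype), treatment = as.character(treatment),
      records = records, events = ev)
}

#' Combine catalogs into one tidy event table
#'
#' @param catalogs list of [SampleCatalog-class] objects.
#' @return data.frame of events with `genotype` and `treatment` columns
#'   added, suitable for [perGenomeBurden()] and friends. Attribute
#'   `"samples"` maps every sample (including zero-burden ones) to its
#'   labels.
#' @export
combineEvents <- function(catalogs) {
  stopifnot(length(catalogs) >= 1L,
            all(vapply(catalogs, is, logical(1L), "SampleCatalog")))
  ids <- vapply(catalogs, sampleId, character(1L))
  if (anyDuplicated(ids))
    stop("duplicate sampleId(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  ev <- do.call(rbind, lapply(catalogs, function(ct) {
    ev <- events(ct)
    if (nrow(ev) == 0L) return(NULL)
    ev$sample <- sampleId(ct)
    ev$genotype <- genotype(ct)
    ev$treatment <- ct@treatment
    ev
  }))
  if (is.null(ev))
    ev <- data.frame(sample = character(), chrom = character(),
                     start = numeric(), end = numeric(),
                     event_class = character(), n_records = integer(),
                     ref = character(), alt = character(),
                     genotype = character(), treatment = character())
  rownames(ev) <- NULL
  attr(ev, "samples") <- data.frame(
    sample = vapply(catalogs, sampleId, character(1L)),
    genotype = vapply(catalogs, genotype, character(1L)),
    treatment = vapply(catalogs, function(ct) ct@treatment, character(1L)))
  ev
}
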