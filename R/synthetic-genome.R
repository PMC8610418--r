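#' @include mutasym-package.R
NULL

TX_FLANK_TOTAL <- 1500L  # reserved flank either side of a transcript, bp

#' Parameters for a synthetic reference genome
#'
#' Describes a toy genome used as ground truth for the analysis pipeline:
#' random sequence of a given GC content, non-overlapping stranded
#' transcripts with reserved 1500-bp flanks, and per-chromosome replication
#' origin maps.
#'
#' @param seed RNG seed (all generator functions are deterministic for a
#'   fixed seed).
#' @param nChromosomes,chromLength chromosome count and length (bp).
#' @param gcFraction genome GC content in [0, 1].
#' @param nTranscripts total transcripts, distributed round-robin across
#'   chromosomes.
#' @param transcriptLengthRange min/max transcript length (bp).
#' @param intergenicMin minimum gap between transcript flank blocks (bp).
#' @param originsPerChromosome replication origins per chromosome (>= 2).
#' @return validated parameter list of class `"SyntheticGenomeSpec"`.
#' @export
genomeSpec <- function(seed = 1L, nChromosomes = 2L, chromLength = 200000L,
                       gcFraction = 0.38, nTranscripts = 20L,
                       transcriptLengthRange = c(1000L, 4000L),
                       intergenicMin = 500L, originsPerChromosome = 4L) {
  .assertCount(nChromosomes, "nChromosomes", 1L)
  .assertCount(chromLength, "chromLength", 1L)
  .assertProportion(gcFraction, "gcFraction")
  .assertCount(nTranscripts, "nTranscripts", 0L)
  .assertCount(intergenicMin, "intergenicMin", 0L)
  .assertCount(originsPerChromosome, "originsPerChromosome", 2L)
  stopifnot(length(transcriptLengthRange) == 2L,
            transcriptLengthRange[1L] >= 1,
            transcriptLengthRange[1L] <= transcriptLengthRange[2L])
  if (chromLength <= transcriptLengthRange[2L] + 2L * TX_FLANK_TOTAL)
    stop("chromLength must exceed the maximum transcript length plus ",
         2L * TX_FLANK_TOTAL, " bp of flanks")
  structure(list(seed = as.integer(seed),
                 nChromosomes = as.integer(nChromosomes),
                 chromLength = as.integer(chromLength),
                 gcFraction = gcFraction,
                 nTranscripts = as.integer(nTranscripts),
                 transcriptLengthRange = as.integer(transcriptLengthRange),
                 intergenicMin = as.integer(intergenicMin),
                 originsPerChromosome = as.integer(originsPerChromosome)),
            class = "SyntheticGenomeSpec")
}

# Random composition of `slack` bp into n parts (non-negative integers).
.randomGaps <- function(slack, n) {
  if (n == 1L) return(slack)
  cuts <- sort(runif(n - 1L))
  diff(c(0, cuts, 1)) * slack
}

#' Generate a synthetic reference genome, transcripts, and origin map
#'
#' Produces a random genome of the requested GC content, places
#' non-overlapping transcripts (reserving 1500 bp flanks on each side plus
#' a minimum intergenic gap) with random strands, and lays out replication
#' origins roughly evenly with random jitter. Deterministic for a fixed
#' seed.
#'
#' @param spec a [genomeSpec()].
#' @return list with `genome` (named `DNAStringSet`), `transcripts`
#'   (`GRanges` with strand and `name`), `origins` (`GRanges` of origin
#'   midpoints).
#' @export
makeReference <- function(spec) {
  stopifnot(inherits(spec, "SyntheticGenomeSpec"))
  withSeed(spec$seed, {
    chroms <- paste0("chr", seq_len(spec$nChromosomes))
    probs <- c(A = (1 - spec$gcFraction) / 2, C = spec$gcFraction / 2,
               G = spec$gcFraction / 2, T = (1 - spec$gcFraction) / 2)
    genome <- DNAStringSet(vapply(chroms, function(ch)
      paste(sample(DNA_BASES, spec$chromLength, replace = TRUE,
                   prob = probs), collapse = ""), character(1L)))
    names(genome) <- chroms

    perChrom <- tabulate(rep(seq_len(spec$nChromosomes),
                             length.out = spec$nTranscripts),
                         nbins = spec$nChromosomes)
    txRows <- list()
    txCounter <- 0L
    for (ci in seq_len(spec$nChromosomes)) {
      nTx <- perChrom[ci]
      if (nTx == 0L) next
      lens <- sample(seq(spec$transcriptLengthRange[1L],
                         spec$transcriptLengthRange[2L]), nTx,
                     replace = TRUE)
      need <- sum(lens + 2L * TX_FLANK_TOTAL) +
        (nTx + 1L) * spec$intergenicMin
      if (need > spec$chromLength)
        stop("cannot place ", nTx, " transcripts on a ",
             spec$chromLength, " bp chromosome: ", need, " bp required")
      gaps <- .randomGaps(spec$chromLength - need, nTx + 1L)
      cursor <- 0
      for (j in seq_len(nTx)) {
        cursor <- cursor + spec$intergenicMin + gaps[j] + TX_FLANK_TOTAL
        start <- floor(cursor) + 1L
        end <- start + lens[j] - 1L
        cursor <- end + TX_FLANK_TOTAL
        txCounter <- txCounter + 1L
        txRows[[txCounter]] <- data.frame(
          chrom = chroms[ci], start = start, end = end,
          strand = sample(c("+", "-"), 1L),
          name = sprintf("tx%03d", txCounter))
      }
    }
    tx <- do.call(rbind, txRows)
    transcripts <- if (is.null(tx)) GRanges() else
      GRanges(tx$chrom, IRanges(tx$start, tx$end), strand = tx$strand,
              name = tx$name)

    k <- spec$originsPerChromosome
    oriRows <- lapply(seq_len(spec$nChromosomes), function(ci) {
      base <- spec$chromLength * (seq_len(k) - 0.5) / k
      jitter <- runif(k, -1, 1) * spec$chromLength / (20 * k)
      o <- sort(round(base + jitter))
      o <- pmin(pmax(o, 1), spec$chromLength)
      if (any(diff(o) <= 0)) o <- cummax(o) + (seq_along(o) - 1L)
      data.frame(chrom = chroms[ci], pos = o)
    })
    ori <- do.call(rbind, oriRows)
    origins <- GRanges(ori$chrom, IRanges(ori$pos, width = 1L))

    list(genome = genome, transcripts = transcripts, origins = origins)
  })
}

#' Write a synthetic reference to disk
#'
#' Genome as FASTA, transcripts and origins as BED (transcripts with strand),
#' and the generating parameters as a JSON sidecar when jsonlite is
#' available. The files round-trip through `Biostrings::readDNAStringSet`
#' and `rtracklayer::import`.
#'
#' @param reference output of [makeReference()].
#' @param dir output directory (created if needed).
#' @param spec optional [genomeSpec()] echoed to `params.json`.
#' @return `dir`, invisibly.
#' @export
writeReference <- function(reference, dir, spec = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeXStringSet(reference$genome, file.path(dir, "genome.fa"))
  tx <- reference$transcripts
  S4Vectors::mcols(tx)$score <- 0
  rtracklayer::export(tx, file.path(dir, "transcripts.bed"))
  rtracklayer::export(reference$origins, file.path(dir, "origins.bed"))
  if (!is.null(spec) && requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(unclass(spec), file.path(dir, "params.json"),
                         auto_unbox = TRUE)
  invisible(dir)
}
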