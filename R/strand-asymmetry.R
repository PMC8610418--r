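#' @include spectrum.R
NULL

#' Ordered bin labels for transcription profiles
#'
#' Upstream flank bins run outward from the TSS (`-1` abuts the TSS),
#' body bins `1..bodyBins` run TSS to TTS in transcript orientation, and
#' downstream flank bins `+1..+flankBins` run outward from the TTS.
#'
#' @param bodyBins,flankBins bin counts.
#' @return character vector of labels in profile order.
#' @export
transcriptionBinLevels <- function(bodyBins = 5, flankBins = 3) {
  c(paste0("-", rev(seq_len(flankBins))),
    as.character(seq_len(bodyBins)),
    paste0("+", seq_len(flankBins)))
}

#' Assign a position to a fractional transcript bin
#'
#' Positions inside the transcript map to `bodyBins` equal fractional bins
#' (default 0.2 of the transcript length each) in transcript orientation;
#' positions within `flankBins * flankSize` bp upstream of the TSS map to
#' bins `-flankBins..-1` and downstream of the TTS to `+1..+flankBins`
#' (500 bp each by default). Everything else maps to NA.
#'
#' @param pos positions (1-based, vectorised).
#' @param txStart,txEnd transcript span (1-based, inclusive).
#' @param txStrand `"+"` or `"-"`.
#' @param bodyBins,flankBins,flankSize binning parameters.
#' @return factor with levels [transcriptionBinLevels()]; NA outside scope.
#' @export
assignTranscriptionBin <- function(pos, txStart, txEnd, txStrand,
                                   bodyBins = 5, flankBins = 3,
                                   flankSize = 500) {
  stopifnot(txStart < txEnd, txStrand %in% c("+", "-"))
  w <- txEnd - txStart + 1
  out <- rep(NA_character_, length(pos))
  inside <- pos >= txStart & pos <= txEnd
  frac <- if (txStrand == "+") (pos - txStart) / w else (txEnd - pos) / w
  out[inside] <- as.character(pmin(floor(bodyBins * frac[inside]) + 1L,
                                   bodyBins))
  # distance upstream of the TSS / downstream of the TTS, in orientation
  dUp <- if (txStrand == "+") txStart - pos else pos - txEnd
  dDn <- if (txStrand == "+") pos - txEnd else txStart - pos
  up <- dUp >= 1 & dUp <= flankBins * flankSize
  dn <- dDn >= 1 & dDn <= flankBins * flankSize
  out[up] <- paste0("-", ceiling(dUp[up] / flankSize))
  out[dn] <- paste0("+", ceiling(dDn[dn] / flankSize))
  factor(out, levels = transcriptionBinLevels(bodyBins, flankBins))
}

#' Strand identity of a mutated base
#'
#' Reads the reference base on the top (Watson) strand and reports which of
#' the two strand-symmetric base identities (A or C) was mutated and on
#' which strand of the given frame it sits. The non-transcribed strand is
#' the mRNA-like (coding) strand, i.e. the top strand for a `+` transcript.
#'
#' @param ref single reference bases as read on the top strand (vectorised).
#' @param frameStrand frame strand, `"+"` or `"-"`: a transcript's strand
#'   for transcription profiles, or `"+"` for the fixed top/bottom frame of
#'   replication profiles.
#' @return data.frame with `base` (`"A"` or `"C"`), `top_strand` (logical:
#'   the mutated base lies on the top strand), and `strand` (label
#'   `"non_transcribed"`/`"transcribed"`, or `"top"`/`"bottom"` when
#'   `labels = "replication"`).
#' @param labels `"transcription"` or `"replication"` label set.
#' @export
strandMutatedBase <- function(ref, frameStrand = "+",
                              labels = c("transcription", "replication")) {
  labels <- match.arg(labels)
  if (!all(nchar(ref) == 1L))
    stop("strandMutatedBase expects single-base substitutions; ",
         "indels must be excluded upstream")
  if (!all(ref %in% DNA_BASES)) stop("non-ACGT base")
  onTop <- ref %in% c("A", "C")
  base <- ifelse(onTop, ref, COMPLEMENT[ref])
  if (labels == "replication") {
    strand <- ifelse(onTop, "top", "bottom")
  } else {
    stopifnot(all(frameStrand %in% c("+", "-")))
    plus <- frameStrand == "+"
    # + transcript: top strand is the coding / non-transcribed strand
    strand <- ifelse(onTop == plus, "non_transcribed", "transcribed")
  }
  data.frame(base = unname(base), top_strand = onTop, strand = strand)
}

.snvRecords <- function(records) {
  snv <- nchar(records$ref) == 1L & nchar(records$alt) == 1L &
    records$ref %in% DNA_BASES & records$alt %in% DNA_BASES
  list(snv = records[snv, , drop = FALSE], nExcluded = sum(!snv))
}

#' Transcriptional strand-asymmetry profile
#'
#' For every transcript, assigns substitutions to fractional body bins and
#' fixed-width flank bins, attributes each mutated A or C to the transcribed
#' or non-transcribed strand, and normalises counts by the number of A or C
#' bases of that strand present in the bin (mutational opportunity, from the
#' reference genome). Mutations under overlapping transcripts are counted
#' once per transcript, since each transcript defines its own frame.
#'
#' @param records mutation record data.frame (only single-base substitutions
#'   contribute; indels are excluded and counted).
#' @param transcripts `GRanges` with strand.
#' @param genome named `DNAStringSet` matching the transcript seqnames.
#' @param bodyBins,flankBins,flankSize see [assignTranscriptionBin()].
#' @return A [TranscriptionProfile-class].
#' @export
transcriptionDensityProfile <- function(records, transcripts, genome,
                                        bodyBins = 5, flankBins = 3,
                                        flankSize = 500) {
  sr <- .snvRecords(records)
  snv <- sr$snv
  levs <- transcriptionBinLevels(bodyBins, flankBins)
  strands <- c("transcribed", "non_transcribed")
  mut <- opp <- array(0L, dim = c(length(levs), 2L, 2L),
                      dimnames = list(bin = levs, base = c("A", "C"),
                                      strand = strands))
  nInScope <- 0L
  for (i in seq_along(transcripts)) {
    chrom <- as.character(seqnames(transcripts)[i])
    if (!chrom %in% names(genome))
      stop("transcript on unknown chromosome: ", chrom)
    s <- start(transcripts)[i]; e <- end(transcripts)[i]
    st <- as.character(strand(transcripts)[i])
    if (!st %in% c("+", "-"))
      stop("transcript ", i, " has no strand")
    chromLen <- width(genome[chrom])
    if (s < 1 || e > chromLen) stop("transcript outside genome bounds")
    lo <- max(1L, s - flankBins * flankSize)
    hi <- min(chromLen, e + flankBins * flankSize)
    posAll <- lo:hi
    baseAll <- strsplit(as.character(subseq(genome[[chrom]], lo, hi)),
                        "", fixed = TRUE)[[1L]]
    binAll <- assignTranscriptionBin(posAll, s, e, st, bodyBins, flankBins,
                                     flankSize)
    use <- !is.na(binAll) & baseAll %in% DNA_BASES
    sb <- strandMutatedBase(baseAll[use], st)
    opp <- opp + table(bin = binAll[use],
                       base = factor(sb$base, c("A", "C")),
                       strand = factor(sb$strand, strands))
    hit <- snv$chrom == chrom & snv$pos >= lo & snv$pos <= hi
    if (any(hit)) {
      binMut <- assignTranscriptionBin(snv$pos[hit], s, e, st, bodyBins,
                                       flankBins, flankSize)
      ok <- !is.na(binMut)
      if (any(ok)) {
        mb <- strandMutatedBase(snv$ref[hit][ok], st)
        mut <- mut + table(bin = binMut[ok],
                           base = factor(mb$base, c("A", "C")),
                           strand = factor(mb$strand, strands))
        nInScope <- nInScope + sum(ok)
      }
    }
  }
  bins <- expand.grid(bin = factor(levs, levels = levs),
                      base = c("A", "C"), strand = strands,
                      stringsAsFactors = FALSE)
  idx <- cbind(as.character(bins$bin), bins$base, bins$strand)
  bins$mutation_count <- as.integer(mut[idx])
  bins$opportunity_count <- as.integer(opp[idx])
  bins$density <- ifelse(bins$opportunity_count > 0,
                         bins$mutation_count / bins$opportunity_count,
                         NA_real_)
  bins <- bins[, c("base", "strand", "bin", "mutation_count",
                   "opportunity_count", "density")]
  new("TranscriptionProfile", bins = bins, bodyBins = as.integer(bodyBins),
      flankBins = as.integer(flankBins), flankSize = as.integer(flankSize),
      nInScope = as.integer(nInScope),
      nExcludedIndels = as.integer(sr$nExcluded))
}

.originVector <- function(origins) {
  if (is(origins, "GRanges")) {
    mids <- floor((start(origins) + end(origins)) / 2)
    split(mids, as.character(seqnames(origins)))
  } else if (is.list(origins)) {
    origins
  } else stop("origins must be a GRanges or a named list of positions")
}

#' Assign positions to fractional inter-origin bins
#'
#' For a position strictly between neighbouring origins `o_i < o_{i+1}`, the
#' fractional coordinate is `(pos - o_i) / (o_{i+1} - o_i)` and the bin is
#' `floor(nBins * fraction)` clipped to `nBins - 1`. A position sitting
#' exactly on an origin starts bin 0 of the rightward interval; positions
#' before the first or after the last origin are out of scope (NA).
#'
#' @param pos positions (vectorised).
#' @param origins strictly increasing origin midpoints for one chromosome
#'   (>= 2).
#' @param nBins number of fractional bins.
#' @return data.frame `bin` (0-based), `interval` (index of the left
#'   origin), `fraction`; NA rows are out of scope.
#' @export
assignReplicationBin <- function(pos, origins, nBins = 10) {
  origins <- as.numeric(origins)
  if (length(origins) < 2L || is.unsorted(origins, strictly = TRUE))
    stop("origins must be >= 2 strictly increasing positions")
  i <- findInterval(pos, origins)
  ok <- i >= 1L & i < length(origins)
  frac <- rep(NA_real_, length(pos))
  frac[ok] <- (pos[ok] - origins[i[ok]]) /
    (origins[i[ok] + 1L] - origins[i[ok]])
  bin <- ifelse(ok, pmin(floor(nBins * frac), nBins - 1L), NA_integer_)
  data.frame(bin = as.integer(bin),
             interval = ifelse(ok, i, NA_integer_), fraction = frac)
}

#' Replicative strand-asymmetry profile
#'
#' Bins substitutions by fractional position between neighbouring
#' replication origins and computes, per bin, the fraction of A (and C)
#' mutations whose mutated base lies on the top versus bottom strand.
#' Fractions are complementary by construction; empty bins are flagged NA,
#' not imputed. Ordinary least-squares trend lines are fitted per base and
#' strand via [fitAsymmetryRegression()].
#'
#' @param records mutation record data.frame.
#' @param origins `GRanges` of origins or a named per-chromosome list of
#'   midpoint positions.
#' @param nBins fractional bins per inter-origin interval.
#' @return A [ReplicationProfile-class].
#' @export
replicationFractionProfile <- function(records, origins, nBins = 10) {
  sr <- .snvRecords(records)
  snv <- sr$snv
  originsByChrom <- .originVector(origins)
  counts <- array(0L, dim = c(nBins, 2L, 2L),
                  dimnames = list(bin = as.character(seq_len(nBins) - 1L),
                                  base = c("A", "C"),
                                  strand = c("top", "bottom")))
  nInScope <- 0L
  for (chrom in intersect(unique(snv$chrom), names(originsByChrom))) {
    rec <- snv[snv$chrom == chrom, , drop = FALSE]
    ab <- assignReplicationBin(rec$pos, originsByChrom[[chrom]], nBins)
    ok <- !is.na(ab$bin)
    if (!any(ok)) next
    sb <- strandMutatedBase(rec$ref[ok], labels = "replication")
    counts <- counts + table(bin = factor(ab$bin[ok],
                                          seq_len(nBins) - 1L),
                             base = factor(sb$base, c("A", "C")),
                             strand = factor(sb$strand, c("top", "bottom")))
    nInScope <- nInScope + sum(ok)
  }
  bins <- expand.grid(bin = seq_len(nBins) - 1L, base = c("A", "C"),
                      stringsAsFactors = FALSE)
  idx <- cbind(as.character(bins$bin), bins$base)
  bins$n_top <- as.integer(counts[cbind(idx, "top")])
  bins$n_bottom <- as.integer(counts[cbind(idx, "bottom")])
  tot <- bins$n_top + bins$n_bottom
  bins$fraction_top <- ifelse(tot > 0, bins$n_top / tot, NA_real_)
  bins$fraction_bottom <- ifelse(tot > 0, bins$n_bottom / tot, NA_real_)
  bins$bin_center <- (bins$bin + 0.5) / nBins
  bins <- bins[, c("base", "bin", "bin_center", "n_top", "n_bottom",
                   "fraction_top", "fraction_bottom")]
  fits <- fitAsymmetryRegression(bins)
  new("ReplicationProfile", bins = bins, fits = fits,
      nBins = as.integer(nBins), nInScope = as.integer(nInScope))
}

#' Fit linear trends to per-strand mutation fractions
#'
#' Ordinary least squares of the per-bin strand fraction against the bin
#' centre on the fractional inter-origin coordinate, one fit per base and
#' strand. Because top and bottom fractions are complementary, their slopes
#' are equal in magnitude and opposite in sign.
#'
#' @param bins a [ReplicationProfile-class] or its bin data.frame (columns
#'   `base`, `bin_center`, `fraction_top`, `fraction_bottom`).
#' @param conf confidence level for the slope interval.
#' @return data.frame `base`, `strand`, `slope`, `intercept`, `r_squared`,
#'   `slope_se`, `ci_lo`, `ci_hi`, `n_bins`.
#' @export
fitAsymmetryRegression <- function(bins, conf = 0.95) {
  if (is(bins, "ReplicationProfile")) bins <- profileBins(bins)
  out <- list()
  for (b in unique(bins$base)) {
    sub <- bins[bins$base == b, ]
    for (side in c("top", "bottom")) {
      y <- sub[[paste0("fraction_", side)]]
      ok <- !is.na(y)
      if (sum(ok) < 2L) {
        out[[paste(b, side)]] <- data.frame(
          base = b, strand = side, slope = NA_real_, intercept = NA_real_,
          r_squared = NA_real_, slope_se = NA_real_, ci_lo = NA_real_,
          ci_hi = NA_real_, n_bins = sum(ok))
        next
      }
      fit <- lm(y[ok] ~ sub$bin_center[ok])
      sm <- suppressWarnings(summary(fit))  # exact fits are legitimate here
      cf <- coef(fit)
      ssTot <- sum((y[ok] - mean(y[ok]))^2)
      ssRes <- sum(fit$residuals^2)
      r2 <- if (ssTot < 1e-24) 1 else 1 - ssRes / ssTot
      se <- sm$coefficients[2L, 2L]
      z <- -qnorm((1 - conf) / 2)
      ci <- if (sum(ok) > 2L)
              suppressWarnings(confint(fit, level = conf))[2L, ]
            else cf[2L] + c(-1, 1) * z * se
      out[[paste(b, side)]] <- data.frame(
        base = b, strand = side, slope = unname(cf[2L]),
        intercept = unname(cf[1L]), r_squared = max(0, min(1, r2)),
        slope_se = se, ci_lo = unname(ci[1L]), ci_hi = unname(ci[2L]),
        n_bins = sum(ok))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
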