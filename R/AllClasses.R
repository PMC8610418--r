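#' @include mutasym-package.R
NULL

REQUIRED_RECORD_COLS <- c("sample", "chrom", "pos", "ref", "alt",
                          "depth", "alt_fraction")

#' SampleCatalog: one sample's filtered, clustered mutation catalog
#'
#' Holds the mutation records called in one sequenced isolate together with
#' the events derived from them by [clusterEvents()]: runs of records on the
#' same chromosome separated by at most 10 bp form a single complex event,
#' and isolated records are classified as substitutions, insertions, or
#' deletions by their allele lengths.
#'
#' @slot sampleId single sample identifier.
#' @slot genotype,treatment free-text group labels (e.g. strain and exposure).
#' @slot records data.frame of mutation records (columns `sample`, `chrom`,
#'   `pos`, `ref`, `alt`, `depth`, `alt_fraction`).
#' @slot events data.frame of clustered events (columns `sample`, `chrom`,
#'   `start`, `end`, `event_class`, `n_records`, `ref`, `alt`), sorted by
#'   chromosome and start.
#' @seealso [SampleCatalog()], [clusterEvents()]
#' @exportClass SampleCatalog
setClass("SampleCatalog",
  slots = c(sampleId = "character", genotype = "character",
            treatment = "character", records = "data.frame",
            events = "data.frame"))

setValidity("SampleCatalog", function(object) {
  msg <- character()
  if (length(object@sampleId) != 1L)
    msg <- c(msg, "sampleId must be a single string")
  ev <- object@events
  if (nrow(ev)) {
    o <- order(ev$chrom, ev$start)
    if (!identical(o, seq_len(nrow(ev))))
      msg <- c(msg, "events must be sorted by (chrom, start)")
  }
  rec <- object@records
  if (nrow(rec) && anyDuplicated(paste(rec$chrom, rec$pos)))
    msg <- c(msg, "duplicate positions within a sample")
  if (length(msg)) msg else TRUE
})

#' TranscriptionProfile: strand-resolved mutation densities across transcripts
#'
#' Mutation densities (mutated bases per base of opportunity) for A and C
#' bases on the transcribed and non-transcribed strands, across fractional
#' transcript-body bins and fixed-width flanking bins upstream of the TSS and
#' downstream of the TTS.
#'
#' @slot bins data.frame with columns `base` (A/C), `strand`
#'   (transcribed/non_transcribed), `bin` (ordered factor, e.g. "-3".."-1",
#'   "1".."5", "+1".."+3"), `mutation_count`, `opportunity_count`, `density`.
#' @slot bodyBins,flankBins,flankSize binning parameters (counts and bp).
#' @slot nInScope number of (record, transcript) substitution assignments.
#' @slot nExcludedIndels indel/MNV records excluded from the profile.
#' @exportClass TranscriptionProfile
setClass("TranscriptionProfile",
  slots = c(bins = "data.frame", bodyBins = "integer", flankBins = "integer",
            flankSize = "integer", nInScope = "integer",
            nExcludedIndels = "integer"))

#' ReplicationProfile: per-strand mutation fractions between origins
#'
#' For each fractional bin of the interval between neighbouring replication
#' origins, the fraction of A (and C) mutations whose mutated base lies on
#' the top versus the bottom strand, with ordinary least-squares trend lines.
#'
#' @slot bins data.frame with columns `base`, `bin` (0..nBins-1),
#'   `bin_center` (fractional inter-origin coordinate), `n_top`, `n_bottom`,
#'   `fraction_top`, `fraction_bottom` (NA for empty bins, flagged not
#'   imputed).
#' @slot fits data.frame of per-base, per-strand regression fits
#'   (see [fitAsymmetryRegression()]).
#' @slot nBins number of fractional bins.
#' @slot nInScope substitutions falling between origins.
#' @exportClass ReplicationProfile
setClass("ReplicationProfile",
  slots = c(bins = "data.frame", fits = "data.frame", nBins = "integer",
            nInScope = "integer"))

#' FluctuationResult: mutation-rate estimate from a fluctuation assay
#'
#' @slot estimator "lea_coulson" (method of the median) or "frequency".
#' @slot rate mutations per cell per division/generation.
#' @slot rateCI approximate 95 percent confidence interval (NA when the
#'   estimator provides none).
#' @slot m expected mutation events per culture (Lea-Coulson only).
#' @slot medianCount median resistant-colony count across cultures.
#' @slot nCultures,nCells bookkeeping.
#' @slot upperBound TRUE when every culture had zero resistant colonies and
#'   the reported rate is an upper bound (p0-style fallback).
#' @exportClass FluctuationResult
setClass("FluctuationResult",
  slots = c(estimator = "character", rate = "numeric", rateCI = "numeric",
            m = "numeric", medianCount = "numeric", nCultures = "integer",
            nCells = "numeric", upperBound = "logical"))

#' BindingFit: quadratic one-site binding fit of anisotropy titrations
#'
#' Nonlinear least-squares fit of baseline-subtracted anisotropy versus
#' titrant concentration to the ligand-depletion (quadratic) one-site model
#' \eqn{Y = M((x+D+K_d) - \sqrt{(x+D+K_d)^2 - 4Dx})/(2D)}.
#'
#' @slot perReplicate data.frame with one row per replicate: `replicate`,
#'   `kd`, `m`, `y0` (0 unless a free offset was requested), `rss`,
#'   `converged`, `boundary`.
#' @slot kd,kdSD mean and SD of Kd across converged replicates (nM).
#' @slot m,mSD mean and SD of the amplitude M.
#' @slot d labeled-substrate concentration D (nM).
#' @slot mode "per_replicate" or "pooled".
#' @exportClass BindingFit
setClass("BindingFit",
  slots = c(perReplicate = "data.frame", kd = "numeric", kdSD = "numeric",
            m = "numeric", mSD = "numeric", d = "numeric", mode = "character"))
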