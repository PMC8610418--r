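#' @include AllClasses.R
NULL

#' Accessors for mutasym result objects
#'
#' `records()` and `events()` return the record/event tables of a
#' [SampleCatalog-class]; `sampleId()` and `genotype()` its labels.
#' `profileBins()` returns the bin table of a profile object and
#' `asymmetryFits()` the regression table of a [ReplicationProfile-class].
#' `mutationRate()` extracts the estimate from a [FluctuationResult-class];
#' `kdEstimate()` and `amplitude()` extract `Kd` and `M` from a
#' [BindingFit-class].
#'
#' @param x a mutasym result object.
#' @return The corresponding slot, as a data.frame or numeric.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))
#' @rdname accessors
#' @export
setGeneric("events", function(x) standardGeneric("events"))
#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setGeneric("genotype", function(x) standardGeneric("genotype"))
#' @rdname accessors
#' @export
setGeneric("profileBins", function(x) standardGeneric("profileBins"))
#' @rdname accessors
#' @export
setGeneric("asymmetryFits", function(x) standardGeneric("asymmetryFits"))
#' @rdname accessors
#' @export
setGeneric("mutationRate", function(x) standardGeneric("mutationRate"))
#' @rdname accessors
#' @export
setGeneric("kdEstimate", function(x) standardGeneric("kdEstimate"))
#' @rdname accessors
#' @export
setGeneric("amplitude", function(x) standardGeneric("amplitude"))

#' @rdname accessors
setMethod("records", "SampleCatalog", function(x) x@records)
#' @rdname accessors
setMethod("events", "SampleCatalog", function(x) x@events)
#' @rdname accessors
setMethod("sampleId", "SampleCatalog", function(x) x@sampleId)
#' @rdname accessors
setMethod("genotype", "SampleCatalog", function(x) x@genotype)
#' @rdname accessors
setMethod("profileBins", "TranscriptionProfile", function(x) x@bins)
#' @rdname accessors
setMethod("profileBins", "ReplicationProfile", function(x) x@bins)
#' @rdname accessors
setMethod("asymmetryFits", "ReplicationProfile", function(x) x@fits)
#' @rdname accessors
setMethod("mutationRate", "FluctuationResult", function(x) x@rate)
#' @rdname accessors
setMethod("kdEstimate", "BindingFit", function(x) x@kd)
#' @rdname accessors
setMethod("amplitude", "BindingFit", function(x) x@m)

setMethod("show", "SampleCatalog", function(object) {
  cat("SampleCatalog:", object@sampleId,
      sprintf("[%s/%s]", object@genotype, object@treatment), "\n")
  cat(" ", nrow(object@records), "records in", nrow(object@events),
      "events\n")
  if (nrow(object@events)) {
    tab <- table(object@events$event_class)
    cat("  ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
})

setMethod("show", "TranscriptionProfile", function(object) {
  cat("TranscriptionProfile:", object@bodyBins, "body bins +",
      object@flankBins, "x", object@flankSize, "bp flank bins per side\n")
  cat(" ", object@nInScope, "substitution-in-transcript assignments;",
      object@nExcludedIndels, "non-SNV records excluded\n")
})

setMethod("show", "ReplicationProfile", function(object) {
  cat("ReplicationProfile:", object@nBins, "fractional inter-origin bins,",
      object@nInScope, "substitutions in scope\n")
  f <- object@fits
  for (i in seq_len(nrow(f)))
    cat(sprintf("  %s %s: slope %+0.4f (R^2 %.3f)\n",
                f$base[i], f$strand[i], f$slope[i], f$r_squared[i]))
})

setMethod("show", "FluctuationResult", function(object) {
  cat("FluctuationResult (", object@estimator, "): rate = ",
      format(object@rate, digits = 4), " per cell per generation\n",
      sep = "")
  if (!anyNA(object@rateCI))
    cat("  95% CI [", format(object@rateCI[1], digits = 4), ", ",
        format(object@rateCI[2], digits = 4), "]\n", sep = "")
  if (object@upperBound) cat("  NOTE: all-zero counts; rate is an upper bound\n")
  cat("  median resistant count ", object@medianCount, " over ",
      object@nCultures, " cultures\n", sep = "")
})

setMethod("show", "BindingFit", function(object) {
  cat(sprintf("BindingFit (%s, D = %g nM): Kd = %.0f +/- %s nM, M = %.3g\n",
              object@mode, object@d, object@kd,
              ifelse(is.na(object@kdSD), "NA", sprintf("%.0f", object@kdSD)),
              object@m))
  nbad <- sum(!object@perReplicate$converged)
  if (nbad) cat(" ", nbad, "replicate(s) failed to converge\n")
})
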