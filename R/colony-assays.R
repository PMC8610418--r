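#' @include mutasym-package.R
NULL

#' Mutation frequency from selective and permissive plate counts
#'
#' Frequency of resistant mutants per viable cell: resistant-colony count
#' divided by the viable count scaled by its plating dilution. Vector inputs
#' are duplicate plates of the same culture and are averaged before the
#' ratio is formed.
#'
#' @param canrColonies colonies on selective (canavanine) plates; a vector
#'   is averaged as duplicate plates.
#' @param scColonies colonies on permissive (SC) plates (duplicates
#'   averaged).
#' @param dilution dilution factor of the permissive plating (e.g. 1e4).
#' @return mutation frequency (mutants per viable cell).
#' @export
mutationFrequency <- function(canrColonies, scColonies, dilution) {
  if (any(canrColonies < 0) || any(scColonies < 0))
    stop("negative colony count")
  if (dilution <= 0) stop("dilution must be positive")
  sc <- mean(scColonies)
  if (sc == 0) stop("zero viable (SC) colony count")
  mean(canrColonies) / (sc * dilution)
}

# Lea-Coulson median relation: the median resistant count r~ and the
# expected mutations per culture m satisfy r~/m - ln(m) = 1.24.
.leaCoulsonSolve <- function(rMedian) {
  f <- function(m) rMedian / m - log(m) - 1.24
  # f is strictly decreasing; bracket the root
  lo <- 1e-12
  hi <- max(rMedian, 1)
  while (f(hi) > 0) hi <- hi * 10
  uniroot(f, c(lo, hi), tol = 1e-12)$root
}

#' Mutation rate from a fluctuation assay
#'
#' Converts per-culture resistant-colony counts into a mutation rate per
#' cell per generation. The default is the Lea-Coulson method of the
#' median: solve \eqn{\tilde r/m - \ln m = 1.24} for the expected number of
#' mutation events per culture \eqn{m} from the median resistant count
#' \eqn{\tilde r}, then \eqn{\mu = m/N} with \eqn{N} the final cell number
#' per culture. An approximate 95 percent CI uses Stewart's log-normal
#' sigma \eqn{1.225\, m^{-0.315}/\sqrt{C}} for C cultures. A plain
#' `"frequency"` mode reports the median per-culture frequency instead.
#'
#' When the median count is zero the p0 method (\eqn{m = -\ln p_0}) is used;
#' with all-zero counts the rate is an upper bound and flagged as such.
#'
#' @param counts per-culture resistant colony counts.
#' @param nCells final viable cells per culture (N).
#' @param estimator `"lea_coulson"` or `"frequency"`.
#' @param conf confidence level for the Lea-Coulson CI.
#' @return A [FluctuationResult-class].
#' @export
frequencyToRate <- function(counts, nCells,
                            estimator = c("lea_coulson", "frequency"),
                            conf = 0.95) {
  estimator <- match.arg(estimator)
  if (length(counts) < 1L || any(counts < 0)) stop("invalid counts")
  if (nCells <= 1) stop("nCells must exceed 1")
  rMedian <- median(counts)
  nC <- length(counts)
  upperBound <- FALSE
  ci <- c(NA_real_, NA_real_)
  if (estimator == "frequency") {
    rate <- rMedian / nCells
    m <- NA_real_
  } else if (all(counts == 0)) {
    # every culture mutant-free: p0 > nC/(nC+1) at the observation limit
    m <- -log(nC / (nC + 1))
    rate <- m / nCells
    upperBound <- TRUE
  } else if (rMedian == 0) {
    p0 <- mean(counts == 0)
    m <- -log(p0)
    rate <- m / nCells
  } else {
    m <- .leaCoulsonSolve(rMedian)
    rate <- m / nCells
    sigma <- 1.225 * m^(-0.315) / sqrt(nC)
    z <- -qnorm((1 - conf) / 2)
    ci <- exp(log(m) + c(-1, 1) * z * sigma) / nCells
  }
  new("FluctuationResult", estimator = estimator, rate = rate,
      rateCI = ci, m = m, medianCount = rMedian,
      nCultures = as.integer(nC), nCells = as.numeric(nCells),
      upperBound = upperBound)
}

#' Survival percentage after treatment
#'
#' @param treated,untreated colony counts with and without treatment.
#' @return `100 * treated / untreated`.
#' @export
survivalPercent <- function(treated, untreated) {
  if (any(untreated <= 0)) stop("untreated count must be positive")
  if (any(treated < 0)) stop("negative treated count")
  100 * treated / untreated
}

#' Fold rescue of survival
#'
#' Ratio of two survival values, e.g. cells expressing a repair enzyme over
#' cells carrying the empty plasmid.
#'
#' @param survivalA,survivalB survival percentages (B must be positive).
#' @return `survivalA / survivalB`.
#' @export
foldRescue <- function(survivalA, survivalB) {
  if (any(survivalB <= 0)) stop("denominator survival must be positive")
  if (any(survivalA < 0)) stop("negative survival")
  survivalA / survivalB
}
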