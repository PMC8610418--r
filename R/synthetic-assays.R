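#' @include synthetic-catalog.R
NULL

#' Parameters for simulating a fluctuation assay
#'
#' @param seed RNG seed.
#' @param mu mutation rate per cell per division (0 <= mu < 1).
#' @param nFinal final cells per culture (>= 2).
#' @param nCultures parallel cultures.
#' @param platingDilution dilution factor used for the permissive (viable
#'   count) plating.
#' @return validated parameter list of class `"FluctuationSimParams"`.
#' @export
fluctuationSimParams <- function(seed = 1L, mu = 1e-7, nFinal = 1e8,
                                 nCultures = 24L, platingDilution = 1e4) {
  if (mu < 0 || mu >= 1) stop("mu must be in [0, 1)")
  if (nFinal < 2) stop("nFinal must be >= 2")
  .assertCount(nCultures, "nCultures", 1L)
  if (platingDilution <= 0) stop("platingDilution must be positive")
  structure(list(seed = as.integer(seed), mu = mu, nFinal = nFinal,
                 nCultures = as.integer(nCultures),
                 platingDilution = platingDilution),
            class = "FluctuationSimParams")
}

#' Simulate resistant-colony counts of a fluctuation assay
#'
#' Generates a Luria-Delbruck process per culture: mutation events arise
#' during clonal expansion at rate `mu` per cell division (Poisson with
#' mean `mu * nFinal` events, since an expansion to N cells comprises about
#' N divisions), and each event founds a resistant clone whose final size
#' follows the classic power-law clone-size distribution
#' \eqn{P(C \ge k) = 1/k} (capped at the culture size). Viable counts are
#' Poisson after dilution. Deterministic for a fixed seed.
#'
#' @param params a [fluctuationSimParams()].
#' @return data.frame with one row per culture: `culture`, `canr_colonies`
#'   (resistant colonies, full plating), `sc_colonies` (viable colonies at
#'   `platingDilution`), `dilution`. Attribute `"params"` echoes the
#'   generator parameters.
#' @export
simulateFluctuation <- function(params) {
  stopifnot(inherits(params, "FluctuationSimParams"))
  withSeed(params$seed, {
    canr <- vapply(seq_len(params$nCultures), function(i) {
      nMut <- rpois(1L, params$mu * params$nFinal)
      if (nMut == 0L) return(0)
      sum(pmin(floor(1 / runif(nMut)), params$nFinal))
    }, numeric(1L))
    sc <- rpois(params$nCultures, params$nFinal / params$platingDilution)
    out <- data.frame(culture = seq_len(params$nCultures),
                      canr_colonies = canr, sc_colonies = sc,
                      dilution = params$platingDilution)
    attr(out, "params") <- params
    out
  })
}

#' Simulate a noisy anisotropy titration
#'
#' Evaluates the quadratic one-site [bindingModel()] on a concentration
#' grid and adds Gaussian noise of the stated SD. Deterministic for a fixed
#' seed.
#'
#' @param kd dissociation constant, nM.
#' @param m anisotropy amplitude.
#' @param d labeled substrate concentration, nM.
#' @param xGrid non-negative increasing titrant concentrations, nM.
#' @param noiseSd Gaussian noise SD (anisotropy units); 0 reproduces the
#'   model exactly.
#' @param seed RNG seed (ignored when `noiseSd = 0`).
#' @return data.frame with `x` and `y`; attribute `"truth"` holds the
#'   generating parameters.
#' @export
simulateTitration <- function(kd, m, d, xGrid, noiseSd = 0, seed = NULL) {
  if (any(diff(xGrid) <= 0)) stop("xGrid must be strictly increasing")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  y <- bindingModel(xGrid, m, d, kd)
  if (noiseSd > 0)
    y <- withSeed(seed, y + rnorm(length(xGrid), 0, noiseSd))
  out <- data.frame(x = xGrid, y = y)
  attr(out, "truth") <- list(kd = kd, m = m, d = d, noiseSd = noiseSd)
  out
}
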