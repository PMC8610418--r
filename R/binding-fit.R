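#' @include AllClasses.R
NULL

#' Quadratic one-site (ligand-depletion) binding model
#'
#' Exact bound-fraction solution for one-site equilibrium binding when the
#' labeled substrate concentration D is comparable to Kd, so that free and
#' total titrant cannot be equated:
#' \deqn{Y = M \frac{(x + D + K_d) - \sqrt{(x + D + K_d)^2 - 4 D x}}{2 D}}
#' Y runs from 0 at x = 0 to the amplitude M at saturation and is monotone
#' non-decreasing in x. As D tends to 0 it reduces to the hyperbolic
#' Langmuir isotherm \eqn{M x / (x + K_d)}.
#'
#' @param x titrant (protein) concentrations, nM (non-negative, vectorised).
#' @param m anisotropy amplitude M.
#' @param d labeled substrate concentration D, nM (> 0).
#' @param kd dissociation constant, nM (> 0).
#' @return anisotropy values Y.
#' @export
bindingModel <- function(x, m, d, kd) {
  if (d <= 0) stop("d must be positive")
  if (kd <= 0) stop("kd must be positive")
  if (any(x < 0)) stop("x must be non-negative")
  s <- x + d + kd
  disc <- s^2 - 4 * d * x
  stopifnot(all(disc > -1e-8 * s^2))  # impossible for valid inputs
  m * (s - sqrt(pmax(disc, 0))) / (2 * d)
}

.fitOne <- function(x, y, d, offset) {
  m0 <- max(y)
  half <- which.min(abs(y - m0 / 2))
  # half-max starting guess, with fallbacks should the Jacobian degenerate
  kd0s <- unique(c(max(x[half], max(x) / 20, 1e-3),
                   max(x) / 20, median(x), max(x)))
  form <- if (offset) y ~ y0 + bindingModel(x, M, d, Kd)
          else y ~ bindingModel(x, M, d, Kd)
  lower <- if (offset) c(1e-12, 1e-9, -Inf) else c(1e-12, 1e-9)
  fit <- NULL
  for (kd0 in kd0s) {
    start <- if (offset) list(M = m0, Kd = kd0, y0 = 0)
             else list(M = m0, Kd = kd0)
    fit <- tryCatch(
      nlsLM(form, data = data.frame(x = x, y = y), start = start,
            lower = lower, control = nls.lm.control(maxiter = 500)),
      error = function(e) e)
    if (!inherits(fit, "error")) break
  }
  if (inherits(fit, "error"))
    return(list(kd = NA_real_, m = NA_real_, y0 = NA_real_, rss = NA_real_,
                converged = FALSE, boundary = FALSE,
                message = conditionMessage(fit)))
  cf <- coef(fit)
  list(kd = unname(cf["Kd"]), m = unname(cf["M"]),
       y0 = if (offset) unname(cf["y0"]) else 0,
       rss = sum(residuals(fit)^2), converged = TRUE,
       boundary = unname(cf["Kd"]) <= 2e-9, message = "")
}

#' Fit anisotropy titrations to the quadratic one-site model
#'
#' Nonlinear least squares of baseline-subtracted anisotropy versus titrant
#' concentration under [bindingModel()], per replicate (default) or pooled
#' across replicates. Starting values are M = max(Y) and Kd = x at half-max;
#' Kd and M are bounded positive and no per-point weighting is applied.
#' Per-replicate fits are summarised as mean and SD across converged
#' replicates, the usual "n protein preparations" summary.
#'
#' @param titration data.frame with columns `x` (nM) and `y` (anisotropy);
#'   an optional `replicate` column separates replicates.
#' @param d labeled substrate concentration, nM.
#' @param mode `"per_replicate"` or `"pooled"`.
#' @param offset allow a free baseline offset (for raw, non-subtracted
#'   anisotropy); by default the curve is pinned to Y(0) = 0 as in the
#'   model.
#' @return A [BindingFit-class]. Non-convergent replicates are kept in the
#'   table with `converged = FALSE` and excluded from the summary; fits
#'   driven to the lower Kd bound are flagged `boundary`.
#' @export
fitBinding <- function(titration, d, mode = c("per_replicate", "pooled"),
                       offset = FALSE) {
  mode <- match.arg(mode)
  stopifnot(all(c("x", "y") %in% names(titration)))
  if (!"replicate" %in% names(titration)) titration$replicate <- "1"
  if (d <= 0) stop("d must be positive")
  if (length(unique(titration$x)) < 4L)
    stop("need >= 4 distinct titrant concentrations")
  reps <- if (mode == "pooled") list(pooled = titration)
          else split(titration, titration$replicate)
  rows <- lapply(names(reps), function(r) {
    f <- .fitOne(reps[[r]]$x, reps[[r]]$y, d, offset)
    if (!f$converged)
      warning("replicate ", r, " did not converge: ", f$message)
    data.frame(replicate = r, kd = f$kd, m = f$m, y0 = f$y0, rss = f$rss,
               converged = f$converged, boundary = f$boundary)
  })
  per <- do.call(rbind, rows)
  ok <- per$converged
  if (!any(ok)) stop("no replicate converged")
  kd <- mean(per$kd[ok])
  m <- mean(per$m[ok])
  kdSD <- if (sum(ok) > 1L) sd(per$kd[ok]) else NA_real_
  mSD <- if (sum(ok) > 1L) sd(per$m[ok]) else NA_real_
  new("BindingFit", perReplicate = per, kd = kd, kdSD = kdSD, m = m,
      mSD = mSD, d = as.numeric(d), mode = mode)
}
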