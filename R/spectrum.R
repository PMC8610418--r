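#' @include cluster.R
NULL

#' The six purine-keyed substitution classes
#' @return Character vector `c("A>C","A>G","A>T","G>A","G>C","G>T")`.
#' @export
substitutionClasses <- function()
  c("A>C", "A>G", "A>T", "G>A", "G>C", "G>T")

#' Classify a base substitution by its purine-reference key
#'
#' Because a substitution on one strand implies the complementary
#' substitution on the other, the twelve possible single-base changes
#' collapse to six strand-symmetric classes keyed to the purine reference
#' base: pyrimidine-reference changes are complemented (T>C becomes A>G,
#' C>A becomes G>T) and purine-reference changes pass through.
#'
#' @param ref,alt single reference and alternate bases (vectorised).
#' @return factor with levels [substitutionClasses()].
#' @export
classifySubstitution <- function(ref, alt) {
  if (length(ref) != length(alt)) stop("ref and alt lengths differ")
  if (!all(nchar(ref) == 1L & nchar(alt) == 1L))
    stop("classifySubstitution expects single bases")
  if (!all(ref %in% DNA_BASES) || !all(alt %in% DNA_BASES))
    stop("non-ACGT base")
  if (any(ref == alt)) stop("ref equals alt")
  pyr <- ref %in% c("C", "T")
  r <- ifelse(pyr, COMPLEMENT[ref], ref)
  a <- ifelse(pyr, COMPLEMENT[alt], alt)
  factor(paste0(r, ">", a), levels = substitutionClasses())
}

.eventsAndSamples <- function(x, group) {
  if (is.list(x) && !is.data.frame(x)) x <- combineEvents(x)
  samples <- attr(x, "samples")
  if (is.null(samples))
    samples <- unique(x[, c("sample", group), drop = FALSE])
  if (!group %in% names(samples))
    stop("no grouping column '", group, "'")
  list(events = x, samples = samples)
}

#' Per-genome mutation burden, group medians, and fold change
#'
#' Counts events per sample (a complex event counts once), takes the median
#' per group, and reports the fold change of medians relative to a reference
#' group. Counting member records instead of events is available via
#' `countRecords`.
#'
#' @param x list of [SampleCatalog-class] objects or a combined event
#'   data.frame from [combineEvents()].
#' @param group grouping column, default `"genotype"`.
#' @param refGroup reference group for the fold change (default: first group
#'   in order of appearance).
#' @param countRecords count member records of complex events individually.
#' @return list with `perSample` (sample, group, n), `medians` (named), and
#'   `fold` (named vector, one entry per non-reference group).
#' @export
perGenomeBurden <- function(x, group = "genotype", refGroup = NULL,
                            countRecords = FALSE) {
  es <- .eventsAndSamples(x, group)
  ev <- es$events
  samples <- es$samples
  w <- if (countRecords) ev$n_records else rep(1L, nrow(ev))
  n <- rowsum(w, ev$sample)
  perSample <- samples[, c("sample", group)]
  names(perSample)[2L] <- "group"
  perSample$n <- ifelse(perSample$sample %in% rownames(n),
                        n[perSample$sample, 1L], 0)
  groups <- as.character(unique(perSample$group))
  if (length(groups) < 1L) stop("empty group")
  medians <- vapply(groups, function(g)
    median(perSample$n[perSample$group == g]), numeric(1L))
  names(medians) <- groups
  if (is.null(refGroup)) refGroup <- groups[1L]
  if (!refGroup %in% groups) stop("unknown refGroup: ", refGroup)
  fold <- medians[setdiff(groups, refGroup)] / medians[[refGroup]]
  list(perSample = perSample, medians = medians, fold = fold)
}

#' Event-class fractions per group
#'
#' Fractions of substitution, insertion, deletion, and complex events per
#' group; fractions sum to one within each group.
#'
#' @inheritParams perGenomeBurden
#' @return data.frame with `group`, `event_class`, `n`, `fraction`.
#' @export
eventClassFractions <- function(x, group = "genotype") {
  ev <- .eventsAndSamples(x, group)$events
  if (!nrow(ev)) stop("no events")
  classes <- c("substitution", "insertion", "deletion", "complex")
  tab <- table(factor(ev[[group]]),
               factor(ev$event_class, levels = classes))
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("group", "event_class", "n")
  out$group <- as.character(out$group)
  out$event_class <- as.character(out$event_class)
  tot <- rowsum(out$n, out$group)
  out$fraction <- out$n / tot[out$group, 1L]
  out[order(out$group, match(out$event_class, classes)), ]
}

#' Per-class substitution counts: mean and SD per genome
#'
#' Counts single-base substitution events per purine-keyed class and sample,
#' then reports the arithmetic mean and sample standard deviation per class
#' within each group (the usual bar-plot-with-error-bars summary of a
#' mutation spectrum).
#'
#' @inheritParams perGenomeBurden
#' @return data.frame `group`, `class`, `mean`, `sd`, `n_samples`; attribute
#'   `"perSample"` holds the per-sample class-count matrix used.
#' @export
spectrumMeans <- function(x, group = "genotype") {
  es <- .eventsAndSamples(x, group)
  ev <- es$events
  samples <- es$samples
  sub <- ev[ev$event_class == "substitution" &
              !is.na(ev$ref) & nchar(ev$ref) == 1L & nchar(ev$alt) == 1L, ]
  cls <- classifySubstitution(sub$ref, sub$alt)
  counts <- table(factor(sub$sample, levels = samples$sample), cls)
  out <- do.call(rbind, lapply(as.character(unique(samples[[group]])),
                               function(g) {
    m <- counts[samples$sample[samples[[group]] == g], , drop = FALSE]
    data.frame(group = g, class = colnames(m),
               mean = colMeans(m),
               sd = apply(m, 2L, sd),
               n_samples = nrow(m), row.names = NULL)
  }))
  attr(out, "perSample") <- counts
  out
}

#' Two-group comparison tests
#'
#' Thin wrappers over the standard two-sided tests used to compare mutation
#' burdens and spectra: Mann-Whitney (rank sum) and Student's t for
#' per-sample values, chi-square (without continuity correction) for
#' event-class contingency tables.
#'
#' @param x numeric vector (first group) or a contingency matrix for
#'   `"chi_square"`.
#' @param y numeric vector (second group); ignored for `"chi_square"`.
#' @param test one of `"mann_whitney"`, `"t_test"`, `"chi_square"`.
#' @return list with `statistic`, `p_value`, `method`, and `degenerate`
#'   (TRUE when the input cannot support the test, e.g. zero variance for
#'   the t test; `p_value` is then NA).
#' @export
compareGroups <- function(x, y = NULL,
                          test = c("mann_whitney", "t_test", "chi_square")) {
  test <- match.arg(test)
  degenerate <- FALSE
  res <- switch(test,
    mann_whitney = {
      stopifnot(is.numeric(x), is.numeric(y))
      suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    },
    t_test = {
      stopifnot(is.numeric(x), is.numeric(y))
      if (sd(x) == 0 && sd(y) == 0 && mean(x) == mean(y)) {
        degenerate <- TRUE
        list(statistic = NA_real_, p.value = NA_real_,
             method = "Two Sample t-test (degenerate: zero variance)")
      } else t.test(x, y)
    },
    chi_square = {
      x <- as.matrix(x)
      if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
        degenerate <- TRUE
        list(statistic = NA_real_, p.value = NA_real_,
             method = "Chi-squared test (degenerate: empty margin)")
      } else suppressWarnings(chisq.test(x, correct = FALSE))
    })
  list(statistic = unname(res$statistic), p_value = res$p.value,
       method = res$method, degenerate = degenerate)
}

#' Reporter-gene frequency spectrum
#'
#' Distributes a total mutation rate (or frequency) over event classes in
#' proportion to their share among sequenced resistant isolates, giving the
#' per-class mutation frequency plotted in reporter-assay spectra.
#'
#' @param proportions named non-negative vector of class proportions among
#'   sequenced isolates; must sum to 1 (tolerance 1e-6).
#' @param totalRate total mutation rate (>= 0), e.g. from
#'   [frequencyToRate()].
#' @return data.frame `class`, `proportion`, `frequency`; frequencies sum to
#'   `totalRate`.
#' @export
can1FrequencySpectrum <- function(proportions, totalRate) {
  if (is.null(names(proportions))) stop("proportions must be named")
  if (any(proportions < 0)) stop("negative proportion")
  if (abs(sum(proportions) - 1) > 1e-6)
    stop("proportions are not normalized (sum = ", sum(proportions), ")")
  if (length(totalRate) != 1L || totalRate < 0)
    stop("totalRate must be a single non-negative number")
  data.frame(class = names(proportions),
             proportion = unname(proportions),
             frequency = unname(proportions) * totalRate)
}
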