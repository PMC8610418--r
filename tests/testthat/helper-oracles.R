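# Independent oracles used to cross-check the package implementation.

# Brute-force event clustering: build the full pairwise distance graph on
# records of one (sample, chrom) and take connected components under the
# relation |pos_i - pos_j| <= maxGap (transitive closure), ignoring the
# sorted-sweep shortcut the package uses.
bruteForceComponents <- function(pos, maxGap = 10) {
  n <- length(pos)
  adj <- abs(outer(pos, pos, "-")) <= maxGap
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    k <- k + 1L
    frontier <- i
    while (length(frontier)) {
      comp[frontier] <- k
      nxt <- which(apply(adj[, frontier, drop = FALSE], 1L, any) &
                     is.na(comp))
      frontier <- nxt
    }
  }
  comp
}

# Generation-by-generation Luria-Delbruck simulator: explicit doublings
# from a single cell, binomial mutation events per division round, mutant
# lineages doubling thereafter. Slow but assumption-free.
naiveFluctuationCulture <- function(mu, nFinal) {
  gens <- ceiling(log2(nFinal))
  wt <- 1
  mut <- 0
  for (g in seq_len(gens)) {
    newMut <- rbinom(1L, wt, mu)
    wt <- 2 * wt - newMut
    mut <- 2 * mut + newMut
  }
  # trim the final overshoot proportionally (nFinal need not be a power of 2)
  scale <- nFinal / (wt + mut)
  round(mut * scale)
}

# Monte-Carlo conditional (margin-fixed) permutation oracle for the
# chi-square p-value on a contingency table.
permutationChisqP <- function(tab, nSim = 20000) {
  obs <- suppressWarnings(chisq.test(tab, correct = FALSE))$statistic
  sims <- r2dtable(nSim, rowSums(tab), colSums(tab))
  stat <- function(m) {
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    sum((m - e)^2 / e)
  }
  mean(vapply(sims, stat, numeric(1L)) >= obs - 1e-12)
}

# Shared small reference used by several test files.
testReference <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- makeReference(genomeSpec(
        seed = 11, nChromosomes = 2, chromLength = 200000,
        gcFraction = 0.5, nTranscripts = 20,
        transcriptLengthRange = c(1000, 4000),
        originsPerChromosome = 4))
    cache
  }
})

# Reference with high transcript coverage, for asymmetry-recovery tests
# that need thousands of in-transcript mutations.
asymReference <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- makeReference(genomeSpec(
        seed = 13, nChromosomes = 2, chromLength = 200000,
        gcFraction = 0.5, nTranscripts = 16,
        transcriptLengthRange = c(12000, 15000),
        originsPerChromosome = 4))
    cache
  }
})

# Records data.frame builder for hand-made fixtures.
makeRecords <- function(pos, ref = "A", alt = "G", chrom = "chr1",
                        sample = "s1", depth = 50, alt_fraction = 0.5) {
  if (length(pos) == 0)
    return(data.frame(sample = character(), chrom = character(),
                      pos = numeric(), ref = character(), alt = character(),
                      depth = numeric(), alt_fraction = numeric()))
  data.frame(sample = sample, chrom = chrom, pos = pos,
             ref = ref, alt = alt, depth = depth,
             alt_fraction = alt_fraction)
}
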