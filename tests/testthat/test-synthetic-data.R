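test_that("reference generation is deterministic and satisfies its invariants", {
  spec <- genomeSpec(seed = 5, nChromosomes = 2, chromLength = 200000,
                     gcFraction = 0.5, nTranscripts = 20,
                     originsPerChromosome = 4)
  ref1 <- makeReference(spec)
  ref2 <- makeReference(spec)
  expect_identical(as.character(ref1$genome), as.character(ref2$genome))
  expect_identical(as.data.frame(ref1$transcripts),
                   as.data.frame(ref2$transcripts))
  expect_identical(GenomicRanges::start(ref1$origins),
                   GenomicRanges::start(ref2$origins))

  # transcripts non-overlapping including 1500 bp flanks
  tx <- ref1$transcripts
  for (ch in unique(as.character(GenomicRanges::seqnames(tx)))) {
    sub <- tx[as.character(GenomicRanges::seqnames(tx)) == ch]
    sub <- sub[order(GenomicRanges::start(sub))]
    if (length(sub) > 1) {
      gaps <- GenomicRanges::start(sub)[-1] -
        GenomicRanges::end(sub)[-length(sub)]
      expect_true(all(gaps > 2 * 1500))
    }
  }
  expect_true(all(as.character(GenomicRanges::strand(tx)) %in%
                    c("+", "-")))

  # origins strictly increasing, >= 2 per chromosome
  ori <- split(GenomicRanges::start(ref1$origins),
               as.character(GenomicRanges::seqnames(ref1$origins)))
  for (o in ori) {
    expect_gte(length(o), 2)
    expect_true(all(diff(o) > 0))
  }

  # base composition within 3 SD of the binomial expectation for GC = 0.5
  gc <- sum(Biostrings::letterFrequency(ref1$genome, "GC")) / (2 * 200000)
  bound <- 3 * sqrt(0.5 * 0.5 / (2 * 200000))
  expect_lt(abs(gc - 0.5), bound)
})

test_that("infeasible transcript placement raises a sizing error", {
  spec <- genomeSpec(seed = 1, nChromosomes = 1, chromLength = 20000,
                     nTranscripts = 8, transcriptLengthRange = c(2000, 3000))
  expect_error(makeReference(spec), "cannot place")
})

test_that("simulated catalogs carry the configured event mixture", {
  ref <- testReference()
  p <- catalogSimParams(seed = 21, nSamples = 10,
                        mutationsPerGenomeMean = 200,
                        substitutionFraction = 0.95,
                        indelFraction = 0.04, complexFraction = 0.01)
  cat1 <- simulateCatalog(ref$genome, ref$transcripts, ref$origins, p)
  cat2 <- simulateCatalog(ref$genome, ref$transcripts, ref$origins, p)
  expect_identical(cat1, cat2)

  ev <- clusterEvents(cat1)
  fracSub <- mean(ev$event_class == "substitution")
  # binomial 3 SD at ~2000 events plus a small allowance for chance merges
  bound <- 3 * sqrt(0.95 * 0.05 / nrow(ev)) + 0.005
  expect_lt(abs(fracSub - 0.95), bound)

  # complex ground truth: exactly two records, 1-10 bp apart
  truth <- attr(cat1, "truth")
  cpx <- truth[truth$event_type == "complex", ]
  if (nrow(cpx)) {
    bySize <- split(cpx$pos, cpx$event_id)
    expect_true(all(lengths(bySize) == 2))
    gaps <- vapply(bySize, function(x) abs(diff(x)), numeric(1))
    expect_true(all(gaps >= 1 & gaps <= 10))
  }

  # read-support metadata produces records on both sides of the filters
  expect_gt(sum(cat1$alt_fraction < 0.45 | cat1$alt_fraction > 0.55), 0)
  expect_gt(sum(cat1$alt_fraction >= 0.45 & cat1$alt_fraction <= 0.55), 0)
})

test_that("catalogs and references round-trip through their file formats", {
  ref <- testReference()
  dir <- withr::local_tempdir()
  writeReference(ref, dir)
  genome2 <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  expect_identical(as.character(genome2), as.character(ref$genome))
  tx2 <- rtracklayer::import(file.path(dir, "transcripts.bed"))
  expect_identical(GenomicRanges::start(tx2),
                   GenomicRanges::start(ref$transcripts))
  expect_identical(as.character(GenomicRanges::strand(tx2)),
                   as.character(GenomicRanges::strand(ref$transcripts)))

  p <- catalogSimParams(seed = 3, nSamples = 2, mutationsPerGenomeMean = 30)
  cat1 <- simulateCatalog(ref$genome, ref$transcripts, ref$origins, p)
  tsv <- file.path(dir, "cat.tsv")
  writeCatalogTsv(cat1, tsv)
  back <- readCatalog(tsv, "tsv")
  expect_equal(back$pos, cat1$pos)
  expect_equal(back$alt_fraction, cat1$alt_fraction, tolerance = 1e-12)

  one <- cat1[cat1$sample == "s001", ]
  vcf <- file.path(dir, "s001.vcf")
  writeCatalogVcf(one, vcf)
  backv <- readCatalog(vcf, "vcf")
  expect_equal(backv$pos, one$pos)
  expect_equal(backv$ref, one$ref)
  expect_equal(backv$alt, one$alt)
  expect_equal(backv$depth, round(one$depth))
  expect_equal(backv$sample, rep("s001", nrow(one)))
})

test_that("fluctuation simulator matches a naive generation-by-generation oracle", {
  p0 <- fluctuationSimParams(seed = 4, mu = 0, nFinal = 1e6, nCultures = 12)
  expect_true(all(simulateFluctuation(p0)$canr_colonies == 0))

  p <- fluctuationSimParams(seed = 8, mu = 1e-4, nFinal = 2^17,
                            nCultures = 300)
  tab1 <- simulateFluctuation(p)
  expect_identical(tab1, simulateFluctuation(p))

  set.seed(42)
  naive <- replicate(300, naiveFluctuationCulture(1e-4, 2^17))
  # medians of the two generative routes agree within sampling error
  expect_gt(median(tab1$canr_colonies) / median(naive), 0.7)
  expect_lt(median(tab1$canr_colonies) / median(naive), 1.4)
})

test_that("titration simulator reproduces the binding model", {
  x <- seq(0, 1600, length.out = 20)
  clean <- simulateTitration(250, 0.2, 5, x, noiseSd = 0)
  expect_equal(clean$y, bindingModel(x, 0.2, 5, 250))
  expect_identical(clean$y[1], 0)

  noisy1 <- simulateTitration(250, 0.2, 5, x, noiseSd = 0.01, seed = 2)
  noisy2 <- simulateTitration(250, 0.2, 5, x, noiseSd = 0.01, seed = 2)
  expect_identical(noisy1, noisy2)
  expect_false(identical(noisy1$y, clean$y))
})
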