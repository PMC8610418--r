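test_that("transcription bin assignment follows fractional and flank rules", {
  # + transcript 1001..3000 (width 2000), TSS at 1001
  bin <- function(p) as.character(assignTranscriptionBin(p, 1001, 3000, "+"))
  expect_equal(bin(2000), "3")          # fractional position ~0.5
  expect_equal(bin(1001), "1")
  expect_equal(bin(3000), "5")
  expect_equal(bin(1001 - 400), "-1")   # 400 bp upstream of TSS
  expect_equal(bin(1001 - 500), "-1")
  expect_equal(bin(1001 - 501), "-2")
  expect_equal(bin(1001 - 1500), "-3")
  expect_true(is.na(bin(1001 - 1501)))  # beyond the flank bins
  expect_equal(bin(3000 + 1), "+1")
  expect_equal(bin(3000 + 1500), "+3")
  # - transcript: orientation flips, TSS sits at the right end
  binM <- function(p) as.character(assignTranscriptionBin(p, 1001, 3000, "-"))
  expect_equal(binM(3000), "1")
  expect_equal(binM(1001), "5")
  expect_equal(binM(3000 + 400), "-1")  # upstream of the TSS, rightward
  expect_equal(binM(1001 - 400), "+1")
})

test_that("mutated-base strand assignment matches the 8-case truth table", {
  # non-transcribed strand = mRNA-like strand = top strand of a + transcript
  cases <- data.frame(
    ref = rep(c("A", "T", "C", "G"), 2),
    frame = rep(c("+", "-"), each = 4),
    base = rep(c("A", "A", "C", "C"), 2),
    strand = c("non_transcribed", "transcribed", "non_transcribed",
               "transcribed",
               "transcribed", "non_transcribed", "transcribed",
               "non_transcribed"))
  for (i in seq_len(nrow(cases))) {
    got <- strandMutatedBase(cases$ref[i], cases$frame[i])
    expect_equal(got$base, cases$base[i])
    expect_equal(got$strand, cases$strand[i])
  }
  rep1 <- strandMutatedBase(c("A", "T", "C", "G"), labels = "replication")
  expect_equal(rep1$strand, c("top", "bottom", "top", "bottom"))
  expect_equal(rep1$base, c("A", "A", "C", "C"))
  expect_error(strandMutatedBase("AT", "+"), "single-base")
})

test_that("transcription density normalises counts by strand opportunity", {
  # hand-built genome: one chromosome, one + transcript at 2001..2100
  seqs <- paste(rep("ACGT", 1500), collapse = "")  # 6000 bp, 25% each base
  genome <- Biostrings::DNAStringSet(c(chr1 = seqs))
  tx <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2001, 2100),
                               strand = "+")
  # one A>G mutation at 2041: body bin 3, A on the non-transcribed strand
  rec <- makeRecords(2041, ref = "A", alt = "G")
  prof <- transcriptionDensityProfile(rec, tx, genome)
  bins <- profileBins(prof)
  hit <- bins[bins$base == "A" & bins$strand == "non_transcribed" &
                bins$bin == "3", ]
  # each 20-bp body bin holds 5 top-strand A's
  expect_equal(hit$opportunity_count, 5)
  expect_equal(hit$mutation_count, 1)
  expect_equal(hit$density, 0.2)
  expect_equal(sum(bins$mutation_count), 1)
  expect_equal(prof@nInScope, 1L)

  # zero mutations: all densities zero where opportunities exist
  prof0 <- transcriptionDensityProfile(makeRecords(numeric(0)), tx, genome)
  b0 <- profileBins(prof0)
  expect_true(all(b0$density[!is.na(b0$density)] == 0))
})

test_that("replication bin assignment uses the fractional inter-origin coordinate", {
  ab <- assignReplicationBin(c(15000, 10000, 5000, 19999, 20000),
                             c(10000, 20000))
  expect_equal(ab$bin, c(5L, 0L, NA, 9L, NA))
  expect_equal(ab$fraction[1], 0.5)
  expect_error(assignReplicationBin(1, c(5, 5)), "strictly increasing")
})

test_that("replication fractions are complementary and feed exact regressions", {
  # 3 top-strand (ref C) vs 1 bottom-strand (ref G) C mutations in one bin
  rec <- makeRecords(c(10100, 10300, 10600, 10800),
                     ref = c("C", "C", "C", "G"), alt = "T")
  rec$alt[4] <- "A"
  prof <- replicationFractionProfile(rec, list(chr1 = c(10000, 20000)))
  bins <- profileBins(prof)
  b0 <- bins[bins$base == "C" & bins$bin == 0, ]
  expect_equal(b0$fraction_top, 0.75)
  expect_equal(b0$fraction_bottom, 0.25)
  tot <- bins$fraction_top + bins$fraction_bottom
  expect_true(all(tot[!is.na(tot)] == 1))

  # exactly linear synthetic fractions recover slope/intercept exactly
  lin <- data.frame(base = "C", bin = 0:9, bin_center = (0:9 + 0.5) / 10)
  lin$fraction_top <- 0.3 + 0.4 * lin$bin_center
  lin$fraction_bottom <- 1 - lin$fraction_top
  fit <- fitAsymmetryRegression(lin)
  top <- fit[fit$strand == "top", ]
  bot <- fit[fit$strand == "bottom", ]
  expect_equal(top$slope, 0.4, tolerance = 1e-12)
  expect_equal(top$intercept, 0.3, tolerance = 1e-12)
  expect_equal(top$r_squared, 1)
  expect_equal(top$slope, -bot$slope, tolerance = 1e-12)

  # flat fractions give slope 0, intercept 0.5
  flat <- lin
  flat$fraction_top <- 0.5
  flat$fraction_bottom <- 0.5
  ffit <- fitAsymmetryRegression(flat)
  expect_equal(ffit$slope, c(0, 0), tolerance = 1e-12)
  expect_equal(ffit$intercept, c(0.5, 0.5), tolerance = 1e-12)
})

test_that("injected transcriptional bias and replicative gradient are recovered", {
  ref <- asymReference()
  gOnly <- c(`A>C` = 0, `A>G` = 0, `A>T` = 0,
             `G>A` = 1 / 3, `G>C` = 1 / 3, `G>T` = 1 / 3)
  pBias <- catalogSimParams(seed = 31, nSamples = 1,
                            mutationsPerGenomeMean = 6000,
                            substitutionFraction = 1, indelFraction = 0,
                            complexFraction = 0, classWeights = gOnly,
                            txBiasC = 2)
  catB <- simulateCatalog(ref$genome, ref$transcripts, ref$origins, pBias)
  prof <- transcriptionDensityProfile(catB, ref$transcripts, ref$genome)
  bins <- profileBins(prof)
  body <- bins[bins$bin %in% as.character(1:5) & bins$base == "C", ]
  dens <- tapply(body$mutation_count, body$strand, sum) /
    tapply(body$opportunity_count, body$strand, sum)
  ratio <- dens[["non_transcribed"]] / dens[["transcribed"]]
  expect_gt(ratio, 2 * 0.85)
  expect_lt(ratio, 2 * 1.15)

  pGrad <- catalogSimParams(seed = 37, nSamples = 1,
                            mutationsPerGenomeMean = 8000,
                            substitutionFraction = 1, indelFraction = 0,
                            complexFraction = 0, classWeights = gOnly,
                            repGradientC = 0.6)
  catG <- simulateCatalog(ref$genome, ref$transcripts, ref$origins, pGrad)
  rp <- replicationFractionProfile(catG, ref$origins)
  fits <- asymmetryFits(rp)
  top <- fits[fits$base == "C" & fits$strand == "top", ]
  bot <- fits[fits$base == "C" & fits$strand == "bottom", ]
  expect_gt(0.6, top$ci_lo)
  expect_lt(0.6, top$ci_hi)
  expect_lt(abs(top$slope + bot$slope), 1e-9)
})

test_that("profiles conserve their in-scope substitution counts", {
  ref <- testReference()
  p <- catalogSimParams(seed = 41, nSamples = 3,
                        mutationsPerGenomeMean = 300)
  cat1 <- simulateCatalog(ref$genome, ref$transcripts, ref$origins, p)
  rp <- replicationFractionProfile(cat1, ref$origins)
  bins <- profileBins(rp)
  expect_equal(sum(bins$n_top + bins$n_bottom), rp@nInScope)
  tp <- transcriptionDensityProfile(cat1, ref$transcripts, ref$genome)
  expect_equal(sum(profileBins(tp)$mutation_count), tp@nInScope)
  expect_true(all(profileBins(tp)$mutation_count <=
                    profileBins(tp)$opportunity_count))
})
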