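test_that("substitution classification collapses to the six purine keys", {
  expect_equal(as.character(classifySubstitution("A", "T")), "A>T")
  expect_equal(as.character(classifySubstitution("T", "C")), "A>G")
  expect_equal(as.character(classifySubstitution("C", "A")), "G>T")
  # strand involution: complementing both alleles never changes the class
  refs <- rep(c("A", "C", "G", "T"), each = 3)
  alts <- unlist(lapply(c("A", "C", "G", "T"),
                        function(r) setdiff(c("A", "C", "G", "T"), r)))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  expect_equal(classifySubstitution(refs, alts),
               classifySubstitution(unname(comp[refs]), unname(comp[alts])))
  expect_error(classifySubstitution("A", "A"), "ref equals alt")
  expect_error(classifySubstitution("N", "A"), "non-ACGT")
})

test_that("per-genome burden reports medians and fold change of medians", {
  mk <- function(sample, n, genotype)
    SampleCatalog(makeRecords(seq(1, by = 100, length.out = n),
                              sample = sample), genotype = genotype)
  wt <- lapply(1:3, function(i) mk(paste0("w", i), c(8, 10, 12)[i], "WT"))
  mut <- lapply(1:3, function(i) mk(paste0("m", i), c(120, 127, 130)[i],
                                    "mut"))
  b <- perGenomeBurden(c(wt, mut), refGroup = "WT")
  expect_equal(unname(b$medians), c(10, 127))
  expect_equal(unname(b$fold), 12.7)
  # invariant to sample ordering
  b2 <- perGenomeBurden(rev(c(wt, mut)), refGroup = "WT")
  expect_equal(b2$fold, b$fold)
  # single sample per group: medians are those samples' totals
  b3 <- perGenomeBurden(list(wt[[1]], mut[[2]]), refGroup = "WT")
  expect_equal(unname(b3$medians), c(8, 127))
})

test_that("event class fractions sum to one and match the catalog", {
  rec <- rbind(makeRecords(seq(1, by = 100, length.out = 95)),
               data.frame(sample = "s1", chrom = "chr1",
                          pos = seq(10000, by = 100, length.out = 5),
                          ref = "AT", alt = "A", depth = 50,
                          alt_fraction = 0.5))
  ct <- SampleCatalog(rec, genotype = "WT")
  fr <- eventClassFractions(list(ct))
  expect_equal(sum(fr$fraction), 1, tolerance = 1e-12)
  expect_equal(fr$fraction[fr$event_class == "substitution"], 0.95)
  allSub <- SampleCatalog(makeRecords(seq(1, by = 100, length.out = 40)),
                          genotype = "WT")
  fr2 <- eventClassFractions(list(allSub))
  expect_equal(fr2$fraction[fr2$event_class == "substitution"], 1.0)
})

test_that("spectrum means and SDs summarise per-sample class counts", {
  s1 <- SampleCatalog(makeRecords(seq(1, by = 100, length.out = 4),
                                  ref = "A", alt = "G", sample = "a"),
                      genotype = "WT")
  s2 <- SampleCatalog(makeRecords(seq(1, by = 100, length.out = 6),
                                  ref = "A", alt = "G", sample = "b"),
                      genotype = "WT")
  sm <- spectrumMeans(list(s1, s2))
  ag <- sm[sm$class == "A>G", ]
  expect_equal(ag$mean, 5)
  expect_equal(ag$sd, sqrt(2))
  expect_equal(sm$mean[sm$class == "G>T"], 0)
  s3 <- SampleCatalog(makeRecords(seq(1, by = 100, length.out = 4),
                                  ref = "A", alt = "G", sample = "c"),
                      genotype = "WT")
  smSame <- spectrumMeans(list(s1, s3))
  expect_equal(smSame$sd[smSame$class == "A>G"], 0)
  # conservation: per-class means times sample count add to total events
  expect_equal(sum(sm$mean) * 2, 10)
})

test_that("group comparison tests give null results on identical input", {
  mw <- compareGroups(1:10, 1:10, test = "mann_whitney")
  expect_gte(mw$p_value, 0.99)
  tab <- rbind(c(10, 20, 30), c(10, 20, 30))
  cs <- compareGroups(tab, test = "chi_square")
  expect_equal(cs$statistic, 0)
  tt <- compareGroups(c(1, 1, 1), c(1, 1, 1), test = "t_test")
  expect_true(tt$degenerate)
  expect_true(is.na(tt$p_value))
})

test_that("chi-square p-value agrees with a permutation oracle", {
  set.seed(7)
  tab <- matrix(c(40, 55, 23, 18, 30, 12,
                  52, 48, 30, 25, 21, 19), nrow = 2, byrow = TRUE)
  p <- compareGroups(tab, test = "chi_square")$p_value
  pPerm <- permutationChisqP(tab, nSim = 20000)
  # Monte-Carlo error plus the asymptotic gap at these cell counts
  expect_lt(abs(p - pPerm), 0.04)
})

test_that("reporter frequency spectrum distributes the total rate", {
  sp <- can1FrequencySpectrum(c(substitution = 0.5, deletion = 0.5), 2e-7)
  expect_equal(sp$frequency, c(1e-7, 1e-7))
  expect_equal(sum(sp$frequency), 2e-7, tolerance = 1e-20)
  one <- can1FrequencySpectrum(c(complex = 1), 5e-8)
  expect_equal(one$frequency, 5e-8)
  expect_error(can1FrequencySpectrum(c(a = 0.5, b = 0.4), 1e-7),
               "not normalized")
})
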