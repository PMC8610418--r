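#' @include synthetic-genome.R
NULL

#' Parameters for simulating mutation catalogs
#'
#' Controls per-sample catalogs with known structure: class mixture over the
#' six purine-keyed substitution classes, indel and complex-event fractions,
#' a transcriptional strand bias for C mutations, a linear replicative
#' strand gradient for C mutations, and read-support metadata.
#'
#' @param seed RNG seed.
#' @param nSamples samples to simulate.
#' @param mutationsPerGenomeMean Poisson mean of events per sample.
#' @param substitutionFraction,indelFraction,complexFraction event-class
#'   mixture; must sum to 1 (tolerance 1e-9).
#' @param classWeights named 6-vector of substitution-class weights over
#'   [substitutionClasses()]; must sum to 1 (tolerance 1e-9).
#' @param txBiasC target non-transcribed : transcribed C-mutation density
#'   ratio inside transcripts (1 = no bias).
#' @param repGradientC slope of the top-strand C-mutation probability
#'   across the fractional inter-origin coordinate (0 = no gradient); the
#'   probability is `0.5 + repGradientC * (fraction - 0.5)`.
#' @param depthMean Poisson mean read depth per record.
#' @param vafMode centre of the alt-fraction distribution; alt fractions are
#'   Normal(vafMode, 0.03) truncated to [0, 1], so a predictable share of
#'   records fails the 45--55 percent support filter.
#' @return validated parameter list of class `"CatalogSimParams"`.
#' @export
catalogSimParams <- function(seed = 1L, nSamples = 5L,
                             mutationsPerGenomeMean = 15,
                             substitutionFraction = 0.95,
                             classWeights = c(`A>C` = 0.05, `A>G` = 0.30,
                                              `A>T` = 0.30, `G>A` = 0.15,
                                              `G>C` = 0.08, `G>T` = 0.12),
                             indelFraction = 0.04, complexFraction = 0.01,
                             txBiasC = 1, repGradientC = 0,
                             depthMean = 50, vafMode = 0.5) {
  .assertCount(nSamples, "nSamples", 1L)
  .assertProportion(substitutionFraction, "substitutionFraction")
  .assertProportion(indelFraction, "indelFraction")
  .assertProportion(complexFraction, "complexFraction")
  .assertProportion(vafMode, "vafMode")
  if (abs(substitutionFraction + indelFraction + complexFraction - 1) > 1e-9)
    stop("substitution, indel, and complex fractions must sum to 1")
  if (!identical(sort(names(classWeights)), sort(substitutionClasses())))
    stop("classWeights must be named by the six substitution classes")
  if (abs(sum(classWeights) - 1) > 1e-9)
    stop("classWeights must sum to 1")
  if (any(classWeights < 0)) stop("negative class weight")
  if (txBiasC < 0) stop("txBiasC must be >= 0")
  if (mutationsPerGenomeMean <= 0 || depthMean <= 0)
    stop("means must be positive")
  structure(list(seed = as.integer(seed), nSamples = as.integer(nSamples),
                 mutationsPerGenomeMean = mutationsPerGenomeMean,
                 substitutionFraction = substitutionFraction,
                 classWeights = classWeights[substitutionClasses()],
                 indelFraction = indelFraction,
                 complexFraction = complexFraction,
                 txBiasC = txBiasC, repGradientC = repGradientC,
                 depthMean = depthMean, vafMode = vafMode),
            class = "CatalogSimParams")
}

# Precomputed per-chromosome lookup tables used during simulation.
.simContext <- function(genome, transcripts, origins) {
  chroms <- names(genome)
  chars <- lapply(chroms, function(ch)
    strsplit(as.character(genome[[ch]]), "", fixed = TRUE)[[1L]])
  names(chars) <- chroms
  sites <- lapply(chroms, function(ch) list(
    AT = which(chars[[ch]] %in% c("A", "T")),
    CG = which(chars[[ch]] %in% c("C", "G"))))
  names(sites) <- chroms
  txByChrom <- lapply(chroms, function(ch) {
    sel <- as.character(seqnames(transcripts)) == ch
    tx <- transcripts[sel]
    tx[order(start(tx))]
  })
  names(txByChrom) <- chroms
  oriByChrom <- .originVector(origins)
  list(chroms = chroms, chars = chars, sites = sites,
       tx = txByChrom, ori = oriByChrom,
       lens = setNames(width(genome), chroms))
}

# Top-strand probability for a C mutation at (chrom, pos): a linear
# replicative gradient between origins, reweighted inside transcripts so
# the non-transcribed strand carries `txBiasC` times the density.
.pTopC <- function(ctx, chrom, pos, txBiasC, repGradientC) {
  p <- rep(0.5, length(pos))
  ori <- ctx$ori[[chrom]]
  if (!is.null(ori) && length(ori) >= 2L && repGradientC != 0) {
    i <- findInterval(pos, ori)
    ok <- i >= 1L & i < length(ori)
    f <- (pos[ok] - ori[i[ok]]) / (ori[i[ok] + 1L] - ori[i[ok]])
    p[ok] <- pmin(pmax(0.5 + repGradientC * (f - 0.5), 0.01), 0.99)
  }
  if (txBiasC != 1) {
    tx <- ctx$tx[[chrom]]
    if (length(tx)) {
      i <- findInterval(pos, start(tx))
      inTx <- i >= 1L & pos <= end(tx)[pmax(i, 1L)]
      if (any(inTx)) {
        plus <- as.character(strand(tx))[i[inTx]] == "+"
        wTop <- ifelse(plus, txBiasC, 1)
        wBot <- ifelse(plus, 1, txBiasC)
        pi <- p[inTx]
        p[inTx] <- pi * wTop / (pi * wTop + (1 - pi) * wBot)
      }
    }
  }
  p
}

# Sample n sites uniformly from the given per-chromosome index lists.
.sampleSites <- function(ctx, kind, n) {
  counts <- vapply(ctx$chroms, function(ch)
    length(ctx$sites[[ch]][[kind]]), numeric(1L))
  if (sum(counts) == 0L)
    stop("zero mutational opportunities for ", kind, " sites")
  chrom <- sample(ctx$chroms, n, replace = TRUE, prob = counts)
  pos <- vapply(seq_len(n), function(j) {
    idx <- ctx$sites[[chrom[j]]][[kind]]
    idx[sample.int(length(idx), 1L)]
  }, numeric(1L))
  data.frame(chrom = chrom, pos = pos)
}

.randomAlt <- function(ref) vapply(ref, function(b)
  sample(setdiff(DNA_BASES, b), 1L), character(1L), USE.NAMES = FALSE)

#' Simulate per-sample mutation catalogs with known structure
#'
#' Draws events per sample from a Poisson, splits them into substitutions,
#' indels, and complex events (exactly two substitution records 1--10 bp
#' apart), assigns substitution classes by `classWeights`, and places
#' C-class mutations so that the transcriptional bias `txBiasC` and the
#' replicative gradient `repGradientC` are recoverable by the asymmetry
#' profiles. Each record carries Poisson read depth and a truncated-normal
#' alt fraction so that a predictable share fails the call filters.
#' Deterministic for a fixed seed.
#'
#' @param genome,transcripts,origins a reference as from [makeReference()].
#' @param params a [catalogSimParams()].
#' @return data.frame of mutation records (`sample`, `chrom`, `pos`, `ref`,
#'   `alt`, `depth`, `alt_fraction`), sorted within samples. Attributes:
#'   `"params"` (the generator parameters) and `"truth"` (per-record
#'   `event_type` and `event_id` ground truth).
#' @export
simulateCatalog <- function(genome, transcripts, origins, params) {
  stopifnot(inherits(params, "CatalogSimParams"))
  ctx <- .simContext(genome, transcripts, origins)
  withSeed(params$seed, {
    perSample <- lapply(seq_len(params$nSamples), function(si) {
      sampleName <- sprintf("s%03d", si)
      n <- rpois(1L, params$mutationsPerGenomeMean)
      if (n == 0L) return(NULL)
      mix <- rmultinom(1L, n, c(params$substitutionFraction,
                                params$indelFraction,
                                params$complexFraction))[, 1L]
      nSub <- mix[1L]; nIndel <- mix[2L]; nComplex <- mix[3L]
      rows <- list()

      if (nSub > 0L) {
        cls <- sample(substitutionClasses(), nSub, replace = TRUE,
                      prob = params$classWeights)
        isA <- substr(cls, 1L, 1L) == "A"
        sub <- data.frame(chrom = character(nSub), pos = numeric(nSub),
                          ref = character(nSub), alt = character(nSub))
        if (any(isA)) {
          s <- .sampleSites(ctx, "AT", sum(isA))
          ref <- mapply(function(ch, p) ctx$chars[[ch]][p],
                        s$chrom, s$pos, USE.NAMES = FALSE)
          target <- substr(cls[isA], 3L, 3L)
          sub[isA, ] <- data.frame(
            chrom = s$chrom, pos = s$pos, ref = ref,
            alt = unname(ifelse(ref == "A", target, COMPLEMENT[target])))
        }
        nG <- sum(!isA)
        if (nG > 0L) {
          picked <- NULL
          while (is.null(picked) || nrow(picked) < nG) {
            cand <- .sampleSites(ctx, "CG", max(2L * nG, 20L))
            ref <- mapply(function(ch, p) ctx$chars[[ch]][p],
                          cand$chrom, cand$pos, USE.NAMES = FALSE)
            pTop <- numeric(nrow(cand))
            for (ii in split(seq_len(nrow(cand)), cand$chrom))
              pTop[ii] <- .pTopC(ctx, cand$chrom[ii[1L]], cand$pos[ii],
                                 params$txBiasC, params$repGradientC)
            pAccept <- ifelse(ref == "C", pTop, 1 - pTop)
            keep <- runif(nrow(cand)) < pAccept
            cand$ref <- ref
            picked <- rbind(picked, cand[keep, , drop = FALSE])
          }
          picked <- picked[seq_len(nG), , drop = FALSE]
          target <- substr(cls[!isA], 3L, 3L)  # alt keyed to purine G
          sub[!isA, ] <- data.frame(
            chrom = picked$chrom, pos = picked$pos, ref = picked$ref,
            alt = unname(ifelse(picked$ref == "G", target,
                                COMPLEMENT[target])))
        }
        sub$event_type <- "substitution"
        sub$event_id <- paste0(sampleName, "_s", seq_len(nSub))
        rows <- c(rows, list(sub))
      }

      if (nIndel > 0L) {
        chrom <- sample(ctx$chroms, nIndel, replace = TRUE,
                        prob = ctx$lens)
        pos <- floor(runif(nIndel, 1, ctx$lens[chrom]))
        ins <- runif(nIndel) < 0.5
        ref1 <- mapply(function(ch, p) ctx$chars[[ch]][p], chrom, pos,
                       USE.NAMES = FALSE)
        ref2 <- mapply(function(ch, p)
          paste0(ctx$chars[[ch]][p], ctx$chars[[ch]][p + 1L]), chrom, pos,
          USE.NAMES = FALSE)
        ind <- data.frame(
          chrom = chrom, pos = pos,
          ref = ifelse(ins, ref1, ref2),
          alt = ifelse(ins, paste0(ref1, sample(DNA_BASES, nIndel,
                                                replace = TRUE)), ref1),
          event_type = ifelse(ins, "insertion", "deletion"),
          event_id = paste0(sampleName, "_i", seq_len(nIndel)))
        rows <- c(rows, list(ind))
      }

      if (nComplex > 0L) {
        chrom <- sample(ctx$chroms, nComplex, replace = TRUE,
                        prob = ctx$lens)
        anchor <- floor(runif(nComplex, 1, ctx$lens[chrom] - 10))
        gap <- sample.int(10L, nComplex, replace = TRUE)
        cpx <- data.frame(
          chrom = rep(chrom, each = 2L),
          pos = as.numeric(rbind(anchor, anchor + gap)),
          event_type = "complex",
          event_id = rep(paste0(sampleName, "_c", seq_len(nComplex)),
                         each = 2L))
        cpx$ref <- mapply(function(ch, p) ctx$chars[[ch]][p], cpx$chrom,
                          cpx$pos, USE.NAMES = FALSE)
        cpx$alt <- .randomAlt(cpx$ref)
        rows <- c(rows, list(cpx[, c("chrom", "pos", "ref", "alt",
                                     "event_type", "event_id")]))
      }

      rec <- do.call(rbind, rows)
      rec$sample <- sampleName
      rec$depth <- rpois(nrow(rec), params$depthMean)
      rec$alt_fraction <- pmin(pmax(rnorm(nrow(rec), params$vafMode, 0.03),
                                    0), 1)
      rec <- rec[order(rec$chrom, rec$pos), , drop = FALSE]
      rec[!duplicated(paste(rec$chrom, rec$pos)), , drop = FALSE]
    })
    all <- do.call(rbind, perSample)
    rownames(all) <- NULL
    out <- all[, REQUIRED_RECORD_COLS]
    attr(out, "params") <- params
    attr(out, "truth") <- all[, c("sample", "chrom", "pos", "event_type",
                                  "event_id")]
    out
  })
}
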