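## Synthetic cohort generator.
##
## Emulates the statistical structure the downstream analysis assumes: a
## cohort of diploid samples carrying one contiguous multiallelic CNV block
## embedded among decoy CNVs whose copy numbers vary independently of the
## focal block, assayed on a jittered tiling array; PRT / ddPCR replicate
## measurements; and tandem-paralog haplotype pairs with separate paralog-
## divergence and allelic-diversity substitution processes.

#' Tile a genomic region with jittered array probes
#'
#' Lays probes across \code{region} at an average spacing of
#' \code{meanSpacing} bp, with uniform jitter of up to
#' \code{jitterFrac * meanSpacing} around each grid position (zero jitter
#' gives an exact grid). Mimics tiling-oligo aCGH designs with a density of
#' e.g. ~1.5 probes/kb at a 667-bp spacing.
#'
#' @param region length-1 \link[GenomicRanges]{GRanges}; must be at least
#'   twice the spacing wide.
#' @param meanSpacing mean probe spacing in bp (> 0).
#' @param probeLength probe footprint in bp.
#' @param jitterFrac jitter amplitude as a fraction of \code{meanSpacing},
#'   in [0, 0.5).
#' @param seed integer seed for the jitter draw.
#' @return \code{GRanges} of probes, sorted, with unique names
#'   (\code{probe_id}).
#' @examples
#' reg <- GenomicRanges::GRanges("chr8", IRanges::IRanges(1, 10000))
#' makeProbeSet(reg, meanSpacing = 1000, jitterFrac = 0)
#' @export
makeProbeSet <- function(region, meanSpacing, probeLength = 50,
                         jitterFrac = 0.25, seed = 1) {
  stopifnot(is(region, "GRanges"), length(region) == 1L)
  if (meanSpacing <= 0) stop("meanSpacing must be > 0")
  if (jitterFrac < 0 || jitterFrac >= 0.5)
    stop("jitterFrac must be in [0, 0.5)")
  len <- width(region)
  if (len < 2 * meanSpacing)
    stop("region must be at least twice the probe spacing")
  n <- as.integer(floor(len / meanSpacing))
  grid <- start(region) + round((seq_len(n) - 1L) * meanSpacing)
  jit <- if (jitterFrac > 0)
    withSeed(seed, round(runif(n, -jitterFrac, jitterFrac) * meanSpacing))
  else rep(0L, n)
  starts <- pmin(pmax(grid + jit, start(region)),
                 end(region) - probeLength + 1L)
  starts <- sort(starts)
  gr <- GRanges(seqnames(region),
                IRanges(start = starts, width = probeLength))
  names(gr) <- sprintf("p%05d", seq_len(n))
  gr
}

## Expected log2 test/reference ratio; pseudocount floors the cn = 0 case
## (arrays saturate near zero signal; -Inf would poison every matrix op).
expectedLog2Ratio <- function(cn, refCn = 2, pseudo = 0.05) {
  ifelse(cn == 0, log2((cn + pseudo) / (refCn + pseudo)), log2(cn / refCn))
}

#' Simulate an aCGH cohort over a CNV locus
#'
#' Draws per-sample integer copy numbers for the focal block (uniform over
#' \code{config$cnRange}) and, independently, for each decoy CNV; sets the
#' expected log2 ratio of every probe overlapping a copy-number-variable
#' interval to \code{attenuation * log2(cn / refCn)} (0 elsewhere); and
#' adds i.i.d. Gaussian probe noise. An optional dropout element (a
#' polymorphic retroelement-absence analogue) subtracts a fixed delta from
#' carrier samples over a sub-interval of the block. Identical seed and
#' config reproduce the cohort bit-for-bit.
#'
#' @param config a cohort configuration list, see [cohortConfig()].
#' @param seed integer seed; defaults to \code{config$seed}.
#' @return a \linkS4class{CNVCohort}; truth (block, per-sample copy number,
#'   decoys, dropout carriers) is in \code{colData()}/\code{metadata()}.
#' @seealso [humanLocusConfig()], [macaqueLocusConfig()]
#' @export
simulateCohort <- function(config, seed = config$seed) {
  config <- validateCohortConfig(config)
  probes <- makeProbeSet(config$region, config$probeSpacing,
                         probeLength = config$probeLength,
                         jitterFrac = config$jitterFrac,
                         seed = deriveSeed(seed, "probes"))
  n <- config$nSamples
  sampleIds <- sprintf("S%03d", seq_len(n))
  cnr <- config$cnRange

  drawCn <- function(rng, n) {
    vals <- seq(rng[1], rng[2])     # guard the scalar case: sample(2) == 1:2
    vals[sample.int(length(vals), n, replace = TRUE)]
  }

  res <- withSeed(deriveSeed(seed, "cohort"), {
    cn <- drawCn(cnr, n)
    decoyCN <- if (length(config$decoys))
      vapply(seq_along(config$decoys),
             function(i) drawCn(config$decoyCnRange, n), numeric(n))
    else matrix(numeric(0), nrow = n, ncol = 0)
    E <- matrix(0, nrow = length(probes), ncol = n)
    inBlock <- overlapsAny(probes, config$block)
    E[inBlock, ] <- config$attenuation *
      rep(expectedLog2Ratio(cn, config$refCn), each = sum(inBlock))
    for (i in seq_along(config$decoys)) {
      inDecoy <- overlapsAny(probes, config$decoys[i])
      E[inDecoy, ] <- config$attenuation *
        rep(expectedLog2Ratio(decoyCN[, i], config$refCn),
            each = sum(inDecoy))
    }
    carriers <- character(0)
    if (!is.null(config$dropout)) {
      d <- config$dropout
      carriers <- sample(sampleIds, d$nCarriers)
      inDrop <- overlapsAny(probes, d$interval)
      E[inDrop, match(carriers, sampleIds)] <-
        E[inDrop, match(carriers, sampleIds)] - d$delta
    }
    lr <- E + rnorm(length(E), sd = config$noiseSd)
    list(cn = cn, decoyCN = decoyCN, carriers = carriers, lr = lr)
  })

  dimnames(res$lr) <- list(names(probes), sampleIds)
  se <- SummarizedExperiment(
    assays = list(lr = res$lr), rowRanges = probes,
    colData = DataFrame(trueCN = as.integer(res$cn), row.names = sampleIds))
  metadata(se)$truth <- list(block = config$block, decoys = config$decoys,
                             decoyCN = res$decoyCN,
                             dropoutCarriers = res$carriers,
                             dropout = config$dropout)
  metadata(se)$config <- config
  metadata(se)$seed <- seed
  new("CNVCohort", se)
}

#' Simulate paralog-ratio-test replicates for one sample
#'
#' Replicate test/reference peak-area ratios have expectation
#' \code{trueCn / refCn} under multiplicative lognormal noise with
#' coefficient of variation \code{noiseCv} (mean-corrected so the
#' expectation is exact).
#'
#' @param trueCn true diploid copy number of the sample.
#' @param nReplicates number of replicate reactions (default 5).
#' @param noiseCv coefficient of variation of the ratio (0 = noise-free).
#' @param refCn reference-locus diploid copy number (2: a non-CNV locus).
#' @param sampleId sample identifier.
#' @param seed integer seed.
#' @return a \linkS4class{PRTRun}.
#' @export
simulatePRT <- function(trueCn, nReplicates = 5, noiseCv = 0.05, refCn = 2,
                        sampleId = "sample", seed = 1) {
  if (nReplicates < 1) stop("nReplicates must be >= 1")
  ratio <- trueCn / refCn
  withSeed(deriveSeed(seed, "prt"), {
    refArea <- 10000 * exp(rnorm(nReplicates, 0, 0.1))
    mult <- if (noiseCv > 0) {
      s <- sqrt(log(1 + noiseCv^2))
      exp(rnorm(nReplicates, -s^2 / 2, s))
    } else rep(1, nReplicates)
    PRTRun(sampleId, testArea = refArea * ratio * mult, refArea = refArea)
  })
}

#' Simulate duplex droplet-digital-PCR replicates for one sample
#'
#' Droplets are loaded under a Poisson model: the reference channel at
#' \code{lambdaRef} mean molecules per droplet, the test channel at
#' \code{lambdaRef * trueCn / refCn}. Positive-droplet counts per replicate
#' are binomial with success probability \code{1 - exp(-lambda)}. A
#' replicate in which every droplet is positive in a channel is flagged
#' saturated.
#'
#' @param trueCn true diploid copy number.
#' @param nDroplets droplets generated per replicate.
#' @param lambdaRef mean reference molecules per droplet (>= 0).
#' @param nReplicates replicate reactions (default 4).
#' @param refCn reference diploid copy number.
#' @param sampleId sample identifier.
#' @param seed integer seed.
#' @return a \linkS4class{DdpcrRun}.
#' @export
simulateDdpcr <- function(trueCn, nDroplets = 20000, lambdaRef = 0.5,
                          nReplicates = 4, refCn = 2, sampleId = "sample",
                          seed = 1) {
  if (lambdaRef < 0) stop("lambdaRef must be >= 0")
  if (nReplicates < 1) stop("nReplicates must be >= 1")
  lambdaTest <- lambdaRef * trueCn / refCn
  withSeed(deriveSeed(seed, "ddpcr"), {
    nd <- rep(as.integer(nDroplets), nReplicates)
    tp <- rbinom(nReplicates, nd, 1 - exp(-lambdaTest))
    rp <- rbinom(nReplicates, nd, 1 - exp(-lambdaRef))
    DdpcrRun(sampleId, nDroplets = nd, nTestPositive = tp,
             nRefPositive = rp, saturated = tp == nd | rp == nd)
  })
}

## ---- coding-sequence machinery -------------------------------------------

stopCodons <- c("TAA", "TAG", "TGA")

codonTable <- function() Biostrings::GENETIC_CODE

## all single-nucleotide changes of a codon that avoid stop codons,
## classified synonymous / nonsynonymous
codonChangeOptions <- function(codon) {
  gc <- codonTable()
  aa <- gc[[codon]]
  out <- list()
  for (pos in 1:3) for (b in c("A", "C", "G", "T")) {
    if (substr(codon, pos, pos) == b) next
    new <- codon
    substr(new, pos, pos) <- b
    if (new %in% stopCodons) next
    out[[length(out) + 1L]] <- data.frame(
      pos = pos, to = b, newCodon = new,
      class = if (gc[[new]] == aa) "syn" else "nonsyn")
  }
  do.call(rbind, out)
}

#' Generate a random in-frame coding sequence
#'
#' Uniform draw over non-stop codons; no internal stop codons by
#' construction.
#'
#' @param nCodons number of codons.
#' @param seed integer seed.
#' @return single-element character vector (DNA).
#' @export
randomCds <- function(nCodons = 64, seed = 1) {
  codons <- setdiff(names(codonTable()), stopCodons)
  withSeed(deriveSeed(seed, "cds"),
           paste(sample(codons, nCodons, replace = TRUE), collapse = ""))
}

## pick class labels for a substitution batch
substClasses <- function(nSubs, nonsynFrac, stochastic) {
  if (nSubs == 0) return(character(0))
  nNon <- if (stochastic) rbinom(1, nSubs, nonsynFrac)
          else as.integer(round(nSubs * nonsynFrac))
  sample(c(rep("nonsyn", nNon), rep("syn", nSubs - nNon)))
}

#' Simulate tandem-paralog haplotype pairs with labelled substitutions
#'
#' Builds two haplotypes, each carrying a proximal and a distal copy of one
#' coding sequence. Paralog-divergence substitutions (shared by both
#' haplotypes) are applied to the distal copy; allelic-diversity
#' substitutions are applied to the second haplotype, alternating between
#' paralog positions. Every substitution occupies its own codon
#' (zero homoplasy, no multi-hit codons), is engineered to be synonymous or
#' nonsynonymous per the requested mix, and never creates a stop codon.
#' Truth labels, including the expected divergence/diversity class counts
#' under the within-haplotype (averaged) / between-haplotype
#' (position-summed) counting used by [partitionVariation()], are returned
#' in the \code{truth} slot.
#'
#' @param paralogSubs number of paralog-divergence substitutions.
#' @param allelicSubs number of allelic-diversity substitutions.
#' @param nonsynFracParalog,nonsynFracAllele nonsynonymous fraction of each
#'   substitution batch (deterministic rounding by default).
#' @param ancestralCds optional ancestral CDS (character); generated with
#'   [randomCds()] when \code{NULL}.
#' @param nCodons codons in the generated ancestral CDS.
#' @param stochasticClasses draw each substitution's class as
#'   Bernoulli(\code{nonsynFrac}) instead of a fixed rounded split.
#' @param seed integer seed.
#' @param haplotypeIds labels for the two haplotypes.
#' @return a \linkS4class{HaplotypeSet} of four sequences.
#' @export
simulateParalogHaplotypes <- function(paralogSubs, allelicSubs,
                                      nonsynFracParalog = 0.5,
                                      nonsynFracAllele = 0.5,
                                      ancestralCds = NULL, nCodons = 64,
                                      stochasticClasses = FALSE, seed = 1,
                                      haplotypeIds = c("hapA", "hapB")) {
  if (is.null(ancestralCds))
    ancestralCds <- randomCds(nCodons, seed = seed)
  ancestralCds <- toupper(as.character(ancestralCds))
  if (nchar(ancestralCds) %% 3 != 0)
    stop("ancestral CDS length must be divisible by 3")
  nc <- nchar(ancestralCds) / 3
  codons <- substring(ancestralCds, 3 * seq_len(nc) - 2, 3 * seq_len(nc))
  if (any(codons %in% stopCodons)) stop("ancestral CDS has internal stops")

  withSeed(deriveSeed(seed, "sequences"), {
    classes <- c(substClasses(paralogSubs, nonsynFracParalog,
                              stochasticClasses),
                 substClasses(allelicSubs, nonsynFracAllele,
                              stochasticClasses))
    kind <- rep(c("divergence", "diversity"),
                c(paralogSubs, allelicSubs))
    avail <- sample(seq_len(nc))       # codon pool, each used at most once
    subs <- vector("list", length(classes))
    for (i in seq_along(classes)) {
      found <- FALSE
      for (j in seq_along(avail)) {
        opts <- codonChangeOptions(codons[avail[j]])
        opts <- opts[opts$class == classes[i], , drop = FALSE]
        if (nrow(opts) > 0) {
          pick <- opts[sample(nrow(opts), 1), ]
          subs[[i]] <- data.frame(codon = avail[j], pos = pick$pos,
                                  newCodon = pick$newCodon,
                                  class = classes[i], kind = kind[i])
          avail <- avail[-j]
          found <- TRUE
          break
        }
      }
      if (!found)
        stop("requested substitution count exceeds available sites of ",
             "class '", classes[i], "'")
    }
    subs <- if (length(subs)) do.call(rbind, subs) else
      data.frame(codon = integer(0), pos = integer(0),
                 newCodon = character(0), class = character(0),
                 kind = character(0))

    apply_subs <- function(cod, rows) {
      for (r in seq_len(nrow(rows))) cod[rows$codon[r]] <- rows$newCodon[r]
      cod
    }
    div <- subs[subs$kind == "divergence", , drop = FALSE]
    alle <- subs[subs$kind == "diversity", , drop = FALSE]
    # alternate allelic substitutions between paralog positions of hap 2
    alle$position <- rep_len(c("proximal", "distal"),
                             nrow(alle))[seq_len(nrow(alle))]
    h1p <- codons
    h1d <- apply_subs(codons, div)
    h2p <- apply_subs(codons, alle[alle$position == "proximal", ,
                                   drop = FALSE])
    h2d <- apply_subs(apply_subs(codons, div),
                      alle[alle$position == "distal", , drop = FALSE])

    countClasses <- function(cl)
      c(nonsyn = sum(cl == "nonsyn"), syn = sum(cl == "syn"))
    ## expected cells under partitionVariation's counting: hap2's
    ## paralog comparison also crosses every allelic substitution
    expected <- rbind(
      divergence = countClasses(div$class) + countClasses(alle$class) / 2,
      diversity = countClasses(alle$class))

    seqs <- DNAStringSet(vapply(list(h1p, h1d, h2p, h2d),
                                paste, character(1), collapse = ""))
    names(seqs) <- paste(rep(haplotypeIds, each = 2),
                         rep(c("proximal", "distal"), 2), sep = "|")
    HaplotypeSet(seqs,
                 haplotype = rep(haplotypeIds, each = 2),
                 position = rep(c("proximal", "distal"), 2),
                 truth = list(substitutions = subs,
                              expectedCounts = expected,
                              ancestralCds = ancestralCds))
  })
}

#' Simulate a PRT + ddPCR assay panel for a cohort
#'
#' Convenience wrapper: one [simulatePRT()] and one [simulateDdpcr()] run
#' per sample, seeded from one top-level seed through per-sample
#' substreams.
#'
#' @param trueCn named integer vector of per-sample diploid copy numbers.
#' @param seed integer seed.
#' @param prtNoiseCv,prtReplicates PRT noise and replication settings.
#' @param ddpcrDroplets,ddpcrLambdaRef,ddpcrReplicates ddPCR settings.
#' @return list with elements \code{prt} and \code{ddpcr}, each a named
#'   list of runs.
#' @export
simulateAssayPanel <- function(trueCn, seed = 1, prtNoiseCv = 0.05,
                               prtReplicates = 5, ddpcrDroplets = 20000,
                               ddpcrLambdaRef = 0.5, ddpcrReplicates = 4) {
  ids <- names(trueCn)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_along(trueCn))
  prt <- lapply(seq_along(trueCn), function(i)
    simulatePRT(trueCn[i], nReplicates = prtReplicates,
                noiseCv = prtNoiseCv, sampleId = ids[i],
                seed = deriveSeed(seed, paste0("prt", ids[i]))))
  dd <- lapply(seq_along(trueCn), function(i)
    simulateDdpcr(trueCn[i], nDroplets = ddpcrDroplets,
                  lambdaRef = ddpcrLambdaRef,
                  nReplicates = ddpcrReplicates, sampleId = ids[i],
                  seed = deriveSeed(seed, paste0("ddpcr", ids[i]))))
  names(prt) <- names(dd) <- ids
  list(prt = prt, ddpcr = dd)
}
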