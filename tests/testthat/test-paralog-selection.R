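## build a 64-codon reference with known codons at chosen positions
refWith <- function(replacements = list()) {
  codons <- rep("GCT", 64)            # Ala backbone
  codons[1] <- "ATG"
  for (nm in names(replacements)) codons[as.integer(nm)] <- replacements[[nm]]
  paste(codons, collapse = "")
}

mkCountsOf <- function(dn, ds, pn, ps, sitesN = 150, sitesS = 50) {
  counts <- rbind(divergence = c(nonsyn = dn, syn = ds),
                  diversity = c(nonsyn = pn, syn = ps))
  corrected <- counts; corrected[] <- NA_real_
  new("MKCounts", counts = counts, corrected = corrected,
      sites = c(nonsyn = sitesN, syn = sitesS), nHaplotypes = 2L)
}

test_that("codon differences classify by pathway averaging", {
  ref <- refWith()
  expect_equal(classifyNucDiffs(ref, ref)[c("nonsyn", "syn")],
               list(nonsyn = 0, syn = 0))

  # GGA -> AGA is Gly -> Arg: one nonsynonymous change
  a <- refWith(list(`10` = "GGA"))
  b <- refWith(list(`10` = "AGA"))
  expect_equal(classifyNucDiffs(a, b)$nonsyn, 1)
  expect_equal(classifyNucDiffs(a, b)$syn, 0)

  # TTA vs CTG (Leu vs Leu), two differences: both substitution orders
  # pass through Leu codons (CTA, TTG), so both steps are synonymous on
  # every minimal pathway
  x <- refWith(list(`20` = "TTA"))
  y <- refWith(list(`20` = "CTG"))
  d <- classifyNucDiffs(x, y)
  expect_equal(d$nonsyn, 0)
  expect_equal(d$syn, 2)
  expect_equal(d$records$nDiff, 2)

  # a mixed-pathway codon gives fractional counts that sum to nDiff
  two <- classifyNucDiffs(refWith(list(`30` = "TTT")),
                          refWith(list(`30` = "CTA")))
  expect_equal(two$nonsyn + two$syn, 2)

  # symmetry in counts
  set.seed(5)
  h <- simulateParalogHaplotypes(7, 0, nonsynFracParalog = 0.5, seed = 15)
  sA <- as.character(h@sequences[[1]]); sB <- as.character(h@sequences[[2]])
  expect_equal(classifyNucDiffs(sA, sB)[c("nonsyn", "syn")],
               classifyNucDiffs(sB, sA)[c("nonsyn", "syn")])

  expect_error(classifyNucDiffs("ATG", "ATGGCT"), "equal length")
})

test_that("Jukes-Cantor correction matches the closed form", {
  expect_equal(jcCorrect(0, 100), 0)
  expect_equal(round(jcCorrect(10, 100), 2), 10.73)
  expect_equal(jcCorrect(10, 100), 100 * (-0.75 * log(1 - 0.4 / 3)))
  expect_error(jcCorrect(75, 100), "saturation")
  expect_error(jcCorrect(80, 100), "saturation")
  # corrected/raw -> 1 as p -> 0
  expect_equal(jcCorrect(1, 10000) / 1, 1, tolerance = 1e-3)
  # correction never shrinks a count
  for (k in c(1, 5, 20, 50)) expect_gte(jcCorrect(k, 100), k)
})

test_that("variation partitions into divergence and diversity cells", {
  h0 <- simulateParalogHaplotypes(0, 0, seed = 2)
  c0 <- partitionVariation(h0, jc = FALSE)
  expect_true(all(c0@counts == 0))

  # recovered cells match the generator's truth labels exactly
  h <- simulateParalogHaplotypes(6, 4, nonsynFracParalog = 2/3,
                                 nonsynFracAllele = 1/4, seed = 17)
  cc <- partitionVariation(h, jc = FALSE)
  expect_equal(cc@counts, h@truth$expectedCounts)
  expect_equal(sum(cc@counts["diversity", ]), 4)

  # JC-corrected cells dominate raw cells and use per-class sites
  ccJC <- partitionVariation(h)
  expect_true(all(ccJC@corrected >= ccJC@counts))
  expect_equal(unname(sum(ccJC@sites)), 192)

  # BAC-style labels pass through untouched
  hb <- HaplotypeSet(h@sequences, haplotype = rep(c("65I2", "243E20"),
                                                  each = 2),
                     position = h@position)
  expect_equal(partitionVariation(hb, jc = FALSE)@counts, cc@counts)

  # a haplotype missing one paralog position is excluded with a warning
  h3 <- HaplotypeSet(c(h@sequences, h@sequences[1]),
                     haplotype = c(h@haplotype, "hapC"),
                     position = c(h@position, "proximal"))
  expect_warning(c3 <- partitionVariation(h3, jc = FALSE), "hapC")
  expect_equal(c3@counts, cc@counts)
})

test_that("the MK test reproduces Fisher exact probabilities and NI", {
  r <- mkTest(mkCountsOf(10, 2, 2, 8))
  expect_equal(r@pValue,
               fisherEnumOracle(rbind(c(10, 2), c(2, 8))), tolerance = 1e-12)
  expect_equal(r@neutralityIndex, (2 / 8) / (10 / 2))
  expect_identical(r@direction, "positive")

  # balanced table: p = 1, NI = 1, neutral
  rb <- mkTest(mkCountsOf(5, 5, 5, 5))
  expect_equal(rb@pValue, 1)
  expect_equal(rb@neutralityIndex, 1)
  expect_identical(rb@direction, "neutral")

  # swapping rows leaves p unchanged
  expect_equal(mkTest(mkCountsOf(2, 8, 10, 2))@pValue, r@pValue)

  # an empty margin is uninformative, not significant
  rz <- mkTest(mkCountsOf(0, 0, 3, 4))
  expect_false(rz@informative)
  expect_equal(rz@pValue, 1)
})

test_that("amino-acid variants are named in reference-first style", {
  ref <- refWith(list(`45` = "GGA", `52` = "GTT", `56` = "CCT",
                      `57` = "CTT"))
  expect_length(diffAA(ref, ref), 0)

  oneVar <- refWith(list(`45` = "AGA", `52` = "GTT", `56` = "CCT",
                         `57` = "CTT"))
  expect_identical(as.character(diffAA(oneVar, ref)), "G45R")

  # a four-change variant mirroring the G45R/V52I/P56S/L57A pattern
  fourVar <- refWith(list(`45` = "AGA", `52` = "ATT", `56` = "TCT",
                          `57` = "GCT"))
  expect_identical(as.character(diffAA(fourVar, ref)),
                   c("G45R", "V52I", "P56S", "L57A"))

  # premature stop flagged and labelled X
  stopVar <- refWith(list(`45` = "TGA", `52` = "GTT", `56` = "CCT",
                          `57` = "CTT"))
  labs <- diffAA(stopVar, ref)
  expect_true(attr(labs, "prematureStop"))
  expect_identical(as.character(labs), "G45X")
})

test_that("global-alignment identity agrees with an exhaustive DP oracle", {
  base <- randomCds(nCodons = 40, seed = 33)   # 120 bp
  expect_equal(pairwiseIdentity(base, base), 100.0)

  m100 <- substr(paste0(base, base), 1, 100)
  s100 <- m100
  substr(s100, 42, 42) <- if (substr(s100, 42, 42) == "G") "T" else "G"
  expect_equal(pairwiseIdentity(m100, s100), 99.0)

  # 200-bp pair: 9 substitutions + one 3-bp deletion
  a <- substr(paste0(base, base, base), 1, 200)
  b <- a
  for (pos in c(10, 30, 55, 79, 101, 126, 150, 171, 195)) {
    substr(b, pos, pos) <- chartr("ACGT", "CAtg", toupper(substr(b, pos, pos)))
  }
  b <- toupper(b)
  b <- paste0(substr(b, 1, 60), substr(b, 64, 200))    # drop 3 bp
  expect_equal(pairwiseIdentity(a, b), round(100 * 188 / 200, 1))
  # the aligner's optimum equals the full Gotoh DP table's optimum
  mat <- Biostrings::nucleotideSubstitutionMatrix(1, -1, baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                       Biostrings::DNAString(b),
                                       type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 5, gapExtension = 1)
  expect_equal(BiocGenerics::score(aln), gotohScoreOracle(a, b))
  expect_equal(BiocGenerics::score(aln), 188 - 9 - (5 + 3))

  expect_error(pairwiseIdentity("", "ACGT"), "empty")
})
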