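## Paralog-vs-allele selection analysis: partition coding variation into
## paralog divergence (between tandem copies, within a phased haplotype)
## and allelic diversity (between haplotypes at the same copy), correct
## for multiple hits, and test for selection with a McDonald-Kreitman
## 2x2 Fisher exact test. An excess of nonsynonymous changes in the
## divergence class relative to the diversity class indicates positive
## selection acting on the paralogs after duplication.

.codonAt <- function(seq, i) substr(seq, 3 * i - 2, 3 * i)

## memoization caches: codon-pair pathway tallies and per-codon site counts
.pathCache <- new.env(parent = emptyenv())
.siteCache <- new.env(parent = emptyenv())

## classify the substitutions separating two codons, averaging over all
## minimal substitution pathways (Nei-Gojobori style); pathways passing
## through a stop codon are excluded unless every pathway does
.codonPathCounts <- function(ca, cb) {
  key <- paste0(ca, cb)
  hit <- .pathCache[[key]]
  if (!is.null(hit)) return(hit)
  diffPos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  k <- length(diffPos)
  if (k == 0) return(c(nonsyn = 0, syn = 0))
  gc <- codonTable()
  paths <- combinat_perms(diffPos)
  tally <- matrix(NA_real_, nrow = nrow(paths), ncol = 2)
  viaStop <- logical(nrow(paths))
  for (p in seq_len(nrow(paths))) {
    cur <- ca
    ns <- s <- 0
    for (pos in paths[p, ]) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(cb, pos, pos)
      if (nxt %in% stopCodons && nxt != cb) viaStop[p] <- TRUE
      if (gc[[cur]] == gc[[nxt]]) s <- s + 1 else ns <- ns + 1
      cur <- nxt
    }
    tally[p, ] <- c(ns, s)
  }
  use <- if (all(viaStop)) seq_len(nrow(paths)) else which(!viaStop)
  out <- c(nonsyn = mean(tally[use, 1]), syn = mean(tally[use, 2]))
  .pathCache[[key]] <- out
  out
}

## tiny permutation enumerator (k <= 3 here)
combinat_perms <- function(x) {
  if (length(x) == 1) return(matrix(x, 1, 1))
  out <- NULL
  for (i in seq_along(x)) {
    rest <- combinat_perms(x[-i])
    out <- rbind(out, cbind(x[i], rest))
  }
  out
}

#' Classify nucleotide differences between two coding sequences
#'
#' Codon-by-codon comparison of two frame-aligned, equal-length coding
#' sequences. Codons differing at one site are classified by whether the
#' encoded amino acid changes; codons differing at two or three sites
#' contribute fractional counts obtained by averaging the
#' synonymous/nonsynonymous step tallies over all minimal substitution
#' pathways (pathways through stop codons excluded when avoidable).
#'
#' @param cdsA,cdsB character or \code{DNAString} coding sequences, equal
#'   length divisible by 3.
#' @return list with \code{nonsyn}, \code{syn} (possibly fractional) and
#'   \code{records}: one row per differing codon (codon index, number of
#'   differing sites, fractional class counts).
#' @export
classifyNucDiffs <- function(cdsA, cdsB) {
  a <- toupper(as.character(cdsA)); b <- toupper(as.character(cdsB))
  if (nchar(a) != nchar(b)) stop("sequences must have equal length")
  if (nchar(a) %% 3 != 0) stop("length must be divisible by 3")
  nc <- nchar(a) / 3
  rec <- list()
  ns <- s <- 0
  for (i in seq_len(nc)) {
    ca <- .codonAt(a, i); cb <- .codonAt(b, i)
    if (ca == cb) next
    cnt <- .codonPathCounts(ca, cb)
    ns <- ns + cnt["nonsyn"]; s <- s + cnt["syn"]
    rec[[length(rec) + 1L]] <- data.frame(
      codon = i, nDiff = sum(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]]),
      nonsyn = unname(cnt["nonsyn"]), syn = unname(cnt["syn"]))
  }
  list(nonsyn = unname(ns), syn = unname(s),
       records = if (length(rec)) do.call(rbind, rec) else
         data.frame(codon = integer(0), nDiff = integer(0),
                    nonsyn = numeric(0), syn = numeric(0)))
}

#' Nonsynonymous and synonymous site counts of a coding sequence
#'
#' Per-codon degeneracy tally: for each codon position, the fraction of
#' the three possible single-nucleotide changes that are synonymous
#' contributes to the synonymous site total (changes to stop codons count
#' as nonsynonymous); each codon contributes 3 sites in total.
#'
#' @param cds character or \code{DNAString} coding sequence.
#' @return named numeric \code{c(nonsyn=, syn=)}.
#' @export
ngSites <- function(cds) {
  a <- toupper(as.character(cds))
  if (nchar(a) %% 3 != 0) stop("length must be divisible by 3")
  gc <- codonTable()
  synOf <- function(cod) {
    hit <- .siteCache[[cod]]
    if (!is.null(hit)) return(hit)
    aa <- gc[[cod]]
    syn1 <- 0
    for (pos in 1:3) for (bse in c("A", "C", "G", "T")) {
      if (substr(cod, pos, pos) == bse) next
      alt <- cod
      substr(alt, pos, pos) <- bse
      if (!(alt %in% stopCodons) && gc[[alt]] == aa) syn1 <- syn1 + 1 / 3
    }
    .siteCache[[cod]] <- syn1
    syn1
  }
  syn <- sum(vapply(seq_len(nchar(a) / 3),
                    function(i) synOf(.codonAt(a, i)), numeric(1)))
  c(nonsyn = nchar(a) - syn, syn = syn)
}

#' Jukes-Cantor multiple-hit correction of a substitution count
#'
#' Converts an observed difference count over \code{sites} comparable
#' sites into the expected number of substitutions under the one-parameter
#' Jukes-Cantor model: \eqn{d = -\frac{3}{4}\ln(1 - \frac{4}{3}p)} with
#' \eqn{p} the observed proportion, scaled back to a count
#' (\code{sites * d}). The corrected count is never below the raw count
#' and diverges as \eqn{p \to 3/4} (saturation).
#'
#' @param rawCount observed differences (>= 0).
#' @param sites comparable sites (> 0).
#' @return corrected count.
#' @examples
#' jcCorrect(10, 100)  # 10.73
#' @export
jcCorrect <- function(rawCount, sites) {
  if (sites <= 0) stop("sites must be > 0")
  p <- rawCount / sites
  if (p < 0) stop("negative count")
  if (p >= 0.75)
    stop("observed proportion ", round(p, 3),
         " at or beyond Jukes-Cantor saturation (3/4)")
  sites * (-0.75 * log(1 - 4 * p / 3))
}

#' Partition coding variation into paralog divergence and allelic diversity
#'
#' Divergence cells: pathway-classified differences between the proximal
#' and distal paralog within each haplotype, averaged over haplotypes.
#' Diversity cells: differences between haplotype pairs at the same
#' paralog position, summed over positions. Jukes-Cantor correction is
#' applied per cell on its own site denominator (nonsynonymous vs
#' synonymous site totals from the per-codon degeneracy tally, averaged
#' over the sequences).
#'
#' @param h a \linkS4class{HaplotypeSet} with >= 2 haplotypes; haplotypes
#'   missing a paralog position are excluded with a warning.
#' @param jc apply the Jukes-Cantor correction (default TRUE).
#' @return an \linkS4class{MKCounts}.
#' @export
partitionVariation <- function(h, jc = TRUE) {
  stopifnot(is(h, "HaplotypeSet"))
  seqs <- as.character(h@sequences)
  haps <- unique(h@haplotype)
  complete <- vapply(haps, function(hp)
    all(c("proximal", "distal") %in% h@position[h@haplotype == hp]),
    logical(1))
  if (any(!complete))
    warning("excluding haplotype(s) missing a paralog position: ",
            paste(haps[!complete], collapse = ", "))
  haps <- haps[complete]
  if (length(haps) < 2) stop("need >= 2 haplotypes with both positions")

  getSeq <- function(hp, pos) seqs[h@haplotype == hp & h@position == pos][1]
  divergence <- rowMeans(vapply(haps, function(hp) {
    d <- classifyNucDiffs(getSeq(hp, "proximal"), getSeq(hp, "distal"))
    c(d$nonsyn, d$syn)
  }, numeric(2)))
  pairs <- utils::combn(haps, 2)
  diversity <- c(0, 0)
  for (pos in c("proximal", "distal"))
    for (j in seq_len(ncol(pairs))) {
      d <- classifyNucDiffs(getSeq(pairs[1, j], pos),
                            getSeq(pairs[2, j], pos))
      diversity <- diversity + c(d$nonsyn, d$syn)
    }
  counts <- rbind(divergence = divergence, diversity = diversity)
  colnames(counts) <- c("nonsyn", "syn")

  sites <- rowMeans(vapply(seqs, ngSites, numeric(2)))
  names(sites) <- c("nonsyn", "syn")
  corrected <- counts
  if (jc)
    for (r in 1:2) for (cl in c("nonsyn", "syn"))
      corrected[r, cl] <- jcCorrect(counts[r, cl], sites[cl])
  else corrected[] <- NA_real_
  new("MKCounts", counts = counts, corrected = corrected, sites = sites,
      nHaplotypes = length(haps))
}

#' McDonald-Kreitman test on a divergence/diversity table
#'
#' Two-sided Fisher exact test on the 2x2 table \{divergence, diversity\}
#' x \{nonsynonymous, synonymous\}; Jukes-Cantor corrected counts are
#' rounded to the nearest integer first (exact tests require counts). The
#' neutrality index NI = (diversity_nonsyn / diversity_syn) /
#' (divergence_nonsyn / divergence_syn) is reported when defined; NI < 1
#' (equivalently, nonsynonymous excess in divergence) with a significant p
#' indicates positive selection on the paralogs.
#'
#' @param counts an \linkS4class{MKCounts}.
#' @param useCorrected test the Jukes-Cantor corrected table (default
#'   TRUE; falls back to raw when no correction was computed).
#' @return an \linkS4class{MKResult}.
#' @export
mkTest <- function(counts, useCorrected = TRUE) {
  stopifnot(is(counts, "MKCounts"))
  tab <- if (useCorrected && all(is.finite(counts@corrected)))
    counts@corrected else counts@counts
  tab <- round(tab)
  storage.mode(tab) <- "integer"
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(new("MKResult", table = tab, pValue = 1,
               neutralityIndex = NA_real_, direction = "neutral",
               informative = FALSE))
  p <- fisher.test(tab)$p.value
  ni <- if (tab["diversity", "syn"] > 0 && tab["divergence", "syn"] > 0 &&
            tab["divergence", "nonsyn"] > 0)
    (tab["diversity", "nonsyn"] / tab["diversity", "syn"]) /
      (tab["divergence", "nonsyn"] / tab["divergence", "syn"])
  else NA_real_
  direction <- if (is.na(ni) || ni == 1) "neutral"
               else if (ni < 1) "positive" else "negative"
  new("MKResult", table = tab, pValue = p, neutralityIndex = ni,
      direction = direction, informative = TRUE)
}

#' Name amino-acid variants relative to a reference
#'
#' One label per changed residue in \code{"G45R"} style: reference residue,
#' 1-based residue number from the initiator methionine of the reference
#' protein, variant residue. A premature stop in the variant is labelled
#' \code{"X"} at its position and the result carries attribute
#' \code{"prematureStop" = TRUE}.
#'
#' @param cdsVariant,cdsReference frame-aligned, equal-length coding
#'   sequences.
#' @return character vector of labels (empty when identical).
#' @export
diffAA <- function(cdsVariant, cdsReference) {
  v <- toupper(as.character(cdsVariant))
  r <- toupper(as.character(cdsReference))
  if (nchar(v) != nchar(r)) stop("sequences must have equal length")
  if (nchar(v) %% 3 != 0) stop("length must be divisible by 3")
  aaV <- strsplit(as.character(translate(DNAStringSet(v))[[1]]), "")[[1]]
  aaR <- strsplit(as.character(translate(DNAStringSet(r))[[1]]), "")[[1]]
  stopPos <- which(aaV == "*")
  premature <- length(stopPos) > 0 && any(stopPos < length(aaV))
  aaV[aaV == "*"] <- "X"
  changed <- which(aaV != aaR & aaR != "*")
  labels <- sprintf("%s%d%s", aaR[changed], changed, aaV[changed])
  structure(labels, prematureStop = premature)
}

#' Percent nucleotide identity by global alignment
#'
#' Needleman-Wunsch global alignment with affine gap penalties (declared
#' defaults: match +1, mismatch -1, gap open -5, gap extend -1); identity
#' is matches over aligned columns, gap columns counting as non-matches,
#' reported as percent to one decimal place.
#'
#' @param seqA,seqB non-empty DNA sequences (character or
#'   \code{DNAString}).
#' @param match,mismatch,gapOpening,gapExtension alignment parameters
#'   (penalties as positive magnitudes for the gap arguments).
#' @return percent identity (one decimal).
#' @export
pairwiseIdentity <- function(seqA, seqB, match = 1, mismatch = -1,
                             gapOpening = 5, gapExtension = 1) {
  a <- toupper(as.character(seqA)); b <- toupper(as.character(seqB))
  if (nchar(a) == 0 || nchar(b) == 0) stop("empty sequence")
  mat <- nucleotideSubstitutionMatrix(match = match, mismatch = mismatch,
                                      baseOnly = TRUE)
  aln <- pairwiseAlignment(DNAString(a), DNAString(b), type = "global",
                           substitutionMatrix = mat,
                           gapOpening = gapOpening,
                           gapExtension = gapExtension)
  cols <- nchar(as.character(alignedPattern(aln)))
  round(100 * nmatch(aln) / cols, 1)
}
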