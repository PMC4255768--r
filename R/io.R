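## File formats. Genomic intervals are GRanges (1-based, closed)
## in memory and BED/bedGraph (0-based, half-open) on disk; every output
## file opens with comment lines recording the package version, seed and
## configuration hash. Machine-readable outputs never mix with logs.

writeWithHeader <- function(df, path, seed = NA, config = NULL,
                            colNames = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(fileHeader(seed, config), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = colNames)
  invisible(path)
}

#' Write / read probe tables as BED4
#'
#' BED is 0-based half-open on disk; coordinates are converted from/to the
#' 1-based closed \code{GRanges} convention used in memory. Malformed
#' rows (end <= start, duplicate ids) are rejected with the offending line
#' number.
#'
#' @param probes probe \code{GRanges} with unique names.
#' @param path file path.
#' @param seed,config provenance stamped into the file header.
#' @return \code{writeProbesBed}: the path, invisibly;
#'   \code{readProbesBed}: a \code{GRanges}.
#' @export
writeProbesBed <- function(probes, path, seed = NA, config = NULL) {
  df <- data.frame(chrom = as.character(seqnames(probes)),
                   start = start(probes) - 1L, end = end(probes),
                   name = names(probes))
  writeWithHeader(df, path, seed, config, colNames = FALSE)
}

#' @rdname writeProbesBed
#' @export
readProbesBed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  if (!any(keep)) stop("no records in ", path)
  df <- read.table(text = lines[keep], sep = "\t",
                   col.names = c("chrom", "start", "end", "name"),
                   colClasses = c("character", "integer", "integer",
                                  "character"))
  bad <- which(df$end <= df$start)
  if (length(bad))
    stop("interval with end <= start at line ",
         which(keep)[bad[1]], " of ", path)
  dup <- which(duplicated(df$name))
  if (length(dup))
    stop("duplicate probe id '", df$name[dup[1]], "' at line ",
         which(keep)[dup[1]], " of ", path)
  gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end))
  names(gr) <- df$name
  sort(gr)
}

#' Write / read intensity matrices as TSV
#'
#' One row per probe (\code{probe_id} first column), one column per
#' sample. Ragged rows are a parse error naming the line.
#'
#' @param m numeric matrix, probes x samples, dimnames required.
#' @param path file path.
#' @param seed,config provenance header fields.
#' @export
writeIntensitiesTsv <- function(m, path, seed = NA, config = NULL) {
  stopifnot(nrow(m) == 0 || !is.null(rownames(m)), !is.null(colnames(m)))
  if (nrow(m) == 0) {
    df <- as.data.frame(matrix(character(0), nrow = 0, ncol = ncol(m) + 1,
                               dimnames = list(NULL,
                                               c("probe_id", colnames(m)))))
    return(writeWithHeader(df, path, seed, config))
  }
  ## 17 significant digits: doubles survive the text round trip bit-exactly
  fm <- matrix(sprintf("%.17g", m), nrow = nrow(m),
               dimnames = dimnames(m))
  fm[is.na(m)] <- "NA"
  df <- data.frame(probe_id = rownames(m), fm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  writeWithHeader(df, path, seed, config)
}

#' @rdname writeIntensitiesTsv
#' @export
readIntensitiesTsv <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  fields <- lengths(strsplit(lines[keep], "\t", fixed = TRUE))
  if (length(unique(fields)) > 1)
    stop("ragged matrix: line ",
         which(keep)[which(fields != fields[1])[1]], " of ", path,
         " has ", fields[which(fields != fields[1])[1]], " fields, expected ",
         fields[1])
  df <- read.table(text = lines[keep], sep = "\t", header = TRUE,
                   check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$probe_id
  m
}

#' Write block calls as BED6
#'
#' Score is the mean r2 inside the block scaled to 0-1000.
#'
#' @param blocks output of [callBlocks()].
#' @param path file path.
#' @param seed,config provenance header fields.
#' @export
writeBlocksBed <- function(blocks, path, seed = NA, config = NULL) {
  df <- data.frame(chrom = as.character(seqnames(blocks)),
                   start = start(blocks) - 1L, end = end(blocks),
                   name = sprintf("block%d", seq_along(blocks)),
                   score = pmin(1000L,
                                pmax(0L, round(mcols(blocks)$meanR2 * 1000))),
                   strand = ".")
  writeWithHeader(df, path, seed, config, colNames = FALSE)
}

#' Write an r2 track as bedGraph
#'
#' @param track output of [probeCnR2()].
#' @param path file path.
#' @param seed,config provenance header fields.
#' @export
writeR2Bedgraph <- function(track, path, seed = NA, config = NULL) {
  df <- data.frame(chrom = as.character(seqnames(track)),
                   start = start(track) - 1L, end = end(track),
                   value = round(mcols(track)$r2, 6))
  writeWithHeader(df[!is.na(df$value), ], path, seed, config,
                  colNames = FALSE)
}

#' Write / read raw assay measurements as TSV
#'
#' Long format: one row per sample x assay x replicate with columns
#' \code{sample}, \code{assay} (\code{prt}/\code{ddpcr}),
#' \code{replicate}, \code{v1..v3} (PRT: test and reference peak areas;
#' ddPCR: droplets, test positives, reference positives).
#'
#' @param panel list with \code{prt} and \code{ddpcr} run lists (see
#'   [simulateAssayPanel()]).
#' @param path file path.
#' @param seed,config provenance header fields.
#' @export
writeAssaysTsv <- function(panel, path, seed = NA, config = NULL) {
  rows <- list()
  for (r in panel$prt)
    rows[[length(rows) + 1L]] <- data.frame(
      sample = r@sampleId, assay = "prt",
      replicate = seq_along(r@testArea),
      v1 = r@testArea, v2 = r@refArea, v3 = NA_real_)
  for (r in panel$ddpcr)
    rows[[length(rows) + 1L]] <- data.frame(
      sample = r@sampleId, assay = "ddpcr",
      replicate = seq_along(r@nDroplets),
      v1 = r@nDroplets, v2 = r@nTestPositive, v3 = r@nRefPositive)
  writeWithHeader(do.call(rbind, rows), path, seed, config)
}

#' @rdname writeAssaysTsv
#' @export
readAssaysTsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#")
  prt <- lapply(split(df[df$assay == "prt", ],
                      df$sample[df$assay == "prt"]),
                function(d) PRTRun(d$sample[1], d$v1, d$v2))
  dd <- lapply(split(df[df$assay == "ddpcr", ],
                     df$sample[df$assay == "ddpcr"]),
               function(d) DdpcrRun(d$sample[1], d$v1, d$v2, d$v3,
                                    saturated = d$v2 == d$v1 | d$v3 == d$v1))
  list(prt = prt, ddpcr = dd)
}

#' Write / read haplotype coding sequences as FASTA
#'
#' Headers are pipe-delimited; the last two fields are the haplotype and
#' the paralog position (\code{proximal}/\code{distal}), any leading
#' fields (e.g. a variant label) are preserved in the sequence names.
#'
#' @param h a \linkS4class{HaplotypeSet}.
#' @param path file path.
#' @export
writeHaplotypeFasta <- function(h, path) {
  seqs <- h@sequences
  names(seqs) <- paste(h@haplotype, h@position, sep = "|")
  writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname writeHaplotypeFasta
#' @export
readHaplotypeFasta <- function(path) {
  seqs <- readDNAStringSet(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  if (any(lengths(parts) < 2))
    stop("FASTA headers must be '...|haplotype|position'")
  pos <- vapply(parts, function(p) p[length(p)], character(1))
  hap <- vapply(parts, function(p) p[length(p) - 1L], character(1))
  HaplotypeSet(seqs, haplotype = hap, position = pos)
}

#' Write cohort truth / an age bracket / an MK report as JSON
#'
#' @param cohort a \linkS4class{CNVCohort}.
#' @param path file path.
#' @export
writeTruthJson <- function(cohort, path) {
  tr <- metadata(cohort)$truth
  obj <- list(
    provenance = list(version = as.character(packageVersion("defensinCNV")),
                      seed = metadata(cohort)$seed,
                      config_hash = configHash(metadata(cohort)$config)),
    block = list(chrom = as.character(seqnames(tr$block)),
                 start = start(tr$block) - 1L, end = end(tr$block)),
    trueCN = as.list(trueCopyNumber(cohort)),
    dropoutCarriers = tr$dropoutCarriers)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeTruthJson
#' @param bracket an \linkS4class{AgeBracket}.
#' @export
writeBracketJson <- function(bracket, path) {
  jsonlite::write_json(
    list(min_age_Ma = bracket@minAge, max_age_Ma = bracket@maxAge,
         evidence = bracket@evidence),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeTruthJson
#' @param result an \linkS4class{MKResult}.
#' @param counts the \linkS4class{MKCounts} behind \code{result}.
#' @export
writeMkJson <- function(result, counts, path) {
  jsonlite::write_json(
    list(raw = as.data.frame(counts@counts),
         corrected = as.data.frame(counts@corrected),
         tested = as.data.frame(result@table),
         sites = as.list(counts@sites),
         p_value = result@pValue,
         neutrality_index = result@neutralityIndex,
         direction = result@direction),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write integer copy-number calls / method concordance as TSV
#'
#' @param calls data.frame from [callIntegers()].
#' @param path file path.
#' @param seed,config provenance header fields.
#' @export
writeCallsTsv <- function(calls, path, seed = NA, config = NULL) {
  writeWithHeader(calls, path, seed, config)
}

#' @rdname writeCallsTsv
#' @param concordance matrix from [methodConcordance()].
#' @export
writeConcordanceTsv <- function(concordance, path, seed = NA,
                                config = NULL) {
  df <- data.frame(method = rownames(concordance), concordance,
                   check.names = FALSE)
  writeWithHeader(df, path, seed, config)
}

#' Write every artifact of a pipeline run into a directory
#'
#' Emits probes.bed, intensities.tsv, truth.json, assays.tsv,
#' r2_track.bedgraph, blocks.bed, calls.tsv and concordance.tsv.
#'
#' @param result list from [runCohortPipeline()].
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
writePipelineOutputs <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cohort <- result$cohort
  seed <- metadata(cohort)$seed
  cfg <- metadata(cohort)$config
  writeProbesBed(probes(cohort), file.path(dir, "probes.bed"), seed, cfg)
  writeIntensitiesTsv(intensities(cohort),
                      file.path(dir, "intensities.tsv"), seed, cfg)
  writeTruthJson(cohort, file.path(dir, "truth.json"))
  writeAssaysTsv(result$panel, file.path(dir, "assays.tsv"), seed, cfg)
  writeR2Bedgraph(result$track, file.path(dir, "r2_track.bedgraph"), seed,
                  cfg)
  writeBlocksBed(result$blocks, file.path(dir, "blocks.bed"), seed, cfg)
  writeCallsTsv(result$calls, file.path(dir, "calls.tsv"), seed, cfg)
  writeConcordanceTsv(result$concordance,
                      file.path(dir, "concordance.tsv"), seed, cfg)
  invisible(dir)
}
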