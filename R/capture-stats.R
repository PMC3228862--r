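#' Read a per-base depth track
#'
#' Accepts a 3-column TSV `(chrom, pos, depth)`. `zeroBased = TRUE` (the
#' default) treats `pos` as a 0-based base offset; use `zeroBased = FALSE`
#' for `samtools depth`-style 1-based positions.
#'
#' @param path TSV file, no header.
#' @param zeroBased whether positions are 0-based.
#' @return a data.frame with columns `chrom`, `pos` (1-based), `depth`.
#' @export
readDepthTsv <- function(path, zeroBased = TRUE) {
  df <- read.table(path, header = FALSE, sep = "\t",
                   col.names = c("chrom", "pos", "depth"),
                   colClasses = c("character", "integer", "numeric"))
  if (zeroBased) df$pos <- df$pos + 1L
  df
}

#' Depth-filter a coverage track into high-quality regions
#'
#' Keeps maximal runs of consecutive bases whose depth meets `minDepth`;
#' regions with coverage below that are not analyzed further. Each region
#' records the mean depth over its bases.
#'
#' @param depthTrack data.frame with `chrom`, `pos` (1-based), `depth`
#'   (see [readDepthTsv()]); positions absent from the track count as depth
#'   0 and break runs.
#' @param minDepth minimum per-base read depth (default 10).
#' @return a [GenomicRanges::GRanges] of regions with a `meanDepth`
#'   metadata column, sorted by (chrom, start).
#' @export
filterRegionsByDepth <- function(depthTrack, minDepth = 10) {
  stopifnot(all(c("chrom", "pos", "depth") %in% names(depthTrack)))
  if (any(depthTrack$depth < 0)) stop("negative depth in track")
  keep <- depthTrack[depthTrack$depth >= minDepth, , drop = FALSE]
  if (!nrow(keep)) return(GRanges(meanDepth = numeric()))
  keep <- keep[order(keep$chrom, keep$pos), , drop = FALSE]
  if (anyDuplicated(paste(keep$chrom, keep$pos)))
    stop("duplicate positions in depth track")
  new_run <- c(TRUE, keep$chrom[-1L] != keep$chrom[-nrow(keep)] |
                 keep$pos[-1L] != keep$pos[-nrow(keep)] + 1L)
  run <- cumsum(new_run)
  first <- which(new_run)
  last <- c(first[-1L] - 1L, nrow(keep))
  gr <- GRanges(keep$chrom[first], IRanges(keep$pos[first], keep$pos[last]),
                meanDepth = as.numeric(tapply(keep$depth,
                                              factor(run, levels = unique(run)),
                                              mean)))
  sort(gr, ignore.strand = TRUE)
}

#' Genic overlap of captured regions
#'
#' Overlap of the high-quality regions with gene bodies (TSS to transcript
#' end; exons and introns are not distinguished), as bp, percent of the
#' total region bp, and excess over the genome-wide gene content baseline.
#'
#' @param regions `GRanges` of captured regions.
#' @param genes `GRanges` of gene intervals (merged internally).
#' @param genomeGeneFraction genome-wide gene content baseline in percent
#'   (default 40).
#' @return list with `genicBp`, `genicPct` (1 decimal), `excessPct`.
#' @export
genicOverlap <- function(regions, genes, genomeGeneFraction = 40.0) {
  total <- sum(as.numeric(width(reduce(granges(regions),
                                       ignore.strand = TRUE))))
  if (total == 0) stop("regions cover zero bp")
  genic <- sum(as.numeric(width(GenomicRanges::intersect(
    reduce(granges(regions), ignore.strand = TRUE),
    reduce(granges(genes), ignore.strand = TRUE), ignore.strand = TRUE))))
  enrichmentPct(genic, total, genomeGeneFraction,
                labels = c("genicBp", "genicPct", "excessPct"))
}

#' Enrichment percentage from printed counts
#'
#' Core arithmetic shared by the enrichment summaries: percentage of a
#' numerator over a denominator, reported to 1 decimal, and its excess over
#' a genome-wide baseline percentage.
#'
#' @param numerator,denominator bp or gene counts.
#' @param baselinePct genome-wide baseline in percent.
#' @param labels names for the three returned values.
#' @return named list: count, percentage (1 decimal), excess (1 decimal).
#' @export
enrichmentPct <- function(numerator, denominator, baselinePct,
                          labels = c("count", "pct", "excessPct")) {
  if (denominator <= 0) stop("denominator must be positive")
  pct <- round(100 * numerator / denominator, 1)
  setNames(list(numerator, pct, round(pct - baselinePct, 1)), labels)
}

#' Candidate-gene enrichment among captured genes
#'
#' Fraction of captured genes (genes with at least 1 bp of high-quality
#' mapped region) that belong to a candidate-gene list, and the excess over
#' the fraction of all human genes on that list. Gene identifiers are
#' matched case-insensitively.
#'
#' @param genesHit character vector of captured gene identifiers.
#' @param candidateList character vector of candidate gene identifiers.
#' @param genomeCandidateFraction baseline percent of all genes on the
#'   candidate list (default 26).
#' @return list with `candidateGenesHit`, `candidatePct`, `excessPct`.
#' @export
candidateGeneStats <- function(genesHit, candidateList,
                               genomeCandidateFraction = 26.0) {
  genesHit <- unique(toupper(genesHit))
  if (!length(genesHit)) stop("no captured genes")
  hit <- sum(genesHit %in% unique(toupper(candidateList)))
  enrichmentPct(hit, length(genesHit), genomeCandidateFraction,
                labels = c("candidateGenesHit", "candidatePct", "excessPct"))
}

#' Genes overlapped by captured regions
#'
#' @param regions `GRanges` of captured regions.
#' @param genes `GRanges` of gene intervals with a `name` or `gene`
#'   metadata column.
#' @return character vector of gene identifiers with >= 1 bp overlap.
#' @export
genesHitByRegions <- function(regions, genes) {
  id <- if ("name" %in% names(mcols(genes))) genes$name else genes$gene
  if (is.null(id)) stop("gene intervals need a 'name' or 'gene' column")
  hit <- overlapsAny(genes, regions, ignore.strand = TRUE)
  unique(id[hit])
}

#' Inter-Alu fraction of captured regions
#'
#' Bp of captured regions not overlapping any Alu element, and the percent
#' of the total captured bp that this represents.
#'
#' @param regions `GRanges` of captured regions.
#' @param aluElements `GRanges` of Alu elements (merged internally).
#' @return list with `interAluBp` and `fractionPct` (1 decimal).
#' @export
interAluFraction <- function(regions, aluElements) {
  reg <- reduce(granges(regions), ignore.strand = TRUE)
  total <- sum(as.numeric(width(reg)))
  if (total == 0) return(list(interAluBp = 0, fractionPct = NA_real_))
  inter <- GenomicRanges::setdiff(reg, reduce(granges(aluElements),
                                              ignore.strand = TRUE),
                                  ignore.strand = TRUE)
  bp <- sum(as.numeric(width(inter)))
  list(interAluBp = bp, fractionPct = round(100 * bp / total, 1))
}

#' Per-chromosome correlation of captured bp with Alu counts
#'
#' Pearson product-moment correlation between captured bp per chromosome
#' and the number of Alu elements per chromosome.
#'
#' @param perChromBp named numeric vector of captured bp.
#' @param perChromAluCounts named numeric vector of Alu counts over the
#'   same chromosomes.
#' @return Pearson r.
#' @export
chromosomeCorrelation <- function(perChromBp, perChromAluCounts) {
  if (is.null(names(perChromBp)) || is.null(names(perChromAluCounts)))
    stop("both vectors must be named by chromosome")
  common <- intersect(names(perChromBp), names(perChromAluCounts))
  if (length(common) < length(perChromBp) ||
      length(common) < length(perChromAluCounts))
    stop("chromosome sets differ between the two vectors")
  if (length(common) < 3L) stop("need at least 3 chromosomes")
  x <- perChromBp[common]; y <- perChromAluCounts[common]
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance: correlation undefined")
  cor(x, y)
}

#' Captured bp in fixed non-overlapping windows
#'
#' Bp of region coverage per non-overlapping window anchored at position 1
#' of each chromosome (window `i` covers bases `(i-1)*window + 1` to
#' `i*window`).
#'
#' @param regions `GRanges` of captured regions.
#' @param window window size in bp (default 10 kb).
#' @param seqlens optional named chromosome lengths; by default windows
#'   extend to the last covered base per chromosome.
#' @return a `GRanges` of windows with a `bp` metadata column (windows with
#'   zero coverage included up to the track end).
#' @export
windowDensity <- function(regions, window = 10000, seqlens = NULL) {
  stopifnot(window > 0)
  reg <- reduce(granges(regions), ignore.strand = TRUE)
  if (!length(reg)) return(GRanges(bp = numeric()))
  if (is.null(seqlens)) {
    seqlens <- vapply(split(end(reg), as.character(seqnames(reg))), max,
                      numeric(1))
  }
  seqlens <- ceiling(seqlens / window) * window
  tiles <- tileGenome(seqlens, tilewidth = window,
                      cut.last.tile.in.chrom = TRUE)
  ov <- GenomicRanges::intersect(tiles, reg, ignore.strand = TRUE)
  hits <- findOverlaps(tiles, ov)
  bp <- rep(0, length(tiles))
  inter_w <- width(pintersect(tiles[queryHits(hits)], ov[subjectHits(hits)]))
  agg <- tapply(inter_w, queryHits(hits), sum)
  bp[as.integer(names(agg))] <- as.numeric(agg)
  mcols(tiles)$bp <- bp
  tiles
}

#' Write a window-density track as BedGraph
#'
#' @param track result of [windowDensity()].
#' @param path output file.
#' @export
writeBedGraph <- function(track, path) {
  out <- granges(track)
  mcols(out)$score <- track$bp
  rtracklayer::export(out, path, format = "bedGraph")
  invisible(path)
}

#' Overlap and coverage-density correlation between two samples
#'
#' Intersection bp between two captured-region sets, that intersection as a
#' percent of set A, and the Pearson correlation between the two samples'
#' window-density tracks (computed over the union of windows either sample
#' touches).
#'
#' @param regionsA,regionsB `GRanges` of captured regions (e.g. control and
#'   tumor).
#' @param window window size for the density correlation (default 10 kb).
#' @return list with `overlapBp`, `pctOfA` (1 decimal), and
#'   `densityCorrelation`.
#' @export
pairedRegionOverlap <- function(regionsA, regionsB, window = 10000) {
  a <- reduce(granges(regionsA), ignore.strand = TRUE)
  b <- reduce(granges(regionsB), ignore.strand = TRUE)
  totalA <- sum(as.numeric(width(a)))
  if (totalA == 0) stop("region set A covers zero bp")
  ov <- sum(as.numeric(width(GenomicRanges::intersect(a, b,
                                                      ignore.strand = TRUE))))
  all_ends <- c(setNames(end(a), as.character(seqnames(a))),
                setNames(end(b), as.character(seqnames(b))))
  seqlens <- vapply(split(all_ends, names(all_ends)), max, numeric(1))
  ta <- windowDensity(a, window = window, seqlens = seqlens)
  tb <- windowDensity(b, window = window, seqlens = seqlens)
  r <- if (sd(ta$bp) == 0 || sd(tb$bp) == 0) NA_real_ else cor(ta$bp, tb$bp)
  list(overlapBp = ov, pctOfA = round(100 * ov / totalA, 1),
       densityCorrelation = r)
}

#' Capture summary in the style of the published output table
#'
#' Convenience wrapper assembling the headline capture statistics for one
#' sample.
#'
#' @param regions depth-filtered `GRanges` with `meanDepth` metadata
#'   (optional).
#' @param aluElements `GRanges` of Alu elements.
#' @param genes `GRanges` of gene intervals with identifiers.
#' @param candidateList character vector of candidate gene identifiers.
#' @param genomeGeneFraction,genomeCandidateFraction baselines in percent.
#' @return a named list of totals, percentages and excesses.
#' @export
captureSummary <- function(regions, aluElements, genes, candidateList,
                           genomeGeneFraction = 40.0,
                           genomeCandidateFraction = 26.0) {
  total <- sum(as.numeric(width(reduce(granges(regions),
                                       ignore.strand = TRUE))))
  avg <- if ("meanDepth" %in% names(mcols(regions))) {
    sum(regions$meanDepth * width(regions)) / sum(as.numeric(width(regions)))
  } else NA_real_
  ia <- interAluFraction(regions, aluElements)
  gn <- genicOverlap(regions, genes, genomeGeneFraction)
  hit <- genesHitByRegions(regions, genes)
  cg <- candidateGeneStats(hit, candidateList, genomeCandidateFraction)
  list(totalRegionBp = total, averageDepth = avg,
       interAluBp = ia$interAluBp, interAluPct = ia$fractionPct,
       genicBp = gn$genicBp, genicPct = gn$genicPct,
       genicExcessPct = gn$excessPct,
       genesHit = length(hit), candidateGenesHit = cg$candidateGenesHit,
       candidatePct = cg$candidatePct, candidateExcessPct = cg$excessPct)
}
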