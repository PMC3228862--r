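#' Genotype class from non-reference read frequency
#'
#' Classifies each site by the fraction of reads carrying a non-reference
#' allele: homozygous reference below 10%, heterozygous from 10% up to (but
#' excluding) 85%, homozygous non-reference from 85%. Sites with total
#' depth below `minDepth` (or zero) are not analyzed further and come back
#' `UNCLASSIFIED`. Boundary values follow the printed inequalities exactly:
#' a frequency of exactly 0.10 is heterozygous and exactly 0.85 homozygous
#' non-reference.
#'
#' @param nonrefDepth reads carrying a non-reference allele (vectorized).
#' @param totalDepth total reads at the site.
#' @param minDepth minimum depth for classification (default 10).
#' @return factor with levels `HOMREF`, `HET`, `HOMALT`, `UNCLASSIFIED`.
#' @examples
#' classifyGenotype(c(2, 20, 36, 5), c(40, 40, 40, 9))
#' @export
classifyGenotype <- function(nonrefDepth, totalDepth, minDepth = 10) {
  stopifnot(length(nonrefDepth) == length(totalDepth))
  if (any(nonrefDepth < 0 | totalDepth < 0)) stop("negative depth")
  if (any(nonrefDepth > totalDepth))
    stop("nonrefDepth exceeds totalDepth")
  cls <- rep("UNCLASSIFIED", length(totalDepth))
  ok <- totalDepth >= minDepth & totalDepth > 0
  f <- nonrefDepth[ok] / totalDepth[ok]
  cls[ok] <- ifelse(f < 0.10, "HOMREF", ifelse(f < 0.85, "HET", "HOMALT"))
  factor(cls, levels = c("HOMREF", "HET", "HOMALT", "UNCLASSIFIED"))
}

#' Somatic SNV / LOH call from a paired control-tumor site
#'
#' A somatic SNV is a site heterozygous in the tumor but homozygous
#' (reference or non-reference) in the matched control; loss of
#' heterozygosity (LOH) is the converse, heterozygous in the control and
#' homozygous in the tumor. Everything else is `NONE`. Sites where either
#' member is `UNCLASSIFIED` return `NA` and should be skipped.
#'
#' @param controlClass,tumorClass genotype classes from
#'   [classifyGenotype()] (factor or character, vectorized).
#' @return factor with levels `SOMATIC_SNV`, `LOH`, `NONE`; `NA` where a
#'   member is unclassified.
#' @export
classifyPaired <- function(controlClass, tumorClass) {
  controlClass <- as.character(controlClass)
  tumorClass <- as.character(tumorClass)
  stopifnot(length(controlClass) == length(tumorClass))
  hom <- c("HOMREF", "HOMALT")
  out <- rep("NONE", length(controlClass))
  out[controlClass %in% hom & tumorClass == "HET"] <- "SOMATIC_SNV"
  out[controlClass == "HET" & tumorClass %in% hom] <- "LOH"
  out[controlClass == "UNCLASSIFIED" | tumorClass == "UNCLASSIFIED"] <- NA
  factor(out, levels = c("SOMATIC_SNV", "LOH", "NONE"))
}

#' Classify a paired control/tumor call table
#'
#' Applies [classifyGenotype()] to both members and [classifyPaired()] to
#' the pair. Sites where either member cannot be classified are dropped
#' with a message.
#'
#' @param paired data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `control_depth`, `control_nonref`, `tumor_depth`, `tumor_nonref` (see
#'   [readPairedTsv()]).
#' @param minDepth minimum depth for genotype classification.
#' @return the input with added columns `control_class`, `tumor_class`,
#'   `paired_class`, minus the unclassifiable rows.
#' @export
classifyPairedTable <- function(paired, minDepth = 10) {
  need <- c("chrom", "pos", "control_depth", "control_nonref",
            "tumor_depth", "tumor_nonref")
  stopifnot(all(need %in% names(paired)))
  paired$control_class <- classifyGenotype(paired$control_nonref,
                                           paired$control_depth, minDepth)
  paired$tumor_class <- classifyGenotype(paired$tumor_nonref,
                                         paired$tumor_depth, minDepth)
  paired$paired_class <- classifyPaired(paired$control_class,
                                        paired$tumor_class)
  drop <- is.na(paired$paired_class)
  if (any(drop))
    message(sum(drop), " site(s) skipped: member below depth threshold")
  paired[!drop, , drop = FALSE]
}

#' Novel somatic SNVs
#'
#' Removes from the somatic SNV set all LOH positions and all positions
#' already present in a known-SNP list (a dbSNP stand-in). Positions are
#' matched by (chrom, pos); coordinate order is preserved.
#'
#' @param somaticSnvs data.frame of somatic sites with `chrom`, `pos`.
#' @param lohSites data.frame of LOH sites with `chrom`, `pos` (may be
#'   empty or `NULL`).
#' @param knownPositions data.frame with `chrom`, `pos` of known SNPs (may
#'   be empty or `NULL`).
#' @return the novel subset of `somaticSnvs`, sorted by (chrom, pos).
#' @export
filterNovel <- function(somaticSnvs, lohSites = NULL, knownPositions = NULL) {
  key <- function(df) if (is.null(df) || !nrow(df)) character() else
    paste(df$chrom, df$pos)
  k <- key(somaticSnvs)
  novel <- somaticSnvs[!(k %in% key(lohSites)) & !(k %in% key(knownPositions)),
                       , drop = FALSE]
  novel[order(novel$chrom, novel$pos), , drop = FALSE]
}

#' Transition or transversion
#'
#' Purine-purine and pyrimidine-pyrimidine changes (A<->G, C<->T) are
#' transitions; all other single-base changes are transversions.
#'
#' @param ref,alt single reference/alternate bases (vectorized).
#' @return character vector `"transition"` / `"transversion"`.
#' @export
tsTv <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (any(nchar(ref) != 1L | nchar(alt) != 1L |
          !ref %in% c("A", "C", "G", "T") | !alt %in% c("A", "C", "G", "T")))
    stop("ref and alt must be single bases A/C/G/T")
  if (any(ref == alt)) stop("ref and alt must differ")
  purine <- c("A", "G")
  ifelse((ref %in% purine) == (alt %in% purine), "transition", "transversion")
}

#' Tally of nucleotide change classes
#'
#' Counts per unordered change class (`A:G`, `C:T` transitions; `A:C`,
#' `A:T`, `C:G`, `G:T` transversions), plus totals and the Ts/Tv ratio.
#'
#' @param ref,alt vectors of single bases.
#' @return list with `byClass` (named counts over the six classes),
#'   `transitions`, `transversions` and `tsTvRatio`.
#' @export
tsTvTally <- function(ref, alt) {
  kind <- tsTv(ref, alt)
  cls <- paste(pmin(toupper(ref), toupper(alt)),
               pmax(toupper(ref), toupper(alt)), sep = ":")
  classes <- c("A:G", "C:T", "A:C", "A:T", "C:G", "G:T")
  byClass <- setNames(integer(length(classes)), classes)
  tab <- table(cls)
  byClass[names(tab)] <- as.integer(tab)
  ts <- sum(kind == "transition"); tv <- sum(kind == "transversion")
  list(byClass = byClass, transitions = ts, transversions = tv,
       tsTvRatio = if (tv > 0) ts / tv else NA_real_)
}

#' Partition indels by size
#'
#' Indel size is the absolute difference of ref and alt allele lengths.
#' Indels of `smallMax` bp or less are "small"; larger ones (such as
#' multi-hundred-bp deletions) are reported separately.
#'
#' @param indels data.frame with `ref` and `alt` allele strings.
#' @param smallMax size threshold in bp (default 30).
#' @return list with `small` and `large` subsets, each with an added
#'   `size` column.
#' @export
partitionIndels <- function(indels, smallMax = 30) {
  size <- abs(nchar(indels$ref) - nchar(indels$alt))
  if (any(size == 0)) stop("ref and alt lengths equal: not an indel")
  indels$size <- size
  list(small = indels[size <= smallMax, , drop = FALSE],
       large = indels[size > smallMax, , drop = FALSE])
}

#' Detect somatic SNV hotspot windows
#'
#' Counts somatic SNVs in fixed non-overlapping windows (anchored at the
#' chromosome start, the last window truncated at the chromosome end),
#' computes the mean and sample standard deviation of the per-window counts
#' genome-wide, and flags windows whose count strictly exceeds
#' mean + 2 * sd. By default the mean/sd are taken over windows overlapping
#' at least one covered region when `coveredRegions` is supplied (windows
#' that are empty by design would deflate the mean), otherwise over all
#' genomic windows. An absolute count threshold can be supplied instead via
#' `minCount` (flagging windows with count > `minCount`).
#'
#' @param somaticSnvs data.frame with `chrom`, `pos` (1-based) or a
#'   `GRanges` of SNV positions.
#' @param chromLengths named numeric vector of chromosome lengths.
#' @param window window size in bp (default 5 Mb).
#' @param coveredRegions optional `GRanges`; restrict the statistic to
#'   windows overlapping these regions.
#' @param minCount optional absolute override: flag count > `minCount`
#'   instead of the mean + 2 sd rule.
#' @return list with `windows` (a `GRanges` with `snvCount` and
#'   `isHotspot`), `mean` and `sd` (both also rounded to 1 decimal in
#'   `summary`), `threshold`, and `hotspots` (the flagged windows).
#' @export
detectHotspots <- function(somaticSnvs, chromLengths, window = 5e6,
                           coveredRegions = NULL, minCount = NULL) {
  stopifnot(window > 0, !is.null(names(chromLengths)))
  st <- lapply(chromLengths, function(len) seq(1, len, by = window))
  stv <- unlist(st, use.names = FALSE)
  lenv <- rep(unname(chromLengths), lengths(st))
  tiles <- GRanges(rep(names(chromLengths), lengths(st)),
                   IRanges(stv, pmin(stv + window - 1, lenv)))
  if (length(tiles) < 2L) stop("need at least 2 windows for a sd")
  snv <- if (is(somaticSnvs, "GRanges")) granges(somaticSnvs) else
    GRanges(somaticSnvs$chrom, IRanges(somaticSnvs$pos, somaticSnvs$pos))
  counts <- countOverlaps(tiles, snv, ignore.strand = TRUE)
  use <- if (!is.null(coveredRegions)) {
    overlapsAny(tiles, coveredRegions, ignore.strand = TRUE)
  } else rep(TRUE, length(tiles))
  if (sum(use) < 2L) stop("fewer than 2 windows in the statistic")
  m <- mean(counts[use]); s <- sd(counts[use])
  threshold <- if (is.null(minCount)) m + 2 * s else minCount
  mcols(tiles)$snvCount <- counts
  mcols(tiles)$inStatistic <- use
  mcols(tiles)$isHotspot <- use & counts > threshold
  list(windows = tiles, mean = m, sd = s, threshold = threshold,
       summary = c(mean = round(m, 1), sd = round(s, 1),
                   threshold = round(threshold, 1)),
       hotspots = tiles[tiles$isHotspot])
}

#' Read the paired control/tumor TSV dialect
#'
#' A 7-column table `chrom, pos, ref, alt, sample, total_depth,
#' nonref_depth` with one row per (site, sample), `sample` being
#' `"control"` or `"tumor"`. Rows are paired by (chrom, pos, ref); sites
#' present in only one sample are dropped with a message.
#'
#' @param path TSV file with header.
#' @return data.frame with one row per site: `chrom`, `pos`, `ref`, `alt`,
#'   `control_depth`, `control_nonref`, `tumor_depth`, `tumor_nonref`.
#' @export
readPairedTsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "sample", "total_depth",
            "nonref_depth")
  if (!all(need %in% names(df)))
    stop("paired TSV needs columns: ", paste(need, collapse = ", "))
  ctl <- df[df$sample == "control", ]
  tum <- df[df$sample == "tumor", ]
  key <- function(d) paste(d$chrom, d$pos, d$ref)
  common <- intersect(key(ctl), key(tum))
  n_drop <- (nrow(ctl) - length(common)) + (nrow(tum) - length(common))
  if (n_drop > 0) message(n_drop, " unpaired row(s) dropped")
  ctl <- ctl[match(common, key(ctl)), ]
  tum <- tum[match(common, key(tum)), ]
  out <- data.frame(chrom = ctl$chrom, pos = ctl$pos, ref = ctl$ref,
                    alt = ctl$alt,
                    control_depth = ctl$total_depth,
                    control_nonref = ctl$nonref_depth,
                    tumor_depth = tum$total_depth,
                    tumor_nonref = tum$nonref_depth,
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Read per-site depths from a VCF
#'
#' Extracts total depth and non-reference depth for one sample from a VCF
#' carrying per-sample `AD` (allele depth) fields; total depth is the sum
#' of the AD entries (falling back to `DP` when AD is absent) and
#' non-reference depth the sum of the non-reference AD entries. Requires
#' the VariantAnnotation package.
#'
#' @param path VCF file.
#' @param sample sample name or index (default 1).
#' @return data.frame with `chrom`, `pos`, `ref`, `alt`, `total_depth`,
#'   `nonref_depth`.
#' @export
readSiteVcf <- function(path, sample = 1L) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("readSiteVcf() needs the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  geno <- VariantAnnotation::geno(vcf)
  alt <- vapply(as.list(rr$ALT), function(a)
    paste(as.character(a), collapse = ","), "")
  n <- length(rr)
  if ("AD" %in% names(geno)) {
    ad <- geno$AD[, sample]
    total <- vapply(ad, function(x) sum(as.numeric(x)), numeric(1))
    nonref <- vapply(ad, function(x)
      sum(as.numeric(x[-1L])), numeric(1))
  } else if ("DP" %in% names(geno)) {
    stop("VCF has no AD field; non-reference depth unavailable")
  } else stop("VCF has neither AD nor DP genotype fields")
  data.frame(chrom = as.character(seqnames(rr)), pos = start(rr),
             ref = as.character(rr$REF), alt = alt,
             total_depth = total, nonref_depth = nonref,
             stringsAsFactors = FALSE)
}

#' Pair control and tumor site tables
#'
#' Joins two per-sample site tables (from [readSiteVcf()] or equivalent)
#' by (chrom, pos, ref) into the paired layout of [readPairedTsv()].
#'
#' @param control,tumor data.frames with `chrom`, `pos`, `ref`, `alt`,
#'   `total_depth`, `nonref_depth`.
#' @return paired data.frame; sites absent from one sample are dropped.
#' @export
pairSiteTables <- function(control, tumor) {
  key <- function(d) paste(d$chrom, d$pos, d$ref)
  common <- intersect(key(control), key(tumor))
  ctl <- control[match(common, key(control)), ]
  tum <- tumor[match(common, key(tumor)), ]
  out <- data.frame(chrom = ctl$chrom, pos = ctl$pos, ref = ctl$ref,
                    alt = ifelse(nzchar(tum$alt) & tum$alt != ".",
                                 tum$alt, ctl$alt),
                    control_depth = ctl$total_depth,
                    control_nonref = ctl$nonref_depth,
                    tumor_depth = tum$total_depth,
                    tumor_nonref = tum$nonref_depth,
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Read a known-SNP position list
#'
#' Two-column TSV `(chrom, pos)`, 1-based positions, standing in for a
#' dbSNP release.
#'
#' @param path TSV file, no header.
#' @return data.frame with `chrom`, `pos`.
#' @export
readKnownPositions <- function(path) {
  read.table(path, header = FALSE, sep = "\t",
             col.names = c("chrom", "pos"),
             colClasses = c("character", "integer"))
}
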