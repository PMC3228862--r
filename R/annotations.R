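#' Read Alu elements from a RepeatMasker .out file
#'
#' Parses the standard RepeatMasker annotation format (three header lines,
#' whitespace-delimited columns; query coordinates 1-based inclusive;
#' orientation `C` means minus strand) and keeps the records whose repeat
#' class/family matches `classFilter`. The `divergence` metadata column is
#' the file's percent-substitution field.
#'
#' @param path path to a RepeatMasker `.out` file.
#' @param classFilter regular expression applied to the repeat class/family
#'   column; the default keeps Alu SINEs.
#' @param subfamilyFilter optional regular expression applied to the repeat
#'   (subfamily) name, e.g. `"^AluY"`.
#' @return a [GenomicRanges::GRanges] sorted by (chrom, start) with metadata
#'   columns `subfamily`, `repClass` and `divergence`.
#' @export
readRepeatMaskerOut <- function(path, classFilter = "^SINE/Alu",
                                subfamilyFilter = NULL) {
  lines <- readLines(path)
  if (length(lines) > 3L) lines <- lines[-(1:3)] else lines <- character()
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("no records in ", path)
    return(GRanges(subfamily = character(), repClass = character(),
                   divergence = numeric()))
  }
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  bad <- which(nf < 11L)
  if (length(bad))
    stop("malformed RepeatMasker record at data line ", bad[1L],
         " of ", path, " (", nf[bad[1L]], " fields)")
  get <- function(i) vapply(fields, `[[`, "", i)
  qstart <- suppressWarnings(as.integer(get(6L)))
  qend <- suppressWarnings(as.integer(get(7L)))
  div <- suppressWarnings(as.numeric(get(2L)))
  bad <- which(is.na(qstart) | is.na(qend))
  if (length(bad))
    stop("malformed RepeatMasker record at data line ", bad[1L],
         " of ", path, " (non-numeric query coordinates)")
  ori <- get(9L)
  gr <- GRanges(get(5L), IRanges(qstart, qend),
                strand = ifelse(ori == "C", "-", "+"),
                subfamily = get(10L), repClass = get(11L), divergence = div)
  keep <- grepl(classFilter, gr$repClass)
  if (!is.null(subfamilyFilter))
    keep <- keep & grepl(subfamilyFilter, gr$subfamily)
  gr <- gr[keep]
  if (!length(gr)) warning("no records matching '", classFilter, "' in ", path)
  sort(gr, ignore.strand = TRUE)
}

#' Merge overlapping or abutting Alu elements
#'
#' Overlapping and abutting same-chromosome elements are collapsed into one
#' interval regardless of strand; the merged element takes the subfamily and
#' strand of its longest constituent. Needed before inter-Alu gap
#' computation so gaps are non-negative and unique.
#'
#' @param elements a [GenomicRanges::GRanges] of Alu elements, with an
#'   optional `subfamily` metadata column.
#' @return a sorted, non-overlapping `GRanges` with `subfamily` metadata.
#' @export
mergeAluElements <- function(elements) {
  if (!length(elements)) return(elements)
  has_sub <- "subfamily" %in% names(mcols(elements))
  red <- reduce(granges(elements), with.revmap = TRUE, ignore.strand = TRUE)
  longest <- vapply(red$revmap, function(idx) {
    idx[which.max(width(elements)[idx])]
  }, integer(1))
  strand(red) <- strand(elements)[longest]
  mcols(red)$revmap <- NULL
  if (has_sub) mcols(red)$subfamily <- elements$subfamily[longest]
  sort(red, ignore.strand = TRUE)
}

#' Inter-Alu gaps between adjacent elements
#'
#' One gap per adjacent pair of elements on the same chromosome; the gap is
#' the open space between the element boundaries. Gaps are never formed
#' across chromosome boundaries. Input must be merged (non-overlapping) and
#' sorted, e.g. via [mergeAluElements()].
#'
#' @param elements merged, sorted [GenomicRanges::GRanges].
#' @return a `GRanges` of gaps with metadata columns `leftAlu` and
#'   `rightAlu` (indices of the flanking elements in `elements`); gap length
#'   is `width()` of the result.
#' @export
interAluGaps <- function(elements) {
  elements <- sort(granges(elements, use.mcols = TRUE), ignore.strand = TRUE)
  if (!isDisjoint(elements, ignore.strand = TRUE))
    stop("elements overlap; merge with mergeAluElements() first")
  empty <- GRanges(leftAlu = integer(), rightAlu = integer())
  if (length(elements) < 2L) return(empty)
  chrom <- as.character(seqnames(elements))
  left <- seq_len(length(elements) - 1L)
  right <- left + 1L
  same <- chrom[left] == chrom[right]
  left <- left[same]; right <- right[same]
  if (!length(left)) return(empty)
  if (any(start(elements)[right] <= end(elements)[left]))
    stop("adjacent elements overlap or abut after sorting; merge first")
  GRanges(chrom[left],
          IRanges(end(elements)[left] + 1L, start(elements)[right] - 1L),
          leftAlu = left, rightAlu = right,
          seqinfo = seqinfo(elements))
}

#' Histogram of inter-Alu gap lengths
#'
#' Bins gap lengths over `[minLen, maxLen]` (inclusive); gaps outside the
#' range are excluded from both the counts and the bp total. The defaults
#' drop gaps shorter than 200 bp, the fragments removed during sequencing
#' library construction.
#'
#' @param gaps a `GRanges` of gaps (from [interAluGaps()]) or a numeric
#'   vector of gap lengths in bp.
#' @param binWidth bin width in bp.
#' @param minLen,maxLen inclusive length range in bp.
#' @return a list with `bins` (data.frame of `bin_start`, `bin_end`
#'   inclusive bounds, `count`, `bp`), `totalBpInRange`, `nGapsInRange` and
#'   the parameters.
#' @export
gapHistogram <- function(gaps, binWidth = 200, minLen = 200, maxLen = 6000) {
  if (binWidth <= 0) stop("binWidth must be positive")
  if (maxLen <= minLen) stop("maxLen must exceed minLen")
  if (minLen < 0) stop("minLen must be >= 0")
  len <- if (is(gaps, "GRanges")) width(gaps) else as.numeric(gaps)
  stopifnot(all(len >= 0))
  inside <- len[len >= minLen & len <= maxLen]
  starts <- seq(minLen, maxLen, by = binWidth)
  ends <- pmin(starts + binWidth - 1, maxLen)
  idx <- findInterval(inside, starts)
  bins <- data.frame(
    bin_start = starts, bin_end = ends,
    count = tabulate(idx, nbins = length(starts)),
    bp = vapply(seq_along(starts),
                function(i) sum(inside[idx == i]), numeric(1))
  )
  list(bins = bins, totalBpInRange = sum(inside), nGapsInRange = length(inside),
       binWidth = binWidth, minLen = minLen, maxLen = maxLen)
}

#' Mean inter-Alu gap length
#'
#' @param gaps a `GRanges` of gaps or a numeric vector of lengths.
#' @return arithmetic mean gap length in bp.
#' @export
meanGapLength <- function(gaps) {
  len <- if (is(gaps, "GRanges")) width(gaps) else as.numeric(gaps)
  if (!length(len)) stop("no gaps: mean undefined")
  mean(len)
}

#' Write a gap histogram as TSV
#'
#' Columns: `bin_start` (0-based inclusive), `bin_end` (exclusive), `count`,
#' `bp`, following BED-style half-open conventions on output.
#'
#' @param hist result of [gapHistogram()].
#' @param path output file.
#' @export
writeGapHistogramTsv <- function(hist, path) {
  out <- data.frame(bin_start = hist$bins$bin_start,
                    bin_end = hist$bins$bin_end + 1L,
                    count = hist$bins$count, bp = hist$bins$bp)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write Alu elements as BED6
#'
#' Thin wrappers over [rtracklayer::import.bed()]/[rtracklayer::export.bed()]
#' mapping the BED name column to the `subfamily` metadata column.
#'
#' @param path BED file.
#' @return `readAluBed`: a sorted `GRanges` with `subfamily` metadata.
#' @export
readAluBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if ("name" %in% names(mcols(gr))) {
    mcols(gr)$subfamily <- mcols(gr)$name
    mcols(gr)$name <- NULL
  }
  mcols(gr)$score <- NULL
  sort(gr, ignore.strand = TRUE)
}

#' @rdname readAluBed
#' @param gr a `GRanges` with optional `subfamily` metadata.
#' @export
writeAluBed <- function(gr, path) {
  out <- granges(gr)
  if ("subfamily" %in% names(mcols(gr))) out$name <- gr$subfamily
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}
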