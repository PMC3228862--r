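#' Enumerate convergent primer-site pairs as candidate amplicons
#'
#' Every pair of a rightward-extending site L and a leftward-extending site
#' R on the same chromosome with L before R and an outer span (including
#' both primer footprints) inside `[minLen, maxLen]` is a candidate
#' amplicon. Nested and overlapping pairs are all reported: the enumeration
#' describes what is in principle capturable, not PCR competition. The pair
#' class is derived from the two primers' H/T types, order-insensitively
#' (`HT` = `TH`).
#'
#' @param sites a [GenomicRanges::GRanges] from [findPrimerSites()] /
#'   [predictSitesFromAnnotation()], with `extensionDirection` and `ptype`
#'   metadata.
#' @param minLen,maxLen inclusive amplicon length window in bp (defaults
#'   200-6000, the size range retained during sequencing library
#'   construction).
#' @return a `GRanges` of amplicon outer spans sorted by (chrom, start),
#'   with metadata columns `leftPrimer`, `rightPrimer`, `pairClass`
#'   (`"HH"`, `"TT"` or `"HT"`), `leftSite` and `rightSite` (indices into
#'   `sites`). Amplicon length is `width()`.
#' @export
enumerateAmplicons <- function(sites, minLen = 200, maxLen = 6000) {
  stopifnot(minLen < maxLen)
  empty <- GRanges(leftPrimer = character(), rightPrimer = character(),
                   pairClass = character(), leftSite = integer(),
                   rightSite = integer())
  if (!length(sites)) return(empty)
  dir <- sites$extensionDirection
  stopifnot(all(dir %in% c("left", "right")))
  idxL <- which(dir == "right")
  idxR <- which(dir == "left")
  if (!length(idxL) || !length(idxR)) return(empty)
  out <- lapply(unique(as.character(seqnames(sites))), function(chrom) {
    on_chr <- as.character(seqnames(sites)) == chrom
    L <- idxL[on_chr[idxL]]
    R <- idxR[on_chr[idxR]]
    if (!length(L) || !length(R)) return(NULL)
    Rend <- end(sites)[R]
    ord <- order(Rend)
    R <- R[ord]; Rend <- Rend[ord]
    pairs <- lapply(L, function(l) {
      span <- Rend - start(sites)[l] + 1L
      hit <- which(span >= minLen & span <= maxLen & Rend > start(sites)[l])
      if (!length(hit)) return(NULL)
      cbind(l, R[hit])
    })
    pairs <- do.call(rbind, pairs)
    if (is.null(pairs)) return(NULL)
    l <- unname(pairs[, 1L]); r <- unname(pairs[, 2L])
    pc <- paste0(sites$ptype[l], sites$ptype[r])
    pc[pc == "TH"] <- "HT"
    GRanges(chrom, IRanges(start(sites)[l], end(sites)[r]),
            leftPrimer = sites$primer[l], rightPrimer = sites$primer[r],
            pairClass = pc, leftSite = l, rightSite = r)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  sort(do.call(c, out), ignore.strand = TRUE)
}

#' Merged capturable footprint
#'
#' Union of amplicon outer spans: the genome subset the assay can sequence.
#'
#' @param amplicons a `GRanges` of amplicons (or any spans).
#' @return a list with `intervals` (merged, sorted, disjoint `GRanges`) and
#'   `totalBp` (unique bp covered).
#' @export
mergedFootprint <- function(amplicons) {
  merged <- reduce(granges(amplicons), ignore.strand = TRUE)
  list(intervals = merged, totalBp = sum(as.numeric(width(merged))))
}

#' Amplicon length histogram
#'
#' Counts and bp per length bin; bins of `binWidth` starting at `minLen`,
#' truncated at `maxLen` (inclusive bounds as in [gapHistogram()]).
#'
#' @param amplicons `GRanges` of amplicons or numeric lengths.
#' @param binWidth bin width in bp.
#' @param minLen,maxLen inclusive length range.
#' @return as [gapHistogram()].
#' @export
ampliconLengthHistogram <- function(amplicons, binWidth = 200, minLen = 200,
                                    maxLen = 6000) {
  gapHistogram(amplicons, binWidth = binWidth, minLen = minLen,
               maxLen = maxLen)
}
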