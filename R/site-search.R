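#' Find primer binding sites on a genome sequence
#'
#' Scans every chromosome on both strands for the primer oligo within a
#' Hamming-distance mismatch tolerance (substitutions only, no indels; `N`
#' bases in the genome count as mismatches). A match of the oligo itself on
#' the top strand anneals to the bottom strand and extends rightward in
#' genome coordinates; a match of its reverse complement extends leftward.
#' All sites are reported, including overlapping ones.
#'
#' @param genome a named [Biostrings::DNAStringSet] (one entry per
#'   chromosome) or the path to a FASTA file.
#' @param primer an [AluPrimer-class].
#' @param maxMismatches maximum number of mismatched bases tolerated.
#' @return a [GenomicRanges::GRanges] of primer footprints sorted by
#'   (chrom, start), with metadata columns `primer`, `ptype`,
#'   `extensionDirection` (`"right"` or `"left"`) and `mismatches`. Strand
#'   is `+` for rightward and `-` for leftward extension.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "AAAAGATTACAAAAA"))
#' p <- aluPrimer("toy", sequence = "GATTACA", ptype = "T")
#' findPrimerSites(g, p, maxMismatches = 0)
#' @export
findPrimerSites <- function(genome, primer, maxMismatches = 0) {
  stopifnot(is(primer, "AluPrimer"), maxMismatches >= 0)
  if (is.character(genome)) genome <- readDNAStringSet(genome)
  if (is.null(names(genome)) || anyDuplicated(names(genome)))
    stop("genome sequences must have unique names")
  names(genome) <- sub("\\s.*$", "", names(genome))
  fwd <- primerSequence(primer)
  rev <- reverseComplement(fwd)
  hits <- lapply(names(genome), function(chrom) {
    subject <- genome[[chrom]]
    if (length(subject) < length(fwd)) return(NULL)
    one <- function(pattern, direction) {
      m <- matchPattern(pattern, subject, max.mismatch = maxMismatches,
                        with.indels = FALSE, fixed = TRUE)
      r <- ranges(m)
      r <- r[start(r) >= 1L & end(r) <= length(subject)]
      if (!length(r)) return(NULL)
      mm <- Biostrings::neditStartingAt(pattern, subject, starting.at = start(r),
                                        fixed = TRUE)
      GRanges(chrom, r,
              strand = if (direction == "right") "+" else "-",
              primer = primerName(primer), ptype = primerType(primer),
              extensionDirection = direction, mismatches = mm)
    }
    res <- list(one(fwd, "right"), one(rev, "left"))
    res <- res[!vapply(res, is.null, logical(1))]
    if (!length(res)) NULL else do.call(c, res)
  })
  hits <- hits[!vapply(hits, is.null, logical(1))]
  if (!length(hits)) return(.emptySites())
  sort(do.call(c, hits), ignore.strand = TRUE)
}

.emptySites <- function() {
  GRanges(primer = character(), ptype = character(),
          extensionDirection = character(), mismatches = integer())
}

#' Predict primer sites from Alu annotations without sequence
#'
#' Fast annotation-only mode: instead of scanning sequence, each convention
#' primer is placed inside every annotated Alu element at its consensus
#' offset. On a `+` strand element the footprint starts at
#' `start + consensusStart - 1`; a T-type site extends rightward (toward and
#' beyond the tail) and an H-type site leftward. On a `-` strand element the
#' footprint is mirrored from the element end and directions flip. Sites
#' whose footprint falls outside the (possibly truncated) element are
#' dropped.
#'
#' @param elements merged, sorted [GenomicRanges::GRanges] of Alu elements
#'   with `+`/`-` strand.
#' @param primer an [AluPrimer-class] with a consensus offset.
#' @param matchFamily when `TRUE` (default) and the elements carry a
#'   `subfamily` column, the primer is placed only in elements of its own
#'   subfamily; set `FALSE` to place it in every annotated element
#'   (divergent copies of other subfamilies may still bind a consensus
#'   primer in practice, at the cost of mismatches).
#' @return a `GRanges` of predicted sites in the format of
#'   [findPrimerSites()] (`mismatches` set to `NA`).
#' @export
predictSitesFromAnnotation <- function(elements, primer, matchFamily = TRUE) {
  stopifnot(is(primer, "AluPrimer"))
  if (matchFamily && "subfamily" %in% names(mcols(elements)) &&
      !is.na(primerFamily(primer)))
    elements <- elements[elements$subfamily == primerFamily(primer)]
  cstart <- primerConsensusStart(primer)
  if (is.na(cstart))
    stop("primer '", primerName(primer), "' has no consensus offset; ",
         "use findPrimerSites() on sequence instead")
  len <- primerLength(primer)
  if (!length(elements)) return(.emptySites())
  st <- as.character(strand(elements))
  if (any(st == "*"))
    stop("elements must be stranded (+/-) for annotation-mode prediction")
  plus <- st == "+"
  s <- ifelse(plus, start(elements) + cstart - 1L,
              end(elements) - cstart - len + 2L)
  e <- s + len - 1L
  ok <- s >= start(elements) & e <= end(elements)
  if (!any(ok)) return(.emptySites())
  tailward <- primerType(primer) == "T"
  # T-type extends away from the head: rightward on +, leftward on -
  dir <- ifelse(plus == tailward, "right", "left")[ok]
  gr <- GRanges(seqnames(elements)[ok], IRanges(s[ok], e[ok]),
                strand = ifelse(dir == "right", "+", "-"),
                primer = primerName(primer), ptype = primerType(primer),
                extensionDirection = dir, mismatches = NA_integer_,
                seqinfo = seqinfo(elements))
  sort(gr, ignore.strand = TRUE)
}

#' Find sites for several primers at once
#'
#' @param genome as in [findPrimerSites()].
#' @param primers a list of [AluPrimer-class] objects.
#' @param maxMismatches mismatch tolerance applied per primer.
#' @return the concatenated, coordinate-sorted site `GRanges`.
#' @export
findPrimerSiteSet <- function(genome, primers, maxMismatches = 0) {
  if (is.character(genome)) genome <- readDNAStringSet(genome)
  out <- lapply(primers, findPrimerSites, genome = genome,
                maxMismatches = maxMismatches)
  sort(do.call(c, unname(out)), ignore.strand = TRUE)
}
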