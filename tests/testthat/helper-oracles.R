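# Brute-force oracles, independent of the package's implementation paths.
# All coordinates here are 1-based closed (GRanges convention).

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

# Hamming scan of a primer over every offset of both strands of one
# chromosome string; character arithmetic only.
bruteHammingSites <- function(seqStr, primerStr, k) {
  n <- nchar(seqStr)
  m <- nchar(primerStr)
  subject <- strsplit(seqStr, "")[[1]]
  scan1 <- function(pat, direction) {
    pat <- strsplit(pat, "")[[1]]
    out <- list()
    for (s in seq_len(n - m + 1L)) {
      mm <- sum(subject[s:(s + m - 1L)] != pat)
      if (mm <= k)
        out[[length(out) + 1L]] <- data.frame(start = s, end = s + m - 1L,
                                              direction = direction,
                                              mismatches = mm)
    }
    out
  }
  rc <- as.character(reverseComplement(DNAString(primerStr)))
  res <- c(scan1(primerStr, "right"), scan1(rc, "left"))
  if (!length(res))
    return(data.frame(start = integer(), end = integer(),
                      direction = character(), mismatches = integer()))
  df <- do.call(rbind, res)
  df[order(df$start, df$direction), ]
}

# quadratic all-pairs convergent filter over a site data.frame
# (chrom, start, end, direction)
bruteAllPairs <- function(sites, minLen, maxLen) {
  out <- list()
  for (i in seq_len(nrow(sites))) {
    for (j in seq_len(nrow(sites))) {
      L <- sites[i, ]; R <- sites[j, ]
      if (L$direction != "right" || R$direction != "left") next
      if (L$chrom != R$chrom) next
      if (R$end <= L$start) next
      len <- R$end - L$start + 1L
      if (len < minLen || len > maxLen) next
      out[[length(out) + 1L]] <- data.frame(chrom = L$chrom, start = L$start,
                                            end = R$end)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  df <- unique(do.call(rbind, out))
  df[order(df$chrom, df$start, df$end), ]
}

# per-base set union size of spans on one chromosome
bruteBaseUnion <- function(starts, ends) {
  covered <- logical(max(ends))
  for (i in seq_along(starts)) covered[starts[i]:ends[i]] <- TRUE
  sum(covered)
}

# per-base merge of intervals on one chromosome -> data.frame(start, end)
bruteMerge <- function(starts, ends) {
  covered <- logical(max(ends) + 1L)
  for (i in seq_along(starts)) covered[starts[i]:ends[i]] <- TRUE
  r <- rle(covered)
  stops <- cumsum(r$lengths)
  begins <- stops - r$lengths + 1L
  data.frame(start = begins[r$values], end = stops[r$values])
}

# per-base intersection size of two interval sets on one chromosome
bruteBaseIntersect <- function(sa, ea, sb, eb) {
  n <- max(c(ea, eb))
  a <- logical(n); b <- logical(n)
  for (i in seq_along(sa)) a[sa[i]:ea[i]] <- TRUE
  for (i in seq_along(sb)) b[sb[i]:eb[i]] <- TRUE
  sum(a & b)
}

# covered bp per fixed window by per-base counting (windows anchored at 1)
bruteWindowBp <- function(starts, ends, window, chromLen) {
  covered <- logical(chromLen)
  for (i in seq_along(starts)) covered[starts[i]:ends[i]] <- TRUE
  nw <- ceiling(chromLen / window)
  vapply(seq_len(nw), function(w) {
    sum(covered[((w - 1L) * window + 1L):min(w * window, chromLen)])
  }, numeric(1))
}

randomSites <- function(n, chromLen, width = 18L, seed) {
  set.seed(seed)
  start <- sample.int(chromLen - width, n)
  GRanges("chr1", IRanges(start, width = width),
          strand = sample(c("+", "-"), n, TRUE),
          primer = sample(c("P1", "P2"), n, TRUE),
          ptype = sample(c("H", "T"), n, TRUE),
          extensionDirection = sample(c("left", "right"), n, TRUE),
          mismatches = 0L)
}
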