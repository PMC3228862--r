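test_that("depth filtering keeps maximal runs of bases at or above threshold", {
  # depths [12,12,5,12] at 0-based pos 0..3 -> regions [0,2) and [3,4)
  track <- data.frame(chrom = "chr1", pos = 1:4, depth = c(12, 12, 5, 12))
  r <- filterRegionsByDepth(track, minDepth = 10)
  expect_equal(start(r), c(1L, 4L))
  expect_equal(end(r), c(2L, 4L))
  expect_equal(r$meanDepth, c(12, 12))
  low <- data.frame(chrom = "chr1", pos = 1:5, depth = rep(9, 5))
  expect_length(filterRegionsByDepth(low, 10), 0L)
  neg <- data.frame(chrom = "chr1", pos = 1, depth = -1)
  expect_error(filterRegionsByDepth(neg), "negative")
})

test_that("depth filtering equals a per-base run-length oracle", {
  set.seed(19)
  pos <- sort(sample.int(600, 400))
  track <- data.frame(chrom = "chr1", pos = pos,
                      depth = rpois(400, 12))
  r <- filterRegionsByDepth(track, minDepth = 10)
  covered <- logical(600)
  covered[track$pos[track$depth >= 10]] <- TRUE
  rl <- rle(covered)
  stops <- cumsum(rl$lengths)
  begins <- stops - rl$lengths + 1L
  expect_equal(start(r), begins[rl$values])
  expect_equal(end(r), stops[rl$values])
  # mean depth recomputed per region from the raw track
  for (i in seq_along(r)) {
    inside <- track$pos >= start(r)[i] & track$pos <= end(r)[i]
    expect_equal(r$meanDepth[i], mean(track$depth[inside]))
  }
})

test_that("genic percentages match the published worked example", {
  # 5,644,023 genic bp of 10,638,683 total -> 53.1%, excess 13.1 over 40%
  ex <- enrichmentPct(5644023, 10638683, 40.0,
                      labels = c("genicBp", "genicPct", "excessPct"))
  expect_equal(ex$genicPct, 53.1)
  expect_equal(ex$excessPct, 13.1)
})

test_that("genic overlap handles full, partial and zero overlap", {
  genes <- GRanges("chr1", IRanges(1, 1000))
  inside <- GRanges("chr1", IRanges(c(11, 501), c(110, 600)))
  g <- genicOverlap(inside, genes)
  expect_equal(g$genicPct, 100)
  expect_equal(g$excessPct, 60.0)
  outside <- GRanges("chr1", IRanges(2001, 3000))
  g2 <- genicOverlap(outside, genes)
  expect_equal(g2$genicBp, 0)
  expect_equal(g2$excessPct, -40.0)
  half <- GRanges("chr1", IRanges(901, 1100))
  expect_equal(genicOverlap(half, genes)$genicBp, 100)
  expect_error(genicOverlap(GRanges(), genes), "zero bp")
})

test_that("candidate-gene stats match the published counts and edge cases", {
  hit <- paste0("G", 1:8502)
  cand <- paste0("g", 1:2921)        # case-insensitive match
  cg <- candidateGeneStats(hit, cand)
  expect_equal(cg$candidateGenesHit, 2921)
  expect_equal(cg$candidatePct, 34.4)
  expect_equal(cg$excessPct, 8.4)
  expect_equal(candidateGeneStats(hit, character())$candidatePct, 0)
  expect_equal(candidateGeneStats(hit, character())$excessPct, -26.0)
  expect_equal(candidateGeneStats(c("A", "B"), c("A", "B"))$candidatePct, 100)
  expect_error(candidateGeneStats(character(), "A"), "no captured genes")
})

test_that("inter-Alu fraction is the region bp outside Alu elements", {
  region <- GRanges("chr1", IRanges(1, 100))   # 0-based [0,100)
  alu <- GRanges("chr1", IRanges(1, 30))       # [0,30)
  ia <- interAluFraction(region, alu)
  expect_equal(ia$interAluBp, 70)
  expect_equal(ia$fractionPct, 70)
  expect_equal(interAluFraction(region, GRanges())$fractionPct, 100)
  # the published ratio: 10,149,445 of 10,638,683 -> 95.4%
  expect_equal(enrichmentPct(10149445, 10638683, 0)$pct, 95.4)
})

test_that("inter-Alu and Alu-overlap bp partition the region bp", {
  set.seed(43)
  rs <- sample.int(9000, 30); re <- rs + sample.int(400, 30)
  as_ <- sample.int(9000, 40); ae <- as_ + sample.int(300, 40)
  regions <- reduce(GRanges("chr1", IRanges(rs, re)))
  alus <- GRanges("chr1", IRanges(as_, ae))
  ia <- interAluFraction(regions, alus)
  aluBp <- sum(width(GenomicRanges::intersect(regions, reduce(alus))))
  expect_equal(ia$interAluBp + aluBp, sum(width(regions)))
})

test_that("chromosome correlation is Pearson r with input validation", {
  bp <- c(chr1 = 10, chr2 = 20, chr3 = 30)
  expect_equal(chromosomeCorrelation(bp, bp * 2), 1.0)
  expect_equal(chromosomeCorrelation(bp, c(chr1 = 3, chr2 = 2, chr3 = 1)),
               -1.0)
  set.seed(47)
  x <- setNames(runif(10), paste0("chr", 1:10))
  y <- setNames(runif(10), paste0("chr", 1:10))
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(chromosomeCorrelation(x, y), manual)
  expect_error(chromosomeCorrelation(bp, bp[1:2]), "differ")
  expect_error(chromosomeCorrelation(bp[1:2], bp[1:2] * 2), "at least 3")
  expect_error(chromosomeCorrelation(bp, setNames(rep(1, 3), names(bp))),
               "zero variance")
})

test_that("window density splits coverage into anchored windows", {
  # region 0-based [5000,15000), 10-kb windows -> 5000 bp in each
  region <- GRanges("chr1", IRanges(5001, 15000))
  w <- windowDensity(region, window = 10000)
  expect_equal(w$bp, c(5000, 5000))
  expect_equal(start(w), c(1L, 10001L))
  expect_length(windowDensity(GRanges(), 10000), 0L)
})

test_that("window sums conserve total bp and match per-base counting", {
  set.seed(53)
  s <- sample.int(80000, 60); e <- s + sample.int(5000, 60)
  regions <- reduce(GRanges("chr1", IRanges(s, e)))
  w <- windowDensity(regions, window = 10000)
  expect_equal(sum(w$bp), sum(width(regions)))
  chromLen <- max(end(regions))
  oracle <- bruteWindowBp(start(regions), end(regions), 10000,
                          ceiling(chromLen / 10000) * 10000)
  expect_equal(w$bp, oracle)
})

test_that("paired-sample overlap reports intersection, percent and correlation", {
  a <- GRanges("chr1", IRanges(c(1, 20001), c(10000, 30000)))
  same <- pairedRegionOverlap(a, a)
  expect_equal(same$pctOfA, 100)
  expect_equal(same$densityCorrelation, 1.0)
  b <- GRanges("chr1", IRanges(50001, 60000))
  dis <- pairedRegionOverlap(a, b)
  expect_equal(dis$overlapBp, 0)
  expect_equal(dis$pctOfA, 0)
  set.seed(59)
  sa <- sample.int(40000, 25); ea <- sa + sample.int(2000, 25)
  sb <- sample.int(40000, 25); eb <- sb + sample.int(2000, 25)
  res <- pairedRegionOverlap(GRanges("chr1", IRanges(sa, ea)),
                             GRanges("chr1", IRanges(sb, eb)))
  expect_equal(res$overlapBp, bruteBaseIntersect(sa, ea, sb, eb))
  expect_error(pairedRegionOverlap(GRanges(), b), "zero bp")
})

test_that("capture summary fields are mutually consistent", {
  set.seed(61)
  regions <- reduce(GRanges("chr1", IRanges(sample.int(50000, 20),
                                            width = 500)))
  regions$meanDepth <- runif(length(regions), 10, 90)
  alus <- GRanges("chr1", IRanges(sample.int(50000, 30), width = 300))
  genes <- GRanges("chr1", IRanges(sample.int(50000, 10), width = 3000))
  genes$name <- paste0("G", seq_along(genes))
  s <- captureSummary(regions, alus, genes, candidateList = c("G1", "G2"))
  expect_equal(s$totalRegionBp, sum(width(regions)))
  nonGenic <- s$totalRegionBp - s$genicBp
  expect_equal(s$genicBp + nonGenic, s$totalRegionBp)
  expect_equal(round(100 * s$genicBp / s$totalRegionBp, 1), s$genicPct)
  expect_equal(round(100 * s$interAluBp / s$totalRegionBp, 1), s$interAluPct)
  expect_true(s$candidateGenesHit <= s$genesHit)
  expect_true(s$genicPct >= 0 && s$genicPct <= 100)
})
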