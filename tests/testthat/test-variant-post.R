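test_that("genotype classes follow the non-reference frequency thresholds", {
  expect_equal(as.character(classifyGenotype(2, 40)), "HOMREF")    # f = 0.05
  expect_equal(as.character(classifyGenotype(20, 40)), "HET")      # f = 0.50
  expect_equal(as.character(classifyGenotype(36, 40)), "HOMALT")   # f = 0.90
  # boundaries are inclusive on the upper class
  expect_equal(as.character(classifyGenotype(4, 40)), "HET")       # f = 0.10
  expect_equal(as.character(classifyGenotype(34, 40)), "HOMALT")   # f = 0.85
  # depth below 10 is not analyzed further
  expect_equal(as.character(classifyGenotype(5, 9)), "UNCLASSIFIED")
  expect_equal(as.character(classifyGenotype(0, 0)), "UNCLASSIFIED")
  expect_error(classifyGenotype(5, 4), "exceeds")
  expect_error(classifyGenotype(-1, 4), "negative")
})

test_that("every frequency in [0,1] maps to exactly one class, no gaps", {
  total <- 1000L
  nonref <- 0:1000
  cls <- classifyGenotype(nonref, rep(total, length(nonref)))
  expect_false(anyNA(cls))
  expect_false(any(cls == "UNCLASSIFIED"))
  f <- nonref / total
  expect_true(all(cls[f < 0.10] == "HOMREF"))
  expect_true(all(cls[f >= 0.10 & f < 0.85] == "HET"))
  expect_true(all(cls[f >= 0.85] == "HOMALT"))
})

test_that("somatic and LOH calls follow the homozygous/heterozygous pattern", {
  expect_equal(as.character(classifyPaired("HOMREF", "HET")), "SOMATIC_SNV")
  expect_equal(as.character(classifyPaired("HOMALT", "HET")), "SOMATIC_SNV")
  expect_equal(as.character(classifyPaired("HET", "HOMALT")), "LOH")
  expect_equal(as.character(classifyPaired("HET", "HOMREF")), "LOH")
  expect_equal(as.character(classifyPaired("HET", "HET")), "NONE")
  expect_equal(as.character(classifyPaired("HOMREF", "HOMALT")), "NONE")
  expect_true(is.na(classifyPaired("UNCLASSIFIED", "HET")))
  # somatic and LOH are disjoint over every class combination
  grid <- expand.grid(c("HOMREF", "HET", "HOMALT"),
                      c("HOMREF", "HET", "HOMALT"))
  cls <- classifyPaired(grid[[1]], grid[[2]])
  expect_false(any(cls == "SOMATIC_SNV" & cls == "LOH"))
  expect_equal(sum(cls == "SOMATIC_SNV"), 2L)
  expect_equal(sum(cls == "LOH"), 2L)
})

test_that("novel sites are the somatic set minus LOH and known positions", {
  som <- data.frame(chrom = "chr1", pos = c(100, 200, 300))
  known <- data.frame(chrom = "chr1", pos = 200)
  expect_equal(filterNovel(som, NULL, known)$pos, c(100, 300))
  expect_equal(filterNovel(som, NULL, NULL), som)
  loh <- data.frame(chrom = "chr1", pos = 300)
  expect_equal(filterNovel(som, loh, known)$pos, 100)
  # random fixture vs set-difference oracle
  set.seed(67)
  s <- data.frame(chrom = sample(c("chr1", "chr2"), 200, TRUE),
                  pos = sample.int(5000, 200))
  k <- s[sample.int(200, 60), ]
  l <- s[sample.int(200, 40), ]
  nv <- filterNovel(s, l, k)
  oracle <- setdiff(setdiff(paste(s$chrom, s$pos), paste(l$chrom, l$pos)),
                    paste(k$chrom, k$pos))
  expect_setequal(paste(nv$chrom, nv$pos), oracle)
})

test_that("transitions are purine-purine or pyrimidine-pyrimidine changes", {
  expect_equal(tsTv("A", "G"), "transition")
  expect_equal(tsTv("C", "T"), "transition")
  expect_equal(tsTv("A", "C"), "transversion")
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(ref = bases, alt = bases,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  tally <- tsTvTally(pairs$ref, pairs$alt)
  expect_equal(tally$transitions, 4L)
  expect_equal(tally$transversions, 8L)
  expect_equal(tally$tsTvRatio, 0.5)
  expect_equal(unname(tally$byClass[c("A:G", "C:T")]), c(2L, 2L))
  expect_error(tsTv("AT", "A"), "single bases")
  expect_error(tsTv("A", "A"), "differ")
})

test_that("indels partition at the size threshold", {
  indels <- data.frame(
    ref = c("ATTTTT", "A", "A", "A"),
    alt = c("A", paste(rep("T", 31), collapse = ""),
            paste(rep("G", 32), collapse = ""),
            paste(rep("C", 768), collapse = "")))
  # sizes 5, 30, 31, 767
  p <- partitionIndels(indels)
  expect_equal(sort(p$small$size), c(5, 30))
  expect_equal(sort(p$large$size), c(31, 767))
  empty <- partitionIndels(data.frame(ref = character(), alt = character()))
  expect_equal(nrow(empty$small), 0L)
  expect_equal(nrow(empty$large), 0L)
  expect_error(partitionIndels(data.frame(ref = "AT", alt = "GC")),
               "not an indel")
  set.seed(71)
  sizes <- sample.int(100, 100, replace = TRUE)
  rnd <- data.frame(ref = vapply(sizes + 1L, strrep, "", x = "A"),
                    alt = "A")
  p2 <- partitionIndels(rnd)
  expect_equal(nrow(p2$small), sum(sizes <= 30))
  expect_equal(nrow(p2$large), sum(sizes > 30))
})

test_that("hotspot windows exceed mean plus two standard deviations", {
  # frozen count vector: sample mean exactly 1.5, sd 1.88 (1.9 to 1 dp),
  # threshold 5.26 (5.3 to 1 dp) -> the 6 is flagged, the 5 is not
  counts <- c(6, 5, 4, 3, 3, 3, 2, 1, 1, 1, 1, rep(0, 9))
  window <- 1000L
  pos <- unlist(lapply(seq_along(counts), function(i) {
    if (counts[i] > 0) (i - 1L) * window + seq_len(counts[i]) else integer()
  }))
  snvs <- data.frame(chrom = "chr1", pos = pos)
  hs <- detectHotspots(snvs, c(chr1 = 20 * window), window = window)
  expect_equal(hs$mean, 1.5)
  expect_equal(unname(hs$summary["sd"]), 1.9)
  expect_equal(unname(hs$summary["threshold"]), 5.3)
  expect_equal(hs$windows$snvCount, counts)
  expect_equal(which(hs$windows$isHotspot), 1L)   # only the 6
  # direct-formula oracle on the flags
  thr <- mean(counts) + 2 * sd(counts)
  expect_equal(hs$windows$isHotspot, counts > thr)
})

test_that("equal counts give no hotspots and tiny inputs error", {
  snvs <- data.frame(chrom = "chr1",
                     pos = c(500, 1500, 2500, 3500))
  hs <- detectHotspots(snvs, c(chr1 = 4000), window = 1000)
  expect_equal(hs$sd, 0)
  expect_length(hs$hotspots, 0L)    # strict inequality
  expect_error(detectHotspots(snvs, c(chr1 = 900), window = 1000),
               "at least 2 windows")
})

test_that("hotspot flags depend only on the count multiset, not window order", {
  set.seed(73)
  counts <- rpois(20, 1.5)
  mk <- function(perm) {
    pos <- unlist(lapply(seq_along(perm), function(i)
      if (perm[i] > 0) (i - 1L) * 1000L + seq_len(perm[i]) else integer()))
    detectHotspots(data.frame(chrom = "chr1", pos = pos),
                   c(chr1 = 20000), window = 1000)
  }
  a <- mk(counts)
  b <- mk(rev(counts))
  expect_equal(a$threshold, b$threshold)
  expect_equal(sort(a$windows$snvCount[a$windows$isHotspot]),
               sort(b$windows$snvCount[b$windows$isHotspot]))
})

test_that("the absolute-count override replaces the mean + 2 sd rule", {
  counts <- c(6, 5, rep(1, 18))
  pos <- unlist(lapply(seq_along(counts), function(i)
    (i - 1L) * 1000L + seq_len(counts[i])))
  snvs <- data.frame(chrom = "chr1", pos = pos)
  hs <- detectHotspots(snvs, c(chr1 = 20000), window = 1000, minCount = 4)
  expect_equal(sort(hs$hotspots$snvCount), c(5L, 6L))   # both exceed 4
})

test_that("covered-window restriction changes the statistic, not the counts", {
  counts <- c(3, 0, 0, 0, 3, 3)
  pos <- unlist(lapply(seq_along(counts), function(i)
    if (counts[i] > 0) (i - 1L) * 1000L + seq_len(counts[i]) else integer()))
  snvs <- data.frame(chrom = "chr1", pos = pos)
  covered <- GRanges("chr1", IRanges(c(1, 4001), c(1000, 6000)))
  all_w <- detectHotspots(snvs, c(chr1 = 6000), window = 1000)
  cov_w <- detectHotspots(snvs, c(chr1 = 6000), window = 1000,
                          coveredRegions = covered)
  expect_equal(all_w$windows$snvCount, cov_w$windows$snvCount)
  expect_equal(cov_w$mean, 3)      # only the three covered windows count
  expect_equal(all_w$mean, 1.5)
})

test_that("paired table classification drops unclassifiable sites", {
  paired <- data.frame(
    chrom = "chr1", pos = c(10, 20, 30), ref = "A", alt = "G",
    control_depth = c(40, 40, 8), control_nonref = c(1, 20, 1),
    tumor_depth = c(40, 40, 40), tumor_nonref = c(20, 2, 20))
  expect_message(out <- classifyPairedTable(paired), "skipped")
  expect_equal(nrow(out), 2L)
  expect_equal(as.character(out$paired_class), c("SOMATIC_SNV", "LOH"))
})

test_that("the paired TSV dialect and the VCF reader agree on depths", {
  sim <- simulatePairedCalls(seed = 5, nGermlineHet = 30, nSomatic = 10,
                             nLoh = 10, nRefSites = 5)
  path <- tempfile(fileext = ".tsv")
  writePairedTsv(sim, path)
  back <- readPairedTsv(path)
  expect_equal(nrow(back), nrow(sim$calls))
  m <- match(paste(back$chrom, back$pos), paste(sim$calls$chrom,
                                                sim$calls$pos))
  expect_equal(back$control_depth, sim$calls$control_depth[m])
  expect_equal(back$tumor_nonref, sim$calls$tumor_nonref[m])
})

test_that("VCF AD fields yield total and non-reference depths", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=100000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "chr1\t100\t.\tA\tG\t50\tPASS\t.\tGT:AD\t0/1:30,10",
    "chr1\t200\t.\tC\tT\t50\tPASS\t.\tGT:AD\t1/1:2,38"), vcf)
  df <- readSiteVcf(vcf, sample = 1L)
  expect_equal(df$pos, c(100L, 200L))
  expect_equal(df$total_depth, c(40, 40))
  expect_equal(df$nonref_depth, c(10, 38))
  paired <- pairSiteTables(df, df)
  expect_equal(paired$control_depth, paired$tumor_depth)
})
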