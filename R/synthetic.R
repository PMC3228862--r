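# Synthetic Alu-like consensus backbone, 311 bp. This is NOT a published
# subfamily consensus: it is a constructed stand-in carrying the printed
# AluY primer windows at their stated consensus offsets (H window at 66-86,
# T window at 278-295) over an Alu-like body and poly-A tail, so primer
# derivation and site search can be exercised without external downloads.
.ALU_BACKBONE <- paste0(
  "GGCCGGGCGCGGTGGCTCACGCCTGTAATCCCAGCACTTTGGGAGGCCGAGGCGGGCGGATCACG",
  "GAGGTCAGGAGATCGAGACCA",
  "TCCCGGCTAAAACGGTGAAACCCCGTCTCTACTAAAAATACAAAAAATTAGCCGGGCGTGGTGG",
  "CGGGCGCCTGTAGTCCCAGCTACTCGGGAGGCTGAGGCAGGAGAATGGCGTGAACCCGGGAGGC",
  "GGAGCTTGCAGTGAGCCGAGATCGCGCCACTGCACTCCAGCCTGGGCGACAGCCTCCCAAAGT",
  "GAGCGAGACTCCGTCTCA",
  "AAAAAAAAAAAAAAAA"
)

.plant <- function(seq, window, at) {
  paste0(substr(seq, 1, at - 1), window,
         substr(seq, at + nchar(window), nchar(seq)))
}

#' Synthetic subfamily consensus registry
#'
#' A three-family (AluY, AluJo, AluSq) consensus registry built in code for
#' simulation and testing. The sequences are synthetic Alu-like stand-ins,
#' not published consensus sequences; each carries the printed primer
#' windows of its family at the stated consensus offsets (AluY: H at 66,
#' T at 278; AluJo: H at 56, T at 232; AluSq: H at 56, T at 263), so
#' convention primer names derive to the printed oligos.
#'
#' @return a named [Biostrings::DNAStringSet].
#' @examples
#' reg <- syntheticConsensusRegistry()
#' aluPrimer("AluY278T18", registry = reg)
#' @export
syntheticConsensusRegistry <- function() {
  comp <- function(s) chartr("ACGT", "TGCA", s)
  windows <- list(
    AluY  = list(list(66,  substr(.ALU_BACKBONE, 66, 86)),    # H window
                 list(278, substr(.ALU_BACKBONE, 278, 295))), # T window
    AluJo = list(list(56,  "GAGGATCGCTTGAGCC"),   # revcomp of AluJo56H16
                 list(232, "TATGATCGTGCCACTG")),  # AluJo232T16
    AluSq = list(list(56,  "GTGGATCACCTGAGGT"),   # revcomp of AluSq56H16
                 list(263, "AACAAGAGCGAAACTC"))   # AluSq263T16
  )
  # each family carries its own primer windows at the stated offsets and
  # the base-complement of every other family's window, so a primer of one
  # family never matches another family's consensus copy
  build <- function(fam) {
    s <- .ALU_BACKBONE
    for (other in setdiff(names(windows), fam))
      for (w in windows[[other]]) s <- .plant(s, comp(w[[2]]), w[[1]])
    for (w in windows[[fam]]) s <- .plant(s, w[[2]], w[[1]])
    s
  }
  DNAStringSet(vapply(names(windows), build, ""))
}

#' Simulate a genome with planted Alu copies
#'
#' Generates an i.i.d. uniform A/C/G/T background sequence and plants
#' non-overlapping full-length copies of subfamily consensus sequences,
#' each on a uniformly chosen strand, with every base independently
#' substituted at the divergence rate. The recorded annotation is the
#' ground truth for site search and amplicon enumeration.
#'
#' The defaults emulate the Alu density of the human genome: one ~300 bp
#' element per ~2.7 kb of sequence, a subfamily mix dominated by AluS-aged
#' copies, and ~10% divergence from consensus.
#'
#' @param seed integer seed; all randomness flows from it.
#' @param chromLength chromosome length in bp.
#' @param nAlus number of Alu copies to plant.
#' @param registry consensus registry (default
#'   [syntheticConsensusRegistry()]).
#' @param subfamilyProbs named sampling weights over `names(registry)`.
#' @param divergence per-base substitution probability in `[0, 0.3]`.
#' @param chromName chromosome name.
#' @param minGap minimum space between planted copies in bp.
#' @param nGenes optional number of synthetic gene intervals to record
#'   (uniform starts, widths 2-10 kb, merged).
#' @param starts optional explicit 1-based start positions (sorted),
#'   overriding random placement.
#' @return a list with `genome` (named `DNAStringSet`), `alus` (truth
#'   `GRanges` with `subfamily` and `divergence`), `genes` (truth
#'   `GRanges`, possibly empty) and `params`.
#' @export
simulateGenome <- function(seed, chromLength = 100000, nAlus = 37,
                           registry = syntheticConsensusRegistry(),
                           subfamilyProbs = c(AluY = 0.15, AluSq = 0.60,
                                              AluJo = 0.25),
                           divergence = 0.1, chromName = "chrS1",
                           minGap = 1, nGenes = 0, starts = NULL) {
  stopifnot(nAlus >= 0, divergence >= 0, divergence <= 0.3)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  seq <- sample(bases, chromLength, replace = TRUE)
  if (nAlus > 0) {
    fams <- sample(names(subfamilyProbs), nAlus, replace = TRUE,
                   prob = subfamilyProbs)
    lens <- width(registry)[match(fams, names(registry))]
    if (anyNA(lens)) stop("subfamilyProbs names must be registry families")
    if (is.null(starts)) {
      slack <- chromLength - sum(lens) - (nAlus - 1) * minGap
      if (slack < 0)
        stop("chromosome too small to place ", nAlus,
             " Alu copies without overlap")
      u <- sort(round(runif(nAlus, 0, slack)))
      starts <- u + cumsum(c(0, lens[-nAlus] + minGap)) + 1L
    } else {
      stopifnot(length(starts) == nAlus, !is.unsorted(starts))
      if (any(starts[-1L] < starts[-nAlus] + lens[-nAlus]))
        stop("explicit starts overlap")
      if (starts[nAlus] + lens[nAlus] - 1L > chromLength)
        stop("explicit starts exceed chromosome length")
    }
    strands <- sample(c("+", "-"), nAlus, replace = TRUE)
    for (i in seq_len(nAlus)) {
      copy <- strsplit(as.character(registry[[fams[i]]]), "")[[1]]
      mut <- which(runif(lens[i]) < divergence)
      if (length(mut))
        copy[mut] <- vapply(copy[mut], function(b)
          sample(setdiff(bases, b), 1L), "")
      if (strands[i] == "-")
        copy <- rev(c(A = "T", C = "G", G = "C", T = "A")[copy])
      seq[starts[i]:(starts[i] + lens[i] - 1L)] <- copy
    }
    alus <- GRanges(chromName, IRanges(starts, width = lens),
                    strand = strands, subfamily = fams,
                    divergence = 100 * divergence)
  } else {
    alus <- GRanges(subfamily = character(), divergence = numeric())
  }
  genes <- if (nGenes > 0) {
    gs <- sample.int(chromLength, nGenes)
    gw <- pmin(round(runif(nGenes, 2000, 10000)), chromLength - gs + 1L)
    g <- reduce(GRanges(chromName, IRanges(gs, width = gw)))
    g$name <- sprintf("GENE%03d", seq_along(g))
    g
  } else GRanges(name = character())
  genome <- DNAStringSet(setNames(paste(seq, collapse = ""), chromName))
  list(genome = genome, alus = sort(alus, ignore.strand = TRUE),
       genes = genes,
       params = list(seed = seed, chromLength = chromLength, nAlus = nAlus,
                     divergence = divergence, minGap = minGap))
}

#' Write a simulated genome and its truth annotations
#'
#' Writes `<prefix>.fa` (genome FASTA), `<prefix>.out` (RepeatMasker-style
#' annotation), `<prefix>_alus.bed` and, when genes were simulated,
#' `<prefix>_genes.bed`.
#'
#' @param sim result of [simulateGenome()].
#' @param dir output directory.
#' @param prefix file name prefix.
#' @return named character vector of the written paths.
#' @export
writeSimulatedGenome <- function(sim, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(prefix, ".fa"))
  out <- file.path(dir, paste0(prefix, ".out"))
  bed <- file.path(dir, paste0(prefix, "_alus.bed"))
  writeXStringSet(sim$genome, fa)
  writeRepeatMaskerOut(sim$alus, out)
  writeAluBed(sim$alus, bed)
  paths <- c(fasta = fa, rmsk = out, alu_bed = bed)
  if (length(sim$genes)) {
    gbed <- file.path(dir, paste0(prefix, "_genes.bed"))
    g <- granges(sim$genes)
    g$name <- sim$genes$name
    rtracklayer::export(g, gbed, format = "BED")
    paths <- c(paths, genes_bed = gbed)
  }
  paths
}

#' Write Alu elements in RepeatMasker .out format
#'
#' Emits the standard whitespace-aligned layout (three header lines,
#' 1-based inclusive query coordinates, `C` for minus strand) consumable by
#' [readRepeatMaskerOut()].
#'
#' @param gr `GRanges` with `subfamily` and optionally `divergence`
#'   metadata.
#' @param path output file.
#' @param repClass repeat class/family column value.
#' @export
writeRepeatMaskerOut <- function(gr, path, repClass = "SINE/Alu") {
  header <- c(
    "   SW   perc perc perc  query     position in query          matching    repeat       position in repeat",
    "score   div. del. ins.  sequence  begin end    (left)  C/+  repeat      class/family  begin end  (left)  ID",
    "")
  div <- if ("divergence" %in% names(mcols(gr))) gr$divergence else
    rep(0, length(gr))
  lines <- sprintf(
    "%5d %6.1f %4.1f %4.1f  %s %d %d (0) %s %s %s 1 %d (0) %d",
    rep(1000L, length(gr)), div, 0, 0,
    as.character(seqnames(gr)), start(gr), end(gr),
    ifelse(as.character(strand(gr)) == "-", "C", "+"),
    gr$subfamily, repClass, width(gr), seq_along(gr))
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Simulate paired control/tumor variant calls with known truth
#'
#' Generates per-site paired calls whose true allele fractions follow the
#' site label: germline heterozygous (0.5 in both samples), somatic SNV
#' (control homozygous, tumor 0.5), LOH (control 0.5, tumor homozygous 0
#' or 1), and homozygous-reference filler sites (0 in both). Observed
#' non-reference depths are drawn binomially at the true fraction when
#' `noise = TRUE`; total depths are Poisson with the stated mean. A subset
#' of sites is flagged "known" as a dbSNP stand-in.
#'
#' The default site counts and mean depth mirror a paired white blood
#' cell/glioma comparison: 274 somatic SNVs, 357 LOH sites, mean coverage
#' 67.4x, and ~30% of somatic sites previously reported.
#'
#' @param seed integer seed.
#' @param nGermlineHet,nSomatic,nLoh,nRefSites site counts per label.
#' @param meanDepth mean total depth per site/sample.
#' @param noise draw binomial allele-depth noise; when `FALSE` observed
#'   non-reference depths are the true fraction times the depth, rounded.
#' @param poissonDepth draw total depths from a Poisson with mean
#'   `meanDepth`; when `FALSE` every site has fixed depth
#'   `round(meanDepth)`.
#' @param knownFraction probability a site is on the known-SNP list.
#' @param somaticFromHomalt fraction of somatic sites whose control is
#'   homozygous non-reference rather than homozygous reference.
#' @param tsProb probability the simulated change is a transition.
#' @param chromLengths named chromosome lengths over which site positions
#'   are drawn uniformly (distinct positions).
#' @return a list with `calls` (data.frame: `chrom`, `pos`, `ref`, `alt`,
#'   `truth`, `control_depth`, `control_nonref`, `tumor_depth`,
#'   `tumor_nonref`, `known`), `known` (data.frame `chrom`, `pos`) and
#'   `params`.
#' @export
simulatePairedCalls <- function(seed, nGermlineHet = 2000, nSomatic = 274,
                                nLoh = 357, nRefSites = 500,
                                meanDepth = 67.4, noise = TRUE,
                                poissonDepth = TRUE, knownFraction = 0.3,
                                somaticFromHomalt = 0.1, tsProb = 0.7,
                                chromLengths = c(chrS1 = 25e6,
                                                 chrS2 = 20e6)) {
  set.seed(seed)
  n <- nGermlineHet + nSomatic + nLoh + nRefSites
  stopifnot(n > 0, !is.null(names(chromLengths)))
  truth <- rep(c("germline_het", "somatic", "loh", "homref"),
               c(nGermlineHet, nSomatic, nLoh, nRefSites))
  chrom <- sample(names(chromLengths), n, replace = TRUE,
                  prob = chromLengths / sum(chromLengths))
  pos <- integer(n)
  for (ch in unique(chrom)) {
    i <- chrom == ch
    pos[i] <- sample.int(chromLengths[[ch]], sum(i))
  }
  bases <- c("A", "C", "G", "T")
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  ref <- sample(bases, n, replace = TRUE)
  is_ts <- runif(n) < tsProb
  alt <- ifelse(is_ts, transition[ref],
                vapply(ref, function(b)
                  sample(setdiff(bases, c(b, transition[[b]])), 1L), ""))
  ctl_f <- numeric(n); tum_f <- numeric(n)
  ctl_f[truth == "germline_het"] <- 0.5
  tum_f[truth == "germline_het"] <- 0.5
  som <- truth == "somatic"
  ctl_f[som] <- ifelse(runif(sum(som)) < somaticFromHomalt, 1, 0)
  tum_f[som] <- 0.5
  loh <- truth == "loh"
  ctl_f[loh] <- 0.5
  tum_f[loh] <- ifelse(runif(sum(loh)) < 0.5, 1, 0)
  if (poissonDepth) {
    cd <- rpois(n, meanDepth)
    td <- rpois(n, meanDepth)
  } else {
    cd <- td <- rep(as.integer(round(meanDepth)), n)
  }
  if (noise) {
    cn <- rbinom(n, cd, ctl_f)
    tn <- rbinom(n, td, tum_f)
  } else {
    cn <- as.integer(round(ctl_f * cd))
    tn <- as.integer(round(tum_f * td))
  }
  known <- runif(n) < knownFraction
  calls <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = unname(alt),
                      truth = truth,
                      control_depth = cd, control_nonref = cn,
                      tumor_depth = td, tumor_nonref = tn,
                      known = known, stringsAsFactors = FALSE)
  calls <- calls[order(calls$chrom, calls$pos), , drop = FALSE]
  rownames(calls) <- NULL
  list(calls = calls,
       known = calls[calls$known, c("chrom", "pos")],
       params = list(seed = seed, meanDepth = meanDepth, noise = noise,
                     knownFraction = knownFraction,
                     counts = c(germline_het = nGermlineHet,
                                somatic = nSomatic, loh = nLoh,
                                homref = nRefSites)))
}

#' Write simulated paired calls in the 7-column TSV dialect
#'
#' Two rows per site (control, then tumor), columns `chrom, pos, ref, alt,
#' sample, total_depth, nonref_depth`, readable by [readPairedTsv()].
#'
#' @param sim result of [simulatePairedCalls()] (or its `calls` element).
#' @param path output TSV.
#' @export
writePairedTsv <- function(sim, path) {
  calls <- if (is.data.frame(sim)) sim else sim$calls
  long <- rbind(
    data.frame(chrom = calls$chrom, pos = calls$pos, ref = calls$ref,
               alt = calls$alt, sample = "control",
               total_depth = calls$control_depth,
               nonref_depth = calls$control_nonref),
    data.frame(chrom = calls$chrom, pos = calls$pos, ref = calls$ref,
               alt = calls$alt, sample = "tumor",
               total_depth = calls$tumor_depth,
               nonref_depth = calls$tumor_nonref))
  long <- long[order(long$chrom, long$pos, long$sample), ]
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a known-SNP position list
#'
#' @param known data.frame with `chrom`, `pos` (e.g. the `known` element of
#'   [simulatePairedCalls()]).
#' @param path output TSV (no header), readable by [readKnownPositions()].
#' @export
writeKnownPositions <- function(known, path) {
  write.table(known[, c("chrom", "pos")], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
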