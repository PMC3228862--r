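#' Parse a convention primer name
#'
#' Primer names follow the pattern `<family><start><H|T><length>`, e.g.
#' `"AluY278T18"`: subfamily AluY, first consensus position paired with the
#' primer 278, tail-type, 18 nt. The family part is the leading run of
#' letters (optionally ending in a lowercase suffix such as `"AluJo"`); the
#' two integers are separated by the single type letter.
#'
#' @param name primer name string.
#' @return a list with elements `family` (character), `consensusStart`
#'   (integer), `ptype` (`"H"` or `"T"`) and `length` (integer).
#' @examples
#' parsePrimerName("AluY278T18")
#' @export
parsePrimerName <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  m <- regmatches(name, regexec("^([A-Za-z]+)([0-9]+)([HT])([0-9]+)$", name))[[1]]
  if (length(m) != 5L)
    stop("not a convention primer name: '", name,
         "' (expected <family><start><H|T><length>)")
  list(
    family = m[2L],
    consensusStart = as.integer(m[3L]),
    ptype = m[4L],
    length = as.integer(m[5L])
  )
}

#' Format a convention primer name
#'
#' Inverse of [parsePrimerName()].
#'
#' @param family subfamily name.
#' @param consensusStart 1-based first consensus position.
#' @param ptype `"H"` or `"T"`.
#' @param length oligo length in bases.
#' @return the name string.
#' @export
formatPrimerName <- function(family, consensusStart, ptype, length) {
  stopifnot(ptype %in% c("H", "T"))
  sprintf("%s%d%s%d", family, as.integer(consensusStart), ptype,
          as.integer(length))
}

#' Reverse complement of a DNA sequence
#'
#' Thin wrapper over [Biostrings::reverseComplement()] accepting and
#' returning a plain character string. Only A/C/G/T/N are accepted.
#'
#' @param sequence DNA string.
#' @return the reverse complement, same class as the input.
#' @export
revcomp <- function(sequence) {
  if (is(sequence, "DNAString"))
    return(reverseComplement(sequence))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!grepl("^[ACGTNacgtn]*$", sequence))
    stop("sequence contains characters other than A/C/G/T/N")
  if (!nzchar(sequence)) return(sequence)
  as.character(reverseComplement(DNAString(sequence)))
}

#' Read a subfamily consensus registry from FASTA
#'
#' The registry maps subfamily names (FASTA headers up to the first
#' whitespace) to consensus sequences. Sequences are uppercased.
#'
#' @param path FASTA file of consensus sequences.
#' @return a named [Biostrings::DNAStringSet].
#' @export
readConsensusFasta <- function(path) {
  reg <- readDNAStringSet(path)
  names(reg) <- sub("\\s.*$", "", names(reg))
  if (anyDuplicated(names(reg)))
    stop("duplicate subfamily names in consensus FASTA")
  if (any(width(reg) == 0L))
    stop("empty consensus sequence in FASTA")
  reg
}

#' Derive a primer oligo from a subfamily consensus
#'
#' A T-type primer equals the consensus window
#' `[consensusStart, consensusStart + length - 1]` in sense orientation, so
#' its 3' extension proceeds toward and beyond the poly-A tail. An H-type
#' primer is the reverse complement of the same window, so its 3' extension
#' proceeds toward and beyond the head.
#'
#' @param registry named [Biostrings::DNAStringSet] of consensus sequences
#'   (see [readConsensusFasta()]).
#' @param family subfamily name, a key of `registry`.
#' @param consensusStart 1-based first consensus position paired with the
#'   primer.
#' @param ptype `"H"` or `"T"`.
#' @param length oligo length in bases.
#' @return the oligo 5'->3' as a [Biostrings::DNAString].
#' @examples
#' reg <- Biostrings::DNAStringSet(c(toy = "AACCGGTT"))
#' derivePrimerSequence(reg, "toy", 1, "T", 4)  # AACC
#' derivePrimerSequence(reg, "toy", 1, "H", 4)  # GGTT
#' @export
derivePrimerSequence <- function(registry, family, consensusStart, ptype,
                                 length) {
  stopifnot(ptype %in% c("H", "T"), length >= 1L, consensusStart >= 1L)
  if (!family %in% names(registry))
    stop("unknown subfamily '", family, "' in consensus registry")
  cons <- registry[[family]]
  last <- consensusStart + length - 1L
  if (last > base::length(cons))
    stop("primer window [", consensusStart, ", ", last,
         "] exceeds ", family, " consensus length ", base::length(cons))
  win <- subseq(cons, start = consensusStart, end = last)
  if (ptype == "T") win else reverseComplement(win)
}

#' Construct an AluPrimer
#'
#' Two modes. With a `registry`, `name` must be a convention name
#' (`<family><start><H|T><length>`) and the oligo is derived from the
#' subfamily consensus via [derivePrimerSequence()]. With an explicit
#' `sequence` and `ptype`, any name is accepted (legacy primers such as
#' `"R12A/267"` carry no consensus offset and are never derived).
#'
#' @param name primer name.
#' @param registry optional named [Biostrings::DNAStringSet] of consensus
#'   sequences.
#' @param sequence optional explicit oligo (character or `DNAString`).
#' @param ptype required with `sequence`: `"H"` or `"T"`.
#' @return an [AluPrimer-class] object.
#' @examples
#' aluPrimer("R12A/267", sequence = "AGCGAGACTCCG", ptype = "T")
#' @export
aluPrimer <- function(name, registry = NULL, sequence = NULL, ptype = NULL) {
  if (!is.null(sequence)) {
    if (is.null(ptype))
      stop("explicit-sequence primers need a declared ptype (\"H\" or \"T\")")
    seq <- if (is(sequence, "DNAString")) sequence else DNAString(toupper(sequence))
    return(new("AluPrimer", name = name, family = NA_character_,
               consensusStart = NA_integer_, ptype = ptype, sequence = seq))
  }
  if (is.null(registry))
    stop("supply either a consensus registry or an explicit sequence")
  p <- parsePrimerName(name)
  seq <- derivePrimerSequence(registry, p$family, p$consensusStart, p$ptype,
                              p$length)
  new("AluPrimer", name = name, family = p$family,
      consensusStart = p$consensusStart, ptype = p$ptype,
      sequence = as(seq, "DNAString"))
}

#' Read primer definitions from TSV
#'
#' Accepts a tab-separated file with columns `name`, `ptype`, `sequence`
#' (explicit primers) or a single `name` column of convention names resolved
#' against `registry`.
#'
#' @param path TSV file.
#' @param registry optional consensus registry for convention names.
#' @return a list of [AluPrimer-class] objects, named by primer name.
#' @export
readPrimerTsv <- function(path, registry = NULL) {
  # colClasses: a lone "T" in the ptype column must not parse as logical
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   comment.char = "#", colClasses = "character")
  if (!"name" %in% names(df)) stop("primer TSV needs a 'name' column")
  primers <- lapply(seq_len(nrow(df)), function(i) {
    if (all(c("ptype", "sequence") %in% names(df)) &&
        !is.na(df$sequence[i]) && nzchar(df$sequence[i])) {
      aluPrimer(df$name[i], sequence = df$sequence[i], ptype = df$ptype[i])
    } else {
      aluPrimer(df$name[i], registry = registry)
    }
  })
  setNames(primers, df$name)
}
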