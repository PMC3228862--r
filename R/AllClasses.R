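#' AluPrimer: an Alu-consensus PCR primer
#'
#' Represents one inter-Alu PCR primer. A primer is either derived from a
#' subfamily consensus sequence (in which case `consensusStart` records the
#' 1-based first consensus position paired with the primer) or supplied as an
#' explicit oligo with a declared type. `ptype` is `"H"` (head-type: the 3'
#' extension points outward from the Alu head, i.e. the oligo is the reverse
#' complement of the consensus window) or `"T"` (tail-type: the oligo equals
#' the consensus window in sense orientation, extending through and beyond
#' the poly-A tail).
#'
#' @slot name primer name, e.g. `"AluY278T18"` or a legacy name.
#' @slot family Alu subfamily the primer targets (`NA` for legacy primers).
#' @slot consensusStart 1-based first consensus position paired with the
#'   primer; `NA` for explicit-sequence primers.
#' @slot ptype `"H"` or `"T"`.
#' @slot sequence the oligo 5'->3' as a [Biostrings::DNAString].
#'
#' @seealso [aluPrimer()], [parsePrimerName()], [derivePrimerSequence()]
#' @exportClass AluPrimer
setClass("AluPrimer",
  representation(
    name = "character",
    family = "character",
    consensusStart = "integer",
    ptype = "character",
    sequence = "DNAString"
  )
)

setValidity("AluPrimer", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(object@ptype) != 1L || !object@ptype %in% c("H", "T"))
    msg <- c(msg, "'ptype' must be \"H\" or \"T\"")
  if (length(object@sequence) < 1L)
    msg <- c(msg, "'sequence' must be non-empty")
  if (!is.na(object@consensusStart) && object@consensusStart < 1L)
    msg <- c(msg, "'consensusStart' must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn AluPrimer-class display a one-line primer summary
#' @param object an `AluPrimer`
#' @export
setMethod("show", "AluPrimer", function(object) {
  anchor <- if (is.na(object@consensusStart)) {
    "explicit sequence"
  } else {
    sprintf("%s consensus position %d", object@family, object@consensusStart)
  }
  cat(sprintf(
    "AluPrimer %s (%s-type, %d nt, %s)\n  5'-%s-3'\n",
    object@name, object@ptype, length(object@sequence), anchor,
    as.character(object@sequence)
  ))
})

#' Primer length
#'
#' @param x an [AluPrimer-class]
#' @return integer oligo length in bases
#' @export
primerLength <- function(x) {
  stopifnot(is(x, "AluPrimer"))
  length(x@sequence)
}

#' @rdname AluPrimer-class
#' @param x an `AluPrimer`
#' @export
primerName <- function(x) x@name

#' @rdname AluPrimer-class
#' @export
primerType <- function(x) x@ptype

#' @rdname AluPrimer-class
#' @export
primerSequence <- function(x) x@sequence

#' @rdname AluPrimer-class
#' @export
primerFamily <- function(x) x@family

#' @rdname AluPrimer-class
#' @export
primerConsensusStart <- function(x) x@consensusStart
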