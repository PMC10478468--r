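#' @keywords internal
#' @useDynLib evohotspot
"_PACKAGE"

## Codon -> amino acid map of the bacterial genetic code (translation table 11).
## Table 11 differs from the standard code only in the set of allowed initiation
## codons; the codon-to-residue map used here is identical, so internal codons
## and alternative start codons alike are translated positionally.
.GENETIC_CODE_11 <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L", TCT = "S", TCC = "S", TCA = "S",
  TCG = "S", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*", TGT = "C", TGC = "C",
  TGA = "*", TGG = "W", CTT = "L", CTC = "L", CTA = "L", CTG = "L", CCT = "P",
  CCC = "P", CCA = "P", CCG = "P", CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R", ATT = "I", ATC = "I", ATA = "I",
  ATG = "M", ACT = "T", ACC = "T", ACA = "T", ACG = "T", AAT = "N", AAC = "N",
  AAA = "K", AAG = "K", AGT = "S", AGC = "S", AGA = "R", AGG = "R", GTT = "V",
  GTC = "V", GTA = "V", GTG = "V", GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E", GGT = "G", GGC = "G", GGA = "G",
  GGG = "G"
)

.STOP_CODONS <- c("TAA", "TAG", "TGA")
.SENSE_CODONS <- setdiff(names(.GENETIC_CODE_11), .STOP_CODONS)

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

## Molar masses [g mol^-1]; both molecules carry 6 carbon atoms.
.M_HIS <- 155.15
.M_GLC <- 180.16

#' Complement DNA bases
#'
#' Vectorised single-base complement over `{A, C, G, T, N}`.
#'
#' @param base character vector of single bases.
#' @return character vector of complementary bases.
#' @keywords internal
complement_base <- function(base) {
  out <- .COMPLEMENT[toupper(base)]
  if (anyNA(out)) stop("non-ACGTN base in complement_base()")
  unname(out)
}

#' Reverse-complement a DNA string
#'
#' @param x character scalar (or vector) of DNA sequence.
#' @return reverse-complemented string(s).
#' @export
#' @examples
#' revcomp("ATGC")  # "GCAT"
revcomp <- function(x) {
  vapply(x, function(s) {
    chars <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    paste(rev(complement_base(chars)), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Extract a subsequence with circular wrap-around
#'
#' Coordinates are 1-based inclusive; `end` may exceed the sequence length for
#' circular chromosomes, in which case the slice wraps through the origin.
#'
#' @param sequence character scalar, the full chromosome sequence.
#' @param start,end integer vectors of 1-based inclusive coordinates.
#' @param circular logical; allow wrapping past the end.
#' @return character vector of slices.
#' @keywords internal
subseq_circular <- function(sequence, start, end, circular = TRUE) {
  n <- nchar(sequence)
  if (any(start < 1L) || any(end < start)) stop("invalid slice coordinates")
  if (!circular && any(end > n)) stop("slice beyond end of linear sequence")
  if (circular && any(start > n)) {
    # renormalise slices that begin past the origin
    width <- end - start
    start <- wrap_position(start, n)
    end <- start + width
  }
  wrap <- end > n
  out <- character(length(start))
  if (any(!wrap)) {
    out[!wrap] <- substring(sequence, start[!wrap], end[!wrap])
  }
  if (any(wrap)) {
    out[wrap] <- paste0(
      substring(sequence, start[wrap], n),
      substring(sequence, 1L, end[wrap] - n)
    )
  }
  out
}

## Normalise a 1-based position onto [1, length] of a circular chromosome.
wrap_position <- function(pos, len) {
  ((pos - 1L) %% len) + 1L
}

#' Round half away from zero
#'
#' Display rounding for percent values: 0.5 rounds to 1, -0.5 to -1 (base R's
#' `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

## Translate a vector of codons; unknown codons (e.g. containing N) -> NA.
translate_codons <- function(codons) {
  unname(.GENETIC_CODE_11[toupper(codons)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
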