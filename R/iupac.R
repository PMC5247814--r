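# IUPAC degenerate nucleotide alphabet and low-level sequence primitives.

# 15-letter IUPAC code -> set of concrete bases (U excluded; DNA only).
.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# reverse lookup: sorted set string ("ACG") -> letter ("V")
.IUPAC_KEYS <- stats::setNames(
  names(.IUPAC_SETS),
  vapply(.IUPAC_SETS, function(s) paste(sort(s), collapse = ""), character(1))
)

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Expand an IUPAC letter to its set of concrete bases
#'
#' @param letter A single IUPAC nucleotide letter (case-insensitive).
#' @return Character vector of bases from `{A,C,G,T}`.
#' @keywords internal
iupac_to_set <- function(letter) {
  up <- toupper(letter)
  set <- .IUPAC_SETS[[up]]
  if (is.null(set)) {
    stop("invalid IUPAC nucleotide character '", letter, "'", call. = FALSE)
  }
  set
}

#' Serialize position sets to an IUPAC string
#'
#' Each allowed-nucleotide set maps to its unique IUPAC letter; this is the
#' inverse of pattern parsing and is used to print degenerate consensus
#' strings.
#'
#' @param positions List of non-empty character vectors, each a subset of
#'   `{A,C,G,T}`.
#' @return A single IUPAC string, one letter per position.
#' @examples
#' sets_to_iupac(list(c("A", "G"), "G", c("G", "T"), "T", "C", "A"))  # "RGKTCA"
#' @export
sets_to_iupac <- function(positions) {
  letters <- vapply(positions, function(set) {
    set <- unique(toupper(set))
    if (length(set) == 0L) {
      stop("empty nucleotide set cannot be serialized to IUPAC", call. = FALSE)
    }
    if (!all(set %in% c("A", "C", "G", "T"))) {
      stop("nucleotide set contains non-ACGT symbols: ",
           paste(set, collapse = ","), call. = FALSE)
    }
    key <- paste(sort(set), collapse = "")
    .IUPAC_KEYS[[key]]
  }, character(1))
  paste(letters, collapse = "")
}

#' Reverse complement of a DNA string
#'
#' Standard Watson-Crick reverse complement over `{A,C,G,T,N}`; case is
#' preserved (soft-masked lowercase stays lowercase).
#'
#' @param sequence DNA string over `{A,C,G,T,N}`, case-insensitive.
#' @return The reverse-complemented string.
#' @examples
#' reverse_complement("AGTTCA")  # "TGAACT"
#' @export
reverse_complement <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!grepl("^[ACGTNacgtn]*$", sequence)) {
    bad <- regmatches(sequence, regexpr("[^ACGTNacgtn]", sequence))
    stop("non-nucleotide character '", bad, "' in sequence", call. = FALSE)
  }
  if (nchar(sequence) == 0L) return(sequence)
  chartr("ACGTNacgtn", "TGCANtgcan",
         paste(rev(strsplit(sequence, "", fixed = TRUE)[[1]]), collapse = ""))
}

# complement of a set of concrete bases (no N members expected)
.complement_set <- function(set) sort(unname(.COMPLEMENT[set]))
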