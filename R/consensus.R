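# Degenerate IUPAC consensus and information content from aligned,
# fixed-structure binding sites. Sites of one DR class are column-aligned by
# construction (6 + spacer + 6), so no motif discovery is needed: per-column
# nucleotide counting with a frequency threshold reproduces the printed
# degenerate-consensus semantics.

#' Build a degenerate consensus from aligned sites
#'
#' Position `j` of the consensus includes nucleotide `x` iff
#' `count(x, j) / n_sites > theta`. The default `theta = 0` gives union
#' semantics: every observed variant is included, so every training site
#' matches the consensus (closure).
#'
#' @param sites Character vector of equal-length DNA strings over
#'   `{A,C,G,T}`.
#' @param theta Frequency threshold in `[0, 1)`.
#' @return An object of class `consensus_model` with fields `length`,
#'   `counts` (4 x L matrix, rows A,C,G,T), `n_sites`, `theta`, `sets`, and
#'   `iupac`.
#' @examples
#' build_consensus(c("AGTTCA", "GGGTCA"))$iupac  # "RGKTCA"
#' @export
build_consensus <- function(sites, theta = 0) {
  stopifnot(is.character(sites))
  if (length(sites) == 0L) stop("no sites given", call. = FALSE)
  stopifnot(theta >= 0, theta < 1)
  sites <- toupper(sites)
  L <- unique(nchar(sites))
  if (length(L) != 1L) {
    stop("sites have unequal lengths (", paste(sort(L), collapse = ", "),
         "); group sites by spacer length before counting", call. = FALSE)
  }
  if (!all(grepl("^[ACGT]*$", sites))) {
    stop("sites must be over {A,C,G,T}", call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(sites, "", fixed = TRUE))
  counts <- vapply(seq_len(L), function(j) {
    tab <- table(factor(mat[, j], levels = c("A", "C", "G", "T")))
    as.integer(tab)
  }, integer(4))
  counts <- matrix(counts, nrow = 4L,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  n <- length(sites)
  sets <- lapply(seq_len(L), function(j) {
    rownames(counts)[counts[, j] / n > theta]
  })
  if (any(lengths(sets) == 0L)) {
    stop("theta too high: some position would have an empty set", call. = FALSE)
  }
  structure(
    list(length = L, counts = counts, n_sites = n, theta = theta,
         sets = sets, iupac = sets_to_iupac(sets)),
    class = "consensus_model"
  )
}

#' Per-position information content of a consensus model
#'
#' `IC_j = 2 + sum_x p(x, j) log2 p(x, j)` bits, with frequencies smoothed
#' by a pseudocount: `p = (count + pc) / (n_sites + 4 pc)`. The default
#' pseudocount of 0 reports the raw small-sample estimate.
#'
#' @param model A `consensus_model`.
#' @param pseudocount Non-negative smoothing count added to each cell.
#' @return Numeric vector of per-position bits in `[0, 2]`.
#' @export
information_content <- function(model, pseudocount = 0) {
  stopifnot(inherits(model, "consensus_model"))
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  apply(model$counts, 2, function(col) {
    p <- (col + pseudocount) / (sum(col) + 4 * pseudocount)
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
}

#' Does a site match a consensus model?
#'
#' @param model A `consensus_model`.
#' @param site DNA string of the model's length.
#' @return `TRUE` iff every residue is in the position's consensus set.
#' @export
consensus_matches_site <- function(model, site) {
  stopifnot(inherits(model, "consensus_model"))
  site <- toupper(site)
  if (nchar(site) != model$length) {
    stop("site length ", nchar(site), " != model length ", model$length,
         call. = FALSE)
  }
  chars <- strsplit(site, "", fixed = TRUE)[[1]]
  all(vapply(seq_len(model$length),
             function(j) chars[j] %in% model$sets[[j]], logical(1)))
}

#' @export
print.consensus_model <- function(x, ...) {
  cat(sprintf("<consensus_model> %d sites, length %d, theta = %g\n",
              x$n_sites, x$length, x$theta))
  cat("  IUPAC:", x$iupac, "\n")
  cat("  IC (bits):", paste(sprintf("%.2f", information_content(x)),
                            collapse = " "), "\n")
  invisible(x)
}
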