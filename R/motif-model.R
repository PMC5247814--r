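# Direct-repeat motif grammar: hexameric half-sites plus a spacer, either of
# variable wildcard length (N{a,b}) or of fixed degenerate composition.

.parse_iupac_positions <- function(string, what) {
  chars <- strsplit(toupper(string), "", fixed = TRUE)[[1]]
  raw <- strsplit(string, "", fixed = TRUE)[[1]]
  lapply(seq_along(chars), function(i) {
    set <- .IUPAC_SETS[[chars[i]]]
    if (is.null(set)) {
      stop(what, ": invalid IUPAC character '", raw[i], "' at position ", i,
           call. = FALSE)
    }
    set
  })
}

#' Construct a hexameric half-site pattern
#'
#' @param iupac 6-character IUPAC string, e.g. `"RGKTCA"` for the nuclear
#'   receptor half-site (A/G)G(G/T)TCA.
#' @param name Optional label.
#' @return An object of class `half_site_pattern` with a `positions` list of
#'   six allowed-nucleotide sets.
#' @export
half_site_pattern <- function(iupac, name = iupac) {
  stopifnot(is.character(iupac), length(iupac) == 1L)
  if (nchar(iupac) != 6L) {
    stop("half-site must be exactly 6 nucleotides, got ", nchar(iupac),
         call. = FALSE)
  }
  structure(
    list(name = name, positions = .parse_iupac_positions(iupac, "half-site")),
    class = "half_site_pattern"
  )
}

#' Construct a spacer specification
#'
#' Either a variable-length run of wildcards (`mode = "variable"`, matching
#' any `min_len` to `max_len` bases) or a fixed degenerate string
#' (`mode = "fixed"`, one allowed-nucleotide set per position).
#'
#' @param mode `"variable"` or `"fixed"`.
#' @param min_len,max_len Length bounds for variable mode.
#' @param positions List of allowed-nucleotide sets for fixed mode.
#' @param max_spacer Upper bound accepted for spacer length (default 9,
#'   hard-capped at 15 to bound scan cost).
#' @return An object of class `spacer_spec`.
#' @export
spacer_spec <- function(mode = c("variable", "fixed"), min_len = 0L,
                        max_len = 9L, positions = NULL, max_spacer = 9L) {
  mode <- match.arg(mode)
  max_spacer <- as.integer(max_spacer)
  if (max_spacer > 15L) stop("max_spacer is capped at 15", call. = FALSE)
  if (mode == "variable") {
    min_len <- as.integer(min_len); max_len <- as.integer(max_len)
    if (min_len < 0L || min_len > max_len || max_len > max_spacer) {
      stop("spacer bounds must satisfy 0 <= min <= max <= ", max_spacer,
           call. = FALSE)
    }
    positions <- NULL
  } else {
    if (is.null(positions)) stop("fixed spacer needs positions", call. = FALSE)
    if (length(positions) > max_spacer) {
      stop("fixed spacer longer than ", max_spacer, call. = FALSE)
    }
    min_len <- max_len <- length(positions)
  }
  structure(
    list(mode = mode, min_len = min_len, max_len = max_len,
         positions = positions),
    class = "spacer_spec"
  )
}

#' Parse a direct-repeat pattern from IUPAC strings
#'
#' Builds the full DR grammar: a 5' hexameric half-site, a spacer, and a 3'
#' hexameric half-site. The spacer expression is either `"N{a,b}"` (variable
#' wildcard length, `0 <= a <= b`) or a fixed IUPAC string (possibly empty
#' for a DR0-only pattern).
#'
#' @param half1,half2 6-character IUPAC strings.
#' @param spacer Spacer expression (see above).
#' @param name Pattern label carried into hit tables.
#' @param max_spacer Upper bound for spacer length (default 9, cap 15).
#' @return An object of class `dr_pattern`.
#' @examples
#' parse_iupac_pattern("RGKTCA", "N{0,9}", "RGKTCA")
#' parse_iupac_pattern("RGKTSA", "NNNRV", "RGKWCA")
#' @export
parse_iupac_pattern <- function(half1, spacer, half2,
                                name = paste0(half1, "(", spacer, ")", half2),
                                max_spacer = 9L) {
  h5 <- half_site_pattern(half1)
  h3 <- half_site_pattern(half2)
  m <- regmatches(spacer, regexec("^N\\{([0-9]+)(,([0-9]+))?\\}$", spacer))[[1]]
  if (length(m)) {
    a <- as.integer(m[2])
    b <- if (nzchar(m[4])) as.integer(m[4]) else a
    sp <- spacer_spec("variable", min_len = a, max_len = b,
                      max_spacer = max_spacer)
  } else {
    sp <- spacer_spec("fixed",
                      positions = if (nchar(spacer)) {
                        .parse_iupac_positions(spacer, "spacer")
                      } else list(),
                      max_spacer = max_spacer)
  }
  structure(
    list(name = name, half_site_5p = h5, spacer = sp, half_site_3p = h3),
    class = "dr_pattern"
  )
}

#' The canonical vertebrate RARE scan pattern
#'
#' RGKTCA half-sites, i.e. (A/G)G(G/T)TCA, separated by 0 to 9 wildcard
#' bases — the exhaustive DR0-DR9 direct-repeat grammar used as the default
#' scan pattern.
#'
#' @return A `dr_pattern` named `"canonical-RARE"`.
#' @export
canonical_rare_pattern <- function() {
  parse_iupac_pattern("RGKTCA", "N{0,9}", "RGKTCA", name = "canonical-RARE")
}

#' The degenerate signature of in-vitro validated amphioxus DR5 elements
#'
#' Half-site 1 RGKTSA, fixed 5-base spacer NNNRV, half-site 2 RGKWCA. Shipped
#' as a named built-in; it is derived *from* validated hits, so it is not the
#' default scan pattern.
#'
#' @return A `dr_pattern` named `"amphioxus-validated-DR5"`.
#' @export
amphioxus_validated_dr5_pattern <- function() {
  parse_iupac_pattern("RGKTSA", "NNNRV", "RGKWCA",
                      name = "amphioxus-validated-DR5")
}

#' A literal DR signature pattern
#'
#' Convenience constructor for cross-taxa signature searches, e.g. the DR5
#' signature `AGTTCA(N)5AGTTCA` (`dr_signature(5)`) or its DR2 counterpart
#' (`dr_signature(2)`).
#'
#' @param spacer_len Fixed spacer length in nucleotides.
#' @param half Half-site IUPAC string used on both sides (default the literal
#'   `"AGTTCA"`).
#' @return A `dr_pattern`.
#' @export
dr_signature <- function(spacer_len, half = "AGTTCA") {
  parse_iupac_pattern(half, sprintf("N{%d,%d}", spacer_len, spacer_len), half,
                      name = sprintf("%s-DR%d-signature", half, spacer_len))
}

# spacer position sets realised for a concrete spacer length
.spacer_sets <- function(spacer, len) {
  if (spacer$mode == "fixed") {
    stopifnot(len == length(spacer$positions))
    spacer$positions
  } else {
    rep(list(c("A", "C", "G", "T")), len)
  }
}

# reverse-complemented pattern: swap half-sites, reverse and complement sets
.pattern_revcomp <- function(pattern) {
  rc_sets <- function(positions) {
    lapply(rev(positions), .complement_set)
  }
  sp <- pattern$spacer
  if (sp$mode == "fixed") sp$positions <- rc_sets(sp$positions)
  structure(
    list(name = pattern$name,
         half_site_5p = structure(
           list(name = paste0("rc:", pattern$half_site_3p$name),
                positions = rc_sets(pattern$half_site_3p$positions)),
           class = "half_site_pattern"),
         spacer = sp,
         half_site_3p = structure(
           list(name = paste0("rc:", pattern$half_site_5p$name),
                positions = rc_sets(pattern$half_site_5p$positions)),
           class = "half_site_pattern")),
    class = "dr_pattern"
  )
}

#' Test a hexameric half-site at a sequence offset
#'
#' A genomic residue `N` satisfies only a fully degenerate position
#' (`{A,C,G,T}`); it never matches a constrained set, which avoids phantom
#' elements in gappy assemblies. Matching is case-insensitive.
#'
#' @param sequence DNA string.
#' @param offset 0-based offset of the half-site start.
#' @param pattern A `half_site_pattern`.
#' @return `TRUE` iff all six residues are members of their position sets.
#' @export
half_site_matches <- function(sequence, offset, pattern) {
  stopifnot(inherits(pattern, "half_site_pattern"))
  n <- nchar(sequence)
  if (offset < 0L || offset + 6L > n) {
    stop("offset ", offset, " out of bounds for sequence of length ", n,
         call. = FALSE)
  }
  chars <- strsplit(toupper(substr(sequence, offset + 1L, offset + 6L)),
                    "", fixed = TRUE)[[1]]
  all(vapply(seq_len(6L), function(j) {
    set <- pattern$positions[[j]]
    chars[j] %in% set || (chars[j] == "N" && length(set) == 4L)
  }, logical(1)))
}

#' @export
print.dr_pattern <- function(x, ...) {
  sp <- x$spacer
  spacer_txt <- if (sp$mode == "variable") {
    sprintf("N{%d,%d}", sp$min_len, sp$max_len)
  } else {
    sets_to_iupac(sp$positions)
  }
  cat(sprintf("<dr_pattern> %s: %s + %s + %s\n", x$name,
              sets_to_iupac(x$half_site_5p$positions), spacer_txt,
              sets_to_iupac(x$half_site_3p$positions)))
  invisible(x)
}
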