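# Exhaustive direct-repeat scanner: every (offset, spacer length, strand)
# combination matching a DR pattern is reported, including overlapping and
# nested matches. Coordinates are 0-based half-open on the plus strand.

.empty_hits <- function() {
  data.frame(
    species = character(0), seq_id = character(0),
    start = integer(0), end = integer(0), strand = character(0),
    pattern_name = character(0), dr_class = character(0),
    spacer_length = integer(0), half_site_1 = character(0),
    spacer = character(0), half_site_2 = character(0),
    stringsAsFactors = FALSE
  )
}

.check_alphabet <- function(residues) {
  if (!grepl("^[ACGTNacgtn]*$", residues)) {
    bad <- regmatches(residues, regexpr("[^ACGTNacgtn]", residues))
    stop("invalid residue '", bad, "' in sequence (alphabet is A,C,G,T,N)",
         call. = FALSE)
  }
}

#' Scan one sequence for direct-repeat elements
#'
#' Enumerates every position, spacer length, and strand combination that
#' satisfies a DR pattern; overlapping and nested matches are all reported
#' (one upstream half-site may pair with several downstream half-sites at
#' different spacings). Minus-strand elements are found by matching the
#' reverse-complemented pattern on the plus strand and are reported in
#' plus-strand coordinates with `strand = "-"`; their `half_site_1`,
#' `spacer`, and `half_site_2` fields read 5'->3' on the minus strand.
#'
#' @param residues DNA string over `{A,C,G,T,N}` (case-insensitive).
#' @param patterns A `dr_pattern` or list of them.
#' @param strand_mode `"both"` (default) or `"plus"`.
#' @param window Optional 0-based half-open interval `c(lo, hi)`; only
#'   elements fully inside it are reported.
#' @param masked_policy `"match"` (default: soft-masked lowercase matches) or
#'   `"skip"` (lowercase residues fail every position).
#' @param seq_id,species Provenance labels attached to the hit table.
#' @return A `data.frame` of hits sorted by `(start, end, strand)` with
#'   columns `species, seq_id, start, end, strand, pattern_name, dr_class,
#'   spacer_length, half_site_1, spacer, half_site_2`, deduplicated on
#'   `(start, end, strand, pattern_name)`.
#' @examples
#' scan_sequence("AGTTCAACAAAAGTTCA", canonical_rare_pattern())
#' @export
scan_sequence <- function(residues, patterns = canonical_rare_pattern(),
                          strand_mode = c("both", "plus"), window = NULL,
                          masked_policy = c("match", "skip"),
                          seq_id = NA_character_, species = NA_character_) {
  strand_mode <- match.arg(strand_mode)
  masked_policy <- match.arg(masked_policy)
  stopifnot(is.character(residues), length(residues) == 1L)
  .check_alphabet(residues)
  if (inherits(patterns, "dr_pattern")) patterns <- list(patterns)
  if (length(patterns) == 0L) stop("at least one pattern required", call. = FALSE)
  stopifnot(all(vapply(patterns, inherits, logical(1), "dr_pattern")))

  n <- nchar(residues)
  if (is.null(window)) {
    window <- c(0L, n)
  } else {
    window <- as.integer(window)
    if (length(window) != 2L || window[1] < 0L || window[1] > window[2] ||
        window[2] > n) {
      stop("window must be 0-based half-open within [0, ", n, "]", call. = FALSE)
    }
  }
  lo <- window[1]; hi <- window[2]
  sub <- substr(residues, lo + 1L, hi)
  raw <- strsplit(sub, "", fixed = TRUE)[[1]]
  chars <- toupper(raw)
  if (masked_policy == "skip" && length(raw)) {
    chars[raw %in% c("a", "c", "g", "t", "n")] <- "#"
  }
  upper <- toupper(residues)

  # per-position membership masks are shared across spacer lengths
  mask_cache <- new.env(parent = emptyenv())
  get_mask <- function(set) {
    key <- paste(set, collapse = "")
    m <- mask_cache[[key]]
    if (is.null(m)) {
      mset <- if (length(set) == 4L) c(set, "N") else set
      m <- chars %in% mset
      mask_cache[[key]] <- m
    }
    m
  }
  match_starts <- function(sets) {
    nn <- length(chars); L <- length(sets)
    if (L == 0L || nn < L) return(integer(0))
    ok <- get_mask(sets[[1]])[seq_len(nn - L + 1L)]
    for (j in seq_len(L)[-1]) {
      ok <- ok & get_mask(sets[[j]])[j:(nn - L + j)]
      if (!any(ok)) return(integer(0))
    }
    which(ok) - 1L
  }

  out <- list()
  for (pat in patterns) {
    orientations <- list(list(strand = "+", p = pat))
    if (strand_mode == "both") {
      orientations <- c(orientations,
                        list(list(strand = "-", p = .pattern_revcomp(pat))))
    }
    for (ori in orientations) {
      p <- ori$p
      for (s in seq.int(p$spacer$min_len, p$spacer$max_len)) {
        sets <- c(p$half_site_5p$positions, .spacer_sets(p$spacer, s),
                  p$half_site_3p$positions)
        starts <- match_starts(sets) + lo
        if (!length(starts)) next
        ends <- starts + 12L + s
        elt <- substring(upper, starts + 1L, ends)
        if (ori$strand == "-") {
          elt <- vapply(elt, reverse_complement, character(1), USE.NAMES = FALSE)
        }
        out[[length(out) + 1L]] <- data.frame(
          species = species, seq_id = seq_id,
          start = starts, end = ends, strand = ori$strand,
          pattern_name = pat$name, dr_class = paste0("DR", s),
          spacer_length = s,
          half_site_1 = substr(elt, 1L, 6L),
          spacer = substr(elt, 7L, 6L + s),
          half_site_2 = substr(elt, 7L + s, 12L + s),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) return(.empty_hits())
  hits <- do.call(rbind, out)
  key <- paste(hits$start, hits$end, hits$strand, hits$pattern_name)
  hits <- hits[!duplicated(key), , drop = FALSE]
  hits <- hits[order(hits$start, hits$end, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Scan a collection of sequences
#'
#' @param sequences A `data.frame` with columns `species`, `seq_id`,
#'   `residues` (one genomic sequence per row).
#' @param windows Optional named list of 0-based half-open intervals keyed by
#'   `seq_id`.
#' @inheritParams scan_sequence
#' @return Concatenated hit table with provenance, ordered by
#'   `(species, seq_id, start)`.
#' @export
scan_collection <- function(sequences, patterns = canonical_rare_pattern(),
                            strand_mode = c("both", "plus"), windows = NULL,
                            masked_policy = c("match", "skip")) {
  strand_mode <- match.arg(strand_mode)
  masked_policy <- match.arg(masked_policy)
  stopifnot(is.data.frame(sequences),
            all(c("species", "seq_id", "residues") %in% names(sequences)))
  if (nrow(sequences) == 0L) return(.empty_hits())
  key <- paste(sequences$species, sequences$seq_id)
  if (anyDuplicated(key)) {
    stop("duplicate (species, seq_id): ", key[duplicated(key)][1], call. = FALSE)
  }
  parts <- lapply(seq_len(nrow(sequences)), function(i) {
    scan_sequence(sequences$residues[i], patterns, strand_mode,
                  window = windows[[sequences$seq_id[i]]],
                  masked_policy = masked_policy,
                  seq_id = sequences$seq_id[i], species = sequences$species[i])
  })
  hits <- do.call(rbind, parts)
  hits <- hits[order(hits$species, hits$seq_id, hits$start, hits$end,
                     hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Survey window around a gene cluster
#'
#' The interval from `up` bases upstream of the first (by cluster rank)
#' gene's start codon to `down` bases downstream of the last gene's stop
#' codon, along the cluster axis, clamped to the sequence. Defaults of
#' 20 kb on each side reproduce the standard survey region.
#'
#' @param genes Gene-model `data.frame` (see [annotate_hits()]).
#' @param up,down Flank sizes in bp.
#' @param seq_length Host sequence length in bp.
#' @return Integer vector `c(lo, hi)`, 0-based half-open.
#' @export
cluster_window <- function(genes, up = 20000L, down = 20000L, seq_length) {
  genes <- .validate_genes(genes)
  bodies <- .gene_bodies(genes)
  if (any(bodies$hi > seq_length) || any(bodies$lo < 0L)) {
    stop("gene coordinates outside [0, seq_length]", call. = FALSE)
  }
  axis <- .axis_strand(genes)
  first <- which(genes$cluster_rank == min(genes$cluster_rank))
  last <- which(genes$cluster_rank == max(genes$cluster_rank))
  if (axis == "+") {
    lo <- bodies$lo[first] - up
    hi <- bodies$hi[last] + down
  } else {
    lo <- bodies$lo[last] - down
    hi <- bodies$hi[first] + up
  }
  c(max(0L, as.integer(lo)), min(as.integer(seq_length), as.integer(hi)))
}
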