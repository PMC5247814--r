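# Cross-species conservation filter: elements are deemed "the same" when
# they agree in DR class, motif sequence (at a configurable stringency), and
# relative position within the cluster (compartment by ortholog rank,
# orientation, normalized intra-compartment position).

#' Conservation criteria
#'
#' @param require_all_species Require one member per input species.
#' @param sequence_stringency `"exact-element"` (half-sites and spacer
#'   sequence letter-identical, the default), `"half-sites-and-spacer-length"`
#'   (spacer sequence free), or `"class-only"`.
#' @param require_same_compartment Compare compartments by ortholog-rank key.
#' @param require_same_orientation Compare orientation relative to the
#'   cluster axis.
#' @param position_tolerance Maximum allowed difference in normalized
#'   intra-compartment position, as a fraction of compartment length in
#'   `[0, 1]` (default 0.25).
#' @return An object of class `conservation_criteria`.
#' @export
conservation_criteria <- function(require_all_species = TRUE,
                                  sequence_stringency = c("exact-element",
                                                          "half-sites-and-spacer-length",
                                                          "class-only"),
                                  require_same_compartment = TRUE,
                                  require_same_orientation = TRUE,
                                  position_tolerance = 0.25) {
  sequence_stringency <- match.arg(sequence_stringency)
  stopifnot(position_tolerance >= 0, position_tolerance <= 1)
  structure(
    list(require_all_species = isTRUE(require_all_species),
         sequence_stringency = sequence_stringency,
         require_same_compartment = isTRUE(require_same_compartment),
         require_same_orientation = isTRUE(require_same_orientation),
         position_tolerance = position_tolerance),
    class = "conservation_criteria"
  )
}

.check_annotated <- function(hit) {
  need <- c("compartment_key", "norm_pos", "cluster_orientation")
  if (!all(need %in% names(hit))) {
    stop("hits lack annotation columns; run annotate_hits() first",
         call. = FALSE)
  }
}

.element_string <- function(hit) {
  paste0(hit$half_site_1, hit$spacer, hit$half_site_2)
}

#' Do two annotated elements from different species correspond?
#'
#' @param a,b One-row annotated hit `data.frame`s from different species.
#' @param criteria A [conservation_criteria()] object.
#' @return `TRUE` iff every enabled criterion holds.
#' @export
elements_match <- function(a, b, criteria = conservation_criteria()) {
  .check_annotated(a); .check_annotated(b)
  if (a$dr_class != b$dr_class) return(FALSE)
  seq_ok <- switch(criteria$sequence_stringency,
    "exact-element" = .element_string(a) == .element_string(b),
    "half-sites-and-spacer-length" =
      a$half_site_1 == b$half_site_1 && a$half_site_2 == b$half_site_2 &&
      a$spacer_length == b$spacer_length,
    "class-only" = TRUE)
  if (!seq_ok) return(FALSE)
  if (criteria$require_same_compartment &&
      a$compartment_key != b$compartment_key) return(FALSE)
  if (criteria$require_same_orientation &&
      a$cluster_orientation != b$cluster_orientation) return(FALSE)
  abs(a$norm_pos - b$norm_pos) <= criteria$position_tolerance
}

#' Find elements conserved across species
#'
#' Greedy assembly of cross-species groups: species are processed in
#' alphabetical order (so the result does not depend on input order); hits
#' of the first species, sorted along the cluster axis (compartment rank,
#' then normalized position, then coordinate), seed candidate groups; for
#' each remaining species the unused hit with the smallest normalized
#' position discrepancy that satisfies [elements_match()] joins the group.
#' A group is emitted only when every pairwise check passes (full transitive
#' consistency) and, under `require_all_species`, has exactly one member per
#' species. Each hit belongs to at most one group.
#'
#' @param annotated Annotated hit table covering >= 2 species.
#' @param criteria A [conservation_criteria()] object.
#' @param species Species expected in the comparison (defaults to those
#'   present in `annotated`); a listed species with zero hits makes
#'   all-species groups impossible.
#' @return A long-format `data.frame` with one row per group member:
#'   `group_id, dr_class, species, seq_id, start, end, strand, element,
#'   compartment_key, norm_pos`, carrying the criteria as attribute
#'   `"criteria"`.
#' @export
find_conserved <- function(annotated, criteria = conservation_criteria(),
                           species = sort(unique(annotated$species))) {
  .check_annotated(annotated)
  empty <- data.frame(group_id = character(0), dr_class = character(0),
                      species = character(0), seq_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), element = character(0),
                      compartment_key = character(0), norm_pos = numeric(0),
                      stringsAsFactors = FALSE)
  attr(empty, "criteria") <- criteria
  species <- sort(species)
  if (length(species) < 2L) {
    stop("conservation filtering needs hits from at least 2 species",
         call. = FALSE)
  }
  by_sp <- lapply(species, function(sp) {
    h <- annotated[annotated$species == sp, , drop = FALSE]
    h[order(h$comp_index, h$norm_pos, h$start), , drop = FALSE]
  })
  names(by_sp) <- species
  if (criteria$require_all_species && any(vapply(by_sp, nrow, 0L) == 0L)) {
    message("a species has zero hits; no all-species groups possible")
    return(empty)
  }
  used <- lapply(by_sp, function(h) rep(FALSE, nrow(h)))
  ref_sp <- species[1]
  groups <- list()
  refh <- by_sp[[ref_sp]]
  for (i in seq_len(nrow(refh))) {
    if (used[[ref_sp]][i]) next
    seed <- refh[i, , drop = FALSE]
    members <- list(seed)
    member_idx <- stats::setNames(list(i), ref_sp)
    ok <- TRUE
    for (sp in species[-1]) {
      h <- by_sp[[sp]]
      cand <- which(!used[[sp]] &
                      vapply(seq_len(nrow(h)), function(j) {
                        !used[[sp]][j] &&
                          elements_match(seed, h[j, , drop = FALSE], criteria)
                      }, logical(1)))
      if (!length(cand)) {
        if (criteria$require_all_species) { ok <- FALSE; break }
        next
      }
      disc <- abs(h$norm_pos[cand] - seed$norm_pos)
      best <- cand[order(disc, h$start[cand])][1]
      members[[length(members) + 1L]] <- h[best, , drop = FALSE]
      member_idx[[sp]] <- best
    }
    if (!ok) next
    if (criteria$require_all_species && length(members) < length(species)) next
    if (length(members) < 2L) next
    # transitive consistency: all pairwise checks, not just seed-vs-member
    pairwise <- TRUE
    for (p in seq_along(members)) {
      for (q in seq_along(members)) {
        if (p < q && !elements_match(members[[p]], members[[q]], criteria)) {
          pairwise <- FALSE
        }
      }
    }
    if (!pairwise) next
    for (sp in names(member_idx)) used[[sp]][member_idx[[sp]]] <- TRUE
    groups[[length(groups) + 1L]] <- members
  }
  if (!length(groups)) return(empty)
  out <- do.call(rbind, lapply(seq_along(groups), function(g) {
    do.call(rbind, lapply(groups[[g]], function(m) {
      data.frame(group_id = sprintf("grp%03d", g), dr_class = m$dr_class,
                 species = m$species, seq_id = m$seq_id, start = m$start,
                 end = m$end, strand = m$strand,
                 element = .element_string(m),
                 compartment_key = m$compartment_key, norm_pos = m$norm_pos,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  attr(out, "criteria") <- criteria
  out
}

#' Search sequences for a literal DR signature
#'
#' A scanner run restricted to a fixed signature pattern, e.g. the DR5
#' signature `AGTTCA(N)5AGTTCA` used for cross-taxa screens.
#'
#' @param sequences Sequence `data.frame` (see [scan_collection()]).
#' @param signature A `dr_pattern`, typically from [dr_signature()].
#' @param ... Passed to [scan_collection()].
#' @return A hit table.
#' @export
signature_search <- function(sequences, signature = dr_signature(5), ...) {
  scan_collection(sequences, patterns = list(signature), ...)
}
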