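# Cluster-relative annotation of scanned elements: compartment, nearest
# downstream gene, distance to its start codon, and orientation relative to
# the cluster axis.

# non-genic + genic compartment intervals in axis order
# returns data.frame(key, label, lo, hi, index, genic)
.compartments <- function(genes, window) {
  genes <- .validate_genes(genes)
  bodies <- .gene_bodies(genes)
  n <- nrow(genes)
  axis <- .axis_strand(genes)
  rows <- list()
  add <- function(key, label, lo, hi, index, genic) {
    rows[[length(rows) + 1L]] <<- data.frame(
      key = key, label = label, lo = as.integer(lo), hi = as.integer(hi),
      index = index, genic = genic, stringsAsFactors = FALSE)
  }
  if (axis == "+") {
    add("U", "upstream-of-cluster", window[1], bodies$lo[1], 0L, FALSE)
    for (k in seq_len(n)) {
      add(sprintf("G%d", k), sprintf("intragenic(%s)", bodies$gene_id[k]),
          bodies$lo[k], bodies$hi[k], 2L * k - 1L, TRUE)
      if (k < n) {
        add(sprintf("I%d.%d", k, k + 1L),
            sprintf("intergenic(%s,%s)", bodies$gene_id[k], bodies$gene_id[k + 1L]),
            bodies$hi[k], bodies$lo[k + 1L], 2L * k, FALSE)
      }
    }
    add("D", "downstream-of-cluster", bodies$hi[n], window[2], 2L * n, FALSE)
  } else {
    add("U", "upstream-of-cluster", bodies$hi[1], window[2], 0L, FALSE)
    for (k in seq_len(n)) {
      add(sprintf("G%d", k), sprintf("intragenic(%s)", bodies$gene_id[k]),
          bodies$lo[k], bodies$hi[k], 2L * k - 1L, TRUE)
      if (k < n) {
        add(sprintf("I%d.%d", k, k + 1L),
            sprintf("intergenic(%s,%s)", bodies$gene_id[k], bodies$gene_id[k + 1L]),
            bodies$hi[k + 1L], bodies$lo[k], 2L * k, FALSE)
      }
    }
    add("D", "downstream-of-cluster", window[1], bodies$lo[n], 2L * n, FALSE)
  }
  do.call(rbind, rows)
}

#' Distance from an element to a gene's start codon
#'
#' The number of bases strictly between the element's proximal edge (the
#' edge nearest the start codon along the cluster axis) and the first base
#' of the ATG; 0 means the element abuts the start codon.
#'
#' @param hit_start,hit_end 0-based half-open element coordinates.
#' @param gene One-row gene-model `data.frame`.
#' @return Distance in bp (>= 0).
#' @export
distance_to_start <- function(hit_start, hit_end, gene) {
  d <- if (gene$strand == "+") {
    gene$start_codon_pos - hit_end
  } else {
    hit_start - gene$start_codon_pos - 1L
  }
  if (d < 0L) {
    stop("element is not upstream of the start codon of ", gene$gene_id,
         " (assign compartments first)", call. = FALSE)
  }
  as.integer(d)
}

#' Orientation of an element relative to the cluster axis
#'
#' @param hit_strand `"+"` or `"-"` on the assembly.
#' @param cluster_axis_strand Strand of the cluster axis on the assembly.
#' @return `"+"` if they agree, `"-"` otherwise.
#' @export
cluster_orientation <- function(hit_strand, cluster_axis_strand) {
  ifelse(hit_strand == cluster_axis_strand, "+", "-")
}

#' Assign a hit to a cluster compartment
#'
#' An element overlapping any base of a gene body (codon-to-codon span, or
#' UTR-extended span when such coordinates are supplied) is `intragenic`;
#' otherwise the element belongs to the flanking or intergenic interval
#' containing its midpoint.
#'
#' @param hit_start,hit_end 0-based half-open element coordinates.
#' @param genes Gene-model `data.frame` for the host sequence.
#' @param window 0-based half-open survey window (bounds the flanking
#'   compartments).
#' @return Compartment label, e.g. `"intergenic(cyp26_1,cyp26_2)"`.
#' @export
assign_compartment <- function(hit_start, hit_end, genes, window = NULL) {
  genes <- .validate_genes(genes)
  if (is.null(window)) {
    window <- c(0L, max(.gene_bodies(genes)$hi, hit_end))
  }
  comps <- .compartments(genes, window)
  .locate_compartment(hit_start, hit_end, comps)$label
}

# row of the compartment table a hit falls in
.locate_compartment <- function(hit_start, hit_end, comps) {
  genic <- comps[comps$genic, , drop = FALSE]
  ov <- genic[hit_start < genic$hi & hit_end > genic$lo, , drop = FALSE]
  if (nrow(ov)) return(ov[1, , drop = FALSE])
  m <- (hit_start + hit_end) / 2
  non <- comps[!comps$genic, , drop = FALSE]
  inside <- non[m >= non$lo & m < non$hi, , drop = FALSE]
  if (nrow(inside)) return(inside[1, , drop = FALSE])
  # outside the survey window: annotate as the flanking compartment
  warning("element midpoint outside the survey window; annotated as flanking",
          call. = FALSE)
  edge <- if (m < min(non$lo)) non[which.min(non$lo), ] else non[which.max(non$hi), ]
  edge
}

#' Annotate scanned elements relative to their gene cluster
#'
#' Adds to each hit: its compartment (label and cross-species rank key), the
#' nearest downstream gene along the cluster axis with the distance to its
#' start codon, the orientation relative to the cluster axis, and the
#' normalized position of the element midpoint within its compartment
#' (0 at the axis-upstream edge, 1 at the downstream edge) used by the
#' conservation filter.
#'
#' @param hits Hit table from [scan_sequence()] or [scan_collection()].
#' @param genes Gene-model `data.frame`; must cover every species in `hits`
#'   (column `species` required when hits span several species).
#' @param windows Survey window: a single `c(lo, hi)` vector, or a named
#'   list keyed by species. Defaults to `[0, max coordinate)` per species.
#' @return The hit table with annotation columns appended.
#' @export
annotate_hits <- function(hits, genes, windows = NULL) {
  if (nrow(hits) == 0L) {
    out <- hits
    out$compartment <- character(0); out$compartment_key <- character(0)
    out$comp_index <- integer(0); out$norm_pos <- numeric(0)
    out$nearest_downstream_gene <- character(0)
    out$distance_to_start_codon <- integer(0)
    out$cluster_orientation <- character(0)
    return(out)
  }
  species_set <- unique(hits$species)
  parts <- lapply(species_set, function(sp) {
    h <- hits[hits$species == sp | (is.na(sp) & is.na(hits$species)), ,
              drop = FALSE]
    g <- if ("species" %in% names(genes) && !is.na(sp)) {
      genes[genes$species == sp, , drop = FALSE]
    } else genes
    g <- .validate_genes(g)
    win <- if (is.list(windows)) windows[[sp]] else windows
    if (is.null(win)) win <- c(0L, max(.gene_bodies(g)$hi, h$end))
    .annotate_one_species(h, g, win)
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$species, out$seq_id, out$start, out$end, out$strand), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

.annotate_one_species <- function(hits, genes, window) {
  axis <- .axis_strand(genes)
  comps <- .compartments(genes, window)
  bodies <- .gene_bodies(genes)
  n <- nrow(hits)
  hits$compartment <- character(n)
  hits$compartment_key <- character(n)
  hits$comp_index <- integer(n)
  hits$norm_pos <- numeric(n)
  hits$nearest_downstream_gene <- NA_character_
  hits$distance_to_start_codon <- NA_integer_
  hits$cluster_orientation <- cluster_orientation(hits$strand, axis)
  for (i in seq_len(n)) {
    s <- hits$start[i]; e <- hits$end[i]
    comp <- .locate_compartment(s, e, comps)
    hits$compartment[i] <- comp$label
    hits$compartment_key[i] <- comp$key
    hits$comp_index[i] <- comp$index
    width <- comp$hi - comp$lo
    t <- if (width > 0) ((s + e) / 2 - comp$lo) / width else 0.5
    if (axis == "-") t <- 1 - t
    hits$norm_pos[i] <- min(1, max(0, t))
    # nearest gene downstream along the axis whose start codon the hit precedes
    for (k in seq_len(nrow(genes))) {
      g <- genes[k, , drop = FALSE]
      d <- if (g$strand == "+") g$start_codon_pos - e else s - g$start_codon_pos - 1L
      if (d >= 0L) {
        hits$nearest_downstream_gene[i] <- g$gene_id
        hits$distance_to_start_codon[i] <- as.integer(d)
        break
      }
    }
  }
  hits
}
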