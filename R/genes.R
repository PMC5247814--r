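# Gene-model tables: one row per gene with codon-anchored coordinates.
#
# Conventions (0-based, plus strand of the assembly):
#   * plus-strand gene:  start_codon_pos = first base of ATG;
#     stop_codon_end = one past the last stop-codon base; the gene body is
#     [start_codon_pos, stop_codon_end).
#   * minus-strand gene: start_codon_pos = plus-strand position of the ATG's
#     first base read 5'->3' on the minus strand (the rightmost body base);
#     stop_codon_end = one past the last stop base in transcript direction,
#     i.e. body_lo - 1; the body is [stop_codon_end + 1, start_codon_pos + 1).

.validate_genes <- function(genes) {
  stopifnot(is.data.frame(genes))
  need <- c("gene_id", "strand", "start_codon_pos", "stop_codon_end",
            "cluster_rank")
  missing <- setdiff(need, names(genes))
  if (length(missing)) {
    stop("gene table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(genes) == 0L) stop("empty gene list", call. = FALSE)
  if (anyDuplicated(genes$cluster_rank)) {
    stop("cluster_rank values must be unique", call. = FALSE)
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'", call. = FALSE)
  }
  genes[order(genes$cluster_rank), , drop = FALSE]
}

# per-gene body interval [lo, hi) on the plus strand
.gene_bodies <- function(genes) {
  lo <- ifelse(genes$strand == "+", genes$start_codon_pos,
               genes$stop_codon_end + 1L)
  hi <- ifelse(genes$strand == "+", genes$stop_codon_end,
               genes$start_codon_pos + 1L)
  data.frame(gene_id = genes$gene_id, lo = as.integer(lo), hi = as.integer(hi),
             stringsAsFactors = FALSE)
}

# cluster axis strand: strand of the rank-1 gene (genes of one cluster share it)
.axis_strand <- function(genes) {
  genes$strand[which.min(genes$cluster_rank)]
}

#' Read a gene-model table from TSV
#'
#' Expected columns: `species, seq_id, gene_id, start_codon_pos,
#' stop_codon_end, strand` and optionally `cluster_rank` (defaults to file
#' order per species).
#'
#' @param path Path to a tab-separated file (comment lines `#` allowed).
#' @return A gene-model `data.frame`.
#' @export
read_gene_table <- function(path) {
  genes <- utils::read.delim(path, comment.char = "#",
                             stringsAsFactors = FALSE)
  if (!"cluster_rank" %in% names(genes)) {
    genes$cluster_rank <- stats::ave(seq_len(nrow(genes)), genes$species,
                                     FUN = seq_along)
  }
  genes
}

#' Read gene models from GFF3 start/stop codon features
#'
#' Uses `start_codon` and `stop_codon` features (grouped by their `Parent`
#' or `gene_id` attribute) to build the codon-anchored gene table. Requires
#' the rtracklayer package.
#'
#' @param path Path to a GFF3 file.
#' @param species Species label attached to all genes.
#' @return A gene-model `data.frame` with cluster ranks in coordinate order
#'   along the cluster axis.
#' @export
read_gene_models_gff3 <- function(path, species = NA_character_) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading GFF3 requires the rtracklayer package", call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "gff3")
  feats <- as.data.frame(gr)
  feats$gene <- if ("Parent" %in% names(feats)) {
    vapply(feats$Parent, function(p) if (length(p)) as.character(p[[1]]) else NA_character_,
           character(1))
  } else {
    as.character(feats$gene_id)
  }
  keep <- feats$type %in% c("start_codon", "stop_codon")
  feats <- feats[keep, , drop = FALSE]
  if (!nrow(feats)) stop("no start_codon/stop_codon features in ", path,
                         call. = FALSE)
  out <- do.call(rbind, lapply(split(feats, feats$gene), function(f) {
    sc <- f[f$type == "start_codon", ][1, ]
    st <- f[f$type == "stop_codon", ][1, ]
    strand <- as.character(sc$strand)
    # GFF3 is 1-based inclusive; convert to the 0-based codon anchors
    if (strand == "+") {
      scp <- sc$start - 1L
      ste <- st$end
    } else {
      scp <- sc$end - 1L
      ste <- st$start - 2L
    }
    data.frame(species = species, seq_id = as.character(sc$seqnames)[1],
               gene_id = f$gene[1], start_codon_pos = as.integer(scp),
               stop_codon_end = as.integer(ste), strand = strand,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  axis <- out$strand[1]
  ord <- order(if (axis == "+") out$start_codon_pos else -out$start_codon_pos)
  out <- out[ord, , drop = FALSE]
  out$cluster_rank <- seq_len(nrow(out))
  out
}
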