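# Pipeline orchestration: windowed scan -> cluster annotation ->
# cross-species conservation -> per-class consensus, with TSV/BED output.
# All analysis stages are deterministic; only the synthetic generator
# consumes randomness.

.pkg_version <- function() {
  as.character(utils::packageVersion("rarescan"))
}

# short stable hash of a config list (provenance header, no external deps)
.config_hash <- function(x) {
  s <- paste(utils::capture.output(utils::str(x)), collapse = "\n")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% .Machine$integer.max)
}

#' Read per-species FASTA files into a sequence table
#'
#' @param paths Character vector of FASTA paths (plain or gzip), named by
#'   species label.
#' @return A `data.frame` with columns `species, seq_id, residues`.
#' @export
read_species_fasta <- function(paths) {
  stopifnot(!is.null(names(paths)), all(nzchar(names(paths))))
  do.call(rbind, lapply(names(paths), function(sp) {
    if (!file.exists(paths[[sp]])) {
      stop("missing input file: ", paths[[sp]], call. = FALSE)
    }
    dna <- Biostrings::readDNAStringSet(paths[[sp]])
    data.frame(species = sp,
               seq_id = sub("\\s.*$", "", names(dna)),
               residues = as.character(dna),
               stringsAsFactors = FALSE)
  }))
}

.hit_header <- function(extra = character(0)) {
  c(sprintf("# rarescan v%s", .pkg_version()),
    "# coordinates: start/end are 0-based half-open on the plus strand",
    extra)
}

#' Write a hit or annotation table as TSV
#'
#' @param hits Hit table.
#' @param path Output path.
#' @param extra_header Additional `#`-prefixed header lines.
#' @return Invisibly, `path`.
#' @export
write_hits_tsv <- function(hits, path, extra_header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.hit_header(extra_header), con)
  utils::write.table(hits, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write hits as BED6
#'
#' `name` is `pattern_name|dr_class|half1|spacer|half2`; score is 0; BED
#' coordinates are 0-based half-open.
#'
#' @param hits Hit table.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hits_bed <- function(hits, path) {
  bed <- data.frame(
    chrom = hits$seq_id, start = hits$start, end = hits$end,
    name = paste(hits$pattern_name, hits$dr_class, hits$half_site_1,
                 hits$spacer, hits$half_site_2, sep = "|"),
    score = 0L, strand = hits$strand, stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.hit_header(), con)
  utils::write.table(bed, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Windowed direct-repeat scan across species
#'
#' Computes the survey window per species from its gene models (by default
#' 20 kb upstream of the first gene's start codon to 20 kb downstream of
#' the last gene's stop codon) and scans both strands exhaustively.
#'
#' @param sequences Sequence table (`species, seq_id, residues`), e.g. from
#'   [read_species_fasta()] or [generate_cluster_set()].
#' @param genes Gene-model table covering the same species.
#' @param patterns Scan patterns (default the canonical DR0-DR9 pattern).
#' @param up,down Survey flanks in bp.
#' @param strand_mode,masked_policy See [scan_sequence()].
#' @param out_dir Optional directory to receive per-species TSV + BED and a
#'   JSON summary sidecar.
#' @return Hit table with a `"windows"` attribute (named per species).
#' @export
run_scan <- function(sequences, genes, patterns = canonical_rare_pattern(),
                     up = 20000L, down = 20000L,
                     strand_mode = c("both", "plus"),
                     masked_policy = c("match", "skip"), out_dir = NULL) {
  strand_mode <- match.arg(strand_mode)
  masked_policy <- match.arg(masked_policy)
  if (inherits(patterns, "dr_pattern")) patterns <- list(patterns)
  species <- unique(sequences$species)
  parts <- list(); windows <- list()
  for (sp in species) {
    rows <- which(sequences$species == sp)
    for (i in rows) {
      g <- genes[genes$species == sp & genes$seq_id == sequences$seq_id[i], ,
                 drop = FALSE]
      win <- cluster_window(g, up, down, nchar(sequences$residues[i]))
      windows[[sp]] <- win
      parts[[length(parts) + 1L]] <- scan_sequence(
        sequences$residues[i], patterns, strand_mode, window = win,
        masked_policy = masked_policy, seq_id = sequences$seq_id[i],
        species = sp)
    }
  }
  hits <- do.call(rbind, parts)
  hits <- hits[order(hits$species, hits$seq_id, hits$start, hits$end,
                     hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (sp in species) {
      h <- hits[hits$species == sp, , drop = FALSE]
      write_hits_tsv(h, file.path(out_dir, paste0("hits_", sp, ".tsv")),
                     sprintf("# window: [%d, %d)", windows[[sp]][1],
                             windows[[sp]][2]))
      write_hits_bed(h, file.path(out_dir, paste0("hits_", sp, ".bed")))
      summary <- list(species = sp, n_hits = nrow(h),
                      by_class = as.list(table(h$dr_class)),
                      window = windows[[sp]])
      jsonlite::write_json(summary,
                           file.path(out_dir, paste0("hits_", sp, ".json")),
                           auto_unbox = TRUE)
    }
  }
  for (sp in species) {
    h <- hits[hits$species == sp, , drop = FALSE]
    tally <- paste(sprintf("%s:%d", names(table(h$dr_class)),
                           as.integer(table(h$dr_class))), collapse = " ")
    message(sprintf("scan %s: %d hits (%s)", sp, nrow(h), tally))
  }
  attr(hits, "windows") <- windows
  hits
}

#' Run the full element-discovery workflow
#'
#' Scan (windowed, both strands) -> cluster-relative annotation ->
#' cross-species conservation filter -> degenerate consensus per DR class of
#' the conserved (optionally validated-only) elements. Every intermediate
#' is returned; with `out_dir` every intermediate is also written, plus a
#' YAML run manifest with the configuration and its hash.
#'
#' @inheritParams run_scan
#' @param criteria A [conservation_criteria()] object.
#' @param theta Consensus frequency threshold.
#' @param pseudocount Pseudocount for information content.
#' @param validated Optional `data.frame(group_id, validated)`; when given,
#'   consensus models are built from validated groups only.
#' @return A list of class `rare_run` with `hits`, `annotated`, `groups`,
#'   `consensus` (named by DR class), `windows`.
#' @export
run_full <- function(sequences, genes, patterns = canonical_rare_pattern(),
                     up = 20000L, down = 20000L,
                     criteria = conservation_criteria(),
                     theta = 0, pseudocount = 0, validated = NULL,
                     strand_mode = c("both", "plus"),
                     masked_policy = c("match", "skip"), out_dir = NULL) {
  strand_mode <- match.arg(strand_mode)
  masked_policy <- match.arg(masked_policy)
  if (length(unique(sequences$species)) < 2L) {
    stop("the conservation stage needs sequences from at least 2 species",
         call. = FALSE)
  }
  hits <- run_scan(sequences, genes, patterns, up, down, strand_mode,
                   masked_policy, out_dir = out_dir)
  windows <- attr(hits, "windows")
  annotated <- annotate_hits(hits, genes, windows = windows)
  groups <- find_conserved(annotated, criteria)

  cons_groups <- groups
  if (!is.null(validated) && nrow(groups)) {
    ok_ids <- validated$group_id[as.logical(validated$validated)]
    cons_groups <- groups[groups$group_id %in% ok_ids, , drop = FALSE]
  }
  consensus <- list()
  if (nrow(cons_groups)) {
    for (cls in sort(unique(cons_groups$dr_class))) {
      sites <- cons_groups$element[cons_groups$dr_class == cls]
      consensus[[cls]] <- build_consensus(sites, theta = theta)
    }
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_hits_tsv(annotated, file.path(out_dir, "annotated.tsv"),
                   "# distance convention: bases strictly between the element edge nearest the ATG and its first base")
    write_hits_tsv(groups, file.path(out_dir, "conserved_groups.tsv"),
                   sprintf("# stringency: %s; position tolerance: %g",
                           criteria$sequence_stringency,
                           criteria$position_tolerance))
    for (cls in names(consensus)) {
      m <- consensus[[cls]]
      utils::write.table(
        m$counts, file.path(out_dir, paste0("consensus_", cls, "_counts.tsv")),
        sep = "\t", quote = FALSE, col.names = FALSE)
      writeLines(m$iupac, file.path(out_dir, paste0("consensus_", cls, ".txt")))
      utils::write.table(
        data.frame(position = seq_len(m$length),
                   bits = information_content(m, pseudocount)),
        file.path(out_dir, paste0("consensus_", cls, "_ic.tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    config <- list(patterns = vapply(if (inherits(patterns, "dr_pattern"))
      list(patterns) else patterns, function(p) p$name, character(1)),
      up = up, down = down, strand_mode = strand_mode,
      masked_policy = masked_policy,
      criteria = unclass(criteria), theta = theta,
      pseudocount = pseudocount)
    yaml::write_yaml(c(config,
                       list(version = .pkg_version(),
                            config_hash = .config_hash(config))),
                     file.path(out_dir, "manifest.yaml"))
  }
  structure(list(hits = hits, annotated = annotated, groups = groups,
                 consensus = consensus, windows = windows),
            class = "rare_run")
}

#' @export
print.rare_run <- function(x, ...) {
  cat(sprintf("<rare_run> %d hits in %d species; %d conserved groups\n",
              nrow(x$hits), length(unique(x$hits$species)),
              length(unique(x$groups$group_id))))
  if (nrow(x$groups)) {
    tally <- table(x$groups$dr_class[!duplicated(x$groups$group_id)])
    cat("  class tally:",
        paste(sprintf("%s=%d", names(tally), as.integer(tally)),
              collapse = ", "), "\n")
  }
  for (cls in names(x$consensus)) {
    cat(sprintf("  %s consensus: %s\n", cls, x$consensus[[cls]]$iupac))
  }
  invisible(x)
}

#' Published cross-taxa DR elements around CYP26 genes
#'
#' The ten elements reported with the DR5 signature `AGTTCA(N)5AGTTCA` (and
#' the sea-urchin DR2 variant) in the vicinity of deuterostome CYP26 genes,
#' with their orientation relative to the gene and distance to its start
#' codon. Useful as a literal fixture: each sequence contains exactly its
#' own element.
#'
#' @return A `data.frame` with columns `species, element_name, orientation,
#'   sequence, upstream_of, distance_bp`.
#' @export
cyp26_reference_elements <- function() {
  data.frame(
    species = c("S.purpuratus", "S.kowalevskii", "B.floridae", "B.belcheri",
                "B.lanceolatum", "H.sapiens", "M.musculus", "D.rerio",
                "D.rerio", "T.rubripes"),
    element_name = c("DR2", "DR5", "DR5-6", "DR5-6", "DR5-6", "R1", "R1",
                     "R1", "R2", "R1"),
    orientation = c("+", "-", "-", "-", "-", "-", "-", "-", "-", "-"),
    sequence = c("AGTTCAATAGTTCA", "AGTTCATACCCAGTTCA", "AGTTCAACAAAAGTTCA",
                 "AGTTCAACAAAAGTTCA", "AGTTCAACAAAAGTTCA",
                 "AGTTCACCCAAAGTTCA", "AGTTCACCCAAAGTTCA",
                 "AGTTCACACAAAGTTCA", "AGTTCAAGGATAGTTCA",
                 "AGTTCATTCAAAGTTCA"),
    upstream_of = c("CYP26", "CYP26a", "CYP26-2", "CYP26-2", "CYP26-2",
                    "CYP26A1", "CYP26A1", "CYP26A1", "CYP26A1", "CYP26A1"),
    distance_bp = c(2503L, 137L, 6405L, 6740L, 4083L, 132L, 134L, 166L,
                    1963L, 103L),
    stringsAsFactors = FALSE)
}
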