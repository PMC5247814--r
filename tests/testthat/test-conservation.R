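# one annotated-hit row for constructing pairwise test cases
ann_row <- function(species, element = "AGTTCAACAAAAGTTCA", spacer_len = 5L,
                    comp = "I1.2", norm = 0.5, orient = "-", start = 1000L) {
  data.frame(species = species, seq_id = paste0(species, "_c"),
             start = start, end = start + nchar(element), strand = "-",
             pattern_name = "canonical-RARE",
             dr_class = paste0("DR", spacer_len), spacer_length = spacer_len,
             half_site_1 = substr(element, 1, 6),
             spacer = substr(element, 7, 6 + spacer_len),
             half_site_2 = substr(element, 7 + spacer_len,
                                  12 + spacer_len),
             compartment = comp, compartment_key = comp,
             comp_index = 2L, norm_pos = norm, cluster_orientation = orient,
             stringsAsFactors = FALSE)
}

test_that("pairwise matching applies each criterion gate", {
  crit <- conservation_criteria()
  a <- ann_row("sp1")
  expect_true(elements_match(a, ann_row("sp2"), crit))
  expect_false(elements_match(a, ann_row("sp2", comp = "I2.3"), crit))
  expect_false(elements_match(a, ann_row("sp2", orient = "+"), crit))
  expect_false(elements_match(a, ann_row("sp2", norm = 0.8), crit))
  expect_true(elements_match(a, ann_row("sp2", norm = 0.8),
                             conservation_criteria(position_tolerance = 0.4)))
  # class mismatch dominates every other setting
  expect_false(elements_match(a, ann_row("sp2", element = "AGTTCAATAGTTCA",
                                         spacer_len = 2L),
                              conservation_criteria(
                                sequence_stringency = "class-only",
                                require_same_compartment = FALSE,
                                require_same_orientation = FALSE,
                                position_tolerance = 1)))

  # spacer sequence free at the intermediate stringency
  b <- ann_row("sp2", element = "AGTTCAGGGGGAGTTCA")
  expect_false(elements_match(a, b, crit))
  expect_true(elements_match(a, b, conservation_criteria(
    sequence_stringency = "half-sites-and-spacer-length")))

  bare <- a[, !(names(a) %in% c("compartment_key", "norm_pos"))]
  expect_error(elements_match(bare, b, crit), "annotate")
})

test_that("conserved groups recover the planted truth on the benchmark", {
  set <- generate_cluster_set(small_spec())
  res <- suppressMessages(run_full(set$sequences, set$genes))
  groups <- res$groups
  n_groups <- length(unique(groups$group_id))
  truth_cons <- set$truth[set$truth$conserved, ]
  expect_equal(n_groups, 16L)
  tally <- table(groups$dr_class[!duplicated(groups$group_id)])
  expect_equal(as.integer(tally[c("DR5", "DR2", "DR3")]), c(13L, 1L, 2L))

  got <- paste(groups$species, groups$start, groups$end, groups$strand)
  want <- paste(truth_cons$species, truth_cons$start, truth_cons$end,
                truth_cons$strand)
  expect_setequal(got, want)

  # exact-element stringency: members of a group are letter-identical
  for (g in unique(groups$group_id)) {
    expect_equal(length(unique(groups$element[groups$group_id == g])), 1L)
  }
})

test_that("grouping is invariant under species input order", {
  set <- generate_cluster_set(small_spec())
  ann <- annotate_hits(
    suppressMessages(run_scan(set$sequences, set$genes)),
    set$genes, windows = set$windows)
  canonical <- NULL
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  sp <- unique(ann$species)
  for (p in perms) {
    shuffled <- do.call(rbind, lapply(sp[p], function(s)
      ann[ann$species == s, , drop = FALSE]))
    g <- find_conserved(shuffled)
    key <- sort(paste(g$group_id, g$species, g$start, g$end))
    if (is.null(canonical)) canonical <- key else expect_identical(key, canonical)
  }
})

test_that("tightening criteria never increases the number of groups", {
  set <- generate_cluster_set(small_spec())
  ann <- annotate_hits(
    suppressMessages(run_scan(set$sequences, set$genes)),
    set$genes, windows = set$windows)
  n_of <- function(crit) {
    length(unique(find_conserved(ann, crit)$group_id))
  }
  loose <- conservation_criteria(sequence_stringency = "class-only",
                                 require_same_compartment = FALSE,
                                 require_same_orientation = FALSE,
                                 position_tolerance = 1)
  chain <- list(
    loose,
    conservation_criteria(sequence_stringency = "class-only",
                          position_tolerance = 1),
    conservation_criteria(sequence_stringency = "half-sites-and-spacer-length",
                          position_tolerance = 1),
    conservation_criteria(sequence_stringency = "exact-element",
                          position_tolerance = 1),
    conservation_criteria(sequence_stringency = "exact-element",
                          position_tolerance = 0.25),
    conservation_criteria(sequence_stringency = "exact-element",
                          position_tolerance = 0.02))
  counts <- vapply(chain, n_of, integer(1))
  expect_true(all(diff(counts) <= 0L))
})

test_that("a species without hits yields no all-species groups", {
  a <- ann_row("sp1"); b <- ann_row("sp2")
  both <- rbind(a, b)
  expect_message(
    g0 <- find_conserved(both, species = c("sp1", "sp2", "sp3")),
    "zero hits")
  expect_equal(nrow(g0), 0L)
  expect_error(find_conserved(a), "2 species")
  g <- find_conserved(both)
  expect_equal(length(unique(g$group_id)), 1L)
})

test_that("literal signature search matches published elements", {
  seqs <- data.frame(
    species = c("S.k", "H.s", "S.p"),
    seq_id = c("r1", "r2", "r3"),
    residues = c("AGTTCATACCCAGTTCA", "AGTTCACCCAAAGTTCA", "AGTTCAATAGTTCA"),
    stringsAsFactors = FALSE)
  h5 <- signature_search(seqs, dr_signature(5))
  expect_equal(nrow(h5[h5$species == "S.k", ]), 1L)
  expect_equal(nrow(h5[h5$species == "H.s", ]), 1L)
  expect_equal(nrow(h5[h5$species == "S.p", ]), 0L)  # it is a DR2
  h2 <- signature_search(seqs, dr_signature(2))
  expect_equal(nrow(h2[h2$species == "S.p", ]), 1L)
})
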