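test_that("distance to the start codon follows the exclusive-edge convention", {
  gene <- data.frame(gene_id = "g2", strand = "+", start_codon_pos = 5000L,
                     stop_codon_end = 12000L, cluster_rank = 2L,
                     stringsAsFactors = FALSE)
  expect_equal(distance_to_start(900L, 917L, gene), 4083L)
  expect_equal(distance_to_start(4983L, 5000L, gene), 0L)
  expect_error(distance_to_start(6000L, 6017L, gene), "not upstream")

  # minus-strand mirror of the same situation
  L <- 20000L
  gene_m <- data.frame(gene_id = "g2", strand = "-",
                       start_codon_pos = L - 1L - 5000L,
                       stop_codon_end = L - 1L - 12000L, cluster_rank = 2L,
                       stringsAsFactors = FALSE)
  expect_equal(distance_to_start(L - 917L, L - 900L, gene_m), 4083L)
  expect_equal(distance_to_start(L - 5000L, L - 4983L, gene_m), 0L)
})

test_that("compartment assignment partitions the cluster", {
  genes <- toy_genes()
  win <- c(5000L, 113000L)
  expect_match(assign_compartment(40000L, 40017L, genes, win),
               "intergenic\\(gene1,gene2\\)")
  expect_match(assign_compartment(26000L, 26017L, genes, win), "intragenic\\(gene1\\)")
  # straddling a gene-body boundary counts as intragenic (overlap rule)
  expect_match(assign_compartment(24990L, 25007L, genes, win), "intragenic\\(gene1\\)")
  expect_match(assign_compartment(6000L, 6017L, genes, win), "upstream")
  expect_match(assign_compartment(100000L, 100017L, genes, win), "downstream")
  # abutting a body exactly is not overlap
  expect_match(assign_compartment(24983L, 25000L, genes, win), "upstream")
  expect_warning(out <- assign_compartment(1000L, 1017L, genes, win),
                 "flanking")
  expect_match(out, "upstream")
})

test_that("compartments are invariant under coordinate translation", {
  genes <- toy_genes()
  win <- c(5000L, 113000L)
  shift <- 12345L
  genes2 <- genes
  genes2$start_codon_pos <- genes2$start_codon_pos + shift
  genes2$stop_codon_end <- genes2$stop_codon_end + shift
  for (s in c(6000L, 26000L, 40000L, 70000L, 100000L)) {
    expect_identical(assign_compartment(s, s + 17L, genes, win),
                     assign_compartment(s + shift, s + 17L + shift, genes2,
                                        win + shift))
  }
})

test_that("distance decreases exactly with movement toward the start codon", {
  gene <- data.frame(gene_id = "g", strand = "+", start_codon_pos = 9000L,
                     stop_codon_end = 15000L, cluster_rank = 1L,
                     stringsAsFactors = FALSE)
  d0 <- distance_to_start(1000L, 1017L, gene)
  for (delta in c(1L, 10L, 500L)) {
    expect_equal(distance_to_start(1000L + delta, 1017L + delta, gene),
                 d0 - delta)
  }
  expect_true(all(vapply(c(0L, 1L, 100L), function(dd)
    distance_to_start(9000L - 17L - dd, 9000L - dd, gene), integer(1)) >= 0L))
})

test_that("orientation is relative to the cluster axis", {
  expect_identical(cluster_orientation("+", "+"), "+")
  expect_identical(cluster_orientation("+", "-"), "-")
  expect_identical(cluster_orientation("-", "-"), "+")
  # a planted pair on opposite strands gets opposite signs
  expect_false(cluster_orientation("+", "+") == cluster_orientation("-", "+"))
})

test_that("full annotation joins compartment, nearest gene, and distance", {
  genes <- toy_genes()
  residues <- strrep("T", 120000)
  residues <- plant_element(residues, "AGTTCAACAAAAGTTCA", 50917L - 17L, "-")
  residues <- plant_element(residues, "AGTTCAATAGTTCA", 26000L, "+")
  hits <- scan_sequence(residues, seq_id = "chr", species = "sp1")
  ann <- annotate_hits(hits, genes, windows = c(5000L, 113000L))
  expect_equal(nrow(ann), 2L)
  intra <- ann[ann$dr_class == "DR2", ]
  expect_match(intra$compartment, "intragenic\\(gene1\\)")
  expect_identical(intra$nearest_downstream_gene, "gene2")
  ig <- ann[ann$dr_class == "DR5", ]
  expect_match(ig$compartment, "intergenic\\(gene1,gene2\\)")
  expect_identical(ig$nearest_downstream_gene, "gene2")
  expect_equal(ig$distance_to_start_codon, 55000L - 50917L)
  expect_identical(ig$cluster_orientation, "-")
  expect_true(ig$norm_pos > 0 && ig$norm_pos < 1)
})

test_that("annotating a reflected cluster reflects the annotation", {
  genes <- toy_genes(species = "s")
  L <- 120000L
  residues <- strrep("T", L)
  residues <- plant_element(residues, "AGTTCAACAAAAGTTCA", 45000L, "+")
  residues <- plant_element(residues, "AGTTCAATAGTTCA", 99000L, "-")
  win <- c(5000L, 113000L)
  ann <- annotate_hits(scan_sequence(residues, seq_id = "chr", species = "s"),
                       genes, windows = win)

  genes_r <- genes
  genes_r$strand <- "-"
  genes_r$start_codon_pos <- L - 1L - genes$start_codon_pos
  genes_r$stop_codon_end <- L - 1L - genes$stop_codon_end
  res_r <- reverse_complement(residues)
  ann_r <- annotate_hits(scan_sequence(res_r, seq_id = "chr", species = "s"),
                         genes_r, windows = c(L - win[2], L - win[1]))
  expect_equal(nrow(ann_r), nrow(ann))
  ann_r$map_start <- L - ann_r$end
  ann_r <- ann_r[order(ann_r$map_start), ]
  ann <- ann[order(ann$start), ]
  expect_equal(ann_r$map_start, ann$start)
  expect_identical(ann_r$compartment_key, ann$compartment_key)
  expect_identical(ann_r$cluster_orientation, ann$cluster_orientation)
  expect_identical(ann_r$nearest_downstream_gene, ann$nearest_downstream_gene)
  expect_equal(ann_r$distance_to_start_codon, ann$distance_to_start_codon)
  expect_equal(ann_r$norm_pos, ann$norm_pos, tolerance = 1e-9)
})
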