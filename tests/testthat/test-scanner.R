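test_that("single planted elements are found with correct read-out", {
  h <- scan_sequence("AGTTCAACAAAAGTTCA")
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, 0L)
  expect_equal(h$end, 17L)
  expect_identical(h$strand, "+")
  expect_identical(h$dr_class, "DR5")
  expect_identical(h$spacer, "ACAAA")
  expect_identical(h$half_site_1, "AGTTCA")

  h2 <- scan_sequence("AGTTCAATAGTTCA")
  expect_equal(nrow(h2), 1L)
  expect_identical(h2$dr_class, "DR2")
  expect_identical(h2$spacer, "AT")

  expect_equal(nrow(scan_sequence(strrep("A", 20))), 0L)
})

test_that("overlapping and nested matches are all enumerated", {
  h <- scan_sequence("AGTTCAAGTTCAAGTTCA")
  expect_equal(nrow(h), 3L)
  expect_equal(h$start, c(0L, 0L, 6L))
  expect_equal(h$end, c(12L, 18L, 18L))
  expect_identical(h$dr_class, c("DR0", "DR6", "DR0"))
  expect_true(all(h$strand == "+"))
})

test_that("hit set equals the brute-force regex oracle on random sequences", {
  set.seed(101)
  for (i in 1:30) {
    s <- rand_seq(2000, gc = sample(c(0.3, 0.5, 0.7), 1))
    mine <- scan_sequence(s)
    expect_identical(hit_key(mine), hit_key(oracle_scan(s)))
  }
})

test_that("minus-strand hits correspond to plus hits on the reverse complement", {
  set.seed(202)
  for (i in 1:20) {
    s <- rand_seq(1500, gc = 0.45)
    L <- nchar(s)
    fwd <- scan_sequence(s)
    rev <- scan_sequence(reverse_complement(s))
    plus_on_rc <- rev[rev$strand == "+", ]
    minus_on_s <- fwd[fwd$strand == "-", ]
    mapped <- paste(L - plus_on_rc$end, L - plus_on_rc$start, "-")
    expect_setequal(mapped, paste(minus_on_s$start, minus_on_s$end, "-"))
    # read-out strings also correspond
    expect_setequal(
      paste0(plus_on_rc$half_site_1, plus_on_rc$spacer, plus_on_rc$half_site_2),
      paste0(minus_on_s$half_site_1, minus_on_s$spacer, minus_on_s$half_site_2))
  }
})

test_that("every hit reconstructs the genomic substring", {
  set.seed(303)
  s <- rand_seq(50000, gc = 0.4)
  s <- plant_element(s, "AGTTCAACAAAAGTTCA", 1000L, "+")
  s <- plant_element(s, "AGTTCAATAGTTCA", 20000L, "-")
  h <- scan_sequence(s)
  expect_gte(nrow(h), 2L)
  for (i in seq_len(nrow(h))) {
    sub <- substr(s, h$start[i] + 1L, h$end[i])
    elt <- paste0(h$half_site_1[i], h$spacer[i], h$half_site_2[i])
    expect_identical(if (h$strand[i] == "-") reverse_complement(sub) else sub,
                     elt)
    expect_equal(h$end[i] - h$start[i], 12L + h$spacer_length[i])
    expect_identical(h$dr_class[i], paste0("DR", h$spacer_length[i]))
  }
})

test_that("spacer-range and window monotonicity hold", {
  set.seed(404)
  s <- rand_seq(8000, gc = 0.45)
  wide <- scan_sequence(s, parse_iupac_pattern("RGKTCA", "N{0,9}", "RGKTCA"))
  narrow <- scan_sequence(s, parse_iupac_pattern("RGKTCA", "N{2,5}", "RGKTCA"))
  expect_true(all(hit_key(narrow) %in% hit_key(wide)))

  full <- scan_sequence(s)
  win <- scan_sequence(s, window = c(1000L, 5000L))
  expect_true(all(hit_key(win) %in% hit_key(full)))
  expect_true(all(win$start >= 1000L & win$end <= 5000L))
  expect_error(scan_sequence(s, window = c(-1L, 50L)), "window")
})

test_that("soft-masked and N residues follow the configured policies", {
  s <- paste0(strrep("t", 30), "agttcaacaaaagttca", strrep("t", 30))
  expect_equal(nrow(scan_sequence(s)), 1L)
  expect_equal(nrow(scan_sequence(s, masked_policy = "skip")), 0L)

  # N in the wildcard spacer matches; N in a half-site never does
  expect_equal(nrow(scan_sequence("AGTTCANNNNNAGTTCA")), 1L)
  expect_equal(nrow(scan_sequence("NGTTCAACAAAAGTTCA")), 0L)
  expect_error(scan_sequence("AGTTCA-ACAAAAGTTCA"), "alphabet")
})

test_that("collections attach provenance and reject duplicates", {
  seqs <- data.frame(
    species = c("sp1", "sp2"), seq_id = c("c1", "c2"),
    residues = c(paste0(strrep("T", 10), "AGTTCAACAAAAGTTCA", strrep("T", 10)),
                 paste0(strrep("T", 5), "AGTTCAATAGTTCA", strrep("T", 5))),
    stringsAsFactors = FALSE)
  h <- scan_collection(seqs)
  expect_equal(nrow(h), 2L)
  expect_identical(h$species, c("sp1", "sp2"))
  expect_identical(h$dr_class, c("DR5", "DR2"))

  expect_equal(nrow(scan_collection(seqs[0, ])), 0L)
  dup <- rbind(seqs, seqs[1, ])
  expect_error(scan_collection(dup), "duplicate")
})

test_that("the survey window spans the cluster plus flanks, clamped", {
  genes <- toy_genes(lo = c(25000L, 55000L, 87000L), width = 8000L)
  expect_equal(cluster_window(genes, 20000, 20000, 130000),
               c(5000L, 115000L))
  genes2 <- toy_genes(lo = c(10000L, 40000L, 70000L), width = 8000L)
  expect_equal(cluster_window(genes2, 20000, 20000, 90000),
               c(0L, 90000L))
  expect_error(cluster_window(genes[0, ], 20000, 20000, 130000), "empty")
})
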