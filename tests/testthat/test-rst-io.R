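test_that("program detection recognizes both dialects and rejects junk", {
  fx_c <- sim_fixture(tips = 4, length_codons = 20, seed = 1, dialect = "codeml")
  fx_b <- sim_fixture(tips = 4, length_codons = 20, seed = 1, dialect = "baseml")
  expect_identical(detect_program(fx_c$rst), "codeml")
  expect_identical(detect_program(fx_b$rst), "baseml")
  expect_error(detect_program(character()), class = "pamlsubs_unrecognized_format")
  expect_error(detect_program(""), class = "pamlsubs_unrecognized_format")
  expect_error(detect_program(c("just", "some", "text")),
               class = "pamlsubs_unrecognized_format")
})

test_that("parsing recovers every simulated change record", {
  fx <- sim_fixture(tips = 6, length_codons = 40, events_per_branch = 4,
                    seed = 21)
  doc <- parse_rst(fx$rst)
  expect_s3_class(doc, "rst_document")
  expect_equal(doc$alignment_length, 120L)
  expect_equal(nrow(doc$changes), nrow(fx$log$events))
  expect_equal(nrow(doc$branches), nrow(fx$log$tree$edge))
  # branch count for a rooted binary tree: 2n - 2
  expect_equal(nrow(doc$branches), 2L * nrow(doc$taxa) - 2L)
  # all sequences same length, pure ACGT
  expect_true(all(nchar(unlist(doc$node_sequences)) == doc$alignment_length))
  expect_false(any(grepl("[^ACGT]", unlist(doc$node_sequences))))
  # every branch's parent is an internal node present in the tree
  expect_true(all(doc$branches$parent > nrow(doc$taxa)))
  edge_key <- paste(doc$tree$edge[, 1], doc$tree$edge[, 2])
  expect_setequal(paste(doc$branches$parent, doc$branches$child), edge_key)
})

test_that("gap and ambiguity characters abort parsing", {
  fx <- sim_fixture(tips = 4, length_codons = 20, seed = 4)
  gapped <- sub("^(t1\\s+)([ACGT])", "\\1-", fx$rst)
  expect_error(parse_rst(gapped), class = "pamlsubs_gap_error")
  ambig <- sub("^(t1\\s+)([ACGT])", "\\1N", fx$rst)
  expect_error(parse_rst(ambig), class = "pamlsubs_gap_error")
})

test_that("a codeml alignment whose length is not a multiple of 3 is a frame error", {
  fx <- sim_fixture(tips = 4, length_codons = 20, events_per_branch = 0,
                    seed = 5)
  # drop two trailing bases from every sequence line -> length 58
  broken <- fx$rst
  seq_lines <- grepl("^(t\\d+|node #\\d+)\\s+[ACGT]+$", broken)
  broken[seq_lines] <- substr(broken[seq_lines], 1L,
                              nchar(broken[seq_lines]) - 2L)
  expect_error(parse_rst(broken), class = "pamlsubs_frame_error")
})

test_that("malformed change lines report a structured error; stray lines only warn", {
  fx <- sim_fixture(tips = 4, length_codons = 20, events_per_branch = 3,
                    seed = 6)
  i <- grep("->", fx$rst)[1]
  bad <- fx$rst
  bad[i] <- "      12 AXT (?) zzz -> ACC"
  expect_error(parse_rst(bad), class = "pamlsubs_malformed_block")
  stray <- append(fx$rst, "some PAML chatter we do not model",
                  after = grep("Summary of changes", fx$rst))
  expect_warning(doc <- parse_rst(stray), class = "pamlsubs_skipped_line")
  expect_equal(nrow(doc$changes), nrow(fx$log$events))
})

test_that("write/parse round trip preserves tree, sequences and events in both dialects", {
  set.seed(99)
  seeds <- sample.int(10000, 8)
  for (dialect in c("codeml", "baseml")) {
    for (s in seeds) {
      log <- simulate_substitutions(tips = sample(3:8, 1),
                                    length_codons = sample(10:40, 1),
                                    events_per_branch = sample(0:6, 1),
                                    seed = s)
      doc <- parse_rst(write_rst(log, dialect))
      expect_equal(doc$alignment_length, log$alignment_length)
      expect_identical(doc$taxa$name, log$tree$tip.label)
      expect_equal(doc$node_sequences[order(as.integer(names(doc$node_sequences)))],
                   log$node_sequences[order(as.integer(names(log$node_sequences)))])
      got <- doc$changes[order(doc$changes$parent, doc$changes$child,
                               doc$changes$site), ]
      truth <- sort_events(log$events)
      expect_equal(nrow(got), nrow(truth))
      expect_equal(got$site, truth$site)
      expect_equal(got$from_base, truth$from_base)
      expect_equal(got$to_base, truth$to_base)
      expect_equal(paste(got$parent, got$child), paste(truth$parent, truth$child))
    }
  }
})

test_that("parser is total on the fixture grammar (seeded random fixtures)", {
  set.seed(1234)
  n_trials <- 300L
  for (k in seq_len(n_trials)) {
    dialect <- if (k %% 2L == 0L) "codeml" else "baseml"
    log <- simulate_substitutions(tips = sample(3:6, 1),
                                  length_codons = sample(5:20, 1),
                                  events_per_branch = sample(0:4, 1),
                                  seed = sample.int(.Machine$integer.max, 1))
    expect_no_error(parse_rst(write_rst(log, dialect)))
  }
})

test_that("annotated Newick writing round-trips topology and labels", {
  tr <- ape::read.tree(text = "((t1,t2),t3);")
  nwk <- write_annotated_newick(tr, c(`1` = "one label"))
  expect_equal(lengths(regmatches(nwk, gregexpr("one label", nwk))), 1L)
  rt <- parse_annotated_newick(nwk)
  expect_true(ape::all.equal.phylo(rt$tree, tr, use.edge.length = FALSE))
  expect_setequal(unname(rt$labels), "one label")

  # empty label map -> plain parseable Newick
  plain <- write_annotated_newick(tr)
  expect_false(grepl("[", plain, fixed = TRUE))
  expect_s3_class(ape::read.tree(text = plain), "phylo")

  # labels on absent branches are rejected
  expect_error(write_annotated_newick(tr, c(`99` = "x")),
               class = "pamlsubs_unknown_branch")

  # full annotation round trip on a simulated tree
  log <- simulate_substitutions(tips = 7, length_codons = 30,
                                events_per_branch = 3, seed = 77)
  labels <- setNames(paste0("lab", seq_len(nrow(log$tree$edge))),
                     log$tree$edge[, 2])
  nwk2 <- write_annotated_newick(log$tree, labels)
  rt2 <- parse_annotated_newick(nwk2)
  expect_true(ape::all.equal.phylo(rt2$tree, log$tree,
                                   use.edge.length = FALSE))
  expect_setequal(unname(rt2$labels), unname(labels))
})
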