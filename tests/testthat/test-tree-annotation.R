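test_that("the published annotation example parses and re-formats exactly", {
  p <- parse_annotation("18_1@Ts1_3@Ts2_2@Tv1")
  expect_equal(p$seq_index, 18L)
  expect_equal(p$counts["Ts", 1], 1L)
  expect_equal(p$counts["Ts", 2], 3L)
  expect_equal(p$counts["Tv", 1], 2L)
  expect_equal(sum(p$counts), 6L)
  expect_identical(format_annotation(p$counts, seq_index = p$seq_index),
                   "18_1@Ts1_3@Ts2_2@Tv1")
})

test_that("annotation formatting follows the grammar and rejects empty counts", {
  counts <- matrix(0L, 2, 3, dimnames = list(c("Ts", "Tv"), NULL))
  counts["Tv", 3] <- 1L
  expect_identical(format_annotation(counts, seq_index = 4), "4_1@Tv3")
  expect_error(format_annotation(matrix(0L, 2, 3,
                                        dimnames = list(c("Ts", "Tv"), NULL)),
                                 seq_index = 1),
               class = "pamlsubs_empty_annotation")
  expect_error(parse_annotation("18_@Ts1"), class = "pamlsubs_annotation_syntax")
  expect_error(parse_annotation("x_1@Ts1"), class = "pamlsubs_annotation_syntax")
  expect_error(parse_annotation("18_1@Tz1"), class = "pamlsubs_annotation_syntax")
})

test_that("format and parse are mutual inverses over 1000 random annotations", {
  set.seed(2024)
  for (i in seq_len(1000)) {
    counts <- matrix(rpois(6, 0.8), 2, 3,
                     dimnames = list(c("Ts", "Tv"), paste0("pos", 1:3)))
    if (sum(counts) == 0L) counts[sample(1:2, 1), sample(1:3, 1)] <- 1L
    idx <- sample(1:500, 1)
    txt <- format_annotation(counts, seq_index = idx)
    back <- parse_annotation(txt)
    expect_identical(back$seq_index, idx)
    expect_identical(unname(back$counts), unname(counts))
    expect_identical(format_annotation(back$counts, seq_index = back$seq_index),
                     txt)
  }
})

test_that("branch annotations conserve event counts and match the simulator per branch", {
  fx <- sim_fixture(tips = 9, length_codons = 60, events_per_branch = 6,
                    seed = 61)
  ev <- classify_substitutions(parse_rst(fx$rst))
  ann <- annotate_branches(ev)
  expect_equal(sum(vapply(ann, function(a) sum(a$counts), integer(1))),
               nrow(fx$log$events))
  truth_by_branch <- table(paste(fx$log$events$parent, fx$log$events$child))
  for (a in ann) {
    key <- paste(a$parent, a$child)
    expect_equal(sum(a$counts), unname(unclass(truth_by_branch[key])))
    ns <- fx$log$events[fx$log$events$parent == a$parent &
                          fx$log$events$child == a$child &
                          fx$log$events$effect == "nonsynonymous", ]
    expect_setequal(a$aa_changes, paste0(ns$from_aa, ns$codon_index, ns$to_aa))
    expect_setequal(a$nt_changes,
                    paste0(tolower(ns$from_base), ns$site, tolower(ns$to_base)))
  }
  # single event on a tip branch: one annotation keyed by the tip index
  one <- ev[1, , drop = FALSE]
  attr(one, "tree") <- attr(ev, "tree")
  class(one) <- class(ev)
  a1 <- annotate_branches(one)
  expect_length(a1, 1L)
  expect_equal(a1[[1]]$seq_index, one$child)
  expect_equal(sum(a1[[1]]$counts), 1L)
  # no events -> no annotations
  empty <- ev[0, , drop = FALSE]
  attr(empty, "tree") <- attr(ev, "tree")
  class(empty) <- class(ev)
  expect_length(annotate_branches(empty), 0L)
})

test_that("highlighting selects branches by class, position and count", {
  fx <- sim_fixture(tips = 8, length_codons = 50, events_per_branch = 6,
                    seed = 67)
  ev <- classify_substitutions(parse_rst(fx$rst))
  ann <- annotate_branches(ev)
  hits <- highlight_branches(ann, class = "Ts", position = 2, min_count = 1)
  truth <- unique(ev$child[ev$class == "Ts" & ev$codon_position == 2])
  expect_setequal(hits, truth)
  expect_length(highlight_branches(ann, min_count = 1e9), 0L)
  expect_setequal(highlight_branches(ann, min_count = 1),
                  vapply(ann, `[[`, integer(1), "child"))
})

test_that("the two exported trees carry amino-acid and nucleotide change labels", {
  fx <- sim_fixture(tips = 7, length_codons = 50, events_per_branch = 6,
                    seed = 71)
  ev <- classify_substitutions(parse_rst(fx$rst))
  ann <- annotate_branches(ev)
  out <- withr::local_tempdir()
  paths <- export_trees(ann, out_dir = out)
  expect_length(paths, 2L)
  expect_true(all(file.exists(paths)))
  aa <- readLines(paths[1])
  rt <- parse_annotated_newick(aa, attr_name = "aa")
  expect_true(ape::all.equal.phylo(rt$tree, attr(ev, "tree"),
                                   use.edge.length = FALSE))
  logged_aa <- with(fx$log$events[fx$log$events$effect == "nonsynonymous", ],
                    paste0(from_aa, codon_index, to_aa))
  exported_aa <- unlist(strsplit(unname(rt$labels), ","))
  expect_equal(sort(exported_aa), sort(logged_aa))

  # a run with zero nonsynonymous events leaves the nucleotide tree unlabeled
  syn <- ev[ev$effect == "synonymous", , drop = FALSE]
  attr(syn, "tree") <- attr(ev, "tree")
  class(syn) <- class(ev)
  paths2 <- export_trees(annotate_branches(syn), out_dir = out)
  expect_false(grepl("[&nt=", readLines(paths2[2]), fixed = TRUE))
})
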