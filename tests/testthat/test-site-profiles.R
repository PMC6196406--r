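test_that("per-site tallies count events by category", {
  ev <- manual_events(site = c(10, 10, 10), category = c("As", "As", "Ba"),
                      length = 30)
  prof <- site_counts(ev)
  expect_equal(unname(prof$counts[10, "As"]), 2L)
  expect_equal(unname(prof$counts[10, "Ba"]), 1L)
  expect_equal(sum(prof$counts), 3L)
  expect_equal(sum(prof$ts) + sum(prof$tv), 3L)
  expect_equal(sum(prof$type_position), 3L)

  empty <- manual_events(integer(), character(), length = 30)
  expect_equal(sum(site_counts(empty)$counts), 0L)

  out_of_range <- manual_events(31, "As", length = 30)
  expect_error(site_counts(out_of_range), class = "pamlsubs_site_range")
})

test_that("per-site profile totals equal the simulator's category totals", {
  fx <- sim_fixture(tips = 8, length_codons = 70, events_per_branch = 7,
                    seed = 31)
  ev <- classify_substitutions(parse_rst(fx$rst))
  prof <- site_counts(ev)
  truth <- table(factor(fx$log$events$category, c("As", "Bs", "Aa", "Ba")))
  expect_equal(colSums(prof$counts), unclass(truth)[colnames(prof$counts)],
               ignore_attr = TRUE)
  expect_equal(sum(prof$counts), nrow(fx$log$events))
  # Ts/Tv by position grand total equals the same count
  expect_equal(sum(prof$type_position), nrow(fx$log$events))
})

test_that("window means are plain arithmetic means with trailing partial windows dropped", {
  ev <- manual_events(site = c(1, 3, 3), category = c("As", "As", "As"),
                      length = 9)
  prof <- site_counts(ev)
  w <- sliding_windows(prof, window = 3, step = 3)
  expect_equal(w$start, c(1L, 4L, 7L))
  expect_equal(w$As[1], 1.0)  # sites 1-3 hold counts 1, 0, 2
  expect_equal(w$As[2:3], c(0, 0))

  # window = length: single window of genome-wide means
  w1 <- sliding_windows(prof, window = 9, step = 3)
  expect_equal(nrow(w1), 1L)
  expect_equal(w1$As, sum(prof$counts[, "As"]) / 9)

  expect_error(sliding_windows(prof, window = 2, step = 1),
               class = "pamlsubs_window_error")
  expect_error(sliding_windows(prof, window = 10, step = 1),
               class = "pamlsubs_window_error")
  expect_error(sliding_windows(prof, window = 3, step = 0),
               class = "pamlsubs_window_error")
})

test_that("non-overlapping window means recombine to the genome-wide mean", {
  fx <- sim_fixture(tips = 6, length_codons = 60, events_per_branch = 8,
                    seed = 37)
  prof <- site_counts(classify_substitutions(parse_rst(fx$rst)))
  w <- sliding_windows(prof, window = 30, step = 30)  # tiles the alignment
  for (cat in c("As", "Bs", "Aa", "Ba")) {
    expect_equal(mean(w[[cat]]), sum(prof$counts[, cat]) / prof$length)
  }
  # conservation: summed window totals recover Kt when step = window
  expect_equal(sum((w$dS + w$dN) * 30), sum(prof$counts))
})

test_that("dN/dS is a guarded ratio: 0, 1 and undefined where dS = 0", {
  ev <- manual_events(site = c(2, 5), category = c("As", "Aa"), length = 6)
  w <- sliding_windows(site_counts(ev), window = 3, step = 3)
  expect_equal(dn_ds(w), w$dNdS)
  # dN = 0, dS > 0 -> 0
  expect_equal(w$dNdS[1], 0)
  # dN > 0, dS = 0 -> undefined marker (NA), never Inf
  expect_true(is.na(w$dNdS[2]))
  expect_false(any(is.infinite(dn_ds(w)), na.rm = TRUE))
  # dN = dS > 0 -> 1
  ev2 <- manual_events(site = c(1, 2), category = c("As", "Aa"), length = 3)
  w2 <- sliding_windows(site_counts(ev2), window = 3, step = 1)
  expect_equal(w2$dNdS, 1)
})

test_that("cumulative curves are nondecreasing prefix sums ending at the event total", {
  fx <- sim_fixture(tips = 7, length_codons = 50, events_per_branch = 6,
                    seed = 41)
  ev <- classify_substitutions(parse_rst(fx$rst))
  prof <- site_counts(ev)
  cum <- cumulative_series(prof, step = 7)
  for (col in c("As", "Bs", "Aa", "Ba", "Kt")) {
    expect_true(all(diff(cum[[col]]) >= 0))
  }
  expect_equal(cum$Kt, cum$As + cum$Bs + cum$Aa + cum$Ba)
  expect_equal(cum$Kt[nrow(cum)], nrow(ev))
  # direct prefix-sum oracle over the raw event sites
  for (p in cum$position) {
    expect_equal(cum$Kt[cum$position == p], sum(fx$log$events$site <= p))
  }
  # all-zero profile -> flat zero series
  prof0 <- site_counts(manual_events(integer(), character(), length = 30))
  cum0 <- cumulative_series(prof0, step = 10)
  expect_true(all(cum0$Kt == 0))
  expect_error(cumulative_series(prof, step = 0), class = "pamlsubs_window_error")
})

test_that("changing window and step never mutates the profile", {
  fx <- sim_fixture(tips = 5, length_codons = 40, events_per_branch = 5,
                    seed = 43)
  prof <- site_counts(classify_substitutions(parse_rst(fx$rst)))
  before <- unserialize(serialize(prof, NULL))
  invisible(sliding_windows(prof, window = 12, step = 4))
  invisible(sliding_windows(prof, window = 30, step = 10))
  invisible(cumulative_series(prof, step = 5))
  expect_identical(prof, before)
})
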