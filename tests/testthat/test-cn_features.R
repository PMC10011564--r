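toy_arm_map <- function() {
  arm_map_from_lengths(c(chrA = 50e6, chrB = 30e6))
}

seg_tbl <- function(...) {
  rows <- list(...)
  tibble::as_tibble(do.call(rbind, lapply(rows, function(r) {
    data.frame(chrom = r[[1]], start = as.integer(r[[2]]),
               end = as.integer(r[[3]]), total_cn = as.integer(r[[4]]),
               major_cn = as.integer(r[[5]]), minor_cn = as.integer(r[[6]]))
  })))
}

test_that("breakpoints per 10 Mb exclude terminal endpoints", {
  am <- toy_arm_map()
  # one whole-chromosome segment: no breaks anywhere -> bin 0 = all windows
  seg <- seg_tbl(list("chrA", 1, 50e6, 2, 1, 1), list("chrB", 1, 30e6, 2, 1, 1))
  h <- breakpoints_per_10mb(seg, am)
  expect_equal(unname(h["BCper10Mb_0"]), 8)  # 5 + 3 windows
  expect_equal(sum(h), 8)
  # 3 segments ending in one window: two counted, terminal excluded
  seg <- seg_tbl(list("chrA", 1, 2e6, 2, 1, 1), list("chrA", 2e6 + 1, 5e6, 3, 2, 1),
                 list("chrA", 5e6 + 1, 50e6, 2, 1, 1))
  h <- breakpoints_per_10mb(seg, am)
  expect_equal(unname(h["BCper10Mb_2"]), 1)
  expect_error(breakpoints_per_10mb(
    seg_tbl(list("chrA", 1, 60e6, 2, 1, 1)), am), "beyond chromosome end")
})

test_that("breaks per arm count overlapping segments minus one", {
  am <- toy_arm_map()
  seg <- seg_tbl(list("chrA", 1, 50e6, 2, 1, 1), list("chrB", 1, 30e6, 2, 1, 1))
  h <- breaks_per_arm(seg, am)
  expect_equal(unname(h["BCperCA_0"]), 4)  # one segment overlaps both arms
  # 4 segments in one arm -> 3 breaks; straddler counted in both arms
  seg <- seg_tbl(list("chrA", 1, 5e6, 2, 1, 1), list("chrA", 5e6 + 1, 10e6, 3, 2, 1),
                 list("chrA", 10e6 + 1, 15e6, 2, 1, 1),
                 list("chrA", 15e6 + 1, 50e6, 4, 3, 1))
  h <- breaks_per_arm(seg, toy_arm_map())
  # p arm (1..20Mb): 4 segments -> 3 breaks; q arm: 1 segment -> 0
  expect_equal(unname(h["BCperCA_3"]), 1)
  expect_equal(unname(h["BCperCA_0"]), 3)  # q of chrA + both arms of chrB
})

test_that("copy-state counts and fractions follow definitions", {
  seg <- seg_tbl(list("chrA", 1, 10e6, 2, 1, 1), list("chrA", 10e6 + 1, 20e6, 2, 1, 1),
                 list("chrA", 20e6 + 1, 30e6, 12, 11, 1))
  counts <- cn_state_counts(seg)
  expect_equal(unname(counts["CN_2"]), 2)
  expect_equal(unname(counts["CN_8+"]), 1)
  cf <- copy_fraction(seg)
  expect_equal(unname(cf["CopyFraction_2"]), 2 / 3, tolerance = 1e-9)
  expect_equal(sum(cf), 1, tolerance = 1e-9)
  # two equal-length segments at 2 and 4 -> 0.5 / 0.5
  seg2 <- seg_tbl(list("chrA", 1, 1e6, 2, 1, 1), list("chrA", 1e6 + 1, 2e6, 4, 2, 2))
  cf2 <- copy_fraction(seg2)
  expect_equal(unname(cf2[c("CopyFraction_2", "CopyFraction_4")]), c(0.5, 0.5))
  expect_equal(sum(copy_fraction(seg2[0, ])), 0)
})

test_that("segment sizes histogram into the documented bins", {
  seg <- seg_tbl(list("chrA", 1, 100e6, 2, 1, 1),    # 100 Mb -> SegSize_10
                 list("chrB", 1, 4e3, 2, 1, 1),      # 4 kb -> SegSize_1
                 list("chrB", 1e6, 16e6, 2, 1, 1))   # ~15 Mb -> SegSize_8
  h <- segment_size_features(seg)
  expect_equal(unname(h[c("SegSize_10", "SegSize_1", "SegSize_8")]),
               c(1, 1, 1))
  expect_equal(sum(h), 3)
})

test_that("change points count absolute copy steps, ignoring zero", {
  seg <- seg_tbl(list("chrA", 1, 1e6, 2, 1, 1), list("chrA", 1e6 + 1, 2e6, 3, 2, 1),
                 list("chrA", 2e6 + 1, 3e6, 2, 1, 1), list("chrA", 3e6 + 1, 4e6, 3, 2, 1))
  h <- cncp_features(seg)
  expect_equal(unname(h["CNCP_1"]), 3)
  expect_equal(sum(h), 3)
  # allelic change with identical total copies is not a change point
  seg2 <- seg_tbl(list("chrA", 1, 1e6, 2, 1, 1), list("chrA", 1e6 + 1, 2e6, 2, 2, 0))
  expect_equal(sum(cncp_features(seg2)), 0)
  # single-segment chromosomes contribute nothing
  expect_equal(sum(cncp_features(seg_tbl(list("chrA", 1, 1e6, 5, 3, 2)))), 0)
})

test_that("the 45-feature vector is named, ordered and complete", {
  am <- toy_arm_map()
  empty <- seg_tbl(list("chrA", 1, 1, 2, 1, 1))[0, ]
  v <- extract_cn_features(empty, am)
  expect_length(v, 45)
  expect_true(all(v == 0))
  full <- extract_cn_features(random_segments(am), am)
  expect_equal(names(full), unlist(cn_schema()$names, use.names = FALSE))
})

test_that("all six categories match brute-force oracles on random genomes", {
  set.seed(202)
  am <- toy_arm_map()
  for (i in 1:40) {
    seg <- random_segments(am)
    expect_equal(unname(breakpoints_per_10mb(seg, am)), oracle_bc10(seg, am))
    expect_equal(unname(breaks_per_arm(seg, am)), oracle_bcca(seg, am))
    expect_equal(unname(cn_state_counts(seg)), oracle_cn_counts(seg))
    expect_equal(unname(copy_fraction(seg)), oracle_copy_fraction(seg),
                 tolerance = 1e-12)
    expect_equal(unname(segment_size_features(seg)), oracle_segsize(seg))
    expect_equal(unname(cncp_features(seg)), oracle_cncp(seg))
  }
})

test_that("features are permutation-invariant and respond to genome doubling", {
  set.seed(303)
  am <- toy_arm_map()
  seg <- random_segments(am)
  perm <- seg[sample(nrow(seg)), ]
  expect_equal(extract_cn_features(perm, am), extract_cn_features(seg, am))
  doubled <- dplyr::mutate(seg, total_cn = total_cn * 2L,
                           major_cn = major_cn * 2L, minor_cn = minor_cn * 2L)
  expect_equal(unname(cncp_features(doubled)), oracle_cncp(doubled))
  # doubling doubles every copy step: CNCP_1 empties into even classes
  expect_equal(unname(cncp_features(doubled)["CNCP_1"]), 0)
  expect_equal(sum(cncp_features(doubled)), sum(cncp_features(seg)))
})
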