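balanced_context <- function() {
  paste(rep(c("A", "C", "G", "T"), length.out = 41), collapse = "")
}

somatic_record <- function(chrom = "chr1", pos = 1000L, ref = "C", alt = "T",
                           tumour_depth = 200L, tumour_alt = 20L,
                           normal_depth = 180L, normal_alt = 0L,
                           mean_end_distance = 30,
                           context = balanced_context(),
                           repeat_adjacent = FALSE) {
  tibble::tibble(chrom = chrom, pos = pos, ref = ref, alt = alt,
                 tumour_depth = tumour_depth, tumour_alt = tumour_alt,
                 normal_depth = normal_depth, normal_alt = normal_alt,
                 mean_end_distance = mean_end_distance, context = context,
                 repeat_adjacent = repeat_adjacent)
}

test_that("error model averages position-matched VAFs across the panel", {
  pile <- tibble::tibble(
    sample_id = c("L1", "L2"), chrom = "chr1", pos = 500L, base = "T",
    count = c(0L, 2L), depth = c(100L, 100L))
  em <- build_error_model(pile)
  expect_equal(em$rate, 0.01)
  expect_equal(attr(em, "panel_size"), 2)
  # single sample: rate equals that sample's VAF
  em1 <- build_error_model(pile[2, ])
  expect_equal(em1$rate, 0.02)
})

test_that("error model equals a brute-force mean and skips zero depth", {
  set.seed(11)
  pile <- tidyr::expand_grid(
    sample_id = paste0("L", 1:5), pos = c(10L, 20L, 30L),
    base = c("A", "T")) |>
    dplyr::mutate(chrom = "chr2",
                  depth = sample(c(0L, 50L, 100L, 200L), dplyr::n(), TRUE),
                  count = pmin(depth, stats::rpois(dplyr::n(), 1)))
  em <- build_error_model(pile)
  for (i in seq_len(nrow(em))) {
    sub <- pile[pile$pos == em$pos[i] & pile$base == em$base[i] &
                  pile$depth > 0, ]
    expect_equal(em$rate[i], mean(sub$count / sub$depth))
  }
  expect_equal(attr(em, "n_zero_depth"), sum(pile$depth == 0))
})

test_that("context dominance uses a strict threshold", {
  expect_true(context_dominant_base(paste0(strrep("A", 36), strrep("C", 4))))
  expect_false(context_dominant_base(balanced_context()))
  # exactly 80% is NOT dominant
  expect_false(context_dominant_base(paste0(strrep("A", 32), strrep("C", 8))))
  expect_true(context_dominant_base(paste0(strrep("A", 33), strrep("C", 7))))
})

test_that("a clean record passes and boundary violations fail named rules", {
  v <- call_somatic(somatic_record(), NULL, filter_config())
  expect_true(v$pass)
  expect_length(v$failed_rules[[1]], 0)

  v <- call_somatic(somatic_record(mean_end_distance = 5), NULL)
  expect_false(v$pass)
  expect_equal(v$failed_rules[[1]], "end_distance")
  # end distance exactly 6 bp passes (discard is "< 6 bp")
  expect_true(call_somatic(somatic_record(mean_end_distance = 6), NULL)$pass)

  # VAF exactly 2% fails the strict > rule
  v <- call_somatic(somatic_record(tumour_depth = 500L, tumour_alt = 10L),
                    NULL)
  expect_equal(v$failed_rules[[1]], "vaf")
})

test_that("12-record handcrafted table matches rule-by-rule evaluation", {
  em <- build_error_model(tibble::tibble(
    sample_id = "L1", chrom = "chr1", pos = 777L, base = "T",
    count = 1L, depth = 100L))  # error rate 0.01
  dominant_ctx <- paste0(strrep("A", 20), "C", strrep("A", 17), "GCT")
  records <- dplyr::bind_rows(
    somatic_record(),                                        # 1 clean pass
    somatic_record(tumour_alt = 9L),                         # 2 alt_reads(+vaf ok: 9/200)
    somatic_record(tumour_depth = 30L, tumour_alt = 10L),    # 3 depth fail
    somatic_record(normal_depth = 30L),                      # 4 depth fail
    somatic_record(normal_alt = 18L),                        # 5 ratio fail (0.1 < 3*0.1)
    somatic_record(normal_alt = 6L),                         # 6 ratio pass (0.1 >= 3*1/30)
    somatic_record(pos = 777L, tumour_depth = 200L,
                   tumour_alt = 40L),                        # 7 err: 0.20 >= 20*0.01 pass
    somatic_record(pos = 777L, tumour_depth = 200L,
                   tumour_alt = 39L),                        # 8 0.195 < 0.2 fail
    somatic_record(pos = 777L, tumour_alt = 80L,
                   repeat_adjacent = TRUE),                  # 9 0.4 >= 40*0.01 pass
    somatic_record(pos = 777L, tumour_alt = 79L,
                   repeat_adjacent = TRUE),                  # 10 0.395 < 0.4 fail
    somatic_record(pos = 777L, tumour_alt = 79L,
                   context = dominant_ctx),                  # 11 dominant ctx fail
    somatic_record(mean_end_distance = 5.9)                  # 12 end distance
  )
  verdicts <- call_somatic(records, em, filter_config())
  expect_equal(verdicts$pass,
               c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE,
                 FALSE, FALSE, FALSE))
  expect_equal(verdicts$failed_rules[[2]], "alt_reads")
  expect_equal(verdicts$failed_rules[[3]], "depth")
  expect_equal(verdicts$failed_rules[[5]], "normal_ratio")
  expect_equal(verdicts$failed_rules[[8]], "error_rate")
  expect_equal(verdicts$failed_rules[[10]], "error_rate")
  expect_equal(verdicts$failed_rules[[11]], "error_rate")
  expect_equal(verdicts$failed_rules[[12]], "end_distance")
  # verdict conservation
  expect_equal(sum(verdicts$pass) + sum(!verdicts$pass), nrow(records))
})

test_that("verdicts are order-invariant and thresholds act monotonically", {
  set.seed(7)
  co <- simulate_cohort(1, default_generators()["BRCA2d"], seed = 13)
  rec <- co$samples[[1]]$variants
  v1 <- call_somatic(rec, NULL)
  perm <- sample(nrow(rec))
  v2 <- call_somatic(rec[perm, ], NULL)
  expect_equal(v2$pass, v1$pass[perm])
  # relaxing any single threshold never shrinks the pass set
  relaxed <- list(
    filter_config(min_vaf = 0.01), filter_config(min_alt_reads = 5),
    filter_config(min_depth = 20), filter_config(tumour_vs_normal_ratio = 2),
    filter_config(error_multiplier = 10), filter_config(min_end_distance = 3))
  for (cfg in relaxed) {
    expect_true(all(call_somatic(rec, NULL, cfg)$pass >= v1$pass))
  }
})

test_that("germline filter applies the VAF band and depth floor", {
  rec <- dplyr::bind_rows(
    somatic_record(normal_depth = 60L, normal_alt = 30L),   # 0.50, kept
    somatic_record(normal_depth = 100L, normal_alt = 29L),  # 0.29, dropped
    somatic_record(normal_depth = 100L, normal_alt = 30L),  # 0.30 boundary kept
    somatic_record(normal_depth = 100L, normal_alt = 70L),  # 0.70 boundary kept
    somatic_record(normal_depth = 100L, normal_alt = 71L),  # 0.71 dropped
    somatic_record(normal_depth = 39L, normal_alt = 19L),   # depth 39 dropped
    somatic_record(normal_depth = 40L, normal_alt = 20L)    # depth 40 kept
  )
  kept <- call_germline(rec)
  expect_equal(nrow(kept), 4)
  # equals brute-force filter
  vaf <- rec$normal_alt / rec$normal_depth
  manual <- rec[vaf >= 0.3 & vaf <= 0.7 & rec$normal_depth >= 40, ]
  expect_equal(kept, manual)
})

test_that("verdict TSV contains one logical column per rule", {
  v <- call_somatic(dplyr::bind_rows(somatic_record(),
                                     somatic_record(mean_end_distance = 2)),
                    NULL)
  path <- file.path(withr::local_tempdir(), "verdicts.tsv")
  write_verdicts(v, path)
  out <- readr::read_tsv(path, show_col_types = FALSE)
  expect_true(all(c("vaf", "alt_reads", "depth", "normal_ratio",
                    "error_rate", "end_distance", "pass") %in% names(out)))
  expect_equal(out$end_distance, c(TRUE, FALSE))
})
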