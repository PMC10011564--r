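test_that("channel name vectors have the canonical sizes", {
  expect_length(sbs_channels(), 96)
  expect_length(unique(sbs_channels()), 96)
  expect_length(indel_channels(), 83)
  expect_length(unique(indel_channels()), 83)
  expect_length(feature_names(), 224)
})

test_that("substitution classification matches the exhaustive oracle", {
  bases <- c("A", "C", "G", "T")
  hits <- character(0)
  for (ref in bases) for (alt in setdiff(bases, ref)) {
    for (l in bases) for (r in bases) {
      tri <- paste0(l, ref, r)
      got <- classify_sbs(ref, alt, tri)
      expect_equal(got, oracle_sbs(ref, alt, tri))
      hits <- c(hits, got)
    }
  }
  # 12 x 16 = 192 cases fold onto exactly 96 channels, each hit twice
  expect_equal(sort(unique(hits)), sort(sbs_channels()))
  expect_true(all(table(hits) == 2))
})

test_that("strand symmetry and context windows behave", {
  expect_equal(classify_sbs("C", "T", "ACA"), "A[C>T]A")
  expect_equal(classify_sbs("G", "A", "CGT"), "A[C>T]G")
  # wide window: only the trinucleotide core matters
  ctx <- paste0(strrep("T", 19), "ACA", strrep("T", 19))
  expect_equal(classify_sbs("C", "T", ctx), "A[C>T]A")
  # N in the core is unclassifiable
  expect_true(is.na(classify_sbs("C", "T", "NCA")))
  expect_error(classify_sbs("C", "T", "ATA"), "middle base")
})

test_that("homopolymer deletions land in the documented channels", {
  # run of >= 6 Cs (incl. deleted base) -> 1:Del:C:5
  expect_equal(classify_indel("AC", "A", "TTTTTTTTTTTTTTTTTTTA",
                              "CCCCCGGGGGGGGGGGGGGG"), "1:Del:C:5")
  # run of exactly 2 -> label 1
  expect_equal(classify_indel("AC", "A", "TTTTTTTTTTTTTTTTTTTA",
                              "CGGGTGGGGGGGGGGGGGGG"), "1:Del:C:1")
  # isolated deletion -> label 0; purine base complements to pyrimidine
  expect_equal(classify_indel("TG", "T", "ATCATCATCATCATCATCAT",
                              "TCCTCCTCCTCCTCCTCCTC"), "1:Del:C:0")
  # insertion into an existing run of 3 -> label 3
  expect_equal(classify_indel("A", "AT", "GCGCGCGCGCGCGCGCGCGA",
                              "TTTGGGCCCAAAGGGCCCAA"), "1:Ins:T:3")
})

test_that("long indels split into repeat and microhomology channels", {
  # deletion of ACGT with right flank beginning ACG: microhomology 3
  expect_equal(classify_indel("TACGT", "T", "GGCCGGCCGGCCGGCCGGCT",
                              "ACGAAGTCCGGTTAACCGGT"), "4:Del:M:3")
  # deleted sequence tandem-repeated once to the right: repeat-mediated
  expect_equal(classify_indel("TACG", "T", "GGCCGGCCGGCCGGCCGGCT",
                              "ACGTTGGCCAAGGTTCCAAG"), "3:Del:R:1")
  # no repeat, no shared sequence: R:0
  expect_equal(classify_indel("TAACG", "T", "GGCCGGCCGGCCGGCCGGCT",
                              "GTTCCGGTTCCGGTTAAGGC"), "4:Del:R:0")
  # insertion with two adjacent copies in the reference
  expect_equal(classify_indel("T", "TGACA", "CCGGCCGGCCGGCCGGCCGT",
                              "GACAGACATTCCGGAACCGG"), "4:Ins:R:2")
  # complex substitution is unclassified
  expect_true(is.na(classify_indel("ACG", "ATT", "CCCCCCCCCCCCCCCCCCCC",
                                   "GGGGGGGGGGGGGGGGGGGG")))
})

test_that("random indels match the independent decision-tree oracle", {
  set.seed(101)
  for (i in 1:200) {
    case <- random_indel_case()
    got <- classify_indel(case$ref, case$alt, case$left, case$right)
    want <- oracle_indel(case$event, case$is_del, case$left, case$right)
    expect_equal(got, want, info = paste("case", i, case$ref, ">", case$alt))
  }
})

test_that("1 bp channels are reverse-complement invariant", {
  set.seed(77)
  for (i in 1:50) {
    case <- random_indel_case()
    if (nchar(case$event) != 1) next
    fwd <- classify_indel(case$ref, case$alt, case$left, case$right)
    # reverse-complement representation: flanks swap and complement
    ev_rc <- rc(case$event)
    left_rc <- rc(case$right)
    right_rc <- rc(case$left)
    rev_ref <- if (case$is_del) paste0(substr(left_rc, 20, 20), ev_rc) else
      substr(left_rc, 20, 20)
    rev_alt <- if (case$is_del) substr(left_rc, 20, 20) else
      paste0(substr(left_rc, 20, 20), ev_rc)
    bwd <- classify_indel(rev_ref, rev_alt, left_rc, right_rc)
    expect_equal(bwd, fwd)
  }
})

test_that("catalogs conserve counts and order channels canonically", {
  empty <- build_catalog(tibble::tibble(ref = character(),
                                        alt = character(),
                                        context = character()))
  expect_equal(sum(empty$sbs) + sum(empty$indel) + empty$unclassified, 0)
  expect_equal(names(empty$sbs), sbs_channels())
  expect_equal(names(empty$indel), indel_channels())

  flank19 <- strrep("G", 19)
  v <- tibble::tibble(
    ref = c("C", "G", "AC", "A", "CC"),
    alt = c("T", "C", "A", "AT", "TT"),
    context = c(
      paste0(flank19, "ACAT", strrep("G", 18)),
      paste0(flank19, "TGTA", strrep("G", 18)),
      paste0(strrep("T", 19), "A", "C", strrep("G", 20)),
      paste0(strrep("G", 19), "A", strrep("C", 20)),
      strrep("A", 41)))
  cat_ <- build_catalog(v, "toy")
  # hand-computed: C>T in ACA; G>C in TGT -> A[C>G]A; 1bp C del; 1bp T ins;
  # CC>TT is a double substitution -> unclassified
  expect_equal(cat_$sbs[["A[C>T]A"]], 1L)
  expect_equal(cat_$sbs[["A[C>G]A"]], 1L)
  expect_equal(sum(cat_$sbs), 2)
  expect_equal(sum(cat_$indel), 2)
  expect_equal(cat_$unclassified, 1L)
  expect_equal(sum(cat_$sbs) + sum(cat_$indel) + cat_$unclassified, nrow(v))
})

test_that("catalog counts conserve on simulated samples", {
  s <- simulate_sample(default_generators()$BRCA2d, 31)
  keep <- call_somatic(s$variants, NULL)
  passing <- keep[keep$pass, ]
  cat_ <- build_catalog(passing, "b1")
  expect_equal(sum(cat_$sbs) + sum(cat_$indel) + cat_$unclassified,
               nrow(passing))
  expect_equal(cat_$unclassified, 0L)
})
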