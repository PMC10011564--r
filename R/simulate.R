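BASES <- c("A", "C", "G", "T")

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

rand_dna <- function(n, len, exclude = NULL) {
  pool <- setdiff(BASES, exclude)
  m <- matrix(sample(pool, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Template substitution spectra used by the simulator
#'
#' Four stylized mutational processes over the 96 channels, each summing
#' to 1: `ageing` (spontaneous deamination: C>T at NpCpG), `mmr`
#' (mismatch-repair failure: heavy C>T at NpCpG plus broad C>T), `hrr`
#' (defective homologous recombination: near-flat with C>G enrichment,
#' strongest at A\[C>G\]G) and `apobec` (C>T/C>G in TpCpW). These are
#' synthetic stand-ins shaped like the corresponding catalogued processes,
#' not copies of any published matrix.
#'
#' @return 96 x 4 numeric matrix, canonical channel rows.
#' @export
template_spectra <- function() {
  ch <- sbs_channels()
  left <- substr(ch, 1, 1)
  right <- substr(ch, 7, 7)
  sub <- substr(ch, 3, 5)
  ageing <- 0.4 + 10 * (sub == "C>T" & right == "G") + 1 * (sub == "C>T")
  mmr <- 0.3 + 22 * (sub == "C>T" & right == "G") + 3 * (sub == "C>T") +
    1.5 * (sub == "T>C")
  hrr <- 1 + 3 * (sub == "C>G") + 8 * (sub == "C>G" & left == "A" & right == "G")
  apobec <- 0.2 + 10 * (sub == "C>T" & left == "T" & right %in% c("A", "T")) +
    7 * (sub == "C>G" & left == "T" & right %in% c("A", "T"))
  m <- cbind(ageing = ageing, mmr = mmr, hrr = hrr, apobec = apobec)
  rownames(m) <- ch
  sweep(m, 2, colSums(m), "/")
}

#' Synthetic reference signature matrix
#'
#' A small signature matrix in the version-2 catalogue layout (96 canonical
#' channel rows, columns named `Signature.N`) assembled from the simulator's
#' template spectra with per-signature re-weightings. It exists so signature
#' refitting and the combined MMRd-weight rule are testable without bundling
#' third-party data; it is a synthetic stand-in, not the published catalogue.
#'
#' @return 96 x 9 signature matrix (signatures 1, 2, 3, 5, 6, 13, 15, 20, 26).
#' @export
synthetic_signature_matrix <- function() {
  t <- template_spectra()
  ch <- rownames(t)
  left <- substr(ch, 1, 1)
  right <- substr(ch, 7, 7)
  sub <- substr(ch, 3, 5)
  flat <- rep(1 / 96, 96)
  mk <- function(v) v / sum(v)
  m <- cbind(
    Signature.1 = t[, "ageing"],
    Signature.2 = mk(0.1 / 96 + (sub == "C>T" & left == "T")),
    Signature.3 = t[, "hrr"],
    Signature.5 = mk(flat + 0.5 * as.numeric(sub %in% c("T>C", "C>T")) / 96),
    Signature.6 = t[, "mmr"],
    Signature.13 = mk(0.1 / 96 + (sub == "C>G" & left == "T")),
    Signature.15 = mk(0.2 / 96 + (sub == "C>T" & right == "G") +
                        0.8 * (sub == "C>T" & left == "G")),
    Signature.20 = mk(0.2 / 96 + 0.7 * (sub == "C>T" & right == "G") +
                        (sub == "T>C" & left == "A")),
    Signature.26 = mk(0.2 / 96 + (sub == "T>C") * 0.9 +
                        0.4 * (sub == "C>T" & right == "A"))
  )
  rownames(m) <- ch
  validate_signature_matrix(m)
}

#' Default synthetic genome arm map
#'
#' Five synthetic chromosomes (120, 100, 90, 80 and 60 Mb) with centromeres
#' at 40% of each length — long enough for the 10 Mb window, 15 Mb LOH and
#' 10 Mb transition features to behave as they do on real genomes.
#'
#' @return A `darc_armmap`.
#' @export
default_arm_map <- function() {
  arm_map_from_lengths(c(chr1 = 120e6, chr2 = 100e6, chr3 = 90e6,
                         chr4 = 80e6, chr5 = 60e6))
}

#' Phenotype class generator
#'
#' Bundles the per-class simulation program: expected substitution and indel
#' burdens, the mixture over template spectra, the indel type mix
#' (1 bp homopolymer deletions, microhomology deletions, long indels,
#' generic short indels), and the copy-number program.
#'
#' @param name Class label.
#' @param snv_mean Expected substitution count per exome.
#' @param spectrum Named mixture weights over [template_spectra()] columns
#'   (normalized internally).
#' @param indel_mean Expected indel count.
#' @param indel_mix Named weights over types `hp_del_c`, `hp_del_t`,
#'   `mh_del`, `long_indel`, `short_indel`.
#' @param cn_program One of `"diploid"`, `"tandem_dup"`, `"aneuploid_hrd"`,
#'   `"aneuploid_large"`.
#' @param burden_sdlog Log-sd of the per-sample burden multiplier applied
#'   jointly to the substitution and indel means. Wide values make class
#'   burdens overlap, as they do across real patients.
#' @param hp_run_len Reference homopolymer run lengths (including the
#'   deleted base) drawn for 1 bp homopolymer deletions. Replication-slippage
#'   deletions in mismatch-repair-deficient genomes occur in long runs;
#'   background deletions in short ones.
#' @param cellularity_range Tumour-fraction range sampled per sample.
#' @param fail_fraction Fraction of emitted variant records deliberately
#'   corrupted to fail exactly one somatic filter rule (they exercise the
#'   filters and are removed before feature extraction).
#' @return A `darc_class_generator` list.
#' @export
class_generator <- function(name, snv_mean, spectrum, indel_mean, indel_mix,
                            cn_program, burden_sdlog = 0.3,
                            hp_run_len = 2:7,
                            cellularity_range = c(0.25, 0.7),
                            fail_fraction = 0.05) {
  spectrum <- spectrum / sum(spectrum)
  indel_mix <- indel_mix / sum(indel_mix)
  structure(as.list(environment()), class = "darc_class_generator")
}

#' Default class generators
#'
#' The study conditions of the simulator: hypermutated near-diploid MMRd
#' rich in C-homopolymer deletions; diploid CDK12d with genome-wide focal
#' tandem duplications; aneuploid BRCA2d with microhomology deletions, C>G
#' enrichment and LOH; aged aneuploid DDRwt with large-segment changes; and
#' an APOBEC-enriched aneuploid bladder-like class. The `"strong"` profile
#' gives clean class separation; `"hard"` overlaps the burdens and attenuates
#' copy-number signal, mimicking low tumour fraction.
#'
#' @param profile `"strong"` or `"hard"`.
#' @param include_bladder Append the bladder-like class (not part of the
#'   default training classes), default `FALSE`.
#' @return Named list of [class_generator()] objects.
#' @export
default_generators <- function(profile = c("strong", "hard"),
                               include_bladder = FALSE) {
  profile <- match.arg(profile)
  hard <- profile == "hard"
  gens <- list(
    MMRd = class_generator(
      "MMRd",
      snv_mean = if (hard) 700 else 1100,
      spectrum = c(mmr = 0.85, ageing = 0.1, hrr = 0.05),
      indel_mean = if (hard) 90 else 140,
      indel_mix = c(hp_del_c = 0.6, hp_del_t = 0.2, mh_del = 0.02,
                    long_indel = 0.05, short_indel = 0.13),
      cn_program = "diploid",
      burden_sdlog = 0.25, hp_run_len = 6:9),
    CDK12d = class_generator(
      "CDK12d",
      snv_mean = if (hard) 140 else 200,
      spectrum = c(ageing = 0.8, hrr = 0.2),
      indel_mean = 15,
      indel_mix = c(hp_del_c = 0.2, hp_del_t = 0.2, mh_del = 0.05,
                    long_indel = 0.15, short_indel = 0.4),
      cn_program = "tandem_dup",
      burden_sdlog = 0.5,
      cellularity_range = if (hard) c(0.12, 0.35) else c(0.25, 0.7)),
    BRCA2d = class_generator(
      "BRCA2d",
      snv_mean = if (hard) 250 else 420,
      spectrum = c(hrr = 0.7, ageing = 0.3),
      indel_mean = if (hard) 50 else 90,
      indel_mix = c(hp_del_c = 0.08, hp_del_t = 0.07, mh_del = 0.45,
                    long_indel = 0.25, short_indel = 0.15),
      cn_program = "aneuploid_hrd",
      burden_sdlog = 0.35),
    DDRwt = class_generator(
      "DDRwt",
      # aged genomes: broad burden range overlapping the defect classes
      snv_mean = if (hard) 300 else 300,
      spectrum = c(ageing = 0.9, hrr = 0.1),
      indel_mean = 18,
      indel_mix = c(hp_del_c = 0.25, hp_del_t = 0.25, mh_del = 0.03,
                    long_indel = 0.12, short_indel = 0.35),
      cn_program = "aneuploid_large",
      burden_sdlog = 0.6)
  )
  if (include_bladder) {
    gens$Bladder <- class_generator(
      "Bladder",
      snv_mean = 600,
      spectrum = c(apobec = 0.75, ageing = 0.25),
      indel_mean = 30,
      indel_mix = c(hp_del_c = 0.2, hp_del_t = 0.2, mh_del = 0.1,
                    long_indel = 0.15, short_indel = 0.35),
      cn_program = "aneuploid_large",
      burden_sdlog = 0.4)
  }
  gens
}

parse_channel <- function(ch) {
  tibble::tibble(
    left = substr(ch, 1, 1),
    ref = substr(ch, 3, 3),
    alt = substr(ch, 5, 5),
    right = substr(ch, 7, 7)
  )
}

sim_read_evidence <- function(n, cellularity) {
  depth <- pmax(60L, stats::rpois(n, 220))
  vaf <- pmin(0.9, pmax(0.06, stats::rbeta(n, 4, 4) * cellularity))
  alt <- pmax(12L, stats::rbinom(n, depth, vaf))
  tibble::tibble(
    tumour_depth = depth,
    tumour_alt = pmin(alt, depth),
    normal_depth = pmax(60L, stats::rpois(n, 200)),
    normal_alt = 0L,
    mean_end_distance = round(stats::runif(n, 15, 60), 1),
    repeat_adjacent = FALSE
  )
}

sim_positions <- function(n, arm_map, margin = 1e5) {
  lens <- chrom_lengths(arm_map)
  chrom <- sample(names(lens), n, replace = TRUE,
                  prob = as.numeric(lens) / sum(lens))
  pos <- floor(stats::runif(n, margin, as.numeric(lens[chrom]) - margin))
  tibble::tibble(chrom = chrom, pos = as.integer(pos))
}

sim_snvs <- function(n, spectrum_vec, arm_map, cellularity, flank = 20L) {
  if (n == 0) return(empty_variants())
  ch <- sample(sbs_channels(), n, replace = TRUE, prob = spectrum_vec)
  p <- parse_channel(ch)
  ctx <- paste0(rand_dna(n, flank - 1L), p$left, p$ref, p$right,
                rand_dna(n, flank - 1L))
  ref <- p$ref
  alt <- p$alt
  # half the records emitted on the purine strand to exercise normalization
  flip <- stats::runif(n) < 0.5
  if (any(flip)) {
    ctx[flip] <- revcomp(ctx[flip])
    ref[flip] <- unname(DNA_COMP[ref[flip]])
    alt[flip] <- unname(DNA_COMP[alt[flip]])
  }
  dplyr::bind_cols(
    sim_positions(n, arm_map),
    tibble::tibble(ref = ref, alt = alt),
    sim_read_evidence(n, cellularity),
    tibble::tibble(context = ctx)
  )
}

# 1 bp deletion inside a homopolymer run of `base` (run length incl. the
# deleted base drawn from run_len). Context: [flank ending at anchor][b][flank].
sim_hp_del <- function(n, base, arm_map, cellularity, flank = 20L,
                       run_len = 6:9) {
  if (n == 0) return(empty_variants())
  runs <- sample(rep(run_len, 2), n, replace = TRUE)
  anchor <- rand_dna(n, 1, exclude = base)
  left <- paste0(rand_dna(n, flank - 1L, exclude = base), anchor)
  right <- vapply(runs, function(r) {
    paste0(strrep(base, r - 1L), rand_dna(1, flank - (r - 1L), exclude = base))
  }, character(1))
  dplyr::bind_cols(
    sim_positions(n, arm_map),
    tibble::tibble(ref = paste0(anchor, base), alt = anchor),
    sim_read_evidence(n, cellularity),
    tibble::tibble(context = paste0(left, base, substr(right, 1, flank)))
  )
}

# Deletion of length 2-5 with microhomology: the deleted tract's first
# `mh` bases recur at the start of the right flank, no full extra copy.
sim_mh_del <- function(n, arm_map, cellularity, flank = 20L) {
  if (n == 0) return(empty_variants())
  len <- sample(rep(2:5, 2), n, replace = TRUE)
  mh <- vapply(len, function(l) sample(seq_len(l - 1L), 1), integer(1))
  rows <- purrr::map(seq_len(n), function(i) {
    d <- rand_dna(1, len[i])
    first <- substr(d, 1, 1)
    last <- substr(d, len[i], len[i])
    # anchor != last base of d: prevents left-alignment shifts and spurious
    # suffix microhomology
    anchor <- rand_dna(1, 1, exclude = unique(c(first, last)))
    seed_mh <- substr(d, 1, mh[i])
    next_in_d <- substr(d, mh[i] + 1L, mh[i] + 1L)
    # right flank continues differently after the shared prefix
    breaker <- rand_dna(1, 1, exclude = c(next_in_d, first))
    right <- paste0(seed_mh, breaker, rand_dna(1, flank))
    left <- paste0(rand_dna(1, flank - 1L,
                            exclude = substr(d, len[i], len[i])), anchor)
    tibble::tibble(ref = paste0(anchor, d), alt = anchor,
                   context = paste0(left, d, substr(right, 1, flank)))
  }) |> dplyr::bind_rows()
  dplyr::bind_cols(
    sim_positions(n, arm_map), rows[c("ref", "alt")],
    sim_read_evidence(n, cellularity), rows["context"]
  )
}

# Insertions/deletions of length 2-8 in non-repetitive context.
sim_long_indel <- function(n, arm_map, cellularity, flank = 20L) {
  if (n == 0) return(empty_variants())
  len <- sample(rep(2:8, 2), n, replace = TRUE)
  is_del <- stats::runif(n) < 0.7
  rows <- purrr::map(seq_len(n), function(i) {
    d <- rand_dna(1, len[i])
    first <- substr(d, 1, 1)
    last <- substr(d, len[i], len[i])
    anchor <- rand_dna(1, 1, exclude = last)
    left <- paste0(rand_dna(1, flank - 1L, exclude = last), anchor)
    right <- rand_dna(1, flank, exclude = first)
    if (is_del[i]) {
      tibble::tibble(ref = paste0(anchor, d), alt = anchor,
                     context = paste0(left, d, right))
    } else {
      tibble::tibble(ref = anchor, alt = paste0(anchor, d),
                     context = paste0(left, right))
    }
  }) |> dplyr::bind_rows()
  dplyr::bind_cols(
    sim_positions(n, arm_map), rows[c("ref", "alt")],
    sim_read_evidence(n, cellularity), rows["context"]
  )
}

# 1 bp insertions/deletions in short (1-3) runs: background indels.
sim_short_indel <- function(n, arm_map, cellularity, flank = 20L) {
  if (n == 0) return(empty_variants())
  base <- sample(BASES, n, replace = TRUE)
  run <- sample(1:3, n, replace = TRUE)
  is_del <- stats::runif(n) < 0.5
  rows <- purrr::map(seq_len(n), function(i) {
    b <- base[i]
    anchor <- rand_dna(1, 1, exclude = b)
    left <- paste0(rand_dna(1, flank - 1L, exclude = b), anchor)
    right <- paste0(strrep(b, run[i] - 1L),
                    rand_dna(1, flank - run[i] + 1L, exclude = b))
    if (is_del[i]) {
      tibble::tibble(ref = paste0(anchor, b), alt = anchor,
                     context = paste0(left, b, substr(right, 1, flank)))
    } else {
      tibble::tibble(ref = anchor, alt = paste0(anchor, b),
                     context = paste0(left, substr(right, 1, flank)))
    }
  }) |> dplyr::bind_rows()
  dplyr::bind_cols(
    sim_positions(n, arm_map), rows[c("ref", "alt")],
    sim_read_evidence(n, cellularity), rows["context"]
  )
}

empty_variants <- function() {
  tibble::tibble(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), tumour_depth = integer(), tumour_alt = integer(),
    normal_depth = integer(), normal_alt = integer(),
    mean_end_distance = numeric(), repeat_adjacent = logical(),
    context = character()
  )
}

# Corrupt a record so it fails exactly one named somatic filter rule.
corrupt_record <- function(v, i, rule, flank = 20L) {
  switch(rule,
    vaf = {
      # VAF exactly 2% fails the strict rule while keeping >= 10 alt reads
      v$tumour_depth[i] <- 600L
      v$tumour_alt[i] <- 12L
    },
    alt_reads = {
      v$tumour_depth[i] <- 200L
      v$tumour_alt[i] <- 9L  # VAF 4.5% passes; alt-read floor fails
    },
    depth = {
      v$normal_depth[i] <- 25L
      v$normal_alt[i] <- 0L
    },
    normal_ratio = {
      v$normal_alt[i] <- ceiling(v$normal_depth[i] *
                                   (v$tumour_alt[i] / v$tumour_depth[i]) / 2)
    },
    end_distance = {
      v$mean_end_distance[i] <- round(stats::runif(1, 1, 5.5), 1)
    }
  )
  v
}

sim_filter_failures <- function(v, fraction, flank = 20L) {
  n_bad <- round(nrow(v) * fraction)
  if (n_bad == 0 || nrow(v) == 0) return(v)
  rules <- c("vaf", "alt_reads", "depth", "normal_ratio", "end_distance")
  idx <- sample(nrow(v), n_bad)
  for (j in seq_along(idx)) {
    v <- corrupt_record(v, idx[j], rules[(j - 1L) %% length(rules) + 1L],
                        flank)
  }
  v
}

seg_row <- function(chrom, start, end, total, minor) {
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), total_cn = as.integer(total),
                 major_cn = as.integer(total - minor),
                 minor_cn = as.integer(minor))
}

sim_segments_diploid <- function(arm_map) {
  lens <- chrom_lengths(arm_map)
  purrr::map_dfr(names(lens), function(ch) {
    seg_row(ch, 1, lens[[ch]], 2, 1)
  })
}

# Focal tandem duplications on a diploid backbone: 2 -> 3 -> 2 steps.
sim_segments_tandem_dup <- function(arm_map, dups_per_chrom = 10,
                                    small_fraction = 0.3) {
  lens <- chrom_lengths(arm_map)
  purrr::map_dfr(names(lens), function(ch) {
    len <- lens[[ch]]
    k <- stats::rpois(1, dups_per_chrom)
    if (k == 0) return(seg_row(ch, 1, len, 2, 1))
    dup_len <- ifelse(stats::runif(k) < small_fraction,
                      floor(stats::runif(k, 1e3, 5e3)),
                      floor(stats::runif(k, 5e4, 2e6)))
    starts <- sort(floor(stats::runif(k, 2e6, len - 3e6)))
    # discard overlapping duplications
    keep <- c(TRUE, diff(starts) > utils::head(dup_len, -1) + 1e4)
    starts <- starts[keep]; dup_len <- dup_len[keep]
    rows <- list()
    cursor <- 1
    for (i in seq_along(starts)) {
      rows <- c(rows, list(seg_row(ch, cursor, starts[i] - 1, 2, 1)))
      rows <- c(rows, list(seg_row(ch, starts[i],
                                   starts[i] + dup_len[i] - 1, 3, 1)))
      cursor <- starts[i] + dup_len[i]
    }
    rows <- c(rows, list(seg_row(ch, cursor, len, 2, 1)))
    dplyr::bind_rows(rows)
  })
}

# Highly rearranged aneuploid genome: mostly 8-25 Mb segments with varied
# states and LOH, plus occasional bursts of clustered 0.3-2 Mb segments
# (successive small copy changes also occur in rearranged HRD genomes).
sim_segments_aneuploid_hrd <- function(arm_map, loh_prob = 0.4) {
  lens <- chrom_lengths(arm_map)
  purrr::map_dfr(names(lens), function(ch) {
    len <- lens[[ch]]
    cuts <- c(0)
    while (utils::tail(cuts, 1) < len) {
      if (stats::runif(1) < 0.15) {
        for (j in seq_len(sample(3:6, 1))) {
          step <- floor(stats::runif(1, 3e5, 2e6))
          cuts <- c(cuts, min(utils::tail(cuts, 1) + step, len))
        }
      } else {
        step <- floor(stats::runif(1, 8e6, 25e6))
        cuts <- c(cuts, min(utils::tail(cuts, 1) + step, len))
      }
    }
    cuts <- unique(cuts)
    n <- length(cuts) - 1
    total <- numeric(n)
    total[1] <- sample(c(1, 2, 3, 4), 1)
    for (i in seq_len(n - 1)) {
      total[i + 1] <- max(1, total[i] + sample(c(-2, -1, 1, 2), 1))
    }
    minor <- ifelse(stats::runif(n) < loh_prob, 0,
                    pmax(0, pmin(floor(total / 2), 1)))
    purrr::map_dfr(seq_len(n), function(i) {
      seg_row(ch, cuts[i] + 1, cuts[i + 1], total[i], minor[i])
    })
  })
}

# Aged aneuploid genome: large (10-50 Mb) events, frequent whole-genome
# doubling, enough segment churn to overlap the defect classes on naive
# breakpoint counts, but no focal duplications or LOH excess.
sim_segments_aneuploid_large <- function(arm_map) {
  lens <- chrom_lengths(arm_map)
  doubled <- stats::runif(1) < 0.4
  base <- if (doubled) 4 else 2
  purrr::map_dfr(names(lens), function(ch) {
    len <- lens[[ch]]
    k <- sample(1:7, 1)
    cuts <- sort(sample(seq(0.1 * len, 0.9 * len, by = 1e6), k))
    bounds <- c(0, cuts, len)
    purrr::map_dfr(seq_len(k + 1), function(i) {
      total <- max(1, base + sample(c(-1, 0, 0, 1, 2), 1))
      seg_row(ch, bounds[i] + 1, bounds[i + 1], total,
              pmin(floor(total / 2), 1))
    })
  })
}

sim_segments <- function(program, arm_map) {
  switch(program,
    diploid = sim_segments_diploid(arm_map),
    tandem_dup = sim_segments_tandem_dup(arm_map),
    aneuploid_hrd = sim_segments_aneuploid_hrd(arm_map),
    aneuploid_large = sim_segments_aneuploid_large(arm_map),
    stop("unknown cn program: ", program)
  )
}

#' Simulate one labelled sample
#'
#' Draws substitutions, indels and an allele-specific segment table from a
#' class generator. All emitted variant records satisfy the somatic filter
#' pass criteria by construction, except for the generator's configured
#' fraction of deliberate single-rule failures.
#'
#' @param generator A [class_generator()].
#' @param seed Integer seed (results are a pure function of generator and
#'   seed).
#' @param arm_map A `darc_armmap`, default [default_arm_map()].
#' @param sample_id Identifier, default derived from the label and seed.
#' @return List with `sample_id`, `label`, `variants` (tibble), `segments`
#'   (tibble), `solution` (a `darc_solution` with cellularity and mean
#'   ploidy).
#' @export
simulate_sample <- function(generator, seed, arm_map = default_arm_map(),
                            sample_id = NULL) {
  with_seed_local(seed, {
    cellularity <- stats::runif(1, generator$cellularity_range[1],
                                generator$cellularity_range[2])
    spectrum_vec <- as.numeric(
      template_spectra()[, names(generator$spectrum), drop = FALSE] %*%
        generator$spectrum)
    # one lognormal burden multiplier couples SNV and indel load per sample
    mult <- stats::rlnorm(1, 0, generator$burden_sdlog)
    n_snv <- stats::rpois(1, generator$snv_mean * mult)
    n_indel <- stats::rpois(1, generator$indel_mean * mult)
    mix <- generator$indel_mix
    n_by_type <- stats::setNames(
      as.integer(stats::rmultinom(1, n_indel, mix)), names(mix))
    variants <- dplyr::bind_rows(
      sim_snvs(n_snv, spectrum_vec, arm_map, cellularity),
      sim_hp_del(n_by_type[["hp_del_c"]], "C", arm_map, cellularity,
                 run_len = generator$hp_run_len),
      sim_hp_del(n_by_type[["hp_del_t"]], "T", arm_map, cellularity,
                 run_len = generator$hp_run_len),
      sim_mh_del(n_by_type[["mh_del"]], arm_map, cellularity),
      sim_long_indel(n_by_type[["long_indel"]], arm_map, cellularity),
      sim_short_indel(n_by_type[["short_indel"]], arm_map, cellularity)
    )
    variants <- sim_filter_failures(variants, generator$fail_fraction)
    variants <- dplyr::arrange(variants, .data$chrom, .data$pos)
    segments <- sim_segments(generator$cn_program, arm_map)
    lens <- seg_lengths(segments)
    mean_ploidy <- sum(segments$total_cn * lens) / sum(lens)
    if (is.null(sample_id)) {
      sample_id <- paste0(generator$name, "_s", seed)
    }
    list(
      sample_id = sample_id,
      label = generator$name,
      variants = variants[c("chrom", "pos", "ref", "alt", "tumour_depth",
                            "tumour_alt", "normal_depth", "normal_alt",
                            "mean_end_distance", "context",
                            "repeat_adjacent")],
      segments = segments,
      solution = new_solution(segments, cellularity, mean_ploidy)
    )
  })
}

#' Simulate a labelled cohort
#'
#' Generates `n_per_class` samples per generator, reproducibly for a given
#' seed. When `dir` is given, every sample is written in the exact dialects
#' the readers consume (variant TSV, segment TSV) together with a labels TSV
#' and a cytoband file for the synthetic genome.
#'
#' @param n_per_class Samples per class.
#' @param generators Named list of [class_generator()]s, default
#'   [default_generators()].
#' @param seed Integer master seed; per-sample seeds are derived from it.
#' @param arm_map A `darc_armmap`.
#' @param dir Optional output directory.
#' @return List with `samples` (list of per-sample lists), `labels`
#'   (tibble: sample_id, label, cellularity, mean_ploidy), `arm_map`.
#' @export
simulate_cohort <- function(n_per_class, generators = default_generators(),
                            seed = 1L, arm_map = default_arm_map(),
                            dir = NULL) {
  counter <- 0L
  samples <- purrr::imap(generators, function(gen, cls) {
    purrr::map(seq_len(n_per_class), function(i) {
      counter <<- counter + 1L
      simulate_sample(gen, seed * 10000L + counter, arm_map,
                      sample_id = sprintf("%s_%03d", cls, i))
    })
  }) |> purrr::flatten()
  labels <- purrr::map_dfr(samples, function(s) {
    tibble::tibble(sample_id = s$sample_id, label = s$label,
                   cellularity = s$solution$cellularity,
                   mean_ploidy = s$solution$mean_ploidy)
  })
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_cytobands(arm_map, file.path(dir, "cytobands.txt"))
    readr::write_tsv(labels, file.path(dir, "labels.tsv"), progress = FALSE)
    for (s in samples) {
      write_variants(s$variants,
                     file.path(dir, paste0(s$sample_id, ".variants.tsv")))
      write_segments(s$solution,
                     file.path(dir, paste0(s$sample_id, ".segments.tsv")))
    }
  }
  list(samples = samples, labels = labels, arm_map = arm_map)
}

#' Write a miniature synthetic reference genome
#'
#' A few short contigs (default 60 kb each) of balanced base composition
#' with embedded homopolymers and tandem repeats, written as FASTA. It
#' exists so context retrieval is testable end to end at desk scale; it is
#' synthetic and unrelated to any real genome.
#'
#' @param path Output FASTA path.
#' @param n_contigs Number of contigs.
#' @param contig_length Length of each contig in bp.
#' @param seed Integer seed.
#' @return `path`, invisibly.
#' @export
simulate_reference <- function(path, n_contigs = 3, contig_length = 6e4,
                               seed = 1L) {
  with_seed_local(seed, {
    lines <- character(0)
    for (i in seq_len(n_contigs)) {
      seqs <- rand_dna(ceiling(contig_length / 1000), 1000)
      seq <- substr(paste(seqs, collapse = ""), 1, contig_length)
      # embed homopolymers and a tandem repeat at fixed offsets
      substr(seq, 5001, 5008) <- strrep("C", 8)
      substr(seq, 15001, 15007) <- strrep("T", 7)
      unit <- rand_dna(1, 4)
      substr(seq, 25001, 25012) <- strrep(unit, 3)
      lines <- c(lines, paste0(">ctg", i),
                 substring(seq, seq(1, contig_length, 80),
                           pmin(seq(80, contig_length + 79, 80),
                                contig_length)))
    }
    writeLines(lines, path)
  })
  invisible(path)
}
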