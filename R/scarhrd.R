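#' Homologous-recombination scar scores
#'
#' Three established copy-number scar counts plus their sum, computed from
#' allele-specific segments:
#' \describe{
#'   \item{HRD-LOH}{number of loss-of-heterozygosity regions (minor copy 0,
#'     total copy >= 1; contiguous LOH segments merged first) longer than
#'     15 Mb that do not span the entire chromosome.}
#'   \item{LST}{number of chromosomal breaks between adjacent segments of at
#'     least 10 Mb each, separated by no more than 3 Mb, with differing
#'     (total, minor) copy state.}
#'   \item{TelomericAI}{number of allelically imbalanced segments
#'     (major != minor) that extend to a telomeric chromosome end without
#'     spanning the whole chromosome.}
#' }
#'
#' @param segments Validated segment tibble.
#' @param arm_map A `darc_armmap` (needed for telomere positions).
#' @param min_loh_mb,min_lst_mb,max_lst_gap_mb Size/gap thresholds in Mb.
#' @param telomere_tol Distance from the chromosome end (bp) within which a
#'   segment boundary counts as telomeric, default 10 kb.
#' @return `scar_scores()`: one-row tibble with `hrd_loh`, `lst`,
#'   `telomeric_ai`, `total`. The component functions return integers.
#' @export
scar_scores <- function(segments, arm_map, min_loh_mb = 15,
                        min_lst_mb = 10, max_lst_gap_mb = 3,
                        telomere_tol = 1e4) {
  h <- hrd_loh(segments, min_loh_mb)
  l <- lst(segments, min_lst_mb, max_lst_gap_mb)
  t_ <- telomeric_ai(segments, arm_map, telomere_tol)
  tibble::tibble(hrd_loh = h, lst = l, telomeric_ai = t_,
                 total = h + l + t_)
}

#' @rdname scar_scores
#' @export
hrd_loh <- function(segments, min_loh_mb = 15) {
  min_len <- min_loh_mb * 1e6
  total <- 0L
  for (ch in unique(segments$chrom)) {
    seg <- dplyr::arrange(segments[segments$chrom == ch, ], .data$start)
    span <- c(min(seg$start), max(seg$end))
    loh <- seg[seg$minor_cn == 0 & seg$total_cn >= 1, ]
    n <- nrow(loh)
    if (n == 0) next
    # merge contiguous LOH segments (gap tolerance 0 bp)
    grp <- cumsum(c(1L, as.integer(loh$start[-1] != loh$end[-n] + 1)))
    lo <- tapply(loh$start, grp, min)
    hi <- tapply(loh$end, grp, max)
    total <- total + sum(hi - lo + 1 > min_len &
                           !(lo == span[1] & hi == span[2]))
  }
  as.integer(total)
}

#' @rdname scar_scores
#' @export
lst <- function(segments, min_lst_mb = 10, max_lst_gap_mb = 3) {
  min_len <- min_lst_mb * 1e6
  max_gap <- max_lst_gap_mb * 1e6
  total <- 0L
  for (ch in unique(segments$chrom)) {
    seg <- dplyr::arrange(segments[segments$chrom == ch, ], .data$start)
    if (nrow(seg) < 2) next
    for (i in 2:nrow(seg)) {
      len1 <- seg$end[i - 1] - seg$start[i - 1] + 1
      len2 <- seg$end[i] - seg$start[i] + 1
      gap <- seg$start[i] - seg$end[i - 1] - 1
      state_diff <- seg$total_cn[i] != seg$total_cn[i - 1] ||
        seg$minor_cn[i] != seg$minor_cn[i - 1]
      if (len1 >= min_len && len2 >= min_len && gap <= max_gap && state_diff) {
        total <- total + 1L
      }
    }
  }
  total
}

#' @rdname scar_scores
#' @export
telomeric_ai <- function(segments, arm_map, telomere_tol = 1e4) {
  lens <- chrom_lengths(arm_map)
  check_chroms(segments, lens)
  at_start <- segments$start - 1 <= telomere_tol
  at_end <- lens[segments$chrom] - segments$end <= telomere_tol
  imbalanced <- segments$major_cn != segments$minor_cn
  sum(imbalanced & (at_start | at_end) & !(at_start & at_end))
}

#' Naive genome-instability burden summary
#'
#' Per-sample counts and copy-number burden: SNV and indel counts from the
#' mutation catalog, the length-weighted mean ploidy, the base ploidy (the
#' length-weighted modal integer copy state), and the fraction of the covered
#' genome whose total copy number differs from the base ploidy.
#'
#' @param catalog A `darc_catalog`.
#' @param segments Validated segment tibble.
#' @return One-row tibble.
#' @export
burden_summary <- function(catalog, segments) {
  lens <- seg_lengths(segments)
  mean_ploidy <- sum(segments$total_cn * lens) / sum(lens)
  by_state <- tapply(lens, segments$total_cn, sum)
  base_ploidy <- as.integer(names(by_state)[which.max(by_state)])
  altered <- sum(lens[segments$total_cn != base_ploidy]) / sum(lens)
  tibble::tibble(
    sample_id = catalog$sample_id,
    snv_count = sum(catalog$sbs),
    indel_count = sum(catalog$indel),
    mean_ploidy = mean_ploidy,
    base_ploidy = base_ploidy,
    altered_fraction = altered
  )
}

#' Cohen's d standardized mean difference
#'
#' `(mean(a) - mean(b)) / s_pooled`, with the pooled standard deviation
#' computed from within-group variances weighted by `n - 1`.
#'
#' @param a,b Numeric vectors (each of length >= 2).
#' @return Numeric scalar.
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  stopifnot(na >= 2, nb >= 2)
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
               (na + nb - 2))
  if (sp == 0) return(0)
  (mean(a) - mean(b)) / sp
}
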