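#' Somatic/germline filter configuration
#'
#' Thresholds for the cell-free DNA small-variant filters. Defaults encode
#' the study conditions: somatic candidates need tumour VAF > 2% with at
#' least 10 supporting unique reads at loci with > 30x depth in both the
#' cell-free DNA and the matched leukocyte sample; the tumour VAF must be at
#' least 3x the leukocyte VAF and at least 20x the panel background error
#' rate (40x for variants adjacent to catalogued repeats or inside a
#' context window whose composition is > 80% a single nucleotide); the mean
#' distance from supporting-read ends to the variant must be at least 6 bp.
#' Germline calls from leukocyte samples require VAF in \[30%, 70%\] and
#' depth >= 40x.
#'
#' @param min_vaf Minimum tumour VAF (exclusive), default 0.02.
#' @param min_alt_reads Minimum supporting unique reads, default 10.
#' @param min_depth Minimum depth in both samples (exclusive), default 30.
#' @param tumour_vs_normal_ratio Required tumour/leukocyte VAF ratio, default 3.
#' @param error_multiplier Required VAF multiple of the background error
#'   rate, default 20.
#' @param repeat_error_multiplier Error multiple for repeat-adjacent or
#'   dominant-context variants, default 40.
#' @param context_dominance Single-nucleotide fraction (exclusive) that marks
#'   a dominant context, default 0.80.
#' @param context_window Context flank size in bp, default 20.
#' @param min_end_distance Minimum mean end-of-read distance in bp, default 6.
#' @param germline_vaf_low,germline_vaf_high Germline VAF band, default
#'   0.30-0.70 (inclusive).
#' @param germline_min_depth Minimum leukocyte depth for germline calls,
#'   default 40 (inclusive).
#' @return A `darc_filter_config` list.
#' @export
filter_config <- function(min_vaf = 0.02, min_alt_reads = 10L,
                          min_depth = 30L, tumour_vs_normal_ratio = 3,
                          error_multiplier = 20, repeat_error_multiplier = 40,
                          context_dominance = 0.80, context_window = 20L,
                          min_end_distance = 6, germline_vaf_low = 0.30,
                          germline_vaf_high = 0.70, germline_min_depth = 40L) {
  cfg <- as.list(environment())
  stopifnot(all(unlist(cfg) > 0), germline_vaf_low < germline_vaf_high)
  structure(cfg, class = "darc_filter_config")
}

#' Build the leukocyte-panel background error model
#'
#' The background error rate of a substitution is the mean VAF of the
#' position-matched substituted base across all leukocyte samples in the
#' panel. Zero-depth observations do not contribute to the mean (they are
#' excluded, and their count reported in the `n_zero_depth` attribute).
#'
#' @param pileups Tibble of per-sample per-position base counts with columns
#'   `sample_id`, `chrom`, `pos`, `base` (the substituted base), `count`,
#'   `depth`.
#' @return A `darc_error_model`: tibble keyed by (`chrom`, `pos`, `base`)
#'   with the mean `rate`, plus attributes `panel_size` and `n_zero_depth`.
#' @export
build_error_model <- function(pileups) {
  req <- c("sample_id", "chrom", "pos", "base", "count", "depth")
  missing <- setdiff(req, names(pileups))
  if (length(missing) > 0) {
    stop("pileups missing columns: ", paste(missing, collapse = ", "))
  }
  panel <- length(unique(pileups$sample_id))
  if (panel < 1) stop("error model needs at least one leukocyte sample")
  zero <- pileups$depth == 0
  model <- pileups[!zero, ] |>
    dplyr::mutate(vaf = .data$count / .data$depth) |>
    dplyr::group_by(.data$chrom, .data$pos, .data$base) |>
    dplyr::summarise(rate = mean(.data$vaf), .groups = "drop")
  if (any(model$rate < 0 | model$rate > 1)) stop("error rates outside [0,1]")
  structure(model, class = c("darc_error_model", class(model)),
            panel_size = panel, n_zero_depth = sum(zero))
}

error_rate <- function(model, chrom, pos, base) {
  # positions absent from the leukocyte panel have no measurable error: rate 0
  if (is.null(model)) return(rep(0, length(chrom)))
  key <- paste(chrom, pos, base)
  mkey <- paste(model$chrom, model$pos, model$base)
  r <- model$rate[match(key, mkey)]
  dplyr::coalesce(r, 0)
}

#' Test whether a context window is dominated by one nucleotide
#'
#' True when any single nucleotide strictly exceeds `threshold` as a fraction
#' of the window, the variant base itself excluded from the window.
#'
#' @param context Context sequence (variant base excluded, i.e. the
#'   concatenated flanks).
#' @param threshold Dominance fraction, default 0.80 (strict).
#' @return Logical scalar.
#' @export
context_dominant_base <- function(context, threshold = 0.80) {
  stopifnot(nchar(context) > 0)
  b <- strsplit(toupper(context), "")[[1]]
  b <- b[b %in% c("A", "C", "G", "T")]
  if (length(b) == 0) return(FALSE)
  max(table(b)) / length(b) > threshold
}

# Flank-only window (variant base / deleted tract excluded) for dominance.
context_without_variant <- function(ref, alt, context, flank = 20L) {
  if (is_snv_allele(toupper(ref), toupper(alt))) {
    n <- nchar(context)
    mid <- (n + 1) / 2
    return(paste0(substr(context, 1, mid - 1), substr(context, mid + 1, n)))
  }
  fl <- indel_flanks(toupper(ref), toupper(alt), toupper(context), flank)
  paste0(fl$left, fl$right)
}

#' Apply the somatic filter rules to candidate variants
#'
#' Evaluates every rule for every record and returns a verdict table: a
#' record passes iff no rule fails, and each failed rule is named. Rules
#' (identifiers as emitted in `failed_rules`):
#' \describe{
#'   \item{vaf}{tumour VAF > `min_vaf`}
#'   \item{alt_reads}{`tumour_alt >= min_alt_reads`}
#'   \item{depth}{tumour and normal depth both > `min_depth`}
#'   \item{normal_ratio}{tumour VAF >= `tumour_vs_normal_ratio` x normal VAF
#'     (trivially satisfied when the normal VAF is 0)}
#'   \item{error_rate}{tumour VAF >= M x background error rate, with
#'     M = `repeat_error_multiplier` when the record is repeat-adjacent or
#'     its context is dominated by one nucleotide, else `error_multiplier`}
#'   \item{end_distance}{`mean_end_distance >= min_end_distance`}
#' }
#' The "less than" wordings of the discard conditions make the pass
#' conditions non-strict (`>=`); the VAF, depth and dominance conditions are
#' strict (`>`).
#'
#' @param records Variant tibble (see [read_variants()]).
#' @param error_model A `darc_error_model`, or `NULL` (no panel: error rate 0
#'   everywhere, the error-rate rule passes vacuously).
#' @param config A [filter_config()].
#' @return Tibble: the input records plus `pass` (logical) and
#'   `failed_rules` (list of character vectors).
#' @export
call_somatic <- function(records, error_model = NULL,
                         config = filter_config()) {
  n <- nrow(records)
  tvaf <- records$tumour_alt / records$tumour_depth
  nvaf <- records$normal_alt / records$normal_depth
  dominant <- purrr::map_lgl(seq_len(n), function(i) {
    context_dominant_base(
      context_without_variant(records$ref[i], records$alt[i],
                              records$context[i], config$context_window),
      config$context_dominance)
  })
  mult <- ifelse(records$repeat_adjacent | dominant,
                 config$repeat_error_multiplier, config$error_multiplier)
  base_sub <- ifelse(is_snv_allele(toupper(records$ref), toupper(records$alt)),
                     toupper(records$alt), NA_character_)
  err <- error_rate(error_model, records$chrom, records$pos, base_sub)
  rules <- list(
    vaf = tvaf > config$min_vaf,
    alt_reads = records$tumour_alt >= config$min_alt_reads,
    depth = records$tumour_depth > config$min_depth &
      records$normal_depth > config$min_depth,
    normal_ratio = tvaf >= config$tumour_vs_normal_ratio * nvaf,
    error_rate = tvaf >= mult * err,
    end_distance = records$mean_end_distance >= config$min_end_distance
  )
  failed <- purrr::map(seq_len(n), function(i) {
    names(rules)[!purrr::map_lgl(rules, ~ .x[i])]
  })
  dplyr::mutate(records,
                pass = lengths(failed) == 0,
                failed_rules = failed)
}

#' Call putative germline variants from leukocyte records
#'
#' Keeps non-reference leukocyte observations with VAF between
#' `germline_vaf_low` and `germline_vaf_high` (inclusive) and leukocyte depth
#' of at least `germline_min_depth`.
#'
#' @param records Variant tibble with normal-side counts populated.
#' @param config A [filter_config()].
#' @return The subset of records passing the germline criteria.
#' @export
call_germline <- function(records, config = filter_config()) {
  nvaf <- records$normal_alt / records$normal_depth
  keep <- nvaf >= config$germline_vaf_low &
    nvaf <= config$germline_vaf_high &
    records$normal_depth >= config$germline_min_depth
  records[keep, ]
}

#' Write somatic filter verdicts as TSV
#'
#' One row per record with a logical column per rule plus the overall `pass`.
#'
#' @param verdicts Output of [call_somatic()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_verdicts <- function(verdicts, path) {
  rule_names <- c("vaf", "alt_reads", "depth", "normal_ratio",
                  "error_rate", "end_distance")
  out <- verdicts |>
    dplyr::select(-"failed_rules") |>
    dplyr::mutate(purrr::map_dfc(stats::setNames(rule_names, rule_names),
                                 function(r) {
                                   !purrr::map_lgl(verdicts$failed_rules,
                                                   ~ r %in% .x)
                                 }))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
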