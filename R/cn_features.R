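#' Copy-number feature schema
#'
#' Bin definitions for the six copy-number feature categories (45 features in
#' total): breakpoint counts per 10 Mb window (`BCper10Mb_0..5+`), breaks per
#' chromosome arm (`BCperCA_0..5+`), segment counts per integer copy state
#' (`CN_0..8+`), genome fraction per copy state (`CopyFraction_0..8+`),
#' segment-size histogram (`SegSize_1..10`, upper edges 5 kb, 50 kb, 500 kb,
#' 1 Mb, 3 Mb, 5 Mb, 10 Mb, 20 Mb, 50 Mb, Inf) and copy-number change points
#' between 5'-adjacent segments (`CNCP_1..5+`).
#'
#' @param count_max Top (open-ended) class for the two breakpoint-count
#'   categories and CNCP, default 5.
#' @param state_max Top copy state, default 8.
#' @param segsize_edges Upper bin edges in bp for the segment-size histogram.
#' @param window 10 Mb window size in bp for `BCper10Mb`.
#' @return A `darc_cn_schema` list.
#' @export
cn_schema <- function(count_max = 5L, state_max = 8L,
                      segsize_edges = c(5e3, 5e4, 5e5, 1e6, 3e6, 5e6,
                                        1e7, 2e7, 5e7, Inf),
                      window = 1e7) {
  stopifnot(all(diff(segsize_edges) > 0))
  schema <- list(count_max = count_max, state_max = state_max,
                 segsize_edges = segsize_edges, window = window)
  schema$names <- list(
    bc10 = paste0("BCper10Mb_", c(0:(count_max - 1), paste0(count_max, "+"))),
    bcca = paste0("BCperCA_", c(0:(count_max - 1), paste0(count_max, "+"))),
    cn = paste0("CN_", c(0:(state_max - 1), paste0(state_max, "+"))),
    cf = paste0("CopyFraction_", c(0:(state_max - 1), paste0(state_max, "+"))),
    segsize = paste0("SegSize_", seq_along(segsize_edges)),
    cncp = paste0("CNCP_", c(1:(count_max - 1), paste0(count_max, "+")))
  )
  structure(schema, class = "darc_cn_schema")
}

#' Canonical names of the 224-dimensional feature vector
#'
#' 96 substitution channels, then 83 indel channels, then the 45 copy-number
#' features in schema order.
#'
#' @param schema A [cn_schema()].
#' @return Character vector of length 224.
#' @export
feature_names <- function(schema = cn_schema()) {
  c(sbs_channels(), indel_channels(), unlist(schema$names, use.names = FALSE))
}

count_histogram <- function(counts, max_class) {
  binned <- pmin(counts, max_class)
  as.numeric(table(factor(binned, levels = 0:max_class)))
}

seg_lengths <- function(segments) segments$end - segments$start + 1

chrom_lengths <- function(arm_map) {
  m <- arm_map |> dplyr::distinct(.data$chrom, .data$length)
  stats::setNames(m$length, m$chrom)
}

#' Breakpoint count per 10 Mb window
#'
#' Tiles each chromosome into fixed windows and counts 3' segment endpoints
#' per window; each chromosome's terminal endpoint is excluded (a chromosome
#' end is not a break). Window counts are then histogrammed into the schema's
#' count classes, so the six values sum to the number of windows.
#'
#' @param segments Validated segment tibble.
#' @param arm_map A `darc_armmap` covering every segment chromosome.
#' @param schema A [cn_schema()].
#' @return Named numeric vector (6 bins).
#' @export
breakpoints_per_10mb <- function(segments, arm_map, schema = cn_schema()) {
  lens <- chrom_lengths(arm_map)
  check_chroms(segments, lens)
  window_counts <- unlist(lapply(names(lens), function(ch) {
    n_win <- ceiling(lens[[ch]] / schema$window)
    seg <- segments[segments$chrom == ch, ]
    counts <- numeric(n_win)
    if (nrow(seg) > 0) {
      ends <- seg$end[seg$end != max(seg$end)]  # drop terminal endpoint
      if (length(ends) > 0) {
        w <- ceiling(ends / schema$window)
        tab <- table(w)
        counts[as.integer(names(tab))] <- as.numeric(tab)
      }
    }
    counts
  }))
  stats::setNames(count_histogram(window_counts, schema$count_max),
                  schema$names$bc10)
}

check_chroms <- function(segments, lens) {
  missing <- setdiff(unique(segments$chrom), names(lens))
  if (length(missing) > 0) {
    stop("segment chromosome(s) absent from arm map: ",
         paste(missing, collapse = ", "))
  }
  too_far <- segments$end > lens[segments$chrom]
  if (any(too_far)) {
    stop("segment(s) beyond chromosome end on ",
         paste(unique(segments$chrom[too_far]), collapse = ", "))
  }
}

#' Breaks per chromosome arm
#'
#' Per arm, breaks = max(number of overlapping segments - 1, 0); a segment
#' straddling the centromere counts in both arms. Arm break counts are
#' histogrammed into the schema's count classes (values sum to the number of
#' arms).
#'
#' @inheritParams breakpoints_per_10mb
#' @return Named numeric vector (6 bins).
#' @export
breaks_per_arm <- function(segments, arm_map, schema = cn_schema()) {
  check_chroms(segments, chrom_lengths(arm_map))
  per_arm <- purrr::pmap_dbl(
    arm_map[c("chrom", "start", "end")],
    function(chrom, start, end) {
      n <- sum(segments$chrom == chrom &
                 segments$start <= end & segments$end >= start)
      max(n - 1, 0)
    })
  stats::setNames(count_histogram(per_arm, schema$count_max),
                  schema$names$bcca)
}

#' Segment counts per integer copy state
#'
#' @inheritParams breakpoints_per_10mb
#' @return Named numeric vector (9 bins, states 0..7 and 8+).
#' @export
cn_state_counts <- function(segments, schema = cn_schema()) {
  states <- pmin(segments$total_cn, schema$state_max)
  stats::setNames(
    as.numeric(table(factor(states, levels = 0:schema$state_max))),
    schema$names$cn)
}

#' Genome fraction per integer copy state
#'
#' Length-weighted fraction of the covered genome in each total-copy state;
#' sums to 1 whenever any segment exists.
#'
#' @inheritParams breakpoints_per_10mb
#' @return Named numeric vector (9 bins).
#' @export
copy_fraction <- function(segments, schema = cn_schema()) {
  out <- stats::setNames(numeric(schema$state_max + 1), schema$names$cf)
  if (nrow(segments) == 0) return(out)
  lens <- seg_lengths(segments)
  states <- pmin(segments$total_cn, schema$state_max)
  agg <- tapply(lens, factor(states, levels = 0:schema$state_max), sum,
                default = 0)
  out[] <- as.numeric(agg) / sum(lens)
  out
}

#' Segment-size histogram
#'
#' @inheritParams breakpoints_per_10mb
#' @return Named numeric vector (10 bins).
#' @export
segment_size_features <- function(segments, schema = cn_schema()) {
  out <- stats::setNames(numeric(length(schema$segsize_edges)),
                         schema$names$segsize)
  if (nrow(segments) == 0) return(out)
  bin <- findInterval(seg_lengths(segments),
                      c(0, schema$segsize_edges[-length(schema$segsize_edges)]),
                      left.open = TRUE)
  tab <- table(factor(bin, levels = seq_along(schema$segsize_edges)))
  out[] <- as.numeric(tab)
  out
}

#' Copy-number change points between adjacent segments
#'
#' For each within-chromosome adjacent segment pair, the absolute difference
#' in total copies between the segment and its 5' neighbour; differences of 0
#' are not change points and are not counted.
#'
#' @inheritParams breakpoints_per_10mb
#' @return Named numeric vector (5 bins, classes 1..4 and 5+).
#' @export
cncp_features <- function(segments, schema = cn_schema()) {
  out <- stats::setNames(numeric(schema$count_max), schema$names$cncp)
  if (nrow(segments) < 2) return(out)
  deltas <- segments |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(delta = abs(.data$total_cn -
                                dplyr::lag(.data$total_cn))) |>
    dplyr::ungroup() |>
    dplyr::pull(.data$delta)
  deltas <- deltas[!is.na(deltas) & deltas > 0]
  if (length(deltas) == 0) return(out)
  tab <- table(factor(pmin(deltas, schema$count_max),
                      levels = 1:schema$count_max))
  out[] <- as.numeric(tab)
  out
}

#' Extract the 45 copy-number features
#'
#' Concatenates the six category vectors in schema order with stable names.
#'
#' @inheritParams breakpoints_per_10mb
#' @return Named numeric vector of length 45.
#' @export
extract_cn_features <- function(segments, arm_map, schema = cn_schema()) {
  nm <- unlist(schema$names, use.names = FALSE)
  if (nrow(segments) == 0) {
    return(stats::setNames(numeric(length(nm)), nm))  # no data, no features
  }
  segments <- dplyr::arrange(segments, .data$chrom, .data$start)
  c(breakpoints_per_10mb(segments, arm_map, schema),
    breaks_per_arm(segments, arm_map, schema),
    cn_state_counts(segments, schema),
    copy_fraction(segments, schema),
    segment_size_features(segments, schema),
    cncp_features(segments, schema))
}
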