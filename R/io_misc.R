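#' Read a UCSC cytoband file into a chromosome arm map
#'
#' Parses the standard 5-column `cytoBand.txt` layout (chrom, 0-based start,
#' end, band, Giemsa stain; half-open intervals converted to 1-based
#' inclusive on read). Arms are assembled from band-name prefixes (`p*`/`q*`),
#' the centromere midpoint from the `acen` bands (falling back to the p/q
#' boundary), and chromosome length from the maximum band end.
#'
#' @param path Cytoband file (optionally gzipped).
#' @param strip_chr Drop a leading `"chr"` from chromosome names.
#' @return A `darc_armmap`: tibble with one row per arm (`chrom`, `arm`,
#'   `start`, `end`) plus per-chromosome `length` and `centromere` columns.
#' @export
read_cytobands <- function(path, strip_chr = FALSE) {
  if (!file.exists(path)) stop("cytoband file not found: ", path)
  df <- readr::read_tsv(path,
                        col_names = c("chrom", "start", "end", "band", "stain"),
                        col_types = "ciicc", progress = FALSE)
  if (nrow(df) == 0) stop("cytoband file is empty")
  if (strip_chr) df$chrom <- sub("^chr", "", df$chrom)
  df$start <- df$start + 1L  # half-open 0-based -> 1-based inclusive
  df$arm <- substr(df$band, 1, 1)
  if (!all(df$arm %in% c("p", "q"))) {
    stop("band names must start with p or q")
  }
  per_arm <- df |>
    dplyr::group_by(.data$chrom, .data$arm) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     .groups = "drop")
  both <- per_arm |>
    dplyr::count(.data$chrom) |>
    dplyr::filter(.data$n < 2)
  if (nrow(both) > 0) {
    stop("chromosome(s) lacking both arms: ",
         paste(both$chrom, collapse = ", "))
  }
  meta <- df |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(
      length = max(.data$end),
      centromere = centromere_pos(.data$start, .data$end, .data$stain,
                                  .data$arm),
      .groups = "drop")
  arm_map <- per_arm |>
    dplyr::left_join(meta, by = "chrom") |>
    dplyr::arrange(.data$chrom, .data$arm)
  structure(arm_map, class = c("darc_armmap", class(arm_map)))
}

centromere_pos <- function(start, end, stain, arm) {
  acen <- stain == "acen"
  if (any(acen)) {
    return(round((min(start[acen]) + max(end[acen])) / 2))
  }
  max(end[arm == "p"])
}

#' Build an arm map directly from chromosome lengths
#'
#' Convenience constructor for synthetic genomes: p arm spans
#' `[1, centromere]`, q arm `[centromere + 1, length]`.
#'
#' @param lengths Named integer vector of chromosome lengths.
#' @param centromeres Named vector of centromere positions; defaults to 40%
#'   of each length.
#' @return A `darc_armmap` tibble.
#' @export
arm_map_from_lengths <- function(lengths,
                                 centromeres = round(lengths * 0.4)) {
  stopifnot(!is.null(names(lengths)))
  arm_map <- purrr::map_dfr(names(lengths), function(ch) {
    tibble::tibble(
      chrom = ch,
      arm = c("p", "q"),
      start = c(1L, as.integer(centromeres[[ch]]) + 1L),
      end = c(as.integer(centromeres[[ch]]), as.integer(lengths[[ch]])),
      length = as.integer(lengths[[ch]]),
      centromere = as.integer(centromeres[[ch]])
    )
  })
  structure(arm_map, class = c("darc_armmap", class(arm_map)))
}

#' Write an arm map as a UCSC-style cytoband file
#'
#' Emits two Giemsa bands plus two `acen` bands per chromosome — enough
#' structure for [read_cytobands()] to reconstruct the same arm map.
#'
#' @param arm_map A `darc_armmap`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cytobands <- function(arm_map, path) {
  rows <- arm_map |>
    dplyr::distinct(.data$chrom, .data$length, .data$centromere) |>
    purrr::pmap_dfr(function(chrom, length, centromere) {
      acen_half <- max(1L, round(length * 0.005))
      tibble::tibble(
        chrom = chrom,
        start = c(0L, centromere - acen_half, centromere,
                  centromere + acen_half),
        end = c(centromere - acen_half, centromere,
                centromere + acen_half, length),
        band = c("p11", "p10", "q10", "q11"),
        stain = c("gneg", "acen", "acen", "gneg")
      )
    })
  readr::write_tsv(rows, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a reference signature matrix
#'
#' Expects a TSV with the 96 substitution channel names in the first column
#' (any order; reordered canonically on read) and one named column of
#' per-channel probabilities per signature. Columns must be non-negative and
#' sum to 1 within `1e-6`.
#'
#' @param path Signature matrix TSV.
#' @return Numeric matrix, 96 canonical rows x named signature columns.
#' @export
read_signature_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  chan <- df[[1]]
  if (!setequal(chan, sbs_channels()) || length(chan) != 96) {
    stop("signature matrix must have exactly the 96 substitution channels")
  }
  m <- as.matrix(df[-1])
  rownames(m) <- chan
  m <- m[sbs_channels(), , drop = FALSE]
  validate_signature_matrix(m)
}

validate_signature_matrix <- function(m) {
  if (nrow(m) != 96) stop("signature matrix must have 96 rows")
  if (any(m < 0)) stop("signature probabilities must be non-negative")
  s <- colSums(m)
  if (any(abs(s - 1) > 1e-6)) {
    stop("signature column(s) not summing to 1: ",
         paste(colnames(m)[abs(s - 1) > 1e-6], collapse = ", "))
  }
  m
}

#' Read repeat regions from a BED file
#'
#' Minimal three-column BED reader (0-based half-open, converted to 1-based
#' inclusive) for catalogued repeat regions used by the repeat-adjacency
#' filter flag.
#'
#' @param path BED path.
#' @return Tibble with `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_repeat_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                        progress = FALSE)
  if (ncol(df) < 3) stop("BED needs at least 3 columns")
  tibble::tibble(chrom = as.character(df[[1]]),
                 start = as.integer(df[[2]]) + 1L,
                 end = as.integer(df[[3]]))
}

#' Flag variants adjacent to catalogued repeat regions
#'
#' @param variants Variant tibble.
#' @param repeats Repeat tibble from [read_repeat_bed()].
#' @param pad Adjacency padding in bp (default 5).
#' @return The variants with `repeat_adjacent` recomputed.
#' @export
flag_repeat_adjacent <- function(variants, repeats, pad = 5L) {
  variants$repeat_adjacent <- purrr::map_lgl(
    seq_len(nrow(variants)),
    function(i) {
      r <- repeats[repeats$chrom == variants$chrom[i], ]
      any(variants$pos[i] >= r$start - pad & variants$pos[i] <= r$end + pad)
    })
  variants
}

#' Read or write a samples-by-features matrix TSV
#'
#' The on-disk layout is one row per sample with a leading `sample_id`
#' column followed by the named feature columns in canonical order.
#'
#' @param x Feature tibble (for writing).
#' @param path File path.
#' @return `read_feature_matrix`: tibble with `sample_id` plus feature
#'   columns. `write_feature_matrix`: `path`, invisibly.
#' @export
read_feature_matrix <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(sample_id = "c",
                                          .default = readr::col_double()))
}

#' @rdname read_feature_matrix
#' @export
write_feature_matrix <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
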