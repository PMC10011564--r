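#' Read an allele-specific copy-number segment table
#'
#' Reads the tab-separated segment dialect emitted by the upstream
#' purity/ploidy caller: one row per segment with chromosome, start, end,
#' total copies and major/minor allele copies, 1-based inclusive coordinates.
#' Column names are configurable through `aliases` because schema versions
#' differ. Rows are validated (integer copies, `major + minor = total`,
#' `major >= minor >= 0`, no within-chromosome overlap) and returned sorted.
#'
#' Solution-level metadata (`cellularity`, `ploidy`) is picked up either from
#' identically-named columns (constant per file) or from `# key value` header
#' comments.
#'
#' @param path Path to the segment file.
#' @param aliases Named list mapping internal names (`chrom`, `start`, `end`,
#'   `total_cn`, `major_cn`, `minor_cn`) to the column names in the file.
#' @param strip_chr Drop a leading `"chr"` from chromosome names.
#' @return A `darc_solution`: list with `segments` (tibble), `cellularity`,
#'   `mean_ploidy` (either may be `NA`).
#' @export
read_segments <- function(path,
                          aliases = list(
                            chrom = "chromosome", start = "start.pos",
                            end = "end.pos", total_cn = "CNt",
                            major_cn = "A", minor_cn = "B"),
                          strip_chr = FALSE) {
  if (!file.exists(path)) stop("segment file not found: ", path)
  header_meta <- read_header_meta(path)
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  missing <- setdiff(unlist(aliases), names(df))
  if (length(missing) > 0) {
    stop("segment file is missing required columns: ",
         paste(missing, collapse = ", "))
  }
  seg <- tibble::tibble(
    chrom = as.character(df[[aliases$chrom]]),
    start = df[[aliases$start]],
    end = df[[aliases$end]],
    total_cn = df[[aliases$total_cn]],
    major_cn = df[[aliases$major_cn]],
    minor_cn = df[[aliases$minor_cn]]
  )
  if (strip_chr) seg$chrom <- sub("^chr", "", seg$chrom)
  cellularity <- first_scalar(df, header_meta, "cellularity")
  mean_ploidy <- first_scalar(df, header_meta, c("ploidy", "mean_ploidy"))
  new_solution(validate_segments(seg), cellularity, mean_ploidy)
}

read_header_meta <- function(path) {
  lines <- readLines(path, n = 20L)
  lines <- lines[startsWith(lines, "#")]
  out <- list()
  for (l in lines) {
    parts <- strsplit(trimws(sub("^#+\\s*", "", l)), "[\t =]+")[[1]]
    if (length(parts) == 2) out[[parts[1]]] <- suppressWarnings(as.numeric(parts[2]))
  }
  out
}

first_scalar <- function(df, meta, keys) {
  for (k in keys) {
    if (k %in% names(df)) return(as.numeric(df[[k]][1]))
    if (!is.null(meta[[k]])) return(meta[[k]])
  }
  NA_real_
}

#' Validate a segment tibble
#'
#' Enforces the segment invariants: positive integer-valued copy numbers with
#' `major + minor = total` and `major >= minor >= 0`, `start <= end`, and
#' non-overlapping segments per chromosome. Returns the segments sorted by
#' chromosome then start.
#'
#' @param seg Tibble with columns `chrom`, `start`, `end`, `total_cn`,
#'   `major_cn`, `minor_cn`.
#' @return The validated, sorted tibble.
#' @export
validate_segments <- function(seg) {
  req <- c("chrom", "start", "end", "total_cn", "major_cn", "minor_cn")
  missing <- setdiff(req, names(seg))
  if (length(missing) > 0) {
    stop("segments missing columns: ", paste(missing, collapse = ", "))
  }
  cn <- c(seg$total_cn, seg$major_cn, seg$minor_cn)
  if (any(is.na(cn)) || any(cn != round(cn)) || any(cn < 0)) {
    stop("copy numbers must be non-negative integers")
  }
  if (any(seg$start > seg$end)) stop("segment start exceeds end")
  if (any(seg$start < 1)) stop("segment coordinates are 1-based; start < 1")
  bad <- seg$major_cn + seg$minor_cn != seg$total_cn
  if (any(bad)) {
    stop("major_cn + minor_cn != total_cn at row(s) ",
         paste(which(bad), collapse = ", "))
  }
  bad <- seg$major_cn < seg$minor_cn
  if (any(bad)) {
    stop("major_cn < minor_cn at row(s) ", paste(which(bad), collapse = ", "))
  }
  seg <- dplyr::arrange(seg, .data$chrom, .data$start)
  ov <- seg |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(.row = dplyr::row_number(),
                  overlap = .data$start <= dplyr::lag(.data$end,
                                                      default = 0L)) |>
    dplyr::ungroup()
  if (any(ov$overlap)) {
    i <- which(ov$overlap)[1]
    stop(sprintf(
      "overlapping segments on %s: sorted rows %d-%d ([%d,%d] then [%d,%d])",
      ov$chrom[i], i - 1L, i, seg$start[i - 1L], seg$end[i - 1L],
      seg$start[i], seg$end[i]))
  }
  dplyr::mutate(seg, dplyr::across(
    c("total_cn", "major_cn", "minor_cn"), as.integer))
}

new_solution <- function(segments, cellularity = NA_real_,
                         mean_ploidy = NA_real_) {
  structure(
    list(segments = segments, cellularity = cellularity,
         mean_ploidy = mean_ploidy),
    class = "darc_solution"
  )
}

#' @export
print.darc_solution <- function(x, ...) {
  cat("<darc_solution>", nrow(x$segments), "segments | cellularity:",
      x$cellularity, "| mean ploidy:", x$mean_ploidy, "\n")
  invisible(x)
}

#' Accept or reject an upstream segmentation solution
#'
#' Low tumour fraction precludes reliable determination of non-diploid
#' status, so a solution whose mean ploidy falls outside `[1.1, 2.9]` is
#' accepted only when the estimated cellularity exceeds 0.18. Near-diploid
#' solutions are always accepted.
#'
#' @param solution A `darc_solution` (or any list with `mean_ploidy` and
#'   `cellularity`).
#' @param ploidy_range Ploidy band treated as diploid-like, default
#'   `c(1.1, 2.9)`.
#' @param min_cellularity Cellularity needed to trust a non-diploid call,
#'   default 0.18 (exclusive).
#' @return `TRUE` if the solution is accepted.
#' @export
accept_solution <- function(solution, ploidy_range = c(1.1, 2.9),
                            min_cellularity = 0.18) {
  p <- solution$mean_ploidy
  c_ <- solution$cellularity
  if (is.null(p) || is.na(p)) stop("solution lacks mean_ploidy")
  if (p >= ploidy_range[1] && p <= ploidy_range[2]) return(TRUE)
  if (is.null(c_) || is.na(c_)) stop("non-diploid solution lacks cellularity")
  c_ > min_cellularity
}

#' Write a segment table in the upstream caller dialect
#'
#' @param solution A `darc_solution` or a plain segment tibble.
#' @param path Output path.
#' @param aliases Column-name mapping as in [read_segments()].
#' @return `path`, invisibly.
#' @export
write_segments <- function(solution, path,
                           aliases = list(
                             chrom = "chromosome", start = "start.pos",
                             end = "end.pos", total_cn = "CNt",
                             major_cn = "A", minor_cn = "B")) {
  seg <- if (inherits(solution, "darc_solution")) solution$segments else solution
  out <- tibble::tibble(
    !!aliases$chrom := seg$chrom,
    !!aliases$start := seg$start,
    !!aliases$end := seg$end,
    !!aliases$total_cn := seg$total_cn,
    !!aliases$major_cn := seg$major_cn,
    !!aliases$minor_cn := seg$minor_cn
  )
  hdr <- character(0)
  if (inherits(solution, "darc_solution")) {
    if (!is.na(solution$cellularity)) {
      hdr <- c(hdr, paste0("# cellularity ", solution$cellularity))
    }
    if (!is.na(solution$mean_ploidy)) {
      hdr <- c(hdr, paste0("# ploidy ", solution$mean_ploidy))
    }
  }
  writeLines(c(hdr, paste(names(out), collapse = "\t")), path)
  readr::write_tsv(out, path, append = TRUE, col_names = FALSE,
                   progress = FALSE)
  invisible(path)
}
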