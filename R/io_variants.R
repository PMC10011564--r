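variant_cols <- c("chrom", "pos", "ref", "alt", "tumour_depth", "tumour_alt",
                  "normal_depth", "normal_alt", "mean_end_distance",
                  "context", "repeat_adjacent")

#' Read candidate small variants
#'
#' Supports two dialects: a documented plain TSV with one row per candidate
#' variant (columns `chrom, pos, ref, alt, tumour_depth, tumour_alt,
#' normal_depth, normal_alt, mean_end_distance, context, repeat_adjacent`) and
#' VCF, where pileup evidence is taken from per-sample `DP`/`AD` FORMAT
#' fields and the extra record fields from the INFO keys `MED` (mean
#' end-of-read distance), `CTX` (reference context) and `REPADJ` (repeat
#' adjacency). Indel alleles are reduced to minimal representation and
#' left-aligned within the available context so channel assignment never
#' depends on the caller's allele style. Records with symbolic alleles
#' (`<DEL>` etc.) or unresolvable context are excluded with a warning.
#'
#' @param path Input file.
#' @param dialect `"tabular"` or `"vcf"`.
#' @param tumour,normal Sample column names for the VCF dialect.
#' @param strip_chr Drop a leading `"chr"` from chromosome names.
#' @return Tibble of validated variant records.
#' @export
read_variants <- function(path, dialect = c("tabular", "vcf"),
                          tumour = "TUMOUR", normal = "NORMAL",
                          strip_chr = FALSE) {
  dialect <- match.arg(dialect)
  v <- if (dialect == "tabular") {
    read_variants_tsv(path)
  } else {
    read_variants_vcf(path, tumour, normal)
  }
  if (strip_chr) v$chrom <- sub("^chr", "", v$chrom)
  normalize_variants(validate_variants(v))
}

read_variants_tsv <- function(path) {
  if (!file.exists(path)) stop("variant file not found: ", path)
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          chrom = "c", ref = "c", alt = "c", context = "c",
                          .default = readr::col_guess()))
  missing <- setdiff(variant_cols, names(df))
  if (length(missing) > 0) {
    stop("variant table missing columns: ", paste(missing, collapse = ", "))
  }
  tibble::as_tibble(df[variant_cols])
}

read_variants_vcf <- function(path, tumour, normal) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("the vcf dialect requires the vcfR package")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(vcf)))
  symbolic <- grepl("[][<>]", fix$ALT)
  if (any(symbolic)) {
    warning(sum(symbolic), " record(s) with symbolic/breakend alleles excluded")
  }
  dp <- vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
  ad <- vcfR::extract.gt(vcf, element = "AD")
  for (s in c(tumour, normal)) {
    if (!s %in% colnames(dp)) stop("VCF lacks sample column: ", s)
  }
  alt_count <- function(x) as.integer(vapply(
    strsplit(x, ","), function(p) p[2], character(1)))
  med <- as.numeric(vcfR::extract.info(vcf, "MED"))
  ctx <- vcfR::extract.info(vcf, "CTX")
  info <- vcfR::getINFO(vcf)  # REPADJ is a Flag: test for key presence
  rep_adj <- grepl("(^|;)REPADJ(;|$)", info)
  v <- tibble::tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    tumour_depth = as.integer(dp[, tumour]),
    tumour_alt = alt_count(ad[, tumour]),
    normal_depth = as.integer(dp[, normal]),
    normal_alt = alt_count(ad[, normal]),
    mean_end_distance = med,
    context = ctx,
    repeat_adjacent = rep_adj
  )
  v[!symbolic, ]
}

validate_variants <- function(v) {
  no_ctx <- is.na(v$context) | v$context == ""
  if (any(no_ctx)) {
    warning(sum(no_ctx), " record(s) with unresolvable context excluded")
    v <- v[!no_ctx, ]
  }
  if (any(v$pos < 1)) stop("positions are 1-based; pos < 1 found")
  if (any(v$tumour_alt > v$tumour_depth | v$normal_alt > v$normal_depth)) {
    stop("supporting reads exceed depth")
  }
  if (any(v$ref == v$alt)) stop("ref == alt record found")
  v
}

# Minimal representation + left alignment of one indel within its context.
normalize_one <- function(pos, ref, alt, context, flank = 20L) {
  # trim shared suffix (keep >=1 base in the longer allele)
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, nchar(ref), nchar(ref)) ==
         substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1, nchar(ref) - 1)
    alt <- substr(alt, 1, nchar(alt) - 1)
  }
  # trim shared prefix down to the single VCF anchor
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1L
  }
  if (nchar(ref) == nchar(alt)) {
    return(list(pos = pos, ref = ref, alt = alt, context = context))
  }
  is_del <- nchar(ref) > nchar(alt)
  anchored <- substr(ref, 1, 1) == substr(alt, 1, 1)
  d <- if (is_del) substr(ref, 2 - !anchored, nchar(ref)) else
    substr(alt, 2 - !anchored, nchar(alt))
  len <- nchar(d)
  # context layout: [flank bp ending at the anchor][deleted tract][flank bp]
  left <- substr(context, 1, flank)
  right_start <- flank + (if (is_del) len else 0L) + 1L
  right <- substr(context, right_start, nchar(context))
  # shift left while the base preceding the event equals the event's last base
  while (nchar(left) > (if (anchored) 1L else 0L) &&
         substr(left, nchar(left), nchar(left)) == substr(d, len, len)) {
    last_l <- substr(left, nchar(left), nchar(left))
    right <- paste0(substr(d, len, len), right)
    d <- paste0(last_l, substr(d, 1, len - 1L))
    left <- substr(left, 1, nchar(left) - 1L)
    pos <- pos - 1L
  }
  ctx2 <- paste0(str_pad_left(left, flank),
                 if (is_del) d else "",
                 substr(right, 1, flank))
  if (anchored) {
    anchor <- substr(left, nchar(left), nchar(left))
    list(pos = pos,
         ref = if (is_del) paste0(anchor, d) else anchor,
         alt = if (is_del) anchor else paste0(anchor, d),
         context = ctx2)
  } else {
    list(pos = pos, ref = if (is_del) d else "",
         alt = if (is_del) "" else d, context = ctx2)
  }
}

str_pad_left <- function(s, n) {
  if (nchar(s) >= n) substr(s, nchar(s) - n + 1L, nchar(s)) else
    paste0(strrep("N", n - nchar(s)), s)
}

normalize_variants <- function(v, flank = 20L) {
  if (nrow(v) == 0) return(v)
  idx <- which(nchar(v$ref) != nchar(v$alt))
  for (i in idx) {
    n <- normalize_one(v$pos[i], v$ref[i], v$alt[i], v$context[i], flank)
    v$pos[i] <- n$pos; v$ref[i] <- n$ref; v$alt[i] <- n$alt
    v$context[i] <- n$context
  }
  v
}

#' Write variant records
#'
#' Writes the tabular dialect read back by [read_variants()], or a minimal
#' VCF 4.2 with `DP`/`AD` FORMAT fields for the tumour and normal samples and
#' `MED`/`CTX`/`REPADJ` INFO keys.
#'
#' @param variants Tibble of variant records.
#' @param path Output path.
#' @param dialect `"tabular"` or `"vcf"`.
#' @param tumour,normal Sample names for the VCF dialect.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path, dialect = c("tabular", "vcf"),
                           tumour = "TUMOUR", normal = "NORMAL") {
  dialect <- match.arg(dialect)
  if (dialect == "tabular") {
    readr::write_tsv(variants[variant_cols], path, progress = FALSE)
    return(invisible(path))
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=MED,Number=1,Type=Float,Description=\"Mean distance from supporting read ends to variant (bp)\">",
    "##INFO=<ID=CTX,Number=1,Type=String,Description=\"Reference context around the variant\">",
    "##INFO=<ID=REPADJ,Number=0,Type=Flag,Description=\"Adjacent to catalogued repeat region\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", tumour, normal, sep = "\t")
  )
  info <- paste0(
    "MED=", variants$mean_end_distance,
    ";CTX=", variants$context,
    ifelse(variants$repeat_adjacent, ";REPADJ", "")
  )
  rows <- paste(
    variants$chrom, variants$pos, ".", variants$ref, variants$alt, ".",
    "PASS", info, "DP:AD",
    paste0(variants$tumour_depth, ":",
           variants$tumour_depth - variants$tumour_alt, ",",
           variants$tumour_alt),
    paste0(variants$normal_depth, ":",
           variants$normal_depth - variants$normal_alt, ",",
           variants$normal_alt),
    sep = "\t"
  )
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Load a reference FASTA
#'
#' @param path FASTA path.
#' @return A `Biostrings::DNAStringSet` keyed by contig name.
#' @export
read_reference <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("read_reference() requires the Biostrings package")
  }
  ref <- Biostrings::readDNAStringSet(path)
  names(ref) <- sub("\\s.*$", "", names(ref))
  ref
}

#' Fetch reference context around a position
#'
#' Returns the uppercase window `pos - flank .. pos + span - 1 + flank`
#' (1-based inclusive), i.e. `2*flank + 1` bases for an SNV and `flank` bases
#' either side of a `span`-long tract for a deletion. An `N` in the window is
#' tolerated (downstream classification routes such records to
#' `unclassified`); a window falling outside the contig is an error.
#'
#' @param reference A `DNAStringSet` from [read_reference()].
#' @param chrom Contig name.
#' @param pos 1-based position of the variant (first affected base).
#' @param flank Flank size in bp (default 20).
#' @param span Length of the affected reference tract (1 for SNVs).
#' @return Character scalar context sequence.
#' @export
fetch_context <- function(reference, chrom, pos, flank = 20L, span = 1L) {
  if (!chrom %in% names(reference)) stop("unknown contig: ", chrom)
  n <- length(reference[[chrom]])
  lo <- pos - flank
  hi <- pos + span - 1L + flank
  if (lo < 1 || hi > n) {
    stop(sprintf("context window [%d,%d] outside contig %s (1..%d)",
                 lo, hi, chrom, n))
  }
  toupper(as.character(Biostrings::subseq(reference[[chrom]], lo, hi)))
}
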