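#' Canonical mutation channel names
#'
#' `sbs_channels()` returns the 96 single-base-substitution channels in
#' canonical order: the six pyrimidine substitution classes (C>A, C>G, C>T,
#' T>A, T>C, T>G), each crossed with the 16 flanking-base combinations in
#' alphabetical order, named like `"A[C>G]G"`. `indel_channels()` returns the
#' 83 small insertion/deletion channels: 1 bp deletions and insertions of C or
#' T by homopolymer-length class (24), longer deletions and insertions by
#' length class 2/3/4/5+ and adjacent tandem-repeat-copy class (48), and
#' deletions with flanking microhomology by length and microhomology size
#' (11), named like `"1:Del:C:5"` or `"3:Del:M:2"`.
#'
#' @return Character vector of channel names (length 96 or 83).
#' @export
sbs_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    ref <- substr(s, 1, 1)
    as.vector(t(outer(bases, bases, function(l, r) paste0(l, "[", s, "]", r))))
  }))
}

#' @rdname sbs_channels
#' @export
indel_channels <- function() {
  hp <- 0:5
  one_bp <- c(
    paste0("1:Del:C:", hp), paste0("1:Del:T:", hp),
    paste0("1:Ins:C:", hp), paste0("1:Ins:T:", hp)
  )
  rep_cls <- 0:5
  long_del <- unlist(lapply(2:5, function(l) paste0(l, ":Del:R:", rep_cls)))
  long_ins <- unlist(lapply(2:5, function(l) paste0(l, ":Ins:R:", rep_cls)))
  mh <- c(
    "2:Del:M:1",
    paste0("3:Del:M:", 1:2),
    paste0("4:Del:M:", 1:3),
    paste0("5:Del:M:", 1:5)
  )
  c(one_bp, long_del, long_ins, mh)
}

DNA_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse-complement a DNA string
#'
#' Minimal uppercase-DNA reverse complement used for pyrimidine-strand
#' normalization of mutation channels (A/C/G/T/N only).
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(strsplit(toupper(x), ""), function(b) {
    paste(rev(unname(DNA_COMP[b])), collapse = "")
  }, character(1))
}

#' Classify a single-base substitution into its 96-channel name
#'
#' Purine-reference variants are projected onto the pyrimidine strand by
#' reverse complementation, so `G>A` in `CGT` and `C>T` in `ACA`-style
#' contexts land on the same channel set. The context may be any odd-length
#' window centred on the variant (e.g. the 41 bp record context); only the
#' trinucleotide core is used.
#'
#' @param ref,alt Single reference/alternate bases.
#' @param context Odd-length reference sequence centred on the variant;
#'   its middle base must equal `ref`.
#' @return The channel name, or `NA_character_` when the trinucleotide
#'   contains a base outside A/C/G/T (unclassifiable).
#' @export
classify_sbs <- function(ref, alt, context) {
  stopifnot(length(ref) == 1, length(alt) == 1, length(context) == 1)
  ref <- toupper(ref); alt <- toupper(alt); context <- toupper(context)
  if (nchar(ref) != 1 || nchar(alt) != 1 || ref == alt) {
    stop("classify_sbs() expects distinct single-base alleles")
  }
  n <- nchar(context)
  if (n %% 2 != 1) stop("context must have odd length")
  mid <- (n + 1) / 2
  if (substr(context, mid, mid) != ref) {
    stop("middle base of context does not match ref allele")
  }
  tri <- substr(context, mid - 1, mid + 1)
  if (grepl("[^ACGT]", tri) || !alt %in% c("A", "C", "G", "T")) {
    return(NA_character_)
  }
  if (ref %in% c("A", "G")) {
    tri <- revcomp(tri)
    ref <- unname(DNA_COMP[ref])
    alt <- unname(DNA_COMP[alt])
  }
  paste0(
    substr(tri, 1, 1), "[", ref, ">", alt, "]", substr(tri, 3, 3)
  )
}

# Run length of base `b` at the right end of `s` (suffix) or left end (prefix).
run_suffix <- function(s, b) {
  n <- nchar(s); k <- 0L
  while (k < n && substr(s, n - k, n - k) == b) k <- k + 1L
  k
}
run_prefix <- function(s, b) {
  n <- nchar(s); k <- 0L
  while (k < n && substr(s, k + 1L, k + 1L) == b) k <- k + 1L
  k
}

# Number of full tandem copies of `unit` at the start of `s`.
tandem_copies_prefix <- function(s, unit) {
  l <- nchar(unit); k <- 0L
  while (substr(s, k * l + 1L, (k + 1L) * l) == unit) k <- k + 1L
  k
}
# Number of full tandem copies of `unit` at the end of `s`.
tandem_copies_suffix <- function(s, unit) {
  l <- nchar(unit); n <- nchar(s); k <- 0L
  while ((k + 1L) * l <= n &&
         substr(s, n - (k + 1L) * l + 1L, n - k * l) == unit) k <- k + 1L
  k
}

# Longest k such that the first k bases of `a` equal the first k of `b`.
common_prefix_len <- function(a, b) {
  m <- min(nchar(a), nchar(b)); k <- 0L
  while (k < m && substr(a, k + 1L, k + 1L) == substr(b, k + 1L, k + 1L)) {
    k <- k + 1L
  }
  k
}
common_suffix_len <- function(a, b) {
  na <- nchar(a); nb <- nchar(b); m <- min(na, nb); k <- 0L
  while (k < m && substr(a, na - k, na - k) == substr(b, nb - k, nb - k)) {
    k <- k + 1L
  }
  k
}

#' Classify a small insertion or deletion into its 83-channel name
#'
#' Implements the 83-channel indel scheme: 1 bp events are typed by the
#' (pyrimidine-normalized) base and the length of the homopolymer they sit in
#' (for deletions, the reference run including the deleted base, label
#' `run - 1` capped at 5; for insertions the pre-existing run, capped at 5).
#' Longer events are typed by length class (2,3,4,5+) and the number of
#' additional full tandem copies of the event sequence adjacent in the
#' reference (0–5+). Deletions with no adjacent copy but with sequence shared
#' between the deleted tract's ends and the flank are classed as
#' microhomology deletions; the repeat test takes precedence over the
#' microhomology test.
#'
#' @param ref,alt Minimal left-aligned alleles in VCF style: one is a prefix
#'   of the other (e.g. `ref = "AC", alt = "A"` deletes one C) or the pure
#'   inserted/deleted sequence with an empty counterpart.
#' @param left_flank,right_flank Reference sequence immediately 5' and 3' of
#'   the affected tract (for deletions the tract is the deleted bases; for
#'   insertions the insertion point). The VCF anchor base, when present, is
#'   the last base of `left_flank`.
#' @return The channel name, or `NA_character_` for complex substitutions
#'   (both alleles longer than 1 after trimming) or degenerate sequence.
#' @export
classify_indel <- function(ref, alt, left_flank, right_flank) {
  ref <- toupper(ref); alt <- toupper(alt)
  left_flank <- toupper(left_flank); right_flank <- toupper(right_flank)
  # strip shared VCF anchor prefix (already the tail of left_flank)
  k <- common_prefix_len(ref, alt)
  if (k > 0) {
    ref <- substr(ref, k + 1L, nchar(ref))
    alt <- substr(alt, k + 1L, nchar(alt))
  }
  if (nchar(ref) > 0 && nchar(alt) > 0) return(NA_character_)  # complex/MNV
  if (nchar(ref) == 0 && nchar(alt) == 0) stop("ref and alt are identical")
  is_del <- nchar(ref) > 0
  seq <- if (is_del) ref else alt
  if (grepl("[^ACGT]", seq)) return(NA_character_)
  len <- nchar(seq)
  lenc <- min(len, 5L)
  if (len == 1L) {
    b <- seq
    run <- run_suffix(left_flank, b) + run_prefix(right_flank, b)
    base <- if (b %in% c("A", "G")) unname(DNA_COMP[b]) else b
    if (is_del) {
      lab <- min(run, 5L)  # run incl. deleted base is run+1; label = run
      return(paste0("1:Del:", base, ":", lab))
    }
    return(paste0("1:Ins:", base, ":", min(run, 5L)))
  }
  copies <- tandem_copies_prefix(right_flank, seq) +
    tandem_copies_suffix(left_flank, seq)
  if (!is_del) {
    return(paste0(lenc, ":Ins:R:", min(copies, 5L)))
  }
  if (copies >= 1L) {
    return(paste0(lenc, ":Del:R:", min(copies, 5L)))
  }
  mh <- max(common_prefix_len(seq, right_flank),
            common_suffix_len(seq, left_flank))
  mh <- min(mh, len - 1L)
  if (mh >= 1L) {
    mh_cap <- if (len >= 5L) 5L else len - 1L
    return(paste0(lenc, ":Del:M:", min(mh, mh_cap)))
  }
  paste0(lenc, ":Del:R:0")
}

is_snv_allele <- function(ref, alt) {
  nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    ref != alt
}

# Split an indel record's context field into flanks around the affected tract.
# Deletion context layout: [flank bp left][deleted tract][flank bp right];
# insertion context: [flank][flank] around the insertion point.
indel_flanks <- function(ref, alt, context, flank = 20L) {
  k <- common_prefix_len(ref, alt)
  del_len <- max(nchar(ref) - k, 0L)
  left <- substr(context, 1L, flank)
  right <- substr(context, flank + del_len + 1L, nchar(context))
  list(left = left, right = right)
}

#' Build a per-sample mutation catalog
#'
#' Counts filtered somatic variants over the 96 substitution channels and the
#' 83 indel channels. Records that cannot be classified (degenerate context,
#' complex substitutions, multi-nucleotide variants) are tallied in
#' `unclassified`, never dropped silently, so
#' `sum(sbs) + sum(indel) + unclassified` always equals the number of input
#' records.
#'
#' @param variants Tibble of variant records with columns `ref`, `alt`,
#'   `context` (±`flank` bp for SNVs; `flank` bp each side of the affected
#'   tract for indels).
#' @param sample_id Sample identifier stored on the catalog.
#' @param flank Flank size used when the contexts were extracted (bp).
#' @return A `darc_catalog`: list with `sample_id`, named integer vectors
#'   `sbs` (96) and `indel` (83), and `unclassified`.
#' @export
build_catalog <- function(variants, sample_id = "sample", flank = 20L) {
  sbs_names <- sbs_channels()
  id_names <- indel_channels()
  sbs <- stats::setNames(integer(96), sbs_names)
  ind <- stats::setNames(integer(83), id_names)
  uncl <- 0L
  if (nrow(variants) > 0) {
    for (i in seq_len(nrow(variants))) {
      ref <- toupper(variants$ref[i]); alt <- toupper(variants$alt[i])
      ctx <- toupper(variants$context[i])
      ch <- if (is_snv_allele(ref, alt)) {
        classify_sbs(ref, alt, ctx)
      } else if (nchar(ref) != nchar(alt)) {
        fl <- indel_flanks(ref, alt, ctx, flank)
        classify_indel(ref, alt, fl$left, fl$right)
      } else {
        NA_character_  # MNV / double-base substitution
      }
      if (is.na(ch)) {
        uncl <- uncl + 1L
      } else if (ch %in% sbs_names) {
        sbs[ch] <- sbs[ch] + 1L
      } else {
        ind[ch] <- ind[ch] + 1L
      }
    }
  }
  structure(
    list(sample_id = sample_id, sbs = sbs, indel = ind, unclassified = uncl),
    class = "darc_catalog"
  )
}

#' @export
print.darc_catalog <- function(x, ...) {
  cat("<darc_catalog> sample:", x$sample_id,
      "| SBS:", sum(x$sbs), "| indels:", sum(x$indel),
      "| unclassified:", x$unclassified, "\n")
  invisible(x)
}

#' Tidy a mutation catalog into a long tibble
#'
#' @param x A `darc_catalog`.
#' @param ... Unused.
#' @return Tibble with columns `sample_id`, `class` ("SBS"/"ID"), `channel`,
#'   `count`, in canonical channel order.
#' @method tidy darc_catalog
#' @export
tidy.darc_catalog <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(sample_id = x$sample_id, class = "SBS",
                   channel = names(x$sbs), count = as.integer(x$sbs)),
    tibble::tibble(sample_id = x$sample_id, class = "ID",
                   channel = names(x$indel), count = as.integer(x$indel))
  )
}

#' Catalog bar plot over mutation channels
#'
#' @param object A `darc_catalog`.
#' @param ... Unused.
#' @return A ggplot object: counts per channel, faceted by channel class.
#' @method autoplot darc_catalog
#' @export
autoplot.darc_catalog <- function(object, ...) {
  df <- tidy(object)
  df$channel <- factor(df$channel, levels = df$channel)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$channel, y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~class, ncol = 1, scales = "free_x") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(
      angle = 90, vjust = 0.5, size = 4)) +
    ggplot2::labs(x = NULL, y = "mutations")
}
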