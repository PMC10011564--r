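# Independent brute-force oracles. These re-derive expected values from
# first principles with deliberately different code paths (rle, startsWith,
# explicit loops) than the implementations they check.

COMP <- c(A = "T", C = "G", G = "C", T = "A")

rc <- function(s) {
  paste(rev(COMP[strsplit(s, "")[[1]]]), collapse = "")
}

# SBS oracle: exhaustive lookup table over both strand representations.
sbs_lookup <- local({
  tab <- new.env()
  bases <- c("A", "C", "G", "T")
  for (ref in c("C", "T")) for (alt in setdiff(bases, ref)) {
    for (l in bases) for (r in bases) {
      chan <- paste0(l, "[", ref, ">", alt, "]", r)
      assign(paste(paste0(l, ref, r), ref, alt), chan, envir = tab)
      assign(paste(rc(paste0(l, ref, r)), COMP[[ref]], COMP[[alt]]), chan,
             envir = tab)
    }
  }
  tab
})

oracle_sbs <- function(ref, alt, tri) {
  key <- paste(tri, ref, alt)
  if (!exists(key, envir = sbs_lookup)) return(NA_character_)
  get(key, envir = sbs_lookup)
}

# ID83 oracle: direct transcription of the published decision tree, using
# rle/startsWith primitives.
run_left_of <- function(left, b) {
  r <- rle(rev(strsplit(left, "")[[1]]))
  if (length(r$values) > 0 && r$values[1] == b) r$lengths[1] else 0L
}
run_right_of <- function(right, b) {
  r <- rle(strsplit(right, "")[[1]])
  if (length(r$values) > 0 && r$values[1] == b) r$lengths[1] else 0L
}
copies_right_of <- function(right, unit) {
  k <- 0L
  while (startsWith(right, strrep(unit, k + 1L))) k <- k + 1L
  k
}
copies_left_of <- function(left, unit) {
  k <- 0L
  while (endsWith(left, strrep(unit, k + 1L))) k <- k + 1L
  k
}
prefix_overlap <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  eq <- strsplit(substr(a, 1, n), "")[[1]] == strsplit(substr(b, 1, n), "")[[1]]
  if (all(eq)) n else which.min(eq) - 1L
}

# `event`: pure inserted/deleted sequence; flanks surround the tract.
oracle_indel <- function(event, is_del, left, right) {
  len <- nchar(event)
  if (grepl("[^ACGT]", event)) return(NA_character_)
  if (len == 1L) {
    adj <- run_left_of(left, event) + run_right_of(right, event)
    b <- if (event %in% c("A", "G")) COMP[[event]] else event
    n <- min(adj, 5L)
    return(paste0("1:", if (is_del) "Del" else "Ins", ":", b, ":", n))
  }
  lc <- min(len, 5L)
  copies <- copies_left_of(left, event) + copies_right_of(right, event)
  if (!is_del) return(paste0(lc, ":Ins:R:", min(copies, 5L)))
  if (copies > 0L) return(paste0(lc, ":Del:R:", min(copies, 5L)))
  mh <- max(prefix_overlap(event, right),
            prefix_overlap(paste(rev(strsplit(event, "")[[1]]), collapse = ""),
                           paste(rev(strsplit(left, "")[[1]]), collapse = "")))
  mh <- min(mh, len - 1L, 5L)
  if (mh > 0L) return(paste0(lc, ":Del:M:", mh))
  paste0(lc, ":Del:R:0")
}

# Random simple indel on a random local sequence; returns both the VCF-style
# record fields and the oracle's event view.
random_indel_case <- function() {
  flank <- 20L
  len <- sample(1:6, 1)
  is_del <- runif(1) < 0.6
  left <- paste(sample(c("A", "C", "G", "T"), flank, replace = TRUE),
                collapse = "")
  right <- paste(sample(c("A", "C", "G", "T"), flank, replace = TRUE),
                 collapse = "")
  event <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = "")
  anchor <- substr(left, flank, flank)
  list(
    ref = if (is_del) paste0(anchor, event) else anchor,
    alt = if (is_del) anchor else paste0(anchor, event),
    context = paste0(left, if (is_del) event else "", right),
    event = event, is_del = is_del, left = left, right = right
  )
}

# Random valid allele-specific segment genome over an arm map's chromosomes.
random_segments <- function(arm_map, max_segs_per_chrom = 8) {
  lens <- dplyr::distinct(arm_map, chrom, length)
  out <- list()
  for (i in seq_len(nrow(lens))) {
    n <- sample(1:max_segs_per_chrom, 1)
    cuts <- sort(sample(seq(1e6, lens$length[i] - 1e6, by = 1e5), n - 1))
    bounds <- c(0, cuts, lens$length[i])
    for (j in seq_len(n)) {
      total <- sample(0:9, 1)
      minor <- if (total == 0) 0 else sample(0:floor(total / 2), 1)
      out[[length(out) + 1]] <- data.frame(
        chrom = lens$chrom[i], start = bounds[j] + 1, end = bounds[j + 1],
        total_cn = total, major_cn = total - minor, minor_cn = minor)
    }
  }
  tibble::as_tibble(do.call(rbind, out))
}

# Brute-force CN feature oracles -------------------------------------------

oracle_bc10 <- function(seg, arm_map, window = 1e7, max_class = 5) {
  lens <- dplyr::distinct(arm_map, chrom, length)
  counts <- c()
  for (i in seq_len(nrow(lens))) {
    ch <- lens$chrom[i]
    nw <- ceiling(lens$length[i] / window)
    s <- seg[seg$chrom == ch, ]
    ends <- sort(s$end)
    if (length(ends) > 0) ends <- ends[-length(ends)]  # drop terminal
    for (w in seq_len(nw)) {
      lo <- (w - 1) * window + 1
      hi <- w * window
      counts <- c(counts, sum(ends >= lo & ends <= hi))
    }
  }
  tabulate(pmin(counts, max_class) + 1, nbins = max_class + 1)
}

oracle_bcca <- function(seg, arm_map, max_class = 5) {
  counts <- c()
  for (i in seq_len(nrow(arm_map))) {
    a <- arm_map[i, ]
    n <- 0
    for (j in seq_len(nrow(seg))) {
      if (seg$chrom[j] == a$chrom && seg$start[j] <= a$end &&
          seg$end[j] >= a$start) n <- n + 1
    }
    counts <- c(counts, max(n - 1, 0))
  }
  tabulate(pmin(counts, max_class) + 1, nbins = max_class + 1)
}

oracle_cn_counts <- function(seg, max_state = 8) {
  tabulate(pmin(seg$total_cn, max_state) + 1, nbins = max_state + 1)
}

oracle_copy_fraction <- function(seg, max_state = 8) {
  lens <- seg$end - seg$start + 1
  out <- numeric(max_state + 1)
  for (j in seq_len(nrow(seg))) {
    s <- min(seg$total_cn[j], max_state) + 1
    out[s] <- out[s] + lens[j]
  }
  out / sum(lens)
}

oracle_segsize <- function(seg, edges = c(5e3, 5e4, 5e5, 1e6, 3e6, 5e6,
                                          1e7, 2e7, 5e7, Inf)) {
  lens <- seg$end - seg$start + 1
  out <- numeric(length(edges))
  for (l in lens) {
    out[which(l <= edges)[1]] <- out[which(l <= edges)[1]] + 1
  }
  out
}

oracle_cncp <- function(seg, max_class = 5) {
  out <- numeric(max_class)
  for (ch in unique(seg$chrom)) {
    s <- seg[seg$chrom == ch, ]
    s <- s[order(s$start), ]
    if (nrow(s) < 2) next
    for (i in 2:nrow(s)) {
      d <- abs(s$total_cn[i] - s$total_cn[i - 1])
      if (d > 0) out[min(d, max_class)] <- out[min(d, max_class)] + 1
    }
  }
  out
}

oracle_hrd_loh <- function(seg, min_len = 15e6) {
  n <- 0
  for (ch in unique(seg$chrom)) {
    s <- seg[seg$chrom == ch, ]
    s <- s[order(s$start), ]
    lo_chrom <- min(s$start); hi_chrom <- max(s$end)
    regions <- list()
    cur <- NULL
    for (i in seq_len(nrow(s))) {
      if (s$minor_cn[i] == 0 && s$total_cn[i] >= 1) {
        if (!is.null(cur) && s$start[i] == cur[2] + 1) {
          cur[2] <- s$end[i]
        } else {
          if (!is.null(cur)) regions[[length(regions) + 1]] <- cur
          cur <- c(s$start[i], s$end[i])
        }
      } else {
        if (!is.null(cur)) regions[[length(regions) + 1]] <- cur
        cur <- NULL
      }
    }
    if (!is.null(cur)) regions[[length(regions) + 1]] <- cur
    for (r in regions) {
      if (r[2] - r[1] + 1 > min_len && !(r[1] == lo_chrom && r[2] == hi_chrom)) {
        n <- n + 1
      }
    }
  }
  n
}

oracle_lst <- function(seg, min_len = 1e7, max_gap = 3e6) {
  n <- 0
  for (ch in unique(seg$chrom)) {
    s <- seg[seg$chrom == ch, ]
    s <- s[order(s$start), ]
    if (nrow(s) < 2) next
    for (i in 2:nrow(s)) {
      a <- s[i - 1, ]; b <- s[i, ]
      if (a$end - a$start + 1 >= min_len && b$end - b$start + 1 >= min_len &&
          b$start - a$end - 1 <= max_gap &&
          (a$total_cn != b$total_cn || a$minor_cn != b$minor_cn)) {
        n <- n + 1
      }
    }
  }
  n
}

oracle_tai <- function(seg, arm_map, tol = 1e4) {
  lens <- dplyr::distinct(arm_map, chrom, length)
  n <- 0
  for (i in seq_len(nrow(seg))) {
    s <- seg[i, ]
    len <- lens$length[lens$chrom == s$chrom]
    touch_start <- s$start - 1 <= tol
    touch_end <- len - s$end <= tol
    if (s$major_cn != s$minor_cn && xor(touch_start, touch_end)) n <- n + 1
  }
  n
}

# Exhaustive F1 threshold-scan oracle.
oracle_threshold <- function(labels, probs) {
  best_f1 <- -1; best_t <- NA
  for (t in (0:1000) / 1000) {
    pred <- as.integer(probs >= t)
    tp <- sum(pred == 1 & labels == 1)
    fp <- sum(pred == 1 & labels == 0)
    fn <- sum(pred == 0 & labels == 1)
    f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    if (f1 > best_f1 + 1e-12) { best_f1 <- f1; best_t <- t }
  }
  best_t
}

# Tiny labelled feature tables for classifier tests.
toy_separable_cohort <- function(n = 60, seed = 42) {
  set.seed(seed)
  y <- rep(c(1, 0), length.out = n)
  x <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  x[, 1] <- y * 3 + rnorm(n, sd = 0.1)
  list(x = x, y = y)
}
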