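#' Refit a mutation catalog against reference signatures
#'
#' Normalizes the 96-channel substitution catalog to proportions and solves a
#' non-negative least-squares problem for the per-signature weights,
#' constrained to sum to at most 1. Weights below `cutoff` are then zeroed
#' and the remaining signatures refit, iterating until every surviving weight
#' clears the cutoff. The residual is the root-mean-square error between the
#' fitted mixture and the catalog proportions.
#'
#' @param catalog A `darc_catalog`, or a named 96-vector of channel counts in
#'   canonical order.
#' @param signatures Signature matrix from [read_signature_matrix()] (96
#'   canonical rows x named columns).
#' @param cutoff Minimum retained weight, default 0.06.
#' @return A `darc_sig_weights`: list with `weights` (named, one per
#'   signature column), `residual`, `cutoff`, `n_mutations`.
#' @export
fit_signature_weights <- function(catalog, signatures, cutoff = 0.06) {
  counts <- if (inherits(catalog, "darc_catalog")) catalog$sbs else catalog
  if (length(counts) != 96) stop("catalog must have 96 substitution channels")
  if (!is.null(names(counts)) && !identical(names(counts), rownames(signatures))) {
    stop("catalog channel order does not match the signature matrix")
  }
  total <- sum(counts)
  if (total <= 0) stop("catalog has no substitutions to fit")
  p <- as.numeric(counts) / total
  w <- nnls_sum_constrained(signatures, p)
  repeat {
    nz <- w > 0
    if (!any(nz) || all(w[nz] >= cutoff)) break
    active <- w >= cutoff
    w[] <- 0
    if (!any(active)) break
    w[active] <- nnls_sum_constrained(signatures[, active, drop = FALSE], p)
  }
  fitted <- as.numeric(signatures %*% w)
  structure(
    list(weights = stats::setNames(w, colnames(signatures)),
         residual = sqrt(mean((fitted - p)^2)),
         cutoff = cutoff, n_mutations = total),
    class = "darc_sig_weights"
  )
}

# NNLS with the simplex-style side constraint sum(w) <= 1: plain NNLS first,
# projected by rescaling in the rare case the solution overshoots.
nnls_sum_constrained <- function(S, p) {
  w <- pracma::lsqnonneg(as.matrix(S), p)$x
  if (sum(w) > 1) w <- w / sum(w)
  w
}

#' @export
print.darc_sig_weights <- function(x, ...) {
  nz <- x$weights[x$weights > 0]
  cat("<darc_sig_weights>", x$n_mutations, "mutations | residual",
      signif(x$residual, 3), "\n")
  if (length(nz)) {
    cat(paste0("  ", names(nz), ": ", round(nz, 3), collapse = "\n"), "\n")
  }
  invisible(x)
}

#' @method tidy darc_sig_weights
#' @export
tidy.darc_sig_weights <- function(x, ...) {
  tibble::tibble(signature = names(x$weights),
                 weight = as.numeric(x$weights))
}

#' Combined mismatch-repair-deficiency signature weight
#'
#' Sums the fitted weights of the MMRd-associated reference signatures
#' (6, 15, 20 and 26 in the version-2 catalogue) and flags the sample when
#' the combined weight reaches `min_weight`.
#'
#' @param weights A `darc_sig_weights`.
#' @param mmrd_signatures Names of the MMRd-associated columns.
#' @param min_weight Flagging threshold (inclusive), default 0.05.
#' @return List with `combined` and logical `flag`.
#' @export
mmrd_combined_weight <- function(weights,
                                 mmrd_signatures = c(
                                   "Signature.6", "Signature.15",
                                   "Signature.20", "Signature.26"),
                                 min_weight = 0.05) {
  missing <- setdiff(mmrd_signatures, names(weights$weights))
  if (length(missing) > 0) {
    stop("signature(s) absent from the fit: ", paste(missing, collapse = ", "))
  }
  combined <- sum(weights$weights[mmrd_signatures])
  list(combined = combined, flag = combined >= min_weight)
}

#' Flag a sample by its HRR-deficiency (signature 3) weight
#'
#' @param weights A `darc_sig_weights`.
#' @param signature Column name of the HRR-deficiency signature.
#' @param min_weight Flagging threshold (inclusive), default 0.05.
#' @return Logical flag.
#' @export
brca2d_signature_flag <- function(weights, signature = "Signature.3",
                                  min_weight = 0.05) {
  if (!signature %in% names(weights$weights)) {
    stop("signature absent from the fit: ", signature)
  }
  unname(weights$weights[signature] >= min_weight)
}
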