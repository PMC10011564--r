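#' Assemble the 224-dimensional somatic feature vector for one sample
#'
#' Concatenates the 96 substitution channel counts, the 83 indel channel
#' counts and the 45 copy-number features, in canonical order. Mutation
#' channels are raw counts (proportions are a display convention, not the
#' model input).
#'
#' @param catalog A `darc_catalog` from [build_catalog()].
#' @param segments Validated segment tibble.
#' @param arm_map A `darc_armmap`.
#' @param schema A [cn_schema()].
#' @return Named numeric vector of length 224.
#' @export
extract_sample_features <- function(catalog, segments, arm_map,
                                    schema = cn_schema()) {
  v <- c(as.numeric(catalog$sbs), as.numeric(catalog$indel),
         as.numeric(extract_cn_features(segments, arm_map, schema)))
  stats::setNames(v, feature_names(schema))
}

#' Build a cohort feature matrix from per-sample inputs
#'
#' Runs the somatic filters, builds the mutation catalog from passing records
#' and extracts the full feature vector for every sample.
#'
#' @param samples List of per-sample lists with elements `sample_id`,
#'   `variants` (tibble) and `segments` (tibble), e.g. from
#'   [simulate_cohort()].
#' @param arm_map A `darc_armmap`.
#' @param error_model Optional `darc_error_model` for the filters.
#' @param config A [filter_config()].
#' @param schema A [cn_schema()].
#' @return Tibble: `sample_id` plus 224 feature columns.
#' @export
extract_cohort_features <- function(samples, arm_map, error_model = NULL,
                                    config = filter_config(),
                                    schema = cn_schema()) {
  purrr::map_dfr(samples, function(s) {
    verdicts <- call_somatic(s$variants, error_model, config)
    passing <- verdicts[verdicts$pass, ]
    cat_ <- build_catalog(passing, s$sample_id, config$context_window)
    fv <- extract_sample_features(cat_, s$segments, arm_map, schema)
    dplyr::bind_cols(tibble::tibble(sample_id = s$sample_id),
                     tibble::as_tibble_row(fv))
  })
}
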