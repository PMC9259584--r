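#' Reconcile an orthogonal validation call set with pipeline calls
#'
#' Performs a 1:1 comparison between a Sanger-style truth list and the
#' sequencing pipeline's calls within the regions covered by validation.
#' Variants are matched on normalized keys (see [normalize_variant_key()]),
#' so indel calls that differ only in representation still match; those
#' whose raw representations differ are counted as matches after review.
#' Pipeline variants that were discovered but removed by the filter
#' hierarchy (rows flagged `filtered`) and confirmed by the truth set form
#' their own category. The total is every variant called by either method
#' in covered regions, and the categories partition it exactly.
#'
#' Two rate conventions are reported: the operational rates used in
#' validation accounting, which relate hard false negatives and false
#' positives to the total (`sensitivity = 1 - n_hard_fn / n_total`,
#' `specificity = 1 - n_fp / n_total`), and classical rates over called
#' variants only (`sensitivity_classical` = confirmed calls over all truth
#' variants; `precision` = confirmed calls over all pipeline calls).
#'
#' @param sanger_calls Tibble of truth calls: `chrom`, `pos`, `ref`, `alt`.
#' @param pipeline_calls Tibble of pipeline calls, same columns plus an
#'   optional logical `filtered` column (discovered but removed by the
#'   filter hierarchy).
#' @param covered_regions Tibble `chrom`, `start`, `end` of validated
#'   regions, BED-style 0-based half-open; calls outside them are excluded
#'   with a message. `NULL` keeps all calls.
#' @param reference Optional reference passed to [normalize_variant_key()]
#'   for left-alignment.
#' @param manual_overrides Optional tibble with `sanger_key` and
#'   `pipeline_key` columns naming residual pairs to treat as matches after
#'   review.
#' @return One-row tibble of class `blc_recon` with category counts
#'   (`n_total`, `n_match`, `n_match_after_review`, `n_filtered_confirmed`,
#'   `n_hard_fn`, `n_fp`) and rates (`fn_rate`, `sensitivity`, `fp_rate`,
#'   `specificity`, `sensitivity_classical`, `precision`).
#' @export
reconcile <- function(sanger_calls, pipeline_calls, covered_regions = NULL,
                      reference = NULL, manual_overrides = NULL) {
  sanger <- as_tibble(sanger_calls)
  pipeline <- as_tibble(pipeline_calls)
  if (is.null(pipeline[["filtered"]])) pipeline$filtered <- FALSE

  if (!is.null(covered_regions)) {
    keep_in <- function(df) {
      kept <- df %>%
        inner_join(as_tibble(covered_regions),
                   by = join_by("chrom", "pos" > "start", "pos" <= "end")) %>%
        select(-"start", -"end") %>% distinct()
      dropped <- nrow(df) - nrow(kept)
      if (dropped > 0) message(dropped, " call(s) outside covered regions excluded")
      kept
    }
    sanger <- keep_in(sanger)
    pipeline <- keep_in(pipeline)
  }
  keyed <- function(df) df %>%
    mutate(raw = paste0(sub("^chr", "", .data$chrom), ":", .data$pos, ":",
                        .data$ref, ">", .data$alt),
           key = normalize_variant_key(.data$chrom, .data$pos, .data$ref,
                                       .data$alt, reference))
  sanger <- keyed(sanger)
  pipeline <- keyed(pipeline)
  called <- pipeline %>% filter(!.data$filtered)
  filtered <- pipeline %>% filter(.data$filtered)

  overlap <- inner_join(sanger %>% select(s_raw = "raw", "key"),
                        called %>% select(p_raw = "raw", "key"),
                        by = "key")
  override_keys <- if (is.null(manual_overrides)) character(0) else {
    manual_overrides$sanger_key
  }
  n_match <- sum(overlap$s_raw == overlap$p_raw & !overlap$key %in% override_keys)
  n_review <- sum(overlap$s_raw != overlap$p_raw | overlap$key %in% override_keys)
  n_filtered_confirmed <- nrow(semi_join(sanger, filtered, by = "key"))
  n_hard_fn <- nrow(anti_join(sanger, pipeline, by = "key"))
  n_fp <- nrow(anti_join(called, sanger, by = "key"))
  n_total <- n_match + n_review + n_filtered_confirmed + n_hard_fn + n_fp

  out <- tibble(
    n_total = n_total, n_match = n_match, n_match_after_review = n_review,
    n_filtered_confirmed = n_filtered_confirmed,
    n_hard_fn = n_hard_fn, n_fp = n_fp,
    fn_rate = n_hard_fn / n_total,
    sensitivity = 1 - n_hard_fn / n_total,
    fp_rate = n_fp / n_total,
    specificity = 1 - n_fp / n_total,
    sensitivity_classical = (n_match + n_review) /
      (n_match + n_review + n_filtered_confirmed + n_hard_fn),
    precision = (n_match + n_review) / (n_match + n_review + n_fp)
  )
  class(out) <- c("blc_recon", class(out))
  out
}

#' @export
print.blc_recon <- function(x, ...) {
  cat("<validation reconciliation>\n")
  cat(sprintf("  %d variants in covered regions: %d matches + %d after review,\n",
              x$n_total, x$n_match, x$n_match_after_review))
  cat(sprintf("  %d confirmed-filtered, %d hard FN, %d pipeline-only\n",
              x$n_filtered_confirmed, x$n_hard_fn, x$n_fp))
  cat(sprintf("  operational: sensitivity %.3f (fn rate %.3f), specificity %.3f (fp rate %.3f)\n",
              x$sensitivity, x$fn_rate, x$specificity, x$fp_rate))
  cat(sprintf("  classical: sensitivity %.3f, precision %.3f\n",
              x$sensitivity_classical, x$precision))
  invisible(x)
}
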