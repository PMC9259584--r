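#' Cancer cell fraction from VAF, purity and copy number
#'
#' Estimates the fraction of tumor cells carrying a mutation from its variant
#' allele frequency, the sample's tumor purity, and the local copy number:
#'
#' \deqn{f_{CCF} = \frac{f_{VAF}}{f_{purity}} \left((1 - f_{purity})\, n_{CN,normal} + f_{purity}\, n_{CN,tumor}\right)}
#'
#' assuming diploid normal bystander cells and one mutated copy. Values above
#' 1 are reported as-is (never clipped): they flag sites where the
#' single-mutated-copy assumption is violated (e.g., a mutation on an
#' amplified allele), which is informative in itself.
#'
#' @param vaf Variant allele frequency in `[0, 1]`.
#' @param purity Tumor purity in `(0, 1]`; a purity of 0 leaves the CCF
#'   undefined and raises an error.
#' @param cn_tumor Tumor copy number at the variant position (>= 0).
#' @param cn_normal Normal copy number, 2 for autosomes by assumption.
#' @return Numeric vector of cancer cell fractions.
#' @examples
#' compute_ccf(0.5, 1.0, 2)    # pure diploid heterozygous clonal -> 1
#' compute_ccf(0.30, 0.6, 3)   # 1.3: flags a multi-copy mutation
#' @export
compute_ccf <- function(vaf, purity, cn_tumor, cn_normal = 2) {
  assert_that(is_proportion(vaf), "vaf must lie in [0, 1]")
  assert_that(all(purity > 0 & purity <= 1, na.rm = TRUE),
              "purity must lie in (0, 1]; CCF is undefined at purity 0")
  assert_that(all(cn_tumor >= 0, na.rm = TRUE) && all(cn_normal >= 0, na.rm = TRUE),
              "copy numbers must be >= 0")
  vaf / purity * ((1 - purity) * cn_normal + purity * cn_tumor)
}

#' Look up tumor copy number for variant positions
#'
#' Matches each variant to the copy-number segment containing it. Segments
#' use half-open `[start, end)` coordinates; variants are matched by their
#' 1-based position. Variants falling outside all segments of their sample
#' (or on a contig with no segments) receive the sample ploidy rounded to the
#' nearest integer as a fallback, flagged in `cn_fallback`.
#'
#' @param variants Data frame with `sample_id`, `chrom`, `pos`.
#' @param segments Data frame with `sample_id`, `chrom`, `start`, `end`, `cn`
#'   (non-overlapping within a sample and chromosome).
#' @param purity Data frame with `sample_id`, `purity`, `ploidy`, used for the
#'   fallback.
#' @return The variants tibble with `cn_tumor` and `cn_fallback` columns.
#' @export
lookup_cn <- function(variants, segments, purity) {
  variants <- as_tibble(variants)
  segments <- as_tibble(segments)
  needed <- c("sample_id", "chrom", "start", "end", "cn")
  assert_that(all(needed %in% names(segments)),
              paste("segments must have columns:", paste(needed, collapse = ", ")))
  assert_that(all(segments$end > segments$start), "malformed segment table: end <= start")

  out <- variants %>%
    left_join(
      segments %>% select("sample_id", "chrom", "start", "end", seg_cn = "cn"),
      by = join_by("sample_id", "chrom", "pos" >= "start", "pos" < "end")
    ) %>%
    left_join(purity %>% select("sample_id", "ploidy"), by = "sample_id") %>%
    mutate(
      cn_fallback = is.na(.data$seg_cn),
      cn_tumor = if_else(.data$cn_fallback, round(.data$ploidy), .data$seg_cn)
    ) %>%
    select(-"start", -"end", -"seg_cn", -"ploidy")
  nfb <- sum(out$cn_fallback)
  if (nfb > 0) {
    message(nfb, " variant(s) outside all copy-number segments; ",
            "using rounded sample ploidy as fallback")
  }
  out
}

#' Estimate per-variant cancer cell fractions for a cohort
#'
#' Joins called variants with sample purity/ploidy and copy-number segments,
#' computes the CCF of every variant, and calls clonality at the given
#' threshold. Samples without purity estimates (not every case has an
#' informative SNP array) are skipped, not imputed; their count is reported
#' in a message and in the `n_skipped_samples` attribute.
#'
#' @param variants Called variant table with `sample_id`, `chrom`, `pos`,
#'   `vaf` (and allele columns for keying).
#' @param purity Data frame `(sample_id, purity, ploidy)`.
#' @param segments Optional segment table for [lookup_cn()]; without it every
#'   variant uses the rounded-ploidy copy number.
#' @param threshold Clonality threshold on the CCF (default 0.9, boundary
#'   inclusive).
#' @return Tibble of CCF records: the variant columns plus `cn_tumor`,
#'   `cn_fallback`, `ccf`, `ccf_above_one` and `clonal`.
#' @export
estimate_ccf <- function(variants, purity, segments = NULL, threshold = 0.9) {
  variants <- add_variant_key(as_tibble(variants))
  purity <- as_tibble(purity)
  assert_that(all(c("sample_id", "purity", "ploidy") %in% names(purity)),
              "purity table must have sample_id, purity, ploidy")
  have <- unique(purity$sample_id[!is.na(purity$purity)])
  skipped <- setdiff(unique(variants$sample_id), have)
  if (length(skipped) > 0) {
    message(length(skipped), " sample(s) lack purity estimates; ",
            "their variants are skipped, not imputed")
  }
  variants <- variants %>% filter(.data$sample_id %in% have)
  if (is.null(segments)) {
    variants <- variants %>%
      left_join(purity %>% select("sample_id", "ploidy"), by = "sample_id") %>%
      mutate(cn_tumor = round(.data$ploidy), cn_fallback = TRUE) %>%
      select(-"ploidy")
  } else {
    variants <- lookup_cn(variants, segments, purity)
  }
  out <- variants %>%
    left_join(purity %>% select("sample_id", "purity"), by = "sample_id") %>%
    mutate(
      ccf = compute_ccf(.data$vaf, .data$purity, .data$cn_tumor),
      ccf_above_one = .data$ccf > 1
    )
  out <- call_clonal(out, threshold = threshold)
  attr(out, "n_skipped_samples") <- length(skipped)
  out
}

#' Call clonal mutations at a CCF threshold
#'
#' @param records Data frame with a `ccf` column.
#' @param threshold Clonality threshold; a mutation is clonal when
#'   `ccf >= threshold` (default 0.9, inclusive).
#' @return The records with a logical `clonal` column; per-sample clonal and
#'   subclonal counts are attached as the `"clonal_summary"` attribute when a
#'   `sample_id` column is present.
#' @export
call_clonal <- function(records, threshold = 0.9) {
  records <- as_tibble(records)
  records$clonal <- records$ccf >= threshold
  if (!is.null(records[["sample_id"]])) {
    attr(records, "clonal_summary") <- records %>%
      group_by(.data$sample_id) %>%
      summarise(n_clonal = sum(.data$clonal, na.rm = TRUE),
                n_subclonal = sum(!.data$clonal, na.rm = TRUE),
                .groups = "drop")
  }
  records
}
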