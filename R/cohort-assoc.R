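#' Build the gene-by-patient mutation matrix
#'
#' Aggregates called somatic variants into per-gene, per-patient mutation
#' counts, aligned with the clinical table. Multiplicity is preserved in the
#' count matrix (a patient with two MYC variants counts 2), while the binary
#' indicator collapses it for frequency work.
#'
#' @param variants Called variant table with `sample_id` and `gene`.
#' @param clinical Clinical table with `patient_id` (one row per patient);
#'   every variant's `sample_id` must appear in it.
#' @return An object of class `blc_mutmat`: a list with integer matrix
#'   `counts` (genes x patients), logical `indicator`, and the aligned
#'   `clinical` tibble.
#' @export
build_matrix <- function(variants, clinical) {
  variants <- as_tibble(variants)
  clinical <- as_tibble(clinical)
  assert_that(!anyDuplicated(clinical$patient_id),
              "duplicate patient_id in clinical table")
  orphans <- setdiff(unique(variants$sample_id), clinical$patient_id)
  if (length(orphans) > 0) {
    stop("variants reference samples missing from the clinical table: ",
         paste(utils::head(orphans, 10), collapse = ", "), call. = FALSE)
  }
  genes <- sort(unique(variants$gene))
  patients <- clinical$patient_id
  counts <- matrix(0L, nrow = length(genes), ncol = length(patients),
                   dimnames = list(genes, patients))
  if (nrow(variants) > 0) {
    tab <- variants %>% count(.data$gene, .data$sample_id)
    counts[cbind(match(tab$gene, genes), match(tab$sample_id, patients))] <- tab$n
  }
  structure(list(counts = counts, indicator = counts >= 1L, clinical = clinical),
            class = "blc_mutmat")
}

#' @export
print.blc_mutmat <- function(x, ...) {
  cat(sprintf("<mutation matrix: %d genes x %d patients, %d mutated cells>\n",
              nrow(x$counts), ncol(x$counts), sum(x$indicator)))
  invisible(x)
}

#' Per-gene mutation frequencies
#'
#' @param mat A [build_matrix()] object.
#' @param by Optional clinical column to stratify by.
#' @return Tibble `(gene, [group,] n_mutated, n_total, frequency)`.
#' @export
gene_frequency <- function(mat, by = NULL) {
  ind <- mat$indicator
  if (is.null(by)) {
    return(tibble(gene = rownames(ind),
                  n_mutated = rowSums(ind),
                  n_total = ncol(ind),
                  frequency = rowSums(ind) / ncol(ind)))
  }
  groups <- mat$clinical[[by]]
  purrr::map_dfr(unique(groups[!is.na(groups)]), function(g) {
    cols <- which(groups == g)
    tibble(gene = rownames(ind), group = g,
           n_mutated = rowSums(ind[, cols, drop = FALSE]),
           n_total = length(cols),
           frequency = rowSums(ind[, cols, drop = FALSE]) / length(cols))
  })
}

#' One-sided Fisher exact test for a 2x2 mutation table
#'
#' Computes the exact hypergeometric tail probability of observing a
#' mutation split at least as extreme as `k_a/n_a` versus `k_b/n_b` in the
#' stated direction, conditioning on both margins.
#'
#' @param k_a,n_a Mutated and total counts in group A.
#' @param k_b,n_b Mutated and total counts in group B.
#' @param direction `"a_greater"` tests enrichment in group A,
#'   `"b_greater"` in group B. Vectorised over all count arguments.
#' @return Numeric vector of one-sided p-values.
#' @examples
#' fisher_one_sided(145, 191, 39, 97, "a_greater")  # pediatric ID3 contrast
#' @export
fisher_one_sided <- function(k_a, n_a, k_b, n_b, direction = "a_greater") {
  assert_that(all(n_a > 0) && all(n_b > 0), "group sizes must be positive")
  assert_that(all(k_a >= 0 & k_a <= n_a) && all(k_b >= 0 & k_b <= n_b),
              "counts must satisfy 0 <= k <= n")
  direction <- rep_len(direction, max(length(k_a), length(k_b)))
  swap <- direction == "b_greater"
  ka <- ifelse(swap, k_b, k_a); na <- ifelse(swap, n_b, n_a)
  kb <- ifelse(swap, k_a, k_b); nb <- ifelse(swap, n_a, n_b)
  # P(X >= ka), X ~ Hypergeometric(white = ka+kb, black = na+nb-ka-kb, drawn = na)
  phyper(ka - 1, ka + kb, na + nb - ka - kb, na, lower.tail = FALSE)
}

#' Benjamini-Hochberg false discovery control
#'
#' Step-up q-values over a family of hypotheses with a significance call at
#' the prescribed error threshold (default q = 0.1).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param q_threshold FDR threshold for the `significant` flag.
#' @return Tibble `(p, q, significant)` in input order.
#' @export
bh_fdr <- function(p, q_threshold = 0.1) {
  assert_that(length(p) > 0, "empty p-value vector")
  assert_that(is_proportion(p), "p-values must lie in [0, 1]")
  q <- p.adjust(p, method = "BH")
  tibble(p = p, q = q, significant = q <= q_threshold)
}

# named clinical contrasts: field plus the two levels (A first)
comparison_catalog <- function() {
  list(
    cohort = list(field = "cohort", a = "pediatric", b = "adult"),
    sex = list(field = "sex", a = "male", b = "female"),
    age10 = list(field = "age10", a = "under10", b = "over10"),
    bm = list(field = "bm_involved", a = TRUE, b = FALSE),
    cns = list(field = "cns_involved", a = TRUE, b = FALSE),
    entity = list(field = "entity", a = "B-AL", b = "BL")
  )
}

#' Gene-by-subcohort association testing
#'
#' For every gene mutated in at least `min_freq` of the cohort, contrasts
#' mutation frequency between two clinical groups with a one-sided Fisher
#' exact test. The tested direction follows the observed frequency difference
#' (the enriched side) and is recorded in the output. False discovery rates
#' are Benjamini-Hochberg q-values computed within the comparison family,
#' with significance called at `q_threshold`.
#'
#' @param mat A [build_matrix()] object whose clinical table carries the
#'   comparison field.
#' @param comparison Either the name of a predefined contrast (`"cohort"`,
#'   `"sex"`, `"age10"`, `"bm"`, `"cns"`, `"entity"`) or a list
#'   `list(field =, a =, b =)` naming a clinical column and its two levels.
#'   `"age10"` splits the pediatric cohort at 10 years of age.
#' @param min_freq Minimum overall mutation frequency for a gene to enter the
#'   hypothesis family (default 0.02).
#' @param q_threshold FDR threshold (default 0.1).
#' @param alpha Per-test significance level for the star annotation.
#' @return Tibble with one row per tested gene: group counts and frequencies,
#'   tested `direction`, one-sided `p`, `q`, `significant`, and `stars`.
#' @export
run_comparisons <- function(mat, comparison = "cohort", min_freq = 0.02,
                            q_threshold = 0.1, alpha = 0.05) {
  if (is.character(comparison)) {
    spec <- comparison_catalog()[[comparison]]
    if (is.null(spec)) stop("unknown comparison: ", comparison, call. = FALSE)
  } else {
    spec <- comparison
  }
  clinical <- mat$clinical
  if (identical(spec$field, "age10")) {
    clinical$age10 <- dplyr::if_else(clinical$age_years < 10, "under10", "over10")
    clinical$age10[clinical$cohort != "pediatric"] <- NA_character_
  }
  if (is.null(clinical[[spec$field]])) {
    stop("unknown clinical field: ", spec$field, call. = FALSE)
  }
  grp <- clinical[[spec$field]]
  in_a <- !is.na(grp) & grp == spec$a
  in_b <- !is.na(grp) & grp == spec$b
  dropped <- sum(!in_a & !in_b)
  if (dropped > 0) {
    message(dropped, " patient(s) without usable '", spec$field,
            "' dropped from this comparison")
  }
  n_a <- sum(in_a); n_b <- sum(in_b)
  assert_that(n_a > 0 && n_b > 0, "both comparison groups must be non-empty")

  ind <- mat$indicator
  eligible <- rowSums(ind) / ncol(ind) >= min_freq
  ind <- ind[eligible, , drop = FALSE]
  assert_that(nrow(ind) > 0, "no gene meets the minimum frequency for testing")

  k_a <- rowSums(ind[, in_a, drop = FALSE])
  k_b <- rowSums(ind[, in_b, drop = FALSE])
  direction <- if_else(k_a / n_a >= k_b / n_b, "a_greater", "b_greater")
  p <- fisher_one_sided(k_a, n_a, k_b, n_b, direction)
  fdr <- bh_fdr(p, q_threshold)
  tibble(
    gene = rownames(ind),
    comparison = if (is.character(comparison)) comparison else spec$field,
    group_a = as.character(spec$a), group_b = as.character(spec$b),
    k_a = k_a, n_a = n_a, k_b = k_b, n_b = n_b,
    freq_a = k_a / n_a, freq_b = k_b / n_b,
    direction = direction,
    p = p, q = fdr$q, significant = fdr$significant,
    stars = if_else(p <= alpha, p_stars(p), "ns")
  ) %>% arrange(.data$p)
}

#' Mutual-exclusivity accounting for a gene pair
#'
#' Cross-tabulates carriers of two genes and reports how often cases carry
#' both, exactly one, or neither -- the accounting behind mutual-exclusivity
#' statements such as pathway-level hits.
#'
#' @param mat A [build_matrix()] object.
#' @param gene_a,gene_b Gene symbols present in the matrix.
#' @param by Optional clinical column to stratify by (e.g. `"cohort"`).
#' @return Tibble with columns `both`, `only_a`, `only_b`, `neither`, `n`,
#'   `pct_exactly_one`, `pct_either`, one row per stratum.
#' @export
exclusivity_summary <- function(mat, gene_a, gene_b, by = NULL) {
  for (g in c(gene_a, gene_b)) {
    if (!g %in% rownames(mat$indicator)) {
      stop("gene absent from matrix: ", g, call. = FALSE)
    }
  }
  a <- mat$indicator[gene_a, ]
  b <- mat$indicator[gene_b, ]
  strata <- if (is.null(by)) list(all = rep(TRUE, length(a))) else {
    g <- mat$clinical[[by]]
    setNames(lapply(unique(g[!is.na(g)]), function(x) !is.na(g) & g == x),
             unique(g[!is.na(g)]))
  }
  purrr::imap_dfr(strata, function(sel, nm) {
    aa <- a[sel]; bb <- b[sel]
    n <- sum(sel)
    tibble(
      stratum = nm, gene_a = gene_a, gene_b = gene_b,
      both = sum(aa & bb), only_a = sum(aa & !bb), only_b = sum(!aa & bb),
      neither = sum(!aa & !bb), n = n,
      pct_exactly_one = 100 * (sum(aa & !bb) + sum(!aa & bb)) / n,
      pct_either = 100 * sum(aa | bb) / n
    )
  })
}
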