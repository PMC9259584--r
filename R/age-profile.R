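#' Boundary-reflected Gaussian kernel density estimate
#'
#' An ordinary kernel density estimate decays artificially near the edges of
#' a bounded support (ages cannot be negative, nor exceed the oldest patient).
#' Reflecting the data about both boundaries before smoothing removes this
#' edge bias; the resulting curve is evaluated on a uniform grid within the
#' support and renormalized to integrate to exactly 1 there.
#'
#' @param values Numeric observations, all within `support`.
#' @param support Length-2 vector `c(lo, hi)`, `hi > lo`.
#' @param bandwidth Gaussian kernel bandwidth; `NULL` uses Silverman's rule
#'   ([stats::bw.nrd0()]) on the unreflected data.
#' @param n_grid Number of grid points (default 512).
#' @return Tibble `(x, density)` with attributes `bandwidth` and `support`.
#' @export
reflected_kde <- function(values, support, bandwidth = NULL, n_grid = 512L) {
  assert_that(length(values) >= 2, "need at least 2 values")
  lo <- support[1]; hi <- support[2]
  assert_that(hi > lo, "degenerate support")
  assert_that(all(values >= lo & values <= hi), "values must lie within support")
  bw <- bandwidth %||% bw.nrd0(values)
  assert_that(bw > 0, "bandwidth must be positive")
  aug <- c(values, 2 * lo - values, 2 * hi - values)
  grid <- seq(lo, hi, length.out = n_grid)
  # f(x) = (1/n) sum over original + reflected copies of the kernel
  dens <- vapply(grid, function(g) sum(dnorm(g, mean = aug, sd = bw)),
                 numeric(1)) / length(values)
  dens <- dens / trapz(grid, dens)
  structure(tibble(x = grid, density = dens),
            bandwidth = bw, support = support)
}

#' Mutation-density-over-age curves per gene
#'
#' For each gene, estimates the age density of mutated cases and of all
#' cases with a boundary-reflected KDE, forms the smoothed mutation
#' frequency over age (the density ratio scaled by the gene's overall
#' prevalence), and normalizes it to its mean value over pediatric ages to
#' give the mutation density relative to children. The support is
#' `[0, max observed age]`: age zero is a natural boundary even when the
#' youngest patient is older. One bandwidth -- Silverman's rule on all ages
#' -- is shared by both densities of a gene so their ratio is stable.
#'
#' @param mat A [build_matrix()] object whose clinical table has `age_years`.
#' @param genes Genes to profile (default: all genes in the matrix with at
#'   least two mutated cases).
#' @param n_grid Grid resolution.
#' @param pediatric_cut Age (years) bounding the pediatric reference range
#'   (default 18).
#' @return Long tibble `(gene, age, density_mutated, density_all,
#'   smoothed_frequency, relative_to_children)`.
#' @export
age_density_curves <- function(mat, genes = NULL, n_grid = 512L,
                               pediatric_cut = 18) {
  ages <- mat$clinical$age_years
  support <- c(0, max(ages))
  bw <- bw.nrd0(ages)
  dens_all <- reflected_kde(ages, support, bandwidth = bw, n_grid = n_grid)
  ind <- mat$indicator
  genes <- genes %||% rownames(ind)[rowSums(ind) >= 2]
  purrr::map_dfr(genes, function(g) {
    carrier <- ind[g, ]
    if (sum(carrier) < 2) return(tibble())
    dens_mut <- reflected_kde(ages[carrier], support, bandwidth = bw,
                              n_grid = n_grid)
    prevalence <- mean(carrier)
    freq <- pmin(1, pmax(0, prevalence * dens_mut$density / dens_all$density))
    ped <- dens_all$x <= pediatric_cut
    ped_mean <- mean(freq[ped])
    tibble(
      gene = g, age = dens_all$x,
      density_mutated = dens_mut$density,
      density_all = dens_all$density,
      smoothed_frequency = freq,
      relative_to_children = if (ped_mean > 0) freq / ped_mean else NA_real_
    )
  })
}

# running-sum enrichment score given ordered membership flags
running_sum_es <- function(member_positions, m, n) {
  i <- seq_along(member_positions)
  max(i / m - (member_positions - i) / (n - m))
}

#' Age-rank permutation enrichment test
#'
#' Cutoff-free test for whether carriers of a mutation concentrate at young
#' or old ages. Patients are ranked by age (ascending for the young tail,
#' descending for the old tail; ties broken by stable input order) and the
#' classic unweighted running-sum statistic is computed, stepping up by
#' `1/m` at each of the `m` mutated cases and down by `1/(n-m)` otherwise;
#' the enrichment score is the maximum of the running sum. Significance
#' comes from permuting membership labels: the reported p-value uses the
#' `(1 + exceed) / (n_perm + 1)` correction so it can never be zero. When
#' the number of distinct membership placements is at most
#' `exhaustive_limit`, complete enumeration replaces sampling and the
#' p-value is exact.
#'
#' @param ages Numeric ages.
#' @param mutated Logical membership flags, same length.
#' @param tail `"young"` or `"old"`.
#' @param n_perm Number of permutations (default 1e5).
#' @param seed Optional seed for the permutation stream.
#' @param exhaustive_limit Enumerate exactly when `choose(n, m)` is at most
#'   this (default 2e5).
#' @return One-row tibble `(tail, es, p_perm, n_perm, exact)`.
#' @export
age_rank_enrichment <- function(ages, mutated, tail = c("young", "old"),
                                n_perm = 1e5, seed = NULL,
                                exhaustive_limit = 2e5) {
  tail <- match.arg(tail)
  assert_that(length(ages) == length(mutated) && length(ages) >= 2,
              "ages and membership must have equal length >= 2")
  m <- sum(mutated); n <- length(mutated)
  assert_that(m >= 1 && m < n,
              "need at least one member and one non-member")
  ord <- if (tail == "young") order(ages) else order(-ages)
  positions <- which(mutated[ord])
  es <- running_sum_es(positions, m, n)

  n_placements <- choose(n, m)
  if (n_placements <= exhaustive_limit) {
    all_pos <- utils::combn(n, m)
    es_null <- apply(all_pos, 2, running_sum_es, m = m, n = n)
    p <- sum(es_null >= es - 1e-12) / n_placements
    return(tibble(tail = tail, es = es, p_perm = p,
                  n_perm = n_placements, exact = TRUE))
  }
  if (!is.null(seed)) set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    pos <- sort.int(sample.int(n, m))
    if (running_sum_es(pos, m, n) >= es - 1e-12) exceed <- exceed + 1L
  }
  tibble(tail = tail, es = es, p_perm = (1 + exceed) / (n_perm + 1),
         n_perm = n_perm, exact = FALSE)
}

#' Run the age enrichment test over a mutation matrix
#'
#' @param mat A [build_matrix()] object with `age_years` in its clinical
#'   table.
#' @param genes Genes to test (default: all with at least one carrier and
#'   one non-carrier).
#' @param tails Which tails to test per gene.
#' @param n_perm Permutations per tail.
#' @param seed Seed; per-gene sub-seeds are derived deterministically.
#' @return Tibble `(gene, tail, es, p_perm, n_perm, exact)`.
#' @export
age_enrichment <- function(mat, genes = NULL, tails = c("young", "old"),
                           n_perm = 1e5, seed = 1L) {
  ages <- mat$clinical$age_years
  ind <- mat$indicator
  genes <- genes %||% rownames(ind)[rowSums(ind) >= 1 & rowSums(ind) < ncol(ind)]
  purrr::map_dfr(seq_along(genes), function(i) {
    purrr::map_dfr(tails, function(tl) {
      age_rank_enrichment(ages, ind[genes[i], ], tail = tl, n_perm = n_perm,
                          seed = child_seed(seed, i * 2 + (tl == "old"))) %>%
        mutate(gene = genes[i], .before = 1)
    })
  })
}

#' Locate the age transition of each gene's mutation profile
#'
#' For pediatric-enriched genes the mutation density relative to children
#' starts at 1 and falls toward an adult plateau; the transition interval is
#' where the curve crosses from above 80% to below 60% of its pediatric
#' mean. Adult-enriched genes are handled symmetrically on the curve
#' normalized to the adult plateau (ages >= `adult_ref`), rising through the
#' mirrored thresholds. Genes whose curve does not cross both thresholds in
#' order, or recrosses afterwards, are flagged `no transition` and excluded
#' from the cohort median.
#'
#' @param curves Output of [age_density_curves()].
#' @param hi,lo Crossing thresholds (defaults 0.8 and 0.6).
#' @param pediatric_cut Pediatric reference bound (years).
#' @param adult_ref Age from which the adult plateau is measured.
#' @return List with `per_gene` (tibble: gene, direction, age_start,
#'   age_end, midpoint, transition flag) and `median_transition_age`, the
#'   cohort median of transition midpoints.
#' @export
transition_summary <- function(curves, hi = 0.8, lo = 0.6,
                               pediatric_cut = 18, adult_ref = 40) {
  per_gene <- curves %>%
    group_by(.data$gene) %>%
    group_modify(function(df, key) {
      # restrict to the data-supported age range: the density ratio is
      # unstable where almost no patients exist (the very old tail)
      supported <- df$density_all >= 0.10 * max(df$density_all)
      df <- df[supported, ]
      age <- df$age
      ped_mean <- mean(df$smoothed_frequency[age <= pediatric_cut])
      adult_mean <- mean(df$smoothed_frequency[age >= adult_ref])
      none <- tibble(direction = NA_character_, age_start = NA_real_,
                     age_end = NA_real_, midpoint = NA_real_,
                     transition = FALSE)
      if (!any(age <= pediatric_cut) || !any(age >= adult_ref)) return(none)
      falling <- is.finite(ped_mean) && ped_mean >= adult_mean
      if (falling && ped_mean > 0) {
        r <- df$smoothed_frequency / ped_mean
      } else if (!falling && adult_mean > 0) {
        # symmetric rise: normalize to the adult plateau, scan age downwards
        r <- rev(df$smoothed_frequency / adult_mean)
        age <- rev(age)
      } else {
        return(none)
      }
      flagged <- tibble(direction = if (falling) "falling" else "rising",
                        age_start = NA_real_, age_end = NA_real_,
                        midpoint = NA_real_, transition = FALSE)
      # the completing crossing: first drop below `lo` with no later
      # recovery above `hi` (monotone completion of the transition)
      below_lo <- which(r < lo)
      i_lo <- NA_integer_
      for (i in below_lo) {
        if (!any(r[i:length(r)] > hi)) { i_lo <- i; break }
      }
      if (is.na(i_lo)) return(flagged)
      # the entering crossing: last point still at/above `hi` before it
      before <- which(r[seq_len(i_lo)] >= hi)
      if (length(before) == 0) return(flagged)
      i_hi <- max(before)
      a_hi <- age[i_hi]; a_lo <- age[i_lo]
      tibble(direction = if (falling) "falling" else "rising",
             age_start = min(a_hi, a_lo), age_end = max(a_hi, a_lo),
             midpoint = (a_hi + a_lo) / 2, transition = TRUE)
    }) %>%
    ungroup()
  list(per_gene = per_gene,
       median_transition_age = median(per_gene$midpoint[per_gene$transition]))
}
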