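clin3 <- tibble::tibble(
  patient_id = c("P1", "P2", "P3"),
  age_years = c(5, 10, 40),
  cohort = c("pediatric", "pediatric", "adult"),
  sex = c("male", "female", "male")
)

test_that("the mutation matrix preserves multiplicity and full patient sets", {
  empty <- build_matrix(tibble::tibble(sample_id = character(),
                                       gene = character()), clin3)
  expect_equal(dim(empty$counts), c(0L, 3L))
  v <- tibble::tibble(sample_id = c("P1", "P1", "P2"),
                      gene = c("MYC", "MYC", "ID3"))
  m <- build_matrix(v, clin3)
  expect_equal(m$counts["MYC", "P1"], 2L)
  expect_true(m$indicator["MYC", "P1"])
  expect_equal(m$counts["MYC", "P2"], 0L)
  expect_error(build_matrix(tibble::tibble(sample_id = "P9", gene = "MYC"),
                            clin3), "P9")
})

test_that("one-sided Fisher p equals exhaustive fixed-margin enumeration", {
  expect_gte(fisher_one_sided(5, 10, 5, 10), 0.5)
  # oracle: enumerate all tables with the observed margins via binomial
  # coefficients, summing the probability of tables at least as extreme
  enum_p <- function(ka, na, kb, nb) {
    K <- ka + kb; N <- na + nb
    ks <- max(0, K - nb):min(na, K)
    probs <- choose(na, ks) * choose(nb, K - ks) / choose(N, na)
    # normalisation guards against floating overflow for larger tables
    probs <- probs / sum(probs)
    sum(probs[ks >= ka])
  }
  expect_equal(fisher_one_sided(8, 10, 1, 10), enum_p(8, 10, 1, 10))
  set.seed(2)
  for (i in 1:50) {
    na <- sample(1:30, 1); nb <- sample(1:30, 1)
    ka <- sample(0:na, 1); kb <- sample(0:nb, 1)
    expect_equal(fisher_one_sided(ka, na, kb, nb), enum_p(ka, na, kb, nb),
                 tolerance = 1e-12)
  }
  # direction swap is symmetric
  expect_equal(fisher_one_sided(3, 10, 8, 12, "b_greater"),
               fisher_one_sided(8, 12, 3, 10, "a_greater"))
  # the reconstructed pediatric-vs-adult ID3 table lands at order 1e-9
  p_id3 <- fisher_one_sided(145, 191, 39, 97)
  expect_lt(p_id3, 1e-8)
  expect_gt(p_id3, 1e-10)
  expect_error(fisher_one_sided(1, 0, 1, 5), "positive")
})

test_that("BH q-values follow the step-up rule and input order", {
  expect_equal(bh_fdr(0.04)$q, 0.04)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04))$q, rep(0.04, 4))
  all1 <- bh_fdr(rep(1, 5))
  expect_true(all(all1$q == 1) && !any(all1$significant))
  # permutation invariance
  p <- runif(20)
  perm <- sample(20)
  expect_equal(bh_fdr(p)$q[perm], bh_fdr(p[perm])$q)
  expect_error(bh_fdr(numeric(0)), "empty")
})

test_that("a real age effect is detected and the null is calibrated", {
  cfg <- cohort_config(n_pediatric = 300, n_adult = 150, seed = 11)
  cl <- quiet(simulate_clinical(cfg))
  v <- dplyr::transmute(cl$gene_counts, sample_id = patient_id, gene)
  m <- build_matrix(v[rep(seq_len(nrow(v)), cl$gene_counts$n_muts), ],
                    cl$clinical)
  res <- quiet(run_comparisons(m, "cohort"))
  id3 <- res[res$gene == "ID3", ]
  expect_equal(id3$direction, "a_greater")
  expect_true(id3$significant)
  expect_gt(id3$freq_a, id3$freq_b)
  # DDX3X male bias is recovered within the pediatric cohort
  ped <- cl$clinical[cl$clinical$cohort == "pediatric", ]
  m_ped <- build_matrix(
    v[rep(seq_len(nrow(v)), cl$gene_counts$n_muts), ] |>
      dplyr::filter(sample_id %in% ped$patient_id), ped)
  sexres <- quiet(run_comparisons(m_ped, "sex"))
  ddx <- sexres[sexres$gene == "DDX3X", ]
  expect_gt(ddx$freq_a, 5 * ddx$freq_b)
})

test_that("under a null contrast the empirical FDR stays below threshold", {
  set.seed(17)
  n_rep <- 200; n_pat <- 120; n_gene <- 30
  fdp <- numeric(n_rep)
  grp <- rep(c("a", "b"), each = n_pat / 2)
  for (r in seq_len(n_rep)) {
    rate <- runif(n_gene, 0.05, 0.4)
    ind <- matrix(rbinom(n_gene * n_pat, 1, rep(rate, n_pat)), nrow = n_gene)
    ka <- rowSums(ind[, grp == "a"]); kb <- rowSums(ind[, grp == "b"])
    dir <- ifelse(ka >= kb, "a_greater", "b_greater")
    p <- fisher_one_sided(ka, n_pat / 2, kb, n_pat / 2, dir)
    res <- bh_fdr(p, 0.1)
    fdp[r] <- as.numeric(sum(res$significant) > 0)  # all discoveries false
  }
  # every rejection is a false discovery under the null, so the rate of
  # replicates with any rejection bounds the FDR estimate
  expect_lte(mean(fdp), 0.1 + 2 * sqrt(0.1 * 0.9 / n_rep))
})

test_that("exclusivity accounting covers disjoint, identical and independent sets", {
  clin <- tibble::tibble(patient_id = sprintf("P%02d", 1:10),
                         age_years = 5, cohort = "pediatric")
  v <- tibble::tibble(
    sample_id = c("P01", "P02", "P03", "P04", "P01", "P02"),
    gene = c("A", "A", "B", "B", "C", "C"))
  m <- build_matrix(v, clin)
  dis <- exclusivity_summary(m, "A", "B")
  expect_equal(dis$both, 0)
  expect_equal(dis$pct_exactly_one, 40)
  same <- exclusivity_summary(m, "A", "C")
  expect_equal(same$only_a, 0)
  expect_equal(same$only_b, 0)
  expect_error(exclusivity_summary(m, "A", "Z"), "absent")
  # independent rates multiply: expected double-hit fraction is p_a * p_b
  set.seed(5)
  n <- 4000
  clin_big <- tibble::tibble(patient_id = sprintf("Q%04d", 1:n),
                             age_years = 8, cohort = "pediatric")
  va <- clin_big$patient_id[runif(n) < 0.32]
  vb <- clin_big$patient_id[runif(n) < 0.35]
  m2 <- build_matrix(tibble::tibble(
    sample_id = c(va, vb), gene = rep(c("ARID1A", "SMARCA4"),
                                      c(length(va), length(vb)))), clin_big)
  ex <- exclusivity_summary(m2, "ARID1A", "SMARCA4")
  expect_equal(ex$both / n, 0.32 * 0.35, tolerance = 0.15)
})
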