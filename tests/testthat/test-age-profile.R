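test_that("reflected KDE is symmetric, normalized, and edge-bias free", {
  set.seed(8)
  vals <- c(runif(200, 0, 80))
  sym <- c(vals, 80 - vals)  # symmetric about the midpoint by construction
  d <- reflected_kde(sym, c(0, 80))
  expect_equal(d$density, rev(d$density), tolerance = 1e-10)
  # integral equals 1 on the support
  integral <- sum((d$density[-1] + d$density[-nrow(d)]) * diff(d$x)) / 2
  expect_equal(integral, 1, tolerance = 1e-3)
  # uniform data: flat within 10% across the central 90%, including close
  # to the borders where an unreflected KDE decays to about half
  set.seed(9)
  u <- runif(10000, 0, 80)
  du <- reflected_kde(u, c(0, 80))
  central <- du$x >= 4 & du$x <= 76
  expect_true(all(abs(du$density[central] - 1 / 80) < 0.1 / 80))
  # histogram oracle agrees
  h <- hist(u, breaks = seq(0, 80, by = 8), plot = FALSE)
  at <- vapply(h$mids, function(m) du$density[which.min(abs(du$x - m))],
               numeric(1))
  expect_equal(at, h$density, tolerance = 0.05)
  # unreflected estimate decays at the boundary; reflection does not
  plain <- density(u, bw = attr(du, "bandwidth"), from = 0, to = 80)
  expect_lt(plain$y[1], 0.7 / 80)
  expect_gt(du$density[1], 0.9 / 80)
  expect_error(reflected_kde(1, c(0, 1)), "at least 2")
  expect_error(reflected_kde(c(1, 2), c(5, 5)), "degenerate")
})

test_that("enrichment p is exact under enumeration and calibrated under the null", {
  ages <- c(2, 4, 6, 8, 10, 25, 35, 45, 55, 65)
  mutated <- ages <= 6
  r <- age_rank_enrichment(ages, mutated, "young")
  expect_true(r$exact)
  expect_equal(r$n_perm, choose(10, 3))
  # independent oracle: enumerate every membership placement directly
  es_of <- function(memb) max(cumsum(ifelse(memb, 1 / 3, -1 / 7)))
  obs <- es_of(mutated[order(ages)])
  null_es <- apply(utils::combn(10, 3), 2,
                   function(ix) es_of(seq_len(10) %in% ix))
  expect_equal(r$p_perm, mean(null_es >= obs - 1e-12))
  expect_gte(r$p_perm, 1 / (r$n_perm + 1))
  # null calibration across 20 replicates
  set.seed(21)
  ps <- vapply(1:20, function(i) {
    a <- runif(200, 0, 80); m <- runif(200) < 0.3
    age_rank_enrichment(a, m, "young", n_perm = 600, seed = i)$p_perm
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("the enrichment score is rank-based and reflection-symmetric", {
  set.seed(3)
  a <- runif(40, 1, 80); m <- runif(40) < 0.4
  r1 <- age_rank_enrichment(a, m, "young", n_perm = 300, seed = 7)
  r2 <- age_rank_enrichment(a^3, m, "young", n_perm = 300, seed = 7)
  expect_equal(r1$es, r2$es)           # invariant to monotone transforms
  expect_equal(r1$p_perm, r2$p_perm)
  r3 <- age_rank_enrichment(-a, m, "old", n_perm = 300, seed = 7)
  expect_equal(r1$es, r3$es)           # young on ages = old on negated ages
  expect_equal(r1$p_perm, r3$p_perm)
  expect_error(age_rank_enrichment(a, rep(TRUE, 40), "young"), "non-member")
})

test_that("an old-enriched gene with no pediatric carriers reaches significance", {
  set.seed(12)
  cfg <- cohort_config(n_pediatric = 191, n_adult = 97, seed = 12)
  cl <- quiet(simulate_clinical(cfg))
  ages <- cl$clinical$age_years
  bcl2 <- cl$clinical$patient_id %in%
    cl$gene_counts$patient_id[cl$gene_counts$gene == "BCL2"]
  expect_gte(sum(bcl2), 3)  # deterministic under the config seed
  r <- age_rank_enrichment(ages, bcl2, "old", n_perm = 5000, seed = 2)
  expect_lt(r$p_perm, 0.001)
  expect_gt(min(ages[bcl2]), 25)
})

test_that("flat genes are flagged as having no transition", {
  grid <- seq(0, 80, length.out = 200)
  flat <- tibble::tibble(
    gene = "FLAT", age = grid,
    density_mutated = 1 / 80, density_all = 1 / 80,
    smoothed_frequency = 0.3,
    relative_to_children = 1)
  ts <- transition_summary(flat)
  expect_false(ts$per_gene$transition)
  expect_true(is.na(ts$median_transition_age) ||
                length(ts$median_transition_age) == 0)
})
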