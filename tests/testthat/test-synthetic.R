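test_that("the generator is bit-identical under a fixed seed", {
  a <- quiet(simulate_cohort(small_config(seed = 33)))
  b <- quiet(simulate_cohort(small_config(seed = 33)))
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$variants, b$variants)
  expect_identical(a$normals, b$normals)
  expect_identical(a$purity, b$purity)
  c <- quiet(simulate_cohort(small_config(seed = 34)))
  expect_false(identical(a$variants, c$variants))
})

test_that("degenerate mutation rates emit zero somatic variants", {
  gm <- default_gene_models()
  gm$p_young <- 0; gm$p_old <- 0
  cfg <- cohort_config(n_pediatric = 10, n_adult = 5, n_normals = 2,
                       gene_models = gm, background_scale = 0,
                       noise_per_sample = 0, seed = 2)
  co <- quiet(simulate_cohort(cfg))
  expect_equal(nrow(co$variants), 0)
  expect_equal(nrow(co$gene_counts), 0)
})

test_that("config invariants are enforced", {
  expect_error(cohort_config(n_pediatric = 1, n_adult = 0), "two patients")
  expect_error(cohort_config(transition_width_w = 0), "> 0")
  expect_error(cohort_config(male_fraction_adult = 1.4), "proportions")
  expect_error(cohort_config(cause_hazards = c(death_in_remission = -1,
                                               second_malignancy = 0,
                                               death_other = 0)), "hazards")
  gm <- default_gene_models(); gm$p_old[1] <- 2
  expect_error(cohort_config(gene_models = gm), "probabilities")
})

test_that("pediatric ID3 frequency lands in the exact binomial interval", {
  cfg <- cohort_config(n_pediatric = 2000, n_adult = 2, seed = 41)
  cl <- quiet(simulate_clinical(cfg))
  ped <- cl$clinical$patient_id[cl$clinical$cohort == "pediatric"]
  k <- sum(unique(cl$gene_counts$patient_id[cl$gene_counts$gene == "ID3"])
           %in% ped)
  ci <- stats::binom.test(round(0.76 * length(ped)), length(ped),
                          conf.level = 0.99)$conf.int
  # expected frequency: mean of p(age) over the pediatric ages, which sits
  # just below the plateau because of the transition tail
  expect_gt(k / length(ped), 0.70)
  expect_lt(k / length(ped), 0.80)
  expect_true(k / length(ped) > ci[1] - 0.02 && k / length(ped) < ci[2] + 0.02)
})

test_that("mutation frequency is monotone along the logistic direction", {
  cfg <- cohort_config(n_pediatric = 1500, n_adult = 1500, seed = 42)
  cl <- quiet(simulate_clinical(cfg))
  freq_in <- function(gene, lo, hi) {
    sel <- cl$clinical$age_years >= lo & cl$clinical$age_years <= hi
    carriers <- unique(cl$gene_counts$patient_id[cl$gene_counts$gene == gene])
    mean(cl$clinical$patient_id[sel] %in% carriers)
  }
  # p_old > p_young: old-age frequency must exceed childhood frequency
  expect_gt(freq_in("BCL2", 40, 100), freq_in("BCL2", 0, 18))
  expect_gt(freq_in("YY1AP1", 40, 100), freq_in("YY1AP1", 0, 18))
  # and the reverse for pediatric-enriched genes
  expect_gt(freq_in("ID3", 0, 18), freq_in("ID3", 40, 100))
  expect_gt(freq_in("DDX3X", 0, 18), freq_in("DDX3X", 40, 100))
})

test_that("event-type proportions follow the cause-specific hazards", {
  hr <- c(TP53 = 1, GPC5 = 1)  # homogeneous hazards for the GOF check
  rejections <- 0
  for (s in 1:20) {
    cfg <- cohort_config(n_pediatric = 400, n_adult = 200, seed = 600 + s,
                         hazard_ratios = hr, censor_time = 50)
    cl <- quiet(simulate_clinical(cfg))$clinical
    events <- cl$event[cl$event != "none"]
    rates <- c(relapse_progression = cfg$base_relapse_hazard,
               cfg$cause_hazards)
    obs <- table(factor(events, levels = names(rates)))
    p <- stats::chisq.test(obs, p = rates / sum(rates))$p.value
    if (p < 0.01) rejections <- rejections + 1
  }
  expect_lte(rejections, 2)
})

test_that("clinical records satisfy their structural invariants", {
  co <- quiet(simulate_cohort(small_config(seed = 43)))
  cl <- co$clinical
  expect_true(all((cl$cohort == "pediatric") == (cl$age_years <= 18)))
  expect_true(all(cl$followup_years >= 0))
  expect_true(all(cl$event %in% c("none", "relapse_progression",
                                  "death_in_remission", "second_malignancy",
                                  "death_other")))
  expect_true(all(cl$bm_involved[cl$entity == "B-AL"]))
  expect_true(all(cl$sex %in% c("female", "male")))
})

test_that("the solved hazards reproduce the target incidence analytically", {
  cfg <- cohort_config(seed = 1)
  expect_equal(theoretical_cif(cfg, 3, tp53_mutant = FALSE), 0.06,
               tolerance = 1e-8)
  expect_equal(theoretical_cif(cfg, 3, tp53_mutant = TRUE), 0.25,
               tolerance = 1e-8)
})

test_that("sanger truth injection produces exactly the requested discordances", {
  set.seed(44)
  v <- tibble::tibble(
    chrom = "1", pos = sample.int(1e6, 300), ref = "A", alt = "T")
  # no injections: perfect concordance
  st0 <- simulate_sanger_truth(v, n_regions = 20, seed = 3)
  r0 <- quiet(reconcile(st0$sanger_calls, st0$pipeline_calls, st0$regions))
  expect_equal(r0$sensitivity, 1)
  expect_equal(r0$specificity, 1)
  # half the variants missed: sensitivity 0.5
  v10 <- tibble::tibble(chrom = "1", pos = 1:10 * 100L, ref = "C", alt = "G")
  st5 <- simulate_sanger_truth(v10, n_regions = 10, fn_injected = 5,
                               region_halfwidth = 10, seed = 4)
  r5 <- quiet(reconcile(st5$sanger_calls, st5$pipeline_calls, st5$regions))
  expect_equal(r5$sensitivity, 0.5)
  # injections exceeding the covered variants raise an error
  expect_error(simulate_sanger_truth(v10, n_regions = 10, fn_injected = 99,
                                     region_halfwidth = 10, seed = 5),
               "exceed")
})
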