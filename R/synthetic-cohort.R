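#' Configure the synthetic Burkitt lymphoma cohort generator
#'
#' The generator emulates the statistical structure that the analysis stages
#' assume: per-gene mutation frequencies that transition logistically with
#' age between a pediatric and an adult plateau, a male-biased X-linked
#' gene, cause-specific exponential relapse/competing-event hazards
#' modulated by TP53 status, VAFs derived by inverting the purity/copy
#' number CCF relation for a drawn cancer cell fraction, and background
#' germline/artifact/noise variants that exercise the filter hierarchy and
#' panel of normals.
#'
#' The baseline relapse hazard and the TP53 hazard ratio are solved
#' numerically so that the true cumulative incidence of relapse at
#' `cif_horizon` equals `target_cif_wt` for TP53 wild-type and
#' `target_cif_mut` for TP53-mutant patients given the competing hazards.
#'
#' @param n_pediatric,n_adult Cohort sizes (default 191 / 97).
#' @param n_normals Number of normal subjects for panel-of-normals
#'   construction (default 86).
#' @param seed Integer seed; one seed governs every draw.
#' @param gene_models Tibble as [default_gene_models()].
#' @param transition_center_a0,transition_width_w Logistic age-transition
#'   parameters in years (defaults 35 and 5).
#' @param male_fraction_pediatric,male_fraction_adult Sex composition.
#' @param censor_time Administrative censoring horizon in years; individual
#'   censoring times are uniform on `[2, censor_time]`.
#' @param cause_hazards Named per-year rates for
#'   `death_in_remission`, `second_malignancy`, `death_other`; the
#'   `relapse_progression` baseline is solved from `target_cif_wt`.
#' @param hazard_ratios Named lesion -> multiplier on the relapse hazard;
#'   `TP53 = NA` is solved from `target_cif_mut`. `GPC5` multiplies the
#'   hazard of cases carrying the GPC5/MIR17HG copy gain (default 1 so the
#'   TP53 contrast has analytically exact truth; set it above 1 to study
#'   the double-hit pattern).
#' @param target_cif_wt,target_cif_mut,cif_horizon True relapse cumulative
#'   incidence targets at the horizon (defaults 0.06 / 0.25 at 3 years).
#' @param p_bal Probability of the leukemic presentation (B-AL).
#' @param bm_fraction,cns_fraction,rituximab_fraction Clinical covariate
#'   rates.
#' @param array_fraction Fraction of tumors with purity/copy-number
#'   estimates available.
#' @param gpc5_gain_fraction Fraction of pediatric cases with the
#'   GPC5/MIR17HG gain.
#' @param depth_mean Mean sequencing depth for binomial read sampling.
#' @param clonal_fraction Fraction of somatic variants that are clonal
#'   (true CCF 1); the rest draw a subclonal CCF.
#' @param paired_fraction Fraction of tumors with a matched normal.
#' @param n_snp_sites,n_rare_sites,n_artifact_sites,noise_per_sample
#'   Background panel sizes per the filter-stage emulation.
#' @param artifact_carrier_rate Per-sample presence probability of each
#'   recurrent artifact site (tumors and normals alike).
#' @param background_scale Scales all background panel sizes at once
#'   (useful for fast tests).
#' @return A validated list of class `blc_cohort_config`.
#' @export
cohort_config <- function(n_pediatric = 191L, n_adult = 97L, n_normals = 86L,
                          seed = 1L,
                          gene_models = default_gene_models(),
                          transition_center_a0 = 35,
                          transition_width_w = 5,
                          male_fraction_pediatric = 0.70,
                          male_fraction_adult = 0.60,
                          censor_time = 7,
                          cause_hazards = c(death_in_remission = 0.008,
                                            second_malignancy = 0.003,
                                            death_other = 0.002),
                          hazard_ratios = c(TP53 = NA_real_, GPC5 = 1),
                          target_cif_wt = 0.06, target_cif_mut = 0.25,
                          cif_horizon = 3,
                          p_bal = 0.24, bm_fraction = 0.35,
                          cns_fraction = 0.20, rituximab_fraction = 0.21,
                          array_fraction = 1.0, gpc5_gain_fraction = 0.18,
                          depth_mean = 200, clonal_fraction = 0.8,
                          paired_fraction = 0.45,
                          n_snp_sites = 1500L, n_rare_sites = 3000L,
                          n_artifact_sites = 300L, noise_per_sample = 1500L,
                          artifact_carrier_rate = 0.8,
                          background_scale = 1) {
  assert_that(n_pediatric >= 0 && n_adult >= 0 && n_pediatric + n_adult >= 2,
              "need at least two patients in total")
  assert_that(transition_width_w > 0, "transition_width_w must be > 0")
  assert_that(all(vapply(list(male_fraction_pediatric, male_fraction_adult,
                              p_bal, bm_fraction, cns_fraction,
                              rituximab_fraction, array_fraction,
                              gpc5_gain_fraction, clonal_fraction,
                              paired_fraction, artifact_carrier_rate),
                         is_proportion, logical(1))),
              "all proportions must lie in [0, 1]")
  assert_that(all(cause_hazards >= 0), "hazards must be >= 0")
  assert_that(is_proportion(gene_models$p_young) &&
                is_proportion(gene_models$p_old),
              "gene mutation probabilities must lie in [0, 1]")
  assert_that(all(gene_models$sex_odds_male > 0), "sex_odds_male must be > 0")
  assert_that(all(gene_models$mean_muts_if_mutated >= 1),
              "mean_muts_if_mutated must be >= 1")

  competing <- sum(cause_hazards)
  base_relapse <- solve_relapse_hazard(target_cif_wt, cif_horizon, competing)
  if (is.na(hazard_ratios[["TP53"]])) {
    mut_hazard <- solve_relapse_hazard(target_cif_mut, cif_horizon, competing)
    hazard_ratios[["TP53"]] <- mut_hazard / base_relapse
  }
  assert_that(all(hazard_ratios > 0), "hazard ratios must be > 0")

  structure(list(
    n_pediatric = as.integer(n_pediatric), n_adult = as.integer(n_adult),
    n_normals = as.integer(n_normals), seed = as.integer(seed),
    gene_models = gene_models,
    transition_center_a0 = transition_center_a0,
    transition_width_w = transition_width_w,
    male_fraction_pediatric = male_fraction_pediatric,
    male_fraction_adult = male_fraction_adult,
    censor_time = censor_time,
    cause_hazards = cause_hazards,
    base_relapse_hazard = base_relapse,
    hazard_ratios = hazard_ratios,
    target_cif_wt = target_cif_wt, target_cif_mut = target_cif_mut,
    cif_horizon = cif_horizon,
    p_bal = p_bal, bm_fraction = bm_fraction, cns_fraction = cns_fraction,
    rituximab_fraction = rituximab_fraction,
    array_fraction = array_fraction,
    gpc5_gain_fraction = gpc5_gain_fraction,
    depth_mean = depth_mean, clonal_fraction = clonal_fraction,
    paired_fraction = paired_fraction,
    n_snp_sites = as.integer(round(n_snp_sites * background_scale)),
    n_rare_sites = as.integer(round(n_rare_sites * background_scale)),
    n_artifact_sites = as.integer(round(n_artifact_sites * background_scale)),
    noise_per_sample = as.integer(round(noise_per_sample * background_scale)),
    artifact_carrier_rate = artifact_carrier_rate
  ), class = "blc_cohort_config")
}

# baseline hazard of the interest cause such that its CIF at `horizon`
# equals `target` under exponential competing hazards
solve_relapse_hazard <- function(target, horizon, competing) {
  if (target <= 0) return(0)
  f <- function(l1) {
    l <- l1 + competing
    l1 / l * (1 - exp(-l * horizon)) - target
  }
  uniroot(f, c(1e-8, 50), tol = 1e-12)$root
}

#' Analytic cumulative incidence of relapse under the generator model
#'
#' @param config A [cohort_config()].
#' @param t Time(s) in years.
#' @param tp53_mutant Evaluate for TP53-mutant (`TRUE`) or wild-type
#'   carriers at baseline GPC5 status.
#' @return True cumulative incidence values.
#' @export
theoretical_cif <- function(config, t, tp53_mutant = FALSE) {
  l1 <- config$base_relapse_hazard *
    if (tp53_mutant) config$hazard_ratios[["TP53"]] else 1
  l2 <- sum(config$cause_hazards)
  l1 / (l1 + l2) * (1 - exp(-(l1 + l2) * t))
}

#' @export
print.blc_cohort_config <- function(x, ...) {
  cat(sprintf("<synthetic cohort config: %d pediatric + %d adult, %d normals, seed %d>\n",
              x$n_pediatric, x$n_adult, x$n_normals, x$seed))
  cat(sprintf("  age transition: center %.0f y, width %.0f y; %d gene models\n",
              x$transition_center_a0, x$transition_width_w, nrow(x$gene_models)))
  cat(sprintf("  relapse hazard %.4f/y (TP53 HR %.2f); true 3y CIF %.0f%%/%.0f%%\n",
              x$base_relapse_hazard, x$hazard_ratios[["TP53"]],
              100 * x$target_cif_wt, 100 * x$target_cif_mut))
  invisible(x)
}

#' Simulate the clinical table and per-gene mutation status
#'
#' Draws demographics (discretized Beta ages with median 9 for children,
#' triangular ages with mode 52 for adults), disease descriptors, per-gene
#' mutation indicators from the logistic age model with male odds
#' multipliers, the GPC5/MIR17HG gain, and first-event follow-up from
#' cause-specific exponential hazards with lesion hazard ratios, censored
#' administratively.
#'
#' @param config A [cohort_config()].
#' @return List with `clinical` (one row per patient) and `gene_counts`
#'   (long tibble `patient_id`, `gene`, `n_muts` for mutated cases).
#' @export
simulate_clinical <- function(config) {
  set.seed(child_seed(config$seed, 1L))
  n_ped <- config$n_pediatric; n_ad <- config$n_adult
  n <- n_ped + n_ad

  age_ped <- round(18 * rbeta(n_ped, 2, 2))
  age_ad <- round(rtriangular(n_ad, 18, 85, 52))
  clinical <- tibble(
    patient_id = sprintf("P%04d", seq_len(n)),
    age_years = c(age_ped, age_ad),
    cohort = rep(c("pediatric", "adult"), c(n_ped, n_ad)),
    sex = if_else(
      runif(n) < rep(c(config$male_fraction_pediatric,
                       config$male_fraction_adult), c(n_ped, n_ad)),
      "male", "female"),
    entity = if_else(runif(n) < config$p_bal, "B-AL", "BL")
  )
  clinical <- clinical %>%
    mutate(
      bm_involved = .data$entity == "B-AL" | runif(n) < config$bm_fraction,
      cns_involved = runif(n) < config$cns_fraction,
      stage = sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                     prob = c(0.04, 0.06, 0.40, 0.50)),
      rituximab = runif(n) < config$rituximab_fraction,
      gpc5_gain = .data$cohort == "pediatric" &
        runif(n) < config$gpc5_gain_fraction
    )

  gm <- config$gene_models
  status <- purrr::map_dfr(seq_len(nrow(gm)), function(i) {
    p <- mutation_probability(clinical$age_years, clinical$sex,
                              gm$p_young[i], gm$p_old[i], gm$sex_odds_male[i],
                              config$transition_center_a0,
                              config$transition_width_w)
    mutated <- runif(n) < p
    k <- sum(mutated)
    if (k == 0) return(tibble())
    tibble(patient_id = clinical$patient_id[mutated], gene = gm$gene[i],
           n_muts = 1L + rpois(k, gm$mean_muts_if_mutated[i] - 1))
  })

  tp53_mut <- clinical$patient_id %in% status$patient_id[status$gene == "TP53"]
  hr <- config$hazard_ratios
  lambda_relapse <- config$base_relapse_hazard *
    ifelse(tp53_mut, hr[["TP53"]], 1) *
    ifelse(clinical$gpc5_gain, hr[["GPC5"]] %||% 1, 1)

  causes <- c("relapse_progression", names(config$cause_hazards))
  rates <- cbind(lambda_relapse,
                 matrix(rep(config$cause_hazards, each = n), nrow = n))
  times <- matrix(rexp(n * ncol(rates), rate = pmax(as.vector(rates), 1e-12)),
                  nrow = n)
  times[rates == 0] <- Inf
  first <- max.col(-times)
  t_event <- times[cbind(seq_len(n), first)]
  t_censor <- runif(n, min(2, config$censor_time), config$censor_time)
  clinical$followup_years <- pmin(t_event, t_censor)
  clinical$event <- if_else(t_event <= t_censor, causes[first], "none")
  clinical$tp53_mutant <- tp53_mut

  list(clinical = clinical, gene_counts = status)
}

# triangular distribution sampler on (lo, hi] with the given mode
rtriangular <- function(n, lo, hi, mode) {
  u <- runif(n)
  fc <- (mode - lo) / (hi - lo)
  if_else(u < fc,
          lo + sqrt(u * (hi - lo) * (mode - lo)),
          hi - sqrt((1 - u) * (hi - lo) * (hi - mode)))
}
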