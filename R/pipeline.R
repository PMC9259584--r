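#' Configure an end-to-end analysis run
#'
#' Bundles the cohort generator settings and every stage's analysis
#' parameters into one serializable object. A configuration round-trips
#' losslessly through YAML, and every pipeline artifact records the
#' configuration hash and seed, so a run is reproducible from its config
#' alone.
#'
#' @param cohort A [cohort_config()].
#' @param filter A [filter_config()].
#' @param n_perm Permutations per tail for the age enrichment stage.
#' @param q_threshold FDR threshold for association testing.
#' @param clonality_threshold CCF threshold for the clonal call.
#' @param horizon Reporting horizon (years) for cumulative incidence.
#' @param comparisons Character vector of association contrasts to run.
#' @param sanger_regions,sanger_fn,sanger_fp Validation-stage fixture
#'   parameters (regions and injected discordances).
#' @return List of class `blc_pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            filter = filter_config(),
                            n_perm = 1e4,
                            q_threshold = 0.1,
                            clonality_threshold = 0.9,
                            horizon = 3,
                            comparisons = c("cohort", "sex"),
                            sanger_regions = 40, sanger_fn = 1, sanger_fp = 1) {
  structure(list(
    cohort = cohort, filter = filter, n_perm = n_perm,
    q_threshold = q_threshold, clonality_threshold = clonality_threshold,
    horizon = horizon, comparisons = comparisons,
    sanger_regions = sanger_regions, sanger_fn = sanger_fn,
    sanger_fp = sanger_fp
  ), class = "blc_pipeline_config")
}

#' Serialize / restore a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `write_pipeline_config()` returns the path;
#'   `read_pipeline_config()` the restored configuration.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$cohort <- unclass(x$cohort)
  x$cohort$gene_models <- lapply(
    split(x$cohort$gene_models, seq_len(nrow(x$cohort$gene_models))),
    as.list)
  names(x$cohort$gene_models) <- NULL
  x$cohort$cause_hazards <- as.list(x$cohort$cause_hazards)
  x$cohort$hazard_ratios <- as.list(x$cohort$hazard_ratios)
  x$filter <- unclass(x$filter)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  gm <- purrr::map_dfr(x$cohort$gene_models, as_tibble)
  ch <- unlist(x$cohort$cause_hazards)
  hr <- unlist(x$cohort$hazard_ratios)
  cohort <- cohort_config(
    n_pediatric = x$cohort$n_pediatric, n_adult = x$cohort$n_adult,
    n_normals = x$cohort$n_normals, seed = x$cohort$seed,
    gene_models = gm,
    transition_center_a0 = x$cohort$transition_center_a0,
    transition_width_w = x$cohort$transition_width_w,
    male_fraction_pediatric = x$cohort$male_fraction_pediatric,
    male_fraction_adult = x$cohort$male_fraction_adult,
    censor_time = x$cohort$censor_time,
    cause_hazards = ch, hazard_ratios = hr,
    target_cif_wt = x$cohort$target_cif_wt,
    target_cif_mut = x$cohort$target_cif_mut,
    cif_horizon = x$cohort$cif_horizon,
    p_bal = x$cohort$p_bal, bm_fraction = x$cohort$bm_fraction,
    cns_fraction = x$cohort$cns_fraction,
    rituximab_fraction = x$cohort$rituximab_fraction,
    array_fraction = x$cohort$array_fraction,
    gpc5_gain_fraction = x$cohort$gpc5_gain_fraction,
    depth_mean = x$cohort$depth_mean,
    clonal_fraction = x$cohort$clonal_fraction,
    paired_fraction = x$cohort$paired_fraction,
    n_snp_sites = x$cohort$n_snp_sites,
    n_rare_sites = x$cohort$n_rare_sites,
    n_artifact_sites = x$cohort$n_artifact_sites,
    noise_per_sample = x$cohort$noise_per_sample,
    artifact_carrier_rate = x$cohort$artifact_carrier_rate
  )
  filter <- do.call(filter_config, x$filter)
  pipeline_config(
    cohort = cohort, filter = filter, n_perm = x$n_perm,
    q_threshold = x$q_threshold,
    clonality_threshold = x$clonality_threshold, horizon = x$horizon,
    comparisons = x$comparisons, sanger_regions = x$sanger_regions,
    sanger_fn = x$sanger_fn, sanger_fp = x$sanger_fp
  )
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes simulate, filter, CCF, association, age enrichment, survival
#' and validation stages in order, writing each stage's outputs as TSV
#' files with deterministic names into `out_dir`, and returns a manifest
#' of written files with MD5 hashes. Rerunning with the same configuration
#' reproduces the hashes exactly.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Tibble manifest `(stage, file, md5)` with the configuration
#'   hash and seed as attributes.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("blc_run_")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(out_dir, "config.yaml")
  write_pipeline_config(config, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  seed <- config$cohort$seed
  message("pipeline run: seed ", seed, ", config hash ", cfg_hash)
  files <- c(config = cfg_path)
  stage <- c(config = "config")
  emit <- function(df, name, stg) {
    p <- file.path(out_dir, name)
    readr::write_tsv(df, p)
    files[[name]] <<- p
    stage[[name]] <<- stg
  }

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  cohort <- run_stage("simulate", simulate_cohort(config$cohort))
  emit(cohort$clinical, "clinical.tsv", "simulate")
  write_variants_maf(cohort$variants, file.path(out_dir, "variants_raw.tsv"))
  files[["variants_raw.tsv"]] <- file.path(out_dir, "variants_raw.tsv")
  stage[["variants_raw.tsv"]] <- "simulate"
  emit(cohort$purity, "purity.tsv", "simulate")
  emit(cohort$segments, "segments.tsv", "simulate")

  filt <- run_stage("filter", {
    pon <- build_pon(cohort$normals)
    apply_filter_hierarchy(cohort$variants, config$filter, pon)
  })
  emit(filt$called %>% select(-dplyr::any_of(c("true_ccf", "true_vaf",
                                               "true_cn", "truth"))),
       "called.tsv", "filter")
  emit(filt$retention, "retention.tsv", "filter")

  ccf <- run_stage("ccf", suppressMessages(
    estimate_ccf(filt$called, cohort$purity, cohort$segments,
                 threshold = config$clonality_threshold)))
  emit(ccf %>% select(dplyr::any_of(c("sample_id", "key", "gene", "vaf",
                                      "cn_tumor", "ccf", "clonal"))),
       "ccf.tsv", "ccf")

  mat <- run_stage("associate", build_matrix(filt$called, cohort$clinical))
  assoc <- purrr::map_dfr(config$comparisons, function(cmp) {
    suppressMessages(run_comparisons(mat, cmp, q_threshold = config$q_threshold))
  })
  emit(assoc, "associations.tsv", "associate")

  enr <- run_stage("age_enrich", {
    curves <- age_density_curves(mat)
    top <- unique(curves$gene)
    list(curves = curves,
         enrich = age_enrichment(mat, genes = head(top, 10),
                                 n_perm = config$n_perm, seed = seed))
  })
  emit(enr$curves, "age_density.tsv", "age_enrich")
  emit(enr$enrich, "age_enrichment.tsv", "age_enrich")

  surv <- run_stage("survival", {
    rel <- derive_endpoint(cohort$clinical, "relapse")
    rel$group <- if_else(cohort$clinical$tp53_mutant, "TP53_mut", "TP53_wt")
    cif <- cumulative_incidence(rel, "relapse_progression", group = "group")
    gt <- gray_test(rel, "relapse_progression")
    list(cif = cif, gray = gt)
  })
  emit(surv$cif$curve, "cif_relapse.tsv", "survival")
  emit(tidy(surv$gray), "gray_test.tsv", "survival")

  val <- run_stage("validate", {
    st <- simulate_sanger_truth(filt$called, n_regions = config$sanger_regions,
                                fn_injected = config$sanger_fn,
                                fp_injected = config$sanger_fp,
                                seed = seed)
    reconcile(st$sanger_calls, st$pipeline_calls, st$regions)
  })
  emit(as_tibble(val), "validation.tsv", "validate")

  manifest <- tibble(
    stage = unname(unlist(stage)),
    file = basename(unname(unlist(files))),
    md5 = unname(tools::md5sum(unlist(files)))
  )
  attr(manifest, "config_hash") <- cfg_hash
  attr(manifest, "seed") <- seed
  manifest
}
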