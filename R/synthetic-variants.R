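#' Simulate a complete synthetic cohort
#'
#' Generates every input the analysis stages consume: the clinical table
#' with follow-up, per-sample purity/ploidy and copy-number segments, the
#' raw discovered variant table for all tumors (true somatic mutations plus
#' realistic background: recurrent germline SNPs, rare germline variants,
#' recurrent pipeline artifacts, and low-level sequencing noise), and
#' normal-sample variant lists for panel-of-normals construction.
#'
#' Somatic VAFs are generated by inverting the CCF relation: a true cancer
#' cell fraction is drawn (clonal mass at 1 plus a subclonal tail), the
#' noise-free VAF follows from purity and local copy number, and the
#' observed VAF adds binomial read sampling at the configured depth. The
#' noise-free columns (`true_ccf`, `true_vaf`, `true_cn`) are retained so
#' the estimator can be checked against generator truth.
#'
#' @param config A [cohort_config()].
#' @return List of class `blc_cohort`: `clinical`, `gene_counts`,
#'   `variants`, `purity`, `segments`, `normals`, `config`.
#' @export
simulate_cohort <- function(config) {
  clin <- simulate_clinical(config)
  clinical <- clin$clinical
  n <- nrow(clinical)

  set.seed(child_seed(config$seed, 2L))
  purity_all <- tibble(
    sample_id = clinical$patient_id,
    purity = 0.30 + 0.65 * rbeta(n, 8, 3),
    ploidy = if_else(runif(n) < 0.04, 2 + round(runif(n, 1.2, 1.8), 1), 2)
  )
  segments_all <- make_segments(clinical, purity_all)

  set.seed(child_seed(config$seed, 3L))
  somatic <- make_somatic_variants(clin$gene_counts, clinical, purity_all,
                                   segments_all, config)

  set.seed(child_seed(config$seed, 4L))
  bg <- make_background(clinical, config)
  somatic$paired_normal <- unname(bg$paired[somatic$sample_id])

  set.seed(child_seed(config$seed, 5L))
  normals <- make_normals(bg$panels, config)

  variants <- bind_rows(somatic, bg$variants) %>%
    arrange(.data$sample_id, .data$chrom, .data$pos)

  with_array <- runif(n) < config$array_fraction
  structure(list(
    clinical = clinical,
    gene_counts = clin$gene_counts,
    variants = variants,
    purity = purity_all[with_array, ],
    segments = semi_join(segments_all, purity_all[with_array, ],
                         by = "sample_id"),
    normals = normals,
    config = config
  ), class = "blc_cohort")
}

#' @export
print.blc_cohort <- function(x, ...) {
  cat(sprintf("<synthetic cohort: %d patients, %d raw variants (%d somatic), %d normals>\n",
              nrow(x$clinical), nrow(x$variants),
              sum(x$variants$truth == "somatic"),
              dplyr::n_distinct(x$normals$subject_id)))
  invisible(x)
}

# copy-number segments per sample: chromosome-wide baseline at rounded
# ploidy, a GPC5/MIR17HG focal gain for flagged cases, and an occasional
# focal 1p deletion covering E2F2/ID3
make_segments <- function(clinical, purity) {
  loci <- gene_loci()
  chroms <- unique(loci$chrom)
  chrom_len <- 250e6
  gpc5 <- loci[loci$gene == "GPC5", ]
  base <- tidyr::expand_grid(sample_id = clinical$patient_id, chrom = chroms) %>%
    left_join(purity %>% select("sample_id", "ploidy"), by = "sample_id") %>%
    mutate(start = 1, end = chrom_len, cn = round(.data$ploidy)) %>%
    select(-"ploidy")
  gain_ids <- clinical$patient_id[clinical$gpc5_gain]
  del_ids <- clinical$patient_id[runif(nrow(clinical)) < 0.08]
  focal <- bind_rows(
    tibble(sample_id = gain_ids, chrom = gpc5$chrom,
           start = gpc5$start, end = gpc5$end + 1, cn = 4L),
    tibble(sample_id = del_ids, chrom = "1",
           start = 23400000, end = 23700000, cn = 1L)
  )
  if (nrow(focal) == 0) return(base)
  # split baselines around each focal segment to keep segments disjoint
  hit <- base %>%
    inner_join(focal %>% select("sample_id", "chrom") %>% distinct(),
               by = c("sample_id", "chrom"))
  unhit <- base %>%
    anti_join(focal %>% select("sample_id", "chrom") %>% distinct(),
              by = c("sample_id", "chrom"))
  pieces <- hit %>%
    left_join(focal %>% rename(f_start = "start", f_end = "end", f_cn = "cn"),
              by = c("sample_id", "chrom")) %>%
    group_by(.data$sample_id, .data$chrom) %>%
    group_modify(function(df, key) {
      cuts <- sort(unique(c(1, df$f_start, df$f_end, 250e6 + 1)))
      out <- tibble(start = head(cuts, -1), end = tail(cuts, -1),
                    cn = df$cn[1])
      for (i in seq_len(nrow(df))) {
        inside <- out$start >= df$f_start[i] & out$end <= df$f_end[i]
        out$cn[inside] <- df$f_cn[i]
      }
      out
    }) %>%
    ungroup()
  bind_rows(unhit, pieces) %>%
    arrange(.data$sample_id, .data$chrom, .data$start)
}

# expand per-gene mutation counts into somatic variant records with VAFs
# derived by inverting the CCF relation, then binomial read noise
make_somatic_variants <- function(gene_counts, clinical, purity, segments,
                                  config) {
  if (nrow(gene_counts) == 0) return(empty_variants())
  loci <- gene_loci()
  rows <- gene_counts[rep(seq_len(nrow(gene_counts)), gene_counts$n_muts), ] %>%
    select("patient_id", "gene") %>%
    left_join(loci, by = "gene")
  m <- nrow(rows)
  pos <- floor(runif(m, rows$start, rows$end + 1))
  is_indel <- runif(m) < 0.15
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  ins <- is_indel & runif(m) < 0.5
  ext <- vapply(sample.int(6, m, replace = TRUE), function(k) {
    paste(sample(bases, k, replace = TRUE), collapse = "")
  }, character(1))
  ref[is_indel & !ins] <- paste0(ref[is_indel & !ins], ext[is_indel & !ins])
  alt[is_indel & !ins] <- substr(ref[is_indel & !ins], 1, 1)
  alt[ins] <- paste0(ref[ins], ext[ins])

  consequence <- sample(
    c("missense", "nonsense", "frameshift", "splice_site", "synonymous",
      "inframe_indel"),
    m, replace = TRUE, prob = c(0.52, 0.15, 0.15, 0.07, 0.08, 0.03))

  out <- tibble(
    sample_id = rows$patient_id, chrom = rows$chrom, pos = as.integer(pos),
    ref = ref, alt = alt, gene = rows$gene, consequence = consequence
  ) %>%
    left_join(purity, by = "sample_id") %>%
    left_join(
      segments %>% select("sample_id", "chrom", "start", "end", cn = "cn"),
      by = join_by("sample_id", "chrom", "pos" >= "start", "pos" < "end")
    ) %>%
    mutate(
      true_cn = dplyr::coalesce(.data$cn, round(.data$ploidy)),
      true_ccf = if_else(runif(m) < config$clonal_fraction,
                         1, 0.05 + 0.9 * rbeta(m, 2, 3)),
      true_vaf = pmin(0.999, .data$true_ccf * .data$purity /
                        ((1 - .data$purity) * 2 + .data$purity * .data$true_cn)),
      depth = rnbinom(m, size = 25, mu = config$depth_mean) + 1L,
      alt_count = rbinom(m, .data$depth, .data$true_vaf),
      vaf = .data$alt_count / .data$depth,
      caller_pass = runif(m) < 0.97,
      pop_af = NA_real_,
      dbsnp_common = FALSE,
      in_cosmic = runif(m) < 0.35,
      truth = "somatic"
    ) %>%
    select(-"start", -"end", -"cn", -"purity", -"ploidy")
  out
}

empty_variants <- function() {
  tibble(sample_id = character(), chrom = character(), pos = integer(),
         ref = character(), alt = character(), gene = character(),
         consequence = character(), true_cn = numeric(), true_ccf = numeric(),
         true_vaf = numeric(), depth = integer(), alt_count = integer(),
         vaf = numeric(), caller_pass = logical(), pop_af = numeric(),
         dbsnp_common = logical(), in_cosmic = logical(), truth = character(),
         paired_normal = logical())
}

# shared background site panels (common SNPs, rare germline, recurrent
# artifacts) and per-tumor background variants including sequencing noise
make_background <- function(clinical, config) {
  loci <- gene_loci()
  site_panel <- function(n_sites) {
    g <- loci[sample.int(nrow(loci), n_sites, replace = TRUE), ]
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_sites, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    tibble(chrom = g$chrom,
           pos = as.integer(floor(runif(n_sites, g$start, g$end + 1))),
           ref = ref, alt = alt, gene = g$gene)
  }
  snp <- site_panel(config$n_snp_sites) %>%
    mutate(af = pmin(0.5, rbeta(dplyr::n(), 0.7, 1.3) * 0.5))
  rare <- site_panel(config$n_rare_sites) %>%
    mutate(af = 10^runif(dplyr::n(), -4, -2.3))
  artifact <- site_panel(config$n_artifact_sites)

  samples <- clinical$patient_id
  n_s <- length(samples)
  paired <- setNames(runif(n_s) < config$paired_fraction, samples)

  germline_cons <- function(k) sample(
    c("intronic", "UTR", "synonymous", "missense", "inframe_indel",
      "splice_site", "nonsense"),
    k, replace = TRUE, prob = c(0.45, 0.20, 0.12, 0.18, 0.02, 0.01, 0.02))

  draw_germline <- function(sites, common) {
    p_carrier <- 1 - (1 - sites$af)^2
    idx <- which(runif(nrow(sites) * n_s) <
                   rep(p_carrier, times = n_s))
    site_i <- (idx - 1) %% nrow(sites) + 1
    samp_i <- (idx - 1) %/% nrow(sites) + 1
    k <- length(idx)
    if (k == 0) return(empty_variants())
    hom <- runif(k) < sites$af[site_i] / (2 - sites$af[site_i])
    tv <- if_else(hom, 1, 0.5)
    depth <- rnbinom(k, size = 25, mu = config$depth_mean) + 1L
    altc <- rbinom(k, depth, pmin(tv, 0.999))
    is_paired <- paired[samples[samp_i]]
    tibble(
      sample_id = samples[samp_i],
      chrom = sites$chrom[site_i], pos = sites$pos[site_i],
      ref = sites$ref[site_i], alt = sites$alt[site_i],
      gene = sites$gene[site_i],
      consequence = germline_cons(k),
      true_cn = NA_real_, true_ccf = NA_real_, true_vaf = tv,
      depth = depth, alt_count = altc, vaf = altc / depth,
      # a paired caller removes most germline variants itself
      caller_pass = if_else(is_paired, runif(k) < 0.05, TRUE),
      pop_af = sites$af[site_i],
      dbsnp_common = sites$af[site_i] >= 0.05,
      in_cosmic = FALSE,
      truth = if (common) "germline_common" else "germline_rare",
      paired_normal = unname(is_paired)
    )
  }
  g_common <- draw_germline(snp, TRUE)
  g_rare <- draw_germline(rare, FALSE)

  # recurrent artifacts: same sites keep showing up across samples
  art_idx <- which(runif(nrow(artifact) * n_s) < config$artifact_carrier_rate)
  asite <- (art_idx - 1) %% nrow(artifact) + 1
  asamp <- (art_idx - 1) %/% nrow(artifact) + 1
  ka <- length(art_idx)
  art <- if (ka == 0) empty_variants() else {
    tv <- runif(ka, 0.03, 0.25)
    depth <- rnbinom(ka, size = 25, mu = config$depth_mean) + 1L
    altc <- rbinom(ka, depth, tv)
    tibble(
      sample_id = samples[asamp],
      chrom = artifact$chrom[asite], pos = artifact$pos[asite],
      ref = artifact$ref[asite], alt = artifact$alt[asite],
      gene = artifact$gene[asite],
      consequence = germline_cons(ka),
      true_cn = NA_real_, true_ccf = NA_real_, true_vaf = tv,
      depth = depth, alt_count = altc, vaf = altc / depth,
      caller_pass = TRUE, pop_af = NA_real_, dbsnp_common = FALSE,
      in_cosmic = FALSE, truth = "artifact",
      paired_normal = unname(paired[samples[asamp]])
    )
  }

  # low-level sequencing noise, mostly rejected by the caller already
  kn <- rpois(1, config$noise_per_sample * n_s)
  noise <- if (kn == 0) empty_variants() else {
    g <- loci[sample.int(nrow(loci), kn, replace = TRUE), ]
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, kn, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    tv <- rbeta(kn, 1, 80)
    depth <- rnbinom(kn, size = 25, mu = config$depth_mean) + 1L
    altc <- rbinom(kn, depth, tv)
    sid <- sample(samples, kn, replace = TRUE)
    tibble(
      sample_id = sid, chrom = g$chrom,
      pos = as.integer(floor(runif(kn, g$start, g$end + 1))),
      ref = ref, alt = alt, gene = g$gene,
      consequence = germline_cons(kn),
      true_cn = NA_real_, true_ccf = NA_real_, true_vaf = tv,
      depth = depth, alt_count = altc, vaf = altc / depth,
      caller_pass = runif(kn) < 0.05,
      pop_af = NA_real_, dbsnp_common = FALSE, in_cosmic = FALSE,
      truth = "noise", paired_normal = unname(paired[sid])
    )
  }

  variants <- bind_rows(g_common, g_rare, art, noise)
  list(variants = variants,
       panels = list(snp = snp, rare = rare, artifact = artifact),
       paired = paired)
}

# normal-subject variant lists: germline carriers plus the same recurrent
# artifacts, so the panel of normals can discover both
make_normals <- function(panels, config) {
  n_norm <- config$n_normals
  subjects <- sprintf("N%03d", seq_len(n_norm))
  draw <- function(sites, p_present) {
    idx <- which(runif(nrow(sites) * n_norm) < rep(p_present, times = n_norm))
    site_i <- (idx - 1) %% nrow(sites) + 1
    subj_i <- (idx - 1) %/% nrow(sites) + 1
    tibble(subject_id = subjects[subj_i],
           chrom = sites$chrom[site_i], pos = sites$pos[site_i],
           ref = sites$ref[site_i], alt = sites$alt[site_i])
  }
  bind_rows(
    draw(panels$snp, 1 - (1 - panels$snp$af)^2),
    draw(panels$rare, 1 - (1 - panels$rare$af)^2),
    draw(panels$artifact, rep(config$artifact_carrier_rate,
                              nrow(panels$artifact)))
  ) %>% arrange(.data$subject_id, .data$chrom, .data$pos)
}

#' Simulate an orthogonal validation call-set pair
#'
#' Builds a Sanger-style truth list and a pipeline call list over a set of
#' covered regions, differing by exactly the injected discordances: hard
#' false negatives (variants the pipeline never discovered), false
#' positives (pipeline-only calls), confirmed-filtered calls (discovered by
#' both but filtered by the pipeline), and representation-review matches
#' (same variant, different raw allele representation).
#'
#' @param variants Called variant table (`chrom`, `pos`, `ref`, `alt`).
#' @param n_regions Number of covered regions, each centered on a sampled
#'   variant.
#' @param fn_injected,fp_injected,filtered_injected,review_injected Counts
#'   of injected discordances/categories.
#' @param region_halfwidth Half-width of each covered region in bp.
#' @param seed Seed for the draws.
#' @return List with `sanger_calls`, `pipeline_calls` (with a `filtered`
#'   flag) and `regions` (BED-style 0-based half-open).
#' @export
simulate_sanger_truth <- function(variants, n_regions = 40, fn_injected = 0,
                                  fp_injected = 0, filtered_injected = 0,
                                  review_injected = 0,
                                  region_halfwidth = 400, seed = 1L) {
  set.seed(seed)
  variants <- as_tibble(variants) %>%
    distinct(.data$chrom, .data$pos, .data$ref, .data$alt)
  assert_that(nrow(variants) > 0, "no variants supplied")
  anchors <- variants[sample.int(nrow(variants), min(n_regions, nrow(variants))), ]
  regions <- tibble(chrom = anchors$chrom,
                    start = pmax(0, anchors$pos - region_halfwidth - 1),
                    end = anchors$pos + region_halfwidth) %>%
    distinct()
  covered <- variants %>%
    inner_join(regions, by = join_by("chrom", "pos" > "start", "pos" <= "end")) %>%
    distinct(.data$chrom, .data$pos, .data$ref, .data$alt)
  n_cov <- nrow(covered)
  n_inject <- fn_injected + fp_injected + filtered_injected + review_injected
  assert_that(n_inject <= n_cov + fp_injected,
              "injected counts exceed the variants available in covered regions")

  idx <- sample.int(n_cov)
  fn_idx <- idx[seq_len(fn_injected)]
  filt_idx <- idx[seq_len(filtered_injected) + fn_injected]
  rev_idx <- idx[seq_len(review_injected) + fn_injected + filtered_injected]

  sanger <- covered
  pipeline <- if (length(fn_idx) > 0) covered[-fn_idx, ] else covered
  pipeline$filtered <- FALSE
  pipeline$filtered[match_rows(pipeline, covered[filt_idx, ])] <- TRUE
  # representation shift: pad ref and alt with one shared trailing base so
  # the raw strings differ but the normalized key is unchanged
  shift <- match_rows(pipeline, covered[rev_idx, ])
  pipeline$ref[shift] <- paste0(pipeline$ref[shift], "G")
  pipeline$alt[shift] <- paste0(pipeline$alt[shift], "G")

  if (fp_injected > 0) {
    fp_anchor <- regions[sample.int(nrow(regions), fp_injected, replace = TRUE), ]
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, fp_injected, replace = TRUE)
    fp <- tibble(
      chrom = fp_anchor$chrom,
      pos = as.integer(fp_anchor$start + 1 +
                         floor(runif(fp_injected, 0, 2 * region_halfwidth))),
      ref = ref,
      alt = vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1)),
      filtered = FALSE
    )
    pipeline <- bind_rows(pipeline, anti_join(
      fp, sanger, by = c("chrom", "pos", "ref", "alt")))
  }
  list(sanger_calls = sanger, pipeline_calls = pipeline, regions = regions)
}

match_rows <- function(x, y) {
  which(paste(x$chrom, x$pos, x$ref, x$alt) %in%
          paste(y$chrom, y$pos, y$ref, y$alt))
}
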