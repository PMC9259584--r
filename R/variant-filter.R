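#' Build a panel of normals (PON)
#'
#' Catalogues variants seen across normal (germline) samples so that
#' recurrent germline variants and pipeline-specific artifacts can be removed
#' from tumor call sets. A variant becomes a panel member when it is supported
#' by at least `min_support` *distinct* normal subjects; duplicate records of
#' the same variant within one subject count once.
#'
#' @param normal_variants Data frame of variants observed in normals, with a
#'   `subject_id` column and either a `key` column or `chrom`/`pos`/`ref`/`alt`.
#' @param min_support Minimum number of distinct supporting subjects for
#'   membership (default 2).
#' @return A tibble of class `blc_pon` with columns `key` and `n_subjects`
#'   (one row per variant ever seen in a normal), and a `min_support`
#'   attribute governing membership.
#' @examples
#' normals <- tibble::tibble(
#'   subject_id = c("A", "B", "C"),
#'   chrom = "1", pos = c(100, 100, 200), ref = "A", alt = "G"
#' )
#' pon <- build_pon(normals)
#' pon_member(pon, normalize_variant_key("1", c(100, 200), "A", "G"))
#' @export
build_pon <- function(normal_variants, min_support = 2L) {
  assert_that(is.numeric(min_support) && min_support >= 1,
              "min_support must be >= 1")
  if (nrow(normal_variants) == 0) {
    pon <- tibble(key = character(), n_subjects = integer())
  } else {
    assert_that(!is.null(normal_variants[["subject_id"]]),
                "normal variants must carry a subject_id column")
    pon <- normal_variants %>%
      add_variant_key() %>%
      distinct(.data$subject_id, .data$key) %>%
      count(.data$key, name = "n_subjects") %>%
      arrange(.data$key)
  }
  structure(pon, class = c("blc_pon", class(pon)),
            min_support = as.integer(min_support))
}

#' Test panel membership for a set of variant keys
#'
#' @param pon A panel built by [build_pon()].
#' @param keys Character vector of normalized variant keys.
#' @return Logical vector: is each key supported by at least the panel's
#'   `min_support` distinct subjects?
#' @export
pon_member <- function(pon, keys) {
  members <- pon$key[pon$n_subjects >= attr(pon, "min_support")]
  keys %in% members
}

#' Consequence severity ranking
#'
#' The default protein-level severity order used to pick, per variant, the
#' transcript annotation with the strongest biological consequence. Most
#' severe first.
#'
#' @return Character vector of consequence classes, most severe first.
#' @export
consequence_severity <- function() {
  c("frameshift", "nonsense", "splice_site", "missense", "inframe_indel",
    "synonymous", "UTR", "intronic", "intergenic")
}

#' Pick the strongest-consequence transcript annotation
#'
#' A variant annotated against several transcripts of the same gene can look
#' intronic on one transcript and protein-changing on another. For calling
#' purposes the annotation with the strongest possible protein-level
#' consequence is retained; ties are broken by the lexicographically smallest
#' transcript identifier so the choice is deterministic.
#'
#' @param consequences Data frame with columns `transcript_id` and
#'   `consequence`, one row per transcript annotation of a single variant.
#' @param severity Character vector ordering consequence classes from most to
#'   least severe; every class present must appear in it.
#' @return A one-row tibble `(transcript_id, consequence)`.
#' @examples
#' strongest_consequence(tibble::tibble(
#'   transcript_id = c("NM_1", "NM_2"),
#'   consequence = c("intronic", "missense")
#' ))
#' @export
strongest_consequence <- function(consequences, severity = consequence_severity()) {
  consequences <- as_tibble(consequences)
  assert_that(nrow(consequences) > 0, "at least one transcript annotation required")
  unknown <- setdiff(unique(consequences$consequence), severity)
  if (length(unknown) > 0) {
    stop("unknown consequence class: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  consequences %>%
    mutate(.rank = match(.data$consequence, severity)) %>%
    arrange(.data$.rank, .data$transcript_id) %>%
    slice(1) %>%
    select("transcript_id", "consequence")
}

#' Collapse a long transcript-annotation table to strongest consequences
#'
#' @param annotations Data frame with `key`, `transcript_id`, `consequence`
#'   (one row per variant x transcript).
#' @param severity Severity order, most severe first.
#' @return Tibble with one row per `key`: the selected `transcript_id` and
#'   `consequence`.
#' @export
annotate_strongest_consequence <- function(annotations,
                                           severity = consequence_severity()) {
  annotations <- as_tibble(annotations)
  unknown <- setdiff(unique(annotations$consequence), severity)
  if (length(unknown) > 0) {
    stop("unknown consequence class: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  annotations %>%
    mutate(.rank = match(.data$consequence, severity)) %>%
    arrange(.data$key, .data$.rank, .data$transcript_id) %>%
    distinct(.data$key, .keep_all = TRUE) %>%
    select("key", "transcript_id", "consequence")
}

#' Configure the multistage somatic filter hierarchy
#'
#' The filter converts raw discovered variants into called somatic mutations
#' through an explicit, ordered chain of steps. Each step's parameters and the
#' step order itself are recorded alongside results, so a filtering run is
#' fully reproducible from its configuration.
#'
#' @param steps Character vector giving the step order. Available steps:
#'   `caller_pass`, `panel_of_normals`, `population_af`, `dbsnp_common`,
#'   `min_depth`, `min_alt_count`, `min_vaf`, `consequence`.
#' @param caller_pass_required Drop variants failing upstream caller QC.
#' @param max_pop_af Maximum population allele frequency (gnomAD-style) for a
#'   somatic candidate; missing values pass. Default 0.001.
#' @param drop_dbsnp_common Drop variants flagged as common (>= 5\% population
#'   frequency) in dbSNP. Default `TRUE`.
#' @param cosmic_rescue When `TRUE`, a variant failing the population-AF or
#'   dbSNP step is retained if it is a confirmed somatic mutation in COSMIC.
#' @param min_depth Minimum read depth (default 20).
#' @param min_alt_count Minimum alt-supporting reads (default 3).
#' @param min_vaf Minimum variant allele frequency (default 0.05).
#' @param min_vaf_unpaired Stricter VAF floor applied to samples without a
#'   matched normal when `unpaired_strict = TRUE` (default 0.10).
#' @param unpaired_strict Apply `min_vaf_unpaired` to unpaired samples.
#' @param consequence_blacklist Consequence classes dropped in the
#'   `consequence` step.
#' @return A list of class `blc_filter_config`.
#' @export
filter_config <- function(steps = c("caller_pass", "panel_of_normals",
                                    "population_af", "dbsnp_common",
                                    "min_depth", "min_alt_count", "min_vaf",
                                    "consequence"),
                          caller_pass_required = TRUE,
                          max_pop_af = 0.001,
                          drop_dbsnp_common = TRUE,
                          cosmic_rescue = TRUE,
                          min_depth = 20L,
                          min_alt_count = 3L,
                          min_vaf = 0.05,
                          min_vaf_unpaired = 0.10,
                          unpaired_strict = FALSE,
                          consequence_blacklist = c("synonymous", "intronic",
                                                    "intergenic", "UTR")) {
  known <- c("caller_pass", "panel_of_normals", "population_af", "dbsnp_common",
             "min_depth", "min_alt_count", "min_vaf", "consequence")
  assert_that(all(steps %in% known),
              paste("unknown filter step(s):",
                    paste(setdiff(steps, known), collapse = ", ")))
  assert_that(is_proportion(max_pop_af) && is_proportion(min_vaf) &&
                is_proportion(min_vaf_unpaired),
              "thresholds on proportions must lie in [0, 1]")
  assert_that(min_depth >= 0 && min_alt_count >= 0, "count thresholds must be >= 0")
  structure(list(
    steps = steps,
    caller_pass_required = caller_pass_required,
    max_pop_af = max_pop_af,
    drop_dbsnp_common = drop_dbsnp_common,
    cosmic_rescue = cosmic_rescue,
    min_depth = as.integer(min_depth),
    min_alt_count = as.integer(min_alt_count),
    min_vaf = min_vaf,
    min_vaf_unpaired = min_vaf_unpaired,
    unpaired_strict = unpaired_strict,
    consequence_blacklist = consequence_blacklist
  ), class = "blc_filter_config")
}

# verdict (keep = TRUE) of one named step on a variant subset
step_verdict <- function(step, df, config, pon) {
  col <- function(nm, default) df[[nm]] %||% rep(default, nrow(df))
  rescue <- if (isTRUE(config$cosmic_rescue)) {
    col("in_cosmic", FALSE) %in% TRUE
  } else rep(FALSE, nrow(df))
  switch(step,
    caller_pass = if (isTRUE(config$caller_pass_required)) {
      col("caller_pass", TRUE) %in% TRUE
    } else rep(TRUE, nrow(df)),
    panel_of_normals = if (is.null(pon)) rep(TRUE, nrow(df)) else {
      !pon_member(pon, df$key)
    },
    population_af = {
      af <- col("pop_af", NA_real_)
      (is.na(af) | af <= config$max_pop_af) | rescue
    },
    dbsnp_common = if (isTRUE(config$drop_dbsnp_common)) {
      !(col("dbsnp_common", FALSE) %in% TRUE) | rescue
    } else rep(TRUE, nrow(df)),
    min_depth = col("depth", Inf) >= config$min_depth,
    min_alt_count = col("alt_count", Inf) >= config$min_alt_count,
    min_vaf = {
      floorv <- rep(config$min_vaf, nrow(df))
      if (isTRUE(config$unpaired_strict)) {
        unpaired <- !(col("paired_normal", TRUE) %in% TRUE)
        floorv[unpaired] <- config$min_vaf_unpaired
      }
      col("vaf", 1) >= floorv
    },
    consequence = !(col("consequence", "missense") %in% config$consequence_blacklist),
    stop("unknown filter step: ", step, call. = FALSE)
  )
}

#' Apply the ordered somatic filter hierarchy
#'
#' Runs every configured step in order over a raw variant table. Each
#' variant's filter trail records the verdict of every step it reached (a
#' variant dropped at step *k* has a trail of length *k*); the retention table
#' reports, per step, how many variants entered, how many survived, and the
#' percentage of the *original* input remaining -- the bookkeeping needed to
#' report what fraction of discovered variants is ultimately called somatic.
#'
#' @param variants Raw variant table. Recognised columns: `sample_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `gene`, `consequence`, `vaf`, `alt_count`,
#'   `depth`, `caller_pass`, `pop_af`, `in_cosmic`, `dbsnp_common`,
#'   `paired_normal`. Missing annotation columns make the corresponding step
#'   a no-op for those fields.
#' @param config A [filter_config()].
#' @param pon Optional [build_pon()] panel for the `panel_of_normals` step.
#' @return A list of class `blc_filter_result`:
#'   \describe{
#'     \item{called}{tibble of variants surviving every step}
#'     \item{retention}{tibble `(step, n_in, n_out, pct_remaining)`}
#'     \item{trail}{logical matrix (variant x step) of verdicts, `NA` for
#'       steps after a variant was dropped}
#'     \item{variants}{the input, keyed, in input order}
#'     \item{config}{the configuration used}
#'   }
#' @export
apply_filter_hierarchy <- function(variants, config = filter_config(), pon = NULL) {
  variants <- add_variant_key(as_tibble(variants))
  nsteps <- length(config$steps)
  n0 <- nrow(variants)
  trail <- matrix(NA, nrow = n0, ncol = nsteps,
                  dimnames = list(NULL, config$steps))
  alive <- rep(TRUE, n0)
  retention <- tibble(step = config$steps, n_in = NA_integer_,
                      n_out = NA_integer_, pct_remaining = NA_real_)
  for (k in seq_len(nsteps)) {
    retention$n_in[k] <- sum(alive)
    if (any(alive)) {
      verdict <- step_verdict(config$steps[k], variants[alive, , drop = FALSE],
                              config, pon)
      trail[alive, k] <- verdict
      alive[alive] <- verdict
    }
    retention$n_out[k] <- sum(alive)
    retention$pct_remaining[k] <- if (n0 > 0) 100 * sum(alive) / n0 else NA_real_
  }
  if (n0 == 0) retention <- retention[0, ]
  structure(list(
    called = variants[alive, , drop = FALSE],
    retention = retention,
    trail = trail,
    variants = variants,
    config = config
  ), class = "blc_filter_result")
}

#' Replay recorded filter verdicts
#'
#' Reconstructs the called set purely from the recorded trail, without
#' re-evaluating any step -- a consistency check that the trail is a faithful
#' record of the filtering run.
#'
#' @param result A [apply_filter_hierarchy()] result.
#' @return Tibble of called variants reconstructed from the trail.
#' @export
replay_filter_trail <- function(result) {
  keep <- apply(result$trail, 1, function(v) all(!is.na(v)) && all(v))
  result$variants[keep, , drop = FALSE]
}

#' @export
print.blc_filter_result <- function(x, ...) {
  cat("<somatic filter hierarchy run>\n")
  cat(sprintf("  %d variants in, %d called somatic (%.3f%%)\n",
              nrow(x$variants), nrow(x$called),
              if (nrow(x$variants)) 100 * nrow(x$called) / nrow(x$variants) else NA))
  print(x$retention)
  invisible(x)
}
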