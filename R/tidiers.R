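# broom-style tidiers for the package's fitted objects

#' @export
tidy.blc_km <- function(x, ...) x$curve

#' @export
glance.blc_km <- function(x, ...) {
  med <- x$curve %>%
    group_by(.data$group) %>%
    summarise(median_survival = {
      i <- which(.data$surv <= 0.5)
      if (length(i) == 0) NA_real_ else .data$time[min(i)]
    }, .groups = "drop")
  tibble(n = x$n, n_event = x$n_event,
         median_survival = list(med))
}

#' @export
tidy.blc_cif <- function(x, ...) x$curve

#' @export
glance.blc_cif <- function(x, horizon = 3, ...) {
  x$curve %>%
    group_by(.data$group) %>%
    summarise(
      estimate = {
        i <- which(.data$time <= horizon)
        if (length(i) == 0) 0 else .data$cif[max(i)]
      },
      se = {
        i <- which(.data$time <= horizon)
        if (length(i) == 0) 0 else .data$se[max(i)]
      },
      .groups = "drop"
    ) %>%
    mutate(event = x$event, horizon = horizon)
}

#' @export
tidy.blc_test <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p.value = x$p, method = x$method)
}

#' @export
glance.blc_test <- tidy.blc_test

#' @export
tidy.blc_mutmat <- function(x, ...) {
  as_tibble(as.data.frame.table(x$counts, stringsAsFactors = FALSE)) %>%
    rename(gene = "Var1", patient_id = "Var2", n_muts = "Freq") %>%
    mutate(mutated = .data$n_muts >= 1)
}

#' @export
glance.blc_mutmat <- function(x, ...) {
  tibble(n_genes = nrow(x$counts), n_patients = ncol(x$counts),
         n_variants = sum(x$counts),
         mean_muts_per_patient = sum(x$counts) / ncol(x$counts))
}

#' @export
tidy.blc_recon <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(unclass(x)), dplyr::everything(),
                      names_to = "measure", values_to = "value")
}

#' @export
tidy.blc_pon <- function(x, ...) {
  as_tibble(unclass(x)) %>%
    mutate(member = .data$n_subjects >= attr(x, "min_support"))
}
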