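#' Derive analysis endpoints from clinical follow-up records
#'
#' Maps the per-patient first-event record onto the three endpoints used in
#' outcome analysis:
#' \describe{
#'   \item{`"efs"`}{event-free survival -- time to the first of relapse or
#'     progression, death from any cause, or a second malignancy; all of
#'     these count as events.}
#'   \item{`"os"`}{overall survival -- time to death from any cause; relapse
#'     and second malignancy censor the record at their time (the record
#'     stores first events only).}
#'   \item{`"relapse"`}{competing-risks input -- relapse/progression is the
#'     event of interest; death in remission and second malignancy (and any
#'     other death) are competing events, censoring is `"censored"`.}
#' }
#'
#' @param clinical Clinical tibble with `patient_id`, `followup_years`, and
#'   `event` in `none`, `relapse_progression`, `death_in_remission`,
#'   `second_malignancy`, `death_other`.
#' @param endpoint One of `"efs"`, `"os"`, `"relapse"`.
#' @return Tibble `(patient_id, time, status)` for `efs`/`os` (status 1 =
#'   event) or `(patient_id, time, event_type)` for `relapse`.
#' @export
derive_endpoint <- function(clinical, endpoint = c("efs", "os", "relapse")) {
  endpoint <- match.arg(endpoint)
  ev <- clinical$event
  known <- c("none", "relapse_progression", "death_in_remission",
             "second_malignancy", "death_other")
  assert_that(all(ev %in% known), "unknown event label in clinical table")
  time <- clinical$followup_years
  assert_that(all(time >= 0), "negative follow-up time")
  switch(endpoint,
    efs = tibble(patient_id = clinical$patient_id, time = time,
                 status = as.integer(ev != "none")),
    os = tibble(patient_id = clinical$patient_id, time = time,
                status = as.integer(ev %in% c("death_in_remission", "death_other"))),
    relapse = tibble(
      patient_id = clinical$patient_id, time = time,
      event_type = dplyr::case_when(
        ev == "none" ~ "censored",
        ev == "relapse_progression" ~ "relapse_progression",
        .default = "competing"
      )
    )
  )
}

# per-group event-time table: n at risk, events, censorings at each
# distinct event time (censorings tied with an event count after it)
km_table <- function(time, status) {
  ut <- sort(unique(time[status == 1]))
  n_risk <- vapply(ut, function(t0) sum(time >= t0), numeric(1))
  n_event <- vapply(ut, function(t0) sum(time == t0 & status == 1), numeric(1))
  tibble(time = ut, n_risk = n_risk, n_event = n_event)
}

#' Kaplan-Meier product-limit estimator with Greenwood standard errors
#'
#' @param data Tibble with the time and status columns.
#' @param time,status Column names (strings) for follow-up time and event
#'   indicator (1 = event, 0 = censored).
#' @param group Optional column name of a grouping factor.
#' @return Object of class `blc_km`: list with `curve`, a tibble
#'   `(group, time, n_risk, n_event, surv, se)` stepping only at event
#'   times, and `n`/`n_event` totals. `tidy()` returns the curve.
#' @export
kaplan_meier <- function(data, time = "time", status = "status", group = NULL) {
  tm <- data[[time]]; st <- data[[status]]
  assert_that(length(tm) >= 1, "need at least one record")
  assert_that(all(tm >= 0), "negative times")
  gr <- if (is.null(group)) rep("all", length(tm)) else as.character(data[[group]])
  curve <- purrr::map_dfr(unique(gr), function(g) {
    sel <- gr == g
    tab <- km_table(tm[sel], st[sel])
    if (nrow(tab) == 0) {
      return(tibble(group = g, time = numeric(), n_risk = numeric(),
                    n_event = numeric(), surv = numeric(), se = numeric()))
    }
    surv <- cumprod(1 - tab$n_event / tab$n_risk)
    gw_terms <- tab$n_event / (tab$n_risk * (tab$n_risk - tab$n_event))
    gw_terms[tab$n_risk == tab$n_event] <- 0  # variance 0 once S hits 0
    se <- surv * sqrt(cumsum(gw_terms))
    tibble(group = g, time = tab$time, n_risk = tab$n_risk,
           n_event = tab$n_event, surv = surv, se = se)
  })
  structure(list(curve = curve, n = length(tm), n_event = sum(st == 1),
                 grouped = !is.null(group)),
            class = "blc_km")
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' @param fit A [kaplan_meier()] fit.
#' @param t Times at which to read the step function.
#' @param group Group label (defaults to the single group).
#' @return Numeric vector of survival probabilities.
#' @export
km_at <- function(fit, t, group = NULL) {
  cv <- fit$curve
  if (!is.null(group)) cv <- cv[cv$group == group, ]
  vapply(t, function(tt) {
    i <- which(cv$time <= tt)
    if (length(i) == 0) 1 else cv$surv[max(i)]
  }, numeric(1))
}

#' @export
print.blc_km <- function(x, ...) {
  cat(sprintf("<Kaplan-Meier fit: %d records, %d events>\n", x$n, x$n_event))
  print(x$curve)
  invisible(x)
}

#' Log-rank test for differences in survival between groups
#'
#' Classic observed-minus-expected chi-square: at each distinct event time
#' the expected event split follows the hypergeometric distribution given
#' the at-risk sets, ties handled by simultaneous processing, censorings at
#' an event time ordered after the event.
#'
#' @param data Tibble with time, status and group columns.
#' @param time,status,group Column names.
#' @return Object of class `blc_test` with fields `statistic`, `df`, `p`,
#'   `method = "logrank"`, and the per-group observed/expected table.
#' @export
logrank_test <- function(data, time = "time", status = "status", group = "group") {
  tm <- data[[time]]; st <- data[[status]]; gr <- as.character(data[[group]])
  groups <- sort(unique(gr))
  k <- length(groups)
  assert_that(k >= 2, "need at least two groups")
  assert_that(sum(st == 1) >= 1, "need at least one event")
  ut <- sort(unique(tm[st == 1]))
  obs <- exp_ <- setNames(numeric(k), groups)
  V <- matrix(0, k, k, dimnames = list(groups, groups))
  for (t in ut) {
    at_risk <- tm >= t
    n <- sum(at_risk)
    d <- sum(tm == t & st == 1)
    if (n == 0 || d == 0) next
    nj <- vapply(groups, function(g) sum(at_risk & gr == g), numeric(1))
    dj <- vapply(groups, function(g) sum(tm == t & st == 1 & gr == g), numeric(1))
    obs <- obs + dj
    exp_ <- exp_ + d * nj / n
    if (n > 1) {
      mult <- d * (n - d) / (n - 1)
      p_j <- nj / n
      V <- V + mult * (diag(p_j, k) - tcrossprod(p_j))
    }
  }
  z <- (obs - exp_)[-k]
  Vk <- V[-k, -k, drop = FALSE]
  stat <- tryCatch(drop(t(z) %*% solve(Vk, z)), error = function(e) NA_real_)
  structure(list(
    statistic = stat, df = k - 1L,
    p = pchisq(stat, df = k - 1L, lower.tail = FALSE),
    method = "logrank",
    table = tibble(group = groups, observed = obs, expected = exp_)
  ), class = "blc_test")
}

#' @export
print.blc_test <- function(x, ...) {
  cat(sprintf("<%s test: chi-square = %.4g, df = %d, p = %.4g>\n",
              x$method, x$statistic, x$df, x$p))
  invisible(x)
}
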