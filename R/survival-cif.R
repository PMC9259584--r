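# per-group competing-risks event table: at each distinct all-cause event
# time, the risk set, all-cause events, cause-of-interest events, the
# all-cause KM just before, and the running CIF
cif_table <- function(time, cause_interest, cause_any) {
  ut <- sort(unique(time[cause_any]))
  n_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  d_all <- vapply(ut, function(t) sum(time == t & cause_any), numeric(1))
  d_int <- vapply(ut, function(t) sum(time == t & cause_interest), numeric(1))
  S_prev <- cumprod(c(1, 1 - d_all / n_risk))[seq_along(ut)]
  tibble(time = ut, n_risk = n_risk, d_all = d_all, d_int = d_int,
         S_prev = S_prev, cif = cumsum(S_prev * d_int / n_risk))
}

# delta-method variance of the CIF at each tabulated time (the standard
# counting-process estimator; cross-checked against bootstrap resampling)
cif_variance <- function(tab) {
  nt <- nrow(tab)
  vapply(seq_len(nt), function(i) {
    Ft <- tab$cif[i]
    idx <- seq_len(i)
    km_term <- tab$d_all[idx] / (tab$n_risk[idx] * (tab$n_risk[idx] - tab$d_all[idx]))
    km_term[tab$n_risk[idx] == tab$d_all[idx]] <- 0
    a <- sum((Ft - tab$cif[idx])^2 * km_term)
    b <- sum(tab$S_prev[idx]^2 *
               ((tab$n_risk[idx] - tab$d_int[idx]) / tab$n_risk[idx]) *
               tab$d_int[idx] / tab$n_risk[idx]^2)
    cc <- sum((Ft - tab$cif[idx]) * tab$S_prev[idx] * tab$d_int[idx] /
                tab$n_risk[idx]^2)
    max(0, a + b - 2 * cc)
  }, numeric(1))
}

#' Cumulative incidence under competing risks
#'
#' Nonparametric cumulative incidence of one event type in the presence of
#' competing events, combining the all-cause Kaplan-Meier survival with the
#' cause-specific hazard at each event time:
#' \deqn{\hat F_1(t) = \sum_{t_i \le t} \hat S(t_i-)\, d_{1i} / n_i}
#' where \eqn{\hat S} is the all-cause product-limit estimate just before
#' \eqn{t_i}, \eqn{d_{1i}} the events of interest at \eqn{t_i}, and
#' \eqn{n_i} the risk set. Standard errors come from the counting-process
#' delta-method variance. Without competing events this reduces exactly to
#' `1 - KM`.
#'
#' @param data Tibble with time, event-type and (optionally) group columns.
#' @param event_of_interest Label of the event type whose incidence is
#'   estimated; every other non-censoring label is a competing event.
#' @param time,event_type,group Column names; `event_type` must use
#'   `censored` for censored records.
#' @param censor_label Label marking censored records (default
#'   `"censored"`).
#' @return Object of class `blc_cif`: list with `curve`, a tibble
#'   `(group, time, n_risk, n_event, n_competing, cif, se)`, and the event
#'   label. `tidy()` returns the curve; [cif_at()] reads the step function.
#' @export
cumulative_incidence <- function(data, event_of_interest,
                                 time = "time", event_type = "event_type",
                                 group = NULL, censor_label = "censored") {
  tm <- data[[time]]; ev <- as.character(data[[event_type]])
  labels <- setdiff(unique(ev), censor_label)
  if (!event_of_interest %in% c(labels, censor_label)) {
    stop("unknown event label: ", event_of_interest, call. = FALSE)
  }
  gr <- if (is.null(group)) rep("all", length(tm)) else as.character(data[[group]])
  curve <- purrr::map_dfr(sort(unique(gr)), function(g) {
    sel <- gr == g
    tab <- cif_table(tm[sel], ev[sel] == event_of_interest,
                     ev[sel] != censor_label)
    if (nrow(tab) == 0) {
      return(tibble(group = g, time = numeric(), n_risk = numeric(),
                    n_event = numeric(), n_competing = numeric(),
                    cif = numeric(), se = numeric()))
    }
    tibble(group = g, time = tab$time, n_risk = tab$n_risk,
           n_event = tab$d_int, n_competing = tab$d_all - tab$d_int,
           cif = tab$cif, se = sqrt(cif_variance(tab)))
  })
  structure(list(curve = curve, event = event_of_interest,
                 grouped = !is.null(group)),
            class = "blc_cif")
}

#' Read a cumulative incidence step function
#'
#' @param fit A [cumulative_incidence()] object.
#' @param t Times at which to evaluate.
#' @param group Group label (defaults to the single group).
#' @param what `"cif"` or `"se"`.
#' @return Numeric vector.
#' @export
cif_at <- function(fit, t, group = NULL, what = c("cif", "se")) {
  what <- match.arg(what)
  cv <- fit$curve
  if (!is.null(group)) cv <- cv[cv$group == group, ]
  vapply(t, function(tt) {
    i <- which(cv$time <= tt)
    if (length(i) == 0) 0 else cv[[what]][max(i)]
  }, numeric(1))
}

#' @export
print.blc_cif <- function(x, ...) {
  cat(sprintf("<cumulative incidence of '%s'>\n", x$event))
  print(x$curve)
  invisible(x)
}

# Gray's modified risk set per group at the pooled cause-1 event times:
# subjects failing from a competing cause remain represented, weighting the
# ordinary risk set by (1 - F1_j(t-)) / S_j(t-)
gray_risk <- function(time, ev_int, ev_any, at_times) {
  tab <- cif_table(time, ev_int, ev_any)
  step_before <- function(values, times, t0, init) {
    vapply(t0, function(tt) {
      i <- which(times < tt)
      if (length(i) == 0) init else values[max(i)]
    }, numeric(1))
  }
  Y <- vapply(at_times, function(t) sum(time >= t), numeric(1))
  if (nrow(tab) == 0) return(Y)
  F1m <- step_before(tab$cif, tab$time, at_times, 0)
  Sm <- step_before(cumprod(1 - tab$d_all / tab$n_risk), tab$time, at_times, 1)
  R <- ifelse(Sm > 0, Y * (1 - F1m) / Sm, 0)
  R
}

# Gray's rho = 0 score vector and a hypergeometric-style variance on the
# modified risk sets; reduces exactly to the log-rank test when no
# competing events are present
gray_core <- function(tm, ev, gr, groups, event_of_interest, censor_label) {
  k <- length(groups)
  ev_int <- ev == event_of_interest
  ev_any <- ev != censor_label
  ut <- sort(unique(tm[ev_int]))
  z <- setNames(numeric(k), groups)
  V <- matrix(0, k, k, dimnames = list(groups, groups))
  Rj_at <- sapply(groups, function(g) {
    sel <- gr == g
    gray_risk(tm[sel], ev_int[sel], ev_any[sel], ut)
  })
  if (length(ut) == 1) Rj_at <- matrix(Rj_at, nrow = 1, dimnames = list(NULL, groups))
  for (i in seq_along(ut)) {
    t <- ut[i]
    d1j <- vapply(groups, function(g) sum(tm == t & ev_int & gr == g), numeric(1))
    d1 <- sum(d1j)
    Rj <- Rj_at[i, ]
    R <- sum(Rj)
    if (R <= 0 || d1 == 0) next
    z <- z + d1j - Rj * d1 / R
    if (R > 1) {
      mult <- d1 * (R - d1) / (R - 1)
      p_j <- Rj / R
      V <- V + mult * (diag(p_j, k) - tcrossprod(p_j))
    }
  }
  list(z = z, V = V)
}

#' Gray's test comparing cumulative incidence between groups
#'
#' K-sample test on subdistribution hazards with weight `rho = 0`. Subjects
#' who fail from a competing cause remain in Gray's modified risk set,
#' down-weighted by the ratio of the group's subdistribution survival to its
#' all-cause survival. The score is the observed-minus-expected count of
#' events of interest over the modified risk sets; the variance uses the
#' hypergeometric form on those risk sets, so on data without competing
#' events both score and variance collapse to the ordinary log-rank test.
#' A permutation p-value (group labels permuted, exhaustively when
#' feasible) is available as a small-sample alternative to the chi-square
#' approximation.
#'
#' @inheritParams cumulative_incidence
#' @param p_method `"asymptotic"` (chi-square, k-1 df) or `"permutation"`.
#' @param n_perm Permutations when sampling (ignored if exhaustive
#'   enumeration over label assignments is feasible).
#' @param exhaustive_limit Maximum number of label assignments to
#'   enumerate.
#' @param seed Optional seed for sampled permutations.
#' @return Object of class `blc_test` (`statistic`, `df`, `p`,
#'   `method = "gray"`).
#' @export
gray_test <- function(data, event_of_interest, time = "time",
                      event_type = "event_type", group = "group",
                      p_method = c("asymptotic", "permutation"),
                      n_perm = 2000, exhaustive_limit = 1e5, seed = NULL,
                      censor_label = "censored") {
  p_method <- match.arg(p_method)
  tm <- data[[time]]; ev <- as.character(data[[event_type]])
  gr <- as.character(data[[group]])
  groups <- sort(unique(gr))
  k <- length(groups)
  assert_that(k >= 2, "need at least two groups")
  assert_that(sum(ev == event_of_interest) >= 1,
              "no events of interest anywhere")

  stat_of <- function(glab) {
    core <- gray_core(tm, ev, glab, groups, event_of_interest, censor_label)
    z <- core$z[-k]
    Vk <- core$V[-k, -k, drop = FALSE]
    out <- tryCatch(drop(t(z) %*% solve(Vk, z)), error = function(e) NA_real_)
    out
  }
  stat <- stat_of(gr)
  if (p_method == "asymptotic") {
    p <- pchisq(stat, df = k - 1L, lower.tail = FALSE)
    n_used <- NA_integer_
  } else {
    n <- length(gr)
    if (k == 2 && choose(n, sum(gr == groups[1])) <= exhaustive_limit) {
      idx <- utils::combn(n, sum(gr == groups[1]))
      stats <- apply(idx, 2, function(ii) {
        glab <- rep(groups[2], n); glab[ii] <- groups[1]
        stat_of(glab)
      })
      p <- mean(stats >= stat - 1e-12, na.rm = TRUE)
      n_used <- ncol(idx)
    } else {
      if (!is.null(seed)) set.seed(seed)
      stats <- replicate(n_perm, stat_of(sample(gr)))
      p <- (1 + sum(stats >= stat - 1e-12, na.rm = TRUE)) / (n_perm + 1)
      n_used <- n_perm
    }
  }
  structure(list(statistic = stat, df = k - 1L, p = p, method = "gray",
                 p_method = p_method, n_perm = n_used),
            class = "blc_test")
}
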