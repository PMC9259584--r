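# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @noRd
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# trapezoidal integral on a (possibly non-uniform) grid
trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# proportion in [0, 1] check, vectorised
is_proportion <- function(x) is.numeric(x) && all(is.na(x) | (x >= 0 & x <= 1))

# deterministic child seed derived from a parent seed and an index;
# kept below .Machine$integer.max so it is a valid set.seed() argument
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 16807) %% 2147483647L)
}

# significance stars at the conventional 0.05 / 0.01 / 0.001 thresholds
p_stars <- function(p) {
  dplyr::case_when(
    p <= 0.001 ~ "***",
    p <= 0.01 ~ "**",
    p <= 0.05 ~ "*",
    .default = "ns"
  )
}
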