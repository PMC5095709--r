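#' Matched-pair t-test
#'
#' Student's paired two-sample t-test comparing the same eyes before and
#' after an intervention (df = n - 1, two-tailed).
#'
#' @param before,after Equal-length numeric vectors, n >= 2.
#' @return One-row tibble: `n`, `estimate` (mean after - before),
#'   `statistic` (t), `df`, `p.value`.
#' @export
paired_t <- function(before, after) {
  if (length(before) != length(after)) {
    stop_difcanal("`before` and `after` must have equal length",
                  "invalid_input")
  }
  if (length(before) < 2) {
    stop_difcanal("need at least 2 pairs", "insufficient_data")
  }
  d <- after - before
  if (var(d) == 0) {
    stop_difcanal("zero variance of the paired differences",
                  "degenerate_variance")
  }
  tt <- t.test(after, before, paired = TRUE)
  tibble(
    n = length(before),
    estimate = unname(tt$estimate),
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p.value = tt$p.value
  )
}

#' Two-sample (unpaired, pooled-variance) t-test
#'
#' Used to check for systematic differences between independent groups,
#' e.g. right versus left eyes.
#'
#' @param group_a,group_b Numeric vectors, each n >= 2.
#' @return One-row tibble: `n_a`, `n_b`, `estimate` (mean a - mean b),
#'   `statistic`, `df`, `p.value`.
#' @export
unpaired_t <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop_difcanal("each group needs at least 2 observations",
                  "insufficient_data")
  }
  if (var(group_a) == 0 && var(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      # identical constant groups: no evidence of difference
      return(tibble(n_a = length(group_a), n_b = length(group_b),
                    estimate = 0, statistic = 0,
                    df = length(group_a) + length(group_b) - 2, p.value = 1))
    }
    stop_difcanal("both groups have zero variance", "degenerate_variance")
  }
  tt <- t.test(group_a, group_b, var.equal = TRUE)
  tibble(
    n_a = length(group_a), n_b = length(group_b),
    estimate = unname(tt$estimate[1] - tt$estimate[2]),
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p.value = tt$p.value
  )
}

#' Power of the matched-pair t-test
#'
#' Exact two-tailed power via the noncentral t distribution with
#' noncentrality \eqn{\sqrt{n}\,\delta/\sigma_d}.
#'
#' @param n Number of pairs (>= 2).
#' @param delta True mean difference.
#' @param sd_diff SD of the paired differences.
#' @param alpha Two-tailed type-I error rate; default 0.05.
#' @return Power in (0, 1).
#' @export
power_paired_t <- function(n, delta, sd_diff, alpha = 0.05) {
  df <- n - 1
  tc <- qt(1 - alpha / 2, df)
  ncp <- sqrt(n) * delta / sd_diff
  1 - pt(tc, df, ncp) + pt(-tc, df, ncp)
}

#' Sample size for a matched-pair comparison
#'
#' Smallest number of pairs whose matched-pair t-test power reaches the
#' target, found by iterating the exact noncentral-t power upward from
#' n = 2.
#'
#' @param delta Expected mean difference (nonzero).
#' @param sd_diff SD of the paired differences (> 0).
#' @param alpha Two-tailed alpha; default 0.05.
#' @param power Target power; default 0.8.
#' @param n_max Search bound; default 1e6.
#' @return Smallest adequate n (integer).
#' @export
sample_size_paired <- function(delta, sd_diff, alpha = 0.05, power = 0.8,
                               n_max = 1e6) {
  if (!is.finite(delta) || delta == 0) {
    stop_difcanal("`delta` must be nonzero", "invalid_input")
  }
  check_number(sd_diff, "sd_diff", 0, strict = TRUE)
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stop_difcanal("`alpha` and `power` must lie in (0, 1)", "invalid_input")
  }
  n <- 2
  while (n <= n_max) {
    if (power_paired_t(n, abs(delta), sd_diff, alpha) >= power) {
      return(as.integer(n))
    }
    n <- n + 1
  }
  stop_difcanal("target power not reachable within `n_max` pairs",
                "no_solution")
}

# zero-variance differences (e.g. identical replicate eyes) yield NA test
# columns instead of aborting the whole summary
safe_paired_t <- function(before, after) {
  tryCatch(
    paired_t(before, after),
    difcanal_error_degenerate_variance = function(e) {
      tibble(n = length(before), estimate = mean(after - before),
             statistic = NA_real_, df = length(before) - 1,
             p.value = NA_real_)
    }
  )
}

#' Summarize a group of differential canalogram results
#'
#' Per-quadrant mean percent change with SD and SEM across eyes, plus the
#' matched-pair t-test on each quadrant's before/after flow rates. Note:
#' p-values are raw per-quadrant values with no multiple-testing correction
#' across the four quadrants -- apply one yourself if your design needs it.
#'
#' @param results List of `canalogram_result` objects (>= 2), one per eye,
#'   analyzed under the same geometry conventions.
#' @param comparison Optional label for the comparison (e.g. `"AIT"`).
#' @return A `canalogram_group_summary` tibble: `quadrant`, `n`,
#'   `mean_pct`, `sd_pct`, `sem_pct`, `statistic`, `df`, `p.value`.
#' @export
summarize_group <- function(results, comparison = NULL) {
  if (!is.list(results) || length(results) < 2 ||
      !all(vapply(results, inherits, logical(1), "canalogram_result"))) {
    stop_difcanal("`results` must be a list of >= 2 canalogram_result objects",
                  "invalid_input")
  }
  geoms <- lapply(results, function(r) {
    g <- attr(r, "geometry")
    g[c("limbus_radius", "outer_radius", "image_up_is_superior")]
  })
  if (!all(vapply(geoms, identical, logical(1), geoms[[1]]))) {
    stop_difcanal("results come from incompatible geometries",
                  "incompatible_results")
  }
  long <- purrr::imap_dfr(results, function(r, i) {
    dplyr::mutate(as_tibble(r), eye = i)
  })
  out <- long |>
    dplyr::group_by(.data$quadrant) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_pct = mean(.data$percent_change),
      sd_pct = sd(.data$percent_change),
      sem_pct = sd(.data$percent_change) / sqrt(dplyr::n()),
      test = list(safe_paired_t(.data$flow_before, .data$flow_after)),
      .groups = "drop"
    ) |>
    tidyr::unnest_wider("test", names_sep = ".") |>
    dplyr::select(
      "quadrant", "n", "mean_pct", "sd_pct", "sem_pct",
      statistic = "test.statistic", df = "test.df", p.value = "test.p.value"
    )
  structure(dplyr::mutate(out, comparison = comparison %||% NA_character_),
            class = c("canalogram_group_summary", class(tibble())))
}
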