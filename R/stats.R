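#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples.  The U statistic counts
#' the pairs `(x_i, y_j)` with `x_i > y_j`, plus half of any ties.  For
#' small tie-free samples (`n1 + n2 <= 12`) the two-sided p value is
#' computed by exact enumeration of all rank arrangements (doubling the
#' smaller tail, capped at 1); otherwise a normal approximation with tie
#' and continuity corrections is used.  Identical degenerate samples give
#' p = 1 with a warning.
#'
#' @param x,y Numeric samples.
#' @param group_names Labels for the two groups.
#' @return One-row tibble: `group1`, `group2`, `n1`, `n2`, `u`, `p_value`,
#'   `method`, `alpha`.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
#' @export
mann_whitney_u <- function(x, y, group_names = c("x", "y")) {
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) abort("Both samples must be non-empty.")
  all_v <- c(x, y)
  r <- rank(all_v)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(all_v) > 0
  if (length(unique(all_v)) == 1) {
    warn("All values are identical across both groups; p set to 1.")
    p <- 1
    method <- "degenerate"
  } else if (n1 + n2 <= 12 && !has_ties) {
    method <- "exact enumeration"
    combos <- combn(n1 + n2, n1)
    rr <- rank(all_v)
    u_all <- apply(combos, 2, function(ix) sum(rr[ix])) - n1 * (n1 + 1) / 2
    p <- min(1, 2 * min(mean(u_all <= u), mean(u_all >= u)))
  } else {
    method <- "normal approximation"
    n <- n1 + n2
    ties <- table(all_v)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - n1 * n2 / 2)
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
      p <- 2 * pnorm(-abs(z))
    }
  }
  tibble(
    group1 = group_names[1], group2 = group_names[2],
    n1 = n1, n2 = n2, u = u, p_value = p, method = method, alpha = 0.05
  )
}

#' Welch two-sample t test (alternative comparison)
#'
#' A labelled alternative to [mann_whitney_u()] for users preferring a
#' parametric comparison; the rank test is the package's primary group
#' comparison.
#'
#' @inheritParams mann_whitney_u
#' @return One-row tibble: `group1`, `group2`, `n1`, `n2`, `statistic`,
#'   `p_value`, `method`, `alpha`.
#' @export
welch_t <- function(x, y, group_names = c("x", "y")) {
  tt <- stats::t.test(x, y, var.equal = FALSE)
  tibble(
    group1 = group_names[1], group2 = group_names[2],
    n1 = length(x), n2 = length(y),
    statistic = unname(tt$statistic), p_value = tt$p.value,
    method = "Welch t test", alpha = 0.05
  )
}

#' Biodistribution summary across a cohort
#'
#' Per-tissue mean and SD (sample convention, divisor n-1) of the static
#' uptake parameters across scans, in stable tissue order (first
#' appearance).
#'
#' @param params Tibble with columns `label` (tissue), `suv_max`,
#'   `suv_mean` — e.g. stacked [static_params()] rows, one per scan and
#'   tissue.
#' @return Tibble `label`, `n_scans`, `suv_max_mean`, `suv_max_sd`,
#'   `suv_mean_mean`, `suv_mean_sd`.
#' @export
biodistribution_summary <- function(params) {
  stopifnot(all(c("label", "suv_max", "suv_mean") %in% names(params)))
  params |>
    mutate(label = factor(.data$label, levels = unique(.data$label))) |>
    group_by(.data$label) |>
    summarise(
      n_scans = n(),
      suv_max_mean = mean(.data$suv_max),
      suv_max_sd = ifelse(n() > 1, sd(.data$suv_max), 0),
      suv_mean_mean = mean(.data$suv_mean),
      suv_mean_sd = ifelse(n() > 1, sd(.data$suv_mean), 0),
      .groups = "drop"
    ) |>
    mutate(label = as.character(.data$label))
}

#' Box-plot style summary of a parameter by group
#'
#' Median, interquartile range and the individual values per group, the
#' layout used for lesion-type comparisons.
#'
#' @param values Numeric vector.
#' @param groups Group label per value.
#' @return Tibble `group`, `n`, `median`, `q25`, `q75`, `values`
#'   (list column).
#' @export
group_summary <- function(values, groups) {
  tibble(value = values, group = groups) |>
    group_by(.data$group) |>
    summarise(
      n = n(),
      median = stats::median(.data$value),
      q25 = unname(stats::quantile(.data$value, 0.25)),
      q75 = unname(stats::quantile(.data$value, 0.75)),
      values = list(.data$value),
      .groups = "drop"
    )
}
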