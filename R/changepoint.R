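#' Gaussian segment cost for change-point detection
#'
#' The negative twice-profile-log-likelihood (up to constants) of a normal
#' segment with both mean and variance free: `n * log(sigma2_mle)` with
#' `sigma2_mle = mean((y - mean(y))^2)`. Degenerate (constant) segments
#' are floored at `var_floor` to keep the log finite.
#'
#' @param y Numeric segment (length >= 2).
#' @param var_floor Lower bound on the MLE variance (default 1e-12).
#' @return Single number.
#' @examples
#' segment_cost(c(0, 2))  # variance 1, cost 0
#' @export
segment_cost <- function(y, var_floor = 1e-12) {
  n <- length(y)
  if (n < 2) abort("segment cost needs at least 2 points")
  s2 <- mean((y - mean(y))^2)
  n * log(max(s2, var_floor))
}

#' At-most-one-change detection of a mean/variance shift
#'
#' Searches every admissible split of `y` into two segments (each at least
#' 2 points, so a variance exists on both sides), scoring each with the
#' Gaussian mean+variance segment cost. The statistic is the likelihood
#' gain `cost(y) - min_tau [cost(left) + cost(right)]`; the change is
#' significant when the statistic exceeds the penalty. Ties are broken to
#' the smallest split index for determinism.
#'
#' @param y Numeric series (length >= 4, finite).
#' @param penalty Numeric threshold or `"MBIC"` (default), the modified
#'   BIC-style value `4 * log(n)` (three extra parameters plus the change
#'   location).
#' @param var_floor Passed to [segment_cost()].
#' @return An object of class `amoc_cp`: list with `tau_index` (last index
#'   of the first segment), `statistic`, `penalty`, `significant`,
#'   segment summaries, and a `floored` flag marking degenerate segments.
#' @examples
#' fit <- amoc_meanvar(c(rnorm(20), rnorm(20, 5)))
#' fit$tau_index
#' @export
amoc_meanvar <- function(y, penalty = "MBIC", var_floor = 1e-12) {
  n <- length(y)
  if (n < 4) abort("AMOC needs at least 4 points")
  if (any(!is.finite(y))) abort("series must be finite")
  pen <- if (identical(penalty, "MBIC")) 4 * log(n) else penalty
  check_number(pen, "penalty")

  # O(n) split scan via cumulative first and second moments
  cs <- cumsum(y)
  cs2 <- cumsum(y^2)
  taus <- 2:(n - 2)
  n1 <- taus
  n2 <- n - taus
  v1 <- pmax(cs2[taus] / n1 - (cs[taus] / n1)^2, var_floor)
  v2 <- pmax((cs2[n] - cs2[taus]) / n2 - ((cs[n] - cs[taus]) / n2)^2,
             var_floor)
  split_cost <- n1 * log(v1) + n2 * log(v2)
  best <- which.min(split_cost)  # smallest tau on ties
  tau <- taus[best]
  statistic <- max(segment_cost(y, var_floor) - split_cost[best], 0)

  left <- y[seq_len(tau)]
  right <- y[(tau + 1):n]
  structure(
    list(tau_index = tau, statistic = statistic, penalty = pen,
         significant = statistic > pen,
         mean_before = mean(left), mean_after = mean(right),
         var_before = mean((left - mean(left))^2),
         var_after = mean((right - mean(right))^2),
         floored = min(v1[best], v2[best]) <= var_floor,
         n = n),
    class = "amoc_cp")
}

#' @export
print.amoc_cp <- function(x, ...) {
  cat("<amoc_cp> tau =", x$tau_index,
      if (!is.null(x$tau_year)) paste0("(", round(x$tau_year), " CE)"),
      " statistic =", round(x$statistic, 3), "vs penalty",
      round(x$penalty, 3), if (x$significant) "[significant]" else
        "[not significant]", "\n")
  invisible(x)
}

#' @rdname amoc_meanvar
#' @param x An `amoc_cp` object.
#' @param ... Unused.
#' @return `tidy()`: one-row tibble of the estimate; `glance()`: one-row
#'   model summary.
#' @export
tidy.amoc_cp <- function(x, ...) {
  tibble(tau_index = x$tau_index,
         tau_year = x$tau_year %||% NA_real_,
         statistic = x$statistic, penalty = x$penalty,
         significant = x$significant,
         mean_before = x$mean_before, mean_after = x$mean_after,
         var_before = x$var_before, var_after = x$var_after)
}

#' @rdname amoc_meanvar
#' @export
glance.amoc_cp <- function(x, ...) {
  tibble(n = x$n, statistic = x$statistic, penalty = x$penalty,
         significant = x$significant, floored = x$floored)
}

#' Change-point detection on a composite burning curve
#'
#' Runs [amoc_meanvar()] on the smoothed composite mean series. The split
#' localises the change between two adjacent targets (the last point of
#' the first segment and the first point of the second); `tau_year` dates
#' it at their midpoint — the boundary between the two regimes — which
#' avoids a systematic half-step-early bias in the reported year.
#'
#' @param curve A `composite_curve` from [bootstrap_composite()].
#' @param penalty Passed to [amoc_meanvar()].
#' @return An `amoc_cp` object with `tau_year` and `group` fields.
#' @export
changepoint_on_composite <- function(curve, penalty = "MBIC") {
  keep <- is.finite(curve$mean)
  if (sum(keep) < 4) abort("composite has fewer than 4 finite targets")
  y <- curve$mean[keep]
  yrs <- curve$target_ce[keep]
  fit <- amoc_meanvar(y, penalty = penalty)
  fit$tau_year <- mean(yrs[fit$tau_index + c(0L, 1L)])
  fit$group <- curve$group[1]
  fit
}
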