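#' Validate survival records
#'
#' Survival records are a data frame with columns `sample`, `time`
#' (non-negative, study units such as months) and `event` (1 = event
#' observed, 0 = right-censored).
#'
#' @param records A data frame with columns `sample`, `time`, `event`.
#' @return The records as a tibble, validated.
#' @export
survival_records <- function(records) {
  records <- tibble::as_tibble(records)
  need <- c("sample", "time", "event")
  if (!all(need %in% names(records))) {
    stop("survival records need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(records) == 0) stop("no survival records", call. = FALSE)
  if (any(!is.finite(records$time)) || any(records$time < 0)) {
    stop("survival times must be finite and non-negative", call. = FALSE)
  }
  if (!all(records$event %in% c(0, 1))) {
    stop("event indicator must be 0 (censored) or 1 (event)", call. = FALSE)
  }
  records$sample <- as.character(records$sample)
  records
}

#' Kaplan-Meier product-limit estimate
#'
#' Computes the product-limit estimator
#' \deqn{\hat S(t) = \prod_{t_i \le t} (1 - d_i / n_i)}
#' over the distinct event times \eqn{t_i}, where \eqn{d_i} is the number
#' of events at \eqn{t_i} and \eqn{n_i} the number at risk just before it.
#' Subjects censored exactly at an event time are counted in the risk set
#' at that time (the standard convention). Censored-only input gives a
#' flat curve at 1.
#'
#' @param records Survival records (see [survival_records()]).
#' @return A tibble of class `km_curve`, one row per distinct event time:
#'   `time`, `n_risk`, `n_event`, `survival`.
#' @examples
#' km_estimate(data.frame(sample = letters[1:4],
#'                        time = c(2, 3, 3, 5), event = c(1, 1, 0, 1)))
#' @export
km_estimate <- function(records) {
  records <- survival_records(records)
  ev_times <- sort(unique(records$time[records$event == 1]))
  if (length(ev_times) == 0) {
    out <- tibble::tibble(time = numeric(0), n_risk = integer(0),
                          n_event = integer(0), survival = numeric(0))
    return(structure(out, class = c("km_curve", class(out)),
                     n = nrow(records), n_events = 0L))
  }
  n_risk <- vapply(ev_times, function(t) sum(records$time >= t), 0L)
  n_event <- vapply(ev_times, function(t) {
    sum(records$time == t & records$event == 1)
  }, 0L)
  surv <- cumprod(1 - n_event / n_risk)
  out <- tibble::tibble(time = ev_times, n_risk = n_risk,
                        n_event = n_event, survival = surv)
  structure(out, class = c("km_curve", class(out)),
            n = nrow(records), n_events = sum(n_event))
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' @param curve A `km_curve` from [km_estimate()].
#' @param times Numeric vector of evaluation times.
#' @return \eqn{\hat S(t)} at each requested time (right-continuous step
#'   function; 1 before the first event).
#' @export
km_survival_at <- function(curve, times) {
  stopifnot(inherits(curve, "km_curve"))
  vapply(times, function(t) {
    i <- sum(curve$time <= t)
    if (i == 0) 1 else curve$survival[i]
  }, numeric(1))
}

#' Plot Kaplan-Meier curves
#'
#' @param object A `km_curve`, or a named list of them (one per group).
#' @param ... Unused.
#' @return A ggplot object (step curves, censoring not marked).
#' @export
autoplot.km_curve <- function(object, ...) {
  plot_km(list(all = object))
}

#' @rdname autoplot.km_curve
#' @param curves Named list of `km_curve` objects.
#' @export
plot_km <- function(curves) {
  stopifnot(is.list(curves), length(curves) >= 1)
  df <- purrr::imap_dfr(curves, function(cv, nm) {
    tibble::tibble(group = nm,
                   time = c(0, cv$time),
                   survival = c(1, cv$survival))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time", y = expression(hat(S)(t)), colour = NULL) +
    ggplot2::theme_minimal()
}

#' Mantel-Haenszel (log-rank) test for two groups
#'
#' At each distinct event time \eqn{t_j} with \eqn{d_j} total events and
#' \eqn{n_j} subjects at risk (\eqn{n_{aj}} of them in group a), the
#' observed events in group a are compared with the hypergeometric
#' expectation \eqn{E_{aj} = d_j n_{aj} / n_j}; the variance uses the
#' tie-corrected form
#' \deqn{V_j = d_j \frac{n_{aj}}{n_j}\left(1-\frac{n_{aj}}{n_j}\right)
#'       \frac{n_j - d_j}{n_j - 1}.}
#' The statistic \eqn{(O_a - E_a)^2 / V} is referred to a chi-squared
#' distribution with 1 degree of freedom (two-sided). Swapping the groups
#' leaves statistic and p-value unchanged.
#'
#' @param group_a,group_b Survival records for the two groups (see
#'   [survival_records()]); both non-empty, at least one event overall.
#' @return A list of class `logrank_result`: `statistic`, `p_value`,
#'   `observed` and `expected` (length-2 vectors, groups a and b), `n`.
#' @export
logrank_test <- function(group_a, group_b) {
  a <- survival_records(group_a)
  b <- survival_records(group_b)
  d_total <- sum(a$event) + sum(b$event)
  if (d_total == 0) stop("log-rank test undefined: zero events", call. = FALSE)
  times <- sort(unique(c(a$time[a$event == 1], b$time[b$event == 1])))
  o_a <- e_a <- v <- 0
  for (t in times) {
    n_a <- sum(a$time >= t); n_b <- sum(b$time >= t)
    n_j <- n_a + n_b
    d_a <- sum(a$time == t & a$event == 1)
    d_j <- d_a + sum(b$time == t & b$event == 1)
    o_a <- o_a + d_a
    e_a <- e_a + d_j * n_a / n_j
    if (n_j > 1) {
      v <- v + d_j * (n_a / n_j) * (1 - n_a / n_j) * (n_j - d_j) / (n_j - 1)
    }
  }
  stat <- if (v > 0) (o_a - e_a)^2 / v else 0
  structure(list(
    statistic = stat,
    p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
    observed = c(a = o_a, b = d_total - o_a),
    expected = c(a = e_a, b = d_total - e_a),
    n = c(a = nrow(a), b = nrow(b))
  ), class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("<logrank_result> chi-squared(1) = %.4g, p = %.4g\n",
              x$statistic, x$p_value))
  cat(sprintf("  group a: n = %d, observed = %d, expected = %.2f\n",
              x$n[["a"]], x$observed[["a"]], x$expected[["a"]]))
  cat(sprintf("  group b: n = %d, observed = %d, expected = %.2f\n",
              x$n[["b"]], x$observed[["b"]], x$expected[["b"]]))
  invisible(x)
}

#' @export
tidy.logrank_result <- function(x, ...) {
  tibble::tibble(group = c("a", "b"),
                 n = unname(x$n),
                 observed = unname(x$observed),
                 expected = unname(x$expected))
}

#' @export
glance.logrank_result <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value, df = 1L)
}
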