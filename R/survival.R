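#' Kaplan-Meier survival curve for one group
#'
#' Product-limit estimate over the distinct observed times.  Times with
#' only censoring reduce the risk set without a step.  Backed by
#' [survival::survfit()].
#'
#' @param data Tibble/data frame with numeric `time` (days, >= 0) and
#'   binary `event` (1 = death observed, 0 = censored).
#' @return Tibble of class `"km_curve"` with `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival`.
#' @examples
#' km_curve(tibble::tibble(time = 1:6, event = c(1, 1, 0, 1, 0, 1)))
#' @export
km_curve <- function(data) {
  data <- as_tibble(data)
  if (nrow(data) < 1) abort("at least one sample is required")
  if (any(data$time < 0)) abort("negative follow-up times are not allowed")
  if (!all(data$event %in% c(0, 1))) abort("event must be 0/1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = data)
  out <- tibble(time = fit$time, n_risk = fit$n.risk,
                n_event = fit$n.event, n_censor = fit$n.censor,
                survival = fit$surv)
  class(out) <- c("km_curve", class(out))
  out
}

#' Median survival time from a Kaplan-Meier curve
#'
#' The smallest observed time at which the survival estimate is at or
#' below 0.5; `NA` (undefined) when the curve never reaches 0.5.
#'
#' @param curve A [km_curve()] result (or a data frame with `time` and
#'   `survival`).
#' @return Time in the curve's units, or `NA_real_` if undefined.
#' @examples
#' median_survival(km_curve(tibble::tibble(time = 1:6,
#'                                         event = c(1, 1, 0, 1, 0, 1))))
#' @export
median_survival <- function(curve) {
  curve <- as_tibble(curve)
  hit <- curve$time[curve$survival <= 0.5 + 1e-12]
  if (length(hit) == 0) {
    return(NA_real_)
  }
  min(hit)
}

#' Multi-group log-rank test
#'
#' Standard log-rank comparison of survival across `g >= 2` groups:
#' observed versus expected events at each distinct event time, chi-square
#' with `g - 1` degrees of freedom, no continuity correction.  Backed by
#' [survival::survdiff()].
#'
#' @param data Tibble with `time`, `event` (0/1) and `group`.
#' @return Object of class `"logrank_test"`: list with `statistic`, `df`,
#'   `p_value`, `n_groups`, and the per-group observed/expected table.
#' @examples
#' d <- simulate_survival(rep(c("A", "B"), each = 30),
#'                        hazard = c(A = 0.001, B = 0.004), seed = 1)
#' logrank_test(d)
#' @export
logrank_test <- function(data) {
  data <- as_tibble(data)
  groups <- unique(data$group)
  if (length(groups) < 2) abort("at least two non-empty groups are required")
  if (sum(data$event) < 1) abort("test refused: no events observed")
  if (any(data$time < 0)) abort("negative follow-up times are not allowed")
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ group,
                               data = data, rho = 0)
  df <- length(groups) - 1
  stat <- unname(sd_fit$chisq)
  structure(list(
    statistic = stat, df = df,
    p_value = pchisq(stat, df = df, lower.tail = FALSE),
    n_groups = length(groups),
    table = tibble(group = sub("^group=", "", names(sd_fit$n)),
                   n = as.integer(sd_fit$n),
                   observed = sd_fit$obs, expected = sd_fit$exp)
  ), class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4g on %d df, p = %.3g\n",
              x$statistic, x$df, x$p_value))
  print(x$table)
  invisible(x)
}

#' @export
#' @exportS3Method
glance.logrank_test <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
         n_groups = x$n_groups)
}

#' Combine two labelings into joint strata
#'
#' Cartesian-product label per sample (e.g. molecular class x immune
#' phenotype, at most 9 occupied cells for 3 x 3); empty combinations are
#' simply absent.
#'
#' @param class_labels,immune_labels Vectors over the same samples; if both
#'   are named, samples are matched by name.
#' @param sep Separator (default `"."`).
#' @return Character vector of combined labels (named if inputs are).
#' @examples
#' combine_groups(c(a = 1, b = 2), c(a = "active", b = "inactive"))
#' @export
combine_groups <- function(class_labels, immune_labels, sep = ".") {
  if (!is.null(names(class_labels)) && !is.null(names(immune_labels))) {
    if (!setequal(names(class_labels), names(immune_labels))) {
      abort("labelings cover different samples")
    }
    immune_labels <- immune_labels[names(class_labels)]
  }
  if (length(class_labels) != length(immune_labels)) {
    abort("labelings cover different samples")
  }
  out <- paste(as.character(class_labels), as.character(immune_labels),
               sep = sep)
  names(out) <- names(class_labels)
  out
}

#' Kaplan-Meier curves by group
#'
#' @param data Tibble with `time`, `event` and `group`.
#' @return A ggplot of step survival curves per group.
#' @export
plot_km_curves <- function(data) {
  data <- as_tibble(data)
  curves <- data %>%
    group_by(.data$group) %>%
    dplyr::group_modify(~ {
      km <- km_curve(.x)
      bind_rows(tibble(time = 0, n_risk = nrow(.x), n_event = 0L,
                       n_censor = 0L, survival = 1),
                as_tibble(km))
    }) %>%
    ungroup()
  ggplot(curves, aes(x = .data$time, y = .data$survival,
                     color = .data$group)) +
    geom_step() +
    coord_cartesian(ylim = c(0, 1)) +
    labs(x = "time (days)", y = "survival probability") +
    theme_minimal()
}
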