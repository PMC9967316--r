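# Xenograft tumor-volume computation and treatment-group comparisons.

#' Caliper tumor volume
#'
#' `V = 1/2 * length * width^2` (mm^3). If a length/width pair violates the
#' caliper convention `length >= width`, the dimensions are swapped (with a
#' warning) before the formula is applied, so the larger dimension is always
#' treated as the length.
#'
#' @param length_mm,width_mm Caliper dimensions in mm (> 0); vectorized.
#' @return Tumor volume(s) in mm^3.
#' @examples
#' tumor_volume(10, 10)  # 500
#' @export
tumor_volume <- function(length_mm, width_mm) {
  if (any(length_mm <= 0) || any(width_mm <= 0)) {
    abort("caliper dimensions must be > 0.")
  }
  swap <- width_mm > length_mm
  if (any(swap)) {
    warn(sprintf("%d measurement(s) had width > length; dimensions swapped.", sum(swap)))
    l <- pmax(length_mm, width_mm)
    w <- pmin(length_mm, width_mm)
  } else {
    l <- length_mm
    w <- width_mm
  }
  0.5 * l * w^2
}

#' Per-animal tumor volume series
#'
#' Converts caliper measurements into per-animal (day, volume) series using
#' [tumor_volume()], ordered by day within animal. Days must be strictly
#' increasing per animal (one measurement per day).
#'
#' @param measurements A tumor-measurement tibble ([read_tumor_csv()] /
#'   [simulate_growth()]).
#' @return A tibble with columns `animal_id`, `group`, `day`, `volume`.
#' @export
tumor_series <- function(measurements) {
  check_columns(measurements, tumor_cols, "measurements")
  dup <- dplyr::count(measurements, .data$animal_id, .data$day)
  if (any(dup$n > 1)) {
    abort("duplicate (animal, day) measurements; one measurement per animal per day expected.")
  }
  out <- dplyr::mutate(measurements,
                       volume = tumor_volume(.data$length_mm, .data$width_mm))
  out <- dplyr::arrange(out, .data$group, .data$animal_id, .data$day)
  out[c("animal_id", "group", "day", "volume")]
}

# volumes of one group at the measurement day nearest `day` (within tolerance)
volumes_at_day <- function(series, group, day, tolerance = 1) {
  g <- dplyr::filter(series, .data$group == !!group)
  if (nrow(g) == 0) abort(sprintf("no animals in group '%s'.", group))
  nearest <- g$day[which.min(abs(g$day - day))]
  if (abs(nearest - day) > tolerance) {
    abort(sprintf("group '%s' has no measurement within %g day(s) of day %g.",
                  group, tolerance, day))
  }
  dplyr::filter(g, .data$day == nearest)$volume
}

#' Percent difference in mean tumor volume between groups
#'
#' `100 * (mean(B) - mean(A)) / mean(A)` at the given day, where A is the
#' reference group; negative values mean the comparison group's tumors are
#' smaller (a volume reduction relative to the reference). Measurements are
#' matched to the nearest recorded day within `tolerance`.
#'
#' @param series A [tumor_series()] tibble.
#' @param reference,comparison Group labels (A and B above).
#' @param day Endpoint day; default the last day measured in both groups.
#' @param tolerance Nearest-day matching window in days.
#' @return Percent difference (a single number).
#' @export
percent_difference <- function(series, reference, comparison, day = NULL,
                               tolerance = 1) {
  day <- day %||% last_common_day(series, c(reference, comparison))
  va <- volumes_at_day(series, reference, day, tolerance)
  vb <- volumes_at_day(series, comparison, day, tolerance)
  100 * (mean(vb) - mean(va)) / mean(va)
}

last_common_day <- function(series, groups = unique(series$group)) {
  days <- lapply(groups, function(g) unique(series$day[series$group == g]))
  common <- Reduce(intersect, days)
  if (length(common) == 0) abort("groups share no common measurement day.")
  max(common)
}

# pooled-variance two-sample t-test summary (Student's independent t-test)
pooled_t <- function(xa, xb) {
  tt <- t.test(xa, xb, var.equal = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' Compare treatment groups at an endpoint day
#'
#' Endpoint analysis of tumor volumes at a single day (default: the last day
#' measured in every group). Two groups are compared with the pooled-variance
#' (Student) independent t-test; more than two groups with a one-way ANOVA
#' followed by pairwise pooled t-tests, Bonferroni-adjusted over the number
#' of pairwise comparisons. Groups with fewer than two animals at the
#' endpoint are excluded with a warning. Percent differences of means are
#' reported per pair (sign convention of [percent_difference()], first group
#' of the pair as reference).
#'
#' @param series A [tumor_series()] tibble.
#' @param day Endpoint day (default last common day across groups).
#' @param tolerance Nearest-day matching window in days.
#' @return A `group_comparison`: the endpoint `day`, an `anova` component
#'   (`NULL` for two groups), and a `pairwise` tibble with `group_a`,
#'   `group_b`, `statistic`, `df`, `p_value`, `p_adjusted`, `pct_difference`.
#'   Supports [tidy()] and [glance()].
#' @examples
#' series <- tumor_series(simulate_growth(growth_truth(seed = 1)))
#' compare_groups(series)
#' @export
compare_groups <- function(series, day = NULL, tolerance = 1) {
  groups <- unique(series$group)
  if (length(groups) < 2) abort("need >= 2 groups to compare.")
  day <- day %||% last_common_day(series, groups)

  vols <- setNames(lapply(groups, function(g) {
    volumes_at_day(series, g, day, tolerance)
  }), groups)
  small <- names(vols)[vapply(vols, length, 1L) < 2]
  if (length(small)) {
    warn(sprintf("group(s) excluded with < 2 animals at day %g: %s.",
                 day, paste(small, collapse = ", ")))
    vols <- vols[setdiff(names(vols), small)]
  }
  if (length(vols) < 2) abort("fewer than 2 usable groups at the endpoint day.")
  groups <- names(vols)

  anova_res <- NULL
  if (length(groups) > 2) {
    df <- tibble(volume = unlist(vols, use.names = FALSE),
                 group = factor(rep(groups, vapply(vols, length, 1L))))
    av <- anova(aov(volume ~ group, data = df))
    anova_res <- list(statistic = av[["F value"]][1],
                      df1 = av[["Df"]][1], df2 = av[["Df"]][2],
                      p_value = av[["Pr(>F)"]][1])
  }

  pairs <- utils::combn(groups, 2, simplify = FALSE)
  pw <- purrr::map_dfr(pairs, function(p) {
    tt <- pooled_t(vols[[p[1]]], vols[[p[2]]])
    tibble(group_a = p[1], group_b = p[2],
           statistic = tt$statistic, df = tt$df, p_value = tt$p_value,
           pct_difference = 100 * (mean(vols[[p[2]]]) - mean(vols[[p[1]]])) /
             mean(vols[[p[1]]]))
  })
  pw$p_adjusted <- p.adjust(pw$p_value, method = "bonferroni")

  structure(list(day = day, groups = groups, anova = anova_res,
                 pairwise = pw[c("group_a", "group_b", "statistic", "df",
                                 "p_value", "p_adjusted", "pct_difference")]),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> endpoint day %g, groups: %s\n",
              x$day, paste(x$groups, collapse = ", ")))
  if (!is.null(x$anova)) {
    cat(sprintf("  one-way ANOVA: F(%d, %d) = %.3g, p = %.3g\n",
                x$anova$df1, x$anova$df2, x$anova$statistic, x$anova$p_value))
  }
  print(x$pairwise)
  invisible(x)
}
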