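#' Per-variable tests of platform group differences
#'
#' Compares every selected variable between exactly two groups:
#' binary (0/1) variables by Pearson chi-square on the 2x2 table with
#' continuity correction, numeric variables by Welch's two-sample
#' t-test. Zero-variance variables are skipped with a reason rather
#' than producing a spurious p-value.
#'
#' @param data Data frame of variables plus a grouping column.
#' @param group Name of the grouping column (must have exactly 2
#'   nonempty levels), e.g. `"platform"`.
#' @param vars Variables to test; defaults to every column except
#'   `group` and `id`.
#' @return A data frame with one row per variable: `variable`, `type`
#'   (`"proportion"` or `"mean"`), per-group summary (proportion or
#'   mean), `statistic`, `p_value`, `direction` (which group is
#'   higher), `note` (skip reason if any).
#' @export
group_tests <- function(data, group = "platform", vars = NULL) {
  hq_assert(is.data.frame(data), "data must be a data frame")
  hq_assert(group %in% names(data), "grouping column '", group, "' not found")
  g <- factor(as.character(data[[group]]))
  hq_assert(nlevels(g) == 2L, "need exactly 2 groups, found ", nlevels(g))
  hq_assert(all(table(g) > 0L), "both groups must be nonempty")
  lv <- levels(g)
  vars <- vars %||% setdiff(names(data), c(group, "id"))
  rows <- lapply(vars, function(v) {
    x <- data[[v]]
    if (!is.numeric(x)) x <- suppressWarnings(as.numeric(as.character(x)))
    x1 <- x[g == lv[1]]; x2 <- x[g == lv[2]]
    is_binary <- all(x %in% c(0, 1) | is.na(x))
    base <- data.frame(variable = v,
                       type = if (is_binary) "proportion" else "mean",
                       group1 = mean(x1, na.rm = TRUE),
                       group2 = mean(x2, na.rm = TRUE),
                       statistic = NA_real_, p_value = NA_real_,
                       direction = "", note = "", stringsAsFactors = FALSE)
    if (is_binary) {
      tab <- rbind(c(sum(x1 == 1, na.rm = TRUE), sum(x1 == 0, na.rm = TRUE)),
                   c(sum(x2 == 1, na.rm = TRUE), sum(x2 == 0, na.rm = TRUE)))
      if (any(colSums(tab) == 0)) {
        base$note <- "skipped: variable constant in both groups"
        return(base)
      }
      tst <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
      base$statistic <- unname(tst$statistic)
      base$p_value <- tst$p.value
    } else {
      if (stats::sd(x, na.rm = TRUE) == 0 || is.na(stats::sd(x, na.rm = TRUE))) {
        base$note <- "skipped: zero variance"
        return(base)
      }
      if (stats::sd(x1, na.rm = TRUE) == 0 && stats::sd(x2, na.rm = TRUE) == 0) {
        # identical constants within groups: no variability to test
        base$statistic <- 0
        base$p_value <- if (base$group1 == base$group2) 1 else 0
      } else {
        tst <- stats::t.test(x1, x2)  # Welch by default
        base$statistic <- unname(tst$statistic)
        base$p_value <- tst$p.value
      }
    }
    base$direction <- if (base$group1 > base$group2) lv[1]
                      else if (base$group2 > base$group1) lv[2] else "equal"
    base
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "group1"] <- lv[1]
  names(out)[names(out) == "group2"] <- lv[2]
  out
}
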