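# Subgroup comparison of best-model criteria with the normality-gated test
# ladder: Shapiro-Wilk gate, then t-test / Mann-Whitney U for two groups and
# ANOVA / Kruskal-Wallis for three or more. Raw alpha = 0.05 across all
# cells; an optional Benjamini-Hochberg adjustment is exposed but off by
# default.

#' Shapiro-Wilk normality gate
#'
#' @param values Numeric sample.
#' @param alpha Gate level: normal iff the Shapiro-Wilk p-value is `>= alpha`.
#' @return `TRUE` when the sample passes; samples with fewer than 3 values
#'   fail the gate by convention (with a warning).
#' @export
normality_gate <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  if (length(values) < 3L) {
    warning("fewer than 3 values: treated as non-normal by convention")
    return(FALSE)
  }
  if (stats::sd(values) == 0) return(FALSE)
  stats::shapiro.test(values)$p.value >= alpha
}

#' Two-group comparison with the normality gate
#'
#' A pooled-variance two-sample t-test when both groups pass the
#' Shapiro-Wilk gate, otherwise a two-sided Mann-Whitney U test (exact when
#' the smaller group has at most 8 observations and there are no ties; normal
#' approximation with continuity correction otherwise).
#'
#' @param values_a,values_b Numeric samples.
#' @param alpha Significance level.
#' @param welch Use the Welch (unequal-variance) t-test instead of pooled.
#' @param method `"gated"` (default) applies the normality gate;
#'   `"t"` or `"mann-whitney"` force the named test.
#' @return List with `test`, `p_value`, `significant`, `n` (group sizes);
#'   `NA` result when a group has fewer than 2 values.
#' @export
compare_two <- function(values_a, values_b, alpha = 0.05, welch = FALSE,
                        method = c("gated", "t", "mann-whitney")) {
  method <- match.arg(method)
  a <- values_a[!is.na(values_a)]; b <- values_b[!is.na(values_b)]
  if (length(a) < 2L || length(b) < 2L) {
    return(list(test = NA_character_, p_value = NA_real_, significant = NA,
                n = c(length(a), length(b))))
  }
  normal <- switch(method,
    gated = suppressWarnings(normality_gate(a) && normality_gate(b)),
    t = TRUE, `mann-whitney` = FALSE)
  if (normal) {
    p <- stats::t.test(a, b, var.equal = !welch)$p.value
    test <- "t-test"
  } else {
    exact <- min(length(a), length(b)) <= 8 && !anyDuplicated(c(a, b))
    p <- suppressWarnings(
      stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
    test <- "Mann-Whitney U"
  }
  list(test = test, p_value = p, significant = p < alpha,
       n = c(length(a), length(b)))
}

#' Multi-group comparison with the normality gate
#'
#' One-way ANOVA when every group passes the Shapiro-Wilk gate, otherwise a
#' Kruskal-Wallis test (tie-corrected).
#'
#' @param groups Named list of numeric samples (>= 2 non-empty groups).
#' @param alpha Significance level.
#' @return List with `test`, `p_value`, `significant`, `n`.
#' @export
compare_k <- function(groups, alpha = 0.05) {
  groups <- lapply(groups, function(v) v[!is.na(v)])
  groups <- groups[lengths(groups) > 0L]
  if (length(groups) < 2L) {
    return(list(test = NA_character_, p_value = NA_real_, significant = NA,
                n = lengths(groups)))
  }
  all_normal <- suppressWarnings(
    all(vapply(groups, function(v) length(v) >= 3 && normality_gate(v),
               logical(1))))
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(names(groups), lengths(groups)))
  if (all_normal) {
    p <- summary(stats::aov(values ~ labels))[[1]][["Pr(>F)"]][1]
    test <- "ANOVA"
  } else {
    p <- stats::kruskal.test(values, labels)$p.value
    test <- "Kruskal-Wallis"
  }
  list(test = test, p_value = p, significant = p < alpha,
       n = lengths(groups))
}

# The clinical grouping variables and their levels.
.subgroup_vars <- list(
  sex = c("M", "F"),
  age_group = c(">=40", "<40"),
  hypoxia = c("yes", "no"),
  hypotension = c("yes", "no"),
  pupils = c("bilateral reactive", "unilateral unreactive",
             "bilateral unreactive"),
  marshall_group = c(">=5", "<5")
)

#' Subgroup analysis of best-model criteria
#'
#' For every signal x grouping x metric triple, compares the per-patient
#' optimum-model criterion values between clinical subgroups using the
#' normality-gated ladder: two-level groupings (sex, age, hypoxia,
#' hypotension, Marshall) use [compare_two()]; the three-level pupillary
#' response uses [compare_k()]. Groupings with a level absent from the cohort
#' are skipped.
#'
#' @param optima data.frame of per-patient optima with columns `patient_id,
#'   signal` and metric columns `aic, bic, ll`.
#' @param meta Patient covariate table (as from [simulate_cohort()]): columns
#'   `patient_id, sex, age_group, hypoxia, hypotension, pupils,
#'   marshall_group`.
#' @param metrics Which metric columns to test.
#' @param alpha Significance level (raw, per cell).
#' @param adjust `"none"` (default) or `"BH"` for a Benjamini-Hochberg
#'   adjustment across all cells.
#' @return data.frame with one row per signal x grouping x metric:
#'   `signal, grouping, subgroup_1, subgroup_2, metric, test, p_value,
#'   significant, n_1, n_2`. For the three-level grouping `subgroup_*` hold
#'   the first two levels and `n_2` the second group's size.
#' @export
subgroup_analysis <- function(optima, meta, metrics = c("aic", "bic", "ll"),
                              alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  df <- merge(optima, meta, by = "patient_id")
  rows <- list()
  for (sig in unique(df$signal)) {
    sub <- df[df$signal == sig, ]
    for (gv in names(.subgroup_vars)) {
      levels_needed <- .subgroup_vars[[gv]]
      present <- levels_needed[levels_needed %in% sub[[gv]]]
      if (length(present) < length(levels_needed)) next  # level absent: skip
      for (metric in metrics) {
        if (length(levels_needed) == 2L) {
          res <- compare_two(sub[[metric]][sub[[gv]] == present[1]],
                             sub[[metric]][sub[[gv]] == present[2]],
                             alpha = alpha)
        } else {
          res <- compare_k(split(sub[[metric]], sub[[gv]]), alpha = alpha)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          signal = sig, grouping = gv,
          subgroup_1 = present[1], subgroup_2 = present[2],
          metric = toupper(metric), test = res$test, p_value = res$p_value,
          significant = res$significant,
          n_1 = res$n[1], n_2 = res$n[2])
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(invisible(NULL))
  if (adjust == "BH") {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
    out$significant <- out$p_adjusted < alpha
  }
  rownames(out) <- NULL
  out
}

#' Significant-only view of a subgroup results table
#'
#' @param results Output of [subgroup_analysis()].
#' @return The rows with `significant == TRUE`, in the column order
#'   `signal, grouping, subgroup_1, subgroup_2, metric, test, p_value`.
#' @export
significant_subgroups <- function(results) {
  keep <- which(results$significant %in% TRUE)
  results[keep, c("signal", "grouping", "subgroup_1", "subgroup_2",
                  "metric", "test", "p_value")]
}
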