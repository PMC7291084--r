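#' Mann-Whitney U tests of every treatment against the negative control
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney U) test of each treatment group
#' against the control group, with Bonferroni adjustment over the number of
#' comparisons: adjusted p = min(1, p * m). Exact p-values are used for small
#' samples without ties, the continuity-corrected normal approximation
#' otherwise (the `stats::wilcox.test` default).
#'
#' @param data Tidy tibble with one row per observation.
#' @param value Name of the measurement column (string).
#' @param group Name of the treatment column (string).
#' @param control Control group label (default `"NEG"`).
#' @return A tibble with one row per non-control group: `treatment`, `n`,
#'   `median`, `p_value`, `p_adjusted`, `stars`.
#' @export
mann_whitney_vs_control <- function(data, value, group, control = "NEG") {
  stopifnot(value %in% names(data), group %in% names(data))
  if (!control %in% data[[group]])
    stop("control group '", control, "' absent", call. = FALSE)
  ctrl <- data[[value]][data[[group]] == control]
  if (length(ctrl) < 2) stop("control needs n >= 2", call. = FALSE)
  groups <- setdiff(unique(data[[group]]), control)
  if (length(groups) == 0) stop("no treatment groups to test", call. = FALSE)
  rows <- lapply(groups, function(g) {
    x <- data[[value]][data[[group]] == g]
    if (length(x) < 2) stop("group '", g, "' needs n >= 2", call. = FALSE)
    p <- suppressWarnings(stats::wilcox.test(x, ctrl)$p.value)
    tibble::tibble(treatment = g, n = length(x), median = stats::median(x),
                   p_value = p)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- pmin(1, out$p_value * length(groups))
  out$stars <- significance_stars(out$p_adjusted)
  out
}

#' One-way ANOVA with Bonferroni-corrected contrasts against the control
#'
#' Fits a one-way ANOVA across all groups, then tests each treatment against
#' the control with a two-sample t contrast, Bonferroni-adjusted.
#'
#' @inheritParams mann_whitney_vs_control
#' @return A list: `anova_p` (global F-test p-value) and `comparisons`
#'   (tibble: `treatment`, `n`, `mean`, `p_value`, `p_adjusted`, `stars`).
#' @export
anova_vs_control <- function(data, value, group, control = "NEG") {
  stopifnot(value %in% names(data), group %in% names(data))
  if (!control %in% data[[group]])
    stop("control group '", control, "' absent", call. = FALSE)
  groups <- setdiff(unique(data[[group]]), control)
  if (length(groups) == 0) stop("need at least 2 groups", call. = FALSE)
  if (all(tapply(data[[value]], data[[group]], stats::var) == 0))
    stop("zero within-group variance everywhere; ANOVA undefined",
         call. = FALSE)
  df <- data.frame(y = data[[value]], g = factor(data[[group]]))
  fit <- stats::aov(y ~ g, data = df)
  anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  ctrl <- df$y[df$g == control]
  rows <- lapply(groups, function(gl) {
    x <- df$y[df$g == gl]
    if (length(x) < 2) stop("group '", gl, "' needs n >= 2", call. = FALSE)
    p <- stats::t.test(x, ctrl)$p.value
    tibble::tibble(treatment = gl, n = length(x), mean = mean(x), p_value = p)
  })
  comp <- dplyr::bind_rows(rows)
  comp$p_adjusted <- pmin(1, comp$p_value * length(groups))
  comp$stars <- significance_stars(comp$p_adjusted)
  list(anova_p = anova_p, comparisons = comp)
}

#' Pearson correlation with validation
#'
#' Standard product-moment correlation; errors on fewer than three points,
#' non-finite values, or zero variance (where r is undefined).
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @return The correlation coefficient r in `[-1, 1]`.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need n >= 3", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite values", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  stats::cor(x, y)
}

#' Relative expression and knockdown efficiency from qPCR Ct values
#'
#' Delta-delta-Ct with control normalization: per condition,
#' `dCt = Ct_target - Ct_reference`; relative expression is
#' `2^-(dCt_treated - dCt_control)` and knockdown percent is
#' `(1 - relative expression) * 100`. Set `reference = FALSE` for the raw
#' variant without a reference gene (`dCt = Ct_target`).
#'
#' @param data Tibble with one row per target x condition, columns `target`,
#'   `condition` (containing `control` rows), `ct_target` and (unless
#'   `reference = FALSE`) `ct_reference`.
#' @param control Label of the control condition (default `"NEG"`).
#' @param reference Use a reference gene (default `TRUE`).
#' @return A tibble per target and non-control condition: `target`,
#'   `condition`, `ddct`, `relative_expression`, `knockdown_pct`.
#' @export
knockdown_fold_change <- function(data, control = "NEG", reference = TRUE) {
  need <- c("target", "condition", "ct_target",
            if (reference) "ct_reference")
  stopifnot(all(need %in% names(data)))
  ct <- data$ct_target
  if (any(!is.finite(ct)) || any(ct <= 0))
    stop("Ct values must be finite and positive", call. = FALSE)
  data$dct <- if (reference) data$ct_target - data$ct_reference else
    data$ct_target
  rows <- lapply(unique(data$target), function(tg) {
    sub <- data[data$target == tg, ]
    ctrl <- sub[sub$condition == control, ]
    if (nrow(ctrl) == 0)
      stop("no control ('", control, "') measurement for target ", tg,
           call. = FALSE)
    trt <- sub[sub$condition != control, ]
    if (nrow(trt) == 0) return(NULL)
    tibble::tibble(target = tg, condition = trt$condition,
                   ddct = trt$dct - mean(ctrl$dct))
  })
  out <- dplyr::bind_rows(rows)
  dplyr::mutate(out, relative_expression = 2^(-.data$ddct),
                knockdown_pct = (1 - .data$relative_expression) * 100)
}

#' Significance stars at the conventional thresholds
#'
#' @param p Numeric vector of (adjusted) p-values.
#' @return Character vector: `***` p < 0.001, `**` p < 0.01, `*` p < 0.05,
#'   `""` otherwise.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Replicate summary: mean and s.e.m. across replicate means
#'
#' Summarises a measurement per treatment as the mean of replicate means with
#' its standard error across replicates, the convention for "mean +/- s.e.m.
#' of n independent experiments".
#'
#' @param data Tidy tibble with `treatment`, `replicate` and a value column.
#' @param value Name of the value column (string).
#' @return Tibble: `treatment`, `n_replicates`, `mean`, `sem`.
#' @export
replicate_summary <- function(data, value) {
  stopifnot(all(c("treatment", "replicate") %in% names(data)),
            value %in% names(data))
  rep_means <- dplyr::summarise(
    dplyr::group_by(data, .data$treatment, .data$replicate),
    m = mean(.data[[value]]), .groups = "drop")
  dplyr::summarise(
    dplyr::group_by(rep_means, .data$treatment),
    n_replicates = dplyr::n(), mean = mean(.data$m),
    sem = stats::sd(.data$m) / sqrt(dplyr::n()), .groups = "drop")
}
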