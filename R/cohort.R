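#' Significance threshold used throughout
#'
#' p values below this value are considered significant.
#' @export
SIGNIFICANCE_LEVEL <- 0.05

#' Load the packaged 18-patient cohort table
#'
#' A transcription of the published patient summary: body weight and BMI
#' at baseline, 2 weeks and 12 weeks of treatment, percent changes from
#' baseline to the last measurement for VAT, SCAT and LTW, therapy
#' (PD-1-mAb / CTLA-4-mAb / BRAF) and response group (PD / MIXED / RTT).
#'
#' @param path Path to a CSV with the same columns; defaults to the
#'   packaged fixture.
#' @return Tibble of class `cohort_table` with tidy column names
#'   (`patient`, `bw_baseline`, `bw_2wk`, `bw_12wk`, `bmi_baseline`,
#'   `bmi_2wk`, `bmi_12wk`, `vat_change`, `scat_change`, `ltw_change`,
#'   `therapy`, `response`).
#' @export
load_cohort_table <- function(path = system.file("extdata", "table1.csv",
                                                 package = "adipoquant")) {
  raw <- utils::read.csv(path, check.names = FALSE)
  expected <- c("Patient", "BW at baseline [kg]", "BW after 2 weeks [kg]",
                "BW after 12 weeks [kg]", "BMI at baseline [kg/m^2]",
                "BMI after 2 weeks [kg/m^2]", "BMI after 3 months [kg/m^2]",
                "VAT change from baseline (%)",
                "SCAT change from baseline (%)",
                "LTW change from baseline (%)", "Therapy", "Response")
  if (!all(expected %in% names(raw)))
    stop("cohort table is missing columns: ",
         paste(setdiff(expected, names(raw)), collapse = "; "))
  tb <- tibble::tibble(
    patient = raw[["Patient"]],
    bw_baseline = raw[["BW at baseline [kg]"]],
    bw_2wk = raw[["BW after 2 weeks [kg]"]],
    bw_12wk = raw[["BW after 12 weeks [kg]"]],
    bmi_baseline = raw[["BMI at baseline [kg/m^2]"]],
    bmi_2wk = raw[["BMI after 2 weeks [kg/m^2]"]],
    bmi_12wk = raw[["BMI after 3 months [kg/m^2]"]],
    vat_change = raw[["VAT change from baseline (%)"]],
    scat_change = raw[["SCAT change from baseline (%)"]],
    ltw_change = raw[["LTW change from baseline (%)"]],
    therapy = raw[["Therapy"]],
    response = raw[["Response"]])
  bad_th <- setdiff(unique(tb$therapy), c("PD-1-mAb", "CTLA-4-mAb", "BRAF"))
  bad_rs <- setdiff(unique(tb$response), c("PD", "MIXED", "RTT"))
  if (length(bad_th)) stop("unknown therapy labels: ",
                           paste(bad_th, collapse = ", "))
  if (length(bad_rs)) stop("unknown response labels: ",
                           paste(bad_rs, collapse = ", "))
  class(tb) <- c("cohort_table", class(tb))
  tb
}

#' Checkpoint-inhibitor therapies
#'
#' The therapy labels counted as checkpoint-inhibitor therapy (CIT):
#' PD-1 and CTLA-4 monoclonal antibodies. BRAF-inhibitor rows remain in
#' the table but are excluded by CIT-filtered analyses.
#' @export
CIT_THERAPIES <- c("PD-1-mAb", "CTLA-4-mAb")

#' Group mean and SD of a cohort variable
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of a
#' variable per group, optionally restricted to a therapy set (e.g.
#' [CIT_THERAPIES]). Groups of size 1 report `NA` for the SD.
#'
#' @param data A cohort tibble (e.g. [load_cohort_table()]).
#' @param variable Column name of the variable to summarize.
#' @param by Grouping column name (default `"response"`).
#' @param therapies Optional character vector: keep only these therapy
#'   labels.
#' @return Tibble with `group`, `n`, `mean`, `sd`.
#' @export
group_summary <- function(data, variable, by = "response",
                          therapies = NULL) {
  stopifnot(is.data.frame(data), variable %in% names(data),
            by %in% names(data))
  if (!is.null(therapies)) {
    data <- dplyr::filter(data, .data$therapy %in% therapies)
    if (nrow(data) == 0L) stop("no subjects left after therapy filter")
  }
  data |>
    dplyr::group_by(group = .data[[by]]) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data[[variable]]),
      sd = ifelse(dplyr::n() > 1L, stats::sd(.data[[variable]]), NA_real_),
      .groups = "drop") |>
    dplyr::arrange(.data$group)
}

.as_group_list <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  groups <- lapply(groups, as.numeric)
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("each group needs n >= 2")
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  groups
}

.stats_result <- function(test, statistic, p_value, summary = NULL,
                          pairwise = NULL, adjust = "none", extra = list()) {
  structure(c(list(test = test, statistic = statistic, p_value = p_value,
                   summary = summary, pairwise = pairwise,
                   adjust = adjust), extra),
            class = "adipo_stats")
}

#' One-way analysis of variance
#'
#' Classical between/within-group F with (k - 1, N - k) degrees of
#' freedom. Zero within-group variance with unequal means yields an
#' infinite F, flagged.
#'
#' @param groups List of numeric samples (each n >= 2), or a data frame
#'   with `value` and `group` columns given via `value`/`by`.
#' @param value,by Column names when `groups` is a data frame.
#' @return An `adipo_stats` with the F statistic, p value and per-group
#'   summaries.
#' @export
one_way_anova <- function(groups, value = NULL, by = NULL) {
  if (is.data.frame(groups)) {
    stopifnot(!is.null(value), !is.null(by))
    groups <- split(groups[[value]], groups[[by]])
  }
  groups <- .as_group_list(groups)
  x <- unlist(groups)
  g <- factor(rep(names(groups), vapply(groups, length, integer(1))))
  k <- length(groups); N <- length(x)
  gm <- mean(x)
  ssb <- sum(vapply(groups, function(v) length(v) * (mean(v) - gm)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  df1 <- k - 1L; df2 <- N - k
  if (ssw == 0 && ssb > 0) {
    warning("zero within-group variance with unequal means; F is infinite")
    Fstat <- Inf; p <- 0
  } else if (ssw == 0) {
    Fstat <- 0; p <- 1
  } else {
    Fstat <- (ssb / df1) / (ssw / df2)
    p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  }
  summ <- tibble::tibble(
    group = names(groups),
    n = vapply(groups, length, integer(1)),
    mean = vapply(groups, mean, numeric(1)),
    sd = vapply(groups, stats::sd, numeric(1)))
  .stats_result("one-way ANOVA", c(F = Fstat), p, summary = summ,
                extra = list(df = c(df1, df2)))
}

#' Pairwise comparisons with Bonferroni correction
#'
#' All pairwise mean differences via pooled-variance two-sample t tests;
#' two-sided p values are multiplied by the number of comparisons (capped
#' at 1), and confidence intervals are Bonferroni-adjusted
#' (level 1 - 0.05/m) so an interval excludes zero exactly when the
#' adjusted p is below 0.05.
#'
#' @inheritParams one_way_anova
#' @return An `adipo_stats`; `$pairwise` holds `group1`, `group2`,
#'   `diff`, `conf_low`, `conf_high`, `p_raw`, `p_adj`.
#' @export
pairwise_bonferroni <- function(groups, value = NULL, by = NULL) {
  if (is.data.frame(groups)) {
    stopifnot(!is.null(value), !is.null(by))
    groups <- split(groups[[value]], groups[[by]])
  }
  groups <- .as_group_list(groups)
  nms <- names(groups)
  pairs <- utils::combn(seq_along(groups), 2)
  m <- ncol(pairs)
  conf_level <- 1 - SIGNIFICANCE_LEVEL / m
  rows <- lapply(seq_len(m), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    x <- groups[[i1]]; y <- groups[[i2]]
    n1 <- length(x); n2 <- length(y)
    sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
      (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    diffm <- mean(x) - mean(y)
    df <- n1 + n2 - 2L
    if (se == 0) {
      tval <- if (diffm == 0) 0 else sign(diffm) * Inf
      p_raw <- if (diffm == 0) 1 else 0
      ci <- c(diffm, diffm)
    } else {
      tval <- diffm / se
      p_raw <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
      tcrit <- stats::qt(1 - (1 - conf_level) / 2, df)
      ci <- diffm + c(-1, 1) * tcrit * se
    }
    tibble::tibble(group1 = nms[i1], group2 = nms[i2], diff = diffm,
                   conf_low = ci[1], conf_high = ci[2],
                   t = tval, p_raw = p_raw,
                   p_adj = min(1, p_raw * m))
  })
  pw <- dplyr::bind_rows(rows)
  .stats_result("pairwise t (Bonferroni)", c(comparisons = m),
                min(pw$p_adj), pairwise = pw, adjust = "bonferroni",
                extra = list(conf_level = conf_level))
}

#' Unpaired (pooled-variance) Student's t test
#'
#' @param x,y Numeric samples, each n >= 2.
#' @return An `adipo_stats` with t, p, the mean difference and its 95% CI.
#' @export
unpaired_t <- function(x, y) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  sp2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
    (length(x) + length(y) - 2)
  if (sp2 == 0) {
    d <- mean(x) - mean(y)
    if (d == 0)
      return(.stats_result("unpaired t", c(t = 0), 1,
                           extra = list(estimate = 0)))
    warning("zero pooled variance with unequal means")
    return(.stats_result("unpaired t", c(t = sign(d) * Inf), 0,
                         extra = list(estimate = d)))
  }
  ht <- stats::t.test(x, y, var.equal = TRUE)
  .stats_result("unpaired t", c(t = unname(ht$statistic)), ht$p.value,
                extra = list(estimate = unname(diff(rev(ht$estimate))),
                             conf_int = as.numeric(ht$conf.int),
                             df = unname(ht$parameter)))
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors (n >= 3, nonzero variance).
#' @return An `adipo_stats` with r and the two-sided p from the t
#'   transform.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for zero-variance input")
  ht <- stats::cor.test(x, y, method = "pearson")
  .stats_result("Pearson correlation", c(r = unname(ht$estimate)),
                ht$p.value, extra = list(df = unname(ht$parameter)))
}

#' Shapiro-Wilk normality test
#'
#' @param x Numeric sample with 3 <= n <= 5000 and nonzero variance.
#' @return An `adipo_stats` with W and p.
#' @export
shapiro_wilk <- function(x) {
  if (length(x) < 3L || length(x) > 5000L)
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::sd(x) == 0)
    stop("Shapiro-Wilk undefined for a constant sample")
  ht <- stats::shapiro.test(x)
  .stats_result("Shapiro-Wilk", c(W = unname(ht$statistic)), ht$p.value)
}

#' @export
print.adipo_stats <- function(x, ...) {
  cat(sprintf("<adipo_stats> %s: %s = %.4g, p = %.4g\n", x$test,
              names(x$statistic)[1], x$statistic[1], x$p_value))
  if (!is.null(x$summary)) print(x$summary)
  if (!is.null(x$pairwise)) print(x$pairwise)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a statistical result
#'
#' @param x An `adipo_stats`.
#' @param ... Unused.
#' @return For pairwise results, one row per comparison; otherwise one row
#'   with the statistic and p value.
#' @export
tidy.adipo_stats <- function(x, ...) {
  if (!is.null(x$pairwise)) {
    out <- x$pairwise
    out$method <- x$test
    return(out)
  }
  tibble::tibble(method = x$test,
                 statistic = unname(x$statistic[1]),
                 term = names(x$statistic)[1],
                 p.value = x$p_value)
}

#' One-row summary of a statistical result
#'
#' @inheritParams tidy.adipo_stats
#' @export
glance.adipo_stats <- function(x, ...) {
  tibble::tibble(method = x$test,
                 statistic = unname(x$statistic[1]),
                 p.value = x$p_value,
                 significant = x$p_value < SIGNIFICANCE_LEVEL)
}
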