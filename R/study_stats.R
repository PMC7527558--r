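#' Derive lung-function indices
#'
#' Fills the two derived physiology indices from the forced-oscillation and
#' forced-expiration raw parameters: tissue hysteresivity `eta = G/H`
#' (damping over elasticity) and the Tiffeneau index `FEV_0.1 / FVC`. Other
#' columns pass through unchanged; rows with missing raw parameters get
#' missing indices.
#'
#' @param table Data frame with columns `g_cmh2o_ml`, `h_cmh2o_ml`,
#'   `fev01_ml`, `fvc_ml` (e.g. a [simulate_study()] table).
#' @return The table with `eta` and `tiffeneau` columns added.
#' @export
derive_indices <- function(table) {
  req <- c("g_cmh2o_ml", "h_cmh2o_ml", "fev01_ml", "fvc_ml")
  if (!all(req %in% names(table))) {
    stop("missing raw lung-function columns: ",
         paste(setdiff(req, names(table)), collapse = ", "), call. = FALSE)
  }
  if (any(table$h_cmh2o_ml <= 0, na.rm = TRUE)) {
    stop("domain error: H must be > 0", call. = FALSE)
  }
  if (any(table$fvc_ml <= 0, na.rm = TRUE)) {
    stop("domain error: FVC must be > 0", call. = FALSE)
  }
  table$eta <- table$g_cmh2o_ml / table$h_cmh2o_ml
  table$tiffeneau <- table$fev01_ml / table$fvc_ml
  table
}

#' Pearson correlation with t-test p-value
#'
#' Product-moment correlation on complete pairs, with the two-sided p-value
#' from the t transform `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom, and optional Sidak adjustment for a family of `m`
#' comparisons.
#'
#' @param x,y Numeric vectors of equal length.
#' @param subset Optional logical vector selecting pairs (e.g. silica
#'   animals only) before complete-case filtering.
#' @param m Number of comparisons in the Sidak family (default 1 = no
#'   adjustment).
#' @return A `correlation_result`: list with `r`, `n`, `p`, `adjusted_p`.
#' @export
pearson_cor <- function(x, y, subset = NULL, m = 1) {
  stopifnot(length(x) == length(y))
  if (!is.null(subset)) {
    x <- x[subset]
    y <- y[subset]
  }
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) stop("insufficient data: need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate input: zero variance", call. = FALSE)
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  structure(list(r = r, n = n, p = p, adjusted_p = sidak_adjust(p, m)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation> r = %.4f (n = %d, p = %.4g, adjusted p = %.4g)\n",
              x$r, x$n, x$p, x$adjusted_p))
  invisible(x)
}

#' Sidak multiple-comparison adjustment
#'
#' `p_adj = 1 - (1 - p)^m`, clipped to `[0, 1]`.
#'
#' @param p Unadjusted p-value(s) in `[0, 1]`.
#' @param m Number of comparisons (>= 1).
#' @return Adjusted p-value(s).
#' @export
sidak_adjust <- function(p, m) {
  stopifnot(all(p >= 0 & p <= 1), m >= 1)
  pmin(pmax(1 - (1 - p)^m, 0), 1)
}

#' Per-cell group summaries
#'
#' Mean, sample SD (n-1 denominator) and n of a biomarker per group x week
#' cell; cells with a single observation report `NA` SD.
#'
#' @param table Study table.
#' @param var Column to summarize.
#' @return Tibble with `group`, `week`, `mean`, `sd`, `n`.
#' @export
group_summaries <- function(table, var) {
  stopifnot(var %in% names(table))
  table |>
    dplyr::filter(!is.na(.data[[var]])) |>
    dplyr::group_by(.data$group, .data$week) |>
    dplyr::summarise(mean = mean(.data[[var]]),
                     sd = if (dplyr::n() >= 2) stats::sd(.data[[var]]) else NA_real_,
                     n = dplyr::n(), .groups = "drop")
}

#' Correlation table between imaging biomarkers and endpoint readouts
#'
#' Computes the Pearson correlation for each requested (imaging column,
#' endpoint column) pair on the chosen group's animals, pooled across
#' endpoint cohorts (endpoint rows only), with Sidak adjustment over `m`
#' comparisons per pair. The published correlation analysis pools
#' silica-instilled animals only.
#'
#' @param table Study table with derived indices (see [derive_indices()]).
#' @param pairs Data frame with columns `x`, `y` and optionally `m`.
#' @param group Group filter (default `"silica"`).
#' @return Tibble: `x`, `y`, `n`, `r`, `p`, `adjusted_p`.
#' @export
correlation_table <- function(table, pairs, group = "silica") {
  stopifnot(all(c("x", "y") %in% names(pairs)))
  end_rows <- !is.na(table$endpoint_week) &
    table$week == table$endpoint_week & table$group == group
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    m <- if ("m" %in% names(pairs)) pairs$m[i] else 1
    res <- pearson_cor(table[[pairs$x[i]]], table[[pairs$y[i]]],
                       subset = end_rows, m = m)
    tibble::tibble(x = pairs$x[i], y = pairs$y[i], n = res$n, r = res$r,
                   p = res$p, adjusted_p = res$adjusted_p)
  })
  dplyr::bind_rows(out)
}

#' Longitudinal mixed-model stage (delegated)
#'
#' Tests the group x time interaction of a longitudinal biomarker with an
#' unbalanced, monotonically missing design. This stage is delegated to an
#' established mixed-model routine (a random-intercept linear mixed model
#' with Satterthwaite denominator degrees of freedom via lme4/lmerTest)
#' rather than re-implemented; its output is validated for sanity, not for
#' agreement with any particular proprietary implementation. Optional
#' per-timepoint group contrasts are Sidak-adjusted across timepoints via
#' emmeans.
#'
#' @param table Study table.
#' @param var Biomarker column to model.
#' @param contrasts If `TRUE`, also compute per-week Sidak-adjusted group
#'   contrasts.
#' @return List with `interaction_p`, the fitted `model`, the `anova` table
#'   and (optionally) `contrasts`.
#' @export
fit_longitudinal_model <- function(table, var = "non_aerated_ml",
                                   contrasts = FALSE) {
  stopifnot(var %in% names(table))
  dat <- data.frame(y = table[[var]], group = factor(table$group),
                    week = factor(table$week),
                    animal_id = factor(table$animal_id))
  dat <- dat[!is.na(dat$y), ]
  if (nlevels(droplevels(dat$group)) < 2 || nlevels(droplevels(dat$week)) < 2) {
    stop("delegation error: need at least two groups and two timepoints",
         call. = FALSE)
  }
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lmerTest::lmer(y ~ group * week + (1 | animal_id), data = dat))),
    error = function(e) {
      stop("delegation error: mixed-model fit failed: ",
           conditionMessage(e), call. = FALSE)
    })
  an <- suppressMessages(stats::anova(fit))
  p_int <- an["group:week", "Pr(>F)"]
  out <- list(interaction_p = as.numeric(p_int), model = fit, anova = an)
  if (contrasts) {
    emm <- emmeans::emmeans(fit, ~ group | week)
    out$contrasts <- summary(emmeans::contrast(emm, method = "revpairwise",
                                               adjust = "none"),
                             adjust = "sidak")
  }
  out
}
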