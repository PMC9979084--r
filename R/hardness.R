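#' Vickers hardness number from indent geometry
#'
#' `HV = 1854.4 * load_gf / mean_diagonal_um^2`, the standard conversion for
#' load in gram-force and the mean indent diagonal in micrometres. The
#' microhardness protocol this supports uses a 25 g load with a 5 s dwell.
#'
#' @param load_gf applied load, gram-force (vectorised).
#' @param mean_diagonal_um mean of the two indent diagonals, micrometres.
#' @return Vickers hardness numbers.
#' @examples
#' vickers_hv(25, 11.6)  # ~344.5 HV
#' @export
vickers_hv <- function(load_gf, mean_diagonal_um) {
  abort_if(!is.numeric(load_gf) || !is.numeric(mean_diagonal_um) ||
             any(!is.finite(load_gf)) || any(!is.finite(mean_diagonal_um)) ||
             any(load_gf <= 0) || any(mean_diagonal_um <= 0),
           "`load_gf` and `mean_diagonal_um` must be positive and finite",
           class = "enamelmat_validation_error")
  hv <- 1854.4 * load_gf / mean_diagonal_um^2
  out_of_window <- hv < 10 | hv > 600
  if (any(out_of_window)) {
    warning(sprintf("%d HV value(s) outside the 10-600 plausibility window for enamel (flagged, not rejected)",
                    sum(out_of_window)))
  }
  hv
}

#' Two-way ANOVA of hardness by age and location
#'
#' Fits `response ~ A * B` with sum-to-zero contrasts and reports Type III
#' sums of squares, F statistics and p-values per effect (matching the
#' convention of common biostatistics GUIs for factorial designs; for
#' balanced designs Types I/II/III coincide with the classical
#' decomposition). Optionally aggregates replicate indents to per-unit means
#' first — hardness protocols typically analyse per-animal site means rather
#' than individual indents, which is what published degrees of freedom
#' usually reflect.
#'
#' @param t data frame (e.g. from [make_hardness_table()] or
#'   [read_hardness_csv()]).
#' @param factor_a,factor_b column names of the two factors.
#' @param response response column name (default `"hv"`).
#' @param aggregate optional column name (e.g. `"animal_id"`): responses are
#'   averaged within `aggregate x factor_a x factor_b` cells before fitting.
#' @param alpha significance level recorded for the Tukey tables.
#' @param tukey logical: also run Tukey HSD for both factors.
#' @return An `anova_result`: list with `effects` (data frame: effect, df,
#'   sum_sq, F, p, infinite_F flag), `residual_df`, `residual_ss`, `type`,
#'   `contrasts`, `tukey` (named list of Tukey tables), `alpha`.
#' @export
two_way_anova <- function(t, factor_a = "age_weeks", factor_b = "level",
                          response = "hv", aggregate = NULL, alpha = 0.05,
                          tukey = TRUE) {
  abort_if(!is.data.frame(t), "`t` must be a data frame",
           class = "enamelmat_validation_error")
  for (nm in c(factor_a, factor_b, response, aggregate)) {
    abort_if(!nm %in% names(t), sprintf("column `%s` not found", nm),
             class = "enamelmat_validation_error")
  }
  if (!is.null(aggregate)) {
    t <- stats::aggregate(t[[response]],
                          by = list(t[[aggregate]], t[[factor_a]],
                                    t[[factor_b]]),
                          FUN = mean)
    names(t) <- c(aggregate, factor_a, factor_b, response)
  }
  df <- data.frame(y = t[[response]],
                   A = factor(t[[factor_a]]),
                   B = factor(t[[factor_b]]))
  abort_if(nlevels(df$A) < 2 || nlevels(df$B) < 2,
           "each factor needs at least 2 observed levels",
           class = "enamelmat_validation_error")
  cells <- table(df$A, df$B)
  abort_if(any(cells == 0),
           "empty cells: interaction effects are not estimable",
           class = "enamelmat_estimability_error")

  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old), add = TRUE)
  fit <- stats::lm(y ~ A * B, data = df)
  ss_total <- sum((df$y - mean(df$y))^2)
  rss <- sum(stats::residuals(fit)^2)
  rdf <- stats::df.residual(fit)

  rows <- c("A", "B", "A:B")
  if (rss > 1e-10 * max(ss_total, 1)) {
    a3 <- car::Anova(fit, type = 3, singular.ok = FALSE)
    eff_ss <- a3[rows, "Sum Sq"]
    eff_df <- a3[rows, "Df"]
  } else {
    # zero residual variance: car refuses the fit, so compute the Type III
    # sums of squares directly by dropping each term's columns
    X <- stats::model.matrix(fit)
    asgn <- attr(X, "assign")
    eff_ss <- eff_df <- numeric(3)
    for (i in 1:3) {
      Xr <- X[, asgn != i, drop = FALSE]
      eff_ss[i] <- sum(stats::resid(stats::lm.fit(Xr, df$y))^2) - rss
      eff_df[i] <- sum(asgn == i)
    }
  }

  inf_flag <- rss <= 1e-10 * max(ss_total, 1) & eff_ss > 1e-10 * max(ss_total, 1)
  Fv <- (eff_ss / eff_df) / (rss / rdf)
  pv <- stats::pf(Fv, eff_df, rdf, lower.tail = FALSE)
  # degenerate cases: zero effect SS -> F = 0, p = 1; zero residual with a
  # real effect -> infinite F, p = 0 (flagged)
  zero_eff <- eff_ss <= 1e-10 * max(ss_total, 1)
  Fv[zero_eff] <- 0; pv[zero_eff] <- 1
  Fv[inf_flag] <- Inf; pv[inf_flag] <- 0

  effects <- data.frame(
    effect = c(factor_a, factor_b, paste0(factor_a, ":", factor_b)),
    df = eff_df, sum_sq = eff_ss, F = Fv, p = pv,
    infinite_F = inf_flag, row.names = NULL)

  tuk <- NULL
  if (tukey) {
    afit <- stats::aov(y ~ A * B, data = df)
    tt <- stats::TukeyHSD(afit, which = c("A", "B"), conf.level = 1 - alpha)
    tuk <- list(tidy_tukey(tt$A, alpha), tidy_tukey(tt$B, alpha))
    names(tuk) <- c(factor_a, factor_b)
  }
  structure(list(effects = effects, residual_df = rdf, residual_ss = rss,
                 total_ss = ss_total, type = "III",
                 contrasts = "sum-to-zero", tukey = tuk, alpha = alpha),
            class = "anova_result")
}

tidy_tukey <- function(m, alpha) {
  out <- data.frame(comparison = rownames(m),
                    estimate = m[, "diff"],
                    lwr = m[, "lwr"], upr = m[, "upr"],
                    p_adj = m[, "p adj"], row.names = NULL)
  out$significant <- out$p_adj < alpha
  out
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("Two-way ANOVA (Type %s SS, %s contrasts)\n", x$type,
              x$contrasts))
  eff <- x$effects
  for (i in seq_len(nrow(eff))) {
    cat(sprintf("  %-28s F(%d, %d) = %.3g, p = %.4g%s\n", eff$effect[i],
                eff$df[i], x$residual_df, eff$F[i], eff$p[i],
                if (eff$infinite_F[i]) " [zero residual variance]" else ""))
  }
  invisible(x)
}

#' Tukey HSD pairwise comparisons for one factor
#'
#' All pairwise differences between the levels of `factor` with studentized-
#' range adjusted p-values, using the residual variance of the fitted model
#' (`response ~ factor`, or the full two-factor model when `other_factor` is
#' given).
#'
#' @param t data frame of measurements.
#' @param factor column name of the factor compared.
#' @param alpha family-wise significance level.
#' @param response response column name.
#' @param other_factor optional second factor retained in the model so the
#'   residual variance matches the two-way analysis.
#' @return Data frame `comparison`, `estimate`, `lwr`, `upr`, `p_adj`,
#'   `significant`.
#' @export
tukey_hsd <- function(t, factor, alpha = 0.05, response = "hv",
                      other_factor = NULL) {
  abort_if(!is.data.frame(t) || !factor %in% names(t) ||
             !response %in% names(t),
           "`t` must contain the factor and response columns",
           class = "enamelmat_validation_error")
  df <- data.frame(y = t[[response]], A = factor(t[[factor]]))
  abort_if(nlevels(df$A) < 2, "factor must have at least 2 levels",
           class = "enamelmat_validation_error")
  if (!is.null(other_factor)) {
    df$B <- factor(t[[other_factor]])
    afit <- stats::aov(y ~ A * B, data = df)
  } else {
    afit <- stats::aov(y ~ A, data = df)
  }
  tt <- stats::TukeyHSD(afit, which = "A", conf.level = 1 - alpha)
  tidy_tukey(tt$A, alpha)
}
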