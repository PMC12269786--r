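# The statistical battery: correlations, two-sample linear-model t-tests,
# Poisson GLMs with overdispersion and Type-II deviance checks, permutation
# linear models, Holm-corrected pairwise contrasts, normality checks.

stat_result <- function(method, statistic, df, p_value, estimate = NA_real_,
                        se = NA_real_, notes = NULL) {
  structure(list(method = method, statistic = statistic, df = df,
                 p_value = p_value, estimate = estimate, se = se,
                 notes = notes),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s: statistic = %.4g, df = %s, p = %.4g",
              x$method, x$statistic,
              paste(format(x$df, digits = 4), collapse = ","), x$p_value))
  if (is.finite(x$estimate)) cat(sprintf(", estimate = %.4g +/- %.4g SE", x$estimate, x$se))
  cat("\n")
  if (!is.null(x$notes)) cat("  ", x$notes, "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.stat_result <- function(x, ...) {
  data.frame(method = x$method, statistic = x$statistic,
             df = paste(format(x$df), collapse = ","), p_value = x$p_value,
             estimate = x$estimate, se = x$se,
             notes = x$notes %||% NA_character_, stringsAsFactors = FALSE)
}

#' Pearson correlation test
#'
#' @param x,y Equal-length finite numeric vectors, n >= 3, non-constant.
#' @return A `stat_result` with r as `estimate`, t statistic, df = n - 2,
#'   two-sided p; R^2 is reported in the notes.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("`x` and `y` must have equal length >= 3", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y) || !all(is.finite(c(x, y)))) {
    stop("inputs must be finite", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance input: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  stat_result("pearson_cor", statistic = unname(ct$statistic),
              df = unname(ct$parameter), p_value = ct$p.value, estimate = r,
              se = sqrt((1 - r^2) / unname(ct$parameter)),
              notes = sprintf("R^2 = %.4f", r^2))
}

#' Two-sample comparison via a one-factor linear model
#'
#' The pooled-variance Student t-test, computed as the group-coefficient
#' test of `lm(y ~ group)` (the two are identical); df = n1 + n2 - 2.
#'
#' @param y Numeric response.
#' @param group Two-level factor (each level n >= 2).
#' @return A `stat_result`; `estimate` is the group-2 coefficient (difference
#'   in means).
#' @export
two_sample_lm <- function(y, group) {
  group <- factor(group)
  if (nlevels(group) != 2L) stop("`group` must have exactly two levels", call. = FALSE)
  if (any(table(group) < 2L)) stop("each group needs n >= 2", call. = FALSE)
  fit <- stats::lm(y ~ group)
  co <- summary(fit)$coefficients
  stat_result("two_sample_lm", statistic = co[2, "t value"],
              df = fit$df.residual, p_value = co[2, "Pr(>|t|)"],
              estimate = co[2, "Estimate"], se = co[2, "Std. Error"],
              notes = sprintf("levels: %s vs %s", levels(group)[1], levels(group)[2]))
}

#' Poisson GLM for count responses
#'
#' Log-link maximum-likelihood fit via `stats::glm`; counts are validated
#' first. Deviance and Pearson residuals are available from the returned fit
#' for the overdispersion check.
#'
#' @param y Non-negative integer counts.
#' @param x Predictor (factor or numeric) or a data frame of predictors.
#' @return The fitted `glm` object.
#' @export
poisson_glm <- function(y, x) {
  if (any(y < 0) || any(y != round(y))) {
    stop("`y` must be non-negative integer counts", call. = FALSE)
  }
  dat <- if (is.data.frame(x)) cbind(y = y, x) else data.frame(y = y, x = x)
  stats::glm(y ~ ., data = dat, family = stats::poisson())
}

#' Overdispersion check for a Poisson GLM
#'
#' Dispersion ratio = Pearson chi-square / residual df; the p-value is the
#' upper tail of the chi-square distribution with the residual df. A ratio
#' well above 1 (small p) indicates variance in excess of the Poisson
#' mean-variance equality.
#'
#' @param fit A Poisson `glm` fit.
#' @return A `stat_result`: `statistic` = Pearson chi-square, `estimate` =
#'   dispersion ratio, `df` = residual df.
#' @export
overdispersion_check <- function(fit) {
  stopifnot(inherits(fit, "glm"))
  df <- fit$df.residual
  if (df <= 0) stop("no residual degrees of freedom", call. = FALSE)
  chi2 <- sum(stats::residuals(fit, type = "pearson")^2)
  stat_result("overdispersion_check", statistic = chi2, df = df,
              p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
              estimate = chi2 / df,
              notes = sprintf("dispersion ratio = %.3f", chi2 / df))
}

#' Type-II deviance (likelihood-ratio) test
#'
#' Likelihood-ratio chi-square between the fitted model and the model with
#' each predictor dropped (respecting marginality), as in a Type-II analysis
#' of deviance. With a single predictor this equals the full-versus-intercept
#' LR test.
#'
#' @param fit A `glm` fit.
#' @param term Predictor to test; defaults to the first (only) term.
#' @return A `stat_result` with the LR chi-square, df = parameters dropped.
#' @export
type2_deviance_test <- function(fit, term = NULL) {
  stopifnot(inherits(fit, "glm"))
  if (anyNA(stats::coef(fit))) {
    stop("model matrix is rank deficient (aliased predictors)", call. = FALSE)
  }
  dr <- stats::drop1(fit, test = "LRT")
  terms <- rownames(dr)[-1]
  term <- term %||% terms[1]
  if (!term %in% terms) stop("unknown term: ", term, call. = FALSE)
  row <- dr[term, ]
  stat_result("type2_deviance_test", statistic = row$LRT, df = row$Df,
              p_value = row$`Pr(>Chi)`, notes = sprintf("term: %s", term))
}

# Overall F statistic of lm(y ~ X) for a matrix of responses, via the thin-Q
# factor of the design: RSS = y'y - ||Q'y||^2.
lm_f_stats <- function(Ymat, Q, p_model) {
  n <- nrow(Ymat)
  tss <- colSums(scale(Ymat, center = TRUE, scale = FALSE)^2)
  rss <- colSums(Ymat^2) - colSums((crossprod(Q, Ymat))^2)
  df1 <- p_model - 1L
  df2 <- n - p_model
  ((tss - rss) / df1) / (rss / df2)
}

#' Monte Carlo permutation test for a linear model
#'
#' The observed overall F of `lm(y ~ x)` is compared with its distribution
#' under `B` random permutations of the response rows against the fixed
#' design. The p-value uses the add-one convention
#' `p = (1 + #permuted >= observed) / (B + 1)`, so p is never zero and never
#' smaller than `1 / (B + 1)`. Fully reproducible for a fixed seed.
#'
#' @param y Numeric response (n >= 5).
#' @param x Predictor (numeric or factor) or data frame of predictors.
#' @param B Number of permutations (>= 1); the survey battery uses 1,000.
#' @param seed Integer seed.
#' @return A `stat_result`: observed F, df = (model df, residual df).
#' @export
lm_permutation_test <- function(y, x, B = 1000, seed = 1) {
  if (B < 1) stop("`B` must be at least 1", call. = FALSE)
  n <- length(y)
  if (n < 5) stop("need n >= 5 observations", call. = FALSE)
  dat <- if (is.data.frame(x)) x else data.frame(x = x)
  X <- stats::model.matrix(~ ., data = dat)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design", call. = FALSE)
  Q <- qr.Q(qr(X))
  p_model <- ncol(X)
  f_obs <- lm_f_stats(matrix(y, ncol = 1), Q, p_model)
  perm <- withr::with_seed(seed, {
    Ymat <- vapply(seq_len(B), function(b) y[sample.int(n)], numeric(n))
    lm_f_stats(Ymat, Q, p_model)
  })
  p <- (1 + sum(perm >= f_obs)) / (B + 1)
  stat_result("lm_permutation_test", statistic = f_obs,
              df = c(p_model - 1L, n - p_model), p_value = p,
              notes = sprintf("B = %d permutations, seed = %d", B, seed))
}

#' Sequential Bonferroni (Holm) adjustment
#'
#' Step-down adjustment: with p-values sorted ascending, the i-th adjusted
#' value is the running maximum of `(m - j + 1) * p_(j)` for `j <= i`,
#' capped at 1, returned in the original order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, never smaller than the raw ones.
#' @export
holm_adjust <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "holm")
}

#' Pairwise group contrasts with Holm correction
#'
#' For every unordered pair of groups, the two-group linear-model contrast
#' (beta, SE, t, F = t^2, raw p) is computed on the pair's subset, then all
#' raw p-values are Holm-adjusted across the pairs. Groups with fewer than
#' two observations are excluded with a warning.
#'
#' @param y Numeric response (e.g. bathymetry at sighting points).
#' @param group Factor of group labels (e.g. behaviours).
#' @param alpha Significance level for the `significant` flag (on adjusted p).
#' @return A `pairwise_matrix`: data frame with one row per pair
#'   (`group1`, `group2`, `estimate`, `se`, `t`, `F`, `df`, `p`, `p_adj`,
#'   `significant`).
#' @export
pairwise_behaviour_test <- function(y, group, alpha = 0.05) {
  group <- factor(group)
  tab <- table(group)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    warning("dropping group(s) with n < 2: ", paste(small, collapse = ", "),
            call. = FALSE)
    keep <- !group %in% small
    y <- y[keep]; group <- droplevels(group[keep])
  }
  lv <- levels(group)
  if (length(lv) < 2L) stop("need at least two groups with n >= 2", call. = FALSE)
  pairs <- utils::combn(lv, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    sel <- group %in% c(g1, g2)
    r <- two_sample_lm(y[sel], droplevels(group[sel]))
    data.frame(group1 = g1, group2 = g2, estimate = r$estimate, se = r$se,
               t = r$statistic, F = r$statistic^2, df = r$df, p = r$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- holm_adjust(out$p)
  out$significant <- out$p_adj < alpha
  class(out) <- c("pairwise_matrix", class(out))
  out
}

#' Shapiro-Wilk normality check
#'
#' @param residuals Numeric vector, 3 <= n <= 5000, non-constant.
#' @return A `stat_result` with W and p.
#' @export
normality_check <- function(residuals) {
  n <- length(residuals)
  if (n < 3 || n > 5000) stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  if (stats::sd(residuals) == 0) stop("constant input: normality test undefined",
                                      call. = FALSE)
  sw <- stats::shapiro.test(residuals)
  stat_result("shapiro_wilk", statistic = unname(sw$statistic), df = n,
              p_value = sw$p.value)
}
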