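# Mixed-model inference on transit speeds and distributional comparisons.
#
# The monitoring questions are answered with Gaussian linear mixed models on
# per-transit distance-weighted average speed (DWAS), with a year random
# intercept: (1) does the active measure shift DWAS; (2) how does the shift
# evolve by active year; (3) which vessel covariates explain DWAS when the
# measures are active. Estimation is REML via lme4::lmer; confidence
# intervals and p-values use the Wald normal approximation.

new_speed_model_fit <- function(fit, terms, n) {
  vc <- as.data.frame(lme4::VarCorr(fit))
  year_sd <- vc$sdcor[vc$grp == "year"][1]
  structure(list(terms = terms, year_sd = year_sd, sigma = stats::sigma(fit),
                 n = n, fit = fit),
            class = "speed_model_fit")
}

wald_terms <- function(fit, level = 0.95) {
  sm <- summary(fit)$coefficients
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
             se = sm[, "Std. Error"],
             ci_lo = sm[, "Estimate"] - z * sm[, "Std. Error"],
             ci_hi = sm[, "Estimate"] + z * sm[, "Std. Error"],
             p = 2 * stats::pnorm(-abs(sm[, "Estimate"] / sm[, "Std. Error"])),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.speed_model_fit <- function(x, ...) {
  cat(sprintf("Mixed model on transit DWAS (n = %d, year-intercept sd = %.2f, residual sd = %.2f)\n",
              x$n, x$year_sd, x$sigma))
  df <- x$terms
  df$estimate <- round(df$estimate, 2)
  df$ci <- sprintf("%.2f – %.2f", df$ci_lo, df$ci_hi)
  df$p <- ifelse(df$p < 0.001, "< .001", sprintf("%.3f", df$p))
  print(df[, c("term", "estimate", "ci", "p")], row.names = FALSE)
  invisible(x)
}

#' @export
coef.speed_model_fit <- function(object, ...) {
  stats::setNames(object$terms$estimate, object$terms$term)
}

#' @export
confint.speed_model_fit <- function(object, ...) {
  m <- as.matrix(object$terms[, c("ci_lo", "ci_hi")])
  rownames(m) <- object$terms$term
  m
}

#' Effect of the active measures on transit speed
#'
#' Gaussian linear mixed model `dwas ~ active + (1 | year)` (REML). The
#' intercept is the mean DWAS when the measures are inactive; the `active`
#' effect is the shift when they are active. Wald 95% CIs and p-values.
#'
#' @param table data.frame with columns `dwas` (knots), `active` (logical),
#'   `year`.
#' @return A `speed_model_fit`.
#' @export
fit_active_effect <- function(table) {
  stopifnot(length(unique(table$year)) >= 2)
  if (length(unique(table$active)) < 2)
    stop("both active and inactive transits are required")
  table$active <- factor(table$active, levels = c(FALSE, TRUE),
                         labels = c("inactive", "active"))
  fit <- lme4::lmer(dwas ~ active + (1 | year), data = table, REML = TRUE)
  terms <- wald_terms(fit)
  terms$term <- sub("^activeactive$", "active", terms$term)
  new_speed_model_fit(fit, terms, nrow(table))
}

#' Per-year effects of the active measures on transit speed
#'
#' `dwas ~ active_year + (1 | year)` with one dummy per active year; the
#' intercept pools all inactive transits.
#'
#' @param table data.frame with `dwas`, `active` (logical), `year`.
#' @return A `speed_model_fit` with one term per active year.
#' @export
fit_year_effects <- function(table) {
  if (!any(table$active) || !any(!table$active))
    stop("both active and inactive transits are required")
  lev <- c("inactive", sort(unique(table$year[table$active])))
  table$ay <- factor(ifelse(table$active, as.character(table$year), "inactive"),
                     levels = as.character(lev))
  fit <- lme4::lmer(dwas ~ ay + (1 | year), data = table, REML = TRUE)
  terms <- wald_terms(fit)
  terms$term <- sub("^ay", "active ", terms$term)
  new_speed_model_fit(fit, terms, nrow(table))
}

#' Covariate effects on transit speed under active measures
#'
#' `dwas ~ ship_class + flag + pilot + direction + (1 | year)` on
#' active-period transits. Reference levels: tanker, Canadian flag, no
#' pilot onboard, upstream. Covariates that are constant or collinear in the
#' design are dropped with a warning.
#'
#' @param table data.frame with `dwas`, `year`, `ship_class`
#'   (cargo/passenger/tanker), `flag` (Canadian/international),
#'   `pilot_onboard` (logical), `direction` (upstream/downstream).
#' @return A `speed_model_fit`.
#' @export
fit_covariate_model <- function(table) {
  table$ship_class <- factor(table$ship_class,
                             levels = c("tanker", "cargo", "passenger"))
  table$flag <- factor(table$flag, levels = c("Canadian", "international"))
  table$pilot <- factor(ifelse(table$pilot_onboard, "yes", "no"),
                        levels = c("no", "yes"))
  table$direction <- factor(table$direction,
                            levels = c("upstream", "downstream"))
  # flag is assessed last: when pilotage and registration are confounded
  # (all internationals piloted), the pilotage effect is the one retained
  vars <- c("ship_class", "pilot", "direction", "flag")
  keep <- character(0)
  X <- stats::model.matrix(~1, table)
  for (v in vars) {
    if (length(unique(table[[v]])) < 2) {
      warning("covariate '", v, "' has a single level; dropped")
      next
    }
    Xtry <- stats::model.matrix(stats::reformulate(c(keep, v)), table)
    if (qr(Xtry)$rank < ncol(Xtry)) {
      warning("covariate '", v, "' is collinear with the others; dropped")
      next
    }
    keep <- c(keep, v)
  }
  if (!length(keep)) stop("no usable covariates")
  fml <- stats::as.formula(paste("dwas ~", paste(keep, collapse = " + "),
                                 "+ (1 | year)"))
  fit <- lme4::lmer(fml, data = table, REML = TRUE)
  terms <- wald_terms(fit)
  terms$term <- sub("^ship_class", "ship class ", terms$term)
  terms$term <- sub("^flag", "flag ", terms$term)
  terms$term <- sub("^pilotyes$", "pilot onboard (yes)", terms$term)
  terms$term <- sub("^directiondownstream$", "direction (downstream)", terms$term)
  new_speed_model_fit(fit, terms, nrow(table))
}

#' Two-sample Kolmogorov-Smirnov comparison of speed distributions
#'
#' `D` is the sup-distance between the empirical CDFs. With
#' `alternative = "greater"` the test asks whether sample `a` is
#' stochastically greater than `b` (its CDF lies below), the orientation
#' used for year-over-year speed comparisons; the statistic is then
#' `sup(F_b - F_a)`.
#'
#' @param a,b Numeric samples (non-empty).
#' @param alternative `"two.sided"` or `"greater"`.
#' @return list of class `ks_result`: `D`, `p`, `alternative`.
#' @export
ks_two_sample <- function(a, b, alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(length(a) > 0, length(b) > 0)
  # R's ks.test alternatives are phrased in terms of the CDF of x relative to
  # y: "less" means the CDF of x lies below that of y, i.e. x stochastically
  # greater. Map accordingly.
  kt <- if (alternative == "two.sided")
    suppressWarnings(stats::ks.test(a, b, alternative = "two.sided"))
  else
    suppressWarnings(stats::ks.test(a, b, alternative = "less"))
  structure(list(D = unname(kt$statistic), p = kt$p.value,
                 alternative = alternative), class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("Kolmogorov-Smirnov (%s): D = %.3f, p = %.4g\n",
              x$alternative, x$D, x$p))
  invisible(x)
}
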