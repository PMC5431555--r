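#' 2x2 contingency table
#'
#' Layout: `a` = exposed & event, `b` = exposed & no event, `c` = unexposed &
#' event, `d` = unexposed & no event.
#'
#' @param a,b,c,d non-negative integer counts (total >= 1).
#' @return Object of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts)))
    stopf("cell counts must be non-negative integers")
  if (sum(counts) < 1) stopf("table total must be >= 1")
  structure(as.list(counts), class = "contingency_2x2")
}

#' Odds ratio of a 2x2 table with Wald confidence interval
#'
#' OR = (a d)/(b c); the 95% CI is Wald on the log-odds scale,
#' exp(ln OR +/- z sqrt(1/a + 1/b + 1/c + 1/d)). Any zero cell triggers the
#' Haldane-Anscombe continuity correction (+0.5 to every cell), recorded in
#' the method tag. The p-value is the two-sided Wald test of ln OR = 0.
#'
#' @param t a [contingency_2x2].
#' @param conf_level confidence level (default 0.95).
#' @return Object of class `or_result`: `or`, `ci_lower`, `ci_upper`, `p`,
#'   `method` ("2x2" or "2x2+0.5").
#' @examples
#' or_2x2 <- odds_ratio_2x2(contingency_2x2(12, 13, 4, 43))
#' round(or_2x2$or, 3)
#' @export
odds_ratio_2x2 <- function(t, conf_level = 0.95) {
  stopifnot(inherits(t, "contingency_2x2"))
  a <- t$a; b <- t$b; cc <- t$c; d <- t$d
  if ((a + b == 0) || (cc + d == 0) || (a + cc == 0) || (b + d == 0))
    stopf("undefined odds ratio: a row or column of the table is entirely zero")
  method <- "2x2"
  if (min(a, b, cc, d) == 0) {
    a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
    method <- "2x2+0.5"
  }
  lor <- log(a * d / (b * cc))
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  # the conventional two-decimal critical value for the standard 95% interval
  z <- if (isTRUE(all.equal(conf_level, 0.95))) 1.96
       else stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(or = exp(lor), ci_lower = exp(lor - z * se),
                 ci_upper = exp(lor + z * se),
                 p = 2 * stats::pnorm(abs(lor) / se, lower.tail = FALSE),
                 method = method),
            class = "or_result")
}

#' @export
print.or_result <- function(x, ...) {
  cat(sprintf("OR %.3f (95%% CI %.3f-%.3f), p = %.3g [%s]\n",
              x$or, x$ci_lower, x$ci_upper, x$p, x$method))
  invisible(x)
}

#' Logistic regression odds ratios
#'
#' Maximum-likelihood logistic fits by iteratively reweighted least squares.
#' Univariate mode fits one model per covariate; multivariate mode fits the
#' joint model. For a single binary covariate the fitted OR equals the
#' closed-form 2x2 odds ratio. Complete or quasi-complete separation is
#' detected (fitted probabilities collapsing to 0/1) and flagged rather than
#' silently reported.
#'
#' @param data data.frame holding outcome and covariates.
#' @param outcome name of the binary outcome column (default "pcr").
#' @param covariates character vector of covariate column names.
#' @param mode "univariate" (one model per covariate) or "multivariate".
#' @param conf_level confidence level for Wald CIs (default 0.95).
#' @return data.frame with one row per covariate term: `term`, `or`,
#'   `ci_lower`, `ci_upper`, `p`, `separation` flag, `mode`.
#' @export
logistic_fit <- function(data, outcome = "pcr", covariates,
                         mode = c("univariate", "multivariate"),
                         conf_level = 0.95) {
  mode <- match.arg(mode)
  y <- data[[outcome]]
  if (is.null(y)) stopf("outcome column '%s' not found", outcome)
  if (length(unique(y[!is.na(y)])) < 2L)
    stopf("degenerate outcome: '%s' is constant", outcome)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  fit_one <- function(covs) {
    fml <- stats::as.formula(paste(outcome, "~", paste(covs, collapse = " + ")))
    warned <- FALSE
    fit <- withCallingHandlers(
      stats::glm(fml, data = data, family = stats::binomial()),
      warning = function(w) {
        warned <<- TRUE
        invokeRestart("muffleWarning")
      })
    mu <- stats::fitted(fit)
    sep <- warned || !fit$converged || any(mu < 1e-8 | mu > 1 - 1e-8)
    cf <- summary(fit)$coefficients
    terms_keep <- setdiff(rownames(cf), "(Intercept)")
    data.frame(term = terms_keep,
               or = exp(cf[terms_keep, "Estimate"]),
               ci_lower = exp(cf[terms_keep, "Estimate"] - z * cf[terms_keep, "Std. Error"]),
               ci_upper = exp(cf[terms_keep, "Estimate"] + z * cf[terms_keep, "Std. Error"]),
               p = cf[terms_keep, "Pr(>|z|)"],
               separation = sep,
               stringsAsFactors = FALSE)
  }
  out <- if (mode == "univariate")
    do.call(rbind, lapply(covariates, fit_one)) else fit_one(covariates)
  out$mode <- mode
  rownames(out) <- NULL
  out
}

#' Chi-square test of trait proportions across groups
#'
#' Pearson chi-square without continuity correction on the r x c
#' cross-tabulation of group against trait.
#'
#' @param group grouping vector (e.g. cluster labels; NAs dropped).
#' @param trait categorical/binary trait vector.
#' @return List: `statistic`, `df`, `p`, `observed`, `expected`.
#' @export
proportions_test <- function(group, trait) {
  keep <- !is.na(group) & !is.na(trait)
  group <- group[keep]; trait <- trait[keep]
  if (length(unique(group)) < 2L) stopf("need at least 2 non-empty groups")
  tab <- table(group, trait)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stopf("empty group or trait level")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, observed = ct$observed, expected = ct$expected)
}

#' Kaplan-Meier estimate and log-rank test by group
#'
#' Product-limit survival per group (right-censored) and the log-rank test
#' across groups. When no events occurred anywhere the log-rank statistic is
#' undefined; the result carries `no_events = TRUE` instead of a test.
#'
#' @param data data.frame with columns `dfs_months` and `event` (0/1).
#' @param group grouping vector (NAs dropped); `NULL` fits a single curve.
#' @return Object of class `survival_fit`: `fit` (a [survival::survfit]
#'   object), `logrank_chisq`, `logrank_df`, `logrank_p`, `no_events`,
#'   `n_events`.
#' @export
km_logrank <- function(data, group = NULL) {
  if (is.null(data$dfs_months) || is.null(data$event))
    stopf("`data` must contain dfs_months and event columns")
  keep <- if (is.null(group)) rep(TRUE, nrow(data)) else !is.na(group)
  d <- data.frame(time = data$dfs_months[keep], status = data$event[keep])
  if (any(d$time < 0)) stopf("negative follow-up time")
  if (!all(d$status %in% 0:1)) stopf("event must be 0/1")
  if (nrow(d) == 0L) stopf("group with zero subjects")
  n_events <- sum(d$status)
  if (is.null(group)) {
    fit <- survival::survfit(survival::Surv(time, status) ~ 1, data = d)
    return(structure(list(fit = fit, logrank_chisq = NA_real_,
                          logrank_df = NA_integer_, logrank_p = NA_real_,
                          no_events = n_events == 0, n_events = n_events),
                     class = "survival_fit"))
  }
  d$group <- factor(group[keep])
  if (any(table(d$group) == 0)) stopf("group with zero subjects")
  fit <- survival::survfit(survival::Surv(time, status) ~ group, data = d)
  if (n_events == 0) {
    return(structure(list(fit = fit, logrank_chisq = NA_real_,
                          logrank_df = NA_integer_, logrank_p = NA_real_,
                          no_events = TRUE, n_events = 0L),
                     class = "survival_fit"))
  }
  lr <- survival::survdiff(survival::Surv(time, status) ~ group, data = d)
  df <- length(lr$n) - 1L
  structure(list(fit = fit, logrank_chisq = unname(lr$chisq),
                 logrank_df = df,
                 logrank_p = stats::pchisq(lr$chisq, df, lower.tail = FALSE),
                 no_events = FALSE, n_events = n_events),
            class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  if (x$no_events) {
    cat("Kaplan-Meier fit: no events observed; survival = 1 throughout, log-rank undefined\n")
  } else if (is.na(x$logrank_chisq)) {
    cat(sprintf("Kaplan-Meier fit: %d events, single group\n", x$n_events))
  } else {
    cat(sprintf("Kaplan-Meier fit: %d events; log-rank chi-square %.3f (df %d), p = %.4g\n",
                x$n_events, x$logrank_chisq, x$logrank_df, x$logrank_p))
  }
  invisible(x)
}

#' Cox proportional hazards regression
#'
#' Partial-likelihood fit with Efron tie handling. A covariate stratum with
#' no events produces a monotone partial likelihood; such terms are flagged
#' (`monotone = TRUE`) rather than reported as ordinary estimates.
#'
#' @param data data.frame with `dfs_months`, `event` and covariate columns.
#' @param covariates character vector of covariate names.
#' @param mode "univariate" (one model per covariate) or "multivariate".
#' @param conf_level confidence level (default 0.95).
#' @return data.frame per term: `term`, `hr`, `ci_lower`, `ci_upper`, `p`,
#'   `monotone`, `mode`.
#' @export
cox_fit <- function(data, covariates, mode = c("univariate", "multivariate"),
                    conf_level = 0.95) {
  mode <- match.arg(mode)
  if (sum(data$event) < 1) stopf("no events: Cox model undefined")
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  fit_one <- function(covs) {
    fml <- stats::as.formula(
      paste("survival::Surv(dfs_months, event) ~", paste(covs, collapse = " + ")))
    warned <- FALSE
    fit <- withCallingHandlers(
      survival::coxph(fml, data = data, ties = "efron"),
      warning = function(w) { warned <<- TRUE; invokeRestart("muffleWarning") })
    cf <- summary(fit)$coefficients
    se <- cf[, "se(coef)"]
    mono <- warned | !is.finite(se) | se > 50 | abs(cf[, "coef"]) > 50
    data.frame(term = rownames(cf),
               hr = exp(cf[, "coef"]),
               ci_lower = exp(cf[, "coef"] - z * se),
               ci_upper = exp(cf[, "coef"] + z * se),
               p = cf[, "Pr(>|z|)"],
               monotone = unname(mono),
               stringsAsFactors = FALSE)
  }
  out <- if (mode == "univariate")
    do.call(rbind, lapply(covariates, fit_one)) else fit_one(covariates)
  out$mode <- mode
  rownames(out) <- NULL
  out
}
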