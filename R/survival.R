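#' Split samples at the median expression level
#'
#' Values strictly above the median are `high`; values at or below the
#' median are `low` (ties go to `low`, recorded in the result's
#' attributes so the rule is explicit in downstream metadata).
#'
#' @param values named numeric vector of per-sample expression.
#' @return factor with levels `low`, `high` (reference `low`); attribute
#'   `median` holds the cutpoint and `tie_rule` the convention.
#' @export
#' @examples
#' median_split(c(a = 1, b = 2, c = 2, d = 3))
median_split <- function(values) {
  if (length(values) < 2) stopf("median_split: need >= 2 samples")
  if (length(unique(values)) == 1) {
    stopf("median_split: all values identical, split undefined")
  }
  med <- stats::median(values)
  out <- factor(ifelse(values > med, "high", "low"),
                levels = c("low", "high"))
  names(out) <- names(values)
  attr(out, "median") <- med
  attr(out, "tie_rule") <- "values equal to the median are assigned to low"
  out
}

#' Kaplan-Meier product-limit estimator
#'
#' Thin wrapper over [survival::survfit()] returning the step function as
#' a data.frame. Survival starts at 1 and is non-increasing.
#'
#' @param time follow-up times (> 0).
#' @param event event indicator (1 = death, 0 = censored).
#' @return data.frame with columns `time`, `n_risk`, `n_event`,
#'   `survival`.
#' @export
kaplan_meier <- function(time, event) {
  if (length(time) < 1) stopf("kaplan_meier: no records")
  if (any(time <= 0)) stopf("kaplan_meier: times must be > 0")
  if (!all(event %in% c(0, 1))) stopf("kaplan_meier: event must be 0/1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             survival = fit$surv)
}

#' Two-group log-rank test
#'
#' Chi-square statistic from observed-minus-expected event counts summed
#' over distinct event times with hypergeometric variance (via
#' [survival::survdiff()]), referred to 1 degree of freedom.
#'
#' @param time,event survival outcome.
#' @param group two-level factor or character vector.
#' @return `cs_test` with the chi-square statistic and p-value.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(droplevels(as.factor(group)))
  if (nlevels(group) != 2) stopf("logrank_test: exactly 2 groups required")
  if (any(table(group) == 0)) stopf("logrank_test: empty group")
  if (sum(event) < 1) stopf("logrank_test: no events")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  chi2 <- unname(sd$chisq)
  new_test_result(chi2, stats::pchisq(chi2, df = 1, lower.tail = FALSE),
                  "logrank")
}

#' Cox proportional-hazards fit
#'
#' Maximizes the log partial likelihood with Efron tie handling (the
#' default of [survival::coxph()], which performs the Newton-Raphson
#' optimization). Categorical covariates are expanded to reference-coded
#' indicators; the reference is the first factor level. Wald 95% CIs are
#' `exp(beta +/- 1.96 se)`. Monotone likelihood (complete separation) is
#' detected and reported in the result.
#'
#' @param data data.frame with columns `time`, `event` and the covariates.
#' @param covariates character vector of covariate column names.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return object of class `cox_result`: a coefficient `table`
#'   (`covariate`, `level`, `beta`, `hr`, `ci_low`, `ci_high`, `p`), the
#'   model log partial likelihood `loglik`, counts `n`/`n_event`, and
#'   `warnings`.
#' @export
cox_fit <- function(data, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(all(c("time", "event") %in% names(data)))
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov) > 0) {
    stopf("cox_fit: covariate '%s' not in data", missing_cov[1])
  }
  if (sum(data$event) < 1) stopf("cox_fit: no events")
  keep <- stats::complete.cases(data[, c("time", "event", covariates)])
  n_dropped <- sum(!keep)
  data <- data[keep, , drop = FALSE]
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(sprintf("`%s`", covariates),
                                       collapse = " + ")))
  warns <- character()
  fit <- withCallingHandlers(
    survival::coxph(fml, data = data, ties = ties),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  if (!is.null(fit$info) && any(grepl("converge", warns))) {
    stopf("cox_fit: Newton-Raphson failed to converge: %s",
          paste(warns, collapse = "; "))
  }
  separated <- any(grepl("infinite|Loglik converged", warns)) ||
    any(abs(stats::coef(fit)) > 15, na.rm = TRUE)
  sm <- summary(fit)
  beta <- stats::coef(fit)
  se <- sm$coefficients[, "se(coef)"]
  terms_raw <- names(beta)
  # split "covariateLEVEL" into covariate and level for factor terms
  cov_of <- character(length(terms_raw))
  lev_of <- character(length(terms_raw))
  for (i in seq_along(terms_raw)) {
    hit <- covariates[startsWith(terms_raw[i],
                                 gsub("`", "", covariates))][1]
    cov_of[i] <- if (is.na(hit)) terms_raw[i] else hit
    lev_of[i] <- sub(paste0("^", cov_of[i]), "", terms_raw[i])
    if (lev_of[i] == "") lev_of[i] <- "(linear)"
  }
  tab <- data.frame(
    covariate = cov_of, level = lev_of, beta = unname(beta),
    hr = unname(exp(beta)),
    ci_low = unname(exp(beta - 1.96 * se)),
    ci_high = unname(exp(beta + 1.96 * se)),
    p = unname(sm$coefficients[, "Pr(>|z|)"]),
    stringsAsFactors = FALSE
  )
  structure(list(table = tab, loglik = fit$loglik[2], n = fit$n,
                 n_event = fit$nevent, n_dropped = n_dropped,
                 separated = separated, warnings = warns, ties = ties,
                 fit = fit),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox PH fit (%s ties): n = %d, events = %d, loglik = %.3f\n",
              x$ties, x$n, x$n_event, x$loglik))
  print(x$table, digits = 3)
  if (x$separated) cat("warning: monotone likelihood / separation suspected\n")
  invisible(x)
}

#' Univariate-to-multivariate Cox screening
#'
#' Each candidate covariate is first fit alone; covariates with any
#' coefficient p-value below `univ_p_enter` enter a joint multivariate
#' model. Records with missing values are dropped listwise per model and
#' the counts reported.
#'
#' @param data data.frame with `time`, `event` and candidate covariates.
#' @param candidates character vector of covariate names.
#' @param univ_p_enter univariate entry threshold (0.05 by default; the
#'   looser 0.1 convention is available by argument).
#' @param ties tie-handling method passed to [cox_fit()].
#' @return list with `univariate` (stacked coefficient table with a
#'   `covariate` column), `entered` (covariates passing the screen) and
#'   `multivariate` (a `cox_result`, or `NULL` when nothing passes).
#' @export
cox_screen <- function(data, candidates, univ_p_enter = 0.05,
                       ties = "efron") {
  uni <- list()
  entered <- character()
  for (cv in candidates) {
    fit <- cox_fit(data, cv, ties = ties)
    uni[[cv]] <- fit$table
    if (any(fit$table$p < univ_p_enter, na.rm = TRUE)) {
      entered <- c(entered, cv)
    }
  }
  uni_tab <- do.call(rbind, uni)
  rownames(uni_tab) <- NULL
  multi <- if (length(entered) > 0) {
    cox_fit(data, entered, ties = ties)
  } else {
    NULL
  }
  list(univariate = uni_tab, entered = entered, multivariate = multi,
       univ_p_enter = univ_p_enter)
}

#' Optimal survival cutpoint by maximally selected log-rank statistic
#'
#' Scans every observed value of `values` inside the quantile band as a
#' candidate cutpoint, computes the two-group log-rank statistic for each
#' admissible split, and returns the maximizing cutpoint. The associated
#' p-value is NOT corrected for the multiplicity of the scan and is
#' reported with that caveat.
#'
#' @param values per-sample marker values (same order as `time`/`event`).
#' @param time,event survival outcome.
#' @param quantile_band two quantiles restricting candidate cutpoints.
#' @return list with `cutpoint`, `statistic`, `p_uncorrected`, `note`, and
#'   the full `scan` table.
#' @export
optimal_cutoff <- function(values, time, event,
                           quantile_band = c(0.1, 0.9)) {
  if (length(values) < 10 || sum(event) < 1) {
    stopf("optimal_cutoff: need >= 10 records with at least one event")
  }
  lo <- stats::quantile(values, quantile_band[1])
  hi <- stats::quantile(values, quantile_band[2])
  cand <- sort(unique(values[values >= lo & values <= hi]))
  # a cutpoint must leave both sides non-empty
  cand <- cand[vapply(cand, function(ct) {
    sum(values > ct) > 0 && sum(values <= ct) > 0
  }, TRUE)]
  if (length(cand) == 0) stopf("optimal_cutoff: no admissible cutpoint")
  stat <- vapply(cand, function(ct) {
    grp <- values > ct
    tryCatch(logrank_test(time, event, grp)$statistic,
             error = function(e) NA_real_)
  }, 1.0)
  if (all(is.na(stat))) stopf("optimal_cutoff: no admissible cutpoint")
  best <- which.max(stat)
  list(cutpoint = cand[best], statistic = stat[best],
       p_uncorrected = stats::pchisq(stat[best], 1, lower.tail = FALSE),
       note = "p-value not corrected for cutpoint selection multiplicity",
       scan = data.frame(cutpoint = cand, statistic = stat))
}

#' Write Cox screening tables to TSV
#'
#' @param screen result of [cox_screen()].
#' @param univariate_path,multivariate_path output paths.
#' @param seed,config_hash optional provenance fields.
#' @export
write_cox_tsv <- function(screen, univariate_path, multivariate_path,
                          seed = NULL, config_hash = NULL) {
  write_tsv(screen$univariate, univariate_path, seed = seed,
            config_hash = config_hash)
  multi <- if (is.null(screen$multivariate)) {
    data.frame(covariate = character(), level = character(),
               beta = numeric(), hr = numeric(), ci_low = numeric(),
               ci_high = numeric(), p = numeric())
  } else {
    screen$multivariate$table
  }
  write_tsv(multi, multivariate_path, seed = seed, config_hash = config_hash)
}
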