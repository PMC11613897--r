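#' Kaplan-Meier fit on age scale
#'
#' Product-limit estimator of the probability of remaining free of a first
#' breast-cancer code by age, with Greenwood log-transformed confidence
#' bands. Time zero is birth; censoring is at the current age. Cumulative
#' incidence ("% diagnosed by age") is `1 - survival`. Optional left
#' truncation enters each woman at her EHR start age instead of birth.
#'
#' @param records `data.frame` with `time`, `event` (0/1) and, when
#'   `left_truncate = TRUE`, `entry_age`.
#' @param left_truncate Enter at `entry_age` (counting-process form)
#'   instead of at birth. Default `FALSE`.
#' @return Object of class `km_curve`: list with `times`, `n_risk`,
#'   `n_event`, `survival`, `lower`, `upper` and the underlying
#'   [survival::survfit] fit.
#' @export
km_fit <- function(records, left_truncate = FALSE) {
  stopifnot(nrow(records) >= 1L, all(records$time > 0))
  if (all(records$event == 0)) {
    warning("no events: degenerate curve with survival identically 1")
  }
  fit <- if (left_truncate) {
    survival::survfit(survival::Surv(entry_age, time, event) ~ 1,
                      data = records, conf.type = "log")
  } else {
    survival::survfit(survival::Surv(time, event) ~ 1, data = records,
                      conf.type = "log")
  }
  out <- list(times = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
              survival = fit$surv, lower = fit$lower, upper = fit$upper,
              fit = fit)
  class(out) <- "km_curve"
  out
}

#' Cumulative incidence read-out from a KM curve
#'
#' `1 - S(age)` at the largest step time at or before `age`
#' (right-continuous step convention); 0 before the first event and the
#' last step value carried forward beyond the curve.
#'
#' @param curve A `km_curve` from [km_fit()].
#' @param age Target age(s), >= 0.
#' @return Cumulative incidence at each age.
#' @export
km_risk_at <- function(curve, age) {
  stopifnot(inherits(curve, "km_curve"))
  if (any(age < 0)) stop("age must be >= 0")
  if (!length(curve$times)) return(rep(0, length(age)))
  s <- stats::stepfun(curve$times, c(1, curve$survival), right = FALSE)
  1 - s(age)
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood fit with the Efron tie correction (ages in years make
#' heavy ties) via [survival::coxph]; Wald 95% confidence intervals use
#' `exp(beta +/- 1.959964 * se)`.
#'
#' @param records `data.frame` with `time`, `event` and the covariate
#'   columns.
#' @param covariates Character vector of covariate column names.
#' @param left_truncate Enter at `entry_age` instead of birth.
#' @return Object of class `cox_fit`: list with `coefficients` (log-hazard
#'   per covariate), `hr`, `se`, `ci95` (matrix with `lower`/`upper`),
#'   `p` (Wald), `loglik`, `n`, `n_event` and the underlying fit.
#' @export
cox_fit <- function(records, covariates, left_truncate = FALSE) {
  stopifnot(length(covariates) >= 1L, all(covariates %in% names(records)))
  if (sum(records$event) < 2L) stop("Cox fit requires at least 2 events")
  for (cv in covariates) {
    v <- records[[cv]]
    if (length(unique(v[!is.na(v)])) < 2L) {
      stop("constant covariate: ", cv)
    }
  }
  lhs <- if (left_truncate) "survival::Surv(entry_age, time, event)" else
    "survival::Surv(time, event)"
  fml <- stats::as.formula(paste(lhs, "~",
                                 paste(sprintf("`%s`", covariates), collapse = " + ")))
  fit <- survival::coxph(fml, data = records, ties = "efron",
                         control = survival::coxph.control(eps = 1e-9,
                                                           iter.max = 100))
  if (!is.null(fit$info) && any(grepl("infinite", unlist(fit$info)))) {
    warning("possible complete separation in Cox fit")
  }
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z975 <- 1.959964
  ci <- cbind(lower = exp(beta - z975 * se), upper = exp(beta + z975 * se))
  out <- list(coefficients = beta, hr = exp(beta), se = se, ci95 = ci,
              p = 2 * stats::pnorm(-abs(beta / se)),
              loglik = fit$loglik[length(fit$loglik)],
              n = fit$n, n_event = fit$nevent, fit = fit)
  class(out) <- "cox_fit"
  out
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional-hazards fit (Efron ties),", x$n, "subjects,",
      x$n_event, "events\n")
  tab <- data.frame(HR = round(x$hr, 3),
                    `2.5%` = round(x$ci95[, "lower"], 3),
                    `97.5%` = round(x$ci95[, "upper"], 3),
                    p = signif(x$p, 3), check.names = FALSE)
  print(tab)
  invisible(x)
}

#' Two-sample log-rank test
#'
#' Standard 1-df log-rank chi-square comparing two arms.
#'
#' @param records_a,records_b `data.frame`s with `time`, `event`.
#' @return List with `statistic` (chi-square), `p`.
#' @export
logrank <- function(records_a, records_b) {
  stopifnot(nrow(records_a) >= 1L, nrow(records_b) >= 1L)
  if (sum(records_a$event) + sum(records_b$event) == 0L) {
    stop("log-rank test requires at least one event")
  }
  dat <- rbind(
    data.frame(time = records_a$time, event = records_a$event, arm = 0L),
    data.frame(time = records_b$time, event = records_b$event, arm = 1L)
  )
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ arm, data = dat)
  list(statistic = unname(sd_fit$chisq),
       p = stats::pchisq(sd_fit$chisq, df = 1, lower.tail = FALSE))
}
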