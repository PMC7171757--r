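#' Harrell's concordance index
#'
#' Fraction of concordant pairs among comparable pairs: a pair is comparable
#' iff the smaller observed time is an event (tied times are not
#' comparable); it is concordant when the shorter-lived patient has the
#' higher predicted risk, and tied risks count one half. A C-index of 0.5
#' describes a random prediction and 1.0 a perfect one.
#'
#' @param risk numeric predicted risks (higher = worse).
#' @param time observed times.
#' @param event event indicators (0/1).
#' @return Concordant fraction in [0, 1], or `NA` (with a message) when no
#'   pair is comparable.
#' @export
harrell_cindex <- function(risk, time, event) {
  stopifnot(length(risk) == length(time), length(time) == length(event))
  dt <- outer(time, time, `<`)                 # dt[i,j]: t_i < t_j
  comparable <- dt & matrix(event == 1, length(time), length(time))
  n_comp <- sum(comparable)
  if (n_comp == 0) {
    message("no comparable pairs; C-index undefined")
    return(NA_real_)
  }
  dr <- outer(risk, risk, `-`)                 # r_i - r_j
  conc <- sum(comparable & dr > 0) + 0.5 * sum(comparable & dr == 0)
  conc / n_comp
}

# Kaplan-Meier estimate of the censoring distribution G(t), returned as a
# left-continuous step function evaluator (G at t-).
censoring_km <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  st <- summary(fit, censored = TRUE)
  function(t) {
    vapply(t, function(ti) {
      keep <- st$time < ti
      if (!any(keep)) 1 else min(st$surv[keep])
    }, 0)
  }
}

#' Time-dependent (cumulative/dynamic) AUC with IPCW
#'
#' Discrimination at horizon `t`: cases are patients with an event by `t`,
#' controls are patients event-free past `t`. Censoring is corrected by
#' inverse-probability-of-censoring weights from the Kaplan-Meier estimate
#' of the censoring distribution: a case observed at time `T_i` gets weight
#' `1/G(T_i-)` and a control `1/G(t)`. Without censoring all weights are 1
#' and the estimate equals the plain binary AUC of (event by `t`) against
#' the risk score.
#'
#' @inheritParams harrell_cindex
#' @param t evaluation horizon (months; 36 = 3 years).
#' @return AUC in [0, 1]; `NA` with a message when there is no case or no
#'   control.
#' @export
time_dependent_auc <- function(risk, time, event, t = 36) {
  cases <- which(time <= t & event == 1)
  controls <- which(time > t)
  if (!length(cases) || !length(controls)) {
    message("no cases or no controls at t = ", t, "; AUC undefined")
    return(NA_real_)
  }
  G <- censoring_km(time, event)
  w_case <- 1 / G(time[cases])
  w_ctrl <- rep(1 / G(t), length(controls))
  dr <- outer(risk[cases], risk[controls], `-`)
  w <- outer(w_case, w_ctrl)
  sum(w * ((dr > 0) + 0.5 * (dr == 0))) / sum(w)
}

#' Kaplan-Meier estimate and survival at query times
#'
#' Product-limit estimator via [survival::survfit()].
#'
#' @inheritParams harrell_cindex
#' @return list with the `survfit` object and `survival_at(t)`, a function
#'   returning S(t).
#' @export
km_estimate <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  survival_at <- function(t) {
    vapply(t, function(ti) {
      keep <- fit$time <= ti
      if (!any(keep)) 1 else min(fit$surv[keep])
    }, 0)
  }
  list(fit = fit, survival_at = survival_at)
}

#' Two-group log-rank test
#'
#' Standard two-sided log-rank chi-square on 1 degree of freedom, via
#' [survival::survdiff()].
#'
#' @param time,event outcome vectors.
#' @param group two-level grouping vector.
#' @return list with `statistic` and `p`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L)
    stop("log-rank test requires exactly two non-empty groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(statistic = sd$chisq, p = pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Maximally selected log-rank cutpoint
#'
#' Scans the observed risk values as candidate cutoffs (patients with risk
#' above the cutoff form the high-risk group) and returns the cutoff
#' maximizing the log-rank statistic, in the spirit of survMisc-style
#' optimal cutpoint selection. Candidates leaving either group with fewer
#' than `min_group_frac` of patients are inadmissible (a guard against
#' degenerate groups; set 0 to disable). Ties are broken toward the lower
#' cutoff.
#'
#' @inheritParams harrell_cindex
#' @param min_group_frac minimum fraction of patients per group.
#' @return list with `cutpoint`, `statistic` and the scanned `candidates`
#'   data frame.
#' @export
optimal_cutpoint <- function(risk, time, event, min_group_frac = 0.10) {
  n <- length(risk)
  if (n < 10L) stop("need at least 10 patients for cutpoint selection")
  if (sum(event) == 0) stop("no events; cutpoint undefined")
  cand <- sort(unique(risk))
  cand <- cand[-length(cand)]                  # top value leaves empty group
  min_n <- ceiling(min_group_frac * n)
  adm <- vapply(cand, function(cc) {
    hi <- sum(risk > cc)
    hi >= min_n && (n - hi) >= min_n
  }, TRUE)
  cand <- cand[adm]
  if (!length(cand)) stop("no admissible cutoff (risks too concentrated)")
  stat <- vapply(cand, function(cc) {
    g <- risk > cc
    tryCatch(logrank_test(time, event, g)$statistic, error = function(e) -Inf)
  }, 0)
  best <- which(stat == max(stat))[1]          # ties -> lower cutoff
  list(cutpoint = cand[best], statistic = stat[best],
       candidates = data.frame(cutpoint = cand, statistic = stat))
}

#' Univariate and multivariate Cox hazard-ratio table
#'
#' For each covariate: a univariate proportional-hazards fit (Efron tie
#' handling, the coxph default) with Wald p-value, plus one joint
#' multivariate fit of all covariates together, reporting multivariate
#' hazard ratios with 95% confidence intervals. For binary/factor
#' covariates the per-level patient counts and 3-year (36-month)
#' Kaplan-Meier survival are reported. Covariates exhibiting
#' monotone-likelihood separation (degenerate estimates) are flagged
#' `unstable` and their HR reported as missing rather than a number;
#' duplicated covariate columns are rejected as collinear.
#'
#' @param covariates data frame of covariates (numeric or factor), one row
#'   per patient.
#' @param time,event outcome vectors aligned with `covariates`.
#' @return data frame, one row per covariate (and level), with columns
#'   `variable`, `level`, `n`, `surv_3y_pct`, `p_univariate`,
#'   `p_multivariate`, `HR`, `CI_low`, `CI_high`, `unstable`.
#' @export
cox_table <- function(covariates, time, event) {
  stopifnot(is.data.frame(covariates), nrow(covariates) == length(time))
  num <- as.data.frame(lapply(covariates, function(x)
    if (is.factor(x) || is.character(x)) as.numeric(as.factor(x)) else
      as.numeric(x)))
  if (any(duplicated(t(num))))
    stop("collinearity error: duplicated covariate columns")
  uni <- lapply(names(covariates), function(v) {
    fit <- survival::coxph(survival::Surv(time, event) ~ covariates[[v]],
                           ties = "efron")
    s <- summary(fit)
    c(p = s$coefficients[1, "Pr(>|z|)"], coef = s$coefficients[1, "coef"],
      se = s$coefficients[1, "se(coef)"])
  })
  names(uni) <- names(covariates)
  mdf <- cbind(covariates, ..time = time, ..event = event)
  mform <- stats::as.formula(paste(
    "survival::Surv(..time, ..event) ~",
    paste(sprintf("`%s`", names(covariates)), collapse = " + ")))
  multi <- survival::coxph(mform, data = mdf, ties = "efron")
  sm <- summary(multi)
  mrow <- function(v) {
    hit <- grep(paste0("^", v), rownames(sm$coefficients))[1]
    if (is.na(hit)) return(c(NA, NA, NA))
    sm$coefficients[hit, c("coef", "se(coef)", "Pr(>|z|)")]
  }
  rows <- lapply(names(covariates), function(v) {
    m <- mrow(v)
    unstable <- is.na(m[1]) || abs(m[1]) > 10 || m[2] > 100 ||
      abs(uni[[v]][["coef"]]) > 10
    hr <- if (unstable) NA_real_ else exp(m[1])
    ci <- if (unstable) c(NA_real_, NA_real_) else
      exp(m[1] + c(-1.96, 1.96) * m[2])
    x <- covariates[[v]]
    if (is.numeric(x) && length(unique(x)) > 2) {
      data.frame(variable = v, level = "", n = length(x),
                 surv_3y_pct = NA_real_,
                 p_univariate = uni[[v]][["p"]], p_multivariate = m[3],
                 HR = hr, CI_low = ci[1], CI_high = ci[2],
                 unstable = unstable)
    } else {
      lv <- sort(unique(as.character(x)))
      do.call(rbind, lapply(lv, function(l) {
        sel <- as.character(x) == l
        data.frame(variable = v, level = l, n = sum(sel),
                   surv_3y_pct = 100 * km_estimate(time[sel],
                                                   event[sel])$survival_at(36),
                   p_univariate = uni[[v]][["p"]], p_multivariate = m[3],
                   HR = hr, CI_low = ci[1], CI_high = ci[2],
                   unstable = unstable)
      }))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Evaluate a fitted risk model on a cohort
#'
#' Computes the C-index, the 36-month IPCW time-dependent AUC, and (given a
#' cutpoint, typically derived on the training risks) the Kaplan-Meier
#' 3-year survival per risk group and the two-group log-rank test.
#'
#' @param model a [fit_rsf()] model.
#' @param table feature table for the cohort to evaluate.
#' @param outcomes single-endpoint outcome table.
#' @param t_eval evaluation horizon in months.
#' @param cutpoint risk cutoff for the low/high groups; `NULL` skips the
#'   group analysis.
#' @return An `evaluation_report` list.
#' @export
evaluate_model <- function(model, table, outcomes, t_eval = 36,
                           cutpoint = NULL) {
  prep <- align_outcomes(table, outcomes)
  risk <- predict_risk(model, table)
  rep <- list(endpoint = model$endpoint,
              n = nrow(table),
              cindex = harrell_cindex(risk, prep$time, prep$event),
              auc = time_dependent_auc(risk, prep$time, prep$event, t_eval),
              t_eval = t_eval,
              risk = risk)
  if (!is.null(cutpoint)) {
    grp <- risk > cutpoint
    rep$cutpoint <- cutpoint
    rep$group_n <- c(low = sum(!grp), high = sum(grp))
    if (all(c(TRUE, FALSE) %in% grp)) {
      rep$surv_3y_pct <- c(
        low = 100 * km_estimate(prep$time[!grp], prep$event[!grp])$survival_at(t_eval),
        high = 100 * km_estimate(prep$time[grp], prep$event[grp])$survival_at(t_eval))
      lr <- logrank_test(prep$time, prep$event, grp)
      rep$logrank_p <- lr$p
    }
  }
  structure(rep, class = "evaluation_report")
}
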