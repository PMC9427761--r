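#' ROC curve and AUC with DeLong confidence interval
#'
#' AUC is the Mann-Whitney probability that a positive case scores above a
#' negative one, with half credit for ties; the 95% CI uses DeLong's
#' variance estimate.
#'
#' @param scores numeric predictor (higher = more likely positive).
#' @param labels binary labels (0/1, logical, or two-level factor with the
#'   positive class second).
#' @return list of class \code{roc_summary}: \code{auc}, \code{ci_low},
#'   \code{ci_high}, \code{curve} (data.frame of fpr/tpr).
#' @export
roc_auc <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels == levels(labels)[2])
  labels <- as.integer(labels)
  if (length(unique(labels)) != 2)
    ring_stop("both classes must be present", "validation_error")
  r <- pROC::roc(response = labels, predictor = scores, levels = c(0, 1),
                 direction = "<", quiet = TRUE)
  ci <- as.numeric(pROC::ci.auc(r, method = "delong"))
  structure(list(auc = as.numeric(pROC::auc(r)),
                 ci_low = ci[1], ci_high = ci[3],
                 curve = data.frame(fpr = rev(1 - r$specificities),
                                    tpr = rev(r$sensitivities))),
            class = "roc_summary")
}

#' @export
print.roc_summary <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f)\n", x$auc, x$ci_low, x$ci_high))
  invisible(x)
}

#' Kaplan-Meier estimate and log-rank test
#'
#' \code{km_estimate} returns the product-limit survival curve with
#' Greenwood standard errors; \code{logrank_test} the K-group log-rank
#' chi-square with K-1 degrees of freedom.
#'
#' @param times non-negative follow-up times.
#' @param events 0/1 event indicators.
#' @param groups group labels (factor or character) for the log-rank test.
#' @return \code{km_estimate}: data.frame of class \code{km_curve} with
#'   columns time, n_risk, n_event, surv, se, lower, upper.
#'   \code{logrank_test}: list with \code{statistic}, \code{df}, \code{p}.
#' @export
km_estimate <- function(times, events) {
  check_surv(times, events)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  structure(data.frame(time = fit$time, n_risk = fit$n.risk,
                       n_event = fit$n.event, surv = fit$surv,
                       se = fit$std.err * fit$surv,
                       lower = fit$lower, upper = fit$upper),
            class = c("km_curve", "data.frame"))
}

#' @rdname km_estimate
#' @export
logrank_test <- function(times, events, groups) {
  check_surv(times, events)
  if (sum(events) < 1)
    ring_stop("log-rank test needs at least one event", "validation_error")
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- length(sd$n) - 1
  list(statistic = as.numeric(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

check_surv <- function(times, events) {
  if (any(times < 0) || any(!is.finite(times)))
    ring_stop("times must be finite and >= 0", "validation_error")
  if (!all(events %in% c(0, 1)))
    ring_stop("events must be 0/1", "validation_error")
  invisible(TRUE)
}

#' Univariate and multivariate Cox regression
#'
#' Fits a univariate Cox proportional-hazards model (Efron tie handling)
#' per covariate, then a multivariate model over the covariates whose
#' univariate likelihood-ratio p-value is below \code{entry_p} (set
#' \code{entry_p = 1} for the full-covariate fit). Hazard ratios with Wald
#' confidence intervals and p-values are reported per coefficient, plus the
#' model C-index.
#'
#' @param data data.frame of cases.
#' @param time,event column names of the outcome time and 0/1 event.
#' @param covariates character vector of covariate column names.
#' @param entry_p univariate screening threshold for multivariate entry.
#' @return list of class \code{cox_summary}: \code{univariate} and
#'   \code{multivariate} coefficient tables, the fitted multivariate
#'   \code{model}, \code{entered} covariates and \code{c_index}.
#' @export
cox_fit <- function(data, time, event, covariates, entry_p = 0.05) {
  check_surv(data[[time]], data[[event]])
  if (sum(data[[event]]) < 1)
    ring_stop("Cox regression needs at least one event", "validation_error")
  # covariates constant in this cohort carry no information and break
  # factor contrasts; drop them up front
  covariates <- covariates[vapply(covariates, function(cv)
    length(unique(data[[cv]])) > 1, logical(1))]
  if (length(covariates) == 0)
    ring_stop("no non-constant covariates", "validation_error")
  surv_obj <- survival::Surv(data[[time]], data[[event]])

  coef_table <- function(fit) {
    s <- summary(fit)
    data.frame(term = rownames(s$coefficients),
               hr = s$coefficients[, "exp(coef)"],
               ci_low = s$conf.int[, "lower .95"],
               ci_high = s$conf.int[, "upper .95"],
               p = s$coefficients[, "Pr(>|z|)"],
               row.names = NULL)
  }
  uni <- lapply(covariates, function(cv) {
    f <- stats::as.formula(paste("surv_obj ~", cv))
    fit <- survival::coxph(f, data = data, ties = "efron")
    tab <- coef_table(fit)
    tab$covariate <- cv
    tab$model_p <- summary(fit)$logtest["pvalue"]
    tab
  })
  uni_tab <- do.call(rbind, uni)
  model_p <- vapply(uni, function(u) u$model_p[1], numeric(1))
  entered <- covariates[model_p < entry_p]
  if (length(entered) == 0) entered <- covariates[which.min(model_p)]

  f <- stats::as.formula(paste("surv_obj ~", paste(entered, collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(f, data = data, ties = "efron"),
    warning = function(w) {
      # a genuine iteration failure is fatal; monotone-likelihood warnings
      # ("coefficient may be infinite") still yield a usable fit
      if (grepl("Ran out of iterations", conditionMessage(w)))
        ring_stop(paste0("multivariate Cox fit did not converge: ",
                         conditionMessage(w)), "convergence_error")
      invokeRestart("muffleWarning")
    })
  conc <- survival::concordance(fit)
  structure(list(univariate = uni_tab,
                 multivariate = coef_table(fit),
                 model = fit,
                 entered = entered,
                 c_index = as.numeric(conc$concordance),
                 c_index_se = sqrt(as.numeric(conc$var))),
            class = "cox_summary")
}

#' @export
print.cox_summary <- function(x, ...) {
  cat("Cox proportional hazards (Efron ties)\n")
  cat("  multivariate covariates:", paste(x$entered, collapse = ", "), "\n")
  tab <- x$multivariate
  for (i in seq_len(nrow(tab)))
    cat(sprintf("    %-24s HR %.3f (%.3f-%.3f) p=%.4g\n", tab$term[i],
                tab$hr[i], tab$ci_low[i], tab$ci_high[i], tab$p[i]))
  cat(sprintf("  C-index %.3f (SE %.3f)\n", x$c_index, x$c_index_se))
  invisible(x)
}

#' Harrell's concordance index with bootstrap confidence interval
#'
#' The fraction of usable pairs ranked concordantly by the linear predictor
#' (higher predictor = shorter survival), ties counted 0.5. The CI is a
#' seeded case-resampling bootstrap percentile interval.
#'
#' @param lp numeric linear predictor (risk score).
#' @param times,events survival outcome.
#' @param n_boot bootstrap draws.
#' @param seed integer seed.
#' @return list: \code{c_index}, \code{ci_low}, \code{ci_high},
#'   \code{n_pairs}.
#' @export
c_index <- function(lp, times, events, n_boot = 1000, seed = 1) {
  check_surv(times, events)
  cc <- survival::concordance(survival::Surv(times, events) ~ lp,
                              reverse = TRUE)
  npairs <- sum(cc$count[c("concordant", "discordant", "tied.x")])
  if (npairs < 1)
    ring_stop("no usable pairs for concordance", "validation_error")
  set.seed(as.integer(seed))
  n <- length(lp)
  boots <- vapply(seq_len(n_boot), function(b) {
    ii <- sample.int(n, n, replace = TRUE)
    if (sum(events[ii]) == 0) return(NA_real_)
    as.numeric(survival::concordance(
      survival::Surv(times[ii], events[ii]) ~ lp[ii],
      reverse = TRUE)$concordance)
  }, numeric(1))
  qs <- quantile(boots, c(0.025, 0.975), na.rm = TRUE)
  list(c_index = as.numeric(cc$concordance),
       ci_low = unname(qs[1]), ci_high = unname(qs[2]),
       n_pairs = unname(npairs))
}

#' Nomogram points and linear predictor
#'
#' Scores cases against a multivariate Cox model the way a printed nomogram
#' would: each covariate contributes points proportional to its effect on
#' the linear predictor, scaled so the single largest covariate effect
#' (over the training data range) spans 100 points; a case at every
#' reference level scores 0. Total points are monotone in the linear
#' predictor.
#'
#' @param cox a \code{cox_summary} from \code{\link{cox_fit}}.
#' @param newdata data.frame containing every model covariate.
#' @return data.frame with per-case \code{points} and \code{lp}.
#' @export
nomogram_score <- function(cox, newdata) {
  fit <- cox$model
  covs <- cox$entered
  missing <- setdiff(covs, colnames(newdata))
  if (length(missing) > 0)
    ring_stop(paste0("missing covariates: ", paste(missing, collapse = ", ")),
              "schema_error")
  tt <- stats::delete.response(stats::terms(fit))
  beta <- stats::coef(fit)
  # per-covariate contribution ranges over the training design
  mm_train <- stats::model.matrix(fit)
  asg <- attr(mm_train, "assign")
  if (length(asg) == ncol(mm_train) + 1) asg <- asg[-1]  # drop intercept slot
  contrib_train <- sweep(mm_train, 2, beta, `*`)
  per_cov_train <- vapply(seq_along(covs), function(j) {
    cols <- which(asg == j)
    rowSums(contrib_train[, cols, drop = FALSE])
  }, numeric(nrow(mm_train)))
  ranges <- apply(per_cov_train, 2, function(v) diff(range(v)))
  mins <- apply(per_cov_train, 2, min)
  scale_pts <- 100 / max(ranges)

  mf <- stats::model.frame(tt, newdata, xlev = fit$xlevels)
  mm <- stats::model.matrix(tt, mf)
  keep <- colnames(mm) %in% names(beta)
  contrib <- sweep(mm[, keep, drop = FALSE], 2, beta[colnames(mm)[keep]], `*`)
  asg_new <- attr(mm, "assign")[keep]
  per_cov <- vapply(seq_along(covs), function(j) {
    cols <- which(asg_new == j)
    rowSums(contrib[, cols, drop = FALSE])
  }, numeric(nrow(mm)))
  if (is.null(dim(per_cov))) per_cov <- matrix(per_cov, nrow = nrow(mm))
  pts <- sweep(per_cov, 2, mins, `-`) * scale_pts
  data.frame(points = rowSums(pts), lp = rowSums(per_cov))
}

#' Treatment response rates by RS group
#'
#' Tabulates objective response (CR+PR), disease control (CR+PR+SD) and PD
#' rates per RS group, tests the group x response table by chi-square, and
#' compares RS between response groups (OR vs SD vs PD) by two-tailed
#' unpaired t-tests. Empty groups report NA rates, never 0.
#'
#' @param response RECIST categories (\code{CR}, \code{PR}, \code{SD},
#'   \code{PD}), one per case.
#' @param rs_group RS group labels per case.
#' @param rs numeric radiomics scores per case.
#' @return list of class \code{response_summary}: \code{rates} data.frame,
#'   \code{chisq} (htest), \code{rs_tests} data.frame of pairwise t-tests.
#' @export
response_table <- function(response, rs_group, rs) {
  if (any(is.na(response)))
    ring_stop("every case needs a response category", "validation_error")
  if (!all(response %in% c("CR", "PR", "SD", "PD")))
    ring_stop("responses must be CR/PR/SD/PD", "validation_error")
  groups <- sort(unique(rs_group))
  rates <- do.call(rbind, lapply(groups, function(g) {
    rr <- response[rs_group == g]
    n <- length(rr)
    data.frame(group = g, n = n,
               objective_response = if (n > 0)
                 100 * mean(rr %in% c("CR", "PR")) else NA_real_,
               disease_control = if (n > 0)
                 100 * mean(rr %in% c("CR", "PR", "SD")) else NA_real_,
               progressive_disease = if (n > 0)
                 100 * mean(rr == "PD") else NA_real_)
  }))
  chisq <- suppressWarnings(chisq.test(table(rs_group, response)))
  cat3 <- ifelse(response %in% c("CR", "PR"), "OR", response)
  if (length(unique(cat3)) < 2) {
    return(structure(list(rates = rates, chisq = chisq,
                          rs_tests = data.frame(group1 = character(0),
                                                group2 = character(0),
                                                mean1 = numeric(0),
                                                mean2 = numeric(0),
                                                t = numeric(0),
                                                p = numeric(0))),
                     class = "response_summary"))
  }
  pairs <- utils::combn(sort(unique(cat3)), 2, simplify = FALSE)
  rs_tests <- do.call(rbind, lapply(pairs, function(pr) {
    a <- rs[cat3 == pr[1]]
    b <- rs[cat3 == pr[2]]
    if (length(a) < 2 || length(b) < 2)
      return(data.frame(group1 = pr[1], group2 = pr[2], mean1 = mean(a),
                        mean2 = mean(b), t = NA_real_, p = NA_real_))
    tt <- t.test(a, b, var.equal = FALSE)
    data.frame(group1 = pr[1], group2 = pr[2], mean1 = mean(a),
               mean2 = mean(b), t = unname(tt$statistic),
               p = tt$p.value)
  }))
  structure(list(rates = rates, chisq = chisq, rs_tests = rs_tests),
            class = "response_summary")
}

#' @export
print.response_summary <- function(x, ...) {
  cat("Response rates by RS group (%):\n")
  print(x$rates, row.names = FALSE, digits = 3)
  cat(sprintf("  chi-square p = %.4g\n", x$chisq$p.value))
  invisible(x)
}
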