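#' NLR status from paired region ratios
#'
#' Applies the threshold-1 labeling rule to the intratumoral and peritumoral
#' neutrophil-to-lymphocyte ratios: \code{High} when both are >= 1,
#' \code{Low} when both are < 1, \code{Mix} otherwise. The boundary value 1
#' counts as >= 1.
#'
#' @param nlr_intra,nlr_peri finite non-negative ratios (vectorized).
#' @return character vector of \code{"High"}, \code{"Mix"}, \code{"Low"}.
#' @export
nlr_status <- function(nlr_intra, nlr_peri) {
  if (any(!is.finite(nlr_intra)) || any(!is.finite(nlr_peri)) ||
      any(nlr_intra < 0) || any(nlr_peri < 0))
    ring_stop("NLR ratios must be finite and non-negative",
              "validation_error")
  hi_i <- nlr_intra >= 1
  hi_p <- nlr_peri >= 1
  ifelse(hi_i & hi_p, "High", ifelse(!hi_i & !hi_p, "Low", "Mix"))
}

#' Rank features by maximum relevance, minimum redundancy
#'
#' Greedy mRMR in the F-statistic/correlation-difference (FCD) variant:
#' relevance is the one-way ANOVA F statistic of a feature against the
#' binary label, expressed on the correlation scale (the point-biserial
#' correlation \code{sqrt(F / (F + n - 2))}, a monotone map of F) so that
#' it is commensurable with the redundancy term; redundancy is the mean
#' absolute Pearson correlation with the already selected features. Each
#' step picks the feature maximizing relevance minus redundancy.
#' Deterministic; exact score ties fall back to column order.
#'
#' @param x numeric matrix (cases x features) with column names.
#' @param y binary labels (two distinct values).
#' @param k number of features to rank (1 <= k <= ncol(x)).
#' @return character vector of k selected column names, in selection order.
#' @export
mrmr_rank <- function(x, y, k) {
  x <- as.matrix(x)
  if (k < 1) ring_stop("k must be >= 1", "validation_error")
  if (k > ncol(x)) ring_stop("k exceeds feature count", "validation_error")
  yl <- unique(y)
  if (length(yl) != 2) ring_stop("labels must take two values",
                                 "validation_error")
  g <- y == yl[2]
  n1 <- sum(g); n0 <- sum(!g); n <- n1 + n0
  m1 <- colMeans(x[g, , drop = FALSE])
  m0 <- colMeans(x[!g, , drop = FALSE])
  v1 <- apply(x[g, , drop = FALSE], 2, var)
  v0 <- apply(x[!g, , drop = FALSE], 2, var)
  mall <- colMeans(x)
  ssb <- n1 * (m1 - mall)^2 + n0 * (m0 - mall)^2
  ssw <- (n1 - 1) * v1 + (n0 - 1) * v0
  fstat <- ifelse(ssw > 0, ssb / (ssw / (n - 2)),
                  ifelse(ssb > 0, Inf, 0))
  # point-biserial scale: sqrt(F / (F + n - 2)), 1 for infinite F
  relevance <- ifelse(is.finite(fstat),
                      sqrt(fstat / (fstat + n - 2)), 1)

  sel <- integer(0)
  red_sum <- rep(0, ncol(x))
  for (step in seq_len(k)) {
    score <- relevance - if (length(sel) > 0) red_sum / length(sel) else 0
    score[sel] <- -Inf
    pick <- which.max(score)  # first max = catalogue order on ties
    sel <- c(sel, pick)
    if (step < k) {
      r <- abs(suppressWarnings(cor(x, x[, pick])))
      r[!is.finite(r)] <- 0
      red_sum <- red_sum + as.numeric(r)
    }
  }
  colnames(x)[sel]
}

#' Fit a radiomics signature by mRMR and cross-validated LASSO
#'
#' The core estimator: features are pre-ranked by \code{\link{mrmr_rank}}
#' (top \code{k}), z-scored with training statistics, and entered into a
#' LASSO-penalized logistic regression whose penalty is chosen to minimize
#' the mean binomial deviance over seeded label-stratified
#' \code{nfolds}-fold cross-validation. The radiomics score (RS) of a case
#' is the fitted linear predictor (intercept plus coefficient-weighted
#' standardized features); tertile cutoffs of the training RS define the
#' RS-Low / RS-Middle / RS-High groups.
#'
#' @param x numeric matrix or data.frame (cases x features) with column
#'   names; typically the 584-column table from \code{\link{extract_cohort}}.
#' @param y binary outcome: 1 (or the second factor level) for NLR-High,
#'   0 for NLR-Low. Mix cases are excluded before calling.
#' @param k mRMR pre-selection size.
#' @param nfolds cross-validation folds (>= cases per class required).
#' @param seed integer seed controlling fold assignment.
#' @param lambda optional fixed penalty; overrides cross-validation.
#' @return An object of class \code{radiomics_signature} with components
#'   \code{selected}, \code{coefficients}, \code{intercept},
#'   \code{standardization} (per-feature mean/sd), \code{lambda},
#'   \code{tertile_cutoffs}, \code{group_labels}, and training diagnostics.
#' @export
rs_fit <- function(x, y, k = 30, nfolds = 5, seed = 1, lambda = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x)))
    ring_stop("x must have column names", "validation_error")
  storage.mode(x) <- "double"
  if (is.factor(y)) {
    y <- as.integer(y == levels(y)[2])
  } else if (is.numeric(y) && all(y %in% c(0, 1))) {
    y <- as.integer(y)
  } else {
    ring_stop("y must be 0/1 or a two-level factor (positive class second)",
              "validation_error")
  }
  if (min(table(y)) < nfolds)
    ring_stop("need at least nfolds cases per class", "validation_error")

  keep <- apply(x, 2, sd) > 1e-12
  xk <- x[, keep, drop = FALSE]
  ranked <- mrmr_rank(xk, y, min(k, ncol(xk)))
  xr <- xk[, ranked, drop = FALSE]
  ctr <- colMeans(xr)
  scl <- apply(xr, 2, sd)
  xs <- scale(xr, center = ctr, scale = scl)

  set.seed(as.integer(seed))
  foldid <- integer(length(y))
  for (cl in unique(y))
    foldid[y == cl] <- sample(rep_len(seq_len(nfolds), sum(y == cl)))

  if (is.null(lambda)) {
    cvfit <- glmnet::cv.glmnet(xs, y, family = "binomial", foldid = foldid,
                               standardize = FALSE,
                               type.measure = "deviance")
    lam <- cvfit$lambda.min
    cv_curve <- data.frame(lambda = cvfit$lambda, deviance = cvfit$cvm,
                           se = cvfit$cvsd)
  } else {
    cvfit <- NULL
    lam <- lambda
    cv_curve <- NULL
  }
  fit <- glmnet::glmnet(xs, y, family = "binomial", standardize = FALSE)
  cf <- as.matrix(coef(fit, s = lam, exact = TRUE, x = xs, y = y))
  beta <- cf[-1, 1]
  nz <- beta[beta != 0]
  if (length(nz) == 0)
    ring_stop(paste0("all coefficients are zero at lambda = ",
                     signif(lam, 4),
                     "; inspect the lambda grid (cross-validation curve) ",
                     "or lower the penalty"),
              "signature_empty_error")
  intercept <- cf[1, 1]
  rs <- as.numeric(intercept + xs[, names(nz), drop = FALSE] %*% nz)
  cutoffs <- unname(quantile(rs, c(1 / 3, 2 / 3)))

  structure(list(
    selected = names(nz),
    coefficients = nz,
    intercept = intercept,
    standardization = data.frame(feature = names(nz),
                                 mean = ctr[names(nz)],
                                 sd = scl[names(nz)]),
    lambda = lam,
    tertile_cutoffs = cutoffs,
    group_labels = c("RS-Low", "RS-Middle", "RS-High"),
    mrmr_ranked = ranked,
    cv_curve = cv_curve,
    training = list(rs = rs, y = y, n = length(y), seed = seed,
                    nfolds = nfolds, k = k)),
    class = "radiomics_signature")
}

#' @export
print.radiomics_signature <- function(x, ...) {
  cat("Radiomics signature (mRMR + LASSO logistic regression)\n")
  cat("  training cases:", x$training$n, " folds:", x$training$nfolds,
      " lambda:", signif(x$lambda, 4), "\n")
  cat("  selected features (", length(x$selected), "):\n", sep = "")
  for (f in x$selected)
    cat(sprintf("    %-40s %+.4f\n", f, x$coefficients[[f]]))
  cat(sprintf("  intercept: %+.4f\n", x$intercept))
  cat(sprintf("  RS tertile cutoffs: %.4f / %.4f\n",
              x$tertile_cutoffs[1], x$tertile_cutoffs[2]))
  invisible(x)
}

#' @export
summary.radiomics_signature <- function(object, ...) {
  grp <- assign_rs_group(object$training$rs, object$tertile_cutoffs)
  res <- list(signature = object,
              n_selected = length(object$selected),
              rs_fivenum = fivenum(object$training$rs),
              group_sizes = table(factor(grp, levels = object$group_labels)))
  class(res) <- "summary.radiomics_signature"
  res
}

#' @export
print.summary.radiomics_signature <- function(x, ...) {
  print(x$signature)
  cat("  training RS five-number summary:",
      paste(signif(x$rs_fivenum, 4), collapse = " "), "\n")
  cat("  training group sizes:",
      paste(names(x$group_sizes), x$group_sizes, sep = "=",
            collapse = " "), "\n")
  invisible(x)
}

#' @export
coef.radiomics_signature <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @export
plot.radiomics_signature <- function(x, ...) {
  if (is.null(x$cv_curve)) {
    graphics::hist(x$training$rs, breaks = 20, main = "Training RS",
                   xlab = "radiomics score")
  } else {
    plot(log(x$cv_curve$lambda), x$cv_curve$deviance, type = "b", pch = 16,
         cex = 0.6, xlab = "log(lambda)", ylab = "mean CV binomial deviance",
         main = "LASSO cross-validation", ...)
    graphics::abline(v = log(x$lambda), lty = 2)
  }
  invisible(x)
}

#' Compute the radiomics score for new cases
#'
#' @param signature a \code{radiomics_signature}.
#' @param newdata matrix/data.frame containing every selected feature
#'   column (missing columns are an error, never imputed), or a single
#'   named numeric row.
#' @return numeric RS per case.
#' @export
compute_rs <- function(signature, newdata) {
  if (is.null(dim(newdata))) newdata <- t(as.matrix(newdata))
  missing <- setdiff(signature$selected, colnames(newdata))
  if (length(missing) > 0)
    ring_stop(paste0("missing selected features: ",
                     paste(missing, collapse = ", ")), "schema_error")
  xm <- as.matrix(newdata[, signature$selected, drop = FALSE])
  storage.mode(xm) <- "double"
  st <- signature$standardization
  xs <- scale(xm, center = st$mean, scale = st$sd)
  as.numeric(signature$intercept +
               xs %*% signature$coefficients[signature$selected])
}

#' @param object a \code{radiomics_signature}.
#' @param type \code{"score"} for the RS, \code{"group"} for the tertile
#'   group label, \code{"response"} for the logistic probability of the
#'   positive (NLR-High) class.
#' @rdname compute_rs
#' @export
predict.radiomics_signature <- function(object, newdata,
                                        type = c("score", "group",
                                                 "response"), ...) {
  type <- match.arg(type)
  rs <- compute_rs(object, newdata)
  switch(type,
         score = rs,
         group = assign_rs_group(rs, object$tertile_cutoffs),
         response = 1 / (1 + exp(-rs)))
}

#' Pooled out-of-fold AUC of the signature pipeline
#'
#' Honest resubstitution-free discrimination estimate: the cases are split
#' into seeded label-stratified outer folds; for each fold the full
#' selection-and-fit pipeline (\code{\link{rs_fit}}, including its inner
#' cross-validation for the penalty) runs on the remaining folds only, the
#' held-out cases are scored, and a single AUC is computed on the pooled
#' out-of-fold scores.
#'
#' @inheritParams rs_fit
#' @param folds number of outer folds.
#' @return list: \code{auc}, \code{scores} (pooled out-of-fold RS),
#'   \code{fold} assignment.
#' @export
oof_auc <- function(x, y, k = 30, folds = 5, nfolds = 5, seed = 1) {
  x <- as.matrix(x)
  y <- as.integer(y)
  set.seed(as.integer(seed))
  fold <- integer(length(y))
  for (cl in unique(y))
    fold[y == cl] <- sample(rep_len(seq_len(folds), sum(y == cl)))
  scores <- numeric(length(y))
  for (f in seq_len(folds)) {
    tr <- fold != f
    sig <- rs_fit(x[tr, , drop = FALSE], y[tr], k = k, nfolds = nfolds,
                  seed = seed + f)
    scores[!tr] <- compute_rs(sig, x[!tr, , drop = FALSE])
  }
  list(auc = roc_auc(scores, y)$auc, scores = scores, fold = fold)
}

#' Assign tertile-based RS groups
#'
#' \code{RS-Low} for RS <= q1, \code{RS-Middle} for q1 < RS <= q2,
#' \code{RS-High} for RS > q2 (boundaries close on the lower-group side).
#'
#' @param rs numeric radiomics scores.
#' @param cutoffs length-2 non-decreasing cutoffs (q1, q2).
#' @return character vector of group labels.
#' @export
assign_rs_group <- function(rs, cutoffs) {
  if (length(cutoffs) != 2 || cutoffs[1] > cutoffs[2])
    ring_stop("cutoffs must be non-decreasing (q1, q2)", "validation_error")
  ifelse(rs <= cutoffs[1], "RS-Low",
         ifelse(rs <= cutoffs[2], "RS-Middle", "RS-High"))
}
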