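#' Pearson correlation with p-value
#'
#' Product-moment correlation and two-sided t-based p-value. Applied to a
#' continuous score against a 0/1 status this is the point-biserial
#' correlation coefficient.
#'
#' @param x,y Equal-length numeric vectors (length >= 3, non-zero
#'   variance each).
#' @return List with elements `r` and `p`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) ith_parameter_error("x and y lengths differ")
  if (length(x) < 3) ith_parameter_error("need at least 3 observations")
  if (var(x) == 0 || var(y) == 0)
    ith_degenerate_input_error("zero variance in x or y")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' ROC analysis with a Youden operating point
#'
#' AUC is the Mann-Whitney concordance probability with 0.5 credit for
#' ties. The operating point is the threshold (predict positive when
#' `score >= threshold`, swept over the observed score values) that
#' maximizes Youden's J = sensitivity + specificity - 1; J ties are
#' broken toward higher specificity, then toward the higher threshold.
#'
#' @param scores Numeric vector.
#' @param labels 0/1 vector (both classes present).
#' @return An object of class `roc_summary`: `auc`, `sensitivity`,
#'   `specificity`, `threshold`, `youden_j`, `n_pos`, `n_neg`, and a
#'   `curve` data frame (threshold, sensitivity, specificity, fpr).
#' @export
roc_analysis <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    ith_parameter_error("scores and labels lengths differ")
  if (any(!labels %in% c(0L, 1L)))
    ith_parameter_error("labels must be 0/1")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0 || n_neg == 0)
    ith_degenerate_labels_error("both classes must be present")

  r <- rank(scores)   # midranks: ties earn 0.5 credit
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  thr <- sort(unique(scores))
  sens <- vapply(thr, function(t) mean(scores[labels == 1L] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[labels == 0L] < t), numeric(1))
  j <- sens + spec - 1
  best <- order(-j, -spec, -thr)[1]
  structure(
    list(auc = auc, sensitivity = sens[best], specificity = spec[best],
         threshold = thr[best], youden_j = j[best],
         n_pos = n_pos, n_neg = n_neg,
         curve = data.frame(threshold = thr, sensitivity = sens,
                            specificity = spec, fpr = 1 - spec)),
    class = "roc_summary")
}

#' @exportS3Method base::print
print.roc_summary <- function(x, ...) {
  cat(sprintf("roc_summary: AUC %.3f, sens %.3f / spec %.3f at threshold %.4g (%d pos / %d neg)\n",
              x$auc, x$sensitivity, x$specificity, x$threshold,
              x$n_pos, x$n_neg))
  invisible(x)
}

#' Fit the combined ITH + age HER2 model
#'
#' Logistic regression of binary status on ITH and age (default), exposed
#' with coefficients and a nomogram point-scale export. If the logistic
#' fit separates (fitted probabilities numerically 0/1), a
#' ridge-penalized fit takes over with a logged note. A boosted-trees
#' variant (depth <= 3, fixed seed, single thread) is available for
#' nonlinear screening.
#'
#' @param train Data frame with columns `HER2` (0/1), `ITH`, `age`.
#' @param algorithm "logistic" (default) or "boosted_trees".
#' @param seed Integer seed (restarts / tree subsampling).
#' @return An object of class `ith_her2_model` with a [predict()] method
#'   returning positive-class probabilities.
#' @export
fit_combined_model <- function(train, algorithm = c("logistic", "boosted_trees"),
                               seed = 1L) {
  algorithm <- match.arg(algorithm)
  need <- c("HER2", "ITH", "age")
  miss <- setdiff(need, names(train))
  if (length(miss))
    ith_usage_error(paste("missing column(s):", paste(miss, collapse = ", ")))
  y <- as.integer(train$HER2)
  if (length(unique(y)) < 2)
    ith_degenerate_labels_error("training data must contain both classes")

  if (algorithm == "logistic") {
    separated <- FALSE
    fit <- withCallingHandlers(
      glm(HER2 ~ ITH + age, data = train, family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          separated <<- TRUE
        invokeRestart("muffleWarning")
      })
    ridge <- FALSE
    if (separated) {
      message("logistic fit separated; falling back to ridge-penalized fit")
      X <- as.matrix(train[, c("ITH", "age")])
      rfit <- tryCatch(
        suppressWarnings(glmnet::glmnet(X, y, family = "binomial",
                                        alpha = 0, lambda = 1e-2,
                                        standardize = TRUE)),
        error = function(e) NULL)   # e.g. a class with < 2 observations
      if (!is.null(rfit)) {
        cf <- as.numeric(coef(rfit))
        names(cf) <- c("(Intercept)", "ITH", "age")
        fit <- rfit
        ridge <- TRUE
        coefs <- cf
      } else {
        message("ridge fallback unavailable; keeping the unpenalized fit")
        coefs <- coef(fit)
        coefs[is.na(coefs)] <- 0
      }
    } else {
      coefs <- coef(fit)
      coefs[is.na(coefs)] <- 0   # rank-deficient (e.g. constant) predictor
    }
    out <- list(algorithm = "logistic", fit = fit, coefficients = coefs,
                ridge = ridge, seed = as.integer(seed))
  } else {
    if (!requireNamespace("xgboost", quietly = TRUE))
      ith_usage_error("the boosted_trees variant requires the xgboost package")
    set.seed(seed)
    X <- as.matrix(train[, c("ITH", "age")])
    dtrain <- xgboost::xgb.DMatrix(data = X, label = y)
    fit <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = 3,
                    eta = 0.1, nthread = 1, seed = seed),
      data = dtrain, nrounds = 50, verbose = 0)
    out <- list(algorithm = "boosted_trees", fit = fit,
                coefficients = NULL, ridge = FALSE, seed = as.integer(seed))
  }
  class(out) <- "ith_her2_model"
  out
}

#' @param object An `ith_her2_model`.
#' @param newdata Data frame with columns `ITH` and `age`.
#' @param ... Unused.
#' @return Numeric vector of positive-class probabilities.
#' @rdname fit_combined_model
#' @export
predict.ith_her2_model <- function(object, newdata, ...) {
  if (object$algorithm == "logistic") {
    if (object$ridge) {
      X <- as.matrix(newdata[, c("ITH", "age")])
      as.numeric(predict(object$fit, newx = X, type = "response"))
    } else {
      as.numeric(predict(object$fit, newdata = newdata, type = "response"))
    }
  } else {
    X <- as.matrix(newdata[, c("ITH", "age")])
    as.numeric(predict(object$fit, X))
  }
}

#' Nomogram point scales for a logistic combined model
#'
#' Standard point-scale construction: each predictor's contribution
#' `beta_j * (x - min_j)` is rescaled so the predictor with the largest
#' score range spans 0-100 points; total points map to predicted
#' probability via the linear predictor.
#'
#' @param model A logistic `ith_her2_model`.
#' @param ith_range,age_range Predictor ranges displayed on the scales.
#' @return List with `points` (data frame: predictor, value, points) and
#'   `points_per_unit`, `intercept`.
#' @export
nomogram_table <- function(model, ith_range = c(0, 1), age_range = c(25, 80)) {
  stopifnot(inherits(model, "ith_her2_model"))
  if (model$algorithm != "logistic")
    ith_usage_error("nomogram export requires the logistic model")
  cf <- model$coefficients
  ranges <- list(ITH = ith_range, age = age_range)
  span <- vapply(names(ranges), function(p)
    abs(cf[[p]]) * diff(ranges[[p]]), numeric(1))
  scale_pts <- 100 / max(span)
  tabs <- lapply(names(ranges), function(p) {
    v <- seq(ranges[[p]][1], ranges[[p]][2], length.out = 11)
    base <- if (cf[[p]] >= 0) ranges[[p]][1] else ranges[[p]][2]
    data.frame(predictor = p, value = v,
               points = scale_pts * cf[[p]] * (v - base),
               stringsAsFactors = FALSE)
  })
  pts <- do.call(rbind, tabs)
  list(points = pts,
       points_per_unit = c(ITH = unname(scale_pts * abs(cf[["ITH"]])),
                           age = unname(scale_pts * abs(cf[["age"]]))),
       intercept = unname(cf[["(Intercept)"]]))
}

#' Molecular subtype from IHC markers
#'
#' Hormone-receptor positive (ER+ and/or PR+) tumors are Luminal A when
#' HER2- with low Ki-67, Luminal B when HER2- with high Ki-67 or when
#' HER2+; hormone-receptor negative tumors are HER2-enriched when HER2+
#' and Triple-negative when HER2-.
#'
#' @param er,pr,her2 0/1 vectors.
#' @param ki67 Character vector, "low" (< 20\%) or "high" (>= 20\%).
#' @return Character vector of subtypes.
#' @export
classify_subtype <- function(er, pr, her2, ki67) {
  er <- as.integer(er); pr <- as.integer(pr); her2 <- as.integer(her2)
  ki67 <- tolower(as.character(ki67))
  if (!all(ki67 %in% c("low", "high")))
    ith_parameter_error("ki67 must be 'low' or 'high'")
  n <- max(length(er), length(pr), length(her2), length(ki67))
  er <- rep_len(er, n); pr <- rep_len(pr, n)
  her2 <- rep_len(her2, n); ki67 <- rep_len(ki67, n)
  hr <- er == 1L | pr == 1L
  out <- character(n)
  out[hr & her2 == 0L & ki67 == "low"]  <- "Luminal A"
  out[hr & her2 == 0L & ki67 == "high"] <- "Luminal B"
  out[hr & her2 == 1L]                  <- "Luminal B"
  out[!hr & her2 == 1L]                 <- "HER2-enriched"
  out[!hr & her2 == 0L]                 <- "Triple-negative"
  out
}

roc_or_skip <- function(scores, labels, what) {
  if (length(unique(labels)) < 2 || length(labels) < 3) {
    list(skipped = TRUE,
         reason = sprintf("%s: fewer than 2 classes or 3 cases", what))
  } else {
    roc_analysis(scores, labels)
  }
}

#' Run the full association study on a scored cohort
#'
#' Computes (a) the overall Pearson (point-biserial) ITH-HER2 correlation
#' and ROC of ITH; (b) ROC of the combined ITH + age model fitted on the
#' whole cohort; (c) per-site ROC of ITH; (d) age-subgroup ROC (<= cut vs
#' > cut); (e) the combined model trained on `train_site` and evaluated
#' on the other site (external validation). Analyses whose stratum lacks
#' both classes are skipped with a recorded reason.
#'
#' @param cohort Data frame with columns `patient_id`, `site`, `age`,
#'   `ITH`, `HER2` (optionally `ER`, `PR`, `Ki67` for subtype counts).
#' @param age_cut Age subgroup cut in years (default 40).
#' @param model_algorithm Passed to [fit_combined_model()].
#' @param train_site Site used for training in the external-validation
#'   split; defaults to the first site in sorted order.
#' @param seed Seed forwarded to model fitting.
#' @return A list of class `ith_study_report`.
#' @export
run_study <- function(cohort, age_cut = 40, model_algorithm = "logistic",
                      train_site = NULL, seed = 1L) {
  need <- c("patient_id", "site", "age", "ITH", "HER2")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    ith_usage_error(paste("cohort is missing column(s):",
                          paste(miss, collapse = ", ")))
  if (any(is.na(cohort$ITH)) || any(is.na(cohort$HER2)))
    ith_usage_error("ITH and HER2 must not contain missing values")
  y <- as.integer(cohort$HER2)

  overall <- list(
    n = nrow(cohort),
    pearson = pearson_r(cohort$ITH, y),
    roc_ith = roc_or_skip(cohort$ITH, y, "overall ITH ROC"))

  combined <- roc_or_skip(rep(0, 0), integer(0), "combined model")
  model <- NULL
  if (length(unique(y)) == 2) {
    model <- fit_combined_model(cohort, algorithm = model_algorithm, seed = seed)
    combined <- roc_or_skip(predict(model, cohort), y, "combined model ROC")
  }

  sites <- sort(unique(as.character(cohort$site)))
  per_site <- lapply(sites, function(s) {
    sel <- cohort$site == s
    res <- roc_or_skip(cohort$ITH[sel], y[sel], sprintf("site %s ROC", s))
    res$n <- sum(sel)
    res
  })
  names(per_site) <- sites

  groups <- list(young = cohort$age <= age_cut, old = cohort$age > age_cut)
  names(groups) <- c(sprintf("age_le_%g", age_cut), sprintf("age_gt_%g", age_cut))
  age_subgroups <- lapply(names(groups), function(g) {
    sel <- groups[[g]]
    res <- roc_or_skip(cohort$ITH[sel], y[sel], sprintf("%s ROC", g))
    res$n <- sum(sel)
    res
  })
  names(age_subgroups) <- names(groups)

  if (is.null(train_site)) train_site <- sites[1]
  external <- list(skipped = TRUE, reason = "fewer than two sites")
  if (length(sites) >= 2 && train_site %in% sites) {
    valid_sites <- setdiff(sites, train_site)
    tr <- cohort[cohort$site == train_site, ]
    va <- cohort[cohort$site %in% valid_sites, ]
    if (length(unique(tr$HER2)) == 2 && length(unique(va$HER2)) == 2) {
      m <- fit_combined_model(tr, algorithm = model_algorithm, seed = seed)
      rocv <- roc_analysis(predict(m, va), as.integer(va$HER2))
      external <- list(skipped = FALSE, train_site = train_site,
                       validation_sites = valid_sites,
                       n_train = nrow(tr), n_validation = nrow(va),
                       roc = rocv, model = m)
    } else {
      external <- list(skipped = TRUE,
                       reason = "a split side has a single class")
    }
  }

  subtype_counts <- NULL
  if (all(c("ER", "PR", "Ki67") %in% names(cohort))) {
    st <- classify_subtype(cohort$ER, cohort$PR, cohort$HER2, cohort$Ki67)
    subtype_counts <- table(factor(st, levels = c(
      "Luminal A", "Luminal B", "HER2-enriched", "Triple-negative")))
    median_ith_by_subtype <- tapply(cohort$ITH, st, median)
  } else {
    median_ith_by_subtype <- NULL
  }

  structure(
    list(overall = overall, combined = combined, model = model,
         per_site = per_site, age_subgroups = age_subgroups,
         external_validation = external,
         subtype_counts = subtype_counts,
         median_ith_by_subtype = median_ith_by_subtype,
         median_ith = median(cohort$ITH),
         config = list(age_cut = age_cut, model_algorithm = model_algorithm,
                       train_site = train_site, seed = as.integer(seed))),
    class = "ith_study_report")
}

#' @exportS3Method base::print
print.ith_study_report <- function(x, ...) {
  cat(sprintf("ith_study_report: n = %d, Pearson r = %.4f (p = %.3g)\n",
              x$overall$n, x$overall$pearson$r, x$overall$pearson$p))
  if (is.null(x$overall$roc_ith$skipped))
    cat(sprintf("  ITH alone:    AUC %.3f (sens %.3f, spec %.3f)\n",
                x$overall$roc_ith$auc, x$overall$roc_ith$sensitivity,
                x$overall$roc_ith$specificity))
  if (is.null(x$combined$skipped))
    cat(sprintf("  ITH + age:    AUC %.3f (sens %.3f, spec %.3f)\n",
                x$combined$auc, x$combined$sensitivity,
                x$combined$specificity))
  for (s in names(x$per_site)) {
    r <- x$per_site[[s]]
    if (is.null(r$skipped))
      cat(sprintf("  site %-10s AUC %.3f (n = %d)\n", paste0(s, ":"), r$auc, r$n))
  }
  if (!x$external_validation$skipped)
    cat(sprintf("  external val: AUC %.3f (train %s, n = %d -> validate n = %d)\n",
                x$external_validation$roc$auc, x$external_validation$train_site,
                x$external_validation$n_train, x$external_validation$n_validation))
  invisible(x)
}
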