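test_that("pearson_r matches the closed-form product-moment coefficient", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6))$r, 1)
  expect_equal(pearson_r(c(1, 2, 3), c(6, 4, 2))$r, -1)

  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 5)
  # closed form: cov / (sd_x sd_y), population normalization cancels
  cv <- sum((x - mean(x)) * (y - mean(y)))
  r_hand <- cv / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  got <- pearson_r(x, y)
  expect_equal(got$r, r_hand, tolerance = 1e-12)
  expect_equal(r_hand, 0.8315218, tolerance = 1e-6)
  expect_true(got$p > 0 && got$p < 1)

  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)),
               class = "ith_degenerate_input_error")
  expect_error(pearson_r(1:3, 1:4), class = "ith_parameter_error")
  expect_error(pearson_r(1:2, 2:3), class = "ith_parameter_error")
})

test_that("pearson_r is invariant to positive affine transforms", {
  set.seed(2)
  x <- rnorm(40); y <- 0.6 * x + rnorm(40)
  base <- pearson_r(x, y)$r
  expect_equal(pearson_r(3.2 * x + 7, y)$r, base, tolerance = 1e-12)
  expect_equal(pearson_r(x, 0.01 * y - 5)$r, base, tolerance = 1e-12)
})

test_that("roc_analysis reproduces hand-computed AUCs", {
  perfect <- roc_analysis(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)

  ties <- roc_analysis(rep(0.4, 10), rep(c(0, 1), 5))
  expect_equal(ties$auc, 0.5)

  mixed <- roc_analysis(c(0.8, 0.3, 0.5, 0.1), c(1, 1, 0, 0))
  expect_equal(mixed$auc, 0.75)   # 3 of 4 pos-neg pairs concordant

  expect_error(roc_analysis(1:4, c(1, 1, 1, 1)),
               class = "ith_degenerate_labels_error")
  expect_error(roc_analysis(1:4, c(0, 1, 2, 1)), class = "ith_parameter_error")
})

test_that("AUC equals exhaustive pairwise concordance on random cohorts", {
  set.seed(77)
  for (i in 1:15) {
    n <- sample(10:120, 1)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    scores <- round(rnorm(n), sample(0:2, 1))   # rounding induces ties
    expect_equal(roc_analysis(scores, labels)$auc, oracle_auc(scores, labels))
  }
})

test_that("the operating point maximizes Youden's J over all thresholds", {
  set.seed(13)
  for (i in 1:10) {
    n <- 60
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    scores <- round(rnorm(n), 1)
    res <- roc_analysis(scores, labels)
    for (t in c(-Inf, sort(unique(scores)), Inf)) {
      j <- mean(scores[labels == 1] >= t) + mean(scores[labels == 0] < t) - 1
      expect_lte(j, res$youden_j + 1e-12)
    }
    expect_equal(res$sensitivity + res$specificity - 1, res$youden_j)
  }
})

test_that("roc_analysis agrees with pROC on a tied cohort", {
  skip_if_not_installed("pROC")
  set.seed(55)
  scores <- round(rnorm(80), 1)
  labels <- rbinom(80, 1, 0.45)
  ours <- roc_analysis(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("the combined model handles separable and degenerate data", {
  set.seed(6)
  train <- data.frame(ITH = runif(80), age = rnorm(80, 48, 9))
  train$HER2 <- as.integer(train$ITH > 0.5)
  fit <- suppressMessages(fit_combined_model(train))
  expect_equal(roc_analysis(predict(fit, train), train$HER2)$auc, 1)

  const_age <- train; const_age$age <- 50
  fit2 <- suppressMessages(fit_combined_model(const_age))
  expect_lt(abs(fit2$coefficients[["age"]]), 1e-8)

  one_class <- train; one_class$HER2 <- 1L
  expect_error(fit_combined_model(one_class),
               class = "ith_degenerate_labels_error")
})

test_that("the logistic model recovers generating coefficients", {
  set.seed(29)
  n <- 2000
  ith <- runif(n); age <- rnorm(n, 48, 9.6)
  p <- plogis(-3.9 + 5 * ith + 0.03 * age)
  dat <- data.frame(ITH = ith, age = age, HER2 = rbinom(n, 1, p))
  fit <- fit_combined_model(dat)
  expect_lt(abs(fit$coefficients[["ITH"]] - 5) / 5, 0.15)
})

test_that("boosted-trees variant is deterministic and discriminative", {
  skip_if_not_installed("xgboost")
  set.seed(17)
  n <- 300
  dat <- data.frame(ITH = runif(n), age = rnorm(n, 48, 9))
  dat$HER2 <- rbinom(n, 1, plogis(-2 + 4 * dat$ITH))
  f1 <- fit_combined_model(dat, algorithm = "boosted_trees", seed = 3)
  f2 <- fit_combined_model(dat, algorithm = "boosted_trees", seed = 3)
  expect_identical(predict(f1, dat), predict(f2, dat))
  expect_gt(roc_analysis(predict(f1, dat), dat$HER2)$auc, 0.6)
})

test_that("nomogram export scales the dominant predictor to 100 points", {
  set.seed(40)
  n <- 400
  dat <- data.frame(ITH = runif(n), age = rnorm(n, 48, 9.6))
  dat$HER2 <- rbinom(n, 1, plogis(-4 + 5 * dat$ITH + 0.03 * dat$age))
  fit <- fit_combined_model(dat)
  nomo <- nomogram_table(fit)
  expect_setequal(unique(nomo$points$predictor), c("ITH", "age"))
  expect_equal(max(nomo$points$points), 100)
  expect_true(all(nomo$points$points >= 0))
})

test_that("subtype classification follows the IHC rules and partitions", {
  expect_identical(classify_subtype(1, 1, 0, "low"), "Luminal A")
  expect_identical(classify_subtype(1, 0, 0, "high"), "Luminal B")
  expect_identical(classify_subtype(0, 1, 1, "low"), "Luminal B")
  expect_identical(classify_subtype(0, 0, 1, "high"), "HER2-enriched")
  expect_identical(classify_subtype(0, 0, 0, "high"), "Triple-negative")

  grid <- expand.grid(er = 0:1, pr = 0:1, her2 = 0:1,
                      ki67 = c("low", "high"), stringsAsFactors = FALSE)
  st <- classify_subtype(grid$er, grid$pr, grid$her2, grid$ki67)
  expect_true(all(st %in% c("Luminal A", "Luminal B", "HER2-enriched",
                            "Triple-negative")))
  expect_identical(length(st), nrow(grid))
  expect_error(classify_subtype(1, 1, 0, "mid"), class = "ith_parameter_error")
})

test_that("run_study assembles all sections and skips degenerate strata", {
  set.seed(61)
  n <- 240
  cohort <- data.frame(
    patient_id = sprintf("P%03d", 1:n),
    site = rep(c("hospital1", "hospital2"), each = n / 2),
    age = round(rnorm(n, 48, 9.6), 1),
    ITH = runif(n))
  cohort$HER2 <- rbinom(n, 1, plogis(-3 + 5 * cohort$ITH))
  cohort$ER <- rbinom(n, 1, 0.64)
  cohort$PR <- rbinom(n, 1, 0.67)
  cohort$Ki67 <- sample(c("low", "high"), n, TRUE, prob = c(0.14, 0.86))

  rep_ <- run_study(cohort)
  expect_s3_class(rep_, "ith_study_report")
  expect_named(rep_$per_site, c("hospital1", "hospital2"))
  expect_named(rep_$age_subgroups, c("age_le_40", "age_gt_40"))
  expect_false(rep_$external_validation$skipped)
  expect_identical(rep_$external_validation$train_site, "hospital1")
  expect_identical(rep_$external_validation$n_train, as.integer(n / 2))
  expect_equal(sum(rep_$subtype_counts), n)
  expect_gt(rep_$overall$roc_ith$auc, 0.6)
  expect_gt(rep_$overall$pearson$r, 0)

  # custom age cut changes the subgroup split
  rep50 <- run_study(cohort, age_cut = 50)
  expect_named(rep50$age_subgroups, c("age_le_50", "age_gt_50"))
  expect_identical(rep50$age_subgroups$age_le_50$n, sum(cohort$age <= 50))

  # one site only: external validation skipped with a reason
  solo <- cohort[cohort$site == "hospital1", ]
  rep1 <- run_study(solo)
  expect_named(rep1$per_site, "hospital1")
  expect_true(rep1$external_validation$skipped)
  expect_match(rep1$external_validation$reason, "site")

  # a single-class site is skipped, the rest still runs
  broken <- cohort
  broken$HER2[broken$site == "hospital2"] <- 1L
  rep2 <- run_study(broken)
  expect_true(isTRUE(rep2$per_site$hospital2$skipped))
  expect_true(rep2$external_validation$skipped)
  expect_false(isTRUE(rep2$per_site$hospital1$skipped))

  expect_error(run_study(cohort[, setdiff(names(cohort), "HER2")]),
               "HER2", class = "ith_usage_error")
})
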