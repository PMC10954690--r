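test_that("participant aggregation is the excerpt mean with pairwise NA handling", {
  fx <- data.frame(participant_id = rep("P1", 8), excerpt_id = 1:8,
                   version = "manual",
                   m1 = rep(2.5, 8), m2 = as.numeric(1:8))
  class(fx) <- c("marker_table", "data.frame")
  fp <- aggregate_participants(fx)
  expect_equal(nrow(fp), 1)
  expect_equal(fp$m1, 2.5)
  expect_equal(fp$m2, 4.5)
  fx$m2[3] <- NA
  fp2 <- suppressMessages(aggregate_participants(fx))
  expect_equal(fp2$m2, mean(c(1, 2, 4:8)))
  fx$m1 <- NA
  fp3 <- suppressMessages(aggregate_participants(fx))
  expect_true(is.na(fp3$m1))
})

test_that("the BH step-up worked example rejects all three p-values", {
  # thresholds at m = 3, alpha = 0.05: 0.0167, 0.0333, 0.05
  expect_identical(bh_significant(c(0.01, 0.02, 0.04), 0.05),
                   c(TRUE, TRUE, TRUE))
  expect_identical(bh_significant(c(0.01, 0.2, 0.9), 0.05),
                   c(TRUE, FALSE, FALSE))
})

test_that("BH flags equal the literal step-up rule on random p-vectors", {
  set.seed(71)
  for (i in 1:200) {
    m <- sample(1:20, 1)
    p <- round(runif(m), 3)
    alpha <- sample(c(0.01, 0.05, 0.1), 1)
    expect_identical(bh_significant(p, alpha), oracle_bh_reject(p, alpha),
                     label = paste(c(alpha, p), collapse = " "))
  }
})

test_that("correlations recover a planted monotone marker and skip constants", {
  f <- data.frame(participant_id = sprintf("P%d", 1:20),
                  version = "manual",
                  planted = 1:20, noise = rnorm(20), flat = 1)
  out <- data.frame(participant_id = sprintf("P%d", 1:20),
                    spq = (1:20) * 2, pdi = rnorm(20))
  cr <- suppressMessages(correlate_bh(f, out))
  row <- cr[cr$marker == "planted" & cr$outcome == "spq", ]
  expect_equal(row$rho, 1)
  expect_true(row$sig_05)
  expect_true(is.na(cr$rho[cr$marker == "flat" & cr$outcome == "spq"]))
})

test_that("Mann-Whitney results match exhaustive enumeration for separated groups", {
  f <- data.frame(participant_id = sprintf("P%d", 1:6), version = "manual",
                  m = c(1, 2, 3, 4, 5, 6))
  g <- data.frame(participant_id = sprintf("P%d", 1:6),
                  group = rep(c("low", "high"), c(3, 3)))
  res <- group_test(f, g)
  # first sorted level is "high" (values 4,5,6): rank-sum statistic W = 9
  expect_equal(res$W, 9)
  expect_equal(res$p, oracle_mw_exact_p(c(4, 5, 6), c(1, 2, 3)),
               tolerance = 1e-12)
  expect_equal(res$p, 0.1, tolerance = 1e-12)
  # identical groups are far from significance
  f2 <- f
  f2$m <- rep(c(5, 6, 7), 2)
  res2 <- group_test(f2, g)
  expect_gt(res2$p, 0.5)
})

test_that("the group test detects a one-SD shift most of the time", {
  reps <- 50
  hit <- logical(reps)
  for (i in seq_len(reps)) {
    set.seed(7200 + i)
    f <- data.frame(participant_id = sprintf("P%d", 1:100),
                    version = "manual",
                    m = c(rnorm(50), rnorm(50, mean = 1)))
    g <- data.frame(participant_id = sprintf("P%d", 1:100),
                    group = rep(c("low", "high"), each = 50))
    hit[i] <- group_test(f, g)$p < 0.05
  }
  expect_gte(mean(hit), 0.9)
})

test_that("linear ladder matches closed-form least squares on a hand case", {
  # y = 3 + 2x on 4 points with one perturbed response
  f <- data.frame(participant_id = sprintf("P%d", 1:4),
                  version = "manual", x = c(0, 1, 2, 3))
  f <- rbind(f, transform(f, version = "automated"))
  out <- data.frame(participant_id = sprintf("P%d", 1:4),
                    spq = c(3, 5, 8, 9), pdi = 1,
                    age = 30, gender = "female", education = 3,
                    device = "computer")
  lad <- suppressMessages(fit_linear_ladder(f, out, "spq"))
  xs <- c(0, 1, 2, 3); ys <- c(3, 5, 8, 9)
  beta <- sum((xs - mean(xs)) * (ys - mean(ys))) / sum((xs - mean(xs))^2)
  r2 <- beta^2 * var(xs) / var(ys)
  row <- lad[lad$model == "markers_manual", ]
  expect_equal(row$r2, r2, tolerance = 1e-12)
  expect_equal(row$rmse,
               sqrt(mean((ys - mean(ys) - beta * (xs - mean(xs)))^2)),
               tolerance = 1e-12)
})

test_that("a noiseless linear outcome gives R2 = 1 and RMSE = 0", {
  f <- data.frame(participant_id = sprintf("P%d", 1:10),
                  version = "manual", x = 1:10)
  f <- rbind(f, transform(f, version = "automated"))
  out <- data.frame(participant_id = sprintf("P%d", 1:10),
                    spq = 2 * (1:10) + 7, pdi = 1, age = 30,
                    gender = "female", education = 3, device = "computer")
  # lm flags the exact fit as "essentially perfect"; that is the point here
  lad <- suppressWarnings(suppressMessages(fit_linear_ladder(f, out, "spq")))
  row <- lad[lad$model == "markers_auto", ]
  expect_equal(row$r2, 1)
  expect_equal(row$rmse, 0, tolerance = 1e-9)
})

test_that("in-sample fit never degrades when regressors are added", {
  co <- gen_cohort(tiny_config(n_participants = 30, seed = 73))
  fp <- suppressMessages(aggregate_participants(extract_corpus(co)))
  lad <- suppressMessages(fit_linear_ladder(fp, co$outcomes, "spq"))
  r2 <- setNames(lad$r2, lad$model)
  expect_gte(r2[["demographics+markers_auto"]], r2[["demographics"]])
  expect_gte(r2[["demographics+markers_auto"]], r2[["markers_auto"]])
  expect_gte(r2[["demographics+markers_manual"]], r2[["markers_manual"]])
  co2 <- gen_cohort(tiny_config(n_participants = 80, two_group = TRUE,
                                seed = 74))
  fp2 <- suppressMessages(aggregate_participants(extract_corpus(co2)))
  lad2 <- suppressWarnings(suppressMessages(
    fit_logistic_ladder(fp2, co2$outcomes)))
  ll <- setNames(lad2$loglik, lad2$model)
  expect_gte(ll[["demographics+markers_auto"]] + 1e-6,
             ll[["demographics"]])
  expect_gte(ll[["demographics+markers_manual"]] + 1e-6,
             ll[["markers_manual"]])
})

test_that("intercept-only logistic metrics collapse to their null identities", {
  y <- rep(c(0, 1), c(12, 8))
  m <- logistic_metrics(rep(mean(y), 20), y)
  expect_equal(m[["nagelkerke_r2"]], 0, tolerance = 1e-12)
  expect_equal(m[["tjur_r2"]], 0, tolerance = 1e-12)
  expect_equal(m[["cox_snell_r2"]], 0, tolerance = 1e-12)
  expect_equal(m[["auc"]], 0.5)
  # perfect probabilities: Tjur and accuracy are 1
  m2 <- logistic_metrics(y, y)
  expect_equal(m2[["tjur_r2"]], 1)
  expect_equal(m2[["accuracy"]], 1)
})

test_that("pseudo-R2 on a balanced 2x2 table matches hand-computed likelihoods", {
  # x = 0: 6 of 8 in class 0; x = 1: 6 of 8 in class 1
  x <- rep(c(0, 1), each = 8)
  y <- c(rep(0, 6), rep(1, 2), rep(0, 2), rep(1, 6))
  fit <- glm(y ~ x, family = binomial())
  n <- 16
  # saturated-by-group MLE: p = 0.25 and 0.75
  ll1 <- 12 * log(0.75) + 4 * log(0.25)
  ll0 <- 16 * log(0.5)
  cs <- 1 - exp((2 / n) * (ll0 - ll1))
  nag <- cs / (1 - exp((2 / n) * ll0))
  tjur <- (2 * 0.25 + 6 * 0.75) / 8 - (6 * 0.25 + 2 * 0.75) / 8
  m <- logistic_metrics(fitted(fit), y)
  expect_equal(m[["cox_snell_r2"]], cs, tolerance = 1e-6)
  expect_equal(m[["nagelkerke_r2"]], nag, tolerance = 1e-6)
  expect_equal(m[["tjur_r2"]], tjur, tolerance = 1e-6)
})

test_that("collinear demographics raise a rank-deficiency error", {
  f <- data.frame(participant_id = sprintf("P%d", 1:12),
                  version = "manual", x = rnorm(12))
  f <- rbind(f, transform(f, version = "automated"))
  out <- data.frame(participant_id = sprintf("P%d", 1:12),
                    spq = rnorm(12), pdi = 1,
                    age = 1:12, gender = "female",
                    education = 1:12,  # exact copy of age
                    device = "computer")
  expect_error(suppressMessages(fit_linear_ladder(f, out, "spq")),
               "collinear")
})

test_that("report writes deterministic CSV tables", {
  dir <- withr::local_tempdir()
  res <- list(correlations = data.frame(marker = "a", rho = 0.5),
              linear_ladder = data.frame(model = "demographics", r2 = 0.1))
  report(res, dir)
  expect_true(file.exists(file.path(dir, "correlations.csv")))
  first <- readLines(file.path(dir, "linear_ladder.csv"))
  report(res, dir)
  expect_identical(readLines(file.path(dir, "linear_ladder.csv")), first)
})
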