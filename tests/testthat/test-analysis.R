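test_that("choose_imputation_method follows the distribution rules", {
  expect_equal(choose_imputation_method(c(0, 1, 1, 0, NA)), "PMM")  # binary
  expect_equal(choose_imputation_method(factor(c("a", "b"))), "PMM")
  set.seed(1)
  expect_equal(choose_imputation_method(stats::rnorm(500)), "MODEL_PREDICTION")
  expect_equal(choose_imputation_method(stats::rlnorm(500, sdlog = 1)), "PMM")
  expect_equal(choose_imputation_method(sample(0:10, 200, TRUE)), "PMM")
  expect_error(choose_imputation_method(c(NA, NA)), "no observed")
})

test_that("impute is deterministic and leaves complete panels untouched", {
  set.seed(2)
  panel <- data.table::data.table(participant_id = sprintf("P%02d", 1:40),
                                  x = stats::rnorm(40), y = stats::rnorm(40),
                                  time_years = stats::runif(40, 1, 5),
                                  status = rbinom(40, 1, 0.5))
  # no missing cells: m identical copies
  imp0 <- impute(panel, m = 3, seed = 5)
  expect_identical(as.data.frame(imp0$panels[[1]]),
                   as.data.frame(imp0$panels[[3]]))
  expect_identical(as.data.frame(imp0$panels[[1]])[, names(panel)],
                   as.data.frame(panel))
  # same seed twice: identical results
  panel$x[1:8] <- NA
  a <- impute(panel, m = 3, seed = 9)
  b <- impute(panel, m = 3, seed = 9)
  expect_identical(lapply(a$panels, as.data.frame),
                   lapply(b$panels, as.data.frame))
  # observed cells identical across panels; only missing cells vary
  obs <- !is.na(panel$x)
  expect_identical(a$panels[[1]]$x[obs], panel$x[obs])
  expect_identical(a$panels[[2]]$x[obs], panel$x[obs])
  expect_error(impute(panel, m = 3), "seed")
  expect_error(impute(data.table::data.table(participant_id = "a", z = NA_real_),
                      m = 2, seed = 1), "entirely missing")
})

test_that("imputation recovers the mean of MCAR-missing data (simulation)", {
  # scaled-down version of the calibration check: pooled mean of an MCAR
  # variable should land within its Rubin CI at roughly nominal rate
  set.seed(31)
  reps <- 60; n <- 150
  covered <- logical(reps)
  for (r in seq_len(reps)) {
    x <- stats::rnorm(n, 10, 2)
    z <- 0.6 * x + stats::rnorm(n)
    panel <- data.table::data.table(participant_id = as.character(1:n),
                                    x = x, z = z)
    panel$x[stats::runif(n) < 0.2] <- NA
    imp <- impute(panel, m = 5, seed = r, maxit = 3)
    means <- vapply(imp$panels, function(p) mean(p$x), numeric(1))
    vars <- vapply(imp$panels, function(p) stats::var(p$x) / n, numeric(1))
    pooled <- rubin_pool(matrix(means, ncol = 1), matrix(vars, ncol = 1))
    ci <- pooled$estimate + c(-1, 1) * stats::qt(0.975, pooled$df) * pooled$se
    covered[r] <- ci[1] <= 10 && 10 <= ci[2]
  }
  expect_gte(mean(covered), 0.9)
})

test_that("fit_cox recovers planted effects and rejects degenerate input", {
  set.seed(13)
  n <- 3000
  x <- rbinom(n, 1, 0.5)
  t <- stats::rexp(n, 0.1 * exp(0.5 * x))
  cens <- stats::runif(n, 0, 15)
  d <- data.table::data.table(x = x, time_years = pmin(t, cens),
                              status = as.integer(t <= cens))
  f <- fit_cox(d, "x")
  expect_lt(abs(f$coef[["x"]] - 0.5), 0.1)
  # null covariate estimates near zero
  d$z <- stats::rnorm(n)
  f2 <- fit_cox(d, "z")
  expect_lt(abs(f2$coef[["z"]]), 0.08)
  # duplicated covariate column: collinearity error naming the column
  d$x2 <- d$x
  expect_error(fit_cox(d, c("x", "x2")), "x2")
})

test_that("rubin_pool reproduces the hand-worked example", {
  out <- rubin_pool(matrix(c(0.5, 0.7), ncol = 1, dimnames = list(NULL, "b")),
                    matrix(c(0.01, 0.01), ncol = 1))
  expect_equal(out$estimate, 0.6)
  expect_equal(out$se^2, 0.04)
  expect_equal(out$se, 0.2)
  # identical fits: pooled SE equals the within-fit SE
  same <- rubin_pool(matrix(c(0.5, 0.5, 0.5), ncol = 1),
                     matrix(rep(0.01, 3), ncol = 1))
  expect_equal(same$se, 0.1)
  expect_error(rubin_pool(matrix(1, 1, 1), matrix(1, 1, 1)), "m >= 2")
})

test_that("rubin_pool matches an independent textbook implementation", {
  set.seed(44)
  for (r in 1:5) {
    m <- sample(3:8, 1); p <- 3
    Q <- matrix(stats::rnorm(m * p), m, p,
                dimnames = list(NULL, letters[1:p]))
    U <- matrix(stats::runif(m * p, 0.01, 0.2), m, p)
    got <- rubin_pool(Q, U)
    for (j in 1:p) {
      qbar <- mean(Q[, j]); wbar <- mean(U[, j]); B <- stats::var(Q[, j])
      Tt <- wbar + (1 + 1 / m) * B
      rr <- (1 + 1 / m) * B / wbar
      df <- (m - 1) * (1 + 1 / rr)^2
      expect_equal(got$estimate[j], qbar)
      expect_equal(got$se[j], sqrt(Tt))
      expect_equal(got$df[j], df)
      expect_equal(got$p[j], 2 * stats::pt(-abs(qbar / sqrt(Tt)), df))
    }
  }
})

mk_complete_imp <- function(panel, m = 3) {
  impute(panel, m = m, seed = 1)
}

test_that("pooled stepwise selection keeps forced variables and finds signal", {
  set.seed(55)
  n <- 1500
  d <- data.table::data.table(
    participant_id = as.character(1:n),
    age = stats::rnorm(n, 60, 7), sex = rbinom(n, 1, 0.5),
    signal = stats::rnorm(n), null1 = stats::rnorm(n))
  lp <- 0.02 * (d$age - 60) + 0.2 * d$sex + log(1.8) * d$signal
  t <- stats::rexp(n, 0.05 * exp(lp))
  cens <- stats::runif(n, 2, 12)
  d[, `:=`(time_years = pmin(t, cens), status = as.integer(t <= cens))]
  imp <- mk_complete_imp(d)
  # empty candidate set: base model only
  base <- pooled_stepwise_select(imp, forced = c("age", "sex"),
                                 candidates = character())
  expect_equal(base$selected_vars, character(0))
  expect_setequal(base$table$term, c("age", "sex"))
  sel <- pooled_stepwise_select(imp, forced = c("age", "sex"),
                                candidates = c("signal", "null1"))
  expect_true("signal" %in% sel$selected_vars)
  expect_true(all(c("age", "sex") %in% sel$table$term))
  expect_equal(sel$selection_trace$action[1], "add")
  expect_equal(sel$selection_trace$var[1], "signal")
  # pooled HR of the signal is near the planted 1.8
  expect_lt(abs(sel$table[term == "signal", hr] - 1.8), 0.25)
  # trace replay: re-running is deterministic
  sel2 <- pooled_stepwise_select(imp, forced = c("age", "sex"),
                                 candidates = c("signal", "null1"))
  expect_identical(as.data.frame(sel$selection_trace),
                   as.data.frame(sel2$selection_trace))
})

test_that("train_validate_split partitions 2:1 deterministically", {
  sp <- train_validate_split(as.character(1:300), seed = 3)
  expect_equal(length(sp$train_ids), 200L)
  expect_equal(length(sp$valid_ids), 100L)
  expect_setequal(c(sp$train_ids, sp$valid_ids), as.character(1:300))
  expect_length(intersect(sp$train_ids, sp$valid_ids), 0L)
  expect_identical(sp, train_validate_split(as.character(1:300), seed = 3))
})

test_that("compute_risk_scores averages per-panel linear predictors", {
  set.seed(66)
  n <- 400
  d <- data.table::data.table(participant_id = as.character(1:n),
                              a = stats::rnorm(n), b = stats::rnorm(n))
  lp <- 0.8 * d$a - 0.5 * d$b
  t <- stats::rexp(n, 0.1 * exp(lp))
  d[, `:=`(time_years = pmin(t, 8), status = as.integer(t <= 8))]
  f1 <- fit_cox(d, c("a", "b"))
  vp <- d[1:50]
  # m = 1: score equals the single linear predictor
  s1 <- compute_risk_scores(list(f1), list(vp))
  oracle <- as.vector((as.matrix(vp[, .(a, b)]) -
                         matrix(f1$means, 50, 2, byrow = TRUE)) %*% f1$coef)
  expect_equal(s1$risk_score, oracle)
  # m = 2 averages the two panels' predictors
  f2 <- fit_cox(d[101:400], c("a", "b"))
  vp2 <- data.table::copy(vp)[, a := a + 0.1]
  s2 <- compute_risk_scores(list(f1, f2), list(vp, vp2))
  o2 <- as.vector((as.matrix(vp2[, .(a, b)]) -
                     matrix(f2$means, 50, 2, byrow = TRUE)) %*% f2$coef)
  expect_equal(s2$risk_score, (oracle + o2) / 2)
  # zero coefficients give constant scores
  f0 <- f1; f0$coef[] <- 0
  expect_equal(stats::var(compute_risk_scores(list(f0), list(vp))$risk_score), 0)
  expect_error(compute_risk_scores(list(f1), list(vp[, .(participant_id, a)])),
               "missing")
})

test_that("evaluate_auc is the Mann-Whitney concordance with DeLong CI", {
  # perfectly separating scores
  expect_equal(evaluate_auc(c(5, 6, 1, 2), c(1, 1, 0, 0))$auc, 1)
  # printed toy: cases {0.9, 0.6} vs controls {0.7, 0.1} -> 3/4
  toy <- evaluate_auc(c(0.9, 0.6, 0.7, 0.1), c(1, 1, 0, 0))
  expect_equal(toy$auc, 0.75)
  # ties count one half
  expect_equal(evaluate_auc(c(1, 1), c(1, 0))$auc, 0.5)
  # invariant under strictly increasing transforms
  set.seed(7)
  s <- stats::rnorm(200); y <- rbinom(200, 1, stats::plogis(s))
  expect_equal(evaluate_auc(exp(s), y)$auc, evaluate_auc(s, y)$auc)
  expect_equal(evaluate_auc(rank(s), y)$auc, evaluate_auc(s, y)$auc)
  # null scores: AUC near 0.5 at large n
  s2 <- stats::rnorm(4000); y2 <- rbinom(4000, 1, 0.4)
  expect_lt(abs(evaluate_auc(s2, y2)$auc - 0.5), 0.04)
  expect_error(evaluate_auc(s2, rep(1, 4000)), "both classes")
})

test_that("km_by_median splits at the median and detects group differences", {
  set.seed(17)
  n <- 1000
  score <- stats::rnorm(n)
  grp_hr <- ifelse(score > stats::median(score), 2, 1)
  t <- stats::rexp(n, 0.1 * grp_hr)
  tte <- data.table::data.table(participant_id = as.character(1:n),
                                time_years = pmin(t, 10),
                                status = as.integer(t <= 10))
  km <- km_by_median(score, tte)
  expect_equal(as.vector(sort(table(km$groups$risk_group))), c(n / 2, n / 2))
  expect_lt(km$logrank_p, 0.001)
  expect_error(km_by_median(rep(0, n), tte), "degenerate")
})
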