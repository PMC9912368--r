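# Landmark survival analysis: Cox fitting, pooled stepwise variable
# selection over imputed datasets, 2:1 train/validation risk prediction,
# AUC with DeLong confidence interval, median-split Kaplan-Meier curves.

#' Fit a Cox proportional hazards model on one (imputed) panel
#'
#' Partial-likelihood estimation with Efron tie handling, via
#' [survival::coxph()]. Covariates listed in `standardize` are z-scored;
#' the standardisation moments default to the fitting data's own (pass
#' `moments` to reuse training-set moments on validation data).
#' Non-convergence, separation (runaway coefficients) and collinearity
#' (aliased coefficients) raise errors naming the offending covariate.
#'
#' @param panel data with the covariates, follow-up time and status columns.
#' @param covariates character vector of covariate column names (numeric or
#'   two-level categorical; dummy-code wider factors upstream).
#' @param time,status column names of follow-up time and event indicator.
#' @param standardize covariates to z-score (training-set moments).
#' @param moments optional named list `mean`, `sd` (named vectors) reusing
#'   previously computed standardisation moments.
#' @return an `ehr_cox` list: `coef`, `vcov`, `means` (covariate means on the
#'   model scale), `moments`, `n`, `nevent`, `loglik`, `covariates`.
#' @export
fit_cox <- function(panel, covariates, time = "time_years", status = "status",
                    standardize = character(), moments = NULL) {
  dt <- data.table::as.data.table(panel)
  assert_cols(dt, c(covariates, time, status), "panel")
  X <- covariate_matrix(dt, covariates)
  standardize <- intersect(standardize, colnames(X))
  if (is.null(moments)) {
    moments <- list(mean = colMeans(X[, standardize, drop = FALSE]),
                    sd = apply(X[, standardize, drop = FALSE], 2L, stats::sd))
  }
  for (v in intersect(standardize, colnames(X))) {
    s <- moments$sd[[v]]
    if (is.na(s) || s == 0) s <- 1
    X[, v] <- (X[, v] - moments$mean[[v]]) / s
  }
  y <- survival::Surv(dt[[time]], dt[[status]])
  if (sum(dt[[status]]) < 1) stop("no events in the data", call. = FALSE)
  fit <- survival::coxph(y ~ X, ties = "efron")
  cf <- fit$coefficients
  names(cf) <- colnames(X)   # coxph prefixes matrix names with "X"
  if (anyNA(cf)) {
    stop(sprintf("collinear covariate(s) dropped by the fit: %s",
                 paste(names(cf)[is.na(cf)], collapse = ", ")), call. = FALSE)
  }
  if (any(abs(cf) > 15)) {
    stop(sprintf("separation suspected (runaway coefficient): %s",
                 paste(names(cf)[abs(cf) > 15], collapse = ", ")), call. = FALSE)
  }
  V <- fit$var
  dimnames(V) <- list(names(cf), names(cf))
  structure(list(coef = cf, vcov = V, means = colMeans(X),
                 moments = moments, n = fit$n, nevent = fit$nevent,
                 loglik = fit$loglik, iter = fit$iter,
                 covariates = covariates, standardize = standardize),
            class = "ehr_cox")
}

covariate_matrix <- function(dt, covariates) {
  cols <- lapply(covariates, function(v) {
    x <- dt[[v]]
    if (is.logical(x)) return(as.numeric(x))
    if (is.factor(x) || is.character(x)) {
      lev <- sort(unique(as.character(x)))
      if (length(lev) > 2L) {
        stop(sprintf("covariate '%s' has > 2 levels; dummy-code it upstream", v),
             call. = FALSE)
      }
      return(as.numeric(as.character(x) == lev[length(lev)]))
    }
    as.numeric(x)
  })
  X <- do.call(cbind, cols)
  colnames(X) <- covariates
  if (anyNA(X)) stop("covariate matrix contains missing values; impute first",
                     call. = FALSE)
  X
}

#' @export
print.ehr_cox <- function(x, ...) {
  cat(sprintf("<ehr_cox> n = %d, events = %d\n", x$n, x$nevent))
  print(data.table::data.table(term = names(x$coef), coef = x$coef,
                               se = sqrt(diag(x$vcov)),
                               hr = exp(x$coef)))
  invisible(x)
}

fit_over_panels <- function(imp, covariates, time, status, standardize) {
  lapply(imp$panels, fit_cox, covariates = covariates, time = time,
         status = status, standardize = standardize)
}

pooled_p_for <- function(fits, term_cols) {
  if (length(term_cols) == 1L) {
    est <- vapply(fits, function(f) f$coef[[term_cols]], numeric(1))
    v <- vapply(fits, function(f) f$vcov[term_cols, term_cols], numeric(1))
    rubin_pool(matrix(est, ncol = 1, dimnames = list(NULL, term_cols)),
               matrix(v, ncol = 1))$p
  } else {
    pool_wald_D1(lapply(fits, function(f) f$coef[term_cols]),
                 lapply(fits, function(f) f$vcov[term_cols, term_cols]))$p
  }
}

#' Pooled stepwise Cox variable selection over imputed datasets
#'
#' Forward-with-backward stepwise selection in which every add/drop decision
#' uses the Wald p-value pooled across the `m` imputed-data fits by Rubin's
#' rules (a multi-parameter D1 pooled test when a candidate spans several
#' columns). The base covariates in `forced` are always in the model and
#' never tested. Ties are broken by smallest p then alphabetically; the full
#' decision trace is recorded. Revisiting a previously seen model stops the
#' search (cycling guard).
#'
#' @param imputation_result an [impute()] result.
#' @param forced covariate names always in the model (e.g. age and sex).
#' @param candidates candidate covariates: character vector, or a named list
#'   mapping a candidate name to the panel columns it spans.
#' @param time,status outcome column names.
#' @param alpha_enter,alpha_remove entry/removal thresholds on the pooled p.
#' @param standardize covariates to z-score within each fit.
#' @return a `pooled_cox` list: `selected_vars`, `forced_vars`, `table`
#'   (pooled log-HRs, SEs, HRs, 95% CIs, p), `selection_trace`, `fits`.
#' @export
pooled_stepwise_select <- function(imputation_result, forced = c("age", "sex"),
                                   candidates, time = "time_years",
                                   status = "status", alpha_enter = 0.05,
                                   alpha_remove = 0.05,
                                   standardize = character()) {
  imp <- imputation_result
  stopifnot(inherits(imp, "imputation_result"))
  if (!is.list(candidates) || is.null(names(candidates))) {
    candidates <- stats::setNames(as.list(candidates), as.character(candidates))
  }
  if (length(intersect(names(candidates), forced))) {
    stop("candidates must be disjoint from forced covariates", call. = FALSE)
  }
  model <- character()        # selected candidate names, in entry order
  trace <- list()
  seen <- character()
  step_i <- 0L
  model_cols <- function(mod) c(forced, unlist(candidates[mod], use.names = FALSE))
  repeat {
    changed <- FALSE
    sig <- paste(sort(model), collapse = "+")
    if (sig %in% seen) {
      warning("stepwise selection revisited a model; stopping (see trace)",
              call. = FALSE)
      break
    }
    seen <- c(seen, sig)
    # forward
    remaining <- setdiff(names(candidates), model)
    if (length(remaining)) {
      ps <- vapply(remaining, function(cand) {
        fits <- fit_over_panels(imp, c(model_cols(model), candidates[[cand]]),
                                time, status, standardize)
        pooled_p_for(fits, candidates[[cand]])
      }, numeric(1))
      ord <- order(ps, remaining)   # smallest p, then alphabetical
      best <- remaining[ord[1L]]
      if (ps[ord[1L]] < alpha_enter) {
        model <- c(model, best)
        step_i <- step_i + 1L
        trace[[length(trace) + 1L]] <- data.table::data.table(
          step = step_i, action = "add", var = best, pooled_p = ps[ord[1L]])
        changed <- TRUE
      }
    }
    # backward
    if (length(model)) {
      fits <- fit_over_panels(imp, model_cols(model), time, status, standardize)
      ps <- vapply(model, function(cand) pooled_p_for(fits, candidates[[cand]]),
                   numeric(1))
      ord <- order(-ps, model)
      worst <- model[ord[1L]]
      if (ps[ord[1L]] > alpha_remove) {
        model <- setdiff(model, worst)
        step_i <- step_i + 1L
        trace[[length(trace) + 1L]] <- data.table::data.table(
          step = step_i, action = "remove", var = worst, pooled_p = ps[ord[1L]])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  final_cols <- model_cols(model)
  fits <- fit_over_panels(imp, final_cols, time, status, standardize)
  est <- do.call(rbind, lapply(fits, function(f) f$coef))
  v <- do.call(rbind, lapply(fits, function(f) diag(f$vcov)))
  tab <- rubin_pool(est, v)
  tab[, hr := exp(estimate)]
  tab[, ci_low := exp(estimate - 1.96 * se)]
  tab[, ci_high := exp(estimate + 1.96 * se)]
  structure(list(selected_vars = model, forced_vars = forced, table = tab[],
                 selection_trace = if (length(trace))
                   data.table::rbindlist(trace)
                 else data.table::data.table(step = integer(),
                                             action = character(),
                                             var = character(),
                                             pooled_p = numeric()),
                 fits = fits, candidates = candidates,
                 alpha_enter = alpha_enter, alpha_remove = alpha_remove),
            class = "pooled_cox")
}

#' @export
print.pooled_cox <- function(x, ...) {
  cat(sprintf("<pooled_cox> forced: %s; selected: %s\n",
              paste(x$forced_vars, collapse = ", "),
              if (length(x$selected_vars))
                paste(x$selected_vars, collapse = ", ") else "(none)"))
  print(x$table[, list(term, hr, ci_low, ci_high, p)])
  invisible(x)
}

#' Random 2:1 train/validation split
#'
#' @param ids participant ids (length >= 3).
#' @param ratio integer ratio, default `c(2, 1)`; the training size is
#'   `round(n * ratio[1] / sum(ratio))`.
#' @param seed RNG seed.
#' @return list with `train_ids`, `valid_ids` (a partition of `ids`).
#' @export
train_validate_split <- function(ids, ratio = c(2, 1), seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  stopifnot(length(ids) >= 3L)
  set.seed(as.integer(seed))
  n_train <- round(length(ids) * ratio[1] / sum(ratio))
  train <- sort(sample(as.character(ids), n_train))
  list(train_ids = train, valid_ids = sort(setdiff(as.character(ids), train)))
}

#' Average linear-predictor risk scores over imputed fits
#'
#' For each validation participant the risk score is the mean over the `m`
#' fits of the linear predictor `(x - xbar_train)' beta`, where `xbar_train`
#' are the training covariate means (and any standardisation uses
#' training-set moments).
#'
#' @param fits list of `m` [fit_cox()] objects sharing a covariate set.
#' @param validation_panels list of `m` validation panels (one per imputed
#'   dataset) containing the covariates and `participant_id`.
#' @return `data.table` `participant_id`, `risk_score`.
#' @export
compute_risk_scores <- function(fits, validation_panels) {
  stopifnot(length(fits) == length(validation_panels))
  covs <- fits[[1L]]$covariates
  if (!all(vapply(fits, function(f) identical(f$covariates, covs), logical(1)))) {
    stop("fits do not share a covariate set", call. = FALSE)
  }
  scores <- NULL
  for (d in seq_along(fits)) {
    f <- fits[[d]]
    vp <- data.table::as.data.table(validation_panels[[d]])
    missing_cov <- setdiff(covs, names(vp))
    if (length(missing_cov)) {
      stop(sprintf("covariate(s) missing from validation panel %d: %s",
                   d, paste(missing_cov, collapse = ", ")), call. = FALSE)
    }
    X <- covariate_matrix(vp, covs)
    for (v in intersect(f$standardize, colnames(X))) {
      s <- f$moments$sd[[v]]
      if (is.na(s) || s == 0) s <- 1
      X[, v] <- (X[, v] - f$moments$mean[[v]]) / s
    }
    lp <- as.vector(sweep(X, 2L, f$means) %*% f$coef)
    scores <- if (is.null(scores)) lp else scores + lp
  }
  data.table::data.table(
    participant_id = as.character(
      data.table::as.data.table(validation_panels[[1L]])$participant_id),
    risk_score = scores / length(fits))
}

#' AUC of risk scores against binary event status
#'
#' Mann-Whitney concordance (ties count one half) with a 95% DeLong
#' confidence interval. Event status is taken as the binary status at the
#' end of follow-up (censoring-naive).
#'
#' @param scores numeric risk scores.
#' @param event_status binary 0/1 vector (both classes must be present).
#' @return list `auc`, `ci` (length 2), `se`, `n_case`, `n_control`.
#' @export
evaluate_auc <- function(scores, event_status) {
  stopifnot(length(scores) == length(event_status))
  status <- as.integer(event_status)
  if (length(unique(status)) < 2L) {
    stop("both classes must be present to compute an AUC", call. = FALSE)
  }
  cases <- scores[status == 1L]
  controls <- scores[status == 0L]
  nc <- length(cases); nn <- length(controls)
  r <- rank(c(cases, controls), ties.method = "average")
  auc <- (sum(r[seq_len(nc)]) - nc * (nc + 1) / 2) / (nc * nn)
  # DeLong placements
  psi_case <- vapply(cases, function(x)
    mean((x > controls) + 0.5 * (x == controls)), numeric(1))
  psi_control <- vapply(controls, function(y)
    mean((cases > y) + 0.5 * (cases == y)), numeric(1))
  v <- stats::var(psi_case) / nc + stats::var(psi_control) / nn
  se <- sqrt(v)
  ci <- pmin(pmax(auc + c(-1, 1) * 1.96 * se, 0), 1)
  list(auc = auc, ci = ci, se = se, n_case = nc, n_control = nn)
}

#' Median-split Kaplan-Meier comparison of risk groups
#'
#' Splits the validation cohort at the median risk score (strictly greater
#' means high risk), fits product-limit curves per group and reports the
#' log-rank test p-value.
#'
#' @param scores `data.table` `participant_id`, `risk_score` (or a numeric
#'   vector aligned with `tte_records`).
#' @param tte_records validation time-to-event rows (`participant_id`,
#'   `time_years`, `status`).
#' @return list `survfit` ([survival::survfit] object over the two groups),
#'   `logrank_p`, `median_score`, `groups` (`data.table` id/group).
#' @export
km_by_median <- function(scores, tte_records) {
  tte <- data.table::as.data.table(tte_records)
  assert_cols(tte, c("participant_id", "time_years", "status"), "tte_records")
  if (is.data.frame(scores)) {
    sc <- data.table::as.data.table(scores)
    assert_cols(sc, c("participant_id", "risk_score"), "scores")
    tte <- merge(tte, sc, by = "participant_id")
  } else {
    tte[, risk_score := as.numeric(scores)]
  }
  med <- stats::median(tte$risk_score)
  tte[, risk_group := data.table::fifelse(risk_score > med, "high", "low")]
  if (length(unique(tte$risk_group)) < 2L) {
    stop("degenerate median split: one risk group is empty", call. = FALSE)
  }
  df <- as.data.frame(tte)
  sf <- survival::survfit(survival::Surv(time_years, status) ~ risk_group,
                          data = df)
  sd_ <- survival::survdiff(survival::Surv(time_years, status) ~ risk_group,
                            data = df)
  p <- stats::pchisq(sd_$chisq, df = length(sd_$n) - 1L, lower.tail = FALSE)
  list(survfit = sf, logrank_p = p, median_score = med,
       groups = tte[, list(participant_id, risk_group)])
}

#' End-to-end risk prediction on an imputation result
#'
#' Implements the prediction workflow: 2:1 train/validation split (common to
#' all imputed panels), pooled stepwise selection on the training panels,
#' per-dataset Cox fits of the selected model, averaged validation risk
#' scores, AUC with DeLong CI, and the median-split Kaplan-Meier comparison.
#'
#' @param imputation_result an [impute()] result whose panels carry
#'   `participant_id`, the outcome columns and all candidate covariates.
#' @param forced,candidates,time,status,alpha_enter,alpha_remove,standardize
#'   passed to [pooled_stepwise_select()].
#' @param split_seed seed for the train/validation split.
#' @return a `risk_evaluation` list: `split`, `selection`, `scores`, `auc`,
#'   `km`.
#' @export
run_risk_prediction <- function(imputation_result, forced = c("age", "sex"),
                                candidates, time = "time_years",
                                status = "status", split_seed,
                                alpha_enter = 0.05, alpha_remove = 0.05,
                                standardize = character()) {
  imp <- imputation_result
  ids <- as.character(imp$panels[[1L]]$participant_id)
  split <- train_validate_split(ids, seed = split_seed)
  subset_imp <- function(keep) {
    structure(list(m = imp$m,
                   panels = lapply(imp$panels, function(p)
                     data.table::as.data.table(p)[participant_id %in% keep]),
                   method_per_variable = imp$method_per_variable,
                   seed = imp$seed),
              class = "imputation_result")
  }
  train_imp <- subset_imp(split$train_ids)
  valid_panels <- lapply(imp$panels, function(p)
    data.table::as.data.table(p)[participant_id %in% split$valid_ids])
  sel <- pooled_stepwise_select(train_imp, forced = forced,
                                candidates = candidates, time = time,
                                status = status, alpha_enter = alpha_enter,
                                alpha_remove = alpha_remove,
                                standardize = standardize)
  final_cols <- c(forced, unlist(sel$candidates[sel$selected_vars],
                                 use.names = FALSE))
  fits <- lapply(train_imp$panels, fit_cox, covariates = final_cols,
                 time = time, status = status, standardize = standardize)
  scores <- compute_risk_scores(fits, valid_panels)
  vp1 <- valid_panels[[1L]]
  vstat <- data.table::data.table(
    participant_id = as.character(vp1$participant_id),
    time_years = vp1[[time]], status = vp1[[status]])
  auc <- evaluate_auc(scores$risk_score,
                      vstat$status[match(scores$participant_id,
                                         vstat$participant_id)])
  km <- km_by_median(scores, vstat)
  structure(list(split = split, selection = sel, scores = scores,
                 auc = auc, km = km),
            class = "risk_evaluation")
}

#' @export
print.risk_evaluation <- function(x, ...) {
  cat(sprintf("<risk_evaluation> AUC %.3f (95%% CI %.3f-%.3f); log-rank p = %.3g\n",
              x$auc$auc, x$auc$ci[1], x$auc$ci[2], x$km$logrank_p))
  invisible(x)
}
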