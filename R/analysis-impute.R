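# Multiple imputation by chained equations with per-variable method choice
# (predictive mean matching vs model prediction), and Rubin's rules for
# pooling estimates across imputed datasets.

#' Choose the imputation method for a variable
#'
#' Predictive mean matching (PMM) is used when the variable is categorical
#' (factor, character or logical), integer-valued, or when its distribution
#' is skewed (absolute sample skewness above `skew_threshold`); otherwise
#' plain model prediction is used.
#'
#' @param variable_values a vector with at least one observed value.
#' @param skew_threshold absolute skewness above which PMM is chosen.
#' @return `"PMM"` or `"MODEL_PREDICTION"`.
#' @export
choose_imputation_method <- function(variable_values, skew_threshold = 1) {
  obs <- variable_values[!is.na(variable_values)]
  if (!length(obs)) stop("variable has no observed values", call. = FALSE)
  if (is.factor(obs) || is.character(obs) || is.logical(obs)) return("PMM")
  if (all(obs == round(obs))) return("PMM")
  sk <- sample_skewness(obs)
  if (!is.na(sk) && abs(sk) > skew_threshold) return("PMM")
  "MODEL_PREDICTION"
}

# least-squares fit robust to rank deficiency; aliased coefs predict as 0
ls_predict <- function(X_obs, y_obs, X_new) {
  fit <- stats::lm.fit(cbind(1, X_obs), y_obs)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  list(fitted = as.vector(cbind(1, X_obs) %*% beta),
       pred = as.vector(cbind(1, X_new) %*% beta))
}

pmm_draw <- function(fitted_obs, pred_mis, y_obs, k) {
  vapply(pred_mis, function(p) {
    d <- abs(fitted_obs - p)
    donors <- order(d)[seq_len(min(k, length(d)))]
    y_obs[donors[sample.int(length(donors), 1L)]]
  }, numeric(1))
}

#' Multiple imputation by chained equations
#'
#' Generates `m` completed copies of a covariate panel by iterative chained
#' equations. Each incomplete variable is regressed on all other variables;
#' missing values are filled either by predictive mean matching against a
#' donor pool of the `k` observed cases with closest predicted means, or by
#' the model prediction itself, according to [choose_imputation_method()].
#' Categorical variables are regression-coded as integers and imputed by PMM,
#' so imputed values are always observed levels. Observed cells are identical
#' across the `m` panels; the procedure is deterministic given `seed`.
#'
#' The panel should include the outcome (follow-up time and event status) so
#' the imputation model conditions on it.
#'
#' @param panel a data.frame/data.table; non-predictor columns are named in
#'   `id_cols`.
#' @param m number of imputed datasets, default 5.
#' @param seed RNG seed (mandatory).
#' @param k PMM donor pool size, default 5.
#' @param maxit chained-equation sweeps per dataset, default 5.
#' @param id_cols columns excluded from the imputation model and carried
#'   through unchanged.
#' @param skew_threshold passed to [choose_imputation_method()].
#' @param max_missing_frac warn when a variable exceeds this missing
#'   fraction.
#' @return an `imputation_result`: list with `m`, `panels` (list of
#'   completed `data.table`s), `method_per_variable`, `seed`.
#' @export
impute <- function(panel, m = 5L, seed, k = 5L, maxit = 5L,
                   id_cols = "participant_id", skew_threshold = 1,
                   max_missing_frac = 0.5) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  dt <- data.table::as.data.table(panel)
  vars <- setdiff(names(dt), id_cols)
  date_like <- vars[vapply(vars, function(v) inherits(dt[[v]], "Date"), logical(1))]
  vars <- setdiff(vars, date_like)
  id_cols <- c(id_cols, date_like)

  # encode categoricals as integer codes, remembering levels and types
  levels_map <- list()
  int_cols <- character()
  enc <- data.table::copy(dt)
  for (v in vars) {
    x <- enc[[v]]
    if (is.factor(x) || is.character(x) || is.logical(x)) {
      lev <- sort(unique(stats::na.omit(as.character(x))))
      levels_map[[v]] <- list(levels = lev, logical = is.logical(x),
                              factor = is.factor(x))
      data.table::set(enc, j = v, value = as.numeric(match(as.character(x), lev)))
    } else {
      if (is.integer(x)) int_cols <- c(int_cols, v)
      data.table::set(enc, j = v, value = as.numeric(x))
    }
  }
  miss_frac <- vapply(vars, function(v) mean(is.na(enc[[v]])), numeric(1))
  if (any(miss_frac >= 1)) {
    stop(sprintf("variable(s) entirely missing: %s",
                 paste(vars[miss_frac >= 1], collapse = ", ")), call. = FALSE)
  }
  high <- vars[miss_frac > max_missing_frac]
  if (length(high)) {
    warning(sprintf("variable(s) with > %.0f%% missing: %s",
                    100 * max_missing_frac, paste(high, collapse = ", ")),
            call. = FALSE)
  }
  methods <- vapply(vars, function(v)
    choose_imputation_method(dt[[v]], skew_threshold), character(1))
  incomplete <- vars[miss_frac > 0]
  incomplete <- incomplete[order(miss_frac[match(incomplete, vars)])]

  decode <- function(tab) {
    out <- data.table::copy(tab)
    for (v in names(levels_map)) {
      lm_ <- levels_map[[v]]
      val <- lm_$levels[as.integer(round(out[[v]]))]
      if (lm_$logical) val <- as.logical(val)
      if (lm_$factor) val <- factor(val, levels = lm_$levels)
      data.table::set(out, j = v, value = val)
    }
    for (v in int_cols) {
      data.table::set(out, j = v, value = as.integer(round(out[[v]])))
    }
    out
  }

  set.seed(as.integer(seed))
  panels <- vector("list", m)
  X_all <- as.matrix(enc[, vars, with = FALSE])
  obs_mask <- !is.na(X_all)
  for (d in seq_len(m)) {
    Xd <- X_all
    # initial fill: random draws from the observed values
    for (v in incomplete) {
      j <- match(v, vars)
      nm <- which(!obs_mask[, j])
      Xd[nm, j] <- sample(Xd[obs_mask[, j], j], length(nm), replace = TRUE)
    }
    if (length(incomplete)) {
      for (it in seq_len(maxit)) {
        for (v in incomplete) {
          j <- match(v, vars)
          oo <- obs_mask[, j]
          pred_cols <- setdiff(seq_along(vars), j)
          fitpred <- ls_predict(Xd[oo, pred_cols, drop = FALSE],
                                Xd[oo, j],
                                Xd[!oo, pred_cols, drop = FALSE])
          if (methods[[v]] == "PMM") {
            Xd[!oo, j] <- pmm_draw(fitpred$fitted, fitpred$pred, Xd[oo, j], k)
          } else {
            Xd[!oo, j] <- fitpred$pred
          }
        }
      }
    }
    comp <- data.table::as.data.table(Xd)
    comp <- cbind(dt[, id_cols, with = FALSE], comp)
    panels[[d]] <- decode(comp)
  }
  structure(list(m = as.integer(m), panels = panels,
                 method_per_variable = as.list(methods),
                 seed = as.integer(seed)),
            class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  cat(sprintf("<imputation_result> m = %d, %d variable(s), seed = %d\n",
              x$m, length(x$method_per_variable), x$seed))
  invisible(x)
}

#' Pool estimates across imputed datasets by Rubin's rules
#'
#' Pooled estimate is the mean of the per-dataset estimates; the total
#' variance is `T = Wbar + (1 + 1/m) B` with `Wbar` the mean within-dataset
#' variance and `B` the between-dataset variance. Wald tests use a
#' t-reference with the Barnard-Rubin adjusted degrees of freedom (reducing
#' to the classic `(m-1)(1 + 1/r)^2` when the complete-data df is infinite,
#' and to the single-fit normal test when `B = 0`).
#'
#' @param estimates an `m x p` matrix (or vector for `p = 1`) of
#'   per-dataset coefficient estimates; column names are the terms.
#' @param variances matching matrix of squared standard errors.
#' @param dfcom complete-data degrees of freedom (default `Inf`).
#' @return `data.table` `term`, `estimate`, `se`, `statistic`, `df`, `p`.
#' @export
rubin_pool <- function(estimates, variances, dfcom = Inf) {
  Q <- rbind(estimates)
  U <- rbind(variances)
  if (!all(dim(Q) == dim(U))) {
    stop("estimates and variances have mismatched dimensions", call. = FALSE)
  }
  m <- nrow(Q)
  if (m < 2L) stop("pooling requires m >= 2 fits", call. = FALSE)
  qbar <- colMeans(Q)
  wbar <- colMeans(U)
  B <- apply(Q, 2L, stats::var)
  Tv <- wbar + (1 + 1 / m) * B
  r <- (1 + 1 / m) * B / wbar
  df_old <- ifelse(B > 0, (m - 1) * (1 + 1 / r)^2, Inf)
  if (is.finite(dfcom)) {
    df_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * wbar / Tv
    df <- ifelse(is.finite(df_old), df_old * df_obs / (df_old + df_obs), df_obs)
  } else {
    df <- df_old
  }
  stat <- qbar / sqrt(Tv)
  p <- 2 * stats::pt(-abs(stat), df)
  p[!is.finite(df)] <- 2 * stats::pnorm(-abs(stat[!is.finite(df)]))
  data.table::data.table(term = colnames(Q) %||% paste0("V", seq_along(qbar)),
                         estimate = qbar, se = sqrt(Tv), statistic = stat,
                         df = df, p = p)
}

# D1 multi-parameter pooled Wald test (for candidates spanning > 1 column,
# e.g. dummy-coded categorical variables with > 2 levels)
pool_wald_D1 <- function(coef_list, vcov_list) {
  m <- length(coef_list)
  kdim <- length(coef_list[[1]])
  Q <- do.call(rbind, coef_list)
  qbar <- colMeans(Q)
  Ubar <- Reduce(`+`, vcov_list) / m
  Bm <- stats::cov(Q)
  Ubar_inv <- solve(Ubar)
  r <- (1 + 1 / m) * sum(diag(Bm %*% Ubar_inv)) / kdim
  D1 <- as.numeric(t(qbar) %*% Ubar_inv %*% qbar) / (kdim * (1 + r))
  t_ <- kdim * (m - 1)
  df2 <- if (t_ > 4) {
    4 + (t_ - 4) * (1 + (1 - 2 / t_) / r)^2
  } else {
    t_ * (1 + 1 / kdim) * (1 + 1 / r)^2 / 2
  }
  if (!is.finite(df2) || r <= 0) df2 <- 1e6
  p <- stats::pf(D1, kdim, df2, lower.tail = FALSE)
  list(statistic = D1, df1 = kdim, df2 = df2, p = p)
}

#' Inject MCAR missingness into a panel
#'
#' Each eligible cell is independently blanked with probability `rate`
#' (missing completely at random). The realised mask is returned alongside
#' the panel. Errors if a column would end up entirely missing.
#'
#' @param panel data.frame/data.table.
#' @param rate missingness probability in `[0, 1)`.
#' @param mechanism only `"MCAR"` is supported.
#' @param seed RNG seed.
#' @param cols columns eligible for blanking (default: all but
#'   `participant_id`).
#' @return list with `panel` (blanked copy) and `mask` (logical matrix,
#'   `TRUE` = blanked).
#' @export
inject_missingness <- function(panel, rate, mechanism = "MCAR", seed,
                               cols = NULL) {
  stopifnot(mechanism == "MCAR", rate >= 0, rate < 1)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  dt <- data.table::copy(data.table::as.data.table(panel))
  cols <- cols %||% setdiff(names(dt), "participant_id")
  set.seed(as.integer(seed))
  mask <- matrix(stats::runif(nrow(dt) * length(cols)) < rate,
                 nrow = nrow(dt), dimnames = list(NULL, cols))
  for (v in cols) {
    hit <- mask[, v] & !is.na(dt[[v]])
    if (any(hit) && all(hit | is.na(dt[[v]]))) {
      stop(sprintf("missingness rate would blank the entire column '%s'", v),
           call. = FALSE)
    }
    dt[hit, (v) := NA]
  }
  list(panel = dt[], mask = mask)
}
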