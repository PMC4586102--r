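#' Z-transform a numeric vector
#'
#' Centers to mean 0 and scales to sample standard deviation 1 (n - 1
#' denominator). Missing values are preserved and ignored in the moments.
#'
#' @param values Numeric vector with at least 2 distinct non-missing values.
#' @return The standardized vector.
#' @export
z_transform <- function(values) {
  obs <- values[!is.na(values)]
  if (length(unique(obs)) < 2) stop("cannot Z-transform a constant vector")
  (values - mean(obs)) / stats::sd(obs)
}

#' Correlation ratio (eta) of a numeric variable across groups
#'
#' `eta = sqrt(SS_between / SS_total)` from the one-way sum-of-squares
#' decomposition: 0 when group means are equal, 1 when all variation lies
#' between groups. This is the statistic used to summarise how strongly the
#' log epimutation burden tracks age ranges.
#'
#' @param data Data frame.
#' @param value Name of the numeric column.
#' @param group Name of the grouping column (>= 2 non-empty groups).
#' @return eta in \[0, 1\].
#' @examples
#' correlation_ratio(data.frame(g = c("A", "A", "B", "B"), y = c(0, 2, 1, 3)),
#'                   "y", "g")
#' @export
correlation_ratio <- function(data, value, group) {
  data <- dplyr::filter(tibble::as_tibble(data),
                        !is.na(.data[[value]]), !is.na(.data[[group]]))
  y <- data[[value]]
  g <- as.factor(as.character(data[[group]]))
  if (nlevels(g) < 2) stop("at least 2 groups are required")
  if (length(unique(y)) < 2) stop("all values identical; eta undefined")
  grand <- mean(y)
  ss_total <- sum((y - grand)^2)
  means <- tapply(y, g, mean)
  n_k <- tabulate(g)
  ss_between <- sum(n_k * (means - grand)^2)
  sqrt(ss_between / ss_total)
}

#' Multiple regression on Z-scores with standardized coefficients
#'
#' Ordinary least squares of the Z-transformed response on the Z-transformed
#' predictors, on complete cases. Coefficients are therefore standardized
#' regression coefficients; confidence intervals use the normal
#' approximation and p-values the usual t-test.
#'
#' @param data Data frame holding the variables.
#' @param response Name of the response column.
#' @param predictors Character vector of predictor column names.
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble with one row per predictor: `term`, `beta_std`,
#'   `std_error`, `ci_low`, `ci_high`, `p`, plus `n` (complete cases used).
#' @export
standardized_regression <- function(data, response, predictors, conf_level = 0.95) {
  data <- tibble::as_tibble(data)
  vars <- c(response, predictors)
  miss <- setdiff(vars, names(data))
  if (length(miss) > 0) stop("variable(s) not in data: ", paste(miss, collapse = ", "))
  cc <- stats::complete.cases(data[vars])
  d <- data[cc, vars]
  if (nrow(d) < length(predictors) + 2) {
    stop("too few complete cases (", nrow(d), ") for ", length(predictors), " predictor(s)")
  }
  dz <- dplyr::mutate(d, dplyr::across(dplyr::everything(), z_transform))
  xmat <- as.matrix(dz[predictors])
  qr_x <- qr(cbind(1, xmat))
  if (qr_x$rank < ncol(xmat) + 1) {
    dropped <- c("(intercept)", predictors)[qr_x$pivot[-seq_len(qr_x$rank)]]
    stop("collinear design; offending term(s): ", paste(dropped, collapse = ", "))
  }
  if (kappa(xmat, exact = TRUE) > 1e8) {
    stop("near-singular design (condition number > 1e8) among: ",
         paste(predictors, collapse = ", "))
  }
  fit <- stats::lm(stats::reformulate(predictors, response = response), data = dz)
  sm <- summary(fit)$coefficients
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  est <- sm[predictors, "Estimate"]
  se <- sm[predictors, "Std. Error"]
  tibble::tibble(term = predictors, beta_std = unname(est),
                 std_error = unname(se),
                 ci_low = unname(est - zq * se), ci_high = unname(est + zq * se),
                 p = unname(sm[predictors, "Pr(>|t|)"]),
                 n = nrow(d))
}

#' Default path-model edge set
#'
#' The recursive model relating age, log epimutation burden, average
#' methylation and X-inactivation skewing: age is exogenous; the burden is
#' regressed on age; average methylation on age and burden; skewing on age,
#' burden and average methylation. The age -> skewing edge is the
#' conditional (burden-adjusted) association whose loss of significance
#' indicates mediation through the epimutation burden.
#'
#' @return A tibble with columns `from` and `to`.
#' @export
sem_path_edges <- function() {
  tibble::tribble(
    ~from,      ~to,
    "age",      "log_sem",
    "age",      "avg_beta",
    "log_sem",  "avg_beta",
    "age",      "ds_xci",
    "log_sem",  "ds_xci",
    "avg_beta", "ds_xci"
  )
}

#' Recursive path analysis with standardized coefficients
#'
#' Fits the recursive (acyclic) path model given by `edges`: each endogenous
#' variable is regressed by OLS on its parents, all variables Z-transformed,
#' so every edge coefficient is a standardized partial regression
#' coefficient. For a just-identified recursive model this coincides with
#' the structural-equation estimates.
#'
#' @param data Data frame holding every variable named in `edges`.
#' @param edges Data frame with columns `from` and `to` (default
#'   [sem_path_edges()]); must be acyclic.
#' @param alpha Significance level for flagging edges (default 0.05).
#' @return An object of class `sem_path` with an `edges` tibble (`from`,
#'   `to`, `beta_std`, `std_error`, `ci_low`, `ci_high`, `p`, `significant`,
#'   `n`). Use [tidy()] / [glance()] / [autoplot()].
#' @export
path_analysis <- function(data, edges = sem_path_edges(), alpha = 0.05) {
  data <- tibble::as_tibble(data)
  edges <- tibble::as_tibble(as.data.frame(edges))
  if (!all(c("from", "to") %in% names(edges))) stop("`edges` needs columns from, to")
  vars <- unique(c(edges$from, edges$to))
  miss <- setdiff(vars, names(data))
  if (length(miss) > 0) stop("variable(s) not in data: ", paste(miss, collapse = ", "))
  assert_acyclic(edges)
  fitted <- edges |>
    dplyr::group_by(.data$to) |>
    dplyr::group_map(function(grp, key) {
      res <- standardized_regression(data, key$to, grp$from)
      res$to <- key$to
      dplyr::rename(res, from = "term")
    }) |>
    purrr::list_rbind() |>
    dplyr::mutate(significant = .data$p < alpha) |>
    dplyr::select("from", "to", "beta_std", "std_error", "ci_low",
                  "ci_high", "p", "significant", "n")
  # restore the input edge order
  fitted <- fitted[match(paste(edges$from, edges$to),
                         paste(fitted$from, fitted$to)), ]
  structure(list(edges = fitted, alpha = alpha), class = "sem_path")
}

assert_acyclic <- function(edges) {
  nodes <- unique(c(edges$from, edges$to))
  remaining <- edges
  repeat {
    if (nrow(remaining) == 0) return(invisible(TRUE))
    sinks <- setdiff(nodes, remaining$from)
    drop <- remaining$to %in% sinks
    if (!any(drop)) stop("path model specification contains a cycle")
    remaining <- remaining[!drop, ]
    nodes <- unique(c(remaining$from, remaining$to))
  }
}

#' @export
print.sem_path <- function(x, ...) {
  cat("Path analysis (", nrow(x$edges), " edges, alpha = ", x$alpha, ")\n", sep = "")
  print(x$edges)
  invisible(x)
}

#' Multiple imputation by chained regression
#'
#' Produces `m` completed copies of the table by iterated chained-equation
#' regression imputation: each incomplete numeric variable is regressed on
#' the other model variables, coefficients and the residual scale are drawn
#' from their approximate posterior, and missing entries are replaced with
#' noisy predictive draws. Deterministic for a given `seed`.
#'
#' @param data Data frame; missingness is expected in numeric covariates
#'   such as `bmi` and `ds_xci`.
#' @param vars Variables in the imputation model; defaults to all numeric
#'   columns. Incomplete variables among them are imputed.
#' @param m Number of imputations (default 5).
#' @param seed Integer seed.
#' @param iterations Chained-equation sweeps per imputation (default 10).
#' @return A list of `m` completed tibbles.
#' @export
impute_missing <- function(data, vars = NULL, m = 5, seed = 1, iterations = 10) {
  data <- tibble::as_tibble(data)
  vars <- vars %||% names(data)[vapply(data, is.numeric, logical(1))]
  all_missing <- vars[vapply(data[vars], function(v) all(is.na(v)), logical(1))]
  if (length(all_missing) > 0) {
    stop("variable(s) entirely missing: ", paste(all_missing, collapse = ", "))
  }
  incomplete <- vars[vapply(data[vars], anyNA, logical(1))]
  if (length(incomplete) == 0) {
    return(replicate(m, data, simplify = FALSE))
  }
  if (sum(stats::complete.cases(data[vars])) < 10) {
    stop("fewer than 10 complete cases; imputation model unsupported")
  }
  withr::with_seed(seed, {
    lapply(seq_len(m), function(i) {
      imp <- data
      # warm start: observed mean plus resampled residual spread
      for (v in incomplete) {
        obs <- imp[[v]][!is.na(imp[[v]])]
        nmis <- sum(is.na(imp[[v]]))
        imp[[v]][is.na(imp[[v]])] <- sample(obs, nmis, replace = TRUE)
      }
      for (it in seq_len(iterations)) {
        for (v in incomplete) {
          mis <- is.na(data[[v]])
          preds <- setdiff(vars, v)
          preds <- preds[vapply(imp[preds], function(z) stats::sd(z) > 0, logical(1))]
          x_obs <- cbind(1, as.matrix(imp[!mis, preds, drop = FALSE]))
          y_obs <- data[[v]][!mis]
          fit <- stats::lm.fit(x_obs, y_obs)
          res <- fit$residuals
          df <- length(y_obs) - fit$rank
          sigma2 <- sum(res^2) / max(df, 1)
          sigma_star2 <- sigma2 * df / stats::rchisq(1, df)
          xtx_inv <- chol2inv(chol(crossprod(x_obs)))
          beta_star <- fit$coefficients +
            drop(chol(sigma_star2 * xtx_inv) %*% stats::rnorm(ncol(x_obs)))
          x_mis <- cbind(1, as.matrix(imp[mis, preds, drop = FALSE]))
          imp[[v]][mis] <- drop(x_mis %*% beta_star) +
            stats::rnorm(sum(mis), 0, sqrt(sigma_star2))
        }
      }
      imp
    })
  })
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Combines `m` per-imputation estimates of the same quantity: the pooled
#' estimate is their mean, the within-imputation variance `W` is the mean of
#' the per-imputation variances, the between-imputation variance `B` is the
#' sample variance of the estimates, and the total variance is
#' `T = W + (1 + 1/m) * B`, with the classic degrees of freedom
#' `(m - 1) * (1 + W / ((1 + 1/m) * B))^2`.
#'
#' @param estimates Data frame with columns `estimate` and `variance`, one
#'   row per imputation (m >= 2).
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row tibble with `estimate`, `var_within`, `var_between`,
#'   `var_total`, `std_error`, `df`, `ci_low`, `ci_high`, `p`, `m`.
#' @examples
#' rubin_pool(data.frame(estimate = c(1, 2, 3), variance = c(1, 1, 1)))
#' @export
rubin_pool <- function(estimates, conf_level = 0.95) {
  estimates <- tibble::as_tibble(estimates)
  if (!all(c("estimate", "variance") %in% names(estimates))) {
    stop("`estimates` needs columns estimate, variance")
  }
  m <- nrow(estimates)
  if (m < 2) stop("at least 2 imputations are required to pool")
  q_bar <- mean(estimates$estimate)
  w <- mean(estimates$variance)
  b <- stats::var(estimates$estimate)
  total <- w + (1 + 1 / m) * b
  df <- if (b > 0) (m - 1) * (1 + w / ((1 + 1 / m) * b))^2 else Inf
  se <- sqrt(total)
  tq <- stats::qt(1 - (1 - conf_level) / 2, df)
  p <- if (se > 0) 2 * stats::pt(-abs(q_bar / se), df) else as.numeric(q_bar == 0)
  tibble::tibble(estimate = q_bar, var_within = w, var_between = b,
                 var_total = total, std_error = se, df = df,
                 ci_low = q_bar - tq * se, ci_high = q_bar + tq * se,
                 p = p, m = m)
}

#' Pool standardized regressions fitted on multiple imputations
#'
#' Runs [standardized_regression()] on each completed dataset and pools each
#' term's coefficient with [rubin_pool()].
#'
#' @param imputations List of completed data frames (from
#'   [impute_missing()]).
#' @inheritParams standardized_regression
#' @return A tibble with one pooled row per predictor.
#' @export
pooled_standardized_regression <- function(imputations, response, predictors,
                                           conf_level = 0.95) {
  fits <- purrr::map(imputations, standardized_regression,
                     response = response, predictors = predictors)
  purrr::map(predictors, function(term) {
    per_imp <- purrr::map(fits, ~ .x[.x$term == term, ]) |> purrr::list_rbind()
    pooled <- rubin_pool(
      tibble::tibble(estimate = per_imp$beta_std, variance = per_imp$std_error^2),
      conf_level = conf_level
    )
    dplyr::bind_cols(tibble::tibble(term = term), pooled)
  }) |> purrr::list_rbind()
}

age_range_levels <- c("0-19", "20-39", "40-59", "60-79", "80-106")

#' Assign the study age ranges
#'
#' Bins ages into the five ranges 0-19, 20-39, 40-59, 60-79, 80-106 years.
#'
#' @param age Numeric ages in years.
#' @return An ordered factor of age ranges.
#' @export
age_range <- function(age) {
  # left-closed bins on completed years: a 39.9-year-old is 39, hence 20-39
  cut(age, breaks = c(0, 20, 40, 60, 80, 107), labels = age_range_levels,
      include.lowest = TRUE, right = FALSE, ordered_result = TRUE)
}

#' Assemble the per-subject cohort table
#'
#' Joins the epimutation burden, the sample sheet and the sample-wise mean
#' methylation into one analysis table, one row per subject. Technical
#' replicates (rows with `replicate_of` set) are excluded.
#'
#' @param counts A [count_sems()] tibble.
#' @param sheet Sample sheet.
#' @param beta Beta matrix used to compute `avg_beta` (the per-sample mean
#'   over all probes).
#' @return A tibble with `sample_id`, `age`, `sex`, `bmi`, `avg_beta`,
#'   `n_sem`, `log_sem`, `ds_xci`, `age_range`.
#' @export
build_cohort_table <- function(counts, sheet, beta) {
  sheet <- validate_sample_sheet(sheet)
  beta <- validate_beta_matrix(beta)
  avg <- tibble::tibble(sample_id = sample_ids(beta),
                        avg_beta = colMeans(beta_values(beta), na.rm = TRUE))
  counts |>
    dplyr::inner_join(sheet, by = "sample_id") |>
    dplyr::inner_join(avg, by = "sample_id") |>
    dplyr::filter(is.na(.data$replicate_of)) |>
    dplyr::mutate(age_range = age_range(.data$age)) |>
    dplyr::select("sample_id", "age", "sex", "bmi", "avg_beta", "n_sem",
                  "log_sem", "ds_xci", "age_range")
}
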