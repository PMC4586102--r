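test_that("Z-transform standardises and is affine-invariant", {
  expect_equal(z_transform(c(1, 2, 3)), c(-1, 0, 1))
  withr::local_seed(17)
  v <- rnorm(50, 7, 3)
  z <- z_transform(v)
  expect_lt(abs(mean(z)), 1e-12)
  expect_equal(sd(z), 1)
  expect_equal(z_transform(5 * v - 2), z, tolerance = 1e-12)
  expect_error(z_transform(rep(4, 10)), "constant")
  # missing values pass through
  v[3] <- NA
  expect_true(is.na(z_transform(v)[3]))
})

test_that("correlation ratio matches the hand-computed decomposition", {
  df <- data.frame(g = c("A", "A", "B", "B"), y = c(0, 2, 1, 3))
  # SS_between = 1, SS_total = 5
  expect_equal(correlation_ratio(df, "y", "g"), sqrt(1 / 5))
  expect_equal(correlation_ratio(data.frame(g = c("A", "A", "B", "B"),
                                            y = c(1, 1, 3, 3)), "y", "g"), 1)
  expect_equal(correlation_ratio(data.frame(g = c("A", "A", "B", "B"),
                                            y = c(1, 3, 1, 3)), "y", "g"), 0)
  expect_error(correlation_ratio(data.frame(g = "A", y = 1:3), "y", "g"),
               "2 groups")
  expect_error(correlation_ratio(data.frame(g = c("A", "B"), y = c(1, 1)),
                                 "y", "g"), "identical")
})

test_that("correlation ratio equals |r| when groups are encoded by their means", {
  withr::local_seed(18)
  df <- data.frame(g = sample(letters[1:5], 200, replace = TRUE),
                   y = rnorm(200))
  df$y <- df$y + as.integer(factor(df$g))
  eta <- correlation_ratio(df, "y", "g")
  means <- tapply(df$y, df$g, mean)
  expect_equal(eta, abs(cor(df$y, means[df$g])), tolerance = 1e-12)
})

test_that("standardized regression recovers exact and null relationships", {
  withr::local_seed(19)
  df <- data.frame(x = rnorm(100))
  df$y <- 2 * df$x + 5
  fit <- suppressWarnings(standardized_regression(df, "y", "x"))  # exact fit
  expect_equal(fit$beta_std, 1, tolerance = 1e-10)
  expect_lt(fit$p, 1e-20)

  # independent response: coefficient within 3 SE of zero
  big <- data.frame(x = rnorm(1e4), y = rnorm(1e4))
  fit0 <- standardized_regression(big, "y", "x")
  expect_lt(abs(fit0$beta_std), 3 * fit0$std_error)

  # two orthogonalised predictors: partial coefficients = marginal correlations
  a <- rnorm(400)
  b <- residuals(lm(rnorm(400) ~ a))
  df2 <- data.frame(a = a, b = b)
  df2$y <- 0.5 * scale(a)[, 1] - 0.3 * scale(b)[, 1] + rnorm(400, 0, 0.4)
  fit2 <- standardized_regression(df2, "y", c("a", "b"))
  expect_equal(fit2$beta_std[1], cor(df2$y, df2$a), tolerance = 1e-10)
  expect_equal(fit2$beta_std[2], cor(df2$y, df2$b), tolerance = 1e-10)

  df2$c <- df2$a
  expect_error(standardized_regression(df2, "y", c("a", "c")), "collinear")
  expect_error(standardized_regression(df2, "y", "nope"), "not in data")
  expect_error(standardized_regression(df2[1:2, ], "y", c("a", "b")),
               "complete cases")
})

test_that("path analysis equals standardized regression on a single edge", {
  withr::local_seed(20)
  df <- data.frame(age = runif(80, 0, 100))
  df$log_sem <- 0.03 * df$age + rnorm(80, 0, 0.8)
  pa <- path_analysis(df, data.frame(from = "age", to = "log_sem"))
  sr <- standardized_regression(df, "log_sem", "age")
  expect_equal(pa$edges$beta_std, sr$beta_std)
  expect_equal(pa$edges$p, sr$p)
})

test_that("path analysis exposes full mediation that marginal regression hides", {
  withr::local_seed(21)
  n <- 2000
  df <- data.frame(age = runif(n, 3, 106))
  df$log_sem <- 0.035 * df$age + rnorm(n, 0, 1)
  df$ds_xci <- 6 * z_transform(df$log_sem) + rnorm(n, 0, 8)
  edges <- data.frame(from = c("age", "age", "log_sem"),
                      to = c("log_sem", "ds_xci", "ds_xci"))
  pa <- tidy(path_analysis(df, edges))
  lookup <- function(f, t) pa[pa$from == f & pa$to == t, ]
  expect_true(lookup("age", "log_sem")$significant)
  expect_true(lookup("log_sem", "ds_xci")$significant)
  expect_false(lookup("age", "ds_xci")$significant)
  # yet the *marginal* age ~ skewing association is strongly significant
  marg <- standardized_regression(df, "ds_xci", "age")
  expect_lt(marg$p, 1e-10)
})

test_that("deterministic mediation yields unit and zero path coefficients", {
  df <- data.frame(x = rnorm(50))
  df$m <- df$x
  df$y <- df$m
  edges <- data.frame(from = c("x", "x", "m"), to = c("m", "y", "y"))
  expect_error(suppressWarnings(path_analysis(df, edges)), "collinear")
  # with a hair of noise on m the structure is identifiable
  withr::local_seed(22)
  df$m <- df$x + rnorm(50, 0, 1e-4)
  df$y <- df$m
  pa <- tidy(suppressWarnings(path_analysis(df, edges)))
  expect_equal(pa$beta_std[pa$from == "m" & pa$to == "y"], 1, tolerance = 1e-4)
  expect_equal(pa$beta_std[pa$from == "x" & pa$to == "y"], 0, tolerance = 1e-4)
})

test_that("cyclic path specifications are rejected", {
  df <- data.frame(a = rnorm(20), b = rnorm(20))
  expect_error(path_analysis(df, data.frame(from = c("a", "b"), to = c("b", "a"))),
               "cycle")
})

test_that("imputation is deterministic and a no-op on complete data", {
  withr::local_seed(23)
  df <- tibble::tibble(x = rnorm(30), y = rnorm(30))
  imps <- impute_missing(df, m = 3, seed = 9)
  expect_length(imps, 3)
  for (i in 1:3) expect_equal(imps[[i]], df)

  df$y[1:5] <- NA
  a <- impute_missing(df, m = 2, seed = 9)
  b <- impute_missing(df, m = 2, seed = 9)
  expect_identical(a, b)
  c_ <- impute_missing(df, m = 2, seed = 10)
  expect_false(identical(a, c_))
  expect_false(anyNA(a[[1]]$y))
  # observed values are never altered
  expect_equal(a[[1]]$y[-(1:5)], df$y[-(1:5)])
  expect_error(impute_missing(tibble::tibble(x = rnorm(20), y = NA_real_)),
               "entirely missing")
})

test_that("MCAR imputation recovers a planted slope within pooled error", {
  withr::local_seed(24)
  n <- 500
  df <- tibble::tibble(log_sem = rnorm(n), age = rnorm(n))
  df$ds_xci <- 0.5 * df$log_sem + 0.2 * df$age + rnorm(n)
  truth <- standardized_regression(df, "ds_xci", c("log_sem", "age"))
  df$ds_xci[runif(n) < 0.2] <- NA
  imps <- impute_missing(df, m = 5, seed = 31)
  pooled <- pooled_standardized_regression(imps, "ds_xci", c("log_sem", "age"))
  slope <- pooled[pooled$term == "log_sem", ]
  expect_lt(abs(slope$estimate - truth$beta_std[1]), 2 * slope$std_error)
})

test_that("Rubin pooling matches the hand-worked example and scales correctly", {
  pooled <- rubin_pool(data.frame(estimate = c(1, 2, 3), variance = c(1, 1, 1)))
  expect_equal(pooled$estimate, 2)
  expect_equal(pooled$var_within, 1)
  expect_equal(pooled$var_between, 1)
  expect_equal(pooled$var_total, 7 / 3)

  same <- rubin_pool(data.frame(estimate = rep(1.7, 5), variance = rep(0.4, 5)))
  expect_equal(same$estimate, 1.7)
  expect_equal(same$var_between, 0)
  expect_equal(same$var_total, 0.4)

  base <- rubin_pool(data.frame(estimate = c(1, 2, 4), variance = c(1, 2, 3)))
  scaled <- rubin_pool(data.frame(estimate = 10 * c(1, 2, 4),
                                  variance = 100 * c(1, 2, 3)))
  expect_equal(scaled$estimate, 10 * base$estimate)
  expect_equal(scaled$var_total, 100 * base$var_total)
  expect_equal(scaled$var_between, 100 * base$var_between)

  expect_error(rubin_pool(data.frame(estimate = 1, variance = 1)), "at least 2")
})

test_that("age ranges bin the study strata correctly", {
  expect_equal(as.character(age_range(c(0, 19, 20, 39.5, 59, 60, 79.9, 80, 106))),
               c("0-19", "0-19", "20-39", "20-39", "40-59", "60-79", "60-79",
                 "80-106", "80-106"))
})
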