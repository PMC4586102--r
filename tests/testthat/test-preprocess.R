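make_sheet <- function(ids, bs = 5000) {
  tibble::tibble(sample_id = ids, age = 40, sex = "F", platform = "450K",
                 bs_control_intensity = rep_len(bs, length(ids)))
}

test_that("bisulfite-control filter is strict at the threshold", {
  withr::local_seed(1)
  m <- random_beta_matrix(10, 5)
  sheet <- make_sheet(sample_ids(m), bs = c(5000, 3999, 4000, 5000, 5000))
  res <- filter_samples(m, sheet, bs_threshold = 4000, pca_sd = 50)
  expect_equal(res$qc$id, "s002")
  expect_equal(res$qc$reason, "bs_control")
  expect_equal(res$n_samples_retained, 4)
  # intensities all above threshold and identical profiles: nothing removed
  flat <- beta_matrix(matrix(0.5, 10, 5,
                             dimnames = list(paste0("cg", 1:10), paste0("s", 1:5))))
  res2 <- filter_samples(flat, make_sheet(paste0("s", 1:5)))
  expect_equal(nrow(res2$qc), 0)
})

test_that("PCA screen flags the sample an independent eigen-decomposition flags", {
  withr::local_seed(42)
  n_probes <- 30
  v <- matrix(runif(n_probes * 20, 0.2, 0.5), n_probes, 20,
              dimnames = list(paste0("cg", 1:n_probes), sprintf("s%02d", 1:20)))
  v[, 13] <- v[, 13] + 0.4
  m <- beta_matrix(v)
  res <- filter_samples(m, make_sheet(sample_ids(m)), pca_sd = 4)
  expect_equal(res$qc$id, "s13")
  expect_equal(res$qc$reason, "pca_outlier")

  # independent oracle: eigen-decomposition of the sample-sample Gram matrix
  # of probe-standardized data
  z <- scale(t(v))
  e <- eigen(z %*% t(z), symmetric = TRUE)
  flagged <- character()
  for (comp in 1:2) {
    score <- e$vectors[, comp] * sqrt(e$values[comp])
    dev <- abs(score - mean(score))
    flagged <- union(flagged, colnames(v)[dev > 4 * sd(score)])
  }
  expect_equal(sort(flagged), sort(res$qc$id))
})

test_that("too few samples for the PCA screen is an error", {
  m <- random_beta_matrix(5, 3)
  sheet <- make_sheet(sample_ids(m), bs = c(3000, 5000, 5000))
  expect_error(filter_samples(m, sheet), "fewer than 3")
})

test_that("probe filters remove in order with first-applicable reasons", {
  withr::local_seed(2)
  v <- matrix(runif(5 * 20, 0.3, 0.7), 5, 20,
              dimnames = list(paste0("cg", 1:5), sprintf("s%02d", 1:20)))
  v[2, 3] <- NA # missing beta
  m <- beta_matrix(v)
  pv <- matrix(0.001, 5, 20, dimnames = dimnames(v))
  pv[3, 1:2] <- 0.5            # 18/20 = 0.90 < 0.95 -> detection_p
  pv[4, 1] <- 0.5              # 19/20 = 0.95, not below call_rate -> kept
  pv[2, 1:5] <- 0.5            # also fails detection, but missing_beta wins
  detp <- beta_matrix(pv)
  names(detp) <- names(m)
  annot <- toy_annot(paste0("cg", 1:5))
  annot$chromosome[5] <- "X"
  res <- filter_probes(m, annot, detp = detp)
  expect_equal(res$qc$id, c("cg2", "cg3", "cg5"))
  expect_equal(res$qc$reason, c("missing_beta", "detection_p", "sex_chromosome"))
  expect_equal(res$beta$probe_id, c("cg1", "cg4"))

  # idempotent: filtering the filtered matrix removes nothing
  detp2 <- detp[detp$probe_id %in% res$beta$probe_id, ]
  res2 <- filter_probes(res$beta, annot, detp = detp2)
  expect_equal(nrow(res2$qc), 0)
  expect_equal(res2$beta, res$beta)
})

test_that("probe filter requires annotation coverage and warns without detp", {
  m <- random_beta_matrix(3, 5)
  expect_error(filter_probes(m, toy_annot(c("cg0001", "cg0002"))), "cg0003")
  expect_warning(filter_probes(m, toy_annot(probe_ids(m))), "detection p-value")
})

test_that("quantile normalisation equalises sample distributions", {
  # worked example: columns (0.1, 0.3) and (0.2, 0.4) -> both (0.15, 0.35)
  m <- beta_matrix(matrix(c(0.1, 0.3, 0.2, 0.4), 2, 2,
                          dimnames = list(c("p1", "p2"), c("a", "b"))))
  out <- beta_values(quantile_normalize(m))
  expect_equal(out[, "a"], c(p1 = 0.15, p2 = 0.35))
  expect_equal(out[, "b"], c(p1 = 0.15, p2 = 0.35))

  # ties take the mean of the reference over the tied rank span
  m2 <- beta_matrix(matrix(c(0.2, 0.2, 0.6, 0.1, 0.3, 0.5), 3, 2,
                           dimnames = list(paste0("p", 1:3), c("a", "b"))))
  out2 <- beta_values(quantile_normalize(m2))
  expect_equal(out2[, "a"], c(p1 = 0.2, p2 = 0.2, p3 = 0.55))
  expect_equal(out2[, "b"], c(p1 = 0.15, p2 = 0.25, p3 = 0.55))

  # identical value multisets: unchanged up to within-sample order
  m3 <- beta_matrix(matrix(c(0.1, 0.5, 0.9, 0.9, 0.1, 0.5), 3, 2,
                           dimnames = list(paste0("p", 1:3), c("a", "b"))))
  expect_equal(beta_values(quantile_normalize(m3)), beta_values(m3))

  # single sample: the reference is itself
  m4 <- random_beta_matrix(10, 1)
  expect_equal(quantile_normalize(m4), m4)

  expect_error(quantile_normalize(beta_matrix(
    matrix(c(NA, 0.5), 1, 2, dimnames = list("p", c("a", "b"))))), "missing")
})

test_that("quantile normalisation matches limma on tie-free data", {
  skip_if_not_installed("limma")
  withr::local_seed(3)
  m <- random_beta_matrix(50, 8)
  ours <- beta_values(quantile_normalize(m))
  theirs <- limma::normalizeQuantiles(beta_values(m))
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-12)
})

test_that("column value multisets are identical after normalisation", {
  withr::local_seed(4)
  m <- random_beta_matrix(40, 6)
  out <- beta_values(quantile_normalize(m))
  ref <- unname(sort(out[, 1]))
  for (j in 2:ncol(out)) expect_equal(unname(sort(out[, j])), ref)
})

test_that("platform pooling intersects probes and concatenates samples", {
  mk <- function(probes, samples, fill) {
    beta_matrix(matrix(fill, length(probes), length(samples),
                       dimnames = list(probes, samples)))
  }
  m27 <- mk(c("a", "b", "c"), c("s1", "s2"), 0.3)
  m450 <- mk(c("b", "c", "d"), c("s3", "s4"), 0.7)
  pooled <- pool_platforms(m27, m450)
  expect_equal(pooled$probe_id, c("b", "c"))
  expect_equal(sample_ids(pooled), c("s1", "s2", "s3", "s4"))

  # identical probe sets: all retained, in 450K order
  m450b <- mk(c("c", "b", "a"), c("s3", "s4"), 0.7)
  pooled2 <- pool_platforms(m27, m450b)
  expect_equal(pooled2$probe_id, c("c", "b", "a"))

  expect_error(pool_platforms(m27, mk("z", "s9", 0.1)), "common")
  expect_error(pool_platforms(m27, mk("a", "s1", 0.1)), "overlapping")

  # values are preserved exactly under pooling of disjoint-renamed samples
  withr::local_seed(5)
  m <- random_beta_matrix(20, 4)
  m2 <- m
  names(m2)[-1] <- paste0(names(m2)[-1], "_x")
  pooled3 <- pool_platforms(m, m2)
  expect_equal(beta_values(pooled3)[, sample_ids(m)], beta_values(m))
})
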