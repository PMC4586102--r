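# Independent oracles and tiny fixture builders shared across tests.

# Naive sort-and-interpolate fence calling, written independently of the
# package's vectorised implementation: loops probe by probe, interpolates
# quartiles at position p*(n-1) on the sorted values, applies the strict
# fence rule.
oracle_call_sems <- function(v, k = 3) {
  out <- data.frame(probe_id = character(), sample_id = character(),
                    direction = character())
  for (i in seq_len(nrow(v))) {
    x <- v[i, ]
    s <- sort(x)
    n <- length(x)
    interp <- function(p) {
      h <- p * (n - 1)
      lo <- floor(h)
      if (lo + 2 > n) s[n] else s[lo + 1] + (h - lo) * (s[lo + 2] - s[lo + 1])
    }
    q1 <- interp(0.25)
    q3 <- interp(0.75)
    lo_f <- q1 - k * (q3 - q1)
    hi_f <- q3 + k * (q3 - q1)
    for (j in seq_len(length(x))) {
      if (x[j] > hi_f) {
        out <- rbind(out, data.frame(probe_id = rownames(v)[i],
                                     sample_id = colnames(v)[j],
                                     direction = "hyper"))
      } else if (x[j] < lo_f) {
        out <- rbind(out, data.frame(probe_id = rownames(v)[i],
                                     sample_id = colnames(v)[j],
                                     direction = "hypo"))
      }
    }
  }
  out
}

# sample() treats a length-1 vector as 1:n; pick1 never does
pick1 <- function(v) v[sample.int(length(v), 1)]

call_signature <- function(calls_df) {
  sort(paste(calls_df$probe_id, calls_df$sample_id, calls_df$direction, sep = "/"))
}

# Exact combinatorial upper-tail hypergeometric: direct summation of
# positive terms; for N_G <= 500 every binomial coefficient fits the double
# range and the positive sum carries ~1e-15 relative error.
oracle_hypergeom_upper <- function(n_g, n_s, g_i, s_i) {
  ss <- seq(s_i, min(g_i, n_s))
  if (length(ss) == 0) return(0)
  sum(choose(n_s, ss) * choose(n_g - n_s, g_i - ss)) / choose(n_g, g_i)
}

random_beta_matrix <- function(n_probes, n_samples, prefix = "cg") {
  v <- matrix(stats::runif(n_probes * n_samples), n_probes, n_samples,
              dimnames = list(sprintf("%s%04d", prefix, seq_len(n_probes)),
                              sprintf("s%03d", seq_len(n_samples))))
  beta_matrix(v)
}

toy_annot <- function(probes, chromosome = "1", gene = "") {
  tibble::tibble(probe_id = probes, chromosome = chromosome,
                 position = seq_along(probes) * 100L, gene = gene,
                 platforms = "27K;450K")
}
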