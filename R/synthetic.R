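#' Configuration for the synthetic methylation cohort
#'
#' Defaults emulate the study design the package targets: 178 whole-blood
#' subjects aged 3-106 (ages uniform, so each of the five age ranges holds
#' well over 10 subjects), split across the 27K and 450K platforms, with an
#' epimutation burden that grows exponentially with age, a mild global
#' age/BMI hypomethylation drift, technical duplicate pairs, and
#' SEM-correlated X-inactivation skewing in females with no direct age
#' effect (so skewing is mediated entirely by the burden).
#'
#' @param n_subjects Number of subjects (default 178).
#' @param age_range Min/max age in years (default `c(3, 106)`).
#' @param n_probes_shared CpG probes present on both platforms (default
#'   1000; the pooled analysis universe).
#' @param n_probes_private Platform-private probes per platform (default
#'   200; a tenth are placed on chromosomes X/Y to exercise the QC filter).
#' @param sem_rate_intercept Expected SEM count at age 0 (lambda0, default
#'   2).
#' @param sem_rate_slope Per-year log-rate of the SEM count (b, default
#'   0.04): planted counts are Poisson with mean
#'   `lambda0 * exp(b * age) * u`, where `u` is a per-subject gamma frailty.
#' @param sem_rate_dispersion Shape of the mean-1 gamma frailty `u`
#'   (default 2). Real epimutation burdens are highly variable between
#'   subjects of the same age; the frailty reproduces that over-dispersion
#'   (negative-binomial marginal counts) without biasing the age slope.
#'   `Inf` disables it.
#' @param global_drift Per-year change in mean beta (default -3e-4,
#'   hypomethylation with age).
#' @param bmi_effect Per-unit-BMI change in mean beta (default -4e-4).
#' @param beta_logit_sd Measurement noise SD on the logit scale (default
#'   0.2).
#' @param sample_logit_sd Per-sample global offset SD on the logit scale
#'   (default 0.08); this is what makes average methylation vary between
#'   subjects beyond the age/BMI drift.
#' @param beta_modes,beta_mode_weights,beta_mode_sd Bimodal baseline profile
#'   of per-probe means (unmethylated/methylated modes).
#' @param epimutation_effect_size Minimum |delta beta| of a planted
#'   epimutation (default 0.2); displacement is adaptive, toward the far
#'   unit-interval boundary and always beyond the probe's expected fences.
#' @param duplicate_pairs Technical duplicate pairs to append (default 3).
#' @param duplicate_share Fraction of planted epimutations shared within a
#'   duplicate pair (default 0.99).
#' @param imprinting_samples Subjects given a fully epimutated gene block as
#'   imprinting-disorder positive controls (default 0).
#' @param xci_base,xci_slope,xci_noise XCI-skewing link: for females,
#'   `ds = 50 * plogis(xci_base + xci_slope * z(log SEM) + N(0, xci_noise))`.
#'   The default slope/noise give a standardized burden-to-skewing path near
#'   0.6 with no direct age term, strong enough that the mediation pattern
#'   is recoverable in the large majority of replicate cohorts at the
#'   default cohort size despite the age-burden collinearity.
#' @param female_fraction Fraction of female subjects (default 0.55).
#' @param xci_measured_fraction Fraction of females heterozygous at the AR
#'   repeat, i.e. with a measurable `ds_xci` (default 0.85).
#' @param bmi_mean,bmi_sd,bmi_missing BMI distribution and the fraction of
#'   subjects with BMI absent from the sheet.
#' @param platform_fraction_450k Fraction of subjects on the 450K platform
#'   (default 94/178).
#' @param probes_per_gene Shared probes grouped per gene symbol (default
#'   10).
#' @param bs_intensity_mean,bs_intensity_sd Bisulfite-control intensity
#'   distribution (defaults pass the 4000 QC cut).
#' @param n_bs_fail Samples planted with a failing bisulfite control
#'   (default 0).
#' @param n_failed_probes Probes planted with failing detection p-values
#'   (default 0).
#' @param seed Integer seed; the cohort is deterministic given the seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 178,
                          age_range = c(3, 106),
                          n_probes_shared = 1000,
                          n_probes_private = 200,
                          sem_rate_intercept = 2,
                          sem_rate_slope = 0.04,
                          sem_rate_dispersion = 2,
                          global_drift = -3e-4,
                          bmi_effect = -4e-4,
                          beta_logit_sd = 0.2,
                          sample_logit_sd = 0.08,
                          beta_modes = c(0.12, 0.85),
                          beta_mode_weights = c(0.6, 0.4),
                          beta_mode_sd = 0.04,
                          epimutation_effect_size = 0.2,
                          duplicate_pairs = 3,
                          duplicate_share = 0.99,
                          imprinting_samples = 0,
                          xci_base = -0.8,
                          xci_slope = 0.8,
                          xci_noise = 0.7,
                          female_fraction = 0.55,
                          xci_measured_fraction = 0.85,
                          bmi_mean = 25.5, bmi_sd = 4, bmi_missing = 0.1,
                          platform_fraction_450k = 94 / 178,
                          probes_per_gene = 10,
                          bs_intensity_mean = 5200, bs_intensity_sd = 150,
                          n_bs_fail = 0,
                          n_failed_probes = 0,
                          seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_subjects >= 4, cfg$n_probes_shared >= 1,
            cfg$sem_rate_intercept >= 0,
            cfg$duplicate_share >= 0, cfg$duplicate_share <= 1,
            cfg$epimutation_effect_size > 0, cfg$epimutation_effect_size < 1)
  structure(cfg, class = "cohort_config")
}

#' Generate a synthetic methylation cohort
#'
#' Simulates the full data bundle the pipeline consumes: per-platform and
#' pooled beta matrices with logit-normal noise, a probe annotation (genes,
#' chromosomes, positions, platform membership), a sample sheet (age, sex,
#' BMI, platform, bisulfite control, XCI skewing), detection p-value
#' matrices, and a `truth` record of everything planted: the epimutation set
#' (each displaced beyond the probe's eventual fences, toward the far
#' boundary), per-subject planted counts, and the generating coefficients.
#'
#' @param cfg A [cohort_config()].
#' @return An object of class `synthetic_cohort`: a list with `beta`
#'   (pooled shared-probe matrix), `beta_27`, `beta_450`, `detp_27`,
#'   `detp_450`, `sheet`, `annot` and `truth`.
#' @export
generate_cohort <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  withr::with_seed(cfg$seed, generate_cohort_impl(cfg))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_subjects
  subjects <- tibble::tibble(
    sample_id = sprintf("S%03d", seq_len(n)),
    age = stats::runif(n, cfg$age_range[1], cfg$age_range[2]),
    sex = ifelse(stats::runif(n) < cfg$female_fraction, "F", "M"),
    bmi_true = pmax(16, stats::rnorm(n, cfg$bmi_mean, cfg$bmi_sd)),
    platform = ifelse(seq_len(n) %in%
                        sample.int(n, round(cfg$platform_fraction_450k * n)),
                      "450K", "27K"),
    sample_offset = stats::rnorm(n, 0, cfg$sample_logit_sd),
    bs_control_intensity = stats::rnorm(n, cfg$bs_intensity_mean, cfg$bs_intensity_sd)
  )
  if (cfg$n_bs_fail > 0) {
    subjects$bs_control_intensity[seq_len(min(cfg$n_bs_fail, n))] <-
      stats::runif(min(cfg$n_bs_fail, n), 2000, 3500)
  }

  annot <- make_annotation(cfg)
  shared_ids <- annot$probe_id[annot$platforms == "27K;450K"]
  mu <- draw_baseline_means(nrow(annot), cfg)
  names(mu) <- annot$probe_id

  # planted stochastic epimutations: Poisson burden, probes uniform at random
  frailty <- if (is.finite(cfg$sem_rate_dispersion)) {
    stats::rgamma(n, shape = cfg$sem_rate_dispersion, rate = cfg$sem_rate_dispersion)
  } else rep(1, n)
  lambda <- cfg$sem_rate_intercept * exp(cfg$sem_rate_slope * subjects$age) * frailty
  n_planted <- stats::rpois(n, lambda)
  n_planted <- pmin(n_planted, length(shared_ids))
  epis <- purrr::map2(subjects$sample_id, n_planted, function(id, k) {
    if (k == 0) return(NULL)
    tibble::tibble(probe_id = sample(shared_ids, k), sample_id = id)
  }) |> purrr::list_rbind()
  if (is.null(epis) || nrow(epis) == 0) {
    epis <- tibble::tibble(probe_id = character(), sample_id = character())
  }
  epis$direction <- ifelse(mu[epis$probe_id] < 0.5, "hyper", "hypo")

  sigma_total <- sqrt(cfg$beta_logit_sd^2 + cfg$sample_logit_sd^2)
  grids <- build_value_grids(cfg, subjects, annot, mu, epis, sigma_total)

  # XCI skewing: monotone logistic map of the log planted burden onto [0, 50]
  log_sem_true <- log(n_planted + 1)
  z <- if (stats::sd(log_sem_true) > 0) {
    (log_sem_true - mean(log_sem_true)) / stats::sd(log_sem_true)
  } else rep(0, n)
  ds <- 50 * stats::plogis(cfg$xci_base + cfg$xci_slope * z +
                             stats::rnorm(n, 0, cfg$xci_noise))
  measurable <- subjects$sex == "F" & stats::runif(n) < cfg$xci_measured_fraction
  ds[!measurable] <- NA_real_

  bmi_rec <- subjects$bmi_true
  bmi_rec[stats::runif(n) < cfg$bmi_missing] <- NA_real_

  sheet <- tibble::tibble(
    sample_id = subjects$sample_id, age = subjects$age, sex = subjects$sex,
    bmi = bmi_rec, platform = subjects$platform,
    bs_control_intensity = subjects$bs_control_intensity,
    ds_xci = ds, replicate_of = NA_character_
  )

  cohort <- structure(
    list(beta = grids$beta, beta_27 = grids$beta_27, beta_450 = grids$beta_450,
         detp_27 = grids$detp_27, detp_450 = grids$detp_450,
         sheet = sheet, annot = annot,
         truth = list(
           epimutations = epis[, c("probe_id", "sample_id", "direction")],
           counts = tibble::tibble(sample_id = subjects$sample_id,
                                   n_planted = n_planted,
                                   log_sem_planted = log_sem_true),
           imprinting = tibble::tibble(gene = character(),
                                       sample_id = character()),
           coefficients = list(sem_rate_intercept = cfg$sem_rate_intercept,
                               sem_rate_slope = cfg$sem_rate_slope,
                               global_drift = cfg$global_drift,
                               bmi_effect = cfg$bmi_effect,
                               xci_slope = cfg$xci_slope,
                               xci_base = cfg$xci_base)
         ),
         internals = list(cfg = cfg, mu = mu, subjects = subjects,
                          sigma_total = sigma_total)),
    class = "synthetic_cohort"
  )

  if (cfg$imprinting_samples > 0) {
    genes <- unique(annot$gene[annot$probe_id %in% shared_ids & annot$gene != ""])
    hosts <- utils::tail(subjects$sample_id, cfg$imprinting_samples)
    for (i in seq_along(hosts)) {
      cohort <- plant_imprinting_block(cohort, genes[i], hosts[i])
    }
  }
  cohort
}

make_annotation <- function(cfg) {
  n_sh <- cfg$n_probes_shared
  n_pr <- cfg$n_probes_private
  ids <- c(sprintf("cgS%05d", seq_len(n_sh)),
           sprintf("cgA%05d", seq_len(n_pr)),
           sprintf("cgB%05d", seq_len(n_pr)))
  platforms <- rep(c("27K;450K", "27K", "450K"), c(n_sh, n_pr, n_pr))
  # a tenth of the private probes sit on the sex chromosomes
  chrom <- rep_len(as.character(1:22), length(ids))
  n_sex <- ceiling(n_pr / 10)
  if (n_pr > 0) {
    chrom[n_sh + seq_len(n_sex)] <- "X"
    chrom[n_sh + n_pr + seq_len(n_sex)] <- "Y"
  }
  gene <- character(length(ids))
  gene[seq_len(n_sh)] <- sprintf("GENE%04d", (seq_len(n_sh) - 1) %/% cfg$probes_per_gene + 1)
  ann <- tibble::tibble(probe_id = ids, chromosome = chrom,
                        position = NA_integer_, gene = gene,
                        platforms = platforms)
  ann <- ann |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::mutate(position = 10000L * seq_len(dplyr::n())) |>
    dplyr::ungroup()
  ann[order(match(ann$probe_id, ids)), ]
}

draw_baseline_means <- function(n_probes, cfg) {
  mode <- sample(seq_along(cfg$beta_modes), n_probes, replace = TRUE,
                 prob = cfg$beta_mode_weights)
  pmin(pmax(stats::rnorm(n_probes, cfg$beta_modes[mode], cfg$beta_mode_sd),
            0.03), 0.97)
}

# expected mean beta for subject i at probe j before noise
expected_mu <- function(mu_j, age, bmi, cfg) {
  pmin(pmax(mu_j + cfg$global_drift * age + cfg$bmi_effect * (bmi - 25),
            0.01), 0.99)
}

# displacement target for a planted epimutation: toward the far boundary,
# past the configured effect size and past the reach of the fences
# (~4.72 noise SDs) with margin
epimutation_target <- function(mu_ij, direction, effect, sigma_logit, jitter = NULL) {
  sigma_beta <- sigma_logit * mu_ij * (1 - mu_ij)
  delta <- pmax(effect, 6.5 * sigma_beta)
  jitter <- jitter %||% stats::runif(length(mu_ij), 0, 0.02)
  target <- ifelse(direction == "hyper", mu_ij + delta + jitter,
                   mu_ij - delta - jitter)
  infeasible <- (direction == "hyper" & mu_ij + effect > 0.995) |
    (direction == "hypo" & mu_ij - effect < 0.005)
  list(target = pmin(pmax(target, 0.001), 0.999), infeasible = infeasible)
}

simulate_values <- function(mu_grid, offsets, cfg) {
  logit_mu <- stats::qlogis(mu_grid)
  noise <- matrix(stats::rnorm(length(mu_grid), 0, cfg$beta_logit_sd),
                  nrow = nrow(mu_grid))
  v <- stats::plogis(sweep(logit_mu + noise, 2, offsets, `+`))
  pmin(pmax(v, 0.001), 0.999)
}

build_value_grids <- function(cfg, subjects, annot, mu, epis, sigma_total) {
  mu_grid <- outer(mu, rep(1, nrow(subjects)))
  for (i in seq_len(nrow(subjects))) {
    mu_grid[, i] <- expected_mu(mu, subjects$age[i], subjects$bmi_true[i], cfg)
  }
  dimnames(mu_grid) <- list(annot$probe_id, subjects$sample_id)
  v <- simulate_values(mu_grid, subjects$sample_offset, cfg)

  if (nrow(epis) > 0) {
    idx <- cbind(match(epis$probe_id, annot$probe_id),
                 match(epis$sample_id, subjects$sample_id))
    disp <- epimutation_target(mu_grid[idx], epis$direction,
                               cfg$epimutation_effect_size, sigma_total)
    if (any(disp$infeasible)) {
      stop("epimutation displacement infeasible for probe(s): ",
           paste(utils::head(unique(epis$probe_id[disp$infeasible]), 10),
                 collapse = ", "))
    }
    v[idx] <- disp$target
  }

  shared <- annot$platforms == "27K;450K"
  on27 <- annot$platforms %in% c("27K;450K", "27K")
  on450 <- annot$platforms %in% c("27K;450K", "450K")
  s27 <- subjects$platform == "27K"
  s450 <- subjects$platform == "450K"

  detp_for <- function(nr, nc, dn) {
    p <- matrix(stats::runif(nr * nc, 0, 0.01), nr, nc, dimnames = dn)
    if (cfg$n_failed_probes > 0) {
      bad <- seq_len(min(cfg$n_failed_probes, nr))
      n_fail <- pmax(1, ceiling(0.10 * nc))
      for (j in bad) p[j, sample.int(nc, n_fail)] <- stats::runif(n_fail, 0.2, 1)
    }
    p
  }
  v27 <- v[on27, s27, drop = FALSE]
  v450 <- v[on450, s450, drop = FALSE]
  list(
    beta = beta_matrix(v[shared, , drop = FALSE]),
    beta_27 = beta_matrix(v27),
    beta_450 = beta_matrix(v450),
    detp_27 = beta_matrix(detp_for(nrow(v27), ncol(v27), dimnames(v27))),
    detp_450 = beta_matrix(detp_for(nrow(v450), ncol(v450), dimnames(v450)))
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic methylation cohort: ", nrow(x$sheet), " samples, ",
      nrow(x$beta), " shared probes (", nrow(x$beta_27), " on 27K, ",
      nrow(x$beta_450), " on 450K); ", nrow(x$truth$epimutations),
      " planted epimutations\n", sep = "")
  invisible(x)
}

#' Append technical duplicates to a synthetic cohort
#'
#' Adds replicate samples that emulate independent bisulfite conversion and
#' re-hybridisation of the same DNA: each replicate re-draws all measurement
#' noise, retains each of its subject's planted epimutations with
#' probability `share`, and gains a matching number of conversion-artefact
#' epimutations at new probes with probability `1 - share` each, so
#' discordance runs in both directions. Duplicated subjects are drawn from
#' those with at least one planted epimutation.
#'
#' @param cohort A [generate_cohort()] result.
#' @param pairs Number of duplicate pairs (default from the config).
#' @param share Fraction of epimutations shared within a pair (default from
#'   the config).
#' @param seed Seed for the replicate noise (default: config seed + 1000).
#' @param min_burden Duplicated subjects are drawn from those with at least
#'   this many planted epimutations (default 10, relaxed automatically when
#'   too few subjects qualify). Concordance is only a meaningful validation
#'   statistic when the duplicated sample carries a measurable burden, which
#'   is how duplicate samples are chosen in practice.
#' @return The cohort with replicate samples appended (sheet rows carry
#'   `replicate_of`) and `truth$duplicate_pairs` recording the pairing.
#' @export
generate_duplicates <- function(cohort, pairs = NULL, share = NULL, seed = NULL,
                                min_burden = 10) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  cfg <- cohort$internals$cfg
  pairs <- pairs %||% cfg$duplicate_pairs
  share <- share %||% cfg$duplicate_share
  seed <- seed %||% (cfg$seed + 1000)
  if (pairs == 0) return(cohort)
  counts <- cohort$truth$counts
  eligible <- counts$sample_id[counts$n_planted >= min_burden]
  if (pairs > length(eligible)) {
    eligible <- counts$sample_id[counts$n_planted > 0]
  }
  if (pairs > length(eligible)) stop("not enough epimutated subjects to duplicate")
  withr::with_seed(seed, {
    chosen <- sample(eligible, pairs)
    for (id in chosen) cohort <- append_replicate(cohort, id, share)
  })
  cohort$truth$duplicate_pairs <- tibble::tibble(
    sample_1 = chosen, sample_2 = paste0(chosen, "_rep"))
  cohort
}

append_replicate <- function(cohort, id, share) {
  internals <- cohort$internals
  cfg <- internals$cfg
  subj <- internals$subjects[internals$subjects$sample_id == id, ]
  rep_id <- paste0(id, "_rep")
  annot <- cohort$annot
  shared_ids <- annot$probe_id[annot$platforms == "27K;450K"]

  on_plat <- annot$platforms %in% c("27K;450K", subj$platform)
  probes <- annot$probe_id[on_plat]
  mu_vec <- expected_mu(internals$mu[probes], subj$age, subj$bmi_true, cfg)
  offset <- stats::rnorm(1, 0, cfg$sample_logit_sd)
  v <- simulate_values(matrix(mu_vec, ncol = 1, dimnames = list(probes, rep_id)),
                       offset, cfg)

  own <- cohort$truth$epimutations[cohort$truth$epimutations$sample_id == id, ]
  kept <- own[stats::runif(nrow(own)) < share, ]
  n_new <- stats::rbinom(1, nrow(own), 1 - share)
  free <- setdiff(shared_ids, own$probe_id)
  new_probes <- if (n_new > 0) sample(free, min(n_new, length(free))) else character()
  gained <- tibble::tibble(
    probe_id = new_probes, sample_id = rep_id,
    direction = as.character(ifelse(internals$mu[new_probes] < 0.5,
                                    "hyper", "hypo")))
  rep_epis <- dplyr::bind_rows(
    tibble::tibble(probe_id = kept$probe_id, sample_id = rep_id,
                   direction = kept$direction),
    gained)
  if (nrow(rep_epis) > 0) {
    ridx <- match(rep_epis$probe_id, probes)
    disp <- epimutation_target(mu_vec[ridx], rep_epis$direction,
                               cfg$epimutation_effect_size, internals$sigma_total)
    v[ridx, 1] <- disp$target
  }

  add_col <- function(m) {
    m[[rep_id]] <- v[match(m$probe_id, probes), 1]
    m
  }
  cohort$beta <- add_col(cohort$beta)
  plat_field <- if (subj$platform == "27K") "beta_27" else "beta_450"
  detp_field <- if (subj$platform == "27K") "detp_27" else "detp_450"
  cohort[[plat_field]] <- add_col(cohort[[plat_field]])
  cohort[[detp_field]][[rep_id]] <- stats::runif(nrow(cohort[[detp_field]]), 0, 0.01)

  cohort$sheet <- dplyr::bind_rows(cohort$sheet, dplyr::mutate(
    cohort$sheet[cohort$sheet$sample_id == id, ],
    sample_id = rep_id, replicate_of = id,
    bs_control_intensity = stats::rnorm(1, cfg$bs_intensity_mean, cfg$bs_intensity_sd)))
  cohort$truth$epimutations <- dplyr::bind_rows(cohort$truth$epimutations, rep_epis)
  cohort$truth$counts <- dplyr::bind_rows(
    cohort$truth$counts,
    tibble::tibble(sample_id = rep_id, n_planted = nrow(rep_epis),
                   log_sem_planted = log(nrow(rep_epis) + 1)))
  cohort
}

#' Plant a fully epimutated gene block
#'
#' Displaces every probe of `gene` in one sample beyond the probe's fences
#' (toward the far boundary), emulating the regional epigenetic alteration
#' of an imprinting-disorder sample; the planted block is recorded in
#' `truth$imprinting` and the per-probe calls in `truth$epimutations`.
#' Re-planting the same block is idempotent on the truth record.
#'
#' @param cohort A [generate_cohort()] result.
#' @param gene Gene symbol (>= 3 annotated probes on the pooled array).
#' @param sample Sample id receiving the block.
#' @return The modified cohort.
#' @export
plant_imprinting_block <- function(cohort, gene, sample) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  internals <- cohort$internals
  cfg <- internals$cfg
  annot <- cohort$annot
  probes <- annot$probe_id[annot$gene == gene & annot$platforms == "27K;450K"]
  if (length(probes) == 0) stop("unknown gene: ", gene)
  if (length(probes) < 3) stop("gene ", gene, " has fewer than 3 probes")
  if (!sample %in% cohort$sheet$sample_id) stop("unknown sample: ", sample)
  subj <- internals$subjects[internals$subjects$sample_id ==
                               sub("_rep$", "", sample), ]
  mu_vec <- expected_mu(internals$mu[probes], subj$age, subj$bmi_true, cfg)
  direction <- ifelse(internals$mu[probes] < 0.5, "hyper", "hypo")
  disp <- epimutation_target(mu_vec, direction, cfg$epimutation_effect_size,
                             internals$sigma_total, jitter = 0.01)
  if (any(disp$infeasible)) {
    stop("displacement infeasible for probe(s): ",
         paste(probes[disp$infeasible], collapse = ", "))
  }
  set_cells <- function(m) {
    if (!sample %in% names(m)) return(m)
    ridx <- match(probes, m$probe_id)
    ok <- !is.na(ridx)
    m[[sample]][ridx[ok]] <- disp$target[ok]
    m
  }
  cohort$beta <- set_cells(cohort$beta)
  cohort$beta_27 <- set_cells(cohort$beta_27)
  cohort$beta_450 <- set_cells(cohort$beta_450)
  block <- tibble::tibble(probe_id = probes, sample_id = sample,
                          direction = direction)
  cohort$truth$epimutations <- dplyr::distinct(
    dplyr::bind_rows(cohort$truth$epimutations, block))
  cohort$truth$imprinting <- dplyr::distinct(dplyr::bind_rows(
    cohort$truth$imprinting, tibble::tibble(gene = gene, sample_id = sample)))
  cohort
}
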