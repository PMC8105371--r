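#' Configuration of the synthetic multifocal-cohort generator
#'
#' Defines the statistical structure of a simulated cohort of cancer
#' patients with multiple tumors: how many patients, how tumor counts are
#' distributed across metastasis-count strata, the tumor-volume law, the
#' radiomic feature panel and its correlation structure, which features
#' carry a survival effect and through which patient-level aggregate, the
#' baseline Weibull survival law, and the right-censoring mechanism.
#'
#' Defaults emulate a single-institution brain-metastasis SRS cohort:
#' 831 patients whose metastasis-count strata (<5 / 5-10 / 11+) occur with
#' probabilities 0.653 / 0.258 / 0.089, a mean of ~4.3 tumors per patient,
#' a lognormal volume law placing the per-patient largest-tumor volume
#' roughly in thirds across the <0.2 / 0.2-0.7 / >0.7 cc bins, median
#' survival of 12 months, and ~31% right-censoring.
#'
#' @param n_patients number of patients.
#' @param strata_probs probabilities of the three metastasis-count strata
#'   (<5, 5-10, 11+); must sum to 1 within 1e-9.
#' @param count_geom_p per-stratum success probability of the
#'   zero-truncated geometric law governing tumor counts inside each
#'   stratum's bounds.
#' @param count_bounds list of 3 integer ranges `c(lo, hi)` per stratum.
#' @param volume_meanlog,volume_sdlog lognormal tumor-volume parameters
#'   (log-cc scale); volumes are i.i.d. across tumors.
#' @param n_features,n_additive size of the feature panel, passed to
#'   [default_feature_schema()].
#' @param schema_variant `"strict"` or `"physical"` (see
#'   [default_feature_schema()]).
#' @param informative names of features with nonzero survival effect.
#' @param effects log-hazard coefficients, one per informative feature,
#'   applied to the patient-level aggregate named by `true_aggregation`.
#' @param volume_coupling in `[0, 1]`: correlation between (standardized
#'   log) tumor volume and every feature value.
#' @param block_rho in `[0, 1)`: within-family feature correlation induced
#'   by a shared per-tumor family factor (radiomic features are strongly
#'   collinear within families; redundancy-aware selection needs this).
#' @param noise_sd scale of the independent per-feature noise.
#' @param true_aggregation aggregation method generating the true linear
#'   predictor; one of the six method names of [aggregate_cohort()].
#' @param true_k tumor-subset size when `true_aggregation` is
#'   `"weighted_top_k"`.
#' @param weibull_shape Weibull shape of the baseline survival law.
#' @param weibull_scale Weibull scale in months; `NULL` (default)
#'   calibrates it so the realized median death time equals
#'   `median_survival_months`.
#' @param median_survival_months calibration target for the scale.
#' @param admin_horizon administrative censoring horizon in months.
#' @param dropout_horizon width in months of the uniform dropout window
#'   (defaults to 36, a typical median follow-up for such cohorts; it must
#'   be short enough that the censoring target is reachable).
#' @param dropout_rate probability that a patient is subject to uniform
#'   dropout on `(0, dropout_horizon)` rather than administrative
#'   censoring; `NULL` (default) solves for the rate whose expected
#'   censored fraction equals `target_censoring`.
#' @param target_censoring calibration target for the censored fraction.
#' @param time_resolution survival times are rounded to this resolution in
#'   months (0.25 = roughly weekly follow-up granularity; guarantees tied
#'   times, as real month-resolution data have).
#' @param seed integer seed; all randomness flows from it via per-patient
#'   sub-streams.
#' @return A `generator_config` object.
#' @seealso [simulate_cohort()], [true_risk()]
#' @export
generator_config <- function(n_patients = 831L,
                             strata_probs = c(0.653, 0.258, 0.089),
                             count_geom_p = c(0.45, 0.20, 0.15),
                             count_bounds = list(c(1L, 4L), c(5L, 10L), c(11L, 30L)),
                             volume_meanlog = log(0.15),
                             volume_sdlog = 1.2,
                             n_features = 32L,
                             n_additive = 8L,
                             schema_variant = "strict",
                             informative = c("firstorder_01", "firstorder_02",
                                             "texture_01", "texture_02"),
                             effects = c(0.6, -0.5, 0.5, 0.4),
                             volume_coupling = 0.35,
                             block_rho = 0.4,
                             noise_sd = 1,
                             true_aggregation = "weighted_top_k",
                             true_k = 3L,
                             weibull_shape = 1.1,
                             weibull_scale = NULL,
                             median_survival_months = 12,
                             admin_horizon = 60,
                             dropout_horizon = 36,
                             dropout_rate = NULL,
                             target_censoring = 257 / 831,
                             time_resolution = 0.25,
                             seed = 1L) {
  cfg <- structure(as.list(environment()), class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  if (length(cfg$n_patients) != 1L || cfg$n_patients < 1) {
    stop("n_patients must be a positive integer")
  }
  if (length(cfg$strata_probs) != 3L || any(cfg$strata_probs < 0) ||
      abs(sum(cfg$strata_probs) - 1) > 1e-9) {
    stop("strata_probs must be 3 non-negative probabilities summing to 1")
  }
  if (length(cfg$effects) != length(cfg$informative)) {
    stop("effects must have one entry per informative feature")
  }
  pos <- c(volume_sdlog = cfg$volume_sdlog, noise_sd = cfg$noise_sd,
           weibull_shape = cfg$weibull_shape, admin_horizon = cfg$admin_horizon,
           dropout_horizon = cfg$dropout_horizon,
           median_survival_months = cfg$median_survival_months,
           time_resolution = cfg$time_resolution)
  if (any(pos <= 0)) {
    stop("scale parameter(s) must be strictly positive: ",
         paste(names(pos)[pos <= 0], collapse = ", "))
  }
  if (!is.null(cfg$weibull_scale) && cfg$weibull_scale <= 0) {
    stop("weibull_scale must be strictly positive")
  }
  if (cfg$volume_coupling < 0 || cfg$volume_coupling > 1) {
    stop("volume_coupling must lie in [0, 1]")
  }
  if (cfg$block_rho < 0 || cfg$block_rho >= 1) {
    stop("block_rho must lie in [0, 1)")
  }
  methods <- c("unweighted_average", "weighted_average", "weighted_top_k",
               "largest_plus_count", "largest_only", "smallest_only")
  if (!cfg$true_aggregation %in% methods) {
    stop("true_aggregation must be one of: ", paste(methods, collapse = ", "))
  }
  schema <- default_feature_schema(cfg$n_features, cfg$n_additive,
                                   cfg$schema_variant)
  allowed <- c(schema$feature,
               if (cfg$true_aggregation == "largest_plus_count") "n_metastases")
  bad <- setdiff(cfg$informative, allowed)
  if (length(bad)) {
    stop("informative feature(s) not in the schema: ",
         paste(bad, collapse = ", "))
  }
  invisible(cfg)
}

# zero-truncated geometric on the integer range [lo, hi]
rtrunc_geom <- function(n, p, lo, hi) {
  k <- lo:hi
  sample(k, n, replace = TRUE, prob = (1 - p)^(k - lo))
}

#' Simulate a multifocal survival cohort
#'
#' Draws, per patient: a metastasis-count stratum, a tumor count from a
#' zero-truncated geometric law inside the stratum's bounds, i.i.d.
#' lognormal tumor volumes, and per-tumor feature vectors built from a
#' volume-coupled signal, a shared per-tumor family factor (inducing
#' within-family collinearity) and independent Gaussian noise. The true
#' per-patient log-hazard is `effects` applied to the patient-level
#' aggregate computed by `true_aggregation`; survival times follow a
#' Weibull proportional-hazards law shifted by it, and censoring combines
#' an administrative horizon with uniform dropout whose rate is solved in
#' closed form to hit the target censored fraction in expectation.
#'
#' Deterministic given `cfg$seed`: each patient draws from its own
#' sub-stream, so cohorts are bit-identical across runs.
#'
#' @param cfg a [generator_config()].
#' @return A [cohort()] whose `provenance` is `cfg`.
#' @examples
#' coh <- simulate_cohort(generator_config(n_patients = 50, seed = 7))
#' coh
#' @export
simulate_cohort <- function(cfg) {
  validate_generator_config(cfg)
  n <- as.integer(cfg$n_patients)
  schema <- default_feature_schema(cfg$n_features, cfg$n_additive,
                                   cfg$schema_variant)
  fam <- schema$family
  fam_levels <- unique(fam)
  p <- nrow(schema)

  set.seed(as.integer(cfg$seed))
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n + 1L)

  vc <- cfg$volume_coupling
  lb <- sqrt((1 - vc^2) * cfg$block_rho)
  le <- cfg$noise_sd * sqrt((1 - vc^2) * (1 - cfg$block_rho))

  tum_list <- vector("list", n)
  u_surv <- u_drop <- d_drop <- numeric(n)
  pid <- sprintf("P%04d", seq_len(n))
  for (i in seq_len(n)) {
    set.seed(sub_seeds[i])
    st <- sample.int(3L, 1L, prob = cfg$strata_probs)
    b <- cfg$count_bounds[[st]]
    k <- rtrunc_geom(1L, cfg$count_geom_p[st], b[1], b[2])
    vol <- stats::rlnorm(k, cfg$volume_meanlog, cfg$volume_sdlog)
    sv <- (log(vol) - cfg$volume_meanlog) / cfg$volume_sdlog
    u_fam <- matrix(stats::rnorm(k * length(fam_levels)), k,
                    dimnames = list(NULL, fam_levels))
    eps <- matrix(stats::rnorm(k * p), k, p)
    x <- vc * sv + lb * u_fam[, fam, drop = FALSE] + le * eps
    colnames(x) <- schema$feature
    tum_list[[i]] <- data.frame(patient_id = pid[i],
                                tumor_id = sprintf("T%02d", seq_len(k)),
                                volume_cc = vol, x,
                                stringsAsFactors = FALSE)
    u_surv[i] <- stats::runif(1)
    d_drop[i] <- stats::runif(1)
    u_drop[i] <- stats::runif(1)
  }
  tumors <- do.call(rbind, tum_list)
  rownames(tumors) <- NULL

  # ground-truth linear predictor via the configured aggregation
  draft <- structure(list(tumors = tumors,
                          outcomes = data.frame(patient_id = pid,
                                                time_months = 1,
                                                event = 1),
                          schema = schema, provenance = NULL),
                     class = "cohort")
  lp <- compute_true_lp(draft, cfg)

  # Weibull PH death times; scale calibrated on the realized draws so the
  # median death time hits the configured target exactly
  t_raw <- (-log(u_surv) / exp(lp))^(1 / cfg$weibull_shape)
  scale <- cfg$weibull_scale
  if (is.null(scale)) scale <- cfg$median_survival_months / stats::median(t_raw)
  t_death <- scale * t_raw

  # dropout rate q: expected censored fraction is linear in q given t_death
  H <- cfg$admin_horizon
  Hd <- min(cfg$dropout_horizon, H)
  q <- cfg$dropout_rate
  if (is.null(q)) {
    a <- mean(t_death > H)
    b <- mean(pmin(t_death / Hd, 1))
    if (b - a < 1e-12 || cfg$target_censoring <= a ||
        cfg$target_censoring > b) {
      q <- if (cfg$target_censoring <= a) 0 else 1
      warning("censoring target unattainable; dropout_rate clipped to ", q)
    } else {
      q <- (cfg$target_censoring - a) / (b - a)
    }
  }
  t_cens <- ifelse(d_drop < q, pmin(u_drop * Hd, H), H)
  event <- as.integer(t_death <= t_cens)
  t_obs <- pmin(t_death, t_cens)
  res <- cfg$time_resolution
  t_obs <- pmax(res, round(t_obs / res) * res)

  out <- data.frame(patient_id = pid, time_months = t_obs, event = event,
                    stringsAsFactors = FALSE)
  cfg$weibull_scale_used <- scale
  cfg$dropout_rate_used <- q
  cohort(tumors, out, schema, provenance = cfg)
}

# effects applied to the configured patient-level aggregate, outcomes order
compute_true_lp <- function(coh, cfg) {
  k <- if (cfg$true_aggregation == "weighted_top_k") cfg$true_k else NULL
  pfm <- aggregate_cohort(coh, cfg$true_aggregation, k = k,
                          append_count = cfg$true_aggregation == "largest_plus_count")
  drop(pfm$x[, cfg$informative, drop = FALSE] %*% cfg$effects)
}

#' Ground-truth patient risk of a simulated cohort
#'
#' Recomputes the exact linear predictor the generator used (the
#' configured effects applied to the configured aggregate); higher values
#' mean worse prognosis. Useful as an oracle risk score in recovery tests.
#'
#' @param coh a cohort produced by [simulate_cohort()].
#' @param cfg the [generator_config()] that produced it; defaults to the
#'   cohort's provenance.
#' @return Named numeric vector, one value per patient in outcomes order.
#' @export
true_risk <- function(coh, cfg = coh$provenance) {
  stopifnot(inherits(coh, "cohort"))
  if (!inherits(cfg, "generator_config")) {
    stop("cfg must be a generator_config (cohort has no generator provenance)")
  }
  pid <- sprintf("P%04d", seq_len(cfg$n_patients))
  if (!identical(as.character(coh$outcomes$patient_id), pid)) {
    stop("cohort/config mismatch: patient ids differ from the generator's")
  }
  lp <- compute_true_lp(coh, cfg)
  names(lp) <- coh$outcomes$patient_id
  lp
}
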