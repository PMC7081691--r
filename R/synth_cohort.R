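#' Default regional effect sizes for cohort simulation
#'
#' Per-region generating parameters for the linear model
#' `FD% = beta0 + beta_age * age + beta_severity * stage + b_patient + e_eye`.
#' The age and severity slopes and the inter-eye correlations `alpha` follow
#' the effect sizes reported for macular choriocapillaris flow deficits in
#' diabetic cohorts (age effects of 0.05-0.12 FD %/year and severity effects
#' of 0.33-0.65 FD %/stage, strongest centrally, with inter-eye correlation
#' around 0.3). Intercepts and total eye-level standard deviations are model
#' choices: `sigma_total` is set so that, at a ~90-patient study size, the
#' implied robust standard errors match the magnitudes such studies report,
#' and `beta0` keeps marginal FD % in a realistic range (roughly 8-20 %,
#' highest in the inner ring) so that clamping to \[0, 100\] is negligible.
#'
#' @return data.frame with columns `region`, `beta0`, `beta_age`,
#'   `beta_severity`, `alpha` (inter-eye correlation), `sigma_total`
#'   (marginal SD in FD % units).
#' @export
default_region_effects <- function() {
  data.frame(
    region        = c("inner", "middle", "outer", "full"),
    beta0         = c(11.0, 7.2, 5.0, 5.3),
    beta_age      = c(0.12, 0.09, 0.05, 0.06),
    beta_severity = c(0.65, 0.56, 0.33, 0.36),
    alpha         = c(0.29, 0.29, 0.35, 0.32),
    sigma_total   = c(4.7, 3.2, 2.1, 2.3))
}

#' Configure a simulated paired-eye cohort
#'
#' Defines the cohort layout (patients, severity-stage counts, eyes per
#' patient, age distribution) and the per-region generating model. Patients
#' contribute two eyes with probability `both_eyes_probability`; both eyes
#' share the patient's age, severity stage and a patient-level random effect
#' `b_patient ~ N(0, sigma_patient^2)`, while each eye adds an independent
#' residual `e_eye ~ N(0, sigma_eye^2)`. The implied exchangeable inter-eye
#' correlation is `alpha = sigma_patient^2 / (sigma_patient^2 + sigma_eye^2)`.
#'
#' @param n_patients Number of patients (default 90).
#' @param stage_counts Patients per severity stage 0-4 (no DR, mild NPDR,
#'   moderate NPDR, severe NPDR, PDR); must sum to `n_patients`. Default
#'   `c(33, 17, 8, 10, 22)`.
#' @param both_eyes_probability Probability a patient contributes both eyes
#'   (default 7/9, giving 160 eyes from 90 patients in expectation).
#' @param age_mean,age_sd Age distribution in years (normal, truncated to
#'   `age_range`); defaults 58.14 and 12.
#' @param age_range Truncation bounds for age, default `c(18, 100)`.
#' @param effects Per-region generating parameters: a data.frame with
#'   columns `region`, `beta0`, `beta_age`, `beta_severity` and either
#'   `alpha` + `sigma_total` (from which `sigma_patient`, `sigma_eye` are
#'   derived as `sigma_total * sqrt(alpha)` and `sigma_total *
#'   sqrt(1 - alpha)`) or explicit `sigma_patient` + `sigma_eye`. Default
#'   [default_region_effects()].
#' @param seed Optional integer seed.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 90,
                          stage_counts = c(33, 17, 8, 10, 22),
                          both_eyes_probability = 7 / 9,
                          age_mean = 58.14, age_sd = 12,
                          age_range = c(18, 100),
                          effects = default_region_effects(),
                          seed = NULL) {
  if (length(stage_counts) != 5 || any(stage_counts < 0) ||
      sum(stage_counts) != n_patients) {
    stop_ccfd("`stage_counts` must be 5 non-negative counts summing to `n_patients`",
              "ccfd_invalid_config")
  }
  assert_scalar_num(both_eyes_probability, "both_eyes_probability", 0, 1)
  assert_scalar_num(age_sd, "age_sd", lower = 0)
  stopifnot(is.data.frame(effects),
            all(c("region", "beta0", "beta_age", "beta_severity") %in%
                  names(effects)))
  if (!all(c("sigma_patient", "sigma_eye") %in% names(effects))) {
    if (!all(c("alpha", "sigma_total") %in% names(effects))) {
      stop_ccfd("`effects` needs sigma_patient+sigma_eye or alpha+sigma_total",
                "ccfd_invalid_config")
    }
    if (any(effects$alpha < 0 | effects$alpha > 1) ||
        any(effects$sigma_total < 0)) {
      stop_ccfd("alpha must lie in [0, 1] and sigma_total be non-negative",
                "ccfd_invalid_config")
    }
    effects$sigma_patient <- effects$sigma_total * sqrt(effects$alpha)
    effects$sigma_eye <- effects$sigma_total * sqrt(1 - effects$alpha)
  }
  if (any(effects$sigma_patient < 0 | effects$sigma_eye < 0)) {
    stop_ccfd("random-effect SDs must be non-negative", "ccfd_invalid_config")
  }
  v <- effects$sigma_patient^2 + effects$sigma_eye^2
  effects$alpha_true <- ifelse(v > 0, effects$sigma_patient^2 / v, 0)
  structure(list(n_patients = as.integer(n_patients),
                 stage_counts = as.integer(stage_counts),
                 both_eyes_probability = both_eyes_probability,
                 age_mean = age_mean, age_sd = age_sd, age_range = age_range,
                 effects = effects, seed = seed),
            class = "cohort_config")
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lo | out[bad] > hi]
  }
  out
}

#' Simulate a paired-eye cohort with known generating truth
#'
#' Draws a cohort under the configured linear model. Severity stages are
#' assigned at the patient level (both eyes share a stage), ages are drawn
#' from a truncated normal, and each region's FD % is
#' `beta0 + beta_age * age + beta_severity * stage + b_patient + e_eye`,
#' clamped to \[0, 100\] (clamping events are counted and reported in the
#' generating truth; under the default parameters they are essentially
#' absent). Deterministic for a fixed seed.
#'
#' @param config A [cohort_config()].
#' @param seed Seed overriding `config$seed`.
#' @return data.frame with one row per eye: `patient_id`, `eye` (OD/OS),
#'   `age_years`, `dr_stage` (0-4) and one `fd_<region>` column per
#'   configured region. The generating truth (effects table with
#'   `alpha_true`, clamp count, eye count) is attached as attribute
#'   `generating_truth`, retrievable with [generating_truth()].
#' @export
generate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(seed, {
    np <- config$n_patients
    stages <- sample(rep.int(0:4, config$stage_counts))
    ages <- round(rtruncnorm1(np, config$age_mean, config$age_sd,
                              config$age_range[1], config$age_range[2]), 1)
    two <- stats::runif(np) < config$both_eyes_probability
    n_eyes_per <- ifelse(two, 2L, 1L)
    first_eye <- sample(c("OD", "OS"), np, replace = TRUE)
    pidx <- rep.int(seq_len(np), n_eyes_per)
    eye <- unlist(lapply(seq_len(np), function(i) {
      if (two[i]) c("OD", "OS") else first_eye[i]
    }), use.names = FALSE)
    eff <- config$effects
    n_obs <- length(pidx)
    fd <- matrix(NA_real_, n_obs, nrow(eff))
    clamped <- 0L
    for (r in seq_len(nrow(eff))) {
      b_pat <- stats::rnorm(np, 0, eff$sigma_patient[r])
      e_eye <- stats::rnorm(n_obs, 0, eff$sigma_eye[r])
      mu <- eff$beta0[r] + eff$beta_age[r] * ages[pidx] +
        eff$beta_severity[r] * stages[pidx]
      y <- mu + b_pat[pidx] + e_eye
      out_of_range <- y < 0 | y > 100
      clamped <- clamped + sum(out_of_range)
      fd[, r] <- pmin(pmax(y, 0), 100)
    }
    colnames(fd) <- paste0("fd_", eff$region)
    dat <- data.frame(patient_id = sprintf("P%03d", pidx),
                      eye = eye,
                      age_years = ages[pidx],
                      dr_stage = stages[pidx])
    dat <- cbind(dat, as.data.frame(fd))
    truth <- structure(list(effects = eff, n_eyes = n_obs,
                            n_patients = np, clamped = clamped),
                       class = "generating_truth")
    attr(dat, "generating_truth") <- truth
    dat
  })
}

#' Retrieve the generating truth attached to a simulated cohort
#' @param cohort A [generate_cohort()] result.
#' @return The `generating_truth` object (effects table with `alpha_true`,
#'   counts of eyes/patients/clamping events).
#' @export
generating_truth <- function(cohort) attr(cohort, "generating_truth")

#' Write / read a cohort table as CSV
#'
#' The on-disk schema is one row per eye with columns `patient_id`, `eye`,
#' `age_years`, `dr_stage`, `fd_inner`, `fd_middle`, `fd_outer`, `fd_full`
#' (regions present in the table).
#'
#' @param cohort data.frame of eye observations.
#' @param path CSV path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "eye", "age_years", "dr_stage")
  miss <- setdiff(need, names(dat))
  if (length(miss)) {
    stop_ccfd(paste("cohort CSV is missing columns:",
                    paste(miss, collapse = ", ")), "ccfd_io_error")
  }
  dat
}

#' Build a cohort configuration from a YAML file
#'
#' The YAML keys mirror the [cohort_config()] arguments; `effects` may be
#' given as a list of per-region records.
#'
#' @param path YAML file path.
#' @return A `cohort_config`.
#' @export
cohort_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$effects)) {
    y$effects <- do.call(rbind, lapply(y$effects, as.data.frame))
  }
  args <- y[intersect(names(y),
                      names(formals(cohort_config)))]
  do.call(cohort_config, args)
}
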