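#' Configure an end-to-end study run
#'
#' Bundles every parameter of the images -> FD % -> GEE pipeline. Three
#' modes are supported: `"images"` (a directory of en face PNGs plus a
#' metadata CSV), `"synthetic-cohort"` (simulate FD % tables directly from
#' a [cohort_config()]) and `"synthetic-images"` (simulate angiograms with
#' known truth for a simulated cohort, then quantify them through the
#' imaging pipeline). The defaults reproduce the standard analysis
#' parameters: threshold 0.2, 500 um^2 minimum deficit area,
#' 8-connectivity, 6 mm field.
#'
#' @param mode One of `"images"`, `"synthetic-cohort"`, `"synthetic-images"`.
#' @param image_dir,metadata For `"images"`: image directory and metadata
#'   CSV path (or data.frame) with columns `patient_id`, `eye`,
#'   `age_years`, `dr_stage`, `image` (file name), optional
#'   `center_x`/`center_y` fovea overrides in mm.
#' @param cohort For synthetic modes: a [cohort_config()].
#' @param angiogram For `"synthetic-images"`: an [angiogram_spec()] used
#'   per eye.
#' @param threshold,min_area,connectivity,field_width Imaging parameters;
#'   see [flow_deficit_map()].
#' @param covariates Model covariates for the GEE fits.
#' @param do_fit Fit the per-region GEE models (default TRUE; disable for
#'   small smoke runs with too few clusters).
#' @param age_bin_width Width in years of the age groups used in summaries.
#' @param output_dir Optional directory to write CSV outputs into.
#' @param seed Optional integer seed governing all randomness of the run.
#' @return Object of class `study_config`.
#' @export
study_config <- function(mode = c("images", "synthetic-cohort", "synthetic-images"),
                         image_dir = NULL, metadata = NULL,
                         cohort = NULL, angiogram = NULL,
                         threshold = 0.2, min_area = 500, connectivity = 8,
                         field_width = 6,
                         covariates = c("age_years", "dr_stage"),
                         do_fit = TRUE, age_bin_width = 10,
                         output_dir = NULL, seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "images" && (is.null(image_dir) || is.null(metadata))) {
    stop_ccfd("mode 'images' needs `image_dir` and `metadata`",
              "ccfd_invalid_config")
  }
  if (mode != "images" && is.null(cohort)) {
    stop_ccfd("synthetic modes need a `cohort` configuration",
              "ccfd_invalid_config")
  }
  if (mode == "synthetic-images" && is.null(angiogram)) {
    angiogram <- angiogram_spec(grid_size = 500, field_width = field_width)
  }
  structure(list(mode = mode, image_dir = image_dir, metadata = metadata,
                 cohort = cohort, angiogram = angiogram,
                 threshold = threshold, min_area = min_area,
                 connectivity = connectivity, field_width = field_width,
                 covariates = covariates, do_fit = do_fit,
                 age_bin_width = age_bin_width,
                 output_dir = output_dir, seed = seed),
            class = "study_config")
}

#' Read a study configuration from YAML
#'
#' Top-level keys mirror [study_config()] arguments; `cohort` and
#' `angiogram` sub-maps mirror [cohort_config()] and [angiogram_spec()].
#'
#' @param path YAML file path.
#' @return A `study_config`.
#' @export
study_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$cohort)) {
    if (!is.null(y$cohort$effects)) {
      y$cohort$effects <- do.call(rbind, lapply(y$cohort$effects, as.data.frame))
    }
    y$cohort <- do.call(cohort_config, y$cohort)
  }
  if (!is.null(y$angiogram)) y$angiogram <- do.call(angiogram_spec, y$angiogram)
  do.call(study_config, y[intersect(names(y), names(formals(study_config)))])
}

validate_metadata <- function(md) {
  need <- c("patient_id", "eye", "age_years", "dr_stage")
  miss <- setdiff(need, names(md))
  if (length(miss)) {
    stop_ccfd(paste("metadata is missing columns:", paste(miss, collapse = ", ")),
              "ccfd_invalid_config")
  }
  reason <- rep(NA_character_, nrow(md))
  bad_stage <- !(md$dr_stage %in% 0:4)
  reason[bad_stage] <- "invalid_dr_stage"
  bad_age <- is.na(reason) & (!is.finite(md$age_years) | md$age_years < 0 |
                                md$age_years > 120)
  reason[bad_age] <- "invalid_age"
  bad_eye <- is.na(reason) & !(md$eye %in% c("OD", "OS"))
  reason[bad_eye] <- "invalid_eye"
  dup <- duplicated(md[c("patient_id", "eye")])
  reason[is.na(reason) & dup] <- "duplicate_patient_eye"
  reason
}

#' Quantify a set of en face images into regional FD %
#'
#' For every accepted metadata row: read the image, binarize at the global
#' threshold, label components, drop deficits below the minimum area, and
#' compute the four regional FD % values. Rows failing validation or whose
#' image cannot be read are collected in the rejection log with a
#' machine-readable reason; the run continues.
#'
#' @param metadata data.frame (or CSV path) with columns `patient_id`,
#'   `eye`, `age_years`, `dr_stage`, `image`, optional `center_x`,
#'   `center_y` (mm).
#' @param image_dir Directory containing the image files.
#' @inheritParams study_config
#' @return list with `fd_table` (accepted rows plus `fd_*` columns) and
#'   `log` (data.frame of rejected rows: `row`, `patient_id`, `eye`,
#'   `reason`).
#' @export
quantify_images <- function(metadata, image_dir, threshold = 0.2,
                            min_area = 500, connectivity = 8,
                            field_width = 6) {
  md <- if (is.character(metadata)) utils::read.csv(metadata) else metadata
  if (!"image" %in% names(md)) {
    stop_ccfd("metadata needs an `image` column of file names",
              "ccfd_invalid_config")
  }
  reason <- validate_metadata(md)
  regions_cache <- list()
  fd <- matrix(NA_real_, nrow(md), 4,
               dimnames = list(NULL, paste0("fd_", c("inner", "middle",
                                                     "outer", "full"))))
  for (i in seq_len(nrow(md))) {
    if (!is.na(reason[i])) next
    path <- file.path(image_dir, md$image[i])
    img <- tryCatch(read_angiogram(path, field_width = field_width),
                    error = function(e) NULL)
    if (is.null(img)) { reason[i] <- "unreadable_image"; next }
    ctr <- NULL
    if (all(c("center_x", "center_y") %in% names(md)) &&
        is.finite(md$center_x[i]) && is.finite(md$center_y[i])) {
      ctr <- c(md$center_x[i], md$center_y[i])
    }
    key <- paste(img$geometry$grid_size, paste(ctr, collapse = ","))
    if (is.null(regions_cache[[key]])) {
      rg <- tryCatch(region_masks(img$geometry$grid_size, field_width,
                                  center = ctr),
                     error = function(e) e)
      if (inherits(rg, "error")) { reason[i] <- "region_clipped"; next }
      regions_cache[[key]] <- rg
    }
    mask <- flow_deficit_map(img, threshold = threshold, min_area = min_area,
                             connectivity = connectivity)
    fd[i, ] <- fd_percentage(mask, regions_cache[[key]])
  }
  ok <- is.na(reason)
  fd_table <- cbind(md[ok, setdiff(names(md), colnames(fd)), drop = FALSE],
                    as.data.frame(fd[ok, , drop = FALSE]))
  rownames(fd_table) <- NULL
  list(fd_table = fd_table,
       log = data.frame(row = which(!ok),
                        patient_id = md$patient_id[!ok],
                        eye = md$eye[!ok],
                        reason = reason[!ok]))
}

#' Group-wise FD % summaries (severity groups or age bins)
#'
#' Plain per-group averages with the standard error of the mean,
#' uncorrected for other covariates, per region: the usual descriptive
#' companion to the regression fits.
#'
#' @param fd_table Eye-level table with `fd_*` columns.
#' @param grouping `"severity"` (by `dr_stage`) or `"age"` (decade bins by
#'   default).
#' @param age_bin_width Bin width in years for `grouping = "age"`.
#' @return data.frame with columns `group`, `n`, `region`, `mean_fd`,
#'   `sem` (`NA` for singleton groups). Empty groups are omitted with a
#'   warning.
#' @export
summarize_groups <- function(fd_table, grouping = c("severity", "age"),
                             age_bin_width = 10) {
  grouping <- match.arg(grouping)
  g <- if (grouping == "severity") {
    factor(fd_table$dr_stage, levels = 0:4,
           labels = c("DM no DR", "Mild NPDR", "Moderate NPDR",
                      "Severe NPDR", "PDR"))
  } else {
    lo <- floor(min(fd_table$age_years) / age_bin_width) * age_bin_width
    hi <- ceiling((max(fd_table$age_years) + 1e-9) / age_bin_width) *
      age_bin_width
    cut(fd_table$age_years, seq(lo, hi, by = age_bin_width), right = FALSE)
  }
  if (any(table(g) == 0)) {
    warning("empty groups omitted: ",
            paste(names(which(table(g) == 0)), collapse = ", "))
  }
  regions <- grep("^fd_", names(fd_table), value = TRUE)
  out <- do.call(rbind, lapply(levels(g)[table(g) > 0], function(lv) {
    rows <- fd_table[g == lv, regions, drop = FALSE]
    n <- nrow(rows)
    data.frame(group = lv, n = n, region = sub("^fd_", "", regions),
               mean_fd = vapply(rows, mean, numeric(1)),
               sem = if (n > 1) vapply(rows, stats::sd, numeric(1)) / sqrt(n)
                     else rep(NA_real_, length(regions)),
               row.names = NULL)
  }))
  out
}

#' Run the full study pipeline
#'
#' Orchestrates image quantification (or cohort simulation), group
#' summaries and the four per-region GEE fits, optionally writing all
#' tables as CSV. Deterministic given the configuration and seed.
#'
#' @param config A [study_config()].
#' @return Object of class `study_results`: list with `fd_table`,
#'   `summary_severity`, `summary_age`, `fits` (per-region coefficient
#'   table from [fit_gee_regions()], `NULL` if `do_fit = FALSE`), `log`
#'   (rejected rows), and in synthetic-images mode `truth_fd` (the exact
#'   per-eye ground-truth FD % table for validation).
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  with_seed(config$seed, {
    truth_fd <- NULL
    log <- data.frame(row = integer(), patient_id = character(),
                      eye = character(), reason = character())
    if (config$mode == "images") {
      q <- quantify_images(config$metadata, config$image_dir,
                           threshold = config$threshold,
                           min_area = config$min_area,
                           connectivity = config$connectivity,
                           field_width = config$field_width)
      fd_table <- q$fd_table
      log <- q$log
    } else if (config$mode == "synthetic-cohort") {
      fd_table <- generate_cohort(config$cohort, seed = NULL)
    } else { # synthetic-images
      covs <- generate_cohort(config$cohort, seed = NULL)
      covs <- covs[, c("patient_id", "eye", "age_years", "dr_stage")]
      spec <- config$angiogram
      regions <- region_masks(spec$grid_size, spec$field_width)
      fd <- truth <- matrix(NA_real_, nrow(covs), 4)
      for (i in seq_len(nrow(covs))) {
        syn <- generate_angiogram(spec, seed = NULL)
        mask <- flow_deficit_map(syn$image, threshold = config$threshold,
                                 min_area = config$min_area,
                                 connectivity = config$connectivity)
        fd[i, ] <- fd_percentage(mask, regions)
        keep <- syn$truth$components$area_um2 >= config$min_area
        truth_mask <- matrix(syn$truth$labels %in%
                               syn$truth$components$label[keep],
                             spec$grid_size, spec$grid_size)
        truth[i, ] <- fd_percentage(truth_mask, regions)
      }
      colnames(fd) <- colnames(truth) <-
        paste0("fd_", c("inner", "middle", "outer", "full"))
      fd_table <- cbind(covs, as.data.frame(fd))
      truth_fd <- cbind(covs, as.data.frame(truth))
    }
    fits <- NULL
    if (config$do_fit) {
      fits <- fit_gee_regions(fd_table, covariates = config$covariates)
    }
    res <- structure(list(fd_table = fd_table,
                          summary_severity = summarize_groups(fd_table, "severity"),
                          summary_age = summarize_groups(fd_table, "age",
                                                         config$age_bin_width),
                          fits = fits, log = log, truth_fd = truth_fd,
                          config = config),
                     class = "study_results")
    if (!is.null(config$output_dir)) write_study_results(res, config$output_dir)
    res
  })
}

write_study_results <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  num <- function(d) { # fixed 6-significant-digit CSV output
    isn <- vapply(d, is.numeric, logical(1))
    d[isn] <- lapply(d[isn], signif, 6)
    d
  }
  utils::write.csv(num(res$fd_table), file.path(dir, "fd_table.csv"),
                   row.names = FALSE)
  utils::write.csv(num(res$summary_severity),
                   file.path(dir, "summary_severity.csv"), row.names = FALSE)
  utils::write.csv(num(res$summary_age), file.path(dir, "summary_age.csv"),
                   row.names = FALSE)
  if (!is.null(res$fits)) {
    utils::write.csv(num(res$fits), file.path(dir, "gee_fits.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(res$log, file.path(dir, "log.csv"), row.names = FALSE)
  invisible(dir)
}

#' @export
print.study_results <- function(x, ...) {
  cat(sprintf("study results: %d eyes accepted, %d rejected\n",
              nrow(x$fd_table), nrow(x$log)))
  if (!is.null(x$fits)) {
    cat("per-region GEE fits:\n")
    print(round_df(x$fits[x$fits$term != "(Intercept)", ], 4))
  }
  invisible(x)
}

#' Parameter-recovery experiment over simulated cohorts
#'
#' Simulates `n_reps` cohorts from a known generating model, fits the
#' default per-region GEE to each, and summarises how well the estimates
#' recover the generating coefficients: Monte-Carlo mean and SD of each
#' estimate, mean robust SE, empirical coverage of the truth by
#' `estimate +/- 1.96 robust_se`, and the mean estimated inter-eye
#' correlation. Non-converged replicates are counted and excluded.
#'
#' @param config A [cohort_config()] holding the generating truth.
#' @param n_reps Number of simulated cohorts (>= 2).
#' @param seed Integer seed for the whole experiment.
#' @param covariates Model covariates (default age + severity).
#' @return Object of class `recovery_report`: list with `estimates`
#'   (data.frame: `region`, `term`, `truth`, `mean_est`, `sd_est`,
#'   `mean_se`, `coverage`), `alpha` (data.frame: `region`, `alpha_true`,
#'   `mean_alpha`), `n_reps`, `n_nonconverged`.
#' @export
recovery_experiment <- function(config, n_reps, seed = NULL,
                                covariates = c("age_years", "dr_stage")) {
  stopifnot(inherits(config, "cohort_config"), n_reps >= 2)
  with_seed(seed, {
    eff <- config$effects
    regions <- eff$region
    terms <- c("(Intercept)", covariates)
    est <- array(NA_real_, c(n_reps, length(regions), length(terms)),
                 dimnames = list(NULL, regions, terms))
    se <- est
    alpha_hat <- matrix(NA_real_, n_reps, length(regions),
                        dimnames = list(NULL, regions))
    bad <- logical(n_reps)
    for (b in seq_len(n_reps)) {
      dat <- generate_cohort(config, seed = NULL)
      for (j in seq_along(regions)) {
        fit <- fit_gee(dat, paste0("fd_", regions[j]),
                       covariates = covariates)
        if (!fit$converged) { bad[b] <- TRUE; next }
        est[b, j, ] <- fit$coefficients[terms]
        se[b, j, ] <- fit$robust_se[terms]
        alpha_hat[b, j] <- fit$alpha
      }
    }
    keep <- !bad
    truth_tab <- data.frame(region = rep(regions, each = length(terms)),
                            term = rep(terms, length(regions)))
    truth_tab$truth <- mapply(function(rg, tm) {
      row <- eff[eff$region == rg, ]
      switch(tm, "(Intercept)" = row$beta0, age_years = row$beta_age,
             dr_stage = row$beta_severity, NA_real_)
    }, truth_tab$region, truth_tab$term)
    truth_tab$mean_est <- mapply(function(rg, tm) mean(est[keep, rg, tm]),
                                 truth_tab$region, truth_tab$term)
    truth_tab$sd_est <- mapply(function(rg, tm) stats::sd(est[keep, rg, tm]),
                               truth_tab$region, truth_tab$term)
    truth_tab$mean_se <- mapply(function(rg, tm) mean(se[keep, rg, tm]),
                                truth_tab$region, truth_tab$term)
    truth_tab$coverage <- mapply(function(rg, tm) {
      tr <- truth_tab$truth[truth_tab$region == rg & truth_tab$term == tm]
      mean(abs(est[keep, rg, tm] - tr) <= 1.96 * se[keep, rg, tm])
    }, truth_tab$region, truth_tab$term)
    alpha_tab <- data.frame(region = regions,
                            alpha_true = eff$alpha_true,
                            mean_alpha = colMeans(alpha_hat[keep, , drop = FALSE]))
    structure(list(estimates = truth_tab, alpha = alpha_tab,
                   n_reps = n_reps, n_nonconverged = sum(bad)),
              class = "recovery_report")
  })
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("recovery over %d cohorts (%d non-converged, excluded)\n",
              x$n_reps, x$n_nonconverged))
  print(round_df(x$estimates[x$estimates$term != "(Intercept)", ], 4))
  print(round_df(x$alpha, 4))
  invisible(x)
}
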