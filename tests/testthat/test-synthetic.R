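# pitch of 12 um on a small grid: field chosen so 1000 * field / grid = 12
small_spec <- function(n_components, sizes, grid = 96, seed = 1, ...) {
  angiogram_spec(grid_size = grid, field_width = grid * 12 / 1000,
                 n_components = n_components, component_sizes = sizes,
                 seed = seed, ...)
}

test_that("binarizing a synthetic angiogram recovers the truth exactly", {
  for (seed in c(3, 4)) {
    syn <- generate_angiogram(small_spec(25, list(family = "poisson",
                                                  lambda = 4, min = 1),
                                         seed = seed))
    bm <- binarize(syn$image, 0.2)
    expect_identical(bm$mask, syn$truth$mask)
    # labeling recovers the placed components one-to-one
    cs <- label_components(bm)
    expect_equal(nrow(cs$components), 25)
    expect_equal(sort(cs$components$pixel_count),
                 sort(syn$truth$components$pixel_count))
  }
})

test_that("an empty spec yields an all-flow image with zero FD everywhere", {
  syn <- generate_angiogram(angiogram_spec(grid_size = 500, n_components = 0,
                                           seed = 5))
  expect_false(any(syn$truth$mask))
  mask <- flow_deficit_map(syn$image)
  expect_equal(unname(fd_percentage(mask, region_masks(500, 6))), rep(0, 4))
})

test_that("the 500 um^2 filter keeps a 5-px and drops a 3-px component at 12 um pitch", {
  syn <- generate_angiogram(small_spec(2, c(3L, 5L), seed = 9))
  expect_equal(sort(syn$truth$components$area_um2), c(432, 720))
  filtered <- flow_deficit_map(syn$image, min_area = 500)
  expect_equal(nrow(filtered$components), 1)
  expect_equal(filtered$components$pixel_count, 5)
  expect_equal(sum(filtered$mask), 5)
})

test_that("angiogram generation is seed-deterministic and seed-sensitive", {
  s <- small_spec(15, list(family = "uniform", min = 1, max = 6))
  a <- generate_angiogram(s, seed = 42)
  b <- generate_angiogram(s, seed = 42)
  c <- generate_angiogram(s, seed = 43)
  expect_identical(a$image$values, b$image$values)
  expect_identical(a$truth$labels, b$truth$labels)
  expect_false(identical(a$truth$mask, c$truth$mask))
})

test_that("over-dense specs fail with a generation error", {
  expect_error(
    generate_angiogram(small_spec(40, rep(10L, 40), grid = 16, seed = 1,
                                  max_tries = 5)),
    class = "ccfd_generation_error")
})

test_that("band invariants are enforced at spec construction", {
  expect_error(angiogram_spec(deficit_band = c(0, 0.25)),
               class = "ccfd_invalid_argument")
  expect_error(angiogram_spec(background_band = c(0.15, 1)),
               class = "ccfd_invalid_argument")
  expect_error(angiogram_spec(n_components = -1),
               class = "ccfd_invalid_argument")
})

test_that("written angiograms round-trip to the same deficit mask", {
  syn <- generate_angiogram(small_spec(10, list(family = "poisson",
                                                lambda = 3, min = 1),
                                       seed = 12))
  path <- file.path(tempdir(), "syn.png")
  write_synthetic_angiogram(syn, path)
  img <- read_angiogram(path, field_width = syn$spec$field_width)
  expect_identical(binarize(img, 0.2)$mask, syn$truth$mask)
  truth <- jsonlite::read_json(paste0(path, ".truth.json"))
  expect_equal(length(truth$components), 10)
  unlink(c(path, paste0(path, ".truth.json")))
})

test_that("cohort layout matches the configured stage counts and eye count", {
  cfg <- cohort_config(seed = 2)
  dat <- generate_cohort(cfg)
  per_patient <- dat[!duplicated(dat$patient_id), ]
  expect_equal(unname(table(per_patient$dr_stage)),
               table(rep(0:4, c(33, 17, 8, 10, 22))) |> unname())
  expect_true(all(dat$eye %in% c("OD", "OS")))
  expect_true(all(dat$age_years >= 18 & dat$age_years <= 100))
  # both eyes of a patient share age and stage
  split_ok <- tapply(paste(dat$age_years, dat$dr_stage), dat$patient_id,
                     function(v) length(unique(v)) == 1)
  expect_true(all(split_ok))
  # expected cohort size ~ 160 eyes
  sizes <- vapply(1:30, function(i) nrow(generate_cohort(cfg, seed = 100 + i)),
                  numeric(1))
  expect_true(abs(mean(sizes) - 160) < 4)
})

test_that("invalid cohort configurations are rejected", {
  expect_error(cohort_config(stage_counts = c(33, 17, 8, 10, 21)),
               class = "ccfd_invalid_config")
  eff <- default_region_effects(); eff$sigma_total <- -1
  expect_error(cohort_config(effects = eff), class = "ccfd_invalid_config")
})

test_that("noise-free cohorts are exactly linear in age and stage", {
  eff <- default_region_effects()
  eff$sigma_total <- 0
  dat <- generate_cohort(cohort_config(effects = eff, seed = 6))
  for (r in c("inner", "full")) {
    ols <- lm(stats::reformulate(c("age_years", "dr_stage"),
                                 paste0("fd_", r)), dat)
    row <- eff[eff$region == r, ]
    expect_equal(unname(coef(ols)),
                 c(row$beta0, row$beta_age, row$beta_severity),
                 tolerance = 1e-8)
  }
})

test_that("sigma_patient = 0 yields uncorrelated fellow eyes", {
  eff <- default_region_effects()[1, ]
  eff$alpha <- 0; eff$sigma_total <- 1
  cfg <- cohort_config(n_patients = 10000,
                       stage_counts = c(10000, 0, 0, 0, 0),
                       both_eyes_probability = 1, effects = eff, seed = 8)
  dat <- generate_cohort(cfg)
  resid <- dat$fd_inner - mean(dat$fd_inner) -
    cov(dat$fd_inner, dat$age_years) / var(dat$age_years) *
      (dat$age_years - mean(dat$age_years))
  od <- resid[dat$eye == "OD"]; os <- resid[dat$eye == "OS"]
  expect_lt(abs(cor(od, os)), 0.05)
})

test_that("variance components are recovered from cohort moments", {
  eff <- data.frame(region = "inner", beta0 = 30, beta_age = 0,
                    beta_severity = 0, sigma_patient = 2, sigma_eye = 3)
  cfg <- cohort_config(n_patients = 5000, stage_counts = c(5000, 0, 0, 0, 0),
                       both_eyes_probability = 1, effects = eff, seed = 13)
  dat <- generate_cohort(cfg)
  wide <- reshape(dat[c("patient_id", "eye", "fd_inner")],
                  idvar = "patient_id", timevar = "eye", direction = "wide")
  d <- wide$fd_inner.OD - wide$fd_inner.OS
  m <- (wide$fd_inner.OD + wide$fd_inner.OS) / 2
  sigma_eye_hat <- sqrt(var(d) / 2)
  sigma_patient_hat <- sqrt(var(m) - sigma_eye_hat^2 / 2)
  expect_lt(abs(sigma_eye_hat - 3) / 3, 0.05)
  expect_lt(abs(sigma_patient_hat - 2) / 2, 0.05)
})

test_that("clamping events are counted in the generating truth", {
  eff <- data.frame(region = "inner", beta0 = 0.5, beta_age = 0,
                    beta_severity = 0, sigma_patient = 0, sigma_eye = 5)
  cfg <- cohort_config(n_patients = 200, stage_counts = c(200, 0, 0, 0, 0),
                       effects = eff, seed = 14)
  dat <- generate_cohort(cfg)
  tr <- generating_truth(dat)
  expect_gt(tr$clamped, 0)
  expect_true(all(dat$fd_inner >= 0))
  # defaults essentially never clamp
  expect_equal(generating_truth(generate_cohort(cohort_config(seed = 15)))$clamped, 0)
})

test_that("cohort generation is deterministic for a fixed seed", {
  cfg <- cohort_config(seed = 77)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  expect_false(identical(generate_cohort(cfg, seed = 78)$fd_inner,
                         generate_cohort(cfg)$fd_inner))
})
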