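#' Specification of a synthetic phantom cohort
#'
#' Defines the generative model for a cohort of contrast-CT-like tumor
#' phantoms with a planted texture-outcome signal. Each patient carries
#' three latent standard-normal texture factors `z1..z3`:
#' `z1` scales the spatial correlation length of a fine Gaussian random
#' field (coarser texture for larger `z1`), `z2` scales the amplitude of
#' that field (stronger local contrast), and `z3` scales the amplitude of a
#' coarse blob field. Survival times follow an exponential
#' proportional-hazards model `h0 * exp(beta' z)` with independent uniform
#' censoring calibrated to `censor_rate`; recurrence labels are Bernoulli
#' with a logistic model on `z`. Clinical covariates (gender, T stage,
#' N stage, site, resection) are sampled from realistic marginal frequencies
#' and are independent of the latent factors by default, so a clinical-only
#' model is uninformative by construction.
#'
#' @param n_patients number of phantoms (>= 6).
#' @param image_shape voxel grid, length-3 integer (each >= 16).
#' @param voxel_size_mm voxel size in mm (positive triple).
#' @param texture_params list of generative knobs: `base` (mean intensity),
#'   `field_sd` (sd of the fine correlated field), `corr_length` (its
#'   correlation length in voxels at `z1 = 0`), `corr_sens` / `amp_sens` /
#'   `coarse_sens` (log-scale sensitivities to `z1`, `z2`, `z3`),
#'   `coarse_sd` (sd of the coarse field), `white_sd` (uncorrelated voxel
#'   noise sd).
#' @param effect_sizes length-3 log-hazard coefficients on the latent factors.
#' @param baseline_hazard exponential baseline hazard per day.
#' @param censor_rate target censored fraction in `[0, 1)`.
#' @param recurrence_intercept,recurrence_slopes logistic coefficients for
#'   the recurrence label.
#' @param clinical_signal optional strength of a weak association between
#'   clinical covariates and the first latent factor (0 = independent).
#' @param seed integer RNG seed for [generate_cohort()].
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 74,
                        image_shape = c(28L, 28L, 28L),
                        voxel_size_mm = c(2, 2, 2),
                        texture_params = list(),
                        effect_sizes = c(1, 1, 1),
                        baseline_hazard = log(2) / 450,
                        censor_rate = 0.07,
                        recurrence_intercept = -0.4,
                        recurrence_slopes = c(1, 1, 1),
                        clinical_signal = 0,
                        seed = 1L) {
  tp <- utils::modifyList(list(base = 60, field_sd = 12, corr_length = 1.1,
                               corr_sens = 0.30, amp_sens = 0.35,
                               coarse_sd = 7, coarse_sens = 0.35,
                               white_sd = 3), texture_params)
  if (n_patients < 6) stop("cohort_spec: n_patients must be >= 6")
  if (censor_rate < 0 || censor_rate >= 1) stop("cohort_spec: censor_rate must be in [0, 1)")
  if (any(image_shape < 16)) stop("cohort_spec: image_shape must be >= 16 voxels per axis")
  if (any(voxel_size_mm <= 0)) stop("cohort_spec: voxel size must be positive")
  if (any(unlist(tp[c("field_sd", "coarse_sd", "white_sd")]) < 0))
    stop("cohort_spec: noise standard deviations must be non-negative")
  structure(list(n_patients = as.integer(n_patients),
                 image_shape = as.integer(image_shape),
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 texture_params = tp,
                 effect_sizes = as.numeric(effect_sizes),
                 baseline_hazard = baseline_hazard,
                 censor_rate = censor_rate,
                 recurrence_intercept = recurrence_intercept,
                 recurrence_slopes = as.numeric(recurrence_slopes),
                 clinical_signal = clinical_signal,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate one tumor phantom
#'
#' Draws an ellipsoidal mask with randomized semi-axes and fills the volume
#' with `base + fine field + coarse field + white noise`, where the fine
#' field's correlation length grows with `z1`, its amplitude with `z2`, and
#' the coarse field's amplitude with `z3` (all log-linear), so texture
#' features such as GLCM contrast and NGTDM coarseness vary systematically
#' with the latent factors. Degenerate masks (< 27 voxels) are rejected and
#' the axes resampled.
#'
#' @param latent_factors length-3 numeric latent texture factors.
#' @param image_shape voxel grid (each axis >= 16).
#' @param texture_params see [cohort_spec()].
#' @param seed integer seed; the draw is reproducible bit-for-bit.
#' @return list with `volume` and `mask` (3-D arrays).
#' @export
generate_phantom <- function(latent_factors = c(0, 0, 0),
                             image_shape = c(28L, 28L, 28L),
                             texture_params = cohort_spec()$texture_params,
                             seed = 1L) {
  if (any(image_shape < 16)) stop("generate_phantom: image_shape must be >= 16")
  tp <- utils::modifyList(cohort_spec()$texture_params, texture_params)
  z <- rep(as.numeric(latent_factors), length.out = 3)
  d <- as.integer(image_shape)
  set.seed(seed)

  # ellipsoid mask; reject degenerate draws
  ctr <- d / 2 + runif(3, -1, 1)
  mask <- NULL
  for (try in 1:20) {
    ax <- runif(3, 3.2, 0.28 * min(d))
    gx <- (seq_len(d[1]) - ctr[1]) / ax[1]
    gy <- (seq_len(d[2]) - ctr[2]) / ax[2]
    gz <- (seq_len(d[3]) - ctr[3]) / ax[3]
    r2 <- outer(outer(gx^2, gy^2, "+"), gz^2, "+")
    cand <- array(as.integer(r2 <= 1), d)
    if (sum(cand) >= 27L) { mask <- cand; break }
  }
  if (is.null(mask)) stop("generate_phantom: could not draw a non-degenerate mask")

  corr_len <- tp$corr_length * exp(tp$corr_sens * z[1])
  amp <- tp$field_sd * exp(tp$amp_sens * z[2])
  coarse_amp <- tp$coarse_sd * exp(tp$coarse_sens * z[3])

  vol <- array(tp$base, d)
  if (tp$field_sd > 0) {
    f <- smooth_gaussian(array(rnorm(prod(d)), d), corr_len)
    s <- sd(f)
    if (s > 0) vol <- vol + amp * f / s
  }
  if (tp$coarse_sd > 0) {
    g <- smooth_gaussian(array(rnorm(prod(d)), d), 2.5)
    s <- sd(g)
    if (s > 0) vol <- vol + coarse_amp * g / s
  }
  if (tp$white_sd > 0) vol <- vol + array(rnorm(prod(d), 0, tp$white_sd), d)
  list(volume = vol, mask = mask)
}

#' Generate a phantom cohort with planted outcome signal
#'
#' Draws latent factors, images, clinical covariates and both outcomes
#' (survival with censoring, recurrence label) according to a
#' [cohort_spec()]. Censoring is uniform on `[0, c]` with `c` calibrated on
#' the drawn event times so the expected censored fraction matches
#' `censor_rate`; if the achieved fraction deviates by more than 0.05 a
#' warning reports it.
#'
#' @param spec a [cohort_spec()].
#' @return Object of class `phantom_cohort`: list with `volumes`, `masks`
#'   (lists of 3-D arrays), `clinical` (tibble: patient_id, gender, t_stage,
#'   n_stage, site, resection; integer codes), `outcomes` (tibble:
#'   patient_id, time, event, recurrence), `latent` (n x 3 matrix), `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  set.seed(spec$seed)
  z <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("z1", "z2", "z3")))
  phantom_seeds <- sample.int(.Machine$integer.max - 1L, n)

  volumes <- vector("list", n)
  masks <- vector("list", n)
  for (i in seq_len(n)) {
    ph <- generate_phantom(z[i, ], spec$image_shape, spec$texture_params,
                           seed = phantom_seeds[i])
    volumes[[i]] <- ph$volume
    masks[[i]] <- ph$mask
  }

  set.seed(spec$seed + 1L)
  eta <- drop(z %*% spec$effect_sizes)
  t_true <- rexp(n, rate = 1) / (spec$baseline_hazard * exp(eta))
  if (spec$censor_rate > 0) {
    target <- spec$censor_rate
    # censored iff C < T; with C ~ U(0, c), P(C < T | T) = min(T/c, 1)
    crate <- function(cc) mean(pmin(t_true / cc, 1)) - target
    cmax <- uniroot(crate, lower = min(t_true) * 1e-3,
                    upper = max(t_true) * 1e4, tol = 1e-6)$root
    cens <- runif(n, 0, cmax)
    time <- pmin(t_true, cens)
    event <- as.integer(t_true <= cens)
    achieved <- 1 - mean(event)
    # tolerance: calibration slack plus binomial noise at this n
    if (abs(achieved - target) > 0.05 + 2.5 * sqrt(target * (1 - target) / n))
      warning(sprintf("generate_cohort: achieved censor rate %.3f vs target %.3f",
                      achieved, target))
  } else {
    time <- t_true
    event <- rep(1L, n)
  }
  time <- pmax(time, 1e-3)

  recur <- rbinom(n, 1, plogis(spec$recurrence_intercept +
                                 drop(z %*% spec$recurrence_slopes)))

  clinical <- sample_clinical(n, z, spec$clinical_signal)
  ids <- sprintf("P%03d", seq_len(n))
  clinical <- tibble::add_column(clinical, patient_id = ids, .before = 1)
  outcomes <- tibble::tibble(patient_id = ids, time = time, event = event,
                             recurrence = recur)
  structure(list(volumes = volumes, masks = masks, clinical = clinical,
                 outcomes = outcomes, latent = z, spec = spec),
            class = "phantom_cohort")
}

# Marginal frequencies mirror a realistic SBRT pancreatic-cancer cohort:
# 60.8% male; T stage T2/T3/T4 = 6.8/59.5/33.8%; N1 44.6%; site
# head/neck/tail/body/uncinate = 79.7/4.1/4.1/8.1/4.1%; resection 31.1%.
# Codes: gender 0 = female, 1 = male; T 0 = T2, 1 = T3, 2 = T4; N 0/1;
# site 0 = head, 1 = neck, 2 = tail, 3 = body, 4 = uncinate; resection 0/1.
sample_clinical <- function(n, z, clinical_signal = 0) {
  shift <- plogis(clinical_signal * z[, 1]) - 0.5   # 0 when signal is off
  draw <- function(p) {
    pr <- pmin(pmax(p + shift, 0.01), 0.99)
    as.integer(runif(n) < pr)
  }
  tibble::tibble(
    gender = draw(0.608),
    t_stage = as.integer(cut(runif(n), c(-Inf, 0.068, 0.663, Inf),
                             labels = FALSE)) - 1L,
    n_stage = draw(0.446),
    site = {
      u <- runif(n)
      as.integer(cut(u, c(-Inf, 0.797, 0.838, 0.879, 0.960, Inf),
                     labels = FALSE)) - 1L
    },
    resection = draw(0.311))
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat("<phantom_cohort> ", length(x$volumes), " phantoms, grid ",
      paste(x$spec$image_shape, collapse = "x"), " @ ",
      paste(x$spec$voxel_size_mm, collapse = "x"), " mm\n", sep = "")
  cat("  events: ", sum(x$outcomes$event), ", recurrences: ",
      sum(x$outcomes$recurrence), "\n", sep = "")
  invisible(x)
}

#' Write a phantom cohort to disk
#'
#' Writes one NRRD pair per patient (`<id>_volume.nrrd`, `<id>_mask.nrrd`),
#' the clinical and outcome tables as CSV, and a JSON manifest holding the
#' generating spec and the latent factors.
#'
#' @param cohort a `phantom_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- cohort$spec$voxel_size_mm
  for (i in seq_along(cohort$volumes)) {
    id <- cohort$clinical$patient_id[i]
    write_volume(image_volume(cohort$volumes[[i]], sp),
                 file.path(dir, paste0(id, "_volume.nrrd")))
    write_volume(image_volume(cohort$masks[[i]], sp),
                 file.path(dir, paste0(id, "_mask.nrrd")))
  }
  write.csv(cohort$clinical, file.path(dir, "clinical.csv"), row.names = FALSE)
  write.csv(cohort$outcomes, file.path(dir, "outcomes.csv"), row.names = FALSE)
  manifest <- list(spec = unclass(cohort$spec),
                   latent = as.data.frame(cohort$latent),
                   patient_id = cohort$clinical$patient_id)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
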