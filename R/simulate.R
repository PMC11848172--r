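#' Default spatial effect patches
#'
#' Focal thinning patches standing in for the parietal/temporal pattern of
#' Down-syndrome Alzheimer cortical involvement: a larger "parietal-like" and
#' a smaller "temporal-like" geodesic disc per hemisphere, with thinning
#' growing across stages and right-hemisphere magnitudes 1.25x the left
#' (rightward asymmetry). Magnitudes are generator defaults in mm, zero in
#' the amyloid-negative reference group.
#'
#' @param right_asymmetry Right/left thinning magnitude ratio (default 1.25).
#' @return List of patch definitions: `hemisphere`, `name`, `direction`
#'   (unit vector resolved to the nearest mesh vertex), `radius_mm`,
#'   `thin_mm` (named per-group thinning in mm).
#' @export
default_effect_patches <- function(right_asymmetry = 1.25) {
  base <- list(
    list(name = "parietal", direction = c(-0.35, -0.65, 0.68),
         radius_mm = 30, thin_mm = c("CS-" = 0, "CS+" = 0.10, "IMP+" = 0.40)),
    list(name = "temporal", direction = c(0.75, -0.35, -0.56),
         radius_mm = 20, thin_mm = c("CS-" = 0, "CS+" = 0.06, "IMP+" = 0.25))
  )
  out <- list()
  for (p in base) {
    for (h in c("left", "right")) {
      q <- p
      q$hemisphere <- h
      if (h == "right") q$thin_mm <- q$thin_mm * right_asymmetry
      out[[length(out) + 1L]] <- q
    }
  }
  out
}

#' Default subcortical volume trajectories
#'
#' Region means/SDs (mm^3) for an adult Down-syndrome population and additive
#' per-stage shifts. The stagewise pattern is qualitative by design:
#' hippocampus declines monotonically across stages, accumbens shifts almost
#' entirely between the amyloid-negative and preclinical stages, putamen
#' almost entirely between the preclinical and symptomatic stages; caudate is
#' a deliberately poor discriminator.
#'
#' @return Data frame with columns `region`, `mean_mm3`, `sd_mm3`,
#'   `shift_csp` (CS+ minus CS-), `shift_imp` (IMP+ minus CS-).
#' @export
default_subcortical_params <- function() {
  data.frame(
    region = SUBCORTICAL_REGIONS,
    mean_mm3 = c(3500, 1300, 450, 3200, 4300, 1500, 6500),
    sd_mm3 = c(280, 110, 45, 260, 340, 120, 520),
    shift_csp = c(-280, -80, -55, -10, -85, -30, -190),
    shift_imp = c(-520, -130, -60, -60, -510, -60, -390)
  )
}

#' Synthetic cohort configuration
#'
#' Defaults reproduce the demographic structure of the reference
#' Down-syndrome Alzheimer cohort: group sizes 106/45/27
#' (amyloid-negative stable / preclinical / symptomatic), ages 36.20 (6.20),
#' 48.91 (6.18), 51.93 (4.33) years, centiloids 1.05 (7.42), 51.96 (23.82),
#' 76.37 (35.32) (truncated to the correct side of the tracer positivity
#' threshold per group), male fractions 54/106, 28/45, 19/27, APOE e4 carrier
#' fractions 22/106, 6/45, 8/27, and a 15/12 MCI/dementia split inside the
#' impaired group. Thickness maps are a 2.5 mm baseline plus smooth spatial
#' noise (0.25 mm SD, 20 mm FWHM), a small negative age slope, and the
#' per-group patch thinning of [default_effect_patches()].
#'
#' @param sizes Named group sizes.
#' @param age_mean,age_sd Per-group age distributions (years).
#' @param male_frac,apoe_frac Per-group male / APOE e4 carrier fractions.
#' @param centiloid_mean,centiloid_sd Per-group centiloid distributions.
#' @param imp_split Named MCI-DS / DEM counts inside the impaired group.
#' @param pib_frac Fraction of subjects scanned with PiB (the rest get
#'   florbetapir).
#' @param mesh_order Icosphere subdivision order of the shared meshes.
#' @param baseline_mm,noise_sd_mm,noise_fwhm_mm Thickness field parameters:
#'   baseline (mm), per-vertex SD of the smooth noise field (mm), noise
#'   smoothness (FWHM mm).
#' @param age_slope Thickness change per year of age (mm/year).
#' @param patches Effect-patch list ([default_effect_patches()]).
#' @param subcortical Region parameter table
#'   ([default_subcortical_params()]).
#' @param icv_mean,icv_sd Intracranial volume distribution (mm^3).
#' @param icv_slope_scale Regional volume-on-ICV slope as
#'   `mean_mm3 / icv_mean` times this factor (default 1: proportional
#'   scaling).
#' @param seed Generator seed.
#' @return `cohort_config` list.
#' @export
cohort_config <- function(sizes = c("CS-" = 106L, "CS+" = 45L, "IMP+" = 27L),
                          age_mean = c(36.20, 48.91, 51.93),
                          age_sd = c(6.20, 6.18, 4.33),
                          male_frac = c(54 / 106, 28 / 45, 19 / 27),
                          apoe_frac = c(22 / 106, 6 / 45, 8 / 27),
                          centiloid_mean = c(1.05, 51.96, 76.37),
                          centiloid_sd = c(7.42, 23.82, 35.32),
                          imp_split = c("MCI-DS" = 15L, "DEM" = 12L),
                          pib_frac = 115 / 178,
                          mesh_order = 4L,
                          baseline_mm = 2.5,
                          noise_sd_mm = 0.25,
                          noise_fwhm_mm = 20,
                          age_slope = -0.005,
                          patches = default_effect_patches(),
                          subcortical = default_subcortical_params(),
                          icv_mean = 1.15e6, icv_sd = 1e5,
                          icv_slope_scale = 1,
                          seed = 1L) {
  groups <- c("CS-", "CS+", "IMP+")
  sizes <- stats::setNames(as.integer(sizes), groups)
  if (any(sizes < 0L)) stopf("group sizes must be >= 0")
  if (any(age_sd < 0) || any(centiloid_sd < 0) || noise_sd_mm < 0 ||
      icv_sd < 0)
    stopf("SDs must be >= 0")
  if (any(male_frac < 0 | male_frac > 1) || any(apoe_frac < 0 | apoe_frac > 1))
    stopf("fractions must lie in [0, 1]")
  for (p in patches) if (p$radius_mm <= 0) stopf("patch radii must be > 0")
  structure(list(
    groups = groups, sizes = sizes,
    age_mean = stats::setNames(age_mean, groups),
    age_sd = stats::setNames(age_sd, groups),
    male_frac = stats::setNames(male_frac, groups),
    apoe_frac = stats::setNames(apoe_frac, groups),
    centiloid_mean = stats::setNames(centiloid_mean, groups),
    centiloid_sd = stats::setNames(centiloid_sd, groups),
    imp_split = imp_split, pib_frac = pib_frac,
    mesh_order = as.integer(mesh_order),
    baseline_mm = baseline_mm, noise_sd_mm = noise_sd_mm,
    noise_fwhm_mm = noise_fwhm_mm, age_slope = age_slope,
    patches = patches, subcortical = subcortical,
    icv_mean = icv_mean, icv_sd = icv_sd,
    icv_slope_scale = icv_slope_scale,
    seed = as.integer(seed)), class = "cohort_config")
}

rnorm_truncated <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    draw <- stats::rnorm(length(todo), mean, sd)
    ok <- draw >= lower & draw < upper
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}

exact_count_flags <- function(n, frac) {
  k <- round(frac * n)
  sample(rep(c(TRUE, FALSE), c(k, n - k)))
}

#' Generate a synthetic staged cohort
#'
#' Draws demographics per group from the configured distributions (centiloids
#' truncated so the amyloid-negative group falls below its tracer's
#' positivity threshold and the positive groups at or above it; sex and APOE
#' carriage hit the configured counts exactly), builds per-subject thickness
#' maps on shared left/right icospheres as baseline + smooth spatial noise +
#' age slope - stagewise patch thinning, and simulates subcortical volumes
#' with region-specific stage shifts and proportional ICV scaling.
#' Deterministic given `config$seed`; thickness draws below 0.5 mm are
#' truncated there with a warning.
#'
#' @param config A [cohort_config()].
#' @return `ds_cohort`: list with `subjects` (one row per subject: `id`,
#'   `stage`, `clinical_status`, `age`, `sex`, `apoe_e4`, `tracer`,
#'   `centiloid`, `icv`), `thickness` (named list of V x n matrices, columns
#'   ordered as `subjects`), `volumes` (long table), `meshes`, `truth`
#'   (per-hemisphere ground-truth patch masks and configured thinning) and
#'   `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  meshes <- list(left = build_icosphere(config$mesh_order, "left"),
                 right = build_icosphere(config$mesh_order, "right"))

  subj <- do.call(rbind, lapply(config$groups, function(g) {
    n <- config$sizes[[g]]
    if (n == 0L) return(NULL)
    tracer <- ifelse(exact_count_flags(n, config$pib_frac), "PiB",
                     "florbetapir")
    thr <- amyloid_thresholds[tracer]
    centiloid <- if (g == "CS-") {
      vapply(thr, function(th) rnorm_truncated(1, config$centiloid_mean[[g]],
                                               config$centiloid_sd[[g]],
                                               upper = th), numeric(1))
    } else {
      vapply(thr, function(th) rnorm_truncated(1, config$centiloid_mean[[g]],
                                               config$centiloid_sd[[g]],
                                               lower = th), numeric(1))
    }
    clinical <- if (g == "IMP+") {
      k <- round(n * config$imp_split[["MCI-DS"]] / sum(config$imp_split))
      sample(rep(c("MCI-DS", "DEM"), c(k, n - k)))
    } else {
      rep("CS", n)
    }
    data.frame(
      group = g,
      clinical_status = clinical,
      age = stats::rnorm(n, config$age_mean[[g]], config$age_sd[[g]]),
      sex = ifelse(exact_count_flags(n, config$male_frac[[g]]), "male",
                   "female"),
      apoe_e4 = exact_count_flags(n, config$apoe_frac[[g]]),
      tracer = tracer,
      centiloid = unname(centiloid))
  }))
  n_total <- nrow(subj)
  subj$id <- sprintf("S%04d", seq_len(n_total))
  staged <- assign_stage(classify_amyloid(subj$tracer, subj$centiloid),
                         subj$clinical_status)
  stopifnot(all(as.character(staged$stage) == subj$group))
  subj$stage <- staged$stage
  subj$icv <- stats::rnorm(n_total, config$icv_mean, config$icv_sd)
  subj <- subj[, c("id", "stage", "clinical_status", "age", "sex", "apoe_e4",
                   "tracer", "centiloid", "icv")]

  # ground-truth patch structure, resolved per hemisphere
  truth <- lapply(meshes, function(mesh) {
    ps <- Filter(function(p) p$hemisphere == mesh$hemisphere, config$patches)
    masks <- lapply(ps, function(p)
      geodesic_disc(mesh, nearest_vertex(mesh, p$direction), p$radius_mm))
    thin <- lapply(ps, function(p) p$thin_mm)
    union <- Reduce(`|`, masks, init = logical(n_vertices(mesh)))
    list(patches = ps, masks = masks, thin = thin, union = union)
  })

  age_centered <- subj$age - mean(subj$age)
  thickness <- lapply(names(meshes), function(h) {
    mesh <- meshes[[h]]
    V <- n_vertices(mesh)
    M <- smoothing_operator(mesh, config$noise_fwhm_mm)
    noise <- as.matrix(M %*% matrix(stats::rnorm(V * n_total), V, n_total))
    scale <- config$noise_sd_mm / sqrt(Matrix::rowSums(M^2))
    noise <- noise * scale
    thick <- config$baseline_mm + noise +
      matrix(config$age_slope * age_centered, V, n_total, byrow = TRUE)
    tr <- truth[[h]]
    for (i in seq_along(tr$masks)) {
      drop_mm <- tr$thin[[i]][as.character(subj$stage)]
      thick[tr$masks[[i]], ] <- thick[tr$masks[[i]], ] -
        matrix(drop_mm, sum(tr$masks[[i]]), n_total, byrow = TRUE)
    }
    low <- thick < 0.5
    if (any(low)) {
      warnf("%d thickness draw(s) below 0.5 mm truncated", sum(low))
      thick[low] <- 0.5
    }
    colnames(thick) <- subj$id
    thick
  })
  names(thickness) <- names(meshes)

  sc <- config$subcortical
  slope <- config$icv_slope_scale * sc$mean_mm3 / config$icv_mean
  volumes <- do.call(rbind, lapply(seq_len(nrow(sc)), function(r) {
    do.call(rbind, lapply(c("left", "right"), function(side) {
      shift <- c("CS-" = 0, "CS+" = sc$shift_csp[r],
                 "IMP+" = sc$shift_imp[r])[as.character(subj$stage)]
      v <- sc$mean_mm3[r] + shift +
        slope[r] * (subj$icv - config$icv_mean) +
        stats::rnorm(n_total, 0, sc$sd_mm3[r])
      v <- pmax(v, 1)
      data.frame(id = subj$id, region = sc$region[r], side = side,
                 volume = v)
    }))
  }))

  structure(list(subjects = subj, thickness = thickness, volumes = volumes,
                 meshes = meshes, truth = truth, config = config),
            class = "ds_cohort")
}

#' @export
print.ds_cohort <- function(x, ...) {
  tab <- table(x$subjects$stage)
  cat(sprintf("ds_cohort: %d subjects (%s) on order-%d icospheres\n",
              nrow(x$subjects),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
              x$config$mesh_order))
  invisible(x)
}

#' Re-derive stage labels of a cohort from its measurements
#'
#' Applies [classify_amyloid()] and [assign_stage()] to the subject table and
#' stores the result in `subjects$stage`.
#'
#' @param cohort A `ds_cohort` (or compatible list).
#' @return The cohort with refreshed stage labels.
#' @export
stage_cohort <- function(cohort) {
  st <- assign_stage(classify_amyloid(cohort$subjects$tracer,
                                      cohort$subjects$centiloid),
                     cohort$subjects$clinical_status)
  cohort$subjects$stage <- st$stage
  cohort
}

#' Default configuration of the contrast variant
#'
#' A stand-in for a second disease variant with more focal, symmetric and
#' milder cortical effects than the primary configuration: a single
#' parietal-like patch per hemisphere, equal magnitude on both sides.
#'
#' @param mesh_order Icosphere order (must match the primary config for map
#'   comparison).
#' @param seed Generator seed.
#' @return A [cohort_config()].
#' @export
variant_config <- function(mesh_order = 4L, seed = 2L) {
  # focal patch with a plateau deep enough (0.45 mm) that its >= 0.2 mm
  # thinning mask survives 10 mm surface smoothing
  patches <- list()
  for (h in c("left", "right")) {
    patches[[length(patches) + 1L]] <- list(
      name = "parietal", direction = c(-0.35, -0.65, 0.68),
      radius_mm = 18, hemisphere = h,
      thin_mm = c("CS-" = 0, "CS+" = 0.08, "IMP+" = 0.45))
  }
  cohort_config(mesh_order = mesh_order, patches = patches, seed = seed)
}

#' Generate a pair of variant cohorts with shared mesh topology
#'
#' Two cohorts whose effect patches differ in extent, magnitude and symmetry
#' (stand-ins for two disease variants), with ground truth retained so
#' overlap-recovery statistics can be checked against the analytic geometry
#' of the configured patches.
#'
#' @param config_a,config_b [cohort_config()]s with the same `mesh_order`.
#' @return Named list `a`, `b` of `ds_cohort`s.
#' @export
generate_variant_pair <- function(config_a, config_b) {
  if (config_a$mesh_order != config_b$mesh_order)
    stopf("mesh orders differ (%d vs %d): variant maps would not be comparable",
          config_a$mesh_order, config_b$mesh_order)
  list(a = generate_cohort(config_a), b = generate_cohort(config_b))
}
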