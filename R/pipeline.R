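#' Pipeline configuration
#'
#' Collects every tunable of the staging analysis. Round-trips losslessly
#' through YAML ([write_pipeline_config()] / [read_pipeline_config()]).
#'
#' @param cohort_config Synthetic cohort configuration ([cohort_config()]);
#'   ignored when `cohort_dir` points at a cohort on disk.
#' @param cohort_dir Optional directory of a cohort written by
#'   [write_cohort()].
#' @param smoothing_fwhm_mm Surface smoothing FWHM applied to thickness maps
#'   before the vertex models (default 10 mm).
#' @param vertex_p_grid Candidate vertex-wise p thresholds.
#' @param cluster_p Cluster-wise significance level (default 0.001).
#' @param n_perm Permutations for the cluster null (default 1000).
#' @param withheld_fraction Fraction of the reference group withheld from
#'   derivation for unbiased ROC evaluation (default 0.2).
#' @param amyloid_thresholds Named tracer positivity cut-offs.
#' @param thinning_threshold_mm Threshold for cross-variant thinning masks
#'   (default 0.2 mm).
#' @param variant Optional second [cohort_config()] enabling the
#'   cross-variant map comparison stage.
#' @param seed Master seed; stage-specific seeds are derived from it.
#' @param out_dir Optional output directory for the report bundle.
#' @return `pipeline_config` list.
#' @export
pipeline_config <- function(cohort_config = cortexstage::cohort_config(),
                            cohort_dir = NULL,
                            smoothing_fwhm_mm = 10,
                            vertex_p_grid = c(0.05, 0.01, 0.005, 0.001,
                                              0.0005, 0.0001),
                            cluster_p = 0.001,
                            n_perm = 1000L,
                            withheld_fraction = 0.2,
                            amyloid_thresholds = c(PiB = 16.4,
                                                   florbetapir = 20.6),
                            thinning_threshold_mm = 0.2,
                            variant = NULL,
                            seed = 1L,
                            out_dir = NULL) {
  if (!length(vertex_p_grid)) stopf("'vertex_p_grid' must be nonempty")
  if (any(c(smoothing_fwhm_mm, cluster_p, thinning_threshold_mm,
            amyloid_thresholds) <= 0))
    stopf("thresholds must be positive")
  if (withheld_fraction <= 0 || withheld_fraction >= 1)
    stopf("'withheld_fraction' must lie in (0, 1)")
  structure(list(
    cohort_config = cohort_config, cohort_dir = cohort_dir,
    smoothing_fwhm_mm = smoothing_fwhm_mm,
    vertex_p_grid = vertex_p_grid, cluster_p = cluster_p,
    n_perm = as.integer(n_perm), withheld_fraction = withheld_fraction,
    amyloid_thresholds = amyloid_thresholds,
    thinning_threshold_mm = thinning_threshold_mm,
    variant = variant, seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `path` invisibly / the restored `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass_deep(config), path, precision = 15L)
  invisible(path)
}

# Strip S3 classes and turn named atomic vectors into lists so YAML stores
# them as maps (names survive the round trip).
unclass_deep <- function(x) {
  if (is.atomic(x) && !is.null(names(x))) x <- as.list(x)
  if (is.list(x)) {
    x <- lapply(x, unclass_deep)
    attributes(x) <- list(names = names(x))
  }
  x
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cc <- raw$cohort_config
  cohort_cfg <- cohort_config(
    sizes = unlist(cc$sizes), age_mean = unlist(cc$age_mean),
    age_sd = unlist(cc$age_sd), male_frac = unlist(cc$male_frac),
    apoe_frac = unlist(cc$apoe_frac),
    centiloid_mean = unlist(cc$centiloid_mean),
    centiloid_sd = unlist(cc$centiloid_sd),
    imp_split = unlist(cc$imp_split), pib_frac = cc$pib_frac,
    mesh_order = cc$mesh_order, baseline_mm = cc$baseline_mm,
    noise_sd_mm = cc$noise_sd_mm, noise_fwhm_mm = cc$noise_fwhm_mm,
    age_slope = cc$age_slope,
    patches = lapply(cc$patches, function(p) {
      p$thin_mm <- unlist(p$thin_mm)
      p$direction <- unlist(p$direction)
      p
    }),
    subcortical = as.data.frame(lapply(cc$subcortical, unlist)),
    icv_mean = cc$icv_mean, icv_sd = cc$icv_sd,
    icv_slope_scale = cc$icv_slope_scale, seed = cc$seed)
  pipeline_config(
    cohort_config = cohort_cfg, cohort_dir = raw$cohort_dir,
    smoothing_fwhm_mm = raw$smoothing_fwhm_mm,
    vertex_p_grid = unlist(raw$vertex_p_grid), cluster_p = raw$cluster_p,
    n_perm = raw$n_perm, withheld_fraction = raw$withheld_fraction,
    amyloid_thresholds = unlist(raw$amyloid_thresholds),
    thinning_threshold_mm = raw$thinning_threshold_mm,
    variant = if (is.null(raw$variant)) NULL else raw$variant,
    seed = raw$seed, out_dir = raw$out_dir)
}

STAGE_COMPARISONS <- list(c("CS-", "CS+"), c("CS+", "IMP+"), c("CS-", "IMP+"))

#' Run the full staging analysis
#'
#' Orchestrates the pipeline end to end: cohort (simulated or loaded) ->
#' stage labels and reference split -> surface smoothing -> vertex-wise
#' group models for the three stage contrasts -> candidate signature
#' derivation with permutation cluster correction -> signature evaluation and
#' ideal-signature selection -> ICV-corrected subcortical staging ->
#' cortical-vs-subcortical effect comparison -> optional cross-variant map
#' comparison. Deterministic given `config$seed`; each stage logs its seed
#' and parameters in the report.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return `pipeline_report`: list with `cohort`, `split`, `glm` (per
#'   comparison), `candidates`, `evaluation`, `ideal` (per comparison, with
#'   AUC), `subcortical`, `domain_comparison`, `variant` (or `NULL`) and
#'   `summary` (JSON-serializable numbers only).
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  stage_guard <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  }

  say("stage cohort: %s",
      if (is.null(config$cohort_dir)) "simulating" else config$cohort_dir)
  cohort <- stage_guard("cohort", {
    if (is.null(config$cohort_dir)) {
      cc <- config$cohort_config
      cc$seed <- as.integer(derive_seed(config$seed, 1))
      generate_cohort(cc)
    } else {
      read_cohort(config$cohort_dir,
                  mesh_order = config$cohort_config$mesh_order)
    }
  })

  say("stage staging/split")
  cohort <- stage_guard("staging", stage_cohort(cohort))
  split <- stage_guard("split", split_reference(
    cohort, group = "CS-", fraction = 1 - config$withheld_fraction,
    seed = derive_seed(config$seed, 2)))

  say("stage smoothing (FWHM %.1f mm)", config$smoothing_fwhm_mm)
  smoothed <- stage_guard("smoothing", lapply(names(cohort$meshes), function(h)
    smooth_map(cohort$meshes[[h]], cohort$thickness[[h]],
               config$smoothing_fwhm_mm)))
  names(smoothed) <- names(cohort$meshes)

  say("stage glm (3 comparisons)")
  glms <- stage_guard("glm", lapply(STAGE_COMPARISONS, function(cmp)
    fit_vertex_glm(cohort, cmp, subject_ids =
                     setdiff(cohort$subjects$id, split$withheld_ids),
                   thickness = smoothed)))
  names(glms) <- vapply(STAGE_COMPARISONS, paste, collapse = " vs ",
                        character(1))

  say("stage derive (%d permutations)", config$n_perm)
  candidates <- stage_guard("derive", {
    out <- list()
    for (i in seq_along(STAGE_COMPARISONS)) {
      out <- c(out, derive_candidates(
        cohort, STAGE_COMPARISONS[[i]], split = split,
        vertex_p_grid = config$vertex_p_grid, cluster_p = config$cluster_p,
        n_perm = config$n_perm, thickness = smoothed,
        seed = derive_seed(config$seed, 10 + i)))
    }
    out
  })

  say("stage evaluate/select")
  evaluation <- stage_guard("evaluate", evaluate_signatures(
    candidates, cohort, comparisons = STAGE_COMPARISONS, split = split,
    thickness = smoothed))
  ideal <- stage_guard("select", lapply(STAGE_COMPARISONS, function(cmp)
    select_ideal_signature(candidates, cmp, cohort, split = split,
                           thickness = smoothed)))
  names(ideal) <- names(glms)

  say("stage subcortical")
  volumes_adj <- stage_guard("subcortical", icv_correct(
    cohort$volumes, cohort$subjects, reference_group = "CS-"))
  subcortical <- stage_guard("subcortical", region_staging_table(
    volumes_adj, cohort$subjects, comparisons = STAGE_COMPARISONS,
    split = split))

  say("stage domain comparison")
  domain <- stage_guard("domains", lapply(names(glms), function(cmp) {
    cort <- evaluation$cohens_d[evaluation$comparison == cmp]
    subc <- subcortical$cohens_d[subcortical$comparison == cmp]
    if (!length(cort) || !length(subc)) return(NULL)
    compare_effect_domains(cort, subc)
  }))
  names(domain) <- names(glms)

  variant <- NULL
  if (!is.null(config$variant)) {
    say("stage variant comparison")
    variant <- stage_guard("variant", {
      vc <- config$variant
      vc$seed <- as.integer(derive_seed(config$seed, 20))
      if (vc$mesh_order != cohort$config$mesh_order)
        stopf("variant mesh order %d != cohort order %d", vc$mesh_order,
              cohort$config$mesh_order)
      vcoh <- generate_cohort(vc)
      vsm <- lapply(names(vcoh$meshes), function(h)
        smooth_map(vcoh$meshes[[h]], vcoh$thickness[[h]],
                   config$smoothing_fwhm_mm))
      names(vsm) <- names(vcoh$meshes)
      vglm <- fit_vertex_glm(vcoh, c("CS-", "IMP+"), thickness = vsm)
      maps_a <- lapply(c(left = "left", right = "right"), function(h)
        effect_size_map(glms[["CS- vs IMP+"]], "delta_mm", h))
      maps_b <- lapply(c(left = "left", right = "right"), function(h)
        effect_size_map(vglm, "delta_mm", h))
      list(summary = overlap_summary(maps_a, maps_b, cohort$meshes,
                                     threshold_mm =
                                       config$thinning_threshold_mm),
           glm = vglm, cohort = vcoh)
    })
  }

  summary <- report_summary(cohort, split, evaluation, ideal, subcortical,
                            domain, variant, config)
  report <- structure(
    list(cohort = cohort, split = split, glm = glms,
         candidates = candidates, evaluation = evaluation, ideal = ideal,
         subcortical = subcortical, domain_comparison = domain,
         variant = variant, summary = summary, config = config),
    class = "pipeline_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

report_summary <- function(cohort, split, evaluation, ideal, subcortical,
                           domain, variant, config) {
  tab <- table(cohort$subjects$stage)
  s <- list(
    seed = config$seed,
    n_subjects = nrow(cohort$subjects),
    group_sizes = as.list(stats::setNames(as.integer(tab), names(tab))),
    n_derivation = length(split$derivation_ids),
    n_withheld = length(split$withheld_ids),
    n_candidates = length(unique(evaluation$candidate)),
    n_evaluation_rows = nrow(evaluation),
    ideal = lapply(ideal, function(m) if (is.null(m)) NULL else
      list(vertex_p = m$vertex_p, derived_from =
             paste(m$comparison, collapse = " vs "),
           area_mm2 = m$area_mm2, auc = m$auc)),
    subcortical_best = {
      best <- lapply(base::split(subcortical, subcortical$comparison),
                     function(d)
        d[which.max(d$auc), c("region", "side", "auc")])
      lapply(best, function(d) list(region = d$region, side = d$side,
                                    auc = d$auc))
    },
    domain_comparison = lapply(domain, function(d) if (is.null(d)) NULL else
      list(mean_d_cortical = unname(d$mean_d[1L]),
           mean_d_subcortical = unname(d$mean_d[2L]), t = d$t,
           p_value = d$p_value))
  )
  if (!is.null(variant)) {
    s$variant <- lapply(variant$summary, function(h)
      list(dice = h$dice, rho = h$rho, area_ratio = h$area$ratio,
           containment = h$area$containment))
  }
  s
}

#' Write a pipeline report bundle
#'
#' Machine-readable JSON summary, evaluation and subcortical tables as CSV,
#' and the ideal signatures as label/GIFTI masks.
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  utils::write.csv(report$evaluation, file.path(dir, "evaluation.csv"),
                   row.names = FALSE)
  utils::write.csv(report$subcortical, file.path(dir, "subcortical.csv"),
                   row.names = FALSE)
  for (nm in names(report$ideal)) {
    m <- report$ideal[[nm]]
    if (is.null(m)) next
    write_signature(m, report$cohort$meshes, dir,
                    prefix = sprintf("ideal_%s", gsub("[^A-Za-z]+", "_", nm)))
  }
  invisible(dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report\n")
  cat(sprintf("  subjects: %d (%s)\n", x$summary$n_subjects,
              paste(sprintf("%s %d", names(x$summary$group_sizes),
                            unlist(x$summary$group_sizes)), collapse = ", ")))
  for (nm in names(x$ideal)) {
    m <- x$ideal[[nm]]
    if (is.null(m)) {
      cat(sprintf("  %s: no usable signature\n", nm))
    } else {
      cat(sprintf("  %s: AUC %.3f (vertex p <= %g, %.0f mm^2)\n",
                  nm, m$auc, m$vertex_p, m$area_mm2))
    }
  }
  invisible(x)
}
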