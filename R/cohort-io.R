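#' Write a cohort to disk
#'
#' Subjects and volumes as CSV, per-subject per-hemisphere thickness maps as
#' FreeSurfer curv (or GIFTI functional) files, meshes as binary surfaces,
#' and ground-truth patch masks as FreeSurfer label files.
#'
#' @param cohort A `ds_cohort`.
#' @param dir Output directory (created if missing).
#' @param format `"curv"` (default) or `"gifti"` for the thickness maps.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("curv", "gifti")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$volumes, file.path(dir, "volumes.csv"),
                   row.names = FALSE)
  for (h in names(cohort$meshes)) {
    write_surface(cohort$meshes[[h]], file.path(dir, sprintf("%s.surf", h)))
    thick <- cohort$thickness[[h]]
    for (j in seq_len(ncol(thick))) {
      id <- cohort$subjects$id[j]
      if (format == "curv") {
        write_curv(thick[, j], file.path(dir, sprintf("%s_%s.curv", id, h)),
                   fnum = nrow(cohort$meshes[[h]]$faces))
      } else {
        write_gifti_map(thick[, j],
                        file.path(dir, sprintf("%s_%s.func.gii", id, h)))
      }
    }
    if (!is.null(cohort$truth))
      write_label(cohort$truth[[h]]$union, cohort$meshes[[h]],
                  file.path(dir, sprintf("truth_%s.label", h)))
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @param mesh_order Icosphere order to rebuild the shared meshes with
#'   (`NULL` to read the stored surfaces instead; stored surfaces lose the
#'   nested-ordering metadata).
#' @param format Thickness file format used at write time.
#' @return A `ds_cohort` (without generator config; `truth` only carries the
#'   union masks).
#' @export
read_cohort <- function(dir, mesh_order = NULL, format = c("curv", "gifti")) {
  format <- match.arg(format)
  subj <- utils::read.csv(file.path(dir, "subjects.csv"),
                          stringsAsFactors = FALSE)
  subj$stage <- factor(subj$stage, levels = STAGE_LEVELS)
  volumes <- utils::read.csv(file.path(dir, "volumes.csv"),
                             stringsAsFactors = FALSE)
  meshes <- lapply(c(left = "left", right = "right"), function(h) {
    if (is.null(mesh_order)) {
      read_surface(file.path(dir, sprintf("%s.surf", h)), hemisphere = h)
    } else {
      build_icosphere(mesh_order, h)
    }
  })
  thickness <- lapply(c(left = "left", right = "right"), function(h) {
    n <- n_vertices(meshes[[h]])
    mat <- vapply(subj$id, function(id) {
      if (format == "curv") {
        read_curv(file.path(dir, sprintf("%s_%s.curv", id, h)), expected_n = n)
      } else {
        read_gifti_map(file.path(dir, sprintf("%s_%s.func.gii", id, h)),
                       expected_n = n)
      }
    }, numeric(n))
    colnames(mat) <- subj$id
    mat
  })
  truth <- NULL
  if (file.exists(file.path(dir, "truth_left.label"))) {
    truth <- lapply(c(left = "left", right = "right"), function(h)
      list(union = read_label(file.path(dir, sprintf("truth_%s.label", h)),
                              n_vertices(meshes[[h]]))))
  }
  structure(list(subjects = subj, thickness = thickness, volumes = volumes,
                 meshes = meshes, truth = truth, config = NULL),
            class = "ds_cohort")
}

#' Export a group-comparison result as surface map files
#'
#' Writes t, p, mm-difference and Cohen's d maps per hemisphere (curv or
#' GIFTI functional) plus a JSON sidecar of the comparison metadata. mm and d
#' maps use the exported sign convention (thinning negative).
#'
#' @param result A [fit_vertex_glm()] result.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @param format `"curv"` or `"gifti"`.
#' @return `dir`, invisibly.
#' @export
write_comparison_maps <- function(result, dir, prefix = "glm",
                                  format = c("curv", "gifti")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writer <- if (format == "curv") write_curv else write_gifti_map
  ext <- if (format == "curv") "curv" else "func.gii"
  for (h in names(result$hemi)) {
    maps <- list(t = result$hemi[[h]]$t, p = result$hemi[[h]]$p,
                 delta_mm = -result$hemi[[h]]$delta_mm,
                 cohens_d = -result$hemi[[h]]$cohens_d)
    for (nm in names(maps))
      writer(maps[[nm]], file.path(dir, sprintf("%s_%s_%s.%s",
                                                prefix, h, nm, ext)))
  }
  meta <- list(comparison = result$comparison, covariates = result$covariates,
               n = as.list(result$n), df = result$df,
               sign_convention = "thinning negative (exported)")
  jsonlite::write_json(meta, file.path(dir, sprintf("%s_meta.json", prefix)),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Export a signature mask as label and GIFTI files
#'
#' @param mask A `signature_mask`.
#' @param meshes Named mesh list.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return `dir`, invisibly.
#' @export
write_signature <- function(mask, meshes, dir, prefix = "signature") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (h in names(mask$masks)) {
    write_label(mask$masks[[h]], meshes[[h]],
                file.path(dir, sprintf("%s_%s.label", prefix, h)))
    write_gifti_mask(mask$masks[[h]],
                     file.path(dir, sprintf("%s_%s.label.gii", prefix, h)))
  }
  invisible(dir)
}
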