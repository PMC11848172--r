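#' Derive candidate cortical signatures by cluster-corrected thresholding
#'
#' The core signature-derivation procedure: the vertex-wise |t| map of a
#' covariate-adjusted group comparison is thresholded at each element of a
#' vertex-wise p grid, suprathreshold vertices are grouped into connected
#' clusters, and clusters are retained when their surface area exceeds the
#' permutation null of the maximum cluster area (Freedman-Lane residual
#' permutation, so covariates are respected). One candidate signature
#' (left + right masks) is produced per grid point; a grid point at which no
#' cluster survives still yields a (recorded, empty) candidate, since
#' signatures are evaluated on every comparison regardless of where they were
#' derived.
#'
#' @param cohort A staged cohort with thickness maps (pre-smoothed if
#'   desired).
#' @param comparison Character pair, reference stage first.
#' @param split Optional [split_reference()] result; when given, withheld
#'   members of the split group are excluded from derivation.
#' @param vertex_p_grid Vertex-wise two-sided p thresholds (default
#'   `c(0.05, 0.01, 0.005, 0.001, 0.0005, 0.0001)`).
#' @param cluster_p Cluster-wise significance level (default 0.001).
#' @param n_perm Permutations for the max-cluster-area null (default 1000); a
#'   warning is issued when `n_perm < 1 / cluster_p` (null resolution
#'   insufficient).
#' @param covariates Passed to the vertex model (default age + sex).
#' @param thickness Optional thickness override as in [fit_vertex_glm()].
#' @param seed Permutation seed.
#' @return List of `signature_mask` objects, one per grid point: per-hemisphere
#'   logical masks, `comparison`, `vertex_p`, `cluster_p`, `area_mm2`, and the
#'   surviving-cluster tables.
#' @export
derive_candidates <- function(cohort, comparison, split = NULL,
                              vertex_p_grid = c(0.05, 0.01, 0.005, 0.001,
                                                0.0005, 0.0001),
                              cluster_p = 0.001, n_perm = 1000L,
                              covariates = c("age", "sex"),
                              thickness = NULL, seed = 1L) {
  if (!length(vertex_p_grid)) stopf("'vertex_p_grid' must be nonempty")
  if (n_perm < 1L) stopf("'n_perm' must be >= 1")
  if (n_perm < 1 / cluster_p)
    warnf("n_perm = %d cannot resolve cluster_p = %g (need >= %.0f)",
          n_perm, cluster_p, 1 / cluster_p)
  subj <- cohort$subjects
  keep <- subj$stage %in% comparison
  if (!is.null(split))
    keep <- keep & !(subj$id %in% split$withheld_ids)
  sdf <- subj[keep, , drop = FALSE]
  des <- build_design(sdf, covariates, advanced_stage = comparison[2L])
  X <- des$X
  gidx <- which(colnames(X) == "group")
  X0 <- X[, -gidx, drop = FALSE]
  thickness <- thickness %||% cohort$thickness
  n <- nrow(X)
  df <- n - ncol(X)
  tcrit <- stats::qt(1 - vertex_p_grid / 2, df)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  perms <- replicate(n_perm, sample.int(n), simplify = FALSE)

  hemis <- names(thickness)
  per_hemi <- lapply(hemis, function(h) {
    mesh <- cohort$meshes[[h]]
    adj <- vertex_adjacency(mesh)
    areas <- vertex_areas(mesh)
    Y <- t(thickness[[h]][, which(keep), drop = FALSE])
    obs <- ols_vertex_t(X, Y, gidx)
    # Freedman-Lane: permute reduced-model residuals, refit the full model
    B0 <- chol2inv(chol(crossprod(X0))) %*% crossprod(X0, Y)
    F0 <- X0 %*% B0
    R0 <- Y - F0
    null_max <- matrix(0, nrow = n_perm, ncol = length(vertex_p_grid))
    for (b in seq_len(n_perm)) {
      Yp <- F0 + R0[perms[[b]], , drop = FALSE]
      tp <- ols_vertex_t(X, Yp, gidx)$t
      atp <- abs(tp)
      for (k in seq_along(tcrit)) {
        m <- atp >= tcrit[k]
        if (any(m)) {
          cc <- connected_components(mesh, m, adj = adj, areas = areas)
          null_max[b, k] <- max(cc$area_mm2)
        }
      }
    }
    list(obs = obs, null_max = null_max, mesh = mesh, adj = adj,
         areas = areas)
  })
  names(per_hemi) <- hemis

  lapply(seq_along(vertex_p_grid), function(k) {
    masks <- list(); clusters <- list()
    for (h in hemis) {
      ph <- per_hemi[[h]]
      m <- abs(ph$obs$t) >= tcrit[k]
      cc <- connected_components(ph$mesh, m, stat = ph$obs$t, adj = ph$adj,
                                 areas = ph$areas)
      if (nrow(cc)) {
        # permutation p of each observed cluster against the max-area null
        cc$p_cluster <- vapply(cc$area_mm2, function(a)
          (1 + sum(ph$null_max[, k] >= a)) / (n_perm + 1), numeric(1))
        cc <- cc[cc$p_cluster <= cluster_p, , drop = FALSE]
      }
      mask <- logical(n_vertices(ph$mesh))
      if (nrow(cc)) mask[unlist(cc$vertices)] <- TRUE
      masks[[h]] <- mask
      clusters[[h]] <- cc
    }
    area <- sum(vapply(hemis, function(h)
      sum(per_hemi[[h]]$areas[masks[[h]]]), numeric(1)))
    structure(list(masks = masks, comparison = comparison,
                   vertex_p = vertex_p_grid[k], cluster_p = cluster_p,
                   area_mm2 = area, clusters = clusters,
                   n_perm = n_perm),
              class = "signature_mask")
  })
}

#' @export
print.signature_mask <- function(x, ...) {
  nv <- sum(vapply(x$masks, sum, numeric(1)))
  cat(sprintf(
    "signature_mask [%s vs %s, vertex p <= %g, cluster p <= %g]: %d vertices, %.0f mm^2\n",
    x$comparison[1L], x$comparison[2L], x$vertex_p, x$cluster_p, nv,
    x$area_mm2))
  invisible(x)
}

is_empty_mask <- function(mask) {
  sum(vapply(mask$masks, sum, numeric(1))) == 0
}

#' Mean signature thickness per subject
#'
#' Area-weighted mean thickness over the signature vertices, pooling both
#' hemispheres by vertex area — the per-subject staging score.
#'
#' @param cohort Cohort whose thickness maps to score (raw, not smoothed, by
#'   default convention; pass `thickness` to override).
#' @param mask A `signature_mask` from [derive_candidates()].
#' @param subject_ids Optional subject subset.
#' @param thickness Optional thickness override (named list of V x n
#'   matrices).
#' @return Named numeric vector of scores (mm), one per scored subject.
#' @export
signature_score <- function(cohort, mask, subject_ids = NULL,
                            thickness = NULL) {
  if (is_empty_mask(mask))
    stopf("empty signature mask: score undefined (candidate unusable)")
  thickness <- thickness %||% cohort$thickness
  keep <- if (is.null(subject_ids)) rep(TRUE, nrow(cohort$subjects)) else
    cohort$subjects$id %in% subject_ids
  num <- 0; den <- 0
  for (h in names(mask$masks)) {
    m <- mask$masks[[h]]
    if (!any(m)) next
    w <- vertex_areas(cohort$meshes[[h]])[m]
    num <- num + as.numeric(crossprod(w, thickness[[h]][m, keep, drop = FALSE]))
    den <- den + sum(w)
  }
  stats::setNames(num / den, cohort$subjects$id[keep])
}

# Evaluation subjects for one comparison: comparisons involving the split
# group use only its withheld members (derivation subjects would bias the
# ROC); all other groups enter in full.
evaluation_ids <- function(cohort, comparison, split) {
  subj <- cohort$subjects
  ids <- subj$id[subj$stage %in% comparison]
  if (!is.null(split) && split$group %in% comparison)
    ids <- setdiff(ids, split$derivation_ids)
  ids
}

candidate_label <- function(mask) {
  sprintf("%svs%s_p%g", mask$comparison[1L], mask$comparison[2L],
          mask$vertex_p)
}

#' Evaluate candidate signatures across all group comparisons
#'
#' Scores every candidate on every comparison (signatures derived from one
#' comparison are deliberately applied to the others), computes the ROC AUC,
#' group means/SDs, Cohen's d and a Welch t test per cell, and adjusts the
#' whole table with Benjamini-Hochberg.
#'
#' @param candidates List of `signature_mask` objects.
#' @param cohort Staged cohort.
#' @param comparisons List of stage pairs (default the three stage contrasts).
#' @param split Optional [split_reference()] result controlling evaluation
#'   subsets.
#' @param thickness Optional thickness override.
#' @return `signature_evaluation` data frame: one row per usable candidate x
#'   comparison with `candidate`, `derived_from`, `vertex_p`, `comparison`,
#'   `auc`, `mean_ref`, `sd_ref`, `mean_adv`, `sd_adv`, `cohens_d`, `t`,
#'   `p_value`, `p_adjusted`.
#' @export
evaluate_signatures <- function(candidates, cohort,
                                comparisons = list(c("CS-", "CS+"),
                                                   c("CS+", "IMP+"),
                                                   c("CS-", "IMP+")),
                                split = NULL, thickness = NULL) {
  rows <- list()
  for (cand in candidates) {
    if (is_empty_mask(cand)) next
    for (cmp in comparisons) {
      ids <- evaluation_ids(cohort, cmp, split)
      sc <- signature_score(cohort, cand, subject_ids = ids,
                            thickness = thickness)
      st <- cohort$subjects$stage[match(names(sc), cohort$subjects$id)]
      adv <- st == cmp[2L]
      roc <- roc_auc(sc, adv, direction = "lower")
      tt <- stats::t.test(sc[!adv], sc[adv])            # Welch
      sp <- sqrt(((sum(!adv) - 1) * stats::var(sc[!adv]) +
                    (sum(adv) - 1) * stats::var(sc[adv])) /
                   (length(sc) - 2))
      rows[[length(rows) + 1L]] <- data.frame(
        candidate = candidate_label(cand),
        derived_from = paste(cand$comparison, collapse = " vs "),
        vertex_p = cand$vertex_p,
        comparison = paste(cmp, collapse = " vs "),
        auc = roc$auc,
        mean_ref = mean(sc[!adv]), sd_ref = stats::sd(sc[!adv]),
        mean_adv = mean(sc[adv]), sd_adv = stats::sd(sc[adv]),
        cohens_d = (mean(sc[!adv]) - mean(sc[adv])) / sp,
        t = unname(tt$statistic), p_value = tt$p.value)
    }
  }
  out <- do.call(rbind, rows) %||% data.frame()
  if (nrow(out)) out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  class(out) <- c("signature_evaluation", "data.frame")
  out
}

#' Select the ideal signature for a comparison
#'
#' The candidate whose per-subject mean thickness best separates the two
#' stages by AUC on the evaluation subjects; exact AUC ties go to the smaller
#' mask area.
#'
#' @param candidates List of `signature_mask` objects (empty masks are
#'   skipped).
#' @param comparison Stage pair to differentiate.
#' @param cohort Staged cohort.
#' @param split Optional [split_reference()] controlling the evaluation
#'   subset.
#' @param thickness Optional thickness override.
#' @return The winning `signature_mask` with `auc` and `roc` attached, or
#'   `NULL` when every candidate is empty (explicit no-signature result).
#' @export
select_ideal_signature <- function(candidates, comparison, cohort,
                                   split = NULL, thickness = NULL) {
  usable <- Filter(Negate(is_empty_mask), candidates)
  if (!length(usable)) return(NULL)
  ids <- evaluation_ids(cohort, comparison, split)
  aucs <- numeric(length(usable))
  rocs <- vector("list", length(usable))
  for (i in seq_along(usable)) {
    sc <- signature_score(cohort, usable[[i]], subject_ids = ids,
                          thickness = thickness)
    st <- cohort$subjects$stage[match(names(sc), cohort$subjects$id)]
    rocs[[i]] <- roc_auc(sc, st == comparison[2L], direction = "lower")
    aucs[i] <- rocs[[i]]$auc
  }
  best <- which(aucs == max(aucs))
  if (length(best) > 1L) {
    areas <- vapply(usable[best], function(m) m$area_mm2, numeric(1))
    best <- best[which.min(areas)]
  }
  win <- usable[[best]]
  win$auc <- aucs[best]
  win$roc <- rocs[[best]]
  win$evaluated_comparison <- comparison
  win
}

#' Compare effect-size collections between measurement domains
#'
#' Two-sample comparison (Welch t) of two collections of Cohen's d values,
#' e.g. cortical-signature versus subcortical-volume effect sizes for one
#' stage contrast.
#'
#' @param cortical_ds,subcortical_ds Numeric vectors of effect sizes.
#' @return List with `mean_d` (named pair), `t`, `df`, `p_value`; for
#'   singleton or zero-variance inputs `t` is `NA`/`Inf` with means still
#'   reported (degenerate case flagged via `degenerate`).
#' @export
compare_effect_domains <- function(cortical_ds, subcortical_ds) {
  if (!length(cortical_ds) || !length(subcortical_ds))
    stopf("both effect-size collections must be nonempty")
  means <- c(cortical = mean(cortical_ds), subcortical = mean(subcortical_ds))
  if (length(cortical_ds) < 2L || length(subcortical_ds) < 2L)
    return(list(mean_d = means, t = NA_real_, df = NA_real_,
                p_value = NA_real_, degenerate = TRUE))
  if (stats::var(cortical_ds) == 0 && stats::var(subcortical_ds) == 0) {
    diff <- unname(means[1L] - means[2L])
    return(list(mean_d = means, t = if (diff == 0) 0 else Inf * sign(diff),
                df = NA_real_, p_value = if (diff == 0) 1 else 0,
                degenerate = TRUE))
  }
  tt <- stats::t.test(cortical_ds, subcortical_ds)
  list(mean_d = means, t = unname(tt$statistic),
       df = unname(tt$parameter), p_value = tt$p.value, degenerate = FALSE)
}
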