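SUBCORTICAL_REGIONS <- c("hippocampus", "amygdala", "accumbens", "caudate",
                         "putamen", "pallidum", "thalamus")

#' Correct subcortical volumes for intracranial volume
#'
#' Residual (regression) head-size correction: per region and side, volume is
#' regressed on intracranial volume (ICV) within the reference group (default
#' the amyloid-negative stable group, so the slope is not biased by disease
#' effects), and every subject's volume is adjusted along that slope to the
#' reference mean ICV. The operation is idempotent: correcting an
#' already-corrected table is a no-op up to floating point.
#'
#' @param volumes Long data frame with columns `id`, `region`, `side`,
#'   `volume` (mm^3).
#' @param subjects Subject table with `id`, `icv`, `stage`.
#' @param reference_group Stage label fitting the ICV slope (default
#'   `"CS-"`); needs >= 10 members.
#' @return `volumes` with `volume` replaced by the adjusted values; the
#'   per-region fits (slope, reference mean ICV) are attached as attribute
#'   `icv_fits`.
#' @export
icv_correct <- function(volumes, subjects, reference_group = "CS-") {
  ref_ids <- subjects$id[subjects$stage == reference_group]
  if (length(ref_ids) < 10L)
    stopf("reference group '%s' has %d subjects; >= 10 required",
          reference_group, length(ref_ids))
  icv <- subjects$icv[match(volumes$id, subjects$id)]
  if (anyNA(icv)) stopf("missing ICV for some volume rows")
  ref_icv <- subjects$icv[subjects$stage == reference_group]
  if (stats::var(ref_icv) == 0)
    stopf("degenerate ICV variance in reference group")
  icv_mean <- mean(ref_icv)
  out <- volumes
  fits <- list()
  for (key in unique(paste(volumes$region, volumes$side))) {
    sel <- paste(volumes$region, volumes$side) == key
    ref_sel <- sel & volumes$id %in% ref_ids
    fit <- stats::lm.fit(cbind(1, icv[ref_sel]), volumes$volume[ref_sel])
    slope <- fit$coefficients[2L]
    out$volume[sel] <- volumes$volume[sel] - slope * (icv[sel] - icv_mean)
    fits[[key]] <- c(slope = unname(slope), icv_mean = icv_mean)
  }
  attr(out, "icv_fits") <- fits
  out
}

#' Per-region staging evaluation of subcortical volumes
#'
#' Applies the same ROC / effect-size / FDR machinery as the cortical
#' signature evaluation to each region x side: AUC (smaller volume read as
#' more advanced), Welch t, Cohen's d, Benjamini-Hochberg adjustment across
#' the whole table.
#'
#' @param volumes (ICV-corrected) long volume table (`id`, `region`, `side`,
#'   `volume`).
#' @param subjects Subject table with `id`, `stage`.
#' @param comparisons List of stage pairs (default the three stage
#'   contrasts).
#' @param split Optional [split_reference()]; comparisons involving the split
#'   group use only its withheld members, mirroring the cortical evaluation.
#' @return `region_staging` data frame: `region`, `side`, `comparison`,
#'   `auc`, `cohens_d`, `t`, `p_value`, `p_adjusted`.
#' @export
region_staging_table <- function(volumes, subjects,
                                 comparisons = list(c("CS-", "CS+"),
                                                    c("CS+", "IMP+"),
                                                    c("CS-", "IMP+")),
                                 split = NULL) {
  rows <- list()
  for (cmp in comparisons) {
    ids <- subjects$id[subjects$stage %in% cmp]
    if (!is.null(split) && split$group %in% cmp)
      ids <- setdiff(ids, split$derivation_ids)
    for (region in unique(volumes$region)) for (side in unique(volumes$side)) {
      sel <- volumes$region == region & volumes$side == side &
        volumes$id %in% ids
      v <- volumes$volume[sel]
      st <- subjects$stage[match(volumes$id[sel], subjects$id)]
      adv <- st == cmp[2L]
      if (!any(adv) || !all(c(TRUE, FALSE) %in% adv)) next
      roc <- roc_auc(v, adv, direction = "lower")
      tt <- stats::t.test(v[!adv], v[adv])
      sp <- sqrt(((sum(!adv) - 1) * stats::var(v[!adv]) +
                    (sum(adv) - 1) * stats::var(v[adv])) / (length(v) - 2))
      rows[[length(rows) + 1L]] <- data.frame(
        region = region, side = side,
        comparison = paste(cmp, collapse = " vs "),
        auc = roc$auc,
        cohens_d = (mean(v[!adv]) - mean(v[adv])) / sp,
        t = unname(tt$statistic), p_value = tt$p.value)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  class(out) <- c("region_staging", "data.frame")
  out
}
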