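#' Threshold an effect-size map into a thinning mask
#'
#' Vertices where the exported mm-difference map shows thinning of at least
#' `threshold_mm` (i.e. values <= -threshold, the threshold being inclusive).
#'
#' @param effect_map Numeric map in the exported convention (thinning
#'   negative), in mm. Maps carrying a `units` attribute other than `"mm"`
#'   are rejected; bare numeric maps are assumed to be mm.
#' @param threshold_mm Thinning magnitude threshold (default 0.2 mm).
#' @return Logical vertex mask.
#' @export
thinning_mask <- function(effect_map, threshold_mm = 0.2) {
  units <- attr(effect_map, "units")
  if (!is.null(units) && units != "mm")
    stopf("thinning_mask needs a mm-difference map, got units '%s'", units)
  if (threshold_mm <= 0) stopf("'threshold_mm' must be > 0")
  as.numeric(effect_map) <= -threshold_mm
}

#' Dice overlap coefficient of two vertex masks
#'
#' `2 |A intersect B| / (|A| + |B|)` over vertex counts: 1 for complete
#' overlap, 0 for complete separation. Two empty masks return 1 by convention
#' (with a warning). Set `areas` to weight vertices by surface area instead
#' of counting them.
#'
#' @param mask_a,mask_b Logical vertex masks on the same mesh.
#' @param areas Optional per-vertex areas for the area-weighted variant.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(mask_a, mask_b, areas = NULL) {
  mask_a <- as.logical(mask_a); mask_b <- as.logical(mask_b)
  if (length(mask_a) != length(mask_b))
    stopf("masks live on different meshes (%d vs %d vertices)",
          length(mask_a), length(mask_b))
  w <- areas %||% rep(1, length(mask_a))
  denom <- sum(w[mask_a]) + sum(w[mask_b])
  if (denom == 0) {
    warnf("both masks empty: Dice = 1 by convention")
    return(1)
  }
  2 * sum(w[mask_a & mask_b]) / denom
}

OVERLAP_LEVELS <- c("neither", "A only", "B only", "both")

#' Categorical overlap map of two masks
#'
#' @param mask_a,mask_b Logical vertex masks on the same mesh.
#' @return Factor vertex map with levels `neither`, `A only`, `B only`,
#'   `both`; the category areas partition the total mesh area.
#' @export
overlap_map <- function(mask_a, mask_b) {
  mask_a <- as.logical(mask_a); mask_b <- as.logical(mask_b)
  if (length(mask_a) != length(mask_b))
    stopf("masks live on different meshes (%d vs %d vertices)",
          length(mask_a), length(mask_b))
  cat <- rep("neither", length(mask_a))
  cat[mask_a & !mask_b] <- "A only"
  cat[!mask_a & mask_b] <- "B only"
  cat[mask_a & mask_b] <- "both"
  factor(cat, levels = OVERLAP_LEVELS)
}

#' Spatial correlation of two vertex maps
#'
#' Correlation across vertices, Spearman's rho by default (Pearson
#' available), optionally after nested-icosphere downsampling of both maps.
#'
#' @param map_a,map_b Numeric vertex maps on the same mesh.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param mesh Icosphere mesh, required when `downsample_order` is given.
#' @param downsample_order Optional coarser icosphere order at which to
#'   correlate.
#' @return List with `rho`, `method`, `n_vertices`.
#' @export
spatial_correlation <- function(map_a, map_b,
                                method = c("spearman", "pearson"),
                                mesh = NULL, downsample_order = NULL) {
  method <- match.arg(method)
  if (length(map_a) != length(map_b))
    stopf("maps live on different meshes (%d vs %d vertices)",
          length(map_a), length(map_b))
  a <- as.numeric(map_a); b <- as.numeric(map_b)
  if (!is.null(downsample_order)) {
    if (is.null(mesh)) stopf("'mesh' required for downsampling")
    a <- downsample_map(a, mesh, downsample_order)
    b <- downsample_map(b, mesh, downsample_order)
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warnf("constant map: spatial correlation undefined")
    return(list(rho = NA_real_, method = method, n_vertices = length(a)))
  }
  list(rho = stats::cor(a, b, method = method), method = method,
       n_vertices = length(a))
}

#' Area ratio and containment of two masks
#'
#' Surface areas via [vertex_areas()]: the A:B area ratio and the fraction of
#' B's area also inside A.
#'
#' @param mask_a,mask_b Logical vertex masks on `mesh`.
#' @param mesh The shared [surface_mesh()].
#' @return List with `area_a`, `area_b`, `area_both` (mm^2), `ratio`
#'   (`area_a / area_b`, `NA` with a warning when B is empty) and
#'   `containment` (`area_both / area_b`).
#' @export
area_statistics <- function(mask_a, mask_b, mesh) {
  mask_a <- as.logical(mask_a); mask_b <- as.logical(mask_b)
  n <- n_vertices(mesh)
  if (length(mask_a) != n || length(mask_b) != n)
    stopf("masks do not match mesh vertex count %d", n)
  w <- vertex_areas(mesh)
  area_a <- sum(w[mask_a]); area_b <- sum(w[mask_b])
  area_both <- sum(w[mask_a & mask_b])
  if (area_b == 0) {
    warnf("mask B empty: area ratio/containment undefined")
    return(list(area_a = area_a, area_b = 0, area_both = 0,
                ratio = NA_real_, containment = NA_real_))
  }
  list(area_a = area_a, area_b = area_b, area_both = area_both,
       ratio = area_a / area_b, containment = area_both / area_b)
}

#' Cross-variant overlap summary of two effect-size maps
#'
#' Per hemisphere: thinning masks at the mm threshold, vertex-count and
#' area-weighted Dice, category areas, A:B area ratio, containment of B in A,
#' and the spatial correlation of the raw maps. Side B may be a bare map
#' (e.g. an external variant's published effect map).
#'
#' @param maps_a,maps_b Named lists (`left`, `right`) of exported
#'   mm-difference maps.
#' @param meshes Named list (`left`, `right`) of meshes.
#' @param threshold_mm Thinning threshold (default 0.2 mm).
#' @param method Correlation estimator, default Spearman.
#' @param downsample_order Optional icosphere order for the correlation.
#' @return `overlap_summary`: per-hemisphere list of the statistics above.
#' @export
overlap_summary <- function(maps_a, maps_b, meshes, threshold_mm = 0.2,
                            method = "spearman", downsample_order = NULL) {
  out <- lapply(names(meshes), function(h) {
    mesh <- meshes[[h]]
    a <- thinning_mask(maps_a[[h]], threshold_mm)
    b <- thinning_mask(maps_b[[h]], threshold_mm)
    w <- vertex_areas(mesh)
    stats_ab <- area_statistics(a, b, mesh)
    corr <- spatial_correlation(maps_a[[h]], maps_b[[h]], method = method,
                                mesh = mesh,
                                downsample_order = downsample_order)
    list(dice = dice(a, b), dice_area = dice(a, b, areas = w),
         area = stats_ab, rho = corr$rho, method = corr$method,
         mask_a = a, mask_b = b, overlap = overlap_map(a, b))
  })
  names(out) <- names(meshes)
  structure(out, class = "overlap_summary")
}
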