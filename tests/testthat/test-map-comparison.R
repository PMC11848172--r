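test_that("thinning masks use an inclusive threshold on mm maps", {
  m <- c(-0.3, -0.2, -0.1999, 0, 0.1)
  attr(m, "units") <- "mm"
  expect_identical(thinning_mask(m), c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_identical(sum(thinning_mask(rep(0.1, 5))), 0L)   # thickening only
  expect_identical(sum(thinning_mask(rep(-0.3, 5))), 5L)
  d <- rep(-1, 4); attr(d, "units") <- "d"
  expect_error(thinning_mask(d), "mm-difference")
  expect_error(thinning_mask(m, threshold_mm = 0), "> 0")
})

test_that("dice satisfies its identities and matches set arithmetic", {
  a <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  b <- c(TRUE, FALSE, TRUE, FALSE, TRUE)
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, !a), 0)
  expect_equal(dice(c(TRUE, TRUE, FALSE, FALSE),
                    c(TRUE, FALSE, TRUE, FALSE)), 0.5)
  set.seed(70)
  for (i in 1:20) {
    x <- runif(200) < 0.3; y <- runif(200) < 0.3
    want <- if (sum(x) + sum(y) == 0) 1 else
      2 * sum(x & y) / (sum(x) + sum(y))
    expect_equal(dice(x, y), want)
    expect_identical(dice(x, y), dice(y, x))
    expect_identical((dice(x, y) == 1), identical(x, y) || want == 1)
  }
  expect_warning(expect_equal(dice(logical(5), logical(5)), 1), "empty")
  expect_error(dice(logical(5), logical(6)), "different meshes")
})

test_that("overlap categories partition the mesh area exactly", {
  mesh <- test_mesh(2)
  n <- nrow(mesh$vertices)
  set.seed(71)
  a <- runif(n) < 0.25; b <- runif(n) < 0.25
  om <- overlap_map(a, b)
  expect_identical(sum(om == "A only"), sum(a & !b))
  expect_identical(sum(om == "B only"), sum(!a & b))
  expect_identical(sum(om == "both"), sum(a & b))
  w <- vertex_areas(mesh)
  cat_area <- tapply(w, om, sum, default = 0)
  expect_equal(sum(cat_area), sum(w), tolerance = 1e-9)
  # degenerate cases
  expect_setequal(as.character(unique(overlap_map(a, a))),
                  c("neither", "both")[c(any(!a), any(a))])
  expect_identical(sum(overlap_map(a, !a) == "both"), 0L)
})

test_that("spatial correlation: identity, inversion, and the independent null", {
  set.seed(72)
  x <- rnorm(500)
  expect_equal(spatial_correlation(x, x)$rho, 1)
  expect_equal(spatial_correlation(x, -x)$rho, -1)
  expect_identical(spatial_correlation(x, x)$method, "spearman")
  expect_equal(spatial_correlation(x, 2 * x + 5, method = "pearson")$rho, 1)
  expect_warning(out <- spatial_correlation(rep(1, 10), rnorm(10)),
                 "constant map")
  expect_true(is.na(out$rho))
  # independent maps at the downsampled resolution stay near zero
  n_small <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    rho <- spatial_correlation(rnorm(2562), rnorm(2562))$rho
    n_small <- n_small + (abs(rho) < 0.06)
  }
  expect_gte(n_small, 19L)
})

test_that("correlation downsampling follows the nested icosphere subset", {
  mesh <- test_mesh(4)
  set.seed(73)
  a <- rnorm(2562); b <- a + rnorm(2562, 0, 0.5)
  full <- spatial_correlation(a, b, method = "pearson")
  down <- spatial_correlation(a, b, method = "pearson", mesh = mesh,
                              downsample_order = 2)
  expect_identical(down$n_vertices, 162L)
  expect_equal(down$rho, cor(a[1:162], b[1:162]))
  expect_gt(full$rho, 0.7)
})

test_that("area statistics report ratio and containment from vertex areas", {
  mesh <- test_mesh(3)
  w <- vertex_areas(mesh)
  b <- geodesic_disc(mesh, 1L, 20)
  far <- which.min(mesh$vertices %*% mesh$vertices[1L, ])
  a <- b | geodesic_disc(mesh, far, 20)      # B plus a disjoint twin of B
  st <- area_statistics(a, b, mesh)
  expect_equal(st$containment, 1.0)
  expect_equal(st$ratio, sum(w[a]) / sum(w[b]))
  expect_equal(st$ratio, 2, tolerance = 0.1)
  ident <- area_statistics(b, b, mesh)
  expect_equal(ident$ratio, 1)
  expect_equal(ident$containment, 1)
  expect_warning(st0 <- area_statistics(b, logical(length(b)), mesh),
                 "empty")
  expect_true(is.na(st0$ratio))
  set.seed(74)
  x <- runif(length(b)) < 0.3; y <- runif(length(b)) < 0.3
  st2 <- area_statistics(x, y, mesh)
  expect_equal(st2$area_both, sum(w[x & y]), tolerance = 1e-9)
  expect_equal(st2$ratio, sum(w[x]) / sum(w[y]), tolerance = 1e-12)
})

test_that("variant pairs expose analytic ground-truth overlap", {
  # nested patches, same center: Dice from spherical-cap geometry
  mk_cfg <- function(r, seed) cohort_config(
    sizes = c("CS-" = 2L, "CS+" = 1L, "IMP+" = 1L),
    imp_split = c("MCI-DS" = 1L, "DEM" = 0L),
    mesh_order = 4L, noise_fwhm_mm = 40,
    patches = lapply(c("left", "right"), function(h)
      list(name = "parietal", hemisphere = h, direction = c(0, 0, 1),
           radius_mm = r, thin_mm = c("CS-" = 0, "CS+" = 0, "IMP+" = 0.4))),
    seed = seed)
  pair <- generate_variant_pair(mk_cfg(30, 80L), mk_cfg(15, 81L))
  a <- pair$a$truth$left$union; b <- pair$b$truth$left$union
  expect_true(all(!b | a))                   # nested by construction
  cap <- function(r) 2 * pi * 100^2 * (1 - cos(r / 100))
  want <- 2 * cap(15) / (cap(30) + cap(15))
  expect_equal(dice(a, b), want, tolerance = 0.15)
  # mismatched mesh orders are refused
  expect_error(generate_variant_pair(mk_cfg(30, 80L),
                                     cohort_config(mesh_order = 3L)),
               "mesh order")
})

test_that("a 6x patch-area configuration yields a ~6x true-mask area ratio", {
  # cap areas: 1 - cos(r_a / R) = 6 * (1 - cos(r_b / R)) with r_b = 15
  r_b <- 15
  r_a <- 100 * acos(1 - 6 * (1 - cos(r_b / 100)))
  mesh <- test_mesh(4)
  a <- geodesic_disc(mesh, 1L, r_a)
  b <- geodesic_disc(mesh, 1L, r_b)
  st <- area_statistics(a, b, mesh)
  expect_equal(st$ratio, 6, tolerance = 6 * 0.12)
})
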