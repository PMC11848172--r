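test_that("icosphere subdivision gives the closed-sphere counts and topology", {
  for (k in 0:5) {
    m <- test_mesh(k)
    expect_identical(nrow(m$vertices), as.integer(10 * 4^k + 2))
    expect_identical(nrow(m$faces), as.integer(20 * 4^k))
    if (k <= 3) {
      e <- oracle_edges(m$faces)
      # closed surface: Euler characteristic V - E + F = 2
      expect_identical(nrow(m$vertices) - nrow(e) + nrow(m$faces), 2L)
    }
    expect_true(all(abs(sqrt(rowSums(m$vertices^2)) - 100) < 1e-9))
  }
  expect_error(build_icosphere(8), "order <= 7")
  expect_error(build_icosphere(-1), "integer >= 0")
})

test_that("icosphere vertex ordering is nested across orders", {
  m2 <- test_mesh(2); m4 <- test_mesh(4)
  expect_equal(m4$vertices[seq_len(nrow(m2$vertices)), ], m2$vertices)
})

test_that("vertex adjacency matches brute-force edge enumeration", {
  m0 <- test_mesh(0)
  expect_true(all(lengths(vertex_adjacency(m0)) == 5L))
  m2 <- test_mesh(2)
  deg <- lengths(vertex_adjacency(m2))
  expect_identical(sum(deg == 5L), 12L)
  expect_identical(sum(deg == 6L), nrow(m2$vertices) - 12L)
  # symmetric and consistent with an independent edge enumeration
  ed <- oracle_edges(m2$faces)
  oracle_deg <- tabulate(c(ed[, 1], ed[, 2]), nbins = nrow(m2$vertices))
  expect_identical(as.integer(deg), oracle_deg)
  adj <- vertex_adjacency(m2)
  for (v in sample(nrow(m2$vertices), 20))
    for (w in adj[[v]]) expect_true(v %in% adj[[w]])
})

test_that("single-triangle mesh: two neighbours and analytic vertex areas", {
  tri <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0)),
                      rbind(c(1, 2, 3)), "left")
  expect_true(all(lengths(vertex_adjacency(tri)) == 2L))
  expect_equal(vertex_areas(tri), rep(sqrt(3) / 4 / 3, 3), tolerance = 1e-12)
})

test_that("vertex areas conserve total triangle area and approximate the sphere", {
  m3 <- test_mesh(3)
  v <- m3$vertices; f <- m3$faces
  cross_norm <- function(a, b) {
    sqrt((a[, 2] * b[, 3] - a[, 3] * b[, 2])^2 +
           (a[, 3] * b[, 1] - a[, 1] * b[, 3])^2 +
           (a[, 1] * b[, 2] - a[, 2] * b[, 1])^2)
  }
  face_area <- cross_norm(v[f[, 2], ] - v[f[, 1], ],
                          v[f[, 3], ] - v[f[, 1], ]) / 2
  va <- vertex_areas(m3)
  expect_equal(sum(va), sum(face_area), tolerance = 1e-9)
  expect_lt(abs(sum(va) - 4 * pi * 100^2) / (4 * pi * 100^2), 0.03)
})

test_that("degenerate zero-area faces are flagged", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(2, 0, 0))
  f <- rbind(c(1, 2, 3), c(1, 2, 4))     # second face is collinear
  m <- surface_mesh(v, f, "left")
  expect_warning(vertex_areas(m), "degenerate")
})

test_that("connected components match the flood-fill oracle on random masks", {
  for (order in c(2, 3)) {
    m <- test_mesh(order)
    n <- nrow(m$vertices)
    set.seed(100 + order)
    for (rep in 1:10) {
      mask <- runif(n) < runif(1, 0.05, 0.5)
      got <- connected_components(m, mask)
      want <- oracle_components(m$faces, mask)
      got_sets <- lapply(got$vertices, sort)
      expect_identical(length(got_sets), length(want))
      expect_setequal(
        vapply(got_sets, paste, collapse = ",", character(1)),
        vapply(want, paste, collapse = ",", character(1)))
    }
  }
})

test_that("connected components: empty, full, and two-disc masks", {
  m <- test_mesh(3)
  n <- nrow(m$vertices)
  expect_identical(nrow(connected_components(m, logical(n))), 0L)
  full <- connected_components(m, rep(TRUE, n))
  expect_identical(nrow(full), 1L)
  expect_equal(full$area_mm2, sum(vertex_areas(m)), tolerance = 1e-9)
  # two antipodal geodesic discs stay separate clusters
  d1 <- geodesic_disc(m, 1L, 25)
  far <- which.min(m$vertices %*% m$vertices[1L, ])
  d2 <- geodesic_disc(m, far, 25)
  expect_false(any(d1 & d2))
  cc <- connected_components(m, d1 | d2)
  expect_identical(nrow(cc), 2L)
  expect_setequal(unlist(cc$vertices), which(d1 | d2))
})

test_that("cluster vertex sets are disjoint and internally connected", {
  m <- test_mesh(2)
  set.seed(42)
  mask <- runif(nrow(m$vertices)) < 0.3
  cc <- connected_components(m, mask)
  all_v <- unlist(cc$vertices)
  expect_identical(anyDuplicated(all_v), 0L)
  for (vs in cc$vertices) {
    sub <- logical(nrow(m$vertices)); sub[vs] <- TRUE
    expect_identical(length(oracle_components(m$faces, sub)), 1L)
  }
})

test_that("downsampling takes the nested vertex subset", {
  m4 <- test_mesh(4)
  idx_map <- seq_len(nrow(m4$vertices))
  down <- downsample_map(idx_map, m4, 2)
  expect_identical(down, seq_len(162L))
  expect_equal(downsample_map(rep(2.5, 2562), m4, 1), rep(2.5, 42))
  expect_error(downsample_map(idx_map, m4, 4), "target_order")
  tri <- surface_mesh(diag(3), rbind(c(1, 2, 3)), "left")
  expect_error(downsample_map(1:3, tri, 0), "icosphere")
})

test_that("geodesic disc radii behave like spherical caps", {
  m <- test_mesh(3)
  r <- 30
  cap_area <- 2 * pi * 100^2 * (1 - cos(r / 100))
  disc <- geodesic_disc(m, 1L, r)
  got <- sum(vertex_areas(m)[disc])
  expect_lt(abs(got - cap_area) / cap_area, 0.15)
})
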