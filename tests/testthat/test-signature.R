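# Small, strong-signal cohort used across derivation tests.
signal_cohort <- function(seed = 40L, order = 2L) {
  cfg <- cohort_config(
    sizes = c("CS-" = 30L, "CS+" = 0L, "IMP+" = 20L),
    imp_split = c("MCI-DS" = 10L, "DEM" = 10L),
    mesh_order = order, noise_fwhm_mm = 40,
    patches = list(list(name = "parietal", hemisphere = "left",
                        direction = c(0, 0, 1), radius_mm = 35,
                        thin_mm = c("CS-" = 0, "CS+" = 0, "IMP+" = 0.5)),
                   list(name = "parietal", hemisphere = "right",
                        direction = c(0, 0, 1), radius_mm = 35,
                        thin_mm = c("CS-" = 0, "CS+" = 0, "IMP+" = 0.5))),
    seed = seed)
  generate_cohort(cfg)
}

test_that("candidate masks from nested vertex thresholds are nested", {
  coh <- signal_cohort()
  cand <- derive_candidates(coh, c("CS-", "IMP+"),
                            vertex_p_grid = c(0.005, 0.0005),
                            cluster_p = 0.5, n_perm = 99L, seed = 41L)
  expect_length(cand, 2L)
  expect_equal(cand[[1L]]$vertex_p, 0.005)
  for (h in c("left", "right")) {
    strict <- cand[[2L]]$masks[[h]]
    loose <- cand[[1L]]$masks[[h]]
    expect_true(all(!strict | loose))        # strict subset of loose
  }
  expect_gt(cand[[1L]]$area_mm2, 0)
})

test_that("derivation excludes withheld reference subjects", {
  coh <- signal_cohort(seed = 42L)
  sp <- split_reference(coh, "CS-", 0.8, seed = 1L)
  c_all <- derive_candidates(coh, c("CS-", "IMP+"), vertex_p_grid = 0.01,
                             cluster_p = 0.05, n_perm = 99L, seed = 5L)
  c_split <- derive_candidates(coh, c("CS-", "IMP+"), split = sp,
                               vertex_p_grid = 0.01,
                               cluster_p = 0.05, n_perm = 99L, seed = 5L)
  # different derivation samples -> generally different t maps/masks; at the
  # least the candidate is still a strong overlap of the truth patch
  expect_gt(dice(c_split[[1L]]$masks$left, coh$truth$left$union), 0.5)
  expect_gt(dice(c_all[[1L]]$masks$left, coh$truth$left$union), 0.5)
})

test_that("insufficient permutation resolution warns", {
  coh <- signal_cohort(seed = 43L)
  expect_warning(
    derive_candidates(coh, c("CS-", "IMP+"), vertex_p_grid = 0.01,
                      cluster_p = 0.001, n_perm = 50L, seed = 1L),
    "cannot resolve")
})

test_that("signature scores are area-weighted mean thickness", {
  coh <- signal_cohort(seed = 44L)
  mesh <- coh$meshes$left
  V <- nrow(mesh$vertices)
  # uniform map: score equals the constant regardless of mask
  uni <- coh
  uni$thickness$left[] <- 2.5
  uni$thickness$right[] <- 2.5
  mask <- manual_mask(list(left = seq_len(V) <= 10,
                           right = logical(V)))
  expect_equal(unname(signature_score(uni, mask)),
               rep(2.5, nrow(coh$subjects)), tolerance = 1e-12)
  # random mask: equals the direct weighted-sum oracle over both hemispheres
  set.seed(45)
  m2 <- manual_mask(list(left = runif(V) < 0.2, right = runif(V) < 0.1))
  got <- signature_score(coh, m2)
  w <- list(left = vertex_areas(coh$meshes$left),
            right = vertex_areas(coh$meshes$right))
  for (j in c(1L, 11L)) {
    num <- sum(w$left[m2$masks$left] *
                 coh$thickness$left[m2$masks$left, j]) +
      sum(w$right[m2$masks$right] * coh$thickness$right[m2$masks$right, j])
    den <- sum(w$left[m2$masks$left]) + sum(w$right[m2$masks$right])
    expect_equal(unname(got[j]), num / den, tolerance = 1e-12)
  }
  # two-vertex weighted-mean arithmetic: areas w1, w2 and values 2, 4
  v2 <- which(m2$masks$left)[1:2]
  single <- manual_mask(list(left = seq_len(V) %in% v2, right = logical(V)))
  uni$thickness$left[v2, ] <- c(2, 4)
  ww <- w$left[v2]
  expect_equal(unname(signature_score(uni, single)[1L]),
               (2 * ww[1] + 4 * ww[2]) / sum(ww), tolerance = 1e-12)
})

test_that("empty masks are unusable for scoring but tolerated in selection", {
  coh <- signal_cohort(seed = 46L)
  V <- nrow(coh$meshes$left$vertices)
  empty <- manual_mask(list(left = logical(V), right = logical(V)))
  expect_error(signature_score(coh, empty), "empty signature mask")
  expect_null(select_ideal_signature(list(empty), c("CS-", "IMP+"), coh))
  # empty candidates are skipped in evaluation
  ev <- evaluate_signatures(list(empty), coh,
                            comparisons = list(c("CS-", "IMP+")))
  expect_identical(nrow(ev), 0L)
})

test_that("selection maximizes AUC and breaks exact ties by smaller area", {
  coh <- signal_cohort(seed = 47L)
  V <- nrow(coh$meshes$left$vertices)
  # zero out noise so that any mask separates groups perfectly (AUC tie)
  adv <- coh$subjects$stage == "IMP+"
  for (h in c("left", "right")) {
    coh$thickness[[h]][] <- 2.5
    coh$thickness[[h]][, adv] <- 2.2
  }
  small <- manual_mask(list(left = seq_len(V) <= 5, right = logical(V)),
                       area = 100)
  big <- manual_mask(list(left = seq_len(V) <= 50, right = logical(V)),
                     area = 200)
  sel <- select_ideal_signature(list(big, small), c("CS-", "IMP+"), coh)
  expect_equal(sel$auc, 1.0)
  expect_equal(sel$area_mm2, 100)
  # a genuinely better candidate wins regardless of area
  set.seed(48)
  coh$thickness$left[1:5, ] <- coh$thickness$left[1:5, ] + rnorm(5 * 50, 0, 2)
  sel2 <- select_ideal_signature(list(big, small), c("CS-", "IMP+"), coh)
  expect_equal(sel2$area_mm2, 200)
})

test_that("evaluation covers the full candidate-by-comparison cross", {
  cfg <- cohort_config(sizes = c("CS-" = 25L, "CS+" = 15L, "IMP+" = 12L),
                       imp_split = c("MCI-DS" = 6L, "DEM" = 6L),
                       mesh_order = 2L, noise_fwhm_mm = 40, seed = 49L)
  coh <- generate_cohort(cfg)
  V <- nrow(coh$meshes$left$vertices)
  set.seed(50)
  cands <- list(manual_mask(list(left = runif(V) < 0.2, right = logical(V))),
                manual_mask(list(left = logical(V), right = runif(V) < 0.2),
                            comparison = c("CS+", "IMP+"), vertex_p = 0.005))
  ev <- evaluate_signatures(cands, coh)
  expect_identical(nrow(ev), 6L)             # 2 candidates x 3 comparisons
  expect_setequal(unique(ev$comparison),
                  c("CS- vs CS+", "CS+ vs IMP+", "CS- vs IMP+"))
  expect_true(all(ev$p_adjusted >= ev$p_value - 1e-15))
  expect_true(all(ev$p_adjusted >= 0 & ev$p_adjusted <= 1))
  # BH adjustment equals the step-up oracle on the table
  expect_equal(ev$p_adjusted, oracle_bh(ev$p_value), tolerance = 1e-12)
})

test_that("cortical-vs-subcortical effect comparison follows Welch's t", {
  set.seed(51)
  a <- rnorm(12, 1.2, 0.3); b <- rnorm(14, 0.75, 0.25)
  got <- compare_effect_domains(a, b)
  want <- oracle_welch(a, b)
  expect_equal(got$t, want$t, tolerance = 1e-12)
  expect_equal(got$p_value, want$p, tolerance = 1e-12)
  expect_equal(unname(got$mean_d), c(mean(a), mean(b)))
  # identical collections: t = 0
  expect_equal(compare_effect_domains(a, a)$t, 0)
  # zero-variance difference is flagged degenerate
  deg <- compare_effect_domains(rep(1, 3), rep(0, 3))
  expect_true(deg$degenerate)
  expect_identical(deg$t, Inf)
  expect_equal(unname(deg$mean_d[1] - deg$mean_d[2]), 1)
})
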