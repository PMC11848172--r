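test_that("without covariates the vertex t equals the pooled two-sample t", {
  set.seed(20)
  n1 <- 14; n2 <- 9; V <- 40
  stage <- rep(c("CS-", "IMP+"), c(n1, n2))
  thick <- matrix(rnorm(V * (n1 + n2), 2.5, 0.3), V)
  coh <- make_mini_cohort(thick, stage)
  fit <- fit_vertex_glm(coh, c("CS-", "IMP+"), covariates = character(0))
  for (v in seq_len(V)) {
    tt <- t.test(thick[v, stage == "CS-"], thick[v, stage == "IMP+"],
                 var.equal = TRUE)
    expect_equal(fit$hemi$left$t[v], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(fit$hemi$left$p[v], tt$p.value, tolerance = 1e-10)
  }
})

test_that("covariate-adjusted t matches a normal-equations oracle exactly", {
  set.seed(21)
  n <- 30; V <- 25
  stage <- rep(c("CS-", "CS+"), c(17, 13))
  age <- rnorm(n, 45, 8)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  thick <- matrix(rnorm(V * n, 2.5, 0.25), V)
  coh <- make_mini_cohort(thick, stage, age = age, sex = sex)
  fit <- fit_vertex_glm(coh, c("CS-", "CS+"))
  g <- as.numeric(stage == "CS+")
  s <- as.numeric(sex == "male")
  for (v in seq_len(V)) {
    sm <- summary(lm(thick[v, ] ~ g + age + s))
    expect_equal(-fit$hemi$left$t[v], unname(sm$coefficients["g", "t value"]),
                 tolerance = 1e-10)
    expect_equal(fit$hemi$left$delta_mm[v],
                 -unname(sm$coefficients["g", "Estimate"]), tolerance = 1e-10)
  }
})

test_that("t, p, d and delta are invariant to a constant thickness shift", {
  set.seed(22)
  stage <- rep(c("CS-", "IMP+"), c(12, 10))
  thick <- matrix(rnorm(30 * 22, 2.5, 0.3), 30)
  age <- rnorm(22, 45, 7)
  f1 <- fit_vertex_glm(make_mini_cohort(thick, stage, age = age),
                       c("CS-", "IMP+"))
  f2 <- fit_vertex_glm(make_mini_cohort(thick + 5, stage, age = age),
                       c("CS-", "IMP+"))
  expect_equal(f1$hemi$left$t, f2$hemi$left$t, tolerance = 1e-9)
  expect_equal(f1$hemi$left$p, f2$hemi$left$p, tolerance = 1e-9)
  expect_equal(f1$hemi$left$delta_mm, f2$hemi$left$delta_mm, tolerance = 1e-9)
  expect_equal(f1$hemi$left$cohens_d, f2$hemi$left$cohens_d, tolerance = 1e-9)
})

test_that("a noiseless constant group difference is recovered exactly", {
  stage <- rep(c("CS-", "IMP+"), c(8, 6))
  base <- matrix(rep(seq(2, 3, length.out = 10), 14), 10)
  base[, stage == "IMP+"] <- base[, stage == "IMP+"] - 0.3
  coh <- make_mini_cohort(base, stage)
  fit <- fit_vertex_glm(coh, c("CS-", "IMP+"), covariates = character(0))
  expect_equal(fit$hemi$left$delta_mm, rep(0.3, 10), tolerance = 1e-10)
  exported <- effect_size_map(fit, "delta_mm", "left")
  expect_equal(as.numeric(exported), rep(-0.3, 10), tolerance = 1e-10)
  expect_identical(attr(exported, "units"), "mm")
})

test_that("null data give calibrated t and p distributions", {
  set.seed(23)
  n1 <- 20; n2 <- 20; V <- 3000
  stage <- rep(c("CS-", "CS+"), c(n1, n2))
  thick <- matrix(rnorm(V * (n1 + n2)), V)
  fit <- fit_vertex_glm(make_mini_cohort(thick, stage),
                        covariates = character(0), comparison = c("CS-", "CS+"))
  frac <- mean(fit$hemi$left$p < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / V))
  df <- fit$df
  e_abs_t <- 2 * sqrt(df) * gamma((df + 1) / 2) /
    (sqrt(pi) * (df - 1) * gamma(df / 2))
  se <- sd(abs(fit$hemi$left$t)) / sqrt(V)
  expect_lt(abs(mean(abs(fit$hemi$left$t)) - e_abs_t), 3 * se)
})

test_that("Cohen's d recovers a one-SD shift and shares delta's sign", {
  set.seed(24)
  n1 <- 400; n2 <- 400; V <- 50
  stage <- rep(c("CS-", "IMP+"), c(n1, n2))
  thick <- matrix(rnorm(V * (n1 + n2), 2.5, 0.25), V)
  thick[, stage == "IMP+"] <- thick[, stage == "IMP+"] - 0.25   # 1 SD thinner
  fit <- fit_vertex_glm(make_mini_cohort(thick, stage),
                        comparison = c("CS-", "IMP+"),
                        covariates = character(0))
  expect_lt(abs(mean(fit$hemi$left$cohens_d) - 1), 0.1)
  expect_true(all(sign(fit$hemi$left$cohens_d) ==
                    sign(fit$hemi$left$delta_mm)))
  # raw-SD variant agrees closely in the no-covariate case
  fit_raw <- fit_vertex_glm(make_mini_cohort(thick, stage),
                            comparison = c("CS-", "IMP+"),
                            covariates = character(0), d_method = "raw")
  expect_equal(fit$hemi$left$cohens_d, fit_raw$hemi$left$cohens_d,
               tolerance = 0.01)
})

test_that("rank-deficient covariates are dropped with a warning", {
  set.seed(25)
  stage <- rep(c("CS-", "IMP+"), c(8, 7))
  thick <- matrix(rnorm(10 * 15, 2.5, 0.3), 10)
  coh <- make_mini_cohort(thick, stage, age = rnorm(15, 45, 6),
                          sex = rep("male", 15))
  expect_warning(fit <- fit_vertex_glm(coh, c("CS-", "IMP+")),
                 "rank-deficient")
  expect_identical(fit$covariates, "age")
})

test_that("synthetic patch thinning appears at the configured magnitude", {
  cfg <- cohort_config(sizes = c("CS-" = 60L, "CS+" = 0L, "IMP+" = 40L),
                       imp_split = c("MCI-DS" = 20L, "DEM" = 20L),
                       mesh_order = 3L, seed = 26L)
  coh <- generate_cohort(cfg)
  fit <- fit_vertex_glm(coh, c("CS-", "IMP+"))
  for (h in c("left", "right")) {
    tr <- coh$truth[[h]]
    parietal <- which(vapply(tr$patches, function(p) p$name, "") == "parietal")
    est <- mean(fit$hemi[[h]]$delta_mm[tr$masks[[parietal]]])
    want <- tr$thin[[parietal]][["IMP+"]]
    se1 <- 0.25 * sqrt(1 / 60 + 1 / 40)    # single-vertex SE upper bound
    expect_lt(abs(est - want), 2 * se1,
              label = sprintf("%s parietal: est %.3f vs configured %.3f",
                              h, est, want))
  }
})
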