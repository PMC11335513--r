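test_that("preprocessing handles closed-form and degenerate cases", {
  # constant matrix, log_only
  vm <- volume_matrix(matrix(2.5, 4, 3))
  out <- preprocess_volumes(vm, rep(1, 4), mode = "log_only")
  expect_equal(unclass(out), matrix(log(2.5), 4, 3), ignore_attr = TRUE)

  # closed form 3x2 under log_only
  vm2 <- volume_matrix(matrix(c(1, exp(1), exp(1), exp(1), 1, exp(1)), 3, 2))
  out2 <- preprocess_volumes(vm2, rep(1, 3), mode = "log_only")
  expect_equal(unclass(out2), matrix(c(0, 1, 1, 1, 0, 1), 3, 2),
               tolerance = 1e-12, ignore_attr = TRUE)

  # constant tiv degenerates to log_only
  vm3 <- fixture_volumes()
  a <- preprocess_volumes(vm3, rep(1500, 30), mode = "log_tiv_residual")
  b <- preprocess_volumes(vm3, rep(1500, 30), mode = "log_only")
  expect_equal(unclass(a), unclass(b), ignore_attr = TRUE)

  # tiv residualization kills the log-tiv slope per region
  set.seed(2)
  tiv <- exp(rnorm(30, 7, 0.1))
  vm4 <- volume_matrix(unclass(vm3) * (tiv / mean(tiv)))
  res <- preprocess_volumes(vm4, tiv, mode = "log_tiv_residual")
  for (j in 1:3) expect_lt(abs(cor(res[, j], log(tiv))), 1e-10)

  expect_error(volume_matrix(matrix(c(-1, 1, 1, 1), 2, 2)), "non-positive")
})

test_that("double centering removes additive structure", {
  u <- rnorm(8); v <- rnorm(5)
  additive <- outer(u, rep(1, 5)) + outer(rep(1, 8), v)
  expect_lt(max(abs(double_center(additive))), 1e-12)

  expect_equal(unclass(double_center(matrix(c(0, 2, 2, 0), 2, 2))),
               matrix(c(-1, 1, 1, -1), 2, 2), ignore_attr = TRUE)

  set.seed(3)
  x <- matrix(rnorm(50 * 14, 5), 50, 14)
  srp <- double_center(x)
  expect_lt(max(abs(rowMeans(srp))), 1e-10 * max(abs(x)))
  expect_lt(max(abs(colMeans(srp))), 1e-10 * max(abs(x)))
})

test_that("decomposition satisfies rank, orthonormality and reconstruction", {
  set.seed(4)
  # exact rank-1 srp
  u <- rnorm(20); w <- rnorm(6)
  srp1 <- double_center((u - mean(u)) %o% (w - mean(w)))
  dec1 <- derive_components(srp1)
  expect_equal(length(dec1$eigenvalues), 1L)

  x <- matrix(rnorm(40 * 8), 40, 8)
  dec <- derive_components(double_center(x))
  expect_equal(crossprod(dec$gis), diag(ncol(dec$gis)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(dec$ssf %*% t(dec$gis), dec$srp, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(dec$eigenvalues) <= 1e-12))
  # ssf columns mutually uncorrelated
  cc <- cor(dec$ssf)
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-8)

  expect_warning(derive_components(matrix(0, 5, 4)), "degenerate")
})

test_that("planted pattern is recovered by the leading component", {
  g <- fixture_cohort500()
  pre <- preprocess_volumes(g$volumes, g$cohort$tiv)
  dec <- derive_components(double_center(pre))
  cos1 <- abs(sum(dec$gis[, 1] * default_pattern_weights()))
  expect_gte(cos1, 0.9)
})

test_that("AIC prefix selection matches its definition", {
  set.seed(6)
  x <- matrix(rnorm(200 * 14), 200, 14)
  dec <- derive_components(double_center(x))

  # biomarker == first score: k = 1, floored RSS
  sel1 <- select_component_set(dec$ssf, dec$ssf[, 1], max_k = 5)
  expect_identical(sel1$component_set, 1L)

  # argmin property on independent noise
  bm <- rnorm(200)
  sel <- select_component_set(dec$ssf, bm, max_k = 8)
  expect_equal(min(sel$aic_trace), sel$aic_trace[length(sel$component_set)])
  expect_true(all(sel$aic_trace >= sel$aic_trace[length(sel$component_set)]))

  # brute-force AIC recomputation oracle
  k <- 3L
  fit <- lm(bm ~ dec$ssf[, 1:k])
  aic_oracle <- 200 * log(sum(resid(fit)^2) / 200) + 2 * (k + 2)
  expect_equal(sel$aic_trace[k], aic_oracle, tolerance = 1e-10)

  # biomarker loading strongly and equally on components 1 and 2:
  # near-exact fit regime, where the floored RSS makes {1,2} the AIC optimum
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    xs <- matrix(rnorm(200 * 14), 200, 14)
    ds <- derive_components(double_center(xs))
    bm2 <- scale(ds$ssf[, 1])[, 1] + scale(ds$ssf[, 2])[, 1] +
      1e-8 * rnorm(200)
    if (identical(select_component_set(ds$ssf, bm2,
                                       max_k = 8)$component_set, 1:2))
      hits <- hits + 1L
  }
  expect_gte(hits, 90L)

  expect_error(select_component_set(dec$ssf, bm, max_k = 0), "integer")
})

test_that("combined pattern has the documented sign behavior", {
  set.seed(8)
  x <- matrix(rnorm(100 * 10), 100, 10)
  dec <- derive_components(double_center(x))
  bm <- dec$ssf[, 1] + 0.2 * rnorm(100)
  sel <- select_component_set(dec$ssf, bm, max_k = 4)
  cmb <- combine_pattern(dec, sel$component_set, sel$combine_coefs, bm)
  expect_equal(sqrt(sum(cmb$weights^2)), 1, tolerance = 1e-12)
  expect_gte(cor(dec$srp %*% cmb$weights, bm), 0)

  cmb_flip <- combine_pattern(dec, sel$component_set, sel$combine_coefs, -bm)
  expect_equal(cmb_flip$sign_convention, -cmb$sign_convention)
  expect_equal(abs(cmb_flip$weights), abs(cmb$weights), tolerance = 1e-12)

  # planted cohort: hippocampus/accumbens one sign, basal ganglia opposite
  g <- fixture_cohort500()
  model <- derive_pattern(g$volumes, g$cohort$tiv, g$cohort$hcy)
  w <- model$weights
  hip_acc <- w[c("L_hippocampus", "R_hippocampus",
                 "L_accumbens", "R_accumbens")]
  bg <- w[c("L_caudate", "R_caudate", "L_putamen", "R_putamen",
            "L_pallidum", "R_pallidum")]
  expect_true(all(sign(hip_acc) == sign(hip_acc[1])))
  expect_true(all(sign(bg) == -sign(hip_acc[1])))
})

test_that("expression scoring is reproducible and recovers the truth", {
  g <- fixture_cohort500()
  model <- derive_pattern(g$volumes, g$cohort$tiv, g$cohort$hcy)
  ex <- express_pattern(model, g$volumes, g$cohort$tiv)
  expect_equal(mean(ex$z), 0, tolerance = 1e-10)
  expect_equal(sd(ex$z), 1, tolerance = 1e-10)
  expect_gte(cor(ex$z, g$cohort$true_expression), 0.8)
  # positive association with the biomarker under the sign convention
  expect_gte(cor(ex$z, g$cohort$hcy), 0)

  # duplicating every subject: identical scores per duplicate
  vm2 <- volume_matrix(rbind(unclass(g$volumes), unclass(g$volumes)),
                       region_names = colnames(g$volumes),
                       subject_ids = c(rownames(g$volumes),
                                       paste0(rownames(g$volumes), "_dup")))
  ex2 <- express_pattern(model, vm2, rep(g$cohort$tiv, 2))
  expect_equal(unname(ex2$z[1:500]), unname(ex2$z[501:1000]),
               tolerance = 1e-12)

  # region mismatch errors name the offenders
  vm3 <- g$volumes
  colnames(vm3)[1] <- "not_a_region"
  expect_error(express_pattern(model, vm3, g$cohort$tiv), "L_hippocampus")
})

test_that("pipeline is invariant to reordering and volume scaling", {
  g <- fixture_cohort160()
  vm <- g$volumes; tiv <- g$cohort$tiv; hcy <- g$cohort$hcy
  model <- derive_pattern(vm, tiv, hcy)

  # region reordering permutes weights
  perm <- sample(ncol(vm))
  vmp <- volume_matrix(unclass(vm)[, perm], region_names = colnames(vm)[perm],
                       subject_ids = rownames(vm))
  mp <- derive_pattern(vmp, tiv, hcy)
  expect_equal(mp$weights[colnames(vm)], model$weights, tolerance = 1e-8)

  # subject reordering permutes expression
  sperm <- sample(nrow(vm))
  vms <- volume_matrix(unclass(vm)[sperm, ], region_names = colnames(vm),
                       subject_ids = rownames(vm)[sperm])
  ms <- derive_pattern(vms, tiv[sperm], hcy[sperm])
  zs <- express_pattern(ms, vms, tiv[sperm])$z
  z <- express_pattern(model, vm, tiv)$z
  expect_equal(zs, z[sperm], tolerance = 1e-8)

  # global volume scaling leaves srp, weights and z untouched
  vmc <- volume_matrix(unclass(vm) * 3.7, region_names = colnames(vm),
                       subject_ids = rownames(vm))
  mc <- derive_pattern(vmc, tiv, hcy)
  expect_equal(mc$weights, model$weights, tolerance = 1e-8)
  expect_equal(express_pattern(mc, vmc, tiv)$z, z, tolerance = 1e-8)
})

test_that("bootstrap reliability is deterministic and calibrated", {
  g <- fixture_cohort160()
  r1 <- bootstrap_pattern(g$volumes, g$cohort$tiv, g$cohort$hcy,
                          n_iterations = 100, seed = 42)
  r2 <- bootstrap_pattern(g$volumes, g$cohort$tiv, g$cohort$hcy,
                          n_iterations = 100, seed = 42)
  expect_identical(r1$table, r2$table)
  expect_equal(r1$n_iterations, 100L)
  # percentile bounds bracket the point estimate for most regions
  ok <- with(r1$table, ci_lower <= weight & weight <= ci_upper)
  expect_gte(mean(ok), 0.95)

  # strong planted pattern: strongly weighted regions are reliable
  strong <- names(which(abs(default_pattern_weights()) > 0.3))
  hits <- 0L
  for (s in 1:20) {
    gs <- generate_cohort(cohort_config(n_subjects = 160, seed = 100 + s,
                                        hcy_loading = 0.9,
                                        pattern_scale = 0.1,
                                        region_noise_sd = 0.01))
    rel <- bootstrap_pattern(gs$volumes, gs$cohort$tiv, gs$cohort$hcy,
                             n_iterations = 100, seed = s)
    z <- setNames(rel$table$z, rel$table$region)
    if (all(abs(z[strong]) > 2)) hits <- hits + 1L
  }
  expect_gte(hits, 18L)

  # pure-noise biomarker: few spuriously reliable regions
  fr <- vapply(1:5, function(s) {
    set.seed(1000 + s)
    noise <- rnorm(160)
    rel <- bootstrap_pattern(g$volumes, g$cohort$tiv, noise,
                             n_iterations = 100, seed = s)
    mean(abs(rel$table$z) > 2)
  }, numeric(1))
  expect_lte(mean(fr), 0.15)
})

test_that("hemisphere averaging collapses bilateral regions", {
  g <- fixture_cohort160()
  avg <- average_hemispheres(g$volumes)
  expect_equal(ncol(avg), 7L)
  expect_equal(unclass(avg)[, "hippocampus"],
               rowMeans(unclass(g$volumes)[, c("L_hippocampus",
                                               "R_hippocampus")]),
               tolerance = 1e-12)
})
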