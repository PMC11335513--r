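test_that("spec validation and path enumeration", {
  expect_error(mediation_spec("x", "y", character()), "1 to 3")
  expect_error(mediation_spec("x", "y", c("m1", "m2", "m3", "m4")), "1 to 3")
  expect_error(mediation_spec("x", "x", "m"), "disjoint")
  expect_error(mediation_spec("x", "y", "m", covariates = "m"), "overlap")

  expect_equal(enumerate_indirect_paths(1), list(1L))
  expect_equal(length(enumerate_indirect_paths(2)), 3L)
  p3 <- enumerate_indirect_paths(3)
  expect_equal(length(p3), 7L)
  # brute-force power-set filter oracle
  brute <- Filter(length, lapply(1:7, function(s)
    (1:3)[as.logical(bitwAnd(s, c(1L, 2L, 4L)))]))
  expect_true(setequal(lapply(p3, paste, collapse = ","),
                       lapply(brute, paste, collapse = ",")))
  expect_error(enumerate_indirect_paths(4), "1, 2 or 3")
})

test_that("fit_paths agrees with the lm oracle submodel by submodel", {
  ch <- fixture_cohort160()$cohort
  spec <- mediation_spec("age", "tmta_log",
                         c("log_wmh", "true_expression", "parietal"),
                         c("tiv", "sex", "education", "interval_days"),
                         n_boot = 100, seed = 1)
  fp <- fit_paths(ch, spec)
  m1 <- lm(log_wmh ~ age + tiv + sex + education + interval_days, ch)
  m2 <- lm(true_expression ~ age + log_wmh + tiv + sex + education +
             interval_days, ch)
  m3 <- lm(parietal ~ age + log_wmh + true_expression + tiv + sex +
             education + interval_days, ch)
  my <- lm(tmta_log ~ age + log_wmh + true_expression + parietal + tiv +
             sex + education + interval_days, ch)
  mt <- lm(tmta_log ~ age + tiv + sex + education + interval_days, ch)
  expect_equal(fp$a, c(coef(m1)[["age"]], coef(m2)[["age"]],
                       coef(m3)[["age"]]), tolerance = 1e-10)
  expect_equal(fp$d[2, 1], coef(m2)[["log_wmh"]], tolerance = 1e-10)
  expect_equal(fp$d[3, 1], coef(m3)[["log_wmh"]], tolerance = 1e-10)
  expect_equal(fp$d[3, 2], coef(m3)[["true_expression"]], tolerance = 1e-10)
  expect_equal(unname(fp$b),
               unname(coef(my)[c("log_wmh", "true_expression", "parietal")]),
               tolerance = 1e-10)
  expect_equal(fp$c_prime, coef(my)[["age"]], tolerance = 1e-10)
  expect_equal(fp$c, coef(mt)[["age"]], tolerance = 1e-10)
  # SEs and p-values from the outcome model
  sm <- summary(my)$coefficients
  expect_equal(unname(fp$se$b),
               unname(sm[c("log_wmh", "true_expression", "parietal"), 2]),
               tolerance = 1e-10)
  expect_equal(fp$p$c_prime, sm["age", 4], tolerance = 1e-10)
})

test_that("null and near-deterministic chains recover generating values", {
  pc0 <- default_path_coefficients(); pc0[] <- 0
  ch0 <- generate_cohort(cohort_config(n_subjects = 5000, seed = 55,
                                       path_coefficients = pc0))$cohort
  fp0 <- fit_paths(ch0, mediation_spec("age", "parietal",
                                       c("log_wmh", "true_expression"),
                                       n_boot = 100, seed = 1))
  expect_close(fp0$std$a, c(0, 0), tol = 3 / sqrt(5000) * 1.5)

  # deterministic limit: noise -> 0 downstream of M1 (M1 keeps independent
  # variation so the M2 design stays well conditioned)
  set.seed(9)
  x <- rnorm(500)
  m1 <- 2 * x + 0.2 * rnorm(500)
  m2 <- -1.5 * m1 + 0.1 * rnorm(500)
  y <- 0.5 * m2 + 0.01 * rnorm(500)
  d <- data.frame(x = x, m1 = m1, m2 = m2, y = y)
  fp <- fit_paths(d, mediation_spec("x", "y", c("m1", "m2"), n_boot = 100,
                                    seed = 1))
  expect_close(fp$a[1], 2, tol = 0.05)
  expect_close(fp$d[2, 1], -1.5, tol = 0.05)
  expect_close(fp$b[2], 0.5, tol = 0.02)
})

test_that("telescoping identity and zero-path annihilation hold", {
  ch <- fixture_cohort160()$cohort
  spec <- mediation_spec("age", "tmta_log",
                         c("log_wmh", "true_expression", "parietal"),
                         c("tiv", "sex", "education"), n_boot = 100, seed = 2)
  fp <- fit_paths(ch, spec)
  ind <- indirect_effects(fp)
  # std = raw * sd(x)/sd(y)
  expect_equal(ind$std, ind$raw * sd(ch$age) / sd(ch$tmta_log),
               tolerance = 1e-10)
  # full chain std effect = product of standardized path coefficients
  full <- ind$std[ind$path ==
    "age -> log_wmh -> true_expression -> parietal -> tmta_log"]
  prod_std <- fp$std$a[[1]] * fp$std$d[2, 1] * fp$std$d[3, 2] * fp$std$b[[3]]
  expect_equal(full, prod_std, tolerance = 1e-10)

  # any zero path coefficient kills the corresponding indirect effect
  fp$a[1] <- 0
  ind0 <- indirect_effects(fp)
  through_m1 <- grepl("log_wmh", ind0$path)
  expect_true(all(ind0$raw[through_m1] == 0))
  expect_true(all(ind0$raw[!through_m1] != 0))
})

test_that("affine rescaling leaves standardized effects unchanged", {
  ch <- fixture_cohort160()$cohort
  spec <- mediation_spec("age", "parietal", c("log_wmh", "true_expression"),
                         c("tiv", "sex"), n_boot = 100, seed = 3)
  base <- indirect_effects(fit_paths(ch, spec))
  ch2 <- ch
  ch2$age <- ch$age / 10 + 3
  ch2$parietal <- ch$parietal * 1000 - 5
  ch2$log_wmh <- ch$log_wmh * 2
  resc <- indirect_effects(fit_paths(ch2, spec))
  expect_equal(resc$std, base$std, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(resc$raw, base$raw)))
})

test_that("bootstrap mediation is deterministic, decomposable, reversible", {
  ch <- fixture_cohort160()$cohort
  ch$expression <- ch$true_expression
  spec <- mediation_spec("age", "parietal", c("log_wmh", "expression"),
                         c("tiv", "sex", "education"), n_boot = 200,
                         seed = 17)
  r1 <- bootstrap_mediation(ch, spec)
  r2 <- bootstrap_mediation(ch, spec)
  expect_identical(r1$indirects, r2$indirects)
  expect_equal(r1$boot_failures, 0L)
  expect_equal(r1$n_used, 160L)

  dec <- decompose_total(r1)
  expect_equal(dec$raw[dec$effect == "total"],
               dec$raw[dec$effect == "direct"] +
                 sum(dec$raw[-(1:2)]), tolerance = 1e-8)

  # k = 1: c - c' = a1 * b1 exactly
  sp1 <- mediation_spec("age", "parietal", "log_wmh", c("tiv", "sex"),
                        n_boot = 100, seed = 5)
  fp1 <- fit_paths(ch, sp1)
  expect_equal(fp1$c - fp1$c_prime, fp1$a[1] * fp1$b[1], tolerance = 1e-10)

  # reversal
  spr <- reverse_mediators(spec)
  expect_equal(spr$mediators, c("expression", "log_wmh"))
  expect_equal(reverse_mediators(spr)$mediators, spec$mediators)
  expect_error(reverse_mediators(sp1), "2 mediators")

  # reversed full-chain effect attenuates on a forward-generated cohort
  big <- fixture_cohort5000()$cohort
  big$expression <- big$true_expression
  fwd <- indirect_effects(fit_paths(big, spec))
  rev <- indirect_effects(fit_paths(big, spr))
  full_lab <- function(x) grepl("log_wmh.*expression|expression.*log_wmh",
                                x$path) & lengths(x$indices) == 2
  expect_lt(abs(rev$std[full_lab(rev)]), abs(fwd$std[full_lab(fwd)]))
})

test_that("bootstrap failure accounting and input checks work", {
  ch <- fixture_cohort160()$cohort
  expect_error(fit_paths(ch, mediation_spec("age", "parietal", "nope",
                                            n_boot = 100)),
               "missing column")
  ch$dup <- 2 * ch$age
  expect_error(fit_paths(ch, mediation_spec("age", "parietal", "log_wmh",
                                            covariates = "dup",
                                            n_boot = 100)),
               "collinear|rank")
  small <- ch[1:8, ]
  expect_error(fit_paths(small, mediation_spec("age", "parietal",
                                               c("log_wmh", "tmta_log"),
                                               covariates = c("tiv", "sex",
                                                              "education"),
                                               n_boot = 100)),
               "insufficient")
})
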