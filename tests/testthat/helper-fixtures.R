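# shared fixtures, built in code and cached per test run

fixture_env <- new.env(parent = emptyenv())

# default-world cohort at n = 160 (the study's sample size)
fixture_cohort160 <- function() {
  if (is.null(fixture_env$c160))
    fixture_env$c160 <- generate_cohort(cohort_config(n_subjects = 160,
                                                      seed = 20240807))
  fixture_env$c160
}

# large cohort for Monte-Carlo checks
fixture_cohort5000 <- function() {
  if (is.null(fixture_env$c5000))
    fixture_env$c5000 <- generate_cohort(cohort_config(n_subjects = 5000,
                                                       seed = 99))
  fixture_env$c5000
}

# low-noise planted-pattern cohort at n = 500 for recovery checks
fixture_cohort500 <- function() {
  if (is.null(fixture_env$c500))
    fixture_env$c500 <- generate_cohort(cohort_config(n_subjects = 500,
                                                      seed = 7))
  fixture_env$c500
}

# small deterministic volume matrix
fixture_volumes <- function(n = 30, p = 6, seed = 5) {
  set.seed(seed)
  volume_matrix(matrix(exp(rnorm(n * p, mean = 1, sd = 0.3)), n, p))
}

expect_close <- function(actual, expected, tol) {
  expect_true(all(abs(actual - expected) <= tol),
              label = paste0("max |diff| = ",
                             signif(max(abs(actual - expected)), 3),
                             " (tol ", tol, ")"))
}
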