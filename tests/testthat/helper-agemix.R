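# shared fixtures: all data built in code at test time

# ages from a two-component normal mixture (untruncated)
make_bimodal_ages <- function(n, seed, w = 0.7, m1 = 45, s1 = 8, m2 = 65, s2 = 6) {
  withr::with_seed(seed, {
    z <- stats::runif(n) < w
    ifelse(z, stats::rnorm(n, m1, s1), stats::rnorm(n, m2, s2))
  })
}

# independent quadrature oracle for density normalization
integrate_pdf <- function(params, lo, hi) {
  stats::integrate(function(x) agemix:::density_pdf(params, x), lo, hi,
                   rel.tol = 1e-10, subdivisions = 400L)$value
}

# a small case CSV written to a temp file; returns the path
write_case_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

# one-stratum truncated cohort with given early weight
one_stratum_cohort <- function(n, w, seed, m1 = 46, s1 = 9, m2 = 67, s2 = 7) {
  truth <- mixture_params(normal_params(m1, s1), normal_params(m2, s2), w)
  generate_cohort(cohort_spec(n, list(stratum_spec("s", 1, truth)),
                              truncation = c(20, 74), seed = seed))
}

fast_config <- function(seed = 1L, truncation = NULL) {
  fit_config(n_random_starts = 3L, snp_starts = 2L, seed = seed,
             truncation = truncation)
}
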