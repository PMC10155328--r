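make_spectrum <- function(eigenvalues, n, p_effective) {
  structure(list(eigenvalues = eigenvalues,
                 ratios = eigenvalues[-1] / eigenvalues[-length(eigenvalues)],
                 n = n, p_effective = p_effective),
            class = "spectrum_result")
}

make_ensemble <- function(w1, w2, seed = 0L) {
  structure(list(n = 10L, rep = length(w1), w1 = w1, w2 = w2, seed = seed),
            class = "goe_ensemble")
}

test_that("bulk coefficients match hand-computed values", {
  sp <- make_spectrum(c(3, 2, 1), n = 4, p_effective = 9)
  c1 <- bulk_coefficients(sp, 1)
  expect_equal(c1$a_hat, 2)
  expect_equal(c1$b_hat, 2)            # 9/9 * (1 + 0 + 1)
  c2 <- bulk_coefficients(sp, 2)
  expect_equal(c2$a_hat, 1.5)
  expect_equal(c2$b_hat, 1.125)        # 9/4 * (0.25 + 0.25)
  flat <- bulk_coefficients(make_spectrum(c(5, 5, 5), 4, 9), 1)
  expect_equal(flat$a_hat, 5)
  expect_equal(flat$b_hat, 0)
  expect_error(bulk_coefficients(sp, 3), "between 1 and")
  expect_error(bulk_coefficients(sp, 0), "between 1 and")
})

test_that("the null-ratio transform follows its closed form", {
  # w1=2, w2=1, a_hat=1, s=1  (b_hat = p_effective)
  coeff <- list(k = 1L, a_hat = 1, b_hat = 4)
  ens <- make_ensemble(w1 = 2, w2 = 1)
  expect_equal(null_ratio_sample(coeff, ens, p_effective = 4), 2 / 3)
  # w1 = w2 -> ratio exactly 1 regardless of scale
  expect_equal(null_ratio_sample(list(k = 1, a_hat = 3, b_hat = 7),
                                 make_ensemble(1.7, 1.7), 5), 1)
  # b_hat = 0 -> all ratios 1
  expect_equal(null_ratio_sample(list(k = 1, a_hat = 2, b_hat = 0),
                                 make_ensemble(c(3, 2), c(1, 0)), 5), c(1, 1))
  # returned sorted ascending
  out <- null_ratio_sample(list(k = 1, a_hat = 1, b_hat = 1),
                           make_ensemble(c(5, 2, 9), c(1, 1, 1)), 1)
  expect_identical(out, sort(out))
})

test_that("critical values pick the floor(alpha * rep) order statistic", {
  sorted <- seq(10, 50000, by = 10) / 50000
  expect_equal(critical_value(sorted, 0.001), sorted[5])   # rep=5000 -> 5th
  expect_equal(critical_value(sorted[1:1000], 0.001), sorted[1])  # floor -> 1
  expect_error(critical_value(sorted[1:500], 0.001), "rep >= 1/alpha")
  # non-decreasing in alpha for a fixed sample
  xis <- vapply(c(0.001, 0.01, 0.1, 0.5), critical_value,
                numeric(1), sorted_null = sorted)
  expect_true(all(diff(xis) >= 0))
})

test_that("the sequential rule returns the smallest all-pass suffix start", {
  # degenerate ensemble with w1 = w2: every simulated null ratio, hence
  # every critical value, is exactly 1, so index k passes iff r_k = 1.
  # Tied eigenvalues then engineer the pass flags exactly, and passing at
  # r = xi = 1 also exercises the ties-count-as-passing rule.
  ens <- make_ensemble(w1 = rep(1.5, 100), w2 = rep(1.5, 100))
  make_sp <- function(ell) make_spectrum(ell, n = 10, p_effective = 500)
  all_pass <- make_sp(rep(3, 9))                       # flags (T,T,T,T)
  expect_equal(estimate_K(all_pass, ens, alpha = 0.02, K_c = 4)$K_hat, 1)
  first_fail <- make_sp(c(2, rep(1, 8)))               # flags (F,T,T,T)
  est <- estimate_K(first_fail, ens, alpha = 0.02, K_c = 4)
  expect_equal(est$K_hat, 2)
  expect_equal(est$per_k$pass, c(FALSE, TRUE, TRUE, TRUE))
  mid_fail <- make_sp(c(2, 2, 2, rep(1, 6)))           # flags (T,T,F,T)
  expect_equal(estimate_K(mid_fail, ens, alpha = 0.02, K_c = 4)$K_hat, 4)
  end_fail <- make_sp(c(2, 2, 2, 2, rep(1, 5)))        # flags (T,T,T,F)
  expect_error(estimate_K(end_fail, ens, alpha = 0.02, K_c = 4),
               "highly correlated genetic markers")
})

test_that("estimate_K validates dimensions, rep and clamps K_c", {
  g <- random_genotypes(30, 400, seed = 32)
  src <- geno_from_matrix(g)
  acc <- accumulate_covariance(src, plan_chunks(src, 2^24), column_stats(src))
  sp <- sample_spectrum(acc)
  ens <- simulate_goe(30, 200, seed = 33)
  expect_error(estimate_K(sp, simulate_goe(29, 50, seed = 1), alpha = 0.02),
               "does not match")
  expect_error(estimate_K(sp, ens, alpha = 0.001), "rep >= 1/alpha")
  # clamp check on a flat spectrum + degenerate ensemble so every k passes
  flat_sp <- make_spectrum(rep(2, 29), n = 30, p_effective = 400)
  flat_ens <- make_ensemble(rep(1, 200), rep(1, 200))
  flat_ens$n <- 30L
  expect_warning(est <- estimate_K(flat_sp, flat_ens, alpha = 0.02, K_c = 40),
                 "clamped")
  expect_equal(est$K_c, 28L)
  expect_equal(est$K_hat, 1L)
})

test_that("simulated null ratios live in (0, 1] across a real ensemble", {
  ens <- simulate_goe(40, 300, seed = 34)
  sp <- make_spectrum(sort(rchisq(39, df = 5), decreasing = TRUE) + 1,
                      n = 40, p_effective = 5000)
  for (k in c(1, 3, 10)) {
    nr <- null_ratio_sample(bulk_coefficients(sp, k), ens, sp$p_effective)
    expect_true(all(nr > 0 & nr <= 1))
  }
})

test_that("observed eigenvalue ratios are invariant to rescaling the data", {
  g <- random_genotypes(15, 200, seed = 35)
  src <- geno_from_matrix(g)
  acc <- accumulate_covariance(src, plan_chunks(src, 2^24), column_stats(src))
  sp <- sample_spectrum(acc)
  scaled <- acc
  scaled$gram <- acc$gram * 7.3
  sp2 <- sample_spectrum(scaled)
  expect_equal(sp$ratios, sp2$ratios)
})
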