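# Sequential eigenvalue-ratio estimator of the number of top informative
# principal components.
#
# For each candidate index k the null distribution of the ratio r_k is
# approximated by mapping simulated GOE top eigenvalues (w1, w2) through
#
#   r_null = (w2 * s + a_hat) / (w1 * s + a_hat),   s = sqrt(b_hat / p),
#
# where a_hat is the mean of the bulk eigenvalues l_k ... l_{n-1} and b_hat
# their p-scaled squared dispersion. The critical value xi_{alpha,k} is the
# lower-alpha empirical quantile (the floor(alpha * rep)-th order statistic)
# of that sample, and the estimate is the smallest k from which every ratio
# up to the coarse bound K_c sits at or above its critical value.

#' Bulk mean and dispersion coefficients at index k
#'
#' Computes `a_hat = mean(l_k, ..., l_{n-1})` over the `n - k` trailing
#' eigenvalues and `b_hat = p_effective / (n - k)^2 * sum((l_i - a_hat)^2)`.
#'
#' @param spectrum A `spectrum_result`.
#' @param k Candidate spike count, `1 <= k <= n - 2`.
#' @return List with `k`, `a_hat`, `b_hat`.
#' @export
bulk_coefficients <- function(spectrum, k) {
  stopifnot(inherits(spectrum, "spectrum_result"))
  n <- spectrum$n
  if (!is.numeric(k) || k < 1 || k > n - 2) {
    stop("k must be between 1 and n - 2 = ", n - 2, call. = FALSE)
  }
  ell <- spectrum$eigenvalues[k:(n - 1L)]
  a_hat <- mean(ell)
  b_hat <- spectrum$p_effective / (n - k)^2 * sum((ell - a_hat)^2)
  list(k = as.integer(k), a_hat = a_hat, b_hat = b_hat)
}

#' Simulated null sample of the k-th eigenvalue ratio
#'
#' Maps each ensemble replication through the null-ratio transform using
#' the bulk coefficients at index k, and returns the sample sorted in
#' ascending order.
#'
#' @param coeff Output of [bulk_coefficients()].
#' @param ensemble A `goe_ensemble`.
#' @param p_effective Number of markers that formed the covariance.
#' @return Ascending numeric vector of length `ensemble$rep`, values in
#'   (0, 1].
#' @export
null_ratio_sample <- function(coeff, ensemble, p_effective) {
  stopifnot(inherits(ensemble, "goe_ensemble"), p_effective >= 1)
  if (coeff$a_hat <= 0) {
    stop("bulk mean a_hat must be positive (got ", coeff$a_hat, ")",
         call. = FALSE)
  }
  s <- sqrt(coeff$b_hat / p_effective)
  denom <- ensemble$w1 * s + coeff$a_hat
  if (any(denom <= 0)) {
    stop("non-positive denominator in the null-ratio transform at k = ",
         coeff$k, "; the bulk coefficients are pathological", call. = FALSE)
  }
  sort((ensemble$w2 * s + coeff$a_hat) / denom)
}

#' Lower-alpha critical value from a sorted null sample
#'
#' Picks the `floor(alpha * rep)`-th smallest simulated ratio (with a floor
#' of 1), the empirical lower-alpha quantile.
#'
#' @param sorted_null Ascending numeric vector of simulated null ratios.
#' @param alpha Significance level in (0, 1).
#' @return The critical value, a scalar in (0, 1].
#' @export
critical_value <- function(sorted_null, alpha) {
  nrep <- length(sorted_null)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  if (nrep * alpha < 1) {
    stop("rep = ", nrep, " is too small for alpha = ", alpha,
         "; use rep >= 1/alpha (recommended between 2/alpha and 5/alpha)",
         call. = FALSE)
  }
  sorted_null[max(1L, floor(alpha * nrep))]
}

#' Estimate the number of top informative principal components
#'
#' Runs the sequential eigenvalue-ratio test: for every `k = 1, ..., K_c`
#' the observed ratio `r_k` is compared against its simulated critical
#' value `xi_{alpha,k}`; the estimate is the smallest `k` such that
#' `r_j >= xi_{alpha,j}` holds for every `j` in `[k, K_c]` (ties count as
#' passing). All `K_c` indices are evaluated so the per-k table is complete
#' for diagnostics.
#'
#' @param spectrum A `spectrum_result`.
#' @param ensemble A `goe_ensemble` with the same `n` as the spectrum.
#' @param alpha Significance level, default 0.001.
#' @param K_c Coarse upper bound for the search; default `floor(n / 10)`,
#'   clamped to `[1, n - 2]` with a warning when the clamp binds.
#' @return An `er_estimate`: `K_hat`, `K_c`, `alpha`, `rep`, and `per_k`, a
#'   data.frame of `(k, ratio, xi, pass)`.
#' @export
estimate_K <- function(spectrum, ensemble, alpha = 0.001, K_c = NULL) {
  stopifnot(inherits(spectrum, "spectrum_result"),
            inherits(ensemble, "goe_ensemble"))
  n <- spectrum$n
  if (ensemble$n != n) {
    stop("GOE ensemble dimension (", ensemble$n, ") does not match the ",
         "spectrum's individual count (", n, ")", call. = FALSE)
  }
  if (ensemble$rep * alpha < 1) {
    stop("rep = ", ensemble$rep, " is too small for alpha = ", alpha,
         "; use rep >= 1/alpha (recommended between 2/alpha and 5/alpha)",
         call. = FALSE)
  }
  if (is.null(K_c)) K_c <- floor(n / 10)
  if (K_c > n - 2 || K_c < 1) {
    clamped <- min(max(K_c, 1L), n - 2L)
    warning("K_c = ", K_c, " outside [1, ", n - 2, "]; clamped to ", clamped,
            call. = FALSE)
    K_c <- clamped
  }
  K_c <- as.integer(K_c)
  xi <- numeric(K_c)
  for (k in seq_len(K_c)) {
    coeff <- bulk_coefficients(spectrum, k)
    xi[k] <- critical_value(
      null_ratio_sample(coeff, ensemble, spectrum$p_effective), alpha)
  }
  r <- spectrum$ratios[seq_len(K_c)]
  pass <- r >= xi
  if (!pass[K_c]) {
    stop("no index k in 1..", K_c, " satisfies the sequential ratio test ",
         "(r_", K_c, " = ", signif(r[K_c], 5), " < xi = ",
         signif(xi[K_c], 5), "); the data may exhibit serious ",
         "multicollinearity - pre-process the genetic data to remove ",
         "highly correlated genetic markers", call. = FALSE)
  }
  # length of the trailing run of passes determines the smallest valid start
  trailing <- 0L
  for (k in rev(seq_len(K_c))) {
    if (!pass[k]) break
    trailing <- trailing + 1L
  }
  structure(
    list(K_hat = K_c - trailing + 1L, K_c = K_c, alpha = alpha,
         rep = ensemble$rep,
         per_k = data.frame(k = seq_len(K_c), ratio = r, xi = xi,
                            pass = pass)),
    class = "er_estimate")
}

#' @export
print.er_estimate <- function(x, ...) {
  cat("Eigenvalue-ratio estimate of the number of top informative PCs\n",
      " K_hat =", x$K_hat, " (searched k = 1..", x$K_c, ", alpha = ",
      x$alpha, ", rep = ", x$rep, ")\n", sep = "")
  invisible(x)
}
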