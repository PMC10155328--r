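# Genotype normalization and the sample covariance spectrum.
#
# Each kept marker column j is centered at its mean count mu_j and scaled by
# d_j = 1 / sqrt(mu_j * (1 - mu_j / 2)), the binomial standard deviation of
# a count with allele frequency mu_j / 2 (EIGENSTRAT-style standardization).
# The n x n matrix S_p = M M^T / p is accumulated over column chunks so the
# full normalized matrix never needs to be in memory at once.

#' Per-marker means, scales and keep/drop flags
#'
#' Streams over the source once, computing for every marker the mean count
#' over observed (non-missing) entries, the normalization scale
#' `1 / sqrt(mu * (1 - mu/2))`, the observed-entry count, and the sample
#' minor-allele frequency `min(mu/2, 1 - mu/2)`. Markers are dropped
#' (keep = FALSE) when monomorphic (`mu` is 0 or 2), entirely missing, or —
#' if `maf_threshold` is set — below the MAF threshold; the scale is
#' undefined for the first two and such markers carry no structure signal.
#'
#' @param source A `genotype_source`.
#' @param plan Optional `chunk_plan`; defaults to a single full-width pass.
#' @param maf_threshold Optional minor-allele-frequency cutoff in [0, 0.5);
#'   `NULL` (default) disables the filter.
#' @return A `column_stats` object: `mu_hat`, `d`, `keep`, `n_obs`, `maf`,
#'   and a `drop_log` data.frame (marker index, reason).
#' @export
column_stats <- function(source, plan = NULL, maf_threshold = NULL) {
  stopifnot(inherits(source, "genotype_source"))
  if (is.null(plan)) plan <- structure(list(chunk_width = source$p),
                                       class = "chunk_plan")
  mu <- numeric(source$p)
  n_obs <- integer(source$p)
  chunk_apply(source, plan, function(start, end, block) {
    idx <- (start + 1L):end
    n_obs[idx] <<- colSums(!is.na(block))
    sums <- colSums(block, na.rm = TRUE)
    mu[idx] <<- ifelse(n_obs[idx] > 0L, sums / n_obs[idx], NA_real_)
    NULL
  })
  maf <- pmin(mu / 2, 1 - mu / 2)
  keep <- n_obs > 0L & !is.na(mu) & mu > 0 & mu < 2
  reason <- rep(NA_character_, source$p)
  reason[n_obs == 0L] <- "all_missing"
  reason[is.na(reason) & !keep] <- "monomorphic"
  if (!is.null(maf_threshold)) {
    low <- keep & maf < maf_threshold
    keep[low] <- FALSE
    reason[low] <- "low_maf"
  }
  d <- rep(NA_real_, source$p)
  d[keep] <- 1 / sqrt(mu[keep] * (1 - mu[keep] / 2))
  if (!any(keep)) {
    stop("all ", source$p, " markers were dropped (monomorphic, missing or ",
         "below the MAF threshold); the spectrum is empty", call. = FALSE)
  }
  structure(
    list(mu_hat = mu, d = d, keep = keep, n_obs = n_obs, maf = maf,
         drop_log = data.frame(marker = which(!keep),
                               reason = reason[!keep])),
    class = "column_stats")
}

#' @export
print.column_stats <- function(x, ...) {
  cat("column_stats:", length(x$mu_hat), "markers,", sum(x$keep), "kept,",
      sum(!x$keep), "dropped\n")
  invisible(x)
}

#' Center and scale one chunk of genotype columns
#'
#' Applies the per-marker normalization `(c - mu_j) * d_j` to a block of raw
#' counts; dropped columns are excluded from the output. Missing cells are
#' imputed according to `impute_mode`: `"raw_zero"` (default) treats the
#' missing raw count as 0 and then centers and scales it, giving
#' `(0 - mu_j) * d_j`; `"centered_zero"` sets the normalized value to 0,
#' which is equivalent to mean imputation.
#'
#' @param block n x w matrix of raw counts for columns `[start, end)`.
#' @param stats A `column_stats` object covering the whole source.
#' @param start,end 0-based half-open global column range of `block`.
#' @param impute_mode `"raw_zero"` or `"centered_zero"`.
#' @return n x w' normalized matrix, w' = number of kept columns in range.
#' @export
normalize_chunk <- function(block, stats, start, end,
                            impute_mode = c("raw_zero", "centered_zero")) {
  impute_mode <- match.arg(impute_mode)
  idx <- (start + 1L):end
  keep <- stats$keep[idx]
  mu <- stats$mu_hat[idx][keep]
  d <- stats$d[idx][keep]
  x <- block[, keep, drop = FALSE]
  if (impute_mode == "raw_zero") {
    miss <- is.na(x)
    if (any(miss)) x[miss] <- 0
    m <- sweep(sweep(x, 2L, mu, "-"), 2L, d, "*")
  } else {
    m <- sweep(sweep(x, 2L, mu, "-"), 2L, d, "*")
    m[is.na(m)] <- 0
  }
  m
}

#' Accumulate the sample covariance over column chunks
#'
#' Computes `gram = sum_chunks M_chunk %*% t(M_chunk)` in double precision,
#' where each chunk is normalized with [normalize_chunk()]. The finalized
#' sample covariance is `S_p = gram / p_effective` with `p_effective` the
#' number of kept markers; the result is independent of the chunk width up
#' to round-off.
#'
#' @inheritParams column_stats
#' @param stats A `column_stats` for `source`.
#' @param impute_mode Passed to [normalize_chunk()].
#' @return A `covariance_accumulator`: `gram` (n x n), `p_effective`, `n`.
#' @export
accumulate_covariance <- function(source, plan, stats,
                                  impute_mode = c("raw_zero", "centered_zero")) {
  impute_mode <- match.arg(impute_mode)
  stopifnot(inherits(stats, "column_stats"))
  n <- source$n
  gram <- matrix(0, n, n)
  chunk_apply(source, plan, function(start, end, block) {
    m <- normalize_chunk(block, stats, start, end, impute_mode)
    if (ncol(m) == 0L) return(NULL)
    g <- tcrossprod(m)
    if (!all(is.finite(g))) {
      stop("non-finite values while accumulating covariance over columns [",
           start, ", ", end, ")", call. = FALSE)
    }
    gram <<- gram + g
    NULL
  })
  gram <- (gram + t(gram)) / 2   # remove accumulation round-off asymmetry
  structure(list(gram = gram, p_effective = sum(stats$keep), n = n),
            class = "covariance_accumulator")
}

#' Finalized sample covariance matrix
#'
#' @param acc A `covariance_accumulator`.
#' @return The n x n matrix `S_p = gram / p_effective`.
#' @export
sample_covariance <- function(acc) {
  stopifnot(inherits(acc, "covariance_accumulator"))
  acc$gram / acc$p_effective
}

#' Eigenvalues and eigenvalue ratios of the sample covariance
#'
#' Performs the symmetric eigendecomposition of `S_p`, retains the `n - 1`
#' largest eigenvalues in descending order (the centering in the
#' normalization consumes one rank), and forms the consecutive ratios
#' `r_i = l_{i+1} / l_i`, i = 1, ..., n - 2. Under latent population
#' structure with K groups, the top K - 1 ratios (the spikes) sit below the
#' remaining ratios (the bulk), which crowd toward 1.
#'
#' @param acc A `covariance_accumulator` with `n >= 3`.
#' @return A `spectrum_result`: `eigenvalues` (length n - 1, decreasing),
#'   `ratios` (length n - 2, each in (0, 1]), `n`, `p_effective`.
#' @export
sample_spectrum <- function(acc) {
  stopifnot(inherits(acc, "covariance_accumulator"))
  n <- acc$n
  if (n < 3L) stop("need at least 3 individuals for one eigenvalue ratio",
                   call. = FALSE)
  S <- sample_covariance(acc)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  ell <- ev[seq_len(n - 1L)]
  if (ell[n - 1L] <= 1e-10 * ell[1L]) {
    stop("sample covariance is numerically rank-deficient (eigenvalue ",
         signif(ell[n - 1L], 3), " vs top ", signif(ell[1L], 3), "); the ",
         "data likely contain highly correlated markers or duplicated ",
         "individuals - pre-process to remove highly correlated genetic ",
         "markers", call. = FALSE)
  }
  structure(
    list(eigenvalues = ell,
         ratios = ell[2:(n - 1L)] / ell[1:(n - 2L)],
         n = n, p_effective = acc$p_effective),
    class = "spectrum_result")
}

#' @export
print.spectrum_result <- function(x, ...) {
  cat("spectrum_result: n =", x$n, ", p_effective =", x$p_effective,
      "\n  top eigenvalues:", signif(utils::head(x$eigenvalues, 5), 4),
      "\n  first ratios:   ", signif(utils::head(x$ratios, 5), 4), "\n")
  invisible(x)
}

#' Write a spectrum report TSV
#'
#' @param spectrum A `spectrum_result`.
#' @param path Output TSV path (columns: index, eigenvalue, ratio).
#' @return `path`, invisibly.
#' @export
write_spectrum_report <- function(spectrum, path) {
  nr <- length(spectrum$eigenvalues)
  data.table::fwrite(
    data.frame(index = seq_len(nr),
               eigenvalue = spectrum$eigenvalues,
               ratio = c(spectrum$ratios, NA_real_)),
    path, sep = "\t")
  invisible(path)
}
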