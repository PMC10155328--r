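# Monte-Carlo simulation of the top two eigenvalues of Gaussian Orthogonal
# Ensemble (GOE) matrices: symmetric n x n matrices with independent
# N(0, 2) diagonal and N(0, 1) off-diagonal entries. Their two largest
# eigenvalues (w1, w2) calibrate the null fluctuations of the sample
# eigenvalue ratios.

goe_matrix <- function(n) {
  a <- matrix(0, n, n)
  up <- upper.tri(a)
  a[up] <- stats::rnorm(n * (n - 1) / 2)   # off-diagonal ~ N(0, 1)
  a <- a + t(a)
  diag(a) <- stats::rnorm(n, sd = sqrt(2)) # diagonal ~ N(0, 2)
  a
}

#' Draw the top two eigenvalues of one GOE matrix
#'
#' Draws an n x n GOE matrix (upper triangle sampled, mirrored) from the
#' current R random stream and returns its two largest eigenvalues via a
#' full symmetric eigendecomposition.
#'
#' @param n Matrix dimension, at least 2.
#' @return Numeric vector `c(w1, w2)` with `w1 >= w2`.
#' @export
sample_goe_top2 <- function(n) {
  if (!is.numeric(n) || n < 2) {
    stop("GOE dimension n must be at least 2", call. = FALSE)
  }
  ev <- eigen(goe_matrix(as.integer(n)), symmetric = TRUE,
              only.values = TRUE)$values
  ev[1:2]
}

#' Simulate a GOE top-eigenvalue ensemble
#'
#' Generates `rep` independent replications of `(w1, w2)` for n x n GOE
#' matrices. Replication m draws from its own L'Ecuyer-CMRG stream derived
#' deterministically from `(seed, m)`, so the ensemble is bit-identical for
#' any number of workers; parallel execution forks over the replications.
#' When `cache_dir` is set, the ensemble is stored keyed by
#' `(n, rep, seed)` and re-loaded on repeated calls.
#'
#' @param n GOE dimension (the individual count of the study), at least 2.
#' @param rep Number of Monte-Carlo replications, at least 1.
#' @param seed Master seed (integer).
#' @param workers Number of parallel workers, at least 1.
#' @param cache_dir Optional directory for the ensemble cache; `NULL`
#'   (default) disables caching.
#' @return A `goe_ensemble`: vectors `w1`, `w2` of length `rep`, plus
#'   `n`, `rep`, `seed`.
#' @export
simulate_goe <- function(n, rep, seed, workers = 1L, cache_dir = NULL) {
  if (!is.numeric(rep) || rep < 1) {
    stop("rep must be at least 1", call. = FALSE)
  }
  if (!is.numeric(workers) || workers < 1) {
    stop("workers must be at least 1", call. = FALSE)
  }
  if (!is.null(cache_dir)) {
    cache_file <- file.path(cache_dir,
                            sprintf("goe-n%d-rep%d-seed%d.rds", n, rep, seed))
    if (file.exists(cache_file)) return(readRDS(cache_file))
  }
  streams <- .rng_streams(seed, rep)
  draw_one <- function(m) {
    assign(".Random.seed", streams[[m]], envir = globalenv())
    sample_goe_top2(n)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  })
  res <- if (workers > 1L) {
    parallel::mclapply(seq_len(rep), draw_one, mc.cores = workers)
  } else {
    lapply(seq_len(rep), draw_one)
  }
  w <- do.call(rbind, res)
  ens <- structure(
    list(n = as.integer(n), rep = as.integer(rep), w1 = w[, 1L],
         w2 = w[, 2L], seed = seed),
    class = "goe_ensemble")
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    saveRDS(ens, cache_file)
  }
  ens
}

# rep independent L'Ecuyer-CMRG stream states derived from one master seed.
# The session RNG state and kind are restored on exit, so simulation never
# perturbs the caller's stream.
.rng_streams <- function(seed, rep) {
  old_kind <- RNGkind()
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    RNGkind(old_kind[1L], old_kind[2L], old_kind[3L])
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed, kind = "L'Ecuyer-CMRG")
  s <- get(".Random.seed", envir = globalenv())
  streams <- vector("list", rep)
  for (m in seq_len(rep)) {
    streams[[m]] <- s
    s <- parallel::nextRNGStream(s)
  }
  streams
}

#' @export
print.goe_ensemble <- function(x, ...) {
  cat("goe_ensemble: n =", x$n, ", rep =", x$rep, ", seed =", x$seed,
      "\n  mean(w1) =", signif(mean(x$w1), 5),
      ", mean(w2) =", signif(mean(x$w2), 5), "\n")
  invisible(x)
}
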