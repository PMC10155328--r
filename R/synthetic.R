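# Synthetic genotype data under a latent-subpopulation model: individual i
# in group k has count vector mu_k plus independent noise, realized as
# per-marker binomial draws C(i, j) ~ Binomial(2, f_{k,j}). Group allele
# frequencies share a common base frequency per marker plus a symmetric
# group-specific perturbation whose size is the separation knob; growing p
# at fixed per-marker separation grows the distance between group means,
# which is the regime in which spikes separate from the bulk.

#' Sample a latent-subpopulation frequency model
#'
#' Draws per-marker base minor-allele frequencies from `base_freq_law`
#' (default uniform on [0.05, 0.5]) and per-group frequencies
#' `clamp(base_j + separation * delta_{k,j}, margin, 1 - margin)` with
#' `delta` independent Uniform(-1, 1) perturbations. Group sizes are as
#' equal as possible, remainder to the first groups.
#'
#' @param K Number of subpopulations, at least 1.
#' @param n Number of individuals, at least K.
#' @param p Number of markers.
#' @param separation Non-negative frequency-scale divergence between
#'   groups; 0 gives identical groups (no structure).
#' @param seed Integer seed for the model draw.
#' @param base_freq_law Function of one integer argument returning that
#'   many base frequencies.
#' @param margin Frequencies are clamped to `[margin, 1 - margin]` so
#'   monomorphic columns are rare; default 0.02.
#' @return A `population_model`: `K`, `n`, `p`, `group_sizes`, `freqs`
#'   (K x p), `separation`, `ld_rho`.
#' @export
population_model <- function(K, n, p, separation, seed,
                             base_freq_law = function(p) stats::runif(p, 0.05, 0.5),
                             margin = 0.02) {
  stopifnot(K >= 1, n >= K, p >= 1)
  if (separation < 0) stop("separation must be non-negative", call. = FALSE)
  set.seed(seed)
  base <- base_freq_law(p)
  delta <- matrix(stats::runif(K * p, -1, 1), K, p)
  freqs <- pmin(pmax(sweep(separation * delta, 2L, base, "+"),
                     margin), 1 - margin)
  sizes <- rep(n %/% K, K)
  extra <- n %% K
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  structure(
    list(K = as.integer(K), n = as.integer(n), p = as.integer(p),
         group_sizes = as.integer(sizes), freqs = freqs,
         separation = separation, ld_rho = 0),
    class = "population_model")
}

#' Generate genotype counts from a population model
#'
#' Each individual's genotype at marker j is a Binomial(2, f) draw at its
#' group's frequency, independent across markers when `ld_rho = 0`. With
#' `ld_rho > 0` a latent Gaussian copula with equicorrelation `ld_rho`
#' inside blocks of `ld_block` consecutive markers induces linkage
#' disequilibrium before thresholding to \{0, 1, 2\} by the binomial
#' quantile function. Missing cells are then set uniformly at random.
#'
#' @param model A `population_model`.
#' @param seed Integer seed for the genotype draw.
#' @param missing_rate Fraction of cells set missing, in [0, 0.5].
#' @param ld_rho Within-block latent correlation in [0, 1); default from
#'   the model (0 = independent markers).
#' @param ld_block Block width for the LD structure; default 10 markers.
#' @return A `synthetic_dataset`: `genotypes` (n x p, entries in
#'   \{0, 1, 2\} or `NA`), `labels` (group index per individual),
#'   `truth_K`, `seed`.
#' @export
generate_genotypes <- function(model, seed, missing_rate = 0,
                               ld_rho = model$ld_rho, ld_block = 10L) {
  stopifnot(inherits(model, "population_model"))
  if (missing_rate < 0 || missing_rate > 0.5) {
    stop("missing_rate must be in [0, 0.5]", call. = FALSE)
  }
  if (ld_rho < 0 || ld_rho >= 1) {
    stop("ld_rho must be in [0, 1)", call. = FALSE)
  }
  set.seed(seed)
  n <- model$n
  p <- model$p
  geno <- matrix(NA_real_, n, p)
  labels <- rep(seq_len(model$K), times = model$group_sizes)
  for (k in seq_len(model$K)) {
    rows <- which(labels == k)
    nk <- length(rows)
    fk <- model$freqs[k, ]
    if (ld_rho == 0) {
      g <- matrix(stats::rbinom(nk * p, 2L, rep(fk, each = nk)), nk, p)
    } else {
      nb <- ceiling(p / ld_block)
      shared <- matrix(stats::rnorm(nk * nb), nk, nb)
      z <- sqrt(ld_rho) * shared[, rep(seq_len(nb), each = ld_block)[seq_len(p)],
                                 drop = FALSE] +
        sqrt(1 - ld_rho) * matrix(stats::rnorm(nk * p), nk, p)
      u <- stats::pnorm(z)
      g <- matrix(stats::qbinom(as.vector(u), 2L,
                                rep(fk, each = nk)), nk, p)
    }
    geno[rows, ] <- g
  }
  if (missing_rate > 0) {
    miss <- stats::runif(n * p) < missing_rate
    geno[miss] <- NA_real_
  }
  structure(
    list(genotypes = geno, labels = labels, truth_K = model$K, seed = seed),
    class = "synthetic_dataset")
}

#' Well-separated 12-subpopulation illustration preset
#'
#' A reference configuration with K = 12 latent subpopulations, n = 2500
#' individuals and p = 8,000,000 markers that produces a clean spike/bulk
#' split in the eigenvalue ratios. `p_scale` shrinks the marker dimension
#' (and `n` may be reduced independently) to desk scale; the subpopulation
#' count and the per-marker frequency separation of 0.15 are kept. A
#' warning is raised when the scaled p falls below 50 * n, where the
#' many-more-markers-than-individuals regime starts to erode and estimator
#' quality degrades.
#'
#' @param p_scale Fraction in (0, 1] applied to p = 8e6.
#' @param n Individual count; default 2500.
#' @param seed Seed for the model draw; default 1.
#' @return List with `model` (a `population_model` with K = 12) and the
#'   recommended run parameters `alpha = 0.001`, `rep = 2000`.
#' @export
demo_preset <- function(p_scale, n = 2500L, seed = 1L) {
  stopifnot(p_scale > 0, p_scale <= 1)
  p <- as.integer(round(8e6 * p_scale))
  if (p < 50 * n) {
    warning("scaled p = ", p, " is below 50 * n = ", 50 * n,
            "; the n/p -> 0 regime is violated and estimator quality ",
            "degrades", call. = FALSE)
  }
  list(model = population_model(K = 12L, n = n, p = p, separation = 0.15,
                                seed = seed),
       alpha = 0.001, rep = 2000L)
}

#' Write a synthetic dataset to disk
#'
#' Writes the genotype matrix in a format [geno_open()] reads (`.npy`
#' signed bytes with missing as -9, or TSV), the per-individual group
#' labels as TSV, and a small JSON truth manifest recording `truth_K`,
#' dimensions and seed.
#'
#' @param dataset A `synthetic_dataset`.
#' @param out_prefix Path prefix for the three output files.
#' @param format `"npy"` (default) or `"tsv"` for the genotype matrix.
#' @return Invisibly, the named list of written paths.
#' @export
write_dataset <- function(dataset, out_prefix, format = c("npy", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(dataset, "synthetic_dataset"))
  geno_path <- paste0(out_prefix, "_genotypes.", format)
  if (format == "npy") {
    write_npy(dataset$genotypes, geno_path, dtype = "|i1", na_code = -9L)
  } else {
    data.table::fwrite(data.table::as.data.table(dataset$genotypes),
                       geno_path, sep = "\t", col.names = FALSE, na = "NA")
  }
  labels_path <- paste0(out_prefix, "_labels.tsv")
  data.table::fwrite(
    data.frame(individual = seq_along(dataset$labels),
               group = dataset$labels),
    labels_path, sep = "\t")
  manifest_path <- paste0(out_prefix, "_truth.json")
  jsonlite::write_json(
    list(truth_K = dataset$truth_K, n = nrow(dataset$genotypes),
         p = ncol(dataset$genotypes), seed = dataset$seed,
         missing_cells = sum(is.na(dataset$genotypes))),
    manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(genotypes = geno_path, labels = labels_path,
                 manifest = manifest_path))
}
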