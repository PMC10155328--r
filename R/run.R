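# End-to-end pipeline: genotype files -> spectrum, GOE ensemble -> estimate,
# plus the simulation entry point. These functions back the command-line
# script shipped at inst/cli/eigenratio.R.

#' Assemble a validated run configuration
#'
#' @param input Character vector of genotype file paths (or a single
#'   `genotype_source`).
#' @param alpha Significance level, default 0.001.
#' @param rep GOE replications, default 5000; must satisfy
#'   `rep * alpha >= 1`.
#' @param K_c Coarse search bound; `NULL` (default) resolves to
#'   `floor(n / 10)` once n is known.
#' @param seed Master seed for the GOE simulation.
#' @param workers Parallel workers for the GOE simulation.
#' @param memory_budget Bytes available for the chunked covariance pass;
#'   accepts numbers or strings like `"2G"`, `"512M"`.
#' @param impute_mode Missing-cell handling, `"raw_zero"` (default) or
#'   `"centered_zero"`; see [normalize_chunk()].
#' @param maf_threshold Optional in-memory minor-allele-frequency filter.
#' @param out Optional path for the JSON run report; a per-k TSV is written
#'   next to it.
#' @param cache_dir Optional GOE ensemble cache directory.
#' @return A `run_config` list.
#' @export
run_config <- function(input, alpha = 0.001, rep = 5000L, K_c = NULL,
                       seed = 1L, workers = 1L, memory_budget = "2G",
                       impute_mode = c("raw_zero", "centered_zero"),
                       maf_threshold = NULL, out = NULL, cache_dir = NULL) {
  impute_mode <- match.arg(impute_mode)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (rep * alpha < 1) {
    stop("rep = ", rep, " is too small for alpha = ", alpha,
         "; use rep >= 1/alpha (recommended between 2/alpha and 5/alpha)",
         call. = FALSE)
  }
  if (workers < 1) stop("workers must be at least 1", call. = FALSE)
  structure(
    list(input = input, alpha = alpha, rep = as.integer(rep), K_c = K_c,
         seed = as.integer(seed), workers = as.integer(workers),
         memory_budget = parse_bytes(memory_budget),
         impute_mode = impute_mode, maf_threshold = maf_threshold,
         out = out, cache_dir = cache_dir),
    class = "run_config")
}

#' Parse a memory size such as "2G" or "512M" into bytes
#'
#' @param x A number (bytes) or a string with a K/M/G/T suffix.
#' @return Number of bytes.
#' @export
parse_bytes <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  m <- regexec("^([0-9.]+)\\s*([KkMmGgTt]?)[Bb]?$", trimws(x))
  parts <- regmatches(x, m)[[1]]
  if (length(parts) == 0L) stop("cannot parse memory size '", x, "'",
                                call. = FALSE)
  mult <- c(` ` = 1, K = 2^10, M = 2^20, G = 2^30, T = 2^40)
  suffix <- toupper(parts[3])
  as.numeric(parts[2]) * if (nzchar(suffix)) mult[[suffix]] else 1
}

.log_kv <- function(stage, ...) {
  kv <- list(...)
  message(paste0("[", stage, "] ",
                 paste(names(kv), unlist(kv), sep = "=", collapse = " ")))
}

#' Run the full estimation pipeline
#'
#' Reads the genotype source, computes column statistics and the chunked
#' sample covariance, extracts the eigenvalue spectrum, simulates the GOE
#' null ensemble, and applies the sequential ratio test. Progress is logged
#' as structured `key=value` messages. When `config$out` is set, a JSON run
#' report and a per-k TSV are written.
#'
#' @param config A `run_config` from [run_config()].
#' @return An `er_estimate` with additional fields `n`, `p`, `p_effective`,
#'   `n_dropped`, and `seed`.
#' @export
er_run <- function(config) {
  stopifnot(inherits(config, "run_config"))
  source <- if (inherits(config$input, "genotype_source")) config$input
            else geno_open(config$input)
  .log_kv("input", n = source$n, p = source$p,
          files = length(source$paths))
  plan <- plan_chunks(source, config$memory_budget)
  .log_kv("chunking", chunk_width = plan$chunk_width,
          n_chunks = plan$n_chunks,
          memory_budget_bytes = format(plan$memory_budget_bytes,
                                       scientific = FALSE))
  stats <- column_stats(source, plan, config$maf_threshold)
  .log_kv("markers", kept = sum(stats$keep), dropped = sum(!stats$keep))
  acc <- accumulate_covariance(source, plan, stats, config$impute_mode)
  spectrum <- sample_spectrum(acc)
  .log_kv("spectrum", top_eigenvalue = signif(spectrum$eigenvalues[1], 6),
          p_effective = spectrum$p_effective)
  ensemble <- simulate_goe(source$n, config$rep, config$seed,
                           config$workers, config$cache_dir)
  .log_kv("goe", n = ensemble$n, rep = ensemble$rep, seed = ensemble$seed)
  est <- estimate_K(spectrum, ensemble, config$alpha, config$K_c)
  est$n <- source$n
  est$p <- source$p
  est$p_effective <- spectrum$p_effective
  est$n_dropped <- sum(!stats$keep)
  est$seed <- config$seed
  .log_kv("estimate", K_hat = est$K_hat, K_c = est$K_c)
  if (!is.null(config$out)) {
    write_run_report(est, config$out)
  }
  est
}

#' Write the JSON run report and per-k TSV
#'
#' @param est An `er_estimate` returned by [er_run()] or [estimate_K()].
#' @param path Output JSON path; the per-k table goes to the same path with
#'   a `.per_k.tsv` suffix.
#' @return Invisibly, the report path.
#' @export
write_run_report <- function(est, path) {
  report <- list(K_hat = est$K_hat, alpha = est$alpha, rep = est$rep,
                 K_c = est$K_c, seed = est$seed, n = est$n, p = est$p,
                 p_effective = est$p_effective,
                 n_dropped = est$n_dropped, per_k = est$per_k)
  jsonlite::write_json(report[!vapply(report, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  data.table::fwrite(est$per_k, paste0(path, ".per_k.tsv"), sep = "\t")
  invisible(path)
}

#' Simulate and write a synthetic genotype dataset
#'
#' Thin wrapper over [population_model()], [generate_genotypes()] and
#' [write_dataset()], used by the command-line `simulate` entry point.
#'
#' @param K,n,p,separation Model parameters; see [population_model()].
#' @param seed Master seed (drives both the model and the genotype draw).
#' @param missing_rate Fraction of cells set missing.
#' @param out_prefix Output path prefix.
#' @param format Matrix format, `"npy"` or `"tsv"`.
#' @return Invisibly, the list of written paths.
#' @export
er_simulate <- function(K, n, p, separation, seed = 1L, missing_rate = 0,
                        out_prefix = "synthetic", format = c("npy", "tsv")) {
  model <- population_model(K, n, p, separation, seed = seed)
  dataset <- generate_genotypes(model, seed = seed + 1L,
                                missing_rate = missing_rate)
  paths <- write_dataset(dataset, out_prefix, format = match.arg(format))
  .log_kv("simulate", truth_K = K, n = n, p = p,
          genotypes = paths$genotypes)
  invisible(paths)
}
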