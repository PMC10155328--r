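# Genotype matrix input: multi-file sources, validation, memory-bounded
# column chunking, and a minimal VCF-to-matrix converter.
#
# Orientation is fixed: rows are individuals, columns are genetic markers
# (n x p, with n << p the intended regime). Entries are minor-allele counts
# in {0, 1, 2}; missing genotypes are normalized to NA at read time whatever
# the on-disk dialect (NaN in .npy files, negative codes or "NA"/"." tokens
# in delimited text).

# Workspace multiplier in the chunk-width formula: one chunk is held as the
# raw read buffer plus the normalized copy plus transpose workspace, with
# slack. Conservative so the memory-budget promise holds.
CHUNK_OVERHEAD <- 4

#' Open one or more genotype matrix files as a single source
#'
#' Validates and stitches genotype files side by side into one logical
#' n x p matrix: every file must contain the same individuals (rows) in the
#' same order, and columns are concatenated in the order the paths are
#' given. Supported formats are NumPy `.npy` binary arrays and delimited
#' text (`.tsv`/`.csv`/anything `data.table::fread` can sniff). All
#' non-missing entries must be minor-allele counts in \{0, 1, 2\}.
#'
#' @param paths Character vector of file paths, ordered.
#' @return A `genotype_source` object with elements `paths`, `n`
#'   (individuals), `p` (total markers), and `file_cols` (markers per file).
#' @export
geno_open <- function(paths) {
  if (length(paths) < 1L) stop("at least one input path is required", call. = FALSE)
  missing_files <- paths[!file.exists(paths)]
  if (length(missing_files)) {
    stop("input file(s) not found: ", paste(missing_files, collapse = ", "),
         call. = FALSE)
  }
  dims <- matrix(0L, length(paths), 2L)
  for (i in seq_along(paths)) {
    m <- .read_genotype_file(paths[i])
    .validate_genotypes(m, paths[i])
    dims[i, ] <- dim(m)
    if (i > 1L && dims[i, 1L] != dims[1L, 1L]) {
      stop("row (individual) count mismatch: '", paths[1L], "' has ",
           dims[1L, 1L], " rows but '", paths[i], "' has ", dims[i, 1L],
           call. = FALSE)
    }
  }
  n <- dims[1L, 1L]
  p <- sum(dims[, 2L])
  if (n > p) {
    warning("source has more individuals (", n, ") than markers (", p,
            "); expected orientation is rows = individuals, columns = ",
            "markers with n << p", call. = FALSE)
  }
  structure(
    list(paths = paths, n = n, p = p, file_cols = dims[, 2L],
         missing_code = NA_real_, .cache = new.env(parent = emptyenv())),
    class = "genotype_source")
}

#' Wrap an in-memory genotype matrix as a source
#'
#' Convenience constructor used with synthetic data: presents a matrix
#' already in memory through the same interface as file-backed sources, so
#' the chunked pipeline downstream is identical.
#'
#' @param x Numeric matrix, individuals x markers, entries in \{0, 1, 2\}
#'   or `NA`.
#' @return A `genotype_source`.
#' @export
geno_from_matrix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  .validate_genotypes(x, "<matrix>")
  cache <- new.env(parent = emptyenv())
  cache$mem <- x
  if (nrow(x) > ncol(x)) {
    warning("matrix has more individuals (", nrow(x), ") than markers (",
            ncol(x), "); expected orientation is rows = individuals",
            call. = FALSE)
  }
  structure(
    list(paths = "<memory>", n = nrow(x), p = ncol(x),
         file_cols = ncol(x), missing_code = NA_real_, .cache = cache),
    class = "genotype_source")
}

#' @export
print.genotype_source <- function(x, ...) {
  cat("genotype_source: n =", x$n, "individuals, p =", x$p, "markers in",
      length(x$paths), "file(s)\n")
  invisible(x)
}

.read_genotype_file <- function(path) {
  if (grepl("\\.npy$", path, ignore.case = TRUE)) {
    m <- read_npy(path)
  } else {
    dt <- data.table::fread(path, header = FALSE, na.strings = c("NA", "."),
                            showProgress = FALSE)
    m <- as.matrix(dt)
    dimnames(m) <- NULL
    storage.mode(m) <- "double"
  }
  # normalize missing dialects to NA: NaN (binary) and negative codes (text)
  m[is.nan(m) | (!is.na(m) & m < 0)] <- NA_real_
  m
}

.validate_genotypes <- function(m, path) {
  bad <- which(!is.na(m) & m != 0 & m != 1 & m != 2)
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(m)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(m)) + 1L
    stop("genotype value ", m[bad[1L]], " outside {0,1,2} at (row ", i,
         ", column ", j, ") of '", path, "'", call. = FALSE)
  }
  invisible(TRUE)
}

#' Plan memory-bounded column chunks
#'
#' Derives the number of marker columns that can be processed per block
#' while also holding the n x n covariance accumulator, all in double
#' precision. The chunk width is
#' `max(1, floor((budget - 8*n^2) / (8*n*overhead)))` with a workspace
#' overhead factor of 4 (read buffer, normalized copy, transpose workspace,
#' slack).
#'
#' @param source A `genotype_source`.
#' @param memory_budget_bytes Positive number of bytes available.
#' @return A `chunk_plan` with `chunk_width`, `memory_budget_bytes`, and
#'   `n_chunks`.
#' @export
plan_chunks <- function(source, memory_budget_bytes) {
  stopifnot(inherits(source, "genotype_source"))
  if (!is.numeric(memory_budget_bytes) || memory_budget_bytes <= 0) {
    stop("memory_budget_bytes must be a positive number", call. = FALSE)
  }
  n <- source$n
  minimum <- 8 * n^2 + 8 * n * CHUNK_OVERHEAD
  if (memory_budget_bytes < minimum) {
    stop("memory budget ", memory_budget_bytes, " bytes is too small to ",
         "hold one marker column plus the ", n, "x", n, " accumulator; ",
         "need at least ", minimum, " bytes", call. = FALSE)
  }
  width <- max(1, floor((memory_budget_bytes - 8 * n^2) /
                          (8 * n * CHUNK_OVERHEAD)))
  width <- min(width, source$p)
  structure(
    list(chunk_width = as.integer(width),
         memory_budget_bytes = memory_budget_bytes,
         n_chunks = as.integer(ceiling(source$p / width))),
    class = "chunk_plan")
}

#' Column ranges tiling a source under a chunk plan
#'
#' @param source A `genotype_source`.
#' @param plan A `chunk_plan` (or an integer chunk width).
#' @return A data.frame with 0-based half-open `start`/`end` column ranges
#'   in ascending order, exactly tiling `[0, p)`.
#' @export
chunk_ranges <- function(source, plan) {
  width <- if (inherits(plan, "chunk_plan")) plan$chunk_width else as.integer(plan)
  stopifnot(width >= 1L)
  starts <- seq.int(0L, source$p - 1L, by = width)
  data.frame(start = starts, end = pmin(starts + width, source$p))
}

#' Read a contiguous block of marker columns
#'
#' Columns are addressed by a 0-based half-open range spanning the stitched
#' multi-file matrix; files are loaded one at a time and the most recent is
#' cached, so memory stays bounded by one file plus one chunk. Missing
#' entries surface as `NA` regardless of the on-disk dialect.
#'
#' @param source A `genotype_source`.
#' @param start,end 0-based half-open column range.
#' @return An n x (end - start) numeric matrix.
#' @export
read_columns <- function(source, start, end) {
  stopifnot(start >= 0, end <= source$p, start < end)
  if (!is.null(source$.cache$mem)) {
    return(source$.cache$mem[, (start + 1L):end, drop = FALSE])
  }
  offsets <- cumsum(c(0L, source$file_cols))
  out <- matrix(NA_real_, source$n, end - start)
  filled <- 0L
  for (i in seq_along(source$paths)) {
    lo <- max(start, offsets[i])
    hi <- min(end, offsets[i + 1L])
    if (lo >= hi) next
    m <- .cached_file(source, i)
    cols <- (lo - offsets[i] + 1L):(hi - offsets[i])
    out[, (filled + 1L):(filled + length(cols))] <- m[, cols, drop = FALSE]
    filled <- filled + length(cols)
  }
  out
}

.cached_file <- function(source, i) {
  if (identical(source$.cache$idx, i)) return(source$.cache$mat)
  m <- .read_genotype_file(source$paths[i])
  source$.cache$idx <- i
  source$.cache$mat <- m
  m
}

#' Apply a function over column chunks
#'
#' Iterates the chunk ranges of `plan` in ascending column order, calling
#' `f(start, end, block)` for each; concatenating the blocks column-wise
#' reconstructs the full matrix exactly.
#'
#' @param source A `genotype_source`.
#' @param plan A `chunk_plan` or integer width.
#' @param f Function of `(start, end, block)`.
#' @return Invisibly, the list of values returned by `f`.
#' @export
chunk_apply <- function(source, plan, f) {
  ranges <- chunk_ranges(source, plan)
  out <- vector("list", nrow(ranges))
  for (r in seq_len(nrow(ranges))) {
    out[[r]] <- f(ranges$start[r], ranges$end[r],
                  read_columns(source, ranges$start[r], ranges$end[r]))
  }
  invisible(out)
}

#' Convert a VCF to a minor-allele count matrix
#'
#' Extracts diploid GT calls from biallelic sites and writes an
#' individuals x markers matrix of minor-allele counts. The minor allele at
#' each site is the allele with the lower sample frequency among called
#' genotypes; exact ties at 0.5 are oriented toward the ALT allele. Missing
#' or half-called genotypes become missing cells. Multi-allelic records are
#' skipped (not split) and counted in the manifest.
#'
#' @param vcf_path Path to a VCF file (plain or bgzipped).
#' @param out_path Output matrix path; `.npy` writes a binary array,
#'   anything else writes a TSV.
#' @param manifest_path Output path for the per-site manifest TSV
#'   (`chrom`, `pos`, `ref`, `alt`, `minor_allele`, `skipped`). Defaults to
#'   `out_path` with a `.manifest.tsv` suffix.
#' @return Invisibly, a list with the matrix `path`, `manifest` path,
#'   `n_sites` kept and `n_skipped` multi-allelic records.
#' @export
vcf_to_matrix <- function(vcf_path, out_path,
                          manifest_path = paste0(out_path, ".manifest.tsv")) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))  # single-record VCF
  gt <- vcfR::extract.gt(vcf, element = "GT")
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt) | is.na(alt) | alt == "."
  if (all(multi)) {
    stop("no biallelic variants with GT calls in '", vcf_path, "'",
         call. = FALSE)
  }
  n <- ncol(gt)
  keep_idx <- which(!multi)
  cols <- matrix(NA_real_, n, length(keep_idx))
  minor <- rep(NA_character_, nrow(fix))
  for (jj in seq_along(keep_idx)) {
    j <- keep_idx[jj]
    alleles <- strsplit(sub(":.*", "", gt[j, ]), "[/|]")
    counts <- vapply(alleles, function(a) {
      if (length(a) != 2L || any(a %in% c(".", ""))) return(NA_real_)
      sum(a == "1")
    }, numeric(1))
    called <- !is.na(counts)
    alt_freq <- if (any(called)) sum(counts[called]) / (2 * sum(called)) else 0
    if (alt_freq <= 0.5) {       # ties at 0.5 orient toward ALT
      cols[, jj] <- counts
      minor[j] <- fix[j, "ALT"]
    } else {
      cols[, jj] <- 2 - counts
      minor[j] <- fix[j, "REF"]
    }
  }
  if (grepl("\\.npy$", out_path, ignore.case = TRUE)) {
    write_npy(cols, out_path)
  } else {
    data.table::fwrite(data.table::as.data.table(cols), out_path, sep = "\t",
                       col.names = FALSE, na = "NA")
  }
  manifest <- data.frame(
    chrom = fix[, "CHROM"], pos = fix[, "POS"], ref = fix[, "REF"],
    alt = fix[, "ALT"], minor_allele = minor, skipped = multi)
  data.table::fwrite(manifest, manifest_path, sep = "\t")
  invisible(list(path = out_path, manifest = manifest_path,
                 n_sites = length(keep_idx), n_skipped = sum(multi)))
}
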