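# Shared fixture builders: small genotype matrices written in the formats
# the package reads, built in code at test time.

random_genotypes <- function(n, p, seed, missing_rate = 0) {
  set.seed(seed)
  g <- matrix(rbinom(n * p, 2L, runif(p, 0.1, 0.5)[rep(seq_len(p), each = n)]),
              n, p)
  g <- matrix(as.numeric(g), n, p)
  if (missing_rate > 0) g[runif(n * p) < missing_rate] <- NA_real_
  g
}

write_genotype_tsv <- function(m, path = tempfile(fileext = ".tsv"),
                               na = "NA") {
  write.table(m, path, sep = "\t", row.names = FALSE, col.names = FALSE,
              na = na)
  path
}

write_genotype_npy <- function(m, path = tempfile(fileext = ".npy")) {
  write_npy(m, path)
  path
}

# dense single-shot oracle for the normalized covariance: nan-aware means,
# binomial scaling, raw-zero imputation, no chunking
dense_covariance_oracle <- function(g, impute_mode = "raw_zero") {
  mu <- colMeans(g, na.rm = TRUE)
  keep <- !is.na(mu) & mu > 0 & mu < 2
  g <- g[, keep, drop = FALSE]
  mu <- mu[keep]
  d <- 1 / sqrt(mu * (1 - mu / 2))
  if (impute_mode == "raw_zero") g[is.na(g)] <- 0
  m <- sweep(sweep(g, 2, mu, "-"), 2, d, "*")
  if (impute_mode == "centered_zero") m[is.na(m)] <- 0
  tcrossprod(m) / ncol(m)
}

# minimal VCF writer for converter tests
write_test_vcf <- function(sites, samples, path = tempfile(fileext = ".vcf")) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  rows <- vapply(sites, function(s) {
    paste(c(s$chrom, s$pos, ".", s$ref, s$alt, ".", "PASS", ".", "GT",
            s$gt), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  path
}
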