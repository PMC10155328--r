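test_that("multi-file sources stitch columns and report n, p additively", {
  a <- write_genotype_npy(random_genotypes(4, 10, seed = 1))
  b <- write_genotype_tsv(random_genotypes(4, 15, seed = 2))
  src_a <- suppressWarnings(geno_open(a))
  src_ab <- suppressWarnings(geno_open(c(a, b)))
  expect_equal(src_ab$n, 4)
  expect_equal(src_ab$p, 25)
  expect_equal(src_ab$p - src_a$p, 15)
})

test_that("row-count mismatches and out-of-domain entries fail with location", {
  a <- write_genotype_npy(random_genotypes(4, 10, seed = 3))
  b <- write_genotype_npy(random_genotypes(5, 10, seed = 4))
  expect_error(suppressWarnings(geno_open(c(a, b))), "mismatch.*4.*5")

  m <- random_genotypes(4, 6, seed = 5)
  m[2, 3] <- 3
  expect_error(suppressWarnings(geno_open(write_genotype_npy(m))),
               "outside \\{0,1,2\\} at \\(row 2, column 3\\)")
})

test_that("chunk plans follow the budget formula and tile all columns", {
  n <- 1000
  g <- random_genotypes(10, 25, seed = 6)   # only dims matter for the formula
  src <- structure(list(paths = "x", n = n, p = 25000L, file_cols = 25000L,
                        missing_code = NA_real_,
                        .cache = new.env(parent = emptyenv())),
                   class = "genotype_source")
  # budget for exactly 10,000 columns alongside the n x n accumulator
  budget <- 8 * n^2 + 8 * n * 4 * 10000
  plan <- plan_chunks(src, budget)
  expect_equal(plan$chunk_width, 10000L)
  ranges <- chunk_ranges(src, plan)
  expect_equal(nrow(ranges), 3)
  expect_equal(ranges$end - ranges$start, c(10000, 10000, 5000))
  # exact tiling, half-open
  expect_equal(ranges$start, c(0, 10000, 20000))
  expect_equal(ranges$end[3], src$p)

  expect_error(plan_chunks(src, 8 * n^2 + 8), "too small")

  wide <- plan_chunks(src, 8 * n^2 + 8 * n * 4 * 1e6)
  expect_equal(chunk_ranges(src, wide)$start, 0)
})

test_that("chunked reads reconstruct the whole matrix for many widths", {
  m <- random_genotypes(6, 23, seed = 7, missing_rate = 0.1)
  paths <- c(write_genotype_npy(m[, 1:9]), write_genotype_tsv(m[, 10:23]))
  src <- suppressWarnings(geno_open(paths))
  whole <- read_columns(src, 0, 23)
  expect_equal(whole, m)
  for (w in c(1, 2, 22, 23, 30)) {
    ranges <- chunk_ranges(src, w)
    got <- do.call(cbind, lapply(seq_len(nrow(ranges)), function(r) {
      read_columns(src, ranges$start[r], ranges$end[r])
    }))
    expect_identical(got, whole)
  }
})

test_that("missing dialects (-9 text codes, NaN binary, NA/. tokens) normalize to NA", {
  m <- random_genotypes(5, 8, seed = 8)
  m[1, 2] <- NA
  npy <- write_genotype_npy(m)                # NA stored as NaN
  txt <- tempfile(fileext = ".tsv")
  m2 <- m
  lines <- apply(m2, 1, function(r) paste(ifelse(is.na(r), "-9", r),
                                          collapse = "\t"))
  lines[2] <- sub("^([0-9])", ".", lines[2])  # a "." token as well
  writeLines(lines, txt)
  src <- suppressWarnings(geno_open(c(npy, txt)))
  block <- read_columns(src, 0, 16)
  expect_true(is.na(block[1, 2]))   # NaN dialect
  expect_true(is.na(block[1, 10]))  # -9 dialect
  expect_true(is.na(block[2, 9]))   # "." dialect
  expect_false(anyNA(block[3, ]))
})

test_that("VCF conversion orients to the minor allele with ALT tie-break", {
  vcf <- write_test_vcf(list(
    list(chrom = "1", pos = 100, ref = "A", alt = "G",
         gt = c("0/0", "0/1", "1/1")),            # ALT freq 0.5: tie -> ALT
    list(chrom = "1", pos = 200, ref = "A", alt = "C",
         gt = c("1/1", "1/1", "0/1")),            # ALT freq 5/6 -> REF minor
    list(chrom = "1", pos = 300, ref = "T", alt = "C",
         gt = c("./.", "0/1", "0/0")),            # missing call
    list(chrom = "1", pos = 400, ref = "T", alt = "C,G",
         gt = c("0/1", "0/2", "0/0"))),           # multi-allelic: skipped
    samples = c("s1", "s2", "s3"))
  out <- tempfile(fileext = ".tsv")
  res <- vcf_to_matrix(vcf, out)
  m <- as.matrix(data.table::fread(out, header = FALSE))
  expect_equal(unname(m[, 1]), c(0, 1, 2))
  expect_equal(unname(m[, 2]), c(0, 0, 1))
  expect_true(is.na(m[1, 3]))
  expect_equal(res$n_sites, 3)
  expect_equal(res$n_skipped, 1)
  manifest <- data.table::fread(res$manifest)
  expect_equal(manifest$minor_allele[1:3], c("G", "A", "C"))
  expect_equal(manifest$skipped, c(FALSE, FALSE, FALSE, TRUE))
  # non-missing column frequencies never exceed 0.5 except exact ties
  freqs <- colMeans(m, na.rm = TRUE) / 2
  expect_true(all(freqs <= 0.5 + 1e-12))
})

test_that("VCF with only multi-allelic sites is an empty-output error", {
  vcf <- write_test_vcf(list(
    list(chrom = "1", pos = 1, ref = "A", alt = "C,G",
         gt = c("0/1", "0/2"))), samples = c("s1", "s2"))
  expect_error(vcf_to_matrix(vcf, tempfile()), "no biallelic")
})

test_that("npy round-trip preserves values, NA and both storage dtypes", {
  m <- random_genotypes(7, 11, seed = 9, missing_rate = 0.15)
  f8 <- tempfile(fileext = ".npy")
  write_npy(m, f8)
  back <- read_npy(f8)
  expect_equal(ifelse(is.nan(back), NA_real_, back), m)
  i1 <- tempfile(fileext = ".npy")
  write_npy(m, i1, dtype = "|i1", na_code = -9L)
  raw <- read_npy(i1)
  expect_equal(raw[!is.na(m)], m[!is.na(m)])
  expect_true(all(raw[is.na(m)] == -9))
})
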