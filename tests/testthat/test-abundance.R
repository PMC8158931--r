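test_that("read/write round-trips and orientation is an involution", {
  m <- matrix(c(1.5, 0, 2, 3.25, 4, 0), nrow = 3,
              dimnames = list(c("s1", "s2", "s3"), c("fA", "fB")))
  t1 <- abundance_table(m, "microbiome")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_abundance(t1, path)
  back <- read_abundance(path, "microbiome", "samples_as_rows")
  expect_equal(unclass(back), unclass(t1), tolerance = 1e-9)
  expect_identical(rownames(back), rownames(t1))

  # the same file read transposed, then transposed back, is identical
  path2 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(
    data.frame(feature = colnames(m), t(m), check.names = FALSE),
    path2, sep = "\t", quote = FALSE, row.names = FALSE)
  flipped <- read_abundance(path2, "microbiome", "features_as_rows")
  expect_equal(unclass(flipped), unclass(t1))
})

test_that("parse errors name the offending cell and reject duplicates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tfA\tfB", "s1\t1\tNA", "s2\t2\t3"), path)
  expect_error(read_abundance(path, "microbiome", "samples_as_rows"),
               "non-numeric cell 'NA'.*row 's1'.*column 'fB'")
  writeLines(c("id\tfA", "s1\t1", "s1\t2"), path)
  expect_error(read_abundance(path, "microbiome", "samples_as_rows"),
               "duplicate")
  expect_error(abundance_table(matrix(1:4, 2), sample_ids = c("a", "a")),
               "duplicate sample")
})

test_that("align_samples restricts to the shared samples in order", {
  a <- abundance_table(matrix(1:6, 3, 2,
                              dimnames = list(c("s1", "s2", "s3"), NULL)),
                       "microbiome")
  b <- abundance_table(matrix(1:6, 3, 2,
                              dimnames = list(c("s2", "s3", "s4"), NULL)),
                       "metabolome")
  al <- align_samples(a, b)
  expect_identical(rownames(al$a), c("s2", "s3"))
  expect_identical(rownames(al$b), c("s2", "s3"))

  # same sets in different orders give identical reordered tables
  b2 <- abundance_table(unclass(a)[c(3, 1, 2), ], "metabolome")
  al2 <- align_samples(a, b2)
  expect_identical(rownames(al2$a), rownames(al2$b))
  expect_equal(unclass(al2$b), unclass(a)[rownames(al2$a), ],
               ignore_attr = TRUE)

  d <- abundance_table(matrix(1:2, 1, 2, dimnames = list("zz", NULL)),
                       "metabolome")
  expect_error(align_samples(a, d), "no shared samples")
})

test_that("prevalence filter uses 'present in >= min_fraction' and is idempotent", {
  set.seed(42)
  v <- matrix(runif(20 * 4, 1, 2), 20, 4,
              dimnames = list(NULL, c("keep", "five_pct", "ten_pct", "zero")))
  v[, "five_pct"] <- 0; v[1, "five_pct"] <- 1          # 1/20 = 5%
  v[, "ten_pct"] <- 0; v[1:2, "ten_pct"] <- 1          # 2/20 = 10%
  v[, "zero"] <- 0
  t1 <- abundance_table(v, "microbiome")
  f <- prevalence_filter(t1, 0.10)
  expect_identical(colnames(f), c("keep", "ten_pct"))
  expect_equal(unclass(prevalence_filter(f, 0.10)), unclass(f))
  sparse <- abundance_table(matrix(c(0, 1, 0, 0), 2, 2), "microbiome")
  expect_error(prevalence_filter(sparse, 1), "every feature")
})

test_that("relative abundance divides rows by their sums", {
  t1 <- abundance_table(matrix(c(2, 1, 2, 3), 2, 2), "microbiome")
  r <- relative_abundance(t1)
  expect_equal(unclass(r)[1, ], c(F1 = 0.5, F2 = 0.5))
  expect_equal(unclass(r)[2, ], c(F1 = 0.25, F2 = 0.75))
  expect_identical(attr(r, "transform"), "relative")

  set.seed(7)
  big <- abundance_table(matrix(rexp(200), 20, 10), "microbiome")
  expect_equal(rowSums(unclass(relative_abundance(big))), rep(1, 20),
               tolerance = 1e-12, ignore_attr = TRUE)
  z <- abundance_table(rbind(c(1, 1), c(0, 0)), "microbiome")
  expect_error(relative_abundance(z), "all-zero sample")
})

test_that("CLR transform matches the log-proportion formula", {
  t1 <- abundance_table(matrix(c(1, 3), 1, 2), "microbiome")
  # pseudocount 1: x' = [2, 4], g = 6
  clr1 <- clr_transform(t1, pseudocount = 1)
  expect_equal(as.numeric(unclass(clr1)), c(log(1 / 3), log(2 / 3)),
               tolerance = 1e-12)
  # equal entries, pseudocount 0
  t2 <- abundance_table(matrix(c(1, 1), 1, 2), "microbiome")
  expect_equal(as.numeric(unclass(clr_transform(t2, 0))),
               rep(log(0.5), 2), tolerance = 1e-12)
  expect_identical(attr(clr1, "transform"), "clr")
  expect_error(clr_transform(clr1), "already")
})

test_that("CLR with pseudocount 0 is scale-invariant per sample", {
  set.seed(11)
  v <- matrix(rexp(30, 0.2) + 0.1, 5, 6)
  t1 <- abundance_table(v, "microbiome")
  t2 <- abundance_table(v * 7.3, "microbiome")
  expect_equal(unclass(clr_transform(t1, 0)), unclass(clr_transform(t2, 0)),
               tolerance = 1e-12)
})

test_that("geometric-mean denominator reproduces the conventional CLR", {
  set.seed(3)
  v <- matrix(rexp(24) + 0.5, 4, 6)
  t1 <- abundance_table(v, "microbiome")
  got <- unclass(clr_transform(t1, 0, denominator = "geometric_mean"))
  want <- t(apply(log(v), 1, function(r) r - mean(r)))
  expect_equal(got, want, tolerance = 1e-12, ignore_attr = TRUE)
})
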