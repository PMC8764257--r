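# SNP I/O, quality filters, mean imputation and the genomic relationship
# matrix.

test_that("VCF genotypes are read with the reference-homozygote-is-2 coding", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tind1\tind2\tind3",
    "1\t100\ts1\tA\tC\t.\t.\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\ts2\tG\tT\t.\t.\t.\tGT\t./.\t1|1\t0/0",
    "1\t300\ts3\tA\tC,T\t.\t.\t.\tGT\t0/0\t0/1\t1/1"), f)
  suppressMessages(m <- read_markers(f, format = "vcf"))
  expect_equal(ncol(m), 2)                       # multi-allelic record skipped
  expect_equal(attr(m, "n_multiallelic"), 1)
  expect_equal(unname(unclass(m)["ind1", "s1"]), 2)   # 0/0 -> reference hom
  expect_equal(unname(unclass(m)["ind2", "s1"]), 1)
  expect_equal(unname(unclass(m)["ind3", "s1"]), 0)
  expect_true(is.na(unclass(m)["ind1", "s2"]))        # ./. -> missing
  expect_equal(unname(unclass(m)["ind2", "s2"]), 0)   # phased alt hom
  unlink(f)
})

test_that("marker matrices round-trip through CSV and VCF", {
  set.seed(1)
  g <- matrix(sample(c(0, 1, 2, NA), 60, replace = TRUE), 6, 10,
              dimnames = list(paste0("i", 1:6), paste0("m", 1:10)))
  m <- marker_matrix(g)
  f <- tempfile(fileext = ".csv")
  write_markers(m, f)
  m2 <- read_markers(f, format = "matrix-csv")
  expect_equal(unclass(m2), unclass(m), ignore_attr = TRUE)
  fv <- tempfile(fileext = ".vcf")
  write_vcf(m, fv)
  m3 <- read_markers(fv, format = "vcf")
  expect_equal(unclass(m3), unclass(m), ignore_attr = TRUE)
  unlink(c(f, fv))
})

test_that("marker filters match an independent per-marker re-check", {
  set.seed(2)
  n_ind <- 80; n_mk <- 1000
  p <- runif(n_mk, 0.001, 0.999)
  g <- sapply(p, function(pp) rbinom(n_ind, 2, pp))
  miss <- matrix(runif(n_ind * n_mk) < rep(runif(n_mk, 0, 0.6), each = n_ind),
                 n_ind, n_mk)
  g[miss] <- NA
  m <- marker_matrix(g)
  res <- filter_markers(m, maf_min = 0.01, max_missing = 0.40)
  # independent recount
  keep_oracle <- vapply(seq_len(n_mk), function(j) {
    col <- g[, j]
    obs <- col[!is.na(col)]
    if (!length(obs)) return(FALSE)
    pj <- mean(obs) / 2
    maf <- min(pj, 1 - pj)
    maf >= 0.01 && mean(is.na(col)) <= 0.40
  }, logical(1))
  expect_equal(res$report$retained, sum(keep_oracle))
  expect_equal(ncol(res$markers), sum(keep_oracle))
  expect_equal(res$report$removed + res$report$retained, n_mk)

  # the two rules individually
  g2 <- cbind(c(rep(2, 199), 1),              # p = 0.9975, MAF 0.0025 < 0.01
              c(rep(NA, 90), rep(1, 110)))    # 45% missing > 40%
  expect_warning(r2 <- filter_markers(marker_matrix(g2)), "removed")
  expect_equal(r2$report$retained, 0)
  expect_equal(r2$report$removed_maf, 1)
  expect_equal(r2$report$removed_missing, 1)
})

test_that("mean imputation replaces only missing calls with column means", {
  m <- marker_matrix(matrix(c(0, 2, NA, 1, 1, 1), 3, 2,
                            dimnames = list(letters[1:3], c("s1", "s2"))))
  im <- impute_mean(m)
  expect_equal(unname(unclass(im)[3, "s1"]), 1.0)
  expect_equal(unclass(im)[, "s2"], unclass(m)[, "s2"])
  # no missing: identity
  expect_equal(unclass(impute_mean(im)), unclass(im))
  # column means unchanged by imputation
  set.seed(3)
  g <- matrix(rbinom(2000, 2, 0.4), 40, 50)
  g[runif(2000) < 0.10] <- NA
  mm <- marker_matrix(g)
  before <- colMeans(unclass(mm), na.rm = TRUE)
  after <- colMeans(unclass(impute_mean(mm)))
  expect_equal(after, before, tolerance = 1e-12)
})

test_that("the genomic relationship matrix follows the VanRaden form", {
  # 2 individuals, 1 marker, codes 0 and 2: Z = (-1, +1), G = [[1,-1],[-1,1]]
  m <- marker_matrix(matrix(c(0, 2), 2, 1,
                            dimnames = list(c("i1", "i2"), "s1")))
  G <- genomic_relationship(m)
  expect_equal(unclass(G), matrix(c(1, -1, -1, 1), 2,
                                  dimnames = list(c("i1", "i2"), c("i1", "i2"))),
               ignore_attr = TRUE)

  # monomorphic input is degenerate
  mono <- marker_matrix(matrix(2, 3, 2, dimnames = list(letters[1:3], c("a", "b"))))
  expect_error(genomic_relationship(mono), "monomorphic")

  # trace normalization: trace(G) = number of individuals
  set.seed(4)
  g <- matrix(rbinom(200 * 500, 2, runif(500, 0.1, 0.9)[rep(1:500, each = 200)]),
              200, 500)
  G2 <- genomic_relationship(marker_matrix(g))
  expect_equal(sum(diag(G2)), 200, tolerance = 1e-9)
  expect_equal(mean(diag(G2)), 1, tolerance = 1e-12)
  # markers divisor: trace equals the marker count instead
  G3 <- genomic_relationship(marker_matrix(g), divisor = "markers")
  expect_equal(sum(diag(G3)), 500, tolerance = 1e-9)

  # determinism: same input, same G bit for bit
  expect_identical(as.numeric(genomic_relationship(marker_matrix(g))),
                   as.numeric(G2))
})

test_that("stabilization only acts on near-singular matrices", {
  # identity in, identity out
  I5 <- relationship_matrix(
    matrix(diag(5), 5, dimnames = list(letters[1:5], letters[1:5])),
    kind = "marker")
  out <- stabilize(I5)
  expect_false(attr(out, "stabilized"))
  expect_equal(unclass(out), unclass(I5), ignore_attr = TRUE)

  # duplicated individuals give a rank-deficient G
  set.seed(5)
  g <- matrix(rbinom(300, 2, 0.5), 10, 30)
  g[10, ] <- g[9, ]
  G <- genomic_relationship(marker_matrix(g))
  st <- stabilize(G, ridge = 1e-6)
  expect_true(attr(st, "stabilized"))
  lam <- min(eigen(unclass(st), symmetric = TRUE, only.values = TRUE)$values)
  expect_gte(lam, 1e-6 - 1e-12)
})
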