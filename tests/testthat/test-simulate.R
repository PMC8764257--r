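# The synthetic-data generator: pedigree structure, gene dropping, trial
# simulation and the bundled default scenario.

test_that("simulated pedigrees have the requested family structure", {
  sc <- simulation_scenario(n_parents = 4, n_families = 2,
                            genotypes_per_family = 3, ramets = 1,
                            grid_rows = 3, grid_cols = 2,
                            traits = list())
  ped <- simulate_pedigree(sc, seed = 1)
  expect_equal(nrow(ped), 4 + 2 * 3)
  # full sibs share both parents: additive relationship one half
  A <- numerator_relationship(ped)
  fam1 <- ped$id[grepl("^F01", ped$id)]
  expect_equal(unname(unclass(A)[fam1[1], fam1[2]]), 0.5)

  expect_error(simulate_pedigree(
    simulation_scenario(n_parents = 3, n_families = 10,
                        genotypes_per_family = 1, ramets = 1,
                        grid_rows = 5, grid_cols = 2, traits = list()),
    seed = 1), "parent pairs")

  # the default scenario: 55 parents + 63 x 10 offspring
  ped_d <- simulate_pedigree(radiata_scenario(), seed = 2)
  expect_equal(nrow(ped_d), 55 + 630)
})

test_that("gene dropping respects Mendelian transmission and the seed", {
  ped <- pedigree(c("S", "D", paste0("o", 1:30)),
                  c(NA, NA, rep("S", 30)), c(NA, NA, rep("D", 30)))
  m <- gene_drop(ped, n_markers = 200, seed = 3)
  g <- unclass(m)
  # both parents alt-homozygous -> all offspring alt-homozygous
  snp0 <- which(g["S", ] == 0 & g["D", ] == 0)
  expect_true(length(snp0) > 0)
  expect_true(all(g[paste0("o", 1:30), snp0] == 0))
  # cross of opposite homozygotes -> all offspring heterozygous
  snp_x <- which(g["S", ] == 0 & g["D", ] == 2)
  if (length(snp_x))
    expect_true(all(g[paste0("o", 1:30), snp_x] == 1))
  # determinism
  expect_identical(unclass(gene_drop(ped, 200, seed = 3)), g)
  expect_false(identical(unclass(gene_drop(ped, 200, seed = 4)), g))
})

test_that("genomic relationships from gene-dropped markers track the
           pedigree", {
  sc <- simulation_scenario(n_parents = 40, n_families = 50,
                            genotypes_per_family = 10, ramets = 1,
                            grid_rows = 25, grid_cols = 20,
                            n_markers = 2000, traits = list())
  ped <- simulate_pedigree(sc, seed = 5)
  mk <- gene_drop(ped, n_markers = 2000, maf_low = 0.05, maf_high = 0.5,
                  seed = 6)
  clones <- ped$id[!(is.na(ped$sire) & is.na(ped$dam))]
  G <- genomic_relationship(marker_matrix(unclass(mk)[clones, ]))
  A <- unclass(numerator_relationship(ped))[clones, clones]
  off <- upper.tri(A)
  slope <- stats::coef(stats::lm(unclass(G)[off] ~ A[off]))[2]
  expect_gt(slope, 0.8)
  expect_lt(slope, 1.2)
})

test_that("trial simulation reproduces the generative decomposition", {
  # all variances zero: phenotype equals the trait mean everywhere
  sc0 <- simulation_scenario(n_parents = 6, n_families = 5,
                             genotypes_per_family = 4, ramets = 2,
                             grid_rows = 8, grid_cols = 5, block_size = 10,
                             traits = list(list(name = "T", mean = 7,
                                                additive = 0, pe = 0, block = 0,
                                                spatial = 0, residual = 0,
                                                rho_row = 0, rho_col = 0)))
  ped0 <- simulate_pedigree(sc0, seed = 7)
  tr0 <- simulate_trial(ped0, sc0, seed = 8)
  expect_true(all(tr0$pheno$T == 7))
  # one plant per cell
  expect_false(anyDuplicated(tr0$pheno[, c("row", "col")]) > 0)

  # determinism
  tr0b <- simulate_trial(ped0, sc0, seed = 8)
  expect_identical(tr0$pheno, tr0b$pheno)

  # pure additive trait: breeding-value variance concentrates around truth
  sc1 <- simulation_scenario(n_parents = 60, n_families = 100,
                             genotypes_per_family = 10, ramets = 1,
                             grid_rows = 40, grid_cols = 25, block_size = 40,
                             traits = list(list(name = "T", mean = 0,
                                                additive = 1, pe = 0, block = 0,
                                                spatial = 0, residual = 0,
                                                rho_row = 0, rho_col = 0)))
  ped1 <- simulate_pedigree(sc1, seed = 9)
  tr1 <- simulate_trial(ped1, sc1, seed = 10)
  clones <- ped1$id[!(is.na(ped1$sire) & is.na(ped1$dam))]
  v <- stats::var(tr1$truth$breeding_values$T[clones])
  expect_gt(v, 0.85); expect_lt(v, 1.15)

  # grid capacity is enforced
  expect_error(simulation_scenario(n_parents = 6, n_families = 5,
                                   genotypes_per_family = 4, ramets = 2,
                                   grid_rows = 3, grid_cols = 3,
                                   traits = list()),
               "capacity")
})

test_that("the bundled default scenario matches the study dimensions", {
  sc <- radiata_scenario()
  expect_equal(sc$n_families * sc$genotypes_per_family * sc$ramets, 1890)
  tr <- sc$traits[[1]]
  h2 <- tr$additive / (tr$additive + tr$pe + tr$residual)
  expect_equal(round(h2, 2), 0.38)
  # config round trip
  f <- tempfile(fileext = ".yaml")
  write_scenario(sc, f)
  sc2 <- read_scenario(f)
  expect_equal(unclass(sc2)[names(unclass(sc))], unclass(sc),
               ignore_attr = TRUE)
  unlink(f)
})

test_that("written datasets can be read back by the pipeline readers", {
  st <- small_trial(n_fam = 5, gpf = 3, ramets = 2, seed = 13)
  mk <- gene_drop(st$ped, n_markers = 40, seed = 14)
  dir <- tempfile()
  write_dataset(st$ped, mk, st$trial, st$scenario, dir)
  ped2 <- read_pedigree(file.path(dir, "pedigree.csv"))
  expect_setequal(ped2$id, st$ped$id)
  ph2 <- read_phenotypes(file.path(dir, "phenotypes.csv"))
  expect_equal(nrow(ph2), nrow(st$trial$pheno))
  m2 <- read_markers(file.path(dir, "genotypes.csv"), format = "matrix-csv")
  expect_equal(unclass(m2), unclass(mk), ignore_attr = TRUE)
  m3 <- read_markers(file.path(dir, "genotypes.vcf"), format = "vcf")
  expect_equal(unclass(m3), unclass(mk), ignore_attr = TRUE)
  unlink(dir, recursive = TRUE)
})
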