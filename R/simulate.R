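# Synthetic-data generation: pedigrees with full-sib family structure,
# gene-dropped SNP genotypes consistent with the pedigree, and spatially
# structured clonal-trial phenotypes with known ground truth.

#' Define a simulation scenario
#'
#' Bundles the family structure, trial grid, marker panel and true variance
#' components that drive the generator. Every generator is a pure function of
#' (scenario, seed).
#'
#' @param n_parents Number of unrelated founder parents.
#' @param n_families Number of full-sib families (distinct parent pairs; a
#'   parent may appear in several pairs).
#' @param genotypes_per_family Clones per family.
#' @param ramets Ramets (vegetative copies) per genotype.
#' @param grid_rows,grid_cols Trial grid extent; capacity must cover all
#'   plants.
#' @param block_size Incomplete blocks are contiguous column-major grid
#'   segments of this many cells.
#' @param n_markers Number of biallelic SNPs gene-dropped through the
#'   pedigree.
#' @param maf_low,maf_high Founder minor-allele-frequency range (uniform).
#' @param traits List of per-trait parameter lists: `name`, `mean`, and the
#'   true variance components `additive`, `pe`, `block`, `spatial`,
#'   `residual`, plus `rho_row`, `rho_col`.
#' @param additive_correlation Optional additive-genetic correlation between
#'   the first two traits.
#' @return A `sim_scenario` object.
#' @export
simulation_scenario <- function(n_parents = 55, n_families = 63,
                                genotypes_per_family = 10, ramets = 3,
                                grid_rows = 45, grid_cols = 42,
                                block_size = 30, n_markers = 2000,
                                maf_low = 0.05, maf_high = 0.5,
                                traits = list(), additive_correlation = NULL) {
  stopifnot(n_parents >= 2, n_families >= 1, genotypes_per_family >= 1,
            ramets >= 1, maf_low > 0, maf_high <= 0.5, maf_low <= maf_high)
  n_plants <- n_families * genotypes_per_family * ramets
  if (grid_rows * grid_cols < n_plants)
    stopf("grid capacity %d below plant count %d", grid_rows * grid_cols, n_plants)
  if (!is.null(additive_correlation) && abs(additive_correlation) > 1)
    stopf("additive correlation must lie in [-1, 1]")
  for (tr in traits) {
    vcs <- unlist(tr[c("additive", "pe", "block", "spatial", "residual")])
    if (any(vcs < 0)) stopf("trait '%s' has a negative variance component", tr$name)
  }
  structure(list(
    n_parents = n_parents, n_families = n_families,
    genotypes_per_family = genotypes_per_family, ramets = ramets,
    grid_rows = grid_rows, grid_cols = grid_cols, block_size = block_size,
    n_markers = n_markers, maf_low = maf_low, maf_high = maf_high,
    traits = traits, additive_correlation = additive_correlation
  ), class = "sim_scenario")
}

#' The bundled clonal-trial default scenario
#'
#' 55 parents crossed into 63 full-sib families of 10 genotypes, three ramets
#' per genotype (1,890 plants) on a 45 x 42 grid in contiguous incomplete
#' blocks of 30, with 2,000 gene-dropped SNPs (founder MAF uniform on
#' 0.05-0.5). The trait uses the initial-height variance components
#' (additive 15.41, non-additive 11.50, independent residual 14.04, implying
#' narrow-sense heritability 0.38); the block variance (2), spatial variance
#' (3) and autocorrelations (0.5) are package defaults, flagged as such in the
#' scenario's `note` field when serialized.
#'
#' @return A `sim_scenario`.
#' @export
radiata_scenario <- function() {
  sc <- simulation_scenario(
    n_parents = 55, n_families = 63, genotypes_per_family = 10, ramets = 3,
    grid_rows = 45, grid_cols = 42, block_size = 30,
    n_markers = 2000, maf_low = 0.05, maf_high = 0.5,
    traits = list(list(name = "H_I", mean = 39.01,
                       additive = 15.41, pe = 11.50, block = 2,
                       spatial = 3, residual = 14.04,
                       rho_row = 0.5, rho_col = 0.5))
  )
  attr(sc, "note") <- paste(
    "block, spatial and autocorrelation values are package defaults;",
    "additive, pe and residual follow the initial-height components")
  sc
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf("Simulation scenario: %d parents, %d families x %d genotypes x %d ramets (%d plants)\n",
              x$n_parents, x$n_families, x$genotypes_per_family, x$ramets,
              x$n_families * x$genotypes_per_family * x$ramets))
  cat(sprintf("  grid %d x %d, blocks of %d; %d markers (founder MAF U(%.2f, %.2f))\n",
              x$grid_rows, x$grid_cols, x$block_size, x$n_markers,
              x$maf_low, x$maf_high))
  for (tr in x$traits)
    cat(sprintf("  trait %s: mean %.2f, vc(a=%.3g, pe=%.3g, b=%.3g, xi=%.3g, e=%.3g), rho(%.2f, %.2f)\n",
                tr$name, tr$mean, tr$additive, tr$pe, tr$block, tr$spatial,
                tr$residual, tr$rho_row, tr$rho_col))
  invisible(x)
}

#' Write / read a scenario as structured text (YAML)
#' @param scenario A `sim_scenario`.
#' @param path File path.
#' @return `path` invisibly / the scenario.
#' @export
write_scenario <- function(scenario, path) {
  lst <- unclass(scenario)
  lst$note <- attr(scenario, "note")
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  lst <- yaml::read_yaml(path)
  note <- lst$note
  lst$note <- NULL
  sc <- do.call(simulation_scenario, lst)
  if (!is.null(note)) attr(sc, "note") <- note
  sc
}

#' Simulate a crossing pedigree
#'
#' Unrelated founder parents; families are distinct parent pairs sampled
#' without replacement of pairs (a parent may serve in several families);
#' `genotypes_per_family` offspring per family.
#'
#' @param scenario A `sim_scenario` (fields `n_parents`, `n_families`,
#'   `genotypes_per_family` are used).
#' @param seed Integer seed.
#' @return A [pedigree] with parents first, then offspring; offspring ids are
#'   `F<family>_G<index>`.
#' @export
simulate_pedigree <- function(scenario, seed = 1) {
  np <- scenario$n_parents; nf <- scenario$n_families
  ng <- scenario$genotypes_per_family
  n_pairs <- np * (np - 1) / 2
  if (nf > n_pairs)
    stopf("%d families requested but only %d distinct parent pairs exist", nf, n_pairs)
  parents <- sprintf("P%03d", seq_len(np))
  pairs <- with_seed(seed, {
    idx <- sample.int(n_pairs, nf)
    # enumerate unordered pairs (i < j) lexicographically
    all_pairs <- which(upper.tri(matrix(0, np, np)), arr.ind = TRUE)
    all_pairs[idx, , drop = FALSE]
  })
  fam <- rep(seq_len(nf), each = ng)
  kid <- rep(seq_len(ng), nf)
  ids <- sprintf("F%02d_G%02d", fam, kid)
  pedigree(c(parents, ids),
           c(rep(NA, np), parents[pairs[fam, 1]]),
           c(rep(NA, np), parents[pairs[fam, 2]]))
}

#' Gene-drop biallelic SNPs through a pedigree
#'
#' Founder alleles are drawn per marker with a reference-allele frequency
#' whose minor-allele frequency is uniform on (`maf_low`, `maf_high`) (the
#' minor allele is the reference or the alternative with equal probability);
#' each offspring inherits one uniformly chosen allele per parent per marker,
#' independently across markers. Codes follow the 0/1/2 convention with 2 the
#' reference homozygote.
#'
#' @param ped A [pedigree].
#' @param n_markers Number of markers.
#' @param maf_low,maf_high Founder MAF range.
#' @param seed Integer seed.
#' @return A `marker_matrix` over all pedigree individuals.
#' @export
gene_drop <- function(ped, n_markers, maf_low = 0.05, maf_high = 0.5, seed = 1) {
  stopifnot(inherits(ped, "pedigree"), n_markers >= 1)
  n <- nrow(ped)
  pos <- stats::setNames(seq_len(n), ped$id)
  si <- unname(pos[ped$sire]); di <- unname(pos[ped$dam])
  with_seed(seed, {
    maf <- stats::runif(n_markers, maf_low, maf_high)
    flip <- stats::runif(n_markers) < 0.5
    p_ref <- ifelse(flip, maf, 1 - maf)
    hap1 <- matrix(0L, n, n_markers)  # 1 = reference allele
    hap2 <- matrix(0L, n, n_markers)
    for (i in seq_len(n)) {
      if (is.na(si[i])) {
        hap1[i, ] <- stats::rbinom(n_markers, 1L, p_ref)
        hap2[i, ] <- stats::rbinom(n_markers, 1L, p_ref)
      } else {
        pick_s <- stats::runif(n_markers) < 0.5
        hap1[i, ] <- ifelse(pick_s, hap1[si[i], ], hap2[si[i], ])
        pick_d <- stats::runif(n_markers) < 0.5
        hap2[i, ] <- ifelse(pick_d, hap1[di[i], ], hap2[di[i], ])
      }
    }
    g <- hap1 + hap2
    dimnames(g) <- list(ped$id, sprintf("snp%05d", seq_len(n_markers)))
    marker_matrix(g)
  })
}

#' Simulate a spatially structured clonal trial
#'
#' Generates phenotypes from the additive-genetic / clone / block / AR1xAR1
#' spatial / independent-residual decomposition: breeding values are drawn
#' from `N(0, K sigma_a^2)` via a matrix square root of the relationship
#' matrix (all pedigree individuals get a value; only the clones are planted),
#' pe and block effects are iid normal, the spatial field is drawn on the full
#' grid from the separable AR1 correlation, and ramets of each genotype are
#' placed at random grid positions (one plant per cell; unused cells stay
#' empty). A second trait can share additive structure through the scenario's
#' `additive_correlation`.
#'
#' @param ped A [pedigree] (clones are the non-founder individuals), or a
#'   precomputed `relationship_matrix` whose non-parent labels are the clones.
#' @param scenario A `sim_scenario` with at least one trait.
#' @param seed Integer seed.
#' @return List with `pheno` (plant table: `plant_id`, `genotype_id`, `block`,
#'   `row`, `col`, one column per trait), `truth` (true breeding values, pe,
#'   block, spatial and residual draws and the realized components), and
#'   `kinship` (the A matrix used).
#' @export
simulate_trial <- function(ped, scenario, seed = 1) {
  stopifnot(inherits(scenario, "sim_scenario"), length(scenario$traits) >= 1)
  if (inherits(ped, "pedigree")) {
    A <- numerator_relationship(ped)
    clones <- ped$id[!(is.na(ped$sire) & is.na(ped$dam))]
  } else {
    A <- as_relationship(ped)
    clones <- rownames(A)
  }
  K <- unclass(A)
  nq <- length(clones)
  m <- scenario$ramets
  n_plants <- nq * m
  nr <- scenario$grid_rows; nc <- scenario$grid_cols
  if (nr * nc < n_plants) stopf("grid too small for %d plants", n_plants)

  L <- t(chol(K + diag(1e-10, nrow(K))))  # lower-triangular sqrt of A
  traits <- scenario$traits
  ntr <- length(traits)
  rho_a <- scenario$additive_correlation

  with_seed(seed, {
    # placement and blocks
    cells <- sample.int(nr * nc, n_plants)
    row <- ((cells - 1) %% nr) + 1L
    col <- ((cells - 1) %/% nr) + 1L
    block <- sprintf("B%03d", ((cells - 1) %/% scenario$block_size) + 1L)
    geno <- rep(clones, each = m)
    plant_id <- sprintf("%s_r%d", geno, rep(seq_len(m), nq))

    # standardized additive draws over all pedigree individuals
    z <- matrix(stats::rnorm(nrow(K) * ntr), nrow(K), ntr)
    u <- L %*% z   # columns: N(0, A)
    if (!is.null(rho_a) && ntr >= 2) {
      u2 <- rho_a * u[, 1] + sqrt(1 - rho_a^2) * u[, 2]
      u[, 2] <- u2
    }

    pheno <- data.frame(plant_id = plant_id, genotype_id = geno,
                        block = block, row = row, col = col,
                        stringsAsFactors = FALSE)
    truth <- list(breeding_values = list(), pe = list(), block_effects = list(),
                  spatial = list(), residual = list(), realized = list())
    for (t in seq_len(ntr)) {
      tr <- traits[[t]]
      a_all <- sqrt(tr$additive) * u[, t]
      names(a_all) <- rownames(K)
      pe <- stats::rnorm(nq, 0, sqrt(tr$pe))
      names(pe) <- clones
      blocks_all <- sort(unique(block))
      b <- stats::rnorm(length(blocks_all), 0, sqrt(tr$block))
      names(b) <- blocks_all
      # spatial field on the full grid via the separable square root
      if (tr$spatial > 0) {
        Lr <- t(chol(pow_int(tr$rho_row, abs(outer(1:nr, 1:nr, "-")))))
        Lc <- t(chol(pow_int(tr$rho_col, abs(outer(1:nc, 1:nc, "-")))))
        field <- sqrt(tr$spatial) * (Lr %*% matrix(stats::rnorm(nr * nc), nr, nc) %*% t(Lc))
        xi <- field[cbind(row, col)]
      } else {
        xi <- numeric(n_plants)
      }
      eta <- stats::rnorm(n_plants, 0, sqrt(tr$residual))
      y <- tr$mean + a_all[geno] + pe[geno] + b[block] + xi + eta
      pheno[[tr$name]] <- as.numeric(y)
      truth$breeding_values[[tr$name]] <- a_all
      truth$pe[[tr$name]] <- pe
      truth$block_effects[[tr$name]] <- b
      truth$spatial[[tr$name]] <- xi
      truth$residual[[tr$name]] <- eta
      truth$realized[[tr$name]] <- c(
        additive = stats::var(a_all[clones]), pe = stats::var(pe),
        block = stats::var(b), spatial = stats::var(xi),
        residual = stats::var(eta))
    }
    list(pheno = pheno, truth = truth, kinship = A)
  })
}

#' Write a simulated dataset to disk
#'
#' Emits the same file formats the pipeline reads: `pedigree.csv`,
#' `genotypes.csv` and `genotypes.vcf`, `phenotypes.csv` and `scenario.yaml`.
#'
#' @param ped A [pedigree].
#' @param markers A `marker_matrix` (or `NULL` to skip genotype files).
#' @param trial Output of [simulate_trial()].
#' @param scenario The `sim_scenario` used.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ped, markers, trial, scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pedigree(ped, file.path(dir, "pedigree.csv"))
  if (!is.null(markers)) {
    write_markers(markers, file.path(dir, "genotypes.csv"))
    write_vcf(markers, file.path(dir, "genotypes.vcf"))
  }
  utils::write.csv(trial$pheno, file.path(dir, "phenotypes.csv"),
                   row.names = FALSE, quote = FALSE)
  write_scenario(scenario, file.path(dir, "scenario.yaml"))
  invisible(dir)
}

#' Write a marker matrix as a minimal VCF
#'
#' Biallelic SNP records with a GT field; code 2 (reference homozygote) maps
#' to `0/0`, 1 to `0/1`, 0 to `1/1`, missing to `./.`. Intended for round
#' trips with `read_markers(format = "vcf")`.
#'
#' @param m A `marker_matrix` with integer codes.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(m, path) {
  g <- unclass(m)
  if (any(!is.na(g) & g != round(g)))
    stopf("VCF output needs integer genotype codes (write before imputation)")
  ids <- rownames(g); snps <- colnames(g)
  gt <- matrix("./.", ncol(g), nrow(g))
  codes <- t(g)
  gt[!is.na(codes) & codes == 2] <- "0/0"
  gt[!is.na(codes) & codes == 1] <- "0/1"
  gt[!is.na(codes) & codes == 0] <- "1/1"
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              "##contig=<ID=1>",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", ids), collapse = "\t"))
  body <- vapply(seq_along(snps), function(j) {
    paste(c("1", j, snps[j], "A", "C", ".", ".", ".", "GT", gt[j, ]),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
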