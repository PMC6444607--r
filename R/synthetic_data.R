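# Synthetic QTL-trait simulator: Hardy-Weinberg genotypes plus a trait built
# from planted additive, dominance, over-dominance and under-dominance loci.
# Targets the statistical structure the solver consumes (genotype-class
# effects, MAF spectrum, cohort-style train/test split), not the pedigree or
# coalescent ancestry of real workshop data.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Simulation configuration
#'
#' Defaults state the emulated world: two major additive QTLs with effects
#' -3 and 3; polygenic additive effects drawn from a standard normal
#' truncated at |a| < 2; one dominance locus (heterozygote 5.00, upper
#' homozygote 5.01), one over-dominance locus (heterozygote 5.00,
#' homozygotes -0.01 / 0.01) and one under-dominance locus (heterozygote
#' -5.00, homozygotes -0.01 / 0.01); the last \code{test_fraction} of
#' individuals form the test cohort (generation-style holdout).
#'
#' @param n_individuals number of individuals (default 2000).
#' @param n_snps number of SNPs (default 1000).
#' @param maf_range allele-frequency sampling range, in (0, 0.5].
#' @param n_random_qtl number of polygenic additive QTLs (default 28).
#' @param random_qtl_truncation acceptance bound on |additive effect|
#'   (default 2).
#' @param major_qtl_effects additive effects of the major QTLs.
#' @param dominance_spec data.frame with columns \code{type}
#'   (dominance/overdominance/underdominance), \code{het}, \code{hom0},
#'   \code{hom2}.
#' @param noise_sd residual SD; NULL (default) sets it to the SD of the
#'   realized genetic values, giving heritability ~ 0.5.
#' @param test_fraction held-out tail fraction (default 0.3).
#' @param seed integer seed; the dataset is a pure function of
#'   (config, seed).
#' @param ld_rho within-block genotype-copy probability in \[0, 1) for an
#'   optional crude linkage approximation (default 0: independent SNPs).
#' @param ld_block_size SNPs per LD block when \code{ld_rho > 0}.
#' @return List of class \code{simulation_config}.
#' @export
simulation_config <- function(n_individuals = 2000, n_snps = 1000,
                              maf_range = c(0.05, 0.5),
                              n_random_qtl = 28,
                              random_qtl_truncation = 2,
                              major_qtl_effects = c(-3, 3),
                              dominance_spec = default_dominance_spec(),
                              noise_sd = NULL, test_fraction = 0.3,
                              seed = 1, ld_rho = 0, ld_block_size = 10) {
  stopifnot(n_individuals >= 2, n_snps >= 1,
            length(maf_range) == 2, maf_range[1] > 0,
            maf_range[2] <= 0.5, maf_range[1] <= maf_range[2],
            n_random_qtl >= 0, random_qtl_truncation > 0,
            test_fraction > 0, test_fraction < 1,
            ld_rho >= 0, ld_rho < 1)
  dominance_spec <- as.data.frame(dominance_spec)
  if (nrow(dominance_spec) > 0) {
    stopifnot(all(c("type", "het", "hom0", "hom2") %in%
                    names(dominance_spec)),
              all(dominance_spec$type %in%
                    c("dominance", "overdominance", "underdominance")))
  }
  n_loci <- n_random_qtl + length(major_qtl_effects) + nrow(dominance_spec)
  if (n_loci > n_snps) stop("more QTLs than SNPs: need distinct loci")
  structure(list(n_individuals = as.integer(n_individuals),
                 n_snps = as.integer(n_snps), maf_range = maf_range,
                 n_random_qtl = as.integer(n_random_qtl),
                 random_qtl_truncation = random_qtl_truncation,
                 major_qtl_effects = major_qtl_effects,
                 dominance_spec = dominance_spec, noise_sd = noise_sd,
                 test_fraction = test_fraction, seed = as.integer(seed),
                 ld_rho = ld_rho, ld_block_size = as.integer(ld_block_size)),
            class = "simulation_config")
}

#' Default dominance-type locus effects
#'
#' @return data.frame of the three planted heterozygote-effect loci.
#' @export
default_dominance_spec <- function() {
  data.frame(
    type = c("dominance", "overdominance", "underdominance"),
    het = c(5.00, 5.00, -5.00),
    hom0 = c(0, -0.01, -0.01),
    hom2 = c(5.01, 0.01, 0.01),
    stringsAsFactors = FALSE)
}

#' Simulate Hardy-Weinberg genotypes
#'
#' Per SNP, an allele frequency is drawn uniformly from \code{maf_range} and
#' genotypes as two Bernoulli allele draws summed (binomial(2, p)),
#' independent across SNPs unless \code{ld_rho > 0}, in which case each
#' individual copies the previous within-block genotype with probability
#' \code{ld_rho}.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return A \code{\link{genotype_matrix}} with attribute
#'   \code{allele_freqs}.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, simulate_genotypes_impl(config))
}

simulate_genotypes_impl <- function(config) {
  n <- config$n_individuals; p <- config$n_snps
  freqs <- stats::runif(p, config$maf_range[1], config$maf_range[2])
  G <- matrix(0L, nrow = n, ncol = p)
  for (j in seq_len(p)) {
    g <- stats::rbinom(n, 2L, freqs[j])
    if (config$ld_rho > 0 && (j - 1L) %% config$ld_block_size != 0L) {
      copy <- stats::runif(n) < config$ld_rho
      g[copy] <- G[copy, j - 1L]
    }
    G[, j] <- g
  }
  out <- genotype_matrix(G, snp_ids = sprintf("snp%04d", seq_len(p)),
                         individual_ids = sprintf("ind%05d", seq_len(n)))
  attr(out, "allele_freqs") <- freqs
  out
}

#' Place QTLs and draw their effects
#'
#' Major additive loci take the configured effects; polygenic additive
#' effects are standard-normal draws rejected until
#' |effect| < \code{random_qtl_truncation}; the dominance-type loci carry
#' their configured per-genotype-class values. All loci occupy distinct
#' random SNP indices.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return data.frame of class \code{truth_table}: \code{locus} (column
#'   index), \code{type}, \code{a} (additive effect, NA for
#'   genotype-class loci), \code{het}, \code{hom0}, \code{hom2}.
#' @export
assign_effects <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  # seed offset keeps effect draws decoupled from the genotype stream
  with_seed(config$seed + 1L, assign_effects_impl(config))
}

assign_effects_impl <- function(config) {
  n_major <- length(config$major_qtl_effects)
  n_dom <- nrow(config$dominance_spec)
  n_loci <- n_major + n_dom + config$n_random_qtl
  loci <- sample.int(config$n_snps, n_loci)
  rtrunc <- function(k, bound) {
    out <- numeric(k)
    for (i in seq_len(k)) {
      repeat {
        x <- stats::rnorm(1)
        if (abs(x) < bound) break
      }
      out[i] <- x
    }
    out
  }
  truth <- data.frame(
    locus = loci,
    type = c(rep("major", n_major), as.character(config$dominance_spec$type),
             rep("random", config$n_random_qtl)),
    a = c(config$major_qtl_effects, rep(NA_real_, n_dom),
          rtrunc(config$n_random_qtl, config$random_qtl_truncation)),
    het = c(rep(NA_real_, n_major), config$dominance_spec$het,
            rep(NA_real_, config$n_random_qtl)),
    hom0 = c(rep(NA_real_, n_major), config$dominance_spec$hom0,
             rep(NA_real_, config$n_random_qtl)),
    hom2 = c(rep(NA_real_, n_major), config$dominance_spec$hom2,
             rep(NA_real_, config$n_random_qtl)),
    stringsAsFactors = FALSE)
  class(truth) <- c("truth_table", "data.frame")
  truth
}

genetic_values <- function(G, truth) {
  vals <- numeric(nrow(G$values))
  for (i in seq_len(nrow(truth))) {
    g <- G$values[, truth$locus[i]]
    vals <- vals + if (!is.na(truth$a[i])) {
      truth$a[i] * g
    } else {
      c(truth$hom0[i], truth$het[i], truth$hom2[i])[g + 1L]
    }
  }
  vals
}

#' Build phenotypes from genotypes and a truth table
#'
#' Additive loci contribute effect x genotype count; genotype-class loci
#' contribute their per-class value; Gaussian noise with SD
#' \code{noise_sd} is added.
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @param truth a truth table from \code{\link{assign_effects}}.
#' @param noise_sd residual standard deviation (>= 0).
#' @param seed integer seed for the noise draw.
#' @return Numeric phenotype vector.
#' @export
simulate_phenotypes <- function(G, truth, noise_sd, seed = 1) {
  stopifnot(inherits(G, "genotype_matrix"), noise_sd >= 0)
  g_vals <- genetic_values(G, truth)
  noise <- with_seed(seed + 2L,
                     stats::rnorm(nrow(G$values), 0, noise_sd))
  g_vals + noise
}

#' Generate a complete synthetic dataset
#'
#' Orchestrates \code{\link{simulate_genotypes}},
#' \code{\link{assign_effects}} and \code{\link{simulate_phenotypes}} and
#' attaches a generation-style tail holdout split. When
#' \code{config$noise_sd} is NULL the residual SD is set to the SD of the
#' realized genetic values, so heritability is approximately 0.5.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return List of class \code{simulated_dataset}: \code{genotypes},
#'   \code{phenotypes}, \code{truth}, \code{split}, \code{noise_sd},
#'   \code{config}.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  G <- simulate_genotypes(config)
  truth <- assign_effects(config)
  noise_sd <- config$noise_sd
  if (is.null(noise_sd)) noise_sd <- stats::sd(genetic_values(G, truth))
  y <- simulate_phenotypes(G, truth, noise_sd, seed = config$seed)
  split <- make_splits(config$n_individuals, mode = "holdout_tail",
                       test_fraction = config$test_fraction,
                       seed = config$seed)
  structure(list(genotypes = G, phenotypes = y, truth = truth,
                 split = split, noise_sd = noise_sd, config = config),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf(
    "simulated_dataset: %d individuals x %d SNPs, %d QTLs, noise_sd = %.3g\n",
    nrow(x$genotypes$values), ncol(x$genotypes$values), nrow(x$truth),
    x$noise_sd))
  invisible(x)
}

#' Write a simulated dataset as delimited text files
#'
#' Emits \code{genotypes.tsv} (individuals x SNPs with header and id
#' column), \code{phenotypes.tsv} (id, value) and \code{truth.tsv}.
#'
#' @param sim a \code{simulated_dataset}.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "simulated_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- as.data.frame(sim$genotypes$values)
  names(g) <- sim$genotypes$snp_ids
  utils::write.table(
    cbind(data.frame(id = sim$genotypes$individual_ids), g),
    file.path(dir, "genotypes.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(id = sim$genotypes$individual_ids,
               phenotype = sim$phenotypes),
    file.path(dir, "phenotypes.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(as.data.frame(sim$truth),
                     file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
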