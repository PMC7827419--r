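#' Simulate noisy GBS read observations of known genotypes
#'
#' Converts true per-sample alternate-allele dosages into a
#' [genotype_matrix()] of depth and allele-depth observations.  Per cell,
#' total depth is negative-binomial with mean `depth_mean` and size
#' `depth_dispersion` (`Inf` = Poisson); each read reports the wrong
#' allele with probability `genotype_error_rate`, so observed
#' alternate-read counts are binomial with success probability
#' `f (1 - e) + (1 - f) e` where `f` is the true alternate fraction.
#' Cells drawing depth 0 are emitted as absent, not as zero-depth
#' records.
#'
#' @param sites Data frame `chrom`, `pos`, `ref`, `alt` (sorted).
#' @param f_alt Numeric matrix, sites x samples, of true alternate-allele
#'   fractions (0 hom-ref, 0.5 het, 1 hom-alt).
#' @param samples Sample names (columns of `f_alt`).
#' @param config A [sim_config()] supplying depth and error parameters.
#' @return A `genotype_matrix`.
#' @export
simulate_observations <- function(sites, f_alt, samples, config) {
  config <- validate_sim_config(config)
  n <- nrow(sites); m <- length(samples)
  stopifnot(is.matrix(f_alt), nrow(f_alt) == n, ncol(f_alt) == m)
  dp <- if (is.infinite(config$depth_dispersion))
    stats::rpois(n * m, config$depth_mean)
  else
    stats::rnbinom(n * m, size = config$depth_dispersion,
                   mu = config$depth_mean)
  e <- config$genotype_error_rate
  p <- as.vector(f_alt) * (1 - e) + (1 - as.vector(f_alt)) * e
  ad_alt <- stats::rbinom(n * m, size = dp, prob = p)
  ad_ref <- dp - ad_alt
  absent <- dp == 0
  dp[absent] <- NA; ad_ref[absent] <- NA; ad_alt[absent] <- NA
  genotype_matrix(sites, samples,
                  matrix(dp, n, m), matrix(ad_ref, n, m),
                  matrix(ad_alt, n, m))
}

#' Simulate a complete mutagenesis GBS experiment
#'
#' Builds a genome, injects induced mutations into mutant lines (controls
#' stay clean), and observes every mutated site across all samples.
#' Induced mutations are heterozygous in the observed generation, so
#' carriers have true alternate fraction 0.5; all other samples are
#' homozygous for the consensus (reference) allele.
#'
#' @param config A [sim_config()]; `config$seed` seeds all draws.
#' @param n_controls,n_mutants Numbers of non-irradiated control and
#'   mutant lines.
#' @param groups Optional character vector of group labels for the mutant
#'   lines (recycled); defaults to a single `"irradiated"` group.
#' @return List of class `gbs_mut_sim`: `genome`, `truth`
#'   (a `mutation_truth`), `matrix` (a `genotype_matrix`), `manifest`
#'   (data frame `sample`, `role`, `group`), `config`.
#' @examples
#' sim <- simulate_mutation_experiment(
#'   sim_config(n_chromosomes = 2, chrom_length = 1e6, n_regions = 300,
#'              mutation_density = 50, seed = 42))
#' nrow(sim$truth)
#' @export
simulate_mutation_experiment <- function(config, n_controls = 4,
                                         n_mutants = 3, groups = NULL) {
  config <- validate_sim_config(config)
  set.seed(config$seed)
  genome <- build_genome(config)
  controls <- sprintf("control_%d", seq_len(n_controls))
  mutants <- sprintf("mutant_%d", seq_len(n_mutants))
  truth <- inject_mutations(genome, config, mutants)
  sites <- unique(truth[, c("chrom", "pos", "ref", "alt")])
  sites <- sites[order(sites$chrom, sites$pos, sites$alt), , drop = FALSE]
  rownames(sites) <- NULL
  samples <- c(controls, mutants)
  f_alt <- matrix(0, nrow(sites), length(samples),
                  dimnames = list(NULL, samples))
  if (nrow(truth)) {
    key <- paste(sites$chrom, sites$pos, sites$ref, sites$alt)
    hit <- match(paste(truth$chrom, truth$pos, truth$ref, truth$alt), key)
    f_alt[cbind(hit, match(truth$sample, samples))] <- 0.5
  }
  gm <- simulate_observations(sites, f_alt, samples, config)
  grp <- if (is.null(groups)) "irradiated" else groups
  manifest <- data.frame(
    sample = samples,
    role = c(rep("control", n_controls), rep("mutant", n_mutants)),
    group = c(rep("control", n_controls),
              rep_len(grp, n_mutants)),
    stringsAsFactors = FALSE)
  structure(list(genome = genome, truth = truth, matrix = gm,
                 manifest = manifest, config = config),
            class = "gbs_mut_sim")
}

#' Simulate a complete backcross (BC1) GBS experiment
#'
#' Builds a genome, a divergent biparental cross, and a BC1 panel with
#' recorded crossovers, then observes all informative markers in
#' replicated parental pools, F1 pools, and every progeny line.
#'
#' @param config A [sim_config()]; `config$seed` seeds all draws.
#' @param n_progeny Number of BC1 progeny lines.
#' @param n_per_pool Replicate plants per parental/F1 pool (such
#'   designs typically pool four plants per line).
#' @return List of class `gbs_bc_sim`: `genome`, `cross`
#'   (`marker_truth`), `truth` (`bc1_truth`), `matrix`
#'   (`genotype_matrix`), `manifest`, `config`.
#' @export
simulate_backcross_experiment <- function(config, n_progeny = 20,
                                          n_per_pool = 4) {
  config <- validate_sim_config(config)
  set.seed(config$seed)
  genome <- build_genome(config)
  cross <- simulate_cross(genome, config)
  if (!nrow(cross))
    stop("cross is uninformative: no divergent sites (snp_rate too low?)")
  panel <- simulate_bc1_panel(genome, cross, config, n_progeny)
  pa <- sprintf("parent_a_%d", seq_len(n_per_pool))
  pb <- sprintf("parent_b_%d", seq_len(n_per_pool))
  f1 <- sprintf("f1_%d", seq_len(n_per_pool))
  samples <- c(pa, pb, f1, panel$samples)
  f_alt <- cbind(matrix(0, nrow(cross), n_per_pool),
                 matrix(1, nrow(cross), n_per_pool),
                 matrix(0.5, nrow(cross), n_per_pool),
                 ifelse(panel$zygosity == "HET", 0.5, 0))
  colnames(f_alt) <- samples
  gm <- simulate_observations(cross[, c("chrom", "pos", "ref", "alt")],
                              f_alt, samples, config)
  manifest <- data.frame(
    sample = samples,
    role = c(rep("parentA", n_per_pool), rep("parentB", n_per_pool),
             rep("f1", n_per_pool), rep("progeny", n_progeny)),
    group = c(rep("parental", 3 * n_per_pool), rep("progeny", n_progeny)),
    stringsAsFactors = FALSE)
  structure(list(genome = genome, cross = cross, truth = panel,
                 matrix = gm, manifest = manifest, config = config),
            class = "gbs_bc_sim")
}
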