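#' Strand-collapsed single-base substitution categories
#'
#' The six categories a substitution can fall into once forward- and
#' reverse-strand representations are collapsed (e.g. A>G and T>C are the
#' same event, `A/T>G/C`).  The first two categories are the transitions.
#'
#' @format Character vector of length six.
#' @export
SBS_CATEGORIES <- c("A/T>G/C", "G/C>A/T", "A/T>T/A",
                    "A/T>C/G", "G/C>T/A", "G/C>C/G")

#' @rdname SBS_CATEGORIES
#' @export
SBS_TRANSITIONS <- SBS_CATEGORIES[1:2]

BASES <- c("A", "C", "G", "T")
COMP  <- c(A = "T", C = "G", G = "C", T = "A")

#' Default induced-substitution spectrum
#'
#' Category shares typical of progeny from irradiated reproductive
#' tissue: `A/T>G/C` 31%, `G/C>A/T` 38%, `G/C>T/A` 11%, with the
#' remaining 20% spread over the other transversions (`A/T>T/A`
#' comparable to `G/C>T/A`).  Used as the simulator default.
#'
#' @format Named numeric over [SBS_CATEGORIES], summing to 1.
#' @export
DEFAULT_SBS_SPECTRUM <- c(
  "A/T>G/C" = 0.31, "G/C>A/T" = 0.38, "A/T>T/A" = 0.12,
  "A/T>C/G" = 0.05, "G/C>T/A" = 0.11, "G/C>C/G" = 0.03
)

#' Simulation configuration for synthetic GBS experiments
#'
#' Bundles and validates every tunable of the synthetic genotyping-by-
#' sequencing generator.  Defaults emulate the structure of a pepper-style
#' GBS experiment: a 12-chromosome genome of which roughly 0.4% is covered
#' by short mapped regions (mean 144 bp), parental divergence of about
#' 3e-4 per mapped base, around 1.5 crossovers per chromosome per meiosis,
#' induced mutation density of 20 per 10 Mb of mapped sequence with a
#' realistic substitution spectrum and ~10% small InDels, mean depth 35
#' with negative-binomial overdispersion, and a small read-level
#' genotyping error.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Chromosome length in bp; scalar or one per chromosome.
#' @param n_regions Total number of mapped (GBS-covered) regions.
#' @param region_length_mean Mean mapped-region length in bp.
#' @param snp_rate Parental divergence per bp of mapped sequence.
#' @param xo_rate Expected crossovers per chromosome per meiosis.
#' @param mutation_density Induced mutations per 10 Mb of mapped sequence
#'   per mutant line.
#' @param sbs_spectrum Named non-negative proportions over
#'   [SBS_CATEGORIES], summing to 1.
#' @param indel_fraction Proportion of induced mutations that are 1-2 bp
#'   insertions/deletions.
#' @param depth_mean Mean per-site read depth.
#' @param depth_dispersion Negative-binomial size parameter of the depth
#'   distribution (smaller = more overdispersed; `Inf` gives Poisson
#'   depth).
#' @param genotype_error_rate Probability that a single read reports the
#'   wrong allele.
#' @param seed Integer seed from which all stochastic draws flow.
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_chromosomes = 1, chrom_length = 1e6, n_regions = 10)
#' cfg$n_regions
#' @export
sim_config <- function(n_chromosomes = 12,
                       chrom_length = 5e6,
                       n_regions = 1500,
                       region_length_mean = 144,
                       snp_rate = 3e-4,
                       xo_rate = 1.5,
                       mutation_density = 20,
                       sbs_spectrum = DEFAULT_SBS_SPECTRUM,
                       indel_fraction = 0.1,
                       depth_mean = 35,
                       depth_dispersion = 8,
                       genotype_error_rate = 0.002,
                       seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.numeric(chrom_length),
    n_regions = as.integer(n_regions),
    region_length_mean = as.numeric(region_length_mean),
    snp_rate = as.numeric(snp_rate),
    xo_rate = as.numeric(xo_rate),
    mutation_density = as.numeric(mutation_density),
    sbs_spectrum = sbs_spectrum,
    indel_fraction = as.numeric(indel_fraction),
    depth_mean = as.numeric(depth_mean),
    depth_dispersion = as.numeric(depth_dispersion),
    genotype_error_rate = as.numeric(genotype_error_rate),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_chromosomes < 1) stop("need at least one chromosome")
  if (!length(cfg$chrom_length) %in% c(1L, cfg$n_chromosomes))
    stop("chrom_length must be scalar or one value per chromosome")
  if (any(cfg$chrom_length < 1)) stop("chromosome lengths must be positive")
  if (cfg$n_regions < 0) stop("n_regions must be non-negative")
  if (cfg$region_length_mean <= 0) stop("region_length_mean must be positive")
  if (cfg$snp_rate < 0 || cfg$snp_rate > 1)
    stop("snp_rate must lie in [0, 1]")
  if (cfg$xo_rate < 0) stop("xo_rate must be non-negative")
  if (cfg$mutation_density < 0) stop("mutation_density must be non-negative")
  sp <- cfg$sbs_spectrum
  if (is.null(names(sp)) || !setequal(names(sp), SBS_CATEGORIES))
    stop("sbs_spectrum must be named by the six SBS categories")
  sp <- sp[SBS_CATEGORIES]
  if (any(sp < 0)) stop("sbs_spectrum entries must be non-negative")
  if (abs(sum(sp) - 1) > 1e-9) stop("sbs_spectrum must sum to 1")
  cfg$sbs_spectrum <- sp
  if (cfg$indel_fraction < 0 || cfg$indel_fraction > 1)
    stop("indel_fraction must lie in [0, 1]")
  if (cfg$depth_mean <= 0) stop("depth_mean must be positive")
  if (cfg$depth_dispersion <= 0) stop("depth_dispersion must be positive")
  if (cfg$genotype_error_rate < 0 || cfg$genotype_error_rate >= 0.5)
    stop("genotype_error_rate must lie in [0, 0.5)")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  genome: %d chromosomes, %s bp each (first)\n",
              x$n_chromosomes, format(x$chrom_length[1], big.mark = ",")))
  cat(sprintf("  mapped: %d regions, mean %.0f bp\n",
              x$n_regions, x$region_length_mean))
  cat(sprintf("  snp_rate %.2g, xo_rate %.2g, mutation_density %.3g/10 Mb (indels %.0f%%)\n",
              x$snp_rate, x$xo_rate, x$mutation_density, 100 * x$indel_fraction))
  cat(sprintf("  depth NB(mean %.3g, size %.3g), read error %.2g, seed %d\n",
              x$depth_mean, x$depth_dispersion, x$genotype_error_rate, x$seed))
  invisible(x)
}

chrom_names <- function(n) sprintf("chr%02d", seq_len(n))

chrom_lengths_of <- function(cfg) {
  stats::setNames(rep(cfg$chrom_length, length.out = cfg$n_chromosomes),
                  chrom_names(cfg$n_chromosomes))
}
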