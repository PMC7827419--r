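# Mutation screen: consensus, depth rules, classification, densities,
# spectra, generation correction.

# small hand-built matrix: 4 controls + 1 mutant over constructed sites
build_screen_gm <- function(sites, dp, ad_ref, ad_alt) {
  genotype_matrix(sites, c(paste0("c", 1:4), "m"),
                  dp = dp, ad_ref = ad_ref, ad_alt = ad_alt)
}

test_that("control consensus requires full agreement at adequate depth", {
  sites <- data.frame(chrom = "chr01", pos = c(10, 20, 30),
                      ref = "G", alt = "A", stringsAsFactors = FALSE)
  dp <- matrix(10, 3, 5)
  ar <- matrix(10, 3, 5)
  aa <- matrix(0, 3, 5)
  # site 2: one control carries the alternate allele -> disagreement
  ar[2, 4] <- 0; aa[2, 4] <- 10
  # site 3: one control below the 5x depth floor
  dp[3, 2] <- 3; ar[3, 2] <- 3
  gm <- build_screen_gm(sites, dp, ar, aa)
  cons <- control_consensus(gm, paste0("c", 1:4))
  expect_identical(cons, c("G", NA, NA))
  expect_error(control_consensus(gm, character(0)), "control")
})

test_that("screen calls mutations at >=5x and respects the InDel length rule", {
  sites <- data.frame(chrom = "chr01",
                      pos = c(10, 20, 30, 40, 50),
                      ref = c("G", "G", "GA", "G", "G"),
                      alt = c("A", "A", "G", "GAT", "GATTT"),
                      stringsAsFactors = FALSE)
  dp <- matrix(10, 5, 5); ar <- matrix(10, 5, 5); aa <- matrix(0, 5, 5)
  # mutant column: site1 SBS at depth 7 (call), site2 SBS at depth 4
  # (below floor), site3 1bp deletion, site4 net +2 insertion, site5
  # net +4 insertion (excluded)
  dp[, 5] <- c(7, 4, 12, 12, 12)
  ar[, 5] <- c(3, 2, 6, 6, 6)
  aa[, 5] <- c(4, 2, 6, 6, 6)
  gm <- build_screen_gm(sites, dp, ar, aa)
  calls <- screen_mutations(gm, paste0("c", 1:4), "m", min_depth = 5)
  expect_equal(calls$pos, c(10, 30, 40))
  expect_equal(calls$mtype, c("SBS", "DEL", "INS"))
  expect_equal(calls$indel_len, c(0L, 1L, 2L))
  expect_equal(calls$sbs_category[1], "G/C>A/T")
  expect_error(screen_mutations(gm, paste0("c", 1:4), "nope"),
               "mutant sample")
})

test_that("sub-threshold allele fractions are treated as noise", {
  sites <- data.frame(chrom = "chr01", pos = 10, ref = "G", alt = "A",
                      stringsAsFactors = FALSE)
  gm <- build_screen_gm(sites, matrix(40, 1, 5), matrix(c(rep(40, 4), 36), 1, 5),
                        matrix(c(rep(0, 4), 4), 1, 5))
  expect_equal(nrow(screen_mutations(gm, paste0("c", 1:4), "m")), 0)
  gm2 <- build_screen_gm(sites, matrix(40, 1, 5), matrix(c(rep(40, 4), 30), 1, 5),
                         matrix(c(rep(0, 4), 10), 1, 5))
  expect_equal(nrow(screen_mutations(gm2, paste0("c", 1:4), "m")), 1)
})

test_that("strand collapse yields six categories of two ordered pairs each", {
  pairs <- expand.grid(ref = c("A", "C", "G", "T"),
                       alt = c("A", "C", "G", "T"),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  cl <- classify_sbs(pairs$ref, pairs$alt)
  expect_setequal(unique(cl$sbs_category), SBS_CATEGORIES)
  expect_true(all(table(cl$sbs_category) == 2))
  # a change equals its reverse complement
  expect_identical(classify_sbs("A", "G"), classify_sbs("T", "C"))
  expect_equal(classify_sbs("G", "A")$ti_tv, "transition")
  expect_equal(classify_sbs("G", "T")$ti_tv, "transversion")
  expect_error(classify_sbs("N", "A"), "ACGT")
})

test_that("density arithmetic matches the per-10Mb definition", {
  expect_equal(mutation_density(0, 1e7), 0)
  expect_equal(mutation_density(10, 1e7), 10)
  expect_equal(round(mutation_density(17, 11449437), 2), 14.85)
  expect_error(mutation_density(5, 0), "mapped_length")
})

test_that("generation back-correction divides by the retained fraction", {
  expect_equal(correct_generation_density(1.25), 1.5)
  expect_equal(correct_generation_density(2, het_fraction = 0), 2)
  expect_equal(correct_generation_density(1, het_fraction = 1, loss = 1/4),
               4 / 3)
  expect_error(correct_generation_density(1, het_fraction = 2), "het_fraction")
})

test_that("spectrum table recovers multinomial proportions and flags empty groups", {
  probs <- c(0.3, 0.3, 0.1, 0.1, 0.1, 0.1)
  set.seed(15)
  cats <- sample(SBS_CATEGORIES, 5000, replace = TRUE, prob = probs)
  calls <- data.frame(sample = "m", chrom = "chr01", pos = seq_along(cats),
                      ref = "A", alt = "G", mtype = "SBS",
                      indel_len = 0L, sbs_category = cats,
                      stringsAsFactors = FALSE)
  st <- spectrum_table(calls, "g1")
  # each estimated proportion inside the binomial 99% CI
  for (k in seq_along(probs)) {
    ci <- qbinom(c(0.005, 0.995), 5000, probs[k]) / 5000
    expect_gte(st$proportions[k, 1], ci[1])
    expect_lte(st$proportions[k, 1], ci[2])
  }
  expect_equal(sum(st$proportions[, 1]), 1)
  expect_equal(unname(st$transition_share["g1"]),
               sum(st$proportions[SBS_TRANSITIONS, 1]))
  # all calls in one category
  mono <- calls[1:10, ]; mono$sbs_category <- "G/C>A/T"
  stm <- spectrum_table(mono, "g")
  expect_equal(unname(stm$proportions["G/C>A/T", "g"]), 1)
  expect_equal(unname(stm$transition_share["g"]), 1)
  # a group with only InDels is flagged and excluded
  mixed <- rbind(calls[1:5, ],
                 within(calls[6, ], { mtype <- "INS"; sbs_category <- NA }))
  expect_warning(st2 <- spectrum_table(mixed, c(rep("a", 5), "b")),
                 "zero SBS")
  expect_identical(st2$empty_groups, "b")
})

test_that("annotation partitions calls across the three context classes", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 2e5, n_regions = 40,
                    region_length_mean = 500, mutation_density = 2000,
                    seed = 19)
  sim <- simulate_mutation_experiment(cfg, n_controls = 2, n_mutants = 1)
  idx <- annotation_index_from_genome(sim$genome)
  calls <- annotate_calls(
    screen_mutations(sim$matrix, c("control_1", "control_2"), "mutant_1"),
    idx)
  expect_true(all(calls$context %in% c("exon", "intron", "intergenic")))
  expect_equal(sum(table(calls$context)), nrow(calls))
})

test_that("clean-data screen equals the injected truth and is depth-monotone", {
  cfg <- sim_config(n_chromosomes = 2, chrom_length = 2e6, n_regions = 200,
                    region_length_mean = 2000, mutation_density = 50,
                    depth_mean = 30, depth_dispersion = Inf,
                    genotype_error_rate = 0, seed = 23)
  sim <- simulate_mutation_experiment(cfg, n_controls = 4, n_mutants = 2)
  controls <- sprintf("control_%d", 1:4)
  key <- function(d) sort(paste(d$sample, d$chrom, d$pos, d$ref, d$alt))
  calls <- do.call(rbind, lapply(c("mutant_1", "mutant_2"), function(s)
    screen_mutations(sim$matrix, controls, s)))
  expect_identical(key(calls), key(sim$truth))
  # raising min_depth never increases the number of calls
  n_prev <- Inf
  for (d in c(5, 10, 20, 30, 40)) {
    n <- nrow(screen_mutations(sim$matrix, controls, "mutant_1",
                               min_depth = d))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("estimated density scales linearly with injected density", {
  base <- sim_config(n_chromosomes = 1, chrom_length = 5e6, n_regions = 300,
                     region_length_mean = 2000, mutation_density = 20,
                     depth_mean = 30, depth_dispersion = Inf,
                     genotype_error_rate = 0, seed = 31)
  double <- base; double$mutation_density <- 40
  n_of <- function(cfg) {
    sim <- simulate_mutation_experiment(cfg, n_controls = 3, n_mutants = 5)
    sum(vapply(sprintf("mutant_%d", 1:5), function(s)
      nrow(screen_mutations(sim$matrix, sprintf("control_%d", 1:3), s)),
      integer(1)))
  }
  n1 <- n_of(base); n2 <- n_of(double)
  lambda <- 20 * 300 * 2000 / 1e7 * 5          # expected count at base density
  # var(n2 - 2 n1) = 2 lambda + 4 lambda under the Poisson oracle
  expect_lt(abs(n2 - 2 * n1), 3 * sqrt(6 * lambda))
})
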