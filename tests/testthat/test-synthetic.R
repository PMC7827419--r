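# Synthetic GBS generator: genome layout, cross, meiosis, mutations,
# observations.

test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  bad_spec <- DEFAULT_SBS_SPECTRUM
  bad_spec[1] <- bad_spec[1] + 0.1
  expect_error(sim_config(sbs_spectrum = bad_spec), "sum to 1")
  expect_error(sim_config(indel_fraction = 1.2), "indel_fraction")
  expect_error(sim_config(xo_rate = -1), "xo_rate")
  expect_error(sim_config(mutation_density = -1), "mutation_density")
  # spectrum is reordered to canonical category order
  shuffled <- DEFAULT_SBS_SPECTRUM[c(3, 1, 2, 6, 4, 5)]
  expect_identical(names(sim_config(sbs_spectrum = shuffled)$sbs_spectrum),
                   SBS_CATEGORIES)
})

test_that("build_genome places disjoint in-bounds regions and is seed-stable", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 1e6, n_regions = 10,
                    region_length_mean = 144, seed = 3)
  set.seed(cfg$seed); g <- build_genome(cfg)
  r <- g$regions
  expect_equal(nrow(r), 10)
  expect_true(all(r$start >= 1 & r$end <= 1e6))
  expect_true(all(diff(r$start) > 0))
  expect_true(all(r$start[-1] > r$end[-nrow(r)]))    # disjoint
  expect_equal(mapped_length(g), sum(r$end - r$start + 1))
  # total length concentrates near n * mean
  expect_gt(mapped_length(g), 1000)
  expect_lt(mapped_length(g), 2000)

  set.seed(cfg$seed); g2 <- build_genome(cfg)
  expect_identical(g, g2)

  empty <- build_genome(sim_config(n_regions = 0))
  expect_equal(nrow(empty$regions), 0)
  expect_equal(mapped_length(empty), 0)
})

test_that("build_genome refuses region demand beyond chromosome capacity", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 2000, n_regions = 40,
                    region_length_mean = 144, seed = 1)
  set.seed(1)
  expect_error(build_genome(cfg), "exceeds capacity of chr01")
})

test_that("simulate_cross places divergent sites at snp_rate with valid alleles", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 1e6, n_regions = 10,
                    region_length_mean = 144, snp_rate = 0, seed = 5)
  set.seed(5); g <- build_genome(cfg)
  expect_equal(nrow(simulate_cross(g, cfg)), 0)

  cfg$snp_rate <- 1e-3
  # count over 200 draws is Poisson(200 * mapped * rate); check the 99%
  # interval of that oracle
  total <- 0L
  set.seed(11)
  for (i in 1:200) {
    cr <- simulate_cross(g, cfg)
    total <- total + nrow(cr)
    if (nrow(cr)) expect_true(all(cr$ref != cr$alt))
  }
  lambda <- 200 * mapped_length(g) * 1e-3
  expect_gte(total, qpois(0.005, lambda))
  expect_lte(total, qpois(0.995, lambda))
})

test_that("meiosis draws Poisson crossovers with sorted breakpoints", {
  cfg <- sim_config(n_chromosomes = 12, chrom_length = 1e6, n_regions = 12,
                    xo_rate = 0, seed = 2)
  set.seed(2); g <- build_genome(cfg)
  mei <- simulate_meiosis(g, cfg)
  expect_true(all(vapply(mei, function(m) length(m$breakpoints) == 0,
                         logical(1))))

  cfg$xo_rate <- 2
  set.seed(21)
  totals <- replicate(1000, {
    m <- simulate_meiosis(g, cfg)
    for (ch in m) expect_false(is.unsorted(ch$breakpoints, strictly = TRUE))
    sum(vapply(m, function(ch) length(ch$breakpoints), integer(1)))
  })
  # mean total crossovers ~ Poisson(24): 3 SE around 24
  se <- sqrt(24 / 1000)
  expect_lt(abs(mean(totals) - 24), 3 * se)
})

test_that("BC1 panel zygosity follows gamete phase and fair starting phase", {
  cfg <- sim_config(n_chromosomes = 2, chrom_length = 1e6, n_regions = 100,
                    snp_rate = 2e-3, xo_rate = 0, seed = 9)
  set.seed(9)
  g <- build_genome(cfg)
  cr <- simulate_cross(g, cfg)
  panel <- simulate_bc1_panel(g, cr, cfg, n_progeny = 60)
  # xo_rate 0: constant zygosity per chromosome in every progeny
  for (ch in unique(cr$chrom)) {
    idx <- which(cr$chrom == ch)
    expect_true(all(apply(panel$zygosity[idx, , drop = FALSE], 2,
                          function(col) length(unique(col)) == 1)))
  }
  # fair phase: per-progeny-chromosome HET indicator is Bernoulli(1/2);
  # 120 draws, binomial 99.9% interval
  het <- sum(vapply(unique(cr$chrom), function(ch) {
    idx <- which(cr$chrom == ch)[1]
    sum(panel$zygosity[idx, ] == "HET")
  }, numeric(1)))
  expect_gte(het, qbinom(0.0005, 120, 0.5))
  expect_lte(het, qbinom(0.9995, 120, 0.5))
  # crossovers strictly increasing within sample x chromosome
  cfg$xo_rate <- 2
  set.seed(10)
  panel2 <- simulate_bc1_panel(g, cr, cfg, n_progeny = 20)
  by <- split(panel2$crossovers$pos,
              paste(panel2$crossovers$sample, panel2$crossovers$chrom))
  for (p in by) expect_false(is.unsorted(p, strictly = TRUE))
})

test_that("inject_mutations hits the target density, spectrum and length rule", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 1e7, n_regions = 100,
                    region_length_mean = 5000, mutation_density = 0, seed = 4)
  set.seed(4); g <- build_genome(cfg)
  expect_equal(nrow(inject_mutations(g, cfg, c("m1", "m2"))), 0)

  # density 20/10 Mb over ~0.5 Mb mapped: expected ~1 per sample; mean
  # over 500 samples within 3 SE of the Poisson oracle
  cfg$mutation_density <- 20
  lambda <- cfg$mutation_density * mapped_length(g) / 1e7
  set.seed(41)
  tr <- inject_mutations(g, cfg, sprintf("s%03d", 1:500))
  expect_lt(abs(nrow(tr) / 500 - lambda), 3 * sqrt(lambda / 500))
  # every mutation lies inside a mapped region
  gr_reg <- GenomicRanges::GRanges(g$regions$chrom,
                                   IRanges::IRanges(g$regions$start,
                                                    g$regions$end))
  gr_mut <- GenomicRanges::GRanges(tr$chrom,
                                   IRanges::IRanges(tr$pos, tr$pos))
  expect_true(all(IRanges::overlapsAny(gr_mut, gr_reg)))
  # SBS alleles realize their recorded category
  sbs <- tr[tr$mtype == "SBS", ]
  expect_identical(classify_sbs(sbs$ref, sbs$alt)$sbs_category,
                   sbs$sbs_category)

  cfg$indel_fraction <- 1
  set.seed(42)
  tri <- inject_mutations(g, cfg, "only")
  expect_true(all(abs(nchar(tri$alt) - nchar(tri$ref)) %in% 1:2))
  expect_true(all(tri$mtype %in% c("INS", "DEL")))
})

test_that("observations reflect genotypes, overdispersion and read error", {
  sites <- data.frame(chrom = "chr01", pos = 1:2000,
                      ref = "A", alt = "G", stringsAsFactors = FALSE)
  f <- matrix(rep(c(0, 0.5), each = 1000), ncol = 1)
  cfg <- sim_config(depth_mean = 30, depth_dispersion = 5,
                    genotype_error_rate = 0)
  set.seed(8)
  gm <- simulate_observations(sites, f, "s1", cfg)
  hom <- !is.na(gm$dp[1:1000, 1])
  expect_true(all(gm$ad_alt[1:1000, 1][hom] == 0))        # error-free purity
  dp <- gm$dp[!is.na(gm$dp)]
  expect_gt(var(dp), mean(dp))                            # NB overdispersion

  # LLN at one deep site: donor fraction within [0.49, 0.51]
  cfg2 <- sim_config(depth_mean = 1e5, depth_dispersion = Inf,
                     genotype_error_rate = 0.01)
  set.seed(9)
  one <- simulate_observations(sites[1, ], matrix(0.5, 1, 1), "s1", cfg2)
  f_obs <- one$ad_alt[1, 1] / (one$ad_ref[1, 1] + one$ad_alt[1, 1])
  expect_gte(f_obs, 0.49); expect_lte(f_obs, 0.51)

  # zero depth is an absent cell
  cfg3 <- sim_config(depth_mean = 0.2, depth_dispersion = Inf)
  set.seed(10)
  sparse <- simulate_observations(sites, f, "s1", cfg3)
  expect_gt(sum(is.na(sparse$dp)), 0)
  expect_true(all(is.na(sparse$ad_ref[is.na(sparse$dp)])))
})

test_that("whole experiments are reproducible from their seed", {
  cfg <- sim_config(n_chromosomes = 2, chrom_length = 5e5, n_regions = 150,
                    snp_rate = 1e-3, mutation_density = 100, seed = 77)
  a <- simulate_mutation_experiment(cfg)
  b <- simulate_mutation_experiment(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$matrix, b$matrix)
  x <- simulate_backcross_experiment(cfg, n_progeny = 5)
  y <- simulate_backcross_experiment(cfg, n_progeny = 5)
  expect_identical(x$matrix, y$matrix)
  expect_identical(x$truth$crossovers, y$truth$crossovers)
})
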