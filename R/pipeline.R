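#' Simulate a complete dataset to disk
#'
#' Runs both synthetic experiments (mutagenesis panel and BC1 backcross
#' panel) and writes a self-contained dataset directory:
#'
#' * `mutscan/variants.vcf`, `regions.bed`, `genes.gff3`,
#'   `manifest.tsv`, `truth_mutations.tsv`
#' * `recomb/variants.vcf`, `manifest.tsv`, `truth_crossovers.tsv`,
#'   `truth_zygosity.tsv`
#' * `provenance.yaml` capturing the configuration, seeds, package
#'   version and per-file MD5 checksums.
#'
#' The two experiments use `config$seed` and `config$seed + 1`; a fixed
#' seed reproduces every file byte for byte.
#'
#' @param config A [sim_config()].
#' @param out Output directory.
#' @param n_controls,n_mutants,n_progeny Panel sizes.
#' @param force Overwrite an existing non-empty directory.
#' @return Invisibly, a list with the two simulation objects and `out`.
#' @export
run_simulate <- function(config, out, n_controls = 4, n_mutants = 3,
                         n_progeny = 20, force = FALSE) {
  config <- validate_sim_config(config)
  if (dir.exists(out) && length(dir(out)) && !force)
    stop("output directory ", out, " is non-empty; use force = TRUE")
  dir.create(file.path(out, "mutscan"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out, "recomb"), recursive = TRUE,
             showWarnings = FALSE)

  mut <- simulate_mutation_experiment(config, n_controls = n_controls,
                                      n_mutants = n_mutants)
  cfg2 <- config
  cfg2$seed <- config$seed + 1L
  bc <- simulate_backcross_experiment(cfg2, n_progeny = n_progeny)

  md <- file.path(out, "mutscan")
  write_vcf(mut$matrix, file.path(md, "variants.vcf"),
            contigs = mut$genome$chrom_lengths)
  write_regions_bed(mut$genome$regions, file.path(md, "regions.bed"))
  write_gene_models(mut$genome, file.path(md, "genes.gff3"))
  write_tsv(mut$manifest, file.path(md, "manifest.tsv"))
  write_tsv(mut$truth, file.path(md, "truth_mutations.tsv"))

  rd <- file.path(out, "recomb")
  write_vcf(bc$matrix, file.path(rd, "variants.vcf"),
            contigs = bc$genome$chrom_lengths)
  write_tsv(bc$manifest, file.path(rd, "manifest.tsv"))
  write_tsv(bc$truth$crossovers, file.path(rd, "truth_crossovers.tsv"))
  zyg <- data.frame(bc$cross[, c("chrom", "pos")], bc$truth$zygosity,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(zyg, file.path(rd, "truth_zygosity.tsv"))

  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  files <- files[!basename(files) == "provenance.yaml"]
  prov <- list(
    package = "irradgbs",
    version = as.character(utils::packageVersion("irradgbs")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = config$seed,
    panels = list(mutscan = list(n_controls = n_controls,
                                 n_mutants = n_mutants),
                  recomb = list(n_progeny = n_progeny)),
    config = config_as_list(config),
    md5 = as.list(tools::md5sum(files)))
  names(prov$md5) <- substring(names(prov$md5), nchar(out) + 2)
  yaml::write_yaml(prov, file.path(out, "provenance.yaml"))
  invisible(list(mutscan = mut, recomb = bc, out = out))
}

config_as_list <- function(config) {
  out <- unclass(config)
  out$sbs_spectrum <- as.list(out$sbs_spectrum)
  out
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Run the mutation screen stage on files
#'
#' Reads a variant table, sample manifest, mapped regions and gene
#' models; screens every mutant line against the control consensus;
#' annotates genomic context; and writes `calls.tsv`, `density.tsv` and
#' `spectrum.tsv` under `out`.
#'
#' @param vcf,manifest,regions_bed,gff Input file paths.  The manifest
#'   needs columns `sample`, `role` (`control`/`mutant`), `group`.
#' @param min_depth Minimum depth for both mutant and control records.
#' @param out Output directory (created if needed).
#' @return Invisibly, list with `calls`, `density`, `spectrum`.
#' @export
run_mutscan <- function(vcf, manifest, regions_bed, gff,
                        min_depth = 5, out = NULL) {
  gm <- read_vcf(vcf)
  man <- read_tsv(manifest)
  regions <- read_regions_bed(regions_bed)
  index <- read_annotation(gff)
  controls <- man$sample[man$role == "control"]
  mutants <- man$sample[man$role == "mutant"]
  if (!length(mutants)) stop("manifest lists no mutant samples")
  calls <- do.call(rbind, lapply(mutants, function(s)
    screen_mutations(gm, controls, s, min_depth = min_depth)))
  calls <- annotate_calls(calls, index)
  ml <- sum(regions$end - regions$start + 1)
  dens <- density_table(calls, ml, samples = mutants)
  dens$group <- man$group[match(dens$sample, man$sample)]
  spec <- spectrum_table(calls,
                         man$group[match(calls$sample, man$sample)])
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write_tsv(calls, file.path(out, "calls.tsv"))
    write_tsv(dens, file.path(out, "density.tsv"))
    sp <- data.frame(category = rownames(spec$counts), spec$counts,
                     check.names = FALSE)
    write_tsv(sp, file.path(out, "spectrum.tsv"))
  }
  invisible(list(calls = calls, density = dens, spectrum = spec))
}

#' Run the recombination stage on files
#'
#' Reads a variant table and manifest, selects markers through the
#' parental/F1 cascade, calls progeny zygosity, applies the singleton
#' exclusion, counts events, and writes `marker_map.tsv`,
#' `genotypes.tsv` (marker x line) and `counts.tsv` under `out`.
#'
#' @param vcf,manifest Input file paths; manifest roles must include
#'   `parentA`, `parentB`, `f1`, `progeny`.
#' @param recurrent Role of the recurrent parent (`"parentA"` or
#'   `"parentB"`).
#' @param min_depth_pool Pooled-depth floor for marker selection.
#' @param min_depth_line Per-line depth floor for zygosity calls.
#' @param out Output directory.
#' @return Invisibly, list with `markers`, `zygosity`, `counts`,
#'   `totals`.
#' @export
run_recomb <- function(vcf, manifest, recurrent = "parentA",
                       min_depth_pool = 10, min_depth_line = 5,
                       out = NULL) {
  gm <- read_vcf(vcf)
  man <- read_tsv(manifest)
  role_of <- function(r) man$sample[man$role == r]
  progeny <- role_of("progeny")
  if (!length(progeny))
    stop("manifest lists no progeny samples; nothing to count")
  markers <- select_markers(gm, role_of("parentA"), role_of("parentB"),
                            role_of("f1"), min_depth = min_depth_pool)
  z <- zygosity_matrix(gm, markers, progeny,
                       recurrent = if (recurrent == "parentA") "a" else "b",
                       min_depth = min_depth_line)
  counts <- count_panel(z)
  totals <- stats::aggregate(n_events ~ sample, counts, sum)
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write_tsv(markers, file.path(out, "marker_map.tsv"))
    write_tsv(data.frame(markers[, c("chrom", "pos")], z,
                         check.names = FALSE),
              file.path(out, "genotypes.tsv"))
    write_tsv(counts, file.path(out, "counts.tsv"))
    write_tsv(totals, file.path(out, "totals.tsv"))
  }
  invisible(list(markers = markers, zygosity = z, counts = counts,
                 totals = totals))
}

#' Summarize stage outputs into report tables
#'
#' Reads the TSV outputs of [run_mutscan()] and/or [run_recomb()] and
#' produces group-level summaries with test statistics; when the
#' simulator's truth table is supplied, also reports screen recall and
#' precision against it.
#'
#' @param mutscan_dir,recomb_dir Stage output directories (either may be
#'   `NULL`).
#' @param truth_mutations Optional path to a `truth_mutations.tsv`.
#' @return List with any of: `density_by_group`, `density_tests`,
#'   `spectrum_chisq`, `recomb_totals`, `recomb_by_group`,
#'   `recomb_tests`, `screen_recall`, `screen_precision`.
#' @export
run_report <- function(mutscan_dir = NULL, recomb_dir = NULL,
                       truth_mutations = NULL) {
  rep <- list()
  if (!is.null(mutscan_dir)) {
    dens <- read_tsv(file.path(mutscan_dir, "density.tsv"))
    calls <- read_tsv(file.path(mutscan_dir, "calls.tsv"))
    rep$density_by_group <- group_summary(dens$density, dens$group)
    if (length(unique(dens$group)) >= 2)
      rep$density_tests <- pairwise_ttests(dens$density, dens$group)
    spec <- read_tsv(file.path(mutscan_dir, "spectrum.tsv"))
    cnt <- as.matrix(spec[, -1, drop = FALSE])
    rownames(cnt) <- spec$category
    if (ncol(cnt) >= 2)
      rep$spectrum_chisq <- spectrum_chisq(cnt)
    if (!is.null(truth_mutations)) {
      truth <- read_tsv(truth_mutations)
      key <- function(d) paste(d$sample, d$chrom, d$pos, d$ref, d$alt)
      tp <- sum(key(calls) %in% key(truth))
      rep$screen_recall <- if (nrow(truth)) tp / nrow(truth) else NA_real_
      rep$screen_precision <- if (nrow(calls)) tp / nrow(calls) else NA_real_
    }
  }
  if (!is.null(recomb_dir)) {
    counts <- read_tsv(file.path(recomb_dir, "counts.tsv"))
    totals <- stats::aggregate(n_events ~ sample, counts, sum)
    rep$recomb_totals <- totals
    rep$recomb_by_group <- group_summary(totals$n_events,
                                         rep("progeny", nrow(totals)))
  }
  rep
}
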