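#' Per-site consensus allele of non-irradiated controls
#'
#' A site is assessable only when every control line covers it at
#' `min_depth` or more and all its reads carry one and the same allele;
#' controls that disagree with each other, show mixed reads, or fall
#' below the depth floor mark the site non-assessable (`NA`), and such
#' sites are excluded downstream.  Requiring the controls' own depth
#' removes residual heterozygosity and caller noise before background
#' subtraction.
#'
#' @param gm A [genotype_matrix()].
#' @param control_samples Character vector of control sample names
#'   (at least one; typically four).
#' @param min_depth Minimum control read depth per site (default 5).
#' @return Character vector over site rows: the consensus allele, or
#'   `NA` where the site is non-assessable.
#' @export
control_consensus <- function(gm, control_samples, min_depth = 5) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!length(control_samples))
    stop("no control samples given; the screen needs a non-irradiated background")
  j <- match(control_samples, gm$samples)
  if (anyNA(j))
    stop("control sample(s) absent from matrix: ",
         paste(control_samples[is.na(j)], collapse = ", "))
  dp <- gm$dp[, j, drop = FALSE]
  ar <- gm$ad_ref[, j, drop = FALSE]
  aa <- gm$ad_alt[, j, drop = FALSE]
  covered <- !is.na(dp) & dp >= min_depth & (ar + aa) > 0
  fixed_ref <- covered & aa == 0
  fixed_alt <- covered & ar == 0
  all_ref <- rowSums(fixed_ref) == length(j)
  all_alt <- rowSums(fixed_alt) == length(j)
  ifelse(all_ref, gm$sites$ref, ifelse(all_alt, gm$sites$alt, NA))
}

#' Screen induced mutations in one mutant line against control consensus
#'
#' Calls a mutation wherever the mutant line, covered at `min_depth` or
#' more, shows an allele different from the control consensus at
#' fraction `min_af` or above.  Induced mutations in these designs are
#' heterozygous, so a consensus-plus-new-allele site counts as one
#' mutation; new-allele fractions below `min_af` are treated as read
#' noise.  InDels are retained only when the net length difference
#' `|nchar(alt) - nchar(ref)|` is 1 or 2 bp; longer events (and
#' length-neutral multi-base changes) are outside what short-fragment
#' GBS can screen and are dropped.
#'
#' @param gm A [genotype_matrix()].
#' @param control_samples Control sample names.
#' @param mutant_sample One mutant sample name.
#' @param min_depth Minimum mutant depth (default 5); also applied to
#'   controls via [control_consensus()] unless `control_min_depth`
#'   overrides it.
#' @param min_af Minimum mutant-allele read fraction (default 0.25).
#' @param control_min_depth Depth floor for the controls (defaults to
#'   `min_depth`).
#' @return A `mutation_calls` data frame: `sample`, `chrom`, `pos`,
#'   `ref` (consensus allele), `alt` (mutant allele), `mtype`,
#'   `indel_len`, `sbs_category`, `ti_tv`.
#' @export
screen_mutations <- function(gm, control_samples, mutant_sample,
                             min_depth = 5, min_af = 0.25,
                             control_min_depth = min_depth) {
  stopifnot(inherits(gm, "genotype_matrix"), length(mutant_sample) == 1)
  jm <- match(mutant_sample, gm$samples)
  if (is.na(jm)) stop("mutant sample not in matrix: ", mutant_sample)
  cons <- control_consensus(gm, control_samples, control_min_depth)
  dp <- gm$dp[, jm]
  ar <- gm$ad_ref[, jm]
  aa <- gm$ad_alt[, jm]
  tot <- ar + aa
  ok <- !is.na(cons) & !is.na(dp) & dp >= min_depth & tot > 0
  # fraction of the allele NOT matching the consensus
  cons_is_ref <- cons == gm$sites$ref
  f_new <- ifelse(cons_is_ref, aa, ar) / tot
  hit <- which(ok & f_new >= min_af)
  if (!length(hit)) return(empty_mutation_calls())
  ref <- ifelse(cons_is_ref[hit], gm$sites$ref[hit], gm$sites$alt[hit])
  alt <- ifelse(cons_is_ref[hit], gm$sites$alt[hit], gm$sites$ref[hit])
  dlen <- abs(nchar(alt) - nchar(ref))
  is_sbs <- nchar(ref) == 1 & nchar(alt) == 1
  keep <- is_sbs | dlen %in% 1:2
  hit <- hit[keep]; ref <- ref[keep]; alt <- alt[keep]
  dlen <- dlen[keep]; is_sbs <- is_sbs[keep]
  if (!length(hit)) return(empty_mutation_calls())
  mtype <- ifelse(is_sbs, "SBS",
                  ifelse(nchar(alt) > nchar(ref), "INS", "DEL"))
  cat_lab <- rep(NA_character_, length(hit))
  titv <- rep(NA_character_, length(hit))
  if (any(is_sbs)) {
    cl <- classify_sbs(ref[is_sbs], alt[is_sbs])
    cat_lab[is_sbs] <- cl$sbs_category
    titv[is_sbs] <- cl$ti_tv
  }
  calls <- data.frame(sample = mutant_sample,
                      chrom = gm$sites$chrom[hit],
                      pos = gm$sites$pos[hit],
                      ref = ref, alt = alt, mtype = mtype,
                      indel_len = ifelse(is_sbs, 0L, as.integer(dlen)),
                      sbs_category = cat_lab, ti_tv = titv,
                      stringsAsFactors = FALSE)
  class(calls) <- c("mutation_calls", class(calls))
  calls
}

empty_mutation_calls <- function() {
  calls <- data.frame(sample = character(0), chrom = character(0),
                      pos = numeric(0), ref = character(0),
                      alt = character(0), mtype = character(0),
                      indel_len = integer(0), sbs_category = character(0),
                      ti_tv = character(0), stringsAsFactors = FALSE)
  class(calls) <- c("mutation_calls", class(calls))
  calls
}

#' Strand-collapsed classification of a single-base substitution
#'
#' Collapses the twelve ordered base changes into the six categories of
#' [SBS_CATEGORIES], so that a change and its reverse-strand
#' representation map to the same class (e.g. `A>G` and `T>C` are both
#' `A/T>G/C`).  The two categories `A/T>G/C` and `G/C>A/T` are
#' transitions; the other four are transversions.
#'
#' @param ref,alt Parallel vectors of single bases in `ACGT`,
#'   elementwise distinct.
#' @return Data frame with `sbs_category` and `ti_tv`.
#' @examples
#' classify_sbs(c("G", "A", "G"), c("A", "G", "T"))
#' @export
classify_sbs <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (length(ref) != length(alt))
    stop("ref and alt must have equal length")
  if (any(!ref %in% BASES) || any(!alt %in% BASES))
    stop("alleles must be single bases in ACGT")
  if (any(ref == alt)) stop("ref and alt must differ")
  flip <- ref %in% c("T", "C")
  r <- ifelse(flip, COMP[ref], ref)
  a <- ifelse(flip, COMP[alt], alt)
  category <- paste0(r, "/", COMP[r], ">", a, "/", COMP[a])
  data.frame(sbs_category = category,
             ti_tv = ifelse(category %in% SBS_TRANSITIONS,
                            "transition", "transversion"),
             stringsAsFactors = FALSE)
}

#' Mutation density per 10 Mb of mapped sequence
#'
#' @param n Number of mutations.
#' @param mapped_length Assessable mapped length in bp (the GBS-covered
#'   denominator, not the genome size).
#' @return Density in mutations per 10 Mb: `n / mapped_length * 1e7`.
#' @examples
#' mutation_density(17, 11449437)  # 14.85 per 10 Mb
#' @export
mutation_density <- function(n, mapped_length) {
  if (any(mapped_length <= 0)) stop("mapped_length must be positive")
  if (any(n < 0)) stop("n must be non-negative")
  n / mapped_length * 1e7
}

#' Back-correct an observed density for Mendelian segregation loss
#'
#' In a selfing series, a fraction of heterozygous induced mutations
#' segregates away between generations: if a fraction `het_fraction` of
#' surviving mutations is heterozygous and a fraction `loss` of those is
#' lost in the next generation, the earlier-generation density is the
#' observed one divided by `1 - het_fraction * loss`.  With the default
#' carrier composition after one selfing (1/3 homozygous, 2/3
#' heterozygous) and a quarter of heterozygous mutations lost, an
#' observed 1.25 mutations/10 Mb back-corrects to 1.5.
#'
#' @param d_obs Observed (later-generation) density.
#' @param het_fraction Fraction of mutations that are heterozygous
#'   (default 2/3).
#' @param loss Fraction of heterozygous mutations lost per generation
#'   (default 1/4).
#' @return Corrected (earlier-generation) density.
#' @examples
#' correct_generation_density(1.25)  # 1.5
#' @export
correct_generation_density <- function(d_obs, het_fraction = 2/3,
                                       loss = 1/4) {
  if (het_fraction < 0 || het_fraction > 1)
    stop("het_fraction must lie in [0, 1]")
  if (loss < 0 || loss >= 1) stop("loss must lie in [0, 1)")
  denom <- 1 - het_fraction * loss
  if (denom <= 0) stop("correction denominator must be positive")
  d_obs / denom
}

#' Substitution-spectrum table per group
#'
#' Counts SBS calls over the six strand-collapsed categories for each
#' group and derives within-group proportions and the transition share.
#' Groups contributing zero SBS calls are flagged and dropped from the
#' proportion table with a warning.
#'
#' @param calls A `mutation_calls` data frame (InDel rows are ignored).
#' @param group Group label per call row (recycled if length 1).
#' @return List of class `spectrum_table`: `counts` (6 x groups matrix),
#'   `proportions`, `transition_share` (named numeric), and
#'   `empty_groups`.
#' @export
spectrum_table <- function(calls, group) {
  stopifnot(is.data.frame(calls))
  if (length(group) == 1) group <- rep(group, nrow(calls))
  stopifnot(length(group) == nrow(calls))
  sbs <- calls$mtype == "SBS"
  if (!any(sbs)) stop("no SBS calls to tabulate")
  counts <- table(factor(calls$sbs_category[sbs], levels = SBS_CATEGORIES),
                  factor(group[sbs], levels = unique(group)))
  counts <- unclass(counts)
  totals <- colSums(counts)
  empty <- names(totals)[totals == 0]
  if (length(empty))
    warning("group(s) with zero SBS calls excluded from proportions: ",
            paste(empty, collapse = ", "))
  keep <- totals > 0
  props <- sweep(counts[, keep, drop = FALSE], 2, totals[keep], "/")
  structure(list(counts = counts,
                 proportions = props,
                 transition_share = colSums(props[SBS_TRANSITIONS, ,
                                                  drop = FALSE]),
                 empty_groups = empty),
            class = "spectrum_table")
}

#' @export
print.spectrum_table <- function(x, ...) {
  cat("<spectrum_table>\n")
  print(round(x$proportions, 3))
  cat("transition share:",
      paste(sprintf("%s=%.3f", names(x$transition_share),
                    x$transition_share), collapse = ", "), "\n")
  invisible(x)
}

#' Attach exon/intron/intergenic context to mutation calls
#'
#' @param calls A `mutation_calls` data frame.
#' @param index An `annotation_index` (see [read_annotation()]).
#' @return `calls` with a `context` column; every call gets exactly one
#'   class.
#' @export
annotate_calls <- function(calls, index) {
  calls$context <- classify_positions(index, calls$chrom, calls$pos)
  calls
}

#' Per-sample mutation density table
#'
#' @param calls A `mutation_calls` data frame (possibly several samples).
#' @param mapped_length Either a single mapped length in bp shared by all
#'   samples, or a named vector per sample.  Per-line denominators are
#'   the norm in real GBS, where each line covers its own region set.
#' @param samples Samples to report (defaults to those present in
#'   `calls`); include screened lines with zero calls explicitly.
#' @return Data frame `sample`, `n_mutations`, `mapped_length`,
#'   `density` (per 10 Mb).
#' @export
density_table <- function(calls, mapped_length,
                          samples = unique(calls$sample)) {
  n <- vapply(samples, function(s) sum(calls$sample == s), integer(1))
  ml <- if (is.null(names(mapped_length)))
    rep_len(mapped_length, length(samples))
  else {
    if (!all(samples %in% names(mapped_length)))
      stop("mapped_length missing for some samples")
    mapped_length[samples]
  }
  data.frame(sample = samples, n_mutations = as.integer(n),
             mapped_length = as.numeric(ml),
             density = mutation_density(n, ml),
             row.names = NULL, stringsAsFactors = FALSE)
}
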