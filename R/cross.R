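#' Simulate a biparental cross over mapped regions
#'
#' Places divergent sites between two fully homozygous inbred parents at
#' rate `snp_rate` per mapped bp, uniformly within mapped regions.  Parent
#' A (the recurrent parent in a backcross design) carries the reference
#' allele at every site; parent B (donor) the alternate; the F1 is
#' heterozygous everywhere the parents differ.
#'
#' @param genome A `sim_genome` from [build_genome()].
#' @param config A [sim_config()].
#' @return A `marker_truth` data frame: `chrom`, `pos`, `ref`, `alt`
#'   sorted by (chrom, pos); `ref` is parent A's allele, `alt` parent B's.
#' @export
simulate_cross <- function(genome, config) {
  stopifnot(inherits(genome, "sim_genome"))
  config <- validate_sim_config(config)
  reg <- genome$regions
  out <- data.frame(chrom = character(0), pos = numeric(0),
                    ref = character(0), alt = character(0),
                    stringsAsFactors = FALSE)
  if (nrow(reg) && config$snp_rate > 0) {
    len <- reg$end - reg$start + 1
    n <- stats::rbinom(nrow(reg), size = len, prob = config$snp_rate)
    keep <- which(n > 0)
    if (length(keep)) {
      pos <- unlist(lapply(keep, function(j) {
        reg$start[j] + sample.int(len[j], n[j]) - 1L
      }))
      chrom <- rep(reg$chrom[keep], n[keep])
      ref <- sample(BASES, length(pos), replace = TRUE)
      alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1L), "")
      out <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                        stringsAsFactors = FALSE)
      out <- out[order(out$chrom, out$pos), , drop = FALSE]
      rownames(out) <- NULL
    }
  }
  class(out) <- c("marker_truth", class(out))
  out
}

#' Simulate one meiosis of the F1
#'
#' Crossovers per chromosome are Poisson(`xo_rate`) with positions uniform
#' along the chromosome (no interference); the transmitted haplotype
#' starts in a fair-coin parental phase and switches phase at each
#' breakpoint.
#'
#' @param genome A `sim_genome`.
#' @param config A [sim_config()].
#' @return List with one element per chromosome, each a list of
#'   `breakpoints` (strictly increasing numeric) and `start_phase`
#'   (`"A"` or `"B"`).
#' @export
simulate_meiosis <- function(genome, config) {
  stopifnot(inherits(genome, "sim_genome"))
  config <- validate_sim_config(config)
  lens <- genome$chrom_lengths
  out <- lapply(seq_along(lens), function(i) {
    k <- stats::rpois(1L, config$xo_rate)
    bp <- sort(stats::runif(k, 0, lens[i]))
    list(breakpoints = bp,
         start_phase = if (stats::runif(1) < 0.5) "A" else "B")
  })
  names(out) <- names(lens)
  out
}

# Parental phase of a gamete at given positions on one chromosome.
gamete_phase <- function(meiosis_chrom, pos) {
  flips <- findInterval(pos, meiosis_chrom$breakpoints)
  start <- meiosis_chrom$start_phase
  other <- if (start == "A") "B" else "A"
  ifelse(flips %% 2 == 0, start, other)
}

#' Simulate a BC1 backcross panel with ground truth
#'
#' Each progeny is the union of one F1 gamete (with recorded crossovers)
#' and an intact recurrent-parent (parent A) haplotype.  At every marker
#' the progeny is heterozygous when the gamete carries the donor (parent
#' B) allele and recurrent-homozygous otherwise; donor-homozygous
#' genotypes cannot occur in a backcross.
#'
#' @param genome A `sim_genome`.
#' @param cross A `marker_truth` from [simulate_cross()].
#' @param config A [sim_config()].
#' @param n_progeny Number of BC1 progeny.
#' @return List of class `bc1_truth`: `zygosity` (character matrix,
#'   markers x progeny, values `"HOM"`/`"HET"`, rows aligned to `cross`),
#'   `crossovers` (data frame `sample`, `chrom`, `pos` with strictly
#'   increasing positions within a sample x chromosome), and `samples`.
#' @export
simulate_bc1_panel <- function(genome, cross, config, n_progeny) {
  stopifnot(inherits(genome, "sim_genome"), inherits(cross, "marker_truth"))
  config <- validate_sim_config(config)
  n_progeny <- as.integer(n_progeny)
  samples <- sprintf("progeny_%03d", seq_len(n_progeny))
  z <- matrix(NA_character_, nrow = nrow(cross), ncol = n_progeny,
              dimnames = list(NULL, samples))
  xo <- vector("list", n_progeny)
  by_chrom <- split(seq_len(nrow(cross)), cross$chrom)
  for (j in seq_len(n_progeny)) {
    mei <- simulate_meiosis(genome, config)
    for (ch in names(by_chrom)) {
      idx <- by_chrom[[ch]]
      ph <- gamete_phase(mei[[ch]], cross$pos[idx])
      z[idx, j] <- ifelse(ph == "B", "HET", "HOM")
    }
    nbp <- vapply(mei, function(m) length(m$breakpoints), integer(1))
    if (sum(nbp)) {
      xo[[j]] <- data.frame(sample = samples[j],
                            chrom = rep(names(mei), nbp),
                            pos = unlist(lapply(mei, `[[`, "breakpoints"),
                                         use.names = FALSE),
                            stringsAsFactors = FALSE)
    }
  }
  xo <- xo[!vapply(xo, is.null, logical(1))]
  crossovers <- if (length(xo)) do.call(rbind, xo) else
    data.frame(sample = character(0), chrom = character(0),
               pos = numeric(0), stringsAsFactors = FALSE)
  rownames(crossovers) <- NULL
  structure(list(zygosity = z, crossovers = crossovers, samples = samples),
            class = "bc1_truth")
}
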