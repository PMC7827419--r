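#' Build a synthetic reduced-representation genome
#'
#' Lays out non-overlapping mapped regions (the loci a GBS library would
#' cover) over a multi-chromosome genome, and a sparse set of gene models
#' (genes with exons) used for exon/intron/intergenic annotation.  Regions
#' are assigned to chromosomes with probability proportional to chromosome
#' length; lengths are Poisson around `region_length_mean` (floored at
#' 30 bp so a region can hold a marker) and placements are uniform subject
#' to disjointness.
#'
#' Coordinates are 1-based and inclusive throughout the package; BED
#' export/import converts to and from 0-based half-open.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_genome`: list with `chrom_lengths`
#'   (named numeric), `regions` and `genes`/`exons` data frames
#'   (`chrom`, `start`, `end`, plus `gene_id`).
#' @examples
#' g <- build_genome(sim_config(n_chromosomes = 1, chrom_length = 1e6,
#'                              n_regions = 10, seed = 7))
#' nrow(g$regions)
#' @export
build_genome <- function(config) {
  config <- validate_sim_config(config)
  lens <- chrom_lengths_of(config)
  chroms <- names(lens)

  regions <- empty_intervals()
  if (config$n_regions > 0) {
    idx <- sample.int(length(lens), config$n_regions, replace = TRUE,
                      prob = lens)
    rl <- pmax(30L, stats::rpois(config$n_regions, config$region_length_mean))
    pieces <- lapply(seq_along(lens), function(i) {
      li <- rl[idx == i]
      if (!length(li)) return(empty_intervals())
      place_disjoint(chroms[i], lens[i], li)
    })
    regions <- do.call(rbind, pieces)
  }

  # Gene models: ~30% of each chromosome in genes of mean 3 kb, three
  # exons per gene at fixed relative offsets.  Only the interval classes
  # matter downstream, not realism of gene structure.
  gene_pieces <- lapply(seq_along(lens), function(i) {
    k <- floor(0.3 * lens[i] / 3000)
    if (k < 1) return(NULL)
    gl <- pmax(300L, stats::rpois(k, 3000))
    g <- place_disjoint(chroms[i], lens[i], gl)
    g$gene_id <- sprintf("%s_g%04d", chroms[i], seq_len(nrow(g)))
    g
  })
  gene_pieces <- gene_pieces[!vapply(gene_pieces, is.null, logical(1))]
  if (length(gene_pieces)) {
    genes <- do.call(rbind, gene_pieces)
    exons <- gene_exons(genes)
  } else {
    genes <- cbind(empty_intervals(), gene_id = character(0))
    exons <- genes
  }

  structure(list(chrom_lengths = lens, regions = regions,
                 genes = genes, exons = exons),
            class = "sim_genome")
}

empty_intervals <- function() {
  data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
             stringsAsFactors = FALSE)
}

# Place k disjoint intervals of given lengths uniformly on [1, L]:
# draw the left-over gap budget as sorted uniforms, then stack lengths.
place_disjoint <- function(chrom, L, lengths) {
  free <- L - sum(lengths)
  if (free < 0)
    stop(sprintf("region demand (%d bp in %d regions) exceeds capacity of %s (%d bp)",
                 sum(lengths), length(lengths), chrom, as.integer(L)))
  u <- sort(stats::runif(length(lengths), 0, free))
  start <- floor(u) + cumsum(c(0, lengths[-length(lengths)])) + 1
  data.frame(chrom = chrom, start = start, end = start + lengths - 1,
             stringsAsFactors = FALSE)
}

# Three exons per gene at relative spans [0,.2], [.4,.6], [.8,1].
gene_exons <- function(genes) {
  rel <- rbind(c(0, 0.2), c(0.4, 0.6), c(0.8, 1))
  pieces <- lapply(seq_len(nrow(rel)), function(j) {
    w <- genes$end - genes$start
    data.frame(chrom = genes$chrom,
               start = genes$start + floor(w * rel[j, 1]),
               end = genes$start + floor(w * rel[j, 2]),
               gene_id = genes$gene_id,
               stringsAsFactors = FALSE)
  })
  ex <- do.call(rbind, pieces)
  ex[order(ex$chrom, ex$start), , drop = FALSE]
}

#' Total mapped length of a synthetic genome
#'
#' @param genome A `sim_genome`.
#' @return Sum of mapped-region lengths in bp.
#' @export
mapped_length <- function(genome) {
  stopifnot(inherits(genome, "sim_genome"))
  if (!nrow(genome$regions)) return(0)
  sum(genome$regions$end - genome$regions$start + 1)
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("<sim_genome> %d chromosomes (%s bp), %d mapped regions (%s bp, %.2f%% of genome), %d genes\n",
              length(x$chrom_lengths),
              format(sum(x$chrom_lengths), big.mark = ","),
              nrow(x$regions),
              format(mapped_length(x), big.mark = ","),
              100 * mapped_length(x) / sum(x$chrom_lengths),
              nrow(x$genes)))
  invisible(x)
}
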