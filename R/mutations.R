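#' Inject induced mutations into mutant samples
#'
#' Draws, per mutant sample, Poisson(`mutation_density` x mapped length /
#' 1e7) induced mutations placed uniformly over mapped regions (mutations
#' outside mapped regions are invisible to GBS and are not generated).
#' Each mutation is a 1-2 bp insertion or deletion with probability
#' `indel_fraction`, otherwise a single-base substitution whose
#' strand-collapsed category is drawn from `sbs_spectrum`.  Control
#' samples receive no mutations.  Positions are drawn without replacement
#' across the whole panel, so every mutated site is unique to one line
#' (recurrent hits are vanishingly rare at these densities).
#'
#' @param genome A `sim_genome`.
#' @param config A [sim_config()].
#' @param samples Character vector of mutant sample names.
#' @return A `mutation_truth` data frame: `sample`, `chrom`, `pos`,
#'   `ref`, `alt`, `mtype` (`SBS`/`INS`/`DEL`), `indel_len` (0 for SBS),
#'   `sbs_category` (`NA` for InDels).
#' @export
inject_mutations <- function(genome, config, samples) {
  stopifnot(inherits(genome, "sim_genome"))
  config <- validate_sim_config(config)
  ml <- mapped_length(genome)
  n_per <- stats::rpois(length(samples),
                        config$mutation_density * ml / 1e7)
  all_loc <- sample_mapped_positions(genome, sum(n_per))
  loc_of <- split(seq_len(sum(n_per)), rep(seq_along(samples), n_per))
  out <- lapply(seq_along(samples), function(si) {
    s <- samples[si]
    n <- n_per[si]
    if (n == 0) return(NULL)
    loc <- list(chrom = all_loc$chrom[loc_of[[as.character(si)]]],
                pos = all_loc$pos[loc_of[[as.character(si)]]])
    is_indel <- stats::runif(n) < config$indel_fraction
    ref <- alt <- character(n)
    mtype <- rep("SBS", n)
    indel_len <- integer(n)
    cat_lab <- rep(NA_character_, n)
    if (any(!is_indel)) {
      k <- sum(!is_indel)
      cats <- sample(SBS_CATEGORIES, k, replace = TRUE,
                     prob = config$sbs_spectrum)
      ra <- sbs_alleles(cats)
      ref[!is_indel] <- ra$ref
      alt[!is_indel] <- ra$alt
      cat_lab[!is_indel] <- cats
    }
    if (any(is_indel)) {
      k <- sum(is_indel)
      len <- sample(1:2, k, replace = TRUE)
      ins <- stats::runif(k) < 0.5
      anchor <- sample(BASES, k, replace = TRUE)
      extra <- vapply(len, function(l)
        paste(sample(BASES, l, replace = TRUE), collapse = ""), "")
      ref[is_indel] <- ifelse(ins, anchor, paste0(anchor, extra))
      alt[is_indel] <- ifelse(ins, paste0(anchor, extra), anchor)
      mtype[is_indel] <- ifelse(ins, "INS", "DEL")
      indel_len[is_indel] <- len
    }
    data.frame(sample = s, chrom = loc$chrom, pos = loc$pos,
               ref = ref, alt = alt, mtype = mtype,
               indel_len = indel_len, sbs_category = cat_lab,
               stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(sample = character(0), chrom = character(0), pos = numeric(0),
               ref = character(0), alt = character(0), mtype = character(0),
               indel_len = integer(0), sbs_category = character(0),
               stringsAsFactors = FALSE)
  res <- res[order(res$sample, res$chrom, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("mutation_truth", class(res))
  res
}

# n unique positions uniform over the mapped-region bp of the genome.
sample_mapped_positions <- function(genome, n) {
  if (n == 0) return(list(chrom = character(0), pos = numeric(0)))
  reg <- genome$regions
  if (!nrow(reg)) stop("genome has no mapped regions to mutate")
  len <- reg$end - reg$start + 1
  total <- sum(len)
  if (n > total) stop("more mutations requested than mapped bases")
  offs <- cumsum(c(0, len[-length(len)]))
  # rejection-free: sample global offsets without replacement
  gpos <- sample(total, n)
  ridx <- findInterval(gpos - 1, cumsum(len), left.open = FALSE) + 1L
  # findInterval on cumsum: offset within region
  within <- gpos - offs[ridx]
  list(chrom = reg$chrom[ridx], pos = reg$start[ridx] + within - 1)
}

# ref/alt pair realizing a strand-collapsed category, strand chosen fairly.
sbs_alleles <- function(categories) {
  left <- substr(categories, 1, 3)   # "A/T" or "G/C"
  l1 <- substr(left, 1, 1); l2 <- substr(left, 3, 3)
  r1 <- substr(categories, 5, 5); r2 <- substr(categories, 7, 7)
  first <- stats::runif(length(categories)) < 0.5
  list(ref = ifelse(first, l1, l2), alt = ifelse(first, r1, r2))
}
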