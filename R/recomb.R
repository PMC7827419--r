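#' Select informative SNP markers via the parental/F1 quality cascade
#'
#' Keeps biallelic sites where (i) each pooled parent reaches
#' `min_depth` and is fixed for one allele (every pooled read carries
#' it), (ii) the two parents are fixed for different alleles, and (iii)
#' the pooled F1 reaches `min_depth` with an alternate-allele read
#' fraction inside the closed interval `f1_af_bounds`.  Pools are formed
#' by summing allele depths over the listed samples (absent cells
#' contribute nothing).
#'
#' @param gm A [genotype_matrix()].
#' @param parent_a,parent_b,f1 Non-empty character vectors of sample
#'   names forming each pool; `parent_a` is the recurrent parent of the
#'   backcross.
#' @param min_depth Minimum pooled depth (default 10).
#' @param f1_af_bounds Closed allele-frequency interval the F1 pool must
#'   satisfy (default `c(0.25, 0.75)`).
#' @return A `marker_set` data frame: `site` (row index into `gm`),
#'   `chrom`, `pos`, `ref`, `alt`, `allele_a`, `allele_b`.
#' @export
select_markers <- function(gm, parent_a, parent_b, f1,
                           min_depth = 10, f1_af_bounds = c(0.25, 0.75)) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!length(parent_a) || !length(parent_b) || !length(f1))
    stop("parental and F1 pools must be non-empty")
  pool <- function(samps) {
    j <- match(samps, gm$samples)
    if (anyNA(j))
      stop("pool sample(s) absent from matrix: ",
           paste(samps[is.na(j)], collapse = ", "))
    list(dp = rowSums(gm$dp[, j, drop = FALSE], na.rm = TRUE),
         ar = rowSums(gm$ad_ref[, j, drop = FALSE], na.rm = TRUE),
         aa = rowSums(gm$ad_alt[, j, drop = FALSE], na.rm = TRUE))
  }
  a <- pool(parent_a); b <- pool(parent_b); h <- pool(f1)
  a_ref <- a$aa == 0 & a$ar > 0
  a_alt <- a$ar == 0 & a$aa > 0
  b_ref <- b$aa == 0 & b$ar > 0
  b_alt <- b$ar == 0 & b$aa > 0
  f1_tot <- h$ar + h$aa
  f1_af <- ifelse(f1_tot > 0, h$aa / f1_tot, NA)
  keep <- a$dp >= min_depth & b$dp >= min_depth & h$dp >= min_depth &
    ((a_ref & b_alt) | (a_alt & b_ref)) &
    !is.na(f1_af) & f1_af >= f1_af_bounds[1] & f1_af <= f1_af_bounds[2]
  idx <- which(keep)
  out <- data.frame(site = idx,
                    chrom = gm$sites$chrom[idx],
                    pos = gm$sites$pos[idx],
                    ref = gm$sites$ref[idx],
                    alt = gm$sites$alt[idx],
                    allele_a = ifelse(a_ref[idx], gm$sites$ref[idx],
                                      gm$sites$alt[idx]),
                    allele_b = ifelse(a_ref[idx], gm$sites$alt[idx],
                                      gm$sites$ref[idx]),
                    stringsAsFactors = FALSE)
  class(out) <- c("marker_set", class(out))
  out
}

#' Call marker zygosity in a backcross line
#'
#' BC1 genotypes are recurrent-homozygous or heterozygous only, so the
#' call is made on the recurrent-parent allele fraction: depth below
#' `min_depth` is `MISSING`; a fraction of exactly 1 is `HOM`; a
#' fraction inside the closed interval `het_bounds` is `HET`; anything
#' else (including fractions in (0.75, 1)) is `MISSING` rather than
#' forced into a class.
#'
#' @param recurrent_depth,donor_depth Read counts of the recurrent and
#'   donor alleles (vectors).
#' @param depth Total site depth (defaults to the allele-depth sum).
#' @param min_depth Minimum depth to call (default 5).
#' @param het_bounds Closed recurrent-allele-fraction interval for `HET`
#'   (default `c(0.25, 0.75)`).
#' @return Character vector in `{HOM, HET, MISSING}`.
#' @examples
#' call_zygosity(c(8, 5, 9), c(0, 5, 1))
#' @export
call_zygosity <- function(recurrent_depth, donor_depth,
                          depth = recurrent_depth + donor_depth,
                          min_depth = 5, het_bounds = c(0.25, 0.75)) {
  tot <- recurrent_depth + donor_depth
  f <- ifelse(tot > 0, recurrent_depth / tot, NA)
  out <- rep("MISSING", length(f))
  callable <- !is.na(depth) & depth >= min_depth & !is.na(f)
  out[callable & f == 1] <- "HOM"
  out[callable & f >= het_bounds[1] & f <= het_bounds[2]] <- "HET"
  out
}

#' Zygosity vectors for progeny lines at selected markers
#'
#' Orients each marker's allele depths to the recurrent parent (erroring
#' if the recurrent allele is neither of a marker's two alleles) and
#' calls zygosity per progeny line with [call_zygosity()].
#'
#' @param gm A [genotype_matrix()].
#' @param markers A `marker_set` from [select_markers()].
#' @param progeny Character vector of progeny sample names.
#' @param recurrent Which parent is recurrent: `"a"` (default) or `"b"`.
#' @inheritParams call_zygosity
#' @return Character matrix (markers x progeny) of
#'   `HOM`/`HET`/`MISSING`, with marker metadata retained in
#'   `attr(, "markers")`.
#' @export
zygosity_matrix <- function(gm, markers, progeny, recurrent = "a",
                            min_depth = 5, het_bounds = c(0.25, 0.75)) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(markers, "marker_set"))
  rec_allele <- if (recurrent == "a") markers$allele_a else markers$allele_b
  rec_is_ref <- rec_allele == markers$ref
  rec_is_alt <- rec_allele == markers$alt
  if (any(!rec_is_ref & !rec_is_alt))
    stop("recurrent allele is neither marker allele at ",
         markers$chrom[which(!rec_is_ref & !rec_is_alt)[1]], ":",
         markers$pos[which(!rec_is_ref & !rec_is_alt)[1]])
  j <- match(progeny, gm$samples)
  if (anyNA(j))
    stop("progeny sample(s) absent from matrix: ",
         paste(progeny[is.na(j)], collapse = ", "))
  i <- markers$site
  z <- matrix(NA_character_, length(i), length(j),
              dimnames = list(NULL, progeny))
  for (k in seq_along(j)) {
    ar <- gm$ad_ref[i, j[k]]
    aa <- gm$ad_alt[i, j[k]]
    rec <- ifelse(rec_is_ref, ar, aa)
    don <- ifelse(rec_is_ref, aa, ar)
    z[, k] <- call_zygosity(rec, don, depth = gm$dp[i, j[k]],
                            min_depth = min_depth,
                            het_bounds = het_bounds)
  }
  z[is.na(z)] <- "MISSING"
  attr(z, "markers") <- markers
  z
}

#' Exclude singleton zygosity calls
#'
#' A lone marker whose two flanking informative calls both differ from
#' it is far more likely a genotyping error than a double crossover, and
#' is removed.  The pass is single and simultaneous: exclusion flags are
#' computed on the unmodified input, terminal calls are never removed,
#' and the filter is deliberately not iterated (repeated passes could
#' erode genuine short double-crossover tracts).  `MISSING` calls must
#' already have been dropped so that adjacency is over informative calls.
#'
#' @param calls Character vector of `HOM`/`HET` calls along one
#'   chromosome.
#' @return The filtered vector, with the number of removed calls in
#'   `attr(, "n_excluded")`.
#' @examples
#' singleton_filter(c("HET", "HET", "HOM", "HET", "HET"))
#' @export
singleton_filter <- function(calls) {
  n <- length(calls)
  if (any(!calls %in% c("HOM", "HET")))
    stop("singleton_filter expects only HOM/HET calls (drop MISSING first)")
  if (n < 3) {
    attr(calls, "n_excluded") <- 0L
    return(calls)
  }
  mid <- 2:(n - 1)
  flag <- c(FALSE,
            calls[mid] != calls[mid - 1] & calls[mid] != calls[mid + 1],
            FALSE)
  out <- calls[!flag]
  attr(out, "n_excluded") <- as.integer(sum(flag))
  out
}

#' Count recombination events along one chromosome
#'
#' One event per adjacent pair of informative markers with different
#' zygosity.  The count is between 0 and `length - 1`, and its parity
#' equals whether the first and last calls differ.
#'
#' @param calls Character vector of `HOM`/`HET` calls (already filtered).
#' @return Integer event count.
#' @examples
#' count_recombination(c("HET", "HET", "HOM", "HOM"))
#' @export
count_recombination <- function(calls) {
  calls <- as.character(calls)
  if (!length(calls)) {
    warning("empty zygosity vector; counting 0 events")
    return(0L)
  }
  if (any(!calls %in% c("HOM", "HET")))
    stop("count_recombination expects only HOM/HET calls")
  if (length(calls) == 1) return(0L)
  sum(calls[-1] != calls[-length(calls)])
}

#' Summarize recombination for one line over its chromosomes
#'
#' Drops `MISSING` calls, applies the singleton exclusion per
#' chromosome, counts zygosity switches, and sums.  No event spans a
#' chromosome boundary.
#'
#' @param vectors Named list (one element per chromosome, names unique)
#'   of `HOM`/`HET`/`MISSING` call vectors.
#' @param sample Optional sample label for the output.
#' @return A `recombination_count` list: `sample`, `per_chromosome`
#'   (data frame `chrom`, `n_events`, `n_markers_used`,
#'   `n_markers_excluded_singleton`), `total`.
#' @export
summarize_line <- function(vectors, sample = NA_character_) {
  if (is.null(names(vectors)) || anyDuplicated(names(vectors)))
    stop("vectors must be uniquely named by chromosome")
  rows <- lapply(names(vectors), function(ch) {
    v <- vectors[[ch]]
    v <- v[v != "MISSING"]
    fv <- singleton_filter(v)
    n_ev <- if (length(fv)) suppressWarnings(count_recombination(fv)) else 0L
    data.frame(chrom = ch, n_events = n_ev,
               n_markers_used = length(fv),
               n_markers_excluded_singleton = attr(fv, "n_excluded"),
               stringsAsFactors = FALSE)
  })
  per_chrom <- do.call(rbind, rows)
  structure(list(sample = sample, per_chromosome = per_chrom,
                 total = sum(per_chrom$n_events)),
            class = "recombination_count")
}

#' @export
print.recombination_count <- function(x, ...) {
  cat(sprintf("<recombination_count> %s: %d events over %d chromosomes (%d markers used, %d singletons excluded)\n",
              x$sample, x$total, nrow(x$per_chromosome),
              sum(x$per_chromosome$n_markers_used),
              sum(x$per_chromosome$n_markers_excluded_singleton)))
  invisible(x)
}

#' Recombination counts for a whole progeny panel
#'
#' Convenience wrapper: splits a [zygosity_matrix()] by chromosome and
#' applies [summarize_line()] to every progeny column.
#'
#' @param z A zygosity matrix from [zygosity_matrix()].
#' @return Data frame `sample`, `chrom`, `n_events`, `n_markers_used`,
#'   `n_markers_excluded_singleton`; totals per line are the sums over
#'   chromosomes.
#' @export
count_panel <- function(z) {
  markers <- attr(z, "markers")
  if (is.null(markers)) stop("z must carry its marker_set attribute")
  by_chrom <- split(seq_len(nrow(markers)), markers$chrom)
  out <- lapply(colnames(z), function(s) {
    vecs <- lapply(by_chrom, function(idx) z[idx, s])
    rc <- summarize_line(vecs, sample = s)
    cbind(sample = s, rc$per_chromosome, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Average marker density per chromosome
#'
#' @param n_markers Markers genotyped in a line.
#' @param n_chromosomes Number of chromosomes (default 12).
#' @return Markers per chromosome.
#' @examples
#' markers_per_chromosome(1554)  # 129.5
#' @export
markers_per_chromosome <- function(n_markers, n_chromosomes = 12) {
  if (any(n_chromosomes < 1)) stop("n_chromosomes must be positive")
  n_markers / n_chromosomes
}
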