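#' In-memory genotype matrix
#'
#' The package's uniform variant/genotype model: a table of biallelic
#' sites (multi-allelic VCF records are split on read and merged on
#' write) crossed with samples, holding per-cell total depth (`DP`) and
#' per-allele depths (`AD`).  An `NA` depth marks an absent cell (site
#' not covered / genotype missing in that sample), which is distinct
#' from a zero-depth record.
#'
#' @param sites Data frame with `chrom`, `pos` (1-based), `ref`, `alt`;
#'   sorted by (chrom, pos); ties in `pos` are allowed only for split
#'   multi-allelic records, which must share `ref` and differ in `alt`.
#' @param samples Character vector of sample names.
#' @param dp,ad_ref,ad_alt Numeric matrices, sites x samples.
#' @return Object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, samples, dp, ad_ref, ad_alt) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  n <- nrow(sites); m <- length(samples)
  for (mt in list(dp, ad_ref, ad_alt))
    stopifnot(is.matrix(mt), nrow(mt) == n, ncol(mt) == m)
  viol <- site_order_violation(sites)
  if (!is.na(viol))
    stop("sites out of order: first violation at ", viol)
  bad <- which(!is.na(dp) & (ad_ref + ad_alt > dp))
  if (length(bad))
    stop("allele depths exceed total depth at site row ",
         ((bad[1] - 1) %% n) + 1)
  if (any(sites$ref == sites$alt)) stop("ref and alt must differ")
  if (any(sites$pos < 1)) stop("positions are 1-based and must be >= 1")
  dimnames(dp) <- dimnames(ad_ref) <- dimnames(ad_alt) <-
    list(NULL, samples)
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  rownames(sites) <- NULL
  structure(list(sites = sites,
                 samples = as.character(samples),
                 dp = dp, ad_ref = ad_ref, ad_alt = ad_alt),
            class = "genotype_matrix")
}

# NA if sorted; otherwise a human-readable locator of the first violation.
site_order_violation <- function(sites) {
  if (nrow(sites) < 2) return(NA_character_)
  for (i in 2:nrow(sites)) {
    if (sites$chrom[i] == sites$chrom[i - 1]) {
      if (sites$pos[i] < sites$pos[i - 1])
        return(sprintf("%s:%d before %s:%d", sites$chrom[i], sites$pos[i],
                       sites$chrom[i - 1], sites$pos[i - 1]))
      if (sites$pos[i] == sites$pos[i - 1] &&
          (sites$ref[i] != sites$ref[i - 1] ||
           sites$alt[i] == sites$alt[i - 1]))
        return(sprintf("duplicate site %s:%d", sites$chrom[i], sites$pos[i]))
    }
  }
  NA_character_
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d sites x %d samples (%d absent cells)\n",
              nrow(x$sites), length(x$samples), sum(is.na(x$dp))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(nrow(x$sites), length(x$samples))

#' Subset a genotype matrix
#'
#' @param gm A `genotype_matrix`.
#' @param sites Integer/logical index over site rows (optional).
#' @param samples Character names or index over samples (optional).
#' @return A `genotype_matrix`.
#' @export
gm_subset <- function(gm, sites = NULL, samples = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  si <- if (is.null(sites)) seq_len(nrow(gm$sites)) else sites
  if (is.null(samples)) {
    sj <- seq_along(gm$samples)
  } else if (is.character(samples)) {
    sj <- match(samples, gm$samples)
    if (anyNA(sj))
      stop("unknown sample(s): ",
           paste(samples[is.na(sj)], collapse = ", "))
  } else sj <- samples
  genotype_matrix(gm$sites[si, , drop = FALSE], gm$samples[sj],
                  gm$dp[si, sj, drop = FALSE],
                  gm$ad_ref[si, sj, drop = FALSE],
                  gm$ad_alt[si, sj, drop = FALSE])
}

#' Flatten a genotype matrix to one row per covered sample-site record
#'
#' @param x A `genotype_matrix`.
#' @param ... Unused.
#' @return Data frame with `chrom`, `pos`, `ref`, `alt`, `sample`,
#'   `depth`, `ad_ref`, `ad_alt`; absent cells are omitted.
#' @export
as.data.frame.genotype_matrix <- function(x, ...) {
  idx <- which(!is.na(x$dp), arr.ind = TRUE)
  out <- data.frame(x$sites[idx[, 1], , drop = FALSE],
                    sample = x$samples[idx[, 2]],
                    depth = x$dp[idx],
                    ad_ref = x$ad_ref[idx],
                    ad_alt = x$ad_alt[idx],
                    stringsAsFactors = FALSE)
  out <- out[order(idx[, 2], idx[, 1]), , drop = FALSE]
  rownames(out) <- NULL
  out
}
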