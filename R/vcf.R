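#' Read a minimal VCF 4.2 into a genotype matrix
#'
#' Honors `CHROM`, `POS`, `REF`, `ALT` and the per-sample `FORMAT` keys
#' `DP` and `AD`; everything else passes through unparsed.  Multi-allelic
#' records are split into biallelic records sharing the position, each
#' keeping the shared reference allele depth.  A missing genotype
#' (`.` or `./.`, or missing `DP`) becomes an absent cell, not a
#' zero-depth record.
#'
#' @param path Path to an uncompressed VCF file.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "##fileformat=VCF"))
    stop("malformed VCF header: missing ##fileformat (line 1)")
  hdr <- which(startsWith(lines, "#CHROM"))
  if (!length(hdr)) stop("malformed VCF header: no #CHROM line")
  hdr <- hdr[1]
  cols <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]]
  if (length(cols) < 10)
    stop("VCF has no sample columns (line ", hdr, ")")
  samples <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  if (!length(body)) {
    z <- matrix(numeric(0), 0, length(samples))
    return(genotype_matrix(
      data.frame(chrom = character(0), pos = numeric(0),
                 ref = character(0), alt = character(0)),
      samples, z, z, z))
  }
  recs <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(recs)
  if (any(nf != length(cols)))
    stop("wrong field count at line ", hdr + which(nf != length(cols))[1])
  mat <- matrix(unlist(recs), ncol = length(cols), byrow = TRUE)
  chrom <- mat[, 1]; pos <- as.numeric(mat[, 2])
  ref <- mat[, 4]; alt_field <- mat[, 5]
  fmt <- strsplit(mat[, 9], ":", fixed = TRUE)

  n_in <- nrow(mat); m <- length(samples)
  alts <- strsplit(alt_field, ",", fixed = TRUE)
  nalt <- lengths(alts)
  out_row <- rep(seq_len(n_in), nalt)          # input record per output row
  alt_idx <- unlist(lapply(nalt, seq_len))     # which ALT within record
  n_out <- length(out_row)
  dp <- ad_ref <- ad_alt <- matrix(NA_real_, n_out, m)

  for (i in seq_len(n_in)) {
    fk <- fmt[[i]]
    i_dp <- match("DP", fk); i_ad <- match("AD", fk)
    if (is.na(i_dp) || is.na(i_ad))
      stop("FORMAT lacks DP or AD at line ", hdr + i)
    rows <- which(out_row == i)
    cells <- strsplit(mat[i, -(1:9)], ":", fixed = TRUE)
    for (j in seq_len(m)) {
      cl <- cells[[j]]
      if (identical(cl[1], ".") || identical(cl[1], "./.") ||
          length(cl) < max(i_dp, i_ad))
        next
      dpv <- cl[i_dp]; adv <- cl[i_ad]
      if (dpv == "." || adv == ".") next
      ad <- suppressWarnings(as.numeric(strsplit(adv, ",", fixed = TRUE)[[1]]))
      dpn <- suppressWarnings(as.numeric(dpv))
      if (anyNA(ad) || is.na(dpn) || length(ad) != nalt[i] + 1)
        stop("malformed AD/DP at line ", hdr + i)
      if (sum(ad) > dpn)
        stop("AD exceeds DP at line ", hdr + i)
      for (k in seq_len(nalt[i])) {
        r <- rows[k]
        dp[r, j] <- dpn
        ad_ref[r, j] <- ad[1]
        ad_alt[r, j] <- ad[1 + k]
      }
    }
  }
  sites <- data.frame(chrom = chrom[out_row], pos = pos[out_row],
                      ref = ref[out_row],
                      alt = unlist(alts),
                      stringsAsFactors = FALSE)
  ord <- order(sites$chrom, sites$pos, sites$alt)
  genotype_matrix(sites[ord, , drop = FALSE], samples,
                  dp[ord, , drop = FALSE], ad_ref[ord, , drop = FALSE],
                  ad_alt[ord, , drop = FALSE])
}

#' Write a genotype matrix as minimal VCF 4.2
#'
#' Inverse of [read_vcf()]: biallelic records sharing (chrom, pos, ref)
#' are merged back into one multi-allelic record with a comma-joined
#' `ALT` and a combined `AD`.  Refuses unsorted sites, naming the first
#' violation.  Output is byte-stable for identical input.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output file path.
#' @param contigs Optional named vector of chromosome lengths for
#'   `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, contigs = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  viol <- site_order_violation(gm$sites)
  if (!is.na(viol)) stop("refusing to write unsorted sites: ", viol)
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(contigs))
             sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                     as.integer(contigs)),
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", gm$samples), collapse = "\t"))
  n <- nrow(gm$sites)
  if (n == 0) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  key <- paste(gm$sites$chrom, gm$sites$pos, gm$sites$ref, sep = "\r")
  grp <- match(key, unique(key))
  rows_of <- split(seq_len(n), grp)
  lines <- vapply(rows_of, function(rows) {
    s <- gm$sites[rows, , drop = FALSE]
    cells <- vapply(seq_along(gm$samples), function(j) {
      dpv <- gm$dp[rows, j]
      if (all(is.na(dpv))) return("./.")
      ads <- c(gm$ad_ref[rows[1], j], gm$ad_alt[rows, j])
      sprintf("%d:%s", as.integer(dpv[1]),
              paste(as.integer(ads), collapse = ","))
    }, "")
    paste(c(s$chrom[1], format(s$pos[1], scientific = FALSE), ".",
            s$ref[1], paste(s$alt, collapse = ","), ".", ".", ".",
            "DP:AD", cells), collapse = "\t")
  }, "")
  writeLines(c(hdr, lines), path)
  invisible(path)
}
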