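#' Read and write mapped-region BED files
#'
#' Mapped regions are kept 1-based inclusive in memory and exchanged as
#' BED3 (0-based, half-open) on disk via `rtracklayer`.
#'
#' @param path BED file path.
#' @return `read_regions_bed()`: data frame `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @export
read_regions_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' @rdname read_regions_bed
#' @param regions Data frame `chrom`, `start`, `end` (1-based inclusive),
#'   e.g. `genome$regions`.
#' @return `write_regions_bed()`: `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  gr <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$start, regions$end))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write synthetic gene models as GFF3
#'
#' Emits `gene` and `exon` features (exons carrying `Parent` links) plus
#' `##sequence-region` directives so the chromosome universe survives the
#' round trip.
#'
#' @param genome A `sim_genome`.
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genome, path) {
  stopifnot(inherits(genome, "sim_genome"))
  g <- genome$genes; e <- genome$exons
  gr <- GenomicRanges::GRanges(
    c(g$chrom, e$chrom),
    IRanges::IRanges(c(g$start, e$start), c(g$end, e$end)),
    type = c(rep("gene", nrow(g)), rep("exon", nrow(e))),
    ID = c(g$gene_id, sprintf("%s_e%d", e$gene_id, seq_len(nrow(e)))),
    Parent = c(rep(NA_character_, nrow(g)), e$gene_id),
    seqlengths = genome$chrom_lengths)
  gr <- GenomicRanges::sort(gr)
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' Build an exon/intron/intergenic annotation index
#'
#' @param path Path to a GFF3 file with `gene` and `exon` features.
#' @return An `annotation_index`: gene and exon `GRanges` plus the known
#'   chromosome universe.  Errors if any exon lies outside every gene.
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  genes <- gr[gr$type == "gene"]
  exons <- gr[gr$type == "exon"]
  annotation_index(genes, exons,
                   chroms = GenomeInfoDb::seqlevels(gr))
}

#' @rdname read_annotation
#' @param genes,exons `GRanges` of gene extents and exon intervals.
#' @param chroms Character vector of valid chromosome names; defaults to
#'   the seqlevels of `genes`.
#' @export
annotation_index <- function(genes, exons, chroms = NULL) {
  if (is.null(chroms)) chroms <- GenomeInfoDb::seqlevels(genes)
  orphan <- !IRanges::overlapsAny(exons, genes, type = "within")
  if (any(orphan))
    stop("exon outside any gene extent at ",
         as.character(exons[which(orphan)[1]]))
  structure(list(genes = genes, exons = exons, chroms = chroms),
            class = "annotation_index")
}

#' Annotation index from a synthetic genome, without touching disk
#'
#' @param genome A `sim_genome`.
#' @return An `annotation_index`.
#' @export
annotation_index_from_genome <- function(genome) {
  stopifnot(inherits(genome, "sim_genome"))
  g <- genome$genes; e <- genome$exons
  annotation_index(
    GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start, g$end)),
    GenomicRanges::GRanges(e$chrom, IRanges::IRanges(e$start, e$end)),
    chroms = names(genome$chrom_lengths))
}

#' Classify genomic positions as exon, intron or intergenic
#'
#' A position inside an exon is `exon`; inside a gene but no exon,
#' `intron`; otherwise `intergenic` — every position resolves to exactly
#' one class.
#'
#' @param index An `annotation_index`.
#' @param chrom,pos Parallel vectors of chromosome names and 1-based
#'   positions.
#' @return Character vector in `{exon, intron, intergenic}`.
#' @export
classify_positions <- function(index, chrom, pos) {
  stopifnot(inherits(index, "annotation_index"),
            length(chrom) == length(pos))
  unknown <- setdiff(unique(chrom), index$chroms)
  if (length(unknown))
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  if (!length(pos)) return(character(0))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  in_exon <- IRanges::overlapsAny(q, index$exons)
  in_gene <- IRanges::overlapsAny(q, index$genes)
  ifelse(in_exon, "exon", ifelse(in_gene, "intron", "intergenic"))
}
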