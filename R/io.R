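# File-format boundary: BED, VCF, MTX. Intervals are 1-based inclusive
# inside the package; BED files are 0-based half-open.

#' Write / read BED intervals
#'
#' @param intervals Tibble with chrom, start, end (1-based inclusive).
#' @param path BED path (0-based half-open on disk).
#' @return `path` (write) or a tibble (read, converted to 1-based inclusive).
#' @export
write_bed <- function(intervals, path) {
  gr <- GenomicRanges::GRanges(
    intervals$chrom, IRanges::IRanges(intervals$start, intervals$end))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr)
  )
}

#' Write / read SNV calls as VCF
#'
#' @param calls Tibble with chrom, pos, ref, alt (1-based).
#' @param path VCF path.
#' @param sample Sample name recorded in the VCF.
#' @return `path` (write) or a tibble (read).
#' @export
write_calls_vcf <- function(calls, path, sample = "cell") {
  if (nrow(calls) == 0) {
    writeLines(c("##fileformat=VCFv4.2",
                 "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), path)
    return(invisible(path))
  }
  ord <- order(calls$chrom, calls$pos)
  calls <- calls[ord, ]
  vr <- VariantAnnotation::VRanges(
    seqnames = calls$chrom,
    ranges = IRanges::IRanges(calls$pos, calls$pos),
    ref = calls$ref, alt = calls$alt, sampleNames = sample
  )
  VariantAnnotation::writeVcf(vr, path)
  invisible(path)
}

#' @rdname write_calls_vcf
#' @export
read_calls_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- VariantAnnotation::alt(vcf)
  alt <- vapply(as.list(alt), function(a) as.character(a)[1], character(1))
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = alt
  )
}

#' Write / read a count matrix as MatrixMarket with TSV sidecars
#'
#' @param counts Genes x cells matrix with dimnames.
#' @param meta Cell metadata tibble (first column must be `cell_id`).
#' @param dir Output directory.
#' @return `dir` (write) or a list with `counts` and `meta` (read).
#' @export
write_counts_mtx <- function(counts, meta, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                              "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  readr::write_tsv(tibble::tibble(gene = rownames(counts)),
                   file.path(dir, "features.tsv"), col_names = FALSE)
  readr::write_tsv(tibble::tibble(cell_id = colnames(counts)),
                   file.path(dir, "barcodes.tsv"), col_names = FALSE)
  readr::write_tsv(meta, file.path(dir, "cell_metadata.tsv"))
  invisible(dir)
}

#' @rdname write_counts_mtx
#' @export
read_counts_mtx <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  rownames(m) <- readr::read_tsv(file.path(dir, "features.tsv"),
                                 col_names = "gene",
                                 show_col_types = FALSE)$gene
  colnames(m) <- readr::read_tsv(file.path(dir, "barcodes.tsv"),
                                 col_names = "cell_id",
                                 show_col_types = FALSE)$cell_id
  meta <- readr::read_tsv(file.path(dir, "cell_metadata.tsv"),
                          show_col_types = FALSE)
  list(counts = m, meta = meta)
}
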