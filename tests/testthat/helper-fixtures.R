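# Shared fixtures, built once per test run.

.fx <- new.env(parent = emptyenv())

fx_ref <- function() {
  if (is.null(.fx$ref)) .fx$ref <- generate_reference(50000, 0.5, seed = 42)
  .fx$ref
}

fx_models <- function() {
  if (is.null(.fx$models)) .fx$models <- generate_gene_models(fx_ref(), 5, seed = 7)
  .fx$models
}

fx_catalog <- function() {
  if (is.null(.fx$catalog)) .fx$catalog <- synthetic_signature_catalog(4, seed = 9)
  .fx$catalog
}

# hand-built single-gene reference for codon-level tests:
# gene on +, one exon = whole tx, CDS = ATG CGA CTA TGA
fx_codon_world <- function(strand = "+") {
  cds <- "ATGCGACTATGA"
  pad <- strrep("ACGT", 10)          # 40 bp flanks
  seq <- paste0(pad, cds, pad)
  if (strand == "-") {
    seq <- chartr("ACGT", "TGCA", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
  }
  ref <- structure(list(sequence = seq, length = nchar(seq),
                        contig_name = "chrT"), class = "toy_reference")
  cds_start <- if (strand == "+") 41L else nchar(seq) - 52L + 1L
  cds_end <- cds_start + 11L
  models <- structure(list(
    genes = tibble::tibble(gene_id = "g1", chrom = "chrT", strand = strand,
                           tx_start = cds_start - 5L, tx_end = cds_end + 5L,
                           cds_start = cds_start, cds_end = cds_end),
    exons = tibble::tibble(gene_id = "g1", exon_start = cds_start - 5L,
                           exon_end = cds_end + 5L)
  ), class = "gene_models")
  list(ref = ref, models = models, cds_start = cds_start, cds_end = cds_end)
}

# two-sided Fisher exact P by hypergeometric enumeration (oracle)
enum_fisher_p <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# grid-search oracle: best reconstruction error over the simplex of two
# catalog signatures at the given step
grid_refit_error <- function(counts, catalog, sig_pair, step = 0.01) {
  total <- sum(counts)
  fs <- seq(0, 1, by = step)
  errs <- vapply(fs, function(f) {
    recon <- total * (f * catalog[, sig_pair[1]] +
                        (1 - f) * catalog[, sig_pair[2]])
    sqrt(sum((counts - recon)^2))
  }, numeric(1))
  min(errs)
}
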