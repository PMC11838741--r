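# Synthetic reference sequence and gene models.

#' Generate a toy reference sequence
#'
#' Draws an i.i.d. random DNA sequence with the requested GC content. Stands
#' in for a real reference genome so that every downstream stage (context
#' lookup, mutation placement, annotation) can be exercised self-contained.
#'
#' @param length Sequence length in bp (>= 1000).
#' @param gc_fraction Target GC proportion in \[0, 1\].
#' @param seed Integer seed; fixed seed gives an identical sequence.
#' @param contig_name Contig name used in all emitted files.
#' @return An object of class `toy_reference`: a list with `sequence`
#'   (character scalar), `length` and `contig_name`.
#' @export
generate_reference <- function(length, gc_fraction = 0.41, seed = 1L,
                               contig_name = "chrS") {
  if (!is.numeric(length) || length < 1000) {
    abort("generate_reference(): length must be >= 1000 bp")
  }
  if (gc_fraction < 0 || gc_fraction > 1) {
    abort("generate_reference(): gc_fraction must be in [0, 1]")
  }
  length <- as.integer(length)
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  seq <- withr::with_seed(seed,
    paste(sample(BASES, length, replace = TRUE, prob = p), collapse = ""))
  structure(
    list(sequence = seq, length = length, contig_name = contig_name),
    class = "toy_reference"
  )
}

#' @export
print.toy_reference <- function(x, ...) {
  cat("<toy_reference> ", x$contig_name, ": ", x$length, " bp, GC = ",
      round(reference_gc(x), 3), "\n", sep = "")
  invisible(x)
}

#' GC fraction of a toy reference
#' @param ref A `toy_reference`.
#' @return Observed GC proportion.
#' @export
reference_gc <- function(ref) {
  counts <- table(strsplit(ref$sequence, "")[[1]])
  sum(counts[c("C", "G")], na.rm = TRUE) / ref$length
}

#' Write / read a toy reference as FASTA
#' @param ref A `toy_reference`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(ref, path) {
  x <- Biostrings::DNAStringSet(ref$sequence)
  names(x) <- ref$contig_name
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_reference_fasta
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  structure(
    list(sequence = as.character(x[[1]]), length = Biostrings::width(x)[1],
         contig_name = names(x)[1]),
    class = "toy_reference"
  )
}

#' Base(s) of the reference at given positions
#' @param ref A `toy_reference`.
#' @param pos 1-based positions.
#' @return Character vector of bases.
#' @export
reference_base <- function(ref, pos) substring(ref$sequence, pos, pos)

#' Generate non-overlapping synthetic gene models
#'
#' Lays out `n_genes` multi-exon genes with strand, UTRs and a CDS whose
#' length is divisible by 3, evenly spaced along the reference. Supports the
#' genic-region categories used downstream (upstream/UTR/exonic/splicing/
#' intronic/downstream/intergenic).
#'
#' @param ref A `toy_reference`.
#' @param n_genes Number of genes (0 allowed).
#' @param seed Integer seed.
#' @param n_exons Exons per gene.
#' @return An object of class `gene_models`: list with tibbles `genes`
#'   (gene_id, chrom, strand, tx_start, tx_end, cds_start, cds_end) and
#'   `exons` (gene_id, exon_start, exon_end), 1-based inclusive coordinates.
#' @export
generate_gene_models <- function(ref, n_genes, seed = 1L, n_exons = 3L) {
  stopifnot(inherits(ref, "toy_reference"), n_genes >= 0)
  slot <- if (n_genes > 0) ref$length %/% (n_genes + 1L) else ref$length
  # each gene needs tx plus 1 kb flanks inside its slot
  tx_len <- min(3000L, slot - 2200L)
  if (n_genes > 0 && tx_len < 200L) {
    abort(paste0("generate_gene_models(): cannot fit ", n_genes,
                 " genes in a ", ref$length, " bp reference"))
  }
  if (n_genes == 0) {
    return(structure(list(
      genes = tibble::tibble(gene_id = character(), chrom = character(),
                             strand = character(), tx_start = integer(),
                             tx_end = integer(), cds_start = integer(),
                             cds_end = integer()),
      exons = tibble::tibble(gene_id = character(), exon_start = integer(),
                             exon_end = integer())
    ), class = "gene_models"))
  }
  withr::with_seed(seed, {
    genes <- vector("list", n_genes)
    exons <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
      tx_start <- as.integer((g - 1L) * slot + 1100L)
      tx_end <- tx_start + tx_len - 1L
      strand <- sample(c("+", "-"), 1L)
      # equal exons separated by introns, intron >= 50 bp
      exon_len <- max(50L, tx_len %/% (2L * n_exons))
      gap <- (tx_len - n_exons * exon_len) %/% max(1L, n_exons - 1L)
      ex_start <- tx_start + (seq_len(n_exons) - 1L) * (exon_len + gap)
      ex_end <- ex_start + exon_len - 1L
      ex_end[n_exons] <- tx_end
      # CDS: from inside first exon to inside last exon, UTRs at both ends
      utr <- max(10L, exon_len %/% 5L)
      cds_start <- ex_start[1] + utr
      cds_end <- ex_end[n_exons] - utr
      cds_len <- sum(pmin(ex_end, cds_end) - pmax(ex_start, cds_start) + 1L)
      rem <- cds_len %% 3L
      if (rem != 0L) cds_end <- cds_end - rem
      genes[[g]] <- tibble::tibble(
        gene_id = sprintf("gene%02d", g), chrom = ref$contig_name,
        strand = strand, tx_start = tx_start, tx_end = tx_end,
        cds_start = cds_start, cds_end = cds_end
      )
      exons[[g]] <- tibble::tibble(
        gene_id = sprintf("gene%02d", g),
        exon_start = ex_start, exon_end = ex_end
      )
    }
    structure(list(genes = dplyr::bind_rows(genes),
                   exons = dplyr::bind_rows(exons)),
              class = "gene_models")
  })
}

#' @export
print.gene_models <- function(x, ...) {
  cat("<gene_models> ", nrow(x$genes), " genes, ", nrow(x$exons),
      " exons\n", sep = "")
  invisible(x)
}

#' Export / import gene models as GFF3
#' @param models A `gene_models` object.
#' @param path GFF3 path.
#' @return `path` (write) or a `gene_models` object (read).
#' @export
write_gene_models_gff3 <- function(models, path) {
  g <- models$genes
  e <- models$exons |> dplyr::left_join(g, by = "gene_id")
  feats <- dplyr::bind_rows(
    tibble::tibble(chrom = g$chrom, start = g$tx_start, end = g$tx_end,
                   strand = g$strand, type = "gene", ID = g$gene_id,
                   Parent = NA_character_),
    tibble::tibble(chrom = e$chrom, start = e$exon_start, end = e$exon_end,
                   strand = e$strand, type = "exon",
                   ID = paste0(e$gene_id, ".e", seq_len(nrow(e))),
                   Parent = e$gene_id),
    tibble::tibble(chrom = g$chrom, start = g$cds_start, end = g$cds_end,
                   strand = g$strand, type = "CDS",
                   ID = paste0(g$gene_id, ".cds"), Parent = g$gene_id)
  )
  gr <- GenomicRanges::GRanges(
    feats$chrom, IRanges::IRanges(feats$start, feats$end),
    strand = feats$strand, type = feats$type, ID = feats$ID,
    Parent = feats$Parent,
    phase = ifelse(feats$type == "CDS", 0L, NA_integer_)
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_gene_models_gff3
#' @export
read_gene_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- tibble::as_tibble(as.data.frame(gr))
  parent <- vapply(df$Parent, function(p) {
    if (length(p) == 0) NA_character_ else as.character(p[[1]])
  }, character(1))
  df$parent <- parent
  genes <- df |> dplyr::filter(.data$type == "gene")
  cds <- df |> dplyr::filter(.data$type == "CDS")
  exons <- df |> dplyr::filter(.data$type == "exon")
  structure(list(
    genes = tibble::tibble(
      gene_id = as.character(genes$ID), chrom = as.character(genes$seqnames),
      strand = as.character(genes$strand),
      tx_start = genes$start, tx_end = genes$end,
      cds_start = cds$start[match(genes$ID, cds$parent)],
      cds_end = cds$end[match(genes$ID, cds$parent)]
    ),
    exons = tibble::tibble(
      gene_id = exons$parent, exon_start = exons$start, exon_end = exons$end
    ) |> dplyr::arrange(.data$gene_id, .data$exon_start)
  ), class = "gene_models")
}
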