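# Genic-region and functional annotation plus germline-normalized
# selection statistics.

REGION_LEVELS <- c("splicing", "exonic", "UTR5", "UTR3", "intronic",
                   "upstream", "downstream", "intergenic")

# region category of positions with respect to ONE gene (NA when unrelated)
region_for_gene <- function(pos, gene, exons) {
  out <- rep(NA_character_, length(pos))
  ex <- exons[exons$gene_id == gene$gene_id, , drop = FALSE]
  in_tx <- pos >= gene$tx_start & pos <= gene$tx_end
  in_exon <- rep(FALSE, length(pos))
  near_junction <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(ex))) {
    in_exon <- in_exon | (pos >= ex$exon_start[i] & pos <= ex$exon_end[i])
    # splice donor/acceptor: within 2 bp on the intronic side of a junction
    if (ex$exon_start[i] > gene$tx_start) {
      near_junction <- near_junction |
        (pos >= ex$exon_start[i] - 2L & pos <= ex$exon_start[i] - 1L)
    }
    if (ex$exon_end[i] < gene$tx_end) {
      near_junction <- near_junction |
        (pos >= ex$exon_end[i] + 1L & pos <= ex$exon_end[i] + 2L)
    }
  }
  in_cds <- pos >= gene$cds_start & pos <= gene$cds_end
  left_utr <- in_exon & pos < gene$cds_start
  right_utr <- in_exon & pos > gene$cds_end
  utr5 <- if (gene$strand == "+") left_utr else right_utr
  utr3 <- if (gene$strand == "+") right_utr else left_utr
  upstream_iv <- if (gene$strand == "+") {
    c(gene$tx_start - 1000L, gene$tx_start - 1L)
  } else {
    c(gene$tx_end + 1L, gene$tx_end + 1000L)
  }
  downstream_iv <- if (gene$strand == "+") {
    c(gene$tx_end + 1L, gene$tx_end + 1000L)
  } else {
    c(gene$tx_start - 1000L, gene$tx_start - 1L)
  }
  out[in_tx & !in_exon] <- "intronic"
  out[in_tx & !in_exon & near_junction] <- "splicing"
  out[utr5] <- "UTR5"
  out[utr3] <- "UTR3"
  out[in_exon & in_cds] <- "exonic"
  no_tx <- !in_tx
  out[no_tx & pos >= upstream_iv[1] & pos <= upstream_iv[2]] <- "upstream"
  out[no_tx & pos >= downstream_iv[1] & pos <= downstream_iv[2]] <- "downstream"
  out
}

#' Annotate calls with genic-region categories
#'
#' Assigns each call exactly one of intergenic, upstream (within 1 kb of
#' the TSS), 5' UTR, exonic (CDS), 3' UTR, downstream (within 1 kb of the
#' TTS), splicing (within 2 bp of an intronic splice junction) or intronic.
#' When a position maps to several genes or categories, the most severe
#' wins under the precedence splicing > exonic > UTR5 > UTR3 > intronic >
#' upstream > downstream > intergenic.
#'
#' @param calls Tibble with chrom, pos.
#' @param gene_models A `gene_models`.
#' @return `calls` with added `region` and `gene_id` columns.
#' @export
annotate_region <- function(calls, gene_models) {
  g <- gene_models$genes
  e <- gene_models$exons
  if (nrow(g) > 0 && any(g$cds_start < g$tx_start | g$cds_end > g$tx_end)) {
    abort("annotate_region(): malformed gene model (CDS outside transcript)")
  }
  best <- rep("intergenic", nrow(calls))
  best_gene <- rep(NA_character_, nrow(calls))
  rank_of <- function(x) match(x, REGION_LEVELS)
  for (i in seq_len(nrow(g))) {
    cand <- region_for_gene(calls$pos, g[i, ], e)
    better <- !is.na(cand) & rank_of(cand) < rank_of(best)
    best[better] <- cand[better]
    best_gene[better] <- g$gene_id[i]
  }
  calls |> dplyr::mutate(region = best, gene_id = best_gene)
}

#' Functional consequence of exonic calls
#'
#' Translates the affected codon (strand-aware, standard genetic code) and
#' classifies CDS variants as synonymous, nonsynonymous, stopgain or
#' stoploss. Calls outside a CDS come back `NA`.
#'
#' @param calls Tibble with chrom, pos, ref, alt.
#' @param gene_models A `gene_models`.
#' @param ref A `toy_reference`.
#' @return `calls` with added `functional` column.
#' @export
classify_functional <- function(calls, gene_models, ref) {
  g <- gene_models$genes
  e <- gene_models$exons
  gc <- Biostrings::GENETIC_CODE
  functional <- rep(NA_character_, nrow(calls))
  for (i in seq_len(nrow(g))) {
    gene <- g[i, ]
    ex <- e[e$gene_id == gene$gene_id, , drop = FALSE]
    cds_iv <- tibble::tibble(
      start = pmax(ex$exon_start, gene$cds_start),
      end = pmin(ex$exon_end, gene$cds_end)
    ) |> dplyr::filter(.data$start <= .data$end)
    cds_pos <- unlist(purrr::map2(cds_iv$start, cds_iv$end, seq))
    cds_seq <- paste(reference_base(ref, cds_pos), collapse = "")
    if (nchar(cds_seq) %% 3 != 0) {
      abort(paste0("classify_functional(): CDS of ", gene$gene_id,
                   " is not a multiple of 3"))
    }
    in_cds <- match(calls$pos, cds_pos)
    hits <- which(!is.na(in_cds))
    if (length(hits) == 0) next
    # sense-strand CDS and coordinate
    if (gene$strand == "+") {
      sense <- cds_seq
      coord <- in_cds[hits]
      s_ref <- calls$ref[hits]
      s_alt <- calls$alt[hits]
    } else {
      sense <- revcomp(cds_seq)
      coord <- nchar(cds_seq) - in_cds[hits] + 1L
      s_ref <- comp_base(calls$ref[hits])
      s_alt <- comp_base(calls$alt[hits])
    }
    aa_ref_full <- as.character(Biostrings::translate(
      Biostrings::DNAString(sense), no.init.codon = TRUE))
    if (grepl("\\*", substr(aa_ref_full, 1, nchar(aa_ref_full) - 1))) {
      warn(paste0("classify_functional(): internal stop codon in reference frame of ",
                  gene$gene_id))
    }
    for (j in seq_along(hits)) {
      ci <- (coord[j] - 1L) %/% 3L  # 0-based codon index
      off <- (coord[j] - 1L) %% 3L + 1L
      codon <- substr(sense, ci * 3L + 1L, ci * 3L + 3L)
      stopifnot(substr(codon, off, off) == s_ref[j])
      mut <- codon
      substr(mut, off, off) <- s_alt[j]
      aa_ref <- gc[[codon]]
      aa_alt <- gc[[mut]]
      functional[hits[j]] <- if (aa_ref == aa_alt) {
        "synonymous"
      } else if (aa_alt == "*") {
        "stopgain"
      } else if (aa_ref == "*") {
        "stoploss"
      } else {
        "nonsynonymous"
      }
    }
  }
  calls |> dplyr::mutate(functional = functional)
}

#' Germline-normalized selection ratios
#'
#' Builds the exonic:intronic and nonsynonymous:synonymous (dN/dS) 2x2
#' tables of somatic versus germline variants, reports the
#' germline-normalized ratio (somatic A/B divided by germline A/B) and a
#' two-sided Fisher exact test per table. Ratios above 1 indicate relaxed
#' negative selection on somatic variants relative to germline.
#'
#' @param somatic Annotated somatic calls (columns `region`, `functional`).
#' @param germline Annotated germline calls (same columns).
#' @return Tibble: comparison, somatic_a, somatic_b, germline_a,
#'   germline_b, ratio, p.value.
#' @export
selection_ratios <- function(somatic, germline) {
  one <- function(sa, sb, ga, gb, label) {
    ratio <- if (sb > 0 && ga > 0 && gb > 0) (sa / sb) / (ga / gb) else NA_real_
    p <- fisher.test(matrix(c(sa, sb, ga, gb), 2,
                            dimnames = list(c("A", "B"),
                                            c("somatic", "germline"))))$p.value
    tibble::tibble(comparison = label, somatic_a = sa, somatic_b = sb,
                   germline_a = ga, germline_b = gb, ratio = ratio,
                   p.value = p)
  }
  dplyr::bind_rows(
    one(sum(somatic$region == "exonic"), sum(somatic$region == "intronic"),
        sum(germline$region == "exonic"), sum(germline$region == "intronic"),
        "exonic:intronic"),
    one(sum(somatic$functional %in% c("nonsynonymous", "stopgain", "stoploss")),
        sum(somatic$functional %in% "synonymous"),
        sum(germline$functional %in% c("nonsynonymous", "stopgain", "stoploss")),
        sum(germline$functional %in% "synonymous"),
        "dN/dS")
  )
}

#' Intersect calls with disease-associated loci
#'
#' Simple interval-intersection report against a user-supplied BED of
#' loci (e.g. known risk loci for the disease under study).
#'
#' @param calls Tibble with chrom, pos.
#' @param loci Tibble with chrom, start, end (1-based inclusive) and
#'   optionally a `name` column.
#' @return The subset of calls overlapping a locus, with locus columns.
#' @export
overlap_loci <- function(calls, loci) {
  hits <- IRanges::findOverlaps(
    IRanges::IRanges(calls$pos, calls$pos),
    IRanges::IRanges(loci$start, loci$end))
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  dplyr::bind_cols(
    calls[q, , drop = FALSE],
    loci[s, , drop = FALSE] |>
      dplyr::rename(locus_chrom = "chrom", locus_start = "start",
                    locus_end = "end")
  )
}
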