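# SBS96 spectra, strand bias, catalog refitting (NNLS) and de novo NMF
# signature extraction with cophenetic/RSS rank selection.

#' Build an SBS96 spectrum from calls
#'
#' Trinucleotide contexts are read from the reference sequence (never from
#' the VCF), purine-reference calls are reverse-complemented to the
#' pyrimidine standard, and counts are accumulated over the 96 channels.
#'
#' @param calls Tibble with chrom, pos, ref, alt.
#' @param ref A `toy_reference` (or object with `$sequence`).
#' @return Tibble of class `sbs_spectrum`: channel (factor in COSMIC
#'   order), substitution, class, count; attribute `total`.
#' @export
build_spectrum <- function(calls, ref) {
  chans <- sbs96_channels()
  if (nrow(calls) == 0) {
    cls <- classify_channel_table()
    out <- cls |> dplyr::mutate(count = 0L)
    return(structure(out, total = 0L,
                     class = c("sbs_spectrum", class(out))))
  }
  if (any(calls$pos < 2 | calls$pos > nchar(ref$sequence) - 1)) {
    bad <- calls[calls$pos < 2 | calls$pos > nchar(ref$sequence) - 1, ]
    abort(paste0("build_spectrum(): call(s) at contig edge without flanks: ",
                 paste(bad$pos, collapse = ", ")))
  }
  up <- reference_base(ref, calls$pos - 1L)
  down <- reference_base(ref, calls$pos + 1L)
  ref_b <- reference_base(ref, calls$pos)
  if (any(ref_b != calls$ref)) {
    abort("build_spectrum(): REF allele does not match the reference base")
  }
  cl <- classify_substitution(calls$ref, calls$alt, up, down)
  counts <- table(factor(cl$channel, levels = chans))
  out <- classify_channel_table() |>
    dplyr::mutate(count = as.integer(counts))
  structure(out, total = nrow(calls),
            class = c("sbs_spectrum", class(out)))
}

# channel -> substitution/class lookup for all 96 channels
classify_channel_table <- function() {
  chans <- sbs96_channels()
  sub <- paste0(substr(chans, 3, 3), ">", substr(chans, 5, 5))
  down <- substr(chans, 7, 7)
  class <- sub
  class[sub == "C>T" & down == "G"] <- "C>T at CpG"
  class[sub == "C>T" & down != "G"] <- "C>T at non-CpG"
  tibble::tibble(channel = factor(chans, levels = chans),
                 substitution = sub, class = class)
}

#' Seven-way substitution class summary of a spectrum
#'
#' @param spectrum An `sbs_spectrum`.
#' @return Tibble: class (C>A, C>G, C>T at CpG, C>T at non-CpG, T>A, T>C,
#'   T>G), count.
#' @export
substitution_classes <- function(spectrum) {
  spectrum |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
}

#' Per-cell SBS96 spectrum matrix
#'
#' @param calls Tibble with cell_id, chrom, pos, ref, alt.
#' @param ref Reference.
#' @return 96 x n_cells matrix (rows in COSMIC channel order).
#' @export
spectrum_matrix <- function(calls, ref) {
  cells <- unique(calls$cell_id)
  m <- sapply(cells, function(cid) {
    build_spectrum(calls[calls$cell_id == cid, ], ref)$count
  })
  m <- matrix(m, nrow = 96, dimnames = list(sbs96_channels(), cells))
  m
}

#' Assign the transcriptional strand of calls
#'
#' The pyrimidine-standardized base on the same strand as the gene
#' annotation is "untranscribed" (the coding strand), the opposite strand
#' "transcribed". Positions outside genes are intergenic; positions covered
#' by genes on both strands are ambiguous and excluded from strand-bias
#' counts (tallied separately).
#'
#' @param calls Tibble with chrom, pos, ref.
#' @param gene_models A `gene_models` object.
#' @return `calls` with an added `tx_strand` column in
#'   {transcribed, untranscribed, intergenic, ambiguous}.
#' @export
assign_transcriptional_strand <- function(calls, gene_models) {
  g <- gene_models$genes
  if (nrow(g) == 0) {
    return(calls |> dplyr::mutate(tx_strand = "intergenic"))
  }
  hits <- IRanges::findOverlaps(
    IRanges::IRanges(calls$pos, calls$pos),
    IRanges::IRanges(g$tx_start, g$tx_end))
  per_call <- tibble::tibble(
    call = S4Vectors::queryHits(hits),
    gene_strand = g$strand[S4Vectors::subjectHits(hits)]
  ) |>
    dplyr::group_by(.data$call) |>
    dplyr::summarise(n_strands = dplyr::n_distinct(.data$gene_strand),
                     gene_strand = .data$gene_strand[1], .groups = "drop")
  tx <- rep("intergenic", nrow(calls))
  pyr_strand <- ifelse(calls$ref %in% c("C", "T"), "+", "-")
  tx[per_call$call] <- ifelse(
    per_call$n_strands > 1, "ambiguous",
    ifelse(pyr_strand[per_call$call] == per_call$gene_strand,
           "untranscribed", "transcribed"))
  calls |> dplyr::mutate(tx_strand = tx)
}

#' Per-class transcriptional strand-bias test
#'
#' For each of the six substitution classes, compares the per-cell
#' transcribed and untranscribed counts with a two-sided Wilcoxon rank-sum
#' test, within each condition.
#'
#' @param strand_counts Tibble with cell_id, condition, class,
#'   transcribed, untranscribed (counts per cell and class).
#' @return Tibble: condition, class, median_transcribed,
#'   median_untranscribed, statistic, p.value, degenerate flag.
#' @export
strand_bias_test <- function(strand_counts) {
  n_cells <- strand_counts |>
    dplyr::distinct(.data$condition, .data$cell_id) |>
    dplyr::count(.data$condition)
  if (any(n_cells$n < 3)) {
    abort("strand_bias_test(): need >= 3 cells per condition")
  }
  strand_counts |>
    dplyr::group_by(.data$condition, .data$class) |>
    dplyr::group_modify(function(df, key) {
      if (all(df$transcribed == 0) && all(df$untranscribed == 0)) {
        return(tibble::tibble(
          median_transcribed = 0, median_untranscribed = 0,
          statistic = NA_real_, p.value = 1, degenerate = TRUE))
      }
      wt <- suppressWarnings(
        wilcox.test(df$transcribed, df$untranscribed, exact = FALSE))
      tibble::tibble(
        median_transcribed = median(df$transcribed),
        median_untranscribed = median(df$untranscribed),
        statistic = unname(wt$statistic), p.value = wt$p.value,
        degenerate = FALSE)
    }) |>
    dplyr::ungroup()
}

#' Tally per-cell strand counts by substitution class
#'
#' Convenience aggregation feeding [strand_bias_test()].
#'
#' @param calls Tibble with cell_id, chrom, pos, ref, alt.
#' @param gene_models A `gene_models`.
#' @param ref Reference (for channel classification).
#' @param meta Optional tibble mapping cell_id to condition.
#' @return Tibble: cell_id, condition, class, transcribed, untranscribed.
#' @export
strand_class_counts <- function(calls, gene_models, ref, meta = NULL) {
  up <- reference_base(ref, calls$pos - 1L)
  down <- reference_base(ref, calls$pos + 1L)
  cl <- classify_substitution(calls$ref, calls$alt, up, down)
  x <- calls |>
    dplyr::mutate(substitution = cl$substitution) |>
    assign_transcriptional_strand(gene_models) |>
    dplyr::filter(.data$tx_strand %in% c("transcribed", "untranscribed")) |>
    dplyr::count(.data$cell_id, .data$substitution, .data$tx_strand) |>
    tidyr::pivot_wider(names_from = "tx_strand", values_from = "n",
                       values_fill = 0L)
  for (col in c("transcribed", "untranscribed")) {
    if (!col %in% names(x)) x[[col]] <- 0L
  }
  x <- x |> dplyr::rename(class = "substitution")
  if (!is.null(meta)) {
    x <- x |> dplyr::left_join(meta |> dplyr::select("cell_id", "condition"),
                               by = "cell_id")
  }
  x
}

#' Refit a spectrum onto a signature catalog (non-negative least squares)
#'
#' Finds non-negative signature exposures minimizing the squared
#' reconstruction error of the observed spectrum, then rescales them so
#' their sum equals the spectrum total. Deterministic, in contrast to
#' sampling- or network-based attribution.
#'
#' @param spectrum An `sbs_spectrum`, or a numeric 96-vector of counts.
#' @param catalog Catalog accepted by [as_catalog_matrix()].
#' @return Tibble of class `exposure_fit`: signature, exposure (counts),
#'   fraction; attributes `residual` (relative L2 reconstruction error) and
#'   `total`.
#' @export
fit_exposures <- function(spectrum, catalog) {
  catalog <- as_catalog_matrix(catalog)
  counts <- if (is.data.frame(spectrum)) {
    stats::setNames(spectrum$count, as.character(spectrum$channel))
  } else {
    spectrum
  }
  if (is.null(names(counts))) names(counts) <- sbs96_channels()
  counts <- counts[sbs96_channels()]
  total <- sum(counts)
  if (total <= 0) abort("fit_exposures(): spectrum total must be > 0")
  dup <- duplicated(round(t(catalog), 12))
  if (any(dup)) {
    warn("fit_exposures(): catalog contains duplicate identical columns; ties resolve to the first")
    catalog <- catalog[, !dup, drop = FALSE]
  }
  sol <- pracma::lsqnonneg(catalog, as.numeric(counts))
  w <- sol$x
  recon <- as.numeric(catalog %*% w)
  resid <- sqrt(sum((counts - recon)^2)) / sqrt(sum(counts^2))
  if (sum(w) > 0) w <- w / sum(w) * total
  out <- tibble::tibble(
    signature = colnames(catalog), exposure = w, fraction = w / total)
  structure(out, residual = resid, total = total,
            class = c("exposure_fit", class(out)))
}

#' Decompose de novo signatures into catalog signatures
#'
#' Applies the non-negative refit column-wise to each de novo signature
#' profile (as a probability vector), returning the catalog weights.
#'
#' @param denovo 96 x k matrix of de novo signature profiles (columns sum
#'   to 1), e.g. `nmf_result$signatures`.
#' @param catalog Catalog accepted by [as_catalog_matrix()].
#' @return Tibble: denovo, signature, weight (weights sum to 1 per de novo
#'   signature).
#' @export
decompose_denovo <- function(denovo, catalog) {
  denovo <- as.matrix(denovo)
  if (is.null(colnames(denovo))) {
    colnames(denovo) <- paste0("N", seq_len(ncol(denovo)))
  }
  purrr::map_dfr(colnames(denovo), function(nm) {
    v <- denovo[, nm]
    fe <- fit_exposures(stats::setNames(v, rownames(denovo) %||%
                                          sbs96_channels()), catalog)
    tibble::tibble(denovo = nm, signature = fe$signature,
                   weight = fe$exposure / sum(fe$exposure))
  })
}

# ---- de novo NMF ----------------------------------------------------------

# One multiplicative-update Frobenius NMF run on V (96 x cells).
nmf_once <- function(V, k, max_iter = 400, tol = 1e-6) {
  n <- nrow(V); m <- ncol(V)
  W <- matrix(runif(n * k, 0.1, 1), n, k)
  H <- matrix(runif(k * m, 0.1, 1), k, m)
  eps <- 1e-10
  rss_prev <- Inf
  for (it in seq_len(max_iter)) {
    H <- H * (t(W) %*% V) / (t(W) %*% W %*% H + eps)
    W <- W * (V %*% t(H)) / (W %*% H %*% t(H) + eps)
    if (it %% 20 == 0) {
      rss <- sum((V - W %*% H)^2)
      if (abs(rss_prev - rss) < tol * (rss_prev + eps)) break
      rss_prev <- rss
    }
  }
  # scale signatures to probability columns, push mass into H
  cs <- pmax(colSums(W), eps)
  W <- sweep(W, 2, cs, "/")
  H <- sweep(H, 1, cs, "*")
  list(W = W, H = H, rss = sum((V - W %*% H)^2))
}

connectivity <- function(H) {
  cl <- apply(H, 2, which.max)
  outer(cl, cl, "==") * 1
}

cophenetic_coef <- function(C) {
  d <- as.dist(1 - C)
  if (all(d == 0) || sd(d) == 0) return(1)
  hc <- hclust(d, method = "average")
  suppressWarnings(cc <- cor(cophenetic(hc), d))
  if (is.na(cc)) 1 else cc
}

#' De novo signature extraction by NMF with rank selection
#'
#' For each candidate rank, runs `n_restarts` random-restart multiplicative
#' -update factorizations of the cell x channel count matrix, records the
#' consensus-clustering cophenetic correlation and the best residual sum of
#' squares, then chooses the largest rank before the cophenetic coefficient
#' starts to decrease (cross-checked against the RSS curve, whose values
#' are returned for audit).
#'
#' @param spectra 96 x cells (or cells x 96) count matrix; see
#'   [spectrum_matrix()].
#' @param ranks Candidate ranks (default 2:6).
#' @param n_restarts Random restarts per rank (default 50).
#' @param seed Integer seed.
#' @param coph_min Minimum consensus cophenetic coefficient for a rank to
#'   count as stable (default 0.9).
#' @param rss_frac Fraction of the total RSS range an incremental
#'   improvement must reach to count as part of the steep segment before
#'   the inflection (default 0.05).
#' @param max_iter Iterations per factorization.
#' @return Object of class `nmf_result`: `rank`, `signatures` (96 x k,
#'   columns sum to 1), `contributions` (k x cells), `diagnostics` (tibble
#'   rank/cophenetic/rss), `ranks`.
#' @export
extract_denovo <- function(spectra, ranks = 2:6, n_restarts = 50L,
                           seed = 1L, coph_min = 0.9, rss_frac = 0.05,
                           max_iter = 400L) {
  V <- as.matrix(spectra)
  if (nrow(V) != 96 && ncol(V) == 96) V <- t(V)
  if (nrow(V) != 96) abort("extract_denovo(): spectra must have a 96-channel dimension")
  if (any(V < 0)) abort("extract_denovo(): counts must be non-negative")
  if (max(ranks) >= min(ncol(V), 96)) {
    abort("extract_denovo(): rank must be < min(n_cells, 96)")
  }
  if (ncol(V) < max(ranks) + 1) {
    abort("extract_denovo(): need at least rank+1 cells")
  }
  V <- V + 1e-9  # guard all-zero rows

  per_rank <- withr::with_seed(seed, {
    lapply(ranks, function(k) {
      runs <- lapply(seq_len(n_restarts), function(r) nmf_once(V, k, max_iter))
      Cbar <- Reduce(`+`, lapply(runs, function(x) connectivity(x$H))) /
        n_restarts
      best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "rss"))]]
      list(k = k, coph = cophenetic_coef(Cbar), rss = best$rss, best = best)
    })
  })
  diag <- tibble::tibble(
    rank = vapply(per_rank, `[[`, numeric(1), "k"),
    cophenetic = vapply(per_rank, `[[`, numeric(1), "coph"),
    rss = vapply(per_rank, `[[`, numeric(1), "rss")
  )
  # rank choice: the RSS inflection point (last rank reached by a sizable
  # incremental improvement) among ranks whose consensus clustering is
  # still stable (cophenetic >= coph_min, i.e. before it falls off)
  stable <- diag$cophenetic >= coph_min
  n_r <- nrow(diag)
  imp <- c(Inf, -diff(diag$rss))   # improvement achieved *at* each rank
  rng <- max(diag$rss) - min(diag$rss)
  sizable <- imp >= rss_frac * rng
  # a true inflection: improvements beyond the rank have collapsed (noise
  # fitting improves RSS steadily, structure fitting improves it in steps)
  tail_flat <- vapply(seq_len(n_r), function(i) {
    if (i == n_r) TRUE else mean(imp[(i + 1):n_r]) < 0.5 * imp[i]
  }, logical(1))
  cand <- which(stable & sizable & tail_flat)
  chosen <- if (length(cand) == 0) {
    diag$rank[which.max(diag$cophenetic)]
  } else {
    diag$rank[max(cand)]
  }
  best <- per_rank[[match(chosen, diag$rank)]]$best
  sig <- best$W
  colnames(sig) <- paste0("N", seq_len(ncol(sig)))
  rownames(sig) <- rownames(V) %||% sbs96_channels()
  contrib <- best$H
  rownames(contrib) <- colnames(sig)
  colnames(contrib) <- colnames(V)
  structure(list(rank = chosen, signatures = sig, contributions = contrib,
                 diagnostics = diag, ranks = ranks),
            class = "nmf_result")
}

#' @export
print.nmf_result <- function(x, ...) {
  cat("<nmf_result> chosen rank ", x$rank, " (candidates ",
      paste(range(x$ranks), collapse = "-"), ")\n", sep = "")
  print(x$diagnostics)
  invisible(x)
}

#' Signature-specific burden models across a cohort
#'
#' Splits each cell's total burden across signatures by its exposure
#' fractions, then fits the aging/disease burden model per signature
#' (model 2 when both conditions are present, else model 1), falling back
#' to linear regression on singular fits. Signatures absent from every cell
#' are skipped with a flag.
#'
#' @param exposures Tibble: cell_id, signature, fraction.
#' @param burdens Tibble: cell_id, burden_per_gb.
#' @param meta Tibble: cell_id, donor_id, age, condition.
#' @return Tibble with one row per signature and term: signature, term,
#'   estimate, std.error, df, statistic, p.value, fallback, skipped.
#' @export
signature_burden_series <- function(exposures, burdens, meta) {
  data <- exposures |>
    dplyr::inner_join(burdens, by = "cell_id") |>
    dplyr::inner_join(meta, by = "cell_id") |>
    dplyr::mutate(sig_burden = .data$burden_per_gb * .data$fraction)
  if (nrow(data) == 0) abort("signature_burden_series(): no overlapping cells")
  model <- if (dplyr::n_distinct(data$condition) > 1) 2 else 1
  data |>
    dplyr::group_by(signature = .data$signature) |>
    dplyr::group_modify(function(df, key) {
      if (all(df$sig_burden == 0)) {
        return(tibble::tibble(term = NA_character_, estimate = NA_real_,
                              std.error = NA_real_, df = NA_real_,
                              statistic = NA_real_, p.value = NA_real_,
                              fallback = NA, skipped = TRUE))
      }
      fit <- fit_burden_model(df, model = model, response = "sig_burden")
      tidy(fit) |>
        dplyr::mutate(fallback = fit$fallback, skipped = FALSE)
    }) |>
    dplyr::ungroup()
}
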