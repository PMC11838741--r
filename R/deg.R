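# Leave-one-out consensus differential expression, metagene scoring and
# the donor-level cell-type proportion test.

#' Library-size normalization for count matrices
#'
#' Scales each cell to `scale_factor` total counts and applies log1p —
#' the convention the default log-fold-change thresholds were tuned
#' against.
#'
#' @param counts Genes x cells count matrix.
#' @param scale_factor Target library size (default 1e4).
#' @return Dense genes x cells matrix of log-normalized expression.
#' @export
normalize_counts <- function(counts, scale_factor = 1e4) {
  lib <- colSums(counts)
  lib[lib == 0] <- 1
  log1p(sweep(counts, 2, lib, "/") * scale_factor)
}

# natural-log fold change of group means of normalized counts, pseudocount 1
fold_change <- function(norm, cells_a, cells_b) {
  ma <- Matrix::rowMeans(expm1(norm[, cells_a, drop = FALSE]))
  mb <- Matrix::rowMeans(expm1(norm[, cells_b, drop = FALSE]))
  log((ma + 1) / (mb + 1))
}

#' Rank-sum marker test between two cell groups
#'
#' Genes are prefiltered on the fraction of expressing cells (`min_pct` in
#' at least one group) and on the natural-log fold change of group means
#' of normalized counts (pseudocount 1), then tested with a two-sided
#' Wilcoxon rank-sum test on normalized expression.
#'
#' @param counts Genes x cells count matrix.
#' @param cells_a,cells_b Cell ids (columns) of the two groups; group A is
#'   the "case" whose positive log-fold-changes are "up".
#' @param lfc_threshold Minimum |lfc| to test (default 0.25).
#' @param min_pct Minimum expressing fraction in at least one group.
#' @param direction `"both"`, `"up"` or `"down"` (relative to group A).
#' @param norm Optional precomputed [normalize_counts()] matrix.
#' @return Tibble: gene, lfc, pct_a, pct_b, p.value, direction.
#' @export
markers <- function(counts, cells_a, cells_b, lfc_threshold = 0.25,
                    min_pct = 0.1, direction = c("both", "up", "down"),
                    norm = NULL) {
  direction <- match.arg(direction)
  if (length(cells_a) < 3 || length(cells_b) < 3) {
    abort("markers(): each group needs >= 3 cells")
  }
  if (is.null(norm)) norm <- normalize_counts(counts)
  pct_a <- Matrix::rowMeans(counts[, cells_a, drop = FALSE] > 0)
  pct_b <- Matrix::rowMeans(counts[, cells_b, drop = FALSE] > 0)
  lfc <- fold_change(norm, cells_a, cells_b)
  keep <- pmax(pct_a, pct_b) >= min_pct & abs(lfc) >= lfc_threshold
  if (direction == "up") keep <- keep & lfc > 0
  if (direction == "down") keep <- keep & lfc < 0
  genes <- rownames(counts)[keep]
  if (length(genes) == 0) {
    return(tibble::tibble(gene = character(), lfc = numeric(),
                          pct_a = numeric(), pct_b = numeric(),
                          p.value = numeric(), direction = character()))
  }
  p <- vapply(genes, function(g) {
    suppressWarnings(wilcox.test(norm[g, cells_a], norm[g, cells_b],
                                 exact = FALSE)$p.value)
  }, numeric(1))
  lfc_keep <- unname(lfc[keep])
  tibble::tibble(
    gene = genes, lfc = lfc_keep, pct_a = unname(pct_a[keep]),
    pct_b = unname(pct_b[keep]), p.value = unname(p),
    direction = ifelse(lfc_keep > 0, "up", "down")
  ) |>
    dplyr::arrange(.data$p.value)
}

#' Leave-one-out consensus differential expression
#'
#' Enumerates every (control donor, diseased donor) pair; in each
#' iteration both donors are excluded and case-versus-control markers are
#' recomputed on the remaining cells with direction-specific
#' log-fold-change thresholds. The consensus lists are the genes called in
#' every iteration, separately for up- and down-regulation, which guards
#' against genes driven by a single donor.
#'
#' @param counts Genes x cells count matrix.
#' @param meta Tibble with cell_id, donor_id, condition (control/IHD).
#' @param up_threshold,down_threshold Log-fold-change thresholds for up-
#'   and down-regulated genes (defaults 0.30 and 0.25).
#' @param min_pct Minimum expressing fraction.
#' @param min_cells_per_donor Optional donor pre-filter: donors with fewer
#'   cells are dropped before iterating (default off).
#' @param alpha P-value cutoff a gene must meet in an iteration.
#' @return List of class `loo_consensus`: `up`, `down` (character
#'   vectors), `iterations` (tibble: iteration, excluded_control,
#'   excluded_ihd, n_up, n_down), `per_iteration` (list of marker
#'   tibbles).
#' @export
loo_consensus <- function(counts, meta, up_threshold = 0.30,
                          down_threshold = 0.25, min_pct = 0.1,
                          min_cells_per_donor = NULL, alpha = 0.05) {
  if (!is.null(min_cells_per_donor)) {
    keep_donors <- meta |>
      dplyr::count(.data$donor_id) |>
      dplyr::filter(.data$n >= min_cells_per_donor) |>
      dplyr::pull(.data$donor_id)
    meta <- meta |> dplyr::filter(.data$donor_id %in% keep_donors)
  }
  donors <- meta |> dplyr::distinct(.data$donor_id, .data$condition)
  ctrl <- donors$donor_id[donors$condition == "control"]
  ihd <- donors$donor_id[donors$condition == "IHD"]
  if (length(ctrl) < 2 || length(ihd) < 2) {
    abort("loo_consensus(): need >= 2 donors per condition")
  }
  norm <- normalize_counts(counts)
  iter <- tidyr::expand_grid(excluded_control = ctrl, excluded_ihd = ihd)
  per_iter <- vector("list", nrow(iter))
  for (i in seq_len(nrow(iter))) {
    keep <- meta |>
      dplyr::filter(!.data$donor_id %in%
                      c(iter$excluded_control[i], iter$excluded_ihd[i]))
    ca <- keep$cell_id[keep$condition == "IHD"]
    cb <- keep$cell_id[keep$condition == "control"]
    if (length(ca) == 0 || length(cb) == 0) {
      abort("loo_consensus(): an iteration removed all donors of a condition")
    }
    up <- markers(counts, ca, cb, lfc_threshold = up_threshold,
                  min_pct = min_pct, direction = "up", norm = norm)
    down <- markers(counts, ca, cb, lfc_threshold = down_threshold,
                    min_pct = min_pct, direction = "down", norm = norm)
    per_iter[[i]] <- dplyr::bind_rows(up, down) |>
      dplyr::filter(.data$p.value < alpha) |>
      dplyr::mutate(iteration = i)
  }
  up_sets <- lapply(per_iter, function(x) x$gene[x$direction == "up"])
  down_sets <- lapply(per_iter, function(x) x$gene[x$direction == "down"])
  consensus_up <- Reduce(intersect, up_sets)
  consensus_down <- Reduce(intersect, down_sets)
  iter$iteration <- seq_len(nrow(iter))
  iter$n_up <- vapply(up_sets, length, integer(1))
  iter$n_down <- vapply(down_sets, length, integer(1))
  structure(list(up = consensus_up, down = consensus_down,
                 iterations = iter, per_iteration = per_iter),
            class = "loo_consensus")
}

#' @export
print.loo_consensus <- function(x, ...) {
  cat("<loo_consensus> ", nrow(x$iterations), " iterations; consensus: ",
      length(x$up), " up, ", length(x$down), " down\n", sep = "")
  invisible(x)
}

#' Per-cell metagene scores with a between-condition test
#'
#' A metagene score is the mean normalized expression over a named gene
#' set per cell; each set is compared between conditions with a two-sided
#' Wilcoxon rank-sum test.
#'
#' @param counts Genes x cells count matrix.
#' @param meta Tibble with cell_id, condition.
#' @param gene_sets Named list of gene-id vectors.
#' @return List: `scores` (tibble cell_id, set, score, condition),
#'   `tests` (tibble set, median per condition, p.value).
#' @export
metagene_score <- function(counts, meta, gene_sets) {
  norm <- normalize_counts(counts)
  scores <- purrr::imap_dfr(gene_sets, function(genes, nm) {
    present <- intersect(genes, rownames(counts))
    if (length(present) == 0) {
      abort(paste0("metagene_score(): no genes of set '", nm,
                   "' are in the matrix"))
    }
    if (length(present) < length(genes)) {
      warn(paste0("metagene_score(): ", length(genes) - length(present),
                  " gene(s) of set '", nm, "' missing from the matrix"))
    }
    tibble::tibble(
      cell_id = colnames(counts), set = nm,
      score = unname(Matrix::colMeans(norm[present, , drop = FALSE])))
  }) |>
    dplyr::left_join(meta |> dplyr::select("cell_id", "condition"),
                     by = "cell_id")
  tests <- scores |>
    dplyr::group_by(.data$set) |>
    dplyr::group_modify(function(df, key) {
      conds <- unique(df$condition)
      if (length(conds) != 2) {
        return(tibble::tibble(p.value = NA_real_))
      }
      wt <- suppressWarnings(wilcox.test(score ~ condition, data = df,
                                         exact = FALSE))
      med <- df |>
        dplyr::group_by(.data$condition) |>
        dplyr::summarise(m = median(.data$score), .groups = "drop")
      tibble::tibble(
        median_control = med$m[med$condition == "control"],
        median_ihd = med$m[med$condition == "IHD"],
        p.value = wt$p.value)
    }) |>
    dplyr::ungroup()
  list(scores = scores, tests = tests)
}

#' Donor-level cell-type proportion test
#'
#' The donor is the unit of analysis: the fraction of cells of the given
#' type is computed per donor and compared between conditions with a
#' two-sided Wilcoxon rank-sum test (exact for small donor counts).
#'
#' @param meta Tibble with cell_id, donor_id, condition, cell_type.
#' @param type Cell type whose proportions are compared.
#' @return List: `fractions` (tibble donor_id, condition, n_cells,
#'   fraction), `p.value`.
#' @export
proportion_test <- function(meta, type) {
  frac <- meta |>
    dplyr::group_by(.data$donor_id, .data$condition) |>
    dplyr::summarise(n_cells = dplyr::n(),
                     fraction = mean(.data$cell_type == type),
                     .groups = "drop")
  empty <- frac$n_cells == 0
  if (any(empty)) {
    warn(paste0("proportion_test(): donor(s) without cells excluded: ",
                paste(frac$donor_id[empty], collapse = ", ")))
    frac <- frac[!empty, , drop = FALSE]
  }
  per_cond <- frac |> dplyr::count(.data$condition)
  if (nrow(per_cond) < 2 || any(per_cond$n < 2)) {
    abort("proportion_test(): need >= 2 donors per condition")
  }
  grp <- frac$condition == frac$condition[1]
  p <- if (nrow(frac) <= 12) {
    exact_ranksum_p(frac$fraction[grp], frac$fraction[!grp])
  } else {
    suppressWarnings(
      wilcox.test(fraction ~ condition, data = frac, exact = FALSE)$p.value)
  }
  list(fractions = frac, p.value = p)
}

# exact two-sided rank-sum permutation P (handles ties via average ranks)
exact_ranksum_p <- function(x, y) {
  r <- rank(c(x, y))
  nx <- length(x)
  obs <- sum(r[seq_len(nx)])
  combs <- utils::combn(length(r), nx)
  sums <- colSums(matrix(r[combs], nrow = nx))
  center <- nx * (length(r) + 1) / 2
  mean(abs(sums - center) >= abs(obs - center) - 1e-12)
}
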