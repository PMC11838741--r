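# Amplification-evenness QC: MAPD, CoV, composite QC score and the
# cell-inclusion filter.

#' Log2 copy-number ratios from a binned depth profile
#'
#' Ratio for bin b is log2(depth_b / reference median depth); zero-depth
#' bins are returned as `NA` (excluded from all downstream evenness
#' computations rather than imputed).
#'
#' @param profile Tibble with columns chrom, start, end, depth (one cell).
#' @param ref_median Reference median depth; defaults to the median over
#'   bins with positive depth.
#' @return Numeric vector of log2 ratios, `NA` where depth is zero.
#' @export
compute_bin_ratios <- function(profile, ref_median = NULL) {
  depth <- profile$depth
  if (all(depth == 0)) {
    abort("compute_bin_ratios(): all bins have zero depth")
  }
  if (is.null(ref_median)) ref_median <- median(depth[depth > 0])
  if (ref_median <= 0) {
    abort("compute_bin_ratios(): reference median depth must be > 0")
  }
  ifelse(depth > 0, log2(depth / ref_median), NA_real_)
}

# absolute differences between adjacent non-missing bins
adjacent_abs_diffs <- function(ratios) {
  r <- ratios[!is.na(ratios)]
  if (length(r) < 2) {
    abort("need >= 2 non-missing bins to form adjacent differences")
  }
  abs(diff(r))
}

#' Median absolute pairwise difference (MAPD)
#'
#' Median of absolute differences between log2 copy-number ratios of
#' adjacent genomic bins; higher values indicate more uneven amplification.
#' Zero-depth (missing) bins are skipped, so "adjacent" means adjacent
#' among usable bins.
#'
#' @param ratios Log2 ratio vector ([compute_bin_ratios()]).
#' @return A single non-negative number.
#' @export
mapd <- function(ratios) {
  median(adjacent_abs_diffs(ratios))
}

#' Coefficient of variation of adjacent-bin absolute differences
#'
#' SD of the absolute adjacent-bin differences divided by their mean
#' (population SD, dividing by n). Defined as 0 when all differences are
#' zero (perfect evenness).
#'
#' @param ratios Log2 ratio vector.
#' @return A single non-negative number.
#' @export
cov_metric <- function(ratios) {
  d <- adjacent_abs_diffs(ratios)
  m <- mean(d)
  if (m == 0) return(0)
  pop_sd <- sqrt(mean((d - m)^2))
  pop_sd / m
}

#' Composite amplification QC score
#'
#' Weighted combination of depth, genome coverage and the two evenness
#' metrics, each normalized by its maximum over the cohort:
#' 0.3 * depth/max + 0.3 * coverage/max + 0.2 * (1 - MAPD/max) +
#' 0.2 * (1 - CoV/max). Values lie in \[0, 1\]; higher is better. When the
#' cohort maximum of MAPD or CoV is 0, that penalty term contributes its
#' full weight (perfect evenness across the cohort).
#'
#' @param depth,coverage,mapd,cov Per-cell metric vectors.
#' @param maxima Optional named list/vector with elements depth, coverage,
#'   mapd, cov; defaults to the maxima of the supplied vectors (the cohort).
#' @return Numeric vector of QC scores.
#' @export
qc_score <- function(depth, coverage, mapd, cov, maxima = NULL) {
  if (is.null(maxima)) {
    maxima <- c(depth = max(depth), coverage = max(coverage),
                mapd = max(mapd), cov = max(cov))
  }
  maxima <- unlist(maxima)[c("depth", "coverage", "mapd", "cov")]
  if (maxima[["depth"]] <= 0 || maxima[["coverage"]] <= 0) {
    abort("qc_score(): cohort depth and coverage maxima must be > 0")
  }
  if (any(depth > maxima[["depth"]] + 1e-12) ||
      any(coverage > maxima[["coverage"]] + 1e-12) ||
      any(mapd > maxima[["mapd"]] + 1e-12) ||
      any(cov > maxima[["cov"]] + 1e-12)) {
    abort("qc_score(): a cell exceeds the cohort maxima it was scored against")
  }
  pen_mapd <- if (maxima[["mapd"]] > 0) mapd / maxima[["mapd"]] else 0
  pen_cov <- if (maxima[["cov"]] > 0) cov / maxima[["cov"]] else 0
  0.3 * depth / maxima[["depth"]] + 0.3 * coverage / maxima[["coverage"]] +
    0.2 * (1 - pen_mapd) + 0.2 * (1 - pen_cov)
}

#' Per-cell QC metrics from binned depth profiles
#'
#' Computes mean depth, coverage (fraction of bins with depth >= 1), MAPD
#' and CoV for every cell, then the cohort-normalized composite QC score.
#'
#' @param depth_bins Tibble with cell_id, chrom, start, end, depth.
#' @return Tibble: cell_id, depth, coverage, mapd, cov, qc_score.
#' @export
score_cells <- function(depth_bins) {
  per_cell <- depth_bins |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(function(df, key) {
      ratios <- compute_bin_ratios(df)
      tibble::tibble(
        depth = mean(df$depth), coverage = mean(df$depth > 0),
        mapd = mapd(ratios), cov = cov_metric(ratios)
      )
    }) |>
    dplyr::ungroup()
  per_cell |>
    dplyr::mutate(qc_score = qc_score(.data$depth, .data$coverage,
                                      .data$mapd, .data$cov))
}

#' Filter cells on the composite QC score
#'
#' Keeps cells with `qc_score` strictly greater than the threshold (a score
#' exactly at the threshold is excluded). Order is preserved; excluded
#' cells are attached as an attribute and reported.
#'
#' @param cells Tibble with at least `cell_id` and `qc_score`.
#' @param threshold Inclusion threshold (default 0.5).
#' @param quiet Suppress the exclusion message.
#' @return The included rows, with attribute `excluded` (tibble).
#' @export
filter_cells <- function(cells, threshold = 0.5, quiet = FALSE) {
  if (!"qc_score" %in% names(cells)) {
    abort("filter_cells(): cells must carry a qc_score column")
  }
  keep <- cells$qc_score > threshold
  excluded <- cells[!keep, , drop = FALSE]
  if (!quiet && nrow(excluded) > 0) {
    message(sprintf("filter_cells(): excluded %d/%d cells (QC score <= %g): %s",
                    nrow(excluded), nrow(cells), threshold,
                    paste0(excluded$cell_id, " (",
                           signif(excluded$qc_score, 3), ")",
                           collapse = ", ")))
  }
  out <- cells[keep, , drop = FALSE]
  attr(out, "excluded") <- excluded
  out
}
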