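# Context-preserving permutation null for mutation enrichment against
# expression / accessibility tracks.

#' Split units into equal-count ordered groups
#'
#' Ranks units (genes or genomic bins) by a value and splits them into `k`
#' equal-count groups with group 1 lowest and group `k` highest. Ties are
#' broken by stable input order; an all-tied input is flagged degenerate.
#'
#' @param units Tibble with one row per unit; must contain `value_col`.
#' @param value_col Column holding the track value (default `"value"`).
#' @param k Number of groups (default 8).
#' @return `units` with an integer `group` column (1..k); attribute
#'   `degenerate` when all values tie.
#' @export
make_groups <- function(units, value_col = "value", k = 8L) {
  v <- units[[value_col]]
  if (is.null(v)) abort(paste0("make_groups(): no column '", value_col, "'"))
  v <- v[is.finite(v)]
  if (nrow(units) < k || length(v) < k) {
    abort("make_groups(): fewer units with finite values than groups")
  }
  vals <- units[[value_col]]
  rnk <- rank(vals, ties.method = "first")
  grp <- ceiling(rnk * k / nrow(units))
  out <- units |> dplyr::mutate(group = as.integer(grp))
  degenerate <- length(unique(vals)) == 1
  if (degenerate) {
    warn("make_groups(): all values tie; groups assigned by stable order")
  }
  attr(out, "degenerate") <- degenerate
  out
}

#' Context-preserving permutations of call positions
#'
#' Each permutation replaces every call's position with a uniformly drawn
#' position of the same pyrimidine trinucleotide context inside the
#' phaseable intervals, without duplicate positions within a permutation.
#' Substitution identity travels with the call, so every permuted set's
#' SBS96 context histogram equals the observed histogram exactly.
#'
#' @param calls Tibble with chrom, pos, ref, alt.
#' @param phaseable Tibble of phaseable intervals (chrom, start, end,
#'   1-based inclusive).
#' @param ref A `toy_reference`.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed (mandatory for reproducibility).
#' @param ctx_index Optional precomputed [context_position_index()] on the
#'   phaseable intervals, to amortize across calls.
#' @return Tibble: perm (1..n_perm), chrom, pos, ref, alt, context.
#' @export
permute_calls <- function(calls, phaseable, ref, n_perm = 1000L, seed,
                          ctx_index = NULL) {
  if (missing(seed)) abort("permute_calls(): seed is required")
  if (is.null(ctx_index)) {
    ctx_index <- context_position_index(ref, phaseable)
  }
  pos_by_ctx <- split(ctx_index$pos, ctx_index$context)
  ctx <- pyr_context_at(ref$sequence, calls$pos)
  need <- table(ctx)
  for (cc in names(need)) {
    avail <- length(pos_by_ctx[[cc]] %||% integer())
    if (avail < need[[cc]]) {
      abort(sprintf(
        "permute_calls(): context %s needs %d positions but only %d are phaseable",
        cc, need[[cc]], avail))
    }
  }
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_perm), function(p) {
      new_pos <- integer(nrow(calls))
      for (cc in names(need)) {
        idx <- which(ctx == cc)
        new_pos[idx] <- sample(pos_by_ctx[[cc]], length(idx),
                               replace = FALSE)
      }
      ref_b <- reference_base(ref, new_pos)
      # carry the pyrimidine-standardized substitution to the new strand
      orig_pyr_alt <- ifelse(calls$ref %in% c("C", "T"), calls$alt,
                             comp_base(calls$alt))
      alt <- ifelse(ref_b %in% c("C", "T"), orig_pyr_alt,
                    comp_base(orig_pyr_alt))
      tibble::tibble(perm = p, chrom = ref$contig_name, pos = new_pos,
                     ref = ref_b, alt = alt, context = ctx)
    })
  })
}

# sSNV density (per Mb) of positions within a set of footprints per group
group_density <- function(pos, groups) {
  fp <- IRanges::IRanges(groups$start, groups$end)
  hits <- IRanges::findOverlaps(IRanges::IRanges(pos, pos), fp,
                                select = "first")
  grp <- groups$group[hits]
  len_mb <- groups |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(mb = sum(.data$end - .data$start + 1) / 1e6,
                     .groups = "drop")
  counts <- tibble::tibble(group = grp[!is.na(grp)]) |>
    dplyr::count(.data$group)
  len_mb |>
    dplyr::left_join(counts, by = "group") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  density = .data$n / .data$mb)
}

#' Observed/expected enrichment ratios across track groups
#'
#' Computes per-group observed sSNV density, the permutation-expected
#' density (mean over permutations), their ratio with a permutation-based
#' SD, and a least-squares linear fit of the ratio against the group index
#' (Pearson R and slope P value).
#'
#' @param calls Observed calls (chrom, pos).
#' @param perms Permuted call sets from [permute_calls()].
#' @param groups Group track: tibble with group, start, end (footprints,
#'   1-based inclusive; one row per footprint interval).
#' @param min_perm Minimum permutations required for SD reporting.
#' @return Object of class `enrichment_result`: list with `groups` tibble
#'   (group, observed, expected_mean, expected_sd, ratio, ratio_sd) and
#'   scalars `R`, `p.value`, `n_perm`.
#' @export
enrichment_ratio <- function(calls, perms, groups, min_perm = 100L) {
  n_perm <- dplyr::n_distinct(perms$perm)
  if (n_perm < min_perm) {
    abort(sprintf("enrichment_ratio(): need >= %d permutations, got %d",
                  min_perm, n_perm))
  }
  obs <- group_density(calls$pos, groups)
  # one interval join for all permutations, then count by perm x group
  len_mb <- groups |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(mb = sum(.data$end - .data$start + 1) / 1e6,
                     .groups = "drop")
  hit <- IRanges::findOverlaps(IRanges::IRanges(perms$pos, perms$pos),
                               IRanges::IRanges(groups$start, groups$end),
                               select = "first")
  perm_dens <- tibble::tibble(perm = perms$perm,
                              group = groups$group[hit]) |>
    dplyr::filter(!is.na(.data$group)) |>
    dplyr::count(.data$perm, .data$group) |>
    tidyr::complete(perm = unique(perms$perm), group = len_mb$group,
                    fill = list(n = 0L)) |>
    dplyr::left_join(len_mb, by = "group") |>
    dplyr::mutate(density = .data$n / .data$mb)
  perm_stats <- perm_dens |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(expected_mean = mean(.data$density),
                     expected_sd = sd(.data$density), .groups = "drop")
  res <- obs |>
    dplyr::select("group", observed = "density") |>
    dplyr::left_join(perm_stats, by = "group")
  dead <- res$expected_mean <= 0
  if (any(dead)) {
    warn(paste0("enrichment_ratio(): group(s) with zero expected density excluded: ",
                paste(res$group[dead], collapse = ", ")))
  }
  res <- res[!dead, , drop = FALSE]
  ratio_draws <- perm_dens |>
    dplyr::left_join(res |> dplyr::select("group", "observed"),
                     by = "group") |>
    dplyr::filter(!is.na(.data$observed), .data$density > 0) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(ratio_sd = sd(.data$observed / .data$density),
                     .groups = "drop")
  res <- res |>
    dplyr::mutate(ratio = .data$observed / .data$expected_mean) |>
    dplyr::left_join(ratio_draws, by = "group")
  fit <- lm(ratio ~ group, data = res)
  R <- unname(cor(res$group, res$ratio))
  p <- summary(fit)$coefficients["group", "Pr(>|t|)"]
  structure(list(groups = res, R = R, p.value = p, n_perm = n_perm),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("<enrichment_result> ", nrow(x$groups), " groups, ", x$n_perm,
      " permutations; R = ", round(x$R, 3), ", P = ",
      signif(x$p.value, 3), "\n", sep = "")
  print(x$groups)
  invisible(x)
}

#' Fixed-width genomic bins as accessibility units
#'
#' Helper for reusing the enrichment engine with binned accessibility
#' signal instead of genes.
#'
#' @param ref A `toy_reference`.
#' @param bin_width Bin width in bp (default 10 kb).
#' @return Tibble: unit, chrom, start, end.
#' @export
genomic_bins <- function(ref, bin_width = 10000L) {
  n <- ceiling(ref$length / bin_width)
  tibble::tibble(
    unit = sprintf("bin%05d", seq_len(n)),
    chrom = ref$contig_name,
    start = as.integer((seq_len(n) - 1L) * bin_width + 1L),
    end = pmin(as.integer(seq_len(n) * bin_width), ref$length)
  )
}
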