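# Synthetic cohort generation: donors, per-cell burdens from the mixed-effects
# generative model, signature-driven mutation placement, depth profiles and
# germline variants.

#' Describe a synthetic cohort design
#'
#' Captures the generative model for per-cell somatic burden: burden/GB =
#' beta0 + beta1 * age (+ beta_I for diseased donors) + donor intercept
#' N(0, sigma_u^2) + residual N(0, sigma_e^2). Defaults reproduce the study
#' conditions: 10 control and 5 IHD donors, 5 cells each, aging rate
#' 7.90 sSNVs/GB/year and disease excess 686 sSNVs/GB.
#'
#' @param n_control_donors,n_ihd_donors Donor counts per condition.
#' @param ages_control,ages_ihd Donor ages in years; when `NULL`, control
#'   ages spread evenly over 0.5-82 years and IHD ages interleave them.
#' @param cells_per_donor Cells sequenced per donor.
#' @param beta0 Burden at age 0 (sSNVs/GB).
#' @param beta1 Aging rate (sSNVs/GB/year).
#' @param beta_I Disease excess (sSNVs/GB).
#' @param sigma_u Donor random-intercept SD (sSNVs/GB) for control donors.
#' @param sigma_u_ihd Donor random-intercept SD for diseased donors
#'   (defaults to `sigma_u`).
#' @param sigma_e Residual SD (sSNVs/GB).
#' @param signature_exposure_by_condition Named list (`control`, `IHD`) of
#'   per-signature exposure fractions, each summing to 1; `NULL` defers the
#'   choice to [generate_cohort()].
#' @param seed Integer master seed.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(n_control_donors = 10L, n_ihd_donors = 5L,
                          ages_control = NULL, ages_ihd = NULL,
                          cells_per_donor = 5L,
                          beta0 = 50, beta1 = 7.90, beta_I = 686,
                          sigma_u = 50, sigma_u_ihd = sigma_u, sigma_e = 100,
                          signature_exposure_by_condition = NULL,
                          seed = 1L) {
  if (any(c(sigma_u, sigma_u_ihd, sigma_e) < 0)) {
    abort("cohort_design(): SDs must be >= 0")
  }
  if (is.null(ages_control) && n_control_donors > 0) {
    ages_control <- seq(0.5, 82, length.out = max(n_control_donors, 2))[
      seq_len(n_control_donors)]
    if (n_control_donors == 1) ages_control <- 41
  }
  if (is.null(ages_ihd) && n_ihd_donors > 0) {
    grid <- seq(0.5, 82, length.out = n_ihd_donors + 2)
    ages_ihd <- grid[-c(1, length(grid))]
  }
  if (any(c(ages_control, ages_ihd) < 0)) {
    abort("cohort_design(): ages must be >= 0")
  }
  if (!is.null(signature_exposure_by_condition)) {
    for (cond in names(signature_exposure_by_condition)) {
      e <- signature_exposure_by_condition[[cond]]
      if (any(e < 0) || abs(sum(e) - 1) > 1e-8) {
        abort("cohort_design(): exposures must be in [0,1] and sum to 1")
      }
    }
  }
  structure(list(
    n_control_donors = as.integer(n_control_donors),
    n_ihd_donors = as.integer(n_ihd_donors),
    ages_control = ages_control, ages_ihd = ages_ihd,
    cells_per_donor = as.integer(cells_per_donor),
    beta0 = beta0, beta1 = beta1, beta_I = beta_I,
    sigma_u = sigma_u, sigma_u_ihd = sigma_u_ihd, sigma_e = sigma_e,
    signature_exposure_by_condition = signature_exposure_by_condition,
    seed = as.integer(seed)
  ), class = "cohort_design")
}

#' Donor table for a design
#' @param design A `cohort_design`.
#' @return Tibble with donor_id, age, condition, sex.
#' @export
design_donors <- function(design) {
  donors <- dplyr::bind_rows(
    tibble::tibble(
      donor_id = sprintf("C%02d", seq_len(design$n_control_donors)),
      age = design$ages_control, condition = "control"),
    tibble::tibble(
      donor_id = sprintf("I%02d", seq_len(design$n_ihd_donors)),
      age = design$ages_ihd, condition = "IHD")
  )
  donors$sex <- rep_len(c("M", "F"), nrow(donors))
  donors
}

#' Simulate per-cell somatic burdens from the generative mixed model
#'
#' Draws donor random intercepts and per-cell residuals and returns the true
#' per-cell burden (sSNVs/GB). Burdens are truncated at zero by default
#' (counts cannot be negative); signature-specific series where a near-zero
#' baseline is itself the object of study should disable truncation so the
#' Gaussian generative model is preserved exactly.
#'
#' @param design A `cohort_design`.
#' @param seed Optional seed override (defaults to `design$seed`).
#' @param truncate Truncate burdens at 0 (default TRUE).
#' @return Tibble: cell_id, donor_id, age, condition, sex,
#'   true_burden_per_gb.
#' @export
simulate_burden <- function(design, seed = NULL, truncate = TRUE) {
  stopifnot(inherits(design, "cohort_design"))
  seed <- if (is.null(seed)) design$seed else as.integer(seed)
  donors <- design_donors(design)
  withr::with_seed(seed, {
    donors$u <- rnorm(nrow(donors), 0,
                      ifelse(donors$condition == "IHD",
                             design$sigma_u_ihd, design$sigma_u))
    cells <- donors |>
      dplyr::slice(rep(seq_len(nrow(donors)), each = design$cells_per_donor)) |>
      dplyr::mutate(
        cell_id = paste0(.data$donor_id, "_c",
                         rep(seq_len(design$cells_per_donor), nrow(donors))),
        eps = rnorm(dplyr::n(), 0, design$sigma_e),
        true_burden_per_gb = design$beta0 + design$beta1 * .data$age +
          design$beta_I * (.data$condition == "IHD") + .data$u + .data$eps
      )
    if (truncate) {
      cells$true_burden_per_gb <- pmax(cells$true_burden_per_gb, 0)
    }
    cells |>
      dplyr::select("cell_id", "donor_id", "age", "condition", "sex",
                    "true_burden_per_gb")
  })
}

#' Index reference positions by pyrimidine trinucleotide context
#'
#' @param ref A `toy_reference`.
#' @param intervals Optional tibble (chrom, start, end; 1-based inclusive)
#'   restricting the index, e.g. phaseable regions.
#' @return Tibble with columns `pos` and `context` (32-way pyrimidine class).
#' @export
context_position_index <- function(ref, intervals = NULL) {
  pos <- 2:(ref$length - 1L)
  if (!is.null(intervals)) {
    keep <- rep(FALSE, ref$length)
    for (i in seq_len(nrow(intervals))) {
      keep[intervals$start[i]:intervals$end[i]] <- TRUE
    }
    pos <- pos[keep[pos]]
  }
  tibble::tibble(pos = pos, context = pyr_context_at(ref$sequence, pos))
}

#' Default phaseable intervals for a toy reference
#'
#' Splits the genome into `n_intervals` windows and keeps the central
#' `fraction` of each, emulating the patchy territory where somatic calls
#' can be validated against phased germline heterozygous sites.
#'
#' @param ref A `toy_reference`.
#' @param fraction Fraction of each window retained.
#' @param n_intervals Number of windows.
#' @return Tibble (chrom, start, end), 1-based inclusive.
#' @export
phaseable_intervals <- function(ref, fraction = 0.9, n_intervals = 10L) {
  bounds <- floor(seq(1, ref$length + 1, length.out = n_intervals + 1L))
  tibble::tibble(
    chrom = ref$contig_name,
    w_start = bounds[-length(bounds)], w_end = bounds[-1] - 1L
  ) |>
    dplyr::mutate(
      margin = floor((.data$w_end - .data$w_start + 1L) * (1 - fraction) / 2),
      start = pmax(2L, .data$w_start + .data$margin),
      end = pmin(ref$length - 1L, .data$w_end - .data$margin)
    ) |>
    dplyr::select("chrom", "start", "end")
}

# Sample positions for a set of channel draws, respecting context classes.
# ctx_index: list mapping context -> integer positions.
place_mutations <- function(channels, ctx_index, ref) {
  ctx <- channel_context(channels)
  out_pos <- integer(length(channels))
  for (cc in unique(ctx)) {
    idx <- which(ctx == cc)
    avail <- ctx_index[[cc]]
    if (is.null(avail) || length(avail) < length(idx)) {
      abort(sprintf(
        "place_mutations(): context %s has %d available positions, need %d",
        cc, length(avail %||% integer()), length(idx)))
    }
    out_pos[idx] <- sample(avail, length(idx), replace = FALSE)
  }
  ref_base <- reference_base(ref, out_pos)
  pyr_alt <- substr(channels, 5, 5)
  alt <- ifelse(ref_base %in% c("A", "G"), comp_base(pyr_alt), pyr_alt)
  tibble::tibble(
    chrom = ref$contig_name, pos = out_pos,
    ref = ref_base, alt = alt, channel = channels, context = ctx
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a full synthetic cohort with placed mutations
#'
#' Simulates per-cell burdens from the mixed-effects generative model, draws
#' each cell's mutations from the condition's signature mixture, places them
#' at context-matching positions inside phaseable intervals (without
#' replacement within a cell), and simulates binned depth profiles with a
#' contiguous zero-depth block per cell plus a germline variant set.
#'
#' @param design A `cohort_design`.
#' @param ref A `toy_reference`.
#' @param catalog Signature catalog (see [as_catalog_matrix()]). Exposures
#'   default to 100% of the first signature for both conditions when the
#'   design does not specify them.
#' @param callable_fraction Fraction of the genome callable per cell; the
#'   complement is a contiguous zero-depth block (default 0.85).
#' @param phaseable_fraction Fraction of each genomic window that is
#'   phaseable (default 0.9).
#' @param bin_size Depth profile bin size in bp.
#' @param mean_depth Mean sequencing depth across cells.
#' @param sensitivity Somatic detection sensitivity applied to expected
#'   mutation counts.
#' @param n_germline Number of germline heterozygous variants simulated.
#' @param out_dir Optional directory; when given, FASTA/VCF/TSV/BED fixtures
#'   are written and their paths returned in `$files`.
#' @return Object of class `synthetic_cohort`: list of tibbles `donors`,
#'   `cells`, `mutations`, `phaseable`, `depth_bins`, `germline`, plus
#'   `ref`, `catalog` and (optionally) `files`.
#' @export
generate_cohort <- function(design, ref, catalog,
                            callable_fraction = 0.85,
                            phaseable_fraction = 0.9,
                            bin_size = 10000L, mean_depth = 30,
                            sensitivity = 1, n_germline = 500L,
                            out_dir = NULL) {
  stopifnot(inherits(design, "cohort_design"), inherits(ref, "toy_reference"))
  catalog <- as_catalog_matrix(catalog)
  expo <- design$signature_exposure_by_condition
  if (is.null(expo)) {
    e1 <- setNames(c(1, rep(0, ncol(catalog) - 1)), colnames(catalog))
    expo <- list(control = e1, IHD = e1)
  }
  for (cond in names(expo)) {
    if (is.null(names(expo[[cond]]))) {
      names(expo[[cond]]) <- colnames(catalog)[seq_along(expo[[cond]])]
    }
  }

  cells <- simulate_burden(design)
  donors <- design_donors(design)
  phase <- phaseable_intervals(ref, fraction = phaseable_fraction)
  idx_tbl <- context_position_index(ref, phase)
  ctx_index <- split(idx_tbl$pos, idx_tbl$context)
  callable_gb <- callable_fraction * ref$length / 1e9

  n_bins <- ceiling(ref$length / bin_size)
  bin_start <- as.integer((seq_len(n_bins) - 1L) * bin_size + 1L)
  bin_end <- pmin(as.integer(seq_len(n_bins) * bin_size), ref$length)

  withr::with_seed(design$seed + 1L, {
    channel_probs <- lapply(expo, function(e) {
      p <- as.vector(catalog[, names(e), drop = FALSE] %*% e)
      p / sum(p)
    })
    muts <- vector("list", nrow(cells))
    depth_rows <- vector("list", nrow(cells))
    qc_truth <- vector("list", nrow(cells))
    for (i in seq_len(nrow(cells))) {
      cell <- cells[i, ]
      n_mut <- rpois(1, max(cell$true_burden_per_gb, 0) * callable_gb *
                       sensitivity)
      if (n_mut > 0) {
        pr <- channel_probs[[cell$condition]]
        ch <- sample(sbs96_channels(), n_mut, replace = TRUE, prob = pr)
        m <- place_mutations(ch, ctx_index, ref)
        m$cell_id <- cell$cell_id
        muts[[i]] <- m
      }
      # depth bins with a contiguous zero-depth block
      cell_depth <- max(5, rnorm(1, mean_depth, 3))
      depth <- rnbinom(n_bins, mu = cell_depth, size = 30)
      n_zero <- round((1 - callable_fraction) * n_bins)
      if (n_zero > 0) {
        z0 <- sample.int(n_bins - n_zero + 1L, 1)
        depth[z0:(z0 + n_zero - 1L)] <- 0L
      }
      depth_rows[[i]] <- tibble::tibble(
        cell_id = cell$cell_id, chrom = ref$contig_name,
        start = bin_start, end = bin_end, depth = depth
      )
      qc_truth[[i]] <- tibble::tibble(
        cell_id = cell$cell_id, mean_depth = mean(depth),
        coverage = mean(depth > 0), n_mutations = n_mut,
        callable_gb = callable_gb
      )
    }
    mutations <- dplyr::bind_rows(muts)
    if (nrow(mutations) > 0) {
      mutations <- mutations |>
        dplyr::relocate("cell_id") |>
        dplyr::distinct(.data$cell_id, .data$pos, .keep_all = TRUE)
    }
    depth_bins <- dplyr::bind_rows(depth_rows)
    cells <- cells |> dplyr::left_join(dplyr::bind_rows(qc_truth), by = "cell_id")

    gpos <- sample(2:(ref$length - 1L), n_germline, replace = FALSE)
    gref <- reference_base(ref, gpos)
    galt <- vapply(gref, function(b) sample(setdiff(BASES, b), 1), character(1))
    germline <- tibble::tibble(
      chrom = ref$contig_name, pos = sort(gpos),
      ref = gref[order(gpos)], alt = galt[order(gpos)]
    )
  })

  out <- structure(list(
    design = design, donors = donors, cells = cells, mutations = mutations,
    phaseable = phase, depth_bins = depth_bins, germline = germline,
    ref = ref, catalog = catalog, callable_gb = callable_gb
  ), class = "synthetic_cohort")

  if (!is.null(out_dir)) {
    out$files <- write_cohort(out, out_dir)
  }
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", nrow(x$cells), " cells / ", nrow(x$donors),
      " donors, ", nrow(x$mutations), " somatic mutations on ",
      x$ref$contig_name, " (", x$ref$length, " bp)\n", sep = "")
  invisible(x)
}

#' Write cohort fixtures to disk
#'
#' Emits FASTA (reference), per-cell somatic VCFs, a germline VCF, metadata
#' TSV, phaseable BED (0-based half-open) and the binned depth TSV.
#'
#' @param cohort A `synthetic_cohort`.
#' @param out_dir Output directory (created if needed).
#' @return Named list of file paths.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  files$fasta <- file.path(out_dir, "reference.fa")
  write_reference_fasta(cohort$ref, files$fasta)
  files$metadata <- file.path(out_dir, "cells.tsv")
  readr::write_tsv(cohort$cells, files$metadata)
  files$phaseable <- file.path(out_dir, "phaseable.bed")
  write_bed(cohort$phaseable, files$phaseable)
  files$depth <- file.path(out_dir, "depth_bins.tsv")
  readr::write_tsv(cohort$depth_bins, files$depth)
  files$germline_vcf <- file.path(out_dir, "germline.vcf")
  write_calls_vcf(cohort$germline, files$germline_vcf, sample = "bulk")
  files$catalog <- file.path(out_dir, "catalog.tsv")
  write_signature_catalog(cohort$catalog, files$catalog)
  vcf_dir <- file.path(out_dir, "cells")
  dir.create(vcf_dir, showWarnings = FALSE)
  files$cell_vcfs <- vapply(unique(cohort$cells$cell_id), function(cid) {
    p <- file.path(vcf_dir, paste0(cid, ".vcf"))
    write_calls_vcf(cohort$mutations |> dplyr::filter(.data$cell_id == cid),
                    p, sample = cid)
    p
  }, character(1))
  files
}

#' Simulate a cell x gene count matrix with donor structure
#'
#' Negative-binomial counts with optional condition-level differential
#' expression and injectable donor effects, used to exercise the
#' leave-one-out consensus differential-expression procedure.
#'
#' @param n_donors_per_condition Donors per condition (>= 2).
#' @param cells_per_donor Cells per donor.
#' @param n_genes Number of genes.
#' @param de_genes Optional tibble with columns `gene` (index or name),
#'   `lfc` (natural-log fold change), `condition` and optional `donor_id`
#'   restricting the shift to one donor.
#' @param donor_effect_sd SD of per-gene, per-donor log-scale random effects.
#' @param dispersion Negative-binomial size parameter.
#' @param seed Integer seed.
#' @return List with `counts` (genes x cells integer matrix, dimnames set)
#'   and `meta` (tibble: cell_id, donor_id, condition, cell_type).
#' @export
simulate_counts_matrix <- function(n_donors_per_condition = 3L,
                                   cells_per_donor = 100L,
                                   n_genes = 200L, de_genes = NULL,
                                   donor_effect_sd = 0, dispersion = 10,
                                   seed = 1L) {
  if (n_donors_per_condition < 2) {
    abort("simulate_counts_matrix(): need >= 2 donors per condition")
  }
  genes <- sprintf("g%04d", seq_len(n_genes))
  if (!is.null(de_genes)) {
    if (is.numeric(de_genes$gene)) {
      if (any(de_genes$gene < 1 | de_genes$gene > n_genes)) {
        abort("simulate_counts_matrix(): de_genes indexes an unknown gene")
      }
      de_genes$gene <- genes[de_genes$gene]
    } else if (!all(de_genes$gene %in% genes)) {
      abort("simulate_counts_matrix(): de_genes names an unknown gene")
    }
  }
  donors <- c(sprintf("C%02d", seq_len(n_donors_per_condition)),
              sprintf("I%02d", seq_len(n_donors_per_condition)))
  cond <- rep(c("control", "IHD"), each = n_donors_per_condition)
  meta <- tibble::tibble(
    donor_id = rep(donors, each = cells_per_donor),
    condition = rep(cond, each = cells_per_donor)
  ) |>
    dplyr::mutate(cell_id = paste0(.data$donor_id, "_n", dplyr::row_number()),
                  cell_type = "cardiomyocyte") |>
    dplyr::relocate("cell_id")

  withr::with_seed(seed, {
    base <- exp(rnorm(n_genes, log(5), 1))
    counts <- matrix(0L, n_genes, nrow(meta),
                     dimnames = list(genes, meta$cell_id))
    for (d in donors) {
      cells_d <- which(meta$donor_id == d)
      cond_d <- meta$condition[cells_d[1]]
      mu <- base
      if (donor_effect_sd > 0) {
        mu <- mu * exp(rnorm(n_genes, 0, donor_effect_sd))
      }
      if (!is.null(de_genes)) {
        donor_col <- if ("donor_id" %in% names(de_genes)) {
          de_genes$donor_id
        } else {
          rep(NA_character_, nrow(de_genes))
        }
        hit <- de_genes$condition == cond_d &
          (is.na(donor_col) | donor_col == d)
        if (any(hit)) {
          gi <- match(de_genes$gene[hit], genes)
          mu[gi] <- mu[gi] * exp(de_genes$lfc[hit])
        }
      }
      counts[, cells_d] <- matrix(
        rnbinom(n_genes * length(cells_d), mu = mu, size = dispersion),
        n_genes, length(cells_d))
    }
    list(counts = counts, meta = meta)
  })
}
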