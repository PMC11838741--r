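# End-to-end orchestration over the synthetic cohort with deterministic
# per-stage seeds and a machine-readable run report.

# stable per-stage seed derived from the master seed and the stage name
stage_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  as.integer((as.numeric(master) * 7919 + h) %% .Machine$integer.max)
}

default_config <- function() {
  list(
    out_dir = NULL, seed = 1L,
    ref_length = 2e5, gc_fraction = 0.41, n_genes = 10L,
    n_control_donors = 4L, n_ihd_donors = 3L, cells_per_donor = 3L,
    n_signatures = 4L,
    qc_threshold = 0.5, trim = c(0.25, 0.75),
    n_perm = 200L, n_groups = 8L,
    up_lfc = 0.30, down_lfc = 0.25, min_pct = 0.1,
    genome_gb = diploid_genome_gb(),
    counts_genes = 120L, counts_cells_per_donor = 60L,
    counts_donors_per_condition = 3L,
    stages = c("synth", "qc", "burden", "signatures", "enrichment",
               "selection", "deg")
  )
}

#' Validate a pipeline run configuration
#'
#' @param config Named list or path to a YAML file; unknown keys are
#'   rejected, referenced paths must exist, and defaults fill the rest.
#' @return The completed config list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort(paste0("validate_config(): config file not found: ", config))
    }
    config <- yaml::read_yaml(config)
  }
  defaults <- default_config()
  unknown <- setdiff(names(config), c(names(defaults), "catalog"))
  if (length(unknown) > 0) {
    abort(paste0("validate_config(): unknown config keys: ",
                 paste(unknown, collapse = ", ")))
  }
  out <- utils::modifyList(defaults, config)
  if (is.null(out$out_dir)) abort("validate_config(): out_dir is required")
  if (!is.null(config$catalog) && !file.exists(config$catalog)) {
    abort(paste0("validate_config(): catalog file not found: ",
                 config$catalog))
  }
  out
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes the stages in dependency order (synthesis, amplification QC,
#' burden estimation and mixed-model fits, signature refit and de novo
#' extraction, permutation enrichment, selection statistics, LOO
#' differential expression), writes stage outputs under `out_dir` and
#' returns a run report with the seeds, thresholds and MD5 checksums of
#' every output file. Rerunning with an identical config reproduces the
#' checksums.
#'
#' @param config List or YAML path accepted by [validate_config()].
#' @return The run report (list), invisibly written as
#'   `run_report.json` in `out_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(config = cfg[setdiff(names(cfg), "out_dir")],
                 stages = list(), files = list())
  t0 <- Sys.time()
  outputs <- character()
  log_line <- function(...) message(sprintf(...))
  save_tsv <- function(x, name) {
    p <- file.path(cfg$out_dir, name)
    readr::write_tsv(x, p)
    outputs <<- c(outputs, p)
    p
  }

  stage_on <- function(s) s %in% cfg$stages

  # -- synth ---------------------------------------------------------------
  catalog <- if (!is.null(cfg$catalog)) {
    read_signature_catalog(cfg$catalog)
  } else {
    synthetic_signature_catalog(cfg$n_signatures,
                                seed = stage_seed(cfg$seed, "catalog"))
  }
  stopifnot(stage_on("synth"))
  seed_synth <- stage_seed(cfg$seed, "synth")
  log_line("[synth] seed %d", seed_synth)
  ref <- generate_reference(cfg$ref_length, cfg$gc_fraction,
                            seed = seed_synth)
  models <- generate_gene_models(ref, cfg$n_genes, seed = seed_synth)
  sig_names <- colnames(catalog)
  expo_ctrl <- setNames(rep(0, length(sig_names)), sig_names)
  expo_ctrl[1] <- 1
  expo_ihd <- setNames(rep(1 / length(sig_names), length(sig_names)),
                       sig_names)
  design <- cohort_design(
    n_control_donors = cfg$n_control_donors, n_ihd_donors = cfg$n_ihd_donors,
    cells_per_donor = cfg$cells_per_donor,
    # toy genome: scale burden so each cell carries a workable call count
    beta0 = 2e5, beta1 = 2e4, beta_I = 8e5, sigma_u = 5e4, sigma_e = 1e5,
    signature_exposure_by_condition = list(control = expo_ctrl,
                                           IHD = expo_ihd),
    seed = seed_synth)
  cohort <- generate_cohort(design, ref, catalog,
                            out_dir = file.path(cfg$out_dir, "fixtures"))
  outputs <- c(outputs, unlist(cohort$files, use.names = FALSE))
  report$stages$synth <- list(seed = seed_synth,
                              n_cells = nrow(cohort$cells),
                              n_mutations = nrow(cohort$mutations))

  # -- qc ------------------------------------------------------------------
  cells_meta <- cohort$cells
  if (stage_on("qc")) {
    qc <- score_cells(cohort$depth_bins)
    included <- filter_cells(qc, cfg$qc_threshold, quiet = TRUE)
    qc$included <- qc$qc_score > cfg$qc_threshold
    save_tsv(qc, "qc_scores.tsv")
    report$stages$qc <- list(threshold = cfg$qc_threshold,
                             n_included = nrow(included))
    cells_meta <- cells_meta |>
      dplyr::semi_join(included, by = "cell_id")
  }

  # -- burden + fits -------------------------------------------------------
  if (stage_on("burden")) {
    burdens <- purrr::map_dfr(seq_len(nrow(cells_meta)), function(i) {
      cid <- cells_meta$cell_id[i]
      prof <- cohort$depth_bins |> dplyr::filter(.data$cell_id == cid)
      calls <- cohort$mutations |> dplyr::filter(.data$cell_id == cid)
      sens <- estimate_sensitivity(cohort$germline, cohort$germline, prof,
                                   trim = cfg$trim, method = "refined")
      dplyr::bind_cols(
        cells_meta[i, ],
        genome_burden(calls, sens, depth_profile = prof,
                      genome_gb = cfg$genome_gb))
    })
    save_tsv(burdens |>
               dplyr::select("cell_id", "donor_id", "age", "condition",
                             "n_calls", "effective_callable_gb",
                             "burden_per_gb", "burden_per_cell"),
             "burden.tsv")
    fit1 <- fit_burden_model(
      burdens |> dplyr::filter(.data$condition == "control"), model = 1)
    fit2 <- fit_burden_model(burdens, model = 2)
    fits <- dplyr::bind_rows(
      tidy(fit1) |> dplyr::mutate(model = 1),
      tidy(fit2) |> dplyr::mutate(model = 2))
    save_tsv(fits, "burden_fits.tsv")
    report$stages$burden <- list(trim = cfg$trim,
                                 genome_gb = cfg$genome_gb,
                                 n_cells = nrow(burdens))
  }

  # -- signatures ----------------------------------------------------------
  if (stage_on("signatures")) {
    seed_sig <- stage_seed(cfg$seed, "signatures")
    spec_all <- build_spectrum(cohort$mutations, ref)
    expos <- fit_exposures(spec_all, catalog)
    save_tsv(expos, "exposures.tsv")
    sm <- spectrum_matrix(cohort$mutations, ref)
    nm <- extract_denovo(sm, ranks = 2:4, n_restarts = 10, seed = seed_sig)
    save_tsv(nm$diagnostics, "nmf_diagnostics.tsv")
    decomp <- decompose_denovo(nm$signatures, catalog)
    save_tsv(decomp, "denovo_decomposition.tsv")
    report$stages$signatures <- list(seed = seed_sig, chosen_rank = nm$rank,
                                     refit_residual = attr(expos, "residual"))
  }

  # -- enrichment ----------------------------------------------------------
  if (stage_on("enrichment")) {
    seed_enr <- stage_seed(cfg$seed, "enrichment")
    bins <- genomic_bins(ref, bin_width = 10000L)
    track <- withr::with_seed(seed_enr,
      bins |> dplyr::mutate(value = runif(dplyr::n())))
    groups <- make_groups(track, "value", k = cfg$n_groups)
    perms <- permute_calls(cohort$mutations, cohort$phaseable, ref,
                           n_perm = cfg$n_perm, seed = seed_enr)
    enr <- enrichment_ratio(cohort$mutations, perms, groups,
                            min_perm = min(cfg$n_perm, 100L))
    save_tsv(enr$groups, "enrichment.tsv")
    report$stages$enrichment <- list(seed = seed_enr, n_perm = cfg$n_perm,
                                     R = enr$R, p.value = enr$p.value)
  }

  # -- selection -----------------------------------------------------------
  if (stage_on("selection")) {
    som <- cohort$mutations |>
      annotate_region(models) |>
      classify_functional(models, ref)
    germ <- cohort$germline |>
      annotate_region(models) |>
      classify_functional(models, ref)
    save_tsv(som |> dplyr::select("cell_id", "chrom", "pos", "ref", "alt",
                                  "region", "functional"),
             "annotated_somatic.tsv")
    sel <- selection_ratios(som, germ)
    save_tsv(sel, "selection.tsv")
    report$stages$selection <- as.list(setNames(sel$p.value, sel$comparison))
  }

  # -- deg -----------------------------------------------------------------
  if (stage_on("deg")) {
    seed_deg <- stage_seed(cfg$seed, "deg")
    de <- tibble::tibble(gene = 1:4, lfc = c(1.2, 1.0, -1.2, -1.0),
                         condition = "IHD")
    sim <- simulate_counts_matrix(
      n_donors_per_condition = cfg$counts_donors_per_condition,
      cells_per_donor = cfg$counts_cells_per_donor,
      n_genes = cfg$counts_genes, de_genes = de, seed = seed_deg)
    loo <- loo_consensus(sim$counts, sim$meta,
                         up_threshold = cfg$up_lfc,
                         down_threshold = cfg$down_lfc,
                         min_pct = cfg$min_pct)
    save_tsv(loo$iterations, "loo_iterations.tsv")
    save_tsv(tibble::tibble(
      gene = c(loo$up, loo$down),
      direction = rep(c("up", "down"), c(length(loo$up), length(loo$down)))),
      "loo_consensus.tsv")
    report$stages$deg <- list(seed = seed_deg,
                              n_iterations = nrow(loo$iterations),
                              n_up = length(loo$up),
                              n_down = length(loo$down))
  }

  report$files <- as.list(tools::md5sum(sort(unique(outputs))))
  report$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(report, file.path(cfg$out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}
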