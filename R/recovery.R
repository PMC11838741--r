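# Parameter-recovery experiments: simulate cohorts from the generative
# mixed model and refit, the package's main validation device.

#' Simulate-and-refit recovery of a burden model fixed effect
#'
#' Repeatedly simulates per-cell burdens from a cohort design's generative
#' model (Gaussian, untruncated, so the fitted model matches the simulated
#' one exactly) and refits the requested burden model, collecting the
#' estimate of one fixed-effect term per replicate.
#'
#' @param design A [cohort_design()].
#' @param model Burden model id (1, 2 or 3).
#' @param term Fixed-effect term to extract (`"age"` or `"conditionIHD"`).
#' @param n_seeds Number of simulation replicates.
#' @param base_seed Integer; replicate r uses seed `base_seed + r`.
#' @param response Response column written into the simulated data.
#' @return Tibble: seed, estimate, p.value, fallback.
#' @export
simulate_model_recovery <- function(design, model, term, n_seeds = 20L,
                                    base_seed = 0L,
                                    response = "burden_per_gb") {
  purrr::map_dfr(seq_len(n_seeds), function(r) {
    cells <- simulate_burden(design, seed = base_seed + r, truncate = FALSE)
    cells[[response]] <- cells$true_burden_per_gb
    fit <- suppressWarnings(suppressMessages(
      fit_burden_model(cells, model = model, response = response)))
    td <- tidy(fit)
    i <- match(term, td$term)
    if (is.na(i)) {
      abort(paste0("simulate_model_recovery(): term '", term,
                   "' not in the fitted model"))
    }
    tibble::tibble(seed = base_seed + r, estimate = td$estimate[i],
                   p.value = td$p.value[i], fallback = fit$fallback)
  })
}
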