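# Genome-wide burden estimation (trimmed-mean with zero-depth refinement)
# and linear mixed-effects burden models.

#' Estimate depth-stratified somatic detection sensitivity
#'
#' Sensitivity is the fraction of known germline heterozygous sites
#' recovered by single-cell calling, estimated per depth stratum inside the
#' trimmed (central) part of the depth distribution. The `standard` method
#' takes trim quantiles over all bins; when a large zero-depth block drags
#' the lower quantile to zero the trimmed region is undefined and the
#' profile comes back empty. The `refined` method excludes zero-depth bins
#' before taking quantiles, recovering cells whose only failure mode is
#' missing territory.
#'
#' @param recovered Tibble of germline sites recovered in the cell
#'   (chrom, pos).
#' @param truth Tibble of all germline heterozygous sites (chrom, pos).
#' @param depth_profile Tibble with chrom, start, end, depth for one cell.
#' @param trim Lower/upper trim quantiles (default central 50%).
#' @param n_strata Number of equal-count depth strata inside the trim.
#' @param method `"standard"` or `"refined"`.
#' @return Tibble (class `sensitivity_profile`): stratum, depth_lo,
#'   depth_hi, n_truth, n_recovered, sensitivity, length_bp; attribute
#'   `method`.
#' @export
estimate_sensitivity <- function(recovered, truth, depth_profile,
                                 trim = c(0.25, 0.75), n_strata = 4L,
                                 method = c("standard", "refined")) {
  method <- match.arg(method)
  stopifnot(length(trim) == 2, trim[1] < trim[2])
  depths <- depth_profile$depth
  basis <- if (method == "refined") depths[depths > 0] else depths
  if (length(basis) == 0) abort("estimate_sensitivity(): no usable bins")
  qs <- quantile(basis, trim, names = FALSE, type = 1)
  empty <- tibble::tibble(
    stratum = integer(), depth_lo = numeric(), depth_hi = numeric(),
    n_truth = integer(), n_recovered = integer(), sensitivity = numeric(),
    length_bp = numeric()
  )
  if (qs[1] <= 0) {
    # zero-depth territory dominates the lower tail: the trimmed region is
    # undefined under the standard calculation
    return(structure(empty, method = method, class = c("sensitivity_profile",
                                                       class(empty))))
  }
  in_trim <- depths >= qs[1] & depths <= qs[2] & depths > 0
  bins <- depth_profile[in_trim, , drop = FALSE]
  if (nrow(bins) == 0) {
    return(structure(empty, method = method, class = c("sensitivity_profile",
                                                       class(empty))))
  }
  # equal-count strata by depth rank
  n_strata <- max(1L, min(n_strata, dplyr::n_distinct(bins$depth)))
  brk <- unique(quantile(bins$depth, seq(0, 1, length.out = n_strata + 1),
                         names = FALSE, type = 1))
  stratum <- findInterval(bins$depth, brk, rightmost.closed = TRUE,
                          all.inside = TRUE)

  site_stratum <- function(sites) {
    idx <- IRanges::findOverlaps(
      IRanges::IRanges(sites$pos, sites$pos),
      IRanges::IRanges(bins$start, bins$end), select = "first")
    stratum[idx]
  }

  tr_stratum <- site_stratum(truth)
  rec_key <- paste(recovered$chrom, recovered$pos)
  is_rec <- paste(truth$chrom, truth$pos) %in% rec_key

  usable <- !is.na(tr_stratum)
  if (!any(usable)) {
    abort("estimate_sensitivity(): no germline sites in the trimmed region")
  }
  out <- tibble::tibble(stratum = tr_stratum[usable],
                        recovered = is_rec[usable]) |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(n_truth = dplyr::n(),
                     n_recovered = sum(.data$recovered), .groups = "drop") |>
    dplyr::mutate(sensitivity = .data$n_recovered / .data$n_truth)
  len <- tibble::tibble(stratum = stratum,
                        len = bins$end - bins$start + 1) |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(length_bp = sum(.data$len), .groups = "drop")
  bounds <- tibble::tibble(stratum = stratum, depth = bins$depth) |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(depth_lo = min(.data$depth), depth_hi = max(.data$depth),
                     .groups = "drop")
  out <- out |>
    dplyr::left_join(len, by = "stratum") |>
    dplyr::left_join(bounds, by = "stratum") |>
    dplyr::select("stratum", "depth_lo", "depth_hi", "n_truth",
                  "n_recovered", "sensitivity", "length_bp") |>
    dplyr::arrange(.data$stratum)
  structure(out, method = method,
            class = c("sensitivity_profile", class(out)))
}

#' Sensitivity-corrected genome-wide burden
#'
#' Extrapolates the somatic calls observed in the trimmed depth strata to a
#' genome-wide burden: burden/GB = calls / sum_s(sensitivity_s x length_s),
#' with the per-cell count obtained by multiplying by the diploid genome
#' size constant (see [diploid_genome_gb()]).
#'
#' @param calls Either a count of calls within the profiled strata, or a
#'   tibble of calls (chrom, pos) which is then restricted to the strata.
#' @param sensitivity A `sensitivity_profile` (with its depth bins implied
#'   by `depth_profile` used to build it; pass the same bins via
#'   `depth_profile` when `calls` is a tibble).
#' @param depth_profile Depth bins, required when `calls` is a tibble.
#' @param genome_gb Diploid genome size in GB for the per-cell conversion.
#' @return One-row tibble: n_calls, effective_callable_gb, burden_per_gb,
#'   burden_per_cell, method.
#' @export
genome_burden <- function(calls, sensitivity, depth_profile = NULL,
                          genome_gb = diploid_genome_gb()) {
  method <- attr(sensitivity, "method") %||% "standard"
  effective_gb <- sum(sensitivity$sensitivity * sensitivity$length_bp) / 1e9
  if (nrow(sensitivity) == 0 || effective_gb <= 0) {
    abort(paste0(
      "genome_burden(): effective callable genome is zero under the '",
      method, "' method; for cells failing only through zero-depth ",
      "territory, retry with estimate_sensitivity(method = 'refined')"))
  }
  if (is.data.frame(calls)) {
    if (is.null(depth_profile)) {
      abort("genome_burden(): depth_profile required when calls is a tibble")
    }
    in_trim <- depth_profile$depth >= min(sensitivity$depth_lo) &
      depth_profile$depth <= max(sensitivity$depth_hi) &
      depth_profile$depth > 0
    bins <- depth_profile[in_trim, , drop = FALSE]
    o <- IRanges::findOverlaps(
      IRanges::IRanges(calls$pos, calls$pos),
      IRanges::IRanges(bins$start, bins$end), select = "first")
    n_calls <- sum(!is.na(o))
  } else {
    n_calls <- as.numeric(calls)
  }
  tibble::tibble(
    n_calls = n_calls,
    effective_callable_gb = effective_gb,
    burden_per_gb = n_calls / effective_gb,
    burden_per_cell = n_calls / effective_gb * genome_gb,
    method = method
  )
}

#' Per-cell to per-GB burden conversion
#' @param burden_per_gb Burden in sSNVs/GB.
#' @param genome_gb Diploid genome size in GB.
#' @return Burden per cell.
#' @export
burden_per_cell <- function(burden_per_gb, genome_gb = diploid_genome_gb()) {
  burden_per_gb * genome_gb
}

#' Fit a burden model (linear mixed-effects or linear regression)
#'
#' Model 1 regresses burden on age with a random donor intercept; model 2
#' adds the disease-condition fixed effect; model 3 drops the random term
#' (ordinary linear regression). Mixed models are fitted by maximum
#' likelihood with Satterthwaite-approximate t-tests for the fixed effects.
#' Singular random-intercept fits (variance estimated at the boundary, or
#' below 1e-8 of the residual variance, or Satterthwaite producing no
#' P value) trigger an automatic fallback to the corresponding linear
#' regression, flagged in the result.
#'
#' @param data Tibble with columns `donor_id`, `age`, optionally
#'   `condition` (control/IHD) and covariates, plus the response.
#' @param model 1, 2 or 3.
#' @param response Response column (default `burden_per_gb`).
#' @param covariates Character vector of additional fixed-effect columns.
#' @return Object of class `burden_fit`; see [tidy.burden_fit()] and
#'   [glance.burden_fit()].
#' @export
fit_burden_model <- function(data, model = 1, response = "burden_per_gb",
                             covariates = character()) {
  stopifnot(model %in% 1:3)
  if (!response %in% names(data)) {
    abort(paste0("fit_burden_model(): no response column '", response, "'"))
  }
  if (dplyr::n_distinct(data$donor_id) < 2) {
    abort("fit_burden_model(): need >= 2 donors")
  }
  fixed <- "age"
  if (model == 2) {
    if (dplyr::n_distinct(data$condition) < 2) {
      abort("fit_burden_model(): model 2 requires both conditions present")
    }
    fixed <- c(fixed, "condition")
  }
  if ("condition" %in% names(data)) {
    data$condition <- factor(data$condition,
                             levels = intersect(c("control", "IHD"),
                                                unique(data$condition)))
  }
  fixed <- c(fixed, covariates)
  rhs <- paste(fixed, collapse = " + ")
  f_mixed <- as.formula(paste(response, "~", rhs, "+ (1 | donor_id)"))
  f_lin <- as.formula(paste(response, "~", rhs))

  fit_lm <- function(fallback) {
    fit <- lm(f_lin, data = data)
    structure(list(fit = fit, model = model, formula = f_lin,
                   mixed = FALSE, fallback = fallback, singular = NA,
                   data = data),
              class = "burden_fit")
  }
  if (model == 3) return(fit_lm(fallback = FALSE))

  fit <- tryCatch(
    suppressMessages(lmerTest::lmer(f_mixed, data = data, REML = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) return(fit_lm(fallback = TRUE))

  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma_u2 <- vc$vcov[vc$grp == "donor_id"]
  sigma2 <- vc$vcov[vc$grp == "Residual"]
  singular <- lme4::isSingular(fit, tol = 1e-5) ||
    sigma_u2 < 1e-8 * sigma2
  co <- tryCatch(summary(fit)$coefficients, error = function(e) NULL)
  bad_p <- is.null(co) || !"Pr(>|t|)" %in% colnames(co) ||
    any(!is.finite(co[, "Pr(>|t|)"]))
  if (singular && bad_p) return(fit_lm(fallback = TRUE))
  if (is.null(co)) return(fit_lm(fallback = TRUE))

  structure(list(fit = fit, model = model, formula = f_mixed, mixed = TRUE,
                 fallback = FALSE, singular = singular, data = data),
            class = "burden_fit")
}

#' @export
print.burden_fit <- function(x, ...) {
  cat("<burden_fit> model ", x$model,
      if (x$fallback) " (fallback to linear regression)" else "",
      if (isTRUE(x$singular)) " [singular random effect]" else "",
      "\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' Tidy a burden model fit
#'
#' @param x A `burden_fit`.
#' @param ... Unused.
#' @return Tibble: term, estimate, std.error, df, statistic, p.value. For
#'   mixed fits, df is the Satterthwaite approximation; for linear fits the
#'   residual df. A `normal` approximation flag column is added when
#'   Satterthwaite df were unavailable and a normal approximation was used.
#' @export
tidy.burden_fit <- function(x, ...) {
  if (x$mixed) {
    co <- tryCatch(summary(x$fit)$coefficients, error = function(e) NULL)
    if (!is.null(co) && "df" %in% colnames(co) &&
        all(is.finite(co[, "df"]))) {
      return(tibble::tibble(
        term = rownames(co), estimate = unname(co[, "Estimate"]),
        std.error = unname(co[, "Std. Error"]), df = unname(co[, "df"]),
        statistic = unname(co[, "t value"]),
        p.value = unname(co[, "Pr(>|t|)"])
      ))
    }
    # normal-approximation fallback, flagged via df = Inf
    co <- lme4::fixef(x$fit)
    se <- sqrt(diag(as.matrix(stats::vcov(x$fit))))
    z <- co / se
    warn("tidy.burden_fit(): Satterthwaite df unavailable; normal approximation used")
    return(tibble::tibble(
      term = names(co), estimate = unname(co), std.error = unname(se),
      df = Inf, statistic = unname(z),
      p.value = 2 * stats::pnorm(-abs(unname(z)))
    ))
  }
  co <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(co), estimate = unname(co[, "Estimate"]),
    std.error = unname(co[, "Std. Error"]), df = x$fit$df.residual,
    statistic = unname(co[, "t value"]), p.value = unname(co[, "Pr(>|t|)"])
  )
}

#' One-row summary of a burden model fit
#'
#' @param x A `burden_fit`.
#' @param ... Unused.
#' @return Tibble with sigma_u (donor intercept SD), sigma (residual SD),
#'   logLik, AIC, nobs, model, fallback and singular flags.
#' @export
glance.burden_fit <- function(x, ...) {
  if (x$mixed) {
    vc <- as.data.frame(lme4::VarCorr(x$fit))
    sigma_u <- sqrt(vc$vcov[vc$grp == "donor_id"])
    sigma <- sqrt(vc$vcov[vc$grp == "Residual"])
  } else {
    sigma_u <- 0
    sigma <- summary(x$fit)$sigma
  }
  tibble::tibble(
    sigma_u = sigma_u, sigma = sigma,
    logLik = as.numeric(logLik(x$fit)), AIC = AIC(x$fit),
    nobs = nrow(x$data), model = x$model,
    fallback = x$fallback, singular = isTRUE(x$singular)
  )
}

#' Fit a burden model adjusted for a technical covariate
#'
#' Adds a per-cell technical metric (e.g. MAPD, CoV, depth or coverage) as a
#' fixed effect so the age and condition effects are reported net of it.
#'
#' @param data Model data as in [fit_burden_model()].
#' @param covariate Name of the covariate column.
#' @param model 1 or 2.
#' @param response Response column.
#' @return A `burden_fit`.
#' @export
adjust_covariate <- function(data, covariate, model = 2,
                             response = "burden_per_gb") {
  if (!covariate %in% names(data)) {
    abort(paste0("adjust_covariate(): no covariate column '", covariate, "'"))
  }
  x <- data[[covariate]]
  if (!is.numeric(x) || any(!is.finite(x))) {
    abort("adjust_covariate(): covariate must be numeric and finite")
  }
  if (sd(x) == 0) abort("adjust_covariate(): covariate is constant")
  if (model == 2 && "condition" %in% names(data)) {
    ind <- as.numeric(data$condition == "IHD")
    if (sd(ind) > 0 && abs(cor(x, ind)) >= 1 - 1e-12) {
      abort("adjust_covariate(): covariate is collinear with condition")
    }
  }
  fit_burden_model(data, model = model, response = response,
                   covariates = covariate)
}
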