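test_that("substitution classification standardizes to the pyrimidine strand", {
  x <- classify_substitution("C", "A", "A", "A")
  expect_equal(x$channel, "A[C>A]A")
  # purine reference reverse-complements: T[G>T]T -> A[C>A]A
  y <- classify_substitution("G", "T", "T", "T")
  expect_equal(y$channel, "A[C>A]A")
  # CpG status from the standardized downstream base
  cpg <- classify_substitution(c("C", "C"), c("T", "T"), c("A", "A"),
                               c("G", "A"))
  expect_equal(cpg$class, c("C>T at CpG", "C>T at non-CpG"))

  expect_error(classify_substitution("N", "A", "C", "C"), "ambiguity")
  expect_error(classify_substitution("C", "C", "A", "A"), "differ")
})

test_that("classification is invariant under reverse complement", {
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (r in bases) for (a in setdiff(bases, r)) {
    for (u in bases) for (d in bases) {
      fwd <- classify_substitution(r, a, u, d)
      rev <- classify_substitution(comp[[r]], comp[[a]], comp[[d]], comp[[u]])
      expect_equal(fwd$channel, rev$channel)
      expect_equal(fwd$class, rev$class)
    }
  }
})

test_that("spectra conserve counts and read context from the reference", {
  ref <- fx_ref()
  empty <- build_spectrum(tibble::tibble(chrom = character(), pos = integer(),
                                         ref = character(), alt = character()),
                          ref)
  expect_true(all(empty$count == 0))

  # single call occupies exactly one channel
  idx <- context_position_index(ref)
  p <- idx$pos[idx$context == "ACA"][1]
  b <- reference_base(ref, p)
  call1 <- tibble::tibble(chrom = "chrS", pos = p, ref = b,
                          alt = ifelse(b == "C", "A", "T"))
  sp1 <- build_spectrum(call1, ref)
  expect_equal(sum(sp1$count), 1)
  expect_equal(sum(sp1$count > 0), 1)

  # REF mismatch and edge calls are rejected
  expect_error(build_spectrum(tibble::tibble(chrom = "chrS", pos = p,
                                             ref = setdiff(c("C", "G"), b)[1],
                                             alt = "T"), ref),
               "does not match")
  expect_error(build_spectrum(tibble::tibble(chrom = "chrS", pos = 1L,
                                             ref = "A", alt = "C"), ref),
               "edge")
})

test_that("sampled spectra converge to their generating signature", {
  ref <- fx_ref()
  cat4 <- fx_catalog()
  d <- cohort_design(n_control_donors = 1, n_ihd_donors = 0,
                     cells_per_donor = 1, beta0 = 1.5e7, beta1 = 0,
                     sigma_u = 0, sigma_e = 0,
                     signature_exposure_by_condition = list(
                       control = setNames(c(0, 1, 0, 0), colnames(cat4)),
                       IHD = setNames(c(0, 1, 0, 0), colnames(cat4))),
                     seed = 13)
  co <- generate_cohort(d, ref, cat4)
  expect_gt(nrow(co$mutations), 500)
  sp <- build_spectrum(co$mutations, ref)
  expect_gte(cosine_sim(sp$count, cat4[, 2]), 0.97)

  cls <- substitution_classes(sp)
  expect_equal(sum(cls$count), nrow(co$mutations))
  expect_setequal(cls$class, c("C>A", "C>G", "C>T at CpG", "C>T at non-CpG",
                               "T>A", "T>C", "T>G"))
})

test_that("transcriptional strand assignment follows gene orientation", {
  models <- structure(list(
    genes = tibble::tibble(
      gene_id = c("plus", "minus", "plus2"), chrom = "chrT",
      strand = c("+", "-", "+"),
      tx_start = c(100L, 1000L, 1800L), tx_end = c(500L, 1500L, 2400L),
      cds_start = c(150L, 1050L, 1850L), cds_end = c(450L, 1450L, 2350L)),
    exons = tibble::tibble(
      gene_id = c("plus", "minus", "plus2"),
      exon_start = c(100L, 1000L, 1800L), exon_end = c(500L, 1500L, 2400L))
  ), class = "gene_models")
  # C ref (pyrimidine on +): same strand as + gene -> untranscribed
  calls <- tibble::tibble(chrom = "chrT", pos = c(200L, 1200L, 700L),
                          ref = c("C", "C", "C"))
  out <- assign_transcriptional_strand(calls, models)
  expect_equal(out$tx_strand, c("untranscribed", "transcribed", "intergenic"))
  # G ref (pyrimidine on -): flips
  out2 <- assign_transcriptional_strand(
    tibble::tibble(chrom = "chrT", pos = c(200L, 1200L), ref = "G"), models)
  expect_equal(out2$tx_strand, c("transcribed", "untranscribed"))

  # antisense overlap is ambiguous and excluded
  models$genes$tx_end[2] <- 2000L
  models$exons$exon_end[2] <- 2000L
  out3 <- assign_transcriptional_strand(
    tibble::tibble(chrom = "chrT", pos = 1900L, ref = "C"), models)
  expect_equal(out3$tx_strand, "ambiguous")
})

test_that("strand-bias test is calibrated under symmetry and powered under bias", {
  null_p <- withr::with_seed(31, {
    vapply(1:100, function(i) {
      df <- tibble::tibble(
        cell_id = sprintf("c%d", 1:20), condition = "control", class = "T>C",
        transcribed = rpois(20, 10), untranscribed = rpois(20, 10))
      min(strand_bias_test(df)$p.value)
    }, numeric(1))
  })
  expect_gte(mean(null_p > 0.05), 0.95)

  biased <- withr::with_seed(32, tibble::tibble(
    cell_id = sprintf("c%d", 1:20), condition = "control", class = "C>T",
    untranscribed = rpois(20, 10)))
  biased$transcribed <- biased$untranscribed * 2L
  expect_lt(strand_bias_test(biased)$p.value, 0.05)

  zero <- tibble::tibble(cell_id = sprintf("c%d", 1:5), condition = "x",
                         class = "C>G", transcribed = 0, untranscribed = 0)
  z <- strand_bias_test(zero)
  expect_equal(z$p.value, 1)
  expect_true(z$degenerate)

  one <- tibble::tibble(cell_id = "c1", condition = "x", class = "C>A",
                        transcribed = 1, untranscribed = 2)
  expect_error(strand_bias_test(one), ">= 3 cells")
})

test_that("exposure refitting recovers exact members and mixtures", {
  cat4 <- fx_catalog()
  sp <- 100 * cat4[, 3]
  fe <- fit_exposures(sp, cat4)
  expect_equal(fe$exposure[fe$signature == "SYN3"], 100, tolerance = 1e-8)
  expect_equal(sum(fe$exposure), 100, tolerance = 1e-8)
  expect_lt(attr(fe, "residual"), 1e-10)

  mix <- 60 * cat4[, 1] + 40 * cat4[, 4]
  fm <- fit_exposures(mix, cat4)
  expect_equal(fm$exposure[fm$signature == "SYN1"], 60, tolerance = 1e-6)
  expect_equal(fm$exposure[fm$signature == "SYN4"], 40, tolerance = 1e-6)

  dup_cat <- cbind(cat4, SYN1b = cat4[, 1])
  expect_warning(fit_exposures(sp, dup_cat), "duplicate")
})

test_that("refit dominates a fine grid search over the two-signature simplex", {
  cat4 <- fx_catalog()
  withr::with_seed(41, {
    true_mix <- 0.63 * cat4[, 1] + 0.37 * cat4[, 2]
    counts <- as.numeric(stats::rmultinom(1, 5000, true_mix))
  })
  names(counts) <- sbs96_channels()
  fe <- fit_exposures(counts, cat4[, 1:2])
  # attr residual is the unconstrained NNLS error (relative L2)
  our_err <- attr(fe, "residual") * sqrt(sum(counts^2))
  grid_err <- grid_refit_error(counts, cat4, c("SYN1", "SYN2"), step = 0.01)
  expect_lte(our_err, grid_err + 1e-8)
  # and the recovered mixture is near the truth
  expect_lt(abs(fe$fraction[fe$signature == "SYN1"] - 0.63), 0.05)
})

test_that("de novo decomposition inverts known combinations", {
  cat4 <- fx_catalog()
  dn <- cbind(N1 = cat4[, 2],
              N2 = 0.5 * cat4[, 1] + 0.5 * cat4[, 3])
  dec <- decompose_denovo(dn, cat4)
  w1 <- dec[dec$denovo == "N1", ]
  expect_equal(w1$weight[w1$signature == "SYN2"], 1, tolerance = 1e-6)
  w2 <- dec[dec$denovo == "N2", ]
  expect_equal(w2$weight[w2$signature == "SYN1"], 0.5, tolerance = 1e-6)
  expect_equal(w2$weight[w2$signature == "SYN3"], 0.5, tolerance = 1e-6)

  withr::with_seed(43, {
    mix <- c(0.2, 0.3, 0.5)
    dn3 <- cbind(N1 = as.numeric(cat4[, c(1, 2, 4)] %*% mix))
    noisy <- as.numeric(stats::rmultinom(1, 8000, dn3[, 1])) / 8000
  })
  dec3 <- decompose_denovo(cbind(N1 = noisy), cat4)
  got <- dec3$weight[match(c("SYN1", "SYN2", "SYN4"), dec3$signature)]
  expect_true(all(abs(got - mix) < 0.05))
})

test_that("NMF recovers the generating rank and signatures", {
  cat5 <- synthetic_signature_catalog(5, seed = 9)
  truth <- cat5[, 2:5]
  withr::with_seed(51, {
    H <- matrix(stats::rgamma(4 * 30, 2), 4, 30)
    H <- sweep(H, 2, colSums(H), "/")
    V <- sapply(1:30, function(i) {
      as.numeric(stats::rmultinom(1, 2000, truth %*% H[, i, drop = FALSE]))
    })
  })
  rownames(V) <- sbs96_channels()
  nm <- extract_denovo(V, ranks = 2:6, n_restarts = 15, seed = 4)
  expect_equal(nm$rank, 4)
  matched <- vapply(1:4, function(j) {
    max(vapply(1:4, function(i) cosine_sim(nm$signatures[, i], truth[, j]),
               numeric(1)))
  }, numeric(1))
  expect_true(all(matched >= 0.9))

  # permuting cell order does not change the chosen rank or signatures
  perm <- withr::with_seed(52, sample(30))
  nm_p <- extract_denovo(V[, perm], ranks = 2:6, n_restarts = 15, seed = 4)
  expect_equal(nm_p$rank, 4)
  matched_p <- vapply(1:4, function(i) {
    max(vapply(1:4, function(j) cosine_sim(nm_p$signatures[, i],
                                           nm$signatures[, j]), numeric(1)))
  }, numeric(1))
  expect_true(all(matched_p >= 0.95))
})

test_that("NMF identifies rank-1 structure and validates inputs", {
  cat4 <- fx_catalog()
  withr::with_seed(53, {
    V1 <- sapply(1:12, function(i) {
      as.numeric(stats::rmultinom(1, 1500, cat4[, 1]))
    })
  })
  rownames(V1) <- sbs96_channels()
  nm1 <- extract_denovo(V1, ranks = 1:4, n_restarts = 10, seed = 5)
  expect_equal(nm1$rank, 1)
  expect_gte(cosine_sim(nm1$signatures[, 1], cat4[, 1]), 0.99)

  expect_error(extract_denovo(V1, ranks = 2:12), "rank")
  expect_error(extract_denovo(-V1, ranks = 2:3), "non-negative")
})

test_that("signature-specific burdens partition the total and fit per signature", {
  cat4 <- fx_catalog()
  d <- cohort_design(seed = 61)
  cells <- simulate_burden(d)
  cells$burden_per_gb <- cells$true_burden_per_gb
  withr::with_seed(61, {
    fr <- matrix(stats::rgamma(nrow(cells) * 3, 2), ncol = 3)
    fr <- sweep(fr, 1, rowSums(fr), "/")
  })
  expos <- tidyr::expand_grid(cell_id = cells$cell_id,
                              signature = c("SYN1", "SYN2", "SYN3")) |>
    dplyr::arrange(signature) |>
    dplyr::mutate(fraction = as.vector(fr))
  res <- suppressWarnings(signature_burden_series(
    expos, cells[, c("cell_id", "burden_per_gb")],
    cells[, c("cell_id", "donor_id", "age", "condition")]))
  expect_setequal(unique(res$signature), c("SYN1", "SYN2", "SYN3"))
  expect_true(all(!res$skipped))

  # conservation: signature burdens sum to the total per cell
  tot <- expos |>
    dplyr::left_join(cells[, c("cell_id", "burden_per_gb")], by = "cell_id") |>
    dplyr::group_by(cell_id) |>
    dplyr::summarise(s = sum(fraction * burden_per_gb),
                     b = burden_per_gb[1])
  expect_equal(tot$s, tot$b, tolerance = 1e-6)

  # absent signature is skipped with a flag
  expos0 <- expos |> dplyr::mutate(
    fraction = ifelse(signature == "SYN3", 0, fraction))
  res0 <- suppressWarnings(signature_burden_series(
    expos0, cells[, c("cell_id", "burden_per_gb")],
    cells[, c("cell_id", "donor_id", "age", "condition")]))
  expect_true(all(res0$skipped[res0$signature == "SYN3"]))
})
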