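mk_models <- function(genes, exons) {
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

test_that("region categories follow the window and precedence rules", {
  genes <- tibble::tibble(
    gene_id = c("gA", "gB"), chrom = "chrT", strand = c("+", "+"),
    tx_start = c(2000L, 4500L), tx_end = c(4000L, 6500L),
    cds_start = c(2200L, 4700L), cds_end = c(3800L, 6300L))
  exons <- tibble::tibble(
    gene_id = c("gA", "gA", "gB"),
    exon_start = c(2000L, 3000L, 4500L),
    exon_end = c(2500L, 4000L, 6500L))
  gm <- mk_models(genes, exons)

  probe <- function(pos) {
    annotate_region(tibble::tibble(chrom = "chrT", pos = as.integer(pos)),
                    gm)$region
  }
  expect_equal(probe(1500), "upstream")     # 500 bp before TSS, outside genes
  expect_equal(probe(999), "intergenic")    # > 1 kb upstream
  expect_equal(probe(2100), "UTR5")         # exonic, before CDS
  expect_equal(probe(2300), "exonic")
  expect_equal(probe(3900), "UTR3")
  expect_equal(probe(2502), "splicing")     # 2 bp into the intron
  expect_equal(probe(2503), "intronic")     # 3 bp in
  expect_equal(probe(2998), "splicing")
  expect_equal(probe(2700), "intronic")
  expect_equal(probe(4200), "upstream")     # gB upstream outranks gA downstream
  expect_equal(probe(6700), "downstream")   # < 1 kb after gB TTS
  # all variants receive exactly one category and partition the input
  pos <- seq(500, 7000, by = 7)
  ann <- annotate_region(tibble::tibble(chrom = "chrT", pos = pos), gm)
  expect_equal(nrow(ann), length(pos))
  expect_true(all(ann$region %in% c("splicing", "exonic", "UTR5", "UTR3",
                                    "intronic", "upstream", "downstream",
                                    "intergenic")))
})

test_that("exonic outranks intronic across overlapping transcripts", {
  genes <- tibble::tibble(
    gene_id = c("tA", "tB"), chrom = "chrT", strand = "+",
    tx_start = c(1000L, 1000L), tx_end = c(3000L, 3000L),
    cds_start = c(1100L, 1100L), cds_end = c(2900L, 2900L))
  exons <- tibble::tibble(
    gene_id = c("tA", "tA", "tB"),
    exon_start = c(1000L, 2000L, 1000L),
    exon_end = c(1500L, 3000L, 3000L))  # tB single exon spans tA's intron
  gm <- mk_models(genes, exons)
  ann <- annotate_region(tibble::tibble(chrom = "chrT", pos = 1700L), gm)
  expect_equal(ann$region, "exonic")  # intronic in tA, exonic in tB

  bad <- gm
  bad$genes$cds_end[1] <- 5000L
  expect_error(annotate_region(tibble::tibble(chrom = "chrT", pos = 1L), bad),
               "malformed")
})

test_that("upstream/downstream windows are strand aware", {
  genes <- tibble::tibble(
    gene_id = "gm", chrom = "chrT", strand = "-",
    tx_start = 5000L, tx_end = 7000L, cds_start = 5100L, cds_end = 6900L)
  exons <- tibble::tibble(gene_id = "gm", exon_start = 5000L,
                          exon_end = 7000L)
  gm <- mk_models(genes, exons)
  # for a minus-strand gene the TSS is at tx_end
  up <- annotate_region(tibble::tibble(chrom = "chrT", pos = 7500L), gm)
  dn <- annotate_region(tibble::tibble(chrom = "chrT", pos = 4500L), gm)
  expect_equal(up$region, "upstream")
  expect_equal(dn$region, "downstream")
})

test_that("codon translation classifies substitutions by the genetic code", {
  # CDS on + strand: ATG CGA CTA TGA
  w <- fx_codon_world("+")
  probe <- function(pos, ref, alt) {
    classify_functional(tibble::tibble(chrom = "chrT", pos = as.integer(pos),
                                       ref = ref, alt = alt),
                        w$models, w$ref)$functional
  }
  # CGA -> TGA (C>T at codon 2 position 1): Arg -> stop
  expect_equal(probe(w$cds_start + 3, "C", "T"), "stopgain")
  # CTA -> CTG (A>G at codon 3 position 3): Leu -> Leu
  expect_equal(probe(w$cds_start + 8, "A", "G"), "synonymous")
  # TGA -> TGG (A>G at terminal codon position 3): stop -> Trp
  expect_equal(probe(w$cds_start + 11, "A", "G"), "stoploss")
  # CGA -> CCA (G>C at codon 2 position 2): Arg -> Pro
  expect_equal(probe(w$cds_start + 4, "G", "C"), "nonsynonymous")
  # outside the CDS: NA
  expect_true(is.na(probe(w$cds_start - 3, "A", "G")))
})

test_that("functional classification is strand consistent", {
  plus <- fx_codon_world("+")
  minus <- fx_codon_world("-")
  L <- plus$ref$length
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  # the same biological substitutions, expressed on the mirrored genome
  cases <- tibble::tibble(pos = plus$cds_start + c(3L, 8L, 11L, 4L),
                          ref = c("C", "A", "A", "G"),
                          alt = c("T", "G", "G", "C"))
  f_plus <- classify_functional(dplyr::mutate(cases, chrom = "chrT"),
                                plus$models, plus$ref)$functional
  mirrored <- tibble::tibble(chrom = "chrT", pos = L - cases$pos + 1L,
                             ref = unname(comp[cases$ref]),
                             alt = unname(comp[cases$alt]))
  f_minus <- classify_functional(mirrored, minus$models, minus$ref)$functional
  expect_equal(f_minus, f_plus)
})

test_that("selection ratios normalize by germline and test exactly", {
  # identical proportions: ratio 1, P 1
  som <- tibble::tibble(region = rep(c("exonic", "intronic"), c(30, 60)),
                        functional = rep(c("nonsynonymous", "synonymous", NA),
                                         c(20, 10, 60)))
  germ <- tibble::tibble(region = rep(c("exonic", "intronic"), c(60, 120)),
                         functional = rep(c("nonsynonymous", "synonymous", NA),
                                          c(40, 20, 120)))
  st <- selection_ratios(som, germ)
  expect_equal(st$ratio, c(1, 1))
  expect_equal(st$p.value, c(1, 1))

  # 30/10 somatic vs 20/20 germline: normalized dN/dS = 3
  som2 <- tibble::tibble(region = rep("exonic", 40),
                         functional = rep(c("nonsynonymous", "synonymous"),
                                          c(30, 10)))
  germ2 <- tibble::tibble(region = rep("exonic", 40),
                          functional = rep(c("nonsynonymous", "synonymous"),
                                           c(20, 20)))
  st2 <- selection_ratios(som2, germ2)
  dn <- st2[st2$comparison == "dN/dS", ]
  expect_equal(dn$ratio, 3)
  expect_equal(dn$p.value, enum_fisher_p(30, 10, 20, 20), tolerance = 1e-9)

  # doubling counts: same ratio, smaller P
  som4 <- som2[rep(1:40, 2), ]; germ4 <- germ2[rep(1:40, 2), ]
  st4 <- selection_ratios(som4, germ4)
  dn4 <- st4[st4$comparison == "dN/dS", ]
  expect_equal(dn4$ratio, 3)
  expect_lt(dn4$p.value, dn$p.value)

  # zero germline category: ratio undefined, P still reported
  germ0 <- tibble::tibble(region = rep("exonic", 10),
                          functional = rep("nonsynonymous", 10))
  st0 <- selection_ratios(som2, germ0)
  expect_true(is.na(st0$ratio[st0$comparison == "dN/dS"]))
  expect_true(is.finite(st0$p.value[st0$comparison == "dN/dS"]))
})

test_that("the exact test agrees with hypergeometric enumeration up to n=200", {
  withr::with_seed(77, {
    for (i in 1:40) {
      tot <- sample(8:200, 1)
      a <- sample(0:tot, 1); b <- sample(0:(tot - a), 1)
      c_ <- sample(0:(tot - a - b), 1); d <- tot - a - b - c_
      p_fisher <- fisher.test(matrix(c(a, b, c_, d), 2))$p.value
      p_enum <- enum_fisher_p(a, b, c_, d)
      expect_equal(p_fisher, p_enum, tolerance = 1e-7)
    }
  })
})

test_that("locus overlap reports intersecting calls only", {
  calls <- tibble::tibble(chrom = "chrT", pos = c(100L, 5000L, 9000L))
  loci <- tibble::tibble(chrom = "chrT", start = c(4000L, 8500L),
                         end = c(6000L, 9500L), name = c("locus1", "locus2"))
  ov <- overlap_loci(calls, loci)
  expect_equal(ov$pos, c(5000L, 9000L))
  expect_equal(ov$name, c("locus1", "locus2"))
})

test_that("annotation partitions synthetic cohort calls completely", {
  ref <- fx_ref()
  gm <- fx_models()
  d <- cohort_design(n_control_donors = 2, n_ihd_donors = 0,
                     cells_per_donor = 1, beta0 = 1e7, beta1 = 0,
                     sigma_u = 0, sigma_e = 0, seed = 99)
  co <- generate_cohort(d, ref, fx_catalog())
  ann <- suppressWarnings(
    co$mutations |> annotate_region(gm) |> classify_functional(gm, ref))
  expect_equal(nrow(ann), nrow(co$mutations))
  expect_false(any(is.na(ann$region)))
  # functional classes only for exonic CDS variants
  expect_true(all(!is.na(ann$functional[ann$region == "exonic"])))
  expect_true(all(is.na(ann$functional[ann$region == "intergenic"])))
})
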