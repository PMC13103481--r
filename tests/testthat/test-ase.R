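# TPM normalization, allele-pair tests, ASE classification, dominance.

test_that("TPM normalizes to one million per sample", {
  counts <- tibble::tibble(gene_id = c("g1", "g2"), s1 = c(10, 10),
                           s2 = c(3, 9))
  lengths <- tibble::tibble(gene_id = c("g1", "g2"), length = c(100, 100))
  tpm <- compute_tpm(counts, lengths)
  expect_equal(tpm$s1, c(5e5, 5e5))
  expect_equal(sum(tpm$s2), 1e6)
  # doubling a gene's length halves its share
  lengths2 <- tibble::tibble(gene_id = c("g1", "g2"), length = c(200, 100))
  tpm2 <- compute_tpm(counts, lengths2)
  expect_equal(tpm2$s1[1] / tpm2$s1[2], 0.5)

  set.seed(21)
  big <- tibble::as_tibble(matrix(rpois(200, 30), 20, 10,
                                  dimnames = list(NULL, paste0("s", 1:10))))
  big <- dplyr::bind_cols(tibble::tibble(gene_id = paste0("g", 1:20)), big)
  lens <- tibble::tibble(gene_id = paste0("g", 1:20),
                         length = sample(500:2000, 20))
  tt <- compute_tpm(big, lens)
  expect_true(all(abs(colSums(as.matrix(tt[, -1])) - 1e6) < 1e-6))

  zero <- dplyr::mutate(counts, s1 = 0)
  expect_error(compute_tpm(zero, lengths), "zero total")
})

test_that("allele-pair test behaves on balanced, unbalanced and swapped input", {
  even <- test_allele_pair(c(100, 100, 100), c(100, 100, 100),
                           c(100, 100, 100), c(100, 100, 100))
  expect_equal(even$log2fc, 0, tolerance = 1e-4)
  expect_equal(even$p, 1)

  # 400 vs 100 with equal length shares: fourfold, decisively significant
  unb <- test_allele_pair(400, 100, 400, 100)
  expect_equal(unb$log2fc, 2, tolerance = 1e-4)
  expect_lt(unb$p, 0.05)
  expect_equal(unb$p, stats::binom.test(400, 500, 0.5)$p.value)

  sw <- test_allele_pair(100, 400, 100, 400)
  expect_equal(sw$log2fc, -unb$log2fc, tolerance = 1e-9)
  expect_equal(sw$p, unb$p)

  none <- test_allele_pair(0, 0, 0, 0)
  expect_true(is.na(none$p))
})

make_ase_fixture <- function(seed = 22, n_genes = 120, mu = 300,
                             dominance_log2 = 0, ase_fraction = 0.25,
                             ase_log2 = 2) {
  sim <- small_sim(n_genes = n_genes, codons = 30, seed = seed)
  ex <- simulate_expression(sim, mu = mu, dispersion = 20,
                            dominance_log2 = dominance_log2,
                            ase_fraction = ase_fraction,
                            ase_log2 = ase_log2, seed = seed)
  hits <- similarity_hits(sim, seed = seed)
  loci <- build_loci(cscore_pairs(hits),
                     dplyr::transmute(sim$truth, gene_id = gene_id,
                                      haplotype = haplotype))
  list(sim = sim, ex = ex, loci = loci)
}

test_that("ase_test agrees with test_allele_pair row by row", {
  fx <- make_ase_fixture(n_genes = 12)
  res <- ase_test(fx$ex$counts, fx$ex$lengths, fx$loci, fx$ex$samples)
  tpm <- compute_tpm(fx$ex$counts, fx$ex$lengths)
  set.seed(23)
  for (i in sample(nrow(res), 10)) {
    row <- res[i, ]
    cols <- fx$ex$samples$sample[fx$ex$samples$timepoint == row$timepoint]
    cm <- as.data.frame(fx$ex$counts[, -1])
    rownames(cm) <- fx$ex$counts$gene_id
    tm <- as.data.frame(tpm[, -1])
    rownames(tm) <- tpm$gene_id
    ref <- test_allele_pair(
      as.numeric(tm[row$gene_a, cols]), as.numeric(tm[row$gene_b, cols]),
      as.numeric(cm[row$gene_a, cols]), as.numeric(cm[row$gene_b, cols])
    )
    expect_equal(row$log2fc, ref$log2fc)
    expect_equal(row$p, ref$p)
  }
})

test_that("ASE classification counts loci with any significant pair", {
  fx <- make_ase_fixture()
  res <- ase_test(fx$ex$counts, fx$ex$lengths, fx$loci, fx$ex$samples)
  census <- classify_asegs(res, fx$loci)
  expect_equal(census$n_sextuple, nrow(fx$loci))
  expect_equal(census$pct_ase,
               round(100 * census$n_ase / census$n_sextuple, 2))
  # invariant to row order of results and loci
  census2 <- classify_asegs(dplyr::arrange(res, dplyr::desc(locus_id)),
                            dplyr::arrange(fx$loci, dplyr::desc(locus_id)))
  expect_equal(census2, census)

  none <- dplyr::mutate(res, significant = FALSE)
  expect_equal(classify_asegs(none, fx$loci)$pct_ase, 0)
})

test_that("inconsistent ASE detection matches the sign/significance truth table", {
  # all 16 combinations of significance over 2 timepoints x sign patterns
  combos <- expand.grid(sig1 = c(TRUE, FALSE), sig2 = c(TRUE, FALSE),
                        up1 = c(TRUE, FALSE), up2 = c(TRUE, FALSE))
  res <- dplyr::bind_rows(lapply(seq_len(nrow(combos)), function(i) {
    cb <- combos[i, ]
    tibble::tibble(
      locus_id = sprintf("L%02d", i), gene_a = "A", gene_b = "B",
      hap_a = 1, hap_b = 2, timepoint = c("DAF0", "DAF3"),
      log2fc = c(ifelse(cb$up1, 2, -2), ifelse(cb$up2, 2, -2)),
      p = 0.001, significant = c(cb$sig1, cb$sig2),
      dominant = dplyr::if_else(c(cb$sig1, cb$sig2),
                                dplyr::if_else(c(cb$up1, cb$up2), "A", "B"),
                                NA_character_)
    )
  }))
  out <- inconsistent_asegs(res)
  for (i in seq_len(nrow(combos))) {
    cb <- combos[i, ]
    expected <- cb$sig1 && cb$sig2 && (cb$up1 != cb$up2)
    row <- out[out$locus_id == sprintf("L%02d", i), ]
    if (!cb$sig1 && !cb$sig2) {
      expect_equal(nrow(row), 0)
    } else {
      expect_equal(row$inconsistent, expected)
    }
  }
})

test_that("dominance summary classifies bias from subgenome mean ratios", {
  fx <- make_ase_fixture(n_genes = 30, dominance_log2 = 0, ase_fraction = 0)
  dom <- dominance_summary(fx$ex$counts, fx$ex$lengths, fx$loci)
  expect_equal(nrow(dom), 30)
  expect_true(all(abs(dom$log2_b_over_a) < 1)) # no planted bias
  g <- glance(dom)
  expect_equal(g$n_biased_a + g$n_biased_b + g$n_unbiased, g$n_loci)

  # planted fourfold B dominance
  fx2 <- make_ase_fixture(n_genes = 30, dominance_log2 = 2, ase_fraction = 0)
  dom2 <- dominance_summary(fx2$ex$counts, fx2$ex$lengths, fx2$loci)
  expect_gt(stats::median(dom2$log2_b_over_a), 1.5)
  expect_gt(glance(dom2)$n_biased_b, 25)
})
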