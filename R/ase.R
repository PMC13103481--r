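# Allele-specific expression and subgenome dominance over allelic loci,
# from a gene-by-sample count matrix.

counts_matrix <- function(counts) {
  m <- as.matrix(counts[, setdiff(names(counts), "gene_id")])
  rownames(m) <- counts$gene_id
  storage.mode(m) <- "double"
  m
}

#' Transcripts-per-million normalization
#'
#' `TPM = 1e6 * (count / length) / sum(count / length)` per sample, over
#' the genes present in the matrix.
#'
#' @param counts Tibble with a `gene_id` column and one integer column per
#'   sample.
#' @param lengths Tibble `gene_id`, `length` (effective length in bp).
#' @return A tibble of the same shape as `counts` holding TPM values;
#'   every sample column sums to 1e6.
#' @export
compute_tpm <- function(counts, lengths) {
  m <- counts_matrix(counts)
  len <- lengths$length[match(rownames(m), lengths$gene_id)]
  if (anyNA(len)) rlang::abort("lengths missing for some genes")
  if (any(len <= 0)) rlang::abort("gene lengths must be positive")
  rate <- m / len
  tot <- colSums(rate)
  if (any(tot == 0)) {
    rlang::abort(paste0("sample with zero total counts: ",
                        colnames(m)[which(tot == 0)[1]]))
  }
  tpm <- sweep(rate, 2, tot, "/") * 1e6
  dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)),
                   tibble::as_tibble(tpm))
}

#' Test one allele pair at one timepoint
#'
#' The fold change is `log2((mean TPM_a + eps) / (mean TPM_b + eps))` over
#' replicates. The p-value is a two-sided exact binomial test on the
#' replicate-summed raw counts, with null success probability equal to
#' allele a's effective-length share `len_a / (len_a + len_b)` (0.5 for
#' equal lengths, i.e. equal expected shares under no ASE).
#'
#' @param tpm_a,tpm_b Per-replicate TPM values of the two alleles.
#' @param counts_a,counts_b Per-replicate raw counts of the two alleles.
#' @param len_a,len_b Effective lengths (default equal).
#' @param epsilon Pseudocount in TPM units.
#' @return Tibble with `log2fc`, `p` and `n_total` (summed counts).
#' @export
test_allele_pair <- function(tpm_a, tpm_b, counts_a, counts_b,
                             len_a = 1, len_b = 1, epsilon = 0.01) {
  ka <- sum(counts_a)
  kb <- sum(counts_b)
  if (ka + kb == 0) {
    return(tibble::tibble(log2fc = NA_real_, p = NA_real_, n_total = 0))
  }
  p0 <- len_a / (len_a + len_b)
  log2fc <- log2((mean(tpm_a) + epsilon) / (mean(tpm_b) + epsilon))
  p <- stats::binom.test(ka, ka + kb, p = p0)$p.value
  tibble::tibble(log2fc = log2fc, p = p, n_total = ka + kb)
}

#' Allele-pair expression tests across loci and timepoints
#'
#' Runs [test_allele_pair()] for every within-locus allele pair at every
#' timepoint. Pairs with zero counts at a timepoint are recorded as
#' untestable (`NA` statistics). Significance is `|log2fc| > lfc` and
#' `p < alpha` (optionally BH-adjusted across all tests).
#'
#' @param counts,lengths As in [compute_tpm()].
#' @param loci Locus table from [build_loci()].
#' @param samples Tibble `sample`, `timepoint`, `replicate`.
#' @param alpha Significance level on the (adjusted) p-value.
#' @param lfc Absolute log2 fold-change threshold.
#' @param epsilon TPM pseudocount.
#' @param adjust If `TRUE`, apply Benjamini-Hochberg correction across all
#'   tests before thresholding (the default mirrors a raw p < alpha
#'   criterion).
#' @return Tibble with one row per locus x allele pair x timepoint:
#'   `locus_id`, `gene_a`, `gene_b`, `hap_a`, `hap_b`, `timepoint`,
#'   `log2fc`, `p`, `significant`, `dominant` (the higher-expressed gene
#'   when significant).
#' @export
ase_test <- function(counts, lengths, loci, samples, alpha = 0.05, lfc = 1,
                     epsilon = 0.01, adjust = FALSE) {
  tpm <- compute_tpm(counts, lengths)
  cm <- counts_matrix(counts)
  tm <- counts_matrix(tpm)
  len <- stats::setNames(lengths$length, lengths$gene_id)

  hap_cols <- paste0("hap", 1:6)
  members <- loci |>
    tidyr::pivot_longer(dplyr::all_of(hap_cols), names_to = "hap",
                        values_to = "gene_id") |>
    dplyr::filter(!is.na(.data$gene_id)) |>
    dplyr::mutate(haplotype = as.integer(sub("hap", "", .data$hap)))

  # Per-timepoint summed counts and mean TPM (genes x timepoints).
  tps <- sort(unique(samples$timepoint))
  design <- vapply(tps, function(tp) {
    as.numeric(colnames(cm) %in% samples$sample[samples$timepoint == tp])
  }, numeric(ncol(cm)))
  cm_tp <- cm %*% design
  tm_tp <- sweep(tm %*% design, 2, colSums(design), "/")
  colnames(cm_tp) <- colnames(tm_tp) <- tps

  # All within-locus allele pairs.
  pair_tbl <- members |>
    dplyr::group_by(.data$locus_id) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 2) {
        return(tibble::tibble(gene_a = character(0), gene_b = character(0),
                              hap_a = integer(0), hap_b = integer(0)))
      }
      idx <- utils::combn(seq_len(nrow(df)), 2)
      tibble::tibble(
        gene_a = df$gene_id[idx[1, ]], gene_b = df$gene_id[idx[2, ]],
        hap_a = df$haplotype[idx[1, ]], hap_b = df$haplotype[idx[2, ]]
      )
    }) |>
    dplyr::ungroup()
  out <- tidyr::expand_grid(pair_tbl, timepoint = tps)
  if (nrow(out) == 0) return(out)

  ka <- cm_tp[cbind(out$gene_a, out$timepoint)]
  kb <- cm_tp[cbind(out$gene_b, out$timepoint)]
  ma <- tm_tp[cbind(out$gene_a, out$timepoint)]
  mb <- tm_tp[cbind(out$gene_b, out$timepoint)]
  p0 <- len[out$gene_a] / (len[out$gene_a] + len[out$gene_b])
  out$log2fc <- ifelse(ka + kb == 0, NA_real_,
                       log2((ma + epsilon) / (mb + epsilon)))
  out$p <- vapply(seq_len(nrow(out)), function(i) {
    if (ka[i] + kb[i] == 0) return(NA_real_)
    stats::binom.test(ka[i], ka[i] + kb[i], p = p0[i])$p.value
  }, numeric(1))
  p_use <- if (adjust) stats::p.adjust(out$p, method = "BH") else out$p
  out |>
    dplyr::mutate(
      p_adj = if (adjust) p_use else NA_real_,
      significant = !is.na(.data$log2fc) & abs(.data$log2fc) > lfc &
        !is.na(p_use) & p_use < alpha,
      dominant = dplyr::case_when(
        !.data$significant ~ NA_character_,
        .data$log2fc > 0 ~ .data$gene_a,
        TRUE ~ .data$gene_b
      )
    )
}

#' Classify allele-specific expressed loci
#'
#' A locus shows allele-specific expression (ASE) when at least one of its
#' allele pairs is significant at at least one timepoint. The reported
#' percentage is over the sextuple-class loci, matching the convention of
#' summarizing ASE among fully-represented loci.
#'
#' @param results Output of [ase_test()].
#' @param loci Locus table from [build_loci()].
#' @return One-row tibble: `n_sextuple`, `n_ase`, `pct_ase` (2 decimals).
#' @export
classify_asegs <- function(results, loci) {
  sextuple <- loci$locus_id[loci$class == "sextuple"]
  ase_loci <- results |>
    dplyr::filter(.data$locus_id %in% sextuple, .data$significant) |>
    dplyr::distinct(.data$locus_id)
  tibble::tibble(
    n_sextuple = length(sextuple),
    n_ase = nrow(ase_loci),
    pct_ase = round(100 * nrow(ase_loci) / length(sextuple), 2)
  )
}

#' Allele pairs with inconsistent (switching) dominance
#'
#' A pair is inconsistent when it is significant at two or more timepoints
#' and the dominant allele differs between some pair of significant
#' timepoints.
#'
#' @param results Output of [ase_test()].
#' @return Tibble `locus_id`, `gene_a`, `gene_b`, `n_significant`,
#'   `inconsistent`.
#' @export
inconsistent_asegs <- function(results) {
  results |>
    dplyr::filter(.data$significant) |>
    dplyr::group_by(.data$locus_id, .data$gene_a, .data$gene_b) |>
    dplyr::summarise(
      n_significant = dplyr::n(),
      inconsistent = dplyr::n() >= 2 &
        dplyr::n_distinct(.data$dominant) > 1,
      .groups = "drop"
    )
}

#' Subgenome dominance summary over sextuple loci
#'
#' Per locus, the mean TPM over subgenome-A copies (haplotypes 1-2) is
#' compared with the mean over subgenome-B copies (haplotypes 3-6); loci
#' with `|log2((B + eps) / (A + eps))| > lfc` are counted as biased.
#'
#' @param counts,lengths As in [compute_tpm()].
#' @param loci Locus table from [build_loci()]; only sextuple loci enter.
#' @param subgenome_a Integer haplotypes forming subgenome A.
#' @param lfc Bias threshold on `|log2(B/A)|`.
#' @param epsilon TPM pseudocount.
#' @return Tibble of class `dominance_summary` with one row per locus:
#'   `locus_id`, `mean_a`, `mean_b`, `log2_b_over_a`, `bias` in
#'   `{"A", "B", "unbiased"}`. Counts are available via [glance()].
#' @export
dominance_summary <- function(counts, lengths, loci,
                              subgenome_a = c(1L, 2L), lfc = 1,
                              epsilon = 0.01) {
  tpm <- compute_tpm(counts, lengths)
  tm <- counts_matrix(tpm)
  hap_cols <- paste0("hap", 1:6)
  sext <- dplyr::filter(loci, .data$class == "sextuple")
  rows <- purrr::pmap(sext[, c("locus_id", hap_cols)], function(...) {
    r <- list(...)
    genes_a <- unlist(r[paste0("hap", subgenome_a)])
    genes_b <- unlist(r[paste0("hap", setdiff(1:6, subgenome_a))])
    ma <- mean(tm[genes_a, , drop = FALSE])
    mb <- mean(tm[genes_b, , drop = FALSE])
    l2 <- log2((mb + epsilon) / (ma + epsilon))
    tibble::tibble(
      locus_id = r$locus_id, mean_a = ma, mean_b = mb, log2_b_over_a = l2,
      bias = dplyr::case_when(l2 > lfc ~ "B", l2 < -lfc ~ "A",
                              TRUE ~ "unbiased")
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("dominance_summary", class(out))
  out
}

#' @exportS3Method generics::glance
glance.dominance_summary <- function(x, ...) {
  tibble::tibble(
    n_loci = nrow(x),
    n_biased_b = sum(x$bias == "B"),
    n_biased_a = sum(x$bias == "A"),
    n_unbiased = sum(x$bias == "unbiased"),
    median_log2_b_over_a = stats::median(x$log2_b_over_a)
  )
}
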