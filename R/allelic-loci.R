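# One-to-one allelic gene pairing across haplotypes (c-score filter,
# collinear block chaining, best-score matching) and allele-multiplicity
# classification of the resulting loci.

#' Filter similarity hits into one-to-one allelic gene pairs
#'
#' Three filters applied in sequence per haplotype pair, mirroring
#' c-score-based synteny pairing:
#' 1. *c-score*: a hit `(i, j)` is retained iff
#'    `score >= cscore * max(best outgoing score of i, best incoming score
#'    of j)` (bests computed over the whole hits table).
#' 2. *Collinear blocks*: retained hits on the same chromosome pair are
#'    sorted by `rank_a` and chained while consecutive hits differ by at
#'    most `dist` gene ranks on both haplotypes; blocks with fewer than
#'    `min_size` hits are dropped.
#' 3. *One-to-one*: surviving hits are greedily accepted in descending
#'    score order, keeping at most one partner per gene.
#'
#' @param hits Tibble with columns `gene_a`, `hap_a`, `chrom_a`, `rank_a`,
#'   `gene_b`, `hap_b`, `chrom_b`, `rank_b`, `score`. Ranks are gene-order
#'   indices along the chromosome.
#' @param cscore Relative-score threshold in `(0, 1]`; `cscore = 1`
#'   reduces the first filter to reciprocal best hits.
#' @param dist Maximum gene-rank gap between consecutive block members.
#' @param min_size Minimum number of hits per retained block.
#' @return The retained one-to-one pairs (same columns as `hits`).
#' @export
cscore_pairs <- function(hits, cscore = 0.7, dist = 20, min_size = 4) {
  if (cscore <= 0 || cscore > 1) rlang::abort("cscore must be in (0, 1]")
  if (dist < 1) rlang::abort("dist must be >= 1")
  if (min_size < 1) rlang::abort("min_size must be >= 1")
  if (nrow(hits) == 0) return(hits)
  best_out <- hits |>
    dplyr::group_by(.data$gene_a) |>
    dplyr::summarise(best_out = max(.data$score), .groups = "drop")
  best_in <- hits |>
    dplyr::group_by(.data$gene_b) |>
    dplyr::summarise(best_in = max(.data$score), .groups = "drop")
  retained <- hits |>
    dplyr::left_join(best_out, by = "gene_a") |>
    dplyr::left_join(best_in, by = "gene_b") |>
    dplyr::filter(.data$score >= cscore * pmax(.data$best_out, .data$best_in)) |>
    dplyr::select(-"best_out", -"best_in")

  blocks <- retained |>
    dplyr::group_by(.data$hap_a, .data$hap_b, .data$chrom_a, .data$chrom_b) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$rank_a, .data$rank_b)
      if (nrow(df) == 0) return(df)
      new_block <- c(TRUE, abs(diff(df$rank_a)) > dist |
                       abs(diff(df$rank_b)) > dist)
      df$block <- cumsum(new_block)
      df
    }) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$hap_a, .data$hap_b, .data$chrom_a, .data$chrom_b,
                    .data$block) |>
    dplyr::filter(dplyr::n() >= min_size) |>
    dplyr::ungroup() |>
    dplyr::select(-"block")

  # Greedy one-to-one matching per haplotype pair, descending score; ties
  # broken by gene ids for determinism.
  blocks |>
    dplyr::group_by(.data$hap_a, .data$hap_b) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, dplyr::desc(.data$score), .data$gene_a,
                           .data$gene_b)
      used_a <- character(0)
      used_b <- character(0)
      keep <- logical(nrow(df))
      for (i in seq_len(nrow(df))) {
        if (!(df$gene_a[i] %in% used_a) && !(df$gene_b[i] %in% used_b)) {
          keep[i] <- TRUE
          used_a <- c(used_a, df$gene_a[i])
          used_b <- c(used_b, df$gene_b[i])
        }
      }
      df[keep, ]
    }) |>
    dplyr::ungroup()
}

#' Build allelic loci from one-to-one pairs and classify multiplicity
#'
#' Loci are the connected components of the pair graph across all
#' haplotype pairs. Components containing two genes on the same haplotype
#' are repaired by iteratively dropping their lowest-score edge until
#' every haplotype is represented at most once. Genes in `genes` that end
#' up in no pair are reported as singletons.
#'
#' @param pairs One-to-one pairs from [cscore_pairs()].
#' @param genes Optional tibble `gene_id`, `haplotype` listing every
#'   annotated gene; needed for the singleton census.
#' @return Tibble with `locus_id`, columns `hap1`..`hap6` (member gene ids
#'   or `NA`) and `class` in sextuple, quintuple, quadruple, triple,
#'   double, singleton.
#' @export
build_loci <- function(pairs, genes = NULL) {
  edges <- tibble::tibble(
    from = pairs$gene_a, to = pairs$gene_b,
    hap_from = pairs$hap_a, hap_to = pairs$hap_b,
    score = pairs$score
  )
  hap_of <- c(
    stats::setNames(edges$hap_from, edges$from),
    stats::setNames(edges$hap_to, edges$to)
  )
  hap_of <- hap_of[!duplicated(names(hap_of))]
  if (!is.null(genes)) {
    extra <- stats::setNames(genes$haplotype, genes$gene_id)
    hap_of <- c(hap_of, extra[setdiff(names(extra), names(hap_of))])
  }

  components <- list()
  if (nrow(edges) > 0) {
    g <- igraph::graph_from_data_frame(edges[, c("from", "to", "score")],
                                       directed = FALSE)
    repeat {
      comp <- igraph::components(g)
      bad <- NULL
      for (ci in seq_len(comp$no)) {
        vs <- names(comp$membership)[comp$membership == ci]
        if (anyDuplicated(hap_of[vs])) {
          bad <- ci
          break
        }
      }
      if (is.null(bad)) break
      vs <- names(comp$membership)[comp$membership == bad]
      sub_edges <- igraph::E(g)[igraph::`%--%`(igraph::V(g)[vs],
                                               igraph::V(g)[vs])]
      weakest <- sub_edges[which.min(sub_edges$score)]
      g <- igraph::delete_edges(g, weakest)
    }
    comp <- igraph::components(g)
    components <- split(names(comp$membership), comp$membership)
  }
  if (!is.null(genes)) {
    paired <- unlist(components, use.names = FALSE)
    singles <- setdiff(genes$gene_id, paired)
    components <- c(components, as.list(singles))
  }

  class_names <- c("singleton", "double", "triple", "quadruple",
                   "quintuple", "sextuple")
  rows <- purrr::imap(components, function(members, i) {
    haps <- hap_of[members]
    row <- stats::setNames(rep(NA_character_, 6), paste0("hap", 1:6))
    row[paste0("hap", haps)] <- members
    c(list(locus_id = sprintf("locus_%05d", as.integer(i))),
      as.list(row),
      list(class = class_names[length(members)]))
  })
  out <- dplyr::bind_rows(rows)
  out$locus_id <- sprintf("locus_%05d", seq_len(nrow(out)))
  out
}

#' Allele-multiplicity census of a locus table
#'
#' @param loci Output of [build_loci()].
#' @return Tibble `class`, `n` ordered sextuple to singleton.
#' @export
locus_census <- function(loci) {
  lev <- c("sextuple", "quintuple", "quadruple", "triple", "double",
           "singleton")
  loci |>
    dplyr::mutate(class = factor(.data$class, levels = lev)) |>
    dplyr::count(.data$class, .drop = FALSE) |>
    dplyr::mutate(class = as.character(.data$class))
}

#' Alignment-free similarity hits between haplotype CDS sets
#'
#' Emits directed scored hits between gene copies of different haplotypes
#' using `1 - p_distance` of their coding sequences as the similarity
#' score, plus gene rank positions. Intended to feed [cscore_pairs()]
#' without requiring an aligner. Hits below `min_score` are dropped.
#'
#' @param sim A `hex_sim` object.
#' @param min_score Minimum similarity score to emit.
#' @param noise_sd Standard deviation of Gaussian score noise (adds
#'   realism to the otherwise clean truth-derived scores).
#' @param seed Integer seed.
#' @return A hits tibble suitable for [cscore_pairs()].
#' @export
similarity_hits <- function(sim, min_score = 0.9, noise_sd = 0,
                            seed = 1L) {
  stopifnot(inherits(sim, "hex_sim"))
  set.seed(seed)
  n <- sim$params$n_genes
  genes <- sprintf("g%04d", seq_len(n))
  combos <- utils::combn(1:6, 2)
  res <- list()
  for (i in seq_len(ncol(combos))) {
    ha <- combos[1, i]
    hb <- combos[2, i]
    a_seq <- sim$cds[[ha]]
    b_seq <- sim$cds[[hb]]
    pdist <- vapply(seq_len(n), function(g) {
      x <- strsplit(a_seq[g], "")[[1]]
      y <- strsplit(b_seq[g], "")[[1]]
      mean(x != y)
    }, numeric(1))
    score <- 1 - pdist + stats::rnorm(n, 0, noise_sd)
    keep <- score >= min_score
    res[[i]] <- tibble::tibble(
      gene_a = paste0("hap", ha, "_", genes)[keep], hap_a = ha,
      chrom_a = "chr01", rank_a = seq_len(n)[keep],
      gene_b = paste0("hap", hb, "_", genes)[keep], hap_b = hb,
      chrom_b = "chr01", rank_b = seq_len(n)[keep],
      score = pmin(score[keep], 1)
    )
  }
  dplyr::bind_rows(res)
}
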