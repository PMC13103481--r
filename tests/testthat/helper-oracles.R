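# Independent brute-force oracles used to validate the package's
# implementations on small instances.

# ---- NG86 oracle: naive site counting and recursive pathway enumeration ----

.oracle_gc <- Biostrings::GENETIC_CODE
.oracle_bases <- c("A", "C", "G", "T")

oracle_syn_sites <- function(codon) {
  s <- 0
  for (p in 1:3) {
    for (b in setdiff(.oracle_bases, substr(codon, p, p))) {
      alt <- codon
      substr(alt, p, p) <- b
      if (.oracle_gc[[alt]] != "*" && .oracle_gc[[alt]] == .oracle_gc[[codon]]) {
        s <- s + 1 / 3
      }
    }
  }
  s
}

# All minimal mutational pathways between two codons, recursively; returns
# list of c(syn_steps, nonsyn_steps) per stop-free pathway.
oracle_paths <- function(c1, c2) {
  d <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(d) == 0) {
    return(list(c(0, 0)))
  }
  out <- list()
  for (p in d) {
    nxt <- c1
    substr(nxt, p, p) <- substr(c2, p, p)
    if (.oracle_gc[[nxt]] == "*") next
    step <- if (.oracle_gc[[c1]] == .oracle_gc[[nxt]]) c(1, 0) else c(0, 1)
    for (rest in oracle_paths(nxt, c2)) {
      out[[length(out) + 1]] <- step + rest
    }
  }
  out
}

oracle_ng86 <- function(a, b) {
  n <- nchar(a)
  starts <- seq(1, n, 3)
  ca <- substring(a, starts, starts + 2)
  cb <- substring(b, starts, starts + 2)
  s_sites_a <- 0
  s_sites_b <- 0
  sd_sum <- 0
  nd_sum <- 0
  used <- 0
  for (i in seq_along(ca)) {
    if (grepl("[^ACGT]", ca[i]) || grepl("[^ACGT]", cb[i])) next
    if (.oracle_gc[[ca[i]]] == "*" || .oracle_gc[[cb[i]]] == "*") next
    paths <- oracle_paths(ca[i], cb[i])
    if (length(paths) == 0) next
    used <- used + 1
    s_sites_a <- s_sites_a + oracle_syn_sites(ca[i])
    s_sites_b <- s_sites_b + oracle_syn_sites(cb[i])
    m <- do.call(rbind, paths)
    sd_sum <- sd_sum + mean(m[, 1])
    nd_sum <- nd_sum + mean(m[, 2])
  }
  s <- (s_sites_a + s_sites_b) / 2
  nn <- 3 * used - s
  ps <- sd_sum / s
  pn <- nd_sum / nn
  list(
    S = s, N = nn, Sd = sd_sum, Nd = nd_sum, pS = ps, pN = pn,
    ks = if (ps >= 0.75) NA_real_ else -0.75 * log(1 - 4 / 3 * ps),
    saturated = ps >= 0.75
  )
}

# Random in-frame stop-free CDS and a mutated partner.
random_cds_pair <- function(n_codons, n_mut) {
  sense <- names(.oracle_gc)[.oracle_gc != "*"]
  a_cod <- sample(sense, n_codons, replace = TRUE)
  b_cod <- a_cod
  for (i in seq_len(n_mut)) {
    repeat {
      ci <- sample(n_codons, 1)
      p <- sample(3, 1)
      cand <- b_cod[ci]
      substr(cand, p, p) <- sample(setdiff(.oracle_bases,
                                           substr(cand, p, p)), 1)
      if (.oracle_gc[[cand]] != "*") {
        b_cod[ci] <- cand
        break
      }
    }
  }
  list(a = paste0(a_cod, collapse = ""), b = paste0(b_cod, collapse = ""))
}

# ---- partition oracle: exhaustive search over set partitions into k ----

all_k_partitions <- function(n, k) {
  # Restricted-growth strings of length n with exactly k blocks.
  out <- list()
  rec <- function(assign, max_used) {
    i <- length(assign) + 1
    if (i > n) {
      if (max_used == k) out[[length(out) + 1]] <<- assign
      return(invisible())
    }
    for (g in seq_len(min(max_used + 1, k))) {
      rec(c(assign, g), max(max_used, g))
    }
  }
  rec(integer(0), 0L)
  out
}

# Total within-group link density (links per bp^2, summed over groups).
partition_objective <- function(assign, m, len) {
  sum(vapply(unique(assign), function(g) {
    idx <- which(assign == g)
    lg <- sum(len[idx])
    sum(m[idx, idx, drop = FALSE]) / 2 / lg^2
  }, numeric(1)))
}

oracle_partition <- function(contacts, lengths, k) {
  units <- sort(lengths$unitig)
  m <- matrix(0, length(units), length(units),
              dimnames = list(units, units))
  for (i in seq_len(nrow(contacts))) {
    a <- contacts$unitig_a[i]
    b <- contacts$unitig_b[i]
    m[a, b] <- m[a, b] + contacts$count[i]
    m[b, a] <- m[b, a] + contacts$count[i]
  }
  len <- stats::setNames(lengths$length, lengths$unitig)[units]
  best <- NULL
  best_obj <- -Inf
  for (assign in all_k_partitions(length(units), k)) {
    obj <- partition_objective(assign, m, len)
    if (obj > best_obj) {
      best_obj <- obj
      best <- assign
    }
  }
  stats::setNames(best, units)
}

# Planted two-block Poisson contact map.
planted_contacts <- function(n_per_block, lambda_intra, lambda_bg,
                             length_bp = 1e5) {
  units <- sprintf("u%02d", seq_len(2 * n_per_block))
  block <- rep(1:2, each = n_per_block)
  pairs <- t(utils::combn(seq_along(units), 2))
  rate <- ifelse(block[pairs[, 1]] == block[pairs[, 2]],
                 lambda_intra, lambda_bg)
  contacts <- tibble::tibble(
    unitig_a = units[pairs[, 1]], unitig_b = units[pairs[, 2]],
    count = stats::rpois(nrow(pairs), rate)
  )
  list(
    contacts = contacts[contacts$count > 0, ],
    lengths = tibble::tibble(unitig = units, length = length_bp),
    truth = stats::setNames(block, units)
  )
}

# ---- small simulation reused across tests ----

small_sim <- function(n_genes = 40, codons = 30, seed = 1,
                      t_div = 7.9e6, t_wgdt = 0.88e6, t_wgdh = 0.44e6) {
  simulate_haplotype_cds(history_params(
    t_div = t_div, t_wgdt = t_wgdt, t_wgdh = t_wgdh,
    n_genes = n_genes, codons_per_gene = codons, seed = seed
  ))
}

# ---- allelic pairing oracle: the three filters, written naively ----

oracle_cscore_pairs <- function(hits, cscore, dist, min_size) {
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    bo <- max(hits$score[hits$gene_a == hits$gene_a[i]])
    bi <- max(hits$score[hits$gene_b == hits$gene_b[i]])
    keep[i] <- hits$score[i] >= cscore * max(bo, bi)
  }
  retained <- hits[keep, ]
  # blocks by chained rank proximity within hap/chrom combination
  retained$block_key <- NA_character_
  for (grp in split(seq_len(nrow(retained)),
                    paste(retained$hap_a, retained$hap_b,
                          retained$chrom_a, retained$chrom_b))) {
    idx <- grp[order(retained$rank_a[grp], retained$rank_b[grp])]
    bid <- 1
    for (j in seq_along(idx)) {
      if (j > 1 &&
            (abs(retained$rank_a[idx[j]] - retained$rank_a[idx[j - 1]]) > dist ||
               abs(retained$rank_b[idx[j]] - retained$rank_b[idx[j - 1]]) > dist)) {
        bid <- bid + 1
      }
      retained$block_key[idx[j]] <- paste(retained$hap_a[idx[j]],
                                          retained$hap_b[idx[j]],
                                          retained$chrom_a[idx[j]],
                                          retained$chrom_b[idx[j]], bid)
    }
  }
  tab <- table(retained$block_key)
  retained <- retained[tab[retained$block_key] >= min_size, ]
  # greedy one-to-one per haplotype pair by descending score
  out <- list()
  for (grp in split(seq_len(nrow(retained)),
                    paste(retained$hap_a, retained$hap_b))) {
    idx <- grp[order(-retained$score[grp], retained$gene_a[grp],
                     retained$gene_b[grp])]
    used_a <- used_b <- character(0)
    for (j in idx) {
      if (!(retained$gene_a[j] %in% used_a) &&
            !(retained$gene_b[j] %in% used_b)) {
        out[[length(out) + 1]] <- retained[j, ]
        used_a <- c(used_a, retained$gene_a[j])
        used_b <- c(used_b, retained$gene_b[j])
      }
    }
  }
  res <- dplyr::bind_rows(out)
  res$block_key <- NULL
  res[order(res$hap_a, res$hap_b, res$gene_a), ]
}
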