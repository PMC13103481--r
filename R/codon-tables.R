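# Codon-level lookup tables shared by the sequence simulator and the NG86
# estimator. Built lazily once per session and cached in a package
# environment; everything downstream indexes codons as integers 1..64.

.hex_cache <- new.env(parent = emptyenv())

# Permutations of 1..n for n <= 3, used for mutational pathway enumeration.
.perms <- list(
  list(1L),
  list(c(1L, 2L), c(2L, 1L)),
  list(
    c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
    c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)
  )
)

#' @keywords internal
codon_tables <- function() {
  if (!is.null(.hex_cache$tables)) {
    return(.hex_cache$tables)
  }
  bases <- c("T", "C", "A", "G")
  grid <- expand.grid(p3 = bases, p2 = bases, p1 = bases,
                      stringsAsFactors = FALSE)
  codons <- paste0(grid$p1, grid$p2, grid$p3)
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  is_stop <- aa == "*"
  n <- length(codons)
  codon_index <- stats::setNames(seq_len(n), codons)

  # Base at each position and the integer codon reached by substituting
  # alternative `a` (1..3, the three non-identical bases in `bases` order)
  # at position `p`. Column j of the 64 x 9 proposal tables is
  # (p - 1) * 3 + a.
  base_at <- matrix("", n, 3)
  for (p in 1:3) base_at[, p] <- substr(codons, p, p)
  target <- matrix(0L, n, 9)
  syn <- matrix(FALSE, n, 9)
  stp <- matrix(FALSE, n, 9)
  for (p in 1:3) {
    for (a in 1:3) {
      j <- (p - 1L) * 3L + a
      alt <- vapply(seq_len(n), function(i) {
        setdiff(bases, base_at[i, p])[a]
      }, character(1))
      mutated <- codons
      substr(mutated, p, p) <- alt
      tgt <- codon_index[mutated]
      target[, j] <- tgt
      syn[, j] <- aa[tgt] == aa & !is_stop[tgt]
      stp[, j] <- is_stop[tgt]
    }
  }

  # NG86 synonymous site count per codon: at each position, the fraction of
  # the three single-base changes that are synonymous. Changes to stop
  # codons count as non-synonymous, following the standard convention.
  syn_sites <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is_stop[i]) next
    s <- 0
    for (p in 1:3) {
      cols <- (p - 1L) * 3L + 1:3
      s <- s + sum(syn[i, cols]) / 3
    }
    syn_sites[i] <- s
  }

  # Pairwise difference counts averaged over minimal mutational pathways.
  # Pathways passing through a stop codon are excluded; pairs where every
  # pathway is blocked get NA and are skipped (and logged) by the estimator.
  diff_pos <- function(i, k) which(base_at[i, ] != base_at[k, ])
  step_syn <- function(from, to) aa[from] == aa[to]
  sd_tab <- matrix(NA_real_, n, n)
  nd_tab <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    if (is_stop[i]) next
    for (k in seq_len(n)) {
      if (is_stop[k]) next
      d <- diff_pos(i, k)
      m <- length(d)
      if (m == 0L) {
        sd_tab[i, k] <- 0
        nd_tab[i, k] <- 0
        next
      }
      tot_s <- 0
      tot_n <- 0
      ok <- 0L
      for (ord in .perms[[m]]) {
        cur <- codons[i]
        s <- 0L
        nn <- 0L
        valid <- TRUE
        for (p in d[ord]) {
          nxt <- cur
          substr(nxt, p, p) <- base_at[k, p]
          if (is_stop[codon_index[nxt]]) {
            valid <- FALSE
            break
          }
          if (step_syn(codon_index[cur], codon_index[nxt])) s <- s + 1L
          else nn <- nn + 1L
          cur <- nxt
        }
        if (valid) {
          ok <- ok + 1L
          tot_s <- tot_s + s
          tot_n <- tot_n + nn
        }
      }
      if (ok > 0L) {
        sd_tab[i, k] <- tot_s / ok
        nd_tab[i, k] <- tot_n / ok
      }
    }
  }

  .hex_cache$tables <- list(
    codons = codons, aa = aa, is_stop = is_stop, codon_index = codon_index,
    target = target, syn = syn, stop = stp, syn_sites = syn_sites,
    sd = sd_tab, nd = nd_tab,
    sense = which(!is_stop)
  )
  .hex_cache$tables
}

#' @keywords internal
codons_to_index <- function(x) {
  tab <- codon_tables()
  nc <- nchar(x)
  if (nc %% 3 != 0) {
    rlang::abort("coding sequence length is not a multiple of 3")
  }
  cod <- substring(x, seq(1, nc, 3), seq(3, nc, 3))
  unname(tab$codon_index[cod])
}

#' @keywords internal
index_to_cds <- function(idx) {
  paste0(codon_tables()$codons[idx], collapse = "")
}
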