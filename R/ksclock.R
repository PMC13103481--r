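# Ks estimation (Nei-Gojobori 1986) and molecular-clock dating of
# polyploidy events from Ks distribution peaks.

#' Nei-Gojobori (1986) Ka/Ks for aligned coding sequence pairs
#'
#' Counts synonymous and non-synonymous sites and differences per the NG86
#' method and applies the Jukes-Cantor multiple-hit correction
#' `Ks = -(3/4) * log(1 - (4/3) * pS)`. Sites are averaged over both
#' sequences; codons differing at more than one position are resolved by
#' averaging over all minimal mutational pathways, excluding pathways that
#' pass through a stop codon. Codon pairs containing a gap (`-`) or an
#' ambiguous base, and codon pairs for which every pathway is blocked by a
#' stop, are skipped and counted in `codons_skipped`.
#'
#' @param cds_a,cds_b Character vectors of equal length holding aligned,
#'   in-frame coding sequences (A/C/G/T and `-`); element `i` of `cds_a` is
#'   compared with element `i` of `cds_b`.
#' @return A tibble with one row per pair: site counts `S` and `N`, observed
#'   differences `Sd` and `Nd`, proportions `pS` and `pN`, corrected rates
#'   `ks` and `ka` (`NA` when saturated), a `saturated` flag (`pS >= 3/4`),
#'   and `codons_skipped`.
#' @examples
#' a <- "ATGGCTGCTAAA"
#' ng86_ks(a, a)$ks # 0
#' @export
ng86_ks <- function(cds_a, cds_b) {
  if (length(cds_a) != length(cds_b)) {
    rlang::abort("cds_a and cds_b must have the same length")
  }
  tab <- codon_tables()
  res <- purrr::map2(cds_a, cds_b, function(a, b) ng86_one(a, b, tab))
  dplyr::bind_rows(res)
}

ng86_one <- function(a, b, tab) {
  if (nchar(a) != nchar(b)) {
    rlang::abort("sequences in a pair must have equal aligned length")
  }
  if (nchar(a) %% 3 != 0) {
    rlang::abort("aligned length must be a multiple of 3")
  }
  nc <- nchar(a)
  starts <- seq(1, nc, 3)
  ca <- substring(a, starts, starts + 2)
  cb <- substring(b, starts, starts + 2)
  ia <- unname(tab$codon_index[ca])
  ib <- unname(tab$codon_index[cb])
  usable <- !is.na(ia) & !is.na(ib) & !tab$is_stop[ifelse(is.na(ia), 1L, ia)] &
    !tab$is_stop[ifelse(is.na(ib), 1L, ib)]
  skipped <- sum(!usable)
  ia <- ia[usable]
  ib <- ib[usable]
  if (length(ia) == 0L) {
    rlang::abort("no comparable codons (all gapped or invalid)")
  }
  sd_i <- tab$sd[cbind(ia, ib)]
  blocked <- is.na(sd_i)
  if (any(blocked)) {
    skipped <- skipped + sum(blocked)
    ia <- ia[!blocked]
    ib <- ib[!blocked]
    sd_i <- sd_i[!blocked]
  }
  nd_i <- tab$nd[cbind(ia, ib)]
  s_sites <- (sum(tab$syn_sites[ia]) + sum(tab$syn_sites[ib])) / 2
  n_sites <- 3 * length(ia) - s_sites
  sd_sum <- sum(sd_i)
  nd_sum <- sum(nd_i)
  ps <- sd_sum / s_sites
  pn <- nd_sum / n_sites
  sat <- ps >= 0.75
  ks <- if (sat) NA_real_ else -0.75 * log(1 - 4 / 3 * ps)
  ka <- if (pn >= 0.75) NA_real_ else -0.75 * log(1 - 4 / 3 * pn)
  tibble::tibble(
    S = s_sites, N = n_sites, Sd = sd_sum, Nd = nd_sum,
    pS = ps, pN = pn, ks = ks, ka = ka,
    saturated = sat, codons_skipped = skipped
  )
}

#' Ks records for a list of gene pairs
#'
#' @param cds Named character vector (or `Biostrings::DNAStringSet`) of
#'   coding sequences covering every gene named in `pairs`.
#' @param pairs Tibble with columns `gene_a`, `gene_b` and optionally
#'   `category` (a pair-class label such as `"hap1 x hap2"`).
#' @return `pairs` with the [ng86_ks()] columns appended.
#' @export
ks_records <- function(pairs, cds) {
  if (inherits(cds, "XStringSet")) {
    cds <- stats::setNames(as.character(cds), names(cds))
  }
  missing <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), names(cds))
  if (length(missing) > 0) {
    rlang::abort(paste0("genes absent from cds: ", missing[1], " ..."))
  }
  dplyr::bind_cols(pairs, ng86_ks(cds[pairs$gene_a], cds[pairs$gene_b]))
}

#' Per-category Ks distributions with Gaussian kernel density estimates
#'
#' Saturated and undefined Ks values are excluded. The default bandwidth is
#' Silverman's rule-of-thumb (`stats::bw.nrd0`); the density is evaluated on
#' a 512-point grid over `[0, 1.05 * max(ks)]` per category.
#'
#' @param records Tibble of Ks records with columns `ks`, `saturated` and
#'   `category` (see [ks_records()]).
#' @param bandwidth `"silverman"` or a positive number.
#' @param min_records Minimum usable records required per category.
#' @param grid_n Number of density grid points.
#' @return An object of class `ks_distribution`: list with `data` (the
#'   retained records), `kde` (tibble `category`, `x`, `y`) and `bw`.
#' @export
ks_distribution <- function(records, bandwidth = "silverman",
                            min_records = 30, grid_n = 512) {
  if (!"category" %in% names(records)) records$category <- "all"
  records <- dplyr::filter(records, !.data$saturated, is.finite(.data$ks))
  counts <- dplyr::count(records, .data$category)
  bad <- counts$category[counts$n < min_records]
  if (length(bad) > 0) {
    rlang::abort(paste0(
      "too few unsaturated Ks records (< ", min_records, ") in category: ",
      paste(bad, collapse = ", ")
    ))
  }
  kde <- records |>
    dplyr::group_by(.data$category) |>
    dplyr::group_modify(function(df, key) {
      x <- df$ks
      bw <- if (identical(bandwidth, "silverman")) {
        b <- stats::bw.nrd0(x)
        if (!is.finite(b) || b <= 0) b <- max(1e-6, 0.01 * max(x, 1e-6))
        b
      } else {
        as.numeric(bandwidth)
      }
      hi <- 1.05 * max(x)
      if (hi <= 0) hi <- 1e-4
      d <- stats::density(x, bw = bw, n = grid_n, from = 0, to = hi)
      tibble::tibble(x = d$x, y = d$y, bw = bw)
    }) |>
    dplyr::ungroup()
  structure(
    list(
      data = records,
      kde = dplyr::select(kde, "category", "x", "y"),
      bw = dplyr::distinct(kde, .data$category, .data$bw)
    ),
    class = "ks_distribution"
  )
}

#' Detect Ks density peaks
#'
#' Local maxima of each category's kernel density estimate on its grid;
#' maxima closer than `min_separation` are merged, keeping the higher one.
#' Peaks are returned in descending density order within category.
#'
#' @param dist A [ks_distribution()] object.
#' @param min_separation Minimum Ks distance between reported peaks.
#' @return Tibble with `category`, `peak_ks`, `density` and `rank`.
#' @export
find_peaks <- function(dist, min_separation = 0.001) {
  stopifnot(inherits(dist, "ks_distribution"))
  dist$kde |>
    dplyr::group_by(.data$category) |>
    dplyr::group_modify(function(df, key) {
      y <- df$y
      n <- length(y)
      is_max <- y > dplyr::lag(y, default = -Inf) &
        y >= dplyr::lead(y, default = -Inf)
      px <- df$x[is_max]
      py <- y[is_max]
      ord <- order(py, decreasing = TRUE)
      px <- px[ord]
      py <- py[ord]
      keep_x <- numeric(0)
      keep_y <- numeric(0)
      for (i in seq_along(px)) {
        if (all(abs(px[i] - keep_x) >= min_separation)) {
          keep_x <- c(keep_x, px[i])
          keep_y <- c(keep_y, py[i])
        }
      }
      tibble::tibble(peak_ks = keep_x, density = keep_y,
                     rank = seq_along(keep_x))
    }) |>
    dplyr::ungroup()
}

#' Convert Ks to divergence time via the molecular clock
#'
#' `T = Ks / (2 r)`, with `r` the per-year synonymous substitution rate.
#' `mya` is reported rounded to two decimals.
#'
#' @param ks Non-negative Ks value(s).
#' @param r Synonymous substitution rate per site per year (default
#'   3.39e-9, an angiosperm neutral-rate calibration).
#' @return Tibble with `ks`, `r`, `years` and `mya`.
#' @examples
#' ks_to_time(0.003)$mya # 0.44
#' @export
ks_to_time <- function(ks, r = 3.39e-9) {
  if (any(r <= 0)) rlang::abort("substitution rate r must be positive")
  if (any(ks < 0, na.rm = TRUE)) rlang::abort("ks must be non-negative")
  years <- ks / (2 * r)
  tibble::tibble(ks = ks, r = r, years = years, mya = round(years / 1e6, 2))
}

#' Partition six haplotypes into a diploid-derived and a tetraploid-derived
#' subgenome
#'
#' Exhaustive search over all `choose(6, 2) = 15` two-versus-four splits of
#' the haplotypes, choosing the split that minimizes the mean
#' within-subgenome Ks. Suited to an allopolyploid whose haplotypes fall
#' into an older cross-subgenome divergence and younger within-subgenome
#' duplications.
#'
#' @param ks_summary Tibble with columns `hap_a`, `hap_b`, `ks` giving a
#'   summary (typically the median) Ks for every unordered haplotype pair,
#'   or a symmetric 6 x 6 matrix with haplotype names.
#' @param margin Warn when `between - within` mean Ks contrast falls below
#'   this value (no clear subgenome structure).
#' @return List of class `subgenome_assignment`: `subgenome_a` (size 2),
#'   `subgenome_b` (size 4), `within_mean`, `between_mean`, `contrast`.
#' @export
assign_subgenomes <- function(ks_summary, margin = 0.005) {
  if (is.matrix(ks_summary)) {
    haps <- rownames(ks_summary)
    idx <- which(upper.tri(ks_summary), arr.ind = TRUE)
    ks_summary <- tibble::tibble(
      hap_a = haps[idx[, 1]], hap_b = haps[idx[, 2]],
      ks = ks_summary[idx]
    )
  }
  haps <- sort(unique(c(ks_summary$hap_a, ks_summary$hap_b)))
  if (length(haps) != 6) {
    rlang::abort("subgenome assignment expects exactly 6 haplotypes")
  }
  lookup <- function(a, b) {
    hit <- ks_summary$ks[(ks_summary$hap_a == a & ks_summary$hap_b == b) |
                           (ks_summary$hap_a == b & ks_summary$hap_b == a)]
    if (length(hit) == 0 || !is.finite(hit[1])) {
      rlang::abort(paste0("missing or non-finite Ks summary for ", a, "-", b))
    }
    hit[1]
  }
  splits <- utils::combn(haps, 2, simplify = FALSE)
  best <- NULL
  for (a_set in splits) {
    b_set <- setdiff(haps, a_set)
    within <- c(
      lookup(a_set[1], a_set[2]),
      utils::combn(b_set, 2, function(p) lookup(p[1], p[2]))
    )
    between <- as.vector(outer(a_set, b_set, Vectorize(lookup)))
    cand <- list(
      subgenome_a = a_set, subgenome_b = b_set,
      within_mean = mean(within), between_mean = mean(between),
      contrast = mean(between) - mean(within)
    )
    if (is.null(best) || cand$within_mean < best$within_mean) best <- cand
  }
  if (best$contrast < margin) {
    rlang::warn("no clear subgenome structure: between/within Ks contrast below margin")
  }
  structure(best, class = "subgenome_assignment")
}

#' Date polyploidy events from category-labelled Ks records
#'
#' Takes the strongest density peak of each category and converts it to a
#' divergence time. Intended for categories such as allelic pairs within
#' each subgenome (dating the duplications) and pairs across subgenomes
#' (dating the ancestral species divergence).
#'
#' @inheritParams ks_distribution
#' @param r Synonymous substitution rate per site per year.
#' @param min_separation Passed to [find_peaks()].
#' @return Tibble with one row per category: `category`, `peak_ks`, `years`,
#'   `mya`.
#' @export
date_events <- function(records, r = 3.39e-9, bandwidth = "silverman",
                        min_separation = 0.001) {
  dist <- ks_distribution(records, bandwidth = bandwidth)
  peaks <- find_peaks(dist, min_separation = min_separation)
  top <- peaks |>
    dplyr::filter(.data$rank == 1) |>
    dplyr::select("category", peak_ks = "peak_ks")
  dplyr::bind_cols(
    top,
    ks_to_time(top$peak_ks, r = r)[, c("years", "mya")]
  )
}

#' @export
print.subgenome_assignment <- function(x, ...) {
  cat("Subgenome assignment\n")
  cat("  A (diploid-derived):    ", paste(x$subgenome_a, collapse = ", "), "\n")
  cat("  B (tetraploid-derived): ", paste(x$subgenome_b, collapse = ", "), "\n")
  cat(sprintf("  within-subgenome mean Ks:  %.5f\n", x$within_mean))
  cat(sprintf("  between-subgenome mean Ks: %.5f\n", x$between_mean))
  invisible(x)
}
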