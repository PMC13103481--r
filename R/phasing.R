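# Hi-C haplotype-group phasing of unitigs: allele-aware contact pruning,
# greedy density clustering, overlap deduplication within groups, ordered
# rescue of ungrouped unitigs, alignment-based chromosome assignment and
# depth-based collapse QC.
#
# Contacts are a tibble (unitig_a, unitig_b, count) over unordered pairs;
# lengths a tibble (unitig, length). A grouping is a tibble
# (unitig, group, status) with status in {grouped, ungrouped, removed} and
# group NA whenever the unitig is not grouped.

canonical_contacts <- function(contacts) {
  swap <- contacts$unitig_a > contacts$unitig_b
  tmp <- contacts$unitig_a[swap]
  contacts$unitig_a[swap] <- contacts$unitig_b[swap]
  contacts$unitig_b[swap] <- tmp
  contacts |>
    dplyr::filter(.data$unitig_a != .data$unitig_b) |>
    dplyr::group_by(.data$unitig_a, .data$unitig_b) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
}

contact_lookup <- function(contacts, units) {
  m <- matrix(0, length(units), length(units),
              dimnames = list(units, units))
  cc <- dplyr::filter(contacts, .data$unitig_a %in% units,
                      .data$unitig_b %in% units)
  m[cbind(cc$unitig_a, cc$unitig_b)] <- cc$count
  m[cbind(cc$unitig_b, cc$unitig_a)] <- cc$count
  m
}

#' Hi-C link density of a unitig against a set of unitigs
#'
#' Summed contact counts between `unitig` and the members of `group`,
#' divided by the unitig's length in bp (links per bp). An empty group has
#' density 0.
#'
#' @param contacts Tibble `unitig_a`, `unitig_b`, `count`.
#' @param lengths Tibble `unitig`, `length`.
#' @param unitig A unitig id present in `lengths`.
#' @param group Character vector of unitig ids (the reference set).
#' @return A single non-negative number (links per bp).
#' @export
link_density <- function(contacts, lengths, unitig, group) {
  len <- lengths$length[match(unitig, lengths$unitig)]
  if (is.na(len)) rlang::abort(paste0("unknown unitig: ", unitig))
  group <- setdiff(group, unitig)
  if (length(group) == 0) return(0)
  hits <- dplyr::filter(
    contacts,
    (.data$unitig_a == unitig & .data$unitig_b %in% group) |
      (.data$unitig_b == unitig & .data$unitig_a %in% group)
  )
  sum(hits$count) / len
}

#' Remove Hi-C contact signal between allelic unitigs
#'
#' For every reference gene in the allele table, all pairwise contacts
#' among the unitigs carrying a copy of that gene are set to zero (the
#' pairs are dropped from the sparse map). All other entries are untouched.
#' Idempotent; never increases a count.
#'
#' @inheritParams link_density
#' @param alleles Allele table as a long tibble `gene`, `unitig`.
#' @return The pruned contacts tibble.
#' @export
prune_allelic <- function(contacts, alleles) {
  if (nrow(alleles) == 0) return(contacts)
  pruned_pairs <- alleles |>
    dplyr::inner_join(alleles, by = "gene", suffix = c("_a", "_b"),
                      relationship = "many-to-many") |>
    dplyr::filter(.data$unitig_a < .data$unitig_b) |>
    dplyr::distinct(.data$unitig_a, .data$unitig_b)
  contacts |>
    dplyr::anti_join(pruned_pairs, by = c("unitig_a", "unitig_b")) |>
    dplyr::anti_join(
      dplyr::rename(pruned_pairs, unitig_a = "unitig_b", unitig_b = "unitig_a"),
      by = c("unitig_a", "unitig_b")
    )
}

#' Cluster unitigs into K haplotype groups by Hi-C link density
#'
#' Greedy agglomerative clustering: every unitig starts as its own cluster
#' and the pair of clusters with the highest inter-cluster link density
#' (summed counts between the clusters divided by the product of their
#' total lengths) is merged until `k` clusters remain. Ties are broken by
#' the lexicographically smallest member ids, making the result
#' deterministic.
#'
#' @inheritParams link_density
#' @param k Number of groups (>= 2).
#' @return A grouping tibble `unitig`, `group` (integer), `status`
#'   (`"grouped"`).
#' @export
partition_groups <- function(contacts, lengths, k) {
  units <- sort(lengths$unitig)
  if (k < 2) rlang::abort("k must be >= 2")
  if (length(units) < k) {
    rlang::abort("fewer unitigs than requested groups")
  }
  m <- contact_lookup(canonical_contacts(contacts), units)
  len <- stats::setNames(lengths$length, lengths$unitig)[units]
  clusters <- as.list(units)
  while (length(clusters) > k) {
    nc <- length(clusters)
    clen <- vapply(clusters, function(cl) sum(len[cl]), numeric(1))
    best <- NULL
    best_d <- -Inf
    for (i in seq_len(nc - 1)) {
      for (j in (i + 1):nc) {
        d <- sum(m[clusters[[i]], clusters[[j]], drop = FALSE]) /
          (clen[i] * clen[j])
        if (d > best_d + 1e-15) {
          best_d <- d
          best <- c(i, j)
        }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1]] <- merged
    # Keep cluster order deterministic: sort by first member id.
    clusters <- clusters[order(vapply(clusters, `[`, character(1), 1))]
  }
  dplyr::bind_rows(lapply(seq_along(clusters), function(g) {
    tibble::tibble(unitig = clusters[[g]], group = g, status = "grouped")
  })) |>
    dplyr::arrange(.data$unitig)
}

large_overlap_pairs <- function(overlaps, lengths, large_frac, min_identity) {
  len <- stats::setNames(lengths$length, lengths$unitig)
  overlaps |>
    dplyr::transmute(
      unitig_a = pmin(.data$qname, .data$tname),
      unitig_b = pmax(.data$qname, .data$tname),
      ov_len = .data$alen,
      identity = .data$nmatch / .data$alen
    ) |>
    dplyr::mutate(
      shorter = pmin(unname(len[.data$unitig_a]), unname(len[.data$unitig_b]))
    ) |>
    dplyr::filter(.data$ov_len >= large_frac * .data$shorter,
                  .data$identity >= min_identity) |>
    dplyr::distinct(.data$unitig_a, .data$unitig_b, .keep_all = TRUE)
}

#' Deduplicate overlapping unitigs inside haplotype groups
#'
#' Within each group, overlapping pairs whose overlap is at least
#' `large_frac` of the shorter unitig (and whose identity reaches
#' `min_identity`) are processed in descending overlap length; for each,
#' the member with the lower Hi-C link density to the rest of its group is
#' moved to the ungrouped pool. Densities are recomputed after every
#' removal.
#'
#' @param grouping A grouping tibble (see [partition_groups()]).
#' @inheritParams link_density
#' @param overlaps PAF-style overlap tibble (see [read_paf()]).
#' @param large_frac Overlap fraction of the shorter unitig that counts as
#'   "large", in `(0, 1]`.
#' @param min_identity Minimum overlap identity.
#' @return List with `grouping` (updated tibble; removed members get
#'   status `"removed"`, group `NA`) and `removals` (log tibble with both
#'   densities for every removal).
#' @export
dedup_overlaps <- function(grouping, contacts, lengths, overlaps,
                           large_frac = 0.5, min_identity = 0.9) {
  if (large_frac <= 0 || large_frac > 1) {
    rlang::abort("large_frac must be in (0, 1]")
  }
  ov <- large_overlap_pairs(overlaps, lengths, large_frac, min_identity) |>
    dplyr::arrange(dplyr::desc(.data$ov_len), .data$unitig_a, .data$unitig_b)
  log <- list()
  grp_of <- function(u) grouping$group[match(u, grouping$unitig)]
  for (i in seq_len(nrow(ov))) {
    a <- ov$unitig_a[i]
    b <- ov$unitig_b[i]
    ga <- grp_of(a)
    gb <- grp_of(b)
    if (is.na(ga) || is.na(gb) || ga != gb) next
    members <- grouping$unitig[!is.na(grouping$group) &
                                 grouping$group == ga]
    da <- link_density(contacts, lengths, a, setdiff(members, a))
    db <- link_density(contacts, lengths, b, setdiff(members, b))
    # Lower density loses; tie broken by removing the lexicographically
    # larger id.
    drop <- if (da < db) a else if (db < da) b else max(a, b)
    grouping$group[grouping$unitig == drop] <- NA_integer_
    grouping$status[grouping$unitig == drop] <- "removed"
    log[[length(log) + 1]] <- tibble::tibble(
      removed = drop, kept = setdiff(c(a, b), drop), group = ga,
      ov_len = ov$ov_len[i], density_removed = min(da, db),
      density_kept = max(da, db)
    )
  }
  list(grouping = grouping, removals = dplyr::bind_rows(log))
}

#' Rescue ungrouped unitigs into haplotype groups
#'
#' Ungrouped (and removed) unitigs are processed in descending order of
#' their strongest group link density; for each, candidate groups are
#' tried in descending link-density order and the unitig joins the first
#' group in which it has no large overlap with any member. Unitigs that
#' conflict with every group stay ungrouped. Earlier placements are
#' visible to later tests. Ties are broken by unitig id, then by lowest
#' group index.
#'
#' @inheritParams dedup_overlaps
#' @return The updated grouping tibble (rescued members get status
#'   `"grouped"`).
#' @export
rescue_ungrouped <- function(grouping, contacts, lengths, overlaps,
                             large_frac = 0.5, min_identity = 0.9) {
  ov <- large_overlap_pairs(overlaps, lengths, large_frac, min_identity)
  conflict <- function(u, members) {
    any((ov$unitig_a == u & ov$unitig_b %in% members) |
          (ov$unitig_b == u & ov$unitig_a %in% members))
  }
  repeat_pool <- sort(grouping$unitig[is.na(grouping$group)])
  if (length(repeat_pool) == 0) return(grouping)
  groups <- sort(unique(grouping$group[!is.na(grouping$group)]))
  best_signal <- vapply(repeat_pool, function(u) {
    max(vapply(groups, function(g) {
      link_density(contacts, lengths, u,
                   grouping$unitig[!is.na(grouping$group) &
                                     grouping$group == g])
    }, numeric(1)))
  }, numeric(1))
  order_pool <- repeat_pool[order(-best_signal, repeat_pool)]
  for (u in order_pool) {
    dens <- vapply(groups, function(g) {
      link_density(contacts, lengths, u,
                   grouping$unitig[!is.na(grouping$group) &
                                     grouping$group == g])
    }, numeric(1))
    for (g in groups[order(-dens, groups)]) {
      members <- grouping$unitig[!is.na(grouping$group) &
                                   grouping$group == g]
      if (!conflict(u, members)) {
        grouping$group[grouping$unitig == u] <- g
        grouping$status[grouping$unitig == u] <- "grouped"
        break
      }
    }
  }
  grouping
}

#' Assign unitigs without gene evidence to chromosomes by alignment score
#'
#' Each unitig goes to its highest-scoring chromosome; unitigs without
#' hits are left unassigned. Score ties are broken by the lowest
#' chromosome id.
#'
#' @param hits Tibble `unitig`, `chrom`, `score`.
#' @param unitigs Optional character vector of unitigs to report (those
#'   without hits appear with `chrom = NA`).
#' @return Tibble `unitig`, `chrom`, `score`.
#' @export
assign_by_alignment <- function(hits, unitigs = NULL) {
  best <- hits |>
    dplyr::arrange(.data$unitig, dplyr::desc(.data$score), .data$chrom) |>
    dplyr::distinct(.data$unitig, .keep_all = TRUE)
  if (!is.null(unitigs)) {
    best <- tibble::tibble(unitig = unitigs) |>
      dplyr::left_join(best, by = "unitig")
  }
  best
}

#' Flag candidate collapsed regions from window depths
#'
#' Windows whose mean coverage reaches `fold` times the genome-wide median
#' are flagged as candidate collapsed (multi-copy sequence assembled once
#' attracts the summed depth of its copies).
#'
#' @param depths Tibble `chrom`, `start`, `end`, `depth` (BED-like,
#'   0-based half-open windows).
#' @param fold Flagging threshold as a multiple of the median (> 1).
#' @param median_depth Optional externally supplied genome median; by
#'   default the median of `depths$depth`.
#' @return `depths` with a logical `flagged` column; the fraction flagged
#'   is stored in attribute `fraction_flagged`.
#' @export
detect_collapse <- function(depths, fold = 1.75, median_depth = NULL) {
  if (fold <= 1) rlang::abort("fold must be > 1")
  med <- if (is.null(median_depth)) stats::median(depths$depth) else median_depth
  if (!is.finite(med) || med == 0) {
    rlang::abort("genome median depth is zero; cannot normalize")
  }
  out <- dplyr::mutate(depths, flagged = .data$depth >= fold * med)
  attr(out, "fraction_flagged") <- mean(out$flagged)
  out
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1)
  out <- list()
  for (p in sub) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1]] <- append(p, n, after = pos - 1)
    }
  }
  out
}

#' Length-weighted phasing accuracy against simulation truth
#'
#' Finds the group-to-haplotype label permutation maximizing agreement and
#' returns the length-weighted fraction of grouped unitigs placed with
#' their true haplotype. Ungrouped/removed unitigs are not counted.
#'
#' @param grouping A grouping tibble.
#' @param truth Tibble `unitig`, `haplotype` (and optionally a `length`
#'   column or `start`/`end`) covering all grouped unitigs.
#' @param lengths Optional tibble `unitig`, `length` if `truth` lacks one.
#' @return A single number in `[0, 1]`.
#' @export
phasing_accuracy <- function(grouping, truth, lengths = NULL) {
  g <- dplyr::filter(grouping, !is.na(.data$group))
  if (nrow(g) == 0) return(NA_real_)
  if (!"length" %in% names(truth)) {
    if (all(c("start", "end") %in% names(truth))) {
      truth$length <- truth$end - truth$start
    } else if (!is.null(lengths)) {
      truth <- dplyr::left_join(truth, lengths, by = "unitig")
    } else {
      truth$length <- 1
    }
  }
  g <- dplyr::inner_join(g, truth[, c("unitig", "haplotype", "length")],
                         by = "unitig")
  if (nrow(g) == 0) rlang::abort("truth does not cover any grouped unitig")
  groups <- sort(unique(g$group))
  haps <- sort(unique(truth$haplotype))
  k <- max(length(groups), length(haps))
  # Weight matrix: length of agreement if group i is labelled haplotype j.
  w <- matrix(0, k, k)
  for (i in seq_along(groups)) {
    for (j in seq_along(haps)) {
      w[i, j] <- sum(g$length[g$group == groups[i] &
                                g$haplotype == haps[j]])
    }
  }
  best <- 0
  for (p in all_permutations(k)) {
    s <- sum(w[cbind(seq_len(k), p)])
    if (s > best) best <- s
  }
  best / sum(g$length)
}

#' Run the full phasing stage on a fragment set
#'
#' Convenience composition: prune allelic contacts, cluster into `k`
#' groups, deduplicate overlapping group members, rescue the ungrouped
#' pool.
#'
#' @param fragments A `hex_fragments` object (or a list with `contacts`,
#'   `lengths`, `alleles`, `overlaps`).
#' @param k Number of haplotype groups.
#' @inheritParams dedup_overlaps
#' @return List with `grouping`, `removals` and the pruned `contacts`.
#' @export
phase_unitigs <- function(fragments, k = 6, large_frac = 0.5,
                          min_identity = 0.9) {
  pruned <- prune_allelic(fragments$contacts, fragments$alleles)
  grouping <- partition_groups(pruned, fragments$lengths, k = k)
  dd <- dedup_overlaps(grouping, pruned, fragments$lengths,
                       fragments$overlaps, large_frac, min_identity)
  grouping <- rescue_ungrouped(dd$grouping, pruned, fragments$lengths,
                               fragments$overlaps, large_frac, min_identity)
  list(grouping = grouping, removals = dd$removals, contacts = pruned)
}
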