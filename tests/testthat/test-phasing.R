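# Phasing stage: link density, pruning, clustering, dedup, rescue,
# chromosome assignment, collapse QC and accuracy scoring.

toy_contacts <- function() {
  tibble::tibble(
    unitig_a = c("u1", "u1", "u2"),
    unitig_b = c("u2", "u3", "u3"),
    count = c(5, 7, 2)
  )
}
toy_lengths <- function() {
  tibble::tibble(unitig = c("u1", "u2", "u3"), length = c(1000, 2000, 500))
}

test_that("link density is summed counts over unitig length", {
  expect_equal(link_density(toy_contacts(), toy_lengths(), "u1",
                            c("u2", "u3")), 12 / 1000)
  expect_equal(link_density(toy_contacts(), toy_lengths(), "u1",
                            character(0)), 0)
  expect_equal(link_density(toy_contacts(), toy_lengths(), "u3", "u9"), 0)
  expect_error(link_density(toy_contacts(), toy_lengths(), "uX", "u1"),
               "unknown")
  # brute-force oracle on a random sparse map
  set.seed(11)
  units <- sprintf("u%02d", 1:12)
  pairs <- t(utils::combn(units, 2))
  cc <- tibble::tibble(unitig_a = pairs[, 1], unitig_b = pairs[, 2],
                       count = rpois(nrow(pairs), 2))
  lens <- tibble::tibble(unitig = units, length = sample(1e4:1e5, 12))
  grp <- sample(units, 5)
  u <- setdiff(units, grp)[1]
  brute <- sum(vapply(grp, function(g) {
    sum(cc$count[(cc$unitig_a == u & cc$unitig_b == g) |
                   (cc$unitig_a == g & cc$unitig_b == u)])
  }, numeric(1))) / lens$length[lens$unitig == u]
  expect_equal(link_density(cc, lens, u, grp), brute)
})

test_that("allelic pruning zeroes exactly the allelic pair set and is idempotent", {
  cc <- toy_contacts()
  al <- tibble::tibble(gene = c("g1", "g1"), unitig = c("u1", "u2"))
  pruned <- prune_allelic(cc, al)
  expect_equal(nrow(dplyr::filter(pruned, unitig_a == "u1",
                                  unitig_b == "u2")), 0)
  expect_equal(dplyr::filter(pruned, unitig_a == "u1", unitig_b == "u3")$count, 7)
  expect_identical(prune_allelic(pruned, al), pruned)
  expect_identical(prune_allelic(cc, al[0, ]), cc)

  # randomized set-union oracle
  set.seed(12)
  units <- sprintf("u%02d", 1:10)
  pairs <- t(utils::combn(units, 2))
  cc2 <- tibble::tibble(unitig_a = pairs[, 1], unitig_b = pairs[, 2],
                        count = rpois(nrow(pairs), 3) + 1)
  al2 <- tibble::tibble(
    gene = sample(sprintf("g%d", 1:4), 12, replace = TRUE),
    unitig = sample(units, 12, replace = TRUE)
  ) |> dplyr::distinct()
  pruned2 <- prune_allelic(cc2, al2)
  # brute force: union of all within-gene pairs
  zap <- unique(unlist(lapply(split(al2$unitig, al2$gene), function(us) {
    if (length(us) < 2) return(character(0))
    apply(utils::combn(sort(us), 2), 2, paste, collapse = "|")
  })))
  for (i in seq_len(nrow(cc2))) {
    key <- paste(sort(c(cc2$unitig_a[i], cc2$unitig_b[i])), collapse = "|")
    present <- any(pruned2$unitig_a == cc2$unitig_a[i] &
                     pruned2$unitig_b == cc2$unitig_b[i])
    expect_equal(present, !(key %in% zap))
  }
})

test_that("clustering separates perfect blocks and respects boundaries", {
  # two perfect triangles
  cc <- tibble::tibble(
    unitig_a = c("a1", "a1", "a2", "b1", "b1", "b2"),
    unitig_b = c("a2", "a3", "a3", "b2", "b3", "b3"),
    count = 10
  )
  lens <- tibble::tibble(unitig = c("a1", "a2", "a3", "b1", "b2", "b3"),
                         length = 1e5)
  g <- partition_groups(cc, lens, k = 2)
  expect_equal(length(unique(g$group[g$unitig %in% c("a1", "a2", "a3")])), 1)
  expect_equal(length(unique(g$group[g$unitig %in% c("b1", "b2", "b3")])), 1)
  expect_equal(dplyr::n_distinct(g$group), 2)

  g_all <- partition_groups(cc, lens, k = 6)
  expect_equal(dplyr::n_distinct(g_all$group), 6)
  expect_error(partition_groups(cc, lens, k = 7), "fewer unitigs")
  expect_error(partition_groups(cc, lens, k = 1), "k must be")
})

test_that("greedy clustering matches the exhaustive optimum on planted maps", {
  for (seed in 1:4) {
    set.seed(seed)
    pl <- planted_contacts(4, lambda_intra = 20, lambda_bg = 1)
    got <- partition_groups(pl$contacts, pl$lengths, k = 2)
    want <- oracle_partition(pl$contacts, pl$lengths, k = 2)
    got_assign <- stats::setNames(got$group, got$unitig)[names(want)]
    # same partition up to label permutation
    expect_equal(length(unique(paste(got_assign, want))),
                 length(unique(got_assign)))
    # and both recover the planted blocks
    expect_equal(phasing_accuracy(
      got, tibble::tibble(unitig = names(pl$truth), haplotype = pl$truth)
    ), 1.0)
  }
})

make_group_fixture <- function() {
  units <- c("u1", "u2", "u3", "u4")
  grouping <- tibble::tibble(
    unitig = units, group = c(1L, 1L, 1L, NA), status =
      c(rep("grouped", 3), "ungrouped")
  )
  lengths <- tibble::tibble(unitig = units, length = c(1e5, 8e4, 9e4, 7e4))
  contacts <- tibble::tibble(
    unitig_a = c("u1", "u1", "u2", "u4", "u4"),
    unitig_b = c("u2", "u3", "u3", "u1", "u2"),
    count = c(50, 30, 40, 9, 4)
  )
  list(grouping = grouping, lengths = lengths, contacts = contacts)
}

paf_row <- function(q, t, alen, qlen = 1e5, tlen = 1e5, ident = 0.95) {
  tibble::tibble(
    qname = q, qlen = qlen, qstart = 0L, qend = alen, strand = "+",
    tname = t, tlen = tlen, tstart = 0L, tend = alen,
    nmatch = round(ident * alen), alen = alen, mapq = 60L
  )
}

test_that("dedup removes the lower-density member of a large overlap", {
  fx <- make_group_fixture()
  # u2 (len 80k) vs u3 (len 90k): overlap 70k >= 0.5 * 80k -> large
  ov <- paf_row("u2", "u3", 7e4, qlen = 8e4, tlen = 9e4)
  dd <- dedup_overlaps(fx$grouping, fx$contacts, fx$lengths, ov)
  # densities to rest of group: u2 = (50+40)/8e4; u3 = (30+40)/9e4 -> u3 lower
  expect_equal(dd$grouping$status[dd$grouping$unitig == "u3"], "removed")
  expect_equal(nrow(dd$removals), 1)
  expect_equal(dd$removals$removed, "u3")
  expect_lt(dd$removals$density_removed, dd$removals$density_kept)

  # below threshold: no removal
  ov_small <- paf_row("u2", "u3", 3e4, qlen = 8e4, tlen = 9e4)
  dd2 <- dedup_overlaps(fx$grouping, fx$contacts, fx$lengths, ov_small)
  expect_equal(nrow(dd2$removals), 0)
  # low identity: no removal
  ov_lowid <- paf_row("u2", "u3", 7e4, qlen = 8e4, tlen = 9e4, ident = 0.5)
  dd3 <- dedup_overlaps(fx$grouping, fx$contacts, fx$lengths, ov_lowid)
  expect_equal(nrow(dd3$removals), 0)
})

test_that("dedup on an overlap chain equals ordered sequential replay", {
  fx <- make_group_fixture()
  # chain u1-u2 (85k overlap), u2-u3 (75k): processed by descending length.
  ov <- dplyr::bind_rows(
    paf_row("u1", "u2", 7.9e4, qlen = 1e5, tlen = 8e4),
    paf_row("u2", "u3", 7.5e4, qlen = 8e4, tlen = 9e4)
  )
  dd <- dedup_overlaps(fx$grouping, fx$contacts, fx$lengths, ov)
  # replay: first pair u1/u2: d(u1)=(50+30)/1e5=8e-4, d(u2)=(50+40)/8e4=1.125e-3
  #   -> u1 removed. second pair u2/u3 (both still grouped):
  #   d(u2)=40/8e4=5e-4, d(u3)=40/9e4=4.4e-4 -> u3 removed.
  expect_setequal(dd$removals$removed, c("u1", "u3"))
  expect_equal(dd$grouping$status[dd$grouping$unitig == "u2"], "grouped")
})

test_that("rescue places ungrouped unitigs into the best conflict-free group", {
  grouping <- tibble::tibble(
    unitig = c("a1", "a2", "b1", "b2", "u5"),
    group = c(1L, 1L, 2L, 2L, NA),
    status = c(rep("grouped", 4), "ungrouped")
  )
  lengths <- tibble::tibble(unitig = grouping$unitig, length = 1e5)
  contacts <- tibble::tibble(
    unitig_a = c("a1", "b1", "u5", "u5"),
    unitig_b = c("a2", "b2", "a1", "b1"),
    count = c(10, 10, 9, 4)
  )
  ov <- paf_row("u5", "a1", 8e4) # conflict with group 1 only
  out <- rescue_ungrouped(grouping, contacts, lengths, ov)
  expect_equal(out$group[out$unitig == "u5"], 2L)
  expect_equal(out$status[out$unitig == "u5"], "grouped")

  # conflicting with every group: stays ungrouped
  ov_all <- dplyr::bind_rows(paf_row("u5", "a1", 8e4),
                             paf_row("u5", "b2", 8e4))
  out2 <- rescue_ungrouped(grouping, contacts, lengths, ov_all)
  expect_true(is.na(out2$group[out2$unitig == "u5"]))
})

test_that("dedup then rescue leaves no large overlap inside any group", {
  for (seed in 1:3) {
    sim <- small_sim(n_genes = 60, codons = 30, seed = seed)
    fr <- fragment_and_contacts(sim, unitigs_per_hap = 8, seed = seed)
    ph <- phase_unitigs(fr, k = 6)
    ov <- hexorigin:::large_overlap_pairs(fr$overlaps, fr$lengths, 0.5, 0.9)
    g <- ph$grouping
    grouped <- g[!is.na(g$group), ]
    in_same_group <- function(a, b) {
      ga <- grouped$group[match(a, grouped$unitig)]
      gb <- grouped$group[match(b, grouped$unitig)]
      !is.na(ga) & !is.na(gb) & ga == gb
    }
    expect_false(any(in_same_group(ov$unitig_a, ov$unitig_b)))
    # partition invariant: statuses partition the unitig set
    expect_setequal(g$unitig, fr$truth$unitig)
    expect_true(all(is.na(g$group) == (g$status != "grouped")))
  }
})

test_that("alignment assignment takes the argmax with deterministic ties", {
  hits <- tibble::tibble(
    unitig = c("u9", "u9", "u7", "u7"),
    chrom = c("chr1", "chr2", "chr2", "chr1"),
    score = c(500, 900, 300, 300)
  )
  out <- assign_by_alignment(hits, unitigs = c("u9", "u7", "u0"))
  expect_equal(out$chrom[out$unitig == "u9"], "chr2")
  expect_equal(out$chrom[out$unitig == "u7"], "chr1") # tie -> lowest chrom
  expect_true(is.na(out$chrom[out$unitig == "u0"]))

  # randomized exhaustive oracle
  set.seed(20)
  for (i in 1:20) {
    ht <- tibble::tibble(
      unitig = sample(sprintf("u%d", 1:5), 12, replace = TRUE),
      chrom = sample(sprintf("chr%d", 1:4), 12, replace = TRUE),
      score = sample(100:999, 12)
    )
    got <- assign_by_alignment(ht)
    for (u in unique(ht$unitig)) {
      sub <- ht[ht$unitig == u, ]
      best <- sub[sub$score == max(sub$score), ]
      expect_equal(got$chrom[got$unitig == u], min(best$chrom))
    }
  }
})

test_that("collapse detection flags high-depth windows", {
  d <- tibble::tibble(chrom = "chr1", start = seq(0, 4e4, 1e4),
                      end = seq(1e4, 5e4, 1e4),
                      depth = c(48, 48, 96, 50, 47))
  out <- detect_collapse(d, fold = 1.75)
  expect_equal(which(out$flagged), 3)
  expect_equal(attr(out, "fraction_flagged"), 0.2)
  flat <- dplyr::mutate(d, depth = 50)
  expect_false(any(detect_collapse(flat)$flagged))
  expect_error(detect_collapse(dplyr::mutate(d, depth = 0)), "zero")
  expect_error(detect_collapse(d, fold = 1), "fold")

  # simulated single-copy region in a duplicated background: the assembly
  # collapses the duplication, so the two-copy windows map at double depth
  set.seed(5)
  copy_n <- rep(c(2, 1, 2), times = c(30, 10, 30))
  depth <- rpois(70, 30 * copy_n)
  dd <- tibble::tibble(chrom = "chr1", start = 0:69, end = 1:70,
                       depth = depth)
  out2 <- detect_collapse(dd, fold = 1.5, median_depth = 30)
  expect_equal(out2$flagged, copy_n == 2)
})

test_that("phasing accuracy is permutation-invariant and length-weighted", {
  truth <- tibble::tibble(
    unitig = sprintf("u%d", 1:6),
    haplotype = rep(1:2, each = 3),
    length = c(10, 10, 10, 10, 10, 50)
  )
  g_true <- tibble::tibble(unitig = truth$unitig,
                           group = rep(1:2, each = 3), status = "grouped")
  expect_equal(phasing_accuracy(g_true, truth), 1.0)
  g_perm <- dplyr::mutate(g_true, group = 3L - group)
  expect_equal(phasing_accuracy(g_perm, truth), 1.0)
  # one heavy unitig misplaced
  g_bad <- g_true
  g_bad$group[6] <- 1L
  expect_equal(phasing_accuracy(g_bad, truth), 50 / 100)

  # random 2-group null: expected accuracy about 0.5
  set.seed(30)
  tr <- tibble::tibble(unitig = sprintf("u%d", 1:20),
                       haplotype = rep(1:2, each = 10), length = 1)
  accs <- replicate(60, {
    g <- tibble::tibble(unitig = tr$unitig,
                        group = sample(1:2, 20, replace = TRUE),
                        status = "grouped")
    phasing_accuracy(g, tr)
  })
  # E[max(a, 20 - a)/20], a ~ Bin(20, 1/2): (10 + 20 C(19,9) / 2^20) / 20
  expect_lt(abs(mean(accs) - 0.588), 0.035)
})
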