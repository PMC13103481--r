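# Truth-annotated synthetic hexaploid generator: coding sequences evolved
# along the hybridization/WGD event tree, unitig fragmentation with
# block-structured Hi-C contacts and overlaps, and negative-binomial
# expression with subgenome dominance and allele-specific effects.

#' Evolutionary history parameters for the synthetic hexaploid
#'
#' Describes an allohexaploid formed by hybridization between a diploid
#' lineage (subgenome A: haplotypes 1-2) and an autotetraploid lineage
#' (subgenome B: haplotypes 3-6). The two ancestors diverged `t_div` years
#' ago; the tetraploid-forming duplication (WGDt) happened `t_wgdt` years
#' ago and the hexaploid-forming doubling (WGDh) `t_wgdh` years ago.
#' Synonymous sites substitute at `r_syn` per site per year and
#' non-synonymous sites at `omega * r_syn`.
#'
#' @param t_div,t_wgdt,t_wgdh Event times in years before present; must
#'   satisfy `t_div > t_wgdt > t_wgdh >= 0`.
#' @param r_syn Synonymous substitution rate per site per year.
#' @param omega Non-synonymous/synonymous rate ratio in `[0, 1]`.
#' @param n_genes Number of ancestral loci.
#' @param codons_per_gene Codons per coding sequence (>= 10). The default of
#'   500 keeps the expected number of synonymous differences at the youngest
#'   event above one, which is what lets a density peak resolve it.
#' @param b_topology List of two integer pairs giving which subgenome-B
#'   haplotypes coalesce at WGDh; the two resulting ancestors split at WGDt.
#' @param seed Integer seed controlling all randomness.
#' @return A validated list of class `history_params`.
#' @export
history_params <- function(t_div = 7.9e6, t_wgdt = 0.88e6, t_wgdh = 0.44e6,
                           r_syn = 3.39e-9, omega = 0.2, n_genes = 500,
                           codons_per_gene = 500,
                           b_topology = list(c(3L, 4L), c(5L, 6L)),
                           seed = 1L) {
  if (!(t_div > t_wgdt && t_wgdt > t_wgdh && t_wgdh >= 0)) {
    rlang::abort("event times must satisfy t_div > t_wgdt > t_wgdh >= 0")
  }
  if (r_syn <= 0) rlang::abort("r_syn must be positive")
  if (omega < 0 || omega > 1) rlang::abort("omega must be in [0, 1]")
  if (n_genes < 1) rlang::abort("n_genes must be >= 1")
  if (codons_per_gene < 10) {
    rlang::abort("codons_per_gene < 10: Ks estimates would be unstable")
  }
  tops <- sort(unlist(b_topology))
  if (!identical(as.integer(tops), 3:6)) {
    rlang::abort("b_topology must partition haplotypes 3..6 into two pairs")
  }
  structure(
    list(
      t_div = t_div, t_wgdt = t_wgdt, t_wgdh = t_wgdh, r_syn = r_syn,
      omega = omega, n_genes = as.integer(n_genes),
      codons_per_gene = as.integer(codons_per_gene),
      b_topology = lapply(b_topology, as.integer), seed = as.integer(seed)
    ),
    class = "history_params"
  )
}

# Evolve a matrix of codon indices (genes x codons) for `years` years.
# Mutation proposals arrive at rate r_syn per nucleotide site and pick one
# of the three alternative bases uniformly; synonymous proposals fix,
# non-synonymous proposals fix with probability omega, and proposals
# creating a stop codon are discarded (keeping realized synonymous rates
# exactly consistent with NG86 site counting).
evolve_codons <- function(mat, years, r_syn, omega) {
  tab <- codon_tables()
  n_sites <- length(mat) * 3
  n_ev <- stats::rpois(1, n_sites * r_syn * years)
  if (n_ev == 0) return(mat)
  cell <- sample.int(length(mat), n_ev, replace = TRUE)
  col_j <- sample.int(9L, n_ev, replace = TRUE)
  u <- stats::runif(n_ev)
  for (i in seq_len(n_ev)) {
    c0 <- mat[cell[i]]
    j <- col_j[i]
    if (tab$stop[c0, j]) next
    if (tab$syn[c0, j] || u[i] <= omega) {
      mat[cell[i]] <- tab$target[c0, j]
    }
  }
  mat
}

#' Simulate six haplotype CDS sets along the hexaploid event tree
#'
#' Each ancestral gene is evolved along the tree
#' `((hap1, hap2)@t_wgdh, ((B-pair1)@t_wgdh, (B-pair2)@t_wgdh)@t_wgdt)@t_div`
#' under a codon model whose synonymous sites follow the same Jukes-Cantor
#' assumptions as the downstream NG86 estimator. The expected Ks between
#' two copies that separated `T` years ago is `2 * r_syn * T`.
#'
#' @param params A [history_params()] object.
#' @return A list of class `hex_sim` with `cds` (named list `hap1..hap6` of
#'   named character vectors), `truth` (tibble `gene`, `haplotype`,
#'   `gene_id`) and `params`.
#' @export
simulate_haplotype_cds <- function(params) {
  stopifnot(inherits(params, "history_params"))
  set.seed(params$seed)
  tab <- codon_tables()
  n <- params$n_genes
  cpg <- params$codons_per_gene
  r <- params$r_syn
  w <- params$omega

  anc <- matrix(
    sample(tab$sense, n * cpg, replace = TRUE),
    nrow = n, ncol = cpg
  )
  # Stem lineages.
  a_stem <- evolve_codons(anc, params$t_div - params$t_wgdh, r, w)
  b_root <- evolve_codons(anc, params$t_div - params$t_wgdt, r, w)
  hap <- vector("list", 6)
  hap[[1]] <- evolve_codons(a_stem, params$t_wgdh, r, w)
  hap[[2]] <- evolve_codons(a_stem, params$t_wgdh, r, w)
  for (pair in params$b_topology) {
    pair_anc <- evolve_codons(b_root, params$t_wgdt - params$t_wgdh, r, w)
    for (h in pair) {
      hap[[h]] <- evolve_codons(pair_anc, params$t_wgdh, r, w)
    }
  }

  genes <- sprintf("g%04d", seq_len(n))
  cds <- lapply(1:6, function(h) {
    seqs <- vapply(seq_len(n), function(g) index_to_cds(hap[[h]][g, ]),
                   character(1))
    stats::setNames(seqs, paste0("hap", h, "_", genes))
  })
  names(cds) <- paste0("hap", 1:6)
  truth <- tidyr::expand_grid(gene = genes, haplotype = 1:6) |>
    dplyr::mutate(gene_id = paste0("hap", .data$haplotype, "_", .data$gene))
  structure(
    list(cds = cds, truth = truth, params = params),
    class = "hex_sim"
  )
}

#' Expected Ks between haplotype copies under the history parameters
#'
#' @param params A [history_params()] object.
#' @return Tibble with `hap_a`, `hap_b`, `split_years` and `expected_ks`
#'   (`2 * r_syn * split_years`) for all 15 haplotype pairs.
#' @export
expected_ks <- function(params) {
  stopifnot(inherits(params, "history_params"))
  pair_of <- function(h) {
    which(vapply(params$b_topology, function(p) h %in% p, logical(1)))
  }
  split_time <- function(a, b) {
    in_a <- function(h) h <= 2
    if (in_a(a) && in_a(b)) {
      params$t_wgdh
    } else if (!in_a(a) && !in_a(b)) {
      if (pair_of(a) == pair_of(b)) params$t_wgdh else params$t_wgdt
    } else {
      params$t_div
    }
  }
  pairs <- utils::combn(1:6, 2)
  tibble::tibble(
    hap_a = pairs[1, ], hap_b = pairs[2, ],
    split_years = vapply(seq_len(ncol(pairs)), function(i) {
      split_time(pairs[1, i], pairs[2, i])
    }, numeric(1))
  ) |>
    dplyr::mutate(expected_ks = 2 * params$r_syn * .data$split_years)
}

#' Fragment haplotypes into unitigs and simulate Hi-C contacts and overlaps
#'
#' Each haplotype chromosome is cut into unitigs (some deliberately
#' gene-free, as rescue fodder). Hi-C contact counts are Poisson:
#' `lambda_intra` between unitigs of the same haplotype, `lambda_allelic`
#' between allelic unitigs (those carrying copies of a shared ancestral
#' gene on different haplotypes), `lambda_bg` otherwise. Allelic unitig
#' pairs are also emitted as PAF overlap records with overlap length at
#' least `overlap_frac` of the shorter unitig.
#'
#' @param sim A `hex_sim` object from [simulate_haplotype_cds()].
#' @param unitigs_per_hap Number of unitigs per haplotype (>= 2).
#' @param gene_free_frac Fraction of unitigs carrying no gene.
#' @param lambda_intra,lambda_allelic,lambda_bg Poisson contact rates,
#'   `lambda_intra > lambda_allelic >= lambda_bg >= 0`.
#' @param overlap_frac Minimum overlap as a fraction of the shorter unitig.
#' @param seed Integer seed.
#' @return List of class `hex_fragments`: `contacts` (tibble `unitig_a`,
#'   `unitig_b`, `count`), `lengths` (`unitig`, `length`), `alleles`
#'   (`gene`, `unitig`), `overlaps` (PAF-style tibble), `hits` (`unitig`,
#'   `chrom`, `score` alignment hits for gene-free unitigs), `truth`
#'   (`unitig`, `haplotype`, `chrom`, `start`, `end`, `gene_free`;
#'   0-based half-open coordinates).
#' @export
fragment_and_contacts <- function(sim, unitigs_per_hap = 10,
                                  gene_free_frac = 0.2,
                                  lambda_intra = 50, lambda_allelic = 10,
                                  lambda_bg = 1, overlap_frac = 0.6,
                                  seed = 1L) {
  stopifnot(inherits(sim, "hex_sim"))
  if (!(lambda_intra > lambda_allelic && lambda_allelic >= lambda_bg &&
          lambda_bg >= 0)) {
    rlang::abort("need lambda_intra > lambda_allelic >= lambda_bg >= 0")
  }
  if (unitigs_per_hap < 2) {
    rlang::abort("each haplotype chromosome must yield at least 2 unitigs")
  }
  set.seed(seed)
  n_genes <- sim$params$n_genes
  genes <- sprintf("g%04d", seq_len(n_genes))
  gene_span <- 3 * sim$params$codons_per_gene + 2000L # CDS + intergenic

  n_free <- round(gene_free_frac * unitigs_per_hap)
  n_carry <- unitigs_per_hap - n_free
  if (n_carry < 1) rlang::abort("gene_free_frac leaves no gene-bearing unitig")
  if (n_carry > n_genes) {
    rlang::abort("more gene-bearing unitigs than genes to distribute")
  }

  truth <- list()
  alleles <- list()
  gene_unitig <- list() # per hap: gene -> unitig id
  for (h in 1:6) {
    # Random cut of the gene sequence into n_carry contiguous runs.
    cuts <- sort(sample(seq_len(n_genes - 1), n_carry - 1))
    bounds <- c(0, cuts, n_genes)
    free_len <- round(stats::runif(n_free, 5e4, 2e5))
    # Interleave gene-free unitigs at random positions.
    order_idx <- sample(unitigs_per_hap)
    is_free <- order_idx <= n_free
    carry_i <- 0L
    free_i <- 0L
    pos <- 0L
    for (u in seq_len(unitigs_per_hap)) {
      uid <- sprintf("hap%d_utg%02d", h, u)
      if (is_free[u]) {
        free_i <- free_i + 1L
        len <- free_len[free_i]
        gset <- character(0)
      } else {
        carry_i <- carry_i + 1L
        gset <- genes[(bounds[carry_i] + 1):bounds[carry_i + 1]]
        len <- length(gset) * gene_span
      }
      truth[[length(truth) + 1]] <- tibble::tibble(
        unitig = uid, haplotype = h, chrom = "chr01",
        start = pos, end = pos + len, gene_free = length(gset) == 0
      )
      if (length(gset) > 0) {
        alleles[[length(alleles) + 1]] <- tibble::tibble(
          gene = gset, unitig = uid
        )
        gene_unitig[[length(gene_unitig) + 1]] <- tibble::tibble(
          gene = gset, haplotype = h, unitig = uid
        )
      }
      pos <- pos + len
    }
  }
  truth <- dplyr::bind_rows(truth)
  alleles <- dplyr::bind_rows(alleles) |> dplyr::arrange(.data$gene, .data$unitig)
  lengths <- truth |>
    dplyr::transmute(unitig = .data$unitig,
                     length = .data$end - .data$start)

  # Allelic unitig pairs: share at least one ancestral gene, different hap.
  gu <- dplyr::bind_rows(gene_unitig)
  allelic_pairs <- dplyr::inner_join(
    gu, gu, by = "gene", suffix = c("_a", "_b"),
    relationship = "many-to-many"
  ) |>
    dplyr::filter(.data$unitig_a < .data$unitig_b,
                  .data$haplotype_a != .data$haplotype_b) |>
    dplyr::distinct(.data$unitig_a, .data$unitig_b)

  # Contacts over all unordered unitig pairs.
  all_pairs <- t(utils::combn(truth$unitig, 2))
  pairs <- tibble::tibble(unitig_a = all_pairs[, 1], unitig_b = all_pairs[, 2])
  hap_of <- stats::setNames(truth$haplotype, truth$unitig)
  pairs <- pairs |>
    dplyr::left_join(
      dplyr::mutate(allelic_pairs, allelic = TRUE),
      by = c("unitig_a", "unitig_b")
    ) |>
    dplyr::mutate(
      allelic = !is.na(.data$allelic),
      same_hap = hap_of[.data$unitig_a] == hap_of[.data$unitig_b],
      rate = dplyr::case_when(
        .data$same_hap ~ lambda_intra,
        .data$allelic ~ lambda_allelic,
        TRUE ~ lambda_bg
      )
    )
  pairs$count <- stats::rpois(nrow(pairs), pairs$rate)
  contacts <- pairs |>
    dplyr::filter(.data$count > 0) |>
    dplyr::select("unitig_a", "unitig_b", "count")

  # PAF overlaps for allelic unitig pairs.
  len_of <- stats::setNames(lengths$length, lengths$unitig)
  ov <- allelic_pairs |>
    dplyr::mutate(
      len_a = unname(len_of[.data$unitig_a]),
      len_b = unname(len_of[.data$unitig_b]),
      shorter = pmin(.data$len_a, .data$len_b),
      ov_len = round(stats::runif(dplyr::n(), overlap_frac, 1) * .data$shorter),
      identity = stats::runif(dplyr::n(), 0.97, 1)
    )
  overlaps <- tibble::tibble(
    qname = ov$unitig_a, qlen = ov$len_a, qstart = 0L, qend = ov$ov_len,
    strand = "+",
    tname = ov$unitig_b, tlen = ov$len_b,
    tstart = ov$len_b - ov$ov_len, tend = ov$len_b,
    nmatch = round(ov$identity * ov$ov_len), alen = ov$ov_len, mapq = 60L
  )

  # Alignment hits for gene-free unitigs against the reference chromosome.
  free_utg <- truth$unitig[truth$gene_free]
  hits <- tibble::tibble(
    unitig = free_utg, chrom = "chr01",
    score = round(stats::runif(length(free_utg), 500, 2000))
  )

  structure(
    list(contacts = contacts, lengths = lengths, alleles = alleles,
         overlaps = overlaps, hits = hits, truth = truth,
         params = list(unitigs_per_hap = unitigs_per_hap,
                       gene_free_frac = gene_free_frac,
                       lambda_intra = lambda_intra,
                       lambda_allelic = lambda_allelic,
                       lambda_bg = lambda_bg,
                       overlap_frac = overlap_frac, seed = seed)),
    class = "hex_fragments"
  )
}

#' Simulate negative-binomial expression with dominance and ASE effects
#'
#' Generates counts for every haplotype copy of every ancestral locus over
#' a timepoint-by-replicate design (default 4 timepoints x 3 replicates =
#' 12 samples). Subgenome-B copies (haplotypes 3-6) receive a
#' `dominance_log2` mean shift; a random `ase_fraction` of loci get an
#' additional `+/- ase_log2` shift on one randomly chosen allele.
#'
#' @param sim A `hex_sim` object.
#' @param mu Baseline mean count per copy.
#' @param dispersion Negative-binomial size parameter.
#' @param dominance_log2 log2 fold shift applied to subgenome-B copies.
#' @param ase_fraction Fraction of loci with an allele-specific effect.
#' @param ase_log2 Magnitude of the allele-specific log2 shift.
#' @param n_timepoints,n_reps Design dimensions; timepoints are labelled
#'   `DAF0..DAF(n-1)` (days after flooding).
#' @param seed Integer seed.
#' @return List of class `hex_expression`: `counts` (tibble `gene_id` +
#'   one column per sample), `lengths` (`gene_id`, `length` in bp),
#'   `samples` (`sample`, `timepoint`, `replicate`), `ase_truth`
#'   (`gene` = locus, `ase_hap`, `direction`).
#' @export
simulate_expression <- function(sim, mu = 100, dispersion = 10,
                                dominance_log2 = 1, ase_fraction = 0.2,
                                ase_log2 = 2, n_timepoints = 4, n_reps = 3,
                                seed = 1L) {
  stopifnot(inherits(sim, "hex_sim"))
  if (mu <= 0) rlang::abort("mu must be positive")
  if (dispersion <= 0) rlang::abort("dispersion must be positive")
  if (ase_fraction < 0 || ase_fraction > 1) {
    rlang::abort("ase_fraction must be in [0, 1]")
  }
  set.seed(seed)
  n <- sim$params$n_genes
  genes <- sprintf("g%04d", seq_len(n))
  copies <- tidyr::expand_grid(gene = genes, haplotype = 1:6) |>
    dplyr::mutate(gene_id = paste0("hap", .data$haplotype, "_", .data$gene))

  n_ase <- round(ase_fraction * n)
  ase_genes <- if (n_ase > 0) sample(genes, n_ase) else character(0)
  ase_truth <- tibble::tibble(
    gene = ase_genes,
    ase_hap = sample(1:6, n_ase, replace = TRUE),
    direction = sample(c(-1, 1), n_ase, replace = TRUE)
  )

  copies <- copies |>
    dplyr::left_join(ase_truth, by = "gene") |>
    dplyr::mutate(
      log2_mean = log2(mu) +
        dominance_log2 * (.data$haplotype >= 3) +
        dplyr::coalesce(
          ifelse(.data$haplotype == .data$ase_hap,
                 .data$direction * ase_log2, 0),
          0
        ),
      mean = 2^.data$log2_mean
    )

  samples <- tidyr::expand_grid(
    timepoint = paste0("DAF", seq_len(n_timepoints) - 1),
    replicate = seq_len(n_reps)
  ) |>
    dplyr::mutate(sample = paste0(.data$timepoint, "_r", .data$replicate)) |>
    dplyr::select("sample", "timepoint", "replicate")

  counts <- copies |> dplyr::select("gene_id")
  for (s in samples$sample) {
    counts[[s]] <- stats::rnbinom(nrow(copies), mu = copies$mean,
                                  size = dispersion)
  }
  lengths <- copies |>
    dplyr::transmute(gene_id = .data$gene_id,
                     length = 3L * sim$params$codons_per_gene)
  structure(
    list(counts = counts, lengths = lengths, samples = samples,
         ase_truth = ase_truth,
         params = list(mu = mu, dispersion = dispersion,
                       dominance_log2 = dominance_log2,
                       ase_fraction = ase_fraction, ase_log2 = ase_log2,
                       n_timepoints = n_timepoints, n_reps = n_reps,
                       seed = seed)),
    class = "hex_expression"
  )
}
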