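# End-to-end synthetic benchmark: simulate -> phase -> pair -> date -> ASE,
# with a serializable run report.

#' Pipeline configuration
#'
#' Collects every stage parameter with its default. Anything not supplied
#' keeps the value documented in the stage function.
#'
#' @param seed Master seed; stage seeds are derived from it.
#' @param history A [history_params()] object (its own seed is overridden
#'   by `seed`).
#' @param k Number of haplotype groups for phasing.
#' @param unitigs_per_hap,gene_free_frac,lambda_intra,lambda_allelic,lambda_bg,overlap_frac
#'   Fragment/contact generator settings (see [fragment_and_contacts()]).
#' @param large_frac,min_identity Overlap thresholds for dedup and rescue.
#' @param cscore,dist,min_size Allelic pairing filters (see
#'   [cscore_pairs()]).
#' @param r Synonymous substitution rate per site per year for dating.
#' @param mu,dispersion,dominance_log2,ase_fraction,ase_log2 Expression
#'   generator settings (see [simulate_expression()]).
#' @param alpha,lfc ASE significance thresholds.
#' @return A list of class `hex_config`.
#' @export
hex_config <- function(seed = 1L, history = history_params(seed = seed),
                       k = 6, unitigs_per_hap = 10, gene_free_frac = 0.2,
                       lambda_intra = 50, lambda_allelic = 10,
                       lambda_bg = 1, overlap_frac = 0.6,
                       large_frac = 0.5, min_identity = 0.9,
                       cscore = 0.7, dist = 20, min_size = 4,
                       r = 3.39e-9, mu = 100, dispersion = 10,
                       dominance_log2 = 1, ase_fraction = 0.2,
                       ase_log2 = 2, alpha = 0.05, lfc = 1) {
  history$seed <- as.integer(seed)
  structure(
    list(seed = as.integer(seed), history = history, k = k,
         unitigs_per_hap = unitigs_per_hap,
         gene_free_frac = gene_free_frac, lambda_intra = lambda_intra,
         lambda_allelic = lambda_allelic, lambda_bg = lambda_bg,
         overlap_frac = overlap_frac, large_frac = large_frac,
         min_identity = min_identity, cscore = cscore, dist = dist,
         min_size = min_size, r = r, mu = mu, dispersion = dispersion,
         dominance_log2 = dominance_log2, ase_fraction = ase_fraction,
         ase_log2 = ase_log2, alpha = alpha, lfc = lfc),
    class = "hex_config"
  )
}

#' Haplotype-pair Ks records and dating categories for a simulation
#'
#' Computes NG86 Ks for every gene across the relevant haplotype-pair
#' categories: the subgenome-A allelic pair (`A_wgdh`, hap1 x hap2), the
#' within-subgenome-B pairs split by coalescence event (`B_wgdh`,
#' `B_wgdt`) and the cross-subgenome pairs (`AxB`).
#'
#' @param sim A `hex_sim` object.
#' @param max_pairs_per_category Optional cap on gene pairs per category
#'   (subsampled deterministically by taking the first genes).
#' @return A Ks record tibble with a `category` column.
#' @export
sim_ks_records <- function(sim, max_pairs_per_category = Inf) {
  exp_ks <- expected_ks(sim$params)
  cat_of <- function(a, b) {
    row <- exp_ks[exp_ks$hap_a == min(a, b) & exp_ks$hap_b == max(a, b), ]
    if (a <= 2 && b <= 2) "A_wgdh"
    else if (a >= 3 && b >= 3) {
      if (row$split_years == sim$params$t_wgdh) "B_wgdh" else "B_wgdt"
    } else "AxB"
  }
  n <- sim$params$n_genes
  genes <- sprintf("g%04d", seq_len(n))
  combos <- utils::combn(1:6, 2)
  all_cds <- unlist(unname(sim$cds))
  pair_list <- list()
  for (i in seq_len(ncol(combos))) {
    a <- combos[1, i]
    b <- combos[2, i]
    take <- genes[seq_len(min(n, max_pairs_per_category))]
    pair_list[[i]] <- tibble::tibble(
      gene_a = paste0("hap", a, "_", take),
      gene_b = paste0("hap", b, "_", take),
      hap_a = a, hap_b = b,
      category = cat_of(a, b)
    )
  }
  ks_records(dplyr::bind_rows(pair_list), all_cds)
}

#' Run the full synthetic benchmark pipeline
#'
#' Stages in order: simulate coding sequences, fragment into unitigs with
#' Hi-C contacts and overlaps, phase (prune, partition, dedup, rescue),
#' pair alleles and build loci, compute the Ks distribution and date the
#' WGD/hybridization events, assign subgenomes, simulate expression and
#' quantify ASE and subgenome dominance. Each stage's headline metrics go
#' into the returned report.
#'
#' @param config A [hex_config()] object.
#' @return A list of class `hex_run` with elements `config`, `sim`,
#'   `fragments`, `phasing` (grouping + accuracy), `loci` (+ census),
#'   `dating` (per-category dated peaks + subgenome call), `ase`
#'   (census, dominance glance) and `report` (flat serializable list).
#' @export
run_pipeline <- function(config = hex_config()) {
  stopifnot(inherits(config, "hex_config"))
  seed <- config$seed

  sim <- simulate_haplotype_cds(config$history)

  fragments <- fragment_and_contacts(
    sim, unitigs_per_hap = config$unitigs_per_hap,
    gene_free_frac = config$gene_free_frac,
    lambda_intra = config$lambda_intra,
    lambda_allelic = config$lambda_allelic,
    lambda_bg = config$lambda_bg, overlap_frac = config$overlap_frac,
    seed = seed + 1L
  )
  phased <- phase_unitigs(fragments, k = config$k,
                          large_frac = config$large_frac,
                          min_identity = config$min_identity)
  accuracy <- phasing_accuracy(phased$grouping, fragments$truth)

  hits <- similarity_hits(sim, seed = seed + 2L)
  pairs <- cscore_pairs(hits, cscore = config$cscore, dist = config$dist,
                        min_size = config$min_size)
  genes_tbl <- sim$truth |>
    dplyr::transmute(gene_id = .data$gene_id, haplotype = .data$haplotype)
  loci <- build_loci(pairs, genes_tbl)
  census <- locus_census(loci)

  records <- sim_ks_records(sim)
  dating <- date_events(records, r = config$r)
  truth_mya <- tibble::tibble(
    category = c("A_wgdh", "B_wgdh", "B_wgdt", "AxB"),
    truth_mya = c(config$history$t_wgdh, config$history$t_wgdh,
                  config$history$t_wgdt, config$history$t_div) / 1e6
  )
  dating <- dplyr::left_join(dating, truth_mya, by = "category")
  med <- records |>
    dplyr::filter(!.data$saturated) |>
    dplyr::group_by(.data$hap_a, .data$hap_b) |>
    dplyr::summarise(ks = stats::median(.data$ks), .groups = "drop") |>
    dplyr::mutate(hap_a = paste0("hap", .data$hap_a),
                  hap_b = paste0("hap", .data$hap_b))
  subgenomes <- assign_subgenomes(med)

  expr <- simulate_expression(
    sim, mu = config$mu, dispersion = config$dispersion,
    dominance_log2 = config$dominance_log2,
    ase_fraction = config$ase_fraction, ase_log2 = config$ase_log2,
    seed = seed + 3L
  )
  ase_res <- ase_test(expr$counts, expr$lengths, loci, expr$samples,
                      alpha = config$alpha, lfc = config$lfc)
  ase_census <- classify_asegs(ase_res, loci)
  dom <- dominance_summary(expr$counts, expr$lengths, loci)
  dom_glance <- glance(dom)

  report <- list(
    package_version = as.character(utils::packageVersion("hexorigin")),
    seed = seed,
    n_genes = config$history$n_genes,
    phasing = list(
      n_unitigs = nrow(fragments$lengths),
      n_grouped = sum(!is.na(phased$grouping$group)),
      accuracy = accuracy
    ),
    loci = stats::setNames(as.list(census$n), census$class),
    dating = lapply(seq_len(nrow(dating)), function(i) {
      as.list(dating[i, c("category", "peak_ks", "mya", "truth_mya")])
    }),
    subgenome_a = subgenomes$subgenome_a,
    ase = as.list(ase_census),
    dominance = as.list(dom_glance)
  )
  structure(
    list(config = config, sim = sim, fragments = fragments,
         phasing = c(phased, list(accuracy = accuracy)),
         loci = loci, census = census, records = records,
         dating = dating, subgenomes = subgenomes,
         expression = expr, ase_results = ase_res,
         ase_census = ase_census, dominance = dom, report = report),
    class = "hex_run"
  )
}

#' @export
print.hex_run <- function(x, ...) {
  cat("Hexaploid origin benchmark run (seed ", x$config$seed, ")\n", sep = "")
  cat(sprintf("  phasing accuracy (length-weighted): %.3f\n",
              x$phasing$accuracy))
  cat("  locus census:",
      paste(x$census$class, x$census$n, sep = "=", collapse = " "), "\n")
  cat("  dated events:\n")
  for (i in seq_len(nrow(x$dating))) {
    cat(sprintf("    %-7s peak Ks %.4f -> %.2f Mya (truth %.2f)\n",
                x$dating$category[i], x$dating$peak_ks[i],
                x$dating$mya[i], x$dating$truth_mya[i]))
  }
  cat("  subgenome A haplotypes:",
      paste(x$subgenomes$subgenome_a, collapse = ", "), "\n")
  cat(sprintf("  ASE: %d / %d sextuple loci (%.2f%%)\n",
              x$ase_census$n_ase, x$ase_census$n_sextuple,
              x$ase_census$pct_ase))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.hex_run <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(stage = "phasing", metric = "accuracy",
                   value = x$phasing$accuracy),
    tibble::tibble(stage = "loci", metric = x$census$class,
                   value = as.numeric(x$census$n)),
    tibble::tibble(stage = "dating",
                   metric = paste0(x$dating$category, "_mya"),
                   value = x$dating$mya),
    tibble::tibble(stage = "ase", metric = "pct_ase",
                   value = x$ase_census$pct_ase)
  )
}

#' @exportS3Method generics::glance
glance.hex_run <- function(x, ...) {
  tibble::tibble(
    seed = x$config$seed,
    n_genes = x$config$history$n_genes,
    phasing_accuracy = x$phasing$accuracy,
    n_sextuple = x$ase_census$n_sextuple,
    pct_ase = x$ase_census$pct_ase,
    wgdh_mya = x$dating$mya[x$dating$category == "A_wgdh"],
    wgdt_mya = x$dating$mya[x$dating$category == "B_wgdt"],
    divergence_mya = x$dating$mya[x$dating$category == "AxB"]
  )
}

#' @exportS3Method generics::tidy
tidy.ks_distribution <- function(x, ...) x$kde

#' @exportS3Method generics::tidy
tidy.subgenome_assignment <- function(x, ...) {
  tibble::tibble(
    haplotype = c(x$subgenome_a, x$subgenome_b),
    subgenome = rep(c("A", "B"), c(length(x$subgenome_a),
                                   length(x$subgenome_b)))
  )
}

#' @exportS3Method generics::glance
glance.subgenome_assignment <- function(x, ...) {
  tibble::tibble(within_mean = x$within_mean,
                 between_mean = x$between_mean, contrast = x$contrast)
}

#' Write the tabular outputs of a pipeline run to a directory
#'
#' Emits the external formats: per-haplotype CDS FASTA, contacts TSV, PAF
#' overlaps, allele table, grouping TSV, loci TSV, Ks records TSV, counts
#' TSV and the JSON run report.
#'
#' @param run A `hex_run` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (h in names(run$sim$cds)) {
    write_cds_fasta(run$sim$cds[[h]], file.path(dir, paste0(h, "_cds.fa")))
  }
  write_contacts(run$fragments$contacts, file.path(dir, "contacts.tsv"))
  write_paf(run$fragments$overlaps, file.path(dir, "overlaps.paf"))
  write_allele_table(run$fragments$alleles,
                     file.path(dir, "allele_table.tsv"))
  readr::write_tsv(run$phasing$grouping, file.path(dir, "grouping.tsv"))
  readr::write_tsv(run$loci, file.path(dir, "loci.tsv"))
  readr::write_tsv(run$records, file.path(dir, "ks_records.tsv"))
  write_counts(run$expression$counts, file.path(dir, "counts.tsv"))
  write_report_json(run$report, file.path(dir, "report.json"))
  invisible(dir)
}
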