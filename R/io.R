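# Plain-text readers and writers for the pipeline's formats: FASTA (via
# Biostrings), PAF overlaps, contact / allele-table / hits / depth / count
# TSVs, and JSON reports. All tables round-trip losslessly.

#' Read and write unitig Hi-C contact tables
#'
#' Three-column TSV `unitig_a`, `unitig_b`, `count`.
#'
#' @param path File path.
#' @return A contacts tibble.
#' @export
read_contacts <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    unitig_a = readr::col_character(),
    unitig_b = readr::col_character(),
    count = readr::col_double()
  ))
}

#' @rdname read_contacts
#' @param x Contacts tibble.
#' @export
write_contacts <- function(x, path) {
  readr::write_tsv(x[, c("unitig_a", "unitig_b", "count")], path)
  invisible(path)
}

#' Read and write PAF overlap records
#'
#' The 12 mandatory PAF columns (query name/length/start/end, strand,
#' target name/length/start/end, matching bases, alignment length, mapping
#' quality). A record with fewer than 12 fields is a parse error naming
#' the offending line.
#'
#' @param path File path.
#' @return A tibble with the 12 mandatory PAF columns.
#' @export
read_paf <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12)) {
    rlang::abort(paste0("malformed PAF record (fewer than 12 columns) at line ",
                        which(nf < 12)[1]))
  }
  m <- t(vapply(fields, function(f) f[1:12], character(12)))
  tibble::tibble(
    qname = m[, 1], qlen = as.integer(m[, 2]),
    qstart = as.integer(m[, 3]), qend = as.integer(m[, 4]),
    strand = m[, 5],
    tname = m[, 6], tlen = as.integer(m[, 7]),
    tstart = as.integer(m[, 8]), tend = as.integer(m[, 9]),
    nmatch = as.integer(m[, 10]), alen = as.integer(m[, 11]),
    mapq = as.integer(m[, 12])
  )
}

#' @rdname read_paf
#' @param x PAF tibble.
#' @export
write_paf <- function(x, path) {
  cols <- c("qname", "qlen", "qstart", "qend", "strand", "tname", "tlen",
            "tstart", "tend", "nmatch", "alen", "mapq")
  readr::write_tsv(x[, cols], path, col_names = FALSE)
  invisible(path)
}

#' Read and write allele tables
#'
#' On disk: TSV with `gene` and a comma-separated list of the unitigs
#' carrying a copy. In memory: long tibble `gene`, `unitig`.
#'
#' @param path File path.
#' @return A long allele tibble.
#' @export
read_allele_table <- function(path) {
  wide <- readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(), unitigs = readr::col_character()
  ))
  wide |>
    dplyr::mutate(unitig = strsplit(.data$unitigs, ",", fixed = TRUE)) |>
    tidyr::unnest("unitig") |>
    dplyr::select("gene", "unitig")
}

#' @rdname read_allele_table
#' @param x Long allele tibble (`gene`, `unitig`).
#' @export
write_allele_table <- function(x, path) {
  wide <- x |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(unitigs = paste(sort(.data$unitig), collapse = ","),
                     .groups = "drop")
  readr::write_tsv(wide, path)
  invisible(path)
}

#' Read and write CDS FASTA files
#'
#' Thin wrappers over Biostrings returning/accepting named character
#' vectors of sequences.
#'
#' @param path File path.
#' @return Named character vector of sequences.
#' @export
read_cds_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_cds_fasta
#' @param x Named character vector of sequences.
#' @export
write_cds_fasta <- function(x, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path)
  invisible(path)
}

#' Read a gene-by-sample count matrix TSV
#'
#' First column `gene_id`, remaining columns one per sample.
#'
#' @param path File path.
#' @return Counts tibble.
#' @export
read_counts <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()
  ))
}

#' @rdname read_counts
#' @param x Counts tibble.
#' @export
write_counts <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' Read per-window depth TSV (BED-like, 0-based half-open)
#'
#' Columns `chrom`, `start`, `end`, `depth`.
#'
#' @param path File path.
#' @return Depth tibble.
#' @export
read_depths <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), start = readr::col_integer(),
    end = readr::col_integer(), depth = readr::col_double()
  ))
}

#' Write a run report (or any list) as JSON
#'
#' @param x A list or tibble.
#' @param path Output path.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
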