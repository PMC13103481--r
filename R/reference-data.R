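# Published summary numbers for the hexaploid Actinidia valvata 'DE'
# haplotype-resolved assembly, used for arithmetic consistency checks.

#' Per-haplotype gene counts of the A. valvata 'DE' assembly
#'
#' Annotated protein-coding gene counts and shared (multi-haplotype) gene
#' counts for the six haplotypes of the hexaploid *Actinidia valvata* 'DE'
#' reference assembly. The annotated counts sum to 162 561 genes and the
#' shared counts to 158 975.
#'
#' @return Tibble with `haplotype`, `genes` and `shared_genes`.
#' @export
avalvata_gene_counts <- function() {
  tibble::tibble(
    haplotype = 1:6,
    genes = c(30352L, 29975L, 26322L, 25649L, 25371L, 24892L),
    shared_genes = c(29640L, 29070L, 25806L, 25184L, 24932L, 24343L)
  )
}

#' Published allele-multiplicity census of the A. valvata 'DE' assembly
#'
#' Numbers of allelic loci by multiplicity class reported for the 'DE'
#' assembly, plus the singleton gene count.
#'
#' @return Tibble with `class` and `n_loci` (`n_loci` for `singleton` is a
#'   gene count).
#' @export
avalvata_locus_census <- function() {
  tibble::tibble(
    class = c("sextuple", "quintuple", "quadruple", "triple", "double",
              "singleton"),
    n_loci = c(7023L, 7372L, 7845L, 6005L, 8383L, 17402L)
  )
}
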