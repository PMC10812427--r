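#' Cross-reference candidate targets against a sperm-proteome list
#'
#' A target hits when its gene name (case-insensitive exact match) or its
#' UniProt ID matches any record of the sperm-proteome reference list. Each
#' target appears at most once in the output, with the matching key(s)
#' recorded and the target's origin (first-pass screen or cross-species
#' addition) preserved.
#'
#' @param targets Tibble with columns `gene_name`, `uniprot_id`, `origin`
#'   (`first_pass_target` or `cross_species_addition`); either key may be
#'   `NA`.
#' @param sperm Sperm-list tibble (see [read_sperm_list()]).
#' @return Tibble of hits: `gene_name`, `uniprot_id`, `matched_by`
#'   (`gene_name`, `uniprot_id`, or `both`), `origin`, sorted by gene name.
#' @export
crossref_sperm <- function(targets, sperm) {
  sperm_genes <- tolower(sperm$gene_name[!is.na(sperm$gene_name)])
  sperm_ids <- toupper(sperm$uniprot_id[!is.na(sperm$uniprot_id)])
  hit_gene <- !is.na(targets$gene_name) &
    tolower(targets$gene_name) %in% sperm_genes
  hit_id <- !is.na(targets$uniprot_id) &
    toupper(targets$uniprot_id) %in% sperm_ids
  hits <- targets[hit_gene | hit_id, , drop = FALSE]
  hits$matched_by <- dplyr::case_when(
    hit_gene[hit_gene | hit_id] & hit_id[hit_gene | hit_id] ~ "both",
    hit_gene[hit_gene | hit_id] ~ "gene_name",
    TRUE ~ "uniprot_id"
  )
  hits |>
    distinct(gene_name, uniprot_id, .keep_all = TRUE) |>
    select(gene_name, uniprot_id, matched_by, origin) |>
    arrange(gene_name)
}
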