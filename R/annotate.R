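# Default evidence codes treated as experimental when parsing annotation
# evidence. Configurable; covers the experimental and high-throughput
# GO evidence code families.
EXPERIMENTAL_GO_CODES <- c(
  "EXP", "IDA", "IPI", "IMP", "IGI", "IEP",
  "HTP", "HDA", "HMP", "HGI", "HEP"
)

#' Configuration for filtering eggNOG-mapper hits
#'
#' Defaults follow the orthology-transfer search filters used for the
#' screening: minimum hit e-value 0.001, minimum bit-score 60, minimum
#' percent identity 80, minimum query and subject coverage 80, one-to-one
#' orthology only, and GO transfer restricted to experimentally supported
#' annotations. All thresholds are inclusive.
#'
#' @param max_evalue Maximum hit e-value.
#' @param min_bit_score Minimum hit bit-score.
#' @param min_identity_pct Minimum percent identity (0-100).
#' @param min_query_cov_pct Minimum percent query coverage (0-100).
#' @param min_subject_cov_pct Minimum percent subject coverage (0-100).
#' @param require_one2one Keep only one-to-one orthology hits.
#' @param require_experimental_go Strip GO IDs from retained hits that lack
#'   experimental evidence (names and descriptions are kept).
#' @return A list of class `eggnog_filter_config`.
#' @export
eggnog_filter_config <- function(max_evalue = 0.001,
                                 min_bit_score = 60,
                                 min_identity_pct = 80,
                                 min_query_cov_pct = 80,
                                 min_subject_cov_pct = 80,
                                 require_one2one = TRUE,
                                 require_experimental_go = TRUE) {
  vals <- c(max_evalue, min_bit_score, min_identity_pct,
            min_query_cov_pct, min_subject_cov_pct)
  if (any(!is.finite(vals))) {
    abort("eggnog_filter_config thresholds must be finite",
          class = "surfscreen_config_error")
  }
  structure(
    list(
      max_evalue = max_evalue,
      min_bit_score = min_bit_score,
      min_identity_pct = min_identity_pct,
      min_query_cov_pct = min_query_cov_pct,
      min_subject_cov_pct = min_subject_cov_pct,
      require_one2one = require_one2one,
      require_experimental_go = require_experimental_go
    ),
    class = "eggnog_filter_config"
  )
}

#' Filter raw eggNOG-mapper hits by quality thresholds
#'
#' Retains rows meeting every threshold (inclusive at the boundary). When
#' `require_experimental_go` is set, GO IDs are removed from retained rows
#' lacking experimental evidence, while preferred names and descriptions are
#' kept (gene naming does not require experimental support, GO transfer
#' does).
#'
#' @param raw Tibble of annotations (see [read_eggnog_table()]).
#' @param cfg An [eggnog_filter_config()].
#' @return The filtered tibble.
#' @export
filter_eggnog_hits <- function(raw, cfg = eggnog_filter_config()) {
  keep <- raw$evalue <= cfg$max_evalue &
    raw$bit_score >= cfg$min_bit_score &
    raw$pct_identity >= cfg$min_identity_pct &
    raw$query_coverage >= cfg$min_query_cov_pct &
    raw$subject_coverage >= cfg$min_subject_cov_pct
  if (cfg$require_one2one) keep <- keep & raw$orthology_type == "one2one"
  out <- raw[which(keep), , drop = FALSE]
  if (cfg$require_experimental_go && nrow(out) > 0) {
    out$go_ids <- map2(
      out$go_ids, out$go_evidence_experimental,
      ~ if (.y) .x else character(0)
    )
  }
  out
}

#' Merge UniProt and eggNOG annotations into one evidence-tracked union
#'
#' For each proteome entry, the GO union is the set union of the entry's own
#' GO IDs and the accepted eggNOG GO IDs, with a per-ID record of which
#' source(s) contributed it. The eggNOG preferred name is kept (as
#' `eggnog_name`) when the entry lacks a gene name. Proteins without a
#' topology prediction carry `NA` topology and are flagged
#' (`topology_missing`); downstream classification treats them as
#' non-transmembrane.
#'
#' Experimentally supported GO IDs are accumulated from the entry's
#' `experimental_go_ids` (UniProt evidence codes) and from eggNOG rows whose
#' GO transfer carried experimental evidence.
#'
#' @param entries Proteome tibble (typically the filtered proteome).
#' @param egg Filtered eggNOG tibble; at most one row per accession.
#' @param topo Topology tibble (see [read_topology()]); at most one row per
#'   accession.
#' @return Annotated-protein tibble with columns `accession`, `gene_name`,
#'   `protein_name`, `chromosome`, `eggnog_name`, `go_union` (list),
#'   `go_sources` (list of named lists mapping GO ID to source vector),
#'   `experimental_go` (list), `protein_type`, `n_tmr`,
#'   `has_signal_peptide`, `topology_missing`.
#' @export
merge_annotations <- function(entries, egg, topo) {
  for (nm in list(list(df = egg, key = "query_accession", what = "eggNOG"),
                  list(df = topo, key = "accession", what = "topology"))) {
    dups <- nm$df[[nm$key]][duplicated(nm$df[[nm$key]])]
    if (length(dups) > 0) {
      integrity_abort(sprintf(
        "More than one %s row for accession(s): %s",
        nm$what, paste(unique(dups), collapse = ", ")
      ))
    }
  }
  egg_idx <- match(entries$accession, egg$query_accession)
  topo_idx <- match(entries$accession, topo$accession)

  n <- nrow(entries)
  go_union <- vector("list", n)
  go_sources <- vector("list", n)
  experimental <- vector("list", n)
  eggnog_name <- rep(NA_character_, n)

  for (i in seq_len(n)) {
    uni <- sort(unique(entries$go_ids[[i]]))
    egg_go <- character(0)
    exp_go <- sort(unique(entries$experimental_go_ids[[i]]))
    if (!is.na(egg_idx[i])) {
      j <- egg_idx[i]
      egg_go <- sort(unique(egg$go_ids[[j]]))
      if (isTRUE(egg$go_evidence_experimental[j])) {
        exp_go <- sort(unique(c(exp_go, egg_go)))
      }
      if (is.na(entries$gene_name[i]) && !is.na(egg$preferred_name[j])) {
        eggnog_name[i] <- egg$preferred_name[j]
      }
    }
    ids <- sort(unique(c(uni, egg_go)))
    src <- setNames(vector("list", length(ids)), ids)
    for (id in ids) {
      src[[id]] <- c(
        if (id %in% uni) "uniprot",
        if (id %in% egg_go) "eggnog"
      )
    }
    go_union[[i]] <- ids
    go_sources[[i]] <- src
    experimental[[i]] <- intersect(exp_go, ids)
  }

  tibble(
    accession = entries$accession,
    gene_name = entries$gene_name,
    protein_name = entries$protein_name,
    chromosome = entries$chromosome,
    eggnog_name = eggnog_name,
    go_union = go_union,
    go_sources = go_sources,
    experimental_go = experimental,
    protein_type = ifelse(is.na(topo_idx), NA_character_,
                          topo$protein_type[topo_idx]),
    n_tmr = ifelse(is.na(topo_idx), NA_integer_, topo$n_tmr[topo_idx]),
    has_signal_peptide = ifelse(is.na(topo_idx), NA,
                                topo$has_signal_peptide[topo_idx]),
    topology_missing = is.na(topo_idx)
  )
}

#' Write an annotated-protein table and its evidence sidecar
#'
#' The TSV serialises the GO union `";"`-joined; the JSON sidecar records
#' per-ID sources and the experimentally supported subset.
#'
#' @param annotated Annotated-protein tibble (see [merge_annotations()]).
#' @param path Output TSV path; the sidecar is written next to it with a
#'   `.sources.json` suffix.
#' @export
write_annotated_table <- function(annotated, path) {
  df <- annotated |>
    mutate(
      go_union = map_chr(go_union, join_multi),
      experimental_go = map_chr(experimental_go, join_multi)
    ) |>
    select(-go_sources)
  readr::write_tsv(df, path, progress = FALSE)
  sidecar <- paste0(sub("\\.tsv$", "", path), ".sources.json")
  jsonlite::write_json(
    setNames(annotated$go_sources, annotated$accession),
    sidecar, auto_unbox = FALSE
  )
  invisible(path)
}
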