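#' Reduce a raw chromosome proteome to a less redundant entry set
#'
#' Reference proteomes carry a high fraction of duplicate entries: several
#' UniProt entries can be products of the same gene, and a single entry can
#' be mapped to several transcripts. Filtering applies three rules:
#'
#' 1. Entries whose transcripts all lack an associated gene (or that have no
#'    transcript mapping at all) are dropped.
#' 2. Among entries sharing a gene, exactly one is retained: the reviewed
#'    entry if one exists, otherwise the entry whose transcript is the
#'    canonical transcript for the gene, otherwise the lexicographically
#'    smallest accession (deterministic tie-break).
#' 3. An entry mapped to several transcripts keeps a single transcript
#'    association, preferring the canonical one.
#'
#' Two reviewed entries for one gene are resolved by the tie-break and
#' logged as a warning, not an error.
#'
#' @param entries Proteome tibble (see [read_proteome_table()]).
#' @param mapping Transcript-mapping tibble (see
#'   [read_transcript_mapping()]).
#'
#' @return A list with components `entries` (the filtered proteome, each
#'   entry carrying exactly one transcript) and `audit`, a `filter_audit`
#'   object recording the input count, every dropped accession by category,
#'   and the output count. Counts reconcile exactly:
#'   `input_count == output_count + dropped`.
#' @export
filter_redundant <- function(entries, mapping) {
  validate_transcript_mapping(mapping)
  input_count <- nrow(entries)

  gene_of <- setNames(mapping$gene_id, mapping$transcript_id)
  canonical <- setNames(mapping$is_canonical, mapping$transcript_id)

  # Per entry: transcripts that carry a gene, the chosen transcript
  # (canonical preferred), and its gene.
  info <- map(seq_len(input_count), function(i) {
    tx <- entries$transcript_ids[[i]]
    tx <- tx[tx %in% names(gene_of)]
    tx <- tx[!is.na(gene_of[tx])]
    if (length(tx) == 0) {
      return(list(keep_tx = NA_character_, gene = NA_character_,
                  dropped_tx = character(0), is_canonical = FALSE))
    }
    tx <- sort(tx)
    canon <- tx[canonical[tx]]
    keep <- if (length(canon) > 0) canon[1] else tx[1]
    list(
      keep_tx = keep,
      gene = unname(gene_of[keep]),
      dropped_tx = setdiff(tx, keep),
      is_canonical = unname(canonical[keep])
    )
  })

  genes <- map_chr(info, "gene")
  no_gene <- is.na(genes)
  dropped_no_gene <- entries$accession[no_gene]

  dropped_tx_tbl <- tibble(
    accession = entries$accession,
    kept_transcript = map_chr(info, "keep_tx"),
    dropped_transcripts = map(info, "dropped_tx")
  ) |>
    filter(!no_gene, lengths(dropped_transcripts) > 0)

  cand <- tibble(
    idx = which(!no_gene),
    accession = entries$accession[!no_gene],
    reviewed = entries$reviewed[!no_gene],
    gene = genes[!no_gene],
    tx_canonical = map_lgl(info, "is_canonical")[!no_gene]
  )

  kept_idx <- integer(0)
  dropped_dup <- list()
  for (g in unique(cand$gene)) {
    grp <- cand[cand$gene == g, ]
    grp <- grp[order(grp$accession), ]
    reviewed_in <- grp$accession[grp$reviewed]
    if (length(reviewed_in) > 1) {
      warn(sprintf(
        "Gene '%s' has %d reviewed entries (%s); keeping '%s' by tie-break",
        g, length(reviewed_in), paste(reviewed_in, collapse = ", "),
        reviewed_in[1]
      ))
    }
    if (length(reviewed_in) > 0) {
      keep_acc <- reviewed_in[1]
      reason <- "reviewed_priority"
    } else if (any(grp$tx_canonical)) {
      keep_acc <- grp$accession[grp$tx_canonical][1]
      reason <- "canonical_priority"
    } else {
      keep_acc <- grp$accession[1]
      reason <- "tie_break"
    }
    kept_idx <- c(kept_idx, grp$idx[grp$accession == keep_acc])
    losers <- grp$accession[grp$accession != keep_acc]
    if (length(losers) > 0) {
      dropped_dup[[g]] <- tibble(
        accession = losers, kept_accession = keep_acc, reason = reason
      )
    }
  }
  dropped_dup_tbl <- if (length(dropped_dup) > 0) {
    bind_rows(dropped_dup)
  } else {
    tibble(accession = character(0), kept_accession = character(0),
           reason = character(0))
  }

  kept_idx <- sort(kept_idx)
  out <- entries[kept_idx, , drop = FALSE]
  out$transcript_ids <- map(info[kept_idx], ~ .x$keep_tx)

  audit <- structure(
    list(
      input_count = input_count,
      dropped_no_gene = dropped_no_gene,
      dropped_gene_duplicate = dropped_dup_tbl,
      dropped_uniprot_duplicate_transcripts = dropped_tx_tbl,
      output_count = nrow(out)
    ),
    class = "filter_audit"
  )
  stopifnot(
    audit$input_count ==
      audit$output_count + length(audit$dropped_no_gene) +
      nrow(audit$dropped_gene_duplicate)
  )
  list(entries = out, audit = audit)
}

#' @export
print.filter_audit <- function(x, ...) {
  cat("Proteome redundancy-filter audit\n")
  cat(sprintf("  input entries:      %d\n", x$input_count))
  cat(sprintf("  dropped (no gene):  %d\n", length(x$dropped_no_gene)))
  cat(sprintf("  dropped (gene dup): %d\n", nrow(x$dropped_gene_duplicate)))
  cat(sprintf("  entries with extra transcripts trimmed: %d\n",
              nrow(x$dropped_uniprot_duplicate_transcripts)))
  cat(sprintf("  retained entries:   %d\n", x$output_count))
  invisible(x)
}

#' Serialise a filter audit to JSON
#' @param audit A `filter_audit`.
#' @param path Output JSON path.
#' @export
write_filter_audit <- function(audit, path) {
  jsonlite::write_json(
    list(
      input_count = audit$input_count,
      dropped_no_gene = audit$dropped_no_gene,
      dropped_gene_duplicate = audit$dropped_gene_duplicate,
      dropped_uniprot_duplicate_transcripts = list(
        accession = audit$dropped_uniprot_duplicate_transcripts$accession,
        kept_transcript = audit$dropped_uniprot_duplicate_transcripts$kept_transcript,
        dropped_transcripts = audit$dropped_uniprot_duplicate_transcripts$dropped_transcripts
      ),
      output_count = audit$output_count
    ),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}
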