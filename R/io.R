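#' Read a UniProt-style proteome table
#'
#' One row per proteome entry. Multi-valued columns (`go_ids`,
#' `transcript_ids`, and the optional `experimental_go_ids`) are split on
#' `";"` or `","`; bracketed descriptive text after a GO ID is stripped.
#' Missing gene names (empty field or `"-"`) are recorded as `NA`, never as
#' an empty string.
#'
#' @param path Path to a TSV file with header columns `accession`, `reviewed`,
#'   `gene_name`, `protein_name`, `length`, `chromosome`, `go_ids`,
#'   `transcript_ids`. An optional `sequence` column and an optional
#'   `experimental_go_ids` column (the subset of `go_ids` carried with an
#'   experimental evidence code) are honoured.
#' @param format Input dialect; only `"uniprot_tsv"` is supported.
#'
#' @return A tibble with one row per entry; `go_ids`, `transcript_ids` and
#'   `experimental_go_ids` are list-columns of character vectors.
#' @export
read_proteome_table <- function(path, format = c("uniprot_tsv")) {
  format <- match.arg(format)
  df <- read_tsv_quiet(path, col_types = readr::cols(.default = "c"))
  required <- c(
    "accession", "reviewed", "gene_name", "protein_name",
    "length", "chromosome", "go_ids", "transcript_ids"
  )
  check_columns(df, required, path)
  if (anyDuplicated(df$accession)) {
    dup <- unique(df$accession[duplicated(df$accession)])
    integrity_abort(sprintf(
      "Duplicate accession(s) in '%s': %s", path, paste(dup, collapse = ", ")
    ))
  }
  go_ids <- map(df$go_ids, split_multi)
  check_go_ids(unique(unlist(go_ids)), path)
  exp_ids <- if ("experimental_go_ids" %in% names(df)) {
    map(df$experimental_go_ids, split_multi)
  } else {
    rep(list(character(0)), nrow(df))
  }
  out <- tibble(
    accession = df$accession,
    reviewed = tolower(df$reviewed) %in% c("yes", "true", "reviewed", "1"),
    gene_name = na_if_blank(df$gene_name),
    protein_name = df$protein_name,
    length = as.integer(df$length),
    chromosome = df$chromosome,
    sequence = if ("sequence" %in% names(df)) na_if_blank(df$sequence) else NA_character_,
    go_ids = go_ids,
    experimental_go_ids = exp_ids,
    transcript_ids = map(df$transcript_ids, split_multi)
  )
  bad_len <- !is.na(out$sequence) & nchar(out$sequence) != out$length
  if (any(bad_len)) {
    integrity_abort(sprintf(
      "length does not match sequence length for: %s",
      paste(out$accession[bad_len], collapse = ", ")
    ))
  }
  out
}

#' Write a proteome table
#'
#' Inverse of [read_proteome_table()]: multi-valued columns are `";"`-joined
#' and absent values become empty fields, so a read-write-read cycle is the
#' identity.
#'
#' @param proteome Tibble as returned by [read_proteome_table()].
#' @param path Output TSV path.
#' @export
write_proteome_table <- function(proteome, path) {
  df <- tibble(
    accession = proteome$accession,
    reviewed = ifelse(proteome$reviewed, "yes", "no"),
    gene_name = ifelse(is.na(proteome$gene_name), "", proteome$gene_name),
    protein_name = proteome$protein_name,
    length = proteome$length,
    chromosome = proteome$chromosome,
    sequence = ifelse(is.na(proteome$sequence), "", proteome$sequence),
    go_ids = map_chr(proteome$go_ids, join_multi),
    experimental_go_ids = map_chr(proteome$experimental_go_ids, join_multi),
    transcript_ids = map_chr(proteome$transcript_ids, join_multi)
  )
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a BioMart-style transcript-to-gene mapping table
#'
#' @param path TSV with columns `transcript_id`, `gene_id`, `is_canonical`.
#'   Empty `gene_id` fields are recorded as `NA` (transcripts with no
#'   associated gene).
#' @return Tibble with `transcript_id` (chr), `gene_id` (chr, `NA` allowed)
#'   and `is_canonical` (lgl).
#' @details At most one canonical transcript is allowed per gene, and a
#'   transcript may not be mapped to two different genes; violations raise an
#'   integrity error.
#' @export
read_transcript_mapping <- function(path) {
  df <- read_tsv_quiet(path, col_types = readr::cols(.default = "c"))
  check_columns(df, c("transcript_id", "gene_id", "is_canonical"), path)
  out <- tibble(
    transcript_id = df$transcript_id,
    gene_id = na_if_blank(df$gene_id),
    is_canonical = tolower(df$is_canonical) %in% c("yes", "true", "1")
  )
  validate_transcript_mapping(out)
  out
}

#' @noRd
validate_transcript_mapping <- function(mapping) {
  if (any(!nzchar(mapping$transcript_id))) {
    integrity_abort("transcript_id must be non-empty")
  }
  multi_gene <- mapping |>
    filter(!is.na(gene_id)) |>
    distinct(transcript_id, gene_id) |>
    dplyr::count(transcript_id) |>
    filter(n > 1)
  if (nrow(multi_gene) > 0) {
    integrity_abort(sprintf(
      "Transcript(s) mapped to more than one gene: %s",
      paste(multi_gene$transcript_id, collapse = ", ")
    ))
  }
  multi_canon <- mapping |>
    filter(is_canonical, !is.na(gene_id)) |>
    distinct(transcript_id, gene_id) |>
    dplyr::count(gene_id) |>
    filter(n > 1)
  if (nrow(multi_canon) > 0) {
    integrity_abort(sprintf(
      "More than one canonical transcript for gene(s): %s",
      paste(multi_canon$gene_id, collapse = ", ")
    ))
  }
  invisible(mapping)
}

#' Write a transcript mapping table
#' @param mapping Tibble as returned by [read_transcript_mapping()].
#' @param path Output TSV path.
#' @export
write_transcript_mapping <- function(mapping, path) {
  df <- tibble(
    transcript_id = mapping$transcript_id,
    gene_id = ifelse(is.na(mapping$gene_id), "", mapping$gene_id),
    is_canonical = ifelse(mapping$is_canonical, "yes", "no")
  )
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read an eggNOG-mapper-style annotation table
#'
#' @param path TSV with columns `query`, `seed_ortholog`, `evalue`, `score`,
#'   `preferred_name`, `description`, `GOs`, `orthology_type`, `identity`,
#'   `query_cov`, `subject_cov`, `go_evidence`. `go_evidence` is
#'   `experimental` or `nonexperimental`; orthology types other than
#'   `one2one` are collapsed to `other`.
#' @return Tibble with one row per annotation; `go_ids` is a list-column.
#' @export
read_eggnog_table <- function(path) {
  df <- read_tsv_quiet(path, col_types = readr::cols(.default = "c"))
  required <- c(
    "query", "seed_ortholog", "evalue", "score", "preferred_name",
    "description", "GOs", "orthology_type", "identity", "query_cov",
    "subject_cov", "go_evidence"
  )
  check_columns(df, required, path)
  go_ids <- map(df$GOs, split_multi)
  check_go_ids(unique(unlist(go_ids)), path)
  out <- tibble(
    query_accession = df$query,
    seed_ortholog = df$seed_ortholog,
    evalue = as.numeric(df$evalue),
    bit_score = as.numeric(df$score),
    preferred_name = na_if_blank(df$preferred_name),
    description = na_if_blank(df$description),
    go_ids = go_ids,
    orthology_type = ifelse(df$orthology_type == "one2one", "one2one", "other"),
    pct_identity = as.numeric(df$identity),
    query_coverage = as.numeric(df$query_cov),
    subject_coverage = as.numeric(df$subject_cov),
    go_evidence_experimental = tolower(df$go_evidence) %in%
      c("experimental", "true", "yes", "1")
  )
  if (any(out$evalue < 0, na.rm = TRUE)) {
    integrity_abort("eggNOG e-values must be non-negative")
  }
  pct_cols <- c("pct_identity", "query_coverage", "subject_coverage")
  for (col in pct_cols) {
    v <- out[[col]]
    if (any(v < 0 | v > 100, na.rm = TRUE)) {
      integrity_abort(sprintf("%s must lie in [0, 100]", col))
    }
  }
  out
}

#' Write an eggNOG-style annotation table
#' @param egg Tibble as returned by [read_eggnog_table()].
#' @param path Output TSV path.
#' @export
write_eggnog_table <- function(egg, path) {
  df <- tibble(
    query = egg$query_accession,
    seed_ortholog = egg$seed_ortholog,
    evalue = egg$evalue,
    score = egg$bit_score,
    preferred_name = ifelse(is.na(egg$preferred_name), "", egg$preferred_name),
    description = ifelse(is.na(egg$description), "", egg$description),
    GOs = map_chr(egg$go_ids, join_multi),
    orthology_type = egg$orthology_type,
    identity = egg$pct_identity,
    query_cov = egg$query_coverage,
    subject_cov = egg$subject_coverage,
    go_evidence = ifelse(egg$go_evidence_experimental, "experimental", "nonexperimental")
  )
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

TOPOLOGY_REGION_LABELS <- c(
  "signal", "TMhelix", "Beta sheet", "inside", "outside", "periplasm"
)

#' Read transmembrane-topology predictions
#'
#' Supports two dialects of topology-predictor output:
#'
#' * `gff3_like`: tab-separated region records `accession<TAB>label<TAB>start
#'   <TAB>end`, with `#` comment lines. Region labels are `signal`,
#'   `TMhelix`, `Beta sheet`, `inside`, `outside`, `periplasm`.
#' * `three_line`: per protein, a header `>accession | TYPE` (printed label,
#'   e.g. `TM`, `SP+TM`, `SP`, `GLOB`, `BETA`), the sequence line, and a
#'   per-residue annotation line over the alphabet `S`/`M`/`B`/`I`/`O`/`P`.
#'
#' The per-protein type is derived from the regions: any `TMhelix` makes the
#' protein alpha-helical transmembrane (`TM`, or `TM_SP` with a `signal`
#' region), any `Beta sheet` makes it `BETA`, a `signal` region alone makes
#' it `GLOB_SP`, otherwise `GLOB`. `n_tmr` counts `TMhelix`/`Beta sheet`
#' regions (runs of `M`/`B` in the three-line dialect).
#'
#' @param path Input file.
#' @param dialect `"gff3_like"` or `"three_line"`.
#' @return Tibble with `accession`, `protein_type`, `n_tmr`,
#'   `has_signal_peptide`.
#' @export
read_topology <- function(path, dialect = c("gff3_like", "three_line")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  if (dialect == "gff3_like") {
    parse_topology_gff(lines, path)
  } else {
    parse_topology_three_line(lines, path)
  }
}

#' @noRd
parse_topology_gff <- function(lines, path) {
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0) {
    return(tibble(
      accession = character(0), protein_type = character(0),
      n_tmr = integer(0), has_signal_peptide = logical(0)
    ))
  }
  parts <- str_split(lines[idx], "\t")
  bad <- which(lengths(parts) < 4)
  if (length(bad) > 0) {
    abort(
      sprintf("Malformed topology record at line %d of '%s'", idx[bad[1]], path),
      class = "surfscreen_parse_error"
    )
  }
  rec <- tibble(
    line = idx,
    accession = map_chr(parts, 1),
    label = map_chr(parts, 2)
  )
  unknown <- which(!rec$label %in% TOPOLOGY_REGION_LABELS)
  if (length(unknown) > 0) {
    abort(
      sprintf(
        "Unknown topology region label '%s' at line %d of '%s'",
        rec$label[unknown[1]], rec$line[unknown[1]], path
      ),
      class = "surfscreen_parse_error"
    )
  }
  rec |>
    group_by(accession) |>
    summarise(
      n_tmr = sum(label %in% c("TMhelix", "Beta sheet")),
      has_sp = any(label == "signal"),
      has_tm = any(label == "TMhelix"),
      has_beta = any(label == "Beta sheet"),
      .groups = "drop"
    ) |>
    mutate(
      protein_type = dplyr::case_when(
        has_beta ~ "BETA",
        has_tm & has_sp ~ "TM_SP",
        has_tm ~ "TM",
        has_sp ~ "GLOB_SP",
        TRUE ~ "GLOB"
      ),
      # Beta-barrel predictions do not carry the signal-peptide flag.
      has_signal_peptide = protein_type %in% c("TM_SP", "GLOB_SP"),
      n_tmr = as.integer(n_tmr)
    ) |>
    select(accession, protein_type, n_tmr, has_signal_peptide) |>
    arrange(accession)
}

#' @noRd
parse_topology_three_line <- function(lines, path) {
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) {
    return(tibble(
      accession = character(0), protein_type = character(0),
      n_tmr = integer(0), has_signal_peptide = logical(0)
    ))
  }
  recs <- map(seq_along(hdr), function(i) {
    h <- lines[hdr[i]]
    topo_line <- lines[hdr[i] + 2L]
    acc <- str_trim(sub("\\|.*$", "", sub("^>", "", h)))
    chars <- strsplit(topo_line, "")[[1]]
    bad <- which(!chars %in% c("S", "M", "B", "I", "O", "P", "i", "o"))
    if (length(bad) > 0) {
      abort(
        sprintf(
          "Unknown topology annotation character '%s' at line %d of '%s'",
          chars[bad[1]], hdr[i] + 2L, path
        ),
        class = "surfscreen_parse_error"
      )
    }
    runs <- rle(chars)
    n_tm <- sum(runs$values %in% c("M", "B"))
    has_sp <- any(chars == "S")
    has_beta <- any(chars == "B")
    has_helix <- any(chars == "M")
    type <- if (has_beta) "BETA"
    else if (has_helix && has_sp) "TM_SP"
    else if (has_helix) "TM"
    else if (has_sp) "GLOB_SP"
    else "GLOB"
    tibble(
      accession = acc,
      protein_type = type,
      n_tmr = as.integer(n_tm),
      has_signal_peptide = type %in% c("TM_SP", "GLOB_SP")
    )
  })
  bind_rows(recs) |> arrange(accession)
}

#' Write topology predictions in the region-record dialect
#'
#' Emits a minimal region structure consistent with the prediction: a
#' `signal` region when the protein carries a signal peptide, `n_tmr`
#' `TMhelix` (or `Beta sheet`) regions, and `inside` linkers. Positions are
#' schematic; [read_topology()] recovers the type, region count and
#' signal-peptide flag exactly.
#'
#' @param topology Tibble as returned by [read_topology()].
#' @param path Output path.
#' @export
write_topology_gff <- function(topology, path) {
  out <- character(0)
  for (i in seq_len(nrow(topology))) {
    acc <- topology$accession[i]
    type <- topology$protein_type[i]
    pos <- 1L
    rows <- character(0)
    emit <- function(label, len) {
      rows <<- c(rows, paste(acc, label, pos, pos + len - 1L, sep = "\t"))
      pos <<- pos + len
    }
    if (topology$has_signal_peptide[i]) emit("signal", 20L)
    tm_label <- if (type == "BETA") "Beta sheet" else "TMhelix"
    n <- topology$n_tmr[i]
    if (n > 0) {
      for (k in seq_len(n)) {
        emit("inside", 5L)
        emit(tm_label, 21L)
      }
      emit("outside", 5L)
    } else {
      emit("inside", 50L)
    }
    out <- c(out, paste0("# ", acc), rows)
  }
  writeLines(out, path)
  invisible(path)
}

#' Read protein sequences from a FASTA file
#'
#' The header token before the first whitespace is the key; sequences are
#' upper-cased. Duplicate keys and empty sequences raise integrity errors.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_sequences <- function(path) {
  set <- Biostrings::readBStringSet(path)
  keys <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(keys)) {
    dup <- unique(keys[duplicated(keys)])
    integrity_abort(sprintf(
      "Duplicate FASTA key(s) in '%s': %s", path, paste(dup, collapse = ", ")
    ))
  }
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    empty <- keys[!nzchar(seqs)]
    integrity_abort(sprintf(
      "Empty sequence(s) in '%s': %s", path, paste(empty, collapse = ", ")
    ))
  }
  setNames(seqs, keys)
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a sperm-proteome reference list
#'
#' @param path TSV with columns `gene_name` and `uniprot_id`; each record
#'   must carry at least one of the two keys.
#' @return Tibble with `gene_name` and `uniprot_id` (both chr, `NA` allowed).
#' @export
read_sperm_list <- function(path) {
  df <- read_tsv_quiet(path, col_types = readr::cols(.default = "c"))
  check_columns(df, c("gene_name", "uniprot_id"), path)
  out <- tibble(
    gene_name = na_if_blank(df$gene_name),
    uniprot_id = na_if_blank(df$uniprot_id)
  )
  both_na <- is.na(out$gene_name) & is.na(out$uniprot_id)
  if (any(both_na)) {
    integrity_abort(sprintf(
      "Sperm-list row(s) with neither gene name nor UniProt ID: %s",
      paste(which(both_na), collapse = ", ")
    ))
  }
  out
}
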