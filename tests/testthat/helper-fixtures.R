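# Shared builders for in-code fixtures.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

rand_seq <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# A proteome tibble row with sensible defaults.
entry_row <- function(accession, gene = NA_character_, reviewed = FALSE,
                      go = character(0), exp_go = character(0),
                      tx = character(0), seq = NULL,
                      chromosome = "X", protein_name = "Test protein") {
  if (is.null(seq)) seq <- NA_character_
  tibble::tibble(
    accession = accession, reviewed = reviewed, gene_name = gene,
    protein_name = protein_name,
    length = if (is.na(seq)) 100L else nchar(seq),
    chromosome = chromosome, sequence = seq,
    go_ids = list(go), experimental_go_ids = list(exp_go),
    transcript_ids = list(tx)
  )
}

mapping_row <- function(tx, gene = NA_character_, canonical = FALSE) {
  tibble::tibble(transcript_id = tx, gene_id = gene, is_canonical = canonical)
}

# An annotated-protein row (post-merge form) for classification tests.
ann_row <- function(accession, go = character(0), type = "GLOB",
                    exp_go = character(0), gene = NA_character_,
                    eggnog_name = NA_character_) {
  tibble::tibble(
    accession = accession, gene_name = gene, protein_name = "Test protein",
    chromosome = "X", eggnog_name = eggnog_name,
    go_union = list(go),
    go_sources = list(setNames(rep(list("uniprot"), length(go)), go)),
    experimental_go = list(exp_go),
    protein_type = type,
    n_tmr = if (!is.na(type) && type %in% c("TM", "TM_SP", "BETA")) 1L else 0L,
    has_signal_peptide = !is.na(type) && type %in% c("TM_SP", "GLOB_SP"),
    topology_missing = is.na(type)
  )
}

eggnog_row <- function(accession, go = character(0), evalue = 1e-50,
                       bit = 200, identity = 95, qcov = 95, scov = 95,
                       orthology = "one2one", experimental = TRUE,
                       name = NA_character_) {
  tibble::tibble(
    query_accession = accession, seed_ortholog = "9986.SEED",
    evalue = evalue, bit_score = bit, preferred_name = name,
    description = "annotation", go_ids = list(go),
    orthology_type = orthology, pct_identity = identity,
    query_coverage = qcov, subject_coverage = scov,
    go_evidence_experimental = experimental
  )
}

topo_row <- function(accession, type = "GLOB", n_tmr = NULL) {
  if (is.null(n_tmr)) n_tmr <- if (type %in% c("TM", "TM_SP", "BETA")) 1L else 0L
  tibble::tibble(
    accession = accession, protein_type = type, n_tmr = as.integer(n_tmr),
    has_signal_peptide = type %in% c("TM_SP", "GLOB_SP")
  )
}

extdata <- function(file) system.file("extdata", file, package = "surfscreen")
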