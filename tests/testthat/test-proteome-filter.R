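# Independent brute-force re-implementation of the redundancy rules, used
# as the oracle for filter_redundant(). Deliberately written as plain loops
# over the raw tables.
brute_force_filter <- function(entries, mapping) {
  gene_of <- setNames(mapping$gene_id, mapping$transcript_id)
  canon_of <- setNames(mapping$is_canonical, mapping$transcript_id)
  per_entry <- lapply(seq_len(nrow(entries)), function(i) {
    tx <- entries$transcript_ids[[i]]
    tx <- tx[tx %in% names(gene_of)]
    tx <- sort(tx[!is.na(gene_of[tx])])
    if (length(tx) == 0) return(NULL)
    keep <- if (any(canon_of[tx])) tx[canon_of[tx]][1] else tx[1]
    list(acc = entries$accession[i], gene = unname(gene_of[keep]),
         reviewed = entries$reviewed[i], canon = unname(canon_of[keep]))
  })
  per_entry <- Filter(Negate(is.null), per_entry)
  survivors <- character(0)
  for (g in unique(vapply(per_entry, `[[`, "", "gene"))) {
    grp <- Filter(function(e) e$gene == g, per_entry)
    accs <- sort(vapply(grp, `[[`, "", "acc"))
    revd <- sort(vapply(Filter(function(e) e$reviewed, grp), `[[`, "", "acc"))
    cano <- sort(vapply(Filter(function(e) e$canon, grp), `[[`, "", "acc"))
    survivors <- c(survivors,
                   if (length(revd) > 0) revd[1]
                   else if (length(cano) > 0) cano[1]
                   else accs[1])
  }
  sort(survivors)
}

test_that("a reviewed entry beats an unreviewed canonical entry for the same gene", {
  entries <- dplyr::bind_rows(
    entry_row("A", gene = "G1", reviewed = FALSE, tx = "T1"),
    entry_row("B", gene = "G1", reviewed = TRUE, tx = "T2")
  )
  mapping <- dplyr::bind_rows(
    mapping_row("T1", "ENSG1", canonical = TRUE),
    mapping_row("T2", "ENSG1", canonical = FALSE)
  )
  res <- filter_redundant(entries, mapping)
  expect_equal(res$entries$accession, "B")
  expect_equal(res$audit$dropped_gene_duplicate$accession, "A")
  expect_equal(res$audit$dropped_gene_duplicate$reason, "reviewed_priority")
})

test_that("entries whose transcripts lack a gene are dropped as unmapped", {
  entries <- dplyr::bind_rows(
    entry_row("A", tx = "T1"),
    entry_row("B", tx = "T2"),
    entry_row("C", tx = character(0)) # no transcript mapping at all
  )
  mapping <- dplyr::bind_rows(
    mapping_row("T1", "ENSG1", canonical = TRUE),
    mapping_row("T2", NA_character_)
  )
  res <- filter_redundant(entries, mapping)
  expect_equal(res$entries$accession, "A")
  expect_setequal(res$audit$dropped_no_gene, c("B", "C"))
})

test_that("a multi-transcript entry keeps only the canonical transcript", {
  entries <- entry_row("A", tx = c("T1", "T2", "T3"))
  mapping <- dplyr::bind_rows(
    mapping_row("T1", "ENSG1", canonical = FALSE),
    mapping_row("T2", "ENSG1", canonical = TRUE),
    mapping_row("T3", "ENSG1", canonical = FALSE)
  )
  res <- filter_redundant(entries, mapping)
  expect_equal(res$entries$transcript_ids[[1]], "T2")
  tx_audit <- res$audit$dropped_uniprot_duplicate_transcripts
  expect_equal(tx_audit$kept_transcript, "T2")
  expect_setequal(tx_audit$dropped_transcripts[[1]], c("T1", "T3"))
})

test_that("a 40-entry / 25-gene proteome with planted duplicates matches the brute-force oracle", {
  set.seed(2024)
  entries <- list()
  mapping <- list()
  k <- 0
  for (g in 1:25) {
    gene <- sprintf("ENSG%03d", g)
    n_tx <- sample(1:3, 1)
    txs <- sprintf("T%03d_%d", g, 1:n_tx)
    for (t in seq_along(txs)) {
      mapping[[paste0(gene, t)]] <- mapping_row(txs[t], gene, canonical = t == 1)
    }
    n_entries <- if (g <= 15) sample(1:3, 1) else 1
    for (e in 1:n_entries) {
      k <- k + 1
      entries[[k]] <- entry_row(
        sprintf("ACC%03d", k),
        reviewed = runif(1) < 0.3,
        tx = sample(txs, sample(1:n_tx, 1))
      )
    }
  }
  # pad with unmapped entries up to 40
  while (k < 40) {
    k <- k + 1
    tx_o <- sprintf("TORPH%d", k)
    mapping[[tx_o]] <- mapping_row(tx_o, NA_character_)
    entries[[k]] <- entry_row(sprintf("ACC%03d", k), tx = tx_o)
  }
  entries <- dplyr::bind_rows(entries)
  mapping <- dplyr::bind_rows(mapping)
  expect_equal(nrow(entries), 40)

  res <- suppressWarnings(filter_redundant(entries, mapping))
  expect_equal(sort(res$entries$accession), brute_force_filter(entries, mapping))
})

test_that("filtering is idempotent and the audit reconciles exactly", {
  set.seed(99)
  sim <- generate_proteome(sim_config(n_genes = 120, seed = 31),
                           dir = withr::local_tempdir())
  entries <- read_proteome_table(sim$paths$proteome)
  mapping <- read_transcript_mapping(sim$paths$mapping)
  res <- filter_redundant(entries, mapping)

  # audit conservation
  a <- res$audit
  expect_equal(a$input_count,
               a$output_count + length(a$dropped_no_gene) +
                 nrow(a$dropped_gene_duplicate))
  dropped_all <- c(a$dropped_no_gene, a$dropped_gene_duplicate$accession)
  expect_equal(anyDuplicated(dropped_all), 0)
  expect_length(intersect(dropped_all, res$entries$accession), 0)

  # output accessions unique, output subset of input
  expect_equal(anyDuplicated(res$entries$accession), 0)
  expect_true(all(res$entries$accession %in% entries$accession))

  # idempotence: refiltering the survivors drops nothing
  res2 <- filter_redundant(res$entries, mapping)
  expect_identical(res2$entries$accession, res$entries$accession)
  expect_length(res2$audit$dropped_no_gene, 0)
  expect_equal(nrow(res2$audit$dropped_gene_duplicate), 0)
})

test_that("two reviewed entries for one gene resolve by tie-break with a warning", {
  entries <- dplyr::bind_rows(
    entry_row("B", reviewed = TRUE, tx = "T1"),
    entry_row("A", reviewed = TRUE, tx = "T2")
  )
  mapping <- dplyr::bind_rows(
    mapping_row("T1", "ENSG1", canonical = TRUE),
    mapping_row("T2", "ENSG1")
  )
  expect_warning(res <- filter_redundant(entries, mapping), "reviewed entries")
  expect_equal(res$entries$accession, "A") # lexicographically smallest
})

test_that("a transcript mapped to two genes is an integrity error", {
  mapping <- dplyr::bind_rows(
    mapping_row("T1", "ENSG1", canonical = TRUE),
    mapping_row("T1", "ENSG2", canonical = TRUE)
  )
  expect_error(filter_redundant(entry_row("A", tx = "T1"), mapping),
               class = "surfscreen_integrity_error")
})
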