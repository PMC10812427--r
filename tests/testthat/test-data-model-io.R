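test_that("proteome TSV parsing splits GO fields, strips brackets, maps '-' to NA", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "accession\treviewed\tgene_name\tprotein_name\tlength\tchromosome\tgo_ids\ttranscript_ids",
    "G1SV48\tno\tCD24\tCD24 molecule\t80\tX\tGO:0009986;GO:0005886\tT1",
    "P00002\tyes\t-\tUnnamed protein\t50\tX\tGO:0005615 [extracellular space], GO:0005634\tT2;T3",
    "P00003\tno\t\tEmpty-GO protein\t60\tX\t\t"
  ), tmp)
  p <- read_proteome_table(tmp)
  expect_equal(nrow(p), 3)
  expect_setequal(p$go_ids[[1]], c("GO:0009986", "GO:0005886"))
  expect_setequal(p$go_ids[[2]], c("GO:0005615", "GO:0005634"))
  expect_true(is.na(p$gene_name[2]))   # "-" means absent
  expect_true(is.na(p$gene_name[3]))   # empty means absent, not ""
  expect_equal(p$go_ids[[3]], character(0))
  expect_equal(p$transcript_ids[[2]], c("T2", "T3"))
  expect_true(p$reviewed[2])
})

test_that("proteome reader rejects missing columns and duplicate accessions", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "accession\treviewed\tgene_name\tprotein_name\tlength\tchromosome\tgo_ids",
    "A\tno\tG\tP\t10\tX\t"
  ), tmp)
  expect_error(read_proteome_table(tmp), "transcript_ids",
               class = "surfscreen_format_error")

  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "accession\treviewed\tgene_name\tprotein_name\tlength\tchromosome\tgo_ids\ttranscript_ids",
    "A\tno\tG\tP\t10\tX\t\t",
    "A\tno\tG\tP\t10\tX\t\t"
  ), tmp2)
  expect_error(read_proteome_table(tmp2), "Duplicate accession",
               class = "surfscreen_integrity_error")
})

test_that("empty data section with a valid header yields an empty table", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(
    "accession\treviewed\tgene_name\tprotein_name\tlength\tchromosome\tgo_ids\ttranscript_ids",
    tmp
  )
  expect_equal(nrow(read_proteome_table(tmp)), 0)
})

test_that("proteome read-write-read is the identity, field by field", {
  set.seed(101)
  rows <- lapply(1:10, function(i) {
    seq <- rand_seq(sample(40:80, 1))
    entry_row(
      accession = sprintf("ACC%03d", i),
      gene = if (i %% 3 == 0) NA_character_ else sprintf("GENE%d", i),
      reviewed = i %% 2 == 0,
      go = if (i %% 2 == 0) c("GO:0005886", "GO:0005615") else character(0),
      exp_go = if (i %% 4 == 0) "GO:0005886" else character(0),
      tx = sprintf("TX%d_%d", i, seq_len(i %% 3 + 1)),
      seq = seq
    )
  })
  proteome <- dplyr::bind_rows(rows)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_proteome_table(proteome, tmp)
  back <- read_proteome_table(tmp)
  for (col in names(proteome)) expect_equal(back[[col]], proteome[[col]], label = col)
})

test_that("FASTA reading keys on first header token, uppercases, rejects dups/empties", {
  tmp <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">A some description", "mkt", ">B", "ACDE", "FGHI"), tmp)
  s <- read_sequences(tmp)
  expect_equal(s[["A"]], "MKT")
  expect_equal(s[["B"]], "ACDEFGHI") # wrapped lines reassembled

  dup <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">A", "MKT", ">A", "MKT"), dup)
  expect_error(read_sequences(dup), "Duplicate",
               class = "surfscreen_integrity_error")
})

test_that("FASTA round-trips 100 synthetic records", {
  set.seed(42)
  seqs <- setNames(
    vapply(1:100, function(i) rand_seq(sample(30:200, 1)), character(1)),
    sprintf("SEQ%03d", 1:100)
  )
  tmp <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, tmp)
  expect_identical(read_sequences(tmp), seqs)
})

test_that("region-record topology parsing derives type, TMR count and SP flag", {
  tmp <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "# P1",
    "P1\tsignal\t1\t20",
    "P1\tTMhelix\t30\t52",
    "P1\tinside\t53\t100",
    "P2\tinside\t1\t100",
    "P3\tTMhelix\t5\t25",
    "P3\toutside\t26\t40",
    "P3\tTMhelix\t41\t60",
    "P4\tsignal\t1\t18",
    "P4\toutside\t19\t80"
  ), tmp)
  topo <- read_topology(tmp, dialect = "gff3_like")
  expect_equal(topo$protein_type[topo$accession == "P1"], "TM_SP")
  expect_equal(topo$n_tmr[topo$accession == "P1"], 1L)
  expect_true(topo$has_signal_peptide[topo$accession == "P1"])
  expect_equal(topo$protein_type[topo$accession == "P2"], "GLOB")
  expect_equal(topo$n_tmr[topo$accession == "P2"], 0L)
  expect_equal(topo$n_tmr[topo$accession == "P3"], 2L)
  expect_equal(topo$protein_type[topo$accession == "P4"], "GLOB_SP")
})

test_that("unknown region labels are rejected with a line number", {
  tmp <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("P1\tinside\t1\t10", "P1\tWIBBLE\t11\t20"), tmp)
  expect_error(read_topology(tmp, "gff3_like"), "line 2",
               class = "surfscreen_parse_error")
})

test_that("three-line topology dialect agrees with the region dialect", {
  tmp <- withr::local_tempfile(fileext = ".3line")
  writeLines(c(
    ">P1 | SP+TM",
    paste(rep("A", 30), collapse = ""),
    paste(c(rep("S", 10), rep("I", 5), rep("M", 10), rep("O", 5)), collapse = ""),
    ">P2 | GLOB",
    paste(rep("A", 10), collapse = ""),
    paste(rep("I", 10), collapse = "")
  ), tmp)
  topo <- read_topology(tmp, dialect = "three_line")
  expect_equal(topo$protein_type, c("TM_SP", "GLOB"))
  expect_equal(topo$n_tmr, c(1L, 0L))
  expect_equal(topo$has_signal_peptide, c(TRUE, FALSE))
})

test_that("every parsed topology satisfies the type/TMR/SP consistency invariant", {
  sim <- generate_proteome(sim_config(n_genes = 50, seed = 7), dir = withr::local_tempdir())
  topo <- read_topology(sim$paths$topology, "gff3_like")
  tm_types <- c("TM", "TM_SP", "BETA")
  expect_true(all((topo$n_tmr >= 1) == (topo$protein_type %in% tm_types)))
  expect_true(all(topo$has_signal_peptide ==
                    (topo$protein_type %in% c("TM_SP", "GLOB_SP"))))
  # Composition matches the generator's ledger.
  counts <- as.list(table(topo$protein_type))
  expect_equal(counts[order(names(counts))],
               sim$ledger$topology_counts[order(names(sim$ledger$topology_counts))])
})

test_that("topology write-read recovers type, count and SP flag exactly", {
  topo <- dplyr::bind_rows(
    topo_row("A1", "TM", 3), topo_row("A2", "TM_SP", 1),
    topo_row("A3", "GLOB"), topo_row("A4", "GLOB_SP"), topo_row("A5", "BETA", 8)
  )
  tmp <- withr::local_tempfile(fileext = ".gff3")
  write_topology_gff(topo, tmp)
  back <- read_topology(tmp, "gff3_like")
  expect_equal(back, dplyr::arrange(topo, accession))
})

test_that("the GO catalogue is validated for disjointness and coverage", {
  cat <- go_catalog()
  expect_length(cat$interest_ids, 13)
  expect_equal(unname(cat$es_id), "ES")
  expect_length(intersect(cat$surface_classes, cat$membrane_classes_requiring_tm), 0)
  expect_error(
    go_catalog(surface_classes = c("CS", "PM"),
               membrane_classes_requiring_tm = c("PM", "ACPM", "ICPM", "ES")),
    "disjoint", class = "surfscreen_catalog_error"
  )
  expect_error(
    go_catalog(surface_classes = "CS",
               membrane_classes_requiring_tm = c("PM", "ES")),
    "not assigned", class = "surfscreen_catalog_error"
  )
})

test_that("printed topology labels and topology types interconvert", {
  labels <- c("TM", "SP+TM", "SP", "GLOB", "BETA")
  expect_equal(label_from_topology(topology_from_label(labels)), labels)
  expect_equal(topology_from_label("SP"), "GLOB_SP")
  expect_equal(topology_from_label("SP+TM"), "TM_SP")
  expect_error(topology_from_label("XXX"), class = "surfscreen_format_error")
})

test_that("eggNOG table read-write-read is the identity", {
  egg <- dplyr::bind_rows(
    eggnog_row("A1", go = c("GO:0005886", "GO:0005615"), name = "GENE1"),
    eggnog_row("A2", evalue = 0.01, experimental = FALSE),
    eggnog_row("A3", orthology = "other")
  )
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_eggnog_table(egg, tmp)
  back <- read_eggnog_table(tmp)
  for (col in names(egg)) expect_equal(back[[col]], egg[[col]], label = col)
})

test_that("sperm list requires at least one key per record", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_name\tuniprot_id", "ACE2\tQ9BYF1", "\tP12345", "MSN\t"), tmp)
  sl <- read_sperm_list(tmp)
  expect_equal(nrow(sl), 3)
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_name\tuniprot_id", "ACE2\tQ9BYF1", "-\t-"), bad)
  expect_error(read_sperm_list(bad), class = "surfscreen_integrity_error")
})
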