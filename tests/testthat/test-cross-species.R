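make_store <- function(dir, manifest, fastas) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"), progress = FALSE)
  for (key in names(fastas)) {
    write_fasta(fastas[[key]], file.path(dir, paste0(key, ".fasta")))
  }
  sequence_store(dir)
}

test_that("product fetch returns all isoforms, flags alias-only matches, reports not-found", {
  set.seed(21)
  s1 <- rand_seq(60); s2 <- rand_seq(70)
  manifest <- tibble::tibble(
    gene = c("GENE1", "GENE1", "ALIASG"),
    species = c("speciesA", "speciesA", "speciesA"),
    refseq_id = c("NP_001", "NP_002", "NP_001"),
    description = c("GENE1 isoform 1", "GENE1 isoform 2", "shared product"),
    chromosome = c("X", "X", "X"),
    alias_of = c("", "", "GENE1")
  )
  store <- make_store(withr::local_tempdir(), manifest,
                      list(speciesA__GENE1 = c(NP_001 = s1, NP_002 = s2)))
  got <- fetch_gene_products("GENE1", "speciesA", store)
  expect_equal(got$status, "ok")
  expect_equal(nrow(got$products), 2)
  expect_equal(got$products$sequence, c(s1, s2))

  alias <- fetch_gene_products("ALIASG", "speciesA", store)
  expect_equal(alias$status, "not_found")  # no primary products
  expect_equal(nrow(alias$alias_matches), 1)

  missing <- fetch_gene_products("NOPE", "speciesA", store)
  expect_equal(missing$status, "not_found")
  expect_equal(nrow(missing$products), 0)
})

test_that("isoform selection prefers X1, then 1, then length, then lexicographic ID", {
  mk_set <- function(descs, seqs, ids = sprintf("NP_%03d", seq_along(descs))) {
    structure(list(
      gene_name = "G", species = "s", status = "ok",
      products = tibble::tibble(refseq_id = ids, description = descs,
                                chromosome = "X", sequence = seqs)
    ), class = "gene_product_set")
  }
  s <- mk_set(c("prot isoform X1", "prot isoform 1"), c("AAAA", "CCCC"))
  expect_equal(select_isoform(s)$refseq_id, "NP_001")
  s2 <- mk_set(c("prot isoform 2", "prot isoform 1"), c("AAAA", "CCCC"))
  expect_equal(select_isoform(s2)$refseq_id, "NP_002")
  s3 <- mk_set(c("prot", "prot"), c(strrep("A", 300), strrep("C", 450)))
  expect_equal(select_isoform(s3)$refseq_id, "NP_002") # longest wins
  s4 <- mk_set(c("prot", "prot"), c(strrep("A", 300), strrep("C", 300)),
               ids = c("NP_B", "NP_A"))
  expect_equal(select_isoform(s4)$refseq_id, "NP_A") # lexicographic tie-break
  # "isoform X1" must not match "isoform X12"
  s5 <- mk_set(c("prot isoform X12", "prot isoform 1"), c("AAAA", "CCCC"))
  expect_equal(select_isoform(s5)$refseq_id, "NP_002")
  empty <- structure(list(gene_name = "G", species = "s", status = "not_found",
                          products = s$products[0, ]),
                     class = "gene_product_set")
  expect_error(select_isoform(empty), class = "surfscreen_precondition_error")
})

test_that("cross-species mapping categorises genes and flags low similarity", {
  fx <- generate_crossmap_fixture(sim_config(seed = 23), dir = withr::local_tempdir())
  store <- sequence_store(fx$paths$store)
  ref <- readr::read_tsv(fx$paths$ref_targets, show_col_types = FALSE)
  out <- map_targets_across_species(ref, fx$query_targets, store)

  expect_equal(sum(out$category == "common_target"), length(fx$query_targets))
  expect_equal(sum(out$category == "unresolved"), 2)
  expect_true(out$needs_review[out$gene_name == "CGDIV"])
  expect_lt(out$similarity_pct[out$gene_name == "CGDIV"], 70)
  expect_equal(out$chromosome_status[out$gene_name == "CGADD2"], "unplaced")
  expect_equal(out$chromosome_status[out$gene_name == "CGADD1"], "on_chromosome")
  # similarity attached wherever both sequences were available
  expect_true(all(!is.na(out$similarity_pct[out$category != "unresolved"])))
})

test_that("curation applies the four exclusion rules in order, with the neighborhood exemption", {
  fx <- generate_crossmap_fixture(sim_config(seed = 23), dir = withr::local_tempdir())
  store <- sequence_store(fx$paths$store)
  ref <- readr::read_tsv(fx$paths$ref_targets, show_col_types = FALSE)
  out <- map_targets_across_species(ref, fx$query_targets, store)
  out2 <- apply_curation(out, read_curation_table(fx$paths$curation))

  expected <- fx$ledger$expected
  for (g in names(expected)) {
    row <- out2[out2$gene_name == g, ]
    expect_equal(row$category[1], expected[[g]]$category, label = g)
    want_r <- expected[[g]]$reason
    if (!is.na(want_r)) {
      expect_equal(row$exclusion_reason[1], want_r, label = paste(g, "reason"))
    }
  }
  # common targets and unresolved rows are untouched by curation
  expect_identical(out2$category[out$category == "common_target"],
                   out$category[out$category == "common_target"])

  # a candidate without a curation record is left unchanged with a warning
  extra <- out[out$gene_name == "CGADD1", ]
  extra$gene_name <- "CGUNKNOWN"
  expect_warning(
    res <- apply_curation(rbind(out, extra), read_curation_table(fx$paths$curation)),
    "CGUNKNOWN"
  )
  expect_equal(res$category[res$gene_name == "CGUNKNOWN"], "additional_candidate")
})

test_that("eggNOG-name rescue matches unnamed entries to candidates case-insensitively", {
  fx <- generate_crossmap_fixture(sim_config(seed = 29), dir = withr::local_tempdir())
  store <- sequence_store(fx$paths$store)
  ref <- readr::read_tsv(fx$paths$ref_targets, show_col_types = FALSE)
  out <- apply_curation(map_targets_across_species(ref, fx$query_targets, store),
                        read_curation_table(fx$paths$curation))
  unnamed <- fx$unnamed_annotated
  unnamed$eggnog_name <- tolower(unnamed$eggnog_name) # case-insensitivity
  hits <- match_unnamed_via_eggnog(unnamed, out)
  expect_setequal(hits$candidate_gene, fx$ledger$expected_name_rescue)
  expect_true(all(hits$needs_verification))

  none <- match_unnamed_via_eggnog(unnamed[0, ], out)
  expect_equal(nrow(none), 0)
})

test_that("a planted ortholog pair at 50% divergence is recovered as a flagged candidate", {
  set.seed(41)
  base <- rand_seq(150)
  diverged <- mutate_sequence(base, 0.5, 0, seed = 99)$sequence
  manifest <- tibble::tibble(
    gene = c("DIVG", "DIVG"), species = c("human", "rabbit"),
    refseq_id = c("NP_H", "XP_R"),
    description = c("DIVG protein", "DIVG protein"),
    chromosome = c("X", "X"), alias_of = c("", "")
  )
  store <- make_store(withr::local_tempdir(), manifest,
                      list(human__DIVG = c(NP_H = base),
                           rabbit__DIVG = c(XP_R = diverged)))
  out <- map_targets_across_species(
    tibble::tibble(gene_name = "DIVG", protein_name = "DIVG protein"),
    query_targets = character(0), store
  )
  expect_equal(out$category, "additional_candidate")
  expect_true(out$needs_review)
  expect_lt(out$similarity_pct, 70)
  expect_gt(out$similarity_pct, 30)
})
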