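test_that("interest rule: catalogue term, or extracellular space on a transmembrane protein", {
  # cell-surface term on a globular protein: of interest via CS
  a1 <- ann_row("P1", go = "GO:0009986", type = "GLOB")
  i1 <- classify_interest(a1)
  expect_true(i1$of_interest)
  expect_equal(i1$classes[[1]], "CS")
  expect_false(i1$via_es_tm)

  # extracellular space only, globular: not of interest
  a2 <- ann_row("P2", go = "GO:0005615", type = "GLOB")
  expect_false(classify_interest(a2)$of_interest)

  # extracellular space only, transmembrane: of interest via the ES+TM route
  a3 <- ann_row("P3", go = "GO:0005615", type = "TM")
  i3 <- classify_interest(a3)
  expect_true(i3$of_interest)
  expect_true(i3$via_es_tm)
  expect_equal(i3$classes[[1]], "ES")
})

test_that("target rule: surface branch ignores topology, membrane branch requires TM", {
  # surface-class terms on a signal-peptide-only protein (CD24-like): target
  cd24 <- ann_row("P1", go = c("GO:0009986", "GO:0005886", "GO:0009897",
                               "GO:0046658", "GO:0031362"), type = "GLOB_SP")
  c1 <- classify_target(cd24)
  expect_true(c1$is_target)
  expect_true(all(c("CS", "ESPM", "ACESPM") %in% c1$triggering_classes[[1]]))

  # plasma membrane only, globular: of interest but not a target
  pm_glob <- ann_row("P2", go = "GO:0005886", type = "GLOB")
  c2 <- classify_target(pm_glob)
  expect_true(c2$of_interest)
  expect_false(c2$is_target)

  # plasma membrane only, transmembrane (claudin-like): target
  pm_tm <- ann_row("P3", go = "GO:0005886", type = "TM")
  c3 <- classify_target(pm_tm)
  expect_true(c3$is_target)
  expect_equal(c3$triggering_classes[[1]], "PM")

  # beta-barrel counts as transmembrane for the membrane branch
  pm_beta <- ann_row("P4", go = "GO:0005886", type = "BETA")
  expect_true(classify_target(pm_beta)$is_target)

  # missing topology is treated as non-transmembrane
  pm_na <- ann_row("P5", go = "GO:0005886", type = NA_character_)
  c5 <- classify_target(pm_na)
  expect_false(c5$is_target)
  expect_true(c5$topology_missing)
})

test_that("experimental support requires a triggering GO ID with experimental evidence", {
  with_exp <- ann_row("P1", go = c("GO:0005886", "GO:0005634"), type = "TM",
                      exp_go = "GO:0005886")
  expect_true(classify_target(with_exp)$experimental_support)
  # evidence on a non-triggering term does not count
  wrong_exp <- ann_row("P2", go = c("GO:0005886", "GO:0005634"), type = "TM",
                       exp_go = "GO:0005634")
  expect_false(classify_target(wrong_exp)$experimental_support)
  # target via surface term, evidence on the membrane term that also fired
  no_exp <- ann_row("P3", go = "GO:0009986", type = "GLOB")
  expect_false(classify_target(no_exp)$experimental_support)
})

test_that("the target set is always a subset of the interest set", {
  set.seed(31)
  all_go <- c(names(go_catalog()$interest_ids), "GO:0005615", "GO:0005634")
  types <- c("TM", "TM_SP", "BETA", "GLOB", "GLOB_SP", NA_character_)
  ann <- dplyr::bind_rows(lapply(1:150, function(i) {
    ann_row(sprintf("P%03d", i),
            go = sample(all_go, sample(0:3, 1)),
            type = sample(types, 1))
  }))
  calls <- classify_target(ann)
  expect_true(all(!calls$is_target | calls$of_interest))
  # via_es_tm implies ES is the only triggering interest class
  es_rows <- calls[calls$via_es_tm, ]
  if (nrow(es_rows) > 0) {
    expect_true(all(vapply(es_rows$triggering_classes,
                           function(x) identical(x, "ES"), logical(1))))
  }
})

test_that("adding a surface-class term never demotes a target (monotonicity)", {
  set.seed(32)
  all_go <- c(names(go_catalog()$interest_ids), "GO:0005615", "GO:0005634")
  types <- c("TM", "GLOB", "GLOB_SP", NA_character_)
  for (i in 1:50) {
    go <- sample(all_go, sample(0:3, 1))
    type <- sample(types, 1)
    before <- classify_target(ann_row("P", go = go, type = type))$is_target
    after <- classify_target(
      ann_row("P", go = unique(c(go, "GO:0009986")), type = type)
    )$is_target
    expect_true(after >= before)
    expect_true(after) # a surface term alone suffices
  }
})

test_that("for surface-annotated proteins the call is invariant to topology", {
  for (type in c("TM", "TM_SP", "BETA", "GLOB", "GLOB_SP", NA_character_)) {
    call <- classify_target(ann_row("P", go = "GO:0009897", type = type))
    expect_true(call$is_target, label = paste("topology", type))
  }
})

test_that("screening recovers planted interest and target sets exactly", {
  sim <- generate_proteome(sim_config(n_genes = 150, seed = 13),
                           dir = withr::local_tempdir())
  entries <- read_proteome_table(sim$paths$proteome)
  mapping <- read_transcript_mapping(sim$paths$mapping)
  filtered <- filter_redundant(entries, mapping)
  egg <- filter_eggnog_hits(read_eggnog_table(sim$paths$eggnog))
  topo <- read_topology(sim$paths$topology)
  screen <- screen_proteome(merge_annotations(filtered$entries, egg, topo))
  calls <- screen$calls
  expect_identical(sort(calls$accession[calls$of_interest]),
                   sim$ledger$expected_interest)
  expect_identical(sort(calls$accession[calls$is_target]),
                   sim$ledger$expected_targets)
  expect_identical(sort(calls$accession[calls$is_target & calls$experimental_support]),
                   sim$ledger$expected_experimental_targets)
  expect_equal(screen$summary$n_target, length(sim$ledger$expected_targets))
})

test_that("screening an empty proteome yields zero counts", {
  empty <- ann_row("X")[0, ]
  screen <- screen_proteome(empty)
  expect_equal(screen$summary$n_proteins, 0)
  expect_equal(screen$summary$n_interest, 0)
  expect_equal(screen$summary$n_target, 0)
})
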