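#' Assemble a pipeline configuration
#'
#' Collects input paths and stage parameters for [run_pipeline()]. A YAML
#' file with the same field names can be loaded with [read_pipeline_config()].
#'
#' @param proteome,mapping,eggnog,topology Paths to the proteome TSV,
#'   transcript-mapping TSV, eggNOG TSV (optional) and topology file.
#' @param topology_dialect Dialect for [read_topology()].
#' @param sperm_list Optional sperm-proteome TSV.
#' @param store_dir,curation,ref_targets Optional cross-species inputs: a
#'   [sequence_store()] directory, curation TSV and reference-target TSV.
#' @param enrichment_annotation Optional named list mapping term to
#'   accession vector (or a TSV path with columns `term`, `accession`).
#' @param out_dir Output directory for per-stage tables.
#' @param catalog A [go_catalog()].
#' @param eggnog_cfg An [eggnog_filter_config()].
#' @param align_params An [alignment_params()].
#' @param cross_cfg A [cross_species_config()].
#' @param alpha Significance level for the enrichment stage.
#' @param seed Integer seed recorded in the manifest.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(proteome, mapping, topology,
                            eggnog = NULL,
                            topology_dialect = "gff3_like",
                            sperm_list = NULL,
                            store_dir = NULL, curation = NULL,
                            ref_targets = NULL,
                            enrichment_annotation = NULL,
                            out_dir = tempfile("surfscreen_run"),
                            catalog = go_catalog(),
                            eggnog_cfg = eggnog_filter_config(),
                            align_params = alignment_params(),
                            cross_cfg = cross_species_config(),
                            alpha = 0.05,
                            seed = 1L) {
  structure(
    list(
      proteome = proteome, mapping = mapping, topology = topology,
      eggnog = eggnog, topology_dialect = topology_dialect,
      sperm_list = sperm_list, store_dir = store_dir, curation = curation,
      ref_targets = ref_targets,
      enrichment_annotation = enrichment_annotation,
      out_dir = out_dir, catalog = catalog, eggnog_cfg = eggnog_cfg,
      align_params = align_params, cross_cfg = cross_cfg,
      alpha = alpha, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from YAML
#'
#' Path fields are taken verbatim; tuning blocks (`eggnog_cfg`,
#' `cross_cfg`, `align` gap penalties, `alpha`, `seed`) override defaults.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), c(
    "proteome", "mapping", "topology", "eggnog", "topology_dialect",
    "sperm_list", "store_dir", "curation", "ref_targets", "out_dir",
    "alpha", "seed"
  ))]
  if (!is.null(y$eggnog_cfg)) {
    args$eggnog_cfg <- do.call(eggnog_filter_config, y$eggnog_cfg)
  }
  if (!is.null(y$cross_cfg)) {
    args$cross_cfg <- do.call(cross_species_config, y$cross_cfg)
  }
  if (!is.null(y$align)) {
    args$align_params <- alignment_params(
      gap_open = y$align$gap_open %||% -11,
      gap_extend = y$align$gap_extend %||% -1,
      penalize_end_gaps = y$align$penalize_end_gaps %||% TRUE
    )
  }
  do.call(pipeline_config, args)
}

#' Run the screening pipeline end to end
#'
#' Executes filter, annotate and classify; then, where the corresponding
#' inputs are configured, enrichment, cross-species mapping with curation,
#' name rescue of unnamed entries, the combined target table (first-pass
#' targets plus cross-species additions, deduplicated by gene name with
#' accession fallback for unnamed entries), and the sperm-proteome
#' cross-reference. Per-stage tables are written under `cfg$out_dir` and a
#' manifest of row counts and the configuration hash is returned (and
#' written as `manifest.json`).
#'
#' @param cfg A [pipeline_config()].
#' @return A list with the per-stage results and `manifest`.
#' @export
run_pipeline <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)),
            class = "surfscreen_pipeline_error", parent = e)
    })
  }

  proteome <- stage("read", read_proteome_table(cfg$proteome))
  mapping <- stage("read", read_transcript_mapping(cfg$mapping))
  topo <- stage("read", read_topology(cfg$topology, cfg$topology_dialect))

  filtered <- stage("filter", filter_redundant(proteome, mapping))
  write_proteome_table(filtered$entries, file.path(cfg$out_dir, "filtered.tsv"))
  write_filter_audit(filtered$audit, file.path(cfg$out_dir, "filter_audit.json"))

  egg <- if (!is.null(cfg$eggnog) && file.exists(cfg$eggnog)) {
    stage("annotate", filter_eggnog_hits(read_eggnog_table(cfg$eggnog),
                                         cfg$eggnog_cfg))
  } else {
    read_eggnog_table_empty()
  }
  annotated <- stage("annotate",
                     merge_annotations(filtered$entries, egg, topo))
  write_annotated_table(annotated, file.path(cfg$out_dir, "annotated.tsv"))

  screen <- stage("classify", screen_proteome(annotated, cfg$catalog))
  write_target_calls(screen, file.path(cfg$out_dir, "targets.tsv"))

  enrichment <- NULL
  if (!is.null(cfg$enrichment_annotation)) {
    ann <- cfg$enrichment_annotation
    if (is.character(ann) && length(ann) == 1) {
      df <- read_tsv_quiet(ann, col_types = readr::cols(.default = "c"))
      check_columns(df, c("term", "accession"), ann)
      ann <- split(df$accession, df$term)
    }
    enrichment <- stage("enrich", overrepresentation_test(
      sample = screen$calls$accession[screen$calls$is_target],
      annotation = ann,
      reference = annotated$accession,
      alpha = cfg$alpha
    ))
    readr::write_tsv(enrichment, file.path(cfg$out_dir, "enrichment.tsv"),
                     progress = FALSE)
  }

  outcomes <- NULL
  rescue <- NULL
  if (!is.null(cfg$store_dir) && !is.null(cfg$ref_targets)) {
    store <- stage("crossmap", sequence_store(cfg$store_dir))
    ref_targets <- read_tsv_quiet(cfg$ref_targets,
                                  col_types = readr::cols(.default = "c"))
    check_columns(ref_targets, c("gene_name", "protein_name"), cfg$ref_targets)
    query_target_genes <- screen$calls |>
      filter(is_target, !is.na(gene_name)) |>
      pull(gene_name)
    outcomes <- stage("crossmap", map_targets_across_species(
      ref_targets, query_target_genes, store, cfg$cross_cfg, cfg$align_params
    ))
    if (!is.null(cfg$curation) && file.exists(cfg$curation)) {
      records <- read_curation_table(cfg$curation)
      outcomes <- stage("curate", apply_curation(
        outcomes, records, cfg$cross_cfg$target_chromosome, cfg$cross_cfg
      ))
    }
    readr::write_tsv(outcomes, file.path(cfg$out_dir, "crossmap.tsv"),
                     progress = FALSE)
    rescue <- match_unnamed_via_eggnog(annotated, outcomes)
    readr::write_tsv(rescue, file.path(cfg$out_dir, "name_rescue.tsv"),
                     progress = FALSE)
  }

  combined <- combine_targets(screen$calls, outcomes)
  readr::write_tsv(combined, file.path(cfg$out_dir, "combined_targets.tsv"),
                   progress = FALSE)

  crossref <- NULL
  if (!is.null(cfg$sperm_list) && file.exists(cfg$sperm_list)) {
    sperm <- read_sperm_list(cfg$sperm_list)
    targets_tbl <- combined |>
      rename(uniprot_id = accession) |>
      mutate(uniprot_id = ifelse(origin == "first_pass_target", uniprot_id,
                                 NA_character_))
    crossref <- stage("crossref", crossref_sperm(targets_tbl, sperm))
    readr::write_tsv(crossref, file.path(cfg$out_dir, "sperm_crossref.tsv"),
                     progress = FALSE)
  }

  manifest <- list(
    config_hash = hash(cfg[setdiff(names(cfg), "out_dir")]),
    seed = cfg$seed,
    counts = list(
      input_entries = nrow(proteome),
      filtered_entries = nrow(filtered$entries),
      dropped_no_gene = length(filtered$audit$dropped_no_gene),
      dropped_gene_duplicate = nrow(filtered$audit$dropped_gene_duplicate),
      eggnog_rows_kept = nrow(egg),
      annotated = nrow(annotated),
      of_interest = screen$summary$n_interest,
      targets = screen$summary$n_target,
      targets_experimental = screen$summary$n_target_experimental,
      crossmap_common = if (!is.null(outcomes)) sum(outcomes$category == "common_target") else NA,
      crossmap_additional = if (!is.null(outcomes)) sum(outcomes$category == "additional_candidate") else NA,
      crossmap_excluded = if (!is.null(outcomes)) sum(outcomes$category == "excluded") else NA,
      crossmap_unresolved = if (!is.null(outcomes)) sum(outcomes$category == "unresolved") else NA,
      combined_targets = nrow(combined),
      sperm_hits = if (!is.null(crossref)) nrow(crossref) else NA
    )
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  list(
    filtered = filtered, annotated = annotated, screen = screen,
    enrichment = enrichment, crossmap = outcomes, name_rescue = rescue,
    combined = combined, sperm_crossref = crossref, manifest = manifest
  )
}

#' @noRd
read_eggnog_table_empty <- function() {
  tibble(
    query_accession = character(0), seed_ortholog = character(0),
    evalue = double(0), bit_score = double(0),
    preferred_name = character(0), description = character(0),
    go_ids = list(), orthology_type = character(0),
    pct_identity = double(0), query_coverage = double(0),
    subject_coverage = double(0), go_evidence_experimental = logical(0)
  )
}

#' Combine first-pass targets with cross-species additions
#'
#' The comprehensive target list is the gene-level union of the species' own
#' target calls and the surviving cross-species additional candidates,
#' deduplicated by gene name (case-insensitive), falling back to the
#' accession for entries without a gene name.
#'
#' @param calls Target-call tibble (see [classify_target()]).
#' @param outcomes Optional cross-species outcome tibble (post-curation).
#' @return Tibble with `gene_name`, `accession`, `origin`.
#' @export
combine_targets <- function(calls, outcomes = NULL) {
  first_pass <- calls |>
    filter(is_target) |>
    mutate(origin = "first_pass_target") |>
    select(gene_name, accession, origin)
  additions <- if (!is.null(outcomes)) {
    outcomes |>
      filter(category == "additional_candidate") |>
      mutate(accession = query_refseq_id, origin = "cross_species_addition") |>
      select(gene_name, accession, origin)
  } else {
    first_pass[0, ]
  }
  bind_rows(first_pass, additions) |>
    mutate(dedup_key = tolower(ifelse(is.na(gene_name), accession, gene_name))) |>
    distinct(dedup_key, .keep_all = TRUE) |>
    select(-dedup_key) |>
    arrange(gene_name)
}
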