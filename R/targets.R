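#' Classify proteins as "of interest" (plasma-membrane associated)
#'
#' A protein is of interest if any catalogue GO ID of interest is in its GO
#' union, or if its only relevant annotation is the extracellular-space term
#' and it is predicted to be transmembrane. Proteins with missing topology
#' are treated as non-transmembrane.
#'
#' @param annotated Annotated-protein tibble (see [merge_annotations()]).
#' @param catalog A [go_catalog()].
#' @return Tibble with `accession`, `of_interest`, `classes` (list-column of
#'   matched class abbreviations, including `ES` on transmembrane proteins
#'   carrying the extracellular-space term) and `via_es_tm` (interest granted
#'   only through extracellular space + transmembrane topology).
#' @export
classify_interest <- function(annotated, catalog = go_catalog()) {
  es_go <- names(catalog$es_id)
  res <- map(seq_len(nrow(annotated)), function(i) {
    go <- annotated$go_union[[i]]
    is_tm <- isTRUE(annotated$protein_type[i] %in% TM_TYPES)
    classes <- sort(unique(unname(catalog$interest_ids[
      intersect(go, names(catalog$interest_ids))
    ])))
    has_es <- es_go %in% go
    # ES only counts on transmembrane proteins.
    if (has_es && is_tm) classes <- sort(unique(c(classes, "ES")))
    interest_via_ids <- length(setdiff(classes, "ES")) > 0
    of_interest <- interest_via_ids || (has_es && is_tm)
    list(
      of_interest = of_interest,
      classes = classes,
      via_es_tm = of_interest && !interest_via_ids
    )
  })
  tibble(
    accession = annotated$accession,
    of_interest = map_lgl(res, "of_interest"),
    classes = map(res, "classes"),
    via_es_tm = map_lgl(res, "via_es_tm")
  )
}

#' Classify proteins as cell-surface-accessible targets
#'
#' The target rule has two branches: a protein is a target if (a) any
#' surface-class GO term is attached to it, regardless of topology, or (b)
#' any membrane-class GO term (plasma membrane, anchored or integral
#' component of the plasma membrane, extracellular space) is attached *and*
#' the protein is predicted transmembrane. `triggering_classes` records the
#' classes that fired; `experimental_support` is true when at least one
#' triggering GO ID carries experimental evidence.
#'
#' @inheritParams classify_interest
#' @return Target-call tibble with `accession`, `gene_name`, `of_interest`,
#'   `is_target`, `triggering_classes` (list-column), `via_es_tm`,
#'   `experimental_support`, `topology_missing`.
#' @export
classify_target <- function(annotated, catalog = go_catalog()) {
  interest <- classify_interest(annotated, catalog)
  id_class <- catalog$all_ids
  res <- map(seq_len(nrow(annotated)), function(i) {
    go <- annotated$go_union[[i]]
    is_tm <- isTRUE(annotated$protein_type[i] %in% TM_TYPES)
    classes <- interest$classes[[i]]
    surface <- intersect(classes, catalog$surface_classes)
    membrane <- intersect(classes, catalog$membrane_classes_requiring_tm)
    is_target <- length(surface) > 0 || (length(membrane) > 0 && is_tm)
    triggering <- sort(unique(c(surface, if (is_tm) membrane)))
    trig_ids <- names(id_class)[unname(id_class) %in% triggering]
    trig_ids <- intersect(go, trig_ids)
    exp_support <- is_target &&
      length(intersect(trig_ids, annotated$experimental_go[[i]])) > 0
    list(is_target = is_target, triggering = triggering,
         exp_support = exp_support)
  })
  tibble(
    accession = annotated$accession,
    gene_name = annotated$gene_name,
    of_interest = interest$of_interest,
    is_target = map_lgl(res, "is_target"),
    triggering_classes = map(res, "triggering"),
    via_es_tm = interest$via_es_tm,
    experimental_support = map_lgl(res, "exp_support"),
    topology_missing = annotated$topology_missing
  )
}

#' Screen a whole annotated proteome
#'
#' Runs [classify_target()] over every protein and summarises the screen.
#'
#' @inheritParams classify_interest
#' @return A list with `calls` (the target-call tibble) and `summary`: the
#'   number of proteins screened, of interest, called target, called target
#'   with experimental support, and topology-category counts.
#' @export
screen_proteome <- function(annotated, catalog = go_catalog()) {
  calls <- classify_target(annotated, catalog)
  topo <- table(factor(annotated$protein_type, levels = TOPOLOGY_TYPES))
  list(
    calls = calls,
    summary = list(
      n_proteins = nrow(calls),
      n_interest = sum(calls$of_interest),
      n_target = sum(calls$is_target),
      n_target_experimental = sum(calls$is_target & calls$experimental_support),
      n_topology_missing = sum(calls$topology_missing),
      topology_counts = as.list(setNames(as.integer(topo), names(topo)))
    )
  )
}

#' Write target calls as TSV plus a JSON summary
#'
#' @param screen Result of [screen_proteome()].
#' @param path Output TSV path; the summary is written next to it with a
#'   `.summary.json` suffix.
#' @export
write_target_calls <- function(screen, path) {
  df <- screen$calls |>
    mutate(triggering_classes = map_chr(triggering_classes, join_multi))
  readr::write_tsv(df, path, progress = FALSE)
  jsonlite::write_json(
    screen$summary, paste0(sub("\\.tsv$", "", path), ".summary.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}
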