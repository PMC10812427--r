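#' The catalogue of plasma-membrane and cell-surface GO terms
#'
#' The screening rule is driven by a fixed set of cellular-component GO IDs,
#' each mapped to a class abbreviation. Classes fall into two disjoint groups:
#' *surface classes* (cell surface, external/anchored/integral components of
#' the external side of the plasma membrane, external side of cell wall or
#' outer membrane), which make a protein a candidate target regardless of its
#' predicted topology, and *membrane classes* (plasma membrane, anchored or
#' integral component of the plasma membrane, extracellular space), which make
#' it a target only when the protein is predicted to be transmembrane.
#'
#' The anchored-component-of-plasma-membrane term (GO:0046658) is retained
#' although it is obsolete in the ontology, because it encodes a protein
#' topology. The cell-wall and outer-membrane terms cannot fire on mammalian
#' data but are kept for completeness. GO descendants are *not* expanded:
#' only the exact IDs listed trigger the rule.
#'
#' @param interest_ids Named character vector mapping GO IDs to class
#'   abbreviations. The default is the built-in catalogue.
#' @param es_id Named character vector of length 1: the extracellular-space
#'   GO ID mapped to its class abbreviation `"ES"`.
#' @param surface_classes Character vector of class abbreviations that grant
#'   target status irrespective of topology.
#' @param membrane_classes_requiring_tm Character vector of class abbreviations
#'   that grant target status only on predicted transmembrane proteins.
#'
#' @return An object of class `go_catalog`: a list with the four components
#'   above plus `all_ids`, the union of `interest_ids` and `es_id`.
#'
#' @details Loading a catalogue whose two class sets are not disjoint, or that
#'   leaves a class unassigned to either set, is an error.
#'
#' @examples
#' cat <- go_catalog()
#' cat$interest_ids[["GO:0005886"]] # "PM"
#' @export
go_catalog <- function(interest_ids = NULL,
                       es_id = c("GO:0005615" = "ES"),
                       surface_classes = c(
                         "CS", "ESPM", "ECESPM", "ACESPM",
                         "ICESPM", "ESCW", "ESCOM"
                       ),
                       membrane_classes_requiring_tm = c(
                         "PM", "ACPM", "ICPM", "ES"
                       )) {
  if (is.null(interest_ids)) {
    interest_ids <- c(
      "GO:0005886" = "PM",     # plasma membrane
      "GO:0005904" = "PM",
      "GO:0009986" = "CS",     # cell surface
      "GO:0009928" = "CS",
      "GO:0009929" = "CS",
      "GO:0009897" = "ESPM",   # external side of plasma membrane
      "GO:0031232" = "ECESPM", # extrinsic component of external side of PM
      "GO:0046658" = "ACPM",   # anchored component of plasma membrane
      "GO:0031362" = "ACESPM", # anchored component of external side of PM
      "GO:0071575" = "ICESPM", # integral component of external side of PM
      "GO:0005887" = "ICPM",   # integral component of plasma membrane
      "GO:0010339" = "ESCW",   # external side of cell wall
      "GO:0031240" = "ESCOM"   # external side of cell outer membrane
    )
  }
  check_go_ids(names(interest_ids), "go_catalog interest_ids")
  check_go_ids(names(es_id), "go_catalog es_id")
  classes <- unique(c(unname(interest_ids), unname(es_id)))
  overlap <- intersect(surface_classes, membrane_classes_requiring_tm)
  if (length(overlap) > 0) {
    abort(
      sprintf(
        "go_catalog class sets must be disjoint; shared class(es): %s",
        paste(overlap, collapse = ", ")
      ),
      class = "surfscreen_catalog_error"
    )
  }
  uncovered <- setdiff(classes, c(surface_classes, membrane_classes_requiring_tm))
  if (length(uncovered) > 0) {
    abort(
      sprintf(
        "go_catalog class(es) not assigned to either class set: %s",
        paste(uncovered, collapse = ", ")
      ),
      class = "surfscreen_catalog_error"
    )
  }
  structure(
    list(
      interest_ids = interest_ids,
      es_id = es_id,
      surface_classes = surface_classes,
      membrane_classes_requiring_tm = membrane_classes_requiring_tm,
      all_ids = c(interest_ids, es_id)
    ),
    class = "go_catalog"
  )
}

#' Load a GO catalogue from a YAML configuration file
#'
#' The file may define `interest_ids` (mapping GO ID to class abbreviation),
#' `es_id`, `surface_classes` and `membrane_classes_requiring_tm`; omitted
#' components fall back to the built-in defaults. Disjointness and coverage
#' are validated on load.
#'
#' @param path Path to a YAML file.
#' @return A `go_catalog` object.
#' @export
read_go_catalog <- function(path) {
  cfg <- yaml::read_yaml(path)
  default <- go_catalog()
  go_catalog(
    interest_ids = if (!is.null(cfg$interest_ids)) unlist(cfg$interest_ids) else default$interest_ids,
    es_id = if (!is.null(cfg$es_id)) unlist(cfg$es_id) else default$es_id,
    surface_classes = cfg$surface_classes %||% default$surface_classes,
    membrane_classes_requiring_tm =
      cfg$membrane_classes_requiring_tm %||% default$membrane_classes_requiring_tm
  )
}

# One representative GO ID per class abbreviation, used when printed
# class-level tables are encoded back into GO-ID-level records. The
# representative is the first catalogue ID carrying that class.
#' Representative GO IDs for the catalogue classes
#'
#' @param catalog A `go_catalog`.
#' @return Named character vector mapping class abbreviation to one GO ID.
#' @export
class_representative_ids <- function(catalog = go_catalog()) {
  ids <- catalog$all_ids
  classes <- unique(unname(ids))
  setNames(names(ids)[match(classes, unname(ids))], classes)
}

# The five-way topology classification and the printed table labels must
# interconvert unambiguously; this mapping is fixed here and nowhere else.
PRINTED_TOPOLOGY_LABELS <- c(
  "TM"     = "TM",
  "SP+TM"  = "TM_SP",
  "BETA"   = "BETA",
  "GLOB"   = "GLOB",
  "SP"     = "GLOB_SP"
)

#' Convert between printed topology labels and topology types
#'
#' Printed tables label alpha-helical transmembrane proteins `TM`, proteins
#' with both a transmembrane region and a signal peptide `SP+TM`, proteins
#' with only a signal peptide `SP`, and globular proteins `GLOB`. Internally
#' the five prediction classes are `TM`, `TM_SP`, `BETA`, `GLOB`, `GLOB_SP`.
#'
#' @param label Character vector of printed labels.
#' @return Character vector of topology types.
#' @export
topology_from_label <- function(label) {
  out <- unname(PRINTED_TOPOLOGY_LABELS[label])
  if (anyNA(out)) {
    abort(
      sprintf(
        "Unknown printed topology label(s): %s",
        paste(unique(label[is.na(out)]), collapse = ", ")
      ),
      class = "surfscreen_format_error"
    )
  }
  out
}

#' @rdname topology_from_label
#' @param type Character vector of topology types.
#' @export
label_from_topology <- function(type) {
  rev_map <- setNames(names(PRINTED_TOPOLOGY_LABELS), PRINTED_TOPOLOGY_LABELS)
  out <- unname(rev_map[type])
  if (anyNA(out)) {
    abort(
      sprintf(
        "Unknown topology type(s): %s",
        paste(unique(type[is.na(out)]), collapse = ", ")
      ),
      class = "surfscreen_format_error"
    )
  }
  out
}

TOPOLOGY_TYPES <- unname(PRINTED_TOPOLOGY_LABELS)
TM_TYPES <- c("TM", "TM_SP", "BETA")

#' Read a printed target table and encode it as annotated proteins
#'
#' Published target tables report, per protein, a topology label and the
#' catalogue *classes* (not the GO IDs) attached to it. This reader encodes
#' such a table into the annotated-protein form consumed by
#' [classify_target()], substituting one representative GO ID per printed
#' class and mapping the printed topology labels to topology types.
#'
#' @param path TSV with columns `protein_id`, `gene_name`, `name_source`,
#'   `protein_name`, `topology` (printed label), `go_classes` (";"-joined
#'   class abbreviations) and `go_experimental`
#'   (`none`/`eggnog`/`uniprot_eggnog`).
#' @param catalog A `go_catalog`.
#' @return An annotated-protein tibble (see [merge_annotations()]).
#' @export
read_printed_target_table <- function(path, catalog = go_catalog()) {
  df <- read_tsv_quiet(path, col_types = readr::cols(.default = "c"))
  check_columns(
    df,
    c("protein_id", "gene_name", "name_source", "protein_name",
      "topology", "go_classes", "go_experimental"),
    path
  )
  rep_ids <- class_representative_ids(catalog)
  go_union <- map(df$go_classes, function(cls) {
    cls <- split_multi(cls)
    bad <- setdiff(cls, names(rep_ids))
    if (length(bad) > 0) {
      abort(
        sprintf("Unknown GO class abbreviation(s): %s", paste(bad, collapse = ", ")),
        class = "surfscreen_format_error"
      )
    }
    unname(rep_ids[cls])
  })
  has_exp <- df$go_experimental != "none"
  tibble(
    accession = df$protein_id,
    gene_name = na_if_blank(df$gene_name),
    protein_name = df$protein_name,
    chromosome = NA_character_,
    eggnog_name = ifelse(df$name_source == "eggnog", df$gene_name, NA_character_),
    go_union = go_union,
    go_sources = map(go_union, ~ setNames(rep(list("uniprot"), length(.x)), .x)),
    # The printed evidence footnote applies to the triggering annotations as a
    # whole; encode it by flagging every listed class's GO ID.
    experimental_go = map2(go_union, has_exp, ~ if (.y) .x else character(0)),
    protein_type = topology_from_label(df$topology),
    n_tmr = ifelse(topology_from_label(df$topology) %in% TM_TYPES, 1L, 0L),
    has_signal_peptide = topology_from_label(df$topology) %in% c("TM_SP", "GLOB_SP"),
    topology_missing = FALSE
  )
}
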