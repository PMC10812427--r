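#' Cross-species mapping configuration
#'
#' @param similarity_review_threshold_pct Candidates with cross-species
#'   sequence similarity below this percentage are flagged for review (not
#'   auto-excluded). Default 70.
#' @param neighbor_window Number of flanking genes considered on each side
#'   when the identical-neighborhood exemption is evaluated. Default 3.
#' @param reference_species Species providing the reference target list.
#' @param query_species Species whose proteome is searched for the targets.
#' @param target_chromosome Chromosome label defining "on chromosome" status
#'   in the query species.
#' @return A list of class `cross_species_config`.
#' @export
cross_species_config <- function(similarity_review_threshold_pct = 70,
                                 neighbor_window = 3L,
                                 reference_species = "human",
                                 query_species = "rabbit",
                                 target_chromosome = "X") {
  if (!(similarity_review_threshold_pct > 0 &&
        similarity_review_threshold_pct <= 100)) {
    abort("similarity_review_threshold_pct must be in (0, 100]",
          class = "surfscreen_config_error")
  }
  structure(
    list(
      similarity_review_threshold_pct = similarity_review_threshold_pct,
      neighbor_window = as.integer(neighbor_window),
      reference_species = reference_species,
      query_species = query_species,
      target_chromosome = target_chromosome
    ),
    class = "cross_species_config"
  )
}

#' Open a local gene-product sequence store
#'
#' The store is a directory holding a manifest (`manifest.tsv` with columns
#' `gene`, `species`, `refseq_id`, `description`, `chromosome`, `alias_of`)
#' and one FASTA per (species, gene) named `<species>__<gene>.fasta`, whose
#' record keys are the RefSeq IDs. `alias_of`, when non-empty, marks a
#' product reachable under `gene` only as an alias of another gene.
#'
#' @param dir Store directory.
#' @return A list of class `sequence_store`.
#' @export
sequence_store <- function(dir) {
  manifest_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(manifest_path)) {
    abort(sprintf("No manifest.tsv under '%s'", dir),
          class = "surfscreen_format_error")
  }
  df <- read_tsv_quiet(manifest_path, col_types = readr::cols(.default = "c"))
  check_columns(df, c("gene", "species", "refseq_id", "description",
                      "chromosome", "alias_of"), manifest_path)
  manifest <- df |>
    mutate(
      chromosome = na_if_blank(chromosome),
      alias_of = na_if_blank(alias_of)
    )
  structure(list(dir = dir, manifest = manifest), class = "sequence_store")
}

#' Fetch the protein products of a gene for one species
#'
#' Looks the gene up in the store manifest for the given species and returns
#' its products with sequences. Matches where the gene record's primary name
#' differs from the query (alias-only matches, guarding against distinct
#' genes sharing an alias) are flagged and excluded from the default
#' products. A gene absent from the store yields an empty product set with
#' status `"not_found"`, not an error.
#'
#' @param gene Gene name (matched case-insensitively).
#' @param species Species name.
#' @param store A [sequence_store()].
#' @return A list of class `gene_product_set` with `gene_name`, `species`,
#'   `status` (`"ok"`/`"not_found"`), `products` (tibble `refseq_id`,
#'   `description`, `chromosome`, `sequence`) and `alias_matches` (tibble of
#'   flagged alias-only products).
#' @export
fetch_gene_products <- function(gene, species, store) {
  rows <- store$manifest |>
    filter(tolower(.data$gene) == tolower(.env$gene),
           tolower(.data$species) == tolower(.env$species))
  primary <- rows |> filter(is.na(alias_of))
  alias <- rows |> filter(!is.na(alias_of))
  seqs <- character(0)
  fasta <- file.path(store$dir, paste0(species, "__", gene, ".fasta"))
  if (file.exists(fasta)) seqs <- read_sequences(fasta)
  build <- function(df) {
    tibble(
      refseq_id = df$refseq_id,
      description = df$description,
      chromosome = df$chromosome,
      sequence = unname(seqs[df$refseq_id])
    )
  }
  products <- build(primary)
  if (nrow(products) > 0 && anyDuplicated(products$refseq_id)) {
    integrity_abort(sprintf(
      "Duplicate refseq_id for gene '%s' (%s) in store", gene, species
    ))
  }
  structure(
    list(
      gene_name = gene,
      species = species,
      status = if (nrow(products) > 0) "ok" else "not_found",
      products = products,
      alias_matches = build(alias)
    ),
    class = "gene_product_set"
  )
}

#' Select a single isoform from a gene product set
#'
#' Preference order: a product whose description contains "isoform X1"; else
#' "isoform 1"; else the longest sequence; ties broken by lexicographically
#' smallest RefSeq ID.
#'
#' @param set A `gene_product_set` (see [fetch_gene_products()]).
#' @return A list with `refseq_id` and `sequence`.
#' @export
select_isoform <- function(set) {
  products <- set$products
  if (nrow(products) == 0) {
    abort(sprintf("No products for gene '%s' (%s)", set$gene_name, set$species),
          class = "surfscreen_precondition_error")
  }
  pick <- function(df) df[order(df$refseq_id), ][1, ]
  # "isoform X1"/"isoform 1" as whole designations (not a prefix of X10/10)
  x1 <- products[grepl("isoform X1($|[^0-9])", products$description), ]
  i1 <- products[grepl("isoform 1($|[^0-9])", products$description), ]
  chosen <- if (nrow(x1) > 0) {
    pick(x1)
  } else if (nrow(i1) > 0) {
    pick(i1)
  } else {
    longest <- products[nchar(products$sequence) == max(nchar(products$sequence)), ]
    pick(longest)
  }
  list(refseq_id = chosen$refseq_id, sequence = chosen$sequence,
       chromosome = chosen$chromosome)
}

#' Map reference-species targets onto a query-species proteome
#'
#' For each reference target gene, retrieves the reference and query
#' products from the store, selects one isoform per species, aligns them
#' globally and computes percent similarity. A gene already among the query
#' species' own targets is a `common_target`; a gene found in the query
#' store but not among its targets is an `additional_candidate`; a gene with
#' no query product is `unresolved`. Candidates below the similarity review
#' threshold are flagged for review, never auto-excluded.
#'
#' @param ref_targets Tibble with columns `gene_name` and `protein_name`
#'   (reference-species targets that carry a gene name).
#' @param query_targets Character vector of the query species' own target
#'   gene names.
#' @param store A [sequence_store()].
#' @param cfg A [cross_species_config()].
#' @param params [alignment_params()] used for the similarity alignment.
#' @return Outcome tibble: `gene_name`, `category` (`common_target`,
#'   `additional_candidate`, `unresolved`), `similarity_pct`,
#'   `ref_refseq_id`, `query_refseq_id`, `chromosome`, `chromosome_status`
#'   (`on_chromosome`/`unplaced`/`other`), `needs_review`,
#'   `exclusion_reason` (`NA` until curation).
#' @export
map_targets_across_species <- function(ref_targets, query_targets, store,
                                       cfg = cross_species_config(),
                                       params = alignment_params()) {
  query_targets_lc <- tolower(query_targets)
  rows <- map(seq_len(nrow(ref_targets)), function(i) {
    gene <- ref_targets$gene_name[i]
    ref_set <- fetch_gene_products(gene, cfg$reference_species, store)
    q_set <- fetch_gene_products(gene, cfg$query_species, store)
    if (q_set$status == "not_found") {
      return(tibble(
        gene_name = gene, category = "unresolved",
        similarity_pct = NA_real_, ref_refseq_id = NA_character_,
        query_refseq_id = NA_character_, chromosome = NA_character_,
        chromosome_status = NA_character_, needs_review = FALSE,
        exclusion_reason = NA_character_
      ))
    }
    q_iso <- select_isoform(q_set)
    sim <- NA_real_
    ref_id <- NA_character_
    if (ref_set$status == "ok") {
      r_iso <- select_isoform(ref_set)
      ref_id <- r_iso$refseq_id
      aln <- global_align(r_iso$sequence, q_iso$sequence, params,
                          query_id = r_iso$refseq_id,
                          subject_id = q_iso$refseq_id)
      sim <- aln$similarity_pct
    }
    chrom <- q_iso$chromosome
    status <- if (is.na(chrom) || tolower(chrom) == "unplaced") {
      "unplaced"
    } else if (chrom == cfg$target_chromosome) {
      "on_chromosome"
    } else {
      "other"
    }
    tibble(
      gene_name = gene,
      category = if (tolower(gene) %in% query_targets_lc) "common_target"
                 else "additional_candidate",
      similarity_pct = sim,
      ref_refseq_id = ref_id,
      query_refseq_id = q_iso$refseq_id,
      chromosome = chrom,
      chromosome_status = status,
      needs_review = !is.na(sim) && sim < cfg$similarity_review_threshold_pct,
      exclusion_reason = NA_character_
    )
  })
  bind_rows(rows)
}

#' Read a curation record table
#'
#' @param path TSV with columns `gene_name`, `removed_from_source`,
#'   `chromosome`, `ortholog_confirmed`, `flanking_genes_query`,
#'   `flanking_genes_subject` (both `";"`-joined ordered lists),
#'   `maps_to_same_product_as`, `is_alias_mapping`.
#' @return Tibble with flanking-gene list-columns.
#' @export
read_curation_table <- function(path) {
  df <- read_tsv_quiet(path, col_types = readr::cols(.default = "c"))
  check_columns(df, c(
    "gene_name", "removed_from_source", "chromosome", "ortholog_confirmed",
    "flanking_genes_query", "flanking_genes_subject",
    "maps_to_same_product_as", "is_alias_mapping"
  ), path)
  tibble(
    gene_name = df$gene_name,
    removed_from_source = tolower(df$removed_from_source) %in% c("true", "yes", "1"),
    chromosome = na_if_blank(df$chromosome),
    ortholog_confirmed = tolower(df$ortholog_confirmed) %in% c("true", "yes", "1"),
    flanking_genes_query = map(df$flanking_genes_query, split_multi),
    flanking_genes_subject = map(df$flanking_genes_subject, split_multi),
    maps_to_same_product_as = na_if_blank(df$maps_to_same_product_as),
    is_alias_mapping = tolower(df$is_alias_mapping) %in% c("true", "yes", "1")
  )
}

#' Apply the codified curation rules to cross-species outcomes
#'
#' Additional candidates are excluded, in this order, when (1) the source
#' database entry has been removed, (2) the gene is placed on a chromosome
#' other than the target chromosome, (3) the gene maps to the same product
#' as another gene and only as an alias (the gene for which the shared
#' product's primary name matches is kept), or (4) the query entry is not a
#' confirmed ortholog of the reference entry — unless the two genes have
#' identical ordered flanking-gene lists (the neighborhood exemption, window
#' `cfg$neighbor_window` genes each side). A candidate with no curation
#' record is left unchanged with a warning.
#'
#' @param outcomes Outcome tibble from [map_targets_across_species()].
#' @param records Curation tibble (see [read_curation_table()]).
#' @param target_chromosome Chromosome defining rule (2).
#' @param cfg A [cross_species_config()].
#' @return The outcome tibble with `category` set to `"excluded"` and
#'   `exclusion_reason` filled where a rule fired.
#' @export
apply_curation <- function(outcomes, records,
                           target_chromosome = "X",
                           cfg = cross_species_config()) {
  rec_idx <- match(tolower(outcomes$gene_name), tolower(records$gene_name))
  for (i in seq_len(nrow(outcomes))) {
    if (outcomes$category[i] != "additional_candidate") next
    j <- rec_idx[i]
    if (is.na(j)) {
      warn(sprintf("No curation record for gene '%s'; outcome left unchanged",
                   outcomes$gene_name[i]))
      next
    }
    reason <- NA_character_
    flank_q <- records$flanking_genes_query[[j]]
    flank_s <- records$flanking_genes_subject[[j]]
    if (length(flank_q) > 2 * cfg$neighbor_window ||
        length(flank_s) > 2 * cfg$neighbor_window) {
      integrity_abort(sprintf(
        "Flanking-gene list for '%s' exceeds 2 x neighbor_window",
        records$gene_name[j]
      ))
    }
    if (records$removed_from_source[j]) {
      reason <- "removed_entry"
    } else if (!is.na(records$chromosome[j]) &&
               tolower(records$chromosome[j]) != "unplaced" &&
               records$chromosome[j] != target_chromosome) {
      reason <- "other_chromosome"
    } else if (!is.na(records$maps_to_same_product_as[j]) &&
               records$is_alias_mapping[j]) {
      reason <- "duplicate_mapping"
    } else if (!records$ortholog_confirmed[j]) {
      identical_flanks <- length(flank_q) > 0 &&
        identical(flank_q, flank_s)
      if (!identical_flanks) reason <- "not_ortholog"
    }
    if (!is.na(reason)) {
      outcomes$category[i] <- "excluded"
      outcomes$exclusion_reason[i] <- reason
    }
  }
  outcomes
}

#' Match unnamed proteins to candidate genes via their eggNOG names
#'
#' Proteome entries without a gene or protein name can still correspond to a
#' cross-species candidate through the gene name assigned by orthology-based
#' annotation. Each case-insensitive match is emitted with a flag requesting
#' follow-up similarity/orthology verification.
#'
#' @param annotated Annotated-protein tibble; rows with an absent
#'   `gene_name` and a present `eggnog_name` participate.
#' @param outcomes Cross-species outcome tibble; `additional_candidate` rows
#'   are matched.
#' @return Tibble with `candidate_gene`, `accession`,
#'   `needs_verification` (always `TRUE`).
#' @export
match_unnamed_via_eggnog <- function(annotated, outcomes) {
  unnamed <- annotated |>
    filter(is.na(gene_name), !is.na(eggnog_name))
  candidates <- outcomes |>
    filter(category == "additional_candidate")
  if (nrow(unnamed) == 0 || nrow(candidates) == 0) {
    return(tibble(candidate_gene = character(0), accession = character(0),
                  needs_verification = logical(0)))
  }
  hits <- map(seq_len(nrow(unnamed)), function(i) {
    m <- candidates$gene_name[
      tolower(candidates$gene_name) == tolower(unnamed$eggnog_name[i])
    ]
    if (length(m) == 0) return(NULL)
    tibble(candidate_gene = m[1], accession = unnamed$accession[i],
           needs_verification = TRUE)
  })
  hits <- purrr::compact(hits)
  if (length(hits) == 0) {
    return(tibble(candidate_gene = character(0), accession = character(0),
                  needs_verification = logical(0)))
  }
  bind_rows(hits) |> arrange(candidate_gene, accession)
}

#' Live NCBI E-utilities sequence adapter (optional)
#'
#' Downloads the protein products of a gene/species combination from the
#' NCBI Gene and Protein databases through the E-utilities API and writes
#' them into the local [sequence_store()] layout, with simple rate limiting
#' and on-disk caching (existing FASTA files are not re-fetched). Requires
#' network access; every analysis function in the package operates on the
#' local store only.
#'
#' @param genes Character vector of gene names.
#' @param species Character vector of species names.
#' @param dir Store directory to populate.
#' @param sleep Seconds to wait between requests.
#' @param base_url E-utilities endpoint.
#' @return The store directory, invisibly.
#' @export
fetch_ncbi_store <- function(genes, species, dir,
                             sleep = 0.4,
                             base_url = "https://eutils.ncbi.nlm.nih.gov/entrez/eutils") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(dir, "manifest.tsv")
  rows <- list()
  for (sp in species) {
    for (gene in genes) {
      fasta <- file.path(dir, paste0(sp, "__", gene, ".fasta"))
      if (file.exists(fasta)) next
      Sys.sleep(sleep)
      term <- utils::URLencode(
        sprintf('%s[Gene Name] AND %s[Organism]', gene, sp), reserved = TRUE
      )
      search <- sprintf("%s/esearch.fcgi?db=protein&term=%s&retmax=50",
                        base_url, term)
      ids <- tryCatch({
        x <- paste(readLines(search, warn = FALSE), collapse = "")
        unlist(regmatches(x, gregexpr("(?<=<Id>)\\d+(?=</Id>)", x, perl = TRUE)))
      }, error = function(e) character(0))
      if (length(ids) == 0) next
      Sys.sleep(sleep)
      fetch <- sprintf("%s/efetch.fcgi?db=protein&id=%s&rettype=fasta&retmode=text",
                       base_url, paste(ids, collapse = ","))
      ok <- tryCatch({
        writeLines(readLines(fetch, warn = FALSE), fasta)
        TRUE
      }, error = function(e) FALSE)
      if (ok) {
        seqs <- read_sequences(fasta)
        rows[[paste(sp, gene)]] <- tibble(
          gene = gene, species = sp, refseq_id = names(seqs),
          description = names(seqs), chromosome = "", alias_of = ""
        )
      }
    }
  }
  if (length(rows) > 0) {
    readr::write_tsv(bind_rows(rows), manifest_path, progress = FALSE)
  }
  invisible(dir)
}
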