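#' Fold enrichment of a term in a sample against a reference
#'
#' The ratio of the sample annotation rate to the reference annotation rate,
#' `(k/n) / (K/N)`. Values above 1 indicate overrepresentation, below 1
#' underrepresentation.
#'
#' @param k Annotated members in the sample.
#' @param n Sample size.
#' @param K Annotated members in the reference.
#' @param N Reference size.
#' @return The fold enrichment as a double.
#' @export
fold_enrichment <- function(k, n, K, N) {
  if (any(n <= 0) || any(K <= 0) || any(N <= 0)) {
    abort("fold enrichment is undefined for n = 0, K = 0 or N = 0",
          class = "surfscreen_domain_error")
  }
  (k / n) / (K / N)
}

#' One-sided Fisher exact (hypergeometric tail) p-value
#'
#' For a sample of `n` drawn from a reference of `N` containing `K`
#' annotated members, with `k` annotated members observed in the sample, the
#' overrepresentation p-value is `P[X >= k]` and the underrepresentation
#' p-value `P[X <= k]`, with `X ~ Hypergeometric(N, K, n)`. Tails are
#' evaluated with the numerically stable log-space hypergeometric
#' distribution function.
#'
#' @inheritParams fold_enrichment
#' @param direction `"over"` or `"under"`.
#' @return The tail probability.
#' @export
fisher_exact_p <- function(k, n, K, N, direction = c("over", "under")) {
  direction <- match.arg(direction)
  if (k < 0 || n < 0 || K < 0 || N < 0 || k > n || k > K || n > N || K > N) {
    abort(
      sprintf("Invalid contingency values: k=%d n=%d K=%d N=%d", k, n, K, N),
      class = "surfscreen_domain_error"
    )
  }
  if (direction == "over") {
    phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  } else {
    phyper(k, K, N - K, n, lower.tail = TRUE)
  }
}

#' GO-term overrepresentation test with Bonferroni correction
#'
#' Tests every annotated term for over- and/or underrepresentation of a
#' sample of accessions against a reference set, reporting fold enrichment,
#' the one-sided Fisher exact p-value and the Bonferroni-adjusted p-value
#' `min(1, m * p)` where `m` is the number of terms tested in the run (both
#' directions share one `m`). Terms are tested flat, with no
#' ontology-hierarchy elimination.
#'
#' @param sample Character vector of sample accessions; must be a subset of
#'   `reference`.
#' @param annotation Named list mapping term to a character vector of
#'   annotated accessions.
#' @param reference Character vector: the reference accession set.
#' @param alpha Significance level applied to the adjusted p-value.
#' @param directions Which one-sided tests to run; by default both, reported
#'   as separate rows.
#' @return Tibble with one row per term and direction (`term`, `k`, `n`,
#'   `K`, `N`, `fold_enrichment`, `p_raw`, `p_adjusted`, `direction`,
#'   `significant`), sorted by adjusted p-value then term. Terms annotated
#'   in neither the sample nor the reference are omitted.
#' @export
overrepresentation_test <- function(sample, annotation, reference,
                                    alpha = 0.05,
                                    directions = c("over", "under")) {
  directions <- match.arg(directions, several.ok = TRUE)
  missing <- setdiff(sample, reference)
  if (length(missing) > 0) {
    abort(
      sprintf("Sample accession(s) not in reference: %s",
              paste(missing, collapse = ", ")),
      class = "surfscreen_precondition_error"
    )
  }
  sample <- unique(sample)
  reference <- unique(reference)
  n <- length(sample)
  N <- length(reference)
  if (length(annotation) == 0) {
    return(tibble(
      term = character(0), k = integer(0), n = integer(0), K = integer(0),
      N = integer(0), fold_enrichment = double(0), p_raw = double(0),
      p_adjusted = double(0), direction = character(0), significant = logical(0)
    ))
  }
  counts <- tibble(
    term = names(annotation),
    K = map_int(annotation, ~ length(intersect(.x, reference))),
    k = map_int(annotation, ~ length(intersect(.x, sample)))
  ) |>
    filter(K > 0 | k > 0)
  m <- nrow(counts)
  rows <- list()
  for (dir in directions) {
    rows[[dir]] <- counts |>
      mutate(
        n = n, N = N,
        fold_enrichment = ifelse(K > 0 & n > 0, (k / n) / (K / N), NA_real_),
        p_raw = map2_dbl_int(k, K, n, N, dir),
        p_adjusted = pmin(1, p_raw * m),
        direction = dir,
        significant = p_adjusted < alpha
      )
  }
  bind_rows(rows) |>
    select(term, k, n, K, N, fold_enrichment, p_raw, p_adjusted,
           direction, significant) |>
    arrange(p_adjusted, term, direction)
}

#' @noRd
map2_dbl_int <- function(k, K, n, N, dir) {
  n <- rep_len(n, length(k))
  N <- rep_len(N, length(k))
  vapply(seq_along(k),
         function(i) fisher_exact_p(k[i], n[i], K[i], N[i], dir),
         numeric(1))
}
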