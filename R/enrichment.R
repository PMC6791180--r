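#' Hypergeometric GO enrichment with a configurable background
#'
#' For each GO term annotated to at least one study gene, tests whether the
#' term is over-represented in the study set relative to the background by an
#' upper-tail hypergeometric test, then Benjamini-Hochberg adjusts across the
#' tested terms of this run. Terms annotated to no study gene are not tested
#' (zero-overlap rows would only dilute the correction).
#'
#' @param study Character vector of study gene ids; must be a subset of
#'   `background`.
#' @param background Character vector of background gene ids.
#' @param go_map Tibble with `gene_id`, `go_id` (many-to-many).
#' @param alpha Enrichment threshold on `q` (default 0.05).
#' @return Tibble per tested term: `go_id`, `k` (study genes with term), `K`
#'   (background genes with term), `n` (study size), `N` (background size),
#'   `p`, `q`, `enriched`.
#' @export
go_enrichment <- function(study, background, go_map, alpha = 0.05) {
  study <- unique(study); background <- unique(background)
  if (!all(study %in% background)) {
    abort_ct("study set must be a subset of the background")
  }
  if (length(study) == 0L) {
    return(tibble(go_id = character(), k = integer(), K = integer(),
                  n = integer(), N = integer(), p = double(), q = double(),
                  enriched = logical()))
  }
  map_bg <- go_map |>
    filter(.data$gene_id %in% background) |>
    distinct(.data$gene_id, .data$go_id)
  term_K <- map_bg |> dplyr::count(.data$go_id, name = "K")
  term_k <- map_bg |>
    filter(.data$gene_id %in% study) |>
    dplyr::count(.data$go_id, name = "k")
  n <- length(study); N <- length(background)
  out <- term_k |>
    left_join(term_K, by = "go_id") |>
    mutate(n = n, N = N,
           p = phyper(.data$k - 1, .data$K, N - .data$K, n,
                      lower.tail = FALSE)) |>
    mutate(q = p.adjust(.data$p, method = "BH"),
           enriched = .data$q < alpha) |>
    select("go_id", "k", "K", "n", "N", "p", "q", "enriched") |>
    arrange(.data$p)
  out
}

#' Reciprocal-best-hit ortholog pairs from two BLAST runs
#'
#' Builds a one-to-one putative-ortholog set from species A-vs-B and B-vs-A
#' hit tables: (1) drop hits with `evalue > max_evalue`; (2) keep the single
#' best hit per query (lowest e-value, ties broken by higher bitscore;
#' queries still tied between different subjects are discarded with a
#' message); (3) keep pairs that are best hits in both directions to the same
#' partner; (4) discard any gene that still participates in more than one
#' surviving pair.
#'
#' @param hits_ab Hits with species-A queries and species-B subjects
#'   (`query_id`, `subject_id`, `evalue`, `bitscore`).
#' @param hits_ba The reciprocal table.
#' @param max_evalue E-value threshold (default 1e-3).
#' @return Tibble of ortholog pairs: `gene_a`, `gene_b`, `evalue_ab`,
#'   `evalue_ba`; each gene appears at most once.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba, max_evalue = 1e-3) {
  best_ab <- best_hit_per_query(hits_ab, max_evalue)
  best_ba <- best_hit_per_query(hits_ba, max_evalue)
  pairs <- inner_join(
    best_ab |> rename(gene_a = "query_id", gene_b = "subject_id",
                      evalue_ab = "evalue"),
    best_ba |> rename(gene_b = "query_id", gene_a = "subject_id",
                      evalue_ba = "evalue"),
    by = c("gene_a", "gene_b")
  ) |>
    select("gene_a", "gene_b", "evalue_ab", "evalue_ba")
  multi <- c(pairs$gene_a[duplicated(pairs$gene_a)],
             pairs$gene_b[duplicated(pairs$gene_b)])
  if (length(multi) > 0L) {
    pairs <- filter(pairs, !(.data$gene_a %in% multi), !(.data$gene_b %in% multi))
  }
  arrange(pairs, .data$gene_a)
}

# Best hit per query after the e-value filter; fully tied queries dropped.
best_hit_per_query <- function(hits, max_evalue) {
  h <- filter(hits, .data$evalue <= max_evalue)
  if (nrow(h) == 0L) {
    return(tibble(query_id = character(), subject_id = character(),
                  evalue = double(), bitscore = double()))
  }
  h <- h |>
    group_by(.data$query_id) |>
    filter(.data$evalue == min(.data$evalue)) |>
    filter(.data$bitscore == max(.data$bitscore)) |>
    distinct(.data$query_id, .data$subject_id, .keep_all = TRUE) |>
    ungroup()
  tied <- h |> dplyr::count(.data$query_id) |> filter(.data$n > 1)
  if (nrow(tied) > 0L) {
    message(sprintf("%d quer%s with unresolvable best-hit ties discarded",
                    nrow(tied), ifelse(nrow(tied) == 1, "y", "ies")))
    h <- filter(h, !(.data$query_id %in% tied$query_id))
  }
  select(h, "query_id", "subject_id", "evalue", "bitscore")
}

#' Cross-species overlap of differentially methylated genes
#'
#' Maps species-A DM genes through a reciprocal-best-hit ortholog set and
#' counts how many have a partner in the species-B DM list.
#'
#' @param pairs Ortholog pairs from [reciprocal_best_hits()].
#' @param dm_a,dm_b Character vectors of DM gene ids in species A and B.
#' @return List with `n_a_in_orthologs` (A-side DM genes with an ortholog),
#'   `k_overlap` (those whose partner is DM in B) and `genes` (tibble of the
#'   overlapping pairs).
#' @export
cross_species_dm_overlap <- function(pairs, dm_a, dm_b) {
  with_orth <- filter(pairs, .data$gene_a %in% dm_a)
  hit <- filter(with_orth, .data$gene_b %in% dm_b)
  list(n_a_in_orthologs = nrow(with_orth),
       k_overlap = nrow(hit),
       genes = select(hit, "gene_a", "gene_b"))
}
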