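normalize_gene <- function(gene) toupper(stringr::str_trim(as.character(gene)))

#' Create a result store
#'
#' A result store collects analysis result files across probands, keyed by
#' (proband, model), plus optional per-proband *final results* (the short
#' list of candidate causative gene/variant pairs selected for a proband).
#' All query operations are read-only.
#'
#' @return An empty `mm_store`.
#' @export
result_store <- function() {
  structure(list(entries = list(), final_results = list()), class = "mm_store")
}

#' Add an analysis result to a store
#'
#' @param store An `mm_store`.
#' @param result An [result_file()].
#' @return The updated store.
#' @export
store_add <- function(store, result) {
  stopifnot(inherits(store, "mm_store"), inherits(result, "mm_result"))
  store$entries[[paste(result$proband_id, result$model, sep = "\r")]] <- result
  store
}

#' Record a proband's final candidate list
#'
#' @param store An `mm_store`.
#' @param proband_id Proband identifier.
#' @param candidates Tibble with at least a `gene` column, ordered as in the
#'   final result file; locus columns (`chrom`, `pos`, `ref`, `alt`) are
#'   kept when present.
#' @return The updated store.
#' @export
store_set_final <- function(store, proband_id, candidates) {
  stopifnot(inherits(store, "mm_store"))
  store$final_results[[proband_id]] <- as_tibble(candidates)
  store
}

#' @export
print.mm_store <- function(x, ...) {
  cat("<result store> ", length(x$entries), " result file(s), ",
      length(x$final_results), " final result list(s)\n", sep = "")
  invisible(x)
}

# entries of a store, optionally restricted to one model
store_entries <- function(store, model = NULL) {
  entries <- store$entries
  if (!is.null(model)) {
    entries <- purrr::keep(entries, function(e) identical(e$model, model))
  }
  entries
}

# long (proband_id, model, gene) incidence table, deduplicated per proband
store_gene_incidence <- function(store, model = NULL) {
  entries <- store_entries(store, model)
  if (length(entries) == 0) {
    return(tibble(proband_id = character(), model = character(), gene = character()))
  }
  purrr::map(entries, function(e) {
    genes <- unique(normalize_gene(e$rows$gene))
    genes <- genes[!is.na(genes) & nzchar(genes)]
    tibble(proband_id = e$proband_id, model = e$model, gene = genes)
  }) |>
    dplyr::bind_rows() |>
    distinct(.data$proband_id, .data$gene, .keep_all = TRUE)
}

#' Genes recurrently mutated across a cohort
#'
#' Finds genes that appear in the chosen model's result files of at least
#' `k` distinct probands — e.g. "any 3 individuals in a cohort of 10
#' families with variants in the same gene in the autosomal dominant
#' files". Multiple variants in one gene in one proband count once.
#'
#' @param store An `mm_store`.
#' @param model Inheritance model/result-file label to search, or `NULL`
#'   for all files.
#' @param k Minimum number of distinct supporting probands (>= 2).
#' @return Tibble with `gene`, `n_probands`, and a `probands` list-column
#'   (sorted ids), ordered by decreasing support then gene.
#' @export
cohort_recurrence <- function(store, model = NULL, k = 2L) {
  if (!is.numeric(k) || k < 2) {
    abort("k must be an integer >= 2.", class = "mm_argument_error")
  }
  inc <- store_gene_incidence(store, model)
  out <- inc |>
    group_by(.data$gene) |>
    summarise(n_probands = dplyr::n_distinct(.data$proband_id),
              probands = list(sort(unique(.data$proband_id))), .groups = "drop") |>
    filter(.data$n_probands >= .env$k) |>
    arrange(dplyr::desc(.data$n_probands), .data$gene)
  out
}

#' Proband groups sharing multiple mutated genes
#'
#' Answers "who are the individuals with the same 2 or more genes
#' mutated?": returns maximal groups of probands (size >= 2) whose result
#' files share at least `m` mutated genes, together with the shared gene
#' set. A group is suppressed when a proper superset of it also qualifies.
#'
#' @param store An `mm_store`.
#' @param m Minimum number of shared genes (>= 2).
#' @param model Optional model restriction.
#' @return Tibble with list-columns `probands` and `genes` plus counts
#'   `n_probands`, `n_genes`; deterministic order (larger groups first,
#'   then lexicographic).
#' @export
oligogenic_overlap <- function(store, m = 2L, model = NULL) {
  if (!is.numeric(m) || m < 2) {
    abort("m must be an integer >= 2.", class = "mm_argument_error")
  }
  inc <- store_gene_incidence(store, model)
  probands <- sort(unique(inc$proband_id))
  gene_sets <- lapply(probands, function(p) unique(inc$gene[inc$proband_id == p]))
  names(gene_sets) <- probands
  n <- length(probands)
  empty <- tibble(probands = list(), genes = list(),
                  n_probands = integer(), n_genes = integer())
  if (n < 2) return(empty)

  qualifying <- list()
  for (size in 2:n) {
    combos <- utils::combn(probands, size, simplify = FALSE)
    for (grp in combos) {
      shared <- Reduce(intersect, gene_sets[grp])
      if (length(shared) >= m) {
        qualifying[[length(qualifying) + 1L]] <- list(probands = grp,
                                                      genes = sort(shared))
      }
    }
  }
  if (length(qualifying) == 0) return(empty)
  # maximality: drop any group strictly contained in another qualifying group
  keep <- vapply(seq_along(qualifying), function(i) {
    gi <- qualifying[[i]]$probands
    !any(vapply(seq_along(qualifying), function(j) {
      j != i && length(qualifying[[j]]$probands) > length(gi) &&
        all(gi %in% qualifying[[j]]$probands)
    }, logical(1)))
  }, logical(1))
  qualifying <- qualifying[keep]
  out <- tibble(
    probands = purrr::map(qualifying, "probands"),
    genes = purrr::map(qualifying, "genes"),
    n_probands = purrr::map_int(qualifying, ~ length(.x$probands)),
    n_genes = purrr::map_int(qualifying, ~ length(.x$genes))
  )
  arrange(out, dplyr::desc(.data$n_probands),
          purrr::map_chr(.data$probands, paste, collapse = ","))
}

#' Search stored results for a gene or variant
#'
#' Finds every (proband, variant) row matching a gene symbol and/or a
#' genomic location — the location may be partial (chromosome and position
#' without alleles matches every alternate allele at that position). The
#' search can be restricted to one model's result files and narrowed by
#' phenotype features (probands whose profile contains all the given
#' features).
#'
#' @param store An `mm_store`.
#' @param gene Optional gene symbol (case-insensitive).
#' @param locus Optional list/one-row data frame with `chrom` and optionally
#'   `pos`, `ref`, `alt`.
#' @param model Optional model restriction.
#' @param features Optional character vector of phenotype features.
#' @param profiles Feature profile tibble (`individual_id`, `feature`);
#'   required when `features` is given.
#' @return Tibble of matching rows with `proband_id` and `model` prepended.
#' @export
genomic_search <- function(store, gene = NULL, locus = NULL, model = NULL,
                           features = NULL, profiles = NULL) {
  if (is.null(gene) && is.null(locus)) {
    abort("Provide a gene and/or a locus to search.", class = "mm_argument_error")
  }
  entries <- store_entries(store, model)
  hits <- purrr::map(entries, function(e) {
    rows <- e$rows
    if (nrow(rows) == 0) return(NULL)
    keep <- rep(TRUE, nrow(rows))
    if (!is.null(gene)) {
      keep <- keep & !is.na(rows$gene) & normalize_gene(rows$gene) == normalize_gene(gene)
    }
    if (!is.null(locus)) {
      loc <- as.list(locus)
      keep <- keep & rows$chrom == normalize_chrom(loc$chrom)
      if (!is.null(loc$pos) && !is.na(loc$pos)) keep <- keep & rows$pos == as.integer(loc$pos)
      if (!is.null(loc$ref) && !is.na(loc$ref)) keep <- keep & rows$ref == toupper(loc$ref)
      if (!is.null(loc$alt) && !is.na(loc$alt)) keep <- keep & rows$alt == toupper(loc$alt)
    }
    if (!any(keep)) return(NULL)
    dplyr::bind_cols(tibble(proband_id = e$proband_id, model = e$model),
                     rows[keep, ])
  })
  out <- dplyr::bind_rows(purrr::compact(hits))
  if (!is.null(features)) {
    if (is.null(profiles)) {
      abort("Narrowing by features requires the profiles table.",
            class = "mm_argument_error")
    }
    wanted <- normalize_features(features)
    ok <- feature_search(profiles, wanted, mode = "ALL")
    out <- filter(out, .data$proband_id %in% ok)
  }
  if (nrow(out) > 0) {
    out <- arrange(out, .data$proband_id, .data$model,
                   chrom_rank(.data$chrom), .data$pos, .data$ref, .data$alt)
  }
  out
}

#' Restrict a result file to a gene list
#'
#' Keeps the rows whose gene is in the supplied list (for example the ACMG
#' secondary-findings genes or any user list); matching is case-insensitive
#' after trimming. The provenance records a digest of the list.
#'
#' @param result An [result_file()].
#' @param genes Non-empty character vector of gene symbols.
#' @return A new `mm_result` with the retained rows.
#' @export
filter_by_gene_list <- function(result, genes) {
  stopifnot(inherits(result, "mm_result"))
  genes <- unique(normalize_gene(genes))
  genes <- genes[nzchar(genes) & !is.na(genes)]
  if (length(genes) == 0) {
    abort("Gene list must be non-empty.", class = "mm_argument_error")
  }
  keep <- !is.na(result$rows$gene) & normalize_gene(result$rows$gene) %in% genes
  out <- result
  out$rows <- result$rows[keep, ]
  digest <- sprintf("%d genes/%s", length(genes),
                    substr(rlang::hash(sort(genes)), 1, 8))
  out$provenance$gene_list <- digest
  out
}

#' Read a gene list (one symbol per line)
#'
#' @param path Path to the text file; blank and `#` lines are skipped.
#' @return Character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  lines <- stringr::str_trim(readLines(path))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Build a protein-interaction graph from an edge table
#'
#' @param edges Data frame (or path to a 3-column TSV) with columns
#'   `gene_a`, `gene_b`, `confidence` in `[0, 1]`. Self-loops are rejected;
#'   the graph is undirected.
#' @return An `mm_graph` (tibble of normalized edges).
#' @export
interaction_graph <- function(edges) {
  if (is.character(edges) && length(edges) == 1) {
    edges <- readr::read_tsv(edges, col_names = c("gene_a", "gene_b", "confidence"),
                             comment = "#", show_col_types = FALSE, progress = FALSE)
  }
  edges <- as_tibble(edges)
  stopifnot(all(c("gene_a", "gene_b", "confidence") %in% names(edges)))
  edges <- mutate(edges, gene_a = normalize_gene(.data$gene_a),
                  gene_b = normalize_gene(.data$gene_b),
                  confidence = as.numeric(.data$confidence))
  if (any(edges$gene_a == edges$gene_b)) {
    abort("Interaction graph must not contain self-loops.", class = "mm_argument_error")
  }
  if (any(is.na(edges$confidence) | edges$confidence < 0 | edges$confidence > 1)) {
    abort("Interaction confidences must lie in [0, 1].", class = "mm_argument_error")
  }
  structure(edges, class = c("mm_graph", class(edges)))
}

#' Genes within n interaction steps of a seed set
#'
#' Returns the genes whose protein products interact with any seed gene
#' within at most `order` edges (first-, second- or third-order
#' interactions), considering only edges at or above `min_confidence`.
#' Seeds themselves are excluded; the result is typically fed to
#' [filter_by_gene_list()].
#'
#' @param graph An [interaction_graph()].
#' @param seeds Non-empty character vector of seed gene symbols.
#' @param order Interaction order, 1, 2 or 3 (edges, not nodes).
#' @param min_confidence Minimum edge confidence in `[0, 1]`.
#' @return Sorted character vector of gene symbols.
#' @export
interaction_neighborhood <- function(graph, seeds, order = 1L, min_confidence = 0) {
  if (!order %in% 1:3) {
    abort("order must be 1, 2 or 3.", class = "mm_argument_error")
  }
  seeds <- unique(normalize_gene(seeds))
  seeds <- seeds[nzchar(seeds)]
  if (length(seeds) == 0) {
    abort("Seed set must be non-empty.", class = "mm_argument_error")
  }
  edges <- filter(as_tibble(graph), .data$confidence >= .env$min_confidence)
  if (nrow(edges) == 0) return(character())
  g <- igraph::graph_from_data_frame(edges[, c("gene_a", "gene_b")], directed = FALSE)
  present <- intersect(seeds, igraph::V(g)$name)
  if (length(present) == 0) return(character())
  d <- igraph::distances(g, v = present)
  reach <- colnames(d)[apply(d, 2, min) <= order]
  sort(setdiff(reach, seeds))
}
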