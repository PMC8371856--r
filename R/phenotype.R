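#' Read phenotype feature profiles
#'
#' @param path Path to a 2-column TSV (`individual_id`, `feature`). Terms
#'   are normalized (case-folded, whitespace-squished).
#' @return A tidy profile tibble, one row per (individual, feature).
#' @export
read_feature_profiles <- function(path) {
  tbl <- readr::read_tsv(path, col_names = c("individual_id", "feature"),
                         comment = "#", show_col_types = FALSE, progress = FALSE)
  feature_profiles(tbl)
}

#' Normalize a profile table
#'
#' @param profiles Data frame with `individual_id` and `feature` columns.
#' @return Tibble with normalized, deduplicated features.
#' @export
feature_profiles <- function(profiles) {
  as_tibble(profiles) |>
    mutate(individual_id = as.character(.data$individual_id),
           feature = tolower(stringr::str_squish(as.character(.data$feature)))) |>
    filter(nzchar(.data$feature)) |>
    distinct(.data$individual_id, .data$feature)
}

profile_features <- function(profiles, id) {
  profiles$feature[profiles$individual_id == id]
}

#' Find individuals by phenotype features
#'
#' `ALL` mode returns the individuals whose profile contains every query
#' feature; `ANY` mode those sharing at least one.
#'
#' @param profiles Profile tibble (see [feature_profiles()]).
#' @param query Non-empty character vector of features.
#' @param mode `"ALL"` or `"ANY"`.
#' @return Sorted character vector of individual ids.
#' @export
feature_search <- function(profiles, query, mode = c("ALL", "ANY")) {
  mode <- match.arg(toupper(mode[1]), c("ALL", "ANY"))
  query <- normalize_features(query)
  if (length(query) == 0) {
    abort("Feature query must be non-empty.", class = "mm_argument_error")
  }
  profiles <- feature_profiles(profiles)
  hits <- profiles |>
    group_by(.data$individual_id) |>
    summarise(n_hit = sum(unique(.data$feature) %in% .env$query), .groups = "drop")
  need <- if (mode == "ALL") length(query) else 1L
  sort(hits$individual_id[hits$n_hit >= need])
}

#' Overlap coefficient between two feature sets
#'
#' `|A intersect B| / min(|A|, |B|)` — symmetric, bounded in `[0, 1]`, and
#' equal to 1 whenever one set contains the other.
#'
#' @param a,b Character vectors of features.
#' @return A number in `[0, 1]` (`NA` if either set is empty).
#' @export
overlap_coefficient <- function(a, b) {
  a <- normalize_features(a); b <- normalize_features(b)
  if (length(a) == 0 || length(b) == 0) return(NA_real_)
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Match a proband against the database by phenotype overlap
#'
#' Computes the overlap coefficient between the target's feature set and
#' every other profiled individual, returning those at or above the
#' threshold (e.g. "all individuals with an at least 80% overlap of
#' phenotypic features" at `min_overlap = 0.8`).
#'
#' @param profiles Profile tibble.
#' @param target The target individual's id (present in `profiles`) or a
#'   character vector of features.
#' @param min_overlap Minimum overlap coefficient, in `(0, 1]`.
#' @return Tibble (`individual_id`, `coefficient`) sorted by decreasing
#'   coefficient, ties broken by id.
#' @export
overlap_match <- function(profiles, target, min_overlap = 0.8) {
  if (!is.numeric(min_overlap) || min_overlap <= 0 || min_overlap > 1) {
    abort("min_overlap must lie in (0, 1].", class = "mm_argument_error")
  }
  profiles <- feature_profiles(profiles)
  exclude <- character()
  if (length(target) == 1 && target %in% profiles$individual_id) {
    exclude <- target
    target_features <- profile_features(profiles, target)
  } else {
    target_features <- normalize_features(target)
  }
  if (length(target_features) == 0) {
    abort("Target feature set must be non-empty.", class = "mm_argument_error")
  }
  ids <- setdiff(sort(unique(profiles$individual_id)), exclude)
  coef <- vapply(ids, function(id) {
    f <- profile_features(profiles, id)
    if (length(f) == 0) {
      warn(paste0("Skipping individual '", id, "' with empty feature profile."))
      return(NA_real_)
    }
    overlap_coefficient(target_features, f)
  }, numeric(1))
  out <- tibble(individual_id = ids, coefficient = unname(coef)) |>
    filter(!is.na(.data$coefficient), .data$coefficient >= .env$min_overlap) |>
    arrange(dplyr::desc(.data$coefficient), .data$individual_id)
  out
}

#' Read a disease knowledge table
#'
#' @param path Path to a 5-column TSV: `disease_id`, `name`, semicolon-joined
#'   `features`, semicolon-joined `genes`, `inheritance`.
#' @return An `mm_knowledge` tibble with `features`/`genes` list-columns.
#' @export
read_disease_knowledge <- function(path) {
  tbl <- readr::read_tsv(
    path, col_names = c("disease_id", "name", "features", "genes", "inheritance"),
    comment = "#", show_col_types = FALSE, progress = FALSE
  )
  disease_knowledge(tbl)
}

#' Construct a disease knowledge table
#'
#' @param diseases Data frame with columns `disease_id`, `name`, `features`
#'   (list-column or `;`-joined strings), `genes` (likewise), `inheritance`.
#' @return An `mm_knowledge` tibble.
#' @export
disease_knowledge <- function(diseases) {
  kb <- as_tibble(diseases)
  split_col <- function(x) {
    if (is.list(x)) lapply(x, normalize_features)
    else lapply(strsplit(as.character(x), ";", fixed = TRUE), normalize_features)
  }
  split_genes <- function(x) {
    vals <- if (is.list(x)) x else strsplit(as.character(x), ";", fixed = TRUE)
    lapply(vals, function(g) unique(normalize_gene(g[nzchar(stringr::str_trim(g))])))
  }
  kb <- mutate(kb,
    disease_id = as.character(.data$disease_id),
    name = as.character(.data$name),
    features = split_col(.data$features),
    genes = split_genes(.data$genes),
    inheritance = as.character(.data$inheritance)
  )
  structure(kb, class = c("mm_knowledge", class(kb)))
}

#' Write a disease knowledge table
#'
#' @param knowledge An `mm_knowledge`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_disease_knowledge <- function(knowledge, path) {
  flat <- tibble(
    disease_id = knowledge$disease_id,
    name = knowledge$name,
    features = purrr::map_chr(knowledge$features, paste, collapse = ";"),
    genes = purrr::map_chr(knowledge$genes, paste, collapse = ";"),
    inheritance = knowledge$inheritance
  )
  readr::write_tsv(flat, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Rank differential diagnoses for a phenotype profile
#'
#' Scores every disease whose feature set intersects the profile and
#' returns the `top_n` most likely clinical differential diagnoses.
#' Diseases are ranked by the number of shared features (primary), the
#' fraction of the disease's features present in the profile (tie-break),
#' then disease id; zero-intersection diseases are excluded.
#'
#' @param profile Character vector of the individual's features.
#' @param knowledge An `mm_knowledge` table.
#' @param top_n Number of diagnoses retained (default 20).
#' @return An `mm_ddx` tibble: `rank`, `disease_id`, `name`, `n_shared`,
#'   `precision`, `score`.
#' @export
differential_diagnosis <- function(profile, knowledge, top_n = 20L) {
  profile <- normalize_features(profile)
  scored <- tibble(
    disease_id = knowledge$disease_id,
    name = knowledge$name,
    n_disease_features = purrr::map_int(knowledge$features, length),
    n_shared = purrr::map_int(knowledge$features,
                              ~ length(intersect(.x, profile)))
  ) |>
    filter(.data$n_shared > 0, .data$n_disease_features > 0) |>
    mutate(precision = .data$n_shared / .data$n_disease_features,
           score = .data$n_shared * .data$precision) |>
    arrange(dplyr::desc(.data$n_shared), dplyr::desc(.data$precision),
            .data$disease_id) |>
    mutate(rank = row_number()) |>
    select("rank", "disease_id", "name", "n_shared", "precision", "score")
  out <- scored[seq_len(min(top_n, nrow(scored))), ]
  structure(out, class = c("mm_ddx", class(out)))
}

#' Append the "OMIM Matching Phenotypes" column to a result file
#'
#' For each variant row, lists every top-ranked differential diagnosis
#' whose known gene set contains the row's gene, in rank order (empty cell
#' when none match). Rows are never removed or reordered.
#'
#' @param result An [result_file()].
#' @param differential An `mm_ddx` ranking computed from the same proband's
#'   phenotype profile (see [differential_diagnosis()]).
#' @param knowledge The `mm_knowledge` table the ranking came from.
#' @return The result with an added `OMIM Matching Phenotypes` column.
#' @export
annotate_omim_matching <- function(result, differential, knowledge) {
  stopifnot(inherits(result, "mm_result"))
  kb_idx <- match(differential$disease_id, knowledge$disease_id)
  disease_genes <- knowledge$genes[kb_idx]
  labels <- paste0(differential$disease_id, " (", differential$name, ")")
  cells <- vapply(result$rows$gene, function(g) {
    if (is.na(g)) return("")
    hit <- purrr::map_lgl(disease_genes, ~ normalize_gene(g) %in% .x)
    paste(labels[hit], collapse = "; ")
  }, character(1), USE.NAMES = FALSE)
  out <- result
  out$rows[["OMIM Matching Phenotypes"]] <- cells
  out
}
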