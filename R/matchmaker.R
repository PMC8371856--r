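#' Create a matchmaking registry
#'
#' The registry holds gene-level submissions (connecting submitters with an
#' interest in the same gene), a variant-level database of rare coding
#' single-nucleotide variants with optional phenotype payloads, stored
#' unmatched variant queries awaiting future data, an append-only match log
#' (the notification record: every match names both parties), and
#' per-submitter daily query quotas. "Day" is an abstract token supplied by
#' the caller, so behaviour is fully deterministic.
#'
#' All operations are functional: they return `list(registry = <updated>,
#' ...)` rather than mutating in place.
#'
#' @param build Genome build of the variant database (default `"hg19"`).
#'   Queries on other builds are lifted over before matching (see
#'   [register_liftover()]).
#' @param daily_quota Maximum accepted variant queries per submitter per day
#'   token (default 10).
#' @param position_only If `TRUE`, variant matching ignores the alleles and
#'   compares (chromosome, position) only; the default compares the full
#'   (chromosome, position, ref, alt).
#' @return An `mm_registry`.
#' @export
mm_registry <- function(build = "hg19", daily_quota = 10L, position_only = FALSE) {
  structure(
    list(
      build = match.arg(build, c("hg18", "hg19", "hg38")),
      daily_quota = as.integer(daily_quota),
      position_only = isTRUE(position_only),
      gene_subs = tibble(submitter_id = character(), gene = character(),
                         chrom = character(), pos = integer(), ref = character(),
                         alt = character(), inheritance = character(),
                         features = list(), timestamp = integer()),
      variant_db = tibble(chrom = character(), pos = integer(), ref = character(),
                          alt = character(), individual_id = character(),
                          features = list()),
      stored_queries = tibble(submitter_id = character(), chrom = character(),
                              pos = integer(), ref = character(), alt = character(),
                              features = list(), day = character(),
                              timestamp = integer()),
      match_log = tibble(kind = character(), key = character(),
                         party_a = character(), party_b = character(),
                         phenotype_shared = logical(), timestamp = integer()),
      quota_log = tibble(submitter_id = character(), day = character(),
                         n = integer()),
      liftover = list(),
      clock = 0L
    ),
    class = "mm_registry"
  )
}

#' @export
print.mm_registry <- function(x, ...) {
  cat("<matchmaking registry> build ", x$build, ": ",
      nrow(x$gene_subs), " gene submission(s), ",
      nrow(x$variant_db), " database variant record(s), ",
      nrow(x$stored_queries), " stored query(ies), ",
      nrow(x$match_log), " match-log entry(ies)\n", sep = "")
  invisible(x)
}

tick <- function(registry) {
  registry$clock <- registry$clock + 1L
  registry
}

# ---- liftover -------------------------------------------------------------

#' Register a coordinate liftover table for a build pair
#'
#' The matchmaking database lives on one build; queries on other builds are
#' mapped through a registered coordinate table before matching. The table
#' is pluggable data — any (chrom, pos) -> (new_chrom, new_pos) mapping.
#'
#' @param registry An `mm_registry`.
#' @param from,to Build identifiers (`"hg18"`, `"hg19"`, `"hg38"`).
#' @param map Data frame with columns `chrom`, `pos`, `new_chrom`, `new_pos`.
#' @return The updated registry.
#' @export
register_liftover <- function(registry, from, to, map) {
  map <- as_tibble(map)
  stopifnot(all(c("chrom", "pos", "new_chrom", "new_pos") %in% names(map)))
  map <- mutate(map, chrom = normalize_chrom(.data$chrom), pos = as.integer(.data$pos),
                new_chrom = normalize_chrom(.data$new_chrom),
                new_pos = as.integer(.data$new_pos))
  registry$liftover[[paste(from, to, sep = "->")]] <- map
  registry
}

#' Map a locus between genome builds
#'
#' Identity when the builds are equal; otherwise looks the position up in
#' the registered liftover table for the build pair. An unmappable
#' coordinate is an explicit error — the query is neither matched nor
#' silently dropped.
#'
#' @param registry An `mm_registry` holding the liftover tables.
#' @param locus One-row locus tibble (see [locus()]).
#' @param from,to Build identifiers.
#' @return The mapped one-row locus tibble.
#' @export
liftover_hook <- function(registry, locus, from, to) {
  if (identical(from, to)) return(locus)
  key <- paste(from, to, sep = "->")
  map <- registry$liftover[[key]]
  if (is.null(map)) {
    abort(paste0("No liftover table registered for ", key, "."),
          class = "mm_liftover_error")
  }
  hit <- map[map$chrom == locus$chrom & map$pos == locus$pos, ]
  if (nrow(hit) == 0) {
    abort(paste0("Coordinate ", locus$chrom, ":", locus$pos,
                 " is not mappable from ", from, " to ", to, "."),
          class = "mm_liftover_error")
  }
  mutate(locus, chrom = hit$new_chrom[1], pos = hit$new_pos[1])
}

# ---- gene matchmaking -----------------------------------------------------

#' Submit a candidate gene to the registry
#'
#' Stores the submission and returns one match record for every prior
#' submission of the same gene (case-insensitive); each match is logged as
#' a reciprocal notification naming both parties. After `n` submitters of
#' one gene, the registry-wide match log holds `n(n-1)/2` pairs.
#'
#' @param registry An `mm_registry`.
#' @param submitter_id Submitting party.
#' @param gene Gene symbol.
#' @param variant Optional one-row locus tibble of the candidate variant.
#' @param features Optional character vector of phenotype features.
#' @param inheritance Optional inheritance annotation.
#' @return `list(registry, matches)`; `matches` is a tibble with one row per
#'   matched prior submission (`gene`, `party_a`, `party_b`).
#' @export
submit_gene <- function(registry, submitter_id, gene, variant = NULL,
                        features = NULL, inheritance = NA_character_) {
  stopifnot(inherits(registry, "mm_registry"))
  gene <- normalize_gene(gene)
  if (!nzchar(gene) || is.na(gene)) {
    abort("Gene symbol must be non-empty.", class = "mm_validation_error")
  }
  registry <- tick(registry)
  prior <- filter(registry$gene_subs, .data$gene == .env$gene)
  loc <- if (is.null(variant)) {
    tibble(chrom = NA_character_, pos = NA_integer_, ref = NA_character_,
           alt = NA_character_)
  } else variant[, c("chrom", "pos", "ref", "alt")]
  registry$gene_subs <- dplyr::bind_rows(
    registry$gene_subs,
    dplyr::bind_cols(tibble(submitter_id = submitter_id, gene = gene), loc,
                     tibble(inheritance = inheritance,
                            features = list(normalize_features(features %||% character())),
                            timestamp = registry$clock))
  )
  matches <- tibble(gene = character(), party_a = character(), party_b = character())
  if (nrow(prior) > 0) {
    parties <- sort(unique(prior$submitter_id))
    parties <- setdiff(parties, submitter_id)  # self-matches are not notified
    if (length(parties) > 0) {
      matches <- tibble(gene = gene, party_a = parties, party_b = submitter_id)
      registry$match_log <- dplyr::bind_rows(
        registry$match_log,
        tibble(kind = "gene", key = gene, party_a = parties,
               party_b = submitter_id,
               phenotype_shared = length(normalize_features(features %||% character())) > 0,
               timestamp = registry$clock)
      )
    }
  }
  list(registry = registry, matches = matches)
}

#' Export a proband's candidate genes for gene matchmaking
#'
#' From a final result list (the strongest candidate causative variants and
#' genes for one proband), selects the candidate genes with no known
#' disease phenotype and caps the export at 10 genes, keeping the result
#' file's row order.
#'
#' @param final_results Tibble of final candidates in file order, with a
#'   `gene` column and optionally locus columns.
#' @param known_disease_genes Character vector of genes already associated
#'   with a disease phenotype (excluded from export).
#' @param submitter_id Submitter recorded on the generated submissions.
#' @param features Optional proband features attached to each submission.
#' @param max_genes Export cap (default 10).
#' @return Tibble of gene submissions ready for [submit_gene()].
#' @export
export_candidates_for_matching <- function(final_results, known_disease_genes,
                                           submitter_id = "auto-export",
                                           features = NULL, max_genes = 10L) {
  fr <- as_tibble(final_results)
  if (nrow(fr) == 0) {
    abort("Final results must be non-empty.", class = "mm_argument_error")
  }
  known <- unique(normalize_gene(known_disease_genes))
  fr <- mutate(fr, gene = normalize_gene(.data$gene))
  fr <- fr[!duplicated(fr$gene), , drop = FALSE]          # one submission per gene
  fr <- fr[!fr$gene %in% known, , drop = FALSE]           # novel genes only
  fr <- fr[seq_len(min(max_genes, nrow(fr))), , drop = FALSE]
  out <- tibble(submitter_id = submitter_id, gene = fr$gene)
  for (col in c("chrom", "pos", "ref", "alt")) {
    out[[col]] <- if (col %in% names(fr)) fr[[col]] else NA
  }
  out$features <- rep(list(normalize_features(features %||% character())), nrow(out))
  out
}

# ---- variant matchmaking --------------------------------------------------

variant_key <- function(x, position_only = FALSE) {
  if (position_only) paste0(x$chrom, ":", x$pos) else locus_key(x)
}

#' Ingest variant records into the matchmaking database
#'
#' Adds per-individual variant records (with optional phenotype features)
#' to the registry's database, optionally applying the ingest rule for the
#' public database — rare (MAF < 1% in every annotated population column),
#' coding with synonymous excluded, single-nucleotide variants only. Stored
#' unmatched queries are then replayed against the new records: any stored
#' query now matching produces a retroactive match record, so
#' (store query, ingest variant) and (ingest variant, query) yield the same
#' final match set.
#'
#' @param registry An `mm_registry`.
#' @param variants Tibble with `chrom`, `pos`, `ref`, `alt`,
#'   `individual_id`, optionally `func_class` and `maf_*` columns, and
#'   optionally a `features` list-column.
#' @param profiles Optional profile tibble (`individual_id`, `feature`)
#'   supplying features when `variants` has no `features` column.
#' @param apply_ingest_filter Apply the rare/coding/SNV rule (default
#'   `TRUE`; columns that are absent are not tested).
#' @param maf_threshold Rarity threshold for the ingest rule.
#' @return `list(registry, matches)`; `matches` holds retroactive match
#'   records for previously stored queries.
#' @export
vm_ingest <- function(registry, variants, profiles = NULL,
                      apply_ingest_filter = TRUE, maf_threshold = 0.01) {
  stopifnot(inherits(registry, "mm_registry"))
  v <- as_tibble(variants)
  v <- mutate(v, chrom = normalize_chrom(.data$chrom), pos = as.integer(.data$pos),
              ref = toupper(.data$ref), alt = toupper(.data$alt),
              individual_id = as.character(.data$individual_id))
  if (apply_ingest_filter && nrow(v) > 0) {
    keep <- nchar(v$ref) == 1L & nchar(v$alt) == 1L          # SNVs only
    if ("func_class" %in% names(v)) {
      keep <- keep & v$func_class %in% setdiff(FUNC_CLASSES, c("SYNONYMOUS", "OTHER"))
    }
    for (col in maf_cols(v)) {
      keep <- keep & (is.na(v[[col]]) | v[[col]] < maf_threshold)
    }
    v <- v[keep, , drop = FALSE]
  }
  if (!"features" %in% names(v)) {
    v$features <- lapply(v$individual_id, function(id) {
      if (is.null(profiles)) character()
      else normalize_features(profiles$feature[profiles$individual_id == id])
    })
  }
  registry <- tick(registry)
  registry$variant_db <- dplyr::bind_rows(
    registry$variant_db,
    v[, c("chrom", "pos", "ref", "alt", "individual_id", "features")]
  )
  # replay stored queries against the enlarged database
  matches <- list()
  still_stored <- rep(TRUE, nrow(registry$stored_queries))
  for (i in seq_len(nrow(registry$stored_queries))) {
    q <- registry$stored_queries[i, ]
    hit <- db_lookup(registry, q)
    if (nrow(hit) > 0) {
      rec <- make_match_record(registry, q$submitter_id, q, hit, q$features[[1]])
      registry <- rec$registry
      matches[[length(matches) + 1L]] <- rec$record
      still_stored[i] <- FALSE
    }
  }
  registry$stored_queries <- registry$stored_queries[still_stored, , drop = FALSE]
  list(registry = registry, matches = matches)
}

db_lookup <- function(registry, loc) {
  db <- registry$variant_db
  if (registry$position_only) {
    db[db$chrom == loc$chrom & db$pos == loc$pos, , drop = FALSE]
  } else {
    db[db$chrom == loc$chrom & db$pos == loc$pos &
         db$ref == loc$ref & db$alt == loc$alt, , drop = FALSE]
  }
}

make_match_record <- function(registry, submitter_id, loc, hit, query_features) {
  share_phenotypes <- length(query_features) >= 3 && length(query_features) <= 6
  record <- structure(
    list(
      query = locus_key(loc),
      submitter_id = submitter_id,
      matched = tibble(
        individual_id = hit$individual_id,
        features = if (share_phenotypes) hit$features else
          rep(list(character()), nrow(hit))
      ),
      phenotype_shared = share_phenotypes,
      query_features = query_features
    ),
    class = "mm_match"
  )
  registry$match_log <- dplyr::bind_rows(
    registry$match_log,
    tibble(kind = "variant", key = locus_key(loc),
           party_a = submitter_id, party_b = hit$individual_id,
           phenotype_shared = share_phenotypes, timestamp = registry$clock)
  )
  list(registry = registry, record = record)
}

#' @export
print.mm_match <- function(x, ...) {
  cat("<match record> ", x$query, ": ", x$submitter_id, " <-> ",
      paste(x$matched$individual_id, collapse = ", "),
      if (x$phenotype_shared) " [phenotypes shared]" else "", "\n", sep = "")
  invisible(x)
}

#' Query the variant matchmaking database
#'
#' Matches the queried coordinate against the database after normalizing
#' the build (queries on other builds are lifted over to the database
#' build first). A match is exact on (chromosome, position, ref, alt)
#' unless the registry was created `position_only`. On a match, both
#' parties are recorded in the match log, and the matched individuals'
#' phenotype payloads are attached iff the query supplied 3-6 features. If
#' no match is made the query is stored for future matching. Each
#' submitter may place at most `daily_quota` accepted queries per day
#' token.
#'
#' @param registry An `mm_registry`.
#' @param query An [parse_variant_query()] object (or query string).
#' @param submitter_id Querying party.
#' @param day Abstract day token used for quota accounting.
#' @return `list(registry, record)`; `record` is an `mm_match` on success or
#'   an `mm_stored_receipt` when the query was stored.
#' @export
query_variant <- function(registry, query, submitter_id, day = "day-1") {
  stopifnot(inherits(registry, "mm_registry"))
  if (is.character(query)) query <- parse_variant_query(query)
  stopifnot(inherits(query, "mm_variant_query"))
  if (!is.null(query$features)) {
    nf <- length(query$features)
    if (nf < 3 || nf > 6) {
      abort("Variant queries with phenotypes require 3 to 6 features.",
            class = "mm_validation_error")
    }
  }
  used <- registry$quota_log |>
    filter(.data$submitter_id == .env$submitter_id, .data$day == .env$day)
  n_used <- if (nrow(used) == 0) 0L else used$n[1]
  if (n_used >= registry$daily_quota) {
    abort(paste0("Daily quota of ", registry$daily_quota,
                 " queries exhausted for '", submitter_id, "' on ", day, "."),
          class = "mm_quota_error")
  }
  registry <- tick(registry)
  loc <- liftover_hook(registry, query$locus, query$build, registry$build)
  registry$quota_log <- registry$quota_log |>
    filter(!(.data$submitter_id == .env$submitter_id & .data$day == .env$day)) |>
    dplyr::bind_rows(tibble(submitter_id = submitter_id, day = day, n = n_used + 1L))

  hit <- db_lookup(registry, loc)
  if (nrow(hit) > 0) {
    rec <- make_match_record(registry, submitter_id, loc, hit,
                             query$features %||% character())
    return(list(registry = rec$registry, record = rec$record))
  }
  registry$stored_queries <- dplyr::bind_rows(
    registry$stored_queries,
    dplyr::bind_cols(tibble(submitter_id = submitter_id), loc,
                     tibble(features = list(query$features %||% character()),
                            day = day, timestamp = registry$clock))
  )
  receipt <- structure(
    list(query = locus_key(loc), submitter_id = submitter_id, stored = TRUE),
    class = "mm_stored_receipt"
  )
  list(registry = registry, record = receipt)
}

#' @export
print.mm_stored_receipt <- function(x, ...) {
  cat("<stored query> ", x$query, " (", x$submitter_id,
      "): no match yet, stored for future matching\n", sep = "")
  invisible(x)
}

#' Persist a registry as line-delimited JSON
#'
#' @param registry An `mm_registry`.
#' @param path Output path; one JSON object per line, first line the header
#'   (build, quota), then one line per stored table row.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  ser_tbl <- function(tbl, table) {
    if (nrow(tbl) == 0) return(character())
    vapply(seq_len(nrow(tbl)), function(i) {
      row <- as.list(tbl[i, ])
      row <- lapply(row, function(x) if (is.list(x)) x[[1]] else x)
      jsonlite::toJSON(c(list(table = table), row), auto_unbox = TRUE,
                       null = "null", na = "null")
    }, character(1))
  }
  lines <- c(
    jsonlite::toJSON(list(table = "header", build = registry$build,
                          daily_quota = registry$daily_quota,
                          position_only = registry$position_only,
                          clock = registry$clock), auto_unbox = TRUE),
    ser_tbl(registry$gene_subs, "gene_submission"),
    ser_tbl(registry$variant_db, "variant_record"),
    ser_tbl(registry$stored_queries, "stored_query"),
    ser_tbl(registry$match_log, "match"),
    ser_tbl(registry$quota_log, "quota")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Load a registry written by [write_registry()]
#'
#' @param path Path to the line-delimited JSON file.
#' @return An `mm_registry`.
#' @export
read_registry <- function(path) {
  objs <- lapply(readLines(path), jsonlite::fromJSON)
  header <- objs[[which(vapply(objs, `[[`, "", "table") == "header")[1]]]
  reg <- mm_registry(header$build, header$daily_quota, isTRUE(header$position_only))
  reg$clock <- as.integer(header$clock)
  grab <- function(table, template) {
    rows <- objs[vapply(objs, `[[`, "", "table") == table]
    if (length(rows) == 0) return(template)
    out <- dplyr::bind_rows(lapply(rows, function(o) {
      o$table <- NULL
      o <- lapply(o, function(x) if (is.null(x)) NA else x)
      for (nm in names(template)) {
        if (is.list(template[[nm]])) o[[nm]] <- list(as.character(unlist(o[[nm]])))
      }
      as_tibble(o[names(template)])
    }))
    for (nm in names(template)) {
      if (is.integer(template[[nm]]) && !is.list(template[[nm]])) {
        out[[nm]] <- as.integer(out[[nm]])
      }
    }
    out
  }
  reg$gene_subs <- grab("gene_submission", reg$gene_subs)
  reg$variant_db <- grab("variant_record", reg$variant_db)
  reg$stored_queries <- grab("stored_query", reg$stored_queries)
  reg$match_log <- grab("match", reg$match_log)
  reg$quota_log <- grab("quota", reg$quota_log)
  reg
}

`%||%` <- function(x, y) if (is.null(x)) y else x
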