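# Independent brute-force oracles. These restate the segregation rules,
# the filter predicates and the graph/set computations directly, without
# calling the package's engine, so the suite can check the implementation
# against a second, independent derivation.

oracle_carrier <- function(g) g %in% c("HET", "HOM_ALT", "HEMI")

# trio verdict for the single-variant models; genotypes are the trio's
# (proband, father, mother); "ABSENT" marks a parent not in the pedigree
oracle_trio_verdict <- function(model, gp, gf, gm,
                                father_affected = FALSE,
                                proband_sex = "FEMALE") {
  miss <- function(g) g %in% c("MISSING", "ABSENT")
  if (miss(gp)) return("FAIL")
  fail <- FALSE
  possible <- FALSE
  note_parent <- function(g, violated_when) {
    if (miss(g)) possible <<- TRUE
    else if (violated_when(g)) fail <<- TRUE
  }
  if (model == "AD_DENOVO") {
    if (gp != "HET") return("FAIL")
    note_parent(gf, function(g) g != "HOM_REF")
    note_parent(gm, function(g) g != "HOM_REF")
  } else if (model == "AD_INHERITED") {
    if (gp != "HET") return("FAIL")
    if (father_affected) {
      note_parent(gf, function(g) g != "HET")
    } else {
      note_parent(gf, function(g) g != "HOM_REF")
    }
    note_parent(gm, function(g) g != "HOM_REF")
    if (!miss(gf) && !miss(gm) && !oracle_carrier(gf) && !oracle_carrier(gm)) {
      fail <- TRUE  # nobody transmitted the allele
    }
  } else if (model == "AR_HOMOZYGOUS") {
    if (gp != "HOM_ALT") return("FAIL")
    note_parent(gf, function(g) g != "HET")
    note_parent(gm, function(g) g != "HET")
  } else if (model == "IMPRINTING_MATERNAL") {
    if (gp != "HET") return("FAIL")
    note_parent(gf, function(g) !oracle_carrier(g))
    note_parent(gm, function(g) g != "HOM_REF")
  } else if (model == "IMPRINTING_PATERNAL") {
    if (gp != "HET") return("FAIL")
    note_parent(gm, function(g) !oracle_carrier(g))
    note_parent(gf, function(g) g != "HOM_REF")
  } else if (model == "XL_RECESSIVE") {
    if (proband_sex == "MALE") {
      if (gp != "HEMI") return("FAIL")
      note_parent(gm, function(g) !oracle_carrier(g))
      note_parent(gf, function(g) oracle_carrier(g))
    } else {
      if (gp != "HOM_ALT") return("FAIL")
      note_parent(gm, function(g) !oracle_carrier(g))
      note_parent(gf, function(g) !oracle_carrier(g))
    }
  } else if (model == "XL_DOMINANT") {
    expected <- if (proband_sex == "MALE") "HEMI" else "HET"
    if (gp != expected) return("FAIL")
    # trio parents are unaffected here: they must not carry
    note_parent(gf, function(g) oracle_carrier(g))
    note_parent(gm, function(g) oracle_carrier(g))
  } else {
    stop("oracle does not know model ", model)
  }
  if (fail) "FAIL" else if (possible) "PASS_POSSIBLE" else "PASS"
}

# row-wise re-evaluation of the rare/functional filter predicates
oracle_filter_keep <- function(row, config, proband) {
  if (!row$func_class %in% config$include_func_classes) return(FALSE)
  for (db in config$maf_databases) {
    col <- paste0("maf_", db)
    if (col %in% names(row)) {
      m <- row[[col]]
      if (!is.na(m) && m >= config$maf_threshold) return(FALSE)
    }
  }
  if (config$depth_min > 0) {
    d <- row[[paste0("DP_", proband)]]
    if (is.na(d) || d < config$depth_min) return(FALSE)
  }
  if (!is.null(config$rvis_percentile_max) && "rvis_percentile" %in% names(row)) {
    r <- row$rvis_percentile
    if (!is.na(r) && r > config$rvis_percentile_max) return(FALSE)
  }
  if (!is.null(config$regions)) {
    hit <- FALSE
    for (i in seq_len(nrow(config$regions))) {
      rg <- config$regions[i, ]
      if (rg$chrom == row$chrom && rg$start <= row$pos && row$pos < rg$end) {
        hit <- TRUE
        break
      }
    }
    if (!hit) return(FALSE)
  }
  TRUE
}

# breadth-first search over an edge list, by hand
oracle_bfs_within <- function(edges, seeds, order, min_confidence) {
  edges <- edges[edges$confidence >= min_confidence, , drop = FALSE]
  adj <- list()
  add_edge <- function(a, b) adj[[a]] <<- union(adj[[a]] %||% character(), b)
  for (i in seq_len(nrow(edges))) {
    add_edge(edges$gene_a[i], edges$gene_b[i])
    add_edge(edges$gene_b[i], edges$gene_a[i])
  }
  frontier <- intersect(seeds, names(adj))
  seen <- frontier
  out <- character()
  for (step in seq_len(order)) {
    nxt <- setdiff(unique(unlist(adj[frontier])), seen)
    out <- union(out, nxt)
    seen <- union(seen, nxt)
    frontier <- nxt
    if (length(frontier) == 0) break
  }
  sort(setdiff(out, seeds))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# set-algebra oracle for feature search
oracle_feature_search <- function(profiles, query, mode) {
  ids <- sort(unique(profiles$individual_id))
  hit <- vapply(ids, function(id) {
    f <- profiles$feature[profiles$individual_id == id]
    if (mode == "ALL") all(query %in% f) else length(intersect(query, f)) > 0
  }, logical(1))
  ids[hit]
}

# incidence-matrix oracle for cohort recurrence
oracle_cohort <- function(entries, k) {
  inc <- unique(do.call(rbind, lapply(entries, function(e) {
    genes <- toupper(unique(e$rows$gene))
    if (length(genes) == 0) return(NULL)
    data.frame(proband = e$proband_id, gene = genes)
  })))
  counts <- table(inc$gene)
  sort(names(counts)[counts >= k])
}
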