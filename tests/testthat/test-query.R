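# small helper: a result file holding one HET variant per listed gene
result_for <- function(proband, genes, model = "AD_MONOALLELIC") {
  rows <- dplyr::bind_rows(lapply(seq_along(genes), function(i) {
    make_var(chrom = as.character((i %% 22) + 1), pos = i * 100 + 1,
             gene = genes[i], calls = c(P = "HET"))
  }))
  result_file(proband, model, rows)
}

test_that("cohort recurrence counts distinct probands per gene", {
  store <- result_store()
  # gene G planted in the dominant files of probands 1-3 of a 10-family cohort
  for (i in 1:10) {
    genes <- c(if (i <= 3) "G", paste0("PRIV", i))
    store <- store_add(store, result_for(paste0("P", i), genes))
  }
  hit3 <- cohort_recurrence(store, model = "AD_MONOALLELIC", k = 3)
  expect_equal(hit3$gene, "G")
  expect_equal(hit3$probands[[1]], c("P1", "P2", "P3"))
  expect_equal(nrow(cohort_recurrence(store, k = 4)), 0L)
  expect_equal(nrow(cohort_recurrence(store, k = 11)), 0L)  # k beyond cohort
  expect_error(cohort_recurrence(store, k = 1), class = "mm_argument_error")
})

test_that("multiple variants in one gene in one proband count once", {
  store <- result_store()
  rows <- make_vars(make_var(pos = 1, gene = "DUP", calls = c(P = "HET")),
                    make_var(pos = 2, gene = "DUP", calls = c(P = "HET")))
  store <- store_add(store, result_file("P1", "AD_MONOALLELIC", rows))
  store <- store_add(store, result_for("P2", "DUP"))
  out <- cohort_recurrence(store, k = 2)
  expect_equal(out$n_probands, 2L)
})

test_that("random stores agree with incidence-matrix counting", {
  set.seed(31)
  for (rep in 1:10) {
    store <- result_store()
    entries <- list()
    for (i in 1:8) {
      genes <- sample(paste0("G", 1:6), sample(1:4, 1))
      res <- result_for(paste0("P", i), genes)
      store <- store_add(store, res)
      entries[[i]] <- res
    }
    for (k in 2:4) {
      expect_equal(cohort_recurrence(store, k = k)$gene |> sort(),
                   oracle_cohort(entries, k))
    }
  }
})

test_that("oligogenic overlap reports maximal proband groups", {
  store <- result_store()
  store <- store_add(store, result_for("X", c("A", "B", "C")))
  store <- store_add(store, result_for("Y", c("A", "B", "C")))
  store <- store_add(store, result_for("Z", c("D", "E")))
  out2 <- oligogenic_overlap(store, m = 2)
  expect_equal(nrow(out2), 1L)
  expect_equal(out2$probands[[1]], c("X", "Y"))
  expect_equal(out2$genes[[1]], c("A", "B", "C"))
  out3 <- oligogenic_overlap(store, m = 3)
  expect_equal(out3$genes[[1]], c("A", "B", "C"))
  expect_error(oligogenic_overlap(store, m = 1), class = "mm_argument_error")
  # disjoint gene sets: nothing to report
  disjoint <- result_store()
  disjoint <- store_add(disjoint, result_for("U", c("A", "B")))
  disjoint <- store_add(disjoint, result_for("V", c("C", "D")))
  expect_equal(nrow(oligogenic_overlap(disjoint, m = 2)), 0L)
})

test_that("oligogenic groups equal exhaustive subset enumeration", {
  set.seed(59)
  for (rep in 1:5) {
    store <- result_store()
    gene_sets <- list()
    ids <- paste0("P", 1:8)
    for (id in ids) {
      genes <- sample(paste0("G", 1:5), sample(2:4, 1))
      gene_sets[[id]] <- sort(toupper(genes))
      store <- store_add(store, result_for(id, genes))
    }
    got <- oligogenic_overlap(store, m = 2)
    # brute force: all subsets, then keep maximal qualifying ones
    all_groups <- list()
    for (size in 2:8) {
      cmb <- utils::combn(ids, size, simplify = FALSE)
      for (grp in cmb) {
        shared <- Reduce(intersect, gene_sets[grp])
        if (length(shared) >= 2) all_groups[[length(all_groups) + 1]] <- grp
      }
    }
    maximal <- Filter(function(g) {
      !any(vapply(all_groups, function(h) length(h) > length(g) && all(g %in% h),
                  logical(1)))
    }, all_groups)
    expect_equal(nrow(got), length(maximal))
    got_sets <- lapply(got$probands, sort)
    for (g in maximal) {
      expect_true(any(vapply(got_sets, function(s) identical(s, sort(g)),
                             logical(1))),
                  label = paste("group", paste(g, collapse = ",")))
    }
  }
})

test_that("genomic search matches genes, partial loci, and their intersection", {
  store <- result_store()
  rows1 <- make_vars(
    make_var(chrom = "10", pos = 89000, ref = "C", alt = "T", gene = "PTEN",
             calls = c(P = "HET")),
    make_var(chrom = "10", pos = 89000, ref = "C", alt = "G", gene = "PTEN",
             calls = c(P = "HET"))
  )
  store <- store_add(store, result_file("P1", "AD_DENOVO", rows1))
  store <- store_add(store, result_file(
    "P2", "AR_HOMOZYGOUS",
    make_var(chrom = "4", pos = 500, gene = "SPATA5", calls = c(P = "HOM_ALT"))
  ))
  store <- store_add(store, result_file(
    "P3", "AR_HOMOZYGOUS",
    make_var(chrom = "4", pos = 500, gene = "SPATA5", calls = c(P = "HOM_ALT"))
  ))

  by_gene <- genomic_search(store, gene = "pten", model = "AD_DENOVO")
  expect_equal(unique(by_gene$proband_id), "P1")
  expect_equal(nrow(by_gene), 2L)
  # position without alleles returns every alt record there
  by_pos <- genomic_search(store, locus = list(chrom = "chr10", pos = 89000))
  expect_equal(by_pos$alt, c("G", "T"))
  # gene AND locus equals the intersection of the single searches
  both <- genomic_search(store, gene = "PTEN",
                         locus = list(chrom = "10", pos = 89000, ref = "C",
                                      alt = "T"))
  expect_equal(nrow(both), 1L)
  expect_error(genomic_search(store), class = "mm_argument_error")
})

test_that("feature narrowing intersects with phenotype profiles", {
  store <- result_store()
  for (p in c("P2", "P3")) {
    store <- store_add(store, result_file(
      p, "AR_HOMOZYGOUS",
      make_var(chrom = "4", pos = 500, gene = "SPATA5", calls = c(P = "HOM_ALT"))
    ))
  }
  profiles <- tibble::tibble(
    individual_id = c("P2", "P2", "P3"),
    feature = c("microcephaly", "seizures", "tall stature")
  )
  hit <- genomic_search(store, gene = "SPATA5", model = "AR_HOMOZYGOUS",
                        features = "microcephaly", profiles = profiles)
  # independent double filter: gene hit AND feature in profile
  expect_equal(unique(hit$proband_id), "P2")
})

test_that("gene-list filtering is exact set membership", {
  res <- result_for("P1", c("A", "B", "C", "D"))
  same <- filter_by_gene_list(res, c("a", "b", "c", "d"))
  expect_equal(as.data.frame(same$rows), as.data.frame(res$rows))
  none <- filter_by_gene_list(res, c("ZZ"))
  expect_equal(nrow(none$rows), 0L)
  expect_error(filter_by_gene_list(res, character()), class = "mm_argument_error")
  set.seed(8)
  for (rep in 1:10) {
    genes <- sample(c("A", "B", "C", "D", "E", "F"), sample(1:5, 1))
    got <- filter_by_gene_list(res, genes)$rows$gene
    expect_equal(got, res$rows$gene[res$rows$gene %in% toupper(genes)])
  }
})

test_that("interaction neighborhoods follow edge distance", {
  path_graph <- interaction_graph(tibble::tibble(
    gene_a = c("A", "B", "C"), gene_b = c("B", "C", "D"), confidence = 0.9
  ))
  expect_equal(interaction_neighborhood(path_graph, "A", order = 1), "B")
  expect_equal(interaction_neighborhood(path_graph, "A", order = 2), c("B", "C"))
  expect_equal(interaction_neighborhood(path_graph, "A", order = 3),
               c("B", "C", "D"))
  # a seed with no edges has an empty neighborhood
  expect_equal(interaction_neighborhood(path_graph, "LONER", order = 2),
               character())
  expect_error(interaction_neighborhood(path_graph, "A", order = 4),
               class = "mm_argument_error")
  expect_error(interaction_neighborhood(path_graph, character(), order = 1),
               class = "mm_argument_error")
})

test_that("random graphs agree with hand-rolled breadth-first search", {
  set.seed(17)
  for (rep in 1:8) {
    n <- 50
    nodes <- paste0("N", 1:n)
    m <- 120
    edges <- tibble::tibble(
      gene_a = sample(nodes, m, replace = TRUE),
      gene_b = sample(nodes, m, replace = TRUE),
      confidence = round(stats::runif(m), 2)
    )
    edges <- edges[edges$gene_a != edges$gene_b, ]
    graph <- interaction_graph(edges)
    seeds <- sample(nodes, sample(1:3, 1))
    for (ord in 1:3) {
      for (conf in c(0, 0.5)) {
        expect_equal(interaction_neighborhood(graph, seeds, ord, conf),
                     oracle_bfs_within(edges, seeds, ord, conf),
                     label = paste("rep", rep, "order", ord, "conf", conf))
      }
    }
  }
})

test_that("neighborhoods grow with order and shrink with confidence", {
  set.seed(23)
  edges <- tibble::tibble(
    gene_a = sample(paste0("N", 1:30), 60, replace = TRUE),
    gene_b = sample(paste0("N", 1:30), 60, replace = TRUE),
    confidence = stats::runif(60)
  )
  edges <- edges[edges$gene_a != edges$gene_b, ]
  graph <- interaction_graph(edges)
  n1 <- interaction_neighborhood(graph, "N1", 1, 0.2)
  n2 <- interaction_neighborhood(graph, "N1", 2, 0.2)
  n3 <- interaction_neighborhood(graph, "N1", 3, 0.2)
  expect_true(all(n1 %in% n2) && all(n2 %in% n3))
  strict <- interaction_neighborhood(graph, "N1", 2, 0.8)
  expect_true(all(strict %in% n2))
})
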