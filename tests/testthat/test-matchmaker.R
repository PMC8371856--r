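test_that("gene submissions match all prior submitters reciprocally", {
  reg <- mm_registry()
  r1 <- submit_gene(reg, "alice", "ABCD1")
  expect_equal(nrow(r1$matches), 0L)           # first submission: stored, no match
  r2 <- submit_gene(r1$registry, "bob", "abcd1 ")  # case/space-insensitive
  expect_equal(nrow(r2$matches), 1L)
  expect_setequal(unlist(r2$matches[, c("party_a", "party_b")]), c("alice", "bob"))
  r3 <- submit_gene(r2$registry, "carol", "ABCD1")
  expect_equal(nrow(r3$matches), 2L)           # nth submission matches n-1 parties
  log <- tidy(r3$registry)
  expect_equal(nrow(log), 3L)                  # 3 submitters -> 3(3-1)/2 pairs
})

test_that("n submitters of one gene produce n(n-1)/2 logged pairs", {
  for (n in c(2, 5, 8)) {
    reg <- mm_registry()
    last <- NULL
    for (i in seq_len(n)) {
      last <- submit_gene(reg, paste0("S", i), "SHARED")
      reg <- last$registry
    }
    expect_equal(nrow(last$matches), n - 1)
    pairs <- tidy(reg)
    expect_equal(nrow(pairs), n * (n - 1) / 2)
    # every pair names two distinct parties, each pair exactly once
    expect_true(all(pairs$party_a != pairs$party_b))
    key <- apply(cbind(pmin(pairs$party_a, pairs$party_b),
                       pmax(pairs$party_a, pairs$party_b)), 1, paste, collapse = "|")
    expect_equal(anyDuplicated(key), 0L)
  }
})

test_that("submission order does not change the pair set", {
  run <- function(order) {
    reg <- mm_registry()
    for (s in order) reg <- submit_gene(reg, s, "G1")$registry
    pairs <- tidy(reg)
    sort(paste(pmin(pairs$party_a, pairs$party_b),
               pmax(pairs$party_a, pairs$party_b)))
  }
  expect_equal(run(c("A", "B", "C")), run(c("C", "A", "B")))
})

ingest_tbl <- function(chrom = "2", pos = 1234567L, ref = "G", alt = "T",
                       id = "patient1") {
  tibble::tibble(chrom = chrom, pos = pos, ref = ref, alt = alt,
                 individual_id = id, func_class = "MISSENSE",
                 maf_gnomad = 0.0001)
}

test_that("variant queries match exactly and attach phenotypes when supplied", {
  reg <- mm_registry()
  profiles <- tibble::tibble(individual_id = "patient1",
                             feature = c("seizures", "ataxia"))
  reg <- vm_ingest(reg, ingest_tbl(), profiles)$registry
  q <- parse_variant_query("chr2:1234567G > T", build = "hg19",
                           features = c("seizures", "ataxia", "nystagmus"))
  res <- query_variant(reg, q, "alice", day = "d1")
  expect_s3_class(res$record, "mm_match")
  expect_equal(res$record$matched$individual_id, "patient1")
  expect_true(res$record$phenotype_shared)
  expect_equal(res$record$matched$features[[1]], c("seizures", "ataxia"))
  # without query features the payload is withheld
  res2 <- query_variant(reg, parse_variant_query("2:1234567G>T"), "bob", "d1")
  expect_false(res2$record$phenotype_shared)
  expect_equal(res2$record$matched$features[[1]], character())
  # different alt allele: no match, stored instead
  res3 <- query_variant(reg, parse_variant_query("2:1234567G>C"), "bob", "d1")
  expect_s3_class(res3$record, "mm_stored_receipt")
})

test_that("the daily quota is enforced per submitter per day token", {
  reg <- mm_registry()
  for (i in 1:10) {
    res <- query_variant(reg, parse_variant_query(paste0("1:", i, "A>G")),
                         "alice", day = "d1")
    reg <- res$registry
  }
  expect_error(query_variant(reg, parse_variant_query("1:999A>G"), "alice", "d1"),
               class = "mm_quota_error")
  # other submitters and other days are unaffected
  expect_no_error(query_variant(reg, parse_variant_query("1:999A>G"), "bob", "d1"))
  expect_no_error(query_variant(reg, parse_variant_query("1:999A>G"), "alice", "d2"))
})

test_that("quota holds under interleaved submitters", {
  reg <- mm_registry()
  set.seed(9)
  accepted <- c(alice = 0L, bob = 0L)
  for (i in 1:30) {
    who <- sample(c("alice", "bob"), 1)
    res <- tryCatch(
      query_variant(reg, parse_variant_query(paste0("1:", i, "A>G")), who, "d1"),
      mm_quota_error = function(e) NULL
    )
    if (!is.null(res)) {
      reg <- res$registry
      accepted[who] <- accepted[who] + 1L
    }
  }
  expect_true(all(accepted <= 10L))
})

test_that("stored queries replay when matching variants arrive later", {
  reg <- mm_registry()
  res <- query_variant(reg, parse_variant_query("2:1234567G>T"), "alice", "d1")
  expect_s3_class(res$record, "mm_stored_receipt")
  reg <- res$registry
  expect_equal(nrow(reg$stored_queries), 1L)
  later <- vm_ingest(reg, ingest_tbl())
  expect_length(later$matches, 1L)
  expect_equal(later$matches[[1]]$submitter_id, "alice")
  expect_equal(nrow(later$registry$stored_queries), 0L)

  # store-then-ingest equals ingest-then-query in the final match log
  reg_a <- query_variant(mm_registry(), parse_variant_query("2:1234567G>T"),
                         "alice", "d1")$registry
  reg_a <- vm_ingest(reg_a, ingest_tbl())$registry
  reg_b <- vm_ingest(mm_registry(), ingest_tbl())$registry
  reg_b <- query_variant(reg_b, parse_variant_query("2:1234567G>T"),
                         "alice", "d1")$registry
  cols <- c("kind", "key", "party_a", "party_b")
  expect_equal(tidy(reg_a)[cols], tidy(reg_b)[cols])
})

test_that("the ingest rule keeps rare coding non-synonymous SNVs only", {
  reg <- mm_registry()
  v <- dplyr::bind_rows(
    ingest_tbl(pos = 1L),
    dplyr::mutate(ingest_tbl(pos = 2L), func_class = "SYNONYMOUS"),
    dplyr::mutate(ingest_tbl(pos = 3L), maf_gnomad = 0.05),
    dplyr::mutate(ingest_tbl(pos = 4L), ref = "GA")  # indel
  )
  reg <- vm_ingest(reg, v)$registry
  expect_equal(reg$variant_db$pos, 1L)
})

test_that("liftover maps through registered tables and errors when unmappable", {
  reg <- mm_registry(build = "hg19")
  loc <- locus("2", 1000, "G", "T")
  expect_equal(liftover_hook(reg, loc, "hg19", "hg19"), loc)  # identity
  map <- tibble::tibble(chrom = "2", pos = 1000, new_chrom = "2", new_pos = 1100)
  reg <- register_liftover(reg, "hg38", "hg19", map)
  lifted <- liftover_hook(reg, loc, "hg38", "hg19")
  expect_equal(lifted$pos, 1100L)
  expect_error(liftover_hook(reg, locus("2", 55, "G", "T"), "hg38", "hg19"),
               class = "mm_liftover_error")
  expect_error(liftover_hook(reg, loc, "hg18", "hg19"),
               class = "mm_liftover_error")
  # round trip through the inverse table is the identity
  reg <- register_liftover(reg, "hg19", "hg38",
                           tibble::tibble(chrom = "2", pos = 1100,
                                          new_chrom = "2", new_pos = 1000))
  back <- liftover_hook(reg, lifted, "hg19", "hg38")
  expect_equal(back, loc)
  # queries on another build are lifted before matching
  reg <- vm_ingest(reg, ingest_tbl(pos = 1100L))$registry
  hit <- query_variant(reg, parse_variant_query("2:1000G>T", build = "hg38"),
                       "alice", "d1")
  expect_s3_class(hit$record, "mm_match")
})

test_that("candidate export filters known disease genes and caps at ten", {
  fr <- tibble::tibble(gene = paste0("G", 1:12), chrom = "1",
                       pos = 1:12, ref = "A", alt = "G")
  out <- export_candidates_for_matching(fr, known_disease_genes = c("G2", "G5", "G9"))
  expect_equal(nrow(out), 9L)
  expect_false(any(c("G2", "G5", "G9") %in% out$gene))

  many <- tibble::tibble(gene = paste0("N", 1:15))
  capped <- export_candidates_for_matching(many, character())
  expect_equal(capped$gene, paste0("N", 1:10))  # first ten in row order

  set.seed(33)
  for (rep in 1:10) {
    genes <- paste0("R", sample(1:30, 20))
    known <- paste0("R", sample(1:30, 8))
    got <- export_candidates_for_matching(tibble::tibble(gene = genes), known)$gene
    want <- head(unique(genes)[!unique(genes) %in% known], 10)
    expect_equal(got, want)
  }
})

test_that("registries persist to line-delimited records and back", {
  reg <- mm_registry()
  reg <- submit_gene(reg, "alice", "ABCD1", features = c("seizures"))$registry
  reg <- submit_gene(reg, "bob", "ABCD1")$registry
  reg <- vm_ingest(reg, ingest_tbl(),
                   tibble::tibble(individual_id = "patient1",
                                  feature = "ataxia"))$registry
  reg <- query_variant(reg, parse_variant_query("9:77A>C"), "carol", "d1")$registry
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_registry(reg, path)
  back <- read_registry(path)
  expect_equal(glance(back), glance(reg))
  expect_equal(as.data.frame(tidy(back)), as.data.frame(tidy(reg)))
  expect_equal(back$stored_queries$pos, reg$stored_queries$pos)
  # identical operation sequences yield identical persisted registries
  path2 <- withr::local_tempfile(fileext = ".jsonl")
  write_registry(reg, path2)
  expect_identical(readLines(path), readLines(path2))
})
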