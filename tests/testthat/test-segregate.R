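trio <- make_trio_ped()

trio_var <- function(gp, gf, gm, chrom = "1", pos = 100, gene = "G1") {
  make_var(chrom = chrom, pos = pos, gene = gene,
           calls = c(P = gp, D = gf, M = gm))
}

test_that("textbook trio verdicts come out as expected", {
  # de novo: child het, parents reference
  expect_equal(status_of(trio_var("HET", "HOM_REF", "HOM_REF"), trio, "AD_DENOVO"),
               "PASS")
  # an unaffected carrier father defeats de novo, naming him
  v <- segregate_one(trio_var("HET", "HET", "HOM_REF"), trio, "AD_DENOVO")
  expect_equal(v$status, "FAIL")
  expect_match(v$reason, "father")
  # recessive homozygote with carrier parents
  expect_equal(status_of(trio_var("HOM_ALT", "HET", "HET"), trio, "AR_HOMOZYGOUS"),
               "PASS")
  # dominant inherited needs an affected transmitting parent
  aff_trio <- make_trio_ped(father_affected = TRUE)
  expect_equal(status_of(trio_var("HET", "HET", "HOM_REF"), aff_trio, "AD_INHERITED"),
               "PASS")
  expect_equal(status_of(trio_var("HET", "HOM_REF", "HOM_REF"), trio, "AD_INHERITED"),
               "FAIL")
  # imprinting: pathogenic allele from the non-silenced parent
  expect_equal(status_of(trio_var("HET", "HET", "HOM_REF"), trio,
                         "IMPRINTING_MATERNAL"), "PASS")
  expect_equal(status_of(trio_var("HET", "HOM_REF", "HET"), trio,
                         "IMPRINTING_PATERNAL"), "PASS")
})

test_that("X-linked models require X data and respect hemizygosity", {
  male_trio <- make_trio_ped(proband_sex = "MALE")
  xv <- trio_var("HEMI", "HOM_REF", "HET", chrom = "X")
  expect_equal(status_of(xv, male_trio, "XL_RECESSIVE"), "PASS")
  # carrier father defeats X-linked recessive for a male proband
  expect_equal(status_of(trio_var("HEMI", "HEMI", "HET", chrom = "X"),
                         male_trio, "XL_RECESSIVE"), "FAIL")
  # female het with non-carrier parents passes X-linked dominant (de novo)
  expect_equal(status_of(trio_var("HET", "HOM_REF", "HOM_REF", chrom = "X"),
                         trio, "XL_DOMINANT"), "PASS")
  # autosomal data only: empty verdicts plus a warning
  expect_warning(out <- segregate(trio_var("HET", "HOM_REF", "HOM_REF"),
                                  trio, "XL_RECESSIVE"),
                 "X-chromosome")
  expect_equal(nrow(out), 0L)
})

test_that("autosomal models do not evaluate X variants", {
  xv <- trio_var("HET", "HOM_REF", "HOM_REF", chrom = "X")
  for (m in c("AD_DENOVO", "AD_INHERITED", "AR_HOMOZYGOUS",
              "IMPRINTING_MATERNAL", "IMPRINTING_PATERNAL")) {
    expect_equal(status_of(xv, trio, m), "FAIL", label = m)
  }
})

test_that("every trio genotype combination matches the brute-force evaluator", {
  gts <- c("HOM_REF", "HET", "HOM_ALT", "MISSING")
  autosomal <- c("AD_DENOVO", "AD_INHERITED", "AR_HOMOZYGOUS",
                 "IMPRINTING_MATERNAL", "IMPRINTING_PATERNAL")
  combos <- expand.grid(gp = gts, gf = gts, gm = gts, stringsAsFactors = FALSE)
  for (model in autosomal) {
    for (i in seq_len(nrow(combos))) {
      got <- status_of(trio_var(combos$gp[i], combos$gf[i], combos$gm[i]),
                       trio, model)
      want <- oracle_trio_verdict(model, combos$gp[i], combos$gf[i], combos$gm[i])
      expect_equal(got, want,
                   label = paste(model, combos$gp[i], combos$gf[i], combos$gm[i]))
    }
  }
  # X models: male and female probands with hemizygous male calls
  male_trio <- make_trio_ped(proband_sex = "MALE")
  x_combos <- expand.grid(gf = c("HOM_REF", "HEMI", "MISSING"),
                          gm = gts, stringsAsFactors = FALSE)
  for (model in c("XL_RECESSIVE", "XL_DOMINANT")) {
    for (gp in c("HOM_REF", "HEMI", "MISSING")) {
      for (i in seq_len(nrow(x_combos))) {
        v <- trio_var(gp, x_combos$gf[i], x_combos$gm[i], chrom = "X")
        expect_equal(status_of(v, male_trio, model),
                     oracle_trio_verdict(model, gp, x_combos$gf[i], x_combos$gm[i],
                                         proband_sex = "MALE"),
                     label = paste(model, "male", gp, x_combos$gf[i], x_combos$gm[i]))
      }
    }
    for (gp in gts) {
      for (i in seq_len(nrow(x_combos))) {
        v <- trio_var(gp, x_combos$gf[i], x_combos$gm[i], chrom = "X")
        expect_equal(status_of(v, trio, model),
                     oracle_trio_verdict(model, gp, x_combos$gf[i], x_combos$gm[i],
                                         proband_sex = "FEMALE"),
                     label = paste(model, "female", gp, x_combos$gf[i], x_combos$gm[i]))
      }
    }
  }
})

test_that("compound heterozygotes pair across parental origins", {
  vars <- make_vars(
    trio_var("HET", "HOM_REF", "HET", pos = 100),  # from mother
    trio_var("HET", "HET", "HOM_REF", pos = 200)   # from father
  )
  out <- segregate(vars, trio, "AR_COMPOUND_HET")
  expect_equal(out$status, c("PASS", "PASS"))
  expect_equal(out$partners[[1]], locus_key(vars[2, ]))
  expect_equal(out$partners[[2]], locus_key(vars[1, ]))
})

test_that("same-origin and carrier-vetoed pairs fail", {
  both_mother <- make_vars(
    trio_var("HET", "HOM_REF", "HET", pos = 100),
    trio_var("HET", "HOM_REF", "HET", pos = 200)
  )
  expect_equal(segregate(both_mother, trio, "AR_COMPOUND_HET")$status,
               c("FAIL", "FAIL"))
  # unaffected mother carries both members of the pair
  veto <- make_vars(
    trio_var("HET", "HET", "HET", pos = 100),
    trio_var("HET", "HET", "HET", pos = 200)
  )
  expect_equal(segregate(veto, trio, "AR_COMPOUND_HET")$status, c("FAIL", "FAIL"))
  # a single heterozygote has no partner
  lone <- trio_var("HET", "HOM_REF", "HET", pos = 100)
  expect_equal(segregate(lone, trio, "AR_COMPOUND_HET")$status, "FAIL")
})

test_that("partner links are always mutual", {
  set.seed(12)
  gts <- c("HOM_REF", "HET", "HOM_ALT", "MISSING")
  for (rep in 1:25) {
    n <- sample(2:5, 1)
    vars <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
      trio_var(sample(c("HET", "HOM_REF"), 1), sample(gts, 1), sample(gts, 1),
               pos = i * 10, gene = sample(c("GA", "GB"), 1))
    }))
    out <- segregate(vars, trio, "AR_COMPOUND_HET")
    keys <- locus_key(out)
    for (i in seq_len(nrow(out))) {
      for (p in out$partners[[i]]) {
        j <- match(p, keys)
        expect_true(keys[i] %in% out$partners[[j]],
                    label = paste("mutual partner", keys[i], "<->", p))
      }
    }
  }
})

test_that("missing relatives downgrade to PASS_POSSIBLE, never PASS", {
  singleton <- make_singleton_ped()
  v <- make_var(calls = c(P = "HET"))
  expect_equal(status_of(v, singleton, "AD_DENOVO"), "PASS_POSSIBLE")
  expect_equal(status_of(v, singleton, "AD_INHERITED"), "PASS_POSSIBLE")
  hom <- make_var(calls = c(P = "HOM_ALT"))
  expect_equal(status_of(hom, singleton, "AR_HOMOZYGOUS"), "PASS_POSSIBLE")
  # unphased compound het in a singleton
  pair <- make_vars(make_var(pos = 1, calls = c(P = "HET")),
                    make_var(pos = 2, calls = c(P = "HET")))
  expect_equal(segregate(pair, singleton, "AR_COMPOUND_HET")$status,
               c("PASS_POSSIBLE", "PASS_POSSIBLE"))
  # one missing parent in a trio
  expect_equal(status_of(trio_var("HET", "MISSING", "HOM_REF"), trio, "AD_DENOVO"),
               "PASS_POSSIBLE")
})

test_that("no genotyped unaffected member carries the full causal genotype of a PASS", {
  set.seed(77)
  gts <- c("HOM_REF", "HET", "HOM_ALT", "MISSING")
  quartet <- pedigree(tibble::tibble(
    id = c("P", "D", "M", "S"),
    sex = c("FEMALE", "MALE", "FEMALE", "FEMALE"),
    affected = c("AFFECTED", "UNAFFECTED", "UNAFFECTED", "UNAFFECTED"),
    father_id = c("D", NA, NA, "D"),
    mother_id = c("M", NA, NA, "M"),
    proband = c(TRUE, FALSE, FALSE, FALSE)
  ))
  causal <- c(AD_DENOVO = "HET", AD_INHERITED = "HET", AR_HOMOZYGOUS = "HOM_ALT")
  for (rep in 1:200) {
    g <- sample(gts, 4, replace = TRUE)
    v <- make_var(calls = c(P = g[1], D = g[2], M = g[3], S = g[4]))
    for (model in names(causal)) {
      out <- segregate_one(v, quartet, model)
      if (out$status == "PASS") {
        for (m in c("D", "M", "S")) {
          expect_false(v[[paste0("GT_", m)]] == causal[[model]],
                       label = paste(model, "unaffected", m, "with causal genotype"))
        }
      }
    }
  }
})

test_that("the automated run splits dominant sub-verdicts and recovers plants", {
  fam <- generate_family(fixture_spec(seed = 21, n_decoys = 60), 1)
  res <- run_automated_analyses(fam$variants, fam$pedigree)
  man <- fam$manifest
  ad <- res$AD_MONOALLELIC$rows
  expect_equal(locus_key(ad), locus_key(man[man$model == "AD_DENOVO", ]))
  expect_equal(ad$ad_subtype, "DENOVO")
  hom <- res$AR_HOMOZYGOUS$rows
  expect_equal(locus_key(hom), locus_key(man[man$model == "AR_HOMOZYGOUS", ]))
  chet <- res$AR_COMPOUND_HET$rows
  expect_setequal(locus_key(chet), locus_key(man[man$model == "AR_COMPOUND_HET", ]))
  expect_match(res$AD_MONOALLELIC$provenance$config, "maf<0.01", fixed = TRUE)
})
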