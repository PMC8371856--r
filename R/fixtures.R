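#' Specify a synthetic fixture set
#'
#' Describes a deterministic synthetic study: families with a chosen
#' structure, decoy variants drawn from a population-frequency mixture with
#' Hardy-Weinberg parental genotypes and Mendelian transmission, planted
#' variants constructed to satisfy exactly one inheritance model each, and
#' phenotype profiles/disease tables for the matching operations. The same
#' spec and seed always reproduce byte-identical fixtures.
#'
#' @param seed Integer seed; every random draw derives from it.
#' @param n_families Number of families.
#' @param family_structure `"trio"`, `"quartet"` (trio plus an unaffected
#'   sibling) or `"singleton"`.
#' @param n_decoys Decoy variants per family; each decoy gets its own gene
#'   and is constructed to violate every model predicate.
#' @param planted Data frame with columns `model` (an inheritance model)
#'   and optionally `gene`; one plant per row per family.
#'   `AR_COMPOUND_HET` plants two variants in one gene. `NULL` plants
#'   nothing (decoys only).
#' @param maf_mix Named numeric mixture over decoy frequency classes:
#'   `common` (uniform on `[0.01, 0.5]`), `rare` (uniform on `[0, 0.01)`)
#'   and `absent` (not observed in any database). Must sum to 1.
#' @param feature_vocab_size Size of the controlled feature vocabulary.
#' @param n_diseases Number of diseases in the synthetic knowledge table.
#' @param mean_features Mean features per affected individual (Poisson,
#'   truncated at >= 1); default 6.8.
#' @return An `mm_fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_families = 1L,
                         family_structure = c("trio", "quartet", "singleton"),
                         n_decoys = 100L,
                         planted = tibble(model = c("AD_DENOVO", "AR_HOMOZYGOUS",
                                                    "AR_COMPOUND_HET")),
                         maf_mix = c(common = 0.3, rare = 0.4, absent = 0.3),
                         feature_vocab_size = 300L, n_diseases = 100L,
                         mean_features = 6.8) {
  family_structure <- match.arg(family_structure)
  if (!is.null(planted)) {
    planted <- as_tibble(planted)
    if (!"gene" %in% names(planted)) planted$gene <- NA_character_
    bad <- setdiff(planted$model, inheritance_models())
    if (length(bad) > 0) {
      abort(paste0("Unknown model(s) in plants: ", paste(bad, collapse = ", ")),
            class = "mm_spec_error")
    }
    if (family_structure == "singleton" && nrow(planted) > 0) {
      abort("Plants require parental genotypes; none can be planted in a singleton.",
            class = "mm_spec_error")
    }
  } else {
    planted <- tibble(model = character(), gene = character())
  }
  if (abs(sum(maf_mix) - 1) > 1e-8 || !all(c("common", "rare", "absent") %in% names(maf_mix))) {
    abort("maf_mix must name common/rare/absent fractions summing to 1.",
          class = "mm_spec_error")
  }
  structure(
    list(seed = as.integer(seed), n_families = as.integer(n_families),
         family_structure = family_structure, n_decoys = as.integer(n_decoys),
         planted = planted, maf_mix = maf_mix,
         feature_vocab_size = as.integer(feature_vocab_size),
         n_diseases = as.integer(n_diseases), mean_features = mean_features),
    class = "mm_fixture_spec"
  )
}

# run code under a derived seed without disturbing the caller's RNG stream
with_derived_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

family_seed <- function(spec, family_index) {
  (abs(spec$seed) %% 100000L) * 20011L + family_index * 7919L
}

MAF_DBS <- c("1000g", "evs", "exac", "gnomad")

# would this autosomal trio genotype pattern satisfy any model predicate?
decoy_pattern_unsafe <- function(gp, gf, gm) {
  car <- function(g) g %in% c("HET", "HOM_ALT")
  if (gp == "HET" && (gf == "HOM_REF" || gm == "HOM_REF")) return(TRUE)
  if (gp == "HOM_ALT" && gf == "HET" && gm == "HET") return(TRUE)
  FALSE
}

hw_genotype <- function(maf) {
  p <- maf
  sample(c("HOM_REF", "HET", "HOM_ALT"), 1,
         prob = c((1 - p)^2, 2 * p * (1 - p), p^2))
}

transmit <- function(gf, gm) {
  pick <- function(g) switch(g, HOM_REF = 0L, HOM_ALT = 1L,
                             HET = sample(0:1, 1), MISSING = 0L)
  n <- pick(gf) + pick(gm)
  c("HOM_REF", "HET", "HOM_ALT")[n + 1L]
}

rand_alleles <- function() sample(c("A", "C", "G", "T"), 2)

# models whose genotype predicate a plant satisfies; a paternally inherited
# heterozygous plant additionally satisfies AD_INHERITED when the father is
# affected (he is then a legitimate transmitting parent)
plant_expected_models <- function(model, which_of_pair = NA,
                                  father_affected = FALSE) {
  switch(model,
    AD_DENOVO = "AD_DENOVO",
    AD_INHERITED = c("AD_INHERITED", "IMPRINTING_MATERNAL"),
    AR_HOMOZYGOUS = "AR_HOMOZYGOUS",
    AR_COMPOUND_HET = if (identical(which_of_pair, 1L)) {
      c("AR_COMPOUND_HET", "IMPRINTING_PATERNAL")  # maternally inherited half
    } else {
      c("AR_COMPOUND_HET", "IMPRINTING_MATERNAL",  # paternally inherited half
        if (father_affected) "AD_INHERITED")
    },
    XL_RECESSIVE = "XL_RECESSIVE",
    XL_DOMINANT = "XL_DOMINANT",
    IMPRINTING_MATERNAL = c("IMPRINTING_MATERNAL",
                            if (father_affected) "AD_INHERITED"),
    IMPRINTING_PATERNAL = "IMPRINTING_PATERNAL"
  )
}

#' Generate one synthetic family
#'
#' Builds the pedigree, the annotated genotype table (decoys plus plants)
#' and the ground-truth manifest for one family. Decoy parental genotypes
#' follow Hardy-Weinberg proportions at the decoy's frequency with
#' Mendelian transmission to the children, then any draw that would
#' satisfy a model predicate is redrawn, so decoys violate every model by
#' construction. Planted variants satisfy their model's predicate exactly;
#' the manifest records each plant with the full set of models whose
#' genotype predicate it satisfies (predicates overlap on genotypes: an
#' inherited dominant variant is also consistent with an imprinting
#' model).
#'
#' @param spec An [fixture_spec()].
#' @param family_index Family number (1-based); determines ids and the
#'   derived seed.
#' @return List with `pedigree`, `variants` (annotation tibble with
#'   genotype columns) and `manifest` (tibble: gene, locus, planted model,
#'   `expected_models` semicolon-joined, `partner` locus key for compound
#'   heterozygotes).
#' @export
generate_family <- function(spec, family_index = 1L) {
  with_derived_seed(family_seed(spec, family_index), {
    fam <- paste0("F", family_index)
    pid <- paste0(fam, "_P")
    fid <- paste0(fam, "_D")  # dad
    mid <- paste0(fam, "_M")  # mum
    sid <- paste0(fam, "_S")  # sibling (quartet)
    models <- spec$planted$model
    proband_sex <- if ("XL_RECESSIVE" %in% models) "MALE" else "FEMALE"
    father_affected <- "AD_INHERITED" %in% models

    members <- tibble(
      id = pid, sex = proband_sex, affected = "AFFECTED",
      father_id = if (spec$family_structure == "singleton") NA_character_ else fid,
      mother_id = if (spec$family_structure == "singleton") NA_character_ else mid,
      proband = TRUE
    )
    if (spec$family_structure != "singleton") {
      members <- dplyr::bind_rows(
        members,
        tibble(id = fid, sex = "MALE",
               affected = if (father_affected) "AFFECTED" else "UNAFFECTED",
               father_id = NA_character_, mother_id = NA_character_, proband = FALSE),
        tibble(id = mid, sex = "FEMALE", affected = "UNAFFECTED",
               father_id = NA_character_, mother_id = NA_character_, proband = FALSE)
      )
    }
    if (spec$family_structure == "quartet") {
      members <- dplyr::bind_rows(
        members,
        tibble(id = sid, sex = "MALE", affected = "UNAFFECTED",
               father_id = fid, mother_id = mid, proband = FALSE)
      )
    }
    ped <- pedigree(members)
    has_parents <- spec$family_structure != "singleton"
    has_sib <- spec$family_structure == "quartet"

    used_pos <- new.env()
    draw_locus <- function(chrom) {
      repeat {
        pos <- sample.int(2e8L, 1)
        key <- paste(chrom, pos)
        if (is.null(used_pos[[key]])) {
          used_pos[[key]] <- TRUE
          return(pos)
        }
      }
    }

    rows <- list()
    manifest <- list()
    add_row <- function(chrom, pos, ref, alt, gene, func_class, mafs,
                        gt, dp, rvis) {
      r <- tibble(chrom = chrom, pos = pos, ref = ref, alt = alt,
                  gene = gene, func_class = func_class)
      for (db in MAF_DBS) r[[paste0("maf_", db)]] <- mafs[[db]]
      r$rvis_percentile <- rvis
      r$splice_region <- FALSE
      for (id in ped$id) {
        r[[paste0("GT_", id)]] <- gt[[id]]
        r[[paste0("DP_", id)]] <- dp[[id]]
      }
      rows[[length(rows) + 1L]] <<- r
    }
    rand_dp <- function() stats::setNames(
      as.list(sample(20:60, nrow(ped), replace = TRUE)), ped$id)
    no_maf <- stats::setNames(as.list(rep(NA_real_, length(MAF_DBS))), MAF_DBS)

    # ---- plants ----------------------------------------------------------
    plant_rows <- spec$planted
    for (i in seq_len(nrow(plant_rows))) {
      model <- plant_rows$model[i]
      gene <- plant_rows$gene[i]
      if (is.na(gene)) gene <- paste0("GENE_", model, "_", family_index)
      chrom <- if (model_scope(model) == "X") "X" else as.character(sample(1:22, 1))
      n_var <- if (model == "AR_COMPOUND_HET") 2L else 1L
      pair_keys <- character(n_var)
      for (k in seq_len(n_var)) {
        pos <- draw_locus(chrom)
        al <- rand_alleles()
        gt <- stats::setNames(as.list(rep("HOM_REF", nrow(ped))), ped$id)
        gt[[pid]] <- switch(model,
          AD_DENOVO = "HET", AD_INHERITED = "HET",
          AR_HOMOZYGOUS = "HOM_ALT", AR_COMPOUND_HET = "HET",
          XL_RECESSIVE = if (proband_sex == "MALE") "HEMI" else "HOM_ALT",
          XL_DOMINANT = if (proband_sex == "MALE") "HEMI" else "HET",
          IMPRINTING_MATERNAL = "HET", IMPRINTING_PATERNAL = "HET")
        if (has_parents) {
          if (model == "AD_INHERITED") gt[[fid]] <- "HET"
          if (model == "AR_HOMOZYGOUS") { gt[[fid]] <- "HET"; gt[[mid]] <- "HET" }
          if (model == "AR_COMPOUND_HET") {
            if (k == 1L) gt[[mid]] <- "HET" else gt[[fid]] <- "HET"
          }
          if (model == "XL_RECESSIVE") {
            gt[[mid]] <- "HET"
            if (proband_sex == "FEMALE") gt[[fid]] <- "HEMI"
          }
          if (model == "XL_DOMINANT" && father_affected) gt[[fid]] <- "HEMI"
          if (model == "IMPRINTING_MATERNAL") gt[[fid]] <- "HET"
          if (model == "IMPRINTING_PATERNAL") gt[[mid]] <- "HET"
        }
        if (has_sib) {
          gt[[sid]] <- if (model == "AR_HOMOZYGOUS") "HET" else "HOM_REF"
        }
        mafs <- no_maf
        mafs[["gnomad"]] <- round(stats::runif(1, 0, 0.005), 6)  # rare, observed
        add_row(chrom, pos, al[1], al[2], gene, "MISSENSE", mafs, gt,
                rand_dp(), sample(10:90, 1))
        pair_keys[k] <- paste0(chrom, ":", pos, " ", al[1], ">", al[2])
        manifest[[length(manifest) + 1L]] <- tibble(
          family = fam, proband_id = pid, gene = gene, chrom = chrom, pos = pos,
          ref = al[1], alt = al[2], model = model,
          expected_models = paste(plant_expected_models(model, k, father_affected),
                                  collapse = ";"),
          partner = NA_character_
        )
      }
      if (n_var == 2L) {
        n <- length(manifest)
        manifest[[n - 1L]]$partner <- pair_keys[2]
        manifest[[n]]$partner <- pair_keys[1]
      }
    }

    # ---- decoys ----------------------------------------------------------
    classes <- sample(names(spec$maf_mix), spec$n_decoys, replace = TRUE,
                      prob = spec$maf_mix)
    for (i in seq_len(spec$n_decoys)) {
      chrom <- as.character(sample(1:22, 1))
      pos <- draw_locus(chrom)
      al <- rand_alleles()
      # frequencies kept at reporting precision so tables round-trip exactly
      maf <- switch(classes[i],
        common = round(stats::runif(1, 0.01, 0.5), 6),
        rare = round(stats::runif(1, 0, 0.00999), 6),
        absent = NA_real_)
      mafs <- no_maf
      if (!is.na(maf)) {
        for (db in sample(MAF_DBS, sample(2:4, 1))) mafs[[db]] <- maf
      }
      func <- if (i %% 7 == 0) "SYNONYMOUS" else
        sample(c("MISSENSE", "NONSENSE", "FRAMESHIFT_INDEL", "SPLICE_SITE"), 1)
      hw_maf <- if (is.na(maf)) 0.005 else maf
      repeat {
        gf <- hw_genotype(hw_maf); gm <- hw_genotype(hw_maf)
        gp <- if (has_parents) transmit(gf, gm) else hw_genotype(hw_maf)
        filtered_out <- classes[i] == "common" || func == "SYNONYMOUS"
        if (filtered_out || !has_parents || !decoy_pattern_unsafe(gp, gf, gm)) break
      }
      gt <- stats::setNames(as.list(rep("HOM_REF", nrow(ped))), ped$id)
      gt[[pid]] <- gp
      if (has_parents) { gt[[fid]] <- gf; gt[[mid]] <- gm }
      if (has_sib) gt[[sid]] <- transmit(gf, gm)
      add_row(chrom, pos, al[1], al[2],
              paste0("DECOY", family_index, "_", i), func, mafs, gt,
              rand_dp(), sample(10:90, 1))
    }

    variants <- sort_variants(dplyr::bind_rows(rows))
    manifest <- if (length(manifest)) dplyr::bind_rows(manifest) else
      tibble(family = character(), proband_id = character(), gene = character(),
             chrom = character(), pos = integer(), ref = character(),
             alt = character(), model = character(), expected_models = character(),
             partner = character())
    list(pedigree = ped, variants = variants, manifest = manifest)
  })
}

gt_to_vcf <- function(gt, male_x) {
  if (male_x) {
    switch(gt, HEMI = "1", HOM_REF = "0", MISSING = ".", "0")
  } else {
    switch(gt, HOM_REF = "0/0", HET = "0/1", HOM_ALT = "1/1",
           HEMI = "1", MISSING = "./.")
  }
}

#' Write a generated family as VCF, PED and annotation TSV
#'
#' @param fam Output of [generate_family()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix, default the family id from the manifest
#'   or `"family"`.
#' @return Named character vector of the written paths.
#' @export
write_family_fixture <- function(fam, dir, prefix = NULL) {
  if (is.null(prefix)) {
    prefix <- if (nrow(fam$manifest) > 0) fam$manifest$family[1] else "family"
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ped_path <- file.path(dir, paste0(prefix, ".ped"))
  vcf_path <- file.path(dir, paste0(prefix, ".vcf"))
  annot_path <- file.path(dir, paste0(prefix, ".annot.tsv"))
  write_pedigree(fam$pedigree, ped_path, family = prefix)
  write_annotation_table(fam$variants, annot_path)

  ped <- fam$pedigree
  v <- sort_variants(fam$variants)
  male <- stats::setNames(ped$sex == "MALE", ped$id)
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ped$id), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(v)), function(i) {
    calls <- vapply(ped$id, function(id) {
      g <- gt_to_vcf(v[[paste0("GT_", id)]][i],
                     male[[id]] && v$chrom[i] %in% c("X", "Y"))
      paste0(g, ":", v[[paste0("DP_", id)]][i])
    }, character(1))
    paste(c(v$chrom[i], v$pos[i], ".", v$ref[i], v$alt[i], ".", "PASS", ".",
            "GT:DP", calls), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), vcf_path)
  c(ped = ped_path, vcf = vcf_path, annot = annot_path)
}

#' Generate synthetic phenotype profiles and a disease knowledge table
#'
#' Profiles are drawn from the controlled vocabulary with sizes from a
#' Poisson distribution (mean `spec$mean_features`, truncated at >= 1).
#' Designated profile pairs are constructed with an exact overlap
#' coefficient of 0.8 (two size-5 profiles sharing 4 features) and
#' recorded in the manifest, as are the gene-feature links of each
#' synthetic disease.
#'
#' @param spec An [fixture_spec()].
#' @param n_individuals Number of profiled individuals (default
#'   `spec$n_families`, one proband per family, ids `F<i>_P`).
#' @param n_exact_pairs Number of extra profile pairs built with exact
#'   coefficient 0.8 (ids `PAIR<i>a`/`PAIR<i>b`).
#' @return List with `profiles` (tidy tibble), `knowledge`
#'   (`mm_knowledge`) and `manifest` (list with `pairs` and
#'   `disease_genes` tibbles).
#' @export
generate_phenotypes <- function(spec, n_individuals = spec$n_families,
                                n_exact_pairs = 2L) {
  with_derived_seed(family_seed(spec, 0L) + 17L, {
    vocab <- sprintf("feat%04d", seq_len(spec$feature_vocab_size))
    draw_size <- function(n) pmax(1L, stats::rpois(n, spec$mean_features))
    ids <- paste0("F", seq_len(n_individuals), "_P")
    profiles <- purrr::map2(ids, draw_size(n_individuals), function(id, k) {
      tibble(individual_id = id,
             feature = sample(vocab, min(k, length(vocab))))
    })
    pairs <- list()
    for (i in seq_len(n_exact_pairs)) {
      base <- sample(vocab, 6)
      a <- base[1:5]
      b <- c(base[1:4], base[6])  # |A&B| = 4, min size 5 -> coefficient 0.8
      ida <- paste0("PAIR", i, "a"); idb <- paste0("PAIR", i, "b")
      profiles <- c(profiles, list(
        tibble(individual_id = ida, feature = a),
        tibble(individual_id = idb, feature = b)
      ))
      pairs[[i]] <- tibble(id_a = ida, id_b = idb, coefficient = 0.8)
    }
    profiles <- feature_profiles(dplyr::bind_rows(profiles))

    gene_pool <- c(paste0("KNOWN", seq_len(50)),
                   unique(paste0("GENE_", spec$planted$model, "_1")))
    kb <- dplyr::bind_rows(lapply(seq_len(spec$n_diseases), function(d) {
      tibble(disease_id = sprintf("DIS%04d", d),
             name = paste0("synthetic disease ", d),
             features = paste(sample(vocab, sample(3:10, 1)), collapse = ";"),
             genes = paste(sample(gene_pool, sample(1:3, 1)), collapse = ";"),
             inheritance = sample(c("AD", "AR", "XL"), 1))
    }))
    knowledge <- disease_knowledge(kb)
    disease_genes <- tibble(
      disease_id = knowledge$disease_id,
      genes = purrr::map_chr(knowledge$genes, paste, collapse = ";")
    )
    list(profiles = profiles, knowledge = knowledge,
         manifest = list(pairs = dplyr::bind_rows(pairs),
                         disease_genes = disease_genes))
  })
}

#' Generate a whole synthetic study
#'
#' Convenience wrapper running [generate_family()] for every family and
#' [generate_phenotypes()] once.
#'
#' @param spec An [fixture_spec()].
#' @return List with `families` (list of per-family fixtures), `manifest`
#'   (combined plant manifest) and `phenotypes`.
#' @export
generate_study <- function(spec) {
  families <- lapply(seq_len(spec$n_families), function(i) generate_family(spec, i))
  manifest <- dplyr::bind_rows(lapply(families, `[[`, "manifest"))
  list(families = families, manifest = manifest,
       phenotypes = generate_phenotypes(spec))
}
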