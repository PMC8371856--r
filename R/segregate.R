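#' The supported inheritance models
#'
#' @return Character vector of the eight segregation model names.
#' @export
inheritance_models <- function() {
  c("AD_DENOVO", "AD_INHERITED", "AR_HOMOZYGOUS", "AR_COMPOUND_HET",
    "XL_RECESSIVE", "XL_DOMINANT", "IMPRINTING_MATERNAL", "IMPRINTING_PATERNAL")
}

model_scope <- function(model) {
  if (model %in% c("XL_RECESSIVE", "XL_DOMINANT")) "X" else "AUTOSOME"
}

carries <- function(gt) !is.na(gt) & gt %in% c("HET", "HOM_ALT", "HEMI")
lacks <- function(gt) !is.na(gt) & gt == "HOM_REF"
is_missing_gt <- function(gt) is.na(gt) | gt == "MISSING"

# genotype of member `id` on variant row `v`; NA when the member has no
# genotype column or id is NA (member absent from the pedigree)
row_gt <- function(v, id) {
  if (is.na(id)) return(NA_character_)
  col <- paste0("GT_", id)
  if (!col %in% names(v)) return(NA_character_)
  as.character(v[[col]])
}

# pedigree context shared by all predicates
ped_context <- function(ped) {
  p <- proband_id(ped)
  parents <- proband_parents(ped)
  others <- setdiff(ped$id, c(p, parents$father, parents$mother))
  list(
    proband = p,
    proband_sex = ped$sex[ped$id == p],
    father = parents$father,
    mother = parents$mother,
    siblings = proband_siblings(ped),
    affected_others = others[ped$affected[match(others, ped$id)] == "AFFECTED"],
    unaffected_others = others[ped$affected[match(others, ped$id)] == "UNAFFECTED"],
    unaffected_all = ped$id[ped$affected == "UNAFFECTED"],
    affected_all = setdiff(ped$id[ped$affected == "AFFECTED"], p)
  )
}

# verdict assembly: any violation -> FAIL; else any missing requirement ->
# PASS_POSSIBLE; else PASS
finish_verdict <- function(fails, missing) {
  if (length(fails) > 0) {
    list(status = "FAIL", reason = paste(fails, collapse = "; "))
  } else if (length(missing) > 0) {
    list(status = "PASS_POSSIBLE",
         reason = paste0("ungenotyped: ", paste(missing, collapse = ", ")))
  } else {
    list(status = "PASS", reason = "segregation consistent")
  }
}

# ---- single-variant predicates -------------------------------------------

verdict_ad_denovo <- function(v, cx) {
  fails <- character(); miss <- character()
  gp <- row_gt(v, cx$proband)
  if (is_missing_gt(gp)) return(list(status = "FAIL", reason = "proband not genotyped"))
  if (gp != "HET") return(list(status = "FAIL", reason = paste0("proband is ", gp, ", not HET")))
  for (side in c("father", "mother")) {
    id <- cx[[side]]
    g <- row_gt(v, id)
    if (is_missing_gt(g)) miss <- c(miss, side)
    else if (g != "HOM_REF") fails <- c(fails, paste0(side, " ", id, " carries the allele (", g, ")"))
  }
  for (id in cx$affected_others) {
    g <- row_gt(v, id)
    if (!is_missing_gt(g) && !carries(g)) {
      fails <- c(fails, paste0("affected ", id, " lacks the allele"))
    }
  }
  for (id in cx$unaffected_others) {
    g <- row_gt(v, id)
    if (!is_missing_gt(g) && carries(g)) {
      fails <- c(fails, paste0("unaffected ", id, " carries the allele"))
    }
  }
  finish_verdict(fails, miss)
}

verdict_ad_inherited <- function(v, cx) {
  fails <- character(); miss <- character()
  gp <- row_gt(v, cx$proband)
  if (is_missing_gt(gp)) return(list(status = "FAIL", reason = "proband not genotyped"))
  if (gp != "HET") return(list(status = "FAIL", reason = paste0("proband is ", gp, ", not HET")))
  # the allele must be transmitted: at least one genotyped parent carries it
  gf <- row_gt(v, cx$father); gm <- row_gt(v, cx$mother)
  if (is_missing_gt(gf) || is_missing_gt(gm)) {
    miss <- c(miss, c("father", "mother")[c(is_missing_gt(gf), is_missing_gt(gm))])
    if (!is_missing_gt(gf) && !carries(gf) && !is_missing_gt(gm) && !carries(gm)) {
      # unreachable (one of them is missing), kept for clarity
    }
  } else if (!carries(gf) && !carries(gm)) {
    return(list(status = "FAIL", reason = "no carrier parent (allele not inherited)"))
  }
  for (id in cx$affected_all) {
    g <- row_gt(v, id)
    if (!is_missing_gt(g) && g != "HET") {
      fails <- c(fails, paste0("affected ", id, " is ", g, ", not HET"))
    }
  }
  for (id in cx$unaffected_all) {
    g <- row_gt(v, id)
    if (!is_missing_gt(g) && g != "HOM_REF") {
      fails <- c(fails, paste0("unaffected ", id, " is ", g, ", not HOM_REF"))
    }
  }
  finish_verdict(fails, miss)
}

verdict_ar_homozygous <- function(v, cx) {
  fails <- character(); miss <- character()
  gp <- row_gt(v, cx$proband)
  if (is_missing_gt(gp)) return(list(status = "FAIL", reason = "proband not genotyped"))
  if (gp != "HOM_ALT") {
    return(list(status = "FAIL", reason = paste0("proband is ", gp, ", not HOM_ALT")))
  }
  for (side in c("father", "mother")) {
    g <- row_gt(v, cx[[side]])
    if (is_missing_gt(g)) miss <- c(miss, side)
    else if (g != "HET") fails <- c(fails, paste0(side, " is ", g, ", not HET"))
  }
  aff <- ped_affected_status_of(cx)
  for (id in cx$siblings) {
    g <- row_gt(v, id)
    status <- aff[id]
    if (is.na(status)) next
    if (status == "UNAFFECTED" && !is_missing_gt(g) && g == "HOM_ALT") {
      fails <- c(fails, paste0("unaffected sibling ", id, " is HOM_ALT"))
    }
    if (status == "AFFECTED") {
      if (is_missing_gt(g)) miss <- c(miss, paste0("sibling ", id))
      else if (g != "HOM_ALT") fails <- c(fails, paste0("affected sibling ", id, " is ", g))
    }
  }
  # no unaffected genotyped member may hold the causal genotype
  for (id in setdiff(cx$unaffected_all, cx$siblings)) {
    g <- row_gt(v, id)
    if (!is_missing_gt(g) && g == "HOM_ALT") {
      fails <- c(fails, paste0("unaffected ", id, " is HOM_ALT"))
    }
  }
  finish_verdict(fails, unique(miss))
}

# affected-status lookup keyed by member id (built once per pedigree would be
# nicer; kept local to the context for simplicity)
ped_affected_status_of <- function(cx) {
  ids <- c(cx$affected_all, cx$unaffected_all)
  stats::setNames(
    c(rep("AFFECTED", length(cx$affected_all)),
      rep("UNAFFECTED", length(cx$unaffected_all))),
    ids
  )
}

verdict_xl_recessive <- function(v, cx) {
  fails <- character(); miss <- character()
  gp <- row_gt(v, cx$proband)
  if (is_missing_gt(gp)) return(list(status = "FAIL", reason = "proband not genotyped"))
  gf <- row_gt(v, cx$father); gm <- row_gt(v, cx$mother)
  if (cx$proband_sex == "MALE") {
    if (gp != "HEMI") {
      return(list(status = "FAIL", reason = paste0("male proband is ", gp, ", not HEMI")))
    }
    if (is_missing_gt(gm)) miss <- c(miss, "mother")
    else if (!carries(gm)) fails <- c(fails, "mother is not a carrier")
    if (is_missing_gt(gf)) miss <- c(miss, "father")
    else if (carries(gf)) fails <- c(fails, "father carries the allele")
  } else {
    if (gp != "HOM_ALT") {
      return(list(status = "FAIL", reason = paste0("female proband is ", gp, ", not HOM_ALT")))
    }
    if (is_missing_gt(gm)) miss <- c(miss, "mother")
    else if (!carries(gm)) fails <- c(fails, "mother is not a carrier")
    if (is_missing_gt(gf)) miss <- c(miss, "father")
    else if (!carries(gf)) fails <- c(fails, "father is not a carrier")
  }
  causal <- if (cx$proband_sex == "MALE") "HEMI" else "HOM_ALT"
  for (id in cx$unaffected_others) {
    g <- row_gt(v, id)
    if (!is_missing_gt(g) && g == causal) {
      fails <- c(fails, paste0("unaffected ", id, " has the causal genotype"))
    }
  }
  finish_verdict(fails, miss)
}

verdict_xl_dominant <- function(v, cx) {
  fails <- character(); miss <- character()
  gp <- row_gt(v, cx$proband)
  if (is_missing_gt(gp)) return(list(status = "FAIL", reason = "proband not genotyped"))
  expected <- if (cx$proband_sex == "MALE") "HEMI" else "HET"
  if (gp != expected) {
    return(list(status = "FAIL",
                reason = paste0("proband is ", gp, ", not ", expected)))
  }
  for (side in c("father", "mother")) {
    if (is_missing_gt(row_gt(v, cx[[side]]))) miss <- c(miss, side)
  }
  for (id in cx$affected_all) {
    g <- row_gt(v, id)
    if (!is_missing_gt(g) && !carries(g)) {
      fails <- c(fails, paste0("affected ", id, " lacks the allele"))
    }
  }
  for (id in cx$unaffected_all) {
    g <- row_gt(v, id)
    if (!is_missing_gt(g) && carries(g)) {
      fails <- c(fails, paste0("unaffected ", id, " carries the allele"))
    }
  }
  finish_verdict(fails, miss)
}

# maternal imprinting: the maternal copy is silenced, so the pathogenic
# allele is the paternally inherited one; an unaffected carrier parent is
# expected under imprinting, so no affected-status veto applies
verdict_imprinting <- function(v, cx, pathogenic_from = c("father", "mother")) {
  pathogenic_from <- match.arg(pathogenic_from)
  silent_side <- setdiff(c("father", "mother"), pathogenic_from)
  fails <- character(); miss <- character()
  gp <- row_gt(v, cx$proband)
  if (is_missing_gt(gp)) return(list(status = "FAIL", reason = "proband not genotyped"))
  if (gp != "HET") return(list(status = "FAIL", reason = paste0("proband is ", gp, ", not HET")))
  g_origin <- row_gt(v, cx[[pathogenic_from]])
  g_silent <- row_gt(v, cx[[silent_side]])
  if (is_missing_gt(g_origin)) miss <- c(miss, pathogenic_from)
  else if (!carries(g_origin)) {
    fails <- c(fails, paste0(pathogenic_from, " does not carry the allele"))
  }
  if (is_missing_gt(g_silent)) miss <- c(miss, silent_side)
  else if (g_silent != "HOM_REF") {
    fails <- c(fails, paste0(silent_side, " carries the allele (origin ambiguous)"))
  }
  finish_verdict(fails, miss)
}

# ---- compound heterozygotes ----------------------------------------------

# phase one proband-HET variant: "mother"/"father"/"ambiguous"/"denovo",
# or "unknown" when a parental genotype is unavailable
trace_origin <- function(v, cx) {
  gf <- row_gt(v, cx$father); gm <- row_gt(v, cx$mother)
  if (is_missing_gt(gf) || is_missing_gt(gm)) return("unknown")
  fc <- carries(gf); mc <- carries(gm)
  if (mc && !fc) return("mother")
  if (fc && !mc) return("father")
  if (fc && mc) return("ambiguous")
  "denovo"
}

segregate_compound_het <- function(variants, ped, cx) {
  v <- variants
  gp <- as.character(v[[paste0("GT_", cx$proband)]])
  het_idx <- which(!is.na(gp) & gp == "HET" & v$chrom %in% as.character(1:22) &
                     !is.na(v$gene))
  keys <- locus_key(v)
  status <- rep("FAIL", nrow(v))
  reason <- rep("", nrow(v))
  partners <- vector("list", nrow(v))
  for (i in seq_len(nrow(v))) partners[[i]] <- character()
  reason[setdiff(seq_len(nrow(v)), het_idx)] <-
    "proband not HET on an autosome (or gene unknown)"

  parents_known <- !is.na(cx$father) && !is.na(cx$mother)
  origins <- stats::setNames(rep("unknown", length(het_idx)), het_idx)
  if (parents_known) {
    for (i in het_idx) origins[[as.character(i)]] <- trace_origin(v[i, ], cx)
  }

  for (gene in unique(v$gene[het_idx])) {
    idx <- het_idx[v$gene[het_idx] == gene]
    if (length(idx) < 2) {
      status[idx] <- "FAIL"
      reason[idx] <- "no second heterozygous variant in the gene"
      next
    }
    pairs <- utils::combn(idx, 2)
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      # genotyped unaffected members must not carry both members of the pair
      veto <- FALSE
      for (id in cx$unaffected_all) {
        ga <- row_gt(v[a, ], id); gb <- row_gt(v[b, ], id)
        if (!is_missing_gt(ga) && !is_missing_gt(gb) && carries(ga) && carries(gb)) {
          veto <- TRUE
          break
        }
      }
      if (veto) next
      oa <- origins[[as.character(a)]]; ob <- origins[[as.character(b)]]
      pair_status <- if (oa %in% c("mother", "father") && ob %in% c("mother", "father")) {
        if (oa != ob) "PASS" else "SAME_ORIGIN"
      } else if (oa == "unknown" || ob == "unknown") {
        "POSSIBLE"  # phase unknowable without parental genotypes
      } else {
        "UNPHASEABLE"  # fully genotyped yet origin not establishable
      }
      if (pair_status == "PASS") {
        for (x in c(a, b)) {
          status[x] <- "PASS"
          partners[[x]] <- union(partners[[x]], keys[setdiff(c(a, b), x)])
        }
      } else if (pair_status == "POSSIBLE") {
        for (x in c(a, b)) {
          if (status[x] != "PASS") {
            status[x] <- "PASS_POSSIBLE"
            partners[[x]] <- union(partners[[x]], keys[setdiff(c(a, b), x)])
          }
        }
      }
    }
    for (x in idx) {
      if (status[x] == "PASS") {
        reason[x] <- "biallelic pair with opposite parental origin"
      } else if (status[x] == "PASS_POSSIBLE") {
        reason[x] <- "heterozygous pair, phase not establishable"
      } else if (reason[x] == "") {
        reason[x] <- "no qualifying partner variant"
      }
      partners[[x]] <- sort(partners[[x]])
    }
  }

  tibble(
    chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
    gene = if ("gene" %in% names(v)) v$gene else NA_character_,
    model = "AR_COMPOUND_HET", status = status, reason = reason,
    partners = partners
  )
}

# ---- public segregation API ----------------------------------------------

#' Segregate variants under a Mendelian inheritance model
#'
#' Evaluates one segregation predicate per variant against all genotyped
#' family members and returns one verdict per variant. Autosomal models
#' (`AD_*`, `AR_*`, `IMPRINTING_*`) evaluate autosomal variants only and the
#' X-linked models evaluate X variants only; out-of-scope variants receive a
#' `FAIL` verdict. A `MISSING` genotype in a required relative downgrades
#' the verdict to `PASS_POSSIBLE`, never `PASS`. For
#' `AR_COMPOUND_HET` the `partners` list-column holds the locus keys of the
#' qualifying partner variants (mutually: `a` lists `b` iff `b` lists `a`).
#'
#' @param variants A variant tibble, already rare/functional-filtered.
#' @param pedigree The family [pedigree()].
#' @param model One of [inheritance_models()].
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`, `gene`,
#'   `model`, `status` (`PASS`, `PASS_POSSIBLE` or `FAIL`), `reason`, and
#'   `partners` (list-column).
#' @export
segregate <- function(variants, pedigree, model) {
  model <- match.arg(model, inheritance_models())
  v <- as_tibble(variants)
  cx <- ped_context(pedigree)
  if (model_scope(model) == "X" && !any(v$chrom == "X")) {
    warn(paste0("No X-chromosome variants supplied for model ", model, "."))
    return(empty_verdicts(model))
  }
  if (model == "AR_COMPOUND_HET") {
    return(segregate_compound_het(v, pedigree, cx))
  }
  fn <- switch(model,
    AD_DENOVO = verdict_ad_denovo,
    AD_INHERITED = verdict_ad_inherited,
    AR_HOMOZYGOUS = verdict_ar_homozygous,
    XL_RECESSIVE = verdict_xl_recessive,
    XL_DOMINANT = verdict_xl_dominant,
    IMPRINTING_MATERNAL = function(v, cx) verdict_imprinting(v, cx, "father"),
    IMPRINTING_PATERNAL = function(v, cx) verdict_imprinting(v, cx, "mother")
  )
  in_scope <- if (model_scope(model) == "X") v$chrom == "X" else v$chrom %in% as.character(1:22)
  verdicts <- purrr::map(seq_len(nrow(v)), function(i) {
    if (!in_scope[i]) {
      list(status = "FAIL",
           reason = paste0("chromosome ", v$chrom[i], " out of scope for ", model))
    } else {
      fn(v[i, ], cx)
    }
  })
  tibble(
    chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
    gene = if ("gene" %in% names(v)) v$gene else NA_character_,
    model = model,
    status = purrr::map_chr(verdicts, "status"),
    reason = purrr::map_chr(verdicts, "reason"),
    partners = purrr::map(verdicts, function(x) character())
  )
}

empty_verdicts <- function(model) {
  tibble(chrom = character(), pos = integer(), ref = character(),
         alt = character(), gene = character(), model = character(),
         status = character(), reason = character(), partners = list())
}

#' Run the automated default analyses
#'
#' Reproduces the automated run performed when a family's files are loaded:
#' the rare/functional filter followed by segregation under the three
#' default models — autosomal dominant monoallelic (de novo and inherited
#' sub-verdicts flagged separately in one file), autosomal recessive
#' homozygous, and autosomal recessive compound heterozygous. Each result
#' file keeps only the `PASS`/`PASS_POSSIBLE` variants with all annotation
#' columns carried through, plus `status`, `reason` and (per model) the
#' `ad_subtype` or `partners` column.
#'
#' @param variants A variant tibble.
#' @param pedigree The family [pedigree()].
#' @param config An [analysis_config()].
#' @param inputs Optional named digests recorded in each file's provenance.
#' @return Named list of [result_file()] objects: `AD_MONOALLELIC`,
#'   `AR_HOMOZYGOUS`, `AR_COMPOUND_HET`.
#' @export
run_automated_analyses <- function(variants, pedigree, config = analysis_config(),
                                   inputs = NULL) {
  filtered <- filter_rare_functional(variants, config, pedigree)
  pid <- proband_id(pedigree)

  dn <- segregate(filtered, pedigree, "AD_DENOVO")
  inh <- segregate(filtered, pedigree, "AD_INHERITED")
  ad_rows <- build_ad_rows(filtered, dn, inh)

  hom <- segregate(filtered, pedigree, "AR_HOMOZYGOUS")
  hom_rows <- attach_verdict(filtered, hom)

  chet <- segregate(filtered, pedigree, "AR_COMPOUND_HET")
  chet_rows <- attach_verdict(filtered, chet, with_partners = TRUE)

  list(
    AD_MONOALLELIC = result_file(pid, "AD_MONOALLELIC", ad_rows, config, inputs),
    AR_HOMOZYGOUS = result_file(pid, "AR_HOMOZYGOUS", hom_rows, config, inputs),
    AR_COMPOUND_HET = result_file(pid, "AR_COMPOUND_HET", chet_rows, config, inputs)
  )
}

build_ad_rows <- function(filtered, dn, inh) {
  keep_dn <- dn$status %in% c("PASS", "PASS_POSSIBLE")
  keep_inh <- inh$status %in% c("PASS", "PASS_POSSIBLE")
  keep <- keep_dn | keep_inh
  if (!any(keep)) {
    return(dplyr::bind_cols(filtered[0, ],
                            tibble(ad_subtype = character(), status = character(),
                                   reason = character())))
  }
  subtype <- ifelse(keep_dn & keep_inh, "DENOVO+INHERITED",
                    ifelse(keep_dn, "DENOVO", "INHERITED"))
  status <- ifelse(keep_dn & dn$status == "PASS" | keep_inh & inh$status == "PASS",
                   "PASS", "PASS_POSSIBLE")
  reason <- ifelse(keep_dn, dn$reason, inh$reason)
  dplyr::bind_cols(filtered[keep, ],
                   tibble(ad_subtype = subtype[keep], status = status[keep],
                          reason = reason[keep]))
}

attach_verdict <- function(filtered, verdicts, with_partners = FALSE) {
  if (nrow(verdicts) != nrow(filtered)) filtered <- filtered[0, ]  # X model, no X data
  keep <- verdicts$status %in% c("PASS", "PASS_POSSIBLE")
  out <- dplyr::bind_cols(
    filtered[keep, ],
    tibble(status = verdicts$status[keep], reason = verdicts$reason[keep])
  )
  if (with_partners) {
    out$partner <- purrr::map_chr(verdicts$partners[keep], paste, collapse = ";")
  }
  out
}

#' Analyze one family under one or more inheritance models
#'
#' Convenience wrapper: filters then segregates under each requested model,
#' returning one result file per model (passing variants only).
#'
#' @param variants A variant tibble.
#' @param pedigree The family [pedigree()].
#' @param config An [analysis_config()].
#' @param models Character vector of model names; defaults to
#'   `config$model` or all eight.
#' @param inputs Optional named digests for provenance.
#' @return Named list of [result_file()] objects.
#' @export
analyze_family <- function(variants, pedigree, config = analysis_config(),
                           models = NULL, inputs = NULL) {
  if (is.null(models)) {
    models <- if (!is.null(config$model)) config$model else inheritance_models()
  }
  filtered <- filter_rare_functional(variants, config, pedigree)
  pid <- proband_id(pedigree)
  out <- lapply(models, function(m) {
    verdicts <- withCallingHandlers(
      segregate(filtered, pedigree, m),
      warning = function(w) invokeRestart("muffleWarning")
    )
    rows <- attach_verdict(filtered, verdicts, with_partners = m == "AR_COMPOUND_HET")
    result_file(pid, m, rows, config, inputs)
  })
  stats::setNames(out, models)
}
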