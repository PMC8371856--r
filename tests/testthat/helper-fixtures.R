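# Builders for tiny in-code fixtures used across the suite.

make_trio_ped <- function(father_affected = FALSE, proband_sex = "FEMALE",
                          ids = c("P", "D", "M")) {
  pedigree(tibble::tibble(
    id = ids,
    sex = c(proband_sex, "MALE", "FEMALE"),
    affected = c("AFFECTED", ifelse(father_affected, "AFFECTED", "UNAFFECTED"),
                 "UNAFFECTED"),
    father_id = c(ids[2], NA, NA),
    mother_id = c(ids[3], NA, NA),
    proband = c(TRUE, FALSE, FALSE)
  ))
}

make_singleton_ped <- function(id = "P", sex = "FEMALE") {
  pedigree(tibble::tibble(id = id, sex = sex, affected = "AFFECTED",
                          father_id = NA, mother_id = NA, proband = TRUE))
}

# one variant row; `calls` is a named vector sample -> genotype
make_var <- function(chrom = "1", pos = 100L, ref = "A", alt = "G",
                     gene = "G1", func = "MISSENSE", calls = c(P = "HET"),
                     mafs = list(), dp = 30L, rvis = NA_real_) {
  row <- tibble::tibble(chrom = chrom, pos = as.integer(pos), ref = ref,
                        alt = alt, gene = gene, func_class = func)
  for (db in c("1000g", "evs", "exac", "gnomad")) {
    row[[paste0("maf_", db)]] <- if (db %in% names(mafs)) mafs[[db]] else NA_real_
  }
  row$rvis_percentile <- rvis
  for (s in names(calls)) {
    row[[paste0("GT_", s)]] <- unname(calls[s])
    row[[paste0("DP_", s)]] <- as.integer(dp)
  }
  row
}

make_vars <- function(...) dplyr::bind_rows(...)

segregate_one <- function(var, ped, model) {
  suppressWarnings(segregate(var, ped, model))
}

status_of <- function(var, ped, model) segregate_one(var, ped, model)$status
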