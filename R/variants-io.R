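#' @title Variant tables
#' @description
#' Annotated variants are plain tibbles, one row per (site, alternate
#' allele), with the locus columns `chrom`, `pos`, `ref`, `alt`, the
#' annotation columns `gene` and `func_class`, per-database allele
#' frequencies in `maf_<database>` columns (`NA` = not observed in that
#' database), per-sample genotype calls in `GT_<sample>` columns (values
#' `HOM_REF`, `HET`, `HOM_ALT`, `HEMI`, `MISSING`) and read depths in
#' `DP_<sample>` columns. Any further columns (RVIS percentile, ClinVar
#' class, ...) are carried through verbatim.
#' @name variant-tables
NULL

MANDATORY_ANNOT_COLS <- c("chrom", "pos", "ref", "alt", "gene", "func_class")

chrom_rank <- function(chrom) match(chrom, VALID_CHROMS)

gt_cols <- function(x) grep("^GT_", names(x), value = TRUE)
dp_cols <- function(x) grep("^DP_", names(x), value = TRUE)
maf_cols <- function(x) grep("^maf_", names(x), value = TRUE)

sort_variants <- function(x) {
  dplyr::arrange(x, chrom_rank(.data$chrom), .data$pos, .data$ref, .data$alt)
}

#' Map annotation function strings to the canonical function classes
#'
#' Understands both the canonical tokens (`MISSENSE`, `NONSENSE`, ...) and
#' common annotator spellings (`"nonsynonymous SNV"`, `"stopgain"`,
#' `"frameshift deletion"`, ...). A synonymous variant flagged as lying in a
#' splice region is classed `SPLICE_REGION_SYNONYMOUS` — the flag is input
#' annotation, not recomputed here.
#'
#' @param func Character vector of function-class strings.
#' @param splice_region Logical vector (recycled): variant lies within the
#'   annotated splice region of an exon boundary.
#' @return Character vector of canonical function classes.
#' @export
normalize_func_class <- function(func, splice_region = FALSE) {
  splice_region <- rep_len(as.logical(splice_region), length(func))
  f <- tolower(stringr::str_squish(as.character(func)))
  out <- dplyr::case_when(
    toupper(f) %in% FUNC_CLASSES ~ toupper(f),
    f %in% c("missense snv", "nonsynonymous snv", "missense") ~ "MISSENSE",
    f %in% c("stopgain", "stopgain snv", "nonsense") ~ "NONSENSE",
    f %in% c("stoploss", "stoploss snv", "stop-loss") ~ "STOP_LOSS",
    f %in% c("synonymous snv", "synonymous") ~ "SYNONYMOUS",
    grepl("^frameshift", f) ~ "FRAMESHIFT_INDEL",
    grepl("^(nonframeshift|non-frameshift|inframe)", f) ~ "INFRAME_INDEL",
    f %in% c("splicing", "splice site", "splice_site") ~ "SPLICE_SITE",
    .default = "OTHER"
  )
  ifelse(out == "SYNONYMOUS" & splice_region, "SPLICE_REGION_SYNONYMOUS", out)
}

# map one diploid/haploid GT string to a call for alternate-allele index k
gt_to_call <- function(gt, k, hemizygous = FALSE) {
  vapply(gt, function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return("MISSING")
    alleles <- strsplit(sub(":.*$", "", g), "[/|]")[[1]]
    if (any(alleles == ".") || length(alleles) == 0) return("MISSING")
    n_alt <- sum(alleles == as.character(k))
    if (hemizygous) return(if (n_alt >= 1) "HEMI" else "HOM_REF")
    if (length(alleles) == 1L) {
      return(if (n_alt >= 1) "HOM_ALT" else "HOM_REF")
    }
    c("HOM_REF", "HET", "HOM_ALT")[pmin(n_alt, 2L) + 1L]
  }, character(1), USE.NAMES = FALSE)
}

#' Read a multi-sample VCF into a variant table
#'
#' Parses a VCF 4.x file, splits multiallelic sites into one record per
#' alternate allele (re-expressing each sample's genotype relative to that
#' allele: a `0/2` call is `HET` for the second alternate and `HOM_REF` for
#' the first), and maps male calls on X or Y to `HEMI`. Pseudoautosomal
#' intervals, when supplied, are treated as autosomal.
#'
#' @param path Path to the VCF file.
#' @param pedigree An [pedigree()]; every member present in the pedigree must
#'   have a sample column in the VCF.
#' @param par_regions Optional tibble (`chrom`, `start`, `end`, half-open)
#'   of pseudoautosomal intervals on X/Y. `NULL` treats all of X/Y as
#'   non-pseudoautosomal.
#' @return A variant tibble (see [variant-tables]) with `GT_*`/`DP_*`
#'   columns but no annotations.
#' @export
read_vcf <- function(path, pedigree, par_regions = NULL) {
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) abort(paste0("Malformed VCF '", path, "': ", conditionMessage(e)),
                              class = "mm_parse_error")
  )
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  samples <- colnames(vcf@gt)[-1]
  missing_members <- setdiff(pedigree$id, samples)
  if (length(missing_members) > 0) {
    abort(paste0("Pedigree member(s) absent from VCF: ",
                 paste(missing_members, collapse = ", ")),
          class = "mm_missing_sample_error")
  }
  if (nrow(fix) == 0) {
    return(empty_variant_tbl(pedigree$id))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
  if (is.null(dp)) dp <- matrix(NA_real_, nrow = nrow(fix), ncol = length(samples))
  male_ids <- pedigree$id[pedigree$sex == "MALE"]

  rows <- purrr::map(seq_len(nrow(fix)), function(i) {
    chrom <- normalize_chrom(fix$CHROM[i])
    pos <- as.integer(fix$POS[i])
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    hemi_site <- chrom %in% c("X", "Y") && !in_regions(chrom, pos, par_regions)
    purrr::map(seq_along(alts), function(k) {
      calls <- lapply(pedigree$id, function(s) {
        hemi <- hemi_site && s %in% male_ids
        gt_to_call(gt[i, s], k, hemizygous = hemi)
      })
      depths <- lapply(pedigree$id, function(s) {
        d <- dp[i, s]
        if (is.na(d)) NA_integer_ else as.integer(d)
      })
      names(calls) <- paste0("GT_", pedigree$id)
      names(depths) <- paste0("DP_", pedigree$id)
      dplyr::bind_cols(
        tibble(chrom = chrom, pos = pos, ref = toupper(fix$REF[i]),
               alt = toupper(alts[k])),
        as_tibble(calls), as_tibble(depths)
      )
    })
  })
  sort_variants(dplyr::bind_rows(purrr::flatten(rows)))
}

empty_variant_tbl <- function(sample_ids) {
  cols <- c(list(chrom = character(), pos = integer(), ref = character(),
                 alt = character()),
            stats::setNames(rep(list(character()), length(sample_ids)),
                            paste0("GT_", sample_ids)),
            stats::setNames(rep(list(integer()), length(sample_ids)),
                            paste0("DP_", sample_ids)))
  as_tibble(cols)
}

# is (chrom, pos) inside any half-open [start, end) interval?
in_regions <- function(chrom, pos, regions) {
  if (is.null(regions) || nrow(regions) == 0) return(FALSE)
  any(regions$chrom == chrom & regions$start <= pos & pos < regions$end)
}

#' Read an annotation table (ANNOVAR-style TSV)
#'
#' The table must name the locus columns (`chrom`, `pos`, `ref`, `alt`),
#' `gene` and `func_class`; `maf_<database>` columns hold population allele
#' frequencies (an empty cell means the variant was not observed in that
#' database, not frequency zero); `GT_<sample>`/`DP_<sample>` columns hold
#' per-sample calls. All other columns are preserved verbatim as extra
#' annotations. Function-class strings are normalized via
#' [normalize_func_class()], honouring a logical `splice_region` column when
#' present.
#'
#' @param path Path to the tab-separated file; `#`-prefixed leading lines
#'   are ignored.
#' @return A variant tibble, sorted by locus.
#' @export
locus_col_types <- function() {
  # single-base alleles would otherwise be guessed as logicals ("T"/"F")
  readr::cols(chrom = readr::col_character(), ref = readr::col_character(),
              alt = readr::col_character(), .default = readr::col_guess())
}

read_annotation_table <- function(path) {
  tbl <- readr::read_tsv(path, comment = "#", na = "", col_types = locus_col_types(),
                         show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(MANDATORY_ANNOT_COLS, names(tbl))
  if (length(missing_cols) > 0) {
    abort(paste0("Annotation table is missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "mm_schema_error")
  }
  splice_flag <- if ("splice_region" %in% names(tbl)) {
    as.logical(tbl$splice_region) %in% TRUE
  } else FALSE
  tbl <- mutate(tbl,
    chrom = normalize_chrom(.data$chrom),
    pos = as.integer(.data$pos),
    ref = toupper(.data$ref),
    alt = toupper(.data$alt),
    gene = as.character(.data$gene),
    func_class = normalize_func_class(.data$func_class, .env$splice_flag)
  )
  tbl <- mutate(tbl, across(all_of(maf_cols(tbl)), as.numeric))
  tbl <- mutate(tbl, across(all_of(dp_cols(tbl)), as.integer))
  bad_maf <- purrr::map_lgl(maf_cols(tbl), function(cl) {
    v <- tbl[[cl]]
    any(!is.na(v) & (v < 0 | v > 1))
  })
  if (any(bad_maf)) {
    abort("Allele frequencies must lie in [0, 1].", class = "mm_schema_error")
  }
  sort_variants(tbl)
}

#' Write an annotation table
#'
#' Inverse of [read_annotation_table()]: tab-separated, `NA` written as the
#' empty cell, deterministic column and row order.
#'
#' @param variants A variant tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(variants, path) {
  readr::write_tsv(sort_variants(variants), path, na = "", progress = FALSE)
  invisible(path)
}

#' Construct an analysis result
#'
#' An analysis result bundles the retained variant rows (plus any appended
#' columns such as the segregation status or `OMIM Matching Phenotypes`)
#' with the proband, the inheritance model, and a provenance record
#' (configuration snapshot and input digests). Rows are stored sorted by
#' locus; writing the same result twice yields byte-identical files.
#'
#' @param proband_id Proband identifier.
#' @param model Inheritance model name (or a label such as `"AD_MONOALLELIC"`).
#' @param rows Variant tibble with any appended columns.
#' @param config Optional `mm_config` recorded in the provenance.
#' @param inputs Optional named character vector of input-file digests.
#' @return An `mm_result` object.
#' @export
result_file <- function(proband_id, model, rows, config = NULL, inputs = NULL) {
  rows <- sort_variants(as_tibble(rows))
  structure(
    list(proband_id = proband_id, model = model, rows = rows,
         provenance = list(
           config = if (is.null(config)) NA_character_ else config_snapshot(config),
           inputs = inputs
         )),
    class = "mm_result"
  )
}

#' @export
print.mm_result <- function(x, ...) {
  cat("<analysis result> proband ", x$proband_id, ", model ", x$model, ", ",
      nrow(x$rows), " variant(s)\n", sep = "")
  invisible(x)
}

#' Write an analysis result as tab-delimited text
#'
#' Provenance (proband, model, configuration snapshot, input digests) is
#' written as leading `#` comment lines, followed by the header and the
#' locus-sorted rows. Output is deterministic: identical results produce
#' byte-identical files.
#'
#' @param result An `mm_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_file <- function(result, path) {
  stopifnot(inherits(result, "mm_result"))
  header <- c(
    paste0("# proband=", result$proband_id),
    paste0("# model=", result$model),
    paste0("# config=", result$provenance$config)
  )
  if (!is.null(result$provenance$inputs)) {
    header <- c(header, paste0("# input ", names(result$provenance$inputs), "=",
                               result$provenance$inputs))
  }
  body <- readr::format_tsv(sort_variants(result$rows), na = "")
  con <- file(path, open = "wb")  # fixed newlines for byte-identical output
  on.exit(close(con))
  writeLines(c(header, sub("\n$", "", body)), con, sep = "\n")
  invisible(path)
}

#' Read back an analysis result written by [write_result_file()]
#'
#' @param path Path to the result TSV.
#' @return An `mm_result`.
#' @export
read_result_file <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "# ")]
  kv <- stringr::str_match(meta, "^# ([^=]+)=(.*)$")
  vals <- stats::setNames(kv[, 3], kv[, 2])
  rows <- readr::read_tsv(I(paste(lines[!startsWith(lines, "#")], collapse = "\n")),
                          na = "", col_types = locus_col_types(),
                          show_col_types = FALSE, progress = FALSE)
  if (nrow(rows) >= 0) {
    rows <- mutate(rows, chrom = as.character(.data$chrom),
                   pos = as.integer(.data$pos),
                   across(all_of(maf_cols(rows)), as.numeric),
                   across(all_of(dp_cols(rows)), as.integer))
    if ("rvis_percentile" %in% names(rows)) {
      rows <- mutate(rows, rvis_percentile = as.numeric(.data$rvis_percentile))
    }
  }
  inputs <- vals[startsWith(names(vals), "input ")]
  names(inputs) <- sub("^input ", "", names(inputs))
  res <- result_file(unname(vals[["proband"]]), unname(vals[["model"]]), rows,
                     inputs = if (length(inputs)) inputs else NULL)
  res$provenance$config <- unname(vals[["config"]])
  res
}

#' Attach annotations to VCF-derived genotype records
#'
#' Joins a genotype table from [read_vcf()] with an annotation table on the
#' locus; annotation rows supply gene, function class, frequencies and any
#' extra columns, genotype rows supply the calls.
#'
#' @param vcf_variants Output of [read_vcf()].
#' @param annotations Output of [read_annotation_table()] (genotype columns
#'   there, if any, are ignored in favour of the VCF's).
#' @return A merged variant tibble; variants absent from the annotation
#'   table get `gene = NA` and `func_class = "OTHER"`.
#' @export
merge_annotations <- function(vcf_variants, annotations) {
  ann <- select(annotations, -any_of(c(gt_cols(annotations), dp_cols(annotations))))
  out <- left_join(vcf_variants, ann, by = c("chrom", "pos", "ref", "alt"))
  out <- mutate(out,
    func_class = ifelse(is.na(.data$func_class), "OTHER", .data$func_class))
  sort_variants(out)
}
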