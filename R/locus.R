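#' @importFrom rlang .data abort warn .env
#' @importFrom dplyr mutate filter select arrange bind_rows group_by ungroup
#'   summarise distinct left_join n across all_of any_of row_number rename
#' @importFrom tibble tibble as_tibble
NULL

VALID_CHROMS <- c(as.character(1:22), "X", "Y", "MT")

GT_LEVELS <- c("HOM_REF", "HET", "HOM_ALT", "HEMI", "MISSING")

FUNC_CLASSES <- c(
  "MISSENSE", "NONSENSE", "STOP_LOSS", "SYNONYMOUS", "FRAMESHIFT_INDEL",
  "INFRAME_INDEL", "SPLICE_SITE", "SPLICE_REGION_SYNONYMOUS", "OTHER"
)

#' Normalize a chromosome name
#'
#' Strips any `chr` prefix, upper-cases, and maps the mitochondrial aliases
#' `M`/`chrM` to `MT`, so that `"chr2"` and `"2"` denote the same chromosome.
#' Normalization is idempotent.
#'
#' @param chrom Character vector of chromosome names.
#' @param strict If `TRUE` (default), names outside 1-22, X, Y, MT are an
#'   error; otherwise they are returned normalized but unvalidated.
#' @return Character vector of normalized chromosome names.
#' @export
#' @examples
#' normalize_chrom(c("chr2", "2", "chrX", "M"))
normalize_chrom <- function(chrom, strict = TRUE) {
  out <- toupper(stringr::str_remove(stringr::str_trim(as.character(chrom)), "^[Cc][Hh][Rr]"))
  out[out == "M"] <- "MT"
  if (strict) {
    bad <- setdiff(unique(out), VALID_CHROMS)
    if (length(bad) > 0) {
      abort(paste0("Invalid chromosome name(s): ", paste(bad, collapse = ", ")),
            class = "mm_locus_error")
    }
  }
  out
}

#' Construct a locus tibble
#'
#' A locus identifies one alternate allele at one genomic position:
#' chromosome (normalized, no `chr` prefix), 1-based position, reference and
#' alternate alleles.
#'
#' @param chrom Chromosome name(s); normalized via [normalize_chrom()].
#' @param pos 1-based position(s).
#' @param ref,alt Reference / alternate alleles (A/C/G/T strings).
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`.
#' @export
locus <- function(chrom, pos, ref, alt) {
  chrom <- normalize_chrom(chrom)
  pos <- as.integer(pos)
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  if (any(is.na(pos)) || any(pos < 1L)) {
    abort("Locus position must be an integer >= 1.", class = "mm_locus_error")
  }
  bad_allele <- !grepl("^[ACGT]+$", ref) | !grepl("^[ACGT]+$", alt)
  if (any(bad_allele)) {
    abort("Alleles must be non-empty A/C/G/T strings.", class = "mm_locus_error")
  }
  if (any(ref == alt)) {
    abort("Reference and alternate allele must differ.", class = "mm_locus_error")
  }
  tibble(chrom = chrom, pos = pos, ref = ref, alt = alt)
}

#' Format loci as "chrom:pos ref>alt" keys
#'
#' @param x A data frame with `chrom`, `pos`, `ref`, `alt` columns.
#' @return Character vector of locus keys, e.g. `"2:1234567 G>T"`.
#' @export
locus_key <- function(x) {
  paste0(x$chrom, ":", x$pos, " ", x$ref, ">", x$alt)
}

#' Parse a matchmaker variant query string
#'
#' Accepts the `"chr:coordinate refAllele>altAllele"` grammar used for
#' variant-level matchmaking queries, e.g. `"chr2:1234567G > T"`. The `chr`
#' prefix and whitespace around `>` are optional; alleles must be A/C/G/T.
#'
#' @param text Query string.
#' @param build Genome build the coordinate refers to: `"hg18"`, `"hg19"` or
#'   `"hg38"`.
#' @param features Optional character vector of phenotype features. When
#'   supplied, between 3 and 6 features are required.
#' @return A `mm_variant_query` object: a list with `locus` (one-row locus
#'   tibble), `build`, and `features` (`NULL` or a normalized character
#'   vector).
#' @export
#' @examples
#' parse_variant_query("chr2:1234567G > T", build = "hg19")
parse_variant_query <- function(text, build = "hg19", features = NULL) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    abort("Query must be a single string.", class = "mm_parse_error")
  }
  build <- match.arg(build, c("hg18", "hg19", "hg38"))
  m <- stringr::str_match(
    stringr::str_trim(text),
    "^(?:[Cc][Hh][Rr])?([0-9XYMxym]+[Tt]?)\\s*:\\s*([0-9]+)\\s*([A-Za-z]+)\\s*>\\s*([A-Za-z]+)$"
  )
  if (is.na(m[1, 1])) {
    abort(paste0("Cannot parse variant query: '", text,
                 "' (expected 'chr:coordinate refAllele>altAllele')."),
          class = "mm_parse_error")
  }
  chrom <- tryCatch(normalize_chrom(m[1, 2]), error = function(e) {
    abort(paste0("Invalid chromosome token '", m[1, 2], "' in query."),
          class = "mm_parse_error")
  })
  pos <- suppressWarnings(as.integer(m[1, 3]))
  if (is.na(pos) || pos < 1L) {
    abort(paste0("Invalid coordinate '", m[1, 3], "' in query."),
          class = "mm_parse_error")
  }
  ref <- toupper(m[1, 4]); alt <- toupper(m[1, 5])
  if (!grepl("^[ACGT]+$", ref) || !grepl("^[ACGT]+$", alt)) {
    abort(paste0("Alleles must be A/C/G/T (got '", ref, ">", alt, "')."),
          class = "mm_allele_error")
  }
  if (ref == alt) {
    abort("Reference and alternate allele are identical.", class = "mm_parse_error")
  }
  if (!is.null(features)) {
    features <- normalize_features(features)
    if (length(features) < 3L || length(features) > 6L) {
      abort("Variant queries with phenotypes require 3 to 6 features.",
            class = "mm_validation_error")
    }
  }
  structure(
    list(locus = locus(chrom, pos, ref, alt), build = build, features = features),
    class = "mm_variant_query"
  )
}

#' @export
print.mm_variant_query <- function(x, ...) {
  cat("<variant query> ", locus_key(x$locus), " [", x$build, "]", sep = "")
  if (!is.null(x$features)) cat(" +", length(x$features), "features")
  cat("\n")
  invisible(x)
}

# normalize controlled-vocabulary feature terms: case-fold + trim + drop empties
normalize_features <- function(features) {
  f <- tolower(stringr::str_squish(as.character(features)))
  unique(f[!is.na(f) & nzchar(f)])
}
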