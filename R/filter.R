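#' Filter variants to the rare, functional set
#'
#' Applies the pre-segregation filters of the automated analysis: function
#' class, population allele frequency, read depth, RVIS intolerance
#' percentile and coordinate restriction. Row order is preserved.
#'
#' A variant is *rare* iff its frequency is strictly below
#' `config$maf_threshold` in **every** configured database in which it has
#' been observed; absence from a database (empty cell / `NA`) counts as rare
#' there. The depth filter applies to the proband's call by default
#' (`config$depth_scope = "all"` extends it to every genotyped member); a
#' call with no recorded depth passes a disabled filter only
#' (`depth_min = 0`). The RVIS filter reads the `rvis_percentile` column and
#' keeps variants with percentile at or below the ceiling; variants in genes
#' without an RVIS annotation are retained.
#'
#' @param variants A variant tibble (see [variant-tables]).
#' @param config An [analysis_config()].
#' @param pedigree The family [pedigree()]; required when the depth filter
#'   is enabled (to identify the proband's depth column).
#' @return The retained subset of `variants`, original order preserved.
#' @export
filter_rare_functional <- function(variants, config, pedigree = NULL) {
  v <- as_tibble(variants)
  if (nrow(v) == 0) return(v)
  keep <- v$func_class %in% config$include_func_classes

  for (db in config$maf_databases) {
    col <- paste0("maf_", db)
    if (!col %in% names(v)) next  # database not annotated: unobserved = rare
    maf <- v[[col]]
    keep <- keep & (is.na(maf) | maf < config$maf_threshold)
  }

  if (config$depth_min > 0) {
    if (identical(config$depth_scope, "proband")) {
      if (is.null(pedigree)) {
        abort("Depth filtering on the proband requires a pedigree.",
              class = "mm_config_error")
      }
      cols <- paste0("DP_", proband_id(pedigree))
    } else {
      cols <- dp_cols(v)
    }
    for (col in intersect(cols, names(v))) {
      d <- v[[col]]
      keep <- keep & !is.na(d) & d >= config$depth_min
    }
  }

  if (!is.null(config$rvis_percentile_max) && "rvis_percentile" %in% names(v)) {
    rvis <- suppressWarnings(as.numeric(v$rvis_percentile))
    keep <- keep & (is.na(rvis) | rvis <= config$rvis_percentile_max)
  }

  if (!is.null(config$regions)) {
    keep <- keep & purrr::map_lgl(seq_len(nrow(v)), function(i) {
      in_regions(v$chrom[i], v$pos[i], config$regions)
    })
  }

  v[keep, ]
}
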