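#' Analysis configuration
#'
#' Holds every user-tunable threshold of the variant analysis: the
#' minor-allele-frequency cutoff and the population databases it is tested
#' against, the minimum read depth, the RVIS intolerance-percentile ceiling,
#' an optional coordinate restriction, the inheritance model, and the
#' variant function classes retained.
#'
#' The defaults reproduce the automated run: MAF < 1% in every configured
#' population database, all coding classes (missense, nonsense, stop-loss,
#' synonymous-affecting-splicing, indels) plus splice-site variants, no
#' depth/RVIS/region restriction.
#'
#' @param maf_threshold Strict upper bound on the allele frequency, in
#'   `[0, 1]`. A variant is rare iff its frequency is `< maf_threshold` in
#'   every configured database where it has been observed; a variant absent
#'   from a database is treated as rare there.
#' @param maf_databases Character vector of database names; each corresponds
#'   to a `maf_<name>` column in the annotation table.
#' @param depth_min Minimum read depth (0 disables the filter).
#' @param depth_scope `"proband"` (default) applies `depth_min` to the
#'   proband's call only; `"all"` to every genotyped member.
#' @param rvis_percentile_max RVIS percentile ceiling in `(0, 100]`, or `NULL`
#'   to disable. Low percentiles mark genes intolerant to variation.
#' @param regions Optional data frame with `chrom`, `start`, `end` columns
#'   giving half-open 1-based intervals `[start, end)`; variants outside all
#'   intervals are removed. `NULL` disables coordinate restriction.
#' @param model Inheritance model name (see [inheritance_models()]), used by
#'   [analyze_family()] when a single model is requested.
#' @param include_func_classes Function classes retained by the filter.
#' @return An `mm_config` list.
#' @export
analysis_config <- function(maf_threshold = 0.01,
                            maf_databases = c("1000g", "evs", "exac", "gnomad"),
                            depth_min = 0L,
                            depth_scope = c("proband", "all"),
                            rvis_percentile_max = NULL,
                            regions = NULL,
                            model = NULL,
                            include_func_classes = setdiff(FUNC_CLASSES,
                                                           c("SYNONYMOUS", "OTHER"))) {
  depth_scope <- match.arg(depth_scope)
  if (!is.numeric(maf_threshold) || maf_threshold < 0 || maf_threshold > 1) {
    abort("maf_threshold must lie in [0, 1].", class = "mm_config_error")
  }
  if (!is.numeric(depth_min) || depth_min < 0) {
    abort("depth_min must be a non-negative integer.", class = "mm_config_error")
  }
  if (!is.null(rvis_percentile_max) &&
      (!is.numeric(rvis_percentile_max) || rvis_percentile_max <= 0 ||
       rvis_percentile_max > 100)) {
    abort("rvis_percentile_max must lie in (0, 100] or be NULL.", class = "mm_config_error")
  }
  if (!is.null(regions)) {
    regions <- as_tibble(regions)
    if (!all(c("chrom", "start", "end") %in% names(regions))) {
      abort("regions needs chrom, start, end columns.", class = "mm_config_error")
    }
    regions <- mutate(regions, chrom = normalize_chrom(.data$chrom),
                      start = as.integer(.data$start), end = as.integer(.data$end))
    if (any(regions$end <= regions$start)) {
      abort("regions are half-open [start, end); end must exceed start.",
            class = "mm_config_error")
    }
  }
  bad_fc <- setdiff(include_func_classes, FUNC_CLASSES)
  if (length(bad_fc) > 0) {
    abort(paste0("Unknown function class(es): ", paste(bad_fc, collapse = ", ")),
          class = "mm_config_error")
  }
  if (!is.null(model)) model <- match.arg(model, inheritance_models())
  structure(
    list(maf_threshold = maf_threshold,
         maf_databases = as.character(maf_databases),
         depth_min = as.integer(depth_min),
         depth_scope = depth_scope,
         rvis_percentile_max = rvis_percentile_max,
         regions = regions,
         model = model,
         include_func_classes = include_func_classes),
    class = "mm_config"
  )
}

#' Read an analysis configuration from YAML
#'
#' The YAML keys mirror the arguments of [analysis_config()]; absent keys
#' take the defaults. `regions` may be given inline as a list of
#' `{chrom, start, end}` maps.
#'
#' @param path Path to the YAML file.
#' @param ... Overrides applied on top of the file's values (e.g. CLI flags).
#' @return An `mm_config`.
#' @export
read_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$regions)) {
    vals$regions <- dplyr::bind_rows(lapply(vals$regions, as_tibble))
  }
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  keep <- intersect(names(vals), names(formals(analysis_config)))
  do.call(analysis_config, vals[keep])
}

#' @export
print.mm_config <- function(x, ...) {
  cat("<analysis config>\n",
      "  MAF < ", x$maf_threshold, " in {", paste(x$maf_databases, collapse = ", "), "}\n",
      "  depth >= ", x$depth_min, " (", x$depth_scope, ")\n",
      "  RVIS percentile <= ", ifelse(is.null(x$rvis_percentile_max), "off",
                                      x$rvis_percentile_max), "\n",
      "  regions: ", ifelse(is.null(x$regions), "off",
                            paste(nrow(x$regions), "interval(s)")), "\n",
      "  classes: ", paste(x$include_func_classes, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

# one-line config snapshot used in result-file provenance
config_snapshot <- function(config) {
  paste0(
    "maf<", config$maf_threshold,
    " dbs=", paste(config$maf_databases, collapse = "+"),
    " depth>=", config$depth_min, "(", config$depth_scope, ")",
    " rvis<=", ifelse(is.null(config$rvis_percentile_max), "off",
                      config$rvis_percentile_max),
    " regions=", ifelse(is.null(config$regions), "off", nrow(config$regions)),
    " classes=", paste(sort(config$include_func_classes), collapse = "+")
  )
}
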