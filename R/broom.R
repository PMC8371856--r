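#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an analysis result into its variant rows
#'
#' @param x An `mm_result`.
#' @param ... Unused.
#' @return The locus-sorted variant tibble with `proband_id` and `model`
#'   prepended.
#' @export
tidy.mm_result <- function(x, ...) {
  dplyr::bind_cols(tibble(proband_id = x$proband_id, model = x$model), x$rows)
}

#' One-row summary of an analysis result
#'
#' @param x An `mm_result`.
#' @param ... Unused.
#' @return Tibble with proband, model, variant/gene counts and the
#'   PASS / PASS_POSSIBLE split.
#' @export
glance.mm_result <- function(x, ...) {
  status <- if ("status" %in% names(x$rows)) x$rows$status else character()
  tibble(
    proband_id = x$proband_id,
    model = x$model,
    n_variants = nrow(x$rows),
    n_genes = dplyr::n_distinct(x$rows$gene[!is.na(x$rows$gene)]),
    n_pass = sum(status == "PASS"),
    n_pass_possible = sum(status == "PASS_POSSIBLE")
  )
}

#' @rdname tidy.mm_result
#' @export
tidy.mm_ddx <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "mm_ddx")
  out
}

#' @rdname glance.mm_result
#' @export
glance.mm_ddx <- function(x, ...) {
  tibble(n_diagnoses = nrow(x),
         top_disease = if (nrow(x)) x$disease_id[1] else NA_character_,
         top_shared = if (nrow(x)) x$n_shared[1] else NA_integer_)
}

#' Tidy a matchmaking registry into its match log
#'
#' @param x An `mm_registry`.
#' @param ... Unused.
#' @return The append-only match log (one row per notified pair).
#' @export
tidy.mm_registry <- function(x, ...) x$match_log

#' @rdname tidy.mm_registry
#' @export
glance.mm_registry <- function(x, ...) {
  tibble(
    build = x$build,
    n_gene_submissions = nrow(x$gene_subs),
    n_unique_genes = dplyr::n_distinct(x$gene_subs$gene),
    n_db_variants = nrow(x$variant_db),
    n_stored_queries = nrow(x$stored_queries),
    n_matches = nrow(x$match_log)
  )
}

#' Plot the gene-level summary of an analysis result
#'
#' Bar chart of retained variants per gene, filled by segregation status.
#'
#' @param object An `mm_result`.
#' @param max_genes Show at most this many genes (by variant count).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mm_result <- function(object, max_genes = 25, ...) {
  df <- tidy(object)
  if (nrow(df) == 0 || !"status" %in% names(df)) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::ggtitle("No variants retained"))
  }
  top <- df |>
    dplyr::count(.data$gene, sort = TRUE) |>
    dplyr::slice_head(n = max_genes)
  df <- filter(df, .data$gene %in% top$gene)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$gene, .data$gene,
                                                      FUN = length),
                                   fill = .data$status)) +
    ggplot2::geom_bar() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "variants",
                  title = paste0(object$model, " — proband ", object$proband_id),
                  fill = "status") +
    ggplot2::theme_minimal()
}

#' Plot a differential-diagnosis ranking
#'
#' Horizontal bars of shared-feature counts for the ranked diagnoses,
#' shaded by the fraction of the disease's features present in the
#' profile.
#'
#' @param object An `mm_ddx`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mm_ddx <- function(object, ...) {
  df <- tidy(object)
  if (nrow(df) == 0) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::ggtitle("No overlapping diseases"))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$disease_id, -.data$rank),
                                   y = .data$n_shared, fill = .data$precision)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "shared features",
                  title = "Differential diagnoses", fill = "precision") +
    ggplot2::theme_minimal()
}

#' Plot phenotype-overlap matches
#'
#' @param object Output tibble of [overlap_match()].
#' @param min_overlap Threshold drawn as a reference line.
#' @return A ggplot object.
#' @export
plot_overlap_matches <- function(object, min_overlap = NULL) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = stats::reorder(.data$individual_id,
                                                       .data$coefficient),
                                    y = .data$coefficient)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "overlap coefficient") +
    ggplot2::theme_minimal()
  if (!is.null(min_overlap)) {
    p <- p + ggplot2::geom_hline(yintercept = min_overlap, linetype = "dashed")
  }
  p
}
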