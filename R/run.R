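# Pipeline orchestration: one call from expression + design/contrasts +
# collections to scored tables, outputs on disk, and the HTML report; plus
# the run-config plumbing the command-line interface uses.

#' Run the full ensemble gene set analysis
#'
#' For every collection and contrast, runs the requested base methods,
#' aggregates them into ensemble score tables, and adds the cross-contrast
#' comparison. All stochastic components draw reproducible sub-streams from
#' the master seed keyed by method, collection and contrast, so results are
#' identical for any worker count.
#'
#' @param em An `expression_matrix`.
#' @param design Samples x coefficients matrix.
#' @param contrasts Coefficients x contrasts matrix.
#' @param collections List of `collection_index` objects (named by label if
#'   unnamed).
#' @param methods Base methods (default [base_method_names()]).
#' @param combine_method P-value combiner (default `"wilkinson"`).
#' @param sort_by Default report sort key (default `"p.adj"`).
#' @param vote_bin Vote-rank bin width (default 5).
#' @param params Per-method parameter overrides (see [run_base_methods()]).
#' @param seed Master seed.
#' @param workers Parallel workers for the method loop.
#' @param verbose Emit per-collection progress messages.
#' @return A `gsa_result`: gene-level statistics, per-collection score
#'   tables (per contrast plus `"comparison"`), rank matrices and the run
#'   configuration echo.
#' @export
gsa_analysis <- function(em, design, contrasts, collections,
                         methods = base_method_names(),
                         combine_method = "wilkinson", sort_by = "p.adj",
                         vote_bin = 5, params = list(), seed = 1,
                         workers = 1, verbose = TRUE) {
  t0 <- Sys.time()
  if (inherits(collections, "collection_index"))
    collections <- list(collections)
  labels <- vapply(collections, `[[`, character(1), "label")
  names(collections) <- labels
  if (verbose) message("Log fold changes are estimated with the gene-wise ",
                       "linear model ...")
  gs <- gene_level_stats(em, design, contrasts)
  cns <- contrast_names(gs)
  out <- list()
  for (label in labels) {
    index <- collections[[label]]
    if (verbose)
      message("Ensemble testing is running on the provided data and ",
              label, " collection (", n_sets(index), " sets)")
    mrms <- lapply(cns, function(cn)
      run_base_methods(gs, em, index, cn, methods = methods,
                       params = params, seed = seed, workers = workers))
    names(mrms) <- cns
    tables <- lapply(mrms, ensemble_scores, gs = gs, index = index,
                     combine_method = combine_method, vote_bin = vote_bin)
    tables$comparison <- comparative_scores(mrms, gs, index,
                                            combine_method = combine_method,
                                            vote_bin = vote_bin)
    ranks <- lapply(mrms, rank_by_method)
    out[[label]] <- list(tables = tables, ranks = ranks, index = index)
  }
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  if (verbose)
    message(sprintf("Ensemble analysis took %.3f seconds.", elapsed))
  structure(
    list(collections = out, gene_stats = gs,
         contrasts_tested = cns,
         config = list(methods = methods, combine_method = combine_method,
                       sort_by = sort_by, vote_bin = vote_bin, seed = seed,
                       workers = workers),
         n_genes = nrow(em$E), n_samples = ncol(em$E)),
    class = "gsa_result")
}

#' @export
print.gsa_result <- function(x, ...) {
  cat("Ensemble gene set analysis result\n")
  cat("Total number of genes:", x$n_genes, "\n")
  cat("Total number of samples:", x$n_samples, "\n")
  cat("Contrasts:", paste(x$contrasts_tested, collapse = ", "), "\n")
  cat("Base GSE methods:", paste(x$config$methods, collapse = ", "), "\n")
  cat("P-values combining method:", x$config$combine_method, "\n")
  cat("Sorting statistic:", x$config$sort_by, "\n")
  cat("Tested gene set collections:\n")
  for (coll in x$collections)
    cat(" ", summarize_collection(coll$index), "\n")
  invisible(x)
}

#' @export
summary.gsa_result <- function(object, n = 10, ...) {
  for (label in names(object$collections)) {
    coll <- object$collections[[label]]
    cat("**** Top", n, "gene sets in the",
        coll$index$name, "collection ****\n")
    for (cn in names(coll$tables)) {
      cat("**", if (cn == "comparison") "Comparison analysis"
          else paste("Contrast", cn), "**\n")
      top <- top_sets(coll$tables[[cn]],
                      sort_by = object$config$sort_by, n = n)
      cat(paste(rownames(top), collapse = " | "), "\n")
    }
  }
  invisible(object)
}

#' Read a run configuration file
#'
#' YAML or JSON (by extension); all paths in the file are interpreted
#' relative to the file's own directory.
#'
#' @param path Config path.
#' @return Named list with a `base_dir` attribute.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  attr(cfg, "base_dir") <- dirname(normalizePath(path))
  cfg
}

cfg_get <- function(cfg, key, default = NULL) {
  if (!is.null(cfg[[key]])) cfg[[key]] else default
}

cfg_path <- function(cfg, key) {
  p <- cfg[[key]]
  if (is.null(p)) return(NULL)
  base <- attr(cfg, "base_dir")
  vapply(p, function(x)
    if (file.exists(x) || is.null(base)) x else file.path(base, x),
    character(1))
}

# Counts are non-negative near-integers with a plausibly large maximum.
looks_like_counts <- function(m) {
  all(m >= 0) && max(abs(m - round(m))) < 1e-8 && max(m) > 50
}

#' Run an analysis from a configuration file
#'
#' Reads the expression (auto-detecting raw counts, which are TMM-normalised
#' and weighted through the count path, versus ready-made log-expression;
#' override with `mode: counts|logexpr`), the design/contrast CSVs and one
#' collection per GMT file, runs [gsa_analysis()], writes the ranked tables
#' under `<out_dir>/ranked-sets/` and, when `report: true`, the HTML report
#' under `<out_dir>/report/`.
#'
#' @param config Path to a YAML/JSON config, or an already-read config list.
#' @param verbose Progress messages (default TRUE).
#' @return The `gsa_result`, invisibly.
#' @export
run_from_config <- function(config, verbose = TRUE) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  design <- read_design_csv(cfg_path(cfg, "design"))
  contrasts <- read_design_csv(cfg_path(cfg, "contrasts"))
  methods <- cfg_get(cfg, "base_methods", base_method_names())
  expr_path <- cfg_path(cfg, "expr")
  if (is.null(expr_path)) expr_path <- cfg_path(cfg, "counts")
  if (is.null(expr_path)) stop("config must name an 'expr' or 'counts' file")
  m <- read_matrix_tsv(expr_path)
  mode <- cfg_get(cfg, "mode", "auto")
  if (mode == "auto") mode <- if (looks_like_counts(m)) "counts" else "logexpr"
  if (mode == "counts") {
    cm <- count_matrix(m)
    cm$norm_factors <- tmm_norm_factors(cm)
    em <- voom_weights(cm, design)
  } else {
    em <- expression_matrix(m)
  }
  min_size <- cfg_get(cfg, "min_set_size", 5)
  gmt_paths <- cfg_path(cfg, "gmt")
  collections <- lapply(seq_along(gmt_paths), function(i) {
    label <- tools::file_path_sans_ext(basename(gmt_paths[[i]]))
    build_index(read_gmt(gmt_paths[[i]]), rownames(em$E),
                min_size = min_size, name = label, label = label)
  })
  res <- gsa_analysis(
    em, design, contrasts, collections, methods = methods,
    combine_method = cfg_get(cfg, "combine_method", "wilkinson"),
    sort_by = cfg_get(cfg, "sort_by", "p.adj"),
    vote_bin = cfg_get(cfg, "vote_bin", 5),
    params = cfg_get(cfg, "method_params", list()),
    seed = cfg_get(cfg, "seed", 1),
    workers = cfg_get(cfg, "workers", 1), verbose = verbose)
  out_dir <- cfg_get(cfg, "out_dir")
  if (!is.null(out_dir)) {
    base <- attr(cfg, "base_dir")
    if (!is.null(base) && !grepl("^/", out_dir))
      out_dir <- file.path(base, out_dir)
    write_result_tables(res, out_dir)
    if (isTRUE(cfg_get(cfg, "report", FALSE)))
      generate_report(res, file.path(out_dir, "report"),
                      number = cfg_get(cfg, "display_top", 20))
  }
  invisible(res)
}

#' Write all ranked tables of a result
#'
#' One TSV per collection x contrast (plus `comparison`) under
#' `<out_dir>/ranked-sets/`.
#'
#' @param result A `gsa_result`.
#' @param out_dir Output directory.
#' @export
write_result_tables <- function(result, out_dir) {
  dir.create(file.path(out_dir, "ranked-sets"), recursive = TRUE,
             showWarnings = FALSE)
  for (label in names(result$collections)) {
    tabs <- result$collections[[label]]$tables
    for (cn in names(tabs))
      write_ranked_table(tabs[[cn]],
                         file.path(out_dir, "ranked-sets",
                                   paste0(label, "-", cn, ".tsv")),
                         sort_by = result$config$sort_by)
  }
  invisible(out_dir)
}

#' Rebuild the HTML index from stored ranked tables
#'
#' Regenerates a report index from the TSVs written by
#' [write_result_tables()] without recomputing any score.
#'
#' @param results_dir Directory holding `ranked-sets/*.tsv`.
#' @param number Rows shown per table (default 20).
#' @return Path of the written index, invisibly.
#' @export
report_from_tables <- function(results_dir, number = 20) {
  tsvs <- sort(list.files(file.path(results_dir, "ranked-sets"),
                          pattern = "\\.tsv$", full.names = TRUE))
  if (length(tsvs) == 0L)
    stop("no ranked tables found under ", results_dir)
  body <- c("<html><head><meta charset='utf-8'>",
            "<title>Ensemble gene set analysis</title></head><body>",
            "<h1>Ensemble gene set analysis report</h1>")
  for (f in tsvs) {
    df <- utils::read.delim(f, check.names = FALSE)
    body <- c(body,
              sprintf("<h2>%s</h2>",
                      html_escape(tools::file_path_sans_ext(basename(f)))),
              sprintf("<p><a href='ranked-sets/%s'>full table</a></p>",
                      basename(f)),
              html_table(utils::head(df[, seq_len(min(10, ncol(df)))],
                                     number)))
  }
  body <- c(body, "</body></html>")
  out <- file.path(results_dir, "index.html")
  writeLines(body, out)
  invisible(out)
}
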