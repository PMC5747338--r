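# Plot-data extractors (pure functions of score tables, oracle-testable as
# joins/sorts/filters), simple base-graphics renderers, and the static HTML
# report.

p_like_keys <- c("p.value", "p.adj", "min.pvalue")

#' Gene-level heatmap data for one set
#'
#' Log-fold-changes of the set's expressed genes across contrasts (column
#' order follows the contrast matrix), a per-gene significance flag (gene
#' FDR <= 0.05 in at least one contrast), and the full per-gene top-table
#' rows for all contrasts for CSV export.
#'
#' @param gs A `gene_stats` object.
#' @param index A `collection_index`.
#' @param set_name Gene set name.
#' @param contrast `"all"` (default) or a single contrast name.
#' @param symbols Optional feature-to-symbol map for row labels.
#' @return List with `matrix`, `significant` and `csv`.
#' @export
set_heatmap_data <- function(gs, index, set_name, contrast = "all",
                             symbols = NULL) {
  s <- get_set_by_name(index, set_name)
  idx <- index$index[[match(set_name, names(index$sets))]]
  if (length(idx) == 0L) stop("no expressed members for set ", set_name)
  ctr <- if (identical(contrast, "all")) contrast_names(gs) else contrast
  if (!all(ctr %in% contrast_names(gs)))
    stop("unknown contrast in ", paste(ctr, collapse = ", "))
  m <- gs$logFC[idx, ctr, drop = FALSE]
  ids <- gs$gene_ids[idx]
  labels <- if (is.null(symbols)) ids else {
    sy <- unname(symbols[ids]); ifelse(is.na(sy), ids, sy)
  }
  rownames(m) <- labels
  sig <- apply(gs$fdr[idx, ctr, drop = FALSE] <= 0.05, 1, any)
  names(sig) <- labels
  csv <- do.call(rbind, lapply(ctr, function(cn) {
    tt <- top_table(gs, cn, symbols = symbols)
    tt <- tt[tt$GeneID %in% ids, , drop = FALSE]
    cbind(Contrast = cn, tt)
  }))
  list(matrix = m, significant = sig, csv = csv)
}

#' Classical MDS of base methods by ranking similarity
#'
#' Dissimilarity between two methods is one minus the Spearman correlation of
#' their rank columns; classical (Torgerson) scaling of the doubly-centred
#' squared dissimilarities gives two coordinates per method, sign-fixed so
#' the first method has non-negative coordinates.
#'
#' @param ranks Sets x methods rank matrix (>= 3 methods).
#' @return Methods x 2 coordinate matrix.
#' @export
methods_mds <- function(ranks) {
  if (ncol(ranks) < 3L) stop("need at least 3 methods for an MDS plot")
  C <- suppressWarnings(stats::cor(ranks, method = "spearman"))
  C[is.na(C)] <- 0                     # constant rank column: no information
  diag(C) <- 1
  D <- 1 - C
  xy <- suppressWarnings(stats::cmdscale(stats::as.dist(D), k = 2))
  if (ncol(xy) < 2L)                   # degenerate geometry: pad with zeros
    xy <- cbind(xy, matrix(0, nrow(xy), 2 - ncol(xy)))
  rownames(xy) <- colnames(ranks)
  for (j in 1:2) if (xy[1, j] < 0) xy[, j] <- -xy[, j]
  colnames(xy) <- c("dim1", "dim2")
  xy
}

#' Bubble summary plot data
#'
#' One bubble per set: x is `-log10(score)` for p-like axes and the raw value
#' for rank-like axes, y is the mean absolute set log-fold-change. The
#' directional variant sizes bubbles by the significance score and colours by
#' direction; the rank variant sizes by set cardinality and colours by rank
#' under the active sort. Sets beyond `x_cutoff` (raw scale) are dropped.
#' Labels flag the `top_k` sets under the active sort plus up to
#' `highlight_extra` sets whose significance scores are in the collection's
#' top `highlight_extra` but fall outside the `top_k` (distinct highlight
#' class).
#'
#' @param table An `ensemble_table`.
#' @param x_axis Score for the x axis (default `"p.adj"`).
#' @param x_cutoff Optional raw-scale cutoff retaining sets with score <=
#'   cutoff.
#' @param variant `"directional"` or `"rank"`.
#' @param sort_by Active sort key (defaults to `x_axis`).
#' @param top_k Number of top sets to label (default 10).
#' @param highlight_extra Size of the significance-based highlight pool
#'   (default 5).
#' @return Data frame with columns set, x, y, size, colour_key, label,
#'   highlight.
#' @export
summary_plot_data <- function(table, x_axis = "p.adj", x_cutoff = NULL,
                              variant = c("directional", "rank"),
                              sort_by = x_axis, top_k = 10,
                              highlight_extra = 5) {
  variant <- match.arg(variant)
  if (nrow(table) == 0L) stop("empty score table")
  if (!x_axis %in% colnames(table)) stop("unknown x_axis '", x_axis, "'")
  raw <- table[[x_axis]]
  keep <- if (is.null(x_cutoff)) rep(TRUE, nrow(table)) else raw <= x_cutoff
  tab <- table[keep, , drop = FALSE]
  raw <- raw[keep]
  x <- if (x_axis %in% p_like_keys) -log10(pmax(raw, 1e-300)) else raw
  sorted <- top_sets(tab, sort_by = sort_by, n = Inf)
  top_names <- rownames(sorted)[seq_len(min(top_k, nrow(sorted)))]
  by_sig <- rownames(top_sets(tab, sort_by = "significance", n = Inf))
  hi_pool <- by_sig[seq_len(min(highlight_extra, length(by_sig)))]
  highlight <- setdiff(hi_pool, top_names)
  rank_pos <- match(rownames(tab), rownames(sorted))
  data.frame(
    set = rownames(tab), x = x, y = tab$avg.logfc,
    size = if (variant == "directional") tab$significance else tab$n_genes,
    colour_key = if (variant == "directional") {
      c("down", "neutral", "up")[tab$direction + 2]
    } else rank_pos,
    label = rownames(tab) %in% c(top_names, highlight),
    highlight = rownames(tab) %in% highlight,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Contrast-versus-contrast summary plot data
#'
#' Inner join of two score tables from the same collection;
#' `-log10(p.adj)` per axis and a joint-direction class: `both-up`,
#' `both-down`, `opposite` (the purple class) or `neutral`.
#'
#' @param tableA,tableB `ensemble_table`s of the same collection.
#' @return Data frame with set, x, y, class.
#' @export
comparative_summary_plot_data <- function(tableA, tableB) {
  common <- intersect(rownames(tableA), rownames(tableB))
  if (length(common) == 0L) stop("tables share no gene sets")
  a <- tableA[common, ]; b <- tableB[common, ]
  cls <- ifelse(a$direction == 0 | b$direction == 0, "neutral",
         ifelse(a$direction == b$direction,
                ifelse(a$direction > 0, "both-up", "both-down"),
                "opposite"))
  data.frame(set = common,
             x = -log10(pmax(a$p.adj, 1e-300)),
             y = -log10(pmax(b$p.adj, 1e-300)),
             class = cls, row.names = NULL, stringsAsFactors = FALSE)
}

#' Bar plot data for the top sets
#'
#' Top `n` sets under `sort_by`; bar length is `-log10` of the value for
#' p-like scores (default `p.adj`) or the raw value otherwise; colour keys
#' follow set direction (`up` / `down` / `neutral`).
#'
#' @param table An `ensemble_table`.
#' @param n Number of bars (default 20).
#' @param value Score plotted (default `"p.adj"`).
#' @param sort_by Ordering key (default `"p.adj"`).
#' @return Data frame with set, value, colour_key in plot order.
#' @export
bar_plot_data <- function(table, n = 20, value = "p.adj",
                          sort_by = "p.adj") {
  if (n <= 0) stop("n must be positive")
  top <- top_sets(table, sort_by = sort_by, n = n)
  v <- top[[value]]
  if (value %in% p_like_keys) v <- -log10(pmax(v, 1e-300))
  data.frame(set = rownames(top), value = v,
             colour_key = c("down", "neutral", "up")[top$direction + 2],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Summary heatmap data across contrasts
#'
#' Rows are the top `n` sets of the comparison table under `sort_by`; cells
#' hold the requested per-contrast score (default `avg.logfc.dir`), with an
#' optional annotation matrix of a second score.
#'
#' @param comparison The comparative `ensemble_table`.
#' @param contrast_tables Named list of per-contrast `ensemble_table`s.
#' @param n Number of rows (default 20).
#' @param values Cell score name (default `"avg.logfc.dir"`).
#' @param sort_by Row selection key (default `"p.adj"`).
#' @param show_vals Optional annotation score name.
#' @return List with `matrix` and optional `annotation`.
#' @export
summary_heatmap_data <- function(comparison, contrast_tables, n = 20,
                                 values = "avg.logfc.dir",
                                 sort_by = "p.adj", show_vals = NULL) {
  if (!values %in% colnames(comparison))
    stop("unknown value key '", values, "'")
  top <- top_sets(comparison, sort_by = sort_by, n = n)
  sets <- rownames(top)
  grab <- function(key) {
    m <- sapply(contrast_tables, function(tb) {
      v <- tb[sets, key]
      ifelse(is.na(v), NA_real_, v)
    })
    m <- matrix(m, nrow = length(sets),
                dimnames = list(sets, names(contrast_tables)))
    m
  }
  out <- list(matrix = grab(values))
  if (!is.null(show_vals)) out$annotation <- grab(show_vals)
  out
}

# --- renderers (base graphics; PNG always, SVG when cairo is available) ----

save_plot <- function(file_base, draw, width = 7, height = 6) {
  grDevices::png(paste0(file_base, ".png"), width = width * 100,
                 height = height * 100, res = 100)
  draw()
  grDevices::dev.off()
  if (isTRUE(capabilities("cairo"))) {
    grDevices::svg(paste0(file_base, ".svg"), width = width,
                   height = height)
    draw()
    grDevices::dev.off()
  }
  invisible(file_base)
}

dir_cols <- c(up = "#d7301f", down = "#0570b0", neutral = "#7b3294")

render_summary_plot <- function(spd, file_base, x_lab, title) {
  save_plot(file_base, function() {
    cex <- 0.5 + 2.5 * (spd$size - min(spd$size)) /
      max(1e-9, diff(range(spd$size)))
    col <- if (is.numeric(spd$colour_key)) {
      grDevices::hcl.colors(max(spd$colour_key), "viridis")[spd$colour_key]
    } else dir_cols[spd$colour_key]
    graphics::plot(spd$x, spd$y, cex = cex, pch = 19,
                   col = grDevices::adjustcolor(col, 0.7),
                   xlab = x_lab, ylab = "avg |logFC|", main = title)
    lab <- spd[spd$label, ]
    if (nrow(lab))
      graphics::text(lab$x, lab$y, labels = lab$set, cex = 0.6, pos = 3,
                     col = ifelse(lab$highlight, "blue", "black"))
  })
}

render_bar_plot <- function(bpd, file_base, title) {
  save_plot(file_base, function() {
    op <- graphics::par(mar = c(4, 14, 3, 1))
    on.exit(graphics::par(op))
    graphics::barplot(rev(bpd$value), names.arg = rev(bpd$set),
                      horiz = TRUE, las = 1, cex.names = 0.55,
                      col = rev(dir_cols[bpd$colour_key]),
                      xlab = "-log10(p.adj)", main = title)
  })
}

render_mds_plot <- function(xy, file_base, title) {
  save_plot(file_base, function() {
    graphics::plot(xy, type = "n", xlab = "dim 1", ylab = "dim 2",
                   main = title)
    graphics::text(xy, labels = rownames(xy), cex = 0.9)
  })
}

render_heatmap <- function(m, file_base, title) {
  save_plot(file_base, function() {
    op <- graphics::par(mar = c(6, 10, 3, 1))
    on.exit(graphics::par(op))
    pal <- grDevices::hcl.colors(51, "Blue-Red 2")
    lim <- max(abs(m), na.rm = TRUE)
    graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m),
                    zlim = c(-lim, lim), col = pal, axes = FALSE,
                    xlab = "", ylab = "", main = title)
    graphics::axis(1, seq_len(ncol(m)), colnames(m), las = 2, cex.axis = 0.7)
    graphics::axis(2, seq_len(nrow(m)), rownames(m), las = 1, cex.axis = 0.6)
  })
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

html_table <- function(df, digits = 4) {
  fmt <- function(v) if (is.numeric(v)) signif(v, digits) else html_escape(v)
  cells <- vapply(df, function(col) as.character(fmt(col)), character(nrow(df)))
  cells <- matrix(cells, nrow = nrow(df))
  paste0("<table><tr>",
         paste0("<th>", html_escape(colnames(df)), "</th>", collapse = ""),
         "</tr>\n",
         paste(apply(cells, 1, function(r)
           paste0("<tr>", paste0("<td>", r, "</td>", collapse = ""),
                  "</tr>")), collapse = "\n"),
         "</table>")
}

#' Generate the static HTML report
#'
#' Assembles a self-contained static site for a finished analysis: an index
#' page echoing the run parameters, per collection x contrast sections with
#' the top-`number` ranked sets, links to the full ranked TSV tables and the
#' rendered plots (bar, bubble summary, method MDS), and a cross-contrast
#' comparison section. No network resources; regeneration from the same
#' inputs is byte-stable for the tables.
#'
#' @param result A `gsa_result` from [gsa_analysis()].
#' @param out_dir Output directory (created if needed).
#' @param number Rows shown per table (default 20).
#' @return The output directory, invisibly.
#' @export
generate_report <- function(result, out_dir, number = 20) {
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create report directory ", out_dir)
  for (d in c("ranked-sets", "plots"))
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  body <- c("<html><head><meta charset='utf-8'><title>Ensemble gene set analysis</title>",
            "<style>body{font-family:sans-serif;margin:2em}table{border-collapse:collapse}",
            "td,th{border:1px solid #999;padding:2px 6px;font-size:12px}</style>",
            "</head><body>",
            "<h1>Ensemble gene set analysis report</h1>",
            "<h2>Analysis parameters</h2><ul>",
            sprintf("<li>Base methods: %s</li>",
                    paste(result$config$methods, collapse = ", ")),
            sprintf("<li>P-value combining method: %s</li>",
                    result$config$combine_method),
            sprintf("<li>Sorting statistic: %s</li>", result$config$sort_by),
            sprintf("<li>Contrasts: %s</li>",
                    paste(result$contrasts_tested, collapse = ", ")),
            sprintf("<li>Seed: %s</li>", result$config$seed),
            "</ul>")
  for (label in names(result$collections)) {
    coll <- result$collections[[label]]
    body <- c(body, sprintf("<h2>Collection %s</h2>", html_escape(label)))
    for (cn in names(coll$tables)) {
      tab <- coll$tables[[cn]]
      slug <- paste0(label, "-", cn)
      tsv <- file.path("ranked-sets", paste0(slug, ".tsv"))
      write_ranked_table(tab, file.path(out_dir, tsv),
                         sort_by = result$config$sort_by)
      top <- top_sets(tab, sort_by = result$config$sort_by, n = number)
      shown <- cbind(set = rownames(top),
                     top[, c("Rank", "p.value", "p.adj", "direction",
                             "vote.rank", "avg.rank", "med.rank",
                             "avg.logfc", "significance")])
      plots <- character(0)
      bar_base <- file.path(out_dir, "plots", paste0(slug, "-bars"))
      render_bar_plot(bar_plot_data(tab, n = min(number, nrow(tab)),
                                    sort_by = result$config$sort_by),
                      bar_base, paste(label, cn))
      plots <- c(plots, paste0("plots/", slug, "-bars.png"))
      sum_base <- file.path(out_dir, "plots", paste0(slug, "-summary"))
      render_summary_plot(summary_plot_data(tab), sum_base,
                          "-log10(p.adj)", paste(label, cn))
      plots <- c(plots, paste0("plots/", slug, "-summary.png"))
      if (cn != "comparison" && length(attr(tab, "methods")) >= 3) {
        mds_base <- file.path(out_dir, "plots", paste0(slug, "-mds"))
        render_mds_plot(methods_mds(coll$ranks[[cn]]), mds_base,
                        paste(label, cn))
        plots <- c(plots, paste0("plots/", slug, "-mds.png"))
      }
      body <- c(body,
                sprintf("<h3>%s</h3>", html_escape(cn)),
                sprintf("<p><a href='%s'>full ranked table (TSV)</a></p>",
                        tsv),
                html_table(shown),
                paste(sprintf("<p><img src='%s' width='640'></p>", plots),
                      collapse = "\n"))
    }
  }
  body <- c(body, "</body></html>")
  writeLines(body, file.path(out_dir, "index.html"))
  invisible(out_dir)
}

#' Write a ranked ensemble table as TSV
#'
#' Full table sorted by the given key, with a set-name leading column; the
#' on-disk byte content is deterministic for identical inputs.
#'
#' @param table An `ensemble_table`.
#' @param path Output path.
#' @param sort_by Sort key (default `"p.adj"`).
#' @export
write_ranked_table <- function(table, path, sort_by = "p.adj") {
  out <- top_sets(table, sort_by = sort_by, n = Inf)
  df <- cbind(set = rownames(out), as.data.frame(out))
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
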