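# Consensus scoring: combine per-method p-values and rankings into ensemble
# scores per contrast and across contrasts.

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment with monotone enforcement, capped at 1;
#' invariant to input order.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Combine a vector of p-values
#'
#' Meta-analytic combination of k p-values from different base methods.
#' Inputs are clipped to `[1e-300, 1 - 1e-15]` to keep the log/logit
#' transforms finite; a single p-value is returned unchanged by every method.
#'
#' Methods: `fisher` (chi-square tail of -2 sum log p on 2k df), `wilkinson`
#' (first order statistic, `1 - (1 - p_min)^k`), `average` (normal
#' approximation `z = (0.5 - pbar) sqrt(12 k)`), `logitp` (scaled-t tail of
#' the summed logits on 5k + 4 df), `sump` (exact Irwin-Hall lower tail of
#' the sum), `sumz` (Stouffer), `votep` (binomial upper tail of the count of
#' p below 0.5), `median` (Beta order-statistic CDF at the lower median).
#'
#' @param p Numeric vector of valid p-values (length >= 1).
#' @param method Combination method name.
#' @return Combined p-value.
#' @export
combine_pvalues <- function(p,
                            method = c("wilkinson", "fisher", "average",
                                       "logitp", "sump", "sumz", "votep",
                                       "median")) {
  method <- match.arg(method)
  if (length(p) == 0L) stop("no p-values to combine")
  p <- pmin(pmax(p, 1e-300), 1 - 1e-15)
  k <- length(p)
  if (k == 1L) return(p)
  switch(method,
    fisher = stats::pchisq(-2 * sum(log(p)), df = 2 * k,
                           lower.tail = FALSE),
    wilkinson = 1 - (1 - min(p))^k,
    average = stats::pnorm((0.5 - mean(p)) * sqrt(12 * k),
                           lower.tail = FALSE),
    logitp = {
      tstat <- -sum(log(p / (1 - p))) /
        sqrt(k * pi^2 * (5 * k + 2) / (3 * (5 * k + 4)))
      stats::pt(tstat, df = 5 * k + 4, lower.tail = FALSE)
    },
    sump = irwin_hall_cdf(sum(p), k),
    sumz = stats::pnorm(sum(stats::qnorm(p, lower.tail = FALSE)) / sqrt(k),
                        lower.tail = FALSE),
    votep = stats::pbinom(sum(p < 0.5) - 1, k, 0.5, lower.tail = FALSE),
    median = {
      r <- ceiling(k / 2)
      stats::pbeta(sort(p)[r], r, k - r + 1)
    })
}

#' Irwin-Hall cumulative distribution
#'
#' Exact lower-tail probability that the sum of k independent Uniform(0,1)
#' variables is at most `s` (the alternating-sign binomial expansion).
#'
#' @param s Sum of the uniforms.
#' @param k Number of uniforms.
#' @return `P(S <= s)`.
#' @export
irwin_hall_cdf <- function(s, k) {
  if (s <= 0) return(0)
  if (s >= k) return(1)
  j <- 0:floor(s)
  val <- sum((-1)^j * choose(k, j) * (s - j)^k) / factorial(k)
  min(max(val, 0), 1)
}

#' Rank gene sets within each base method
#'
#' Ascending rank by p-value within each method column over its valid
#' entries; ties share the minimum rank; invalid entries get rank
#' `(number of valid sets) + 1`.
#'
#' @param mrm A `method_result`.
#' @return Integer sets x methods rank matrix.
#' @export
rank_by_method <- function(mrm) {
  ranks <- matrix(NA_real_, nrow(mrm$p), ncol(mrm$p),
                  dimnames = dimnames(mrm$p))
  for (j in seq_len(ncol(mrm$p))) {
    v <- mrm$valid[, j]
    nv <- sum(v)
    ranks[v, j] <- rank(mrm$p[v, j], ties.method = "min")
    ranks[!v, j] <- nv + 1
  }
  ranks
}

# Modal bin of ceiling(rank / bin), ties to the smallest bin.
vote_rank_of <- function(ranks, bin) {
  b <- ceiling(ranks / bin)
  tab <- table(b)
  best <- as.integer(names(tab)[tab == max(tab)])
  bin * min(best)
}

# Lower median: element at floor((k + 1) / 2) of the sorted values.
lower_median <- function(x) sort(x)[floor((length(x) + 1) / 2)]

# Per-set gene-level summaries for one contrast: mean |logFC|, majority
# direction (sign of the mean logFC), and the mean logFC over genes whose
# sign matches that direction.
set_gene_summaries <- function(gs, index, contrast) {
  lfc <- gs$logFC[, contrast]
  t(vapply(index$index, function(idx) {
    v <- lfc[idx]
    dir <- sign(mean(v))
    matched <- v[sign(v) == dir]
    c(avg_logfc = mean(abs(v)), direction = dir,
      avg_logfc_dir = if (length(matched)) mean(matched) else 0,
      n_genes = length(idx))
  }, numeric(4)))
}

# Shared scoring core for per-contrast and comparative tables.
score_core <- function(pm, dm, vm, gene_sum, combine_method, vote_bin,
                       contrast, collection) {
  usable <- rowSums(vm) > 0
  if (!all(usable))
    warning(sum(!usable), " set(s) failed all base methods and were dropped")
  pm <- pm[usable, , drop = FALSE]
  vm <- vm[usable, , drop = FALSE]
  gene_sum <- gene_sum[usable, , drop = FALSE]
  ranks <- rank_by_method(structure(list(p = pm, valid = vm),
                                    class = "method_result"))
  S <- nrow(pm)
  p_comb <- min_p <- avg_r <- med_r <- min_r <- vote_r <- numeric(S)
  nmeth <- integer(S)
  for (i in seq_len(S)) {
    v <- vm[i, ]
    p_comb[i] <- combine_pvalues(pm[i, v], method = combine_method)
    min_p[i] <- min(pm[i, v])
    rv <- ranks[i, v]
    avg_r[i] <- mean(rv)
    med_r[i] <- lower_median(rv)
    min_r[i] <- min(rv)
    vote_r[i] <- vote_rank_of(rv, vote_bin)
    nmeth[i] <- sum(v)
  }
  p_adj <- bh_adjust(p_comb)
  sig_raw <- gene_sum[, "avg_logfc"] * -log10(pmax(p_adj, 1e-300))
  rng <- range(sig_raw)
  significance <- if (diff(rng) > 0)
    pmin(pmax(100 * (sig_raw - rng[1]) / diff(rng), 0), 100) else rep(50, S)
  out <- data.frame(
    id = rownames(pm), p.value = p_comb, p.adj = p_adj,
    direction = gene_sum[, "direction"], vote.rank = vote_r,
    avg.rank = avg_r, med.rank = med_r, min.pvalue = min_p,
    min.rank = min_r, avg.logfc = gene_sum[, "avg_logfc"],
    avg.logfc.dir = gene_sum[, "avg_logfc_dir"],
    significance = significance, n_methods = nmeth,
    n_genes = gene_sum[, "n_genes"],
    row.names = rownames(pm), check.names = FALSE,
    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(ranks))
  attr(out, "contrast") <- contrast
  attr(out, "collection") <- collection
  attr(out, "methods") <- colnames(pm)
  class(out) <- c("ensemble_table", "data.frame")
  out
}

#' Ensemble consensus scores for one contrast
#'
#' Combines the per-method p-values (over valid methods only) with the chosen
#' combiner, BH-adjusts across sets, aggregates per-method rankings into
#' min/average/median/vote ranks, and attaches set-level fold-change
#' summaries and the min-max scaled significance score
#' `|avg.logfc| * -log10(p.adj)` (0-100 within collection x contrast; all 50
#' when constant).
#'
#' @param mrm A `method_result` for one contrast.
#' @param gs The `gene_stats` the methods consumed.
#' @param index The `collection_index`.
#' @param combine_method P-value combiner (default `"wilkinson"`).
#' @param vote_bin Rank-bin width for the vote rank (default 5).
#' @return An `ensemble_table` data frame, one row per scored set, with the
#'   per-method ranks as trailing columns.
#' @export
ensemble_scores <- function(mrm, gs, index, combine_method = "wilkinson",
                            vote_bin = 5) {
  gene_sum <- set_gene_summaries(gs, index, mrm$contrast)
  score_core(mrm$p, mrm$direction, mrm$valid, gene_sum, combine_method,
             vote_bin, mrm$contrast, mrm$collection)
}

#' Comparative (cross-contrast) consensus scores
#'
#' For every base method, its per-contrast p-values are first combined (same
#' combiner) into a method-level comparison p-value; ranks and all ensemble
#' scores are then computed exactly as for a single contrast. Set-level
#' fold-change summaries are averaged over contrasts, and the comparison
#' direction is the sign of the mean of the per-contrast signed means (0 when
#' contrasts cancel). With a single contrast the comparison table equals that
#' contrast's table.
#'
#' @param mrm_list Named list of `method_result` objects, one per contrast.
#' @param gs A `gene_stats` object.
#' @param index The `collection_index`.
#' @inheritParams ensemble_scores
#' @return An `ensemble_table` for the cross-contrast comparison.
#' @export
comparative_scores <- function(mrm_list, gs, index,
                               combine_method = "wilkinson", vote_bin = 5) {
  if (length(mrm_list) == 0L) stop("need at least one contrast")
  methods <- mrm_list[[1]]$methods
  S <- nrow(mrm_list[[1]]$p)
  pm <- matrix(NA_real_, S, length(methods),
               dimnames = list(rownames(mrm_list[[1]]$p), methods))
  dm <- pm; vm <- matrix(FALSE, S, length(methods), dimnames = dimnames(pm))
  for (i in seq_len(S)) {
    for (j in seq_along(methods)) {
      ps <- vapply(mrm_list, function(m) m$p[i, j], numeric(1))
      ok <- vapply(mrm_list, function(m) m$valid[i, j], logical(1))
      if (any(ok)) {
        pm[i, j] <- combine_pvalues(ps[ok], method = combine_method)
        dsum <- sum(vapply(mrm_list,
                           function(m) m$direction[i, j], numeric(1))[ok])
        dm[i, j] <- sign(dsum)
        vm[i, j] <- TRUE
      }
    }
  }
  sums <- lapply(names(mrm_list), function(cn)
    set_gene_summaries(gs, index, mrm_list[[cn]]$contrast))
  avg_lfc <- rowMeans(sapply(sums, function(s) s[, "avg_logfc"]))
  signed <- rowMeans(sapply(names(mrm_list), function(cn) {
    lfc <- gs$logFC[, mrm_list[[cn]]$contrast]
    vapply(index$index, function(idx) mean(lfc[idx]), numeric(1))
  }))
  dir <- sign(signed)
  avg_lfc_dir <- rowMeans(sapply(sums, function(s) s[, "avg_logfc_dir"]))
  gene_sum <- cbind(avg_logfc = avg_lfc, direction = dir,
                    avg_logfc_dir = avg_lfc_dir,
                    n_genes = lengths(index$index))
  rownames(gene_sum) <- rownames(pm)
  score_core(pm, dm, vm, gene_sum, combine_method, vote_bin,
             "comparison", mrm_list[[1]]$collection)
}

#' Retrieve the top ranked gene sets
#'
#' Sorts an ensemble table by any consensus score or any base method's rank
#' column: ascending for p-like and rank-like keys, descending for
#' `significance`, `avg.logfc` and `avg.logfc.dir`; ties broken by set name.
#' A `Rank` column reports the 1-based position under the chosen key.
#'
#' @param table An `ensemble_table`.
#' @param sort_by Sort key (default `"p.adj"`).
#' @param n Number of sets to return (default 10; `Inf` for all).
#' @return The top rows with a leading `Rank` column.
#' @export
top_sets <- function(table, sort_by = "p.adj", n = 10) {
  keys <- setdiff(colnames(table), c("id", "n_methods", "n_genes"))
  if (!sort_by %in% keys)
    stop("unknown sort key '", sort_by, "'; available: ",
         paste(keys, collapse = ", "))
  descending <- sort_by %in% c("significance", "avg.logfc", "avg.logfc.dir")
  v <- table[[sort_by]]
  ord <- order(if (descending) -v else v, rownames(table))
  out <- table[ord, , drop = FALSE]
  out <- cbind(Rank = seq_len(nrow(out)), out)
  utils::head(out, n)
}

#' @export
print.ensemble_table <- function(x, ...) {
  cat("Ensemble gene set scores -", attr(x, "collection"), "/",
      attr(x, "contrast"), "\n")
  cat(nrow(x), "sets,", length(attr(x, "methods")), "base methods\n")
  print.data.frame(utils::head(as.data.frame(x)[, seq_len(
    min(9, ncol(x)))], 10), digits = 4)
  invisible(x)
}
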