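# Per-sample set-score methods. Each turns the expression matrix into a
# sets x samples activity matrix; a shared set-level linear-model contrast
# test converts scores into per-contrast p-values.

standardize_rows <- function(E) {
  mu <- rowMeans(E)
  sdv <- apply(E, 1, stats::sd)
  Z <- (E - mu) / ifelse(sdv > 0, sdv, 1)
  attr(Z, "zero_var") <- sdv == 0
  Z
}

#' PLAGE set activity scores
#'
#' Per-set activity is the first right-singular vector of the
#' gene-standardised set submatrix, sign-aligned so the summed correlation
#' with member gene profiles is non-negative. Zero-variance member genes are
#' dropped with a warning; a set empty after dropping is returned as NA and
#' flagged invalid downstream.
#'
#' @param em An `expression_matrix` (2+ samples).
#' @param index A `collection_index` over the expression rows.
#' @return A `set_scores` object: sets x samples matrix plus method tag.
#' @export
plage_scores <- function(em, index) {
  if (ncol(em$E) < 2L) stop("PLAGE needs at least two samples")
  Z <- standardize_rows(em$E)
  zero <- attr(Z, "zero_var")
  scores <- matrix(NA_real_, n_sets(index), ncol(em$E),
                   dimnames = list(names(index$sets), colnames(em$E)))
  dropped_any <- FALSE
  for (i in seq_len(n_sets(index))) {
    idx <- index$index[[i]]
    live <- idx[!zero[idx]]
    if (length(live) < length(idx)) dropped_any <- TRUE
    if (length(live) == 0L) next
    sub <- Z[live, , drop = FALSE]
    sv <- svd(sub, nu = 0, nv = 1)
    v <- sv$v[, 1]
    if (stats::sd(v) > 0) {
      cors <- suppressWarnings(apply(sub, 1, stats::cor, y = v))
      csum <- sum(cors, na.rm = TRUE)
      if (is.finite(csum) && csum < 0) v <- -v
    }
    scores[i, ] <- v
  }
  if (dropped_any)
    warning("zero-variance gene(s) dropped from PLAGE set scores")
  structure(list(scores = scores, method = "plage"), class = "set_scores")
}

#' Combined z-score set scores
#'
#' Per-sample score is the sum of the set's gene-standardised values divided
#' by sqrt(set size).
#'
#' @inheritParams plage_scores
#' @return A `set_scores` object.
#' @export
zscore_scores <- function(em, index) {
  Z <- standardize_rows(em$E)
  scores <- t(vapply(index$index, function(idx) {
    colSums(Z[idx, , drop = FALSE]) / sqrt(length(idx))
  }, numeric(ncol(em$E))))
  dimnames(scores) <- list(names(index$sets), colnames(em$E))
  structure(list(scores = scores, method = "zscore"), class = "set_scores")
}

#' Single-sample GSEA enrichment scores
#'
#' Per sample, genes are ordered by decreasing expression (stable, so ties
#' keep input row order); the enrichment score integrates the difference
#' between the weighted in-set rank ECDF (weights = descending rank raised to
#' `tau`, normalised over set genes) and the uniform out-of-set ECDF. Scores
#' are finally normalised by the global max minus min across all sets and
#' samples. Invariant to strictly monotone per-sample transforms.
#'
#' @inheritParams plage_scores
#' @param tau Rank-weight exponent (default 0.25).
#' @param normalize Apply the global (max - min) normalisation (default TRUE).
#' @return A `set_scores` object.
#' @export
ssgsea_scores <- function(em, index, tau = 0.25, normalize = TRUE) {
  E <- em$E
  G <- nrow(E); S <- n_sets(index)
  if (any(lengths(index$index) >= G))
    stop("ssGSEA needs a set strictly smaller than the gene universe")
  M <- matrix(FALSE, S, G)
  for (i in seq_len(S)) M[i, index$index[[i]]] <- TRUE
  m <- lengths(index$index)
  scores <- matrix(NA_real_, S, ncol(E),
                   dimnames = list(names(index$sets), colnames(E)))
  w <- (G:1)^tau                       # weight by descending-rank position
  for (s in seq_len(ncol(E))) {
    ord <- order(E[, s], decreasing = TRUE)   # stable: ties keep row order
    ind <- t(M[, ord, drop = FALSE])          # G x S indicator, sorted order
    in_w <- ind * w
    cum_in <- apply(in_w, 2, cumsum)
    tot_in <- colSums(in_w)
    p_in <- sweep(cum_in, 2, ifelse(tot_in > 0, tot_in, 1), "/")
    cum_out <- apply(!ind, 2, cumsum)
    p_out <- sweep(cum_out, 2, G - m, "/")
    scores[, s] <- colSums(p_in - p_out)
  }
  if (normalize) {
    rng <- max(scores) - min(scores)
    if (rng > 0) scores <- scores / rng
  }
  structure(list(scores = scores, method = "ssgsea"), class = "set_scores")
}

#' Linear-model contrast test on set scores
#'
#' Ordinary least squares of each set's score vector on the design matrix;
#' the contrast t statistic has n - p degrees of freedom, two-sided p-value,
#' direction by the sign of the contrast estimate. This is the shared
#' set-level test behind the PLAGE / z-score / ssGSEA base methods.
#'
#' @param ssm A `set_scores` object.
#' @param design Samples x coefficients matrix.
#' @param contrasts Coefficients x contrasts matrix.
#' @param contrast Contrast name to test.
#' @return List with per-set `p`, `direction` and `valid`.
#' @export
set_contrast_test <- function(ssm, design, contrasts, contrast) {
  scores <- ssm$scores
  valid <- stats::complete.cases(scores)
  p <- rep(NA_real_, nrow(scores))
  dir <- rep(0, nrow(scores))
  names(p) <- names(dir) <- rownames(scores)
  if (any(valid)) {
    em <- expression_matrix(scores[valid, , drop = FALSE])
    gs <- gene_level_stats(em, design, contrasts, moderate = FALSE)
    p[valid] <- gs$p_value[, contrast]
    dir[valid] <- sign(gs$logFC[, contrast])
  }
  list(p = p, direction = dir, valid = valid & is.finite(p))
}
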