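#' Read a design or contrast matrix from CSV
#'
#' Header row of coefficient/contrast names, first column of sample (or
#' coefficient) labels, numeric body.
#'
#' @param path CSV path.
#' @return Numeric matrix with dimnames.
#' @export
read_design_csv <- function(path) {
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

#' Write a design or contrast matrix as CSV
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @param id_col Leading label column name.
#' @export
write_design_csv <- function(m, path, id_col = "sample") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  colnames(df)[1] <- id_col
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Gene-wise weighted least squares fit
#'
#' Fits the same linear model to every gene by (weighted) least squares.
#' When the expression object carries precision weights, each gene gets its
#' own weighted normal equations; otherwise a single QR decomposition is
#' shared. Residual-space coordinates (the projection of each gene's response
#' onto an orthonormal basis of the design's orthogonal complement, in the
#' weighted geometry) are retained for rotation-based set tests.
#'
#' @param em An `expression_matrix`.
#' @param design Samples x coefficients numeric matrix, full column rank,
#'   rows aligned with the expression columns by order.
#' @return A `gene_fit`: coefficients (genes x p), `sigma`, `df_residual`,
#'   weighted-scale residuals, residual-space coordinates, and the unscaled
#'   coefficient covariance (shared matrix, or per-gene array when weighted).
#' @export
fit_gene_lm <- function(em, design) {
  design <- as.matrix(design)
  Y <- em$E
  n <- ncol(Y); p <- ncol(design)
  if (nrow(design) != n) stop("design rows must equal sample count")
  if (qr(design)$rank < p) stop("design matrix is not full rank")
  d <- n - p
  if (d < 1L) stop("no residual degrees of freedom (n <= p)")
  G <- nrow(Y)
  W <- em$weights
  coef <- matrix(NA_real_, G, p, dimnames = list(rownames(Y), colnames(design)))
  res_w <- matrix(NA_real_, G, n, dimnames = dimnames(Y))
  res_coords <- matrix(NA_real_, G, d)
  if (is.null(W)) {
    qrX <- qr(design)
    coef[] <- t(qr.coef(qrX, t(Y)))
    res_w[] <- Y - coef %*% t(design)
    Qfull <- qr.Q(qrX, complete = TRUE)
    Q2 <- Qfull[, (p + 1):n, drop = FALSE]
    res_coords[] <- res_w %*% Q2
    cov_unscaled <- solve(crossprod(design))
  } else {
    cov_unscaled <- array(NA_real_, c(p, p, G))
    for (g in seq_len(G)) {
      sw <- sqrt(W[g, ])
      Xw <- design * sw
      yw <- Y[g, ] * sw
      qrX <- qr(Xw)
      b <- qr.coef(qrX, yw)
      coef[g, ] <- b
      res_w[g, ] <- yw - drop(Xw %*% b)
      Qfull <- qr.Q(qrX, complete = TRUE)
      res_coords[g, ] <- drop(crossprod(Qfull[, (p + 1):n, drop = FALSE], yw))
      cov_unscaled[, , g] <- chol2inv(qr.R(qrX))[order(qrX$pivot),
                                                 order(qrX$pivot)]
    }
  }
  sigma2 <- rowSums(res_w^2) / d
  structure(
    list(coefficients = coef, sigma = sqrt(sigma2), df_residual = d,
         residuals = res_w, res_coords = res_coords,
         cov_unscaled = cov_unscaled, weighted = !is.null(W),
         design = design, Amean = rowMeans(Y)),
    class = "gene_fit")
}

#' Apply a contrast matrix to a gene-wise fit
#'
#' @param fit A `gene_fit`.
#' @param contrasts Coefficients x contrasts numeric matrix; rownames must
#'   match the design coefficient names.
#' @return List with `logFC` (genes x contrasts, the contrast estimates) and
#'   `se_unscaled` (sqrt of the contrast quadratic form in the unscaled
#'   covariance; multiply by the residual/posterior sd for a standard error).
#' @export
apply_contrasts <- function(fit, contrasts) {
  contrasts <- as.matrix(contrasts)
  if (!identical(rownames(contrasts), colnames(fit$coefficients)))
    stop("contrast rownames do not match design coefficient names")
  if (any(colSums(contrasts != 0) == 0)) stop("all-zero contrast column")
  logFC <- fit$coefficients %*% contrasts
  G <- nrow(logFC); k <- ncol(contrasts)
  se <- matrix(NA_real_, G, k, dimnames = dimnames(logFC))
  if (!fit$weighted) {
    q <- sqrt(diag(t(contrasts) %*% fit$cov_unscaled %*% contrasts))
    se[] <- rep(q, each = G)
  } else {
    for (g in seq_len(G))
      se[g, ] <- sqrt(diag(t(contrasts) %*% fit$cov_unscaled[, , g] %*%
                             contrasts))
  }
  list(logFC = logFC, se_unscaled = se)
}

#' Empirical-Bayes moderation of gene-wise variances
#'
#' Shrinks gene-wise residual variances towards a common prior by the
#' standard moments (digamma/trigamma matching) estimator of the scaled-F
#' hierarchy, giving prior degrees of freedom `d0` (possibly infinite) and
#' prior variance `s0^2`; the moderated variance is
#' `(d0 s0^2 + d s^2) / (d0 + d)`. Setting `d0 = 0` disables shrinkage so
#' moderated t equals ordinary t.
#'
#' @param s2 Gene-wise residual variances.
#' @param df Residual degrees of freedom (scalar or vector).
#' @param d0 Optional forced prior degrees of freedom (`0` = no shrinkage).
#' @return List with `df_prior`, `var_prior` and `var_post`.
#' @export
ebayes_moderate <- function(s2, df, d0 = NULL) {
  if (!is.null(d0)) {
    if (d0 == 0) return(list(df_prior = 0, var_prior = mean(s2), var_post = s2))
    stop("only d0 = 0 (no shrinkage) may be forced")
  }
  if (sum(is.finite(s2) & s2 > 0) < 2L)
    stop("need at least two genes with positive residual variance")
  sq <- limma::squeezeVar(s2, df)
  list(df_prior = sq$df.prior, var_prior = sq$var.prior,
       var_post = sq$var.post)
}

#' Gene-level differential expression statistics
#'
#' Fits the gene-wise linear model, applies the contrasts, moderates the
#' variances and returns per-contrast log-fold-changes, moderated t
#' statistics, two-sided p-values and BH-adjusted FDR — the gene-level input
#' every base set test consumes.
#'
#' @param em An `expression_matrix`.
#' @param design Samples x coefficients matrix.
#' @param contrasts Coefficients x contrasts matrix.
#' @param moderate Use empirical-Bayes variance shrinkage (default TRUE).
#' @return A `gene_stats` object.
#' @export
gene_level_stats <- function(em, design, contrasts, moderate = TRUE) {
  fit <- fit_gene_lm(em, design)
  ac <- apply_contrasts(fit, contrasts)
  eb <- ebayes_moderate(fit$sigma^2, fit$df_residual,
                        d0 = if (moderate) NULL else 0)
  df_total <- fit$df_residual + eb$df_prior
  tstat <- ac$logFC / (ac$se_unscaled * sqrt(eb$var_post))
  pval <- 2 * stats::pt(-abs(tstat), df = df_total)
  fdr <- apply(pval, 2, stats::p.adjust, method = "BH")
  dimnames(fdr) <- dimnames(pval)
  structure(
    list(logFC = ac$logFC, se_unscaled = ac$se_unscaled, t = tstat,
         p_value = pval, fdr = fdr, AveExpr = fit$Amean,
         sigma = fit$sigma, s2_post = eb$var_post,
         df_residual = fit$df_residual, df_prior = eb$df_prior,
         s2_prior = eb$var_prior, df_total = df_total,
         residuals = fit$residuals, res_coords = fit$res_coords,
         design = fit$design, contrasts = as.matrix(contrasts),
         gene_ids = rownames(em$E)),
    class = "gene_stats")
}

#' Contrast names of a `gene_stats` object
#' @param gs A `gene_stats` object.
#' @export
contrast_names <- function(gs) colnames(gs$contrasts)

#' Ranked gene-level top table for one contrast
#'
#' @param gs A `gene_stats` object.
#' @param contrast Contrast name.
#' @param n Number of genes to return (default all).
#' @param symbols Optional named feature-to-symbol map.
#' @return Data frame sorted by ascending p-value with columns GeneID,
#'   Symbol, logFC, AveExpr, t, P.Value, adj.P.Val.
#' @export
top_table <- function(gs, contrast, n = Inf, symbols = NULL) {
  if (!contrast %in% contrast_names(gs))
    stop("unknown contrast '", contrast, "'")
  ids <- gs$gene_ids
  sym <- if (is.null(symbols)) ids else {
    s <- unname(symbols[ids]); ifelse(is.na(s), ids, s)
  }
  df <- data.frame(
    GeneID = ids, Symbol = sym,
    logFC = gs$logFC[, contrast], AveExpr = gs$AveExpr,
    t = gs$t[, contrast], P.Value = gs$p_value[, contrast],
    adj.P.Val = gs$fdr[, contrast],
    stringsAsFactors = FALSE, row.names = NULL)
  df <- df[order(df$P.Value, df$GeneID), , drop = FALSE]
  utils::head(df, n)
}
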