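#' Construct a count matrix container
#'
#' @param counts Non-negative integer matrix, genes x samples, with rownames
#'   (gene IDs) and colnames (sample IDs).
#' @param norm_factors Optional per-sample normalisation factors (default 1).
#' @return A `count_matrix`: list with `counts`, `lib_sizes`, `norm_factors`.
#' @export
count_matrix <- function(counts, norm_factors = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene IDs")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample IDs")
  if (any(counts < 0)) stop("negative counts")
  lib <- colSums(counts)
  if (is.null(norm_factors)) norm_factors <- rep(1, ncol(counts))
  structure(list(counts = counts, lib_sizes = lib,
                 norm_factors = norm_factors),
            class = "count_matrix")
}

#' TMM normalisation factors
#'
#' Trimmed mean of M-values between-sample scaling factors: the reference
#' sample is the library whose upper-quartile count fraction is closest to
#' the mean of those fractions; each sample's factor is 2 to the weighted
#' trimmed mean of gene-wise log-ratios against the reference (weights =
#' inverse delta-method variances; genes with a zero count in either sample
#' excluded), rescaled so the factors have geometric mean one.
#'
#' @param cm A [count_matrix()].
#' @param trim_m Two-sided trim fraction on the log-ratios (default 0.3).
#' @param trim_a Two-sided trim fraction on average abundance (default 0.05).
#' @return Numeric vector of per-sample factors (geometric mean 1).
#' @export
tmm_norm_factors <- function(cm, trim_m = 0.3, trim_a = 0.05) {
  if (any(cm$lib_sizes == 0))
    stop("sample(s) with zero library size: ",
         paste(colnames(cm$counts)[cm$lib_sizes == 0], collapse = ", "))
  dge <- edgeR::DGEList(counts = cm$counts)
  dge <- edgeR::calcNormFactors(dge, method = "TMM",
                                logratioTrim = trim_m, sumTrim = trim_a)
  stats::setNames(dge$samples$norm.factors, colnames(cm$counts))
}

#' Log counts per million
#'
#' `log2((count + prior) / (lib_size * norm_factor + 2 * prior) * 1e6)`, the
#' conventional offset form; strictly monotone in the count for a fixed
#' library.
#'
#' @param cm A [count_matrix()] with `norm_factors` set.
#' @param prior Prior count added to the numerator (default 0.5).
#' @return An `expression_matrix` (see [expression_matrix()]).
#' @export
log_cpm <- function(cm, prior = 0.5) {
  eff <- cm$lib_sizes * cm$norm_factors
  vals <- log2(sweep(cm$counts + prior, 2, eff + 2 * prior, "/") * 1e6)
  expression_matrix(vals)
}

#' Construct a log-expression matrix container
#'
#' @param values Numeric matrix, genes x samples, log2 scale, no missing
#'   values, with dimnames.
#' @param weights Optional positive precision weights of the same dimension.
#' @return An `expression_matrix`: list with `E` and optional `weights`.
#' @export
expression_matrix <- function(values, weights = NULL) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("missing values in expression matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(values))) stop("duplicate gene IDs")
  if (!is.null(weights)) {
    weights <- as.matrix(weights)
    if (!all(dim(weights) == dim(values)))
      stop("weights dimensions differ from values")
    if (any(weights <= 0)) stop("weights must be strictly positive")
  }
  structure(list(E = values, weights = weights), class = "expression_matrix")
}

#' Log-CPM with mean-variance precision weights
#'
#' Converts counts to log-CPM and estimates per-observation precision weights
#' from the fitted mean-variance trend: gene-wise linear fits on log-CPM, a
#' lowess trend of sqrt residual standard deviation against average log-count,
#' and inverse fourth-power predicted standard deviations as weights
#' (constant extrapolation beyond the fitted range; weights clamped to
#' [1e-6, 1e6] for numerical safety).
#'
#' @param cm A [count_matrix()] with `norm_factors` set.
#' @param design Design matrix (samples x coefficients), full column rank.
#' @param span Lowess span for the trend (default 0.5).
#' @return An `expression_matrix` with `E` (log-CPM) and `weights`.
#' @export
voom_weights <- function(cm, design, span = 0.5) {
  design <- as.matrix(design)
  if (qr(design)$rank < ncol(design)) stop("design matrix is not full rank")
  if (nrow(cm$counts) < 2L) stop("need at least two genes")
  v <- limma::voom(cm$counts, design = design, span = span,
                   lib.size = cm$lib_sizes * cm$norm_factors, plot = FALSE)
  expression_matrix(v$E, weights = pmin(pmax(v$weights, 1e-6), 1e6))
}

#' Detection-based feature filter
#'
#' Keeps a feature when its detection p-value is below `alpha` in at least
#' `min_samples` samples (the microarray-style expression filter).
#'
#' @param values Features x samples matrix of detection p-values in [0, 1].
#' @param alpha Detection p-value threshold (default 0.05).
#' @param min_samples Minimum number of samples passing (default 5).
#' @return Logical keep-mask, one entry per feature.
#' @export
detection_filter <- function(values, alpha = 0.05, min_samples = 5) {
  values <- as.matrix(values)
  if (any(values < 0 | values > 1)) stop("detection p-values outside [0, 1]")
  if (min_samples > ncol(values))
    stop("min_samples (", min_samples, ") exceeds sample count (",
         ncol(values), ")")
  rowSums(values < alpha) >= min_samples
}

#' Collapse features to genes by highest average expression
#'
#' For each gene keeps exactly the mapped feature with the highest row-mean
#' expression (ties broken by first occurrence in input order); features
#' without a gene mapping are dropped. Output rows are named by gene.
#'
#' @param em An `expression_matrix` of feature-level values.
#' @param feature_to_gene Named character vector: feature ID -> gene ID.
#' @return An `expression_matrix` with one row per mapped gene.
#' @export
collapse_features <- function(em, feature_to_gene) {
  if (length(feature_to_gene) == 0L) stop("empty feature-to-gene map")
  genes <- feature_to_gene[rownames(em$E)]
  keep <- !is.na(genes) & nzchar(genes)
  vals <- em$E[keep, , drop = FALSE]
  genes <- genes[keep]
  if (nrow(vals) == 0L) stop("no features map to a gene")
  means <- rowMeans(vals)
  ord <- order(means, decreasing = TRUE)    # stable: ties keep input order
  sel <- ord[!duplicated(genes[ord])]
  sel <- sort(sel)                          # preserve input row order
  out <- vals[sel, , drop = FALSE]
  rownames(out) <- unname(genes[sel])
  w <- if (!is.null(em$weights)) em$weights[keep, , drop = FALSE][sel, , drop = FALSE]
  if (!is.null(w)) rownames(w) <- unname(genes[sel])
  expression_matrix(out, weights = w)
}

#' Read a counts (or expression) TSV
#'
#' First column gene ID, header row of sample IDs, numeric body.
#'
#' @param path TSV path.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

#' Write a genes-x-samples matrix as TSV
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @param id_col Name of the leading identifier column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
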