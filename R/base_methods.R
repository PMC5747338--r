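# Base gene set tests. Every method yields, per set and contrast, a
# two-sided p-value, a direction in {-1, 0, +1}, and a validity flag; an
# individual failure never aborts the whole run.

#' Derive a reproducible sub-stream seed
#'
#' Hashes the master seed together with arbitrary string keys (method,
#' collection, contrast, set) into an integer below 2^31 so every stochastic
#' component consumes its own stream and scheduling order cannot change
#' results.
#'
#' @param master Master integer seed.
#' @param ... Further keys (coerced to character).
#' @return Integer seed.
#' @export
derive_seed <- function(master, ...) {
  key <- paste(c(as.character(master),
                 vapply(list(...), as.character, character(1))),
               collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

#' Map design and contrast to a two-group comparison
#'
#' Permutation-based methods need explicit groups. The per-sample contrast
#' loading `design %*% contrast` defines them: samples with positive loading
#' versus samples with negative loading. The contrast is reducible to two
#' groups only when the positive loadings are all equal, the negative
#' loadings are all equal, and both groups have at least two samples;
#' otherwise permutation methods flag their column untestable.
#'
#' @param design Samples x coefficients matrix.
#' @param contrast_vec Numeric contrast vector over the coefficients.
#' @return List with `ok`, and when `ok`, integer sample indices `g1`, `g2`.
#' @export
extract_two_groups <- function(design, contrast_vec) {
  l <- drop(as.matrix(design) %*% contrast_vec)
  g1 <- which(l > 1e-10)
  g2 <- which(l < -1e-10)
  ok <- length(g1) >= 2L && length(g2) >= 2L &&
    diff(range(l[g1])) < 1e-10 && diff(range(l[g2])) < 1e-10
  list(ok = ok, g1 = g1, g2 = g2)
}

# All C(n1+n2, n1) assignments when few enough, else B random label
# permutations. Returns samples x splits 0/1 indicator of "group 1".
perm_split_matrix <- function(n1, n2, B, seed) {
  n <- n1 + n2
  n_comb <- choose(n, n1)
  if (n_comb <= B) {
    combs <- utils::combn(n, n1)
    A <- matrix(0, n, ncol(combs))
    A[cbind(as.vector(combs), rep(seq_len(ncol(combs)), each = n1))] <- 1
    list(A = A, exhaustive = TRUE)
  } else {
    set.seed(seed)
    A <- replicate(B, {
      a <- numeric(n); a[sample.int(n, n1)] <- 1; a
    })
    list(A = A, exhaustive = FALSE)
  }
}

# Pooled-variance two-sample t for every gene under every split.
# E: genes x n; A: n x B indicator of group 1. Zero pooled variance -> t 0.
two_group_t <- function(E, A) {
  n1 <- colSums(A)[1]; n2 <- nrow(A) - n1
  M1 <- E %*% A / n1
  M2 <- E %*% (1 - A) / n2
  E2 <- E^2
  v1 <- (E2 %*% A - n1 * M1^2) / (n1 - 1)
  v2 <- (E2 %*% (1 - A) - n2 * M2^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(pmax(sp2, 0) * (1 / n1 + 1 / n2))
  tt <- (M1 - M2) / se
  tt[!is.finite(tt)] <- 0
  tt
}

#' Gene-level z-scores from moderated t
#'
#' Probability-integral transform of the moderated t statistic through its
#' t distribution into a standard normal quantile, preserving sign, with a
#' saturation guard for extreme statistics.
#'
#' @param gs A `gene_stats` object.
#' @param contrast Contrast name.
#' @return Numeric vector of per-gene z-scores.
#' @export
gene_zscores <- function(gs, contrast) {
  tt <- gs$t[, contrast]
  lp <- stats::pt(-abs(tt), df = gs$df_total, log.p = TRUE)
  z <- -stats::qnorm(lp, log.p = TRUE)
  z <- pmin(z, 37)                     # saturation guard
  sign(tt) * z
}

# Mean off-diagonal inter-gene correlation of a set's residual rows,
# estimated from the residual-space coordinates; at most `max_genes` rows
# are used (seeded subsample) to bound cost on very large sets.
set_residual_rho <- function(res_coords, idx, max_genes = 200, seed = 1) {
  if (length(idx) < 2L || ncol(res_coords) < 2L) return(0)
  if (length(idx) > max_genes) {
    set.seed(seed)
    idx <- sample(idx, max_genes)
  }
  R <- res_coords[idx, , drop = FALSE]
  sds <- apply(R, 1, stats::sd)
  R <- R[sds > 0, , drop = FALSE]
  m <- nrow(R)
  if (m < 2L) return(0)
  C <- stats::cor(t(R))
  (sum(C) - m) / (m * (m - 1))
}

#' Over-representation analysis (hypergeometric test)
#'
#' Upper-tail hypergeometric probability of the observed overlap between a
#' set and the differentially expressed genes (default definition: gene-level
#' BH FDR below `fdr_cutoff`; optionally the top `top_fallback` genes by
#' p-value when no gene passes).
#'
#' @param gs A `gene_stats` object.
#' @param index A `collection_index`.
#' @param contrast Contrast name.
#' @param fdr_cutoff Gene FDR threshold defining DE genes (default 0.05).
#' @param top_fallback Number of top genes (by p-value) to use as the DE
#'   list when no gene passes the FDR cutoff, so the test stays defined in
#'   low-powered experiments (default 100; 0 disables the fallback).
#' @param de_mask Optional logical per-gene DE mask overriding the FDR rule.
#' @return List with per-set `p`, `direction`, `valid`.
#' @export
ora_test <- function(gs, index, contrast, fdr_cutoff = 0.05,
                     top_fallback = 100, de_mask = NULL) {
  G <- index$universe_size
  if (is.null(de_mask)) {
    de_mask <- gs$fdr[, contrast] < fdr_cutoff
    if (!any(de_mask) && top_fallback > 0) {
      ord <- order(gs$p_value[, contrast])
      de_mask[ord[seq_len(min(top_fallback, G))]] <- TRUE
    }
  }
  K <- sum(de_mask)
  lfc <- gs$logFC[, contrast]
  m <- lengths(index$index)
  res <- vapply(index$index, function(idx) {
    k <- sum(de_mask[idx])
    p <- stats::phyper(k - 1, K, G - K, length(idx), lower.tail = FALSE)
    d <- if (k == 0) 0 else sign(mean(lfc[idx][de_mask[idx]]))
    c(p, d)
  }, numeric(2))
  list(p = res[1, ], direction = res[2, ], valid = m > 0)
}

#' Competitive parametric set test with correlation correction
#'
#' Compares the mean gene z-score inside the set against the rest of the
#' genome with a pooled two-sample t on G - 2 degrees of freedom, inflating
#' the set variance by the VIF `1 + (m - 1) * rho` where `rho` is the mean
#' inter-gene residual correlation of the set (floored at 1e-3).
#'
#' @param gs A `gene_stats` object.
#' @param index A `collection_index`.
#' @param contrast Contrast name.
#' @param max_cor_genes Subsample cap for the correlation estimate.
#' @param seed Seed for the correlation subsample.
#' @param rho Optional fixed inter-gene correlation; when supplied the
#'   residual-based estimate is skipped (``rho = 0`` reduces the statistic to
#'   a plain pooled two-sample t on the z-scores).
#' @return List with per-set `p`, `direction`, `valid`.
#' @export
camera_test <- function(gs, index, contrast, max_cor_genes = 200, seed = 1,
                        rho = NULL) {
  z <- gene_zscores(gs, contrast)
  G <- length(z)
  S <- n_sets(index)
  p <- dir <- rep(NA_real_, S)
  valid <- rep(FALSE, S)
  for (i in seq_len(S)) {
    idx <- index$index[[i]]
    m <- length(idx)
    if (m < 1L || m >= G) next
    rho_i <- if (is.null(rho))
      set_residual_rho(gs$res_coords, idx, max_cor_genes,
                       derive_seed(seed, "camera-rho", i)) else rho
    # spurious negative estimated correlations would deflate the variance
    # and inflate type I error, so the estimated path is floored at VIF 1
    vif <- max(1 + (m - 1) * rho_i, if (is.null(rho)) 1 else 1e-3)
    zin <- z[idx]; zout <- z[-idx]
    sp2 <- ((m - 1) * stats::var(zin) + (G - m - 1) * stats::var(zout)) /
      (G - 2)
    delta <- mean(zin) - mean(zout)
    tt <- delta / sqrt(sp2 * (vif / m + 1 / (G - m)))
    p[i] <- if (is.finite(tt)) 2 * stats::pt(-abs(tt), df = G - 2)
            else if (delta == 0) 1 else 0    # zero pooled spread
    dir[i] <- sign(delta)
    valid[i] <- is.finite(p[i])
  }
  list(p = p, direction = ifelse(is.na(dir), 0, dir), valid = valid)
}

#' Self-contained rotation set test
#'
#' The set statistic is the mean of gene-wise standardised contrast effects:
#' each gene's effect coordinate over its effect-plus-residual norm, mapped
#' through its exact null distribution (a scaled t on the residual degrees of
#' freedom) into a standard normal z. In `mc` mode the null is built by
#' rotating the contrast direction uniformly within the effect + residual
#' space — the same rotation for all genes, so inter-gene correlation is
#' preserved — applying the identical z transform to the rotated effects, and
#' `p = (1 + #\{|S_rot| >= |S_obs|\}) / (n_rot + 1)`. In `analytic` mode
#' `p = 2 (1 - Phi(|zbar| sqrt(m / VIF)))` with the camera-style VIF; the two
#' modes agree on independent-gene data.
#'
#' @param gs A `gene_stats` object.
#' @param index A `collection_index`.
#' @param contrast Contrast name.
#' @param n_rot Number of random rotations in `mc` mode (default 9999,
#'   minimum 99).
#' @param mode `"mc"` or `"analytic"`.
#' @param seed Seed for the rotations.
#' @param rho Optional fixed inter-gene correlation for analytic mode
#'   (estimated from residuals when NULL).
#' @return List with per-set `p`, `direction`, `valid`.
#' @export
rotation_set_test <- function(gs, index, contrast, n_rot = 9999,
                              mode = c("mc", "analytic"), seed = 1,
                              rho = NULL) {
  mode <- match.arg(mode)
  b <- gs$logFC[, contrast] / gs$se_unscaled[, contrast]
  V <- cbind(b, gs$res_coords)
  nrm <- sqrt(rowSums(V^2))
  U <- V / ifelse(nrm > 0, nrm, 1)
  d <- gs$df_residual
  # exact null map: effect fraction e -> ordinary t on d dof -> normal z
  e_to_z <- function(e) {
    e <- pmin(pmax(e, -1 + 1e-12), 1 - 1e-12)
    tt <- sqrt(d) * e / sqrt(1 - e^2)
    sign(tt) * pmin(-stats::qnorm(stats::pt(-abs(tt), df = d,
                                            log.p = TRUE), log.p = TRUE), 37)
  }
  z_obs <- e_to_z(U[, 1])
  S <- n_sets(index)
  idxs <- index$index
  s_obs <- vapply(idxs, function(i) mean(z_obs[i]), numeric(1))
  dir <- sign(s_obs)
  if (mode == "analytic") {
    p <- vapply(seq_len(S), function(i) {
      idx <- idxs[[i]]
      m <- length(idx)
      rho_i <- if (is.null(rho))
        set_residual_rho(gs$res_coords, idx,
                         seed = derive_seed(seed, "fry-rho", i)) else rho
      vif <- max(1 + (m - 1) * rho_i, 1e-3)
      2 * stats::pnorm(-abs(s_obs[i]) * sqrt(m / vif))
    }, numeric(1))
  } else {
    if (n_rot < 99) stop("n_rot must be at least 99 in mc mode")
    set.seed(seed)
    R <- matrix(stats::rnorm(ncol(U) * n_rot), ncol(U), n_rot)
    R <- sweep(R, 2, sqrt(colSums(R^2)), "/")
    E_rot <- U %*% R                       # genes x n_rot rotated effects
    # interpolate the (monotone) z transform on a fine grid for speed
    grid_e <- seq(-1, 1, length.out = 4001)
    Z_rot <- matrix(stats::approx(grid_e, e_to_z(grid_e), xout = E_rot,
                                  rule = 2)$y, nrow(E_rot))
    M <- matrix(0, S, nrow(U))
    for (i in seq_len(S)) M[i, idxs[[i]]] <- 1 / length(idxs[[i]])
    S_rot <- M %*% Z_rot                   # sets x n_rot
    exceed <- rowSums(abs(S_rot) >= abs(s_obs) - 1e-12)
    p <- (1 + exceed) / (n_rot + 1)
  }
  list(p = p, direction = dir, valid = is.finite(p))
}

#' Competitive Welch test of set versus background statistics
#'
#' Welch two-sample t comparing the set genes' scores against all non-set
#' genes' scores with Satterthwaite degrees of freedom; two-sided p,
#' direction by the sign of the mean difference. Location shifts common to
#' all genes cancel.
#'
#' @param gs A `gene_stats` object.
#' @param index A `collection_index`.
#' @param contrast Contrast name.
#' @param stat Gene-level statistic, `"z"` (default) or `"logfc"`.
#' @return List with per-set `p`, `direction`, `valid`.
#' @export
gage_test <- function(gs, index, contrast, stat = c("z", "logfc")) {
  stat <- match.arg(stat)
  x <- if (stat == "z") gene_zscores(gs, contrast) else gs$logFC[, contrast]
  G <- length(x)
  S <- n_sets(index)
  p <- dir <- rep(NA_real_, S)
  valid <- rep(FALSE, S)
  for (i in seq_len(S)) {
    idx <- index$index[[i]]
    m <- length(idx)
    if (m < 2L || m >= G) next
    xin <- x[idx]; xout <- x[-idx]
    v1 <- stats::var(xin) / m
    v2 <- stats::var(xout) / (G - m)
    delta <- mean(xin) - mean(xout)
    if (v1 + v2 <= 0) { p[i] <- 1; dir[i] <- 0; valid[i] <- TRUE; next }
    tt <- delta / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (m - 1) + v2^2 / (G - m - 1))
    p[i] <- 2 * stats::pt(-abs(tt), df = df)
    dir[i] <- sign(delta)
    valid[i] <- is.finite(p[i])
  }
  list(p = p, direction = ifelse(is.na(dir), 0, dir), valid = valid)
}

# Down-weights genes that occur in many sets of the collection:
# w = 1 + sqrt((f_max - f) / (f_max - f_min)); all 1 when frequencies tie.
padog_gene_weights <- function(index, n_genes) {
  f <- integer(n_genes)
  for (idx in index$index) f[idx] <- f[idx] + 1L
  fmax <- max(f); fmin <- min(f)
  if (fmax == fmin) return(rep(1, n_genes))
  1 + sqrt((fmax - f) / (fmax - fmin))
}

#' Permutation test with set-frequency gene weights
#'
#' The observed statistic is the mean over the set of `w_g * |t_g|`, with
#' gene weights damping genes shared by many sets in the collection and t
#' the two-group pooled statistic; the null recomputes t under group-label
#' permutations (all splits when few enough, else `B` random ones with the
#' +1 correction).
#'
#' @param gs A `gene_stats` object.
#' @param em The `expression_matrix` the statistics came from.
#' @param index A `collection_index`.
#' @param contrast Contrast name.
#' @param B Number of permutations (default 500, minimum 100).
#' @param seed Seed for the permutations.
#' @return List with per-set `p`, `direction`, `valid`.
#' @export
padog_test <- function(gs, em, index, contrast, B = 500, seed = 1) {
  if (B < 100) stop("B must be at least 100")
  grp <- extract_two_groups(gs$design, gs$contrasts[, contrast])
  S <- n_sets(index)
  if (!grp$ok)
    return(list(p = rep(NA_real_, S), direction = rep(0, S),
                valid = rep(FALSE, S)))
  samp <- c(grp$g1, grp$g2)
  E <- em$E[, samp, drop = FALSE]
  n1 <- length(grp$g1)
  ps <- perm_split_matrix(n1, length(grp$g2), B, seed)
  Tm <- abs(two_group_t(E, ps$A))              # genes x splits
  w <- padog_gene_weights(index, nrow(E))
  Mw <- matrix(0, S, nrow(E))
  for (i in seq_len(S)) Mw[i, index$index[[i]]] <-
      w[index$index[[i]]] / length(index$index[[i]])
  Sm <- Mw %*% Tm                              # sets x splits
  a0 <- numeric(ncol(E)); a0[seq_len(n1)] <- 1
  obs <- drop(Mw %*% abs(two_group_t(E, matrix(a0))[, 1]))
  p <- perm_pvalue(Sm, obs, ps$exhaustive)
  lfc <- gs$logFC[, contrast]
  dir <- vapply(index$index, function(idx) sign(mean(lfc[idx])), numeric(1))
  list(p = p, direction = dir, valid = lengths(index$index) > 0)
}

# Upper-tail permutation p from a sets x splits null matrix.
perm_pvalue <- function(Sm, obs, exhaustive) {
  exceed <- rowSums(Sm >= obs - 1e-12)
  if (exhaustive) exceed / ncol(Sm) else (1 + exceed) / (ncol(Sm) + 1)
}

#' Self-contained quadratic score permutation test
#'
#' `Q = ||X_set' y_c||^2 / (m * y_c' y_c)` with `y_c` the centred two-group
#' indicator and `X_set` the gene-standardised set submatrix (samples x
#' genes); the null permutes the group labels.
#'
#' @inheritParams padog_test
#' @param B Number of permutations (default 1000, minimum 100).
#' @return List with per-set `p`, `direction`, `valid`.
#' @export
globaltest_test <- function(gs, em, index, contrast, B = 1000, seed = 1) {
  if (B < 100) stop("B must be at least 100")
  grp <- extract_two_groups(gs$design, gs$contrasts[, contrast])
  S <- n_sets(index)
  if (!grp$ok)
    return(list(p = rep(NA_real_, S), direction = rep(0, S),
                valid = rep(FALSE, S)))
  samp <- c(grp$g1, grp$g2)
  Z <- standardize_rows(em$E[, samp, drop = FALSE])   # genes x n
  n1 <- length(grp$g1); n <- length(samp)
  ps <- perm_split_matrix(n1, n - n1, B, seed)
  Yc <- sweep(ps$A, 2, colMeans(ps$A))                # centred indicators
  yty <- colSums(Yc^2)
  Xt <- Z %*% Yc                                     # genes x splits
  X2 <- Xt^2
  M <- matrix(0, S, nrow(Z))
  for (i in seq_len(S)) M[i, index$index[[i]]] <- 1
  m <- lengths(index$index)
  Qm <- sweep(M %*% X2, 2, yty, "/") / m              # sets x splits
  a0 <- numeric(n); a0[seq_len(n1)] <- 1
  y0 <- a0 - mean(a0)
  q0 <- drop(M %*% (Z %*% y0)^2) / (m * sum(y0^2))
  p <- perm_pvalue(Qm, q0, ps$exhaustive)
  lfc <- gs$logFC[, contrast]
  dir <- vapply(index$index, function(idx) sign(mean(lfc[idx])), numeric(1))
  list(p = p, direction = dir, valid = m > 0)
}

#' Rank-based self-contained permutation test
#'
#' Global statistic: Wilcoxon rank-sum of the set genes' |t| against the
#' complement; the null re-computes the two-group t statistics under label
#' permutations.
#'
#' @inheritParams globaltest_test
#' @return List with per-set `p`, `direction`, `valid`.
#' @export
safe_test <- function(gs, em, index, contrast, B = 1000, seed = 1) {
  if (B < 100) stop("B must be at least 100")
  grp <- extract_two_groups(gs$design, gs$contrasts[, contrast])
  S <- n_sets(index)
  if (!grp$ok)
    return(list(p = rep(NA_real_, S), direction = rep(0, S),
                valid = rep(FALSE, S)))
  samp <- c(grp$g1, grp$g2)
  E <- em$E[, samp, drop = FALSE]
  n1 <- length(grp$g1)
  ps <- perm_split_matrix(n1, length(samp) - n1, B, seed)
  Tm <- abs(two_group_t(E, ps$A))
  Rm <- apply(Tm, 2, rank)                     # genes x splits rank of |t|
  M <- matrix(0, S, nrow(E))
  for (i in seq_len(S)) M[i, index$index[[i]]] <- 1
  Wm <- M %*% Rm                               # rank sums, sets x splits
  a0 <- numeric(ncol(E)); a0[seq_len(n1)] <- 1
  w0 <- drop(M %*% rank(abs(two_group_t(E, matrix(a0))[, 1])))
  p <- perm_pvalue(Wm, w0, ps$exhaustive)
  lfc <- gs$logFC[, contrast]
  dir <- vapply(index$index, function(idx) sign(mean(lfc[idx])), numeric(1))
  list(p = p, direction = dir, valid = lengths(index$index) > 0)
}

#' Supported base method names
#' @return Character vector of method identifiers.
#' @export
base_method_names <- function() {
  c("ora", "camera", "fry", "gage", "padog", "plage", "zscore", "ssgsea",
    "globaltest", "safe")
}

#' Run a panel of base gene set tests for one contrast
#'
#' Dispatches every requested method and assembles a sets x methods matrix of
#' p-values, directions and validity flags. A method failing on an individual
#' set is recorded in the validity flags, never aborting the run. `"gsva"` is
#' recognised but not implemented and rejected with a clear error.
#'
#' @param gs A `gene_stats` object.
#' @param em The `expression_matrix` used for the fit.
#' @param index A `collection_index`.
#' @param contrast Contrast name.
#' @param methods Character vector of method names (see
#'   [base_method_names()]).
#' @param params Named list of per-method overrides: `B_padog`, `B_perm`,
#'   `n_rot`, `fry_mode`, `tau`, `ora_fdr`, `ora_top_fallback`.
#' @param seed Master seed; every method consumes a derived sub-stream.
#' @param workers Number of parallel workers (results are identical for any
#'   worker count).
#' @return A `method_result`: list with matrices `p`, `direction`, `valid`.
#' @export
run_base_methods <- function(gs, em, index, contrast,
                             methods = base_method_names(),
                             params = list(), seed = 1, workers = 1) {
  if (length(methods) == 0L) stop("empty base method list")
  if ("gsva" %in% methods)
    stop("base method 'gsva' is not implemented; choose among: ",
         paste(base_method_names(), collapse = ", "))
  unknown <- setdiff(methods, base_method_names())
  if (length(unknown))
    stop("unsupported base method(s): ", paste(unknown, collapse = ", "))
  pget <- function(nm, default) if (!is.null(params[[nm]])) params[[nm]] else default
  run_one <- function(meth) {
    sd <- derive_seed(seed, meth, index$label, contrast)
    res <- tryCatch(switch(
      meth,
      ora = ora_test(gs, index, contrast, fdr_cutoff = pget("ora_fdr", 0.05),
                     top_fallback = pget("ora_top_fallback", 100)),
      camera = camera_test(gs, index, contrast, seed = sd),
      fry = rotation_set_test(gs, index, contrast,
                              n_rot = pget("n_rot", 9999),
                              mode = pget("fry_mode", "mc"), seed = sd),
      gage = gage_test(gs, index, contrast),
      padog = padog_test(gs, em, index, contrast,
                         B = pget("B_padog", 500), seed = sd),
      plage = set_contrast_test(plage_scores(em, index), gs$design,
                                gs$contrasts, contrast),
      zscore = set_contrast_test(zscore_scores(em, index), gs$design,
                                 gs$contrasts, contrast),
      ssgsea = set_contrast_test(
        ssgsea_scores(em, index, tau = pget("tau", 0.25)),
        gs$design, gs$contrasts, contrast),
      globaltest = globaltest_test(gs, em, index, contrast,
                                   B = pget("B_perm", 1000), seed = sd),
      safe = safe_test(gs, em, index, contrast,
                       B = pget("B_perm", 1000), seed = sd)),
      error = function(e) {
        warning("base method '", meth, "' failed for contrast '", contrast,
                "': ", conditionMessage(e))
        S <- n_sets(index)
        list(p = rep(NA_real_, S), direction = rep(0, S),
             valid = rep(FALSE, S))
      })
    res
  }
  results <- if (workers > 1) {
    parallel::mclapply(methods, run_one, mc.cores = workers)
  } else {
    lapply(methods, run_one)
  }
  names(results) <- methods
  setn <- names(index$sets)
  pm <- sapply(results, function(r) as.numeric(r$p))
  dm <- sapply(results, function(r) as.numeric(r$direction))
  vm <- sapply(results, function(r) as.logical(r$valid) & is.finite(r$p))
  if (n_sets(index) == 1L) {       # sapply drops to vector for one set
    pm <- matrix(pm, 1); dm <- matrix(dm, 1); vm <- matrix(vm, 1)
  }
  dimnames(pm) <- dimnames(dm) <- dimnames(vm) <- list(setn, methods)
  structure(list(p = pm, direction = dm, valid = vm, contrast = contrast,
                 methods = methods, collection = index$label),
            class = "method_result")
}
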