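# Shared fixture: moderate two-group experiment with a known collection.
bm_fixture <- function(n_genes = 120, n1 = 4, n2 = 4, n_sets = 8,
                       set_size = 10, seed = 1, shift = NULL) {
  set.seed(seed)
  E <- matrix(rnorm(n_genes * (n1 + n2), 6), n_genes,
              dimnames = list(sprintf("g%03d", 1:n_genes),
                              c(paste0("a", 1:n1), paste0("b", 1:n2))))
  sets <- lapply(seq_len(n_sets), function(i)
    gene_set(sprintf("S%02d", i), "d",
             sample(rownames(E), set_size)))
  if (!is.null(shift)) {
    idx <- match(sets[[1]]$members[seq_len(shift$n_active)], rownames(E))
    E[idx, seq_len(n1)] <- E[idx, seq_len(n1)] + shift$logfc
  }
  design <- cbind(A = rep(c(1, 0), c(n1, n2)), B = rep(c(0, 1), c(n1, n2)))
  rownames(design) <- colnames(E)
  contrasts <- matrix(c(1, -1), 2, dimnames = list(c("A", "B"), "AvsB"))
  em <- expression_matrix(E)
  ci <- build_index(sets, rownames(E), min_size = 2, label = "bm")
  gs <- gene_level_stats(em, design, contrasts)
  list(em = em, ci = ci, gs = gs, design = design, contrasts = contrasts)
}

test_that("gene z-scores are a monotone signed probability transform", {
  fx <- bm_fixture()
  z <- gene_zscores(fx$gs, "AvsB")
  tt <- fx$gs$t[, 1]
  ord <- order(tt)
  expect_true(all(diff(z[ord]) > -1e-12))
  oracle <- qnorm(pt(tt, df = fx$gs$df_total))
  expect_equal(unname(z), unname(oracle), tolerance = 1e-8)
  # exact zero statistic maps to exact zero
  gs2 <- fx$gs; gs2$t[1, 1] <- 0
  expect_identical(unname(gene_zscores(gs2, "AvsB")[1]), 0)
})

test_that("hypergeometric ORA equals exhaustive enumeration and handles edges", {
  fx <- bm_fixture()
  # no DE genes -> k = 0 -> p = 1, direction 0
  res <- ora_test(fx$gs, fx$ci, "AvsB", de_mask = rep(FALSE, 120))
  expect_true(all(res$p == 1) && all(res$direction == 0))

  # brute force over all possible m-subsets of a small universe
  G <- 20; K <- 5; m <- 4
  de <- c(rep(TRUE, K), rep(FALSE, G - K))
  draws <- utils::combn(G, m)
  for (k in 0:m) {
    p_enum <- mean(apply(draws, 2, function(d) sum(de[d])) >= k)
    expect_equal(stats::phyper(k - 1, K, G - K, m, lower.tail = FALSE),
                 p_enum, tolerance = 1e-12)
  }
  # whole-universe set is certain: k = K, p = 1
  uni <- fx$gs$gene_ids
  ci_all <- build_index(list(gene_set("ALL", "d", uni)), uni, min_size = 1,
                        label = "bm")
  mask <- fx$gs$fdr[, 1] * 0 + c(rep(1, 10), rep(0, 110))
  resA <- ora_test(fx$gs, ci_all, "AvsB", de_mask = mask > 0)
  expect_equal(unname(resA$p), 1)
})

test_that("competitive test at rho = 0 is a plain pooled two-sample t", {
  fx <- bm_fixture(n_genes = 300, n_sets = 12, seed = 7)
  res <- camera_test(fx$gs, fx$ci, "AvsB", rho = 0)
  z <- gene_zscores(fx$gs, "AvsB")
  for (i in seq_len(n_sets(fx$ci))) {
    idx <- fx$ci$index[[i]]
    ot <- stats::t.test(z[idx], z[-idx], var.equal = TRUE)
    expect_equal(unname(res$p[i]), ot$p.value, tolerance = 1e-10)
  }
  # estimated correlations on independent genes stay near the rho = 0 case
  est <- camera_test(fx$gs, fx$ci, "AvsB")
  expect_lt(mean(abs(est$p - res$p)), 0.1)
  expect_true(all(est$p >= 0 & est$p <= 1))
})

test_that("duplicated member rows inflate the VIF and the competitive p", {
  fx <- bm_fixture(n_genes = 150, n_sets = 5, seed = 9,
                   shift = list(n_active = 10, logfc = 0.8))
  # make every member of set 1 a copy of one row: correlation -> 1
  E2 <- fx$em$E
  idx <- fx$ci$index[[1]]
  E2[idx, ] <- rep(E2[idx[1], ], each = length(idx)) +
    matrix(rnorm(length(idx) * ncol(E2), 0, 1e-3), length(idx))
  gs2 <- gene_level_stats(expression_matrix(E2), fx$design, fx$contrasts)
  rho_hat <- ensembleGSA:::set_residual_rho(gs2$res_coords, idx)
  expect_gt(rho_hat, 0.9)
  dup <- camera_test(gs2, fx$ci, "AvsB")
  flat <- camera_test(gs2, fx$ci, "AvsB", rho = 0)
  # same data, inflated variance: the correlated p can only be larger
  expect_gt(dup$p[1], flat$p[1])
})

test_that("identical in/out z-scores give a null competitive result", {
  fx <- bm_fixture()
  gsc <- fx$gs
  gsc$t[, 1] <- 1.3            # constant statistic everywhere
  res <- camera_test(gsc, fx$ci, "AvsB")
  expect_true(all(res$p == 1))
})

test_that("Welch set-vs-background test matches its oracle and invariances", {
  fx <- bm_fixture(seed = 11)
  res <- gage_test(fx$gs, fx$ci, "AvsB")
  z <- gene_zscores(fx$gs, "AvsB")
  for (i in seq_len(n_sets(fx$ci))) {
    idx <- fx$ci$index[[i]]
    ot <- stats::t.test(z[idx], z[-idx])
    expect_equal(unname(res$p[i]), ot$p.value, tolerance = 1e-10)
  }
  gs3 <- fx$gs
  gs3$t[, 1] <- gs3$t[, 1]      # location shift enters through z directly
  z_shift <- z + 5
  for (i in 1:2) {
    idx <- fx$ci$index[[i]]
    expect_equal(stats::t.test(z_shift[idx], z_shift[-idx])$p.value,
                 stats::t.test(z[idx], z[-idx])$p.value, tolerance = 1e-10)
  }
})

test_that("rotation test: determinism, error guard, cross-mode agreement", {
  fx <- bm_fixture(n_genes = 200, n_sets = 10, seed = 13)
  a <- rotation_set_test(fx$gs, fx$ci, "AvsB", n_rot = 999, seed = 5)
  b <- rotation_set_test(fx$gs, fx$ci, "AvsB", n_rot = 999, seed = 5)
  expect_identical(a$p, b$p)
  expect_error(rotation_set_test(fx$gs, fx$ci, "AvsB", n_rot = 50),
               "at least 99")
  # independent genes, adequate residual dof: analytic approximates mc
  fy <- bm_fixture(n_genes = 300, n1 = 10, n2 = 10, n_sets = 12,
                   set_size = 20, seed = 7)
  mc <- rotation_set_test(fy$gs, fy$ci, "AvsB", n_rot = 20000, seed = 2)
  an <- rotation_set_test(fy$gs, fy$ci, "AvsB", mode = "analytic")
  expect_lt(mean(abs(mc$p - an$p)), 0.02)
  expect_identical(unname(mc$direction), unname(an$direction))
})

test_that("permutation engines reproduce exhaustive enumeration at n = 3 + 3", {
  fx <- bm_fixture(n_genes = 80, n1 = 3, n2 = 3, n_sets = 4, seed = 17)
  splits <- utils::combn(6, 3)

  # naive per-split statistics
  naive_t <- function(cols1) {
    apply(fx$em$E, 1, function(x) {
      a <- x[cols1]; b <- x[-cols1]
      sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
                   (length(a) + length(b) - 2))
      if (sp == 0) 0 else (mean(a) - mean(b)) / (sp * sqrt(1 / 3 + 1 / 3))
    })
  }
  w <- ensembleGSA:::padog_gene_weights(fx$ci, 80)
  obs_t <- naive_t(1:3)

  pad <- padog_test(fx$gs, fx$em, fx$ci, "AvsB", B = 500, seed = 3)
  glo <- globaltest_test(fx$gs, fx$em, fx$ci, "AvsB", B = 500, seed = 3)
  saf <- safe_test(fx$gs, fx$em, fx$ci, "AvsB", B = 500, seed = 3)

  Zs <- t(scale(t(fx$em$E)))
  for (i in seq_len(n_sets(fx$ci))) {
    idx <- fx$ci$index[[i]]
    s_obs <- mean(w[idx] * abs(obs_t[idx]))
    s_perm <- apply(splits, 2, function(cols1)
      mean(w[idx] * abs(naive_t(cols1)[idx])))
    expect_equal(unname(pad$p[i]), mean(s_perm >= s_obs - 1e-12),
                 tolerance = 1e-12)

    q_of <- function(cols1) {
      y <- numeric(6); y[cols1] <- 1; y <- y - mean(y)
      sum((drop(Zs[idx, , drop = FALSE] %*% y))^2) /
        (length(idx) * sum(y^2))
    }
    q_perm <- apply(splits, 2, q_of)
    expect_equal(unname(glo$p[i]), mean(q_perm >= q_of(1:3) - 1e-12),
                 tolerance = 1e-12)

    w_of <- function(cols1) sum(rank(abs(naive_t(cols1)))[idx])
    w_perm <- apply(splits, 2, w_of)
    expect_equal(unname(saf$p[i]), mean(w_perm >= w_of(1:3) - 1e-12),
                 tolerance = 1e-12)
  }
})

test_that("permutation methods are seed-deterministic with random splits", {
  fx <- bm_fixture(n_genes = 80, n1 = 5, n2 = 5, n_sets = 4, seed = 19)
  for (f in list(padog_test, globaltest_test, safe_test)) {
    a <- f(fx$gs, fx$em, fx$ci, "AvsB", B = 150, seed = 11)
    b <- f(fx$gs, fx$em, fx$ci, "AvsB", B = 150, seed = 11)
    expect_identical(a$p, b$p)
  }
})

test_that("degenerate gene-set frequencies give unit weights", {
  uni <- sprintf("g%03d", 1:40)
  sets <- lapply(1:4, function(i)
    gene_set(paste0("S", i), "d", uni[((i - 1) * 10 + 1):(i * 10)]))
  ci <- build_index(sets, uni, min_size = 1, label = "w")
  expect_equal(ensembleGSA:::padog_gene_weights(ci, 40), rep(1, 40))
})

test_that("an outcome orthogonal to the set genes is not flagged by the quadratic test", {
  # construct set genes orthogonal to the centred group indicator
  n <- 6
  y <- c(1, 1, 1, 0, 0, 0); yc <- y - mean(y)
  base <- diag(n) - outer(yc, yc) / sum(yc^2)
  set.seed(23)
  E <- matrix(rnorm(20 * n, 5), 20, n)
  E[1:5, ] <- E[1:5, ] %*% base          # project out the group direction
  dimnames(E) <- list(sprintf("g%02d", 1:20), paste0("s", 1:n))
  design <- cbind(A = y, B = 1 - y); rownames(design) <- colnames(E)
  contrasts <- matrix(c(1, -1), 2, dimnames = list(c("A", "B"), "AvsB"))
  ci <- build_index(list(gene_set("ORTH", "d", rownames(E)[1:5])),
                    rownames(E), min_size = 1, label = "o")
  gs <- gene_level_stats(expression_matrix(E), design, contrasts)
  res <- globaltest_test(gs, expression_matrix(E), ci, "AvsB", B = 500,
                         seed = 1)
  expect_gte(res$p[1], 0.5)
})

test_that("the method runner composes, validates and parallelises deterministically", {
  fx <- bm_fixture(n_genes = 100, n_sets = 5, seed = 29)
  pars <- list(n_rot = 499, B_padog = 200, B_perm = 200)
  one <- run_base_methods(fx$gs, fx$em, fx$ci, "AvsB", methods = "gage")
  expect_identical(dim(one$p), c(5L, 1L))

  expect_error(run_base_methods(fx$gs, fx$em, fx$ci, "AvsB",
                                methods = c("gage", "gsva")),
               "not implemented")
  expect_error(run_base_methods(fx$gs, fx$em, fx$ci, "AvsB",
                                methods = character(0)), "empty")
  expect_error(run_base_methods(fx$gs, fx$em, fx$ci, "AvsB",
                                methods = "bogus"), "unsupported")

  full <- run_base_methods(fx$gs, fx$em, fx$ci, "AvsB", params = pars,
                           seed = 31)
  # column-wise equality with running each op individually
  sd_cam <- derive_seed(31, "camera", "bm", "AvsB")
  expect_equal(unname(full$p[, "camera"]),
               unname(camera_test(fx$gs, fx$ci, "AvsB", seed = sd_cam)$p))
  expect_equal(unname(full$p[, "gage"]),
               unname(gage_test(fx$gs, fx$ci, "AvsB")$p))
  sd_saf <- derive_seed(31, "safe", "bm", "AvsB")
  expect_equal(unname(full$p[, "safe"]),
               unname(safe_test(fx$gs, fx$em, fx$ci, "AvsB", B = 200,
                                seed = sd_saf)$p))
  par2 <- run_base_methods(fx$gs, fx$em, fx$ci, "AvsB", params = pars,
                           seed = 31, workers = 2)
  expect_identical(full$p, par2$p)
  expect_true(all(full$p >= 0 & full$p <= 1, na.rm = TRUE))
  expect_true(all(full$direction %in% c(-1, 0, 1)))
})
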