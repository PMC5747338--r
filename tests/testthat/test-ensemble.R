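combiners <- c("fisher", "wilkinson", "average", "logitp", "sump", "sumz",
               "votep", "median")

test_that("every combiner returns a single p-value unchanged", {
  for (m in combiners)
    for (p in c(0.001, 0.2, 0.5, 0.77))
      expect_equal(combine_pvalues(p, m), p, tolerance = 1e-12)
})

test_that("combiners reproduce their closed-form values", {
  expect_equal(combine_pvalues(c(0.5, 0.5), "sumz"), 0.5, tolerance = 1e-10)
  expect_equal(combine_pvalues(c(0.2, 0.4, 0.6), "wilkinson"),
               1 - 0.8^3, tolerance = 1e-12)
  expect_equal(combine_pvalues(c(0.5, 0.5), "fisher"),
               pchisq(-2 * log(0.25), 4, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(combine_pvalues(c(0.5, 0.5), "fisher"), 0.5966, tolerance = 1e-4)
  expect_equal(combine_pvalues(c(0.25, 0.35), "sump"), 0.6^2 / 2,
               tolerance = 1e-12)
  expect_error(combine_pvalues(numeric(0)), "no p-values")
  expect_error(combine_pvalues(0.5, "nonsense"))
})

test_that("all combiners match independent oracles on random vectors", {
  set.seed(101)
  for (m in combiners) {
    for (rep in 1:25) {
      k <- sample(1:12, 1)
      p <- runif(k)
      expect_equal(combine_pvalues(p, m), oracle_combine(p, m),
                   tolerance = 1e-10,
                   label = paste(m, "k =", k, "rep", rep))
    }
  }
})

test_that("combiners are monotone in every input", {
  set.seed(5)
  for (m in combiners) {
    for (rep in 1:20) {
      k <- sample(2:10, 1)
      p <- runif(k)
      j <- sample(k, 1)
      q <- p; q[j] <- p[j] * runif(1)
      expect_lte(combine_pvalues(q, m), combine_pvalues(p, m) + 1e-12,
                 label = m)
    }
  }
})

fake_mrm <- function(pm, valid = NULL) {
  if (is.null(valid)) valid <- matrix(TRUE, nrow(pm), ncol(pm))
  dimnames(valid) <- dimnames(pm)
  structure(list(p = pm, direction = sign(pm) * 0 + 1, valid = valid,
                 contrast = "AvsB", methods = colnames(pm),
                 collection = "x"),
            class = "method_result")
}

test_that("per-method ranking applies minimum-tie and invalid rules", {
  pm <- matrix(c(0.1, 0.1, 0.5), 3, 1,
               dimnames = list(paste0("S", 1:3), "m1"))
  r <- rank_by_method(fake_mrm(pm))
  expect_equal(unname(r[, 1]), c(1, 1, 3))

  pm2 <- matrix(c(0.3, 0.1, 0.2), 3, 1,
                dimnames = list(paste0("S", 1:3), "m1"))
  expect_equal(unname(rank_by_method(fake_mrm(pm2))[, 1]), c(3, 1, 2))

  valid <- matrix(c(TRUE, FALSE, TRUE), 3, 1)
  r3 <- rank_by_method(fake_mrm(pm2, valid))
  expect_equal(unname(r3[, 1]), c(2, 3, 1))   # invalid -> n_valid + 1

  set.seed(6)
  pm4 <- matrix(runif(200 * 4), 200, 4,
                dimnames = list(sprintf("S%03d", 1:200), paste0("m", 1:4)))
  r4 <- rank_by_method(fake_mrm(pm4))
  for (j in 1:4) {
    ord <- order(pm4[, j])
    expect_equal(unname(r4[ord, j]), 1:200)
  }
})

test_that("rank aggregation matches brute force on random rank matrices", {
  fx <- make_rank_fixture(200, 11, "random", seed = 3)
  # identical-column fixture collapses every aggregate onto the permutation
  fi <- make_rank_fixture(30, 7, "identical", seed = 4)
  expect_equal(fi$expected$med_rank, fi$ranks[, 1], ignore_attr = TRUE)
  expect_equal(fi$expected$avg_rank, fi$ranks[, 1], ignore_attr = TRUE)

  # feed p-values whose per-column ranks equal the fixture's rank matrix
  pm <- fx$ranks / (nrow(fx$ranks) + 1)
  mrm <- fake_mrm(pm)
  gs_stub <- list(logFC = matrix(1, 2, 1, dimnames = list(NULL, "AvsB")))
  idx_stub <- list(sets = as.list(rownames(pm)), index = rep(list(1:2),
                                                             nrow(pm)))
  names(idx_stub$sets) <- rownames(pm)
  class(idx_stub) <- "collection_index"
  tab <- ensemble_scores(mrm, gs_stub, idx_stub)
  expect_equal(tab$med.rank, unname(fx$expected$med_rank))
  expect_equal(tab$avg.rank, unname(fx$expected$avg_rank))
  expect_equal(tab$min.rank, unname(fx$expected$min_rank))
  # vote rank: brute-force mode of 5-wide bins, ties to the smallest bin
  vote_oracle <- apply(fx$ranks, 1, function(r) {
    b <- ceiling(r / 5)
    counts <- table(b)
    5 * min(as.integer(names(counts)[counts == max(counts)]))
  })
  expect_equal(tab$vote.rank, unname(vote_oracle))
  expect_true(all(tab$vote.rank %% 5 == 0))
  # shuffling method columns leaves the aggregates unchanged
  mrm_sh <- fake_mrm(pm[, sample(ncol(pm))])
  tab_sh <- ensemble_scores(mrm_sh, gs_stub, idx_stub)
  expect_equal(tab_sh$med.rank, tab$med.rank)
  expect_equal(tab_sh$vote.rank, tab$vote.rank)
})

test_that("identical method rankings collapse all rank aggregates", {
  set.seed(9)
  p <- runif(20)
  pm <- matrix(rep(p, 5), 20, dimnames = list(sprintf("S%02d", 1:20),
                                              paste0("m", 1:5)))
  mrm <- fake_mrm(pm)
  gs_stub <- list(logFC = matrix(rnorm(40), 40, 1,
                                 dimnames = list(NULL, "AvsB")))
  idx_stub <- list(sets = as.list(rownames(pm)),
                   index = lapply(1:20, function(i) ((i - 1) * 2 + 1):(i * 2)))
  names(idx_stub$sets) <- rownames(pm)
  class(idx_stub) <- "collection_index"
  tab <- ensemble_scores(mrm, gs_stub, idx_stub)
  base_rank <- rank(p, ties.method = "min")
  expect_equal(tab$avg.rank, unname(base_rank))
  expect_equal(tab$med.rank, unname(base_rank))
  expect_equal(tab$min.rank, unname(base_rank))
  expect_equal(tab$vote.rank, unname(5 * ceiling(base_rank / 5)))
  expect_true(all(tab$significance >= 0 & tab$significance <= 100))
})

test_that("significance scaling is invariant to affine transforms of sigma", {
  # affine rescaling of the underlying score leaves the min-max result fixed
  sig <- c(0.2, 1.7, 3.1, 0.9)
  scale01 <- function(x) 100 * (x - min(x)) / diff(range(x))
  expect_equal(scale01(sig), scale01(2.5 * sig + 7))
})

test_that("comparative analysis: identity, sharpening, and direction", {
  fx <- local({
    set.seed(12)
    E <- matrix(rnorm(90 * 9, 5), 90, 9,
                dimnames = list(sprintf("g%02d", 1:90),
                                paste0("s", 1:9)))
    design <- cbind(A = rep(c(1, 0, 0), each = 3),
                    B = rep(c(0, 1, 0), each = 3),
                    C = rep(c(0, 0, 1), each = 3))
    rownames(design) <- colnames(E)
    contrasts <- cbind(AvsB = c(1, -1, 0), AvsC = c(1, 0, -1))
    rownames(contrasts) <- colnames(design)
    sets <- lapply(1:6, function(i)
      gene_set(paste0("S", i), "d", sample(rownames(E), 10)))
    ci <- build_index(sets, rownames(E), min_size = 2, label = "cmp")
    em <- expression_matrix(E)
    gs <- gene_level_stats(em, design, contrasts)
    mrms <- lapply(c("AvsB", "AvsC"), function(cn)
      run_base_methods(gs, em, ci, cn, methods = c("camera", "gage",
                                                   "zscore"),
                       seed = 2))
    names(mrms) <- c("AvsB", "AvsC")
    list(gs = gs, ci = ci, mrms = mrms)
  })
  single <- comparative_scores(fx$mrms["AvsB"], fx$gs, fx$ci)
  direct <- ensemble_scores(fx$mrms$AvsB, fx$gs, fx$ci)
  for (col in c("p.value", "p.adj", "med.rank", "avg.rank", "vote.rank",
                "avg.logfc", "direction", "significance"))
    expect_equal(single[[col]], direct[[col]], tolerance = 1e-12,
                 label = col)

  # two identical contrasts: method-level comparison p follows the
  # first-order-statistic closed form 1 - (1 - p)^2 (conservative for
  # duplicated evidence, as a minimum-based combiner must be)
  p1 <- fx$mrms$AvsB$p
  pm_cmp <- 1 - (1 - p1)^2
  for (i in 1:3)
    for (j in 1:3)
      expect_equal(combine_pvalues(rep(p1[i, j], 2), "wilkinson"),
                   pm_cmp[i, j], tolerance = 1e-12)
  both <- comparative_scores(fx$mrms[c("AvsB", "AvsB")], fx$gs, fx$ci)
  expect_equal(both$direction, direct$direction)
  expect_equal(both$avg.logfc, direct$avg.logfc, tolerance = 1e-12)
})

test_that("top set retrieval sorts correctly, breaks ties by name, errors cleanly", {
  tab <- data.frame(
    id = paste0("S", 1:5),
    p.value = c(0.01, 0.2, 0.05, 0.2, 0.001),
    p.adj = c(0.05, 0.5, 0.2, 0.5, 0.01),
    direction = c(1, -1, 1, 0, 1),
    vote.rank = c(5, 10, 5, 15, 5),
    avg.rank = c(2, 4, 3, 5, 1),
    med.rank = c(2, 4, 3, 5, 1),
    min.pvalue = c(0.01, 0.1, 0.02, 0.15, 0.001),
    min.rank = c(1, 3, 2, 4, 1),
    avg.logfc = c(1, 0.5, 2, 0.1, 1.5),
    avg.logfc.dir = c(1, -0.5, 2, 0, 1.5),
    significance = c(40, 10, 100, 0, 80),
    n_methods = rep(3, 5), n_genes = rep(10, 5),
    row.names = paste0("S", 1:5))
  class(tab) <- c("ensemble_table", "data.frame")
  top <- top_sets(tab, "p.adj", n = 3)
  expect_identical(rownames(top), c("S5", "S1", "S3"))
  expect_identical(top$Rank, 1:3)
  # descending keys
  expect_identical(rownames(top_sets(tab, "significance", n = 2)),
                   c("S3", "S5"))
  # ties broken by set name: S2 and S4 share p.adj 0.5
  allr <- top_sets(tab, "p.adj", n = Inf)
  expect_identical(rownames(allr)[4:5], c("S2", "S4"))
  expect_identical(nrow(top_sets(tab, "p.adj", n = 100)), 5L)
  expect_error(top_sets(tab, "bogus"), "unknown sort key")
  # brute-force sort oracle
  expect_identical(rownames(top_sets(tab, "med.rank", n = Inf)),
                   rownames(tab)[order(tab$med.rank, rownames(tab))])
})
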