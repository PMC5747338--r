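# Independent oracles and small fixture builders shared across the suite.
# Oracles are deliberately naive (loops, enumeration, alternative closed
# forms) and stay independent of the package code paths they check.

random_collection <- function(n_sets, seed = 1, universe = NULL) {
  set.seed(seed)
  if (is.null(universe)) universe <- sprintf("gene%03d", 1:100)
  sets <- lapply(seq_len(n_sets), function(i) {
    m <- sample(3:12, 1)
    gene_set(sprintf("RS_%03d", i),
             description = sample(c("", "a desc", "x y z"), 1),
             members = sample(universe, m))
  })
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  sets
}

# Textbook BH step-up.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Alternative closed forms for the p-value combiners.
oracle_combine <- function(p, method) {
  k <- length(p)
  p <- pmin(pmax(p, 1e-300), 1 - 1e-15)
  if (k == 1L) return(p)     # single p is returned unchanged by contract
  switch(method,
    fisher = stats::pgamma(sum(-log(p)), shape = k, rate = 1,
                           lower.tail = FALSE),
    wilkinson = stats::pbeta(min(p), 1, k),
    average = stats::pnorm((mean(p) - 0.5) / sqrt(1 / (12 * k))),
    logitp = {
      denom <- sqrt(k * pi^2 * (5 * k + 2) / (3 * (5 * k + 4)))
      1 - stats::pt(sum(-log(p / (1 - p))) / denom, df = 5 * k + 4)
    },
    sump = oracle_irwin_hall(sum(p), k),
    sumz = 1 - stats::pnorm(sum(stats::qnorm(1 - p)) / sqrt(k)),
    votep = sum(stats::dbinom(sum(p < 0.5):k, k, 0.5)),
    median = {
      r <- ceiling(k / 2)
      x <- sort(p)[r]
      sum(vapply(r:k, function(j) choose(k, j) * x^j * (1 - x)^(k - j),
                 numeric(1)))
    })
}

# Irwin-Hall CDF accumulated term-by-term on the log scale.
oracle_irwin_hall <- function(s, k) {
  if (s <= 0) return(0)
  if (s >= k) return(1)
  total <- 0
  for (j in 0:floor(s)) {
    term <- exp(lchoose(k, j) + k * log(s - j) - lfactorial(k))
    total <- total + if (j %% 2 == 0) term else -term
  }
  min(max(total, 0), 1)
}

# Direct published TMM recipe for a two-or-more-sample count matrix.
oracle_tmm <- function(counts, logratioTrim = 0.3, sumTrim = 0.05) {
  lib <- colSums(counts)
  uq <- apply(counts, 2, function(x) stats::quantile(x, 0.75)) / lib
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(s) {
    if (s == ref) return(1)
    nO <- lib[s]; nR <- lib[ref]
    obs <- counts[, s]; refc <- counts[, ref]
    keep <- obs > 0 & refc > 0
    obs <- obs[keep]; refc <- refc[keep]
    M <- log2((obs / nO) / (refc / nR))
    A <- (log2(obs / nO) + log2(refc / nR)) / 2
    v <- (nO - obs) / nO / obs + (nR - refc) / nR / refc
    keep2 <- is.finite(M) & is.finite(A) & abs(M) < 1e10
    M <- M[keep2]; A <- A[keep2]; v <- v[keep2]
    n <- length(M)
    loM <- floor(n * logratioTrim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * sumTrim) + 1; hiA <- n + 1 - loA
    keep3 <- rank(M) >= loM & rank(M) <= hiM &
      rank(A) >= loA & rank(A) <= hiA
    2^(sum(M[keep3] / v[keep3]) / sum(1 / v[keep3]))
  }, numeric(1))
  f / exp(mean(log(f)))
}

# Tiny two-group log-expression fixture.
tiny_em <- function(n_genes = 60, n1 = 4, n2 = 4, seed = 1, sd = 1) {
  set.seed(seed)
  E <- matrix(rnorm(n_genes * (n1 + n2), 6, sd), n_genes,
              dimnames = list(sprintf("g%03d", 1:n_genes),
                              c(paste0("a", 1:n1), paste0("b", 1:n2))))
  design <- cbind(A = rep(c(1, 0), c(n1, n2)), B = rep(c(0, 1), c(n1, n2)))
  rownames(design) <- colnames(E)
  contrasts <- matrix(c(1, -1), 2, 1,
                      dimnames = list(c("A", "B"), "AvsB"))
  list(em = expression_matrix(E), design = design, contrasts = contrasts)
}

# Membership reconstruction by a naive double loop.
oracle_intersect_positions <- function(members, universe) {
  out <- integer(0)
  for (i in seq_along(universe)) {
    for (m in members) if (identical(m, universe[i])) out <- c(out, i)
  }
  out
}

expect_vector_equal <- function(a, b, tol = 1e-10) {
  expect_equal(unname(as.numeric(a)), unname(as.numeric(b)),
               tolerance = tol)
}
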