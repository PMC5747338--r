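# Seeded synthetic experiments with planted enriched sets, standing in for
# the external expression accessions so every pipeline stage is testable
# offline.

#' Generate a synthetic multi-group expression experiment
#'
#' Baseline log2 expression is Normal(mu_g, noise_sd) with gene baselines
#' drawn uniformly on [2, 12]; optional exchangeable within-set correlation
#' is induced by a shared latent factor per set (variance share `rho`).
#' Planted effects add `logfc` to the stated fraction of a set's member genes
#' in the samples loading positively on the stated contrast. Counts mode
#' draws negative binomial counts around 2^log-mean. The gene set collection
#' is drawn at random (sets may overlap); the design uses group-means coding
#' and the contrasts are all pairwise group differences.
#'
#' @param n_genes Number of genes (default 2000).
#' @param groups Named integer vector of group sizes (>= 2 each), default
#'   `c(grpA = 5, grpB = 5)`.
#' @param n_sets Number of gene sets (default 200).
#' @param set_size Genes per set (default 20).
#' @param planted List of planted effects, each a list with `set` (name or
#'   index), `contrast` (name), `logfc` (log2 units) and `fraction` in (0,1].
#' @param rho Within-set exchangeable correlation share in [0, 1) (default 0).
#' @param noise_sd Residual standard deviation in log2 units (default 0.5,
#'   typical of bulk expression data after normalisation).
#' @param mode `"logexpr"` (default) or `"counts"`.
#' @param nb_dispersion Negative binomial dispersion for counts mode
#'   (default 0.1).
#' @param seed Master seed; identical seeds give identical output.
#' @param out_dir Optional directory; when given, writes `expr.tsv` (or
#'   `counts.tsv`), `sets.gmt`, `design.csv`, `contrasts.csv`, `truth.json`.
#' @return List with `em` (or `cm` in counts mode), `sets`, `design`,
#'   `contrasts` and `truth`.
#' @export
make_dataset <- function(n_genes = 2000, groups = c(grpA = 5, grpB = 5),
                         n_sets = 200, set_size = 20, planted = list(),
                         rho = 0, noise_sd = 0.5,
                         mode = c("logexpr", "counts"),
                         nb_dispersion = 0.1, seed = 1, out_dir = NULL) {
  mode <- match.arg(mode)
  if (any(groups < 2)) stop("every group needs at least two samples")
  if (is.null(names(groups)))
    names(groups) <- paste0("grp", LETTERS[seq_along(groups)])
  set.seed(seed)
  n <- sum(groups)
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  sample_ids <- unlist(lapply(names(groups), function(g)
    paste0(g, "_", seq_len(groups[[g]]))))
  grp_of <- rep(names(groups), groups)

  design <- stats::model.matrix(~ 0 + factor(grp_of, levels = names(groups)))
  colnames(design) <- names(groups)
  rownames(design) <- sample_ids
  pairs <- utils::combn(names(groups), 2)
  contrasts <- apply(pairs, 2, function(pr) {
    v <- stats::setNames(numeric(length(groups)), names(groups))
    v[pr[1]] <- 1; v[pr[2]] <- -1
    v
  })
  colnames(contrasts) <- apply(pairs, 2, paste, collapse = "vs")
  rownames(contrasts) <- names(groups)

  sets <- lapply(seq_len(n_sets), function(i)
    gene_set(sprintf("SET_%03d", i), description = "synthetic",
             members = sample(gene_ids, set_size)))
  names(sets) <- vapply(sets, `[[`, character(1), "name")

  mu <- stats::runif(n_genes, 2, 12)
  E <- matrix(stats::rnorm(n_genes * n, 0, noise_sd * sqrt(1 - rho)),
              n_genes, n, dimnames = list(gene_ids, sample_ids))
  E <- E + mu
  if (rho > 0) {
    for (s in sets) {
      f <- stats::rnorm(n, 0, noise_sd * sqrt(rho))
      rows <- match(s$members, gene_ids)
      E[rows, ] <- E[rows, ] + rep(f, each = length(rows))
    }
  }

  truth_planted <- list()
  for (pl in planted) {
    sname <- if (is.numeric(pl$set)) names(sets)[pl$set] else pl$set
    if (!sname %in% names(sets)) stop("planted set not generated: ", sname)
    if (!pl$contrast %in% colnames(contrasts))
      stop("planted contrast unknown: ", pl$contrast)
    if (pl$fraction <= 0 || pl$fraction > 1)
      stop("planted fraction must be in (0, 1]")
    members <- sets[[sname]]$members
    n_active <- ceiling(pl$fraction * length(members))
    active <- members[seq_len(n_active)]
    load <- drop(design %*% contrasts[, pl$contrast])
    up <- which(load > 0)
    E[match(active, gene_ids), up] <-
      E[match(active, gene_ids), up] + pl$logfc
    truth_planted[[length(truth_planted) + 1]] <-
      list(set = sname, contrast = pl$contrast, logfc = pl$logfc,
           fraction = pl$fraction, active_genes = active)
  }
  truth <- list(planted = truth_planted, noise_sd = noise_sd, rho = rho,
                seed = seed, n_genes = n_genes,
                groups = as.list(groups), mode = mode)

  out <- list(sets = sets, design = design, contrasts = contrasts,
              truth = truth)
  if (mode == "counts") {
    mu_counts <- 2^E
    cnt <- matrix(stats::rnbinom(length(E), mu = mu_counts,
                                 size = 1 / nb_dispersion),
                  n_genes, n, dimnames = dimnames(E))
    out$cm <- count_matrix(cnt)
  } else {
    out$em <- expression_matrix(E)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (mode == "counts")
      write_matrix_tsv(out$cm$counts, file.path(out_dir, "counts.tsv"))
    else
      write_matrix_tsv(out$em$E, file.path(out_dir, "expr.tsv"))
    write_gmt(sets, file.path(out_dir, "sets.gmt"))
    write_design_csv(design, file.path(out_dir, "design.csv"),
                     id_col = "sample")
    write_design_csv(contrasts, file.path(out_dir, "contrasts.csv"),
                     id_col = "coefficient")
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' Generate a rank matrix with known aggregation answers
#'
#' Fixture generator for the rank-aggregation unit tests: emits a sets x
#' methods rank matrix together with min / average / lower-median ranks
#' computed by direct per-row loops.
#'
#' @param n_sets Number of sets (rows).
#' @param n_methods Number of methods (columns).
#' @param structure `"identical"` (every column the same permutation) or
#'   `"random"` (independent permutations per column).
#' @param seed Seed.
#' @return List with `ranks` and `expected` (`min_rank`, `avg_rank`,
#'   `med_rank`).
#' @export
make_rank_fixture <- function(n_sets, n_methods,
                              structure = c("random", "identical"),
                              seed = 1) {
  structure <- match.arg(structure)
  if (n_methods < 1L) stop("need at least one method")
  set.seed(seed)
  ranks <- if (structure == "identical") {
    perm <- sample.int(n_sets)
    matrix(rep(perm, n_methods), n_sets, n_methods)
  } else {
    matrix(unlist(lapply(seq_len(n_methods),
                         function(j) sample.int(n_sets))),
           n_sets, n_methods)
  }
  dimnames(ranks) <- list(sprintf("SET_%03d", seq_len(n_sets)),
                          paste0("m", seq_len(n_methods)))
  expected <- list(
    min_rank = apply(ranks, 1, min),
    avg_rank = apply(ranks, 1, mean),
    med_rank = apply(ranks, 1, function(r) sort(r)[floor((length(r) + 1) / 2)])
  )
  list(ranks = ranks, expected = expected)
}
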