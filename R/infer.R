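#' Cluster-wise regularized GRN inference
#'
#' For every cell cluster, fits one regularized linear model per target gene
#' predicting its expression from the expression of its base-GRN candidate
#' TFs:
#'
#'   x_j = sum_i b_ij x_i + c_j
#'
#' with b_jj = 0. Two engines are available: a bagging ridge (an ensemble of
#' ridge fits on bootstrap resamples of cells; the default, and the better
#' performing engine) and a Bayesian ridge with evidence-maximized
#' non-informative Gamma(1e-6, 1e-6) hyperpriors. Both yield a coefficient
#' distribution per edge (mean, sd) and a p-value for "center of b = 0"
#' (one-sample t-test across bags; two-sided normal tail of mean/sd for the
#' Bayesian posterior).
#'
#' @name grn_inference
NULL

#' Split a gem_bundle by cluster
#'
#' @param gem a [gem_bundle()].
#' @param min_cells clusters with fewer cells are skipped with a warning
#'   (default 10).
#' @return named list (sorted cluster labels) of cell-index vectors.
#' @export
split_by_cluster <- function(gem, min_cells = 10) {
  idx <- split(seq_len(nrow(gem$X)), gem$cluster)
  idx <- idx[order(names(idx))]
  small <- vapply(idx, length, 1L) < min_cells
  if (any(small)) {
    warning(sprintf("skipping %d cluster(s) with < %d cells: %s",
                    sum(small), min_cells,
                    paste(names(idx)[small], collapse = ", ")))
    idx <- idx[!small]
  }
  idx
}

# closed-form ridge on centered data; returns coefficients and intercept
ridge_fit <- function(y, Z, alpha) {
  zm <- colMeans(Z)
  ym <- mean(y)
  Zc <- sweep(Z, 2, zm)
  yc <- y - ym
  A <- crossprod(Zc)
  diag(A) <- diag(A) + alpha
  b <- drop(solve(A, crossprod(Zc, yc)))
  list(coef = b, intercept = ym - sum(zm * b))
}

#' Bayesian ridge fit for one target gene
#'
#' Evidence (type-II maximum likelihood) estimation of the noise precision
#' and the shared coefficient-precision, with Gamma(1e-6, 1e-6) hyperpriors
#' on both — a non-informative prior whose regularization strength is
#' learned from the data. Returns the posterior mean and sd per coefficient.
#'
#' @param y numeric vector, per-cell target expression.
#' @param Z numeric matrix, per-cell candidate-TF expression (>= 1 column,
#'   >= 3 rows).
#' @param max_iter,tol iteration control for evidence maximization.
#' @return list with `coef` (posterior means), `coef_std` (posterior sds),
#'   `intercept`, `p` (two-sided normal tail of mean/sd), and `constant_y`
#'   flag.
#' @export
fit_target_bayesian <- function(y, Z, max_iter = 300, tol = 1e-8) {
  Z <- as.matrix(Z)
  stopifnot(length(y) >= 3, ncol(Z) >= 1)
  p <- ncol(Z); n <- length(y)
  if (stats::sd(y) == 0) {
    return(list(coef = rep(0, p), coef_std = rep(0, p), intercept = mean(y),
                p = rep(1, p), constant_y = TRUE))
  }
  a0 <- b0 <- 1e-6
  zm <- colMeans(Z); ym <- mean(y)
  Zc <- sweep(Z, 2, zm); yc <- y - ym
  XtX <- crossprod(Zc); Xty <- drop(crossprod(Zc, yc))
  lambda <- 1; alpha <- 1 / stats::var(yc)
  m <- rep(0, p)
  for (it in seq_len(max_iter)) {
    A <- alpha * XtX
    diag(A) <- diag(A) + lambda
    S <- solve(A)
    m_new <- alpha * drop(S %*% Xty)
    gamma <- p - lambda * sum(diag(S))
    lambda_new <- (gamma + 2 * a0) / (sum(m_new^2) + 2 * b0)
    rss <- sum((yc - drop(Zc %*% m_new))^2)
    alpha_new <- (n - gamma + 2 * a0) / (rss + 2 * b0)
    done <- max(abs(m_new - m)) < tol
    m <- m_new; lambda <- lambda_new; alpha <- alpha_new
    if (done) break
  }
  A <- alpha * XtX
  diag(A) <- diag(A) + lambda
  S <- solve(A)
  coef_std <- sqrt(pmax(diag(S), .Machine$double.eps))
  pval <- 2 * stats::pnorm(-abs(m) / coef_std)
  list(coef = m, coef_std = coef_std, intercept = ym - sum(zm * m),
       p = pval, constant_y = FALSE)
}

# degenerate-aware one-sample t-test of samples against zero
bag_t_test <- function(s) {
  m <- mean(s)
  sdv <- stats::sd(s)
  if (sdv == 0) return(if (m == 0) 1 else 0)
  t <- m / (sdv / sqrt(length(s)))
  2 * stats::pt(-abs(t), df = length(s) - 1)
}

#' Bagging ridge fit for one target gene
#'
#' Fits `n_bags` ridge regressions, each on a bootstrap resample of cells
#' (drawn with replacement, `bag_frac` of the cells per bag). The per-edge
#' coefficient mean and sd are taken over bags and a two-sided one-sample
#' t-test of the bag samples against zero gives the p-value. Degenerate
#' cases (zero variance across bags) map to p = 0 when the mean is nonzero
#' and p = 1 when it is zero.
#'
#' @param y per-cell target expression.
#' @param Z per-cell candidate-TF expression matrix.
#' @param n_bags number of bootstrap fits (default 50).
#' @param alpha ridge penalty (default 1).
#' @param seed integer seed; resamples are reproducible.
#' @param bag_frac fraction of cells drawn (with replacement) per bag.
#' @return list with `samples` (n_bags x p), `coef` (means), `coef_std`,
#'   `p`, `intercept`.
#' @export
fit_target_bagging <- function(y, Z, n_bags = 50, alpha = 1, seed = 0,
                               bag_frac = 0.8) {
  Z <- as.matrix(Z)
  stopifnot(n_bags >= 2, alpha > 0)
  n <- length(y); p <- ncol(Z)
  if (stats::sd(y) == 0) {
    return(list(samples = matrix(0, n_bags, p), coef = rep(0, p),
                coef_std = rep(0, p), p = rep(1, p), intercept = mean(y)))
  }
  m <- max(2L, round(bag_frac * n))
  samples <- with_seed(seed, {
    out <- matrix(0, n_bags, p)
    for (b in seq_len(n_bags)) {
      take <- sample.int(n, m, replace = TRUE)
      Zb <- Z[take, , drop = FALSE]
      # guard: a bootstrap bag can lose all variance in a column
      keep <- apply(Zb, 2, stats::sd) > 0
      if (!any(keep)) next
      fit <- ridge_fit(y[take], Zb[, keep, drop = FALSE], alpha)
      out[b, keep] <- fit$coef
    }
    out
  })
  coef <- colMeans(samples)
  coef_std <- apply(samples, 2, stats::sd)
  pv <- apply(samples, 2, bag_t_test)
  full <- ridge_fit(y, Z, alpha)
  list(samples = samples, coef = coef, coef_std = coef_std, p = pv,
       intercept = full$intercept)
}

#' Fit cluster-wise GRNs constrained by a base GRN
#'
#' For each cluster (see [split_by_cluster()]) and each target gene with at
#' least one candidate regulator, fits the selected engine and assembles the
#' signed coefficient matrix `B` (regulator x target; zero off the candidate
#' mask, zero diagonal). Candidate regulators for target j are the base-GRN
#' TFs of j that are present in the expression matrix and expressed in at
#' least one cell of the cluster. Targets with no candidates are skipped and
#' listed in the result.
#'
#' @param gem a [gem_bundle()].
#' @param bg a [base_grn()], or `NULL` for the no-base-GRN control in which
#'   every other gene is a candidate regulator of every target.
#' @param engine `"bagging"` (default) or `"bayes"`.
#' @param n_bags,alpha,bag_frac bagging parameters (see
#'   [fit_target_bagging()]).
#' @param min_cells minimum cluster size.
#' @param seed integer; bagging resamples are derived deterministically per
#'   cluster/target.
#' @return Object of class `cluster_grn_set`: named list of `cluster_grn`
#'   objects, each with `B` (genes x genes coefficient matrix), `intercept`,
#'   `edges` (data.frame source/target/coef_mean/coef_std/p), `n_samples`,
#'   `skipped_targets`.
#' @export
infer_grns <- function(gem, bg, engine = c("bagging", "bayes"),
                       n_bags = 50, alpha = 1, bag_frac = 0.8,
                       min_cells = 10, seed = 0) {
  engine <- match.arg(engine)
  genes <- gem$gene_ids
  if (is.null(bg)) {
    cand <- NULL
  } else {
    cand <- regulators_of(bg)
  }
  idx_by_cluster <- split_by_cluster(gem, min_cells = min_cells)
  out <- list()
  for (ci in seq_along(idx_by_cluster)) {
    cl <- names(idx_by_cluster)[ci]
    Xc <- gem$X[idx_by_cluster[[ci]], , drop = FALSE]
    expressed <- colSums(Xc > 0) > 0
    B <- matrix(0, length(genes), length(genes),
                dimnames = list(genes, genes))
    intercept <- stats::setNames(numeric(length(genes)), genes)
    edges <- list()
    skipped <- character()
    for (j in seq_along(genes)) {
      g <- genes[j]
      regs <- if (is.null(cand)) genes[expressed] else {
        r <- cand[[g]]
        if (is.null(r)) character() else
          r[r %in% genes[expressed]]
      }
      regs <- setdiff(regs, g)
      if (length(regs) == 0) { skipped <- c(skipped, g); next }
      y <- Xc[, g]
      Z <- Xc[, regs, drop = FALSE]
      fit <- if (engine == "bagging") {
        fit_target_bagging(y, Z, n_bags = n_bags, alpha = alpha,
                           seed = seed * 10000L + ci * 1000L + j,
                           bag_frac = bag_frac)
      } else {
        fit_target_bayesian(y, Z)
      }
      B[regs, g] <- fit$coef
      intercept[g] <- fit$intercept
      edges[[length(edges) + 1L]] <- data.frame(
        source = regs, target = g, coef_mean = fit$coef,
        coef_std = fit$coef_std, p = fit$p, stringsAsFactors = FALSE)
    }
    edges <- if (length(edges) > 0) do.call(rbind, edges) else
      data.frame(source = character(), target = character(),
                 coef_mean = numeric(), coef_std = numeric(), p = numeric())
    rownames(edges) <- NULL
    diag(B) <- 0
    out[[cl]] <- structure(
      list(cluster = cl, B = B, intercept = intercept, edges = edges,
           n_samples = if (engine == "bagging") n_bags else NA_integer_,
           engine = engine, skipped_targets = skipped),
      class = "cluster_grn")
    gf_log("infer_grns: cluster '%s': %d edges over %d targets (%d skipped)",
           cl, nrow(edges), length(unique(edges$target)), length(skipped))
  }
  structure(out, class = "cluster_grn_set")
}

#' @export
print.cluster_grn <- function(x, ...) {
  cat(sprintf("cluster_grn '%s' (%s): %d edges, %d targets\n", x$cluster,
              x$engine, nrow(x$edges), length(unique(x$edges$target))))
  invisible(x)
}

#' @export
print.cluster_grn_set <- function(x, ...) {
  cat(sprintf("cluster_grn_set: %d clusters (%s)\n", length(x),
              paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Filter GRN edges by p-value and strength
#'
#' Keeps edges with `p <= p_max` and `|coef_mean| >= min_abs_coef`; if
#' `top_n > 0`, additionally keeps only the `top_n` edges by absolute
#' coefficient within the cluster. The coefficient matrix `B` is zeroed
#' outside the surviving edges. Used ahead of network-structure analysis;
#' perturbation simulation uses the unfiltered coefficients.
#'
#' @param grn a `cluster_grn` or `cluster_grn_set`.
#' @param p_max p-value ceiling (default 0.001).
#' @param min_abs_coef minimum absolute coefficient (default 0).
#' @param top_n keep at most this many edges per cluster (default 10000;
#'   0 disables).
#' @return filtered object of the same class.
#' @export
filter_edges <- function(grn, p_max = 0.001, min_abs_coef = 0, top_n = 10000) {
  stopifnot(p_max >= 0, min_abs_coef >= 0, top_n >= 0)
  if (inherits(grn, "cluster_grn_set")) {
    out <- lapply(grn, filter_edges, p_max = p_max,
                  min_abs_coef = min_abs_coef, top_n = top_n)
    return(structure(out, class = "cluster_grn_set", names = names(grn)))
  }
  e <- grn$edges
  keep <- e$p <= p_max & abs(e$coef_mean) >= min_abs_coef
  e <- e[keep, , drop = FALSE]
  if (top_n > 0 && nrow(e) > top_n) {
    ord <- order(-abs(e$coef_mean), e$source, e$target)
    e <- e[ord[seq_len(top_n)], , drop = FALSE]
  }
  if (nrow(e) == 0)
    warning(sprintf("cluster '%s': all edges removed by filtering", grn$cluster))
  B <- matrix(0, nrow(grn$B), ncol(grn$B), dimnames = dimnames(grn$B))
  if (nrow(e) > 0)
    B[cbind(e$source, e$target)] <- e$coef_mean
  grn$edges <- e
  grn$B <- B
  grn
}

#' Write / read a cluster_grn_set as per-cluster CSV edge tables
#' @param grns a `cluster_grn_set`.
#' @param dir output directory (created if needed).
#' @export
write_grns <- function(grns, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cl in names(grns))
    write_edges(grns[[cl]]$edges, file.path(dir, paste0("grn_", cl, ".csv")))
  manifest <- list(clusters = names(grns),
                   engine = grns[[1]]$engine,
                   n_samples = grns[[1]]$n_samples,
                   skipped_targets = lapply(grns, `[[`, "skipped_targets"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(grns)
}

#' @rdname write_grns
#' @param gene_ids gene universe used to rebuild the coefficient matrices.
#' @export
load_grns <- function(dir, gene_ids) {
  files <- list.files(dir, pattern = "^grn_.*\\.csv$", full.names = TRUE)
  out <- list()
  for (f in files) {
    cl <- sub("^grn_(.*)\\.csv$", "\\1", basename(f))
    e <- load_edges(f)
    B <- matrix(0, length(gene_ids), length(gene_ids),
                dimnames = list(gene_ids, gene_ids))
    if (nrow(e) > 0) B[cbind(e$source, e$target)] <- e$coef_mean
    out[[cl]] <- structure(
      list(cluster = cl, B = B,
           intercept = stats::setNames(numeric(length(gene_ids)), gene_ids),
           edges = e, n_samples = NA_integer_, engine = "loaded",
           skipped_targets = character()),
      class = "cluster_grn")
  }
  structure(out, class = "cluster_grn_set")
}
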