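#' Pseudotime-gradient field, perturbation scores and TF ranking
#'
#' The differentiation direction at each grid point is the 2D gradient of
#' pseudotime transferred from cells to the grid. The inner product between
#' this gradient field and a perturbation simulation field is the
#' perturbation score (PS): negative PS marks grid regions where the
#' perturbation pushes cells *against* differentiation. TFs are ranked by
#' the (lineage-restricted) sum of |PS| over negative-PS grids, with a
#' false-positive-rate cutoff calibrated on randomized-GRN nulls.
#'
#' @name flow_score
NULL

#' Transfer per-cell pseudotime onto the embedding grid
#'
#' Predicts pseudotime at the active grid points either by KNN regression
#' (mean over the `k` nearest cells; robust for complex branching) or by
#' polynomial regression on the embedding coordinates (smooth; suited to
#' simple bifurcations). Grid geometry and the active mask are taken from
#' `field` when given (so the pseudotime field aligns with a simulation
#' field), otherwise computed from the cell density with the same defaults
#' as [grid_field()].
#'
#' @param gem a [gem_bundle()] with pseudotime.
#' @param L grid points per axis (ignored when `field` is given).
#' @param method `"knn"` (default, k = 30) or `"polynomial"` (default
#'   degree 3).
#' @param k KNN regression neighbourhood size.
#' @param degree polynomial degree in x and y.
#' @param field optional `grid_field` supplying geometry and mask.
#' @param sigma,min_mass_frac mask parameters when `field` is absent.
#' @return object of class `pseudotime_field`: `points`, `t` (grid
#'   pseudotime, NA on inactive grids), `active`, `L`, `method`, and after
#'   [gradient_field()] a `gradient` matrix.
#' @export
pseudotime_to_grid <- function(gem, L = 40, method = c("knn", "polynomial"),
                               k = 30, degree = 3, field = NULL,
                               sigma = NULL, min_mass_frac = 0.01) {
  method <- match.arg(method)
  if (is.null(gem$pseudotime)) stop("gem has no pseudotime")
  pt <- gem$pseudotime
  if (stats::sd(pt) == 0)
    warning("pseudotime is constant; gradient field will be zero")
  if (!is.null(field)) {
    points <- field$points; active <- field$active
    L <- field$L; gx <- field$gx; gy <- field$gy
  } else {
    geo <- grid_geometry(gem$embedding, L)
    points <- geo$points; gx <- geo$gx; gy <- geo$gy
    if (is.null(sigma)) sigma <- default_sigma(gem$embedding, L)
    mass <- rowSums(gaussian_mass(points, gem$embedding, sigma))
    active <- mass >= min_mass_frac * max(mass)
  }
  t_grid <- rep(NA_real_, nrow(points))
  act <- which(active)
  if (method == "knn") {
    k <- min(k, nrow(gem$embedding))
    for (g in act) {
      d2 <- (gem$embedding[, 1] - points[g, 1])^2 +
        (gem$embedding[, 2] - points[g, 2])^2
      nb <- order(d2, seq_along(d2))[seq_len(k)]
      t_grid[g] <- mean(pt[nb])
    }
  } else {
    df <- data.frame(t = pt, x = gem$embedding[, 1], y = gem$embedding[, 2])
    fit <- stats::lm(t ~ stats::poly(x, degree, raw = TRUE) +
                       stats::poly(y, degree, raw = TRUE), data = df)
    nd <- data.frame(x = points[act, 1], y = points[act, 2])
    t_grid[act] <- stats::predict(fit, newdata = nd)
  }
  structure(list(points = points, gx = gx, gy = gy, t = t_grid,
                 active = active, L = L, method = method, gradient = NULL),
            class = "pseudotime_field")
}

#' Numerical gradient of the grid pseudotime field
#'
#' Central differences on the grid (per data-coordinate unit), one-sided at
#' the borders; inactive grids are excluded from stencils, and grids with no
#' usable neighbour along an axis get a zero component. The gradient is set
#' to zero on inactive grids.
#'
#' @param pf a `pseudotime_field` from [pseudotime_to_grid()].
#' @return the field with `gradient` (L^2 x 2) set.
#' @export
gradient_field <- function(pf) {
  L <- pf$L
  tg <- matrix(pf$t, L, L)          # [ix, iy], row-major-in-x points
  amat <- matrix(pf$active, L, L)
  dx <- if (L > 1) pf$gx[2] - pf$gx[1] else 1
  dy <- if (L > 1) pf$gy[2] - pf$gy[1] else 1
  grad <- matrix(0, L * L, 2)
  axis_grad <- function(ix, iy, along) {
    if (along == 1) { lo <- c(ix - 1, iy); hi <- c(ix + 1, iy); h <- dx }
    else { lo <- c(ix, iy - 1); hi <- c(ix, iy + 1); h <- dy }
    ok <- function(p) p[1] >= 1 && p[1] <= L && p[2] >= 1 && p[2] <= L &&
      amat[p[1], p[2]]
    has_lo <- ok(lo); has_hi <- ok(hi)
    if (has_lo && has_hi) (tg[hi[1], hi[2]] - tg[lo[1], lo[2]]) / (2 * h)
    else if (has_hi) (tg[hi[1], hi[2]] - tg[ix, iy]) / h
    else if (has_lo) (tg[ix, iy] - tg[lo[1], lo[2]]) / h
    else 0
  }
  for (iy in seq_len(L)) for (ix in seq_len(L)) {
    g <- (iy - 1) * L + ix
    if (!amat[ix, iy]) next
    grad[g, 1] <- axis_grad(ix, iy, 1)
    grad[g, 2] <- axis_grad(ix, iy, 2)
  }
  pf$gradient <- grad
  pf
}

#' Perturbation score: inner product of simulation and gradient fields
#'
#' `ps[g] = <v_sim[g], grad_t[g]>` on active grids (0 elsewhere); with
#' `normalize = TRUE` both vectors are unit-normalized first (cosine mode).
#' The negative PS sum is `sum(|ps|)` over grids with negative PS,
#' optionally restricted to a grid mask (e.g. a lineage of interest).
#'
#' @param sim a `grid_field` from a perturbation simulation.
#' @param pf a `pseudotime_field` with gradient set; must share `L` and the
#'   active mask with `sim`.
#' @param normalize cosine mode (default FALSE: raw inner product).
#' @param mask optional logical vector over grid points restricting the
#'   negative-PS sum.
#' @return object of class `ps_result`: `ps` (per-grid), `negative_ps_sum`,
#'   `positive_ps_sum`.
#' @export
perturbation_score <- function(sim, pf, normalize = FALSE, mask = NULL) {
  if (sim$L != pf$L || !identical(sim$active, pf$active))
    stop("simulation field and pseudotime field have mismatched grid/mask")
  if (is.null(pf$gradient)) stop("pseudotime field has no gradient; run gradient_field()")
  v <- sim$vectors
  g <- pf$gradient
  if (normalize) {
    nv <- sqrt(rowSums(v^2)); ng <- sqrt(rowSums(g^2))
    v <- v / pmax(nv, .Machine$double.eps)
    g <- g / pmax(ng, .Machine$double.eps)
    v[nv == 0, ] <- 0; g[ng == 0, ] <- 0
  }
  ps <- rowSums(v * g)
  ps[!sim$active] <- 0
  sel <- if (is.null(mask)) rep(TRUE, length(ps)) else mask
  neg <- sum(abs(ps[sel & ps < 0]))
  pos <- sum(ps[sel & ps > 0])
  structure(list(ps = ps, negative_ps_sum = neg, positive_ps_sum = pos),
            class = "ps_result")
}

#' Randomize fitted GRNs to build a null model
#'
#' Per cluster and per target gene, the coefficient values are permuted
#' among that target's nonzero edges and each is sign-flipped with
#' probability 0.5. The per-target number of nonzero edges (degree
#' structure) is preserved exactly.
#'
#' @param grns a `cluster_grn_set`.
#' @param seed integer seed; same seed, same randomization.
#' @return a randomized `cluster_grn_set`.
#' @export
randomize_grn <- function(grns, seed) {
  with_seed(seed, {
    out <- grns
    for (cl in names(grns)) {
      B <- grns[[cl]]$B
      for (j in seq_len(ncol(B))) {
        nz <- which(B[, j] != 0)
        if (length(nz) == 0) next
        vals <- B[nz, j]
        vals <- vals[sample.int(length(vals))] *
          (1 - 2 * stats::rbinom(length(vals), 1, 0.5))
        B[nz, j] <- vals
      }
      out[[cl]]$B <- B
      e <- out[[cl]]$edges
      if (nrow(e) > 0) {
        e$coef_mean <- B[cbind(e$source, e$target)]
        out[[cl]]$edges <- e
      }
    }
    out
  })
}

#' FPR-calibrated cutoff from null negative-PS sums
#'
#' Nearest-rank `(1 - fpr)` quantile of the null scores (default fpr 0.01,
#' i.e. the 99th percentile).
#'
#' @param null_scores numeric vector (>= 20 values).
#' @param fpr false-positive rate in (0, 1).
#' @return the cutoff value.
#' @export
ps_cutoff <- function(null_scores, fpr = 0.01) {
  stopifnot(fpr > 0, fpr < 1)
  if (length(null_scores) < 20)
    stop("need at least 20 null scores for a cutoff")
  s <- sort(null_scores)
  rank <- ceiling((1 - fpr) * length(s))
  s[max(1L, rank)]
}

#' Grid mask for a set of clusters (majority vote per grid)
#'
#' Each active grid point is assigned the cluster most common among the
#' cells nearest to it (by assigning every cell to its nearest grid point);
#' the mask selects grids whose majority cluster is in `clusters`.
#'
#' @param field a `grid_field` (geometry source).
#' @param gem a [gem_bundle()].
#' @param clusters character vector of cluster labels.
#' @return logical vector over grid points.
#' @export
lineage_mask <- function(field, gem, clusters) {
  n_grid <- nrow(field$points)
  assign <- integer(nrow(gem$embedding))
  for (i in seq_len(nrow(gem$embedding))) {
    d2 <- (field$points[, 1] - gem$embedding[i, 1])^2 +
      (field$points[, 2] - gem$embedding[i, 2])^2
    assign[i] <- which.min(d2)
  }
  mask <- rep(FALSE, n_grid)
  for (g in unique(assign)) {
    cl <- gem$cluster[assign == g]
    top <- names(sort(table(cl), decreasing = TRUE))[1]
    mask[g] <- top %in% clusters
  }
  mask & field$active
}

#' Rank TFs by lineage-restricted negative perturbation-score sums
#'
#' Runs a knockout simulation for every active TF (>= 1 nonzero GRN edge),
#' scores its grid field against the pseudotime gradient, and sums |PS| over
#' negative-PS grids inside `mask`. Null sums are generated by repeating
#' the simulation under randomized GRNs ([randomize_grn()]), pooled across
#' TFs, and turned into an FPR cutoff ([ps_cutoff()]).
#'
#' @param gem a [gem_bundle()] (imputed; with pseudotime).
#' @param grns a `cluster_grn_set`.
#' @param tf_list TFs to test; inactive TFs are skipped with a warning.
#' @param mask optional logical grid mask (e.g. [lineage_mask()]).
#' @param fpr false-positive rate for the cutoff (default 0.01).
#' @param n_null number of null scores (default 100).
#' @param seed integer seed for the null randomizations.
#' @param n,k,T,L,sigma,min_mass_frac simulation parameters (see
#'   [simulate_perturbation()]).
#' @param pt_method,pt_k,pt_degree pseudotime transfer parameters (see
#'   [pseudotime_to_grid()]).
#' @return list with `table` (data.frame tf, neg_ps_sum, exceeds_cutoff,
#'   sorted descending), `cutoff`, `null_scores`.
#' @export
rank_tfs <- function(gem, grns, tf_list, mask = NULL, fpr = 0.01,
                     n_null = 100, seed = 0, n = 3, k = 200, T = 0.05,
                     L = 40, sigma = NULL, min_mass_frac = 0.01,
                     pt_method = "knn", pt_k = 30, pt_degree = 3) {
  active_tf <- tf_list[vapply(tf_list, function(tf)
    tf %in% gem$gene_ids && any(vapply(grns, function(g)
      any(g$B[tf, ] != 0), TRUE)), TRUE)]
  dropped <- setdiff(tf_list, active_tf)
  if (length(dropped) > 0)
    warning("skipping TFs with no GRN edges: ", paste(dropped, collapse = ", "))
  k_eff <- min(k, nrow(gem$X) - 1L)
  nb <- knn_indices(gem$embedding, k_eff, include_self = FALSE)
  score_one <- function(grn_set, tf, pf) {
    sim <- simulate_perturbation(gem, grn_set, tf, value = 0, n = n,
                                 k = k_eff, T = T, L = L, sigma = sigma,
                                 min_mass_frac = min_mass_frac,
                                 neighbors = nb)
    perturbation_score(sim$field, pf, mask = mask)$negative_ps_sum
  }
  # geometry/mask fixed by cell density only, so one pseudotime field serves
  ref_field <- grid_field(structure(list(V = matrix(0, nrow(gem$X), 2)),
                                    class = "cell_vectors"),
                          gem, L = L, sigma = sigma,
                          min_mass_frac = min_mass_frac)
  pf <- gradient_field(pseudotime_to_grid(
    gem, method = pt_method, k = pt_k, degree = pt_degree, field = ref_field))
  scores <- vapply(active_tf, function(tf) score_one(grns, tf, pf), 0)
  null_scores <- numeric(n_null)
  for (r in seq_len(n_null)) {
    g_null <- randomize_grn(grns, seed = seed * 1000L + r)
    tf <- active_tf[(r - 1L) %% length(active_tf) + 1L]
    null_scores[r] <- score_one(g_null, tf, pf)
  }
  cutoff <- ps_cutoff(null_scores, fpr = fpr)
  tab <- data.frame(tf = active_tf, neg_ps_sum = scores,
                    cutoff = cutoff,
                    exceeds_cutoff = scores > cutoff)
  tab <- tab[order(-tab$neg_ps_sum, tab$tf), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, cutoff = cutoff, null_scores = null_scores,
       pseudotime_field = pf)
}
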