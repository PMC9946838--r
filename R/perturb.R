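#' In silico TF perturbation: propagation, transition probabilities, fields
#'
#' The perturbation simulator treats the fitted cluster GRN as a linear
#' response function: a shift in one TF's expression propagates to its
#' (direct and indirect) targets by iterated multiplication with the
#' coefficient matrix. The resulting per-cell expression-shift vector is
#' compared against the expression offsets toward embedding neighbours to
#' obtain cell-state transition probabilities, which are projected to 2D
#' transition vectors and summarized on a grid vector field.
#'
#' @name perturb_sim
NULL

# k nearest neighbours per row of a coordinate matrix (ties broken by row
# index for determinism). include_self: whether a point counts among its own
# neighbours.
knn_indices <- function(coords, k, include_self = FALSE) {
  n <- nrow(coords)
  D <- as.matrix(stats::dist(coords))
  if (!include_self) diag(D) <- Inf
  res <- apply(D, 1, function(d) order(d, seq_len(n))[seq_len(k)])
  if (is.null(dim(res))) res <- matrix(res, nrow = 1L)   # k = 1
  t(res)
}

#' KNN-impute expression ahead of simulation
#'
#' Replaces each cell's expression with the mean over its `k` nearest cells
#' (self inclusive) in PCA space of `log1p(X)`. Imputation reduces dropout
#' noise in the transition-probability correlations; the raw matrix `X` is
#' left untouched and `imputed_X` is stored alongside.
#'
#' @param gem a [gem_bundle()].
#' @param k neighbourhood size; default `max(5, round(0.025 * n_cells))`.
#' @param n_pcs number of principal components (default 30, capped by the
#'   data dimensions).
#' @return the bundle with `imputed_X` set.
#' @export
knn_impute <- function(gem, k = NULL, n_pcs = 30) {
  n <- nrow(gem$X)
  if (is.null(k)) k <- max(5L, round(0.025 * n))
  if (k >= n + 1L) stop("k must be < number of cells")
  if (k > n) k <- n
  n_pcs <- min(n_pcs, ncol(gem$X), n - 1L)
  pcs <- stats::prcomp(log1p(gem$X), center = TRUE, scale. = FALSE,
                       rank. = n_pcs)$x
  nb <- knn_indices(pcs, k, include_self = TRUE)
  imp <- matrix(0, n, ncol(gem$X), dimnames = dimnames(gem$X))
  for (i in seq_len(n))
    imp[i, ] <- colMeans(gem$X[nb[i, ], , drop = FALSE])
  gem$imputed_X <- imp
  gem
}

#' Build a perturbation specification
#'
#' A perturbation sets gene `gene` to `value` in every cell (0 = knockout);
#' the per-cell input shift is `value - x_i(gene)` and zero elsewhere. A
#' requested value outside the gene's observed per-cell expression range is
#' refused as out-of-distribution (0 is always allowed, so a knockout is
#' always legal); a gene with no GRN edge cannot be simulated.
#'
#' @param gem a [gem_bundle()] (imputed values are used when available).
#' @param gene gene symbol.
#' @param value target expression level (>= 0).
#' @param grns optional `cluster_grn_set` used to verify the gene has at
#'   least one edge.
#' @return object of class `perturbation_spec` with `gene`, `target_value`,
#'   `delta_input` (cells x 1 shifts).
#' @export
make_perturbation <- function(gem, gene, value, grns = NULL) {
  if (!gene %in% gem$gene_ids) stop("gene not in expression matrix: ", gene)
  stopifnot(value >= 0)
  X <- if (!is.null(gem$imputed_X)) gem$imputed_X else gem$X
  x <- X[, gene]
  if (value != 0 && (value > max(x) || value < min(x)))
    stop(sprintf("out-of-distribution: requested %s = %g outside observed range [%g, %g]",
                 gene, value, min(x), max(x)))
  if (!is.null(grns)) {
    has_edge <- any(vapply(grns, function(g)
      any(g$B[gene, ] != 0) || any(g$B[, gene] != 0), TRUE))
    if (!has_edge) stop("gene not in GRN (no nonzero edges): ", gene)
  }
  structure(list(gene = gene, target_value = value,
                 delta_input = value - x),
            class = "perturbation_spec")
}

#' Propagate a perturbation through the cluster GRNs
#'
#' Iterates the linear response `Delta <- Delta %*% B` for `n` rounds per
#' cluster, with, in order within each round: (1) the matrix product,
#' (2) the perturbed gene's entry reset to the input shift, (3) simulated
#' levels floored at zero (`imputed_X + Delta >= 0`), and (4), when
#' `clip_delta = TRUE`, simulated levels clipped into the gene's wild-type
#' range. Three rounds (the default) are enough for the shift magnitude to
#' saturate on attenuating networks.
#'
#' @param spec a `perturbation_spec`.
#' @param grns a `cluster_grn_set` covering every cluster present.
#' @param gem a [gem_bundle()]; `imputed_X` must be set (see
#'   [knn_impute()]) or the raw matrix is used with a log note.
#' @param n number of propagation rounds (default 3).
#' @param clip_delta clip simulated levels into the wild-type per-gene range.
#' @return object of class `shift_result`: `delta` (cells x genes),
#'   `n_propagation`, `max_exceedance` (per-gene % above the wild-type
#'   maximum, floor 0), `gene`.
#' @export
propagate <- function(spec, grns, gem, n = 3, clip_delta = FALSE) {
  stopifnot(n >= 1)
  X <- gem$imputed_X
  if (is.null(X)) {
    gf_log("propagate: imputed_X not set; using raw X")
    X <- gem$X
  }
  missing_cl <- setdiff(unique(gem$cluster), names(grns))
  if (length(missing_cl) > 0)
    stop("no fitted GRN for cluster(s): ", paste(missing_cl, collapse = ", "))
  genes <- gem$gene_ids
  gi <- match(spec$gene, genes)
  delta <- matrix(0, nrow(X), length(genes), dimnames = dimnames(X))
  wt_max <- apply(X, 2, max)
  wt_min <- apply(X, 2, min)
  for (cl in unique(gem$cluster)) {
    rows <- which(gem$cluster == cl)
    B <- grns[[cl]]$B
    d <- matrix(0, length(rows), length(genes))
    d[, gi] <- spec$delta_input[rows]
    Xc <- X[rows, , drop = FALSE]
    for (r in seq_len(n)) {
      d <- d %*% B
      d[, gi] <- spec$delta_input[rows]
      # floor: simulated level X + d must be >= 0
      d <- pmax(d, -Xc)
      if (clip_delta) {
        d <- pmin(d, sweep(-Xc, 2, wt_max, "+"))
        d <- pmax(d, sweep(-Xc, 2, wt_min, "+"))
        d[, gi] <- spec$delta_input[rows]
      }
    }
    delta[rows, ] <- d
  }
  sim_level <- X + delta
  exc <- 100 * (apply(sim_level, 2, max) - wt_max) /
    ifelse(wt_max > 0, wt_max, 1)
  exc <- pmax(exc, 0)
  structure(list(delta = delta, n_propagation = n,
                 max_exceedance = exc, gene = spec$gene,
                 clip_delta = clip_delta),
            class = "shift_result")
}

#' @export
print.shift_result <- function(x, ...) {
  cat(sprintf("shift_result: %s perturbation, n = %d, max |delta| = %.4g\n",
              x$gene, x$n_propagation, max(abs(x$delta))))
  invisible(x)
}

# Pearson correlation of vector d against each row of R; degenerate rows
# (constant R row or constant d) give 0.
row_cor <- function(R, d) {
  dc <- d - mean(d)
  dn <- sqrt(sum(dc^2))
  if (dn == 0) return(rep(0, nrow(R)))
  Rc <- R - rowMeans(R)
  rn <- sqrt(rowSums(Rc^2))
  out <- as.vector(Rc %*% dc) / (rn * dn)
  out[rn == 0] <- 0
  out
}

#' Cell-state transition probabilities from a simulated shift
#'
#' For each cell i, the Pearson correlation (over genes) between its
#' simulated shift `d_i` and the expression offset `r_ij = X_j - X_i`
#' toward each of its k nearest embedding neighbours j is passed through a
#' softmax with temperature `T`:
#'
#'   p_ij = exp(corr(r_ij, d_i) / T) / sum_j exp(corr(r_ij, d_i) / T)
#'
#' Degenerate correlations (all-zero shift, constant offset) are defined as
#' zero. Neighbourhoods are computed on the embedding with ties broken by
#' cell index.
#'
#' @param shift a `shift_result`.
#' @param gem a [gem_bundle()].
#' @param k number of embedding neighbours (default 200, capped at
#'   `n_cells - 1`).
#' @param T softmax temperature (default 0.05).
#' @param use_imputed correlate against imputed expression offsets
#'   (default TRUE when available).
#' @param neighbors optional precomputed cells x k neighbour-index matrix
#'   (saves repeated KNN searches when simulating many TFs).
#' @return object of class `transition_model`: `neighbors` (cells x k),
#'   `P` (cells x k row-stochastic), `T`, `k`.
#' @export
transition_probabilities <- function(shift, gem, k = 200, T = 0.05,
                                     use_imputed = TRUE, neighbors = NULL) {
  n <- nrow(gem$X)
  k <- min(k, n - 1L)
  stopifnot(k >= 1)
  X <- if (use_imputed && !is.null(gem$imputed_X)) gem$imputed_X else gem$X
  nb <- if (is.null(neighbors)) {
    knn_indices(gem$embedding, k, include_self = FALSE)
  } else {
    stopifnot(ncol(neighbors) >= k)
    neighbors[, seq_len(k), drop = FALSE]
  }
  P <- matrix(0, n, k)
  for (i in seq_len(n)) {
    R <- X[nb[i, ], , drop = FALSE] -
      matrix(X[i, ], k, ncol(X), byrow = TRUE)
    co <- row_cor(R, shift$delta[i, ])
    e <- exp((co - max(co)) / T)   # shift-invariant softmax
    P[i, ] <- e / sum(e)
  }
  structure(list(neighbors = nb, P = P, T = T, k = k),
            class = "transition_model")
}

#' Project transition probabilities to per-cell 2D vectors
#'
#' The simulated transition vector of cell i is the probability-weighted
#' average of the embedding offsets toward its neighbours:
#' `V_i = sum_j p_ij (embedding_j - embedding_i)`.
#'
#' @param tm a `transition_model`.
#' @param gem a [gem_bundle()].
#' @return object of class `cell_vectors` with `V` (cells x 2).
#' @export
project_vectors <- function(tm, gem) {
  n <- nrow(gem$embedding)
  V <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    off <- gem$embedding[tm$neighbors[i, ], , drop = FALSE] -
      matrix(gem$embedding[i, ], tm$k, 2, byrow = TRUE)
    V[i, ] <- colSums(off * tm$P[i, ])
  }
  structure(list(V = V), class = "cell_vectors")
}

# grid geometry shared by grid_field and the pseudotime field
grid_geometry <- function(embedding, L) {
  rng_x <- range(embedding[, 1])
  rng_y <- range(embedding[, 2])
  gx <- seq(rng_x[1], rng_x[2], length.out = L)
  gy <- seq(rng_y[1], rng_y[2], length.out = L)
  pts <- cbind(rep(gx, times = L), rep(gy, each = L))  # row-major in x
  list(gx = gx, gy = gy, points = pts)
}

default_sigma <- function(embedding, L) {
  d <- sqrt(diff(range(embedding[, 1]))^2 + diff(range(embedding[, 2]))^2)
  d / (L * 2)
}

gaussian_mass <- function(points, embedding, sigma) {
  W <- matrix(0, nrow(points), nrow(embedding))
  for (g in seq_len(nrow(points))) {
    d2 <- (embedding[, 1] - points[g, 1])^2 + (embedding[, 2] - points[g, 2])^2
    W[g, ] <- exp(-d2 / (2 * sigma^2))
  }
  W
}

#' Summarize per-cell vectors on an L x L grid (Gaussian kernel smoothing)
#'
#' Each grid point g receives the kernel-weighted average of the cell
#' vectors, with weights `w_i = exp(-||g - embedding_i||^2 / (2 sigma^2))`.
#' The weighted *average* (sum of weighted vectors divided by the mass
#' `sum w_i`) is reported so the field does not scale with local cell
#' density; the mass is kept alongside. Grid points whose mass falls below
#' `min_mass_frac` of the maximum grid mass are inactive: their vector is
#' zero and they are excluded from downstream scores.
#'
#' @param cv a `cell_vectors`.
#' @param gem a [gem_bundle()].
#' @param L grid points per axis (default 40).
#' @param sigma kernel bandwidth; default = embedding bounding-box diagonal
#'   / (2 L).
#' @param min_mass_frac inactivity threshold as a fraction of the maximum
#'   grid mass (default 0.01).
#' @return object of class `grid_field`: `points` (L^2 x 2), `vectors`
#'   (L^2 x 2), `mass`, `active` (logical), `L`, `sigma`.
#' @export
grid_field <- function(cv, gem, L = 40, sigma = NULL, min_mass_frac = 0.01) {
  stopifnot(L >= 2)
  geo <- grid_geometry(gem$embedding, L)
  if (is.null(sigma)) sigma <- default_sigma(gem$embedding, L)
  stopifnot(sigma > 0)
  W <- gaussian_mass(geo$points, gem$embedding, sigma)
  mass <- rowSums(W)
  vectors <- (W %*% cv$V) / pmax(mass, .Machine$double.eps)
  active <- mass >= min_mass_frac * max(mass)
  vectors[!active, ] <- 0
  structure(list(points = geo$points, gx = geo$gx, gy = geo$gy,
                 vectors = vectors, mass = mass, active = active,
                 L = L, sigma = sigma),
            class = "grid_field")
}

#' @export
print.grid_field <- function(x, ...) {
  cat(sprintf("grid_field: %d x %d, %d active grids, sigma = %.3g\n",
              x$L, x$L, sum(x$active), x$sigma))
  invisible(x)
}

#' One-call knockout/overexpression simulation to a grid vector field
#'
#' Convenience wrapper: [make_perturbation()] then [propagate()],
#' [transition_probabilities()], [project_vectors()], [grid_field()].
#'
#' @inheritParams propagate
#' @inheritParams transition_probabilities
#' @inheritParams grid_field
#' @param gene gene symbol; `value` target level (0 = knockout).
#' @param value target expression value.
#' @return list with `shift`, `tm`, `cv`, `field`.
#' @export
simulate_perturbation <- function(gem, grns, gene, value = 0, n = 3,
                                  clip_delta = FALSE, k = 200, T = 0.05,
                                  L = 40, sigma = NULL, min_mass_frac = 0.01,
                                  neighbors = NULL) {
  spec <- make_perturbation(gem, gene, value, grns = grns)
  shift <- propagate(spec, grns, gem, n = n, clip_delta = clip_delta)
  tm <- transition_probabilities(shift, gem, k = k, T = T,
                                 neighbors = neighbors)
  cv <- project_vectors(tm, gem)
  field <- grid_field(cv, gem, L = L, sigma = sigma,
                      min_mass_frac = min_mass_frac)
  list(shift = shift, tm = tm, cv = cv, field = field)
}
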