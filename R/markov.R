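#' Markov random-walk cell-density simulation
#'
#' Estimates where cells accumulate after a perturbation by a random walk
#' over cells that alternates two row-stochastic transition matrices: one
#' built from the differentiation (pseudotime-gradient) vectors, one from
#' the perturbation transition vectors. The walk starts from cells in early
#' differentiation stages and is propagated as an exact probability
#' distribution (optionally by particle sampling).
#'
#' @name markov_density
NULL

#' Transition matrix from per-cell 2D vectors
#'
#' For cell i with vector `V_i`, the probability of stepping to embedding
#' neighbour j is `p_ij ~ exp(cos_angle(V_i, V_ij) / T)` over the k nearest
#' neighbours, where `V_ij` is the embedding offset toward j. A zero vector
#' gives a uniform row over the neighbours (logged).
#'
#' @param cv a `cell_vectors` (perturbation vectors, or differentiation
#'   vectors sampled at cell positions).
#' @param gem a [gem_bundle()].
#' @param k number of neighbours (default 200, capped).
#' @param T softmax temperature (default 0.05).
#' @return sparse row-stochastic matrix (cells x cells, `Matrix::dgCMatrix`).
#' @export
vectors_to_transition <- function(cv, gem, k = 200, T = 0.05) {
  n <- nrow(gem$embedding)
  k <- min(k, n - 1L)
  nb <- knn_indices(gem$embedding, k, include_self = FALSE)
  ii <- jj <- integer(n * k); xx <- numeric(n * k)
  n_zero <- 0L
  for (i in seq_len(n)) {
    off <- gem$embedding[nb[i, ], , drop = FALSE] -
      matrix(gem$embedding[i, ], k, 2, byrow = TRUE)
    vi <- cv$V[i, ]
    nv <- sqrt(sum(vi^2))
    if (nv == 0) {
      p <- rep(1 / k, k)
      n_zero <- n_zero + 1L
    } else {
      no <- sqrt(rowSums(off^2))
      cosang <- as.vector(off %*% vi) / (pmax(no, .Machine$double.eps) * nv)
      cosang[no == 0] <- 0
      e <- exp((cosang - max(cosang)) / T)
      p <- e / sum(e)
    }
    sl <- ((i - 1L) * k + 1L):(i * k)
    ii[sl] <- i; jj[sl] <- nb[i, ]; xx[sl] <- p
  }
  if (n_zero > 0)
    gf_log("vectors_to_transition: %d cells with zero vector -> uniform rows",
           n_zero)
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
}

#' Differentiation vectors: pseudotime gradient sampled at cell positions
#'
#' Each cell receives the gradient vector of its nearest active grid point,
#' giving per-cell differentiation-direction vectors for
#' [vectors_to_transition()].
#'
#' @param pf a `pseudotime_field` with gradient.
#' @param gem a [gem_bundle()].
#' @return a `cell_vectors`.
#' @export
gradient_at_cells <- function(pf, gem) {
  if (is.null(pf$gradient)) stop("pseudotime field has no gradient")
  act <- which(pf$active)
  V <- matrix(0, nrow(gem$embedding), 2)
  for (i in seq_len(nrow(gem$embedding))) {
    d2 <- (pf$points[act, 1] - gem$embedding[i, 1])^2 +
      (pf$points[act, 2] - gem$embedding[i, 2])^2
    V[i, ] <- pf$gradient[act[which.min(d2)], ]
  }
  structure(list(V = V), class = "cell_vectors")
}

check_stochastic <- function(P, label) {
  rs <- Matrix::rowSums(P)
  bad <- which(abs(rs - 1) > 1e-8)
  if (length(bad) > 0)
    stop(sprintf("%s: row %d is not stochastic (sum = %.6g)",
                 label, bad[1], rs[bad[1]]))
  invisible(TRUE)
}

#' Run the alternating Markov walk
#'
#' The occupancy starts uniform over `initial_mask` and is propagated for
#' `n_steps`; step t applies the differentiation matrix when t is odd and
#' the perturbation matrix when t is even (alternation starts with
#' differentiation; configurable via `schedule`). Default is exact
#' vector-matrix propagation; `n_particles > 0` switches to seeded particle
#' sampling.
#'
#' @param diff_P,pert_P row-stochastic cells x cells matrices over the same
#'   cells.
#' @param initial_mask logical (or index) vector of starting cells.
#' @param n_steps number of steps (default 50).
#' @param schedule function(step) returning "diff" or "pert"; default
#'   alternation.
#' @param n_particles 0 for exact propagation, else particle count.
#' @param seed seed for sampling mode.
#' @return object of class `markov_result`: `occupancy` (steps+1 x cells;
#'   row 1 is the initial state), `n_steps`, `final` (last row).
#' @export
run_markov <- function(diff_P, pert_P, initial_mask, n_steps = 50,
                       schedule = NULL, n_particles = 0, seed = 0) {
  stopifnot(n_steps >= 1)
  n <- nrow(diff_P)
  check_stochastic(diff_P, "diff_P")
  check_stochastic(pert_P, "pert_P")
  if (is.logical(initial_mask)) initial_mask <- which(initial_mask)
  stopifnot(length(initial_mask) >= 1)
  if (is.null(schedule))
    schedule <- function(step) if (step %% 2 == 1) "diff" else "pert"
  p0 <- numeric(n)
  p0[initial_mask] <- 1 / length(initial_mask)
  occ <- matrix(0, n_steps + 1L, n)
  occ[1, ] <- p0
  if (n_particles <= 0) {
    p <- p0
    for (s in seq_len(n_steps)) {
      M <- if (schedule(s) == "diff") diff_P else pert_P
      p <- as.vector(Matrix::crossprod(M, p))
      occ[s + 1L, ] <- p
    }
  } else {
    occ <- with_seed(seed, {
      # particle counts per cell; particles at the same cell draw one
      # multinomial jointly
      cnt <- tabulate(sample(initial_mask, n_particles, replace = TRUE), n)
      occ[1, ] <- cnt / n_particles
      for (s in seq_len(n_steps)) {
        M <- if (schedule(s) == "diff") diff_P else pert_P
        new_cnt <- integer(n)
        for (i in which(cnt > 0L)) {
          row <- M[i, ]
          nz <- which(row != 0)
          draws <- stats::rmultinom(1, cnt[i], prob = row[nz])[, 1]
          new_cnt[nz] <- new_cnt[nz] + draws
        }
        cnt <- new_cnt
        occ[s + 1L, ] <- cnt / n_particles
      }
      occ
    })
  }
  structure(list(occupancy = occ, n_steps = n_steps,
                 initial_mask = initial_mask, final = occ[n_steps + 1L, ]),
            class = "markov_result")
}

#' @export
print.markov_result <- function(x, ...) {
  cat(sprintf("markov_result: %d steps over %d cells, %d initial cells\n",
              x$n_steps, ncol(x$occupancy), length(x$initial_mask)))
  invisible(x)
}

#' Compare per-cluster occupancy mass between two walks
#'
#' Sums the final occupancy per cluster for a wild-type and a perturbed
#' walk and reports their difference and ratio.
#'
#' @param wt,ko `markov_result` objects (or numeric occupancy vectors) over
#'   the same cells.
#' @param cluster per-cell cluster labels.
#' @return data.frame: cluster, wt_mass, ko_mass, diff (ko - wt), ratio.
#' @export
density_compare <- function(wt, ko, cluster) {
  get_occ <- function(x) if (inherits(x, "markov_result")) x$final else x
  w <- get_occ(wt); k <- get_occ(ko)
  stopifnot(length(w) == length(k), length(w) == length(cluster))
  wt_mass <- tapply(w, cluster, sum)
  ko_mass <- tapply(k, cluster, sum)
  data.frame(cluster = names(wt_mass),
             wt_mass = as.numeric(wt_mass),
             ko_mass = as.numeric(ko_mass),
             diff = as.numeric(ko_mass - wt_mass),
             ratio = as.numeric(ifelse(wt_mass > 0, ko_mass / wt_mass, NA)),
             row.names = NULL)
}

#' Early-stage initial mask from a pseudotime quantile
#' @param gem a [gem_bundle()] with pseudotime.
#' @param quantile cells at or below this pseudotime quantile are initial
#'   (default 0.1).
#' @return logical vector over cells.
#' @export
early_cells <- function(gem, quantile = 0.1) {
  if (is.null(gem$pseudotime)) stop("gem has no pseudotime")
  gem$pseudotime <= stats::quantile(gem$pseudotime, quantile)
}
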