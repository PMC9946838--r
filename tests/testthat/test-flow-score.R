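grid_gem <- function(n = 200, seed = 20, pt = NULL) {
  set.seed(seed)
  emb <- cbind(runif(n, 0, 10), runif(n, 0, 10))
  if (is.null(pt)) pt <- emb[, 1]
  toy_gem(matrix(1, n, 2), embedding = emb, pseudotime = pmax(pt, 0))
}

test_that("pseudotime transfers to the grid by KNN and polynomial regression", {
  gem <- grid_gem()
  pf <- pseudotime_to_grid(gem, L = 10, method = "knn", k = 10)
  act <- which(pf$active)
  # pseudotime = x coordinate: grid pseudotime tracks grid x
  expect_gt(cor(pf$t[act], pf$points[act, 1]), 0.98)

  # constant pseudotime: all active grids equal it (and a warning)
  gemc <- grid_gem(pt = rep(5, 200))
  expect_warning(pfc <- pseudotime_to_grid(gemc, L = 8, method = "knn"),
                 "constant")
  expect_true(all(abs(pfc$t[pfc$active] - 5) < 1e-12))

  # two-cluster ramp, polynomial degree 1: matches the least-squares line
  set.seed(21)
  x <- c(runif(100, 0, 1), runif(100, 4, 5))
  gem2 <- toy_gem(matrix(1, 200, 2),
                  embedding = cbind(x, runif(200, 0, 1)),
                  pseudotime = c(rep(0, 100), rep(1, 100)))
  pf2 <- pseudotime_to_grid(gem2, L = 8, method = "polynomial", degree = 1)
  ls <- lm(t ~ x + y, data = data.frame(t = gem2$pseudotime, x = x,
                                        y = gem2$embedding[, 2]))
  pred <- cbind(1, pf2$points[pf2$active, ]) %*% coef(ls)
  expect_equal(pf2$t[pf2$active], as.vector(pred), tolerance = 1e-8)
})

test_that("gradient_field computes central differences per coordinate", {
  gem <- grid_gem()
  mk <- function(fun) {
    pf <- pseudotime_to_grid(gem, L = 10, method = "knn", k = 5)
    pf$t <- fun(pf$points[, 1], pf$points[, 2])
    pf$active <- rep(TRUE, nrow(pf$points))
    gradient_field(pf)
  }
  interior <- function(pf) {
    ix <- ((seq_len(nrow(pf$points)) - 1) %% pf$L) + 1
    iy <- ((seq_len(nrow(pf$points)) - 1) %/% pf$L) + 1
    ix > 1 & ix < pf$L & iy > 1 & iy < pf$L
  }
  g1 <- mk(function(x, y) x)
  expect_true(all(abs(g1$gradient[interior(g1), 1] - 1) < 1e-9))
  expect_true(all(abs(g1$gradient[interior(g1), 2]) < 1e-9))
  g2 <- mk(function(x, y) y)
  expect_true(all(abs(g2$gradient[interior(g2), 1]) < 1e-9))
  expect_true(all(abs(g2$gradient[interior(g2), 2] - 1) < 1e-9))
  g3 <- mk(function(x, y) x + 2 * y)
  expect_true(all(abs(g3$gradient[interior(g3), 1] - 1) < 1e-9))
  expect_true(all(abs(g3$gradient[interior(g3), 2] - 2) < 1e-9))
  # constant field: zero gradient everywhere
  g0 <- mk(function(x, y) rep(3, length(x)))
  expect_true(all(g0$gradient == 0))
})

test_that("gradient of a KNN-transferred ramp points along the ramp", {
  gem <- grid_gem(n = 400)
  pf <- gradient_field(pseudotime_to_grid(gem, L = 10, method = "knn",
                                          k = 20))
  ix <- ((seq_len(nrow(pf$points)) - 1) %% pf$L) + 1
  iy <- ((seq_len(nrow(pf$points)) - 1) %/% pf$L) + 1
  interior <- pf$active & ix > 1 & ix < pf$L & iy > 1 & iy < pf$L
  g <- pf$gradient[interior, , drop = FALSE]
  cosine <- g[, 1] / sqrt(rowSums(g^2))
  expect_gt(mean(cosine), 0.99)
})

test_that("perturbation score is the inner product with sign bookkeeping", {
  gem <- grid_gem()
  base <- grid_field(structure(list(V = matrix(0, 200, 2)),
                               class = "cell_vectors"), gem, L = 6)
  pf <- pseudotime_to_grid(gem, L = 6, field = base)
  pf$gradient <- matrix(rep(c(1, 0), each = nrow(base$points)),
                        ncol = 2)
  mk_sim <- function(vx, vy) {
    f <- base
    f$vectors <- matrix(rep(c(vx, vy), each = nrow(base$points)), ncol = 2)
    f$vectors[!f$active, ] <- 0
    f
  }
  aligned <- perturbation_score(mk_sim(1, 0), pf)
  expect_true(all(aligned$ps[base$active] == 1))
  expect_equal(aligned$negative_ps_sum, 0)
  opposed <- perturbation_score(mk_sim(-1, 0), pf)
  expect_true(all(opposed$ps[base$active] == -1))
  expect_equal(opposed$negative_ps_sum, sum(base$active))
  ortho <- perturbation_score(mk_sim(0, 1), pf)
  expect_true(all(ortho$ps == 0))

  # antisymmetry: negating the simulation field swaps the PS sums
  set.seed(22)
  f <- base
  f$vectors[f$active, ] <- matrix(rnorm(2 * sum(f$active)), ncol = 2)
  fneg <- f; fneg$vectors <- -f$vectors
  a <- perturbation_score(f, pf); b <- perturbation_score(fneg, pf)
  expect_equal(a$negative_ps_sum, b$positive_ps_sum, tolerance = 1e-12)
  expect_equal(a$positive_ps_sum, b$negative_ps_sum, tolerance = 1e-12)
  expect_equal(a$ps, -b$ps, tolerance = 1e-12)

  # bilinearity: scaling the simulation field scales every PS
  fs <- f; fs$vectors <- 2.5 * f$vectors
  expect_equal(perturbation_score(fs, pf)$ps, 2.5 * a$ps, tolerance = 1e-12)

  # mask mismatch is fatal
  pf_bad <- pf; pf_bad$active <- !pf$active
  expect_error(perturbation_score(f, pf_bad), "mismatch")
})

test_that("randomize_grn permutes within-target coefficients with sign flips", {
  g <- small_grns()
  r1 <- randomize_grn(g, seed = 4)
  r2 <- randomize_grn(g, seed = 4)
  expect_equal(r1[["c1"]]$B, r2[["c1"]]$B)   # seeded determinism
  for (cl in names(g)) {
    B0 <- g[[cl]]$B; B1 <- r1[[cl]]$B
    expect_equal(colSums(B0 != 0), colSums(B1 != 0))   # degree preserved
    for (j in which(colSums(B0 != 0) > 0)) {
      expect_equal(unname(sort(abs(B1[B1[, j] != 0, j]))),
                   unname(sort(abs(B0[B0[, j] != 0, j]))),
                   tolerance = 1e-12)
    }
  }
  # sign-flip symmetry: a single coefficient averages to ~0 over replicates
  B <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  B["a", "b"] <- 0.8
  tg <- toy_grns(B)
  vals <- vapply(1:1000, function(s) randomize_grn(tg, s)[[1]]$B["a", "b"], 0)
  expect_lt(abs(mean(vals)), 3 * 0.8 / sqrt(1000))
})

test_that("ps_cutoff is the nearest-rank quantile of the null scores", {
  expect_equal(ps_cutoff(1:100, fpr = 0.01), 99)
  expect_equal(ps_cutoff(rep(0, 50), fpr = 0.01), 0)
  set.seed(23)
  nulls <- abs(rnorm(1000))
  # independent sorted-array oracle
  expect_equal(ps_cutoff(nulls, fpr = 0.05), sort(nulls)[950])
  expect_error(ps_cutoff(1:5, 0.01), "at least 20")
})

test_that("rank_tfs flags the lineage driver and excludes inactive TFs", {
  w <- small_world()
  gem <- small_gem_imputed()
  grns <- small_grns()
  driver <- w$grn$drivers[1]
  # a TF with zero edges everywhere must be skipped with a warning
  tf_zero <- names(which(colSums(do.call(
    rbind, lapply(grns, function(g) rowSums(g$B != 0)))[, w$grn$tfs] > 0)
    == 0))[1]
  tfs <- c(driver, "TF5", "TF9")
  if (!is.na(tf_zero)) tfs <- c(tfs, tf_zero)
  res <- withCallingHandlers(
    rank_tfs(gem, grns, tfs, fpr = 0.05, n_null = 20, seed = 2,
             k = 50, L = 15),
    warning = function(w_) invokeRestart("muffleWarning"))
  expect_true(driver %in% res$table$tf)
  drow <- res$table[res$table$tf == driver, ]
  expect_true(drow$exceeds_cutoff)
  expect_equal(res$table$neg_ps_sum, sort(res$table$neg_ps_sum,
                                          decreasing = TRUE))
  if (!is.na(tf_zero)) expect_false(tf_zero %in% res$table$tf)
})
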