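# Worlds are expensive; build each once per test run and cache.

.world_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.world_cache[[key]])) .world_cache[[key]] <- force(expr)
  .world_cache[[key]]
}

# small world for module-level tests
small_world <- function() cached("small", make_world(seed = 3, n_cells_per_cluster = 120))

small_base_grn <- function() cached("small_bg", {
  w <- small_world()
  pg <- annotate_tss(w$fixtures$peaks, w$fixtures$tss, window_bp = 0)
  regions <- select_cis_regions(pg, w$fixtures$peaks, w$fixtures$coaccess, 0.8)
  scan_motifs(regions, w$fixtures$genome, w$fixtures$motifs, 0.85)
})

small_grns <- function() cached("small_grns", {
  w <- small_world()
  infer_grns(w$gem, small_base_grn(), seed = 1)
})

small_gem_imputed <- function() cached("small_imp", knn_impute(small_world()$gem))

# reference world at the package's study conditions (acceptance suite)
acc_world <- function() cached("acc", make_world(seed = 11))

acc_base_grn <- function() cached("acc_bg", {
  w <- acc_world()
  pg <- annotate_tss(w$fixtures$peaks, w$fixtures$tss, window_bp = 0)
  regions <- select_cis_regions(pg, w$fixtures$peaks, w$fixtures$coaccess, 0.8)
  scan_motifs(regions, w$fixtures$genome, w$fixtures$motifs, 0.85)
})

acc_grns <- function() cached("acc_grns", {
  w <- acc_world()
  infer_grns(w$gem, acc_base_grn(), seed = 1)
})

acc_gem_imputed <- function() cached("acc_imp", knn_impute(acc_world()$gem))

# pooled (true, inferred) coefficient pairs over candidate edges
coef_pairs <- function(world, grns) {
  idx <- cbind(match(world$grn$edges$tf, world$grn$genes),
               match(world$grn$edges$target, world$grn$genes))
  do.call(rbind, lapply(names(grns), function(cl)
    cbind(true = world$grn$cluster_B[[cl]][idx],
          inferred = grns[[cl]]$B[idx])))
}
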