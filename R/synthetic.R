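#' Synthetic world: linear-SEM expression, trajectory, toy genome
#'
#' Generates fully in-silico fixtures for every pipeline stage: a signed
#' ground-truth GRN with cluster-specific active-edge masks, cells simulated
#' from the corresponding linear structural equation model (SEM) with
#' Gaussian residual noise, dropout and a zero floor, a 2D PCA embedding
#' with planted pseudotime along the cluster ordering, and a toy genome in
#' which each true edge is backed by the regulator's consensus motif planted
#' in the target's promoter peak. Because the SEM satisfies the inference
#' model's assumptions exactly (up to noise, dropout and the floor),
#' parameter recovery on this world is a meaningful check rather than a
#' tautology.
#'
#' @name synthetic
NULL

#' Generate a ground-truth GRN
#'
#' Gene universe = `n_tfs` TFs (named TF1..) followed by targets (G..).
#' Each target receives `edges_per_target` distinct TF regulators with
#' coefficient magnitudes uniform in `coef_range` and random signs; edges
#' out of the first `n_drivers` TFs (the lineage drivers, whose expression
#' programs ramp along the trajectory) are forced positive so that their
#' knockout opposes differentiation. Cluster variants zero a fraction
#' `inactive_frac` of edges per cluster (context-dependent regulation).
#' TFs have no regulators, so the graph is a DAG by construction.
#'
#' @param n_genes total genes (> n_tfs).
#' @param n_tfs number of TFs.
#' @param edges_per_target regulators per target gene.
#' @param coef_range length-2 numeric: coefficient magnitude range.
#' @param n_clusters number of cluster variants.
#' @param inactive_frac fraction of edges zeroed per cluster.
#' @param n_drivers number of lineage-driver TFs (positive out-edges).
#' @param seed integer seed.
#' @return object of class `true_grn`: `genes`, `tfs`, `drivers`, `edges`
#'   (data.frame tf, target, coef), `B` (genes x genes base coefficients),
#'   `cluster_B` (named list of per-cluster masked coefficient matrices),
#'   `clusters`.
#' @export
make_grn <- function(n_genes = 100, n_tfs = 20, edges_per_target = 3,
                     coef_range = c(0.2, 1), n_clusters = 3,
                     inactive_frac = 0.25, n_drivers = 2, seed = 1) {
  stopifnot(n_tfs < n_genes, edges_per_target <= n_tfs, n_drivers <= n_tfs)
  tfs <- sprintf("TF%d", seq_len(n_tfs))
  targets <- sprintf("G%d", (n_tfs + 1):n_genes)
  genes <- c(tfs, targets)
  clusters <- sprintf("c%d", seq_len(n_clusters))
  with_seed(seed, {
    edges <- do.call(rbind, lapply(targets, function(g) {
      regs <- sample(tfs, edges_per_target)
      mag <- stats::runif(edges_per_target, coef_range[1], coef_range[2])
      sgn <- ifelse(regs %in% tfs[seq_len(n_drivers)], 1,
                    sample(c(-1, 1), edges_per_target, replace = TRUE))
      data.frame(tf = regs, target = g, coef = mag * sgn,
                 stringsAsFactors = FALSE)
    }))
    B <- matrix(0, n_genes, n_genes, dimnames = list(genes, genes))
    B[cbind(edges$tf, edges$target)] <- edges$coef
    cluster_B <- lapply(clusters, function(cl) {
      Bm <- B
      off <- sample(nrow(edges), round(inactive_frac * nrow(edges)))
      if (length(off) > 0)
        Bm[cbind(edges$tf[off], edges$target[off])] <- 0
      Bm
    })
    names(cluster_B) <- clusters
    structure(list(genes = genes, tfs = tfs,
                   drivers = tfs[seq_len(n_drivers)],
                   targets = targets, edges = edges, B = B,
                   cluster_B = cluster_B, clusters = clusters,
                   seed = seed),
              class = "true_grn")
  })
}

#' @export
print.true_grn <- function(x, ...) {
  cat(sprintf("true_grn: %d genes (%d TFs), %d edges, %d cluster variants\n",
              length(x$genes), length(x$tfs), nrow(x$edges),
              length(x$cluster_B)))
  invisible(x)
}

# per-TF, per-cluster log-normal program means: drivers ramp up along the
# cluster ordering, other TFs get independent cluster-specific levels.
default_tf_mu <- function(tg, base_range = c(0.8, 2.5), ramp = 2) {
  n_tfs <- length(tg$tfs); n_cl <- length(tg$clusters)
  base <- stats::runif(n_tfs, base_range[1], base_range[2])
  mu <- matrix(0, n_tfs, n_cl, dimnames = list(tg$tfs, tg$clusters))
  for (c in seq_len(n_cl)) {
    jitter <- stats::runif(n_tfs, 0.6, 1.4)
    mu[, c] <- base * jitter
  }
  for (d in seq_along(tg$drivers))
    mu[tg$drivers[d], ] <- base[d] * ramp^(seq_len(n_cl) - 1)
  mu
}

#' Simulate expression from the SEM
#'
#' Per cluster: TF expression is `mu_tf,cluster * exp(N(0, tf_sdlog))`
#' (log-normal around the cluster program mean); target expression follows
#' the SEM `x_j = c_j + sum_i b_ij x_i + N(0, noise_sd)` using the
#' cluster's masked coefficients; values are floored at 0 and then zeroed
#' by Bernoulli(`dropout_p`) dropout. The embedding is the first two PCs of
#' `log1p(X)`; pseudotime is the cluster's position in the planted ordering
#' plus uniform jitter. Intercepts are sized so the zero floor rarely
#' binds.
#'
#' All randomness is consumed in a fixed order, so two runs with the same
#' seed differing only in a clamped TF program (`ko_tf`) are cell-by-cell
#' paired.
#'
#' @param tg a [make_grn()] result.
#' @param n_cells_per_cluster cells per cluster (default 500).
#' @param noise_sd SEM residual sd (default 0.1).
#' @param dropout_p Bernoulli dropout probability (default 0.1).
#' @param seed integer seed.
#' @param tf_mu optional TFs x clusters program-mean matrix (default built
#'   from the seed: drivers ramp x2 per cluster step).
#' @param tf_sdlog log-normal spread of TF expression within cluster.
#' @param ko_tf optional TF whose program is clamped to zero (ground-truth
#'   knockout population).
#' @return a [gem_bundle()]; attribute `tf_mu` records the programs.
#' @export
simulate_expression <- function(tg, n_cells_per_cluster = 500,
                                noise_sd = 0.1, dropout_p = 0.1, seed = 1,
                                tf_mu = NULL, tf_sdlog = 0.3, ko_tf = NULL) {
  stopifnot(noise_sd >= 0, dropout_p >= 0, dropout_p < 1)
  genes <- tg$genes; tfs <- tg$tfs; targets <- tg$targets
  n_cl <- length(tg$clusters)
  with_seed(seed, {
    if (is.null(tf_mu)) tf_mu <- default_tf_mu(tg)
    # intercepts: keep SEM means comfortably positive despite negative
    # edges; computed from the unclamped programs so a knockout run shares
    # the wild-type model constants
    mu_max <- apply(tf_mu, 1, max)
    if (!is.null(ko_tf)) {
      stopifnot(ko_tf %in% tfs)
      tf_mu[ko_tf, ] <- 0
    }
    icept <- vapply(targets, function(g) {
      b <- tg$B[tfs, g]
      1 + 1.5 * sum(pmax(-b, 0) * mu_max)
    }, 0)
    X <- NULL; cluster <- character(); pt <- numeric()
    for (c in seq_len(n_cl)) {
      n <- n_cells_per_cluster
      Xtf <- matrix(stats::rnorm(n * length(tfs), 0, tf_sdlog), n)
      Xtf <- exp(Xtf) * matrix(tf_mu[, c], n, length(tfs), byrow = TRUE)
      colnames(Xtf) <- tfs
      noise <- matrix(stats::rnorm(n * length(targets), 0, noise_sd), n)
      Bc <- tg$cluster_B[[c]][tfs, targets, drop = FALSE]
      Xtg <- sweep(Xtf %*% Bc + noise, 2, icept, "+")
      Xc <- cbind(Xtf, Xtg)
      colnames(Xc) <- genes
      Xc[Xc < 0] <- 0
      X <- rbind(X, Xc)
      cluster <- c(cluster, rep(tg$clusters[c], n))
      pt <- c(pt, (c - 1) + stats::runif(n, 0, 0.9))
    }
    if (dropout_p > 0) {
      drop <- matrix(stats::runif(length(X)) < dropout_p, nrow(X))
      X[drop] <- 0
    }
    emb <- stats::prcomp(log1p(X), center = TRUE, rank. = 2)$x
    rownames(X) <- sprintf("cell_%d", seq_len(nrow(X)))
    gem <- gem_bundle(X, cluster = cluster, embedding = emb,
                      pseudotime = pt)
    attr(gem, "tf_mu") <- tf_mu
    gem
  })
}

#' Ground-truth knockout population
#'
#' Re-simulates the SEM with the named TF's expression program clamped to
#' zero, using the same seed (so cells are paired with the wild-type run).
#' This is the oracle population against which simulated shift directions
#' are validated.
#'
#' @param tg a [make_grn()] result.
#' @param gene a TF of the GRN.
#' @param n_cells_per_cluster,noise_sd,dropout_p,seed,tf_mu as in
#'   [simulate_expression()]; pass the same values as the wild-type run.
#' @return a [gem_bundle()].
#' @export
simulate_ko_truth <- function(tg, gene, n_cells_per_cluster = 500,
                              noise_sd = 0.1, dropout_p = 0.1, seed = 1,
                              tf_mu = NULL) {
  if (!gene %in% tg$tfs) stop("knockout gene must be a TF: ", gene)
  simulate_expression(tg, n_cells_per_cluster, noise_sd, dropout_p, seed,
                      tf_mu = tf_mu, ko_tf = gene)
}

# random consensus of given width containing at least one A and one T
# (the toy-genome background is C/G-only, so consensus hits cannot arise by
# chance)
random_consensus <- function(width) {
  repeat {
    s <- sample(c("A", "C", "G", "T"), width, replace = TRUE)
    if ("A" %in% s && "T" %in% s) return(paste(s, collapse = ""))
  }
}

consensus_pfm <- function(consensus, major = 0.97) {
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(consensus, "")[[1]]
  mat <- matrix((1 - major) / 3, 4, length(chars),
                dimnames = list(bases, NULL))
  for (j in seq_along(chars)) mat[chars[j], j] <- major
  mat
}

#' Plant TF motifs into a toy genome matching the true GRN
#'
#' Builds one contig per gene: a C/G-only background (a composition
#' distinct from any motif, which always contains A and T) with a promoter
#' peak around the TSS and a distal enhancer peak. For every true edge
#' (TF -> target), the TF's consensus motif is written into the target's
#' promoter peak (and the first regulator's consensus into the enhancer,
#' which is linked to the promoter with co-accessibility 0.9). A
#' verification scan regenerates any contig with an accidental exact
#' consensus occurrence (bounded retries); distinct consensi are drawn with
#' bounded retries too.
#'
#' @param tg a [make_grn()] result.
#' @param motif_width consensus width (>= 6, default 8).
#' @param seed integer seed.
#' @param contig_len,peak,enhancer,tss_at contig layout (BED half-open
#'   coordinates within each contig).
#' @return list with `genome` (named sequences), `peaks`, `tss`,
#'   `coaccess`, `motifs` (a [motif_library()]), `planted` (data.frame of
#'   planted occurrences).
#' @export
plant_motifs <- function(tg, motif_width = 8, seed = 1, contig_len = 600,
                         peak = c(200, 400), enhancer = c(450, 550),
                         tss_at = c(250, 260)) {
  stopifnot(motif_width >= 6)
  with_seed(seed, {
    consensi <- character(length(tg$tfs))
    for (i in seq_along(tg$tfs)) {
      ok_cs <- FALSE
      for (try in 1:100) {
        cs <- random_consensus(motif_width)
        # distinct from every other consensus and every reverse complement
        # (so a planted site can never read as another TF's motif)
        clash <- cs %in% consensi || revcomp(cs) %in% consensi ||
          cs == revcomp(cs)
        if (!clash) { ok_cs <- TRUE; break }
      }
      if (!ok_cs) stop("could not draw distinct motif consensi")
      consensi[i] <- cs
    }
    names(consensi) <- tg$tfs
    regs <- split(tg$edges$tf, tg$edges$target)
    genome <- character(); peaks_df <- list(); tss_df <- list()
    coacc <- list(); planted <- list()
    all_pat <- c(consensi, vapply(consensi, revcomp, ""))
    for (g in tg$genes) {
      chrom <- paste0("chr_", g)
      for (try in 1:50) {
        bg <- paste(sample(c("C", "G"), contig_len, replace = TRUE),
                    collapse = "")
        seqv <- strsplit(bg, "")[[1]]
        my_regs <- regs[[g]]
        if (!is.null(my_regs)) {
          for (ri in seq_along(my_regs)) {
            at <- peak[1] + 10 + (ri - 1) * (motif_width + 6)
            stopifnot(at + motif_width <= peak[2])
            seqv[(at + 1):(at + motif_width)] <-
              strsplit(consensi[my_regs[ri]], "")[[1]]
            planted[[length(planted) + 1L]] <- data.frame(
              tf = my_regs[ri], target = g, chrom = chrom, offset = at)
          }
          at_e <- enhancer[1] + 10
          seqv[(at_e + 1):(at_e + motif_width)] <-
            strsplit(consensi[my_regs[1]], "")[[1]]
        }
        contig <- paste(seqv, collapse = "")
        # verification: only the planted consensi occur, nowhere else
        count_hits <- function(pat) {
          m <- gregexpr(pat, contig, fixed = TRUE)[[1]]
          sum(m > 0)
        }
        expected <- table(c(if (!is.null(my_regs)) consensi[my_regs],
                            if (!is.null(my_regs)) consensi[my_regs[1]]))
        ok <- TRUE
        for (pat in unique(all_pat)) {
          want <- if (pat %in% names(expected)) expected[[pat]] else 0L
          if (count_hits(pat) != want) { ok <- FALSE; break }
        }
        if (ok) break
      }
      if (!ok) stop("could not build a clean contig for ", g)
      genome[chrom] <- contig
      peaks_df[[length(peaks_df) + 1L]] <- data.frame(
        chrom = chrom, start = peak[1], end = peak[2])
      peaks_df[[length(peaks_df) + 1L]] <- data.frame(
        chrom = chrom, start = enhancer[1], end = enhancer[2])
      tss_df[[length(tss_df) + 1L]] <- data.frame(
        chrom = chrom, start = tss_at[1], end = tss_at[2], name = g,
        strand = "+")
      coacc[[length(coacc) + 1L]] <- data.frame(
        peak1 = sprintf("%s_%d_%d", chrom, peak[1], peak[2]),
        peak2 = sprintf("%s_%d_%d", chrom, enhancer[1], enhancer[2]),
        coaccess = 0.9)
    }
    peaks <- interval_df(
      do.call(rbind, peaks_df)$chrom,
      do.call(rbind, peaks_df)$start,
      do.call(rbind, peaks_df)$end)
    tss_all <- do.call(rbind, tss_df)
    tss <- interval_df(tss_all$chrom, tss_all$start, tss_all$end,
                       tss_all$name, tss_all$strand)
    motifs <- motif_library(
      lapply(tg$tfs, function(tf)
        list(tf_names = tf, matrix = consensus_pfm(consensi[tf]))),
      names = sprintf("SYN%03d", seq_along(tg$tfs)))
    list(genome = genome, peaks = peaks, tss = tss,
         coaccess = do.call(rbind, coacc), motifs = motifs,
         consensi = consensi, planted = do.call(rbind, planted))
  })
}

#' Build a complete synthetic world
#'
#' One call producing the ground-truth GRN, the SEM expression bundle, the
#' genome/peak/TSS/co-accessibility/motif fixtures, and the benchmark
#' ground truth. Defaults are the package's reference study conditions:
#' 100 genes (20 TFs, 2 lineage drivers), 3 clusters of 500 cells, residual
#' noise sd 0.1, dropout 0.1.
#'
#' @param seed integer seed driving every generator.
#' @param n_genes,n_tfs,edges_per_target,coef_range,n_clusters,inactive_frac,n_drivers
#'   see [make_grn()].
#' @param n_cells_per_cluster,noise_sd,dropout_p see [simulate_expression()].
#' @param motif_width see [plant_motifs()].
#' @return object of class `synthetic_world` with `grn`, `gem`, `fixtures`,
#'   `truth`, `params`.
#' @export
make_world <- function(seed = 1, n_genes = 100, n_tfs = 20,
                       edges_per_target = 3, coef_range = c(0.2, 1),
                       n_clusters = 3, inactive_frac = 0.25, n_drivers = 2,
                       n_cells_per_cluster = 500, noise_sd = 0.1,
                       dropout_p = 0.1, motif_width = 8) {
  tg <- make_grn(n_genes, n_tfs, edges_per_target, coef_range, n_clusters,
                 inactive_frac, n_drivers, seed = seed)
  gem <- simulate_expression(tg, n_cells_per_cluster, noise_sd, dropout_p,
                             seed = seed + 1)
  fixtures <- plant_motifs(tg, motif_width = motif_width, seed = seed + 2)
  truth <- ground_truth(tg$edges[, c("tf", "target")],
                        targets = tg$genes, tfs = tg$tfs)
  params <- list(seed = seed, n_genes = n_genes, n_tfs = n_tfs,
                 edges_per_target = edges_per_target,
                 coef_range = coef_range, n_clusters = n_clusters,
                 inactive_frac = inactive_frac, n_drivers = n_drivers,
                 n_cells_per_cluster = n_cells_per_cluster,
                 noise_sd = noise_sd, dropout_p = dropout_p,
                 motif_width = motif_width)
  structure(list(grn = tg, gem = gem, fixtures = fixtures, truth = truth,
                 params = params),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("synthetic_world (seed %d): %d genes, %d cells, %d clusters\n",
              x$params$seed, length(x$grn$genes), nrow(x$gem$X),
              x$params$n_clusters))
  invisible(x)
}

#' Write a synthetic world to standard-format files
#'
#' Emits everything the command-line stages consume: expression CSV +
#' metadata CSV, peaks/TSS BED, co-accessibility CSV, genome FASTA, JASPAR
#' motifs, ground-truth edge CSV, and a JSON manifest of the generator
#' parameters.
#'
#' @param world a [make_world()] result.
#' @param dir output directory.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gem(world$gem, file.path(dir, "expression.csv"),
            file.path(dir, "metadata.csv"))
  write_bed(world$fixtures$peaks, file.path(dir, "peaks.bed"))
  write_bed(world$fixtures$tss, file.path(dir, "tss.bed"))
  utils::write.csv(world$fixtures$coaccess,
                   file.path(dir, "coaccess.csv"), row.names = FALSE,
                   quote = FALSE)
  write_genome(world$fixtures$genome, file.path(dir, "genome.fa"))
  write_motifs(world$fixtures$motifs, file.path(dir, "motifs.jaspar"))
  truth <- world$grn$edges[, c("tf", "target")]
  truth$label <- 1L
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(world$params, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(world)
}
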