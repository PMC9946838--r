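# Shared toy builders and independent oracles.

options(grnflow.quiet = TRUE)

# minimal gem_bundle with given expression matrix (cells x genes)
toy_gem <- function(X, cluster = rep("c1", nrow(X)), embedding = NULL,
                    pseudotime = NULL) {
  if (is.null(colnames(X))) colnames(X) <- paste0("g", seq_len(ncol(X)) - 1L)
  if (is.null(embedding))
    embedding <- cbind(seq_len(nrow(X)), rep(0, nrow(X)))
  gem_bundle(X, cluster = cluster, embedding = embedding,
             pseudotime = pseudotime)
}

# cluster_grn_set holding one coefficient matrix per cluster
toy_grns <- function(B, clusters = "c1") {
  genes <- colnames(B)
  nz <- which(B != 0, arr.ind = TRUE)
  edges <- data.frame(source = genes[nz[, 1]], target = genes[nz[, 2]],
                      coef_mean = B[nz],
                      coef_std = numeric(nrow(nz)), p = numeric(nrow(nz)),
                      stringsAsFactors = FALSE)
  out <- lapply(clusters, function(cl) {
    structure(list(cluster = cl, B = B,
                   intercept = stats::setNames(rep(0, length(genes)), genes),
                   edges = edges, n_samples = NA_integer_, engine = "toy",
                   skipped_targets = character()),
              class = "cluster_grn")
  })
  structure(out, class = "cluster_grn_set", names = clusters)
}

# hand-built perturbation spec (bypasses the range check so positive shifts
# can be exercised directly)
toy_spec <- function(gene, delta_per_cell) {
  structure(list(gene = gene, target_value = NA_real_,
                 delta_input = delta_per_cell),
            class = "perturbation_spec")
}

# independent path-sum oracle: sum over all directed paths of length <= n
# from the source of (product of edge coefficients) * dx, by explicit DFS
# enumeration. Only valid on DAGs.
path_sum_oracle <- function(B, source, dx, n) {
  genes <- seq_len(ncol(B))
  total <- rep(0, ncol(B))
  recurse <- function(node, prod, depth) {
    if (depth >= n) return()
    for (nxt in genes[B[node, ] != 0]) {
      total[nxt] <<- total[nxt] + prod * B[node, nxt]
      recurse(nxt, prod * B[node, nxt], depth + 1L)
    }
  }
  recurse(source, dx, 0L)
  total[source] <- dx
  total
}

# random DAG coefficient matrix on n genes (edges only low -> high index)
random_dag <- function(n_genes, p_edge = 0.35, coef_sd = 0.6,
                       nonneg = FALSE) {
  B <- matrix(0, n_genes, n_genes)
  for (i in seq_len(n_genes - 1)) {
    for (j in (i + 1):n_genes) {
      if (stats::runif(1) < p_edge) {
        b <- stats::rnorm(1, 0, coef_sd)
        B[i, j] <- if (nonneg) abs(b) else b
      }
    }
  }
  colnames(B) <- rownames(B) <- paste0("g", seq_len(n_genes) - 1L)
  B
}

# exact position frequency matrix for a consensus sequence
consensus_mat <- function(consensus) {
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(consensus, "")[[1]]
  mat <- matrix(0, 4, length(chars), dimnames = list(bases, NULL))
  for (j in seq_along(chars)) mat[chars[j], j] <- 1
  mat
}

# brute-force interval overlap oracle over all peak x window pairs
overlap_oracle <- function(peaks, tss, window_bp) {
  hits <- list()
  for (p in seq_len(nrow(peaks))) {
    for (t in seq_len(nrow(tss))) {
      if (peaks$chrom[p] != tss$chrom[t]) next
      ws <- max(tss$start[t] - window_bp, 0)
      we <- tss$end[t] + window_bp
      if (peaks$start[p] < we && ws < peaks$end[p])
        hits[[length(hits) + 1L]] <- c(p, t)
    }
  }
  hits
}
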