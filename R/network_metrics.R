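#' Graph-theoretic reports on filtered cluster GRNs
#'
#' Computed on the directed graph of nonzero (filtered) edges: per-gene
#' degree (distinct in-/out-neighbours, self-loops excluded), unnormalized
#' betweenness centrality, eigenvector centrality (falling back to the
#' undirected projection when the directed computation fails to converge),
#' a degree histogram and a log-log power-law regression slope. Biological
#' GRNs are typically scale-free, so the histogram of an inferred network
#' is expected to follow an approximate power law.
#'
#' @param grn a filtered `cluster_grn` (see [filter_edges()]).
#' @return object of class `network_report`: `scores` (data.frame gene,
#'   in_degree, out_degree, degree, betweenness, eigenvector),
#'   `degree_histogram`, `powerlaw_slope`, `powerlaw_r2`.
#' @export
network_scores <- function(grn) {
  e <- grn$edges
  e <- e[e$source != e$target, , drop = FALSE]
  genes <- sort(unique(c(e$source, e$target)))
  if (nrow(e) == 0) {
    warning("empty graph: all-zero network report")
    return(structure(list(
      scores = data.frame(gene = character(), in_degree = integer(),
                          out_degree = integer(), degree = integer(),
                          betweenness = numeric(), eigenvector = numeric()),
      degree_histogram = table(integer()),
      powerlaw_slope = NA_real_, powerlaw_r2 = NA_real_),
      class = "network_report"))
  }
  g <- igraph::graph_from_data_frame(
    unique(e[, c("source", "target")]), directed = TRUE,
    vertices = genes)
  indeg <- igraph::degree(g, mode = "in")
  outdeg <- igraph::degree(g, mode = "out")
  # distinct neighbours regardless of direction
  und <- igraph::as_undirected(g, mode = "collapse")
  deg <- igraph::degree(und)
  btw <- igraph::betweenness(g, directed = TRUE, normalized = FALSE)
  eig <- tryCatch(
    igraph::eigen_centrality(g, directed = TRUE)$vector,
    warning = function(w) {
      gf_log("eigenvector centrality: directed computation unstable; using undirected projection")
      igraph::eigen_centrality(und, directed = FALSE)$vector
    },
    error = function(e2) {
      gf_log("eigenvector centrality fell back to undirected projection")
      igraph::eigen_centrality(und, directed = FALSE)$vector
    })
  scores <- data.frame(gene = genes,
                       in_degree = as.integer(indeg[genes]),
                       out_degree = as.integer(outdeg[genes]),
                       degree = as.integer(deg[genes]),
                       betweenness = as.numeric(btw[genes]),
                       eigenvector = as.numeric(eig[genes]),
                       row.names = NULL)
  hist <- table(scores$degree)
  pl <- powerlaw_fit(scores$degree)
  structure(list(scores = scores, degree_histogram = hist,
                 powerlaw_slope = pl$slope, powerlaw_r2 = pl$r2),
            class = "network_report")
}

# log-log least squares on the degree distribution (counts > 0, degree > 0)
powerlaw_fit <- function(degrees) {
  tab <- table(degrees[degrees > 0])
  d <- as.numeric(names(tab)); cnt <- as.numeric(tab)
  if (length(d) < 3) return(list(slope = NA_real_, r2 = NA_real_))
  fit <- stats::lm(log10(cnt) ~ log10(d))
  list(slope = unname(stats::coef(fit)[2]),
       r2 = summary(fit)$r.squared)
}

#' @export
print.network_report <- function(x, ...) {
  cat(sprintf("network_report: %d genes, power-law slope %.2f (R^2 %.2f)\n",
              nrow(x$scores), x$powerlaw_slope, x$powerlaw_r2))
  invisible(x)
}

#' Rank genes by total degree
#'
#' @param grn a filtered `cluster_grn`.
#' @param top_n number of genes to return (>= 1; capped at the gene count).
#' @param tf_names optional character vector (e.g. motif-library TFs) used
#'   to flag TFs in the output.
#' @return data.frame gene, degree, is_tf, sorted by degree descending with
#'   alphabetical tie-break.
#' @export
degree_rank <- function(grn, top_n = 30, tf_names = NULL) {
  stopifnot(top_n >= 1)
  rep_ <- network_scores(grn)
  s <- rep_$scores
  s <- s[order(-s$degree, s$gene), , drop = FALSE]
  s <- utils::head(s, top_n)
  out <- data.frame(gene = s$gene, degree = s$degree,
                    is_tf = if (is.null(tf_names)) NA else
                      toupper(s$gene) %in% toupper(tf_names),
                    row.names = NULL)
  out
}
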