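#' @keywords internal
"_PACKAGE"

# Internal logging helper: every filtering step reports counts before/after.
gf_log <- function(...) {
  if (isTRUE(getOption("grnflow.quiet", FALSE))) return(invisible(NULL))
  message("[grnflow] ", sprintf(...))
}

#' Bundle a gene expression matrix with per-cell metadata
#'
#' A `gem_bundle` carries the cells-by-genes expression matrix (per-cell
#' total-count normalized, *not* log-transformed) together with cluster
#' labels, a 2D embedding, and optional pseudotime. All downstream stages
#' (GRN inference, perturbation simulation, scoring) consume this container.
#'
#' @param X numeric matrix, cells x genes, non-negative.
#' @param cluster character/factor vector, one label per cell.
#' @param embedding numeric matrix, cells x 2.
#' @param pseudotime optional numeric vector, one non-negative value per cell.
#' @param cell_ids,gene_ids optional identifiers; taken from dimnames if absent.
#'
#' @return An object of class `gem_bundle`: a list with elements `X`,
#'   `gene_ids`, `cell_ids`, `cluster`, `embedding`, `pseudotime`, and
#'   (after [knn_impute()]) `imputed_X`.
#' @export
gem_bundle <- function(X, cluster, embedding, pseudotime = NULL,
                       cell_ids = NULL, gene_ids = NULL) {
  X <- as.matrix(X)
  if (is.null(cell_ids)) cell_ids <- rownames(X)
  if (is.null(gene_ids)) gene_ids <- colnames(X)
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(nrow(X)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(ncol(X)))
  dimnames(X) <- list(cell_ids, gene_ids)
  obj <- structure(
    list(X = X, gene_ids = gene_ids, cell_ids = cell_ids,
         cluster = as.character(cluster),
         embedding = as.matrix(embedding),
         pseudotime = pseudotime, imputed_X = NULL),
    class = "gem_bundle")
  validate_gem_bundle(obj)
  obj
}

validate_gem_bundle <- function(gem) {
  stopifnot(inherits(gem, "gem_bundle"))
  neg <- which(gem$X < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop(sprintf("negative expression entry at cell '%s', gene '%s'",
                 gem$cell_ids[neg[1, 1]], gem$gene_ids[neg[1, 2]]))
  }
  if (ncol(gem$embedding) != 2L)
    stop("embedding must have exactly 2 columns")
  if (nrow(gem$embedding) != nrow(gem$X))
    stop("embedding rows must match number of cells")
  if (length(gem$cluster) != nrow(gem$X))
    stop("cluster label required for every cell")
  if (anyNA(gem$cluster))
    stop("cluster label required for every cell (NA found)")
  if (anyDuplicated(gem$gene_ids))
    stop("gene_ids must be unique")
  if (!is.null(gem$pseudotime)) {
    if (length(gem$pseudotime) != nrow(gem$X))
      stop("pseudotime must have one value per cell")
    if (any(gem$pseudotime < 0, na.rm = TRUE))
      stop("pseudotime must be >= 0")
  }
  invisible(gem)
}

#' @export
print.gem_bundle <- function(x, ...) {
  cat(sprintf("gem_bundle: %d cells x %d genes, %d clusters%s%s\n",
              nrow(x$X), ncol(x$X), length(unique(x$cluster)),
              if (!is.null(x$pseudotime)) ", pseudotime" else "",
              if (!is.null(x$imputed_X)) ", imputed" else ""))
  invisible(x)
}

#' @export
dim.gem_bundle <- function(x) dim(x$X)

#' Build a genomic-interval table
#'
#' Intervals are plain data.frames (chrom, start, end, name, strand) in BED
#' convention: 0-based half-open. Conversion to GRanges happens internally
#' where overlap machinery is needed.
#'
#' @param chrom,start,end,name,strand vectors, recycled as usual.
#' @return data.frame with the five columns above.
#' @export
interval_df <- function(chrom, start, end, name = NA_character_,
                        strand = NA_character_) {
  if (length(chrom) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      strand = character()))
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), name = as.character(name),
                   strand = as.character(strand), stringsAsFactors = FALSE)
  bad <- which(df$start >= df$end)
  if (length(bad) > 0)
    stop(sprintf("interval with start >= end at row %d (%s:%d-%d)",
                 bad[1], df$chrom[bad[1]], df$start[bad[1]], df$end[bad[1]]))
  df
}

#' Construct a motif library
#'
#' @param motifs list; each element a list with `tf_names` (character) and
#'   `matrix` (4 x width position frequency matrix, rows A,C,G,T). Matrices
#'   are column-normalized to frequencies.
#' @param names optional motif identifiers.
#' @return An object of class `motif_library`.
#' @export
motif_library <- function(motifs, names = NULL) {
  motifs <- lapply(motifs, function(m) {
    mat <- as.matrix(m$matrix)
    if (nrow(mat) != 4L)
      stop("motif matrix must have exactly 4 rows (A,C,G,T)")
    if (ncol(mat) < 4L)
      stop("motif width must be >= 4")
    cs <- colSums(mat)
    if (any(cs <= 0)) stop("motif matrix has a zero column")
    mat <- sweep(mat, 2, cs, "/")
    rownames(mat) <- c("A", "C", "G", "T")
    list(tf_names = toupper(m$tf_names), matrix = mat)
  })
  if (!is.null(names)) names(motifs) <- names
  structure(list(motifs = motifs), class = "motif_library")
}

#' @export
print.motif_library <- function(x, ...) {
  cat(sprintf("motif_library: %d motifs, widths %s\n", length(x$motifs),
              paste(range(vapply(x$motifs, function(m) ncol(m$matrix), 1L)),
                    collapse = "-")))
  invisible(x)
}

#' @export
length.motif_library <- function(x) length(x$motifs)
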