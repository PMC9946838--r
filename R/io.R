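#' Load an expression matrix plus cell metadata
#'
#' Reads a cells x genes matrix (MatrixMarket `.mtx` or dense CSV with a
#' header of gene symbols and cell ids in the first column) and a metadata
#' CSV with columns `cell`, `cluster`, `x`, `y` and optionally `pseudotime`.
#' Genes with all-zero counts are dropped (and the count logged), matching
#' the usual minimum-count gene filter applied before GRN fitting.
#'
#' The expression contract is per-cell total-count normalized, non-log
#' values. If your matrix is log1p-transformed, set `assume_log = TRUE` to
#' apply `expm1()` (a warning is emitted).
#'
#' @param matrix_path path to `.mtx` or `.csv` matrix (cells x genes).
#' @param meta_path path to metadata CSV keyed by cell id.
#' @param genes_path,cells_path for MTX input: one-column text files with
#'   gene / cell identifiers (row order of the matrix).
#' @param assume_log logical; apply `expm1()` to the matrix first.
#' @return A [gem_bundle()].
#' @export
load_gem <- function(matrix_path, meta_path, genes_path = NULL,
                     cells_path = NULL, assume_log = FALSE) {
  ext <- tolower(tools::file_ext(matrix_path))
  if (ext == "mtx") {
    X <- as.matrix(Matrix::readMM(matrix_path))
    if (!is.null(genes_path)) colnames(X) <- readLines(genes_path)
    if (!is.null(cells_path)) rownames(X) <- readLines(cells_path)
  } else {
    df <- utils::read.csv(matrix_path, row.names = 1, check.names = FALSE)
    X <- as.matrix(df)
  }
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  need <- c("cell", "cluster", "x", "y")
  if (!all(need %in% names(meta)))
    stop("metadata CSV must have columns: ", paste(need, collapse = ", "))
  if (nrow(meta) != nrow(X))
    stop(sprintf("dimension mismatch: matrix has %d cells, metadata %d rows",
                 nrow(X), nrow(meta)))
  if (is.null(rownames(X))) rownames(X) <- meta$cell
  meta <- meta[match(rownames(X), meta$cell), , drop = FALSE]
  if (anyNA(meta$cell))
    stop("metadata cell ids do not match matrix cell ids")
  if (assume_log) {
    warning("assume_log = TRUE: applying expm1() to the expression matrix")
    X <- expm1(X)
  }
  neg <- which(X < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("negative expression entry at cell '%s', gene '%s'",
                 rownames(X)[neg[1, 1]], colnames(X)[neg[1, 2]]))
  zero <- colSums(X) == 0
  if (any(zero)) {
    gf_log("dropping %d/%d all-zero genes", sum(zero), ncol(X))
    X <- X[, !zero, drop = FALSE]
  }
  pt <- if ("pseudotime" %in% names(meta)) meta$pseudotime else NULL
  gem_bundle(X, cluster = meta$cluster,
             embedding = cbind(x = meta$x, y = meta$y), pseudotime = pt)
}

#' Write a gem_bundle to CSV files
#'
#' Inverse of [load_gem()] (dense CSV flavour); round-trips values exactly
#' at full double precision.
#'
#' @param gem a [gem_bundle()].
#' @param matrix_path,meta_path output CSV paths.
#' @export
write_gem <- function(gem, matrix_path, meta_path) {
  df <- as.data.frame(gem$X)
  utils::write.csv(cbind(cell = gem$cell_ids, df), matrix_path,
                   row.names = FALSE, quote = FALSE)
  # re-write with rownames convention used by load_gem (first column = id)
  meta <- data.frame(cell = gem$cell_ids, cluster = gem$cluster,
                     x = gem$embedding[, 1], y = gem$embedding[, 2])
  if (!is.null(gem$pseudotime)) meta$pseudotime <- gem$pseudotime
  utils::write.csv(meta, meta_path, row.names = FALSE, quote = FALSE)
  invisible(gem)
}

#' Load a BED file of genomic intervals
#'
#' 3+ column tab-separated BED; 0-based half-open coordinates are kept as-is.
#' Column 4 (name) and column 6 (strand) are retained when present.
#'
#' @param path BED file path.
#' @return data.frame with columns chrom, start, end, name, strand.
#' @export
load_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("empty BED file: ", path)
    return(interval_df(character(), integer(), integer()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n <- vapply(parts, length, 1L)
  if (any(n < 3))
    stop(sprintf("BED line %d has fewer than 3 fields", which(n < 3)[1]))
  chrom <- vapply(parts, `[[`, "", 1)
  start <- as.integer(vapply(parts, `[[`, "", 2))
  end <- as.integer(vapply(parts, `[[`, "", 3))
  bad <- which(start >= end)
  if (length(bad) > 0)
    stop(sprintf("BED line %d: start >= end (%d >= %d)",
                 bad[1], start[bad[1]], end[bad[1]]))
  name <- vapply(parts, function(p) if (length(p) >= 4) p[[4]] else NA_character_, "")
  strand <- vapply(parts, function(p) if (length(p) >= 6) p[[6]] else NA_character_, "")
  interval_df(chrom, start, end, name, strand)
}

#' Write intervals as BED
#' @param df interval data.frame (chrom, start, end, optional name/strand).
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  cols <- list(df$chrom, df$start, df$end)
  if (!is.null(df$name) && any(!is.na(df$name))) {
    cols <- c(cols, list(ifelse(is.na(df$name), ".", df$name)))
    if (!is.null(df$strand) && any(!is.na(df$strand)))
      cols <- c(cols, list("0"), list(ifelse(is.na(df$strand), ".", df$strand)))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(df)
}

#' Load TF motifs from a JASPAR-format file
#'
#' Parses JASPAR position matrices (`>ID NAME` header, then four rows
#' A/C/G/T with counts, brackets optional). Counts are normalized to
#' frequencies per column; TF names are upper-cased so that matching against
#' expression gene symbols is case-insensitive. Dimer names (`TF1::TF2`)
#' yield one TF name per component.
#'
#' @param path JASPAR motif file.
#' @return A [motif_library()].
#' @export
load_motifs <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (length(heads) == 0) stop("no JASPAR headers ('>') found in ", path)
  bounds <- c(heads, length(lines) + 1L)
  motifs <- list()
  ids <- character()
  for (i in seq_along(heads)) {
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    if (length(block) != 4L)
      stop(sprintf("motif block '%s' has %d matrix rows; expected 4",
                   lines[heads[i]], length(block)))
    rows <- lapply(block, function(l) {
      l <- gsub("^[ACGTacgt]\\s*", "", l)
      l <- gsub("[\\[\\]]", " ", l, perl = TRUE)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    w <- unique(vapply(rows, length, 1L))
    if (length(w) != 1L)
      stop("ragged motif matrix under header ", lines[heads[i]])
    mat <- do.call(rbind, rows)
    hdr <- sub("^>\\s*", "", lines[heads[i]])
    toks <- strsplit(trimws(hdr), "\\s+")[[1]]
    id <- toks[1]
    nm <- if (length(toks) >= 2) paste(toks[-1], collapse = " ") else toks[1]
    tf_names <- toupper(unlist(strsplit(nm, "::", fixed = TRUE)))
    motifs[[i]] <- list(tf_names = tf_names, matrix = mat)
    ids[i] <- id
  }
  motif_library(motifs, names = ids)
}

#' Write a motif library in JASPAR format
#' @param lib a [motif_library()].
#' @param path output path.
#' @param counts_scale counts written as `frequency * counts_scale`.
#' @export
write_motifs <- function(lib, path, counts_scale = 100) {
  out <- character()
  ids <- names(lib$motifs)
  if (is.null(ids)) ids <- sprintf("M%04d", seq_along(lib$motifs))
  for (i in seq_along(lib$motifs)) {
    m <- lib$motifs[[i]]
    out <- c(out, sprintf(">%s %s", ids[i], paste(m$tf_names, collapse = "::")))
    cnt <- round(m$matrix * counts_scale, 4)
    for (b in 1:4) {
      out <- c(out, paste0(c("A", "C", "G", "T")[b], "  [ ",
                           paste(cnt[b, ], collapse = " "), " ]"))
    }
  }
  writeLines(out, path)
  invisible(lib)
}

#' Load a genome FASTA as a named character vector of sequences
#' @param path FASTA file.
#' @return named character vector, one element per contig.
#' @export
load_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(ss), names(ss))
}

#' Write contig sequences to FASTA
#' @param genome named character vector of sequences.
#' @param path output path.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome), path)
  invisible(genome)
}

#' Read / write GRN edge tables
#'
#' Edge tables are CSVs with columns `source`, `target`, `coef_mean`,
#' `coef_std`, `p` (and `neg_log_p` on write).
#'
#' @param path CSV path.
#' @return data.frame of edges.
#' @export
load_edges <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname load_edges
#' @param edges edge data.frame.
#' @export
write_edges <- function(edges, path) {
  if (!is.null(edges$p) && is.null(edges$neg_log_p))
    edges$neg_log_p <- -log10(pmax(edges$p, .Machine$double.xmin))
  utils::write.csv(edges, path, row.names = FALSE, quote = FALSE)
  invisible(edges)
}
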