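#' Base GRN: chromatin-derived candidate TF -> target network
#'
#' The base GRN is the binary, directed scaffold of *potential* regulatory
#' interactions: an edge (TF, target) exists when the TF's binding motif is
#' found in an accessible regulatory region (promoter, or a distal peak
#' co-accessible with the promoter) of the target gene. The base GRN
#' constrains which coefficients may be nonzero during model fitting; it
#' carries no weights itself.
#'
#' @param entries data.frame with columns tf, target, chrom, start, end.
#' @return Object of class `base_grn` with `$entries` (region-level rows)
#'   and `$pairs` (deduplicated tf/target data.frame).
#' @export
base_grn <- function(entries) {
  entries$tf <- toupper(entries$tf)
  pairs <- unique(entries[, c("tf", "target")])
  rownames(pairs) <- NULL
  self <- pairs$tf == toupper(pairs$target)
  if (any(self))
    gf_log("%d self-edges (TF motif in its own regulatory region) retained, flagged",
           sum(self))
  structure(list(entries = entries, pairs = pairs), class = "base_grn")
}

#' @export
print.base_grn <- function(x, ...) {
  cat(sprintf("base_grn: %d candidate edges (%d TFs, %d targets), %d region records\n",
              nrow(x$pairs), length(unique(x$pairs$tf)),
              length(unique(x$pairs$target)), nrow(x$entries)))
  invisible(x)
}

#' Candidate regulators per target, as a named list
#' @param bg a [base_grn()].
#' @return named list: target -> character vector of TFs.
#' @export
regulators_of <- function(bg) {
  split(bg$pairs$tf, bg$pairs$target)
}

peak_id <- function(df) paste(df$chrom, df$start, df$end, sep = "_")

#' Assign accessible peaks to genes by TSS overlap
#'
#' A peak maps to gene `g` iff it overlaps the window
#' `[tss_start - window_bp, tss_end + window_bp)` of `g`'s annotated TSS,
#' on either strand. A peak may map to several genes; unassigned peaks are
#' logged and left out.
#'
#' @param peaks interval data.frame (chrom, start, end), e.g. [load_bed()].
#' @param tss interval data.frame with `name` = gene symbol.
#' @param window_bp non-negative window half-width added to each side of the
#'   TSS interval (default 1000, a HOMER-like proximal-promoter definition).
#' @return data.frame with columns chrom, start, end, peak_id, gene.
#' @export
annotate_tss <- function(peaks, tss, window_bp = 1000) {
  stopifnot(window_bp >= 0)
  if (nrow(peaks) == 0 || nrow(tss) == 0)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      peak_id = character(), gene = character()))
  # BED half-open -> GRanges 1-based closed
  gr_peaks <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(peaks$start + 1L, peaks$end))
  win_start <- pmax(tss$start - window_bp, 0L)
  win_end <- tss$end + window_bp
  gr_tss <- GenomicRanges::GRanges(
    tss$chrom, IRanges::IRanges(win_start + 1L, win_end))
  hits <- GenomicRanges::findOverlaps(gr_peaks, gr_tss, ignore.strand = TRUE)
  pi <- S4Vectors::queryHits(hits)
  ti <- S4Vectors::subjectHits(hits)
  out <- data.frame(chrom = peaks$chrom[pi], start = peaks$start[pi],
                    end = peaks$end[pi],
                    peak_id = peak_id(peaks)[pi],
                    gene = tss$name[ti], stringsAsFactors = FALSE)
  n_un <- nrow(peaks) - length(unique(pi))
  gf_log("annotate_tss: %d/%d peaks assigned to a TSS (%d unassigned)",
         length(unique(pi)), nrow(peaks), n_un)
  out
}

#' Select cis-regulatory regions: promoters plus co-accessible distal peaks
#'
#' Keeps every TSS-assigned peak (promoter, with its gene) and every distal
#' peak linked to a promoter by a co-accessibility score at or above
#' `threshold` (default 0.8); the distal peak inherits the promoter's gene.
#' A distal peak co-accessible with promoters of several genes is emitted
#' once per gene. With an empty `coaccess` table this reduces to
#' promoter-only regions.
#'
#' @param peak_gene promoter map from [annotate_tss()].
#' @param peaks all peaks (interval data.frame), source of distal regions.
#' @param coaccess data.frame with columns peak1, peak2, coaccess (score in
#'   `[-1, 1]`; peak ids are `chrom_start_end`).
#' @param threshold minimum co-accessibility score, in `[0, 1]`.
#' @return data.frame (chrom, start, end, peak_id, gene, kind).
#' @export
select_cis_regions <- function(peak_gene, peaks, coaccess = NULL,
                               threshold = 0.8) {
  stopifnot(threshold >= 0, threshold <= 1)
  prom <- peak_gene
  if (nrow(prom) > 0) prom$kind <- "promoter"
  if (is.null(coaccess) || nrow(coaccess) == 0) {
    gf_log("select_cis_regions: %d promoter regions, no co-accessibility input",
           nrow(prom))
    return(prom)
  }
  all_ids <- peak_id(peaks)
  miss <- setdiff(unique(c(coaccess$peak1, coaccess$peak2)), all_ids)
  if (length(miss) > 0)
    stop("co-accessibility pairs reference unknown peaks: ",
         paste(utils::head(miss, 3), collapse = ", "))
  # symmetric pairs: consider both orientations
  pairs <- rbind(
    data.frame(a = coaccess$peak1, b = coaccess$peak2, s = coaccess$coaccess),
    data.frame(a = coaccess$peak2, b = coaccess$peak1, s = coaccess$coaccess))
  pairs <- pairs[pairs$s >= threshold, , drop = FALSE]
  # b is a promoter peak -> a inherits b's gene(s), unless a is that promoter
  hit <- merge(pairs, prom[, c("peak_id", "gene")],
               by.x = "b", by.y = "peak_id")
  if (nrow(hit) > 0) {
    idx <- match(hit$a, all_ids)
    distal <- data.frame(chrom = peaks$chrom[idx], start = peaks$start[idx],
                         end = peaks$end[idx], peak_id = hit$a,
                         gene = hit$gene, kind = "distal",
                         stringsAsFactors = FALSE)
    distal <- unique(distal)
    # drop distal records that duplicate an existing promoter assignment
    dup <- paste(distal$peak_id, distal$gene) %in% paste(prom$peak_id, prom$gene)
    distal <- distal[!dup, , drop = FALSE]
  } else {
    distal <- prom[0, , drop = FALSE]
  }
  out <- rbind(prom, distal)
  rownames(out) <- NULL
  gf_log("select_cis_regions: %d promoter + %d distal regions (threshold %.2f)",
         nrow(prom), nrow(distal), threshold)
  out
}

# log2-odds weight matrix vs uniform background, with pseudocount
pwm_weights <- function(pfm, pseudocount = 0.01) {
  q <- sweep(pfm + pseudocount, 2, colSums(pfm + pseudocount), "/")
  log2(q / 0.25)
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# score a sequence against a weight matrix at all offsets; N scores 0.
# Returns the maximum score over offsets (or -Inf if sequence shorter than
# the motif).
scan_max_score <- function(codes, W) {
  w <- ncol(W)
  n <- length(codes)
  if (n < w) return(-Inf)
  n_off <- n - w + 1L
  s <- numeric(n_off)
  for (k in seq_len(w)) {
    col <- W[, k]
    idx <- codes[k:(k + n_off - 1L)]
    contrib <- ifelse(is.na(idx), 0, col[idx])
    s <- s + contrib
  }
  max(s)
}

seq_to_codes <- function(seq) {
  map <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  unname(map[strsplit(toupper(seq), "")[[1]]])
}

#' Scan regulatory regions for TF-binding motifs to build the base GRN
#'
#' For each (region, gene) pair and each motif, computes the log-odds score
#' (position frequency matrix with pseudocount against a uniform 0.25
#' background) at every offset on both strands. If the best score reaches
#' `score_frac` of the motif's maximum attainable score, an edge
#' (tf, gene, region) is recorded for every TF name attached to the motif.
#' Ambiguous bases (N) contribute zero; regions outside their contig are
#' skipped with a warning.
#'
#' @param regions data.frame from [select_cis_regions()] (chrom, start, end,
#'   gene).
#' @param genome named character vector of contig sequences ([load_genome()]).
#' @param motifs a [motif_library()].
#' @param score_frac fraction of the maximum attainable log-odds score that
#'   a site must reach (default 0.85).
#' @param pseudocount added to PFM entries before log-odds (default 0.01).
#' @return A [base_grn()].
#' @export
scan_motifs <- function(regions, genome, motifs, score_frac = 0.85,
                        pseudocount = 0.01) {
  stopifnot(score_frac > 0, score_frac <= 1)
  Ws <- lapply(motifs$motifs, function(m) pwm_weights(m$matrix, pseudocount))
  max_scores <- vapply(Ws, function(W) sum(apply(W, 2, max)), 0)
  rows <- list()
  for (r in seq_len(nrow(regions))) {
    chrom <- regions$chrom[r]
    if (!chrom %in% names(genome)) {
      warning(sprintf("region %s:%d-%d outside genome; skipped",
                      chrom, regions$start[r], regions$end[r]))
      next
    }
    contig <- genome[[chrom]]
    if (regions$end[r] > nchar(contig)) {
      warning(sprintf("region %s:%d-%d outside contig bounds; skipped",
                      chrom, regions$start[r], regions$end[r]))
      next
    }
    seq <- substr(contig, regions$start[r] + 1L, regions$end[r])
    fwd <- seq_to_codes(seq)
    rev <- seq_to_codes(revcomp(seq))
    for (m in seq_along(Ws)) {
      best <- max(scan_max_score(fwd, Ws[[m]]), scan_max_score(rev, Ws[[m]]))
      if (best >= score_frac * max_scores[m]) {
        rows[[length(rows) + 1L]] <- data.frame(
          tf = motifs$motifs[[m]]$tf_names,
          target = regions$gene[r],
          chrom = chrom, start = regions$start[r], end = regions$end[r],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    gf_log("scan_motifs: no motif hits in %d regions", nrow(regions))
    return(base_grn(data.frame(tf = character(), target = character(),
                               chrom = character(), start = integer(),
                               end = integer())))
  }
  entries <- unique(do.call(rbind, rows))
  rownames(entries) <- NULL
  bg <- base_grn(entries)
  gf_log("scan_motifs: %d candidate edges from %d regions x %d motifs",
         nrow(bg$pairs), nrow(regions), length(Ws))
  bg
}

#' Scramble the TF-name-to-matrix assignment of a motif library
#'
#' Produces the scrambled-motif negative control: the assignment of TF names
#' to position matrices is permuted by a seeded derangement (no motif keeps
#' its own names); matrices themselves are unchanged.
#'
#' @param motifs a [motif_library()] with at least 2 motifs.
#' @param seed integer seed; same seed, same permutation.
#' @return A [motif_library()].
#' @export
scramble_motifs <- function(motifs, seed) {
  n <- length(motifs$motifs)
  if (n < 2) stop("need >= 2 motifs to scramble (no derangement of 1)")
  perm <- with_seed(seed, {
    repeat {
      p <- sample.int(n)
      if (all(p != seq_len(n))) break
    }
    p
  })
  out <- motifs
  for (i in seq_len(n))
    out$motifs[[i]]$tf_names <- motifs$motifs[[perm[i]]]$tf_names
  out
}

# evaluate expr under a local RNG seed without disturbing the global stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
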