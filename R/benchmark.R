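#' Benchmark inferred GRNs against binary ground truth
#'
#' Scores a ranked edge prediction against a binary ground-truth edge set
#' with AUROC (rank-based Mann-Whitney statistic with midrank tie handling)
#' and the early precision ratio (EPR): the precision among the top-k
#' predicted edges, with k equal to the number of true edges, divided by
#' the positive density of the evaluation universe. EPR is 1 in expectation
#' for random scores and `1/density` for a perfect ranking.
#'
#' The evaluation universe is `{ground-truth TFs} x {genes in the GEM}`
#' minus self-pairs; pairs without a prediction receive score 0.
#'
#' @name benchmark
NULL

#' Ground-truth container
#'
#' @param positives data.frame with columns tf, target (label-1 edges).
#' @param tfs TF universe; defaults to the TFs appearing in `positives`.
#' @param targets target-gene universe (e.g. `gem$gene_ids`).
#' @return object of class `ground_truth` with `positives` and `universe`
#'   (data.frames of tf/target pairs).
#' @export
ground_truth <- function(positives, targets, tfs = NULL) {
  positives$tf <- toupper(positives$tf)
  if (is.null(tfs)) tfs <- unique(positives$tf)
  tfs <- toupper(tfs)
  universe <- expand.grid(tf = tfs, target = targets,
                          stringsAsFactors = FALSE)
  universe <- universe[universe$tf != toupper(universe$target), , drop = FALSE]
  key_u <- paste(universe$tf, universe$target)
  key_p <- paste(positives$tf, positives$target)
  keep <- key_p %in% key_u
  if (!all(keep))
    gf_log("ground_truth: %d positives outside the universe dropped",
           sum(!keep))
  positives <- positives[keep, , drop = FALSE]
  structure(list(positives = positives, universe = universe),
            class = "ground_truth")
}

# label vector and aligned score vector over the universe
align_scores <- function(scores, truth) {
  key_u <- paste(truth$universe$tf, truth$universe$target)
  key_p <- paste(truth$positives$tf, truth$positives$target)
  labels <- key_u %in% key_p
  s <- numeric(length(key_u))
  if (nrow(scores) > 0) {
    key_s <- paste(toupper(scores$tf), scores$target)
    m <- match(key_u, key_s)
    s[!is.na(m)] <- scores$score[m[!is.na(m)]]
  }
  list(labels = labels, scores = s, keys = key_u)
}

#' Rank-based AUROC with midrank tie handling
#'
#' @param scores data.frame with columns tf, target, score.
#' @param truth a [ground_truth()].
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, truth) {
  al <- align_scores(scores, truth)
  n_pos <- sum(al$labels); n_neg <- sum(!al$labels)
  if (n_pos == 0 || n_neg == 0)
    stop("AUROC needs at least one positive and one negative pair")
  r <- rank(al$scores)   # midranks
  (sum(r[al$labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Early precision and early precision ratio
#'
#' Takes the top-k pairs by score, k = number of positives; ties at the
#' boundary are broken by lexicographic (tf, target) order (logged).
#'
#' @inheritParams auroc
#' @return list with `early_precision`, `epr`, `k`, `density`.
#' @export
epr <- function(scores, truth) {
  al <- align_scores(scores, truth)
  n_pos <- sum(al$labels); n_all <- length(al$labels)
  if (n_pos == 0 || n_pos == n_all)
    stop("EPR needs at least one positive and one negative pair")
  ord <- order(-al$scores, al$keys)
  k <- n_pos
  boundary <- al$scores[ord[k]]
  if (k < n_all && al$scores[ord[k + 1L]] == boundary)
    gf_log("epr: ties at the top-k boundary broken by pair order")
  top <- ord[seq_len(k)]
  early_precision <- mean(al$labels[top])
  density <- n_pos / n_all
  list(early_precision = early_precision,
       epr = early_precision / density, k = k, density = density)
}

#' Edge scores for benchmarking from a cluster_grn_set
#'
#' The benchmark score of a (tf, target) pair is `|coef_mean|`
#' max-aggregated over clusters.
#'
#' @param grns a `cluster_grn_set`.
#' @return data.frame tf, target, score.
#' @export
benchmark_scores <- function(grns) {
  e <- do.call(rbind, lapply(grns, function(g)
    g$edges[, c("source", "target", "coef_mean")]))
  if (is.null(e) || nrow(e) == 0)
    return(data.frame(tf = character(), target = character(),
                      score = numeric()))
  e$score <- abs(e$coef_mean)
  agg <- stats::aggregate(score ~ source + target, data = e, FUN = max)
  data.frame(tf = toupper(agg$source), target = agg$target,
             score = agg$score, row.names = NULL)
}

#' One-call benchmark of a cluster_grn_set
#'
#' @param grns a `cluster_grn_set`.
#' @param truth a [ground_truth()].
#' @return list with `auroc`, `early_precision`, `epr`.
#' @export
benchmark_grns <- function(grns, truth) {
  s <- benchmark_scores(grns)
  ep <- epr(s, truth)
  list(auroc = auroc(s, truth),
       early_precision = ep$early_precision, epr = ep$epr)
}
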