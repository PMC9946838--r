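test_that("annotate_tss maps peaks to genes by windowed TSS overlap", {
  peaks <- interval_df(c("chr1", "chr1"), c(900, 0), c(1100, 100))
  tss <- interval_df("chr1", 1000, 1001, name = "geneA")
  hit <- annotate_tss(peaks, tss, window_bp = 0)
  expect_equal(hit$gene, "geneA")
  expect_equal(hit$start, 900)

  # far peak stays unassigned even with a 1 kb window
  tss2 <- interval_df("chr1", 5000, 5001, name = "geneB")
  hit2 <- annotate_tss(peaks[2, , drop = FALSE], tss2, window_bp = 1000)
  expect_equal(nrow(hit2), 0L)

  # a peak overlapping two TSS windows maps to both genes
  tss3 <- rbind(interval_df("chr1", 950, 951, name = "geneA"),
                interval_df("chr1", 1050, 1051, name = "geneB"))
  hit3 <- annotate_tss(peaks[1, , drop = FALSE], tss3, window_bp = 0)
  expect_setequal(hit3$gene, c("geneA", "geneB"))
})

test_that("annotate_tss agrees with a brute-force overlap oracle", {
  set.seed(42)
  for (rep in 1:5) {
    peaks <- interval_df("chr1", s <- sample(0:5000, 30),
                             s + sample(50:400, 30, replace = TRUE))
    tp <- sample(0:5000, 10)
    tss <- interval_df("chr1", tp, tp + 1,
                           name = paste0("g", seq_along(tp)))
    w <- sample(c(0, 100, 1000), 1)
    got <- annotate_tss(peaks, tss, window_bp = w)
    oracle <- overlap_oracle(peaks, tss, w)
    expect_equal(nrow(got), length(oracle))
    if (length(oracle) > 0) {
      want <- sort(vapply(oracle, function(h)
        paste(peaks$start[h[1]], tss$name[h[2]]), ""))
      expect_equal(sort(paste(got$start, got$gene)), want)
    }
  }
})

test_that("select_cis_regions keeps promoters and thresholded distal peaks", {
  peaks <- interval_df("chr1", c(100, 5000), c(300, 5200))
  prom <- data.frame(chrom = "chr1", start = 100, end = 300,
                     peak_id = "chr1_100_300", gene = "geneA")
  co <- data.frame(peak1 = "chr1_100_300", peak2 = "chr1_5000_5200",
                   coaccess = 0.85)
  out <- select_cis_regions(prom, peaks, co, threshold = 0.8)
  expect_setequal(out$peak_id, c("chr1_100_300", "chr1_5000_5200"))
  expect_true(all(out$gene == "geneA"))

  # below threshold the distal peak is dropped
  co$coaccess <- 0.75
  out2 <- select_cis_regions(prom, peaks, co, threshold = 0.8)
  expect_equal(out2$peak_id, "chr1_100_300")

  # distal peak linked to promoters of two genes is emitted once per gene
  peaks3 <- interval_df("chr1", c(100, 1000, 5000), c(300, 1200, 5200))
  prom3 <- data.frame(chrom = "chr1", start = c(100, 1000),
                      end = c(300, 1200),
                      peak_id = c("chr1_100_300", "chr1_1000_1200"),
                      gene = c("geneA", "geneB"))
  co3 <- data.frame(peak1 = c("chr1_5000_5200", "chr1_5000_5200"),
                    peak2 = c("chr1_100_300", "chr1_1000_1200"),
                    coaccess = c(0.9, 0.95))
  out3 <- select_cis_regions(prom3, peaks3, co3, threshold = 0.8)
  distal <- out3[out3$kind == "distal", ]
  expect_equal(nrow(distal), 2L)
  expect_setequal(distal$gene, c("geneA", "geneB"))

  # raising the threshold never adds regions (monotone filtering)
  for (th in c(0.5, 0.8, 0.9, 0.99)) {
    n_th <- nrow(select_cis_regions(prom3, peaks3, co3, threshold = th))
    if (exists("n_prev")) expect_lte(n_th, n_prev)
    n_prev <- n_th
  }
})

test_that("scan_motifs finds consensus sites on both strands, not background", {
  genome <- c(chrA = paste0(strrep("CG", 20), "GATA", strrep("GC", 20)),
              chrB = strrep("C", 80),
              chrC = paste0(strrep("CG", 20), "TATC", strrep("GC", 20)))
  lib <- motif_library(list(list(tf_names = "GATA1",
                                 matrix = consensus_mat("GATA"))))
  regions <- data.frame(chrom = c("chrA", "chrB", "chrC"),
                        start = 0, end = 80,
                        gene = c("gA", "gB", "gC"))
  bg <- scan_motifs(regions, genome, lib, score_frac = 0.8)
  # forward hit on chrA, reverse-complement hit on chrC, nothing on chrB
  expect_setequal(bg$pairs$target, c("gA", "gC"))
  expect_true(all(bg$pairs$tf == "GATA1"))

  # raising score_frac never adds edges
  n_prev <- Inf
  for (sf in c(0.5, 0.7, 0.9, 1.0)) {
    n <- nrow(scan_motifs(regions, genome, lib, score_frac = sf)$pairs)
    expect_lte(n, n_prev)
    n_prev <- n
  }

  # region beyond the contig is skipped with a warning
  bad <- data.frame(chrom = "chrB", start = 0, end = 1e4, gene = "gB")
  expect_warning(out <- scan_motifs(bad, genome, lib, 0.8), "bounds")
  expect_equal(nrow(out$pairs), 0L)
})

test_that("scan_motifs recovers exactly the planted edges of the world", {
  w <- small_world()
  bg <- small_base_grn()
  truth <- paste(w$grn$edges$tf, w$grn$edges$target)
  got <- paste(bg$pairs$tf, bg$pairs$target)
  expect_true(all(truth %in% got))
  expect_true(all(got %in% truth))
})

test_that("scramble_motifs is a seeded derangement of name assignments", {
  lib2 <- motif_library(list(
    list(tf_names = "A", matrix = consensus_mat("ACGT")),
    list(tf_names = "B", matrix = consensus_mat("TTAA"))))
  s2 <- scramble_motifs(lib2, seed = 7)
  expect_equal(s2$motifs[[1]]$tf_names, "B")
  expect_equal(s2$motifs[[2]]$tf_names, "A")
  expect_equal(s2$motifs[[1]]$matrix, lib2$motifs[[1]]$matrix)

  lib5 <- motif_library(lapply(1:5, function(i)
    list(tf_names = paste0("TF", i), matrix = consensus_mat("ACGTAC"))))
  s5a <- scramble_motifs(lib5, seed = 13)
  s5b <- scramble_motifs(lib5, seed = 13)
  for (i in 1:5) {
    expect_false(identical(s5a$motifs[[i]]$tf_names,
                           lib5$motifs[[i]]$tf_names))
    expect_identical(s5a$motifs[[i]]$tf_names, s5b$motifs[[i]]$tf_names)
  }
  expect_error(scramble_motifs(motif_library(list(
    list(tf_names = "A", matrix = consensus_mat("ACGT")))), 1),
    "derangement")
})

test_that("scrambled base GRN recovers planted edges at chance level only", {
  w <- small_world()
  pg <- annotate_tss(w$fixtures$peaks, w$fixtures$tss, window_bp = 0)
  regions <- select_cis_regions(pg, w$fixtures$peaks, w$fixtures$coaccess)
  bgs <- scan_motifs(regions, w$fixtures$genome,
                     scramble_motifs(w$fixtures$motifs, seed = 5), 0.85)
  truth <- paste(w$grn$edges$tf, w$grn$edges$target)
  got <- paste(bgs$pairs$tf, bgs$pairs$target)
  n_hit <- sum(truth %in% got)
  # a planted site (tf_a -> g) becomes a hit iff the deranged name tf_b is
  # one of g's other regulators: P = (edges_per_target - 1) / (n_tfs - 1)
  n <- length(truth)
  p0 <- (w$params$edges_per_target - 1) / (w$params$n_tfs - 1)
  expect_lte(n_hit, n * p0 + 3 * sqrt(n * p0 * (1 - p0)))
})
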