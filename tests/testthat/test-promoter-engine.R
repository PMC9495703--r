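# PSSM similarity, threshold calibration, motif discovery, final-set
# construction, promoter ranking and tailoring (internal backend).

uniform_pssm <- function(cols) {
  pssm(matrix(unlist(cols), nrow = 4))
}

test_that("PSSM similarity is 1 at identity and -1 at rank reversal", {
  c_fwd <- c(0.4, 0.3, 0.2, 0.1)
  c_rev <- c(0.1, 0.2, 0.3, 0.4)
  m1 <- uniform_pssm(rep(list(c_fwd), 3) |> c(rep(list(c_rev), 3)))
  expect_equal(pssm_similarity(m1, m1), 1)
  # column-wise probability inversion reverses every rank; the construction
  # is palindromic so the reverse-complement orientation scores -1 too
  m2 <- uniform_pssm(rep(list(c_rev), 3) |> c(rep(list(c_fwd), 3)))
  expect_equal(pssm_similarity(m1, m2), -1)
  expect_equal(pssm_similarity(m2, m1), pssm_similarity(m1, m2))
})

test_that("similarity across lengths is the best ungapped offset", {
  set.seed(41)
  p10 <- vapply(1:10, function(j) { x <- runif(4) + 0.05; x / sum(x) },
                numeric(4))
  m10 <- pssm(p10)
  m6 <- pssm(p10[, 3:8])
  got <- pssm_similarity(m10, m6)
  # brute force over the 5 offsets and both orientations
  rc <- function(p) { q <- p[4:1, rev(seq_len(ncol(p)))]; q }
  best <- -Inf
  for (off in 0:4) {
    win <- p10[, (off + 1):(off + 6)]
    best <- max(best, cor(as.vector(win), as.vector(p10[, 3:8]),
                          method = "spearman"),
                cor(as.vector(win), as.vector(rc(p10[, 3:8])),
                    method = "spearman"))
  }
  expect_equal(got, best, tolerance = 1e-12)
  expect_equal(got, 1)  # exact submatrix at offset 2
})

test_that("threshold calibration reproduces percentile limits and is seeded", {
  set.seed(42)
  S <- random_pssms(3, seed = 9)
  th100 <- calibrate_threshold(S, X = 100, n_random = 20, seed = 5)
  expect_equal(th100$D, max(th100$corr))
  th0 <- calibrate_threshold(S, X = 0, n_random = 20, seed = 5)
  expect_equal(th0$D, min(th0$corr))
  a <- calibrate_threshold(S, X = 95, n_random = 30, seed = 7)
  b <- calibrate_threshold(S, X = 95, n_random = 30, seed = 7)
  expect_identical(a$D, b$D)
  # independent linear-interpolation percentile on the stored correlations
  expect_equal(a$D, oracle_percentile(a$corr, 95), tolerance = 1e-12)
  # monotone in X
  xs <- c(10, 50, 90, 99)
  ds <- vapply(xs, function(x)
    calibrate_threshold(S, X = x, n_random = 30, seed = 7)$D, numeric(1))
  expect_true(all(diff(ds) >= 0))
})

test_that("planted motifs are recovered by the internal discovery backend", {
  set.seed(43)
  plant <- "TATAWTAT"
  primary <- vapply(1:50, function(i) {
    s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
               collapse = "")
    inst <- chartr("W", sample(c("A", "T"), 1), plant)
    off <- sample.int(60 - 8 + 1, 1)
    substr(s, off, off + 7) <- inst
    s
  }, character(1))
  control <- vapply(primary, function(s)
    paste(sample(strsplit(s, "")[[1]]), collapse = ""), character(1))
  motifs <- discover_motifs(primary, control, backend = "internal")
  expect_gt(length(motifs), 0)
  hits <- vapply(motifs, function(m)
    consensus_matches_plant(pssm_consensus(m), plant), logical(1))
  expect_true(any(hits))
  # no enrichment when primary == control
  expect_length(discover_motifs(primary, primary, backend = "internal"), 0)
  expect_error(discover_motifs(c("ACGT"), control, backend = "internal"),
               "shorter")
})

test_that("the external backend reports a structured error when absent", {
  skip_if(Sys.which("streme") != "", "STREME available")
  expect_error(discover_motifs("ACGTACGTAC", "ACGTACGTAC",
                               backend = "external"),
               class = "selectigene_backend_error")
})

test_that("final-set filtering applies the strict percentile rule", {
  # four sharply distinct motifs; unwanted-host anti-sets arranged so the
  # aggregated scores are 0.5, 1, 1.5, 2 at alpha = 0.5
  mk <- function(cons) {
    cols <- lapply(strsplit(cons, "")[[1]], function(b)
      ifelse(c("A", "C", "G", "T") == b, 0.97, 0.01))
    uniform_pssm(cols)
  }
  # consensi chosen so no pair coincides under reverse complement
  m <- lapply(c("AAAAAA", "CCCCCC", "GAGAGA", "ACACAC"), mk)
  hosts <- list(toy_host("a", "wanted", "GAAGAA"),
                toy_host("b1", "unwanted", "GAAGAA"),
                toy_host("b2", "unwanted", "GAAGAA"),
                toy_host("b3", "unwanted", "GAAGAA"))
  mb <- microbiome(hosts)
  S <- list(a = m, b1 = m[2:4], b2 = m[3:4], b3 = m[4])
  D <- setNames(rep(0.99, 4), c("a", "b1", "b2", "b3"))
  fs <- build_final_set(S, mb, alpha = 0.5, Y = 75, D_override = D)
  # scores {0.5, 1, 1.5, 2}: the 75-percentile is 1.625, strict > keeps one
  expect_equal(unname(fs$scores), c(0.5, 1, 1.5, 2))
  expect_equal(fs$cutoff, oracle_percentile(c(0.5, 1, 1.5, 2), 75))
  expect_length(fs$F, 1L)
  expect_equal(pssm_consensus(fs$F[[1]]), "ACACAC")
  # alpha = 1 counts wanted hits only; all equal -> empty set with warning
  expect_warning(fs1 <- build_final_set(S, mb, alpha = 1, Y = 75,
                                        D_override = D), "empty")
  expect_equal(unname(fs1$scores), rep(1, 4))
  expect_length(fs1$F, 0L)
  expect_error(build_final_set(list(a = list()), mb), "empty|candidate")
})

test_that("promoter E-values match the exhaustive-scan oracle", {
  set.seed(44)
  cols <- lapply(1:6, function(j) {
    x <- c(0.7, 0.1, 0.1, 0.1)[order(c(j %% 4, (j + 1) %% 4,
                                       (j + 2) %% 4, (j + 3) %% 4))]
    x
  })
  m <- uniform_pssm(cols)
  cons <- pssm_consensus(m)
  bgseq <- paste(sample(c("A", "C", "G", "T"), 34, replace = TRUE),
                 collapse = "")
  prom1 <- paste0(substr(bgseq, 1, 14), cons, substr(bgseq, 21, 34))
  prom2 <- paste(sample(c("A", "C", "G", "T"), 34, replace = TRUE),
                 collapse = "")
  cands <- data.frame(promoter_id = c("p1", "p2"), seq = c(prom1, prom2))
  ranks <- rank_promoters(list(m), cands, backend = "internal")
  # exact-consensus promoter ranks strictly better
  expect_equal(ranks[[1]]$promoter_id, "p1")
  expect_lt(ranks[[1]]$evalue, ranks[[2]]$evalue)
  # oracle: background from both candidates, smoothed log-odds, full scan of
  # both strands, exact p over all 4^6 windows, window correction, times N
  DNA <- c("A", "C", "G", "T")
  chars <- unlist(strsplit(toupper(paste(c(prom1, prom2), collapse = "")), ""))
  bg <- as.numeric((table(factor(chars, levels = DNA)) + 1) /
                     (length(chars) + 4))
  eps <- 1e-4
  lo <- log((m$probs * (1 - 4 * eps) + eps) / bg)
  score_win <- function(win, mat) {
    idx <- match(strsplit(win, "")[[1]], DNA)
    sum(mat[cbind(idx, 1:6)])
  }
  lo_rc <- lo[4:1, 6:1]
  for (r in ranks) {
    L <- nchar(r$seq)
    best <- -Inf
    for (pos in 1:(L - 5)) {
      win <- substr(r$seq, pos, pos + 5)
      best <- max(best, score_win(win, lo), score_win(win, lo_rc))
    }
    grid <- expand.grid(DNA, DNA, DNA, DNA, DNA, DNA,
                        stringsAsFactors = FALSE)
    scores <- apply(grid, 1, function(w) score_win(paste(w, collapse = ""), lo))
    probs <- apply(grid, 1, function(w) prod(bg[match(w, DNA)]))
    p_pos <- sum(probs[scores >= best - 1e-12])
    p_best <- 1 - (1 - p_pos)^(2 * (L - 5))
    expect_equal(r$evalue, min(p_best, 1) * 2, tolerance = 1e-9)
  }
  # identical promoters tie with stable id order
  cands2 <- data.frame(promoter_id = c("pB", "pA"), seq = c(prom1, prom1))
  r2 <- rank_promoters(list(m), cands2, backend = "internal")
  expect_equal(r2[[1]]$evalue, r2[[2]]$evalue)
  expect_equal(vapply(r2, `[[`, character(1), "promoter_id"), c("pA", "pB"))
})

test_that("tailoring emits one variant per mismatch plus the full correction", {
  set.seed(45)
  cols <- lapply(strsplit("TATAAT", "")[[1]], function(b)
    ifelse(c("A", "C", "G", "T") == b, 0.9, 1 / 30))
  m <- uniform_pssm(cols)
  base <- paste(sample(c("C", "G"), 40, replace = TRUE), collapse = "")
  prom <- base
  substr(prom, 11, 16) <- "TACACT"  # two mismatches to TATAAT
  cands <- data.frame(promoter_id = "p", seq = prom)
  r <- rank_promoters(list(m), cands, backend = "internal",
                      bg_seqs = "ACGTACGTACGT")
  vars <- tailor_promoter(r[[1]])
  expect_length(vars, 4L)  # original, two singles, one full
  expect_equal(vars[1], prom)
  expect_true(all(nchar(vars) == nchar(prom)))
  # fully corrected variant re-scores at least as well
  cands2 <- data.frame(promoter_id = c("orig", "full"),
                       seq = c(prom, vars[length(vars)]))
  r2 <- rank_promoters(list(m), cands2, backend = "internal",
                       bg_seqs = "ACGTACGTACGT")
  ev <- setNames(vapply(r2, `[[`, numeric(1), "evalue"),
                 vapply(r2, `[[`, character(1), "promoter_id"))
  expect_lte(ev["full"], ev["orig"])
  # exact match: original only
  prom3 <- base
  substr(prom3, 11, 16) <- "TATAAT"
  r3 <- rank_promoters(list(m), data.frame(promoter_id = "p", seq = prom3),
                       backend = "internal", bg_seqs = "ACGTACGTACGT")
  expect_equal(tailor_promoter(r3[[1]]), prom3)
})

test_that("MEME text round-trip preserves matrices", {
  set.seed(46)
  ms <- random_pssms(3, seed = 3, min_w = 6, max_w = 9)
  f <- tempfile(fileext = ".txt")
  write_meme(ms, f)
  back <- read_meme(f)
  expect_length(back, 3L)
  for (i in 1:3)
    expect_equal(back[[i]]$probs, ms[[i]]$probs, tolerance = 1e-4)
})
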