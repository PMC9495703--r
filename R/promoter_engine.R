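# Contrastive motif-set construction, similarity-threshold calibration,
# promoter ranking and mismatch tailoring.
#
# Motif discovery and promoter scanning have two backends: "external" calls
# the MEME suite (STREME / MAST) when the binaries are on the PATH, and
# "internal" is a self-contained implementation with the same contract
# (enriched-k-mer seeding + EM refinement for discovery; log-odds scanning
# with exact convolution p-values and the combined-match E-value convention
# for ranking).

.DNA <- c("A", "C", "G", "T")

#' Construct a PSSM
#' @param probs 4 x L numeric matrix (rows A,C,G,T), each column summing to 1
#' @param evalue discovery significance attached to the motif
#' @param source_host host the motif was discovered in
#' @return object of class `pssm`
#' @export
pssm <- function(probs, evalue = 1, source_host = NA_character_) {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4L) stop("PSSM must have 4 rows (A,C,G,T)")
  L <- ncol(probs)
  if (L < 6L || L > 20L) stop("motif length must lie in [6, 20]")
  if (any(probs < 0)) stop("PSSM entries must be non-negative")
  if (any(abs(colSums(probs) - 1) > 1e-9)) stop("PSSM columns must sum to 1")
  rownames(probs) <- .DNA
  structure(list(probs = probs, length = L, evalue = evalue,
                 source_host = source_host), class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("<pssm> %s (L=%d, evalue=%.3g, host=%s)\n",
              pssm_consensus(x), x$length, x$evalue, x$source_host))
  invisible(x)
}

#' Consensus string of a PSSM (modal nucleotide per column)
#' @param m a `pssm`
#' @return character string of length L
#' @export
pssm_consensus <- function(m) {
  paste(.DNA[apply(m$probs, 2, which.max)], collapse = "")
}

# reverse complement of a PSSM: reverse columns, swap A<->T and C<->G rows
.pssm_rc <- function(m) {
  p <- m$probs[c("T", "G", "C", "A"), rev(seq_len(m$length)), drop = FALSE]
  rownames(p) <- .DNA
  pssm(p, m$evalue, m$source_host)
}

# ---- similarity --------------------------------------------------------

#' Spearman similarity between two PSSMs
#'
#' The probability matrices are flattened column-major and compared by
#' Spearman rank correlation; for unequal lengths the shorter matrix slides
#' along the longer (ungapped) and the maximum over offsets and over the
#' reverse-complement orientation is returned, making the measure symmetric.
#'
#' @param m1,m2 `pssm` objects
#' @return correlation in [-1, 1]
#' @export
pssm_similarity <- function(m1, m2) {
  if (m1$length < m2$length) return(pssm_similarity(m2, m1))
  long <- m1; short <- m2
  best <- -Inf
  flat_s <- as.vector(short$probs)
  flat_s_rc <- as.vector(.pssm_rc(short)$probs)
  for (off in 0:(long$length - short$length)) {
    win <- as.vector(long$probs[, (off + 1L):(off + short$length),
                                drop = FALSE])
    best <- max(best,
                suppressWarnings(stats::cor(win, flat_s, method = "spearman")),
                suppressWarnings(stats::cor(win, flat_s_rc,
                                            method = "spearman")),
                na.rm = TRUE)
  }
  best
}

#' Random PSSMs for threshold calibration
#'
#' Columns are independent symmetric Dirichlet(1) draws; lengths are uniform
#' on [min_w, max_w].
#' @param n number of matrices
#' @param seed RNG seed
#' @param min_w,max_w length range
#' @return list of `pssm`
#' @export
random_pssms <- function(n = 100L, seed = 1L, min_w = 6L, max_w = 20L) {
  .with_seed(seed, {
    lapply(seq_len(n), function(i) {
      L <- sample(min_w:max_w, 1L)
      pssm(vapply(seq_len(L), function(j) .rdirichlet(rep(1, 4)),
                  numeric(4)))
    })
  })
}

#' Calibrate a host's motif-similarity threshold
#'
#' All pairwise Spearman similarities between the host's motifs and
#' `n_random` random PSSMs are pooled; the threshold D_h is the X-percentile
#' (linear interpolation) of that pool.
#'
#' @param S_h list of the host's `pssm` motifs
#' @param X percentile (default 95)
#' @param n_random number of random PSSMs (default 100)
#' @param seed RNG seed for the random matrices
#' @param host_id host label
#' @return list with `host_id`, `D`, `X`, `n_random`, `seed` and the raw
#'   correlations
#' @export
calibrate_threshold <- function(S_h, X = 95, n_random = 100L, seed = 1L,
                                host_id = NA_character_) {
  if (!length(S_h)) stop("empty motif set")
  rand <- random_pssms(n_random, seed)
  corr <- as.vector(vapply(S_h, function(m)
    vapply(rand, function(r) pssm_similarity(m, r), numeric(1)),
    numeric(n_random)))
  list(host_id = host_id, D = unname(stats::quantile(corr, X / 100, type = 7)),
       X = X, n_random = n_random, seed = seed, corr = corr)
}

# ---- discovery ---------------------------------------------------------

.backend_error <- function(tool) {
  stop(structure(class = c("selectigene_backend_error", "error", "condition"),
                 list(message = paste0(tool, " binary not found on PATH; ",
                                       "use backend = \"internal\""),
                      call = sys.call(-1))))
}

# 0-order background distribution of a set of sequences
.bg_freq <- function(seqs, pseudo = 1) {
  chars <- unlist(strsplit(toupper(paste(seqs, collapse = "")), "",
                           fixed = TRUE))
  counts <- table(factor(chars, levels = .DNA)) + pseudo
  as.numeric(counts / sum(counts))
}

# which sequences contain a k-mer (presence/absence per sequence)
.kmer_presence <- function(seqs, k) {
  km_list <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    unique(substring(s, 1:(L - k + 1L), k:L))
  })
  tab <- table(unlist(km_list))
  tab[!grepl("[^ACGT]", names(tab))]
}

#' Discover enriched motifs in a primary set against a control set
#'
#' Internal backend: k-mers significantly enriched in the primary sequences
#' (one-sided Fisher exact test on per-sequence presence, p <= `p_value`)
#' seed EM refinement of a PSSM over the primary set against the control
#' 0-order background. External backend shells out to STREME
#' (`--p 0.05 --minw 6 --maxw 20 --order 3`) and parses its MEME-format
#' output.
#'
#' @param primary,control character vectors of DNA sequences
#' @param backend "internal" or "external"
#' @param min_w,max_w motif length range (seed widths are clipped to it)
#' @param p_value significance threshold (default 0.05)
#' @param max_motifs maximum motifs returned
#' @param seed RNG seed (EM is deterministic given the seed order)
#' @param source_host label stamped on the motifs
#' @return list of `pssm`, ordered by significance
#' @export
discover_motifs <- function(primary, control,
                            backend = c("internal", "external"),
                            min_w = 6L, max_w = 20L, p_value = 0.05,
                            max_motifs = 5L, seed = 1L,
                            source_host = NA_character_) {
  backend <- match.arg(backend)
  if (!length(primary) || !length(control))
    stop("primary and control sets must be non-empty")
  primary <- toupper(primary); control <- toupper(control)
  if (any(nchar(primary) < min_w))
    stop("primary sequences shorter than the minimum motif length ", min_w)
  if (backend == "external") {
    if (Sys.which("streme") == "") .backend_error("streme")
    return(.run_streme(primary, control, min_w, max_w, p_value, source_host))
  }

  widths <- intersect(c(6L, 8L), min_w:max_w)
  if (!length(widths)) widths <- min_w
  seeds <- list()
  for (k in widths) {
    prim <- .kmer_presence(primary, k)
    ctrl <- .kmer_presence(control, k)
    if (!length(prim)) next
    np <- length(primary); nc <- length(control)
    pvals <- vapply(names(prim), function(km) {
      a <- prim[[km]]
      b <- if (km %in% names(ctrl)) ctrl[[km]] else 0L
      stats::fisher.test(matrix(c(a, np - a, b, nc - b), 2L),
                         alternative = "greater")$p.value
    }, numeric(1))
    keep <- pvals[pvals <= p_value]
    if (length(keep))
      seeds <- c(seeds, Map(function(km, p) list(kmer = km, p = p),
                            names(keep), keep))
  }
  if (!length(seeds)) return(list())
  seeds <- seeds[order(vapply(seeds, `[[`, numeric(1), "p"),
                       vapply(seeds, `[[`, character(1), "kmer"))]
  # greedy de-duplication of near-identical seeds
  picked <- list()
  for (s in seeds) {
    dup <- any(vapply(picked, function(p) {
      .kmer_close(s$kmer, p$kmer)
    }, logical(1)))
    if (!dup) picked[[length(picked) + 1L]] <- s
    if (length(picked) >= max_motifs) break
  }
  bg <- .bg_freq(control)
  lapply(picked, function(s)
    .em_refine(s$kmer, primary, bg, evalue = s$p, source_host = source_host))
}

# two k-mer seeds are "close" (shifted/overlapping variants of the same
# elicited motif) if some ungapped alignment offset, in either orientation,
# leaves an overlap of >= 4 bases with at most one mismatch (none for short
# overlaps); discovery keeps only one representative per such group
.kmer_close <- function(a, b) {
  close_one <- function(x, y) {
    kx <- nchar(x); ky <- nchar(y)
    cx <- strsplit(x, "")[[1]]; cy <- strsplit(y, "")[[1]]
    for (s in (-(ky - 1L)):(kx - 1L)) {
      i1 <- max(1L, 1L + s); i2 <- min(kx, ky + s)
      ov <- i2 - i1 + 1L
      if (ov < 4L) next
      mism <- sum(cx[i1:i2] != cy[(i1:i2) - s])
      if (mism <= (if (ov >= 6L) 1L else 0L)) return(TRUE)
    }
    FALSE
  }
  close_one(a, b) || close_one(a, revcomp(b))
}

# EM refinement of a seed k-mer into a PSSM (one occurrence per sequence,
# positions equiprobable a priori), 10 iterations, pseudocount 0.1
.em_refine <- function(seed_kmer, primary, bg, iters = 10L, evalue = 1,
                       source_host = NA_character_) {
  k <- nchar(seed_kmer)
  probs <- matrix(0.1 / 3, nrow = 4L, ncol = k, dimnames = list(.DNA, NULL))
  sc <- strsplit(seed_kmer, "")[[1]]
  for (j in seq_len(k)) probs[, j] <- ifelse(.DNA == sc[j], 0.9, 0.1 / 3)
  seq_chars <- lapply(primary, function(s) strsplit(s, "")[[1]])
  for (it in seq_len(iters)) {
    counts <- matrix(0.1, nrow = 4L, ncol = k, dimnames = list(.DNA, NULL))
    for (chars in seq_chars) {
      L <- length(chars)
      if (L < k) next
      n_pos <- L - k + 1L
      lr <- numeric(n_pos)
      for (pos in seq_len(n_pos)) {
        win <- chars[pos:(pos + k - 1L)]
        idx <- match(win, .DNA)
        if (anyNA(idx)) { lr[pos] <- 0; next }
        lr[pos] <- prod(probs[cbind(idx, seq_len(k))] / bg[idx])
      }
      if (sum(lr) == 0) next
      z <- lr / sum(lr)
      for (pos in which(z > 1e-6)) {
        win <- chars[pos:(pos + k - 1L)]
        idx <- match(win, .DNA)
        counts[cbind(idx, seq_len(k))] <-
          counts[cbind(idx, seq_len(k))] + z[pos]
      }
    }
    probs <- sweep(counts, 2, colSums(counts), "/")
  }
  pssm(probs, evalue = evalue, source_host = source_host)
}

#' Enhancing or anti motifs for one host
#'
#' For a wanted host, transcription-enhancing motifs are discovered with the
#' top-`fraction` most highly expressed genes' promoters as primary input and
#' the intergenic sequences as control. For an unwanted host, anti-motifs
#' are discovered with the intergenic sequences as primary and those
#' promoters as control.
#'
#' @param host a `host_genome`; regions are extracted on the fly if missing
#' @param fraction expression fraction defining the highly expressed
#'   promoter set (default top tertile)
#' @param backend passed to [discover_motifs()]
#' @param ... further arguments to [discover_motifs()]
#' @return list with `enhancing` and `anti` (one of them NULL according to
#'   the host's role)
#' @export
host_motifs <- function(host, fraction = 1 / 3,
                        backend = c("internal", "external"), ...) {
  backend <- match.arg(backend)
  if (is.null(host$regions)) host <- with_regions(host)
  proms <- host$regions$promoters
  if (!nrow(proms)) stop("host ", host$host_id, " has no promoters")
  top_ids <- select_reference_genes(host, fraction)$gene_id
  top_proms <- proms$seq[proms$gene_id %in% top_ids]
  if (!length(top_proms)) stop("no promoters for highly expressed genes of ",
                               host$host_id)
  inter <- host$regions$intergenic
  inter <- inter[nchar(inter) >= 6L]
  if (!length(inter)) stop("host ", host$host_id, " has no intergenic sequence")
  if (host$role == "wanted") {
    list(enhancing = discover_motifs(top_proms, inter, backend,
                                     source_host = host$host_id, ...),
         anti = NULL)
  } else {
    list(enhancing = NULL,
         anti = discover_motifs(inter, top_proms, backend,
                                source_host = host$host_id, ...))
  }
}

# ---- final motif set ---------------------------------------------------

#' Build the final contrastive motif set
#'
#' The candidate set C is the union of the wanted hosts' enhancing motifs.
#' For every candidate m and every host h, the per-host indicator is 1 when
#' some motif in the host's own set (enhancing for wanted hosts, anti for
#' unwanted hosts) has similarity >= the host's calibrated threshold D_h.
#' The aggregated score is alpha * (wanted hits) + (1 - alpha) * (unwanted
#' hits); the final set keeps candidates scoring strictly above the
#' Y-percentile of all aggregated scores.
#'
#' @param S_by_host named list, host id -> list of `pssm` (enhancing sets for
#'   wanted hosts, anti sets for unwanted hosts)
#' @param mb a `microbiome`
#' @param alpha tuning weight in [0, 1] (default 0.5)
#' @param Y percentile filter (default 75)
#' @param X threshold percentile (default 95)
#' @param n_random random PSSMs per host threshold (default 100)
#' @param seed base RNG seed for calibration
#' @param D_override optional named numeric vector of per-host similarity
#'   thresholds, bypassing calibration (expert use)
#' @return list with `F` (final motifs), `scores`, `delta` (host x candidate
#'   indicator matrix) and `thresholds`
#' @export
build_final_set <- function(S_by_host, mb, alpha = 0.5, Y = 75, X = 95,
                            n_random = 100L, seed = 1L, D_override = NULL) {
  C <- unlist(lapply(mb$A, function(a) S_by_host[[a]]), recursive = FALSE)
  if (!length(C)) stop("no candidate motifs: wanted hosts' enhancing sets are empty")
  hosts <- c(mb$A, mb$B)
  thresholds <- list()
  delta <- matrix(0L, nrow = length(hosts), ncol = length(C),
                  dimnames = list(hosts, NULL))
  for (hi in seq_along(hosts)) {
    h <- hosts[hi]
    S_h <- S_by_host[[h]]
    if (is.null(S_h) || !length(S_h)) next
    if (!is.null(D_override) && h %in% names(D_override)) {
      th <- list(host_id = h, D = unname(D_override[h]), X = X,
                 n_random = 0L, seed = seed)
    } else {
      th <- calibrate_threshold(S_h, X, n_random, seed + hi, host_id = h)
    }
    thresholds[[h]] <- th
    for (ci in seq_along(C)) {
      sims <- vapply(S_h, function(m) pssm_similarity(C[[ci]], m), numeric(1))
      delta[hi, ci] <- as.integer(any(sims >= th$D))
    }
  }
  wA <- colSums(delta[mb$A, , drop = FALSE])
  wB <- colSums(delta[mb$B, , drop = FALSE])
  scores <- alpha * wA + (1 - alpha) * wB
  cut <- unname(stats::quantile(scores, Y / 100, type = 7))
  keep <- scores > cut
  if (!any(keep))
    warning("final motif set is empty (all aggregated scores at or below the ",
            Y, "-percentile)")
  list(F = C[keep], scores = scores, delta = delta, thresholds = thresholds,
       cutoff = cut, alpha = alpha, Y = Y)
}

# ---- promoter ranking --------------------------------------------------

# exact p-value of a log-odds score under the 0-order background. For short
# motifs (<= 10 columns) the full score distribution is enumerated by
# iterated outer sums; longer motifs use a discretized convolution.
.score_pvalue <- function(lo, bg, score, grid = 1000L) {
  k <- ncol(lo)
  if (k <= 10L) {
    sc <- 0; pr <- 1
    for (j in seq_len(k)) {
      sc <- as.vector(outer(sc, lo[, j], "+"))
      pr <- as.vector(outer(pr, bg, "*"))
    }
    return(sum(pr[sc >= score - 1e-12]))
  }
  q <- round(lo * grid)
  offs <- -apply(q, 2, min)
  dist <- 1
  for (j in seq_len(ncol(q))) {
    col <- q[, j] + offs[j]
    new <- numeric(length(dist) + max(col))
    for (b in 1:4) {
      idx <- seq_along(dist) + col[b]
      new[idx] <- new[idx] + dist * bg[b]
    }
    dist <- new
  }
  target <- round(score * grid) + sum(offs)
  # P(score >= observed); clamp index into the support
  target <- max(1L, min(length(dist), target + 1L))
  sum(dist[target:length(dist)])
}

# best hit of a motif on a promoter (both strands): score, offset, strand
.best_hit <- function(m, seq, bg, eps = 1e-4) {
  lo <- log((m$probs * (1 - 4 * eps) + eps) / bg)
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars); k <- m$length
  best <- list(score = -Inf, offset = NA_integer_, strand = "+")
  if (L < k) return(c(best, list(lo = lo, n_windows = 0L)))
  idx <- match(chars, .DNA)
  for (variant in c("+", "-")) {
    loc <- if (variant == "+") lo else
      lo[c(4:1), rev(seq_len(k)), drop = FALSE]  # rc motif on forward strand
    for (pos in 1:(L - k + 1L)) {
      ii <- idx[pos:(pos + k - 1L)]
      if (anyNA(ii)) next
      s <- sum(loc[cbind(ii, seq_len(k))])
      if (s > best$score)
        best <- list(score = s, offset = pos - 1L, strand = variant)
    }
  }
  c(best, list(lo = lo, n_windows = 2L * (L - k + 1L)))
}

#' Rank candidate promoters against a final motif set
#'
#' Internal backend: each motif is scanned along both strands of each
#' promoter under a 0-order background; the best per-motif hit p-value is
#' computed exactly by convolution and corrected for the number of scanned
#' windows; per-promoter p-values are combined with the product-of-p-values
#' convention (p * sum_{j<k} (-ln p)^j / j!) and multiplied by the number of
#' candidates to give an E-value. Promoters are returned in ascending
#' E-value order (ties by promoter id). External backend shells out to MAST.
#'
#' @param F list of `pssm` (the final motif set)
#' @param candidates data.frame with `promoter_id` and `seq` columns
#' @param backend "internal" or "external"
#' @param bg_seqs optional sequences for background estimation (defaults to
#'   the candidates)
#' @return list of `promoter_rank` records, each with `promoter_id`, `seq`,
#'   `evalue` and per-motif `hits` (offset, strand, mismatch positions)
#' @export
rank_promoters <- function(F, candidates, backend = c("internal", "external"),
                           bg_seqs = NULL) {
  backend <- match.arg(backend)
  if (!length(F)) stop("empty motif set")
  if (backend == "external") {
    if (Sys.which("mast") == "") .backend_error("mast")
  }
  bg <- .bg_freq(if (is.null(bg_seqs)) candidates$seq else bg_seqs)
  N <- nrow(candidates)
  ranks <- lapply(seq_len(N), function(i) {
    seq <- toupper(candidates$seq[i])
    hits <- lapply(F, function(m) {
      bh <- .best_hit(m, seq, bg)
      p_pos <- .score_pvalue(bh$lo, bg, bh$score)
      p_best <- if (bh$n_windows == 0L) 1 else
        1 - (1 - min(1, p_pos))^bh$n_windows
      cons <- pssm_consensus(m)
      mism <- integer(0)
      if (!is.na(bh$offset)) {
        win <- substr(seq, bh$offset + 1L, bh$offset + m$length)
        if (bh$strand == "-") win <- revcomp(win)
        mism <- which(strsplit(win, "")[[1]] != strsplit(cons, "")[[1]])
      }
      list(motif = m, consensus = cons, offset = bh$offset,
           strand = bh$strand, p_best = max(p_best, 1e-300), mismatches = mism)
    })
    rho <- prod(vapply(hits, `[[`, numeric(1), "p_best"))
    k <- length(hits)
    lnr <- -log(rho)
    pcomb <- rho * sum(vapply(0:(k - 1L), function(j)
      lnr^j / factorial(j), numeric(1)))
    structure(list(promoter_id = candidates$promoter_id[i], seq = seq,
                   evalue = min(pcomb, 1) * N, hits = hits),
              class = "promoter_rank")
  })
  ord <- order(vapply(ranks, `[[`, numeric(1), "evalue"),
               vapply(ranks, `[[`, character(1), "promoter_id"))
  ranks[ord]
}

#' Summarize promoter ranks as a data.frame
#' @param ranks output of [rank_promoters()]
#' @return data.frame promoter_id, evalue, n_motifs
#' @export
rank_table <- function(ranks) {
  data.frame(promoter_id = vapply(ranks, `[[`, character(1), "promoter_id"),
             evalue = vapply(ranks, `[[`, numeric(1), "evalue"),
             n_motifs = vapply(ranks, function(r) length(r$hits), integer(1)),
             stringsAsFactors = FALSE)
}

#' Tailor a ranked promoter toward its mapped motifs
#'
#' For every mismatch between a mapped motif and the promoter, one variant is
#' emitted with that single position set to the motif's modal nucleotide;
#' one additional variant corrects all mismatches at once. The original
#' promoter is always first. Variants preserve length.
#'
#' @param p a `promoter_rank`
#' @return character vector of promoter sequences (original first)
#' @export
tailor_promoter <- function(p) {
  seq <- p$seq
  singles <- character(0)
  full <- strsplit(seq, "")[[1]]
  any_mism <- FALSE
  for (h in p$hits) {
    if (is.na(h$offset) || !length(h$mismatches)) next
    cons <- strsplit(h$consensus, "")[[1]]
    for (mpos in h$mismatches) {
      any_mism <- TRUE
      promoter_pos <- if (h$strand == "+") h$offset + mpos else
        h$offset + (h$motif$length - mpos + 1L)
      base <- if (h$strand == "+") cons[mpos] else revcomp(cons[mpos])
      v <- strsplit(seq, "")[[1]]
      v[promoter_pos] <- base
      singles <- c(singles, paste(v, collapse = ""))
      full[promoter_pos] <- base
    }
  }
  if (!any_mism) return(seq)
  unique(c(seq, singles, paste(full, collapse = "")))
}

# ---- MEME text format and external backends ----------------------------

#' Write PSSMs in minimal MEME motif text format
#' @param pssms list of `pssm`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_meme <- function(pssms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (i in seq_along(pssms)) {
    m <- pssms[[i]]
    writeLines(sprintf("MOTIF m%d %s", i, pssm_consensus(m)), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= %g",
      m$length, m$evalue), con)
    for (j in seq_len(m$length))
      writeLines(paste(sprintf("%.6f", m$probs[, j]), collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read motifs from MEME motif text format
#' @param path MEME-format file (as written by STREME or [write_meme()])
#' @return list of `pssm`
#' @export
read_meme <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^letter-probability matrix:", lines)
  lapply(starts, function(s) {
    w <- as.integer(sub(".*w= *(\\d+).*", "\\1", lines[s]))
    ev <- if (grepl("E= *([0-9.eE+-]+)", lines[s]))
      as.numeric(sub(".*E= *([0-9.eE+-]+).*", "\\1", lines[s])) else 1
    rows <- lines[(s + 1L):(s + w)]
    probs <- vapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]]), numeric(4))
    dimnames(probs) <- NULL
    # renormalize against rounding in the text representation
    probs <- sweep(probs, 2, colSums(probs), "/")
    pssm(probs, evalue = ev)
  })
}

.run_streme <- function(primary, control, min_w, max_w, p_value, source_host) {
  dir <- tempfile("streme")
  dir.create(dir)
  pf <- file.path(dir, "primary.fa"); cf <- file.path(dir, "control.fa")
  writeLines(paste0(">p", seq_along(primary), "\n", primary), pf)
  writeLines(paste0(">c", seq_along(control), "\n", control), cf)
  status <- system2("streme", c("--p", pf, "--n", cf, "--oc", dir,
                                "--minw", min_w, "--maxw", max_w,
                                "--pvt", p_value, "--order", 3, "--dna"),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("streme exited with status ", status)
  out <- file.path(dir, "streme.txt")
  motifs <- read_meme(out)
  lapply(motifs, function(m) { m$source_host <- source_host; m })
}
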