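# Independent brute-force oracles used across tests. These re-derive the
# quantities from first principles (direct counting, naive products, full
# enumeration) and stay independent of the package's implementation paths.

# CAI weights by direct counting, log-free
oracle_cai_weights <- function(seqs, pseudo = 0.5) {
  counts <- setNames(rep(0, 61), sense_codons())
  for (s in seqs) {
    L <- nchar(s)
    cods <- substring(s, seq(1, L, 3), seq(3, L, 3))
    cods <- cods[!cods %in% c("TAA", "TAG", "TGA")]
    for (cd in cods) if (cd %in% names(counts)) counts[cd] <- counts[cd] + 1
  }
  w <- counts
  for (aa in amino_acids()) {
    fam <- synonymous_codons(aa)
    mx <- max(counts[fam])
    if (mx == 0) w[fam] <- pseudo
    else {
      w[fam] <- counts[fam] / mx
      w[fam][counts[fam] == 0] <- pseudo
    }
  }
  w
}

# gene score as the naive product-then-root
oracle_gene_score <- function(cds, w) {
  L <- nchar(cds)
  cods <- substring(cds, seq(1, L, 3), seq(3, L, 3))
  cods <- cods[!cods %in% c("TAA", "TAG", "TGA")]
  prod(w[cods])^(1 / length(cods))
}

# percentile with explicit linear interpolation (type-7 convention)
oracle_percentile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p / 100 + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# exhaustive per-position synonymous enumeration of f over a small gene
# (1 wanted + 1 unwanted host); returns data.frame of every variant with f
oracle_enumerate_f <- function(cds, mb, cub, alpha = 1) {
  L <- nchar(cds)
  cods <- substring(cds, seq(1, L, 3), seq(3, L, 3))
  fams <- lapply(cods, function(cd) synonymous_codons(translate_cds(cd)))
  grid <- expand.grid(fams, stringsAsFactors = FALSE)
  f <- vapply(seq_len(nrow(grid)), function(i) {
    neighborhood_score(paste(unlist(grid[i, ]), collapse = ""), mb, cub, alpha)$f
  }, numeric(1))
  data.frame(seq = apply(grid, 1, paste, collapse = ""), f = f,
             stringsAsFactors = FALSE)
}

# does a motif consensus lie within Hamming distance 1 of the planted IUPAC
# motif, over every ungapped alignment offset and either orientation?
consensus_matches_plant <- function(consensus, plant) {
  ham_le1 <- function(short, long) {
    ks <- nchar(short); kl <- nchar(long)
    if (ks > kl) { tmp <- short; short <- long; long <- tmp
                   ks <- nchar(short); kl <- nchar(long) }
    for (off in 0:(kl - ks)) {
      seg <- substr(long, off + 1, off + ks)
      mism <- sum(!iupac_match(strsplit(short, "")[[1]],
                               strsplit(seg, "")[[1]]))
      if (mism <= 1) return(TRUE)
    }
    FALSE
  }
  ham_le1(consensus, plant) || ham_le1(revcomp(consensus), plant)
}
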