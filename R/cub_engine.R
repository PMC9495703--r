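# Per-codon weights (CAI, tAI, TDR), geometric-mean gene scores and
# per-proteome score distributions.

#' Codon weight table constructor
#' @param w named numeric vector over the 61 sense codons, values in (0,1]
#' @param scheme "CAI", "tAI" or "TDR"
#' @param host_id organism the table describes
#' @return object of class `codon_weight_table`
#' @export
codon_weight_table <- function(w, scheme = c("CAI", "tAI", "TDR"),
                               host_id = NA_character_) {
  scheme <- match.arg(scheme)
  sc <- sense_codons()
  if (!all(sc %in% names(w))) stop("weight table must cover all 61 sense codons")
  w <- w[sc]
  if (any(w <= 0)) stop("codon weights must be positive (logs are taken)")
  if (abs(max(w) - 1) > 1e-9) stop("weights must be normalized to max 1")
  structure(list(scheme = scheme, host_id = host_id, w = w),
            class = "codon_weight_table")
}

#' Count sense codons of a CDS
#'
#' The terminal stop codon (if any) is excluded; codons containing ambiguous
#' bases are skipped.
#' @param cds DNA string, length divisible by 3
#' @return named integer vector over the 61 sense codons
#' @export
codon_counts <- function(cds) {
  cod <- split_codons(cds)
  n <- length(cod)
  if (n && cod[n] %in% stop_codons()) cod <- cod[-n]
  cod <- cod[!grepl("[^ACGT]", cod)]
  cod <- cod[!cod %in% stop_codons()]
  counts <- table(factor(cod, levels = sense_codons()))
  setNames(as.integer(counts), names(counts))
}

#' CAI weights from a highly expressed reference set
#'
#' Within each synonymous family the most frequent codon gets weight 1 and
#' every other codon its count divided by the family maximum (the relative
#' synonymous codon usage ratio). Codons never observed in the reference set
#' receive `pseudo_weight` so that the geometric-mean gene score stays
#' defined.
#'
#' @param reference_genes data.frame of gene records (or character vector of
#'   CDS strings)
#' @param pseudo_weight weight assigned to unobserved codons (default 0.5)
#' @param host_id organism label for the table
#' @return a `codon_weight_table` with scheme "CAI"
#' @export
cai_weights <- function(reference_genes, pseudo_weight = 0.5,
                        host_id = NA_character_) {
  seqs <- if (is.data.frame(reference_genes)) reference_genes$cds_seq
          else reference_genes
  if (!length(seqs)) stop("empty reference set")
  counts <- Reduce(`+`, lapply(seqs, codon_counts))
  w <- setNames(numeric(length(counts)), names(counts))
  for (aa in amino_acids()) {
    fam <- synonymous_codons(aa)
    mx <- max(counts[fam])
    if (mx == 0L) {
      w[fam] <- pseudo_weight
    } else {
      w[fam] <- counts[fam] / mx
      w[fam][counts[fam] == 0L] <- pseudo_weight
    }
  }
  codon_weight_table(w, "CAI", host_id)
}

# ---- tAI ---------------------------------------------------------------

.default_s_values <- function() {
  path <- system.file("extdata", "wobble_s_values.tsv", package = "selectigene")
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  setNames(tab$s, tab$class)
}

#' Build a tRNA profile (codon-anticodon pairing plus interaction strengths)
#'
#' The default pairing follows the dos Reis convention: each codon is read by
#' its Watson-Crick anticodon (s = 0) plus one wobble anticodon - G:U wobble
#' for U-ending codons, inosine for C- and A-ending codons, U:G wobble for
#' G-ending codons - with special cases for ATA (lysidine-modified CAT), ATG
#' and TGG.
#'
#' @param tgcn named integer vector, anticodon -> gene copy number
#' @param s named numeric vector of interaction strengths per wobble class
#'   (defaults read from the package's s-value table)
#' @param pairing optional data.frame(codon, anticodon, class) overriding the
#'   default pairing rules
#' @return object of class `trna_profile`
#' @export
trna_profile <- function(tgcn, s = NULL, pairing = NULL) {
  if (all(tgcn <= 0)) stop("all tGCN are zero")
  if (is.null(s)) s <- .default_s_values()
  if (any(s < 0 | s > 1)) stop("s values must lie in [0,1]")
  if (is.null(pairing)) {
    rows <- list()
    add <- function(codon, anticodon, class)
      rows[[length(rows) + 1L]] <<- data.frame(codon = codon,
                                               anticodon = anticodon,
                                               class = class,
                                               stringsAsFactors = FALSE)
    for (codon in sense_codons()) {
      if (codon == "ATG") { add(codon, "CAT", "WC"); next }
      if (codon == "ATA") { add(codon, "CAT", "LYS"); next }
      if (codon == "TGG") { add(codon, "CCA", "WC"); next }
      third <- substr(codon, 3L, 3L)
      box <- substr(codon, 1L, 2L)
      add(codon, revcomp(codon), "WC")
      wob <- switch(third,
        T = list(paste0(box, "C"), "GU"),
        C = list(paste0(box, "T"), "IC"),
        A = list(paste0(box, "T"), "IA"),
        G = list(paste0(box, "A"), "UG"))
      partner <- wob[[1]]
      # the wobble anticodon must itself decode a sense codon of the same aa
      if (translate_cds(partner) == translate_cds(codon))
        add(codon, revcomp(partner), wob[[2]])
    }
    pairing <- do.call(rbind, rows)
  }
  structure(list(tgcn = tgcn, s = s, pairing = pairing),
            class = "trna_profile")
}

#' tAI weights from a tRNA profile
#'
#' Raw weight of codon i is the sum over its recognizing anticodons j of
#' (1 - s_ij) * tGCN_ij; weights are divided by the maximum, and codons with
#' raw weight 0 receive the geometric mean of the nonzero normalized
#' weights.
#'
#' @param profile a `trna_profile`
#' @param host_id organism label
#' @return a `codon_weight_table` with scheme "tAI"
#' @export
tai_weights <- function(profile, host_id = NA_character_) {
  tgcn <- profile$tgcn
  raw <- setNames(numeric(61), sense_codons())
  for (i in seq_len(nrow(profile$pairing))) {
    p <- profile$pairing[i, ]
    g <- tgcn[[p$anticodon]]
    if (is.null(g) || is.na(g)) g <- 0
    sval <- profile$s[[p$class]]
    if (is.null(sval)) stop("unknown wobble class: ", p$class)
    raw[p$codon] <- raw[p$codon] + (1 - sval) * g
  }
  if (all(raw == 0)) stop("all tGCN are zero")
  w <- raw / max(raw)
  nz <- w[w > 0]
  w[w == 0] <- exp(mean(log(nz)))
  codon_weight_table(w, "tAI", host_id)
}

#' TDR weights from per-codon ribosome footprint densities
#'
#' The typical decoding rate of a codon is the inverse of its mean normalized
#' footprint density; weights are rates divided by the maximum rate. Codons
#' missing from the table receive the median rate before normalization.
#'
#' @param ribo_density named numeric vector, codon -> positive mean density
#' @param host_id organism label
#' @return a `codon_weight_table` with scheme "TDR"
#' @export
tdr_weights <- function(ribo_density, host_id = NA_character_) {
  ribo_density <- ribo_density[!is.na(ribo_density)]
  if (!length(ribo_density)) stop("all densities missing")
  if (any(ribo_density <= 0)) stop("densities must be positive")
  rate <- 1 / ribo_density
  full <- setNames(rep(stats::median(rate), 61), sense_codons())
  keep <- intersect(names(rate), sense_codons())
  full[keep] <- rate[keep]
  codon_weight_table(full / max(full), "TDR", host_id)
}

# ---- gene and proteome scores ------------------------------------------

#' Geometric-mean CUB score of a gene
#'
#' score = exp(mean of log codon weights) over the gene's sense codons; the
#' terminal stop codon and ambiguous codons are excluded.
#'
#' @param cds DNA string, length divisible by 3
#' @param w a `codon_weight_table`
#' @return list with `scheme` and `value` in (0, 1]
#' @export
gene_score <- function(cds, w) {
  counts <- codon_counts(cds)
  L <- sum(counts)
  if (L == 0L) stop("gene has no scoreable codons")
  value <- exp(sum(counts * log(w$w)) / L)
  list(scheme = w$scheme, value = value)
}

# Vectorized scoring used by the optimizer: log-weight dot product on counts.
.gene_scores <- function(seqs, w) {
  vapply(seqs, function(s) gene_score(s, w)$value, numeric(1))
}

#' Proteome-wide distribution of gene CUB scores
#'
#' @param host a `host_genome` with at least two scoreable genes
#' @param scheme label recorded on the profile
#' @param w a `codon_weight_table` for this host
#' @return object of class `proteome_profile` with `mu` (mean), `sigma`
#'   (sample SD) and the per-gene scores
#' @export
proteome_profile <- function(host, scheme = w$scheme, w) {
  seqs <- host$genes$cds_seq
  seqs <- seqs[!grepl("[^ACGT]", seqs)]
  if (length(seqs) < 2L) stop("proteome profile needs >= 2 genes")
  scores <- .gene_scores(seqs, w)
  sigma <- stats::sd(scores)
  if (sigma == 0) stop("degenerate proteome: zero score variance")
  structure(list(host_id = host$host_id, scheme = scheme,
                 mu = mean(scores), sigma = sigma,
                 scores = data.frame(gene_id = host$genes$gene_id[
                   !grepl("[^ACGT]", host$genes$cds_seq)],
                   score = scores, stringsAsFactors = FALSE)),
            class = "proteome_profile")
}

#' Write a codon weight table to TSV
#' @param w a `codon_weight_table`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_weights_tsv <- function(w, path) {
  utils::write.table(data.frame(codon = names(w$w), weight = unname(w$w)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build per-host weight tables and proteome profiles for a microbiome
#'
#' Convenience wrapper used by the optimizer and pipeline: for every host it
#' derives the weight table under `scheme` (CAI from the reference gene set,
#' tAI from the host's tGCN table, TDR from its density table) and the
#' proteome profile.
#'
#' @param mb a `microbiome`
#' @param scheme "CAI", "tAI" or "TDR"
#' @param reference_fraction fraction for [select_reference_genes()] (CAI)
#' @return list with `weights` and `profiles`, both named by host
#' @export
microbiome_cub <- function(mb, scheme = c("CAI", "tAI", "TDR"),
                           reference_fraction = 1 / 3) {
  scheme <- match.arg(scheme)
  weights <- lapply(mb$hosts, function(h) {
    switch(scheme,
      CAI = cai_weights(select_reference_genes(h, reference_fraction),
                        host_id = h$host_id),
      tAI = {
        if (is.null(h$tgcn)) stop("host ", h$host_id, " has no tGCN table")
        tai_weights(trna_profile(h$tgcn), host_id = h$host_id)
      },
      TDR = {
        if (is.null(h$tdr)) stop("host ", h$host_id, " has no TDR table")
        tdr_weights(h$tdr, host_id = h$host_id)
      })
  })
  profiles <- lapply(names(mb$hosts), function(id)
    proteome_profile(mb$hosts[[id]], scheme, weights[[id]]))
  names(profiles) <- names(mb$hosts)
  list(weights = weights, profiles = profiles)
}
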