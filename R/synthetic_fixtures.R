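# Seeded synthetic microbiomes with controllable codon-bias contrast,
# planted promoter motifs, tGCN tables and enzyme repertoires, so that every
# module is testable without genome downloads. All randomness flows through
# the mandatory seed; the caller's RNG stream is left untouched.

# common recognition sites seeding the fixture enzyme pool
.common_sites <- c("GAATTC", "GGATCC", "AAGCTT", "GCGGCCGC", "CTGCAG",
                   "GTCGAC", "TCTAGA", "CCCGGG", "GAGCTC", "CATATG",
                   "GGTACC", "AGATCT", "ACTAGT", "CCWWGG", "GRGCYC",
                   "GGWCC", "CTNAG", "GACNNNGTC")

#' Specify a synthetic microbiome fixture
#'
#' Defaults reflect a small soil-like study community: 3 wanted + 3 unwanted
#' hosts of 50 genes x 200 codons, a strong but not absolute codon-bias
#' contrast (0.8), and enzyme repertoires averaging 4.6 sites per host (the
#' REBASE-wide mean).
#'
#' @param n_wanted,n_unwanted host counts
#' @param genes_per_host genes per host
#' @param gene_length_codons protein length of each fixture gene
#' @param bias_strength contrast between wanted and unwanted codon
#'   preferences, in [0, 1]
#' @param planted_motif optional IUPAC motif planted into wanted-host
#'   promoters
#' @param motif_fraction fraction of top-tertile wanted promoters carrying
#'   the plant
#' @param enzyme_pool_size size of the shared recognition-site pool; the
#'   default (120) keeps repertoire overlap low across 10-50-host samples,
#'   mirroring the diversity of the restriction-enzyme database (thousands
#'   of sites over thousands of organisms)
#' @param sites_per_host mean (Poisson) repertoire size per host
#' @param seed mandatory RNG seed
#' @return list of class `fixture_spec`
#' @export
fixture_spec <- function(n_wanted = 3L, n_unwanted = 3L, genes_per_host = 50L,
                         gene_length_codons = 200L, bias_strength = 0.8,
                         planted_motif = NULL, motif_fraction = 0.7,
                         enzyme_pool_size = 120L, sites_per_host = 4.6,
                         seed) {
  if (missing(seed)) stop("fixture seed is mandatory")
  stopifnot(n_wanted >= 1L, n_unwanted >= 1L, genes_per_host >= 1L,
            gene_length_codons >= 1L, bias_strength >= 0, bias_strength <= 1)
  structure(list(n_wanted = n_wanted, n_unwanted = n_unwanted,
                 genes_per_host = genes_per_host,
                 gene_length_codons = gene_length_codons,
                 bias_strength = bias_strength, planted_motif = planted_motif,
                 motif_fraction = motif_fraction,
                 enzyme_pool_size = enzyme_pool_size,
                 sites_per_host = sites_per_host, seed = as.integer(seed)),
            class = "fixture_spec")
}

# per-family codon preference vectors for the two roles: a shared baseline
# blended with role-specific skew by bias_strength
.role_prefs <- function(bias_strength) {
  prefs_A <- setNames(numeric(61), sense_codons())
  prefs_B <- prefs_A
  for (a in amino_acids()) {
    fam <- synonymous_codons(a)
    d <- length(fam)
    base <- .rdirichlet(rep(1, d))
    skewA <- .rdirichlet(rep(0.3, d))
    skewB <- .rdirichlet(rep(0.3, d))
    prefs_A[fam] <- (1 - bias_strength) * base + bias_strength * skewA
    prefs_B[fam] <- (1 - bias_strength) * base + bias_strength * skewB
  }
  list(A = prefs_A, B = prefs_B)
}

# host-level jitter around a role preference vector (per family Dirichlet
# around the role vector, concentration 60)
.host_pref <- function(role_pref) {
  out <- role_pref
  for (a in amino_acids()) {
    fam <- synonymous_codons(a)
    if (length(fam) == 1L) { out[fam] <- 1; next }
    out[fam] <- .rdirichlet(role_pref[fam] * 60 + 0.05)
  }
  out
}

.random_dna <- function(n, p = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# back-translate a random protein under a codon preference vector
.sample_gene <- function(len_codons, pref) {
  aa <- c("M", sample(setdiff(amino_acids(), "M"), len_codons - 1L,
                      replace = TRUE))
  cod <- vapply(aa, function(x) {
    fam <- synonymous_codons(x)
    if (length(fam) == 1L) fam else sample(fam, 1L, prob = pref[fam])
  }, character(1))
  paste(c(cod, sample(c("TAA", "TGA", "TAG"), 1L)), collapse = "")
}

.build_host <- function(host_id, role, pref, spec, pool) {
  n <- spec$genes_per_host
  expr <- stats::rlnorm(n, meanlog = 2, sdlog = 1)
  genes_seq <- vapply(seq_len(n), function(i)
    .sample_gene(spec$gene_length_codons, pref), character(1))
  # plant the motif into top-tertile promoters of wanted hosts
  top_cut <- stats::quantile(expr, 2 / 3, type = 7)
  promoters <- vapply(seq_len(n), function(i) {
    p <- .random_dna(200L)
    if (!is.null(spec$planted_motif) && role == "wanted" &&
        expr[i] > top_cut - 1e-12 &&
        stats::runif(1) < spec$motif_fraction) {
      inst <- .iupac_realize(spec$planted_motif)
      off <- sample.int(200L - nchar(inst) + 1L, 1L)
      substr(p, off, off + nchar(inst) - 1L) <- inst
    }
    p
  }, character(1))
  # assemble one contig: [spacer][promoter][gene] per gene, all + strand
  contig <- ""
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    spacer <- .random_dna(sample(80:150, 1L))
    contig <- paste0(contig, spacer, promoters[i])
    start <- nchar(contig)
    contig <- paste0(contig, genes_seq[i])
    rows[[i]] <- gene_record(sprintf("%s_g%03d", host_id, i), genes_seq[i],
                             "+", paste0(host_id, "_c1"), start,
                             nchar(contig), expression = expr[i])
  }
  contig <- paste0(contig, .random_dna(100L))
  genes <- do.call(rbind, rows)
  # tGCN consistent with the preference vector (Watson-Crick anticodons)
  tgcn <- setNames(integer(0), character(0))
  for (cdn in sense_codons()) {
    fam <- synonymous_codons(.genetic_code()[[cdn]])
    rel <- pref[cdn] / max(pref[fam])
    tgcn[revcomp(cdn)] <- as.integer(round(rel * 8))
  }
  # TDR densities inversely proportional to preference
  rel_pref <- vapply(sense_codons(), function(cdn) {
    fam <- synonymous_codons(.genetic_code()[[cdn]])
    pref[cdn] / max(pref[fam])
  }, numeric(1))
  tdr <- 1 / (rel_pref + 0.05)
  k <- max(1L, stats::rpois(1L, spec$sites_per_host))
  enzymes <- sample(pool, min(k, length(pool)))
  host <- host_genome(host_id, role, genes,
                      contigs = setNames(contig, paste0(host_id, "_c1")),
                      tgcn = tgcn, tdr = tdr, enzymes = enzymes)
  host$pref <- pref  # generating codon preferences (fixture ground truth)
  host$rrna_16s <- NULL  # filled by the caller (shared ancestry)
  host
}

#' Generate a synthetic microbiome
#'
#' Wanted and unwanted hosts draw codons from role preference vectors whose
#' separation scales with `bias_strength`; each host carries one contig of
#' genes with 200-bp promoters and intergenic spacers, an expression table,
#' a tGCN table consistent with its codon preferences, TDR densities, an
#' enzyme repertoire sampled from a shared pool, and a 16S sequence mutated
#' from a common ancestor. Fully reproducible from `spec$seed`.
#'
#' @param spec a [fixture_spec()]
#' @return a `microbiome`
#' @export
make_microbiome <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  .with_seed(spec$seed, {
    prefs <- .role_prefs(spec$bias_strength)
    pool <- unique(c(.common_sites[seq_len(min(length(.common_sites),
                                               spec$enzyme_pool_size))],
                     replicate(max(0L, spec$enzyme_pool_size -
                                     length(.common_sites)),
                               .random_dna(6L))))
    hosts <- list()
    for (i in seq_len(spec$n_wanted))
      hosts[[length(hosts) + 1L]] <-
        .build_host(sprintf("wantedH%02d", i), "wanted",
                    .host_pref(prefs$A), spec, pool)
    for (i in seq_len(spec$n_unwanted))
      hosts[[length(hosts) + 1L]] <-
        .build_host(sprintf("unwantedH%02d", i), "unwanted",
                    .host_pref(prefs$B), spec, pool)
    ancestor <- .random_dna(400L)
    hosts <- lapply(hosts, function(h) {
      h$rrna_16s <- .mutate_dna(ancestor, 0.03)
      h
    })
    microbiome(hosts)
  })
}

.mutate_dna <- function(seq, rate) {
  chars <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  paste(chars, collapse = "")
}

#' Generate a random gene of interest
#'
#' Random protein (Met start) back-translated with uniform codon choice; the
#' returned CDS carries a terminal stop and translates cleanly.
#'
#' @param length_codons protein length in codons (>= 10)
#' @param seed RNG seed
#' @return one-row gene record data.frame
#' @export
make_goi <- function(length_codons = 100L, seed = 1L) {
  stopifnot(length_codons >= 10L)
  .with_seed(seed, {
    aa <- c("M", sample(setdiff(amino_acids(), "M"), length_codons - 1L,
                        replace = TRUE))
    cod <- vapply(aa, function(x) {
      fam <- synonymous_codons(x)
      if (length(fam) == 1L) fam else sample(fam, 1L)
    }, character(1))
    gene_record("goi", paste(c(cod, "TAA"), collapse = ""))
  })
}

#' Write a fixture microbiome as FASTA + GFF3 + TSV files
#'
#' One subdirectory per host with `genome.fasta`, `annotation.gff3`,
#' `expression.tsv`, `tgcn.tsv` and `enzymes.txt`, so fixtures exercise the
#' real readers.
#'
#' @param mb a `microbiome` from [make_microbiome()]
#' @param dir output directory (created)
#' @return `dir`, invisibly
#' @export
write_microbiome_fixture <- function(mb, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (h in mb$hosts) {
    hd <- file.path(dir, h$host_id)
    dir.create(hd, showWarnings = FALSE)
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(h$contigs), file.path(hd, "genome.fasta"))
    g <- h$genes
    gff <- c("##gff-version 3",
             sprintf("%s\tselectigene\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
                     g$contig_id, g$start + 1L, g$end, g$strand, g$gene_id))
    writeLines(gff, file.path(hd, "annotation.gff3"))
    utils::write.table(data.frame(g$gene_id, g$expression),
                       file.path(hd, "expression.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    if (!is.null(h$tgcn))
      utils::write.table(data.frame(names(h$tgcn), unname(h$tgcn)),
                         file.path(hd, "tgcn.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE, col.names = FALSE)
    writeLines(h$enzymes, file.path(hd, "enzymes.txt"))
  }
  invisible(dir)
}
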