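# Data model and I/O: genomes, genes, promoter/intergenic regions and the
# wanted/unwanted partition. All coordinates are 0-based half-open internally;
# GFF3 (1-based inclusive) is converted on read.

#' Construct a gene record
#'
#' @param gene_id gene identifier
#' @param cds_seq coding sequence in coding orientation (A/C/G/T, length
#'   divisible by 3)
#' @param strand "+" or "-"
#' @param contig_id contig the gene lies on
#' @param start,end 0-based half-open genomic coordinates
#' @param expression optional non-negative expression value
#' @param product optional product annotation (used for reference-gene
#'   selection by keyword when no expression data exist)
#' @return one-row data.frame
#' @export
gene_record <- function(gene_id, cds_seq, strand = "+", contig_id = "contig1",
                        start = 0L, end = nchar(cds_seq), expression = NA_real_,
                        product = NA_character_) {
  cds_seq <- toupper(cds_seq)
  stopifnot(nchar(cds_seq) %% 3L == 0L, strand %in% c("+", "-"))
  data.frame(gene_id = gene_id, cds_seq = cds_seq, strand = strand,
             contig_id = contig_id, start = as.integer(start),
             end = as.integer(end), expression = as.numeric(expression),
             product = product, stringsAsFactors = FALSE)
}

#' Construct a host genome
#'
#' @param host_id organism identifier
#' @param role "wanted" or "unwanted"
#' @param genes data.frame of gene records (see [gene_record()])
#' @param contigs named character vector of contig sequences (may be empty
#'   when only CDS-level data are available)
#' @param tgcn optional named integer vector, anticodon -> tRNA gene copy
#'   number
#' @param tdr optional named numeric vector, codon -> typical decoding rate
#'   density
#' @param enzymes character vector of IUPAC recognition sites for the host's
#'   restriction enzymes
#' @param rrna_16s optional 16S rRNA sequence
#' @return object of class `host_genome`
#' @export
host_genome <- function(host_id, role = c("wanted", "unwanted"),
                        genes, contigs = character(0), tgcn = NULL,
                        tdr = NULL, enzymes = character(0), rrna_16s = NULL) {
  role <- match.arg(role)
  if (!is.null(tgcn) && any(tgcn < 0)) stop("tGCN values must be >= 0")
  if (length(enzymes) && !all(vapply(enzymes, is_iupac, logical(1))))
    stop("enzyme sites must use the IUPAC alphabet")
  structure(list(host_id = host_id, role = role, genes = genes,
                 contigs = contigs, regions = NULL, tgcn = tgcn, tdr = tdr,
                 enzymes = toupper(enzymes), rrna_16s = rrna_16s),
            class = "host_genome")
}

#' @export
print.host_genome <- function(x, ...) {
  cat(sprintf("<host_genome> %s (%s): %d genes, %d contigs, %d enzyme sites\n",
              x$host_id, x$role, nrow(x$genes), length(x$contigs),
              length(x$enzymes)))
  invisible(x)
}

#' Construct a microbiome from host genomes
#'
#' @param hosts list of `host_genome` objects
#' @param require_both require at least one wanted and one unwanted host
#'   (TRUE for design operations)
#' @return object of class `microbiome` with `hosts`, `A` (wanted ids) and
#'   `B` (unwanted ids)
#' @export
microbiome <- function(hosts, require_both = TRUE) {
  ids <- vapply(hosts, `[[`, character(1), "host_id")
  if (anyDuplicated(ids)) stop("duplicate host ids: role assigned more than once")
  names(hosts) <- ids
  roles <- vapply(hosts, `[[`, character(1), "role")
  A <- ids[roles == "wanted"]
  B <- ids[roles == "unwanted"]
  if (require_both && (length(A) < 1L || length(B) < 1L))
    stop("design operations need at least one wanted and one unwanted host")
  structure(list(hosts = hosts, A = A, B = B), class = "microbiome")
}

#' @export
print.microbiome <- function(x, ...) {
  cat(sprintf("<microbiome> %d wanted + %d unwanted hosts\n",
              length(x$A), length(x$B)))
  invisible(x)
}

# ---- loading -----------------------------------------------------------

#' Load one host genome from FASTA+GFF3 or GenBank
#'
#' CDS features are extracted in coding orientation (reverse-complemented for
#' minus-strand genes). CDS whose length is not a multiple of 3, or whose
#' translation has an internal stop, are skipped with a warning.
#'
#' @param genome_path FASTA (with `annotation_path` GFF3) or GenBank flat file
#' @param annotation_path GFF3 annotation; NULL when `genome_path` is GenBank
#' @param role "wanted" or "unwanted"
#' @param expression_path optional TSV `gene_id<TAB>value`
#' @param tgcn_path optional TSV `anticodon<TAB>copy_number`
#' @param host_id host identifier; defaults to the file base name
#' @return a `host_genome`
#' @export
load_host <- function(genome_path, annotation_path = NULL,
                      role = c("wanted", "unwanted"),
                      expression_path = NULL, tgcn_path = NULL,
                      host_id = NULL) {
  role <- match.arg(role)
  if (is.null(host_id))
    host_id <- sub("\\.[^.]+$", "", basename(genome_path))
  if (is.null(annotation_path)) {
    parsed <- .read_genbank(genome_path)
    contigs <- parsed$contigs
    feats <- parsed$cds
  } else {
    seqs <- Biostrings::readDNAStringSet(genome_path)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    contigs <- setNames(as.character(seqs), names(seqs))
    gff <- rtracklayer::import(annotation_path)
    gff <- gff[gff$type == "CDS"]
    if (length(gff) == 0L) stop("annotation has no CDS features: ", annotation_path)
    feats <- data.frame(
      contig_id = as.character(GenomicRanges::seqnames(gff)),
      start = GenomicRanges::start(gff) - 1L,   # 1-based inclusive -> 0-based half-open
      end = GenomicRanges::end(gff),
      strand = as.character(GenomicRanges::strand(gff)),
      gene_id = if (!is.null(gff$ID)) as.character(gff$ID) else
        paste0("cds", seq_along(gff)),
      product = if (!is.null(gff$product)) as.character(gff$product) else
        NA_character_,
      stringsAsFactors = FALSE)
  }
  if (nrow(feats) == 0L) stop("no CDS features found in ", genome_path)

  genes <- do.call(rbind, lapply(seq_len(nrow(feats)), function(i) {
    f <- feats[i, ]
    ctg <- contigs[[f$contig_id]]
    if (is.null(ctg)) {
      warning("CDS on unknown contig ", f$contig_id, "; skipped")
      return(NULL)
    }
    seq <- substr(ctg, f$start + 1L, f$end)
    if (f$strand == "-") seq <- revcomp(seq)
    if (nchar(seq) %% 3L != 0L) {
      warning("CDS ", f$gene_id, " length ", nchar(seq),
              " not divisible by 3; skipped")
      return(NULL)
    }
    if (grepl("[^ACGT]", seq)) {
      # genes with ambiguous bases are retained for region extraction but the
      # CUB engine excludes them from counting
      return(gene_record(f$gene_id, seq, f$strand, f$contig_id, f$start, f$end,
                         product = f$product))
    }
    if (!clean_translation(seq)) {
      warning("CDS ", f$gene_id, " has an internal stop; skipped")
      return(NULL)
    }
    gene_record(f$gene_id, seq, f$strand, f$contig_id, f$start, f$end,
                product = f$product)
  }))
  if (is.null(genes) || nrow(genes) == 0L)
    stop("no usable CDS records in ", genome_path)

  if (!is.null(expression_path)) {
    expr <- read_expression_tsv(expression_path)
    genes$expression <- unname(expr[genes$gene_id])
  }
  tgcn <- if (!is.null(tgcn_path)) read_tgcn_tsv(tgcn_path) else NULL
  host_genome(host_id, role, genes, contigs = contigs, tgcn = tgcn)
}

# Minimal GenBank flat-file reader: LOCUS records, CDS features with simple
# `start..end` or `complement(start..end)` locations, ORIGIN sequence.
.read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus_idx <- grep("^LOCUS", lines)
  if (!length(locus_idx)) stop("not a GenBank file: ", path)
  bounds <- c(locus_idx, length(lines) + 1L)
  contigs <- character(0)
  cds <- list()
  for (k in seq_along(locus_idx)) {
    block <- lines[bounds[k]:(bounds[k + 1L] - 1L)]
    ctg_id <- strsplit(trimws(sub("^LOCUS\\s+", "", block[1])), "\\s+")[[1]][1]
    ori <- grep("^ORIGIN", block)
    seq <- ""
    if (length(ori)) {
      body <- block[(ori[1] + 1L):length(block)]
      body <- body[!grepl("^//", body)]
      seq <- toupper(gsub("[^A-Za-z]", "", paste(body, collapse = "")))
    }
    contigs[ctg_id] <- seq
    feat_lines <- grep("^\\s{5}CDS\\s+", block, value = TRUE)
    for (fl in feat_lines) {
      loc <- trimws(sub("^\\s{5}CDS\\s+", "", fl))
      strand <- "+"
      if (grepl("^complement\\(", loc)) {
        strand <- "-"
        loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
      }
      if (grepl("join", loc)) {
        warning("joined CDS location skipped: ", loc)
        next
      }
      m <- regmatches(loc, regexec("(\\d+)\\.\\.(\\d+)", loc))[[1]]
      if (length(m) != 3L) next
      cds[[length(cds) + 1L]] <- data.frame(
        contig_id = ctg_id, start = as.integer(m[2]) - 1L,
        end = as.integer(m[3]), strand = strand,
        gene_id = paste0(ctg_id, "_cds", length(cds) + 1L),
        product = NA_character_, stringsAsFactors = FALSE)
    }
  }
  list(contigs = contigs, cds = if (length(cds)) do.call(rbind, cds)
       else data.frame())
}

#' Read an expression TSV (gene_id<TAB>value)
#' @param path TSV path
#' @return named numeric vector
#' @export
read_expression_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  setNames(as.numeric(tab[[2]]), tab[[1]])
}

#' Read a tRNA gene-copy-number TSV (anticodon<TAB>copy_number)
#' @param path TSV path
#' @return named integer vector
#' @export
read_tgcn_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  setNames(as.integer(tab[[2]]), toupper(tab[[1]]))
}

#' Write a host's CDS set to FASTA
#' @param host a `host_genome`
#' @param path output FASTA path
#' @return `path`, invisibly
#' @export
write_cds_fasta <- function(host, path) {
  set <- Biostrings::DNAStringSet(setNames(host$genes$cds_seq,
                                           host$genes$gene_id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# ---- regions -----------------------------------------------------------

#' Extract promoter and intergenic regions
#'
#' Promoters are the up-to-200 bp immediately 5' of each ORF on its own
#' strand, truncated at the contig edge or at an upstream feature; promoters
#' shorter than `min_promoter` are dropped with a warning. Intergenic
#' sequence is all same-strand sequence belonging to neither an ORF nor a
#' promoter, split at feature boundaries.
#'
#' @param host a `host_genome` with contig sequences and gene coordinates
#' @param promoter_len promoter window size upstream of the start (default
#'   200 bp)
#' @param min_promoter minimum retained promoter length (default 30 bp)
#' @return list with `promoters` (data.frame gene_id, seq) and `intergenic`
#'   (character vector); also stored on the returned host by
#'   [with_regions()]
#' @export
extract_regions <- function(host, promoter_len = 200L, min_promoter = 30L) {
  if (!length(host$contigs)) stop("host has no contig sequences")
  proms <- list(); inter <- character(0)
  for (ctg_id in names(host$contigs)) {
    ctg <- host$contigs[[ctg_id]]
    clen <- nchar(ctg)
    for (strand in c("+", "-")) {
      g <- host$genes[host$genes$contig_id == ctg_id &
                        host$genes$strand == strand, , drop = FALSE]
      if (!nrow(g)) next
      orf_ir <- IRanges::IRanges(g$start + 1L, g$end)  # 1-based inclusive
      taken <- IRanges::reduce(orf_ir)
      for (i in order(g$start)) {
        if (strand == "+") {
          want <- IRanges::IRanges(max(1L, g$start[i] - promoter_len + 1L),
                                   g$start[i])
          if (g$start[i] == 0L) {
            warning("gene ", g$gene_id[i], " at contig start: promoter omitted")
            next
          }
        } else {
          want <- IRanges::IRanges(g$end[i] + 1L,
                                   min(clen, g$end[i] + promoter_len))
          if (g$end[i] >= clen) {
            warning("gene ", g$gene_id[i], " at contig end: promoter omitted")
            next
          }
        }
        free <- IRanges::setdiff(want, taken)
        if (!length(free)) next
        # keep the fragment adjacent to the gene start
        free <- if (strand == "+") free[length(free)] else free[1]
        if (IRanges::width(free) < min_promoter) {
          warning("promoter of ", g$gene_id[i], " shorter than ",
                  min_promoter, " bp; dropped")
          next
        }
        seq <- substr(ctg, IRanges::start(free), IRanges::end(free))
        if (strand == "-") seq <- revcomp(seq)
        proms[[length(proms) + 1L]] <- data.frame(
          gene_id = g$gene_id[i], seq = seq, stringsAsFactors = FALSE)
        taken <- IRanges::reduce(c(taken, free))
      }
      ig <- IRanges::setdiff(IRanges::IRanges(1L, clen), taken)
      for (j in seq_along(ig)) {
        seq <- substr(ctg, IRanges::start(ig)[j], IRanges::end(ig)[j])
        if (strand == "-") seq <- revcomp(seq)
        inter <- c(inter, seq)
      }
    }
  }
  promoters <- if (length(proms)) do.call(rbind, proms) else
    data.frame(gene_id = character(0), seq = character(0))
  list(promoters = promoters, intergenic = inter)
}

#' Attach extracted regions to a host
#' @param host a `host_genome`
#' @param ... passed to [extract_regions()]
#' @return the host with `$regions` filled
#' @export
with_regions <- function(host, ...) {
  host$regions <- extract_regions(host, ...)
  host
}

# ---- reference genes ---------------------------------------------------

#' Select the highly expressed reference gene set
#'
#' Genes are ranked by measured expression when available; otherwise by CAI
#' against a reference set of genes whose product annotation matches
#' /ribosomal protein/ (falling back to CAI against the whole proteome when
#' none is annotated). Ties break on gene_id.
#'
#' @param host a `host_genome`
#' @param fraction top fraction to keep, in (0, 1]
#' @return data.frame of the top `ceiling(fraction * n)` gene records
#' @export
select_reference_genes <- function(host, fraction = 1 / 3) {
  stopifnot(fraction > 0, fraction <= 1)
  genes <- host$genes
  if (!nrow(genes)) stop("host has no genes")
  expr <- genes$expression
  if (all(is.na(expr))) {
    ribo <- genes[grepl("ribosomal protein", genes$product,
                        ignore.case = TRUE) %in% TRUE, , drop = FALSE]
    ref <- if (nrow(ribo) > 0L) ribo else genes
    w <- cai_weights(ref)
    expr <- vapply(genes$cds_seq, function(s) gene_score(s, w)$value,
                   numeric(1))
  }
  ord <- order(-expr, genes$gene_id)
  n_keep <- ceiling(fraction * nrow(genes))
  genes[ord[seq_len(n_keep)], , drop = FALSE]
}
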