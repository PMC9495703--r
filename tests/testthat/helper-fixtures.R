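# Shared toy builders and cached fixture microbiomes (built once per test
# run; all generation is seeded).

.fx_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.fx_cache[[name]])) .fx_cache[[name]] <- builder()
  .fx_cache[[name]]
}

# a host whose proteome is given directly as CDS strings
toy_host <- function(id, role, seqs, expr = NULL, enzymes = character(0),
                     products = NA_character_) {
  genes <- do.call(rbind, lapply(seq_along(seqs), function(i)
    gene_record(sprintf("%s_g%02d", id, i), seqs[i],
                expression = if (is.null(expr)) NA_real_ else expr[i],
                product = if (length(products) == 1) products else products[i])))
  host_genome(id, role, genes, enzymes = enzymes)
}

# hand-made weight table: named weights, everything else filled with `fill`
toy_weights <- function(w_named, fill = 1, scheme = "CAI", host_id = "h") {
  w <- setNames(rep(fill, 61), sense_codons())
  w[names(w_named)] <- w_named
  codon_weight_table(w / max(w), scheme, host_id)
}

# minimal cub object for the optimizer from explicit weights and moments
toy_cub <- function(weights, mu, sigma) {
  profiles <- lapply(names(weights), function(id)
    list(host_id = id, mu = mu[[id]], sigma = sigma[[id]]))
  names(profiles) <- names(weights)
  list(weights = weights, profiles = profiles)
}

# a 1 wanted + 1 unwanted microbiome with strongly mirrored Glu/Lys/Phe
# biases, proteomes built from explicit genes (used by optimizer oracles)
toy_contrast_mb <- function() {
  cached("toy_contrast_mb", function() {
    gene_a1 <- paste(rep(c("GAA", "AAA", "TTT"), 10), collapse = "")
    gene_a2 <- paste(rep(c("GAA", "AAA", "TTC"), 9), collapse = "")
    gene_b1 <- paste(rep(c("GAG", "AAG", "TTC"), 10), collapse = "")
    gene_b2 <- paste(rep(c("GAG", "AAG", "TTT"), 9), collapse = "")
    microbiome(list(
      toy_host("hostA", "wanted", c(gene_a1, gene_a2), expr = c(2, 1)),
      toy_host("hostB", "unwanted", c(gene_b1, gene_b2), expr = c(2, 1))))
  })
}

default_fixture <- function() {
  cached("default_fixture", function()
    make_microbiome(fixture_spec(seed = 101L)))
}

motif_fixture <- function() {
  cached("motif_fixture", function()
    make_microbiome(fixture_spec(n_wanted = 1L, n_unwanted = 1L,
                                 genes_per_host = 40L,
                                 planted_motif = "TATAWTAT",
                                 motif_fraction = 0.7, seed = 202L)))
}

small_pool <- function() {
  cached("small_pool", function() {
    mb <- make_microbiome(fixture_spec(n_wanted = 25L, n_unwanted = 25L,
                                       genes_per_host = 8L,
                                       gene_length_codons = 60L,
                                       seed = 303L))
    mb$hosts
  })
}
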