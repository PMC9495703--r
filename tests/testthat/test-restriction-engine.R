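# Repertoire parsing, site classification, occurrence detection, insertion
# and removal under the synonymous-protein constraint.

test_that("repertoire parsing merges strains and drops unidentified records", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("Escherichia coli K12\tGAATTC",
               "Escherichia coli B\tGGATCC;GACNNNGTC",
               "Unidentified bacterium\tAAGCTT",
               "Bacillus subtilis 168\tGGTCTC(1/5)"), f)
  rep <- parse_rebase(f)
  expect_named(rep, c("Bacillus subtilis", "Escherichia coli"),
               ignore.order = TRUE)
  expect_setequal(rep[["Escherichia coli"]],
                  c("GAATTC", "GGATCC", "GACNNNGTC"))
  expect_equal(rep[["Bacillus subtilis"]], "GGTCTC")  # decoration stripped
  # malformed and short sites are skipped with warnings
  f2 <- tempfile()
  writeLines("Vibrio cholerae\tGAAXTC;ACG;CCAGG", f2)
  expect_warning(rep2 <- parse_rebase(f2), "malformed|shorter")
  expect_equal(rep2[["Vibrio cholerae"]], "CCAGG")
})

test_that("REBASE flat-format records parse to species repertoires", {
  f <- tempfile(fileext = ".txt")
  writeLines(c("<1>EcoRI", "<2>EcoRI", "<3>Escherichia coli RY13",
               "<5>GAATTC", "<8>refs", "",
               "<1>BamHI", "<3>Bacillus amyloliquefaciens H",
               "<5>GGATCC", "",
               "<1>EcoRV", "<3>Escherichia coli J62",
               "<5>GATATC", ""), f)
  rep <- parse_rebase(f)
  expect_setequal(rep[["Escherichia coli"]], c("GAATTC", "GATATC"))
  expect_equal(rep[["Bacillus amyloliquefaciens"]], "GGATCC")
})

test_that("site classification partitions by recognizing role", {
  mk <- function(id, role, sites)
    host_genome(id, role, gene_record(paste0(id, "_g"), "ATGGCTTAA"),
                enzymes = sites)
  hosts <- list(mk("w1", "wanted", c("GAATTC", "CCWWGG")),
                mk("w2", "wanted", c("AAGCTT")),
                mk("w3", "wanted", character(0)),
                mk("u1", "unwanted", c("GGATCC", "CCWWGG")),
                mk("u2", "unwanted", c("TCTAGA")),
                mk("u3", "unwanted", c("AAGCTT", "GAGCTC")))
  mb <- microbiome(hosts)
  cls <- classify_sites(mb)
  # brute-force set algebra
  W <- unique(c("GAATTC", "CCWWGG", "AAGCTT"))
  U <- unique(c("GGATCC", "CCWWGG", "TCTAGA", "AAGCTT", "GAGCTC"))
  expect_setequal(cls$wanted_only, setdiff(W, U))
  expect_setequal(cls$unwanted_only, setdiff(U, W))
  expect_setequal(cls$shared, intersect(W, U))
  expect_length(intersect(cls$wanted_only, cls$shared), 0L)
})

test_that("present occurrences honor IUPAC ambiguity and both strands", {
  orf <- paste0("GCT", "GAATTC", "GGACC", "T")  # 15 nt, 5 codons
  occ <- find_occurrences(orf, c("GAATTC", "GGWCC"))
  pres <- Filter(function(o) o$status == "present", occ)
  keys <- vapply(pres, function(o) paste(o$site, o$offset), character(1))
  expect_true("GAATTC 3" %in% keys)
  expect_true("GGWCC 9" %in% keys)   # W matches A
  # reverse-strand recognition of an asymmetric site
  orf2 <- paste0("ATG", revcomp("GAGACC"), "TAA")
  occ2 <- find_occurrences(orf2, "GAGACC")
  pres2 <- Filter(function(o) o$status == "present", occ2)
  expect_true(any(vapply(pres2, function(o) o$strand == "-", logical(1))))
})

test_that("potential occurrences match exhaustive synonymous enumeration", {
  orf <- "GAGTTC"  # Glu-Phe; GAA TTC realizes GAATTC by one synonymous swap
  occ <- find_occurrences(orf, "GAATTC")
  pot <- Filter(function(o) o$status == "potential" && o$offset == 0, occ)
  expect_length(pot, 1L)
  expect_equal(pot[[1]]$codon_changes$codon_index, 1L)
  expect_equal(pot[[1]]$codon_changes$new_codon, "GAA")
  # oracle: enumerate all synonymous variants of the two codons
  vars <- expand.grid(synonymous_codons("E"), synonymous_codons("F"),
                      stringsAsFactors = FALSE)
  realizing <- apply(vars, 1, function(v) paste0(v[1], v[2]) == "GAATTC")
  expect_equal(sum(realizing), 1L)
  # a site requiring a non-synonymous change is never potential
  occ3 <- find_occurrences("GAAGAAGAA", "CCCCCC")
  expect_length(occ3, 0L)
})

test_that("conflict resolution prefers the site covering more unwanted hosts", {
  # K-E-F ORF; two overlapping, mutually exclusive realizations over
  # codons 1-2: AAGGAG (c1=AAG, c2=GAG) vs AAAGAG (c1=AAA, c2=GAG)
  orf <- "AAAGAATTT"
  mk <- function(id, role, sites)
    host_genome(id, role, gene_record(paste0(id, "_g"), "ATGGCTTAA"),
                enzymes = sites)
  mb <- microbiome(list(mk("w1", "wanted", "CCCGGG"),
                        mk("u1", "unwanted", "AAGGAG"),
                        mk("u2", "unwanted", "AAGGAG"),
                        mk("u3", "unwanted", "AAAGAG")))
  cls <- classify_sites(mb)
  res <- insert_sites(orf, cls, mb)
  # AAGGAG (2 hosts) beats AAAGAG (1 host) in the overlapping window
  expect_true(grepl("AAGGAG", res$seq, fixed = TRUE))
  expect_equal(translate_cds(res$seq), translate_cds(orf))
  # brute force over the two mutually exclusive resolutions
  expect_equal(unname(host_site_fractions("AAGGAGTTT", mb)["unwanted"]), 2 / 3)
  expect_equal(unname(host_site_fractions("AAAGAGTTT", mb)["unwanted"]), 1 / 3)
  expect_equal(unname(host_site_fractions(res$seq, mb)["unwanted"]), 2 / 3)
})

test_that("all conflict-free realizable unwanted sites are inserted", {
  # repeating unit GAG AAG GAT CTG: GAAAAA reachable at codons 1-2 and
  # GACCTG at codons 3-4 of each unit, conflict-free
  orf <- paste(rep(c("GAG", "AAG", "GAT", "CTG"), 3), collapse = "")
  mk <- function(id, role, sites)
    host_genome(id, role, gene_record(paste0(id, "_g"), "ATGGCTTAA"),
                enzymes = sites)
  mb <- microbiome(list(mk("w1", "wanted", "CCGCGG"),
                        mk("u1", "unwanted", c("GAAAAA", "GACCTG"))))
  cls <- classify_sites(mb)
  res <- insert_sites(orf, cls, mb)
  expect_true(grepl("GAAAAA", res$seq, fixed = TRUE))
  expect_true(grepl("GACCTG", res$seq, fixed = TRUE))
  expect_equal(translate_cds(res$seq), translate_cds(orf))
})

test_that("wanted sites are removed by minimal synonymous changes", {
  orf <- paste0("GAATTC", "AAACTGGAT")  # E F K L D
  mk <- function(id, role, sites)
    host_genome(id, role, gene_record(paste0(id, "_g"), "ATGGCTTAA"),
                enzymes = sites)
  mb <- microbiome(list(mk("w1", "wanted", "GAATTC"),
                        mk("u1", "unwanted", "TCTAGA")))
  cls <- classify_sites(mb)
  out <- remove_wanted_sites(orf, cls)
  expect_length(out$irremovable, 0L)
  expect_false(grepl("GAATTC", out$seq, fixed = TRUE))
  expect_equal(translate_cds(out$seq), translate_cds(orf))
  # minimal: exactly one codon differs
  d <- sum(split_codons(out$seq) != split_codons(orf))
  expect_equal(d, 1L)
})

test_that("sites forced by the protein are reported irremovable", {
  orf <- paste0("ATGTGG", "GAAGAT")  # M W E D: ATGTGG is forced
  mk <- function(id, role, sites)
    host_genome(id, role, gene_record(paste0(id, "_g"), "ATGGCTTAA"),
                enzymes = sites)
  mb <- microbiome(list(mk("w1", "wanted", c("ATGTGG", "NNNNNN")),
                        mk("u1", "unwanted", "TCTAGA")))
  cls <- classify_sites(mb)
  out <- remove_wanted_sites(orf, cls)
  irr_sites <- vapply(out$irremovable, `[[`, character(1), "site")
  expect_true("ATGTGG" %in% irr_sites)
  expect_true("NNNNNN" %in% irr_sites)  # degenerate ambiguity
  expect_equal(translate_cds(out$seq), translate_cds(orf))
})

test_that("the full editing pass is protein-safe, monotone and idempotent", {
  pool <- small_pool()
  goi <- make_goi(80, seed = 21)
  for (s in c(1L, 2L, 3L)) {
    idx <- withr::with_seed(s, sample(seq_along(pool), 10))
    hosts <- lapply(seq_along(idx), function(i) {
      h <- pool[[idx[i]]]
      h$role <- if (i <= 5) "wanted" else "unwanted"
      h$contigs <- character(0)
      h
    })
    mb <- microbiome(hosts)
    res <- suppressWarnings(edit_sites(goi$cds_seq, mb))
    expect_equal(translate_cds(res$seq), translate_cds(goi$cds_seq))
    expect_equal(unname(res$summary$after["wanted"]),
                 length(res$irremovable))
    expect_gte(res$summary$after["unwanted"], res$summary$before["unwanted"])
    res2 <- suppressWarnings(edit_sites(res$seq, mb))
    expect_equal(res2$seq, res$seq)
  }
})
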