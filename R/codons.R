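# Genetic-code helpers shared by every module. All sequences are plain
# upper-case character strings over A/C/G/T internally; Biostrings is used at
# the I/O boundary.

#' @importFrom Biostrings GENETIC_CODE
NULL

.codon_env <- new.env(parent = emptyenv())

.genetic_code <- function() {
  if (is.null(.codon_env$gc)) {
    gc <- Biostrings::GENETIC_CODE
    .codon_env$gc <- setNames(as.character(gc), names(gc))
  }
  .codon_env$gc
}

#' All 61 sense codons
#' @return character vector of sense codons (stop codons excluded)
#' @export
sense_codons <- function() {
  gc <- .genetic_code()
  names(gc)[gc != "*"]
}

#' Stop codons
#' @return character vector of the three stop codons
#' @export
stop_codons <- function() {
  gc <- .genetic_code()
  names(gc)[gc == "*"]
}

#' Synonymous codon family of an amino acid
#' @param aa single-letter amino acid code
#' @return character vector of codons encoding `aa`, lexicographic order
#' @export
synonymous_codons <- function(aa) {
  gc <- .genetic_code()
  sort(names(gc)[gc == aa])
}

#' Amino acids with at least one codon
#' @return sorted character vector of the 20 amino acids
#' @export
amino_acids <- function() {
  gc <- .genetic_code()
  sort(unique(gc[gc != "*"]))
}

#' Split a CDS into codons
#' @param cds DNA string, length divisible by 3
#' @return character vector of codons
#' @export
split_codons <- function(cds) {
  cds <- toupper(cds)
  L <- nchar(cds)
  if (L %% 3L != 0L) stop("CDS length not divisible by 3: ", L)
  if (L == 0L) return(character(0))
  substring(cds, seq(1L, L, 3L), seq(3L, L, 3L))
}

#' Translate a CDS
#'
#' Fast table-lookup translation; ambiguous codons translate to `NA`.
#' @param cds DNA string, length divisible by 3
#' @return character string of amino acids (`*` for stop)
#' @export
translate_cds <- function(cds) {
  gc <- .genetic_code()
  paste(gc[split_codons(cds)], collapse = "")
}

#' Reverse complement of a DNA string
#' @param x DNA string (IUPAC letters allowed)
#' @return reverse-complemented string
#' @export
revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  out <- comp[chars]
  if (anyNA(out)) stop("non-IUPAC character in sequence")
  paste(rev(out), collapse = "")
}

# IUPAC code -> set of concrete bases
.iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

#' Does a concrete base satisfy an IUPAC code?
#' @param base concrete base (A/C/G/T), vectorised
#' @param code IUPAC code, vectorised (recycled)
#' @return logical vector
#' @export
iupac_match <- function(base, code) {
  mapply(function(b, cd) {
    s <- .iupac_sets[[cd]]
    if (is.null(s)) stop("unknown IUPAC code: ", cd)
    b %in% s
  }, toupper(base), toupper(code), USE.NAMES = FALSE)
}

#' Validate an IUPAC site string
#' @param site candidate recognition-site string
#' @return TRUE if every character is an IUPAC nucleotide code
#' @export
is_iupac <- function(site) {
  chars <- strsplit(toupper(site), "", fixed = TRUE)[[1]]
  length(chars) > 0 && all(chars %in% names(.iupac_sets))
}

# Translate an IUPAC string into a regular expression character-class pattern.
.iupac_regex <- function(site) {
  chars <- strsplit(toupper(site), "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(cd) {
    s <- .iupac_sets[[cd]]
    if (is.null(s)) stop("unknown IUPAC code: ", cd)
    if (length(s) == 1L) s else paste0("[", paste(s, collapse = ""), "]")
  }, character(1)), collapse = "")
}

# Sample one concrete realization of an IUPAC string.
.iupac_realize <- function(site) {
  chars <- strsplit(toupper(site), "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(cd) {
    s <- .iupac_sets[[cd]]
    if (length(s) == 1L) s else sample(s, 1L)
  }, character(1)), collapse = "")
}

#' Check a DNA string for internal stop codons
#' @param cds DNA string, length divisible by 3
#' @return TRUE if the translation has no `*` before the final codon
#' @export
clean_translation <- function(cds) {
  aa <- translate_cds(cds)
  body <- substr(aa, 1L, nchar(aa) - 1L)
  !grepl("*", body, fixed = TRUE)
}
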