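# Restriction-site classification, insertion and removal on the engineered
# ORF under the synonymous-protein constraint. Recognition acts on dsDNA, so
# both the coding strand and its reverse complement are scanned; palindromic
# sites are deduplicated by interval. Edits are local, so rescans after an
# edit are restricted to a window around the changed codons.

#' Parse a restriction-enzyme repertoire file
#'
#' Accepts either the REBASE flat format (records with `<1>` enzyme, `<3>`
#' organism and `<5>` recognition-site lines) or a simple TSV dialect
#' (`organism<TAB>site;site;...`). All strains of one species (first two
#' words of the organism name) are merged, records labeled
#' "Unidentified bacterium" are dropped, cleavage-position decorations
#' (`^`, `(...)`) are stripped, and malformed or short (< 4 bp) sites are
#' skipped with a warning.
#'
#' @param path input file
#' @return named list, species -> character vector of IUPAC sites
#' @export
parse_rebase <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  add <- function(org, sites) {
    org <- trimws(org)
    if (!nzchar(org) || grepl("^unidentified bacterium", org,
                              ignore.case = TRUE)) return()
    words <- strsplit(org, "\\s+")[[1]]
    species <- paste(words[seq_len(min(2L, length(words)))], collapse = " ")
    clean <- character(0)
    for (s in sites) {
      s <- toupper(gsub("\\(.*?\\)|\\^|\\s", "", s))
      if (!nzchar(s)) next
      if (!is_iupac(s)) {
        warning("malformed site skipped: ", s)
        next
      }
      if (nchar(s) < 4L) {
        warning("site shorter than 4 bp skipped: ", s)
        next
      }
      clean <- c(clean, s)
    }
    if (length(clean))
      out[[species]] <<- sort(unique(c(out[[species]], clean)))
  }
  if (any(grepl("^<1>", lines))) {
    org <- NA_character_; sites <- character(0)
    for (ln in lines) {
      if (grepl("^<1>", ln)) {
        if (!is.na(org)) add(org, sites)
        org <- NA_character_; sites <- character(0)
      } else if (grepl("^<3>", ln)) {
        org <- sub("^<3>", "", ln)
      } else if (grepl("^<5>", ln)) {
        sites <- c(sites, sub("^<5>", "", ln))
      }
    }
    if (!is.na(org)) add(org, sites)
  } else {
    for (ln in lines) {
      if (!nzchar(trimws(ln)) || grepl("^#", ln)) next
      parts <- strsplit(ln, "\t")[[1]]
      if (length(parts) < 2L) next
      add(parts[1], strsplit(parts[2], ";")[[1]])
    }
  }
  out
}

#' Classify restriction sites across the microbiome
#'
#' @param mb a `microbiome` whose hosts carry enzyme repertoires
#' @return list with disjoint `wanted_only`, `unwanted_only` and `shared`
#'   site sets
#' @export
classify_sites <- function(mb) {
  wanted <- unique(unlist(lapply(mb$hosts[mb$A], `[[`, "enzymes")))
  unwanted <- unique(unlist(lapply(mb$hosts[mb$B], `[[`, "enzymes")))
  list(wanted_only = sort(setdiff(wanted, unwanted)),
       unwanted_only = sort(setdiff(unwanted, wanted)),
       shared = sort(intersect(wanted, unwanted)))
}

# hosts recognizing each site, split by role
.site_recognizers <- function(mb) {
  all_sites <- unique(unlist(lapply(mb$hosts, `[[`, "enzymes")))
  setNames(lapply(all_sites, function(s) {
    rec <- names(mb$hosts)[vapply(mb$hosts, function(h) s %in% h$enzymes,
                                  logical(1))]
    list(wanted = intersect(rec, mb$A), unwanted = intersect(rec, mb$B))
  }), all_sites)
}

# oriented patterns to scan on the forward strand: the site itself and, for
# non-palindromic sites, its reverse complement (recognition on the other
# strand)
.site_patterns <- function(site) {
  rc <- revcomp(site)
  if (rc == site) data.frame(site = site, pattern = site, strand = "+",
                             stringsAsFactors = FALSE)
  else data.frame(site = site, pattern = c(site, rc), strand = c("+", "-"),
                  stringsAsFactors = FALSE)
}

# all (overlapping) present matches of an IUPAC pattern; 0-based offsets
.present_offsets <- function(orf, pattern) {
  rx <- paste0("(?=", .iupac_regex(pattern), ")")
  m <- gregexpr(rx, orf, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L
}

# Per-pattern, per-reading-frame compatibility tables. For a pattern of
# length k starting at frame phase f (offset mod 3), the decomposition of
# pattern positions across overlapped codon slots is the same for every
# offset; only the amino acids differ. So for each (pattern, phase, slot) we
# precompute which synonymous codons of each amino acid satisfy the
# pattern's IUPAC constraints at the overlapping positions, making the
# genome-wide scan a table lookup per offset. Tables are memoized.
.slot_env <- new.env(parent = emptyenv())

.pattern_slots <- function(pattern) {
  cached <- .slot_env[[pattern]]
  if (!is.null(cached)) return(cached)
  k <- nchar(pattern)
  pchars <- strsplit(pattern, "")[[1]]
  all_cod <- sense_codons()
  out <- lapply(0:2, function(phase) {
    n_slots <- ((phase + k - 1L) %/% 3L) + 1L
    lapply(seq_len(n_slots) - 1L, function(s) {
      p_cov <- intersect((3L * s - phase):(3L * s - phase + 2L), 0:(k - 1L))
      cpos <- (phase + p_cov) - 3L * s + 1L  # 1-based codon positions
      req <- pchars[p_cov + 1L]
      compat <- all_cod[vapply(all_cod, function(cdn) {
        all(iupac_match(strsplit(cdn, "")[[1]][cpos], req))
      }, logical(1))]
      opts <- lapply(amino_acids(), function(a)
        intersect(synonymous_codons(a), compat))
      names(opts) <- amino_acids()
      list(options = opts)
    })
  })
  .slot_env[[pattern]] <- out
  out
}

# core scanner; when nt_lo/nt_hi (0-based half-open) are given, only
# occurrences overlapping that window are reported
.find_occ <- function(orf, sites, nt_lo = NULL, nt_hi = NULL) {
  orf <- toupper(orf)
  cod <- split_codons(orf)
  aa <- vapply(cod, function(cd) .genetic_code()[[cd]], character(1))
  n_cod <- length(cod)
  L <- nchar(orf)
  windowed <- !is.null(nt_lo)
  occ <- list()
  for (site in unique(sites)) {
    pats <- .site_patterns(site)
    for (pi in seq_len(nrow(pats))) {
      pattern <- pats$pattern[pi]
      strand <- pats$strand[pi]
      k <- nchar(pattern)
      if (k > L) next
      lo_off <- if (windowed) max(0L, nt_lo - k + 1L) else 0L
      hi_off <- if (windowed) min(L - k, nt_hi - 1L) else L - k
      if (lo_off > hi_off) next
      off_range <- lo_off:hi_off
      present <- .present_offsets(orf, pattern)
      for (off in intersect(present, off_range))
        occ[[length(occ) + 1L]] <- list(site = site, pattern = pattern,
                                        strand = strand, offset = off,
                                        status = "present")
      slots <- .pattern_slots(pattern)
      for (off in off_range) {
        if (off %in% present) next
        phase <- off %% 3L
        c0 <- off %/% 3L
        ph_slots <- slots[[phase + 1L]]
        options <- vector("list", length(ph_slots))
        feasible <- TRUE
        for (s in seq_along(ph_slots)) {
          ci <- c0 + s
          if (ci > n_cod) { feasible <- FALSE; break }
          ok <- ph_slots[[s]]$options[[aa[ci]]]
          if (!length(ok)) { feasible <- FALSE; break }
          options[[s]] <- ok
        }
        if (!feasible) next
        ci_change <- integer(0); new_ch <- character(0)
        for (s in seq_along(ph_slots)) {
          ci <- c0 + s
          if (!(cod[ci] %in% options[[s]])) {
            ci_change <- c(ci_change, ci)
            new_ch <- c(new_ch, options[[s]][1])
          }
        }
        if (!length(ci_change)) next  # already matches (handled as present)
        names(options) <- as.character(c0 + seq_along(ph_slots))
        occ[[length(occ) + 1L]] <- list(
          site = site, pattern = pattern, strand = strand, offset = off,
          status = "potential",
          codon_changes = list(codon_index = ci_change, new_codon = new_ch),
          options = options)
      }
    }
  }
  if (length(occ)) {
    key <- vapply(occ, function(o)
      paste(o$site, o$offset, o$status), character(1))
    occ <- occ[!duplicated(key)]
  }
  occ
}

#' Locate current and potential restriction-site occurrences on an ORF
#'
#' Present occurrences are IUPAC matches of the site (either strand) in the
#' current sequence. Potential occurrences are windows where a combination
#' of synonymous codon substitutions realizes the site: each codon
#' overlapping the window must have at least one synonymous codon compatible
#' with the site's IUPAC constraints at the overlap positions (constraints
#' on different codons are independent, so per-codon compatibility
#' suffices).
#'
#' @param orf DNA string, length divisible by 3, clean translation
#' @param sites character vector of IUPAC sites
#' @return list of occurrence records: `site`, `pattern` (as oriented on the
#'   forward strand), `strand`, `offset` (0-based), `status`
#'   ("present"/"potential"), and for potential occurrences
#'   `codon_changes` (codon_index, new_codon) plus per-codon `options`
#' @export
find_occurrences <- function(orf, sites) .find_occ(orf, sites)

.apply_changes <- function(orf, changes) {
  cod <- split_codons(orf)
  for (i in seq_along(changes$codon_index))
    cod[changes$codon_index[i]] <- changes$new_codon[i]
  paste(cod, collapse = "")
}

.present_of <- function(orf, sites, nt_lo = NULL, nt_hi = NULL) {
  occ <- .find_occ(orf, sites, nt_lo, nt_hi)
  Filter(function(o) o$status == "present", occ)
}

.occ_key <- function(o) paste(o$site, o$offset, o$strand)

# nt window (0-based half-open) touched by a set of codon changes
.change_window <- function(changes) {
  c((min(changes$codon_index) - 1L) * 3L, max(changes$codon_index) * 3L)
}

# interval overlap between two occurrence records
.occ_overlap <- function(a, b) {
  a$offset < b$offset + nchar(b$pattern) && b$offset < a$offset + nchar(a$pattern)
}

#' Insert unwanted-host-only restriction sites
#'
#' Potential occurrences of unwanted-only sites are realized by synonymous
#' changes: conflict-free candidates first, then conflicted candidates in
#' ascending conflict-degree order, choosing within a conflict group by
#' (1) the number of unwanted hosts newly gaining a recognized site,
#' (2) coverage weighted toward hosts with fewer existing sites
#' (1/(1+count) per newly recognizing host), (3) lexicographic site,
#' (4) smallest offset. A realization is rejected when it would destroy an
#' existing unwanted-recognized occurrence or create a wanted-recognized
#' site that has no synonymous escape keeping the insertion intact.
#'
#' @param orf DNA string (engineered ORF)
#' @param classification output of [classify_sites()]
#' @param mb the `microbiome` (for per-host coverage bookkeeping)
#' @return list with `seq`, `inserted` (records of realized occurrences) and
#'   `log`
#' @export
insert_sites <- function(orf, classification, mb) {
  orf <- toupper(orf)
  prot <- translate_cds(orf)
  targets <- classification$unwanted_only
  avoid <- c(classification$wanted_only, classification$shared)
  if (!length(targets)) return(list(seq = orf, inserted = list(),
                                    log = character(0)))
  recog <- .site_recognizers(mb)
  logs <- character(0)
  inserted <- list()

  # windowed safety check; returns the new sequence or NULL
  realize_ok <- function(seq_now, cand) {
    new_seq <- .apply_changes(seq_now, cand$codon_changes)
    win <- .change_window(cand$codon_changes)
    # must not destroy an existing unwanted-recognized occurrence
    before <- .present_of(seq_now, targets, win[1], win[2])
    after <- .present_of(new_seq, targets, win[1], win[2])
    if (!all(vapply(before, .occ_key, character(1)) %in%
             vapply(after, .occ_key, character(1)))) return(NULL)
    # any newly created wanted-recognized site must be escapable without
    # touching the freshly inserted window
    if (length(avoid)) {
      w_before <- vapply(.present_of(seq_now, avoid, win[1], win[2]),
                         .occ_key, character(1))
      w_after <- .present_of(new_seq, avoid, win[1], win[2])
      for (wo in w_after) {
        if (.occ_key(wo) %in% w_before) next
        esc <- .escape_variants(new_seq, wo,
                                protect = c(inserted, list(cand)))
        if (is.null(esc)) return(NULL)
      }
    }
    new_seq
  }

  occ <- .find_occ(orf, targets)
  repeat {
    pres <- Filter(function(o) o$status == "present", occ)
    cands <- Filter(function(o) o$status == "potential", occ)
    if (!length(cands)) break
    host_count <- setNames(numeric(length(mb$B)), mb$B)
    for (o in pres)
      for (h in recog[[o$site]]$unwanted) host_count[h] <- host_count[h] + 1
    covered <- names(host_count)[host_count > 0]
    deg <- vapply(seq_along(cands), function(i)
      sum(vapply(seq_along(cands), function(j)
        i != j && .occ_overlap(cands[[i]], cands[[j]]), logical(1))),
      integer(1))
    m1 <- vapply(cands, function(o)
      length(setdiff(recog[[o$site]]$unwanted, covered)), numeric(1))
    m2 <- vapply(cands, function(o)
      sum(1 / (1 + host_count[recog[[o$site]]$unwanted])), numeric(1))
    ord <- order(deg, -m1, -m2,
                 vapply(cands, `[[`, character(1), "site"),
                 vapply(cands, `[[`, integer(1), "offset"))
    advanced <- FALSE
    for (i in ord) {
      cand <- cands[[i]]
      new_seq <- realize_ok(orf, cand)
      if (is.null(new_seq)) {
        # unrealizable in the current sequence; drop it for this round
        occ <- Filter(function(o) .occ_key(o) != .occ_key(cand) ||
                        o$status != "potential", occ)
        next
      }
      orf <- new_seq
      inserted[[length(inserted) + 1L]] <- cand
      logs <- c(logs, sprintf("inserted %s (%s strand) at offset %d",
                              cand$site, cand$strand, cand$offset))
      # refresh only records overlapping the changed window
      win <- .change_window(cand$codon_changes)
      keep <- Filter(function(o)
        o$offset + nchar(o$pattern) <= win[1] || o$offset >= win[2], occ)
      fresh <- .find_occ(orf, targets, win[1], win[2])
      occ <- c(keep, fresh)
      advanced <- TRUE
      break
    }
    if (!advanced) break
  }
  stopifnot(translate_cds(orf) == prot)
  list(seq = orf, inserted = inserted, log = logs)
}

# Synonymous escape search for one present occurrence: minimal number of
# codon changes that break the match. Returns a change list, or NULL when
# the site is forced by the protein sequence and ambiguity. `protect` lists
# occurrences whose windows must keep matching their patterns; `avoid_new`
# are (site, offset, strand) keys that must not re-appear.
.escape_variants <- function(orf, occ, protect = list(),
                             avoid_new = character(0),
                             all_avoid_sites = NULL, cub_logw = NULL) {
  cod <- split_codons(orf)
  aa <- vapply(cod, function(cd) .genetic_code()[[cd]], character(1))
  k <- nchar(occ$pattern)
  ci_first <- occ$offset %/% 3L + 1L
  ci_last <- (occ$offset + k - 1L) %/% 3L + 1L
  idxs <- ci_first:ci_last
  syn_by_ci <- lapply(idxs, function(ci) synonymous_codons(aa[ci]))
  # only occurrences still present can be protected; insertions destroyed by
  # an earlier edit must not veto escapes
  protect <- Filter(function(p)
    p$offset %in% .present_offsets(orf, p$pattern), protect)
  ok_variant <- function(changes) {
    new_seq <- .apply_changes(orf, changes)
    win <- .change_window(changes)
    if (occ$offset %in% .present_offsets(new_seq, occ$pattern)) return(FALSE)
    for (p in protect) {
      if (p$offset + nchar(p$pattern) <= win[1] || p$offset >= win[2]) next
      if (!(p$offset %in% .present_offsets(new_seq, p$pattern))) return(FALSE)
    }
    if (length(avoid_new) && !is.null(all_avoid_sites)) {
      now <- vapply(.present_of(new_seq, all_avoid_sites, win[1], win[2]),
                    .occ_key, character(1))
      if (any(avoid_new %in% now)) return(FALSE)
    }
    TRUE
  }
  delta_cub <- function(changes) {
    if (is.null(cub_logw)) return(0)
    sum(abs(cub_logw[changes$new_codon] -
              cub_logw[cod[changes$codon_index]]))
  }
  for (n_changes in seq_along(idxs)) {
    combos <- utils::combn(seq_along(idxs), n_changes, simplify = FALSE)
    best <- NULL
    for (cb in combos) {
      opts <- lapply(cb, function(j) setdiff(syn_by_ci[[j]], cod[idxs[j]]))
      if (any(!lengths(opts))) next
      grid <- expand.grid(opts, stringsAsFactors = FALSE)
      for (gi in seq_len(nrow(grid))) {
        changes <- list(codon_index = idxs[cb],
                        new_codon = unlist(grid[gi, ], use.names = FALSE))
        if (!ok_variant(changes)) next
        d <- delta_cub(changes)
        if (is.null(best) || d < best$d - 1e-12)
          best <- list(changes = changes, d = d)
      }
    }
    if (!is.null(best)) return(best$changes)
  }
  NULL
}

#' Remove wanted-host-recognized restriction sites
#'
#' Every present occurrence of a wanted-only or shared site is eliminated by
#' the minimal number of synonymous codon changes whenever a synonymous
#' escape exists (exhaustive search over the overlapping codons), preferring
#' escapes that least perturb the wanted-host codon-usage distance when
#' `cub_w` is given. Removal never re-creates a previously removed
#' occurrence; inserted unwanted-only sites are kept intact unless no other
#' escape exists (then the fallback is applied and logged). Irremovable
#' occurrences are reported.
#'
#' @param orf DNA string
#' @param classification output of [classify_sites()]
#' @param protect list of realized insertion records to keep intact (from
#'   [insert_sites()])
#' @param cub_w optional `codon_weight_table` (typically the wanted-host
#'   mean CAI) guiding the minimal-perturbation preference
#' @param max_passes rescan limit (removals can create new sites)
#' @return list with `seq`, `irremovable` (occurrence records) and `log`
#' @export
remove_wanted_sites <- function(orf, classification, protect = list(),
                                cub_w = NULL, max_passes = 25L) {
  orf <- toupper(orf)
  prot <- translate_cds(orf)
  avoid <- c(classification$wanted_only, classification$shared)
  if (!length(avoid)) return(list(seq = orf, irremovable = list(),
                                  log = character(0)))
  cub_logw <- if (!is.null(cub_w)) log(cub_w$w) else NULL
  removed_keys <- character(0)
  irremovable <- list()
  logs <- character(0)
  for (pass in seq_len(max_passes)) {
    pres <- .present_of(orf, avoid)
    if (length(irremovable)) {
      irr_keys <- vapply(irremovable, .occ_key, character(1))
      pres <- Filter(function(o) !(.occ_key(o) %in% irr_keys), pres)
    }
    if (!length(pres)) break
    pres <- pres[order(vapply(pres, `[[`, integer(1), "offset"),
                       vapply(pres, `[[`, character(1), "site"))]
    changed <- FALSE
    for (o in pres) {
      esc <- .escape_variants(orf, o, protect = protect,
                              avoid_new = removed_keys,
                              all_avoid_sites = avoid, cub_logw = cub_logw)
      if (!is.null(esc)) {
        orf <- .apply_changes(orf, esc)
        removed_keys <- c(removed_keys, .occ_key(o))
        logs <- c(logs, sprintf("removed %s at offset %d (%s strand)",
                                o$site, o$offset, o$strand))
        changed <- TRUE
        break  # rescan from the updated sequence
      }
      # retry allowing protected insertions to be sacrificed
      esc2 <- .escape_variants(orf, o, protect = list(),
                               avoid_new = removed_keys,
                               all_avoid_sites = avoid, cub_logw = cub_logw)
      if (is.null(esc2)) {
        irremovable[[length(irremovable) + 1L]] <- o
        logs <- c(logs, sprintf("irremovable: %s at offset %d (%s strand)",
                                o$site, o$offset, o$strand))
      } else {
        orf <- .apply_changes(orf, esc2)
        removed_keys <- c(removed_keys, .occ_key(o))
        logs <- c(logs, sprintf(
          "removed %s at offset %d sacrificing an inserted site",
          o$site, o$offset))
        changed <- TRUE
        break
      }
    }
    if (!changed) break
  }
  stopifnot(translate_cds(orf) == prot)
  list(seq = orf, irremovable = irremovable, log = logs)
}

#' Full restriction-site editing pass
#'
#' Runs [insert_sites()] then [remove_wanted_sites()] in the fixed pipeline
#' order (insertion can create wanted-recognized sites, so removal must come
#' second).
#'
#' @param orf DNA string
#' @param mb a `microbiome` with enzyme repertoires
#' @param cub_w optional wanted-host weight table for minimal-perturbation
#'   removal
#' @return list with `seq`, `classification`, `inserted`, `irremovable`,
#'   `summary` (site counts per group before/after) and `log`
#' @export
edit_sites <- function(orf, mb, cub_w = NULL, max_rounds = 6L) {
  orf <- toupper(orf)
  cls <- classify_sites(mb)
  count <- function(seq, sites)
    if (!length(sites)) 0L else length(.present_of(seq, sites))
  before <- c(wanted = count(orf, c(cls$wanted_only, cls$shared)),
              unwanted = count(orf, c(cls$unwanted_only, cls$shared)))
  inserted <- list(); irremovable <- list(); logs <- character(0)
  seq_now <- orf
  # removal edits can open fresh insertion windows, so the insert/remove
  # pair is iterated to a fixed point (making the editor idempotent)
  for (round in seq_len(max_rounds)) {
    ins <- insert_sites(seq_now, cls, mb)
    inserted <- Filter(function(p)
      p$offset %in% .present_offsets(ins$seq, p$pattern),
      c(inserted, ins$inserted))
    rem <- remove_wanted_sites(ins$seq, cls, protect = inserted,
                               cub_w = cub_w)
    irremovable <- rem$irremovable
    logs <- c(logs, ins$log, rem$log)
    if (rem$seq == seq_now) { seq_now <- rem$seq; break }
    seq_now <- rem$seq
    if (round == max_rounds)
      warning("site editing did not reach a fixed point in ", max_rounds,
              " rounds")
  }
  after <- c(wanted = count(seq_now, c(cls$wanted_only, cls$shared)),
             unwanted = count(seq_now, c(cls$unwanted_only, cls$shared)))
  list(seq = seq_now, classification = cls, inserted = inserted,
       irremovable = irremovable,
       summary = list(before = before, after = after),
       log = logs)
}

#' Fraction of hosts recognizing at least one site in a sequence
#' @param orf DNA string
#' @param mb a `microbiome`
#' @return named numeric: fraction of wanted and of unwanted hosts with a
#'   present recognized occurrence
#' @export
host_site_fractions <- function(orf, mb) {
  has_site <- vapply(mb$hosts, function(h) {
    length(h$enzymes) > 0 && length(.present_of(orf, h$enzymes)) > 0
  }, logical(1))
  c(wanted = mean(has_site[mb$A]), unwanted = mean(has_site[mb$B]))
}
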