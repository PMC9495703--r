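# ORF redesign: proteome-relative greedy hill climbing, per-amino-acid
# ratio/difference codon selection, and the optimization-index evaluation.

# Internal: stack per-host log-weight matrix and profile moments so that a
# candidate's score in every host is one matrix product on its codon counts.
.cub_matrices <- function(mb, cub) {
  ids <- names(mb$hosts)
  logW <- sapply(ids, function(id) log(cub$weights[[id]]$w))  # 61 x H
  mu <- vapply(ids, function(id) cub$profiles[[id]]$mu, numeric(1))
  sigma <- vapply(ids, function(id) cub$profiles[[id]]$sigma, numeric(1))
  if (any(sigma == 0)) stop("zero proteome sigma for host ",
                            paste(ids[sigma == 0], collapse = ", "))
  list(ids = ids, logW = logW, mu = mu, sigma = sigma,
       iA = match(mb$A, ids), iB = match(mb$B, ids))
}

.dist_from_counts <- function(counts, mats) {
  L <- sum(counts)
  cub_h <- exp(as.vector(counts %*% mats$logW) / L)
  (cub_h - mats$mu) / mats$sigma
}

.f_from_counts <- function(counts, mats, alpha) {
  d <- .dist_from_counts(counts, mats)
  alpha * mean(d[mats$iA]) - mean(d[mats$iB])
}

#' Neighborhood optimization score of a candidate sequence
#'
#' f(X') = alpha * mean over wanted hosts of (CUB_a(X') - mu_a)/sigma_a minus
#' the same mean over unwanted hosts.
#'
#' @param candidate DNA string (synonymous candidate of the gene of interest)
#' @param mb a `microbiome`
#' @param cub list of per-host `weights` and `profiles` (see
#'   [microbiome_cub()])
#' @param alpha weighting of the wanted-host term (default 1)
#' @return list with `f`, `alpha` and the per-host normalized distances
#' @export
neighborhood_score <- function(candidate, mb, cub, alpha = 1) {
  mats <- .cub_matrices(mb, cub)
  counts <- codon_counts(candidate)
  d <- .dist_from_counts(counts, mats)
  list(f = alpha * mean(d[mats$iA]) - mean(d[mats$iB]), alpha = alpha,
       dist = setNames(d, mats$ids))
}

# split a CDS into body codons + optional terminal stop
.split_body <- function(cds) {
  cod <- split_codons(cds)
  stop <- character(0)
  if (length(cod) && cod[length(cod)] %in% stop_codons()) {
    stop <- cod[length(cod)]
    cod <- cod[-length(cod)]
  }
  list(body = cod, stop = stop)
}

.counts_from_codons <- function(cod) {
  counts <- table(factor(cod, levels = sense_codons()))
  setNames(as.integer(counts), names(counts))
}

#' Proteome-relative greedy hill climb
#'
#' Each neighborhood move recodes every codon of one amino acid to one
#' synonymous codon (bulk replacement); the move with the largest strictly
#' improving score is accepted, until a local maximum or `max_iter`
#' iterations. Amino acids are visited alphabetically and codons
#' lexicographically; score ties break toward the lexicographically smaller
#' sequence, so the procedure is deterministic.
#'
#' @param goi gene record (one-row data.frame) or DNA string of the gene of
#'   interest
#' @param mb a `microbiome`
#' @param scheme CUB scheme when `cub` is not supplied
#' @param alpha wanted-host weighting in the optimization score
#' @param max_iter maximum accepted moves
#' @param cub optional precomputed [microbiome_cub()] result
#' @return list with `seq` (engineered DNA string, terminal stop preserved),
#'   `f` (final score), `trace` (accepted-score sequence, strictly
#'   increasing, starting at the input's score) and `converged`
#' @export
hill_climb <- function(goi, mb, scheme = "CAI", alpha = 1, max_iter = 200L,
                       cub = NULL) {
  stopifnot(max_iter >= 1L)
  cds <- if (is.data.frame(goi)) goi$cds_seq[1] else toupper(goi)
  if (is.null(cub)) cub <- microbiome_cub(mb, scheme)
  mats <- .cub_matrices(mb, cub)
  parts <- .split_body(cds)
  cod <- parts$body
  aa <- vapply(cod, function(cd) .genetic_code()[[cd]], character(1))
  counts <- .counts_from_codons(cod)
  f_cur <- .f_from_counts(counts, mats, alpha)
  trace <- f_cur
  fams <- sort(unique(aa))
  for (iter in seq_len(max_iter)) {
    best <- NULL
    for (a in fams) {
      fam <- synonymous_codons(a)
      if (length(fam) < 2L) next
      n_fam <- sum(counts[fam])
      for (si in fam) {
        cand <- counts
        cand[fam] <- 0L
        cand[si] <- n_fam
        f <- .f_from_counts(cand, mats, alpha)
        if (f > f_cur + 1e-12 &&
            (is.null(best) || f > best$f + 1e-12 ||
             (abs(f - best$f) <= 1e-12 && (a < best$a ||
               (a == best$a && si < best$si))))) {
          best <- list(f = f, a = a, si = si, counts = cand)
        }
      }
    }
    if (is.null(best)) break
    cod[aa == best$a] <- best$si
    counts <- best$counts
    f_cur <- best$f
    trace <- c(trace, f_cur)
  }
  out <- paste(c(cod, parts$stop), collapse = "")
  stopifnot(translate_cds(out) == translate_cds(cds))
  list(seq = out, f = f_cur, trace = trace,
       converged = length(trace) - 1L < max_iter)
}

#' Ratio and difference codon-selection scores for one amino acid
#'
#' For each synonymous codon i of `amino_acid`, with w_i the host's weight
#' and max the within-host synonymous-family maximum:
#' R_i = sum over wanted hosts of w_i/max minus the same sum over unwanted
#' hosts. The corrected difference score is D_i = sum over wanted of w_i/max
#' plus sum over unwanted of (1 - w_i/max); `d_formula = "printed"` instead
#' evaluates sum over wanted of (1 - w_i + max) plus sum over unwanted of
#' (w_i - max).
#'
#' @param mb a `microbiome`
#' @param weights_by_host named list of `codon_weight_table`s
#' @param amino_acid single-letter amino acid
#' @param d_formula "corrected" (default) or "printed"
#' @return data.frame with codon, R, D, sorted lexicographically
#' @export
per_codon_scores <- function(mb, weights_by_host, amino_acid,
                             d_formula = c("corrected", "printed")) {
  d_formula <- match.arg(d_formula)
  fam <- synonymous_codons(amino_acid)
  if (!length(fam)) stop("unknown amino acid: ", amino_acid)
  score_one <- function(host_ids, sign_wanted) {
    R <- setNames(numeric(length(fam)), fam)
    D <- R
    for (id in host_ids) {
      w <- weights_by_host[[id]]$w[fam]
      mx <- max(w)
      R <- R + w / mx
      D <- D + if (d_formula == "corrected") {
        if (sign_wanted) w / mx else 1 - w / mx
      } else {
        if (sign_wanted) 1 - w + mx else w - mx
      }
    }
    list(R = R, D = D)
  }
  a <- score_one(mb$A, TRUE)
  b <- score_one(mb$B, FALSE)
  data.frame(codon = fam, R = unname(a$R - b$R),
             D = unname(a$D + b$D), stringsAsFactors = FALSE)
}

#' Individual amino acid optimization
#'
#' Every position is recoded to its family's winning codon under the ratio
#' (R) or difference (D) score; ties break to the lexicographically smallest
#' codon. The protein is unchanged.
#'
#' @inheritParams hill_climb
#' @param score_kind "R" or "D"
#' @param d_formula passed to [per_codon_scores()]
#' @return list with `seq` and the per-family winner table
#' @export
individual_optimize <- function(goi, mb, scheme = "CAI",
                                score_kind = c("R", "D"),
                                d_formula = c("corrected", "printed"),
                                cub = NULL) {
  score_kind <- match.arg(score_kind)
  d_formula <- match.arg(d_formula)
  cds <- if (is.data.frame(goi)) goi$cds_seq[1] else toupper(goi)
  if (is.null(cub)) cub <- microbiome_cub(mb, scheme)
  parts <- .split_body(cds)
  aa <- vapply(parts$body, function(cd) .genetic_code()[[cd]], character(1))
  winners <- lapply(sort(unique(aa)), function(a) {
    sc <- per_codon_scores(mb, cub$weights, a, d_formula)
    val <- sc[[score_kind]]
    data.frame(aa = a, codon = sc$codon[order(-val, sc$codon)][1],
               score = max(val), stringsAsFactors = FALSE)
  })
  winners <- do.call(rbind, winners)
  cod <- winners$codon[match(aa, winners$aa)]
  out <- paste(c(cod, parts$stop), collapse = "")
  stopifnot(translate_cds(out) == translate_cds(cds))
  list(seq = out, winners = winners)
}

#' Optimization index of an engineered sequence
#'
#' Per host, Score_h = (CUB_h(engineered) - CUB_h(original)) / sigma_h; the
#' index is the mean over wanted hosts minus the mean over unwanted hosts,
#' and is exactly antisymmetric under swapping the two sets.
#'
#' @param original,engineered synonymous DNA strings
#' @inheritParams hill_climb
#' @return list with `per_host` (named Score_h vector) and `index`
#' @export
optimization_index <- function(original, engineered, mb, scheme = "CAI",
                               cub = NULL) {
  if (translate_cds(original) != translate_cds(engineered))
    stop("sequences are not synonymous")
  if (is.null(cub)) cub <- microbiome_cub(mb, scheme)
  mats <- .cub_matrices(mb, cub)
  sc <- function(cds) {
    counts <- codon_counts(cds)
    exp(as.vector(counts %*% mats$logW) / sum(counts))
  }
  per_host <- setNames((sc(engineered) - sc(original)) / mats$sigma, mats$ids)
  list(per_host = per_host,
       index = mean(per_host[mats$iA]) - mean(per_host[mats$iB]))
}
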