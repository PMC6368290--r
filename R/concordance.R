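#' Call-matching parameters
#'
#' Two variants are considered similar when their interval overlap
#' exceeds a Jaccard index of 0.4 (strict inequality) and the distance
#' between corresponding breakpoints is below 100 kb (strict).  For
#' interchromosomal (BND) pairs the Jaccard criterion is vacuous and
#' similarity reduces to chromosome-pair identity plus the per-end
#' distance cutoff.
#'
#' @param jaccard_min Jaccard threshold (strictly exceeded).
#' @param max_bp_dist Breakpoint distance cutoff in bp (strictly
#'   below).
#' @param per_type Compare only calls of the same SV type.
#' @return List of class `ccr_matchparams`.
#' @export
match_params <- function(jaccard_min = 0.4, max_bp_dist = 1e5, per_type = FALSE) {
  stopifnot(jaccard_min >= 0, jaccard_min <= 1, max_bp_dist > 0)
  structure(list(jaccard_min = jaccard_min, max_bp_dist = max_bp_dist,
                 per_type = per_type), class = "ccr_matchparams")
}

#' Jaccard index of two genomic intervals
#'
#' `|intersection| / |union|` with interval sizes in the package's
#' difference convention (`end - start`, i.e. half-open base
#' counting).  Symmetric, in `[0, 1]`; vectorized.
#'
#' @param startA,endA,startB,endB Interval coordinates
#'   (`start <= end`).
#' @return Numeric vector of Jaccard indices (0 for disjoint
#'   intervals, including zero-size inputs).
#' @export
jaccard_index <- function(startA, endA, startB, endB) {
  inter <- pmax(0, pmin(endA, endB) - pmax(startA, startB))
  un <- (endA - startA) + (endB - startB) - inter
  ifelse(un <= 0, 0, inter / un)
}

# vectorized similarity of one call against a call data.frame
similar_to_call <- function(call, calls, params) {
  if (nrow(calls) == 0) return(logical(0))
  ok <- rep(TRUE, nrow(calls))
  if (params$per_type) ok <- ok & calls$sv_type == call$sv_type
  same_pair <- calls$chrA == call$chrA & calls$chrB == call$chrB
  ok <- ok & same_pair
  dA <- abs(calls$posA - call$posA)
  dB <- abs(calls$posB - call$posB)
  ok <- ok & dA < params$max_bp_dist & dB < params$max_bp_dist
  intra <- call$chrA == call$chrB
  if (intra) {
    jac <- jaccard_index(call$posA, call$posB, calls$posA, calls$posB)
    ok <- ok & jac > params$jaccard_min
  }
  ok
}

#' Are two calls similar?
#'
#' Applies the similarity criterion of [match_params()] to a pair of
#' normalized calls: intrachromosomal pairs need Jaccard strictly
#' above the threshold and both breakpoint distances strictly below
#' the cutoff; interchromosomal pairs need the same chromosome pair
#' and both end distances below the cutoff.  Symmetric.
#'
#' @param callA,callB Single-row call `data.frame`s (normalized).
#' @param params A [match_params()].
#' @return Logical scalar.
#' @export
is_similar <- function(callA, callB, params = match_params()) {
  as.logical(similar_to_call(callA, callB, params))
}

#' Merge call sets into cross-technology variant clusters
#'
#' Greedy clustering: calls are pooled, ordered deterministically by
#' (chromosome, position, source), and each call joins the first
#' cluster whose representative it is similar to, else founds a new
#' cluster.  Merging a merged output with itself yields identical
#' clusters, and the result is invariant to input order.
#'
#' @param callsets List of [callset()]s.
#' @param params A [match_params()].
#' @return `data.frame` of merged variants: representative columns
#'   plus `present_in` (comma-joined source labels) and `n_members`.
#' @export
merge_callsets <- function(callsets, params = match_params()) {
  stopifnot(length(callsets) >= 1)
  genome <- callsets[[1]]$genome
  pool <- do.call(rbind, lapply(callsets, function(cs) cs$calls))
  if (nrow(pool) == 0) {
    pool$present_in <- character(); pool$n_members <- integer()
    return(pool)
  }
  pool <- pool[order(chrom_rank(genome, pool$chrA), pool$posA,
                     chrom_rank(genome, pool$chrB), pool$posB, pool$source), ]
  reps <- pool[0, , drop = FALSE]
  members <- list()
  for (i in seq_len(nrow(pool))) {
    cand <- which(similar_to_call(pool[i, ], reps, params))
    if (length(cand)) {
      k <- cand[1]
      members[[k]] <- c(members[[k]], i)
    } else {
      reps <- rbind(reps, pool[i, ])
      members[[nrow(reps)]] <- i
    }
  }
  reps$present_in <- vapply(members, function(m)
    paste(sort(unique(pool$source[m])), collapse = ","), "")
  reps$n_members <- lengths(members)
  rownames(reps) <- NULL
  reps
}

#' Pairwise overlap matrix of call sets
#'
#' Cell (i, j) counts the calls of set i similar to at least one call
#' of set j; the percentage uses row set i as denominator.
#'
#' @param callsets Named list of [callset()]s.
#' @param params A [match_params()].
#' @return List with integer matrix `counts`, numeric matrix `pct`,
#'   and vector `n` of set sizes.
#' @export
overlap_matrix <- function(callsets, params = match_params()) {
  stopifnot(length(callsets) >= 2)
  nms <- names(callsets)
  if (is.null(nms)) nms <- vapply(callsets, function(cs) cs$source, "")
  n <- length(callsets)
  counts <- matrix(0L, n, n, dimnames = list(nms, nms))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- callsets[[i]]$calls; b <- callsets[[j]]$calls
    if (i == j) { counts[i, j] <- nrow(a); next }
    hit <- vapply(seq_len(nrow(a)), function(k)
      any(similar_to_call(a[k, ], b, params)), FALSE)
    counts[i, j] <- sum(hit)
  }
  sizes <- vapply(callsets, function(cs) nrow(cs$calls), 0L)
  pct <- round(100 * counts / sizes, 1)
  list(counts = counts, pct = pct, n = stats::setNames(sizes, nms))
}

#' Annotate calls with population frequency
#'
#' `freq_count` becomes the number of database variants similar to the
#' call under the matching criterion.
#'
#' @param calls Call `data.frame`.
#' @param freq_db A [build_frequency_db()] result.
#' @param params A [match_params()].
#' @return `calls` with `freq_count` filled.
#' @export
annotate_frequency <- function(calls, freq_db, params = match_params()) {
  db <- freq_db$variants
  calls$freq_count <- vapply(seq_len(nrow(calls)), function(i) {
    hit <- similar_to_call(calls[i, ], db, params)
    sum(db$count[hit])
  }, 0)
  calls
}

#' Filter structural-variant calls
#'
#' Ordered filtering rules mirroring a short-read SV post-processing
#' pipeline: `pass_only` (VCF quality flag), `frequency` (drop
#' anything found in the population database), `small_intergenic`
#' (drop intergenic events below 10 kb), `min_support` (drop calls
#' with fewer than 8 supporting pairs plus split reads).  Each removed
#' call carries the first rule that triggered; kept + removed
#' partitions the input.
#'
#' @param calls Call `data.frame` (`freq_count` must be filled if the
#'   frequency rule is active; `genic` if `small_intergenic` is).
#' @param rules Ordered character subset of `c("pass_only",
#'   "frequency", "small_intergenic", "min_support")`.
#' @param min_support Support threshold (default 8; "less than" is
#'   strict, so exactly 8 is kept).
#' @param small_size Intergenic size cutoff in bp (default 10 kb,
#'   strict).
#' @return List with `kept` and `removed` (with `filtered_reason`).
#' @export
filter_calls <- function(calls,
                         rules = c("pass_only", "frequency",
                                   "small_intergenic", "min_support"),
                         min_support = 8, small_size = 1e4) {
  bad <- setdiff(rules, c("pass_only", "frequency", "small_intergenic", "min_support"))
  if (length(bad)) stop("unknown filter rule(s): ", paste(bad, collapse = ", "))
  reason <- rep(NA_character_, nrow(calls))
  for (r in rules) {
    trig <- switch(r,
      pass_only = calls$filter_flag != "PASS",
      frequency = !is.na(calls$freq_count) & calls$freq_count > 0,
      small_intergenic = !is.na(calls$genic) & !calls$genic &
        !is.na(calls$size_bp) & calls$size_bp < small_size,
      min_support = calls$supporting_pairs + calls$split_reads < min_support)
    reason[is.na(reason) & trig] <- r
  }
  removed <- calls[!is.na(reason), , drop = FALSE]
  removed$filtered_reason <- reason[!is.na(reason)]
  list(kept = calls[is.na(reason), , drop = FALSE], removed = removed)
}

#' Rank calls for manual review
#'
#' Stable deterministic ordering by (i) population frequency
#' ascending, (ii) supporting read pairs descending, (iii) size in
#' base pairs descending for intrachromosomal calls, with remaining
#' ties broken by chromosomal position.
#'
#' @param calls Call `data.frame` with `freq_count` annotated
#'   (`NA` treated as 0).
#' @param genome A [genome_build()] for chromosome ordering.
#' @return `calls` reordered, with a `rank` column prepended.
#' @export
rank_calls <- function(calls, genome) {
  freq <- ifelse(is.na(calls$freq_count), 0, calls$freq_count)
  size <- ifelse(is.na(calls$size_bp), 0, calls$size_bp)
  ord <- order(freq, -calls$supporting_pairs, -size,
               chrom_rank(genome, calls$chrA), calls$posA)
  out <- calls[ord, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Confirm CNVs with an orthogonal platform
#'
#' A CNV found by both aCGH and at least one WGS technology is
#' considered a true positive; all other aCGH CNVs are assumed false.
#' Returns the confirmed subset of the aCGH calls - the truth-set
#' denominator for sensitivity estimates.
#'
#' @param acgh A [callset()] of DEL/DUP calls from aCGH.
#' @param wgs_sets List of [callset()]s from WGS technologies.
#' @param params A [match_params()].
#' @return A [callset()] with the confirmed aCGH calls.
#' @export
confirm_with_orthogonal <- function(acgh, wgs_sets, params = match_params()) {
  stopifnot(all(acgh$calls$sv_type %in% c("DEL", "DUP")))
  a <- acgh$calls
  conf <- vapply(seq_len(nrow(a)), function(i)
    any(vapply(wgs_sets, function(ws)
      any(similar_to_call(a[i, ], ws$calls, params)), FALSE)), FALSE)
  out <- acgh
  out$calls <- a[conf, , drop = FALSE]
  out
}
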