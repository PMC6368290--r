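#' Match truth junctions against a call set
#'
#' Builds one column of a detection table: each truth junction is
#' assigned its nearest candidate call (by summed end distance) with
#' the matching chromosome pair and both ends within the assignment
#' window; in relaxed mode one end may drift up to `slack_bp` as long
#' as the other is inside the window (technologies with kb-scale
#' resolution occasionally report one end far off while clearly
#' describing the same junction).  Unassigned junctions are reported
#' missing.
#'
#' @param truth_junctions A [junction_table()].
#' @param cs A [callset()] (normalized).
#' @param assign_window_bp Per-end assignment window (default 100 kb).
#' @param slack_bp Optional relaxed-mode slack for one end.
#' @return `data.frame` with `junction_id`, reported `start`/`stop`
#'   (`NA` when missed), distances `dist_start`/`dist_stop`, and
#'   `split_read_support`.
#' @export
match_truth_junctions <- function(truth_junctions, cs,
                                  assign_window_bp = 1e5, slack_bp = NULL) {
  j <- orient_junction_ends(as.data.frame(truth_junctions), cs$genome)
  calls <- cs$calls
  out <- data.frame(junction_id = j$id, start = NA_real_, stop = NA_real_,
                    dist_start = NA_real_, dist_stop = NA_real_,
                    split_read_support = FALSE, stringsAsFactors = FALSE)
  if (nrow(j) == 0 || nrow(calls) == 0) return(out)
  for (i in seq_len(nrow(j))) {
    cand <- which(calls$chrA == j$chrA[i] & calls$chrB == j$chrB[i])
    if (!length(cand)) next
    dA <- abs(calls$posA[cand] - j$posA[i])
    dB <- abs(calls$posB[cand] - j$posB[i])
    ok <- dA <= assign_window_bp & dB <= assign_window_bp
    if (!is.null(slack_bp))
      ok <- ok | (pmin(dA, dB) <= assign_window_bp & pmax(dA, dB) <= slack_bp)
    if (!any(ok)) next
    k <- cand[ok][which.min((dA + dB)[ok])]
    out$start[i] <- calls$posA[k]; out$stop[i] <- calls$posB[k]
    out$dist_start[i] <- abs(calls$posA[k] - j$posA[i])
    out$dist_stop[i] <- abs(calls$posB[k] - j$posB[i])
    out$split_read_support[i] <- calls$split_reads[k] > 0
  }
  out
}

# put truth junction ends in normalized call order (chrA/posA lower)
orient_junction_ends <- function(j, genome) {
  if (nrow(j) == 0) return(j)
  swap <- chrom_rank(genome, j$chrA) > chrom_rank(genome, j$chrB) |
    (j$chrA == j$chrB & j$posA > j$posB)
  tmpc <- j$chrA[swap]; tmpp <- j$posA[swap]
  j$chrA[swap] <- j$chrB[swap]; j$posA[swap] <- j$posB[swap]
  j$chrB[swap] <- tmpc; j$posB[swap] <- tmpp
  j
}

#' Build a detection table from truth junctions and call sets
#'
#' The machine twin of a per-junction, per-technology comparison
#' table: one row per truth junction, with the reported coordinates of
#' each source (or `NA` when the junction was not identified).
#'
#' @param truth_junctions A [junction_table()]; an `estimated` column
#'   flags approximately-localized junctions.
#' @param callsets Named list of [callset()]s.
#' @param case Case label for all rows.
#' @inheritParams match_truth_junctions
#' @return Wide `data.frame` with attribute `sources`.
#' @export
detection_table <- function(truth_junctions, callsets, case = 1,
                            assign_window_bp = 1e5, slack_bp = NULL) {
  genome <- callsets[[1]]$genome
  j <- orient_junction_ends(as.data.frame(truth_junctions), genome)
  out <- data.frame(case = case, jct = j$id, chrA = j$chrA,
                    truth_start = j$posA, chrB = j$chrB,
                    truth_stop = j$posB,
                    stringsAsFactors = FALSE)
  for (src in names(callsets)) {
    m <- match_truth_junctions(truth_junctions, callsets[[src]],
                               assign_window_bp, slack_bp)
    out[[paste0(src, "_start")]] <- m$start
    out[[paste0(src, "_stop")]] <- m$stop
  }
  out$estimated <- if ("estimated" %in% names(j)) j$estimated else FALSE
  attr(out, "sources") <- names(callsets)
  out
}

source_cols <- function(table, source) {
  cols <- paste0(source, c("_start", "_stop"))
  miss <- setdiff(cols, names(table))
  if (length(miss)) stop("detection table has no columns for source '", source, "'")
  cols
}

#' Detection and false-negative statistics from a detection table
#'
#' `detection_rate` counts detected / total truth junctions for one
#' source (optionally within cases); `fn_rate` is the rounded
#' percentage of missed junctions.  A junction counts as detected when
#' its reported start is present.  Detected + missed always equals the
#' number of truth junctions.
#'
#' @param table A [detection_table()] (or the packaged
#'   [detection_fixture()]).
#' @param source Source label (e.g. `"mp"`).
#' @param case Optional case filter.
#' @return `detection_rate`: list with `detected`, `total`;
#'   `fn_rate`: list with `missed`, `total`, `pct`.
#' @export
detection_rate <- function(table, source, case = NULL) {
  if (!is.null(case)) table <- table[table$case %in% case, , drop = FALSE]
  det <- !is.na(table[[source_cols(table, source)[1]]])
  list(detected = sum(det), total = nrow(table))
}

#' @rdname detection_rate
#' @export
fn_rate <- function(table, source) {
  d <- detection_rate(table, source)
  missed <- d$total - d$detected
  list(missed = missed, total = d$total,
       pct = round(100 * missed / d$total))
}

#' Median breakpoint resolution of a technology
#'
#' Resolution is the median distance between the reported calls and
#' the exact breakpoint position: absolute per-end distances are
#' pooled over both ends of every detected junction (junctions
#' flagged `estimated` are excluded - their "exact" position is
#' itself uncertain) and the median of the pool is returned.
#' `format_resolution()` renders it the way such tables print it: to
#' the nearest 100 bp below 1 kb, else kb with one decimal.
#'
#' @inheritParams detection_rate
#' @return Median distance in bp (`NA` with a warning when nothing
#'   was detected).
#' @export
resolution_median <- function(table, source) {
  cols <- source_cols(table, source)
  d <- table[!table$estimated, , drop = FALSE]
  pool <- c(abs(d[[cols[1]]] - d$truth_start),
            abs(d[[cols[2]]] - d$truth_stop))
  pool <- pool[!is.na(pool)]
  if (!length(pool)) {
    warning("no detected junctions for source '", source, "': resolution undefined")
    return(NA_real_)
  }
  stats::median(pool)
}

#' @rdname resolution_median
#' @param bp Resolution in bp.
#' @export
format_resolution <- function(bp) {
  ifelse(is.na(bp), "N.i.",
    ifelse(bp >= 1000, sprintf("%.1fkb", bp / 1000),
      ifelse(bp >= 100, sprintf("%dbp", 100 * round(bp / 100)),
        sprintf("%dbp", round(bp)))))
}

#' Sensitivity against an orthogonally confirmed truth set
#'
#' Fraction of the confirmed CNVs (see [confirm_with_orthogonal()])
#' that a call set detects under the similarity criterion, rounded to
#' two decimals.
#'
#' @param confirmed_truth A [callset()] of confirmed CNVs.
#' @param cs The evaluated [callset()].
#' @param params A [match_params()].
#' @return List with `detected`, `total`, `sensitivity`.
#' @export
sensitivity_vs_confirmed <- function(confirmed_truth, cs, params = match_params()) {
  a <- confirmed_truth$calls
  if (nrow(a) == 0) stop("empty confirmed truth set: sensitivity undefined")
  hit <- vapply(seq_len(nrow(a)), function(i)
    any(similar_to_call(a[i, ], cs$calls, params)), FALSE)
  list(detected = sum(hit), total = nrow(a),
       sensitivity = round(sum(hit) / nrow(a), 2))
}

#' Size and type distribution of a call set
#'
#' Histogram of call sizes over the standard bins (<1 kb, 1-10 kb,
#' 10-100 kb, >100 kb; percentages over sized calls) plus per-type
#' counts (BND and other unsized calls counted separately in the type
#' table only).
#'
#' @param cs A [callset()].
#' @param breaks Bin boundaries in bp.
#' @return List with `size_bins` (`data.frame`: bin, n, pct) and
#'   `type_counts` (named integer vector summing to the set size).
#' @export
size_type_distribution <- function(cs, breaks = c(0, 1e3, 1e4, 1e5, Inf)) {
  calls <- cs$calls
  labs <- c("<1kb", "1-10kb", "10-100kb", ">100kb")
  sized <- calls$size_bp[!is.na(calls$size_bp) & calls$sv_type != "BND"]
  n <- as.integer(table(cut(sized, breaks, labels = labs, right = FALSE)))
  pct <- if (length(sized)) round(100 * n / length(sized), 1) else rep(0, length(labs))
  type_counts <- table(factor(calls$sv_type, levels = SV_TYPES))
  list(size_bins = data.frame(bin = labs, n = n, pct = pct),
       type_counts = stats::setNames(as.integer(type_counts), SV_TYPES))
}

#' Concordance with a public variant dataset
#'
#' Both call sets are split per variant type and matching is done
#' within type only (a deletion never matches a public duplication):
#' counts of calls similar to at least one public variant of the same
#' type.
#'
#' @param cs The evaluated [callset()].
#' @param public_set A [callset()] from [read_public_dataset()].
#' @param params A [match_params()]; `per_type` is forced on.
#' @return `data.frame` with `sv_type`, `n_calls`, `n_matched`.
#' @export
public_concordance <- function(cs, public_set, params = match_params()) {
  params$per_type <- TRUE
  types <- sort(unique(cs$calls$sv_type))
  rows <- lapply(types, function(tp) {
    a <- cs$calls[cs$calls$sv_type == tp, , drop = FALSE]
    b <- public_set$calls[public_set$calls$sv_type == tp, , drop = FALSE]
    hit <- if (nrow(b)) vapply(seq_len(nrow(a)), function(i)
      any(similar_to_call(a[i, ], b, params)), FALSE) else rep(FALSE, nrow(a))
    data.frame(sv_type = tp, n_calls = nrow(a), n_matched = sum(hit))
  })
  do.call(rbind, rows)
}
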