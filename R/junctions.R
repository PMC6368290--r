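#' Build a breakpoint-junction table
#'
#' A junction is the novel adjacency joining two breakends in a
#' derivative chromosome; it is the atom of the whole analysis.  Each
#' row holds the two oriented breakends plus junction-level sequence
#' evidence.  Breakend orientation (`sideA`/`sideB`) records which
#' reference direction continues into the derivative at that end
#' (`"pter"` or `"qter"`); it is required for derivative reconstruction
#' but may be `NA` for junctions only used positionally.
#'
#' @param df `data.frame` with columns `chrA`, `posA`, `chrB`, `posB`;
#'   optional `id`, `sideA`, `sideB`, `mh` (microhomology string),
#'   `ins` (inserted sequence), `estimated` (logical: breakpoint only
#'   approximately localized), `repeatA`, `repeatB`.
#' @param genome A [genome_build()] used for validation.
#' @return A `data.frame` of class `ccr_junctions`.
#' @export
junction_table <- function(df, genome) {
  df <- as.data.frame(df)
  need <- c("chrA", "posA", "chrB", "posB")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("junctions missing column(s): ", paste(miss, collapse = ", "))
  defaults <- list(id = NA_character_, sideA = NA_character_,
                   sideB = NA_character_, mh = "", ins = "",
                   estimated = FALSE, repeatA = NA_character_,
                   repeatB = NA_character_)
  for (nm in names(defaults))
    if (!nm %in% names(df)) df[[nm]] <- rep(defaults[[nm]], nrow(df))
  if (nrow(df) > 0 && any(is.na(df$id)))
    df$id <- ifelse(is.na(df$id), sprintf("jct_%d", seq_len(nrow(df))), df$id)
  df$chrA <- as.character(df$chrA); df$chrB <- as.character(df$chrB)
  viol <- validate_junctions(df, genome)
  if (length(viol)) stop("invalid junctions:\n  ", paste(viol, collapse = "\n  "))
  class(df) <- c("ccr_junctions", "data.frame")
  attr(df, "genome") <- genome
  df
}

junction_endpoints <- function(junctions) {
  if (nrow(junctions) == 0)
    return(data.frame(junction_id = character(), end = character(),
                      chrom = character(), pos = numeric(),
                      side = character(), stringsAsFactors = FALSE))
  data.frame(
    junction_id = rep(junctions$id, 2L),
    end = rep(c("A", "B"), each = nrow(junctions)),
    chrom = c(junctions$chrA, junctions$chrB),
    pos = c(junctions$posA, junctions$posB),
    side = c(as.character(junctions$sideA), as.character(junctions$sideB)),
    stringsAsFactors = FALSE)
}

#' Cluster junction endpoints into breakpoints
#'
#' The two sides of one physical breakpoint are reported at slightly
#' different coordinates by different junctions (microhomology and
#' micro-losses of a few bp), so the number of distinct breakpoints is
#' obtained by single-linkage clustering of all junction endpoints per
#' chromosome: endpoints closer than the tolerance chain into one
#' cluster.  The cluster count is the breakpoint count reported for a
#' rearrangement.  The result is invariant under permutation of the
#' input junctions.
#'
#' @param junctions A [junction_table()].
#' @param tolerance_bp Single-linkage distance (default 200 bp).
#' @return List with `clusters` (one row per breakpoint: `cluster_id`,
#'   `chrom`, `representative_pos` = median of members, `n_members`)
#'   and `members` (endpoint-to-cluster assignment).
#' @export
cluster_breakpoints <- function(junctions, tolerance_bp = 200) {
  ep <- junction_endpoints(junctions)
  ep <- ep[order(chrom_sort_key(ep$chrom), ep$pos), , drop = FALSE]
  if (nrow(ep) == 0) {
    return(list(clusters = data.frame(cluster_id = integer(),
                                      chrom = character(),
                                      representative_pos = numeric(),
                                      n_members = integer()),
                members = cbind(ep, cluster_id = integer())))
  }
  new_chrom <- c(TRUE, ep$chrom[-1] != ep$chrom[-nrow(ep)])
  gap <- c(Inf, diff(ep$pos))
  ep$cluster_id <- cumsum(new_chrom | gap > tolerance_bp)
  cl <- do.call(rbind, lapply(split(ep, ep$cluster_id), function(d) {
    data.frame(cluster_id = d$cluster_id[1], chrom = d$chrom[1],
               representative_pos = stats::median(d$pos),
               n_members = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(cl) <- NULL
  list(clusters = cl, members = ep)
}

# numeric-aware chromosome ordering ("2" before "10", X/Y after)
chrom_sort_key <- function(chrom) {
  n <- suppressWarnings(as.numeric(chrom))
  key <- ifelse(is.na(n), 1000 + match(chrom, sort(unique(chrom))), n)
  key
}

longest_common_prefix <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0) return(0L)
  av <- utf8ToInt(substr(a, 1, n)); bv <- utf8ToInt(substr(b, 1, n))
  d <- which(av != bv)
  if (length(d) == 0) n else d[1] - 1L
}

#' Classify a breakpoint junction at the nucleotide level
#'
#' Given the two reference flanks (each oriented as traversed in the
#' derivative: `flankA` ends at breakpoint A, `flankB` starts at
#' breakpoint B) and the sequenced derivative junction, decides whether
#' the join is blunt, carries microhomology (a sequence shared verbatim
#' by both reference flanks abutting their breakpoints), or carries a
#' non-templated insertion.  Microhomology and insertion are mutually
#' exclusive: when both parses exist the one with the shorter total
#' insertion wins, ties going to microhomology.  Homology longer than
#' the search window is treated as unresolvable (likely
#' repeat-mediated) and reported as an error, as is a derivative not
#' anchored by both flanks.
#'
#' @param flankA,flankB Reference flank sequences (A,C,G,T).
#' @param derivative_seq Sequence across the junction in the derivative.
#' @param window Maximum microhomology / insertion length considered
#'   (default 50 nt).
#' @return List with `category` (`"blunt"`, `"microhomology"`,
#'   `"insertion"`), `mh_seq`, `ins_seq`.
#' @export
detect_microhomology <- function(flankA, flankB, derivative_seq, window = 50) {
  D <- nchar(derivative_seq)
  p <- longest_common_prefix(derivative_seq, flankA)
  rev_s <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
  s <- longest_common_prefix(rev_s(derivative_seq), rev_s(flankB))
  if (p == 0 || s == 0 || (D - p - s) > window)
    stop("unresolvable junction: derivative sequence not anchored by both flanks within window")
  m <- p + s - D
  if (m > window)
    stop("unresolvable junction: homology longer than search window (", window, " nt)")
  if (m > 0) {
    list(category = "microhomology",
         mh_seq = substr(derivative_seq, p - m + 1, p), ins_seq = "")
  } else if (m == 0) {
    list(category = "blunt", mh_seq = "", ins_seq = "")
  } else {
    list(category = "insertion", mh_seq = "",
         ins_seq = substr(derivative_seq, p + 1, D - s))
  }
}

#' Annotate breakends with nearby repeats
#'
#' Reports every repeat element whose interval intersects the closed
#' window `[pos - window_bp, pos + window_bp]` around a breakend.  In
#' junction tables an empty result is rendered `"-"`.
#'
#' @param chrom,pos Breakend coordinate (vectors recycle).
#' @param repeat_track `data.frame` with `chrom`, `start`, `end`,
#'   `name` (e.g. from [read_bed_track()] or
#'   [generate_repeat_track()]).
#' @param window_bp Window half-width, default 100 bp (closed at the
#'   boundary).
#' @return List (one element per breakend) of repeat name vectors.
#' @export
annotate_repeat_context <- function(chrom, pos, repeat_track, window_bp = 100) {
  chrom <- as.character(chrom)
  if (is.null(repeat_track) || nrow(repeat_track) == 0)
    return(rep(list(character()), length(pos)))
  q <- IRanges::IRanges(start = pmax(1, pos - window_bp), end = pos + window_bp)
  s <- IRanges::IRanges(start = repeat_track$start, end = repeat_track$end)
  hits <- IRanges::findOverlaps(q, s)
  out <- rep(list(character()), length(pos))
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  keep <- chrom[qh] == as.character(repeat_track$chrom)[sh]
  for (k in which(keep)) out[[qh[k]]] <- c(out[[qh[k]]], repeat_track$name[sh[k]])
  out
}

render_repeat <- function(x) if (length(x) == 0) "-" else paste(unique(x), collapse = ",")

#' Summarize junctions as a publication-style table
#'
#' One row per junction with microhomology, insertion, repeat context
#' within 100 bp of each breakend, and the gene disrupted by each
#' breakend (disease-flagged genes marked with `*`).  Junctions flagged
#' `estimated` have their sequence columns rendered `"N.i."` (the
#' breakpoint is only approximately localized, so junction-level
#' sequence is not informative).  Rows are ordered by (chromosome,
#' lower position).
#'
#' @param junctions A [junction_table()].
#' @param repeat_track,gene_track Optional annotation tracks
#'   (`data.frame`s with `chrom`, `start`, `end`, `name`; gene tracks
#'   may carry `disease_flag`).
#' @return `data.frame` with columns `jct`, `chrA`, `posA`, `chrB`,
#'   `posB`, `mh`, `insertion`, `repeat_context`, `geneA`, `geneB`.
#' @export
summarize_junctions <- function(junctions, repeat_track = NULL, gene_track = NULL) {
  out <- data.frame(jct = junctions$id,
                    chrA = junctions$chrA, posA = junctions$posA,
                    chrB = junctions$chrB, posB = junctions$posB,
                    stringsAsFactors = FALSE)
  blank <- function(x) ifelse(is.na(x) | x == "", "-", x)
  out$mh <- blank(junctions$mh)
  out$insertion <- blank(junctions$ins)
  if (any(junctions$estimated)) {
    out$mh[junctions$estimated] <- "N.i."
    out$insertion[junctions$estimated] <- "N.i."
  }
  repA <- annotate_repeat_context(out$chrA, out$posA, repeat_track)
  repB <- annotate_repeat_context(out$chrB, out$posB, repeat_track)
  out$repeat_context <- paste(vapply(repA, render_repeat, ""),
                              vapply(repB, render_repeat, ""), sep = "/")
  gene_at <- function(chrom, pos) {
    if (is.null(gene_track) || nrow(gene_track) == 0)
      return(rep("-", length(pos)))
    hit <- annotate_repeat_context(chrom, pos, gene_track, window_bp = 0)
    flagged <- vapply(hit, function(g) {
      if (length(g) == 0) return("-")
      fl <- gene_track$disease_flag[match(g, gene_track$name)]
      paste(ifelse(!is.na(fl) & fl, paste0("*", g, "*"), g), collapse = ",")
    }, "")
    flagged
  }
  out$geneA <- gene_at(out$chrA, out$posA)
  out$geneB <- gene_at(out$chrB, out$posB)
  ord <- order(chrom_sort_key(out$chrA), pmin(out$posA, out$posB))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
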