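#' Build a breakpoint graph from a junction set
#'
#' Every involved chromosome is cut at each breakpoint cluster, giving
#' segment nodes; junction records attach pairs of segment ends
#' (respecting breakend orientation), and chromosome ends provide
#' telomere nodes.  Because the two sides of one breakpoint are
#' reported at slightly different coordinates, segment boundaries use
#' the per-side breakend position where one is available (micro-losses
#' of a few bp at junctions then fall out of the conservation
#' accounting naturally).
#'
#' @param junctions A [junction_table()] whose breakends all carry
#'   `sideA`/`sideB` orientations.
#' @param genome A [genome_build()].
#' @param tolerance_bp Clustering tolerance passed to
#'   [cluster_breakpoints()].
#' @return An object of class `ccr_bpgraph`.
#' @export
build_breakpoint_graph <- function(junctions, genome, tolerance_bp = 200) {
  ep <- junction_endpoints(junctions)
  if (nrow(ep) > 0 && any(is.na(ep$side) | !ep$side %in% c("pter", "qter")))
    stop("all breakends need a retained side ('pter'/'qter') for reconstruction")
  cb <- cluster_breakpoints(junctions, tolerance_bp)
  mem <- cb$members
  segs <- list(); attach_err <- character()
  # with no junctions at all, the graph is the intact reference
  chrom_set <- if (nrow(mem) == 0) genome$chromosomes$name else unique(mem$chrom)
  for (chrom in chrom_set) {
    m <- mem[mem$chrom == chrom, , drop = FALSE]
    cl_ids <- sort(unique(m$cluster_id))
    K <- length(cl_ids)
    L <- chrom_length(genome, chrom)
    rep_pos <- cb$clusters$representative_pos[match(cl_ids, cb$clusters$cluster_id)]
    # segment s (1..K+1) spans clusters s-1 and s (0 = pter, K+1 = qter)
    sg <- data.frame(chrom = chrom, seg = seq_len(K + 1),
                     lower = NA_real_, upper = NA_real_,
                     lower_jct = NA_character_, lower_endlab = NA_character_,
                     upper_jct = NA_character_, upper_endlab = NA_character_,
                     stringsAsFactors = FALSE)
    sg$lower[1] <- 1; sg$upper[K + 1] <- L
    for (j in seq_len(K)) {
      at <- m[m$cluster_id == cl_ids[j], , drop = FALSE]
      up <- at[at$side == "pter", , drop = FALSE]   # ends segment j
      lo <- at[at$side == "qter", , drop = FALSE]   # starts segment j+1
      if (nrow(up) > 1)
        attach_err <- c(attach_err, sprintf(
          "chromosome %s cluster at %s: upper segment end claimed by junctions %s",
          chrom, format(rep_pos[j], scientific = FALSE),
          paste(up$junction_id, collapse = ", ")))
      if (nrow(lo) > 1)
        attach_err <- c(attach_err, sprintf(
          "chromosome %s cluster at %s: lower segment end claimed by junctions %s",
          chrom, format(rep_pos[j], scientific = FALSE),
          paste(lo$junction_id, collapse = ", ")))
      sg$upper[j] <- if (nrow(up)) up$pos[1] else rep_pos[j]
      sg$lower[j + 1] <- if (nrow(lo)) lo$pos[1] else rep_pos[j] + 1
      if (nrow(up)) { sg$upper_jct[j] <- up$junction_id[1]; sg$upper_endlab[j] <- up$end[1] }
      if (nrow(lo)) { sg$lower_jct[j + 1] <- lo$junction_id[1]; sg$lower_endlab[j + 1] <- lo$end[1] }
    }
    segs[[chrom]] <- sg
  }
  if (length(attach_err))
    stop("ambiguous junction set:\n  ", paste(attach_err, collapse = "\n  "))
  segs <- if (length(segs)) do.call(rbind, segs) else
    data.frame(chrom = character(), seg = integer(), lower = numeric(),
               upper = numeric(), lower_jct = character(),
               lower_endlab = character(), upper_jct = character(),
               upper_endlab = character(), stringsAsFactors = FALSE)
  rownames(segs) <- NULL
  structure(list(segments = segs, junctions = junctions,
                 endpoints = ep, genome = genome),
            class = "ccr_bpgraph")
}

#' @export
print.ccr_bpgraph <- function(x, ...) {
  cat("<ccr_bpgraph>", nrow(x$segments), "segments on",
      length(unique(x$segments$chrom)), "chromosome(s),",
      nrow(x$junctions), "junctions\n")
  invisible(x)
}

# locate the segment row owning the partner breakend of a junction end
partner_attachment <- function(graph, jct_id, end_used) {
  other <- if (end_used == "A") "B" else "A"
  sg <- graph$segments
  i <- which(sg$lower_jct == jct_id & sg$lower_endlab == other)
  if (length(i)) return(list(row = i[1], entry = "lower"))
  i <- which(sg$upper_jct == jct_id & sg$upper_endlab == other)
  if (length(i)) return(list(row = i[1], entry = "upper"))
  stop("junction ", jct_id, ": partner breakend is attached to no segment end ",
       "(malformed junction set)")
}

#' Walk a breakpoint graph into derivative chromosomes
#'
#' Starting at each unconsumed telomere, the walk alternates segment
#' traversals and junction adjacencies until another telomere is
#' reached; fragments pick up their orientation from the traversal
#' direction.  Closed walks that never touch a telomere are returned
#' as ring derivatives.  Segments attached to no junction and no
#' telomere are the deleted fragments (recovered by
#' [infer_deleted_intervals()]).  Each derivative is canonicalized so
#' its anchor telomere begins the longest unbroken reference run.
#'
#' @param graph A [build_breakpoint_graph()] result.
#' @return List of `ccr_derivative` objects (`name`, `ring`,
#'   `fragments` data.frame with `chrom`, `start`, `end`, `orient`
#'   (`"+"` forward / `"-"` inverted), `label`).
#' @export
walk_derivatives <- function(graph) {
  sg <- graph$segments
  consumed <- rep(FALSE, nrow(sg))
  genome <- graph$genome
  chroms <- genome$chromosomes$name[genome$chromosomes$name %in% sg$chrom]

  do_walk <- function(row, entry, expect_ring = FALSE) {
    frags <- list(); start_row <- row; start_entry <- entry
    repeat {
      if (consumed[row]) {
        if (expect_ring && row == start_row && entry == start_entry)
          return(list(frags = frags, ring = TRUE))
        stop("walk re-entered a consumed segment without closing a ring ",
             "(malformed junction set)")
      }
      consumed[row] <<- TRUE
      orient <- if (entry == "lower") "+" else "-"
      frags[[length(frags) + 1]] <-
        data.frame(chrom = sg$chrom[row], start = sg$lower[row],
                   end = sg$upper[row], orient = orient,
                   stringsAsFactors = FALSE)
      exit <- if (entry == "lower") "upper" else "lower"
      jct <- if (exit == "upper") sg$upper_jct[row] else sg$lower_jct[row]
      if (is.na(jct)) {
        chrom_sg <- sg[sg$chrom == sg$chrom[row], ]
        at_telomere <- (exit == "lower" && sg$seg[row] == 1) ||
          (exit == "upper" && sg$seg[row] == max(chrom_sg$seg))
        if (!at_telomere)
          stop("walk dead-ends at an internal segment boundary on chromosome ",
               sg$chrom[row], " (junction missing from the set?)")
        if (expect_ring)
          stop("ring walk reached a telomere (inconsistent junction set)")
        return(list(frags = frags, ring = FALSE))
      }
      endlab <- if (exit == "upper") sg$upper_endlab[row] else sg$lower_endlab[row]
      nxt <- partner_attachment(graph, jct, endlab)
      row <- nxt$row; entry <- nxt$entry
    }
  }

  derivs <- list()
  for (chrom in chroms) {
    rows <- which(sg$chrom == chrom)
    first <- rows[which.min(sg$seg[rows])]
    last <- rows[which.max(sg$seg[rows])]
    if (!consumed[first])
      derivs[[length(derivs) + 1]] <- do_walk(first, "lower")
    if (!consumed[last])
      derivs[[length(derivs) + 1]] <- do_walk(last, "upper")
  }
  # remaining junction-bearing segments close into rings
  repeat {
    left <- which(!consumed & (!is.na(sg$lower_jct) | !is.na(sg$upper_jct)))
    if (!length(left)) break
    derivs[[length(derivs) + 1]] <- do_walk(left[1], "lower", expect_ring = TRUE)
  }

  out <- lapply(derivs, function(d) {
    fr <- do.call(rbind, d$frags); rownames(fr) <- NULL
    canonicalize_derivative(
      structure(list(name = NA_character_, ring = d$ring, fragments = fr),
                class = "ccr_derivative"),
      genome)
  })
  ord <- order(vapply(out, function(d) chrom_rank(genome, d$fragments$chrom[1]), 0),
               vapply(out, function(d) d$fragments$start[1], 0),
               vapply(out, function(d) d$ring, FALSE))
  out <- out[ord]
  lab <- 0L
  for (i in seq_along(out)) {
    n <- nrow(out[[i]]$fragments)
    out[[i]]$fragments$label <- fragment_labels(lab + seq_len(n))
    lab <- lab + n
    out[[i]]$name <- paste0("der(", out[[i]]$fragments$chrom[1], ")",
                            if (out[[i]]$ring) "ring" else "")
  }
  nms <- vapply(out, function(d) d$name, "")
  dup <- duplicated(nms) | duplicated(nms, fromLast = TRUE)
  if (any(dup)) for (i in which(dup)) out[[i]]$name <- sprintf("%s.%d", out[[i]]$name, i)
  out
}

fragment_labels <- function(i) {
  # A..Z then a..z then A1..; matches the case-study figure convention
  pool <- c(LETTERS, letters)
  ifelse(i <= length(pool), pool[pmin(i, length(pool))],
         paste0(pool[((i - 1) %% length(pool)) + 1], (i - 1) %/% length(pool)))
}

# re-anchor a derivative so the longest terminal reference run comes first
canonicalize_derivative <- function(d, genome) {
  if (d$ring || nrow(d$fragments) <= 1) return(d)
  runs <- merge_deletion_runs(d$fragments)$fragments
  first_len <- runs$end[1] - runs$start[1]
  n <- nrow(runs)
  last_len <- runs$end[n] - runs$start[n]
  flip <- last_len > first_len ||
    (last_len == first_len &&
       chrom_rank(genome, runs$chrom[n]) < chrom_rank(genome, runs$chrom[1]))
  if (flip) {
    fr <- d$fragments[rev(seq_len(nrow(d$fragments))), , drop = FALSE]
    fr$orient <- ifelse(fr$orient == "+", "-", "+")
    rownames(fr) <- NULL
    d$fragments <- fr
  }
  d
}

#' @export
print.ccr_derivative <- function(x, ...) {
  cat("<ccr_derivative>", x$name, if (x$ring) "(ring)" else "", "\n")
  print(x$fragments)
  invisible(x)
}

# merge consecutive same-chromosome, same-orientation fragments joined
# across a reference gap (interstitial deletion junction) or a rejoined
# cut; records the skipped breakend coordinates as a deletion token
merge_deletion_runs <- function(frags) {
  dels <- data.frame(chrom = character(), lo = numeric(), hi = numeric(),
                     after_row = integer(), stringsAsFactors = FALSE)
  i <- 1
  while (i < nrow(frags)) {
    a <- frags[i, ]; b <- frags[i + 1, ]
    mergeable <- a$chrom == b$chrom && a$orient == b$orient &&
      ((a$orient == "+" && b$start > a$end + 1) ||
       (a$orient == "-" && b$end < a$start - 1))
    if (mergeable) {
      if (a$orient == "+") {
        dels <- rbind(dels, data.frame(chrom = a$chrom, lo = a$end,
                                       hi = b$start, after_row = i))
        frags$end[i] <- b$end
      } else {
        dels <- rbind(dels, data.frame(chrom = a$chrom, lo = b$end,
                                       hi = a$start, after_row = i))
        frags$start[i] <- b$start
      }
      frags <- frags[-(i + 1), , drop = FALSE]
    } else i <- i + 1
  }
  rownames(frags) <- NULL
  list(fragments = frags, deletions = dels)
}

#' Infer deleted intervals from walked derivatives
#'
#' Per involved chromosome, the complement of all placed fragments:
#' what the walks never visit has been lost from the genome.  Adjacent
#' complements merge; placed fragments overlapping by more than the
#' clustering tolerance raise an inconsistency error (micro-overlaps
#' of a few bp arise legitimately from per-side breakpoint
#' coordinates).
#'
#' @param derivatives List of derivatives from [walk_derivatives()].
#' @param genome A [genome_build()].
#' @param tolerance_bp Maximum tolerated overlap between placed
#'   fragments (default 200 bp).
#' @return `data.frame` with `chrom`, `start`, `end`, `size_bp`.
#' @export
infer_deleted_intervals <- function(derivatives, genome, tolerance_bp = 200) {
  frags <- do.call(rbind, lapply(derivatives, function(d)
    d$fragments[, c("chrom", "start", "end")]))
  out <- list()
  for (chrom in unique(frags$chrom)) {
    f <- frags[frags$chrom == chrom, , drop = FALSE]
    f <- f[order(f$start, f$end), , drop = FALSE]
    L <- chrom_length(genome, chrom)
    cov_end <- 0
    for (i in seq_len(nrow(f))) {
      if (f$start[i] > cov_end + 1)
        out[[length(out) + 1]] <- data.frame(chrom = chrom,
                                             start = cov_end + 1,
                                             end = f$start[i] - 1)
      if (cov_end - f$start[i] > tolerance_bp)
        stop("placed fragments overlap by more than ", tolerance_bp,
             " bp on chromosome ", chrom, " near position ",
             format(f$start[i], scientific = FALSE))
      cov_end <- max(cov_end, f$end[i])
    }
    if (cov_end < L)
      out[[length(out) + 1]] <- data.frame(chrom = chrom, start = cov_end + 1, end = L)
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), size_bp = numeric()))
  res <- do.call(rbind, out)
  res <- res[order(chrom_sort_key(res$chrom), res$start), , drop = FALSE]
  res$size_bp <- res$end - res$start
  rownames(res) <- NULL
  res
}

#' Genes hit by intervals
#'
#' Intersection semantics: a gene is reported for an interval as soon
#' as the two overlap by at least one base (so genes straddling a
#' boundary are included).  Disease-flagged genes are marked.
#'
#' @param intervals `data.frame` with `chrom`, `start`, `end`.
#' @param gene_track `data.frame` with `chrom`, `start`, `end`, `name`,
#'   optional `disease_flag`.
#' @return List (one per interval row) of `data.frame`s with `name`,
#'   `disease_flag`.
#' @export
genes_in_intervals <- function(intervals, gene_track) {
  out <- rep(list(data.frame(name = character(), disease_flag = logical())),
             nrow(intervals))
  if (is.null(gene_track) || nrow(gene_track) == 0 || nrow(intervals) == 0)
    return(out)
  if (!"disease_flag" %in% names(gene_track)) gene_track$disease_flag <- FALSE
  q <- IRanges::IRanges(intervals$start, intervals$end)
  s <- IRanges::IRanges(gene_track$start, gene_track$end)
  hits <- IRanges::findOverlaps(q, s)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  keep <- as.character(intervals$chrom)[qh] == as.character(gene_track$chrom)[sh]
  for (k in which(keep)) {
    i <- qh[k]
    out[[i]] <- rbind(out[[i]],
                      data.frame(name = gene_track$name[sh[k]],
                                 disease_flag = gene_track$disease_flag[sh[k]]))
  }
  out
}

#' Reconstruct a rearrangement end to end
#'
#' Convenience wrapper: breakpoint graph, derivative walk, deleted
#' intervals and molecular karyotype string in one call.
#'
#' @inheritParams build_breakpoint_graph
#' @return List with `graph`, `derivatives`, `deleted_intervals`,
#'   `karyotype`.
#' @export
reconstruct_ccr <- function(junctions, genome, tolerance_bp = 200) {
  graph <- build_breakpoint_graph(junctions, genome, tolerance_bp)
  derivatives <- walk_derivatives(graph)
  deleted <- infer_deleted_intervals(derivatives, genome, tolerance_bp)
  list(graph = graph, derivatives = derivatives,
       deleted_intervals = deleted,
       karyotype = render_karyotype(derivatives, genome))
}
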