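#' Render derivative chromosomes as a molecular karyotype string
#'
#' Emits the `seq[<build>]` notation used to describe sequenced
#' rearrangements: one `g.[...]` block per derivative, segments joined
#' by `::`.  Telomere-anchored segments are written
#' `chrN:pter_cen_<pos>` / `chrN:qter_cen_<pos>` when they span the
#' centromere (plain `pter_<pos>` otherwise), terminal segments
#' `chrN:<pos>_qter` / `chrN:<pos>_pter`, internal segments
#' `chrN:<start>_<end>` with an `inv` suffix when inverted.
#'
#' Interstitial deletions - two same-chromosome, same-orientation runs
#' joined across a reference gap by a deletion junction - are collapsed
#' into a single run, and the skipped interval is annotated as
#' `<posA>_<posB>del` (the two junction breakend coordinates) inside
#' the block that carries that chromosome's centromere.  Ring
#' derivatives (closed walks) are rendered with a `ring` suffix, an
#' extension to the printed grammar.
#'
#' @param derivatives List of `ccr_derivative` objects
#'   ([walk_derivatives()]).
#' @param genome A [genome_build()].
#' @param deleted_intervals Ignored (accepted for interface symmetry;
#'   deletion annotations are derived from the walks themselves).
#' @return Single karyotype string.
#' @export
render_karyotype <- function(derivatives, genome, deleted_intervals = NULL) {
  merged <- lapply(derivatives, function(d) {
    m <- merge_deletion_runs(d$fragments)
    list(d = d, fragments = m$fragments, dels = m$deletions)
  })
  # locate, for each deletion token, the block/segment carrying the
  # centromere of the deleted chromosome; fall back to where it arose
  tokens <- list()
  for (bi in seq_along(merged)) {
    dl <- merged[[bi]]$dels
    for (k in seq_len(nrow(dl))) {
      target <- c(bi, dl$after_row[k])
      cen <- centromere_pos(genome, dl$chrom[k])
      if (!is.na(cen)) {
        for (bj in seq_along(merged)) {
          f <- merged[[bj]]$fragments
          hit <- which(f$chrom == dl$chrom[k] & f$start <= cen & f$end >= cen)
          if (length(hit)) { target <- c(bj, hit[1]); break }
        }
      }
      tokens[[length(tokens) + 1]] <-
        data.frame(chrom = dl$chrom[k], lo = dl$lo[k], hi = dl$hi[k],
                   block = target[1], after_seg = target[2])
    }
  }
  tokens <- if (length(tokens)) do.call(rbind, tokens) else NULL

  blocks <- vapply(seq_along(merged), function(bi) {
    f <- merged[[bi]]$fragments
    ring <- merged[[bi]]$d$ring
    segs <- vapply(seq_len(nrow(f)), function(i)
      segment_string(f[i, ], i, nrow(f), genome, ring), "")
    if (!is.null(tokens)) {
      tk <- tokens[tokens$block == bi, , drop = FALSE]
      if (nrow(tk)) {
        tk <- tk[order(tk$after_seg, tk$lo), , drop = FALSE]
        for (j in rev(seq_len(nrow(tk))))
          segs <- append(segs, sprintf("%s_%sdel",
                                       format(tk$lo[j], scientific = FALSE),
                                       format(tk$hi[j], scientific = FALSE)),
                         after = tk$after_seg[j])
      }
    }
    paste0("g.[", paste(segs, collapse = "::"), "]", if (ring) "ring" else "")
  }, "")
  paste(c(sprintf("seq[%s]", genome$build_name), blocks), collapse = " ")
}

segment_string <- function(f, i, n, genome, ring = FALSE) {
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  chrom <- f$chrom; cen <- centromere_pos(genome, chrom)
  L <- chrom_length(genome, chrom)
  whole <- f$start == 1 && f$end == L
  if (!ring) {
    if (i == 1 && whole) return(sprintf("chr%s:pter_qter", chrom))
    if (i == 1 && f$orient == "+" && f$start == 1) {
      mid <- if (!is.na(cen) && cen <= f$end) "pter_cen_" else "pter_"
      return(sprintf("chr%s:%s%s", chrom, mid, fmt(f$end)))
    }
    if (i == 1 && f$orient == "-" && f$end == L) {
      mid <- if (!is.na(cen) && cen >= f$start) "qter_cen_" else "qter_"
      return(sprintf("chr%s:%s%s", chrom, mid, fmt(f$start)))
    }
    if (i == n && f$orient == "+" && f$end == L)
      return(sprintf("chr%s:%s_qter", chrom, fmt(f$start)))
    if (i == n && f$orient == "-" && f$start == 1)
      return(sprintf("chr%s:%s_pter", chrom, fmt(f$end)))
  }
  sprintf("chr%s:%s_%s%s", chrom, fmt(f$start), fmt(f$end),
          if (f$orient == "-") "inv" else "")
}

#' Canonicalize karyotype whitespace
#'
#' The printed strings contain incidental spaces (e.g. after a colon);
#' comparisons are made on the whitespace-free form.
#'
#' @param x Karyotype string(s).
#' @return `x` with all whitespace removed.
#' @export
canonical_karyotype <- function(x) gsub("[[:space:]]+", "", x)

#' Parse a molecular karyotype string
#'
#' Inverse of [render_karyotype()] on canonical strings: recovers the
#' derivative fragment lists (order and orientation) and the annotated
#' deleted intervals.  Runs spanning an annotated deletion of their
#' chromosome are re-split around it, so
#' `parse_karyotype(render_karyotype(x))` reproduces fragment order
#' and orientation even though rendering collapses
#' interstitial-deletion runs.  A `<lo>_<hi>del` token takes its
#' chromosome from the nearest preceding segment in its block.
#'
#' @param text Karyotype string.
#' @param genome A [genome_build()].
#' @return List with `derivatives` (list of `ccr_derivative`),
#'   `deleted_intervals` (`data.frame` of junction-flank coordinate
#'   pairs `chrom`, `lo`, `hi`), `build`.
#' @export
parse_karyotype <- function(text, genome) {
  s <- canonical_karyotype(text)
  build <- NA_character_
  m <- regexpr("^seq\\[([^]]*)\\]", s)
  if (m == 1) {
    build <- sub("^seq\\[([^]]*)\\].*$", "\\1", s)
    s <- substr(s, attr(m, "match.length") + 1, nchar(s))
  }
  block_re <- "g\\.\\[[^]]*\\](ring)?"
  blocks <- regmatches(s, gregexpr(block_re, s))[[1]]
  if (!length(blocks)) stop("no g.[...] blocks found in karyotype string")
  dels <- data.frame(chrom = character(), lo = numeric(), hi = numeric())
  derivs <- list()
  for (b in blocks) {
    ring <- grepl("\\]ring$", b)
    inner <- sub("^g\\.\\[", "", sub("\\](ring)?$", "", b))
    toks <- strsplit(inner, "::", fixed = TRUE)[[1]]
    frags <- list(); ctx_chrom <- NA_character_; pend_del <- list()
    for (ti in seq_along(toks)) {
      tok <- toks[ti]
      if (grepl("^[0-9]+_[0-9]+del$", tok)) {
        v <- as.numeric(strsplit(sub("del$", "", tok), "_")[[1]])
        pend_del[[length(pend_del) + 1]] <- list(chrom = ctx_chrom, lo = v[1], hi = v[2], idx = ti)
        next
      }
      f <- parse_segment(tok, genome, ti)
      ctx_chrom <- f$chrom
      frags[[length(frags) + 1]] <- f
    }
    fr <- do.call(rbind, frags)
    for (pd in pend_del) {
      chrom <- pd$chrom
      if (is.na(chrom)) chrom <- fr$chrom[1]   # token preceded no segment
      dels <- rbind(dels, data.frame(chrom = chrom, lo = pd$lo, hi = pd$hi))
    }
    derivs[[length(derivs) + 1]] <-
      structure(list(name = paste0("der(", fr$chrom[1], ")", if (ring) "ring" else ""),
                     ring = ring, fragments = fr),
                class = "ccr_derivative")
  }
  # re-split runs spanning an annotated deletion
  if (nrow(dels)) {
    for (di in seq_len(nrow(dels))) {
      for (k in seq_along(derivs)) {
        fr <- derivs[[k]]$fragments
        hit <- which(fr$chrom == dels$chrom[di] &
                     fr$start < dels$lo[di] & fr$end > dels$hi[di])
        for (i in hit) {
          a <- fr[i, ]; lo <- dels$lo[di]; hi <- dels$hi[di]
          top <- a; bot <- a
          bot$end <- lo; top$start <- hi
          pieces <- if (a$orient == "+") rbind(bot, top) else rbind(top, bot)
          fr <- rbind(if (i > 1) fr[seq_len(i - 1), ], pieces,
                      if (i < nrow(fr)) fr[seq(i + 1, nrow(fr)), ])
          rownames(fr) <- NULL
        }
        derivs[[k]]$fragments <- fr
      }
    }
  }
  for (k in seq_along(derivs)) {
    n <- nrow(derivs[[k]]$fragments)
    derivs[[k]]$fragments$label <- fragment_labels(seq_len(n))
  }
  list(derivatives = derivs, deleted_intervals = dels, build = build)
}

parse_segment <- function(tok, genome, offset) {
  err <- function() stop(sprintf("malformed karyotype segment '%s' (segment %d)",
                                 tok, offset))
  m <- regexec("^chr([0-9A-Za-z]+):(.*)$", tok)[[1]]
  if (m[1] == -1) err()
  chrom <- sub("^chr([0-9A-Za-z]+):.*$", "\\1", tok)
  body <- sub("^chr[0-9A-Za-z]+:", "", tok)
  L <- chrom_length(genome, chrom)
  frag <- function(start, end, orient)
    data.frame(chrom = chrom, start = start, end = end, orient = orient,
               stringsAsFactors = FALSE)
  if (body == "pter_qter") return(frag(1, L, "+"))
  if (grepl("^pter_(cen_)?[0-9]+$", body))
    return(frag(1, as.numeric(sub("^pter_(cen_)?", "", body)), "+"))
  if (grepl("^qter_(cen_)?[0-9]+$", body))
    return(frag(as.numeric(sub("^qter_(cen_)?", "", body)), L, "-"))
  if (grepl("^[0-9]+_qter$", body))
    return(frag(as.numeric(sub("_qter$", "", body)), L, "+"))
  if (grepl("^[0-9]+_pter$", body))
    return(frag(1, as.numeric(sub("_pter$", "", body)), "-"))
  if (grepl("^[0-9]+_[0-9]+(inv)?$", body)) {
    inv <- grepl("inv$", body)
    v <- as.numeric(strsplit(sub("inv$", "", body), "_")[[1]])
    if (v[1] > v[2]) err()
    return(frag(v[1], v[2], if (inv) "-" else "+"))
  }
  err()
}
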