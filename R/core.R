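SV_TYPES <- c("DEL", "DUP", "INS", "INV", "BND", "UNKNOWN")

empty_calls <- function() {
  data.frame(id = character(), sv_type = character(),
             chrA = character(), posA = numeric(), sideA = character(),
             chrB = character(), posB = numeric(), sideB = character(),
             size_bp = numeric(), filter_flag = character(),
             supporting_pairs = numeric(), split_reads = numeric(),
             source = character(), freq_count = numeric(),
             genic = logical(), stringsAsFactors = FALSE)
}

#' Build a structural-variant call set
#'
#' A call set is a plain `data.frame` of technology-agnostic SV records
#' tagged with the technology (`source`) that produced them, together
#' with the genome they validate against.  Missing columns are filled
#' with defaults; calls are normalized (see [normalize_calls()]).
#'
#' @param calls `data.frame` with at least `sv_type`, `chrA`, `posA`,
#'   `chrB`, `posB`.  Optional: `id`, `sideA`/`sideB` (breakend
#'   orientation, `"pter"`/`"qter"`), `size_bp`, `filter_flag`,
#'   `supporting_pairs`, `split_reads`, `freq_count`, `genic`.
#' @param source Technology/pipeline label (e.g. `"pe"`, `"mp"`,
#'   `"optical"`, `"aCGH"`).
#' @param genome A [genome_build()].
#' @return Object of class `ccr_callset`: list with `source`, `calls`,
#'   `genome`.
#' @export
callset <- function(calls, source, genome) {
  stopifnot(inherits(genome, "ccr_genome"))
  calls <- as.data.frame(calls)
  if (nrow(calls) == 0) calls <- empty_calls()
  need <- c("sv_type", "chrA", "posA", "chrB", "posB")
  miss <- setdiff(need, names(calls))
  if (length(miss)) stop("calls missing column(s): ", paste(miss, collapse = ", "))
  defaults <- list(id = NA_character_, sideA = NA_character_,
                   sideB = NA_character_, size_bp = NA_real_,
                   filter_flag = "PASS", supporting_pairs = 0,
                   split_reads = 0, freq_count = NA_real_, genic = NA)
  for (nm in names(defaults))
    if (!nm %in% names(calls)) calls[[nm]] <- rep(defaults[[nm]], nrow(calls))
  calls$source <- rep(source, length.out = nrow(calls))
  calls$chrA <- as.character(calls$chrA)
  calls$chrB <- as.character(calls$chrB)
  if (any(is.na(calls$id)) && nrow(calls) > 0)
    calls$id <- ifelse(is.na(calls$id),
                       sprintf("%s_%d", source, seq_len(nrow(calls))),
                       calls$id)
  bad <- setdiff(calls$sv_type, SV_TYPES)
  if (length(bad)) stop("unknown sv_type: ", paste(unique(bad), collapse = ", "))
  cs <- structure(list(source = source,
                       calls = normalize_calls(calls, genome),
                       genome = genome),
                  class = "ccr_callset")
  viol <- validate_calls(cs$calls, genome)
  if (length(viol)) stop("invalid calls:\n  ", paste(viol, collapse = "\n  "))
  cs
}

#' @export
print.ccr_callset <- function(x, ...) {
  cat("<ccr_callset>", x$source, "-", nrow(x$calls), "calls (",
      paste(sprintf("%s:%d", names(table(x$calls$sv_type)),
                    as.integer(table(x$calls$sv_type))), collapse = " "),
      ")\n")
  invisible(x)
}

flip_side <- function(s) ifelse(s == "pter", "qter",
                                ifelse(s == "qter", "pter", s))

#' Normalize structural-variant calls
#'
#' Puts every record into canonical coordinate order: `chrA`/`chrB`
#' sorted by genome chromosome order (positions and breakend sides
#' travel with their chromosome), `posA <= posB` within a chromosome,
#' and `size_bp` recomputed as `posB - posA` for intrachromosomal
#' DEL/DUP/INV.  Idempotent, and preserves the multiset of
#' (chromosome, position) endpoints.
#'
#' @param calls Call `data.frame` (see [callset()]).
#' @param genome A [genome_build()]; coordinates are checked against it.
#' @return The normalized `data.frame`.
#' @export
normalize_calls <- function(calls, genome) {
  if (nrow(calls) == 0) return(calls)
  for (fld in c("posA", "posB")) {
    ch <- if (fld == "posA") calls$chrA else calls$chrB
    len <- chrom_length(genome, ch)
    bad <- which(calls[[fld]] < 1 | calls[[fld]] > len)
    if (length(bad))
      stop(sprintf("call %s: %s=%s outside chromosome %s [1, %d]",
                   calls$id[bad[1]], fld, calls[[fld]][bad[1]],
                   ch[bad[1]], len[bad[1]]))
  }
  rkA <- chrom_rank(genome, calls$chrA)
  rkB <- chrom_rank(genome, calls$chrB)
  swap <- rkA > rkB | (rkA == rkB & calls$posA > calls$posB)
  if (any(swap)) {
    a <- calls[swap, c("chrA", "posA", "sideA")]
    calls[swap, c("chrA", "posA", "sideA")] <-
      calls[swap, c("chrB", "posB", "sideB")]
    calls[swap, c("chrB", "posB", "sideB")] <- a
  }
  intra <- calls$chrA == calls$chrB & calls$sv_type %in% c("DEL", "DUP", "INV")
  calls$size_bp[intra] <- calls$posB[intra] - calls$posA[intra]
  # other intrachromosomal types keep a supplied size; fall back to span
  fill <- calls$chrA == calls$chrB & !intra & calls$sv_type != "BND" &
    is.na(calls$size_bp)
  calls$size_bp[fill] <- calls$posB[fill] - calls$posA[fill]
  calls
}

#' Validate entities against a genome
#'
#' Returns a character vector of invariant violations (empty when the
#' records are valid); nothing is raised.  `validate_junctions` checks
#' junction tables, `validate_calls` call tables, `validate_fragments`
#' fragment tables.
#'
#' @param x The record `data.frame`.
#' @param genome A [genome_build()].
#' @return Character vector of human-readable violations.
#' @export
validate_calls <- function(x, genome) {
  v <- character()
  if (nrow(x) == 0) return(v)
  v <- c(v, check_pos(genome, x$chrA, x$posA, x$id, "posA"),
         check_pos(genome, x$chrB, x$posB, x$id, "posB"))
  bad <- which(!x$sv_type %in% SV_TYPES)
  for (i in bad) v <- c(v, sprintf("call %s: unknown sv_type %s", x$id[i], x$sv_type[i]))
  intra <- which(x$chrA == x$chrB)
  bad <- intra[x$posA[intra] > x$posB[intra]]
  for (i in bad) v <- c(v, sprintf("call %s: posA > posB", x$id[i]))
  sz <- intra[x$sv_type[intra] %in% c("DEL", "DUP", "INV")]
  bad <- sz[!is.na(x$size_bp[sz]) & x$size_bp[sz] != x$posB[sz] - x$posA[sz]]
  for (i in bad) v <- c(v, sprintf("call %s: size_bp != posB - posA", x$id[i]))
  v
}

check_pos <- function(genome, chrom, pos, id, field) {
  v <- character()
  known <- chrom %in% genome$chromosomes$name
  for (i in which(!known))
    v <- c(v, sprintf("%s %s: unknown chromosome %s", field, id[i], chrom[i]))
  if (any(known)) {
    len <- rep(NA_real_, length(chrom))
    len[known] <- chrom_length(genome, chrom[known])
    bad <- which(known & (pos < 1 | pos > len))
    for (i in bad)
      v <- c(v, sprintf("%s %s: position %s outside [1, %d] on chromosome %s",
                        field, id[i], format(pos[i], scientific = FALSE),
                        len[i], chrom[i]))
  }
  v
}

#' @rdname validate_calls
#' @export
validate_junctions <- function(x, genome) {
  v <- character()
  if (nrow(x) == 0) return(v)
  v <- c(v, check_pos(genome, x$chrA, x$posA, x$id, "posA"),
         check_pos(genome, x$chrB, x$posB, x$id, "posB"))
  if (all(c("mh", "ins") %in% names(x))) {
    both <- which(nzchar(x$mh) & x$mh != "-" & x$mh != "N.i." &
                  nzchar(x$ins) & x$ins != "-" & x$ins != "N.i.")
    for (i in both)
      v <- c(v, sprintf("junction %s: microhomology and insertion are mutually exclusive", x$id[i]))
    for (fld in c("mh", "ins")) {
      seqs <- setdiff(x[[fld]], c("", "-", "N.i.", NA))
      bad <- seqs[grepl("[^ACGT]", seqs)]
      for (s in bad) v <- c(v, sprintf("%s sequence %s contains non-ACGT characters", fld, s))
    }
  }
  v
}

#' @rdname validate_calls
#' @export
validate_fragments <- function(x, genome) {
  v <- character()
  if (nrow(x) == 0) return(v)
  id <- if ("label" %in% names(x)) x$label else as.character(seq_len(nrow(x)))
  v <- c(v, check_pos(genome, x$chrom, x$start, id, "start"),
         check_pos(genome, x$chrom, x$end, id, "end"))
  bad <- which(x$start > x$end)
  for (i in bad) v <- c(v, sprintf("fragment %s: start > end", id[i]))
  if ("label" %in% names(x) && anyDuplicated(x$label))
    v <- c(v, "fragment labels are not unique")
  v
}

#' Interval size and megabase rendering
#'
#' Sizes follow the difference convention `end - start` (matching VCF
#' `SVLEN = END - POS`); megabase rendering rounds to one decimal.
#'
#' @param start,end 1-based coordinates, `start <= end`.
#' @return `interval_size`: size in bp. `format_mb`: character, Mb with
#'   one decimal.
#' @export
interval_size <- function(start, end) {
  if (any(start > end)) stop("start > end")
  end - start
}

#' @rdname interval_size
#' @param bp Size in base pairs.
#' @export
format_mb <- function(bp) sprintf("%.1f", bp / 1e6)
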