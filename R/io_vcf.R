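info_field <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regexpr(pat, info, perl = TRUE)
  out <- rep(NA_character_, length(info))
  hit <- m != -1
  out[hit] <- sub(paste0(".*(?:^|;)", key, "=([^;]*).*"), "\\1", info[hit], perl = TRUE)
  out
}

# VCF breakend ALT bracket notation <-> retained-side orientation
parse_bnd_alt <- function(alt) {
  if (!grepl("^([ACGTNacgtn.]*[\\[\\]][^\\[\\]:]+:[0-9]+[\\[\\]]|[\\[\\]][^\\[\\]:]+:[0-9]+[\\[\\]][ACGTNacgtn.]*)$",
             alt, perl = TRUE))
    return(NULL)
  g <- regmatches(alt, regexec("[\\[\\]]([^\\[\\]:]+):([0-9]+)[\\[\\]]", alt,
                               perl = TRUE))[[1]]
  if (length(g) < 3) return(NULL)
  t_first <- !substr(alt, 1, 1) %in% c("[", "]")
  bracket <- sub("^[^\\[\\]]*", "", alt, perl = TRUE)
  open <- substr(bracket, 1, 1) == "["
  # t[p[ : local pter / mate qter ; t]p] : pter/pter ;
  # ]p]t : qter/pter ; [p[t : qter/qter
  list(mate_chrom = sub("^chr", "", g[2]), mate_pos = as.numeric(g[3]),
       side = if (t_first) "pter" else "qter",
       mate_side = if (open) "qter" else "pter")
}

render_bnd_alt <- function(side, mate_chrom, mate_pos, mate_side, ref = "N") {
  p <- sprintf("%s:%s", mate_chrom, format(mate_pos, scientific = FALSE, trim = TRUE))
  br <- if (mate_side == "qter") sprintf("[%s[", p) else sprintf("]%s]", p)
  if (side == "pter") paste0(ref, br) else paste0(br, ref)
}

#' Read a structural-variant VCF into a call set
#'
#' Supports VCF 4.x SV conventions: symbolic ALTs with `SVTYPE`,
#' `END`/`SVLEN`, and breakend (`BND`) records in bracket notation,
#' paired through `MATEID` into a single interchromosomal call.
#' Supporting evidence is read from configurable INFO keys (unknown
#' keys yield support 0, never an error); records without `SVTYPE`
#' are classified `UNKNOWN`; malformed bracket ALTs are skipped with a
#' counted warning naming the record.  Calls are normalized on the
#' way in.
#'
#' @param path VCF file.
#' @param genome A [genome_build()].
#' @param source Source label (defaults to the file name).
#' @param support_keys Named vector: INFO keys for `pairs` and
#'   `split` read support.
#' @return A [callset()].
#' @export
read_sv_vcf <- function(path, genome, source = basename(path),
                        support_keys = c(pairs = "PE", split = "SR")) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) return(callset(empty_calls(), source, genome))
  info <- unname(v@fix[, "INFO"])
  fix$CHROM <- sub("^chr", "", fix$CHROM)
  fix$POS <- as.numeric(fix$POS)
  svtype <- info_field(info, "SVTYPE")
  svtype[is.na(svtype)] <- "UNKNOWN"
  svtype[!svtype %in% SV_TYPES] <- "UNKNOWN"
  end <- suppressWarnings(as.numeric(info_field(info, "END")))
  svlen <- suppressWarnings(abs(as.numeric(info_field(info, "SVLEN"))))
  pairs <- suppressWarnings(as.numeric(info_field(info, support_keys[["pairs"]])))
  split <- suppressWarnings(as.numeric(info_field(info, support_keys[["split"]])))
  mateid <- info_field(info, "MATEID")
  filt <- ifelse(is.na(fix$FILTER) | fix$FILTER == ".", "PASS", fix$FILTER)

  rows <- list(); n_bad <- 0L; done <- rep(FALSE, nrow(fix))
  for (i in seq_len(nrow(fix))) {
    if (done[i]) next
    if (svtype[i] == "BND") {
      b <- parse_bnd_alt(fix$ALT[i])
      if (is.null(b)) {
        warning("malformed BND ALT '", fix$ALT[i], "' at record ", i, "; skipped")
        n_bad <- n_bad + 1L
        next
      }
      if (!is.na(mateid[i])) {
        m <- which(fix$ID == mateid[i])
        done[m] <- TRUE
      }
      rows[[length(rows) + 1]] <- data.frame(
        id = ifelse(is.na(fix$ID[i]), sprintf("rec%d", i), fix$ID[i]),
        sv_type = "BND", chrA = fix$CHROM[i], posA = fix$POS[i],
        sideA = b$side, chrB = b$mate_chrom, posB = b$mate_pos,
        sideB = b$mate_side, size_bp = 0,
        filter_flag = filt[i],
        supporting_pairs = ifelse(is.na(pairs[i]), 0, pairs[i]),
        split_reads = ifelse(is.na(split[i]), 0, split[i]),
        stringsAsFactors = FALSE)
    } else {
      posB <- if (!is.na(end[i])) end[i]
              else if (!is.na(svlen[i])) fix$POS[i] + svlen[i]
              else fix$POS[i]
      rows[[length(rows) + 1]] <- data.frame(
        id = ifelse(is.na(fix$ID[i]), sprintf("rec%d", i), fix$ID[i]),
        sv_type = svtype[i], chrA = fix$CHROM[i], posA = fix$POS[i],
        sideA = NA_character_, chrB = fix$CHROM[i], posB = posB,
        sideB = NA_character_,
        size_bp = ifelse(is.na(svlen[i]), posB - fix$POS[i], svlen[i]),
        filter_flag = filt[i],
        supporting_pairs = ifelse(is.na(pairs[i]), 0, pairs[i]),
        split_reads = ifelse(is.na(split[i]), 0, split[i]),
        stringsAsFactors = FALSE)
    }
  }
  calls <- if (length(rows)) do.call(rbind, rows) else empty_calls()
  cs <- callset(calls, source, genome)
  attr(cs, "n_malformed") <- n_bad
  cs
}

#' Write a call set as a structural-variant VCF
#'
#' Symbolic records for intrachromosomal types (with `SVTYPE`, `END`,
#' `SVLEN`), breakend mate pairs in bracket notation for BND calls.
#' Round-trips through [read_sv_vcf()]: coordinates, types, filter
#' flags and breakend orientations are reproduced exactly.
#'
#' @param cs A [callset()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(cs, path) {
  calls <- cs$calls
  bad <- setdiff(calls$sv_type, SV_TYPES)
  if (length(bad)) stop("unknown sv_type: ", paste(bad, collapse = ", "))
  g <- cs$genome
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##source=ccrwalk:%s", cs$source),
           sprintf("##contig=<ID=%s,length=%d>",
                   g$chromosomes$name, g$chromosomes$length),
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
           "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
           "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate breakend\">",
           "##INFO=<ID=PE,Number=1,Type=Integer,Description=\"Supporting pairs\">",
           "##INFO=<ID=SR,Number=1,Type=Integer,Description=\"Split reads\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                 sep = "\t"))
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  lines <- character()
  for (i in seq_len(nrow(calls))) {
    cl <- calls[i, ]
    support <- sprintf("PE=%d;SR=%d", round(cl$supporting_pairs), round(cl$split_reads))
    if (cl$sv_type == "BND") {
      sideA <- if (is.na(cl$sideA)) "pter" else cl$sideA
      sideB <- if (is.na(cl$sideB)) "qter" else cl$sideB
      idA <- paste0(cl$id, "_1"); idB <- paste0(cl$id, "_2")
      lines <- c(lines,
        paste(cl$chrA, fmt(cl$posA), idA, "N",
              render_bnd_alt(sideA, cl$chrB, cl$posB, sideB), ".",
              cl$filter_flag,
              sprintf("SVTYPE=BND;MATEID=%s;%s", idB, support), sep = "\t"),
        paste(cl$chrB, fmt(cl$posB), idB, "N",
              render_bnd_alt(sideB, cl$chrA, cl$posA, sideA), ".",
              cl$filter_flag,
              sprintf("SVTYPE=BND;MATEID=%s;%s", idA, support), sep = "\t"))
    } else {
      lines <- c(lines,
        paste(cl$chrA, fmt(cl$posA), cl$id, "N",
              sprintf("<%s>", cl$sv_type), ".", cl$filter_flag,
              sprintf("SVTYPE=%s;END=%s;SVLEN=%s;%s", cl$sv_type,
                      fmt(cl$posB), fmt(ifelse(is.na(cl$size_bp),
                                               cl$posB - cl$posA, cl$size_bp)),
                      support), sep = "\t"))
    }
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}
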