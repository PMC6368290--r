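#' Read an optical-map SMAP-style SV table
#'
#' Tab-separated vendor table; only the columns that matter are
#' required (`Type`, `RefcontigID1`, `RefStartPos`, `RefEndPos`,
#' `Confidence`; `RefcontigID2` for translocations), extra columns are
#' ignored since vendor formats drift.  Vendor type labels map
#' through a dialect table (`insertion` to INS, `translocation_*` to
#' BND, ...); unknown labels become `UNKNOWN` with a warning.  Rows
#' below the confidence threshold are dropped and counted.
#'
#' @param path SMAP-like TSV (comment lines starting `#` allowed).
#' @param genome A [genome_build()].
#' @param min_confidence Confidence threshold (rows strictly below are
#'   dropped).
#' @param source Source label.
#' @return A [callset()]; attribute `n_dropped` counts
#'   low-confidence rows.
#' @export
read_smap_table <- function(path, genome, min_confidence = 0,
                            source = "optical") {
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("Type", "RefcontigID1", "RefStartPos", "RefEndPos", "Confidence")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("SMAP table missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(d) == 0) return(callset(empty_calls(), source, genome))
  low <- !is.na(d$Confidence) & d$Confidence < min_confidence
  n_dropped <- sum(low)
  if (n_dropped) message(n_dropped, " row(s) below confidence ", min_confidence, " dropped")
  d <- d[!low, , drop = FALSE]
  type_map <- c(insertion = "INS", deletion = "DEL", duplication = "DUP",
                duplication_split = "DUP", duplication_inverted = "DUP",
                inversion = "INV", inversion_partial = "INV",
                inversion_paired = "INV")
  lab <- tolower(d$Type)
  sv <- ifelse(grepl("^trans", lab), "BND", unname(type_map[lab]))
  if (anyNA(sv)) {
    warning("unknown SMAP type label(s): ",
            paste(unique(d$Type[is.na(sv)]), collapse = ", "),
            " - classified UNKNOWN")
    sv[is.na(sv)] <- "UNKNOWN"
  }
  chrB <- if ("RefcontigID2" %in% names(d))
    ifelse(sv == "BND", as.character(d$RefcontigID2), as.character(d$RefcontigID1))
  else as.character(d$RefcontigID1)
  calls <- data.frame(sv_type = sv,
                      chrA = as.character(d$RefcontigID1),
                      posA = round(d$RefStartPos),
                      chrB = chrB, posB = round(d$RefEndPos),
                      supporting_pairs = d$Confidence,
                      stringsAsFactors = FALSE)
  cs <- callset(calls, source, genome)
  attr(cs, "n_dropped") <- n_dropped
  cs
}

#' Read an aCGH segment table
#'
#' TSV with `chrom`, `start`, `end`, `call` (`gain`/`loss`), `probes`.
#' Losses become DEL, gains DUP.
#'
#' @param path Segment TSV.
#' @param genome A [genome_build()].
#' @param source Source label (default `"aCGH"`).
#' @return A [callset()].
#' @export
read_acgh_segments <- function(path, genome, source = "aCGH") {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "call")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("aCGH table missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(d) == 0) return(callset(empty_calls(), source, genome))
  bad <- setdiff(d$call, c("gain", "loss"))
  if (length(bad)) stop("aCGH call label must be gain/loss, got: ",
                        paste(unique(bad), collapse = ", "))
  calls <- data.frame(sv_type = ifelse(d$call == "loss", "DEL", "DUP"),
                      chrA = as.character(d$chrom), posA = d$start,
                      chrB = as.character(d$chrom), posB = d$end,
                      stringsAsFactors = FALSE)
  callset(calls, source, genome)
}

#' Read a public SV dataset dump
#'
#' Dialects: `dgv_tsv` (columns `chr`, `start`, `end`,
#' `variantsubtype`), `conrad_tsv` (`chr`, `start`, `end`, `type`),
#' `giab_vcf` (SV VCF; with `evidence_filter = TRUE` only records
#' whose `CGcalls` or `PBcalls` INFO value is non-zero are kept, i.e.
#' variants supported by Complete Genomics or PacBio data).
#' `split_by_type()` splits any call set into one per variant type,
#' conserving record counts.
#'
#' @param path Input file.
#' @param genome A [genome_build()].
#' @param dialect One of `"dgv_tsv"`, `"conrad_tsv"`, `"giab_vcf"`.
#' @param evidence_filter Apply the CGcalls/PBcalls evidence filter
#'   (giab_vcf only).
#' @param source Source label (defaults to the dialect).
#' @return A [callset()].
#' @export
read_public_dataset <- function(path, genome, dialect,
                                evidence_filter = FALSE, source = dialect) {
  subtype_map <- c(loss = "DEL", deletion = "DEL", del = "DEL",
                   gain = "DUP", duplication = "DUP", dup = "DUP",
                   insertion = "INS", ins = "INS", novel_sequence_insertion = "INS",
                   inversion = "INV", inv = "INV", complex = "UNKNOWN")
  if (dialect == "dgv_tsv" || dialect == "conrad_tsv") {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    type_col <- if (dialect == "dgv_tsv") "variantsubtype" else "type"
    need <- c("chr", "start", "end", type_col)
    miss <- setdiff(need, names(d))
    if (length(miss)) stop(dialect, " missing column(s): ", paste(miss, collapse = ", "))
    if (nrow(d) == 0) return(callset(empty_calls(), source, genome))
    sv <- unname(subtype_map[tolower(d[[type_col]])])
    sv[is.na(sv)] <- "UNKNOWN"
    calls <- data.frame(sv_type = sv, chrA = sub("^chr", "", as.character(d$chr)),
                        posA = d$start, chrB = sub("^chr", "", as.character(d$chr)),
                        posB = d$end, stringsAsFactors = FALSE)
    return(callset(calls, source, genome))
  }
  if (dialect == "giab_vcf") {
    cs <- read_sv_vcf(path, genome, source = source)
    if (evidence_filter) {
      v <- vcfR::read.vcfR(path, verbose = FALSE)
      info <- unname(v@fix[, "INFO"])
      ids <- unname(v@fix[, "ID"])
      cg <- suppressWarnings(as.numeric(info_field(info, "CGcalls")))
      pb <- suppressWarnings(as.numeric(info_field(info, "PBcalls")))
      keep_ids <- ids[(!is.na(cg) & cg > 0) | (!is.na(pb) & pb > 0)]
      cs$calls <- cs$calls[cs$calls$id %in% keep_ids, , drop = FALSE]
    }
    return(cs)
  }
  stop("unknown dialect: ", dialect)
}

#' @rdname read_public_dataset
#' @param cs A [callset()].
#' @export
split_by_type <- function(cs) {
  lapply(split(cs$calls, cs$calls$sv_type), function(d) {
    out <- cs; out$calls <- d; rownames(out$calls) <- NULL; out
  })
}

#' Read an annotation BED track
#'
#' BED input (0-based half-open) converted to the package's 1-based
#' inclusive convention via `rtracklayer`.  For `kind = "repeat"` the
#' BED name column is the repeat name (an optional
#' `name;family` encoding fills the family column); for
#' `kind = "gene"` the name is the gene symbol and a non-zero score
#' marks a known disease gene.
#'
#' @param path BED file.
#' @param kind `"repeat"` or `"gene"`.
#' @return `data.frame` track (`chrom`, `start`, `end`, `name`, plus
#'   `family` or `disease_flag`).
#' @export
read_bed_track <- function(path, kind = c("repeat", "gene")) {
  kind <- match.arg(kind)
  gr <- rtracklayer::import(path, format = "bed")
  d <- data.frame(chrom = sub("^chr", "", as.character(GenomeInfoDb::seqnames(gr))),
                  start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
                  name = if (!is.null(gr$name)) gr$name else NA_character_,
                  stringsAsFactors = FALSE)
  if (kind == "repeat") {
    parts <- strsplit(ifelse(is.na(d$name), "", d$name), ";", fixed = TRUE)
    d$name <- vapply(parts, function(p) if (length(p)) p[1] else NA_character_, "")
    d$family <- vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, "")
  } else {
    score <- if (!is.null(gr$score)) gr$score else rep(0, nrow(d))
    d$disease_flag <- !is.na(score) & score > 0
  }
  d
}

#' Write a deterministic report
#'
#' Writes a table as column-ordered TSV plus a JSON twin next to it
#' (same basename, `.json`).
#'
#' @param table `data.frame`.
#' @param path Output TSV path.
#' @return Invisibly, the two paths written.
#' @export
write_report <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  json <- sub("\\.[^.]*$", ".json", path)
  if (json == path) json <- paste0(path, ".json")
  jsonlite::write_json(table, json, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(tsv = path, json = json))
}
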