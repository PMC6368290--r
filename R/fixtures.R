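#' Packaged case-study tables
#'
#' The package ships transcriptions of the published junction and
#' deletion tables for the three case rearrangements: two de novo
#' complex interchromosomal translocations (Case 1: t(2;8;15), Case 2:
#' t(1;10;5)) and one extremely complex intrachromosomal rearrangement
#' of chromosome 1 (Case 3, 26 junctions).  These serve as desk-scale
#' inputs for breakpoint counting, junction analysis, reconstruction
#' and technology benchmarking.
#'
#' `case_junctions(case)` returns the junction table for one case;
#' `curated_walk_junctions(case)` (Cases 1-2 only) additionally carries
#' breakend orientations curated from the published derivative
#' diagrams and karyotype strings, as needed for reconstruction;
#' `detection_fixture()` returns the per-technology detection table
#' (reported coordinates per junction per technology, `NA` = not
#' identified); `reported_deletions()` the deletion coordinate table.
#'
#' @param case Case number (1, 2 or 3).
#' @return See above; junction tables are [junction_table()] objects.
#' @export
case_junctions <- function(case) {
  genome <- genome_grch37()
  if (case %in% c(1, 2)) {
    t2 <- utils::read.delim(ccr_extdata("table2_junctions.tsv"),
                            colClasses = c(chrA = "character", chrB = "character"))
    t2 <- t2[t2$case == case, , drop = FALSE]
    df <- data.frame(id = sprintf("c%d_j%d", case, t2$jct),
                     chrA = t2$chrA, posA = t2$posA,
                     chrB = t2$chrB, posB = t2$posB,
                     mh = clean_seq(t2$mh), ins = clean_seq(t2$insertion),
                     estimated = FALSE,
                     repeatA = t2$repeatA, repeatB = t2$repeatB,
                     stringsAsFactors = FALSE)
  } else if (case == 3) {
    t3 <- utils::read.delim(ccr_extdata("table3_junctions.tsv"))
    df <- data.frame(id = sprintf("c3_j%d", t3$jct),
                     chrA = "1", posA = t3$posA,
                     chrB = "1", posB = t3$posB,
                     mh = clean_seq(t3$mh), ins = clean_seq(t3$insertion),
                     estimated = t3$estimated,
                     repeatA = t3$repeatA, repeatB = t3$repeatB,
                     stringsAsFactors = FALSE)
  } else stop("case must be 1, 2 or 3")
  junction_table(df, genome)
}

clean_seq <- function(x) ifelse(x %in% c("-", "N.i.", "", NA), "", x)

#' @rdname case_junctions
#' @export
curated_walk_junctions <- function(case) {
  stopifnot(case %in% c(1, 2))
  df <- utils::read.delim(ccr_extdata(sprintf("case%d_junctions.tsv", case)),
                          colClasses = c(chrA = "character", chrB = "character"))
  junction_table(df, genome_grch37())
}

#' @rdname case_junctions
#' @export
detection_fixture <- function() {
  d <- utils::read.delim(ccr_extdata("table4_detection.tsv"),
                         na.strings = "N.i.",
                         colClasses = c(chrA = "character", chrB = "character"))
  attr(d, "sources") <- c("pe", "mp", "om", "lr", "sn")
  d
}

#' @rdname case_junctions
#' @export
reported_deletions <- function() {
  utils::read.delim(ccr_extdata("table1_deletions.tsv"),
                    colClasses = c(chrom = "character"))
}

ccr_extdata <- function(file) {
  p <- system.file("extdata", file, package = "ccrwalk")
  if (p == "") stop("fixture not found: ", file)
  p
}
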