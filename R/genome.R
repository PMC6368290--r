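#' Define a genome build
#'
#' A genome build is the coordinate frame every other object in the
#' package validates against: an ordered set of chromosomes with their
#' lengths, plus optional centromere positions (needed only for
#' rendering molecular karyotype strings, where telomere-anchored
#' segments are written `pter_cen_<pos>` / `qter_cen_<pos>` when they
#' span the centromere).
#'
#' Coordinates are 1-based and inclusive throughout the package.
#'
#' @param build_name Label for the build, e.g. `"GRCh37"`.
#' @param chromosomes `data.frame` with columns `name` (character,
#'   unique) and `length` (positive integer bp), in the order that
#'   defines chromosome sorting for this build.
#' @param centromere Optional named numeric vector of centromere
#'   positions (bp), names matching chromosome names.
#' @return An object of class `ccr_genome`.
#' @export
genome_build <- function(build_name, chromosomes, centromere = NULL) {
  stopifnot(is.character(build_name), length(build_name) == 1L)
  chromosomes <- as.data.frame(chromosomes)
  stopifnot(all(c("name", "length") %in% names(chromosomes)))
  chromosomes$name <- as.character(chromosomes$name)
  if (anyDuplicated(chromosomes$name))
    stop("chromosome names must be unique")
  if (any(chromosomes$length <= 0))
    stop("chromosome lengths must be positive")
  if (!is.null(centromere)) {
    bad <- setdiff(names(centromere), chromosomes$name)
    if (length(bad)) stop("centromere given for unknown chromosome: ",
                          paste(bad, collapse = ", "))
    len <- chromosomes$length[match(names(centromere), chromosomes$name)]
    if (any(centromere < 1 | centromere > len))
      stop("centromere position outside chromosome bounds")
  }
  structure(list(build_name = build_name,
                 chromosomes = chromosomes[, c("name", "length")],
                 centromere = centromere),
            class = "ccr_genome")
}

#' @export
print.ccr_genome <- function(x, ...) {
  cat("<ccr_genome>", x$build_name, "-", nrow(x$chromosomes),
      "chromosomes,", sum(x$chromosomes$length), "bp\n")
  invisible(x)
}

#' GRCh37 (hg19) coordinate frame for the case studies
#'
#' Chromosome lengths for the subset of GRCh37 chromosomes involved in
#' the three case rearrangements (1, 2, 5, 8, 10, 15), with approximate
#' centromere midpoints.  Centromeres are used only to decide whether a
#' telomere-anchored karyotype segment spans the centromere, so
#' megabase-level accuracy is sufficient.
#'
#' @return A `ccr_genome`.
#' @export
genome_grch37 <- function() {
  genome_build(
    "GRCh37",
    data.frame(name   = c("1", "2", "5", "8", "10", "15"),
               length = c(249250621, 243199373, 180915260,
                          146364022, 135534747, 102531392)),
    centromere = c("1" = 123035434, "2" = 93826171, "5" = 47905641,
                   "8" = 45338887, "10" = 40754935, "15" = 16800000))
}

#' Toy genome for simulation
#'
#' Three chromosomes of 180, 120 and 90 Mb with centromeres at 40% of
#' the length: large enough that tens of breakpoints never crowd each
#' other, small enough that exhaustive checks stay instant.
#'
#' @param n_chrom Number of chromosomes (1-3).
#' @return A `ccr_genome`.
#' @export
sim_genome <- function(n_chrom = 3) {
  stopifnot(n_chrom >= 1, n_chrom <= 3)
  len <- c(180e6, 120e6, 90e6)[seq_len(n_chrom)]
  nm <- as.character(seq_len(n_chrom))
  genome_build("sim1", data.frame(name = nm, length = len),
               centromere = stats::setNames(round(len * 0.4), nm))
}

chrom_length <- function(genome, chrom) {
  i <- match(as.character(chrom), genome$chromosomes$name)
  if (anyNA(i)) stop("unknown chromosome: ",
                     paste(unique(chrom[is.na(i)]), collapse = ", "))
  genome$chromosomes$length[i]
}

chrom_rank <- function(genome, chrom) {
  match(as.character(chrom), genome$chromosomes$name)
}

centromere_pos <- function(genome, chrom) {
  if (is.null(genome$centromere)) return(NA_real_)
  p <- genome$centromere[as.character(chrom)]
  ifelse(is.na(p), NA_real_, unname(p))
}
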