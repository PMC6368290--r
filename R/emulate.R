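#' Technology error profiles
#'
#' A `technology_profile` is the parametric error model of one SV
#' detection technology: coordinate jitter, false-negative rate (with
#' a multiplier inside repeat elements, where short-read mapping
#' fails), a minimum detectable event size, a variant-type reporting
#' map (e.g. optical maps report duplications as insertions and no
#' duplications at all), and whether split-read support is produced.
#'
#' `tech_profiles()` returns the four built-in profiles used in the
#' benchmarking study.  Their parameters are chosen once to reproduce
#' the qualitative behaviour reported for each technology: paired-end
#' (PE) and linked reads at base-pair resolution with split-read
#' support and elevated miss rates in repeats for PE; mate-pair (MP)
#' at a few-hundred-bp resolution without split reads; optical maps
#' at kb-scale resolution, blind below ~15 kb, reporting no
#' duplications.
#'
#' @param name Source label.
#' @param jitter_sd_bp SD of the Gaussian coordinate error (bp).
#' @param fn_rate Per-junction false-negative probability.
#' @param repeat_fn_multiplier Multiplier on `fn_rate` when a breakend
#'   lies inside a repeat element (>= 1; capped at probability 1).
#' @param min_size_bp Events smaller than this (intrachromosomal) are
#'   not reported.
#' @param type_report_map Named character vector remapping emitted SV
#'   types, e.g. `c(DUP = "INS")`.
#' @param reports_split_reads Does the technology resolve junctions at
#'   the nucleotide level (split reads / split contigs)?
#' @param max_resolution_note Free-text note.
#' @return Object of class `ccr_profile`.
#' @export
technology_profile <- function(name, jitter_sd_bp = 0, fn_rate = 0,
                               repeat_fn_multiplier = 1, min_size_bp = 0,
                               type_report_map = character(),
                               reports_split_reads = TRUE,
                               max_resolution_note = "") {
  stopifnot(jitter_sd_bp >= 0, fn_rate >= 0, fn_rate <= 1,
            repeat_fn_multiplier >= 1, min_size_bp >= 0)
  structure(list(name = name, jitter_sd_bp = jitter_sd_bp,
                 fn_rate = fn_rate,
                 repeat_fn_multiplier = repeat_fn_multiplier,
                 min_size_bp = min_size_bp,
                 type_report_map = type_report_map,
                 reports_split_reads = reports_split_reads,
                 max_resolution_note = max_resolution_note),
            class = "ccr_profile")
}

#' @rdname technology_profile
#' @export
tech_profiles <- function() {
  list(
    pe = technology_profile("pe", jitter_sd_bp = 0, fn_rate = 0.05,
                            repeat_fn_multiplier = 5, min_size_bp = 50,
                            reports_split_reads = TRUE,
                            max_resolution_note = "split reads: 1 bp"),
    mp = technology_profile("mp", jitter_sd_bp = 600, fn_rate = 0.09,
                            repeat_fn_multiplier = 5, min_size_bp = 2000,
                            reports_split_reads = FALSE,
                            max_resolution_note = "span clusters: ~400 bp"),
    optical = technology_profile("optical", jitter_sd_bp = 10700,
                                 fn_rate = 0.12, repeat_fn_multiplier = 1,
                                 min_size_bp = 15000,
                                 type_report_map = c(DUP = "INS"),
                                 reports_split_reads = FALSE,
                                 max_resolution_note = "label distance: ~7 kb"),
    linked = technology_profile("linked", jitter_sd_bp = 0, fn_rate = 0.03,
                                repeat_fn_multiplier = 1, min_size_bp = 50,
                                reports_split_reads = TRUE,
                                max_resolution_note = "split contigs: 1 bp"))
}

# reference-frame SV type of a truth junction from its breakend sides
classify_junction <- function(chrA, posA, sideA, chrB, posB, sideB) {
  inter <- chrA != chrB
  lowA <- posA <= posB
  sl <- ifelse(lowA, sideA, sideB)   # side at the lower coordinate
  sh <- ifelse(lowA, sideB, sideA)
  ifelse(inter, "BND",
         ifelse(sl == "pter" & sh == "qter", "DEL",
                ifelse(sl == "qter" & sh == "pter", "DUP", "INV")))
}

#' Emulate a technology's call set from simulated truth
#'
#' Each truth junction is independently dropped with probability
#' `fn_rate` (multiplied by `repeat_fn_multiplier` when either
#' breakend lies inside a repeat element), surviving breakend
#' coordinates are perturbed by rounded Gaussian jitter, events
#' smaller than `min_size_bp` are dropped, and emitted SV types pass
#' through the profile's reporting map.  Reproducible given the seed.
#'
#' @param sim A [simulate_ccr()] result.
#' @param profile A [technology_profile()].
#' @param seed Integer seed.
#' @return A [callset()]; calls keep their breakend orientations so
#'   noiseless call sets can be converted back to junctions with
#'   [calls_to_junctions()].
#' @export
emulate_technology <- function(sim, profile, seed = sim$config$seed) {
  stopifnot(inherits(profile, "ccr_profile"))
  set.seed(seed)
  j <- as.data.frame(sim$junctions)
  if (nrow(j) == 0) return(callset(empty_calls(), profile$name, sim$genome))
  in_repeat <- function(chrom, pos) {
    hit <- annotate_repeat_context(chrom, pos, sim$repeat_track, window_bp = 0)
    lengths(hit) > 0
  }
  rep_hit <- in_repeat(j$chrA, j$posA) | in_repeat(j$chrB, j$posB)
  p_fn <- pmin(1, profile$fn_rate * ifelse(rep_hit, profile$repeat_fn_multiplier, 1))
  keep <- stats::runif(nrow(j)) >= p_fn
  sv_type <- classify_junction(j$chrA, j$posA, j$sideA, j$chrB, j$posB, j$sideB)
  size <- ifelse(j$chrA == j$chrB, abs(j$posB - j$posA), NA)
  keep <- keep & (is.na(size) | size >= profile$min_size_bp)
  d <- j[keep, , drop = FALSE]
  if (nrow(d) == 0) return(callset(empty_calls(), profile$name, sim$genome))
  sv_type <- sv_type[keep]
  remap <- profile$type_report_map
  if (length(remap)) {
    hit <- sv_type %in% names(remap)
    sv_type[hit] <- unname(remap[sv_type[hit]])
  }
  jit <- function(chrom, pos) {
    p <- pos + round(stats::rnorm(length(pos), 0, profile$jitter_sd_bp))
    pmin(pmax(p, 1), chrom_length(sim$genome, chrom))
  }
  calls <- data.frame(
    id = paste0(profile$name, "_", d$id),
    sv_type = sv_type,
    chrA = d$chrA, posA = jit(d$chrA, d$posA), sideA = d$sideA,
    chrB = d$chrB, posB = jit(d$chrB, d$posB), sideB = d$sideB,
    size_bp = NA_real_, filter_flag = "PASS",
    supporting_pairs = 3 + stats::rpois(nrow(d), 15),
    split_reads = if (profile$reports_split_reads)
      1 + stats::rpois(nrow(d), 10) else 0,
    stringsAsFactors = FALSE)
  callset(calls, profile$name, sim$genome)
}

#' Convert between call sets and junction tables
#'
#' `calls_to_junctions()` turns the calls of a call set (whose
#' breakend orientations are known, either kept by the emulator or
#' implied by the SV type) back into a junction table suitable for
#' reconstruction; `junctions_to_calls()` is the reverse, typing each
#' junction from its breakend sides.
#'
#' @param cs A [callset()].
#' @return A [junction_table()].
#' @export
calls_to_junctions <- function(cs) {
  d <- cs$calls
  need <- is.na(d$sideA) | is.na(d$sideB)
  # orientation implied by type for plain intrachromosomal calls
  d$sideA[need & d$sv_type == "DEL"] <- "pter"
  d$sideB[need & d$sv_type == "DEL"] <- "qter"
  d$sideA[need & d$sv_type == "DUP"] <- "qter"
  d$sideB[need & d$sv_type == "DUP"] <- "pter"
  junction_table(data.frame(id = d$id, chrA = d$chrA, posA = d$posA,
                            sideA = d$sideA, chrB = d$chrB, posB = d$posB,
                            sideB = d$sideB, stringsAsFactors = FALSE),
                 cs$genome)
}

#' @rdname calls_to_junctions
#' @param junctions A [junction_table()].
#' @param source Source label for the resulting call set.
#' @param genome A [genome_build()].
#' @export
junctions_to_calls <- function(junctions, source, genome) {
  j <- as.data.frame(junctions)
  sv_type <- if (nrow(j)) classify_junction(j$chrA, j$posA, j$sideA,
                                            j$chrB, j$posB, j$sideB) else character()
  callset(data.frame(id = j$id, sv_type = sv_type,
                     chrA = j$chrA, posA = j$posA, sideA = j$sideA,
                     chrB = j$chrB, posB = j$posB, sideB = j$sideB,
                     stringsAsFactors = FALSE),
          source, genome)
}
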