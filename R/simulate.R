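#' Simulation configuration
#'
#' Parameters of the synthetic rearrangement generator.  Defaults
#' emulate the kind of event seen in the case studies: a catastrophic
#' shattering with random rejoining, a minority of fragments lost,
#' junctions carrying 0-6 nt of microhomology or occasionally a short
#' non-templated insertion.
#'
#' @param seed Integer seed; every simulation is reproducible from it.
#' @param genome A [genome_build()] (default [sim_genome()], 3 toy
#'   chromosomes).
#' @param n_breakpoints Total number of breakpoints (>= 2, <= 200).
#' @param n_chromosomes_involved Chromosomes hit (1-3).
#' @param p_invert Probability an interior fragment is inverted.
#' @param p_delete_fragment Probability an interior fragment is lost.
#' @param mh_probs Probability weights for microhomology lengths
#'   0..6 nt.  Default puts mass at 0 and spreads the rest over 2-6,
#'   the range observed at sequenced junctions.
#' @param p_insertion Probability a junction carries a non-templated
#'   insertion instead of microhomology.
#' @param insertion_lengths Candidate insertion lengths (uniform).
#' @param repeat_density Repeat elements per Mb for the simulated
#'   repeat track.
#' @param chromothripsis_mode If `TRUE`, all breakpoints fall on a
#'   single chromosome (shattering with random rejoining).
#' @param flank_len Reference flank length used when junction
#'   sequences are generated.
#' @return List of class `ccr_simconfig`.
#' @export
sim_config <- function(seed = 1, genome = sim_genome(),
                       n_breakpoints = 10, n_chromosomes_involved = 2,
                       p_invert = 0.5, p_delete_fragment = 0.15,
                       mh_probs = c(0.35, 0.05, 0.15, 0.15, 0.1, 0.1, 0.1),
                       p_insertion = 0.08,
                       insertion_lengths = 1:10,
                       repeat_density = 10,
                       chromothripsis_mode = FALSE,
                       flank_len = 200) {
  stopifnot(n_breakpoints >= 2, n_breakpoints <= 200,
            p_invert >= 0 && p_invert <= 1,
            p_delete_fragment >= 0 && p_delete_fragment <= 1,
            p_insertion >= 0 && p_insertion <= 1,
            length(mh_probs) == 7, all(mh_probs >= 0),
            flank_len >= 2 * 6 + max(insertion_lengths))
  n_chromosomes_involved <- min(n_chromosomes_involved, nrow(genome$chromosomes))
  if (chromothripsis_mode) n_chromosomes_involved <- 1
  structure(as.list(environment()), class = "ccr_simconfig")
}

#' Simulate a complex chromosomal rearrangement with known truth
#'
#' Chromosomes are cut at random breakpoints; interior fragments are
#' deleted with probability `p_delete_fragment`, the survivors are
#' randomly ordered and oriented, and one linear derivative is
#' assembled per involved chromosome (each starting from a p-telomere
#' fragment and ending in a q-telomere fragment).  Junction records
#' (with breakend orientations and planted microhomology/insertions),
#' the derivative structures, the deleted intervals and annotation
#' tracks are all returned, so downstream detection, reconstruction
#' and benchmarking can be scored against exact truth.
#'
#' Conservation holds by construction: for each involved chromosome,
#' placed fragments plus deleted intervals tile `[1, length]` without
#' overlap.
#'
#' @param config A [sim_config()].
#' @return Object of class `ccr_sim`: list with `config`, `genome`,
#'   `junctions` ([junction_table()]), `derivatives`,
#'   `deleted_intervals`, `repeat_track`, `gene_track`,
#'   `junction_sequences` (filled by [generate_junction_sequences()]).
#' @export
simulate_ccr <- function(config) {
  stopifnot(inherits(config, "ccr_simconfig"))
  set.seed(config$seed)
  genome <- config$genome
  chroms <- genome$chromosomes$name[seq_len(config$n_chromosomes_involved)]
  # at least one breakpoint per involved chromosome
  n_bp <- config$n_breakpoints
  if (n_bp < length(chroms))
    stop("n_breakpoints must be >= number of involved chromosomes")
  alloc <- rep(1L, length(chroms))
  extra <- n_bp - length(chroms)
  if (extra > 0) {
    add <- table(factor(sample(seq_along(chroms), extra, replace = TRUE),
                        levels = seq_along(chroms)))
    alloc <- alloc + as.integer(add)
  }
  margin <- 1e5; min_gap <- 5e3
  frag_list <- list()
  for (ci in seq_along(chroms)) {
    chrom <- chroms[ci]; L <- chrom_length(genome, chrom)
    k <- alloc[ci]
    if ((L - 2 * margin) / (k + 1) < min_gap)
      stop("n_breakpoints exceeds chromosome capacity on chromosome ", chrom)
    repeat {
      bp <- sort(round(stats::runif(k, margin, L - margin)))
      if (k == 1 || min(diff(bp)) >= min_gap) break
    }
    start <- c(1, bp + 1); end <- c(bp, L)
    frag_list[[ci]] <- data.frame(chrom = chrom, start = start, end = end,
                                  terminal = c("pter", rep(NA_character_, k - 1), "qter"),
                                  stringsAsFactors = FALSE)
  }
  frags <- do.call(rbind, frag_list)
  interior <- is.na(frags$terminal)
  frags$deleted <- FALSE
  frags$deleted[interior] <- stats::runif(sum(interior)) < config$p_delete_fragment

  # assemble derivatives: derivative i starts at the pter fragment of
  # chromosome i and ends at the qter fragment of chromosome sigma(i)
  sigma <- sample(seq_along(chroms))
  retained_int <- which(interior & !frags$deleted)
  assign_der <- if (length(retained_int))
    sample(seq_along(chroms), length(retained_int), replace = TRUE) else integer()
  derivs <- list()
  for (di in seq_along(chroms)) {
    mid <- retained_int[assign_der == di]
    if (length(mid) > 1) mid <- sample(mid)
    orient <- ifelse(stats::runif(length(mid)) < config$p_invert, "-", "+")
    rows <- c(which(frags$terminal == "pter" & frags$chrom == chroms[di]),
              mid,
              which(frags$terminal == "qter" & frags$chrom == chroms[sigma[di]]))
    fr <- data.frame(chrom = frags$chrom[rows], start = frags$start[rows],
                     end = frags$end[rows],
                     orient = c("+", orient, "+"), stringsAsFactors = FALSE)
    derivs[[di]] <- structure(list(name = paste0("der(", chroms[di], ")"),
                                   ring = FALSE, fragments = fr),
                              class = "ccr_derivative")
  }

  # junctions from consecutive fragment pairs in each derivative walk
  jl <- list()
  for (d in derivs) {
    fr <- d$fragments
    for (i in seq_len(nrow(fr) - 1)) {
      a <- fr[i, ]; b <- fr[i + 1, ]
      # exit end of a, entry end of b, in reference terms
      posA <- if (a$orient == "+") a$end else a$start
      sideA <- if (a$orient == "+") "pter" else "qter"
      posB <- if (b$orient == "+") b$start else b$end
      sideB <- if (b$orient == "+") "qter" else "pter"
      jl[[length(jl) + 1]] <- data.frame(
        chrA = a$chrom, posA = posA, sideA = sideA,
        chrB = b$chrom, posB = posB, sideB = sideB,
        stringsAsFactors = FALSE)
    }
  }
  jdf <- do.call(rbind, jl)
  jdf$id <- sprintf("sim_j%d", seq_len(nrow(jdf)))
  # planted junction-level sequence signal
  is_ins <- stats::runif(nrow(jdf)) < config$p_insertion
  mh_len <- sample(0:6, nrow(jdf), replace = TRUE, prob = config$mh_probs)
  mh_len[is_ins] <- 0L
  ins_len <- sample(config$insertion_lengths, nrow(jdf), replace = TRUE)
  jdf$mh <- vapply(seq_len(nrow(jdf)), function(i)
    if (mh_len[i] > 0) random_dna(mh_len[i]) else "", "")
  jdf$ins <- vapply(seq_len(nrow(jdf)), function(i)
    if (is_ins[i]) random_dna(ins_len[i]) else "", "")
  jdf$estimated <- FALSE
  junctions <- junction_table(jdf, genome)

  deleted <- frags[frags$deleted, c("chrom", "start", "end"), drop = FALSE]
  deleted <- merge_adjacent_intervals(deleted)

  derivs <- lapply(derivs, canonicalize_derivative, genome = genome)
  for (k in seq_along(derivs))
    derivs[[k]]$fragments$label <- fragment_labels(seq_len(nrow(derivs[[k]]$fragments)))

  repeat_track <- generate_repeat_track(genome, config$repeat_density,
                                        seed = config$seed + 7L,
                                        chroms = chroms)
  gene_track <- generate_gene_track(genome, n_genes = 60,
                                    seed = config$seed + 13L, chroms = chroms)
  sim <- structure(list(config = config, genome = genome,
                        junctions = junctions, derivatives = derivs,
                        deleted_intervals = deleted,
                        repeat_track = repeat_track, gene_track = gene_track,
                        junction_sequences = NULL),
                   class = "ccr_sim")
  sim
}

#' @export
print.ccr_sim <- function(x, ...) {
  cat("<ccr_sim> seed", x$config$seed, "-", nrow(x$junctions), "junctions,",
      length(x$derivatives), "derivative(s),",
      nrow(x$deleted_intervals), "deleted interval(s)\n")
  invisible(x)
}

merge_adjacent_intervals <- function(iv) {
  if (nrow(iv) == 0) {
    iv$size_bp <- numeric(); return(iv)
  }
  iv <- iv[order(iv$chrom, iv$start), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    j <- nrow(out)
    if (iv$chrom[i] == out$chrom[j] && iv$start[i] <= out$end[j] + 1)
      out$end[j] <- max(out$end[j], iv$end[i])
    else out <- rbind(out, iv[i, ])
  }
  out$size_bp <- out$end - out$start
  rownames(out) <- NULL
  out
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

#' Generate junction sequences with planted signal
#'
#' Fills in, for every truth junction, the two reference flanks (each
#' oriented as traversed in the derivative) and the derivative
#' sequence across the join, constructed so that the planted
#' microhomology is shared verbatim by both flanks abutting their
#' breakpoints, or the planted insertion appears between the two
#' mapped flanks.  Flanks are uniform random DNA - the generator
#' controls the planted signal exactly rather than drawing from a
#' reference FASTA.
#'
#' @param sim A [simulate_ccr()] result.
#' @param flank_len Flank length (default from the config).
#' @return `sim` with `junction_sequences` filled: `data.frame` with
#'   `junction_id`, `flankA_ref`, `flankB_ref`, `derivative_seq`,
#'   `planted_mh`, `planted_ins`.
#' @export
generate_junction_sequences <- function(sim, flank_len = sim$config$flank_len) {
  set.seed(sim$config$seed + 101L)
  j <- sim$junctions
  rows <- lapply(seq_len(nrow(j)), function(i) {
    mh <- j$mh[i]; ins <- j$ins[i]; m <- nchar(mh)
    flankA <- random_dna(flank_len)
    if (m > 0) substr(flankA, flank_len - m + 1, flank_len) <- mh
    flankB <- paste0(mh, random_dna(flank_len - m))
    derivative <- if (nchar(ins) > 0)
      paste0(flankA, ins, flankB)
    else
      paste0(flankA, substr(flankB, m + 1, flank_len))
    data.frame(junction_id = j$id[i], flankA_ref = flankA,
               flankB_ref = flankB, derivative_seq = derivative,
               planted_mh = mh, planted_ins = ins,
               stringsAsFactors = FALSE)
  })
  sim$junction_sequences <- do.call(rbind, rows)
  sim
}

#' Simulated annotation tracks and frequency database
#'
#' `generate_repeat_track()` scatters repeat elements (names drawn
#' from common repeat families) at the given density;
#' `generate_gene_track()` places non-overlapping gene models, a
#' fraction flagged as known disease genes; `build_frequency_db()`
#' builds a population-frequency database stand-in containing the
#' supplied polymorphic calls with counts >= 1 and, by construction,
#' never containing the truth rearrangement junctions.
#'
#' @param genome A [genome_build()].
#' @param density_per_mb Repeat elements per Mb.
#' @param seed Integer seed.
#' @param chroms Chromosomes to cover (default all).
#' @return `data.frame` tracks; see each function.
#' @export
generate_repeat_track <- function(genome, density_per_mb, seed = 1, chroms = NULL) {
  set.seed(seed)
  if (is.null(chroms)) chroms <- genome$chromosomes$name
  fams <- c(AluY = "SINE/Alu", AluSx = "SINE/Alu", L1PA4 = "LINE/L1",
            L2 = "LINE/L2", MIRb = "SINE/MIR", THE1B = "LTR/ERVL-MaLR",
            MER41B = "LTR/ERV1", "(CACCC)n" = "Simple_repeat",
            LTR5B = "LTR/ERVK", L1M5 = "LINE/L1")
  out <- lapply(chroms, function(chrom) {
    L <- chrom_length(genome, chrom)
    n <- round(density_per_mb * L / 1e6)
    if (n == 0) return(NULL)
    start <- sort(round(stats::runif(n, 1, L - 1e4)))
    width <- pmax(50, round(stats::rlnorm(n, log(300), 0.6)))
    nm <- sample(names(fams), n, replace = TRUE)
    data.frame(chrom = chrom, start = start,
               end = pmin(start + width, L), name = nm,
               family = unname(fams[nm]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      name = character(), family = character())
  rownames(out) <- NULL
  out
}

#' @rdname generate_repeat_track
#' @param n_genes Number of gene models.
#' @param p_disease Fraction flagged as disease genes.
#' @export
generate_gene_track <- function(genome, n_genes, seed = 1, p_disease = 0.1,
                                chroms = NULL) {
  set.seed(seed)
  if (is.null(chroms)) chroms <- genome$chromosomes$name
  chrom <- sample(chroms, n_genes, replace = TRUE)
  L <- chrom_length(genome, chrom)
  start <- round(stats::runif(n_genes, 1, L * 0.95))
  width <- round(stats::runif(n_genes, 1e4, 5e5))
  df <- data.frame(chrom = chrom, start = start,
                   end = pmin(start + width, L),
                   name = sprintf("G%03d", seq_len(n_genes)),
                   biotype = "protein_coding",
                   disease_flag = stats::runif(n_genes) < p_disease,
                   stringsAsFactors = FALSE)
  df[order(df$chrom, df$start), ]
}

#' @rdname generate_repeat_track
#' @param polymorphic_calls Call `data.frame` of population variants.
#' @param n_samples Cohort size the counts are drawn against.
#' @export
build_frequency_db <- function(polymorphic_calls, n_samples = 100, seed = 1) {
  set.seed(seed)
  db <- as.data.frame(polymorphic_calls)
  db$count <- 1L + stats::rpois(nrow(db), lambda = n_samples * 0.05)
  structure(list(n_samples = n_samples, variants = db), class = "ccr_freqdb")
}
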