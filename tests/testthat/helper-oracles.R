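# Independent brute-force oracles used by property and acceptance tests.

# Jaccard by explicit base counting (half-open integer intervals)
jaccard_base_count <- function(startA, endA, startB, endB) {
  a <- seq.int(startA, endA - 1L)
  b <- seq.int(startB, endB - 1L)
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

# Exhaustive-split microhomology/insertion oracle: tries every
# microhomology length and every insertion length up to the window and
# keeps the parse with the shortest insertion (ties -> microhomology).
mh_oracle <- function(flankA, flankB, derivative, window = 50) {
  D <- nchar(derivative); L <- nchar(flankA)
  stopifnot(nchar(flankB) == L)
  for (m in seq(min(window, L), 0)) {
    if (D != 2 * L - m) next
    okA <- substr(derivative, 1, L) == flankA
    okB <- substr(derivative, L - m + 1, D) == flankB
    shared <- m == 0 || substr(flankA, L - m + 1, L) == substr(flankB, 1, m)
    if (okA && okB && shared) {
      if (m == 0) return(list(category = "blunt", mh_seq = "", ins_seq = ""))
      return(list(category = "microhomology",
                  mh_seq = substr(flankB, 1, m), ins_seq = ""))
    }
  }
  for (k in seq_len(window)) {
    if (D != 2 * L + k) next
    if (substr(derivative, 1, L) == flankA &&
        substr(derivative, L + k + 1, D) == flankB)
      return(list(category = "insertion", mh_seq = "",
                  ins_seq = substr(derivative, L + 1, L + k)))
  }
  stop("oracle: no parse found")
}

# random planted junction sequence (independent of the generator)
plant_junction <- function(mh_len = 0, ins_len = 0, flank_len = 80) {
  rdna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  mh <- if (mh_len > 0) rdna(mh_len) else ""
  ins <- if (ins_len > 0) rdna(ins_len) else ""
  flankA <- paste0(rdna(flank_len - mh_len), mh)
  flankB <- paste0(mh, rdna(flank_len - mh_len))
  derivative <- if (ins_len > 0) paste0(flankA, ins, flankB)
                else paste0(flankA, substr(flankB, mh_len + 1, flank_len))
  list(flankA = flankA, flankB = flankB, derivative = derivative,
       mh = mh, ins = ins)
}

# fragment key for comparing derivative structures
derivative_keys <- function(derivs) {
  sort(vapply(derivs, function(d) {
    f <- d$fragments[, c("chrom", "start", "end", "orient")]
    paste(apply(f, 1, paste, collapse = ":"), collapse = "|")
  }, ""))
}

# scatter n intervals of the given width across a genome so that no
# two are similar under the default criterion (>=150 kb apart)
scatter_intervals <- function(genome, n, width = 1e4, gap = 15e4) {
  slots <- do.call(rbind, lapply(seq_len(nrow(genome$chromosomes)), function(i) {
    L <- genome$chromosomes$length[i]
    start <- seq(1e5, L - width - 1e5, by = gap)
    data.frame(chrom = genome$chromosomes$name[i], start = start)
  }))
  if (n > nrow(slots)) stop("not enough slots")
  s <- slots[seq_len(n), ]
  data.frame(sv_type = "DEL", chrA = s$chrom, posA = s$start,
             chrB = s$chrom, posB = s$start + width,
             stringsAsFactors = FALSE)
}
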