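printed_karyotype <- function(case) {
  if (case == 1) paste(
    "seq[GRCh37]",
    "g.[chr2:pter_cen_209425831::chr15:55083064_qter]",
    "g.[chr8:pter_cen_114508085::chr2:214880375_qter]",
    "g.[chr15:pter_cen_55083061::chr2:211567929_211580844inv::chr2:211580785_212551796::chr8:129040005_qter]")
  else paste(
    "seq[GRCh37]",
    "g.[chr1:pter_cen_196997343::chr5:124956736_qter]",
    "g.[chr5:pter_cen_124956731::chr10:20816168_pter]",
    "g.[chr10:qter_cen_20816166::4689760_19120882del::chr1:196997343_qter]")
}

test_that("case walks reproduce the published derivative structures", {
  g <- genome_grch37()
  for (case in 1:2) {
    rec <- reconstruct_ccr(curated_walk_junctions(case), g)
    expect_length(rec$derivatives, 3)
    expect_equal(canonical_karyotype(rec$karyotype),
                 canonical_karyotype(printed_karyotype(case)))
  }
  # Case 1 deletions at the breakpoints: 2.1, 2.3 and 14.5 Mb
  rec1 <- reconstruct_ccr(curated_walk_junctions(1), g)
  big <- rec1$deleted_intervals[rec1$deleted_intervals$size_bp > 1e4, ]
  expect_equal(format_mb(big$size_bp), c("2.1", "2.3", "14.5"))
  # Case 2: the translocated chr10 block lost 14.4 Mb
  rec2 <- reconstruct_ccr(curated_walk_junctions(2), g)
  big2 <- rec2$deleted_intervals[rec2$deleted_intervals$size_bp > 1e4, ]
  expect_equal(format_mb(big2$size_bp), "14.4")
  expect_equal(big2$chrom, "10")
})

test_that("empty junction sets walk into reference chromosomes", {
  g <- sim_genome()
  empty <- junction_table(data.frame(chrA = character(), posA = numeric(),
                                     chrB = character(), posB = numeric()),
                          g)
  graph <- build_breakpoint_graph(empty, g)
  derivs <- walk_derivatives(graph)
  expect_length(derivs, 3)   # one reference derivative per chromosome
  for (d in derivs) {
    expect_equal(nrow(d$fragments), 1)
    expect_equal(d$fragments$start, 1)
    expect_equal(d$fragments$end, chrom_length(g, d$fragments$chrom))
  }
  expect_equal(nrow(infer_deleted_intervals(derivs, g)), 0)
})

test_that("conflicting junction attachments raise an ambiguity error", {
  g <- sim_genome()
  j <- junction_table(data.frame(
    id = c("a", "b"),
    chrA = c("1", "1"), posA = c(5e6, 5e6), sideA = c("pter", "pter"),
    chrB = c("2", "2"), posB = c(1e6, 2e6), sideB = c("qter", "qter")), g)
  expect_error(build_breakpoint_graph(j, g), "a, b")
})

test_that("karyotype strings parse and render round-trip", {
  g <- genome_grch37()
  for (case in 1:2) {
    s <- printed_karyotype(case)
    p <- parse_karyotype(s, g)
    expect_equal(canonical_karyotype(render_karyotype(p$derivatives, g)),
                 canonical_karyotype(s))
  }
  # the deletion annotation recovers a deleted interval
  p2 <- parse_karyotype(printed_karyotype(2), g)
  expect_equal(p2$deleted_intervals$chrom, "10")
  expect_equal(p2$deleted_intervals$lo, 4689760)
  expect_equal(p2$deleted_intervals$hi, 19120882)
  # ...and re-splits the run that spans it (3 fragments in der(5))
  der5 <- p2$derivatives[[2]]
  expect_equal(nrow(der5$fragments), 3)
  # a normal chromosome renders as a single trivial segment
  whole <- structure(list(name = "der(1)", ring = FALSE,
                          fragments = data.frame(chrom = "1", start = 1,
                                                 end = 249250621,
                                                 orient = "+", label = "A")),
                     class = "ccr_derivative")
  expect_equal(canonical_karyotype(render_karyotype(list(whole), g)),
               "seq[GRCh37]g.[chr1:pter_qter]")
  expect_error(parse_karyotype("seq[GRCh37] g.[chr1:banana]", g), "malformed")
})

test_that("simulated truths reconstruct exactly from noiseless calls", {
  for (s in 1:20) {
    cfg <- sim_config(seed = 100 + s, n_breakpoints = sample(2:40, 1),
                      n_chromosomes_involved = sample(1:3, 1),
                      chromothripsis_mode = s %% 3 == 0)
    sim <- simulate_ccr(cfg)
    cs <- emulate_technology(sim, technology_profile("exact"), seed = s)
    rec <- reconstruct_ccr(calls_to_junctions(cs), sim$genome)
    expect_identical(derivative_keys(rec$derivatives),
                     derivative_keys(sim$derivatives))
    got <- rec$deleted_intervals[, c("chrom", "start", "end")]
    want <- sim$deleted_intervals[, c("chrom", "start", "end")]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got[order(got$chrom, got$start), ],
                 want[order(want$chrom, want$start), ],
                 ignore_attr = TRUE)
    # orientation correctness: inverted count matches the planted truth
    n_inv <- function(dd) sum(vapply(dd, function(d)
      sum(d$fragments$orient == "-"), 0L))
    expect_equal(n_inv(rec$derivatives), n_inv(sim$derivatives))
    # karyotype round-trips fragment order and orientation
    p <- parse_karyotype(render_karyotype(rec$derivatives, sim$genome), sim$genome)
    expect_identical(derivative_keys(p$derivatives),
                     derivative_keys(rec$derivatives))
  }
})

test_that("genes are assigned to deleted intervals by intersection", {
  g <- sim_genome()
  genes <- data.frame(chrom = "1",
                      start = c(1e6, 4e6, 9.9e6), end = c(2e6, 5e6, 10.5e6),
                      name = c("G1", "G2", "G3"),
                      disease_flag = c(TRUE, FALSE, FALSE))
  iv <- data.frame(chrom = "1", start = 3e6, end = 1e7)
  hit <- genes_in_intervals(iv, genes)[[1]]
  expect_setequal(hit$name, c("G2", "G3"))  # G3 straddles the boundary
  expect_equal(nrow(genes_in_intervals(iv, genes[0, ])[[1]]), 0)
})
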