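test_that("minimal simulation is a reciprocal-translocation-like truth", {
  sim <- simulate_ccr(sim_config(seed = 1, n_breakpoints = 2,
                                 n_chromosomes_involved = 2,
                                 p_delete_fragment = 0))
  expect_equal(nrow(sim$junctions), 2)
  expect_equal(nrow(sim$deleted_intervals), 0)
})

test_that("chromothripsis shattering yields breakpoints + 1 fragments", {
  # with no fragment losses every cut keeps both junction sides
  sim <- simulate_ccr(sim_config(seed = 4, n_breakpoints = 33,
                                 chromothripsis_mode = TRUE,
                                 p_delete_fragment = 0))
  # 33 cuts on one chromosome: the truth endpoints cluster into 33
  # breakpoints and the graph cuts the chromosome into 34 segments
  expect_equal(nrow(cluster_breakpoints(sim$junctions)$clusters), 33)
  graph <- build_breakpoint_graph(sim$junctions, sim$genome)
  expect_equal(nrow(graph$segments), 34)
})

test_that("p_delete_fragment = 1 removes every interior fragment", {
  sim <- simulate_ccr(sim_config(seed = 5, n_breakpoints = 8,
                                 n_chromosomes_involved = 2,
                                 p_delete_fragment = 1))
  frags <- do.call(rbind, lapply(sim$derivatives, function(d) d$fragments))
  # only telomere-bearing fragments remain placed
  for (ch in unique(frags$chrom)) {
    f <- frags[frags$chrom == ch, ]
    L <- chrom_length(sim$genome, ch)
    expect_true(all(f$start == 1 | f$end == L))
  }
  expect_true(nrow(sim$deleted_intervals) >= 1)
})

test_that("retained fragments and deleted intervals tile each chromosome", {
  for (s in 1:25) {
    cfg <- sim_config(seed = s,
                      n_breakpoints = sample(2:40, 1),
                      n_chromosomes_involved = sample(1:3, 1),
                      chromothripsis_mode = s %% 4 == 0)
    sim <- simulate_ccr(cfg)
    frags <- do.call(rbind, lapply(sim$derivatives, function(d)
      d$fragments[, c("chrom", "start", "end")]))
    for (ch in unique(frags$chrom)) {
      iv <- rbind(frags[frags$chrom == ch, c("start", "end")],
                  sim$deleted_intervals[sim$deleted_intervals$chrom == ch,
                                        c("start", "end")])
      iv <- iv[order(iv$start), ]
      expect_equal(iv$start[1], 1)
      expect_equal(iv$end[nrow(iv)], chrom_length(sim$genome, ch))
      if (nrow(iv) > 1)
        expect_true(all(iv$start[-1] == iv$end[-nrow(iv)] + 1))
    }
  }
})

test_that("generated junction sequences carry the planted signal", {
  sim <- generate_junction_sequences(
    simulate_ccr(sim_config(seed = 6, n_breakpoints = 30,
                            chromothripsis_mode = TRUE)))
  js <- sim$junction_sequences
  for (i in seq_len(nrow(js))) {
    r <- detect_microhomology(js$flankA_ref[i], js$flankB_ref[i],
                              js$derivative_seq[i])
    expect_equal(r$mh_seq, js$planted_mh[i])
    expect_equal(r$ins_seq, js$planted_ins[i])
  }
})

test_that("noiseless emulation reports every junction at truth coordinates", {
  sim <- simulate_ccr(sim_config(seed = 7, n_breakpoints = 15,
                                 n_chromosomes_involved = 3))
  cs <- emulate_technology(sim, technology_profile("perfect"), seed = 7)
  expect_equal(nrow(cs$calls), nrow(sim$junctions))
  j <- as.data.frame(sim$junctions)
  m <- match(paste0("perfect_", j$id), cs$calls$id)
  expect_false(anyNA(m))
  expect_true(all(sort(c(cs$calls$posA, cs$calls$posB)) ==
                    sort(c(j$posA, j$posB))))
})

test_that("type maps and size floors shape the emitted call set", {
  g <- sim_genome()
  # truth with a tandem-duplication-like junction and a 12 kb inversion
  j <- junction_table(data.frame(
    id = c("dup1", "inv1"),
    chrA = c("1", "2"), posA = c(5e6, 8e6), sideA = c("qter", "pter"),
    chrB = c("1", "2"), posB = c(6e6, 8e6 + 12e3), sideB = c("pter", "pter")),
    g)
  sim <- structure(list(config = sim_config(seed = 1), genome = g,
                        junctions = j,
                        repeat_track = data.frame(chrom = character(),
                                                  start = numeric(),
                                                  end = numeric(),
                                                  name = character())),
                   class = "ccr_sim")
  om <- emulate_technology(sim, technology_profile(
    "optical", min_size_bp = 15000, type_report_map = c(DUP = "INS")), seed = 2)
  expect_equal(sum(om$calls$sv_type == "DUP"), 0)
  expect_equal(om$calls$sv_type, "INS")      # DUP remapped
  expect_false("inv1" %in% sub("^optical_", "", om$calls$id))  # below size floor
  pe <- emulate_technology(sim, technology_profile("pe"), seed = 2)
  expect_setequal(sub("^pe_", "", pe$calls$id), c("dup1", "inv1"))
})

test_that("the frequency database never contains truth junctions", {
  sim <- simulate_ccr(sim_config(seed = 8, n_breakpoints = 10,
                                 n_chromosomes_involved = 2))
  start <- seq(1e5, by = 15e4, length.out = 100)  # uninvolved chromosome
  poly <- data.frame(sv_type = "DEL", chrA = "3", posA = start,
                     chrB = "3", posB = start + 1e4)
  db <- build_frequency_db(poly, n_samples = 100, seed = 8)
  expect_equal(nrow(db$variants), 100)
  expect_true(all(db$variants$count >= 1))
  truth_calls <- junctions_to_calls(sim$junctions, "truth", sim$genome)
  ann <- annotate_frequency(truth_calls$calls, db)
  expect_true(all(ann$freq_count == 0))
  # empty repeat track at density 0
  expect_equal(nrow(generate_repeat_track(sim_genome(), 0, seed = 1)), 0)
})
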