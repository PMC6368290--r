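mk_calls <- function(df, source = "a", genome = genome_grch37()) {
  callset(df, source, genome)
}

test_that("jaccard index matches hand values and is symmetric", {
  expect_equal(jaccard_index(100, 200, 100, 200), 1)
  expect_equal(jaccard_index(100, 200, 300, 400), 0)
  expect_equal(jaccard_index(100, 200, 150, 250), 50 / 150)
  expect_equal(jaccard_index(100, 200, 150, 250),
               jaccard_index(150, 250, 100, 200))
})

test_that("jaccard index equals the base-counting oracle", {
  set.seed(31)
  for (i in 1:1000) {
    a <- sample.int(1e5, 1); b <- a + sample.int(2000, 1)
    c <- a + sample(-1500:1500, 1); d <- c + sample.int(2000, 1)
    expect_equal(jaccard_index(a, b, c, d), jaccard_base_count(a, b, c, d))
  }
})

test_that("similarity thresholds are strict as worded", {
  g <- genome_grch37()
  # jaccard exactly 0.4 must fail ("exceed" is strict):
  # [0,400] vs [0,1000] -> 400/1000 = 0.4
  a <- mk_calls(data.frame(sv_type = "DEL", chrA = "1", posA = 1000,
                           chrB = "1", posB = 1400))$calls
  b <- mk_calls(data.frame(sv_type = "DEL", chrA = "1", posA = 1000,
                           chrB = "1", posB = 2000))$calls
  expect_equal(jaccard_index(a$posA, a$posB, b$posA, b$posB), 0.4)
  expect_false(is_similar(a, b))

  # ends 99,999 bp and 0 bp apart with high jaccard -> similar
  a2 <- mk_calls(data.frame(sv_type = "DEL", chrA = "1", posA = 1e6,
                            chrB = "1", posB = 9e6))$calls
  b2 <- mk_calls(data.frame(sv_type = "DEL", chrA = "1", posA = 1e6 + 99999,
                            chrB = "1", posB = 9e6))$calls
  expect_true(jaccard_index(a2$posA, a2$posB, b2$posA, b2$posB) > 0.4)
  expect_true(is_similar(a2, b2))
  # exactly 100 kb is out
  b3 <- transform(b2, posA = 1e6 + 1e5)
  expect_false(is_similar(a2, b3))

  # interchromosomal pairs need the same chromosome pair
  t1 <- mk_calls(data.frame(sv_type = "BND", chrA = "2", posA = 209425831,
                            chrB = "15", posB = 55083061))$calls
  t2 <- mk_calls(data.frame(sv_type = "BND", chrA = "2", posA = 209425800,
                            chrB = "15", posB = 55083100))$calls
  t3 <- mk_calls(data.frame(sv_type = "BND", chrA = "2", posA = 209425831,
                            chrB = "8", posB = 55083061))$calls
  expect_true(is_similar(t1, t2))
  expect_false(is_similar(t1, t3))
  expect_equal(is_similar(t1, t2), is_similar(t2, t1))
})

test_that("merging is idempotent, order-invariant and counts unions", {
  g <- genome_grch37()
  base <- scatter_intervals(g, 5)
  setA <- mk_calls(base[1:3, ], "A")
  shifted <- base[2:3, ]; shifted$posA <- shifted$posA + 50; shifted$posB <- shifted$posB + 50
  setB <- mk_calls(rbind(shifted, base[4:5, ]), "B")
  m <- merge_callsets(list(setA, setB))
  expect_equal(nrow(m), 5)  # 3 + 4 sharing 2
  expect_setequal(m$present_in[m$n_members == 2], "A,B")

  # self-merge leaves cluster count unchanged
  m2 <- merge_callsets(list(setA, setA))
  expect_equal(nrow(m2), 3)

  # order of inputs does not matter
  m3 <- merge_callsets(list(setB, setA))
  expect_equal(m3[order(m3$chrA, m3$posA), c("chrA", "posA", "present_in")],
               m[order(m$chrA, m$posA), c("chrA", "posA", "present_in")],
               ignore_attr = TRUE)
})

test_that("overlap matrix reproduces a planted concordance pattern", {
  g <- genome_grch37()
  ident <- mk_calls(scatter_intervals(g, 10), "x")
  ident2 <- callset(ident$calls, "y", g)
  om <- overlap_matrix(list(x = ident, y = ident2))
  expect_equal(unname(om$pct["x", "y"]), 100)
  disj <- mk_calls(scatter_intervals(g, 20)[11:20, ], "z")
  om2 <- overlap_matrix(list(x = mk_calls(scatter_intervals(g, 10), "x"), z = disj))
  expect_equal(unname(om2$counts["x", "z"]), 0)
})

test_that("planted 626-of-883 overlap reports 70.9%", {
  g <- genome_grch37()
  slots <- scatter_intervals(g, 883 + 4802 - 626)
  mp <- mk_calls(slots[1:883, ], "mp")
  pe_shared <- slots[1:626, ]
  pe_shared$posA <- pe_shared$posA + 30; pe_shared$posB <- pe_shared$posB + 30
  pe <- mk_calls(rbind(pe_shared, slots[884:(883 + 4802 - 626), ]), "pe")
  om <- overlap_matrix(list(mp = mp, pe = pe))
  expect_equal(unname(om$counts["mp", "pe"]), 626)
  expect_equal(unname(om$pct["mp", "pe"]), 70.9)
})

test_that("filtering rules apply in order and conserve counts", {
  g <- genome_grch37()
  calls <- mk_calls(data.frame(
    sv_type = "DEL", chrA = "1",
    posA = c(1e6, 2e6, 3e6, 4e6, 5e6, 6e6),
    chrB = "1",
    posB = c(1e6, 2e6, 3e6, 4e6, 5e6, 6e6) + c(5e4, 5e4, 5e4, 9999, 9999, 5e4),
    filter_flag = c("LowQual", rep("PASS", 5)),
    supporting_pairs = c(20, 20, 7, 20, 20, 8),
    split_reads = 0))$calls
  calls$freq_count <- c(0, 3, 0, 0, 0, 0)
  calls$genic <- c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE)
  f <- filter_calls(calls)
  expect_equal(nrow(f$kept) + nrow(f$removed), 6)
  expect_setequal(f$removed$filtered_reason,
                  c("pass_only", "frequency", "min_support", "small_intergenic"))
  # supporting pairs: 7 removed, exactly 8 kept
  expect_true(any(f$removed$supporting_pairs == 7 &
                    f$removed$filtered_reason == "min_support"))
  expect_true(8 %in% f$kept$supporting_pairs)
  # 9,999 bp: removed when intergenic, kept when genic
  small <- f$removed[f$removed$filtered_reason == "small_intergenic", ]
  expect_false(small$genic)
  expect_true(any(!is.na(f$kept$size_bp) & f$kept$size_bp == 9999 & f$kept$genic))
  # with the frequency rule active nothing kept is in the database
  expect_true(all(f$kept$freq_count == 0))
})

test_that("ranking follows frequency, support, size, position", {
  g <- genome_grch37()
  calls <- mk_calls(data.frame(
    sv_type = c("DEL", "DEL", "DEL", "BND", "BND"),
    chrA = c("1", "1", "1", "2", "1"),
    posA = c(5e6, 1e6, 2e6, 1e6, 1e6),
    chrB = c("1", "1", "1", "15", "15"),
    posB = c(6e6, 1.5e6, 4e6, 2e6, 2e6),
    supporting_pairs = c(8, 20, 20, 10, 10)))$calls
  calls$freq_count <- c(5, 0, 0, 0, 0)
  r <- rank_calls(calls, g)
  expect_equal(r$freq_count[nrow(r)], 5)        # database hit ranks last
  expect_equal(r$supporting_pairs[1:2], c(20, 20))
  expect_equal(r$size_bp[1], 2e6)               # bigger first at equal support
  # full tie between the two BNDs -> position decides
  bnd <- r[r$sv_type == "BND", ]
  expect_equal(bnd$chrA, c("1", "2"))
})

test_that("orthogonal confirmation keeps only corroborated CNVs", {
  g <- genome_grch37()
  acgh_calls <- scatter_intervals(g, 83, width = 5e4)
  acgh <- callset(acgh_calls, "aCGH", g)
  conf_part <- acgh_calls[1:17, ]
  conf_part$posA <- conf_part$posA + 100; conf_part$posB <- conf_part$posB + 100
  pe <- callset(conf_part, "pe", g)
  confirmed <- confirm_with_orthogonal(acgh, list(pe))
  expect_equal(nrow(confirmed$calls), 17)
  none <- confirm_with_orthogonal(acgh, list(callset(acgh_calls[0, ], "mp", g)))
  expect_equal(nrow(none$calls), 0)
})
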