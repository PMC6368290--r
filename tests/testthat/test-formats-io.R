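test_that("SV VCF round-trips coordinates, types, orientations and filters", {
  set.seed(51)
  for (s in 1:3) {
    sim <- simulate_ccr(sim_config(seed = 50 + s, n_breakpoints = 10 + s,
                                   n_chromosomes_involved = 3))
    cs <- emulate_technology(sim, tech_profiles()$pe, seed = s)
    cs$calls$filter_flag[1] <- "LowQual"
    f <- withr::local_tempfile(fileext = ".vcf")
    write_sv_vcf(cs, f)
    back <- read_sv_vcf(f, sim$genome, source = cs$source)
    cols <- c("sv_type", "chrA", "posA", "chrB", "posB", "filter_flag",
              "supporting_pairs", "split_reads")
    a <- cs$calls[order(cs$calls$chrA, cs$calls$posA, cs$calls$posB), cols]
    b <- back$calls[order(back$calls$chrA, back$calls$posA, back$calls$posB), cols]
    expect_equal(a, b, ignore_attr = TRUE)
    # breakend orientation preserved through bracket notation
    ab <- cs$calls[cs$calls$sv_type == "BND", c("posA", "sideA", "sideB")]
    bb <- back$calls[back$calls$sv_type == "BND", c("posA", "sideA", "sideB")]
    expect_equal(ab[order(ab$posA), ], bb[order(bb$posA), ], ignore_attr = TRUE)
  }
})

test_that("VCF reader handles published-style records and edge cases", {
  g <- genome_grch37()
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "10\t4689760\tdel1\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=19120882;PE=12;SR=9",
    "15\t55083064\tbnd1\tN\tN]2:209425831]\t.\tPASS\tSVTYPE=BND;MATEID=bnd2;PE=8;SR=4",
    "2\t209425831\tbnd2\tN\tN]15:55083064]\t.\tPASS\tSVTYPE=BND;MATEID=bnd1;PE=8;SR=4",
    "1\t1000\tnosv\tA\tT\t.\tPASS\tDP=10",
    "1\t2000\tbad\tN\tN[oops\t.\tPASS\tSVTYPE=BND"), f)
  expect_warning(cs <- read_sv_vcf(f, g), "malformed")
  expect_equal(nrow(cs$calls), 3)  # DEL + paired BND + UNKNOWN
  del <- cs$calls[cs$calls$sv_type == "DEL", ]
  expect_equal(del$size_bp, 14431122)
  expect_equal(del$supporting_pairs, 12)
  bnd <- cs$calls[cs$calls$sv_type == "BND", ]
  expect_equal(nrow(bnd), 1)       # mates collapsed into one call
  expect_setequal(c(bnd$chrA, bnd$chrB), c("2", "15"))
  expect_equal(cs$calls$sv_type[cs$calls$id == "nosv"], "UNKNOWN")

  # empty body
  f2 <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), f2)
  expect_equal(nrow(read_sv_vcf(f2, g)$calls), 0)
})

test_that("SMAP tables map vendor rows onto typed calls", {
  g <- genome_grch37()
  f <- withr::local_tempfile(fileext = ".smap")
  writeLines(c(
    "#h SmapEntryID\tQryContigID\tRefcontigID1\tRefcontigID2\tRefStartPos\tRefEndPos\tType\tConfidence",
    paste("SmapEntryID", "QryContigID", "RefcontigID1", "RefcontigID2",
          "RefStartPos", "RefEndPos", "Type", "Confidence", sep = "\t"),
    "1\t10\t10\t10\t4669757\t19134619\tdeletion\t12.5",
    "2\t11\t2\t15\t209402341\t55089032\ttranslocation_interchr\t9",
    "3\t12\t1\t1\t5000000\t5020000\tinsertion\t0.2",
    "4\t13\t1\t1\t9000000\t9040000\twibble\t8"), f)
  expect_warning(
    expect_message(cs <- read_smap_table(f, g, min_confidence = 1), "1 row"),
    "unknown SMAP type")
  expect_equal(attr(cs, "n_dropped"), 1)     # low-confidence insertion
  expect_equal(nrow(cs$calls), 3)
  del <- cs$calls[cs$calls$sv_type == "DEL", ]
  expect_equal(c(del$posA, del$posB), c(4669757, 19134619))
  expect_equal(sum(cs$calls$sv_type == "BND"), 1)
  expect_equal(sum(cs$calls$sv_type == "UNKNOWN"), 1)

  # header-only file
  f2 <- withr::local_tempfile(fileext = ".smap")
  writeLines(paste("SmapEntryID", "QryContigID", "RefcontigID1", "RefcontigID2",
                   "RefStartPos", "RefEndPos", "Type", "Confidence", sep = "\t"), f2)
  expect_equal(nrow(read_smap_table(f2, g)$calls), 0)
})

test_that("aCGH segments become DEL/DUP calls", {
  g <- genome_grch37()
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tcall\tprobes",
               "8\t114508086\t129040004\tloss\t310",
               "1\t1000000\t1500000\tgain\t25"), f)
  cs <- read_acgh_segments(f, g)
  expect_equal(cs$calls$sv_type[cs$calls$chrA == "8"], "DEL")
  expect_equal(format_mb(cs$calls$size_bp[cs$calls$chrA == "8"]), "14.5")
  expect_equal(cs$calls$sv_type[cs$calls$chrA == "1"], "DUP")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tcall\tprobes", "1\t1\t2\tamplified\t3"), f2)
  expect_error(read_acgh_segments(f2, g), "gain/loss")
})

test_that("public dataset dialects read and split per type", {
  g <- genome_grch37()
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr\tstart\tend\tvariantsubtype",
               "chr1\t100000\t200000\tloss",
               "1\t300000\t400000\tgain",
               "2\t100000\t150000\tdeletion",
               "2\t500000\t600000\tinversion",
               "5\t100000\t101000\tinsertion"), f)
  cs <- read_public_dataset(f, g, "dgv_tsv")
  expect_equal(nrow(cs$calls), 5)
  parts <- split_by_type(cs)
  expect_equal(sum(vapply(parts, function(p) nrow(p$calls), 0L)), 5)
  expect_equal(nrow(parts$DEL$calls), 2)

  # GIAB evidence filter keeps only CG/PB-supported records
  fv <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "1\t100000\tv1\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=101000;CGcalls=0;PBcalls=0",
    "1\t200000\tv2\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=201000;CGcalls=0;PBcalls=2",
    "1\t300000\tv3\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=301000;CGcalls=1;PBcalls=0"), fv)
  kept <- read_public_dataset(fv, g, "giab_vcf", evidence_filter = TRUE)
  expect_setequal(kept$calls$id, c("v2", "v3"))
  all3 <- read_public_dataset(fv, g, "giab_vcf")
  expect_equal(nrow(all3$calls), 3)
  expect_error(read_public_dataset(fv, g, "nonsense"), "dialect")
})

test_that("BED tracks convert to 1-based inclusive coordinates", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t300\tAluY;SINE/Alu",
               "chr1\t5000\t5600\tL1PA4;LINE/L1",
               "chr2\t10\t20\tL2"), f)
  reps <- read_bed_track(f, "repeat")
  expect_equal(nrow(reps), 3)
  expect_equal(reps$start[1], 101)  # BED start 100 -> 1-based 101
  expect_equal(reps$end[1], 300)
  expect_equal(reps$name[1], "AluY")
  expect_equal(reps$family[1], "SINE/Alu")

  fg <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t1000\t2000\tGATA3\t1",
               "chr1\t9000\t9500\tNET1\t0"), fg)
  genes <- read_bed_track(fg, "gene")
  expect_equal(genes$disease_flag, c(TRUE, FALSE))
})

test_that("reports are written as deterministic TSV with a JSON twin", {
  tab <- data.frame(a = c("x", "y"), n = c(1L, 2L))
  f <- withr::local_tempfile(fileext = ".tsv")
  paths <- write_report(tab, f)
  expect_equal(utils::read.delim(f), tab, ignore_attr = TRUE)
  expect_true(file.exists(sub("\\.tsv$", ".json", f)))
  j <- jsonlite::read_json(sub("\\.tsv$", ".json", f), simplifyVector = TRUE)
  expect_equal(as.data.frame(j), tab, ignore_attr = TRUE)
})
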