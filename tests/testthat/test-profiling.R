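test_that("best-hit resolution applies threshold and tie-breaks", {
  hits <- data.frame(
    read_id = c("r1", "r1", "r2", "r3", "r3", "r4", "r4"),
    contig_id = c("c2", "c1", "c9", "cB", "cA", "cZ", "cY"),
    evalue = c(1e-40, 1e-35, 1e-20, 1e-50, 1e-50, 1e-60, 1e-60),
    score = c(100, 90, 80, 70, 60, 55, 55),
    stringsAsFactors = FALSE)
  best <- resolve_best_hits(hits)
  expect_identical(best$contig_id[best$read_id == "r1"], "c2")  # min evalue
  expect_false("r2" %in% best$read_id)                  # e >= 1e-30 dropped
  expect_identical(best$contig_id[best$read_id == "r3"], "cB")  # score tie-break
  expect_identical(best$contig_id[best$read_id == "r4"], "cY")  # lexicographic
  expect_identical(nrow(resolve_best_hits(hits, evalue_max = 1e-100)), 0L)
})

test_that("BLAST tabular parsing validates records and reports line numbers", {
  f <- withr::local_tempfile()
  writeLines(c("r1\tc1\t98.5\t120\t2\t0\t1\t120\t5\t124\t1e-45\t200",
               "r2\tc2\t100\t80\t0\t0\t1\t80\t1\t80\t1e-35\t150"), f)
  h <- read_blast_tab(f)
  expect_identical(h$read_id, c("r1", "r2"))
  expect_equal(h$evalue, c(1e-45, 1e-35))
  expect_equal(h$identity, c(0.985, 1))

  writeLines(c("r1\tc1\t98.5\t120\t2\t0\t1\t120\t5\t124\t1e-45\t200",
               "r2\tc2\tbroken"), f)
  expect_error(read_blast_tab(f), "line 2")
})

test_that("the internal mapper finds exact substrings and rejects noise", {
  set.seed(31)
  ref <- generate_reference(20, c(500, 1500), seed = 31)
  refchar <- as.character(ref)
  starts <- sample(100, 20)
  reads <- Biostrings::DNAStringSet(setNames(
    substr(refchar, starts, starts + 199), paste0("q", 1:20)))
  hits <- map_reads_internal(reads, ref)
  best <- resolve_best_hits(hits)
  expect_identical(nrow(best), 20L)
  expect_identical(best$contig_id[match(paste0("q", 1:20), best$read_id)],
                   names(ref))
  expect_true(all(hits$identity[hits$overlap == 200] == 1))

  # random sequences share no 15-mer with a small reference
  rand <- Biostrings::DNAStringSet(setNames(
    vapply(1:1000, function(i)
      paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = ""),
      character(1)), paste0("n", 1:1000)))
  expect_identical(nrow(map_reads_internal(rand, ref)), 0L)

  # an overlap below the threshold yields no hit
  short <- Biostrings::DNAStringSet(c(s = substr(refchar[1], 1, 49)))
  expect_identical(nrow(map_reads_internal(short, ref)), 0L)

  expect_error(map_reads_internal(reads, Biostrings::DNAStringSet()),
               "empty reference")
})

test_that("count matrix construction counts best hits per library", {
  best <- data.frame(read_id = c("a1", "a2", "a3", "b1"),
                     contig_id = c("C", "C", "C", "D"),
                     evalue = 1e-40, score = 100, stringsAsFactors = FALSE)
  libs <- list(X = c("a1", "a2", "a3"), Y = c("b1", "b2"))
  cm <- build_count_matrix(best, libs, gene_ids = c("C", "D"))
  expect_identical(cm$counts["C", "X"], 3L)
  expect_identical(cm$counts["D", "Y"], 1L)
  expect_identical(unname(cm$library_totals), c(3, 2))
  expect_true(all(colSums(cm$counts) <= cm$library_totals))
  bad <- rbind(best, data.frame(read_id = "zz", contig_id = "C",
                                evalue = 1e-40, score = 1))
  expect_error(build_count_matrix(bad, libs), "no library")
})

test_that("error-free reads round-trip to the exact truth count matrix", {
  sim <- readlevel_sim()
  dm <- demultiplex(sim$pool$reads, DEFAULT_MIDS)
  libs <- lapply(dm$libraries, function(l) dedup(clean_reads(l)))
  allreads <- do.call(c, unname(lapply(libs, function(l) l$reads)))
  best <- resolve_best_hits(map_reads_internal(allreads, sim$ref))
  # >= 99.9% of emitted reads assigned to their true source gene
  truth_gene <- setNames(sim$pool$truth$gene_id, sim$pool$truth$read_id)
  expect_gte(mean(truth_gene[best$read_id] == best$contig_id), 0.999)
  cm <- build_count_matrix(best, libs, gene_ids = rownames(sim$cm$counts))
  expect_identical(cm$counts, sim$cm$counts)
})

test_that("hits written as BLAST tabular reproduce the internal pipeline", {
  sim <- readlevel_sim()
  dm <- demultiplex(sim$pool$reads, DEFAULT_MIDS)
  libs <- lapply(dm$libraries, function(l) dedup(clean_reads(l)))
  allreads <- do.call(c, unname(lapply(libs, function(l) l$reads)))
  hits <- map_reads_internal(allreads[1:500], sim$ref)
  f <- withr::local_tempfile()
  writeLines(sprintf("%s\t%s\t%.3f\t%d\t%d\t0\t1\t%d\t1\t%d\t%.6e\t%.1f",
                     hits$read_id, hits$contig_id, hits$identity * 100,
                     hits$overlap, hits$overlap - hits$score, hits$overlap,
                     hits$overlap, hits$evalue, hits$score), f)
  reparsed <- resolve_best_hits(read_blast_tab(f))
  direct <- resolve_best_hits(hits)
  expect_identical(reparsed$contig_id[match(direct$read_id,
                                            reparsed$read_id)],
                   direct$contig_id)
})

test_that("per-million normalization applies the exact formula", {
  m <- matrix(c(10L, 0L), 2, 1, dimnames = list(c("g1", "g2"), "2CELL"))
  cm <- count_matrix(m, c(`2CELL` = 38923))
  e <- normalize_per_million(cm)
  expect_equal(round(e["g1", 1], 2), 256.92)
  expect_identical(e["g2", 1], 0)
  # homogeneity: scaling counts and totals together changes nothing
  cm2 <- count_matrix(m * 3L, c(`2CELL` = 38923 * 3))
  expect_equal(normalize_per_million(cm2), e)
  m0 <- matrix(c(0L, 0L), 2, 1, dimnames = list(c("g1", "g2"), "2CELL"))
  cm3 <- count_matrix(m0, c(`2CELL` = 0))
  expect_error(normalize_per_million(cm3), "zero library total")
})

test_that("count matrix text round trip preserves counts and totals", {
  sim <- readlevel_sim()
  f <- withr::local_tempfile()
  write_count_matrix(sim$cm, f)
  back <- read_count_matrix(f)
  expect_identical(back$counts, sim$cm$counts)
  expect_equal(unname(back$library_totals), unname(sim$cm$library_totals))
})
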