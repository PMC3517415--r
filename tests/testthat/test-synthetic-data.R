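test_that("reference generation respects bounds, uniqueness and seeding", {
  ref <- generate_reference(10, c(300, 600), seed = 1)
  expect_length(ref, 10)
  expect_true(all(Biostrings::width(ref) >= 300 &
                  Biostrings::width(ref) <= 600))
  expect_false(anyDuplicated(names(ref)) > 0)
  ref2 <- generate_reference(10, c(300, 600), seed = 1)
  expect_identical(as.character(ref), as.character(ref2))
  expect_error(generate_reference(0, c(300, 600)), "positive")
  expect_error(generate_reference(5, c(50, 600)), "length_range")
  expect_error(generate_reference(5, c(600, 300)), "length_range")
})

test_that("expression programs satisfy the archetype fold contracts", {
  sim <- default_sim()
  ab <- sim$prog$abundance
  expect_true(all(abs(colSums(ab) - 1) < 1e-9))
  expect_true(all(ab >= 0))

  arch <- sim$arch
  mat <- ab[names(arch)[arch == "maternal_decay"], , drop = FALSE]
  drop <- mat[, "2CELL"] / mat[, "MORU"]
  expect_true(all(drop >= 40 - 1e-6 & drop <= 80 + 1e-6))

  spk <- ab[names(arch)[arch == "trochophore_spike"], EARLY_STAGES]
  spike_fold <- spk[, "TROC"] / apply(spk[, colnames(spk) != "TROC"], 1, max)
  expect_true(all(spike_fold >= 30 - 1e-6))

  ris <- ab[names(arch)[arch == "postlarval_rise"], EARLY_STAGES]
  rise_fold <- ris[, "144PL"] /
    apply(ris[, colnames(ris) != "144PL"], 1, max)
  expect_true(all(rise_fold >= 25 - 1e-6))

  hk <- ab[names(arch)[arch == "housekeeping"], EARLY_STAGES]
  expect_true(all(apply(hk, 1, max) / apply(hk, 1, min) <= 1.5))
})

test_that("a fixed maternal fold is reproduced exactly in true abundance", {
  cfg <- sim_config(n_genes = 100,
                    archetype_proportions = c(maternal_decay = 0.1,
                                              background = 0.9),
                    fold_params = list(maternal_fold = c(78, 78)),
                    seed = 4)
  prog <- build_program(cfg)
  mat <- prog$abundance[prog$genes$archetype == "maternal_decay", ]
  expect_equal(unname(mat[, "2CELL"] / mat[, "MORU"]),
               rep(78, nrow(mat)), tolerance = 1e-9)
})

test_that("a housekeeping-only program is flat within factor 1.5", {
  cfg <- sim_config(n_genes = 100,
                    archetype_proportions = c(housekeeping = 1), seed = 5)
  prog <- build_program(cfg)
  hk <- prog$abundance[, EARLY_STAGES]
  expect_true(all(apply(hk, 1, max) / apply(hk, 1, min) <= 1.5))
})

test_that("multinomial sampling conserves depths and matches expectation", {
  sim <- default_sim()
  expect_identical(as.integer(colSums(sim$cm$counts)),
                   as.integer(DEFAULT_LIBRARY_DEPTHS))

  # zero-abundance gene never sampled
  prog <- build_program(sim_config(n_genes = 20, seed = 6))
  prog$abundance[1, ] <- 0
  prog$abundance <- sweep(prog$abundance, 2, colSums(prog$abundance), "/")
  cm0 <- sample_counts(prog, c(`2CELL` = 5000), seed = 6)
  expect_identical(unname(cm0$counts[1, ]), 0L)

  # Monte-Carlo: mean normalized count tracks 1e6 x abundance
  prog2 <- build_program(sim_config(n_genes = 50, seed = 11))
  g <- "gene0030"
  x <- vapply(1:200, function(s)
    sample_counts(prog2, c(`2CELL` = 5000), seed = s)$counts[g, 1] /
      5000 * 1e6, numeric(1))
  expected <- prog2$abundance[g, "2CELL"] * 1e6
  se <- stats::sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - expected), 3 * se)
})

test_that("emitted reads are decorated source substrings with bookkeeping", {
  sim <- readlevel_sim()
  pool <- sim$pool
  expect_identical(length(pool$reads), nrow(pool$truth))
  expect_identical(sum(!pool$truth$duplicate), sum(sim$cm$counts))

  # error-free reads: MID + adaptor prefix, then an exact source substring
  idx <- sample(length(pool$reads), 50)
  ref <- as.character(sim$ref)
  for (i in idx) {
    s <- as.character(pool$reads[[i]])
    lib <- pool$truth$library[i]
    expect_true(startsWith(s, paste0(DEFAULT_MIDS[[lib]], DEFAULT_ADAPTOR)))
    frag <- substr(s, nchar(DEFAULT_MIDS[[lib]]) + nchar(DEFAULT_ADAPTOR) + 1,
                   nchar(s))
    expect_true(grepl(frag, ref[[pool$truth$gene_id[i]]], fixed = TRUE))
  }

  expect_error(emit_reads(sim$cm, sim$ref,
                          mids = setNames(rep("ACGT", 8),
                                          names(DEFAULT_MIDS))),
               "MID collision")
})

test_that("duplicate fraction matches the configured rate", {
  sim <- readlevel_sim()
  prog <- sim$prog
  cm <- sample_counts(prog, c(`2CELL` = 10000), seed = 7)
  ref2 <- generate_reference(80, c(800, 2000), seed = 2)
  pool <- emit_reads(cm, ref2, mids = DEFAULT_MIDS["2CELL"],
                     error_rate = 0, dup_rate = 0.2, seed = 8)
  expect_lt(abs(mean(pool$truth$duplicate) - 0.2), 0.02)
})

test_that("qPCR simulation is proportional to truth when noiseless", {
  sim <- default_sim()
  genes <- names(sim$arch)[sim$arch == "trochophore_spike"][1:3]
  qp <- simulate_qpcr(sim$prog, genes, noise_sd = 0, seed = 1)
  for (g in genes) {
    lvl <- qp$level[qp$gene_id == g]
    truth <- sim$prog$abundance[g, EARLY_STAGES]
    expect_equal(lvl, unname(truth / min(truth)), tolerance = 1e-12)
    expect_equal(min(lvl), 1)
  }
  # perfectly flat housekeeping series stays constant
  cfg <- sim_config(n_genes = 20,
                    archetype_proportions = c(housekeeping = 1),
                    fold_params = list(hk_max_fold = 1), seed = 3)
  progf <- build_program(cfg)
  qpf <- simulate_qpcr(progf, "gene0001", noise_sd = 0, seed = 1)
  expect_equal(qpf$level, rep(1, 7), tolerance = 1e-9)
  expect_error(simulate_qpcr(sim$prog, "nope", seed = 1), "unknown gene")
})

test_that("the generator is bit-reproducible end to end for a fixed seed", {
  run <- function() {
    cfg <- sim_config(n_genes = 40, seed = 9)
    prog <- build_program(cfg)
    ref <- generate_reference(40, c(800, 1500), seed = 9)
    cm <- sample_counts(prog, round(DEFAULT_LIBRARY_DEPTHS / 500), seed = 10)
    pool <- emit_reads(cm, ref, seed = 11)
    list(ab = prog$abundance, counts = cm$counts,
         reads = as.character(pool$reads), truth = pool$truth)
  }
  expect_identical(run(), run())
})
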