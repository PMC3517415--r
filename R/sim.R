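# Synthetic-data generator: reference transcripts, stage-wise expression
# programs built from developmental archetypes, multinomial count sampling,
# decorated read emission and qPCR panels — all seeded and with ground truth.

ARCHETYPES <- c("maternal_decay", "trochophore_spike", "postlarval_rise",
                "housekeeping", "background")

#' Simulation configuration
#'
#' Bundles and validates all parameters of the synthetic-data generator. The
#' defaults emulate the study design the package targets: eight barcoded
#' libraries (seven early developmental stages plus adult intestine) at the
#' non-redundant depths of [DEFAULT_LIBRARY_DEPTHS], genes drawn from five
#' expression archetypes, and read decoration with MID barcodes, a shared
#' adaptor, substitution errors and exact duplicate copies.
#'
#' @param n_genes number of reference genes to simulate.
#' @param archetype_proportions named fractions over the five archetypes
#'   (`maternal_decay`, `trochophore_spike`, `postlarval_rise`,
#'   `housekeeping`, `background`); must sum to 1.
#' @param library_depths named vector of reads per library (the multinomial
#'   sizes); defaults to [DEFAULT_LIBRARY_DEPTHS].
#' @param fold_params list of per-archetype fold magnitudes:
#'   `maternal_fold` (range of the two-cell to morula drop),
#'   `maternal_decay_rate` (range of the per-stage continued decay factor),
#'   `spike_fold` (range of the trochophore spike over the max of the other
#'   stages), `rise_fold` (range of the postlarval rise over the max of all
#'   earlier stages), `pre_rise_fold` (range of the anticipatory elevation of
#'   postlarval-rise genes at the late competent veliger stage, used when
#'   `benthic_shift` is on), `hk_max_fold` (cap on max/min across the seven
#'   early stages for housekeeping genes), `bg_noise_sd` (lognormal sd of
#'   background stage fluctuation), `stage_noise_sd` (lognormal sd of the
#'   residual stage fluctuation of non-background archetypes).
#' @param error_rate per-base substitution probability during read emission.
#' @param dup_rate expected duplicate fraction of the emitted read pool
#'   (extra exact copies per read follow a Geometric(1 - dup_rate) law).
#' @param benthic_shift logical; if `TRUE` (default) the late competent
#'   veliger and postlarva libraries share expression programs, emulating
#'   anticipatory development (the pelagic-benthic transcriptome shift
#'   starting before settlement): postlarval-rise genes are already mildly
#'   elevated in late competent veligers (`pre_rise_fold`), and a fraction
#'   `benthic_frac` of background genes carries one shared lognormal
#'   elevation (`benthic_fold`) at both stages.
#' @param benthic_frac fraction of background genes in the shared benthic
#'   program (used when `benthic_shift` is on).
#' @param benthic_fold fold range of the shared benthic elevation.
#' @param mids named MID barcodes per library.
#' @param adaptor library adaptor sequence inserted between MID and insert.
#' @param seed integer seed used by generator calls that accept a config.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 600,
                       archetype_proportions = c(maternal_decay = 0.10,
                                                 trochophore_spike = 0.10,
                                                 postlarval_rise = 0.10,
                                                 housekeeping = 0.20,
                                                 background = 0.50),
                       library_depths = DEFAULT_LIBRARY_DEPTHS,
                       fold_params = list(),
                       error_rate = 0.005,
                       dup_rate = 0.10,
                       benthic_shift = TRUE,
                       benthic_frac = 0.3,
                       benthic_fold = c(3, 6),
                       mids = DEFAULT_MIDS,
                       adaptor = DEFAULT_ADAPTOR,
                       seed = 1L) {
  fp <- list(maternal_fold = c(40, 80),
             maternal_decay_rate = c(1.5, 4),
             spike_fold = c(30, 120),
             rise_fold = c(25, 100),
             pre_rise_fold = c(2, 6),
             hk_max_fold = 1.5,
             bg_noise_sd = 0.5,
             stage_noise_sd = 0.15)
  unknown <- setdiff(names(fold_params), names(fp))
  if (length(unknown))
    stop_param("unknown fold_params: ", paste(unknown, collapse = ", "))
  fp[names(fold_params)] <- fold_params

  if (!is_count(n_genes) || n_genes < 1)
    stop_param("n_genes must be a positive integer")
  if (is.null(names(archetype_proportions)) ||
      !all(names(archetype_proportions) %in% ARCHETYPES))
    stop_param("archetype_proportions must be named by archetype")
  if (any(archetype_proportions < 0) ||
      abs(sum(archetype_proportions) - 1) > 1e-8)
    stop_param("archetype_proportions must be non-negative and sum to 1")
  if (is.null(names(library_depths)) || any(library_depths <= 0))
    stop_param("library_depths must be named and positive")
  if (error_rate < 0 || error_rate >= 1 || dup_rate < 0 || dup_rate >= 1)
    stop_param("error_rate and dup_rate must lie in [0, 1)")
  if (anyDuplicated(mids))
    stop_param("MID barcodes must be distinct")

  props <- setNames(rep(0, length(ARCHETYPES)), ARCHETYPES)
  props[names(archetype_proportions)] <- archetype_proportions

  structure(list(n_genes = as.integer(n_genes),
                 archetype_proportions = props,
                 library_depths = library_depths,
                 fold_params = fp,
                 error_rate = error_rate,
                 dup_rate = dup_rate,
                 benthic_shift = isTRUE(benthic_shift),
                 benthic_frac = benthic_frac,
                 benthic_fold = benthic_fold,
                 mids = mids,
                 adaptor = adaptor,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic reference transcript set
#'
#' Random-composition transcripts with unique identifiers and lengths drawn
#' uniformly in `length_range`. Deterministic for a fixed seed.
#'
#' @param n_genes number of transcripts (>= 1).
#' @param length_range two-element numeric range within [100, 4000] nt.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return A [Biostrings::DNAStringSet] named `gene0001`, `gene0002`, ...
#' @export
generate_reference <- function(n_genes, length_range = c(300, 2000),
                               seed = NULL) {
  if (!is_count(n_genes) || n_genes < 1)
    stop_param("n_genes must be a positive integer")
  if (length(length_range) != 2L || any(!is.finite(length_range)) ||
      length_range[1] > length_range[2] ||
      length_range[1] < 100 || length_range[2] > 4000)
    stop_param("length_range must be an increasing pair within [100, 4000]")
  if (!is.null(seed)) set.seed(seed)
  lens <- floor(runif(n_genes, length_range[1], length_range[2] + 1))
  seqs <- vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  names(seqs) <- sprintf("gene%04d", seq_len(n_genes))
  Biostrings::DNAStringSet(seqs)
}

# Stage multiplier profile for one gene of a given archetype, over the
# labels in `stages` (seven early stages followed by the adult library).
# Profiles are later rescaled to peak 1, so cross-stage ratios — the
# archetype contracts — are exact; absolute gene mass comes from a separate
# lognormal baseline.
.archetype_profile <- function(archetype, fp, benthic_shift, n_early = 7L,
                               n_libs = 8L) {
  noise <- function(n, sd) exp(rnorm(n, 0, sd))
  m <- numeric(n_libs)
  if (archetype == "maternal_decay") {
    f <- runif(1, fp$maternal_fold[1], fp$maternal_fold[2])
    m[1] <- 1
    m[2] <- 1 / f
    decay <- runif(n_early - 2, fp$maternal_decay_rate[1],
                   fp$maternal_decay_rate[2])
    m[3:n_early] <- m[2] / cumprod(decay)
    m[n_libs] <- m[n_early] * noise(1, fp$stage_noise_sd)
  } else if (archetype == "trochophore_spike") {
    others <- noise(n_early - 1, fp$stage_noise_sd)
    s <- runif(1, fp$spike_fold[1], fp$spike_fold[2])
    m[setdiff(seq_len(n_early), 3L)] <- others
    m[3L] <- s * max(others)
    m[n_libs] <- noise(1, fp$stage_noise_sd)
  } else if (archetype == "postlarval_rise") {
    m[1:5] <- noise(5, fp$stage_noise_sd)
    pre <- if (benthic_shift)
      runif(1, fp$pre_rise_fold[1], fp$pre_rise_fold[2]) else 1
    m[6] <- pre * max(m[1:5])
    s <- runif(1, fp$rise_fold[1], fp$rise_fold[2])
    m[7] <- s * max(m[1:6])
    m[n_libs] <- noise(1, fp$stage_noise_sd)
  } else if (archetype == "housekeeping") {
    # slightly conservative band so the max/min contract holds with margin
    half <- 0.9 * log(fp$hk_max_fold) / 2
    m[seq_len(n_early)] <- exp(runif(n_early, -half, half))
    m[n_libs] <- exp(runif(1, -half, half))
  } else { # background
    m[] <- noise(n_libs, fp$bg_noise_sd)
  }
  m
}

#' Build stage-wise expression programs from archetypes
#'
#' Draws each gene from one of five expression archetypes — maternal decay
#' (highest at the two-cell stage, sharply depleted by the morula stage and
#' further after), trochophore spike, postlarval rise, flat housekeeping, and
#' low background — and assembles the true relative transcript fraction of
#' every gene in every library. Each library column sums to 1, and every
#' archetype's cross-stage fold contract holds exactly on the normalized
#' fractions: archetype profiles are scaled to peak 1 and carry a lognormal
#' baseline mass, and the background genes absorb the per-library mass slack
#' (they share each library's remainder in proportion to noisy weights), so
#' library totals are equalized without touching any non-background gene's
#' stage ratios. Without background genes the columns are normalized
#' directly, which perturbs ratios by O(1/sqrt(n_genes)).
#'
#' @param config a [sim_config()] object.
#' @return An object of class `expression_program`: a list with `genes`
#'   (data.frame of `gene_id`, `archetype`) and `abundance` (genes x
#'   libraries matrix of relative fractions, columns summing to 1).
#' @export
build_program <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  labels <- names(config$library_depths)
  n_early <- min(7L, length(labels))

  n_per <- floor(config$archetype_proportions * n)
  rem <- n - sum(n_per)
  if (rem > 0) { # assign remainder to the largest proportion
    i <- which.max(config$archetype_proportions)
    n_per[i] <- n_per[i] + rem
  }
  archetype <- rep(names(n_per), n_per)

  base <- exp(rnorm(n, 0, 1.2))
  profiles <- t(vapply(archetype, .archetype_profile, numeric(length(labels)),
                       fp = config$fold_params,
                       benthic_shift = config$benthic_shift,
                       n_early = n_early, n_libs = length(labels)))
  bg <- archetype == "background"

  if (config$benthic_shift && any(bg) && length(labels) >= 7) {
    # shared benthic program: one elevation applied identically at the
    # late-competent-veliger and postlarva stages
    sel <- which(bg)[runif(sum(bg)) < config$benthic_frac]
    z <- runif(length(sel), config$benthic_fold[1], config$benthic_fold[2])
    profiles[sel, 6:7] <- profiles[sel, 6:7] * z
  }

  if (any(bg) && any(!bg)) {
    # scale non-background profiles to peak 1 over the early stages; the
    # background genes share each library's mass remainder, equalizing
    # library totals so normalization is a single global constant
    peak <- apply(profiles[!bg, seq_len(n_early), drop = FALSE], 1, max)
    raw <- matrix(0, n, length(labels))
    raw[!bg, ] <- base[!bg] * profiles[!bg, , drop = FALSE] / peak
    bg_share <- 0.25
    C <- max(colSums(raw)) / (1 - bg_share)
    remainder <- C - colSums(raw)
    w <- base[bg] * profiles[bg, , drop = FALSE]
    raw[bg, ] <- sweep(w, 2, colSums(w), "/") *
      rep(remainder, each = sum(bg))
    abundance <- raw / C
  } else {
    abundance <- base * profiles
    abundance <- sweep(abundance, 2, colSums(abundance), "/")
  }
  dimnames(abundance) <- list(sprintf("gene%04d", seq_len(n)), labels)

  structure(list(genes = data.frame(gene_id = rownames(abundance),
                                    archetype = archetype,
                                    stringsAsFactors = FALSE),
                 abundance = abundance),
            class = "expression_program")
}

#' Sample read counts from expression programs
#'
#' Draws each library column as one multinomial of size equal to the library
#' depth over the true gene abundances, so column sums equal the configured
#' depths exactly.
#'
#' @param program an `expression_program` from [build_program()].
#' @param library_depths named positive depths, one per program library.
#' @param seed integer seed, or `NULL`.
#' @return A [count_matrix()] whose `library_totals` are the depths.
#' @export
sample_counts <- function(program, library_depths = DEFAULT_LIBRARY_DEPTHS,
                          seed = NULL) {
  stopifnot(inherits(program, "expression_program"))
  if (any(library_depths <= 0)) stop_param("library depths must be positive")
  labels <- colnames(program$abundance)
  if (!all(names(library_depths) %in% labels))
    stop_param("library_depths names must match program libraries")
  if (!is.null(seed)) set.seed(seed)
  counts <- vapply(names(library_depths), function(l)
    rmultinom(1, size = library_depths[[l]],
              prob = program$abundance[, l])[, 1],
    numeric(nrow(program$abundance)))
  storage.mode(counts) <- "integer"
  rownames(counts) <- rownames(program$abundance)
  count_matrix(counts, library_totals = library_depths)
}

.mutate_reads <- function(frags, error_rate) {
  if (error_rate <= 0) return(frags)
  lens <- nchar(frags)
  n_err <- rbinom(length(frags), lens, error_rate)
  hit <- which(n_err > 0)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    pos <- sample.int(lens[i], n_err[i])
    for (p in pos) {
      cur <- substr(frags[i], p, p)
      substr(frags[i], p, p) <- sample(setdiff(bases, cur), 1)
    }
  }
  frags
}

#' Emit a decorated, pooled synthetic read set
#'
#' Converts a count matrix into reads: each counted read is a random
#' subsequence of its source transcript, decorated with the library MID plus
#' the adaptor at the 5' end, with per-base substitution errors at
#' `error_rate`. Exact duplicate copies are appended (extra copies per read
#' are Geometric(1 - `dup_rate`), so the expected duplicate fraction of the
#' pool is `dup_rate`), and the pool is shuffled. A truth table records the
#' library, source gene and duplicate status of every read.
#'
#' @param counts a [count_matrix()] (libraries as columns).
#' @param reference [Biostrings::DNAStringSet] of source transcripts covering
#'   all count rows.
#' @param mids named MID per library (distinct).
#' @param adaptor adaptor sequence between MID and insert.
#' @param error_rate per-base substitution probability.
#' @param dup_rate expected duplicate fraction, in [0, 1).
#' @param read_length_range read insert lengths, drawn uniformly (capped at
#'   transcript length).
#' @param seed integer seed, or `NULL`.
#' @return A list with `reads` (named [Biostrings::DNAStringSet]) and `truth`
#'   (data.frame `read_id`, `library`, `gene_id`, `duplicate`).
#' @export
emit_reads <- function(counts, reference, mids = DEFAULT_MIDS,
                       adaptor = DEFAULT_ADAPTOR, error_rate = 0.005,
                       dup_rate = 0.10, read_length_range = c(50, 600),
                       seed = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  if (anyDuplicated(mids)) stop_param("MID collision: barcodes must differ")
  labels <- colnames(counts$counts)
  if (!all(labels %in% names(mids)))
    stop_param("every library needs a MID")
  if (!all(rownames(counts$counts) %in% names(reference)))
    stop_param("reference is missing count matrix genes")
  if (dup_rate < 0 || dup_rate >= 1) stop_param("dup_rate must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)

  refchar <- as.character(reference)
  out_seq <- character(0)
  out_lib <- character(0)
  out_gene <- character(0)
  out_dup <- logical(0)

  for (l in labels) {
    cnt <- counts$counts[, l]
    gene <- rep(rownames(counts$counts), cnt)
    if (!length(gene)) next
    tlen <- nchar(refchar[gene])
    rlen <- pmin(floor(runif(length(gene), read_length_range[1],
                             read_length_range[2] + 1)), tlen)
    start <- floor(runif(length(gene), 1, tlen - rlen + 1 + 1))
    frag <- substr(refchar[gene], start, start + rlen - 1)
    frag <- .mutate_reads(frag, error_rate)
    full <- paste0(mids[[l]], adaptor, frag)
    extra <- if (dup_rate > 0) rgeom(length(full), 1 - dup_rate) else
      integer(length(full))
    idx <- rep(seq_along(full), 1L + extra)
    out_seq <- c(out_seq, full[idx])
    out_lib <- c(out_lib, rep(l, length(idx)))
    out_gene <- c(out_gene, gene[idx])
    out_dup <- c(out_dup, duplicated(idx))
  }

  ord <- sample.int(length(out_seq))
  ids <- sprintf("read%07d", seq_along(ord))
  reads <- Biostrings::DNAStringSet(setNames(out_seq[ord], ids))
  truth <- data.frame(read_id = ids, library = out_lib[ord],
                      gene_id = out_gene[ord], duplicate = out_dup[ord],
                      stringsAsFactors = FALSE)
  list(reads = reads, truth = truth)
}

#' Simulate a qPCR relative-expression panel
#'
#' Produces per-stage relative expression series for the requested genes:
#' the true per-stage abundance is perturbed by multiplicative lognormal
#' noise of the stated sd, then rescaled so each gene's lowest stage equals
#' 1 (the plotting convention for qPCR fold-changes). Housekeeping genes
#' passed here serve as flat internal-control series.
#'
#' @param program an `expression_program`.
#' @param gene_ids genes to assay (must exist in the program).
#' @param noise_sd lognormal sd of the measurement noise (0 = noiseless).
#' @param stages stage labels to assay (default the seven early stages).
#' @param seed integer seed, or `NULL`.
#' @return A data.frame with columns `gene_id`, `stage`, `level`; per gene
#'   the minimum level is exactly 1.
#' @export
simulate_qpcr <- function(program, gene_ids, noise_sd = 0.1,
                          stages = EARLY_STAGES, seed = NULL) {
  stopifnot(inherits(program, "expression_program"))
  missing <- setdiff(gene_ids, rownames(program$abundance))
  if (length(missing))
    stop_param("unknown gene(s): ", paste(missing, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  res <- lapply(gene_ids, function(g) {
    a <- program$abundance[g, stages]
    lvl <- a * exp(rnorm(length(a), 0, noise_sd))
    data.frame(gene_id = g, stage = stages, level = lvl / min(lvl),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, res)
}
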