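#' Simulation configuration for synthetic reporter libraries
#'
#' Bundles every knob of the synthetic-data generator: library design
#' (number of ref/mt pairs, fragment length, base composition), the decay
#' model relating sequence features to the per-oligo decay rate, the
#' sequencing design (timepoints, replicates, depth), and the SLAM-seq style
#' conversion-table design.
#'
#' The per-oligo decay rate is log-linear in sequence composition:
#' \deqn{\log \lambda = a_0 + a_{ua}\,\mathrm{UA} + a_{gc}\,\mathrm{GC} +
#'   a_{int}\,\mathrm{UA}\cdot\mathrm{GC} + a_{motif}\,m + \epsilon,\qquad
#'   \epsilon \sim N(0, \sigma^2)}
#' where UA is the overlapping UA-dinucleotide ratio, GC the G+C fraction and
#' \eqn{m} the number of occurrences of the planted 7-mer. With
#' `pair_noise = TRUE` (default) the noise draw is shared by the two alleles
#' of a pair, so pairs are exact nulls when all effect coefficients are zero.
#'
#' `spike_in_fraction` reserves a fraction of the sequenced reads for a
#' non-decaying spike-in species (an extra row named `"spike_in"` in the
#' count tensor). Because each (timepoint, replicate) library is sequenced to
#' a fixed total depth, read counts are compositional and the absolute decay
#' scale is only identifiable relative to a stable anchor; the spike-in plays
#' the role that 18S rRNA or ERCC spike-ins play in bench decay assays.
#'
#' @param n_pairs number of ref/mt pairs (>= 1).
#' @param seq_length fragment length in nt; a single value or a `c(min, max)`
#'   range sampled uniformly per pair. Must be >= 10.
#' @param timepoints harvest times in minutes, strictly increasing; the first
#'   is the baseline used as t = 0 by the analysis.
#' @param n_replicates replicates per timepoint.
#' @param depth sequencing reads per (timepoint, replicate) library.
#' @param base_probs sampling probabilities for A, C, G, U, used when
#'   `vary_composition = FALSE`.
#' @param vary_composition draw per-pair compositional targets (GC
#'   fraction, A/U balance, UA-dinucleotide ratio) instead of sampling all
#'   fragments from one fixed probability vector. Real UTR libraries span a
#'   wide compositional range, and crucially their UA-dinucleotide content
#'   varies through base *ordering* (UA alternation), not only through
#'   mononucleotide composition; without that, the UA ratio is a mere
#'   mirror of GC content and the rate model's two axes are confounded.
#'   Targets are hit with a first-order Markov chain whose U-to-A
#'   transition is boosted (or damped) to reach the drawn UA target.
#' @param gc_range per-pair G+C fraction range.
#' @param au_balance_range per-pair range of the A share of the A+U mass.
#' @param ua_target_range per-pair range of the target UA-dinucleotide
#'   ratio (clamped to what the pair's composition can reach).
#' @param a0,a_ua,a_gc,a_int,a_motif coefficients of the log-rate model.
#' @param noise_sd standard deviation of the log-rate noise.
#' @param pair_noise logical; share the noise draw within a pair.
#' @param planted_motif optional 7-mer (RNA alphabet) inserted into a random
#'   position of a fraction of pairs.
#' @param motif_fraction fraction of pairs receiving the planted motif.
#' @param mutation `"substitution"` (single-nt substitution, default) or
#'   `"indel"` (insertion or deletion of 1-2 nt).
#' @param abundance_sdlog log-normal spread of per-oligo initial abundance.
#' @param spike_in_fraction baseline read fraction taken by the stable
#'   spike-in species; 0 disables it.
#' @param conv_timepoints_hr,conv_batches,conv_coverage,conv_rate0 design of
#'   simulated T-to-C conversion tables: chase timepoints in hours, batches
#'   per timepoint, T coverage per transcript, and the baseline conversion
#'   rate (must lie in (0, 0.8); larger rates would be removed by the SNP
#'   filter downstream).
#' @param seed integer seed; every generator op derives a fixed sub-seed from
#'   it so stages can be re-run independently and reproducibly.
#'
#' @return A validated list of class `"sim_config"`.
#' @export
#' @examples
#' cfg <- sim_config(n_pairs = 5, seed = 1)
#' lib <- generate_library(cfg)
#' counts <- simulate_counts(lib$truth, cfg)
sim_config <- function(n_pairs = 100,
                       seq_length = c(75L, 155L),
                       timepoints = c(30, 75, 120),
                       n_replicates = 3L,
                       depth = 1e6,
                       base_probs = c(A = 0.3, C = 0.2, G = 0.2, U = 0.3),
                       vary_composition = TRUE,
                       gc_range = c(0.25, 0.65),
                       au_balance_range = c(0.35, 0.65),
                       ua_target_range = c(0.02, 0.12),
                       a0 = -4.1, a_ua = 3, a_gc = -1.5, a_int = 2,
                       a_motif = 0.35, noise_sd = 0.3,
                       pair_noise = TRUE,
                       planted_motif = NULL, motif_fraction = 0.3,
                       mutation = c("substitution", "indel"),
                       abundance_sdlog = 0.25,
                       spike_in_fraction = 0.2,
                       conv_timepoints_hr = c(0, 2, 4, 8),
                       conv_batches = 3L, conv_coverage = 5000,
                       conv_rate0 = 0.1,
                       seed = 1L) {
  mutation <- match.arg(mutation)
  stopifnot(n_pairs >= 1, length(timepoints) >= 2, depth >= 1,
            n_replicates >= 1, noise_sd >= 0,
            motif_fraction >= 0, motif_fraction <= 1,
            spike_in_fraction >= 0, spike_in_fraction < 1,
            abundance_sdlog >= 0)
  if (any(seq_length < 10)) {
    stop("seq_length must be >= 10 nt (shorter sequences are excluded from UA profiling)")
  }
  if (length(seq_length) == 1) seq_length <- rep(seq_length, 2)
  if (any(diff(timepoints) <= 0)) stop("timepoints must be strictly increasing")
  if (any(timepoints < 0)) stop("timepoints must be non-negative")
  if (conv_rate0 <= 0 || conv_rate0 >= 0.8) {
    stop("conv_rate0 must lie in (0, 0.8): larger baseline rates trip the SNP filter")
  }
  if (!is.null(planted_motif)) {
    planted_motif <- norm_rna(planted_motif, allow_n = FALSE)
    if (nchar(planted_motif) != 7) stop("planted_motif must be a 7-mer")
  }
  if (length(base_probs) != 4 || any(base_probs < 0)) {
    stop("base_probs must be 4 non-negative values for A, C, G, U")
  }
  base_probs <- base_probs / sum(base_probs)
  stopifnot(length(gc_range) == 2, all(gc_range > 0), all(gc_range < 1),
            length(au_balance_range) == 2, all(au_balance_range > 0),
            all(au_balance_range < 1),
            length(ua_target_range) == 2, all(ua_target_range > 0),
            all(ua_target_range < 1))
  cfg <- list(n_pairs = as.integer(n_pairs), seq_length = as.integer(seq_length),
              timepoints = as.numeric(timepoints),
              n_replicates = as.integer(n_replicates), depth = depth,
              base_probs = base_probs,
              vary_composition = isTRUE(vary_composition),
              gc_range = as.numeric(gc_range),
              au_balance_range = as.numeric(au_balance_range),
              ua_target_range = as.numeric(ua_target_range),
              a0 = a0, a_ua = a_ua, a_gc = a_gc,
              a_int = a_int, a_motif = a_motif, noise_sd = noise_sd,
              pair_noise = isTRUE(pair_noise),
              planted_motif = planted_motif, motif_fraction = motif_fraction,
              mutation = mutation, abundance_sdlog = abundance_sdlog,
              spike_in_fraction = spike_in_fraction,
              conv_timepoints_hr = as.numeric(conv_timepoints_hr),
              conv_batches = as.integer(conv_batches),
              conv_coverage = conv_coverage, conv_rate0 = conv_rate0,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Construct a ground-truth table
#'
#' Validates the invariants of a truth table: positive decay rates, ratio
#' features in \[0, 1\] and unique oligo ids. Useful for building simulation
#' inputs directly when only decay rates matter (e.g. estimator-recovery
#' experiments).
#'
#' @param oligo_id character ids, unique.
#' @param true_lambda decay rate per time unit, > 0.
#' @param ua_ratio,gc_fraction composition features in \[0, 1\] (optional).
#' @param planted_motifs comma-separated 7-mers planted in each oligo.
#' @param initial_abundance relative starting mass, > 0.
#' @return A `data.frame` of class `"truth_table"`.
#' @export
truth_table <- function(oligo_id, true_lambda, ua_ratio = NA_real_,
                        gc_fraction = NA_real_, planted_motifs = "",
                        initial_abundance = 1) {
  oligo_id <- as.character(oligo_id)
  if (anyDuplicated(oligo_id)) stop("oligo_id values must be unique")
  if (any(!is.finite(true_lambda)) || any(true_lambda <= 0)) {
    stop("true_lambda must be finite and > 0")
  }
  chk01 <- function(x, nm) {
    if (any(!is.na(x) & (x < 0 | x > 1))) stop(nm, " must lie in [0, 1]")
  }
  chk01(ua_ratio, "ua_ratio"); chk01(gc_fraction, "gc_fraction")
  if (any(initial_abundance <= 0)) stop("initial_abundance must be > 0")
  out <- data.frame(oligo_id = oligo_id, true_lambda = true_lambda,
                    ua_ratio = ua_ratio, gc_fraction = gc_fraction,
                    planted_motifs = planted_motifs,
                    initial_abundance = initial_abundance,
                    stringsAsFactors = FALSE)
  class(out) <- c("truth_table", "data.frame")
  out
}

## Internal: sample one random RNA sequence.
random_seq <- function(len, base_probs) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE, prob = base_probs),
        collapse = "")
}

## Internal: first-order Markov sequence hitting a target UA-dimer ratio.
## The U-to-A transition probability is boosted so the expected dimer
## frequency p_U * P(A|U) matches the target (clamped to 95% of what the
## composition allows).
markov_seq <- function(len, gc, a_share, target_ua) {
  p <- c(A = (1 - gc) * a_share, C = gc / 2, G = gc / 2,
         U = (1 - gc) * (1 - a_share))
  r <- min(target_ua / p[["U"]], 0.95)
  boost <- (1 - p[["A"]]) / p[["A"]] * r / (1 - r)
  p_after_u <- p
  p_after_u[["A"]] <- p_after_u[["A"]] * boost
  p_after_u <- p_after_u / sum(p_after_u)
  bases <- c("A", "C", "G", "U")
  s <- character(len)
  s[1] <- sample(bases, 1, prob = p)
  for (i in 2:len) {
    s[i] <- sample(bases, 1, prob = if (s[i - 1] == "U") p_after_u else p)
  }
  paste(s, collapse = "")
}

## Internal: composition features used by the generator's rate model.
seq_features <- function(seqs) {
  set <- Biostrings::RNAStringSet(seqs)
  len <- Biostrings::width(set)
  ua <- Biostrings::vcountPattern("UA", set) / pmax(len - 1L, 1L)
  gc <- as.numeric(Biostrings::letterFrequency(set, "CG")) / len
  data.frame(ua_ratio = ua, gc_fraction = gc)
}

#' Generate a paired ref/mt oligo library with ground truth
#'
#' Draws `n_pairs` reference fragments from the configured base composition,
#' optionally plants a 7-mer into a fraction of them, derives each mutant
#' allele by a single edit (substitution, or a 1-2 nt indel when
#' `mutation = "indel"`), and assigns every oligo a true decay rate from the
#' log-linear composition model described in [sim_config()].
#'
#' @param config a [sim_config()] object.
#' @return A list with `oligos` (data.frame: `oligo_id`, `pair_id`, `allele`,
#'   `side`, `sequence`) and `truth` (a [truth_table()]).
#' @export
generate_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sub_seed(config$seed, 0L))
  n <- config$n_pairs
  lens <- if (config$seq_length[1] == config$seq_length[2]) {
    rep(config$seq_length[1], n)
  } else {
    sample(seq(config$seq_length[1], config$seq_length[2]), n, replace = TRUE)
  }
  if (config$vary_composition) {
    gc_t <- runif(n, config$gc_range[1], config$gc_range[2])
    a_share <- runif(n, config$au_balance_range[1], config$au_balance_range[2])
    ua_t <- runif(n, config$ua_target_range[1], config$ua_target_range[2])
    ref <- vapply(seq_len(n), function(i) {
      markov_seq(lens[i], gc_t[i], a_share[i], ua_t[i])
    }, "")
  } else {
    ref <- vapply(lens, random_seq, "", base_probs = config$base_probs)
  }

  if (!is.null(config$planted_motif)) {
    gets <- runif(n) < config$motif_fraction
    for (i in which(gets)) {
      pos <- sample.int(lens[i] - 6L, 1L)
      substr(ref[i], pos, pos + 6L) <- config$planted_motif
    }
  }

  bases <- c("A", "C", "G", "U")
  mt <- character(n)
  for (i in seq_len(n)) {
    s <- ref[i]
    if (config$mutation == "substitution") {
      pos <- sample.int(nchar(s), 1L)
      old <- substr(s, pos, pos)
      new <- sample(setdiff(bases, old), 1L)
      substr(s, pos, pos) <- new
    } else {
      k <- sample(1:2, 1L)
      if (runif(1) < 0.5 && nchar(s) - k >= 10) {          # deletion
        pos <- sample.int(nchar(s) - k + 1L, 1L)
        s <- paste0(substr(s, 1L, pos - 1L), substr(s, pos + k, nchar(s)))
      } else {                                             # insertion
        pos <- sample.int(nchar(s) + 1L, 1L)
        ins <- paste(sample(bases, k, replace = TRUE,
                            prob = config$base_probs), collapse = "")
        s <- paste0(substr(s, 1L, pos - 1L), ins, substr(s, pos, nchar(s)))
      }
    }
    mt[i] <- s
  }

  pair_id <- sprintf("pair%05d", seq_len(n))
  side <- sample(c("5p", "3p"), n, replace = TRUE)
  oligos <- data.frame(
    oligo_id = c(paste0(pair_id, "_ref"), paste0(pair_id, "_mt")),
    pair_id = rep(pair_id, 2L),
    allele = rep(c("ref", "mt"), each = n),
    side = rep(side, 2L),
    sequence = c(ref, mt),
    stringsAsFactors = FALSE)
  oligos <- oligos[order(oligos$pair_id, oligos$allele, decreasing = c(FALSE, TRUE),
                         method = "radix"), , drop = FALSE]
  rownames(oligos) <- NULL

  fx <- seq_features(oligos$sequence)
  motif_n <- if (is.null(config$planted_motif)) {
    rep(0L, nrow(oligos))
  } else {
    Biostrings::vcountPattern(config$planted_motif,
                              Biostrings::RNAStringSet(oligos$sequence))
  }
  eps_pair <- rnorm(n, 0, config$noise_sd)
  eps <- if (config$pair_noise) {
    eps_pair[match(oligos$pair_id, pair_id)]
  } else {
    rnorm(nrow(oligos), 0, config$noise_sd)
  }
  log_rate <- config$a0 + config$a_ua * fx$ua_ratio +
    config$a_gc * fx$gc_fraction +
    config$a_int * fx$ua_ratio * fx$gc_fraction +
    config$a_motif * motif_n + eps
  abundance <- rlnorm(nrow(oligos), 0, config$abundance_sdlog)

  truth <- truth_table(oligo_id = oligos$oligo_id,
                       true_lambda = exp(log_rate),
                       ua_ratio = fx$ua_ratio,
                       gc_fraction = fx$gc_fraction,
                       planted_motifs = ifelse(motif_n > 0,
                                               config$planted_motif %||% "", ""),
                       initial_abundance = abundance)
  truth$motif_count <- as.integer(motif_n)
  list(oligos = oligos, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate time-course read counts
#'
#' For every (timepoint, replicate) sequencing library, counts are one
#' multinomial draw of size `depth` with class probabilities proportional to
#' `initial_abundance * exp(-lambda * t)`. When
#' `config$spike_in_fraction > 0` an additional non-decaying `"spike_in"` row
#' holds that fraction of the baseline-expected reads (see [sim_config()] for
#' why an anchor is needed to make absolute rates identifiable from
#' fixed-depth sequencing).
#'
#' @param truth a [truth_table()].
#' @param config a [sim_config()]; `timepoints`, `n_replicates`, `depth`,
#'   `spike_in_fraction` and `seed` are used.
#' @return A 3-d integer array (oligo x timepoint x replicate) with dimnames;
#'   attribute `"timepoints"` stores the numeric harvest times.
#' @export
simulate_counts <- function(truth, config) {
  stopifnot(inherits(truth, "data.frame"), nrow(truth) > 0)
  if (any(config$timepoints < 0)) stop("timepoints must be non-negative")
  set.seed(sub_seed(config$seed, 1L))
  tps <- config$timepoints
  nrep <- config$n_replicates
  m <- truth$initial_abundance
  lam <- truth$true_lambda
  ids <- truth$oligo_id
  f <- config$spike_in_fraction
  if (f > 0) {
    m <- c(m, f / (1 - f) * sum(m))
    lam <- c(lam, 0)
    ids <- c(ids, "spike_in")
  }
  counts <- array(0L, dim = c(length(ids), length(tps), nrep),
                  dimnames = list(oligo_id = ids,
                                  timepoint = format(tps, trim = TRUE),
                                  replicate = seq_len(nrep)))
  for (ti in seq_along(tps)) {
    p <- m * exp(-lam * tps[ti])
    for (r in seq_len(nrep)) {
      counts[, ti, r] <- rmultinom(1L, size = config$depth, prob = p)[, 1L]
    }
  }
  attr(counts, "timepoints") <- tps
  counts
}

#' Simulate SLAM-seq style T-to-C conversion tables
#'
#' Per transcript, timepoint and batch, the number of converted T positions
#' is drawn binomially at the configured coverage, with conversion rate
#' decaying from the baseline rate as `exp(-lambda * t)` (pulse-chase
#' labelling: the labelled fraction decays with the transcript). Decay rates
#' are taken from `truth$true_lambda` and interpreted per unit of
#' `conv_timepoints_hr`.
#'
#' @inheritParams simulate_counts
#' @return A data.frame with columns `transcript_id`, `timepoint_hr`,
#'   `batch`, `ttoc` (converted T count) and `t_total` (unconverted T count).
#' @export
simulate_conversion_tables <- function(truth, config) {
  stopifnot(inherits(truth, "data.frame"), nrow(truth) > 0)
  r0 <- config$conv_rate0
  if (r0 <= 0 || r0 >= 0.8) {
    stop("baseline conversion rate must lie in (0, 0.8)")
  }
  set.seed(sub_seed(config$seed, 2L))
  tps <- config$conv_timepoints_hr
  grid <- expand.grid(i = seq_len(nrow(truth)), t = tps,
                      batch = seq_len(config$conv_batches))
  rate <- r0 * exp(-truth$true_lambda[grid$i] * grid$t)
  conv <- rbinom(nrow(grid), size = config$conv_coverage, prob = rate)
  data.frame(transcript_id = truth$oligo_id[grid$i],
             timepoint_hr = grid$t,
             batch = grid$batch,
             ttoc = conv,
             t_total = config$conv_coverage - conv,
             stringsAsFactors = FALSE)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config:", x$n_pairs, "pairs,",
      paste(x$seq_length, collapse = "-"), "nt, timepoints",
      paste(x$timepoints, collapse = "/"), "min x", x$n_replicates,
      "replicates, depth", format(x$depth, scientific = TRUE), "\n")
  cat("  log-rate model: a0 =", x$a0, " a_ua =", x$a_ua, " a_gc =", x$a_gc,
      " a_int =", x$a_int, " a_motif =", x$a_motif,
      " noise_sd =", x$noise_sd, "\n")
  if (!is.null(x$planted_motif)) {
    cat("  planted motif:", x$planted_motif, "in", x$motif_fraction,
        "of pairs\n")
  }
  invisible(x)
}
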