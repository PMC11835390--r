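IUPAC_MAP <- c(A = "A", C = "C", G = "G", U = "U",
               R = "AG", Y = "CU", W = "AU", S = "CG", K = "GU", M = "AC",
               B = "CGU", D = "AGU", H = "ACU", V = "ACG", N = "ACGU")

## The five Kozak context classes (RNA alphabet); W/R/Y/H/N are IUPAC codes.
KOZAK_PATTERNS <- c(optimal = "GCCRCCAUGG",
                    strong = "NNNRNNAUGG",
                    moderate_H = "NNNRNNAUGH",
                    moderate_Y = "NNNYNNAUGG",
                    weak = "NNNYNNAUGH")

## AU-rich element patterns (RNA alphabet; W = A/U).
ARE_PATTERNS <- c(are_AUUUA = "AUUUA", are_WUUUW = "WUUUW",
                  are_WWUUUWW = "WWUUUWW", are_WWWUUUWWW = "WWWUUUWWW",
                  are_WWWWUUUWWWW = "WWWWUUUWWWW",
                  are_WWWWWUUUWWWWW = "WWWWWUUUWWWWW",
                  are_UUUGUUU = "UUUGUUU", are_GUUUG = "GUUUG",
                  are_AWUAAA = "AWUAAA")

#' Overlapping k-mer ratios
#'
#' For each of the `4^k` RNA k-mers, the overlapping occurrence count
#' divided by the number of windows (`len - k + 1`), so the ratios sum to 1
#' per sequence.
#'
#' @param seq character vector of sequences (RNA or DNA alphabet; DNA is
#'   normalized).
#' @param k word size, 1 to 3.
#' @return Numeric matrix, one row per sequence, `4^k` named columns.
#' @export
#' @examples
#' kmer_ratios("GCGC", 1)[, c("G", "C")]
kmer_ratios <- function(seq, k) {
  stopifnot(k >= 1, k <= 3)
  seq <- norm_rna(seq)
  if (any(nchar(seq) < k)) stop("all sequences must have length >= k")
  set <- Biostrings::RNAStringSet(seq)
  cnt <- Biostrings::oligonucleotideFrequency(set, width = k)
  cnt / (nchar(seq) - k + 1)
}

#' GC content
#'
#' Fraction of G or C letters, `(#G + #C) / len`.
#'
#' @inheritParams kmer_ratios
#' @return Numeric vector in \[0, 1\].
#' @export
gc_content <- function(seq) {
  seq <- norm_rna(seq)
  if (any(nchar(seq) == 0)) stop("sequences must be non-empty")
  set <- Biostrings::RNAStringSet(seq)
  as.numeric(Biostrings::letterFrequency(set, "CG")) / nchar(seq)
}

#' Count overlapping IUPAC pattern matches
#'
#' Number of overlapping windows of `seq` matching `pattern`, where the
#' pattern may use the full IUPAC degenerate alphabet (W = A/U, R = A/G,
#' N = any, ...).
#'
#' @inheritParams kmer_ratios
#' @param pattern a single IUPAC pattern (RNA alphabet).
#' @return Integer vector of match counts, one per sequence.
#' @export
#' @examples
#' scan_iupac("AUUUAUUUA", "WUUUW")  # 2
scan_iupac <- function(seq, pattern) {
  seq <- norm_rna(seq)
  pattern <- chartr("T", "U", toupper(pattern))
  if (!grepl(paste0("^[", paste(names(IUPAC_MAP), collapse = ""), "]+$"), pattern)) {
    stop("invalid IUPAC code in pattern: ", pattern)
  }
  Biostrings::vcountPattern(pattern, Biostrings::RNAStringSet(seq),
                            fixed = FALSE)
}

#' Count Kozak context classes
#'
#' Overlapping occurrence counts of the five translation-initiation context
#' classes (optimal `GCCRCCAUGG`, strong `NNNRNNAUGG`, moderate_H
#' `NNNRNNAUGH`, moderate_Y `NNNYNNAUGG`, weak `NNNYNNAUGH`). Classes are
#' not mutually exclusive: an optimal context also counts as strong.
#'
#' @inheritParams kmer_ratios
#' @return Integer matrix, one row per sequence, one column per class.
#' @export
scan_kozak <- function(seq) {
  seq <- norm_rna(seq)
  if (any(nchar(seq) < 10)) stop("sequences must be at least 10 nt for Kozak scanning")
  out <- vapply(KOZAK_PATTERNS, function(p) scan_iupac(seq, p),
                integer(length(seq)))
  if (length(seq) == 1) out <- matrix(out, nrow = 1,
                                      dimnames = list(NULL, names(KOZAK_PATTERNS)))
  out
}

#' Count PWM matches above a score fraction
#'
#' Slides the position weight matrix along each sequence and counts windows
#' whose score reaches `score_fraction` times the maximum attainable score
#' (the sum of per-column maxima).
#'
#' @inheritParams kmer_ratios
#' @param pwm numeric 4 x L matrix with rownames A, C, G, U.
#' @param score_fraction threshold as a fraction of the maximum score, in
#'   \[0, 1\].
#' @return Integer vector of window counts per sequence.
#' @export
scan_pwm <- function(seq, pwm, score_fraction = 0.9) {
  if (score_fraction < 0 || score_fraction > 1) {
    stop("score_fraction must lie in [0, 1]")
  }
  stopifnot(is.matrix(pwm), nrow(pwm) == 4)
  rownames(pwm) <- chartr("T", "U", toupper(rownames(pwm)))
  if (!identical(sort(rownames(pwm)), c("A", "C", "G", "U"))) {
    stop("pwm must have rownames A, C, G, U")
  }
  pwm <- pwm[c("A", "C", "G", "U"), , drop = FALSE]
  L <- ncol(pwm)
  if (L < 2) stop("pwm must have length >= 2")
  seq <- norm_rna(seq, allow_n = FALSE)
  smax <- sum(apply(pwm, 2, max))
  thr <- score_fraction * smax
  vapply(seq, function(s) {
    n <- nchar(s)
    if (n < L) return(0L)
    idx <- match(strsplit(s, "")[[1]], c("A", "C", "G", "U"))
    nw <- n - L + 1L
    sc <- numeric(nw)
    for (j in seq_len(L)) sc <- sc + pwm[idx[seq_len(nw) + j - 1L], j]
    # tolerance keeps exact-threshold windows in despite float rounding
    sum(sc >= thr - 1e-9)
  }, integer(1), USE.NAMES = FALSE)
}

#' Count miRNA seed-match sites in a 3' UTR
#'
#' Canonical seed site types: 8mer (reverse complement of miRNA positions
#' 2-8 followed by A), 7mer-m8 (reverse complement of positions 2-8), and
#' 7mer-1a (reverse complement of positions 2-7 followed by A). Each seed
#' locus is counted once, as its best (longest) type.
#'
#' @param utr3_seq a single 3' UTR sequence.
#' @param mirna_seq a single mature miRNA sequence (>= 8 nt, 5'-3').
#' @return Named integer vector with counts for `site_8mer`, `site_7mer_m8`,
#'   `site_7mer_1a`.
#' @export
mirna_seed_sites <- function(utr3_seq, mirna_seq) {
  utr <- norm_rna(utr3_seq, allow_n = FALSE)
  mir <- norm_rna(mirna_seq, allow_n = FALSE)
  if (nchar(mir) < 8) stop("miRNA must be at least 8 nt")
  rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::RNAString(x)))
  core6 <- rc(substr(mir, 2, 7))                 # positions 2..7
  seed7 <- rc(substr(mir, 2, 8))                 # positions 2..8 (m8 included)
  n <- nchar(utr)
  counts <- c(site_8mer = 0L, site_7mer_m8 = 0L, site_7mer_1a = 0L)
  if (n < 7) return(counts)
  hits <- as.data.frame(Biostrings::matchPattern(core6, Biostrings::RNAString(utr)))
  for (p in hits$start) {
    has_m8 <- p >= 2 && substr(utr, p - 1, p + 5) == seed7
    has_a <- p + 6 <= n && substr(utr, p + 6, p + 6) == "A"
    if (has_m8 && has_a) counts["site_8mer"] <- counts["site_8mer"] + 1L
    else if (has_m8) counts["site_7mer_m8"] <- counts["site_7mer_m8"] + 1L
    else if (has_a) counts["site_7mer_1a"] <- counts["site_7mer_1a"] + 1L
  }
  counts
}

#' Interval-track features for genomic spans
#'
#' Overlap features of oligo spans against scored interval tracks (eCLIP
#' peaks, conservation tracks, ...). Binary mode reports presence of any
#' overlap; mean mode averages the track score over the covered positions of
#' the span (positions covered by several intervals take the mean of their
#' scores). Spans without coverage get 0 and are flagged.
#'
#' @param spans a `GRanges` of oligo spans (0-based half-open input should
#'   be converted with [read_intervals()]; `GRanges` itself is 1-based).
#' @param tracks named list of `GRanges` with a `score` metadata column.
#' @param mode `"binary"` or `"mean"`.
#' @return Numeric matrix spans x tracks; attribute `"covered"` is a logical
#'   matrix flagging spans with any overlap.
#' @export
interval_features <- function(spans, tracks, mode = c("binary", "mean")) {
  mode <- match.arg(mode)
  stopifnot(is(spans, "GRanges"), is.list(tracks), length(names(tracks)) > 0)
  out <- matrix(0, length(spans), length(tracks),
                dimnames = list(names(spans), names(tracks)))
  covered <- matrix(FALSE, length(spans), length(tracks),
                    dimnames = dimnames(out))
  for (j in seq_along(tracks)) {
    tr <- tracks[[j]]
    hits <- GenomicRanges::findOverlaps(spans, tr)
    covered[, j] <- seq_along(spans) %in% S4Vectors::queryHits(hits)
    if (mode == "binary") {
      out[, j] <- as.numeric(covered[, j])
    } else {
      sc <- if (!is.null(tr$score)) tr$score else rep(1, length(tr))
      for (i in unique(S4Vectors::queryHits(hits))) {
        sub <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]
        pos <- seq(GenomicRanges::start(spans)[i], GenomicRanges::end(spans)[i])
        vals <- rep(NA_real_, length(pos)); nhit <- rep(0L, length(pos))
        acc <- rep(0, length(pos))
        for (s in sub) {
          cover <- pos >= GenomicRanges::start(tr)[s] &
            pos <= GenomicRanges::end(tr)[s]
          acc[cover] <- acc[cover] + sc[s]
          nhit[cover] <- nhit[cover] + 1L
        }
        out[i, j] <- mean(acc[nhit > 0] / nhit[nhit > 0])
      }
    }
  }
  attr(out, "covered") <- covered
  out
}

#' RBP species per UA dinucleotide
#'
#' For each overlapping UA dinucleotide of a sequence, counts the number of
#' distinct RBP species whose binding evidence (intervals in local 1-based
#' coordinates, or motif-hit windows) overlaps that dinucleotide, and
#' returns the total divided by the number of UA dinucleotides.
#'
#' @param seq a single sequence.
#' @param binding named list (one element per RBP species) of data.frames
#'   with columns `start`, `end` (1-based, inclusive, local coordinates).
#' @return A single ratio; error if the sequence contains no UA dinucleotide.
#' @export
rbp_species_per_ua <- function(seq, binding) {
  seq <- norm_rna(seq)
  ua_pos <- as.data.frame(Biostrings::matchPattern("UA", Biostrings::RNAString(seq)))$start
  if (length(ua_pos) == 0) {
    stop("sequence contains no UA dinucleotide; excluded from this feature")
  }
  total <- 0L
  for (p in ua_pos) {
    for (sp in binding) {
      if (nrow(sp) > 0 && any(sp$start <= p + 1 & sp$end >= p)) {
        total <- total + 1L
      }
    }
  }
  total / length(ua_pos)
}

#' Assemble the oligo x feature matrix
#'
#' Builds all enabled feature families for a library: overlapping k-mer
#' ratios (k = 1..3), GC content, AU-rich element counts, Kozak context
#' counts, PWM match counts, miRNA seed-site counts, interval-track
#' features, and user-supplied precomputed columns (e.g. folding energy).
#' Every column carries a category tag.
#'
#' @param library data.frame with `oligo_id` and `sequence` columns (e.g.
#'   the `oligos` element of [generate_library()]).
#' @param kmer_k integer vector of k-mer sizes (subset of 1:3), or NULL.
#' @param gc,are,kozak logical switches for those families.
#' @param pwms optional named list of 4 x L PWMs for [scan_pwm()].
#' @param pwm_score_fraction threshold passed to [scan_pwm()].
#' @param mirnas optional named character vector of mature miRNA sequences.
#' @param spans,tracks,interval_mode optional inputs for
#'   [interval_features()]; `spans` must be named by oligo_id and parallel
#'   to the library.
#' @param precomputed optional data.frame of extra numeric columns with an
#'   `oligo_id` column.
#' @return Numeric matrix of class `"feature_matrix"` with rownames
#'   `oligo_id` and a `"category"` attribute naming each column's family.
#' @export
build_feature_matrix <- function(library, kmer_k = 1:3, gc = TRUE, are = TRUE,
                                 kozak = TRUE, pwms = NULL,
                                 pwm_score_fraction = 0.9, mirnas = NULL,
                                 spans = NULL, tracks = NULL,
                                 interval_mode = "binary",
                                 precomputed = NULL) {
  stopifnot(nrow(library) > 0, all(c("oligo_id", "sequence") %in% names(library)))
  seqs <- norm_rna(library$sequence)
  blocks <- list(); cats <- list()
  add <- function(m, category) {
    blocks[[length(blocks) + 1]] <<- m
    cats[[length(cats) + 1]] <<- rep(category, ncol(m))
  }
  for (k in kmer_k) add(kmer_ratios(seqs, k), "kmer")
  if (gc) add(matrix(gc_content(seqs), ncol = 1,
                     dimnames = list(NULL, "gc_content")), "gc")
  if (are) {
    m <- vapply(ARE_PATTERNS, function(p) as.numeric(scan_iupac(seqs, p)),
                numeric(length(seqs)))
    if (length(seqs) == 1) m <- matrix(m, nrow = 1,
                                       dimnames = list(NULL, names(ARE_PATTERNS)))
    add(m, "are")
  }
  if (kozak) {
    km <- scan_kozak(seqs)
    colnames(km) <- paste0("kozak_", colnames(km))
    add(km, "kozak")
  }
  if (!is.null(pwms)) {
    m <- vapply(pwms, function(p) as.numeric(scan_pwm(seqs, p, pwm_score_fraction)),
                numeric(length(seqs)))
    if (length(seqs) == 1) m <- matrix(m, nrow = 1,
                                       dimnames = list(NULL, names(pwms)))
    colnames(m) <- paste0("pwm_", colnames(m))
    add(m, "pwm")
  }
  if (!is.null(mirnas)) {
    m <- matrix(0, length(seqs), 3 * length(mirnas))
    cn <- character(0)
    for (j in seq_along(mirnas)) {
      sites <- t(vapply(seqs, mirna_seed_sites, integer(3),
                        mirna_seq = mirnas[[j]]))
      m[, (3 * j - 2):(3 * j)] <- sites
      cn <- c(cn, paste0("mirna_", names(mirnas)[j], "_",
                         c("8mer", "7mer_m8", "7mer_1a")))
    }
    colnames(m) <- cn
    add(m, "mirna")
  }
  if (!is.null(tracks)) {
    if (is.null(spans)) stop("interval features need oligo spans")
    m <- interval_features(spans, tracks, mode = interval_mode)
    colnames(m) <- paste0("interval_", colnames(m))
    attr(m, "covered") <- NULL
    add(m, "interval")
  }
  if (!is.null(precomputed)) {
    stopifnot("oligo_id" %in% names(precomputed))
    idx <- match(library$oligo_id, precomputed$oligo_id)
    if (anyNA(idx)) stop("precomputed columns missing some oligo_ids")
    m <- as.matrix(precomputed[idx, setdiff(names(precomputed), "oligo_id"),
                               drop = FALSE])
    add(m, "precomputed")
  }
  if (length(blocks) == 0) {
    out <- matrix(numeric(0), nrow = nrow(library), ncol = 0,
                  dimnames = list(library$oligo_id, NULL))
    attr(out, "category") <- character(0)
    class(out) <- c("feature_matrix", class(out))
    warning("no feature families enabled: empty feature matrix")
    return(out)
  }
  out <- do.call(cbind, blocks)
  rownames(out) <- library$oligo_id
  if (anyDuplicated(colnames(out))) {
    stop("duplicate feature column names: ",
         paste(unique(colnames(out)[duplicated(colnames(out))]), collapse = ", "))
  }
  if (anyNA(out)) stop("feature matrix contains missing values")
  attr(out, "category") <- setNames(unlist(cats), colnames(out))
  class(out) <- c("feature_matrix", class(out))
  out
}
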