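test_that("kmer ratios match the enumerated examples", {
  r1 <- kmer_ratios("GCGC", 1)
  expect_equal(unname(r1[1, c("G", "C", "A", "U")]), c(0.5, 0.5, 0, 0))
  r2 <- kmer_ratios("UAUA", 2)
  expect_equal(unname(r2[1, "UA"]), 2 / 3)
  expect_equal(unname(r2[1, "AU"]), 1 / 3)
  expect_equal(sum(r2[1, ] > 0), 2)
})

test_that("kmer ratios partition the windows (sum to 1 for each k)", {
  set.seed(1)
  seqs <- vapply(sample(10:60, 25, TRUE), rand_rna, "")
  for (k in 1:3) {
    expect_equal(unname(rowSums(kmer_ratios(seqs, k))), rep(1, 25))
  }
})

test_that("gc content follows (#G + #C) / len and rejects empty input", {
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("AUAU"), 0.0)
  expect_equal(gc_content("GAUC"), 0.5)
  expect_equal(gc_content("GATC"), 0.5)   # DNA input normalized
  expect_error(gc_content(""), "non-empty")
})

test_that("IUPAC scanning matches the worked examples", {
  expect_equal(scan_iupac("AUUUAUUUA", "WUUUW"), 2L)
  expect_equal(scan_iupac("GAUUUAG", "AUUUA"), 1L)
  expect_equal(scan_iupac("AAUAAA", "AWUAAA"), 1L)
  expect_error(scan_iupac("ACGU", "AXU"), "IUPAC")
  expect_error(scan_iupac("ACXU", "AU"), "alphabet")
})

test_that("IUPAC scanning equals the brute-force window enumerator", {
  set.seed(2)
  codes <- names(utrstab:::IUPAC_MAP)
  for (i in 1:300) {
    s <- rand_rna(sample(8:40, 1))
    p <- paste(sample(codes, sample(2:6, 1), replace = TRUE,
                      prob = c(rep(3, 4), rep(1, 11))), collapse = "")
    expect_equal(scan_iupac(s, p), brute_iupac_count(s, p),
                 info = paste(s, p))
  }
})

test_that("Kozak classes overlap as expected", {
  k <- scan_kozak("GCCACCAUGG")
  expect_equal(unname(k[1, "optimal"]), 1L)
  expect_equal(unname(k[1, "strong"]), 1L)
  expect_equal(unname(k[1, "moderate_Y"]), 0L)
  expect_true(all(scan_kozak("UUUUUUUUUU") == 0))
  expect_true(all(scan_kozak("CCCCCCCCCCCCCC") == 0))  # no AUG at all
})

test_that("PWM scanning counts windows above the score fraction", {
  one_hot <- function(kmer) {
    m <- matrix(0, 4, nchar(kmer), dimnames = list(c("A", "C", "G", "U"), NULL))
    b <- strsplit(kmer, "")[[1]]
    for (j in seq_along(b)) m[b[j], j] <- 1
    m
  }
  pwm <- one_hot("GAC")
  expect_equal(scan_pwm("GACGAC", pwm, 1.0), 2L)
  expect_equal(scan_pwm("GACGAC", pwm, 0), 4L)   # every window passes
  expect_error(scan_pwm("GACGAC", pwm, 1.5), "\\[0, 1\\]")
})

test_that("PWM scanning equals the brute-force window scorer", {
  set.seed(3)
  for (i in 1:50) {
    L <- sample(3:6, 1)
    pwm <- matrix(runif(4 * L, -1, 2), 4,
                  dimnames = list(c("A", "C", "G", "U"), NULL))
    s <- rand_rna(sample(L:30, 1))
    frac <- runif(1)
    expect_equal(scan_pwm(s, pwm, frac), brute_pwm_count(s, pwm, frac))
  }
})

test_that("miRNA seed sites are classified by their best type per locus", {
  mir <- "UAGCUUAUCAGACUGAUGUUGA"
  expect_equal(unname(mirna_seed_sites("GGAUAAGCUAGG", mir)),
               c(1L, 0L, 0L))                     # 8mer
  expect_equal(unname(mirna_seed_sites("GGAUAAGCUGGG", mir)),
               c(0L, 1L, 0L))                     # 7mer-m8, no adjacent A
  expect_equal(unname(mirna_seed_sites("GGGUAAGCUAGG", mir)),
               c(0L, 0L, 1L))                     # 7mer-1a, no m8 match
  expect_equal(unname(mirna_seed_sites("GGGGGGGG", mir)), c(0L, 0L, 0L))
  expect_error(mirna_seed_sites("GGAUAAGCUAGG", "ACGU"), "8 nt")
})

test_that("8mer sites are never double-counted as 7mers", {
  mir <- "UAGCUUAUCAGACUGAUGUUGA"
  utr <- "AUAAGCUAGGGGGAUAAGCUGG"   # one 8mer locus plus one 7mer-m8 locus
  cts <- mirna_seed_sites(utr, mir)
  expect_equal(unname(cts), c(1L, 1L, 0L))
})

test_that("interval features respect half-open input and mean scores", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t105\t120\tpk1\t1.0",
               "chr1\t100\t105\tpk2\t0.5"), bed)
  track <- read_intervals(bed)
  spans <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 110))
  b <- interval_features(spans, list(tk = track), mode = "binary")
  expect_equal(unname(b[1, 1]), 1)
  m <- interval_features(spans, list(tk = track), mode = "mean")
  expect_equal(unname(m[1, 1]), 0.75)   # half at 0.5, half at 1.0
  far <- GenomicRanges::GRanges("chr1", IRanges::IRanges(500, 510))
  b0 <- interval_features(far, list(tk = track), mode = "mean")
  expect_equal(unname(b0[1, 1]), 0)
  expect_false(attr(b0, "covered")[1, 1])
})

test_that("RBP species per UA follows the stated average", {
  # sequence with exactly 2 UA dimers at positions 1 and 7
  s <- "UAGGGGUAG"
  binding3 <- list(r1 = data.frame(start = 1, end = 3),
                   r2 = data.frame(start = 1, end = 2),
                   r3 = data.frame(start = 2, end = 5))
  expect_equal(rbp_species_per_ua(s, binding3), 1.5)   # (3 + 0) / 2
  expect_equal(rbp_species_per_ua(s, list(r1 = data.frame(start = integer(),
                                                          end = integer()))), 0)
  all_cover <- list(r1 = data.frame(start = 1, end = 9),
                    r2 = data.frame(start = 1, end = 9))
  expect_equal(rbp_species_per_ua(s, all_cover), 2)
  expect_error(rbp_species_per_ua("GGGG", binding3), "no UA")
})

test_that("the k<=3 composition block has 84 columns and is deterministic", {
  cfg <- sim_config(n_pairs = 10, seed = 13)
  lib <- generate_library(cfg)
  fm <- build_feature_matrix(lib$oligos, gc = FALSE, are = FALSE,
                             kozak = FALSE)
  expect_equal(ncol(fm), 4 + 16 + 64)
  expect_true(all(attr(fm, "category") == "kmer"))
  fm2 <- build_feature_matrix(lib$oligos, gc = FALSE, are = FALSE,
                              kozak = FALSE)
  expect_identical(unclass(fm), unclass(fm2))
})

test_that("an empty feature config yields a flagged zero-column matrix", {
  cfg <- sim_config(n_pairs = 3, seed = 14)
  lib <- generate_library(cfg)
  expect_warning(fm <- build_feature_matrix(lib$oligos, kmer_k = NULL,
                                            gc = FALSE, are = FALSE,
                                            kozak = FALSE),
                 "empty")
  expect_equal(ncol(fm), 0)
  expect_equal(nrow(fm), nrow(lib$oligos))
})

test_that("duplicate precomputed columns are rejected", {
  cfg <- sim_config(n_pairs = 3, seed = 15)
  lib <- generate_library(cfg)
  pre <- data.frame(oligo_id = lib$oligos$oligo_id, gc_content = 1)
  expect_error(build_feature_matrix(lib$oligos, kmer_k = NULL, are = FALSE,
                                    kozak = FALSE, precomputed = pre),
               "duplicate")
})
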