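#' Read an oligo library FASTA
#'
#' Headers follow `>{pair_id}|{allele}|{side}|{oligo_id}` with allele in
#' ref/mt and side in 5p/3p. DNA input is normalized to the RNA alphabet
#' and lower case is raised. Malformed headers raise an error naming the
#' record; oligos without a partner of the other allele trigger a warning.
#'
#' @param path FASTA file.
#' @return data.frame with `oligo_id`, `pair_id`, `allele`, `side`,
#'   `sequence`.
#' @export
read_library <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  parts <- strsplit(names(set), "|", fixed = TRUE)
  bad <- which(lengths(parts) != 4)
  if (length(bad)) {
    stop("malformed header at record ", bad[1], ": ", names(set)[bad[1]])
  }
  hdr <- do.call(rbind, parts)
  out <- data.frame(oligo_id = hdr[, 4], pair_id = hdr[, 1],
                    allele = hdr[, 2], side = hdr[, 3],
                    sequence = norm_rna(as.character(set)),
                    stringsAsFactors = FALSE)
  if (!all(out$allele %in% c("ref", "mt"))) {
    stop("malformed header at record ",
         which(!out$allele %in% c("ref", "mt"))[1], ": allele must be ref or mt")
  }
  if (!all(out$side %in% c("5p", "3p"))) {
    stop("malformed header at record ",
         which(!out$side %in% c("5p", "3p"))[1], ": side must be 5p or 3p")
  }
  n_alleles <- table(out$pair_id)
  if (any(n_alleles != 2)) {
    warning("unpaired oligos for pair(s): ",
            paste(names(n_alleles)[n_alleles != 2], collapse = ", "))
  }
  out
}

#' Write an oligo library FASTA
#'
#' @param oligos data.frame as returned by [read_library()] or
#'   [generate_library()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_library <- function(oligos, path) {
  headers <- paste(oligos$pair_id, oligos$allele, oligos$side,
                   oligos$oligo_id, sep = "|")
  writeLines(paste0(">", headers, "\n", oligos$sequence), path)
  invisible(path)
}

#' Read a long-format counts TSV into a count tensor
#'
#' Expects columns `oligo_id`, `timepoint_min`, `replicate`, `count`.
#'
#' @param path TSV file.
#' @return 3-d array as produced by [simulate_counts()].
#' @export
read_counts_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("oligo_id", "timepoint_min", "replicate", "count")
  if (!all(need %in% names(df))) {
    stop("counts TSV needs columns: ", paste(need, collapse = ", "))
  }
  ids <- unique(df$oligo_id)
  tps <- sort(unique(df$timepoint_min))
  reps <- sort(unique(df$replicate))
  arr <- array(0L, dim = c(length(ids), length(tps), length(reps)),
               dimnames = list(oligo_id = ids,
                               timepoint = format(tps, trim = TRUE),
                               replicate = reps))
  arr[cbind(match(df$oligo_id, ids), match(df$timepoint_min, tps),
            match(df$replicate, reps))] <- df$count
  attr(arr, "timepoints") <- tps
  arr
}

#' Write a count tensor as a long-format TSV
#'
#' @param counts 3-d array.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(counts, path) {
  tps <- attr(counts, "timepoints")
  if (is.null(tps)) tps <- as.numeric(dimnames(counts)[[2]])
  dn <- dimnames(counts)
  grid <- expand.grid(o = seq_along(dn[[1]]), t = seq_along(tps),
                      r = seq_len(dim(counts)[3]))
  df <- data.frame(oligo_id = dn[[1]][grid$o],
                   timepoint_min = tps[grid$t],
                   replicate = grid$r,
                   count = counts[cbind(grid$o, grid$t, grid$r)])
  df <- df[order(df$oligo_id, df$timepoint_min, df$replicate), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read BED intervals into a GRanges
#'
#' Native line-validated BED reader (0-based half-open input; the returned
#' `GRanges` uses the usual 1-based closed convention). Columns beyond the
#' third are name, score and strand; a numeric score column is kept as the
#' `score` metadata column. Malformed lines (fewer than 3 columns,
#' non-numeric coordinates, or start >= end) raise an error with the line
#' number.
#'
#' @param path BED file.
#' @return A `GRanges` sorted within chromosomes, with `score` metadata
#'   when present.
#' @export
read_intervals <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  rows <- strsplit(lines[keep], "\t")
  lineno <- which(keep)
  chrom <- character(length(rows)); start <- end <- numeric(length(rows))
  name <- character(length(rows)); score <- rep(NA_real_, length(rows))
  strand <- rep("*", length(rows))
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    if (length(f) < 3) stop("malformed BED line ", lineno[i], ": fewer than 3 columns")
    s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e)) {
      stop("malformed BED line ", lineno[i], ": non-numeric coordinates")
    }
    if (s >= e) stop("malformed BED line ", lineno[i], ": start >= end")
    chrom[i] <- f[1]; start[i] <- s; end[i] <- e
    if (length(f) >= 4) name[i] <- f[4]
    if (length(f) >= 5) score[i] <- suppressWarnings(as.numeric(f[5]))
    if (length(f) >= 6 && f[6] %in% c("+", "-")) strand[i] <- f[6]
  }
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1, end = end),
    strand = strand)
  if (any(nzchar(name))) names(gr) <- name
  if (any(!is.na(score))) gr$score <- score
  gr[order(as.character(GenomicRanges::seqnames(gr)),
           GenomicRanges::start(gr))]
}

#' Read a PWM matrix file
#'
#' ATtRACT-style whitespace-separated matrix with four labelled rows
#' (A/C/G/U, or T for DNA input) and optionally a leading `>id` line.
#'
#' @param path matrix file.
#' @return 4 x L numeric matrix with rownames A, C, G, U and attribute
#'   `"motif_id"` when a header was present.
#' @export
read_pwm <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  id <- NULL
  if (startsWith(lines[1], ">")) {
    id <- sub("^>\\s*", "", lines[1])
    lines <- lines[-1]
  }
  if (length(lines) != 4) stop("PWM file must have 4 base rows")
  fields <- strsplit(trimws(lines), "\\s+")
  bases <- chartr("T", "U", toupper(vapply(fields, `[`, "", 1)))
  vals <- lapply(fields, function(f) as.numeric(f[-1]))
  if (!setequal(bases, c("A", "C", "G", "U"))) {
    stop("PWM rows must be labelled A, C, G, U (or T)")
  }
  if (length(unique(lengths(vals))) != 1 || lengths(vals)[1] < 2) {
    stop("PWM rows must share a common length >= 2")
  }
  m <- do.call(rbind, vals)
  rownames(m) <- bases
  m <- m[c("A", "C", "G", "U"), , drop = FALSE]
  if (any(!is.finite(m))) stop("PWM weights must be finite")
  if (!is.null(id)) attr(m, "motif_id") <- id
  m
}

#' Write a PWM matrix file
#'
#' @param pwm 4 x L matrix, rows A/C/G/U.
#' @param path output file.
#' @param id optional motif id written as a `>id` header.
#' @return `path`, invisibly.
#' @export
write_pwm <- function(pwm, path, id = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(id)) writeLines(paste0(">", id), con)
  for (b in c("A", "C", "G", "U")) {
    writeLines(paste(c(b, format(pwm[b, ], trim = TRUE)), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a conversion table TSV
#'
#' Columns `transcript_id`, `timepoint_hr`, `batch`, `ttoc`, `t_total`.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_conversion_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "timepoint_hr", "batch", "ttoc", "t_total")
  if (!all(need %in% names(df))) {
    stop("conversion TSV needs columns: ", paste(need, collapse = ", "))
  }
  df
}

#' Write a simulation config as YAML
#'
#' @param config a [sim_config()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$base_probs <- as.list(x$base_probs)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a simulation config from YAML
#'
#' Unknown keys are rejected; known keys override [sim_config()] defaults.
#'
#' @param path YAML file.
#' @return A `"sim_config"` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(x$base_probs)) x$base_probs <- unlist(x$base_probs)
  do.call(sim_config, x)
}
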