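#' Demultiplex raw reads by exact barcode prefix
#'
#' A read is assigned to a sample iff its prefix exactly equals that sample's
#' barcode (so a read with any ambiguity, e.g. an N, in the barcode region is
#' discarded). Assigned reads have the barcode stripped.
#'
#' @param reads Data frame with `read_id` and `sequence`, or a character
#'   vector of sequences.
#' @param barcode_map Named character vector, sample id to barcode; barcodes
#'   must be of equal length and pairwise distinct.
#' @return A list with `assigned` (named list of data frames, one per sample,
#'   with `read_id` and barcode-stripped `sequence`), `discarded` (data frame
#'   of unassigned reads) and `n_input`.
#' @export
demultiplex <- function(reads, barcode_map) {
  if (is.character(reads))
    reads <- data.frame(read_id = paste0("read_", seq_along(reads)),
                        sequence = reads, stringsAsFactors = FALSE)
  if (length(unique(nchar(barcode_map))) > 1L)
    stop("all barcodes must have equal length")
  if (anyDuplicated(barcode_map))
    stop("duplicate barcodes in `barcode_map`")
  bl <- nchar(barcode_map[[1L]])
  prefix <- substr(reads$sequence, 1L, bl)
  hit <- match(prefix, barcode_map)  # exact match of the full prefix only
  assigned <- lapply(seq_along(barcode_map), function(i) {
    sel <- which(hit == i)
    data.frame(read_id = reads$read_id[sel],
               sequence = substring(reads$sequence[sel], bl + 1L),
               stringsAsFactors = FALSE)
  })
  names(assigned) <- names(barcode_map)
  list(assigned = assigned,
       discarded = reads[is.na(hit), , drop = FALSE],
       n_input = nrow(reads))
}

hamming <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

#' Four-step 3' adapter trimming cascade
#'
#' Trims the 3' adapter from barcode-stripped reads in four steps:
#' \enumerate{
#'   \item Leftmost exact occurrence of the full adapter; the insert is the
#'     prefix before it (`trimmed_full` if at least `min_insert` = 7 nt,
#'     otherwise `rejected_short`).
#'   \item Otherwise the adapter is shortened from its 3' end one base at a
#'     time down to `min_adapter` = 4 nt; if the read's 3'-terminal bases
#'     equal that adapter prefix the leading bases are the insert
#'     (`trimmed_stepwise`; with 32-nt remainders this identifies 8-28-nt
#'     inserts).
#'   \item Otherwise steps 1-2 are repeated allowing up to `max_mismatch` = 2
#'     substitutions over an adapter match of at least `mismatch_min_match` =
#'     10 nt (`trimmed_mismatch`; leftmost occurrence wins, ties broken by
#'     fewest mismatches then longest match).
#'   \item Any trimmed insert is screened: poly(A) inserts (at least 90% A)
#'     are `rejected_polyA`; inserts with more than one N are `rejected_N`.
#' }
#' Reads in which no adapter is found are `untrimmed`.
#'
#' @param remainder Character vector of barcode-stripped read sequences.
#' @param adapter Adapter sequence (default the 25-nt 3' adapter).
#' @param min_insert Minimum insert length for a full-adapter hit (7).
#' @param min_adapter Minimum stepwise adapter prefix (4).
#' @param mismatch_min_match Minimum adapter match length in step 3 (10).
#' @param max_mismatch Maximum substitutions allowed in step 3 (2).
#' @return Data frame with `outcome` (one of `trimmed_full`,
#'   `trimmed_stepwise`, `trimmed_mismatch`, `rejected_short`,
#'   `rejected_polyA`, `rejected_N`, `untrimmed`) and `insert` (empty string
#'   unless the outcome starts with "trimmed").
#' @export
trim_adapter <- function(remainder, adapter = DEFAULT_ADAPTER,
                         min_insert = 7L, min_adapter = 4L,
                         mismatch_min_match = 10L, max_mismatch = 2L) {
  alen <- nchar(adapter)
  res <- lapply(remainder, function(x) {
    len <- nchar(x)
    ## step 1: leftmost exact full adapter
    i <- regexpr(adapter, x, fixed = TRUE)[1L]
    if (i > 0L) {
      ins <- substr(x, 1L, i - 1L)
      if (nchar(ins) >= min_insert)
        return(list("trimmed_full", ins))
      return(list("rejected_short", ""))
    }
    ## step 2: exact terminal adapter prefix, longest first
    for (k in if (len >= min_adapter)
           seq(min(alen - 1L, len), min_adapter) else integer()) {
      if (substr(x, len - k + 1L, len) == substr(adapter, 1L, k)) {
        ins <- substr(x, 1L, len - k)
        if (nchar(ins) == 0L) return(list("rejected_short", ""))
        return(list("trimmed_stepwise", ins))
      }
    }
    ## step 3: mismatch-tolerant repeat of steps 1-2
    best <- NULL  # (offset, mismatches, k)
    if (len >= alen) {
      for (i in seq_len(len - alen + 1L)) {
        mm <- hamming(substr(x, i, i + alen - 1L), adapter)
        if (mm <= max_mismatch &&
            (is.null(best) || i < best[1L] ||
             (i == best[1L] && (mm < best[2L] ||
                                (mm == best[2L] && alen > best[3L])))))
          best <- c(i, mm, alen)
      }
    }
    for (k in if (len >= mismatch_min_match)
           seq(min(alen - 1L, len), mismatch_min_match) else integer()) {
      i <- len - k + 1L
      mm <- hamming(substr(x, i, len), substr(adapter, 1L, k))
      if (mm <= max_mismatch &&
          (is.null(best) || i < best[1L] ||
           (i == best[1L] && (mm < best[2L] ||
                              (mm == best[2L] && k > best[3L])))))
        best <- c(i, mm, k)
    }
    if (!is.null(best)) {
      ins <- substr(x, 1L, best[1L] - 1L)
      if (nchar(ins) < min_insert) return(list("rejected_short", ""))
      return(list("trimmed_mismatch", ins))
    }
    list("untrimmed", "")
  })
  outcome <- vapply(res, `[[`, character(1L), 1L)
  insert <- vapply(res, `[[`, character(1L), 2L)
  ## step 4: screen trimmed inserts for poly(A) and multiple Ns
  trimmed <- startsWith(outcome, "trimmed")
  if (any(trimmed)) {
    frac_a <- vapply(insert[trimmed], function(s)
      mean(strsplit(s, "")[[1L]] == "A"), numeric(1L), USE.NAMES = FALSE)
    n_n <- vapply(insert[trimmed], function(s)
      sum(strsplit(s, "")[[1L]] == "N"), numeric(1L), USE.NAMES = FALSE)
    polya <- frac_a >= 0.9
    many_n <- !polya & n_n > 1
    idx <- which(trimmed)
    outcome[idx[polya]] <- "rejected_polyA"
    outcome[idx[many_n]] <- "rejected_N"
    insert[idx[polya | many_n]] <- ""
  }
  data.frame(outcome = outcome, insert = insert, stringsAsFactors = FALSE)
}

#' Collapse trimmed inserts to unique sequences with per-sample counts
#'
#' Keeps inserts within the retention window (15-29 nt by default) and
#' collapses identical sequences into one record with per-sample read counts.
#'
#' @param inserts_per_sample Named list, sample id to character vector of
#'   trimmed insert sequences.
#' @param min_len,max_len Retention window (inclusive).
#' @return Data frame with `sequence`, `length` and one count column per
#'   sample; the sum of a sample's column equals its number of retained
#'   inserts. Sample names are stored in attribute `samples`.
#' @export
collapse_inserts <- function(inserts_per_sample, min_len = 15L,
                             max_len = 29L) {
  samples <- names(inserts_per_sample)
  kept <- lapply(inserts_per_sample, function(x)
    x[nchar(x) >= min_len & nchar(x) <= max_len])
  seqs <- sort(unique(unlist(kept, use.names = FALSE)))
  counts <- vapply(kept, function(x)
    as.integer(table(factor(x, levels = seqs))), integer(length(seqs)))
  if (length(seqs) == 0L)
    counts <- matrix(integer(), nrow = 0L, ncol = length(samples),
                     dimnames = list(NULL, samples))
  if (is.null(dim(counts)))
    counts <- matrix(counts, nrow = length(seqs),
                     dimnames = list(NULL, samples))
  out <- data.frame(sequence = seqs, length = nchar(seqs),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(counts))
  rownames(out) <- NULL
  attr(out, "samples") <- samples
  out
}

#' Run the full preprocessing stage on a multiplexed library
#'
#' Demultiplexes, trims adapters, screens and collapses inserts, returning
#' the collapsed records plus per-sample outcome tallies.
#'
#' @param reads Data frame with `read_id` and `sequence`.
#' @param barcode_map Named character vector, sample id to barcode.
#' @param adapter Adapter sequence.
#' @param ... Passed on to [trim_adapter()] and [collapse_inserts()].
#' @return A list with `records` (collapsed insert table), `summary` (data
#'   frame of per-sample outcome counts, including `demux_discarded` on the
#'   first row margin) and `trim` (per-sample trim results).
#' @export
preprocess_library <- function(reads, barcode_map, adapter = DEFAULT_ADAPTER,
                               ...) {
  dm <- demultiplex(reads, barcode_map)
  trim <- lapply(dm$assigned, function(d)
    trim_adapter(d$sequence, adapter = adapter))
  outcomes <- c("trimmed_full", "trimmed_stepwise", "trimmed_mismatch",
                "rejected_short", "rejected_polyA", "rejected_N", "untrimmed")
  tally <- t(vapply(trim, function(tr)
    as.integer(table(factor(tr$outcome, levels = outcomes))),
    integer(length(outcomes))))
  colnames(tally) <- outcomes
  summary <- data.frame(sample = names(dm$assigned), tally,
                        row.names = NULL, stringsAsFactors = FALSE)
  attr(summary, "demux_discarded") <- nrow(dm$discarded)
  inserts <- lapply(trim, function(tr)
    tr$insert[startsWith(tr$outcome, "trimmed")])
  records <- collapse_inserts(inserts, ...)
  list(records = records, summary = summary, trim = trim)
}

#' Write collapsed inserts as per-sample FASTA
#'
#' Headers follow the `>seq{i}_x{count}` dialect; only sequences observed in
#' the sample are written.
#'
#' @param records Collapsed insert table from [collapse_inserts()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_collapsed_fasta <- function(records, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  samples <- attr(records, "samples")
  files <- vapply(samples, function(s) {
    sel <- records[[s]] > 0L
    x <- Biostrings::DNAStringSet(records$sequence[sel])
    names(x) <- sprintf("seq%d_x%d", which(sel), records[[s]][sel])
    f <- file.path(dir, paste0(s, ".fa"))
    Biostrings::writeXStringSet(x, f)
    f
  }, character(1L))
  invisible(files)
}
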