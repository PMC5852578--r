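#' Partition transposon-derived reads by size class
#'
#' 21-nt reads are endo-siRNAs, 23-29-nt reads are piRNAs; everything else
#' within the 15-29-nt retention window (including 22 nt) is `other`.
#'
#' @param lengths Integer vector of read lengths.
#' @param sirna_length siRNA length (default 21).
#' @param pirna_range Inclusive piRNA length interval (default `c(23, 29)`).
#' @return Factor with levels `siRNA`, `piRNA`, `other`.
#' @export
partition_by_size <- function(lengths, sirna_length = 21L,
                              pirna_range = c(23L, 29L)) {
  cls <- ifelse(lengths == sirna_length, "siRNA",
                ifelse(lengths >= pirna_range[1L] &
                         lengths <= pirna_range[2L], "piRNA", "other"))
  factor(cls, levels = c("siRNA", "piRNA", "other"))
}

#' Ping-pong 5'-5' overlap spectrum
#'
#' For every plus-strand read with 5' end at p and every minus-strand read
#' with 5' genomic coordinate q on the same reference, accumulates the
#' offset d = q - p + 1 (so d = 10 corresponds to the canonical 10-nt 5'
#' overlap of a ping-pong pair). Two variants are emitted: raw pair counts,
#' and pairs weighted by 1/(multiplicity of each mate) to down-weight
#' multi-mapping reads.
#'
#' @param reads Data frame with `reference`, `pos5` (1-based 5' coordinate),
#'   `strand` (`+`/`-`), optionally `length` and `multiplicity` (default 1).
#' @param max_offset Spectrum half-width L; offsets outside [-L, L] are
#'   dropped (default 30).
#' @param size_range If non-NULL and a `length` column is present, only
#'   reads in this inclusive length interval are used (default the piRNA
#'   window `c(23, 29)`, which excludes 21-nt siRNAs).
#' @return Data frame with `offset` (-L..L), `count` (raw, integer-valued)
#'   and `weighted`.
#' @export
pingpong_spectrum <- function(reads, max_offset = 30L,
                              size_range = c(23L, 29L)) {
  if (any(is.na(reads$pos5)) || any(is.na(reads$strand)))
    stop("all reads must carry a 5' position and a strand")
  if (!is.null(size_range) && "length" %in% names(reads))
    reads <- reads[reads$length >= size_range[1L] &
                     reads$length <= size_range[2L], , drop = FALSE]
  mult <- if ("multiplicity" %in% names(reads)) reads$multiplicity
          else rep(1, nrow(reads))
  offsets <- seq(-max_offset, max_offset)
  count <- setNames(numeric(length(offsets)), offsets)
  weighted <- count
  ## all-vs-all pair counting via per-position tallies: the number of pairs
  ## at offset d is the cross-correlation of the plus and minus 5'-end
  ## position tallies, which avoids materializing the quadratic pair set
  for (refname in unique(reads$reference)) {
    sel <- reads$reference == refname
    is_p <- sel & reads$strand == "+"
    is_q <- sel & reads$strand == "-"
    if (!any(is_p) || !any(is_q)) next
    w <- max(reads$pos5[sel]) + max_offset + 1L
    np <- nq <- wp <- wq <- numeric(w)
    tp <- tapply(rep(1, sum(is_p)), reads$pos5[is_p], sum)
    np[as.integer(names(tp))] <- tp
    tq <- tapply(rep(1, sum(is_q)), reads$pos5[is_q], sum)
    nq[as.integer(names(tq))] <- tq
    tp <- tapply(1 / mult[is_p], reads$pos5[is_p], sum)
    wp[as.integer(names(tp))] <- tp
    tq <- tapply(1 / mult[is_q], reads$pos5[is_q], sum)
    wq[as.integer(names(tq))] <- tq
    for (di in seq_along(offsets)) {
      d <- offsets[di]
      x <- seq_len(w)                 # plus 5' at x pairs minus 5' at y
      y <- x + d - 1L                 # d = y - x + 1
      ok <- y >= 1L & y <= w
      count[di] <- count[di] + sum(np[x[ok]] * nq[y[ok]])
      weighted[di] <- weighted[di] + sum(wp[x[ok]] * wq[y[ok]])
    }
  }
  data.frame(offset = offsets, count = as.numeric(count),
             weighted = as.numeric(weighted), row.names = NULL)
}

#' Flag reads participating in exact 5'-5' overlap pairs
#'
#' Marks plus-strand reads that have at least one minus-strand partner at
#' offset `overlap` on the same reference (initiator-like) and the converse
#' (responder-like). Used to restrict base-bias matrices to the ping-pong
#' subpopulation.
#'
#' @param reads Data frame as in [pingpong_spectrum()].
#' @param overlap 5'-5' overlap defining a pair (default 10).
#' @return `reads` with added logical columns `is_initiator` and
#'   `is_responder`.
#' @export
pingpong_partners <- function(reads, overlap = 10L) {
  reads$is_initiator <- FALSE
  reads$is_responder <- FALSE
  for (refname in unique(reads$reference)) {
    sel <- which(reads$reference == refname)
    plus <- sel[reads$strand[sel] == "+"]
    minus <- sel[reads$strand[sel] == "-"]
    if (!length(plus) || !length(minus)) next
    reads$is_initiator[plus] <-
      (reads$pos5[plus] + overlap - 1L) %in% reads$pos5[minus]
    reads$is_responder[minus] <-
      (reads$pos5[minus] - overlap + 1L) %in% reads$pos5[plus]
  }
  reads
}

#' Positional base-frequency matrix
#'
#' Computes, for each 1-based read position, the frequency of A, C, G and U
#' over all reads covering that position (logo-ready). T is reported as U.
#'
#' @param seqs Character vector of read sequences (reads, not reference).
#' @param positions Positions to report (default 1:20, covering positions 1
#'   and 10 for all 21-29-nt reads).
#' @return Matrix, positions x bases (A, C, G, U); each row sums to 1 over
#'   the reads covering that position (NaN if none).
#' @export
base_bias <- function(seqs, positions = 1:20) {
  if (!length(seqs)) stop("empty read set")
  bases <- c("A", "C", "G", "U")
  mat <- matrix(0, length(positions), length(bases),
                dimnames = list(positions, bases))
  chars <- strsplit(seqs, "")
  for (pi in seq_along(positions)) {
    p <- positions[pi]
    b <- vapply(chars, function(ch)
      if (length(ch) >= p) ch[p] else NA_character_, character(1L))
    b <- b[!is.na(b)]
    b[b == "T"] <- "U"
    n <- length(b)
    if (n)
      mat[pi, ] <- as.integer(table(factor(b, levels = bases))) / n
    else
      mat[pi, ] <- NaN
  }
  mat
}

#' Strand profile of piRNA-cluster reads
#'
#' Bins each cluster interval and counts plus/minus-strand read 5' ends per
#' bin; the per-bin and overall bias is plus / (plus + minus). Reads falling
#' outside every cluster are ignored and tallied.
#'
#' @param reads Data frame with `contig`, `pos5` and `strand`.
#' @param clusters Data frame with `contig`, `start`, `end` (1-based
#'   closed), as in a `ReferenceSet`.
#' @param bins Number of bins per cluster (default 50).
#' @return A list with `profile` (cluster, bin, bin_start, bin_end, plus,
#'   minus, bias), `overall` (per-cluster totals and bias; NA for empty
#'   clusters) and `n_outside`.
#' @export
strand_profile <- function(reads, clusters, bins = 50L) {
  cluster_ids <- paste0("cluster_", seq_len(nrow(clusters)))
  prof <- list()
  used <- rep(FALSE, nrow(reads))
  overall <- data.frame(cluster = cluster_ids, plus = 0, minus = 0,
                        bias = NA_real_, stringsAsFactors = FALSE)
  for (ci in seq_len(nrow(clusters))) {
    cs <- clusters$start[ci]; ce <- clusters$end[ci]
    sel <- which(reads$contig == clusters$contig[ci] & reads$pos5 >= cs &
                   reads$pos5 <= ce)
    used[sel] <- TRUE
    brk <- round(seq(cs - 1L, ce, length.out = bins + 1L))
    bin <- if (length(sel)) findInterval(reads$pos5[sel], brk[-1L],
                                         left.open = FALSE) + 1L
           else integer()
    bin <- pmin(bin, bins)
    plus <- tabulate(bin[reads$strand[sel] == "+"], nbins = bins)
    minus <- tabulate(bin[reads$strand[sel] == "-"], nbins = bins)
    tot <- plus + minus
    prof[[ci]] <- data.frame(cluster = cluster_ids[ci], bin = seq_len(bins),
                             bin_start = brk[-length(brk)] + 1L,
                             bin_end = brk[-1L], plus = plus, minus = minus,
                             bias = ifelse(tot > 0, plus / tot, NA_real_),
                             stringsAsFactors = FALSE)
    overall$plus[ci] <- sum(plus)
    overall$minus[ci] <- sum(minus)
    overall$bias[ci] <- if (sum(tot) > 0) sum(plus) / sum(tot) else NA_real_
  }
  list(profile = do.call(rbind, prof), overall = overall,
       n_outside = sum(!used))
}

#' Category and size-class composition across libraries
#'
#' For each annotated library, reports the percentage of transposon-derived
#' reads and, within them, the shares of 21-nt siRNAs and 23-29-nt piRNAs
#' (both expressed as percentages of the library, so the size-class shares
#' sum to the transposon total).
#'
#' @param libs Named list of data frames, each with columns `category`,
#'   `length` and `count` (one row per collapsed insert is fine).
#' @param sirna_length,pirna_range Size-class boundaries.
#' @return Data frame with `library`, `pct_transposon`, `pct_sirna`,
#'   `pct_pirna`, `pct_other_size`.
#' @export
stage_composition <- function(libs, sirna_length = 21L,
                              pirna_range = c(23L, 29L)) {
  if (length(libs) < 2L) stop("at least two libraries are required")
  rows <- lapply(names(libs), function(nm) {
    d <- libs[[nm]]
    total <- sum(d$count)
    tp <- d$category == "transposon"
    cls <- partition_by_size(d$length, sirna_length, pirna_range)
    pct <- function(sel) if (total > 0) 100 * sum(d$count[sel]) / total else 0
    data.frame(library = nm,
               pct_transposon = pct(tp),
               pct_sirna = pct(tp & cls == "siRNA"),
               pct_pirna = pct(tp & cls == "piRNA"),
               pct_other_size = pct(tp & cls == "other"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
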