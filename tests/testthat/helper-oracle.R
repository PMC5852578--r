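# Independent brute-force oracle for the adapter-trimming cascade.
#
# Scores every candidate cut (offset i, adapter-match length k) over all
# equal-length remainders at once using character matrices, then applies the
# cascade's precedence globally: exact full adapter (leftmost) beats exact
# terminal adapter prefix (longest, i.e. leftmost cut) beats mismatched
# matches (leftmost cut, then fewest mismatches, then longest match; match
# length >= 10, <= 2 substitutions). This is a different decomposition from
# the staged implementation in the package.
oracle_trim <- function(remainders, adapter, min_insert = 7L,
                        min_adapter = 4L, mismatch_min_match = 10L,
                        max_mismatch = 2L) {
  n <- length(remainders)
  len <- unique(nchar(remainders))
  stopifnot(length(len) == 1L)
  alen <- nchar(adapter)
  M <- matrix(unlist(strsplit(remainders, "")), nrow = n, byrow = TRUE)
  A <- strsplit(adapter, "")[[1L]]

  cand <- list()  # each: type, i (cut position), k, mm (vector over reads)
  for (i in seq_len(max(0L, len - alen + 1L))) {
    mm <- rowSums(M[, i:(i + alen - 1L), drop = FALSE] !=
                    matrix(A, n, alen, byrow = TRUE))
    cand[[length(cand) + 1L]] <- list(type = "full", i = i, k = alen,
                                      mm = mm)
  }
  for (k in seq(min_adapter, min(alen - 1L, len))) {
    i <- len - k + 1L
    mm <- rowSums(M[, i:len, drop = FALSE] !=
                    matrix(A[seq_len(k)], n, k, byrow = TRUE))
    cand[[length(cand) + 1L]] <- list(type = "terminal", i = i, k = k,
                                      mm = mm)
  }

  outcome <- rep("untrimmed", n)
  insert <- rep("", n)
  # rank per read: tier (1 exact-full, 2 exact-terminal, 3 mismatch), then
  # cut position, then mismatches, then -k
  best_rank <- matrix(Inf, n, 4L)
  best_cut <- rep(NA_integer_, n)
  for (cc in cand) {
    exact <- cc$mm == 0L
    tier <- ifelse(exact, ifelse(cc$type == "full", 1L, 2L), 3L)
    elig <- exact | (cc$mm <= max_mismatch & cc$k >= mismatch_min_match)
    rank <- cbind(tier, cc$i, cc$mm, -cc$k)
    better <- elig & (rank[, 1L] < best_rank[, 1L] |
      (rank[, 1L] == best_rank[, 1L] & (rank[, 2L] < best_rank[, 2L] |
        (rank[, 2L] == best_rank[, 2L] & (rank[, 3L] < best_rank[, 3L] |
          (rank[, 3L] == best_rank[, 3L] & rank[, 4L] < best_rank[, 4L]))))))
    if (any(better)) {
      best_rank[better, ] <- rank[better, , drop = FALSE]
      best_cut[better] <- cc$i
    }
  }
  found <- !is.na(best_cut)
  for (r in which(found)) {
    ins <- substr(remainders[r], 1L, best_cut[r] - 1L)
    tier <- best_rank[r, 1L]
    if ((tier == 1L || tier == 3L) && nchar(ins) < min_insert) {
      outcome[r] <- "rejected_short"
    } else if (tier == 2L && nchar(ins) == 0L) {
      outcome[r] <- "rejected_short"
    } else {
      ch <- strsplit(ins, "")[[1L]]
      if (mean(ch == "A") >= 0.9) {
        outcome[r] <- "rejected_polyA"
      } else if (sum(ch == "N") > 1L) {
        outcome[r] <- "rejected_N"
      } else {
        outcome[r] <- c("trimmed_full", "trimmed_stepwise",
                        "trimmed_mismatch")[tier]
        insert[r] <- ins
      }
    }
  }
  data.frame(outcome = outcome, insert = insert, stringsAsFactors = FALSE)
}

# Mixed read population exercising every trimming branch: clean inserts with
# long/short adapter prefixes, mutated adapters, poly(A) and N inserts, and
# pure random sequences.
oracle_read_mix <- function(n, adapter, len = 32L) {
  bases <- c("A", "C", "G", "T")
  rand <- function(k) paste(sample(bases, k, replace = TRUE), collapse = "")
  vapply(seq_len(n), function(i) {
    kind <- sample(c("clean", "mut", "polyA", "nn", "random"), 1L,
                   prob = c(0.35, 0.25, 0.1, 0.1, 0.2))
    if (kind == "random") return(rand(len))
    il <- sample(5:28, 1L)
    ins <- switch(kind,
                  polyA = strrep("A", il),
                  nn = {
                    x <- rand(il)
                    np <- sample(il, min(il, sample(1:3, 1L)))
                    for (p in np) substr(x, p, p) <- "N"
                    x
                  },
                  rand(il))
    body <- paste0(ins, adapter)
    body <- substr(body, 1L, len)
    if (nchar(body) < len) body <- paste0(body, rand(len - nchar(body)))
    if (kind == "mut") {
      nmut <- sample(1:3, 1L)
      pos <- sample(seq(il + 1L, len), min(nmut, len - il))
      for (p in pos) substr(body, p, p) <- sample(bases, 1L)
    }
    body
  }, character(1L))
}
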