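#' Quantify mature miRNAs from exact hairpin matches
#'
#' A read counts toward a mature miRNA if it matches the hairpin exactly
#' (sense, end-to-end, no mismatches) and its 5' end lies within `window` nt
#' of the annotated mature 5' end (the isomiR window). Hairpin-level totals
#' (any exact hit anywhere in the hairpin) are reported alongside.
#'
#' @param records Collapsed insert table from [collapse_inserts()].
#' @param ref A `ReferenceSet` with `categories$miRNA_hairpin` and a
#'   `mature` table (name, hairpin, start, end, cluster).
#' @param window Maximum 5'-end offset from the annotated mature start
#'   (default 3 nt).
#' @param denominators Named numeric vector of per-sample read totals used
#'   as the RPM denominator. Defaults to the total read count of `records`
#'   per sample (use the category-assigned totals for annotation-aware
#'   normalization).
#' @return A list of class `MirnaExpression` with `counts` and `rpm`
#'   (mature miRNA x sample matrices), `hairpin_counts` and `hairpin_rpm`,
#'   and `denominators`.
#' @export
quantify_mirna <- function(records, ref, window = 3L, denominators = NULL) {
  hp <- ref$categories$miRNA_hairpin
  mature <- ref$mature
  hp_chr <- as.character(hp)
  for (i in seq_len(nrow(mature))) {
    ms <- substr(hp_chr[[mature$hairpin[i]]], mature$start[i], mature$end[i])
    if (!nzchar(ms))
      stop("mature miRNA ", mature$name[i], " not contained in its hairpin")
  }
  samples <- attr(records, "samples")
  cmat <- matrix(0, nrow(mature), length(samples),
                 dimnames = list(mature$name, samples))
  hmat <- matrix(0, length(hp), length(samples),
                 dimnames = list(names(hp), samples))
  cnts <- as.matrix(records[, samples, drop = FALSE])
  for (r in seq_len(nrow(records))) {
    s <- records$sequence[r]
    hits <- Biostrings::vmatchPattern(s, hp)
    any_hit <- FALSE
    for (h in seq_along(hp)) {
      st <- BiocGenerics::start(hits[[h]])
      if (!length(st)) next
      any_hit <- TRUE
      hmat[h, ] <- hmat[h, ] + cnts[r, ]
      cand <- which(mature$hairpin == names(hp)[h])
      for (p in st) {
        if (!length(cand)) next
        off <- abs(p - mature$start[cand])
        if (min(off) <= window) {
          m <- cand[which.min(off)]
          cmat[m, ] <- cmat[m, ] + cnts[r, ]
          break  # one mature assignment per (sequence, hairpin)
        }
      }
    }
  }
  if (is.null(denominators)) denominators <- colSums(cnts)
  denominators <- denominators[samples]
  denom <- ifelse(denominators == 0, 1, denominators)
  out <- list(counts = cmat, rpm = sweep(cmat, 2L, denom, "/") * 1e6,
              hairpin_counts = hmat,
              hairpin_rpm = sweep(hmat, 2L, denom, "/") * 1e6,
              denominators = denominators)
  class(out) <- "MirnaExpression"
  out
}

#' Filter low-abundance miRNAs
#'
#' Keeps miRNAs reaching at least `threshold` RPM in at least one sample
#' (inclusive boundary).
#'
#' @param rpm Mature miRNA x sample RPM matrix.
#' @param threshold Minimum RPM (default 50).
#' @return The filtered RPM matrix.
#' @export
filter_low <- function(rpm, threshold = 50) {
  rpm[apply(rpm, 1L, max) >= threshold, , drop = FALSE]
}

#' Pseudocount log2 fold changes between developmental stages
#'
#' For each of the five columns (unfractionated total plus four fractions)
#' computes `log2((late RPM + pseudocount) / (early RPM + pseudocount))`.
#' The pseudocount (10 reads) bounds fold-change estimates for
#' low-abundance miRNAs.
#'
#' @param rpm Mature miRNA x sample RPM matrix with samples named
#'   `stage_fraction` (e.g. `0-1h_mRNP`).
#' @param early,late Stage labels of the early and late stage (defaults
#'   `0-1h` and `7-8h`).
#' @param fractions Named character vector mapping output column names to
#'   fraction labels; default `c(Tot = "UF", mRNP = "mRNP", "60S" = "60S",
#'   "80S" = "80S", Poly = "Poly")`.
#' @param pseudocount Added to both numerator and denominator (default 10).
#' @return Data frame, one row per miRNA, columns `Tot`, `mRNP`, `60S`,
#'   `80S`, `Poly` of log2 fold changes.
#' @export
fold_change <- function(rpm, early = "0-1h", late = "7-8h",
                        fractions = c(Tot = "UF", mRNP = "mRNP",
                                      "60S" = "60S", "80S" = "80S",
                                      Poly = "Poly"),
                        pseudocount = 10) {
  if (any(rpm < 0)) stop("negative RPM values")
  out <- lapply(fractions, function(fr) {
    e <- paste(early, fr, sep = "_")
    l <- paste(late, fr, sep = "_")
    if (!e %in% colnames(rpm) || !l %in% colnames(rpm))
      stop("missing sample column for fraction ", fr)
    log2((rpm[, l] + pseudocount) / (rpm[, e] + pseudocount))
  })
  fc <- data.frame(out, check.names = FALSE)
  rownames(fc) <- rownames(rpm)
  fc
}

FC_COLUMNS <- c("Tot", "mRNP", "60S", "80S", "Poly")

#' Classify miRNAs into four polysome-association groups
#'
#' Reconstructs the four-group classification from the five log2 fold-change
#' columns (threshold `tau`, inclusive):
#' \itemize{
#'   \item G2 if |Tot| < tau (no significant change in unfractionated
#'     embryos);
#'   \item otherwise, with direction d = sign(Tot): G4 if no fraction column
#'     changes in the same direction by at least tau while at least one
#'     changes in the opposite direction by at least tau (discordance between
#'     unfractionated and fractionated behaviour);
#'   \item otherwise G1 (up-regulated, d > 0) or G3 (down-regulated, d < 0).
#' }
#'
#' @param fc Data frame with columns `Tot`, `mRNP`, `60S`, `80S`, `Poly`
#'   (and optionally a `miRNA` column; otherwise row names are used).
#' @param tau Log2 threshold (default 1.0, inclusive).
#' @return Data frame with `miRNA` and `group` (factor G1-G4); `tau` is
#'   stored as an attribute.
#' @export
classify_groups <- function(fc, tau = 1.0) {
  if (!all(FC_COLUMNS %in% colnames(fc)))
    stop("fold-change table must contain columns ",
         paste(FC_COLUMNS, collapse = ", "))
  mirna <- if ("miRNA" %in% colnames(fc)) fc$miRNA else rownames(fc)
  tot <- fc[["Tot"]]
  frac <- as.matrix(fc[, c("mRNP", "60S", "80S", "Poly")])
  group <- character(nrow(fc))
  for (i in seq_len(nrow(fc))) {
    if (abs(tot[i]) < tau) {
      group[i] <- "G2"
      next
    }
    d <- sign(tot[i])
    support <- any(d * frac[i, ] >= tau)
    opposition <- any(-d * frac[i, ] >= tau)
    group[i] <- if (!support && opposition) "G4"
                else if (d > 0) "G1" else "G3"
  }
  out <- data.frame(miRNA = mirna,
                    group = factor(group, levels = paste0("G", 1:4)),
                    stringsAsFactors = FALSE)
  attr(out, "tau") <- tau
  out
}

#' Load a packaged or user-supplied fold-change table
#'
#' Reads a TSV with columns `miRNA`, `Tot`, `mRNP`, `60S`, `80S`, `Poly` and
#' optionally `G` (curated group labels). The default is the packaged
#' reference dataset of log2 fold changes for 94 abundant mature miRNAs of
#' polysome-fractionated Drosophila embryos (7-8 h over 0-1 h, pseudocount
#' 10), with curated group labels.
#'
#' @param path TSV path; default the packaged dataset.
#' @return Data frame with the columns above (`check.names = FALSE`).
#' @export
read_foldchange_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "dme_mirna_polysome_fc.tsv",
                        package = "polysomiR", mustWork = TRUE)
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Panel of most abundant hairpins across samples
#'
#' Takes each sample's top-k hairpins by share and reports the union panel,
#' each member's share per sample, and the panel's total coverage per
#' sample.
#'
#' @param shares Hairpin x sample matrix of percentages (or counts, which
#'   are converted to within-sample percentages).
#' @param k Number of top hairpins per sample (default 10).
#' @return A list with `panel` (character vector), `shares` (panel x sample
#'   percentage matrix) and `coverage` (per-sample percentage covered by the
#'   panel).
#' @export
abundance_panel <- function(shares, k = 10L) {
  if (k <= 0L) stop("k must be positive")
  cs <- colSums(shares)
  pct <- sweep(shares, 2L, ifelse(cs == 0, 1, cs), "/") * 100
  picks <- lapply(seq_len(ncol(pct)), function(j) {
    ord <- order(pct[, j], decreasing = TRUE)
    rownames(pct)[ord[seq_len(min(k, nrow(pct)))]]
  })
  panel <- sort(unique(unlist(picks)))
  list(panel = panel, shares = pct[panel, , drop = FALSE],
       coverage = colSums(pct[panel, , drop = FALSE]))
}

#' Per-stage percentage of each miRNA across the four fractions
#'
#' For every miRNA and stage, expresses its RPM in each of the four
#' fractions (mRNP, 60S, 80S, Poly) as a percentage of the sum over the four
#' fractions. All-zero rows are flagged as undefined.
#'
#' @param rpm Mature miRNA x sample RPM matrix with samples named
#'   `stage_fraction`.
#' @param stages Stage labels (default `c("0-1h", "7-8h")`).
#' @param fractions Fraction labels (default `c("mRNP","60S","80S","Poly")`).
#' @return Data frame with `miRNA`, `stage`, one percentage column per
#'   fraction, and `defined` (FALSE where all four fractions are zero).
#' @export
fraction_distribution <- function(rpm, stages = c("0-1h", "7-8h"),
                                  fractions = c("mRNP", "60S", "80S",
                                                "Poly")) {
  out <- lapply(stages, function(st) {
    cols <- paste(st, fractions, sep = "_")
    if (!all(cols %in% colnames(rpm)))
      stop("missing fraction samples for stage ", st)
    m <- rpm[, cols, drop = FALSE]
    tot <- rowSums(m)
    pct <- sweep(m, 1L, ifelse(tot == 0, 1, tot), "/") * 100
    colnames(pct) <- fractions
    data.frame(miRNA = rownames(rpm), stage = st, pct, defined = tot > 0,
               check.names = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Co-sedimentation of miRNA genomic-cluster members
#'
#' Computes pairwise Euclidean distances between fraction-distribution
#' vectors, a complete-linkage dendrogram, and the separation statistic
#' mean(within-cluster distance) - mean(between-cluster distance). Members
#' of the same genomic cluster are co-transcribed, so similar cytoplasmic
#' distributions yield a negative separation.
#'
#' @param profiles miRNA x feature matrix (e.g. fraction percentages,
#'   possibly both stages side by side).
#' @param clusters Named character vector mapping miRNA to genomic cluster
#'   id; miRNAs absent from `profiles` are ignored.
#' @return A list with `dist`, `hclust` (complete linkage), `within`,
#'   `between`, `separation` (within - between) and `undefined` (TRUE when
#'   no cluster has two or more members).
#' @export
cluster_cosedimentation <- function(profiles, clusters) {
  clusters <- clusters[intersect(names(clusters), rownames(profiles))]
  d <- stats::dist(profiles[names(clusters), , drop = FALSE])
  hc <- if (length(clusters) >= 2L) stats::hclust(d, method = "complete")
        else NULL
  dm <- as.matrix(d)
  same <- outer(clusters, clusters, "==")
  ut <- upper.tri(dm)
  within <- dm[ut & same]
  between <- dm[ut & !same]
  undefined <- length(within) == 0L
  list(dist = d, hclust = hc,
       within = if (undefined) NA_real_ else mean(within),
       between = if (length(between)) mean(between) else NA_real_,
       separation = if (undefined) NA_real_
                    else mean(within) - mean(between),
       undefined = undefined)
}

#' Detect single-substitution editing/SNP candidates
#'
#' Aggregates reads that match a known mature miRNA with exactly one
#' substitution by (miRNA, position, ref, alt) and reports candidates whose
#' supporting-read fraction and absolute read support meet the thresholds.
#' A sequencing-based candidate cannot distinguish RNA editing from a
#' genomic SNP; the output carries that caveat as attribute `note`.
#'
#' @param records Collapsed insert table from [collapse_inserts()].
#' @param mature_seqs Named character vector of mature miRNA sequences.
#' @param min_fraction Minimum fraction of the miRNA's reads carrying the
#'   variant (default 0.1).
#' @param min_reads Minimum variant-supporting read count (default 10).
#' @return Data frame with `miRNA`, `position` (1-based), `ref`, `alt`,
#'   `reads`, `fraction`.
#' @export
editing_candidates <- function(records, mature_seqs, min_fraction = 0.1,
                               min_reads = 10L) {
  total <- rowSums(as.matrix(records[, attr(records, "samples"),
                                     drop = FALSE]))
  exact <- setNames(numeric(length(mature_seqs)), names(mature_seqs))
  hits <- list()
  for (r in seq_len(nrow(records))) {
    s <- records$sequence[r]
    for (m in names(mature_seqs)) {
      ms <- mature_seqs[[m]]
      if (nchar(s) != nchar(ms)) next
      if (s == ms) {
        exact[m] <- exact[m] + total[r]
        next
      }
      diff <- which(charToRaw(s) != charToRaw(ms))
      if (length(diff) == 1L) {
        key <- paste(m, diff, substr(ms, diff, diff), substr(s, diff, diff),
                     sep = "|")
        hits[[key]] <- (if (is.null(hits[[key]])) 0 else hits[[key]]) +
          total[r]
      }
    }
  }
  if (!length(hits)) {
    out <- data.frame(miRNA = character(), position = integer(),
                      ref = character(), alt = character(),
                      reads = numeric(), fraction = numeric(),
                      stringsAsFactors = FALSE)
  } else {
    parts <- do.call(rbind, strsplit(names(hits), "|", fixed = TRUE))
    reads <- unlist(hits, use.names = FALSE)
    denom <- exact[parts[, 1L]] + reads
    out <- data.frame(miRNA = parts[, 1L],
                      position = as.integer(parts[, 2L]),
                      ref = parts[, 3L], alt = parts[, 4L], reads = reads,
                      fraction = reads / denom, stringsAsFactors = FALSE)
    out <- out[out$reads >= min_reads & out$fraction >= min_fraction, ,
               drop = FALSE]
    out <- out[order(-out$reads), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "note") <-
    "single-substitution candidates; SNP vs editing not distinguishable from reads alone"
  out
}
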