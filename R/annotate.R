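## Count end-to-end matches of one insert inside a DNAStringSet, allowing up
## to `mm` substitutions (no indels unless with.indels).
count_hits <- function(pattern, subjects, mm = 0L, with.indels = FALSE) {
  sum(Biostrings::vcountPattern(pattern, subjects, max.mismatch = mm,
                                with.indels = with.indels, fixed = TRUE))
}

#' Genome QC alignment with mismatch tiers
#'
#' Places each insert record in the first matching tier against the genome
#' and CCA-appended mature tRNAs: exact match, one edit (insertion, deletion
#' or substitution), two substitutions, three substitutions, or unmapped.
#' Sense and antisense matches both count. Counts are read-weighted per
#' sample.
#'
#' @param records Collapsed insert table from [collapse_inserts()].
#' @param genome A [Biostrings::DNAStringSet] of genome contigs.
#' @param trnas A [Biostrings::DNAStringSet] of CCA-appended mature tRNAs
#'   (may be empty).
#' @return A list with `tiers` (per-sequence tier label) and `report` (data
#'   frame: sample x {exact, one_edit, two_mismatches, three_mismatches,
#'   unmapped} read counts; rows sum to the sample totals).
#' @export
qc_align <- function(records, genome, trnas = Biostrings::DNAStringSet()) {
  if (length(genome) == 0L) stop("empty genome reference")
  subjects <- c(genome, trnas)
  tiers <- vapply(records$sequence, function(s) {
    rc <- revcomp(s)
    if (count_hits(s, subjects, 0L) + count_hits(rc, subjects, 0L) > 0L)
      return("exact")
    if (count_hits(s, subjects, 1L, TRUE) +
        count_hits(rc, subjects, 1L, TRUE) > 0L)
      return("one_edit")
    if (count_hits(s, subjects, 2L) + count_hits(rc, subjects, 2L) > 0L)
      return("two_mismatches")
    if (count_hits(s, subjects, 3L) + count_hits(rc, subjects, 3L) > 0L)
      return("three_mismatches")
    "unmapped"
  }, character(1L), USE.NAMES = FALSE)
  levels <- c("exact", "one_edit", "two_mismatches", "three_mismatches",
              "unmapped")
  samples <- attr(records, "samples")
  report <- t(vapply(samples, function(s)
    vapply(split(records[[s]], factor(tiers, levels = levels)), sum,
           numeric(1L)), numeric(length(levels))))
  report <- data.frame(sample = samples, report, row.names = NULL,
                       stringsAsFactors = FALSE)
  list(tiers = tiers, report = report)
}

#' Hierarchical category assignment
#'
#' Assigns each insert to one reference category using a tier-major sweep:
#' for mismatch tiers t = 0, 1, 2, 3 in turn, the ordered categories (rRNA,
#' miRNA hairpin, tRNA, miscRNA, ncRNA, transposon, transcript, intron,
#' pseudogene, intergenic) are scanned, and any still-unassigned insert that
#' matches a sequence of that category end-to-end with at most t
#' substitutions (sense or antisense) is assigned there. An exact hit in a
#' low-priority category therefore always pre-empts a mismatched hit in a
#' high-priority one, while category order breaks ties within a tier.
#'
#' @param records Collapsed insert table from [collapse_inserts()].
#' @param ref A `ReferenceSet` from [build_reference()], or any named list of
#'   [Biostrings::DNAStringSet] per category under `$categories`.
#' @param max_tier Highest substitution tier to attempt (default 3).
#' @return Data frame with `sequence`, `category` (factor; `unassigned` if no
#'   tier hits), `tier` (smallest tier achieving a hit, NA if unassigned),
#'   `strand` (`sense` if any forward hit at the winning tier, else
#'   `antisense`) and `multiplicity` (number of match sites at the winning
#'   tier within the winning category).
#' @export
assign_category <- function(records, ref, max_tier = 3L) {
  cats <- ref$categories
  missing <- setdiff(CATEGORY_ORDER, names(cats))
  if (length(missing))
    cats[missing] <- list(Biostrings::DNAStringSet())
  cats <- cats[CATEGORY_ORDER]
  n <- nrow(records)
  category <- rep("unassigned", n)
  tier <- rep(NA_integer_, n)
  strand <- rep(NA_character_, n)
  multiplicity <- rep(NA_integer_, n)
  rc <- revcomp(records$sequence)
  open <- seq_len(n)
  for (t in 0:max_tier) {
    if (!length(open)) break
    for (cat in CATEGORY_ORDER) {
      if (!length(open)) break
      subjects <- cats[[cat]]
      if (length(subjects) == 0L) next
      hit <- vapply(open, function(i) {
        cs <- count_hits(records$sequence[i], subjects, t)
        ca <- count_hits(rc[i], subjects, t)
        c(cs, ca)
      }, integer(2L))
      got <- which(colSums(hit) > 0L)
      if (length(got)) {
        idx <- open[got]
        category[idx] <- cat
        tier[idx] <- t
        strand[idx] <- ifelse(hit[1L, got] > 0L, "sense", "antisense")
        multiplicity[idx] <- colSums(hit)[got]
        open <- open[-got]
      }
    }
  }
  data.frame(sequence = records$sequence,
             category = factor(category,
                               levels = c(CATEGORY_ORDER, "unassigned")),
             tier = tier, strand = strand, multiplicity = multiplicity,
             stringsAsFactors = FALSE)
}

#' Remap transposon and intergenic reads to repeat families and piRNA clusters
#'
#' Transposon-assigned inserts gain an exact-match repeat-family label (or
#' none; mismatched hits do not count). Transposon- and intergenic-assigned
#' inserts are realigned exactly to the genome and flagged with the id and
#' strand of the first piRNA-cluster interval containing the match.
#'
#' @param assignments Data frame from [assign_category()].
#' @param ref A `ReferenceSet` providing `repeat_families`, `genome` and
#'   `clusters` (1-based closed intervals).
#' @return `assignments` with added columns `family`, `cluster`,
#'   `cluster_strand` and the genomic `contig`/`pos5` of the cluster match.
#' @export
remap_special <- function(assignments, ref) {
  n <- nrow(assignments)
  family <- rep(NA_character_, n)
  cluster <- rep(NA_character_, n)
  cluster_strand <- rep(NA_character_, n)
  contig <- rep(NA_character_, n)
  pos5 <- rep(NA_integer_, n)
  cl <- ref$clusters
  cluster_ids <- paste0("cluster_", seq_len(nrow(cl)))
  for (i in which(assignments$category %in% c("transposon", "intergenic"))) {
    s <- assignments$sequence[i]
    rc <- revcomp(s)
    if (assignments$category[i] == "transposon") {
      for (f in seq_along(ref$repeat_families)) {
        if (count_hits(s, ref$repeat_families[f], 0L) +
            count_hits(rc, ref$repeat_families[f], 0L) > 0L) {
          family[i] <- names(ref$repeat_families)[f]
          break
        }
      }
    }
    for (g in seq_along(ref$genome)) {
      gname <- names(ref$genome)[g]
      for (str in c("+", "-")) {
        pat <- if (str == "+") s else rc
        m <- Biostrings::matchPattern(pat, ref$genome[[g]])
        if (length(m) == 0L) next
        st <- BiocGenerics::start(m)
        en <- BiocGenerics::end(m)
        inside <- which(cl$contig == gname)
        for (ci in inside) {
          ok <- which(st >= cl$start[ci] & en <= cl$end[ci])
          if (length(ok)) {
            cluster[i] <- cluster_ids[ci]
            cluster_strand[i] <- str
            contig[i] <- gname
            pos5[i] <- if (str == "+") st[ok[1L]] else en[ok[1L]]
            break
          }
        }
        if (!is.na(cluster[i])) break
      }
      if (!is.na(cluster[i])) break
    }
  }
  assignments$family <- family
  assignments$cluster <- cluster
  assignments$cluster_strand <- cluster_strand
  assignments$contig <- contig
  assignments$pos5 <- pos5
  assignments
}

#' Read-weighted composition table
#'
#' Computes, for every sample, the percentage of reads in each annotation
#' category (including an `unassigned` row). Columns sum to 100.
#'
#' @param assignments Data frame from [assign_category()].
#' @param records Collapsed insert table with per-sample counts (same row
#'   order as `assignments`).
#' @return Matrix, categories (plus `unassigned`) x samples, of percentages.
#'   Per-sample read totals are stored in attribute `totals`.
#' @export
composition_table <- function(assignments, records) {
  stopifnot(nrow(assignments) == nrow(records))
  samples <- attr(records, "samples")
  levels <- c(CATEGORY_ORDER, "unassigned")
  counts <- vapply(samples, function(s)
    vapply(split(records[[s]], factor(assignments$category, levels = levels)),
           sum, numeric(1L)), numeric(length(levels)))
  if (is.null(dim(counts)))
    counts <- matrix(counts, ncol = length(samples),
                     dimnames = list(levels, samples))
  totals <- colSums(counts)
  pct <- sweep(counts, 2L, ifelse(totals == 0, 1, totals), "/") * 100
  attr(pct, "totals") <- totals
  pct
}

#' Write an assignment table as TSV
#'
#' @param assignments Data frame from [assign_category()] (optionally after
#'   [remap_special()]), merged with per-sample counts if desired.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_assignments <- function(assignments, path) {
  write.table(assignments, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
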