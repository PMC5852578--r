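#' @importFrom Biostrings DNAStringSet DNAString reverseComplement writeXStringSet
#'   vcountPattern vmatchPattern BStringSet readDNAStringSet
#' @importFrom stats runif setNames
#' @importFrom utils read.delim write.table
NULL

## Ordered annotation hierarchy: inserts are assigned to the first matching
## category, so the order is part of the method, not cosmetics.
CATEGORY_ORDER <- c("rRNA", "miRNA_hairpin", "tRNA", "miscRNA", "ncRNA",
                    "transposon", "transcript", "intron", "pseudogene",
                    "intergenic")

#' Ordered annotation categories
#'
#' Returns the ordered vector of reference categories used by the hierarchical
#' annotation sweep (highest priority first).
#'
#' @return Character vector of the ten category names.
#' @export
category_order <- function() CATEGORY_ORDER

DEFAULT_ADAPTER <- "ATCTCGTATGCCGTCTTCTGCTTGT"

## Fixed, pairwise-distinct 4-nt barcodes for up to 12 samples.
DEFAULT_BARCODES <- c("AACC", "AAGG", "ACAC", "ACTG", "AGCA", "AGTC",
                      "CATA", "CCTT", "CGAT", "CTGA", "GACT", "GTCA")

default_samples <- function() {
  data.frame(
    stage    = rep(c("0-1h", "7-8h"), each = 5L),
    fraction = rep(c("UF", "mRNP", "60S", "80S", "Poly"), times = 2L),
    stringsAsFactors = FALSE
  )
}

default_composition <- function() {
  c(miRNA = 0.30, rRNA = 0.20, tRNA = 0.15, transposon = 0.20,
    transcript = 0.10, intergenic = 0.05)
}

#' Simulation configuration
#'
#' Builds a validated configuration object for the synthetic-data generator.
#' Defaults emulate the study layout: 36-nt multiplexed reads carrying a 4-nt
#' barcode, a 15-29-nt insert and the 25-nt 3' adapter
#' \code{ATCTCGTATGCCGTCTTCTGCTTGT}, for 2 developmental stages (0-1 h and
#' 7-8 h embryos) times 5 samples (unfractionated total, mRNP, 60S,
#' 80S/monosome, polysome).
#'
#' @param seed Integer seed; mandatory, every simulation is a deterministic
#'   function of (config, seed).
#' @param read_length Raw read length in nt (default 36).
#' @param barcode_map Named character vector, sample id to barcode. If `NULL`
#'   a fixed internal 4-nt barcode set is assigned to the samples.
#' @param adapter 3' adapter sequence (default the 25-nt sequence above).
#' @param samples Data frame with columns `stage` and `fraction`; default the
#'   full 2 x 5 design. Sample ids are `stage_fraction`.
#' @param reads_per_sample Number of raw reads per sample.
#' @param composition Named numeric vector of category proportions (must sum
#'   to 1), or a list of such vectors keyed by sample id for per-fraction
#'   differences (e.g. siRNAs enriched in mRNP). Categories must be a subset
#'   of \code{category_order()}.
#' @param pingpong List with `pair_fraction` (fraction of piRNA-like reads
#'   emitted as ping-pong pairs), `overlap_nt` (5'-5' overlap, default 10),
#'   `u1_bias` (probability an initiator carries U/T at position 1) and
#'   `a10_bias` (probability a responder carries A at position 10).
#' @param sirna_length Length of transposon-derived siRNAs (21 nt).
#' @param pirna_length_range Inclusive piRNA length interval (23-29 nt).
#' @param sirna_fraction Fraction of transposon-derived reads emitted as
#'   21-nt siRNAs rather than piRNAs.
#' @param planted_variants Data frame with columns `mirna`, `position`
#'   (1-based), `ref`, `alt`, `fraction` describing single-nucleotide
#'   variants planted into a fraction of a mature miRNA's reads.
#' @param n_hairpins Number of miRNA hairpins to generate in the reference.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed,
                       read_length = 36L,
                       barcode_map = NULL,
                       adapter = DEFAULT_ADAPTER,
                       samples = default_samples(),
                       reads_per_sample = 1000L,
                       composition = default_composition(),
                       pingpong = list(pair_fraction = 0.9, overlap_nt = 10L,
                                       u1_bias = 0.9, a10_bias = 0.9),
                       sirna_length = 21L,
                       pirna_length_range = c(23L, 29L),
                       sirna_fraction = 0.5,
                       planted_variants = NULL,
                       n_hairpins = 20L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  sample_ids <- paste(samples$stage, samples$fraction, sep = "_")
  if (anyDuplicated(sample_ids))
    stop("duplicated stage/fraction combinations in `samples`")
  if (is.null(barcode_map)) {
    if (length(sample_ids) > length(DEFAULT_BARCODES))
      stop("more samples than built-in barcodes; supply `barcode_map`")
    barcode_map <- setNames(DEFAULT_BARCODES[seq_along(sample_ids)],
                            sample_ids)
  }
  if (!setequal(names(barcode_map), sample_ids))
    stop("`barcode_map` names must match the sample ids (stage_fraction)")
  barcode_map <- barcode_map[sample_ids]
  if (length(unique(nchar(barcode_map))) != 1L)
    stop("all barcodes must have equal length")
  if (anyDuplicated(barcode_map))
    stop("duplicate barcodes in `barcode_map`")

  if (!is.list(composition))
    composition <- setNames(rep(list(composition), length(sample_ids)),
                            sample_ids)
  if (!all(sample_ids %in% names(composition)))
    stop("composition must be defined for every sample")
  for (s in sample_ids) {
    p <- composition[[s]]
    ## "miRNA" draws mature-miRNA reads (annotated via their hairpins)
    valid <- c(CATEGORY_ORDER, "miRNA")
    if (!all(names(p) %in% valid))
      stop("unknown category in composition: ",
           paste(setdiff(names(p), valid), collapse = ", "))
    if (abs(sum(p) - 1) > 1e-9)
      stop("composition for sample ", s, " does not sum to 1")
  }

  pp <- utils::modifyList(list(pair_fraction = 0.9, overlap_nt = 10L,
                               u1_bias = 0.9, a10_bias = 0.9), pingpong)
  if (pp$overlap_nt >= pirna_length_range[1L])
    stop("pingpong overlap_nt must be smaller than the minimum piRNA length")
  if (pp$pair_fraction < 0 || pp$pair_fraction > 1)
    stop("pair_fraction must lie in [0, 1]")

  cfg <- list(seed = as.integer(seed), read_length = as.integer(read_length),
              barcode_map = barcode_map, adapter = adapter,
              samples = samples, sample_ids = sample_ids,
              reads_per_sample = as.integer(reads_per_sample),
              composition = composition, pingpong = pp,
              sirna_length = as.integer(sirna_length),
              pirna_length_range = as.integer(pirna_length_range),
              sirna_fraction = sirna_fraction,
              planted_variants = planted_variants,
              n_hairpins = as.integer(n_hairpins))
  class(cfg) <- "sim_config"
  cfg
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1L))
}

revcomp <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}

#' Generate a synthetic reference collection
#'
#' Deterministically generates named reference sequences for each of the ten
#' annotation categories, mature-miRNA coordinates within their hairpins
#' (with genomic cluster ids), a repeat-family collection for exact remapping
#' of transposon reads, and piRNA-cluster intervals on a miniature two-contig
#' genome. Coordinates are 1-based closed internally; BED output is 0-based
#' half-open.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `ReferenceSet`: a list with elements
#'   `categories` (named list of [Biostrings::DNAStringSet] in hierarchy
#'   order), `mature` (data frame: name, hairpin, start, end, cluster),
#'   `clusters` (data frame: contig, start, end; 1-based closed),
#'   `repeat_families` and `genome`.
#' @export
build_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  lens <- list(rRNA = 300L, miRNA_hairpin = 90L, tRNA = 72L, miscRNA = 150L,
               ncRNA = 200L, transposon = 400L, transcript = 400L,
               intron = 250L, pseudogene = 250L, intergenic = 4000L)
  counts <- list(rRNA = 3L, miRNA_hairpin = config$n_hairpins, tRNA = 8L,
                 miscRNA = 3L, ncRNA = 3L, transposon = 6L, transcript = 8L,
                 intron = 4L, pseudogene = 3L, intergenic = 2L)
  if (any(unlist(lens) < 29L))
    stop("reference sequences must be at least 29 nt (maximum insert length)")

  cats <- vector("list", length(CATEGORY_ORDER))
  names(cats) <- CATEGORY_ORDER
  for (cat in CATEGORY_ORDER) {
    seqs <- random_dna(counts[[cat]], lens[[cat]])
    nm <- switch(cat,
                 rRNA = paste0("rRNA_", seq_along(seqs)),
                 miRNA_hairpin = sprintf("syn-mir-%d", seq_along(seqs)),
                 tRNA = paste0("tRNA_", seq_along(seqs)),
                 transposon = paste0("TE_", seq_along(seqs)),
                 intergenic = paste0("contig_", seq_along(seqs)),
                 paste0(cat, "_", seq_along(seqs)))
    if (cat == "tRNA")  # mature tRNAs carry the post-transcriptional CCA tail
      seqs <- paste0(seqs, "CCA")
    cats[[cat]] <- setNames(DNAStringSet(seqs), nm)
  }

  all_seq <- unlist(lapply(cats, as.character), use.names = FALSE)
  if (anyDuplicated(all_seq))
    stop("generated reference sequences are not mutually distinct")

  ## mature miRNAs: one 22-nt window per hairpin; first six hairpins form two
  ## genomic clusters of three (co-transcribed cluster members), rest singletons
  hp <- cats$miRNA_hairpin
  n_hp <- length(hp)
  start <- sample(10:60, n_hp, replace = TRUE)
  mature <- data.frame(
    name = sprintf("syn-miR-%d-5p", seq_len(n_hp)),
    hairpin = names(hp),
    start = start,
    end = start + 21L,
    cluster = c(rep(c("mcl_1", "mcl_2"), each = min(3L, n_hp)),
                paste0("solo_", seq_len(max(0L, n_hp - 6L))))[seq_len(n_hp)],
    stringsAsFactors = FALSE
  )

  clusters <- data.frame(
    contig = c("contig_1", "contig_2"),
    start = c(501L, 1001L),
    end = c(2500L, 3000L),
    stringsAsFactors = FALSE
  )

  ref <- list(categories = cats,
              mature = mature,
              clusters = clusters,
              repeat_families = setNames(cats$transposon,
                                         paste0("family_",
                                                seq_along(cats$transposon))),
              genome = cats$intergenic)
  class(ref) <- "ReferenceSet"
  ref
}

mature_sequence <- function(ref, name) {
  m <- ref$mature[ref$mature$name == name, , drop = FALSE]
  substr(as.character(ref$categories$miRNA_hairpin[[m$hairpin]]),
         m$start, m$end)
}

## Internal: ping-pong-positioned piRNA-like reads on one reference sequence.
## Initiators are plus-strand with 5' at p; the responder's 5' genomic
## coordinate is q = p + overlap - 1 (minus strand), so the 5'-5' offset
## q - p + 1 equals the configured overlap.
pingpong_reads <- function(refname, refseq, n_total, pp, len_range,
                           id_prefix = "pp") {
  w <- nchar(refseq)
  lmax <- len_range[2L]
  if (pp$overlap_nt >= len_range[1L])
    stop("overlap_nt must be smaller than the minimum read length")
  n_paired <- round(pp$pair_fraction * n_total)
  n_pairs <- floor(n_paired / 2)
  n_bg <- n_total - 2L * n_pairs

  out <- list()
  if (n_pairs > 0L) {
    L1 <- sample(seq(len_range[1L], len_range[2L]), n_pairs, replace = TRUE)
    L2 <- sample(seq(len_range[1L], len_range[2L]), n_pairs, replace = TRUE)
    p <- sample(seq(lmax, w - lmax), n_pairs, replace = TRUE)
    q <- p + pp$overlap_nt - 1L
    ini <- substr(rep(refseq, n_pairs), p, p + L1 - 1L)
    res <- revcomp(substr(rep(refseq, n_pairs), q - L2 + 1L, q))
    ## position 1 of initiators is U(T) with probability u1_bias exactly;
    ## non-U draws are forced off U so the planted frequency is calibrated
    force_u1 <- runif(n_pairs) < pp$u1_bias
    substr(ini, 1L, 1L) <- ifelse(force_u1, "T",
                                  sample(c("A", "C", "G"), n_pairs,
                                         replace = TRUE))
    force_a10 <- runif(n_pairs) < pp$a10_bias
    substr(res, 10L, 10L) <- ifelse(force_a10, "A",
                                    sample(c("C", "G", "T"), n_pairs,
                                           replace = TRUE))
    ini_id <- sprintf("%s_i%06d", id_prefix, seq_len(n_pairs))
    res_id <- sprintf("%s_r%06d", id_prefix, seq_len(n_pairs))
    out$pairs <- data.frame(
      read_id = c(ini_id, res_id),
      reference = refname,
      pos5 = c(p, q),
      strand = rep(c("+", "-"), each = n_pairs),
      length = c(L1, L2),
      sequence = c(ini, res),
      role = rep(c("initiator", "responder"), each = n_pairs),
      partner = c(res_id, ini_id),
      stringsAsFactors = FALSE
    )
  }
  if (n_bg > 0L) {
    Lb <- sample(seq(len_range[1L], len_range[2L]), n_bg, replace = TRUE)
    sb <- sample(c("+", "-"), n_bg, replace = TRUE)
    pos_start <- sample(seq(1L, w - lmax), n_bg, replace = TRUE)
    seq_fwd <- substr(rep(refseq, n_bg), pos_start, pos_start + Lb - 1L)
    sq <- ifelse(sb == "+", seq_fwd, revcomp(seq_fwd))
    pos5 <- ifelse(sb == "+", pos_start, pos_start + Lb - 1L)
    out$bg <- data.frame(
      read_id = sprintf("%s_b%06d", id_prefix, seq_len(n_bg)),
      reference = refname, pos5 = pos5, strand = sb, length = Lb,
      sequence = sq, role = "background", partner = NA_character_,
      stringsAsFactors = FALSE
    )
  }
  df <- do.call(rbind, out)
  if (is.null(df))
    df <- data.frame(read_id = character(), reference = character(),
                     pos5 = integer(), strand = character(),
                     length = integer(), sequence = character(),
                     role = character(), partner = character(),
                     stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

#' Simulate piRNA-like reads with ping-pong geometry
#'
#' Generates positioned, stranded piRNA-length reads on a transposon
#' reference. A fraction `pair_fraction` of reads is emitted as
#' initiator/responder pairs whose 5' ends overlap by exactly `overlap_nt`
#' (the ping-pong signature); initiators carry U(T) at position 1 with
#' probability `u1_bias` and responders carry A at position 10 with
#' probability `a10_bias`. Remaining reads are placed uniformly on both
#' strands.
#'
#' @param ref A `ReferenceSet` from [build_reference()].
#' @param config A [sim_config()] object; `reads_per_sample` sets the total
#'   number of reads and `pingpong` the geometry.
#' @param reference Name of the transposon reference to place reads on
#'   (default the first one).
#' @return A list with `reads` (data frame: read_id, reference, pos5 [1-based
#'   5' coordinate], strand, length, sequence, role, partner) and `truth`
#'   (per-read ground truth).
#' @export
simulate_pingpong <- function(ref, config, reference = NULL) {
  stopifnot(inherits(ref, "ReferenceSet"), inherits(config, "sim_config"))
  set.seed(config$seed + 1999L)
  if (is.null(reference)) reference <- names(ref$categories$transposon)[1L]
  refseq <- as.character(ref$categories$transposon[[reference]])
  reads <- pingpong_reads(reference, refseq, config$reads_per_sample,
                          config$pingpong, config$pirna_length_range)
  truth <- data.frame(
    read_id = reads$read_id, sample = NA_character_, category = "transposon",
    source = reads$reference, strand = reads$strand, insert = reads$sequence,
    size_class = as.character(partition_by_size(reads$length,
                                                config$sirna_length,
                                                config$pirna_length_range)),
    partner = reads$partner, stringsAsFactors = FALSE
  )
  list(reads = reads, truth = truth)
}

## Internal: draw one sample's inserts with ground-truth provenance.
draw_inserts <- function(ref, config, sample_id, n) {
  comp <- config$composition[[sample_id]]
  categories <- sample(names(comp), n, replace = TRUE, prob = comp)
  insert <- character(n); src <- character(n); strand <- rep("+", n)
  partner_row <- rep(NA_integer_, n)  # resolved to read ids by the caller

  idx_by_cat <- split(seq_len(n), factor(categories, levels = names(comp)))
  for (cat in names(idx_by_cat)) {
    idx <- idx_by_cat[[cat]]
    k <- length(idx)
    if (k == 0L) next
    if (cat == "miRNA") {
      pick <- sample(nrow(ref$mature), k, replace = TRUE)
      insert[idx] <- vapply(pick, function(i)
        mature_sequence(ref, ref$mature$name[i]), character(1L))
      src[idx] <- ref$mature$name[pick]
      pv <- config$planted_variants
      if (!is.null(pv)) {
        for (v in seq_len(nrow(pv))) {
          hit <- idx[src[idx] == pv$mirna[v]]
          hit <- hit[runif(length(hit)) < pv$fraction[v]]
          if (length(hit)) substr(insert[hit], pv$position[v],
                                  pv$position[v]) <- pv$alt[v]
        }
      }
    } else if (cat == "tRNA") {
      ## tRFs: 3'-terminal fragments of CCA-appended mature tRNAs
      seqs <- ref$categories$tRNA
      pick <- sample(length(seqs), k, replace = TRUE)
      L <- sample(15:29, k, replace = TRUE)
      full <- as.character(seqs[pick])
      insert[idx] <- substr(full, nchar(full) - L + 1L, nchar(full))
      src[idx] <- names(seqs)[pick]
    } else if (cat == "transposon") {
      is_si <- runif(k) < config$sirna_fraction
      seqs <- ref$categories$transposon
      if (any(is_si)) {
        m <- sum(is_si)
        pick <- sample(length(seqs), m, replace = TRUE)
        w <- nchar(as.character(seqs[pick]))
        st <- vapply(w, function(wi)
          sample(seq_len(wi - config$sirna_length + 1L), 1L), integer(1L))
        frag <- substr(as.character(seqs[pick]), st,
                       st + config$sirna_length - 1L)
        sb <- sample(c("+", "-"), m, replace = TRUE)
        frag[sb == "-"] <- revcomp(frag[sb == "-"])
        insert[idx[is_si]] <- frag
        src[idx[is_si]] <- names(seqs)[pick]
        strand[idx[is_si]] <- sb
      }
      if (any(!is_si)) {
        m <- sum(!is_si)
        pp <- pingpong_reads(names(seqs)[1L], as.character(seqs[[1L]]), m,
                             config$pingpong, config$pirna_length_range,
                             id_prefix = sample_id)
        insert[idx[!is_si]] <- pp$sequence
        src[idx[!is_si]] <- pp$reference
        strand[idx[!is_si]] <- pp$strand
        pidx <- match(pp$partner, pp$read_id)
        partner_row[idx[!is_si]] <- idx[!is_si][pidx]
      }
    } else if (cat == "intergenic") {
      ## mostly cluster-derived (dual-strand), remainder anywhere on the genome
      cl <- ref$clusters
      from_cl <- runif(k) < 0.8
      L <- sample(23:29, k, replace = TRUE)
      ci <- sample(nrow(cl), k, replace = TRUE)
      st <- integer(k); contig <- character(k)
      for (j in seq_len(k)) {
        if (from_cl[j]) {
          contig[j] <- cl$contig[ci[j]]
          st[j] <- sample(seq(cl$start[ci[j]], cl$end[ci[j]] - L[j]), 1L)
        } else {
          contig[j] <- sample(names(ref$genome), 1L)
          st[j] <- sample(seq_len(nchar(as.character(
            ref$genome[[contig[j]]])) - L[j]), 1L)
        }
      }
      frag <- vapply(seq_len(k), function(j)
        substr(as.character(ref$genome[[contig[j]]]), st[j],
               st[j] + L[j] - 1L), character(1L))
      sb <- ifelse(from_cl, sample(c("+", "-"), k, replace = TRUE), "+")
      frag[sb == "-"] <- revcomp(frag[sb == "-"])
      insert[idx] <- frag
      src[idx] <- contig
      strand[idx] <- sb
    } else {
      ## rRNA / miscRNA / ncRNA / transcript / intron / pseudogene fragments
      seqs <- ref$categories[[cat]]
      pick <- sample(length(seqs), k, replace = TRUE)
      L <- sample(15:29, k, replace = TRUE)
      w <- nchar(as.character(seqs[pick]))
      st <- vapply(seq_len(k), function(j)
        sample(seq_len(w[j] - L[j] + 1L), 1L), integer(1L))
      insert[idx] <- substr(as.character(seqs[pick]), st, st + L - 1L)
      src[idx] <- names(seqs)[pick]
    }
  }
  data.frame(category = categories, source = src, strand = strand,
             insert = insert, partner_row = partner_row,
             stringsAsFactors = FALSE)
}

#' Simulate a multiplexed small-RNA library
#'
#' Emits raw multiplexed reads for every configured sample. Each read is the
#' sample barcode, followed by the insert, followed by as much of the 3'
#' adapter as fits, truncated (or A-padded) to `read_length`. Every read has
#' exactly one ground-truth record giving its sample, category, source
#' sequence, strand, intended insert and size class.
#'
#' @param ref A `ReferenceSet` from [build_reference()].
#' @param config A [sim_config()] object.
#' @return A list with `reads` (data frame: read_id, sequence) and `truth`
#'   (data frame: read_id, sample, category, source, strand, insert,
#'   size_class, partner).
#' @export
simulate_library <- function(ref, config) {
  stopifnot(inherits(ref, "ReferenceSet"), inherits(config, "sim_config"))
  set.seed(config$seed + 7919L)
  bl <- nchar(config$barcode_map[[1L]])
  max_insert <- config$read_length - bl
  per_sample <- lapply(config$sample_ids, function(s) {
    n <- config$reads_per_sample
    if (n == 0L) return(NULL)
    d <- draw_inserts(ref, config, s, n)
    if (any(nchar(d$insert) > max_insert))
      stop("insert longer than read_length minus barcode length")
    d$sample <- s
    d$read_id <- sprintf("%s_read%06d", s, seq_len(n))
    d$partner <- ifelse(is.na(d$partner_row), NA_character_,
                        d$read_id[d$partner_row])
    d$partner_row <- NULL
    d
  })
  truth <- do.call(rbind, per_sample)
  if (is.null(truth)) {
    empty <- data.frame(read_id = character(), sequence = character(),
                        stringsAsFactors = FALSE)
    return(list(reads = empty,
                truth = data.frame(read_id = character(),
                                   sample = character(),
                                   category = character(),
                                   source = character(), strand = character(),
                                   insert = character(),
                                   size_class = character(),
                                   partner = character(),
                                   stringsAsFactors = FALSE)))
  }
  rownames(truth) <- NULL
  bc <- config$barcode_map[truth$sample]
  body <- paste0(bc, truth$insert, config$adapter)
  short <- nchar(body) < config$read_length
  if (any(short))
    body[short] <- paste0(body[short],
                          strrep("A", config$read_length - nchar(body[short])))
  seqs <- substr(body, 1L, config$read_length)
  ord <- sample(nrow(truth))  # pool the samples as a multiplexed run
  reads <- data.frame(read_id = truth$read_id[ord], sequence = seqs[ord],
                      stringsAsFactors = FALSE)
  truth$size_class <- as.character(partition_by_size(
    nchar(truth$insert), config$sirna_length, config$pirna_length_range))
  truth <- truth[, c("read_id", "sample", "category", "source", "strand",
                     "insert", "size_class", "partner")]
  list(reads = reads, truth = truth)
}

#' Write simulated reads as FASTQ
#'
#' Writes multiplexed raw reads with a uniform dummy quality of "I".
#'
#' @param reads Data frame with `read_id` and `sequence`.
#' @param path Output FASTQ path.
#' @return Invisibly, the path.
#' @export
write_library_fastq <- function(reads, path) {
  x <- setNames(DNAStringSet(reads$sequence), reads$read_id)
  qual <- BStringSet(strrep("I", nchar(reads$sequence)))
  writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read a FASTQ file into a read table
#'
#' @param path FASTQ path.
#' @return Data frame with `read_id` and `sequence`.
#' @export
read_library_fastq <- function(path) {
  x <- readDNAStringSet(path, format = "fastq")
  data.frame(read_id = names(x), sequence = as.character(x),
             stringsAsFactors = FALSE)
}

#' Write reference categories as per-category FASTA files
#'
#' @param ref A `ReferenceSet`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_reference_fasta <- function(ref, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- vapply(names(ref$categories), function(cat) {
    f <- file.path(dir, paste0(cat, ".fa"))
    writeXStringSet(ref$categories[[cat]], f)
    f
  }, character(1L))
  invisible(files)
}

#' Write piRNA-cluster intervals as 3-column BED
#'
#' Internal coordinates are 1-based closed; BED output is 0-based half-open.
#'
#' @param ref A `ReferenceSet`.
#' @param path Output BED path.
#' @return Invisibly, the path.
#' @export
write_clusters_bed <- function(ref, path) {
  bed <- data.frame(ref$clusters$contig, ref$clusters$start - 1L,
                    ref$clusters$end)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read piRNA-cluster intervals from a 3-column BED file
#'
#' @param path BED path (0-based half-open).
#' @return Data frame with `contig`, `start`, `end` (1-based closed).
#' @export
read_clusters_bed <- function(path) {
  bed <- read.delim(path, header = FALSE,
                    col.names = c("contig", "start", "end"))
  data.frame(contig = as.character(bed$contig), start = bed$start + 1L,
             end = bed$end, stringsAsFactors = FALSE)
}

#' Write ground truth as TSV
#'
#' @param truth Ground-truth data frame from [simulate_library()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_ground_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
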