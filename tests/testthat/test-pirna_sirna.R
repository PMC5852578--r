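test_that("size classes split 21-nt siRNAs from 23-29-nt piRNAs", {
  cls <- partition_by_size(c(15, 20, 21, 22, 23, 26, 29))
  expect_identical(as.character(cls),
                   c("other", "other", "siRNA", "other", "piRNA", "piRNA",
                     "piRNA"))
  # classes are disjoint and exhaustive over the retention window
  all_cls <- partition_by_size(15:29)
  expect_false(anyNA(all_cls))
})

test_that("the 5'-5' offset convention scores a 10-nt overlap as 10", {
  reads <- data.frame(reference = "TE_1", pos5 = c(100L, 109L),
                      strand = c("+", "-"), length = c(25L, 24L))
  sp <- pingpong_spectrum(reads)
  expect_equal(sp$count[sp$offset == 10], 1)
  expect_equal(sum(sp$count), 1)

  # reads on a single strand form no pairs
  one <- data.frame(reference = "TE_1", pos5 = c(5L, 50L),
                    strand = c("+", "+"), length = c(25L, 25L))
  expect_equal(sum(pingpong_spectrum(one)$count), 0)

  # 21-nt reads are excluded from the piRNA spectrum
  with_sirna <- rbind(reads,
                      data.frame(reference = "TE_1", pos5 = 109L,
                                 strand = "-", length = 21L))
  expect_equal(sum(pingpong_spectrum(with_sirna)$count), 1)

  expect_error(pingpong_spectrum(data.frame(reference = "x", pos5 = NA,
                                            strand = "+", length = 25L)),
               "position")
})

test_that("spectrum argmax recovers the configured overlap in >=19/20 seeds", {
  hits <- vapply(1:20, function(s) {
    cfg <- one_sample_cfg(seed = 4000 + s, n = 600L,
                          pingpong = list(pair_fraction = 0.5))
    ref <- build_reference(cfg)
    pg <- simulate_pingpong(ref, cfg)
    sp <- pingpong_spectrum(pg$reads)
    sp$offset[which.max(sp$count)] == 10
  }, logical(1))
  expect_gte(sum(hits), 19L)
})

test_that("under the uniform null no offset dominates (flatness over 20 seeds)", {
  exceed <- vapply(1:20, function(s) {
    cfg <- one_sample_cfg(seed = 6000 + s, n = 2000L,
                          pingpong = list(pair_fraction = 0))
    ref <- build_reference(cfg)
    pg <- simulate_pingpong(ref, cfg)
    sp <- pingpong_spectrum(pg$reads)
    f <- sp$count[sp$offset %in% 1:20]
    f[10] > mean(f) + 3 * stats::sd(f)
  }, logical(1))
  expect_lte(sum(exceed), 1L)
})

test_that("the spectrum is invariant under strand swap with mirrored coordinates", {
  cfg <- one_sample_cfg(seed = 41, n = 400L)
  ref <- build_reference(cfg)
  pg <- simulate_pingpong(ref, cfg)
  w <- nchar(as.character(ref$categories$transposon[[1]]))
  swapped <- pg$reads
  swapped$strand <- ifelse(pg$reads$strand == "+", "-", "+")
  swapped$pos5 <- w - pg$reads$pos5 + 1L
  sp <- pingpong_spectrum(pg$reads)
  sp_sw <- pingpong_spectrum(swapped)
  expect_equal(sp_sw$count, sp$count)
})

test_that("multiplicity weighting reduces to raw counts for unique mappers", {
  cfg <- one_sample_cfg(seed = 43, n = 300L)
  ref <- build_reference(cfg)
  pg <- simulate_pingpong(ref, cfg)
  pg$reads$multiplicity <- 1
  sp <- pingpong_spectrum(pg$reads)
  expect_equal(sp$weighted, sp$count)
  # doubling every multiplicity scales pair weights by 1/4
  pg$reads$multiplicity <- 2
  sp2 <- pingpong_spectrum(pg$reads)
  expect_equal(sp2$weighted, sp$count / 4)
})

test_that("positional base frequencies recover the planted 1U/10A biases", {
  expect_equal(unname(base_bias(c("TAGC", "TGCA"), positions = 1)[1, "U"]), 1)
  expect_error(base_bias(character()), "empty")

  cfg <- one_sample_cfg(seed = 47, n = 4500L,
                        pingpong = list(pair_fraction = 1, u1_bias = 0.9,
                                        a10_bias = 0.9))
  ref <- build_reference(cfg)
  pg <- simulate_pingpong(ref, cfg)
  ini <- pg$reads$sequence[pg$reads$role == "initiator"]
  res <- pg$reads$sequence[pg$reads$role == "responder"]
  expect_gte(length(ini), 2000L)
  bb_i <- base_bias(ini)
  bb_r <- base_bias(res)
  expect_lt(abs(bb_i["1", "U"] - 0.9), 0.03)
  expect_lt(abs(bb_r["10", "A"] - 0.9), 0.03)
  # rows are probability distributions
  expect_equal(unname(rowSums(bb_i)), rep(1, 20))

  # uniform random reads have near-uniform base usage
  set.seed(9)
  unif <- vapply(1:2000, function(i)
    paste(sample(c("A", "C", "G", "T"), 25, replace = TRUE), collapse = ""),
    character(1))
  bb_u <- base_bias(unif)
  expect_true(all(abs(bb_u - 0.25) < 0.03))
})

test_that("pair-participation flags mark initiators and responders", {
  reads <- data.frame(reference = "TE_1",
                      pos5 = c(100L, 109L, 300L),
                      strand = c("+", "-", "+"),
                      length = c(25L, 25L, 25L))
  fl <- pingpong_partners(reads, overlap = 10L)
  expect_identical(fl$is_initiator, c(TRUE, FALSE, FALSE))
  expect_identical(fl$is_responder, c(FALSE, TRUE, FALSE))
})

test_that("cluster strand profiles recover designed strand biases", {
  clusters <- data.frame(contig = "contig_1", start = 1001L, end = 3000L)
  # all-plus reads give bias 1
  all_plus <- data.frame(contig = "contig_1",
                         pos5 = seq(1100L, 2900L, by = 100L), strand = "+")
  sp <- strand_profile(all_plus, clusters, bins = 10)
  expect_equal(sp$overall$bias, 1)

  # designed 70/30 split at n = 2000
  set.seed(55)
  n <- 2000L
  reads <- data.frame(contig = "contig_1",
                      pos5 = sample(1001:3000, n, replace = TRUE),
                      strand = sample(c("+", "-"), n, replace = TRUE,
                                      prob = c(0.7, 0.3)))
  sp2 <- strand_profile(reads, clusters, bins = 50)
  expect_lt(abs(sp2$overall$bias - 0.7), 0.03)
  expect_equal(sum(sp2$profile$plus) + sum(sp2$profile$minus), n)

  # reads outside every cluster are ignored but tallied; empty cluster is NA
  outside <- data.frame(contig = "contig_1", pos5 = c(10L, 50L),
                        strand = c("+", "-"))
  sp3 <- strand_profile(outside, clusters, bins = 5)
  expect_identical(sp3$n_outside, 2L)
  expect_true(is.na(sp3$overall$bias))
})

test_that("stage composition recovers designed transposon shares across libraries", {
  mk <- function(seed, tp_share) {
    comp <- c(miRNA = 1 - tp_share - 0.1, transposon = tp_share, rRNA = 0.1)
    cfg <- one_sample_cfg(seed = seed, n = 5000L, composition = comp)
    ref <- build_reference(cfg)
    sim <- simulate_library(ref, cfg)
    data.frame(category = sim$truth$category,
               length = nchar(sim$truth$insert), count = 1)
  }
  sc <- stage_composition(list(early = mk(61, 0.40), late = mk(62, 0.10)))
  expect_lt(abs(sc$pct_transposon[sc$library == "early"] - 40), 2)
  expect_lt(abs(sc$pct_transposon[sc$library == "late"] - 10), 2)
  # size-class shares sum to the transposon total
  expect_equal(sc$pct_sirna + sc$pct_pirna + sc$pct_other_size,
               sc$pct_transposon)

  none <- data.frame(category = "miRNA", length = 22, count = 5)
  sc0 <- stage_composition(list(a = none, b = none))
  expect_equal(sc0$pct_transposon, c(0, 0))
  expect_error(stage_composition(list(only = none)), "two")
})
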