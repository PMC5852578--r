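test_that("mature quantification uses exact hairpin matches within the 5' window", {
  cfg <- one_sample_cfg(seed = 31, n = 10L)
  ref <- build_reference(cfg)
  m <- ref$mature[1, ]
  hp <- as.character(ref$categories$miRNA_hairpin[[m$hairpin]])
  mat <- substr(hp, m$start, m$end)
  shifted <- substr(hp, m$start + 2, m$end + 2)     # +2 isomiR, in window
  outside <- substr(hp, m$start + 5, m$end + 5)     # beyond the 3-nt window
  mm <- mat
  substr(mm, 4, 4) <- setdiff(c("A", "C", "G", "T"), substr(mm, 4, 4))[1]

  rec <- records_from(s1 = c(rep(mat, 3), shifted, outside, mm))
  q <- quantify_mirna(rec, ref, window = 3L)
  expect_equal(unname(q$counts[m$name, "s1"]), 4)   # mature + shifted isomiR
  expect_equal(unname(q$hairpin_counts[m$hairpin, "s1"]), 5)  # + outside
  # the single-substitution read counts nowhere (exact-only quantification)
  expect_equal(sum(q$counts), 4)

  # RPM conservation against the per-sample denominator
  expect_equal(sum(q$rpm[, "s1"]),
               sum(q$counts[, "s1"]) * 1e6 / q$denominators[["s1"]])
})

test_that("low-abundance filtering keeps miRNAs at or above threshold in any sample", {
  rpm <- rbind(low = c(49.9, 49.9), edge = c(50, 0), high = c(200, 10))
  colnames(rpm) <- c("a", "b")
  kept <- filter_low(rpm, threshold = 50)
  expect_identical(rownames(kept), c("edge", "high"))
})

test_that("fold changes follow the pseudocount formula and its bound", {
  rpm <- cbind("0-1h_UF" = c(0, 10, 0), "7-8h_UF" = c(0, 30, 1e6))
  rownames(rpm) <- c("zero", "arith", "extreme")
  fc <- fold_change(rpm, fractions = c(Tot = "UF"))
  expect_equal(fc["zero", "Tot"], 0)        # log2(10/10)
  expect_equal(fc["arith", "Tot"], 1)       # log2(40/20)
  bound <- log2((1e6 + 10) / 10)
  expect_lt(abs(fc["extreme", "Tot"]), bound + 1e-12)
  expect_error(fold_change(cbind("0-1h_UF" = -1, "7-8h_UF" = 1)), "negative")
})

test_that("the four-group classifier reproduces curated example rows", {
  fc <- data.frame(
    miRNA = c("dme-miR-286-3p", "dme-miR-9a-5p", "dme-miR-306-5p",
              "dme-miR-1-3p", "dme-miR-981-3p"),
    Tot = c(2.6, 0.8, -5.1, -1.5, 1.0),
    mRNP = c(3.1, 0.5, -5.2, 0.2, -1.9),
    "60S" = c(2.2, 1.9, -0.6, 2.2, -0.1),
    "80S" = c(2.1, 1.5, -0.8, 1.2, 0.6),
    Poly = c(1.6, 3.3, -1.1, 3.8, 0.4),
    check.names = FALSE)
  g <- classify_groups(fc, tau = 1.0)
  expect_identical(as.character(g$group), c("G1", "G2", "G3", "G4", "G4"))
  expect_error(classify_groups(fc[, -2]), "Tot")
})

test_that("group labels partition the packaged fold-change table", {
  tab <- read_foldchange_table()
  g <- classify_groups(tab)
  expect_identical(nrow(g), nrow(tab))
  expect_false(anyNA(g$group))
  expect_identical(sum(table(g$group)), nrow(tab))
})

test_that("abundance panels are unions of per-sample top-k hairpins", {
  shares <- matrix(c(50, 30, 20, 50, 30, 20), ncol = 2,
                   dimnames = list(c("h1", "h2", "h3"), c("a", "b")))
  p <- abundance_panel(shares, k = 3)
  expect_identical(p$panel, c("h1", "h2", "h3"))
  expect_equal(unname(p$coverage), c(100, 100))

  disjoint <- matrix(c(9, 1, 0, 0, 0, 0, 1, 9), ncol = 2,
                     dimnames = list(paste0("h", 1:4), c("a", "b")))
  p2 <- abundance_panel(disjoint, k = 2)
  expect_identical(length(p2$panel), 4L)

  # designed high-share set dominates the panel
  set.seed(5)
  sh <- matrix(runif(30 * 4, 0, 1), 30, 4,
               dimnames = list(paste0("h", 1:30), paste0("s", 1:4)))
  sh[1:5, ] <- sh[1:5, ] + 50
  p3 <- abundance_panel(sh, k = 5)
  expect_identical(p3$panel, paste0("h", 1:5))
  expect_error(abundance_panel(sh, k = 0), "positive")
})

test_that("fraction distributions are per-stage percentages over four fractions", {
  samples <- as.vector(outer(c("0-1h", "7-8h"),
                             c("mRNP", "60S", "80S", "Poly"), paste,
                             sep = "_"))
  rpm <- matrix(0, 3, 8, dimnames = list(c("even", "mrnp", "zero"), samples))
  rpm["even", paste0("0-1h_", c("mRNP", "60S", "80S", "Poly"))] <- 10
  rpm["mrnp", "0-1h_mRNP"] <- 42
  fd <- fraction_distribution(rpm)
  e <- fd[fd$miRNA == "even" & fd$stage == "0-1h", ]
  expect_equal(unlist(e[c("mRNP", "60S", "80S", "Poly")], use.names = FALSE),
               rep(25, 4))
  m <- fd[fd$miRNA == "mrnp" & fd$stage == "0-1h", ]
  expect_equal(unlist(m[c("mRNP", "60S", "80S", "Poly")], use.names = FALSE),
               c(100, 0, 0, 0))
  expect_false(fd$defined[fd$miRNA == "zero" & fd$stage == "0-1h"])

  # a designed 60/20/10/10 split is recovered from multinomial read sampling
  set.seed(8)
  counts <- as.vector(stats::rmultinom(1, 2000, c(0.6, 0.2, 0.1, 0.1)))
  rpm2 <- matrix(0, 1, 8, dimnames = list("x", samples))
  rpm2[1, paste0("0-1h_", c("mRNP", "60S", "80S", "Poly"))] <- counts
  fd2 <- fraction_distribution(rpm2)
  got <- unlist(fd2[fd2$stage == "0-1h", c("mRNP", "60S", "80S", "Poly")],
                use.names = FALSE)
  expect_true(all(abs(got - c(60, 20, 10, 10)) < 2))
})

test_that("cluster co-sedimentation separates designed co-expression profiles", {
  v <- c(100, 0, 0, 0)
  profiles <- rbind(a1 = v, a2 = v, b1 = c(0, 100, 0, 0),
                    b2 = c(0, 100, 0, 0))
  cl <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  cs <- cluster_cosedimentation(profiles, cl)
  expect_equal(cs$within, 0)                     # identical within clusters
  expect_equal(cs$between, 100 * sqrt(2))        # orthogonal profiles
  expect_lt(cs$separation, 0)
  expect_s3_class(cs$hclust, "hclust")

  # noisy designed profiles: within still below between
  set.seed(12)
  noisy <- profiles + matrix(runif(16, 0, 5), 4, 4)
  cs2 <- cluster_cosedimentation(noisy, cl)
  expect_lt(cs2$within, cs2$between)

  solo <- cluster_cosedimentation(profiles, c(a1 = "A", b1 = "B"))
  expect_true(solo$undefined)
  expect_true(is.na(solo$separation))
})

test_that("planted single-substitution variants surface as editing candidates", {
  mature <- c(mirX = "TGAGGTAGTAGGTTGTATAGTT", mirY = "ACCCGTAGATCCGAACTTGTGA")
  ref_base <- substr(mature[["mirX"]], 11, 11)
  alt_base <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  variant <- mature[["mirX"]]
  substr(variant, 11, 11) <- alt_base  # planted substitution at position 11

  rec <- records_from(s1 = c(rep(mature[["mirX"]], 70), rep(variant, 30),
                             rep(mature[["mirY"]], 50)))
  ec <- editing_candidates(rec, mature, min_fraction = 0.1, min_reads = 10)
  expect_identical(nrow(ec), 1L)
  expect_identical(ec$miRNA, "mirX")
  expect_identical(ec$position, 11L)
  expect_identical(ec$ref, ref_base)
  expect_identical(ec$alt, alt_base)
  expect_equal(ec$fraction, 0.3)

  # sparse random single errors stay below the support thresholds
  set.seed(3)
  errs <- vapply(1:5, function(i) {
    x <- mature[["mirY"]]
    p <- sample(nchar(x), 1)
    substr(x, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                      substr(x, p, p)), 1)
    x
  }, character(1))
  rec2 <- records_from(s1 = c(rep(mature[["mirY"]], 1000), errs))
  expect_identical(nrow(editing_candidates(rec2, mature)), 0L)

  # no mismatched reads at all
  rec3 <- records_from(s1 = rep(mature[["mirX"]], 5))
  expect_identical(nrow(editing_candidates(rec3, mature)), 0L)
})
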