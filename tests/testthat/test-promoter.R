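test_that("beta value is the Methy/(Methy+Unmethy) ratio with 0/0 missing", {
  expect_equal(compute_beta(30, 10), 0.75)
  expect_equal(compute_beta(0, 50), 0)
  expect_true(is.na(compute_beta(0, 0)))
  expect_equal(compute_beta(c(30, 0, 0), c(10, 50, 0)),
               c(0.75, 0, NA))
  expect_error(compute_beta(-1, 2))
})

test_that("missing-value filter is strict at 30% and imputes probe means", {
  m <- matrix(stats::runif(300), 3, 100,
              dimnames = list(c("p31", "p30", "p0"),
                              sprintf("s%d", 1:100)))
  m["p31", 1:31] <- NA
  m["p30", 1:30] <- NA
  out <- filter_and_impute(m)
  expect_identical(rownames(out), c("p30", "p0"))
  expect_false(anyNA(out))
  expect_equal(out["p30", 1], mean(m["p30", 31:100]))

  # mean imputation in isolation (filter relaxed so the probe survives)
  v <- matrix(c(0.2, NA, 0.4), 1, dimnames = list("p", c("a", "b", "c")))
  expect_equal(filter_and_impute(v, max_missing_frac = 0.4)[1, "b"], 0.3,
               ignore_attr = TRUE)
})

test_that("filter_and_impute is idempotent", {
  set.seed(5)
  m <- matrix(stats::runif(200), 10, 20,
              dimnames = list(sprintf("p%d", 1:10), sprintf("s%d", 1:20)))
  m[sample(length(m), 30)] <- NA
  once <- filter_and_impute(m)
  expect_identical(filter_and_impute(once), once)
})

test_that("promoters are strand-aware 2 kb windows clipped at zero", {
  ann <- data.frame(feature_id = c("a", "b", "c"),
                    feature_name = c("a", "b", "c"), chrom = "chr1",
                    start = c(10000L, 5000L, 500L),
                    end = c(12000L, 10000L, 2000L),
                    strand = c("+", "-", "+"), biotype = "lncRNA",
                    tss = c(10000L, 10000L, 500L),
                    stringsAsFactors = FALSE)
  ps <- define_promoters(ann)
  expect_equal(ps$start, c(8000L, 10000L, 0L))
  expect_equal(ps$end, c(10000L, 12000L, 500L))
})

test_that("probe mapping uses half-open containment and multi-assignment", {
  ps <- define_promoters(data.frame(
    feature_id = c("a", "b"), feature_name = c("a", "b"), chrom = "chr1",
    start = c(10000L, 11000L), end = c(15000L, 16000L),
    strand = c("+", "-"), biotype = "lncRNA",
    tss = c(10000L, 11000L), stringsAsFactors = FALSE))
  # promoters: a = [8000, 10000), b = [11000, 13000)
  man <- data.frame(probe_id = c("p1", "p2", "p3"), chrom = "chr1",
                    pos = c(9000L, 10000L, 12000L),
                    stringsAsFactors = FALSE)
  ps <- map_probes(ps, man)
  expect_equal(ps$probes[[1]], "p1")      # 10000 excluded (half-open)
  expect_equal(ps$probes[[2]], "p3")

  # overlapping promoters share a probe
  ps2 <- define_promoters(data.frame(
    feature_id = c("x", "y"), feature_name = c("x", "y"), chrom = "chr1",
    start = c(9000L, 9500L), end = c(12000L, 12500L), strand = "+",
    biotype = "lncRNA", tss = c(9000L, 9500L), stringsAsFactors = FALSE))
  ps2 <- map_probes(ps2, data.frame(probe_id = "p", chrom = "chr1",
                                    pos = 8000L, stringsAsFactors = FALSE))
  expect_equal(lengths(ps2$probes), c(1L, 1L))
})

test_that("probe mapping agrees with the brute-force interval scan", {
  set.seed(3)
  ann <- data.frame(feature_id = sprintf("l%02d", 1:40),
                    feature_name = sprintf("l%02d", 1:40), chrom = "chr1",
                    start = 0L, end = 0L,
                    strand = sample(c("+", "-"), 40, TRUE),
                    biotype = "lncRNA",
                    tss = sample.int(100000, 40), stringsAsFactors = FALSE)
  ann$start <- pmax(0L, ann$tss - 1000L); ann$end <- ann$tss + 1000L
  ps <- define_promoters(ann)
  man <- data.frame(probe_id = sprintf("p%03d", 1:500), chrom = "chr1",
                    pos = sample.int(110000, 500), stringsAsFactors = FALSE)
  got <- map_probes(ps, man)$probes
  want <- oracle_map(ps, man)
  expect_equal(lapply(got, sort), lapply(want, sort))
})

test_that("promoter level is the unweighted probe mean, order-invariant, in [0,1]", {
  beta <- matrix(c(0.2, 0.4, 0.6, 0.1, 0.3, 0.5), 3,
                 dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
  ps <- define_promoters(data.frame(
    feature_id = c("a", "b", "c"), feature_name = c("a", "b", "c"),
    chrom = "chr1", start = c(3000L, 6000L, 9000L),
    end = c(7000L, 10000L, 13000L), strand = "+", biotype = "lncRNA",
    tss = c(3000L, 6000L, 9000L), stringsAsFactors = FALSE))
  ps$probes <- list(c("p1", "p2"), "p3", character())
  prof <- promoter_level(beta, ps)
  # brute-force mean oracle
  expect_equal(prof["a", ], c(s1 = mean(c(0.2, 0.4)), s2 = mean(c(0.1, 0.3))))
  expect_equal(prof["b", ], beta["p3", ])        # single probe
  expect_false("c" %in% rownames(prof))          # no probes -> dropped
  expect_equal(attr(prof, "n_dropped"), 1L)
  ps$probes[[1]] <- c("p2", "p1")
  expect_equal(promoter_level(beta, ps)["a", ], prof["a", ])
  expect_true(all(prof >= 0 & prof <= 1))
})

test_that("K-S statistic matches explicit step-function enumeration", {
  prof <- rbind(l1 = c(0.1, 0.2), l2 = c(0.5, 0.6), l3 = c(0.9, 0.85))
  colnames(prof) <- c("t1", "n1")
  samples <- data.frame(sample_id = c("t1", "n1"),
                        group = c("tumor", "normal"),
                        stringsAsFactors = FALSE)
  ks <- ks_compare(prof, samples)
  expect_equal(ks$D, oracle_ks_D(prof[, "t1"], prof[, "n1"]))

  # identical distributions -> D = 0, p = 1
  prof2 <- cbind(prof, prof)
  colnames(prof2) <- c("t1", "t2", "n1", "n2")
  samples2 <- data.frame(sample_id = colnames(prof2),
                         group = c("tumor", "tumor", "normal", "normal"),
                         stringsAsFactors = FALSE)
  ks2 <- ks_compare(prof2, samples2)
  expect_equal(ks2$D, 0)
  expect_equal(ks2$p, 1)

  # disjoint supports -> D = 1
  a <- c(0.1, 0.2); b <- c(0.8, 0.9)
  expect_equal(oracle_ks_D(a, b), 1)
  expect_equal(unname(suppressWarnings(
    stats::ks.test(a, b, exact = FALSE)$statistic)), 1)
})
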