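test_that("config validation enforces the documented invariants", {
  expect_s3_class(simulation_config(), "sim_config")
  expect_error(simulation_config(delta_beta = 1.2))
  expect_error(simulation_config(censor_rate = 1))
  expect_error(simulation_config(n_planted = c(high_up = 100,
                                               high_down = 100,
                                               low_up = 100,
                                               low_down = 100)))
  expect_error(simulation_config(n_tumor = 1))
})

test_that("annotation generation is deterministic and strand-consistent", {
  cfg <- simulation_config(seed = 42)
  a1 <- simulate_annotation(cfg)
  a2 <- simulate_annotation(cfg)
  expect_identical(a1, a2)

  # minus-strand body [start, end) gives promoter [end, end + 2000)
  minus <- a1$lnc[a1$lnc$strand == "-", ][1, ]
  prom <- define_promoters(minus)
  expect_equal(prom$start, minus$end)
  expect_equal(prom$end, minus$end + 2000L)

  # most promoters carry probes, and some probes fall outside promoters
  proms <- map_probes(define_promoters(a1$lnc), a1$manifest)
  expect_gte(mean(lengths(proms$probes) > 0), 0.85)
  expect_lt(sum(lengths(proms$probes)), nrow(a1$manifest))

  expect_error(simulate_annotation(
    simulation_config(chrom_length = 1000)), "chromosome too short")

  none <- simulate_annotation(simulation_config(n_probe = 0))
  expect_identical(nrow(none$manifest), 0L)
  p0 <- map_probes(define_promoters(none$lnc), none$manifest)
  expect_true(all(lengths(p0$probes) == 0))
})

test_that("changing the probe count does not perturb the expression stream", {
  s1 <- simulate_study(simulation_config(seed = 5))
  s2 <- simulate_study(simulation_config(seed = 5, n_probe = 500))
  expect_identical(s1$lnc_expr, s2$lnc_expr)
  expect_identical(s1$mrna_expr, s2$mrna_expr)
})

test_that("planted methylation shifts are recovered at the configured size", {
  cfg <- simulation_config(seed = 7)
  ann <- simulate_annotation(cfg)
  meth <- simulate_methylation(cfg, ann)
  expect_true(all(meth$beta >= 0 & meth$beta <= 1, na.rm = TRUE))
  expect_equal(mean(is.na(meth$beta)), cfg$missing_rate, tolerance = 0.25)

  proms <- map_probes(define_promoters(ann$lnc), ann$manifest)
  tum <- meth$samples$group == "tumor"
  cls <- meth$truth$lnc_class
  shift_of <- function(classes) {
    ids <- cls$feature_id[cls$class %in% classes]
    probes <- unlist(proms$probes[proms$lncRNA %in% ids])
    b <- meth$beta[probes, , drop = FALSE]
    mean(rowMeans(b[, tum], na.rm = TRUE) -
           rowMeans(b[, !tum], na.rm = TRUE))
  }
  expect_gt(length(unlist(
    proms$probes[proms$lncRNA %in%
                   cls$feature_id[cls$class == "high_down"]])), 50)
  expect_equal(shift_of(c("high_up", "high_down")), cfg$delta_beta,
               tolerance = 0.05)
  expect_equal(shift_of(c("low_up", "low_down")), -cfg$delta_beta,
               tolerance = 0.05)
  expect_equal(shift_of("null"), 0, tolerance = 0.02)
})

test_that("planted expression effects and ceRNA co-expression hold by construction", {
  cfg <- simulation_config(seed = 3, n_tumor = 60)
  ann <- simulate_annotation(cfg)
  meth <- simulate_methylation(cfg, ann)
  expr <- simulate_expression(cfg, ann, meth$truth)
  tum <- startsWith(colnames(expr$lnc_expr), "T")
  cls <- meth$truth$lnc_class
  fc <- function(ids, mat) {
    rowMeans(mat[ids, tum, drop = FALSE]) /
      rowMeans(mat[ids, !tum, drop = FALSE])
  }
  down <- cls$feature_id[cls$class %in% c("high_down", "low_down")]
  up <- cls$feature_id[cls$class %in% c("high_up", "low_up")]
  expect_lt(median(fc(down, expr$lnc_expr)), 0.5)
  expect_gt(median(fc(up, expr$lnc_expr)), 2)

  pairs <- meth$truth$cerna_pairs
  r <- vapply(seq_len(nrow(pairs)), function(i) {
    pearson(log2(expr$lnc_expr[pairs$lncRNA[i], tum] + 1),
            log2(expr$mrna_expr[pairs$mRNA[i], tum] + 1))
  }, numeric(1))
  expect_gt(mean(r > 0), 0.99)            # sign recovery
  expect_equal(median(r), cfg$cerna_cor, tolerance = 0.1)
})

test_that("interaction tables are deduplicated and guarantee planted overlaps", {
  study <- tiny_study(seed = 19)
  ml <- study$interactions$mir_lnc
  mm <- study$interactions$mir_mrna
  expect_identical(anyDuplicated(ml), 0L)
  expect_identical(anyDuplicated(mm), 0L)
  pairs <- study$truth$cerna_pairs
  shared <- vapply(seq_len(nrow(pairs)), function(i) {
    length(intersect(ml$mirna_id[ml$target_id == pairs$lncRNA[i]],
                     mm$mirna_id[mm$target_id == pairs$mRNA[i]]))
  }, integer(1))
  expect_true(all(shared >= study$config$cerna_overlap))
})

test_that("clinical simulation respects the censoring contract", {
  cfg0 <- simulation_config(seed = 9, censor_rate = 0)
  study0 <- simulate_study(cfg0)
  expect_true(all(study0$clinical$event == 1L))
  expect_true(all(study0$clinical$time > 0))

  cfg <- simulation_config(seed = 9, n_tumor = 300, censor_rate = 0.3)
  study <- simulate_study(cfg)
  expect_equal(mean(study$clinical$event == 0), 0.3, tolerance = 0.08)
  expect_identical(study$clinical$sample,
                   study$samples$sample_id[study$samples$group == "tumor"])
})

test_that("null survival coefficients decouple survival from expression", {
  cfg <- simulation_config(seed = 13, n_tumor = 200, survival_beta = 0)
  study <- simulate_study(cfg)
  rm <- module_survival(names(study$truth$survival_beta),
                        study$mrna_expr, study$clinical)
  expect_gt(rm$logrank$p, 0.01)
})

test_that("a full study is byte-identical across runs and round-trips through IO", {
  study <- tiny_study(seed = 23)
  study2 <- tiny_study(seed = 23)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_study(study, d1); p2 <- write_study(study2, d2)
  for (nm in names(p1)) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]),
                     label = nm)
  }
  # reader round-trips
  expect_equal(read_annotation(p1[["lnc_gtf"]]), study$annotation$lnc)
  expect_equal(read_matrix(p1[["beta"]]), study$beta)
  expect_equal(read_matrix(p1[["lnc_expr"]]), study$lnc_expr,
               tolerance = 1e-12)
  got <- read_interactions(p1[["mir_lnc"]], "lncRNA")
  expect_setequal(paste(got$mirna_id, got$target_id),
                  paste(study$interactions$mir_lnc$mirna_id,
                        study$interactions$mir_lnc$target_id))
  clin <- read_clinical(p1[["clinical"]])
  expect_equal(clin$time, study$clinical$time, tolerance = 1e-12)
  expect_equal(read_samples(p1[["samples"]]), study$samples)
})
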