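test_that("raw-moment Pearson matches longhand and the covariance form", {
  expect_equal(pearson(1:5, 2 * (1:5) + 3), 1)
  expect_equal(pearson(1:5, -(1:5)), -1)
  # longhand: n*Sxy - Sx*Sy = 4*29 - 100 = 16; both sds give sqrt(20)
  expect_equal(pearson(c(1, 2, 3, 4), c(1, 3, 2, 4)), 16 / 20)
  expect_true(is.na(pearson(rep(1, 5), 1:5)))

  set.seed(21)
  for (i in 1:50) {
    x <- rnorm(20); y <- rnorm(20)
    expect_equal(pearson(x, y), oracle_pearson(x, y), tolerance = 1e-12)
  }
})

test_that("correlation p-value matches a quadrature oracle of the t density", {
  expect_equal(pearson_pvalue(0, 10), 1)
  expect_equal(pearson_pvalue(1, 10), 0)
  rs <- seq(0.1, 0.9, by = 0.2)
  expect_true(all(diff(pearson_pvalue(rs, 30)) < 0))  # monotone in |r|
  # numerical integration of the t density tail
  r <- 0.5; n <- 30
  tval <- r * sqrt((n - 2) / (1 - r^2))
  dens <- function(x) stats::dt(x, n - 2)
  tail <- stats::integrate(dens, tval, Inf, rel.tol = 1e-10)$value
  expect_equal(pearson_pvalue(r, n), 2 * tail, tolerance = 1e-8)
})

test_that("shared-miRNA hypergeometric matches exhaustive enumeration", {
  expect_equal(shared_mirna_test(c("m1", "m2"), c("m3", "m4"), N = 10)$p, 1)
  r <- shared_mirna_test(c("m1", "m2"), c("m1", "m2"), N = 4)
  expect_equal(r$m, 2L)
  expect_equal(r$p, 1 / 6)   # C(4,2) = 6 draws, one fully overlapping
  r2 <- shared_mirna_test(paste0("m", 1:5), paste0("m", 1:3), N = 5)
  expect_equal(r2$p, 1)      # full-overlap universe
  expect_error(shared_mirna_test(paste0("m", 1:6), "m1", N = 5),
               "universe")
})

test_that("background network equals the brute-force double loop", {
  study <- simulate_study(simulation_config(
    seed = 13, n_tumor = 25, n_normal = 6, n_lnc = 30, n_gene = 40,
    n_mirna = 40, n_probe = 300,
    n_planted = c(high_up = 3, high_down = 3, low_up = 3, low_down = 3),
    module_size = 3, cerna_cor = 0.7))
  samples <- study$samples
  net <- build_background(
    rownames(study$lnc_expr), rownames(study$mrna_expr),
    study$lnc_expr, study$mrna_expr,
    study$interactions$mir_lnc, study$interactions$mir_mrna, samples)

  # independent double loop over all pairs applying all four criteria
  tum <- samples$sample_id[samples$group == "tumor"]
  ml <- study$interactions$mir_lnc; mm <- study$interactions$mir_mrna
  N <- length(union(ml$mirna_id, mm$mirna_id))
  want <- list()
  for (l in sort(rownames(study$lnc_expr))) {
    for (g in sort(rownames(study$mrna_expr))) {
      sl <- ml$mirna_id[ml$target_id == l]
      sg <- mm$mirna_id[mm$target_id == g]
      m <- length(intersect(sl, sg))
      if (m < 1) next
      x <- log2(study$lnc_expr[l, tum] + 1)
      y <- log2(study$mrna_expr[g, tum] + 1)
      r <- pearson(x, y)
      if (is.na(r)) next
      p <- pearson_pvalue(r, length(tum))
      hp <- hypergeom_p(N, length(unique(sl)), length(unique(sg)), m)
      if (r > 0 && p <= 0.01 && m >= 2 && hp <= 0.01) {
        want[[length(want) + 1]] <- data.frame(
          lncRNA = l, mRNA = g, pcc = r, pcc_p = p, shared = m,
          hyper_p = hp, stringsAsFactors = FALSE)
      }
    }
  }
  want <- do.call(rbind, want)
  rownames(want) <- NULL
  expect_gt(nrow(net$edges), 0)   # fixture produces a nonempty network
  expect_equal(net$edges, want)
})

test_that("edge criteria are conjunctive and monotone in the thresholds", {
  study <- tiny_study(seed = 14)
  args <- list(rownames(study$lnc_expr), rownames(study$mrna_expr),
               study$lnc_expr, study$mrna_expr,
               study$interactions$mir_lnc, study$interactions$mir_mrna,
               study$samples)
  strict <- do.call(build_background, args)
  loose <- do.call(build_background,
                   c(args, list(min_shared = 1, pcc_p = 0.05,
                                hyper_p = 0.05)))
  key <- function(n) paste(n$edges$lncRNA, n$edges$mRNA)
  expect_true(all(key(strict) %in% key(loose)))
  expect_gte(nrow(loose$edges), nrow(strict$edges))

  # pair sharing exactly one miRNA is excluded at min_shared = 2
  one <- loose$edges[loose$edges$shared == 1, ]
  if (nrow(one)) {
    expect_false(any(paste(one$lncRNA, one$mRNA) %in% key(strict)))
  }
})

test_that("empty interaction tables give an empty network with a warning", {
  study <- tiny_study(seed = 15)
  empty <- data.frame(mirna_id = character(), target_id = character(),
                      stringsAsFactors = FALSE)
  expect_warning(
    net <- build_background(rownames(study$lnc_expr),
                            rownames(study$mrna_expr), study$lnc_expr,
                            study$mrna_expr, empty, empty,
                            study$samples),
    "empty")
  expect_identical(nrow(net$edges), 0L)
})

test_that("sub-network extraction keeps seeds and only background edges", {
  edges <- data.frame(lncRNA = c("l1", "l1", "l2"),
                      mRNA = c("m1", "m2", "m1"),
                      pcc = 0.5, pcc_p = 0.001, shared = 2L,
                      hyper_p = 0.001, stringsAsFactors = FALSE)
  bg <- lncMethNet:::new_cerna_network(edges, c("l1", "l2", "l3"),
                                       c("m1", "m2"))
  sn <- extract_subnetwork(bg, c("l1", "l3"))
  expect_equal(nrow(sn$edges), 2L)
  expect_equal(sn$lncRNAs, c("l1", "l3"))   # isolated seed retained
  expect_equal(sn$mRNAs, c("m1", "m2"))
  expect_true(all(paste(sn$edges$lncRNA, sn$edges$mRNA) %in%
                    paste(edges$lncRNA, edges$mRNA)))
  lone <- extract_subnetwork(bg, "l3")
  expect_identical(nrow(lone$edges), 0L)
  expect_equal(lone$lncRNAs, "l3")
})

test_that("degrees and hubs match brute-force incidence counting", {
  star <- lncMethNet:::new_cerna_network(
    data.frame(lncRNA = "l1", mRNA = sprintf("m%d", 1:6), pcc = 0.5,
               pcc_p = 0.001, shared = 2L, hyper_p = 0.001,
               stringsAsFactors = FALSE),
    "l1", sprintf("m%d", 1:6))
  ds <- degrees_and_hubs(star)
  expect_equal(unname(ds$lnc_degree), 6L)
  expect_length(ds$hubs, 0)
  expect_equal(ds$mean_lnc_degree, 6)

  hub <- lncMethNet:::new_cerna_network(
    data.frame(lncRNA = sprintf("l%d", 1:5), mRNA = "m1", pcc = 0.5,
               pcc_p = 0.001, shared = 2L, hyper_p = 0.001,
               stringsAsFactors = FALSE),
    sprintf("l%d", 1:5), "m1")
  expect_equal(degrees_and_hubs(hub)$hubs, "m1")

  set.seed(8)
  edges <- unique(data.frame(lncRNA = sample(sprintf("l%d", 1:10), 40, TRUE),
                             mRNA = sample(sprintf("m%d", 1:15), 40, TRUE),
                             stringsAsFactors = FALSE))
  edges$pcc <- 0.5; edges$pcc_p <- 0.001
  edges$shared <- 2L; edges$hyper_p <- 0.001
  net <- lncMethNet:::new_cerna_network(edges, unique(edges$lncRNA),
                                        unique(edges$mRNA))
  ds <- degrees_and_hubs(net, hub_threshold = 3)
  for (l in names(ds$lnc_degree)) {
    expect_equal(ds$lnc_degree[[l]], sum(edges$lncRNA == l))
  }
  for (g in names(ds$mrna_degree)) {
    expect_equal(ds$mrna_degree[[g]], sum(edges$mRNA == g))
  }
  expect_setequal(ds$hubs,
                  names(which(table(edges$mRNA) >= 3)))
})
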