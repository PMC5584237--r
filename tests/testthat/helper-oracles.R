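# Independent brute-force oracles used across the suite.  These are
# deliberately naive re-derivations (enumeration, explicit loops, grid
# search) kept free of the package's own code paths.

# Upper-tail hypergeometric p by exhaustive enumeration of all C(N, n)
# draws from a universe where items 1..M are annotated.
oracle_hyper <- function(N, M, n, m) {
  if (m == 0) return(1)
  if (n == 0) return(0)   # m >= 1 impossible; tail prob 0 (never reached)
  draws <- utils::combn(N, n)
  overlap <- colSums(draws <= M)
  mean(overlap >= m)
}

# Pearson correlation via the covariance / sd*sd textbook form.
oracle_pearson <- function(x, y) {
  stats::cov(x, y) / (stats::sd(x) * stats::sd(y))
}

# O(P x L) interval scan assigning probes to half-open promoters.
oracle_map <- function(promoters, manifest) {
  lapply(seq_len(nrow(promoters)), function(i) {
    hit <- manifest$chrom == promoters$chrom[i] &
      manifest$pos >= promoters$start[i] &
      manifest$pos < promoters$end[i]
    manifest$probe_id[hit]
  })
}

# Two-sample K-S D by explicit step-function evaluation at all jumps.
oracle_ks_D <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(t) mean(a <= t) - mean(b <= t),
                 numeric(1))))
}

# Longhand Kaplan-Meier table via an explicit risk-set loop.
oracle_km <- function(time, event) {
  ts <- sort(unique(time))
  s <- 1
  out <- data.frame(time = ts, n_risk = NA_real_, n_event = NA_real_,
                    surv = NA_real_)
  for (i in seq_along(ts)) {
    at_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    if (d > 0) s <- s * (1 - d / at_risk)
    out$n_risk[i] <- at_risk; out$n_event[i] <- d; out$surv[i] <- s
  }
  out
}

# Longhand two-group log-rank chi-square via the O-E hypergeometric
# table over pooled event times.
oracle_logrank <- function(time_a, event_a, time_b, event_b) {
  times <- sort(unique(c(time_a[event_a == 1], time_b[event_b == 1])))
  U <- 0; V <- 0
  for (t in times) {
    n1 <- sum(time_a >= t); n2 <- sum(time_b >= t); n <- n1 + n2
    d1 <- sum(time_a == t & event_a == 1)
    d2 <- sum(time_b == t & event_b == 1)
    d <- d1 + d2
    U <- U + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  U^2 / V
}

# Breslow Cox partial log-likelihood for a single covariate; used for
# grid-search argmax oracles.
oracle_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

oracle_cox_grid <- function(time, event, x, lo = -5, hi = 5) {
  grid <- seq(lo, hi, length.out = 2001)
  for (pass in 1:3) {
    ll <- vapply(grid, oracle_cox_loglik, numeric(1), time, event, x)
    b <- grid[which.max(ll)]
    step <- diff(grid[1:2])
    grid <- seq(b - step, b + step, length.out = 2001)
  }
  b
}

# Union-find connected components over an undirected edge list.
oracle_components <- function(nodes, edges) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(a) {
    while (parent[[a]] != a) a <- parent[[a]]
    a
  }
  for (i in seq_len(nrow(edges))) {
    ra <- find(edges$child[i]); rb <- find(edges$parent[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(nodes, find, character(1))
  as.integer(table(roots))
}

# The pipeline's differential stage replayed from an in-memory study
# (no file IO), mirroring run_pipeline's calls.
run_differential_stage <- function(study, B = 1000) {
  proms <- map_probes(
    define_promoters(study$annotation$lnc,
                     study$config$promoter_window),
    study$annotation$manifest)
  beta_f <- filter_and_impute(study$beta)
  profile <- promoter_level(beta_f, proms)
  common <- intersect(rownames(profile), rownames(study$lnc_expr))
  sam_meth <- sam_qvalues(profile[common, , drop = FALSE], study$samples,
                          B = B, seed = study$config$seed)
  lexp <- study$lnc_expr[common, , drop = FALSE]
  sam_lnc <- sam_qvalues(log2(lexp + 1), study$samples, B = B,
                         seed = study$config$seed + 1, fc_from = lexp)
  classify_lnc(call_dml(sam_meth), call_del(sam_lnc))
}

# Tiny deterministic study used by several fixtures.
tiny_study <- function(seed = 11, ...) {
  simulate_study(simulation_config(
    seed = seed, n_tumor = 10, n_normal = 6, n_lnc = 30, n_gene = 40,
    n_mirna = 40, n_probe = 300,
    n_planted = c(high_up = 3, high_down = 3, low_up = 3, low_down = 3),
    module_size = 3, ...))
}
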