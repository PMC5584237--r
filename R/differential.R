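#' SAM two-class statistic for a single feature
#'
#' The SAM statistic is a moderated t-like score
#' `d = (mean_T - mean_N) / (s + s0)` where `s` is the pooled standard
#' error `sqrt((1/nT + 1/nN) * (SS_T + SS_N) / (nT + nN - 2))` and `s0` is
#' an exchangeability constant that damps features with tiny scatter.
#'
#' @param tumor,normal Numeric vectors with at least two values each.
#' @param s0 Exchangeability constant (>= 0).
#' @return List with `d` and `s`.
#' @export
sam_d <- function(tumor, normal, s0) {
  if (length(tumor) < 2 || length(normal) < 2) {
    stop("sam_d needs >= 2 values per group")
  }
  nT <- length(tumor); nN <- length(normal)
  ss <- sum((tumor - mean(tumor))^2) + sum((normal - mean(normal))^2)
  s <- sqrt((1 / nT + 1 / nN) * ss / (nT + nN - 2))
  list(d = (mean(tumor) - mean(normal)) / (s + s0), s = s)
}

#' Exchangeability constant from per-feature scatters
#'
#' The default `s0` is the median of the per-feature pooled standard
#' errors; a percentile override is available.
#'
#' @param s Numeric vector of per-feature scatters.
#' @param percentile Quantile of `s` to use (default 0.5, the median).
#' @return The `s0` scalar.
#' @export
estimate_s0 <- function(s, percentile = 0.5) {
  if (length(s) == 0) stop("estimate_s0: empty feature set")
  unname(stats::quantile(s, percentile, type = 7))
}

# Vectorized d and s for every feature of `mat` under a set of tumor-label
# assignments.  `tumor_idx` is a logical matrix (samples x assignments).
sam_d_matrix <- function(mat, tumor_idx, s0) {
  nT <- colSums(tumor_idx)
  nN <- nrow(tumor_idx) - nT
  stopifnot(all(nT >= 2), all(nN >= 2))
  WT <- tumor_idx * 1
  WN <- (!tumor_idx) * 1
  sumT <- mat %*% WT; sumN <- mat %*% WN
  sqT <- (mat^2) %*% WT; sqN <- (mat^2) %*% WN
  meanT <- sweep(sumT, 2, nT, "/")
  meanN <- sweep(sumN, 2, nN, "/")
  ssT <- sqT - sweep(meanT^2, 2, nT, "*")
  ssN <- sqN - sweep(meanN^2, 2, nN, "*")
  ss <- pmax(ssT + ssN, 0)
  fac <- (1 / nT + 1 / nN) / (nT + nN - 2)
  s <- sqrt(sweep(ss, 2, fac, "*"))
  d <- (meanT - meanN) / (s + s0)
  list(d = d, s = s, meanT = meanT, meanN = meanN)
}

#' SAM differential analysis with permutation q-values
#'
#' Computes the SAM statistic per feature, then estimates an empirical
#' false discovery rate at every observed `|d|` threshold from label
#' permutations: `FDR(t)` is the average (over permutations) number of
#' permuted `|d*|` at or above `t`, divided by the observed count at or
#' above `t`.  A feature's q-value is the minimum `FDR(t)` over all
#' thresholds `t` at or below its own `|d|` (a running minimum that makes
#' q non-increasing in `|d|`), clipped to `[0, 1]`.  With a single
#' feature and `B = "exact"` the q-value reduces to the exact permutation
#' tail fraction.
#'
#' @param mat Feature-by-sample numeric matrix.
#' @param samples Sample table (`sample_id`, `group`); both groups need at
#'   least two samples present among the matrix columns.
#' @param B Number of Monte-Carlo label permutations, or `"exact"` for
#'   full enumeration of tumor-label assignments (refused above 20000
#'   assignments).
#' @param seed Integer seed for the permutation stream.
#' @param s0 Optional exchangeability constant; default
#'   [estimate_s0()] of the observed scatters.
#' @param center `"mean"` (default) or `"median"`: how permutation counts
#'   are summarized into the numerator of `FDR(t)`.
#' @param eps Pseudocount added to both group means before the fold
#'   change (guards against zero denominators in expression matrices).
#' @param fc_from Optional matrix (same dimnames) whose group means are
#'   used for the fold change instead of `mat`; lets the statistic run
#'   on log-scale expression while fold changes stay on the linear
#'   scale.
#' @return A `sam_result` data.frame: `feature_id`, `d`, `s`, `q`,
#'   `delta` (tumor mean minus normal mean), `fold_change`
#'   (pseudocounted tumor/normal mean ratio), `mean_tumor`, `mean_normal`.
#' @export
sam_qvalues <- function(mat, samples, B = 1000, seed = 1, s0 = NULL,
                        center = c("mean", "median"), eps = 0.01,
                        fc_from = NULL) {
  center <- match.arg(center)
  stopifnot(is.matrix(mat), nrow(mat) >= 1)
  grp <- samples$group[match(colnames(mat), samples$sample_id)]
  if (anyNA(grp)) stop("matrix columns missing from sample table")
  is_t <- grp == "tumor"
  nT <- sum(is_t); nN <- sum(!is_t); n <- nT + nN
  if (nT < 2 || nN < 2) stop("need >= 2 samples per group")

  obs <- sam_d_matrix(mat, matrix(is_t, ncol = 1), s0 = 0)
  s_obs <- drop(obs$s)
  if (is.null(s0)) s0 <- estimate_s0(s_obs)
  d_obs <- drop(obs$meanT - obs$meanN) / (s_obs + s0)

  if (identical(B, "exact")) {
    n_assign <- choose(n, nT)
    if (n_assign > 20000) {
      stop("exact enumeration over ", n_assign,
           " assignments refused; use Monte-Carlo B")
    }
    combs <- utils::combn(n, nT)
    perm_idx <- matrix(FALSE, n, ncol(combs))
    perm_idx[cbind(as.vector(combs),
                   rep(seq_len(ncol(combs)), each = nT))] <- TRUE
  } else {
    stopifnot(B >= 1)
    set.seed(as.integer(seed))
    perm_idx <- vapply(seq_len(B), function(b) {
      idx <- rep(FALSE, n); idx[sample.int(n, nT)] <- TRUE; idx
    }, logical(n))
  }
  perm <- sam_d_matrix(mat, perm_idx, s0 = s0)
  abs_perm <- abs(perm$d)
  n_perm <- ncol(perm_idx)

  ord <- order(abs(d_obs))            # thresholds ascending
  t_asc <- abs(d_obs)[ord]
  # observed count at or above each threshold (ties share a count)
  obs_ge <- length(d_obs) - findInterval(t_asc, sort(abs(d_obs)),
                                         left.open = TRUE)
  # thresholds nudged down by a relative epsilon so permuted statistics
  # that tie an observed |d| (e.g. the identity assignment under exact
  # enumeration) are counted despite last-ulp arithmetic differences
  t_cnt <- t_asc - 1e-8 * (1 + t_asc)
  if (center == "mean") {
    pooled <- sort(as.vector(abs_perm))
    perm_ge <- (length(pooled) -
                findInterval(t_cnt, pooled, left.open = TRUE)) / n_perm
  } else {
    per_perm <- apply(abs_perm, 2, function(col) {
      sc <- sort(col)
      length(sc) - findInterval(t_cnt, sc, left.open = TRUE)
    })
    perm_ge <- apply(matrix(per_perm, nrow = length(t_asc)), 1,
                     stats::median)
  }
  fdr <- pmin(1, perm_ge / pmax(1, obs_ge))
  q_asc <- cummin(fdr)
  q <- numeric(length(d_obs)); q[ord] <- q_asc

  meanT <- drop(obs$meanT); meanN <- drop(obs$meanN)
  if (is.null(fc_from)) {
    fcT <- meanT; fcN <- meanN
  } else {
    stopifnot(identical(dimnames(fc_from), dimnames(mat)))
    fcT <- rowMeans(fc_from[, is_t, drop = FALSE])
    fcN <- rowMeans(fc_from[, !is_t, drop = FALSE])
  }
  res <- data.frame(
    feature_id = rownames(mat), d = d_obs, s = s_obs, q = q,
    delta = meanT - meanN,
    fold_change = (fcT + eps) / (fcN + eps),
    mean_tumor = meanT, mean_normal = meanN,
    stringsAsFactors = FALSE)
  attr(res, "s0") <- s0
  attr(res, "n_perm") <- n_perm
  class(res) <- c("sam_result", "data.frame")
  rownames(res) <- NULL
  res
}

#' Call differentially methylated lncRNAs (DMLs)
#'
#' A lncRNA is a DML when `q <= q_threshold` and the absolute methylation
#' difference (tumor mean minus normal mean of promoter beta) is at least
#' `delta_threshold`.  The sign of the difference labels the direction:
#' `high` (hypermethylated in tumor) or `low`.
#'
#' @param sam A `sam_result` on promoter methylation levels.
#' @param q_threshold,delta_threshold Call thresholds (defaults 0.05 and
#'   0.1, both inclusive).
#' @return Data.frame `feature_id`, `q`, `delta`, `call` in
#'   `{high, low, none}`.
#' @export
call_dml <- function(sam, q_threshold = 0.05, delta_threshold = 0.1) {
  is_dml <- sam$q <= q_threshold & abs(sam$delta) >= delta_threshold
  call <- ifelse(!is_dml, "none", ifelse(sam$delta > 0, "high", "low"))
  data.frame(feature_id = sam$feature_id, q = sam$q, delta = sam$delta,
             call = call, stringsAsFactors = FALSE)
}

#' Call differentially expressed genes (DEGs)
#'
#' A gene is a DEG when `q <= q_threshold` and its tumor/normal fold
#' change is `>= fc_up` or `<= fc_down`.
#'
#' @param sam A `sam_result` on mRNA expression.
#' @param q_threshold,fc_up,fc_down Call thresholds (defaults 0.05, 2,
#'   0.5, all inclusive).
#' @return Data.frame `feature_id`, `q`, `fold_change`, `call` in
#'   `{up, down, none}`.
#' @export
call_deg <- function(sam, q_threshold = 0.05, fc_up = 2, fc_down = 0.5) {
  is_deg <- sam$q <= q_threshold &
    (sam$fold_change >= fc_up | sam$fold_change <= fc_down)
  call <- ifelse(!is_deg, "none",
                 ifelse(sam$fold_change >= fc_up, "up", "down"))
  data.frame(feature_id = sam$feature_id, q = sam$q,
             fold_change = sam$fold_change, call = call,
             stringsAsFactors = FALSE)
}

#' Call differentially expressed lncRNAs (DELs)
#'
#' A lncRNA is a DEL when `q <= q_threshold` (no fold-change filter); the
#' direction comes from the sign of the tumor-minus-normal mean.
#'
#' @param sam A `sam_result` on lncRNA expression.
#' @param q_threshold Call threshold (default 0.05, inclusive).
#' @return Data.frame `feature_id`, `q`, `delta`, `call` in
#'   `{up, down, none}`.
#' @export
call_del <- function(sam, q_threshold = 0.05) {
  is_del <- sam$q <= q_threshold
  call <- ifelse(!is_del, "none", ifelse(sam$delta > 0, "up", "down"))
  data.frame(feature_id = sam$feature_id, q = sam$q, delta = sam$delta,
             call = call, stringsAsFactors = FALSE)
}

#' Cross-classify lncRNAs by methylation and expression direction
#'
#' The classified set is the intersection of DML and DEL calls: HMLncs
#' (promoter hypermethylated in tumor) and LMLncs (hypomethylated), each
#' split by expression direction into the four groups `high-up`,
#' `high-down`, `low-up`, `low-down`.  lncRNAs with only one of the two
#' calls are `unclassified`.
#'
#' @param dml Output of [call_dml()].
#' @param del Output of [call_del()].
#' @return Data.frame `feature_id`, `meth_call`, `expr_call`, `group`.
#' @export
classify_lnc <- function(dml, del) {
  ids <- union(dml$feature_id, del$feature_id)
  meth <- dml$call[match(ids, dml$feature_id)]
  expr <- del$call[match(ids, del$feature_id)]
  meth[is.na(meth)] <- "none"; expr[is.na(expr)] <- "none"
  group <- ifelse(meth == "none" | expr == "none", "unclassified",
                  paste(meth, expr, sep = "-"))
  data.frame(feature_id = ids, meth_call = meth, expr_call = expr,
             group = group, stringsAsFactors = FALSE)
}
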