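#' Pearson correlation coefficient (raw-moment form)
#'
#' Evaluates the textbook raw-sum form
#' `(n*Sxy - Sx*Sy) / (sqrt(n*Sxx - Sx^2) * sqrt(n*Syy - Sy^2))`,
#' clamped to `[-1, 1]` against round-off.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`.
#' @return The correlation, or `NA` when either vector has zero variance.
#' @export
pearson <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y), n >= 3)
  sx <- sum(x); sy <- sum(y)
  vx <- n * sum(x^2) - sx^2
  vy <- n * sum(y^2) - sy^2
  if (vx <= 0 || vy <= 0) return(NA_real_)
  r <- (n * sum(x * y) - sx * sy) / (sqrt(vx) * sqrt(vy))
  max(-1, min(1, r))
}

#' Two-sided p-value for a Pearson correlation
#'
#' Uses the exact null distribution of `t = r * sqrt((n-2)/(1-r^2))` on
#' `n - 2` degrees of freedom.
#'
#' @param r Correlation in `[-1, 1]`.
#' @param n Sample size (`n >= 3`).
#' @return Two-sided p-value (1 at `r = 0`, 0 at `|r| = 1`).
#' @export
pearson_pvalue <- function(r, n) {
  stopifnot(n >= 3)
  r <- pmax(-1, pmin(1, r))
  p <- ifelse(abs(r) >= 1, 0,
              2 * stats::pt(-abs(r) * sqrt((n - 2) / (1 - r^2)), n - 2))
  p
}

#' Shared-miRNA hypergeometric test for one lncRNA-mRNA pair
#'
#' Tests whether the `m` miRNAs shared by a lncRNA (with `M` interacting
#' miRNAs) and an mRNA (with `n` interacting miRNAs) exceed chance within
#' a universe of `N` miRNAs:
#' `P = 1 - sum_{i=0}^{m-1} C(M,i) C(N-M, n-i) / C(N,n)`
#' (the upper hypergeometric tail, evaluated in log space).
#'
#' @param lnc_mirnas,mrna_mirnas Character vectors of interacting miRNA
#'   ids (deduplicated internally).
#' @param N Universe size (total distinct miRNAs).
#' @return List with `m` (shared count) and `p`.
#' @export
shared_mirna_test <- function(lnc_mirnas, mrna_mirnas, N) {
  lnc_mirnas <- unique(lnc_mirnas); mrna_mirnas <- unique(mrna_mirnas)
  M <- length(lnc_mirnas); n <- length(mrna_mirnas)
  m <- length(intersect(lnc_mirnas, mrna_mirnas))
  if (M > N || n > N) stop("miRNA set larger than universe N")
  list(m = m, p = hypergeom_p(N = N, M = M, n = n, m = m))
}

new_cerna_network <- function(edges, lncRNAs, mRNAs) {
  structure(list(edges = edges, lncRNAs = lncRNAs, mRNAs = mRNAs),
            class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  cat("ceRNA network:", length(x$lncRNAs), "lncRNAs,",
      length(x$mRNAs), "mRNAs,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Construct the background lncRNA-mRNA ceRNA network
#'
#' Over all (DEL lncRNA, DEG mRNA) pairs that share at least one
#' candidate miRNA, an edge is retained when all four criteria hold:
#' positive expression correlation (`pcc > 0`), correlation p-value at or
#' below `pcc_p`, at least `min_shared` common miRNAs, and a shared-miRNA
#' hypergeometric p-value at or below `hyper_p`.  Correlation is computed
#' across tumor samples by default (the network describes the tumor
#' state).
#'
#' @param del_ids,deg_ids Character vectors of differentially expressed
#'   lncRNAs and genes.
#' @param lnc_expr,mrna_expr Feature-by-sample expression matrices whose
#'   columns cover the chosen samples in a shared order.
#' @param mir_lnc,mir_mrna Interaction tables (`mirna_id`, `target_id`),
#'   deduplicated on load.
#' @param samples Sample table used to restrict to tumor columns.
#' @param min_shared Minimum shared-miRNA count (default 2: "more than
#'   one common miRNA").
#' @param pcc_p,hyper_p Significance cutoffs (defaults 0.01, inclusive).
#' @param sample_scope `"tumor"` (default) or `"all"`.
#' @param universe_N Optional miRNA universe size; default the number of
#'   distinct miRNAs in the union of both interaction tables.
#' @param log2_expr Correlate `log2(x + 1)`-transformed expression
#'   (default `TRUE`; Pearson correlation of RNA-seq-like abundances is
#'   conventionally computed on the log scale).
#' @return A `cerna_network` whose `edges` data.frame carries `lncRNA`,
#'   `mRNA`, `pcc`, `pcc_p`, `shared`, `hyper_p`.
#' @export
build_background <- function(del_ids, deg_ids, lnc_expr, mrna_expr,
                             mir_lnc, mir_mrna, samples,
                             min_shared = 2, pcc_p = 0.01, hyper_p = 0.01,
                             sample_scope = c("tumor", "all"),
                             universe_N = NULL, log2_expr = TRUE) {
  sample_scope <- match.arg(sample_scope)
  mir_lnc <- unique(mir_lnc[, c("mirna_id", "target_id")])
  mir_mrna <- unique(mir_mrna[, c("mirna_id", "target_id")])
  if (nrow(mir_lnc) == 0 || nrow(mir_mrna) == 0) {
    warning("empty interaction table: returning empty network")
    return(new_cerna_network(empty_edges(), character(), character()))
  }
  if (is.null(universe_N)) {
    universe_N <- length(union(mir_lnc$mirna_id, mir_mrna$mirna_id))
  }
  cols <- if (sample_scope == "tumor") {
    samples$sample_id[samples$group == "tumor"]
  } else samples$sample_id
  cols <- intersect(colnames(lnc_expr), cols)
  stopifnot(identical(cols, intersect(colnames(mrna_expr), cols)))

  lnc_ids <- intersect(del_ids, unique(mir_lnc$target_id))
  lnc_ids <- intersect(lnc_ids, rownames(lnc_expr))
  mrna_ids <- intersect(deg_ids, unique(mir_mrna$target_id))
  mrna_ids <- intersect(mrna_ids, rownames(mrna_expr))
  if (length(lnc_ids) == 0 || length(mrna_ids) == 0) {
    return(new_cerna_network(empty_edges(), character(), character()))
  }

  mirs <- sort(union(mir_lnc$mirna_id, mir_mrna$mirna_id))
  A <- incidence01(mir_lnc, lnc_ids, mirs)     # lnc x mir
  Bm <- incidence01(mir_mrna, mrna_ids, mirs)  # mrna x mir
  shared <- A %*% t(Bm)                        # lnc x mrna shared counts
  Msz <- rowSums(A); nsz <- rowSums(Bm)

  X <- lnc_expr[lnc_ids, cols, drop = FALSE]
  Y <- mrna_expr[mrna_ids, cols, drop = FALSE]
  if (log2_expr) {
    X <- log2(X + 1); Y <- log2(Y + 1)
  }
  sdx <- apply(X, 1, stats::sd); sdy <- apply(Y, 1, stats::sd)
  rho <- suppressWarnings(stats::cor(t(X), t(Y)))
  n_s <- length(cols)
  pmat <- matrix(pearson_pvalue(as.vector(rho), n_s), nrow = nrow(rho))

  cand <- which(shared >= 1, arr.ind = TRUE)
  if (nrow(cand)) {
    i <- cand[, 1]; j <- cand[, 2]
    ok_var <- sdx[i] > 0 & sdy[j] > 0
    if (any(!ok_var)) {
      message(sum(!ok_var), " candidate pair(s) skipped: zero variance")
    }
    m <- shared[cand]
    hp <- hypergeom_p(N = universe_N, M = Msz[i], n = nsz[j], m = m)
    keep <- ok_var & rho[cand] > 0 & pmat[cand] <= pcc_p &
      m >= min_shared & hp <= hyper_p
    edges <- data.frame(lncRNA = lnc_ids[i][keep], mRNA = mrna_ids[j][keep],
                        pcc = rho[cand][keep], pcc_p = pmat[cand][keep],
                        shared = as.integer(m[keep]), hyper_p = hp[keep],
                        stringsAsFactors = FALSE)
  } else {
    edges <- empty_edges()
  }
  edges <- edges[order(edges$lncRNA, edges$mRNA, method = "radix"), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  new_cerna_network(edges, lncRNAs = sort(unique(edges$lncRNA)),
                    mRNAs = sort(unique(edges$mRNA)))
}

empty_edges <- function() {
  data.frame(lncRNA = character(), mRNA = character(), pcc = numeric(),
             pcc_p = numeric(), shared = integer(), hyper_p = numeric(),
             stringsAsFactors = FALSE)
}

incidence01 <- function(tab, targets, mirs) {
  m <- matrix(0, length(targets), length(mirs),
              dimnames = list(targets, mirs))
  tab <- tab[tab$target_id %in% targets, , drop = FALSE]
  m[cbind(match(tab$target_id, targets), match(tab$mirna_id, mirs))] <- 1
  m
}

#' Seed sub-network induced by a group of lncRNAs
#'
#' Keeps the background edges incident to the seed lncRNAs; the node set
#' is the seeds (including edge-less ones) plus their mRNA neighbors.
#'
#' @param background A `cerna_network`.
#' @param seeds Character vector of seed lncRNA ids.
#' @return A `cerna_network`.
#' @export
extract_subnetwork <- function(background, seeds) {
  edges <- background$edges[background$edges$lncRNA %in% seeds, ,
                            drop = FALSE]
  rownames(edges) <- NULL
  new_cerna_network(edges, lncRNAs = sort(unique(seeds)),
                    mRNAs = sort(unique(edges$mRNA)))
}

#' Node degrees, hub mRNAs and mean lncRNA degree of a ceRNA network
#'
#' Hubs are mRNA nodes with degree at or above `hub_threshold`.  The mean
#' lncRNA degree is the edge count divided by the number of lncRNA nodes.
#'
#' @param network A `cerna_network`.
#' @param hub_threshold Minimum mRNA degree for hub status (default 5).
#' @return List with `lnc_degree`, `mrna_degree` (named integer vectors),
#'   `hubs` (character) and `mean_lnc_degree`.
#' @export
degrees_and_hubs <- function(network, hub_threshold = 5) {
  e <- network$edges
  lnc_nodes <- network$lncRNAs
  lnc_deg <- stats::setNames(integer(length(lnc_nodes)), lnc_nodes)
  tab <- table(e$lncRNA)
  lnc_deg[names(tab)] <- as.integer(tab)
  mrna_deg <- if (nrow(e)) table(e$mRNA) else table(character())
  mrna_deg <- stats::setNames(as.integer(mrna_deg), names(mrna_deg))
  hubs <- sort(names(mrna_deg)[mrna_deg >= hub_threshold])
  mean_lnc <- if (length(lnc_nodes)) nrow(e) / length(lnc_nodes) else NaN
  list(lnc_degree = lnc_deg, mrna_degree = mrna_deg, hubs = hubs,
       mean_lnc_degree = mean_lnc)
}
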