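#' Multivariate Cox fit for a module of genes
#'
#' Fits a Cox proportional-hazards model (Breslow tie handling) of
#' survival on the expression of the module genes, z-scored across the
#' fitted samples.  Samples are matched between the expression matrix
#' columns and the clinical table.
#'
#' @param expr Gene-by-sample expression matrix containing the module
#'   genes.
#' @param clinical Data.frame `sample`, `time`, `event`.
#' @param genes Character vector of module gene ids (default: all rows of
#'   `expr`).
#' @param standardize z-score covariates before fitting (default `TRUE`).
#' @return List with `beta` (named coefficients), `center`/`scale` used
#'   for standardization, the fitted `coxph` object, and the design
#'   matrix `x` (standardized) with matching `clinical` rows.
#' @export
fit_cox <- function(expr, clinical, genes = rownames(expr),
                    standardize = TRUE) {
  common <- intersect(clinical$sample, colnames(expr))
  if (length(common) < 2) stop("too few samples shared by expression and clinical data")
  clinical <- clinical[match(common, clinical$sample), , drop = FALSE]
  if (sum(clinical$event) < 1) stop("no events in clinical data")
  x <- t(expr[genes, common, drop = FALSE])
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-information covariate (constant expression): ",
         paste(genes[sds == 0], collapse = ", "))
  }
  if (length(genes) >= sum(clinical$event)) {
    warning("module size >= number of events; coefficients may be unstable")
  }
  ctr <- if (standardize) colMeans(x) else rep(0, ncol(x))
  scl <- if (standardize) sds else rep(1, ncol(x))
  xs <- scale(x, center = ctr, scale = scl)
  fit <- survival::coxph(
    survival::Surv(clinical$time, clinical$event) ~ xs,
    ties = "breslow",
    control = survival::coxph.control(eps = 1e-9, iter.max = 100))
  beta <- stats::setNames(as.numeric(stats::coef(fit)), genes)
  if (any(!is.finite(beta)) || any(abs(beta) > 50)) {
    stop("Cox fit did not converge (possible separation) for: ",
         paste(genes[!is.finite(beta) | abs(beta) > 50], collapse = ", "))
  }
  list(beta = beta, center = ctr, scale = scl, fit = fit, x = xs,
       clinical = clinical)
}

#' Prognostic index (risk score)
#'
#' The linear Cox risk score `PI = beta_1 x_1 + ... + beta_p x_p` per
#' sample.
#'
#' @param beta Named coefficient vector.
#' @param x Sample-by-gene covariate matrix (columns matching `beta`).
#' @return Named numeric vector of per-sample PIs.
#' @export
prognostic_index <- function(beta, x) {
  x <- as.matrix(x)
  stopifnot(ncol(x) == length(beta))
  drop(x %*% beta)
}

#' Median split of prognostic indices into risk groups
#'
#' Samples with PI above the median are `high` risk, the rest `low`
#' (samples at exactly the median go to `low`, deterministically).  A
#' split that leaves either group empty is an error.
#'
#' @param pi_values Named numeric vector of prognostic indices.
#' @return Named character vector (`"high"`/`"low"`) with attribute
#'   `median`.
#' @export
median_split <- function(pi_values) {
  med <- stats::median(pi_values)
  grp <- ifelse(pi_values > med, "high", "low")
  if (length(unique(grp)) < 2) {
    stop("degenerate median split: all samples on one side of the median")
  }
  attr(grp, "median") <- med
  grp
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over
#' distinct event times; censored-only times reduce the risk set without
#' an S step.
#'
#' @param time Positive event/censoring times.
#' @param event 0/1 event indicators.
#' @return Data.frame `time`, `n_risk`, `n_event`, `surv` (one row per
#'   distinct observed time).
#' @export
kaplan_meier <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "none")
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             surv = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard log-rank: summed observed-minus-expected events in group A
#' over the pooled event times, with the hypergeometric variance;
#' `chisq = U^2 / V` on one degree of freedom.
#'
#' @param time_a,event_a,time_b,event_b Survival records of the two
#'   groups (both nonempty).
#' @return List with `chisq` and `p`.
#' @export
logrank <- function(time_a, event_a, time_b, event_b) {
  if (length(time_a) == 0 || length(time_b) == 0) {
    stop("logrank needs observations in both groups")
  }
  grp <- factor(c(rep("A", length(time_a)), rep("B", length(time_b))))
  sd <- survival::survdiff(
    survival::Surv(c(time_a, time_b), c(event_a, event_b)) ~ grp)
  chisq <- unname(sd$chisq)
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1,
                                        lower.tail = FALSE))
}

#' Prognostic analysis of a hub-mRNA module
#'
#' Composes the survival workflow on a ceRNA sub-network's hub mRNAs:
#' multivariate Cox fit on the hub genes, per-sample prognostic index,
#' median split into high/low risk, Kaplan-Meier curves per group, and
#' the log-rank test between them.  An empty hub set is an error
#' (sub-networks without hub mRNAs cannot be assessed).
#'
#' When `transfer` (a previous `risk_model`) is supplied, its
#' coefficients and standardization are applied to the new cohort
#' instead of refitting, and the split uses the new cohort's own PI
#' median.
#'
#' @param hubs Character vector of hub mRNA ids (the module).
#' @param expr Gene-by-sample expression matrix.
#' @param clinical Data.frame `sample`, `time`, `event`.
#' @param transfer Optional `risk_model` whose coefficients are
#'   transferred to this cohort.
#' @return A `risk_model`: `genes`, `beta`, `pi` (named), `group`
#'   (named), `km` (list of per-group KM tables), `logrank`
#'   (`chisq`, `p`), `transferred`.
#' @export
module_survival <- function(hubs, expr, clinical, transfer = NULL) {
  if (length(hubs) == 0) stop("no hub mRNAs in this sub-network")
  missing_genes <- setdiff(hubs, rownames(expr))
  if (length(missing_genes)) {
    stop("hub genes absent from expression matrix: ",
         paste(missing_genes, collapse = ", "))
  }
  common <- intersect(clinical$sample, colnames(expr))
  clinical <- clinical[match(common, clinical$sample), , drop = FALSE]
  if (is.null(transfer)) {
    cf <- fit_cox(expr, clinical, genes = hubs)
    beta <- cf$beta; xs <- cf$x; clinical <- cf$clinical
  } else {
    beta <- transfer$beta
    stopifnot(identical(names(beta), transfer$genes))
    x <- t(expr[transfer$genes, common, drop = FALSE])
    xs <- scale(x, center = transfer$center, scale = transfer$scale)
    hubs <- transfer$genes
  }
  pi_values <- stats::setNames(prognostic_index(beta, xs),
                               clinical$sample)
  grp <- median_split(pi_values)
  km <- lapply(c(high = "high", low = "low"), function(g) {
    sel <- grp == g
    kaplan_meier(clinical$time[sel], clinical$event[sel])
  })
  lr <- logrank(clinical$time[grp == "high"], clinical$event[grp == "high"],
                clinical$time[grp == "low"], clinical$event[grp == "low"])
  structure(list(genes = hubs, beta = beta,
                 center = if (is.null(transfer)) cf$center else transfer$center,
                 scale = if (is.null(transfer)) cf$scale else transfer$scale,
                 pi = pi_values, group = grp, km = km, logrank = lr,
                 transferred = !is.null(transfer)),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat("Risk model on", length(x$genes), "module genes",
      if (x$transferred) "(transferred coefficients)" else "(fitted)", "\n")
  cat("  high-risk:", sum(x$group == "high"),
      " low-risk:", sum(x$group == "low"), "\n")
  cat(sprintf("  log-rank chisq = %.4g, p = %.4g\n",
              x$logrank$chisq, x$logrank$p))
  invisible(x)
}
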