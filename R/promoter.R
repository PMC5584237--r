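#' Beta value from methylated/unmethylated intensities
#'
#' The per-probe methylation level is the intensity ratio
#' `Methy / (Methy + Unmethy)`, in `[0, 1]`: 0 is fully unmethylated, 1
#' fully methylated.  When both intensities are zero the value is
#' undefined and returned as `NA` rather than 0/0.
#'
#' @param methy,unmethy Nonnegative finite intensity vectors (recycled).
#' @return Numeric vector of beta values in `[0, 1]`, `NA` where both
#'   intensities are zero.
#' @export
compute_beta <- function(methy, unmethy) {
  stopifnot(all(is.finite(methy)), all(is.finite(unmethy)),
            all(methy >= 0), all(unmethy >= 0))
  tot <- methy + unmethy
  out <- ifelse(tot == 0, NA_real_, methy / tot)
  out
}

#' Missing-value filter and mean imputation for a beta matrix
#'
#' Probes missing in strictly more than `max_missing_frac` of samples are
#' removed; remaining missing entries are replaced by the probe's mean
#' over its non-missing samples.  The result contains no missing values,
#' and the operation is idempotent.
#'
#' @param beta Probe-by-sample numeric matrix (values in `[0, 1]` or
#'   `NA`).
#' @param max_missing_frac Maximum tolerated missing fraction per probe
#'   (default 0.30; a probe missing in exactly 30% of samples is kept).
#' @return Filtered, imputed matrix.
#' @export
filter_and_impute <- function(beta, max_missing_frac = 0.30) {
  stopifnot(is.matrix(beta), nrow(beta) > 0, ncol(beta) > 0)
  frac <- rowMeans(is.na(beta))
  keep <- frac <= max_missing_frac
  beta <- beta[keep, , drop = FALSE]
  miss <- which(is.na(beta), arr.ind = TRUE)
  if (nrow(miss)) {
    rmeans <- rowMeans(beta, na.rm = TRUE)
    beta[miss] <- rmeans[miss[, 1L]]
  }
  beta
}

#' Strand-aware promoter windows upstream of the TSS
#'
#' The promoter of a feature is the `window`-bp region immediately
#' upstream of its transcription start site: `[TSS - window, TSS)` on the
#' `+` strand, `[TSS, TSS + window)` on the `-` strand (0-based half-open
#' coordinates), clipped at coordinate 0.
#'
#' @param annotation Annotation data.frame as from [read_annotation()].
#' @param window Promoter width in bp (default 2000).
#' @return A `promoter_set`: data.frame with columns `lncRNA`, `chrom`,
#'   `start`, `end`, `strand` and a list-column `probes` (empty until
#'   [map_probes()]).
#' @export
define_promoters <- function(annotation, window = 2000L) {
  stopifnot(all(annotation$strand %in% c("+", "-")), window > 0)
  tss <- annotation$tss
  start <- ifelse(annotation$strand == "+", pmax(0L, tss - window), tss)
  end <- ifelse(annotation$strand == "+", tss, tss + window)
  ps <- data.frame(lncRNA = annotation$feature_id,
                   chrom = annotation$chrom,
                   start = as.integer(start), end = as.integer(end),
                   strand = annotation$strand,
                   stringsAsFactors = FALSE)
  ps$probes <- rep(list(character()), nrow(ps))
  class(ps) <- c("promoter_set", "data.frame")
  ps
}

#' Assign 450K probes to promoter windows
#'
#' A probe belongs to every promoter whose half-open interval contains its
#' position (so a probe at the `+`-strand TSS itself is excluded, and one
#' probe may serve several overlapping promoters).
#'
#' @param promoters A `promoter_set` from [define_promoters()].
#' @param manifest Probe manifest data.frame (`probe_id`, `chrom`, `pos`,
#'   0-based positions).
#' @return The `promoter_set` with its `probes` list-column filled.
#' @export
map_probes <- function(promoters, manifest) {
  if (nrow(manifest) == 0L || nrow(promoters) == 0L) return(promoters)
  # internal half-open [start, end) == 1-based closed [start+1, end]
  prom_gr <- GenomicRanges::GRanges(
    promoters$chrom,
    IRanges::IRanges(promoters$start + 1L, promoters$end))
  probe_gr <- GenomicRanges::GRanges(
    manifest$chrom, IRanges::IRanges(manifest$pos + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(probe_gr, prom_gr)
  lists <- split(manifest$probe_id[S4Vectors::queryHits(hits)],
                 factor(S4Vectors::subjectHits(hits), levels = seq_len(nrow(promoters))))
  promoters$probes <- unname(lists)
  promoters
}

#' Promoter methylation level per lncRNA
#'
#' The methylation level of a lncRNA in a sample is the unweighted mean
#' beta of the probes mapped to its promoter.  lncRNAs whose promoters
#' contain no probes present in the matrix are dropped (their count is
#' reported via the `n_dropped` attribute).
#'
#' @param beta Probe-by-sample matrix (filtered/imputed; no `NA`).
#' @param promoters A probe-mapped `promoter_set`.
#' @return A lncRNA-by-sample matrix with attribute `probe_count` (named
#'   integer vector) and `n_dropped`.
#' @export
promoter_level <- function(beta, promoters) {
  lists <- lapply(promoters$probes, function(p) p[p %in% rownames(beta)])
  keep <- lengths(lists) > 0L
  prof <- t(vapply(which(keep), function(i) {
    colMeans(beta[lists[[i]], , drop = FALSE])
  }, numeric(ncol(beta))))
  rownames(prof) <- promoters$lncRNA[keep]
  colnames(prof) <- colnames(beta)
  attr(prof, "probe_count") <- stats::setNames(lengths(lists)[keep],
                                               promoters$lncRNA[keep])
  attr(prof, "n_dropped") <- sum(!keep)
  prof
}

#' Kolmogorov-Smirnov comparison of tumor vs normal methylation levels
#'
#' Compares the distribution of per-lncRNA mean promoter methylation in
#' tumor samples against the one in normal samples (one value per lncRNA
#' per group) with the two-sample K-S statistic
#' `D = sup |F_T - F_N|` and its asymptotic p-value.
#'
#' @param profile lncRNA-by-sample methylation matrix.
#' @param samples Sample table (`sample_id`, `group`).
#' @return List with `D`, `p`, and the two per-lncRNA mean vectors.
#' @export
ks_compare <- function(profile, samples) {
  tumor <- samples$sample_id[samples$group == "tumor"]
  normal <- samples$sample_id[samples$group == "normal"]
  stopifnot(length(tumor) > 0, length(normal) > 0)
  mt <- rowMeans(profile[, colnames(profile) %in% tumor, drop = FALSE])
  mn <- rowMeans(profile[, colnames(profile) %in% normal, drop = FALSE])
  kt <- suppressWarnings(stats::ks.test(mt, mn, exact = FALSE))
  list(D = unname(kt$statistic), p = unname(kt$p.value),
       tumor_means = mt, normal_means = mn)
}
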