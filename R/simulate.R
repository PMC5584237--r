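#' Configuration for the synthetic multi-omics study
#'
#' Bundles and validates every knob of the generator.  The defaults
#' describe the reference study conditions used throughout the test
#' suite: 40 tumor / 20 normal samples, 200 lncRNAs with 20 planted per
#' methylation-by-expression class, a promoter methylation shift of 0.25
#' beta units, a log2 expression effect of 1.5, ceRNA pairs sharing 3
#' miRNAs with a latent-factor co-expression of 0.6, and a prognostic
#' module wired into the high-down group.
#'
#' @param seed Integer master seed; every modality derives its own
#'   stream from it, so e.g. changing `n_probe` does not perturb the
#'   expression draws.
#' @param n_tumor,n_normal Sample counts.
#' @param n_lnc,n_gene,n_mirna,n_probe Feature counts.
#' @param n_planted Named integer vector of planted lncRNAs per class
#'   (`high_up`, `high_down`, `low_up`, `low_down`).
#' @param delta_beta Planted promoter methylation shift in beta units,
#'   in (0, 1).
#' @param expr_effect Planted log2 expression shift for planted lncRNAs
#'   and their partner mRNAs.
#' @param cerna_overlap Number of miRNAs injected as shared between each
#'   true ceRNA pair.
#' @param cerna_cor Latent-factor correlation between true ceRNA
#'   partners across tumor samples, in (0, 1).
#' @param module_size Number of partner mRNAs forming the high-down and
#'   low-down prognostic modules (these mRNAs become network hubs); the
#'   high-up and low-up planted lncRNAs get one private partner each, so
#'   those sub-networks stay hub-less.
#' @param survival_beta Log-hazard coefficient applied to each
#'   standardized high-down module gene (the low-down module is
#'   non-prognostic by construction).
#' @param censor_rate Expected censoring fraction in [0, 1).
#' @param missing_rate Missing-at-random fraction of beta entries.
#' @param expr_sd Log2-scale expression noise standard deviation.
#' @param promoter_window Promoter width in bp.
#' @param covered_frac Fraction of lncRNA promoters that receive
#'   dedicated probes (>= 0.85 so most promoters are measurable).
#' @param mirna_bg_degree Background miRNA interactions per lncRNA/mRNA.
#' @param base_hazard Baseline exponential hazard (per day).
#' @param chrom_length Optional chromosome length override; the default
#'   sizes the chromosome to fit all features on a 20 kb grid, and a
#'   too-small override is a sizing error.
#' @return A validated `sim_config` list.
#' @export
simulation_config <- function(seed = 1, n_tumor = 40, n_normal = 20,
                              n_lnc = 200, n_gene = 300, n_mirna = 150,
                              n_probe = 2000,
                              n_planted = c(high_up = 20, high_down = 20,
                                            low_up = 20, low_down = 20),
                              delta_beta = 0.25, expr_effect = 1.5,
                              cerna_overlap = 3, cerna_cor = 0.6,
                              module_size = 6, survival_beta = 0.3,
                              censor_rate = 0.3, missing_rate = 0.02,
                              expr_sd = 0.7, promoter_window = 2000,
                              covered_frac = 0.9, mirna_bg_degree = 3,
                              base_hazard = 0.002, chrom_length = NULL) {
  stopifnot(n_tumor >= 2, n_normal >= 2, n_lnc >= 1, n_gene >= 1,
            n_mirna >= 1, n_probe >= 0,
            length(n_planted) == 4,
            setequal(names(n_planted),
                     c("high_up", "high_down", "low_up", "low_down")),
            all(n_planted >= 0), sum(n_planted) <= n_lnc,
            delta_beta > 0, delta_beta < 1,
            expr_effect >= 0, cerna_overlap >= 1, cerna_cor > 0,
            cerna_cor < 1, module_size >= 1,
            censor_rate >= 0, censor_rate < 1,
            missing_rate >= 0, missing_rate < 1,
            covered_frac > 0, covered_frac <= 1)
  cfg <- list(seed = as.integer(seed), n_tumor = n_tumor,
              n_normal = n_normal, n_lnc = n_lnc, n_gene = n_gene,
              n_mirna = n_mirna, n_probe = n_probe,
              n_planted = n_planted[c("high_up", "high_down",
                                      "low_up", "low_down")],
              delta_beta = delta_beta, expr_effect = expr_effect,
              cerna_overlap = cerna_overlap, cerna_cor = cerna_cor,
              module_size = module_size, survival_beta = survival_beta,
              censor_rate = censor_rate, missing_rate = missing_rate,
              expr_sd = expr_sd, promoter_window = promoter_window,
              covered_frac = covered_frac,
              mirna_bg_degree = mirna_bg_degree,
              base_hazard = base_hazard, chrom_length = chrom_length)
  class(cfg) <- "sim_config"
  cfg
}

# Per-modality RNG streams derived from the master seed (kept < 2^31).
stream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k) %% 2147483629)
}

#' Synthetic annotation: lncRNAs, genes and a probe manifest
#'
#' Places all features on a single chromosome on a 20 kb grid with
#' jittered TSS positions (so nearest-gene assignments are
#' unambiguous), assigns strands at random, and drops 450K-style probes
#' so that at least 85% of lncRNA promoters carry probes while some
#' probes fall outside all promoters.  Deterministic for a fixed seed.
#'
#' @param config A `sim_config`.
#' @return List with `lnc` and `gene` annotation data.frames (internal
#'   0-based half-open coordinates, as from [read_annotation()]) and a
#'   probe `manifest` (`probe_id`, `chrom`, `pos`).
#' @export
simulate_annotation <- function(config) {
  set.seed(stream_seed(config$seed, 1))
  slot <- 20000L
  n_feat <- config$n_lnc + config$n_gene
  needed <- (n_feat + 2L) * slot
  chrom_len <- if (is.null(config$chrom_length)) needed
               else config$chrom_length
  if (chrom_len < needed) {
    stop("chromosome too short to place ", n_feat,
         " features without overlap (need >= ", needed, " bp)")
  }
  type <- sample(rep(c("lncRNA", "protein_coding"),
                     c(config$n_lnc, config$n_gene)))
  tss <- (seq_len(n_feat)) * slot + sample(0:2000, n_feat, replace = TRUE)
  strand <- sample(c("+", "-"), n_feat, replace = TRUE)
  len <- sample(3000:8000, n_feat, replace = TRUE)
  start <- ifelse(strand == "+", tss, tss - len)
  end <- ifelse(strand == "+", tss + len, tss)
  idx_l <- which(type == "lncRNA"); idx_g <- which(type == "protein_coding")
  mk <- function(idx, prefix, biotype) {
    data.frame(
      feature_id = sprintf("%s%04d", prefix, seq_along(idx)),
      feature_name = sprintf("%s%04d", toupper(prefix), seq_along(idx)),
      chrom = "chrS", start = as.integer(start[idx]),
      end = as.integer(end[idx]), strand = strand[idx],
      biotype = biotype, tss = as.integer(tss[idx]),
      stringsAsFactors = FALSE)
  }
  lnc <- mk(idx_l, "lnc", "lncRNA")
  gene <- mk(idx_g, "gene", "protein_coding")

  manifest <- data.frame(probe_id = character(), chrom = character(),
                         pos = integer(), stringsAsFactors = FALSE)
  if (config$n_probe > 0) {
    w <- config$promoter_window
    prom_start <- ifelse(lnc$strand == "+", pmax(0L, lnc$tss - w), lnc$tss)
    n_cov <- min(ceiling(config$covered_frac * config$n_lnc),
                 config$n_lnc)
    covered <- sort(sample(config$n_lnc, n_cov))
    per_prom <- max(1L, floor(config$n_probe * 0.7 / n_cov))
    pos <- integer(0)
    covered_done <- integer(0)
    for (i in covered) {
      k <- min(per_prom, w)
      if (length(pos) + k > config$n_probe) break
      pos <- c(pos, prom_start[i] + sample.int(w, k) - 1L)
      covered_done <- c(covered_done, i)
    }
    n_rest <- config$n_probe - length(pos)
    if (n_rest > 0) {
      pos <- c(pos, sample.int(chrom_len, n_rest) - 1L)
    }
    pos <- sort(pos)
    manifest <- data.frame(
      probe_id = sprintf("cg%06d", seq_along(pos)),
      chrom = "chrS", pos = as.integer(pos), stringsAsFactors = FALSE)
  }
  covered_ids <- if (config$n_probe > 0) {
    lnc$feature_id[covered_done]
  } else character()
  list(lnc = lnc, gene = gene, manifest = manifest,
       chrom_length = chrom_len, covered_lnc = covered_ids)
}

# Assign planted classes, ceRNA partners and prognostic module genes.
# Planted lncRNAs are drawn among the designed probe-covered promoters
# (so every planted effect is measurable); that design set depends only
# on the annotation stream, keeping the planted truth - and with it the
# expression stream - invariant to incidental probe-count changes.
build_truth <- function(config, annotation) {
  with_probe <- annotation$covered_lnc
  total_planted <- sum(config$n_planted)
  if (length(with_probe) < total_planted) {
    stop("not enough probe-covered lncRNAs to plant ", total_planted,
         " effects")
  }
  planted <- sample(with_probe, total_planted)
  class_lab <- rep(names(config$n_planted), config$n_planted)
  lnc_class <- data.frame(
    feature_id = annotation$lnc$feature_id,
    class = "null", stringsAsFactors = FALSE)
  lnc_class$class[match(planted, lnc_class$feature_id)] <- class_lab

  genes <- annotation$gene$feature_id
  n_mod <- config$module_size
  n_pair <- config$n_planted[["high_up"]] + config$n_planted[["low_up"]]
  part <- sample(genes, 2 * n_mod + n_pair)
  mod_hd <- part[seq_len(n_mod)]
  mod_ld <- part[n_mod + seq_len(n_mod)]
  solo <- part[2 * n_mod + seq_len(n_pair)]

  by_class <- split(planted, class_lab)[names(config$n_planted)]
  pairs <- rbind(
    if (length(by_class$high_down))
      expand.grid(lncRNA = by_class$high_down, mRNA = mod_hd,
                  group = "high_down", stringsAsFactors = FALSE),
    if (length(by_class$low_down))
      expand.grid(lncRNA = by_class$low_down, mRNA = mod_ld,
                  group = "low_down", stringsAsFactors = FALSE),
    if (length(by_class$high_up))
      data.frame(lncRNA = by_class$high_up,
                 mRNA = solo[seq_along(by_class$high_up)],
                 group = "high_up", stringsAsFactors = FALSE),
    if (length(by_class$low_up))
      data.frame(lncRNA = by_class$low_up,
                 mRNA = solo[length(by_class$high_up) +
                               seq_along(by_class$low_up)],
                 group = "low_up", stringsAsFactors = FALSE))
  rownames(pairs) <- NULL
  surv_beta <- stats::setNames(rep(config$survival_beta, n_mod), mod_hd)
  list(lnc_class = lnc_class, cerna_pairs = pairs,
       module_genes = list(high_down = mod_hd, low_down = mod_ld),
       survival_beta = surv_beta)
}

#' Synthetic promoter methylation (450K-style beta matrix)
#'
#' Each probe gets a baseline mean beta drawn uniformly in [0.3, 0.7]
#' shared by tumor and normal samples; values are Beta-distributed
#' around it (method-of-moments shapes at a fixed precision), so all
#' betas respect the [0, 1] support.  Probes inside the promoters of
#' planted high-methylation lncRNAs have their tumor mean shifted by
#' `+delta_beta` (low-methylation classes by `-delta_beta`), clamped to
#' [0.02, 0.98] with a warning when clamping occurs.  A
#' `missing_rate` fraction of entries is set missing completely at
#' random.  Also assigns the planted truth (classes, ceRNA partners and
#' prognostic module) so downstream modalities can use it.
#'
#' @param config A `sim_config`.
#' @param annotation Output of [simulate_annotation()].
#' @return List with `beta` (probe-by-sample matrix with `NA`s),
#'   `samples` (sample table) and `truth`.
#' @export
simulate_methylation <- function(config, annotation) {
  set.seed(stream_seed(config$seed, 2))
  truth <- build_truth(config, annotation)
  samples <- data.frame(
    sample_id = c(sprintf("T%03d", seq_len(config$n_tumor)),
                  sprintf("N%03d", seq_len(config$n_normal))),
    group = rep(c("tumor", "normal"), c(config$n_tumor, config$n_normal)),
    stringsAsFactors = FALSE)
  n_probe <- nrow(annotation$manifest)
  if (n_probe == 0) {
    beta <- matrix(numeric(0), 0, nrow(samples),
                   dimnames = list(character(), samples$sample_id))
    return(list(beta = beta, samples = samples, truth = truth))
  }
  mu <- stats::runif(n_probe, 0.3, 0.7)

  proms <- map_probes(define_promoters(annotation$lnc,
                                       config$promoter_window),
                      annotation$manifest)
  shift_dir <- numeric(n_probe)   # per-probe tumor shift sign
  cls <- truth$lnc_class$class[match(proms$lncRNA,
                                     truth$lnc_class$feature_id)]
  for (i in seq_len(nrow(proms))) {
    dir <- switch(cls[i], high_up = 1, high_down = 1,
                  low_up = -1, low_down = -1, 0)
    if (dir != 0) {
      idx <- match(proms$probes[[i]], annotation$manifest$probe_id)
      shift_dir[idx] <- dir
    }
  }
  mu_t <- mu + shift_dir * config$delta_beta
  clamped <- mu_t < 0.02 | mu_t > 0.98
  if (any(clamped)) {
    warning(sum(clamped), " probe tumor mean(s) clamped to [0.02, 0.98]")
    mu_t <- pmin(0.98, pmax(0.02, mu_t))
  }
  nu <- 60   # Beta precision: sd ~ sqrt(mu (1 - mu) / (nu + 1))
  draw <- function(means, n_samp) {
    matrix(stats::rbeta(length(means) * n_samp,
                        rep(means * nu, n_samp),
                        rep((1 - means) * nu, n_samp)),
           nrow = length(means))
  }
  beta <- cbind(draw(mu_t, config$n_tumor), draw(mu, config$n_normal))
  dimnames(beta) <- list(annotation$manifest$probe_id, samples$sample_id)
  if (config$missing_rate > 0) {
    miss <- stats::runif(length(beta)) < config$missing_rate
    beta[miss] <- NA_real_
  }
  list(beta = beta, samples = samples, truth = truth)
}

#' Synthetic lncRNA and mRNA expression
#'
#' Log-normal expression: log2 values are a per-feature baseline
#' (uniform in [3, 8]) plus Gaussian noise (`expr_sd`).  Planted
#' lncRNAs are shifted in tumor samples by `expr_effect` log2 units (up
#' for `*_up` classes, down for `*_down`), and their partner mRNAs by
#' the same signed amount.  Each true ceRNA pair additionally loads on
#' a shared latent factor across tumor samples with weight chosen so the
#' expected tumor-sample Pearson correlation is `cerna_cor`; the factor
#' loading's lognormal variance contribution is compensated in the mean
#' so expected linear-scale fold changes stay at `2^(+/- expr_effect)`.
#' The high-down and low-down groups each share one module-wide factor
#' (their partner mRNAs are common to the group), while high-up/low-up
#' pairs get private factors.
#'
#' @param config A `sim_config`.
#' @param annotation Output of [simulate_annotation()].
#' @param truth Truth table from [simulate_methylation()].
#' @return List with `lnc_expr` and `mrna_expr` (linear-scale matrices,
#'   features x samples).
#' @export
simulate_expression <- function(config, annotation, truth) {
  set.seed(stream_seed(config$seed, 3))
  nT <- config$n_tumor; nN <- config$n_normal
  samp <- c(sprintf("T%03d", seq_len(nT)), sprintf("N%03d", seq_len(nN)))
  is_t <- c(rep(TRUE, nT), rep(FALSE, nN))
  sigma <- config$expr_sd
  w <- sigma * sqrt(config$cerna_cor / (1 - config$cerna_cor))
  var_comp <- 0.5 * w^2 * log(2)   # lognormal mean compensation, log2 units

  base_mat <- function(ids) {
    b <- stats::runif(length(ids), 3, 8)
    m <- matrix(stats::rnorm(length(ids) * length(samp), sd = sigma),
                nrow = length(ids), dimnames = list(ids, samp))
    m + b
  }
  lnc <- base_mat(annotation$lnc$feature_id)
  mrna <- base_mat(annotation$gene$feature_id)

  dir_of <- c(high_up = 1, low_up = 1, high_down = -1, low_down = -1)
  cls <- truth$lnc_class
  for (k in names(dir_of)) {
    ids <- cls$feature_id[cls$class == k]
    lnc[ids, is_t] <- lnc[ids, is_t] + dir_of[[k]] * config$expr_effect
  }
  pairs <- truth$cerna_pairs
  part_dir <- dir_of[pairs$group]
  mrna_shift <- tapply(part_dir, pairs$mRNA, function(d) d[1])
  for (g in names(mrna_shift)) {
    mrna[g, is_t] <- mrna[g, is_t] + mrna_shift[[g]] * config$expr_effect
  }

  # shared latent factors over tumor samples
  add_factor <- function(mat, ids, z) {
    mat[ids, is_t] <- mat[ids, is_t] +
      matrix(w * z, length(ids), nT, byrow = TRUE) - var_comp
    mat
  }
  for (grp in c("high_down", "low_down")) {
    ids_l <- cls$feature_id[cls$class == grp]
    if (length(ids_l) == 0) next
    z <- stats::rnorm(nT)
    lnc <- add_factor(lnc, ids_l, z)
    mrna <- add_factor(mrna, truth$module_genes[[grp]], z)
  }
  solo <- pairs[pairs$group %in% c("high_up", "low_up"), , drop = FALSE]
  for (i in seq_len(nrow(solo))) {
    z <- stats::rnorm(nT)
    lnc <- add_factor(lnc, solo$lncRNA[i], z)
    mrna <- add_factor(mrna, solo$mRNA[i], z)
  }
  list(lnc_expr = 2^lnc, mrna_expr = 2^mrna)
}

#' Synthetic miRNA interaction tables
#'
#' Every lncRNA and mRNA receives `mirna_bg_degree` background miRNA
#' interactions drawn uniformly from the miRNA universe; each true ceRNA
#' pair is additionally injected with `cerna_overlap` common miRNAs (one
#' shared set per high-down/low-down module, a private set per
#' high-up/low-up pair).  Tables are deduplicated.
#'
#' @param config A `sim_config`.
#' @param annotation Output of [simulate_annotation()].
#' @param truth Truth table from [simulate_methylation()].
#' @return List with `mir_lnc`, `mir_mrna` (data.frames `mirna_id`,
#'   `target_id`) and `truth_mirnas` (the injected sets per group).
#' @export
simulate_interactions <- function(config, annotation, truth) {
  set.seed(stream_seed(config$seed, 4))
  mirs <- sprintf("mir%04d", seq_len(config$n_mirna))
  bg <- function(targets) {
    data.frame(
      mirna_id = unlist(lapply(targets, function(t)
        sample(mirs, min(config$mirna_bg_degree, length(mirs))))),
      target_id = rep(targets, each = min(config$mirna_bg_degree,
                                          length(mirs))),
      stringsAsFactors = FALSE)
  }
  mir_lnc <- bg(annotation$lnc$feature_id)
  mir_mrna <- bg(annotation$gene$feature_id)

  cls <- truth$lnc_class
  truth_mirnas <- list()
  inject <- function(tab, targets, set) {
    rbind(tab, expand.grid(mirna_id = set, target_id = targets,
                           stringsAsFactors = FALSE))
  }
  for (grp in c("high_down", "low_down")) {
    ids_l <- cls$feature_id[cls$class == grp]
    if (length(ids_l) == 0) next
    set <- sample(mirs, config$cerna_overlap)
    truth_mirnas[[grp]] <- set
    mir_lnc <- inject(mir_lnc, ids_l, set)
    mir_mrna <- inject(mir_mrna, truth$module_genes[[grp]], set)
  }
  solo <- truth$cerna_pairs[truth$cerna_pairs$group %in%
                              c("high_up", "low_up"), , drop = FALSE]
  solo_sets <- list()
  for (i in seq_len(nrow(solo))) {
    set <- sample(mirs, config$cerna_overlap)
    solo_sets[[solo$lncRNA[i]]] <- set
    mir_lnc <- inject(mir_lnc, solo$lncRNA[i], set)
    mir_mrna <- inject(mir_mrna, solo$mRNA[i], set)
  }
  truth_mirnas$pair_sets <- solo_sets
  list(mir_lnc = unique(mir_lnc), mir_mrna = unique(mir_mrna),
       truth_mirnas = truth_mirnas)
}

#' Synthetic clinical survival table
#'
#' Tumor-sample survival times follow an exponential model whose
#' log-hazard is `sum_g beta_g * z_g` over the prognostic module genes
#' (`z_g`: expression standardized across tumor samples) on top of
#' `base_hazard`.  Censoring is independent and uniform on a per-sample
#' interval sized so the expected censoring fraction equals
#' `censor_rate` exactly; `censor_rate = 0` yields all-observed events.
#'
#' @param config A `sim_config`.
#' @param mrna_expr mRNA expression matrix from [simulate_expression()].
#' @param truth Truth table (provides `survival_beta`).
#' @param samples Sample table from [simulate_methylation()].
#' @return Data.frame `sample`, `time` (> 0, days), `event` (0/1).
#' @export
simulate_clinical <- function(config, mrna_expr, truth, samples) {
  set.seed(stream_seed(config$seed, 5))
  tumor <- samples$sample_id[samples$group == "tumor"]
  beta <- truth$survival_beta
  z <- scale(t(mrna_expr[names(beta), tumor, drop = FALSE]))
  lp <- drop(z %*% beta)
  lambda <- config$base_hazard * exp(lp)
  t_ev <- stats::rexp(length(tumor), rate = lambda)
  if (config$censor_rate > 0) {
    # solve (1 - exp(-x)) / x = censor_rate for x = lambda * u
    f <- function(x) (1 - exp(-x)) / x - config$censor_rate
    x <- stats::uniroot(f, c(1e-8, 1e6))$root
    cens <- stats::runif(length(tumor), 0, x / lambda)
    time <- pmin(t_ev, cens)
    event <- as.integer(t_ev <= cens)
  } else {
    time <- t_ev
    event <- rep(1L, length(tumor))
  }
  data.frame(sample = tumor, time = time, event = event,
             stringsAsFactors = FALSE)
}

#' Synthetic ontology-style annotation tables
#'
#' Produces a term-to-gene table, a GO-style `is_a` edge table among the
#' terms, and a disease-to-miRNA table.  Two planted terms collect the
#' nearest genes of the hyper- and hypo-methylated planted lncRNAs (so
#' cis enrichment has signal), and one planted disease collects the
#' miRNAs injected into the high-down ceRNA module (so the
#' miRNA-disease test has signal), each padded with random members.
#'
#' @param config A `sim_config`.
#' @param annotation Output of [simulate_annotation()].
#' @param truth Truth table.
#' @param interactions Output of [simulate_interactions()].
#' @param n_terms,n_diseases Numbers of random background terms and
#'   diseases.
#' @return List with `term2gene`, `isa_edges`, `disease2mirna`.
#' @export
simulate_ontology <- function(config, annotation, truth, interactions,
                              n_terms = 30, n_diseases = 10) {
  set.seed(stream_seed(config$seed, 6))
  genes <- annotation$gene$feature_id
  mirs <- sprintf("mir%04d", seq_len(config$n_mirna))

  term_ids <- sprintf("GO:%07d", seq_len(n_terms))
  t2g <- do.call(rbind, lapply(seq_len(n_terms), function(i) {
    data.frame(term_id = term_ids[i],
               term_name = paste0("process_", i),
               gene = sample(genes, sample(10:30, 1)),
               stringsAsFactors = FALSE)
  }))
  ng <- nearest_gene(annotation$lnc, annotation$gene)
  cls <- truth$lnc_class
  planted_term <- function(classes, id, name) {
    g <- ng$gene[ng$lncRNA %in%
                   cls$feature_id[cls$class %in% classes]]
    g <- unique(g[!is.na(g)])
    data.frame(term_id = id, term_name = name, gene = g,
               stringsAsFactors = FALSE)
  }
  t2g <- rbind(t2g,
               planted_term(c("high_up", "high_down"), "GO:HM0000001",
                            "regulation_hyper"),
               planted_term(c("low_up", "low_down"), "GO:LM0000001",
                            "proliferation_hypo"))
  t2g <- unique(t2g)

  all_terms <- unique(t2g$term_id)
  parent <- sample(all_terms, length(all_terms), replace = TRUE)
  keep <- parent != all_terms & stats::runif(length(all_terms)) < 0.6
  isa <- unique(data.frame(child = all_terms[keep], parent = parent[keep],
                           stringsAsFactors = FALSE))

  diseases <- sprintf("disease_%02d", seq_len(n_diseases))
  d2m <- do.call(rbind, lapply(diseases, function(d) {
    data.frame(disease = d, mirna_id = sample(mirs, sample(10:25, 1)),
               stringsAsFactors = FALSE)
  }))
  planted_mirs <- interactions$truth_mirnas$high_down
  if (!is.null(planted_mirs)) {
    d2m <- rbind(d2m, data.frame(
      disease = "breast_neoplasms",
      mirna_id = unique(c(planted_mirs, sample(mirs, 7))),
      stringsAsFactors = FALSE))
  }
  list(term2gene = unique(t2g), isa_edges = isa,
       disease2mirna = unique(d2m))
}

#' Generate a complete synthetic study
#'
#' Runs every generator modality under its own seed stream and bundles
#' the results.
#'
#' @param config A `sim_config` (default [simulation_config()]).
#' @return A `sim_study` list: `config`, `annotation`, `beta`,
#'   `samples`, `truth`, `lnc_expr`, `mrna_expr`, `interactions`,
#'   `clinical`, `ontology`.
#' @export
simulate_study <- function(config = simulation_config()) {
  ann <- simulate_annotation(config)
  meth <- simulate_methylation(config, ann)
  expr <- simulate_expression(config, ann, meth$truth)
  inter <- simulate_interactions(config, ann, meth$truth)
  clin <- simulate_clinical(config, expr$mrna_expr, meth$truth,
                            meth$samples)
  onto <- simulate_ontology(config, ann, meth$truth, inter)
  structure(list(config = config, annotation = ann, beta = meth$beta,
                 samples = meth$samples, truth = meth$truth,
                 lnc_expr = expr$lnc_expr, mrna_expr = expr$mrna_expr,
                 interactions = inter, clinical = clin, ontology = onto),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat("Synthetic multi-omics study (seed", x$config$seed, "):",
      x$config$n_lnc, "lncRNAs,", x$config$n_gene, "genes,",
      x$config$n_tumor, "tumor /", x$config$n_normal, "normal samples\n")
  cat("  planted:", paste(names(x$config$n_planted),
                          x$config$n_planted, collapse = ", "), "\n")
  invisible(x)
}

#' Write a synthetic study to disk in the pipeline's input formats
#'
#' Emits GTF annotations, the probe manifest, beta/expression matrices,
#' interaction, clinical, sample and ontology tables, plus a
#' `truth.tsv` sidecar with the planted per-lncRNA classes (for tests;
#' not a pipeline input).
#'
#' @param study A `sim_study`.
#' @param dir Output directory (created if absent).
#' @return Named character vector of the written paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_annotation_gtf(study$annotation$lnc, p("lncrna.gtf"))
  write_annotation_gtf(study$annotation$gene, p("genes.gtf"))
  utils::write.table(study$annotation$manifest, p("probes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_matrix(study$beta, p("beta.tsv"))
  write_matrix(study$lnc_expr, p("lnc_expr.tsv"))
  write_matrix(study$mrna_expr, p("mrna_expr.tsv"))
  utils::write.table(study$interactions$mir_lnc, p("mir_lnc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$interactions$mir_mrna, p("mir_mrna.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$clinical, p("clinical.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(study$samples, p("samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(study$ontology$term2gene, p("term2gene.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$ontology$isa_edges, p("isa_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$ontology$disease2mirna, p("disease2mirna.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$truth$lnc_class, p("truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- c(lnc_gtf = "lncrna.gtf", gene_gtf = "genes.gtf",
             manifest = "probes.tsv", beta = "beta.tsv",
             lnc_expr = "lnc_expr.tsv", mrna_expr = "mrna_expr.tsv",
             mir_lnc = "mir_lnc.tsv", mir_mrna = "mir_mrna.tsv",
             clinical = "clinical.tsv", samples = "samples.tsv",
             term2gene = "term2gene.tsv", isa_edges = "isa_edges.tsv",
             disease2mirna = "disease2mirna.tsv", truth = "truth.tsv")
  stats::setNames(file.path(dir, files), names(files))
}
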