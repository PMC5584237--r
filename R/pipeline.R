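#' Validate a pipeline configuration
#'
#' Accepts a named list or a path to a YAML file, injects defaults for
#' every threshold the stages use, range-checks them, and verifies that
#' all referenced input files exist.  The validated configuration is
#' echoed into the run log by [run_pipeline()].
#'
#' Input keys (paths): `lnc_gtf`, `gene_gtf`, `manifest`, `beta`,
#' `lnc_expr`, `mrna_expr`, `mir_lnc`, `mir_mrna`, `clinical`,
#' `samples`, `term2gene`, `isa_edges`, `disease2mirna`.  Parameter keys
#' and defaults: `promoter_window` (2000), `max_missing_frac` (0.3),
#' `q_threshold` (0.05), `delta_threshold` (0.1), `fc_up` (2),
#' `fc_down` (0.5), `pcc_p` (0.01), `min_shared` (2), `hyper_p`
#' (0.01), `hub_threshold` (5), `fdr_threshold` (0.05), `disease_p`
#' (0.05), `max_distance` (1e6), `B` (1000), `seed` (1),
#' `sample_scope` ("tumor"), `outdir`.
#'
#' @param config Named list or YAML file path.
#' @return A validated `pipeline_config` list.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(promoter_window = 2000, max_missing_frac = 0.3,
                   q_threshold = 0.05, delta_threshold = 0.1,
                   fc_up = 2, fc_down = 0.5, pcc_p = 0.01,
                   min_shared = 2, hyper_p = 0.01, hub_threshold = 5,
                   fdr_threshold = 0.05, disease_p = 0.05,
                   max_distance = 1e6, B = 1000, seed = 1,
                   sample_scope = "tumor")
  injected <- setdiff(names(defaults), names(config))
  config[injected] <- defaults[injected]
  config$injected_defaults <- injected

  chk01 <- function(key) {
    v <- config[[key]]
    if (!is.numeric(v) || v < 0 || v > 1) {
      stop("config ", key, " must lie in [0, 1], got ", v)
    }
  }
  for (key in c("q_threshold", "delta_threshold", "max_missing_frac",
                "pcc_p", "hyper_p", "fdr_threshold", "disease_p")) {
    chk01(key)
  }
  if (config$fc_up < 1 || config$fc_down > 1 || config$fc_down <= 0) {
    stop("config fold-change thresholds must satisfy fc_up >= 1 >= fc_down > 0")
  }
  stopifnot(config$promoter_window > 0, config$min_shared >= 1,
            config$hub_threshold >= 1, config$max_distance > 0,
            config$sample_scope %in% c("tumor", "all"),
            identical(config$B, "exact") || config$B >= 1)
  if (is.null(config$outdir)) stop("config needs an outdir")
  paths <- c("lnc_gtf", "gene_gtf", "manifest", "beta", "lnc_expr",
             "mrna_expr", "mir_lnc", "mir_mrna", "clinical", "samples",
             "term2gene", "isa_edges", "disease2mirna")
  missing_keys <- setdiff(paths, names(config))
  if (length(missing_keys)) {
    stop("config lacks input path(s): ",
         paste(missing_keys, collapse = ", "))
  }
  for (key in paths) {
    if (!file.exists(config[[key]])) {
      stop("config input file does not exist: ", key, " = ",
           config[[key]])
    }
  }
  class(config) <- "pipeline_config"
  config
}

#' Run the full analysis pipeline
#'
#' Executes every stage end-to-end: promoter definition and probe
#' mapping, missing-value filtering and imputation, promoter-level
#' methylation with a tumor-vs-normal K-S comparison, SAM differential
#' calling of DMLs/DELs/DEGs, four-way methylation-by-expression
#' classification, background and per-group ceRNA sub-networks with hub
#' extraction, nearest-gene cis enrichment with term networks,
#' miRNA-disease enrichment, and hub-module survival analysis.  All
#' stage outputs are written under `config$outdir` together with a
#' `manifest.tsv` of md5 checksums and a `run.log` of stage-wise
#' feature counts; outputs are byte-identical across runs with the same
#' configuration.
#'
#' @param config A `pipeline_config` (or anything [validate_config()]
#'   accepts).
#' @return An `lmn_run` object collecting every intermediate result.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  out <- config$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c("lncMethNet run log",
                 paste0("injected defaults: ",
                        paste(config$injected_defaults, collapse = ", ")))
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }

  stage <- "io"
  res <- tryCatch({
    ann_lnc <- read_annotation(config$lnc_gtf)
    ann_gene <- read_annotation(config$gene_gtf)
    manifest <- read_manifest(config$manifest)
    samples <- read_samples(config$samples)
    beta <- read_matrix(config$beta)
    lnc_expr <- read_matrix(config$lnc_expr)
    mrna_expr <- read_matrix(config$mrna_expr)
    mir_lnc <- read_interactions(config$mir_lnc, "lncRNA")
    mir_mrna <- read_interactions(config$mir_mrna, "mRNA")
    clinical <- read_clinical(config$clinical)
    term2gene <- read_term2gene(config$term2gene)
    isa_edges <- read_isa_edges(config$isa_edges)
    disease2mirna <- read_disease2mirna(config$disease2mirna)
    note("inputs: ", nrow(ann_lnc), " lncRNAs, ", nrow(ann_gene),
         " genes, ", nrow(manifest), " probes, ",
         sum(samples$group == "tumor"), " tumor / ",
         sum(samples$group == "normal"), " normal samples")

    stage <- "promoter_meth"
    promoters <- map_probes(
      define_promoters(ann_lnc, config$promoter_window), manifest)
    write_promoters_bed(promoters, file.path(out, "promoters.bed"))
    beta_f <- filter_and_impute(beta, config$max_missing_frac)
    note("methylation: ", nrow(beta) - nrow(beta_f),
         " probes dropped by the >", 100 * config$max_missing_frac,
         "% missing filter; ", nrow(beta_f), " retained")
    profile <- promoter_level(beta_f, promoters)
    write_matrix(profile, file.path(out, "promoter_methylation.tsv"))
    ks <- ks_compare(profile, samples)
    note("promoter levels for ", nrow(profile), " lncRNAs (",
         attr(profile, "n_dropped"), " without probes dropped); ",
         sprintf("K-S tumor vs normal D = %.4f, p = %.3g", ks$D, ks$p))

    stage <- "differential"
    common_lnc <- intersect(rownames(profile), rownames(lnc_expr))
    sam_meth <- sam_qvalues(profile[common_lnc, , drop = FALSE], samples,
                            B = config$B, seed = config$seed)
    # expression: SAM statistic on the log2 scale, fold change on the
    # linear scale
    lexp <- lnc_expr[common_lnc, , drop = FALSE]
    sam_lnc <- sam_qvalues(log2(lexp + 1), samples,
                           B = config$B, seed = config$seed + 1,
                           fc_from = lexp)
    sam_mrna <- sam_qvalues(log2(mrna_expr + 1), samples, B = config$B,
                            seed = config$seed + 2, fc_from = mrna_expr)
    dml <- call_dml(sam_meth, config$q_threshold, config$delta_threshold)
    del <- call_del(sam_lnc, config$q_threshold)
    deg <- call_deg(sam_mrna, config$q_threshold, config$fc_up,
                    config$fc_down)
    classes <- classify_lnc(dml, del)
    for (nm in c("dml", "del", "deg", "classes")) {
      utils::write.table(get(nm), file.path(out, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    n_dml <- sum(dml$call != "none"); n_del <- sum(del$call != "none")
    n_deg <- sum(deg$call != "none")
    classified <- classes[classes$group != "unclassified", , drop = FALSE]
    grp_counts <- table(factor(classified$group,
                               levels = c("high-up", "high-down",
                                          "low-up", "low-down")))
    note("differential: ", n_dml, " DMLs, ", n_del, " DELs, ", n_deg,
         " DEGs; ", nrow(classified), " classified lncRNAs (",
         sum(classified$meth_call == "high"), " HMLncs, ",
         sum(classified$meth_call == "low"), " LMLncs)")
    note("groups: ", paste(names(grp_counts), grp_counts,
                           collapse = ", "))

    stage <- "cerna"
    background <- build_background(
      del$feature_id[del$call != "none"],
      deg$feature_id[deg$call != "none"],
      lnc_expr, mrna_expr, mir_lnc, mir_mrna, samples,
      min_shared = config$min_shared, pcc_p = config$pcc_p,
      hyper_p = config$hyper_p, sample_scope = config$sample_scope)
    write_network(background, file.path(out, "background_network.tsv"))
    note("background ceRNA network: ", length(background$lncRNAs),
         " lncRNAs, ", length(background$mRNAs), " mRNAs, ",
         nrow(background$edges), " edges")
    groups <- c("high-up", "high-down", "low-up", "low-down")
    subnets <- lapply(stats::setNames(groups, groups), function(g) {
      seeds <- classified$feature_id[classified$group == g]
      sn <- extract_subnetwork(background, seeds)
      write_network(sn, file.path(out, paste0(
        "subnetwork_", gsub("-", "_", g), ".tsv")))
      sn
    })
    netstats <- lapply(subnets, degrees_and_hubs,
                       hub_threshold = config$hub_threshold)
    group_summary <- data.frame(
      group = groups,
      lncRNAs = vapply(subnets, function(s) length(s$lncRNAs), integer(1)),
      miRNAs = vapply(groups, function(g) {
        seeds <- classified$feature_id[classified$group == g]
        length(unique(mir_lnc$mirna_id[mir_lnc$target_id %in% seeds]))
      }, integer(1)),
      mRNAs = vapply(subnets, function(s) length(s$mRNAs), integer(1)),
      edges = vapply(subnets, function(s) nrow(s$edges), integer(1)),
      mean_lnc_degree = vapply(netstats, function(s)
        round(s$mean_lnc_degree, 4), numeric(1)),
      n_hub_mRNAs = vapply(netstats, function(s) length(s$hubs),
                           integer(1)),
      stringsAsFactors = FALSE)
    utils::write.table(group_summary, file.path(out, "group_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (g in groups) {
      note("sub-network ", g, ": ",
           paste(names(group_summary)[-1],
                 unlist(group_summary[group_summary$group == g, -1]),
                 collapse = ", "))
    }

    stage <- "enrichment"
    universe <- ann_gene$feature_id
    cis <- nearest_gene(ann_lnc, ann_gene, config$max_distance)
    sets <- list(
      HMLnc = classified$feature_id[classified$meth_call == "high"],
      LMLnc = classified$feature_id[classified$meth_call == "low"])
    cis_enrich <- lapply(sets, function(ids) {
      genes <- cis$gene[cis$lncRNA %in% ids & !is.na(cis$gene)]
      enrich(genes, term2gene, universe, config$fdr_threshold)
    })
    term_graphs <- lapply(cis_enrich, function(e) {
      build_term_graph(e$term_id[e$significant], isa_edges)
    })
    gene_freq <- lapply(cis_enrich, gene_term_frequency)
    for (nm in names(cis_enrich)) {
      tab <- cis_enrich[[nm]]
      tab$overlap <- vapply(tab$overlap, paste, character(1),
                            collapse = ",")
      utils::write.table(tab, file.path(out, paste0(
        "cis_enrichment_", nm, ".tsv")), sep = "\t", quote = FALSE,
        row.names = FALSE)
      note("cis enrichment ", nm, ": ",
           sum(cis_enrich[[nm]]$significant), " significant terms; ",
           "term network components (n > 20): ",
           sum(term_graphs[[nm]]$component_sizes > 20))
    }
    disease <- lapply(stats::setNames(groups, groups), function(g) {
      seeds <- classified$feature_id[classified$group == g]
      mirs <- unique(mir_lnc$mirna_id[mir_lnc$target_id %in% seeds])
      mirna_disease_enrich(mirs, disease2mirna, config$disease_p)
    })
    disease_tab <- do.call(rbind, lapply(groups, function(g) {
      cbind(group = g, disease[[g]])
    }))
    utils::write.table(disease_tab, file.path(out,
                                              "mirna_disease_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "survival"
    surv <- lapply(stats::setNames(groups, groups), function(g) {
      hubs <- netstats[[g]]$hubs
      if (length(hubs) == 0) {
        note("survival ", g, ": no hub mRNAs, module not assessable")
        return(NULL)
      }
      rm <- module_survival(hubs, mrna_expr, clinical)
      note("survival ", g, ": ", length(hubs), " hub mRNAs, ",
           sprintf("log-rank chisq = %.4g, p = %.4g",
                   rm$logrank$chisq, rm$logrank$p))
      risk <- data.frame(sample = names(rm$pi), PI = rm$pi,
                         group = rm$group, stringsAsFactors = FALSE)
      utils::write.table(risk, file.path(out, paste0(
        "risk_", gsub("-", "_", g), ".tsv")), sep = "\t",
        quote = FALSE, row.names = FALSE)
      rm
    })
    surv_summary <- do.call(rbind, lapply(groups, function(g) {
      rm <- surv[[g]]
      data.frame(group = g,
                 n_hubs = length(netstats[[g]]$hubs),
                 chisq = if (is.null(rm)) NA else rm$logrank$chisq,
                 p = if (is.null(rm)) NA else rm$logrank$p,
                 note = if (is.null(rm)) "no hub mRNAs" else "",
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(surv_summary, file.path(out,
                                               "survival_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    list(config = config, promoters = promoters, profile = profile,
         ks = ks, sam = list(meth = sam_meth, lnc = sam_lnc,
                             mrna = sam_mrna),
         dml = dml, del = del, deg = deg, classes = classes,
         background = background, subnetworks = subnets,
         netstats = netstats, group_summary = group_summary,
         cis = cis, cis_enrichment = cis_enrich,
         term_graphs = term_graphs, gene_frequency = gene_freq,
         disease_enrichment = disease, survival = surv,
         survival_summary = surv_summary)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         " (partial outputs under ", out, ")", call. = FALSE)
  })

  writeLines(log_lines, file.path(out, "run.log"))
  files <- sort(setdiff(list.files(out), "manifest.tsv"))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out, files))),
    stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(out, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  res$manifest <- manifest
  res$log <- log_lines
  class(res) <- "lmn_run"
  res
}

#' @export
print.lmn_run <- function(x, ...) {
  cat(x$log, sep = "\n")
  invisible(x)
}

#' @export
summary.lmn_run <- function(object, ...) {
  cat("Classified lncRNA groups:\n")
  print(table(object$classes$group))
  cat("\nGroup sub-network summary:\n")
  print(object$group_summary, row.names = FALSE)
  cat("\nSurvival summary:\n")
  print(object$survival_summary, row.names = FALSE)
  invisible(object)
}

#' One-call synthetic demo: simulate, write, run
#'
#' Generates a synthetic study, writes its input files under
#' `dir/input`, and runs the full pipeline into `dir/output`.  This is
#' the canonical quickstart and the end-to-end smoke test.
#'
#' @param dir Working directory for the demo.
#' @param sim_config A `sim_config` for the generator.
#' @param ... Overrides for pipeline thresholds (passed into the
#'   pipeline configuration).
#' @return The `lmn_run`.
#' @export
run_synthetic_demo <- function(dir, sim_config = simulation_config(),
                               ...) {
  study <- simulate_study(sim_config)
  paths <- write_study(study, file.path(dir, "input"))
  config <- c(as.list(paths[setdiff(names(paths), "truth")]),
              list(outdir = file.path(dir, "output"),
                   seed = sim_config$seed, ...))
  run <- run_pipeline(config)
  run$study <- study
  run
}
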