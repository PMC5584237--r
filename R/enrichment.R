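#' Upper-tail hypergeometric enrichment p-value
#'
#' For a universe of `N` items of which `M` carry an annotation, a query
#' of size `n`, and an overlap of `m`, the enrichment p-value is
#' `P = 1 - sum_{i=0}^{m-1} C(M,i) C(N-M, n-i) / C(N,n)`, i.e. the
#' probability of drawing `m` or more annotated items.  Evaluated through
#' the stable hypergeometric tail; `m = 0` gives exactly 1.  Vectorized
#' over all four arguments.
#'
#' @param N,M,n,m Nonnegative integers with `M <= N`, `n <= N`,
#'   `m <= min(M, n)`.
#' @return The p-value(s) in `(0, 1]`.
#' @export
hypergeom_p <- function(N, M, n, m) {
  k <- pmax(length(N), length(M), length(n), length(m))
  N <- rep_len(N, k); M <- rep_len(M, k)
  n <- rep_len(n, k); m <- rep_len(m, k)
  if (any(M > N | n > N)) stop("hypergeom_p: M and n must not exceed N")
  if (any(m > pmin(M, n))) stop("hypergeom_p: overlap m exceeds min(M, n)")
  if (any(c(N, M, n, m) < 0)) stop("hypergeom_p: negative input")
  stats::phyper(m - 1, M, N - M, n, lower.tail = FALSE)
}

#' Nearest protein-coding gene for each lncRNA (cis assignment)
#'
#' Maps every lncRNA to the gene on the same chromosome whose TSS is
#' closest to the lncRNA's TSS, within `max_distance`; equidistant genes
#' are resolved toward the smaller TSS coordinate.  lncRNAs with no gene
#' in range are returned with `gene = NA`.
#'
#' @param lnc_annotation,gene_annotation Annotation data.frames (as from
#'   [read_annotation()]).
#' @param max_distance Maximum TSS-to-TSS distance in bp (default 1e6).
#' @return Data.frame `lncRNA`, `gene`, `distance`.
#' @export
nearest_gene <- function(lnc_annotation, gene_annotation,
                         max_distance = 1e6) {
  if (nrow(gene_annotation) == 0) stop("empty gene annotation")
  out <- lapply(seq_len(nrow(lnc_annotation)), function(i) {
    same <- gene_annotation[gene_annotation$chrom ==
                              lnc_annotation$chrom[i], , drop = FALSE]
    if (nrow(same) == 0) return(c(NA_character_, NA))
    dist <- abs(same$tss - lnc_annotation$tss[i])
    dist_ok <- dist <= max_distance
    if (!any(dist_ok)) return(c(NA_character_, NA))
    same <- same[dist_ok, , drop = FALSE]; dist <- dist[dist_ok]
    best <- which(dist == min(dist))
    if (length(best) > 1) best <- best[which.min(same$tss[best])]
    c(same$feature_id[best], dist[best])
  })
  data.frame(lncRNA = lnc_annotation$feature_id,
             gene = vapply(out, `[`, character(1), 1L),
             distance = as.numeric(vapply(out, `[`, character(1), 2L)),
             stringsAsFactors = FALSE)
}

#' Hypergeometric gene-set enrichment with Benjamini-Hochberg FDR
#'
#' Tests every term of a term-to-gene table against a query gene set with
#' [hypergeom_p()], adjusts across all tested terms with the BH
#' procedure, and flags terms at `fdr <= fdr_threshold`.
#'
#' @param query Character vector of query genes.
#' @param term2gene Data.frame `term_id`, `term_name`, `gene`.
#' @param universe Character vector defining the background gene universe
#'   (query and term genes are intersected with it).
#' @param fdr_threshold Significance cutoff on the adjusted p (default
#'   0.05, inclusive).
#' @return Data.frame sorted by `p`: `term_id`, `term_name`, `N`, `M`,
#'   `n`, `m`, `p`, `fdr`, `significant`, plus a list-column `overlap`
#'   with the overlapping genes.
#' @export
enrich <- function(query, term2gene, universe, fdr_threshold = 0.05) {
  universe <- unique(universe)
  query <- intersect(unique(query), universe)
  term2gene <- unique(term2gene[term2gene$gene %in% universe, ,
                                drop = FALSE])
  terms <- unique(term2gene[, c("term_id", "term_name")])
  N <- length(universe); n <- length(query)
  res <- lapply(seq_len(nrow(terms)), function(i) {
    genes <- term2gene$gene[term2gene$term_id == terms$term_id[i]]
    ov <- intersect(query, genes)
    list(M = length(genes), m = length(ov), overlap = ov)
  })
  M <- vapply(res, `[[`, integer(1), "M")
  m <- vapply(res, `[[`, integer(1), "m")
  p <- hypergeom_p(N, M, n, m)
  out <- data.frame(term_id = terms$term_id, term_name = terms$term_name,
                    N = N, M = M, n = n, m = m, p = p,
                    fdr = stats::p.adjust(p, "BH"),
                    stringsAsFactors = FALSE)
  out$significant <- out$fdr <= fdr_threshold
  out$overlap <- lapply(res, `[[`, "overlap")
  out <- out[order(out$p, out$term_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' miRNA-disease hypergeometric enrichment
#'
#' For a group's miRNA set, tests each disease of a disease-to-miRNA
#' annotation with [hypergeom_p()], with `N` the total number of distinct
#' miRNAs in the annotation table.  Significance is at raw
#' `p < p_threshold` (no multiple-testing adjustment).
#'
#' @param mirnas Character vector of the group's miRNAs.
#' @param disease2mirna Data.frame `disease`, `mirna_id`.
#' @param p_threshold Raw p cutoff (default 0.05, strict).
#' @return Data.frame sorted by `p`: `disease`, `N`, `M`, `n`, `m`, `p`,
#'   `significant`.
#' @export
mirna_disease_enrich <- function(mirnas, disease2mirna,
                                 p_threshold = 0.05) {
  disease2mirna <- unique(disease2mirna)
  universe <- unique(disease2mirna$mirna_id)
  N <- length(universe)
  query <- intersect(unique(mirnas), universe)
  diseases <- sort(unique(disease2mirna$disease))
  M <- vapply(diseases, function(d) {
    length(unique(disease2mirna$mirna_id[disease2mirna$disease == d]))
  }, integer(1))
  m <- vapply(diseases, function(d) {
    length(intersect(query,
                     disease2mirna$mirna_id[disease2mirna$disease == d]))
  }, integer(1))
  out <- data.frame(disease = diseases, N = N, M = M, n = length(query),
                    m = m, p = hypergeom_p(N, M, length(query), m),
                    stringsAsFactors = FALSE)
  out$significant <- out$p < p_threshold
  out <- out[order(out$p, out$disease, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank genes by their frequency across significant terms
#'
#' Counts, for every gene, the number of significant enrichment terms
#' whose query overlap contains it; sorted by descending count with ties
#' broken by gene id.
#'
#' @param enrichment Output of [enrich()] (needs `significant` and
#'   `overlap` columns).
#' @return Data.frame `gene`, `n_terms`.
#' @export
gene_term_frequency <- function(enrichment) {
  sig <- enrichment[enrichment$significant, , drop = FALSE]
  genes <- unlist(sig$overlap)
  if (length(genes) == 0) {
    return(data.frame(gene = character(), n_terms = integer(),
                      stringsAsFactors = FALSE))
  }
  tab <- table(genes)
  out <- data.frame(gene = names(tab), n_terms = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_terms, out$gene, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' GO term network restricted to `is_a` relations
#'
#' Builds the graph induced on a set of significant terms by the child ->
#' parent `is_a` edges, and reports its weakly connected components (the
#' original analysis highlights components with more than 20 nodes).
#'
#' @param terms Character vector of term ids (the nodes).
#' @param isa_edges Data.frame `child`, `parent`.
#' @return List with `nodes`, `edges` (restricted data.frame),
#'   `membership` (named component id per node), `component_sizes`
#'   (descending), `n_components`.
#' @export
build_term_graph <- function(terms, isa_edges) {
  terms <- unique(terms)
  edges <- unique(isa_edges[isa_edges$child %in% terms &
                              isa_edges$parent %in% terms, , drop = FALSE])
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = terms))
  comp <- igraph::components(g, mode = "weak")
  sizes <- sort(as.integer(comp$csize), decreasing = TRUE)
  list(nodes = terms, edges = edges,
       membership = stats::setNames(as.integer(comp$membership),
                                    igraph::V(g)$name),
       component_sizes = sizes, n_components = comp$no)
}
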