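#' Read a GTF-style gene annotation
#'
#' Parses a 9-column GTF file and returns gene-level records with
#' coordinates converted from GTF's 1-based closed convention to the
#' package-internal 0-based half-open convention.  The transcription start
#' site (TSS) of a record is its `start` on the `+` strand and its `end` on
#' the `-` strand (both in internal coordinates).
#'
#' @param path Path to a GTF file.
#' @param biotype Optional character vector; keep only records whose
#'   `gene_type`/`gene_biotype` attribute is one of these values.
#' @param feature_type GTF `feature` column value to keep (default
#'   `"gene"`; gene-level records only).
#' @return A data.frame with columns `feature_id`, `feature_name`, `chrom`,
#'   `start`, `end` (0-based half-open), `strand`, `biotype`, `tss`.
#'   An empty file yields a zero-row data.frame.
#' @export
read_annotation <- function(path, biotype = NULL, feature_type = "gene") {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) {
    return(empty_annotation())
  }
  nfield <- lengths(strsplit(lines, "\t", fixed = TRUE))
  if (any(nfield != 9L)) {
    bad <- which(nfield != 9L)[1L]
    stop("malformed GTF line (expected 9 tab-separated fields) at data line ",
         bad, " of ", path)
  }
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  if (!is.null(md$type)) {
    keep <- as.character(md$type) == feature_type
    gr <- gr[keep]
    md <- S4Vectors::mcols(gr)
  }
  if (is.null(md$gene_id)) {
    stop("GTF attribute field lacks gene_id in ", path)
  }
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(!strand %in% c("+", "-"))) {
    warning(sum(!strand %in% c("+", "-")),
            " record(s) with unknown strand rejected")
    keep <- strand %in% c("+", "-")
    gr <- gr[keep]
    md <- S4Vectors::mcols(gr)
    strand <- strand[keep]
  }
  bt <- if (!is.null(md$gene_type)) as.character(md$gene_type)
        else if (!is.null(md$gene_biotype)) as.character(md$gene_biotype)
        else rep(NA_character_, length(gr))
  ann <- data.frame(
    feature_id = as.character(md$gene_id),
    feature_name = if (!is.null(md$gene_name)) as.character(md$gene_name)
                   else as.character(md$gene_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,   # to 0-based half-open
    end = BiocGenerics::end(gr),
    strand = strand,
    biotype = bt,
    stringsAsFactors = FALSE
  )
  if (!is.null(biotype)) ann <- ann[ann$biotype %in% biotype, , drop = FALSE]
  ann$tss <- ifelse(ann$strand == "+", ann$start, ann$end)
  rownames(ann) <- NULL
  ann
}

empty_annotation <- function() {
  data.frame(feature_id = character(), feature_name = character(),
             chrom = character(), start = integer(), end = integer(),
             strand = character(), biotype = character(), tss = integer(),
             stringsAsFactors = FALSE)
}

#' Read a feature-by-sample numeric matrix from TSV
#'
#' The expected layout is a header row of sample ids, a first column of
#' feature ids, and numeric cells.  The missing-value token (default
#' `"NA"`) becomes `NA`; any other non-numeric cell is an error, as are
#' ragged rows and duplicated feature ids.
#'
#' @param path Path to the TSV file.
#' @param na_token Token representing a missing value.
#' @return A numeric matrix with feature rownames and sample colnames.
#' @export
read_matrix <- function(path, na_token = "NA") {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  if (length(lines) < 1L) stop("empty matrix file: ", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]]
  samples <- header[-1L]
  body <- cells[-1L]
  nf <- lengths(body)
  if (length(body) && any(nf != length(header))) {
    stop("ragged row in ", path, ": data row ", which(nf != length(header))[1L])
  }
  ids <- vapply(body, `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicated feature id in ", path, ": ",
         ids[duplicated(ids)][1L])
  }
  vals <- vapply(body, function(r) {
    x <- r[-1L]
    x[x == na_token] <- NA_character_
    suppressWarnings(as.numeric(x))
  }, numeric(length(samples)))
  raw <- vapply(body, function(r) r[-1L], character(length(samples)))
  bad <- is.na(vals) & !(raw == na_token | is.na(raw))
  if (any(bad)) stop("non-numeric cell in ", path)
  m <- t(matrix(vals, nrow = length(samples),
                dimnames = list(samples, ids)))
  m
}

#' Write a feature-by-sample matrix as TSV
#'
#' Inverse of [read_matrix()]: header row of sample ids, first column of
#' feature ids, `NA` for missing values.  Deterministic byte stream for
#' equal inputs.
#'
#' @param m Numeric matrix with dimnames.
#' @param path Output path.
#' @export
write_matrix <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a miRNA-target interaction table
#'
#' Two tab-separated columns (`mirna_id`, `target_id`); duplicate rows are
#' collapsed to one.
#'
#' @param path Path to the TSV file.
#' @param target_kind Label recorded on the result (`"lncRNA"` or
#'   `"mRNA"`); informational only.
#' @return A deduplicated data.frame with columns `mirna_id`, `target_id`
#'   and attribute `target_kind`.
#' @export
read_interactions <- function(path, target_kind = c("lncRNA", "mRNA")) {
  target_kind <- match.arg(target_kind)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("mirna_id", "target_id") %in% names(tab))) {
    stop("interaction table must have columns mirna_id, target_id: ", path)
  }
  tab <- unique(tab[, c("mirna_id", "target_id")])
  rownames(tab) <- NULL
  attr(tab, "target_kind") <- target_kind
  tab
}

#' Read a clinical survival table
#'
#' Columns `sample`, `time`, `event`; times must be positive and events
#' 0/1.
#'
#' @param path Path to the TSV file.
#' @return A validated data.frame.
#' @export
read_clinical <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "time", "event") %in% names(tab))) {
    stop("clinical table must have columns sample, time, event: ", path)
  }
  if (any(!is.finite(tab$time)) || any(tab$time <= 0)) {
    stop("clinical times must be positive and finite: ", path)
  }
  if (!all(tab$event %in% c(0L, 1L))) {
    stop("clinical event indicator must be 0/1: ", path)
  }
  if (anyDuplicated(tab$sample)) stop("duplicated sample id in ", path)
  tab
}

#' Read a sample-group table
#'
#' Columns `sample_id`, `group` with groups `tumor`/`normal`.
#'
#' @param path Path to the TSV file.
#' @return A validated data.frame.
#' @export
read_samples <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(tab))) {
    stop("sample table must have columns sample_id, group: ", path)
  }
  if (anyDuplicated(tab$sample_id)) stop("duplicated sample id in ", path)
  if (!all(tab$group %in% c("tumor", "normal"))) {
    stop("sample groups must be tumor/normal: ", path)
  }
  tab
}

#' Write a ceRNA network to disk
#'
#' Either a TSV edge list carrying all per-edge statistics, or a Cytoscape
#' SIF file (`lncRNA ceRNA mRNA`).  Edges are emitted in lexicographic
#' (lncRNA, mRNA) order so equal networks produce byte-identical files.
#'
#' @param network A `cerna_network` object (see [build_background()]).
#' @param path Output path.
#' @param format `"tsv"` or `"sif"`.
#' @export
write_network <- function(network, path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  edges <- network$edges
  ord <- order(edges$lncRNA, edges$mRNA, method = "radix")
  edges <- edges[ord, , drop = FALSE]
  if (format == "tsv") {
    utils::write.table(edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    writeLines(paste(edges$lncRNA, "ceRNA", edges$mRNA), path)
  }
  invisible(path)
}

#' Read a ceRNA network edge-list TSV written by [write_network()]
#'
#' @param path Path to the TSV edge list.
#' @return A `cerna_network` object.
#' @export
read_network <- function(path) {
  edges <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("lncRNA", "mRNA", "pcc", "pcc_p", "shared", "hyper_p")
  if (!all(need %in% names(edges))) {
    stop("network edge list must have columns ",
         paste(need, collapse = ", "), ": ", path)
  }
  new_cerna_network(edges, lncRNAs = sort(unique(edges$lncRNA)),
                    mRNAs = sort(unique(edges$mRNA)))
}

#' Write promoter intervals as BED
#'
#' Six-column BED (chrom, start, end, lncRNA id, promoter probe count,
#' strand); BED shares the internal 0-based half-open convention so no
#' coordinate shift is applied.
#'
#' @param promoters A `promoter_set` (see [define_promoters()]).
#' @param path Output path.
#' @export
write_promoters_bed <- function(promoters, path) {
  n_probes <- vapply(promoters$probes, length, integer(1))
  bed <- data.frame(promoters$chrom, promoters$start, promoters$end,
                    promoters$lncRNA, n_probes, promoters$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a probe manifest (probe_id, chrom, pos)
#'
#' Positions are 0-based single-base coordinates.
#'
#' @param path Path to the TSV file.
#' @return A validated data.frame.
#' @export
read_manifest <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "chrom", "pos") %in% names(tab))) {
    stop("probe manifest must have columns probe_id, chrom, pos: ", path)
  }
  if (anyDuplicated(tab$probe_id)) stop("duplicated probe id in ", path)
  tab
}

# Generic two-column table readers used for ontology-style annotations.

#' Read a term-to-gene annotation table (term_id, term_name, gene)
#' @param path Path to the TSV file.
#' @return A deduplicated data.frame.
#' @export
read_term2gene <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("term_id", "term_name", "gene") %in% names(tab))) {
    stop("term table must have columns term_id, term_name, gene: ", path)
  }
  unique(tab)
}

#' Read a disease-to-miRNA annotation table (disease, mirna_id)
#' @param path Path to the TSV file.
#' @return A deduplicated data.frame.
#' @export
read_disease2mirna <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("disease", "mirna_id") %in% names(tab))) {
    stop("disease table must have columns disease, mirna_id: ", path)
  }
  unique(tab)
}

#' Read a GO `is_a` edge table (child, parent)
#' @param path Path to the TSV file.
#' @return A deduplicated data.frame.
#' @export
read_isa_edges <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("child", "parent") %in% names(tab))) {
    stop("is_a edge table must have columns child, parent: ", path)
  }
  unique(tab)
}

#' Write a gene-level annotation as GTF
#'
#' Inverse of [read_annotation()]: internal 0-based half-open coordinates
#' become GTF's 1-based closed ones, with `gene_id`, `gene_name` and
#' `gene_type` attributes.
#'
#' @param annotation Annotation data.frame.
#' @param path Output path.
#' @export
write_annotation_gtf <- function(annotation, path) {
  attrs <- sprintf('gene_id "%s"; gene_name "%s"; gene_type "%s";',
                   annotation$feature_id, annotation$feature_name,
                   annotation$biotype)
  lines <- paste(annotation$chrom, "lncMethNet", "gene",
                 annotation$start + 1L, annotation$end, ".",
                 annotation$strand, ".", attrs, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
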