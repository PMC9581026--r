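#' Two-phenotype expression dataset
#'
#' Bundles a gene-by-sample expression matrix with a binary phenotype label
#' per sample. This is the entry container of the differential-interactome
#' pipeline: all downstream stages (discretization, joint-state counting,
#' prognosis) consume it.
#'
#' Gene and sample identifiers are plain strings, case-sensitive, with no
#' alias resolution; users must harmonize identifiers (e.g. to official gene
#' symbols) upstream.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   unique row and column names. Expression intensities or FPKM-like values.
#' @param phenotype character vector of `"normal"`/`"tumor"` labels, one per
#'   sample; either named by sample id or in column order of `values`.
#' @return An object of class `expression_dataset`: a list with elements
#'   `values` (the matrix) and `phenotype` (named character vector).
#' @examples
#' m <- matrix(rlnorm(12), 3, 4,
#'             dimnames = list(c("A", "B", "C"), paste0("S", 1:4)))
#' ds <- expression_dataset(m, c("normal", "normal", "tumor", "tumor"))
#' n_phenotype(ds)
#' @export
expression_dataset <- function(values, phenotype) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (genes x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene row names and sample column names")
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g))
    stop("duplicate gene id(s): ", paste(dup_g, collapse = ", "))
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    stop("duplicate sample id(s): ", paste(dup_s, collapse = ", "))
  if (!is.null(names(phenotype))) {
    missing_lab <- setdiff(colnames(values), names(phenotype))
    if (length(missing_lab))
      stop("sample(s) missing from phenotype labels: ",
           paste(missing_lab, collapse = ", "))
    phenotype <- phenotype[colnames(values)]
  } else {
    if (length(phenotype) != ncol(values))
      stop("`phenotype` length does not match number of samples")
    names(phenotype) <- colnames(values)
  }
  bad <- setdiff(unique(phenotype), c("normal", "tumor"))
  if (length(bad))
    stop("phenotype labels must be 'normal' or 'tumor'; found: ",
         paste(bad, collapse = ", "))
  tab <- table(factor(phenotype, levels = c("normal", "tumor")))
  if (any(tab < 2))
    stop("need at least 2 samples per phenotype (normal: ", tab[["normal"]],
         ", tumor: ", tab[["tumor"]], ")")
  structure(list(values = values, phenotype = phenotype),
            class = "expression_dataset")
}

#' Phenotype group sizes
#'
#' @param ds an [expression_dataset()] or [discretize_expression()] result.
#' @return Named integer vector with elements `normal` and `tumor`.
#' @export
n_phenotype <- function(ds) {
  ph <- ds$phenotype
  c(normal = sum(ph == "normal"), tumor = sum(ph == "tumor"))
}

#' @export
print.expression_dataset <- function(x, ...) {
  np <- n_phenotype(x)
  cat("<expression_dataset> ", nrow(x$values), " genes x ", ncol(x$values),
      " samples (", np[["normal"]], " normal, ", np[["tumor"]], " tumor)\n",
      sep = "")
  invisible(x)
}

#' Protein-protein interaction network
#'
#' An undirected interaction network stored as a canonical edge table:
#' self-loops are removed, each edge is stored once with `gene_a` <
#' `gene_b` (lexicographic), and duplicates are collapsed.
#'
#' @param edges data.frame with two character columns giving the interacting
#'   gene symbols (any column names; the first two columns are used).
#' @return An object of class `interaction_network`: a data.frame with
#'   columns `gene_a`, `gene_b`.
#' @examples
#' interaction_network(data.frame(a = c("B", "A", "A"), b = c("A", "B", "A")))
#' @export
interaction_network <- function(edges = data.frame(gene_a = character(),
                                                   gene_b = character())) {
  a <- as.character(edges[[1]])
  b <- as.character(edges[[2]])
  if (any(!nzchar(a)) || any(!nzchar(b)))
    stop("empty gene symbol in edge list")
  self <- a == b
  if (any(self))
    message("removed ", sum(self), " self-loop(s)")
  a2 <- pmin(a[!self], b[!self])
  b2 <- pmax(a[!self], b[!self])
  keep <- !duplicated(paste(a2, b2, sep = "\r"))
  out <- data.frame(gene_a = a2[keep], gene_b = b2[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("interaction_network", "data.frame")
  out
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("<interaction_network> ", nrow(x), " edges among ",
      length(unique(c(x$gene_a, x$gene_b))), " proteins\n", sep = "")
  if (nrow(x)) print.data.frame(utils::head(x, 6))
  invisible(x)
}

#' Drug-gene interaction table
#'
#' @param records data.frame with columns `drug` and `gene` (first two
#'   columns are used). Duplicate pairs are collapsed.
#' @return Object of class `drug_gene_table`: data.frame with columns
#'   `drug`, `gene`.
#' @export
drug_gene_table <- function(records) {
  drug <- as.character(records[[1]])
  gene <- as.character(records[[2]])
  if (any(!nzchar(drug)) || any(!nzchar(gene)))
    stop("empty drug or gene identifier")
  keep <- !duplicated(paste(drug, gene, sep = "\r"))
  out <- data.frame(drug = drug[keep], gene = gene[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("drug_gene_table", "data.frame")
  out
}

#' Clinical survival table
#'
#' @param records data.frame with columns `sample`, `time`, `event`
#'   (follow-up time >= 0; event 1 = death observed, 0 = censored).
#' @return Object of class `clinical_table`.
#' @export
clinical_table <- function(records) {
  out <- data.frame(sample = as.character(records[["sample"]]),
                    time = as.numeric(records[["time"]]),
                    event = as.integer(records[["event"]]),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$sample))
    stop("duplicate sample id(s): ",
         paste(unique(out$sample[duplicated(out$sample)]), collapse = ", "))
  if (any(is.na(out$time)) || any(out$time < 0))
    stop("survival times must be non-negative")
  if (!all(out$event %in% c(0L, 1L)))
    stop("event indicators must be 0 (censored) or 1 (death)")
  rownames(out) <- NULL
  class(out) <- c("clinical_table", "data.frame")
  out
}
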