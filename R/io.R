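#' Read a gene expression matrix with phenotype labels
#'
#' The matrix file is TSV with a header row of sample ids and gene symbols in
#' the first column. The labels file is a two-column TSV (header `sample`,
#' `phenotype`) mapping every sample id to `normal` or `tumor`.
#'
#' Genes containing missing values are dropped with a warning: the joint
#' state model downstream needs complete expression columns, so a gene with
#' any missing value in either phenotype cannot be used.
#'
#' @param path_matrix path to the expression TSV.
#' @param path_labels path to the label TSV.
#' @return An [expression_dataset()].
#' @export
read_expression <- function(path_matrix, path_labels) {
  raw <- read.delim(path_matrix, check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (ncol(raw) < 2) stop("expression matrix needs gene column plus samples")
  genes <- raw[[1]]
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stop("duplicate gene id(s): ", paste(dup, collapse = ", "))
  samples <- colnames(raw)[-1]
  vals <- matrix(NA_real_, length(genes), length(samples),
                 dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    col <- raw[[j + 1]]
    empty <- is.na(col) | col == "" | toupper(col) == "NA"
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !empty)
    if (length(bad))
      stop("non-numeric value '", col[bad[1]], "' at gene ", genes[bad[1]],
           ", sample ", samples[j])
    vals[, j] <- num
  }
  labs <- read.delim(path_labels, stringsAsFactors = FALSE,
                     colClasses = "character")
  if (ncol(labs) < 2) stop("label file needs sample and phenotype columns")
  phen <- labs[[2]]
  names(phen) <- labs[[1]]
  missing_lab <- setdiff(samples, names(phen))
  if (length(missing_lab))
    stop("sample(s) missing from phenotype labels: ",
         paste(missing_lab, collapse = ", "))
  incomplete <- apply(vals, 1, anyNA)
  if (any(incomplete)) {
    warning("dropped ", sum(incomplete),
            " gene(s) with missing expression values: ",
            paste(utils::head(genes[incomplete], 5), collapse = ", "),
            if (sum(incomplete) > 5) ", ..." else "")
    vals <- vals[!incomplete, , drop = FALSE]
  }
  expression_dataset(vals, phen[samples])
}

#' Read a protein-protein interaction network
#'
#' Two dialects are supported:
#' \describe{
#'   \item{`simple`}{whitespace/tab-separated file, two gene symbols per
#'     line, no header.}
#'   \item{`biogrid-tab`}{BioGRID TAB-delimited export with a header row;
#'     interactors are taken from the "Official Symbol Interactor A/B"
#'     columns and only rows whose "Experimental System Type" is
#'     `physical` are kept, so the network reflects physically and
#'     experimentally detected interactions.}
#' }
#' Edges are canonicalized (lexicographic order), deduplicated, and
#' self-loops are dropped with a message.
#'
#' @param path input file.
#' @param dialect `"simple"` or `"biogrid-tab"`.
#' @return An [interaction_network()].
#' @export
read_network <- function(path, dialect = c("simple", "biogrid-tab")) {
  dialect <- match.arg(dialect)
  if (dialect == "simple") {
    lines <- readLines(path)
    lines_keep <- which(nzchar(trimws(lines)))
    if (!length(lines_keep))
      return(interaction_network())
    toks <- strsplit(trimws(lines[lines_keep]), "[ \t]+")
    bad <- which(vapply(toks, length, 1L) < 2)
    if (length(bad))
      stop("malformed network line ", lines_keep[bad[1]], ": '",
           lines[lines_keep[bad[1]]], "'")
    interaction_network(data.frame(
      a = vapply(toks, `[[`, "", 1),
      b = vapply(toks, `[[`, "", 2),
      stringsAsFactors = FALSE))
  } else {
    tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    need <- c("Official Symbol Interactor A", "Official Symbol Interactor B")
    if (!all(need %in% colnames(tab)))
      stop("biogrid-tab file lacks columns: ",
           paste(setdiff(need, colnames(tab)), collapse = "; "))
    if ("Experimental System Type" %in% colnames(tab))
      tab <- tab[tab[["Experimental System Type"]] == "physical", ,
                 drop = FALSE]
    if (!nrow(tab)) return(interaction_network())
    interaction_network(tab[, need])
  }
}

#' Restrict a network to genes measured in an expression dataset
#'
#' Keeps only interactions whose both protein endpoints are encoded by genes
#' present in the expression dataset, mirroring the standard filtering of an
#' interactome against the transcriptome at hand.
#'
#' @param net an [interaction_network()].
#' @param ds an [expression_dataset()].
#' @return The filtered [interaction_network()].
#' @export
filter_network_to_expression <- function(net, ds) {
  genes <- rownames(ds$values)
  keep <- net$gene_a %in% genes & net$gene_b %in% genes
  out <- net[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("interaction_network", "data.frame")
  out
}

#' Read a GMT gene-set collection
#'
#' Each line holds a set name, a description, then tab-separated members.
#'
#' @param path GMT file.
#' @return Named list of character vectors (unique members per set).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)))
  toks <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(vapply(toks, length, 1L) < 3)
  if (length(bad))
    stop("malformed GMT line ", keep[bad[1]],
         ": need name, description and at least one member")
  sets <- lapply(toks, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(toks, `[[`, "", 1)
  sets
}

#' Read a drug-gene interaction table
#'
#' TSV with header; the first two columns are the drug identifier and the
#' target gene symbol.
#'
#' @param path TSV file.
#' @return A [drug_gene_table()].
#' @export
read_drug_gene_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(tab) < 2) stop("drug-gene table needs drug and gene columns")
  drug_gene_table(tab)
}

#' Read a clinical survival table
#'
#' TSV with header columns `sample`, `time`, `event`.
#'
#' @param path TSV file.
#' @return A [clinical_table()].
#' @export
read_clinical <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "time", "event")
  if (!all(need %in% colnames(tab)))
    stop("clinical table lacks columns: ",
         paste(setdiff(need, colnames(tab)), collapse = ", "))
  clinical_table(tab)
}

#' Write a module catalog to SIF or GraphML files
#'
#' One file per module, named after the module (e.g. `mMYC.sif`). SIF lines
#' are `hub <direction> partner` triples where the relation is the edge's
#' tumor-direction annotation (`activated`, `repressed` or `both`); the
#' files load directly into Cytoscape. GraphML files carry the same
#' direction as an edge attribute.
#'
#' @param catalog a [build_modules()] catalog.
#' @param dir output directory (created if absent).
#' @param format `"sif"` or `"graphml"`.
#' @return Invisibly, the paths written.
#' @export
write_modules <- function(catalog, dir, format = c("sif", "graphml")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(catalog)) {
    mod <- catalog[[nm]]
    partner <- ifelse(mod$edges$gene_a == mod$hub,
                      mod$edges$gene_b, mod$edges$gene_a)
    if (format == "sif") {
      path <- file.path(dir, paste0(nm, ".sif"))
      writeLines(paste(mod$hub, mod$edges$direction, partner), path)
    } else {
      path <- file.path(dir, paste0(nm, ".graphml"))
      g <- igraph::graph_from_data_frame(
        data.frame(from = mod$hub, to = partner,
                   direction = mod$edges$direction),
        directed = FALSE)
      igraph::write_graph(g, path, format = "graphml")
    }
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read a module catalog from SIF files
#'
#' Inverse of [write_modules()] with `format = "sif"`: every `*.sif` file in
#' `dir` becomes one module; the module name is the file name, the hub is
#' the first column.
#'
#' @param dir directory holding `m<HUB>.sif` files.
#' @return A module catalog (see [build_modules()]).
#' @export
read_modules <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.sif$", full.names = TRUE))
  modules <- lapply(files, function(f) {
    lines <- readLines(f)
    lines <- lines[nzchar(trimws(lines))]
    toks <- strsplit(trimws(lines), "[ \t]+")
    bad <- which(vapply(toks, length, 1L) != 3)
    if (length(bad))
      stop("malformed SIF line ", bad[1], " in ", f)
    hub <- vapply(toks, `[[`, "", 1)
    if (length(unique(hub)) != 1)
      stop("SIF module file ", f, " has more than one hub")
    partner <- vapply(toks, `[[`, "", 3)
    new_dip_module(hub[1], partner, vapply(toks, `[[`, "", 2))
  })
  names(modules) <- sub("\\.sif$", "", basename(files))
  structure(modules, class = "module_catalog", dataset = NULL)
}

#' Write a differential-PPI table to TSV
#'
#' @param dppis a [call_differential_ppis()] result.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_dppis <- function(dppis, path) {
  write.table(as.data.frame(dppis), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
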