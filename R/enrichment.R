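#' Hypergeometric over-representation of a query in a reference set
#'
#' Computes the upper-tail hypergeometric probability of drawing at least
#' `k` members of the reference set when sampling `n = |query|` genes
#' without replacement from a universe of `N` genes containing `K`
#' reference genes:
#'
#' \deqn{p = P[X \ge k], \quad X \sim \mathrm{Hypergeom}(N, K, n)}
#'
#' Query and reference members outside the universe are dropped with a
#' warning. The p-value is also converted to a z-score through the inverse
#' normal cumulative distribution ([p_to_z()]).
#'
#' @param query character vector of query genes (e.g. module members).
#' @param reference character vector, the gene set tested.
#' @param universe character vector, the background.
#' @return One-row data.frame of class `enrichment_result` with columns
#'   `k`, `K`, `n`, `N`, `p`, `z`.
#' @examples
#' hypergeom_overrep(c("A", "B", "C"), c("A", "B", "C", "D", "E"),
#'                   paste0(LETTERS[1:10]))  # p = C(5,3)/C(10,3)
#' @export
hypergeom_overrep <- function(query, reference, universe) {
  universe <- unique(universe)
  if (length(universe) < 1) stop("empty universe")
  query <- unique(query)
  reference <- unique(reference)
  out_q <- setdiff(query, universe)
  out_r <- setdiff(reference, universe)
  if (length(out_q) || length(out_r))
    warning(length(out_q), " query and ", length(out_r),
            " reference gene(s) outside the universe were dropped")
  query <- intersect(query, universe)
  reference <- intersect(reference, universe)
  if (!length(query)) stop("query is empty after universe restriction")
  n_big <- length(universe)
  k_big <- length(reference)
  n_q <- length(query)
  k <- length(intersect(query, reference))
  p <- phyper(k - 1, k_big, n_big - k_big, n_q, lower.tail = FALSE)
  res <- data.frame(k = k, K = k_big, n = n_q, N = n_big, p = p,
                    z = if (p > 0 && p < 1) p_to_z(p) else NA_real_)
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Convert a p-value to a z-score
#'
#' Inverse normal cumulative distribution at `1 - p`: small p-values map to
#' large positive z-scores, `p = 0.5` to 0.
#'
#' @param p p-value(s) strictly inside (0, 1).
#' @return Standard normal quantile(s) at `1 - p`.
#' @export
p_to_z <- function(p) {
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly inside (0, 1)")
  qnorm(p, lower.tail = FALSE)
}

#' Rank drugs against target proteins by hypergeometric association
#'
#' For every drug in the interaction table, tests whether the drug's target
#' gene set is over-represented in the query set of proteins. The universe
#' is the set of all genes occurring in the drug-gene table; the query is
#' restricted to it. Drugs with `p < p_cut` are returned sorted by
#' ascending p.
#'
#' @param targets character vector of target gene symbols (e.g. the
#'   members of a differential module).
#' @param table a [drug_gene_table()].
#' @param p_cut significance cutoff on the hypergeometric p
#'   (default `1e-3`).
#' @return data.frame with one row per retained drug: `drug`, `k`, `K`,
#'   `n`, `N`, `p`, `z`, sorted by `p`. Zero rows when no drug passes.
#' @export
reposition_drugs <- function(targets, table, p_cut = 1e-3) {
  if (!nrow(table)) stop("empty drug-gene table")
  universe <- unique(table$gene)
  query <- intersect(unique(targets), universe)
  empty <- data.frame(drug = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      z = numeric())
  if (!length(query)) return(empty)
  drug_sets <- split(table$gene, table$drug)
  rows <- lapply(names(drug_sets), function(d) {
    res <- suppressWarnings(
      hypergeom_overrep(query, drug_sets[[d]], universe))
    cbind(drug = d, as.data.frame(res))
  })
  out <- do.call(rbind, rows)
  out <- out[out$p < p_cut, , drop = FALSE]
  out <- out[order(out$p, out$drug), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Over-representation analysis of module members against gene sets
#'
#' Applies [hypergeom_overrep()] to every (module, gene set) pair. The
#' module's query set is its hub plus its partner proteins. Pairs with no
#' overlap (`k = 0`) are excluded; remaining rows are filtered at `p_cut`.
#' No multiple-testing correction is applied by default, matching the raw
#' cutoff convention of the underlying method; set `adjust = "BH"` for a
#' Benjamini-Hochberg filter instead.
#'
#' @param catalog a [build_modules()] catalog.
#' @param gene_sets named list of character vectors (e.g. [read_gmt()]).
#' @param universe background gene set (typically all genes of the
#'   expression dataset).
#' @param p_cut significance cutoff (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame with columns `module`, `set`, `k`, `K`, `n`, `N`,
#'   `p`, `z` (and `p_adj` when `adjust = "BH"`), sorted by `p`.
#' @export
ora_modules <- function(catalog, gene_sets, universe, p_cut = 0.05,
                        adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  rows <- list()
  for (nm in names(catalog)) {
    mod <- catalog[[nm]]
    query <- unique(c(mod$hub, mod$members))
    for (set_nm in names(gene_sets)) {
      res <- suppressWarnings(tryCatch(
        hypergeom_overrep(query, gene_sets[[set_nm]], universe),
        error = function(e) NULL))
      if (is.null(res) || res$k == 0) next
      rows[[length(rows) + 1L]] <-
        cbind(module = nm, set = set_nm, as.data.frame(res))
    }
  }
  if (!length(rows))
    return(data.frame(module = character(), set = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p = numeric(), z = numeric()))
  out <- do.call(rbind, rows)
  if (adjust == "BH") {
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
    out <- out[out$p_adj < p_cut, , drop = FALSE]
  } else {
    out <- out[out$p < p_cut, , drop = FALSE]
  }
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}
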