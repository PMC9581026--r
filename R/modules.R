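new_dip_module <- function(hub, partners, directions) {
  edges <- data.frame(gene_a = pmin(hub, partners),
                      gene_b = pmax(hub, partners),
                      direction = as.character(directions),
                      stringsAsFactors = FALSE)
  ord <- order(edges$gene_a, edges$gene_b)
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL
  members <- ifelse(edges$gene_a == hub, edges$gene_b, edges$gene_a)
  structure(list(hub = hub, members = members, edges = edges),
            class = "dip_module")
}

#' @export
print.dip_module <- function(x, ...) {
  cat("<dip_module> hub ", x$hub, ", ", length(x$members), " partner(s)\n",
      sep = "")
  invisible(x)
}

#' Build hub-centred modules around differentially interacting proteins
#'
#' A differentially interacting protein (DIP) is a protein incident to at
#' least `min_edges` distinct differential interactions. Each DIP becomes
#' the hub of a star module containing exactly its incident differential
#' edges; the module is named by prefixing the hub symbol with "m" (e.g.
#' `mMYC`). An edge called in both directions carries the annotation
#' `"both"`; it still counts once towards the hub's incidence.
#'
#' @param dppis a [call_differential_ppis()] result (or any data.frame with
#'   columns `gene_a`, `gene_b`, `direction`).
#' @param min_edges minimum number of distinct differential edges a hub
#'   must carry (default 5).
#' @param dataset optional provenance tag stored on the catalog.
#' @return Object of class `module_catalog`: a named list of `dip_module`
#'   objects (fields `hub`, `members`, `edges`).
#' @export
build_modules <- function(dppis, min_edges = 5, dataset = NULL) {
  dppis <- as.data.frame(dppis)
  if (nrow(dppis) == 0) {
    return(structure(stats::setNames(list(), character(0)),
                     class = "module_catalog", dataset = dataset))
  }
  ekey <- paste(dppis$gene_a, dppis$gene_b, sep = "\r")
  dir_by_edge <- vapply(split(dppis$direction, ekey), function(d) {
    d <- unique(d)
    if (length(d) > 1) "both" else d
  }, "")
  edges <- dppis[!duplicated(ekey), c("gene_a", "gene_b"), drop = FALSE]
  edges$direction <- dir_by_edge[paste(edges$gene_a, edges$gene_b,
                                       sep = "\r")]
  deg <- table(c(edges$gene_a, edges$gene_b))
  hubs <- sort(names(deg)[deg >= min_edges])
  modules <- lapply(hubs, function(h) {
    e <- edges[edges$gene_a == h | edges$gene_b == h, , drop = FALSE]
    partners <- ifelse(e$gene_a == h, e$gene_b, e$gene_a)
    new_dip_module(h, partners, e$direction)
  })
  names(modules) <- paste0("m", hubs, recycle0 = TRUE)
  structure(modules, class = "module_catalog", dataset = dataset)
}

#' @export
print.module_catalog <- function(x, ...) {
  ds <- attr(x, "dataset")
  cat("<module_catalog> ", length(x), " module(s)",
      if (!is.null(ds)) paste0(" [", ds, "]"), "\n", sep = "")
  if (length(x)) {
    sizes <- vapply(x, function(m) nrow(m$edges), 1L)
    print(utils::head(sort(sizes, decreasing = TRUE), 10))
  }
  invisible(x)
}

#' Intersect two module catalogs by common interactions
#'
#' A hub survives when it is a hub in both catalogs and its two modules
#' share at least one interaction; the common module keeps exactly the
#' shared edges. By default an edge only counts as shared when its
#' tumor-direction annotation agrees in both datasets (an interaction
#' activated in one cohort and repressed in the other is not a common
#' signature); edges annotated `"both"` match either direction, and the
#' retained annotation is the agreement.
#'
#' @param a,b module catalogs from [build_modules()].
#' @param require_direction_agreement if `FALSE`, edges are matched on
#'   endpoints only and the annotation is taken from `a`.
#' @return A `module_catalog` of common modules.
#' @export
intersect_catalogs <- function(a, b, require_direction_agreement = TRUE) {
  expand_dir <- function(d)
    if (d == "both") c("activated", "repressed") else d
  hubs <- intersect(vapply(a, `[[`, "", "hub"), vapply(b, `[[`, "", "hub"))
  modules <- list()
  for (h in sort(hubs)) {
    ma <- a[[paste0("m", h)]]
    mb <- b[[paste0("m", h)]]
    ka <- paste(ma$edges$gene_a, ma$edges$gene_b, sep = "\r")
    kb <- paste(mb$edges$gene_a, mb$edges$gene_b, sep = "\r")
    common <- intersect(ka, kb)
    if (!length(common)) next
    ea <- ma$edges[match(common, ka), , drop = FALSE]
    if (require_direction_agreement) {
      db <- mb$edges$direction[match(common, kb)]
      agreed <- mapply(function(d1, d2) {
        both <- intersect(expand_dir(d1), expand_dir(d2))
        if (!length(both)) NA_character_
        else if (length(both) == 2) "both" else both
      }, ea$direction, db, USE.NAMES = FALSE)
      keep <- !is.na(agreed)
      if (!any(keep)) next
      ea <- ea[keep, , drop = FALSE]
      ea$direction <- agreed[keep]
    }
    partners <- ifelse(ea$gene_a == h, ea$gene_b, ea$gene_a)
    modules[[paste0("m", h)]] <- new_dip_module(h, partners, ea$direction)
  }
  structure(modules, class = "module_catalog",
            dataset = paste(attr(a, "dataset"), attr(b, "dataset"),
                            sep = " & "))
}

#' Summarize a module catalog
#'
#' @param catalog a `module_catalog`.
#' @return data.frame with one row per module: `module`, `hub`, `n_edges`,
#'   and `hub_sharing_degree` — the number of *other* modules in which the
#'   hub appears as a member (a measure of how interwoven the hub is with
#'   the rest of the differential interactome).
#' @export
module_summary <- function(catalog) {
  if (!length(catalog))
    return(data.frame(module = character(), hub = character(),
                      n_edges = integer(), hub_sharing_degree = integer()))
  hubs <- vapply(catalog, `[[`, "", "hub")
  member_sets <- lapply(catalog, `[[`, "members")
  data.frame(
    module = names(catalog),
    hub = unname(hubs),
    n_edges = vapply(catalog, function(m) nrow(m$edges), 1L,
                     USE.NAMES = FALSE),
    hub_sharing_degree = vapply(seq_along(catalog), function(i) {
      sum(vapply(member_sets[-i], function(mem) hubs[i] %in% mem, TRUE))
    }, 1L),
    row.names = NULL, stringsAsFactors = FALSE)
}
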