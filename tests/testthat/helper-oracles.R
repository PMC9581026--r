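# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately re-derive quantities by naive loops /
# exhaustive enumeration, never by calling the implementation under test.

# naive per-(edge, state, sample) recount of joint co-expression states
naive_state_counts <- function(dm, net) {
  rows <- list()
  genes <- rownames(dm$levels)
  for (i in seq_len(nrow(net))) {
    a <- net$gene_a[i]; b <- net$gene_b[i]
    if (!(a %in% genes) || !(b %in% genes)) next
    for (sa in -1:1) for (sb in -1:1) {
      n0 <- 0L; n1 <- 0L
      for (s in seq_len(ncol(dm$levels))) {
        if (dm$levels[a, s] == sa && dm$levels[b, s] == sb) {
          if (dm$phenotype[[s]] == "tumor") n1 <- n1 + 1L else n0 <- n0 + 1L
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene_a = a, gene_b = b, state_a = sa, state_b = sb,
        n0 = n0, n1 = n1, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# naive dPPI calling straight from the verbal rule
naive_calls <- function(counts, nn, nt, f_min = 0.2, q_low = 0.1,
                        q_high = 0.9) {
  out <- character(0)
  for (i in seq_len(nrow(counts))) {
    n0 <- counts$n0[i]; n1 <- counts$n1[i]
    if (n0 + n1 == 0) next
    f0 <- n0 / nn; f1 <- n1 / nt
    q <- f1 / (f0 + f1)
    if (max(f0, f1) > f_min) {
      if (q > q_high)
        out <- c(out, paste(counts$gene_a[i], counts$gene_b[i], "activated"))
      if (q < q_low)
        out <- c(out, paste(counts$gene_a[i], counts$gene_b[i], "repressed"))
    }
  }
  sort(unique(out))
}

# random discretized matrix (direct levels, both phenotypes)
random_dm <- function(n_genes, n_normal, n_tumor) {
  genes <- sprintf("g%02d", seq_len(n_genes))
  samples <- sprintf("s%02d", seq_len(n_normal + n_tumor))
  lev <- matrix(sample(-1:1, n_genes * length(samples), replace = TRUE),
                n_genes, length(samples),
                dimnames = list(genes, samples))
  phen <- stats::setNames(rep(c("normal", "tumor"), c(n_normal, n_tumor)),
                          samples)
  structure(list(levels = lev, phenotype = phen, band_width_sd = 0.5,
                 reference = "all"),
            class = "discretized_matrix")
}

random_net <- function(genes, n_edges) {
  pairs <- t(combn(genes, 2))
  idx <- sample(nrow(pairs), min(n_edges, nrow(pairs)))
  interaction_network(data.frame(a = pairs[idx, 1], b = pairs[idx, 2]))
}

# exhaustive-enumeration upper-tail hypergeometric probability:
# reference = elements 1..K of a universe 1..N, draws of size n
enum_overlap_counts <- function(n_universe, n_draw) {
  combn(n_universe, n_draw)
}
enum_hypergeom_p <- function(subs, k_ref, k) {
  mean(colSums(subs <= k_ref) >= k)
}

# textbook log-rank observed/expected decomposition by explicit loops
manual_logrank_oe <- function(time, event, group) {
  group <- as.character(group)
  obs <- c(low = 0, high = 0)
  expd <- c(low = 0, high = 0)
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    dying <- event == 1 & time == t
    for (g in c("low", "high")) {
      obs[g] <- obs[g] + sum(dying & group == g)
      expd[g] <- expd[g] + sum(dying) * sum(at_risk & group == g) /
        sum(at_risk)
    }
  }
  list(obs = obs, expected = expd)
}

# random dPPI table over a gene alphabet, for module-algebra tests
random_dppis <- function(genes, n_edges) {
  pairs <- t(combn(genes, 2))
  idx <- sample(nrow(pairs), min(n_edges, nrow(pairs)))
  data.frame(gene_a = pairs[idx, 1], gene_b = pairs[idx, 2],
             direction = sample(c("activated", "repressed"), length(idx),
                                replace = TRUE),
             stringsAsFactors = FALSE)
}

# strip class/attributes so catalogs can be compared structurally
catalog_contents <- function(catalog) {
  lapply(unclass(catalog)[sort(names(catalog))], function(m)
    list(hub = m$hub, members = m$members,
         edges = as.data.frame(m$edges)))
}

# small ready-made expression dataset: 3 genes x 4 samples
tiny_dataset <- function() {
  m <- matrix(c(1, 2, 3, 4,
                8, 6, 4, 2,
                5, 5, 5, 5), 3, 4, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), paste0("s", 1:4)))
  expression_dataset(m, c("normal", "normal", "tumor", "tumor"))
}
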