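#' Count joint co-expression states per interaction
#'
#' For each network edge (A, B) in canonical order, each sample contributes
#' one of nine joint states (level of A, level of B) with levels in
#' \{-1, 0, +1\}. Occurrences are counted separately in the normal group
#' (N0, out of NN samples) and the tumor group (N1, out of NT samples), and
#' normalized to observation frequencies f0 = N0/NN and f1 = N1/NT so that
#' unequal group sizes are comparable. The q statistic — the estimated
#' probability that the state belongs to the tumor phenotype — is
#'
#' \deqn{q = \frac{N_1/N_T}{N_0/N_N + N_1/N_T}}
#'
#' and is undefined (NA) for states observed in neither group.
#'
#' Edges with an endpoint absent from the discretized matrix are skipped
#' with a message.
#'
#' @param dm a [discretize_expression()] result.
#' @param net an [interaction_network()].
#' @return Object of class `state_counts`: a data.frame with 9 rows per
#'   retained edge and columns `gene_a`, `gene_b`, `state_a`, `state_b`,
#'   `n0`, `n1`, `f0`, `f1`, `q`; attributes `n_normal`, `n_tumor`.
#' @export
count_joint_states <- function(dm, net) {
  genes <- rownames(dm$levels)
  keep <- net$gene_a %in% genes & net$gene_b %in% genes
  if (any(!keep))
    message(sum(!keep), " edge(s) skipped: endpoint not in matrix")
  net <- net[keep, , drop = FALSE]
  is_t <- dm$phenotype == "tumor"
  nn <- sum(!is_t)
  nt <- sum(is_t)
  n_e <- nrow(net)
  if (n_e == 0) {
    out <- data.frame(gene_a = character(), gene_b = character(),
                      state_a = integer(), state_b = integer(),
                      n0 = integer(), n1 = integer(),
                      f0 = numeric(), f1 = numeric(), q = numeric())
  } else {
    la <- dm$levels[net$gene_a, , drop = FALSE]
    lb <- dm$levels[net$gene_b, , drop = FALSE]
    code <- (la + 1L) * 3L + (lb + 1L) + 1L  # 1..9
    count9 <- function(m) t(apply(m, 1, tabulate, nbins = 9L))
    n0 <- count9(code[, !is_t, drop = FALSE])
    n1 <- count9(code[, is_t, drop = FALSE])
    out <- data.frame(
      gene_a = rep(net$gene_a, each = 9L),
      gene_b = rep(net$gene_b, each = 9L),
      state_a = rep(rep(-1:1, each = 3L), times = n_e),
      state_b = rep.int(rep(-1:1, times = 3L), n_e),
      n0 = as.integer(t(n0)),
      n1 = as.integer(t(n1)),
      stringsAsFactors = FALSE)
    out$f0 <- out$n0 / nn
    out$f1 <- out$n1 / nt
    out$q <- compute_q(out$n0, out$n1, nn, nt)
  }
  structure(out, class = c("state_counts", "data.frame"),
            n_normal = nn, n_tumor = nt)
}

#' The q statistic of a joint state
#'
#' Estimated probability that a joint co-expression state belongs to the
#' tumor phenotype, from its group-normalized observation frequencies:
#' `q = (n1/n_tumor) / (n0/n_normal + n1/n_tumor)`. Undefined (NA) when the
#' state was observed in neither group.
#'
#' @param n0,n1 occurrence counts in the normal and tumor group (vectors).
#' @param n_normal,n_tumor group sizes (NN, NT), both > 0.
#' @return Numeric vector of q values in \[0, 1\], NA where undefined.
#' @examples
#' compute_q(2, 10, 10, 20)  # 0.5/(0.2+0.5)
#' @export
compute_q <- function(n0, n1, n_normal, n_tumor) {
  stopifnot(n_normal > 0, n_tumor > 0)
  f0 <- n0 / n_normal
  f1 <- n1 / n_tumor
  ifelse(f0 + f1 > 0, f1 / (f0 + f1), NA_real_)
}

#' Call differential protein-protein interactions
#'
#' A joint state supports a differential call when it is observed in more
#' than `f_min` of either group's samples (`max(f0, f1) > f_min`) and its q
#' value is extreme: `q > q_high` marks the state — and hence the
#' interaction — as *activated* in the tumor phenotype, `q < q_low` as
#' *repressed*. All comparisons are strict. An edge yields one differential
#' PPI per direction with at least one supporting state, so an edge can
#' appear in both directions (no tie-break is applied).
#'
#' @param counts a [count_joint_states()] table.
#' @param f_min minimum observation frequency in either phenotype
#'   (default 0.20).
#' @param q_low,q_high q bounds for repressed / activated calls
#'   (defaults 0.10 and 0.90).
#' @return Object of class `dppi_set`: a data.frame with one row per
#'   (edge, direction) and columns `gene_a`, `gene_b`, `direction`,
#'   `state_a`, `state_b` (the most extreme supporting state), `q`, `f0`,
#'   `f1`, `n_states` (number of supporting states). The full supporting
#'   state table is in `attr(, "support")`.
#' @export
call_differential_ppis <- function(counts, f_min = 0.20, q_low = 0.10,
                                   q_high = 0.90) {
  stopifnot(q_low < q_high)
  # q <> threshold evaluated in cross-multiplied integer form: with the
  # thresholds taken as rationals over 1e6, q > q_high on counts is
  # n1 NN (D - P) > P n0 NT, exact in doubles for any realistic cohort.
  # The quotient form can disagree with its mirror by one ulp right at the
  # boundary, which would break the exact phenotype-swap antisymmetry
  # (swapping labels must map q to 1 - q and exchange the two call sets).
  d_res <- 1e6
  p_high <- round(q_high * d_res)
  p_low <- round(q_low * d_res)
  nn <- attr(counts, "n_normal")
  nt <- attr(counts, "n_tumor")
  n0 <- as.numeric(counts$n0)
  n1 <- as.numeric(counts$n1)
  observed <- n0 + n1 > 0
  frequent <- pmax(counts$f0, counts$f1) > f_min
  act <- observed & frequent &
    n1 * nn * (d_res - p_high) > p_high * n0 * nt
  rep_ <- observed & frequent &
    n1 * nn * (d_res - p_low) < p_low * n0 * nt
  sup <- as.data.frame(counts[act | rep_, , drop = FALSE])
  if (nrow(sup)) {
    sup$direction <- ifelse(act[act | rep_], "activated", "repressed")
    # most extreme q first within each (edge, direction)
    ord <- order(sup$gene_a, sup$gene_b, sup$direction, -abs(sup$q - 0.5))
    sup <- sup[ord, , drop = FALSE]
    key <- paste(sup$gene_a, sup$gene_b, sup$direction, sep = "\r")
    first <- !duplicated(key)
    dppis <- sup[first, c("gene_a", "gene_b", "direction",
                          "state_a", "state_b", "q", "f0", "f1")]
    dppis$n_states <- as.integer(table(key)[key[first]])
  } else {
    sup$direction <- character(0)
    dppis <- data.frame(gene_a = character(), gene_b = character(),
                        direction = character(), state_a = integer(),
                        state_b = integer(), q = numeric(), f0 = numeric(),
                        f1 = numeric(), n_states = integer())
  }
  rownames(dppis) <- NULL
  rownames(sup) <- NULL
  structure(dppis, class = c("dppi_set", "data.frame"), support = sup,
            thresholds = c(f_min = f_min, q_low = q_low, q_high = q_high))
}

#' @export
print.dppi_set <- function(x, ...) {
  cat("<dppi_set> ", nrow(x), " edge-direction call(s): ",
      sum(x$direction == "activated"), " activated, ",
      sum(x$direction == "repressed"), " repressed (",
      length(unique(paste(x$gene_a, x$gene_b))), " distinct edges)\n",
      sep = "")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6))
  invisible(x)
}
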