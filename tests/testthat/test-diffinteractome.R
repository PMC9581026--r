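dm_from_levels <- function(la, lb, n_normal) {
  n <- length(la)
  lev <- rbind(A = as.integer(la), B = as.integer(lb))
  colnames(lev) <- sprintf("s%02d", seq_len(n))
  phen <- stats::setNames(rep(c("normal", "tumor"), c(n_normal, n - n_normal)),
                          colnames(lev))
  structure(list(levels = lev, phenotype = phen, band_width_sd = 0.5,
                 reference = "all"),
            class = "discretized_matrix")
}
net_ab <- interaction_network(data.frame(a = "A", b = "B"))

test_that("joint states are counted per edge, per phenotype", {
  # all 8 samples sit in [1 1]
  dm <- dm_from_levels(rep(1, 8), rep(1, 8), n_normal = 3)
  counts <- count_joint_states(dm, net_ab)
  expect_equal(nrow(counts), 9L)
  expect_equal(counts$n0[counts$state_a == 1 & counts$state_b == 1], 3L)
  expect_equal(counts$n1[counts$state_a == 1 & counts$state_b == 1], 5L)
  expect_equal(sum(counts$n0), 3L)
  expect_equal(sum(counts$n1), 5L)

  # hand-counted mixed case: normal (1,1), (-1,0); tumor (1,1), (1,1)
  dm2 <- dm_from_levels(c(1, -1, 1, 1), c(1, 0, 1, 1), n_normal = 2)
  c2 <- count_joint_states(dm2, net_ab)
  get <- function(sa, sb, col)
    c2[[col]][c2$state_a == sa & c2$state_b == sb]
  expect_equal(get(1, 1, "n0"), 1L)
  expect_equal(get(1, 1, "n1"), 2L)
  expect_equal(get(-1, 0, "n0"), 1L)
  expect_equal(get(-1, 0, "n1"), 0L)

  # empty network
  empty <- interaction_network()
  expect_equal(nrow(count_joint_states(dm, empty)), 0L)

  # edge with missing endpoint is skipped with a message
  net_ax <- interaction_network(data.frame(a = c("A", "A"), b = c("B", "X")))
  expect_message(cx <- count_joint_states(dm, net_ax), "skipped")
  expect_equal(nrow(cx), 9L)
})

test_that("q follows the normalized frequency formula", {
  expect_equal(compute_q(0, 3, 10, 10), 1)
  expect_equal(compute_q(4, 8, 10, 20), 0.5)    # f0 = f1
  expect_equal(compute_q(2, 10, 10, 20), 0.5 / 0.7, tolerance = 1e-6)
  expect_true(is.na(compute_q(0, 0, 10, 10)))
  # monotonicity: increasing in n1 at fixed n0, decreasing in n0 at fixed n1
  q_n1 <- compute_q(3, 0:20, 10, 20)
  expect_true(all(diff(q_n1) > 0))
  q_n0 <- compute_q(0:10, 5, 10, 20)
  expect_true(all(diff(q_n0) < 0))
  expect_true(all(q_n1 >= 0 & q_n1 <= 1))
})

test_that("dPPI calling applies strict thresholds per direction", {
  mk_counts <- function(n0, n1, nn, nt) {
    df <- data.frame(gene_a = "A", gene_b = "B", state_a = 1L, state_b = 1L,
                     n0 = n0, n1 = n1, f0 = n0 / nn, f1 = n1 / nt,
                     q = compute_q(n0, n1, nn, nt))
    structure(df, class = c("state_counts", "data.frame"),
              n_normal = nn, n_tumor = nt)
  }
  # f1 = 0.25, f0 = 0 -> q = 1: activated
  act <- call_differential_ppis(mk_counts(0, 5, 20, 20))
  expect_equal(act$direction, "activated")
  # f0 = f1 = 0.5 -> q = 0.5: no call
  expect_equal(nrow(call_differential_ppis(mk_counts(10, 10, 20, 20))), 0L)
  # q below q_low but max frequency 0.15 < 0.20: no call
  low_f <- mk_counts(15, 1, 100, 100)
  expect_lt(low_f$q, 0.10)
  expect_equal(nrow(call_differential_ppis(low_f)), 0L)
  # boundary is strict: f exactly 0.20 does not qualify
  at_f <- mk_counts(0, 4, 20, 20)
  expect_equal(nrow(call_differential_ppis(at_f)), 0L)
})

test_that("an edge can be called in both directions, reported separately", {
  # state [1 1] activated, state [-1 -1] repressed on the same edge
  la <- c(rep(-1, 8), rep(1, 8))
  lb <- c(rep(-1, 8), rep(1, 8))
  # normal: 8 samples in [-1 -1]; tumor: 8 samples in [1 1]
  dm <- dm_from_levels(la, lb, n_normal = 8)
  dppis <- call_differential_ppis(count_joint_states(dm, net_ab))
  expect_equal(sort(dppis$direction), c("activated", "repressed"))
  expect_equal(unique(dppis$gene_a), "A")
})

test_that("vectorized counting matches the naive per-sample oracle", {
  set.seed(101)
  for (rep in 1:6) {
    n_genes <- sample(4:8, 1)
    nn <- sample(3:6, 1); nt <- sample(3:6, 1)
    dm <- random_dm(n_genes, nn, nt)
    net <- random_net(rownames(dm$levels), sample(3:10, 1))
    fast <- count_joint_states(dm, net)
    slow <- naive_state_counts(dm, net)
    fast_df <- as.data.frame(fast)[, c("gene_a", "gene_b", "state_a",
                                       "state_b", "n0", "n1")]
    ord_f <- order(fast_df$gene_a, fast_df$gene_b, fast_df$state_a,
                   fast_df$state_b)
    ord_s <- order(slow$gene_a, slow$gene_b, slow$state_a, slow$state_b)
    expect_equal(fast_df[ord_f, ], slow[ord_s, ], ignore_attr = TRUE)
    # per-edge counts partition each phenotype
    by_edge <- split(fast_df, paste(fast_df$gene_a, fast_df$gene_b))
    expect_true(all(vapply(by_edge, function(e) sum(e$n0), 1) == nn))
    expect_true(all(vapply(by_edge, function(e) sum(e$n1), 1) == nt))
    # calls match the rule applied naively
    dp <- call_differential_ppis(fast)
    expect_equal(sort(unique(paste(dp$gene_a, dp$gene_b, dp$direction))),
                 naive_calls(slow, nn, nt))
  }
})

test_that("swapping phenotype labels maps q to 1 - q and swaps directions", {
  set.seed(77)
  dm <- random_dm(8, 6, 9)
  net <- random_net(rownames(dm$levels), 12)
  swap <- dm
  swap$phenotype <- ifelse(dm$phenotype == "normal", "tumor", "normal")
  names(swap$phenotype) <- names(dm$phenotype)
  c1 <- count_joint_states(dm, net)
  c2 <- count_joint_states(swap, net)
  expect_equal(c2$n0, c1$n1)
  def <- !is.na(c1$q)
  expect_equal(c2$q[def], 1 - c1$q[def])
  d1 <- call_differential_ppis(c1)
  d2 <- call_differential_ppis(c2)
  flip <- function(d) ifelse(d == "activated", "repressed", "activated")
  expect_setequal(paste(d1$gene_a, d1$gene_b, d1$direction),
                  paste(d2$gene_a, d2$gene_b, flip(d2$direction)))
})
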