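#' Run the differential-interactome pipeline on one dataset
#'
#' Convenience wrapper chaining the per-dataset stages: restrict the
#' network to measured genes, discretize expression into three levels,
#' count the nine joint co-expression states per interaction, compute q,
#' call differential interactions, and build hub-centred modules.
#'
#' @param ds an [expression_dataset()].
#' @param net an [interaction_network()].
#' @param band_width_sd,reference see [discretize_expression()].
#' @param f_min,q_low,q_high see [call_differential_ppis()].
#' @param min_edges see [build_modules()].
#' @param dataset optional provenance tag for the module catalog.
#' @return Object of class `diffint_run`: list with `network` (filtered),
#'   `discretized`, `state_counts`, `dppis`, `modules`.
#' @examples
#' sim <- simulate_expression(simulation_config(
#'   n_genes = 60, n_normal = 20, n_tumor = 20, n_edges = 30,
#'   n_activated = 5, n_repressed = 5, seed = 7))
#' run <- run_differential_interactome(sim$dataset, sim$network)
#' run$dppis
#' @export
run_differential_interactome <- function(ds, net, band_width_sd = 0.5,
                                         reference = "all", f_min = 0.20,
                                         q_low = 0.10, q_high = 0.90,
                                         min_edges = 5, dataset = NULL) {
  net_f <- filter_network_to_expression(net, ds)
  dm <- discretize_expression(ds, band_width_sd = band_width_sd,
                              reference = reference)
  counts <- count_joint_states(dm, net_f)
  dppis <- call_differential_ppis(counts, f_min = f_min, q_low = q_low,
                                  q_high = q_high)
  modules <- build_modules(dppis, min_edges = min_edges, dataset = dataset)
  structure(list(network = net_f, discretized = dm, state_counts = counts,
                 dppis = dppis, modules = modules),
            class = "diffint_run")
}

#' @export
print.diffint_run <- function(x, ...) {
  cat("<diffint_run>\n")
  print(x$dppis)
  print(x$modules)
  invisible(x)
}
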