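#' Configuration for the synthetic two-phenotype study generator
#'
#' Collects every knob of the synthetic-data generator in one validated
#' object. Defaults describe a desk-scale two-phenotype cohort: 500 genes,
#' 50 normal and 50 tumor samples, a 300-edge interaction network with 20
#' planted activated and 20 planted repressed differential interactions
#' arranged as hub stars, signal occupancy 0.8 in the enriched phenotype
#' and 0.02 in the other.
#'
#' Planted interactions are arranged as stars of `star_size` edges around
#' dedicated hub genes, so the module-construction stage is exercised by
#' the generator's output. Planted genes are used by exactly one star, and
#' decoy edges connect only unplanted genes, so every unplanted edge is a
#' genuine null for false-call accounting.
#'
#' @param n_genes number of genes.
#' @param n_normal,n_tumor samples per phenotype.
#' @param n_edges total network edges (planted + decoy).
#' @param n_activated,n_repressed number of planted differential edges per
#'   direction.
#' @param star_size edges per planted hub star.
#' @param tumor_rate target occupancy of the planted joint state `[1 1]`
#'   in the phenotype where it is enriched: tumor samples for activated
#'   edges, normal samples for repressed edges.
#' @param normal_rate occupancy in the other phenotype (leakage).
#' @param meanlog_range per-gene log-normal location parameters are drawn
#'   uniformly from this range.
#' @param sdlog log-normal scale parameter, shared by all genes.
#' @param push_shift_sd how far (in gene log-sd units) a planted sample's
#'   value is shifted into the high tail. The default 6 keeps pushed
#'   values above the pooled mean + 0.5 sd discretization threshold even
#'   when nearly half of all samples carry the signal.
#' @param push_sdlog log-scale jitter of pushed values. Kept small
#'   relative to `push_shift_sd`: when a large fraction of samples carries
#'   the signal, the pushed cluster itself dominates the pooled standard
#'   deviation, and the cluster must be tight for its members to clear the
#'   `mean + 0.5 sd` discretization bound.
#' @param baseline_hazard,censoring_rate survival generator defaults
#'   (see [simulate_survival()]).
#' @param n_decoy_drugs,decoy_set_size drug-table generator defaults
#'   (see [simulate_drug_table()]).
#' @param seed integer random seed recorded in all outputs.
#' @return Object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(n_genes = 500, n_normal = 50, n_tumor = 50,
                              n_edges = 300, n_activated = 20,
                              n_repressed = 20, star_size = 5,
                              tumor_rate = 0.8, normal_rate = 0.02,
                              meanlog_range = c(1, 4), sdlog = 0.5,
                              push_shift_sd = 6, push_sdlog = 0.05,
                              baseline_hazard = 0.1, censoring_rate = 0.2,
                              n_decoy_drugs = 50, decoy_set_size = 5,
                              seed = 1L) {
  stopifnot(tumor_rate >= 0, tumor_rate <= 1,
            normal_rate >= 0, normal_rate <= 1,
            censoring_rate >= 0, censoring_rate <= 1,
            n_activated >= 0, n_repressed >= 0, star_size >= 1,
            n_edges >= n_activated + n_repressed,
            n_normal >= 2, n_tumor >= 2, sdlog > 0)
  n_hubs <- ceiling(n_activated / star_size) +
    ceiling(n_repressed / star_size)
  n_planted_genes <- n_hubs + n_activated + n_repressed
  if (n_planted_genes > n_genes)
    stop("not enough genes for the requested planted structure")
  structure(as.list(environment()), class = "simulation_config")
}

# split n edges into stars of at most `size` edges
star_sizes <- function(n, size) {
  if (n == 0) return(integer(0))
  full <- n %/% size
  rest <- n %% size
  c(rep(size, full), if (rest) rest)
}

#' Simulate a two-phenotype expression dataset with planted differential
#' interactions
#'
#' Background expression is i.i.d. log-normal per gene. For every planted
#' star and every sample of the enriched phenotype (tumor for activated
#' edges, normal for repressed edges), with probability `tumor_rate` the
#' hub and all its partners are pushed into the high tail of their gene
#' distributions, realizing the joint state `[1 1]` on every edge of the
#' star; samples of the other phenotype are pushed with probability
#' `normal_rate`. Pushing manipulates raw values, not discretized levels,
#' so the discretization stage is genuinely exercised downstream.
#'
#' @param cfg a [simulation_config()].
#' @return List with `dataset` (an [expression_dataset()]), `network` (an
#'   [interaction_network()] containing the planted edges plus decoys
#'   among unplanted genes), and `manifest` — a list with the planted edge
#'   table (`gene_a`, `gene_b`, `hub`, `direction`), the planted hub
#'   table, and the seed.
#' @export
simulate_expression <- function(cfg) {
  set.seed(cfg$seed)
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  samples <- c(sprintf("N%03d", seq_len(cfg$n_normal)),
               sprintf("T%03d", seq_len(cfg$n_tumor)))
  phen <- rep(c("normal", "tumor"), c(cfg$n_normal, cfg$n_tumor))
  n_s <- length(samples)
  meanlog <- runif(cfg$n_genes, cfg$meanlog_range[1], cfg$meanlog_range[2])
  values <- matrix(rlnorm(cfg$n_genes * n_s, meanlog, cfg$sdlog),
                   cfg$n_genes, n_s, dimnames = list(genes, samples))

  sizes <- c(star_sizes(cfg$n_activated, cfg$star_size),
             star_sizes(cfg$n_repressed, cfg$star_size))
  dirs <- rep(c("activated", "repressed"),
              c(length(star_sizes(cfg$n_activated, cfg$star_size)),
                length(star_sizes(cfg$n_repressed, cfg$star_size))))
  pool <- sample(genes)
  used <- 0L
  planted <- list()
  hubs <- character(0)
  is_tumor <- phen == "tumor"
  for (i in seq_along(sizes)) {
    hub <- pool[used + 1L]
    partners <- pool[used + 1L + seq_len(sizes[i])]
    used <- used + 1L + sizes[i]
    hubs <- c(hubs, hub)
    enriched <- if (dirs[i] == "activated") is_tumor else !is_tumor
    rate <- ifelse(enriched, cfg$tumor_rate, cfg$normal_rate)
    push <- runif(n_s) < rate
    star_genes <- c(hub, partners)
    if (any(push)) {
      idx_g <- match(star_genes, genes)
      for (g in idx_g) {
        values[g, push] <- rlnorm(sum(push),
                                  meanlog[g] + cfg$push_shift_sd * cfg$sdlog,
                                  cfg$push_sdlog)
      }
    }
    planted[[i]] <- data.frame(
      gene_a = pmin(hub, partners), gene_b = pmax(hub, partners),
      hub = hub, direction = dirs[i], stringsAsFactors = FALSE)
  }
  planted <- if (length(planted)) do.call(rbind, planted)
             else data.frame(gene_a = character(), gene_b = character(),
                             hub = character(), direction = character())

  free <- setdiff(genes, pool[seq_len(used)])
  n_decoy <- cfg$n_edges - nrow(planted)
  decoy <- data.frame(gene_a = character(), gene_b = character())
  if (n_decoy > 0) {
    seen <- character(0)
    a <- character(0); b <- character(0)
    while (length(a) < n_decoy) {
      pair <- sample(free, 2L)
      key <- paste(min(pair), max(pair), sep = "\r")
      if (key %in% seen) next
      seen <- c(seen, key)
      a <- c(a, min(pair)); b <- c(b, max(pair))
    }
    decoy <- data.frame(gene_a = a, gene_b = b, stringsAsFactors = FALSE)
  }
  network <- interaction_network(
    rbind(planted[, c("gene_a", "gene_b")], decoy))
  list(dataset = expression_dataset(values, phen),
       network = network,
       manifest = list(planted_edges = planted,
                       planted_hubs = data.frame(
                         hub = hubs, direction = dirs, n_edges = sizes,
                         stringsAsFactors = FALSE),
                       seed = cfg$seed,
                       tumor_rate = cfg$tumor_rate,
                       normal_rate = cfg$normal_rate))
}

#' Simulate survival times whose hazard depends on expression
#'
#' Event times are exponential with hazard
#' `h0 * exp(sum_p beta_p * x~_p)` where `x~` is the gene's expression
#' standardized across samples. With probability `censoring_rate` a sample
#' is censored at a uniformly drawn fraction of its event time.
#'
#' @param expr an [expression_dataset()].
#' @param beta named numeric vector of generative log-hazard coefficients
#'   (names are gene symbols present in `expr`).
#' @param baseline_hazard exponential baseline hazard `h0`.
#' @param censoring_rate expected fraction of censored samples.
#' @param seed random seed.
#' @return A [clinical_table()] covering every sample of `expr`.
#' @export
simulate_survival <- function(expr, beta, baseline_hazard = 0.1,
                              censoring_rate = 0.2, seed = 1L) {
  stopifnot(!is.null(names(beta)), baseline_hazard > 0,
            censoring_rate >= 0, censoring_rate <= 1)
  absent <- setdiff(names(beta), rownames(expr$values))
  if (length(absent))
    stop("beta gene(s) not in expression data: ",
         paste(absent, collapse = ", "))
  set.seed(seed)
  x <- expr$values[names(beta), , drop = FALSE]
  xs <- (x - rowMeans(x)) / apply(x, 1, sd)
  lp <- colSums(beta * xs)
  n <- ncol(expr$values)
  t_event <- rexp(n, rate = baseline_hazard * exp(lp))
  censored <- runif(n) < censoring_rate
  time <- ifelse(censored, runif(n) * t_event, t_event)
  clinical_table(data.frame(sample = colnames(expr$values),
                            time = time,
                            event = as.integer(!censored)))
}

#' Simulate a drug-gene interaction table with one planted drug
#'
#' Decoy drugs receive random gene sets drawn from the universe; the
#' planted drug's set contains exactly the target genes, so it attains the
#' minimal achievable hypergeometric p against that query.
#'
#' @param targets character vector of target genes (the planted drug's
#'   gene set).
#' @param universe character vector of genes the decoy sets are drawn
#'   from; extended with `targets` if necessary.
#' @param n_decoys number of decoy drugs.
#' @param decoy_set_size genes per decoy drug.
#' @param planted_drug identifier of the planted drug.
#' @param seed random seed.
#' @return A [drug_gene_table()].
#' @export
simulate_drug_table <- function(targets, universe, n_decoys = 50,
                                decoy_set_size = 5,
                                planted_drug = "PLANTED_DRUG", seed = 1L) {
  stopifnot(length(targets) >= 1, n_decoys >= 0, decoy_set_size >= 1)
  set.seed(seed)
  universe <- unique(c(universe, targets))
  rows <- data.frame(drug = planted_drug, gene = unique(targets),
                     stringsAsFactors = FALSE)
  if (n_decoys > 0) {
    decoys <- lapply(seq_len(n_decoys), function(i)
      data.frame(drug = sprintf("DECOY_%03d", i),
                 gene = sample(universe, decoy_set_size),
                 stringsAsFactors = FALSE))
    rows <- rbind(rows, do.call(rbind, decoys))
  }
  drug_gene_table(rows)
}
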