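#' Fit a Cox proportional-hazards model on module genes
#'
#' Fits a multivariate Cox model of survival on the expression of the given
#' genes (partial likelihood, Efron tie handling) and keeps the per-gene
#' coefficients beta_p, which define the prognostic index of the module.
#'
#' @param expr an [expression_dataset()] (or anything with a gene x sample
#'   `values` matrix).
#' @param clinical a [clinical_table()]; samples are matched by id against
#'   the expression columns, at least 10 matched samples are required.
#' @param genes gene symbols to include; duplicates are collapsed with a
#'   warning, absent genes are an error.
#' @param standardize centre and scale each gene across samples before
#'   fitting (coefficients then refer to expression in per-gene sd units).
#'   Default `FALSE`: coefficients refer to the expression scale supplied.
#' @return Object of class `prognostic_model`: list with `genes`, `betas`
#'   (named coefficients), `standardize`, `center`, `scale`, `n_samples`,
#'   and the underlying `fit`.
#' @export
fit_module_cox <- function(expr, clinical, genes, standardize = FALSE) {
  if (anyDuplicated(genes)) {
    warning("duplicate gene(s) collapsed: ",
            paste(unique(genes[duplicated(genes)]), collapse = ", "))
    genes <- unique(genes)
  }
  absent <- setdiff(genes, rownames(expr$values))
  if (length(absent))
    stop("gene(s) not in expression data: ", paste(absent, collapse = ", "))
  common <- intersect(colnames(expr$values), clinical$sample)
  if (length(common) < 10)
    stop("need at least 10 samples with clinical data; found ",
         length(common))
  x <- t(expr$values[genes, common, drop = FALSE])
  center <- rep(0, length(genes))
  scale_ <- rep(1, length(genes))
  if (standardize) {
    center <- colMeans(x)
    scale_ <- apply(x, 2, sd)
    if (any(scale_ == 0)) stop("constant gene(s) cannot be standardized")
    x <- scale(x, center = center, scale = scale_)
  }
  cl <- clinical[match(common, clinical$sample), , drop = FALSE]
  dat <- data.frame(time = cl$time, event = cl$event)
  dat$x <- unname(as.matrix(x))
  fit <- withCallingHandlers(
    coxph(Surv(time, event) ~ x, data = dat, ties = "efron"),
    warning = function(w) {
      if (grepl("converge|infinite|singular", conditionMessage(w),
                ignore.case = TRUE))
        stop("Cox fit did not converge; reduce the gene list",
             call. = FALSE)
      invokeRestart("muffleWarning")
    })
  betas <- stats::setNames(as.numeric(stats::coef(fit)), genes)
  if (any(!is.finite(betas)))
    stop("Cox fit produced non-finite coefficients; reduce the gene list")
  structure(list(genes = genes, betas = betas, standardize = standardize,
                 center = stats::setNames(center, genes),
                 scale = stats::setNames(scale_, genes),
                 n_samples = length(common), fit = fit),
            class = "prognostic_model")
}

#' @export
print.prognostic_model <- function(x, ...) {
  cat("<prognostic_model> ", length(x$genes), " gene(s), fitted on ",
      x$n_samples, " samples\n", sep = "")
  print(round(x$betas, 4))
  invisible(x)
}

#' Prognostic index per sample
#'
#' The linear predictor of the Cox model, `PI = sum_p beta_p * x_p`,
#' evaluated for each sample of an expression dataset. When the model was
#' fitted with `standardize = TRUE`, the stored per-gene centre and scale
#' are applied first.
#'
#' @param model a [fit_module_cox()] result.
#' @param expr an [expression_dataset()] containing all model genes.
#' @return Named numeric vector of prognostic indices, one per sample.
#' @export
prognostic_index <- function(model, expr) {
  absent <- setdiff(model$genes, rownames(expr$values))
  if (length(absent))
    stop("gene(s) not in expression data: ", paste(absent, collapse = ", "))
  x <- expr$values[model$genes, , drop = FALSE]
  if (model$standardize)
    x <- (x - model$center[model$genes]) / model$scale[model$genes]
  colSums(model$betas[model$genes] * x)
}

#' Stratify samples by prognostic index and test survival separation
#'
#' Splits samples at a quantile of the prognostic index (median by
#' default; ties go to the low-risk group), estimates Kaplan-Meier curves
#' per risk group, performs the log-rank test, and derives the hazard
#' ratio from the observed/expected event decomposition of that test:
#'
#' \deqn{HR = \frac{O_{high}/E_{high}}{O_{low}/E_{low}}}
#'
#' where O and E are the observed and log-rank-expected numbers of deaths
#' in each group. Separation is flagged significant at log-rank p < 0.05.
#'
#' @param pi named numeric vector of prognostic indices
#'   (see [prognostic_index()]).
#' @param clinical a [clinical_table()] covering the same samples.
#' @param split_quantile quantile of PI used as the cut point
#'   (default 0.5, the median).
#' @return Object of class `risk_stratification`: list with `pi`, `group`
#'   (factor low/high), `observed` and `expected` per group, `hr`,
#'   `logrank_chisq`, `logrank_p`, `significant`, and `km` — a data.frame
#'   of Kaplan-Meier curve coordinates (`group`, `time`, `n_risk`,
#'   `n_event`, `surv`).
#' @export
stratify_and_test <- function(pi, clinical, split_quantile = 0.5) {
  if (is.null(names(pi))) stop("`pi` must be named by sample id")
  common <- intersect(names(pi), clinical$sample)
  if (length(common) < 4)
    stop("need at least 4 samples with both PI and clinical data")
  pi <- pi[common]
  cl <- clinical[match(common, clinical$sample), , drop = FALSE]
  if (diff(range(pi)) == 0)
    stop("all prognostic indices are equal: degenerate split")
  cut <- quantile(pi, split_quantile)
  group <- factor(ifelse(pi > cut, "high", "low"),
                  levels = c("low", "high"))
  if (any(table(group) < 2))
    stop("fewer than 2 samples in a risk group after the split")
  if (sum(cl$event) == 0) stop("no events")
  dat <- data.frame(time = cl$time, event = cl$event, group = group)
  sd_fit <- survdiff(Surv(time, event) ~ group, data = dat)
  obs <- stats::setNames(as.numeric(sd_fit$obs), c("low", "high"))
  exp_ <- stats::setNames(as.numeric(sd_fit$exp), c("low", "high"))
  hr <- (obs[["high"]] / exp_[["high"]]) / (obs[["low"]] / exp_[["low"]])
  p <- pchisq(sd_fit$chisq, df = 1, lower.tail = FALSE)
  km_fit <- survfit(Surv(time, event) ~ group, data = dat)
  km_sum <- summary(km_fit, censored = TRUE)
  km <- data.frame(
    group = sub("^group=", "", as.character(km_sum$strata)),
    time = km_sum$time, n_risk = km_sum$n.risk,
    n_event = km_sum$n.event, surv = km_sum$surv,
    stringsAsFactors = FALSE)
  structure(list(pi = pi, group = group, observed = obs, expected = exp_,
                 hr = unname(hr), logrank_chisq = unname(sd_fit$chisq),
                 logrank_p = unname(p), significant = unname(p < 0.05),
                 km = km),
            class = "risk_stratification")
}

#' @export
print.risk_stratification <- function(x, ...) {
  cat("<risk_stratification> ", length(x$pi), " samples (",
      sum(x$group == "low"), " low / ", sum(x$group == "high"),
      " high risk)\n", sep = "")
  cat(sprintf("  HR (high/low) = %.3f, log-rank p = %.3g%s\n", x$hr,
              x$logrank_p, if (x$significant) " *" else ""))
  cat(sprintf("  observed/expected deaths: low %g/%.2f, high %g/%.2f\n",
              x$observed[["low"]], x$expected[["low"]],
              x$observed[["high"]], x$expected[["high"]]))
  invisible(x)
}
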