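#' Discretize expression into three levels
#'
#' Maps each gene's expression in each sample to a level in \{-1, 0, +1\}
#' relative to the gene's own average: below average is -1, above average is
#' +1. For continuous data a literal mean cutoff leaves the 0 level
#' unreachable, so a tolerance band of `band_width_sd` gene standard
#' deviations around the mean is labelled 0:
#'
#' \deqn{level = -1 \textrm{ if } x < \mu_g - b\sigma_g;\quad
#'       +1 \textrm{ if } x > \mu_g + b\sigma_g;\quad 0 \textrm{ otherwise}}
#'
#' `band_width_sd = 0` reproduces the literal below/above-mean rule (only
#' values exactly equal to the mean are 0).
#'
#' Per-gene statistics are computed across all samples of the dataset by
#' default (both phenotypes pooled, one average per gene); `reference =
#' "normal"` restricts them to the normal group.
#'
#' A constant gene (sd of 0) gets level 0 in every sample.
#'
#' @param ds an [expression_dataset()].
#' @param band_width_sd half-width of the 0 band, in units of the gene's
#'   standard deviation (sample sd, n-1 denominator). Default 0.5.
#' @param reference samples used for the per-gene mean and sd: `"all"`
#'   (default) or `"normal"`.
#' @return Object of class `discretized_matrix`: list with `levels`
#'   (integer gene x sample matrix in \{-1, 0, 1\}), `phenotype`,
#'   `band_width_sd`, `reference`.
#' @examples
#' m <- matrix(c(1, 2, 3, 5, 5, 5), 2, 3, byrow = TRUE,
#'             dimnames = list(c("A", "B"), c("s1", "s2", "s3")))
#' # third sample labelled tumor just to satisfy the two-group contract
#' ds <- expression_dataset(cbind(m, m), rep(c("normal", "tumor"), each = 3))
#' discretize_expression(ds, band_width_sd = 0)$levels
#' @export
discretize_expression <- function(ds, band_width_sd = 0.5,
                                  reference = c("all", "normal")) {
  stopifnot(is.finite(band_width_sd), band_width_sd >= 0)
  reference <- match.arg(reference)
  cols <- if (reference == "all") seq_len(ncol(ds$values))
          else which(ds$phenotype == "normal")
  ref <- ds$values[, cols, drop = FALSE]
  mu <- rowMeans(ref)
  sigma <- apply(ref, 1, sd)
  sigma[is.na(sigma)] <- 0
  n_const <- sum(sigma == 0)
  if (band_width_sd > 0 && n_const > 0)
    message(n_const, " constant gene(s) assigned level 0 everywhere")
  lev <- matrix(0L, nrow(ds$values), ncol(ds$values),
                dimnames = dimnames(ds$values))
  # per-gene bounds recycle down columns of the gene x sample matrix
  lev[ds$values < mu - band_width_sd * sigma] <- -1L
  lev[ds$values > mu + band_width_sd * sigma] <- 1L
  structure(list(levels = lev, phenotype = ds$phenotype,
                 band_width_sd = band_width_sd, reference = reference),
            class = "discretized_matrix")
}

#' @export
print.discretized_matrix <- function(x, ...) {
  np <- n_phenotype(x)
  cat("<discretized_matrix> ", nrow(x$levels), " genes x ", ncol(x$levels),
      " samples (", np[["normal"]], " normal, ", np[["tumor"]],
      " tumor), band ", x$band_width_sd, " sd, reference ", x$reference,
      "\n", sep = "")
  invisible(x)
}
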