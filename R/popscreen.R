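#' Coverage-gate a population heterozygosity table
#'
#' Restricts a per-individual summary table (as produced from RAD-seq
#' style genotyping: one row per animal with its mean coverage and the
#' heterozygous / considered site counts at average coverage) to
#' individuals at or above the minimum mean coverage, and computes
#' percent heterozygosity for each.
#'
#' @param summaries data frame with columns `id`, `species`,
#'   `mean_coverage`, `n_het`, `n_considered`.
#' @param min_coverage minimum mean coverage to retain (default 20).
#' @return the filtered table with a `percent_het` column added.
#' @export
screen_individuals <- function(summaries, min_coverage = 20) {
  need <- c("id", "species", "mean_coverage", "n_het", "n_considered")
  abort_if(!all(need %in% names(summaries)),
           paste("summaries need columns:", paste(need, collapse = ", ")))
  keep <- summaries$mean_coverage >= min_coverage
  abort_if(!any(keep), "all individuals fall below the coverage threshold")
  out <- summaries[keep, , drop = FALSE]
  out$percent_het <- 100 * out$n_het / out$n_considered
  out$percent_het[out$n_considered == 0] <- 0
  rownames(out) <- NULL
  out
}

#' Flag individuals with very low heterozygosity
#'
#' @param table output of [screen_individuals()].
#' @param threshold_percent flag individuals with `percent_het` strictly
#'   below this (default 0.05%, the screen's working definition of
#'   near-complete homozygosity).
#' @return character vector of flagged ids.
#' @export
flag_low_heterozygosity <- function(table, threshold_percent = 0.05) {
  abort_if(nrow(table) == 0L, "empty table")
  table$id[table$percent_het < threshold_percent]
}

#' Generalized extreme Studentized deviate (Rosner) outlier test
#'
#' Iteratively removes the observation farthest from the mean in
#' Studentized units, computing at step i the statistic
#' \eqn{R_i = \max |x - \bar x| / s} on the remaining data and the
#' critical value
#' \eqn{\lambda_i = t_{p,\nu} (n-i) / \sqrt{(\nu + t^2)(n-i+1)}} with
#' \eqn{\nu = n-i-1} and \eqn{p = 1 - \alpha / (2(n-i+1))}. The number of
#' outliers is the largest i with \eqn{R_i > \lambda_i}.
#'
#' @param values numeric observations.
#' @param k maximum number of outliers to test for.
#' @param alpha significance level (default 0.05).
#' @param log_transform test on the log scale (heterozygosity percentages
#'   are strongly right-skewed); zeros are replaced by half the smallest
#'   positive value, with a warning.
#' @return an `esd_result`: `stats` data frame (`i`, `R`, `lambda`,
#'   `value`, `index` into `values`), `n_outliers`, `outliers` (indices
#'   declared outlying), `alpha`, `transformed`.
#' @examples
#' x <- c(rnorm(29), 10)
#' rosner_esd(x, k = 3)$n_outliers  # 1
#' @export
rosner_esd <- function(values, k, alpha = 0.05, log_transform = FALSE) {
  n <- length(values)
  abort_if(k < 1, "k must be >= 1")
  abort_if(n <= k + 1, "need more than k + 1 observations")
  x <- values
  if (log_transform) {
    abort_if(any(x < 0), "log transform needs non-negative values")
    if (any(x == 0)) {
      warning("zero values replaced by half the smallest positive value before log",
              call. = FALSE)
      x[x == 0] <- min(x[x > 0]) / 2
    }
    x <- log(x)
  }
  idx <- seq_len(n)
  R <- lambda <- val <- numeric(k)
  out_idx <- integer(k)
  for (i in seq_len(k)) {
    m <- mean(x)
    s <- stats::sd(x)
    abort_if(s == 0, "zero variance: ESD statistic undefined")
    j <- which.max(abs(x - m))
    R[i] <- abs(x[j] - m) / s
    val[i] <- values[idx[j]]
    out_idx[i] <- idx[j]
    x <- x[-j]
    idx <- idx[-j]
    nu <- n - i - 1
    p <- 1 - alpha / (2 * (n - i + 1))
    tq <- stats::qt(p, nu)
    lambda[i] <- tq * (n - i) / sqrt((nu + tq^2) * (n - i + 1))
  }
  n_out <- if (any(R > lambda)) max(which(R > lambda)) else 0L
  structure(list(stats = data.frame(i = seq_len(k), R = R, lambda = lambda,
                                    value = val, index = out_idx),
                 n_outliers = n_out,
                 outliers = if (n_out > 0) out_idx[seq_len(n_out)] else integer(),
                 alpha = alpha, transformed = log_transform, n = n),
            class = "esd_result")
}

#' @export
print.esd_result <- function(x, ...) {
  cat(sprintf("Generalized ESD (Rosner) test: n = %d, alpha = %g%s\n",
              x$n, x$alpha, if (x$transformed) ", log scale" else ""))
  print(x$stats, row.names = FALSE, digits = 4)
  cat(sprintf("outliers detected: %d\n", x$n_outliers))
  invisible(x)
}

#' Per-species low-heterozygosity outlier screen
#'
#' Runs the generalized ESD test on percent heterozygosity within each
#' species (log scale by default) and keeps only outliers on the *low*
#' side of the species mean -- the signature of parthenogenetic,
#' genome-wide-homozygous individuals. High-side outliers (hybrids,
#' contaminated samples) are reported separately but not flagged.
#'
#' @param table output of [screen_individuals()].
#' @param k maximum outliers per species (default 5).
#' @param alpha significance level.
#' @param log_transform test on the log scale (default TRUE).
#' @param pooled ignore species and test the pooled values.
#' @return data frame of flagged ids: `id`, `species`, `percent_het`,
#'   `side`.
#' @export
screen_outliers <- function(table, k = 5L, alpha = 0.05, log_transform = TRUE,
                            pooled = FALSE) {
  groups <- if (pooled) list(all = table) else split(table, table$species)
  rows <- lapply(groups, function(g) {
    if (nrow(g) <= k + 1) return(NULL)
    res <- tryCatch(rosner_esd(g$percent_het, k, alpha, log_transform),
                    error = function(e) NULL)
    if (is.null(res) || res$n_outliers == 0) return(NULL)
    i <- res$outliers
    side <- ifelse(g$percent_het[i] < mean(g$percent_het[-i]), "low", "high")
    data.frame(id = g$id[i], species = g$species[i],
               percent_het = g$percent_het[i], side = side,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(NULL)))
  if (is.null(out)) out <- data.frame(id = character(), species = character(),
                                      percent_het = numeric(), side = character())
  rownames(out) <- NULL
  out[out$side == "low", , drop = FALSE]
}
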