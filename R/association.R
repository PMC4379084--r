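# Association between phenological fuel classes and a categorical
# environmental covariate (land-cover macro-class or climatic region),
# assessed on a fires-by-category contingency table with a Pearson
# chi-square statistic and a margin-fixed randomization: the covariate
# label vector is permuted across fires, which keeps the number of fires
# in every class and every covariate category exactly fixed.

#' Build a fires contingency table
#'
#' Rows are covariate categories, columns are fuel classes. Category
#' order (and any declared-but-empty categories, kept as zero rows or
#' columns) is taken from `row_levels`/`col_levels`.
#'
#' @param pfc_labels fuel-class label of each fire.
#' @param covariate_labels covariate category of each fire (same length).
#' @param row_levels,col_levels optional category orders.
#' @return integer matrix of class `contingency_table` with margins in
#'   attributes `row_margin`, `col_margin`.
#' @export
build_contingency <- function(pfc_labels, covariate_labels,
                              row_levels = NULL, col_levels = NULL) {
  if (length(pfc_labels) != length(covariate_labels))
    stop("label vectors differ in length")
  r <- factor(covariate_labels,
              levels = if (is.null(row_levels)) sort(unique(covariate_labels))
                       else row_levels)
  cc <- factor(pfc_labels,
               levels = if (is.null(col_levels)) sort(unique(pfc_labels))
                        else col_levels)
  if (anyNA(r) || anyNA(cc))
    stop("labels outside the declared categories; drop them upstream")
  m <- table(r, cc)
  m <- matrix(as.integer(m), nrow(m), ncol(m),
              dimnames = list(levels(r), levels(cc)))
  structure(m, row_margin = rowSums(m), col_margin = colSums(m),
            class = c("contingency_table", class(m)))
}

#' Pearson chi-square statistic of a contingency table
#'
#' `chi2 = sum (O - E)^2 / E` with independence expectations
#' `E = row * col / total`. Zero-margin rows or columns are dropped with a
#' warning (their expectations are undefined).
#'
#' @param tab a matrix of counts (e.g. [build_contingency()]).
#' @return the statistic, with the expected table and df in attributes
#'   `expected`, `df`.
#' @export
pearson_chi2 <- function(tab) {
  m <- unclass(tab)
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  if (sum(m) <= 0) stop("empty table")
  rs <- rowSums(m); cs <- colSums(m)
  if (any(rs == 0) || any(cs == 0)) {
    warning("dropping zero-margin rows/columns")
    m <- m[rs > 0, cs > 0, drop = FALSE]
    rs <- rowSums(m); cs <- colSums(m)
  }
  E <- outer(rs, cs) / sum(m)
  structure(sum((m - E)^2 / E), expected = E,
            df = (nrow(m) - 1L) * (ncol(m) - 1L))
}

#' Margin-fixed randomization test of class-covariate association
#'
#' Each of `n_reps` randomizations permutes the covariate label vector
#' across fires, preserving both table margins exactly, and rebuilds the
#' table. The overall p-value compares the observed Pearson chi-square
#' with its permutation null; each cell gets a two-tailed p (doubled
#' smaller tail, add-one continuity) and a direction: `+` when the
#' observed count exceeds the null mean of that cell, `-` otherwise.
#'
#' @inheritParams build_contingency
#' @param n_reps number of randomizations (default 9999).
#' @param seed RNG seed.
#' @return an `association_test`: list with `table`, `chi2_observed`,
#'   `p_overall`, `expected`, `cell_p`, `direction`, `null_cell_mean`,
#'   `n_reps`, `seed`.
#' @export
margin_fixed_randomization <- function(pfc_labels, covariate_labels,
                                       n_reps = 9999, seed = 1L,
                                       row_levels = NULL, col_levels = NULL) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  obs <- build_contingency(pfc_labels, covariate_labels,
                           row_levels, col_levels)
  chi_obs <- pearson_chi2(obs)
  nr <- nrow(obs); nc <- ncol(obs)
  ri <- as.integer(factor(covariate_labels, levels = rownames(obs)))
  ci <- as.integer(factor(pfc_labels, levels = colnames(obs)))
  N <- length(ri)
  set.seed(seed)
  chi_null <- numeric(n_reps)
  cell_le <- cell_ge <- matrix(0L, nr, nc)
  cell_sum <- matrix(0, nr, nc)
  om <- unclass(obs); attributes(om) <- attributes(om)["dim"]
  rs <- rowSums(om); cs <- colSums(om)
  E <- outer(rs, cs) / N
  for (b in seq_len(n_reps)) {
    rp <- ri[sample.int(N)]
    tb <- matrix(tabulate(rp + nr * (ci - 1L), nr * nc), nr, nc)
    chi_null[b] <- sum((tb - E)^2 / E)
    cell_le <- cell_le + (tb <= om)
    cell_ge <- cell_ge + (tb >= om)
    cell_sum <- cell_sum + tb
  }
  cell_p <- matrix(mapply(perm_p_two_tailed, cell_le, cell_ge,
                          MoreArgs = list(n_reps = n_reps)), nr, nc,
                   dimnames = dimnames(obs))
  null_mean <- cell_sum / n_reps
  dir <- matrix(ifelse(om > null_mean, "+", "-"), nr, nc,
                dimnames = dimnames(obs))
  structure(list(table = obs, chi2_observed = as.numeric(chi_obs),
                 p_overall = (sum(chi_null >= as.numeric(chi_obs)) + 1) /
                   (n_reps + 1),
                 expected = attr(chi_obs, "expected"),
                 cell_p = cell_p, direction = dir,
                 null_cell_mean = structure(null_mean,
                                            dimnames = dimnames(obs)),
                 n_reps = n_reps, seed = seed),
            class = "association_test")
}

#' @export
print.association_test <- function(x, ...) {
  cat(sprintf("Margin-fixed randomization test (%d randomizations)\n",
              x$n_reps))
  cat(sprintf("  chi-square = %.2f, overall p = %s\n", x$chi2_observed,
              format.pval(x$p_overall, digits = 3, eps = 1e-4)))
  cat("  cell directions (+ = above null mean):\n")
  print(x$direction, quote = FALSE)
  invisible(x)
}
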