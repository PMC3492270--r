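#' Fourth-root transform of a descriptor table
#'
#' Standard variance-stabilising pre-treatment before Bray-Curtis
#' dissimilarity: every non-negative descriptor value is replaced by its
#' fourth root; grouping columns are untouched.
#'
#' @param table data.frame; descriptor columns are all numeric columns except
#'   those named in `id_cols`.
#' @param id_cols columns to leave untransformed (default
#'   `c("departure_id", "excursion_number")`).
#' @return the table with transformed descriptor columns.
#' @export
transform_fourth_root <- function(table,
                                  id_cols = c("departure_id",
                                              "excursion_number")) {
  desc <- setdiff(names(table)[vapply(table, is.numeric, logical(1))], id_cols)
  for (cn in desc) {
    v <- table[[cn]]
    if (any(v < 0, na.rm = TRUE)) {
      stopf("column '%s' has negative values; fourth root undefined", cn)
    }
    table[[cn]] <- v^0.25
  }
  table
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(u, v) = sum(|u_i - v_i|) / sum(u_i + v_i)` between non-negative
#' descriptor rows: 0 for identical rows, 1 for rows with disjoint support.
#'
#' @param x numeric matrix or data.frame of non-negative descriptor rows.
#' @return symmetric dissimilarity matrix with zero diagonal, entries in
#'   `[0, 1]`.
#' @export
bray_curtis_matrix <- function(x) {
  m <- as.matrix(x)
  if (any(m < 0, na.rm = TRUE)) stopf("Bray-Curtis requires non-negative values")
  n <- nrow(m)
  rs <- rowSums(m)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tot <- rs[i] + rs[j]
      if (tot == 0) {
        stopf("Bray-Curtis undefined for all-zero row pair (%d, %d)", i, j)
      }
      D[i, j] <- D[j, i] <- sum(abs(m[i, ] - m[j, ])) / tot
    }
  }
  rownames(D) <- colnames(D) <- rownames(m)
  D
}

## pseudo-F from a squared-dissimilarity matrix and integer group codes
permanova_F <- function(D2, g, sizes_tab) {
  N <- nrow(D2)
  a <- length(sizes_tab)
  ss_total <- sum(D2[upper.tri(D2)]) / N
  ss_within <- 0
  for (lev in seq_len(a)) {
    r <- which(g == lev)
    if (length(r) > 1) {
      sub <- D2[r, r]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(r)
    }
  }
  ss_between <- ss_total - ss_within
  Fv <- (ss_between / (a - 1)) / (ss_within / (N - a))
  c(F = Fv, ss_between = ss_between, ss_within = ss_within,
    ss_total = ss_total)
}

## all distinct arrangements of a multiset of integer codes (used only when
## their count is small); returns a matrix with one arrangement per row
multiset_permutations <- function(codes) {
  counts <- tabulate(codes)
  n <- length(codes)
  out <- list()
  rec <- function(prefix, counts) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in seq_along(counts)) {
      if (counts[v] > 0) {
        counts[v] <- counts[v] - 1L
        rec(c(prefix, v), counts)
        counts[v] <- counts[v] + 1L
      }
    }
  }
  rec(integer(0), counts)
  do.call(rbind, out)
}

#' One-way PERMANOVA on a dissimilarity matrix
#'
#' Permutational multivariate analysis of variance: partitions the sum of
#' squared dissimilarities into between- and within-group components,
#' `pseudo-F = (SS_between/(a-1)) / (SS_within/(N-a))`, and obtains the
#' p-value by unrestricted permutation of the group labels over rows. When
#' the number of distinct label arrangements does not exceed `n_perm` the
#' complete permutation distribution is enumerated (exact test); otherwise
#' `n_perm` seeded random permutations are drawn and the Monte-Carlo +1
#' correction `p = (#{F* >= F} + 1)/(n_perm + 1)` is applied.
#'
#' @param dist square symmetric dissimilarity matrix with zero diagonal.
#' @param groups group labels, one per row (>= 2 groups).
#' @param n_perm permutations to sample (default 9951).
#' @param seed integer seed for the permutation stream.
#' @return a `permanova_result` list: `pseudo_F`, `p_value`,
#'   `n_permutations_used`, `exact` (complete enumeration?), `ss_between`,
#'   `ss_within`, `ss_total`, `df`, `degenerate` (TRUE when `ss_within` is 0
#'   with positive `ss_between`, in which case `p_value` is reported as its
#'   Monte-Carlo lower bound).
#' @export
permanova_oneway <- function(dist, groups, n_perm = 9951, seed = NULL) {
  D <- as.matrix(dist)
  N <- nrow(D)
  if (ncol(D) != N || any(abs(D - t(D)) > 1e-12) ||
      any(abs(diag(D)) > 1e-12)) {
    stopf("dist must be square, symmetric, with zero diagonal")
  }
  g <- as.integer(factor(groups))
  if (length(g) != N) stopf("groups length must match dist")
  sizes <- table(g)
  a <- length(sizes)
  if (a < 2) stopf("need >= 2 groups")
  if (any(sizes == 1)) {
    warning("group(s) of size 1 present; within-group SS has no contribution from them")
  }
  D2 <- D^2
  obs <- permanova_F(D2, g, sizes)

  degenerate <- obs[["ss_within"]] <= 1e-15 && obs[["ss_between"]] > 1e-15
  n_distinct <- exp(lgamma(N + 1) - sum(lgamma(as.numeric(sizes) + 1)))
  exact <- is.finite(n_distinct) && n_distinct <= n_perm

  if (degenerate) {
    p <- 1 / (n_perm + 1)
    used <- 0L
  } else if (exact) {
    perms <- multiset_permutations(g)
    Fs <- apply(perms, 1, function(pg) permanova_F(D2, pg, sizes)[["F"]])
    p <- mean(Fs >= obs[["F"]] - 1e-12)
    used <- nrow(perms)
  } else {
    Fs <- with_seed_opt(seed, {
      vapply(seq_len(n_perm), function(i) {
        permanova_F(D2, sample(g), sizes)[["F"]]
      }, numeric(1))
    })
    p <- (sum(Fs >= obs[["F"]] - 1e-12) + 1) / (n_perm + 1)
    used <- n_perm
  }

  structure(list(
    pseudo_F = unname(obs[["F"]]), p_value = p, n_permutations_used = used,
    exact = exact && !degenerate, ss_between = unname(obs[["ss_between"]]),
    ss_within = unname(obs[["ss_within"]]),
    ss_total = unname(obs[["ss_total"]]),
    df = c(between = a - 1, within = N - a), degenerate = degenerate
  ), class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf(
    "One-way PERMANOVA: pseudo-F(%d, %d) = %.4f, p = %.4g (%s, %d permutations)\n",
    x$df[1], x$df[2], x$pseudo_F, x$p_value,
    if (x$exact) "exact" else "sampled", x$n_permutations_used))
  if (x$degenerate) cat("NOTE: degenerate partition (zero within-group SS)\n")
  invisible(x)
}

#' PERMANOVA on a path-descriptor table
#'
#' Convenience wrapper reproducing the full shape-comparison recipe: fourth
#' root transform of the mean wavelength / mean amplitude descriptors,
#' Bray-Curtis dissimilarity, one-way PERMANOVA over the excursion-number
#' groups with 9951 permutations by default.
#'
#' @param table data.frame with columns `excursion_number`,
#'   `mean_wavelength_cm`, `mean_amplitude_cm` (and optionally
#'   `departure_id`).
#' @param n_perm,seed passed to [permanova_oneway()].
#' @return a `permanova_result`.
#' @export
permanova_descriptors <- function(table, n_perm = 9951, seed = NULL) {
  need <- c("excursion_number", "mean_wavelength_cm", "mean_amplitude_cm")
  if (!all(need %in% names(table))) {
    stopf("table must have columns %s", paste(need, collapse = ", "))
  }
  tr <- transform_fourth_root(table)
  D <- bray_curtis_matrix(tr[, c("mean_wavelength_cm", "mean_amplitude_cm")])
  permanova_oneway(D, table$excursion_number, n_perm = n_perm, seed = seed)
}
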