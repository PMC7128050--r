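#' SAM two-class d statistic
#'
#' The moderated t-like statistic `d_i = (mean_B - mean_A) / (s_i + s0)`,
#' where `s_i` is the pooled standard-error term of the unpaired two-class
#' statistic, `sqrt((1/nA + 1/nB) * pooled variance)`. The exchangeability
#' constant `s0` damps the inflation of `d` for low-variance features.
#'
#' @param expr log2 expression matrix (features x samples).
#' @param group_labels two-level factor/vector over the columns; the first
#'   level is the reference group A.
#' @param s0 nonnegative exchangeability constant. With `s0 = 0` a feature
#'   with zero variance in both groups has no defined `d` and an error is
#'   raised.
#' @return named numeric vector of per-feature `d` values.
#' @export
sam_statistic <- function(expr, group_labels, s0 = 0) {
  parts <- sam_parts(expr, group_labels)
  if (s0 == 0 && any(parts$s == 0)) {
    stopf("features with zero variance in both groups and s0 = 0: d undefined (e.g. %s)",
          rownames(expr)[which(parts$s == 0)[1L]], class = "ncmod_zero_variance")
  }
  parts$r / (parts$s + s0)
}

# mean difference r and pooled standard error s for every feature
sam_parts <- function(expr, group_labels) {
  g <- as.factor(group_labels)
  if (nlevels(g) != 2L) stopf("group_labels must have exactly 2 levels")
  a <- g == levels(g)[1L]
  b <- g == levels(g)[2L]
  na <- sum(a); nb <- sum(b)
  if (na < 2L || nb < 2L) stopf("need at least 2 samples per group")
  ma <- rowMeans(expr[, a, drop = FALSE])
  mb <- rowMeans(expr[, b, drop = FALSE])
  ssa <- rowSums((expr[, a, drop = FALSE] - ma)^2)
  ssb <- rowSums((expr[, b, drop = FALSE] - mb)^2)
  s <- sqrt((1 / na + 1 / nb) * (ssa + ssb) / (na + nb - 2))
  list(r = mb - ma, s = s, n_a = na, n_b = nb)
}

#' Estimate the SAM exchangeability constant s0
#'
#' Tusher-style: candidate values are the percentiles of `s` on a 5% grid;
#' for each candidate the features are cut into equal-occupancy bins of `s`
#' and the coefficient of variation (across bins) of the median absolute
#' deviation of `d = r / (s + s0)` is computed. The candidate minimizing
#' that coefficient of variation is returned; degenerate cases fall back to
#' the median of `s`.
#'
#' @param s per-feature pooled standard errors (length >= 10).
#' @param r per-feature raw mean differences.
#' @param n_bins number of s-quantile bins.
#' @return the selected `s0` value.
#' @export
estimate_s0 <- function(s, r, n_bins = 20) {
  if (length(s) < 10L) {
    stopf("s0 estimation needs at least 10 features", class = "ncmod_param_error")
  }
  cand <- unique(stats::quantile(s, seq(0, 1, by = 0.05), names = FALSE))
  if (length(cand) == 1L) return(cand)
  n_bins <- max(2L, min(n_bins, floor(length(s) / 5)))
  bins <- cut(rank(s, ties.method = "first"),
              breaks = n_bins, labels = FALSE)
  cv <- vapply(cand, function(s0) {
    d <- r / (s + s0)
    v <- tapply(d, bins, stats::mad)
    m <- mean(v)
    if (!is.finite(m) || m == 0) return(Inf)
    stats::sd(v) / m
  }, 0)
  if (all(!is.finite(cv))) return(stats::median(s))
  cand[which.min(cv)]
}

#' SAM permutation FDR and DEG selection
#'
#' Computes per-feature q-values from the SAM permutation scheme: at each
#' cutoff `|d_i|`, the estimated false-call count is the median over label
#' permutations of the number of permuted `|d*|` at or above the cutoff,
#' scaled by `pi0 = min(1, 2 x proportion of observed d inside the central
#' 50% band of the permuted d)`; the q-value of a feature is the smallest
#' such FDR over all cutoffs at or below its `|d|`. When the number of
#' distinct label assignments is at most `n_perm` the scheme switches to
#' exact enumeration of all assignments (with a message). Selection keeps
#' both up- and down-regulated features.
#'
#' @inheritParams sam_statistic
#' @param n_perm number of label permutations (>= 100 unless enumeration is
#'   exact).
#' @param fdr_threshold q-value cutoff for the DEG set.
#' @param s0 exchangeability constant; estimated via [estimate_s0()] when
#'   `NULL`.
#' @param seed integer seed for the permutation draw.
#' @param contrast optional label stored in the result.
#' @return object of class `ncmod_deg`: list with `d`, `q`, `deg_ids`,
#'   `s0`, `pi0`, `exact`, `n_perm`, `contrast`.
#' @export
permutation_fdr <- function(expr, group_labels, n_perm = 1000,
                            fdr_threshold = 0.05, s0 = NULL, seed = 1L,
                            contrast = NULL) {
  parts <- sam_parts(expr, group_labels)
  if (is.null(s0)) s0 <- estimate_s0(parts$s, parts$r)
  if (s0 == 0 && any(parts$s == 0)) {
    stopf("zero-variance features with s0 = 0", class = "ncmod_zero_variance")
  }
  d_obs <- parts$r / (parts$s + s0)

  g <- as.factor(group_labels)
  n <- length(g)
  nb <- sum(g == levels(g)[2L])
  n_distinct <- choose(n, nb)
  exact <- n_distinct <= n_perm
  if (exact) {
    message("exact enumeration of all ", n_distinct, " label assignments")
    assign_b <- utils::combn(n, nb, simplify = FALSE)
  } else {
    if (n_perm < 100) warnf("n_perm < 100 limits FDR resolution")
    set.seed(as.integer(seed))
    assign_b <- lapply(seq_len(n_perm), function(i) sample.int(n, nb))
  }

  d_perm <- vapply(assign_b, function(idx) {
    lab <- rep(levels(g)[1L], n)
    lab[idx] <- levels(g)[2L]
    p <- sam_parts(expr, factor(lab, levels = levels(g)))
    p$r / (p$s + s0)
  }, numeric(nrow(expr)))

  band <- stats::quantile(d_perm, c(0.25, 0.75), names = FALSE)
  pi0 <- min(1, mean(d_obs >= band[1L] & d_obs <= band[2L]) / 0.5)

  abs_obs <- abs(d_obs)
  # false calls at cutoff |d_i|: median over permutations of the count of
  # permuted |d*| at or above the cutoff
  abs_perm <- abs(d_perm)
  v_med <- vapply(abs_obs, function(cut) {
    stats::median(colSums(abs_perm >= cut))
  }, 0)
  r_obs <- vapply(abs_obs, function(cut) sum(abs_obs >= cut), 0)
  fdr <- pmin(1, pi0 * v_med / r_obs)
  # q-value: best achievable FDR among cutoffs at or below |d_i|
  ord <- order(abs_obs)
  q <- numeric(length(fdr))
  q[ord] <- cummin(fdr[ord])

  names(d_obs) <- names(q) <- rownames(expr)
  structure(list(d = d_obs, q = q,
                 deg_ids = rownames(expr)[q <= fdr_threshold],
                 s0 = s0, pi0 = pi0, exact = exact,
                 n_perm = length(assign_b), fdr_threshold = fdr_threshold,
                 contrast = contrast),
            class = "ncmod_deg")
}

#' @export
print.ncmod_deg <- function(x, ...) {
  cat("SAM permutation differential expression",
      if (!is.null(x$contrast)) paste0("(", x$contrast, ")"), "\n")
  cat(sprintf("  features: %d   s0: %.4g   pi0: %.3f   permutations: %d%s\n",
              length(x$d), x$s0, x$pi0, x$n_perm,
              if (x$exact) " (exact)" else ""))
  cat(sprintf("  DEGs at q <= %.3g: %d\n", x$fdr_threshold, length(x$deg_ids)))
  invisible(x)
}
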