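#' Univariate Cox regression coefficient for one factor
#'
#' Maximum partial-likelihood estimate of the univariate Cox coefficient
#' (Efron ties), via [survival::coxph()]. A positive coefficient means
#' increased expression is associated with increased hazard (a risk
#' factor); a negative one marks a protective factor.
#'
#' @param expr_factor numeric expression vector over patients.
#' @param time,event survival time and event indicator (0/1).
#' @return the estimated beta, or `NA` (with a message) when the factor is
#'   constant, events are fewer than 2, or the fit does not converge.
#' @export
cox_beta_per_factor <- function(expr_factor, time, event) {
  if (sum(event) < 2L) {
    message("factor skipped: fewer than 2 events")
    return(NA_real_)
  }
  if (stats::sd(expr_factor) == 0) {
    message("factor skipped: constant expression")
    return(NA_real_)
  }
  fit <- tryCatch(
    survival::coxph(survival::Surv(time, event) ~ expr_factor, ties = "efron"),
    error = function(e) NULL, warning = function(w) {
      # refit quietly; coxph warns on infinite coefficients (separation)
      fit <- suppressWarnings(
        survival::coxph(survival::Surv(time, event) ~ expr_factor, ties = "efron"))
      if (abs(stats::coef(fit)) > 15) NULL else fit
    })
  if (is.null(fit)) {
    message("factor skipped: Cox fit failed or separated")
    return(NA_real_)
  }
  unname(stats::coef(fit))
}

#' Per-patient risk score
#'
#' The linear combination `sum_i beta_i * expression_i` over the module's
#' factors, evaluated exactly per patient.
#'
#' @param betas named numeric coefficients.
#' @param expr log2 expression matrix (factors x patients) containing every
#'   named factor.
#' @return named numeric vector of per-patient scores.
#' @export
risk_score <- function(betas, expr) {
  missing <- setdiff(names(betas), rownames(expr))
  if (length(missing)) {
    stopf("factor(s) missing from expression matrix: %s",
          paste(missing, collapse = ", "))
  }
  colSums(betas * expr[names(betas), , drop = FALSE])
}

#' Log-rank test between two groups
#'
#' Two-sample log-rank chi-square with 1 df via [survival::survdiff()] and
#' its p-value.
#'
#' @param groups two-level grouping over patients.
#' @param time,event survival time and event indicator.
#' @return list with `chisq` and `p`.
#' @export
logrank_test <- function(groups, time, event) {
  g <- factor(groups)
  if (nlevels(g) != 2L) stopf("log-rank needs exactly 2 groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ g)
  list(chisq = sd$chisq, p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Median dichotomization and log-rank test of risk scores
#'
#' Patients with scores strictly above the median form the high-risk group;
#' scores at or below the median go to the low-risk group (ties to low).
#'
#' @param scores per-patient risk scores.
#' @param time,event survival time and event indicator.
#' @return list with `group_labels` (factor `high`/`low`), `logrank_p`,
#'   `chisq`.
#' @export
dichotomize_and_logrank <- function(scores, time, event) {
  med <- stats::median(scores)
  lab <- factor(ifelse(scores > med, "high", "low"), levels = c("low", "high"))
  if (min(table(lab)) < 2L) {
    stopf("a risk group has fewer than 2 patients after the median split; ties at the median all go to the low group",
          class = "ncmod_tie_split")
  }
  lr <- logrank_test(lab, time, event)
  list(group_labels = lab, logrank_p = lr$p, chisq = lr$chisq)
}

#' Fit the risk-score survival model for one factor set
#'
#' Per-factor univariate Cox coefficients (or one joint multivariable fit),
#' Eq.-style risk scores, median dichotomization, log-rank p and predictive
#' ability `-log10(p)`.
#'
#' @param expr log2 expression matrix (factors x patients).
#' @param time,event survival outcome vectors aligned with the columns.
#' @param multivariable fit one joint Cox model instead of per-factor
#'   univariate fits.
#' @param mode label stored on the result.
#' @return object of class `ncmod_risk_model`: list with `factor_ids`,
#'   `betas`, `risk_scores`, `group_labels`, `logrank_p`,
#'   `predictive_ability`, `mode`, `n_factors_dropped`.
#' @export
fit_risk_model <- function(expr, time, event, multivariable = FALSE,
                           mode = "genes_only") {
  if (multivariable) {
    keep <- apply(expr, 1L, stats::sd) > 0
    x <- t(expr[keep, , drop = FALSE])
    fit <- suppressWarnings(
      survival::coxph(survival::Surv(time, event) ~ x, ties = "efron"))
    betas <- stats::setNames(unname(stats::coef(fit)), rownames(expr)[keep])
    betas[!is.finite(betas)] <- 0
  } else {
    betas <- vapply(rownames(expr), function(f) {
      suppressMessages(cox_beta_per_factor(expr[f, ], time, event))
    }, 0)
  }
  dropped <- sum(is.na(betas))
  betas <- betas[!is.na(betas)]
  if (length(betas) == 0L) stopf("no usable factor: all Cox fits failed")
  scores <- risk_score(betas, expr)
  split <- dichotomize_and_logrank(scores, time, event)
  structure(list(factor_ids = names(betas), betas = betas,
                 risk_scores = scores, group_labels = split$group_labels,
                 logrank_p = split$logrank_p,
                 predictive_ability = -log10(split$logrank_p),
                 mode = mode, n_factors_dropped = dropped),
            class = "ncmod_risk_model")
}

#' @export
print.ncmod_risk_model <- function(x, ...) {
  cat(sprintf("risk model (%s): %d factors, log-rank p = %.3g, -log10(p) = %.2f\n",
              x$mode, length(x$betas), x$logrank_p, x$predictive_ability))
  invisible(x)
}

#' Compare an NcModule's survival prediction with and without its ncRNAs
#'
#' Runs the full risk-score chain twice — once on the module's genes only,
#' once on genes plus pivot ncRNAs — and flags `improved` when the
#' predictive ability `-log10(p)` increases with the ncRNAs. The flag
#' drives the group-A / group-B partition of NcModules.
#'
#' @param gene_expr log2 expression matrix restricted to the module genes.
#' @param nc_expr log2 expression matrix of the module's pivot ncRNAs (may
#'   have 0 rows).
#' @param time,event survival outcome vectors.
#' @param multivariable passed to [fit_risk_model()].
#' @return list with `genes_only`, `genes_plus_ncrna` (risk models) and
#'   `improved`.
#' @export
survival_comparison <- function(gene_expr, nc_expr, time, event,
                                multivariable = FALSE) {
  genes_only <- fit_risk_model(gene_expr, time, event, multivariable,
                               mode = "genes_only")
  full <- rbind(gene_expr, nc_expr)
  genes_plus <- fit_risk_model(full, time, event, multivariable,
                               mode = "genes_plus_ncrna")
  list(genes_only = genes_only, genes_plus_ncrna = genes_plus,
       improved = genes_plus$predictive_ability > genes_only$predictive_ability)
}

#' Survival comparison for an NcModule against the study matrices
#'
#' Convenience wrapper: pulls the module's gene rows from the gene matrix
#' and its pivot rows from the miRNA/lncRNA matrices, then calls
#' [survival_comparison()].
#'
#' @param nc_module NcModule from [build_nc_modules()].
#' @param gene_expr,mirna_expr,lnc_expr log2 expression matrices with
#'   aligned columns.
#' @param clinical clinical table with `os_time`, `os_event` aligned to the
#'   columns.
#' @param ... passed to [survival_comparison()].
#' @return as [survival_comparison()], plus `nc_module_id`.
#' @export
module_survival_comparison <- function(nc_module, gene_expr, mirna_expr,
                                       lnc_expr, clinical, ...) {
  genes <- intersect(nc_module$gene_ids, rownames(gene_expr))
  if (length(genes) < 2L) stopf("NcModule %s: fewer than 2 genes in the expression matrix",
                                nc_module$id)
  nc_rows <- rbind(
    mirna_expr[intersect(nc_module$pivot_ids, rownames(mirna_expr)), , drop = FALSE],
    lnc_expr[intersect(nc_module$pivot_ids, rownames(lnc_expr)), , drop = FALSE]
  )
  out <- survival_comparison(gene_expr[genes, , drop = FALSE], nc_rows,
                             clinical$os_time, clinical$os_event, ...)
  out$nc_module_id <- nc_module$id
  out
}
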