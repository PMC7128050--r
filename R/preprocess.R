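#' Load an expression matrix and apply zero handling and log2 transform
#'
#' Features whose value is 0 in every sample are removed, remaining zeros
#' are floored at `zero_floor`, and the matrix is log2-transformed. Raw
#' values must be nonnegative: a matrix containing negative values looks
#' already log-transformed and is rejected with an error of class
#' `ncmod_loglike_input`.
#'
#' @param x path to a features-x-samples TSV, or a numeric matrix with
#'   feature row names.
#' @param feature_class one of `"mRNA"`, `"miRNA"`, `"lncRNA"` (recorded as
#'   an attribute).
#' @param zero_floor positive value substituted for residual zeros before
#'   the log2 transform.
#' @return log2 expression matrix with attributes `feature_class` and
#'   `n_dropped` (count of all-zero features removed).
#' @export
load_and_transform <- function(x, feature_class = c("mRNA", "miRNA", "lncRNA"),
                               zero_floor = 0.05) {
  feature_class <- match.arg(feature_class)
  mat <- if (is.character(x) && length(x) == 1L) read_expression_tsv(x) else x
  if (!is.matrix(mat) || !is.numeric(mat)) stopf("expected a numeric matrix or a TSV path")
  if (zero_floor <= 0) stopf("zero_floor must be positive", class = "ncmod_param_error")
  if (anyNA(mat)) stopf("expression matrix contains missing values")
  if (any(mat < 0)) {
    stopf("negative expression values found: input looks already log-transformed; expected raw nonnegative RPKM-like values",
          class = "ncmod_loglike_input")
  }
  dup <- unique(rownames(mat)[duplicated(rownames(mat))])
  if (length(dup)) {
    stopf("duplicate feature ids: %s", paste(dup, collapse = ", "),
          class = "ncmod_duplicate_ids")
  }
  all_zero <- rowSums(mat != 0) == 0L
  mat <- mat[!all_zero, , drop = FALSE]
  mat[mat == 0] <- zero_floor
  out <- log2(mat)
  attr(out, "feature_class") <- feature_class
  attr(out, "n_dropped") <- sum(all_zero)
  out
}

#' Load the clinical table
#'
#' Reads `sample_id`, `stage`, `os_time`, `os_event`. Stages `I` and `II`
#' are merged into the `low` group when `merge_low_stages` is `TRUE`.
#' Samples with unknown or missing stage are dropped (with a message), as
#' are samples with missing survival fields.
#'
#' @param x path to a clinical TSV or a `data.frame`.
#' @param merge_low_stages merge stages I/II into `low`.
#' @return `data.frame` with `sample_id`, `stage` factor
#'   (`low`/`III`/`IV`), `os_time`, `os_event`.
#' @export
load_clinical <- function(x, merge_low_stages = TRUE) {
  df <- if (is.character(x) && length(x) == 1L) read_tsv(x) else x
  need <- c("sample_id", "stage", "os_time", "os_event")
  if (!all(need %in% names(df))) {
    stopf("clinical table must have columns %s", paste(need, collapse = ", "))
  }
  stage <- as.character(df$stage)
  if (merge_low_stages) stage[stage %in% c("I", "II")] <- "low"
  known <- stage %in% c("low", "III", "IV") &
    !is.na(df$os_time) & !is.na(df$os_event)
  if (any(!known)) {
    message(sum(!known), " sample(s) dropped: unknown stage or missing survival fields")
  }
  out <- data.frame(sample_id = as.character(df$sample_id)[known],
                    stage = factor(stage[known], levels = c("low", "III", "IV")),
                    os_time = as.numeric(df$os_time)[known],
                    os_event = as.integer(df$os_event)[known],
                    stringsAsFactors = FALSE)
  if (any(out$os_time < 0)) stopf("negative survival times in clinical table")
  out
}

#' Restrict expression matrices and clinical table to shared samples
#'
#' All outputs are restricted to the intersection of sample ids across the
#' matrices and the staged clinical samples, in the clinical table's order,
#' so columns align across feature classes.
#'
#' @param matrices named list of log2 expression matrices.
#' @param clinical clinical `data.frame` from [load_clinical()].
#' @return list with the aligned `matrices` list and `clinical` table.
#' @export
harmonize_samples <- function(matrices, clinical) {
  common <- Reduce(intersect, c(lapply(matrices, colnames),
                                list(clinical$sample_id)))
  if (length(common) == 0L) {
    stopf("no samples shared by all matrices and the clinical table",
          class = "ncmod_empty_intersection")
  }
  common <- clinical$sample_id[clinical$sample_id %in% common]
  list(matrices = lapply(matrices, function(m) m[, common, drop = FALSE]),
       clinical = clinical[match(common, clinical$sample_id), , drop = FALSE])
}
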