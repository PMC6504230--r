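#' Group summary: mean, s.e.m., n
#'
#' The standard per-group summary of the field (`mean +/- s.e.m.`), with
#' the sample SD (n - 1 denominator). A single observation gets `sem = 0`
#' and `degenerate = TRUE`.
#'
#' @param values Numeric vector (non-empty).
#' @param label Group label.
#' @return One-row tibble: `label`, `n`, `mean`, `sem`, `degenerate`.
#' @export
summarize_group <- function(values, label = "group") {
  if (!length(values) || anyNA(values))
    abort_validation("values must be non-empty and free of NA")
  n <- length(values)
  tibble::tibble(label = label, n = n, mean = mean(values),
                 sem = if (n > 1) stats::sd(values) / sqrt(n) else 0,
                 degenerate = n == 1)
}

#' Two-group comparison
#'
#' The two comparisons used throughout: a two-tailed Student's t-test
#' (pooled variance by default, Welch optional) or a Mann-Whitney U test
#' (exact where possible, normal approximation otherwise). Paired versions
#' require equal lengths.
#'
#' @param a,b Numeric vectors.
#' @param paired Paired comparison (default FALSE).
#' @param method `"t"` or `"mann_whitney"`.
#' @param welch Welch correction for the t-test (default FALSE, the classic
#'   pooled test).
#' @return One-row tibble: `method`, `paired`, `statistic`, `p_value`,
#'   `mean_a`, `mean_b`.
#' @export
compare_groups <- function(a, b, paired = FALSE,
                           method = c("t", "mann_whitney"), welch = FALSE) {
  method <- match.arg(method)
  if (paired && length(a) != length(b))
    abort_validation("paired comparison requires equal lengths")
  if (method == "t" && (length(a) < 2 || length(b) < 2))
    abort_validation("t-test requires n >= 2 per group")
  degenerate_t <- function() {
    # (essentially) constant data: t is formally undefined. Equal means
    # carry no evidence of a difference; a nonzero constant difference is
    # as extreme as a t statistic gets.
    d <- mean(a) - mean(b)
    if (abs(d) < 1e-10 * (abs(mean(a)) + abs(mean(b)) + 1e-30))
      list(statistic = 0, p.value = 1)
    else list(statistic = sign(d) * Inf, p.value = 0)
  }
  res <- if (method == "t") {
    out <- tryCatch(stats::t.test(a, b, paired = paired, var.equal = !welch),
                    error = function(e) NULL)
    if (is.null(out) || is.nan(out$p.value)) degenerate_t() else out
  } else {
    suppressWarnings(stats::wilcox.test(a, b, paired = paired))
  }
  tibble::tibble(method = if (method == "t") {
                   paste0(if (paired) "paired " else "unpaired ",
                          if (welch) "Welch t" else "t")
                 } else "Mann-Whitney U",
                 paired = paired,
                 statistic = unname(res$statistic),
                 p_value = res$p.value,
                 mean_a = mean(a), mean_b = mean(b))
}

#' Relative gene expression by the comparative Ct method
#'
#' For each group, `delta Ct = mean(Ct_target) - mean(Ct_reference)` over
#' technical replicates; `delta delta Ct` is taken against the control
#' group, and relative expression is `2^(-delta delta Ct) * 100` so the
#' control group sits at exactly 100%.
#'
#' @param ct Tidy tibble of cycle thresholds with columns `sample_group`,
#'   `gene`, `ct` (one row per technical replicate; Ct > 0).
#' @param target_gene,reference_gene Gene names in `ct` (reference e.g.
#'   GAPDH).
#' @param control_group Group normalized to 100%.
#' @return Tibble: `sample_group`, `delta_ct`, `delta_delta_ct`,
#'   `expression_pct`.
#' @export
relative_expression <- function(ct, target_gene, reference_gene, control_group) {
  need <- c("sample_group", "gene", "ct")
  if (!all(need %in% names(ct)))
    abort_validation(paste0("ct table must have columns: ", paste(need, collapse = ", ")))
  if (any(ct$ct <= 0)) abort_validation("Ct values must be > 0")
  if (!reference_gene %in% ct$gene)
    abort_validation(paste0("missing reference gene: ", reference_gene))
  if (!target_gene %in% ct$gene)
    abort_validation(paste0("missing target gene: ", target_gene))
  d <- ct |>
    dplyr::filter(.data$gene %in% c(target_gene, reference_gene)) |>
    dplyr::summarise(mean_ct = mean(.data$ct),
                     .by = c("sample_group", "gene")) |>
    tidyr::pivot_wider(names_from = "gene", values_from = "mean_ct")
  if (anyNA(d[[target_gene]]) || anyNA(d[[reference_gene]]))
    abort_validation("every group needs Ct for both target and reference genes")
  d$delta_ct <- d[[target_gene]] - d[[reference_gene]]
  if (!control_group %in% d$sample_group)
    abort_validation(paste0("control group not present: ", control_group))
  ctrl <- d$delta_ct[d$sample_group == control_group]
  d$delta_delta_ct <- d$delta_ct - ctrl
  d$expression_pct <- 2^(-d$delta_delta_ct) * 100
  dplyr::select(d, "sample_group", "delta_ct", "delta_delta_ct", "expression_pct")
}

#' Classify vesicles by distance from the active zone
#'
#' Docked vesicles lie within 10 nm of the presynaptic active-zone
#' membrane, clustered vesicles within 200 nm (inclusive boundaries;
#' docked vesicles count among the clustered).
#'
#' @param distances Perpendicular distances from the active-zone membrane,
#'   nm (>= 0).
#' @param docked_nm,clustered_nm Cutoffs, nm (defaults 10 and 200).
#' @return One-row tibble: `n_vesicles`, `docked`, `clustered`.
#' @export
classify_vesicles <- function(distances, docked_nm = 10, clustered_nm = 200) {
  if (any(distances < 0)) abort_validation("distances must be >= 0 nm")
  tibble::tibble(n_vesicles = length(distances),
                 docked = sum(distances <= docked_nm),
                 clustered = sum(distances <= clustered_nm))
}
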