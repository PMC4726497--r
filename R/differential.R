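# Two-perturbation differential expression: call transcripts inverse to the
# driver (up on knockdown, down on overexpression).

#' Two-sample t test (Welch or pooled)
#'
#' Welch unequal-variance t with Satterthwaite degrees of freedom by
#' default; set `var_equal = TRUE` for the pooled-variance test. The sign of
#' t follows `mean(a) - mean(b)`. When both groups have zero variance and
#' equal means, t is defined as 0 with p = 1; with unequal means t is signed
#' infinite with p = 0.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param var_equal Pool the variances?
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
welch_t <- function(a, b, var_equal = FALSE) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 observations")
  }
  res <- row_t(matrix(a, nrow = 1), matrix(b, nrow = 1),
               var_equal = var_equal)
  list(t = res$t, df = res$df, p = res$p)
}

# Vectorized row-wise two-sample t over matrices (genes x samples).
row_t <- function(a, b, var_equal = FALSE) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(ma))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  diff <- ma - mb
  t <- ifelse(se == 0, ifelse(diff == 0, 0, sign(diff) * Inf), diff / se)
  p <- ifelse(se == 0, ifelse(diff == 0, 1, 0),
              2 * stats::pt(abs(t), df, lower.tail = FALSE))
  list(t = t, df = df, p = p)
}

#' Call driver-anticorrelated transcripts
#'
#' Computes, per gene, the knockdown-vs-control and overexpression-vs-control
#' contrasts (orientation: perturbation minus control). A gene is
#' `dysregulated` when `min(p_kd, p_oe) < alpha` (`rule = "any"`, the
#' default) or when both contrasts are significant (`rule = "both"`), and
#' `anticorrelated` when additionally `t_kd > 0` and `t_oe < 0` (up on
#' knockdown, down on overexpression: inverse to the driver).
#'
#' @param exprs Gene x sample numeric matrix (log2 scale), no missing
#'   values.
#' @param groups Tibble/data.frame mapping `sample` to `group` (levels
#'   `control`, `knockdown`, `overexpression`).
#' @param alpha Per-contrast significance level on raw p-values.
#' @param rule `"any"` or `"both"`: how the two contrasts combine into the
#'   dysregulated call.
#' @param var_equal Use the pooled-variance t instead of Welch.
#' @param fdr Apply Benjamini-Hochberg across genes within each contrast
#'   before thresholding.
#' @return Tibble: `gene`, `t_kd`, `p_kd`, `t_oe`, `p_oe`, `dysregulated`,
#'   `anticorrelated`.
#' @export
call_anticorrelated <- function(exprs, groups, alpha = 0.01,
                                rule = c("any", "both"), var_equal = FALSE,
                                fdr = FALSE) {
  rule <- match.arg(rule)
  groups <- as.data.frame(groups)
  need <- c("control", "knockdown", "overexpression")
  missing_grp <- setdiff(need, unique(groups$group))
  if (length(missing_grp) > 0L) {
    stop("missing expression group: ", missing_grp[1])
  }
  idx <- function(g) {
    s <- groups$sample[groups$group == g]
    s <- intersect(colnames(exprs), s)
    if (length(s) < 2L) stop("fewer than 2 samples in group ", g)
    s
  }
  ctrl <- exprs[, idx("control"), drop = FALSE]
  kd <- exprs[, idx("knockdown"), drop = FALSE]
  oe <- exprs[, idx("overexpression"), drop = FALSE]
  if (anyNA(exprs)) stop("expression matrix contains missing values")
  r_kd <- row_t(kd, ctrl, var_equal = var_equal)
  r_oe <- row_t(oe, ctrl, var_equal = var_equal)
  p_kd <- if (fdr) stats::p.adjust(r_kd$p, "BH") else r_kd$p
  p_oe <- if (fdr) stats::p.adjust(r_oe$p, "BH") else r_oe$p
  dys <- if (rule == "any") {
    pmin(p_kd, p_oe) < alpha
  } else {
    p_kd < alpha & p_oe < alpha
  }
  tibble::tibble(gene = rownames(exprs),
                 t_kd = r_kd$t, p_kd = r_kd$p,
                 t_oe = r_oe$t, p_oe = r_oe$p,
                 dysregulated = dys,
                 anticorrelated = dys & r_kd$t > 0 & r_oe$t < 0)
}

#' Confusion-matrix recovery of a planted truth set
#'
#' Evaluates the `anticorrelated` calls against a planted gene set.
#'
#' @param calls Output of [call_anticorrelated()].
#' @param truth Character vector of planted gene ids.
#' @return List: `sensitivity` (NA if truth is empty), `specificity`,
#'   `fdr` (NA if nothing was called), and the underlying counts.
#' @export
recover_truth <- function(calls, truth) {
  pos <- calls$gene %in% truth
  called <- calls$anticorrelated
  tp <- sum(called & pos); fp <- sum(called & !pos)
  fn <- sum(!called & pos); tn <- sum(!called & !pos)
  list(sensitivity = if (tp + fn == 0L) NA_real_ else tp / (tp + fn),
       specificity = if (tn + fp == 0L) NA_real_ else tn / (tn + fp),
       fdr = if (tp + fp == 0L) NA_real_ else fp / (tp + fp),
       tp = tp, fp = fp, fn = fn, tn = tn)
}
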