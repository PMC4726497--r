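# Inverse-correlation-weighted gene signatures and median-split survival
# stratification.

#' Build an inverse-correlation-weighted signature
#'
#' Each gene's weight is minus its Pearson correlation with the driver gene
#' across all samples, so genes anticorrelated with the driver get positive
#' weights and a high score means high expression of the driver-repressed
#' program. Zero-variance genes are excluded with a warning.
#'
#' @param genes Character vector of signature candidate genes (subset of
#'   `rownames(exprs)`).
#' @param exprs Gene x sample expression matrix containing `driver`.
#' @param driver Driver gene id (e.g. the deadenylase subunit).
#' @return Tibble: `gene`, `weight`.
#' @export
build_signature <- function(genes, exprs, driver) {
  if (!driver %in% rownames(exprs)) stop("driver not in matrix: ", driver)
  absent <- setdiff(genes, rownames(exprs))
  if (length(absent) > 0L) stop("gene not in matrix: ", absent[1])
  d <- exprs[driver, ]
  if (stats::sd(d) == 0) stop("driver has zero variance")
  w <- vapply(genes, function(g) {
    x <- exprs[g, ]
    if (stats::sd(x) == 0) NA_real_ else -stats::cor(x, d)
  }, 0)
  drop <- is.na(w)
  if (any(drop)) {
    warning(sum(drop), " zero-variance gene(s) excluded from the signature")
  }
  tibble::tibble(gene = genes[!drop], weight = unname(w[!drop]))
}

#' Map a signature across an ortholog table
#'
#' Renames signature genes via a mouse-to-human symbol map. Unmapped genes
#' are dropped and counted, never silently. When two source genes map to
#' the same target symbol, the entry with the larger absolute weight is
#' kept and the collision is reported.
#'
#' @param signature Tibble `gene`, `weight`.
#' @param map Tibble/data.frame with columns `mouse`, `human` (a function:
#'   one human symbol per mouse symbol).
#' @return List: `signature` (mapped tibble), `coverage` (mapped / total),
#'   `n_unmapped`, `collisions` (character vector of human symbols that
#'   collided).
#' @export
map_orthologs <- function(signature, map) {
  map <- as.data.frame(map)
  if (anyDuplicated(map$mouse)) {
    stop("ortholog map is not a function: duplicate mouse symbol ",
         map$mouse[duplicated(map$mouse)][1])
  }
  total <- nrow(signature)
  hit <- match(signature$gene, map$mouse)
  mapped <- signature[!is.na(hit), , drop = FALSE]
  mapped$gene <- map$human[hit[!is.na(hit)]]
  collisions <- unique(mapped$gene[duplicated(mapped$gene)])
  if (length(collisions) > 0L) {
    mapped <- dplyr::slice_max(
      dplyr::group_by(mapped, .data$gene), abs(.data$weight), n = 1L,
      with_ties = FALSE)
    mapped <- dplyr::ungroup(mapped)
  }
  mapped <- dplyr::arrange(mapped, .data$gene)
  list(signature = mapped,
       coverage = if (total == 0L) 0 else nrow(mapped) / total,
       n_unmapped = total - sum(!is.na(hit)),
       collisions = collisions)
}

#' Score patients against a weighted signature
#'
#' Each signature gene is z-standardized across patients; a patient's score
#' is the weight-normalized sum `sum(w_g * z_gp) / sum(|w_g|)`. Signature
#' genes missing from the cohort are excluded (with a message) and the
#' normalization uses the remaining weights.
#'
#' @param signature Tibble `gene`, `weight` (weights not all zero).
#' @param expression Gene x patient matrix.
#' @return Named numeric vector of per-patient scores.
#' @export
score_patients <- function(signature, expression) {
  present <- signature$gene %in% rownames(expression)
  if (!any(present)) stop("no signature gene present in the cohort matrix")
  n_missing <- sum(!present)
  if (n_missing > 0L) {
    message(n_missing, " signature gene(s) missing from cohort; ",
            "renormalizing over ", sum(present), " genes")
  }
  sig <- signature[present, , drop = FALSE]
  if (sum(abs(sig$weight)) == 0) stop("signature weights are all zero")
  x <- expression[sig$gene, , drop = FALSE]
  mu <- rowMeans(x)
  s <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1))
  s[s == 0] <- 1          # constant gene contributes a zero z-score
  z <- (x - mu) / s
  drop(crossprod(z, sig$weight))[colnames(expression)] /
    sum(abs(sig$weight))
}

#' Median-split log-rank stratification
#'
#' Splits the cohort at the median score (ties to the low group) and
#' compares distant-metastasis-free survival between the halves with the
#' Mantel-Cox (log-rank) test.
#'
#' @param scores Named numeric vector (names = patient ids).
#' @param cohort Tibble with `patient`, `time`, `event` (1 = event,
#'   0 = censored).
#' @return List of class `stratification`: `group` (factor per patient),
#'   `chisq`, `p`, and `table` (per-group n, events, median survival).
#' @export
stratify_logrank <- function(scores, cohort) {
  s <- scores[cohort$patient]
  if (anyNA(s)) stop("missing score for patient ",
                     cohort$patient[which(is.na(s))[1]])
  med <- stats::median(s)
  group <- factor(ifelse(s <= med, "low", "high"), levels = c("low", "high"))
  if (nlevels(droplevels(group)) < 2L || min(table(group)) < 2L) {
    stop("median split leaves fewer than 2 patients in a group")
  }
  fit <- survival::survdiff(survival::Surv(cohort$time, cohort$event) ~
                              group)
  chisq <- unname(fit$chisq)
  p <- stats::pchisq(chisq, df = 1L, lower.tail = FALSE)
  sf <- survival::survfit(survival::Surv(cohort$time, cohort$event) ~
                            group)
  med_surv <- summary(sf)$table[, "median"]
  n_grp <- as.integer(table(group))
  ev_grp <- as.integer(tapply(cohort$event, group, sum))
  tab <- tibble::tibble(group = levels(group), n = n_grp, events = ev_grp,
                        median_survival = unname(med_surv))
  out <- list(group = stats::setNames(group, cohort$patient),
              chisq = chisq, p = p, table = tab)
  class(out) <- "stratification"
  out
}

#' Kaplan-Meier step coordinates per stratum
#'
#' Convenience export of the survival step functions for plotting.
#'
#' @param scores,cohort As in [stratify_logrank()].
#' @return Tibble: `group`, `time`, `surv`, `n_risk`, `n_event`.
#' @export
km_curves <- function(scores, cohort) {
  s <- scores[cohort$patient]
  med <- stats::median(s)
  group <- factor(ifelse(s <= med, "low", "high"), levels = c("low", "high"))
  sf <- survival::survfit(survival::Surv(cohort$time, cohort$event) ~
                            group)
  strata <- rep(names(sf$strata), sf$strata)
  tibble::tibble(group = sub("^group=", "", strata),
                 time = sf$time, surv = sf$surv,
                 n_risk = sf$n.risk, n_event = sf$n.event)
}
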