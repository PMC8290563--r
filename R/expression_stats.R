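# Experimental-phase statistics: ddCT relative quantification, one-way
# ANOVA with pairwise post-hoc contrasts, Pearson correlation, bootstrap
# ROC/AUC, HOMA-IR, and tolerance-test AUC.

#' Read a long-format qPCR CT table
#'
#' @param path TSV with header columns `sample`, `group`, `target`, `ct`.
#' @return data.frame with those columns; `ct` numeric.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) stop("CT table not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  miss <- setdiff(c("sample", "group", "target", "ct"), names(df))
  if (length(miss)) stop("CT table lacks columns: ",
                         paste(miss, collapse = ", "))
  df$ct <- as.numeric(df$ct)
  df
}

#' Relative expression by the ddCT method
#'
#' Per sample and target: dCT = CT(target) - CT(reference gene);
#' ddCT = dCT - mean dCT of the calibrator group for that target;
#' fold = 2^(-ddCT). Calibration is against the calibrator-group mean
#' because samples (animals) are not paired across groups, so the
#' calibrator-group mean fold is 1 by construction. Samples missing
#' either CT are skipped with a message.
#'
#' @param ct long-format CT data.frame ([read_ct_table()]).
#' @param reference reference assay name (default `"18SrRNA"`).
#' @param calibrator_group group whose mean dCT anchors ddCT (default
#'   `"Ctrl"`).
#' @return data.frame: `sample`, `group`, `target`, `delta_ct`,
#'   `delta_delta_ct`, `fold`.
#' @export
ddct <- function(ct, reference = "18SrRNA", calibrator_group = "Ctrl") {
  if (!reference %in% ct$target)
    stop("reference assay '", reference, "' absent from CT table")
  if (!calibrator_group %in% ct$group)
    stop("calibrator group '", calibrator_group, "' absent from CT table")
  ref <- ct[ct$target == reference & is.finite(ct$ct), ]
  ref_ct <- stats::setNames(ref$ct, ref$sample)
  tgt <- ct[ct$target != reference, , drop = FALSE]
  has_ref <- tgt$sample %in% names(ref_ct)
  ok <- has_ref & is.finite(tgt$ct)
  n_skipped <- sum(!ok)
  if (n_skipped > 0L)
    message("ddct: skipped ", n_skipped,
            " well(s) missing a target or reference CT")
  tgt <- tgt[ok, , drop = FALSE]
  tgt$delta_ct <- tgt$ct - ref_ct[tgt$sample]
  out <- do.call(rbind, lapply(split(tgt, tgt$target), function(d) {
    cal <- d$delta_ct[d$group == calibrator_group]
    if (!length(cal))
      stop("calibrator group empty for target ", d$target[1])
    d$delta_delta_ct <- d$delta_ct - mean(cal)
    d$fold <- 2^(-d$delta_delta_ct)
    d
  }))
  rownames(out) <- NULL
  out[c("sample", "group", "target", "delta_ct", "delta_delta_ct", "fold")]
}

#' One-way fixed-effects ANOVA with group summaries
#'
#' @param values named list mapping group label to a numeric vector
#'   (each of length >= 2).
#' @return list with `F`, `p`, `df`, and a `groups` data.frame (`group`,
#'   `n`, `mean`, `sem`, with SEM = sd/sqrt(n)). When every group has
#'   zero variance and equal means the F statistic is undefined; `p = 1`
#'   is returned with a warning.
#' @export
group_anova <- function(values) {
  if (length(values) < 2L) stop("need at least 2 groups")
  ns <- lengths(values)
  if (any(ns < 2L))
    stop("degenerate group (n < 2): ", names(values)[which(ns < 2L)[1]])
  y <- unlist(values, use.names = FALSE)
  g <- factor(rep(names(values), ns), levels = names(values))
  groups <- data.frame(
    group = names(values), n = as.integer(ns),
    mean = vapply(values, mean, numeric(1)),
    sem = vapply(values, function(v) stats::sd(v) / sqrt(length(v)),
                 numeric(1)),
    stringsAsFactors = FALSE)
  rownames(groups) <- NULL
  if (stats::var(y) == 0) {
    warning("all values identical: ANOVA F undefined, reporting p = 1")
    return(list(F = NA_real_, p = 1,
                df = c(length(values) - 1L, length(y) - length(values)),
                groups = groups))
  }
  fit <- stats::aov(y ~ g)
  tab <- summary(fit)[[1]]
  list(F = tab[["F value"]][1], p = tab[["Pr(>F)"]][1],
       df = c(tab[["Df"]][1], tab[["Df"]][2]), groups = groups)
}

#' Pairwise Welch t-tests with BH correction
#'
#' The post-hoc companion to [group_anova()] for letter-coded group
#' contrasts.
#'
#' @param values named list mapping group label to a numeric vector.
#' @return data.frame: `group_a`, `group_b`, `estimate` (mean a - mean
#'   b), `p`, `p_adjusted`.
#' @export
posthoc_pairwise <- function(values) {
  cmb <- utils::combn(names(values), 2)
  rows <- lapply(seq_len(ncol(cmb)), function(i) {
    a <- cmb[1, i]; b <- cmb[2, i]
    tt <- stats::t.test(values[[a]], values[[b]])
    data.frame(group_a = a, group_b = b,
               estimate = mean(values[[a]]) - mean(values[[b]]),
               p = tt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- adjust_bh(out$p)
  out
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return list with `r`, `p` (two-sided, t transform on n-2 df), `n`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' ROC area under the curve with bootstrap confidence interval
#'
#' AUC is the rank-sum (Mann-Whitney) probability that a positive scores
#' above a negative, ties counted one half. The confidence interval is a
#' percentile bootstrap over class-stratified resamples.
#'
#' @param scores numeric scores (higher = more positive-like).
#' @param labels binary labels (0/1, or logical) of the same length; both
#'   classes must be present.
#' @param n_boot bootstrap resamples (default 2000).
#' @param seed RNG seed for the bootstrap (default 1).
#' @param conf confidence level (default 0.95).
#' @return list with `auc`, `ci_low`, `ci_high`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, n_boot = 2000L, seed = 1L,
                    conf = 0.95) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length")
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  if (!length(pos) || !length(neg))
    stop("both classes must be present")
  point <- .auc_ranksum(pos, neg)
  cis <- c(NA_real_, NA_real_)
  if (n_boot > 0L) {
    boots <- numeric(n_boot)
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
    for (b in seq_len(n_boot)) {
      boots[b] <- .auc_ranksum(sample(pos, replace = TRUE),
                               sample(neg, replace = TRUE))
    }
    alpha <- 1 - conf
    cis <- unname(stats::quantile(boots, c(alpha / 2, 1 - alpha / 2)))
  }
  list(auc = point, ci_low = cis[1], ci_high = cis[2],
       n_pos = length(pos), n_neg = length(neg))
}

# Mann-Whitney AUC via midranks; ties count one half
.auc_ranksum <- function(pos, neg) {
  r <- rank(c(pos, neg), ties.method = "average")
  np <- length(pos); nn <- length(neg)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Homeostatic model assessment of insulin resistance
#'
#' HOMA-IR = fasting insulin (uU/mL) x fasting glucose (mg/dL) / 405.
#' The insulin argument must already be in uU/mL; use
#' [insulin_ng_to_uU()] for ELISA readouts reported in ng/mL.
#'
#' @param fasting_insulin fasting plasma insulin, uU/mL (positive).
#' @param fasting_glucose fasting blood glucose, mg/dL (positive).
#' @return numeric HOMA-IR value(s).
#' @export
homa_ir <- function(fasting_insulin, fasting_glucose) {
  if (any(fasting_insulin <= 0) || any(fasting_glucose <= 0))
    stop("insulin and glucose must be positive")
  fasting_insulin * fasting_glucose / 405
}

#' Convert insulin from ng/mL to uU/mL
#'
#' ELISA kits commonly report insulin mass concentration; the HOMA-IR
#' formula needs activity units. The default factor 25 uU per ng is the
#' conventional conversion for insulin; it is exposed rather than applied
#' silently inside [homa_ir()].
#'
#' @param insulin_ng_ml insulin in ng/mL.
#' @param factor uU per ng (default 25).
#' @return insulin in uU/mL.
#' @export
insulin_ng_to_uU <- function(insulin_ng_ml, factor = 25) {
  if (any(insulin_ng_ml < 0)) stop("insulin must be non-negative")
  insulin_ng_ml * factor
}

#' Tolerance-test area under the glucose curve
#'
#' Trapezoidal area of the blood-glucose time course of a glucose or
#' insulin tolerance test, in mg/dL x min. `incremental = TRUE`
#' subtracts the baseline (first) glucose value before integrating.
#'
#' @param minutes strictly increasing sampling times, min.
#' @param glucose blood glucose at each time, mg/dL.
#' @param incremental subtract the baseline value (default FALSE: total
#'   area).
#' @return numeric area.
#' @export
tolerance_auc <- function(minutes, glucose, incremental = FALSE) {
  if (length(minutes) != length(glucose))
    stop("minutes and glucose must have equal length")
  if (length(minutes) < 2L) stop("need at least 2 time points")
  if (any(diff(minutes) <= 0)) stop("minutes must be strictly increasing")
  if (incremental) glucose <- glucose - glucose[1]
  pracma::trapz(minutes, glucose)
}
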