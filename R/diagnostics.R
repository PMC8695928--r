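## Group testing and diagnostic-accuracy evaluation of the twelve bilateral
## differential parameters: Mann-Whitney U with the tie-corrected normal Z,
## empirical ROC curves, Youden cutoff selection, DeLong AUROC confidence
## intervals, and classification against the shipped reference thresholds.

#' Mann-Whitney U test (tie-corrected normal approximation)
#'
#' U is computed from midranks; the standardized statistic is
#' `Z = (U - n1 n2 / 2) / sqrt(V)` with the tie-corrected variance
#' `V = n1 n2 / 12 * (n + 1 - sum(t^3 - t) / (n (n - 1)))` where `t` runs
#' over tie-group sizes, and no continuity correction — the large-sample
#' convention of the major statistics packages. `Z > 0` means `x` tends to
#' rank above `y`.
#'
#' @param x,y numeric samples for the two groups (e.g. keratoconus and
#'   control values of one differential parameter).
#' @return List of class `mann_whitney_result`: `U`, `Z`, `p` (two-sided),
#'   `n1`, `n2`.
#' @examples
#' mann_whitney(c(4, 5, 6), c(1, 2, 3))  # U = 9, Z = 4.5 / sqrt(5.25)
#' @export
mann_whitney <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty", call. = FALSE)
  n <- n1 + n2
  r <- rank(c(x, y))                        # midranks
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(x, y))
  tie_term <- if (n > 1) sum(ties^3 - ties) / (n * (n - 1)) else 0
  V <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (V <= 0) {
    Z <- 0; p <- 1                          # all values identical
  } else {
    Z <- (U - n1 * n2 / 2) / sqrt(V)
    p <- 2 * stats::pnorm(-abs(Z))
    p <- min(max(p, .Machine$double.xmin), 1)
  }
  structure(list(U = U, Z = Z, p = p, n1 = n1, n2 = n2),
            class = "mann_whitney_result")
}

#' @export
print.mann_whitney_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney: U = %g, Z = %.3f, p = %.3g (n1 = %d, n2 = %d)\n",
              x$U, x$Z, x$p, x$n1, x$n2))
  invisible(x)
}

#' Empirical AUROC (tie-aware)
#'
#' Probability that a randomly chosen positive score exceeds a randomly
#' chosen negative score, crediting ties one half — identical to the
#' trapezoidal area under the empirical ROC curve and to
#' `U / (n1 * n2)` with the midrank Mann-Whitney U.
#'
#' @param scores numeric marker values.
#' @param labels logical or 0/1; `TRUE`/1 marks the positive (disease)
#'   class. Higher scores are assumed to indicate disease.
#' @return AUROC in `[0, 1]`.
#' @export
empirical_auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  if (!any(labels) || all(labels))
    stop("both classes must be present", call. = FALSE)
  mann_whitney(scores[labels], scores[!labels])$U /
    (sum(labels) * sum(!labels))
}

#' AUROC implied by a Mann-Whitney Z statistic
#'
#' Inverts the (tie-free) normal approximation linking the standardized
#' Mann-Whitney statistic to the AUROC:
#' `AUC = 1/2 + |Z| * sqrt(n1 n2 (n1 + n2 + 1) / 12) / (n1 n2)`. With a
#' published group comparison's Z and group sizes this recovers, to the
#' printed precision, the AUROC the same cohort yields — a useful internal
#' consistency check between a rank-test table and a ROC table.
#'
#' @param Z standardized Mann-Whitney statistic (sign ignored).
#' @param n1,n2 group sizes.
#' @return Implied AUROC in `[0.5, 1)` for finite `Z`.
#' @examples
#' implied_auroc_from_z(-15.336, 161, 174)  # 0.985
#' @export
implied_auroc_from_z <- function(Z, n1, n2) {
  stopifnot(n1 >= 1, n2 >= 1)
  0.5 + abs(Z) * sqrt(n1 * n2 * (n1 + n2 + 1) / 12) / (n1 * n2)
}

delong_auc_var <- function(pos, neg) {
  ## placement-value components (Sen/DeLong structural estimate)
  m <- length(pos); n <- length(neg)
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  V10 <- vapply(pos, function(p) mean(psi(p, neg)), numeric(1))
  V01 <- vapply(neg, function(q) mean(psi(pos, q)), numeric(1))
  s10 <- if (m > 1) stats::var(V10) else 0
  s01 <- if (n > 1) stats::var(V01) else 0
  s10 / m + s01 / n
}

#' ROC curve, AUROC with DeLong CI, and Youden-optimal cutoff
#'
#' Scans every threshold at the midpoints between consecutive distinct
#' scores (plus the two outer extremes); a subject is called positive when
#' its score is at or above the threshold. The reported cutoff maximises
#' the Youden index `J = sensitivity + specificity - 1`; ties are broken in
#' favour of higher specificity, then lower threshold. The 95% CI of the
#' AUROC uses DeLong's method.
#'
#' @inheritParams empirical_auroc
#' @return Object of class `roc_result`: `auroc`, `ci95` (length 2),
#'   `cutoff`, `sensitivity`, `specificity` (percent), `youden`, and
#'   `curve` (data frame of `fpr`, `tpr`, `threshold`, ordered (0,0) to
#'   (1,1)).
#' @examples
#' r <- roc_cutoff(c(0, 1, 2, 3), c(FALSE, FALSE, TRUE, TRUE))
#' r$cutoff       # 1.5
#' r$sensitivity  # 100
#' @export
roc_cutoff <- function(scores, labels) {
  labels <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  if (!any(labels) || all(labels))
    stop("both classes must be present", call. = FALSE)
  pos <- scores[labels]; neg <- scores[!labels]
  s <- sort(unique(scores))
  thr <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
           s[length(s)] + 1)
  sens <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg < t), numeric(1))
  curve <- data.frame(fpr = 1 - spec, tpr = sens, threshold = thr)
  curve <- curve[order(curve$fpr, curve$tpr), ]
  rownames(curve) <- NULL
  J <- sens + spec - 1
  best <- order(-J, -spec, thr)[1]
  auc <- empirical_auroc(scores, labels)
  se <- sqrt(delong_auc_var(pos, neg))
  ci <- pmin(pmax(auc + c(-1, 1) * stats::qnorm(0.975) * se, 0), 1)
  structure(list(auroc = auc, ci95 = ci, cutoff = thr[best],
                 sensitivity = 100 * sens[best],
                 specificity = 100 * spec[best], youden = J[best],
                 curve = curve),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(paste0("ROC: AUROC %.3f (95%% CI %.3f-%.3f), cutoff %.4g, ",
                     "sensitivity %.1f%%, specificity %.1f%%\n"),
              x$auroc, x$ci95[1], x$ci95[2], x$cutoff,
              x$sensitivity, x$specificity))
  invisible(x)
}

#' Reference diagnostic statistics for the twelve differential parameters
#'
#' Group statistics and diagnostic accuracies established on the clinical
#' reference cohort of 161 keratoconus/ectasia and 174 control subjects:
#' per-parameter Mann-Whitney Z, AUROC with 95% CI, the validated screening
#' cutoff (same units as the parameter) and its sensitivity/specificity in
#' percent. These cutoffs are the shipped defaults of
#' [classify_subject()].
#'
#' @return Data frame with one row per parameter (`dFKmax ... dCPsd`).
#' @export
kc_reference <- function() {
  data.frame(
    parameter = PARAM_NAMES,
    units = unname(PARAM_UNITS[PARAM_NAMES]),
    Z = c(-15.254, -15.336, -15.341, -15.285, -15.254, -15.301,
          -13.213, -14.648, -14.286, -6.261, -8.204, -8.240),
    auroc = c(0.982, 0.985, 0.985, 0.983, 0.982, 0.984,
              0.918, 0.963, 0.952, 0.698, 0.759, 0.761),
    ci_low = c(0.970, 0.973, 0.974, 0.972, 0.968, 0.972,
               0.887, 0.941, 0.929, 0.639, 0.705, 0.706),
    ci_high = c(0.995, 0.997, 0.996, 0.995, 0.997, 0.996,
                0.949, 0.985, 0.974, 0.757, 0.814, 0.815),
    cutoff = c(2.56, 0.75, 0.67, 14.6, 4.3, 2.9,
               36.3, 9.9, 7.6, 38.4, 13.2, 8.5),
    sensitivity = c(95.7, 95.7, 95.0, 95.0, 95.7, 96.9,
                    85.7, 93.2, 88.8, 65.2, 69.6, 70.8),
    specificity = c(95.4, 96.0, 97.7, 95.4, 96.0, 94.8,
                    85.6, 92.5, 89.1, 65.5, 70.7, 70.7),
    n_kc = 161L, n_control = 174L,
    stringsAsFactors = FALSE)
}

#' Shipped screening thresholds
#'
#' The reference cutoffs of [kc_reference()] as a named vector, with the
#' four headline parameters (`dFKmean` 0.75 D, `dFKsd` 0.67 D, `dFEsd`
#' 2.9 um, `dFEmax` 14.6 um — the highest-accuracy quartet) marked in the
#' `headline` attribute.
#'
#' @return Named numeric vector of length 12 with attribute `headline`.
#' @export
default_thresholds <- function() {
  ref <- kc_reference()
  thr <- stats::setNames(ref$cutoff, ref$parameter)
  attr(thr, "headline") <- c("dFKmean", "dFKsd", "dFEsd", "dFEmax")
  thr
}

#' Classify a subject from its differential parameters
#'
#' Flags each parameter whose value is at or above its cutoff (boundary
#' inclusive). The subject-level decision is positive when any parameter of
#' the decision set flags; by default the decision set is the four headline
#' parameters (`dFKmean`, `dFKsd`, `dFEsd`, `dFEmax`). The per-parameter
#' reference performances were established one parameter at a time, so the
#' combined rule is an explicit extension beyond them.
#'
#' @param params named numeric vector of the twelve parameters, as from
#'   [compute_parameters()] (a subset covering `decision_set` suffices).
#' @param thresholds named cutoffs, default [default_thresholds()].
#' @param decision_set parameters whose flags drive the subject decision.
#' @return List of class `screening_result`: `positive` (logical), `flags`
#'   (named logical), `decision_set`.
#' @examples
#' p <- setNames(numeric(12), kc_reference()$parameter)
#' p["dFKmean"] <- 0.80
#' classify_subject(p)$positive  # TRUE: 0.80 D >= 0.75 D cutoff
#' @export
classify_subject <- function(params, thresholds = default_thresholds(),
                             decision_set = attr(thresholds, "headline")) {
  if (is.null(decision_set))
    decision_set <- names(thresholds)
  use <- intersect(names(thresholds), names(params))
  missing_ref <- setdiff(decision_set, names(params))
  if (length(missing_ref) > 0)
    stop("parameter(s) missing from input: ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  flags <- stats::setNames(as.numeric(params[use]) >= thresholds[use], use)
  structure(list(positive = any(flags[decision_set]), flags = flags,
                 decision_set = decision_set),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("screening decision: %s (rule: any of %s)\n",
              if (x$positive) "POSITIVE" else "negative",
              paste(x$decision_set, collapse = ", ")))
  flagged <- names(x$flags)[x$flags]
  cat("  flagged:", if (length(flagged)) paste(flagged, collapse = ", ")
      else "none", "\n")
  invisible(x)
}

#' Per-parameter group tests and ROC evaluation of a cohort table
#'
#' For each of the twelve differential parameters, compares the `KC` group
#' against `control` with [mann_whitney()] and evaluates discrimination
#' with [roc_cutoff()] (positives = `KC`). Deterministic for fixed input.
#'
#' @param params data frame from [cohort_parameters()]: columns `group`
#'   (values `"KC"`/`"control"`) and the parameter columns.
#' @return Data frame with one row per parameter: `U`, `Z`, `p`, `auroc`,
#'   `ci_low`, `ci_high`, `cutoff`, `sensitivity`, `specificity`.
#' @export
evaluate_cohort <- function(params) {
  stopifnot(is.data.frame(params), "group" %in% names(params))
  groups <- params$group
  if (!any(groups == "KC") || !any(groups == "control"))
    stop("both groups (KC, control) must be present", call. = FALSE)
  present <- intersect(PARAM_NAMES, names(params))
  rows <- lapply(present, function(pn) {
    v <- params[[pn]]
    mw <- mann_whitney(v[groups == "KC"], v[groups == "control"])
    roc <- roc_cutoff(v, groups == "KC")
    data.frame(parameter = pn, units = unname(PARAM_UNITS[pn]),
               U = mw$U, Z = mw$Z, p = mw$p,
               auroc = roc$auroc, ci_low = roc$ci95[1],
               ci_high = roc$ci95[2], cutoff = roc$cutoff,
               sensitivity = roc$sensitivity,
               specificity = roc$specificity,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
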