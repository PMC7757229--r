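#' ROC analysis for a bloom/non-bloom score
#'
#' Builds the full receiver operating characteristic for the rule
#' `score > threshold => bloom`. Candidate thresholds are the midpoints
#' between consecutive sorted unique scores, plus -Inf/+Inf sentinels. The
#' best threshold maximizes Youden's J (sensitivity + specificity - 1);
#' ties break toward the higher threshold (fewer false bloom calls).
#'
#' @param scores Finite numeric scores (higher = more bloom-like).
#' @param labels Logical reference labels (TRUE = bloom); both classes
#'   must be present.
#' @return A `roc_curve` list: `thresholds`, `sensitivity`, `specificity`,
#'   `youden_j`, `best_threshold`, `best_sensitivity`, `best_specificity`.
#' @export
roc_threshold <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  if (any(!is.finite(scores))) stop("roc_threshold(): scores must be finite")
  if (!any(labels) || all(labels))
    stop("roc_threshold(): both classes must be present")
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  sens <- vapply(cand, function(th) sum(scores > th & labels) / n_pos,
                 numeric(1))
  spec <- vapply(cand, function(th) sum(scores <= th & !labels) / n_neg,
                 numeric(1))
  j <- sens + spec - 1
  best <- max(which(j == max(j)))   # ties -> higher threshold
  structure(list(thresholds = cand, sensitivity = sens, specificity = spec,
                 youden_j = j, best_threshold = cand[best],
                 best_sensitivity = sens[best],
                 best_specificity = spec[best]),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf(
    "<roc_curve> %d candidates; best threshold %.4g (sens %.3f, spec %.3f, J %.3f)\n",
    length(x$thresholds), x$best_threshold, x$best_sensitivity,
    x$best_specificity, x$best_sensitivity + x$best_specificity - 1))
  invisible(x)
}

#' Fit the dual optical bloom thresholds for a region
#'
#' Stage 1 runs [roc_threshold()] on the b_bp/[Chl-a] ratio over all
#' labelled in-region records, giving `theta_ratio`. Stage 2 reruns the
#' ROC on surface b_bp restricted to records with ratio above
#' `theta_ratio`, giving `theta_bbp`; this second threshold rejects
#' high-ratio records that owe their ratio to low chlorophyll rather than
#' to the high particle backscatter typical of coccolith-laden waters.
#' Performance of the combined rule (ratio > theta_ratio AND
#' bbp > theta_bbp) is reported on the full in-region set.
#'
#' @param records Labelled surface records ([label_records()]): needs
#'   `ratio_bbp_chl`, `bbp_surf`, `bloom_label`, `lat`, `lon`.
#' @param region Region name stored in the result (default "all").
#' @param polygon Optional region polygon (data.frame with `lon`, `lat`
#'   vertices); records outside it are dropped before fitting.
#' @return A `threshold_set` one-row tibble: `region`, `theta_ratio`
#'   (m^2 mg^-1), `theta_bbp` (m^-1), `sensitivity`, `specificity`
#'   (percent), `stage2_flagged`.
#' @export
fit_dual_thresholds <- function(records, region = "all", polygon = NULL) {
  r <- tibble::as_tibble(records)
  if (!is.null(polygon))
    r <- r[point_in_polygon(r$lat, r$lon, polygon), , drop = FALSE]
  r <- r[is.finite(r$ratio_bbp_chl) & is.finite(r$bbp_surf), , drop = FALSE]
  if (nrow(r) == 0 || !any(r$bloom_label) || all(r$bloom_label))
    stop("fit_dual_thresholds(): region must contain labelled records of both classes")
  roc1 <- roc_threshold(r$ratio_bbp_chl, r$bloom_label)
  theta_ratio <- roc1$best_threshold
  sub <- r[r$ratio_bbp_chl > theta_ratio, , drop = FALSE]
  stage2_flagged <- FALSE
  if (nrow(sub) > 0 && any(sub$bloom_label) && !all(sub$bloom_label)) {
    roc2 <- roc_threshold(sub$bbp_surf, sub$bloom_label)
    theta_bbp <- roc2$best_threshold
  } else {
    stage2_flagged <- TRUE
    pool <- if (any(sub$bloom_label)) sub else r
    theta_bbp <- min(pool$bbp_surf[pool$bloom_label])
    roc2 <- NULL
  }
  pred <- r$ratio_bbp_chl > theta_ratio & r$bbp_surf > theta_bbp
  out <- tibble::tibble(
    region = region, theta_ratio = theta_ratio, theta_bbp = theta_bbp,
    sensitivity = 100 * sum(pred & r$bloom_label) / sum(r$bloom_label),
    specificity = 100 * sum(!pred & !r$bloom_label) / sum(!r$bloom_label),
    stage2_flagged = stage2_flagged)
  attr(out, "roc_ratio") <- roc1
  attr(out, "roc_bbp") <- roc2
  class(out) <- c("threshold_set", class(out))
  out
}

#' Classify float surface records with a dual-threshold set
#'
#' A record is called in-bloom iff `ratio_bbp_chl > theta_ratio` AND
#' `bbp_surf > theta_bbp` (strict inequalities: a record exactly on a
#' threshold is non-bloom). Records with missing chlorophyll or
#' backscattering yield `NA`.
#'
#' @param records Surface-record tibble.
#' @param thresholds A one-row `threshold_set` (or any list with
#'   `theta_ratio` and `theta_bbp`).
#' @return Logical vector of bloom calls (`NA` = undefined).
#' @export
classify_records <- function(records, thresholds) {
  th_r <- thresholds$theta_ratio[1]
  th_b <- thresholds$theta_bbp[1]
  stopifnot(is.finite(th_r), is.finite(th_b), th_r > 0, th_b > 0)
  ok <- is.finite(records$ratio_bbp_chl) & is.finite(records$bbp_surf)
  out <- rep(NA, nrow(tibble::as_tibble(records)))
  out[ok] <- records$ratio_bbp_chl[ok] > th_r & records$bbp_surf[ok] > th_b
  out
}

#' Compare an optical ratio inside vs outside blooms
#'
#' Two-group Kruskal-Wallis test (rank-based H statistic with tie
#' correction, chi-square p-value), the nonparametric one-way ANOVA used
#' to report in-bloom vs out-of-bloom differences in b_bp/c_p and
#' b_bp/[Chl-a]. When every value in both groups is identical the test is
#' degenerate and H = 0, p = 1 is returned.
#'
#' @param values_in,values_out Non-empty numeric vectors.
#' @return List with `statistic` (H), `p_value`, and group sizes.
#' @export
compare_groups <- function(values_in, values_out) {
  stopifnot(length(values_in) > 0, length(values_out) > 0)
  if (length(unique(c(values_in, values_out))) == 1)
    return(list(statistic = 0, p_value = 1,
                n_in = length(values_in), n_out = length(values_out)))
  kt <- kruskal.test(list(values_in, values_out))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       n_in = length(values_in), n_out = length(values_out))
}

#' Bulk refractive index of particles from the backscattering ratio
#'
#' Evaluates the Twardowski et al. (2001) relation between the particulate
#' backscattering ratio b-tilde = b_bp/b_p and the bulk real refractive
#' index n of the suspended particle population,
#' \deqn{n(\tilde{b}, \gamma) = 1 + \tilde{b}^{0.5377 + 0.4867\gamma^2}
#'   (1.4676 + 2.2950\gamma^2 + 2.3113\gamma^4),}
#' where gamma is the hyperbolic (Junge) particle-size-distribution slope
#' parameter. In float applications b_bp/c_p serves as the proxy for the
#' backscattering ratio (c_p at 660 nm is nearly all particulate
#' scattering). High n (calcite ~ 1.2) flags mineral particles such as
#' coccoliths; phytoplankton cells sit near 1.05.
#'
#' @param backscattering_ratio b-tilde, dimensionless, in (0, 0.05].
#' @param gamma PSD slope parameter (default 0).
#' @return Bulk refractive index (dimensionless), increasing in b-tilde.
#' @examples
#' refractive_index(0.013)  # ~1.14, between algal cells and pure calcite
#' @export
refractive_index <- function(backscattering_ratio, gamma = 0) {
  bt <- backscattering_ratio
  if (any(!is.finite(bt)) || any(bt <= 0))
    stop("refractive_index(): backscattering ratio must be in (0, 0.05]")
  if (any(bt > 0.05))
    stop("refractive_index(): ratio ", max(bt),
         " outside the model's validity range (0, 0.05]")
  1 + bt^(0.5377 + 0.4867 * gamma^2) *
    (1.4676 + 2.2950 * gamma^2 + 2.3113 * gamma^4)
}
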