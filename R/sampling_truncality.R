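#' Driver detection statistics over all k-lesion biopsy subsets
#'
#' Enumerates every subset of \code{s} lesions and, for each subset, counts
#' the driver alterations detected (present in at least one sampled lesion)
#' and the non-truncal drivers that would be misclassified as truncal
#' (present in every sampled lesion despite being absent from some
#' unsampled lesion). Summaries quantify how adequate limited biopsy
#' sampling is for recovering a patient's driver landscape.
#'
#' @param presence logical driver x lesion matrix for one patient
#'   (TRUE = alteration present in that lesion).
#' @param s subset size, 1 <= s <= number of lesions.
#' @param enum_cap maximum number of subsets enumerated exactly; above
#'   this a seeded Monte-Carlo sample of \code{enum_cap} subsets is used
#'   with a warning (never needed for cohorts of <= 20 lesions).
#' @param seed seed for the Monte-Carlo fallback.
#' @return object of class \code{subset_summary}: \code{n_subsets},
#'   \code{mean_detected}, \code{sd_detected} (sample sd, n-1),
#'   \code{fraction_complete}, \code{mean_misclassified},
#'   \code{misclassified_dist} (table over subsets) and the per-subset
#'   \code{detected} counts.
#' @examples
#' pres <- rbind(matrix(TRUE, 3, 5),            # three truncal drivers
#'               c(TRUE, rep(FALSE, 4)))        # one private driver
#' subset_statistics(pres, s = 4)               # mean 3.8, sd 0.45
#' @export
subset_statistics <- function(presence, s, enum_cap = 1e6, seed = 1L) {
  presence <- as.matrix(presence)
  storage.mode(presence) <- "logical"
  N <- ncol(presence)
  n_drivers <- nrow(presence)
  if (s < 1) stop("subset size must be >= 1")
  if (s > N) stop("subset size ", s, " exceeds lesion count ", N)
  truncal <- rowSums(presence) == N
  n_subsets <- choose(N, s)
  if (n_subsets <= enum_cap) {
    subsets <- utils::combn(N, s)
    exact <- TRUE
  } else {
    warning("C(", N, ", ", s, ") exceeds the enumeration cap; ",
            "using seeded Monte-Carlo sampling")
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
    subsets <- replicate(enum_cap, sort(sample.int(N, s)))
    exact <- FALSE
  }
  detected <- integer(ncol(subsets))
  miscl <- integer(ncol(subsets))
  for (i in seq_len(ncol(subsets))) {
    sub <- presence[, subsets[, i], drop = FALSE]
    hits <- rowSums(sub)
    detected[i] <- sum(hits > 0)
    miscl[i] <- sum(!truncal & hits == s)
  }
  structure(list(s = s, n_lesions = N, n_drivers = n_drivers,
                 n_subsets = ncol(subsets), exact = exact,
                 mean_detected = mean(detected),
                 sd_detected = if (length(detected) > 1) stats::sd(detected) else 0,
                 fraction_complete = mean(detected == n_drivers),
                 mean_misclassified = mean(miscl),
                 misclassified_dist = table(miscl),
                 detected = detected),
            class = "subset_summary")
}

#' @export
print.subset_summary <- function(x, ...) {
  cat(sprintf(paste0("Subsets of %d of %d lesions (%d%s): mean detected ",
                     "%.2f/%d (sd %.2f), complete in %.1f%%, ",
                     "mean misclassified-as-truncal %.2f\n"),
              x$s, x$n_lesions, x$n_subsets,
              if (x$exact) "" else ", Monte-Carlo",
              x$mean_detected, x$n_drivers, x$sd_detected,
              100 * x$fraction_complete, x$mean_misclassified))
  invisible(x)
}

#' ROC-derived ctDNA CCF threshold for truncality classification
#'
#' Sweeps candidate thresholds (midpoints between sorted distinct CCFs plus
#' sentinels), classifying a mutation as truncal when its ctDNA CCF is at
#' or above the threshold. Reports sensitivity/specificity per threshold,
#' the trapezoidal AUC, and the operating point closest to the top-left
#' corner of the ROC curve (minimum Euclidean distance to false-positive
#' rate 0, sensitivity 1; ties broken toward the higher threshold).
#'
#' @param ccf per-mutation ctDNA CCF values in \[0, 1\].
#' @param truncal logical tissue-truth labels.
#' @return object of class \code{roc_result}: \code{thresholds},
#'   \code{sensitivity}, \code{specificity}, \code{auc},
#'   \code{optimal_threshold}, \code{sens_at_opt}, \code{spec_at_opt}.
#' @export
roc_truncal_threshold <- function(ccf, truncal) {
  keep <- !is.na(ccf) & !is.na(truncal)
  ccf <- ccf[keep]; truncal <- as.logical(truncal[keep])
  if (!any(truncal) || all(truncal))
    stop("need both truncal and non-truncal mutations")
  v <- sort(unique(ccf))
  thr <- c(v[1] - 1e-9,
           if (length(v) > 1) (v[-1] + v[-length(v)]) / 2,
           v[length(v)] + 1e-9)
  sens <- vapply(thr, function(t) mean(ccf[truncal] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(ccf[!truncal] < t), numeric(1))
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(ord)]) / 2)
  d2 <- (1 - sens)^2 + (1 - spec)^2
  best <- which(d2 <= min(d2) + 1e-12)
  opt <- best[which.max(thr[best])]
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, optimal_threshold = thr[opt],
                 sens_at_opt = sens[opt], spec_at_opt = spec[opt]),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC over %d thresholds: AUC %.3f; optimal threshold %.3f (sens %.2f, spec %.2f)\n",
              length(x$thresholds), x$auc, x$optimal_threshold,
              x$sens_at_opt, x$spec_at_opt))
  invisible(x)
}

#' Classify a mutation as truncal from its ctDNA CCF
#'
#' Truncal when the CCF is at or above the threshold (boundary inclusive).
#'
#' @param ccf ctDNA CCF value(s) in \[0, 1\].
#' @param threshold classification threshold, e.g. the
#'   \code{optimal_threshold} of a [roc_truncal_threshold()] result.
#' @return character vector: "truncal" or "non_truncal".
#' @export
classify_truncal_from_cfdna <- function(ccf, threshold) {
  stopifnot(all(ccf >= 0 & ccf <= 1, na.rm = TRUE))
  ifelse(ccf >= threshold, "truncal", "non_truncal")
}
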