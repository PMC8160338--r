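#' Power-model parameters for ctDNA mutation detection
#'
#' @param fpr per-locus false-positive probability tolerated when choosing
#'   the detection read threshold (default 5e-7).
#' @param per_base_error per-base sequencing error probability
#'   (default 1e-3).
#' @param min_reads read support required to rescue a tissue-defined
#'   mutation in plasma (default 3).
#' @param power_target detection power required when inverting the power
#'   curve (default 0.9).
#' @return list of class \code{power_model}.
#' @export
power_model <- function(fpr = 5e-7, per_base_error = 1e-3, min_reads = 3L,
                        power_target = 0.9) {
  stopifnot(fpr > 0, fpr < 1, per_base_error > 0, per_base_error < 1,
            power_target > 0, power_target < 1)
  structure(list(fpr = fpr, per_base_error = per_base_error,
                 min_reads = as.integer(min_reads),
                 power_target = power_target), class = "power_model")
}

#' Minimum read support distinguishing signal from sequencing error
#'
#' The smallest integer k such that the probability of k or more error
#' reads among d total --- Binomial(d, per_base_error) --- does not exceed
#' the tolerated false-positive rate.
#'
#' @param depth total read depth, > 0.
#' @param model a [power_model()].
#' @return integer read threshold k*.
#' @export
min_detectable_reads <- function(depth, model = power_model()) {
  stopifnot(depth > 0)
  for (k in 1:depth) {
    if (stats::pbinom(k - 1, depth, model$per_base_error,
                      lower.tail = FALSE) <= model$fpr)
      return(as.integer(k))
  }
  stop("depth ", depth, " too low to control the false-positive rate at ",
       model$fpr)
}

#' Power to detect a mutation at a given ctDNA CCF
#'
#' Probability that a mutation present at cancer cell fraction \code{ccf}
#' in the tumor-derived plasma compartment yields at least k* variant
#' reads at depth \code{depth}, where k* is the error-controlled threshold
#' from [min_detectable_reads()]. The expected plasma VAF treats the ctDNA
#' tumor fraction as purity in the standard VAF model.
#'
#' @param ccf ctDNA cancer cell fraction(s) in \[0, 1\].
#' @param tumor_fraction ctDNA fraction of the plasma sample.
#' @param depth plasma depth at the locus.
#' @param total_cn,multiplicity plasma copy state (default diploid).
#' @param model a [power_model()].
#' @return detection probabilities; an attribute \code{unreliable} flags
#'   CCFs whose expected VAF does not exceed the error rate.
#' @export
detection_power <- function(ccf, tumor_fraction, depth, total_cn = 2,
                            multiplicity = 1, model = power_model()) {
  kstar <- min_detectable_reads(depth, model)
  f <- expected_vaf(ccf, tumor_fraction, total_cn, multiplicity)
  pow <- stats::pbinom(kstar - 1L, depth, f, lower.tail = FALSE)
  unreliable <- f <= model$per_base_error
  if (any(unreliable))
    warning("expected VAF at or below the error rate for ",
            sum(unreliable), " CCF value(s); power there is unreliable")
  attr(pow, "unreliable") <- unreliable
  pow
}

#' Minimum ctDNA CCF detectable with the target power
#'
#' Inverts the monotone power curve by bisection: the smallest CCF at which
#' [detection_power()] reaches \code{model$power_target}.
#'
#' @inheritParams detection_power
#' @param tol bisection tolerance on the CCF scale.
#' @return minimum CCF, or NA (with a warning) when even CCF = 1 is
#'   underpowered.
#' @export
min_detectable_ccf <- function(tumor_fraction, depth, total_cn = 2,
                               multiplicity = 1, model = power_model(),
                               tol = 1e-4) {
  pw <- function(c) suppressWarnings(
    detection_power(c, tumor_fraction, depth, total_cn, multiplicity, model))
  if (pw(1) < model$power_target) {
    warning("power at CCF = 1 is below the target; no detectable CCF")
    return(NA_real_)
  }
  lo <- 0; hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (pw(mid) >= model$power_target) hi <- mid else lo <- mid
  }
  hi
}

#' Detect tissue-defined mutations in a plasma sample
#'
#' Tissue mutations are rescued in plasma when supported by at least
#' \code{min_rescue_reads} reads; loci without plasma coverage are marked
#' NA and excluded from detection denominators. Plasma-only variants are
#' retained separately when their VAF is at least \code{min_denovo_vaf}.
#' For detected sSNVs, the ctDNA CCF is estimated with the same grid
#' posterior used for tissue, with the plasma tumor fraction as purity.
#'
#' @param tissue_summary per-mutation tissue summary (see
#'   [summarize_tissue_mutations()]): \code{mut_id}, \code{class},
#'   \code{k} (harboring-lesion count), \code{max_ccf}.
#' @param plasma MutationRecord table of the plasma sample (\code{mut_id},
#'   \code{alt_reads}, \code{depth}).
#' @param tumor_fraction ctDNA tumor fraction of the plasma sample.
#' @param min_rescue_reads plasma read support for rescue (default 3).
#' @param min_denovo_vaf VAF filter for plasma-only variants
#'   (default 0.005).
#' @param total_cn,multiplicity plasma copy state for CCF estimation.
#' @return data.frame of detection records (\code{mut_id}, \code{class},
#'   \code{k}, \code{max_ccf}, \code{plasma_alt}, \code{plasma_depth},
#'   \code{detected}, \code{ctdna_ccf}); plasma-only variants passing the
#'   VAF filter are attached as attribute \code{plasma_only}.
#' @export
detect_in_cfdna <- function(tissue_summary, plasma, tumor_fraction,
                            min_rescue_reads = 3L, min_denovo_vaf = 0.005,
                            total_cn = 2, multiplicity = 1) {
  stopifnot(all(c("mut_id", "class", "k") %in% names(tissue_summary)))
  i <- match(tissue_summary$mut_id, plasma$mut_id)
  alt <- plasma$alt_reads[i]
  dep <- plasma$depth[i]
  covered <- !is.na(dep) & dep > 0
  detected <- ifelse(covered, alt >= min_rescue_reads, NA)
  ccf <- rep(NA_real_, length(alt))
  est <- which(covered & detected)
  if (length(est))
    ccf[est] <- ccf_table(alt[est], dep[est], tumor_fraction, total_cn,
                          multiplicity)$point
  out <- data.frame(mut_id = tissue_summary$mut_id,
                    class = tissue_summary$class,
                    k = tissue_summary$k,
                    max_ccf = if ("max_ccf" %in% names(tissue_summary))
                      tissue_summary$max_ccf else NA_real_,
                    plasma_alt = alt, plasma_depth = dep,
                    detected = detected, ctdna_ccf = ccf,
                    stringsAsFactors = FALSE)
  denovo <- plasma[!plasma$mut_id %in% tissue_summary$mut_id, , drop = FALSE]
  if (nrow(denovo)) {
    vaf <- denovo$alt_reads / pmax(denovo$depth, 1L)
    denovo <- denovo[denovo$depth > 0 & vaf >= min_denovo_vaf, , drop = FALSE]
  }
  attr(out, "plasma_only") <- denovo
  out
}

#' Per-mutation tissue summary feeding the plasma comparison
#'
#' Collapses a classified presence matrix to one row per mutation: its
#' class, the number of harboring lesions k, and the maximum CCF point
#' estimate across lesions where it is present (a conservative clonality
#' summary).
#'
#' @param pm classified \code{presence_matrix}.
#' @param sample_sheet sheet with per-lesion \code{purity}.
#' @param total_cn,multiplicity copy state for CCF estimation.
#' @return data.frame with \code{mut_id}, \code{class}, \code{k},
#'   \code{max_ccf}.
#' @export
summarize_tissue_mutations <- function(pm, sample_sheet, total_cn = 2,
                                       multiplicity = 1) {
  stopifnot(inherits(pm, "presence_matrix"))
  purity <- sample_sheet$purity[match(pm$lesions, sample_sheet$sample)]
  pres <- .present(pm)
  max_ccf <- vapply(seq_len(nrow(pres)), function(i) {
    j <- which(pres[i, ] & !is.na(pm$alt[i, ]) & !is.na(pm$depth[i, ]) &
                 pm$depth[i, ] > 0)
    if (!length(j)) return(NA_real_)
    max(ccf_table(pm$alt[i, j], pm$depth[i, j], purity[j], total_cn,
                  multiplicity)$point)
  }, numeric(1))
  data.frame(mut_id = pm$muts$mut_id, class = pm$class,
             k = rowSums(pres), max_ccf = max_ccf,
             stringsAsFactors = FALSE)
}

# Firth-penalized logistic regression (Jeffreys-prior score correction),
# used when maximum likelihood is degenerate under complete separation.
.firth_logistic <- function(X, y, max_iter = 200L, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  info <- NULL
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    info <- crossprod(X * sqrt(w))
    hat <- rowSums((X %*% solve(info)) * X) * w
    score <- crossprod(X, y - p + hat * (0.5 - p))
    delta <- solve(info, score)
    beta <- beta + drop(delta)
    if (max(abs(delta)) < tol) break
  }
  list(coef = beta, se = sqrt(diag(solve(info))))
}

#' Logistic model of plasma detection on lesion count and clonality
#'
#' Fits detected ~ k + max_ccf by maximum likelihood and reports odds
#' ratios with Wald 95\% intervals. Under complete separation the ML fit
#' diverges; a Firth-penalized fit is substituted with a warning.
#'
#' @param records detection records from [detect_in_cfdna()] (rows with
#'   missing detection status are dropped). If \code{max_ccf} is all NA the
#'   model reduces to detected ~ k.
#' @return list with \code{coef}, \code{se}, \code{or} (odds ratios),
#'   \code{ci} (2-column Wald interval matrix on the OR scale),
#'   \code{separation} flag and the fitted \code{model} (NULL for the
#'   penalized fallback).
#' @export
detection_model <- function(records) {
  d <- records[!is.na(records$detected), , drop = FALSE]
  if (!nrow(d) || length(unique(d$detected)) < 2)
    stop("need both detected and undetected mutations")
  use_ccf <- "max_ccf" %in% names(d) && any(!is.na(d$max_ccf))
  if (use_ccf) d <- d[!is.na(d$max_ccf), , drop = FALSE]
  if (length(unique(d$k)) < 2)
    stop("lesion count k is constant; coefficient undefined")
  form <- if (use_ccf) detected ~ k + max_ccf else detected ~ k
  fit <- suppressWarnings(stats::glm(form, family = stats::binomial(), data = d))
  pr <- stats::fitted(fit)
  separation <- !fit$converged || any(abs(stats::coef(fit)) > 15) ||
    all(pr > 1 - 1e-8 | pr < 1e-8)
  if (separation) {
    warning("complete or quasi-complete separation; ",
            "using Firth-penalized fit")
    X <- stats::model.matrix(form, d)
    ff <- .firth_logistic(X, as.numeric(d$detected))
    coef <- stats::setNames(ff$coef, colnames(X))
    se <- stats::setNames(ff$se, colnames(X))
    fit <- NULL
  } else {
    coef <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
  }
  ci <- cbind(lower = exp(coef - 1.96 * se), upper = exp(coef + 1.96 * se))
  list(coef = coef, se = se, or = exp(coef), ci = ci,
       separation = separation, model = fit)
}

#' Linear model of ctDNA CCF on harboring-lesion count
#'
#' Ordinary least squares of the plasma CCF of detected mutations on the
#' number of tissue lesions carrying them; under equal per-lesion shedding
#' the expected slope is 1/N for N lesions.
#'
#' @param records detection records; only rows with \code{detected == TRUE}
#'   and a CCF estimate are used.
#' @return list with \code{slope}, \code{ci} (95\%), \code{intercept} and
#'   the \code{model}.
#' @export
ccf_vs_lesions_model <- function(records) {
  d <- records[!is.na(records$detected) & records$detected &
                 !is.na(records$ctdna_ccf), , drop = FALSE]
  if (nrow(d) < 3) stop("need at least 3 detected mutations")
  if (length(unique(d$k)) < 2) stop("lesion count k is constant")
  fit <- stats::lm(ctdna_ccf ~ k, data = d)
  ci <- stats::confint(fit)["k", ]
  list(slope = unname(stats::coef(fit)["k"]), ci = unname(ci),
       intercept = unname(stats::coef(fit)[1]), model = fit)
}

#' Branch versus private plasma detection contrast
#'
#' Two-sided Fisher exact test of the 2x2 table of detection status against
#' mutation class (branch vs private).
#'
#' @param records detection records with \code{class} and \code{detected}.
#' @return list with the \code{table}, per-class detected \code{proportions}
#'   and \code{p_value}.
#' @export
branch_vs_private_test <- function(records) {
  d <- records[records$class %in% c("branch", "private") &
                 !is.na(records$detected), , drop = FALSE]
  if (length(unique(d$class)) < 2)
    stop("need both branch and private mutations")
  tab <- table(class = factor(d$class, c("branch", "private")),
               detected = factor(d$detected, c(TRUE, FALSE)))
  list(table = tab,
       proportions = c(branch = tab[1, 1] / sum(tab[1, ]),
                       private = tab[2, 1] / sum(tab[2, ])),
       p_value = stats::fisher.test(tab)$p.value)
}
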