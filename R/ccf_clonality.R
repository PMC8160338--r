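#' Expected variant allele fraction under the purity/copy-number model
#'
#' For a mutation carried by a fraction \code{ccf} of cancer cells on
#' \code{multiplicity} chromosomal copies, at a locus with tumor total copy
#' number \code{total_cn} in a sample of purity \code{purity}, the expected
#' fraction of variant reads is
#' \deqn{f = \frac{\alpha c m}{\alpha q_t + (1 - \alpha) q_n}}
#' where \eqn{\alpha} is purity, \eqn{c} the cancer cell fraction, \eqn{m}
#' the multiplicity, \eqn{q_t} the tumor and \eqn{q_n} the normal total copy
#' number. For plasma, \code{purity} is the ctDNA tumor fraction.
#'
#' @param ccf cancer cell fraction(s) in \[0, 1\].
#' @param purity sample purity (tumor fraction for cfDNA), in (0, 1\].
#' @param total_cn tumor total copy number at the locus (default diploid, 2).
#' @param multiplicity number of mutated copies, >= 1.
#' @param normal_cn copy number in contaminating normal cells (default 2).
#' @return expected VAF, same length as \code{ccf}.
#' @examples
#' expected_vaf(1, purity = 1)               # clonal het diploid: 0.5
#' expected_vaf(0.5, purity = 0.6)           # 0.15
#' expected_vaf(1, purity = 0.5, total_cn = 4, multiplicity = 2)  # 1/3
#' @export
expected_vaf <- function(ccf, purity, total_cn = 2, multiplicity = 1,
                         normal_cn = 2) {
  stopifnot(all(purity > 0), all(purity <= 1), all(ccf >= 0), all(ccf <= 1),
            all(total_cn >= 0), all(multiplicity >= 1))
  denom <- purity * total_cn + (1 - purity) * normal_cn
  if (any(denom <= 0))
    stop("no tumor DNA at locus: purity * total_cn + (1 - purity) * normal_cn is zero")
  purity * ccf * multiplicity / denom
}

#' CCF grid used for posterior estimation
#'
#' 100 equally spaced values from 0.01 to 1; 0 is excluded because a somatic
#' mutation present in zero cancer cells is not a somatic state.
#' @return numeric vector of length 100.
#' @export
ccf_grid <- function() seq(0.01, 1, length.out = 100L)

#' Posterior distribution of the cancer cell fraction at one locus
#'
#' Evaluates the binomial likelihood of the observed variant/reference read
#' counts over a grid of 100 CCF values, with a uniform prior, and returns the
#' normalized posterior, the maximum-posterior point estimate and a central
#' 95\% credible interval. Estimates at loci covered by fewer than 30 reads
#' are flagged as not reportable (\code{depth_ok = FALSE}); the posterior is
#' still computed so callers can inspect it.
#'
#' @param alt variant read count.
#' @param depth total read depth (alt + ref).
#' @param purity sample purity, or ctDNA tumor fraction for plasma.
#' @param total_cn,multiplicity,normal_cn locus copy state, see
#'   [expected_vaf()].
#' @param min_depth minimum depth for a reportable estimate (default 30).
#' @return an object of class \code{ccf_estimate}: list with \code{grid},
#'   \code{posterior}, \code{point}, \code{ci_low}, \code{ci_high},
#'   \code{clonal} (point >= 0.9) and \code{depth_ok}.
#' @export
ccf_posterior <- function(alt, depth, purity, total_cn = 2, multiplicity = 1,
                          normal_cn = 2, min_depth = 30L) {
  stopifnot(length(alt) == 1L, length(depth) == 1L, depth >= 0, alt >= 0)
  if (alt > depth) stop("alt reads exceed depth")
  grid <- ccf_grid()
  f <- expected_vaf(grid, purity, total_cn, multiplicity, normal_cn)
  ll <- stats::dbinom(alt, depth, f, log = TRUE)
  post <- exp(ll - max(ll))
  post <- post / sum(post)
  point <- grid[which.max(post)]
  cum <- cumsum(post)
  ci_low <- grid[which(cum >= 0.025)[1L]]
  ci_high <- grid[which(cum >= 0.975)[1L]]
  structure(list(grid = grid, posterior = post, point = point,
                 ci_low = ci_low, ci_high = ci_high,
                 clonal = point >= 0.9, depth_ok = depth >= min_depth),
            class = "ccf_estimate")
}

#' @export
print.ccf_estimate <- function(x, ...) {
  cat(sprintf("CCF estimate: %.2f [%.2f, %.2f] %s%s\n", x$point, x$ci_low,
              x$ci_high, if (x$clonal) "clonal" else "subclonal",
              if (x$depth_ok) "" else " (depth < 30, not reportable)"))
  invisible(x)
}

#' Vectorized CCF point estimates for many loci
#'
#' @param alt,depth integer vectors of variant and total read counts.
#' @param purity scalar or per-locus purity.
#' @param total_cn,multiplicity scalar or per-locus copy state.
#' @param min_depth minimum reportable depth.
#' @return data.frame with columns \code{point}, \code{ci_low},
#'   \code{ci_high}, \code{clonal}, \code{depth_ok}.
#' @export
ccf_table <- function(alt, depth, purity, total_cn = 2, multiplicity = 1,
                      min_depth = 30L) {
  n <- length(alt)
  purity <- rep_len(purity, n)
  total_cn <- rep_len(total_cn, n)
  multiplicity <- rep_len(multiplicity, n)
  out <- vapply(seq_len(n), function(i) {
    e <- ccf_posterior(alt[i], depth[i], purity[i], total_cn[i],
                       multiplicity[i], min_depth = min_depth)
    c(e$point, e$ci_low, e$ci_high, e$clonal, e$depth_ok)
  }, numeric(5))
  data.frame(point = out[1, ], ci_low = out[2, ], ci_high = out[3, ],
             clonal = as.logical(out[4, ]), depth_ok = as.logical(out[5, ]))
}

#' Clonal versus subclonal call from a CCF estimate
#'
#' Clonal means CCF point estimate >= 0.9 (boundary inclusive). Estimates at
#' under-covered loci are refused rather than silently classified.
#'
#' @param est a \code{ccf_estimate} from [ccf_posterior()].
#' @return "clonal" or "subclonal".
#' @export
classify_clonal <- function(est) {
  stopifnot(inherits(est, "ccf_estimate"))
  if (!est$depth_ok)
    stop("CCF not reportable at depth < 30; clonality not assigned")
  if (est$point >= 0.9) "clonal" else "subclonal"
}

#' Estimate mutation multiplicity by inverting the VAF model
#'
#' m = round(f (alpha q_t + (1 - alpha) q_n) / alpha), clipped to
#' \[1, major\]. Needed because multiplicity enters the CCF model but is not
#' observed directly.
#'
#' @param alt,depth read counts.
#' @param purity sample purity.
#' @param total_cn tumor total copy number.
#' @param major major allele copy number (upper bound on multiplicity).
#' @param normal_cn normal copy number.
#' @return integer multiplicity estimate.
#' @export
estimate_multiplicity <- function(alt, depth, purity, total_cn = 2,
                                  major = 1, normal_cn = 2) {
  stopifnot(depth > 0)
  f <- alt / depth
  m <- round(f * (purity * total_cn + (1 - purity) * normal_cn) / purity)
  pmin(pmax(m, 1L), pmax(major, 1L))
}

#' Timing of a mutation relative to a copy-number gain
#'
#' In regions with major copy number >= 2, a mutation present on more than
#' one copy must have preceded the gain (it was duplicated along with its
#' chromosome); multiplicity 1 leaves the order unresolved. Regions without
#' a gain carry no timing information.
#'
#' @param multiplicity mutated copies, >= 1.
#' @param major major allele copy number at the locus.
#' @return one of "before_scna", "after_or_unknown", "not_applicable".
#' @export
multiplicity_timing <- function(multiplicity, major) {
  stopifnot(multiplicity >= 1)
  if (multiplicity > major)
    stop("multiplicity exceeds major copy number")
  if (major < 2) return("not_applicable")
  if (multiplicity > 1) "before_scna" else "after_or_unknown"
}

#' Whole-genome duplication call from allele-specific segments
#'
#' WGD is called when strictly more than half of the genome has an even
#' major copy number.
#'
#' @param segments data.frame with columns \code{chrom}, \code{start},
#'   \code{end} (1-based inclusive), \code{major}, \code{minor}; segments of
#'   one sample, non-overlapping.
#' @param genome_size total genome length in bases.
#' @return logical WGD flag.
#' @export
call_wgd <- function(segments, genome_size) {
  stopifnot(genome_size > 0)
  .check_segments(segments)
  len <- segments$end - segments$start + 1
  even <- segments$major %% 2 == 0 & segments$major > 0
  sum(len[even]) > 0.5 * genome_size
}

# shared segment validation: required columns, coordinates, overlap
.check_segments <- function(segments) {
  need <- c("chrom", "start", "end", "major", "minor")
  miss <- setdiff(need, names(segments))
  if (length(miss))
    stop("segments missing column(s): ", paste(miss, collapse = ", "))
  if (any(segments$start > segments$end))
    stop("segment with start > end")
  if (any(segments$major < 0 | segments$minor < 0))
    stop("negative copy numbers")
  if (any(segments$major < segments$minor))
    stop("major copy number below minor")
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)]))
      stop("overlapping segments on ", ch)
  }
  invisible(TRUE)
}
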