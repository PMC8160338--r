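#' Build a presence matrix by rescuing mutations across lesions
#'
#' A mutation called with high confidence in any lesion of a patient is
#' scored as present ("rescued") in every other lesion where it is supported
#' by at least \code{min_reads} reads with base quality >= \code{min_bq} and
#' mapping quality >= \code{min_mq}. This avoids overestimating heterogeneity
#' caused by borderline caller sensitivity. Original calls are never
#' downgraded. Lesions with no pileup information at a called locus are
#' flagged "unpowered" (missing data).
#'
#' @param calls MutationRecord table of high-confidence calls: columns
#'   \code{patient, sample, chrom, pos, ref, alt, alt_reads, depth,
#'   base_quality, map_quality} (plus optional \code{gene, coding}).
#' @param pileup MutationRecord table giving read support at every called
#'   locus in every lesion (same columns).
#' @param min_reads minimum supporting reads for rescue (default 3).
#' @param min_bq minimum base quality (phred, default 30).
#' @param min_mq minimum mapping quality (phred, default 60).
#' @return object of class \code{presence_matrix}: mutation x lesion
#'   \code{status} matrix with values called/rescued/absent/unpowered,
#'   matching \code{alt} and \code{depth} matrices, mutation metadata in
#'   \code{muts}, and placeholders for the powered flag and class labels.
#' @export
rescue_mutations <- function(calls, pileup, min_reads = 3L, min_bq = 30,
                             min_mq = 60) {
  for (df in list(calls, pileup)) {
    need <- c("patient", "sample", "chrom", "pos", "ref", "alt",
              "alt_reads", "depth")
    miss <- setdiff(need, names(df))
    if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  }
  patient <- unique(c(calls$patient, pileup$patient))
  if (length(patient) != 1L)
    stop("rescue operates on one patient at a time; got: ",
         paste(patient, collapse = ", "))
  mid <- function(df) sprintf("%s:%d:%s:%s", df$chrom, df$pos, df$ref, df$alt)
  calls$mut_id <- mid(calls)
  pileup$mut_id <- mid(pileup)
  muts <- unique(calls[, intersect(c("mut_id", "chrom", "pos", "ref", "alt",
                                     "gene", "coding"), names(calls))])
  muts <- muts[order(muts$chrom, muts$pos), , drop = FALSE]
  lesions <- sort(unique(c(calls$sample, pileup$sample)))
  m <- nrow(muts); n <- length(lesions)
  dn <- list(muts$mut_id, lesions)
  status <- matrix("unpowered", m, n, dimnames = dn)
  alt <- matrix(NA_real_, m, n, dimnames = dn)
  depth <- matrix(NA_real_, m, n, dimnames = dn)

  pu <- pileup[pileup$mut_id %in% muts$mut_id, , drop = FALSE]
  if (nrow(pu)) {
    i <- match(pu$mut_id, muts$mut_id)
    j <- match(pu$sample, lesions)
    alt[cbind(i, j)] <- pu$alt_reads
    depth[cbind(i, j)] <- pu$depth
    bq <- if ("base_quality" %in% names(pu)) pu$base_quality else Inf
    mq <- if ("map_quality" %in% names(pu)) pu$map_quality else Inf
    ok <- pu$alt_reads >= min_reads & bq >= min_bq & mq >= min_mq
    status[cbind(i, j)] <- ifelse(ok, "rescued", "absent")
  }
  ci <- match(calls$mut_id, muts$mut_id)
  cj <- match(calls$sample, lesions)
  status[cbind(ci, cj)] <- "called"
  # calls carry their own read support where the pileup lacks the locus
  fill <- is.na(alt[cbind(ci, cj)])
  if (any(fill)) {
    fidx <- cbind(ci, cj)[fill, , drop = FALSE]
    alt[fidx] <- calls$alt_reads[fill]
    depth[fidx] <- calls$depth[fill]
  }

  structure(list(patient = patient, status = status, alt = alt,
                 depth = depth, muts = muts, lesions = lesions,
                 powered = rep(NA, m), class = rep(NA_character_, m)),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("Presence matrix for %s: %d mutations x %d lesions\n",
              x$patient, nrow(x$status), ncol(x$status)))
  if (!all(is.na(x$powered)))
    cat(sprintf("  powered: %d/%d\n", sum(x$powered), length(x$powered)))
  if (!all(is.na(x$class))) {
    tb <- table(x$class)
    cat("  classes:", paste(sprintf("%s %d", names(tb), tb),
                            collapse = ", "), "\n")
  }
  invisible(x)
}

# logical presence (called or rescued) for downstream set operations
.present <- function(pm) pm$status == "called" | pm$status == "rescued"

#' Flag mutations powered for detection in every lesion
#'
#' A locus is retained for heterogeneity analyses only when, in every lesion
#' of the patient, the probability of observing at least \code{min_reads}
#' variant reads for a clonal heterozygous mutation --- Binomial(depth,
#' expected VAF at CCF 1) --- reaches \code{power_target}. The expected VAF
#' uses the lesion's purity and the default diploid copy state, so low-purity
#' or shallow lesions do not masquerade as mutation-free.
#'
#' @param pm a \code{presence_matrix}.
#' @param sample_sheet data.frame with \code{sample} and \code{purity}
#'   columns covering all lesions of the patient.
#' @param power_target required detection probability (default 0.90).
#' @param min_reads detection support threshold (default 3, matching rescue).
#' @return the presence matrix with the per-mutation \code{powered} flag set
#'   (and a \code{powered_cell} matrix recording per-lesion power).
#' @export
power_filter <- function(pm, sample_sheet, power_target = 0.9,
                         min_reads = 3L) {
  stopifnot(inherits(pm, "presence_matrix"))
  idx <- match(pm$lesions, sample_sheet$sample)
  if (anyNA(idx))
    stop("sample sheet missing lesion(s): ",
         paste(pm$lesions[is.na(idx)], collapse = ", "))
  purity <- sample_sheet$purity[idx]
  vaf <- expected_vaf(1, purity)  # clonal het diploid, multiplicity 1
  cell_ok <- matrix(FALSE, nrow(pm$status), ncol(pm$status),
                    dimnames = dimnames(pm$status))
  for (j in seq_along(pm$lesions)) {
    d <- pm$depth[, j]
    ok <- !is.na(d) & d > 0 &
      stats::pbinom(min_reads - 1L, pmax(d, 1L), vaf[j],
                    lower.tail = FALSE) >= power_target
    cell_ok[, j] <- ok
  }
  cell_ok[pm$status == "unpowered"] <- FALSE
  pm$powered_cell <- cell_ok
  pm$powered <- rowSums(cell_ok) == ncol(cell_ok)
  pm
}

#' Classify mutations as truncal, branch or private
#'
#' Among powered mutations: present (called or rescued) in all lesions =
#' truncal; in exactly one = private; in two or more but not all = branch.
#' Unpowered mutations, and all mutations of a single-lesion patient (where
#' truncal and private are indistinguishable), are "unclassifiable".
#'
#' @param pm a \code{presence_matrix} after [power_filter()] (if the powered
#'   flag is unset, all mutations are treated as powered, which is only
#'   appropriate for saturating-depth data).
#' @return the presence matrix with per-mutation \code{class} labels.
#' @export
classify_mutations <- function(pm) {
  stopifnot(inherits(pm, "presence_matrix"))
  powered <- if (all(is.na(pm$powered))) rep(TRUE, nrow(pm$status)) else pm$powered
  n_lesions <- ncol(pm$status)
  npres <- rowSums(.present(pm))
  cls <- rep("unclassifiable", nrow(pm$status))
  if (n_lesions >= 2L) {
    cls[powered & npres == n_lesions] <- "truncal"
    cls[powered & npres == 1L] <- "private"
    cls[powered & npres >= 2L & npres < n_lesions] <- "branch"
  } else {
    warning("single-lesion patient ", pm$patient,
            ": truncal vs private indistinguishable")
  }
  pm$class <- cls
  pm
}

#' Pairwise Jaccard similarity between lesions
#'
#' For each pair of lesions, the number of powered mutations present in both
#' divided by the number present in either. Rescued mutations count as
#' present. An empty union gives NA.
#'
#' @param pm a classified \code{presence_matrix} (>= 2 lesions).
#' @param powered_only restrict to powered mutations (default TRUE).
#' @return list with the symmetric similarity \code{matrix} and the
#'   per-patient \code{median} of the off-diagonal values.
#' @export
jaccard_similarity <- function(pm, powered_only = TRUE) {
  stopifnot(inherits(pm, "presence_matrix"))
  if (ncol(pm$status) < 2L) stop("need at least two lesions")
  pres <- .present(pm)
  if (powered_only && !all(is.na(pm$powered)))
    pres <- pres[pm$powered, , drop = FALSE]
  n <- ncol(pres)
  jm <- diag(1, n)
  dimnames(jm) <- list(colnames(pres), colnames(pres))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    un <- sum(pres[, i] | pres[, j])
    jm[i, j] <- jm[j, i] <- if (un == 0) NA_real_ else
      sum(pres[, i] & pres[, j]) / un
  }
  list(matrix = jm, median = stats::median(jm[lower.tri(jm)], na.rm = TRUE))
}

#' Tumor mutation burden per megabase
#'
#' Counts coding mutations covered by at least \code{min_depth} reads with
#' VAF above \code{min_vaf}, per megabase of adequately covered coding
#' territory.
#'
#' @param records MutationRecord table for one sample with \code{coding},
#'   \code{alt_reads}, \code{depth} columns.
#' @param powered_coding_bases coding bases covered by >= \code{min_depth}
#'   reads (the denominator).
#' @param min_depth coverage filter (default 30).
#' @param min_vaf VAF filter; mutations with VAF > \code{min_vaf} count
#'   (default 0.01).
#' @return mutations per Mb.
#' @export
tmb <- function(records, powered_coding_bases, min_depth = 30L,
                min_vaf = 0.01) {
  if (powered_coding_bases <= 0) stop("powered_coding_bases must be positive")
  coding <- if ("coding" %in% names(records)) records$coding else TRUE
  keep <- coding & records$depth >= min_depth &
    records$alt_reads / pmax(records$depth, 1L) > min_vaf
  sum(keep) / (powered_coding_bases / 1e6)
}

#' Median absolute deviation (unscaled)
#'
#' Raw descriptive dispersion: median of absolute deviations from the
#' median, with no consistency factor.
#'
#' @param values numeric vector, length >= 1.
#' @return the MAD.
#' @export
dispersion_mad <- function(values) {
  if (!length(values)) stop("empty input")
  stats::mad(values, constant = 1)
}

#' Median Jaccard similarity after downsampling lesions
#'
#' Repeatedly samples \code{n_lesions} lesions without replacement and
#' recomputes the median pairwise Jaccard similarity, to compare patients
#' profiled with different numbers of tissue samples on an equal footing.
#'
#' @param pm a \code{presence_matrix}.
#' @param n_lesions lesions per replicate (>= 2).
#' @param n_reps number of replicates.
#' @param seed integer seed.
#' @return numeric vector of replicate median similarities.
#' @export
downsample_jaccard <- function(pm, n_lesions, n_reps = 100L, seed = 1L) {
  stopifnot(inherits(pm, "presence_matrix"))
  N <- ncol(pm$status)
  if (n_lesions < 2L) stop("n_lesions must be >= 2")
  if (n_lesions > N) stop("n_lesions exceeds patient lesion count")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  vapply(seq_len(n_reps), function(r) {
    keep <- sort(sample.int(N, n_lesions))
    sub <- pm
    sub$status <- pm$status[, keep, drop = FALSE]
    sub$alt <- pm$alt[, keep, drop = FALSE]
    sub$depth <- pm$depth[, keep, drop = FALSE]
    sub$lesions <- pm$lesions[keep]
    jaccard_similarity(sub)$median
  }, numeric(1))
}
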