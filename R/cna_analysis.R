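#' Classify copy-number segments relative to sample ploidy
#'
#' Event classes follow ploidy-relative thresholds: high-level amplification
#' when total copies >= 3x ploidy, gain when >= 2x ploidy, partial deletion
#' when below half the ploidy (but > 0), homozygous deletion at 0 copies.
#' Loss of heterozygosity (minor allele count 0 with remaining copies,
#' including copy-neutral LOH) is reported as a separate flag, since it can
#' co-occur with any total copy number.
#'
#' @param segments data.frame with \code{major} and \code{minor} integer
#'   copy columns (one row per segment; extra columns are carried through).
#' @param ploidy estimated sample ploidy, > 0.
#' @return the input with added \code{total}, \code{class}
#'   (high_amp/gain/partial_del/homozygous_del/neutral) and \code{loh}
#'   columns.
#' @export
classify_cna <- function(segments, ploidy) {
  stopifnot(ploidy > 0)
  if (any(segments$major < 0 | segments$minor < 0))
    stop("negative copy numbers")
  total <- segments$major + segments$minor
  class <- rep("neutral", length(total))
  class[total > 0 & total < ploidy / 2] <- "partial_del"
  class[total >= 2 * ploidy] <- "gain"
  class[total >= 3 * ploidy] <- "high_amp"
  class[total == 0] <- "homozygous_del"
  segments$total <- total
  segments$class <- class
  segments$loh <- segments$minor == 0 & total > 0
  segments
}

# event label used for base-level profile comparison: the ploidy-relative
# class, with copy-neutral/other LOH surfacing when no dosage class applies
.cna_label <- function(classified) {
  ifelse(classified$class != "neutral", classified$class,
         ifelse(classified$loh, "loh", "neutral"))
}

#' Copy-number instability: fraction of the genome altered
#'
#' A base is altered when its total copy number deviates from the rounded
#' sample ploidy or it lies in an LOH segment. Bases not covered by any
#' segment are treated as unaltered.
#'
#' @param segments non-overlapping segments of one sample (\code{chrom},
#'   \code{start}, \code{end}, \code{major}, \code{minor}).
#' @param ploidy sample ploidy.
#' @param genome_size genome length in bases, > 0.
#' @return altered fraction in \[0, 1\].
#' @export
cin <- function(segments, ploidy, genome_size) {
  if (genome_size <= 0) stop("genome_size must be positive")
  .check_segments(segments)
  cl <- classify_cna(segments, ploidy)
  altered <- cl$total != round(ploidy) | cl$loh
  min(sum((cl$end - cl$start + 1)[altered]) / genome_size, 1)
}

#' Base-level Jaccard similarity of copy-number profiles
#'
#' Compares two lesions' altered territory at single-base resolution:
#' intersection = bases altered in both samples with the same event label,
#' union = bases altered in either. Base-level comparison is robust to
#' breakpoint jitter between independently segmented samples.
#'
#' @param seg_a,seg_b segment tables of the two samples.
#' @param ploidy_a,ploidy_b their ploidies.
#' @return similarity in \[0, 1\], or NA when neither sample is altered.
#' @export
scna_jaccard <- function(seg_a, seg_b, ploidy_a = 2, ploidy_b = 2) {
  .check_segments(seg_a); .check_segments(seg_b)
  a <- classify_cna(seg_a, ploidy_a); a$label <- .cna_label(a)
  b <- classify_cna(seg_b, ploidy_b); b$label <- .cna_label(b)
  inter <- 0; un <- 0
  for (ch in union(a$chrom, b$chrom)) {
    sa <- a[a$chrom == ch, , drop = FALSE]
    sb <- b[b$chrom == ch, , drop = FALSE]
    bp <- sort(unique(c(sa$start, sa$end + 1, sb$start, sb$end + 1)))
    if (length(bp) < 2) next
    starts <- bp[-length(bp)]
    lens <- diff(bp)
    lab <- function(s, pos) {
      hit <- which(s$start <= pos & s$end >= pos)
      if (length(hit)) s$label[hit[1]] else "neutral"
    }
    for (i in seq_along(starts)) {
      la <- lab(sa, starts[i]); lb <- lab(sb, starts[i])
      alt_a <- la != "neutral"; alt_b <- lb != "neutral"
      if (alt_a || alt_b) un <- un + lens[i]
      if (alt_a && alt_b && la == lb) inter <- inter + lens[i]
    }
  }
  if (un == 0) NA_real_ else inter / un
}

#' Detect mutation-loss events (mutant allele lost via LOH)
#'
#' A non-truncal mutation is a loss event when (i) at least one lesion
#' carries the mutation without LOH at the locus, (ii) at least one lesion
#' lacks the mutation and shows LOH, and (iii) no lesion lacks both the
#' mutation and LOH. Condition (iii) removes loci where absence could
#' reflect an independent subclone rather than allele loss; condition (i)
#' guards against counting loss of the wild-type allele.
#'
#' @param pm a classified \code{presence_matrix}.
#' @param loh logical mutation x lesion matrix (same shape as
#'   \code{pm$status}): LOH at the mutation's locus in that lesion.
#' @return data.frame per non-truncal mutation: \code{mut_id},
#'   \code{class}, \code{evaluable} (condition iii) and \code{loss_event}.
#' @export
detect_mutation_loss <- function(pm, loh) {
  stopifnot(inherits(pm, "presence_matrix"),
            identical(dim(loh), dim(pm$status)))
  pres <- .present(pm)
  idx <- which(pm$class %in% c("branch", "private"))
  out <- lapply(idx, function(i) {
    p <- pres[i, ]; l <- loh[i, ]
    evaluable <- !any(!p & !l)
    loss <- evaluable && any(p & !l) && any(!p & l)
    data.frame(mut_id = pm$muts$mut_id[i], class = pm$class[i],
               evaluable = evaluable, loss_event = loss,
               stringsAsFactors = FALSE)
  })
  if (!length(out))
    return(data.frame(mut_id = character(), class = character(),
                      evaluable = logical(), loss_event = logical()))
  do.call(rbind, out)
}
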