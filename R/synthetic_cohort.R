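#' Configuration for the synthetic multi-lesion cohort generator
#'
#' Builds a validated configuration for [simulate_cohort()]. Defaults emulate
#' a rapid-autopsy style cohort: 4--17 metastatic lesions per patient, tissue
#' exome depth around 117x, a deep (~1200x) targeted plasma panel, and
#' mutations partitioned into truncal (all lesions), branch (a strict subset
#' of >= 2 lesions, placed on a random clone tree) and private (one lesion)
#' classes.
#'
#' @param n_patients number of patients.
#' @param lesions_per_patient a single count, or a length-2 range from which
#'   per-patient lesion counts are drawn uniformly; must be >= 2.
#' @param n_truncal,n_branch,n_private expected per-patient mutation counts
#'   per class (Poisson-distributed across patients).
#' @param n_drivers number of driver mutations per patient.
#' @param driver_classes character vector recycled to \code{n_drivers};
#'   each is "truncal", "branch" or "private".
#' @param purity_shape shape parameters of the Beta distribution of lesion
#'   purity; draws are clamped to \[0.05, 1\].
#' @param tissue_depth_mean mean per-locus tissue sequencing depth (reads).
#' @param cfdna_depth_mean mean per-locus plasma sequencing depth (reads).
#' @param ctdna_tumor_fraction tumor-derived fraction of plasma cfDNA,
#'   in (0, 1].
#' @param shed_weights "equal", or a function(n) returning n non-negative
#'   per-lesion shedding weights (normalized to sum to 1).
#' @param per_base_error per-base sequencing error probability.
#' @param panel_fraction probability that a non-driver mutation falls on the
#'   targeted plasma panel (drivers are always on panel).
#' @param branch_k_dist "tree" places branch mutations on internal edges of
#'   a random bifurcating clone tree (nested lesion sets); "uniform" draws
#'   the harboring-lesion count of every non-truncal mutation uniformly on
#'   1..(N-1), splitting the branch/private labels by the realized count.
#' @param subclonal_fraction probability that a mutation is subclonal
#'   (CCF drawn uniformly on \[0.2, 0.9\]) within each harboring lesion;
#'   default 0 (clonal, CCF 1).
#' @param seed integer seed; identical config + seed gives identical output.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(n_patients = 9L,
                       lesions_per_patient = c(4L, 17L),
                       n_truncal = 50L, n_branch = 30L, n_private = 40L,
                       n_drivers = 4L,
                       driver_classes = c("truncal", "truncal", "truncal",
                                          "private"),
                       purity_shape = c(8, 3),
                       tissue_depth_mean = 117,
                       cfdna_depth_mean = 1200,
                       ctdna_tumor_fraction = 0.3,
                       shed_weights = "equal",
                       per_base_error = 1e-3,
                       panel_fraction = 0.3,
                       branch_k_dist = c("tree", "uniform"),
                       subclonal_fraction = 0,
                       seed = 1L) {
  branch_k_dist <- match.arg(branch_k_dist)
  stopifnot(n_patients >= 1, length(lesions_per_patient) %in% 1:2,
            all(lesions_per_patient >= 2),
            n_truncal >= 0, n_branch >= 0, n_private >= 0, n_drivers >= 0,
            per_base_error >= 0, per_base_error < 1,
            panel_fraction >= 0, panel_fraction <= 1,
            subclonal_fraction >= 0, subclonal_fraction <= 1,
            tissue_depth_mean > 0, cfdna_depth_mean > 0)
  if (ctdna_tumor_fraction <= 0 || ctdna_tumor_fraction > 1)
    stop("ctdna_tumor_fraction must be in (0, 1]")
  if (!identical(shed_weights, "equal") && !is.function(shed_weights))
    stop("shed_weights must be \"equal\" or a function(n)")
  structure(list(n_patients = as.integer(n_patients),
                 lesions_per_patient = as.integer(lesions_per_patient),
                 n_truncal = n_truncal, n_branch = n_branch,
                 n_private = n_private,
                 n_drivers = as.integer(n_drivers),
                 driver_classes = driver_classes,
                 purity_shape = purity_shape,
                 tissue_depth_mean = tissue_depth_mean,
                 cfdna_depth_mean = cfdna_depth_mean,
                 ctdna_tumor_fraction = ctdna_tumor_fraction,
                 shed_weights = shed_weights,
                 per_base_error = per_base_error,
                 panel_fraction = panel_fraction,
                 branch_k_dist = branch_k_dist,
                 subclonal_fraction = subclonal_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# internal lesion sets of a random bifurcating clone tree over lesions
# 1..n: recursively bipartition; every internal node below the root whose
# set has 2 <= size <= n-1 is a candidate branch-mutation placement.
.clone_tree_sets <- function(n) {
  sets <- list()
  split_set <- function(idx) {
    if (length(idx) < 2) return(invisible())
    cut <- sample(seq_len(length(idx) - 1L), 1L)
    shuffled <- sample(idx)
    left <- sort(shuffled[seq_len(cut)])
    right <- sort(shuffled[-seq_len(cut)])
    for (part in list(left, right)) {
      if (length(part) >= 2) sets[[length(sets) + 1L]] <<- part
      split_set(part)
    }
  }
  split_set(seq_len(n))
  sets
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.driver_gene_pool <- c("PIK3CA", "AKT1", "ESR1", "FGFR2", "ARID1B", "SPEN",
                       "NSD1", "MYC", "TP53", "GATA3", "IDH1", "BAP1")

#' Simulate a multi-patient, multi-lesion cohort with known clonal truth
#'
#' Generates, for each patient, a set of lesions with purities and shedding
#' weights, mutations assigned to truncal/branch/private classes on a clone
#' tree, per-lesion read counts drawn binomially at the expected VAF implied
#' by purity and copy number (Poisson depth around the configured mean), and
#' a plasma cfDNA sample whose variant fractions follow the shedding-weighted
#' mixture of lesions. Loci not harboring a mutation accumulate error reads
#' at the configured per-base rate. A mutation is marked \code{called}
#' (high-confidence) in a lesion when supported by >= 5 reads at VAF >= 0.05.
#'
#' The expected plasma VAF of a mutation is
#' \code{tumor_fraction * sum(w_i * ccf_i) * m / (tf*q_t + (1-tf)*2)} over
#' harboring lesions i, so with equal shedding, diploid loci and clonal
#' mutations the expected ctDNA CCF of a mutation carried by k of N lesions
#' is exactly k/N.
#'
#' @param config a [sim_config()].
#' @return object of class \code{sim_cohort}: list with \code{truth}
#'   (per-mutation class, harboring lesions, driver/panel flags, true ctDNA
#'   CCF), \code{tissue} (long MutationRecord table: one row per mutation x
#'   lesion with \code{alt_reads}, \code{depth}, qualities, \code{called},
#'   \code{true_ccf}), \code{cfdna} (per-mutation plasma read counts),
#'   \code{segments} (diploid SEG table per lesion), \code{sample_sheet}
#'   and \code{config}.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(config$seed)

  truth <- list(); tissue <- list(); cfdna <- list()
  sheet <- list(); segs <- list()
  mut_counter <- 0L

  for (p in seq_len(config$n_patients)) {
    pid <- sprintf("P%02d", p)
    N <- if (length(config$lesions_per_patient) == 2L)
      sample(config$lesions_per_patient[1]:config$lesions_per_patient[2], 1L)
    else config$lesions_per_patient
    lesions <- sprintf("%s-L%02d", pid, seq_len(N))
    purity <- pmin(pmax(stats::rbeta(N, config$purity_shape[1],
                                     config$purity_shape[2]), 0.05), 1)
    w <- if (identical(config$shed_weights, "equal")) rep(1 / N, N)
    else {
      ww <- config$shed_weights(N)
      if (any(ww < 0) || sum(ww) <= 0) stop("invalid shedding weights")
      ww / sum(ww)
    }

    # mutation classes and harboring-lesion sets
    n_tr <- stats::rpois(1, config$n_truncal)
    if (config$branch_k_dist == "tree") {
      n_br <- stats::rpois(1, config$n_branch)
      n_pr <- stats::rpois(1, config$n_private)
      tree_sets <- .clone_tree_sets(N)
      if (!length(tree_sets)) n_br <- 0L
      sets <- c(replicate(n_tr, seq_len(N), simplify = FALSE),
                if (n_br > 0) tree_sets[sample.int(length(tree_sets), n_br,
                                                   replace = TRUE)],
                replicate(n_pr, sample.int(N, 1L), simplify = FALSE))
    } else {
      n_nt <- stats::rpois(1, config$n_branch + config$n_private)
      ks <- sample.int(N - 1L, n_nt, replace = TRUE)
      sets <- c(replicate(n_tr, seq_len(N), simplify = FALSE),
                lapply(ks, function(k) sort(sample.int(N, k))))
    }
    class <- vapply(sets, function(s)
      if (length(s) == N) "truncal" else if (length(s) == 1L) "private"
      else "branch", character(1))

    # drivers: replace/append mutations with driver genes of requested class
    n_mut <- length(sets)
    driver <- rep(FALSE, n_mut)
    if (config$n_drivers > 0) {
      want <- rep_len(config$driver_classes, config$n_drivers)
      for (cl in want) {
        idx <- which(class == cl & !driver)
        if (length(idx)) driver[idx[1]] <- TRUE
        else { # no mutation of that class drawn: append one
          s <- switch(cl, truncal = seq_len(N),
                      private = sample.int(N, 1L),
                      branch = {
                        k <- if (N > 2) sample(2:(N - 1), 1L) else NA
                        if (is.na(k)) sample.int(N, 1L) else sort(sample.int(N, k))
                      })
          sets[[length(sets) + 1L]] <- s
          class <- c(class, if (length(s) == N) "truncal"
                     else if (length(s) == 1L) "private" else "branch")
          driver <- c(driver, TRUE)
        }
      }
      n_mut <- length(sets)
    }

    genes <- sprintf("GENE%05d", mut_counter + seq_len(n_mut))
    dg <- which(driver)
    if (length(dg))
      genes[dg] <- rep_len(.driver_gene_pool, length(dg))
    on_panel <- driver | stats::runif(n_mut) < config$panel_fraction
    chrom <- sprintf("chr%d", sample.int(22L, n_mut, replace = TRUE))
    pos <- mut_counter + seq_len(n_mut) * 1000L
    ref <- sample(c("A", "C", "G", "T"), n_mut, replace = TRUE)
    alt <- vapply(ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1))
    mut_id <- sprintf("%s:%d:%s:%s", chrom, pos, ref, alt)

    # per-lesion true CCF (clonal unless subclonal_fraction drawn)
    ccf_mat <- matrix(0, n_mut, N, dimnames = list(mut_id, lesions))
    for (i in seq_len(n_mut)) {
      cc <- ifelse(stats::runif(length(sets[[i]])) < config$subclonal_fraction,
                   stats::runif(length(sets[[i]]), 0.2, 0.9), 1)
      ccf_mat[i, sets[[i]]] <- cc
    }

    # tissue read counts, one row per mutation x lesion
    for (j in seq_len(N)) {
      d <- stats::rpois(n_mut, config$tissue_depth_mean)
      f <- expected_vaf(ccf_mat[, j], purity[j])
      p_read <- ifelse(ccf_mat[, j] > 0, f, config$per_base_error)
      a <- stats::rbinom(n_mut, d, p_read)
      tissue[[length(tissue) + 1L]] <- data.frame(
        patient = pid, sample = lesions[j], chrom = chrom, pos = pos,
        ref = ref, alt = alt, gene = genes, coding = TRUE,
        mut_id = mut_id, alt_reads = a, depth = d,
        base_quality = 35, map_quality = 60,
        called = a >= 5L & d > 0 & a / pmax(d, 1L) >= 0.05,
        true_ccf = ccf_mat[, j], stringsAsFactors = FALSE)
    }

    # plasma: shedding-weighted mixture over harboring lesions
    ctdna_ccf <- as.numeric(ccf_mat %*% w)
    tf <- config$ctdna_tumor_fraction
    f_plasma <- expected_vaf(ctdna_ccf, tf)
    d_pl <- stats::rpois(n_mut, config$cfdna_depth_mean)
    a_pl <- stats::rbinom(n_mut, d_pl,
                          pmax(f_plasma, config$per_base_error))
    cfdna[[length(cfdna) + 1L]] <- data.frame(
      patient = pid, sample = paste0(pid, "-cfDNA"), chrom = chrom,
      pos = pos, ref = ref, alt = alt, gene = genes, coding = TRUE,
      mut_id = mut_id, alt_reads = a_pl, depth = d_pl,
      base_quality = 35, map_quality = 60, on_panel = on_panel,
      stringsAsFactors = FALSE)[on_panel, , drop = FALSE]

    truth[[length(truth) + 1L]] <- data.frame(
      patient = pid, mut_id = mut_id, chrom = chrom, pos = pos, ref = ref,
      alt = alt, gene = genes, class = class,
      k = vapply(sets, length, integer(1)), n_lesions = N,
      lesions = vapply(sets, function(s)
        paste(lesions[s], collapse = ";"), character(1)),
      multiplicity = 1L, driver = driver, on_panel = on_panel,
      ctdna_ccf_true = ctdna_ccf, tumor_fraction = tf,
      stringsAsFactors = FALSE)

    sheet[[length(sheet) + 1L]] <- data.frame(
      sample = lesions, patient = pid, lesion = seq_len(N),
      site = "synthetic", purity = purity, ploidy = 2,
      mean_depth = config$tissue_depth_mean, shed_weight = w,
      stringsAsFactors = FALSE)

    # diploid background segments: 22 chromosomes of 130 Mb each
    segs[[length(segs) + 1L]] <- do.call(rbind, lapply(lesions, function(l)
      data.frame(sample = l, chrom = sprintf("chr%d", 1:22), start = 1L,
                 end = 130000000L, major = 1L, minor = 1L,
                 stringsAsFactors = FALSE)))
    mut_counter <- mut_counter + n_mut
  }

  structure(list(truth = do.call(rbind, truth),
                 tissue = do.call(rbind, tissue),
                 cfdna = do.call(rbind, cfdna),
                 segments = do.call(rbind, segs),
                 sample_sheet = do.call(rbind, sheet),
                 config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients, %d lesions, %d mutations (%s)\n",
              length(unique(x$truth$patient)), nrow(x$sample_sheet),
              nrow(x$truth),
              paste(sprintf("%s %d", names(table(x$truth$class)),
                            table(x$truth$class)), collapse = ", ")))
  invisible(x)
}
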