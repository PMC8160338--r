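#' Read somatic variant records from VCF or TSV
#'
#' Both dialects yield the same MutationRecord layout: 1-based positions,
#' variant (\code{alt_reads}) and total (\code{depth}) read counts taken
#' from the AD and DP FORMAT fields for VCF. Malformed rows fail with the
#' offending line identified.
#'
#' @param path file path.
#' @param dialect "tsv" (tab-separated with the package's column names) or
#'   "vcf" (VCF 4.2 with AD/DP in FORMAT).
#' @return MutationRecord data.frame with at least \code{sample},
#'   \code{chrom}, \code{pos}, \code{ref}, \code{alt}, \code{alt_reads},
#'   \code{depth}, \code{mut_id}.
#' @export
read_variants <- function(path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("sample", "chrom", "pos", "ref", "alt", "alt_reads", "depth")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
    bad <- which(!is.finite(df$pos) | df$pos < 1 | df$alt_reads > df$depth |
                   df$alt_reads < 0)
    if (length(bad))
      stop(path, ": malformed record at data line ", bad[1],
           " (pos < 1 or alt_reads outside [0, depth])")
  } else {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                         dimnames = list(NULL, names(fix)))
    gt <- v@gt
    if (is.null(gt) || ncol(gt) < 2)
      stop(path, ": VCF has no sample genotype columns")
    fmt <- strsplit(gt[, 1], ":")
    sample_id <- colnames(gt)[2]
    get_field <- function(row, field) {
      idx <- match(field, fmt[[row]])
      if (is.na(idx))
        stop(path, ": record ", row, " (", fix[row, "CHROM"], ":",
             fix[row, "POS"], ") lacks FORMAT field ", field)
      strsplit(gt[row, 2], ":")[[1]][idx]
    }
    n <- nrow(fix)
    ad <- vapply(seq_len(n), get_field, character(1), field = "AD")
    dp <- vapply(seq_len(n), get_field, character(1), field = "DP")
    alt_reads <- vapply(strsplit(ad, ","), function(x)
      as.numeric(x[2]), numeric(1))
    gene <- vcfR::extract.info(v, "GENE")
    df <- data.frame(sample = sample_id,
                     chrom = fix[, "CHROM"],
                     pos = as.integer(fix[, "POS"]),
                     ref = fix[, "REF"], alt = fix[, "ALT"],
                     gene = if (is.null(gene)) NA_character_ else gene,
                     alt_reads = alt_reads, depth = as.numeric(dp),
                     stringsAsFactors = FALSE)
    if (anyNA(df$alt_reads) || anyNA(df$depth))
      stop(path, ": AD/DP could not be parsed for record ",
           which(is.na(df$alt_reads) | is.na(df$depth))[1])
  }
  df$pos <- as.integer(df$pos)
  df$mut_id <- sprintf("%s:%d:%s:%s", df$chrom, df$pos, df$ref, df$alt)
  df
}

#' Write variant records as minimal VCF 4.2
#'
#' One sample per file; AD (ref,alt) and DP are written in FORMAT, the gene
#' symbol and coding flag in INFO.
#'
#' @param records MutationRecord data.frame for one sample.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_variants_vcf <- function(records, path) {
  stopifnot(length(unique(records$sample)) == 1L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
               "##INFO=<ID=CODING,Number=0,Type=Flag,Description=\"Coding variant\">",
               "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", records$sample[1], sep = "\t")), con)
  gene <- if ("gene" %in% names(records)) records$gene else "."
  coding <- if ("coding" %in% names(records)) records$coding else FALSE
  info <- paste0("GENE=", gene, ifelse(coding, ";CODING", ""))
  writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s\tAD:DP\t%d,%d:%d",
                     records$chrom, records$pos, records$ref, records$alt,
                     info, records$depth - records$alt_reads,
                     records$alt_reads, records$depth), con)
  invisible(path)
}

#' Read allele-specific copy-number segments (SEG-like TSV)
#'
#' @param path TSV with columns sample, chrom, start, end, major, minor
#'   (1-based inclusive coordinates).
#' @return validated segments data.frame.
#' @export
read_segments <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "start", "end", "major", "minor")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
  for (s in unique(df$sample))
    .check_segments(df[df$sample == s, , drop = FALSE])
  df
}

#' Read the sample sheet
#'
#' @param path TSV with columns sample, patient, lesion, purity, ploidy,
#'   mean_depth (site optional).
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "patient", "purity", "ploidy")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$purity <= 0 | df$purity > 1))
    stop(path, ": purity outside (0, 1]")
  df
}

#' Write a simulated cohort to disk
#'
#' Emits per-lesion VCFs, flat TSV variant tables (tissue and plasma),
#' SEG-like segment TSV, the sample sheet, and the truth table as TSV and
#' JSON.
#'
#' @param cohort a \code{sim_cohort} from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) utils::write.table(
    df, file.path(dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(cohort$tissue, "tissue_variants.tsv")
  wt(cohort$cfdna, "cfdna_variants.tsv")
  wt(cohort$segments, "segments.tsv")
  wt(cohort$sample_sheet, "sample_sheet.tsv")
  wt(cohort$truth, "truth.tsv")
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  vdir <- file.path(dir, "vcf")
  dir.create(vdir, showWarnings = FALSE)
  for (s in unique(cohort$tissue$sample))
    write_variants_vcf(cohort$tissue[cohort$tissue$sample == s, ,
                                     drop = FALSE],
                       file.path(vdir, paste0(s, ".vcf")))
  invisible(dir)
}

#' End-to-end run configuration
#'
#' Collects every tunable threshold of the pipeline with its default:
#' rescue support 3 reads at BQ >= 30 / MQ >= 60, 90\% detection power,
#' clonal CCF cutoff 0.9, reportable depth 30, TMB filters (depth 30,
#' VAF > 0.01), plasma de novo VAF filter 0.005, and the detection power
#' model (FPR 5e-7, per-base error 1e-3).
#'
#' @param sim a [sim_config()] describing the cohort to simulate (the
#'   bundled demonstration input), or NULL when variants are supplied via
#'   \code{cohort}.
#' @param cohort an existing \code{sim_cohort}; overrides \code{sim}.
#' @param outdir output directory; NULL for no file output.
#' @param min_reads,min_bq,min_mq rescue thresholds.
#' @param power_target locus power filter target.
#' @param clonal_cutoff CCF at or above which a mutation is clonal.
#' @param min_depth minimum reportable depth for CCF and TMB.
#' @param tmb_min_vaf TMB VAF filter.
#' @param min_denovo_vaf plasma-only variant VAF filter.
#' @param fpr,per_base_error detection power model parameters.
#' @param subset_sizes biopsy subset sizes to enumerate.
#' @param seed integer seed.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(sim = sim_config(), cohort = NULL, outdir = NULL,
                       min_reads = 3L, min_bq = 30, min_mq = 60,
                       power_target = 0.9, clonal_cutoff = 0.9,
                       min_depth = 30L, tmb_min_vaf = 0.01,
                       min_denovo_vaf = 0.005, fpr = 5e-7,
                       per_base_error = 1e-3, subset_sizes = 1:5,
                       seed = 1L) {
  structure(list(sim = sim, cohort = cohort, outdir = outdir,
                 min_reads = min_reads, min_bq = min_bq, min_mq = min_mq,
                 power_target = power_target, clonal_cutoff = clonal_cutoff,
                 min_depth = min_depth, tmb_min_vaf = tmb_min_vaf,
                 min_denovo_vaf = min_denovo_vaf, fpr = fpr,
                 per_base_error = per_base_error,
                 subset_sizes = subset_sizes, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full multi-lesion / cfDNA analysis pipeline
#'
#' Simulates (or accepts) a cohort, then per patient: builds the rescued
#' presence matrix, applies the power filter, classifies mutations,
#' computes pairwise Jaccard similarities and the tissue summary, detects
#' tissue mutations in plasma, and enumerates driver-recovery statistics
#' over biopsy subsets. Pooled across patients it fits the detection and
#' CCF-vs-lesion-count models, the branch-vs-private contrast, and the
#' ROC truncality threshold. A manifest (seed, config hash, stage counts)
#' makes reruns verifiable: identical config + seed give an identical
#' manifest hash.
#'
#' @param config a [run_config()].
#' @return list of class \code{pipeline_result} with per-patient matrices,
#'   detection records, model fits, subset summaries, ROC, and the
#'   manifest.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  stage <- "simulate"
  result <- tryCatch({
    cohort <- config$cohort
    if (is.null(cohort)) {
      sim <- config$sim
      sim$seed <- config$seed
      cohort <- simulate_cohort(sim)
    }
    patients <- unique(cohort$sample_sheet$patient)
    model <- power_model(fpr = config$fpr,
                         per_base_error = config$per_base_error,
                         min_reads = config$min_reads,
                         power_target = config$power_target)

    stage <- "classify"
    pms <- list(); tissue_summaries <- list(); jaccards <- list()
    for (p in patients) {
      tp <- cohort$tissue[cohort$tissue$patient == p, , drop = FALSE]
      pm <- rescue_mutations(tp[tp$called, , drop = FALSE], tp,
                             min_reads = config$min_reads,
                             min_bq = config$min_bq, min_mq = config$min_mq)
      pm <- power_filter(pm, cohort$sample_sheet,
                         power_target = config$power_target,
                         min_reads = config$min_reads)
      pm <- classify_mutations(pm)
      pms[[p]] <- pm
      jaccards[[p]] <- jaccard_similarity(pm)
      stage <- "ccf"
      tissue_summaries[[p]] <- summarize_tissue_mutations(
        pm, cohort$sample_sheet)
    }

    stage <- "cfdna"
    detections <- list()
    for (p in patients) {
      pl <- cohort$cfdna[cohort$cfdna$patient == p, , drop = FALSE]
      if (!nrow(pl)) next
      tf <- cohort$truth$tumor_fraction[cohort$truth$patient == p][1]
      ts <- tissue_summaries[[p]]
      ts <- ts[ts$class != "unclassifiable" & ts$mut_id %in% pl$mut_id, ,
               drop = FALSE]
      if (!nrow(ts)) next
      det <- detect_in_cfdna(ts, pl, tf, min_rescue_reads = config$min_reads,
                             min_denovo_vaf = config$min_denovo_vaf)
      det$patient <- p
      detections[[p]] <- det
    }
    det_all <- do.call(rbind, detections)

    stage <- "models"
    models <- list()
    if (!is.null(det_all)) {
      models$detection <- tryCatch(detection_model(det_all),
                                   error = function(e) NULL)
      models$ccf_slope <- tryCatch(ccf_vs_lesions_model(det_all),
                                   error = function(e) NULL)
      models$branch_vs_private <- tryCatch(branch_vs_private_test(det_all),
                                           error = function(e) NULL)
    }

    stage <- "sample-subsets"
    subset_summaries <- list()
    for (p in patients) {
      tr <- cohort$truth[cohort$truth$patient == p & cohort$truth$driver, ,
                         drop = FALSE]
      if (!nrow(tr)) next
      lesions <- cohort$sample_sheet$sample[cohort$sample_sheet$patient == p]
      pres <- t(vapply(seq_len(nrow(tr)), function(i)
        lesions %in% strsplit(tr$lesions[i], ";")[[1]],
        logical(length(lesions))))
      rownames(pres) <- tr$gene
      for (s in config$subset_sizes) {
        if (s > length(lesions))
          stop("subset size ", s, " exceeds lesion count for ", p)
        ss <- subset_statistics(pres, s)
        subset_summaries[[length(subset_summaries) + 1L]] <- data.frame(
          patient = p, s = s, n_subsets = ss$n_subsets,
          mean_detected = ss$mean_detected, sd_detected = ss$sd_detected,
          fraction_complete = ss$fraction_complete,
          mean_misclassified = ss$mean_misclassified)
      }
    }
    subset_tab <- do.call(rbind, subset_summaries)

    stage <- "roc"
    roc <- NULL
    if (!is.null(det_all)) {
      ok <- !is.na(det_all$ctdna_ccf)
      if (any(ok) && length(unique(det_all$class[ok] == "truncal")) == 2)
        roc <- roc_truncal_threshold(det_all$ctdna_ccf[ok],
                                     det_all$class[ok] == "truncal")
    }

    stage <- "manifest"
    cfg_for_hash <- config
    cfg_for_hash$cohort <- NULL
    cfg_for_hash$outdir <- NULL  # output location does not change results
    if (!is.null(cfg_for_hash$sim) && is.function(cfg_for_hash$sim$shed_weights))
      cfg_for_hash$sim$shed_weights <- paste(
        deparse(cfg_for_hash$sim$shed_weights), collapse = "")
    cfg_json <- jsonlite::toJSON(
      list(config = cfg_for_hash[!vapply(cfg_for_hash, is.function, logical(1))],
           seed = config$seed),
      auto_unbox = TRUE, digits = NA, force = TRUE)
    tf <- tempfile(); writeLines(as.character(cfg_json), tf)
    manifest <- list(
      package_version = as.character(utils::packageVersion("clonoshed")),
      seed = config$seed,
      config_hash = unname(tools::md5sum(tf)),
      n_patients = length(patients),
      n_mutations = nrow(cohort$truth),
      n_detection_records = if (is.null(det_all)) 0L else nrow(det_all))
    unlink(tf)

    out <- list(cohort = cohort, presence = pms, jaccard = jaccards,
                tissue_summaries = tissue_summaries, detections = det_all,
                models = models, subset_summaries = subset_tab, roc = roc,
                manifest = manifest, config = config)
    class(out) <- "pipeline_result"

    if (!is.null(config$outdir)) {
      dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
      wt <- function(df, name) if (!is.null(df)) utils::write.table(
        df, file.path(config$outdir, name), sep = "\t", quote = FALSE,
        row.names = FALSE)
      wt(det_all, "detections.tsv")
      wt(subset_tab, "subset_summaries.tsv")
      for (p in patients) {
        pm <- pms[[p]]
        wt(data.frame(mut_id = pm$muts$mut_id, class = pm$class,
                      powered = pm$powered, pm$status,
                      check.names = FALSE),
           paste0("presence_", p, ".tsv"))
      }
      if (!is.null(roc))
        wt(data.frame(threshold = roc$thresholds,
                      sensitivity = roc$sensitivity,
                      specificity = roc$specificity), "roc.tsv")
      jsonlite::write_json(manifest,
                           file.path(config$outdir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    out
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline result: %d patients, %d mutations, %s detection records\n",
              x$manifest$n_patients, x$manifest$n_mutations,
              x$manifest$n_detection_records))
  if (!is.null(x$models$ccf_slope))
    cat(sprintf("  ctDNA CCF ~ lesions slope: %.3f [%.3f, %.3f]\n",
                x$models$ccf_slope$slope, x$models$ccf_slope$ci[1],
                x$models$ccf_slope$ci[2]))
  if (!is.null(x$roc))
    cat(sprintf("  truncality threshold: %.2f (sens %.2f, spec %.2f, AUC %.2f)\n",
                x$roc$optimal_threshold, x$roc$sens_at_opt,
                x$roc$spec_at_opt, x$roc$auc))
  invisible(x)
}
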