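#' Illustrative driver rules for the bundled cancer types
#'
#' A small stand-in for a curated driver catalogue: per cancer type, genes
#' annotated as oncogene or tumor suppressor with known recurrent
#' amino-acid positions for oncogenes. Real analyses should supply their own
#' rules table via [read_driver_rules()] or a data.frame of the same shape.
#'
#' @return data.frame with columns \code{gene}, \code{cancer_type},
#'   \code{role} ("oncogene"/"tsg") and \code{recurrent_sites}
#'   (comma-separated amino-acid positions, may be empty).
#' @export
default_driver_rules <- function() {
  read.table(text = "
gene|cancer_type|role|recurrent_sites
PIK3CA|breast|oncogene|542,545,546,1047
AKT1|breast|oncogene|17
ESR1|breast|oncogene|536,537,538
MYC|breast|oncogene|
ARID1B|breast|tsg|
SPEN|breast|tsg|
GATA3|breast|tsg|
TP53|breast|tsg|
FGFR2|biliary|oncogene|252,549
IDH1|biliary|oncogene|132
BAP1|biliary|tsg|
NSD1|biliary|tsg|
TP53|biliary|tsg|
EGFR|lung|oncogene|790,858
KRAS|lung|oncogene|12,13,61
STK11|lung|tsg|
TP53|lung|tsg|
", header = TRUE, sep = "|", stringsAsFactors = FALSE,
             na.strings = NULL, colClasses = "character")
}

#' Illustrative tier-1 census gene set with cancer-type mapping
#' @return data.frame with \code{gene} and \code{cancer_type}.
#' @export
default_census_tier1 <- function() {
  data.frame(gene = c("TP53", "PTEN", "CDH1", "SMAD4", "ARID1A", "KEAP1"),
             cancer_type = c("breast", "breast", "breast", "biliary",
                             "biliary", "lung"),
             stringsAsFactors = FALSE)
}

#' Read a driver-rules table from TSV
#'
#' @param path TSV with columns gene, cancer_type, role, recurrent_sites.
#' @return validated rules data.frame.
#' @export
read_driver_rules <- function(path) {
  rules <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
  need <- c("gene", "cancer_type", "role", "recurrent_sites")
  miss <- setdiff(need, names(rules))
  if (length(miss)) stop("rules missing column(s): ",
                         paste(miss, collapse = ", "))
  dup <- duplicated(rules[, c("gene", "cancer_type")])
  if (any(dup)) stop("conflicting roles for gene(s): ",
                     paste(unique(rules$gene[dup]), collapse = ", "))
  rules
}

.inactivating <- c("nonsense", "frameshift", "splice")

#' Annotate functional (driver) mutations
#'
#' A mutation is functional when its gene is on the targeted panel AND
#' either (a) it is inactivating (nonsense/frameshift/splice) in a listed
#' tumor suppressor for the cancer type, (b) it hits a listed recurrent
#' amino-acid position of a listed oncogene, or (c) its gene is in the
#' tier-1 census set for the matching cancer type. Genes on the blacklist
#' (e.g. high-homology loci prone to misalignment artifacts) are excluded
#' outright.
#'
#' @param mutations data.frame with \code{gene}, \code{consequence}
#'   (missense/nonsense/frameshift/splice/synonymous), and
#'   \code{protein_pos} (amino-acid position, NA allowed); extra columns
#'   carried through.
#' @param rules driver rules table (see [default_driver_rules()]).
#' @param cancer_type one of the types present in \code{rules}.
#' @param panel_genes genes on the targeted panel; defaults to all genes in
#'   \code{rules} plus the census set.
#' @param census tier-1 census table (see [default_census_tier1()]).
#' @param blacklist genes excluded as likely artifacts.
#' @return the input with a logical \code{functional} column.
#' @export
annotate_functional_mutations <- function(mutations, rules = default_driver_rules(),
                                          cancer_type,
                                          panel_genes = NULL,
                                          census = default_census_tier1(),
                                          blacklist = "KMT2C") {
  types <- unique(c(rules$cancer_type, census$cancer_type))
  if (!cancer_type %in% types)
    stop("unknown cancer type '", cancer_type, "'; available: ",
         paste(sort(types), collapse = ", "))
  r <- rules[rules$cancer_type == cancer_type, , drop = FALSE]
  cs <- census$gene[census$cancer_type == cancer_type]
  if (is.null(panel_genes)) panel_genes <- unique(c(rules$gene, census$gene))
  tsg <- r$gene[r$role == "tsg"]
  onc <- r$gene[r$role == "oncogene"]
  sites <- lapply(strsplit(r$recurrent_sites, ","), function(x)
    suppressWarnings(as.integer(x[nzchar(x)])))
  names(sites) <- r$gene

  pos <- if ("protein_pos" %in% names(mutations)) mutations$protein_pos
  else rep(NA_integer_, nrow(mutations))
  inact <- mutations$consequence %in% .inactivating
  hit_site <- mapply(function(g, p)
    !is.na(p) && g %in% onc && p %in% (sites[[g]] %||% integer(0)),
    mutations$gene, pos)
  functional <- mutations$gene %in% panel_genes &
    !(mutations$gene %in% blacklist) &
    ((inact & mutations$gene %in% tsg) |
       hit_site |
       (mutations$gene %in% cs &
          mutations$consequence != "synonymous"))
  mutations$functional <- as.logical(functional)
  mutations
}

#' Annotate driver copy-number events, with low-level gain rescue
#'
#' High-level amplifications of oncogenes and homozygous deletions of tumor
#' suppressors are drivers. A low-level gain in an oncogene is promoted to a
#' driver in a lesion when at least one other lesion of the same patient
#' carries a high-level amplification of that gene --- the copy-number
#' analogue of the mutation rescue step.
#'
#' @param events data.frame with \code{patient}, \code{sample}, \code{gene},
#'   \code{class} (from [classify_cna()]).
#' @param rules driver rules table.
#' @param cancer_type cancer type used for role lookup.
#' @return the input with a logical \code{driver} column.
#' @export
annotate_driver_cna <- function(events, rules = default_driver_rules(),
                                cancer_type) {
  r <- rules[rules$cancer_type == cancer_type, , drop = FALSE]
  if (!nrow(r)) stop("unknown cancer type '", cancer_type, "'; available: ",
                     paste(sort(unique(rules$cancer_type)), collapse = ", "))
  role <- stats::setNames(r$role, r$gene)
  ev_role <- role[events$gene]
  driver <- (events$class == "high_amp" & ev_role %in% "oncogene") |
    (events$class == "homozygous_del" & ev_role %in% "tsg")
  # gain rescue: oncogene gain counts when the patient has a high-level amp
  amped <- unique(events[driver & events$class == "high_amp",
                         c("patient", "gene")])
  if (nrow(amped)) {
    key <- paste(events$patient, events$gene)
    driver <- driver | (events$class == "gain" & ev_role %in% "oncogene" &
                          key %in% paste(amped$patient, amped$gene))
  }
  events$driver <- as.logical(driver)
  events
}

#' Association between driver status and clonality
#'
#' Cross-tabulates driver vs non-driver mutations against clonal vs
#' subclonal calls, and reports the sample odds ratio with a two-sided
#' Fisher exact p-value.
#'
#' @param is_driver,is_clonal logical vectors of equal length.
#' @return list with the 2x2 \code{table}, \code{odds_ratio} (sample OR;
#'   Inf/NA in degenerate strata), \code{p_value}, and the per-group clonal
#'   \code{proportions}.
#' @export
driver_clonality_association <- function(is_driver, is_clonal) {
  stopifnot(length(is_driver) == length(is_clonal))
  tab <- table(driver = factor(is_driver, c(TRUE, FALSE)),
               clonal = factor(is_clonal, c(TRUE, FALSE)))
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  or <- if (b == 0 || c_ == 0) {
    if (a == 0 || d == 0) NA_real_ else Inf
  } else (a * d) / (b * c_)
  props <- c(driver = if (a + b > 0) a / (a + b) else NA_real_,
             nondriver = if (c_ + d > 0) c_ / (c_ + d) else NA_real_)
  p <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) NA_real_
  else stats::fisher.test(tab)$p.value
  list(table = tab, odds_ratio = or, p_value = p, proportions = props)
}
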