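#' Classifier configuration
#'
#' Thresholds shared by the zygotic-gene identification and arrest-response
#' grouping steps.
#'
#' @param fold_change_threshold linear fold-change cut (> 1); a gene must
#'   exceed it strictly. Default 1.5.
#' @param alpha significance level for the per-gene two-sample test
#'   (strict `p < alpha`, no multiple-testing correction). Default 0.05.
#' @param increase_margin margin in log2 units for "increased"/"decreased"
#'   calls on condition means (strict inequalities at margin 0). Default 0.
#' @param baseline condition key used as reference, default `"control:C12"`.
#' @param decrease_rule `"both"` (default) requires the 30- and 50-minute
#'   arrest means to sit below baseline for an "initial decrease";
#'   `"either"` requires only one.
#' @return an object of class `classifier_config`.
#' @export
classifier_config <- function(fold_change_threshold = 1.5, alpha = 0.05,
                              increase_margin = 0,
                              baseline = "control:C12",
                              decrease_rule = c("both", "either")) {
  if (fold_change_threshold <= 1) stop("fold_change_threshold must be > 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (increase_margin < 0) stop("increase_margin must be >= 0")
  structure(list(fold_change_threshold = fold_change_threshold,
                 alpha = alpha,
                 increase_margin = increase_margin,
                 baseline = baseline,
                 decrease_rule = match.arg(decrease_rule)),
            class = "classifier_config")
}

#' Identify zygotic genes by late-versus-early up-regulation
#'
#' A gene is called zygotic when its mean expression in the late condition
#' exceeds the early condition by more than the fold-change threshold
#' (linear scale, computed from the difference of mean log2 CPM+1) and a
#' Welch two-sample t-test on the replicate log2 CPM+1 values gives
#' p strictly below alpha. Both inequalities are strict, so a fold change
#' exactly at the threshold is excluded.
#'
#' @param x a log2cpm-stage [expr_matrix()].
#' @param late,early condition keys (each needs >= 2 replicate samples).
#' @param cfg a [classifier_config()].
#' @return data.frame with one row per gene: `gene_id`, `mean_early`,
#'   `mean_late`, `log2_fc`, `fold_change`, `p_value`, `zygotic` (logical).
#' @export
identify_zygotic <- function(x, late = "control:C14L",
                             early = "control:C12",
                             cfg = classifier_config()) {
  .check_stage(x, "log2cpm")
  key <- .condition_key(x$meta)
  for (lab in c(late, early)) {
    n <- sum(key == lab)
    if (n == 0L) stop("condition '", lab, "' not present")
    if (n < 2L) stop("condition '", lab, "' has fewer than 2 replicates")
  }
  vl <- x$values[, key == late, drop = FALSE]
  ve <- x$values[, key == early, drop = FALSE]
  ml <- rowMeans(vl)
  me <- rowMeans(ve)
  pv <- vapply(seq_len(nrow(x$values)), function(i) {
    tryCatch(stats::t.test(vl[i, ], ve[i, ])$p.value,
             error = function(e) NA_real_)  # constant rows: untestable
  }, numeric(1))
  lfc <- ml - me
  fc <- 2^lfc
  data.frame(gene_id = rownames(x$values),
             mean_early = me, mean_late = ml,
             log2_fc = lfc, fold_change = fc, p_value = pv,
             zygotic = fc > cfg$fold_change_threshold &
               !is.na(pv) & pv < cfg$alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Intersect a gene set with a prior list
#'
#' Exact set intersection, keeping the order of `own` (order-stable).
#'
#' @param own,prior character vectors of gene ids.
#' @return character vector of shared gene ids.
#' @export
intersect_with_prior <- function(own, prior) {
  own <- unique(as.character(own))
  own[own %in% unique(as.character(prior))]
}

#' Categorize zygotic genes by their response to cell-cycle arrest
#'
#' Classifies each analyzed gene from its condition means (log2 CPM+1,
#' replicates averaged) relative to the baseline:
#' \describe{
#'   \item{group 1}{no initial decrease and the 70-minute arrest mean
#'     exceeds baseline — transcript abundance simply rises under arrest.}
#'   \item{group 2}{an initial decrease (30- and 50-minute means below
#'     baseline; maternal degradation dominating) followed by
#'     re-accumulation: the 70-minute mean exceeds the lower of the 30- and
#'     50-minute means — zygotic transcription resumes on top of decay.}
#'   \item{group 3}{the remainder — no net increase under arrest.}
#' }
#' The three labels partition the analyzed set. The 15-minute arrest point
#' is carried in the output for profile plots but takes no part in the rule.
#'
#' @param x a log2cpm-stage [expr_matrix()].
#' @param analyzed character vector of gene ids to classify.
#' @param arrest_minutes ordered arrest time points; the rule uses the
#'   2nd, 3rd and 4th (30/50/70 by default).
#' @param cfg a [classifier_config()].
#' @return an object of class `zga_groups`: list with `genes` (per-gene
#'   data.frame incl. condition means, `initial_decrease`, `group`) and
#'   `counts` (named integer vector over groups 1-3).
#' @export
categorize_groups <- function(x, analyzed,
                              arrest_minutes = c(15, 30, 50, 70),
                              cfg = classifier_config()) {
  .check_stage(x, "log2cpm")
  if (length(analyzed) == 0L) stop("no genes to categorize")
  key <- .condition_key(x$meta)
  arrest_keys <- paste0("arrested:", arrest_minutes)
  need <- c(cfg$baseline, arrest_keys)
  miss <- setdiff(need, unique(key))
  if (length(miss)) stop("missing condition(s): ", paste(miss, collapse = ", "))
  cm <- .condition_means(x, analyzed)
  b <- cm[, cfg$baseline]
  m30 <- cm[, arrest_keys[2L]]
  m50 <- cm[, arrest_keys[3L]]
  m70 <- cm[, arrest_keys[4L]]
  eps <- cfg$increase_margin
  dec <- if (cfg$decrease_rule == "both") {
    m30 < b - eps & m50 < b - eps
  } else {
    m30 < b - eps | m50 < b - eps
  }
  grp <- integer(length(analyzed))
  grp[!dec & m70 > b + eps] <- 1L
  grp[dec & m70 > pmin(m30, m50) + eps] <- 2L
  grp[grp == 0L] <- 3L
  genes <- data.frame(gene_id = analyzed, baseline = b,
                      m15 = cm[, arrest_keys[1L]], m30 = m30, m50 = m50,
                      m70 = m70, initial_decrease = dec,
                      group = grp, row.names = NULL,
                      stringsAsFactors = FALSE)
  counts <- c(group1 = sum(grp == 1L), group2 = sum(grp == 2L),
              group3 = sum(grp == 3L))
  structure(list(genes = genes, counts = counts, config = cfg),
            class = "zga_groups")
}

#' @export
print.zga_groups <- function(x, ...) {
  n <- nrow(x$genes)
  cat("Arrest-response categorization of", n, "zygotic genes\n")
  for (g in 1:3) {
    cat(sprintf("  group %d: %5d (%.1f%%)\n", g, x$counts[g],
                100 * x$counts[g] / n))
  }
  invisible(x)
}

#' @export
summary.zga_groups <- function(object, ...) {
  cat("Groups:", paste(names(object$counts), object$counts,
                       sep = " = ", collapse = ", "), "\n")
  cat("Initial-decrease genes:", sum(object$genes$initial_decrease),
      "(= group2 + group3 when the 70-min rule splits them)\n")
  invisible(object$counts)
}

#' Select maternally cleared genes
#'
#' From a prior list of purely maternal genes, keeps those whose control
#' expression falls over developmental time: late-control mean below
#' early-control mean by more than the margin.
#'
#' @param prior_maternal character vector of gene ids.
#' @param x a log2cpm-stage [expr_matrix()].
#' @param early,late control condition keys.
#' @param margin log2 margin (default 0, strict decrease).
#' @return character vector of gene ids (order of `prior_maternal`).
#' @export
select_maternal <- function(prior_maternal, x, early = "control:C12",
                            late = "control:C14L", margin = 0) {
  .check_stage(x, "log2cpm")
  keep <- intersect_with_prior(prior_maternal, rownames(x$values))
  if (length(keep) == 0L) return(character(0))
  cm <- .condition_means(x, keep)
  if (!all(c(early, late) %in% colnames(cm))) {
    stop("control conditions '", early, "'/'", late, "' not present")
  }
  keep[cm[, late] < cm[, early] - margin]
}

#' Feature enrichment between two disjoint gene sets
#'
#' Builds the 2x2 contingency table of feature membership (e.g. Pol II
#' loading, Zelda binding, GAGA binding, H4K16ac) across two disjoint gene
#' sets and applies Fisher's exact test (two-sided).
#'
#' @param set_a,set_b disjoint, non-empty character vectors of gene ids.
#' @param feature_members gene ids positive for the feature.
#' @return list with `table` (2x2: rows set a/b, cols in/out of feature),
#'   `odds_ratio` (conditional MLE), `p_value`.
#' @export
feature_enrichment <- function(set_a, set_b, feature_members) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  if (length(set_a) == 0L || length(set_b) == 0L) {
    stop("both gene sets must be non-empty")
  }
  if (length(intersect(set_a, set_b))) {
    stop("sets overlap; the contingency design needs disjoint sets")
  }
  feature_members <- unique(as.character(feature_members))
  tab <- matrix(c(sum(set_a %in% feature_members),
                  sum(!set_a %in% feature_members),
                  sum(set_b %in% feature_members),
                  sum(!set_b %in% feature_members)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(set = c("set_a", "set_b"),
                                feature = c("in", "out")))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(table = tab, odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}

#' Read a one-column gene list
#'
#' @param path TSV/plain file with one gene id per line (no header).
#' @return character vector.
#' @export
read_gene_list <- function(path) {
  as.character(utils::read.table(path, header = FALSE,
                                 stringsAsFactors = FALSE)[[1L]])
}
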