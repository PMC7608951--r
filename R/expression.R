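#' Single-embryo expression matrix
#'
#' A light container binding a genes x samples numeric matrix to per-sample
#' metadata, with an explicit processing stage tag. Stage transitions are
#' one-way (`counts` -> `log2cpm` -> `row_scaled`); every operation checks
#' the tag, which prevents accidental double normalization.
#'
#' @param values numeric matrix, genes in rows (unique rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param meta data.frame of per-sample metadata with at least a
#'   `sample_id` column matching `colnames(values)`; the study design also
#'   carries `condition` (control/arrested), `cycle_label` (C12, C13, C14E,
#'   C14L or arrest minutes), `minutes` (after mitosis 11) and `replicate`.
#' @param stage one of `"counts"`, `"log2cpm"`, `"row_scaled"`.
#' @return an object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, meta = NULL,
                        stage = c("counts", "log2cpm", "row_scaled")) {
  stage <- match.arg(stage)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix")
  }
  if (ncol(values) < 1L) stop("need at least one sample column")
  gid <- rownames(values)
  if (is.null(gid) || anyDuplicated(gid)) {
    stop("rownames must be unique gene ids")
  }
  if (any(!is.finite(values))) stop("values must be finite")
  if (stage == "counts" && any(values < 0)) {
    stop("counts must be non-negative")
  }
  if (is.null(meta)) {
    meta <- data.frame(sample_id = colnames(values),
                       stringsAsFactors = FALSE)
  }
  if (!"sample_id" %in% names(meta)) stop("meta needs a sample_id column")
  if (!identical(as.character(meta$sample_id), colnames(values))) {
    meta <- meta[match(colnames(values), meta$sample_id), , drop = FALSE]
    if (anyNA(meta$sample_id)) {
      stop("meta does not cover all sample columns")
    }
  }
  structure(list(values = values, meta = meta, stage = stage),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix: ", nrow(x$values), " genes x ", ncol(x$values),
      " samples [stage: ", x$stage, "]\n", sep = "")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

# internal: refuse to run an operation at the wrong pipeline stage
.check_stage <- function(x, allowed) {
  stopifnot(inherits(x, "expr_matrix"))
  if (!x$stage %in% allowed) {
    stop("operation requires stage ", paste(allowed, collapse = " or "),
         " but matrix is at stage '", x$stage, "'")
  }
  invisible(x)
}

# internal: one condition key per sample, e.g. "control:C12", "arrested:30"
.condition_key <- function(meta) {
  if (all(c("condition", "cycle_label") %in% names(meta))) {
    paste(meta$condition, meta$cycle_label, sep = ":")
  } else if ("condition" %in% names(meta)) {
    as.character(meta$condition)
  } else {
    stop("meta needs condition (and cycle_label) columns")
  }
}

#' Read a gene x sample count matrix (and optional metadata) from TSV
#'
#' The counts file has a header of sample ids and gene ids in the first
#' column. Ragged rows, non-numeric cells and duplicate gene ids are
#' rejected with an error naming the offending row.
#'
#' @param path path to the counts TSV.
#' @param meta_path optional path to a sample-metadata TSV with columns
#'   `sample_id`, `condition`, `cycle_label`, `minutes`, `replicate`.
#' @return a counts-stage [expr_matrix()].
#' @export
read_counts <- function(path, meta_path = NULL) {
  nf <- utils::count.fields(path, sep = "\t", quote = "\"")
  if (length(unique(nf)) != 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop("ragged TSV: line ", bad, " has ", nf[bad],
         " fields, expected ", nf[1L])
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  gid <- tab[[1L]]
  if (anyDuplicated(gid)) {
    stop("duplicate gene id: ", gid[duplicated(gid)][1L])
  }
  raw <- as.matrix(tab[, -1L, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw),
                                  dimnames = list(gid, colnames(raw))))
  if (anyNA(vals)) {
    bad <- which(rowSums(is.na(vals)) > 0)[1L]
    stop("non-numeric value in row for gene '", gid[bad], "'")
  }
  meta <- if (!is.null(meta_path)) {
    utils::read.delim(meta_path, stringsAsFactors = FALSE)
  } else NULL
  expr_matrix(vals, meta, stage = "counts")
}

#' Write an expression matrix to TSV
#'
#' @param x an [expr_matrix()].
#' @param path output path; gene ids go in a `gene_id` first column.
#' @return the path, invisibly.
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  out <- data.frame(gene_id = rownames(x$values), x$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Log2(CPM + 1) normalization
#'
#' Per sample, counts are scaled to counts per million mapped fragments
#' (library size = column total of the counts assigned to genes in the
#' matrix) and transformed as `log2(CPM + 1)`; the pseudocount avoids
#' log2(0). Scale-invariant: multiplying a sample's counts by a constant
#' leaves its CPM unchanged.
#'
#' @param x a counts-stage [expr_matrix()].
#' @return a log2cpm-stage [expr_matrix()].
#' @export
log2_cpm <- function(x) {
  .check_stage(x, "counts")
  libsize <- colSums(x$values)
  if (any(libsize == 0)) {
    stop("sample(s) with all-zero counts (undefined library size): ",
         paste(colnames(x$values)[libsize == 0], collapse = ", "))
  }
  cpm <- sweep(x$values, 2L, libsize, "/") * 1e6
  expr_matrix(log2(cpm + 1), x$meta, stage = "log2cpm")
}

#' Per-gene (row) standardization
#'
#' Centers and scales each gene across samples to mean 0, sd 1 (the heatmap
#' normalization). Constant rows are mapped to all zeros and recorded in the
#' `constant_rows` attribute. Idempotent on already-scaled rows.
#'
#' @param x a log2cpm- or row_scaled-stage [expr_matrix()].
#' @return a row_scaled-stage [expr_matrix()] with attribute
#'   `constant_rows` (character vector of gene ids).
#' @export
scale_rows <- function(x) {
  .check_stage(x, c("log2cpm", "row_scaled"))
  v <- x$values
  mu <- rowMeans(v)
  sdv <- apply(v, 1L, stats::sd)
  const <- sdv == 0 | !is.finite(sdv)
  sdv[const] <- 1
  scaled <- (v - mu) / sdv
  scaled[const, ] <- 0
  out <- expr_matrix(scaled, x$meta, stage = "row_scaled")
  attr(out, "constant_rows") <- rownames(v)[const]
  out
}

#' PCA trajectory of embryo samples
#'
#' Principal component analysis with samples as observations and genes as
#' features, centered but not variance-scaled (all genes enter on the
#' log2 CPM+1 scale). Coordinates are reproducible up to a per-component
#' sign flip, as for any PCA.
#'
#' @param x a log2cpm-stage [expr_matrix()].
#' @param n_components number of components to keep (<= min(dim)).
#' @return a `pca_trajectory`: list with `coords` (samples x components),
#'   `variance_fraction` (non-increasing, sums to <= 1), `sdev`, and the
#'   sample metadata.
#' @export
pca_trajectory <- function(x, n_components = 2L) {
  .check_stage(x, "log2cpm")
  n <- ncol(x$values)
  if (n < 2L) stop("PCA needs at least 2 samples")
  if (n_components > min(dim(x$values))) {
    stop("n_components exceeds min(genes, samples)")
  }
  p <- stats::prcomp(t(x$values), center = TRUE, scale. = FALSE)
  k <- seq_len(n_components)
  vf <- p$sdev^2 / sum(p$sdev^2)
  structure(list(coords = p$x[, k, drop = FALSE],
                 variance_fraction = vf[k],
                 sdev = p$sdev,
                 meta = x$meta),
            class = "pca_trajectory")
}

#' @export
print.pca_trajectory <- function(x, ...) {
  cat("PCA trajectory: ", nrow(x$coords), " samples, ",
      ncol(x$coords), " components\n", sep = "")
  cat("variance fractions:",
      paste(sprintf("%.1f%%", 100 * x$variance_fraction), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
plot.pca_trajectory <- function(x, ...) {
  col <- if ("condition" %in% names(x$meta)) {
    ifelse(x$meta$condition == "control", "forestgreen", "firebrick")
  } else "black"
  graphics::plot(x$coords[, 1L], x$coords[, 2L], col = col, pch = 19,
                 xlab = sprintf("PC1 (%.1f%%)", 100 * x$variance_fraction[1L]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * x$variance_fraction[2L]),
                 ...)
  invisible(x)
}

# internal: condition means on the value scale, genes x conditions,
# replicates averaged within condition first
.condition_means <- function(x, genes = rownames(x$values)) {
  key <- .condition_key(x$meta)
  miss <- setdiff(genes, rownames(x$values))
  if (length(miss)) {
    stop("genes absent from matrix: ", paste(utils::head(miss, 3L),
                                             collapse = ", "))
  }
  v <- x$values[genes, , drop = FALSE]
  conds <- unique(key)
  m <- vapply(conds, function(k) rowMeans(v[, key == k, drop = FALSE]),
              numeric(length(genes)))
  matrix(m, nrow = length(genes), dimnames = list(genes, conds))
}

#' Mean log2 fold-change profile of a gene set
#'
#' For each condition, the per-gene mean log2 CPM+1 (replicates averaged)
#' is referenced to the baseline condition, and the resulting log2
#' fold changes are averaged over the gene set — the summary used for
#' group-wise response curves.
#'
#' @param x a log2cpm-stage [expr_matrix()].
#' @param gene_set character vector of gene ids (non-empty, present in the
#'   matrix).
#' @param baseline condition key (`"condition:cycle_label"`), default
#'   `"control:C12"`.
#' @return named numeric vector of mean log2 fold changes, one per
#'   condition (baseline included, identically 0).
#' @export
mean_foldchange_profile <- function(x, gene_set, baseline = "control:C12") {
  .check_stage(x, "log2cpm")
  if (length(gene_set) == 0L) stop("gene set is empty")
  cm <- .condition_means(x, gene_set)
  if (!baseline %in% colnames(cm)) {
    stop("baseline condition '", baseline, "' not present")
  }
  lfc <- cm - cm[, baseline]
  colMeans(lfc)
}
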