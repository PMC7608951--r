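#' Classify one gene as N/C-dependent or time-dependent
#'
#' Compares a haploid expression-by-cycle profile against the matched
#' diploid profile under two hypotheses: no shift (expression is scheduled
#' by absolute time, so halving the DNA content changes nothing) versus a
#' one-cycle delay (expression tracks the nucleo-cytoplasmic ratio, which in
#' haploids lags one doubling behind). Both profiles are median-centered,
#' then the mean squared error of the haploid profile against the diploid
#' profile shifted by 0 or by 1 cycle (toward later cycles, truncated
#' overlap) is computed; the strictly better fit wins, and fits within a
#' relative tolerance of each other are labelled ambiguous. Only shifts
#' {0, 1} are considered — the construct of interest is a one-cycle delay.
#'
#' The label is invariant to adding a constant to both profiles (median
#' centering) and to uniform positive rescaling (both errors scale alike).
#'
#' @param diploid,haploid numeric vectors of expression over the same
#'   ordered cycle axis (>= 3 points).
#' @param noise_floor minimum diploid amplitude (max - min) for a gene to
#'   count as activated; below it the gene is not classifiable and an error
#'   is thrown.
#' @param tol relative MSE difference under which the call is `ambiguous`
#'   (default 0.05).
#' @return one of `"nc_dependent"`, `"time_dependent"`, `"ambiguous"`, with
#'   attributes `mse_shift0` and `mse_shift1`.
#' @export
classify_delay <- function(diploid, haploid, noise_floor = 0, tol = 0.05) {
  diploid <- as.numeric(diploid)
  haploid <- as.numeric(haploid)
  if (length(diploid) != length(haploid)) {
    stop("profiles must share the cycle axis")
  }
  n <- length(diploid)
  if (n < 3L) stop("need at least 3 shared cycle points")
  if (any(!is.finite(diploid)) || any(!is.finite(haploid))) {
    stop("profiles must be finite")
  }
  if (max(diploid) - min(diploid) <= noise_floor) {
    stop("not classifiable: no activation in the diploid profile")
  }
  d <- diploid - stats::median(diploid)
  h <- haploid - stats::median(haploid)
  mse0 <- mean((h - d)^2)
  mse1 <- mean((h[-1L] - d[-n])^2)  # haploid at cycle c vs diploid at c-1
  label <- if (max(mse0, mse1) == 0) {
    "ambiguous"
  } else if (abs(mse0 - mse1) / max(mse0, mse1) <= tol) {
    "ambiguous"
  } else if (mse1 < mse0) {
    "nc_dependent"
  } else {
    "time_dependent"
  }
  structure(label, mse_shift0 = mse0, mse_shift1 = mse1)
}

#' Classify a cohort of genes from paired ploidy profiles
#'
#' Applies [classify_delay()] to every gene; genes failing its
#' preconditions (no diploid activation) are recorded as unclassifiable
#' rather than aborting the run. Deterministic and invariant to gene order.
#'
#' @param diploid,haploid genes x cycles numeric matrices with identical
#'   dimensions and rownames (gene ids).
#' @param noise_floor,tol passed to [classify_delay()].
#' @return an object of class `nc_classification`: list with `genes`
#'   (data.frame gene_id, label, mse_shift0, mse_shift1), `counts` (named:
#'   nc_dependent, time_dependent, ambiguous), and `unclassified` (gene
#'   ids).
#' @export
classify_cohort <- function(diploid, haploid, noise_floor = 0, tol = 0.05) {
  if (!is.matrix(diploid) || !is.matrix(haploid) ||
      !identical(dim(diploid), dim(haploid)) ||
      !identical(rownames(diploid), rownames(haploid))) {
    stop("diploid and haploid must be matrices with matching dims and gene ids")
  }
  if (nrow(diploid) == 0L) stop("empty profile table")
  gid <- rownames(diploid)
  res <- lapply(seq_len(nrow(diploid)), function(i) {
    tryCatch(classify_delay(diploid[i, ], haploid[i, ], noise_floor, tol),
             error = function(e) NULL)
  })
  ok <- !vapply(res, is.null, logical(1))
  genes <- data.frame(
    gene_id = gid[ok],
    label = vapply(res[ok], as.character, character(1)),
    mse_shift0 = vapply(res[ok], attr, numeric(1), "mse_shift0"),
    mse_shift1 = vapply(res[ok], attr, numeric(1), "mse_shift1"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  counts <- c(nc_dependent = sum(genes$label == "nc_dependent"),
              time_dependent = sum(genes$label == "time_dependent"),
              ambiguous = sum(genes$label == "ambiguous"))
  structure(list(genes = genes, counts = counts,
                 unclassified = gid[!ok]),
            class = "nc_classification")
}

#' @export
print.nc_classification <- function(x, ...) {
  cat("N/C- vs time-dependence classification\n")
  cat("  nc_dependent:  ", x$counts[["nc_dependent"]], "\n")
  cat("  time_dependent:", x$counts[["time_dependent"]], "\n")
  cat("  ambiguous:     ", x$counts[["ambiguous"]], "\n")
  if (length(x$unclassified)) {
    cat("  unclassifiable:", length(x$unclassified), "\n")
  }
  invisible(x)
}

#' Read paired ploidy profiles from a long-format TSV
#'
#' Columns `gene_id`, `ploidy` (diploid/haploid), `cycle`, `value`; every
#' gene must have both ploidies over the same cycles.
#'
#' @param path path to the TSV.
#' @return list with `diploid` and `haploid` genes x cycles matrices.
#' @export
read_ploidy_profiles <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "ploidy", "cycle", "value")
  if (!all(need %in% names(tab))) {
    stop("profile file must have columns: ", paste(need, collapse = ", "))
  }
  pivot <- function(p) {
    sub <- tab[tab$ploidy == p, ]
    cyc <- sort(unique(sub$cycle))
    gid <- unique(sub$gene_id)
    m <- matrix(NA_real_, length(gid), length(cyc),
                dimnames = list(gid, cyc))
    m[cbind(match(sub$gene_id, gid), match(sub$cycle, cyc))] <- sub$value
    if (anyNA(m)) stop("incomplete ", p, " profiles")
    m
  }
  d <- pivot("diploid")
  h <- pivot("haploid")
  if (!identical(dimnames(d), dimnames(h))) {
    stop("diploid and haploid profiles do not share genes/cycles")
  }
  list(diploid = d, haploid = h)
}
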