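#' Generate a ground-truth gene catalog
#'
#' Draws a catalog of gene specifications with planted labels for recovery
#' testing. Classes mirror the transcript economy of the early embryo:
#' \describe{
#'   \item{zygotic_only}{no maternal deposit; short TUs (1-4 kb) with a
#'     strong initiation rate, so transcripts accrue as soon as the
#'     productive window opens. Planted as arrest-response group 1.}
#'   \item{maternal_and_zygotic}{a maternal deposit destabilized at the MZT
#'     (half-life 15 min) plus strong zygotic re-expression. Most get long
#'     TUs (62-68 kb: the ~45-min eclipse delays arrest accrual past the
#'     50-minute point, giving the decrease-then-re-accumulate group-2
#'     signature while late cycle-14 control embryos still up-regulate
#'     them); a minority get ultra-long TUs (95-110 kb) whose eclipse
#'     exceeds every sampled window, so abundance only falls — planted
#'     group 3.}
#'   \item{maternal_only}{no zygotic transcription; a `maternal_decay_frac`
#'     fraction decays with half-life 100 min (abundance roughly halves
#'     between control C12 and C14L), the rest is stable.}
#'   \item{silent}{never expressed; all-zero counts.}
#' }
#' Zygotic initiation rates are per nucleus, scaled against
#' `nuclei_base` (the cycle-12 nuclear complement); group-2/3 rates are
#' coupled to the gene's maternal deposit so that zygotic accrual overtakes
#' the decayed pool by 70 minutes of arrest.
#'
#' @param n_genes number of genes (>= 1).
#' @param class_mix named proportions over the four classes (sum to 1).
#' @param seed integer seed; fixed seed gives an identical catalog.
#' @param nuclei_base cycle-12 nucleus count the rates are scaled to.
#' @param maternal_decay_frac fraction of maternal_only genes that decay.
#' @param group3_frac fraction of maternal_and_zygotic genes planted as
#'   group 3 (ultra-long TUs).
#' @return data.frame of gene specs: `gene_id`, `class`, `tu_length_kb`,
#'   `maternal_initial`, `decay_rate`, `decay_onset_min`, `zygotic_rate`,
#'   `planted_group` (1/2/3/NA), `planted_delay_class`.
#' @export
generate_catalog <- function(n_genes,
                             class_mix = c(zygotic_only = 0.24,
                                           maternal_and_zygotic = 0.06,
                                           maternal_only = 0.65,
                                           silent = 0.05),
                             seed = 1L,
                             nuclei_base = 2000,
                             maternal_decay_frac = 0.45,
                             group3_frac = 75 / 562) {
  if (n_genes < 1L) stop("n_genes must be >= 1")
  classes <- c("zygotic_only", "maternal_and_zygotic", "maternal_only",
               "silent")
  if (!setequal(names(class_mix), classes)) {
    stop("class_mix must name exactly: ", paste(classes, collapse = ", "))
  }
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  set.seed(seed)
  cls <- sample(classes, n_genes, replace = TRUE,
                prob = class_mix[classes])
  cat_df <- data.frame(
    gene_id = sprintf("g%05d", seq_len(n_genes)),
    class = cls,
    tu_length_kb = 0, maternal_initial = 0, decay_rate = 0,
    decay_onset_min = 0, zygotic_rate = 0,
    planted_group = NA_integer_,
    planted_delay_class = "none",
    stringsAsFactors = FALSE
  )
  zy <- cls == "zygotic_only"
  mz <- cls == "maternal_and_zygotic"
  mo <- cls == "maternal_only"
  # group 1: short, strongly expressed purely zygotic genes
  cat_df$tu_length_kb[zy] <- stats::runif(sum(zy), 1, 4)
  cat_df$zygotic_rate[zy] <-
    stats::rlnorm(sum(zy), log(8), 0.4) / nuclei_base
  cat_df$planted_group[zy] <- 1L
  cat_df$planted_delay_class[zy] <-
    sample(c("nc_like", "time_like", "none"), sum(zy), replace = TRUE,
           prob = c(0.1, 0.1, 0.8))
  # maternal deposits (log-normal around 400 transcripts)
  cat_df$maternal_initial[mz | mo] <-
    stats::rlnorm(sum(mz | mo), log(400), 0.6)
  # groups 2/3: destabilized maternal pool + zygotic re-expression
  g3 <- mz & stats::runif(n_genes) < group3_frac
  g2 <- mz & !g3
  cat_df$decay_rate[mz] <- log(2) / 15
  cat_df$tu_length_kb[g2] <- stats::runif(sum(g2), 62, 68)
  cat_df$tu_length_kb[g3] <- stats::runif(sum(g3), 95, 110)
  cat_df$zygotic_rate[mz] <-
    0.08 * cat_df$maternal_initial[mz] / nuclei_base
  cat_df$planted_group[g2] <- 2L
  cat_df$planted_group[g3] <- 3L
  # maternal clearance vs stable housekeeping pool
  dec <- mo & stats::runif(n_genes) < maternal_decay_frac
  cat_df$decay_rate[dec] <- log(2) / 100
  cat_df$tu_length_kb[mo] <- stats::runif(sum(mo), 1, 20)
  cat_df
}

#' Study design for a synthetic single-embryo experiment
#'
#' Encodes the two-arm layout: control embryos collected in cycles 12, 13,
#' early 14 and late 14 (nuclei doubling each cycle, 4-fold from C12 to
#' C14), and cycle-12-arrested embryos sampled 15/30/50/70 minutes after
#' mitosis 11 (nuclei fixed at the cycle-12 complement). Time zero is the
#' end of mitosis 11; control collection times are derived from the
#' schedule's interphase/mitosis durations plus the within-cycle sampling
#' offsets.
#'
#' @param replicates embryos per condition (default 3).
#' @param nuclei_base nucleus count at cycle 12 (default 2000).
#' @param schedule a [cycle_schedule()].
#' @param arrest_minutes arrest sampling times (minutes after mitosis 11).
#' @param c12_sample_min,c13_sample_min,c14e_min,c14l_min within-interphase
#'   collection offsets for the control conditions (minutes).
#' @param library_meanlog,library_sdlog log-normal library-size parameters.
#' @param dispersion negative-binomial overdispersion (variance =
#'   mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param seed integer seed for count sampling.
#' @return an object of class `embryo_design`: list with `samples`
#'   (data.frame: sample_id, condition, cycle_label, minutes, replicate,
#'   cycle, time_in_cycle, nuclei) and the noise/size parameters.
#' @export
study_design <- function(replicates = 3L, nuclei_base = 2000,
                         schedule = default_cycle_schedule(),
                         arrest_minutes = c(15, 30, 50, 70),
                         c12_sample_min = 6, c13_sample_min = 8,
                         c14e_min = 10, c14l_min = 70,
                         library_meanlog = log(1e6), library_sdlog = 0.15,
                         dispersion = 0.1, seed = 1L) {
  if (replicates < 1L) stop("need >= 1 replicate per condition")
  tab <- schedule$table
  dur <- function(cy) {  # interphase + mitosis of one cycle
    i <- .schedule_row(schedule, cy)
    tab$interphase_min[i] + tab$mitosis_min[i]
  }
  t13 <- dur(12)              # entry into cycle-13 interphase
  t14 <- dur(12) + dur(13)    # entry into cycle-14 interphase
  ctrl <- data.frame(
    condition = "control",
    cycle_label = c("C12", "C13", "C14E", "C14L"),
    cycle = c(12L, 13L, 14L, 14L),
    time_in_cycle = c(c12_sample_min, c13_sample_min, c14e_min, c14l_min),
    minutes = c(c12_sample_min, t13 + c13_sample_min, t14 + c14e_min,
                t14 + c14l_min),
    stringsAsFactors = FALSE
  )
  arr <- data.frame(
    condition = "arrested",
    cycle_label = as.character(arrest_minutes),
    cycle = 12L,
    time_in_cycle = arrest_minutes,
    minutes = arrest_minutes,
    stringsAsFactors = FALSE
  )
  conds <- rbind(ctrl, arr)
  samples <- conds[rep(seq_len(nrow(conds)), each = replicates), ]
  samples$replicate <- rep(seq_len(replicates), times = nrow(conds))
  samples$nuclei <- ifelse(samples$condition == "arrested", nuclei_base,
                           nuclei_base * 2^(samples$cycle - 12L))
  samples$sample_id <- paste(samples$condition, samples$cycle_label,
                             samples$replicate, sep = "_")
  rownames(samples) <- NULL
  structure(list(samples = samples, nuclei_base = nuclei_base,
                 library_meanlog = library_meanlog,
                 library_sdlog = library_sdlog,
                 dispersion = dispersion, seed = as.integer(seed)),
            class = "embryo_design")
}

#' @export
print.embryo_design <- function(x, ...) {
  cat("Synthetic study design: ", nrow(x$samples), " embryos (",
      length(unique(.condition_key(x$samples))), " conditions)\n", sep = "")
  cat("  nuclei at C12: ", x$nuclei_base, "; NB dispersion: ",
      x$dispersion, "\n", sep = "")
  invisible(x)
}

#' Expected transcript abundance of one gene at one design point
#'
#' Deterministic expectation under the window model:
#' \itemize{
#'   \item maternal pool: `maternal_initial * exp(-decay_rate *
#'     max(0, t - decay_onset))`, t in minutes after mitosis 11;
#'   \item zygotic pool: completed transcripts accumulated over every
#'     elapsed cycle, `rate * nuclei(cycle) * productive_window(cycle)`,
#'     plus accrual in the current interphase,
#'     `rate * nuclei * max(0, time_in_cycle - lag - eclipse)`. Arrested
#'     embryos sit in an unbounded cycle-12 interphase, so they accrue
#'     continuously with the cycle-12 nuclear complement.
#' }
#' Nuclei halve per cycle backwards from `nuclei_base` at cycle 12
#' (`nuclei_base * 2^(cycle - 12)`).
#'
#' @param gene one row of a [generate_catalog()] data.frame (or an
#'   equivalent list).
#' @param at one row of `study_design()$samples`.
#' @param schedule a [cycle_schedule()].
#' @param nuclei_base cycle-12 nucleus count.
#' @return expected transcript count (>= 0).
#' @export
expected_abundance <- function(gene, at, schedule = default_cycle_schedule(),
                               nuclei_base = 2000) {
  t_abs <- at$minutes
  maternal <- gene$maternal_initial *
    exp(-gene$decay_rate * max(0, t_abs - gene$decay_onset_min))
  zygotic <- 0
  if (gene$zygotic_rate > 0) {
    ecl <- eclipse_time(gene$tu_length_kb, schedule)
    cyc_now <- at$cycle
    prior <- schedule$table$cycle[schedule$table$cycle < cyc_now]
    if (at$condition == "arrested") {
      prior <- schedule$table$cycle[schedule$table$cycle < 12L]
    }
    if (length(prior)) {
      pw <- productive_window(prior, gene$tu_length_kb, schedule)
      zygotic <- zygotic + sum(gene$zygotic_rate *
                                 nuclei_base * 2^(prior - 12) * pw)
    }
    n_now <- if (at$condition == "arrested") nuclei_base else
      nuclei_base * 2^(cyc_now - 12)
    zygotic <- zygotic + gene$zygotic_rate * n_now *
      max(0, at$time_in_cycle - schedule$lag_min - ecl)
  }
  maternal + zygotic
}

# internal: genes x samples expectation matrix (vectorized over genes;
# agrees with expected_abundance() row by row)
.expected_matrix <- function(catalog, design,
                             schedule = default_cycle_schedule()) {
  s <- design$samples
  nb <- design$nuclei_base
  ecl <- catalog$tu_length_kb * schedule$elongation_min_per_kb
  m <- matrix(0, nrow(catalog), nrow(s),
              dimnames = list(catalog$gene_id, s$sample_id))
  for (j in seq_len(nrow(s))) {
    t_abs <- s$minutes[j]
    maternal <- catalog$maternal_initial *
      exp(-catalog$decay_rate * pmax(0, t_abs - catalog$decay_onset_min))
    upto <- if (s$condition[j] == "arrested") 12L else s$cycle[j]
    prior <- schedule$table$cycle[schedule$table$cycle < upto]
    zprior <- 0
    if (length(prior)) {
      wins <- transcription_window(prior, schedule)
      pw <- outer(ecl, wins, function(e, w) pmax(0, w - e))
      zprior <- as.numeric(pw %*% 2^(prior - 12)) * nb
    }
    n_now <- s$nuclei[j]
    znow <- n_now * pmax(0, s$time_in_cycle[j] - schedule$lag_min - ecl)
    m[, j] <- maternal + catalog$zygotic_rate * (zprior + znow)
  }
  m
}

#' Sample overdispersed counts from an expectation matrix
#'
#' Per sample, a library size is drawn log-normally; each gene's count is
#' negative-binomial with mean proportional to its share of the sample's
#' expected transcript pool times the library size, and variance
#' `mu + dispersion * mu^2` (`dispersion = 0` gives Poisson draws). Genes
#' with zero expectation always yield zero counts. Reproducible under the
#' design's seed.
#'
#' @param expected genes x samples matrix of expected transcript counts
#'   (finite, >= 0).
#' @param design an [study_design()] object (noise parameters + seed).
#' @return a counts-stage [expr_matrix()] carrying the design's sample
#'   metadata.
#' @export
sample_counts <- function(expected, design) {
  stopifnot(inherits(design, "embryo_design"))
  if (any(!is.finite(expected)) || any(expected < 0)) {
    stop("expected values must be finite and >= 0")
  }
  s <- design$samples
  if (ncol(expected) != nrow(s)) stop("expected matrix does not match design")
  set.seed(design$seed)
  libsize <- stats::rlnorm(nrow(s), design$library_meanlog,
                           design$library_sdlog)
  counts <- matrix(0, nrow(expected), ncol(expected),
                   dimnames = dimnames(expected))
  for (j in seq_len(ncol(expected))) {
    tot <- sum(expected[, j])
    if (tot == 0) stop("sample ", s$sample_id[j], " has zero total expectation")
    mu <- expected[, j] / tot * libsize[j]
    counts[, j] <- if (design$dispersion > 0) {
      stats::rnbinom(nrow(expected), mu = mu, size = 1 / design$dispersion)
    } else {
      stats::rpois(nrow(expected), mu)
    }
  }
  meta <- s[, c("sample_id", "condition", "cycle_label", "minutes",
                "replicate")]
  expr_matrix(counts, meta, stage = "counts")
}

#' Generate a complete synthetic study bundle
#'
#' One call produces everything the analysis pipeline consumes: a counts
#' matrix, sample metadata, the planted truth table, and the schedule used.
#' With `dir` set, the bundle is also written as TSV files (`counts.tsv`,
#' `meta.tsv`, `truth.tsv`, `schedule.tsv`).
#'
#' @param n_genes catalog size (ignored when `catalog` is supplied).
#' @param catalog optional [generate_catalog()] data.frame.
#' @param design optional [study_design()]; defaults derive their seeds
#'   from `seed`.
#' @param schedule a [cycle_schedule()].
#' @param seed root seed; the catalog uses `seed`, count sampling
#'   `seed + 1`.
#' @param dir optional output directory for the TSV bundle.
#' @return an object of class `zga_study`: list with `counts`
#'   (counts-stage [expr_matrix()]), `truth` (planted labels), `catalog`,
#'   `design`, `schedule`.
#' @export
make_study <- function(n_genes = 2000, catalog = NULL, design = NULL,
                       schedule = default_cycle_schedule(), seed = 1L,
                       dir = NULL) {
  if (is.null(catalog)) {
    catalog <- generate_catalog(n_genes, seed = seed,
                                nuclei_base = if (is.null(design)) 2000 else
                                  design$nuclei_base)
  }
  if (nrow(catalog) == 0L) stop("empty gene catalog")
  if (is.null(design)) {
    design <- study_design(schedule = schedule, seed = seed + 1L)
  }
  expected <- .expected_matrix(catalog, design, schedule)
  counts <- sample_counts(expected, design)
  truth <- catalog[, c("gene_id", "class", "planted_group",
                       "planted_delay_class", "tu_length_kb")]
  study <- structure(list(counts = counts, truth = truth, catalog = catalog,
                          design = design, schedule = schedule),
                     class = "zga_study")
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_counts(counts, file.path(dir, "counts.tsv"))
    utils::write.table(counts$meta, file.path(dir, "meta.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_cycle_schedule(schedule, file.path(dir, "schedule.tsv"))
  }
  study
}

#' @export
print.zga_study <- function(x, ...) {
  cat("Synthetic single-embryo study: ", nrow(x$counts$values), " genes x ",
      ncol(x$counts$values), " embryos\n", sep = "")
  print(table(planted_group = x$truth$planted_group, useNA = "ifany"))
  invisible(x)
}

#' Generate paired diploid/haploid expression-by-cycle profiles
#'
#' Builds per-cycle activation profiles from the window model: a gene's
#' diploid profile follows its time-averaged expression efficiency across
#' cycles (longer TUs switch on later and more abruptly). "nc_like" genes
#' couple to the nucleo-cytoplasmic ratio, so their haploid profile is the
#' diploid one delayed by exactly one cycle; "time_like" genes follow
#' absolute time and keep the same profile. Gaussian noise with standard
#' deviation `noise_sd_frac` of the activation amplitude is added to every
#' value.
#'
#' @param n_nc,n_time numbers of planted nc_like / time_like genes.
#' @param cycles cycle axis of the profiles (default 10:14).
#' @param tu_length_range kb range the TU lengths are drawn from; the
#'   default (6-14 kb) puts activation onsets inside the cycle axis.
#' @param noise_sd_frac noise sd as a fraction of amplitude (default 0.1).
#' @param amplitude full activation level in expression units.
#' @param schedule a [cycle_schedule()].
#' @param seed integer seed.
#' @return list with `diploid` and `haploid` genes x cycles matrices and
#'   `truth` (data.frame gene_id, delay_class).
#' @export
generate_ploidy_profiles <- function(n_nc = 50L, n_time = 50L,
                                     cycles = 10:14,
                                     tu_length_range = c(6, 14),
                                     noise_sd_frac = 0.1, amplitude = 1,
                                     schedule = default_cycle_schedule(),
                                     seed = 1L) {
  n <- n_nc + n_time
  if (n < 1L) stop("need at least one gene")
  set.seed(seed)
  lens <- stats::runif(n, tu_length_range[1L], tu_length_range[2L])
  delay <- c(rep("nc_like", n_nc), rep("time_like", n_time))
  gid <- sprintf("p%04d", seq_len(n))
  base <- t(vapply(lens, function(L) {
    amplitude * expression_efficiency(cycles, L, schedule) / 100
  }, numeric(length(cycles))))
  prev <- t(vapply(lens, function(L) {
    amplitude *
      expression_efficiency(pmax(cycles - 1L, min(schedule$table$cycle)),
                            L, schedule) / 100
  }, numeric(length(cycles))))
  hap <- base
  hap[delay == "nc_like", ] <- prev[delay == "nc_like", ]
  noise <- function() matrix(stats::rnorm(n * length(cycles), 0,
                                          noise_sd_frac * amplitude),
                             n, length(cycles))
  dip <- base + noise()
  hap <- hap + noise()
  dimnames(dip) <- dimnames(hap) <- list(gid, cycles)
  list(diploid = dip, haploid = hap,
       truth = data.frame(gene_id = gid, delay_class = delay,
                          stringsAsFactors = FALSE))
}
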