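test_that("catalog generation is seeded and multinomially consistent", {
  c1 <- generate_catalog(500, seed = 3)
  c2 <- generate_catalog(500, seed = 3)
  expect_identical(c1, c2)
  # all-maternal mix: no zygotic rates anywhere
  mono <- generate_catalog(100, class_mix = c(zygotic_only = 0,
                                              maternal_and_zygotic = 0,
                                              maternal_only = 1, silent = 0),
                           seed = 1)
  expect_true(all(mono$zygotic_rate == 0))
  expect_true(all(mono$class == "maternal_only"))
  # class frequencies near the requested mix at large n (3-sigma binomial CI)
  mix <- c(zygotic_only = 0.24, maternal_and_zygotic = 0.06,
           maternal_only = 0.65, silent = 0.05)
  big <- generate_catalog(10000, class_mix = mix, seed = 9)
  for (cl in names(mix)) {
    p <- mix[[cl]]
    se <- sqrt(p * (1 - p) / 10000)
    expect_lt(abs(mean(big$class == cl) - p), 3 * se + 1e-9)
  }
  expect_error(generate_catalog(10, class_mix = mix * 2), "sum to 1")
})

test_that("catalog respects the class invariants", {
  cat_df <- generate_catalog(2000, seed = 21)
  expect_true(all(cat_df$maternal_initial[cat_df$class == "zygotic_only"] == 0))
  expect_true(all(cat_df$zygotic_rate[cat_df$class == "maternal_only"] == 0))
  expect_true(all(cat_df$tu_length_kb >= 0))
  # planted groups appear only on zygotic classes and partition them
  z <- cat_df$class %in% c("zygotic_only", "maternal_and_zygotic")
  expect_true(all(!is.na(cat_df$planted_group[z])))
  expect_true(all(is.na(cat_df$planted_group[!z])))
})

test_that("expected abundance follows the decay and accrual model", {
  s <- default_cycle_schedule()
  design <- study_design(seed = 1)
  pts <- design$samples[!duplicated(design$samples$cycle_label), ]
  # maternal-only gene without decay is constant everywhere
  g_flat <- list(maternal_initial = 250, decay_rate = 0, decay_onset_min = 0,
                 zygotic_rate = 0, tu_length_kb = 5)
  ev <- vapply(seq_len(nrow(pts)), function(j)
    expected_abundance(g_flat, pts[j, ], s), numeric(1))
  expect_true(all(ev == 250))
  # a TU too long for every pre-terminal window is silent until cycle 14
  L <- 20  # eclipse 14 min > the 11-min cycle-13 window
  g_long <- list(maternal_initial = 0, decay_rate = 0, decay_onset_min = 0,
                 zygotic_rate = 1e-3, tu_length_kb = L)
  at <- function(lab) pts[pts$cycle_label == lab, ]
  expect_equal(expected_abundance(g_long, at("C12"), s), 0)
  expect_equal(expected_abundance(g_long, at("C13"), s), 0)
  expect_gt(expected_abundance(g_long, at("C14L"), s), 0)
  # exponential decay with onset
  g_dec <- list(maternal_initial = 100, decay_rate = 0.02,
                decay_onset_min = 10, zygotic_rate = 0, tu_length_kb = 1)
  a70 <- design$samples[design$samples$cycle_label == "70", ][1, ]
  expect_equal(expected_abundance(g_dec, a70, s), 100 * exp(-0.02 * 60))
})

test_that("zygotic accrual matches a quadrature oracle over two cycles", {
  s <- cycle_schedule(12:13, c(10, 14), mitosis_min = 4, lag_min = 3,
                      elongation_min_per_kb = 0.5, terminal_cycle = 14L)
  gene <- list(maternal_initial = 0, decay_rate = 0, decay_onset_min = 0,
               zygotic_rate = 0.002, tu_length_kb = 6)  # eclipse 3 min
  nb <- 1000
  at <- list(condition = "control", cycle = 14L, cycle_label = "C14E",
             time_in_cycle = 0, minutes = 10 + 4 + 14 + 4)
  got <- expected_abundance(gene, at, s, nuclei_base = nb)
  # oracle: integrate the initiation density over each interphase, counting
  # only initiations whose completion time falls inside the same interphase
  quad <- function(iph, nuclei) {
    tt <- seq(0, iph, by = 1e-4)
    ok <- tt > s$lag_min & tt + 3 <= iph
    0.002 * nuclei * sum(ok) * 1e-4
  }
  oracle <- quad(10, nb * 2^(12 - 12)) + quad(14, nb * 2^(13 - 12))
  expect_equal(got, oracle, tolerance = 1e-3)
})

test_that("vectorized expectation matrix agrees with the scalar form", {
  s <- default_cycle_schedule()
  cat_df <- generate_catalog(40, seed = 13)
  design <- study_design(replicates = 1L, seed = 2)
  em <- zgawindow:::.expected_matrix(cat_df, design, s)
  for (i in c(1, 7, 25)) {
    for (j in c(1, 5, 8)) {
      expect_equal(em[i, j],
                   expected_abundance(cat_df[i, ], design$samples[j, ], s,
                                      design$nuclei_base))
    }
  }
})

test_that("count sampling is reproducible, zero-faithful, and Poisson in the limit", {
  cat_df <- generate_catalog(60, seed = 4)
  design <- study_design(seed = 11)
  em <- zgawindow:::.expected_matrix(cat_df, design)
  x1 <- sample_counts(em, design)
  x2 <- sample_counts(em, design)
  expect_identical(x1$values, x2$values)
  expect_equal(x1$stage, "counts")
  # zero expectation (silent genes) always yields zero counts
  silent <- cat_df$gene_id[cat_df$class == "silent"]
  expect_true(all(x1$values[silent, ] == 0))
  # dispersion -> 0 with fixed library size: variance ~ mean
  d0 <- study_design(replicates = 1250L, dispersion = 0, library_sdlog = 0,
                     seed = 6)
  two <- data.frame(gene_id = c("gA", "gB"), class = "maternal_only",
                    tu_length_kb = 1, maternal_initial = c(300, 700),
                    decay_rate = 0, decay_onset_min = 0, zygotic_rate = 0,
                    planted_group = NA_integer_,
                    planted_delay_class = "none")
  emp <- zgawindow:::.expected_matrix(two, d0)
  xp <- sample_counts(emp, d0)
  draws <- xp$values["gA", ]
  expect_equal(stats::var(draws) / mean(draws), 1, tolerance = 0.1)
})

test_that("a study bundle runs the full pipeline and round-trips to disk", {
  dir <- withr::local_tempdir()
  st <- make_study(n_genes = 250, seed = 31, dir = dir)
  expect_s3_class(st, "zga_study")
  expect_equal(ncol(st$counts$values), 24L)  # 8 conditions x 3 embryos
  expect_setequal(unique(st$counts$meta$cycle_label),
                  c("C12", "C13", "C14E", "C14L", "15", "30", "50", "70"))
  for (f in c("counts.tsv", "meta.tsv", "truth.tsv", "schedule.tsv")) {
    expect_true(file.exists(file.path(dir, f)))
  }
  back <- read_counts(file.path(dir, "counts.tsv"),
                      file.path(dir, "meta.tsv"))
  expect_equal(back$values, st$counts$values)
  expect_equal(back$meta$condition, st$counts$meta$condition)
  # the bundle is analyzable end to end
  lc <- log2_cpm(back)
  analyzed <- st$truth$gene_id[!is.na(st$truth$planted_group)]
  g <- categorize_groups(lc, analyzed)
  expect_equal(sum(g$counts), length(analyzed))
  expect_error(make_study(catalog = generate_catalog(5, seed = 1)[0, ]),
               "empty gene catalog")
})

test_that("planted zygotic genes are found by the zygotic identifier", {
  st <- make_study(n_genes = 400, seed = 8)
  lc <- log2_cpm(st$counts)
  res <- identify_zygotic(lc)
  called <- res$gene_id[res$zygotic]
  planted <- st$truth$gene_id[st$truth$planted_group %in% c(1L, 2L)]
  # groups 1 and 2 rise strongly by late C14; nearly all should be called
  expect_gt(mean(planted %in% called), 0.95)
  # silent genes are never called
  expect_length(intersect(called,
                          st$truth$gene_id[st$truth$class == "silent"]), 0)
})

test_that("planted maternal clearance genes are recovered", {
  st <- make_study(n_genes = 500, seed = 19)
  lc <- log2_cpm(st$counts)
  decaying <- st$catalog$gene_id[st$catalog$class == "maternal_only" &
                                   st$catalog$decay_rate > 0]
  stable <- st$catalog$gene_id[st$catalog$class == "maternal_only" &
                                 st$catalog$decay_rate == 0]
  sel <- select_maternal(c(decaying, stable), lc)
  expect_gt(mean(decaying %in% sel), 0.95)
  # decaying genes fall further than stable ones, whose apparent drop is
  # only the CPM composition shift as zygotic transcripts flood the library
  cm <- zgawindow:::.condition_means(lc, c(decaying, stable))
  drop <- cm[, "control:C12"] - cm[, "control:C14L"]
  expect_gt(mean(drop[decaying]), mean(drop[stable]) + 0.5)
  # genes rising in controls are never selected
  rising <- st$truth$gene_id[st$truth$planted_group %in% c(1L, 2L)]
  sel2 <- select_maternal(rising, lc)
  expect_lt(length(sel2) / length(rising), 0.05)
})
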