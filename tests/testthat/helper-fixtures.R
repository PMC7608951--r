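# shared fixtures built in code

# small log2cpm-stage matrix with the full study layout
toy_log2cpm <- function(values, conditions, cycle_labels) {
  reps <- ave(seq_along(conditions), paste(conditions, cycle_labels),
              FUN = seq_along)
  meta <- data.frame(
    sample_id = paste(conditions, cycle_labels, reps, sep = "_"),
    condition = conditions, cycle_label = cycle_labels,
    replicate = reps, stringsAsFactors = FALSE
  )
  colnames(values) <- meta$sample_id
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("gene", seq_len(nrow(values)))
  }
  expr_matrix(values, meta, stage = "log2cpm")
}

# a random but valid schedule: monotone interphases, fixed mitosis/lag
random_schedule <- function() {
  n <- sample(4:7, 1)
  cycles <- seq(8L, length.out = n)
  iph <- cumsum(runif(n, 0.5, 6)) + runif(1, 3, 6)
  cycle_schedule(cycles, iph,
                 mitosis_min = runif(1, 2, 6),
                 lag_min = runif(1, 1, 5),
                 elongation_min_per_kb = runif(1, 0.3, 1.5),
                 terminal_cycle = max(cycles))
}
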