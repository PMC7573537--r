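# small in-code fixtures shared across test files

write_tsv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# two participants x one contrast x two ROIs
tiny_bold_lines <- c(
  "participant\tcontrast\troi\tvalue",
  "p1\tc1\tL_STR\t0.10",
  "p1\tc1\tR_STR\t0.20",
  "p2\tc1\tL_STR\t0.30",
  "p2\tc1\tR_STR\t0.40")

# deterministic compound table: one ROI active with mean mu, others at 0
make_est <- function(values_by_roi, condition = "execution") {
  rois <- names(values_by_roi)
  n <- length(values_by_roi[[1]])
  df <- do.call(rbind, lapply(rois, function(r) {
    data.frame(participant = sprintf("p%02d", seq_len(n)), roi = r,
               condition = condition, value = values_by_roi[[r]],
               n_contrasts = 1L, stringsAsFactors = FALSE)
  }))
  class(df) <- c("compound_estimates", "data.frame")
  df
}

# per-ROI BF map with every subcortical ROI at `base` except overrides
bf_map <- function(base = 1, ...) {
  bfs <- stats::setNames(rep(base, 12), roi_ids(subcortical = TRUE))
  over <- list(...)
  bfs[names(over)] <- unlist(over)
  bfs
}
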