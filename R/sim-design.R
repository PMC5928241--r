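#' Generate the sample sheet for a simulated exposure series
#'
#' Expands the dose-by-time-by-replicate design into one record per sample
#' and assigns array batch structure: samples are permuted at random and
#' grouped onto chips of fixed capacity (default 12, i.e. six rows of a
#' two-column beadchip, abstracted to a row index 1-6), so replicates are
#' randomized with respect to chip position.
#'
#' @param config a [sim_config()] object.
#' @param chip_capacity samples per chip (default 12).
#' @return a data.frame with columns `sample_id`, `dose` (Gy), `time`
#'   (days), `replicate`, `chip`, `row`, `series`.
#' @export
#' @examples
#' sheet <- generate_sample_sheet(sim_config(n_probes = 10, seed = 7))
#' table(sheet$dose, sheet$time)
generate_sample_sheet <- function(config, chip_capacity = 12) {
  stopifnot(inherits(config, "sim_config"))
  if (!is_count(chip_capacity) || chip_capacity < 1)
    stop_bad_arg("chip_capacity", "must be a positive count")
  if (length(config$doses) == 0 || length(config$time_points) == 0 ||
      config$n_replicates < 1)
    stop("empty design: doses, time_points and n_replicates must be non-empty",
         call. = FALSE)
  grid <- expand.grid(replicate = seq_len(config$n_replicates),
                      time = config$time_points,
                      dose = config$doses,
                      KEEP.OUT.ATTRS = FALSE)
  n <- nrow(grid)
  rows_per_chip <- max(1L, as.integer(ceiling(chip_capacity / 2)))
  with_seed(config$seed + 1L, {
    slot <- sample.int(n) # random chip position per sample
    sheet <- data.frame(
      sample_id = sprintf("s%03d", seq_len(n)),
      dose = grid$dose,
      time = grid$time,
      replicate = grid$replicate,
      chip = ((slot - 1L) %/% chip_capacity) + 1L,
      row = (((slot - 1L) %% chip_capacity) %% rows_per_chip) + 1L,
      series = config$series,
      stringsAsFactors = FALSE
    )
  })
  sheet
}
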