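# Morphometric quantifiers and lattice fixtures for testing them.

#' Angiogenesis level of a lattice
#'
#' Horizontal scan lines, one per vertical lattice site, are drawn through
#' the lower 90 percent of the initial fibrin region.  On each line the
#' connected runs of cell-or-medium sites are counted, keeping only runs
#' longer than one cell size (strictly more than `min_run` sites) and
#' narrower than the complete line: a full-width run reflects lowering of
#' the whole monolayer rather than sprouting.  The level is the mean count
#' over lines, reflecting sprout count and sprout depth simultaneously.
#'
#' @param state A [lattice_state()].
#' @param fibrin_rows Rows (bottom-up) of the initial fibrin region, as
#'   recorded at initialization; the current fibrin recedes as it is
#'   degraded, so depth is always measured inside the initial region.
#' @param min_run Run-length threshold in sites (one cell diameter).
#' @return Mean component count per scan line (dimensionless, >= 0).
#' @export
angiogenesis_level <- function(state, fibrin_rows, min_run = 20) {
  scan_rows <- fibrin_rows[seq_len(floor(0.9 * length(fibrin_rows)))]
  if (length(scan_rows) == 0) return(0)
  site_type <- matrix(state$type[state$sigma], nrow = nrow(state$sigma))
  open_types <- TYPE_CODES[c("cell", "medium")]
  counts <- vapply(scan_rows, function(r) {
    row <- site_type[r, ]
    keep <- !(row %in% TYPE_CODES[c("border", "cell patch")])
    open <- row[keep] %in% open_types
    full <- sum(keep)
    runs <- rle(open)
    sum(runs$values & runs$lengths > min_run & runs$lengths < full)
  }, numeric(1))
  mean(counts)
}

#' Fibrinolysis percentage
#'
#' Percentage of the initially fibrin-occupied lattice sites that are now
#' occupied by endothelial cells.  Degraded sites now holding medium do
#' not count as invaded.
#'
#' @inheritParams angiogenesis_level
#' @param initial_fibrin Logical matrix marking the initial fibrin sites.
#' @return Percentage in `[0, 100]`.
#' @export
fibrinolysis_percentage <- function(state, initial_fibrin) {
  n0 <- sum(initial_fibrin)
  if (n0 == 0) stop("no initial fibrin sites recorded")
  now <- state$type[state$sigma[initial_fibrin]]
  100 * sum(now == TYPE_CODES[["cell"]]) / n0
}

#' Sprouting percentage over replicate runs
#'
#' @param levels Numeric vector of angiogenesis levels, one per run.
#' @return List with `percentage` (runs with level > 0) and
#'   `mean_level_sprouted` (mean level over the runs that formed sprouts;
#'   `NaN` when none did).
#' @export
sprouting_percentage <- function(levels) {
  if (length(levels) == 0) stop("no angiogenesis levels supplied")
  sprouted <- levels > 0
  list(percentage = 100 * mean(sprouted),
       mean_level_sprouted = mean(levels[sprouted]))
}

#' Cell-cycle statistics from the division log
#'
#' Mean inter-division interval across lineages, converted to days.  Each
#' division event records the dividing cell's birth MCS; the interval is
#' division MCS minus birth MCS.
#'
#' @param events Division log as produced by [run_simulation()].
#' @param minutes_per_mcs Real-time equivalent of one MCS.
#' @return List with `mean_days` (`NA` with `defined = FALSE` when the
#'   log is empty), `n_intervals` and `defined`.
#' @export
cell_cycle_stats <- function(events, minutes_per_mcs = 2.5) {
  if (is.null(events) || nrow(events) == 0)
    return(list(mean_days = NA_real_, n_intervals = 0L, defined = FALSE))
  intervals <- events$mcs - events$parent_birth
  list(mean_days = mean(intervals) * minutes_per_mcs / (24 * 60),
       n_intervals = length(intervals), defined = TRUE)
}

#' Hand-built lattice fixtures for the quantifiers
#'
#' Deterministic monolayer-on-fibrin lattices with optional rectangular
#' sprouts and/or a uniformly lowered monolayer, for testing the
#' morphometrics without running simulations.  The geometry mirrors
#' [initialize_simulation()]: border frame, fibrin block, a single
#' monolayer cell band, medium above.
#'
#' @param width,height Lattice dimensions in sites.
#' @param fibrin_height Height of the fibrin block in sites.
#' @param sprouts Optional data frame with columns `col_start`, `width`
#'   and `depth`: each sprout is a cell-filled column of the given width
#'   descending `depth` sites from the fibrin surface.  Overlapping
#'   sprouts are an error.
#' @param lowered_by Lower the complete monolayer into the fibrin by this
#'   many sites (full-width cell band).
#' @return A [lattice_state()] with attributes `fibrin_rows` and
#'   `initial_fibrin` matching the pre-carving fibrin block.
#' @export
make_fixture <- function(width = 102, height = 62, fibrin_height = 40,
                         sprouts = NULL, lowered_by = 0) {
  MED <- 1L; BOR <- 2L; FIB <- 3L; MONO <- 4L
  mono_h <- 10L
  stopifnot(fibrin_height + mono_h + 2 < height)
  sigma <- matrix(MED, nrow = height, ncol = width)
  sigma[c(1, height), ] <- BOR
  sigma[, c(1, width)] <- BOR
  fib_rows <- 2:(fibrin_height + 1)
  sigma[fib_rows, 2:(width - 1)] <- FIB
  mono_rows <- (fibrin_height + 2):(fibrin_height + 1 + mono_h)
  sigma[mono_rows, 2:(width - 1)] <- MONO
  type <- c("medium", "border", "fibrin", "cell")
  if (lowered_by > 0) {
    low_rows <- (fibrin_height + 1 - lowered_by + 1):(fibrin_height + 1)
    sigma[low_rows, 2:(width - 1)] <- MONO
  }
  if (!is.null(sprouts) && nrow(sprouts) > 0) {
    occ <- integer(0)
    for (i in seq_len(nrow(sprouts))) {
      cols <- sprouts$col_start[i]:(sprouts$col_start[i] + sprouts$width[i] - 1)
      if (any(cols %in% occ) || min(cols) < 2 || max(cols) > width - 1)
        stop("overlapping or out-of-bounds sprout specification")
      occ <- c(occ, cols)
      rows <- (fibrin_height + 1 - sprouts$depth[i] + 1):(fibrin_height + 1)
      id <- 4L + i
      sigma[rows, cols] <- id
      type <- c(type, "cell")
    }
  }
  state <- lattice_state(sigma, type)
  fib_mask <- matrix(FALSE, height, width)
  fib_mask[fib_rows, 2:(width - 1)] <- TRUE
  attr(state, "fibrin_rows") <- fib_rows
  attr(state, "initial_fibrin") <- fib_mask
  state
}

#' Monolayer descent into the fibrin block
#'
#' Median, over interior columns, of how many sites the fibrin surface has
#' receded below its initial height.  Distinguishes uniform lowering of
#' the complete monolayer (large median descent) from localized sprouting
#' (descent near zero away from sprouts): the scan-line angiogenesis level
#' alone cannot separate the two on narrow lattices, where residual fibrin
#' septa keep full-width components from forming.
#'
#' @inheritParams angiogenesis_level
#' @return Median per-column descent in sites (>= 0).
#' @export
monolayer_descent <- function(state, fibrin_rows) {
  site_type <- matrix(state$type[state$sigma], nrow = nrow(state$sigma))
  surf <- max(fibrin_rows)
  n_fib_rows <- length(fibrin_rows)
  cols <- which(site_type[surf, ] != TYPE_CODES[["border"]])
  descent <- vapply(cols, function(cl) {
    fib <- which(site_type[fibrin_rows, cl] == TYPE_CODES[["fibrin"]])
    if (length(fib) == 0) n_fib_rows else n_fib_rows - max(fib)
  }, numeric(1))
  stats::median(descent)
}
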