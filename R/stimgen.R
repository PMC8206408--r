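#' Binary visual stimulation sequences
#'
#' A `stim_sequence` is a binary pixel movie at 1 ms resolution, stored
#' compactly as a matrix of distinct spatial patterns plus a schedule of
#' trial blocks. Every trial block lasts `on_ms + off_ms` milliseconds: the
#' block's pattern is shown (pixels at 1) during the first `on_ms` ms and
#' the screen is dark (all 0) for the remaining `off_ms` ms. The dense
#' frame matrix is materialized on demand with [stim_frames()]; per-bin mean
#' pixel intensities with [stim_intensity()].
#'
#' @param patterns integer 0/1 matrix, one row per distinct spatial pattern,
#'   one column per pixel (row-major pixel order: top-left to bottom-right).
#' @param pattern_ids integer vector: the pattern shown in each consecutive
#'   trial block.
#' @param grid `c(rows, cols)` of the pixel grid.
#' @param on_ms,off_ms ON and OFF durations of every trial block, ms.
#'
#' @return An object of class `stim_sequence` with fields `patterns`,
#'   `markers` (data.frame `trial`, `pattern`, `rep`, `onset_ms`), `grid`,
#'   `on_ms`, `off_ms`, `trial_len_ms`, `total_ms`.
#' @export
stim_sequence <- function(patterns, pattern_ids, grid, on_ms, off_ms) {
  patterns <- as.matrix(patterns)
  storage.mode(patterns) <- "integer"
  if (!all(patterns %in% c(0L, 1L))) {
    stop("`patterns` must be binary (0/1)", call. = FALSE)
  }
  if (prod(grid) != ncol(patterns)) {
    stop("ncol(patterns) must equal prod(grid)", call. = FALSE)
  }
  check_positive(on_ms, "on_ms")
  check_positive(off_ms, "off_ms")
  pattern_ids <- as.integer(pattern_ids)
  if (any(pattern_ids < 1L | pattern_ids > nrow(patterns))) {
    stop("`pattern_ids` out of range", call. = FALSE)
  }
  trial_len <- on_ms + off_ms
  n_tr <- length(pattern_ids)
  markers <- data.frame(
    trial = seq_len(n_tr),
    pattern = pattern_ids,
    rep = stats::ave(rep(1L, n_tr), pattern_ids, FUN = seq_along),
    onset_ms = (seq_len(n_tr) - 1L) * trial_len
  )
  structure(
    list(
      patterns = patterns, markers = markers,
      grid = as.integer(grid), on_ms = on_ms, off_ms = off_ms,
      trial_len_ms = trial_len, total_ms = n_tr * trial_len
    ),
    class = "stim_sequence"
  )
}

#' @export
print.stim_sequence <- function(x, ...) {
  cat(sprintf(
    "stim_sequence: %d x %d grid, %d distinct pattern(s), %d trial blocks\n",
    x$grid[1], x$grid[2], nrow(x$patterns), nrow(x$markers)
  ))
  cat(sprintf(
    "  %d ms ON / %d ms OFF per block; total duration %d ms\n",
    x$on_ms, x$off_ms, x$total_ms
  ))
  invisible(x)
}

#' Materialize the dense binary frame matrix of a stimulus
#'
#' @param stim a [stim_sequence()].
#' @param from_ms,to_ms half-open window `[from_ms, to_ms)` on the 0-based
#'   millisecond axis; defaults to the whole sequence.
#' @return integer 0/1 matrix, one row per millisecond, one column per pixel.
#' @export
stim_frames <- function(stim, from_ms = 0, to_ms = stim$total_ms) {
  stopifnot(inherits(stim, "stim_sequence"))
  if (to_ms <= from_ms || from_ms < 0 || to_ms > stim$total_ms) {
    stop("invalid [from_ms, to_ms) window", call. = FALSE)
  }
  t <- seq.int(from_ms, to_ms - 1L)
  trial <- t %/% stim$trial_len_ms + 1L
  on <- (t %% stim$trial_len_ms) < stim$on_ms
  out <- stim$patterns[stim$markers$pattern[trial], , drop = FALSE]
  out[!on, ] <- 0L
  rownames(out) <- NULL
  out
}

#' Mean pixel intensity per firing-rate bin
#'
#' Averages the 1 ms binary frames inside each bin of width `w_ms`; bin `k`
#' covers milliseconds `[(k-1)w, kw)`. A trailing partial bin is dropped.
#' This is the stimulus representation used by the encoder models when the
#' firing rate is binned at `w_ms`.
#'
#' @inheritParams stim_frames
#' @param w_ms bin width in ms.
#' @return numeric matrix (`n_bins` x `P`) with entries in `[0, 1]`.
#' @export
stim_intensity <- function(stim, w_ms) {
  stopifnot(inherits(stim, "stim_sequence"))
  w_ms <- check_count(w_ms, "w_ms")
  n_bins <- stim$total_ms %/% w_ms
  if (n_bins < 1L) stop("sequence shorter than one bin", call. = FALSE)
  t <- seq.int(0L, n_bins * w_ms - 1L)
  trial <- t %/% stim$trial_len_ms + 1L
  on <- (t %% stim$trial_len_ms) < stim$on_ms
  pid <- stim$markers$pattern[trial]
  bin <- t %/% w_ms + 1L
  k <- nrow(stim$patterns)
  # ON-millisecond count of each (bin, pattern) cell, then mix the patterns
  cnt <- matrix(tabulate_on(bin, pid, on, n_bins, k), n_bins, k)
  (cnt %*% stim$patterns) / w_ms
}

# ON-ms counts per (bin, pattern) cell
tabulate_on <- function(bin, pid, on, n_bins, k) {
  idx <- ((pid - 1L) * n_bins + bin)[on]
  tabulate(idx, nbins = n_bins * k)
}

#' Single-pixel flicker protocol
#'
#' One pixel at a time is turned ON for `on_ms` and OFF for `off_ms`,
#' repeated `trials_per_pixel` times consecutively, then the next pixel in
#' row-major order (top-left to bottom-right) takes over.
#'
#' @param grid `c(rows, cols)` pixel grid (default 4 x 8).
#' @param on_ms,off_ms ON/OFF durations, ms.
#' @param trials_per_pixel consecutive flicker repetitions per pixel.
#' @return a [stim_sequence()] with `prod(grid) * trials_per_pixel` blocks.
#' @export
make_single_pixel <- function(grid = c(4, 8), on_ms = 200, off_ms = 300,
                              trials_per_pixel = 100) {
  p <- prod(check_count(grid[1], "grid rows"), check_count(grid[2], "grid cols"))
  trials_per_pixel <- check_count(trials_per_pixel, "trials_per_pixel")
  stim_sequence(diag(p), rep(seq_len(p), each = trials_per_pixel),
                grid, on_ms, off_ms)
}

#' Full-field flicker protocol
#'
#' The whole screen is turned ON for `on_ms` then OFF for `off_ms`,
#' `repeats` times. Used to identify responsive neurons and to align spike
#' trains with stimulus onset.
#'
#' @inheritParams make_single_pixel
#' @param repeats number of ON/OFF cycles.
#' @export
make_full_field <- function(on_ms = 200, off_ms = 300, repeats = 80,
                            grid = c(4, 8)) {
  repeats <- check_count(repeats, "repeats")
  stim_sequence(matrix(1L, 1, prod(grid)), rep(1L, repeats), grid, on_ms, off_ms)
}

#' Balanced random checkerboard protocol
#'
#' Generates `n_patterns` distinct patterns of `pixels_per_pattern`
#' simultaneously flickering pixels, balanced so every pixel appears in
#' exactly `n_patterns * pixels_per_pattern / P` patterns. The whole pattern
#' sequence is presented consecutively and repeated for `trials` passes.
#'
#' The balanced design is built by shuffling a pool that lists each pixel
#' exactly its quota of times, partitioning it into patterns, then repairing
#' within-pattern duplicates by pairwise swaps until all patterns hold
#' distinct pixels and no two patterns coincide.
#'
#' @inheritParams make_single_pixel
#' @param n_patterns distinct patterns per pass.
#' @param pixels_per_pattern simultaneously ON pixels per pattern.
#' @param trials number of passes through the pattern sequence.
#' @param seed RNG seed; the design is bit-reproducible under a fixed seed.
#' @export
make_checkerboard <- function(grid = c(4, 8), n_patterns = 32,
                              pixels_per_pattern = 4, trials = 100,
                              on_ms = 200, off_ms = 300, seed = 1) {
  p <- prod(grid)
  n_patterns <- check_count(n_patterns, "n_patterns")
  pixels_per_pattern <- check_count(pixels_per_pattern, "pixels_per_pattern")
  trials <- check_count(trials, "trials")
  if (pixels_per_pattern > p) {
    stop("pixels_per_pattern exceeds the number of pixels", call. = FALSE)
  }
  quota <- n_patterns * pixels_per_pattern / p
  if (quota != as.integer(quota)) {
    stop(sprintf(
      "balance infeasible: n_patterns * pixels_per_pattern = %d must be divisible by P = %d",
      n_patterns * pixels_per_pattern, p), call. = FALSE)
  }
  sets <- with_seed(seed, balanced_design(p, n_patterns, pixels_per_pattern))
  patterns <- matrix(0L, n_patterns, p)
  patterns[cbind(rep(seq_len(n_patterns), each = pixels_per_pattern), c(t(sets)))] <- 1L
  stim_sequence(patterns, rep(seq_len(n_patterns), trials), grid, on_ms, off_ms)
}

# Balanced incidence design: n_patterns rows of `size` distinct pixels, each
# pixel used exactly n_patterns*size/p times, all rows distinct as sets.
balanced_design <- function(p, n_patterns, size) {
  quota <- n_patterns * size / p
  for (attempt in 1:1000) {
    pool <- sample(rep.int(seq_len(p), quota))
    m <- matrix(pool, n_patterns, size, byrow = TRUE)
    ok <- TRUE
    # repair within-row duplicates by swapping with another row
    for (iter in 1:2000) {
      dup_rows <- which(apply(m, 1, anyDuplicated) > 0)
      if (!length(dup_rows)) break
      i <- dup_rows[1]
      di <- which(duplicated(m[i, ]))[1]
      val <- m[i, di]
      done <- FALSE
      for (j in sample(setdiff(seq_len(n_patterns), i))) {
        cand <- which(!(m[j, ] %in% m[i, ]))
        for (cj in cand) {
          if (!(val %in% m[j, -cj])) {
            tmp <- m[j, cj]; m[j, cj] <- val; m[i, di] <- tmp
            done <- TRUE; break
          }
        }
        if (done) break
      }
      if (!done) { ok <- FALSE; break }
    }
    if (!ok || any(apply(m, 1, anyDuplicated) > 0)) next
    keys <- apply(m, 1, function(r) paste(sort(r), collapse = ","))
    if (anyDuplicated(keys) && n_patterns > choose(p, size)) {
      stop("distinct patterns infeasible for these dimensions", call. = FALSE)
    }
    if (!anyDuplicated(keys)) {
      stopifnot(all(tabulate(m, p) == quota))
      return(m)
    }
  }
  stop("failed to construct a balanced checkerboard design", call. = FALSE)
}

#' Geometrical shape stimulation protocol
#'
#' Renders full-resolution binary shape patterns (rectangle, circle,
#' triangle, cross) at one of five canvas locations; each pattern flickers
#' 200 ms ON / 300 ms OFF by default and the whole sequence is repeated for
#' `trials` passes. Shapes occupy a bounding box of one quarter of the
#' canvas in each dimension. Project to the model's 4 x 8 space with
#' [project_to_grid()].
#'
#' @param canvas `c(rows, cols)` full-resolution canvas (default 900 x 1600).
#' @param shapes character vector of shapes sampled per pattern.
#' @param locations character vector of candidate locations: `"top-left"`,
#'   `"top-right"`, `"bottom-left"`, `"bottom-right"`, `"center"`.
#' @param n_patterns distinct patterns per pass.
#' @param trials passes through the pattern sequence.
#' @inheritParams make_checkerboard
#' @export
make_shapes <- function(canvas = c(900, 1600),
                        shapes = c("rectangle", "circle", "triangle", "cross"),
                        locations = c("top-left", "top-right", "bottom-left",
                                      "bottom-right", "center"),
                        n_patterns = 20, trials = 50,
                        on_ms = 200, off_ms = 300, seed = 1) {
  known <- c("rectangle", "circle", "triangle", "cross")
  if (!all(shapes %in% known)) {
    stop(sprintf("unknown shape(s): %s",
                 paste(setdiff(shapes, known), collapse = ", ")), call. = FALSE)
  }
  known_loc <- c("top-left", "top-right", "bottom-left", "bottom-right", "center")
  if (!all(locations %in% known_loc)) {
    stop("unknown location name", call. = FALSE)
  }
  n_patterns <- check_count(n_patterns, "n_patterns")
  trials <- check_count(trials, "trials")
  draw <- with_seed(seed, data.frame(
    shape = sample(shapes, n_patterns, replace = TRUE),
    loc = sample(locations, n_patterns, replace = TRUE)
  ))
  patterns <- matrix(0L, n_patterns, prod(canvas))
  for (i in seq_len(n_patterns)) {
    patterns[i, ] <- as.integer(render_shape(canvas, draw$shape[i], draw$loc[i]))
  }
  out <- stim_sequence(patterns, rep(seq_len(n_patterns), trials),
                       canvas, on_ms, off_ms)
  out$shape_table <- draw
  out
}

# Binary mask (vectorized row-major over the canvas) of one shape centred at
# the named location; bounding box is canvas/4 in each dimension.
render_shape <- function(canvas, shape, location) {
  nr <- canvas[1]; nc <- canvas[2]
  ctr <- switch(location,
    "top-left"     = c(nr / 4, nc / 4),
    "top-right"    = c(nr / 4, 3 * nc / 4),
    "bottom-left"  = c(3 * nr / 4, nc / 4),
    "bottom-right" = c(3 * nr / 4, 3 * nc / 4),
    "center"       = c(nr / 2, nc / 2)
  )
  hh <- nr / 8; hw <- nc / 8  # half-height/width of the bounding box
  r <- rep(seq_len(nr), times = nc)  # column-major index over matrix(nr, nc)
  c_ <- rep(seq_len(nc), each = nr)
  dr <- (r - ctr[1]) / hh
  dc <- (c_ - ctr[2]) / hw
  mask <- switch(shape,
    rectangle = abs(dr) <= 1 & abs(dc) <= 1,
    circle    = dr^2 + dc^2 <= 1,
    # upward-pointing isoceles triangle filling the box
    triangle  = dr <= 1 & dr >= -1 & abs(dc) <= (dr + 1) / 2,
    # plus sign with arm width one third of the box
    cross     = (abs(dr) <= 1 / 3 & abs(dc) <= 1) |
                (abs(dc) <= 1 / 3 & abs(dr) <= 1)
  )
  m <- matrix(mask, nr, nc)
  # row-major pixel order to match the stim_sequence convention
  as.vector(t(m))
}

#' Project a full-resolution stimulus onto a coarse pixel grid
#'
#' Each coarse cell takes the mean of its canvas block and is binarized at
#' `threshold` (cell is ON when the block mean is >= threshold). If the
#' canvas dimensions are not divisible by the grid, trailing rows/columns
#' are cropped. Temporal structure (markers, durations) is preserved.
#'
#' @param stim a full-resolution [stim_sequence()], or a plain matrix of
#'   frames (rows = frames, columns = row-major canvas pixels, `canvas`
#'   required).
#' @param grid target `c(rows, cols)` (default 4 x 8).
#' @param threshold binarization threshold on the block mean; the default
#'   0.25 lets a shape that only partially covers a coarse cell still drive
#'   it.
#' @param canvas canvas dimensions when `stim` is a plain matrix.
#' @export
project_to_grid <- function(stim, grid = c(4, 8), threshold = 0.25,
                            canvas = NULL) {
  if (inherits(stim, "stim_sequence")) {
    proj <- project_frames(stim$patterns, stim$grid, grid, threshold)
    out <- stim_sequence(proj, stim$markers$pattern, grid, stim$on_ms, stim$off_ms)
    out$shape_table <- stim$shape_table
    return(out)
  }
  if (is.null(canvas)) stop("`canvas` required for matrix input", call. = FALSE)
  project_frames(as.matrix(stim), canvas, grid, threshold)
}

project_frames <- function(frames, canvas, grid, threshold) {
  if (!nrow(frames) || !ncol(frames)) stop("empty frames", call. = FALSE)
  if (any(canvas < grid)) stop("canvas smaller than target grid", call. = FALSE)
  br <- canvas[1] %/% grid[1]; bc <- canvas[2] %/% grid[2]  # block size
  keep_r <- seq_len(br * grid[1]); keep_c <- seq_len(bc * grid[2])
  out <- matrix(0L, nrow(frames), prod(grid))
  for (i in seq_len(nrow(frames))) {
    m <- matrix(frames[i, ], canvas[1], canvas[2], byrow = TRUE)[keep_r, keep_c]
    # block means: average rows within row-blocks, then columns
    rb <- rowsum(m, rep(seq_len(grid[1]), each = br)) / br
    cb <- t(rowsum(t(rb), rep(seq_len(grid[2]), each = bc)) / bc)
    out[i, ] <- as.integer(as.vector(t(cb)) >= threshold)
  }
  out
}
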