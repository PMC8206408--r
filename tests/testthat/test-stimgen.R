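test_that("single-pixel protocol has the canonical structure", {
  s <- make_single_pixel()
  expect_equal(s$total_ms, 32 * 100 * 500)
  expect_equal(nrow(s$markers), 3200)
  expect_equal(s$trial_len_ms, 500)
  # pixels cycle row-major: first 100 blocks are pixel 1, next 100 pixel 2
  expect_equal(s$markers$pattern[1:200], rep(1:2, each = 100))
  # per-pixel total ON time identical (trials x 200 ms each): pattern matrix
  # is the identity, so each pixel is ON in exactly trials_per_pixel blocks
  blocks_per_pixel <- table(s$markers$pattern)
  expect_true(all(blocks_per_pixel == 100))

  tiny <- make_single_pixel(grid = c(1, 1), trials_per_pixel = 1)
  fr <- stim_frames(tiny)
  expect_equal(nrow(fr), 500)
  expect_equal(mean(fr), 0.4)           # ON fraction exactly 200/500
})

test_that("single-pixel frames light at most one pixel and only during ON", {
  s <- make_single_pixel(grid = c(2, 3), trials_per_pixel = 2)
  fr <- stim_frames(s)
  expect_true(all(fr %in% c(0L, 1L)))
  expect_true(all(rowSums(fr) <= 1))
  # within a trial each pixel is constant during ON and zero during OFF
  tr1 <- fr[1:500, ]
  expect_true(all(tr1[1:200, 1] == 1))
  expect_true(all(tr1[201:500, ] == 0))
  # per-pixel ON totals equal across pixels
  expect_true(all(colSums(fr) == 2 * 200))
})

test_that("checkerboard generator is balanced, distinct and reproducible", {
  s <- make_checkerboard(trials = 2, seed = 4)
  expect_equal(nrow(s$patterns), 32)
  expect_true(all(rowSums(s$patterns) == 4))       # 4 pixels per pattern
  expect_true(all(colSums(s$patterns) == 4))       # each pixel in 4 patterns
  keys <- apply(s$patterns, 1, paste, collapse = "")
  expect_equal(anyDuplicated(keys), 0L)            # 32 distinct patterns
  s2 <- make_checkerboard(trials = 2, seed = 4)
  expect_identical(s$patterns, s2$patterns)        # bit-reproducible
  s3 <- make_checkerboard(trials = 2, seed = 5)
  expect_false(identical(s$patterns, s3$patterns))

  # forced full-field case
  ff <- make_checkerboard(grid = c(2, 2), n_patterns = 1,
                          pixels_per_pattern = 4, trials = 1, seed = 1)
  expect_true(all(ff$patterns == 1L))

  # balance infeasible: error names the constraint
  expect_error(make_checkerboard(n_patterns = 10, pixels_per_pattern = 4),
               "divisible")
})

test_that("checkerboard balance holds for other feasible geometries", {
  for (cfg in list(c(16, 8), c(8, 8), c(64, 2))) {
    s <- make_checkerboard(n_patterns = cfg[1], pixels_per_pattern = cfg[2],
                           trials = 1, seed = 3)
    expect_true(all(colSums(s$patterns) == cfg[1] * cfg[2] / 32))
    expect_equal(anyDuplicated(apply(s$patterns, 1, paste, collapse = "")), 0L)
  }
})

test_that("full-field protocol matches its stated counts", {
  s <- make_full_field()
  expect_equal(nrow(s$markers), 80)
  expect_equal(s$total_ms, 40000)
  one <- make_full_field(repeats = 1)
  expect_equal(one$total_ms, 500)
  fr <- stim_frames(one)
  expect_equal(mean(fr), 0.4)
  # all pixels identical in every frame
  expect_true(all(apply(fr, 1, function(r) length(unique(r)) == 1)))
})

test_that("shapes protocol renders, errors on unknown names, projects", {
  s <- make_shapes(canvas = c(60, 120), n_patterns = 20, trials = 50, seed = 2)
  expect_equal(nrow(s$markers), 1000)              # 20 patterns x 50 trials
  expect_equal(nrow(s$patterns), 20)
  expect_error(make_shapes(shapes = c("hexagon")), "unknown shape")
  expect_error(make_shapes(locations = "middle"), "location")

  # circle at center: projected 4x8 frame peaks at the two center columns
  circ <- make_shapes(canvas = c(80, 160), shapes = "circle",
                      locations = "center", n_patterns = 1, trials = 1,
                      seed = 1)
  proj <- project_to_grid(circ)
  m <- matrix(proj$patterns[1, ], 4, 8, byrow = TRUE)
  lit_cols <- which(colSums(m) > 0)
  expect_true(all(lit_cols %in% 4:5))
  expect_true(length(lit_cols) >= 1)
})

test_that("projection block-means and binarizes correctly", {
  # all-ones canvas -> all ones for any threshold < 1
  ones <- matrix(1, 1, 80 * 160)
  expect_true(all(project_to_grid(ones, canvas = c(80, 160),
                                  threshold = 0.99) == 1L))
  zeros <- matrix(0, 1, 80 * 160)
  expect_true(all(project_to_grid(zeros, canvas = c(80, 160)) == 0L))

  # one cell exactly half covered: block mean 0.5 vs threshold
  cv <- matrix(0L, 8, 16)       # 2x2 blocks for a 4x8 grid
  cv[1:2, 1] <- 1L              # half of the top-left 2x2 block
  fr <- matrix(as.integer(as.vector(t(cv))), 1)
  lo <- project_to_grid(fr, canvas = c(8, 16), threshold = 0.25)
  hi <- project_to_grid(fr, canvas = c(8, 16), threshold = 0.75)
  expect_equal(lo[1, 1], 1L)
  expect_equal(hi[1, 1], 0L)

  expect_error(project_to_grid(matrix(numeric(0), 0, 0), canvas = c(1, 1)),
               "empty")
})

test_that("stimulus fundamental frequency is 1000/(on+off) Hz", {
  s <- make_full_field(repeats = 40)
  fr <- stim_frames(s)
  spec <- rate_psd(as.numeric(fr[, 1]), fs_hz = 1000)
  expect_equal(spec$freq_hz[which.max(spec$psd)], 2)
  s2 <- make_full_field(on_ms = 100, off_ms = 150, repeats = 40)
  spec2 <- rate_psd(as.numeric(stim_frames(s2)[, 1]), fs_hz = 1000)
  expect_equal(spec2$freq_hz[which.max(spec2$psd)], 4)
})

test_that("binned intensity equals frame block means", {
  s <- make_checkerboard(n_patterns = 8, pixels_per_pattern = 4,
                         trials = 2, seed = 9)
  si <- stim_intensity(s, 50)
  fr <- stim_frames(s)
  man <- rowsum(fr[seq_len(nrow(si) * 50), ],
                rep(seq_len(nrow(si)), each = 50)) / 50
  expect_equal(unname(si), unname(man))
  # w = 30 does not divide the trial length: still exact block means
  si30 <- stim_intensity(s, 30)
  man30 <- rowsum(fr[seq_len(nrow(si30) * 30), ],
                  rep(seq_len(nrow(si30)), each = 30)) / 30
  expect_equal(unname(si30), unname(man30))
})

test_that("parameter validation rejects bad inputs", {
  expect_error(make_single_pixel(on_ms = -5), "on_ms")
  expect_error(make_single_pixel(trials_per_pixel = 0), "trials_per_pixel")
  expect_error(stim_sequence(matrix(2, 1, 4), 1, c(2, 2), 200, 300), "binary")
  expect_error(stim_frames(make_full_field(repeats = 1), 0, 600), "window")
})
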