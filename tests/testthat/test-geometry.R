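# Geometry rasterization, appendage bookkeeping and the synthetic cohort.

test_that("rectangular channel rasterizes to the expected fluid count", {
  # hand-rasterized toy: 8 x 4 cells of 1 mm in an 8 x 4 mm channel
  g <- build_geometry(geometry_spec(
    channel_length = 0.008, channel_height = 0.004, pouch_depth = 0,
    n_inlets = 1, inlet_widths = 0.004 - 1e-9,
    outlet_extension_length = 0, h = 0.001))
  expect_equal(sum(g$lab == 1L), 8 * 4)
  expect_equal(sum(g$laa), 0)            # no pouch, no appendage
  expect_equal(laa_area(g), 0)
})

test_that("pouch membership and area follow the neck-plane convention", {
  spec <- test_geometry()
  g <- build_geometry(spec)
  # straight rectangular pouch: area within one cell layer of depth*width
  a <- laa_area(g)
  a0 <- spec$pouch_depth * spec$pouch_neck_width
  per <- 2 * (spec$pouch_depth + spec$pouch_neck_width)
  expect_lt(abs(a - a0), g$h * per)
  # appendage cells are fluid cells strictly below the channel floor
  expect_true(all(g$lab[g$laa] == 1L))
  yc <- matrix(g$yc, g$nx, g$ny, byrow = TRUE)
  expect_true(all(yc[g$laa] < 0))
  # arithmetic: area = h^2 * cell count
  expect_equal(a, g$h^2 * sum(g$laa))
})

test_that("multi-lobe pouches form one connected component per lobe", {
  skip_if_not_installed("igraph")
  g <- build_geometry(test_geometry(n_lobes = 2L, pouch_neck_width = 0.005,
                                    channel_length = 0.04))
  idx <- which(g$laa, arr.ind = TRUE)
  key <- paste(idx[, 1], idx[, 2])
  edges <- integer(0)
  for (r in seq_len(nrow(idx))) {
    for (d in list(c(1, 0), c(0, 1))) {
      nb <- paste(idx[r, 1] + d[1], idx[r, 2] + d[2])
      j <- match(nb, key)
      if (!is.na(j)) edges <- c(edges, r, j)
    }
  }
  gr <- igraph::make_graph(edges, n = nrow(idx), directed = FALSE)
  expect_equal(igraph::count_components(gr), 2)
})

test_that("rasterization is resolution-consistent", {
  spec <- test_geometry(pouch_bend_angle = 25)
  a1 <- laa_area(build_geometry(spec))
  spec$h <- spec$h / 2
  a2 <- laa_area(build_geometry(spec))
  per <- 2 * (spec$pouch_depth + spec$pouch_neck_width)
  expect_lt(abs(a1 - a2), 2 * (2 * spec$h) * per)
})

test_that("unresolved necks are rejected", {
  expect_error(geometry_spec(pouch_neck_width = 0.002, h = 0.001),
               "fewer than 4 cells")
})

test_that("Teichholz cardiac output matches hand evaluation", {
  teich <- function(d) 7.0 * d^3 / (2.4 + d)       # independent oracle
  co <- (teich(5) - teich(3)) * 60 / 1000
  expect_equal(teichholz_cardiac_output(5, 3, 60), co, tolerance = 1e-12)
  expect_equal(co, 4.99, tolerance = 0.001)
  # linear in heart rate
  expect_equal(teichholz_cardiac_output(5, 3, 120),
               2 * teichholz_cardiac_output(5, 3, 60))
  expect_error(teichholz_cardiac_output(4, 4, 60), "ESD")
})

test_that("cohort generation is reproducible and respects the bounds", {
  c1 <- generate_cohort(25, seed = 42)
  c2 <- generate_cohort(25, seed = 42)
  expect_identical(cohort_table(c1), cohort_table(c2))
  big <- cohort_table(generate_cohort(1000, seed = 3))
  expect_true(all(big$co >= 1.9 & big$co <= 6.8))
  expect_true(all(big$hr >= 44 & big$hr <= 84))
  expect_true(all(big$hct >= 0.35 & big$hct <= 0.49))
  r <- cohort_ranges()
  expect_true(all(big$pouch_depth >= r$pouch_depth[1] &
                    big$pouch_depth <= r$pouch_depth[2]))
})

test_that("appendage mask never overlaps boundary cells", {
  for (s in generate_cohort(5, seed = 11)) {
    g <- build_geometry(s$geometry)
    expect_true(all(g$lab[g$laa] == 1L))
  }
})
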