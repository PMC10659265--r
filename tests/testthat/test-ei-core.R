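test_that("compute_ei averages spike windows and drops edge spikes", {
  arr <- hex_array(1, 30)
  N <- arr$n
  tmpl <- matrix(sin(seq(0, 4 * pi, length.out = 18 * N)), 18, N)

  # single spike: EI equals the cropped window exactly
  raw <- matrix(0, 100, N)
  raw[41:58, ] <- tmpl
  ei <- compute_ei(raw, spike_train(46), arr, pre = 6L, post = 12L)
  expect_equal(ei$data, tmpl)
  expect_identical(ei$n_spikes, 1L)

  # two spikes whose windows are identical copies
  raw2 <- matrix(0, 200, N)
  raw2[41:58, ] <- tmpl
  raw2[141:158, ] <- tmpl
  ei2 <- compute_ei(raw2, spike_train(c(46, 146)), arr, pre = 6L, post = 12L)
  expect_equal(ei2$data, tmpl)
  expect_identical(ei2$n_spikes, 2L)

  # edge spikes are dropped, not padded
  ei3 <- compute_ei(raw2, spike_train(c(3, 46, 146, 199)), arr,
                    pre = 6L, post = 12L)
  expect_identical(ei3$n_spikes, 2L)
  expect_equal(ei3$data, tmpl)

  expect_error(compute_ei(raw, spike_train(2), arr, pre = 6L, post = 12L),
               "empty EI")
  expect_error(spike_train(c(10, 5)), "increasing")
  expect_error(spike_train(c(-1, 5)), "nonnegative")
})

test_that("EI noise averages down as 1/sqrt(n_spikes)", {
  set.seed(11)
  arr <- hex_array(1, 30)
  N <- arr$n
  T <- 18L
  tmpl <- matrix(rnorm(T * N), T, N)
  n_spk <- 50L
  times <- seq(20, by = 40, length.out = n_spk)
  raw <- matrix(rnorm((max(times) + 20) * N, 0, 1), max(times) + 20, N)
  for (t0 in times) raw[(t0 - 5):(t0 + 12), ] <- raw[(t0 - 5):(t0 + 12), ] + tmpl
  ei <- compute_ei(raw, spike_train(times), arr, pre = 6L, post = 12L)
  dev <- ei$data - tmpl
  expect_equal(sd(dev), 1 / sqrt(n_spk), tolerance = 0.15)
})

test_that("compute_ei is linear in the raw data", {
  set.seed(2)
  arr <- hex_array(1, 30)
  raw1 <- matrix(rnorm(300 * arr$n), 300)
  raw2 <- matrix(rnorm(300 * arr$n), 300)
  st <- spike_train(c(50, 120, 260))
  e1 <- compute_ei(raw1, st, arr, 10L, 20L)$data
  e2 <- compute_ei(raw2, st, arr, 10L, 20L)$data
  e12 <- compute_ei(2 * raw1 - 3 * raw2, st, arr, 10L, 20L)$data
  expect_equal(e12, 2 * e1 - 3 * e2)
})

test_that("subsample_spikes is uniform, sorted and deterministic", {
  st <- spike_train(sort(sample.int(1e6, 40)))
  expect_identical(subsample_spikes(st, 40, seed = 3)$spike_times,
                   st$spike_times)
  s1 <- subsample_spikes(st, 1, seed = 9)
  s2 <- subsample_spikes(st, 1, seed = 9)
  expect_identical(s1$spike_times, s2$spike_times)
  expect_error(subsample_spikes(st, 41), "more spikes")

  # each spike retained with frequency ~ 1/2 at k = n/2
  hits <- numeric(40)
  for (s in 1:400) {
    kept <- subsample_spikes(st, 20, seed = s)$spike_times
    hits <- hits + st$spike_times %in% kept
  }
  expect_true(all(abs(hits / 400 - 0.5) < 0.12))
  expect_false(is.unsorted(subsample_spikes(st, 17, seed = 1)$spike_times))
})

test_that("neighbor_indices matches lattice geometry and brute force", {
  arr <- hex_array(3, 30)
  ctr <- which.min(rowSums(arr$positions^2))
  nb <- neighbor_indices(arr, ctr, 6L)
  d <- sqrt(colSums((t(arr$positions[nb, ]) - arr$positions[ctr, ])^2))
  expect_equal(d, rep(30, 6), tolerance = 1e-9)

  # corner electrode still returns 6 nearest, some farther than pitch
  corner <- which.max(rowSums(arr$positions^2))
  nbc <- neighbor_indices(arr, corner, 6L)
  expect_length(nbc, 6L)

  # arbitrary point set vs exhaustive sort
  set.seed(5)
  pts <- matrix(runif(40, 0, 500), 20, 2)
  a2 <- electrode_array(pts, 50)
  for (e in c(1, 7, 20)) {
    d <- sqrt(colSums((t(a2$positions) - a2$positions[e, ])^2))
    d[e] <- Inf
    expect_identical(neighbor_indices(a2, e, 5L), order(d)[1:5])
  }
  expect_error(neighbor_indices(a2, 1, 20L), "smaller")
})

test_that("hex arrays satisfy the interior-neighbor invariant", {
  arr <- hex_array(4, 30)
  interior <- which(sqrt(rowSums(arr$positions^2)) < 3 * 30 + 1)
  for (e in interior) {
    nb <- neighbor_indices(arr, e, 6L)
    d <- sqrt(colSums((t(arr$positions[nb, ]) - arr$positions[e, ])^2))
    expect_true(all(abs(d - 30) <= 0.01 * 30))
  }
})

test_that("EI containers round-trip bit-exactly", {
  set.seed(8)
  arr <- hex_array(2, 30)
  ei <- electrical_image(matrix(rnorm(60 * arr$n), 60), arr,
                         sampling_rate = 20000, pre_samples = 20L,
                         n_spikes = 123L)
  path <- tempfile(fileext = ".json")
  write_ei(ei, path)
  back <- read_ei(path)
  expect_identical(back$data, ei$data)
  expect_identical(back$array$positions, ei$array$positions)
  expect_identical(back$sampling_rate, ei$sampling_rate)
  expect_identical(back$pre_samples, ei$pre_samples)
  expect_identical(back$n_spikes, ei$n_spikes)
  expect_identical(back$array$layout_tag, "custom")

  # named tag is preserved
  arr519 <- electrode_array(arr$positions, 30, "hex519_30um")
  ei2 <- electrical_image(ei$data, arr519, pre_samples = 20L)
  write_ei(ei2, path)
  expect_identical(read_ei(path)$array$layout_tag, "hex519_30um")

  # corrupted containers fail loudly
  jsonlite::write_json(list(cells = list(cell = list(
    ei = list(data = matrix(0, 3, 3))))), path, auto_unbox = TRUE)
  expect_error(read_ei(path), "geometry")
})

test_that("electrode maps round-trip through CSV", {
  arr <- hex_array(2, 30)
  path <- tempfile(fileext = ".csv")
  write_electrode_map(arr, path)
  back <- read_electrode_map(path)
  expect_equal(back$positions, arr$positions, tolerance = 1e-12)
  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(x = 1:3, y = 1:3), bad, row.names = FALSE)
  expect_error(read_electrode_map(bad), "columns")
})
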