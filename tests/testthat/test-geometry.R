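test_that("helmet construction yields triplet sites outside the head", {
  sph <- head_sphere()
  arr <- build_helmet_array(102, sph, shell_offset = 20)
  expect_equal(arr$M, 306)
  expect_equal(nrow(arr$site_positions), 102)
  # every site: exactly one magnetometer and two orthogonal gradiometers
  for (s in c(1, 50, 102)) {
    rows <- which(arr$site_index == s)
    expect_setequal(arr$channel_types[rows],
                    c("magnetometer", "planar_grad_1", "planar_grad_2"))
    b1 <- arr$baseline_dirs[rows[arr$channel_types[rows] == "planar_grad_1"], ]
    b2 <- arr$baseline_dirs[rows[arr$channel_types[rows] == "planar_grad_2"], ]
    expect_lt(abs(sum(b1 * b2)), 1e-12)
  }
  # all orientation vectors unit norm
  expect_true(all(abs(sqrt(rowSums(arr$channel_orientations^2)) - 1) < 1e-12))
  # all channels strictly outside the head sphere
  d <- sqrt(rowSums(sweep(arr$channel_positions, 2, sph$center)^2))
  expect_true(all(d > sph$radius))
  # deterministic for fixed inputs
  arr2 <- build_helmet_array(102, sph, shell_offset = 20)
  expect_identical(arr, arr2)
  # small arrays still carry triplets
  arr8 <- build_helmet_array(8, sph)
  expect_equal(arr8$M, 24)
  expect_error(build_helmet_array(102, sph, shell_offset = 0), "positive")
  expect_error(build_helmet_array(4, sph), "8")
})

test_that("region partition is a true partition with eight nonempty regions", {
  sc <- get_scene("small")
  part <- sc$partition
  expect_equal(part$C, 8)
  expect_equal(length(part$counts), 8)
  expect_true(all(part$counts > 0))
  expect_equal(sum(part$counts), sc$array$M)
  expect_false(anyNA(part$labels))
  # all three channels of a site share one label
  lab_by_site <- split(as.character(part$labels), sc$array$site_index)
  expect_true(all(vapply(lab_by_site, function(v) length(unique(v)) == 1,
                         logical(1))))
})

test_that("a strongly anterior left site is labeled frontal-L", {
  sph <- head_sphere(c(0, 0, 0), 75)
  arr <- build_helmet_array(102, sph)
  # plant the queried position as a site by overriding site 1
  arr$site_positions[1, ] <- c(-60, 70, 30)
  part <- partition_regions(arr, sph)
  expect_equal(as.character(part$site_labels[1]), "frontal-L")
})

test_that("mirroring through the mid-sagittal plane swaps L/R labels", {
  sc <- get_scene("small")
  part <- partition_regions(sc$array)
  mirrored <- sc$array
  mirrored$site_positions[, 1] <-
    2 * sc$sphere$center[1] - mirrored$site_positions[, 1]
  mirrored$channel_positions[, 1] <-
    2 * sc$sphere$center[1] - mirrored$channel_positions[, 1]
  part_m <- partition_regions(mirrored, sc$sphere)
  swap <- function(lab) {
    out <- sub("-L$", "-X", lab)
    out <- sub("-R$", "-L", out)
    sub("-X$", "-R", out)
  }
  expect_equal(as.character(part_m$site_labels),
               swap(as.character(part$site_labels)))
})

test_that("source grid is an interior lattice ordered lexicographically", {
  sph <- head_sphere(c(0, 0, 40), 75)
  g <- build_source_grid(sph, spacing = 10, interior_margin = 10)
  d <- sqrt(rowSums(sweep(g$points, 2, sph$center)^2))
  expect_true(all(d <= sph$radius - 10 + 1e-9))
  expect_equal(g$P, nrow(g$points))
  # lexicographic order in (x, y, z)
  o <- order(g$points[, 1], g$points[, 2], g$points[, 3])
  expect_equal(o, seq_len(g$P))
  # halving spacing increases the point count (enumeration comparison)
  g2 <- build_source_grid(sph, spacing = 5, interior_margin = 10)
  expect_gt(g2$P, g$P)
  expect_error(build_source_grid(sph, spacing = 10, interior_margin = 80),
               "empty")
})

test_that("very coarse grid matches exhaustive lattice enumeration", {
  sph <- head_sphere(c(0, 0, 0), 50)
  spacing <- 1.9 * sph$radius
  g <- build_source_grid(sph, spacing = spacing, interior_margin = 0)
  # oracle: exhaustive loop over lattice offsets within the sphere
  count <- 0L
  for (ix in -2:2) for (iy in -2:2) for (iz in -2:2) {
    p <- c(ix, iy, iz) * spacing
    if (sqrt(sum(p^2)) <= sph$radius) count <- count + 1L
  }
  expect_equal(g$P, count)
  expect_gte(g$P, 1)
  expect_lte(g$P, 8)
})

test_that("grid subsampling matches brute-force enumeration", {
  # the published protocol's count
  expect_length(subsample_grid(list(P = 3704), 12), 309)
  expect_equal(subsample_grid(list(P = 10), 1), 1:10)
  expect_equal(subsample_grid(list(P = 100), 12), seq(1, 97, by = 12))
  expect_error(subsample_grid(list(P = 10), 0), "positive")
  # property: count equals floor((P-1)/step)+1 against a brute-force loop
  set.seed(11)
  for (i in 1:50) {
    P <- sample(1:10000, 1); step <- sample(1:50, 1)
    idx <- subsample_grid(list(P = P), step)
    brute <- 0L; j <- 0L
    while (j < P) { brute <- brute + 1L; j <- j + step }
    expect_length(idx, brute)
    expect_length(idx, floor((P - 1) / step) + 1)
  }
})

test_that("sensor layout round-trips through CSV", {
  sc <- get_scene("small")
  f <- tempfile(fileext = ".csv")
  write_sensor_layout(sc$array, f, sc$partition)
  arr2 <- read_sensor_layout(f, sc$sphere)
  expect_equal(arr2$M, sc$array$M)
  expect_equal(arr2$channel_positions, sc$array$channel_positions,
               tolerance = 1e-12)
  expect_equal(arr2$channel_orientations, sc$array$channel_orientations,
               tolerance = 1e-12)
  expect_equal(arr2$channel_types, sc$array$channel_types)
  unlink(f)
})
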