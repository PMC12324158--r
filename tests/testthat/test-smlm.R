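loc_table <- function(x, y, channel) {
  structure(data.frame(frame = seq_along(x), x_nm = x, y_nm = y,
                       channel = channel,
                       uncertainty_nm = rep(10, length(x)),
                       true_cluster = rep(-1L, length(x))),
            class = c("localization_table", "data.frame"))
}

test_that("localization CSV round-trips, including extra columns", {
  cfg <- point_sim_config(n_hetero = 4, molecules_per_cluster = 25,
                          background_density = 1, seed = 12)
  tab <- simulate_localizations(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_localizations(tab, path)
  back <- read_localizations(path)
  expect_equal(back$x_nm, tab$x_nm)
  expect_equal(back$channel, tab$channel)
  expect_equal(back$true_cluster, tab$true_cluster)
  expect_true("true_x_nm" %in% names(back))  # unknown columns preserved
})

test_that("micron-dialect headers are converted to nm", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c('"frame","x [um]","y [um]","channel","uncertainty [nm]"',
               '1,1.5,2,"red",10', '2,0.03,0.04,"green",12'), path)
  tab <- read_localizations(path)
  expect_equal(tab$x_nm, c(1500, 30))
  expect_equal(tab$y_nm, c(2000, 40))
  expect_equal(tab$uncertainty_nm, c(10, 12))
})

test_that("empty files parse and missing columns are named in errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("frame,x_nm,y_nm,channel,uncertainty_nm", path)
  expect_equal(nrow(read_localizations(path)), 0)
  writeLines("frame,x_nm,channel", path)
  expect_error(read_localizations(path), "y_nm.*uncertainty_nm")
})

test_that("NND handles coincident points and the 3-4-5 triangle", {
  tab <- loc_table(c(0, 0), c(0, 0), c("red", "green"))
  expect_equal(cross_channel_nnd(tab, "red", "green")$distances, 0)
  tab2 <- loc_table(c(0, 30), c(0, 40), c("red", "green"))
  expect_equal(cross_channel_nnd(tab2, "red", "green")$distances, 50)
  expect_error(cross_channel_nnd(loc_table(1, 1, "red"), "red", "green"),
               "empty")
})

test_that("NND equals the exhaustive pairwise oracle in both directions", {
  for (s in 1:12) {
    set.seed(s)
    n <- sample(50:200, 1)
    tab <- loc_table(runif(n, 0, 2000), runif(n, 0, 2000),
                     sample(c("red", "green"), n, replace = TRUE))
    for (dir in list(c("red", "green"), c("green", "red"),
                     c("red", "red"))) {
      q <- tab[tab$channel == dir[1], ]
      r <- tab[tab$channel == dir[2], ]
      if (nrow(q) == 0 || nrow(r) < 2) next
      got <- cross_channel_nnd(tab, dir[1], dir[2])$distances
      want <- oracle_nnd(q$x_nm, q$y_nm, r$x_nm, r$y_nm,
                         exclude_self = dir[1] == dir[2])
      expect_equal(got, unname(want), tolerance = 0)
    }
  }
})

test_that("NND distributions bin left-closed and summarize consistently", {
  d <- rep(17, 40)
  s <- nnd_distribution(d, bin_width = 5)
  expect_equal(sum(s$counts > 0), 1)
  expect_equal(s$modal_bin, c(15, 20))
  expect_equal(s$ecdf(16.999), 0)
  expect_equal(s$ecdf(17), 1)
  # fraction within 50 nm is the ECDF at 50 by definition
  set.seed(2)
  d2 <- rexp(500, 1 / 40)
  s2 <- nnd_distribution(d2)
  expect_equal(s2$fraction_within, mean(d2 <= 50))
  expect_error(nnd_distribution(d, bin_width = 0), "bin_width")
})

test_that("paired channels at a fixed 25-30 nm offset put the mode there", {
  # red molecules on a loose grid; green copies offset by 27 nm
  set.seed(9)
  n <- 400
  rx <- runif(n, 0, 20000); ry <- runif(n, 0, 20000)
  tab <- loc_table(c(rx, rx + 27), c(ry, ry), rep(c("red", "green"), each = n))
  res <- cross_channel_nnd(tab, "red", "green")
  s <- nnd_distribution(res, bin_width = 5, range = c(0, 200))
  expect_equal(s$modal_bin, c(25, 30))
})

test_that("degenerate clustering cases behave per the density rules", {
  # 12 coincident points: one cluster of 12
  tab <- loc_table(rep(5, 12), rep(5, 12),
                   rep(c("red", "green"), 6))
  cl <- density_cluster(tab, radius = 20, min_count = 10)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$n_red + cl[[1]]$n_green, 12)
  # 5 isolated points with min_count 10: all noise
  tab2 <- loc_table(seq(0, 4000, 1000), rep(0, 5), rep("red", 5))
  cl2 <- density_cluster(tab2, radius = 20, min_count = 10)
  expect_length(cl2, 0)
  expect_true(all(attr(cl2, "labels") == 0))
  # empty table: empty result
  empty <- loc_table(numeric(0), numeric(0), character(0))
  expect_length(density_cluster(empty, 20, 10), 0)
})

test_that("density clustering matches the brute-force DBSCAN oracle", {
  for (s in 1:25) {
    set.seed(s)
    n_bg <- sample(20:120, 1)
    n_cl <- sample(1:4, 1)
    x <- runif(n_bg, 0, 800); y <- runif(n_bg, 0, 800)
    for (k in seq_len(n_cl)) {
      cx <- runif(1, 100, 700); cy <- runif(1, 100, 700)
      m <- sample(8:30, 1)
      x <- c(x, rnorm(m, cx, 25)); y <- c(y, rnorm(m, cy, 25))
    }
    ord <- sample(seq_along(x))   # row order must not matter
    tab <- loc_table(x[ord], y[ord],
                     sample(c("red", "green"), length(x), replace = TRUE))
    radius <- sample(c(20, 40, 60), 1)
    min_count <- sample(c(5, 10), 1)
    got <- attr(density_cluster(tab, radius, min_count), "labels")
    want <- oracle_dbscan(tab$x_nm, tab$y_nm, radius, min_count)
    expect_identical(as.integer(got), as.integer(want))
  }
})

test_that("composition classification follows the >=1 molecule rule", {
  mk <- function(n_red, n_green) {
    list(id = 1, members = 1:(n_red + n_green), n_red = n_red,
         n_green = n_green, centroid = c(0, 0),
         coords = cbind(rnorm(n_red + n_green), rnorm(n_red + n_green)))
  }
  cl <- structure(list(mk(10, 0), mk(0, 12), mk(9, 1)),
                  class = "smlm_clusters")
  out <- classify_clusters(cl)
  expect_equal(vapply(out$clusters, `[[`, "", "composition"),
               c("homo_red", "homo_green", "hetero"))
  expect_equal(sum(out$distribution$percentage), 100)
  expect_equal(out$distribution$n, c(1L, 1L, 1L))
  # a stricter minority threshold reclassifies the 9:1 cluster
  strict <- classify_clusters(cl, min_minor = 2)
  expect_equal(vapply(strict$clusters, `[[`, "", "composition")[3],
               "homo_red")
})

test_that("a balanced simulated scene recovers ~equal class percentages", {
  cfg <- point_sim_config(field_size = c(15000, 15000),
                          n_homo_red = 10, n_homo_green = 10, n_hetero = 10,
                          molecules_per_cluster = 20, cluster_sd = 20,
                          background_density = 0, seed = 77)
  tab <- simulate_localizations(cfg)
  cl <- density_cluster(tab, radius = 40, min_count = 10)
  dist <- classify_clusters(cl)$distribution
  expect_equal(dist$n, rep(10L, 3))
  expect_equal(dist$percentage, rep(100 / 3, 3), tolerance = 1e-9)
})

test_that("hull areas: square, collinear and random-oracle cases", {
  # 4 corners of a 100x100 square plus interior points -> 10,000 nm^2
  sq <- cbind(c(0, 100, 100, 0, runif(6, 10, 90)),
              c(0, 0, 100, 100, runif(6, 10, 90)))
  cl <- structure(list(list(id = 1, members = 1:10, n_red = 10, n_green = 0,
                            centroid = colMeans(sq), coords = sq)),
                  class = "smlm_clusters")
  out <- cluster_areas(cl)
  expect_equal(out$table$area_nm2, 10000)
  # collinear cluster: area 0, flagged degenerate
  lin <- cbind(1:10, 2 * (1:10))
  cl2 <- structure(list(list(id = 1, members = 1:10, n_red = 10, n_green = 0,
                             centroid = colMeans(lin), coords = lin)),
                   class = "smlm_clusters")
  out2 <- cluster_areas(cl2)
  expect_equal(out2$table$area_nm2, 0)
  expect_true(out2$table$degenerate)
  # random clusters match the independent gift-wrapping oracle
  for (s in 1:20) {
    set.seed(s)
    pts <- cbind(rnorm(50, sd = 30), rnorm(50, sd = 30))
    cl3 <- structure(list(list(id = 1, members = 1:50, n_red = 50,
                               n_green = 0, centroid = colMeans(pts),
                               coords = pts)),
                     class = "smlm_clusters")
    expect_equal(cluster_areas(cl3)$table$area_nm2, oracle_hull_area(pts),
                 tolerance = 1e-9)
  }
})

test_that("radius sweep is monotone and empty-safe", {
  empty <- loc_table(numeric(0), numeric(0), character(0))
  sw0 <- radius_sweep(empty, c(20, 40, 60), 10)
  expect_equal(vapply(sw0$results, `[[`, numeric(1), "n_clustered"),
               c(r20 = 0, r40 = 0, r60 = 0))
  cfg <- point_sim_config(field_size = c(10000, 10000),
                          n_homo_red = 8, n_hetero = 8,
                          molecules_per_cluster = 15, cluster_sd = 30,
                          background_density = 1, seed = 13)
  tab <- simulate_localizations(cfg)
  sw <- radius_sweep(tab, c(20, 40, 60), 10)
  idx <- lapply(sw$results, `[[`, "clustered_idx")
  expect_true(all(idx$r20 %in% idx$r40))
  expect_true(all(idx$r40 %in% idx$r60))
  expect_error(radius_sweep(tab, c(40, 20), 10), "sorted")
})

test_that("hetero percentage is stable across the radius sweep", {
  # 30-nm-SD clusters: the recovered hetero share moves < 5 points between
  # radii once clusters are dense enough to be detected at every radius
  cfg <- point_sim_config(field_size = c(15000, 15000),
                          n_homo_red = 12, n_homo_green = 12, n_hetero = 12,
                          molecules_per_cluster = 40, cluster_sd = 30,
                          background_density = 0, seed = 101)
  tab <- simulate_localizations(cfg)
  sw <- radius_sweep(tab, c(20, 40, 60), 10)
  het <- vapply(sw$results, function(r)
    r$distribution$percentage[r$distribution$composition == "hetero"],
    numeric(1))
  expect_lt(max(het) - min(het), 5)
})
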