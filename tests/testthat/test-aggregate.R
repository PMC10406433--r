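test_that("degenerate aggregates: single particle and touching pair", {
  one <- build_aggregate(1, radii = 1.6, d_f = 2.0, seed = 1)
  expect_equal(one$centers, matrix(0, 1, 3))
  two <- build_aggregate(2, radii = 1.6, d_f = 2.5, seed = 1)
  d <- sqrt(sum((two$centers[1, ] - two$centers[2, ])^2))
  expect_equal(d, 3.2, tolerance = 1e-9)
})

test_that("identical seeds give bitwise identical geometries", {
  a <- build_aggregate(64, 1.6, 2.09, seed = 42)
  b <- build_aggregate(64, 1.6, 2.09, seed = 42)
  expect_identical(a$centers, b$centers)
  c <- build_aggregate(64, 1.6, 2.09, seed = 43)
  expect_false(isTRUE(all.equal(a$centers, c$centers)))
})

test_that("no overlaps and a connected contact graph after every build", {
  for (df in c(1.63, 2.42)) {
    agg <- build_aggregate(96, 1.6, df, seed = 5)
    D <- as.matrix(dist(agg$centers))
    touch <- outer(agg$radii, agg$radii, "+")
    off <- upper.tri(D)
    # overlap tolerance 1e-3 relative
    expect_true(all(D[off] >= touch[off] * (1 - 1e-3)))
    # every particle touches at least one other (contact tolerance)
    contact <- D <= touch * (1 + 1e-3)
    diag(contact) <- FALSE
    expect_true(all(rowSums(contact) >= 1))
    # and the contact graph is connected
    expect_equal(max(oracle_components(contact)), 1)
  }
})

test_that("recorded subclusters obey the scaling law where attainable", {
  a <- 1.6
  for (df in c(1.63, 2.42)) {
    agg <- build_aggregate(256, a, df, seed = 9)
    rec <- agg$subclusters
    # k_f = 1 requires Rg = a N^(1/df); below the linear-chain bound
    # a sqrt((N^2-1)/3) the law is geometrically unattainable
    attainable <- a * rec$N^(1 / df) <= a * sqrt((rec$N^2 - 1) / 3)
    rec <- rec[attainable, ]
    expect_gt(nrow(rec), 10)
    resid <- abs(rec$N - (rec$Rg / a)^df) / rec$N
    expect_true(all(resid <= 0.05))
  }
})

test_that("subcluster mass-size records reproduce the target dimension", {
  agg <- build_aggregate(256, 1.6, 2.42, seed = 3)
  rec <- agg$subclusters[agg$subclusters$N >= 4, ]
  f <- fit_mass_size(data.frame(R = rec$Rg, M = rec$N))
  expect_lt(abs(f$A - 2.42), 0.15)
})

test_that("mass-radius estimator reads off ideal geometries", {
  # dense cubic lattice block: space-filling, d_f ~ 3
  g <- as.matrix(expand.grid(x = 1:12, y = 1:12, z = 1:12)) * 2
  lattice <- list(centers = g, radii = rep(1, 12^3))
  expect_lt(abs(measure_df(lattice) - 3), 0.2)
  # straight line of touching particles: d_f ~ 1
  line <- list(centers = cbind(2 * (1:200), 0, 0), radii = rep(1, 200))
  expect_lt(abs(measure_df(line) - 1), 0.1)
  expect_error(measure_df(list(centers = matrix(0, 5, 3), radii = rep(1, 5))),
               "32")
})

test_that("builder and estimator close the loop at a low fractal dimension", {
  agg <- build_aggregate(512, 1.6, 1.63, seed = 11)
  expect_lt(abs(measure_df(agg) - 1.63), 0.2)
})

test_that("decoration replaces particles by conformers at exact positions", {
  conf <- gen_polymer(60, "compact", seed = 21)
  rg <- radius_of_gyration(conf)
  lib <- conformer_library(list(conf))

  # single particle: decorated Rg equals the conformer Rg (rotation invariant)
  one <- build_aggregate(1, radii = rg, d_f = 2.0, seed = 1)
  dec1 <- decorate(one, lib, seed = 2)
  expect_equal(radius_of_gyration(get_chain(dec1, 1)), rg, tolerance = 1e-9)

  # two particles: chain centers of mass separated by the center distance
  two <- build_aggregate(2, radii = rg, d_f = 2.0, seed = 1)
  dec2 <- decorate(two, lib, seed = 3)
  com <- function(s) {
    m <- atomic_mass(s$elements)
    colSums(s$coords * m) / sum(m)
  }
  sep <- sqrt(sum((com(get_chain(dec2, 1)) - com(get_chain(dec2, 2)))^2))
  expect_equal(sep, sqrt(sum((two$centers[1, ] - two$centers[2, ])^2)),
               tolerance = 1e-6)

  # 64 particles: center-of-mass positions reproduce particle centers and
  # the measured dimension is unchanged
  agg <- build_aggregate(64, radii = rg, d_f = 2.2, seed = 4)
  dec <- decorate(agg, lib, seed = 5)
  coms <- t(vapply(seq_len(64), function(i) com(get_chain(dec, i)),
                   numeric(3)))
  expect_equal(coms, agg$centers, tolerance = 1e-9, ignore_attr = TRUE)
  redone <- list(centers = coms, radii = agg$radii)
  expect_lt(abs(measure_df(redone) - measure_df(agg)), 0.1)

  # incompatible radii are refused with a diagnostic
  big <- build_aggregate(4, radii = 10, d_f = 2.0, seed = 1)
  expect_error(decorate(big, lib, seed = 1), "no conformer within")
})
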