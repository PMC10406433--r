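# minimal hand-built two-chain ensembles for the trivial contact cases
two_chain_ensemble <- function(gap, L = 10) {
  atoms <- data.frame(chain = rep(c("A", "B"), each = 2),
                      element = "C", resid = c(0L, 1L, 0L, 1L), restype = "G")
  coords <- rbind(c(1, 1, 1), c(1.3, 1, 1),
                  c(1.3 + gap, 1, 1), c(1.6 + gap, 1, 1))
  chain_ensemble(atoms, coords, box = L, periodic = TRUE)
}

test_that("chain contacts respect the distance cutoff", {
  st <- chain_contacts(two_chain_ensemble(0.2))
  expect_true(st$adjacency[[1]][1, 2])
  st2 <- chain_contacts(two_chain_ensemble(1.0))
  expect_false(any(st2$adjacency[[1]]))
  expect_equal(diag(st2$adjacency[[1]]), c(A = FALSE, B = FALSE))
})

test_that("minimum-image convention finds contacts across the box boundary", {
  atoms <- data.frame(chain = c("A", "B"), element = "C",
                      resid = 0L, restype = "G")
  # 0.3 nm apart only through the periodic boundary
  coords <- rbind(c(0.1, 5, 5), c(9.8, 5, 5))
  ens <- chain_ensemble(atoms, coords, box = 10, periodic = TRUE)
  expect_true(chain_contacts(ens)$adjacency[[1]][1, 2])
  open_ens <- chain_ensemble(atoms, coords, box = NA, periodic = FALSE)
  expect_false(any(chain_contacts(open_ens)$adjacency[[1]]))
})

test_that("contact adjacency equals the brute-force oracle on random scenes", {
  for (s in 1:6) {
    ens <- random_scene(5, 50, L = 6, seed = s)
    st <- chain_contacts(ens)
    expect_equal(unname(st$adjacency[[1]]), oracle_adjacency(ens, 0.35),
                 info = paste("seed", s))
  }
})

test_that("valency counts partners on planted ring and star graphs", {
  ring <- matrix(FALSE, 6, 6)
  for (i in 1:6) {
    j <- i %% 6 + 1
    ring[i, j] <- ring[j, i] <- TRUE
  }
  sc <- gen_scene(6, 12, ring, seed = 2)
  v <- valency_series(chain_contacts(sc))
  expect_equal(unname(v$chain_mean), rep(2, 6))

  star <- matrix(FALSE, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- TRUE
  sv <- valency_series(chain_contacts(gen_scene(5, 12, star, seed = 3)))
  expect_equal(unname(sv$chain_mean), c(4, 1, 1, 1, 1))
  expect_equal(sv$window_mean, 1.6)
})

test_that("contact probability is the degree fraction of possible partners", {
  star <- matrix(FALSE, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- TRUE
  st <- chain_contacts(gen_scene(5, 12, star, seed = 3))
  expect_equal(contact_probability(st), 1.6 / 4)
  # complete graph on 4 chains: p = 1
  k4 <- matrix(TRUE, 4, 4); diag(k4) <- FALSE
  stk <- chain_contacts(gen_scene(4, 12, k4, seed = 4))
  expect_equal(contact_probability(stk), 1)
  # empty graph: p = 0
  ste <- chain_contacts(gen_scene(3, 12, matrix(FALSE, 3, 3), seed = 5))
  expect_equal(contact_probability(ste), 0)
})

test_that("chain clustering equals connected components of the contact graph", {
  adj <- matrix(FALSE, 3, 3)
  adj[1, 2] <- adj[2, 1] <- TRUE
  st <- chain_contacts(gen_scene(3, 10, adj, seed = 6))
  cl <- cluster_chains(st)
  expect_equal(cl$largest, 2)
  expect_equal(sort(unname(vapply(cl$partitions[[1]], length, integer(1)))),
               c(1, 2))

  # a consecutive chain of contacts percolates into one cluster
  path <- matrix(FALSE, 8, 8)
  for (i in 1:7) path[i, i + 1] <- path[i + 1, i] <- TRUE
  stp <- chain_contacts(gen_scene(8, 16, path, seed = 7))
  expect_equal(cluster_chains(stp)$largest, 8)
})

test_that("clustering matches a union-find oracle on random graphs", {
  set.seed(11)
  for (rep in 1:30) {
    n <- sample(4:12, 1)
    adj <- matrix(runif(n * n) < 0.25, n, n)
    adj <- adj | t(adj)
    diag(adj) <- FALSE
    # inject the adjacency into a minimal stats object
    st <- structure(list(adjacency = list(adj), n_frames = 1L,
                         chains = sprintf("C%02d", 1:n)),
                    class = "contact_stats")
    got <- cluster_chains(st)$membership[1, ]
    want <- oracle_components(adj)
    # identical partitions up to label permutation: same co-membership
    expect_equal(outer(got, got, "=="), outer(want, want, "=="),
                 ignore_attr = TRUE)
  }
})

# fabricate contact stats carrying only residue-level tables
fake_pair_stats <- function(counts, composition, scope = "inter") {
  structure(list(pair_inter = if (scope == "inter") counts else counts * 0,
                 pair_intra = if (scope == "intra") counts else counts * 0,
                 composition = composition, n_frames = 1L,
                 window_frames = 1L, chains = "A"),
            class = "contact_stats")
}

test_that("enrichment of a uniform null converges to 1", {
  set.seed(101)
  types <- c("A", "G", "R", "Y")
  counts <- matrix(0, 4, 4, dimnames = list(types, types))
  n_ev <- 1e5
  i <- sample(4, n_ev, replace = TRUE)
  j <- sample(4, n_ev, replace = TRUE)
  for (k in seq_len(n_ev)) {
    a <- min(i[k], j[k]); b <- max(i[k], j[k])
    counts[a, b] <- counts[a, b] + 1
    if (a != b) counts[b, a] <- counts[b, a] + 1
  }
  st <- fake_pair_stats(counts, setNames(rep(0.25, 4), types))
  enr <- contact_enrichment(st, "inter")
  expect_true(all(abs(enr$enr - 1) < 0.05))
  expect_equal(sum(enr$f_obs), 1, tolerance = 1e-9)
  expect_equal(sum(enr$f_exp), 1, tolerance = 1e-9)
})

test_that("enrichment on a hand-enumerated toy case", {
  # sequence YRYR...: f_Y = f_R = 0.5; contacts only Y-Y
  types <- c("R", "Y")
  counts <- matrix(c(0, 0, 0, 60), 2, 2, dimnames = list(types, types))
  st <- fake_pair_stats(counts, c(R = 0.5, Y = 0.5))
  enr <- contact_enrichment(st, "inter")
  # f_obs(Y,Y) = 1, f_exp(Y,Y) = 0.25 -> ENR = 4 = 1/f_Y^2
  expect_equal(enr$enr[enr$a == "Y" & enr$b == "Y"], 4)
  expect_equal(enr$enr[enr$a == "R" & enr$b == "R"], 0)
  expect_equal(enr$enr[enr$a == "R" & enr$b == "Y"], 0)
})

test_that("interaction profiles localize contacts along the sequence", {
  # two 10-residue chains touching only at residues 3 and 7 (0-based)
  mk <- function() {
    beads <- function(y) cbind(seq(0, 9) * 0.5, y, 0)
    A <- beads(0)
    B <- beads(5)
    B[4, 2] <- 0.3   # residue 3 close to A residue 3
    B[8, 2] <- 0.3   # residue 7
    atoms <- data.frame(chain = rep(c("A", "B"), each = 10), element = "C",
                        resid = rep(0:9, 2), restype = "G")
    chain_ensemble(atoms, rbind(A, B), box = 20, periodic = TRUE)
  }
  st <- chain_contacts(mk())
  prof <- interaction_profiles(st, "inter")
  planted <- rep(0, 10)
  planted[c(4, 8)] <- 1
  expect_equal(unname(prof["B", ] > 0), planted > 0)
  expect_gt(cor(prof["B", ], planted), 0.99)
  expect_error(interaction_profiles(st, "sideways"))
})

test_that("representative mode selects the most mutually correlated profiles", {
  set.seed(7)
  base <- sin(seq(0, 3 * pi, length.out = 40))^2
  profiles <- rbind(
    matrix(rep(base, 4), 4, byrow = TRUE),                      # identical
    matrix(runif(4 * 40), 4)                                    # noise
  )
  valencies <- rep(4, 8)
  rm <- representative_mode(profiles, valencies)
  expect_equal(rm$chains, 1:4)
  expect_equal(rm$profile, base)
  expect_true(rm$pass)
  # exhaustive oracle over all C(8,4) subsets
  best <- NULL
  for (s in asplit(combn(8, 4), 2)) {
    tot <- 0
    for (p in asplit(combn(s, 2), 2))
      tot <- tot + cor(profiles[p[1], ], profiles[p[2], ])
    if (is.null(best) || tot > best$tot) best <- list(s = s, tot = tot)
  }
  expect_equal(rm$chains, as.integer(best$s))
  # all-identical profiles: representative equals any profile with R = 1
  ident <- matrix(rep(base, 6), 6, byrow = TRUE)
  rmi <- representative_mode(ident, rep(2, 6))
  expect_equal(rmi$profile, base)
  expect_equal(rmi$R, 1)
  expect_error(representative_mode(profiles[1:3, ], rep(4, 3)), "fewer than 4")
})

test_that("radius of gyration matches analytic and oracle values", {
  expect_equal(radius_of_gyration(list(coords = matrix(c(1, 2, 3), 1),
                                       elements = "C")), 0)
  expect_equal(radius_of_gyration(list(coords = rbind(c(0, 0, 0), c(2, 0, 0)),
                                       elements = c("C", "C"))), 1.0)
  set.seed(5)
  X <- matrix(rnorm(300), 100, 3)
  m <- runif(100, 1, 16)
  got <- radius_of_gyration(list(coords = X, elements = rep("C", 100)),
                            masses = m)
  expect_equal(got, oracle_rg(X, m), tolerance = 1e-12)
  expect_error(radius_of_gyration(list(coords = X, elements = rep("C", 100)),
                                  masses = rep(0, 100)), "positive")
})

test_that("random-coil reference follows the disordered-chain scaling", {
  expect_equal(round(random_coil_rg(80), 2), 2.50)
  expect_equal(random_coil_rg(1), 0.254)
  expect_equal(round(random_coil_rg(238), 2), 4.42)
})

test_that("compactness: volumes, estimators, and invariances", {
  # single atom with Rh equal to its vdW radius: phi = 1 up to grid error
  # (the estimate may land a fraction of a percent above 1, which warns)
  one <- list(coords = matrix(0, 1, 3), elements = "C")
  cr <- suppressWarnings(compactness(one, grid_spacing = 0.01))
  expect_equal(cr$phi, 1, tolerance = 0.02)
  expect_equal(cr$R_h, 0.17)

  # two disjoint spheres: union volume is additive (within 1% grid error)
  two <- list(coords = rbind(c(0, 0, 0), c(1, 0, 0)), elements = c("C", "C"))
  ct <- compactness(two, grid_spacing = 0.02, radii = 0.2)
  expect_equal(ct$V_vdw, 2 * 4 / 3 * pi * 0.2^3, tolerance = 0.01)

  # compact conformer is denser than an extended one of the same polymer
  pc <- gen_polymer(40, "compact", seed = 9)
  pe <- gen_polymer(40, "extended", seed = 9)
  expect_gt(compactness(pc, grid_spacing = 0.06)$phi,
            compactness(pe, grid_spacing = 0.06)$phi)

  # rigid rotation/translation leaves phi unchanged within grid tolerance
  R <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3)
  rot <- list(coords = sweep(pc$coords %*% R, 2, c(1, -2, 3), "+"),
              elements = pc$elements)
  expect_equal(compactness(rot, grid_spacing = 0.06)$phi,
               compactness(pc, grid_spacing = 0.06)$phi, tolerance = 0.01)
  expect_error(compactness(list(coords = matrix(0, 1, 3), elements = "Zz")),
               "element")
})

test_that("box concentrations reproduce the simulated-system table", {
  expect_equal(round(box_concentration(1, 9.0), 1), 2.3)
  expect_equal(round(box_concentration(24, 19.0), 1), 5.8)
  # printed value for the 18 nm box is 6.9; the geometric formula gives 6.83
  expect_lt(abs(box_concentration(24, 18.0) - 6.9), 0.1)
})

test_that("entropy normalization handles equal and unequal chain sizes", {
  expect_equal(entropy_mutation_difference(1.5, 100, 1.5, 100), 0)
  # equal sizes reduce to a plain difference (x T, in kcal/mol)
  expect_equal(entropy_mutation_difference(2, 10, 1, 10),
               (2 - 1) * 310 / 4.184)
  # asymmetric sizes: hand-evaluated formula
  S_mut <- -3.2; N_mut <- 120; S_wt <- -3.0; N_wt <- 110
  hand <- (S_mut / (3 * 120 - 6) - S_wt / (3 * 110 - 6)) * (3 * 120 - 6) *
    310 / 4.184
  expect_equal(entropy_mutation_difference(S_mut, N_mut, S_wt, N_wt), hand)
})
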