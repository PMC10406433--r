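#' Intermolecular contact statistics of a chain ensemble
#'
#' Two chains are in contact in a frame when their minimum interatomic
#' distance (all atoms, minimum-image convention under a cubic periodic box)
#' does not exceed `cutoff`. Besides the per-frame chain adjacency, residue
#' level statistics are accumulated over the trailing `window` fraction of
#' frames: residue-pair contact events by residue type (one event per residue
#' pair per frame, however many atom pairs qualify) and per-position contact
#' counts along the sequence, split into intermolecular (`inter`) and
#' intramolecular (`intra`, excluding residue pairs closer than 2 in
#' sequence).
#'
#' @param ensemble a [chain_ensemble()].
#' @param cutoff contact distance cutoff, nm (default 0.35, i.e. 3.5 Angstrom).
#' @param window fraction of trailing frames used for residue-level
#'   statistics (default 0.3); adjacency is always recorded for all frames.
#' @return An object of class `contact_stats`.
#' @export
chain_contacts <- function(ensemble, cutoff = 0.35, window = 0.3) {
  stopifnot(inherits(ensemble, "chain_ensemble"))
  .stopifnot_scalar_pos(cutoff, "cutoff")
  if (window <= 0 || window > 1) stop("`window` must be in (0, 1]")
  L <- if (ensemble$periodic) ensemble$box else NULL
  atoms <- ensemble$atoms
  chains <- levels(atoms$chain)
  nc <- length(chains)
  nf <- length(ensemble$coords)
  idx <- lapply(chains, function(ch) which(atoms$chain == ch))
  names(idx) <- chains
  win_frames <- seq.int(nf - ceiling(window * nf) + 1L, nf)

  types <- sort(unique(atoms$restype))
  zero_tab <- matrix(0, length(types), length(types),
                     dimnames = list(types, types))
  pair_inter <- zero_tab
  pair_intra <- zero_tab
  seq_lens <- vapply(idx, function(ii) max(atoms$resid[ii]) + 1L, integer(1))
  lmax <- max(seq_lens)
  pos_inter <- matrix(0, nc, lmax, dimnames = list(chains, NULL))
  pos_intra <- matrix(0, nc, lmax, dimnames = list(chains, NULL))

  adjacency <- vector("list", nf)
  min_dist <- vector("list", nf)

  record_pairs <- function(D, ra, rb, ta, tb) {
    # D: atom-distance matrix; ra/rb residue ids; ta/tb residue types
    hit <- which(D <= cutoff, arr.ind = TRUE)
    if (!nrow(hit)) return(NULL)
    unique(data.frame(i = ra[hit[, 1]], j = rb[hit[, 2]],
                      a = ta[hit[, 1]], b = tb[hit[, 2]]))
  }

  for (f in seq_len(nf)) {
    A <- matrix(FALSE, nc, nc, dimnames = list(chains, chains))
    Dm <- matrix(Inf, nc, nc, dimnames = list(chains, chains))
    diag(Dm) <- 0
    in_win <- f %in% win_frames
    X <- ensemble$coords[[f]]
    for (u in seq_len(nc - 1)) {
      for (v in (u + 1):nc) {
        D <- .cross_dist_pbc(X[idx[[u]], , drop = FALSE],
                             X[idx[[v]], , drop = FALSE], L)
        dmin <- min(D)
        Dm[u, v] <- Dm[v, u] <- dmin
        if (dmin <= cutoff) {
          A[u, v] <- A[v, u] <- TRUE
          if (in_win) {
            ev <- record_pairs(D, atoms$resid[idx[[u]]], atoms$resid[idx[[v]]],
                               atoms$restype[idx[[u]]], atoms$restype[idx[[v]]])
            if (!is.null(ev)) {
              for (k in seq_len(nrow(ev))) {
                pair_inter[ev$a[k], ev$b[k]] <- pair_inter[ev$a[k], ev$b[k]] + 1
                if (ev$a[k] != ev$b[k])
                  pair_inter[ev$b[k], ev$a[k]] <- pair_inter[ev$b[k], ev$a[k]] + 1
                pos_inter[u, ev$i[k] + 1L] <- pos_inter[u, ev$i[k] + 1L] + 1
                pos_inter[v, ev$j[k] + 1L] <- pos_inter[v, ev$j[k] + 1L] + 1
              }
            }
          }
        }
      }
    }
    if (in_win) {
      for (u in seq_len(nc)) {
        # intramolecular contacts of chain u (sequence separation >= 2)
        Du <- .cross_dist_pbc(X[idx[[u]], , drop = FALSE],
                              X[idx[[u]], , drop = FALSE], L)
        ra <- atoms$resid[idx[[u]]]
        Du[abs(outer(ra, ra, "-")) < 2] <- Inf
        ev <- record_pairs(Du, ra, ra, atoms$restype[idx[[u]]],
                           atoms$restype[idx[[u]]])
        if (!is.null(ev)) {
          ev <- ev[ev$i < ev$j, , drop = FALSE]
          for (k in seq_len(nrow(ev))) {
            pair_intra[ev$a[k], ev$b[k]] <- pair_intra[ev$a[k], ev$b[k]] + 1
            if (ev$a[k] != ev$b[k])
              pair_intra[ev$b[k], ev$a[k]] <- pair_intra[ev$b[k], ev$a[k]] + 1
            pos_intra[u, ev$i[k] + 1L] <- pos_intra[u, ev$i[k] + 1L] + 1
            pos_intra[u, ev$j[k] + 1L] <- pos_intra[u, ev$j[k] + 1L] + 1
          }
        }
      }
    }
    adjacency[[f]] <- A
    min_dist[[f]] <- Dm
  }

  comp <- table(unlist(strsplit(paste(ensemble$sequences, collapse = ""), "")))
  composition <- as.numeric(comp) / sum(comp)
  names(composition) <- names(comp)

  structure(list(adjacency = adjacency, min_dist = min_dist,
                 pair_inter = pair_inter, pair_intra = pair_intra,
                 pos_inter = pos_inter, pos_intra = pos_intra,
                 composition = composition, chains = chains,
                 seq_lens = seq_lens, cutoff = cutoff,
                 n_frames = nf, window_frames = win_frames,
                 times = ensemble$times),
            class = "contact_stats")
}

#' @export
print.contact_stats <- function(x, ...) {
  cat(sprintf("contact stats: %d chains, %d frame(s), cutoff %.3g nm, window %d frame(s)\n",
              length(x$chains), x$n_frames, x$cutoff, length(x$window_frames)))
  invisible(x)
}

#' Interaction valency per chain and per frame
#'
#' Valency of a chain in a frame is its degree in the contact graph: the
#' number of distinct partner chains it touches.
#'
#' @param stats a [chain_contacts()] result.
#' @return A list with `degrees` (frames x chains matrix), `mean` (per-frame
#'   system mean), `chain_mean` (per-chain mean over the analysis window) and
#'   `window_mean` (system mean over the window).
#' @export
valency_series <- function(stats) {
  stopifnot(inherits(stats, "contact_stats"))
  deg <- t(vapply(stats$adjacency, rowSums, numeric(length(stats$chains))))
  if (length(stats$chains) == 1L) deg <- matrix(deg, ncol = 1L)
  colnames(deg) <- stats$chains
  chain_mean <- colMeans(deg[stats$window_frames, , drop = FALSE])
  list(degrees = deg, mean = rowMeans(deg),
       chain_mean = chain_mean, window_mean = mean(chain_mean))
}

#' Contact probability under the well-mixed assumption
#'
#' The probability that a given pair of chains is in contact, assuming every
#' chain can in principle reach every other: mean valency divided by the
#' number of possible partners.
#'
#' @param stats a [chain_contacts()] result.
#' @param n_chains number of chains in the system (>= 2).
#' @return Numeric vector, one probability per frame, in `[0, 1]`.
#' @export
contact_probability <- function(stats, n_chains = length(stats$chains)) {
  stopifnot(inherits(stats, "contact_stats"))
  if (n_chains < 2) stop("need at least 2 chains")
  v <- valency_series(stats)
  p <- v$mean / (n_chains - 1)
  pmin(pmax(p, 0), 1)
}

#' Single-linkage chain clustering
#'
#' Cutting a single-linkage dendrogram of chain-chain minimum distances at the
#' contact cutoff is equivalent to taking connected components of the contact
#' graph; both views are exposed here.
#'
#' @param stats a [chain_contacts()] result.
#' @param ensemble optionally, the originating [chain_ensemble()]; when given,
#'   the radius of gyration (nm, mass-weighted, coordinates as stored) of the
#'   largest cluster is reported per frame.
#' @return An object of class `cluster_partition`: list with `partitions` (per
#'   frame, a list of integer chain-index vectors), `membership` (frames x
#'   chains matrix of cluster labels), `largest` (per-frame largest cluster
#'   size) and optionally `largest_rg`.
#' @export
cluster_chains <- function(stats, ensemble = NULL) {
  stopifnot(inherits(stats, "contact_stats"))
  nc <- length(stats$chains)
  partitions <- vector("list", stats$n_frames)
  membership <- matrix(NA_integer_, stats$n_frames, nc,
                       dimnames = list(NULL, stats$chains))
  largest <- integer(stats$n_frames)
  largest_rg <- if (!is.null(ensemble)) rep(NA_real_, stats$n_frames) else NULL
  for (f in seq_len(stats$n_frames)) {
    g <- igraph::graph_from_adjacency_matrix(stats$adjacency[[f]],
                                             mode = "undirected")
    cmp <- igraph::components(g)
    membership[f, ] <- cmp$membership
    partitions[[f]] <- split(seq_len(nc), cmp$membership)
    largest[f] <- max(cmp$csize)
    if (!is.null(ensemble)) {
      big <- which(cmp$membership == which.max(cmp$csize))
      sel <- ensemble$atoms$chain %in% stats$chains[big]
      m <- atomic_mass(ensemble$atoms$element[sel])
      X <- ensemble$coords[[f]][sel, , drop = FALSE]
      cm <- colSums(X * m) / sum(m)
      largest_rg[f] <- sqrt(sum(m * rowSums(sweep(X, 2, cm)^2)) / sum(m))
    }
  }
  structure(list(partitions = partitions, membership = membership,
                 largest = largest, largest_rg = largest_rg),
            class = "cluster_partition")
}

#' Residue-type contact enrichment
#'
#' For each unordered residue-type pair (A, B) the observed contact-event
#' frequency is compared with the frequency expected from sequence
#' composition: `f_A^2` for homotypic pairs and `2 f_A f_B` for heterotypic
#' pairs (the symmetry factor makes the expected table sum to one, like the
#' observed one). `ENR > 1` marks contacts enriched over the sequence
#' background.
#'
#' @param stats a [chain_contacts()] result.
#' @param scope `"inter"` (between chains) or `"intra"` (within chains).
#' @return A data frame with columns `a`, `b`, `events`, `f_obs`, `f_exp` and
#'   `enr` (`NA` where the expected frequency is zero).
#' @export
contact_enrichment <- function(stats, scope = c("inter", "intra")) {
  stopifnot(inherits(stats, "contact_stats"))
  scope <- match.arg(scope)
  tab <- if (scope == "inter") stats$pair_inter else stats$pair_intra
  if (!length(stats$composition)) stop("empty sequence composition")
  types <- rownames(tab)
  ut <- which(upper.tri(tab, diag = TRUE), arr.ind = TRUE)
  events <- tab[ut]
  total <- sum(events)
  if (total < 1) stop("no contact events recorded for scope '", scope, "'")
  fA <- function(t) {
    v <- stats$composition[t]
    ifelse(is.na(v), 0, v)
  }
  a <- types[ut[, 1]]
  b <- types[ut[, 2]]
  f_obs <- events / total
  f_exp <- ifelse(a == b, fA(a)^2, 2 * fA(a) * fA(b))
  f_exp <- f_exp / sum(f_exp)   # exact renormalization over the table's types
  data.frame(a = a, b = b, events = events, f_obs = f_obs, f_exp = f_exp,
             enr = ifelse(f_exp > 0, f_obs / f_exp, NA_real_),
             row.names = NULL)
}

#' Per-position interaction profiles (dynamic interaction mode)
#'
#' Collapses position-resolved contact events to a 1D profile over sequence
#' positions: the per-frame frequency with which each position participates in
#' a contact, averaged over the analysis window.
#'
#' @param stats a [chain_contacts()] result.
#' @param scope `"inter"` or `"intra"`.
#' @return A chains x positions numeric matrix.
#' @export
interaction_profiles <- function(stats, scope = c("inter", "intra")) {
  stopifnot(inherits(stats, "contact_stats"))
  scope <- match.arg(scope)
  counts <- if (scope == "inter") stats$pos_inter else stats$pos_intra
  counts / length(stats$window_frames)
}

# correlation that tolerates constant vectors: 1 if (near-)identical, else NA
.safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    if (max(abs(x - y)) <= 1e-12) return(1)
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Representative interaction mode
#'
#' Selects the four chains whose rounded mean valency equals the rounded
#' system mean and whose interaction profiles are mutually most correlated
#' (exhaustive over all 4-subsets when at most 20 chains are eligible,
#' greedy otherwise), averages their profiles into the representative mode,
#' and reports the Pearson correlation of that mode with the all-chain
#' average profile together with a pass flag at R > 0.6.
#'
#' @param profiles chains x positions matrix from [interaction_profiles()].
#' @param valencies per-chain mean valencies (e.g. `valency_series()$chain_mean`).
#' @return A list with `profile`, `chains` (selected row indices), `R`
#'   (correlation with the all-chain average) and `pass`.
#' @export
representative_mode <- function(profiles, valencies) {
  if (nrow(profiles) != length(valencies))
    stop("one valency per profile row required")
  target <- round(mean(valencies))
  eligible <- which(round(valencies) == target)
  if (length(eligible) < 4)
    stop("fewer than 4 chains at the system-average valency; ",
         "fall back to the all-chain average profile")
  mutual <- function(rows) {
    cb <- utils::combn(rows, 2)
    s <- 0
    for (k in seq_len(ncol(cb))) {
      r <- .safe_cor(profiles[cb[1, k], ], profiles[cb[2, k], ])
      s <- s + ifelse(is.na(r), 0, r)
    }
    s
  }
  if (length(eligible) <= 20) {
    sets <- utils::combn(eligible, 4)
    scores <- apply(sets, 2, mutual)
    pick <- sets[, which.max(scores)]
  } else {
    # greedy: seed with the most correlated pair, extend twice
    cb <- utils::combn(eligible, 2)
    sc <- apply(cb, 2, function(p) {
      r <- .safe_cor(profiles[p[1], ], profiles[p[2], ])
      ifelse(is.na(r), -Inf, r)
    })
    pick <- cb[, which.max(sc)]
    while (length(pick) < 4) {
      rest <- setdiff(eligible, pick)
      gain <- vapply(rest, function(r) mutual(c(pick, r)), numeric(1))
      pick <- c(pick, rest[which.max(gain)])
    }
  }
  rep_prof <- colMeans(profiles[pick, , drop = FALSE])
  overall <- colMeans(profiles)
  R <- .safe_cor(rep_prof, overall)
  list(profile = rep_prof, chains = sort(pick), R = R,
       pass = isTRUE(R > 0.6))
}
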