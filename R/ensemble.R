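#' Multi-chain, multi-frame coordinate ensemble
#'
#' The central container for crowded-scene analysis: a fixed atom table shared
#' by all frames plus one coordinate matrix (nm) per frame.
#'
#' @param atoms data frame with one row per atom and columns `chain` (chain
#'   identifier, coerced to factor in order of appearance), `element` (symbol),
#'   `resid` (0-based residue index within the chain) and `restype` (one-letter
#'   residue code).
#' @param coords a single numeric matrix (n_atoms x 3, nm) or a list of such
#'   matrices, one per frame.
#' @param box cubic box edge length L (nm), or `NA` for open boundaries.
#' @param periodic logical; minimum-image convention is applied when `TRUE`.
#' @param times frame timestamps (ns); defaults to `0, 1, ...`.
#' @return An object of class `chain_ensemble`.
#' @export
chain_ensemble <- function(atoms, coords, box = NA_real_, periodic = !is.na(box),
                           times = NULL) {
  if (!is.data.frame(atoms) ||
      !all(c("chain", "element", "resid", "restype") %in% names(atoms)))
    stop("`atoms` needs columns chain, element, resid, restype")
  if (is.matrix(coords)) coords <- list(coords)
  if (!length(coords)) stop("at least one frame required")
  na <- nrow(atoms)
  for (f in coords) {
    if (!is.matrix(f) || nrow(f) != na || ncol(f) != 3 || !all(is.finite(f)))
      stop("each frame must be a finite n_atoms x 3 matrix")
  }
  if (periodic && (is.na(box) || box <= 0))
    stop("periodic ensembles need a positive cubic box length")
  atoms$chain <- factor(atoms$chain, levels = unique(atoms$chain))
  if (is.null(times)) times <- seq_along(coords) - 1
  sequences <- vapply(split(atoms, atoms$chain), function(a) {
    a <- a[!duplicated(a$resid), ]
    paste(a$restype[order(a$resid)], collapse = "")
  }, character(1))
  structure(list(atoms = atoms, coords = coords, box = box,
                 periodic = periodic, times = as.numeric(times),
                 sequences = sequences),
            class = "chain_ensemble")
}

#' @export
print.chain_ensemble <- function(x, ...) {
  cat(sprintf("chain ensemble: %d chains, %d atoms, %d frame(s)%s\n",
              nlevels(x$atoms$chain), nrow(x$atoms), length(x$coords),
              if (x$periodic) sprintf(", periodic box L = %.3g nm", x$box) else ""))
  invisible(x)
}

#' Number of chains in an ensemble
#' @param ensemble a [chain_ensemble()].
#' @return integer chain count.
#' @export
n_chains <- function(ensemble) nlevels(ensemble$atoms$chain)

#' Extract a single-chain snapshot
#'
#' @param ensemble a [chain_ensemble()].
#' @param chain chain identifier or index.
#' @param frame frame index (1-based).
#' @return A list with `coords` (matrix, nm), `elements`, `resid`, `restype`
#'   -- the unit consumed by [radius_of_gyration()] and [compactness()].
#' @export
get_chain <- function(ensemble, chain, frame = 1L) {
  lv <- levels(ensemble$atoms$chain)
  id <- if (is.numeric(chain)) lv[chain] else as.character(chain)
  sel <- ensemble$atoms$chain == id
  if (!any(sel)) stop("no such chain: ", chain)
  list(coords = ensemble$coords[[frame]][sel, , drop = FALSE],
       elements = ensemble$atoms$element[sel],
       resid = ensemble$atoms$resid[sel],
       restype = ensemble$atoms$restype[sel])
}
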