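# Structure and table I/O. Internal units are nm everywhere; conversions
# happen only at this boundary (PDB files are Angstrom, GRO and XYZ files
# written by this package are nm).

.guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("pdb", "ent")) return("pdb")
  if (ext == "gro") return("gro")
  if (ext == "xyz") return("xyz")
  stop("cannot guess structure format from extension: ", path)
}

#' Read a structure file into a chain ensemble
#'
#' Supports PDB (via bio3d; multi-model files become frames; coordinates
#' converted Angstrom to nm; cubic box from CRYST1 when present), GRO
#' (multi-frame by concatenated blocks; chains split where the residue number
#' decreases; box from the trailing box line) and XYZ (nm; chain identities
#' from a JSON sidecar `<path>.chains` or the `chain_map` argument; multiple
#' frames by concatenated blocks).
#'
#' @param path file path.
#' @param format `"auto"`, `"pdb"`, `"gro"` or `"xyz"`.
#' @param chain_map for XYZ: character vector of per-atom chain identifiers.
#' @return A [chain_ensemble()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "gro", "xyz"),
                           chain_map = NULL) {
  format <- match.arg(format)
  if (format == "auto") format <- .guess_format(path)
  switch(format,
         pdb = .read_pdb(path),
         gro = .read_gro(path),
         xyz = .read_xyz(path, chain_map))
}

.read_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  chain <- at$chain
  if (all(is.na(chain)) || all(chain == "")) {
    segid <- at$segid
    chain <- if (!all(is.na(segid)) && !all(segid == "")) segid else "A"
  }
  chain[is.na(chain) | chain == ""] <- "A"
  element <- at$elesy
  if (is.null(element) || all(is.na(element)))
    element <- substr(trimws(at$elety), 1, 1)
  element[is.na(element) | element == ""] <-
    substr(trimws(at$elety), 1, 1)[is.na(element) | element == ""]
  restype <- .aa3to1(at$resid)
  # 0-based residue index within each chain, in order of appearance
  resid <- unlist(lapply(split(at$resno, factor(chain, unique(chain))),
                         function(r) as.integer(factor(r, unique(r))) - 1L),
                  use.names = FALSE)
  atoms <- data.frame(chain = chain, element = element, resid = resid,
                      restype = restype)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  frames <- lapply(seq_len(nrow(xyz)), function(f)
    matrix(xyz[f, ], ncol = 3, byrow = TRUE) / 10)
  box <- NA_real_
  cryst <- grep("^CRYST1", readLines(path, warn = FALSE), value = TRUE)
  if (length(cryst)) {
    abc <- suppressWarnings(as.numeric(c(substr(cryst[1], 7, 15),
                                         substr(cryst[1], 16, 24),
                                         substr(cryst[1], 25, 33)))) / 10
    if (all(is.finite(abc)) && all(abc > 0)) {
      if (max(abs(abc - abc[1])) > 1e-6)
        stop("only cubic boxes are supported (CRYST1 is non-cubic)")
      box <- abc[1]
    }
  }
  chain_ensemble(atoms, frames, box = box, periodic = !is.na(box))
}

.aa123 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
            E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
            M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
            Y = "TYR", V = "VAL")

.aa3to1 <- function(res3) {
  map <- stats::setNames(names(.aa123), .aa123)
  out <- map[toupper(trimws(res3))]
  out[is.na(out)] <- "X"
  unname(out)
}

.read_gro <- function(path) {
  lines <- readLines(path)
  frames <- list()
  atoms <- NULL
  box <- NA_real_
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) ) { i <- i + 1L; next }
    natoms <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(natoms)) stop("malformed GRO atom count at line ", i + 1L)
    rec <- lines[(i + 2L):(i + 1L + natoms)]
    resno <- as.integer(substr(rec, 1, 5))
    resname <- trimws(substr(rec, 6, 10))
    atname <- trimws(substr(rec, 11, 15))
    x <- as.numeric(substr(rec, 21, 28))
    y <- as.numeric(substr(rec, 29, 36))
    z <- as.numeric(substr(rec, 37, 44))
    if (anyNA(c(x, y, z)))
      stop("malformed GRO coordinates in block starting at line ", i)
    boxline <- strsplit(trimws(lines[i + 2L + natoms]), "\\s+")[[1]]
    bb <- suppressWarnings(as.numeric(boxline))
    if (length(bb) >= 3 && all(is.finite(bb[1:3]))) {
      if (max(abs(bb[1:3] - bb[1])) > 1e-6)
        stop("only cubic boxes are supported (non-cubic GRO box)")
      box <- bb[1]
    }
    if (is.null(atoms)) {
      # chains delimited by decreasing residue numbers
      chain_id <- cumsum(c(TRUE, diff(resno) < 0))
      resid <- unlist(lapply(split(resno, chain_id), function(r)
        as.integer(factor(r, unique(r))) - 1L), use.names = FALSE)
      atoms <- data.frame(chain = sprintf("C%02d", chain_id),
                          element = substr(atname, 1, 1),
                          resid = resid,
                          restype = .aa3to1(resname))
    }
    frames[[length(frames) + 1L]] <- unname(cbind(x, y, z))
    i <- i + 3L + natoms
  }
  if (is.null(atoms)) stop("no frames found in GRO file")
  chain_ensemble(atoms, frames, box = box, periodic = !is.na(box))
}

.read_xyz <- function(path, chain_map = NULL) {
  lines <- readLines(path)
  frames <- list()
  elements <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    natoms <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(natoms)) stop("malformed XYZ atom count at line ", i)
    rec <- strsplit(trimws(lines[(i + 2L):(i + 1L + natoms)]), "\\s+")
    el <- vapply(rec, `[`, character(1), 1L)
    xyz <- t(vapply(rec, function(r) as.numeric(r[2:4]), numeric(3)))
    if (anyNA(xyz)) stop("malformed XYZ coordinates in block at line ", i)
    if (is.null(elements)) elements <- el
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + natoms
  }
  if (is.null(elements)) stop("no frames found in XYZ file")
  if (is.null(chain_map)) {
    sidecar <- paste0(path, ".chains")
    if (!file.exists(sidecar))
      stop("XYZ needs chain identities: pass `chain_map` or provide ", sidecar)
    chain_map <- unlist(jsonlite::read_json(sidecar, simplifyVector = TRUE))
  }
  if (length(chain_map) != length(elements))
    stop("chain_map length does not match atom count")
  atoms <- data.frame(chain = chain_map, element = elements,
                      resid = stats::ave(seq_along(elements), chain_map,
                                         FUN = seq_along) - 1L,
                      restype = "X")
  chain_ensemble(atoms, frames, box = NA_real_, periodic = FALSE)
}

#' Write a chain ensemble to PDB, GRO or XYZ
#'
#' PDB output uses one model per frame, chain letters for the first 62 chains
#' and segment identifiers throughout; if coordinates overflow the fixed PDB
#' fields (or more than 99999 atoms are present) the writer falls back to XYZ
#' with a warning. XYZ output (nm) writes a JSON chain sidecar `<path>.chains`.
#'
#' @param ensemble a [chain_ensemble()].
#' @param path output path.
#' @param format `"auto"`, `"pdb"`, `"gro"` or `"xyz"`.
#' @return The path written, invisibly.
#' @export
write_structure <- function(ensemble, path, format = c("auto", "pdb", "gro", "xyz")) {
  stopifnot(inherits(ensemble, "chain_ensemble"))
  if (!nrow(ensemble$atoms)) stop("empty ensemble")
  format <- match.arg(format)
  if (format == "auto") format <- .guess_format(path)
  if (format == "pdb") {
    ang <- max(abs(unlist(lapply(ensemble$coords, range)))) * 10
    if (ang > 9999.999 || nrow(ensemble$atoms) > 99999) {
      warning("coordinates or atom count overflow PDB fields; writing XYZ instead")
      path <- sub("\\.pdb$", ".xyz", path, ignore.case = TRUE)
      format <- "xyz"
    }
  }
  switch(format,
         pdb = .write_pdb(ensemble, path),
         gro = .write_gro(ensemble, path),
         xyz = .write_xyz(ensemble, path))
  invisible(path)
}

.chain_letters <- c(LETTERS, letters, as.character(0:9))

.write_pdb <- function(ensemble, path) {
  at <- ensemble$atoms
  ci <- as.integer(at$chain)
  letter <- .chain_letters[((ci - 1L) %% length(.chain_letters)) + 1L]
  segid <- sprintf("%-4s", substr(sprintf("C%03d", ci), 1, 4))
  res3 <- .aa123[at$restype]
  res3[is.na(res3)] <- "UNK"
  con <- file(path, "w")
  on.exit(close(con))
  if (ensemble$periodic)
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                       ensemble$box * 10, ensemble$box * 10, ensemble$box * 10,
                       90, 90, 90), con)
  nf <- length(ensemble$coords)
  for (f in seq_len(nf)) {
    if (nf > 1) writeLines(sprintf("MODEL     %4d", f), con)
    X <- ensemble$coords[[f]] * 10
    lines <- sprintf(
      "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00      %-4s%2s",
      seq_len(nrow(at)), substr(at$element, 1, 4),
      res3, letter, (at$resid %% 9999L) + 1L,
      X[, 1], X[, 2], X[, 3], segid, sprintf("%2s", at$element))
    writeLines(lines, con)
    if (nf > 1) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
}

.write_gro <- function(ensemble, path) {
  at <- ensemble$atoms
  ci <- as.integer(at$chain)
  # global residue counter so chain breaks are detectable (resno resets)
  res3 <- .aa123[at$restype]
  res3[is.na(res3)] <- "UNK"
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(ensemble$coords)) {
    writeLines("generated by condenscale", con)
    writeLines(sprintf("%5d", nrow(at)), con)
    X <- ensemble$coords[[f]]
    lines <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     (at$resid %% 99999L) + 1L, res3,
                     substr(paste0(at$element, "X"), 1, 5),
                     ((seq_len(nrow(at)) - 1L) %% 99999L) + 1L,
                     X[, 1], X[, 2], X[, 3])
    writeLines(lines, con)
    b <- if (ensemble$periodic) ensemble$box else 0
    writeLines(sprintf("%10.5f%10.5f%10.5f", b, b, b), con)
  }
}

.write_xyz <- function(ensemble, path) {
  con <- file(path, "w")
  on.exit(close(con))
  at <- ensemble$atoms
  for (f in seq_along(ensemble$coords)) {
    writeLines(as.character(nrow(at)), con)
    writeLines(sprintf("frame %d (nm)", f), con)
    X <- ensemble$coords[[f]]
    writeLines(sprintf("%-2s %12.6f %12.6f %12.6f",
                       at$element, X[, 1], X[, 2], X[, 3]), con)
  }
  jsonlite::write_json(as.character(at$chain), paste0(path, ".chains"))
}

#' Write aggregate geometry as a TSV of centers and radii
#'
#' @param geometry an `aggregate_geometry`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_geometry_tsv <- function(geometry, path) {
  df <- data.frame(x = geometry$centers[, 1], y = geometry$centers[, 2],
                   z = geometry$centers[, 3], r = geometry$radii)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- delimited observable tables with a JSON header line ----

.write_header_table <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", jsonlite::toJSON(header, auto_unbox = TRUE)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

.read_header_table <- function(path) {
  first <- readLines(path, n = 1L)
  header <- if (startsWith(first, "# "))
    jsonlite::fromJSON(sub("^# ", "", first)) else list()
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  list(header = header, data = df)
}

#' Read / write MSD tables
#'
#' Two-column TSV (`lag` ns, `msd` nm^2) with the fit window in a JSON
#' header line.
#'
#' @param series an [msd_series()] (write) / file path (read).
#' @param path file path.
#' @return `read_msd_table()` returns an [msd_series()].
#' @export
write_msd_table <- function(series, path) {
  stopifnot(inherits(series, "msd_series"))
  .write_header_table(data.frame(lag = series$lag, msd = series$msd), path,
                      list(window = series$window))
  invisible(path)
}

#' @rdname write_msd_table
#' @export
read_msd_table <- function(path) {
  x <- .read_header_table(path)
  window <- if (!is.null(x$header$window)) as.numeric(x$header$window) else c(20, 40)
  msd_series(x$data$lag, x$data$msd, window = window)
}

#' Read / write pressure-tensor tables
#'
#' Seven-column TSV (time ps + six deviatoric components, bar) with box
#' volume (nm^3) and temperature (K) in a JSON header line.
#'
#' @param series a [pressure_series()] (write) / file path (read).
#' @param path file path.
#' @return `read_pressure_table()` returns a [pressure_series()].
#' @export
write_pressure_table <- function(series, path) {
  stopifnot(inherits(series, "pressure_series"))
  df <- data.frame(time = series$time, series$P)
  names(df) <- c("time", "Pxy", "Pxz", "Pyz", "Pxxyy", "Pxxzz", "Pyyzz")
  .write_header_table(df, path, list(V = series$V, T = series$T))
  invisible(path)
}

#' @rdname write_pressure_table
#' @export
read_pressure_table <- function(path) {
  x <- .read_header_table(path)
  if (is.null(x$header$V) || is.null(x$header$T))
    stop("pressure table needs V and T in its JSON header line")
  pressure_series(x$data$time, as.matrix(x$data[, 2:7]),
                  V = x$header$V, T = x$header$T)
}

#' Read / write FRAP recovery tables
#'
#' Two-column TSV (`time` s, `intensity` normalized) with the bleach geometry
#' in a JSON header line.
#'
#' @param curve a [recovery_curve()] (write) / file path (read).
#' @param path file path.
#' @return `read_frap_table()` returns a [recovery_curve()].
#' @export
write_frap_table <- function(curve, path) {
  stopifnot(inherits(curve, "recovery_curve"))
  .write_header_table(data.frame(time = curve$time, intensity = curve$intensity),
                      path, list(geometry = curve$geometry))
  invisible(path)
}

#' @rdname write_frap_table
#' @export
read_frap_table <- function(path) {
  x <- .read_header_table(path)
  geometry <- if (!is.null(x$header$geometry)) x$header$geometry else "center"
  recovery_curve(x$data$time, x$data$intensity, geometry)
}

#' Write a fixture together with its ground-truth sidecar JSON
#'
#' Dispatches on the fixture kind (scene, polymer, frap, msd, pressure) and
#' writes the data in the format the matching reader consumes plus
#' `<path>.truth.json` holding the planted parameters.
#'
#' @param x a fixture from one of the `gen_*()` generators.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_fixture <- function(x, path) {
  truth <- ground_truth(x)
  if (is.null(truth)) stop("`x` carries no ground truth; not a fixture?")
  if (inherits(x, "chain_ensemble")) write_structure(x, path)
  else if (inherits(x, "msd_series")) write_msd_table(x, path)
  else if (inherits(x, "pressure_series")) write_pressure_table(x, path)
  else if (inherits(x, "recovery_curve")) write_frap_table(x, path)
  else if (!is.null(x$coords)) {
    ens <- chain_ensemble(data.frame(chain = "A", element = x$elements,
                                     resid = x$resid, restype = x$restype),
                          x$coords)
    write_structure(ens, path)
  } else stop("unsupported fixture type")
  truth$adjacency <- NULL   # matrices stay reproducible from the seed
  jsonlite::write_json(truth, paste0(path, ".truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
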