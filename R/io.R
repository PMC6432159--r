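# Trajectory file formats: extended-XYZ and LAMMPS-dump dialects.
# Both are plain text and gzip-transparent (a ".gz" suffix switches the
# connection).  Positions are printed to 6 decimals.

.traj_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Write a trajectory to disk
#'
#' Extended-XYZ frames carry `Properties=species:S:1:pos:R:3:charge:R:1`
#' and a `Time=` tag; the LAMMPS dialect writes
#' `ITEM: ATOMS id type x y z q` blocks (types: 1 monomer, 2 counterion,
#' 3 coion, 4 wall).
#'
#' @param traj A `trajectory` (or any list with `frames`, `times`,
#'   `species`, `charge`).
#' @param path Output path (".gz" compresses).
#' @param dialect `"xyz"` (extended XYZ) or `"lammps"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, dialect = c("xyz", "lammps")) {
  dialect <- match.arg(dialect)
  con <- .traj_connection(path, "w")
  on.exit(close(con))
  type_of <- c(monomer = 1L, counterion = 2L, coion = 3L, wall = 4L)
  for (fi in seq_along(traj$frames)) {
    p <- traj$frames[[fi]]
    n <- nrow(p)
    if (dialect == "xyz") {
      writeLines(as.character(n), con)
      writeLines(sprintf(
        "Properties=species:S:1:pos:R:3:charge:R:1 Time=%.6f",
        traj$times[fi]), con)
      writeLines(sprintf("%s %.6f %.6f %.6f %.6f",
                         traj$species, p[, 1], p[, 2], p[, 3],
                         traj$charge), con)
    } else {
      writeLines(c("ITEM: TIMESTEP", sprintf("%.6f", traj$times[fi]),
                   "ITEM: NUMBER OF ATOMS", as.character(n),
                   "ITEM: BOX BOUNDS pp pp ff",
                   "0 0", "0 0", "0 0",
                   "ITEM: ATOMS id type x y z q"), con)
      writeLines(sprintf("%d %d %.6f %.6f %.6f %.6f",
                         seq_len(n), unname(type_of[traj$species]),
                         p[, 1], p[, 2], p[, 3], traj$charge), con)
    }
  }
  invisible(path)
}

#' Read a trajectory from disk
#'
#' The dialect is detected from the first line when not given.  Unknown
#' extended-XYZ property columns and extra LAMMPS atom columns are
#' preserved in the `extras` field.
#'
#' @param path Input path (".gz" transparent).
#' @param dialect `"auto"`, `"xyz"` or `"lammps"`.
#' @return A `trajectory` (without a `cfg`; `n_mono` counted from the
#'   species labels).
#' @export
read_trajectory <- function(path, dialect = c("auto", "xyz", "lammps")) {
  dialect <- match.arg(dialect)
  con <- .traj_connection(path, "r")
  lines <- readLines(con)
  close(con)
  if (dialect == "auto")
    dialect <- if (length(lines) && grepl("^ITEM:", lines[1])) "lammps"
  else "xyz"
  if (dialect == "xyz") .read_xyz(lines) else .read_lammps(lines)
}

.read_xyz <- function(lines) {
  frames <- list(); times <- numeric(0)
  species <- NULL; charge <- NULL; extras <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed frame header at line ", i,
                       ": expected an atom count")
    comment <- if (i + 1L <= length(lines)) lines[i + 1L] else
      stop("truncated frame header at line ", i)
    tm <- regmatches(comment, regexpr("Time=[-0-9.eE+]+", comment))
    times <- c(times, if (length(tm)) as.numeric(sub("Time=", "", tm)) else
      length(frames))
    props <- regmatches(comment, regexpr("Properties=[^ ]+", comment))
    fields <- if (length(props)) {
      pp <- strsplit(sub("Properties=", "", props), ":")[[1]]
      data.frame(name = pp[seq(1, length(pp), 3)],
                 width = as.integer(pp[seq(3, length(pp), 3)]))
    } else data.frame(name = c("species", "pos", "charge"),
                      width = c(1L, 3L, 1L))
    if (i + 1L + n > length(lines))
      stop("truncated frame body after line ", i + 1L)
    body <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "[ \t]+")
    ncol_expect <- sum(fields$width)
    if (any(lengths(body) < ncol_expect))
      stop("malformed atom line near line ",
           i + 1L + which(lengths(body) < ncol_expect)[1])
    tab <- do.call(rbind, body)
    col <- 1L
    pos <- NULL; sp <- NULL; q <- NULL; ext <- list()
    for (fidx in seq_len(nrow(fields))) {
      w <- fields$width[fidx]
      block <- tab[, col:(col + w - 1L), drop = FALSE]
      nm <- fields$name[fidx]
      if (nm == "pos") pos <- matrix(as.numeric(block), n, 3)
      else if (nm == "species") sp <- block[, 1]
      else if (nm == "charge") q <- as.numeric(block[, 1])
      else ext[[nm]] <- block
      col <- col + w
    }
    frames[[length(frames) + 1L]] <- pos
    if (is.null(species)) { species <- sp; charge <- q; extras <- ext }
    i <- i + 2L + n
  }
  .as_read_trajectory(frames, times, species, charge, extras)
}

.read_lammps <- function(lines) {
  frames <- list(); times <- numeric(0)
  species <- NULL; charge <- NULL; extras <- list()
  rev_type <- c("monomer", "counterion", "coion", "wall")
  i <- 1L
  while (i <= length(lines)) {
    if (!grepl("^ITEM: TIMESTEP", lines[i]))
      stop("malformed frame header at line ", i, ": expected ITEM: TIMESTEP")
    t <- as.numeric(lines[i + 1L])
    j <- i + 2L
    n <- NA_integer_
    while (j <= length(lines) && !grepl("^ITEM: ATOMS", lines[j])) {
      if (grepl("^ITEM: NUMBER OF ATOMS", lines[j]))
        n <- as.integer(lines[j + 1L])
      j <- j + 1L
    }
    if (j > length(lines) || is.na(n))
      stop("malformed frame near line ", i, ": missing ATOMS block")
    cols <- strsplit(sub("^ITEM: ATOMS ?", "", lines[j]), "[ \t]+")[[1]]
    body <- strsplit(trimws(lines[(j + 1L):(j + n)]), "[ \t]+")
    if (any(lengths(body) < length(cols)))
      stop("malformed atom line near line ",
           j + which(lengths(body) < length(cols))[1])
    tab <- do.call(rbind, body)
    colnames(tab) <- cols
    ord <- order(as.integer(tab[, "id"]))
    tab <- tab[ord, , drop = FALSE]
    pos <- matrix(as.numeric(tab[, c("x", "y", "z")]), n, 3)
    frames[[length(frames) + 1L]] <- pos
    times <- c(times, t)
    if (is.null(species)) {
      ty <- as.integer(tab[, "type"])
      species <- rev_type[pmin(pmax(ty, 1L), 4L)]
      charge <- if ("q" %in% cols) as.numeric(tab[, "q"]) else rep(0, n)
      known <- c("id", "type", "x", "y", "z", "q")
      for (cn in setdiff(cols, known)) extras[[cn]] <- tab[, cn]
    }
    i <- j + n + 1L
  }
  .as_read_trajectory(frames, times, species, charge, extras)
}

.as_read_trajectory <- function(frames, times, species, charge, extras) {
  structure(list(frames = frames, times = times,
                 n_mono = sum(species == "monomer"),
                 species = species, charge = charge, extras = extras,
                 cfg = NULL),
            class = "trajectory")
}

#' Write a built state as a single extended-XYZ frame
#'
#' @param state A `particle_state`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_state_xyz <- function(state, path) {
  traj <- list(frames = list(state$pos), times = 0,
               species = state$species, charge = state$charge)
  write_trajectory(traj, path, "xyz")
}
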