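#' Write a system in LAMMPS-style data format
#'
#' Orthorhombic box `[0, L)`, `Atoms # full` columns
#' (`id mol type q x y z`), `Masses` with a `# name` comment per type so
#' bead type names round-trip, plus `Bonds`/`Angles` when present (one
#' generic bond/angle type id per distinct bead-type pattern).
#' Coordinates are printed with 17 significant digits for exact
#' round-trips.
#'
#' @param sys a `cg_system`
#' @param ff a `cg_forcefield` (masses and charges)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_lammps_data <- function(sys, ff, path) {
  ti <- system_type_index(sys)
  bt <- ff$bead_types[match(ti$names, ff$bead_types$name), ]
  num <- function(x) sprintf("%.17g", x)
  N <- n_beads(sys)
  nb <- if (is.null(sys$bonds)) 0 else nrow(sys$bonds)
  na <- if (is.null(sys$angles)) 0 else nrow(sys$angles)
  ln <- c("cgionfit data file", "",
          paste(N, "atoms"), paste(nb, "bonds"), paste(na, "angles"), "",
          paste(length(ti$names), "atom types"),
          paste(max(1, nb > 0), "bond types"),
          paste(max(1, na > 0), "angle types"), "",
          paste(0, num(sys$box[1]), "xlo xhi"),
          paste(0, num(sys$box[2]), "ylo yhi"),
          paste(0, num(sys$box[3]), "zlo zhi"), "", "Masses", "")
  for (i in seq_along(ti$names))
    ln <- c(ln, paste(i, num(bt$mass[i]), "#", ti$names[i]))
  ln <- c(ln, "", "Atoms # full", "")
  q <- bt$charge[ti$idx0 + 1]
  for (i in seq_len(N))
    ln <- c(ln, paste(i, 1, ti$idx0[i] + 1, num(q[i]),
                      num(sys$pos[i, 1]), num(sys$pos[i, 2]),
                      num(sys$pos[i, 3])))
  if (nb > 0) {
    ln <- c(ln, "", "Bonds", "")
    for (e in seq_len(nb))
      ln <- c(ln, paste(e, 1, sys$bonds[e, 1], sys$bonds[e, 2]))
  }
  if (na > 0) {
    ln <- c(ln, "", "Angles", "")
    for (e in seq_len(na))
      ln <- c(ln, paste(e, 1, sys$angles[e, 1], sys$angles[e, 2],
                        sys$angles[e, 3]))
  }
  writeLines(ln, path)
  invisible(path)
}

#' Read a LAMMPS-style data file written by [write_lammps_data()]
#'
#' @param path input path
#' @return a `cg_system` (type names recovered from the `Masses`
#'   comments)
#' @export
read_lammps_data <- function(path) {
  ln <- readLines(path)
  if (!length(ln)) stop("empty data file: ", path)
  counts <- function(word) {
    i <- grep(paste0("^\\s*\\d+\\s+", word, "\\s*$"), ln)
    if (!length(i)) return(0L)
    as.integer(sub("^\\s*(\\d+).*", "\\1", ln[i[1]]))
  }
  N <- counts("atoms"); nb <- counts("bonds"); na <- counts("angles")
  if (N == 0) stop("no atoms in data file: ", path)
  box <- sapply(c("xlo xhi", "ylo yhi", "zlo zhi"), function(tag) {
    i <- grep(tag, ln, fixed = TRUE)[1]
    v <- as.numeric(strsplit(trimws(ln[i]), "\\s+")[[1]][1:2])
    v[2] - v[1]
  })
  section <- function(name, n) {
    i <- grep(paste0("^", name, "\\b"), ln)[1]
    if (is.na(i)) return(NULL)
    body <- ln[-(1:i)]
    body <- body[trimws(body) != ""]
    if (length(body) < n)
      stop("truncated ", name, " section in ", path, ": expected ", n,
           " rows, found ", length(body))
    body[seq_len(n)]
  }
  nt_line <- grep("atom types", ln)[1]
  ntypes <- as.integer(sub("^\\s*(\\d+).*", "\\1", ln[nt_line]))
  mrows <- section("Masses", ntypes)
  tn <- sub(".*#\\s*", "", mrows)
  arows <- strsplit(trimws(section("Atoms", N)), "\\s+")
  id <- vapply(arows, function(p) as.integer(p[1]), 1L)
  tyi <- vapply(arows, function(p) as.integer(p[3]), 1L)
  xyz <- t(vapply(arows, function(p) as.numeric(p[5:7]), numeric(3)))
  ord <- order(id)
  bonds <- angles <- NULL
  if (nb > 0) {
    brows <- strsplit(trimws(section("Bonds", nb)), "\\s+")
    bonds <- t(vapply(brows, function(p) as.integer(p[3:4]), integer(2)))
  }
  if (na > 0) {
    rows <- strsplit(trimws(section("Angles", na)), "\\s+")
    angles <- t(vapply(rows, function(p) as.integer(p[3:5]), integer(3)))
  }
  cg_system(xyz[ord, , drop = FALSE], box, tn[tyi[ord]],
            bonds = bonds, angles = angles)
}

#' Write trajectory frames in LAMMPS-style dump format
#'
#' One `ITEM: TIMESTEP / NUMBER OF ATOMS / BOX BOUNDS / ATOMS` block per
#' stored frame with columns `id type x y z vx vy vz`; 17 significant
#' digits, so coordinates round-trip exactly.
#'
#' @param traj a `cg_trajectory` with stored frames
#' @param path output path
#' @return `path`, invisibly
#' @export
write_lammps_dump <- function(traj, path) {
  if (!length(traj$frames)) stop("trajectory has no stored frames")
  num <- function(x) sprintf("%.17g", x)
  con <- file(path, "w")
  on.exit(close(con))
  tn <- sort(unique(traj$types))
  for (k in seq_along(traj$frames)) {
    fr <- traj$frames[[k]]
    N <- nrow(fr$pos)
    writeLines(c("ITEM: TIMESTEP", format(fr$time, scientific = FALSE),
                 "ITEM: NUMBER OF ATOMS", as.character(N),
                 "ITEM: BOX BOUNDS pp pp pp",
                 paste(0, num(fr$box[1])), paste(0, num(fr$box[2])),
                 paste(0, num(fr$box[3])),
                 "ITEM: ATOMS id type x y z vx vy vz"), con)
    ty <- match(traj$types, tn)
    writeLines(paste(seq_len(N), ty,
                     num(fr$pos[, 1]), num(fr$pos[, 2]), num(fr$pos[, 3]),
                     num(fr$vel[, 1]), num(fr$vel[, 2]), num(fr$vel[, 3])),
               con)
  }
  invisible(path)
}

#' Read a LAMMPS-style dump file
#'
#' Atoms are re-sorted by id within each frame. Truncated files raise an
#' error naming the offending frame and line.
#'
#' @param path dump file path
#' @return list of frames, each `list(time, box, pos, vel, type)`
#' @export
read_lammps_dump <- function(path) {
  ln <- readLines(path)
  if (!length(ln)) stop("empty dump file: ", path)
  frames <- list()
  i <- 1; nline <- length(ln)
  while (i <= nline) {
    if (ln[i] != "ITEM: TIMESTEP")
      stop("malformed dump at line ", i, ": expected ITEM: TIMESTEP")
    if (i + 8 > nline)
      stop("truncated dump header at line ", i, " (frame ",
           length(frames) + 1, ")")
    time <- as.numeric(ln[i + 1])
    N <- as.integer(ln[i + 3])
    box <- vapply(0:2, function(d) {
      v <- as.numeric(strsplit(trimws(ln[i + 5 + d]), "\\s+")[[1]])
      v[2] - v[1]
    }, numeric(1))
    a0 <- i + 9
    if (a0 + N - 1 > nline)
      stop("truncated dump at frame ", length(frames) + 1, ": expected ",
           N, " atom rows from line ", a0)
    rows <- strsplit(trimws(ln[a0:(a0 + N - 1)]), "\\s+")
    mat <- t(vapply(rows, function(p) as.numeric(p), numeric(length(rows[[1]]))))
    ord <- order(mat[, 1])
    mat <- mat[ord, , drop = FALSE]
    frames[[length(frames) + 1]] <-
      list(time = time, box = box, type = as.integer(mat[, 2]),
           pos = mat[, 3:5, drop = FALSE],
           vel = if (ncol(mat) >= 8) mat[, 6:8, drop = FALSE] else NULL)
    i <- a0 + N
  }
  frames
}

#' Write observable results as CSV
#'
#' One row per observable: value, block-average uncertainty, analysis
#' window and block count — the standard results artifact of the
#' analysis stage.
#'
#' @param results named list of `cg_observable`s
#' @param path output CSV path
#' @return the data frame written, invisibly
#' @export
write_observables_csv <- function(results, path) {
  df <- do.call(rbind, lapply(names(results), function(nm) {
    ob <- results[[nm]]
    data.frame(observable = nm, value = ob$value,
               uncertainty = ob$uncertainty,
               window_start_fs = ob$window[1], window_end_fs = ob$window[2],
               n_blocks = ob$n_blocks)
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
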