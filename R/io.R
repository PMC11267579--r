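# File formats: a hierarchical JSON archive with lossless binary-encoded
# numeric arrays (used for topologies, trajectories and checkpoints), GRO
# coordinate files, and tab-separated density profiles.

# ---- hierarchical archive -------------------------------------------------

# Numeric data are stored as base64-encoded little-endian doubles with the
# array dimensions alongside, so write/read round trips are bitwise exact;
# everything else is plain JSON.  Groups are nested named lists.

encode_node <- function(x) {
  if (is.double(x)) {
    list(`_type` = "f64", dim = if (is.null(dim(x))) length(x) else dim(x),
         data = jsonlite::base64_enc(writeBin(as.vector(x), raw(),
                                              size = 8, endian = "little")))
  } else if (is.integer(x)) {
    list(`_type` = "i32", dim = if (is.null(dim(x))) length(x) else dim(x),
         data = as.vector(x))
  } else if (is.character(x) || is.logical(x)) {
    list(`_type` = if (is.character(x)) "str" else "bool", data = x)
  } else if (is.data.frame(x)) {
    list(`_type` = "table", columns = lapply(as.list(x), encode_node))
  } else if (is.list(x)) {
    lapply(x, encode_node)
  } else if (is.null(x)) {
    list(`_type` = "null")
  } else {
    stop("cannot archive object of class ", class(x)[1])
  }
}

decode_node <- function(x) {
  if (is.list(x) && !is.null(x$`_type`)) {
    switch(x$`_type`,
      f64 = {
        raw <- jsonlite::base64_dec(x$data)
        v <- readBin(raw, "double", n = length(raw) / 8, size = 8,
                     endian = "little")
        d <- unlist(x$dim)
        if (length(d) > 1) dim(v) <- d
        v
      },
      i32 = {
        v <- as.integer(unlist(x$data))
        d <- unlist(x$dim)
        if (length(d) > 1) dim(v) <- d
        v
      },
      str = as.character(unlist(x$data)),
      bool = as.logical(unlist(x$data)),
      table = as.data.frame(lapply(x$columns, decode_node),
                            stringsAsFactors = FALSE),
      null = NULL,
      stop("unknown archive node type ", x$`_type`))
  } else if (is.list(x)) {
    lapply(x, decode_node)
  } else {
    x
  }
}

#' Write a hierarchical archive
#'
#' Serialises nested lists of numeric arrays, integer vectors, strings and
#' data frames to a JSON container in which double-precision data are
#' base64-encoded raw bytes; the round trip through [read_archive()] is
#' bitwise lossless.
#'
#' @param obj nested list.
#' @param path output path.
#' @export
write_archive <- function(obj, path) {
  json <- jsonlite::toJSON(encode_node(obj), auto_unbox = TRUE,
                           digits = NA, null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Read a hierarchical archive
#'
#' @param path path written by [write_archive()].
#' @return the reconstructed nested list.
#' @export
read_archive <- function(path) {
  if (!file.exists(path)) stop("no such archive: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  if (!nzchar(txt)) stop("truncated archive: ", path)
  decode_node(jsonlite::fromJSON(txt, simplifyVector = FALSE))
}

# topology <-> archive layout: groups /species, /particles, /bonds,
# /angles, /parameters
topo_to_archive <- function(topo) {
  list(species = topo$species,
       particles = list(species = topo$particle_species,
                        molecule = topo$particle_mol,
                        mass = topo$masses, charge = topo$charges),
       bonds = topo$bonds, angles = topo$angles,
       parameters = list(n_lipids = topo$n_lipids,
                         lipid_mols = topo$lipid_mols,
                         angle_form = topo$angle_form))
}

archive_to_topo <- function(arc) {
  topology(arc$species, arc$particles$species, arc$particles$molecule,
           arc$particles$mass, arc$particles$charge, arc$bonds,
           arc$angles, arc$parameters$n_lipids, arc$parameters$lipid_mols,
           arc$parameters$angle_form)
}

# ---- trajectories ---------------------------------------------------------

#' Write a trajectory segment
#'
#' Frames are stored in an H5MD-style grouped layout (`particles/position`,
#' `particles/velocity`, `particles/box`, `particles/time`) inside the
#' hierarchical archive; the round trip is bitwise lossless.  Writing zero
#' frames produces a valid empty file.
#'
#' @param frames list of states.
#' @param path output path.
#' @export
write_trajectory <- function(frames, path) {
  nf <- length(frames)
  n <- if (nf) nrow(frames[[1]]$R) else 0L
  pos <- array(0, c(nf, n, 3))
  vel <- array(0, c(nf, n, 3))
  boxes <- matrix(0, nf, 3)
  times <- numeric(nf)
  for (i in seq_len(nf)) {
    pos[i, , ] <- frames[[i]]$R
    vel[i, , ] <- frames[[i]]$V
    boxes[i, ] <- frames[[i]]$box
    times[i] <- frames[[i]]$time
  }
  write_archive(list(particles = list(position = pos, velocity = vel,
                                      box = boxes, time = times),
                     n_frames = as.integer(nf)), path)
}

#' Read a trajectory segment
#'
#' @param path path written by [write_trajectory()].
#' @return list of states.
#' @export
read_trajectory <- function(path) {
  arc <- read_archive(path)
  nf <- arc$n_frames
  frames <- vector("list", nf)
  for (i in seq_len(nf)) {
    frames[[i]] <- system_state(matrix(arc$particles$position[i, , ],
                                       ncol = 3),
                                matrix(arc$particles$velocity[i, , ],
                                       ncol = 3),
                                arc$particles$box[i, ],
                                arc$particles$time[i])
  }
  frames
}

# ---- GRO ------------------------------------------------------------------

#' Write a GRO coordinate file
#'
#' Positions are wrapped into the box; velocities are written when
#' present.  Atom and residue names come from the topology species table.
#'
#' @param state system state.
#' @param topo topology (for names); optional.
#' @param path output path.
#' @param title header line.
#' @export
write_gro <- function(state, topo = NULL, path, title = "hhpf") {
  st <- wrap_positions(state)
  n <- nrow(st$R)
  anames <- if (!is.null(topo))
    topo$species$name[topo$particle_species] else rep("BD", n)
  resid <- if (!is.null(topo)) topo$particle_mol else seq_len(n)
  lines <- c(title, sprintf("%5d", n))
  hasv <- any(st$V != 0)
  for (i in seq_len(n)) {
    base <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                    resid[i] %% 100000, substr(anames[i], 1, 5),
                    substr(anames[i], 1, 5), i %% 100000,
                    st$R[i, 1], st$R[i, 2], st$R[i, 3])
    if (hasv)
      base <- paste0(base, sprintf("%8.4f%8.4f%8.4f", st$V[i, 1],
                                   st$V[i, 2], st$V[i, 3]))
    lines <- c(lines, base)
  }
  lines <- c(lines, sprintf("%10.5f%10.5f%10.5f", st$box[1], st$box[2],
                            st$box[3]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GRO coordinate file
#'
#' @param path input path.
#' @param topo optional topology; the particle count must match.
#' @return system state (velocities zero when absent from the file).
#' @export
read_gro <- function(path, topo = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) stop("GRO file too short: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) stop("malformed atom count on line 2 of ", path)
  if (length(lines) < n + 3) stop("GRO file truncated: ", path)
  if (!is.null(topo) && length(topo$particle_species) != n)
    stop("GRO has ", n, " particles but the topology has ",
         length(topo$particle_species))
  R <- matrix(0, n, 3)
  V <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    ln <- lines[2 + i]
    if (nchar(ln) < 44)
      stop("malformed GRO line ", 2 + i, " in ", path)
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 21, 28),
                                         substr(ln, 29, 36),
                                         substr(ln, 37, 44))))
    if (any(is.na(xyz)))
      stop("malformed coordinates on GRO line ", 2 + i, " in ", path)
    R[i, ] <- xyz
    if (nchar(ln) >= 68) {
      vv <- suppressWarnings(as.numeric(c(substr(ln, 45, 52),
                                          substr(ln, 53, 60),
                                          substr(ln, 61, 68))))
      if (!any(is.na(vv))) V[i, ] <- vv
    }
  }
  box <- suppressWarnings(as.numeric(strsplit(trimws(lines[n + 3]),
                                              "\\s+")[[1]]))[1:3]
  if (any(is.na(box)))
    stop("malformed box line ", n + 3, " in ", path)
  system_state(R, V, box)
}

# ---- profiles -------------------------------------------------------------

#' Write a density profile as tab-separated text
#'
#' Column 1 is the bin center z (nm) followed by one column per species
#' (nm^-3), with a header row of species names; the bandwidth is kept in a
#' leading comment.
#'
#' @param profile `hhpf_profile`.
#' @param path output path.
#' @param species_names column names.
#' @export
write_profile_tsv <- function(profile, path,
                              species_names = colnames(profile$rho)) {
  if (is.null(species_names))
    species_names <- paste0("s", seq_len(ncol(profile$rho)))
  df <- data.frame(z = profile$z, profile$rho)
  names(df) <- c("z", species_names)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# h\t%.17g", profile$h), con)
  write.table(format(df, digits = 17, trim = TRUE), con, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a density profile from tab-separated text
#'
#' @param path path written by [write_profile_tsv()].
#' @return `hhpf_profile`.
#' @export
read_profile_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  h <- NA
  hl <- grep("^# h\t", lines)
  if (length(hl)) h <- as.numeric(sub("^# h\t", "", lines[hl[1]]))
  df <- read.table(text = lines[!startsWith(lines, "#")], header = TRUE,
                   sep = "\t", check.names = FALSE)
  z <- df[[1]]
  rho <- as.matrix(df[, -1, drop = FALSE])
  dz <- if (length(z) > 1) z[2] - z[1] else NA
  structure(list(z = z, rho = rho, dz = dz,
                 h = if (is.na(h)) dz else h),
            class = "hhpf_profile")
}
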