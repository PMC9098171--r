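# Extended-XYZ trajectory output plus a molecule-map sidecar CSV
# (bead_index, molecule_id, molecule_name), the dialect consumed by the
# analysis functions.

#' Write a trajectory to extended XYZ
#'
#' One block per frame: the bead count, a comment line
#' `step=<n> L=<box>`, then `name x y z` records. The molecule map goes to
#' a sidecar CSV when a path is given.
#'
#' @param traj a `dpd_trajectory`.
#' @param file output XYZ path.
#' @param molmap_file optional sidecar CSV path for the molecule map.
#' @export
write_trajectory_xyz <- function(traj, file, molmap_file = NULL) {
  stopifnot(inherits(traj, "dpd_trajectory"))
  con <- file(file, "w")
  on.exit(close(con))
  n <- length(traj$bead_names)
  for (f in seq_along(traj$frames)) {
    writeLines(as.character(n), con)
    writeLines(sprintf("step=%d L=%.8f", traj$steps[f], traj$L[f]), con)
    p <- traj$frames[[f]]
    writeLines(sprintf("%s %.8f %.8f %.8f", traj$bead_names,
                       p[, 1], p[, 2], p[, 3]), con)
  }
  if (!is.null(molmap_file)) {
    write.csv(data.frame(bead_index = seq_len(n),
                         molecule_id = traj$molecule_id,
                         molecule_name = traj$molecule_name),
              molmap_file, row.names = FALSE)
  }
  invisible(file)
}

#' Read an extended-XYZ trajectory
#'
#' Inverse of [write_trajectory_xyz()]. The molecule map sidecar restores
#' molecule identities; without one, all beads are unassigned.
#'
#' @param file XYZ path.
#' @param molmap_file optional sidecar CSV path.
#' @return a `dpd_trajectory` (frames, steps, box sides, bead names,
#'   molecule map; no velocities or observable series).
#' @export
read_trajectory_xyz <- function(file, molmap_file = NULL) {
  lines <- readLines(file)
  frames <- list(); steps <- integer(); Ls <- numeric()
  bead_names <- NULL
  i <- 1L
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    if (is.na(n)) stop("malformed XYZ: expected a bead count at line ", i)
    hdr <- lines[i + 1L]
    step <- as.integer(sub(".*step=([0-9]+).*", "\\1", hdr))
    L <- as.numeric(sub(".*L=([0-9.eE+-]+).*", "\\1", hdr))
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(block, "[ \t]+")
    nm <- vapply(parts, `[[`, "", 1L)
    xyz <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))),
                  ncol = 3, byrow = TRUE)
    if (is.null(bead_names)) bead_names <- nm
    frames[[length(frames) + 1L]] <- xyz
    steps <- c(steps, step)
    Ls <- c(Ls, L)
    i <- i + 2L + n
  }
  molecule_id <- rep(NA_integer_, length(bead_names))
  molecule_name <- rep(NA_character_, length(bead_names))
  if (!is.null(molmap_file)) {
    mm <- read.csv(molmap_file, stringsAsFactors = FALSE)
    molecule_id[mm$bead_index] <- mm$molecule_id
    molecule_name[mm$bead_index] <- mm$molecule_name
  }
  structure(list(frames = frames, steps = steps, L = Ls,
                 temperature = numeric(), pressure = numeric(),
                 potential = numeric(), kinetic = numeric(),
                 bead_names = bead_names, molecule_id = molecule_id,
                 molecule_name = molecule_name,
                 final = list(positions = frames[[length(frames)]],
                              velocities = NULL, L = Ls[length(Ls)]),
                 settings = NULL, system_seed = NA_integer_),
            class = "dpd_trajectory")
}
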