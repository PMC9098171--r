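# Force-field container: pairwise soft-repulsion table, bead metadata,
# molecule topologies, and ion overrides.

# Primed bead names are serialized with a trailing "p" (OH' -> OHp,
# AC' -> ACp); both spellings (unicode prime or ASCII apostrophe) are
# accepted on input.
.normalize_bead <- function(x) {
  x <- gsub("′", "p", x)
  x <- gsub("'", "p", x)
  x
}

.base_bead_roles <- function() {
  data.frame(
    name   = c("W", "T", "T2", "C2", "AM3", "OH", "OHp", "OH2", "ACp", "EO"),
    charge = 0L,
    role   = c("water", "tail", "tail", "tail", "head", "head", "head",
               "head", "head", "head"),
    stringsAsFactors = FALSE
  )
}

.default_ion_beads <- function() {
  data.frame(
    name   = c("Li+", "Na+", "K+", "Cs+", "Cl-", "Br-", "I-", "NO3-", "SCN-"),
    charge = c(1L, 1L, 1L, 1L, -1L, -1L, -1L, -1L, -1L),
    role   = c(rep("cation", 4), rep("anion", 5)),
    stringsAsFactors = FALSE
  )
}

.pair_key <- function(b1, b2) {
  paste(pmin(b1, b2), pmax(b1, b2), sep = "|")
}

#' Load a DPD force field from a pairwise-interaction table
#'
#' Reads a tab-separated table with columns `bead1`, `bead2`, `a`
#' (repulsion amplitude in kBT) and `R` (cutoff in r_c), one row per
#' unordered bead pair, and returns a validated force field. The builtin
#' table ships the published parameter set for the surfactant bead types
#' (10 self pairs + 30 cross pairs). Monovalent ion beads (Li+, Na+, K+,
#' Cs+, Cl-, Br-, I-, NO3-, SCN-) are registered as charged water beads:
#' any pair involving an ion without an explicit override resolves to the
#' corresponding water-bead pair.
#'
#' @param table_path path to a force-field TSV, or `"builtin"` for the
#'   packaged table.
#' @return an object of class `dpd_forcefield`.
#' @export
load_default_forcefield <- function(table_path = "builtin") {
  if (identical(table_path, "builtin")) {
    table_path <- system.file("extdata", "forcefield.tsv", package = "setsolv")
  }
  raw <- tryCatch(
    read.delim(table_path, stringsAsFactors = FALSE),
    error = function(e) stop("cannot read force-field table '", table_path,
                             "': ", conditionMessage(e))
  )
  need <- c("bead1", "bead2", "a", "R")
  if (!all(need %in% names(raw))) {
    stop("force-field table must have columns bead1, bead2, a, R")
  }
  raw$bead1 <- .normalize_bead(raw$bead1)
  raw$bead2 <- .normalize_bead(raw$bead2)
  for (col in c("a", "R")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop("malformed force-field row at line ", bad[1] + 1L,
           ": non-numeric '", col, "' value '", raw[[col]][bad[1]], "'")
    }
    raw[[col]] <- v
  }
  if (any(raw$a < 0)) stop("repulsion amplitudes must be >= 0")
  if (any(raw$R <= 0)) stop("cutoffs must be > 0")
  keys <- .pair_key(raw$bead1, raw$bead2)
  if (anyDuplicated(keys)) {
    d <- keys[duplicated(keys)][1]
    stop("duplicate unordered pair in force-field table: ", d)
  }
  beads <- rbind(.base_bead_roles(), .default_ion_beads())
  extra <- setdiff(unique(c(raw$bead1, raw$bead2)), beads$name)
  if (length(extra)) {
    beads <- rbind(beads, data.frame(name = extra, charge = 0L,
                                     role = "head", stringsAsFactors = FALSE))
  }
  ff <- structure(
    list(beads = beads,
         pairs = data.frame(bead1 = raw$bead1, bead2 = raw$bead2,
                            a = raw$a, R = raw$R, key = keys,
                            stringsAsFactors = FALSE)),
    class = "dpd_forcefield")
  ff
}

#' @export
print.dpd_forcefield <- function(x, ...) {
  cat("DPD force field:", nrow(x$pairs), "explicit pairs,",
      nrow(x$beads), "bead types (",
      sum(x$beads$role %in% c("cation", "anion")), "ion beads )\n")
  invisible(x)
}

#' Register additional ion bead types
#'
#' Ion beads behave as charged water beads: all their short-range
#' interactions are inherited from W unless overridden via
#' [with_ion_overrides()]. Only monovalent charges are supported.
#'
#' @param ff a `dpd_forcefield`.
#' @param names character vector of ion bead names.
#' @param charges integer vector of +1/-1 valences.
#' @return a new `dpd_forcefield`.
#' @export
add_ion_beads <- function(ff, names, charges) {
  stopifnot(inherits(ff, "dpd_forcefield"), length(names) == length(charges))
  if (!all(charges %in% c(-1L, 1L))) {
    stop("ion beads must carry charge +1 or -1 (monovalent scope)")
  }
  names <- .normalize_bead(names)
  dup <- intersect(names, ff$beads$name)
  if (length(dup)) stop("bead name(s) already defined: ",
                        paste(dup, collapse = ", "))
  ff$beads <- rbind(ff$beads, data.frame(
    name = names, charge = as.integer(charges),
    role = ifelse(charges > 0, "cation", "anion"), stringsAsFactors = FALSE))
  ff
}

bead_info <- function(ff, name) {
  i <- match(name, ff$beads$name)
  if (is.na(i)) stop("unknown bead '", name, "'")
  ff$beads[i, , drop = FALSE]
}

bead_charge <- function(ff, names) {
  i <- match(.normalize_bead(names), ff$beads$name)
  if (anyNA(i)) stop("unknown bead(s): ",
                     paste(names[is.na(i)], collapse = ", "))
  ff$beads$charge[i]
}

#' Look up the interaction parameters for a bead pair
#'
#' Lookup is symmetric. Pairs involving ion beads with no explicit
#' override resolve through the ion-as-charged-water rule: the ion is
#' replaced by W and the corresponding water pair is returned. A pair that
#' is neither tabulated nor coverable by that rule raises an error rather
#' than silently defaulting.
#'
#' @param ff a `dpd_forcefield`.
#' @param b1,b2 bead names.
#' @return a list with elements `bead1`, `bead2`, `a` (kBT), `R` (r_c).
#' @export
pair_lookup <- function(ff, b1, b2) {
  stopifnot(inherits(ff, "dpd_forcefield"))
  b1 <- .normalize_bead(b1); b2 <- .normalize_bead(b2)
  i1 <- match(b1, ff$beads$name); i2 <- match(b2, ff$beads$name)
  if (is.na(i1)) stop("unknown bead '", b1, "'")
  if (is.na(i2)) stop("unknown bead '", b2, "'")
  k <- .pair_key(b1, b2)
  hit <- match(k, ff$pairs$key)
  if (!is.na(hit)) {
    return(list(bead1 = b1, bead2 = b2,
                a = ff$pairs$a[hit], R = ff$pairs$R[hit]))
  }
  # ion-as-water substitution
  s1 <- if (ff$beads$role[i1] %in% c("cation", "anion")) "W" else b1
  s2 <- if (ff$beads$role[i2] %in% c("cation", "anion")) "W" else b2
  if (!identical(s1, b1) || !identical(s2, b2)) {
    k2 <- .pair_key(s1, s2)
    hit <- match(k2, ff$pairs$key)
    if (!is.na(hit)) {
      return(list(bead1 = b1, bead2 = b2,
                  a = ff$pairs$a[hit], R = ff$pairs$R[hit]))
    }
  }
  stop("no interaction parameters for pair (", b1, ", ", b2,
       "): absent from the table and not coverable by the ion-as-water rule")
}

#' Apply ion-specific repulsion overrides
#'
#' Returns a new force field in which the listed ion-bead pairs carry the
#' given repulsion amplitudes. The cutoff of an overridden ion-tail pair is
#' inherited from the corresponding water-tail pair (only amplitudes are
#' ion-specific). By default targets must be tail beads (T, T2, C2) and
#' amplitudes must lie in the screened range 35-150 kBT; both restrictions
#' can be lifted explicitly.
#'
#' @param ff a `dpd_forcefield`.
#' @param overrides either a data.frame with columns `ion`, `bead`,
#'   `amplitude`, or a named numeric vector `c("Na+" = 72, ...)` applied to
#'   all three tail beads.
#' @param allow_out_of_range allow amplitudes outside 35-150.
#' @param allow_nontail allow override targets that are not tail beads
#'   (the head/water screening mode).
#' @return a new `dpd_forcefield`; the input is unmodified.
#' @export
with_ion_overrides <- function(ff, overrides, allow_out_of_range = FALSE,
                               allow_nontail = FALSE) {
  stopifnot(inherits(ff, "dpd_forcefield"))
  if (is.numeric(overrides) && !is.null(names(overrides))) {
    tails <- c("T", "T2", "C2")
    overrides <- data.frame(
      ion = rep(names(overrides), each = length(tails)),
      bead = rep(tails, times = length(overrides)),
      amplitude = rep(unname(overrides), each = length(tails)),
      stringsAsFactors = FALSE)
  }
  if (nrow(overrides) == 0L) return(ff)
  stopifnot(all(c("ion", "bead", "amplitude") %in% names(overrides)))
  overrides$ion <- .normalize_bead(overrides$ion)
  overrides$bead <- .normalize_bead(overrides$bead)
  for (r in seq_len(nrow(overrides))) {
    ion <- overrides$ion[r]; bead <- overrides$bead[r]
    amp <- overrides$amplitude[r]
    irole <- bead_info(ff, ion)$role
    brole <- bead_info(ff, bead)$role
    if (!irole %in% c("cation", "anion")) {
      stop("override source '", ion, "' is not an ion bead")
    }
    if (brole != "tail" && !allow_nontail) {
      stop("override target '", bead, "' is not a tail bead; ",
           "set allow_nontail = TRUE to screen head/water interactions")
    }
    if ((amp < 35 || amp > 150) && !allow_out_of_range) {
      stop("override amplitude ", amp, " outside the screened range ",
           "[35, 150] kBT; set allow_out_of_range = TRUE to permit")
    }
    base <- pair_lookup(ff, "W", bead)
    k <- .pair_key(ion, bead)
    hit <- match(k, ff$pairs$key)
    row <- data.frame(bead1 = ion, bead2 = bead, a = amp, R = base$R,
                      key = k, stringsAsFactors = FALSE)
    if (is.na(hit)) ff$pairs <- rbind(ff$pairs, row)
    else ff$pairs[hit, ] <- row
  }
  ff
}

#' Build tail overrides from an ion-parameter table
#'
#' Expands a table with columns `ion` and `amplitude` (as in the packaged
#' ion parameter file) into per-tail-bead overrides for T, T2 and C2.
#'
#' @param ion_params data.frame with columns `ion`, `amplitude`.
#' @return a data.frame accepted by [with_ion_overrides()].
#' @export
ion_tail_overrides <- function(ion_params) {
  stopifnot(all(c("ion", "amplitude") %in% names(ion_params)))
  v <- setNames(ion_params$amplitude, ion_params$ion)
  tails <- c("T", "T2", "C2")
  data.frame(ion = rep(names(v), each = 3L),
             bead = rep(tails, times = length(v)),
             amplitude = rep(unname(v), each = 3L),
             stringsAsFactors = FALSE)
}

#' Write a force field to TSV
#'
#' Serializes all explicit pairs (including ion overrides) in the same
#' four-column dialect read by [load_default_forcefield()]; reloading
#' reproduces every amplitude and cutoff exactly.
#'
#' @param ff a `dpd_forcefield`.
#' @param path output file path.
#' @export
write_forcefield <- function(ff, path) {
  stopifnot(inherits(ff, "dpd_forcefield"))
  out <- ff$pairs[, c("bead1", "bead2", "a", "R")]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# --------------------------------------------------------------------------
# Molecule topologies

#' Load a molecule topology from a YAML config
#'
#' The config carries `name`, `beads` (ordered bead names), `bonds`
#' (1-based indices i, j with equilibrium length `r0` in r_c), `angles`
#' (i, j, k with `theta0_deg`), `head_beads`, `tail_beads` and optionally
#' `molar_mass` (g/mol, used for wt% conversions). Equilibrium values have
#' no universal default and must be present. Topologies packaged under
#' `extdata/topologies` are approximate representations.
#'
#' @param path YAML file path, or one of the packaged names
#'   ("MEGA8", "MEGA9", "GLUCO8", "C12E6", "AMPH4").
#' @return an object of class `dpd_topology`.
#' @export
load_topology <- function(path) {
  builtin <- c(MEGA8 = "mega8", MEGA9 = "mega9", GLUCO8 = "gluco8",
               C12E6 = "c12e6", AMPH4 = "amph4")
  if (path %in% names(builtin)) {
    path <- system.file("extdata", "topologies",
                        paste0(builtin[[path]], ".yaml"), package = "setsolv")
  }
  cfg <- yaml::read_yaml(path)
  need <- c("name", "beads", "bonds")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("topology config missing key(s): ",
                         paste(miss, collapse = ", "))
  beads <- .normalize_bead(unlist(cfg$beads))
  bonds <- do.call(rbind, lapply(cfg$bonds, function(b) {
    if (is.null(b$r0)) stop("bond in topology '", cfg$name,
                            "' lacks required r0")
    data.frame(i = b$i, j = b$j, r0 = b$r0)
  }))
  angles <- if (length(cfg$angles)) {
    do.call(rbind, lapply(cfg$angles, function(a) {
      if (is.null(a$theta0_deg)) stop("angle in topology '", cfg$name,
                                      "' lacks required theta0_deg")
      data.frame(i = a$i, j = a$j, k = a$k, theta0 = a$theta0_deg * pi / 180)
    }))
  } else {
    data.frame(i = integer(), j = integer(), k = integer(),
               theta0 = numeric())
  }
  topo <- structure(
    list(name = cfg$name, beads = beads, bonds = bonds, angles = angles,
         head_beads = .normalize_bead(unlist(cfg$head_beads)),
         tail_beads = .normalize_bead(unlist(cfg$tail_beads)),
         molar_mass = cfg$molar_mass,
         approximate = isTRUE(cfg$approximate)),
    class = "dpd_topology")
  .validate_topology_shape(topo)
  topo
}

.validate_topology_shape <- function(topo) {
  n <- length(topo$beads)
  idx <- c(topo$bonds$i, topo$bonds$j, topo$angles$i, topo$angles$j,
           topo$angles$k)
  if (length(idx) && (min(idx) < 1L || max(idx) > n)) {
    stop("topology '", topo$name, "': bond/angle index out of range")
  }
  if (any(topo$bonds$r0 <= 0)) stop("topology '", topo$name, "': r0 must be > 0")
  if (nrow(topo$angles) &&
      any(topo$angles$theta0 <= 0 | topo$angles$theta0 > pi + 1e-12)) {
    stop("topology '", topo$name, "': theta0 must lie in (0, pi]")
  }
  # bond graph connectivity
  if (n > 1L) {
    parent <- seq_len(n)
    find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
    for (b in seq_len(nrow(topo$bonds))) {
      ri <- find(topo$bonds$i[b]); rj <- find(topo$bonds$j[b])
      if (ri != rj) parent[ri] <- rj
    }
    roots <- vapply(seq_len(n), find, integer(1))
    if (length(unique(roots)) != 1L) {
      stop("topology '", topo$name, "': bond graph is not connected")
    }
  }
  invisible(TRUE)
}

#' Validate a topology against a force field
#'
#' Checks that every bead name resolves in the force field and that every
#' bead-type pair the molecule can bring into contact (including against
#' water) has interaction parameters, failing fast at construction time
#' rather than mid-simulation.
#'
#' @param topo a `dpd_topology`.
#' @param ff a `dpd_forcefield`.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_topology <- function(topo, ff) {
  stopifnot(inherits(topo, "dpd_topology"), inherits(ff, "dpd_forcefield"))
  types <- unique(c(topo$beads, "W"))
  for (i in seq_along(types)) {
    for (j in i:length(types)) {
      pair_lookup(ff, types[i], types[j])
    }
  }
  invisible(TRUE)
}

#' @export
print.dpd_topology <- function(x, ...) {
  cat("Topology", x$name, if (x$approximate) "(approximate)" else "", ":",
      length(x$beads), "beads [", paste(x$beads, collapse = "-"), "],",
      nrow(x$bonds), "bonds,", nrow(x$angles), "angles\n")
  invisible(x)
}
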