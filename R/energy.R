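# Hydrogen-bond energetics: a distance x angle lookup table over the grid
# 2.5-4.0 A (step 0.1) x 90-180 deg (step 0.1), pairwise h-bond/clash
# scoring, and helpers shared by the protocol-level environment scoring.

#' Build the distance-angle hydrogen-bond energy table
#'
#' Tabulates E(d, theta) = well_depth * f(d) * g(theta) on the grid of
#' heavy-atom distances 2.5-4.0 A (0.1 A steps) and donor angles 90-180
#' degrees (0.1 degree steps). The radial factor f is a Morse-type well,
#' f(d) = 1 - (1 - exp(-steepness (d - d_eq)))^2, equal to 1 at the
#' equilibrium distance; the angular factor g(theta) = cos^2(180 - theta)
#' rises smoothly from 0 at 90 degrees to 1 at linearity. The global
#' minimum is therefore exactly `well_depth` at (d_eq, 180). The analytic
#' form stands in for a quantum-mechanical water-dimer surface; a
#' user-supplied table in the same file format can replace it (see
#' [read_energy_table()]).
#'
#' @param well_depth energy at the table minimum, kcal/mol (default -5.0,
#'   a typical water-dimer binding energy).
#' @param d_eq equilibrium heavy-atom distance, Angstrom (default 2.8).
#' @param steepness Morse steepness, 1/Angstrom (default 1.8).
#' @return object of class `rapa_energy_table`: list(dgrid, agrid,
#'   energies (length(dgrid) x length(agrid) matrix, kcal/mol), params).
#' @examples
#' t <- build_energy_table()
#' min(t$energies)  # -5 at (2.8 A, 180 deg)
#' @export
build_energy_table <- function(well_depth = -5.0, d_eq = 2.8,
                               steepness = 1.8) {
  dgrid <- seq(2.5, 4.0, by = 0.1)
  agrid <- seq(90, 180, by = 0.1)
  f <- 1 - (1 - exp(-steepness * (dgrid - d_eq)))^2
  g <- cos(deg2rad(180 - agrid))^2
  energies <- well_depth * outer(f, g)
  structure(list(dgrid = dgrid, agrid = agrid, energies = energies,
                 params = list(well_depth = well_depth, d_eq = d_eq,
                               steepness = steepness)),
            class = "rapa_energy_table")
}

#' Look up a hydrogen-bond energy
#'
#' Nearest-grid-point lookup (the table is a lookup table, not an
#' interpolant; at 0.1 A / 0.1 degree resolution the discretization error
#' is negligible against the 1 kcal/mol degeneracy cutoff). Distances
#' beyond the table (> 4.0 A) and angles below 90 degrees score 0 (no
#' interaction); distances below 2.5 A clamp to the 2.5 A row.
#'
#' @param t a `rapa_energy_table`.
#' @param d heavy-atom distance, Angstrom.
#' @param theta donor-heavy -- hydrogen -- acceptor-heavy angle, degrees.
#' @return energy in kcal/mol (favorable values negative).
#' @export
lookup_energy <- function(t, d, theta) {
  dmax <- t$dgrid[length(t$dgrid)]
  if (d > dmax + 1e-9 || theta < t$agrid[1] - 1e-9) return(0)
  if (theta > 180) theta <- 180
  di <- floor((d - t$dgrid[1]) / 0.1 + 0.5) + 1
  di <- max(1, min(length(t$dgrid), di))
  ai <- floor((theta - t$agrid[1]) / 0.1 + 0.5) + 1
  ai <- max(1, min(length(t$agrid), ai))
  t$energies[di, ai]
}

#' Write / read an energy table as plain-text TSV
#'
#' Format: a header line `# dmin dmax dstep amin amax astep well_depth`
#' followed by one row per distance of tab-separated energies (one column
#' per angle grid point). Values are serialized with 17 significant
#' digits so a round trip is bit-exact.
#'
#' @param t a `rapa_energy_table`.
#' @param path file path.
#' @return `write_energy_table` returns `path` invisibly;
#'   `read_energy_table` returns a `rapa_energy_table`.
#' @export
write_energy_table <- function(t, path) {
  hdr <- sprintf("# %g %g %g %g %g %g %.17g",
                 t$dgrid[1], t$dgrid[length(t$dgrid)], 0.1,
                 t$agrid[1], t$agrid[length(t$agrid)], 0.1,
                 t$params$well_depth)
  rows <- apply(t$energies, 1, function(r) {
    paste(sprintf("%.17g", r), collapse = "\t")
  })
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_energy_table
#' @export
read_energy_table <- function(path) {
  lines <- readLines(path)
  hdr <- as.numeric(strsplit(sub("^#\\s*", "", lines[1]), "\\s+")[[1]])
  dgrid <- seq(hdr[1], hdr[2], by = hdr[3])
  agrid <- seq(hdr[4], hdr[5], by = hdr[6])
  energies <- do.call(rbind, lapply(lines[-1], function(l) {
    as.numeric(strsplit(l, "\t", fixed = TRUE)[[1]])
  }))
  stopifnot(nrow(energies) == length(dgrid),
            ncol(energies) == length(agrid))
  structure(list(dgrid = dgrid, agrid = agrid, energies = energies,
                 params = list(well_depth = hdr[7])),
            class = "rapa_energy_table")
}

# best (shortest H...target) hydrogen candidate of a donor site toward a
# target heavy-atom position; returns list(h, angle) or NULL
best_donor_h <- function(site, target) {
  if (is.null(site$hpos) || nrow(site$hpos) == 0) return(NULL)
  dd <- apply(site$hpos, 1, function(h) vnorm(h - target))
  h <- site$hpos[which.min(dd), ]
  list(h = h, angle = vangle(site$pos, h, target))
}

#' Pairwise interaction between two polar sites
#'
#' A donor/acceptor pair scores as a hydrogen bond: the donor hydrogen
#' candidate closest to the acceptor heavy atom is selected, the
#' donor-heavy -- H -- acceptor-heavy angle measured, and the energy read
#' from the table. Two donors facing each other score as an electrostatic
#' clash: the negative of the h-bond energy at the same geometry, taking
#' the more unfavorable of the two donors' best-hydrogen geometries. Two
#' acceptors clash at the heavy-atom distance with the angle fixed at 180
#' degrees (maximally penalizing; no carrier hydrogen exists). Sites typed
#' "either" (hydroxyls) are evaluated in every feasible role and the most
#' favorable assignment is kept.
#'
#' @param t a `rapa_energy_table`.
#' @param a,b polar sites: list(atom, pos, role, hpos) where role is
#'   `donor`, `acceptor` or `either` and hpos is a k x 3 matrix of
#'   candidate hydrogen positions (NULL for pure acceptors).
#' @param threshold proximal heavy-atom distance, Angstrom; pairs beyond
#'   it do not interact.
#' @return list(kind = "hbond"/"clash"/"none", distance, angle, energy).
#' @export
pair_energy <- function(t, a, b, threshold = 3.8) {
  d <- vdist(a$pos, b$pos)
  if (d > threshold + 1e-9) {
    return(list(kind = "none", distance = d, angle = NA_real_, energy = 0))
  }
  donates <- function(s) s$role %in% c("donor", "either") &&
    !is.null(s$hpos) && nrow(s$hpos) > 0
  accepts <- function(s) s$role %in% c("acceptor", "either")

  opts <- list()
  if (donates(a) && accepts(b)) {
    bh <- best_donor_h(a, b$pos)
    opts[[length(opts) + 1]] <- c(lookup_energy(t, d, bh$angle), bh$angle)
  }
  if (donates(b) && accepts(a)) {
    bh <- best_donor_h(b, a$pos)
    opts[[length(opts) + 1]] <- c(lookup_energy(t, d, bh$angle), bh$angle)
  }
  if (length(opts) > 0) {
    m <- do.call(rbind, opts)
    k <- which.min(m[, 1])
    e <- m[k, 1]
    return(list(kind = if (e < 0) "hbond" else "none", distance = d,
                angle = m[k, 2], energy = e))
  }
  # no feasible donor->acceptor assignment: clash
  if (donates(a) || donates(b)) {
    worst <- -Inf; ang <- 180
    for (pr in list(list(s = a, o = b), list(s = b, o = a))) {
      if (!donates(pr$s)) next
      bh <- best_donor_h(pr$s, pr$o$pos)
      e <- -lookup_energy(t, d, bh$angle)
      if (e > worst) { worst <- e; ang <- bh$angle }
    }
    e <- worst
  } else {
    ang <- 180
    e <- -lookup_energy(t, d, 180)
  }
  list(kind = if (e > 0) "clash" else "none", distance = d, angle = ang,
       energy = e)
}

# total interaction energy between two site lists (different residues)
sites_interaction <- function(t, sa, sb, threshold = 3.8) {
  e <- 0
  for (x in sa) for (y in sb) {
    e <- e + pair_energy(t, x, y, threshold)$energy
  }
  e
}
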