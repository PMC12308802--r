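# Programmatic synthetic fixtures: minimal structures exercising every
# ambiguity class, built from hand-placed idealized coordinates. Each
# motif is laid out so that the amide/ring flip axis and the partner
# geometry share a mirror plane, which makes the flip-related state pairs
# *exactly* energy-degenerate; a `perturb` parameter breaks the symmetry
# continuously. Backbone atoms are kept in the mirror plane too, so they
# never lift the degeneracy even when they fall inside the proximal range.

ortho_vec <- function(v) {
  a <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unitv(pracma_cross(v, a))
}

fx_row <- function(elety, pos) {
  data.frame(elety = elety, x = pos[1], y = pos[2], z = pos[3],
             stringsAsFactors = FALSE)
}

# ASN with the amide in the z = 0 plane, CB->CG along +x (the flip axis),
# and the backbone in the y = 0 plane
fx_asn <- function() {
  cb <- c(0, 0, 0)
  cg <- c(1.52, 0, 0)
  od1 <- cg + 1.23 * c(cos(pi / 3), sin(pi / 3), 0)
  nd2 <- cg + 1.33 * c(cos(pi / 3), -sin(pi / 3), 0)
  ca <- cb + 1.53 * c(cos(deg2rad(114)), 0, sin(deg2rad(114)))
  n <- place_atom(cg, cb, ca, 1.46, 110, 180)
  cc <- place_atom(cg, cb, ca, 1.52, 120, 0)
  o <- place_atom(cb, ca, cc, 1.23, 120, 180)
  df <- rbind(fx_row("N", n), fx_row("CA", ca), fx_row("C", cc),
              fx_row("O", o), fx_row("CB", cb), fx_row("CG", cg),
              fx_row("OD1", od1), fx_row("ND2", nd2))
  attr(df, "resname") <- "ASN"
  df
}

# ASP carboxylate in the z = 0 plane, CB->CG along +x, backbone in y = 0
fx_asp <- function() {
  df <- fx_asn()
  df$elety[df$elety == "OD1"] <- "OD1"
  i <- which(df$elety == "ND2")
  cg <- as.numeric(df[df$elety == "CG", c("x", "y", "z")])
  od2 <- cg + 1.25 * c(cos(pi / 3), -sin(pi / 3), 0)
  df[i, c("x", "y", "z")] <- od2
  df$elety[i] <- "OD2"
  od1 <- cg + 1.25 * c(cos(pi / 3), sin(pi / 3), 0)
  df[df$elety == "OD1", c("x", "y", "z")] <- od1
  attr(df, "resname") <- "ASP"
  df
}

# SER entirely in the y = 0 plane, OG at the local origin, side chain
# extending toward +x
fx_ser <- function() {
  og <- c(0, 0, 0)
  cb <- og + 1.43 * c(cos(deg2rad(40)), 0, sin(deg2rad(40)))
  u <- unitv(og - cb)
  p <- c(-u[3], 0, u[1])
  ca <- cb + 1.53 * (cos(deg2rad(109.5)) * u + sin(deg2rad(109.5)) * p)
  n <- place_atom(og, cb, ca, 1.46, 110, 180)
  cc <- place_atom(og, cb, ca, 1.52, 120, 0)
  o <- place_atom(cb, ca, cc, 1.23, 120, 180)
  df <- rbind(fx_row("N", n), fx_row("CA", ca), fx_row("C", cc),
              fx_row("O", o), fx_row("CB", cb), fx_row("OG", og))
  attr(df, "resname") <- "SER"
  df
}

# HIS with an ideal (regular-pentagon) imidazole in the z = 0 plane and
# the CB->CG flip axis along +x; the 180-degree flip maps the ring onto
# itself with ND1<->CD2 and CE1<->NE2 exchanged exactly
fx_his <- function() {
  side <- 1.37
  r <- side / (2 * sin(pi / 5))
  c0 <- c(r, 0, 0)
  vert <- function(theta) c0 + r * c(cos(deg2rad(theta)),
                                     sin(deg2rad(theta)), 0)
  cg <- vert(180); nd1 <- vert(108); ce1 <- vert(36)
  ne2 <- vert(-36); cd2 <- vert(-108)
  cb <- c(-1.50, 0, 0)
  ca <- cb + 1.53 * c(cos(deg2rad(114)), 0, sin(deg2rad(114))) * c(-1, 1, 1)
  n <- place_atom(cg, cb, ca, 1.46, 110, 180)
  cc <- place_atom(cg, cb, ca, 1.52, 120, 0)
  o <- place_atom(cb, ca, cc, 1.23, 120, 180)
  df <- rbind(fx_row("N", n), fx_row("CA", ca), fx_row("C", cc),
              fx_row("O", o), fx_row("CB", cb), fx_row("CG", cg),
              fx_row("ND1", nd1), fx_row("CD2", cd2), fx_row("CE1", ce1),
              fx_row("NE2", ne2))
  attr(df, "resname") <- "HIS"
  df
}

# THR: the SER frame plus the nonpolar CG2 methyl
fx_thr <- function() {
  df <- fx_ser()
  df$elety[df$elety == "OG"] <- "OG1"
  cb <- as.numeric(df[df$elety == "CB", c("x", "y", "z")])
  df <- rbind(df, fx_row("CG2", cb + 1.54 * unitv(c(0, 1, 0.3))))
  attr(df, "resname") <- "THR"
  df
}

# TYR: ideal hexagonal ring in the z = 0 plane, OH on the CZ axis
fx_tyr <- function() {
  r <- 1.39
  vert <- function(theta) r * c(cos(deg2rad(theta)), sin(deg2rad(theta)), 0)
  cg <- vert(180); cd1 <- vert(120); ce1 <- vert(60); cz <- vert(0)
  ce2 <- vert(-60); cd2 <- vert(-120)
  oh <- cz + 1.36 * c(1, 0, 0)
  cb <- cg + 1.51 * c(-1, 0, 0)
  ca <- cb + 1.53 * c(cos(deg2rad(114)) * -1, 0, sin(deg2rad(114)))
  n <- place_atom(cg, cb, ca, 1.46, 110, 180)
  cc <- place_atom(cg, cb, ca, 1.52, 120, 0)
  o <- place_atom(cb, ca, cc, 1.23, 120, 180)
  df <- rbind(fx_row("N", n), fx_row("CA", ca), fx_row("C", cc),
              fx_row("O", o), fx_row("CB", cb), fx_row("CG", cg),
              fx_row("CD1", cd1), fx_row("CD2", cd2), fx_row("CE1", ce1),
              fx_row("CE2", ce2), fx_row("CZ", cz), fx_row("OH", oh))
  attr(df, "resname") <- "TYR"
  df
}

fx_cys <- function() {
  sg <- c(0, 0, 0)
  cb <- sg + 1.81 * c(-cos(deg2rad(30)), 0, sin(deg2rad(30)))
  ca <- cb + 1.53 * unitv(c(-0.5, 0, 0.866))
  n <- place_atom(sg, cb, ca, 1.46, 110, 180)
  cc <- place_atom(sg, cb, ca, 1.52, 120, 0)
  o <- place_atom(cb, ca, cc, 1.23, 120, 180)
  df <- rbind(fx_row("N", n), fx_row("CA", ca), fx_row("C", cc),
              fx_row("O", o), fx_row("CB", cb), fx_row("SG", sg))
  attr(df, "resname") <- "CYS"
  df
}

fx_gln <- function() {
  cb <- c(0, 0, 0)
  cg <- c(1.52, 0, 0)
  cd <- cg + 1.52 * c(cos(deg2rad(60)), 0, sin(deg2rad(60)))
  oe1 <- place_atom(cb, cg, cd, 1.23, 121, 0)
  ne2 <- place_atom(cb, cg, cd, 1.33, 117, 180)
  ca <- cb + 1.53 * c(cos(deg2rad(114)), 0, -sin(deg2rad(114)))
  n <- place_atom(cg, cb, ca, 1.46, 110, 180)
  cc <- place_atom(cg, cb, ca, 1.52, 120, 0)
  o <- place_atom(cb, ca, cc, 1.23, 120, 180)
  df <- rbind(fx_row("N", n), fx_row("CA", ca), fx_row("C", cc),
              fx_row("O", o), fx_row("CB", cb), fx_row("CG", cg),
              fx_row("CD", cd), fx_row("OE1", oe1), fx_row("NE2", ne2))
  attr(df, "resname") <- "GLN"
  df
}

# minimal glycine probes whose single intended polar atom faces `target`
# while the rest of the backbone trails away along `away`
fx_gly_acceptor <- function(target, away) {
  away <- unitv(away)
  p <- ortho_vec(away)
  o <- target
  cc <- o + 1.23 * away
  ca <- cc + 1.52 * unitv(away + 0.4 * p)
  n <- ca + 1.46 * away
  df <- rbind(fx_row("N", n), fx_row("CA", ca), fx_row("C", cc),
              fx_row("O", o))
  attr(df, "resname") <- "GLY"
  df
}

fx_gly_donor <- function(npos, toward) {
  toward <- unitv(toward)
  p <- ortho_vec(toward)
  n <- npos
  ca <- n - 1.46 * toward
  cc <- ca - 1.52 * unitv(toward + 0.4 * p)
  o <- cc - 1.23 * toward
  df <- rbind(fx_row("N", n), fx_row("CA", ca), fx_row("C", cc),
              fx_row("O", o))
  attr(df, "resname") <- "GLY"
  df
}

fx_transform <- function(df, fun) {
  for (i in seq_len(nrow(df))) {
    df[i, c("x", "y", "z")] <- fun(as.numeric(df[i, c("x", "y", "z")]))
  }
  df
}

fx_translate <- function(df, v) fx_transform(df, function(p) p + v)

# 180-degree rotation about the z axis followed by translation to x = L:
# produces the facing partner with its flip axis collinear with the first
fx_face <- function(df, L) {
  fx_transform(df, function(p) c(L - p[1], -p[2], p[3]))
}

#' Generate a synthetic test structure
#'
#' Builds small idealized motifs as PDB text, one per ambiguity class:
#' \describe{
#'   \item{asn_ser}{an ASN amide facing a SER hydroxyl (donor-or-acceptor
#'     partner); mirror-symmetric, so the two amide rotamers are exactly
#'     degenerate at `perturb = 0`.}
#'   \item{asn_asn}{two facing ASN amides whose flip axes are collinear;
#'     the two self-consistent pairings are exactly degenerate and the
#'     mixed pairings clash.}
#'   \item{his_probe}{a HIS imidazole with an acceptor probe facing the
#'     NE2 hydrogen direction and a donor probe facing ND1; the epsilon
#'     tautomer in the input rotamer is the unique favorable state.}
#'   \item{asp_dyad}{two facing ASP carboxylates within dyad range.}
#'   \item{cys_pair}{two CYS with SG atoms at the given distance.}
#'   \item{isolated}{a single residue (`resname`) with no neighbors.}
#'   \item{multi_pair}{`k` independent asn_asn copies at least 15 A
#'     apart, giving 2^k degenerate configurations.}
#' }
#'
#' @param kind motif name (see above).
#' @param distance key heavy-atom separation in Angstrom: acceptor-donor
#'   N...O for the amide motifs, O-O for the dyad, S-S for the cysteine
#'   pair. Defaults per kind; must lie in [1.5, 20].
#' @param k number of independent copies for `multi_pair`.
#' @param perturb symmetry-breaking magnitude: a y-offset in Angstrom of
#'   the SER (asn_ser) or an in-plane rotation in degrees of the second
#'   amide (asn_asn / multi_pair). 0 keeps the exact degeneracy.
#' @param resname residue for `isolated` (ASN, GLN, HIS, SER, THR, TYR).
#' @param motif motif replicated by `multi_pair`: facing amides
#'   (`asn_asn`, coupled within each pair) or amide-plus-hydroxyl
#'   (`asn_ser`, uncoupled).
#' @param jitter uniform coordinate noise half-width, Angstrom (max
#'   0.05); requires `seed`.
#' @param seed RNG seed for the jitter (deterministic output).
#' @return PDB text (single string).
#' @examples
#' s <- read_structure(make_fixture("asn_asn", distance = 2.9))
#' rapa_run(s)$n_configurations  # 2
#' @export
make_fixture <- function(kind = c("asn_ser", "asn_asn", "his_probe",
                                  "asp_dyad", "cys_pair", "isolated",
                                  "multi_pair"),
                         distance = NULL, k = 3, perturb = 0,
                         resname = "ASN", motif = c("asn_asn", "asn_ser"),
                         jitter = 0, seed = NULL) {
  kind <- match.arg(kind)
  motif <- match.arg(motif)
  defaults <- c(asn_ser = 2.8, asn_asn = 2.9, his_probe = 2.8,
                asp_dyad = 2.6, cys_pair = 2.05, isolated = 0,
                multi_pair = 2.9)
  if (is.null(distance)) distance <- defaults[[kind]]
  if (kind != "isolated" && (distance < 1.5 || distance > 20)) {
    stop("distance must be in [1.5, 20] Angstrom", call. = FALSE)
  }
  if (jitter < 0 || jitter > 0.05) {
    stop("jitter must be in [0, 0.05] Angstrom", call. = FALSE)
  }

  pieces <- list()  # list of list(df, resno)
  add <- function(df, resno) {
    pieces[[length(pieces) + 1]] <<- list(df = df, resno = resno)
  }

  asn_pair <- function(d, perturb, base) {
    a <- fx_asn()
    dy <- 1.33 * sin(pi / 3) - 1.23 * sin(pi / 3)
    L <- (1.52 + 1.23 * cos(pi / 3) + 1.52 + 1.33 * cos(pi / 3)) +
      sqrt(max(d^2 - dy^2, 0.01))
    b <- fx_face(fx_asn(), L)
    if (perturb != 0) {
      # rotate the whole partner about z through its CG: tilts its flip
      # axis out of the shared mirror plane, breaking the degeneracy
      cgb <- as.numeric(b[b$elety == "CG", c("x", "y", "z")])
      b <- fx_transform(b, function(p) {
        rotate_about_axis(p, cgb, c(0, 0, 1), perturb)
      })
    }
    add(a, base); add(b, base + 1)
  }

  if (kind == "asn_ser") {
    a <- fx_asn()
    od1 <- as.numeric(a[a$elety == "OD1", c("x", "y", "z")])
    xg <- od1[1] + sqrt(max(distance^2 - od1[2]^2, 0.01))
    add(a, 1)
    add(fx_translate(fx_ser(), c(xg, perturb, 0)), 5)
  } else if (kind == "asn_asn") {
    asn_pair(distance, perturb, 1)
  } else if (kind == "his_probe") {
    h <- fx_his()
    c0 <- c(1.37 / (2 * sin(pi / 5)), 0, 0)
    ne2 <- as.numeric(h[h$elety == "NE2", c("x", "y", "z")])
    nd1 <- as.numeric(h[h$elety == "ND1", c("x", "y", "z")])
    dir_e <- unitv(ne2 - c0)
    dir_d <- unitv(nd1 - c0)
    add(h, 1)
    add(fx_gly_acceptor(ne2 + distance * dir_e, dir_e), 5)
    add(fx_gly_donor(nd1 + distance * dir_d, -dir_d), 9)
  } else if (kind == "asp_dyad") {
    a <- fx_asp()
    od1 <- as.numeric(a[a$elety == "OD1", c("x", "y", "z")])
    L <- 2 * od1[1] + distance
    add(a, 1)
    add(fx_face(fx_asp(), L), 5)
  } else if (kind == "cys_pair") {
    add(fx_cys(), 1)
    add(fx_face(fx_cys(), distance), 5)
  } else if (kind == "isolated") {
    builder <- switch(resname, ASN = fx_asn, GLN = fx_gln, HIS = fx_his,
                      SER = fx_ser, THR = fx_thr, TYR = fx_tyr,
                      stop("isolated supports ASN, GLN, HIS, SER, THR, TYR",
                           call. = FALSE))
    add(builder(), 1)
  } else if (kind == "multi_pair") {
    stopifnot(k >= 1)
    for (i in seq_len(k)) {
      base <- (i - 1) * 10 + 1
      n0 <- length(pieces)
      if (motif == "asn_asn") {
        asn_pair(distance, perturb, base)
      } else {
        a <- fx_asn()
        od1 <- as.numeric(a[a$elety == "OD1", c("x", "y", "z")])
        xg <- od1[1] + sqrt(max(distance^2 - od1[2]^2, 0.01))
        add(a, base)
        add(fx_translate(fx_ser(), c(xg, perturb, 0)), base + 1)
      }
      for (j in seq(n0 + 1, length(pieces))) {
        pieces[[j]]$df <- fx_translate(pieces[[j]]$df,
                                       c(0, 0, 20 * (i - 1)))
      }
    }
  }

  atoms <- do.call(rbind, lapply(pieces, function(p) {
    df <- p$df
    data.frame(elety = df$elety, resid = attr(df, "resname"),
               chain = "A", resno = p$resno, insert = "",
               x = df$x, y = df$y, z = df$z, o = 1, b = 0,
               elesy = substr(df$elety, 1, 1), stringsAsFactors = FALSE)
  }))
  if (jitter > 0) {
    if (is.null(seed)) stop("jitter requires a seed", call. = FALSE)
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old))
      assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
    n <- nrow(atoms)
    atoms$x <- atoms$x + stats::runif(n, -jitter, jitter)
    atoms$y <- atoms$y + stats::runif(n, -jitter, jitter)
    atoms$z <- atoms$z + stats::runif(n, -jitter, jitter)
  }
  atoms_to_pdb_text(atoms)
}
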