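# Rotamer/protonation state enumeration: amide and imidazole flips,
# histidine tautomers, hydroxyl hydrogen candidates, acid-dyad protonation.
#
# A state (class "rapa_state") is a list:
#   reskey, resname, state_id, rotamer (0/1), protonation (label or NA),
#   coord_overrides: named list atom-name -> xyz (heavy atoms moved by the
#     flip; empty for the unflipped rotamer),
#   sites: list of polar side-chain sites, each list(atom, pos, role,
#     hpos = k x 3 matrix of candidate hydrogen positions or NULL).

BOND_NH <- 1.01
BOND_OH <- 0.96
BOND_SH <- 1.34

new_state <- function(reskey, resname, state_id, rotamer, protonation,
                      overrides, sites) {
  structure(list(reskey = reskey, resname = resname, state_id = state_id,
                 rotamer = rotamer, protonation = protonation,
                 coord_overrides = overrides, sites = sites),
            class = "rapa_state")
}

# position of atom `name` in residue `reskey` after applying overrides
oxyz <- function(s, reskey, name, overrides = list()) {
  if (!is.null(overrides[[name]])) return(overrides[[name]])
  axyz(s, reskey, name)
}

# hydrogen on the external bisector of two bonded neighbors (ring NH,
# backbone NH, guanidinium NE-H)
bisector_h <- function(n, a, b, bond = BOND_NH) {
  n + bond * unitv(unitv(n - a) + unitv(n - b))
}

# the two hydrogens of a planar -NH2 (amide or guanidinium): in the plane
# of (c, ref, n), at 120 degrees from the n->c bond on either side
nh2_hydrogens <- function(n, c, ref, bond = BOND_NH) {
  u <- unitv(n - c)
  v0 <- ref - c
  w <- v0 - sum(v0 * u) * u
  w <- unitv(w)
  rbind(n + bond * (0.5 * u + sqrt(3) / 2 * w),
        n + bond * (0.5 * u - sqrt(3) / 2 * w))
}

# staggered hydrogens about the c->x axis, dihedral reference `ref`
staggered_h <- function(x, c, ref, dihedrals, bond, angle) {
  t(vapply(dihedrals, function(d) place_atom(ref, c, x, bond, angle, d),
           numeric(3)))
}

incomplete <- function(reskey, what) {
  stop("incomplete side chain at ", reskey, ": missing ", what,
       call. = FALSE)
}

need <- function(s, reskey, names, overrides = list()) {
  out <- lapply(names, function(a) oxyz(s, reskey, a, overrides))
  miss <- vapply(out, is.null, logical(1))
  if (any(miss)) incomplete(reskey, paste(names[miss], collapse = ","))
  names(out) <- names
  out
}

#' Flip an ASN/GLN amide by 180 degrees
#'
#' Rigid rotation of the terminal amide about the bond axis ending at the
#' amide carbon (CB-CG for ASN, CG-CD for GLN), exchanging the positions
#' of the amide oxygen and nitrogen. A rigid rotation, not a name swap, so
#' distorted experimental geometry is carried through unchanged; applying
#' the flip twice restores the input exactly.
#'
#' @param s a `rapa_structure`.
#' @param reskey residue key of an ASN or GLN residue.
#' @return named list of coordinate overrides (atom name -> new xyz).
#' @export
flip_amide <- function(s, reskey) {
  rn <- res_row(s, reskey)$resid
  if (length(rn) == 0 || !rn %in% c("ASN", "GLN")) {
    stop("flip_amide requires an ASN or GLN residue", call. = FALSE)
  }
  if (rn == "ASN") {
    p <- need(s, reskey, c("CB", "CG", "OD1", "ND2"))
    moved <- c("OD1", "ND2")
    origin <- p$CB; axis <- p$CG - p$CB
  } else {
    p <- need(s, reskey, c("CG", "CD", "OE1", "NE2"))
    moved <- c("OE1", "NE2")
    origin <- p$CG; axis <- p$CD - p$CG
  }
  out <- lapply(moved, function(a) {
    rotate_about_axis(oxyz(s, reskey, a), origin, axis, 180)
  })
  names(out) <- moved
  out
}

#' Flip a HIS imidazole ring by 180 degrees
#'
#' Rigid rotation of the ring about the CB-CG axis; ND1 and CD2 exchange
#' positions, as do CE1 and NE2 (exactly so for an ideal ring).
#'
#' @inheritParams flip_amide
#' @return named list of coordinate overrides for ND1, CD2, CE1, NE2.
#' @export
flip_imidazole <- function(s, reskey) {
  rn <- res_row(s, reskey)$resid
  if (length(rn) == 0 || rn != "HIS") {
    stop("flip_imidazole requires a HIS residue", call. = FALSE)
  }
  p <- need(s, reskey, c("CB", "CG", "ND1", "CD2", "CE1", "NE2"))
  moved <- c("ND1", "CD2", "CE1", "NE2")
  out <- lapply(moved, function(a) {
    rotate_about_axis(p[[a]], p$CB, p$CG - p$CB, 180)
  })
  names(out) <- moved
  out
}

#' Candidate hydroxyl hydrogen positions for SER/THR/TYR
#'
#' SER and THR hydroxyls are sp3: nine candidates at H-O-C-C(antecedent)
#' dihedrals of the three staggered positions (60, 180, -60 degrees) each
#' also rotated by -20/0/+20 degrees, with O-H 0.96 A and C-O-H 109.5
#' degrees. The TYR hydroxyl is sp2 (ring resonance): two in-plane
#' candidates at dihedral 0 and 180 relative to CE1, C-O-H 120 degrees.
#'
#' @inheritParams flip_amide
#' @return k x 3 matrix of hydrogen coordinates (k = 9 or 2), with the
#'   nominal dihedrals as rownames.
#' @export
hydroxy_hydrogen_positions <- function(s, reskey) {
  rn <- res_row(s, reskey)$resid
  if (length(rn) == 0 || !rn %in% c("SER", "THR", "TYR")) {
    stop("hydroxy_hydrogen_positions requires SER, THR or TYR",
         call. = FALSE)
  }
  if (rn == "TYR") {
    p <- need(s, reskey, c("OH", "CZ", "CE1"))
    dih <- c(0, 180)
    h <- staggered_h(p$OH, p$CZ, p$CE1, dih, BOND_OH, 120)
  } else {
    o <- if (rn == "SER") "OG" else "OG1"
    p <- need(s, reskey, c(o, "CB", "CA"))
    dih <- as.vector(outer(c(-20, 0, 20), c(60, 180, -60), "+"))
    h <- staggered_h(p[[o]], p$CB, p$CA, dih, BOND_OH, 109.47)
  }
  rownames(h) <- sprintf("%g", dih)
  h
}

# histidine tautomer definitions: which ring N is protonated
HIS_TAUTOMERS <- list(HID = c(ND1 = TRUE, NE2 = FALSE),
                      HIE = c(ND1 = FALSE, NE2 = TRUE),
                      HIP = c(ND1 = TRUE, NE2 = TRUE))

his_sites <- function(s, reskey, overrides, tautomer) {
  p <- need(s, reskey, c("CG", "ND1", "CD2", "CE1", "NE2"), overrides)
  prot <- HIS_TAUTOMERS[[tautomer]]
  mk <- function(n, a, b, protonated) {
    pos <- p[[n]]
    if (protonated) {
      list(atom = n, pos = pos, role = "donor",
           hpos = matrix(bisector_h(pos, p[[a]], p[[b]]), nrow = 1))
    } else {
      list(atom = n, pos = pos, role = "acceptor", hpos = NULL)
    }
  }
  list(mk("ND1", "CG", "CE1", prot[["ND1"]]),
       mk("NE2", "CD2", "CE1", prot[["NE2"]]))
}

amide_sites <- function(s, reskey, overrides) {
  rn <- res_row(s, reskey)$resid
  nm <- if (rn == "ASN") c(C = "CG", O = "OD1", N = "ND2")
        else c(C = "CD", O = "OE1", N = "NE2")
  p <- need(s, reskey, unname(nm), overrides)
  list(list(atom = nm[["O"]], pos = p[[nm[["O"]]]], role = "acceptor",
            hpos = NULL),
       list(atom = nm[["N"]], pos = p[[nm[["N"]]]], role = "donor",
            hpos = nh2_hydrogens(p[[nm[["N"]]]], p[[nm[["C"]]]],
                                 p[[nm[["O"]]]])))
}

#' Enumerate the rotamer/protonation states of one ambiguous residue
#'
#' HIS yields six states (2 ring flips x HID/HIE/HIP tautomers); ASN and
#' GLN two (amide flip); SER/THR one state carrying the nine hydroxyl
#' hydrogen candidates; TYR one state with two in-plane candidates;
#' ASP/GLU outside an acid dyad one deprotonated state. Dyads are
#' enumerated pairwise by [enumerate_dyad_states()]; CYS is resolved at
#' initialization and never reaches this function.
#'
#' @inheritParams flip_amide
#' @return list of `rapa_state` objects.
#' @examples
#' s <- read_structure(make_fixture("his_probe"))
#' his <- s$residues$reskey[s$residues$resid == "HIS"]
#' length(enumerate_states(s, his))  # 6
#' @export
enumerate_states <- function(s, reskey) {
  rn <- res_row(s, reskey)$resid
  if (length(rn) == 0) stop("no such residue: ", reskey, call. = FALSE)
  switch(rn,
    HIS = {
      out <- list()
      for (rot in 0:1) {
        ov <- if (rot == 0) list() else flip_imidazole(s, reskey)
        for (tau in names(HIS_TAUTOMERS)) {
          out[[length(out) + 1]] <- new_state(
            reskey, rn, paste0(tau, ":rot", rot), rot, tau, ov,
            his_sites(s, reskey, ov, tau))
        }
      }
      out
    },
    ASN = ,
    GLN = {
      lapply(0:1, function(rot) {
        ov <- if (rot == 0) list() else flip_amide(s, reskey)
        new_state(reskey, rn, paste0(rn, ":rot", rot), rot, NA, ov,
                  amide_sites(s, reskey, ov))
      })
    },
    SER = ,
    THR = ,
    TYR = {
      o <- c(SER = "OG", THR = "OG1", TYR = "OH")[[rn]]
      h <- hydroxy_hydrogen_positions(s, reskey)
      list(new_state(reskey, rn, paste0(rn, ":oh"), 0, NA, list(),
                     list(list(atom = o, pos = axyz(s, reskey, o),
                               role = "either", hpos = h))))
    },
    ASP = ,
    GLU = {
      nm <- if (rn == "ASP") c("OD1", "OD2") else c("OE1", "OE2")
      p <- need(s, reskey, nm)
      list(new_state(reskey, rn, paste0(rn, ":deprot"), 0, "deprotonated",
                     list(),
                     lapply(nm, function(a) {
                       list(atom = a, pos = p[[a]], role = "acceptor",
                            hpos = NULL)
                     })))
    },
    stop("residue type ", rn, " has no ambiguous states", call. = FALSE)
  )
}

#' Enumerate the protonation states of an ASP/GLU acid dyad
#'
#' For a proximal carboxylate pair, evaluates all singly-protonated
#' configurations: one state per carboxylate oxygen (four in total), with
#' the hydroxyl hydrogen placed in the carboxylate plane oriented toward
#' the partner residue's nearest oxygen, plus the doubly-deprotonated
#' reference state.
#'
#' @param s a `rapa_structure`.
#' @param key1,key2 residue keys of the two ASP/GLU residues.
#' @param threshold O-O proximity required for a dyad, Angstrom.
#' @return list of dyad states: each list(state_id, protonated = list(
#'   reskey, atom) or NULL, h = hydrogen xyz or NULL).
#' @export
enumerate_dyad_states <- function(s, key1, key2, threshold = 3.8) {
  rn1 <- res_row(s, key1)$resid
  rn2 <- res_row(s, key2)$resid
  if (!all(c(rn1, rn2) %in% c("ASP", "GLU"))) {
    stop("dyad members must be ASP or GLU", call. = FALSE)
  }
  onames <- function(rn) if (rn == "ASP") c("OD1", "OD2") else c("OE1", "OE2")
  cname <- function(rn) if (rn == "ASP") "CG" else "CD"
  o1 <- need(s, key1, onames(rn1))
  o2 <- need(s, key2, onames(rn2))
  dmin <- Inf
  for (a in o1) for (b in o2) dmin <- min(dmin, vdist(a, b))
  if (dmin > threshold) {
    stop("residues are not a dyad: closest O-O distance ",
         sprintf("%.2f", dmin), " A exceeds ", threshold, " A",
         call. = FALSE)
  }
  states <- list(list(state_id = "dyad:deprot", protonated = NULL,
                      h = NULL))
  mk_h <- function(own_key, own_rn, oxy, partner_oxys) {
    p <- need(s, own_key, c(cname(own_rn), onames(own_rn)))
    cpos <- p[[cname(own_rn)]]
    opos <- p[[oxy]]
    other <- setdiff(onames(own_rn), oxy)
    # in-plane direction toward the partner's nearest oxygen
    nrm <- unitv(pracma_cross(p[[other]] - cpos, opos - cpos))
    tgt <- partner_oxys[[which.min(vapply(partner_oxys,
                                          function(q) vdist(q, opos),
                                          numeric(1)))]]
    d <- tgt - opos
    d <- d - sum(d * nrm) * nrm
    opos + BOND_OH * unitv(d)
  }
  for (oxy in onames(rn1)) {
    states[[length(states) + 1]] <- list(
      state_id = paste0("dyad:", key1, ":", oxy),
      protonated = list(reskey = key1, atom = oxy),
      h = mk_h(key1, rn1, oxy, o2))
  }
  for (oxy in onames(rn2)) {
    states[[length(states) + 1]] <- list(
      state_id = paste0("dyad:", key2, ":", oxy),
      protonated = list(reskey = key2, atom = oxy),
      h = mk_h(key2, rn2, oxy, o1))
  }
  states
}

# --- fixed (state-independent) site builders -------------------------------

# backbone polar sites of one residue; prev_c is the carbonyl carbon of the
# preceding residue (NULL at the N-terminus, where the amine hydrogen is
# approximated anti to CA)
backbone_sites <- function(s, reskey, prev_c = NULL) {
  rn <- res_row(s, reskey)$resid
  out <- list()
  n <- axyz(s, reskey, "N")
  ca <- axyz(s, reskey, "CA")
  if (!is.null(n) && rn != "PRO") {
    h <- if (!is.null(prev_c) && !is.null(ca)) {
      bisector_h(n, ca, prev_c)
    } else if (!is.null(ca)) {
      n + BOND_NH * unitv(n - ca)
    } else NULL
    out[[length(out) + 1]] <- list(
      atom = "N", pos = n, role = "donor",
      hpos = if (is.null(h)) NULL else matrix(h, nrow = 1))
  }
  for (a in c("O", "OXT")) {
    p <- axyz(s, reskey, a)
    if (!is.null(p)) {
      out[[length(out) + 1]] <- list(atom = a, pos = p, role = "acceptor",
                                     hpos = NULL)
    }
  }
  out
}

# side-chain sites of residues that are known at initialization
# (TRP/LYS/ARG always; CYS thiol unless disulfide-bridged; non-dyad
# ASP/GLU deprotonated acceptors)
fixed_sidechain_sites <- function(s, reskey, bridged = FALSE) {
  rn <- res_row(s, reskey)$resid
  g <- function(a) axyz(s, reskey, a)
  out <- list()
  if (rn == "TRP") {
    n <- g("NE1"); cd1 <- g("CD1"); ce2 <- g("CE2")
    if (!is.null(n) && !is.null(cd1) && !is.null(ce2)) {
      out <- list(list(atom = "NE1", pos = n, role = "donor",
                       hpos = matrix(bisector_h(n, cd1, ce2), nrow = 1)))
    }
  } else if (rn == "LYS") {
    nz <- g("NZ"); ce <- g("CE"); cd <- g("CD")
    if (!is.null(nz) && !is.null(ce) && !is.null(cd)) {
      out <- list(list(atom = "NZ", pos = nz, role = "donor",
                       hpos = staggered_h(nz, ce, cd, c(60, 180, -60),
                                          BOND_NH, 109.47)))
    }
  } else if (rn == "ARG") {
    ne <- g("NE"); cd <- g("CD"); cz <- g("CZ")
    nh1 <- g("NH1"); nh2 <- g("NH2")
    if (!is.null(ne) && !is.null(cd) && !is.null(cz)) {
      out[[length(out) + 1]] <- list(
        atom = "NE", pos = ne, role = "donor",
        hpos = matrix(bisector_h(ne, cd, cz), nrow = 1))
    }
    if (!is.null(nh1) && !is.null(cz) && !is.null(ne)) {
      out[[length(out) + 1]] <- list(
        atom = "NH1", pos = nh1, role = "donor",
        hpos = nh2_hydrogens(nh1, cz, ne))
    }
    if (!is.null(nh2) && !is.null(cz) && !is.null(ne)) {
      out[[length(out) + 1]] <- list(
        atom = "NH2", pos = nh2, role = "donor",
        hpos = nh2_hydrogens(nh2, cz, ne))
    }
  } else if (rn == "CYS" && !bridged) {
    sg <- g("SG"); cb <- g("CB"); ca <- g("CA")
    if (!is.null(sg) && !is.null(cb) && !is.null(ca)) {
      out <- list(list(atom = "SG", pos = sg, role = "donor",
                       hpos = staggered_h(sg, cb, ca, c(60, 180, -60),
                                          BOND_SH, 96)))
    }
  } else if (rn %in% c("ASP", "GLU")) {
    nm <- if (rn == "ASP") c("OD1", "OD2") else c("OE1", "OE2")
    for (a in nm) {
      p <- g(a)
      if (!is.null(p)) {
        out[[length(out) + 1]] <- list(atom = a, pos = p,
                                       role = "acceptor", hpos = NULL)
      }
    }
  }
  out
}
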