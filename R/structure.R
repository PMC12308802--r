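# Structure model: PDB parsing/writing, polar-site typing, proximity graph,
# disulfide detection. The in-memory representation is deliberately flat:
# an atom table plus a residue index, in the style of bio3d's pdb$atom.

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

# variant resnames mapped to their parent; HIS tautomer names are remembered
RESNAME_ALIASES <- c(HID = "HIS", HIE = "HIS", HIP = "HIS",
                     HSD = "HIS", HSE = "HIS", HSP = "HIS",
                     CYX = "CYS", CYM = "CYS",
                     ASH = "ASP", GLH = "GLU", LYN = "LYS",
                     MSE = "MET")

WATER_NAMES <- c("HOH", "WAT", "H2O", "DOD", "TIP", "TIP3", "SPC")

residue_key <- function(chain, resno, insert) {
  insert <- ifelse(is.na(insert) | insert == "", "", insert)
  chain <- ifelse(is.na(chain), "_", chain)
  paste(chain, resno, insert, sep = "|")
}

#' Read a protein structure from PDB text
#'
#' Parses a (single-model) PDB file or text, strips waters and non-protein
#' hetero groups, resolves alternate locations and returns the atom/residue
#' tables the rest of the pipeline operates on. Existing hydrogens are kept
#' but flagged: polar hydrogens are always re-placed at idealized geometry
#' before output, so results do not depend on upstream preparation.
#'
#' @param pdb path to a PDB file, or a character vector of PDB lines.
#' @param altloc_policy how alternate locations are resolved. The single
#'   supported policy, `"occupancy"`, keeps the highest-occupancy location
#'   and breaks ties by altloc identifier (so 'A' wins a tie).
#' @return an object of class `rapa_structure`: a list with elements
#'   `atoms` (data.frame: elety, resid, chain, resno, insert, x, y, z, o,
#'   b, elesy, is_h, reskey), `residues` (one row per residue, in chain
#'   then sequence order, with the original resname kept in `orig_resid`)
#'   and `metadata`.
#' @examples
#' s <- read_structure(make_fixture("isolated"))
#' s$residues
#' @export
read_structure <- function(pdb, altloc_policy = "occupancy") {
  altloc_policy <- match.arg(altloc_policy, "occupancy")
  if (length(pdb) == 1 && !grepl("\n", pdb) && file.exists(pdb)) {
    path <- pdb
  } else {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(unlist(strsplit(paste(pdb, collapse = "\n"), "\n")), path)
  }
  parsed <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("PDB parse error: ", conditionMessage(e),
                             call. = FALSE))
  at <- parsed$atom
  orig <- at$resid
  mapped <- ifelse(orig %in% names(RESNAME_ALIASES),
                   unname(RESNAME_ALIASES[orig]), orig)
  keep <- mapped %in% STANDARD_AA & !(orig %in% WATER_NAMES)
  at <- at[keep, , drop = FALSE]
  orig <- orig[keep]
  mapped <- mapped[keep]
  if (nrow(at) == 0) {
    stop("empty structure: no protein residues found", call. = FALSE)
  }

  insert <- ifelse(is.na(at$insert), "", at$insert)
  reskey <- residue_key(at$chain, at$resno, insert)
  alt <- ifelse(is.na(at$alt), "", at$alt)
  occ <- ifelse(is.na(at$o), 1, at$o)

  # altloc resolution: per residue+atom-name group keep one record
  grp <- paste(reskey, at$elety, sep = "@")
  keep_idx <- unlist(lapply(split(seq_along(grp), grp), function(ix) {
    if (length(ix) == 1) return(ix)
    o <- order(-occ[ix], alt[ix])
    ix[o[1]]
  }), use.names = FALSE)
  keep_idx <- sort(keep_idx)
  at <- at[keep_idx, , drop = FALSE]
  orig <- orig[keep_idx]
  mapped <- mapped[keep_idx]
  insert <- insert[keep_idx]
  reskey <- reskey[keep_idx]

  elesy <- at$elesy
  guess <- sub("^[0-9]*", "", at$elety)
  guess <- toupper(substr(guess, 1, 1))
  elesy <- ifelse(is.na(elesy) | elesy == "", guess, elesy)
  is_h <- toupper(elesy) %in% c("H", "D")

  atoms <- data.frame(
    elety = at$elety, resid = mapped, chain = at$chain, resno = at$resno,
    insert = insert, x = at$x, y = at$y, z = at$z,
    o = ifelse(is.na(at$o), 1, at$o), b = ifelse(is.na(at$b), 0, at$b),
    elesy = elesy, is_h = is_h, reskey = reskey,
    stringsAsFactors = FALSE)
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("PDB parse error: non-finite coordinates", call. = FALSE)
  }

  first <- !duplicated(reskey)
  residues <- data.frame(
    reskey = reskey[first], resid = mapped[first], orig_resid = orig[first],
    chain = atoms$chain[first], resno = atoms$resno[first],
    insert = insert[first], stringsAsFactors = FALSE)
  ord <- order(residues$chain, residues$resno, residues$insert)
  residues <- residues[ord, , drop = FALSE]
  rownames(residues) <- NULL
  # re-order atoms to follow the residue order
  atoms <- atoms[order(match(atoms$reskey, residues$reskey)), , drop = FALSE]
  rownames(atoms) <- NULL

  structure(list(atoms = atoms, residues = residues,
                 metadata = list(source = if (exists("path")) path else NA)),
            class = "rapa_structure")
}

#' @export
print.rapa_structure <- function(x, ...) {
  cat("rapa_structure:", nrow(x$residues), "residues,",
      sum(!x$atoms$is_h), "heavy atoms,", sum(x$atoms$is_h), "hydrogens\n")
  tab <- table(x$residues$resid)
  cat("  composition:", paste(names(tab), tab, sep = ":", collapse = " "),
      "\n")
  invisible(x)
}

#' Coordinates of one named atom
#'
#' Convenience accessor: the xyz position of atom `name` in the residue
#' identified by `reskey`, or NULL if the atom is absent.
#'
#' @param s a `rapa_structure`.
#' @param reskey residue key (see `s$residues$reskey`).
#' @param name PDB atom name (e.g. "OD1").
#' @return numeric length-3 vector (Angstrom), or NULL.
#' @export
axyz <- function(s, reskey, name) {
  i <- which(s$atoms$reskey == reskey & s$atoms$elety == name)
  if (length(i) == 0) return(NULL)
  as.numeric(s$atoms[i[1], c("x", "y", "z")])
}

res_row <- function(s, reskey) {
  s$residues[s$residues$reskey == reskey, , drop = FALSE]
}

# side-chain donor/acceptor role table; HIS ring nitrogens and the
# SER/THR/TYR hydroxyls are state-dependent so they enter as "either"
SIDECHAIN_ROLES <- list(
  ASN = c(OD1 = "acceptor", ND2 = "donor"),
  GLN = c(OE1 = "acceptor", NE2 = "donor"),
  HIS = c(ND1 = "either", NE2 = "either"),
  ASP = c(OD1 = "acceptor", OD2 = "acceptor"),
  GLU = c(OE1 = "acceptor", OE2 = "acceptor"),
  SER = c(OG = "either"),
  THR = c(OG1 = "either"),
  TYR = c(OH = "either"),
  LYS = c(NZ = "donor"),
  ARG = c(NE = "donor", NH1 = "donor", NH2 = "donor"),
  TRP = c(NE1 = "donor"),
  CYS = c(SG = "donor")
)

#' Assign polar sites to every residue
#'
#' Types each polar heavy atom (N, O, side-chain S) as a hydrogen-bond
#' donor, acceptor, or either. Backbone amide nitrogens are donor-only
#' (except proline, which carries no amide hydrogen) and backbone carbonyl
#' oxygens acceptor-only. State-dependent atoms -- histidine ring nitrogens
#' and the SER/THR/TYR hydroxyl oxygens -- are typed "either"; their
#' effective role is resolved per rotamer/protonation state during scoring.
#' Cysteine SG sites of disulfide-bonded residues can be removed afterwards
#' (see [detect_disulfides()]).
#'
#' @param s a `rapa_structure`.
#' @return data.frame with one row per polar site: reskey, resname, atom,
#'   role (`donor`, `acceptor`, `either`), backbone flag and coordinates.
#' @export
assign_polar_sites <- function(s) {
  stopifnot(inherits(s, "rapa_structure"))
  out <- list()
  for (i in seq_len(nrow(s$residues))) {
    rk <- s$residues$reskey[i]
    rn <- s$residues$resid[i]
    add <- function(atom, role, backbone) {
      p <- axyz(s, rk, atom)
      if (is.null(p)) return(NULL)
      data.frame(reskey = rk, resname = rn, atom = atom, role = role,
                 backbone = backbone, x = p[1], y = p[2], z = p[3],
                 stringsAsFactors = FALSE)
    }
    rows <- list()
    if (rn != "PRO") rows <- c(rows, list(add("N", "donor", TRUE)))
    rows <- c(rows, list(add("O", "acceptor", TRUE),
                         add("OXT", "acceptor", TRUE)))
    tab <- SIDECHAIN_ROLES[[rn]]
    if (!is.null(tab)) {
      for (a in names(tab)) rows <- c(rows, list(add(a, tab[[a]], FALSE)))
    } else if (!rn %in% STANDARD_AA) {
      warning("unknown residue ", rn, " at ", rk,
              ": treated as nonpolar", call. = FALSE)
    }
    out <- c(out, rows)
  }
  sites <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(sites) <- NULL
  sites
}

#' Build the proximal-neighbor graph over polar sites
#'
#' Connects two polar sites when their heavy-atom distance is at or below
#' the proximal threshold and they belong to different residues. Residues
#' whose sites have no edges are the candidates for the "fully solvated"
#' label.
#'
#' @param sites polar-site table from [assign_polar_sites()].
#' @param threshold proximal distance, Angstrom (default 3.8).
#' @return object of class `rapa_graph`: list(sites, edges, threshold)
#'   where edges has columns i, j (row indices into `sites`, i < j) and
#'   dist.
#' @export
build_neighbor_graph <- function(sites, threshold = 3.8) {
  stopifnot(threshold > 0)
  xyz <- as.matrix(sites[, c("x", "y", "z")])
  n <- nrow(xyz)
  ii <- integer(0); jj <- integer(0); dd <- numeric(0)
  if (n > 1) {
    d <- as.matrix(stats::dist(xyz))
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (sites$reskey[i] != sites$reskey[j] && d[i, j] <= threshold) {
          ii <- c(ii, i); jj <- c(jj, j); dd <- c(dd, d[i, j])
        }
      }
    }
  }
  structure(list(sites = sites,
                 edges = data.frame(i = ii, j = jj, dist = dd),
                 threshold = threshold),
            class = "rapa_graph")
}

#' Detect disulfide bridges
#'
#' Pairs cysteine SG atoms at or below the disulfide threshold. Each SG
#' participates in at most one bridge; when several are mutually close the
#' closest pair wins (with a warning). Bridged cysteines are deprotonated
#' and treated as known; free cysteines keep a protonated thiol.
#'
#' @param s a `rapa_structure`.
#' @param threshold S-S distance cutoff, Angstrom (default 2.3).
#' @return data.frame with columns key1, key2, dist (possibly 0 rows).
#' @export
detect_disulfides <- function(s, threshold = 2.3) {
  stopifnot(threshold > 0)
  cys <- s$residues$reskey[s$residues$resid == "CYS"]
  sg <- lapply(cys, function(k) axyz(s, k, "SG"))
  has <- !vapply(sg, is.null, logical(1))
  cys <- cys[has]; sg <- sg[has]
  pairs <- data.frame(key1 = character(0), key2 = character(0),
                      dist = numeric(0), stringsAsFactors = FALSE)
  if (length(cys) < 2) return(pairs)
  cand <- list()
  for (i in seq_len(length(cys) - 1)) {
    for (j in seq(i + 1, length(cys))) {
      d <- vdist(sg[[i]], sg[[j]])
      if (d <= threshold) cand[[length(cand) + 1]] <- c(i, j, d)
    }
  }
  if (length(cand) == 0) return(pairs)
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand[, 3]), , drop = FALSE]
  used <- logical(length(cys))
  dropped <- FALSE
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (used[i] || used[j]) { dropped <- TRUE; next }
    used[i] <- used[j] <- TRUE
    pairs <- rbind(pairs, data.frame(key1 = cys[i], key2 = cys[j],
                                     dist = cand[r, 3],
                                     stringsAsFactors = FALSE))
  }
  if (dropped) {
    warning("more than two CYS SG atoms mutually close; ",
            "kept closest pairings only", call. = FALSE)
  }
  rownames(pairs) <- NULL
  pairs
}

#' Detect carboxylate acid dyads
#'
#' Two ASP/GLU residues form a dyad when any cross-pair of their
#' carboxylate oxygens lies at or below the proximal threshold; dyad
#' members are then evaluated over all singly-protonated states. Each
#' residue joins at most one dyad (closest pairing wins).
#'
#' @param s a `rapa_structure`.
#' @param threshold O-O cutoff, Angstrom (default 3.8).
#' @return data.frame with columns key1, key2, dist.
#' @export
detect_dyads <- function(s, threshold = 3.8) {
  acid <- s$residues[s$residues$resid %in% c("ASP", "GLU"), , drop = FALSE]
  oxy <- function(k) {
    rn <- res_row(s, k)$resid
    nm <- if (rn == "ASP") c("OD1", "OD2") else c("OE1", "OE2")
    lapply(nm, function(a) axyz(s, k, a))
  }
  pairs <- data.frame(key1 = character(0), key2 = character(0),
                      dist = numeric(0), stringsAsFactors = FALSE)
  if (nrow(acid) < 2) return(pairs)
  keys <- acid$reskey
  cand <- list()
  for (i in seq_len(length(keys) - 1)) {
    oi <- oxy(keys[i])
    for (j in seq(i + 1, length(keys))) {
      oj <- oxy(keys[j])
      d <- Inf
      for (a in oi) for (b in oj) {
        if (!is.null(a) && !is.null(b)) d <- min(d, vdist(a, b))
      }
      if (d <= threshold) cand[[length(cand) + 1]] <- c(i, j, d)
    }
  }
  if (length(cand) == 0) return(pairs)
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand[, 3]), , drop = FALSE]
  used <- logical(length(keys))
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (used[i] || used[j]) next
    used[i] <- used[j] <- TRUE
    pairs <- rbind(pairs, data.frame(key1 = keys[i], key2 = keys[j],
                                     dist = cand[r, 3],
                                     stringsAsFactors = FALSE))
  }
  rownames(pairs) <- NULL
  pairs
}

# Serialize an atom table to PDB text via bio3d. `atoms` uses the same
# columns as rapa_structure$atoms.
atoms_to_pdb_text <- function(atoms) {
  path <- tempfile(fileext = ".pdb")
  on.exit(unlink(path), add = TRUE)
  xyz <- as.numeric(t(as.matrix(atoms[, c("x", "y", "z")])))
  suppressWarnings(bio3d::write.pdb(
    file = path, xyz = xyz, type = rep("ATOM", nrow(atoms)),
    resno = atoms$resno, resid = atoms$resid,
    eleno = seq_len(nrow(atoms)), elety = atoms$elety,
    chain = atoms$chain, insert = ifelse(atoms$insert == "", NA,
                                         atoms$insert),
    o = atoms$o, b = atoms$b, elesy = atoms$elesy))
  paste(readLines(path), collapse = "\n")
}
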