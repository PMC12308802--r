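# PDB/report/summary output for finished runs. Polar hydrogens are always
# written at idealized geometry from the assigned states; input hydrogens
# are not echoed (nonpolar ones would be stale after a ring flip).

# canonical single-hydrogen names by (resname, heavy atom)
H_NAME <- c("HIS.ND1" = "HD1", "HIS.NE2" = "HE2", "TRP.NE1" = "HE1",
            "ARG.NE" = "HE", "CYS.SG" = "HG", "SER.OG" = "HG",
            "THR.OG1" = "HG1", "TYR.OH" = "HH")

# pick the real hydrogen among a donor's candidates: the one closest to
# any proximal acceptor-capable site (shortest-h-bond rule); falls back to
# the trans candidate when no acceptor is in range
choose_single_h <- function(ctx, config, k, site, fallback_row) {
  acc <- list()
  for (q in ctx$adjacency[[k]]) {
    for (y in resolved_sites(ctx, config, q)) {
      if (y$role %in% c("acceptor", "either") &&
          vdist(site$pos, y$pos) <= ctx$proximal) {
        acc[[length(acc) + 1]] <- y$pos
      }
    }
  }
  if (length(acc) == 0) return(site$hpos[fallback_row, ])
  dd <- apply(site$hpos, 1, function(h) {
    min(vapply(acc, function(p) vnorm(h - p), numeric(1)))
  })
  site$hpos[which.min(dd), ]
}

#' Write one configuration as PDB text
#'
#' Emits the heavy atoms with the assigned rotamer flips applied and all
#' polar hydrogens placed at idealized geometry. Histidine residues are
#' renamed HID/HIE/HIP according to their assigned tautomer (or kept as
#' plain HIS with `his_names = FALSE`); a dyad-protonated ASP/GLU is
#' renamed ASH/GLH.
#'
#' @param result a `rapa_result` from [rapa_run()].
#' @param which 1-based index of the configuration to write.
#' @param his_names emit tautomer-specific HIS residue names (default
#'   TRUE).
#' @return PDB text as a single character string.
#' @export
write_configuration <- function(result, which = 1, his_names = TRUE) {
  stopifnot(inherits(result, "rapa_result"),
            which >= 1, which <= result$n_configurations)
  ctx <- result$context
  s <- ctx$structure
  cf <- result$configurations[[which]]
  config <- list(status = stats::setNames(rep("known", length(ctx$units)),
                                          names(ctx$units)),
                 assigned = cf$assigned)
  if (anyNA(unlist(config$assigned))) {
    stop("configuration has unassigned residues", call. = FALSE)
  }

  rows <- list()
  put <- function(elety, elesy, pos, resid, chain, resno, insert) {
    rows[[length(rows) + 1]] <<- data.frame(
      elety = elety, resid = resid, chain = chain, resno = resno,
      insert = insert, x = pos[1], y = pos[2], z = pos[3], o = 1, b = 0,
      elesy = elesy, stringsAsFactors = FALSE)
  }

  for (i in seq_len(nrow(s$residues))) {
    k <- s$residues$reskey[i]
    rn <- s$residues$resid[i]
    chain <- s$residues$chain[i]
    resno <- s$residues$resno[i]
    insert <- s$residues$insert[i]
    uid <- ctx$unit_of[k]
    unit <- if (!is.na(uid)) ctx$units[[uid]] else NULL
    st <- if (!is.null(unit)) unit$states[[cf$assigned[[uid]]]] else NULL

    resname_out <- rn
    overrides <- list()
    if (!is.null(unit) && unit$type == "residue") {
      overrides <- st$coord_overrides
      if (rn == "HIS") resname_out <- if (his_names) st$protonation
                                      else "HIS"
    } else if (!is.null(unit) && unit$type == "dyad") {
      if (!is.null(st$protonated) && st$protonated$reskey == k &&
          his_names) {
        resname_out <- if (rn == "ASP") "ASH" else "GLH"
      }
    }

    heavy <- s$atoms[s$atoms$reskey == k & !s$atoms$is_h, , drop = FALSE]
    for (r in seq_len(nrow(heavy))) {
      nm <- heavy$elety[r]
      pos <- if (!is.null(overrides[[nm]])) overrides[[nm]]
             else as.numeric(heavy[r, c("x", "y", "z")])
      put(nm, heavy$elesy[r], pos, resname_out, chain, resno, insert)
    }

    # backbone amide hydrogen
    for (b in ctx$backbone[[k]]) {
      if (b$atom == "N" && !is.null(b$hpos)) {
        put("H", "H", b$hpos[1, ], resname_out, chain, resno, insert)
      }
    }

    # side-chain polar hydrogens from the assigned state / fixed sites
    sc <- if (!is.null(unit)) {
      unit_state_sites(ctx, unit, cf$assigned[[uid]])[[k]]
    } else {
      ctx$fixed_sidechain[[k]]
    }
    for (site in sc) {
      if (is.null(site$hpos) || nrow(site$hpos) == 0) next
      key <- paste(rn, site$atom, sep = ".")
      if (rn %in% c("ASN", "GLN") && nrow(site$hpos) == 2) {
        pre <- if (rn == "ASN") "HD2" else "HE2"
        put(paste0(pre, "1"), "H", site$hpos[1, ], resname_out, chain,
            resno, insert)
        put(paste0(pre, "2"), "H", site$hpos[2, ], resname_out, chain,
            resno, insert)
      } else if (rn == "ARG" && site$atom %in% c("NH1", "NH2")) {
        pre <- if (site$atom == "NH1") "HH1" else "HH2"
        put(paste0(pre, "1"), "H", site$hpos[1, ], resname_out, chain,
            resno, insert)
        put(paste0(pre, "2"), "H", site$hpos[2, ], resname_out, chain,
            resno, insert)
      } else if (rn == "LYS" && site$atom == "NZ") {
        for (hh in 1:3) {
          put(paste0("HZ", hh), "H", site$hpos[hh, ], resname_out, chain,
              resno, insert)
        }
      } else if (!is.null(unit) && unit$type == "dyad" &&
                 site$role == "donor") {
        put(if (rn == "ASP") "HD2" else "HE2", "H", site$hpos[1, ],
            resname_out, chain, resno, insert)
      } else if (nrow(site$hpos) == 1) {
        nm <- if (!is.na(H_NAME[key])) H_NAME[[key]] else "HX"
        put(nm, "H", site$hpos[1, ], resname_out, chain, resno, insert)
      } else {
        # one real hydrogen among several candidates (thiol, hydroxyl)
        fallback <- if (nrow(site$hpos) == 9) 5L
                    else if (nrow(site$hpos) == 3) 2L else 1L
        h <- choose_single_h(ctx, config, k, site, fallback)
        nm <- if (!is.na(H_NAME[key])) H_NAME[[key]] else "HX"
        put(nm, "H", h, resname_out, chain, resno, insert)
      }
    }
  }
  atoms <- do.call(rbind, rows)
  atoms$insert <- ifelse(is.na(atoms$insert), "", atoms$insert)
  atoms_to_pdb_text(atoms)
}

#' Write all outputs of a run to a directory
#'
#' Emits one PDB per configuration (named `<stem>_rapa_<k>.pdb`, k
#' 0-based), a per-residue TSV label report (`<stem>_rapa_report.tsv`)
#' and a JSON summary (`<stem>_rapa_summary.json`) with the configuration
#' count, cutoff and branch lineages.
#'
#' @param result a `rapa_result`.
#' @param dir output directory (created if needed).
#' @param stem file name stem (default "structure").
#' @param his_names see [write_configuration()].
#' @return invisibly, the vector of files written.
#' @export
write_rapa_result <- function(result, dir, stem = "structure",
                              his_names = TRUE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  for (i in seq_len(result$n_configurations)) {
    f <- file.path(dir, sprintf("%s_rapa_%d.pdb", stem, i - 1))
    writeLines(write_configuration(result, i, his_names), f)
    files <- c(files, f)
  }
  frep <- file.path(dir, paste0(stem, "_rapa_report.tsv"))
  utils::write.table(result$report, frep, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  fsum <- file.path(dir, paste0(stem, "_rapa_summary.json"))
  summary <- list(
    n_configurations = result$n_configurations,
    cutoff = result$cutoff,
    configurations = lapply(result$configurations, function(cf) {
      list(index = cf$index, signature = cf$signature,
           total_energy = cf$total_energy,
           lineage = lapply(cf$lineage, function(l) {
             list(unit = l$unit, state = l$state, score = l$score)
           }))
    }))
  jsonlite::write_json(summary, fsum, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(files, frep, fsum))
}
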