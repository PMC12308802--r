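# The recursive assignment workflow: initialization, iterative local
# resolution, branching on degenerate residues, termination, labeling.
#
# A "unit" is the object the protocol resolves: one ambiguous residue, or
# one ASP/GLU acid dyad (resolved pairwise so that exactly one carboxylate
# oxygen of the four can carry the proton). A configuration tracks, per
# unit, its status and assigned state index, plus the branch lineage.

AMBIGUOUS_TYPES <- c("HIS", "ASN", "GLN", "SER", "THR", "TYR")

#' Prepare the evaluation context for a structure
#'
#' Precomputes everything the workflow needs: polar sites, the
#' proximal-neighbor graph, disulfide bridges, acid dyads, per-residue
#' backbone and fixed side-chain sites, the per-unit state enumerations
#' and the residue-level adjacency used for environment scoring. Residue
#' adjacency is derived from the site graph and additionally considers
#' the alternate (flipped) positions of HIS ring nitrogens, so that an
#' interaction only reachable in the flipped rotamer still marks the
#' residues as proximal.
#'
#' @param s a `rapa_structure`.
#' @param table a `rapa_energy_table` (default [build_energy_table()]).
#' @param cutoff degeneracy cutoff, kcal/mol (default 1).
#' @param proximal proximal heavy-atom threshold, Angstrom (default 3.8).
#' @param disulfide S-S bridge threshold, Angstrom (default 2.3).
#' @param max_environments safety bound on the neighbor state product
#'   evaluated per residue (default 1e6).
#' @return list of class `rapa_context`.
#' @export
rapa_context <- function(s, table = build_energy_table(), cutoff = 1.0,
                         proximal = 3.8, disulfide = 2.3,
                         max_environments = 1e6) {
  stopifnot(inherits(s, "rapa_structure"), cutoff >= 0, proximal > 0,
            disulfide > 0)
  sites <- assign_polar_sites(s)
  graph <- build_neighbor_graph(sites, proximal)
  ss <- detect_disulfides(s, disulfide)
  bridged <- unique(c(ss$key1, ss$key2))
  dyads <- detect_dyads(s, proximal)

  res <- s$residues
  nres <- nrow(res)

  # previous-residue carbonyl carbon for backbone amide H placement
  prev_c <- vector("list", nres)
  for (i in seq_len(nres)) {
    if (i == 1 || res$chain[i] != res$chain[i - 1]) next
    cpos <- axyz(s, res$reskey[i - 1], "C")
    npos <- axyz(s, res$reskey[i], "N")
    if (!is.null(cpos) && !is.null(npos) && vdist(cpos, npos) < 1.8) {
      prev_c[[i]] <- cpos
    }
  }
  bb <- lapply(seq_len(nres), function(i) {
    backbone_sites(s, res$reskey[i], prev_c[[i]])
  })
  names(bb) <- res$reskey

  dyad_members <- unique(c(dyads$key1, dyads$key2))

  # residue-level adjacency, including flipped HIS ring-N positions
  polar_pos <- lapply(res$reskey, function(k) {
    p <- graph$sites[graph$sites$reskey == k, c("x", "y", "z"),
                     drop = FALSE]
    m <- as.matrix(p)
    if (res_row(s, k)$resid == "HIS") {
      extra <- rbind(axyz(s, k, "CD2"), axyz(s, k, "CE1"))
      if (!is.null(extra)) m <- rbind(m, extra)
    }
    m
  })
  names(polar_pos) <- res$reskey
  adjacency <- lapply(res$reskey, function(k) character(0))
  names(adjacency) <- res$reskey
  for (i in seq_len(nres - 1)) {
    mi <- polar_pos[[i]]
    if (is.null(mi) || nrow(mi) == 0) next
    for (j in seq(i + 1, nres)) {
      mj <- polar_pos[[j]]
      if (is.null(mj) || nrow(mj) == 0) next
      dmin <- min(apply(mi, 1, function(p) {
        min(sqrt(colSums((t(mj) - p)^2)))
      }))
      if (dmin <= proximal) {
        ki <- res$reskey[i]; kj <- res$reskey[j]
        adjacency[[ki]] <- c(adjacency[[ki]], kj)
        adjacency[[kj]] <- c(adjacency[[kj]], ki)
      }
    }
  }

  # units: ambiguous residues and dyads, in sequence order
  units <- list()
  unit_of <- character(0)   # reskey -> unit id
  done_dyad <- character(0)
  for (i in seq_len(nres)) {
    k <- res$reskey[i]
    rn <- res$resid[i]
    if (rn %in% AMBIGUOUS_TYPES) {
      st <- tryCatch(enumerate_states(s, k), error = function(e) {
        warning("residue ", k, " (", rn, ") forced known: ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
      if (is.null(st)) next
      id <- k
      units[[id]] <- list(id = id, type = "residue", reskeys = k,
                          resname = rn, states = st)
      unit_of[k] <- id
    } else if (k %in% dyad_members && !k %in% done_dyad) {
      row <- dyads[dyads$key1 == k | dyads$key2 == k, , drop = FALSE]
      k2 <- setdiff(c(row$key1[1], row$key2[1]), k)
      st <- enumerate_dyad_states(s, k, k2, proximal)
      id <- paste(k, k2, sep = "+")
      units[[id]] <- list(id = id, type = "dyad", reskeys = c(k, k2),
                          resname = "dyad", states = st)
      unit_of[k] <- id
      unit_of[k2] <- id
      done_dyad <- c(done_dyad, k, k2)
    }
  }

  fixed_sc <- lapply(res$reskey, function(k) {
    if (!is.null(unit_of[k]) && !is.na(unit_of[k])) return(list())
    fixed_sidechain_sites(s, k, bridged = k %in% bridged)
  })
  names(fixed_sc) <- res$reskey

  structure(list(structure = s, table = table, cutoff = cutoff,
                 proximal = proximal, sites = sites, graph = graph,
                 disulfides = ss, dyads = dyads, adjacency = adjacency,
                 backbone = bb, fixed_sidechain = fixed_sc,
                 units = units, unit_of = unit_of,
                 max_environments = max_environments),
            class = "rapa_context")
}

# side-chain sites of a unit in state `si`, split by residue key
unit_state_sites <- function(ctx, unit, si) {
  st <- unit$states[[si]]
  if (unit$type == "residue") {
    out <- list(st$sites)
    names(out) <- unit$reskeys
    return(out)
  }
  # dyad: carboxylate oxygens of both members; the protonated one donates
  s <- ctx$structure
  out <- lapply(unit$reskeys, function(k) {
    rn <- res_row(s, k)$resid
    nm <- if (rn == "ASP") c("OD1", "OD2") else c("OE1", "OE2")
    lapply(nm, function(a) {
      pos <- axyz(s, k, a)
      if (!is.null(st$protonated) && st$protonated$reskey == k &&
          st$protonated$atom == a) {
        list(atom = a, pos = pos, role = "donor",
             hpos = matrix(st$h, nrow = 1))
      } else {
        list(atom = a, pos = pos, role = "acceptor", hpos = NULL)
      }
    })
  })
  names(out) <- unit$reskeys
  out
}

# full site list (backbone + side chain) of residue `k` as determined by
# the configuration (known residues and already-assigned units)
resolved_sites <- function(ctx, config, k) {
  uid <- ctx$unit_of[k]
  sc <- if (is.null(uid) || is.na(uid)) {
    ctx$fixed_sidechain[[k]]
  } else if (config$status[[uid]] == "known") {
    unit_state_sites(ctx, ctx$units[[uid]], config$assigned[[uid]])[[k]]
  } else {
    NULL  # caller handles ambiguous neighbors explicitly
  }
  c(ctx$backbone[[k]], sc)
}

#' Environment energy of one unit state under a full neighbor assignment
#'
#' Sum of all pairwise polar interactions incident to the unit's sites
#' (backbone and side chain), given an explicit state choice for every
#' proximal ambiguous neighbor; known neighbors contribute their fixed
#' assignment. For a dyad unit the internal member-member interactions are
#' included.
#'
#' @param ctx a `rapa_context`.
#' @param config a configuration (see [rapa_initialize()]).
#' @param unit_id id of the unit being scored.
#' @param si state index of the unit.
#' @param neighbor_states named integer vector: state index per ambiguous
#'   neighbor unit id. Must cover every proximal ambiguous neighbor.
#' @return energy in kcal/mol.
#' @export
environment_energy <- function(ctx, config, unit_id, si,
                               neighbor_states = integer(0)) {
  unit <- ctx$units[[unit_id]]
  own_sc <- unit_state_sites(ctx, unit, si)
  own <- lapply(unit$reskeys, function(k) {
    c(ctx$backbone[[k]], own_sc[[k]])
  })
  names(own) <- unit$reskeys
  e <- 0
  # dyad internal interactions
  if (length(unit$reskeys) == 2) {
    e <- e + sites_interaction(ctx$table, own[[1]], own[[2]], ctx$proximal)
  }
  nbr_keys <- setdiff(unique(unlist(ctx$adjacency[unit$reskeys])),
                      unit$reskeys)
  for (q in nbr_keys) {
    quid <- ctx$unit_of[q]
    ambiguous <- !is.null(quid) && !is.na(quid) &&
      config$status[[quid]] == "ambiguous"
    if (ambiguous) {
      if (is.na(match(quid, names(neighbor_states)))) {
        stop("missing neighbor assignment for unit ", quid, call. = FALSE)
      }
      qs <- unit_state_sites(ctx, ctx$units[[quid]],
                             neighbor_states[[quid]])[[q]]
      qsites <- c(ctx$backbone[[q]], qs)
    } else {
      qsites <- resolved_sites(ctx, config, q)
    }
    for (k in unit$reskeys) {
      e <- e + sites_interaction(ctx$table, own[[k]], qsites,
                                 ctx$proximal)
    }
  }
  e
}

#' Best-case energies of every state of an ambiguous unit
#'
#' For each state of the unit, evaluates the environment energy over the
#' Cartesian product of the state lists of all proximal ambiguous
#' neighbors (known neighbors contribute their fixed state) and keeps the
#' minimum: the most favorable environment reachable for that state.
#'
#' @inheritParams environment_energy
#' @return numeric vector of per-state scores (kcal/mol), named by
#'   state id, with attribute `n_environments` giving the number of
#'   environments evaluated.
#' @export
best_state_energies <- function(ctx, config, unit_id) {
  unit <- ctx$units[[unit_id]]
  nbr_keys <- setdiff(unique(unlist(ctx$adjacency[unit$reskeys])),
                      unit$reskeys)
  nbr_units <- unique(stats::na.omit(ctx$unit_of[nbr_keys]))
  nbr_units <- nbr_units[vapply(nbr_units, function(u) {
    config$status[[u]] == "ambiguous"
  }, logical(1))]
  counts <- vapply(nbr_units, function(u) length(ctx$units[[u]]$states),
                   integer(1))
  n_self <- length(unit$states)
  n_env <- n_self * prod(c(1, counts))
  if (n_env > ctx$max_environments) {
    stop("state product for unit ", unit_id, " exceeds the ",
         "max_environments bound (", n_env, " > ", ctx$max_environments,
         "); offending neighbors: ", paste(nbr_units, collapse = ", "),
         call. = FALSE)
  }
  combos <- if (length(counts) > 0) {
    as.matrix(expand.grid(lapply(counts, seq_len)))
  } else {
    matrix(integer(0), nrow = 1, ncol = 0)
  }
  scores <- vapply(seq_len(n_self), function(si) {
    best <- Inf
    for (r in seq_len(nrow(combos))) {
      ns <- if (ncol(combos) > 0) {
        stats::setNames(as.integer(combos[r, ]), nbr_units)
      } else integer(0)
      best <- min(best, environment_energy(ctx, config, unit_id, si, ns))
    }
    best
  }, numeric(1))
  names(scores) <- vapply(unit$states, function(st) st$state_id,
                          character(1))
  attr(scores, "n_environments") <- n_env
  scores
}

# indices of states within `cutoff` (inclusive, with a tie tolerance) of
# the minimum score
degenerate_states <- function(scores, cutoff) {
  which(scores <= min(scores) + cutoff + 1e-9)
}

# the state a residue keeps when fully solvated: the input-equivalent one
input_state_index <- function(ctx, unit) {
  if (unit$type == "dyad") return(1L)
  if (unit$resname == "HIS") {
    orig <- res_row(ctx$structure, unit$reskeys)$orig_resid
    tau <- if (orig %in% c("HID", "HSD")) "HID"
           else if (orig %in% c("HIP", "HSP")) "HIP"
           else "HIE"
    ids <- vapply(unit$states, function(st) st$state_id, character(1))
    return(match(paste0(tau, ":rot0"), ids))
  }
  1L
}

#' Initialize a configuration
#'
#' Applies the residue treatment rules: nonpolar residues and TRP, LYS,
#' ARG and CYS (protonated thiol, or deprotonated when disulfide-bonded)
#' are known from the start; HIS, ASN, GLN, SER, THR and TYR start
#' ambiguous; ASP/GLU are known and deprotonated unless they sit in a
#' detected acid dyad, in which case the dyad is an ambiguous unit.
#'
#' @param ctx a `rapa_context`.
#' @return a configuration: list(status, assigned, lineage, solvated,
#'   decisions).
#' @export
rapa_initialize <- function(ctx) {
  ids <- names(ctx$units)
  list(status = stats::setNames(rep("ambiguous", length(ids)), ids),
       assigned = stats::setNames(rep(NA_integer_, length(ids)), ids),
       lineage = list(),
       solvated = character(0),
       decisions = list())
}

#' One sequential evaluation pass over the ambiguous residues
#'
#' Visits ambiguous units in sequence order. A unit with no proximal
#' neighbors is fully solvated: it keeps its input-equivalent state and
#' becomes known. Otherwise its per-state best-case energies are computed;
#' if exactly one state lies within the cutoff of the minimum (every
#' alternative more than `cutoff` above it), that state is assigned and
#' the unit becomes known immediately, so later residues in the same pass
#' see the update.
#'
#' @inheritParams environment_energy
#' @return list(config, changed): the updated configuration and whether
#'   any unit status flipped.
#' @export
evaluation_pass <- function(ctx, config) {
  changed <- FALSE
  for (uid in names(ctx$units)) {
    if (config$status[[uid]] != "ambiguous") next
    unit <- ctx$units[[uid]]
    nbr_keys <- setdiff(unique(unlist(ctx$adjacency[unit$reskeys])),
                        unit$reskeys)
    if (length(nbr_keys) == 0 && unit$type == "residue") {
      si <- input_state_index(ctx, unit)
      config$status[[uid]] <- "known"
      config$assigned[[uid]] <- si
      config$solvated <- c(config$solvated, uid)
      config$decisions[[uid]] <- list(scores = NULL, n_within = 1L,
                                      gap = NA_real_, solvated = TRUE,
                                      how = "solvated")
      changed <- TRUE
      next
    }
    scores <- best_state_energies(ctx, config, uid)
    deg <- degenerate_states(scores, ctx$cutoff)
    srt <- sort(scores)
    gap <- if (length(scores) > 1) srt[2] - srt[1] else Inf
    config$decisions[[uid]] <- list(scores = scores,
                                    n_within = length(deg), gap = gap,
                                    solvated = FALSE, how = "pending")
    if (length(deg) == 1) {
      config$status[[uid]] <- "known"
      config$assigned[[uid]] <- deg[[1]]
      config$decisions[[uid]]$how <- "resolved"
      changed <- TRUE
    }
  }
  list(config = config, changed = changed)
}

#' Branch a stalled configuration on its first degenerate unit
#'
#' Called when an evaluation pass makes no progress while ambiguous units
#' remain. The first ambiguous unit in sequence order is branched: one
#' child configuration per state within the cutoff of its minimum score
#' (states above the cutoff are discarded), children ordered most
#' favorable first.
#'
#' @inheritParams environment_energy
#' @return list of child configurations.
#' @export
branch_configuration <- function(ctx, config) {
  for (uid in names(ctx$units)) {
    if (config$status[[uid]] != "ambiguous") next
    scores <- best_state_energies(ctx, config, uid)
    deg <- degenerate_states(scores, ctx$cutoff)
    if (length(deg) < 2) {
      # should have been fixed by the evaluation pass
      stop("internal error: unit ", uid,
           " is not degenerate yet branching was requested",
           call. = FALSE)
    }
    deg <- deg[order(scores[deg])]
    return(lapply(deg, function(si) {
      child <- config
      child$status[[uid]] <- "known"
      child$assigned[[uid]] <- si
      child$lineage <- c(child$lineage,
                         list(list(unit = uid,
                                   state = ctx$units[[uid]]$states[[si]]$state_id,
                                   score = unname(scores[si]))))
      child$decisions[[uid]] <- list(scores = scores,
                                     n_within = length(deg),
                                     gap = sort(scores)[2] - min(scores),
                                     solvated = FALSE, how = "branched")
      child
    }))
  }
  stop("internal error: no ambiguous unit to branch on", call. = FALSE)
}

config_signature <- function(ctx, config) {
  paste(vapply(names(ctx$units), function(uid) {
    si <- config$assigned[[uid]]
    ctx$units[[uid]]$states[[si]]$state_id
  }, character(1)), collapse = ";")
}

#' Run the full assignment workflow
#'
#' Depth-first execution of the recursive protocol: repeated evaluation
#' passes resolve every uniquely favorable residue; when no progress is
#' possible the first degenerate residue is branched and each child is
#' processed independently until all residues are known. Duplicate final
#' assignments (branches can reconverge) are removed; outputs appear in
#' depth-first order with the lowest-energy child explored first, and the
#' run is fully deterministic.
#'
#' @param s a `rapa_structure`, or anything [read_structure()] accepts.
#' @param table a `rapa_energy_table`.
#' @param cutoff degeneracy cutoff, kcal/mol (default 1).
#' @param proximal,disulfide distance thresholds, Angstrom.
#' @param max_branches cap on the number of configurations explored
#'   (default 4096); exceeding it raises a resource error naming the
#'   residues still ambiguous.
#' @param max_environments safety bound for [best_state_energies()].
#' @return object of class `rapa_result`: configurations (each with
#'   per-unit assignments, lineage and total energy), residue labels,
#'   a per-residue report table, and the context.
#' @examples
#' r <- rapa_run(read_structure(make_fixture("asn_asn")))
#' r$n_configurations  # 2: both amide pairings are within the cutoff
#' @export
rapa_run <- function(s, table = build_energy_table(), cutoff = 1.0,
                     proximal = 3.8, disulfide = 2.3, max_branches = 4096,
                     max_environments = 1e6) {
  if (!inherits(s, "rapa_structure")) s <- read_structure(s)
  ctx <- rapa_context(s, table, cutoff, proximal, disulfide,
                      max_environments)
  finals <- list()
  n_explored <- 0

  process <- function(config) {
    repeat {
      if (all(config$status == "known") || length(config$status) == 0) {
        finals[[length(finals) + 1]] <<- config
        return(invisible(NULL))
      }
      res <- evaluation_pass(ctx, config)
      config <- res$config
      if (!res$changed) break
    }
    if (all(config$status == "known")) {
      finals[[length(finals) + 1]] <<- config
      return(invisible(NULL))
    }
    children <- branch_configuration(ctx, config)
    n_explored <<- n_explored + length(children)
    if (n_explored > max_branches) {
      amb <- names(config$status)[config$status == "ambiguous"]
      stop("branch cap exceeded (", max_branches, "); residues still ",
           "ambiguous: ", paste(amb, collapse = ", "), call. = FALSE)
    }
    for (ch in children) process(ch)
  }
  process(rapa_initialize(ctx))

  sigs <- vapply(finals, function(cf) config_signature(ctx, cf),
                 character(1))
  keep <- !duplicated(sigs)
  finals <- finals[keep]
  sigs <- sigs[keep]

  configurations <- lapply(seq_along(finals), function(i) {
    cf <- finals[[i]]
    list(index = i - 1L, assigned = cf$assigned, lineage = cf$lineage,
         signature = sigs[i], decisions = cf$decisions,
         solvated = cf$solvated,
         total_energy = config_total_energy(ctx, cf))
  })

  result <- structure(
    list(structure = s, context = ctx, cutoff = cutoff,
         configurations = configurations,
         n_configurations = length(configurations)),
    class = "rapa_result")
  result$labels <- label_residues(result)
  result$report <- residue_report(result)
  result
}

# total polar interaction energy of a fully-known configuration (each
# proximal residue pair counted once)
config_total_energy <- function(ctx, config) {
  res <- ctx$structure$residues
  e <- 0
  for (i in seq_len(nrow(res))) {
    ki <- res$reskey[i]
    si <- resolved_sites(ctx, config, ki)
    for (kj in ctx$adjacency[[ki]]) {
      j <- match(kj, res$reskey)
      if (j <= i) next
      sj <- resolved_sites(ctx, config, kj)
      e <- e + sites_interaction(ctx$table, si, sj, ctx$proximal)
    }
  }
  e
}

# does residue k make at least one h-bond with the protein in config?
makes_hbond <- function(ctx, config, k) {
  si <- resolved_sites(ctx, config, k)
  for (q in ctx$adjacency[[k]]) {
    sq <- resolved_sites(ctx, config, q)
    for (x in si) for (y in sq) {
      pe <- pair_energy(ctx$table, x, y, ctx$proximal)
      if (pe$kind == "hbond" && pe$energy < 0) return(TRUE)
    }
  }
  FALSE
}

#' Label the ambiguous residues of a finished run
#'
#' Each ASN, GLN and HIS residue receives one label: `fully_solvated` if
#' it makes no hydrogen bond with the protein in the best configuration;
#' `degenerate` if it was ever branched on or its assignment differs
#' across the output configurations; otherwise `fixed`.
#'
#' @param result a `rapa_result`.
#' @return data.frame: reskey, chain, resno, resname, label.
#' @export
label_residues <- function(result) {
  ctx <- result$context
  best <- result$configurations[[1]]
  bestcf <- list(status = stats::setNames(
    rep("known", length(ctx$units)), names(ctx$units)),
    assigned = best$assigned)
  branched <- unique(unlist(lapply(result$configurations, function(cf) {
    vapply(cf$lineage, function(l) l$unit, character(1))
  })))
  differs <- function(uid) {
    a <- vapply(result$configurations, function(cf) cf$assigned[[uid]],
                integer(1))
    length(unique(a)) > 1
  }
  res <- ctx$structure$residues
  rows <- list()
  for (i in seq_len(nrow(res))) {
    k <- res$reskey[i]
    rn <- res$resid[i]
    if (!rn %in% AMBIGUOUS_TYPES) next
    uid <- ctx$unit_of[k]
    label <- if (!makes_hbond(ctx, bestcf, k)) {
      "fully_solvated"
    } else if (!is.null(uid) && !is.na(uid) &&
               (uid %in% branched || differs(uid))) {
      "degenerate"
    } else {
      "fixed"
    }
    rows[[length(rows) + 1]] <- data.frame(
      reskey = k, chain = res$chain[i], resno = res$resno[i],
      resname = rn, label = label, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(reskey = character(0), chain = character(0),
                      resno = integer(0), resname = character(0),
                      label = character(0))
  }
  rownames(out) <- NULL
  out
}

# per-residue report: label, states within cutoff, best energy, gap
residue_report <- function(result) {
  ctx <- result$context
  best <- result$configurations[[1]]
  rows <- list()
  for (i in seq_len(nrow(result$labels))) {
    k <- result$labels$reskey[i]
    uid <- ctx$unit_of[k]
    dec <- if (!is.null(uid) && !is.na(uid)) best$decisions[[uid]]
           else NULL
    rows[[length(rows) + 1]] <- data.frame(
      chain = result$labels$chain[i], resno = result$labels$resno[i],
      resname = result$labels$resname[i], label = result$labels$label[i],
      n_states_within_cutoff = if (!is.null(dec)) dec$n_within
                               else NA_integer_,
      best_energy = if (!is.null(dec) && !is.null(dec$scores))
        min(dec$scores) else NA_real_,
      runner_up_gap = if (!is.null(dec)) unname(dec$gap) else NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(chain = character(0), resno = integer(0),
                      resname = character(0), label = character(0),
                      n_states_within_cutoff = integer(0),
                      best_energy = numeric(0),
                      runner_up_gap = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' @export
print.rapa_result <- function(x, ...) {
  cat("rapa_result:", x$n_configurations, "configuration(s), cutoff",
      x$cutoff, "kcal/mol\n")
  if (nrow(x$labels) > 0) {
    tab <- table(x$labels$label)
    cat("  labels:", paste(names(tab), tab, sep = ":", collapse = " "),
        "\n")
  }
  invisible(x)
}
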