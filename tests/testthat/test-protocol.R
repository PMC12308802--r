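test_that("initialization applies the residue treatment rules", {
  # disulfide pair: both CYS known (no thiol site), no ambiguous units
  ctx <- rapa_context(read_structure(make_fixture("cys_pair",
                                                  distance = 2.0)))
  expect_length(ctx$units, 0)
  expect_equal(nrow(ctx$disulfides), 1)

  # one HIS -> exactly one ambiguous unit (the GLY probes are known)
  ctx <- rapa_context(read_structure(make_fixture("his_probe")))
  expect_length(ctx$units, 1)
  expect_equal(ctx$units[[1]]$resname, "HIS")

  # dyad members form a single pairwise unit with five states
  ctx <- rapa_context(read_structure(make_fixture("asp_dyad")))
  expect_length(ctx$units, 1)
  expect_equal(ctx$units[[1]]$type, "dyad")
  expect_length(ctx$units[[1]]$states, 5)

  # non-dyad ASP is known-deprotonated (not a unit)
  ctx <- rapa_context(read_structure(make_fixture("asp_dyad",
                                                  distance = 6)))
  expect_length(ctx$units, 0)
})

test_that("an evaluation pass fixes uniquely favorable residues", {
  ctx <- rapa_context(read_structure(make_fixture("his_probe")))
  cfg <- rapa_initialize(ctx)
  out <- evaluation_pass(ctx, cfg)
  expect_true(out$changed)
  uid <- names(ctx$units)[1]
  expect_equal(unname(out$config$status[[uid]]), "known")
  st <- ctx$units[[uid]]$states[[out$config$assigned[[uid]]]]
  expect_equal(st$state_id, "HIE:rot0")
})

test_that("isolated residues become known and fully solvated", {
  for (rn in c("ASN", "GLN")) {
    ctx <- rapa_context(read_structure(make_fixture("isolated",
                                                    resname = rn)))
    out <- evaluation_pass(ctx, rapa_initialize(ctx))
    uid <- names(ctx$units)[1]
    expect_true(out$changed)
    expect_equal(unname(out$config$status[[uid]]), "known")
    expect_true(uid %in% out$config$solvated)
    # keeps the input rotamer
    expect_equal(ctx$units[[uid]]$states[[
      out$config$assigned[[uid]]]]$rotamer, 0)
  }
})

test_that("degenerate residues are left ambiguous by the pass", {
  ctx <- rapa_context(read_structure(make_fixture("asn_asn")))
  cfg <- rapa_initialize(ctx)
  out <- evaluation_pass(ctx, cfg)
  amb <- names(ctx$units)[vapply(names(ctx$units), function(u) {
    out$config$status[[u]] == "ambiguous"
  }, logical(1))]
  expect_length(amb, 2)
})

test_that("branch selection keeps only states within the cutoff", {
  # pure threshold arithmetic on a score vector
  sc <- c(A = -5.0, B = -4.4, C = -2.0)
  expect_equal(names(sc)[rapa:::degenerate_states(sc, 1.0)], c("A", "B"))
  expect_equal(names(sc)[rapa:::degenerate_states(sc, 0.5)], "A")
  expect_equal(names(sc)[rapa:::degenerate_states(sc, 3.5)],
               c("A", "B", "C"))
  # exact ties branch (inclusive test)
  expect_length(rapa:::degenerate_states(c(-3, -3), 0), 2)

  # on the symmetric amide pair: two branches from the first residue
  ctx <- rapa_context(read_structure(make_fixture("asn_asn")))
  cfg <- evaluation_pass(ctx, rapa_initialize(ctx))$config
  kids <- branch_configuration(ctx, cfg)
  expect_length(kids, 2)
  first <- names(ctx$units)[1]
  for (ch in kids) {
    expect_equal(unname(ch$status[[first]]), "known")
    expect_length(ch$lineage, 1)
    expect_equal(ch$lineage[[1]]$unit, first)
  }
})

test_that("run resolves, branches, and deduplicates deterministically", {
  # no ambiguity: one configuration
  r <- rapa_run(read_structure(make_fixture("cys_pair")))
  expect_equal(r$n_configurations, 1)

  # symmetric pair: the two self-consistent pairings survive
  r <- rapa_run(read_structure(make_fixture("asn_asn")))
  expect_equal(r$n_configurations, 2)
  sigs <- vapply(r$configurations, function(cf) cf$signature,
                 character(1))
  expect_equal(anyDuplicated(sigs), 0)
  # the two configurations pair rot0-rot0 and rot1-rot1
  expect_setequal(sigs, c("ASN:rot0;ASN:rot0", "ASN:rot1;ASN:rot1"))

  # determinism: byte-identical outputs on repeated runs
  r2 <- rapa_run(read_structure(make_fixture("asn_asn")))
  expect_identical(vapply(r2$configurations, function(cf) cf$signature,
                          character(1)), sigs)
  expect_identical(write_configuration(r2, 1), write_configuration(r, 1))
})

test_that("independent motifs multiply: output equals the product oracle", {
  for (k in 1:3) {
    s <- read_structure(make_fixture("multi_pair", k = k,
                                     motif = "asn_ser"))
    r <- rapa_run(s)
    ctx <- r$context
    cfg <- rapa_initialize(ctx)
    # independent per-unit enumerator at initialization
    sets <- lapply(names(ctx$units), function(uid) {
      sc <- best_state_energies(ctx, cfg, uid)
      rapa:::degenerate_states(sc, ctx$cutoff)
    })
    expect_equal(r$n_configurations, prod(lengths(sets)))
    want <- apply(expand.grid(lapply(sets, function(ix) {
      as.integer(ix)
    })), 1, function(row) paste(row, collapse = "|"))
    got <- vapply(r$configurations, function(cf) {
      paste(unlist(cf$assigned), collapse = "|")
    }, character(1))
    expect_setequal(got, want)
  }
})

test_that("configuration count never decreases with a larger cutoff", {
  fixtures <- list(make_fixture("asn_asn"),
                   make_fixture("asn_asn", perturb = 10),
                   make_fixture("asn_ser"),
                   make_fixture("his_probe"),
                   make_fixture("asp_dyad"))
  for (fix in fixtures) {
    s <- read_structure(fix)
    n1 <- rapa_run(s, cutoff = 1.0)$n_configurations
    n2 <- rapa_run(s, cutoff = 2.0)$n_configurations
    expect_gte(n2, n1)
  }
  # a gap between the cutoffs separates the counts
  s <- read_structure(make_fixture("asn_asn", perturb = 12))
  expect_equal(rapa_run(s, cutoff = 1.0)$n_configurations, 1)
  expect_equal(rapa_run(s, cutoff = 2.0)$n_configurations, 2)
})

test_that("the output count respects the state-count product bound", {
  for (fix in c("asn_asn", "asn_ser", "his_probe", "asp_dyad")) {
    r <- rapa_run(read_structure(make_fixture(fix)))
    bound <- prod(vapply(r$context$units, function(u) length(u$states),
                         integer(1)))
    expect_lte(r$n_configurations, bound)
  }
})

test_that("branch cap raises a resource error naming residues", {
  s <- read_structure(make_fixture("multi_pair", k = 3))
  expect_error(rapa_run(s, max_branches = 3), "branch cap")
})

test_that("labels distinguish solvated, fixed and degenerate residues", {
  r <- rapa_run(read_structure(make_fixture("isolated", resname = "ASN")))
  expect_equal(r$labels$label, "fully_solvated")

  r <- rapa_run(read_structure(make_fixture("his_probe")))
  expect_equal(r$labels$label[r$labels$resname == "HIS"], "fixed")

  r <- rapa_run(read_structure(make_fixture("asn_asn")))
  expect_equal(r$labels$label, c("degenerate", "degenerate"))

  # report carries the decision bookkeeping
  expect_true(all(c("label", "n_states_within_cutoff", "best_energy",
                    "runner_up_gap") %in% names(r$report)))
  expect_equal(r$report$n_states_within_cutoff,
               c(2L, 1L))  # branched ASN, then uniquely resolved partner
})

test_that("write_rapa_result emits one PDB per configuration plus reports", {
  dir <- tempfile()
  r <- rapa_run(read_structure(make_fixture("asn_asn")))
  files <- write_rapa_result(r, dir, "pair")
  expect_true(file.exists(file.path(dir, "pair_rapa_0.pdb")))
  expect_true(file.exists(file.path(dir, "pair_rapa_1.pdb")))
  expect_true(file.exists(file.path(dir, "pair_rapa_report.tsv")))
  js <- jsonlite::read_json(file.path(dir, "pair_rapa_summary.json"))
  expect_equal(js$n_configurations, 2)
  expect_equal(js$cutoff, 1)
  # the two PDBs differ (flipped amides), both re-readable
  p0 <- read_structure(file.path(dir, "pair_rapa_0.pdb"))
  p1 <- read_structure(file.path(dir, "pair_rapa_1.pdb"))
  expect_false(isTRUE(all.equal(axyz(p0, p0$residues$reskey[1], "OD1"),
                                axyz(p1, p1$residues$reskey[1], "OD1"))))
})
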