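# site constructors for controlled geometries
donor_site <- function(pos, h) {
  list(atom = "X", pos = pos, role = "donor", hpos = matrix(h, nrow = 1))
}
acceptor_site <- function(pos) {
  list(atom = "X", pos = pos, role = "acceptor", hpos = NULL)
}
# donor at origin with its H aimed along +x; acceptor placed so that the
# heavy-heavy distance is d and the donor-H-acceptor angle is theta
da_geometry <- function(d, theta) {
  h <- c(1.01, 0, 0)
  th <- theta * pi / 180
  L <- 1.01 * cos(th) + sqrt(d^2 - 1.01^2 * sin(th)^2)
  acc <- h + L * c(-cos(th), sin(th), 0)
  list(don = donor_site(c(0, 0, 0), h), acc = acceptor_site(acc))
}

test_that("energy table has its minimum at the equilibrium geometry", {
  t <- build_energy_table()
  expect_equal(dim(t$energies), c(16, 901))
  # exhaustive scan
  i <- which(t$energies == min(t$energies), arr.ind = TRUE)
  expect_equal(nrow(i), 1)
  expect_equal(t$dgrid[i[1, 1]], 2.8)
  expect_equal(t$agrid[i[1, 2]], 180)
  expect_equal(min(t$energies), t$params$well_depth)
  # least favorable value sits at (4.0, 90)
  expect_equal(t$energies[16, 1], max(t$energies))
})

test_that("angle monotonicity holds on every table row", {
  t <- build_energy_table()
  for (i in seq_along(t$dgrid)) {
    expect_true(all(diff(t$energies[i, ]) <= 1e-12))
  }
})

test_that("lookup uses nearest grid point with the stated edge rules", {
  t <- build_energy_table()
  expect_equal(lookup_energy(t, 3.95, 179.96), t$energies[16, 901])
  expect_equal(lookup_energy(t, 5.0, 170), 0)
  expect_equal(lookup_energy(t, 3.0, 85), 0)
  expect_equal(lookup_energy(t, 2.8, 180), min(t$energies))
  # below-range distances clamp to the first row
  expect_equal(lookup_energy(t, 2.0, 180), t$energies[1, 901])
  expect_equal(lookup_energy(t, 3.14, 135.04), t$energies[7, 451])
})

test_that("energy table TSV round-trips bit-exactly", {
  t <- build_energy_table(well_depth = -4.75, steepness = 2.1)
  path <- tempfile(fileext = ".tsv")
  write_energy_table(t, path)
  t2 <- read_energy_table(path)
  expect_identical(t2$energies, t$energies)
  expect_identical(t2$dgrid, t$dgrid)
  expect_identical(t2$agrid, t$agrid)
  expect_identical(t2$params$well_depth, t$params$well_depth)
})

test_that("donor-acceptor pair energy equals the table at its geometry", {
  t <- build_energy_table()
  g <- da_geometry(2.8, 180)
  pe <- pair_energy(t, g$don, g$acc)
  expect_equal(pe$energy, min(t$energies))
  expect_equal(pe$kind, "hbond")
  for (d in c(2.6, 3.0, 3.4)) {
    for (th in c(120, 150, 170)) {
      g <- da_geometry(d, th)
      pe <- pair_energy(t, g$don, g$acc)
      expect_equal(pe$energy, lookup_energy(t, d, th), tolerance = 1e-9)
    }
  }
})

test_that("clashes are the negative of the h-bond at the same geometry", {
  t <- build_energy_table()
  # acceptor-acceptor: heavy-atom distance, angle fixed at 180
  for (d in seq(2.5, 4.0, by = 0.1)) {
    pe <- pair_energy(t, acceptor_site(c(0, 0, 0)),
                      acceptor_site(c(d, 0, 0)), threshold = Inf)
    expect_equal(pe$energy, -lookup_energy(t, d, 180), tolerance = 1e-12)
    if (d <= 3.8) expect_equal(pe$kind, "clash")
  }
  # donor-donor at a controlled angle: second donor's H points away and
  # contributes nothing, so the clash is exactly -hbond(d, theta)
  for (d in c(2.7, 3.1, 3.6)) {
    for (th in c(110, 145, 178)) {
      g <- da_geometry(d, th)
      don2 <- donor_site(g$acc$pos, g$acc$pos + c(1.01, 0, 0))
      pe <- pair_energy(t, g$don, don2)
      expect_equal(pe$energy, -lookup_energy(t, d, th), tolerance = 1e-9)
    }
  }
  # beyond the proximal threshold: no interaction
  expect_equal(pair_energy(t, acceptor_site(c(0, 0, 0)),
                           acceptor_site(c(3.9, 0, 0)))$energy, 0)
})

test_that("the donor hydrogen closest to the acceptor is selected", {
  t <- build_energy_table()
  s <- read_structure(make_fixture("asn_ser"))
  ctx <- rapa_context(s)
  ser <- s$residues$reskey[s$residues$resid == "SER"]
  asn <- s$residues$reskey[s$residues$resid == "ASN"]
  og <- enumerate_states(s, ser)[[1]]$sites[[1]]
  od1 <- acceptor_site(axyz(s, asn, "OD1"))
  pe <- pair_energy(t, og, od1)
  expect_equal(pe$kind, "hbond")
  # brute force over the 9 candidates
  dd <- apply(og$hpos, 1, function(h) rapa:::vnorm(h - od1$pos))
  hbest <- og$hpos[which.min(dd), ]
  expect_equal(pe$angle, rapa:::vangle(og$pos, hbest, od1$pos),
               tolerance = 1e-9)
})

test_that("environment energy is additive over disjoint neighbor sets", {
  tab <- build_energy_table()
  one <- read_structure(make_fixture("asn_asn"))
  two <- read_structure(make_fixture("multi_pair", k = 2))
  c1 <- rapa_context(one, tab); c2 <- rapa_context(two, tab)
  cfg1 <- rapa_initialize(c1); cfg2 <- rapa_initialize(c2)
  u1 <- names(c1$units)[1]
  u2 <- names(c2$units)[1]
  nb1 <- stats::setNames(1L, names(c1$units)[2])
  nb2 <- stats::setNames(1L, names(c2$units)[2])
  # the far copy contributes nothing to the first pair's environment
  expect_equal(environment_energy(c2, cfg2, u2, 1, nb2),
               environment_energy(c1, cfg1, u1, 1, nb1), tolerance = 1e-9)
  # a residue with no proximal neighbors scores zero
  iso <- read_structure(make_fixture("isolated"))
  ci <- rapa_context(iso, tab)
  expect_equal(environment_energy(ci, rapa_initialize(ci),
                                  names(ci$units)[1], 1), 0)
})

test_that("missing neighbor assignments are a contract error", {
  ctx <- rapa_context(read_structure(make_fixture("asn_asn")))
  cfg <- rapa_initialize(ctx)
  expect_error(environment_energy(ctx, cfg, names(ctx$units)[1], 1),
               "missing neighbor assignment")
})

test_that("best_state_energies agrees with a brute-force product loop", {
  for (fix in list(make_fixture("asn_asn"),
                   make_fixture("asn_asn", perturb = 8),
                   make_fixture("asn_ser"),
                   make_fixture("his_probe"))) {
    ctx <- rapa_context(read_structure(fix))
    cfg <- rapa_initialize(ctx)
    for (uid in names(ctx$units)) {
      scores <- best_state_energies(ctx, cfg, uid)
      # oracle: explicit loop over every neighbor state combination
      unit <- ctx$units[[uid]]
      nbr <- setdiff(unique(unlist(ctx$adjacency[unit$reskeys])),
                     unit$reskeys)
      nbr_units <- unique(stats::na.omit(ctx$unit_of[nbr]))
      nbr_units <- nbr_units[vapply(nbr_units, function(u) {
        cfg$status[[u]] == "ambiguous"
      }, logical(1))]
      for (si in seq_along(unit$states)) {
        best <- Inf
        combos <- expand.grid(lapply(nbr_units, function(u) {
          seq_along(ctx$units[[u]]$states)
        }))
        if (nrow(combos) == 0) combos <- data.frame(row.names = 1)
        for (r in seq_len(nrow(combos))) {
          ns <- stats::setNames(as.integer(combos[r, ]), nbr_units)
          best <- min(best, environment_energy(ctx, cfg, uid, si, ns))
        }
        expect_equal(unname(scores[si]), best, tolerance = 1e-9)
      }
    }
  }
})

test_that("symmetric fixtures give exactly degenerate state scores", {
  for (fix in c("asn_asn", "asn_ser")) {
    ctx <- rapa_context(read_structure(make_fixture(fix)))
    cfg <- rapa_initialize(ctx)
    asn <- names(ctx$units)[1]
    sc <- best_state_energies(ctx, cfg, asn)
    expect_length(sc, 2)
    expect_equal(unname(sc[1]), unname(sc[2]), tolerance = 1e-9)
  }
})
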