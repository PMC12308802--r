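# hand-formatted PDB records for parser tests
pdb_line <- function(serial, name, alt, resn, chain, resno, x, y, z,
                     occ = 1, b = 0, elem = substr(name, 1, 1),
                     record = "ATOM") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, paste0(" ", name), alt, resn, chain, resno,
          x, y, z, occ, b, elem)
}

# apply coordinate overrides to a structure (test-side helper)
apply_overrides <- function(s, reskey, overrides) {
  for (nm in names(overrides)) {
    i <- which(s$atoms$reskey == reskey & s$atoms$elety == nm)
    s$atoms[i, c("x", "y", "z")] <- overrides[[nm]]
  }
  s
}

# independent Rodrigues rotation used as an oracle against the package's
# flip implementation
oracle_rotate <- function(p, origin, axis, theta_deg) {
  k <- axis / sqrt(sum(axis^2))
  v <- p - origin
  th <- theta_deg * pi / 180
  cr <- c(k[2] * v[3] - k[3] * v[2],
          k[3] * v[1] - k[1] * v[3],
          k[1] * v[2] - k[2] * v[1])
  origin + v * cos(th) + cr * sin(th) + k * sum(k * v) * (1 - cos(th))
}
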