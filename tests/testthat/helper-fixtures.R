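# Shared fixtures: tiny maps, models and text files built in code.

random_map <- function(dims = c(8, 8, 8), voxel = 0.5, origin = c(0, 0, 0),
                       seed = 1) {
  set.seed(seed)
  density_map(array(rnorm(prod(dims)), dim = dims), voxel, origin)
}

single_atom_model <- function(xyz = c(0, 0, 0), element = "C",
                              name = "CA", res = "ALA") {
  atomic_model(serial = 1L, name = name, element = element, chain = "A",
               res_name = res, res_seq = 1L,
               x = xyz[1], y = xyz[2], z = xyz[3], entry_id = "single")
}

# Hand-written 3-atom PDB fixture.
write_tiny_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1       2.500   2.000   3.000  1.00 11.50           C",
    "ATOM      3  CB  ALA A   1       3.000   3.400   3.000  1.00 12.00           C",
    "END"), path)
  path
}

# Same three atoms as minimal mmCIF.
write_tiny_cif <- function(path) {
  writeLines(c(
    "data_tiny",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N . ALA A 1 1 ? 1.000 2.000 3.000 1.00 10.00 1 ALA A N 1",
    "ATOM 2 C CA . ALA A 1 1 ? 2.500 2.000 3.000 1.00 11.50 1 ALA A CA 1",
    "ATOM 3 C CB . ALA A 1 1 ? 3.000 3.400 3.000 1.00 12.00 1 ALA A CB 1"),
    path)
  path
}

write_altloc_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00 10.00           N",
    "ATOM      2  CA ASER A   1       2.500   2.000   3.000  0.60 11.00           C",
    "ATOM      3  CA BSER A   1       2.700   2.100   3.000  0.40 11.00           C",
    "END"), path)
  path
}

# Brute-force trilinear interpolation oracle (scalar, loop form).
trilinear_oracle <- function(map, p) {
  f <- (p - map$origin) / map$voxel_size
  i0 <- floor(f)
  t <- f - i0
  v <- 0
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    w <- prod(ifelse(c(cx, cy, cz) == 1, t, 1 - t))
    v <- v + w * map$values[i0[1] + cx + 1, i0[2] + cy + 1, i0[3] + cz + 1]
  }
  v
}

# Textbook Pearson correlation, term by term.
pearson_oracle <- function(u, v) {
  mu <- sum(u) / length(u)
  mv <- sum(v) / length(v)
  num <- sum((u - mu) * (v - mv))
  num / sqrt(sum((u - mu)^2) * sum((v - mv)^2))
}
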