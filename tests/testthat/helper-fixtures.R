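# Fixtures built in code: toy structures, oracle implementations.

# Monomer whose single-atom "residues" are laid out so that, under
# twist -90 / rise 5, residue 2 of subunit k+1 lands 2 A above residue 1 of
# subunit k (a planted offset-1 contact), while residue 3 stays remote.
toy_contact_monomer <- function() {
  fil_structure(data.frame(
    elety = "CA", resid = c("ALA", "GLY", "SER"), chain = "A",
    resno = 1:3,
    x = c(10, 10 * cospi(0.5), -30),
    y = c(0, 10 * sinpi(0.5), 0),
    z = c(0, -3, 0),
    element = "C"))
}

# Small all-atom-ish monomer spanning a radial shell, for geometry tests.
toy_shell_monomer <- function(n = 24, r_in = 12.5, r_out = 37.5) {
  set.seed(7)
  r <- seq(r_in, r_out, length.out = n)
  th <- runif(n, 0, 2 * pi)
  fil_structure(data.frame(
    elety = "CA", resid = "ALA", chain = "A", resno = seq_len(n),
    x = r * cos(th), y = r * sin(th), z = runif(n, 0, 4), element = "C"))
}

# Brute-force all-pairs contact oracle over a built assembly.
brute_contacts <- function(assembly, cutoff, max_offset) {
  a <- assembly$atoms
  base <- a[a$subunit == min(a$subunit), ]
  out <- list()
  for (k in seq_len(max_offset)) {
    other <- a[a$subunit == min(a$subunit) + k, ]
    for (i in seq_len(nrow(base))) for (j in seq_len(nrow(other))) {
      d <- sqrt(sum((c(base$x[i], base$y[i], base$z[i]) -
                     c(other$x[j], other$y[j], other$z[j]))^2))
      if (d <= cutoff)
        out[[length(out) + 1L]] <- data.frame(
          offset = k, resno_i = base$resno[i], elety_i = base$elety[i],
          resno_j = other$resno[j], elety_j = other$elety[j], dist = d)
    }
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  res[order(res$offset, res$resno_i, res$elety_i, res$resno_j,
            res$elety_j), ]
}

euler_rot <- function(a, b, g) {
  Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1),
                           3, 3)
  Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)),
                           3, 3)
  Rz(a) %*% Ry(b) %*% Rz(g)
}

# Numerical superposition oracle: coarse rotation grid then simplex descent,
# independent of the closed-form Kabsch solution.
grid_search_rmsd <- function(a, b) {
  a0 <- sweep(a, 2, colMeans(a)); b0 <- sweep(b, 2, colMeans(b))
  obj <- function(p) {
    R <- euler_rot(p[1], p[2], p[3])
    sqrt(mean(rowSums((a0 - b0 %*% t(R))^2)))
  }
  best <- NULL
  for (al in seq(0, 2 * pi, length.out = 9)[-9])
    for (be in seq(0, pi, length.out = 5))
      for (ga in seq(0, 2 * pi, length.out = 9)[-9]) {
        v <- obj(c(al, be, ga))
        if (is.null(best) || v < best$value)
          best <- list(par = c(al, be, ga), value = v)
      }
  opt <- stats::optim(best$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  opt$value
}

# One-line exact binomial upper-tail oracle by direct summation.
binom_tail_sum <- function(k, n, p) {
  sum(choose(n, k:n) * p^(k:n) * (1 - p)^(n - (k:n)))
}

# Minimal one-atom PDB / mmCIF fixture writers.
write_one_atom_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  CA  ALA A   1      11.104   6.134   2.500  1.00 20.00           C",
    "END"), path)
}
write_one_atom_cif <- function(path) {
  writeLines(c(
    "data_toy", "#", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_comp_id",
    "_atom_site.label_asym_id", "_atom_site.label_entity_id",
    "_atom_site.label_seq_id", "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num",
    paste("ATOM 1 C CA ALA A 1 1 ? 11.104 6.134 2.500 1.00 20.00",
          "? 1 ALA A CA 1"),
    "#"), path)
}
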