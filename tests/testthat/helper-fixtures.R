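# shared fixtures: tiny chains, handcrafted PDB text, independent oracles

# chain of CA-only pseudo-residues at given coordinates
mk_ca_chain <- function(coords, numbers = seq_len(nrow(coords)),
                        ins = rep("", nrow(coords)),
                        aa = rep("A", nrow(coords)),
                        elements = rep("C", nrow(coords)),
                        chain_id = "A", source_id = "toy") {
  res <- lapply(seq_len(nrow(coords)), function(i)
    new_residue(numbers[i], ins[i], aa[i],
                data.frame(name = "CA", element = elements[i],
                           x = coords[i, 1], y = coords[i, 2],
                           z = coords[i, 3], stringsAsFactors = FALSE)))
  new_chain(chain_id, res, source_id)
}

# single residue made of arbitrary atoms
mk_res <- function(coords, number = 1, aa = "A") {
  coords <- matrix(coords, ncol = 3)
  new_residue(number, "", aa,
              data.frame(name = paste0("C", seq_len(nrow(coords))),
                         element = "C", x = coords[, 1], y = coords[, 2],
                         z = coords[, 3], stringsAsFactors = FALSE))
}

# handcrafted PDB ATOM line (strict column layout: name 13-16, alt 17,
# resn 18-20, chain 22, resno 23-26, icode 27, x from 31)
pdb_line <- function(serial, name, alt, resn, chain, resno, icode,
                     x, y, z, occ = 1, b = 0, elem = substr(name, 1, 1)) {
  sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, sprintf(" %-3s", name), alt, resn, chain, resno, icode,
          x, y, z, occ, b, elem)
}

# independent bond-angle oracle: arccos of normalised dot product
oracle_angle <- function(p1, p2, p3) {
  u <- p1 - p2; v <- p3 - p2
  acos(pmin(1, pmax(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}

# independent dihedral oracle: projection formula (atan2 of in-plane
# components), a different derivation from the package's cross-product route
oracle_dihedral <- function(p1, p2, p3, p4) {
  b0 <- p1 - p2
  b1 <- p3 - p2; b1 <- b1 / sqrt(sum(b1^2))
  b2 <- p4 - p3
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  x <- sum(v * w)
  y <- sum(c(b1[2] * v[3] - b1[3] * v[2],
             b1[3] * v[1] - b1[1] * v[3],
             b1[1] * v[2] - b1[2] * v[1]) * w)
  atan2(y, x) * 180 / pi
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

transform_chain <- function(chain, R = diag(3), t = c(0, 0, 0)) {
  chain$residues <- lapply(chain$residues, function(r) {
    m <- as.matrix(r$atoms[, c("x", "y", "z")]) %*% t(R)
    r$atoms$x <- m[, 1] + t[1]
    r$atoms$y <- m[, 2] + t[2]
    r$atoms$z <- m[, 3] + t[3]
    r
  })
  chain
}

# exact two-sided rank-sum p-value by full enumeration of group assignments
enumerate_wilcoxon_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  ranks <- rank(pooled)
  u_obs <- sum(ranks[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  us <- apply(combos, 2, function(ix) sum(ranks[ix]) - nx * (nx + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}
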