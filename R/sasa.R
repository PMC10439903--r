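# Shrake-Rupley solvent-accessible surface area.
#
# Each heavy atom is wrapped in a sphere of radius (vdW + probe) sampled at
# quasi-uniform points (Fibonacci spiral); a point survives if it lies
# outside every neighbouring atom's expanded sphere. SASA is the surviving
# fraction times the sphere area.

# element van der Waals radii (Angstrom): the classic protein set
# (Chothia-type, as used by NACCESS and the Miller reference areas) and the
# Bondi element set
ELEMENT_RADII <- list(
  protein = c(C = 1.87, N = 1.65, O = 1.40, S = 1.85, P = 1.90, SE = 1.90,
              H = 1.00, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98),
  bondi = c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, SE = 1.90,
            H = 1.20, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98))

#' Van der Waals radius of an element
#'
#' @param element Character vector of element symbols.
#' @param set `"protein"` (classic protein-crystallography radii, default;
#'   consistent with the Miller reference maxima) or `"bondi"`, or a named
#'   numeric vector of custom radii.
#' @param default Radius used (with a warning) for unknown elements.
#' @return Numeric vector of radii in Angstrom.
#' @export
vdw_radius <- function(element, set = "protein", default = 1.80) {
  tab <- if (is.numeric(set)) set else ELEMENT_RADII[[match.arg(set, names(ELEMENT_RADII))]]
  r <- tab[toupper(element)]
  if (anyNA(r)) {
    warning("unknown element(s): ",
            paste(unique(element[is.na(r)]), collapse = ", "),
            "; using default radius ", default)
    r[is.na(r)] <- default
  }
  unname(r)
}

# deterministic quasi-uniform unit-sphere points (Fibonacci spiral)
sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# flatten chains to one atom table with chain/residue bookkeeping
flatten_atoms <- function(x) {
  if (inherits(x, "vhh_complex")) x <- c(x$vhh, x$antigen)
  if (inherits(x, "vhh_chain")) x <- list(x)
  rows <- list()
  for (ci in seq_along(x)) {
    ch <- x[[ci]]
    tab <- chain_atom_table(ch)
    if (is.null(tab)) next
    tab$chain_idx <- ci
    tab$chain_id <- ch$chain_id
    rows[[length(rows) + 1L]] <- tab
  }
  do.call(rbind, rows)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' @param x A `vhh_chain`, list of chains, or `vhh_complex` (all chains are
#'   treated as one occluding assembly).
#' @param probe Probe radius in Angstrom, default 1.4 (water).
#' @param n_points Sample points per atom sphere, default 960.
#' @param radii Radii set name or named numeric vector, see [vdw_radius()].
#' @return A `sasa_result`: `atoms` (atom table with `radius` and `area`),
#'   `residue_area` (per-residue sums, keyed `chain_id|res_idx`), `total`,
#'   `probe`, `n_points`.
#' @export
shrake_rupley <- function(x, probe = 1.4, n_points = 960, radii = "protein") {
  at <- flatten_atoms(x)
  if (is.null(at) || nrow(at) == 0L) stop("no atoms")
  at$radius <- vdw_radius(at$element, set = radii)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  R <- at$radius + probe
  n <- nrow(at)
  pts <- sphere_points(n_points)
  # neighbour lists from squared distances
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * xyz %*% t(xyz)
  area <- numeric(n)
  for (i in seq_len(n)) {
    cut <- (R[i] + R)^2
    nb <- which(d2[i, ] < cut & seq_len(n) != i)
    sp <- sweep(pts * R[i], 2, xyz[i, ], "+")
    if (length(nb) == 0L) {
      acc <- n_points
    } else {
      occluded <- rep(FALSE, n_points)
      for (j in nb) {
        dj <- sweep(sp, 2, xyz[j, ], "-")
        occluded <- occluded | (rowSums(dj^2) < R[j]^2)
        if (all(occluded)) break
      }
      acc <- sum(!occluded)
    }
    area[i] <- 4 * pi * R[i]^2 * acc / n_points
  }
  at$area <- area
  key <- paste(at$chain_id, at$res_idx, sep = "|")
  res_area <- tapply(at$area, key, sum)
  structure(list(atoms = at,
                 residue_area = res_area,
                 total = sum(area), probe = probe, n_points = n_points),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("<sasa_result> %d atoms, total %.1f A^2 (probe %.2f, %d points)\n",
              nrow(x$atoms), x$total, x$probe, x$n_points))
  invisible(x)
}

# residue-type maximum accessible areas (Gly-X-Gly reference states, A^2)
MAX_SASA <- list(
  miller = c(A = 113, R = 241, N = 158, D = 151, C = 140, Q = 189, E = 183,
             G = 85, H = 194, I = 182, L = 180, K = 211, M = 204, F = 218,
             P = 143, S = 122, T = 146, W = 259, Y = 229, V = 160),
  tien_theoretical = c(A = 129, R = 274, N = 195, D = 193, C = 167, Q = 225,
                       E = 223, G = 104, H = 224, I = 197, L = 201, K = 236,
                       M = 224, F = 240, P = 159, S = 155, T = 172, W = 285,
                       Y = 263, V = 174))

#' Residue-type maximum accessible surface areas
#'
#' Published Gly-X-Gly reference maxima used to normalise residue SASA into
#' relative solvent accessibility.
#'
#' @param set `"miller"` (Miller et al. 1987 standard-state areas, default)
#'   or `"tien_theoretical"` (theoretical maxima).
#' @return Named numeric vector over the 20 one-letter codes.
#' @export
max_sasa_table <- function(set = c("miller", "tien_theoretical")) {
  MAX_SASA[[match.arg(set)]]
}

#' Relative solvent accessibility of selected positions
#'
#' Residue SASA (computed in the context of the whole chain) divided by the
#' residue-type maximum. Values slightly above 1 can occur for exposed
#' conformations.
#'
#' @param chain A numbered `vhh_chain`.
#' @param positions Chothia positions (integers).
#' @param probe,n_points Passed to [shrake_rupley()].
#' @param max_set Normalisation table, see [max_sasa_table()].
#' @return Data frame `position`, `aa`, `sasa`, `rsa`.
#' @export
relative_sasa <- function(chain, positions, probe = 1.4, n_points = 960,
                          max_set = "miller") {
  sr <- shrake_rupley(chain, probe = probe, n_points = n_points)
  maxima <- max_sasa_table(max_set)
  rows <- lapply(positions, function(p) {
    i <- residue_index(chain, as.integer(p))
    if (is.na(i)) return(NULL)
    r <- chain$residues[[i]]
    a <- unname(sr$residue_area[paste(chain$chain_id, i, sep = "|")])
    mx <- maxima[r$aa]
    data.frame(position = as.integer(p), aa = r$aa, sasa = a,
               rsa = if (is.na(mx)) NA_real_ else a / unname(mx),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
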