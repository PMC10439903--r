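# Paratope accounting: which VHH regions touch antigen, and how much
# surface each region buries on complex formation.

#' Per-region paratope profile of a VHH-antigen complex
#'
#' A region is flagged when any of its residues has a heavy atom within
#' `cutoff` of any antigen atom. The buried area of a region is the sum over
#' its residues of `SASA(VHH alone) - SASA(VHH in complex)`, negative
#' residue differences clamped to zero (sampling noise). The total paratope
#' area is the exact sum of the region areas. Multiple antigen chains are
#' treated as one antigen.
#'
#' @param complex A `vhh_complex` with at least one antigen chain; the first
#'   VHH chain is profiled.
#' @param cutoff Contact cutoff in Angstrom, default 4.0 (inclusive).
#' @param probe,n_points Passed to [shrake_rupley()].
#' @return A `paratope_profile`: data frame `region`, `contact`,
#'   `buried_area`, plus attributes `total_area` and `source_id`.
#' @export
paratope_profile <- function(complex, cutoff = 4.0, probe = 1.4,
                             n_points = 960) {
  stopifnot(inherits(complex, "vhh_complex"))
  if (length(complex$antigen) == 0L) stop("complex has no antigen chains")
  vhh <- complex$vhh[[1]]
  ag_res <- unlist(lapply(complex$antigen, function(ch) ch$residues),
                   recursive = FALSE)
  regions <- names(region_map())
  # contact flags
  contact <- setNames(rep(FALSE, length(regions)), regions)
  for (r in vhh$residues) {
    reg <- region_of(r$number)
    if (is.na(reg) || contact[reg]) next
    for (ar in ag_res) {
      if (residue_contact(r, ar, cutoff)) { contact[reg] <- TRUE; break }
    }
  }
  # buried area: unbound minus bound, per residue, clamped at 0
  free <- shrake_rupley(vhh, probe = probe, n_points = n_points)
  bound_cx <- structure(list(vhh = list(vhh), antigen = complex$antigen,
                             source_id = complex$source_id),
                        class = "vhh_complex")
  bound <- shrake_rupley(bound_cx, probe = probe, n_points = n_points)
  key <- function(i) paste(vhh$chain_id, i, sep = "|")
  buried <- setNames(numeric(length(regions)), regions)
  for (i in seq_along(vhh$residues)) {
    reg <- region_of(vhh$residues[[i]]$number)
    if (is.na(reg)) next
    d <- unname(free$residue_area[key(i)] - bound$residue_area[key(i)])
    buried[reg] <- buried[reg] + max(0, d)
  }
  out <- data.frame(region = regions, contact = unname(contact),
                    buried_area = unname(buried), stringsAsFactors = FALSE)
  structure(out, class = c("paratope_profile", "data.frame"),
            total_area = sum(buried), source_id = complex$source_id)
}

#' Cohort paratope summary by conformation label
#'
#' @param profiles List of [paratope_profile()] results.
#' @param labels Character vector of conformation labels parallel to
#'   `profiles` (e.g. `"kinked"` / `"extended"`).
#' @return A list with `usage` (percent of structures per label with each
#'   region in antigen contact) and `area` (mean and sd of buried area per
#'   region per label), both long-format data frames with `n` per label.
#' @export
cohort_paratope_summary <- function(profiles, labels) {
  stopifnot(length(profiles) == length(labels))
  regions <- names(region_map())
  rows_u <- list(); rows_a <- list()
  for (lb in unique(labels)) {
    sub <- profiles[labels == lb]
    n <- length(sub)
    for (reg in regions) {
      flags <- vapply(sub, function(p) p$contact[p$region == reg], TRUE)
      areas <- vapply(sub, function(p) p$buried_area[p$region == reg], 1)
      rows_u[[length(rows_u) + 1L]] <- data.frame(
        label = lb, region = reg, percent = 100 * mean(flags), n = n,
        stringsAsFactors = FALSE)
      rows_a[[length(rows_a) + 1L]] <- data.frame(
        label = lb, region = reg, mean_area = mean(areas),
        sd_area = if (n > 1) sd(areas) else NA_real_, n = n,
        stringsAsFactors = FALSE)
    }
  }
  list(usage = do.call(rbind, rows_u), area = do.call(rbind, rows_a))
}
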