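## Convenience wrapper for crystal-structure descriptor reports.

#' Interdomain angle and Subdomain-II curvature of a crystal structure
#'
#' Reads a (single-model) PDB file of a receptor ectodomain and reports the
#' Subdomain I/III interdomain angle from the standard C-alpha anchors
#' (Val36 -> Glu118, Ser340 -> Glu431) together with the maximum curvature
#' of the quadratic fit through the Subdomain-II disulfide-module centres
#' of mass. Masses are needed for the module centroids: element-standard
#' masses are filled in for atoms without assigned parameters.
#'
#' @param path PDB file path.
#' @param chain receptor chain label.
#' @param resid_offset residue-number offset for deviant depositions.
#' @param anchors an [anchor_pair()] (chain is overridden by `chain`).
#' @param domain_range Subdomain II residue range.
#' @return list with `angle` (degrees), `n_modules`, `max_curvature`
#'   (1/A), `modules`.
#' @export
crystal_structure_report <- function(path, chain = "A", resid_offset = 0L,
                                     anchors = anchor_pair(),
                                     domain_range = default_domain_map()$II) {
  st <- read_pdb(path, resid_offset = resid_offset)$structure
  anchors$chain <- chain
  ## element-standard masses for centroid weighting
  std_mass <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                P = 30.974)
  m <- std_mass[toupper(st$atoms$element)]
  m[is.na(m)] <- 12.011
  st$atoms$mass <- ifelse(is.na(st$atoms$mass), m, st$atoms$mass)
  ang <- interdomain_angle(st, anchors)
  cv <- subdomain_curvature(st, domain_range = domain_range, chain = chain)
  list(angle = ang, n_modules = nrow(cv$modules),
       max_curvature = cv$max_curvature, modules = cv$modules)
}
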