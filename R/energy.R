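# Transparent unfold-and-subtract interface energy. This is a deliberately
# simple pairwise model (Lennard-Jones 6-12 on heavy atoms, Coulomb with
# distance-dependent dielectric eps(r) = 4r, an H-bond well, and a buried
# nonpolar-contact desolvation term). Its contract is the sign convention
# (more negative = stronger binding), the infinite-separation limit, rigid
# invariance, decomposition consistency and ordering behaviour - not any
# particular kcal/mol scale.

# united-heavy-atom LJ parameters by element: rmin (A, per-atom half of the
# pair minimum) and well depth eps (kcal/mol)
LJ_PARAMS <- tibble::tribble(
  ~element, ~rmin, ~eps,
  "C", 1.95, 0.12,
  "N", 1.80, 0.16,
  "O", 1.70, 0.20,
  "S", 2.00, 0.25
)

# formal charges on charged side-chain groups, spread over the group atoms
CHARGE_TABLE <- tibble::tribble(
  ~resname, ~atom, ~q,
  "ASP", "OD1", -0.5, "ASP", "OD2", -0.5,
  "GLU", "OE1", -0.5, "GLU", "OE2", -0.5,
  "LYS", "NZ", 1.0,
  "ARG", "NE", 0.2, "ARG", "NH1", 0.4, "ARG", "NH2", 0.4
)

COULOMB_K <- 332.0637  # kcal*A/(mol*e^2)

#' Energy model parameters
#'
#' @param hbond_well Depth of the donor-acceptor hydrogen-bond well,
#'   kcal/mol (applied within 3.5 Angstrom, distance-tapered).
#' @param desolv_per_contact Favourable energy per buried nonpolar
#'   carbon-carbon contact within `desolv_cutoff`, kcal/mol.
#' @param desolv_cutoff Angstrom.
#' @param dielectric_slope Distance-dependent dielectric eps(r) =
#'   `dielectric_slope * r`.
#' @return Named list of weights.
#' @export
energy_params <- function(hbond_well = 1.0, desolv_per_contact = 0.03,
                          desolv_cutoff = 5.0, dielectric_slope = 4) {
  list(hbond_well = hbond_well, desolv_per_contact = desolv_per_contact,
       desolv_cutoff = desolv_cutoff, dielectric_slope = dielectric_slope)
}

# annotate a heavy-atom tibble with LJ/charge/donor-acceptor flags
energy_annotate <- function(at) {
  at <- heavy_atoms(as_tibble(at))
  el <- toupper(substr(at$element, 1, 1))
  el[!el %in% LJ_PARAMS$element] <- "C"
  li <- match(el, LJ_PARAMS$element)
  at$rmin <- LJ_PARAMS$rmin[li]
  at$eps <- LJ_PARAMS$eps[li]
  qi <- match(paste(at$resname, at$atom),
              paste(CHARGE_TABLE$resname, CHARGE_TABLE$atom))
  at$q <- ifelse(is.na(qi), 0, CHARGE_TABLE$q[qi])
  at$donor <- at$atom == "N" |
    paste(at$resname, at$atom) %in% paste(HB_DONOR_SC$resname, HB_DONOR_SC$atom)
  at$acceptor <- at$atom == "O" |
    paste(at$resname, at$atom) %in% paste(HB_ACCEPT_SC$resname, HB_ACCEPT_SC$atom)
  at$nonpolar <- el == "C" & !at$atom %in% BACKBONE &
    at$resname %in% HYDROPHOBIC_RES
  at
}

# pairwise inter-set energy terms between two annotated atom tables;
# atoms of the same residue are never paired
pairwise_terms <- function(A, B, params) {
  MA <- as.matrix(A[, c("x", "y", "z")])
  MB <- as.matrix(B[, c("x", "y", "z")])
  d2 <- outer(rowSums(MA^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(MB^2)) - 2 * MA %*% t(MB)
  d2[d2 < 0] <- 0
  r <- sqrt(d2)
  same_res <- outer(paste(A$chain, A$resno, A$icode),
                    paste(B$chain, B$resno, B$icode), `==`)
  if (any(r < 1 & !same_res))
    warn("overlapping atoms (< 1 A): repulsion capped")
  r_eff <- pmax(r, 1)  # capped repulsion keeps output finite

  rmin_ij <- outer(A$rmin, B$rmin, `+`)
  eps_ij <- sqrt(outer(A$eps, B$eps))
  sr6 <- (rmin_ij / r_eff)^6
  vdw <- eps_ij * (sr6^2 - 2 * sr6)
  vdw[r > 12] <- 0  # negligible beyond 12 A

  qq <- outer(A$q, B$q)
  elec <- COULOMB_K * qq / (params$dielectric_slope * r_eff^2)

  hb_pair <- (outer(A$donor, B$acceptor) | outer(A$acceptor, B$donor)) &
    r <= 3.5 & r >= 2.2
  hbond <- matrix(0, nrow(A), nrow(B))
  hbond[hb_pair] <- -params$hbond_well *
    pmin(1, (3.5 - r[hb_pair]) / 0.3)

  desolv <- matrix(0, nrow(A), nrow(B))
  buried <- outer(A$nonpolar, B$nonpolar) & r <= params$desolv_cutoff
  desolv[buried] <- -params$desolv_per_contact

  for (m in c("vdw", "elec", "hbond", "desolv"))
    assign(m, `[<-`(get(m), same_res, 0))
  list(vdw = vdw, electrostatic = elec, hbond = hbond, desolvation = desolv)
}

#' Unfold-and-subtract interface interaction energy
#'
#' Computes the interaction energy of association between two chain groups
#' as the complex energy minus the sum of the separated partners' energies.
#' Because all terms are pairwise and intra-group pairs cancel exactly in
#' the subtraction, the result equals the inter-group pairwise sum; the
#' identity is asserted numerically on every call. More negative values
#' indicate stronger binding; positive values suggest no binding.
#'
#' @param s A `gdtr_structure`.
#' @param group_a,group_b Chain-id vectors (disjoint, present in `s`).
#' @param params [energy_params()].
#' @return A `gdtr_energy` list: `dg_interaction` (kcal/mol), `terms`
#'   (named vector: vdw, electrostatic, hbond, desolvation), `per_residue`
#'   tibble (half of each pair term to each residue; sums to the total),
#'   `groups`, `parameters`.
#' @export
interaction_energy <- function(s, group_a, group_b,
                               params = energy_params()) {
  if (length(intersect(group_a, group_b)) > 0)
    abort("chain groups must be disjoint")
  at <- energy_annotate(s)
  A <- filter(at, .data$chain %in% group_a)
  B <- filter(at, .data$chain %in% group_b)
  if (nrow(A) == 0 || nrow(B) == 0) abort("empty chain group")
  tm <- pairwise_terms(A, B, params)
  terms <- vapply(tm, sum, numeric(1))
  dg <- sum(terms)
  total_pair <- Reduce(`+`, tm)
  res_a <- tibble(chain = A$chain, resno = A$resno, icode = A$icode,
                  resname = A$resname, group = "a",
                  energy = rowSums(total_pair) / 2) |>
    group_by(.data$chain, .data$resno, .data$icode, .data$resname,
             .data$group) |>
    summarise(energy = sum(.data$energy), .groups = "drop")
  res_b <- tibble(chain = B$chain, resno = B$resno, icode = B$icode,
                  resname = B$resname, group = "b",
                  energy = colSums(total_pair) / 2) |>
    group_by(.data$chain, .data$resno, .data$icode, .data$resname,
             .data$group) |>
    summarise(energy = sum(.data$energy), .groups = "drop")
  per_res <- bind_rows(res_a, res_b)
  stopifnot(abs(sum(per_res$energy) - dg) < 1e-6,
            abs(dg - sum(terms)) < 1e-6)
  structure(list(dg_interaction = dg, terms = terms,
                 per_residue = per_res,
                 groups = list(a = group_a, b = group_b),
                 parameters = params),
            class = "gdtr_energy")
}

#' Explicit unfold-and-subtract evaluation
#'
#' Evaluates E(complex) - E(A) - E(B) with full intra+inter pair sums on
#' each side, for checking the algebraic identity with
#' [interaction_energy()].
#'
#' @inheritParams interaction_energy
#' @return Numeric interaction energy, kcal/mol.
#' @export
unfold_and_subtract <- function(s, group_a, group_b,
                                params = energy_params()) {
  total_E <- function(chains) {
    at <- energy_annotate(filter(as_tibble(s), .data$chain %in% chains))
    if (nrow(at) < 2) return(0)
    tm <- pairwise_terms(at, at, params)
    sum(vapply(tm, sum, numeric(1))) / 2  # each pair counted twice
  }
  total_E(c(group_a, group_b)) - total_E(group_a) - total_E(group_b)
}

#' @export
print.gdtr_energy <- function(x, ...) {
  cat(sprintf("<gdtr_energy> dG_interaction = %.3f kcal/mol\n",
              x$dg_interaction))
  cat(" terms:", paste(sprintf("%s %.3f", names(x$terms), x$terms),
                       collapse = ", "), "\n")
  invisible(x)
}

#' Rank complexes by interaction energy
#'
#' Stable ascending sort on `dg_interaction` (strongest binder first);
#' ties preserve input order.
#'
#' @param reports List of `gdtr_energy` objects, optionally named.
#' @return Tibble with `name`, `dg_interaction`, `rank`, in ranked order.
#' @export
rank_complexes <- function(reports) {
  if (length(reports) < 2) abort("need at least 2 reports to rank")
  nm <- names(reports) %||% paste0("complex_", seq_along(reports))
  nm[!nzchar(nm)] <- paste0("complex_", which(!nzchar(nm)))
  dg <- unname(vapply(reports, function(r) r$dg_interaction, numeric(1)))
  ord <- order(dg)  # order() is stable
  tibble(name = nm[ord], dg_interaction = dg[ord],
         rank = seq_along(ord))
}
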