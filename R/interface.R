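# Geometric criteria for the six interface interaction classes (heavy-atom
# rules; hydrogens, when present, are ignored). Thresholds are config-exposed
# through contact_params().

#' Interaction classification parameters
#'
#' Distance thresholds (Angstrom) for the interface interaction classes:
#' ionic within 6; hydrogen bonds at donor-acceptor heavy-atom distance
#' within 3.5 (no angle term: threaded models carry no hydrogens); an
#' aromatic-aromatic ring-centroid window of 4.5-7 inclusive;
#' aromatic-sulfur centroid-to-S within 5.3; cation-pi centroid-to-cationic-N
#' within 6; hydrophobic side-chain carbon pairs within 5.
#'
#' @param ionic,hbond,aromatic_min,aromatic_max,aromatic_sulfur,cation_pi,hydrophobic
#'   Threshold overrides.
#' @return Named list of thresholds.
#' @export
contact_params <- function(ionic = 6.0, hbond = 3.5, aromatic_min = 4.5,
                           aromatic_max = 7.0, aromatic_sulfur = 5.3,
                           cation_pi = 6.0, hydrophobic = 5.0) {
  list(ionic = ionic, hbond = hbond, aromatic_min = aromatic_min,
       aromatic_max = aromatic_max, aromatic_sulfur = aromatic_sulfur,
       cation_pi = cation_pi, hydrophobic = hydrophobic)
}

#' The closed set of interaction type labels
#' @return Character vector of the eight labels.
#' @export
interaction_types <- function() {
  c("IONIC", "HBOND_SS", "HBOND_MS", "HBOND_MM",
    "AROMATIC_AROMATIC", "AROMATIC_SULFUR", "CATION_PI", "HYDROPHOBIC")
}

# charged side-chain groups with formal signs (His treated as potentially
# cationic, and also aromatic below)
CHARGED_ATOMS <- tibble::tribble(
  ~resname, ~atom, ~sign,
  "ASP", "OD1", -1, "ASP", "OD2", -1,
  "GLU", "OE1", -1, "GLU", "OE2", -1,
  "LYS", "NZ",  +1,
  "ARG", "NE",  +1, "ARG", "NH1", +1, "ARG", "NH2", +1,
  "HIS", "ND1", +1, "HIS", "NE2", +1
)

CATIONIC_ATOMS <- tibble::tribble(
  ~resname, ~atom,
  "LYS", "NZ", "ARG", "NE", "ARG", "NH1", "ARG", "NH2"
)

RING_ATOMS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
)

SULFUR_ATOMS <- tibble::tribble(~resname, ~atom, "CYS", "SG", "MET", "SD")

HYDROPHOBIC_RES <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP",
                     "PRO", "TYR")

# side-chain H-bond donor/acceptor heavy atoms; backbone N donates, O accepts
HB_DONOR_SC <- tibble::tribble(
  ~resname, ~atom,
  "ARG", "NE", "ARG", "NH1", "ARG", "NH2",
  "ASN", "ND2", "GLN", "NE2",
  "HIS", "ND1", "HIS", "NE2",
  "LYS", "NZ",
  "SER", "OG", "THR", "OG1", "TYR", "OH",
  "TRP", "NE1", "CYS", "SG"
)
HB_ACCEPT_SC <- tibble::tribble(
  ~resname, ~atom,
  "ASP", "OD1", "ASP", "OD2", "GLU", "OE1", "GLU", "OE2",
  "ASN", "OD1", "GLN", "OE1",
  "HIS", "ND1", "HIS", "NE2",
  "SER", "OG", "THR", "OG1", "TYR", "OH", "MET", "SD"
)

ring_centroid <- function(at) {
  ring <- RING_ATOMS[[at$resname[1]]]
  if (is.null(ring)) return(NULL)
  sub <- at[at$atom %in% ring, ]
  if (nrow(sub) < length(ring)) return(NULL)
  colMeans(as.matrix(sub[, c("x", "y", "z")]))
}

pair_min_dist <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(NULL)
  A <- as.matrix(a[, c("x", "y", "z")])
  B <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  ij <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
  list(dist = sqrt(min(d2)), atom_a = a$atom[ij[1]], atom_b = b$atom[ij[2]])
}

res_label <- function(at) {
  list(chain = at$chain[1], resno = at$resno[1], icode = at$icode[1],
       resname = at$resname[1])
}

#' Classify all interface interaction types between two residues
#'
#' Applies the geometric rules of [contact_params()] to the heavy atoms of
#' two residues and returns one row per applicable type with its defining
#' distance (closest qualifying atom-pair or centroid distance) and the
#' atom/centroid partners used. Classification is symmetric in its
#' arguments. Missing side-chain atoms cause the affected type to be
#' skipped with a warning, never an error.
#'
#' @param res_a,res_b Atom tibbles of the two residues (e.g. from a
#'   `gdtr_structure` filtered to one residue each).
#' @param params [contact_params()] list.
#' @return Tibble of contacts: residue identifiers for both sides, `kind`,
#'   `distance`, `partners`.
#' @export
classify_pair <- function(res_a, res_b, params = contact_params()) {
  a <- heavy_atoms(as_tibble(res_a)); b <- heavy_atoms(as_tibble(res_b))
  if (nrow(a) == 0 || nrow(b) == 0) abort("residue without heavy atoms")
  la <- res_label(a); lb <- res_label(b)
  out <- list()
  add <- function(kind, distance, partners) {
    out[[length(out) + 1]] <<- tibble(
      chain_a = la$chain, resno_a = la$resno, icode_a = la$icode,
      resname_a = la$resname,
      chain_b = lb$chain, resno_b = lb$resno, icode_b = lb$icode,
      resname_b = lb$resname,
      kind = kind, distance = distance, partners = partners)
  }
  sel <- function(at, tab) dplyr::semi_join(
    at, tab[tab$resname == at$resname[1], ], by = c("resname", "atom"))

  # IONIC: opposite formal signs within threshold
  ca <- sel(a, CHARGED_ATOMS); cb <- sel(b, CHARGED_ATOMS)
  if (nrow(ca) > 0 && nrow(cb) > 0) {
    sa <- CHARGED_ATOMS$sign[match(paste(ca$resname, ca$atom),
                                   paste(CHARGED_ATOMS$resname, CHARGED_ATOMS$atom))]
    sb <- CHARGED_ATOMS$sign[match(paste(cb$resname, cb$atom),
                                   paste(CHARGED_ATOMS$resname, CHARGED_ATOMS$atom))]
    if (any(sa > 0) && any(sb < 0) || any(sa < 0) && any(sb > 0)) {
      best <- NULL
      for (i in seq_len(nrow(ca))) for (j in seq_len(nrow(cb))) {
        if (sa[i] * sb[j] < 0) {
          dd <- sqrt(sum((unlist(ca[i, c("x", "y", "z")]) -
                            unlist(cb[j, c("x", "y", "z")]))^2))
          if (is.null(best) || dd < best$dist)
            best <- list(dist = dd, pa = ca$atom[i], pb = cb$atom[j])
        }
      }
      if (!is.null(best) && best$dist <= params$ionic)
        add("IONIC", best$dist, paste0(best$pa, "-", best$pb))
    }
  }

  # hydrogen bonds, sub-typed by main/side membership of donor and acceptor
  hb_sets <- function(at) {
    list(don_m = at[at$atom == "N", ],
         acc_m = at[at$atom == "O", ],
         don_s = sel(at, HB_DONOR_SC),
         acc_s = sel(at, HB_ACCEPT_SC))
  }
  ha <- hb_sets(a); hb <- hb_sets(b)
  hb_best <- list(HBOND_SS = NULL, HBOND_MS = NULL, HBOND_MM = NULL)
  hb_try <- function(d_set, a_set, d_main, a_main) {
    pm <- pair_min_dist(d_set, a_set)
    if (is.null(pm) || pm$dist > params$hbond) return()
    kind <- if (!d_main && !a_main) "HBOND_SS"
    else if (d_main && a_main) "HBOND_MM" else "HBOND_MS"
    cur <- hb_best[[kind]]
    if (is.null(cur) || pm$dist < cur$dist) hb_best[[kind]] <<- pm
  }
  hb_try(ha$don_s, hb$acc_s, FALSE, FALSE); hb_try(hb$don_s, ha$acc_s, FALSE, FALSE)
  hb_try(ha$don_m, hb$acc_s, TRUE, FALSE); hb_try(hb$don_m, ha$acc_s, TRUE, FALSE)
  hb_try(ha$don_s, hb$acc_m, FALSE, TRUE); hb_try(hb$don_s, ha$acc_m, FALSE, TRUE)
  hb_try(ha$don_m, hb$acc_m, TRUE, TRUE); hb_try(hb$don_m, ha$acc_m, TRUE, TRUE)
  for (k in names(hb_best)) if (!is.null(hb_best[[k]]))
    add(k, hb_best[[k]]$dist,
        paste0(hb_best[[k]]$atom_a, "-", hb_best[[k]]$atom_b))

  # aromatic-aromatic: centroid distance inside the inclusive window
  ra <- if (la$resname %in% names(RING_ATOMS)) ring_centroid(a) else NULL
  rb <- if (lb$resname %in% names(RING_ATOMS)) ring_centroid(b) else NULL
  if (la$resname %in% names(RING_ATOMS) && is.null(ra) ||
      lb$resname %in% names(RING_ATOMS) && is.null(rb))
    warn(sprintf("incomplete ring atoms for %s%s/%s%s: aromatic types skipped",
                 la$resname, la$resno, lb$resname, lb$resno))
  if (!is.null(ra) && !is.null(rb)) {
    dd <- sqrt(sum((ra - rb)^2))
    if (dd >= params$aromatic_min && dd <= params$aromatic_max)
      add("AROMATIC_AROMATIC", dd, "ring-ring")
  }

  # aromatic-sulfur: ring centroid to Cys SG / Met SD
  arom_sulf <- function(cent, other, cent_first) {
    ss <- sel(other, SULFUR_ATOMS)
    if (is.null(cent) || nrow(ss) == 0) return()
    d2 <- sqrt(colSums((t(as.matrix(ss[, c("x", "y", "z")])) - cent)^2))
    if (min(d2) <= params$aromatic_sulfur)
      add("AROMATIC_SULFUR", min(d2),
          if (cent_first) paste0("ring-", ss$atom[which.min(d2)])
          else paste0(ss$atom[which.min(d2)], "-ring"))
  }
  arom_sulf(ra, b, TRUE); arom_sulf(rb, a, FALSE)

  # cation-pi: ring centroid to Lys NZ / Arg guanidinium N
  cat_pi <- function(cent, other, cent_first) {
    cs <- sel(other, CATIONIC_ATOMS)
    if (is.null(cent) || nrow(cs) == 0) return()
    d2 <- sqrt(colSums((t(as.matrix(cs[, c("x", "y", "z")])) - cent)^2))
    if (min(d2) <= params$cation_pi)
      add("CATION_PI", min(d2),
          if (cent_first) paste0("ring-", cs$atom[which.min(d2)])
          else paste0(cs$atom[which.min(d2)], "-ring"))
  }
  cat_pi(ra, b, TRUE); cat_pi(rb, a, FALSE)

  # hydrophobic: side-chain carbon pair between apolar residues
  if (la$resname %in% HYDROPHOBIC_RES && lb$resname %in% HYDROPHOBIC_RES) {
    sc_c <- function(at) at[at$element == "C" & !at$atom %in% BACKBONE, ]
    pm <- pair_min_dist(sc_c(a), sc_c(b))
    if (!is.null(pm) && pm$dist <= params$hydrophobic)
      add("HYDROPHOBIC", pm$dist, paste0(pm$atom_a, "-", pm$atom_b))
  }

  if (length(out) == 0)
    return(tibble(chain_a = character(0), resno_a = integer(0),
                  icode_a = character(0), resname_a = character(0),
                  chain_b = character(0), resno_b = integer(0),
                  icode_b = character(0), resname_b = character(0),
                  kind = character(0), distance = numeric(0),
                  partners = character(0)))
  bind_rows(out)
}

#' Interface residues between two chain groups
#'
#' Residues of each group having any heavy atom within `cutoff` of any
#' heavy atom of the other group.
#'
#' @param s A `gdtr_structure`.
#' @param group_a,group_b Character vectors of chain ids (disjoint).
#' @param cutoff Angstrom (default 4.0).
#' @return List with tibbles `a` and `b` of interface residues
#'   (`chain`, `resno`, `icode`, `resname`).
#' @export
interface_residues <- function(s, group_a, group_b, cutoff = 4.0) {
  if (length(intersect(group_a, group_b)) > 0)
    abort("chain groups must be disjoint")
  at <- heavy_atoms(as_tibble(s))
  A <- filter(at, .data$chain %in% group_a)
  B <- filter(at, .data$chain %in% group_b)
  if (nrow(A) == 0 || nrow(B) == 0) abort("empty chain group")
  MA <- as.matrix(A[, c("x", "y", "z")])
  MB <- as.matrix(B[, c("x", "y", "z")])
  d2 <- outer(rowSums(MA^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(MB^2)) - 2 * MA %*% t(MB)
  hit <- d2 <= cutoff^2 + 1e-12
  res_of <- function(at_tbl, sel_rows) {
    distinct(at_tbl[sel_rows, c("chain", "resno", "icode", "resname")])
  }
  list(a = res_of(A, rowSums(hit) > 0), b = res_of(B, colSums(hit) > 0))
}

#' Typed contact table between two chain groups
#'
#' Runs [classify_pair()] over all residue pairs within reach between the
#' two groups (residue pairs prefiltered at the widest threshold plus ring
#' reach) and annotates both sides with IMGT positions and regions from the
#' supplied numbering correspondences. One contact is kept per (residue
#' pair, type), at the minimal defining distance.
#'
#' @param s A `gdtr_structure`.
#' @param group_a,group_b Chain-id vectors.
#' @param numberings Optional list of `gdtr_correspondence` tables (any
#'   chains they cover get IMGT annotation; others keep author numbering
#'   only).
#' @param labels Length-2 character: group labels (default the chain ids
#'   pasted together).
#' @param params [contact_params()].
#' @return A `gdtr_contacts` tibble; columns `group_a/b`, `chain_a/b`,
#'   `resno_a/b`, `icode_a/b`, `resname_a/b`, `aa_a/b`, `imgt_a/b`,
#'   `region_a/b`, `kind`, `distance`, `partners`; attributes `groups`,
#'   `params`, `provenance`.
#' @export
contact_table <- function(s, group_a, group_b, numberings = list(),
                          labels = NULL, params = contact_params()) {
  labels <- labels %||% c(paste(group_a, collapse = "+"),
                          paste(group_b, collapse = "+"))
  # residue-level prefilter: widest atom-atom threshold, plus slack for
  # centroid-based rules whose defining points are inside the residues
  reach <- max(params$ionic, params$hbond, params$aromatic_max,
               params$aromatic_sulfur, params$cation_pi, params$hydrophobic)
  ir <- interface_residues(s, group_a, group_b, cutoff = reach + 3.5)
  rows <- list()
  for (i in seq_len(nrow(ir$a))) for (j in seq_len(nrow(ir$b))) {
    ra <- residue_atoms(s, ir$a$chain[i], ir$a$resno[i], ir$a$icode[i])
    rb <- residue_atoms(s, ir$b$chain[j], ir$b$resno[j], ir$b$icode[j])
    cc <- classify_pair(ra, rb, params)
    if (nrow(cc) > 0) rows[[length(rows) + 1]] <- cc
  }
  contacts <- if (length(rows)) bind_rows(rows) else classify_empty()
  contacts <- contacts |>
    group_by(across(c("chain_a", "resno_a", "icode_a", "chain_b",
                      "resno_b", "icode_b", "kind"))) |>
    arrange(.data$distance, .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup()
  contacts <- mutate(contacts,
                     group_a = labels[1], group_b = labels[2],
                     aa_a = aa_three_to_one(.data$resname_a),
                     aa_b = aa_three_to_one(.data$resname_b),
                     imgt_a = NA_character_, region_a = NA_character_,
                     imgt_b = NA_character_, region_b = NA_character_)
  for (corr in numberings) {
    for (side in c("a", "b")) {
      ch_col <- paste0("chain_", side); no_col <- paste0("resno_", side)
      m <- match(paste(contacts[[ch_col]], contacts[[no_col]]),
                 paste(corr$chain, corr$author_number))
      hit <- !is.na(m)
      contacts[[paste0("imgt_", side)]][hit] <- corr$position[m[hit]]
      contacts[[paste0("region_", side)]][hit] <- corr$region[m[hit]]
    }
  }
  contacts <- select(contacts,
                     "group_a", "chain_a", "region_a", "resname_a", "aa_a",
                     "imgt_a", "resno_a", "icode_a",
                     "kind", "distance", "partners",
                     "group_b", "chain_b", "region_b", "resname_b", "aa_b",
                     "imgt_b", "resno_b", "icode_b")
  new_contacts(contacts, groups = labels, params = params,
               provenance = attr(s, "title") %||% "")
}

classify_empty <- function() {
  tibble(chain_a = character(0), resno_a = integer(0), icode_a = character(0),
         resname_a = character(0), chain_b = character(0),
         resno_b = integer(0), icode_b = character(0),
         resname_b = character(0), kind = character(0),
         distance = numeric(0), partners = character(0))
}

new_contacts <- function(tbl, groups, params = contact_params(),
                         provenance = "") {
  validate_contacts(tbl, params)
  structure(tbl, class = c("gdtr_contacts", class(tbl)),
            groups = groups, params = params, provenance = provenance)
}

# every emitted contact must sit inside its type's distance window
validate_contacts <- function(tbl, params) {
  bad <- rep(FALSE, nrow(tbl))
  d <- tbl$distance; k <- tbl$kind
  bad[k == "IONIC" & d > params$ionic] <- TRUE
  bad[startsWith(k, "HBOND") & d > params$hbond] <- TRUE
  bad[k == "AROMATIC_AROMATIC" &
        (d < params$aromatic_min | d > params$aromatic_max)] <- TRUE
  bad[k == "AROMATIC_SULFUR" & d > params$aromatic_sulfur] <- TRUE
  bad[k == "CATION_PI" & d > params$cation_pi] <- TRUE
  bad[k == "HYDROPHOBIC" & d > params$hydrophobic] <- TRUE
  if (!all(k %in% interaction_types()))
    abort("unknown interaction type in contact table")
  if (any(bad))
    abort("contact distances outside their type windows")
  dup <- duplicated(tbl[, c("chain_a", "resno_a", "icode_a",
                            "chain_b", "resno_b", "icode_b", "kind")])
  if (any(dup)) abort("duplicate (residue pair, type) contacts")
  invisible(tbl)
}

#' @export
print.gdtr_contacts <- function(x, ...) {
  g <- attr(x, "groups")
  cat(sprintf("<gdtr_contacts> %s vs %s: %d contacts\n",
              g[1], g[2], nrow(x)))
  print(as_tibble(x), ...)
  invisible(x)
}

#' Summarise a contact table
#'
#' Deterministic counts: interactions per type, distinct residues per group
#' label, and distinct residues per region label. Counts are invariant to
#' row order.
#'
#' @param t A `gdtr_contacts` tibble (or compatible tibble).
#' @return List with `n_contacts`, `by_type` (tibble), `residues_per_group`
#'   (tibble), `residues_per_region` (tibble).
#' @export
summarize_table <- function(t) {
  t <- as_tibble(t)
  one_side <- function(side) {
    resno <- t[[paste0("resno_", side)]]
    imgt <- t[[paste0("imgt_", side)]]
    # author number is the primary residue identity (IMGT positions recur
    # across the two G domains of one MH-like chain); IMGT as fallback
    key <- ifelse(is.na(resno), paste0("imgt:", imgt), paste0("no:", resno))
    tibble(group = t[[paste0("group_", side)]],
           region = t[[paste0("region_", side)]],
           res = paste0(t[[paste0("chain_", side)]], "/", key))
  }
  sides <- bind_rows(one_side("a"), one_side("b"))
  list(
    n_contacts = nrow(t),
    by_type = t |> dplyr::count(.data$kind, name = "n") |>
      arrange(.data$kind),
    residues_per_group = sides |> distinct() |>
      group_by(.data$group) |>
      summarise(n_residues = dplyr::n_distinct(.data$res), .groups = "drop"),
    residues_per_region = sides |> distinct() |>
      group_by(.data$group, .data$region) |>
      summarise(n_residues = dplyr::n_distinct(.data$res), .groups = "drop")
  )
}

CONTACT_COLS <- c("group_a", "chain_a", "region_a", "resname_a", "aa_a",
                  "imgt_a", "resno_a", "icode_a", "kind", "distance",
                  "partners", "group_b", "chain_b", "region_b", "resname_b",
                  "aa_b", "imgt_b", "resno_b", "icode_b")

#' Read / write contact tables as TSV
#'
#' Fixed documented column order: group_a, chain_a, region_a, resname_a,
#' aa_a, imgt_a, resno_a, icode_a, kind, distance, partners, then the
#' mirrored `_b` columns.
#'
#' @param path TSV path.
#' @param t A `gdtr_contacts`.
#' @param params [contact_params()] used to validate windows on read.
#' @return `read_contact_table()` a `gdtr_contacts`;
#'   `write_contact_table()` the path, invisibly.
#' @export
read_contact_table <- function(path, params = contact_params()) {
  t <- as_tibble(utils::read.delim(path, sep = "\t", header = TRUE,
                                   na.strings = "NA",
                                   colClasses = "character",
                                   check.names = FALSE))
  missing_cols <- setdiff(CONTACT_COLS, names(t))
  if (length(missing_cols) > 0)
    abort(paste0("contact TSV missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  t <- t[, CONTACT_COLS]
  t$resno_a <- as.integer(t$resno_a)
  t$resno_b <- as.integer(t$resno_b)
  t$distance <- as.numeric(t$distance)
  t$icode_a <- t$icode_a %|NA|% ""
  t$icode_b <- t$icode_b %|NA|% ""
  new_contacts(t, groups = c(t$group_a[1], t$group_b[1]), params = params,
               provenance = path)
}

#' @rdname read_contact_table
#' @export
write_contact_table <- function(t, path) {
  utils::write.table(as_tibble(t)[, CONTACT_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}
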