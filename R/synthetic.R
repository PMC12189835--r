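# Synthetic fixture generators. Every generator returns the artifact plus a
# TruthRecord (generator name, seed, parameters, structured answer key);
# the same seed reproduces byte-identical output, and each generator draws
# from its own named RNG stream so adding one never shifts another.

truth_record <- function(generator, seed, parameters, truth) {
  structure(list(generator = generator, seed = seed,
                 parameters = parameters, truth = truth),
            class = "gdtr_truth")
}

#' Generate a rearranged V-(D)-J clone with known composition
#'
#' Assembles a productive in-frame clone as 3'V + alternating PN/D blocks +
#' 5'J on top of the supplied germline segments, with optional point
#' mutations inside D blocks, and records every block and mutated site.
#' PN lengths are redrawn (bounded retries) until the junction stays in
#' frame with no internal stop.
#'
#' @param v_ref,j_ref Single-row germline tibbles (see
#'   [germline_segments()]).
#' @param d_refs Germline D tibble.
#' @param n_d Number of D segments to use (0-5, drawn in gene order from
#'   `d_genes` or sampled).
#' @param d_genes Optional character vector naming the D genes to use in
#'   order (overrides `n_d`).
#' @param pn_len_range Integer range for each PN stretch (default 0:4,
#'   below the D-match detection floor so chance matches stay rare).
#' @param mutation_rate Per-nt substitution probability inside D blocks.
#' @param target_length_aa Optional CDR3-IMGT length to hit exactly; PN
#'   lengths are drawn to fill the difference.
#' @param tissue Tissue label for the clone.
#' @param name Clone id.
#' @param seed Integer seed.
#' @return List `clone` (one-row tibble: `name`, `tissue`, `nt_seq`,
#'   `reading_frame`, `locus`) and `truth` (a TruthRecord whose `truth`
#'   holds the block table over the CDR3 junction, mutated sites, and the
#'   planted CDR3 length).
#' @export
gen_rearrangement <- function(v_ref, j_ref, d_refs, n_d = 2,
                              d_genes = NULL, pn_len_range = 0:4,
                              mutation_rate = 0, target_length_aa = NULL,
                              tissue = "spleen", name = "synth1", seed = 1) {
  stopifnot(n_d >= 0, n_d <= 5)
  with_gen_seed(seed, "rearrangement", {
    v_nt <- toupper(v_ref$nt_seq[1])
    j_nt <- toupper(j_ref$nt_seq[1])
    v_tail <- v_3prime_region(v_ref)   # 3'V-REGION beyond the 2nd-CYS codon
    j_head <- j_5prime_region(j_ref)   # 5'J-REGION before J-PHE/TRP
    use_genes <- d_genes %||%
      sort(sample(d_refs$gene_name, n_d))
    d_seqs <- toupper(d_refs$nt_seq[match(use_genes, d_refs$gene_name)])
    n_pn <- length(d_seqs) + 1L
    pn_budget <- if (!is.null(target_length_aa)) {
      3L * target_length_aa - nchar(v_tail) - sum(nchar(d_seqs)) -
        nchar(j_head)
    } else NA_integer_
    if (!is.na(pn_budget) && pn_budget < 0)
      abort("target CDR3 length shorter than the germline contributions")
    pn_cap <- max(pn_len_range)
    if (!is.na(pn_budget) && pn_budget > pn_cap * n_pn)
      abort(sprintf(
        "target CDR3 length needs %d PN nt but the %d PN stretches are capped at %d each",
        pn_budget, n_pn, pn_cap))
    for (attempt in 1:500) {
      pn_lens <- if (is.na(pn_budget)) {
        vapply(seq_len(n_pn), function(i) sample(pn_len_range, 1), integer(1))
      } else {
        # near-equal split of the budget, randomised remainder; keeps every
        # PN stretch short enough to stay identifiable next to real D matches
        base_len <- pn_budget %/% n_pn
        lens <- rep(base_len, n_pn)
        rem <- pn_budget - base_len * n_pn
        if (rem > 0) {
          bump <- sample.int(n_pn, rem)
          lens[bump] <- lens[bump] + 1L
        }
        lens
      }
      pn <- vapply(pn_lens, function(len)
        paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
              collapse = ""), character(1))
      mut_sites <- integer(0)
      d_mut <- d_seqs
      if (mutation_rate > 0) for (k in seq_along(d_mut)) {
        da <- strsplit(d_mut[k], "")[[1]]
        hit <- which(stats::runif(length(da)) < mutation_rate)
        for (h in hit) da[h] <- sample(setdiff(c("A", "C", "G", "T"), da[h]), 1)
        d_mut[k] <- paste(da, collapse = "")
        mut_sites <- c(mut_sites, hit)
      }
      mids <- character(0)
      for (k in seq_along(d_mut)) mids <- c(mids, pn[k], d_mut[k])
      mids <- c(mids, pn[length(pn)])
      junction <- paste0(v_tail, paste(mids, collapse = ""), j_head)
      if (nchar(junction) %% 3 != 0) next
      # identifiability guards: the junction must not fake the anchors
      # (no Cys, no F/W-G-X-G inside the CDR3) ...
      jaa <- translate_nt(junction)
      if (grepl("\\*|C|[FW]G.G", jaa)) next
      # ... and the planted segmentation must be the one the attribution
      # rules recover (no chance D matches inside PN, no match extension
      # across block boundaries)
      mid_nt <- paste(mids, collapse = "")
      if (nchar(mid_nt) > 0) {
        got <- attribute_d_segments(mid_nt, d_refs, min_match = 5,
                                    max_mismatch = 1)
        want_origin <- c(rbind(ifelse(nchar(pn[seq_along(d_mut)]) > 0,
                                      "PN", NA),
                               paste0("D:", use_genes)),
                         if (nchar(pn[length(pn)]) > 0) "PN")
        want_origin <- want_origin[!is.na(want_origin)]
        want_seq <- c(rbind(ifelse(nchar(pn[seq_along(d_mut)]) > 0,
                                   pn[seq_along(d_mut)], NA), d_mut),
                      if (nchar(pn[length(pn)]) > 0) pn[length(pn)])
        want_seq <- want_seq[!is.na(want_seq)]
        if (!identical(got$origin, want_origin) ||
            !identical(got$seq, want_seq)) next
      }
      nt_seq <- paste0(v_nt, paste(mids, collapse = ""), j_nt)
      aa <- translate_nt(nt_seq)
      if (grepl("\\*", aa)) next
      anch <- tryCatch(locate_anchors(aa), error = function(e) NULL)
      if (is.null(anch)) next
      # truth blocks over the junction (CDR3 nt between codons 105 and 117)
      blocks <- list(tibble(origin = "3'V", seq = v_tail))
      for (k in seq_along(d_mut)) {
        if (nchar(pn[k]) > 0)
          blocks[[length(blocks) + 1]] <- tibble(origin = "PN", seq = pn[k])
        blocks[[length(blocks) + 1]] <-
          tibble(origin = paste0("D:", use_genes[k]), seq = d_mut[k])
      }
      if (nchar(pn[length(pn)]) > 0)
        blocks[[length(blocks) + 1]] <- tibble(origin = "PN",
                                               seq = pn[length(pn)])
      blocks[[length(blocks) + 1]] <- tibble(origin = "5'J", seq = j_head)
      blocks <- bind_rows(blocks)
      blocks$end <- cumsum(nchar(blocks$seq))
      blocks$start <- blocks$end - nchar(blocks$seq) + 1L
      clone <- tibble(name = name, tissue = tissue, nt_seq = nt_seq,
                      reading_frame = 0L, locus = "TRD")
      return(list(
        clone = clone,
        truth = truth_record(
          "gen_rearrangement", seed,
          list(n_d = length(use_genes), d_genes = use_genes,
               pn_len_range = pn_len_range, mutation_rate = mutation_rate),
          list(blocks = blocks[, c("origin", "start", "end", "seq")],
               d_genes = use_genes, mutated_sites = mut_sites,
               cdr3_length_aa = nchar(junction) / 3))))
    }
    abort("could not assemble an identifiable in-frame junction in 500 tries")
  })
}

#' Generate a V- or G-domain amino-acid sequence with planted anchors
#'
#' V domains are built on the shipped scaffold of the requested kind with
#' the conserved anchors (C23, W41, C104, F/W 118 + the F/W-G-X-G motif) at
#' the correct relative offsets and CDRs of the requested lengths; specific
#' residues can be planted at named IMGT positions. G domains are the
#' shipped 92-position scaffold with optional substitutions and letter
#' insertions.
#'
#' @param kind `"V-GAMMA"`, `"V-DELTA"`, `"G-ALPHA1-LIKE"`,
#'   `"G-ALPHA2-LIKE"`.
#' @param cdr_lengths Integer triple for V domains (default c(6, 8, 13)).
#' @param plant Named character vector: IMGT position -> one-letter residue
#'   to plant (V: any numbered position; G: base positions).
#' @param insert_after For G domains, named character vector: base position
#'   -> residues to insert after it (becomes 72A etc.).
#' @param n_mutations Seeded random substitutions sprinkled outside anchors
#'   and planted sites (emulating somatic hypermutation).
#' @param seed Integer seed.
#' @return List `sequence` (string) and `truth` (TruthRecord with anchor
#'   indices, planted positions, per-position answer key).
#' @export
gen_domain_sequence <- function(kind, cdr_lengths = c(6L, 8L, 13L),
                                plant = character(0),
                                insert_after = character(0),
                                n_mutations = 0, seed = 1) {
  if (kind %in% names(V_SCAFFOLD))
    gen_v_domain(kind, cdr_lengths, plant, n_mutations, seed)
  else if (kind %in% names(G_SCAFFOLD))
    gen_g_domain(kind, plant, insert_after, n_mutations, seed)
  else abort(paste0("unknown domain kind: ", kind))
}

gen_v_domain <- function(kind, cdr_lengths, plant, n_mutations, seed) {
  with_gen_seed(seed, "domain", {
    seg <- V_SCAFFOLD[[kind]]
    L <- as.integer(cdr_lengths)
    resize_cdr <- function(full, L_target, region) {
      pos_full <- imgt_cdr_positions(nchar(full),  region)
      pos_tgt <- imgt_cdr_positions(L_target, region)
      if (region == "CDR3" && L_target > 13) {
        extra <- paste(sample(strsplit("GSTADNRY", "")[[1]],
                              L_target - 13, replace = TRUE), collapse = "")
        base <- strsplit(full, "")[[1]]
        # insert between 111 (7th) and 112 (8th) of the 13-residue loop
        return(paste0(paste(base[1:7], collapse = ""), extra,
                      paste(base[8:13], collapse = "")))
      }
      keep <- match(pos_tgt, pos_full)
      paste(strsplit(full, "")[[1]][keep], collapse = "")
    }
    parts <- list(
      fr1 = seg$fr1,
      cdr1 = resize_cdr(seg$cdr1, L[1], "CDR1"),
      fr2 = seg$fr2,
      cdr2 = resize_cdr(seg$cdr2, L[2], "CDR2"),
      fr3 = seg$fr3,
      cdr3 = resize_cdr(seg$cdr3, L[3], "CDR3"),
      fr4 = seg$fr4
    )
    seqv <- strsplit(paste(unlist(parts), collapse = ""), "")[[1]]
    # position table for planting and truth
    pos <- c(as.character(1:26), imgt_cdr_positions(L[1], "CDR1"),
             as.character(39:55), imgt_cdr_positions(L[2], "CDR2"),
             as.character(66:104), imgt_cdr_positions(L[3], "CDR3"),
             as.character(118:128))
    stopifnot(length(pos) == length(seqv))
    anchors <- c(c23 = which(pos == "23"), w41 = which(pos == "41"),
                 c104 = which(pos == "104"), fw118 = which(pos == "118"))
    protected <- c(anchors, fw118_motif = anchors["fw118"] + 1L,
                   anchors["fw118"] + 3L)
    if (length(plant) > 0) {
      idx <- match(names(plant), pos)
      if (anyNA(idx)) abort(paste0("plant positions not occupied: ",
                                   paste(names(plant)[is.na(idx)],
                                         collapse = ", ")))
      seqv[idx] <- unname(plant)
      protected <- c(protected, idx)
    }
    if (n_mutations > 0) {
      free <- setdiff(seq_along(seqv), protected)
      hit <- sample(free, min(n_mutations, length(free)))
      for (h in hit) seqv[h] <- sample(setdiff(names(AA1), c(seqv[h], "C", "W", "F", "*")), 1)
    }
    sequence <- paste(seqv, collapse = "")
    list(sequence = sequence,
         truth = truth_record("gen_domain_sequence", seed,
                              list(kind = kind, cdr_lengths = L,
                                   plant = plant, n_mutations = n_mutations),
                              list(anchors = anchors,
                                   positions = tibble(position = pos,
                                                      aa = seqv))))
  })
}

gen_g_domain <- function(kind, plant, insert_after, n_mutations, seed) {
  with_gen_seed(seed, "domain", {
    seqv <- strsplit(G_SCAFFOLD[[kind]], "")[[1]]
    pos <- as.character(seq_along(seqv))
    if (length(plant) > 0) {
      idx <- match(names(plant), pos)
      if (anyNA(idx)) abort("plant positions outside 1-92")
      seqv[idx] <- unname(plant)
    }
    protected <- match(names(plant), pos)
    if (n_mutations > 0) {
      free <- setdiff(seq_along(seqv), c(protected,
                                         match(names(insert_after), pos)))
      hit <- sample(free, min(n_mutations, length(free)))
      for (h in hit) seqv[h] <- sample(setdiff(names(AA1), seqv[h]), 1)
    }
    if (length(insert_after) > 0) {
      for (k in rev(order(as.integer(names(insert_after))))) {
        at <- as.integer(names(insert_after)[k])
        ins <- strsplit(insert_after[[k]], "")[[1]]
        seqv <- append(seqv, ins, after = at)
        pos <- append(pos, paste0(at, LETTERS[seq_along(ins)]), after = at)
      }
    }
    list(sequence = paste(seqv, collapse = ""),
         truth = truth_record("gen_domain_sequence", seed,
                              list(kind = kind, plant = plant,
                                   insert_after = insert_after,
                                   n_mutations = n_mutations),
                              list(positions = tibble(position = pos,
                                                      aa = seqv))))
  })
}

# minimal idealised residue templates (local frame, Angstrom): backbone +
# the side-chain atoms the classifiers need; rings as regular polygons
residue_template <- function(resname) {
  bb <- tibble(atom = c("N", "CA", "C", "O"),
               element = c("N", "C", "C", "O"),
               x = c(-1.46, 0, 1.52, 2.15), y = c(0, 0, 0.9, 1.9),
               z = c(0, 0, 0, 0))
  hexagon <- function(cx, r = 1.39) {
    ang <- seq(0, by = pi / 3, length.out = 6)
    tibble(x = cx + r * cos(ang), y = 2.5 + r * sin(ang), z = 0)
  }
  sc <- switch(
    resname,
    ALA = tibble(atom = "CB", element = "C", x = -0.5, y = 1.3, z = 1.0),
    ARG = tibble(atom = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
                 element = c("C", "C", "C", "N", "C", "N", "N"),
                 x = c(-0.5, -0.6, -0.7, -0.8, -0.9, -1.8, 0.1),
                 y = c(1.3, 2.8, 3.9, 5.2, 6.4, 7.0, 7.1),
                 z = c(1.0, 1.2, 0.6, 1.1, 0.6, 1.0, 0.1)),
    ASP = tibble(atom = c("CB", "CG", "OD1", "OD2"),
                 element = c("C", "C", "O", "O"),
                 x = c(-0.5, -0.6, -1.6, 0.4),
                 y = c(1.3, 2.8, 3.5, 3.4), z = c(1.0, 1.0, 1.2, 0.8)),
    GLU = tibble(atom = c("CB", "CG", "CD", "OE1", "OE2"),
                 element = c("C", "C", "C", "O", "O"),
                 x = c(-0.5, -0.6, -0.7, -1.7, 0.3),
                 y = c(1.3, 2.8, 4.1, 4.8, 4.7), z = c(1.0, 1.0, 0.9, 1.1, 0.7)),
    LYS = tibble(atom = c("CB", "CG", "CD", "CE", "NZ"),
                 element = c("C", "C", "C", "C", "N"),
                 x = c(-0.5, -0.6, -0.7, -0.8, -0.9),
                 y = c(1.3, 2.8, 3.9, 5.3, 6.4),
                 z = c(1.0, 1.2, 0.6, 0.9, 0.4)),
    SER = tibble(atom = c("CB", "OG"), element = c("C", "O"),
                 x = c(-0.5, -0.6), y = c(1.3, 2.7), z = c(1.0, 1.1)),
    ASN = tibble(atom = c("CB", "CG", "OD1", "ND2"),
                 element = c("C", "C", "O", "N"),
                 x = c(-0.5, -0.6, -1.6, 0.4),
                 y = c(1.3, 2.8, 3.5, 3.4), z = c(1.0, 1.0, 1.2, 0.8)),
    CYS = tibble(atom = c("CB", "SG"), element = c("C", "S"),
                 x = c(-0.5, -0.7), y = c(1.3, 3.0), z = c(1.0, 1.2)),
    MET = tibble(atom = c("CB", "CG", "SD", "CE"),
                 element = c("C", "C", "S", "C"),
                 x = c(-0.5, -0.6, -0.7, -0.9),
                 y = c(1.3, 2.8, 4.2, 5.3), z = c(1.0, 1.1, 0.7, 1.4)),
    LEU = tibble(atom = c("CB", "CG", "CD1", "CD2"),
                 element = c("C", "C", "C", "C"),
                 x = c(-0.5, -0.6, -1.8, 0.6),
                 y = c(1.3, 2.8, 3.6, 3.5), z = c(1.0, 1.1, 1.0, 1.3)),
    PHE = dplyr::bind_cols(
      tibble(atom = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
             element = "C"),
      dplyr::bind_rows(tibble(x = -0.5, y = 1.3, z = 1.0),
                       hexagon(-0.6))[, c("x", "y", "z")]),
    TYR = dplyr::bind_rows(
      dplyr::bind_cols(
        tibble(atom = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
               element = "C"),
        dplyr::bind_rows(tibble(x = -0.5, y = 1.3, z = 1.0),
                         hexagon(-0.6))[, c("x", "y", "z")]),
      tibble(atom = "OH", element = "O", x = -0.6, y = 5.3, z = 0)),
    TRP = dplyr::bind_cols(
      tibble(atom = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3",
                      "CZ2", "CZ3", "CH2"),
             element = c("C", "C", "C", "C", "N", "C", "C", "C", "C", "C")),
      dplyr::bind_rows(
        tibble(x = -0.5, y = 1.3, z = 1.0),
        {ang <- seq(0, by = 2 * pi / 9, length.out = 9)
         tibble(x = -0.6 + 1.7 * cos(ang), y = 2.9 + 1.7 * sin(ang), z = 0)}
      )[, c("x", "y", "z")]),
    HIS = dplyr::bind_cols(
      tibble(atom = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
             element = c("C", "C", "N", "C", "C", "N")),
      dplyr::bind_rows(
        tibble(x = -0.5, y = 1.3, z = 1.0),
        {ang <- seq(0, by = 2 * pi / 5, length.out = 5)
         tibble(x = -0.6 + 1.32 * cos(ang), y = 2.7 + 1.32 * sin(ang), z = 0)}
      )[, c("x", "y", "z")]),
    VAL = tibble(atom = c("CB", "CG1", "CG2"), element = "C",
                 x = c(-0.5, -1.7, 0.7), y = c(1.3, 2.1, 2.1),
                 z = c(1.0, 1.0, 1.2)),
    ILE = tibble(atom = c("CB", "CG1", "CG2", "CD1"), element = "C",
                 x = c(-0.5, -0.6, 0.7, -0.7),
                 y = c(1.3, 2.8, 1.9, 4.2), z = c(1.0, 1.1, 1.6, 1.0)),
    PRO = tibble(atom = c("CB", "CG", "CD"), element = "C",
                 x = c(-0.5, -1.5, -2.2), y = c(1.3, 2.1, 1.0),
                 z = c(1.0, 0.8, 0.5)),
    GLY = NULL,
    abort(paste0("no template for residue ", resname))
  )
  bind_rows(mutate(bb, resname = resname),
            if (!is.null(sc)) mutate(sc, resname = resname))
}

# defining anchor of a residue for a given interaction kind: an atom name
# or "RING" (centroid)
kind_anchor <- function(kind, role) {
  switch(kind,
         IONIC = if (role == "a") "NH2" else "OD1",
         HBOND_SS = if (role == "a") "OG" else "OD1",
         HBOND_MS = if (role == "a") "N" else "OD1",
         HBOND_MM = if (role == "a") "N" else "O",
         AROMATIC_AROMATIC = "RING",
         AROMATIC_SULFUR = if (role == "a") "RING" else "SD",
         CATION_PI = if (role == "a") "RING" else "NZ",
         HYDROPHOBIC = if (role == "a") "CD1" else "CD1")
}

kind_residues <- function(kind) {
  switch(kind,
         IONIC = c("ARG", "ASP"),
         HBOND_SS = c("SER", "ASP"),
         HBOND_MS = c("GLY", "ASP"),
         HBOND_MM = c("GLY", "GLY"),
         AROMATIC_AROMATIC = c("PHE", "TRP"),
         AROMATIC_SULFUR = c("PHE", "MET"),
         CATION_PI = c("PHE", "LYS"),
         HYDROPHOBIC = c("LEU", "ILE"))
}

anchor_point <- function(at, anchor) {
  if (anchor == "RING") ring_centroid(at)
  else unlist(at[at$atom == anchor, c("x", "y", "z")], use.names = FALSE)
}

# orient partner residue side-chain-down (180 degrees about z) and shift it
# so its anchor sits `distance` above the host anchor along +y: side chains
# face each other, backbones point away, and the anchor pair realises the
# minimal (defining) distance exactly
oppose_residue <- function(b, anchor_b, pa, distance) {
  b <- mutate(b, x = -.data$x, y = -.data$y)
  pb <- anchor_point(b, anchor_b)
  shift <- c(pa[1] - pb[1], pa[2] + distance - pb[2], pa[3] - pb[3])
  mutate(b, x = .data$x + shift[1], y = .data$y + shift[2],
         z = .data$z + shift[3])
}

# place residue template `resname` so its anchor sits at `target`, offset
# along +x from the partner, with a seeded random rigid orientation jitter
place_residue <- function(resname, chain, resno, at_origin = c(0, 0, 0)) {
  tpl <- residue_template(resname)
  mutate(tpl, chain = chain, resno = resno, icode = "",
         x = .data$x + at_origin[1], y = .data$y + at_origin[2],
         z = .data$z + at_origin[3], occupancy = 1, b = 0)
}

#' Generate a two-chain fixture with one planted interaction
#'
#' Builds a minimal two-chain structure carrying exactly one residue pair
#' of the requested interaction type with its defining distance (atom-atom
#' or centroid-based, per the type's rule) set exactly to `distance`.
#' Decoy residues (Gly/Ala) are placed at least 10 Angstrom away on each
#' chain.
#'
#' @param kind One of [interaction_types()].
#' @param distance Defining distance, Angstrom.
#' @param seed Integer seed (orients the scattered decoys).
#' @return List `structure` (a `gdtr_structure`) and `truth` (TruthRecord:
#'   planted kind, distance, residue identifiers).
#' @export
gen_interaction_fixture <- function(kind, distance, seed = 1) {
  stopifnot(kind %in% interaction_types())
  with_gen_seed(seed, "interaction", {
    rr <- kind_residues(kind)
    a <- place_residue(rr[1], "A", 1)
    b <- place_residue(rr[2], "B", 1)
    pa <- anchor_point(a, kind_anchor(kind, "a"))
    b <- oppose_residue(b, kind_anchor(kind, "b"), pa, distance)
    decoys <- bind_rows(
      place_residue("GLY", "A", 2, c(-18, 10 + stats::runif(1), 0)),
      place_residue("ALA", "B", 2, c(18, distance + 12 + stats::runif(1), 0)))
    s <- as_structure(bind_rows(a, b, decoys), source = "synthetic",
                      title = paste0("planted ", kind, " at ", distance, " A"))
    list(structure = s,
         truth = truth_record("gen_interaction_fixture", seed,
                              list(kind = kind, distance = distance),
                              list(kind = kind, distance = distance,
                                   res_a = list(chain = "A", resno = 1,
                                                resname = rr[1]),
                                   res_b = list(chain = "B", resno = 1,
                                                resname = rr[2]))))
  })
}

#' Generate a four-chain toy complex with planted contacts
#'
#' Two "receptor" chains (G, D), one "presenter" chain (C) and one "light"
#' chain (L), with the requested number of planted contacts per type
#' between the receptor pair (G vs D) and between the receptor and
#' presenter (G+D vs C). Planted pairs are spaced at least 10 Angstrom
#' apart; the light chain is a distant decoy.
#'
#' @param n_per_type Named integer vector: interaction type -> number of
#'   planted contacts per analysed group pair (defaults to one IONIC and
#'   one HBOND_SS between G and D).
#' @param between `"GD"` (receptor pair) or `"GD_C"` (receptor vs
#'   presenter).
#' @param seed Integer seed.
#' @return List `structure` and `truth` (expected contact rows: groups,
#'   chains, residue numbers, kinds, distances).
#' @export
gen_complex_fixture <- function(n_per_type = c(IONIC = 1, HBOND_SS = 1),
                                between = c("GD", "GD_C"), seed = 1) {
  between <- match.arg(between)
  with_gen_seed(seed, "complex", {
    chains <- if (between == "GD") c("G", "D") else c("G", "C")
    rows <- list(); truth_rows <- list()
    slot <- 0L
    for (kind in names(n_per_type)) {
      n_k <- n_per_type[[kind]]
      if (n_k == 0) next
      dist_k <- default_plant_distance(kind)
      for (r in seq_len(n_k)) {
        slot <- slot + 1L
        # non-collinear slot lattice, >= 20 A apart
        off <- c(13 * (slot %% 3), 11 * (slot %% 2), 25 * slot)
        rr <- kind_residues(kind)
        a <- place_residue(rr[1], chains[1], slot, off)
        b <- place_residue(rr[2], chains[2], slot, off)
        pa <- anchor_point(a, kind_anchor(kind, "a"))
        b <- oppose_residue(b, kind_anchor(kind, "b"), pa, dist_k)
        rows[[length(rows) + 1]] <- bind_rows(a, b)
        truth_rows[[length(truth_rows) + 1]] <- tibble(
          chain_a = chains[1], resno_a = slot, resname_a = rr[1],
          chain_b = chains[2], resno_b = slot, resname_b = rr[2],
          kind = kind, distance = dist_k)
      }
    }
    # distant decoy residues so every chain of the four-chain complex
    # exists and every analysed grouping is non-empty
    present <- unique(purrr::map_chr(rows, ~ .x$chain[1]))
    missing_chains <- setdiff(c("G", "D", "C", "L"), present)
    for (k in seq_along(missing_chains))
      rows[[length(rows) + 1]] <- place_residue(
        "GLY", missing_chains[k], 999L, c(200 + 30 * k, 200, 0))
    rows[[length(rows) + 1]] <- place_residue("GLY", "L", 1, c(170, 230, 0))
    s <- as_structure(bind_rows(rows), source = "synthetic",
                      title = "planted toy complex")
    truth_tbl <- if (length(truth_rows)) bind_rows(truth_rows) else
      tibble(chain_a = character(0))
    list(structure = s,
         truth = truth_record("gen_complex_fixture", seed,
                              list(n_per_type = n_per_type,
                                   between = between),
                              list(contacts = truth_tbl)))
  })
}

# a comfortably in-window planting distance per type
default_plant_distance <- function(kind) {
  switch(kind, IONIC = 4.0, HBOND_SS = 3.0, HBOND_MS = 3.0, HBOND_MM = 3.0,
         AROMATIC_AROMATIC = 5.5, AROMATIC_SULFUR = 4.5, CATION_PI = 4.5,
         HYDROPHOBIC = 4.0)
}
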