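#' Global pairwise alignment of a query to a template sequence
#'
#' Needleman-Wunsch global alignment (BLOSUM62, affine gaps) wrapping
#' `Biostrings::pairwiseAlignment()`. Identity is computed over aligned
#' (both-resolved) columns; coverage is the percentage of query residues
#' aligned to a template residue.
#'
#' @param query,template Amino-acid strings.
#' @param matrix Substitution matrix name (only `"BLOSUM62"` is shipped).
#' @param gap_open,gap_ext Affine gap penalties (defaults 10 and 0.5).
#' @return A `gdtr_alignment` list: `query_seq`, `template_seq`,
#'   `aligned_pairs` (tibble `qpos`, `tpos`, `match`), `identity_pct`,
#'   `coverage_pct`, `score`, `params`.
#' @export
align_pair <- function(query, template, matrix = "BLOSUM62",
                       gap_open = 10, gap_ext = 0.5) {
  stopifnot(nzchar(query), nzchar(template), matrix == "BLOSUM62")
  mp <- aln_mapping(toupper(query), toupper(template), gap_open, gap_ext)
  structure(list(
    query_seq = toupper(query), template_seq = toupper(template),
    aligned_pairs = mp$pairs,
    identity_pct = 100 * mean(mp$pairs$match),
    coverage_pct = 100 * nrow(mp$pairs) / nchar(query),
    score = mp$score,
    params = list(matrix = matrix, gap_open = gap_open, gap_ext = gap_ext)
  ), class = "gdtr_alignment")
}

#' @export
print.gdtr_alignment <- function(x, ...) {
  cat(sprintf("<gdtr_alignment> %d aligned pairs, identity %.1f%%, coverage %.1f%% (score %.1f)\n",
              nrow(x$aligned_pairs), x$identity_pct, x$coverage_pct, x$score))
  invisible(x)
}

BACKBONE <- c("N", "CA", "C", "O")

#' Thread a query sequence onto a template chain
#'
#' Alignment-guided backbone threading: for each aligned query/template
#' residue pair the backbone atoms (N, CA, C, O) are copied from the
#' template; identical residues keep the full template side chain, while
#' substituted residues are truncated to CB (template CB, or an ideal
#' tetrahedral CB built from N/CA/C when the template has none, e.g. Gly).
#' Query insertions relative to the template are left unmodeled and flagged.
#' The model chain is renumbered 1..n by query position.
#'
#' @param aln A `gdtr_alignment` of query vs template chain sequence.
#' @param template A `gdtr_structure` containing the template chain.
#' @param template_chain Chain id of the template chain.
#' @param model_chain Chain id for the model (default `"A"`).
#' @return A `gdtr_structure` with attribute `unmodeled` (integer vector of
#'   query positions left without coordinates).
#' @export
thread_model <- function(aln, template, template_chain, model_chain = "A") {
  stopifnot(inherits(aln, "gdtr_alignment"))
  if (aln$coverage_pct < 60)
    abort(sprintf("template unsuitable: aligned coverage %.1f%% < 60%%",
                  aln$coverage_pct))
  tmpl_res <- structure_residues(template)
  tmpl_res <- tmpl_res[tmpl_res$chain == template_chain, ]
  if (nrow(tmpl_res) < max(aln$aligned_pairs$tpos))
    abort("alignment refers to template positions beyond the chain")
  qa <- strsplit(aln$query_seq, "")[[1]]
  rows <- purrr::pmap(aln$aligned_pairs, function(qpos, tpos, match) {
    tr <- tmpl_res[tpos, ]
    at <- residue_atoms(template, tr$chain, tr$resno, tr$icode)
    if (!all(BACKBONE %in% at$atom))
      abort(sprintf("template residue %s%d has incomplete backbone",
                    tr$chain, tr$resno))
    q3 <- aa_one_to_three(qa[qpos])
    if (match) {
      keep <- heavy_atoms(at)
    } else {
      keep <- at[at$atom %in% c(BACKBONE, "CB"), ]
      if (!"CB" %in% keep$atom && q3 != "GLY") {
        cb <- ideal_cb(at)
        keep <- bind_rows(keep, mutate(keep[keep$atom == "CA", ],
                                       atom = "CB", element = "C",
                                       x = cb[1], y = cb[2], z = cb[3]))
      }
      if (q3 == "GLY") keep <- keep[keep$atom %in% BACKBONE, ]
    }
    mutate(keep, chain = model_chain, resno = qpos, icode = "",
           resname = q3, occupancy = 1, b = 0)
  })
  unmodeled <- setdiff(seq_along(qa), aln$aligned_pairs$qpos)
  if (length(unmodeled) > 0)
    warn(sprintf("%d query position(s) unmodeled (template gaps): %s",
                 length(unmodeled), paste(unmodeled, collapse = ",")))
  out <- as_structure(bind_rows(rows), source = "synthetic",
                      title = "threaded comparative model")
  attr(out, "unmodeled") <- as.integer(unmodeled)
  out
}

# ideal tetrahedral CB from backbone N, CA, C
ideal_cb <- function(at) {
  p <- function(a) unlist(at[at$atom == a, c("x", "y", "z")], use.names = FALSE)
  n <- p("N"); ca <- p("CA"); c_ <- p("C")
  b1 <- (n - ca) / sqrt(sum((n - ca)^2))
  b2 <- (c_ - ca) / sqrt(sum((c_ - ca)^2))
  bisector <- -(b1 + b2); bisector <- bisector / sqrt(sum(bisector^2))
  perp <- pracma_cross(b1, b2); perp <- perp / sqrt(sum(perp^2))
  # 1.53 A bond, tetrahedral placement out of the N-CA-C plane
  ca + 1.53 * (sin(0.9526) * bisector + cos(0.9526) * perp)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Kabsch least-squares superposition
#'
#' Rigid-body superposition of paired CA atoms minimising RMSD, via the
#' Kabsch SVD construction with proper-rotation correction.
#'
#' @param mobile,reference `gdtr_structure` objects.
#' @param pairing Tibble/data frame with columns `mobile_chain`,
#'   `mobile_resno`, `ref_chain`, `ref_resno` (insertion codes `""`
#'   assumed); by default residues are paired by `chain` + `resno`
#'   intersection.
#' @param atom Atom label to superpose on (default `"CA"`).
#' @return A `gdtr_superposition` list: `rotation` (3x3, det +1),
#'   `translation` (length-3, applied as `x %*% R + t`), `rmsd`, `n_pairs`.
#' @export
superpose <- function(mobile, reference, pairing = NULL, atom = "CA") {
  get_xyz <- function(s, chains, resnos) {
    at <- filter(as_tibble(s), .data$atom == !!atom)
    key <- paste(at$chain, at$resno)
    idx <- match(paste(chains, resnos), key)
    if (anyNA(idx)) abort("pairing refers to residues without the chosen atom")
    as.matrix(at[idx, c("x", "y", "z")])
  }
  if (is.null(pairing)) {
    rm_ <- structure_residues(mobile); rr <- structure_residues(reference)
    common <- dplyr::inner_join(rm_[, c("chain", "resno")],
                                rr[, c("chain", "resno")],
                                by = c("chain", "resno"))
    pairing <- tibble(mobile_chain = common$chain, mobile_resno = common$resno,
                      ref_chain = common$chain, ref_resno = common$resno)
  }
  if (nrow(pairing) < 3) abort("need at least 3 residue pairs")
  P <- get_xyz(mobile, pairing$mobile_chain, pairing$mobile_resno)
  Q <- get_xyz(reference, pairing$ref_chain, pairing$ref_resno)
  pc <- colMeans(P); qc <- colMeans(Q)
  P0 <- sweep(P, 2, pc); Q0 <- sweep(Q, 2, qc)
  sv <- svd(crossprod(P0, Q0))
  if (min(sv$d) < 1e-8 && sum(sv$d > 1e-8) < 2)
    abort("degenerate point set: fewer than 3 independent positions")
  d <- sign(det(sv$u) * det(sv$v))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  t_vec <- qc - as.numeric(pc %*% R)
  moved <- P %*% R + matrix(t_vec, nrow(P), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  structure(list(rotation = R, translation = t_vec, rmsd = rmsd,
                 n_pairs = nrow(pairing)),
            class = "gdtr_superposition")
}

#' @export
print.gdtr_superposition <- function(x, ...) {
  cat(sprintf("<gdtr_superposition> %d pairs, RMSD %.4f A\n",
              x$n_pairs, x$rmsd))
  invisible(x)
}

#' Apply a superposition (or any rigid transform) to a structure
#'
#' @param s A `gdtr_structure`.
#' @param sup A `gdtr_superposition`, or a list with `rotation` and
#'   `translation`.
#' @return The transformed structure.
#' @export
transform_structure <- function(s, sup) {
  xyz <- as.matrix(as_tibble(s)[, c("x", "y", "z")])
  moved <- xyz %*% sup$rotation +
    matrix(sup$translation, nrow(xyz), 3, byrow = TRUE)
  out <- as_tibble(s)
  out$x <- moved[, 1]; out$y <- moved[, 2]; out$z <- moved[, 3]
  restore_structure(out, s)
}

#' Count steric clashes between non-bonded heavy atoms
#'
#' Counts heavy-atom pairs from different residues closer than `cutoff`,
#' excluding backbone-backbone contacts between sequence-adjacent residues
#' of the same chain (the peptide bond and its neighbours).
#'
#' @param s A `gdtr_structure`.
#' @param cutoff Distance threshold in Angstrom (default 2.2).
#' @return Integer clash count.
#' @export
clash_count <- function(s, cutoff = 2.2) {
  at <- heavy_atoms(as_tibble(s))
  if (nrow(at) < 2) return(0L)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  close <- which(d < cutoff & upper.tri(d), arr.ind = TRUE)
  if (nrow(close) == 0) return(0L)
  i <- close[, 1]; j <- close[, 2]
  same_res <- at$chain[i] == at$chain[j] & at$resno[i] == at$resno[j] &
    at$icode[i] == at$icode[j]
  adjacent_bb <- at$chain[i] == at$chain[j] &
    abs(at$resno[i] - at$resno[j]) == 1L &
    at$atom[i] %in% BACKBONE & at$atom[j] %in% BACKBONE
  sum(!same_res & !adjacent_bb)
}
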