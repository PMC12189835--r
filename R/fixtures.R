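# Synthetic stand-ins for the study's sequences. The real cDNA clones and
# the crystal template are not redistributable, so these fixtures are built
# on the shipped scaffolds to carry the published hallmarks: CDR-IMGT
# lengths [6.8.15] (RTS88-like V-gamma) and [7.3.37] (SC19-like V-delta),
# the Table-1 residue identities at their IMGT positions, the CD1D G-domain
# letter insertion 72A, and the SC19 D-segment usage TRDD1/D2/D4/D5.

#' Synthetic domain sequences mirroring the study's clones
#'
#' Deterministic synthetic V- and G-domain sequences carrying the published
#' hallmark residues at their IMGT positions: an RTS88-like V-gamma
#' `[6.8.15]` (N37, Y38, H40, Y42, F44, R52, Y55, D57, K64, Y111.1, S112,
#' W114, R115, K116), an SC19-like V-delta `[7.3.37]` (W29, S30, F52, R55,
#' F103, D107, R109, Y111.2, R111.4, W111.5, R111.7, D111.9, W111.10, R112,
#' W112.6), and CD1D-like G-ALPHA1 (D43, F55, E61, N62, H65) and G-ALPHA2
#' (E65, W69, Ser inserted at 72A) platform domains. These are synthetic
#' constructs, not the database accessions.
#'
#' @return Named list of amino-acid strings: `rts88_v_gamma`,
#'   `sc19_v_delta`, `cd1d_g_alpha1`, `cd1d_g_alpha2`.
#' @export
synthetic_hallmark_domains <- function() {
  rts88 <- gen_domain_sequence(
    "V-GAMMA", cdr_lengths = c(6L, 8L, 15L),
    plant = c("37" = "N", "38" = "Y", "40" = "H", "42" = "Y", "44" = "F",
              "52" = "R", "55" = "Y", "57" = "D", "64" = "K",
              "111.1" = "Y", "112" = "S", "114" = "W", "115" = "R",
              "116" = "K"),
    n_mutations = 4, seed = 88)
  sc19 <- gen_domain_sequence(
    "V-DELTA", cdr_lengths = c(7L, 3L, 37L),
    plant = c("29" = "W", "30" = "S", "52" = "F", "55" = "R", "103" = "F",
              "107" = "D", "109" = "R", "111.2" = "Y", "111.4" = "R",
              "111.5" = "W", "111.7" = "R", "111.9" = "D", "111.10" = "W",
              "112" = "R", "112.6" = "W"),
    n_mutations = 4, seed = 19)
  a1 <- gen_domain_sequence(
    "G-ALPHA1-LIKE",
    plant = c("43" = "D", "55" = "F", "61" = "E", "62" = "N", "65" = "H"),
    n_mutations = 6, seed = 11)
  a2 <- gen_domain_sequence(
    "G-ALPHA2-LIKE", plant = c("65" = "E", "69" = "W"),
    insert_after = c("72" = "S"), n_mutations = 6, seed = 12)
  list(rts88_v_gamma = a_seq(rts88), sc19_v_delta = a_seq(sc19),
       cd1d_g_alpha1 = a_seq(a1), cd1d_g_alpha2 = a_seq(a2))
}

a_seq <- function(x) x$sequence

#' Synthetic SC19-like rearranged clone
#'
#' A deterministic synthetic TRD clone whose CDR3-IMGT junction is 37
#' codons long and uses the shipped TRDD1, TRDD2, TRDD4 and TRDD5 segments
#' in that order, mirroring the published gene composition of the long-CDR3
#' spleen clone.
#'
#' @return List `clone` (one-row tibble) and `truth` (TruthRecord), as
#'   from [gen_rearrangement()].
#' @export
synthetic_sc19_clone <- function() {
  germ <- germline_segments()
  gen_rearrangement(
    v_ref = germ[germ$gene_name == "TRDV1", ],
    j_ref = germ[germ$gene_name == "TRDJ4", ],
    d_refs = germ[germ$segment_type == "D", ],
    d_genes = c("TRDD1", "TRDD2", "TRDD4", "TRDD5"),
    target_length_aa = 37L, mutation_rate = 0,
    tissue = "spleen", name = "SC19-like", seed = 1937)
}

#' Shipped Table-style interface contact fixtures
#'
#' Paths to the two contact tables shipped with the package, transcribing
#' the published interface interaction tables: `"AB"` for the
#' V-gamma/V-delta interface (18 interactions) and `"B"` for the
#' (TRG_TRD)/CD1D interface (14 interactions). Interaction types were
#' reconstructed from the printed per-type counts and named examples;
#' distances are nominal within-window values (the source prints none) and
#' are marked synthetic.
#'
#' @param which `"A"` (V-gamma vs V-delta) or `"B"` (vs CD1D).
#' @return File path to the TSV, readable with [read_contact_table()].
#' @export
contact_fixture_path <- function(which = c("A", "B")) {
  which <- match.arg(which)
  fname <- c(A = "interface_vgamma_vdelta_synthetic.tsv",
             B = "interface_trgd_cd1d_synthetic.tsv")[[which]]
  system.file("extdata", fname, package = "gdtr", mustWork = TRUE)
}
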