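# Synthetic reference scaffolds shipped with the package.
#
# Real germline/structure references (camel germline V/D/J segments, the
# human TRG_TRD/CD1D/B2M crystal chains) are not redistributable here, so the
# package ships synthetic stand-ins: full-length V-domain scaffolds carrying
# the conserved IMGT anchors (1st-CYS 23, CONSERVED-TRP 41, 2nd-CYS 104,
# J-PHE/J-TRP 118 with the F/W-G-X-G J-MOTIF) at canonical spacings, G-domain
# scaffolds with the 4-strand + helix layout (positions 1-49 strand,
# 50-92 helix), and short D/J nucleotide segments. The same strings are
# written to inst/extdata as FASTA.

V_SCAFFOLD <- list(
  "V-GAMMA" = list(
    fr1  = "SSNLEGGTKSVTRPTGSSAVITCDLS",
    cdr1 = "TSGDVGSSNYIQ",
    fr2  = "LHWYQQFPGKRAELLIY",
    cdr2 = "DVSKRPSGVP",
    fr3  = "NRFSGSKSGNTASLTISGLQAEDEADYFSASSELTAYYC",
    cdr3 = "ALWEAQQLGKKIE",
    fr4  = "FGSGTKLIVTP"
  ),
  "V-DELTA" = list(
    fr1  = "AQKVTQAQSSVSMPVRKAVTLNCLYE",
    cdr1 = "DRGSTYWYSSGV",
    fr2  = "LFWYVQYPNQGLQLLLK",
    cdr2 = "SEATKQGSGV",
    fr3  = "PDGYNVSRSNTEDFPLRLELASPSQTSVYLTADSATYFC",
    cdr3 = "ALGERDKLTSQMV",
    fr4  = "WGTGTKLVFGE"
  )
)

G_SCAFFOLD <- list(
  "G-ALPHA1-LIKE" = paste0(
    "AEVPQRLFPLRCLQISSFANSSWTRTDGLAWLGELQTHSWSNDSDTVRS",  # strands 1-49
    "LRSLLFGPYLQENQRHLAMDRMTQAELDIQELMKRYNHTEAFS"          # helix 50-92
  ),
  "G-ALPHA2-LIKE" = paste0(
    "TELHVSWTAADMAAITFQLKDASVMESQAWLQDLQDHQWDTVLDHISGF",
    "VSFQAYTELDQAFRIELRDWAKTGIAELQRRYELGPAGLQRLA"
  )
)

#' Shipped synthetic reference domains
#'
#' `ref_v_scaffold()` returns the full-length synthetic V-domain scaffold
#' (128 positions: FR1 26, CDR1 12, FR2 17, CDR2 10, FR3 39, CDR3 13,
#' FR4 11) for the requested kind; `ref_g_scaffold()` the 92-position
#' G-domain scaffold. These anchor-bearing scaffolds seed anchor detection in
#' [assign_v_numbering()] and serve as the reference profile for
#' [assign_g_numbering()].
#'
#' @param kind Domain kind.
#' @return A single amino-acid string (with segment attributes for V).
#' @export
ref_v_scaffold <- function(kind = c("V-GAMMA", "V-DELTA")) {
  kind <- match.arg(kind)
  seg <- V_SCAFFOLD[[kind]]
  structure(paste(unlist(seg), collapse = ""), segments = seg, kind = kind)
}

#' @rdname ref_v_scaffold
#' @export
ref_g_scaffold <- function(kind = c("G-ALPHA1-LIKE", "G-ALPHA2-LIKE")) {
  kind <- match.arg(kind)
  structure(G_SCAFFOLD[[kind]], kind = kind)
}

# Synthetic germline segments for junction work. D segments kept short
# (<= 16 nt); J segments carry the F/W-G-X-G J-MOTIF. The V segment ends
# with the 2nd-CYS codon plus a short 3'V contribution into CDR3.

# D segments avoid the 3-mers TAA/TAG/TGA (stops) and TGT/TGC (Cys) in every
# phase, so a rearranged junction can only break frame or fake an anchor
# through its random P/N nucleotides, keeping generator retries cheap.
GERMLINE_NT <- tibble::tribble(
  ~gene_name, ~segment_type, ~nt_seq,
  "TRDV1", "V", paste0(
    # FR3 tail ... 2nd-CYS (TGT) + 3'V-REGION contribution "GCC CTG GGG GAA"
    "ACAGCGGACTCAGCCACCTACTTCTGT", "GCCCTGGGGGAA"),
  "TRDD1", "D", "GAAATACGGGAC",
  "TRDD2", "D", "CCTTCCTACGGGAC",
  "TRDD3", "D", "ACTGGGGGATACG",
  "TRDD4", "D", "CTGGGGGATACGCCCAGG",
  "TRDD5", "D", "GGGATACGGAGGACCCAGGAAC",
  "TRDD6", "D", "CCGGAGGATACAAC",
  "TRDJ4", "J", paste0(
    # 5'J-REGION contribution "ACC GAC AAG CTC ATC" then J-PHE codon + FR4
    "ACCGACAAGCTCATC", "TTTGGAAGCGGGACAAAACTCATCGTA")
)

#' Shipped synthetic germline V/D/J nucleotide segments
#'
#' A small set of synthetic germline segments (one TRDV 3' end, six TRDD
#' segments, one TRDJ) used by the rearrangement generator and the junction
#' attribution examples. Column layout: `gene_name`, `segment_type`
#' (`V`/`D`/`J`), `nt_seq`.
#'
#' @return A tibble of germline segments.
#' @export
germline_segments <- function() GERMLINE_NT
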