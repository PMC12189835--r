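#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_tile geom_col
#'   labs theme_minimal scale_fill_brewer facet_wrap geom_histogram
#' @export
ggplot2::autoplot

#' Contact-map plot of an interface contact table
#'
#' One tile per (residue a, residue b, type); residues ordered by IMGT
#' position where annotated, author number otherwise.
#'
#' @param object A `gdtr_contacts`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gdtr_contacts
#' @export
autoplot.gdtr_contacts <- function(object, ...) {
  t <- as_tibble(object)
  lab <- function(side) {
    imgt <- t[[paste0("imgt_", side)]]
    paste0(t[[paste0("aa_", side)]],
           ifelse(is.na(imgt), t[[paste0("resno_", side)]], imgt))
  }
  key <- function(side) {
    imgt <- t[[paste0("imgt_", side)]]
    ifelse(is.na(imgt), as.numeric(t[[paste0("resno_", side)]]),
           imgt_position_key(imgt))
  }
  t$res_a <- stats::reorder(lab("a"), key("a"))
  t$res_b <- stats::reorder(lab("b"), key("b"))
  g <- attr(object, "groups")
  ggplot(t, aes(x = .data$res_a, y = .data$res_b, fill = .data$kind)) +
    geom_tile(colour = "grey30") +
    scale_fill_brewer(palette = "Set2") +
    labs(x = g[1], y = g[2], fill = "interaction",
         title = "Interface contacts") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Per-term and per-residue energy plot
#'
#' @param object A `gdtr_energy`.
#' @param ... Unused.
#' @return A ggplot of term energies (kcal/mol).
#' @method autoplot gdtr_energy
#' @export
autoplot.gdtr_energy <- function(object, ...) {
  d <- tibble(term = names(object$terms), energy = as.numeric(object$terms))
  ggplot(d, aes(x = .data$term, y = .data$energy, fill = .data$term)) +
    geom_col(show.legend = FALSE) +
    labs(x = NULL, y = "energy (kcal/mol)",
         title = sprintf("Interface interaction energy: %.2f kcal/mol",
                         object$dg_interaction)) +
    theme_minimal()
}

#' CDR3 length distribution by tissue
#'
#' @param annotated Output of [extract_cdr3()].
#' @param binwidth Histogram bin width (default 2).
#' @return A ggplot.
#' @export
plot_cdr3_lengths <- function(annotated, binwidth = 2) {
  ggplot(as_tibble(annotated),
         aes(x = .data$length_aa, fill = .data$tissue)) +
    geom_histogram(binwidth = binwidth, colour = "grey20",
                   show.legend = FALSE) +
    facet_wrap(~tissue) +
    labs(x = "CDR3-IMGT length (AA)", y = "clones") +
    theme_minimal()
}
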