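#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an alignment into its aligned-pair table
#'
#' @param x A `gdtr_alignment`.
#' @param ... Unused.
#' @return Tibble of aligned pairs (`qpos`, `tpos`, `match`).
#' @method tidy gdtr_alignment
#' @export
tidy.gdtr_alignment <- function(x, ...) x$aligned_pairs

#' @rdname tidy.gdtr_alignment
#' @return `glance()`: one-row tibble with `identity_pct`, `coverage_pct`,
#'   `n_aligned`, `score`.
#' @method glance gdtr_alignment
#' @export
glance.gdtr_alignment <- function(x, ...) {
  tibble(identity_pct = x$identity_pct, coverage_pct = x$coverage_pct,
         n_aligned = nrow(x$aligned_pairs), score = x$score)
}

#' Tidy a superposition
#'
#' @param x A `gdtr_superposition`.
#' @param ... Unused.
#' @return `tidy()`: the rotation matrix as a long tibble plus the
#'   translation; `glance()`: one-row tibble with `rmsd`, `n_pairs`,
#'   `det_rotation`.
#' @method tidy gdtr_superposition
#' @export
tidy.gdtr_superposition <- function(x, ...) {
  rot <- as_tibble(expand.grid(row = 1:3, col = 1:3))
  rot$value <- as.numeric(x$rotation)
  rot$term <- paste0("R", rot$row, rot$col)
  bind_rows(select(rot, "term", "value"),
            tibble(term = paste0("t", 1:3), value = as.numeric(x$translation)))
}

#' @rdname tidy.gdtr_superposition
#' @method glance gdtr_superposition
#' @export
glance.gdtr_superposition <- function(x, ...) {
  tibble(rmsd = x$rmsd, n_pairs = x$n_pairs,
         det_rotation = det(x$rotation))
}

#' Tidy an interaction-energy report
#'
#' @param x A `gdtr_energy`.
#' @param ... Unused.
#' @return `tidy()`: the per-residue contribution table; `glance()`:
#'   one-row tibble with the total and the four term energies.
#' @method tidy gdtr_energy
#' @export
tidy.gdtr_energy <- function(x, ...) x$per_residue

#' @rdname tidy.gdtr_energy
#' @method glance gdtr_energy
#' @export
glance.gdtr_energy <- function(x, ...) {
  bind_cols(tibble(dg_interaction = x$dg_interaction),
            as_tibble(as.list(x$terms)))
}

#' Tidy a numbered domain
#'
#' @param x A `gdtr_numbering`.
#' @param ... Unused.
#' @return `tidy()`: the position table; `glance()`: one-row tibble with
#'   `domain_kind`, `n_positions` and the CDR lengths (V domains).
#' @method tidy gdtr_numbering
#' @export
tidy.gdtr_numbering <- function(x, ...) as_tibble(x)

#' @rdname tidy.gdtr_numbering
#' @method glance gdtr_numbering
#' @export
glance.gdtr_numbering <- function(x, ...) {
  cl <- attr(x, "cdr_lengths")
  out <- tibble(domain_kind = attr(x, "domain_kind"), n_positions = nrow(x))
  if (!is.null(cl))
    out <- bind_cols(out, tibble(cdr1 = cl[1], cdr2 = cl[2], cdr3 = cl[3]))
  out
}
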