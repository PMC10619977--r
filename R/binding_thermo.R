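#' Convert a binding free energy to a dissociation constant
#'
#' `K_D = c0 * exp(-dG / RT)` with the standard state `c0 = 1 M` and the
#' unbinding free energy `dG` in kJ/mol (positive for favourable binding,
#' i.e. the work of removing the ligand). Returned in micromolar.
#'
#' @param dG_kJmol Unbinding free energy, kJ/mol.
#' @param temperature Temperature, K (default 300).
#' @param c0_M Standard-state concentration, M (default 1).
#' @return K_D in uM.
#' @examples
#' deltaG_to_kd(36.3) # ~0.48 uM
#' @export
deltaG_to_kd <- function(dG_kJmol, temperature = 300, c0_M = 1) {
  stopifnot(temperature > 0, c0_M > 0)
  c0_M * exp(-dG_kJmol / kBT(temperature)) * 1e6
}

#' Convert a dissociation constant to a binding free energy
#'
#' Exact inverse of [deltaG_to_kd()]: `dG = -RT ln(K_D / c0)`.
#'
#' @param kd_uM Dissociation constant, uM (> 0).
#' @param temperature Temperature, K.
#' @param c0_M Standard-state concentration, M.
#' @return Unbinding free energy, kJ/mol.
#' @examples
#' kd_to_deltaG(2.3) # ~32.4 kJ/mol
#' @export
kd_to_deltaG <- function(kd_uM, temperature = 300, c0_M = 1) {
  stopifnot(all(kd_uM > 0), temperature > 0, c0_M > 0)
  -kBT(temperature) * log(kd_uM * 1e-6 / c0_M)
}

#' First-order error propagation from Delta G to K_D
#'
#' `sigma_K = K_D * sigma_dG / RT`, the linearisation of the exponential
#' conversion; accurate to a couple of percent for `sigma_dG` up to about
#' 0.2 RT.
#'
#' @param kd_uM Dissociation constant, uM.
#' @param sigma_dG Standard error of Delta G, kJ/mol (>= 0).
#' @param temperature Temperature, K.
#' @return Standard error of K_D, uM.
#' @export
propagate_kd_error <- function(kd_uM, sigma_dG, temperature = 300) {
  stopifnot(all(sigma_dG >= 0), temperature > 0)
  kd_uM * sigma_dG / kBT(temperature)
}

#' Binding entry for a competition table
#'
#' @param label Model / condition name.
#' @param dG_kJmol Unbinding free energy, kJ/mol; `NA` to derive from K_D.
#' @param sigma_dG Its standard error (NA if unknown).
#' @param kd_uM Dissociation constant, uM; computed from dG when missing.
#' @param provenance `"computed"` or `"experimental"`.
#' @param temperature Temperature, K.
#' @return One-row data frame with consistent dG and K_D columns.
#' @export
binding_entry <- function(label, dG_kJmol = NA, sigma_dG = NA, kd_uM = NA,
                          provenance = c("computed", "experimental"),
                          temperature = 300) {
  provenance <- match.arg(provenance)
  if (is.na(dG_kJmol) && is.na(kd_uM))
    stop("either dG or K_D must be given")
  if (is.na(dG_kJmol)) dG_kJmol <- kd_to_deltaG(kd_uM, temperature)
  if (is.na(kd_uM)) kd_uM <- deltaG_to_kd(dG_kJmol, temperature)
  sigma_kd <- if (is.na(sigma_dG)) NA_real_ else
    propagate_kd_error(kd_uM, sigma_dG, temperature)
  data.frame(label = label, dG_kJmol = dG_kJmol, dG_err = sigma_dG,
             Kd_uM = kd_uM, Kd_err = sigma_kd, provenance = provenance)
}

#' Ligand competition table with pairwise Delta Delta G
#'
#' Collates binding entries (protein conformations vs membrane) into the
#' competition report: each entry's Delta G and K_D, plus the antisymmetric
#' pairwise `ddG[x, y] = dG[x] - dG[y]` matrix and the column of differences
#' against a chosen reference (negative = unbinding from x is cheaper than
#' from the reference).
#'
#' @param entries Data frame of [binding_entry()] rows (>= 2, unique labels).
#' @param reference Reference label (default `"Membrane"` when present,
#'   otherwise the first entry).
#' @return An object of class `CompetitionReport`: list with `table` (the
#'   entries plus `ddG_vs_ref`), `ddG_matrix`, `reference`.
#' @export
competition_table <- function(entries, reference = NULL) {
  stopifnot(is.data.frame(entries), nrow(entries) >= 2)
  if (anyDuplicated(entries$label))
    stop("duplicate labels: ",
         paste(unique(entries$label[duplicated(entries$label)]), collapse = ", "))
  if (is.null(reference))
    reference <- if ("Membrane" %in% entries$label) "Membrane"
                 else entries$label[1]
  if (!reference %in% entries$label) stop("reference label not found")
  dd <- outer(entries$dG_kJmol, entries$dG_kJmol, "-")
  dimnames(dd) <- list(entries$label, entries$label)
  tab <- entries
  tab$ddG_vs_ref <- entries$dG_kJmol -
    entries$dG_kJmol[entries$label == reference]
  structure(list(table = tab, ddG_matrix = dd, reference = reference),
            class = "CompetitionReport")
}

#' @export
print.CompetitionReport <- function(x, ...) {
  cat(sprintf("CompetitionReport (reference: %s)\n", x$reference))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Write / read a competition table as TSV
#' @param report A `CompetitionReport`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_competition_tsv <- function(report, path) {
  utils::write.table(report$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
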