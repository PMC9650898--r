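#' Scaffold generation settings
#'
#' Bundles the six options steering scaffold extraction and dissection.
#' Defaults: `SCAFFOLD` mode (rings, linkers, and atoms attached to them by
#' non-single bonds), aromaticity perception enabled with the `"hueckel"`
#' model, double-bond repair applied to non-aromatic systems too
#' (`retain_only_hybridisations_at_aromatic_bonds = FALSE`), prioritisation
#' rule 7 active, and unique aromatic SMILES without stereo or isotopes as
#' the matching key. Disabling `determine_aromaticity` automatically
#' excludes rule 7, since it requires aromaticity perception of candidate
#' parents.
#'
#' @param scaffold_mode one of `"SCAFFOLD"`, `"MURCKO_FRAMEWORK"`,
#'   `"BASIC_WIREFRAME"`, `"BASIC_FRAMEWORK"`, `"ELEMENTAL_WIREFRAME"`.
#' @param determine_aromaticity perceive aromaticity on input molecules,
#'   primary scaffolds and generated parent scaffolds.
#' @param aromaticity_model an [aromaticity_model()].
#' @param retain_only_hybridisations_at_aromatic_bonds when `TRUE`, the
#'   double-bond repair of formerly ring-shared single bonds is applied only
#'   when the removed ring was aromatic.
#' @param rule_seven_applied apply prioritisation rule 7 (a fully aromatic
#'   ring system must not be dissected so that the result is no longer
#'   aromatic).
#' @param smiles_flavor a [smiles_flavor()] used for all scaffold keys and
#'   origin SMILES.
#' @return A list of class `scaffold_settings`.
#' @examples
#' scaffold_settings(scaffold_mode = "MURCKO_FRAMEWORK")
#' @export
scaffold_settings <- function(scaffold_mode = c("SCAFFOLD",
                                                "MURCKO_FRAMEWORK",
                                                "BASIC_WIREFRAME",
                                                "BASIC_FRAMEWORK",
                                                "ELEMENTAL_WIREFRAME"),
                              determine_aromaticity = TRUE,
                              aromaticity_model = hueckel_model(),
                              retain_only_hybridisations_at_aromatic_bonds = FALSE,
                              rule_seven_applied = TRUE,
                              smiles_flavor = default_smiles_flavor()) {
  scaffold_mode <- match.arg(scaffold_mode)
  stopifnot(inherits(aromaticity_model, "aromaticity_model"),
            inherits(smiles_flavor, "smiles_flavor"))
  structure(list(
    scaffold_mode = scaffold_mode,
    determine_aromaticity = isTRUE(determine_aromaticity),
    aromaticity_model = aromaticity_model,
    retain_only_hybridisations_at_aromatic_bonds =
      isTRUE(retain_only_hybridisations_at_aromatic_bonds),
    rule_seven_applied = isTRUE(rule_seven_applied),
    smiles_flavor = smiles_flavor
  ), class = "scaffold_settings")
}

#' @export
print.scaffold_settings <- function(x, ...) {
  cat("<scaffold_settings>\n")
  cat("  scaffold_mode:        ", x$scaffold_mode, "\n")
  cat("  determine_aromaticity:", x$determine_aromaticity, "\n")
  cat("  aromaticity_model:    ", x$aromaticity_model$name, "\n")
  cat("  retain_only_hybridisations_at_aromatic_bonds:",
      x$retain_only_hybridisations_at_aromatic_bonds, "\n")
  cat("  rule_seven_applied:   ", rule7_effective(x), "\n")
  cat("  smiles_flavor:        ",
      paste0("unique=", x$smiles_flavor$unique,
             " aromatic=", x$smiles_flavor$aromatic_symbols,
             " stereo=", x$smiles_flavor$include_stereo,
             " isotopes=", x$smiles_flavor$include_isotopes), "\n")
  invisible(x)
}

# rule 7 is automatically excluded when aromaticity perception is off
rule7_effective <- function(settings) {
  settings$rule_seven_applied && settings$determine_aromaticity
}

# perceive aromaticity if the settings ask for it
maybe_perceive <- function(m, settings) {
  if (settings$determine_aromaticity) {
    perceive_aromaticity(m, settings$aromaticity_model)
  } else {
    m
  }
}
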