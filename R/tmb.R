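#' Targeted-microbubble shell ligand budget
#'
#' Inputs of the order-of-magnitude ligand arithmetic for an
#' antibody-conjugated (targeted) microbubble: lipid packing on the
#' shell, biotinylated-lipid fraction, and the biotin-streptavidin and
#' streptavidin-antibody stoichiometries. Defaults describe a 1.5 um
#' DSPC-shelled bubble with 5 mol% biotinylated lipid, 1:1
#' biotin:streptavidin conjugation and 2 antibodies per streptavidin.
#'
#' @param diameter Bubble diameter, m.
#' @param headgroup_area Area per lipid headgroup, m^2 (default 0.6 nm^2,
#'   the DSPC value).
#' @param biotin_mole_fraction Mole fraction of biotinylated lipid in
#'   `[0, 1]`.
#' @param streptavidin_per_biotin Streptavidin bound per biotin lipid.
#' @param antibody_per_streptavidin Antibodies bound per streptavidin.
#' @return An object of class `shell_budget`.
#' @export
shell_budget <- function(diameter = 1.5e-6,
                         headgroup_area = 0.6e-18,
                         biotin_mole_fraction = 0.05,
                         streptavidin_per_biotin = 1,
                         antibody_per_streptavidin = 2) {
  stopifnot(diameter > 0, headgroup_area > 0,
            biotin_mole_fraction >= 0, biotin_mole_fraction <= 1,
            streptavidin_per_biotin >= 0, antibody_per_streptavidin >= 0)
  structure(list(diameter = diameter,
                 headgroup_area = headgroup_area,
                 biotin_mole_fraction = biotin_mole_fraction,
                 streptavidin_per_biotin = streptavidin_per_biotin,
                 antibody_per_streptavidin = antibody_per_streptavidin),
            class = "shell_budget")
}

#' Lipid molecules per microbubble shell
#'
#' Shell area divided by the lipid headgroup area, using the `pi * d^2`
#' (equivalently `4 pi r^2`) spherical-surface convention. For the
#' defaults (1.5 um diameter, 0.6 nm^2 headgroup) the exact value is
#' 1.178e7; in rounded mode it is reported to one significant figure
#' (1e7), matching the usual order-of-magnitude bookkeeping for these
#' estimates.
#'
#' @param budget A [shell_budget()].
#' @param rounded Logical; round to one significant figure.
#' @return Lipid count (a real number; these are order-of-magnitude
#'   estimates, not integers).
#' @export
lipids_per_shell <- function(budget, rounded = FALSE) {
  stopifnot(inherits(budget, "shell_budget"))
  n <- pi * budget$diameter^2 / budget$headgroup_area
  if (rounded) signif(n, 1) else n
}

#' Ligand counts per targeted microbubble
#'
#' Chains the budget arithmetic: biotin lipids are the biotin mole
#' fraction of all shell lipids, streptavidin binds 1:1 to biotin (by
#' default), and two antibodies bind per streptavidin. In rounded
#' ("order-of-magnitude") mode every intermediate is rounded to one
#' significant figure before the next step, reproducing the conventional
#' chain 1e7 lipids -> 5e5 biotin -> 5e5 streptavidin -> 10e5
#' antibodies; exact mode keeps full precision (default).
#'
#' @param budget A [shell_budget()].
#' @param rounded Logical; apply one-significant-figure rounding at each
#'   step of the chain.
#' @return An object of class `ligand_counts`: list with `lipids`,
#'   `biotin_lipids`, `streptavidin`, `antibodies` and the `rounded`
#'   flag.
#' @export
ligand_counts <- function(budget, rounded = FALSE) {
  stopifnot(inherits(budget, "shell_budget"))
  step <- if (rounded) function(x) signif(x, 1) else identity
  lipids <- step(pi * budget$diameter^2 / budget$headgroup_area)
  biotin <- step(budget$biotin_mole_fraction * lipids)
  strep <- step(budget$streptavidin_per_biotin * biotin)
  ab <- step(budget$antibody_per_streptavidin * strep)
  structure(list(lipids = lipids, biotin_lipids = biotin,
                 streptavidin = strep, antibodies = ab,
                 rounded = rounded),
            class = "ligand_counts")
}

#' @export
print.ligand_counts <- function(x, ...) {
  cat(sprintf("Ligand counts per microbubble (%s mode)\n",
              if (x$rounded) "rounded" else "exact"))
  cat(sprintf("  lipids:       %.4g\n", x$lipids))
  cat(sprintf("  biotin lipid: %.4g\n", x$biotin_lipids))
  cat(sprintf("  streptavidin: %.4g\n", x$streptavidin))
  cat(sprintf("  antibodies:   %.4g\n", x$antibodies))
  invisible(x)
}

#' Effective microbubble binding rate
#'
#' Percentage of offered targeted microbubbles that end up bound per
#' cell: `100 * bound / offered`. With 19.4 bubbles bound per cell out
#' of 50 offered this is 38.8%.
#'
#' @param bound_per_cell Microbubbles bound per cell (>= 0).
#' @param offered_per_cell Microbubbles offered per cell (> 0).
#' @return Binding rate in percent.
#' @export
effective_binding_rate <- function(bound_per_cell, offered_per_cell) {
  stopifnot(offered_per_cell > 0, bound_per_cell >= 0)
  if (any(bound_per_cell > offered_per_cell))
    stop("bound_per_cell cannot exceed offered_per_cell")
  100 * bound_per_cell / offered_per_cell
}
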