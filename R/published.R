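## Published reference values for the alpha-1A adrenoceptor complexes.

#' Published per-residue interaction energies for the alpha-1A adrenoceptor
#'
#' Reference table of per-residue MFCC interaction energies (DFT
#' B97D/6-311+G(d,p), CPCM, epsilon = 40; kcal/mol) reported for the
#' cryo-EM complexes of the alpha-1A adrenoceptor with noradrenaline,
#' oxymetazoline and tamsulosin, together with the ligand region each
#' residue contacts.  Regions are chemical moieties of each ligand:
#' noradrenaline i = catechol ring, ii = beta-hydroxyethylamine;
#' oxymetazoline i = imidazoline, ii = dimethylphenol/methylene, iii =
#' tert-butyl; tamsulosin i = ethoxyphenoxy, ii = ethylaminopropyl, iii =
#' methoxybenzenesulfonamide.  These published values are inputs for
#' regional energy aggregation ([aggregate_regional_energies()]); the
#' package does not recompute them (that requires the external DFT
#' campaign on the deposited structures).
#'
#' @param complex One of `"noradrenaline"`, `"oxymetazoline"`,
#'   `"tamsulosin"`, or `"all"` (default).
#' @return Data.frame with columns `complex`, `residue`, `resno`, `energy`
#'   (kcal/mol) and `region`.
#' @export
#' @examples
#' nora <- alpha1a_published_rankings("noradrenaline")
#' aggregate_regional_energies(nora)
alpha1a_published_rankings <- function(complex = c("all", "noradrenaline",
                                                   "oxymetazoline",
                                                   "tamsulosin")) {
  complex <- match.arg(complex)
  tab <- function(cx, residue, energy, region) {
    data.frame(complex = cx, residue = residue,
               resno = as.integer(sub("^[A-Z]+", "", residue)),
               energy = energy, region = region, stringsAsFactors = FALSE)
  }
  nora <- tab("noradrenaline",
              c("ASP106", "VAL107", "PHE288", "PHE312", "PHE289", "CYS110",
                "TYR316", "ILE178", "SER188", "TRP285", "MET292"),
              c(-8.32, -4.50, -3.36, -3.19, -1.89, -1.58,
                -1.57, -1.27, -0.84, -0.82, 1.40),
              c("ii", "i", "ii", "ii", "i", "i",
                "ii", "i", "i", "ii", "i"))
  oxy <- tab("oxymetazoline",
             c("PHE288", "ASP106", "PHE312", "VAL107", "TRP285", "MET292",
               "TYR184", "PHE289", "CYS110", "TYR316", "ILE178", "VAL185",
               "SER188", "GLU180", "ALA189"),
             c(-7.83, -6.88, -5.93, -4.68, -3.93, -3.08,
               -2.77, -2.54, -2.51, -2.33, -1.99, -1.75,
               -1.39, -1.37, -1.33),
             c("i", "i", "i", "ii", "i", "iii",
               "iii", "ii", "ii", "i", "ii", "iii",
               "iii", "iii", "iii"))
  tam <- tab("tamsulosin",
             c("ASP106", "PHE312", "VAL107", "ILE178", "PHE86", "TYR184",
               "PHE288", "TRP102", "TYR316", "SER83", "MET292", "LYS309",
               "GLU87", "SER188", "CYS110", "PHE308", "PHE289", "CYS176"),
             c(-14.59, -5.08, -4.65, -3.65, -3.39, -3.03,
               -2.78, -2.13, -1.83, -1.54, -1.58, -1.48,
               -1.43, -1.41, -1.38, -1.35, -1.05, -0.75),
             c("ii", "iii", "i", "ii", "iii", "i",
               "i", "iii", "i", "iii", "i", "iii",
               "iii", "i", "i", "ii", "i", "iii"))
  out <- rbind(nora, oxy, tam)
  if (complex != "all") out <- out[out$complex == complex, , drop = FALSE]
  rownames(out) <- NULL
  out
}
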