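#' Read an atomic parameter table
#'
#' Parameter tables supply the per-atom partial charges and Lennard-Jones
#' parameters consumed by the classical energy backend.  The format is CSV
#' with columns `residue` (3-letter residue or ligand code), `atom` (atom
#' name), `charge` (elementary charge units), `epsilon` (LJ well depth,
#' kcal/mol) and `rmin_half` (half the LJ minimum distance, Angstrom).
#'
#' @param path Path to a CSV file in the format above.
#' @return A data.frame with the five columns, checked for completeness.
#' @seealso [default_parameter_table()], [assign_parameters()]
#' @export
read_parameter_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("residue", "atom", "charge", "epsilon", "rmin_half")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("parameter table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  if (anyNA(tab[required])) stop("parameter table contains missing values")
  if (any(tab$epsilon < 0)) stop("LJ epsilon must be non-negative")
  if (any(tab$rmin_half <= 0)) stop("LJ rmin_half must be positive")
  if (anyDuplicated(tab[c("residue", "atom")])) {
    stop("duplicate (residue, atom) entries in parameter table")
  }
  tab[required]
}

#' Built-in default parameter table
#'
#' A simplified additive force-field charge/LJ set shipped with the package,
#' covering the residue types emitted by [generate_toy_complex()] (GLY, ALA,
#' SER, VAL, CYS, ASP, LYS, PHE) and the synthetic ligand `AMX`.  Charges are
#' CHARMM-style group charges that sum exactly to each residue's formal
#' charge (ASP -1, LYS +1, AMX +1, others 0).  Parameters for real ligands
#' are user-supplied through the same CSV format.
#'
#' @return A parameter table data.frame (see [read_parameter_table()]).
#' @export
#' @examples
#' tab <- default_parameter_table()
#' sum(tab$charge[tab$residue == "ASP"])  # -1
default_parameter_table <- function() {
  path <- system.file("extdata", "params_default.csv", package = "mfccr",
                      mustWork = TRUE)
  read_parameter_table(path)
}

# template atom names for one residue type, or NULL if unknown
.template_atoms <- function(table, resname) {
  atoms <- table$atom[table$residue == resname]
  if (length(atoms) == 0) NULL else atoms
}

# formal charge of a residue template: its charge sum, which must be integral
.template_formal_charge <- function(table, resname, tol = 1e-6) {
  q <- sum(table$charge[table$residue == resname])
  fq <- round(q)
  if (abs(q - fq) > tol) {
    stop("template charge sum for ", resname, " (", q, ") is not integral")
  }
  as.integer(fq)
}
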