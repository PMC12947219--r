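## Report writers: per-residue table, sweep curve, regional summary,
## run manifest.  Machine outputs carry full precision (17 significant
## digits, so re-reading reproduces the in-memory values exactly); only the
## human-readable table rounds to 2 decimals.

# format numeric columns so CSV round-trips are exact
.full_precision <- function(df) {
  for (nm in names(df)) {
    if (is.numeric(df[[nm]]) && !is.integer(df[[nm]])) {
      df[[nm]] <- sprintf("%.17g", df[[nm]])
    }
  }
  df
}

#' Run manifest
#'
#' Captures everything needed to re-run a sweep bit-identically with the
#' classical backend: structure source, ligand code, backend and level,
#' dielectric, cap scheme, radius schedule and package version.
#'
#' @param model A `structure_model`.
#' @param backend An energy backend.
#' @param scheme A [cap_scheme()].
#' @param r_max,step Radius schedule parameters.
#' @param seed Optional generator seed for synthetic inputs.
#' @return A `run_manifest` list.
#' @export
run_manifest <- function(model, backend, scheme, r_max, step, seed = NULL) {
  structure(list(
    structure_source = model$source,
    ligand_code = model$ligand$code,
    backend = backend$name,
    level = backend$level,
    epsilon = backend$epsilon,
    cap_scheme = unclass(scheme),
    r_max = r_max, step = step,
    seed = seed,
    package_version = as.character(utils::packageVersion("mfccr")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "run_manifest")
}

#' Write sweep reports to disk
#'
#' Writes the ranked per-residue CSV, the sweep (radius, n_residues,
#' cumulative energy) CSV, the regional summary CSV when available, and a
#' JSON run manifest.
#'
#' @param sweep A `radius_sweep` result.
#' @param dir Output directory (created if needed).
#' @param regional Optional regional summary data.frame
#'   (from [aggregate_regional_energies()]).
#' @param manifest Optional [run_manifest()].
#' @param prefix File-name prefix (default `"mfcc"`).
#' @return Named character vector of the files written, invisibly.
#' @export
write_reports <- function(sweep, dir, regional = NULL, manifest = NULL,
                          prefix = "mfcc") {
  stopifnot(inherits(sweep, "radius_sweep"))
  ok <- dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory ", dir)
  paths <- c()
  f <- function(name) file.path(dir, paste0(prefix, "_", name))

  ranked <- rank_residues(sweep$records)
  utils::write.csv(.full_precision(ranked), f("residues.csv"),
                   row.names = FALSE, quote = FALSE)
  paths["residues"] <- f("residues.csv")

  sweep_df <- data.frame(radius = sweep$radii,
                         n_residues = sweep$n_residues,
                         cumulative_energy = sweep$cumulative_energy)
  utils::write.csv(.full_precision(sweep_df), f("sweep.csv"),
                   row.names = FALSE, quote = FALSE)
  paths["sweep"] <- f("sweep.csv")

  if (!is.null(regional)) {
    utils::write.csv(.full_precision(regional), f("regional.csv"),
                     row.names = FALSE, quote = FALSE)
    paths["regional"] <- f("regional.csv")
  }
  if (!is.null(manifest)) {
    jsonlite::write_json(unclass(manifest), f("manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    paths["manifest"] <- f("manifest.json")
  }
  invisible(paths)
}

#' Human-readable residue table
#'
#' Per-residue panel in ranked order with energies and distances rounded to
#' 2 decimals, matching the conventional printing of MFCC energy tables.
#'
#' @param records Per-residue records (or a `radius_sweep`).
#' @return A data.frame for display.
#' @export
format_residue_table <- function(records) {
  ranked <- rank_residues(records)
  keep <- intersect(c("rank", "label", "residue", "energy", "min_distance",
                      "closest_ligand_atom", "region"), names(ranked))
  out <- ranked[keep]
  for (nm in intersect(c("energy", "min_distance"), names(out))) {
    out[[nm]] <- round(out[[nm]], 2)
  }
  out
}

#' Convergence curve plot
#'
#' Cumulative total interaction energy against the pocket radius, with the
#' convergence radius marked.  Requires ggplot2.
#'
#' @param sweep A `radius_sweep` result.
#' @return A ggplot object.
#' @export
plot_convergence <- function(sweep) {
  stopifnot(inherits(sweep, "radius_sweep"))
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  df <- data.frame(radius = sweep$radii, energy = sweep$cumulative_energy)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$radius, y = .data$energy)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "pocket radius r (Å)",
                  y = "total interaction energy (kcal/mol)")
  if (!is.na(sweep$convergence_radius)) {
    p <- p + ggplot2::geom_vline(xintercept = sweep$convergence_radius,
                                 linetype = "dashed")
  }
  p
}
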