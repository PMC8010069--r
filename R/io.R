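# Plain-text I/O: dense / sparse-triplet Hi-C matrices, profiles, fit
# results (TSV + JSON sidecar), ensemble export, BED6 gene tables, run
# configurations (YAML/JSON).

#' Read a contact map from text
#'
#' Dense whitespace/TSV square matrices or 3-column sparse triplet files
#' (`bin_i bin_j score`, 1-based, any triangle; mirrored on load).
#' Symmetry is checked on load (`sym_tol`), NA scores are masked.
#'
#' @param path input file.
#' @param dialect `"auto"`, `"dense"` or `"triplet"`.
#' @param kind stored map kind.
#' @param sym_tol largest tolerated relative asymmetry.
#' @return a [contact_map()].
#' @export
read_contact_map <- function(path, dialect = c("auto", "dense", "triplet"),
                             kind = "normalized_experimental", sym_tol = 1e-6) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = FALSE)
  if (dialect == "auto")
    dialect <- if (ncol(tab) == 3 && nrow(tab) != 3) "triplet" else "dense"
  if (dialect == "dense") {
    m <- as.matrix(tab)
    if (nrow(m) != ncol(m)) stop("dense contact matrix must be square")
    dimnames(m) <- NULL
  } else {
    ij <- c(tab[[1]], tab[[2]])
    if (any(ij != round(ij)) || any(ij < 1))
      stop("triplet dialect requires positive integer bin indices (is this a malformed dense matrix?)")
    n <- max(tab[[1]], tab[[2]])
    m <- matrix(0, n, n)
    m[cbind(tab[[1]], tab[[2]])] <- tab[[3]]
    lower <- m == 0 & t(m) != 0
    m[lower] <- t(m)[lower]
  }
  contact_map(m, kind = kind, sym_tol = sym_tol)
}

#' Write a contact map as dense TSV
#'
#' Full-precision round trip with [read_contact_map()].
#'
#' @param map a [contact_map()] or matrix.
#' @param path output file.
#' @export
write_contact_map <- function(map, path) {
  m <- if (inherits(map, "contact_map")) map$scores else as.matrix(map)
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Serialize a MaxEnt fit
#'
#' Writes `<stem>_eps.tsv` (couplings; forbidden pairs as `Inf`),
#' `<stem>_history.tsv`, and `<stem>.json` (conversion factor, convergence
#' flag, seed, settings echo) — enough provenance to regenerate the fit.
#'
#' @param fit a `maxent_fit`.
#' @param stem output path stem.
#' @param config optional run-configuration list echoed into the sidecar.
#' @return invisibly, the sidecar path.
#' @export
write_fit_result <- function(fit, stem, config = NULL) {
  e <- fit$eps$eps
  e[fit$eps$infinite_mask] <- Inf
  utils::write.table(format(e, digits = 17, trim = TRUE), paste0(stem, "_eps.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(fit$history, paste0(stem, "_history.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  side <- list(c_tilde = fit$c_tilde, converged = fit$converged,
               gamma = fit$gamma, seed = fit$seed,
               n_regions = fit$eps$n_regions, config = config)
  jsonlite::write_json(side, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(paste0(stem, ".json"))
}

#' Read back a serialized coupling matrix
#'
#' @param path `_eps.tsv` file written by [write_fit_result()].
#' @return an [interaction_matrix()].
#' @export
read_interaction_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  inf <- is.infinite(m)
  m[inf] <- 0
  interaction_matrix(m, inf)
}

#' Export ensemble center positions
#'
#' Long-format TSV (`snapshot`, `region`, `x`, `y`, `z` in nm), plus an
#' XYZ-style flat text export for visualization if `xyz` is given.
#'
#' @param ens `chromo_ensemble`.
#' @param path TSV output.
#' @param xyz optional path for a plain XYZ export.
#' @export
write_ensemble <- function(ens, path, xyz = NULL) {
  S <- nrow(ens$center_sites)
  n <- ens$topo$n_regions
  xyzm <- ens$conf$sites[ens$center_sites, , drop = FALSE]
  # center_sites is S x n in column-major order
  df <- data.frame(snapshot = rep(seq_len(S), n), region = rep(seq_len(n), each = S),
                   x = xyzm[, 1], y = xyzm[, 2], z = xyzm[, 3])
  df <- df[order(df$snapshot, df$region), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(xyz)) {
    con <- file(xyz, "w")
    on.exit(close(con))
    for (s in seq_len(S)) {
      writeLines(c(as.character(n), sprintf("snapshot %d", s)), con)
      sel <- df$snapshot == s
      writeLines(sprintf("C %.3f %.3f %.3f", df$x[sel], df$y[sel], df$z[sel]), con)
    }
  }
  invisible(path)
}

#' Read a BED6 gene table
#'
#' 0-based half-open BED intervals; the strand column classifies genes as
#' forward/backward for stratified overlap tests.
#'
#' @param path BED file (3-6 columns, tab separated).
#' @return data.frame with `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @export
read_bed_genes <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  names(tab) <- cols[seq_len(min(6, ncol(tab)))]
  if (is.null(tab$name)) tab$name <- "."
  if (is.null(tab$score)) tab$score <- 0
  if (is.null(tab$strand)) tab$strand <- "*"
  tab
}

#' Read / build a run configuration
#'
#' YAML or JSON with blocks `geometry` (lattice_spacing_nm,
#' cell_diameter_nm, cell_length_nm, bin_size_bp, monomers_per_region),
#' `sampler`, `fit`, `analysis` and `seed`; missing fields fall back to the
#' defaults below. Round-trips losslessly through [write_run_config()].
#'
#' @param path YAML/JSON file, or NULL for pure defaults.
#' @return nested configuration list.
#' @export
read_run_config <- function(path = NULL) {
  defaults <- list(
    geometry = list(lattice_spacing_nm = 88, cell_diameter_nm = 630,
                    cell_length_nm = 2200, bin_size_bp = 1e4,
                    monomers_per_region = 2),
    sampler = list(n_samples = 2000, thin_sweeps = NULL, burn_in = NULL),
    fit = list(max_iter = 80, n_samples = 2000, n_samples_final = 8000,
               step0 = 0.6, tol_deviation_pct = 6.0, tol_pearson = 0.998,
               tol_residual = 1e-2, mask_band = 1, zero_policy = "exclude"),
    analysis = list(sud_radius = 2, sud_min_size = 5, info_bias = "miller_madow"),
    seed = 1)
  if (is.null(path)) return(defaults)
  user <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
          else yaml::read_yaml(path)
  utils::modifyList(defaults, user)
}

#' @rdname read_run_config
#' @param config configuration list.
#' @param path output path (`.yaml` or `.json`).
#' @export
write_run_config <- function(config, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  } else yaml::write_yaml(config, path)
  invisible(path)
}

# geometry objects from a configuration
config_geometry <- function(config, n_regions) {
  g <- config$geometry
  conf <- spherocylinder_confinement(g$lattice_spacing_nm, g$cell_diameter_nm,
                                     g$cell_length_nm)
  topo <- chain_topology(n_regions, g$monomers_per_region, g$bin_size_bp)
  list(conf = conf, topo = topo)
}
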