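#' Pipeline configuration with study defaults
#'
#' Collects every tunable parameter of the end-to-end analysis with its study
#' default: no mesh smoothing (`f_i = 0`), adjacency weight threshold
#' `z_C = 1`, local kernel width `lambda_s = 2`, no trimming / callosectomy /
#' anisotropy (`eta = kappa = rho = 0`), `K = 100` harmonics, 16 MI bins,
#' 100 surrogates over harmonics 7-11.
#'
#' @param f_i mesh smoothing iterations.
#' @param z_C adjacency weight threshold (weight-population sd units).
#' @param lambda_s local kernel width, 1 or 2.
#' @param eta,kappa,rho alteration percentages (see [trim_long_range()],
#'   [callosectomy()], [anisotropy()]).
#' @param trim_order,callosectomy_order,anisotropy_order alteration orders.
#' @param K number of harmonics.
#' @param n_bins MI bins.
#' @param n_surr,k0,n_k surrogate-test window.
#' @param zero_tol eigenvalue zero tolerance.
#' @param min_track_length_mm,extension_mm,max_gap_mm connectome build
#'   parameters (see [build_long_range()]).
#' @param seed master seed for alteration randomness.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(f_i = 0, z_C = 1, lambda_s = 2,
                            eta = 0, kappa = 0, rho = 0,
                            trim_order = "descending",
                            callosectomy_order = "random",
                            anisotropy_order = "random",
                            K = 100, n_bins = 16,
                            n_surr = 100, k0 = 7, n_k = 5,
                            zero_tol = 1e-8,
                            min_track_length_mm = 10, extension_mm = 3,
                            max_gap_mm = 5, seed = 1L) {
  check_percent(eta, "eta")
  check_percent(rho, "rho")
  if (callosectomy_order == "random") check_percent(kappa, "kappa", upper = 99)
  else check_percent(kappa, "kappa")
  if (!lambda_s %in% c(1, 2)) stop_invalid("'lambda_s' must be 1 or 2")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full connectome-harmonics pipeline on a synthetic brain
#'
#' Chains every stage: synthesize (or accept) a brain, optionally smooth the
#' mesh, build local and long-range connectivity, z-score and threshold,
#' apply the configured alterations, combine, compute the graph Laplacian and
#' its harmonics, and measure the MI of each harmonic with the planted
#' network map. Deterministic for fixed seeds. If `outdir` is given, meshes,
#' matrices, harmonics and the MI table are written there as plain-text /
#' Matrix Market files together with the resolved configuration.
#'
#' @param synth a [synth_brain_config()] or a prebuilt brain from
#'   [synthesize_brain()].
#' @param config a [pipeline_config()].
#' @param outdir optional output directory.
#' @return List with the intermediate objects (`brain`, `local`, `connectome`,
#'   `longrange`, `combined`, `basis`), the local ratio `r`, and `mi_table`
#'   (data.frame of harmonic index, eigenvalue, MI).
#' @export
run_pipeline <- function(synth = synth_brain_config(),
                         config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  brain <- if (inherits(synth, "synth_brain_config")) synthesize_brain(synth) else synth
  mesh <- brain$mesh
  if (config$f_i > 0) mesh <- smooth_mesh(mesh, config$f_i)
  local <- build_local_adjacency(mesh, config$lambda_s)
  wc <- build_long_range(brain$streamlines, mesh,
                         min_track_length_mm = config$min_track_length_mm,
                         extension_mm = config$extension_mm,
                         max_gap_mm = config$max_gap_mm)
  wc <- zscore_weights(wc)
  lr <- threshold_long_range(wc, config$z_C)
  if (config$eta > 0)
    lr <- trim_long_range(lr, wc$Lbar, config$eta, config$trim_order,
                          seed = config$seed + 11L)
  if (config$kappa > 0)
    lr <- callosectomy(lr, mesh$hemisphere, config$kappa,
                       config$callosectomy_order, Lbar = wc$Lbar,
                       seed = config$seed + 12L)
  if (config$rho > 0)
    local <- anisotropy(local, config$rho, config$anisotropy_order,
                        seed = config$seed + 13L)
  combined <- combine_connectome(local, lr)
  basis <- eigendecompose(graph_laplacian(combined),
                          K = min(config$K, mesh$m), zero_tol = config$zero_tol)
  mi <- mi_profile(basis, brain$rsn$map, ks = seq_along(basis$values),
                   n_bins = config$n_bins)
  mi_table <- data.frame(k = seq_along(basis$values), lambda = basis$values,
                         mi = as.numeric(mi))
  r <- local_ratio(local, lr)
  result <- list(brain = brain, mesh = mesh, local = local, connectome = wc,
                 longrange = lr, combined = combined, basis = basis,
                 r = r, mi_table = mi_table, config = config)
  if (!is.null(outdir)) write_pipeline_outputs(result, outdir)
  result
}

write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_mesh(result$mesh, file.path(outdir, "mesh.off"))
  write_vertex_labels(result$mesh$hemisphere, file.path(outdir, "hemisphere.txt"))
  write_vertex_labels(result$brain$parcellation$region,
                      file.path(outdir, "parcellation.txt"))
  writeLines(as.character(result$brain$rsn$map), file.path(outdir, "rsn_map.txt"))
  write_sparse_matrix(result$connectome$C, file.path(outdir, "C.mtx"))
  write_sparse_matrix(result$connectome$Lbar, file.path(outdir, "Lbar.mtx"))
  write_sparse_matrix(result$local$A, file.path(outdir, "A_local.mtx"))
  write_sparse_matrix(result$longrange$A_c, file.path(outdir, "A_longrange.mtx"))
  writeLines(formatC(result$basis$values, format = "g", digits = 17),
             file.path(outdir, "eigenvalues.txt"))
  utils::write.table(result$basis$vectors, file.path(outdir, "eigenvectors.txt"),
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(result$mi_table, file.path(outdir, "mi_table.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  cfg <- result$config
  track_counts <- result$connectome$counts
  report <- c(
    sprintf("r_local_ratio: %.6f", result$r),
    sprintf("tracks_total: %d", track_counts$total),
    sprintf("tracks_kept: %d", track_counts$kept),
    sprintf("tracks_discarded_short: %d", track_counts$discarded_short),
    sprintf("tracks_discarded_unresolved: %d", track_counts$discarded_unresolved),
    sprintf("tracks_discarded_self: %d", track_counts$discarded_self),
    vapply(names(cfg), function(nm) sprintf("config_%s: %s", nm,
                                            paste(format(cfg[[nm]]), collapse = " ")),
           character(1)))
  writeLines(report, file.path(outdir, "report.txt"))
  invisible(outdir)
}
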