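#' Write a simulated mixture to a directory of delimited-text files
#'
#' Lays out one CSV per matrix: `obs_k.csv` (observed datasets `X[k]`),
#' `mix_k.csv` (mixing matrices), `scv_r.csv` (true SCVs), plus
#' `truth.json` holding the true block counts and grouping labels and a
#' `manifest.json` describing shapes and orientation (rows = reduced
#' dimensions / SCV components, columns = samples).
#'
#' @param mixture an `scv_mixture` from [simulate_mixture()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_mixture <- function(mixture, dir) {
  stopifnot(inherits(mixture, "scv_mixture"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wm <- function(M, name) {
    write.table(M, file.path(dir, paste0(name, ".csv")), sep = ",",
                row.names = FALSE, col.names = FALSE)
  }
  for (k in seq_along(mixture$X)) wm(mixture$X[[k]], sprintf("obs_%d", k))
  for (k in seq_along(mixture$A)) wm(mixture$A[[k]], sprintf("mix_%d", k))
  for (r in seq_along(mixture$sources)) {
    wm(mixture$sources[[r]], sprintf("scv_%d", r))
  }
  if (!is.null(mixture$design)) {
    jsonlite::write_json(
      list(d = mixture$design$true_d, labels = mixture$design$true_labels),
      file.path(dir, "truth.json"), auto_unbox = FALSE
    )
  }
  jsonlite::write_json(
    list(K = length(mixture$X), R = nrow(mixture$X[[1]]),
         V = ncol(mixture$X[[1]]),
         orientation = "rows = components, columns = samples",
         files = list(observations = "obs_k.csv", mixing = "mix_k.csv",
                      scvs = "scv_r.csv")),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE
  )
  invisible(dir)
}

#' Read observed datasets from a directory written by [write_mixture()]
#'
#' @param dir directory containing `obs_1.csv .. obs_K.csv`.
#' @return list of `K` numeric matrices.
#' @export
read_observations <- function(dir) {
  files <- list.files(dir, pattern = "^obs_[0-9]+\\.csv$")
  if (length(files) == 0) stop("no obs_k.csv files found in ", dir)
  ord <- order(as.integer(sub("^obs_([0-9]+)\\.csv$", "\\1", files)))
  lapply(files[ord], function(f) {
    as.matrix(read.csv(file.path(dir, f), header = FALSE))
  })
}

#' Serialise a design to / from JSON
#'
#' Schema: `{K, V, rho, noise_sd, specs: [[block index lists]], labels}`.
#'
#' @param design an [scv_design()].
#' @param file path to the JSON file.
#' @return `write_design_json`: `file`, invisibly. `read_design_json`: an
#'   [scv_design()].
#' @export
write_design_json <- function(design, file) {
  stopifnot(inherits(design, "scv_design"))
  jsonlite::write_json(
    list(K = design$K, V = design$V, rho = design$rho,
         noise_sd = design$noise_sd,
         specs = lapply(design$specs, function(s) s$blocks),
         labels = design$true_labels),
    file, auto_unbox = TRUE
  )
  invisible(file)
}

#' @rdname write_design_json
#' @export
read_design_json <- function(file) {
  j <- jsonlite::read_json(file, simplifyVector = TRUE)
  specs <- lapply(j$specs, function(blocks) {
    if (is.matrix(blocks)) blocks <- split(blocks, row(blocks))
    block_spec(unname(lapply(blocks, as.integer)), rho = j$rho, K = j$K,
               noise_sd = j$noise_sd)
  })
  scv_design(rho = j$rho, V = j$V, noise_sd = j$noise_sd, specs = specs,
             true_labels = j$labels)
}

#' Write per-SCV bootstrap reports and the run summary
#'
#' Writes one JSON per SCV (`scv_r.json`: `d_hat`, `epsilon`, `T_hat`,
#' `threshold`, `B`, `Pfa`, `seed`), an aggregate `d_hat.csv`, the flat
#' labels and AMI in `report.json`, the linkage table as `linkage.csv`, the
#' selected IVA run's objective trajectory as `objective.csv`, and the
#' dendrogram in Newick format (`tree.nwk`).
#'
#' @param report a `run_report` from [run_pipeline()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (r in seq_along(report$counts)) {
    ct <- report$counts[[r]]
    jsonlite::write_json(
      list(scv = r, d_hat = ct$d_hat, epsilon = ct$epsilon,
           T_hat = ct$T_hat, threshold = ct$threshold, B = ct$B,
           Pfa = ct$Pfa, seed = ct$seed),
      file.path(dir, sprintf("scv_%d.json", r)), auto_unbox = TRUE,
      digits = NA
    )
  }
  write.csv(data.frame(scv = seq_along(report$d_hat), d_hat = report$d_hat),
            file.path(dir, "d_hat.csv"), row.names = FALSE)
  write.csv(as.data.frame(report$structure$merges),
            file.path(dir, "linkage.csv"), row.names = FALSE)
  traj <- report$ensemble$best$objective_trajectory
  write.csv(data.frame(iteration = seq_along(traj) - 1, objective = traj),
            file.path(dir, "objective.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(d_hat = report$d_hat, common = report$sets$common,
         structured = report$sets$structured, labels = report$labels,
         ami = report$ami, joint_isi = report$joint_isi,
         timings = as.list(report$timings)),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    null = "null"
  )
  if (requireNamespace("ape", quietly = TRUE)) {
    export_newick(report$structure, file.path(dir, "tree.nwk"))
  }
  invisible(dir)
}
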