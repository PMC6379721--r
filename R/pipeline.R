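# Pipeline driver: a validated run configuration, staged execution in
# dependency order, and a checksummed artifact manifest. Deterministic
# stages rerun bit-identically under the same config and seed.

#' Build a run configuration
#'
#' @param stages list of stages; each stage is a list with `op` (one of
#'   `"convert"`, `"ingest"`, `"synth_duplex"`, `"synth_tile"`,
#'   `"synth_bundle"`, `"synth_junction"`, `"junction"`, `"weave"`,
#'   `"corrugation"`, `"mean_structure"`, `"rmsd"`, `"helicity"`) and an
#'   optional `params` list passed to the underlying function.
#' @param out_dir output directory (created if missing).
#' @param seed integer seed forwarded to every stochastic stage.
#' @param log_level `"info"` or `"quiet"`.
#' @return A validated list of class `run_config`.
#' @export
origametry_config <- function(stages, out_dir = "origametry_out", seed = 1,
                              log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  known <- c("convert", "ingest", "synth_duplex", "synth_tile",
             "synth_bundle", "synth_junction", "junction", "weave",
             "corrugation", "mean_structure", "rmsd", "helicity")
  if (!length(stages)) stop("config has no stages")
  for (k in seq_along(stages)) {
    st <- stages[[k]]
    if (is.null(st$op) || !st$op %in% known)
      stop("stage ", k, ": unknown or missing op (known: ",
           paste(known, collapse = ", "), ")")
    if (!is.null(st$params) && !is.list(st$params))
      stop("stage ", k, ": params must be a list")
  }
  structure(list(stages = stages, out_dir = out_dir,
                 seed = as.integer(seed), log_level = log_level),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with keys `stages`, `out_dir`, `seed`,
#'   `log_level`.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  y <- yaml::read_yaml(path)
  origametry_config(stages = y$stages,
                    out_dir = if (is.null(y$out_dir)) "origametry_out"
                              else y$out_dir,
                    seed = if (is.null(y$seed)) 1 else y$seed,
                    log_level = if (is.null(y$log_level)) "info"
                                else y$log_level)
}

#' Run an analysis pipeline
#'
#' Executes the configured stages in order, carrying intermediate objects
#' (topology, trajectory, axes, ...) forward, writing every artifact under
#' `config$out_dir`, and recording an md5-checksummed manifest. The full
#' configuration is serialized into the output directory. Any stage error
#' stops execution with a nonzero status and retains the partial manifest.
#'
#' @param config a [origametry_config()] (or path to a YAML config).
#' @return A list with `status` (0 on success), `manifest` (data frame of
#'   stage, artifact path, md5) and `error` (`NULL` or the failure
#'   message), invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(unclass(config), file.path(config$out_dir, "config.yaml"))
  say <- function(...) if (config$log_level == "info")
    message("[origametry] ", ...)
  manifest <- data.frame(stage = character(0), artifact = character(0),
                         md5 = character(0))
  state <- new.env(parent = emptyenv())
  add_artifact <- function(stage, path) {
    manifest[nrow(manifest) + 1L, ] <<-
      list(stage, path, unname(tools::md5sum(path)))
  }
  out <- function(name) file.path(config$out_dir, name)
  run_stage <- function(st, k) {
    p <- if (is.null(st$params)) list() else st$params
    label <- paste0(st$op, "#", k)
    seed <- if (is.null(p$seed)) config$seed else p$seed
    say("stage ", label)
    switch(st$op,
      convert = {
        if (is.null(p$design) || !file.exists(p$design))
          stop("convert: missing design file ",
               if (is.null(p$design)) "(none given)" else p$design)
        des <- parse_cadnano(p$design,
                             lattice = if (is.null(p$lattice)) "auto"
                                       else p$lattice)
        seq <- NULL
        if (!is.null(p$sequence_fasta)) {
          lines <- readLines(p$sequence_fasta)
          seq <- strsplit(paste(lines[!startsWith(lines, ">")],
                                collapse = ""), "")[[1]]
        }
        built <- build_initial(des, scaffold_sequence = seq, seed = seed)
        fr <- built$frame
        if (is.null(p$relax) || isTRUE(p$relax))
          fr <- relax_config(fr, built$topology)
        prefix <- if (is.null(p$out_prefix)) "converted" else p$out_prefix
        write_oxdna_topology(built$topology, out(paste0(prefix, ".top")))
        write_oxdna_trajectory(oxdna_trajectory(built$topology, list(fr)),
                               out(paste0(prefix, ".conf")))
        state$topology <- built$topology
        state$trajectory <- oxdna_trajectory(built$topology, list(fr))
        state$helices <- built$helices
        add_artifact(label, out(paste0(prefix, ".top")))
        add_artifact(label, out(paste0(prefix, ".conf")))
      },
      ingest = {
        if (is.null(p$topology) || is.null(p$trajectory))
          stop("ingest: need topology and trajectory paths")
        state$topology <- read_oxdna_topology(p$topology)
        state$trajectory <- read_oxdna_trajectory(p$trajectory,
                                                  state$topology)
      },
      synth_duplex = {
        g <- do.call(make_duplex, c(list(n_bp = if (is.null(p$n_bp)) 32
                                               else p$n_bp, seed = seed),
                                    p[setdiff(names(p),
                                              c("n_bp", "seed"))]))
        state$topology <- g$topology
        state$trajectory <- oxdna_trajectory(g$topology, list(g$frame))
        write_synth(g, state$trajectory, label, out, add_artifact)
      },
      synth_tile = {
        g <- do.call(make_tile,
                     c(list(seed = seed), p[setdiff(names(p), "seed")]))
        state$topology <- g$topology
        state$trajectory <- g$trajectory
        state$helices <- g$helices
        state$crossovers <- g$crossovers
        write_synth(g, g$trajectory, label, out, add_artifact)
      },
      synth_bundle = {
        g <- do.call(make_bundle,
                     c(list(seed = seed), p[setdiff(names(p), "seed")]))
        state$topology <- g$topology
        state$trajectory <- g$trajectory
        state$helices <- g$helices
        write_synth(g, g$trajectory, label, out, add_artifact)
      },
      synth_junction = {
        g <- do.call(make_junction_ensemble,
                     c(list(seed = seed), p[setdiff(names(p), "seed")]))
        state$topology <- g$topology
        state$trajectory <- g$trajectory
        state$junction <- g$junction
        state$windows <- g$windows
        write_synth(g, g$trajectory, label, out, add_artifact)
      },
      junction = {
        need(state, "trajectory", "junction")
        tab <- junction_angle_table(state$trajectory, state$junction)
        write_angle_samples(tab, out("junction_angles.tsv"))
        add_artifact(label, out("junction_angles.tsv"))
        if (isTRUE(p$landscape)) {
          samples <- data.frame(phi = tab$phi, theta = tab$theta,
                                window_id = 1L)
          ls <- wham(samples, state$windows)
          write_landscape(ls, out("landscape.tsv"))
          add_artifact(label, out("landscape.tsv"))
        }
      },
      weave = {
        need(state, "trajectory", "helices")
        ax <- helix_axes(state$trajectory, state$helices)
        wp <- weave_profile(ax)
        write_profile(wp, out("weave_profile.tsv"))
        add_artifact(label, out("weave_profile.tsv"))
        state$axes <- ax
      },
      corrugation = {
        need(state, "trajectory", "helices", "crossovers")
        if (is.null(state$axes))
          state$axes <- helix_axes(state$trajectory, state$helices)
        cp <- corrugation_profile(state$axes, state$crossovers,
                                  max_offset = if (is.null(p$max_offset)) 8
                                               else p$max_offset)
        write_profile(cp, out("corrugation_profile.tsv"))
        add_artifact(label, out("corrugation_profile.tsv"))
      },
      mean_structure = {
        need(state, "trajectory")
        ms <- mean_structure(state$trajectory)
        write_oxdna_topology(state$topology, out("mean_structure.top"))
        write_oxdna_trajectory(oxdna_trajectory(state$topology,
                                                list(ms$frame)),
                               out("mean_structure.conf"))
        add_artifact(label, out("mean_structure.top"))
        add_artifact(label, out("mean_structure.conf"))
        state$mean_structure <- ms
      },
      rmsd = {
        need(state, "trajectory")
        if (is.null(p$reference) || !file.exists(p$reference))
          stop("rmsd: missing reference point file")
        ref <- as.matrix(utils::read.table(p$reference))
        model <- if (!is.null(state$mean_structure))
                   state$mean_structure$frame$pos
                 else state$trajectory$frames[[1]]$pos
        res <- rmsd_to_reference(model, ref)
        tab <- data.frame(rmsd = res$rmsd)
        utils::write.table(cbind(tab[rep(1, nrow(res$displacement)), ,
                                     drop = FALSE], res$displacement),
                           out("rmsd.tsv"), sep = "\t", quote = FALSE,
                           row.names = FALSE)
        add_artifact(label, out("rmsd.tsv"))
      },
      helicity = {
        need(state, "trajectory", "helices")
        ax <- helix_axes(state$trajectory, state$helices)
        rows <- lapply(seq_along(ax$points), function(h) {
          r <- helix_path_helicity(ax$points[[h]][, , 1])
          data.frame(helix = h, handedness = r$handedness,
                     period = r$period, amplitude = r$amplitude)
        })
        utils::write.table(do.call(rbind, rows), out("helicity.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        add_artifact(label, out("helicity.tsv"))
      })
  }
  err <- NULL
  for (k in seq_along(config$stages)) {
    ok <- tryCatch({ run_stage(config$stages[[k]], k); TRUE },
                   error = function(e) { err <<- conditionMessage(e); FALSE })
    if (!ok) break
  }
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       dataframe = "rows", pretty = TRUE)
  res <- list(status = if (is.null(err)) 0L else 1L, manifest = manifest,
              error = err)
  if (!is.null(err)) warning("pipeline failed: ", err)
  invisible(res)
}

need <- function(state, ...) {
  for (what in c(...))
    if (is.null(state[[what]]))
      stop("stage needs '", what, "' from an earlier stage")
}

# Shared synth-stage output: topology + trajectory + ground-truth sidecar.
write_synth <- function(g, traj, label, out, add_artifact) {
  write_oxdna_topology(g$topology, out(paste0(label, ".top")))
  write_oxdna_trajectory(traj, out(paste0(label, ".conf")))
  gt <- g$ground_truth
  gt$spec <- unclass(gt$spec)
  gt$centerlines <- NULL      # bulky; regenerable from seed
  jsonlite::write_json(gt, out(paste0(label, ".groundtruth.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  add_artifact(label, out(paste0(label, ".top")))
  add_artifact(label, out(paste0(label, ".conf")))
  add_artifact(label, out(paste0(label, ".groundtruth.json")))
}
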