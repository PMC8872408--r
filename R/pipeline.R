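PIPELINE_STAGES <- c("rmsd", "rmsf", "pucker", "hbonds", "annotate", "dccm",
                     "network", "paths", "sip")

#' Validate a pipeline run configuration
#'
#' Schema validation before any computation: unknown keys are rejected,
#' stage dependencies checked (network needs dccm, paths needs network, sip
#' needs paths), and every violation is reported at once.
#'
#' @param config list (or YAML path) with entries `seed`, `output_dir`,
#'   `systems` (each: `id`, then either `synthetic` generator parameters or
#'   `topology`/`trajectories`/`regions`), and `analyses` (stage toggles and
#'   parameter lists).
#' @return the normalized config list, invisibly; errors on violation.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  errs <- character()
  top_keys <- c("seed", "output_dir", "systems", "analyses")
  unknown <- setdiff(names(config), top_keys)
  if (length(unknown))
    errs <- c(errs, paste0("unknown top-level key(s): ",
                           paste(unknown, collapse = ", ")))
  if (is.null(config$seed) || !is.numeric(config$seed))
    errs <- c(errs, "seed: required integer")
  if (is.null(config$systems) || !length(config$systems))
    errs <- c(errs, "systems: at least one system required")
  sys_keys <- c("id", "synthetic", "topology", "trajectories", "regions",
                "ligand_codes", "window")
  for (i in seq_along(config$systems)) {
    s <- config$systems[[i]]
    unknown <- setdiff(names(s), sys_keys)
    if (length(unknown))
      errs <- c(errs, sprintf("systems[%d]: unknown key(s) %s", i,
                              paste(unknown, collapse = ", ")))
    if (is.null(s$id)) errs <- c(errs, sprintf("systems[%d]: id required", i))
    if (is.null(s$synthetic) && is.null(s$topology))
      errs <- c(errs, sprintf("systems[%d]: needs synthetic block or topology path", i))
  }
  an <- config$analyses
  unknown <- setdiff(names(an), PIPELINE_STAGES)
  if (length(unknown))
    errs <- c(errs, paste0("analyses: unknown stage(s): ",
                           paste(unknown, collapse = ", ")))
  enabled <- function(st) !is.null(an[[st]]) && !identical(an[[st]], FALSE)
  if (enabled("network") && !enabled("dccm"))
    errs <- c(errs, "analyses: network requires dccm")
  if (enabled("paths") && !enabled("network"))
    errs <- c(errs, "analyses: paths requires network")
  if (enabled("sip") && !enabled("paths"))
    errs <- c(errs, "analyses: sip requires paths")
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  invisible(config)
}

stage_params <- function(analyses, stage) {
  p <- analyses[[stage]]
  if (is.list(p)) p else list()
}

#' Assemble one configured system (model, substructure map, trajectory)
#'
#' Materializes a `systems` entry of the run configuration: either the
#' synthetic toy-aptamer generators (with a distance-decay correlation ground
#' truth over residue centres) or file input via [read_structure()] and
#' [read_trajectory()].
#'
#' @param s one entry of `config$systems`.
#' @param seed_offset added to the entry's generator seed so multi-system
#'   studies draw independent noise.
#' @return list with `model`, `map`, `traj`.
#' @export
assemble_system <- function(s, seed_offset = 0L) {
  if (!is.null(s$synthetic)) {
    g <- s$synthetic
    toy <- gen_toy_aptamer(n_residues = g$n_residues %||% 40L,
                           rng_seed = (g$rng_seed %||% 20220209L) + seed_offset,
                           ligand = g$ligand %||% "dG")
    centers <- t(vapply(seq_len(n_residues(toy$model)), function(r) {
      idx <- which(toy$model$atoms$residue_index == r)
      colMeans(toy$model$coords[idx, , drop = FALSE])
    }, numeric(3)))
    d <- as.matrix(stats::dist(centers))
    corr <- exp(-d / (g$corr_length %||% 15))
    traj <- gen_system_trajectory(
      toy$model, corr, sigma = g$sigma %||% 0.5,
      n_frames = g$n_frames %||% 150L,
      n_replicates = g$n_replicates %||% 2L,
      atom_jitter = g$atom_jitter %||% 0.05,
      rng_seed = (g$rng_seed %||% 20220209L) + seed_offset + 1L,
      system_id = s$id)
    list(model = toy$model, map = toy$map, traj = traj)
  } else {
    model <- read_structure(s$topology,
                            ligand_codes = s$ligand_codes %||% c("LIG", "DG", "RG"))
    trajs <- lapply(s$trajectories, read_trajectory, model = model)
    traj <- do.call(merge_replicates, c(trajs, list(system_id = s$id)))
    map <- if (!is.null(s$regions)) {
      regions <- lapply(s$regions, function(rr)
        match(as.integer(rr), model$residues$resnum))
      substructure_map(regions, model)
    } else NULL
    list(model = model, map = map, traj = traj)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis battery over the configured systems
#'
#' Stages run in dependency order (input assembly, then fluctuation, pucker
#' and interaction analyses, then the correlation network, suboptimal paths,
#' degeneracy and cross-system SIP). Descriptive stages (rmsd, rmsf, pucker,
#' hbonds, annotate) are optional: a failure is logged and skipped. Network
#' stages abort on failure. All tabular artifacts are written under
#' `output_dir`, along with the resolved configuration; reruns with the same
#' config and seed are byte-identical.
#'
#' @param config list or YAML path, see [validate_config()].
#' @param output_dir overrides `config$output_dir`.
#' @return a `comparison_report`: per-system results plus (with `sip`
#'   enabled and >= 2 systems) the pairwise SIP matrix and per-region mean
#'   degeneracy.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validate_config(config)
  an <- config$analyses
  enabled <- function(st) !is.null(an[[st]]) && !identical(an[[st]], FALSE)
  out_dir <- output_dir %||% config$output_dir %||% stop("output_dir required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(config, file.path(out_dir, "resolved-config.yaml"))
  set.seed(config$seed)

  systems <- list()
  for (i in seq_along(config$systems)) {
    sc <- config$systems[[i]]
    sys <- assemble_system(sc, seed_offset = i * 1000L + config$seed)
    window <- if (!is.null(sc$window))
      analysis_window(sc$window$start, sc$window$end) else full_window(sys$traj)
    res <- list(id = sc$id)
    sdir <- file.path(out_dir, sc$id)
    dir.create(sdir, showWarnings = FALSE)

    try_stage <- function(name, expr) {
      tryCatch(expr, error = function(e) {
        message(sprintf("[%s] optional stage '%s' skipped: %s",
                        sc$id, name, conditionMessage(e)))
        NULL
      })
    }
    if (enabled("rmsd") && !is.null(sys$map))
      res$rmsd <- try_stage("rmsd", {
        tb <- rmsd_table(sys$traj, sys$model, sys$map, window = window)
        write_report(tb, file.path(sdir, "rmsd.csv"))
        tb
      })
    if (enabled("rmsf"))
      res$rmsf <- try_stage("rmsf", {
        pr <- rmsf_profile(sys$traj, sys$model, window = window)
        write_report(tabular_report(as.data.frame(pr), window = window),
                     file.path(sdir, "rmsf.csv"))
        pr
      })
    if (enabled("pucker"))
      res$pucker <- try_stage("pucker", {
        ts <- pucker_timeseries(sys$traj, sys$model, window = window)
        write_report(tabular_report(ts$states, window = window),
                     file.path(sdir, "pucker.csv"))
        jsonlite::write_json(as.list(ts$occupancy),
                             file.path(sdir, "pucker-occupancy.json"),
                             auto_unbox = TRUE, digits = NA)
        ts
      })
    if (enabled("hbonds"))
      res$hbonds <- try_stage("hbonds", {
        hb <- do.call(hbond_occupancy,
                      c(list(sys$traj, sys$model, window),
                        stage_params(an, "hbonds")))
        write_report(hb, file.path(sdir, "hbonds.csv"))
        hb
      })
    if (enabled("annotate"))
      res$annotate <- try_stage("annotate", {
        am <- do.call(interaction_occupancy_map,
                      c(list(sys$traj, sys$model, window),
                        stage_params(an, "annotate")))
        write_report(am$pairs, file.path(sdir, "basepairs.csv"))
        write_report(am$stacks, file.path(sdir, "stacking.csv"))
        am
      })
    if (enabled("dccm")) {
      per_rep <- lapply(seq_along(sys$traj$replicates), function(r)
        compute_dccm(sys$traj, sys$model, window = window, replicate = r))
      res$dccm <- consensus_dccm(per_rep)
      utils::write.csv(data.frame(node = res$dccm$nodes, res$dccm$C,
                                  check.names = FALSE),
                       file.path(sdir, "dccm-consensus.csv"), row.names = FALSE)
    }
    if (enabled("network")) {
      np <- stage_params(an, "network")
      cm <- contact_map(sys$traj, sys$model,
                        d_cut = np$d_cut %||% 10,
                        frame_fraction = np$frame_fraction %||% 0.75,
                        neighbor_exclusion = np$neighbor_exclusion %||% 0L,
                        window = window)
      res$network <- build_network(res$dccm, cm,
                                   target_edges = np$target_edges)
      write_report(tabular_report(res$network$edges, params = np,
                                  window = window),
                   file.path(sdir, "network-edges.csv"))
    }
    if (enabled("paths")) {
      pp <- stage_params(an, "paths")
      if (is.null(pp$source) || is.null(pp$target))
        stop("paths stage requires source and target nodes")
      res$paths <- yen_k_shortest(res$network, pp$source, pp$target,
                                  k = pp$k %||% 1000L)
      res$degeneracy <- node_degeneracy(res$paths)
      res$node_counts <- path_node_counts(res$paths)
      write_report(tabular_report(
        data.frame(node = res$degeneracy$nodes,
                   fraction = unname(res$degeneracy$fraction)),
        params = pp, window = window),
        file.path(sdir, "degeneracy.csv"))
      jsonlite::write_json(
        list(lengths = res$paths$lengths,
             paths = lapply(res$paths$paths, identity),
             node_counts = as.list(res$node_counts$counts)),
        file.path(sdir, "paths.json"), auto_unbox = FALSE, digits = NA)
    }
    res$model <- sys$model
    res$map <- sys$map
    systems[[sc$id]] <- res
  }

  report <- list(systems = systems, config = config)
  if (enabled("sip") && length(systems) >= 2L) {
    cmp <- compare_systems(systems)
    report$sip_matrix <- cmp$sip_matrix
    report$region_degeneracy <- cmp$region_degeneracy
    utils::write.csv(cmp$sip_matrix, file.path(out_dir, "sip-matrix.csv"))
    if (!is.null(cmp$region_degeneracy))
      utils::write.csv(cmp$region_degeneracy,
                       file.path(out_dir, "region-degeneracy.csv"),
                       row.names = FALSE)
  }
  class(report) <- "comparison_report"
  report
}

#' Pairwise SIP matrix and per-region degeneracy across systems
#'
#' @param systems list of per-system results, each holding a `degeneracy`
#'   profile (and optionally `map`) as produced by [run_pipeline()].
#' @return list with `sip_matrix` (symmetric, unit diagonal) and
#'   `region_degeneracy` (data.frame system x region means, or NULL without
#'   maps).
#' @export
compare_systems <- function(systems) {
  ids <- names(systems)
  profs <- lapply(systems, `[[`, "degeneracy")
  if (any(vapply(profs, is.null, logical(1))))
    stop("every system needs a degeneracy profile (paths stage) for comparison")
  n_univ <- unique(vapply(profs, function(p) length(p$fraction), integer(1)))
  if (length(n_univ) != 1L)
    stop("alignment error: systems have different node universes")
  m <- diag(1, length(ids))
  dimnames(m) <- list(ids, ids)
  for (i in seq_along(ids))
    for (j in seq_along(ids))
      if (i < j) m[i, j] <- m[j, i] <- sip(profs[[i]], profs[[j]])
  region_deg <- NULL
  if (all(!vapply(systems, function(s) is.null(s$map), logical(1)))) {
    rows <- lapply(ids, function(id) {
      map <- systems[[id]]$map
      vals <- vapply(names(map), function(rn)
        mean(profs[[id]]$fraction[map[[rn]]]), numeric(1))
      cbind(data.frame(system = id, stringsAsFactors = FALSE),
            as.data.frame(as.list(vals), check.names = FALSE))
    })
    region_deg <- do.call(rbind, rows)
  }
  list(sip_matrix = m, region_degeneracy = region_deg)
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("comparison_report: %d system(s)\n", length(x$systems)))
  if (!is.null(x$sip_matrix)) {
    cat("pairwise SIP:\n")
    print(round(x$sip_matrix, 3))
  }
  invisible(x)
}
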