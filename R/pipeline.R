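# End-to-end pipeline driver: synthesize -> traits -> geochip -> community
# stats -> networks -> MEND calibration -> warming effects, with a provenance
# manifest. Stages only read files produced by earlier stages and write new
# files into the run directory, so a rerun with the same config is
# bit-identical for the deterministic stages.

.PIPELINE_STAGES <- c("synth", "traits", "geochip", "stats", "network",
                      "mend_sim", "calibrate", "warming_effects")

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with fields `stages` (subset of
#'   synth/traits/geochip/stats/network/mend_sim/calibrate/warming_effects),
#'   `seed`, `out_dir`, and optional per-stage parameter blocks.
#' @return list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$stages <- cfg$stages %||% .PIPELINE_STAGES
  unknown <- setdiff(cfg$stages, .PIPELINE_STAGES)
  if (length(unknown)) abort_fmt("unknown stage name(s): %s",
                                 paste(unknown, collapse = ", "))
  cfg$seed <- cfg$seed %||% 1L
  structure(cfg, class = "pipeline_config")
}

#' Run the synthetic-data pipeline
#'
#' Executes the requested stages in order, writing every product plus a
#' provenance manifest (`manifest.json`: config hash, seed, stage list, md5
#' of every output file) into `out_dir`. Later stages read earlier stages'
#' files from disk, so the run directory is a complete, self-describing
#' record.
#'
#' @param config a `pipeline_config` (from [read_pipeline_config()]) or a
#'   plain list with the same fields.
#' @param out_dir output directory (overrides `config$out_dir`).
#' @param quiet suppress progress messages.
#' @return (invisibly) the manifest as a list.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  cfg <- config
  stages <- cfg$stages %||% .PIPELINE_STAGES
  unknown <- setdiff(stages, .PIPELINE_STAGES)
  if (length(unknown)) abort_fmt("unknown stage name(s): %s",
                                 paste(unknown, collapse = ", "))
  deps <- list(traits = "synth", geochip = "synth", stats = "synth",
               network = "synth", calibrate = "mend_sim",
               warming_effects = "calibrate")
  for (s in stages) {
    need <- deps[[s]]
    if (!is.null(need) && !need %in% stages)
      abort_fmt("stage '%s' requires stage '%s'", s, need)
  }
  out_dir <- out_dir %||% cfg$out_dir %||% abort_fmt("no out_dir configured")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg$seed %||% 1L
  say <- function(...) if (!quiet) message(sprintf(...))
  path <- function(f) file.path(out_dir, f)
  outputs <- character(0)
  emit <- function(f) outputs <<- c(outputs, f)

  sd_args <- cfg$synth %||% list()
  design <- do.call(synthetic_design, c(sd_args, list(seed = seed)))
  fd_args <- cfg$forcing %||% list()
  fdesign <- do.call(forcing_design,
                     c(fd_args, list(seed = derive_seed(seed, 2))))

  if ("synth" %in% stages) {
    say("stage synth: generating communities, traits, probes, forcing")
    comm <- gen_paired_communities(design)
    write_community_table(comm, path("community.tsv")); emit("community.tsv")
    ref <- gen_trait_reference(design)
    write_trait_reference(ref, path("trait_reference.tsv"))
    emit("trait_reference.tsv")
    pt_args <- cfg$probes %||% list(n_probes = 400, detection_rate = 0.8)
    pt <- do.call(gen_probe_table,
                  c(pt_args, list(groups = comm$samples$group,
                                  seed = derive_seed(seed, 3))))
    write_probe_table(pt, path("probes.tsv")); emit("probes.tsv")
    for (w in c(FALSE, TRUE)) {
      f <- gen_forcing(fdesign, warmed = w)
      nm <- if (w) "forcing_warmed.csv" else "forcing_control.csv"
      write_forcing(f, path(nm)); emit(nm)
    }
  }
  if ("traits" %in% stages) {
    say("stage traits: community genomic trait indices")
    comm <- read_community_table(path("community.tsv"))
    ref <- read_trait_reference(path("trait_reference.tsv"))
    tr <- community_traits(comm, ref)
    utils::write.table(tr, path("community_traits.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    emit("community_traits.tsv")
  }
  if ("geochip" %in% stages) {
    say("stage geochip: probe filtering, normalization, response ratios")
    pt <- read_probe_table(path("probes.tsv"))
    pt <- normalize_probes(filter_probes(pt, cfg$geochip$min_detect %||% 3))
    rr <- response_ratio_table(pt, "WL", "CL")
    utils::write.table(rr, path("response_ratios.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    emit("response_ratios.tsv")
  }
  if ("stats" %in% stages) {
    say("stage stats: dissimilarity, dispersion, stochasticity, MRM")
    comm <- read_community_table(path("community.tsv"))
    bc <- bray_curtis(comm, relative = TRUE)
    utils::write.table(as.matrix(bc), path("bray_curtis.tsv"), sep = "\t",
                       quote = FALSE)
    emit("bray_curtis.tsv")
    disp <- group_dispersion(bc, comm$samples$habitat,
                             permutations = cfg$stats$permutations %||% 199,
                             seed = derive_seed(seed, 4))
    nst <- lapply(unique(comm$samples$group), function(g)
      data.frame(group = g,
                 tnst = tnst(comm, g,
                             null_reps = cfg$stats$null_reps %||% 100,
                             seed = derive_seed(seed, 5))$tnst))
    stats_out <- list(
      dispersion = list(group_means = as.list(disp$group_means),
                        F = disp$F, p = disp$p),
      tnst = do.call(rbind, nst))
    jsonlite::write_json(stats_out, path("community_stats.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    emit("community_stats.json")
  }
  if ("network" %in% stages) {
    say("stage network: co-occurrence network and sub-network topology")
    comm <- read_community_table(path("community.tsv"))
    lit <- comm$samples$habitat == "litterbag"
    sub <- community_table(comm$counts[lit, , drop = FALSE],
                           comm$samples[lit, , drop = FALSE])
    net <- build_network(sub,
                         min_prevalence = cfg$network$min_prevalence %||% 6,
                         threshold = cfg$network$threshold %||% 0.8)
    write_network_edgelist(net, path("network_edges.tsv"))
    emit("network_edges.tsv")
    props <- subnetwork_properties(net, sub)
    utils::write.table(props, path("subnetwork_properties.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    emit("subnetwork_properties.tsv")
  }
  if ("mend_sim" %in% stages) {
    say("stage mend_sim: simulating and generating observations")
    params <- do.call(mend_params, cfg$mend$params %||% list())
    init <- mend_state()
    for (w in c(FALSE, TRUE)) {
      nm <- if (w) "warmed" else "control"
      forc <- if ("synth" %in% stages)
        read_forcing(path(sprintf("forcing_%s.csv", nm)))
      else gen_forcing(fdesign, warmed = w)
      obs <- gen_observations(params, init, forc,
                              seed = derive_seed(seed, 6 + w))
      write_observations(obs, path(sprintf("observations_%s.csv", nm)))
      emit(sprintf("observations_%s.csv", nm))
    }
  }
  if ("calibrate" %in% stages) {
    say("stage calibrate: SCE calibration (control and warming) + COFI")
    cal_cfg <- cfg$calibrate %||% list()
    calibrate <- cal_cfg$parameters %||% c("Vd", "Ec", "mR", "Vp2")
    for (w in c(FALSE, TRUE)) {
      nm <- if (w) "warmed" else "control"
      forc <- read_forcing(path(sprintf("forcing_%s.csv", nm)))
      obs <- read_observations(path(sprintf("observations_%s.csv", nm)))
      cal <- calibrate_mend(obs, forc, calibrate = calibrate,
                            spec = objective_spec(cal_cfg$mode %||% "gMEND"),
                            max_evals = cal_cfg$max_evals %||% 400,
                            seed = derive_seed(seed, 8 + w))
      report <- list(mode = cal$spec$mode,
                     best = as.list(cal$sce$par),
                     objective = cal$objective,
                     J_min = cal$cofi$J_min,
                     J_critical = cal$cofi$J_critical,
                     cv = as.list(cal$cofi$cv),
                     n_evals = cal$sce$n_evals)
      jsonlite::write_json(report, path(sprintf("calibration_%s.json", nm)),
                           auto_unbox = TRUE, digits = NA)
      emit(sprintf("calibration_%s.json", nm))
      yaml::write_yaml(unclass(cal$best_params),
                       path(sprintf("calibration_%s_params.yaml", nm)))
      emit(sprintf("calibration_%s_params.yaml", nm))
    }
  }
  if ("warming_effects" %in% stages) {
    say("stage warming_effects: derived-output comparison")
    # Use the control calibration's parameters for both plots so the table
    # isolates the forcing effect.
    pc <- mend_params(yaml::read_yaml(path("calibration_control_params.yaml")))
    fc <- read_forcing(path("forcing_control.csv"))
    fw <- read_forcing(path("forcing_warmed.csv"))
    init <- mend_state()
    tab <- warming_effect_table(mend_simulate(pc, init, fc),
                                mend_simulate(pc, init, fw))
    utils::write.table(tab, path("warming_effects.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    emit("warming_effects.tsv")
  }

  cfg_norm <- unclass(cfg)
  cfg_norm <- cfg_norm[order(names(cfg_norm))]
  cfg_json <- jsonlite::toJSON(cfg_norm, auto_unbox = TRUE, digits = NA)
  outputs <- unique(outputs)
  md5 <- as.list(tools::md5sum(file.path(out_dir, outputs)))
  names(md5) <- outputs
  tmp <- tempfile()
  writeLines(as.character(cfg_json), tmp)
  manifest <- list(
    package_version = as.character(utils::packageVersion("gmendr")),
    seed = seed,
    stages = stages,
    config_md5 = unname(tools::md5sum(tmp)),
    outputs = md5
  )
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
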