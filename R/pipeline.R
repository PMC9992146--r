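#' Run the full L-arginine CEST pipeline
#'
#' End-to-end desk-scale run: pseudo-random schedule, simulated dictionary,
#' reference-FCN training, synthetic vial scenes rendered to raw stacks,
#' GAN training on (truncated input, reference-map target) pairs, held-out
#' reconstruction, and evaluation against the reference quantifier. All
#' stage seeds are fanned out from `config$master_seed`.
#'
#' @param config a `run_config`
#' @param weights GAN `loss_weights`
#' @param gan_epochs maximum GAN epochs (early stopping applies)
#' @param retarget also retrain on direct (concentration, pH) targets and
#'   report the per-vial pH monotonicity?
#' @param write_outputs write artifacts (schedule TSV, dictionary, NIfTI
#'   maps, report JSON, training-log CSV, provenance sidecar) into
#'   `config$output_dir`?
#' @param verbose print stage timings?
#' @return list with `schedule`, `dict`, `fcn`, `gan`, `report`,
#'   `test_eval` (pooled held-out statistics), and when `retarget = TRUE`
#'   a `retarget` element (model + per-vial pH table)
#' @export
run_larg_pipeline <- function(config, weights = loss_weights(),
                              gan_epochs = 100, retarget = FALSE,
                              write_outputs = FALSE, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  ms <- config$master_seed
  t_all <- Sys.time()

  sched <- generate_pseudorandom_schedule(config$m, "cest_3ppm",
                                          seed = fan_seed(ms, "schedule"))
  base <- tissue_parameters(pool_parameters(2.5, 1.0),
                            default_larg_solute())
  grid <- parameter_grid(list(
    volume_fraction = seq(config$grid_fs[1], config$grid_fs[2],
                          length.out = config$grid_fs[3]),
    exchange_rate = seq(config$grid_ksw[1], config$grid_ksw[2],
                        length.out = config$grid_ksw[3])))
  say("dictionary: %d points x M = %d",
      prod(vapply(grid$axes, length, 1L)), config$m)
  dict <- generate_dictionary(grid, sched, base)

  scaling <- list(volume_fraction = c(config$grid_fs[1], config$grid_fs[2]),
                  exchange_rate = c(config$grid_ksw[1], config$grid_ksw[2]))
  fcn_cfg <- do.call(fcn_config, c(list(
    input_length = config$m, output_scaling = scaling,
    seed = fan_seed(ms, "fcn")), config$fcn))
  say("training reference FCN (%d epochs)", fcn_cfg$epochs)
  fcn <- train_reference_fcn(dict, fcn_cfg)

  say("rendering %d scenes", config$n_scenes)
  scenes <- vector("list", config$n_scenes)
  stacks <- vector("list", config$n_scenes)
  layout_seed <- fan_seed(ms, "scenes")
  with_seed(layout_seed, {
    for (i in seq_len(config$n_scenes)) {
      scenes[[i]] <- make_larg_scene(
        vial_layout_ring(6, radius = 7),
        concentrations = sample(c(25, 50, 100), 6, replace = TRUE),
        phs = runif(6, 4, 6))
    }
  })
  for (i in seq_len(config$n_scenes)) {
    stacks[[i]] <- render_raw_stack(scenes[[i]], sched,
                                    noise_sigma = config$noise_sigma,
                                    noise_model = "rician",
                                    seed = fan_seed(ms, paste0("noise", i)))
  }

  pairs <- make_training_pairs(scenes, stacks, fcn, config$n_input, scaling)
  n_test <- max(2L, round(0.15 * config$n_scenes))
  te <- seq(config$n_scenes - n_test + 1L, config$n_scenes)
  tr <- setdiff(seq_len(config$n_scenes), te)
  tr_pairs <- subset_pairs(pairs, tr)

  gan_cfg <- do.call(gan_config, c(list(
    n_input = config$n_input, epochs = gan_epochs,
    seed = fan_seed(ms, "gan"), output_scaling = scaling), config$gan))
  say("training GAN on %d pairs (max %d epochs)", length(tr), gan_epochs)
  gan <- train_gan(tr_pairs, gan_cfg, weights)
  say("GAN stopped after %d epochs (best %d)", nrow(gan$log),
      gan$best_epoch)

  ev <- evaluate_on_scenes(gan, fcn, scenes[te], stacks[te])

  out <- list(schedule = sched, dict = dict, fcn = fcn, gan = gan,
              scenes = scenes, stacks = stacks, test_idx = te,
              report = ev$report, test_eval = ev$pooled)

  if (retarget) {
    rt_pairs <- retarget_to_direct_quantities(
      subset_pairs(pairs, tr), scenes[tr])
    rt_cfg <- gan_cfg
    rt_cfg$seed <- fan_seed(ms, "gan_retarget")
    say("retraining on direct (concentration, pH) targets")
    rt_gan <- train_gan(rt_pairs, rt_cfg, weights)
    ph_tab <- ph_monotonicity_table(rt_gan, scenes[te], stacks[te])
    out$retarget <- list(gan = rt_gan, ph_table = ph_tab)
  }

  if (write_outputs) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(config$output_dir, f)
    write_schedule(sched, p("schedule.tsv"))
    write_dictionary(dict, p("dictionary.json"))
    i1 <- te[1]
    rec <- reconstruct_volume(gan, stacks[[i1]])
    write_parameter_maps(rec, p("gan_maps.nii.gz"),
                         meta = list(master_seed = ms,
                                     units = list(volume_fraction = "1",
                                                  exchange_rate = "Hz")))
    q <- quantify_stack(fcn, stacks[[i1]])
    write_parameter_maps(q[c("volume_fraction", "exchange_rate")],
                         p("reference_maps.nii.gz"),
                         meta = list(master_seed = ms))
    write_report(out$report, p("report.json"))
    utils::write.csv(gan$log, p("training_log.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(master_seed = ms, m = config$m, n_input = config$n_input,
           n_scenes = config$n_scenes, noise_sigma = config$noise_sigma,
           package_version = as.character(utils::packageVersion("ganst")),
           elapsed_s = as.numeric(Sys.time() - t_all, units = "secs")),
      p("provenance.json"), auto_unbox = TRUE, digits = NA)
  }
  say("pipeline finished in %.0f s", as.numeric(Sys.time() - t_all,
                                                units = "secs"))
  out
}

subset_pairs <- function(pairs, idx) {
  structure(pairs[idx],
            target_names = attr(pairs, "target_names"),
            output_scaling = attr(pairs, "output_scaling"),
            input_center = attr(pairs, "input_center"),
            input_scale = attr(pairs, "input_scale"),
            class = "gan_pairs")
}

# pooled held-out comparison of GAN maps against the reference quantifier
evaluate_on_scenes <- function(gan, fcn, scenes, stacks) {
  pf <- c(); rf <- c(); pk <- c(); rk <- c()
  first <- NULL
  for (i in seq_along(scenes)) {
    q <- quantify_stack(fcn, stacks[[i]])
    rec <- reconstruct_volume(gan, stacks[[i]])
    msk <- scenes[[i]]$region_labels > 0
    pf <- c(pf, rec$volume_fraction[msk]); rf <- c(rf, q$volume_fraction[msk])
    pk <- c(pk, rec$exchange_rate[msk]); rk <- c(rk, q$exchange_rate[msk])
    if (is.null(first)) {
      first <- list(pred = rec,
                    ref = q[c("volume_fraction", "exchange_rate")],
                    mask = msk, labels = scenes[[i]]$region_labels)
    }
  }
  stat_f <- pearson_and_icc(pf, rf)
  stat_k <- pearson_and_icc(pk, rk)
  report <- evaluation_report(first$pred, first$ref, mask = NULL,
                              region_labels = first$labels)
  list(pooled = list(
    volume_fraction = list(r = stat_f$r, icc = stat_f$icc,
                           p = stat_f$p_value),
    exchange_rate = list(r = stat_k$r, icc = stat_k$icc,
                         p = stat_k$p_value),
    n_voxels = length(pf)), report = report)
}

# per-vial median predicted pH vs true pH across held-out scenes
ph_monotonicity_table <- function(rt_gan, scenes, stacks) {
  rows <- list()
  for (i in seq_along(scenes)) {
    rec <- reconstruct_volume(rt_gan, stacks[[i]])
    labs <- scenes[[i]]$region_labels
    for (v in sort(setdiff(unique(as.vector(labs)), 0))) {
      sel <- labs == v
      rows[[length(rows) + 1]] <- data.frame(
        scene = i, vial = v,
        true_ph = median(scenes[[i]]$aux$ph[sel]),
        pred_ph = median(rec$ph[sel]),
        true_conc = median(scenes[[i]]$aux$concentration[sel]),
        pred_conc = median(rec$concentration[sel]))
    }
  }
  do.call(rbind, rows)
}
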