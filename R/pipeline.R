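#' Run the full analysis pipeline on synthetic data
#'
#' Orchestrates the stage sequence behaviour -> residualize -> discount fit ->
#' neural generation -> similarity analysis -> geometry -> dynamics, writing
#' per-stage outputs and a JSON manifest (parameters, seeds, file checksums)
#' to an output directory. Re-running with an identical configuration
#' reproduces identical stochastic outputs. Stages depend on each other in
#' order; requesting a stage whose upstream outputs are missing raises an
#' error naming the stage to run first.
#'
#' @param cfg A configuration list, or a path to a JSON file holding one.
#'   Recognised fields: `out_dir` (required), `seed`, `stages` (subset of
#'   `c("behavior", "fit", "neural", "rsa", "geometry", "dynamics")`; default
#'   all), `synth` (arguments for [synth_config()]), `structured_channels`,
#'   `alignment`, `n_perm`, `window_width`, `window_step`.
#' @return The manifest, invisibly (also written to
#'   `file.path(out_dir, "manifest.json")`).
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- jsonlite::read_json(cfg, simplifyVector = TRUE)
  if (is.null(cfg$out_dir)) stop("config error: out_dir is required")
  defaults <- list(
    seed = 1L,
    stages = c("behavior", "fit", "neural", "rsa", "geometry", "dynamics"),
    synth = list(),
    structured_channels = c(2L, 5L, 9L),
    alignment = "stimulus",
    n_perm = 100L,
    window_width = 500L,
    window_step = 100L
  )
  for (nm in names(defaults)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$out_dir, f)
  need <- function(f, stage) {
    if (!file.exists(out(f))) {
      stop(sprintf("dependency error: missing %s; run stage '%s' first", f, stage))
    }
  }
  msg <- function(...) message(sprintf("[cogmap] %s", sprintf(...)))
  sc <- do.call(synth_config,
                utils::modifyList(list(seed = cfg$seed), as.list(cfg$synth)))
  g <- synth_graph(sc)

  if ("behavior" %in% cfg$stages) {
    msg("stage behavior: generating %d trials (%s graph)", sc$n_trials, sc$graph)
    sb <- gen_behavior(sc)
    write_walk_csv(sb$x, out("walk.csv"))
    utils::write.csv(sb$behavior, out("trials.csv"), row.names = FALSE)
    resid <- residualize_rt(filter_trials(sb$behavior))
    utils::write.csv(resid, out("resid.csv"), row.names = FALSE)
    write_graph_json(g, out("graph.json"))
  }

  if ("fit" %in% cfg$stages) {
    need("walk.csv", "behavior"); need("resid.csv", "behavior")
    msg("stage fit: estimating the discount rate")
    x <- read_walk_csv(out("walk.csv"))
    resid <- utils::read.csv(out("resid.csv"))
    fit <- fit_beta(x, resid)
    jsonlite::write_json(
      list(beta = fit$beta, r0 = fit$r0, r1 = fit$r1,
           objective = fit$objective, status = fit$status,
           grid = fit$grid),
      out("fit.json"), auto_unbox = TRUE, digits = NA, na = "null")
  }

  if ("neural" %in% cfg$stages) {
    need("fit.json", "fit")
    fitj <- jsonlite::read_json(out("fit.json"), simplifyVector = TRUE)
    beta_use <- if (identical(fitj$status, "interior")) fitj$beta else sc$beta_true
    msg("stage neural: %d channels, template beta = %.3g",
        sc$n_channels, beta_use)
    tpl <- latent_template(g, beta_use)
    e <- gen_neural(sc, tpl, structured_channels = cfg$structured_channels)
    saveRDS(e, out("epochs.rds"))
  }

  if ("rsa" %in% cfg$stages) {
    need("epochs.rds", "neural"); need("fit.json", "fit")
    fitj <- jsonlite::read_json(out("fit.json"), simplifyVector = TRUE)
    beta_use <- if (identical(fitj$status, "interior")) fitj$beta else sc$beta_true
    msg("stage rsa: %s-aligned, %d permutations", cfg$alignment, cfg$n_perm)
    e <- truncate_epochs(readRDS(out("epochs.rds")), alignment = cfg$alignment)
    sel <- rsa_select(e, latent_template(g, beta_use), exact_template(g),
                      visual = visual_template(n_nodes = g$n_nodes),
                      n_perm = cfg$n_perm, seed = cfg$seed + 2L)
    utils::write.csv(sel, out("selection.csv"), row.names = FALSE)
    saveRDS(attr(sel, "rdms"), out("rdms.rds"))
  }

  if ("geometry" %in% cfg$stages) {
    need("selection.csv", "rsa"); need("epochs.rds", "neural")
    sel <- utils::read.csv(out("selection.csv"))
    chans <- sel$channel[sel$selected_latent]
    if (length(chans) == 0L) chans <- cfg$structured_channels
    msg("stage geometry: embedding %d selected channel(s)", length(chans))
    e <- truncate_epochs(readRDS(out("epochs.rds")), alignment = cfg$alignment)
    d <- cv_euclidean_rdm(e, channels = chans)
    emb <- classical_mds(d)
    write_embedding_csv(emb, out("embedding.csv"))
    fitj <- jsonlite::read_json(out("fit.json"), simplifyVector = TRUE)
    beta_use <- if (identical(fitj$status, "interior")) fitj$beta else sc$beta_true
    res <- list(
      neural_loss = if (sc$graph == "modular")
        lda_module_loss(emb, g$module_labels) else NA,
      latent_loss = if (sc$graph == "modular")
        lda_module_loss(pca_embed(map_analytic(transition_matrix(g), beta_use)),
                        g$module_labels) else NA
    )
    jsonlite::write_json(res, out("geometry.json"), auto_unbox = TRUE,
                         digits = NA, na = "null")
  }

  if ("dynamics" %in% cfg$stages) {
    need("selection.csv", "rsa"); need("epochs.rds", "neural")
    sel <- utils::read.csv(out("selection.csv"))
    chans <- sel$channel[sel$selected_latent]
    if (length(chans) == 0L) chans <- cfg$structured_channels
    fitj <- jsonlite::read_json(out("fit.json"), simplifyVector = TRUE)
    beta_use <- if (identical(fitj$status, "interior")) fitj$beta else sc$beta_true
    w <- sliding_windows(sc$n_trials, cfg$window_width, cfg$window_step)
    msg("stage dynamics: %d windows on %d channel(s)",
        length(w$starts), length(chans))
    e <- truncate_epochs(readRDS(out("epochs.rds")), alignment = cfg$alignment)
    wc <- windowed_template_corr(
      e, list(latent = latent_template(g, beta_use),
              visual = visual_template(n_nodes = g$n_nodes)),
      w, channels = chans)
    utils::write.csv(wc, out("windows.csv"), row.names = FALSE)
  }

  files <- setdiff(list.files(cfg$out_dir), "manifest.json")
  manifest <- list(
    package = as.character(utils::packageVersion("cogmap")),
    seed = cfg$seed,
    stages = cfg$stages,
    parameters = cfg[setdiff(names(cfg), "stages")],
    checksums = as.list(tools::md5sum(file.path(cfg$out_dir, files)))
  )
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(manifest)
}
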