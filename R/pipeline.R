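#' Run the full sequence-space pipeline
#'
#' Wires the stages end to end — distances, tree (imported or
#' neighbor-joining), Sammon embedding, tree overlay, group spread — and
#' writes every intermediate plus a run manifest, so a map is always
#' reproducible from its config alone. Rerunning with the same config and
#' seed reproduces all outputs byte-identically.
#'
#' The config is a flat key-value YAML file (or an equivalent named list):
#' \describe{
#'   \item{alignment}{path to an aligned FASTA/PHYLIP/Clustal file
#'     (alternative: `distances`, a PHYLIP square matrix)}
#'   \item{format}{alignment format, default `auto`}
#'   \item{tree}{`nj` (default) or a path to a Newick file}
#'   \item{model}{`dayhoff_ml` (default), `poisson` or `p`}
#'   \item{gap_policy}{`pairwise_deletion` (default) or
#'     `complete_deletion`}
#'   \item{k}{embedding dimension, default 3}
#'   \item{seed}{integer, default 1}
#'   \item{restarts}{default 10}
#'   \item{overlay}{`centroid` (default) or `joint`}
#'   \item{groups}{optional path to a taxon/group TSV}
#'   \item{outdir}{output directory}
#' }
#'
#' @param config path to a YAML config file, or a named list.
#' @param outdir output directory (overrides the config entry).
#' @return invisibly, a list with the fitted objects and the paths
#'   written: `dist.phy`, `tree.nwk`, `coords.tsv`, `scene.json`,
#'   `spread.tsv`, `manifest.json`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  defaults <- list(format = "auto", tree = "nj", model = "dayhoff_ml",
                   gap_policy = "pairwise_deletion", k = 3, seed = 1,
                   restarts = 10, overlay = "centroid", groups = NULL,
                   outdir = "protspace_run")
  cfg <- utils::modifyList(defaults, cfg[!vapply(cfg, is.null, TRUE)])
  outdir <- outdir %||% cfg$outdir
  cfg$outdir <- outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)

  # canonical config copy; its md5 is the run's provenance digest
  cfg_path <- file.path(outdir, "config.used.yaml")
  ordered <- cfg[order(names(cfg))]
  yaml::write_yaml(ordered, cfg_path)
  # digest covers the analysis config only, not the output location
  digest_path <- tempfile()
  yaml::write_yaml(ordered[setdiff(names(ordered), "outdir")], digest_path)
  digest <- unname(tools::md5sum(digest_path))
  unlink(digest_path)
  version <- as.character(utils::packageVersion("protspace"))
  header <- c(sprintf("# protspace %s", version),
              sprintf("# seed=%s config_md5=%s", cfg$seed, digest))
  warnings_log <- character(0)
  note <- function(...) warnings_log <<- c(warnings_log, paste0(...))

  # --- stage: distances -------------------------------------------------
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      ps_stop("stage '", name, "': ", conditionMessage(e),
              class = class(e)[1]))
  }
  if (!is.null(cfg$distances)) {
    dm <- stage("distances", read_distance_matrix(cfg$distances))
    msa <- NULL
  } else if (!is.null(cfg$alignment)) {
    msa <- stage("read", read_msa(cfg$alignment, cfg$format))
    dm <- stage("distances",
                distance_matrix(msa, method = cfg$model,
                                gap_policy = cfg$gap_policy))
  } else {
    ps_stop("config must name an 'alignment' or a 'distances' file")
  }
  n_sat <- if (is.null(dm$saturated)) 0 else nrow(dm$saturated)
  if (n_sat > 0) note(n_sat, " saturated pair(s) capped at d_max")
  dist_path <- file.path(outdir, "dist.phy")
  write_distance_matrix(dm, dist_path)

  # --- stage: tree ------------------------------------------------------
  if (identical(cfg$tree, "nj")) {
    tree <- stage("nj", withCallingHandlers(
      neighbor_joining(dm),
      warning = function(w) {
        note(conditionMessage(w)); invokeRestart("muffleWarning")
      }))
  } else {
    tree <- stage("tree", read_newick(cfg$tree))
    mism <- c(setdiff(tree$tip.label, dm$labels),
              setdiff(dm$labels, tree$tip.label))
    if (length(mism))
      ps_stop("stage 'tree': tree and alignment taxa mismatch: ",
              paste(unique(mism), collapse = ", "))
  }
  tree_path <- file.path(outdir, "tree.nwk")
  write_newick(tree, tree_path)

  # --- stage: embed -----------------------------------------------------
  fit <- stage("embed", withCallingHandlers(
    sammon_map(dm, k = cfg$k, seed = cfg$seed, restarts = cfg$restarts),
    warning = function(w) {
      note(conditionMessage(w)); invokeRestart("muffleWarning")
    }))
  coords_path <- file.path(outdir, "coords.tsv")
  co <- data.frame(taxon = fit$labels,
                   apply(fit$X, 2, function(v) sprintf("%.12g", v)))
  con <- file(coords_path, "w")
  writeLines(header, con)
  write.table(co, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  # sidecar with stress and config
  jsonlite::write_json(
    list(stress = fit$stress, seed = cfg$seed, k = cfg$k,
         restart_stresses = fit$restart_stresses,
         converged = fit$converged, config_md5 = digest),
    file.path(outdir, "coords.meta.json"), auto_unbox = TRUE, digits = I(17),
    pretty = TRUE)

  # --- stage: overlay + spread -----------------------------------------
  ann <- if (!is.null(cfg$groups)) read_group_annotation(cfg$groups)
         else group_annotation(data.frame(taxon = fit$labels,
                                          group = "all"))
  scene <- stage("overlay", overlay_tree(fit, tree, method = cfg$overlay,
                                         groups = ann))
  scene_path <- file.path(outdir, "scene.json")
  export_scene(scene, scene_path, "json")
  spread <- stage("spread", group_spread(fit, ann))
  spread_path <- file.path(outdir, "spread.tsv")
  con <- file(spread_path, "w")
  writeLines(c(header, sprintf("# global_rms=%.12g",
                               attr(spread, "global_rms"))), con)
  write.table(as.data.frame(spread), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  close(con)

  # --- manifest ---------------------------------------------------------
  outputs <- c(dist = "dist.phy", tree = "tree.nwk", coords = "coords.tsv",
               scene = "scene.json", spread = "spread.tsv")
  manifest <- list(
    tool = "protspace", version = version, seed = cfg$seed,
    config_md5 = digest, config = ordered,
    stress = fit$stress, saturated_pairs = n_sat,
    warnings = as.list(warnings_log),
    outputs = as.list(outputs),
    complete = TRUE)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(list(dm = dm, tree = tree, fit = fit, scene = scene,
                 spread = spread,
                 paths = c(file.path(outdir, outputs),
                           manifest = file.path(outdir, "manifest.json"))))
}
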