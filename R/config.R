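#' Resolved run configuration
#'
#' Two profiles: `desk` (CPU-scale defaults used throughout the tests: 256-px
#' tiles, tiny network, 20 epochs, 512-px context windows) and `paper` (the
#' published training scale: 1024-px crops, 4096-px context windows, 300
#' epochs, medium network). Both share the SGD settings lr 0.001, momentum
#' 0.9, weight decay 0.0005.
#'
#' @param profile "desk" or "paper"
#' @param overrides named nested list merged over the profile defaults
#' @return nested list of class `run_config`
#' @export
run_config <- function(profile = c("desk", "paper"), overrides = list()) {
  profile <- match.arg(profile)
  base <- list(
    profile = profile,
    seed = 1L,
    synth = list(size_px = 256L, n = 50L,
                 stains = c("ER", "PR", "HER2", "Ki67"),
                 scenarios = c("dcis", "invasive", "mixed")),
    network = list(preset = "tiny", num_classes = 3L),
    losses = list(lambda0 = 0.4, lambda1 = 20, lambda2 = 1, lambda3 = 1,
                  t = 0.8, tau = 0.95, lambda_fp = 0.5, mu = 0.5,
                  unlabeled_weight = 1.0),
    stage1 = list(lr = 0.001, momentum = 0.9, weight_decay = 5e-4,
                  epochs = 20L, crop = 256L, batch_labeled = 2L,
                  batch_unlabeled = 2L),
    stage2 = list(context_side = 512L, epochs = 40L, lr = 0.001,
                  momentum = 0.9),
    inference = list(sat_threshold = 0.05, tissue = TRUE),
    ki67 = list(dab_threshold = 0.2, sigma = 1.0, threshold = 0.22,
                min_area = 5, max_area = 400, watershed = TRUE),
    eval = list(k_folds = 5L)
  )
  if (profile == "paper") {
    base$network$preset <- "M"
    base$stage1$epochs <- 300L
    base$stage1$crop <- 1024L
    base$stage2$context_side <- 4096L
    base$synth$size_px <- 1024L
  }
  cfg <- modifyList(base, overrides)
  class(cfg) <- "run_config"
  cfg
}

#' Write a resolved configuration as YAML next to run outputs
#' @param cfg a `run_config`
#' @param path output .yaml file
#' @export
write_run_config <- function(cfg, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Read a YAML configuration (profile defaults filled in)
#' @param path .yaml file written by [write_run_config()] or hand-edited
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  run_config(profile = raw$profile %||% "desk", overrides = raw)
}
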