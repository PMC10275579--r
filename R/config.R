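#' Read a pipeline configuration from YAML
#'
#' The file may contain blocks `sampler` (per model: iterations, warmup,
#' chains, thin, seed), `priors` (arguments of [hb_priors()]), `orl`
#' (arguments of [orl_control()]) and `task` (`n_trials`, `good_decks`).
#' Missing blocks fall back to package defaults.
#'
#' @param path YAML file path.
#' @return List with elements `configs`, `priors`, `control`, `task`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg_one <- function(model) {
    blk <- raw$sampler[[model]]
    if (is.null(blk)) return(sampler_defaults(model))
    dft <- sampler_defaults(model)
    sampler_config(blk$iterations %||% dft$iterations,
                   blk$warmup %||% dft$warmup,
                   blk$chains %||% dft$chains,
                   blk$thin %||% dft$thin,
                   blk$seed %||% dft$seed)
  }
  priors <- do.call(hb_priors, raw$priors %||% list())
  control <- do.call(orl_control, raw$orl %||% list())
  task <- list(n_trials = raw$task$n_trials %||% 100L,
               good_decks = raw$task$good_decks %||% c("C", "D"))
  list(configs = list(m2 = cfg_one("m2"), m3 = cfg_one("m3"),
                      m4 = cfg_one("m4")),
       priors = priors, control = control, task = task)
}
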