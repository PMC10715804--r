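# Experiment configuration: hyperparameter profiles and the YAML config
# consumed by the command-line interface.

#' Hyperparameter profiles
#'
#' Two bundled profiles: `"paper"`, the reference configuration (batch
#' 256, 100 pretraining passes, conv widths 8-16-32-64, 2-second STFT
#' window), and `"desk"`, a scaled-down profile for interactive and
#' continuous-integration use (batch 32, 30 passes, widths halved,
#' 1-second window with 2-second hop, learning rate 1e-3 to converge
#' within the shorter budget).
#'
#' @param name `"desk"` or `"paper"`.
#' @return A list with elements `contrastive` (arguments for
#'   [contrastive_config()]), `encoder` (arguments for [encoder_spec()],
#'   geometry excluded) and `epochs`.
#' @export
contrawr_profile <- function(name = c("desk", "paper")) {
  name <- match.arg(name)
  if (name == "paper") {
    list(contrastive = list(sigma = 2, delta = 0.2, temperature = 2,
                            ema_lambda = 0.99, lr = 2e-4,
                            weight_decay = 1e-4, batch_size = 256L),
         encoder = list(conv_channels = c(8L, 16L, 32L, 64L),
                        proj_hidden = 64L, proj_dim = 32L,
                        head_hidden = 128L),
         stft = function(fs) list(stft_window = 2L * round(fs),
                                  stft_hop = round(fs / 2)),
         epochs = 100L)
  } else {
    list(contrastive = list(sigma = 2, delta = 0.2, temperature = 2,
                            ema_lambda = 0.99, lr = 1e-3,
                            weight_decay = 1e-4, batch_size = 32L),
         encoder = list(conv_channels = c(4L, 8L, 16L, 32L),
                        proj_hidden = 32L, proj_dim = 16L,
                        head_hidden = 32L),
         stft = function(fs) list(stft_window = round(fs),
                                  stft_hop = 2L * round(fs)),
         epochs = 30L)
  }
}

#' Build an encoder spec from a profile
#'
#' @param C,N,fs epoch geometry.
#' @param profile `"desk"` or `"paper"`.
#' @param ... overrides passed on to [encoder_spec()].
#' @return An [encoder_spec()].
#' @export
profile_encoder_spec <- function(C, N, fs, profile = "desk", ...) {
  p <- contrawr_profile(profile)
  args <- c(list(C = C, N = N, fs = fs), p$stft(fs), p$encoder)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(encoder_spec, args)
}

#' Build a contrastive config from a profile
#'
#' @param profile `"desk"` or `"paper"`.
#' @param ... overrides passed on to [contrastive_config()].
#' @return A [contrastive_config()].
#' @export
profile_contrastive_config <- function(profile = "desk", ...) {
  args <- contrawr_profile(profile)$contrastive
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(contrastive_config, args)
}

check_known_keys <- function(x, known, where) {
  bad <- setdiff(names(x), known)
  if (length(bad))
    stopf("unknown key%s in %s: %s", if (length(bad) > 1L) "s" else "",
          where, paste(bad, collapse = ", "))
  invisible(x)
}

#' Read and validate an experiment configuration file
#'
#' The YAML file is the single source of truth of a run.  Unknown keys
#' are rejected at every level, so typos fail fast instead of silently
#' falling back to defaults.  Top-level keys: `profile`, `data`
#' (`path` or `synthetic`), `split` (`pretrain`/`train`/`test`/`seed`),
#' `augment`, `encoder`, `contrastive`, `epochs`, `seeds`, `output_dir`.
#'
#' @param path YAML file path.
#' @param overrides named list applied on top of the file (CLI flags).
#' @return A list of class `experiment_config` with resolved components
#'   `profile`, `data`, `split`, `augment_args`, `encoder_args`,
#'   `contrastive_args`, `epochs`, `seeds`, `output_dir`.
#' @export
read_experiment_config <- function(path, overrides = list()) {
  if (!file.exists(path)) stopf("config file '%s' does not exist", path)
  cf <- yaml::read_yaml(path)
  if (!is.list(cf)) stopf("config must be a YAML mapping")
  cf[names(overrides)] <- overrides
  check_known_keys(cf, c("profile", "data", "split", "augment", "encoder",
                         "contrastive", "epochs", "seeds", "output_dir"),
                   "config")
  profile <- cf$profile %||% "desk"
  if (!profile %in% c("desk", "paper"))
    stopf("unknown profile '%s' (expected desk or paper)", profile)

  data <- cf$data %||% list()
  check_known_keys(data, c("path", "synthetic"), "data")
  if (!is.null(data$synthetic)) {
    # "n_samples" stands in for N, which unquoted YAML reads as a boolean
    check_known_keys(data$synthetic,
                     c("K", "n_subjects", "epochs_per_subject", "C",
                       "n_samples", "N", "fs", "noise_sd",
                       "subject_effect_sd", "subject_freq_jitter", "seed"),
                     "data.synthetic")
    ns <- data$synthetic[["n_samples"]]
    if (!is.null(ns)) {
      data$synthetic[["N"]] <- ns
      data$synthetic[["n_samples"]] <- NULL
    }
  }

  split <- cf$split %||% list()
  check_known_keys(split, c("pretrain", "train", "test", "seed"), "split")
  split <- list(pretrain = split$pretrain %||% 0.6,
                train = split$train %||% 0.2,
                test = split$test %||% 0.2,
                seed = split$seed %||% 1L)

  aug <- cf$augment %||% list()
  check_known_keys(aug, c("enabled_ops", "bandpass_low", "bandpass_high",
                          "noise_snr_db", "flip_pairs", "max_shift"),
                   "augment")

  enc <- cf$encoder %||% list()
  check_known_keys(enc, c("stft_window", "stft_hop", "stft_window_fn",
                          "log_compress", "normalize_input",
                          "conv_channels", "proj_hidden", "proj_dim",
                          "head_hidden"),
                   "encoder")

  ctr <- cf$contrastive %||% list()
  check_known_keys(ctr, c("sigma", "delta", "temperature", "ema_lambda",
                          "lr", "weight_decay", "batch_size", "mode",
                          "topx", "exclude_self"),
                   "contrastive")

  seeds <- cf$seeds %||% 1:5
  if (!length(seeds)) stopf("'seeds' must not be empty")
  structure(list(profile = profile, data = data, split = split,
                 augment_args = aug, encoder_args = enc,
                 contrastive_args = ctr,
                 epochs = cf$epochs %||% contrawr_profile(profile)$epochs,
                 seeds = as.integer(seeds),
                 output_dir = cf$output_dir %||% "runs"),
            class = "experiment_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# resolve an experiment config into the concrete objects the training
# functions take, given the epoch geometry of the data
resolve_config <- function(cfg, C, N, fs) {
  stopifnot(inherits(cfg, "experiment_config"))
  spec <- do.call(profile_encoder_spec,
                  c(list(C = C, N = N, fs = fs, profile = cfg$profile),
                    cfg$encoder_args))
  ctr <- do.call(profile_contrastive_config,
                 c(list(profile = cfg$profile), cfg$contrastive_args))
  pol <- do.call(augmentation_policy, cfg$augment_args)
  list(spec = spec, contrastive = ctr, policy = pol, epochs = cfg$epochs)
}
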