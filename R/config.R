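#' Read and validate a simulation configuration
#'
#' Configurations are plain YAML with keys `models` (1, 2 or both),
#' `settings` (subset of S1..S5), `n` (sample sizes), `proportions`
#' (below-LLOQ proportions), `r2` (target adjusted R-squared values),
#' `reps`, `seed`, and optionally `methods` (default: every method
#' applicable to each model's role), `allow_custom` (accept grid values
#' outside the study design) and `compute_mse` (population MSE for
#' censored-covariate scenarios). Invalid model/setting combinations — S5
#' with the censored-outcome model — are rejected at parse time, as are
#' off-design grid values unless `allow_custom: true`.
#'
#' @param path YAML file path.
#' @param overrides Named list merged over the file's values (e.g.
#'   `list(reps = 50)`).
#'
#' @return A validated `bloq_sim_config` list.
#' @export
read_sim_config <- function(path, overrides = list()) {
  cfg <- yaml::read_yaml(path)
  # YAML 1.1 reads a bare key `n` as the boolean FALSE; map it back
  names(cfg)[names(cfg) == "FALSE"] <- "n"
  cfg[names(overrides)] <- overrides
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  defaults <- list(models = c(1L, 2L), settings = c("S1", "S2", "S3", "S4", "S5"),
                   n = c(45L, 300L, 1000L),
                   proportions = seq(0.1, 0.9, by = 0.2),
                   r2 = 0.6, reps = 200L, seed = 20260101L,
                   methods = NULL, allow_custom = FALSE, compute_mse = FALSE)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]

  cfg$models <- as.integer(cfg$models)
  if (!all(cfg$models %in% c(1L, 2L))) stop("config error: models must be 1 and/or 2")
  if (!all(cfg$settings %in% c("S1", "S2", "S3", "S4", "S5"))) {
    stop("config error: unknown setting")
  }
  if ("S5" %in% cfg$settings && 2L %in% cfg$models && !1L %in% cfg$models) {
    stop("config error: setting S5 is defined for Model 1 only")
  }
  if (identical(cfg$models, 2L) && "S5" %in% cfg$settings) {
    stop("config error: setting S5 is defined for Model 1 only")
  }
  if (!isTRUE(cfg$allow_custom)) {
    if (!all(cfg$n %in% supported_n)) stop("config error: unsupported n")
    if (!all(vapply(cfg$proportions,
                    function(p) any(abs(p - supported_proportions) < 1e-9),
                    logical(1)))) {
      stop("config error: unsupported proportion")
    }
    if (!all(cfg$r2 %in% supported_r2)) stop("config error: unsupported r2")
  }
  if (cfg$reps < 1L) stop("config error: reps must be >= 1")
  known <- bloq_methods()$method
  if (!is.null(cfg$methods) && !all(cfg$methods %in% known)) {
    stop("config error: unknown method tag")
  }
  structure(cfg, class = "bloq_sim_config")
}

# settings actually run for each model (S5 is covariate-model only)
settings_for_model <- function(cfg, model_id) {
  s <- cfg$settings
  if (model_id == 2L) setdiff(s, "S5") else s
}

methods_for_role <- function(cfg, role) {
  tab <- bloq_methods()
  ok <- tab$method[tab$applicability %in% c("both", role)]
  if (is.null(cfg$methods)) ok else intersect(cfg$methods, ok)
}

# 32-bit FNV-1a over the canonical JSON of the config. The xor touches only
# the low byte; the 32-bit multiply is split into 16-bit halves so every
# intermediate stays exactly representable in a double.
config_hash <- function(cfg) {
  bytes <- utf8ToInt(jsonlite::toJSON(cfg[order(names(cfg))],
                                      auto_unbox = TRUE, digits = NA))
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    hi16 <- h %/% 65536
    lo16 <- h %% 65536
    h <- ((hi16 * prime) %% 65536 * 65536 + lo16 * prime) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Write a run manifest
#'
#' A manifest records everything needed to regenerate a results file
#' bit-identically: the config hash, the root seed, the package version,
#' the calibrated sigma of every (model, setting, R-squared) cell and the
#' LLOQ threshold of every scenario, plus a timestamp.
#'
#' @param cfg A `bloq_sim_config`.
#' @param sigmas Named numeric vector of calibrated sigmas.
#' @param lloqs Named numeric vector of scenario thresholds.
#' @param path Output JSON path.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(cfg, sigmas, lloqs, path) {
  manifest <- list(
    config_hash = config_hash(unclass(cfg)),
    root_seed = cfg$seed,
    package_version = as.character(utils::packageVersion("bloqreg")),
    sigmas = as.list(sigmas),
    lloqs = as.list(lloqs),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
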