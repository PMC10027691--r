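#' Pipeline configuration
#'
#' Collects every stage's settings plus the master seed. Serializable to
#' YAML; a hash of the serialized config is written into the run manifest so
#' outputs are traceable.
#'
#' @param seed Master seed.
#' @param n_subjects Cohort size.
#' @param jnd Listener JND in log2 ripple-velocity units.
#' @param coupling,signal_networks Ground-truth content coupling (see
#'   [ground_truth()]).
#' @param network_sizes Network sizes to enumerate.
#' @param n_networks Family subsample size (NULL = full family).
#' @param n_perm Permutations for the null.
#' @param alpha Significance level.
#' @param tr,run_length,lag Acquisition timing, s.
#' @param ... Further overrides stored verbatim.
#' @return A `wm_config` list.
#' @export
wm_config <- function(seed = 1L, n_subjects = 8L, jnd = 0.2, coupling = 0.6,
                      signal_networks = list(c("LSTC", "LSMG", "RSTC")),
                      network_sizes = 2:4, n_networks = 50L, n_perm = 99L,
                      alpha = 0.05, tr = 1.47, run_length = 620, lag = 4.41,
                      ...) {
  if (is.character(signal_networks)) signal_networks <- list(signal_networks)
  signal_networks <- purrr::map(signal_networks, function(m) {
    as.character(unlist(m))  # YAML round-trips vectors as nested lists
  })
  structure(
    c(list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
           jnd = jnd, coupling = coupling, signal_networks = signal_networks,
           network_sizes = network_sizes, n_networks = n_networks,
           n_perm = as.integer(n_perm), alpha = alpha, tr = tr,
           run_length = run_length, lag = lag),
      list(...)),
    class = "wm_config"
  )
}

#' Read/write a pipeline configuration as YAML
#'
#' @param config A [wm_config()].
#' @param path File path.
#' @return `path` / the config.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(wm_config, raw)
}

#' Subsample a network family reproducibly
#'
#' Keeps any networks that contain a required set of ROIs (so planted signal
#' networks stay in the family), then fills up to `n` with a seeded sample of
#' the rest, returning the family in canonical order.
#'
#' Any network sharing two or more ROIs with a signal-carrying network
#' contains a coupled subROI pair and therefore genuinely carries content;
#' with `exclude_partial = TRUE` (the default) such networks are excluded
#' from the sampled controls, so that only the networks in `keep` should be
#' detectable and any other detection is a false positive.
#'
#' @param networks Tibble from [enumerate_networks()].
#' @param n Family size.
#' @param keep Character vector of network ids that must be included.
#' @param seed Integer seed.
#' @param exclude_partial Drop controls sharing >= 2 ROIs with a `keep`
#'   network?
#' @return Subsampled network tibble.
#' @export
subsample_networks <- function(networks, n, keep = character(), seed = 1L,
                               exclude_partial = TRUE) {
  must <- which(networks$network %in% keep)
  rest <- setdiff(seq_len(nrow(networks)), must)
  if (exclude_partial && length(must)) {
    keep_members <- networks$members[must]
    shares_pair <- vapply(rest, function(i) {
      any(vapply(keep_members, function(km) {
        length(intersect(networks$members[[i]], km)) >= 2L
      }, TRUE))
    }, TRUE)
    rest <- rest[!shares_pair]
  }
  n_extra <- min(length(rest), max(0L, n - length(must)))
  extra <- with_seed_if(seed, sample(rest, n_extra))
  networks[sort(c(must, extra)), , drop = FALSE]
}

#' Run the full synthetic pipeline
#'
#' simulate -> residualize -> connectivity features -> decode -> family-wise
#' permutation test, from one [wm_config()]. Writes (optionally) a results
#' CSV, the null distribution, and a JSON manifest recording the seed and a
#' config hash; a rerun with the same config reproduces the outputs exactly.
#'
#' @param config A [wm_config()].
#' @param out_dir Output directory (NULL = no files written).
#' @return A `wm_pipeline_result`: the family result plus `cohort_meta`,
#'   `config`, `manifest`.
#' @export
run_pipeline <- function(config = wm_config(), out_dir = NULL) {
  stopifnot(inherits(config, "wm_config"))
  seeds <- derive_seeds(config$seed, 4L)
  registry <- build_registry("connectivity-16")
  stimset <- build_stimulus_set(config$jnd)
  acq <- acq_config(tr = config$tr, run_length = config$run_length,
                    lag = config$lag)
  truth <- ground_truth(signal_networks = config$signal_networks,
                        coupling = config$coupling)
  cohort <- simulate_cohort(config$n_subjects, registry = registry, acq = acq,
                            truth = truth, stimset = stimset,
                            seed = seeds[1])
  networks <- enumerate_networks(registry, config$network_sizes)
  planted <- vapply(config$signal_networks,
                    function(m) paste(sort(m), collapse = "+"), "")
  if (!is.null(config$n_networks)) {
    networks <- subsample_networks(networks, config$n_networks,
                                   keep = planted, seed = seeds[2])
  }
  fam <- run_family_analysis(cohort, networks, mode = "connectivity",
                             n_perm = config$n_perm, alpha = config$alpha,
                             seed = seeds[3])
  cfg_hash <- digest_config(config)
  manifest <- list(seed = config$seed, config_hash = cfg_hash,
                   n_subjects = config$n_subjects,
                   n_networks = nrow(networks), n_perm = config$n_perm,
                   planted_networks = as.list(planted),
                   timestamp = format(Sys.time(), tz = "UTC"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(fam$report, file.path(out_dir, "results.csv"),
                     row.names = FALSE)
    utils::write.csv(tidy(fam$null), file.path(out_dir, "null.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    write_config(config, file.path(out_dir, "config.yaml"))
  }
  structure(
    list(family = fam, config = config, manifest = manifest,
         networks = networks,
         cohort_meta = tibble::tibble(
           subject = vapply(cohort, function(s) s$subject, ""),
           seed = vapply(cohort, function(s) s$seed, 1L),
           coupling = vapply(cohort, function(s) s$truth$coupling, 1)
         )),
    class = "wm_pipeline_result"
  )
}

# small stable config hash without extra dependencies
digest_config <- function(config) {
  s <- yaml::as.yaml(unclass(config))
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' @export
print.wm_pipeline_result <- function(x, ...) {
  cat(sprintf("<wm_pipeline_result> seed %d, %d subjects, %d networks, %d perms\n",
              x$config$seed, x$config$n_subjects, nrow(x$networks),
              x$config$n_perm))
  print(x$family)
  invisible(x)
}
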