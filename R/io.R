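#' Write and read spike records as TSV
#'
#' Tab-separated file with a `#`-prefixed header line carrying `n_e`,
#' `n_i` and `duration`, then columns `time_ms` (fixed point, one decimal
#' at the default 0.1 ms step) and `neuron_id` (0-based), sorted by time.
#'
#' @param spikes a `spike_record`.
#' @param path output file.
#' @param digits decimals used for the time column.
#' @return `write_spikes`: the path, invisibly.  `read_spikes`: a
#'   `spike_record`.
#' @export
write_spikes <- function(spikes, path, digits = 1) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_e=%d n_i=%d duration=%s",
                     attr(spikes, "n_e"), attr(spikes, "n_i"),
                     format(attr(spikes, "duration"), scientific = FALSE)),
             con)
  writeLines("time_ms\tneuron_id", con)
  if (nrow(spikes))
    writeLines(sprintf(paste0("%.", digits, "f\t%d"), spikes$time,
                       spikes$neuron), con)
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) {
  hdr <- readLines(path, n = 1)
  m <- regmatches(hdr, regexec(
    "^# n_e=(\\d+) n_i=(\\d+) duration=([0-9.eE+-]+)", hdr))[[1]]
  if (length(m) != 4) stop("malformed spike file header: ", hdr)
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   colClasses = c("numeric", "integer"))
  if (nrow(df) && (is.unsorted(df$time_ms) || any(df$time_ms < 0)))
    stop("spike times must be sorted and non-negative")
  new_spike_record(df$time_ms, df$neuron_id, as.integer(m[2]),
                   as.integer(m[3]), as.numeric(m[4]))
}

mtx_dims <- function(topology, cl) {
  n_e <- topology$n_e; n_i <- topology$n_i
  switch(cl, ee = c(n_e, n_e), ei = c(n_e, n_i),
         ie = c(n_i, n_e), ii = c(n_i, n_i))
}

mtx_offsets <- function(topology, cl) {
  n_e <- topology$n_e
  switch(cl, ee = c(0L, 0L), ei = c(0L, n_e), ie = c(n_e, 0L),
         ii = c(n_e, n_e))
}

#' Serialize a topology to MatrixMarket files
#'
#' Writes one MatrixMarket coordinate file per connection class
#' (`<stem>_ee.mtx`, ..., 1-based indices local to each class's pre/post
#' population, entry values = weights; explicitly stored zeros are
#' preserved so zero-weight edges survive the round trip) plus a plain-text
#' sidecar `<stem>_meta.tsv` with `n_e`, `n_i` and, when present, the
#' torus positions.
#'
#' @param topology a [topology] object.
#' @param stem output path stem.
#' @return `write_topology`: the stem, invisibly.  `read_topology`: the
#'   reconstructed [topology].
#' @export
write_topology <- function(topology, stem) {
  for (cl in CLASSES) {
    e <- topology$edges[[cl]]
    off <- mtx_offsets(topology, cl)
    dm <- mtx_dims(topology, cl)
    m <- new("dgTMatrix", i = as.integer(e$pre - off[1]),
             j = as.integer(e$post - off[2]), x = as.numeric(e$w),
             Dim = as.integer(dm))
    Matrix::writeMM(m, paste0(stem, "_", cl, ".mtx"))
  }
  con <- file(paste0(stem, "_meta.tsv"), "w")
  on.exit(close(con))
  writeLines(sprintf("n_e\t%d", topology$n_e), con)
  writeLines(sprintf("n_i\t%d", topology$n_i), con)
  if (!is.null(topology$positions)) {
    writeLines("id\tu\tv", con)
    writeLines(sprintf("%d\t%.17g\t%.17g", topology$positions$id,
                       topology$positions$u, topology$positions$v), con)
  }
  invisible(stem)
}

#' @rdname write_topology
#' @export
read_topology <- function(stem) {
  meta <- readLines(paste0(stem, "_meta.tsv"))
  n_e <- as.integer(sub("n_e\t", "", meta[1]))
  n_i <- as.integer(sub("n_i\t", "", meta[2]))
  positions <- NULL
  if (length(meta) > 2 && meta[3] == "id\tu\tv") {
    positions <- read.table(text = meta[-(1:2)], sep = "\t", header = TRUE)
  }
  edges <- list()
  dummy <- new_topology(n_e, n_i, list(ee = edge_df(integer(0), integer(0)),
                                       ei = edge_df(integer(0), integer(0)),
                                       ie = edge_df(integer(0), integer(0)),
                                       ii = edge_df(integer(0), integer(0))))
  for (cl in CLASSES) {
    m <- Matrix::readMM(paste0(stem, "_", cl, ".mtx"))
    m <- as(m, "TsparseMatrix")
    dm <- mtx_dims(dummy, cl)
    if (any(dim(m) != dm)) stop("MTX dimensions do not match the sidecar")
    off <- mtx_offsets(dummy, cl)
    if (length(m@i) && (max(m@i) >= dm[1] || max(m@j) >= dm[2]))
      stop("MTX index out of bounds")
    w <- if (methods::.hasSlot(m, "x")) m@x else rep(1, length(m@i))
    edges[[cl]] <- edge_df(m@i + off[1], m@j + off[2], w)
  }
  new_topology(n_e, n_i, edges, positions)
}

#' Write a network-state snapshot as TSV
#'
#' Columns: id, V, g_e, g_i, refractory_remaining (ms).
#'
#' @param state a `network_state`.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_state <- function(state, path) {
  df <- data.frame(id = seq_along(state$V) - 1L, V = state$V,
                   g_e = state$g_e, g_i = state$g_i,
                   refractory_remaining = state$refractory * state$dt)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default configuration
#'
#' The full parameter set of the model as a nested list with sections
#' `neuron`, `synapse`, `topology`, `plasticity`, `drive` and `protocol`;
#' every parameter carries the reference value as default.
#'
#' @return A nested named list.
#' @export
default_config <- function() {
  list(
    neuron = list(tau_m = 20, E_L = -60, V_thres = -50, V_reset = -60,
                  tau_ref = 2),
    synapse = list(tau_e = 5, tau_i = 10, c_e_norm = 1, c_i_norm = -9,
                   w_e_max = 20, w_i_max = 5),
    topology = list(n_e = 4000, n_i = 1000, p = 0.02, kind = "random",
                    k_e_in = 80, k_i_in = 20,
                    eps_e = 0.2, sigma_e = 0.1, eps_i = 0.8,
                    sigma_i = 0.05, i_placement = "uniform"),
    plasticity = list(ee_stdp = TRUE, ie_stdp = TRUE,
                      ee_A_plus = 1e-3, ee_A_minus_factor = 1.05,
                      ie_A_minus = 1e-3, ie_A_plus_factor = 4,
                      tau_plus = 20, tau_minus = 20, mode = "additive",
                      homeostasis = "normalization",
                      norm_interval = 100, norm_target = 1,
                      gamma = 1e-6, nu_0 = 0, scale_interval = 50,
                      rate_window = 100),
    drive = list(mode = "constant", depolarization = 11, rate = 2200,
                 weight = 1),
    protocol = list(duration_s = 18000, dt = 0.1,
                    snapshot_interval_s = 600, summary_interval_s = 60,
                    tail_s = 100, ks_tol = 0.01, rate_ceiling = 100,
                    seed = 1))
}

validate_config <- function(cfg) {
  with(cfg$neuron, {
    if (tau_m <= 0) stop("tau_m must be positive")
    if (tau_ref < 0) stop("tau_ref must be non-negative")
    if (!(V_reset <= E_L && E_L < V_thres))
      stop("require V_reset <= E_L < V_thres")
  })
  with(cfg$synapse, {
    if (tau_e <= 0 || tau_i <= 0) stop("synaptic time constants must be positive")
    if (c_e_norm <= 0) stop("c_e_norm must be positive")
    if (c_i_norm >= 0) stop("c_i_norm must be negative")
    if (w_e_max <= 0 || w_i_max <= 0) stop("weight maxima must be positive")
  })
  with(cfg$topology, {
    if (n_e < 0 || n_i < 0) stop("population sizes must be non-negative")
    if (p < 0 || p > 1) stop("p must be in [0, 1]")
  })
  with(cfg$drive, {
    if (depolarization < 0 || rate < 0) stop("drive must be non-negative")
  })
  invisible(cfg)
}

#' Load a configuration file
#'
#' Reads a YAML configuration with sections `neuron`, `synapse`,
#' `topology`, `plasticity`, `drive`, `protocol`; unspecified keys are
#' filled with the defaults of [default_config()], unknown sections or
#' keys raise an error, and ranges are validated.
#'
#' @param path YAML file (an empty file yields the full default set).
#' @return The validated nested configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- default_config()
  for (sec in names(user)) {
    if (!sec %in% names(cfg)) stop("unknown config section: ", sec)
    for (key in names(user[[sec]])) {
      if (!key %in% names(cfg[[sec]]))
        stop("unknown config key: ", sec, "$", key)
      cfg[[sec]][[key]] <- user[[sec]][[key]]
    }
  }
  validate_config(cfg)
}

#' Write a run manifest
#'
#' Records the configuration snapshot, master and derived seeds, package
#' version, and an inventory of the run's output files with MD5 checksums,
#' so that a deterministic stage can be reproduced bit-for-bit.
#'
#' @param path output YAML file.
#' @param config configuration list.
#' @param seed master seed.
#' @param files character vector of output files.
#' @param components component tags whose derived seeds are listed.
#' @return The path, invisibly.
#' @export
write_manifest <- function(path, config, seed, files = character(0),
                           components = c("topology", "dynamics")) {
  inv <- lapply(files, function(f)
    list(file = f, md5 = unname(tools::md5sum(f))))
  derived <- lapply(components, function(cp) derive_seed(seed, cp))
  names(derived) <- components
  yaml::write_yaml(list(
    package = "drivernet",
    version = as.character(utils::packageVersion("drivernet")),
    seed = seed, derived_seeds = derived,
    config = config, files = inv), path)
  invisible(path)
}
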