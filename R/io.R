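# Delimited-text trajectory and sweep formats with commented headers
# (schema version, units, run metadata), lossless at 15 significant digits.

SG_TRAJECTORY_SCHEMA <- "sg-trajectory-1"
SG_SWEEP_SCHEMA <- "sg-sweep-1"

#' Write / read a trajectory as delimited text
#'
#' Tab-separated values preceded by commented header lines carrying the
#' schema version and the run metadata (model, friction, seed, status).
#' Round-trips are lossless to at least 12 significant digits.  Fixture
#' trajectories and simulator trajectories share the same format.
#'
#' @param traj trajectory tibble.
#' @param path file path.
#' @return `read_trajectory()` returns the trajectory tibble with its
#'   metadata attributes restored.
#' @export
write_trajectory <- function(traj, path) {
  meta <- list(
    schema = SG_TRAJECTORY_SCHEMA,
    model = attr(traj, "model") %||% NA,
    mu_s = attr(traj, "mu_s") %||% NA,
    seed = attr(traj, "seed") %||% NA,
    status = attr(traj, "status") %||% NA
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", names(meta), " = ",
                    vapply(meta, function(x) as.character(x)[1], "")), con)
  writeLines(paste(names(traj), collapse = "\t"), con)
  body <- apply(vapply(traj, function(col) {
    if (is.numeric(col)) sprintf("%.15g", col) else as.character(col)
  }, character(nrow(traj))), 1, paste, collapse = "\t")
  writeLines(body, con)
  invisible(path)
}

read_header_meta <- function(path, n_max = 20) {
  hdr <- readLines(path, n = n_max)
  hdr <- hdr[startsWith(hdr, "# ")]
  kv <- strsplit(sub("^# ", "", hdr), " = ")
  stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  meta <- read_header_meta(path)
  if (is.null(meta$schema) || !identical(meta$schema, SG_TRAJECTORY_SCHEMA)) {
    abort(sprintf("unsupported trajectory schema in %s: %s", path,
                  meta$schema %||% "<missing>"))
  }
  tr <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  expected <- utils::count.fields(path, sep = "\t", comment.char = "#")
  if (length(unique(expected)) != 1) {
    abort(sprintf("parse error in %s: ragged row at line %d", path,
                  which(expected != expected[1])[1]))
  }
  attr(tr, "model") <- meta$model
  attr(tr, "mu_s") <- suppressWarnings(as.numeric(meta$mu_s))
  attr(tr, "seed") <- suppressWarnings(as.integer(meta$seed))
  attr(tr, "status") <- meta$status
  class(tr) <- c("sg_trajectory", class(tr))
  tr
}

#' Write / read a sweep result table
#'
#' @param sweep sweep tibble from [run_sweep()].
#' @param path file path.
#' @return `read_sweep()` returns the sweep tibble.
#' @export
write_sweep <- function(sweep, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# schema = ", SG_SWEEP_SCHEMA),
               paste0("# base_seed = ", attr(sweep, "base_seed") %||% NA),
               paste0("# mu_s_slip = ", mu_slip_threshold(sweep))), con)
  writeLines(paste(names(sweep), collapse = "\t"), con)
  writeLines(apply(sweep, 1, function(r) paste(trimws(r), collapse = "\t")), con)
  invisible(path)
}

#' @rdname write_sweep
#' @export
read_sweep <- function(path) {
  meta <- read_header_meta(path)
  if (!identical(meta$schema, SG_SWEEP_SCHEMA)) {
    abort(sprintf("unsupported sweep schema in %s", path))
  }
  sw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  attr(sw, "base_seed") <- suppressWarnings(as.integer(meta$base_seed))
  class(sw) <- c("sg_sweep", class(sw))
  sw
}

#' Run manifest for provenance
#'
#' A JSON snapshot of the configuration, gait model, seeds, and a hash of
#' the network parameter set, written next to every sweep or trajectory
#' output so any trial can be reproduced in isolation.
#'
#' @param config an [sim_config()] object.
#' @param model gait model name.
#' @param base_seed sweep- or trial-level seed.
#' @param network network constants (hashed into the manifest).
#' @param path output path; `NULL` returns the manifest as a list.
#' @return the manifest list, invisibly if written.
#' @export
write_manifest <- function(config, model, base_seed,
                           network = cpg_network_default(), path = NULL) {
  manifest <- list(
    package = "slipgait",
    version = as.character(utils::packageVersion("slipgait")),
    model = model,
    base_seed = base_seed,
    config = unclass(config),
    network_hash = network_hash(network)
  )
  if (is.null(path)) return(manifest)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

# order-stable content hash without external digest dependencies
network_hash <- function(network) {
  s <- paste(utils::capture.output(utils::str(network, digits.d = 12)),
             collapse = "\n")
  v <- utf8ToInt(s)
  h <- 5381
  for (x in v) h <- (h * 33 + x) %% 2147483647
  sprintf("%08x", as.integer(h))
}
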