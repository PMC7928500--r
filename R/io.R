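#' Write and read spike rasters
#'
#' Rasters are delimited text with columns `trial`, `neuron_id`, `time_ms`,
#' one row per spike; neuron ids are 0-based and times are relative to trial
#' onset.
#'
#' @param raster data.frame with columns `trial`, `neuron_id`, `time_ms`.
#' @param path file path.
#' @return `path` (write) or the raster data.frame (read).
#' @export
write_raster <- function(raster, path) {
  stopifnot(all(c("trial", "neuron_id", "time_ms") %in% names(raster)))
  utils::write.table(raster, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}

#' Serialize a network to plain text
#'
#' Writes the node table (`id`, `x_um`, `y_um`, `role`) and the edge list
#' (`pre`, `post`, `weight`) into a single delimited file with section
#' markers, and reads it back losslessly.
#'
#' @param net a `polywave_network`.
#' @param path file path.
#' @return `path` (write) or a `polywave_network` (read). Reading restores
#'   nodes, roles, edges and the task's stimulus patterns.
#' @export
write_network <- function(net, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("# polywave network, task ", net$task), con)
  writeLines("[nodes]", con)
  nodes <- data.frame(id = seq_len(net$n), x_um = net$coords[, 1],
                      y_um = net$coords[, 2], role = net$roles)
  utils::write.table(nodes, con, sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines("[edges]", con)
  utils::write.table(net$edges, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  task <- as.integer(sub(".*task ", "", lines[1]))
  i_nodes <- which(lines == "[nodes]")
  i_edges <- which(lines == "[edges]")
  nodes <- utils::read.table(text = lines[(i_nodes + 1):(i_edges - 1)],
                             header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  edges <- utils::read.table(text = lines[(i_edges + 1):length(lines)],
                             header = TRUE, sep = "\t")
  coords <- cbind(x = nodes$x_um, y = nodes$y_um)
  net <- list(n = nrow(nodes), coords = coords, roles = nodes$role,
              edges = edges, task = task)
  # restore the task's stimulus patterns from roles
  stim <- which(nodes$role == "stimulated")
  targ <- which(nodes$role == "target")
  fals <- which(nodes$role == "false_target")
  if (!is.na(task) && task == 3L) {
    pats <- list(stim[c(1, 3)], stim[c(1, 4)], stim[c(2, 3)], stim[c(2, 4)])
    net$stim_patterns <- pats
    net$pattern_targets <- list(fals, targ, targ, fals)
    net$pattern_false <- list(targ, fals, fals, targ)
  } else {
    net$stim_patterns <- list(stim)
    net$pattern_targets <- list(targ)
    net$pattern_false <- list(fals)
  }
  class(net) <- "polywave_network"
  validate_network(net)
  net
}

#' Write a weight snapshot as an edge list
#'
#' @param net a `polywave_network`.
#' @param S weight vector (defaults to the network's weights).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(net, path, S = net$edges$weight) {
  out <- data.frame(pre_id = net$edges$pre - 1L,
                    post_id = net$edges$post - 1L, weight = S)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}

#' Collect an experiment's raster across trials
#'
#' Re-shapes a list of per-trial spike data.frames (as returned by
#' [run_trial()]) into the raster layout of [write_raster()].
#'
#' @param trial_spikes list of data.frames with `neuron`, `time_ms`.
#' @return data.frame with `trial`, `neuron_id`, `time_ms`.
#' @export
bind_raster <- function(trial_spikes) {
  do.call(rbind, lapply(seq_along(trial_spikes), function(i) {
    s <- trial_spikes[[i]]
    data.frame(trial = i, neuron_id = s$neuron, time_ms = s$time_ms)
  }))
}
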