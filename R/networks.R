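#' Random local connectivity on a set of 2-D coordinates
#'
#' For every unordered pair of neurons whose Euclidean distance is at most
#' `radius` (inclusive), an edge is created with probability `p` in a uniformly
#' random direction, so pairs are connected unidirectionally. Neurons that end
#' up with no incident edge have their candidate pairs re-drawn until they are
#' connected.
#'
#' Role constraints can force edge orientation: pairs involving an
#' `outward_only` neuron always point away from it, pairs involving an
#' `inward_only` neuron always point into it. A pair between an outward-only
#' and an inward-only neuron is oriented outward-to-inward; a pair between two
#' neurons of the same one-sided role is skipped (no orientation satisfies
#' both).
#'
#' @param coords n x 2 matrix of positions (micrometres).
#' @param radius connection radius (micrometres), inclusive.
#' @param p connection probability per candidate pair.
#' @param outward_only,inward_only integer vectors of neuron indices with
#'   orientation constraints.
#' @param rule `"unordered"` (default; per unordered pair, one edge at most) or
#'   `"ordered"` (independent Bernoulli per ordered pair, may create
#'   reciprocal edges).
#' @param max_retry bound on re-draw rounds for isolated neurons.
#' @return data.frame with columns `pre`, `post` (1-based neuron indices).
#' @export
random_local_connect <- function(coords, radius, p,
                                 outward_only = integer(0),
                                 inward_only = integer(0),
                                 rule = c("unordered", "ordered"),
                                 max_retry = 1000L) {
  rule <- match.arg(rule)
  stopifnot(p > 0, p <= 1, radius > 0)
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  within <- d <= radius + 1e-9
  diag(within) <- FALSE
  is_out <- seq_len(n) %in% outward_only
  is_in <- seq_len(n) %in% inward_only

  cand <- which(upper.tri(within) & within, arr.ind = TRUE) # i < j pairs
  # drop pairs whose orientation constraints are unsatisfiable
  bad <- (is_out[cand[, 1]] & is_out[cand[, 2]]) |
         (is_in[cand[, 1]] & is_in[cand[, 2]])
  cand <- cand[!bad, , drop = FALSE]

  draw_pairs <- function(idx) {
    # idx: rows of cand to (re-)draw; returns edge matrix
    if (!nrow(idx)) return(cbind(pre = integer(0), post = integer(0)))
    if (rule == "ordered") {
      keep1 <- stats::runif(nrow(idx)) < p   # i -> j
      keep2 <- stats::runif(nrow(idx)) < p   # j -> i
      e1 <- idx[keep1, , drop = FALSE]
      e2 <- idx[keep2, c(2, 1), drop = FALSE]
      e <- rbind(e1, e2)
    } else {
      keep <- stats::runif(nrow(idx)) < p
      e <- idx[keep, , drop = FALSE]
      flip <- stats::runif(nrow(e)) < 0.5
      e[flip, ] <- e[flip, c(2, 1)]
    }
    colnames(e) <- c("pre", "post")
    # enforce orientation constraints by flipping, never dropping
    flip_to_out <- is_out[e[, 2]]   # constrained neuron drawn as post
    flip_to_in <- is_in[e[, 1]]     # constrained neuron drawn as pre
    sel <- flip_to_out | flip_to_in
    e[sel, ] <- e[sel, c(2, 1)]
    e
  }

  edges <- draw_pairs(cand)
  for (attempt in seq_len(max_retry)) {
    deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = n)
    iso <- which(deg == 0)
    if (!length(iso)) break
    if (attempt == max_retry)
      stop("isolated neuron(s) remain after ", max_retry, " re-draw rounds")
    rows <- which(cand[, 1] %in% iso | cand[, 2] %in% iso)
    if (!length(rows))
      stop("neuron(s) ", paste(iso, collapse = ", "),
           " have no candidate pairs within radius")
    redraw <- draw_pairs(cand[rows, , drop = FALSE])
    keep <- !(edges[, 1] %in% iso | edges[, 2] %in% iso)
    edges <- rbind(edges[keep, , drop = FALSE], redraw)
  }
  edges <- unique(as.data.frame(edges))
  rownames(edges) <- NULL
  edges
}

new_network <- function(coords, roles, edges, task, stim_patterns,
                        pattern_targets, pattern_false) {
  net <- list(
    n = nrow(coords), coords = coords, roles = roles,
    edges = edges, task = task,
    stim_patterns = stim_patterns,       # list of integer vectors (1-based)
    pattern_targets = pattern_targets,   # list of integer vectors
    pattern_false = pattern_false        # list of integer vectors
  )
  class(net) <- "polywave_network"
  validate_network(net)
  net
}

validate_network <- function(net) {
  e <- net$edges
  stopifnot(all(e$weight >= 0), all(e$pre >= 1), all(e$post <= net$n))
  if (any(e$pre == e$post)) stop("self-connections are not allowed")
  deg <- tabulate(c(e$pre, e$post), nbins = net$n)
  if (any(deg == 0)) stop("network contains isolated neurons")
  stim <- which(net$roles == "stimulated")
  tf <- which(net$roles %in% c("target", "false_target"))
  if (any(e$post %in% stim))
    stop("stimulated neurons must have only outgoing connections")
  if (any(e$pre %in% tf))
    stop("target/false-target neurons must have only incoming connections")
  invisible(net)
}

#' @export
print.polywave_network <- function(x, ...) {
  cat("<polywave_network> task ", x$task, ": ", x$n, " neurons, ",
      nrow(x$edges), " edges\n", sep = "")
  cat("  roles:", paste(sprintf("%s=%d", names(table(x$roles)),
                                table(x$roles)), collapse = ", "), "\n")
  invisible(x)
}

reachable <- function(edges, from, n) {
  adj <- split(edges$post, edges$pre)
  seen <- logical(n); seen[from] <- TRUE
  queue <- from
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    nxt <- adj[[as.character(v)]]
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    queue <- c(queue, nxt)
  }
  seen
}

#' Build the Task 1 network: path reinforcement on a lattice
#'
#' An 11 x 11 grid at 100 um spacing spanning (100..1100 um) squared. The
#' central neuron S at (600, 600) is stimulated and has only outgoing
#' connections; the target T at (600, 100) and three false targets F at
#' (100, 600), (1100, 600) and (600, 1100) have only incoming connections.
#' Neurons within 200*sqrt(2) um are unidirectionally connected with
#' probability 0.5. Initial weights are uniform (`task1_weight_init`, default
#' S_max/2 = 0.12). Construction is re-drawn until T is reachable from S.
#'
#' @param cfg a `polywave_config` (defaults applied when missing).
#' @param max_retry bound on whole-network re-draws for the reachability
#'   requirement.
#' @return a `polywave_network`.
#' @export
build_task1 <- function(cfg = pw_config(task = 1), max_retry = 100L) {
  xs <- seq(100, 1100, by = 100)
  coords <- as.matrix(expand.grid(x = xs, y = xs))
  n <- nrow(coords)
  find_at <- function(x, y) which(coords[, 1] == x & coords[, 2] == y)
  s_id <- find_at(600, 600)
  t_id <- find_at(600, 100)
  f_id <- c(find_at(100, 600), find_at(1100, 600), find_at(600, 1100))
  roles <- rep("plain", n)
  roles[s_id] <- "stimulated"; roles[t_id] <- "target"
  roles[f_id] <- "false_target"
  for (attempt in seq_len(max_retry)) {
    edges <- random_local_connect(coords, radius = 200 * sqrt(2), p = 0.5,
                                  outward_only = s_id,
                                  inward_only = c(t_id, f_id),
                                  rule = cfg$pair_connect_rule)
    if (reachable(edges, s_id, n)[t_id]) break
    if (attempt == max_retry)
      stop("target not reachable from stimulated neuron after ",
           max_retry, " re-draws")
  }
  edges$weight <- cfg$task1_weight_init
  new_network(coords, roles, edges, task = 1L,
              stim_patterns = list(s_id),
              pattern_targets = list(t_id),
              pattern_false = list(f_id))
}

#' Build the Task 2 network: finding a shortcut
#'
#' A square sheet (default 5 x 5 grid at 100 um spacing spanning
#' (100..500 um) squared). The stimulated neuron S sits upper-left at
#' (100, 500), the target T bottom-left at (100, 100). Neurons within
#' 100*sqrt(5) um are unidirectionally connected with probability 0.5. A
#' detour chain of edges running from S along the top edge, down the right
#' edge and back along the bottom to T is set three times as strong as the
#' base weight; all other weights start weak (`task2_base_weight`).
#'
#' @inheritParams build_task1
#' @return a `polywave_network`.
#' @export
build_task2 <- function(cfg = pw_config(task = 2), max_retry = 100L) {
  g <- as.integer(cfg$task2_grid_n)
  xs <- seq(100, 100 * g, by = 100)
  coords <- as.matrix(expand.grid(x = xs, y = xs))
  n <- nrow(coords)
  find_at <- function(x, y) which(coords[, 1] == x & coords[, 2] == y)
  s_id <- find_at(100, max(xs))
  t_id <- find_at(100, 100)
  roles <- rep("plain", n)
  roles[s_id] <- "stimulated"; roles[t_id] <- "target"
  # detour: top edge left-to-right, right edge top-to-bottom, bottom edge
  # right-to-left, ending at T
  top <- lapply(xs[-1], function(x) c(x, max(xs)))
  right <- lapply(rev(xs[-g]), function(y) c(max(xs), y))
  bot_x <- rev(xs)[-1]                     # right-to-left along the bottom
  bottom <- lapply(bot_x[-length(bot_x)], function(x) c(x, 100))
  route <- c(list(c(100, max(xs))), top, right, bottom, list(c(100, 100)))
  route_ids <- vapply(route, function(p) find_at(p[1], p[2]), integer(1))
  detour <- data.frame(pre = route_ids[-length(route_ids)],
                       post = route_ids[-1])
  for (attempt in seq_len(max_retry)) {
    edges <- random_local_connect(coords, radius = 100 * sqrt(5), p = 0.5,
                                  outward_only = s_id, inward_only = t_id,
                                  rule = cfg$pair_connect_rule)
    # force the detour chain to exist with the drawn orientation overridden
    key <- function(e) paste(e$pre, e$post)
    edges <- edges[!(key(edges) %in% c(key(detour),
                                       paste(detour$post, detour$pre))), ]
    edges <- rbind(edges, detour)
    if (reachable(edges, s_id, n)[t_id]) break
    if (attempt == max_retry) stop("target unreachable after re-draws")
  }
  edges$weight <- cfg$task2_base_weight
  on_detour <- paste(edges$pre, edges$post) %in% paste(detour$pre, detour$post)
  edges$weight[on_detour] <- cfg$task2_base_weight * cfg$task2_detour_factor
  net <- new_network(coords, roles, edges, task = 2L,
                     stim_patterns = list(s_id),
                     pattern_targets = list(t_id),
                     pattern_false = list(integer(0)))
  net$detour_edges <- which(on_detour)
  net
}

#' Build the Task 3 network: XOR in a feedforward sheet
#'
#' Four stimulated input neurons 0a (15, 0), 1a (45, 0), 0b (75, 0) and
#' 1b (105, 0); 120 middle-layer neurons on the line y = 100 um; two output
#' neurons F (30, 200) and T (90, 200). Each middle neuron receives a strong
#' projection (weight 0.2) from its nearest input, a weak projection (0.1)
#' from one uniformly chosen other input, and sends a strong projection (0.2)
#' to exactly one output, chosen uniformly.
#'
#' The four stimulus patterns are the input pairs 0a0b, 0a1b, 1a0b, 1a1b with
#' rewarded outputs F, T, T, F — the XOR truth table.
#'
#' @inheritParams build_task1
#' @return a `polywave_network`.
#' @export
build_task3 <- function(cfg = pw_config(task = 3)) {
  in_xy <- rbind(c(15, 0), c(45, 0), c(75, 0), c(105, 0)) # 0a 1a 0b 1b
  mid_x <- seq(0.5, 119.5, by = 1)
  mid_xy <- cbind(mid_x, 100)
  out_xy <- rbind(c(30, 200), c(90, 200))                 # F, T
  coords <- rbind(in_xy, mid_xy, out_xy)
  colnames(coords) <- c("x", "y")
  n <- nrow(coords)
  inp <- 1:4; mid <- 5:124; f_id <- 125L; t_id <- 126L
  roles <- c(rep("stimulated", 4), rep("middle", 120),
             "false_target", "target")
  pre <- integer(0); post <- integer(0); w <- numeric(0)
  for (i in mid) {
    dists <- abs(coords[i, 1] - in_xy[, 1])
    nearest <- which.min(dists)
    other <- sample(setdiff(inp, nearest), 1L)
    out_to <- sample(c(f_id, t_id), 1L)
    pre <- c(pre, nearest, other, i)
    post <- c(post, i, i, out_to)
    w <- c(w, 0.2, 0.1, 0.2)
  }
  edges <- data.frame(pre = pre, post = post, weight = w)
  # patterns: 0a0b, 0a1b, 1a0b, 1a1b -> rewarded outputs F, T, T, F
  pats <- list(c(1L, 3L), c(1L, 4L), c(2L, 3L), c(2L, 4L))
  targs <- list(f_id, t_id, t_id, f_id)
  falses <- list(t_id, f_id, f_id, t_id)
  new_network(coords, roles, edges, task = 3L,
              stim_patterns = pats, pattern_targets = targs,
              pattern_false = falses)
}

#' Build a task network by id
#'
#' @param task task id (1, 2 or 3).
#' @param cfg a `polywave_config`; defaults to `pw_config(task)`.
#' @return a `polywave_network`.
#' @export
build_task_network <- function(task, cfg = pw_config(task = task)) {
  switch(as.character(task),
         "1" = build_task1(cfg), "2" = build_task2(cfg),
         "3" = build_task3(cfg),
         stop("unknown task id: ", task))
}
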