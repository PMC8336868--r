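#' Pearson functional-connectivity matrix of a trial-block ERP
#'
#' Pairwise Pearson correlation between channels over the samples of the
#' task (`[0, 1)` s) or rest (`[-1, 0)` s) window of one trial-block ERP.
#' Channels with zero variance in the window are flagged with a warning and
#' their edges set to 0 (never NaN).
#'
#' @param block one row of a [make_trial_blocks()] tibble, or a channels x
#'   samples matrix (then `time_axis` must be supplied).
#' @param window `"task"` or `"rest"`.
#' @param time_axis seconds relative to onset for matrix input.
#' @param channels channel labels for matrix input.
#' @return A `connectivity_matrix`: symmetric channels x channels matrix of
#'   Pearson rho with unit diagonal; attributes carry the window role.
#' @examples
#' m <- rbind(A = c(1, 2, 3), B = c(1, 2, 4))
#' pearson_connectivity(m, time_axis = c(0, 0.4, 0.8))["A", "B"] # 9/sqrt(84)
#' @export
pearson_connectivity <- function(block, window = c("task", "rest"),
                                 time_axis = NULL, channels = NULL) {
  window <- match.arg(window)
  if (is.matrix(block)) {
    dat <- block
    if (is.null(time_axis)) {
      stop("time_axis required for matrix input", call. = FALSE)
    }
    if (is.null(channels)) {
      channels <- rownames(dat)
      if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(dat)))
    }
  } else {
    stopifnot(is.data.frame(block), nrow(block) == 1, "data" %in% names(block))
    dat <- block$data[[1]]
    time_axis <- attr(block, "time_axis")
    channels <- attr(block, "channels")
    if (is.null(time_axis)) {
      stop("block row lost its trial_blocks attributes; subset with [i, ]",
           call. = FALSE)
    }
  }
  idx <- if (window == "task") {
    which(time_axis >= 0 & time_axis < 1)
  } else {
    which(time_axis >= -1 & time_axis < 0)
  }
  if (length(idx) < 3) {
    stop("selected window has fewer than 3 samples", call. = FALSE)
  }
  x <- t(dat[, idx, drop = FALSE])
  sds <- apply(x, 2, stats::sd)
  flat <- sds == 0
  rho <- matrix(0, ncol(x), ncol(x), dimnames = list(channels, channels))
  if (any(!flat)) {
    rho[!flat, !flat] <- stats::cor(x[, !flat, drop = FALSE])
  }
  if (any(flat)) {
    warning(sum(flat), " zero-variance channel(s) (",
            paste(channels[flat], collapse = ", "),
            "); their edges set to 0", call. = FALSE)
  }
  diag(rho) <- 1
  structure(rho, class = c("connectivity_matrix", "matrix"),
            window_role = window)
}

assert_conn <- function(conn) {
  stopifnot(is.matrix(conn), nrow(conn) == ncol(conn))
  if (max(abs(conn - t(conn))) > 1e-12 || any(abs(conn) > 1 + 1e-12)) {
    stop("connectivity matrix must be symmetric with |rho| <= 1",
         call. = FALSE)
  }
  invisible(conn)
}

#' Weighted node degree
#'
#' Sum of the signed connection weights incident to a node,
#' `E_i = sum_{j != i} d_ij`.
#'
#' @param conn a [pearson_connectivity()] matrix (or any symmetric weighted
#'   adjacency with unit or arbitrary diagonal; the diagonal is excluded).
#' @param node channel label(s) or indices; default all nodes.
#' @return Named numeric vector of degrees.
#' @export
node_degree <- function(conn, node = NULL) {
  assert_conn(conn)
  deg <- rowSums(conn) - diag(conn)
  if (is.null(node)) return(deg)
  if (is.character(node) && !all(node %in% rownames(conn))) {
    stop("unknown node label(s): ",
         paste(setdiff(node, rownames(conn)), collapse = ", "), call. = FALSE)
  }
  deg[node]
}

#' Regional weighted degree
#'
#' Sum of the weights of all edges contained in a node set (each unordered
#' pair counted once): within-hemisphere sums LnL/LnR when given the left or
#' right electrode set.
#'
#' @param conn connectivity matrix.
#' @param region character vector of >= 2 channel labels (or indices).
#' @return Scalar weighted edge sum.
#' @export
region_degree <- function(conn, region) {
  assert_conn(conn)
  if (length(region) < 2) {
    stop("region must contain at least 2 nodes", call. = FALSE)
  }
  if (is.character(region) && !all(region %in% rownames(conn))) {
    stop("unknown node label(s): ",
         paste(setdiff(region, rownames(conn)), collapse = ", "),
         call. = FALSE)
  }
  sub <- conn[region, region, drop = FALSE]
  (sum(sub) - sum(diag(sub))) / 2
}

#' Interhemispheric weighted degree (EX)
#'
#' Sum of the weights of all edges between the left and right electrode
#' sets, midline channels (Fz, Cz, Pz) excluded from both sides.
#'
#' @param conn connectivity matrix with montage channel names.
#' @param montage an [mi_montage()].
#' @return Scalar cross-hemisphere edge sum.
#' @export
ex_degree <- function(conn, montage = mi_montage()) {
  assert_conn(conn)
  sum(conn[montage$left_set, montage$right_set])
}

#' Binarize a connectivity matrix
#'
#' Edge present iff `rho_ij >= threshold` (signed comparison: strong
#' negative correlations do not create edges), diagonal zero. The binary
#' graph is the substrate of the transitivity indicator.
#'
#' @param conn connectivity matrix.
#' @param threshold correlation threshold in `(-1, 1)` (default 0.6).
#' @param absolute threshold `|rho|` instead of signed `rho` (default
#'   `FALSE`).
#' @return A `binary_graph`: 0/1 adjacency matrix with attribute
#'   `threshold`.
#' @export
binarize <- function(conn, threshold = 0.6, absolute = FALSE) {
  assert_conn(conn)
  if (threshold <= -1 || threshold >= 1) {
    stop("threshold must lie in (-1, 1)", call. = FALSE)
  }
  v <- if (absolute) abs(conn) else conn
  adj <- (v >= threshold) * 1
  diag(adj) <- 0
  structure(adj, class = c("binary_graph", "matrix"), threshold = threshold)
}

#' Global transitivity of a binary graph
#'
#' `3 * G_triangle / (3 * G_triangle + G_open)`: the number of closed triads
#' over the number of all connected triads in the (sub)graph. Returns 0 when
#' the graph has no connected triple.
#'
#' @param g a [binarize()]d adjacency matrix.
#' @param nodes optional node subset (labels or indices) inducing a
#'   subgraph; must have >= 3 nodes.
#' @return Transitivity coefficient in `[0, 1]`.
#' @export
transitivity_coef <- function(g, nodes = NULL) {
  a <- unclass(g)
  if (!is.null(nodes)) a <- a[nodes, nodes, drop = FALSE]
  if (nrow(a) < 3) {
    stop("transitivity needs at least 3 nodes", call. = FALSE)
  }
  if (any(a != t(a)) || any(!a %in% c(0, 1)) || any(diag(a) != 0)) {
    stop("g must be a symmetric 0/1 adjacency with zero diagonal",
         call. = FALSE)
  }
  deg <- rowSums(a)
  triples <- sum(deg * (deg - 1)) / 2         # connected triples (3*tri + open)
  if (triples == 0) return(0)
  triangles <- sum(diag(a %*% a %*% a)) / 6
  3 * triangles / triples
}

#' All network indicators for one trial-block
#'
#' Assembles the three scales of the network assessment for both the task
#' and rest windows of a block: per-channel weighted node degree
#' (small-scale), regional degrees LnL/LnR/EX (medium-scale), and global and
#' hemispheric transitivity of the 0.6-binarized graph (large-scale).
#'
#' @param block one row of a [make_trial_blocks()] tibble.
#' @param montage an [mi_montage()].
#' @param threshold binarization threshold (default 0.6).
#' @param absolute passed to [binarize()].
#' @param windows which windows to evaluate (default both).
#' @return A tidy tibble, one row per window x indicator, with columns
#'   `day`, `session`, `task`, `block`, `window_role`, `scale`
#'   (`node`/`region`/`clustering`), `indicator` (channel label, `LnL`,
#'   `LnR`, `EX`, `all`, `left`, `right`) and `value`.
#' @export
network_metrics <- function(block, montage = mi_montage(), threshold = 0.6,
                            absolute = FALSE, windows = c("task", "rest")) {
  stopifnot(is.data.frame(block), nrow(block) == 1)
  purrr::map_dfr(windows, function(w) {
    conn <- pearson_connectivity(block, window = w)
    deg <- node_degree(conn)
    lnl <- region_degree(conn, montage$left_set)
    lnr <- region_degree(conn, montage$right_set)
    ex <- ex_degree(conn, montage)
    g <- binarize(conn, threshold, absolute = absolute)
    cl_all <- transitivity_coef(g)
    cl_l <- transitivity_coef(g, montage$left_set)
    cl_r <- transitivity_coef(g, montage$right_set)
    tibble::tibble(
      day = block$day, session = block$session, task = block$task,
      block = block$block, window_role = w,
      scale = c(rep("node", length(deg)), rep("region", 3),
                rep("clustering", 3)),
      indicator = c(names(deg), "LnL", "LnR", "EX", "all", "left", "right"),
      value = c(unname(deg), lnl, lnr, ex, cl_all, cl_l, cl_r)
    )
  })
}

#' Network indicators for every trial-block
#'
#' @param blocks a [make_trial_blocks()] tibble.
#' @inheritParams network_metrics
#' @return Row-bound [network_metrics()] tibble over all blocks.
#' @export
network_metrics_all <- function(blocks, montage = mi_montage(),
                                threshold = 0.6, absolute = FALSE,
                                windows = c("task", "rest")) {
  stopifnot(inherits(blocks, "trial_blocks"))
  purrr::map_dfr(seq_len(nrow(blocks)), function(i) {
    network_metrics(blocks[i, ], montage, threshold, absolute, windows)
  })
}

# Fig.-5-style role map: target nodes per MI side
role_nodes <- function(task, role = c("contra", "ipsi")) {
  role <- match.arg(role)
  contra <- list(left = c("C4", "O2", "Fp2"), right = c("C3", "O1", "Fp1"))
  ipsi <- list(left = contra$right, right = contra$left)
  if (role == "contra") contra[[task]] else ipsi[[task]]
}

#' Five-band degree scan
#'
#' For each band of the scan grid: band-pass filter, build trial-blocks,
#' compute task-window connectivity, and average the weighted node degree
#' over the six target nodes (C3/C4, O1/O2, Fp1/Fp2) per block; summarized
#' as mean +/- SD per session (super-trial).
#'
#' @param rec an [epoched_recording()] (non-hold trials are selected
#'   internally).
#' @param bands a band tibble, default [band_grid()].
#' @param montage an [mi_montage()].
#' @param block_size trials per block (default 20).
#' @param target_nodes channels averaged into the per-block degree (default
#'   the Fig.-5 target set).
#' @return A tibble: `band`, `lo`, `hi`, `session`, `mean`, `sd`,
#'   `n_blocks`.
#' @export
band_scan_degree <- function(rec, bands = band_grid(),
                             montage = mi_montage(), block_size = 20,
                             target_nodes = c("C3", "C4", "O1", "O2",
                                              "Fp1", "Fp2")) {
  stopifnot(inherits(rec, "epoched_recording"))
  rec <- select_trials(rec, tasks = c("left", "right"))
  purrr::map_dfr(seq_len(nrow(bands)), function(b) {
    filt <- bandpass(rec, bands$lo[b], bands$hi[b])
    blocks <- make_trial_blocks(filt, block_size)
    per_block <- purrr::map_dbl(seq_len(nrow(blocks)), function(i) {
      conn <- pearson_connectivity(blocks[i, ], window = "task")
      mean(node_degree(conn, target_nodes))
    })
    tibble::tibble(band = bands$name[b], lo = bands$lo[b], hi = bands$hi[b],
                   session = blocks$session, degree = per_block) |>
      dplyr::group_by(.data$band, .data$lo, .data$hi, .data$session) |>
      dplyr::summarise(mean = mean(.data$degree), sd = stats::sd(.data$degree),
                       n_blocks = dplyr::n(), .groups = "drop")
  })
}
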