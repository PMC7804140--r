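#' Optimal one-to-one assignment of objects between consecutive time points
#'
#' Minimum-total-cost bipartite assignment (not greedy nearest-neighbor)
#' with centroid distance as cost.  A pairing is admissible only if the
#' centroids lie within `max_displacement_px` and the areas agree within
#' `max_log_area_ratio` on the log scale.  Among assignments of maximal
#' cardinality on the admissible edges, the one with minimal total distance
#' is returned (solved as a maximum-weight bipartite matching).
#'
#' @param objects_a,objects_b Object tables (see [measure_objects()]) for
#'   two consecutive time points; empty tables are allowed.
#' @param max_displacement_px Distance gate, pixels (default 30).
#' @param max_log_area_ratio Area-ratio gate on the natural-log scale
#'   (default `log(2)`).
#' @return Data frame `label_a`, `label_b`, `cost` (one row per matched
#'   pair).
#' @export
link_objects <- function(objects_a, objects_b,
                         max_displacement_px = 30,
                         max_log_area_ratio = log(2)) {
  empty <- data.frame(label_a = integer(0), label_b = integer(0),
                      cost = numeric(0))
  na <- nrow(objects_a); nb <- nrow(objects_b)
  if (na == 0 || nb == 0) return(empty)
  d <- sqrt(outer(objects_a$row, objects_b$row, "-")^2 +
              outer(objects_a$col, objects_b$col, "-")^2)
  lr <- abs(outer(log(objects_a$area_px), log(objects_b$area_px), "-"))
  admissible <- d <= max_displacement_px & lr <= max_log_area_ratio
  if (!any(admissible)) return(empty)
  edges <- which(admissible, arr.ind = TRUE)
  # Max-weight matching with weight C - cost, C large enough that any
  # higher-cardinality matching always wins: max cardinality, then min cost.
  C <- max_displacement_px * (min(na, nb) + 1) + 1
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, na), rep(TRUE, nb)),
    edges = as.vector(t(cbind(edges[, 1], na + edges[, 2])))
  )
  w <- C - d[edges]
  m <- igraph::max_bipartite_match(g, weights = w)
  match <- m$matching[seq_len(na)]
  keep <- !is.na(match)
  if (!any(keep)) return(empty)
  ia <- which(keep)
  ib <- match[keep] - na
  out <- data.frame(
    label_a = objects_a$label[ia],
    label_b = objects_b$label[ib],
    cost = d[cbind(ia, ib)]
  )
  out[order(out$label_a), ]
}

#' Build longitudinal islet traces from pairwise assignments
#'
#' Chains the pairwise links between consecutive time points into traces
#' (transitive closure), assigns stable `islet_id`s ordered by (first time
#' point, centroid row, centroid col), and records completeness.  An object
#' left unmatched terminates its trace; an object with no predecessor opens
#' a new one (flagged `merge_suspect` when an admissible but already-taken
#' predecessor existed).
#'
#' @param objects_by_tp List of object tables, one per time point in
#'   temporal order, each carrying a `time_point` column.
#' @param max_displacement_px,max_log_area_ratio Gates for [link_objects()].
#' @return An `islet_traces` object: list with `objects` (row-bound object
#'   tables plus `islet_id`) and `info` (per trace: `islet_id`,
#'   `first_time_point`, `n_points`, `complete`, `merge_suspect`,
#'   `excluded`, `reason`).
#' @export
build_traces <- function(objects_by_tp, max_displacement_px = 30,
                         max_log_area_ratio = log(2)) {
  n_tp <- length(objects_by_tp)
  stopifnot(n_tp >= 1)
  tps <- vapply(objects_by_tp, function(o) {
    if (nrow(o) > 0) o$time_point[1] else NA_real_
  }, numeric(1))
  # trace bookkeeping: per time point, map object label -> trace id
  trace_of <- vector("list", n_tp)
  traces <- list()   # each: list(first_tp_index, members = data.frame(tp_index, label), merge_suspect)
  new_trace <- function(ti, label, merge_suspect = FALSE) {
    traces[[length(traces) + 1]] <<- list(
      first = ti,
      members = data.frame(tp_index = ti, label = label),
      merge_suspect = merge_suspect
    )
    length(traces)
  }
  if (nrow(objects_by_tp[[1]]) > 0) {
    trace_of[[1]] <- setNames(
      vapply(objects_by_tp[[1]]$label, function(l) new_trace(1L, l), numeric(1)),
      objects_by_tp[[1]]$label
    )
  } else trace_of[[1]] <- numeric(0)

  for (ti in seq_len(n_tp - 1)) {
    a <- objects_by_tp[[ti]]
    b <- objects_by_tp[[ti + 1]]
    links <- link_objects(a, b, max_displacement_px, max_log_area_ratio)
    trace_of[[ti + 1]] <- numeric(0)
    if (nrow(b) == 0) next
    # which b objects had at least one admissible predecessor (for the
    # merge_suspect flag on unmatched ones)
    had_candidate <- rep(FALSE, nrow(b))
    if (nrow(a) > 0) {
      d <- sqrt(outer(a$row, b$row, "-")^2 + outer(a$col, b$col, "-")^2)
      lr <- abs(outer(log(a$area_px), log(b$area_px), "-"))
      had_candidate <- apply(d <= max_displacement_px &
                               lr <= max_log_area_ratio, 2, any)
    }
    ids <- numeric(nrow(b))
    for (j in seq_len(nrow(b))) {
      lb <- b$label[j]
      hit <- links$label_a[links$label_b == lb]
      if (length(hit) == 1) {
        tid <- trace_of[[ti]][[as.character(hit)]]
        traces[[tid]]$members <- rbind(traces[[tid]]$members,
                                       data.frame(tp_index = ti + 1L, label = lb))
        ids[j] <- tid
      } else {
        ids[j] <- new_trace(ti + 1L, lb, merge_suspect = had_candidate[j])
      }
    }
    trace_of[[ti + 1]] <- setNames(ids, b$label)
  }

  # stable islet_id ordering: (first time point, centroid row, col)
  first_tp <- vapply(traces, function(t) t$first, numeric(1))
  first_rc <- t(vapply(traces, function(t) {
    o <- objects_by_tp[[t$members$tp_index[1]]]
    i <- match(t$members$label[1], o$label)
    c(o$row[i], o$col[i])
  }, numeric(2)))
  ord <- order(first_tp, first_rc[, 1], first_rc[, 2])
  id_of <- integer(length(traces)); id_of[ord] <- seq_along(traces)

  obj_all <- list()
  for (ti in seq_len(n_tp)) {
    o <- objects_by_tp[[ti]]
    if (nrow(o) == 0) next
    o$islet_id <- id_of[trace_of[[ti]][as.character(o$label)]]
    obj_all[[length(obj_all) + 1]] <- o
  }
  objects <- if (length(obj_all)) do.call(rbind, obj_all) else
    cbind(objects_by_tp[[1]], islet_id = integer(0))
  info <- data.frame(
    islet_id = id_of,
    first_time_point = tps[first_tp],
    n_points = vapply(traces, function(t) nrow(t$members), integer(1)),
    merge_suspect = vapply(traces, function(t) t$merge_suspect, logical(1))
  )
  info$complete <- info$n_points == n_tp
  info$excluded <- rep(FALSE, nrow(info))
  info$reason <- rep(NA_character_, nrow(info))
  info <- info[order(info$islet_id), ]
  rownames(info) <- NULL
  objects <- objects[order(objects$islet_id, objects$time_point), ]
  rownames(objects) <- NULL
  structure(list(objects = objects, info = info, n_time_points = n_tp,
                 time_points = tps),
            class = "islet_traces")
}

#' @export
print.islet_traces <- function(x, ...) {
  cat(sprintf("<islet_traces> %d trace(s) over %d time points; %d complete, %d excluded\n",
              nrow(x$info), x$n_time_points, sum(x$info$complete),
              sum(x$info$excluded)))
  invisible(x)
}

#' Apply artifact-exclusion rules to traces
#'
#' Mirrors the exclusion policy for suspected technical artifacts: a trace
#' is excluded from response statistics if any member object is
#' edge-proximal or saturated, or if the trace does not span every time
#' point.  Excluded traces stay in the table for audit, with the first
#' applicable reason recorded.
#'
#' @param traces An `islet_traces` object.
#' @return The same object with `info$excluded` / `info$reason` filled in
#'   and an `exclusion_counts` attribute (named integer vector).
#' @export
apply_exclusions <- function(traces) {
  info <- traces$info
  obj <- traces$objects
  for (i in seq_len(nrow(info))) {
    id <- info$islet_id[i]
    members <- obj[obj$islet_id == id, ]
    reason <- NULL
    if (any(members$edge_proximal)) reason <- "edge"
    else if (any(members$saturated)) reason <- "saturation"
    else if (!info$complete[i]) reason <- "incomplete"
    if (!is.null(reason)) {
      info$excluded[i] <- TRUE
      info$reason[i] <- reason
    }
  }
  traces$info <- info
  counts <- table(factor(info$reason[info$excluded],
                         levels = c("edge", "saturation", "incomplete")))
  attr(traces, "exclusion_counts") <- setNames(as.integer(counts),
                                               names(counts))
  traces
}
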