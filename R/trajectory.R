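.strand_index <- function(topo, name) {
  k <- match(name, topo$strand_names)
  if (is.na(k))
    stop(sprintf("unknown strand name '%s' (topology has: %s)", name,
                 paste(topo$strand_names, collapse = ", ")), call. = FALSE)
  k
}

# Bonds of `frame` joining strands a and b, as 0-based local 5'->3'
# indices (column 1 on a, column 2 on b). Bonds involving third strands
# are excluded here by construction.
.local_pairs <- function(frame, topo, a, b) {
  sa <- .strand_index(topo, a); sb <- .strand_index(topo, b)
  p <- frame$pairs
  if (!nrow(p)) return(matrix(integer(0), ncol = 2))
  if (any(p < 0L | p >= topo$n_nucleotides))
    stop("frame contains a nucleotide index outside the topology",
         call. = FALSE)
  s1 <- topo$strand_of[p[, 1] + 1L]; s2 <- topo$strand_of[p[, 2] + 1L]
  fwd <- s1 == sa & s2 == sb
  rev <- s1 == sb & s2 == sa
  rbind(cbind(topo$local_index[p[fwd, 1] + 1L], topo$local_index[p[fwd, 2] + 1L]),
        cbind(topo$local_index[p[rev, 2] + 1L], topo$local_index[p[rev, 1] + 1L]))
}

# Longest antiparallel run in a set of (x, y) index pairs: consecutive
# bonds (x + k, y - k) keep x + y constant, so group by the anti-diagonal
# and look for the longest stretch of consecutive x. Returns the run
# length and the (x, y) of its first bond.
.longest_antiparallel_run <- function(pairs) {
  if (!nrow(pairs)) return(list(length = 0L, start = NULL))
  best <- 0L; best_start <- NULL
  for (s in unique(pairs[, 1] + pairs[, 2])) {
    x <- sort(unique(pairs[pairs[, 1] + pairs[, 2] == s, 1]))
    for (g in split(x, cumsum(c(1L, diff(x) != 1L)))) {
      if (length(g) > best) {
        best <- length(g)
        best_start <- c(g[1], s - g[1])
      }
    }
  }
  list(length = as.integer(best), start = best_start)
}

#' Per-frame MCO and TMO between two strands
#'
#' Applies the sequence-level overlap metrics to one recorded frame of
#' hydrogen bonds: TMO is the number of bonds joining strands `a` and `b`
#' (bonds either strand forms with third strands are ignored), and MCO is
#' the longest run of bonds in strict antiparallel register, i.e. local
#' positions `(i + k, j - k)` in each strand's 5'->3' indexing. Bonds in
#' any other geometry count toward TMO only, consistent with the
#' sequence-level definition.
#'
#' @param frame an `hb_frame`.
#' @param topo a `topology`.
#' @param a,b strand names; must differ (see [self_fold()] for
#'   intra-strand pairing).
#' @return Named integer vector `c(mco = , tmo = )`.
#' @export
frame_pair_overlap <- function(frame, topo, a, b) {
  if (identical(a, b))
    stop("a and b must be different strands; use self_fold() for intra-strand pairing",
         call. = FALSE)
  lp <- .local_pairs(frame, topo, a, b)
  c(mco = .longest_antiparallel_run(lp)$length, tmo = nrow(lp))
}

#' Reduce a frame sequence to a per-pair overlap time series
#'
#' @param frames list of `hb_frame` objects.
#' @param topo a `topology`.
#' @param a,b strand names.
#' @return A `pair_trace`: fields `pair`, `steps`, `mco`, `tmo`.
#' @export
pair_trace <- function(frames, topo, a, b) {
  ov <- vapply(frames, frame_pair_overlap, integer(2), topo = topo,
               a = a, b = b)
  structure(list(pair = c(a, b),
                 steps = vapply(frames, `[[`, numeric(1), "step"),
                 mco = unname(ov[1, ]), tmo = unname(ov[2, ])),
            class = "pair_trace")
}

#' @export
print.pair_trace <- function(x, ...) {
  cat(sprintf("<pair_trace> %s-%s: %d frames, bound fraction %.3f, max MCO %d\n",
              x$pair[1], x$pair[2], length(x$mco),
              mean(x$mco > 0), if (length(x$mco)) max(x$mco) else 0L))
  invisible(x)
}

#' Pooled MCO/TMO probability histogram
#'
#' Pools frames from one or more runs of the same strand pair with equal
#' weight per frame and tabulates the probability of each MCO and TMO
#' value. The value 0 encodes "not bonded" and is always present as a
#' bin, so the unbound fraction can be read directly off the histogram.
#'
#' @param traces a `pair_trace` or list of them (one per run).
#' @return An `overlap_histogram`: `p_mco` and `p_tmo` (probability
#'   vectors named by value), matching `counts_mco`/`counts_tmo`,
#'   `n_frames_total` and `n_runs`.
#' @export
overlap_histogram <- function(traces) {
  if (inherits(traces, "pair_trace")) traces <- list(traces)
  if (!length(traces)) stop("no traces supplied", call. = FALSE)
  mco <- unlist(lapply(traces, `[[`, "mco"))
  tmo <- unlist(lapply(traces, `[[`, "tmo"))
  if (!length(mco)) stop("traces contain no frames", call. = FALSE)
  tab <- function(v) {
    lev <- 0:max(v, 0L)
    cnt <- table(factor(v, levels = lev))
    setNames(as.integer(cnt), lev)
  }
  cm <- tab(mco); ct <- tab(tmo)
  structure(list(pair = traces[[1]]$pair,
                 p_mco = cm / length(mco), p_tmo = ct / length(tmo),
                 counts_mco = cm, counts_tmo = ct,
                 n_frames_total = length(mco), n_runs = length(traces)),
            class = "overlap_histogram")
}

#' @export
print.overlap_histogram <- function(x, ...) {
  cat(sprintf("<overlap_histogram> %s-%s: %d frames over %d run(s)\n",
              x$pair[1], x$pair[2], x$n_frames_total, x$n_runs))
  print(data.frame(value = as.integer(names(x$p_mco)),
                   p_mco = round(unname(x$p_mco), 4),
                   p_tmo = round(unname(c(x$p_tmo,
                     rep(0, max(0, length(x$p_mco) - length(x$p_tmo)))))[
                       seq_along(x$p_mco)], 4)))
  invisible(x)
}

#' Ensemble-averaged MCO/TMO time series
#'
#' Pointwise mean over independent runs sharing the same step grid.
#' Smoothing is off by default; when `smooth_window` is given, a centred
#' moving average of that many frames is applied.
#'
#' @param traces list of `pair_trace` objects with identical `steps`.
#' @param smooth_window optional odd integer window (frames).
#' @return data.frame with columns `step`, `mean_mco`, `mean_tmo` and the
#'   number of runs as attribute `n_runs`.
#' @export
ensemble_timeseries <- function(traces, smooth_window = NULL) {
  if (inherits(traces, "pair_trace")) traces <- list(traces)
  stopifnot(length(traces) >= 1L)
  steps <- traces[[1]]$steps
  for (tr in traces)
    if (!identical(tr$steps, steps))
      stop("traces are on different step grids; resample onto a common grid first",
           call. = FALSE)
  m <- rowMeans(do.call(cbind, lapply(traces, `[[`, "mco")))
  t <- rowMeans(do.call(cbind, lapply(traces, `[[`, "tmo")))
  if (!is.null(smooth_window)) {
    k <- rep(1 / smooth_window, smooth_window)
    m <- as.numeric(stats::filter(m, k, sides = 2))
    t <- as.numeric(stats::filter(t, k, sides = 2))
  }
  out <- data.frame(step = steps, mean_mco = m, mean_tmo = t)
  attr(out, "n_runs") <- length(traces)
  out
}

#' Binding events and their lifetimes
#'
#' A binding event is a maximal run of consecutive frames whose MCO is at
#' or above `threshold`. The default threshold of 4 consecutive paired
#' bases is the minimum for an effective attachment between two strands:
#' with fewer bases the duplex does not bend and its bonds break easily.
#' `end_step` is exclusive (the step at which the next frame falls below
#' threshold), so `lifetime_steps = end_step - start_step` equals the
#' event's frame count times the recording interval. Events touching
#' either end of the trace are censored: their lifetime is only a lower
#' bound.
#'
#' @param trace a `pair_trace`.
#' @param threshold minimum MCO for a frame to count as bound.
#' @param record_interval MD steps between frames; inferred from the step
#'   stamps when the trace has more than one frame.
#' @return data.frame with columns `start_step`, `end_step`,
#'   `lifetime_steps`, `n_frames`, `censored_left`, `censored_right`;
#'   attributes `pair` and `threshold`.
#' @export
binding_events <- function(trace, threshold = 4L, record_interval = NULL) {
  stopifnot(threshold >= 1L)
  n <- length(trace$mco)
  if (is.null(record_interval))
    record_interval <- if (n > 1L) trace$steps[2] - trace$steps[1] else 1000
  bound <- trace$mco >= threshold
  runs <- rle(bound)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  hit <- which(runs$values)
  out <- data.frame(
    start_step = trace$steps[starts[hit]],
    end_step = trace$steps[ends[hit]] + record_interval,
    n_frames = runs$lengths[hit],
    censored_left = starts[hit] == 1L,
    censored_right = ends[hit] == n)
  out$lifetime_steps <- out$end_step - out$start_step
  out <- out[, c("start_step", "end_step", "lifetime_steps", "n_frames",
                 "censored_left", "censored_right")]
  attr(out, "pair") <- trace$pair
  attr(out, "threshold") <- threshold
  out
}

.composition_label <- function(species) {
  cnt <- table(species)
  cnt <- cnt[order(names(cnt))]
  paste(ifelse(cnt > 1L, paste0(cnt, "x", names(cnt)), names(cnt)),
        collapse = "+")
}

.size_class <- function(k) {
  if (k <= 4L) c("monomer", "dimer", "trimer", "tetramer")[k]
  else sprintf("%d-mer", k)
}

#' Connected multi-strand complexes in one frame
#'
#' Builds the strand-contact graph of one frame -- an edge between two
#' strands when their pair statistic meets `min_edge` -- and labels its
#' connected components by species composition. The default edge rule
#' (TMO >= 1) admits weakly attached "parasite" strands that hold on via
#' only a few bonds; use `edge_stat = "mco"` with a higher `min_edge` for
#' stricter, effective-attachment complexes.
#'
#' @param frame an `hb_frame`.
#' @param topo a `topology`.
#' @param edge_stat `"tmo"` or `"mco"`.
#' @param min_edge minimum value of the chosen statistic for an edge.
#' @param species optional character vector (one per strand) giving the
#'   species of each strand, so replicate strands such as two resource
#'   copies share a label; defaults to the strand names themselves.
#' @return List with `components` (data.frame: `component`, `members`,
#'   `size`, `size_class`, `composition`) and `edges` (data.frame:
#'   `a`, `b`, `mco`, `tmo`); components are ordered by their first
#'   strand's topology index.
#' @export
detect_complexes <- function(frame, topo, edge_stat = c("tmo", "mco"),
                             min_edge = 1L, species = NULL) {
  edge_stat <- match.arg(edge_stat)
  nm <- topo$strand_names
  if (is.null(species)) species <- nm
  stopifnot(length(species) == length(nm))
  edges <- data.frame(a = character(), b = character(),
                      mco = integer(), tmo = integer())
  if (topo$n_strands >= 2L) {
    for (i in seq_len(topo$n_strands - 1L)) for (j in (i + 1L):topo$n_strands) {
      ov <- frame_pair_overlap(frame, topo, nm[i], nm[j])
      if (ov["tmo"] > 0L)
        edges <- rbind(edges, data.frame(a = nm[i], b = nm[j],
                                         mco = ov[["mco"]], tmo = ov[["tmo"]]))
    }
  }
  keep <- edges[[edge_stat]] >= min_edge
  g <- igraph::graph_from_data_frame(edges[keep, c("a", "b"), drop = FALSE],
                                     directed = FALSE,
                                     vertices = data.frame(name = nm))
  memb <- igraph::components(g)$membership[nm]
  comp_ids <- unique(memb)                    # first-appearance order = nm order
  comps <- do.call(rbind, lapply(seq_along(comp_ids), function(k) {
    idx <- which(memb == comp_ids[k])
    data.frame(component = k,
               members = paste(nm[idx], collapse = ","),
               size = length(idx),
               size_class = .size_class(length(idx)),
               composition = .composition_label(species[idx]))
  }))
  rownames(comps) <- NULL
  list(components = comps, edges = edges)
}

#' Complex occupancy across a trajectory
#'
#' Runs [detect_complexes()] on every frame and tallies how often each
#' species composition occurs, as a fraction of all components observed
#' (a simple per-frame tally, so the fractions sum to 1).
#'
#' @inheritParams detect_complexes
#' @param frames list of `hb_frame` objects.
#' @return List with `per_frame` (list of per-frame component tables) and
#'   `occupancy` (data.frame: `composition`, `n`, `fraction`).
#' @export
complex_report <- function(frames, topo, edge_stat = c("tmo", "mco"),
                           min_edge = 1L, species = NULL) {
  edge_stat <- match.arg(edge_stat)
  per_frame <- lapply(frames, function(fr)
    detect_complexes(fr, topo, edge_stat, min_edge, species)$components)
  comp <- unlist(lapply(per_frame, `[[`, "composition"))
  tab <- sort(table(comp), decreasing = TRUE)
  occupancy <- data.frame(composition = names(tab), n = as.integer(tab),
                          fraction = as.numeric(tab) / sum(tab))
  list(per_frame = per_frame, occupancy = occupancy)
}

#' Intra-strand self-folding in one frame
#'
#' Counts hydrogen bonds a strand forms with itself. Only pairs separated
#' by more than `min_loop` bases along the backbone are counted (a
#' shorter separation cannot close a physical hairpin loop). Reports the
#' longest antiparallel run of such pairs and the length of the loop it
#' closes: for a run whose innermost pair is `(i, j)`, the loop is the
#' `j - i - 1` unpaired bases between them.
#'
#' @param frame an `hb_frame`.
#' @param topo a `topology`.
#' @param strand strand name.
#' @param min_loop minimum backbone separation minus one; pairs `(i, j)`
#'   with `j - i <= min_loop` are excluded.
#' @return List with `strand`, `n_pairs`, `longest_run`, `loop_length`
#'   (NA when no run exists).
#' @export
self_fold <- function(frame, topo, strand, min_loop = 3L) {
  s <- .strand_index(topo, strand)
  p <- frame$pairs
  keep <- if (nrow(p)) topo$strand_of[p[, 1] + 1L] == s &
                       topo$strand_of[p[, 2] + 1L] == s else logical(0)
  lp <- cbind(topo$local_index[p[keep, 1] + 1L],
              topo$local_index[p[keep, 2] + 1L])
  if (nrow(lp)) {
    lp <- cbind(pmin(lp[, 1], lp[, 2]), pmax(lp[, 1], lp[, 2]))
    lp <- lp[lp[, 2] - lp[, 1] > min_loop, , drop = FALSE]
  }
  run <- .longest_antiparallel_run(lp)
  loop <- NA_integer_
  if (run$length > 0L) {
    i_inner <- run$start[1] + run$length - 1L
    j_inner <- run$start[2] - run$length + 1L
    loop <- as.integer(j_inner - i_inner - 1L)
  }
  list(strand = strand, n_pairs = nrow(lp), longest_run = run$length,
       loop_length = loop)
}

#' Write a histogram, time series or event table to TSV
#'
#' @param x an `overlap_histogram`, `ensemble_timeseries` data.frame or
#'   [binding_events()] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(x, path) {
  con <- file(path, "w"); on.exit(close(con))
  if (inherits(x, "overlap_histogram")) {
    writeLines(c(sprintf("# MCO/TMO histogram: %s-%s (%d frames, %d runs)",
                         x$pair[1], x$pair[2], x$n_frames_total, x$n_runs),
                 "# value 0 = not bonded"), con)
    vals <- sort(unique(c(as.integer(names(x$p_mco)),
                          as.integer(names(x$p_tmo)))))
    at <- function(p, v) ifelse(is.na(p[as.character(v)]), 0,
                                p[as.character(v)])
    tab <- data.frame(value = vals, p_mco = as.numeric(at(x$p_mco, vals)),
                      p_tmo = as.numeric(at(x$p_tmo, vals)))
    write.table(format(tab, scientific = FALSE), con, sep = "\t",
                quote = FALSE, row.names = FALSE)
  } else {
    write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
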