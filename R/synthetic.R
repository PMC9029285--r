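#' Kinetic model for one strand pair
#'
#' Describes the stationary binding behaviour of one strand pair in the
#' synthetic trajectory generator: the pair alternates between unbound
#' sojourns and bound sojourns (both geometric in frame units). At the
#' start of each bound sojourn a run length is drawn from `p_run`
#' (probabilities conditional on nothing -- they and `p_unbound` sum to
#' 1), one of the pair's degenerate omega-windows is drawn from
#' `window_weights`, and the run is placed uniformly at random inside the
#' window. The run is held fixed for the sojourn, so the stationary
#' MCO distribution of the generated frames is exactly `p_unbound` at 0
#' and `p_run` elsewhere. Isolated extra complementary pairs outside the
#' run (never adjacent to it or to each other) are added per frame with
#' rate `extra_pair_rate`, realizing TMO > MCO without disturbing MCO.
#'
#' Unbound sojourns get mean length `dwell_bound * p_unbound / (1 -
#' p_unbound)` frames so that the long-run bound fraction equals
#' `1 - p_unbound`.
#'
#' @param a,b strand names of the pair.
#' @param p_unbound stationary probability of the unbound state.
#' @param p_run named numeric vector: run length (as name) to stationary
#'   probability; run lengths must not exceed the pair's omega.
#' @param dwell_bound mean bound-sojourn length in frames (geometric).
#' @param window_weights optional numeric weights over the pair's
#'   omega-windows (in the deterministic window order); uniform when NULL.
#' @param extra_pair_rate per-candidate-site probability of an isolated
#'   extra pair in a bound frame.
#' @return A `pair_kinetics` object.
#' @export
pair_kinetics <- function(a, b, p_unbound, p_run, dwell_bound = 50,
                          window_weights = NULL, extra_pair_rate = 0) {
  stopifnot(p_unbound >= 0, p_unbound <= 1, dwell_bound >= 1,
            extra_pair_rate >= 0, extra_pair_rate <= 1)
  if (length(p_run) && (is.null(names(p_run)) ||
      anyNA(suppressWarnings(as.integer(names(p_run))))))
    stop("'p_run' must be named by integer run lengths", call. = FALSE)
  if (abs(p_unbound + sum(p_run) - 1) > 1e-9)
    stop("p_unbound + sum(p_run) must equal 1", call. = FALSE)
  structure(list(a = a, b = b, p_unbound = p_unbound, p_run = p_run,
                 dwell_bound = dwell_bound, window_weights = window_weights,
                 extra_pair_rate = extra_pair_rate),
            class = "pair_kinetics")
}

#' Scenario configuration for the synthetic generator
#'
#' @param oligos named list of `oligomer` objects (the strand set).
#' @param kinetics list of [pair_kinetics()], one per interacting pair;
#'   list order is the priority order used to resolve one-bond-per-base
#'   conflicts between pairs sharing a strand.
#' @param n_frames number of recorded frames to generate.
#' @param record_interval MD steps between frames (step stamps are
#'   `0, record_interval, 2*record_interval, ...`).
#' @param rng_seed integer seed; output is fully deterministic given it.
#' @param exclusions optional list of shared-window exclusion rules, each
#'   `list(winner = c(a, b), loser = c(a, b), shared = strand)`: whenever
#'   the winner pair's current run occupies bases on `shared` that
#'   intersect the loser pair's current run, the loser is forced unbound
#'   for that frame (the exclusion is logged).
#' @return A `scenario_config` object.
#' @export
scenario_config <- function(oligos, kinetics, n_frames,
                            record_interval = 1000L, rng_seed = 1L,
                            exclusions = NULL) {
  oligos <- lapply(oligos, as_oligomer)
  if (is.null(names(oligos)) || any(!nzchar(names(oligos))))
    names(oligos) <- vapply(oligos, `[[`, character(1), "name")
  stopifnot(n_frames >= 1L)
  for (kin in kinetics)
    if (!all(c(kin$a, kin$b) %in% names(oligos)))
      stop(sprintf("kinetics for pair %s-%s references undefined strand(s)",
                   kin$a, kin$b), call. = FALSE)
  structure(list(oligos = oligos, kinetics = kinetics,
                 n_frames = as.integer(n_frames),
                 record_interval = as.integer(record_interval),
                 rng_seed = as.integer(rng_seed), exclusions = exclusions),
            class = "scenario_config")
}

# Geometric sojourn length with mean d (support 1, 2, ...).
.rdwell <- function(d) 1L + rgeom(1L, prob = 1 / d)

# Alternating bound/unbound sojourn sequence covering n frames.
# Returns a data.frame of sojourns with per-sojourn run draw.
.sim_pair_sojourns <- function(kin, prof, n_frames) {
  omega <- prof$omega
  n_win <- nrow(prof$windows)
  if (length(kin$p_run)) {
    runs <- as.integer(names(kin$p_run))
    if (any(runs < 1L) || any(runs > omega))
      stop(sprintf("pair %s-%s: configured run length outside 1..omega = %d",
                   kin$a, kin$b, omega), call. = FALSE)
    if (n_win == 0L)
      stop(sprintf("pair %s-%s has no omega-window to bind at", kin$a, kin$b),
           call. = FALSE)
  }
  ww <- kin$window_weights
  if (!is.null(ww) && length(ww) != n_win)
    stop(sprintf("pair %s-%s: %d window weight(s) for %d omega-window(s)",
                 kin$a, kin$b, length(ww), n_win), call. = FALSE)
  if (is.null(ww)) ww <- rep(1, max(n_win, 1L))

  dwell_b <- kin$dwell_bound
  p_u <- kin$p_unbound
  dwell_u <- if (p_u <= 0) Inf else if (p_u >= 1) Inf
             else dwell_b * p_u / (1 - p_u)

  soj <- list()
  filled <- 0L
  bound <- if (p_u >= 1) FALSE else if (p_u <= 0) TRUE
           else runif(1L) < (1 - p_u)
  while (filled < n_frames) {
    if (bound) {
      len <- if (p_u <= 0) n_frames else .rdwell(dwell_b)
      m <- as.integer(names(kin$p_run)[
        sample.int(length(kin$p_run), 1L, prob = kin$p_run / sum(kin$p_run))])
      widx <- if (n_win > 1L) sample.int(n_win, 1L, prob = ww)
              else if (n_win == 1L) 1L else NA_integer_
      offset <- if (omega > m) sample.int(omega - m + 1L, 1L) - 1L else 0L
    } else {
      len <- if (p_u >= 1) n_frames else .rdwell(dwell_u)
      m <- 0L; widx <- NA_integer_; offset <- NA_integer_
    }
    len <- min(len, n_frames - filled)
    soj[[length(soj) + 1L]] <- data.frame(
      state = if (bound) "bound" else "unbound",
      start_frame = filled + 1L, n_frames = len,
      run_length = m, window = widx, offset = offset)
    filled <- filled + len
    bound <- !bound
  }
  do.call(rbind, soj)
}

# Bond matrix (global indices) for a run of length m at `offset` inside
# window `win` of the pair's profile.
.run_bonds <- function(win, m, offset, ga, gb) {
  q <- win$start1 + offset + seq_len(m) - 1L             # local on a
  j <- win$start2 + (win$length - 1L) - (q - win$start1) # local on b
  cbind(ga + q, gb + j)
}

#' Generate a synthetic hydrogen-bond trajectory
#'
#' Draws per-pair alternating bound/unbound sojourns from the configured
#' kinetics (independent pairs), turns them into per-frame bond lists at
#' the pair's omega-windows, applies shared-window exclusion rules, and
#' resolves residual one-bond-per-base conflicts between pairs in
#' configuration order (earlier pairs win; dropped bonds are logged).
#' Every generated bond is canonical given the sequences, and every
#' state visit is recorded in a ground-truth log so that downstream
#' statistics can be checked against known parameters.
#'
#' @param config a [scenario_config()].
#' @return List with `topology`, `frames` (list of `hb_frame`), `truth`
#'   (list: `sojourns` data.frame, `exclusions`, `conflicts`) and
#'   `config`.
#' @export
generate_trajectory <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$rng_seed)
  topo <- make_topology(config$oligos)
  lens <- vapply(config$oligos, `[[`, integer(1), "length")
  gstart <- setNames(cumsum(c(0L, lens))[seq_along(lens)], names(config$oligos))
  n <- config$n_frames

  pairs_meta <- lapply(config$kinetics, function(kin) {
    prof <- overlap_profile(config$oligos[[kin$a]], config$oligos[[kin$b]])
    # complementary sites along each window's register, for extra pairs
    pm <- .pair_matrix(config$oligos[[kin$a]], config$oligos[[kin$b]])
    sites <- lapply(seq_len(nrow(prof$windows)), function(w) {
      r <- prof$windows$r[w]
      i <- seq.int(max(0L, r), min(lens[kin$a] - 1L, r + lens[kin$b] - 1L))
      i[pm[cbind(i + 1L, i - r + 1L)]]
    })
    list(kin = kin, prof = prof, extra_sites = sites,
         soj = .sim_pair_sojourns(kin, prof, n))
  })

  # per-frame sojourn lookup per pair
  soj_of <- lapply(pairs_meta, function(p)
    rep(seq_len(nrow(p$soj)), p$soj$n_frames))

  pair_key <- vapply(pairs_meta, function(p)
    paste(p$kin$a, p$kin$b, sep = "-"), character(1))

  # run's local positions on one strand of the pair
  run_span <- function(p, s, strand) {
    win <- p$prof$windows[s$window, ]
    if (strand == p$kin$a)
      win$start1 + s$offset + seq_len(s$run_length) - 1L
    else
      win$start2 + (win$length - 1L) - (s$offset + seq_len(s$run_length) - 1L)
  }

  frames <- vector("list", n)
  excl_log <- list()
  confl_log <- list()
  steps <- as.numeric(seq_len(n) - 1L) * config$record_interval

  for (f in seq_len(n)) {
    states <- lapply(seq_along(pairs_meta), function(k)
      pairs_meta[[k]]$soj[soj_of[[k]][f], ])
    masked <- rep(FALSE, length(pairs_meta))

    for (rule in config$exclusions) {
      kw <- match(paste(rule$winner, collapse = "-"), pair_key)
      kl <- match(paste(rule$loser, collapse = "-"), pair_key)
      if (is.na(kw) || is.na(kl))
        stop("exclusion rule references a pair without kinetics", call. = FALSE)
      if (masked[kw] || masked[kl]) next
      sw <- states[[kw]]; sl <- states[[kl]]
      if (sw$state == "bound" && sl$state == "bound" &&
          length(intersect(run_span(pairs_meta[[kw]], sw, rule$shared),
                           run_span(pairs_meta[[kl]], sl, rule$shared)))) {
        masked[kl] <- TRUE
        excl_log[[length(excl_log) + 1L]] <-
          data.frame(frame = f, pair = pair_key[kl])
      }
    }

    occupied <- rep(FALSE, topo$n_nucleotides)
    bonds <- list()
    for (k in seq_along(pairs_meta)) {
      s <- states[[k]]
      if (masked[k] || s$state != "bound") next
      p <- pairs_meta[[k]]
      win <- p$prof$windows[s$window, ]
      ga <- gstart[[p$kin$a]]; gb <- gstart[[p$kin$b]]
      b <- .run_bonds(win, s$run_length, s$offset, ga, gb)
      if (p$kin$extra_pair_rate > 0) {
        run_lo <- win$start1 + s$offset
        run_hi <- run_lo + s$run_length - 1L
        cand <- p$extra_sites[[s$window]]
        cand <- cand[cand < run_lo - 1L | cand > run_hi + 1L]
        cand <- cand[runif(length(cand)) < p$kin$extra_pair_rate]
        if (length(cand) > 1L)           # keep extras pairwise non-adjacent
          cand <- cand[c(TRUE, diff(cand) > 1L)]
        if (length(cand)) {
          r <- win$r
          j <- lens[p$kin$b] - 1L - (cand - r)
          b <- rbind(b, cbind(ga + cand, gb + j))
        }
      }
      free <- !occupied[b[, 1] + 1L] & !occupied[b[, 2] + 1L]
      if (any(!free))
        confl_log[[length(confl_log) + 1L]] <-
          data.frame(frame = f, pair = pair_key[k], n_dropped = sum(!free))
      b <- b[free, , drop = FALSE]
      occupied[c(b) + 1L] <- TRUE
      bonds[[length(bonds) + 1L]] <- b
    }
    pairs_mat <- if (length(bonds)) do.call(rbind, bonds)
                 else matrix(integer(0), ncol = 2)
    frames[[f]] <- hb_frame(steps[f], pairs_mat)
  }

  sojourns <- do.call(rbind, lapply(seq_along(pairs_meta), function(k)
    cbind(pair = pair_key[k], pairs_meta[[k]]$soj)))
  rownames(sojourns) <- NULL
  empty_log <- data.frame(frame = integer(), pair = character())
  list(topology = topo, frames = frames,
       truth = list(
         sojourns = sojourns,
         exclusions = if (length(excl_log)) do.call(rbind, excl_log)
                      else empty_log,
         conflicts = if (length(confl_log)) do.call(rbind, confl_log)
                     else cbind(empty_log, n_dropped = integer())),
       config = config)
}

#' Generate a competition trajectory with shared-window exclusion
#'
#' Wrapper around [generate_trajectory()] for configurations in which
#' two predator pairs contend for overlapping bases of a shared resource
#' strand. Validates that each exclusion rule's two pairs actually have
#' omega-windows overlapping on the shared strand (warning otherwise:
#' there is no exclusion to emulate).
#'
#' @param config a [scenario_config()] with non-empty `exclusions`.
#' @return As [generate_trajectory()].
#' @export
generate_competition <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  if (!length(config$exclusions))
    stop("competition configuration needs at least one exclusion rule",
         call. = FALSE)
  span_on <- function(pair, shared) {
    prof <- overlap_profile(config$oligos[[pair[1]]], config$oligos[[pair[2]]])
    unlist(lapply(seq_len(nrow(prof$windows)), function(w) {
      win <- prof$windows[w, ]
      if (shared == pair[1]) win$start1 + seq_len(win$length) - 1L
      else win$start2 + seq_len(win$length) - 1L
    }))
  }
  for (rule in config$exclusions) {
    if (!length(intersect(span_on(rule$winner, rule$shared),
                          span_on(rule$loser, rule$shared))))
      warning(sprintf("pairs %s and %s have no overlapping window on '%s': no exclusion to emulate",
                      paste(rule$winner, collapse = "-"),
                      paste(rule$loser, collapse = "-"), rule$shared),
              call. = FALSE)
  }
  generate_trajectory(config)
}

#' Shipped scenario presets
#'
#' Ready-made configurations over the bundled predator/resource strands
#' (see [builtin_oligomers()]), with stationary binding probabilities
#' chosen to echo the MD behaviour of each pair: `"p4res"` (weak,
#' short-lived binding: unbound 25% of frames, full omega-run 60%),
#' `"p10res"` (strong binding: omega-run 55%, omega-1 run 30%),
#' `"p4p10"` (predator-predator binding at omega = 7), and
#' `"competition3"` (all three strands; the two predators' omega-windows
#' overlap on the resource, and the p10-res pair excludes p4-res from the
#' shared bases).
#'
#' @param name preset name.
#' @param n_frames frames to generate (default 10000).
#' @param rng_seed integer seed.
#' @return A [scenario_config()].
#' @export
scenario_preset <- function(name = c("p4res", "p10res", "p4p10",
                                     "competition3"),
                            n_frames = 10000L, rng_seed = 1L) {
  name <- match.arg(name)
  oli <- builtin_oligomers()
  kin_p4res <- pair_kinetics("p4", "res", p_unbound = 0.25,
                             p_run = c(`4` = 0.60, `3` = 0.05, `2` = 0.05,
                                       `1` = 0.05),
                             dwell_bound = 10, extra_pair_rate = 0.15)
  kin_p10res <- pair_kinetics("p10", "res", p_unbound = 0.15,
                              p_run = c(`10` = 0.55, `9` = 0.30),
                              dwell_bound = 50, extra_pair_rate = 0.05)
  kin_p4p10 <- pair_kinetics("p4", "p10", p_unbound = 0.20,
                             p_run = c(`7` = 0.55, `5` = 0.15, `4` = 0.10),
                             dwell_bound = 30, extra_pair_rate = 0.10)
  switch(name,
    p4res = scenario_config(oli[c("p4", "res")], list(kin_p4res),
                            n_frames, rng_seed = rng_seed),
    p10res = scenario_config(oli[c("p10", "res")], list(kin_p10res),
                             n_frames, rng_seed = rng_seed),
    p4p10 = scenario_config(oli[c("p4", "p10")], list(kin_p4p10),
                            n_frames, rng_seed = rng_seed),
    competition3 = scenario_config(
      oli[c("p4", "p10", "res")],
      list(pair_kinetics("p10", "res", p_unbound = 0.25,
                         p_run = c(`10` = 0.50, `9` = 0.25),
                         dwell_bound = 50, extra_pair_rate = 0.05),
           kin_p4res,
           pair_kinetics("p4", "p10", p_unbound = 0.75,
                         p_run = c(`7` = 0.10, `5` = 0.15),
                         dwell_bound = 30, extra_pair_rate = 0.05)),
      n_frames, rng_seed = rng_seed,
      exclusions = list(list(winner = c("p10", "res"),
                             loser = c("p4", "res"), shared = "res"))))
}

#' Write a synthetic scenario to oxDNA-dialect fixture files
#'
#' Generates the trajectory and writes a topology file, a hydrogen-bond
#' pair-list file, a minimal configuration file and a JSON ground-truth
#' log into `out_dir`. Reading the files back reproduces the in-memory
#' objects; output bytes are stable under a fixed seed.
#'
#' @param config a [scenario_config()].
#' @param out_dir output directory (created if missing).
#' @return Named character vector of file paths (`topology`, `pairs`,
#'   `configuration`, `truth`), invisibly returning the generated
#'   trajectory as attribute `sim`.
#' @export
make_fixture_files <- function(config, out_dir) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  sim <- generate_trajectory(config)
  paths <- c(topology = file.path(out_dir, "topology.top"),
             pairs = file.path(out_dir, "bonds.hb"),
             configuration = file.path(out_dir, "init.conf"),
             truth = file.path(out_dir, "truth.json"))
  write_topology(sim$topology, paths["topology"])
  write_hb_frames(sim$frames, paths["pairs"])
  write_configuration(sim$topology, paths["configuration"], step = 0,
                      box = 40)
  jsonlite::write_json(list(
    rng_seed = config$rng_seed,
    n_frames = config$n_frames,
    record_interval = config$record_interval,
    strands = lapply(config$oligos, function(o)
      list(name = o$name, seq = o$seq)),
    sojourns = sim$truth$sojourns,
    exclusions = sim$truth$exclusions,
    conflicts = sim$truth$conflicts), paths["truth"],
    auto_unbox = TRUE, digits = NA)
  attr(paths, "sim") <- sim
  invisible(paths)
}
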