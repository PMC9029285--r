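#' Simulation unit constants
#'
#' Conversion constants for the coarse-grained MD output the analysis
#' consumes: one MD timestep of 0.005 simulation time units corresponds to
#' roughly 15 fs of physical time, observables are recorded every 1000
#' steps, and one simulation length unit is 34.072/40 nm.
#'
#' @param dt_steps MD timestep in simulation units.
#' @param fs_per_step physical femtoseconds per MD step.
#' @param record_interval MD steps between recorded frames.
#' @param nm_per_length_unit nanometres per simulation length unit.
#' @return A `sim_units` list.
#' @export
sim_units <- function(dt_steps = 0.005, fs_per_step = 15,
                      record_interval = 1000L,
                      nm_per_length_unit = 34.072 / 40) {
  stopifnot(dt_steps > 0, fs_per_step > 0, record_interval > 0,
            nm_per_length_unit > 0)
  structure(list(dt_steps = dt_steps, fs_per_step = fs_per_step,
                 record_interval = as.integer(record_interval),
                 nm_per_length_unit = nm_per_length_unit),
            class = "sim_units")
}

#' Convert MD step counts to physical time
#'
#' @param steps non-negative MD step count.
#' @param unit output unit: femto/pico/nano/microseconds.
#' @param units a [sim_units()] object supplying fs per step.
#' @return Numeric time in the requested unit (e.g. 1e8 steps is about
#'   1.5 microseconds).
#' @export
steps_to_time <- function(steps, unit = c("us", "ns", "ps", "fs"),
                          units = sim_units()) {
  unit <- match.arg(unit)
  if (any(steps < 0)) stop("'steps' must be non-negative", call. = FALSE)
  fs <- steps * units$fs_per_step
  fs / switch(unit, fs = 1, ps = 1e3, ns = 1e6, us = 1e9)
}

#' Build a topology from a set of oligomers
#'
#' Assigns global nucleotide indices 0..N-1 strand by strand in 5'->3'
#' order and records each nucleotide's 3' and 5' backbone neighbours
#' (-1 at the strand ends), the in-memory equivalent of a topology file.
#'
#' @param oligos list of `oligomer` objects (or sequences); names become
#'   the strand names.
#' @return An object of class `topology` with fields `n_nucleotides`,
#'   `n_strands`, `records` (data.frame: strand_id, base, neighbor_3,
#'   neighbor_5), `strand_of`, `local_index` (both indexed by global index
#'   + 1), `strand_names` and `strand_seqs`.
#' @export
make_topology <- function(oligos) {
  oligos <- lapply(oligos, as_oligomer)
  if (is.null(names(oligos)) || any(!nzchar(names(oligos))))
    names(oligos) <- vapply(oligos, `[[`, character(1), "name")
  lens <- vapply(oligos, `[[`, integer(1), "length")
  n <- sum(lens)
  strand_id <- rep(seq_along(oligos), lens)
  local <- unname(unlist(lapply(lens, function(k) seq_len(k) - 1L)))
  g <- seq_len(n) - 1L                          # global 0-based
  starts <- cumsum(c(0L, lens))[seq_along(lens)]
  n5 <- ifelse(local == 0L, -1L, g - 1L)
  n3 <- ifelse(local == lens[strand_id] - 1L, -1L, g + 1L)
  records <- data.frame(
    strand_id = strand_id,
    base = unlist(lapply(oligos, function(o) strsplit(o$seq, "")[[1]])),
    neighbor_3 = as.integer(n3), neighbor_5 = as.integer(n5),
    stringsAsFactors = FALSE)
  rownames(records) <- NULL
  structure(list(n_nucleotides = n, n_strands = length(oligos),
                 records = records, strand_of = strand_id,
                 local_index = local, strand_names = names(oligos),
                 strand_seqs = oligos),
            class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("<topology> %d nucleotides, %d strand(s): %s\n",
              x$n_nucleotides, x$n_strands,
              paste(sprintf("%s (%d nt)", x$strand_names,
                            vapply(x$strand_seqs, `[[`, integer(1), "length")),
                    collapse = ", ")))
  invisible(x)
}

#' Read an oxDNA topology file
#'
#' Expects the standard text dialect: a header line `N n_strands`
#' followed by one line per nucleotide giving its 1-based strand id, base
#' letter, and the global indices of its 3' and 5' backbone neighbours
#' (-1 for none). Each strand's neighbour chain must be a simple path;
#' strand sequences are reconstructed 5'->3' by following the chain from
#' the nucleotide with no 5' neighbour.
#'
#' @param path topology file path.
#' @param strand_names optional character vector naming the strands (in
#'   strand-id order); defaults to `strand1`, `strand2`, ...
#' @return A `topology` (see [make_topology()]).
#' @export
read_topology <- function(path, strand_names = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty topology file", call. = FALSE)
  hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[1]), "[ \t]+")[[1]]))
  if (length(hdr) != 2L || anyNA(hdr))
    stop("line 1: malformed topology header (expected 'N n_strands')",
         call. = FALSE)
  n <- hdr[1]; n_strands <- hdr[2]
  if (length(lines) - 1L != n)
    stop(sprintf("topology header announces %d nucleotides but file has %d record lines",
                 n, length(lines) - 1L), call. = FALSE)
  toks <- strsplit(trimws(lines[-1]), "[ \t]+")
  for (i in seq_len(n)) {
    tk <- toks[[i]]
    if (length(tk) < 4L)
      stop(sprintf("line %d: expected 'strand base neighbor_3 neighbor_5'",
                   i + 1L), call. = FALSE)
    if (!toupper(tk[2]) %in% c("A", "C", "G", "T"))
      stop(sprintf("line %d: unknown base letter '%s'", i + 1L, tk[2]),
           call. = FALSE)
  }
  strand_id <- vapply(toks, function(tk) as.integer(tk[1]), integer(1))
  base <- toupper(vapply(toks, `[`, character(1), 2L))
  n3 <- vapply(toks, function(tk) as.integer(tk[3]), integer(1))
  n5 <- vapply(toks, function(tk) as.integer(tk[4]), integer(1))
  if (anyNA(strand_id) || anyNA(n3) || anyNA(n5))
    stop("non-integer strand id or neighbour index in topology records",
         call. = FALSE)
  if (any(c(n3, n5) < -1L) || any(c(n3, n5) >= n))
    stop("neighbour index out of range in topology records", call. = FALSE)
  if (is.null(strand_names)) strand_names <- paste0("strand", seq_len(n_strands))
  if (length(strand_names) != n_strands)
    stop("'strand_names' must have one name per strand", call. = FALSE)

  local <- integer(n)
  seqs <- vector("list", n_strands)
  for (s in seq_len(n_strands)) {
    members <- which(strand_id == s) - 1L       # global 0-based
    if (!length(members))
      stop(sprintf("strand %d has no nucleotides", s), call. = FALSE)
    five_prime <- members[n5[members + 1L] == -1L]
    if (length(five_prime) != 1L)
      stop(sprintf("strand %d: neighbour chain is not a simple path (cycle or break)",
                   s), call. = FALSE)
    chain <- integer(0)
    cur <- five_prime
    while (cur != -1L) {
      if (length(chain) > length(members))
        stop(sprintf("strand %d: neighbour chain has a cycle", s),
             call. = FALSE)
      chain <- c(chain, cur)
      cur <- n3[cur + 1L]
    }
    if (!setequal(chain, members))
      stop(sprintf("strand %d: neighbour chain does not cover the strand", s),
           call. = FALSE)
    local[chain + 1L] <- seq_along(chain) - 1L
    seqs[[s]] <- oligomer(paste(base[chain + 1L], collapse = ""),
                          strand_names[s])
  }
  names(seqs) <- strand_names
  structure(list(n_nucleotides = n, n_strands = n_strands,
                 records = data.frame(strand_id = strand_id, base = base,
                                      neighbor_3 = n3, neighbor_5 = n5,
                                      stringsAsFactors = FALSE),
                 strand_of = strand_id, local_index = local,
                 strand_names = strand_names, strand_seqs = seqs),
            class = "topology")
}

#' Write a topology file
#'
#' @param topo a `topology`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(topo, path) {
  stopifnot(inherits(topo, "topology"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%d %d", topo$n_nucleotides, topo$n_strands), con)
  writeLines(sprintf("%d %s %d %d", topo$records$strand_id, topo$records$base,
                     topo$records$neighbor_3, topo$records$neighbor_5), con)
  invisible(path)
}

#' One recorded frame of hydrogen-bonded pairs
#'
#' @param step MD step stamp.
#' @param pairs two-column integer matrix of global nucleotide indices
#'   (0-based), one bonded pair per row; may have zero rows.
#' @return An `hb_frame` object.
#' @export
hb_frame <- function(step, pairs = matrix(integer(0), ncol = 2)) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (nrow(pairs) && any(pairs[, 1] == pairs[, 2]))
    stop("a nucleotide cannot pair with itself", call. = FALSE)
  structure(list(step = as.numeric(step), pairs = pairs), class = "hb_frame")
}

# Enforce one hydrogen bond per base: keep the first pair claiming an
# index, drop later ones with a warning.
.drop_duplicate_occupancy <- function(pairs, step) {
  seen <- integer(0)
  keep <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    if (any(pairs[i, ] %in% seen)) {
      warning(sprintf("frame at step %s: pair (%d, %d) re-uses an occupied base; dropped",
                      format(step, scientific = FALSE),
                      pairs[i, 1], pairs[i, 2]), call. = FALSE)
    } else {
      keep[i] <- TRUE
      seen <- c(seen, pairs[i, ])
    }
  }
  pairs[keep, , drop = FALSE]
}

#' Read a hydrogen-bond pair-list file
#'
#' One block per recorded frame: a header carrying the MD step stamp as
#' `t = <step>` or `# t = <step>` (both dialects occur in the wild),
#' followed by one bonded pair per line as two whitespace-separated global
#' nucleotide indices. Extra per-line columns (e.g. bond energies) are
#' ignored; other lines starting with `#` are comments. Step stamps must
#' be non-decreasing. A base listed in more than one pair of the same
#' frame keeps its first pair; later ones are dropped with a warning.
#'
#' @param path pair-list file path.
#' @param n_nucleotides optional; when given, indices are range-checked.
#' @return List of `hb_frame` objects in file order.
#' @export
read_hb_frames <- function(path, n_nucleotides = NULL) {
  lines <- readLines(path)
  frames <- list()
  step <- NULL
  rows <- list()
  flush <- function() {
    if (is.null(step)) return()
    pairs <- if (length(rows)) do.call(rbind, rows)
             else matrix(integer(0), ncol = 2)
    pairs <- .drop_duplicate_occupancy(pairs, step)
    frames[[length(frames) + 1L]] <<- hb_frame(step, pairs)
  }
  for (ln in seq_along(lines)) {
    raw <- trimws(lines[ln])
    if (!nzchar(raw)) next
    body <- sub("^#\\s*", "", raw)
    if (grepl("^t\\s*=\\s*[0-9]+$", body)) {
      new_step <- as.numeric(sub("^t\\s*=\\s*", "", body))
      if (!is.null(step) && new_step < step)
        stop(sprintf("line %d: step stamp %s decreases (previous %s)", ln,
                     format(new_step, scientific = FALSE),
                     format(step, scientific = FALSE)), call. = FALSE)
      flush()
      step <- new_step
      rows <- list()
      next
    }
    if (startsWith(raw, "#")) next
    tok <- strsplit(raw, "[ \t]+")[[1]]
    ij <- suppressWarnings(as.integer(tok[1:2]))
    if (length(tok) < 2L || anyNA(ij))
      stop(sprintf("line %d: expected two integer nucleotide indices, got '%s'",
                   ln, raw), call. = FALSE)
    if (is.null(step))
      stop(sprintf("line %d: pair listed before any 't = <step>' header", ln),
           call. = FALSE)
    if (!is.null(n_nucleotides) && any(ij < 0L | ij >= n_nucleotides))
      stop(sprintf("line %d: nucleotide index outside 0..%d", ln,
                   n_nucleotides - 1L), call. = FALSE)
    rows[[length(rows) + 1L]] <- ij
  }
  flush()
  frames
}

#' Write a hydrogen-bond pair-list file
#'
#' @param frames list of `hb_frame` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hb_frames <- function(frames, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (fr in frames) {
    writeLines(sprintf("t = %s", format(fr$step, scientific = FALSE)), con)
    if (nrow(fr$pairs))
      writeLines(sprintf("%d %d", fr$pairs[, 1], fr$pairs[, 2]), con)
  }
  invisible(path)
}

#' Read one configuration block
#'
#' Parses the standard configuration dialect: three header lines
#' (`t = <step>`, `b = Lx Ly Lz`, `E = Etot U K`) followed by one record
#' of floats per nucleotide (position, then orientation and velocity
#' columns, which are parsed and discarded -- only positions can matter
#' for geometric sanity checks).
#'
#' @param path configuration file path.
#' @param header_only if `TRUE`, stop after the three header lines.
#' @return List with `step`, `box` (length 3), `energies` (length 3) and,
#'   unless `header_only`, `positions` (n x 3 matrix).
#' @export
read_configuration <- function(path, header_only = FALSE) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("truncated configuration header", call. = FALSE)
  get_hdr <- function(i, key, n_expected) {
    body <- sub(paste0("^", key, "\\s*=\\s*"), "", trimws(lines[i]))
    if (identical(body, trimws(lines[i])))
      stop(sprintf("line %d: expected '%s = ...'", i, key), call. = FALSE)
    vals <- suppressWarnings(as.numeric(strsplit(body, "[ \t]+")[[1]]))
    if (length(vals) != n_expected || anyNA(vals))
      stop(sprintf("line %d: expected %d numeric value(s) after '%s ='",
                   i, n_expected, key), call. = FALSE)
    vals
  }
  out <- list(step = get_hdr(1, "t", 1), box = get_hdr(2, "b", 3),
              energies = get_hdr(3, "E", 3))
  if (header_only) return(out)
  body <- lines[-(1:3)]
  body <- body[nzchar(trimws(body))]
  recs <- lapply(seq_along(body), function(i) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(body[i]), "[ \t]+")[[1]]))
    if (length(vals) < 3L || anyNA(vals))
      stop(sprintf("line %d: truncated or non-numeric configuration record",
                   i + 3L), call. = FALSE)
    vals[1:3]
  })
  out$positions <- if (length(recs)) do.call(rbind, recs)
                   else matrix(numeric(0), ncol = 3)
  out
}

#' Write a minimal configuration file
#'
#' Emits the three header lines and one 15-column record per nucleotide.
#' Positions default to a line along x (placeholder geometry: this package
#' analyses bond lists, not 3D structure); orientation and velocity
#' columns are zero-filled.
#'
#' @param topo a `topology` (supplies the nucleotide count).
#' @param path output path.
#' @param step MD step stamp.
#' @param box box edge lengths (length-3 or scalar, simulation units).
#' @param positions optional n x 3 matrix of positions.
#' @return `path`, invisibly.
#' @export
write_configuration <- function(topo, path, step = 0, box = 40,
                                positions = NULL) {
  n <- topo$n_nucleotides
  if (length(box) == 1L) box <- rep(box, 3)
  if (is.null(positions))
    positions <- cbind(seq_len(n) * 0.6, 0, 0)
  stopifnot(nrow(positions) == n)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("t = %s", format(step, scientific = FALSE)),
               sprintf("b = %g %g %g", box[1], box[2], box[3]),
               "E = 0 0 0"), con)
  zeros <- paste(rep("0", 12), collapse = " ")
  writeLines(sprintf("%g %g %g %s", positions[, 1], positions[, 2],
                     positions[, 3], zeros), con)
  invisible(path)
}
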