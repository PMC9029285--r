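#' Canonical base complementarity
#'
#' Watson-Crick pairing over the DNA alphabet: A/T and C/G are the only
#' complementary pairs. The test is symmetric; self-pairing is never
#' canonical.
#'
#' @param b1,b2 single bases (character vectors are tested elementwise).
#' @return Logical, `TRUE` where the two bases can form a canonical
#'   hydrogen-bonded pair.
#' @examples
#' complementary("A", "T")   # TRUE
#' complementary("G", "T")   # FALSE
#' @export
complementary <- function(b1, b2) {
  b1 <- toupper(b1); b2 <- toupper(b2)
  bad <- setdiff(unique(c(b1, b2)), c("A", "C", "G", "T"))
  if (length(bad))
    stop("non-canonical base(s): ", paste(bad, collapse = ", "), call. = FALSE)
  partner <- c(A = "T", T = "A", C = "G", G = "C")
  unname(partner[b1] == b2)
}

# Pairing matrix between strand 1 (rows, 5'->3') and strand 2 written
# 3'->5' left-to-right (columns = reversed strand 2). Entry [i, j] is TRUE
# when base i of strand 1 is complementary to reversed-strand-2 base j;
# each relative position r corresponds to the diagonal i - j = r (0-based).
.pair_matrix <- function(s1, s2) {
  a <- strsplit(s1$seq, "")[[1]]
  b <- rev(strsplit(s2$seq, "")[[1]])
  partner <- c(A = "T", T = "A", C = "G", G = "C")
  outer(unname(partner[a]), b, "==")
}

.r_range <- function(L, l) seq.int(-l + 1L, L - 1L)

#' MCO and TMO at one relative position
#'
#' Holds strand 1 fixed (5'->3' left-to-right), writes strand 2 reversed
#' (3'->5' left-to-right, the antiparallel register) and slides it so that
#' its left end sits `r` positions to the right of strand 1's left end.
#' The total mixed overlap (TMO) is the number of opposing complementary
#' bases in that register; the maximum consecutive overlap (MCO) is the
#' longest run of consecutive complementary opposing bases.
#'
#' @param s1,s2 `oligomer` objects (or sequences coercible to one).
#' @param r integer relative position, in `[-l + 1, L - 1]` for strand
#'   lengths `L` (strand 1) and `l` (strand 2).
#' @return Named integer vector `c(mco = , tmo = )`; always
#'   `mco <= tmo <= min(L, l)`.
#' @examples
#' overlap_at("ACGT", "ACGT", 0)  # full self-complementary duplex: 4, 4
#' @export
overlap_at <- function(s1, s2, r) {
  s1 <- as_oligomer(s1); s2 <- as_oligomer(s2)
  r <- as.integer(r)
  if (length(r) != 1L || is.na(r) || r < -s2$length + 1L || r > s1$length - 1L)
    stop(sprintf("relative position r = %s outside admissible range [%d, %d]",
                 r, -s2$length + 1L, s1$length - 1L), call. = FALSE)
  i <- seq.int(max(0L, r), min(s1$length - 1L, r + s2$length - 1L))
  m <- .pair_matrix(s1, s2)[cbind(i + 1L, i - r + 1L)]
  runs <- rle(m)
  mco <- if (any(m)) max(runs$lengths[runs$values]) else 0L
  c(mco = as.integer(mco), tmo = as.integer(sum(m)))
}

#' Full overlap profile and the omega fitness statistic
#'
#' Computes MCO and TMO at every one of the `L + l - 1` admissible
#' antiparallel relative positions between two oligomers, the maximum
#' `omega = max_r MCO|r` used as the pair's hybridization fitness, and
#' every maximal complementary run of length omega (the omega-windows).
#' The maximum is frequently degenerate, so all windows are enumerated and
#' returned in deterministic `(r, start1)` order; window coordinates are
#' 0-based 5'->3' indices on each strand, with base `start1 + k` of strand
#' 1 pairing base `start2 + (length - 1) - k` of strand 2.
#'
#' @param s1,s2 `oligomer` objects (or sequences coercible to one).
#' @return An object of class `overlap_profile` with fields `pair`
#'   (the two oligomers), `mco_by_r` and `tmo_by_r` (integer vectors named
#'   by r), `omega`, and `windows` (data.frame with columns `r`, `start1`,
#'   `start2`, `length`).
#' @examples
#' oli <- builtin_oligomers()
#' overlap_profile(oli$p4, oli$res)
#' @export
overlap_profile <- function(s1, s2) {
  s1 <- as_oligomer(s1); s2 <- as_oligomer(s2)
  L <- s1$length; l <- s2$length
  m <- .pair_matrix(s1, s2)
  r_all <- .r_range(L, l)
  # split by diagonal: within a diagonal, column-major order is increasing i
  diag_id <- factor(row(m) - col(m), levels = r_all)
  diags <- split(as.vector(m), diag_id)
  per_r <- lapply(diags, function(v) {
    runs <- rle(v)
    c(if (any(v)) max(runs$lengths[runs$values]) else 0L, sum(v))
  })
  mco_by_r <- vapply(per_r, `[`, numeric(1), 1L)
  tmo_by_r <- vapply(per_r, `[`, numeric(1), 2L)
  storage.mode(mco_by_r) <- storage.mode(tmo_by_r) <- "integer"
  omega <- max(mco_by_r)

  windows <- data.frame(r = integer(), start1 = integer(),
                        start2 = integer(), length = integer())
  if (omega >= 1L) {
    for (k in which(mco_by_r == omega)) {
      r <- r_all[k]
      v <- diags[[k]]
      runs <- rle(v)
      ends <- cumsum(runs$lengths)
      hit <- which(runs$values & runs$lengths == omega)
      for (h in hit) {
        offset <- ends[h] - runs$lengths[h]       # 0-based within diagonal
        i0 <- max(0L, r) + offset                 # strand 1 start, 0-based
        j0 <- i0 - r                              # reversed strand 2 start
        windows <- rbind(windows, data.frame(
          r = r, start1 = i0, start2 = l - omega - j0, length = omega))
      }
    }
    windows <- windows[order(windows$r, windows$start1), , drop = FALSE]
    rownames(windows) <- NULL
  }
  structure(list(pair = list(s1, s2), mco_by_r = mco_by_r,
                 tmo_by_r = tmo_by_r, omega = as.integer(omega),
                 windows = windows),
            class = "overlap_profile")
}

#' @export
print.overlap_profile <- function(x, ...) {
  cat(sprintf("<overlap_profile> %s (%d nt) vs %s (%d nt)\n",
              x$pair[[1]]$name, x$pair[[1]]$length,
              x$pair[[2]]$name, x$pair[[2]]$length))
  cat(sprintf("  relative positions: %d   omega = %d   omega-windows: %d\n",
              length(x$mco_by_r), x$omega, nrow(x$windows)))
  if (nrow(x$windows)) print(x$windows)
  invisible(x)
}

#' Omega: the maximum consecutive overlap over all relative positions
#'
#' Convenience wrapper around [overlap_profile()] returning only the
#' scalar fitness statistic.
#'
#' @inheritParams overlap_profile
#' @return Non-negative integer.
#' @export
omega <- function(s1, s2) overlap_profile(s1, s2)$omega

#' Pairwise omega matrix for a set of oligomers
#'
#' @param oligos named list of `oligomer` objects.
#' @return Symmetric integer matrix of omega values, including the
#'   inter-strand self-interaction on the diagonal (two independent copies
#'   of the same sequence).
#' @export
omega_matrix <- function(oligos) {
  oligos <- lapply(oligos, as_oligomer)
  n <- length(oligos)
  nm <- vapply(oligos, `[[`, character(1), "name")
  out <- matrix(0L, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n)) for (j in i:n)
    out[i, j] <- out[j, i] <- omega(oligos[[i]], oligos[[j]])
  out
}

#' Independent brute-force check of omega
#'
#' Computes the length of the longest common substring between strand 1
#' and the reverse complement of strand 2 by exhaustive substring-set
#' comparison (all substrings of each length, longest first). An
#' antiparallel run of complementary opposing bases is exactly a common
#' substring with the reverse complement, so this must equal
#' `overlap_profile(s1, s2)$omega` for every input; the code path shares
#' nothing with the per-position profile scan and is kept as a
#' verification oracle.
#'
#' @inheritParams overlap_profile
#' @return Non-negative integer.
#' @export
omega_oracle <- function(s1, s2) {
  s1 <- as_oligomer(s1); s2 <- as_oligomer(s2)
  a <- s1$seq
  b <- revcomp(s2)
  for (k in seq.int(min(nchar(a), nchar(b)), 1L)) {
    subs_a <- unique(substring(a, 1:(nchar(a) - k + 1L), k:nchar(a)))
    subs_b <- unique(substring(b, 1:(nchar(b) - k + 1L), k:nchar(b)))
    if (length(intersect(subs_a, subs_b))) return(k)
  }
  0L
}

#' Export an overlap profile to TSV or JSON
#'
#' TSV output carries a comment header documenting the 0-based 5'->3'
#' coordinate convention, a per-position table (r, MCO, TMO), then the
#' window list. JSON output mirrors the in-memory structure.
#'
#' @param profile an `overlap_profile`.
#' @param path output file path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
export_profile <- function(profile, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(profile, "overlap_profile"))
  r <- as.integer(names(profile$mco_by_r))
  tab <- data.frame(r = r, MCO = unname(profile$mco_by_r),
                    TMO = unname(profile$tmo_by_r))
  if (format == "tsv") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c(
      sprintf("# overlap profile: %s vs %s", profile$pair[[1]]$name,
              profile$pair[[2]]$name),
      sprintf("# omega = %d", profile$omega),
      "# window coordinates are 0-based 5'->3' indices on each strand",
      "# r\tMCO\tTMO"), con)
    write.table(tab, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    writeLines("# windows: r\tstart1\tstart2\tlength", con)
    if (nrow(profile$windows))
      write.table(profile$windows, con, sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = FALSE)
  } else {
    jsonlite::write_json(list(
      pair = lapply(profile$pair, function(o) list(name = o$name, seq = o$seq)),
      omega = profile$omega,
      per_position = tab,
      windows = profile$windows), path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
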