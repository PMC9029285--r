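#' Design a predator strand with a prescribed omega against a resource
#'
#' Rejection sampling: each attempt embeds the reverse complement of a
#' randomly chosen window of the resource, of length `omega_target`, at a
#' random position inside a random background sequence of length `L`, then
#' keeps the candidate only if its full overlap profile against the
#' resource gives exactly the requested omega (the random background can
#' both create unintended longer windows and extend the planted one, so
#' every candidate is verified, never trusted). Deterministic for a given
#' `rng_seed`.
#'
#' The strand lengths are free, but competition setups conventionally use
#' `L` greater than the resource length so that several predators can
#' contend for the short strand.
#'
#' @param resource `oligomer` (or sequence) the design is scored against.
#' @param L length of the designed strand.
#' @param omega_target required omega between the design and the resource;
#'   must be in `[1, min(L, l)]` where `l` is the resource length.
#' @param rng_seed integer seed; the same seed always returns the same
#'   strand.
#' @param max_tries attempts before giving up.
#' @param name name of the returned oligomer.
#' @return An `oligomer` of length `L` whose profile against `resource`
#'   has omega equal to `omega_target` (verified internally).
#' @examples
#' res <- builtin_oligomers()$res
#' p <- design_sequence(res, L = 50, omega_target = 6, rng_seed = 7)
#' omega(p, res)  # 6
#' @export
design_sequence <- function(resource, L, omega_target, rng_seed,
                            max_tries = 2000L, name = "designed") {
  resource <- as_oligomer(resource)
  L <- as.integer(L); omega_target <- as.integer(omega_target)
  l <- resource$length
  if (omega_target < 1L || omega_target > min(L, l))
    stop(sprintf("omega_target = %d not achievable for lengths L = %d, l = %d (must be in [1, %d])",
                 omega_target, L, l, min(L, l)), call. = FALSE)
  bases <- c("A", "C", "G", "T")
  set.seed(as.integer(rng_seed))
  for (try in seq_len(max_tries)) {
    win_start <- sample.int(l - omega_target + 1L, 1L)  # 1-based
    insert <- revcomp(substr(resource$seq, win_start,
                             win_start + omega_target - 1L))
    pos <- sample.int(L - omega_target + 1L, 1L)        # 1-based
    background <- sample(bases, L, replace = TRUE)
    cand <- background
    cand[pos:(pos + omega_target - 1L)] <- strsplit(insert, "")[[1]]
    cand <- oligomer(paste(cand, collapse = ""), name)
    if (overlap_profile(cand, resource)$omega == omega_target) return(cand)
  }
  stop(sprintf("no sequence with omega = %d against '%s' found in %d tries",
               omega_target, resource$name, max_tries), call. = FALSE)
}
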