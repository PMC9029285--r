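#' Construct an oligomer
#'
#' An oligomer is a named, oriented single-stranded DNA sequence. The
#' sequence is stored 5'->3' and indexed 0-based throughout the package,
#' so that reported window coordinates can be read directly off a written
#' sequence. Only the four canonical bases are accepted: ambiguity codes
#' and RNA letters are errors, not silently coerced.
#'
#' @param seq character scalar over the alphabet A/C/G/T (lowercase is
#'   accepted and upper-cased).
#' @param name label for the strand (used in reports and pair keys).
#' @return An object of class `oligomer` with fields `name`, `seq` and
#'   `length`.
#' @examples
#' oligomer("ACGT", "probe")
#' @export
oligomer <- function(seq, name = "strand") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq))
    stop("'seq' must be a single non-empty string", call. = FALSE)
  seq <- toupper(seq)
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), c("A", "C", "G", "T"))
  if (length(bad)) {
    hint <- if ("U" %in% bad) " (RNA input? only DNA bases are supported)" else ""
    stop("non-canonical base(s) in sequence: ", paste(bad, collapse = ", "),
         hint, call. = FALSE)
  }
  structure(list(name = as.character(name), seq = seq, length = nchar(seq)),
            class = "oligomer")
}

#' @export
print.oligomer <- function(x, ...) {
  cat(sprintf("<oligomer> %s: %d nt\n  5'-%s-3'\n", x$name, x$length, x$seq))
  invisible(x)
}

as_oligomer <- function(x, name = "strand") {
  if (inherits(x, "oligomer")) x else oligomer(x, name)
}

#' Reverse complement of a DNA sequence
#'
#' @param x an `oligomer` or a plain character sequence.
#' @return A character scalar, the reverse complement read 5'->3'.
#' @export
revcomp <- function(x) {
  s <- if (inherits(x, "oligomer")) x$seq else as_oligomer(x)$seq
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Read oligomers from a FASTA file
#'
#' Headers are split at whitespace; the first token is the oligomer name.
#' Wrapped and single-line records are both accepted.
#'
#' @param path path to a FASTA file.
#' @return Named list of `oligomer` objects, in file order.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  nm <- vapply(strsplit(names(set), "[ \t]+"), `[[`, character(1), 1L)
  out <- lapply(seq_along(set), function(i)
    oligomer(as.character(set[[i]]), nm[i]))
  names(out) <- nm
  out
}

#' Write oligomers to a FASTA file
#'
#' @param oligos list of `oligomer` objects (or sequences coercible to one).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(oligos, path) {
  oligos <- lapply(oligos, as_oligomer)
  set <- Biostrings::DNAStringSet(vapply(oligos, `[[`, character(1), "seq"))
  names(set) <- vapply(oligos, `[[`, character(1), "name")
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Bundled predator/resource strand set
#'
#' The three strands used throughout the package's examples and presets:
#' a 20-nt resource `res` and two 50-nt predators, `p4` designed for a low
#' maximum consecutive overlap with the resource (omega = 4) and `p10` for
#' a high one (omega = 10).
#'
#' @return Named list of `oligomer` objects: `p4`, `p10`, `res`.
#' @examples
#' omega(builtin_oligomers()$p10, builtin_oligomers()$res)
#' @export
builtin_oligomers <- function() {
  read_fasta(system.file("extdata", "predator_prey.fasta",
                         package = "strandfit", mustWork = TRUE))
}
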