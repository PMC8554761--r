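#' Construct a 10-base self-complementary duplex sequence
#'
#' A duplex here is formed by two copies of one self-complementary
#' 10-base strand, so a single string fully identifies the system. The
#' four named presets (`"AT-all"`, `"GC-end"`, `"GC-core"`, `"GC-mix"`)
#' carry their canonical strings; a custom sequence may be supplied
#' directly and must be self-complementary.
#'
#' @param x a preset name, a 10-base string over `A`, `C`, `G`, `T`
#'   (5'->3'), or a path to a single-record FASTA file.
#' @return An object of class `duplex_sequence` with fields `name` and
#'   `bases`.
#' @examples
#' duplex_sequence("AT-all")
#' duplex_sequence("ATGATATCAT")
#' @export
duplex_sequence <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (x %in% names(.PRESET_SEQUENCES)) {
    bases <- .PRESET_SEQUENCES[[x]]
    name <- x
  } else if (grepl("^[ACGTacgt]+$", x)) {
    bases <- toupper(x)
    hit <- names(.PRESET_SEQUENCES)[.PRESET_SEQUENCES == bases]
    name <- if (length(hit)) hit[1L] else "custom"
  } else {
    bases <- read_sequence_fasta(x)
    hit <- names(.PRESET_SEQUENCES)[.PRESET_SEQUENCES == bases]
    name <- if (length(hit)) hit[1L] else "custom"
  }
  if (nchar(bases) != 10L)
    stop("duplex sequences must be exactly 10 bases, got ", nchar(bases))
  if (reverse_complement(bases) != bases)
    stop("sequence ", bases, " is not self-complementary")
  structure(list(name = name, bases = bases), class = "duplex_sequence")
}

#' Reverse complement of a DNA string
#'
#' @param bases character scalar over `A`, `C`, `G`, `T`.
#' @return The reverse complement, 5'->3'.
#' @export
reverse_complement <- function(bases) {
  comp <- chartr("ACGT", "TGCA", toupper(bases))
  paste(rev(strsplit(comp, "")[[1L]]), collapse = "")
}

# Read a single-record FASTA. Uses Biostrings when available, otherwise a
# minimal reader sufficient for plain single-record files.
read_sequence_fasta <- function(path) {
  if (!file.exists(path))
    stop("not a recognised sequence, preset name or file: ", path)
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    set <- Biostrings::readDNAStringSet(path)
    if (length(set) != 1L)
      stop("expected a single-record FASTA, found ", length(set), " records")
    return(toupper(as.character(set[[1L]])))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!startsWith(lines[1L], ">"))
    stop("not a FASTA file: ", path)
  if (any(startsWith(lines[-1L], ">")))
    stop("expected a single-record FASTA")
  toupper(paste(lines[-1L], collapse = ""))
}

#' @export
print.duplex_sequence <- function(x, ...) {
  cat("<duplex_sequence> ", x$name, ": 5'-", x$bases, "-3' (self-complementary)\n",
      sep = "")
  invisible(x)
}

# TRUE where base a (strand 1) can Watson-Crick pair with base b (strand 2).
.wc_pair <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G")
}

# Intact-contact pattern of a register offset k: logical over strand-1
# positions i = 1..10, TRUE where a geometric partner exists (strand-2 base
# j = 11 - i + k) and the pairing is Watson-Crick.
register_pairing <- function(seq, k) {
  b <- strsplit(seq$bases, "")[[1L]]
  i <- 1:10
  j <- 11L - i + k
  ok <- j >= 1L & j <= 10L
  ok[ok] <- .wc_pair(b[i[ok]], b[j[ok]])
  ok
}

# TRUE if the sequence has a central G:C core (native pairs 5 and 6 are G:C),
# the precondition for the F4 frayed macrostate.
has_gc_core <- function(seq) {
  b <- strsplit(seq$bases, "")[[1L]]
  all(b[5:6] %in% c("G", "C"))
}
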