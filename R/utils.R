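# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

# Deterministic child seed in [0, 2^31): mixes a run seed with a string tag so
# each (sample, chromosome) stream is independent but reproducible.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  (as.numeric(seed) * 69069 + h * 2654435761) %% 2147483647
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

subseq_chr <- function(x, start, end) {
  substr(x, max(1L, start), min(nchar(x), end))
}

# replace bases of `x` at [at, at+nchar(with)-1] with `with`
splice_str <- function(x, at, with) {
  if (nchar(with) == 0) return(x)
  paste0(substr(x, 1, at - 1), with, substr(x, at + nchar(with), nchar(x)))
}

is_transition_pair <- function(ref, alt) {
  (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
    (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
}
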