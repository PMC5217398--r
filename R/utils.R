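# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# Evaluate `code` under a fixed RNG state, restoring the caller's stream.
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# n random DNA sequences of the given lengths (uses the current RNG stream).
randomDNA <- function(lengths) {
  total <- sum(lengths)
  bases <- sample(DNA_BASES, total, replace = TRUE)
  ends <- cumsum(lengths)
  starts <- ends - lengths + 1L
  vapply(seq_along(lengths),
         function(i) paste(bases[starts[i]:ends[i]], collapse = ""),
         character(1))
}

# Coerce a transcript set (named DNAStringSet or named character) to a named
# uppercase character vector, enforcing unique non-empty ids.
asTranscriptChar <- function(transcripts) {
  if (is(transcripts, "DNAStringSet")) {
    seqs <- as.character(transcripts)
  } else if (is.character(transcripts)) {
    seqs <- transcripts
  } else {
    stop("transcripts must be a named DNAStringSet or named character vector")
  }
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("transcripts must be named by gene id")
  }
  if (anyDuplicated(names(seqs))) stop("gene ids must be unique")
  toupper(seqs)
}

# Derive a child seed from a base seed, staying within 32-bit integer range.
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1000003 + k) %% 2147483647)
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
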