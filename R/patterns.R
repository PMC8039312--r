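# Constant-weight binary spatial patterns and spatiotemporal context
# sequences.
#
# A spatial pattern is a binary vector of length n with a fixed number of
# ones (half of n by default).  A pattern set holds k such patterns with
# every pairwise Hamming distance exactly equal to a target hd; sets of
# similar-but-distinct patterns like these are the raw material for
# "contextual" input sequences.

#' Generate a set of constant-weight binary patterns at exact Hamming distance
#'
#' Builds `k` binary vectors of length `n`, each with exactly `ones_count`
#' ones, such that every unordered pair differs in exactly `hd` positions.
#'
#' The construction is a shared-core design: a random core of
#' `ones_count - hd/2` positions is set to 1 in all patterns, and each
#' pattern additionally receives its own disjoint random block of `hd/2`
#' unique ones.  Any two patterns then differ exactly in their two private
#' blocks, so every pairwise Hamming distance is `hd` by construction.
#'
#' @param n Pattern length (number of input neurons). Must be positive.
#' @param k Number of patterns.
#' @param hd Target pairwise Hamming distance; must be even (constant-weight
#'   vectors can only differ in an even number of positions). Ignored when
#'   `k == 1`.
#' @param ones_count Number of ones per pattern; defaults to `n/2`.
#' @param seed Optional integer seed; the generator is a pure function of it.
#' @return An object of class `pattern_set`: a list with `patterns` (a
#'   `k x n` 0/1 integer matrix, one pattern per row), `n`, `k`, `hd`,
#'   `ones_count` and `seed`.
#' @examples
#' ps <- generate_pattern_set(n = 120, k = 5, hd = 10, seed = 1)
#' rowSums(ps$patterns)                     # all 60
#' hamming_distance(ps$patterns[1, ], ps$patterns[2, ])  # 10
#' @export
generate_pattern_set <- function(n, k, hd = 10L, ones_count = n %/% 2L,
                                 seed = NULL) {
  stopifnot(length(n) == 1L, length(k) == 1L, n >= 1L, k >= 1L)
  if (ones_count < 0L || ones_count > n) {
    stop("`ones_count` must lie in [0, n]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))

  if (k == 1L) {
    ones <- sample.int(n, ones_count)
    pat <- matrix(0L, 1L, n)
    pat[1L, ones] <- 1L
  } else {
    if (hd %% 2L != 0L) {
      stop("`hd` must be even: two vectors with the same number of ones ",
           "always differ in an even number of positions", call. = FALSE)
    }
    half <- hd %/% 2L
    core_size <- ones_count - half
    if (core_size < 0L) {
      stop("infeasible parameters: need ones_count >= hd/2 ",
           "(got ones_count = ", ones_count, ", hd = ", hd, ")",
           call. = FALSE)
    }
    if (core_size + k * half > n) {
      stop("infeasible parameters: shared core plus ", k,
           " disjoint blocks of ", half, " ones exceed pattern length ", n,
           call. = FALSE)
    }
    positions <- sample.int(n, core_size + k * half)
    core <- positions[seq_len(core_size)]
    blocks <- matrix(positions[-seq_len(core_size)], nrow = k, byrow = TRUE)
    pat <- matrix(0L, k, n)
    for (i in seq_len(k)) {
      pat[i, c(core, blocks[i, ])] <- 1L
    }
  }
  structure(
    list(patterns = pat, n = as.integer(n), k = as.integer(k),
         hd = if (k == 1L) NA_integer_ else as.integer(hd),
         ones_count = as.integer(ones_count),
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
    class = "pattern_set"
  )
}

#' @export
print.pattern_set <- function(x, ...) {
  cat("<pattern_set> ", x$k, " patterns of length ", x$n,
      ", ", x$ones_count, " ones each",
      if (!is.na(x$hd)) paste0(", pairwise Hamming distance ", x$hd),
      "\n", sep = "")
  invisible(x)
}

#' Hamming distance between two equal-length binary vectors
#'
#' @param a,b Binary vectors (0/1) of equal length.
#' @return Integer count of positions where `a` and `b` differ.
#' @export
hamming_distance <- function(a, b) {
  if (length(a) != length(b)) {
    stop("vectors must have equal length", call. = FALSE)
  }
  sum(a != b)
}

#' Cosine similarity between two vectors
#'
#' For two constant-weight binary patterns with `m` ones and overlap `v`
#' (shared ones), the cosine is `v / m`; with the defaults used here
#' (60 ones, Hamming distance 10, hence overlap 55) it is 55/60 = 0.9167.
#'
#' @param a,b Numeric (or binary) vectors of equal length and nonzero norm.
#' @return The cosine of the angle between `a` and `b`, in \[-1, 1\].
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) {
    stop("vectors must have equal length", call. = FALSE)
  }
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    stop("cosine similarity undefined for zero-norm vectors", call. = FALSE)
  }
  sum(a * b) / (na * nb)
}

new_input_sequence <- function(frames, context) {
  stopifnot(is.matrix(frames), context %in% c("same", "different"))
  structure(list(frames = frames, context = context,
                 t_len = nrow(frames), n = ncol(frames)),
            class = "input_sequence")
}

#' @export
print.input_sequence <- function(x, ...) {
  cat("<input_sequence> ", x$t_len, " frames of length ", x$n,
      ", context = ", x$context, "\n", sep = "")
  invisible(x)
}

#' Same-context sequence: one spatial pattern repeated
#'
#' @param p A spatial pattern: a binary vector, or a `pattern_set` row index
#'   is not accepted — pass `ps$patterns[i, ]`.
#' @param t_len Number of time frames (default 5).
#' @return An `input_sequence` whose `t_len` frames are all identical to `p`,
#'   with `context = "same"`.
#' @export
make_same_context_sequence <- function(p, t_len = 5L) {
  stopifnot(t_len >= 1L)
  p <- as.integer(p)
  frames <- matrix(rep(p, each = t_len), nrow = t_len)
  new_input_sequence(frames, "same")
}

#' Different-context sequence: a walk through distinct similar patterns
#'
#' In canonical mode the frames are the first five patterns of the set in
#' order — the standard different-context training condition.  In randomized
#' mode the first four frames are drawn at random from the set (without
#' replacement by default) and the final frame is a fixed pattern
#' (`final_frame`, the fifth by default).
#'
#' @param ps A `pattern_set` with at least 5 patterns.
#' @param mode `"canonical"` (frames = patterns 1..5 in order) or
#'   `"randomized"`.
#' @param seed Optional seed for randomized mode.
#' @param replace Sample the first four frames with replacement? Default
#'   `FALSE` (four distinct patterns of the five).
#' @param final_frame Index of the pattern used as the fifth frame in
#'   randomized mode. Default 5.
#' @return An `input_sequence` with `context = "different"`.
#' @export
make_different_context_sequence <- function(ps,
                                            mode = c("canonical",
                                                     "randomized"),
                                            seed = NULL, replace = FALSE,
                                            final_frame = 5L) {
  mode <- match.arg(mode)
  stopifnot(inherits(ps, "pattern_set"))
  if (ps$k < 5L) {
    stop("pattern set too small: different-context sequences need at least ",
         "5 patterns, got ", ps$k, call. = FALSE)
  }
  if (mode == "canonical") {
    idx <- 1:5
  } else {
    if (!is.null(seed)) set.seed(as.integer(seed))
    idx <- c(sample.int(ps$k, 4L, replace = replace), as.integer(final_frame))
  }
  new_input_sequence(ps$patterns[idx, , drop = FALSE], "different")
}

#' Write / read patterns and sequences as plain-text matrices
#'
#' Patterns are stored one frame per row, space-separated 0/1, with a JSON
#' sidecar (`<path>.json`) recording the metadata (n, k, hd, ones_count,
#' seed, context).  `read_pattern_set()` and `read_input_sequence()` invert
#' the corresponding writers.
#'
#' @param x A `pattern_set` or `input_sequence`.
#' @param path Path of the text matrix file to write or read.
#' @return Writers return `path` invisibly; readers return the reconstructed
#'   object.
#' @name pattern_io
NULL

write_binary_matrix <- function(m, path) {
  lines <- apply(m, 1L, paste, collapse = " ")
  writeLines(lines, path)
  invisible(path)
}

read_binary_matrix <- function(path) {
  lines <- readLines(path)
  m <- do.call(rbind, lapply(strsplit(lines, "\\s+"), as.integer))
  storage.mode(m) <- "integer"
  m
}

#' @rdname pattern_io
#' @export
write_pattern_set <- function(x, path) {
  stopifnot(inherits(x, "pattern_set"))
  write_binary_matrix(x$patterns, path)
  meta <- x[c("n", "k", "hd", "ones_count", "seed")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       na = "null")
  invisible(path)
}

#' @rdname pattern_io
#' @export
read_pattern_set <- function(path) {
  m <- read_binary_matrix(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(
    list(patterns = m, n = ncol(m), k = nrow(m),
         hd = if (is.null(meta$hd)) NA_integer_ else as.integer(meta$hd),
         ones_count = as.integer(meta$ones_count),
         seed = if (is.null(meta$seed)) NA_integer_
                else as.integer(meta$seed)),
    class = "pattern_set"
  )
}

#' @rdname pattern_io
#' @export
write_input_sequence <- function(x, path) {
  stopifnot(inherits(x, "input_sequence"))
  write_binary_matrix(x$frames, path)
  jsonlite::write_json(list(context = x$context, t_len = x$t_len, n = x$n),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname pattern_io
#' @export
read_input_sequence <- function(path) {
  m <- read_binary_matrix(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new_input_sequence(m, meta$context)
}
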